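# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (loops, enumeration) so they cannot share a defect with
# the vectorized implementations they check.

make_genome <- function(id, copies, marine = FALSE, common_marine = FALSE) {
  structure(list(genome_id = id, copy_numbers = copies, marine = marine,
                 common_marine = common_marine), class = "genome_model")
}

random_hits <- function(n, n_seq = 5, n_prof = 4) {
  data.frame(
    sequence_id = sample(sprintf("s%02d", seq_len(n_seq)), n, replace = TRUE),
    profile_id = sample(sprintf("P%02d", seq_len(n_prof)), n, replace = TRUE),
    e_value = signif(runif(n, 1e-30, 1e-2), 3),
    bit_score = round(runif(n, 10, 90), 1),
    stringsAsFactors = FALSE)
}

# exhaustive scan with the documented tie-break
brute_best <- function(hits) {
  best <- 1
  for (i in seq_len(nrow(hits))[-1]) {
    if (hits$bit_score[i] > hits$bit_score[best]) best <- i
    else if (hits$bit_score[i] == hits$bit_score[best]) {
      if (hits$e_value[i] < hits$e_value[best]) best <- i
      else if (hits$e_value[i] == hits$e_value[best] &&
               hits$profile_id[i] < hits$profile_id[best]) best <- i
    }
  }
  hits$profile_id[best]
}

brute_reciprocal <- function(initial, full_db_best) {
  out <- list()
  for (f in names(initial)) {
    kept <- character(0)
    for (s in unique(initial[[f]])) {
      if (full_db_best[[s]] == f) kept <- c(kept, s)
    }
    out[[f]] <- kept
  }
  out
}

brute_sparsity <- function(mat, k) {
  keep_r <- rep(TRUE, nrow(mat))
  keep_c <- rep(TRUE, ncol(mat))
  for (i in seq_len(nrow(mat))) if (sum(mat[i, ] == 0) > k) keep_r[i] <- FALSE
  for (j in seq_len(ncol(mat))) if (sum(mat[, j] == 0) > k) keep_c[j] <- FALSE
  mat[keep_r, keep_c, drop = FALSE]
}

# naive complete-linkage agglomeration; returns sorted merge heights
brute_complete_heights <- function(m) {
  clusters <- lapply(seq_len(nrow(m)), identity)
  d <- as.matrix(dist(m))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_h <- Inf
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (a >= b) next
        h <- max(d[clusters[[a]], clusters[[b]]])
        if (h < best_h) {
          best_h <- h
          best <- c(a, b)
        }
      }
    }
    heights <- c(heights, best_h)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1]] <- merged
  }
  sort(heights)
}

# site x family lognormal matrix with a given CV, optional per-group effects
lognormal_sites <- function(n_per_group, n_families, cv = 0.3,
                            effect = 1, base_mean = 1) {
  sdlog <- sqrt(log(1 + cv^2))
  n <- 2 * n_per_group
  m <- matrix(rlnorm(n * n_families, meanlog = log(base_mean), sdlog = sdlog),
              nrow = n,
              dimnames = list(sprintf("S%03d", seq_len(n)),
                              sprintf("F%02d", seq_len(n_families))))
  m[seq_len(n_per_group), ] <- m[seq_len(n_per_group), ] * effect
  md <- data.frame(site_id = rownames(m),
                   habitat = rep(c("open_ocean", "coastal"),
                                 each = n_per_group),
                   stringsAsFactors = FALSE)
  list(matrix = m, metadata = md)
}
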