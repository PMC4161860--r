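# Synthetic-data generator. Forward model for the whole pipeline: genome
# copy-number matrices (zero-inflated negative binomial, single-copy marker),
# community-weighted Poisson read sampling per site, clan-style hit confusion,
# HMMER3-format hit tables and site metadata. Everything is deterministic
# given the master seed; each operation uses its own derived RNG stream.

MARKER_DEFAULT <- "RNA_pol_Rpb2_6"

#' Default per-family generative parameters
#'
#' Builds zero-inflated negative-binomial parameters for the bundled 34-family
#' set (see [gos_family_counts()]). Family means are the published per-genome
#' averages; zero inflation and dispersion defaults are chosen so that copy
#' numbers show the high between-genome variance typical of detoxification
#' families (many zeros, CVs roughly 50-350%).
#'
#' @param zero_inflation Probability of structural zero (default 0.25).
#' @param dispersion Negative-binomial size parameter (default 0.5).
#' @return Data frame with columns `family`, `zero_inflation`, `mean`,
#'   `dispersion`. The marker family is present with mean 1 but is always
#'   drawn as exactly one copy by [generate_genomes()].
#' @export
default_family_params <- function(zero_inflation = 0.25, dispersion = 0.5) {
  fam <- gos_family_counts()
  data.frame(
    family = fam$family,
    zero_inflation = ifelse(fam$family == MARKER_DEFAULT, 0, zero_inflation),
    # mean of the NB component; overall mean = (1 - pi) * mean
    mean = ifelse(fam$family == MARKER_DEFAULT, 1, fam$genome_mean / (1 - zero_inflation)),
    dispersion = dispersion,
    stringsAsFactors = FALSE
  )
}

#' Generate synthetic genome copy-number models
#'
#' Copy numbers are drawn per family from a zero-inflated negative binomial:
#' with probability `zero_inflation` the count is 0, otherwise
#' `rnbinom(mu = mean, size = dispersion)`. The single-copy marker family is
#' fixed at exactly 1 copy per genome unless `marker_perturb > 0`, in which
#' case that fraction of genomes (in expectation) carries 2 copies — useful to
#' emulate the near-single-copy behaviour of rpoB in real genomes.
#'
#' @param n_genomes Number of genomes (>= 1).
#' @param family_params Data frame with columns `family`, `zero_inflation`,
#'   `mean`, `dispersion` (see [default_family_params()]).
#' @param seed Master seed.
#' @param marker_family Marker family id (fixed at one copy).
#' @param marker_perturb Probability that a genome carries a second marker
#'   copy (default 0: exactly single copy).
#' @param marine_fraction,common_marine_fraction Fractions of genomes flagged
#'   marine / common-marine (common-marine implies marine).
#' @return List of genome models; each has `genome_id`, `copy_numbers` (named
#'   integer vector), `marine`, `common_marine`.
#' @export
generate_genomes <- function(n_genomes, family_params = default_family_params(),
                             seed = 1L, marker_family = MARKER_DEFAULT,
                             marker_perturb = 0,
                             marine_fraction = 0.2, common_marine_fraction = 0.05) {
  stopifnot(n_genomes >= 1)
  fp <- as.data.frame(family_params)
  req <- c("family", "zero_inflation", "mean", "dispersion")
  if (!all(req %in% names(fp))) stop("family_params must have columns: ",
                                     paste(req, collapse = ", "))
  if (any(fp$mean < 0)) stop("family means must be >= 0")
  if (any(fp$dispersion <= 0)) stop("dispersion must be > 0")
  if (any(fp$zero_inflation < 0 | fp$zero_inflation > 1))
    stop("zero_inflation must be in [0, 1]")
  if (!marker_family %in% fp$family)
    fp <- rbind(fp, data.frame(family = marker_family, zero_inflation = 0,
                               mean = 1, dispersion = 1))
  with_stream(seed, "generate_genomes", {
    n_fam <- nrow(fp)
    counts <- matrix(0L, nrow = n_genomes, ncol = n_fam,
                     dimnames = list(NULL, fp$family))
    for (j in seq_len(n_fam)) {
      nb <- stats::rnbinom(n_genomes, mu = fp$mean[j], size = fp$dispersion[j])
      zero <- stats::runif(n_genomes) < fp$zero_inflation[j]
      counts[, j] <- ifelse(zero, 0L, as.integer(nb))
    }
    counts[, marker_family] <- 1L
    if (marker_perturb > 0) {
      extra <- stats::runif(n_genomes) < marker_perturb
      counts[extra, marker_family] <- 2L
    }
    marine <- stats::runif(n_genomes) < marine_fraction
    common <- marine & (stats::runif(n_genomes) <
                          common_marine_fraction / max(marine_fraction, 1e-12))
    ids <- sprintf("G%04d", seq_len(n_genomes))
    lapply(seq_len(n_genomes), function(i) {
      structure(list(genome_id = ids[i],
                     copy_numbers = counts[i, ],
                     marine = marine[i],
                     common_marine = common[i]),
                class = "genome_model")
    })
  })
}

#' Stack genome models into a genome x family count matrix
#'
#' @param genomes List of genome models from [generate_genomes()].
#' @return Integer matrix, rownames genome ids, colnames family ids.
#' @export
genomes_to_matrix <- function(genomes) {
  stopifnot(length(genomes) >= 1)
  fams <- names(genomes[[1]]$copy_numbers)
  m <- t(vapply(genomes, function(g) g$copy_numbers[fams], numeric(length(fams))))
  rownames(m) <- vapply(genomes, `[[`, "", "genome_id")
  colnames(m) <- fams
  storage.mode(m) <- "integer"
  m
}

#' Genome metadata table from genome models
#'
#' @param genomes List of genome models.
#' @return Data frame with `genome_id`, `marine`, `common_marine`.
#' @export
genomes_metadata <- function(genomes) {
  data.frame(genome_id = vapply(genomes, `[[`, "", "genome_id"),
             marine = vapply(genomes, `[[`, NA, "marine"),
             common_marine = vapply(genomes, `[[`, NA, "common_marine"),
             stringsAsFactors = FALSE)
}

#' Construct a community profile
#'
#' @param site_id Site identifier.
#' @param weights Named numeric vector of genome proportions (must sum to 1).
#' @param depth Expected marker-scale read count (> 0).
#' @param habitat_effects Named multiplicative factors per family (> 0);
#'   families not named get factor 1. The marker is never affected.
#' @return A `community_profile` object.
#' @export
community_profile <- function(site_id, weights, depth,
                              habitat_effects = numeric(0)) {
  if (length(weights) == 0) stop("empty community: no genome weights")
  if (abs(sum(weights) - 1) > 1e-9) stop("community weights must sum to 1")
  if (depth <= 0) stop("depth must be > 0")
  if (length(habitat_effects) && any(habitat_effects <= 0))
    stop("habitat effects must be > 0")
  structure(list(site_id = site_id, weights = weights, depth = depth,
                 habitat_effects = habitat_effects),
            class = "community_profile")
}

#' Construct a confusion model for clan-level cross-matching
#'
#' Models the chance that a sequence truly belonging to one family best-matches
#' a related profile when scanned against the full profile database (as happens
#' within Pfam clans, e.g. peroxiredoxin/thioredoxin).
#'
#' @param families Family ids.
#' @param diagonal Named (or scalar) probability that a hit's full-database
#'   best profile is its true family; off-diagonal mass is spread uniformly
#'   over the other families. Default 1 (no confusion).
#' @param marker_family Exempt family (always diagonal 1).
#' @return A row-stochastic matrix, rows = true family, cols = reported family.
#' @export
confusion_model <- function(families, diagonal = 1,
                            marker_family = MARKER_DEFAULT) {
  k <- length(families)
  d <- rep(diagonal, length.out = k)
  if (!is.null(names(diagonal))) {
    d <- rep(1, k)
    names(d) <- families
    d[names(diagonal)] <- diagonal
  }
  names(d) <- families
  if (marker_family %in% families) d[marker_family] <- 1
  if (any(d < 0 | d > 1)) stop("diagonal probabilities must be in [0, 1]")
  m <- matrix(0, k, k, dimnames = list(families, families))
  for (i in seq_len(k)) {
    m[i, ] <- if (k > 1) (1 - d[i]) / (k - 1) else 0
    m[i, i] <- d[i]
  }
  m
}

#' Simulate per-site family read counts from a community
#'
#' The expected count of family f is
#' `depth * sum_g w_g copy_g(f) * effect_f / sum_g w_g copy_g(marker)`,
#' i.e. `depth` plays the role of the expected marker read count, so the
#' family/marker count ratio estimates the community-average copy number.
#' Observed counts are Poisson, then redistributed among families by the
#' confusion model (total conserved exactly; marker exempt).
#'
#' @param community A [community_profile()].
#' @param genomes List of genome models covering all weighted genomes.
#' @param confusion Confusion matrix from [confusion_model()] or NULL.
#' @param seed Master seed.
#' @param marker_family Marker family id.
#' @return List with `counts` (named integer vector, the site's count-matrix
#'   row) and `truth` (list: site_id, expected per-genome abundance per
#'   family, expected counts).
#' @export
generate_site_counts <- function(community, genomes, confusion = NULL,
                                 seed = 1L, marker_family = MARKER_DEFAULT) {
  stopifnot(inherits(community, "community_profile"))
  gm <- genomes_to_matrix(genomes)
  w <- community$weights
  missing <- setdiff(names(w), rownames(gm))
  if (length(missing)) stop("genomes absent from models: ",
                            paste(missing, collapse = ", "))
  fams <- colnames(gm)
  mix <- as.numeric(w %*% gm[names(w), , drop = FALSE]) # sum_g w_g copy_g(f)
  names(mix) <- fams
  marker_mix <- mix[marker_family]
  if (!is.finite(marker_mix) || marker_mix <= 0)
    stop("community has zero expected marker abundance")
  eff <- rep(1, length(fams)); names(eff) <- fams
  he <- community$habitat_effects
  if (length(he)) eff[names(he)] <- he
  eff[marker_family] <- 1
  lambda <- community$depth * mix * eff / marker_mix
  obs <- with_stream(seed, paste0("site_counts:", community$site_id), {
    x <- stats::rpois(length(lambda), lambda)
    names(x) <- fams
    if (!is.null(confusion)) x <- confuse_counts(x, confusion, seed,
                                                 community$site_id)
    x
  })
  truth <- list(site_id = community$site_id,
                expected_abundance = mix * eff / marker_mix,
                expected_counts = lambda,
                seed = seed)
  list(counts = obs, truth = truth)
}

# Redistribute counts among families by a row-stochastic confusion matrix.
# Multinomial per true family; conserves the per-site total exactly.
confuse_counts <- function(counts, confusion, seed, site_id) {
  fams <- names(counts)
  if (!all(fams %in% rownames(confusion)))
    stop("confusion model does not cover all families")
  out <- stats::setNames(integer(length(fams)), fams)
  for (f in fams) {
    n <- counts[[f]]
    if (n == 0) next
    draw <- stats::rmultinom(1, n, confusion[f, fams])[, 1]
    out <- out + draw
  }
  out
}

#' Write synthetic HMMER3-style hit tables for one site
#'
#' Emits one synthetic protein record per counted read: an initial-search
#' table (per-target "tblout" layout) in which the record is found by its
#' assigned family's profile, and a full-database scan table in which each
#' record's best-scoring profile may differ, drawn from the confusion model.
#' Downstream, [reciprocal_filter()] then retains a hit iff the full-database
#' best profile equals the initial family, so retention per family converges
#' to the confusion diagonal.
#'
#' @param site_counts Named integer vector of per-family counts for one site.
#' @param confusion Confusion matrix (or NULL for none).
#' @param score_params List with `score_mean`, `score_sd`, `cutoff` — bit
#'   scores are drawn N(score_mean, score_sd) truncated at `cutoff`.
#' @param seed Master seed.
#' @param dir Output directory.
#' @param site_id Site identifier (file name stem).
#' @param marker_family Marker family id (never confused).
#' @return Invisible list with paths `initial`, `fulldb`, `truth` and the
#'   ground-truth assignment data frame.
#' @export
generate_hit_tables <- function(site_counts, confusion = NULL,
                                score_params = list(score_mean = 80,
                                                    score_sd = 15, cutoff = 25),
                                seed = 1L, dir = ".", site_id = "site",
                                marker_family = MARKER_DEFAULT) {
  stopifnot(all(is.finite(site_counts)), all(site_counts >= 0))
  fams <- names(site_counts)
  n <- sum(site_counts)
  truth <- with_stream(seed, paste0("hit_tables:", site_id), {
    if (n == 0) {
      data.frame(sequence_id = character(0), initial_family = character(0),
                 fulldb_best = character(0), stringsAsFactors = FALSE)
    } else {
      init <- rep(fams, times = site_counts)
      seqs <- sprintf("%s_read%06d", site_id, seq_len(n))
      best <- init
      if (!is.null(confusion)) {
        for (f in unique(init)) {
          if (f == marker_family) next
          idx <- which(init == f)
          best[idx] <- sample(colnames(confusion), length(idx),
                              replace = TRUE, prob = confusion[f, ])
        }
      }
      sc <- pmax(stats::rnorm(n, score_params$score_mean, score_params$score_sd),
                 score_params$cutoff)
      data.frame(sequence_id = seqs, initial_family = init, fulldb_best = best,
                 score = round(sc, 1), stringsAsFactors = FALSE)
    }
  })
  init_path <- file.path(dir, paste0(site_id, "_initial.tbl"))
  full_path <- file.path(dir, paste0(site_id, "_fulldb.tbl"))
  truth_path <- file.path(dir, paste0(site_id, "_truth.tsv"))
  write_tblout(truth$sequence_id, truth$initial_family, truth$score, init_path)
  # full-db scan: best profile gets the original score, runner-up (when the
  # best differs from the initial family) a strictly lower one
  if (nrow(truth)) {
    defect <- truth$fulldb_best != truth$initial_family
    tgt <- c(truth$sequence_id, truth$sequence_id[defect])
    prof <- c(truth$fulldb_best, truth$initial_family[defect])
    sc <- c(truth$score, pmax(truth$score[defect] - 5, 1))
    o <- order(tgt, -sc)
    write_tblout(tgt[o], prof[o], sc[o], full_path)
  } else {
    write_tblout(character(0), character(0), numeric(0), full_path)
  }
  write_tsv_prov(truth, truth_path)
  invisible(list(initial = init_path, fulldb = full_path, truth_path = truth_path,
                 truth = truth))
}

#' Write hits in HMMER3 per-target tabular ("tblout") layout
#'
#' Whitespace-delimited with `#` header lines; columns 1-6 are target name,
#' target accession, query (profile) name, query accession, full-sequence
#' E-value and full-sequence bit score, followed by placeholder columns as in
#' hmmsearch `--tblout` output.
#'
#' @param target,profile,score Parallel vectors (sequence id, profile id, bit
#'   score).
#' @param path Output path.
#' @param evalue Optional E-values (default derived from score as `2^-score`).
#' @return `path`, invisibly.
#' @export
write_tblout <- function(target, profile, score, path, evalue = NULL) {
  if (is.null(evalue)) evalue <- signif(2^(-as.numeric(score)), 3)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "#                                                               --- full sequence ---",
    "# target name        accession  query name           accession    E-value  score  bias",
    "#------------------- ---------- -------------------- ---------- --------- ------ -----"),
    con)
  if (length(target)) {
    writeLines(sprintf("%-20s -          %-20s -          %9.3g %6.1f   0.0 -",
                       target, profile, evalue, as.numeric(score)), con)
  }
  invisible(path)
}

#' Generate synthetic site metadata
#'
#' Habitat labels are drawn from open_ocean/coastal/estuary; salinity and
#' temperature are habitat-linked Gaussians (defaults: open-ocean salinity
#' 35.7 +/- 1.9 permil, coastal 32.0 +/- 2.8 permil, matching reported GOS
#' habitat averages), with depth, oxygen utilization, pollution and shipping
#' classes as configurable covariates. A configurable fraction of sites lacks
#' chemistry estimates (missing pollution/oxygen), mirroring surveys where
#' chemistry is only available for a subset of sites.
#'
#' @param n_sites Number of sites (>= 0).
#' @param habitat_probs Named probabilities for habitat assignment.
#' @param params List of per-habitat covariate parameters; see defaults.
#' @param chem_missing_fraction Fraction of sites with missing chemistry.
#' @param seed Master seed.
#' @return Data frame with one row per site (columns: site_id, habitat,
#'   region, polluted, shipping, salinity, temperature, depth,
#'   oxygen_utilization, filter_fraction_flag, contaminated_flag).
#' @export
generate_site_metadata <- function(n_sites,
                                   habitat_probs = c(open_ocean = 0.4,
                                                     coastal = 0.4,
                                                     estuary = 0.2),
                                   params = list(
                                     salinity = list(open_ocean = c(35.7, 1.9),
                                                     coastal = c(32.0, 2.8),
                                                     estuary = c(20.0, 6.0)),
                                     temperature = list(open_ocean = c(22, 4),
                                                        coastal = c(18, 5),
                                                        estuary = c(15, 5)),
                                     pollution_prob = c(open_ocean = 0.1,
                                                        coastal = 0.3,
                                                        estuary = 0.5)),
                                   chem_missing_fraction = 0.2,
                                   seed = 1L) {
  stopifnot(n_sites >= 0)
  cols <- c("site_id", "habitat", "region", "polluted", "shipping", "salinity",
            "temperature", "depth", "oxygen_utilization",
            "filter_fraction_flag", "contaminated_flag")
  if (n_sites == 0) {
    df <- as.data.frame(stats::setNames(replicate(length(cols), character(0),
                                                  simplify = FALSE), cols))
    return(df)
  }
  with_stream(seed, "site_metadata", {
    hab <- sample(names(habitat_probs), n_sites, replace = TRUE,
                  prob = habitat_probs)
    par2 <- function(p, h) stats::rnorm(1, p[[h]][1], p[[h]][2])
    sal <- vapply(hab, function(h) par2(params$salinity, h), 0)
    temp <- vapply(hab, function(h) par2(params$temperature, h), 0)
    pol <- vapply(hab, function(h)
      stats::runif(1) < params$pollution_prob[[h]], NA)
    shipping <- ifelse(pol, sample(c("high", "medium"), n_sites, TRUE),
                       sample(c("low", "medium"), n_sites, TRUE))
    region <- sample(c("north_atlantic", "mid_atlantic", "pacific"),
                     n_sites, replace = TRUE)
    miss <- stats::runif(n_sites) < chem_missing_fraction
    pol[miss] <- NA
    oxy <- stats::rnorm(n_sites, 2, 0.8)
    oxy[miss] <- NA
    data.frame(site_id = sprintf("S%03d", seq_len(n_sites)),
               habitat = hab, region = region, polluted = pol,
               shipping = shipping,
               salinity = round(sal, 2), temperature = round(temp, 2),
               depth = round(stats::runif(n_sites, 1, 30), 1),
               oxygen_utilization = round(oxy, 3),
               filter_fraction_flag = FALSE, contaminated_flag = FALSE,
               stringsAsFactors = FALSE)
  })
}
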