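# Profile-search hit handling: HMMER3 table parsing, trusted-cutoff
# application, reciprocal best-profile filtering, read-to-ORF counting,
# retention statistics and the profile-length bias diagnostic.

#' Parse a HMMER3 tabular hit file
#'
#' Supports the per-target (`tblout`) and per-domain (`domtblout`) layouts.
#' For per-target files the full-sequence E-value and bit score are columns 5
#' and 6; for per-domain files they are columns 7 and 8 (full-sequence values,
#' matching sequence-level reciprocity semantics). `#` comment lines are
#' skipped; data-line order is preserved.
#'
#' @param path File path.
#' @param dialect `"per-target"` or `"per-domain"`.
#' @return Data frame with columns `sequence_id`, `profile_id`, `e_value`,
#'   `bit_score`, one row per data line.
#' @export
parse_hit_table <- function(path, dialect = c("per-target", "per-domain")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("hit table not found: ", path)
  lines <- readLines(path)
  data <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  cols <- switch(dialect,
                 "per-target" = c(prof = 3L, eval = 5L, score = 6L, min = 6L),
                 "per-domain" = c(prof = 4L, eval = 7L, score = 8L, min = 8L))
  if (!length(data))
    return(data.frame(sequence_id = character(0), profile_id = character(0),
                      e_value = numeric(0), bit_score = numeric(0),
                      stringsAsFactors = FALSE))
  fields <- strsplit(trimws(lines[data]), "\\s+")
  nf <- lengths(fields)
  short <- nf < cols[["min"]]
  if (any(short)) {
    i <- data[which(short)[1]]
    stop("malformed line ", i, " in ", basename(path),
         ": expected >= ", cols[["min"]], " fields, got ", nf[which(short)[1]])
  }
  pick <- function(j) vapply(fields, `[[`, "", j)
  ev <- suppressWarnings(as.numeric(pick(cols[["eval"]])))
  sc <- suppressWarnings(as.numeric(pick(cols[["score"]])))
  bad <- is.na(ev) | is.na(sc)
  if (any(bad))
    stop("malformed line ", data[which(bad)[1]], " in ", basename(path),
         ": non-numeric E-value or score")
  data.frame(sequence_id = pick(1L), profile_id = pick(cols[["prof"]]),
             e_value = ev, bit_score = sc, stringsAsFactors = FALSE)
}

#' Apply per-profile trusted cutoffs
#'
#' Retains hits whose bit score is greater than or equal to the trusted cutoff
#' of their profile (a score exactly at the cutoff passes: trusted cutoffs are
#' defined as the lowest score of a true family member). Input order is
#' preserved; the operation is idempotent.
#'
#' @param hits Data frame from [parse_hit_table()].
#' @param cutoffs Named numeric vector (or two-column data frame
#'   `profile_id`, `trusted_cutoff`) mapping profile id to cutoff.
#' @return Filtered hit data frame.
#' @export
apply_trusted_cutoffs <- function(hits, cutoffs) {
  if (is.data.frame(cutoffs))
    cutoffs <- stats::setNames(cutoffs[[2]], cutoffs[[1]])
  missing <- setdiff(unique(hits$profile_id), names(cutoffs))
  if (length(missing))
    stop("no trusted cutoff for profile(s): ", paste(missing, collapse = ", "))
  if (any(!is.finite(cutoffs))) stop("trusted cutoffs must be finite")
  hits[hits$bit_score >= cutoffs[hits$profile_id], , drop = FALSE]
}

#' Best-matching profile for one sequence
#'
#' Ties are broken deterministically: highest bit score, then lowest E-value,
#' then lexicographically smallest profile id.
#'
#' @param hits Data frame of hits for a single sequence (>= 1 row).
#' @return The winning `profile_id` (character scalar).
#' @export
best_profile <- function(hits) {
  if (!nrow(hits)) stop("best_profile: no hits for sequence")
  o <- order(-hits$bit_score, hits$e_value, hits$profile_id)
  hits$profile_id[o[1]]
}

#' Best profile per sequence over a full-database scan table
#'
#' @param hits Data frame of hits (possibly many sequences).
#' @return Named character vector: sequence id -> best profile id.
#' @export
best_profile_map <- function(hits) {
  if (!nrow(hits)) return(stats::setNames(character(0), character(0)))
  # same tie-break as best_profile, vectorized: first row per sequence after
  # ordering by score desc, E-value asc, profile id asc
  o <- order(hits$sequence_id, -hits$bit_score, hits$e_value, hits$profile_id)
  h <- hits[o, , drop = FALSE]
  first <- !duplicated(h$sequence_id)
  stats::setNames(h$profile_id[first], h$sequence_id[first])
}

#' Reciprocal best-profile filtering
#'
#' A sequence initially matched by family f is retained iff its best match
#' over the entire profile database is that same family. The retained set is
#' always a subset of the initial set.
#'
#' @param initial Named list: family id -> character vector of sequence ids
#'   initially matched by that family's profile.
#' @param full_db_best Named character vector: sequence id -> best profile id
#'   over the full database.
#' @return Named list: family id -> retained sequence ids.
#' @export
reciprocal_filter <- function(initial, full_db_best) {
  all_seqs <- unique(unlist(initial, use.names = FALSE))
  missing <- setdiff(all_seqs, names(full_db_best))
  if (length(missing))
    stop("sequences missing from full-database scan: ",
         paste(missing, collapse = ", "))
  out <- lapply(names(initial), function(f) {
    s <- unique(initial[[f]])
    s[full_db_best[s] == f]
  })
  names(out) <- names(initial)
  out
}

#' Count reads per family from read-to-ORF overlaps
#'
#' A read overlapping qualifying ORFs of k distinct families contributes one
#' count to each of those families, and at most one count per (read, family)
#' pair regardless of how many ORFs of that family it overlaps.
#'
#' @param read_overlaps Data frame with columns `read_id`, `orf_sequence_id`,
#'   `overlap_length` (>= 1).
#' @param orf_families Named character vector: ORF sequence id -> family id.
#' @param min_overlap Minimum overlap length to qualify (default 1).
#' @return Named integer vector of read counts per family (families present in
#'   `orf_families` reported, absent families as 0).
#' @export
count_reads_by_family <- function(read_overlaps, orf_families, min_overlap = 1L) {
  stopifnot(all(read_overlaps$overlap_length >= 1))
  fams <- sort(unique(orf_families))
  counts <- stats::setNames(integer(length(fams)), fams)
  if (!nrow(read_overlaps)) return(counts)
  keep <- read_overlaps$overlap_length >= min_overlap
  ro <- read_overlaps[keep, , drop = FALSE]
  known <- ro$orf_sequence_id %in% names(orf_families)
  if (any(!known)) {
    warning("skipping ", sum(!known), " overlap(s) with unassigned ORFs: ",
            paste(unique(ro$orf_sequence_id[!known]), collapse = ", "))
    ro <- ro[known, , drop = FALSE]
  }
  if (!nrow(ro)) return(counts)
  pairs <- unique(data.frame(read = ro$read_id,
                             family = orf_families[ro$orf_sequence_id],
                             stringsAsFactors = FALSE))
  tab <- table(pairs$family)
  counts[names(tab)] <- as.integer(tab)
  counts
}

#' Retention statistics of reciprocal filtering
#'
#' Retention is 100 * reciprocal / initial per family; reported rounded to one
#' decimal with the unrounded value retained. Families with zero initial hits
#' have undefined retention (flagged `NA`, not 0 or 100).
#'
#' @param initial_counts Named integer vector of initial hit counts per family.
#' @param reciprocal_counts Named integer vector of reciprocal counts (same
#'   families; must satisfy reciprocal <= initial).
#' @return Data frame: `family_id`, `initial_count`, `reciprocal_count`,
#'   `retention_percent` (rounded, 1 decimal), `retention_exact`,
#'   `undefined` (logical flag).
#' @export
retention_stats <- function(initial_counts, reciprocal_counts) {
  fams <- names(initial_counts)
  stopifnot(!is.null(fams), setequal(fams, names(reciprocal_counts)))
  r <- reciprocal_counts[fams]
  i <- initial_counts[fams]
  bad <- i == 0 & r > 0
  if (any(bad))
    stop("reciprocal count exceeds initial count (zero initial) for: ",
         paste(fams[bad], collapse = ", "))
  if (any(r > i))
    stop("reciprocal count exceeds initial count for: ",
         paste(fams[r > i], collapse = ", "))
  exact <- ifelse(i > 0, 100 * r / i, NA_real_)
  data.frame(family_id = fams,
             initial_count = as.integer(i),
             reciprocal_count = as.integer(r),
             retention_percent = round(exact, 1),
             retention_exact = exact,
             undefined = i == 0,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Profile-length bias diagnostic
#'
#' Pearson correlation between profile length and the number of sequences the
#' profile found, with a two-sided p-value. Short metagenomic reads could
#' bias searches toward short profiles; a non-significant correlation
#' indicates no such length bias.
#'
#' @param profile_lengths Named numeric vector: profile id -> model length.
#' @param hit_counts Named numeric vector: profile id -> number of hits.
#' @return List with `r`, `p_value`, `n`, and `undefined` flag (TRUE when one
#'   of the vectors is constant, where the correlation does not exist).
#' @export
length_bias_check <- function(profile_lengths, hit_counts) {
  common <- intersect(names(profile_lengths), names(hit_counts))
  if (length(common) < 3) stop("length_bias_check needs >= 3 profiles")
  x <- as.numeric(profile_lengths[common])
  y <- as.numeric(hit_counts[common])
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p_value = NA_real_, n = length(common),
                undefined = TRUE))
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(common),
       undefined = FALSE)
}

#' Screen one site: cutoffs, reciprocal filter, per-family counts
#'
#' Convenience composition used by the pipeline: parses the initial and
#' full-database hit tables, applies trusted cutoffs to the initial hits,
#' reciprocally filters against the best full-database profile per sequence
#' and returns per-family counts alongside retention statistics.
#'
#' @param initial_path Initial per-family search results (tblout).
#' @param fulldb_path Full-database scan results (tblout).
#' @param cutoffs Named trusted-cutoff vector (see [apply_trusted_cutoffs()]).
#' @param families Family ids to report (explicit zeros for families with no
#'   hits).
#' @param dialect Table dialect, see [parse_hit_table()].
#' @return List with `counts` (named integer vector over `families`),
#'   `retention` (data frame from [retention_stats()]).
#' @export
screen_site <- function(initial_path, fulldb_path, cutoffs, families,
                        dialect = "per-target") {
  hits <- parse_hit_table(initial_path, dialect)
  hits <- apply_trusted_cutoffs(hits, cutoffs)
  initial <- lapply(stats::setNames(families, families), function(f)
    unique(hits$sequence_id[hits$profile_id == f]))
  full <- parse_hit_table(fulldb_path, dialect)
  best <- best_profile_map(full)
  kept <- reciprocal_filter(initial, best)
  counts <- vapply(kept, length, 0L)
  init_n <- vapply(initial, length, 0L)
  list(counts = counts, retention = retention_stats(init_n, counts))
}
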