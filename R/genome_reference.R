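# Genome reference statistics: genome x family count matrices, the per-family
# copy-number expectations used for paralog normalization, single-copy marker
# validation and the mean/median concordance diagnostic.

#' Build a genome x family count matrix from reciprocal hit tables
#'
#' Each per-genome table must already be reciprocally filtered; the cell
#' (genome, family) is the number of distinct protein sequences of that genome
#' assigned to the family. Families listed in the manifest but hit nowhere are
#' present as explicit zero columns.
#'
#' @param hit_tables Named list (genome id -> data frame with columns
#'   `sequence_id`, `family_id`).
#' @param families Character vector of family ids (the manifest).
#' @return Integer matrix, rows = genomes, cols = families.
#' @export
build_genome_matrix <- function(hit_tables, families) {
  ids <- names(hit_tables)
  if (is.null(ids) || anyDuplicated(ids))
    stop("hit_tables must be uniquely named by genome id")
  m <- matrix(0L, nrow = length(ids), ncol = length(families),
              dimnames = list(ids, families))
  for (g in ids) {
    ht <- hit_tables[[g]]
    if (!nrow(ht)) next
    ht <- unique(ht[, c("sequence_id", "family_id")])
    unknown <- setdiff(unique(ht$family_id), families)
    if (length(unknown))
      stop("genome ", g, " has hits to families absent from the manifest: ",
           paste(unknown, collapse = ", "))
    tab <- table(ht$family_id)
    m[g, names(tab)] <- as.integer(tab)
  }
  m
}

#' Per-family copy-number statistics over a genome set
#'
#' Mean, median, sample standard deviation (n-1 denominator) and coefficient
#' of variation (percent) per family. CV is undefined (`NA`) when the mean is
#' zero; it is never reported as 0 or infinity in that case.
#'
#' @param matrix Genome x family count matrix.
#' @param subset Optional genome ids (or logical/integer index) selecting the
#'   genome set, e.g. marine-only.
#' @return Data frame: `family_id`, `n_genomes`, `mean`, `median`, `sd`,
#'   `cv_percent`.
#' @export
family_stats <- function(matrix, subset = NULL) {
  m <- matrix
  if (!is.null(subset)) m <- m[subset, , drop = FALSE]
  if (nrow(m) == 0) stop("family_stats: empty genome subset")
  mu <- colMeans(m)
  med <- apply(m, 2, stats::median)
  sdv <- apply(m, 2, stats::sd)
  if (nrow(m) == 1) sdv <- rep(NA_real_, ncol(m))
  data.frame(family_id = colnames(m),
             n_genomes = nrow(m),
             mean = mu,
             median = med,
             sd = sdv,
             cv_percent = ifelse(mu > 0, 100 * sdv / mu, NA_real_),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Validate the single-copy marker family
#'
#' The marker is usable for per-genome normalization when its mean copy number
#' across the genome set lies within `1 +/- tol_mean` and its standard
#' deviation does not exceed `max_sd`.
#'
#' @param matrix Genome x family count matrix.
#' @param marker_family Marker family id (must be a column).
#' @param tol_mean Allowed deviation of the mean from 1 (default 0.15).
#' @param max_sd Maximum allowed SD (default 0.2).
#' @return List: `stats` (one-row data frame from [family_stats()]), `pass`
#'   (logical).
#' @export
validate_marker <- function(matrix, marker_family, tol_mean = 0.15,
                            max_sd = 0.2) {
  if (!marker_family %in% colnames(matrix))
    stop("marker family ", marker_family, " not in matrix")
  st <- family_stats(matrix[, marker_family, drop = FALSE])
  pass <- isTRUE(abs(st$mean - 1) <= tol_mean && st$sd <= max_sd)
  list(stats = st, pass = pass)
}

#' Concordance between per-family means and medians
#'
#' Squared Pearson correlation between the per-family mean and median copy
#' numbers; high concordance justifies using either as the genome-content
#' expectation.
#'
#' @param stats Data frame from [family_stats()] (>= 3 families).
#' @return List: `r_squared`, `n`, `undefined` flag (TRUE when either vector
#'   is constant).
#' @export
median_mean_concordance <- function(stats) {
  if (nrow(stats) < 3) stop("median_mean_concordance needs >= 3 families")
  x <- stats$mean
  y <- stats$median
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r_squared = NA_real_, n = nrow(stats), undefined = TRUE))
  list(r_squared = stats::cor(x, y)^2, n = nrow(stats), undefined = FALSE)
}
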