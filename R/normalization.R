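# Abundance normalization: read counts -> per-genome equivalents via the
# single-copy marker, paralog normalization against genome-content
# expectations, sparsity filtering and the log2 transform with a -10 floor.
# The stage of each matrix is tracked so the composition order
# (per_genome -> sparsity filter -> log2) is enforced.

#' Construct a stage-tagged normalized matrix
#'
#' @param values Numeric site x family matrix.
#' @param stage One of `"raw"`, `"per_genome"`, `"paralog"`, `"log2"`.
#' @param sparsity_filtered Has [sparsity_filter()] been applied?
#' @return A `norm_matrix` object (numeric matrix with attributes).
#' @export
normalized_matrix <- function(values, stage = c("raw", "per_genome", "paralog",
                                                "log2"),
                              sparsity_filtered = FALSE) {
  stage <- match.arg(stage)
  if (stage %in% c("per_genome", "paralog") && any(values < 0, na.rm = TRUE))
    stop("stage ", stage, " requires non-negative values")
  if (stage == "log2" && any(values < -10, na.rm = TRUE))
    stop("log2 stage values must be >= -10")
  structure(values, stage = stage, sparsity_filtered = sparsity_filtered,
            class = c("norm_matrix", class(values)))
}

#' Normalization stage of a matrix
#' @param x A `norm_matrix` (or plain matrix, treated as `"raw"`).
#' @return Stage string.
#' @export
norm_stage <- function(x) {
  s <- attr(x, "stage")
  if (is.null(s)) "raw" else s
}

#' Default normalization configuration
#'
#' @param marker_family_id Single-copy marker family id.
#' @param zero_replacement Stand-in for expectation means that are exactly
#'   zero (default 0.01).
#' @param log_floor Value assigned to zeros on the log2 scale (default -10).
#' @param max_zero_entities Sparsity threshold: rows/columns with strictly
#'   more than this many zeros are removed (default 3).
#' @param expectation Use the `"mean"` or `"median"` genome copy number as the
#'   expectation.
#' @return List of class `norm_config`.
#' @export
norm_config <- function(marker_family_id = "RNA_pol_Rpb2_6",
                        zero_replacement = 0.01, log_floor = -10,
                        max_zero_entities = 3L,
                        expectation = c("mean", "median")) {
  stopifnot(zero_replacement > 0, max_zero_entities >= 0)
  structure(list(marker_family_id = marker_family_id,
                 zero_replacement = zero_replacement,
                 log_floor = log_floor,
                 max_zero_entities = as.integer(max_zero_entities),
                 expectation = match.arg(expectation)),
            class = "norm_config")
}

#' Convert site read counts to per-genome equivalents
#'
#' Divides every family count at a site by the marker-family count at that
#' site, so values read as average gene copies per genome in the community.
#' Sites where the marker found no reads cannot be normalized; they are
#' excluded and reported.
#'
#' @param site_counts Site x family count matrix (marker column required).
#' @param config A [norm_config()].
#' @return `norm_matrix` at stage `per_genome` (marker column identically 1),
#'   with attribute `excluded_sites` naming sites dropped for zero marker
#'   counts.
#' @export
per_genome_normalize <- function(site_counts, config = norm_config()) {
  marker <- config$marker_family_id
  if (!marker %in% colnames(site_counts))
    stop("marker family ", marker, " not in count matrix")
  if (any(site_counts < 0)) stop("negative counts")
  mk <- site_counts[, marker]
  excluded <- rownames(site_counts)[mk == 0]
  if (length(excluded))
    message("per_genome_normalize: excluding ", length(excluded),
            " site(s) with zero marker counts: ",
            paste(excluded, collapse = ", "))
  keep <- mk > 0
  vals <- sweep(site_counts[keep, , drop = FALSE], 1, mk[keep], `/`)
  out <- normalized_matrix(vals, "per_genome")
  attr(out, "excluded_sites") <- excluded
  out
}

#' Normalize per-genome equivalents against genome-content expectations
#'
#' Divides each family column by the family's expected copy number per genome
#' (mean or median over a reference genome set). A value of 1 means "as
#' abundant as expected from sequenced genomes"; below 1 underrepresented,
#' above 1 overrepresented. Expectations that are exactly zero are replaced by
#' `config$zero_replacement`; observed values are never altered.
#'
#' @param per_genome `norm_matrix` at stage `per_genome`.
#' @param expectations Data frame from [family_stats()] covering all families.
#' @param config A [norm_config()].
#' @return `norm_matrix` at stage `paralog`.
#' @export
paralog_normalize <- function(per_genome, expectations,
                              config = norm_config()) {
  if (norm_stage(per_genome) != "per_genome")
    stop("paralog_normalize expects a per_genome-stage matrix, got ",
         norm_stage(per_genome))
  fams <- colnames(per_genome)
  missing <- setdiff(fams, expectations$family_id)
  if (length(missing))
    stop("no expectation for family(ies): ", paste(missing, collapse = ", "))
  exp_col <- if (config$expectation == "mean") "mean" else "median"
  e <- stats::setNames(expectations[[exp_col]], expectations$family_id)[fams]
  e[e == 0] <- config$zero_replacement
  vals <- sweep(unclass(per_genome), 2, e, `/`)
  out <- normalized_matrix(vals, "paralog",
                           sparsity_filtered = isTRUE(attr(per_genome,
                                                           "sparsity_filtered")))
  attr(out, "excluded_sites") <- attr(per_genome, "excluded_sites")
  out
}

#' Remove sparse sites and families
#'
#' Sites (rows) with strictly more than `max_zero_entities` zero-valued
#' families, and families (columns) with strictly more than
#' `max_zero_entities` zero-valued sites, are removed. Both criteria are
#' evaluated simultaneously on the input matrix (a single pass, not iterated),
#' which makes the result independent of evaluation order.
#'
#' @param matrix Count matrix or `norm_matrix`.
#' @param config A [norm_config()].
#' @return List: `matrix` (filtered, same class/stage, flagged
#'   `sparsity_filtered`), `removed_sites`, `removed_families` (data frames
#'   with the zero counts that triggered removal).
#' @export
sparsity_filter <- function(matrix, config = norm_config()) {
  k <- config$max_zero_entities
  zr <- rowSums(matrix == 0)
  zc <- colSums(matrix == 0)
  drop_r <- zr > k
  drop_c <- zc > k
  filtered <- matrix[!drop_r, !drop_c, drop = FALSE]
  stage <- norm_stage(matrix)
  out <- if (inherits(matrix, "norm_matrix")) {
    normalized_matrix(unclass(filtered), stage, sparsity_filtered = TRUE)
  } else {
    f <- filtered
    attr(f, "sparsity_filtered") <- TRUE
    f
  }
  list(matrix = out,
       removed_sites = data.frame(site_id = rownames(matrix)[drop_r],
                                  n_zero_families = unname(zr[drop_r]),
                                  stringsAsFactors = FALSE),
       removed_families = data.frame(family_id = colnames(matrix)[drop_c],
                                     n_zero_sites = unname(zc[drop_c]),
                                     stringsAsFactors = FALSE))
}

#' log2 transform with a floor for zeros
#'
#' Values are log2-transformed; exact zeros (which have no finite logarithm)
#' are set to `config$log_floor` (default -10). Requires the sparsity filter
#' to have been applied first, so the floor only handles the small number of
#' zeros that survive filtering.
#'
#' @param matrix `norm_matrix` at stage `per_genome` or `paralog`.
#' @param config A [norm_config()].
#' @return `norm_matrix` at stage `log2`.
#' @export
log2_with_floor <- function(matrix, config = norm_config()) {
  st <- norm_stage(matrix)
  if (!st %in% c("per_genome", "paralog"))
    stop("log2_with_floor expects stage per_genome or paralog, got ", st)
  if (!isTRUE(attr(matrix, "sparsity_filtered")))
    stop("log2_with_floor must come after sparsity_filter ",
         "(stage order: per_genome -> sparsity filter -> log2)")
  if (any(matrix < 0)) stop("negative values cannot be log-transformed")
  vals <- unclass(matrix)
  vals <- ifelse(vals > 0, log2(vals), config$log_floor)
  normalized_matrix(vals, "log2", sparsity_filtered = TRUE)
}

#' Per-family over/underrepresentation ratios from pooled counts
#'
#' For pooled (all-site) read counts, the ratio
#' `(count_f / count_marker) / expectation_f` compares the community-wide
#' per-genome abundance of a family with its expected copy number in sequenced
#' genomes: > 1 overrepresented, < 1 underrepresented.
#'
#' @param pooled_counts Named numeric vector of pooled per-family read counts.
#' @param marker_count Pooled marker read count (> 0).
#' @param expectations Data frame from [family_stats()] (or any frame with
#'   `family_id` and the expectation column).
#' @param config A [norm_config()].
#' @return Data frame: `family_id`, `per_genome`, `expectation`, `ratio`.
#' @export
overrepresentation_ratio <- function(pooled_counts, marker_count, expectations,
                                     config = norm_config()) {
  if (marker_count <= 0) stop("marker count must be > 0")
  fams <- names(pooled_counts)
  missing <- setdiff(fams, expectations$family_id)
  if (length(missing))
    stop("no expectation for family(ies): ", paste(missing, collapse = ", "))
  exp_col <- if (config$expectation == "mean") "mean" else "median"
  e <- stats::setNames(expectations[[exp_col]], expectations$family_id)[fams]
  e[e == 0] <- config$zero_replacement
  pg <- pooled_counts / marker_count
  data.frame(family_id = fams,
             per_genome = unname(pg),
             expectation = unname(e),
             ratio = unname(pg / e),
             row.names = NULL, stringsAsFactors = FALSE)
}
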