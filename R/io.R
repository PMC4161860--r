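# TSV readers/writers with '#'-prefixed provenance headers. All pipeline
# outputs are plain TSV; provenance lines carry package version, seed and
# input checksums but never wall-clock time, so identical configs re-run to
# byte-identical files.

#' Write a data frame as TSV with provenance header lines
#'
#' @param x Data frame.
#' @param path Output path.
#' @param provenance Named character vector written as leading `# key: value`
#'   comment lines (optional).
#' @return `path`, invisibly.
#' @export
write_tsv_prov <- function(x, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(provenance)) {
    writeLines(sprintf("# %s: %s", names(provenance), as.character(provenance)), con)
  }
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a provenance-headed TSV
#'
#' @param path File path.
#' @return Data frame (comment lines skipped).
#' @export
read_tsv_prov <- function(path) {
  utils::read.delim(path, comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Write an entity x family count/value matrix as TSV
#'
#' First column holds entity ids (header `entity_id`), remaining columns are
#' family ids.
#'
#' @param mat Matrix with row and column names.
#' @param path Output path.
#' @param provenance Optional provenance header (see [write_tsv_prov()]).
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(mat, path, provenance = NULL) {
  df <- data.frame(entity_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_prov(df, path, provenance)
}

#' Read an entity x family matrix written by [write_matrix_tsv()]
#'
#' @param path File path.
#' @param integer Coerce cells to integer (for count matrices).
#' @return Numeric (or integer) matrix with entity ids as rownames.
#' @export
read_matrix_tsv <- function(path, integer = FALSE) {
  df <- read_tsv_prov(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- if (integer) "integer" else "double"
  m
}

#' Bundled pooled GOS read counts and genome copy-number statistics
#'
#' Published pooled per-family read counts from the Global Ocean Sampling
#' (GOS) survey for 34 protein families (31 detoxification families plus
#' three single-copy control families), together with the per-genome copy
#' statistics of the same families across 835 sequenced bacterial genomes.
#' Columns: `family` (Pfam profile name), `display_name`, `category`,
#' `gos_initial` (reads matched by the initial profile search),
#' `gos_reciprocal` (reads surviving reciprocal best-profile filtering),
#' `genome_mean` (average copies/genome) and `genome_cv` (copy-number CV,
#' percent). The TehB row's read counts as published are arithmetically
#' inconsistent (reciprocal would exceed initial) and are stored as `NA`;
#' its genome statistics are retained.
#'
#' @return Data frame with one row per protein family.
#' @export
gos_family_counts <- function() {
  path <- system.file("extdata", "gos_family_counts.tsv", package = "detoxprof",
                      mustWork = TRUE)
  read_tsv_prov(path)
}
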