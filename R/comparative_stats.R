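# Comparative analysis layer: cross-site variability, two-way hierarchical
# clustering, habitat/region/pollution group comparisons with significance
# tiers, functional-category aggregation and environmental PCA.

HABITATS <- c("open_ocean", "coastal", "estuary", "other")

#' Cross-site variability per family
#'
#' Coefficient of variation (percent, sample SD) of each family across sites,
#' paired with the family's mean abundance — the variability-vs-abundance
#' diagnostic separating genuinely variable families from low-abundance
#' families whose counts are dominated by sampling noise.
#'
#' @param matrix Site x family matrix (per-genome equivalents).
#' @return Data frame: `family_id`, `mean_abundance`, `cv_percent` (`NA` when
#'   the mean is zero).
#' @export
site_cv <- function(matrix) {
  if (nrow(matrix) < 2) stop("site_cv needs >= 2 sites")
  mu <- colMeans(matrix)
  sdv <- apply(matrix, 2, stats::sd)
  data.frame(family_id = colnames(matrix),
             mean_abundance = unname(mu),
             cv_percent = ifelse(mu > 0, 100 * unname(sdv) / unname(mu),
                                 NA_real_),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Two-way hierarchical clustering of sites and families
#'
#' Agglomerative clustering with Euclidean distances and complete linkage
#' (configurable) on the requested axes. Missing values are refused: filter
#' first with [sparsity_filter()].
#'
#' @param matrix Site x family numeric matrix.
#' @param axis `"sites"`, `"families"` or `"both"`.
#' @param method Linkage method passed to [stats::hclust()].
#' @return List with elements `sites` and/or `families`, each containing
#'   `hclust` (the tree) and `order` (leaf labels in dendrogram order).
#' @export
hierarchical_cluster <- function(matrix, axis = c("both", "sites", "families"),
                                 method = "complete") {
  axis <- match.arg(axis)
  if (anyNA(matrix))
    stop("matrix contains missing values; apply sparsity_filter first")
  one <- function(m) {
    if (nrow(m) < 2) stop("need >= 2 leaves to cluster")
    hc <- stats::hclust(stats::dist(m, method = "euclidean"), method = method)
    list(hclust = hc, order = rownames(m)[hc$order])
  }
  out <- list()
  if (axis %in% c("both", "sites")) out$sites <- one(unclass(matrix))
  if (axis %in% c("both", "families")) out$families <- one(t(unclass(matrix)))
  out
}

#' Export a clustering as a Newick tree
#'
#' @param cluster Element of [hierarchical_cluster()] output (list with
#'   `hclust`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(cluster, path) {
  phy <- ape::as.phylo(cluster$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}

tier_of <- function(p) ifelse(p < 0.01, "p<0.01", ifelse(p < 0.05, "p<0.05", "ns"))

#' Compare family abundances between site groups
#'
#' For each family and each non-reference group, reports the relative
#' abundance (group mean divided by reference-group mean; the reference group
#' is fixed at exactly 1) and a two-sided test of distributional difference:
#' Mann-Whitney U by default, or Welch's t on log2 values. Tiers are assigned
#' at p < 0.01 and p < 0.05. Groups with fewer than `min_sites` sites are
#' skipped with a message; sites with missing group labels are excluded.
#'
#' @param matrix Site x family matrix (normalized abundances).
#' @param metadata Site metadata data frame (must contain `site_id` and the
#'   grouping column).
#' @param grouping `"habitat"`, `"region"` or `"pollution"` (the `polluted`
#'   logical column), or any metadata column name.
#' @param reference_group Label of the reference group (relative abundance 1).
#' @param test `"mwu"` (Mann-Whitney U) or `"welch"` (Welch t on log2).
#' @param min_sites Minimum sites per group (default 3).
#' @param fdr `"none"` (raw tiers, default) or `"bh"` (Benjamini-Hochberg).
#' @return Data frame: `family_id`, `group`, `reference`, `relative_abundance`,
#'   `reference_abundance` (always 1), `p_value`, `tier`.
#' @export
group_compare <- function(matrix, metadata, grouping = "habitat",
                          reference_group = "open_ocean",
                          test = c("mwu", "welch"), min_sites = 3L,
                          fdr = c("none", "bh")) {
  test <- match.arg(test)
  fdr <- match.arg(fdr)
  col <- if (grouping == "pollution") "polluted" else grouping
  if (!col %in% names(metadata)) stop("metadata lacks column ", col)
  md <- metadata[match(rownames(matrix), metadata$site_id), ]
  labels <- md[[col]]
  if (grouping == "pollution")
    labels <- ifelse(is.na(labels), NA, ifelse(labels, "polluted", "non_polluted"))
  keep <- !is.na(labels)
  m <- matrix[keep, , drop = FALSE]
  labels <- as.character(labels[keep])
  if (!reference_group %in% labels)
    stop("reference group ", reference_group, " absent (or unlabeled)")
  ref_idx <- labels == reference_group
  if (sum(ref_idx) < min_sites)
    stop("reference group has fewer than ", min_sites, " sites")
  others <- setdiff(unique(labels), reference_group)
  res <- list()
  for (g in others) {
    g_idx <- labels == g
    if (sum(g_idx) < min_sites) {
      message("group_compare: skipping group ", g, " (", sum(g_idx),
              " sites < ", min_sites, ")")
      next
    }
    for (f in colnames(m)) {
      x <- m[g_idx, f]
      y <- m[ref_idx, f]
      ref_mean <- mean(y)
      rel <- if (ref_mean > 0) mean(x) / ref_mean else NA_real_
      p <- if (test == "mwu") {
        suppressWarnings(stats::wilcox.test(x, y,
                                            alternative = "two.sided")$p.value)
      } else {
        stats::t.test(log2(x + 1e-9), log2(y + 1e-9),
                      alternative = "two.sided")$p.value
      }
      res[[length(res) + 1L]] <- data.frame(
        family_id = f, group = g, reference = reference_group,
        relative_abundance = rel, reference_abundance = 1,
        p_value = p, stringsAsFactors = FALSE)
    }
  }
  if (!length(res))
    return(data.frame(family_id = character(0), group = character(0),
                      reference = character(0),
                      relative_abundance = numeric(0),
                      reference_abundance = numeric(0),
                      p_value = numeric(0), tier = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  if (fdr == "bh") out$p_value <- stats::p.adjust(out$p_value, "BH")
  out$tier <- tier_of(out$p_value)
  out
}

#' Compare functional-category abundances between site groups
#'
#' Family columns are summed per functional category per site, then compared
#' exactly like [group_compare()] — pooling related families gains power when
#' individual families are individually non-significant.
#'
#' @param matrix Site x family matrix.
#' @param metadata Site metadata.
#' @param categories Named character vector: family id -> category (total: all
#'   families of the matrix must be categorized).
#' @param ... Passed to [group_compare()].
#' @return Data frame as [group_compare()] with `family_id` holding category
#'   ids.
#' @export
category_compare <- function(matrix, metadata, categories, ...) {
  missing <- setdiff(colnames(matrix), names(categories))
  if (length(missing))
    stop("uncategorized family(ies): ", paste(missing, collapse = ", "))
  cats <- unique(categories[colnames(matrix)])
  agg <- vapply(cats, function(cc) {
    cols <- colnames(matrix)[categories[colnames(matrix)] == cc]
    rowSums(matrix[, cols, drop = FALSE])
  }, numeric(nrow(matrix)))
  if (is.null(dim(agg))) agg <- t(as.matrix(agg))
  colnames(agg) <- cats
  rownames(agg) <- rownames(matrix)
  group_compare(agg, metadata, ...)
}

#' Joint PCA of family abundances and environmental covariates
#'
#' Centered, unit-variance PCA (abundances and environmental variables are on
#' incommensurate scales) over sites with complete chemistry data.
#'
#' @param matrix Site x family matrix.
#' @param metadata Site metadata containing the covariate columns.
#' @param env_vars Covariate column names (default the chemistry set).
#' @return List: `scores` (site x PC), `loadings` (variable x PC),
#'   `variance_explained` (percent per PC), `sites` (complete-case site ids).
#' @export
environment_pca <- function(matrix, metadata,
                            env_vars = c("salinity", "temperature", "depth",
                                         "oxygen_utilization")) {
  md <- metadata[match(rownames(matrix), metadata$site_id), ]
  env <- as.matrix(md[, env_vars, drop = FALSE])
  complete <- stats::complete.cases(env) & stats::complete.cases(matrix)
  if (sum(complete) < 3) stop("environment_pca needs >= 3 complete-case sites")
  x <- cbind(unclass(matrix)[complete, , drop = FALSE],
             env[complete, , drop = FALSE])
  keep <- apply(x, 2, stats::sd) > 0
  x <- x[, keep, drop = FALSE]
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  ve <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, loadings = pc$rotation,
       variance_explained = ve,
       sites = rownames(matrix)[complete])
}

#' Partition sites into polluted and non-polluted sets
#'
#' Uses the boolean pollution class when present, otherwise thresholds a
#' continuous pollution score. Shipping levels are recorded alongside but
#' never used for the split (high shipping does not always imply high
#' pollution). Sites with missing pollution data are left out of both sets.
#'
#' @param metadata Site metadata with `polluted` (logical) or
#'   `pollution_score` (numeric).
#' @param threshold Score threshold when using `pollution_score` (sites with
#'   score > threshold are polluted).
#' @return List: `polluted`, `non_polluted` (site id vectors), `excluded`
#'   (missing data), `degenerate` flag (TRUE when one set is empty).
#' @export
pollution_partition <- function(metadata, threshold = NULL) {
  if ("polluted" %in% names(metadata) && any(!is.na(metadata$polluted))) {
    lab <- metadata$polluted
  } else if ("pollution_score" %in% names(metadata) &&
             any(!is.na(metadata$pollution_score))) {
    if (is.null(threshold)) stop("threshold required for pollution_score split")
    lab <- metadata$pollution_score > threshold
  } else {
    stop("no pollution data available for any site")
  }
  pol <- metadata$site_id[!is.na(lab) & lab]
  non <- metadata$site_id[!is.na(lab) & !lab]
  degenerate <- length(pol) == 0 || length(non) == 0
  if (degenerate)
    warning("degenerate pollution partition: one set is empty")
  list(polluted = pol, non_polluted = non,
       excluded = metadata$site_id[is.na(lab)], degenerate = degenerate)
}
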