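# End-to-end orchestration: dataset simulation to files, staged pipeline
# execution with fail-fast validation and provenance-headed outputs, and a
# human-readable report.

FIXTURE_FAMILIES <- c("ACR_tran", "AhpC-TSA", "Thioredoxin",
                      "Beta-lactamase", "peroxidase", "Catalase")

#' Simulate a complete dataset to files
#'
#' Generates genomes, communities, per-site hit tables, cutoffs, manifests and
#' metadata under `dir`, in the exact input formats [run_pipeline()] consumes.
#' Defaults give a desk-scale fixture (6 detoxification families plus the
#' rpoB marker, 12 sites, 50 genomes).
#'
#' @param dir Output directory (created if needed).
#' @param n_genomes,n_sites Problem size.
#' @param families Family ids (a subset of the bundled manifest); the marker
#'   is always added.
#' @param depth Expected marker read count per site.
#' @param confusion_diagonal Probability a hit's full-database best profile is
#'   its true family (1 = no clan confusion).
#' @param habitat_effects Named list habitat -> named factor vector, e.g.
#'   `list(open_ocean = c(peroxidase = 2))`; multiplies expected counts for
#'   sites of that habitat.
#' @param seed Master seed.
#' @return The pipeline config list (paths + settings), invisibly usable with
#'   [run_pipeline()].
#' @export
simulate_dataset <- function(dir, n_genomes = 50, n_sites = 12,
                             families = FIXTURE_FAMILIES, depth = 2000,
                             confusion_diagonal = 0.9,
                             habitat_effects = list(), seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hits_dir <- file.path(dir, "hits")
  dir.create(hits_dir, showWarnings = FALSE)
  manifest <- gos_family_counts()
  marker <- MARKER_DEFAULT
  fams <- union(families, marker)
  fp <- default_family_params()
  fp <- fp[fp$family %in% fams, ]
  genomes <- generate_genomes(n_genomes, fp, seed = seed)
  gmat <- genomes_to_matrix(genomes)
  gmeta <- genomes_metadata(genomes)
  conf <- confusion_model(fams, diagonal = confusion_diagonal,
                          marker_family = marker)
  smeta <- generate_site_metadata(n_sites, seed = seed)
  cutoff <- 25
  truths <- list()
  counts <- matrix(0L, n_sites, length(fams),
                   dimnames = list(smeta$site_id, fams))
  for (i in seq_len(n_sites)) {
    sid <- smeta$site_id[i]
    w <- with_stream(seed, paste0("community:", sid), {
      g <- stats::rgamma(n_genomes, 1)
      stats::setNames(g / sum(g), rownames(gmat))
    })
    eff <- habitat_effects[[smeta$habitat[i]]]
    comm <- community_profile(sid, w, depth,
                              habitat_effects = if (is.null(eff)) numeric(0) else eff)
    sc <- generate_site_counts(comm, genomes, confusion = NULL, seed = seed,
                               marker_family = marker)
    counts[sid, ] <- sc$counts[fams]
    truths[[sid]] <- sc$truth
    generate_hit_tables(sc$counts[fams], confusion = conf,
                        score_params = list(score_mean = 80, score_sd = 15,
                                            cutoff = cutoff),
                        seed = seed, dir = hits_dir, site_id = sid,
                        marker_family = marker)
  }
  prov <- c(package = paste0("detoxprof ", utils::packageVersion("detoxprof")),
            seed = seed)
  write_matrix_tsv(gmat, file.path(dir, "genome_counts.tsv"), prov)
  write_tsv_prov(gmeta, file.path(dir, "genome_metadata.tsv"), prov)
  write_tsv_prov(smeta, file.path(dir, "site_metadata.tsv"), prov)
  write_tsv_prov(data.frame(profile_id = fams, trusted_cutoff = cutoff),
                 file.path(dir, "cutoffs.tsv"), prov)
  man <- manifest[manifest$family %in% fams,
                  c("family", "display_name", "category")]
  write_tsv_prov(man, file.path(dir, "family_manifest.tsv"), prov)
  jsonlite::write_json(
    list(seed = seed,
         expected_abundance = lapply(truths, `[[`, "expected_abundance")),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  config <- list(hits_dir = hits_dir,
                 cutoffs = file.path(dir, "cutoffs.tsv"),
                 family_manifest = file.path(dir, "family_manifest.tsv"),
                 genome_counts = file.path(dir, "genome_counts.tsv"),
                 genome_metadata = file.path(dir, "genome_metadata.tsv"),
                 site_metadata = file.path(dir, "site_metadata.tsv"),
                 marker_family = marker, expectation = "mean",
                 subset = "all", test = "mwu", fdr = "none", seed = seed)
  yaml::write_yaml(config, file.path(dir, "config.yaml"))
  invisible(config)
}

validate_config <- function(config) {
  req <- c("hits_dir", "cutoffs", "family_manifest", "genome_counts",
           "genome_metadata", "site_metadata")
  miss <- setdiff(req, names(config))
  if (length(miss)) stop("config lacks field(s): ", paste(miss, collapse = ", "))
  for (f in req) {
    if (!file.exists(config[[f]]))
      stop("config path does not exist: ", f, " = ", config[[f]])
  }
  config$marker_family <- config$marker_family %||% MARKER_DEFAULT
  config$expectation <- config$expectation %||% "mean"
  config$subset <- config$subset %||% "all"
  config$test <- config$test %||% "mwu"
  config$fdr <- config$fdr %||% "none"
  config$seed <- config$seed %||% 1L
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

prov_of <- function(config) {
  paths <- unlist(config[c("cutoffs", "family_manifest", "genome_counts",
                           "genome_metadata", "site_metadata")])
  sums <- tools::md5sum(paths)
  c(package = paste0("detoxprof ", utils::packageVersion("detoxprof")),
    seed = config$seed,
    inputs_md5 = paste(basename(names(sums)), unname(sums), sep = "=",
                       collapse = ";"))
}

#' Run the full profiling pipeline
#'
#' Validates the configuration (fail-fast, before any computation), then runs
#' the stages in order: screen (cutoffs + reciprocal filtering of per-site hit
#' tables), genome-stats (copy-number expectations, marker validation),
#' normalize (per-genome equivalents, sparsity filter, paralog normalization,
#' log2), analyze (cross-site CV, two-way clustering, habitat/pollution and
#' category comparisons, environmental PCA) and report. All outputs are
#' provenance-headed TSV (trees as Newick); re-running an identical config
#' yields byte-identical files. A stage failure halts the run with the stage
#' name, leaving prior outputs plus a `FAILED` marker.
#'
#' @param config Config list or path to a YAML file (fields: `hits_dir`,
#'   `cutoffs`, `family_manifest`, `genome_counts`, `genome_metadata`,
#'   `site_metadata`, and optionally `marker_family`, `expectation`
#'   (mean/median), `subset` (all/marine/common-marine), `test` (mwu/welch),
#'   `fdr` (none/bh), `seed`).
#' @param outdir Output directory.
#' @param stages Stages to run (default all, in order).
#' @return Invisible list of key in-memory results (`site_counts`,
#'   `retention`, `genome_stats`, `per_genome`, `paralog`, `comparisons`).
#' @export
run_pipeline <- function(config, outdir,
                         stages = c("screen", "genome-stats", "normalize",
                                    "analyze", "report")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- validate_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  prov <- prov_of(config)
  res <- list()
  run_stage <- function(name, expr) {
    if (!name %in% stages) return(invisible(NULL))
    message("[detoxprof] stage: ", name)
    tryCatch(expr, error = function(e) {
      writeLines(paste0("stage ", name, ": ", conditionMessage(e)),
                 file.path(outdir, "FAILED"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  manifest <- read_tsv_prov(config$family_manifest)
  families <- manifest$family
  cutoffs_df <- read_tsv_prov(config$cutoffs)
  cutoffs <- stats::setNames(cutoffs_df$trusted_cutoff, cutoffs_df$profile_id)
  smeta <- read_tsv_prov(config$site_metadata)

  run_stage("screen", {
    counts <- matrix(0L, nrow(smeta), length(families),
                     dimnames = list(smeta$site_id, families))
    init_tot <- stats::setNames(integer(length(families)), families)
    recip_tot <- init_tot
    for (sid in smeta$site_id) {
      ip <- file.path(config$hits_dir, paste0(sid, "_initial.tbl"))
      fp <- file.path(config$hits_dir, paste0(sid, "_fulldb.tbl"))
      if (!file.exists(ip) || !file.exists(fp))
        stop("missing hit tables for site ", sid)
      sc <- screen_site(ip, fp, cutoffs, families)
      counts[sid, ] <- sc$counts[families]
      init_tot <- init_tot + sc$retention$initial_count
      recip_tot <- recip_tot + sc$retention$reciprocal_count
    }
    res$site_counts <- counts
    res$retention <- retention_stats(init_tot, recip_tot)
    write_matrix_tsv(counts, file.path(outdir, "site_counts.tsv"), prov)
    write_tsv_prov(res$retention, file.path(outdir, "retention.tsv"), prov)
  })

  run_stage("genome-stats", {
    gmat <- read_matrix_tsv(config$genome_counts, integer = TRUE)
    gmeta <- read_tsv_prov(config$genome_metadata)
    sel <- switch(config$subset,
                  all = gmeta$genome_id,
                  marine = gmeta$genome_id[gmeta$marine],
                  `common-marine` = gmeta$genome_id[gmeta$common_marine],
                  stop("unknown subset: ", config$subset))
    res$genome_stats <- family_stats(gmat, subset = sel)
    res$marker <- validate_marker(gmat[sel, , drop = FALSE],
                                   config$marker_family)
    write_tsv_prov(res$genome_stats, file.path(outdir, "genome_family_stats.tsv"),
                   c(prov, subset = config$subset))
    mk <- cbind(res$marker$stats, pass = res$marker$pass)
    write_tsv_prov(mk, file.path(outdir, "marker_validation.tsv"), prov)
  })

  run_stage("normalize", {
    cfg <- norm_config(marker_family_id = config$marker_family,
                       expectation = config$expectation)
    pg <- per_genome_normalize(res$site_counts, cfg)
    flt <- sparsity_filter(pg, cfg)
    res$per_genome <- flt$matrix
    res$paralog <- paralog_normalize(flt$matrix, res$genome_stats, cfg)
    res$log2_per_genome <- log2_with_floor(flt$matrix, cfg)
    res$log2_paralog <- log2_with_floor(res$paralog, cfg)
    pooled <- colSums(res$site_counts)
    res$overrep <- overrepresentation_ratio(
      pooled[setdiff(names(pooled), config$marker_family)],
      pooled[[config$marker_family]], res$genome_stats, cfg)
    write_matrix_tsv(unclass(flt$matrix),
                     file.path(outdir, "per_genome_matrix.tsv"),
                     c(prov, stage = "per_genome"))
    write_matrix_tsv(unclass(res$paralog),
                     file.path(outdir, "paralog_matrix.tsv"),
                     c(prov, stage = "paralog"))
    write_matrix_tsv(unclass(res$log2_paralog),
                     file.path(outdir, "log2_paralog_matrix.tsv"),
                     c(prov, stage = "log2"))
    write_tsv_prov(flt$removed_sites, file.path(outdir, "removed_sites.tsv"),
                   prov)
    write_tsv_prov(flt$removed_families,
                   file.path(outdir, "removed_families.tsv"), prov)
    write_tsv_prov(res$overrep, file.path(outdir, "overrepresentation.tsv"),
                   prov)
  })

  run_stage("analyze", {
    cv <- site_cv(res$per_genome)
    write_tsv_prov(cv, file.path(outdir, "site_cv.tsv"), prov)
    if (nrow(res$log2_paralog) >= 2 && ncol(res$log2_paralog) >= 2) {
      cl <- hierarchical_cluster(res$log2_paralog, axis = "both")
      write_dendrogram_newick(cl$sites, file.path(outdir, "sites.nwk"))
      write_dendrogram_newick(cl$families, file.path(outdir, "families.nwk"))
    }
    comps <- list()
    md <- smeta[smeta$site_id %in% rownames(res$per_genome), ]
    try_compare <- function(grouping, reference) {
      tryCatch(group_compare(res$per_genome, md, grouping = grouping,
                             reference_group = reference, test = config$test,
                             fdr = config$fdr),
               error = function(e) {
                 message("analyze: skipping ", grouping, " comparison (",
                         conditionMessage(e), ")")
                 NULL
               })
    }
    comps$habitat <- try_compare("habitat", "open_ocean")
    comps$pollution <- try_compare("pollution", "non_polluted")
    cats <- stats::setNames(manifest$category, manifest$family)
    comps$category <- tryCatch(
      category_compare(res$per_genome, md, cats, grouping = "habitat",
                       reference_group = "open_ocean", test = config$test,
                       fdr = config$fdr),
      error = function(e) NULL)
    for (nm in names(comps)) {
      if (!is.null(comps[[nm]]))
        write_tsv_prov(comps[[nm]],
                       file.path(outdir, paste0("comparisons_", nm, ".tsv")),
                       prov)
    }
    res$comparisons <- comps
    pca <- tryCatch(environment_pca(res$per_genome, md),
                    error = function(e) NULL)
    if (!is.null(pca)) {
      write_matrix_tsv(pca$scores, file.path(outdir, "pca_scores.tsv"), prov)
      write_matrix_tsv(pca$loadings, file.path(outdir, "pca_loadings.tsv"),
                       prov)
      write_tsv_prov(data.frame(pc = seq_along(pca$variance_explained),
                                variance_explained = pca$variance_explained),
                     file.path(outdir, "pca_variance.tsv"), prov)
    }
  })

  run_stage("report", make_report(outdir))

  invisible(res)
}

#' Write a human-readable run summary
#'
#' Summarizes whatever output tables are present in `outdir` into
#' `report.md`: reciprocal retention, marker validation, the most over- and
#' underrepresented families, and significant group comparisons by tier.
#' Regeneration is idempotent; an incomplete run yields a partial report with
#' warnings.
#'
#' @param outdir Pipeline output directory.
#' @return Path to `report.md`, invisibly.
#' @export
make_report <- function(outdir) {
  lines <- c("# detoxprof run summary", "")
  grab <- function(file) {
    p <- file.path(outdir, file)
    if (file.exists(p)) read_tsv_prov(p) else {
      warning("report: missing ", file, "; section skipped")
      NULL
    }
  }
  ret <- grab("retention.tsv")
  if (!is.null(ret)) {
    lines <- c(lines, "## Reciprocal retention", "",
               "family | initial | reciprocal | retention %",
               "--- | --- | --- | ---",
               sprintf("%s | %d | %d | %s", ret$family_id, ret$initial_count,
                       ret$reciprocal_count,
                       ifelse(ret$undefined, "undefined",
                              sprintf("%.1f", ret$retention_percent))), "")
  }
  mk <- grab("marker_validation.tsv")
  if (!is.null(mk)) {
    lines <- c(lines, "## Single-copy marker validation", "",
               sprintf("Marker %s: mean %.2f, SD %.2f over %d genomes -> %s",
                       mk$family_id, mk$mean, mk$sd, mk$n_genomes,
                       ifelse(mk$pass, "PASS", "FAIL")), "")
  }
  ov <- grab("overrepresentation.tsv")
  if (!is.null(ov)) {
    ov <- ov[order(ov$ratio), ]
    fmt <- function(d) sprintf("%s: %.2f", d$family_id, d$ratio)
    lines <- c(lines, "## Abundance vs genome expectation (ratio, 1 = as expected)",
               "", "Most underrepresented:",
               paste("-", fmt(utils::head(ov, 3))),
               "", "Most overrepresented:",
               paste("-", fmt(utils::tail(ov, 3))), "")
  }
  any_sig <- FALSE
  for (nm in c("habitat", "pollution", "category")) {
    # comparison tables are optional (a grouping may lack eligible sites)
    p <- file.path(outdir, paste0("comparisons_", nm, ".tsv"))
    if (!file.exists(p)) next
    cmp <- read_tsv_prov(p)
    sig <- cmp[cmp$tier != "ns", , drop = FALSE]
    if (nrow(sig)) {
      any_sig <- TRUE
      lines <- c(lines, paste0("## Significant ", nm, " comparisons"), "",
                 sprintf("- %s: %s vs %s, relative abundance %.2f (%s)",
                         sig$family_id, sig$group, sig$reference,
                         sig$relative_abundance, sig$tier), "")
    }
  }
  if (!any_sig)
    lines <- c(lines, "## Group comparisons", "",
               "No significant differences between site groups.", "")
  path <- file.path(outdir, "report.md")
  writeLines(lines, path)
  invisible(path)
}
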