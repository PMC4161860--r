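test_that("cross-site CV pairs variability with mean abundance", {
  m <- cbind(flat = rep(2, 4), varying = c(1, 2, 3, 4))
  rownames(m) <- paste0("S", 1:4)
  cv <- site_cv(m)
  expect_equal(cv$cv_percent[cv$family_id == "flat"], 0)
  expect_equal(cv$mean_abundance[cv$family_id == "varying"], 2.5)
  expect_equal(round(cv$cv_percent[cv$family_id == "varying"], 1), 51.6)
  expect_error(site_cv(m[1, , drop = FALSE]), ">= 2 sites")
})

test_that("low-abundance families show higher sampling CV under the null", {
  # equal-depth sites, no habitat effects: CV is driven by Poisson noise,
  # so mean abundance and CV rank-correlate negatively; the marker has the
  # lowest CV of all
  genomes <- list(make_genome("g1", c(hi = 20, mid = 2, lo = 1,
                                      RNA_pol_Rpb2_6 = 1)))
  sites <- lapply(1:12, function(i) {
    comm <- community_profile(paste0("S", i), c(g1 = 1), depth = 300)
    generate_site_counts(comm, genomes, seed = 100 + i)$counts
  })
  counts <- do.call(rbind, sites)
  rownames(counts) <- paste0("S", 1:12)
  # drop the marker when rank-correlating (it anchors the normalization)
  cv <- site_cv(counts[, colnames(counts) != "RNA_pol_Rpb2_6"])
  expect_lt(cor(cv$mean_abundance, cv$cv_percent, method = "spearman"), 0)
  cv_all <- site_cv(counts)
  mk <- cv_all$cv_percent[cv_all$family_id == "RNA_pol_Rpb2_6"]
  lo <- cv_all$cv_percent[cv_all$family_id == "lo"]
  expect_lt(mk, lo)
})

test_that("hierarchical clustering matches brute-force complete linkage", {
  m <- rbind(a = c(0, 0), b = c(0, 0), c = c(3, 4))
  cl <- hierarchical_cluster(m, axis = "sites")
  expect_equal(min(cl$sites$hclust$height), 0) # identical rows merge at 0

  onedim <- matrix(c(0, 1, 3, 7, 20), ncol = 1,
                   dimnames = list(paste0("p", 1:5), "x"))
  cl1 <- hierarchical_cluster(onedim, axis = "sites")
  expect_equal(sort(cl1$sites$hclust$height), brute_complete_heights(onedim))

  # permutation invariance of merge heights
  set.seed(50)
  r <- matrix(rnorm(40), 8, 5,
              dimnames = list(paste0("S", 1:8), paste0("F", 1:5)))
  h1 <- sort(hierarchical_cluster(r, "sites")$sites$hclust$height)
  perm <- sample(8)
  h2 <- sort(hierarchical_cluster(r[perm, ], "sites")$sites$hclust$height)
  expect_equal(h1, h2)

  # duplicated columns cluster as zero-height pairs on the family axis
  dup <- cbind(r, r)
  colnames(dup) <- paste0("F", 1:10)
  hf <- hierarchical_cluster(dup, "families")$families$hclust
  expect_equal(sum(hf$height < 1e-12), 5)

  expect_error(hierarchical_cluster(r[1, , drop = FALSE], "sites"),
               ">= 2 leaves")
  r[1, 1] <- NA
  expect_error(hierarchical_cluster(r), "sparsity_filter")
})

test_that("group comparisons normalize to the reference and tier p-values", {
  set.seed(77)
  sim <- lognormal_sites(10, 6)
  res <- group_compare(sim$matrix, sim$metadata, grouping = "habitat",
                       reference_group = "open_ocean")
  expect_equal(unique(res$reference_abundance), 1) # reference fixed at 1
  expect_true(all(res$tier %in% c("p<0.01", "p<0.05", "ns")))
  expect_equal(res$tier, ifelse(res$p_value < 0.01, "p<0.01",
                                ifelse(res$p_value < 0.05, "p<0.05", "ns")))
  # identical distributions: mostly non-significant, ratios near 1
  expect_gt(mean(res$tier == "ns"), 0.5)
  expect_lt(max(abs(log(res$relative_abundance))), log(3))

  # swapping reference inverts relative abundances
  swapped <- group_compare(sim$matrix, sim$metadata, grouping = "habitat",
                           reference_group = "coastal")
  expect_equal(swapped$relative_abundance, 1 / res$relative_abundance)
  expect_equal(swapped$p_value, res$p_value) # two-sided test is symmetric

  # groups below the minimum size are skipped with a message
  md_small <- sim$metadata
  md_small$habitat[md_small$habitat == "coastal"] <- "estuary"
  md_small$habitat[1:2 + 10] <- "coastal"
  expect_message(
    res2 <- group_compare(sim$matrix, md_small, grouping = "habitat",
                          reference_group = "open_ocean"),
    "skipping group coastal")
  expect_false("coastal" %in% res2$group)
})

test_that("welch alternative and BH correction are wired through", {
  set.seed(78)
  sim <- lognormal_sites(8, 4, effect = 3)
  mw <- group_compare(sim$matrix, sim$metadata, reference_group = "open_ocean")
  we <- group_compare(sim$matrix, sim$metadata, reference_group = "open_ocean",
                      test = "welch")
  expect_false(identical(mw$p_value, we$p_value))
  bh <- group_compare(sim$matrix, sim$metadata, reference_group = "open_ocean",
                      fdr = "bh")
  expect_equal(bh$p_value, p.adjust(mw$p_value, "BH"))
})

test_that("category comparison reduces to group_compare for one family", {
  set.seed(79)
  sim <- lognormal_sites(8, 3)
  cats <- setNames(c("oxidative_stress", "metal_resistance",
                     "metal_resistance"), colnames(sim$matrix))
  cc <- category_compare(sim$matrix, sim$metadata, cats,
                         grouping = "habitat", reference_group = "open_ocean")
  gc <- group_compare(sim$matrix, sim$metadata, grouping = "habitat",
                      reference_group = "open_ocean")
  f1 <- colnames(sim$matrix)[1]
  expect_equal(cc$p_value[cc$family_id == "oxidative_stress"],
               gc$p_value[gc$family_id == f1])
  expect_equal(cc$relative_abundance[cc$family_id == "oxidative_stress"],
               gc$relative_abundance[gc$family_id == f1])
  expect_error(category_compare(sim$matrix, sim$metadata, cats[-1],
                                reference_group = "open_ocean"),
               "uncategorized")
})

test_that("category pooling detects an effect single families miss", {
  # weak 1.35x boost shared by 5 families: pooled category significant more
  # often than the median single family
  set.seed(80)
  hits_cat <- 0; hits_fam <- 0
  for (i in 1:30) {
    sim <- lognormal_sites(8, 5, effect = 1.35)
    cats <- setNames(rep("oxidative_stress", 5), colnames(sim$matrix))
    cc <- category_compare(sim$matrix, sim$metadata, cats,
                           reference_group = "open_ocean")
    gc <- group_compare(sim$matrix, sim$metadata,
                        reference_group = "open_ocean")
    hits_cat <- hits_cat + (cc$p_value < 0.05)
    hits_fam <- hits_fam + median(gc$p_value < 0.05)
  }
  expect_gt(hits_cat, hits_fam)
})

test_that("environmental PCA spans gradients and reconstructs exactly", {
  md <- data.frame(site_id = paste0("S", 1:10),
                   salinity = seq(30, 36, length.out = 10),
                   temperature = seq(10, 25, length.out = 10),
                   depth = seq(1, 20, length.out = 10),
                   oxygen_utilization = seq(0.5, 3, length.out = 10))
  # perfect 1-D gradient: every variable linear in the same latent axis
  grad <- outer(seq(0, 1, length.out = 10), c(2, -1, 0.5))
  colnames(grad) <- paste0("F", 1:3)
  rownames(grad) <- md$site_id
  p <- environment_pca(grad, md)
  expect_equal(p$variance_explained[1], 100)

  set.seed(90)
  r <- matrix(rexp(40), 10, 4, dimnames = list(md$site_id, paste0("F", 1:4)))
  pr <- environment_pca(r, md)
  # orthogonal scores and exact reconstruction from all PCs
  g <- crossprod(pr$scores)
  expect_equal(g[lower.tri(g)], rep(0, length(g[lower.tri(g)])),
               tolerance = 1e-8)
  x <- scale(cbind(r, as.matrix(md[, -1])))
  expect_equal(unname(pr$scores %*% t(pr$loadings)),
               unname(x[, rownames(pr$loadings)]), tolerance = 1e-8)

  # a temperature-driven family loads with temperature
  r2 <- r
  r2[, "F1"] <- 5 + 0.8 * md$temperature + rnorm(10, 0, 0.1)
  p2 <- environment_pca(r2, md)
  expect_gt(sum(p2$loadings["F1", ] * p2$loadings["temperature", ]), 0)
  expect_error(environment_pca(grad[1:2, ], md[1:2, ]), ">= 3")
})

test_that("pollution partitioning follows labels, never shipping", {
  md <- data.frame(site_id = paste0("S", 1:6),
                   polluted = c(TRUE, FALSE, TRUE, NA, FALSE, FALSE),
                   shipping = c("low", "high", "low", "high", "high", "low"))
  p <- pollution_partition(md)
  expect_equal(p$polluted, c("S1", "S3"))
  expect_equal(p$non_polluted, c("S2", "S5", "S6"))
  expect_equal(p$excluded, "S4")
  expect_false(p$degenerate)

  all_pol <- data.frame(site_id = c("a", "b"), polluted = c(TRUE, TRUE))
  expect_warning(pd <- pollution_partition(all_pol), "degenerate")
  expect_true(pd$degenerate)

  score <- data.frame(site_id = paste0("S", 1:8),
                      pollution_score = c(0.1, 0.9, 0.4, 0.6, 0.2, 0.8, 0.5, 0.7))
  ps <- pollution_partition(score, threshold = 0.5)
  expect_equal(ps$polluted,
               score$site_id[sapply(score$pollution_score, function(s) s > 0.5)])
  none <- data.frame(site_id = "S1", polluted = NA)
  expect_error(pollution_partition(none), "no pollution data")
})
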