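test_that("hit-table parsing handles comments, dialects and malformed input", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "only_comments.tbl")
  writeLines(c("# header", "# another"), p)
  expect_equal(nrow(parse_hit_table(p)), 0)

  p2 <- file.path(dir, "three.tbl")
  write_tblout(c("s1", "s2", "s3"), c("P1", "P2", "P1"), c(50.5, 30.1, 12.0),
               p2, evalue = c(1e-12, 1e-6, 0.01))
  hits <- parse_hit_table(p2)
  expect_equal(hits$sequence_id, c("s1", "s2", "s3"))
  expect_equal(hits$profile_id, c("P1", "P2", "P1"))
  expect_equal(hits$bit_score, c(50.5, 30.1, 12.0))
  expect_equal(hits$e_value, c(1e-12, 1e-6, 0.01))

  # truncated final line is a parse error naming the line, not a silent drop
  lines <- readLines(p2)
  writeLines(c(lines, "s4 -"), p2)
  expect_error(parse_hit_table(p2), "malformed line 7")

  # per-domain layout: full-sequence E-value/score live in columns 7/8
  p3 <- file.path(dir, "dom.tbl")
  writeLines(c("# domtblout",
               "s1 - 120 P1 - 200 1e-10 55.2 0.1 1 1 1e-10 1e-10 55.0 0.1 1 100 5 104 1 120 0.9 -"),
             p3)
  dom <- parse_hit_table(p3, dialect = "per-domain")
  expect_equal(dom$profile_id, "P1")
  expect_equal(dom$bit_score, 55.2)
  expect_equal(dom$e_value, 1e-10)
  expect_error(parse_hit_table(file.path(dir, "nope.tbl")), "not found")
})

test_that("trusted cutoffs keep boundary scores and match a brute-force scan", {
  hits <- data.frame(sequence_id = c("a", "b", "c"),
                     profile_id = c("P1", "P1", "P2"),
                     e_value = c(1e-5, 1e-4, 1e-3),
                     bit_score = c(25.0, 24.9, 40.0),
                     stringsAsFactors = FALSE)
  cut <- c(P1 = 25.0, P2 = 50.0)
  kept <- apply_trusted_cutoffs(hits, cut)
  expect_equal(kept$sequence_id, "a") # exactly-at-cutoff passes, others fail
  expect_equal(nrow(apply_trusted_cutoffs(hits, c(P1 = 99, P2 = 99))), 0)
  expect_error(apply_trusted_cutoffs(hits, c(P1 = 25)), "P2")

  set.seed(101)
  for (i in 1:20) {
    h <- random_hits(30)
    cuts <- setNames(round(runif(4, 20, 80), 1), sprintf("P%02d", 1:4))
    got <- apply_trusted_cutoffs(h, cuts)
    manual <- h[sapply(seq_len(nrow(h)), function(r)
      h$bit_score[r] >= cuts[[h$profile_id[r]]]), ]
    expect_equal(got, manual)
    expect_equal(apply_trusted_cutoffs(got, cuts), got) # idempotent
  }
})

test_that("best_profile uses the documented tie-break and matches brute force", {
  one <- data.frame(sequence_id = "s", profile_id = "PX", e_value = 1e-3,
                    bit_score = 10)
  expect_equal(best_profile(one), "PX")
  tie <- data.frame(sequence_id = "s", profile_id = c("B", "A"),
                    e_value = c(1e-5, 1e-5), bit_score = c(50.1, 50.1))
  expect_equal(best_profile(tie), "A") # lexicographically smaller id wins
  expect_error(best_profile(tie[0, ]), "no hits")

  set.seed(7)
  h <- random_hits(100, n_seq = 1)
  expect_equal(best_profile(h), brute_best(h))
  # vectorized per-sequence map agrees with the scalar version
  hm <- random_hits(200, n_seq = 12)
  got <- best_profile_map(hm)
  for (s in unique(hm$sequence_id))
    expect_equal(got[[s]], best_profile(hm[hm$sequence_id == s, ]))
})

test_that("reciprocal filtering retains agreeing sequences only", {
  init <- list(F1 = c("a", "b", "c"), F2 = c("d"))
  best <- c(a = "F1", b = "F1", c = "F1", d = "F2")
  expect_equal(reciprocal_filter(init, best), init) # full agreement: identity
  best["b"] <- "F2"
  out <- reciprocal_filter(init, best)
  expect_equal(out$F1, c("a", "c"))
  expect_true(all(out$F1 %in% init$F1)) # subset invariant
  expect_error(reciprocal_filter(init, best[-1]), "a")

  # constructed clan-defector case vs enumeration oracle
  init2 <- list(X = sprintf("s%d", 1:6), Y = sprintf("s%d", 7:10))
  best2 <- setNames(c(rep("X", 4), "Y", "Y", rep("Y", 3), "X"),
                    sprintf("s%d", 1:10))
  expect_equal(reciprocal_filter(init2, best2),
               brute_reciprocal(init2, best2))
})

test_that("a pooled-count fixture reproduces the published ArsC retention", {
  seqs <- sprintf("r%04d", 1:993)
  init <- list(ArsC = seqs)
  best <- setNames(c(rep("ArsC", 853), rep("Other", 140)), seqs)
  kept <- reciprocal_filter(init, best)
  ret <- retention_stats(c(ArsC = 993L),
                         c(ArsC = length(kept$ArsC)))
  expect_equal(ret$retention_percent, 85.9)
})

test_that("read counting is per family, once per (read, family)", {
  fam <- c(o1 = "ArsC", o2 = "ArsC", o3 = "CutA")
  none <- data.frame(read_id = character(0), orf_sequence_id = character(0),
                     overlap_length = integer(0))
  expect_true(all(count_reads_by_family(none, fam) == 0))

  five <- data.frame(read_id = sprintf("r%d", 1:5), orf_sequence_id = "o1",
                     overlap_length = 10L)
  expect_equal(count_reads_by_family(five, fam)[["ArsC"]], 5L)

  # 6-read fixture recounted by hand: r1 hits two families (one count each),
  # r2 hits two ORFs of the same family (one count), r6 hits an unknown ORF
  six <- data.frame(
    read_id = c("r1", "r1", "r2", "r2", "r3", "r4", "r5", "r6"),
    orf_sequence_id = c("o1", "o3", "o1", "o2", "o2", "o3", "o1", "oX"),
    overlap_length = c(5L, 8L, 3L, 4L, 9L, 2L, 7L, 6L))
  expect_warning(counts <- count_reads_by_family(six, fam), "oX")
  expect_equal(counts[["ArsC"]], 4L) # r1, r2, r3, r5
  expect_equal(counts[["CutA"]], 2L) # r1, r4
})

test_that("retention statistics round correctly and flag degenerate input", {
  r <- retention_stats(c(A = 993L, B = 1511L, C = 0L),
                       c(A = 853L, B = 1511L, C = 0L))
  expect_equal(r$retention_percent[r$family_id == "A"], 85.9)
  expect_equal(r$retention_percent[r$family_id == "B"], 100)
  expect_true(is.na(r$retention_percent[r$family_id == "C"]))
  expect_true(r$undefined[r$family_id == "C"])
  expect_equal(r$retention_exact[r$family_id == "A"], 100 * 853 / 993)
  expect_error(retention_stats(c(A = 10L), c(A = 11L)), "exceeds")
  expect_error(retention_stats(c(A = 0L), c(A = 1L)), "exceeds")
})

test_that("profile-length bias check matches the closed-form correlation", {
  lens <- setNames(c(100, 150, 200, 250), paste0("P", 1:4))
  expect_true(length_bias_check(lens, lens * 0 + 5)$undefined)
  perfect <- length_bias_check(lens, lens * 2)
  expect_equal(perfect$r, 1.0)

  set.seed(33)
  x <- setNames(runif(20, 50, 400), paste0("P", 1:20))
  y <- setNames(rpois(20, 40), paste0("P", 1:20))
  got <- length_bias_check(x, y)
  # textbook Pearson formula, computed independently
  r_manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_stat <- r_manual * sqrt(18 / (1 - r_manual^2))
  expect_equal(got$r, r_manual)
  expect_equal(got$p_value, 2 * pt(-abs(t_stat), df = 18))
  expect_error(length_bias_check(x[1:2], y[1:2]), ">= 3")
})
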