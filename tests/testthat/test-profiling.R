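test_that("Spearman distance honors its identities", {
  m <- rbind(a = c(1, 2, 3, 4), b = c(10, 20, 30, 40),
             c = c(4, 3, 2, 1), d = c(2, 2, 2, 2))
  expect_warning(d <- as.matrix(spearman_dist(m)), "zero-variance")
  expect_equal(d["a", "b"], 0)              # identical ranks
  expect_equal(d["a", "c"], 2)              # perfectly anti-correlated
  expect_equal(d["a", "d"], 2)              # zero variance -> max distance
  # invariant to strictly monotone transforms of a profile
  m2 <- m[c("a", "c"), ]
  m2["a", ] <- exp(m2["a", ])
  expect_equal(as.matrix(spearman_dist(m2))[1, 2], 2)
})

test_that("identical drug profiles merge at height zero", {
  m <- rbind(x = c(1, 5, 2, 9), y = c(2, 10, 4, 18), z = c(9, 1, 8, 0),
             w = c(0, 3, 7, 1))
  res <- cluster_profiles(m)
  h <- res$row_hclust
  first <- h$merge[1, ]
  expect_setequal(rownames(m)[-first], c("x", "y"))
  expect_equal(h$height[1], 0)
  expect_true(all(diff(h$height) >= -1e-12))
  expect_setequal(res$row_order, 1:4)
  expect_setequal(res$col_order, 1:4)
})

test_that("clustering equals brute-force complete-linkage agglomeration (cophenetic oracle)", {
  set.seed(5)
  for (n in 3:6) {
    m <- matrix(rnorm(n * 6), n, dimnames = list(paste0("r", 1:n), NULL))
    res <- cluster_profiles(m)
    expect_equal(
      as.matrix(stats::cophenetic(res$row_hclust)),
      brute_force_complete_cophenetic(spearman_dist(m)),
      tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(
      as.matrix(stats::cophenetic(res$col_hclust)),
      brute_force_complete_cophenetic(dist(t(m))),
      tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("clustering is invariant to input permutation (same heights and partitions)", {
  set.seed(8)
  m <- matrix(rnorm(30), 5, dimnames = list(paste0("r", 1:5), paste0("c", 1:6)))
  res1 <- cluster_profiles(m)
  perm <- c(4, 1, 5, 2, 3)
  res2 <- cluster_profiles(m[perm, ])
  expect_equal(res1$row_hclust$height, res2$row_hclust$height,
               tolerance = 1e-12)
  c1 <- as.matrix(stats::cophenetic(res1$row_hclust))
  c2 <- as.matrix(stats::cophenetic(res2$row_hclust))
  expect_equal(c1, c2[rownames(c1), colnames(c1)], tolerance = 1e-12)
})

test_that("TreeView export round trips losslessly", {
  set.seed(12)
  m <- matrix(rnorm(20), 4, dimnames = list(paste0("cmpd", 1:4),
                                            paste0("line", 1:5)))
  res <- cluster_profiles(m)
  base <- file.path(withr::local_tempdir(), "clust")
  paths <- export_cluster_files(res, base)
  expect_true(all(file.exists(paths)))
  back <- read_cdt(base)
  expect_equal(back$values, m[res$row_order, res$col_order],
               tolerance = 1e-12)
  expect_equal(back$row_tree$height, res$row_hclust$height,
               tolerance = 1e-12)
  expect_equal(back$row_tree$merge, res$row_hclust$merge)
  expect_equal(back$col_tree$merge, res$col_hclust$merge)
  # leaf order in the CDT matches the ClusterResult order
  expect_equal(rownames(back$values), rownames(m)[res$row_order])

  # 2x2: one merge per tree
  res2 <- cluster_profiles(m[1:2, 1:2])
  base2 <- file.path(withr::local_tempdir(), "c2")
  export_cluster_files(res2, base2)
  expect_length(readLines(paste0(base2, ".gtr")), 1)
  expect_equal(nrow(read_cdt(base2)$values), 2)
})

test_that("responder groups are recovered exactly from planted truth at zero noise", {
  lib <- make_library(40, seed = 21)
  lines <- sprintf("L%02d", 1:8)
  truth <- make_truth(lines, lib, seed = 22)
  w <- simulate_screen(lines, lib, truth, noise_model(cv_mult = 0, seed = 23),
                       readouts = "tox_fluor")
  scored <- score_screen(normalize_screen(w))
  groups <- define_responder_groups(scored, lib,
                                    drug_class = c("taxane", "vinca",
                                                   "proteasome"),
                                    threshold = 5)
  expect_setequal(groups$sensitive, truth$sensitive_lines)
  expect_setequal(groups$insensitive, setdiff(lines, truth$sensitive_lines))
  expect_error(define_responder_groups(scored, lib, "no_such_class"),
               "no compounds")
})

test_that("responder-group edge cases warn or split as documented", {
  rec <- data.frame(cell_line = c("A", "B"), compound_id = "c1",
                    readout = "tox_fluor", dss = c(20, 1),
                    stringsAsFactors = FALSE)
  lib <- data.frame(compound_id = "c1", drug_class = "taxane",
                    stringsAsFactors = FALSE)
  g <- define_responder_groups(rec, lib, "taxane", threshold = 5)
  expect_equal(g$sensitive, "A")
  expect_equal(g$insensitive, "B")
  rec$dss <- c(2, 1)
  expect_warning(g2 <- define_responder_groups(rec, lib, "taxane",
                                               threshold = 5), "threshold")
  expect_length(g2$sensitive, 0)
})

test_that("marker t-tests match stats::t.test and handle degenerate groups", {
  set.seed(33)
  tab <- matrix(rnorm(5 * 8), 5,
                dimnames = list(paste0("m", 1:5), paste0("L", 1:8)))
  groups <- list(sensitive = paste0("L", 1:4), insensitive = paste0("L", 5:8))
  res <- marker_ttest(tab, groups)
  for (i in 1:5) {
    ref <- t.test(tab[i, 1:4], tab[i, 5:8])
    expect_equal(res$t[i], unname(ref$statistic), tolerance = 1e-12)
    expect_equal(res$p[i], ref$p.value, tolerance = 1e-12)
    expect_equal(res$df[i], unname(ref$parameter), tolerance = 1e-12)
  }
  pooled <- marker_ttest(tab, groups, var_equal = TRUE)
  ref_p <- t.test(tab[1, 1:4], tab[1, 5:8], var.equal = TRUE)
  expect_equal(pooled$t[1], unname(ref_p$statistic), tolerance = 1e-12)

  # identical values in both groups: t = 0, p = 1 rather than an error
  tab2 <- tab
  tab2[2, ] <- 7
  res2 <- marker_ttest(tab2, groups)
  expect_equal(res2$t[2], 0)
  expect_equal(res2$p[2], 1)

  bh <- marker_ttest(tab, groups, adjust = "BH")
  expect_equal(bh$p_adj, p.adjust(bh$p, "BH"))

  expect_error(marker_ttest(tab, list(sensitive = "L1",
                                      insensitive = paste0("L", 5:8))),
               "sensitive")
  expect_error(marker_ttest(tab, list(sensitive = c("L1", "NOPE"),
                                      insensitive = paste0("L", 5:8))),
               "NOPE")
})

test_that("planted informative markers are recovered by the t-test workflow", {
  groups_def <- list(paste0("S", 1:4), paste0("R", 1:4))
  hits <- vapply(1:20, function(seed) {
    sim <- simulate_marker_table(groups_def, 70, 9, effect_size = 3,
                                 seed = seed)
    res <- marker_ttest(sim$table,
                        list(sensitive = groups_def[[1]],
                             insensitive = groups_def[[2]]))
    sum(res$significant & res$marker %in% sim$informative)
  }, numeric(1))
  expect_gte(mean(hits >= 7), 0.8)
})
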