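test_that("make_library respects size, dose design and determinism", {
  lib <- make_library(301, seed = 7)
  expect_s3_class(lib, "compound_library")
  expect_equal(nrow(lib), 301)
  expect_true(all(lib$n_conc == 5))
  ranges <- vapply(seq_len(nrow(lib)), function(i) {
    cc <- tested_concs(lib[i, ])
    max(cc) / min(cc)
  }, numeric(1))
  expect_equal(ranges, rep(1e4, 301))

  expect_identical(make_library(50, seed = 3), make_library(50, seed = 3))
  expect_equal(nrow(make_library(0)), 0)
  expect_error(make_library(10, class_mix = c(a = 0.7, b = 0.7)),
               "sum")
  # class counts follow the mix as closely as integers allow
  counts <- table(lib$drug_class)
  expect_equal(sum(counts), 301)
  expect_true(abs(counts[["inactive"]] - 0.40 * 301) <= 1)
})

test_that("zero-noise plates pin inactive wells to the negative control and lethal doses to the positive control", {
  lib <- make_library(4, class_mix = c(inactive = 1), seed = 1)
  truth <- make_truth("L1", lib, seed = 2)
  w <- simulate_plate("L1", lib, truth, noise_model(cv_mult = 0, seed = 3))
  # force exactly zero effect for the check
  truth$models$top[] <- 0
  w0 <- simulate_plate("L1", lib, truth, noise_model(cv_mult = 0, seed = 3))
  for (rd in unique(w0$readout)) {
    g <- w0[w0$readout == rd, ]
    mu_neg <- mean(g$signal[g$role == "neg"])
    expect_equal(g$signal[g$role == "sample"],
                 rep(mu_neg, sum(g$role == "sample")))
  }
  # fully lethal at every dose: top 100, EC50 far below the tested range
  truth$models$top[] <- 100
  truth$models$log_ec50[] <- -15
  w100 <- simulate_plate("L1", lib, truth, noise_model(cv_mult = 0, seed = 3))
  for (rd in unique(w100$readout)) {
    g <- w100[w100$readout == rd, ]
    mu_pos <- mean(g$signal[g$role == "pos"])
    expect_equal(g$signal[g$role == "sample"],
                 rep(mu_pos, sum(g$role == "sample")), tolerance = 1e-12)
  }
})

test_that("plate layout: 384-well capacity, 16 neg + 8 pos controls, capacity errors", {
  tw <- tiny_world(70, lines = "L1")
  w <- simulate_plate("L1", tw$lib, tw$truth, noise_model(seed = 1),
                      readouts = "viab_lum")
  expect_equal(sum(w$role == "neg"), 16)
  expect_equal(sum(w$role == "pos"), 8)
  expect_lte(length(unique(w$well)), 384)
  expect_false(anyDuplicated(w$well) > 0)

  big <- tiny_world(71, lines = "L1")
  expect_error(
    simulate_plate("L1", big$lib, big$truth, noise_model(seed = 1)),
    "capacity")
})

test_that("missing truth record errors with the offending key", {
  tw <- tiny_world(3, lines = "L1")
  tr <- tw$truth
  tr$models <- tr$models[tr$models$compound_id != "CMPD_0002", ]
  expect_error(
    simulate_plate("L1", tw$lib, tr, noise_model(seed = 1)),
    "CMPD_0002")
})

test_that("every well traces to exactly one truth record and the archetype invariants hold", {
  tw <- tiny_world(40, lines = c("L1", "L2", "L3", "L4"))
  w <- simulate_screen(tw$lines, tw$lib, tw$truth, noise_model(seed = 5))
  te <- true_effects(w, tw$truth)
  expect_equal(nrow(te), sum(w$role == "sample"))

  m <- tw$truth$models
  key <- paste(m$cell_line, m$compound_id, m$channel)
  expect_equal(anyDuplicated(key), 0L)

  wide <- merge(m[m$channel == "viab", c("cell_line", "compound_id",
                                         "archetype", "top")],
                m[m$channel == "tox", c("cell_line", "compound_id", "top")],
                by = c("cell_line", "compound_id"),
                suffixes = c("_viab", "_tox"))
  cs <- wide[wide$archetype == "cytostatic", ]
  expect_true(all(cs$top_viab >= 65 & cs$top_tox <= 10))
  ina <- wide[wide$archetype == "inactive", ]
  expect_true(all(ina$top_viab <= 10 & ina$top_tox <= 10))
  ct <- wide[wide$archetype == "cytotoxic", ]
  expect_true(all(ct$top_tox >= 60 & ct$top_viab >= ct$top_tox - 1e-12))
})

test_that("simulator output is byte-identical under identical seed/config", {
  tw <- tiny_world(10)
  w1 <- simulate_screen(tw$lines, tw$lib, tw$truth,
                        noise_model(0.05, seed = 42))
  w2 <- simulate_screen(tw$lines, tw$lib, tw$truth,
                        noise_model(0.05, seed = 42))
  expect_identical(w1, w2)
  w3 <- simulate_screen(tw$lines, tw$lib, tw$truth,
                        noise_model(0.05, seed = 43))
  expect_false(identical(w1, w3))
})

test_that("control-well noise converges to the configured CV", {
  tw <- tiny_world(1, lines = sprintf("L%03d", 1:630))
  w <- simulate_screen(tw$lines, tw$lib, tw$truth,
                       noise_model(0.05, seed = 9), readouts = "viab_lum")
  neg <- w$signal[w$role == "neg"]
  expect_gte(length(neg), 1e4)
  cv_hat <- sd(neg) / mean(neg)
  se <- 0.05 / sqrt(2 * length(neg))
  expect_lt(abs(cv_hat - 0.05), 3 * se + 1e-4)
})

test_that("edge gradient tilts signals while the default leaves them flat", {
  lib <- make_library(10, class_mix = c(inactive = 1), seed = 1)
  truth <- make_truth("L1", lib, seed = 2)
  truth$models$top[] <- 0
  flat <- simulate_plate("L1", lib, truth, noise_model(cv_mult = 0, seed = 1),
                         readouts = "viab_lum")
  tilt <- simulate_plate("L1", lib, truth,
                         noise_model(cv_mult = 0, gradient = 0.2, seed = 1),
                         readouts = "viab_lum")
  flat_s <- flat[flat$role == "sample", ]
  tilt_s <- tilt[tilt$role == "sample", ]
  expect_equal(length(unique(round(flat_s$signal, 6))), 1L)
  expect_gt(length(unique(round(tilt_s$signal, 6))), 1L)
  first_col <- tilt_s$signal[substring(tilt_s$well, 2) == "01"]
  last_col <- tilt_s$signal[substring(tilt_s$well, 2) == "22"]
  expect_gt(mean(last_col), mean(first_col))
})

test_that("combination simulator validates inputs and plants Bliss-exact matrices", {
  doses <- 10^seq(0, 3, length.out = 7)
  dA <- combo_drug(doses, viab = list(top = 55, log_ec50 = 1.5, slope = 1))
  dB <- combo_drug(doses, viab = list(top = 60, log_ec50 = 2, slope = 1.2))
  expect_error(
    simulate_combination_matrix(dA, dB, interaction_delta = 120),
    "100")
  sim <- simulate_combination_matrix(dA, dB, 0,
                                     noise = noise_model(cv_mult = 0),
                                     readouts = "viab_lum")
  m <- sim$matrices$viab_lum
  expect_equal(dim(m$response), c(8L, 8L))
  expect_equal(m$response[1, 1], 0)
  # monotherapy edges match the planted curves
  expect_equal(m$response[-1, 1],
               55 / (1 + 10^(1 * (1.5 - log10(doses)))), tolerance = 1e-12)
})

test_that("marker simulator plants group shifts and is deterministic", {
  groups <- list(paste0("S", 1:4), paste0("R", 1:4))
  sim <- simulate_marker_table(groups, n_markers = 70, n_informative = 9,
                               effect_size = 3, seed = 5)
  expect_equal(dim(sim$table), c(70L, 8L))
  expect_length(sim$informative, 9)
  sim2 <- simulate_marker_table(groups, 70, 9, 3, seed = 5)
  expect_identical(sim$table, sim2$table)

  null_sim <- simulate_marker_table(groups, 70, 9, effect_size = 0, seed = 5)
  shift <- rowMeans(null_sim$table[, groups[[1]]]) -
    rowMeans(null_sim$table[, groups[[2]]])
  expect_lt(max(abs(shift[null_sim$informative])), 3)

  expect_error(simulate_marker_table(groups, 10, 11), "exceed")
  expect_error(simulate_marker_table(list("A", c("B", "C"))), "2 cell lines")
  expect_error(
    simulate_marker_table(list(c("A", "B"), c("B", "C"))), "disjoint")
})
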