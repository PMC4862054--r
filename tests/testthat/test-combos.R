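doses7 <- 10^seq(0, 3, length.out = 7)
drugA55 <- combo_drug(doses7,
                      viab = list(top = 55, log_ec50 = 1.5, slope = 1),
                      tox = list(top = 50, log_ec50 = 1.8, slope = 1.3))
drugB60 <- combo_drug(doses7,
                      viab = list(top = 60, log_ec50 = 2, slope = 1.2),
                      tox = list(top = 45, log_ec50 = 2.2, slope = 0.8))

sim_matrix <- function(delta, cv = 0, seed = 1, readouts = "viab_lum",
                       mode = "uniform") {
  simulate_combination_matrix(drugA55, drugB60, delta, mode = mode,
                              noise = noise_model(cv_mult = cv, seed = seed),
                              readouts = readouts)$matrices
}

test_that("bliss_expected satisfies the independence identities", {
  expect_equal(bliss_expected(0.5, 0.5), 0.75)
  expect_equal(bliss_expected(0, 0.3), 0.3)
  expect_equal(bliss_expected(1, c(0, 0.4, 1)), c(1, 1, 1))
  expect_error(bliss_expected(1.2, 0.5), "\\[0, 1\\]")
})

test_that("combo_matrix validates shape and dose grids", {
  expect_error(combo_matrix(matrix(0, 7, 7), c(0, doses7[-7]), c(0, doses7[-7])),
               "8x8")
  expect_error(combo_matrix(matrix(0, 8, 8), doses7[1:8 %% 2 == 1], c(0, doses7)),
               "length 8")
  expect_error(combo_matrix(matrix(0, 8, 8), c(1, 2:8), c(0, 2:8)),
               "start at 0")
})

test_that("Bliss score is zero on independent matrices and exact on planted uniform synergy", {
  m0 <- sim_matrix(0)[[1]]
  b0 <- bliss_matrix(m0)
  expect_equal(max(abs(b0$bliss)), 0, tolerance = 1e-10)
  m15 <- sim_matrix(15)[[1]]
  b15 <- bliss_matrix(m15)
  expect_equal(unname(b15$bliss), matrix(15, 7, 7), tolerance = 1e-9)
  expect_equal(b15$bliss_mean, 15, tolerance = 1e-9)
})

test_that("ZIP delta is near zero on Bliss-independent logistic matrices and recovers planted synergy", {
  z0 <- zip_delta(sim_matrix(0)[[1]])
  expect_lte(abs(z0$zip_delta), 0.5)
  expect_length(z0$fallback_slices, 0)
  z15 <- zip_delta(sim_matrix(15)[[1]])
  expect_lt(abs(z15$zip_delta - 15), 2)
  # all-zero matrix gives delta zero
  null_m <- combo_matrix(matrix(0, 8, 8), c(0, doses7), c(0, doses7))
  expect_equal(zip_delta(null_m)$zip_delta, 0, tolerance = 1e-8)
})

test_that("both models are symmetric under drug swap", {
  m <- sim_matrix(10, cv = 0.05, seed = 7)[[1]]
  mt <- combo_matrix(t(m$response), m$drugB_doses, m$drugA_doses,
                     readout = m$readout)
  expect_equal(bliss_matrix(m)$bliss_mean, bliss_matrix(mt)$bliss_mean,
               tolerance = 1e-9)
  expect_equal(zip_delta(m)$zip_delta, zip_delta(mt)$zip_delta,
               tolerance = 1e-6)
})

test_that("dose-dependent mode concentrates the interaction at active doses", {
  m <- sim_matrix(20, mode = "dose_dependent")[[1]]
  b <- bliss_matrix(m)$bliss
  expect_gt(b[7, 7], b[1, 1])
  expect_gte(min(b), -1e-9)
})

test_that("per-readout scoring decouples viability and toxicity interactions", {
  sim <- simulate_combination_matrix(
    drugA55, drugB60,
    interaction_delta = c(viab_lum = 0, tox_fluor = -20),
    noise = noise_model(cv_mult = 0),
    readouts = c("viab_lum", "tox_fluor"))
  res <- score_combination(sim$matrices, model = "both")
  expect_s3_class(res, "synergy_result")
  expect_lt(abs(res$viab_lum$bliss_mean), 0.5)
  expect_lt(res$tox_fluor$bliss_mean, -5)
  expect_lt(res$tox_fluor$zip_delta, -3)
  expect_gt(res$viab_lum$zip_delta, res$tox_fluor$zip_delta)

  single <- score_combination(sim$matrices$viab_lum, model = "bliss")
  expect_length(single, 1)
  expect_null(single[[1]]$zip_delta)
})

test_that("missing monotherapy values error; fractions are clipped before expectation", {
  m <- sim_matrix(0)[[1]]
  m$response[1, 3] <- NA
  expect_error(bliss_matrix(m), "monotherapy")
  # negative and >100 observations are clipped, keeping scores in range
  m2 <- sim_matrix(0)[[1]]
  m2$response[2, 2] <- -50
  m2$response[8, 8] <- 180
  b <- bliss_matrix(m2)$bliss
  expect_gte(min(b), -100)
  expect_lte(max(b), 100)
})

test_that("combination tables round trip through the long TSV format", {
  sim <- simulate_combination_matrix(
    drugA55, drugB60, c(viab_lum = 5, tox_fluor = -5),
    noise = noise_model(cv_mult = 0.05, seed = 3),
    readouts = c("viab_lum", "tox_fluor"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_combination_table(sim$matrices, path)
  back <- read_combination_table(path)
  expect_setequal(names(back), c("viab_lum", "tox_fluor"))
  expect_equal(back$viab_lum$response, sim$matrices$viab_lum$response,
               tolerance = 1e-9)
  expect_equal(back$tox_fluor$drugA_doses, c(0, doses7))
})

test_that("synergy JSON export writes both models per readout", {
  sim <- sim_matrix(10, readouts = "viab_lum")
  res <- score_combination(sim, model = "both")
  path <- withr::local_tempfile(fileext = ".json")
  write_synergy_json(res, path)
  parsed <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(parsed$viab_lum$bliss_mean, res$viab_lum$bliss_mean,
               tolerance = 1e-9)
  expect_equal(dim(parsed$viab_lum$bliss), c(7L, 7L))
  expect_equal(parsed$viab_lum$bliss, unname(res$viab_lum$bliss),
               tolerance = 1e-9)
})
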