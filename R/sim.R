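#' Synthetic dual-readout screen generator
#'
#' Generates single-agent screens, dose-combination matrices and protein
#' marker tables with known ground truth, emulating a 384-well
#' drug-sensitivity-and-resistance-testing (DSRT) design: each compound at 5
#' concentrations in 10-fold dilutions (a 10,000-fold range) centered around
#' its cellular activity concentration, plates carrying 0.1% DMSO negative
#' controls and 100 uM benzethonium chloride positive controls, and three
#' readout channels — two viability channels (fluorescent and luminescent)
#' that share the planted viability response, and one cytotoxicity channel
#' with its own planted response. Decoupling the two planted responses is
#' the point: "cytostatic" compounds have a strong viability effect with
#' near-zero toxicity, which no single-channel simulation can represent.
#'
#' Raw-signal scale is fixed so fixtures are stable: negative-control mean
#' 10,000 units and positive-control mean 200 for viability channels
#' (reversed for the toxicity channel, which gains signal as cells die).
#' Noise is multiplicative log-normal (mean 1, coefficient of variation
#' `cv_mult`) plus optional additive Gaussian background.
#'
#' @name screen_sim
NULL

.default_class_mix <- c(
  mTOR = 0.04, PI3K = 0.04, HSP90 = 0.03, antimetabolite = 0.05,
  NAMPT = 0.01, CDK = 0.05, taxane = 0.04, vinca = 0.03, proteasome = 0.03,
  topoisomerase = 0.04, HDAC = 0.04, kinase_other = 0.20, inactive = 0.40
)

# classes that arrest growth broadly without killing / that kill only a
# sensitive subset of lines
.cytostatic_classes <- c("mTOR", "PI3K", "HSP90", "antimetabolite", "NAMPT")
.cytotoxic_subset_classes <- c("CDK", "taxane", "vinca", "proteasome",
                               "topoisomerase", "HDAC")
.chemo_classes <- c("taxane", "vinca", "antimetabolite", "proteasome",
                    "topoisomerase")

#' Noise model for the simulator
#'
#' @param cv_mult coefficient of variation of multiplicative log-normal
#'   signal noise (default 0.05, a typical well-to-well CV for a tuned
#'   384-well assay).
#' @param sd_add additive Gaussian background standard deviation, in raw
#'   signal units (default 0).
#' @param gradient strength of an optional deterministic linear row/column
#'   edge effect (default 0 = off): expected signals are scaled by
#'   `1 + gradient * g(well)` where `g` runs from -0.5 at the top-left to
#'   +0.5 at the bottom-right of the plate.
#' @param seed integer seed; identical seed and configuration give
#'   bit-identical output. `NULL` uses the current RNG state.
#' @return a `noise_model` list.
#' @export
noise_model <- function(cv_mult = 0.05, sd_add = 0, gradient = 0,
                        seed = NULL) {
  stopifnot(cv_mult >= 0, sd_add >= 0)
  structure(list(cv_mult = cv_mult, sd_add = sd_add, gradient = gradient,
                 seed = seed),
            class = "noise_model")
}

# multiplicative log-normal factor with mean 1 and CV cv
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

add_noise <- function(mu, noise) {
  pmax(mu * rlnorm_cv(length(mu), noise$cv_mult) +
         stats::rnorm(length(mu), 0, noise$sd_add), 0)
}

#' Generate a compound library
#'
#' Draws `n_compounds` compound specifications with drug-class labels from
#' `class_mix` (class counts by largest-remainder rounding, so the library is
#' reproducible and matches the proportions as closely as integers allow).
#' Each compound gets a 5-point, 10-fold dilution series spanning a
#' 10,000-fold range, positioned per class around a plausible activity
#' concentration.
#'
#' @param n_compounds number of compounds (the emulated design uses 301).
#' @param class_mix named proportions summing to 1.
#' @param seed integer seed.
#' @param n_conc concentrations per compound (default 5).
#' @param dilution_factor fold-dilution between consecutive doses (default 10).
#' @return data.frame of class `compound_library`: `compound_id`,
#'   `drug_class`, `conc_min` (nM), `n_conc`, `dilution_factor`.
#' @export
make_library <- function(n_compounds, class_mix = .default_class_mix,
                         seed = 1L, n_conc = 5L, dilution_factor = 10) {
  if (n_compounds < 0) stop("n_compounds must be >= 0")
  if (any(class_mix < 0) || abs(sum(class_mix) - 1) > 1e-8) {
    stop("class_mix must be nonnegative proportions summing to 1")
  }
  if (n_conc < 2L) stop("need at least 2 concentrations")
  if (dilution_factor <= 1) stop("dilution_factor must exceed 1")
  if (n_compounds == 0L) {
    out <- data.frame(compound_id = character(), drug_class = character(),
                      conc_min = numeric(), n_conc = integer(),
                      dilution_factor = numeric(), stringsAsFactors = FALSE)
    class(out) <- c("compound_library", "data.frame")
    return(out)
  }
  set.seed(seed)
  # largest-remainder apportionment of class counts
  quota <- class_mix * n_compounds
  counts <- floor(quota)
  rem <- n_compounds - sum(counts)
  if (rem > 0) {
    top_up <- order(quota - counts, decreasing = TRUE)[seq_len(rem)]
    counts[top_up] <- counts[top_up] + 1
  }
  cls <- rep(names(class_mix), counts)
  # low-dose anchor per compound: classes differ in typical potency; the
  # tested range then covers dilution_factor^(n_conc-1) around it
  conc_min <- 10^stats::runif(n_compounds, -1, 1)
  out <- data.frame(
    compound_id = sprintf("CMPD_%04d", seq_len(n_compounds)),
    drug_class = cls,
    conc_min = conc_min,
    n_conc = as.integer(n_conc),
    dilution_factor = dilution_factor,
    stringsAsFactors = FALSE
  )
  class(out) <- c("compound_library", "data.frame")
  out
}

#' Tested concentrations of a compound
#'
#' @param spec one row of a [make_library()] data.frame.
#' @return numeric vector of `n_conc` concentrations (nM), increasing.
#' @export
tested_concs <- function(spec) {
  spec$conc_min * spec$dilution_factor^(0:(spec$n_conc - 1))
}

draw_active <- function(n, x_center) {
  # log-EC50 centered on the middle of the tested range (the design places
  # doses around each compound's activity concentration); truncated normal
  c_draw <- stats::rnorm(n, x_center, 0.5)
  c_draw <- pmin(pmax(c_draw, x_center - 1), x_center + 1)
  list(top = stats::runif(n, 65, 100), log_ec50 = c_draw,
       slope = stats::runif(n, 0.8, 2.5))
}

draw_inactive <- function(n, x_center) {
  list(top = stats::runif(n, 0, 8),
       log_ec50 = stats::runif(n, x_center - 1, x_center + 1),
       slope = stats::runif(n, 0.8, 2.5))
}

#' Plant ground-truth dose-response models for a screen
#'
#' Assigns each cell line x compound an archetype and draws logistic
#' parameters for the viability and toxicity channels:
#' * `cytostatic` — strong viability response (top 65-100%), near-zero
#'   toxicity (top 0-8%, below the 10% activity threshold);
#' * `cytotoxic` — strong toxicity (top 60-100%) and at least as strong a
#'   viability response;
#' * `inactive` — both tops at most 8%.
#' Broadly cytostatic classes (PI3K/mTOR, HSP90, antimetabolites, NAMPT) are
#' cytostatic in every line; classically cytotoxic classes (CDK inhibitors,
#' anti-mitotics, proteasome/topoisomerase/HDAC inhibitors) are cytotoxic
#' only in a sensitive subset of lines and cytostatic elsewhere; remaining
#' kinase inhibitors respond sporadically; `inactive` compounds never do.
#' Active log-EC50s sit within the central part of each compound's tested
#' range (truncated normal, sd 0.5 log10 units).
#'
#' @param cell_lines character vector of cell-line ids.
#' @param library a [make_library()] data.frame.
#' @param seed integer seed.
#' @param n_sensitive number of toxicity-sensitive lines (default
#'   `max(2, round(length(cell_lines) / 3))`, emulating the minority of lines
#'   that die in response to conventional cytotoxics).
#' @return `dsrt_truth`: list with `models` (data.frame: `cell_line`,
#'   `compound_id`, `channel` in `{viab, tox}`, `archetype`, `top`,
#'   `log_ec50`, `slope`), `sensitive_lines`, `library`.
#' @export
make_truth <- function(cell_lines, library, seed = 1L,
                       n_sensitive = max(2L, round(length(cell_lines) / 3))) {
  stopifnot(length(cell_lines) >= 1L, nrow(library) >= 1L)
  set.seed(seed)
  sensitive <- sample(cell_lines, min(n_sensitive, length(cell_lines)))
  x_center <- log10(library$conc_min) +
    (library$n_conc - 1) / 2 * log10(library$dilution_factor)

  grid <- expand.grid(cell_line = cell_lines,
                      ci = seq_len(nrow(library)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cls <- library$drug_class[grid$ci]
  in_sensitive <- grid$cell_line %in% sensitive
  n <- nrow(grid)

  archetype <- rep("inactive", n)
  archetype[cls %in% .cytostatic_classes] <- "cytostatic"
  archetype[cls %in% .cytotoxic_subset_classes] <-
    ifelse(in_sensitive[cls %in% .cytotoxic_subset_classes],
           "cytotoxic", "cytostatic")
  is_other <- cls == "kinase_other"
  archetype[is_other] <- sample(c("cytostatic", "cytotoxic", "inactive"),
                                sum(is_other), replace = TRUE,
                                prob = c(0.2, 0.1, 0.7))

  xc <- x_center[grid$ci]
  act <- draw_active(n, xc)
  inact_v <- draw_inactive(n, xc)
  act_tox <- draw_active(n, xc)
  act_tox$top <- stats::runif(n, 60, 100)
  inact_t <- draw_inactive(n, xc)

  is_active_v <- archetype != "inactive"
  top_v <- ifelse(is_active_v, act$top, inact_v$top)
  c_v <- ifelse(is_active_v, act$log_ec50, inact_v$log_ec50)
  s_v <- ifelse(is_active_v, act$slope, inact_v$slope)

  is_tox <- archetype == "cytotoxic"
  top_t <- ifelse(is_tox, act_tox$top, inact_t$top)
  c_t <- ifelse(is_tox, act_tox$log_ec50, inact_t$log_ec50)
  s_t <- ifelse(is_tox, act_tox$slope, inact_t$slope)
  # cell death implies loss of viability signal: viability at least as strong
  top_v[is_tox] <- pmax(top_v[is_tox], top_t[is_tox])

  compound_id <- library$compound_id[grid$ci]
  models <- rbind(
    data.frame(cell_line = grid$cell_line, compound_id = compound_id,
               channel = "viab", archetype = archetype, top = top_v,
               log_ec50 = c_v, slope = s_v, stringsAsFactors = FALSE),
    data.frame(cell_line = grid$cell_line, compound_id = compound_id,
               channel = "tox", archetype = archetype, top = top_t,
               log_ec50 = c_t, slope = s_t, stringsAsFactors = FALSE)
  )
  structure(list(models = models, sensitive_lines = sensitive,
                 library = library),
            class = "dsrt_truth")
}

readout_channel <- function(readout) {
  ifelse(readout == "tox_fluor", "tox", "viab")
}

logistic_effect <- function(top, log_ec50, slope, x) {
  top / (1 + 10^(slope * (log_ec50 - x)))
}

# raw-signal anchors per channel (negative mean, positive mean)
.signal_anchors <- list(viab = c(neg = 10000, pos = 200),
                        tox = c(neg = 200, pos = 10000))

effect_to_signal <- function(effect, channel) {
  a <- .signal_anchors[[channel]]
  a[["neg"]] + (a[["pos"]] - a[["neg"]]) * effect / 100
}

well_ids <- function() {
  sprintf("%s%02d", rep(LETTERS[1:16], each = 24), rep(1:24, times = 16))
}

# internal plate builder: no reseeding, noise drawn from current RNG state
simulate_plate_wells <- function(cell_line, library_chunk, truth, noise,
                                 readouts, plate_id) {
  n_sample_wells <- sum(library_chunk$n_conc)
  if (n_sample_wells > 352L) {
    stop("plate capacity exceeded: ", n_sample_wells,
         " sample wells > 352 (384 minus 32 control/spare wells)")
  }
  ids <- well_ids()
  col_of <- rep(1:24, times = 16)
  row_of <- rep(1:16, each = 24)
  sample_ids <- ids[col_of <= 22][seq_len(n_sample_wells)]
  neg_ids <- ids[col_of == 23]                      # 16 negative controls
  pos_ids <- ids[col_of == 24 & row_of <= 8]        # 8 positive controls

  compound <- rep(library_chunk$compound_id, library_chunk$n_conc)
  conc <- unlist(lapply(seq_len(nrow(library_chunk)), function(i) {
    tested_concs(library_chunk[i, ])
  }), use.names = FALSE)

  key <- paste(truth$models$cell_line, truth$models$compound_id,
               truth$models$channel, sep = "\r")
  out <- vector("list", length(readouts))
  for (ri in seq_along(readouts)) {
    rd <- readouts[[ri]]
    ch <- readout_channel(rd)
    idx <- match(paste(cell_line, compound, ch, sep = "\r"), key)
    if (anyNA(idx)) {
      bad <- compound[is.na(idx)][1]
      stop(sprintf("no truth record for (%s, %s, %s)", cell_line, bad, ch))
    }
    tm <- truth$models[idx, ]
    effect <- logistic_effect(tm$top, tm$log_ec50, tm$slope, log10(conc))
    mu <- c(effect_to_signal(effect, ch),
            rep(effect_to_signal(0, ch), length(neg_ids)),
            rep(effect_to_signal(100, ch), length(pos_ids)))
    g <- if (is.null(noise$gradient) || noise$gradient == 0) {
      1
    } else {
      all_ids <- c(sample_ids, neg_ids, pos_ids)
      wr <- match(substring(all_ids, 1, 1), LETTERS)
      wc <- as.integer(substring(all_ids, 2))
      1 + noise$gradient * ((wr - 8.5) / 15 + (wc - 12.5) / 23) / 2
    }
    out[[ri]] <- data.frame(
      plate_id = plate_id,
      well = c(sample_ids, neg_ids, pos_ids),
      role = c(rep("sample", n_sample_wells), rep("neg", length(neg_ids)),
               rep("pos", length(pos_ids))),
      cell_line = cell_line,
      compound_id = c(compound, rep(NA_character_,
                                    length(neg_ids) + length(pos_ids))),
      conc = c(conc, rep(NA_real_, length(neg_ids) + length(pos_ids))),
      readout = rd,
      signal = add_noise(mu * g, noise),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Simulate one 384-well plate
#'
#' Lays compounds (all of their concentrations) into sample wells
#' (columns 1-22), 16 negative-control wells (column 23) and 8
#' positive-control wells (column 24, rows A-H), then maps each well's
#' planted true effect through the control-anchored linear signal scale and
#' applies noise. With zero noise an inactive compound's wells equal the
#' negative-control mean exactly and a fully lethal dose equals the
#' positive-control mean.
#'
#' @param cell_line cell-line id (must exist in `truth`).
#' @param library a [make_library()] data.frame (at most 70 compounds of 5
#'   doses fit one plate).
#' @param truth a [make_truth()] object.
#' @param noise a [noise_model()]; its `seed` (if non-NULL) is set on entry.
#' @param readouts channels to emit (default all three).
#' @param plate_id plate identifier.
#' @return well data.frame in the screen-table schema (one row per well per
#'   readout).
#' @export
simulate_plate <- function(cell_line, library, truth, noise = noise_model(),
                           readouts = c("viab_fluor", "viab_lum", "tox_fluor"),
                           plate_id = "P1") {
  if (!is.null(noise$seed)) set.seed(noise$seed)
  simulate_plate_wells(cell_line, library, truth, noise, readouts, plate_id)
}

#' Simulate a full multi-plate, multi-line screen
#'
#' Splits the compound library over as many 384-well plates as needed per
#' cell line (352 sample wells each) and simulates every plate for every
#' requested readout.
#'
#' @inheritParams simulate_plate
#' @param cell_lines character vector of cell-line ids.
#' @return well data.frame in the screen-table schema.
#' @export
simulate_screen <- function(cell_lines, library, truth,
                            noise = noise_model(),
                            readouts = c("viab_fluor", "viab_lum",
                                         "tox_fluor")) {
  if (!is.null(noise$seed)) set.seed(noise$seed)
  per_plate <- max(1L, floor(352L / max(library$n_conc)))
  chunks <- split(seq_len(nrow(library)),
                  ceiling(seq_len(nrow(library)) / per_plate))
  out <- list()
  for (cl in cell_lines) {
    for (pi in seq_along(chunks)) {
      out[[length(out) + 1L]] <- simulate_plate_wells(
        cl, library[chunks[[pi]], , drop = FALSE], truth, noise, readouts,
        plate_id = sprintf("%s_P%02d", cl, pi))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' True planted effect for each sample well (oracle)
#'
#' Joins wells back to the planted truth and evaluates the noiseless percent
#' effect; used to verify that normalization recovers the planted world
#' exactly at zero noise and that every well traces to exactly one truth
#' record.
#'
#' @param wells screen-table data.frame (sample rows used).
#' @param truth a [make_truth()] object.
#' @return the sample-well subset of `wells` with a `true_effect` column.
#' @export
true_effects <- function(wells, truth) {
  s <- wells[wells$role == "sample", , drop = FALSE]
  key <- paste(truth$models$cell_line, truth$models$compound_id,
               truth$models$channel, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate truth records")
  idx <- match(paste(s$cell_line, s$compound_id,
                     readout_channel(s$readout), sep = "\r"), key)
  if (anyNA(idx)) stop("well without a matching truth record")
  tm <- truth$models[idx, ]
  s$true_effect <- logistic_effect(tm$top, tm$log_ec50, tm$slope,
                                   log10(s$conc))
  s
}

#' DSS of the planted truth curves
#'
#' Computes DSS1 directly from planted parameters over each compound's
#' tested range — the ground-truth score the pipeline should recover.
#'
#' @param truth a [make_truth()] object.
#' @param t activity threshold (default 10).
#' @return truth `models` data.frame with a `true_dss` column.
#' @export
true_dss <- function(truth, t = 10) {
  lib <- truth$library
  x1 <- log10(lib$conc_min)[match(truth$models$compound_id, lib$compound_id)]
  x2 <- x1 + (lib$n_conc[1] - 1) * log10(lib$dilution_factor[1])
  m <- truth$models
  m$true_dss <- vapply(seq_len(nrow(m)), function(i) {
    dss1(list(top = m$top[i], log_ec50 = m$log_ec50[i], slope = m$slope[i]),
         dss_config(x1 = x1[i], x2 = x2[i], t = t))
  }, numeric(1))
  m
}
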