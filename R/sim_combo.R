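#' Combination, anchored-screen and marker-table simulators
#'
#' @name screen_sim_extras
NULL

#' Drug description for combination simulation
#'
#' Holds a 7-point dose series plus per-channel logistic monotherapy
#' parameters — the ground truth a combination matrix is built from.
#'
#' @param doses 7 nonzero concentrations (nM), increasing.
#' @param viab,tox lists with `top`, `log_ec50`, `slope` for the viability /
#'   toxicity channel.
#' @param name drug name.
#' @return a `combo_drug` list.
#' @export
combo_drug <- function(doses, viab, tox = list(top = 0, log_ec50 = 0,
                                               slope = 1),
                       name = "drug") {
  stopifnot(length(doses) == 7L, all(doses > 0), all(diff(doses) > 0))
  structure(list(doses = doses, viab = viab, tox = tox, name = name),
            class = "combo_drug")
}

drug_effect <- function(drug, channel, x) {
  p <- drug[[channel]]
  logistic_effect(p$top, p$log_ec50, p$slope, x)
}

#' Simulate an 8x8 dose-combination matrix
#'
#' Builds the raw percent-response matrix for two drugs: 7 nonzero doses of
#' each plus the zero dose (8 levels per drug), so row 1 and column 1 are
#' monotherapies. Inner cells are the Bliss-independent expectation of the
#' two planted monotherapy effects plus a planted `interaction_delta`
#' (percentage points, clipped to \[0, 100\]), then noise. Deltas are
#' per-readout, so a combination can be planted synergistic in toxicity and
#' additive in viability (or any other decoupling).
#'
#' @param drugA,drugB [combo_drug()] objects.
#' @param interaction_delta named numeric: planted interaction per readout
#'   in percentage points (positive = synergy). Unnamed scalar applies to
#'   all readouts.
#' @param mode `"uniform"` applies the delta to every inner cell;
#'   `"dose_dependent"` scales it by the geometric mean of the two
#'   monotherapy effect fractions, concentrating the interaction at active
#'   doses.
#' @param noise a [noise_model()]; multiplicative CV acts on percent
#'   responses here, `sd_add` is additive percent noise.
#' @param readouts channels to emit.
#' @return list with `matrices` (named list of [combo_matrix()] per readout)
#'   and `truth` (planted deltas and monotherapy effects).
#' @export
simulate_combination_matrix <- function(drugA, drugB,
                                        interaction_delta = 0,
                                        mode = c("uniform", "dose_dependent"),
                                        noise = noise_model(),
                                        readouts = c("viab_lum",
                                                     "tox_fluor")) {
  mode <- match.arg(mode)
  stopifnot(inherits(drugA, "combo_drug"), inherits(drugB, "combo_drug"))
  if (any(abs(interaction_delta) > 100)) {
    stop("|interaction_delta| cannot exceed 100 percentage points")
  }
  if (is.null(names(interaction_delta))) {
    interaction_delta <- stats::setNames(
      rep(interaction_delta[[1]], length(readouts)), readouts)
  }
  if (!is.null(noise$seed)) set.seed(noise$seed)
  dosesA <- c(0, drugA$doses)
  dosesB <- c(0, drugB$doses)
  matrices <- list()
  truth <- list(delta = interaction_delta, mode = mode)
  for (rd in readouts) {
    ch <- readout_channel(rd)
    delta <- if (rd %in% names(interaction_delta)) {
      interaction_delta[[rd]]
    } else 0
    eA <- c(0, drug_effect(drugA, ch, log10(drugA$doses)))
    eB <- c(0, drug_effect(drugB, ch, log10(drugB$doses)))
    expected <- 100 * outer(eA / 100, eB / 100, bliss_expected)
    dmat <- matrix(0, 8, 8)
    dmat[-1, -1] <- switch(mode,
      uniform = delta,
      dose_dependent = delta * sqrt(outer(eA[-1] / 100, eB[-1] / 100)))
    clean <- pmin(pmax(expected + dmat, 0), 100)
    obs <- clean * rlnorm_cv(length(clean), noise$cv_mult) +
      stats::rnorm(length(clean), 0, noise$sd_add)
    truth[[rd]] <- list(clean = clean, monoA = eA, monoB = eB)
    matrices[[rd]] <- combo_matrix(matrix(obs, 8, 8), dosesA, dosesB,
                                   readout = rd, drugA = drugA$name,
                                   drugB = drugB$name)
  }
  list(matrices = matrices, truth = truth)
}

#' Simulate an anchored combination screen
#'
#' Emulates combining a fixed dose of an anchor drug (e.g. an mTOR
#' inhibitor) with a whole compound library in one sensitive cell line, with
#' planted anchor antagonism against conventional chemotherapeutics: for
#' targeted compounds the anchor blunts the toxicity response (top asymptote
#' scaled by `anchor_top_factor`, potency shifted right by
#' `anchor_ec50_shift` log10 units); all other compounds are untouched, so
#' their delta-DSS is exactly zero at zero noise. Targeted compounds are the
#' chemo-class compounds (anti-metabolites, vinca alkaloids, taxanes,
#' topoisomerase and proteasome inhibitors), planted with strong toxicity
#' (top 75-100%, log-EC50 within the central tested range, slope 1-2.5) so
#' the planted antagonism always exceeds the 10-DSS-unit flagging rule.
#'
#' @param cell_line id of the (toxicity-sensitive) screened line.
#' @param library a [make_library()] data.frame.
#' @param seed integer seed.
#' @param noise a [noise_model()].
#' @param anchor_top_factor multiplier on the targeted toxicity top (default
#'   0.4).
#' @param anchor_ec50_shift log10 shift of the targeted toxicity EC50
#'   (default +0.3).
#' @return list: `alone` and `with_anchor` (screen-table well data.frames,
#'   toxicity channel), `truth_alone`, `truth_anchor`, `targeted`
#'   (compound ids with planted antagonism).
#' @export
simulate_anchored_screen <- function(cell_line, library, seed = 1L,
                                     noise = noise_model(cv_mult = 0),
                                     anchor_top_factor = 0.4,
                                     anchor_ec50_shift = 0.3) {
  set.seed(seed)
  truth_alone <- make_truth(cell_line, library, seed = seed,
                            n_sensitive = 1L)
  m <- truth_alone$models
  targeted <- library$compound_id[library$drug_class %in% .chemo_classes]
  # strong planted toxicity for targeted compounds in this line, so the
  # planted anchor effect is unambiguously beyond the flagging threshold
  x_center <- log10(library$conc_min) +
    (library$n_conc - 1) / 2 * log10(library$dilution_factor)
  sel <- m$channel == "tox" & m$compound_id %in% targeted
  nt <- sum(sel)
  ctr <- x_center[match(m$compound_id[sel], library$compound_id)]
  m$top[sel] <- stats::runif(nt, 75, 100)
  m$log_ec50[sel] <- pmin(pmax(stats::rnorm(nt, ctr, 0.4),
                               ctr - 0.8), ctr + 0.5)
  m$slope[sel] <- stats::runif(nt, 1, 2.5)
  m$archetype[m$compound_id %in% targeted] <- "cytotoxic"
  selv <- m$channel == "viab" & m$compound_id %in% targeted
  m$top[selv] <- pmax(m$top[selv], m$top[sel])
  truth_alone$models <- m

  truth_anchor <- truth_alone
  ma <- truth_anchor$models
  ma$top[sel] <- ma$top[sel] * anchor_top_factor
  ma$log_ec50[sel] <- ma$log_ec50[sel] + anchor_ec50_shift
  truth_anchor$models <- ma

  alone <- simulate_screen(cell_line, library, truth_alone, noise,
                           readouts = "tox_fluor")
  with_anchor <- simulate_screen(cell_line, library, truth_anchor, noise,
                                 readouts = "tox_fluor")
  list(alone = alone, with_anchor = with_anchor,
       truth_alone = truth_alone, truth_anchor = truth_anchor,
       targeted = targeted)
}

#' Simulate a protein-marker table with planted group differences
#'
#' Markers x cell-lines matrix of standardized (phospho)protein levels:
#' baseline standard normal; `n_informative` markers get a mean shift of
#' `effect_size` standard deviations in the first group.
#'
#' @param cell_groups list of two disjoint character vectors of cell-line
#'   ids (each of size >= 2).
#' @param n_markers total markers (the emulated RPPA panel has 70).
#' @param n_informative markers with a planted shift.
#' @param effect_size standardized mean difference for informative markers.
#' @param seed integer seed.
#' @return list: `table` (matrix markers x lines), `informative` (marker
#'   ids), `groups`.
#' @export
simulate_marker_table <- function(cell_groups, n_markers = 70,
                                  n_informative = 9, effect_size = 3,
                                  seed = 1L) {
  stopifnot(length(cell_groups) == 2L)
  g1 <- cell_groups[[1]]
  g2 <- cell_groups[[2]]
  if (length(intersect(g1, g2)) > 0L) stop("cell groups must be disjoint")
  if (length(g1) < 2L || length(g2) < 2L) {
    stop("each group needs at least 2 cell lines")
  }
  if (n_informative > n_markers) {
    stop("n_informative cannot exceed n_markers")
  }
  set.seed(seed)
  lines <- c(g1, g2)
  tab <- matrix(stats::rnorm(n_markers * length(lines)), n_markers,
                dimnames = list(sprintf("marker_%03d", seq_len(n_markers)),
                                lines))
  informative <- rownames(tab)[seq_len(n_informative)]
  tab[informative, g1] <- tab[informative, g1] + effect_size
  list(table = tab, informative = informative,
       groups = list(sensitive = g1, insensitive = g2))
}
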