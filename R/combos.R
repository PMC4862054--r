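#' Combination-matrix synergy scoring
#'
#' An 8x8 dose matrix combines 7 nonzero concentrations of drug A (rows)
#' and drug B (columns) plus a zero dose of each, so row 1 / column 1 hold
#' the monotherapies and cell (1,1) is untreated. Two interaction models are
#' scored per readout: Bliss independence, where the expected combined effect
#' fraction is `fA + fB - fA*fB` and each inner cell's excess over it (x100,
#' percentage points) is the Bliss score; and the zero-interaction-potency
#' (ZIP) delta, which smooths both the combination response and the
#' monotherapy effects through logistic fits before taking the same excess,
#' making it robust to single noisy wells. In both models positive values
#' mean synergy and negative values antagonism.
#'
#' @name combos
NULL

#' Construct a combination matrix object
#'
#' @param response 8x8 numeric matrix of percent effect; rows indexed by
#'   drug A dose (first row = drug A absent), columns by drug B dose.
#' @param drugA_doses,drugB_doses length-8 concentration vectors (nM)
#'   starting at 0, strictly increasing.
#' @param readout readout label (e.g. `"viab_lum"`, `"tox_fluor"`).
#' @param drugA,drugB optional drug names.
#' @return a `combo_matrix` object.
#' @export
combo_matrix <- function(response, drugA_doses, drugB_doses,
                         readout = NA_character_,
                         drugA = "drugA", drugB = "drugB") {
  response <- as.matrix(response)
  if (!all(dim(response) == c(8L, 8L))) {
    stop("combination matrix must be 8x8 (zero dose + 7 doses per drug)")
  }
  for (d in list(drugA_doses, drugB_doses)) {
    if (length(d) != 8L || d[1] != 0 || any(diff(d) <= 0)) {
      stop("each dose vector must be length 8, start at 0, and increase")
    }
  }
  structure(list(response = unname(response), drugA_doses = drugA_doses,
                 drugB_doses = drugB_doses, readout = readout,
                 drugA = drugA, drugB = drugB),
            class = "combo_matrix")
}

#' Read combination matrices from a long-format table
#'
#' Expected columns: `drugA_conc`, `drugB_conc`, `readout`, `response`
#' (percent effect). One `combo_matrix` is built per readout.
#'
#' @param path TSV/CSV path.
#' @inheritParams combo_matrix
#' @return named list of `combo_matrix`, one per readout present.
#' @export
read_combination_table <- function(path, drugA = "drugA", drugB = "drugB") {
  if (!file.exists(path)) stop("combination table not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  required <- c("drugA_conc", "drugB_conc", "readout", "response")
  if (!all(required %in% names(df))) {
    stop("combination table needs columns: ", paste(required, collapse = ", "))
  }
  lapply(split(df, df$readout), function(g) {
    da <- sort(unique(g$drugA_conc))
    db <- sort(unique(g$drugB_conc))
    m <- matrix(NA_real_, length(da), length(db))
    m[cbind(match(g$drugA_conc, da), match(g$drugB_conc, db))] <- g$response
    combo_matrix(m, da, db, readout = g$readout[[1]],
                 drugA = drugA, drugB = drugB)
  })
}

#' Bliss-independent expected effect fraction
#'
#' @param fA,fB single-agent effect fractions in \[0, 1\].
#' @return `fA + fB - fA * fB` (vectorized).
#' @export
bliss_expected <- function(fA, fB) {
  if (any(fA < 0 | fA > 1 | fB < 0 | fB > 1)) {
    stop("effect fractions must be in [0, 1]; clip percents first")
  }
  fA + fB - fA * fB
}

clip01 <- function(p) pmin(pmax(p, 0), 100) / 100

#' Bliss score matrix of a dose combination
#'
#' For each inner cell (both doses nonzero) the score is
#' `100 * (f_obs - bliss_expected(f_A, f_B))` with observed fractions clipped
#' to \[0, 1\]; the summary is the unweighted mean over the 7x7 inner cells.
#'
#' @param m a [combo_matrix()].
#' @return list with `bliss` (7x7 signed matrix, percentage points) and
#'   `bliss_mean`.
#' @export
bliss_matrix <- function(m) {
  stopifnot(inherits(m, "combo_matrix"))
  r <- m$response
  if (anyNA(r[1, ]) || anyNA(r[, 1])) {
    stop("monotherapy row/column contains missing values")
  }
  fA <- clip01(r[, 1])   # drug A alone down the rows
  fB <- clip01(r[1, ])   # drug B alone across the columns
  expected <- outer(fA[-1], fB[-1], bliss_expected)
  obs <- clip01(r[-1, -1, drop = FALSE])
  score <- 100 * (obs - expected)
  dimnames(score) <- list(paste0("A", m$drugA_doses[-1]),
                          paste0("B", m$drugB_doses[-1]))
  list(bliss = score, bliss_mean = mean(score))
}

#' ZIP delta matrix of a dose combination
#'
#' The zero-interaction-potency model replaces raw wells with curve-fit
#' smoothed values before taking the Bliss-style excess: (1) monotherapy
#' logistic curves are fitted to row 1 / column 1; (2) along every row
#' (drug B dose fixed) a logistic in drug A dose is refitted with the bottom
#' asymptote pinned at the fitted monotherapy effect of B at that dose, and
#' symmetrically along every column; (3) the fitted combination effect of an
#' inner cell is the mean of its row-wise and column-wise fitted values;
#' (4) the delta is that effect minus 100 x the Bliss expectation of the two
#' fitted monotherapy effects; (5) the summary is the mean over inner cells.
#' A conditional fit that fails falls back to the observed values for that
#' slice and is recorded in `fallback_slices`.
#'
#' @param m a [combo_matrix()].
#' @return list with `zip_delta_matrix` (7x7), `zip_delta` (mean) and
#'   `fallback_slices` (character vector, empty when all fits succeeded).
#' @export
zip_delta <- function(m) {
  stopifnot(inherits(m, "combo_matrix"))
  r <- m$response
  if (anyNA(r)) stop("combination matrix contains missing values")
  xa <- log10(m$drugA_doses[-1])
  xb <- log10(m$drugB_doses[-1])

  fitA <- fit_logistic(xa, r[-1, 1], activity_threshold = 0.5)
  fitB <- fit_logistic(xb, r[1, -1], activity_threshold = 0.5)
  monoA <- pmin(pmax(predict_response(fitA, xa), 0), 100)
  monoB <- pmin(pmax(predict_response(fitB, xb), 0), 100)

  fallback <- character()
  # row-wise: effect along drug A at fixed drug B dose j, bottom = monoB[j]
  fit_slice <- function(x, y, bottom, label) {
    f <- fit_logistic_bottom(x, y, bottom)
    if (!f$ok) {
      fallback <<- c(fallback, label)
      return(pmin(pmax(y, 0), 100))
    }
    pmin(pmax(f$predict(x), 0), 100)
  }
  rowfit <- matrix(NA_real_, 7, 7)
  for (j in 1:7) {
    rowfit[, j] <- fit_slice(xa, r[-1, j + 1], monoB[j], paste0("B", j))
  }
  colfit <- matrix(NA_real_, 7, 7)
  for (i in 1:7) {
    colfit[i, ] <- fit_slice(xb, r[i + 1, -1], monoA[i], paste0("A", i))
  }
  fitted_combo <- (rowfit + colfit) / 2
  expected <- 100 * outer(monoA / 100, monoB / 100, bliss_expected)
  delta <- fitted_combo - expected
  dimnames(delta) <- list(paste0("A", m$drugA_doses[-1]),
                          paste0("B", m$drugB_doses[-1]))
  list(zip_delta_matrix = delta, zip_delta = mean(delta),
       fallback_slices = fallback)
}

#' Score a combination with both synergy models, per readout
#'
#' Scoring each readout independently is the point of the dual-readout
#' design: a combination can be merely additive on viability while strongly
#' antagonistic (or synergistic) on cytotoxicity, and only the per-readout
#' scores expose that.
#'
#' @param matrices a single [combo_matrix()] or a (possibly named) list of
#'   them, one per readout.
#' @param model `"bliss"`, `"zip"` or `"both"`.
#' @return a `synergy_result` list keyed by readout; each element holds the
#'   requested score matrices and their means.
#' @export
score_combination <- function(matrices, model = c("both", "bliss", "zip")) {
  model <- match.arg(model)
  if (inherits(matrices, "combo_matrix")) matrices <- list(matrices)
  if (length(matrices) == 0L) stop("at least one readout matrix required")
  out <- lapply(matrices, function(m) {
    res <- list(readout = m$readout)
    if (model %in% c("both", "bliss")) {
      res <- c(res, bliss_matrix(m))
    }
    if (model %in% c("both", "zip")) {
      res <- c(res, zip_delta(m))
    }
    res
  })
  names(out) <- vapply(matrices, function(m) {
    if (is.na(m$readout)) "unknown" else m$readout
  }, character(1))
  structure(out, class = "synergy_result")
}

#' @export
print.synergy_result <- function(x, ...) {
  for (nm in names(x)) {
    r <- x[[nm]]
    cat(sprintf("%s:", nm))
    if (!is.null(r$bliss_mean)) cat(sprintf("  Bliss mean = %+.2f", r$bliss_mean))
    if (!is.null(r$zip_delta)) cat(sprintf("  ZIP delta = %+.2f", r$zip_delta))
    cat("\n")
  }
  invisible(x)
}

#' Write synergy scores to JSON
#'
#' @param result a `synergy_result` from [score_combination()].
#' @param path output path.
#' @export
write_synergy_json <- function(result, path) {
  ser <- lapply(result, function(r) {
    if (!is.null(r$bliss)) r$bliss <- unname(r$bliss)
    if (!is.null(r$zip_delta_matrix)) {
      r$zip_delta_matrix <- unname(r$zip_delta_matrix)
    }
    r
  })
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
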