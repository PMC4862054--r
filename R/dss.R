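#' Drug sensitivity scoring
#'
#' The drug sensitivity score (DSS) is a normalized area under the fitted
#' dose-response curve above an activity threshold `t`, integrated in log10
#' concentration over the tested range only. With the logistic fit
#' `y(x) = d / (1 + 10^(s(c-x)))` the area has the closed form
#' \deqn{I = \frac{d}{s \ln 10}\Big[\ln\big(1 + 10^{s(x-c)}\big)\Big]_{x_1'}^{x_2}}
#' where `x1'` is the dose at which the curve crosses the threshold
#' (`max(x1, c - log10(d/t - 1)/s)`), and
#' \deqn{DSS_1 = 100\,\frac{I - t\,(x_2 - x_1')}{(100 - t)(x_2 - x_1)}.}
#' The score lives in \[0, 100\], is 0 exactly when the top asymptote does
#' not exceed the threshold, and grows with both efficacy (d) and potency
#' (small EC50), which is why it is preferred over IC50 alone for ranking
#' heterogeneous screens.
#'
#' @name scoring
NULL

#' DSS configuration
#'
#' @param x1,x2 log10 nM bounds of the tested concentration range.
#' @param t activity threshold in percent (default 10).
#' @param variant `"DSS1"` (fully supported). `"DSS2"`/`"DSS3"` are accepted
#'   for forward compatibility but currently error on use: their exact
#'   normalization terms come from a different publication chain and the
#'   pipeline is defined and validated with DSS1.
#' @return a `dss_config` list.
#' @export
dss_config <- function(x1, x2, t = 10, variant = "DSS1") {
  if (!is.finite(x1) || !is.finite(x2) || x2 <= x1) {
    stop("invalid DSS range: need x2 > x1")
  }
  if (t <= 0 || t >= 100) stop("activity threshold t must be in (0, 100)")
  variant <- match.arg(variant, c("DSS1", "DSS2", "DSS3"))
  structure(list(x1 = x1, x2 = x2, t = t, variant = variant),
            class = "dss_config")
}

#' Drug sensitivity score (DSS1) in closed form
#'
#' @param fit a `dsrt_fit` from [fit_logistic()], or a list with elements
#'   `top`, `log_ec50`, `slope`.
#' @param cfg a [dss_config()].
#' @return the DSS, clipped to \[0, 100\].
#' @examples
#' cfg <- dss_config(x1 = 0, x2 = 4, t = 10)
#' f <- list(top = 100, log_ec50 = 2, slope = 1)
#' dss1(f, cfg)  # ~46.2
#' @export
dss1 <- function(fit, cfg) {
  stopifnot(inherits(cfg, "dss_config"))
  if (cfg$variant != "DSS1") {
    stop(cfg$variant, " normalization is not implemented; use DSS1")
  }
  d <- min(max(fit$top, 0), 100)
  s <- fit$slope
  cc <- fit$log_ec50
  t <- cfg$t
  x1 <- cfg$x1
  x2 <- cfg$x2
  if (!is.finite(d) || d <= t) {
    return(0)
  }
  # dose where the fitted curve crosses the threshold
  xt <- cc - log10(d / t - 1) / s
  x1p <- max(x1, xt)
  if (x1p >= x2) {
    return(0)
  }
  ln10 <- log(10)
  antider <- function(x) log1p(10^(s * (x - cc)))
  I <- d / (s * ln10) * (antider(x2) - antider(x1p))
  score <- 100 * (I - t * (x2 - x1p)) / ((100 - t) * (x2 - x1))
  min(max(score, 0), 100)
}

#' Closed-form vs numerical-integration discrepancy
#'
#' Oracle check: recomputes the DSS area by adaptive numerical integration of
#' the fitted curve above the activity threshold and reports the absolute
#' discrepancy against the closed-form score. Used by the test suite to
#' certify the closed form; exposed so users can audit any particular fit.
#'
#' @inheritParams dss1
#' @return list with `closed`, `numeric` (both on the DSS scale) and
#'   `discrepancy` (absolute difference).
#' @export
closed_form_vs_numeric <- function(fit, cfg) {
  stopifnot(inherits(cfg, "dss_config"))
  closed <- dss1(fit, cfg)
  d <- min(max(fit$top, 0), 100)
  t <- cfg$t
  if (d <= t) {
    return(list(closed = closed, numeric = 0, discrepancy = abs(closed)))
  }
  xt <- fit$log_ec50 - log10(d / t - 1) / fit$slope
  x1p <- max(cfg$x1, xt)
  if (x1p >= cfg$x2) {
    return(list(closed = closed, numeric = 0, discrepancy = abs(closed)))
  }
  f <- function(x) {
    pmin(d, d / (1 + 10^(fit$slope * (fit$log_ec50 - x)))) - t
  }
  I <- stats::integrate(f, x1p, cfg$x2, rel.tol = 1e-10,
                        abs.tol = 1e-10)$value
  num <- min(max(100 * I / ((100 - t) * (cfg$x2 - cfg$x1)), 0), 100)
  list(closed = closed, numeric = num, discrepancy = abs(closed - num))
}

#' Score a normalized screen
#'
#' Fits one dose-response curve per cell line x compound x readout from
#' normalized percent responses and computes DSS1 for each. The DSS range
#' defaults to each compound's own tested range (per-compound `x1`/`x2`),
#' which is how multi-range compound libraries are scored in practice.
#'
#' @param normalized a `dsrt_normalized` from [normalize_screen()], or its
#'   `values` data.frame.
#' @param t activity threshold in percent (default 10).
#' @return a `data.frame` (one row per cell line x compound x readout) with
#'   `dss`, `ec50` (nM), `top`, `slope`, `degenerate`.
#' @export
score_screen <- function(normalized, t = 10) {
  df <- if (inherits(normalized, "dsrt_normalized")) {
    normalized$values
  } else {
    normalized
  }
  if (is.null(df) || nrow(df) == 0L) stop("no normalized sample wells to score")
  key <- interaction(df$cell_line, df$compound_id, df$readout, drop = TRUE)
  groups <- split(seq_len(nrow(df)), key)
  out <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    g <- df[groups[[gi]], , drop = FALSE]
    x <- log10(g$conc)
    fit <- fit_logistic(x, g$value, readout = g$readout[[1]],
                        activity_threshold = t)
    cfg <- dss_config(x1 = min(x), x2 = max(x), t = t)
    out[[gi]] <- data.frame(
      cell_line = g$cell_line[[1]], compound_id = g$compound_id[[1]],
      readout = g$readout[[1]], dss = dss1(fit, cfg), ec50 = fit$ec50,
      top = fit$top, slope = fit$slope, degenerate = fit$degenerate,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Reference-panel means for selective DSS
#'
#' Builds a control panel (mean DSS per compound x readout over a set of
#' reference cell lines) from a scored screen. The original workflow used
#' in-house panels of 150 lines for viability readouts and 30 lines for
#' toxicity readouts; any scored table serves here.
#'
#' @param dss_records output of [score_screen()] for the reference lines.
#' @return `control_panel`: data.frame `compound_id`, `readout`,
#'   `panel_mean`, `n_lines`.
#' @export
build_control_panel <- function(dss_records) {
  key <- interaction(dss_records$compound_id, dss_records$readout, drop = TRUE)
  agg <- do.call(rbind, lapply(split(dss_records, key), function(g) {
    data.frame(compound_id = g$compound_id[[1]], readout = g$readout[[1]],
               panel_mean = mean(g$dss), n_lines = nrow(g),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  structure(agg, class = c("control_panel", "data.frame"))
}

#' Selective DSS against a reference panel
#'
#' `sDSS = DSS - panel mean` for the same compound and readout: positive
#' values mean the line is selectively more sensitive than the reference
#' panel; broadly toxic compounds score near zero everywhere.
#'
#' @param dss_records output of [score_screen()].
#' @param panel a [build_control_panel()] result.
#' @return `dss_records` with an `sdss` column; compounds absent from the
#'   panel get `NA` sdss with a warning (they are excluded from clustering).
#' @export
sdss <- function(dss_records, panel) {
  m <- merge(dss_records, as.data.frame(panel),
             by = c("compound_id", "readout"), all.x = TRUE, sort = FALSE)
  m$sdss <- m$dss - m$panel_mean
  if (anyNA(m$sdss)) {
    miss <- unique(m$compound_id[is.na(m$sdss)])
    warning("no panel entry for compound(s): ",
            paste(utils::head(miss, 10), collapse = ", "),
            "; sdss set to NA")
  }
  m$panel_mean <- NULL
  m$n_lines <- NULL
  m
}

#' Classify a response as cytotoxic, cytostatic or inactive
#'
#' The joint readout of the screen: a compound that kills the cells scores on
#' the cytotoxicity channel; one that only halts growth/metabolism scores on
#' viability channels but not on toxicity. Classification is on DSS units:
#' cytotoxic if `dss_tox >= t_tox`; else cytostatic if `dss_viab >= t_viab`;
#' else inactive. Default thresholds `t_viab = 10`, `t_tox = 5`.
#'
#' @param dss_viab,dss_tox DSS on a viability / the toxicity readout
#'   (vectorized).
#' @param t_viab,t_tox classification thresholds in DSS units.
#' @return character vector: `"cytotoxic"`, `"cytostatic"` or `"inactive"`.
#' @export
classify_response <- function(dss_viab, dss_tox, t_viab = 10, t_tox = 5) {
  ifelse(dss_tox >= t_tox, "cytotoxic",
         ifelse(dss_viab >= t_viab, "cytostatic", "inactive"))
}

#' Classify a scored dual-readout screen
#'
#' Joins a viability readout and the toxicity readout of [score_screen()]
#' output per cell line x compound and applies [classify_response()].
#'
#' @param dss_records output of [score_screen()] containing one viability
#'   readout and `tox_fluor`.
#' @param viab_readout which viability channel to use (default `viab_lum`,
#'   the ATP-based channel).
#' @inheritParams classify_response
#' @return data.frame `cell_line`, `compound_id`, `dss_viab`, `dss_tox`,
#'   `class_label`.
#' @export
classify_screen <- function(dss_records, viab_readout = "viab_lum",
                            t_viab = 10, t_tox = 5) {
  v <- dss_records[dss_records$readout == viab_readout,
                   c("cell_line", "compound_id", "dss")]
  names(v)[3] <- "dss_viab"
  tx <- dss_records[dss_records$readout == "tox_fluor",
                    c("cell_line", "compound_id", "dss")]
  names(tx)[3] <- "dss_tox"
  m <- merge(v, tx, by = c("cell_line", "compound_id"), sort = FALSE)
  if (nrow(m) == 0L) {
    stop("no cell line x compound pairs with both ", viab_readout,
         " and tox_fluor scores")
  }
  m$class_label <- classify_response(m$dss_viab, m$dss_tox, t_viab, t_tox)
  m
}

#' Anchored-combination delta DSS
#'
#' In an anchored screen a fixed dose of one drug (the anchor) is combined
#' with the whole compound library; each library compound is then scored as
#' usual and compared with its single-agent score. `delta = dss_with_anchor -
#' dss_alone`; combinations with `delta > flag_threshold` are flagged as
#' potentiation, `delta < -flag_threshold` as antagonism (default threshold
#' 10 DSS units).
#'
#' @param dss_with_anchor,dss_alone DSS vectors for the same compounds under
#'   identical scoring configuration.
#' @param flag_threshold absolute delta above which a combination is flagged.
#' @return data.frame with `delta` and `flag` in
#'   `{"potentiation", "antagonism", "none"}`.
#' @export
anchored_delta_dss <- function(dss_with_anchor, dss_alone,
                               flag_threshold = 10) {
  delta <- dss_with_anchor - dss_alone
  flag <- ifelse(delta > flag_threshold, "potentiation",
                 ifelse(delta < -flag_threshold, "antagonism", "none"))
  data.frame(delta = delta, flag = flag, stringsAsFactors = FALSE)
}
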