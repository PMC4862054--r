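#' Dose-response curve fitting
#'
#' Fits the three-parameter logistic model used throughout the pipeline,
#' \deqn{y(x) = \frac{d}{1 + 10^{\,s (c - x)}},}
#' where `x` is log10 concentration (log10 nM), `d` is the top asymptote
#' (maximum percent effect, bounded to \[0, 100\]), `c` is the log10 EC50 and
#' `s > 0` the Hill slope. The bottom asymptote is fixed at 0: responses are
#' control-anchored percent inhibition / percent toxicity, where 0 means "no
#' effect". Mildly negative or overshooting observations are treated as
#' measurement noise and clipped to \[-20, 120\] before fitting.
#'
#' Optimization is deterministic: bounded least squares (L-BFGS-B with
#' analytic gradient) started from a fixed grid of initial values
#' (`c` at every tested dose, `s` in {0.5, 1, 2}); the start with the best
#' final residual sum of squares wins. Ties on RSS are broken by smallest
#' slope, then smallest `c`, so refitting identical data always returns the
#' identical fit.
#'
#' Degenerate inputs short-circuit: if the largest observed response does not
#' exceed the activity threshold (10 percent) the compound is called inactive
#' and a flat-zero fit is returned without optimization, avoiding spurious
#' EC50 estimates for inactives; if every response is near-saturated
#' (min y >= 90) a flat-max fit is returned; fewer than 3 distinct doses give
#' a flat fit at the mean response.
#'
#' @param x numeric vector of log10 concentrations (log10 nM).
#' @param y numeric vector of percent responses, same length as `x`.
#' @param readout optional readout label carried through to the result.
#' @param activity_threshold percent response below which a profile is
#'   considered flat/inactive (default 10, the DSS activity threshold).
#' @return An object of class `dsrt_fit`: a list with elements `top`,
#'   `log_ec50`, `slope`, `bottom` (always 0), `ec50` (nM, `10^log_ec50`),
#'   `rss`, `converged`, `n_points`, `degenerate` (one of `"none"`,
#'   `"flat_zero"`, `"flat_max"`, `"non_converged"`), `readout`, and the
#'   aggregated data used (`x`, `y`).
#' @examples
#' x <- 0:4
#' y <- 80 / (1 + 10^(1 * (2 - x)))
#' f <- fit_logistic(x, y)
#' c(f$top, f$log_ec50, f$slope)
#' @seealso [predict_response()], [dss1()]
#' @export
fit_logistic <- function(x, y, readout = NA_character_,
                         activity_threshold = 10) {
  if (length(x) != length(y)) {
    stop("`x` and `y` must have the same length")
  }
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  if (length(y) == 0L) {
    stop("no finite dose-response points to fit")
  }
  # replicate aggregation: mean response at identical doses, x increasing
  if (anyDuplicated(x)) {
    agg <- tapply(y, x, mean)
    x <- as.numeric(names(agg))
    y <- as.numeric(agg)
  }
  ord <- order(x)
  x <- x[ord]
  y <- y[ord]
  y <- pmin(pmax(y, -20), 120)
  n <- length(x)

  flat_fit <- function(top, degenerate) {
    structure(list(
      top = top, log_ec50 = min(x) - 1, slope = 1, bottom = 0,
      ec50 = 10^(min(x) - 1), rss = sum((y - top)^2), converged = TRUE,
      n_points = n, degenerate = degenerate, readout = readout,
      x = x, y = y
    ), class = "dsrt_fit")
  }

  if (max(y) <= activity_threshold) {
    return(flat_fit(0, "flat_zero"))
  }
  if (n < 3L) {
    m <- min(max(mean(y), 0), 100)
    return(flat_fit(m, if (m <= activity_threshold) "flat_zero" else "flat_max"))
  }
  if (min(y) >= 90) {
    return(flat_fit(min(max(mean(y), 0), 100), "flat_max"))
  }

  lower <- c(d = 0, c = min(x) - 1, s = 0.1)
  upper <- c(d = 100, c = max(x) + 1, s = 10)

  obj <- function(p) {
    r <- y - p[1] / (1 + 10^(p[3] * (p[2] - x)))
    sum(r * r)
  }
  grad <- function(p) {
    u <- 10^(p[3] * (p[2] - x))
    pr <- 1 / (1 + u)
    yhat <- p[1] * pr
    r <- y - yhat
    ln10 <- log(10)
    dd <- pr
    dc <- -p[1] * ln10 * p[3] * u * pr * pr
    ds <- -p[1] * ln10 * (p[2] - x) * u * pr * pr
    -2 * c(sum(r * dd), sum(r * dc), sum(r * ds))
  }

  d0 <- min(max(max(y), 1), 100)
  best <- NULL
  for (c0 in x) {
    for (s0 in c(0.5, 1, 2)) {
      p0 <- c(d0, c0, s0)
      fit <- tryCatch(
        stats::optim(p0, obj, grad, method = "L-BFGS-B",
                     lower = lower, upper = upper,
                     control = list(maxit = 200, factr = 1e4)),
        error = function(e) NULL
      )
      if (is.null(fit)) next
      cand <- list(par = fit$par, rss = fit$value,
                   converged = fit$convergence == 0L)
      if (is.null(best) ||
          cand$rss < best$rss - 1e-12 ||
          (abs(cand$rss - best$rss) <= 1e-12 &&
           (cand$par[3] < best$par[3] - 1e-12 ||
            (abs(cand$par[3] - best$par[3]) <= 1e-12 &&
             cand$par[2] < best$par[2])))) {
        best <- cand
      }
    }
  }
  if (is.null(best)) {
    out <- flat_fit(min(max(mean(y), 0), 100), "non_converged")
    out$converged <- FALSE
    return(out)
  }
  structure(list(
    top = best$par[[1]], log_ec50 = best$par[[2]], slope = best$par[[3]],
    bottom = 0, ec50 = 10^best$par[[2]], rss = best$rss,
    converged = best$converged, n_points = n, degenerate = "none",
    readout = readout, x = x, y = y
  ), class = "dsrt_fit")
}

#' Predict percent response from a fitted curve
#'
#' Evaluates `top / (1 + 10^(slope * (log_ec50 - x)))` at log10
#' concentrations `x`. Degenerate flat fits return their constant top.
#'
#' @param fit a `dsrt_fit` from [fit_logistic()].
#' @param x numeric vector of log10 concentrations.
#' @return numeric vector of percent responses in `[0, top]`.
#' @export
predict_response <- function(fit, x) {
  stopifnot(inherits(fit, "dsrt_fit"))
  if (identical(fit$degenerate, "non_converged")) {
    stop("cannot predict from a non-converged fit")
  }
  if (fit$degenerate %in% c("flat_zero", "flat_max")) {
    return(rep(fit$top, length(x)))
  }
  fit$top / (1 + 10^(fit$slope * (fit$log_ec50 - x)))
}

#' @export
print.dsrt_fit <- function(x, ...) {
  cat(sprintf(
    "Logistic dose-response fit (%d points%s)\n  top = %.3f%%  log10 EC50 = %.4f (EC50 = %.4g nM)  slope = %.3f\n  RSS = %.4g  degenerate = %s\n",
    x$n_points,
    if (is.na(x$readout)) "" else paste0(", ", x$readout),
    x$top, x$log_ec50, x$ec50, x$slope, x$rss, x$degenerate
  ))
  invisible(x)
}

# Internal: logistic fit with a fixed nonzero bottom asymptote, used by the
# ZIP model's conditional row/column fits. y(x) = b + (d - b)/(1 + 10^(s(c-x)))
# with b fixed, d in [b, 100]. Same deterministic multi-start scheme, with a
# reduced start grid (quartile c starts) because these fits run in bulk.
fit_logistic_bottom <- function(x, y, bottom) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  ord <- order(x)
  x <- x[ord]
  y <- pmin(pmax(y[ord], -20), 120)
  n <- length(x)
  bottom <- min(max(bottom, 0), 100)
  if (n < 3L) {
    return(list(ok = FALSE))
  }
  lower <- c(d = bottom, c = min(x) - 1, s = 0.1)
  upper <- c(d = 100, c = max(x) + 1, s = 10)
  obj <- function(p) {
    r <- y - (bottom + (p[1] - bottom) / (1 + 10^(p[3] * (p[2] - x))))
    sum(r * r)
  }
  grad <- function(p) {
    u <- 10^(p[3] * (p[2] - x))
    pr <- 1 / (1 + u)
    r <- y - (bottom + (p[1] - bottom) * pr)
    ln10 <- log(10)
    dd <- pr
    dc <- -(p[1] - bottom) * ln10 * p[3] * u * pr * pr
    ds <- -(p[1] - bottom) * ln10 * (p[2] - x) * u * pr * pr
    -2 * c(sum(r * dd), sum(r * dc), sum(r * ds))
  }
  d0 <- min(max(max(y), bottom + 1), 100)
  starts_c <- unname(stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE))
  best <- NULL
  for (c0 in starts_c) {
    for (s0 in c(0.5, 1, 2)) {
      fit <- tryCatch(
        stats::optim(c(d0, c0, s0), obj, grad, method = "L-BFGS-B",
                     lower = lower, upper = upper,
                     control = list(maxit = 200, factr = 1e4)),
        error = function(e) NULL
      )
      if (is.null(fit)) next
      if (is.null(best) || fit$value < best$value) best <- fit
    }
  }
  if (is.null(best)) {
    return(list(ok = FALSE))
  }
  list(ok = TRUE, bottom = bottom, top = best$par[[1]],
       log_ec50 = best$par[[2]], slope = best$par[[3]], rss = best$value,
       predict = function(xx) {
         bottom + (best$par[[1]] - bottom) /
           (1 + 10^(best$par[[3]] * (best$par[[2]] - xx)))
       })
}
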