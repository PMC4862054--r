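#' Plate normalization and quality control
#'
#' Raw plate-reader signals are normalized per plate and per readout against
#' the plate's own controls: negative controls (0.1% DMSO, untreated effect)
#' define 0% and positive controls (100 uM benzethonium chloride, fully dead)
#' define 100%. Viability channels lose signal as cells die, so percent
#' inhibition runs opposite to signal; the cytotoxicity channel gains signal
#' with cell death, so percent toxicity runs with it. Both normalizations
#' are affine in the raw signal and are therefore invariant to any per-plate
#' gain/offset of the instrument.
#'
#' @name plates
NULL

.readout_levels <- c("viab_fluor", "viab_lum", "tox_fluor")
.role_levels <- c("sample", "neg", "pos")

#' Read a long-format screen table
#'
#' Parses the tab- or comma-separated screen table emitted by
#' [simulate_screen()] (and by plate-reader export scripts following the same
#' schema). Required columns: `plate_id`, `well`, `role`
#' (sample/neg/pos), `cell_line`, `compound_id`, `conc` (nM), `readout`
#' (`viab_fluor`, `viab_lum`, `tox_fluor`), `signal`. Control wells must have
#' empty compound and concentration; sample wells must have both.
#'
#' @param path path to a TSV/CSV file (delimiter sniffed from the header).
#' @return a `data.frame` of validated well records.
#' @export
read_screen_table <- function(path) {
  if (!file.exists(path)) stop("screen table not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""),
                          quote = "\"", comment.char = "")
  required <- c("plate_id", "well", "role", "cell_line", "compound_id",
                "conc", "readout", "signal")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("screen table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  df$conc <- as.numeric(df$conc)
  df$signal <- as.numeric(df$signal)
  validate_wells(df)
  df
}

# Validates well records; errors cite 1-based data row numbers.
validate_wells <- function(df) {
  bad_role <- setdiff(unique(df$role), .role_levels)
  if (length(bad_role) > 0L) {
    stop("unknown well role(s): ", paste(bad_role, collapse = ", "))
  }
  bad_readout <- setdiff(unique(df$readout), .readout_levels)
  if (length(bad_readout) > 0L) {
    stop("unknown readout(s): ", paste(bad_readout, collapse = ", "))
  }
  is_sample <- df$role == "sample"
  bad <- which(is_sample & (is.na(df$compound_id) | df$compound_id == "" |
                              is.na(df$conc)))
  if (length(bad) > 0L) {
    stop("sample wells without compound/concentration at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  bad <- which(!is_sample & !(is.na(df$compound_id) | df$compound_id == ""))
  if (length(bad) > 0L) {
    stop("control wells with a compound assigned at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  if (any(!is.na(df$signal) & df$signal < 0)) {
    stop("negative raw signals present")
  }
  invisible(df)
}

#' Percent inhibition of a viability signal
#'
#' `100 * (mu_neg - signal) / (mu_neg - mu_pos)`: 0 at the negative-control
#' mean, 100 at the positive-control mean. Not clipped; clipping policy
#' belongs to downstream scoring.
#'
#' @param signal raw viability signal(s).
#' @param mu_neg,mu_pos negative / positive control mean signals.
#' @return percent inhibition, same length as `signal`.
#' @export
percent_inhibition <- function(signal, mu_neg, mu_pos) {
  if (isTRUE(all.equal(mu_neg, mu_pos))) {
    stop("degenerate controls: negative and positive control means are equal")
  }
  100 * (mu_neg - signal) / (mu_neg - mu_pos)
}

#' Percent toxicity of a cytotoxicity signal
#'
#' `100 * (signal - mu_neg) / (mu_pos - mu_neg)`; on the toxicity channel the
#' positive (fully dead) control has the **highest** signal.
#'
#' @inheritParams percent_inhibition
#' @return percent toxicity, same length as `signal`.
#' @export
percent_toxicity <- function(signal, mu_neg, mu_pos) {
  if (isTRUE(all.equal(mu_neg, mu_pos))) {
    stop("degenerate controls: negative and positive control means are equal")
  }
  100 * (signal - mu_neg) / (mu_pos - mu_neg)
}

#' Z'-factor of a plate's controls
#'
#' `1 - 3 * (sd_pos + sd_neg) / |mu_pos - mu_neg|` with sample standard
#' deviations. 1 is a perfect assay window; values below 0.5 indicate a
#' marginal plate. Identical control means yield `-Inf`.
#'
#' @param neg_values,pos_values raw control signals (>= 2 each).
#' @return the Z'-factor (<= 1).
#' @export
z_prime <- function(neg_values, pos_values) {
  if (length(neg_values) < 2L || length(pos_values) < 2L) {
    stop("need at least 2 wells per control group for Z'")
  }
  sep <- abs(mean(pos_values) - mean(neg_values))
  if (sep == 0) {
    return(-Inf)
  }
  1 - 3 * (stats::sd(pos_values) + stats::sd(neg_values)) / sep
}

qc_flag <- function(z) {
  ifelse(z >= 0.5, "pass", ifelse(z >= 0, "warn", "fail"))
}

#' Normalize a screen to percent inhibition / percent toxicity
#'
#' Per plate and per readout, control means anchor the normalization
#' ([percent_inhibition()] for viability channels, [percent_toxicity()] for
#' the toxicity channel) and the Z'-factor is computed from the raw control
#' signals. QC flags: pass (Z' >= 0.5), warn (0 <= Z' < 0.5), fail (Z' < 0) —
#' the standard screening convention. Plates lacking either control group for
#' a readout are excluded from the normalized output and reported.
#'
#' @param wells a well `data.frame` as returned by [read_screen_table()] or
#'   [simulate_screen()].
#' @param control_stat `"mean"` (default, matching the Z'-factor definition)
#'   or `"median"` for a robust variant of the normalization anchors.
#' @return a list of class `dsrt_normalized`:
#'   `values` (sample wells with a `value` percent column), `qc` (per
#'   plate x readout: `z_prime`, `n_neg`, `n_pos`, `flag`), and `excluded`
#'   (data.frame of plate x readout groups dropped for missing controls).
#' @export
normalize_screen <- function(wells, control_stat = c("mean", "median")) {
  control_stat <- match.arg(control_stat)
  validate_wells(wells)
  anchor <- switch(control_stat, mean = mean, median = stats::median)
  key <- interaction(wells$plate_id, wells$readout, drop = TRUE)
  groups <- split(seq_len(nrow(wells)), key)

  values <- vector("list", length(groups))
  qc <- vector("list", length(groups))
  excluded <- list()
  for (gi in seq_along(groups)) {
    idx <- groups[[gi]]
    g <- wells[idx, , drop = FALSE]
    neg <- g$signal[g$role == "neg"]
    pos <- g$signal[g$role == "pos"]
    pid <- g$plate_id[[1]]
    rd <- g$readout[[1]]
    if (length(neg) < 2L || length(pos) < 2L) {
      excluded[[length(excluded) + 1L]] <- data.frame(
        plate_id = pid, readout = rd,
        reason = sprintf("missing controls (neg=%d, pos=%d)",
                         length(neg), length(pos)),
        stringsAsFactors = FALSE)
      next
    }
    mu_neg <- anchor(neg)
    mu_pos <- anchor(pos)
    zp <- z_prime(neg, pos)
    qc[[gi]] <- data.frame(
      plate_id = pid, readout = rd, z_prime = zp,
      n_neg = length(neg), n_pos = length(pos), flag = qc_flag(zp),
      stringsAsFactors = FALSE)
    s <- g[g$role == "sample", , drop = FALSE]
    if (nrow(s) == 0L) next
    s$value <- if (rd == "tox_fluor") {
      percent_toxicity(s$signal, mu_neg, mu_pos)
    } else {
      percent_inhibition(s$signal, mu_neg, mu_pos)
    }
    values[[gi]] <- s
  }
  excluded <- if (length(excluded) > 0L) {
    do.call(rbind, excluded)
  } else {
    data.frame(plate_id = character(), readout = character(),
               reason = character(), stringsAsFactors = FALSE)
  }
  if (nrow(excluded) > 0L) {
    warning("excluded ", nrow(excluded),
            " plate x readout group(s) with missing controls")
  }
  structure(list(
    values = do.call(rbind, values[!vapply(values, is.null, logical(1))]),
    qc = do.call(rbind, qc[!vapply(qc, is.null, logical(1))]),
    excluded = excluded
  ), class = "dsrt_normalized")
}

#' @export
print.dsrt_normalized <- function(x, ...) {
  cat(sprintf(
    "Normalized screen: %d sample wells, %d plate x readout groups (%d pass / %d warn / %d fail), %d excluded\n",
    if (is.null(x$values)) 0L else nrow(x$values),
    nrow(x$qc),
    sum(x$qc$flag == "pass"), sum(x$qc$flag == "warn"),
    sum(x$qc$flag == "fail"), nrow(x$excluded)))
  invisible(x)
}
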