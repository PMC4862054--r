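#' File export helpers
#'
#' Plain-text interchange for the simulator outputs and scored results:
#' long-format screen TSVs (the schema read back by [read_screen_table()]),
#' long-format combination TSVs (read by [read_combination_table()]),
#' marker TSVs, DSS matrix TSVs and truth JSON.
#'
#' @name io
NULL

#' Write a screen-table TSV
#' @param wells well data.frame in the screen schema.
#' @param path output path.
#' @export
write_screen_table <- function(wells, path) {
  utils::write.table(wells, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Write combination matrices as a long-format TSV
#' @param matrices named list of [combo_matrix()] per readout (e.g. the
#'   `matrices` element of [simulate_combination_matrix()]).
#' @param path output path.
#' @export
write_combination_table <- function(matrices, path) {
  rows <- lapply(matrices, function(m) {
    data.frame(
      drugA_conc = rep(m$drugA_doses, times = 8),
      drugB_conc = rep(m$drugB_doses, each = 8),
      readout = m$readout,
      response = as.vector(m$response),
      stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a marker table TSV (markers x cell lines)
#' @param table numeric matrix with marker rownames and cell-line colnames.
#' @param path output path.
#' @export
write_marker_table <- function(table, path) {
  df <- data.frame(marker = rownames(table), table, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a marker table TSV
#' @param path path written by [write_marker_table()].
#' @return numeric matrix, markers x cell lines.
#' @export
read_marker_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write planted truth as JSON
#' @param truth a [make_truth()] object.
#' @param path output path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(list(
    models = truth$models,
    sensitive_lines = truth$sensitive_lines,
    library = as.data.frame(truth$library)
  ), path, digits = NA)
  invisible(path)
}

#' Write a DSS (or sDSS) matrix TSV per readout
#'
#' One file per readout, rows = compounds, columns = cell lines.
#'
#' @param dss_records output of [score_screen()] (or [sdss()]; set
#'   `value_col = "sdss"`).
#' @param basename output prefix; files are `<basename>_<readout>.tsv`.
#' @param value_col which column to pivot (default `"dss"`).
#' @return invisibly, the paths written.
#' @export
write_dss_matrix <- function(dss_records, basename, value_col = "dss") {
  paths <- character()
  for (rd in unique(dss_records$readout)) {
    sub <- dss_records[dss_records$readout == rd, ]
    m <- tapply(sub[[value_col]], list(sub$compound_id, sub$cell_line),
                mean)
    path <- sprintf("%s_%s.tsv", basename, rd)
    df <- data.frame(compound_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Pivot scored records to a response matrix for clustering
#'
#' @param dss_records output of [score_screen()] or [sdss()].
#' @param readout readout to pivot.
#' @param value_col `"sdss"` (default, the clustering input of choice) or
#'   `"dss"`.
#' @return numeric matrix, compounds x cell lines.
#' @export
response_matrix <- function(dss_records, readout = "tox_fluor",
                            value_col = "sdss") {
  sub <- dss_records[dss_records$readout == readout, ]
  if (nrow(sub) == 0L) stop("no records for readout ", readout)
  keep <- is.finite(sub[[value_col]])
  sub <- sub[keep, ]
  tapply(sub[[value_col]], list(sub$compound_id, sub$cell_line), mean)
}
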