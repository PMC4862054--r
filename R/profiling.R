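#' Response-profile clustering and biomarker association
#'
#' Drug-response matrices (rows = compounds, columns = cell lines, values =
#' sDSS or DSS) are clustered with complete linkage: drug profiles with the
#' Spearman rank-correlation distance `1 - rho` (invariant to any monotone
#' rescaling of a profile), cell-line profiles with Euclidean distance —
#' the combination used by the classic Cluster 3.0 / Java TreeView
#' workflow, whose CDT/GTR/ATR files this module reads and writes.
#' Responder-group biomarker testing compares protein-marker levels between
#' sensitive and insensitive cell-line groups with a two-sample t-test
#' (Welch by default).
#'
#' @name profiling
NULL

#' Spearman-distance matrix between rows
#'
#' `1 - rho` with average-rank ties, pairwise-complete observations.
#' Rows with zero rank variance have no defined correlation; their distance
#' is set to the maximum (2, the perfectly anti-correlated distance) and a
#' warning names them.
#'
#' @param m numeric matrix.
#' @return a `dist` object over rows of `m`.
#' @export
spearman_dist <- function(m) {
  zero_var <- apply(m, 1, function(r) {
    r <- r[is.finite(r)]
    length(unique(r)) < 2L
  })
  if (any(zero_var)) {
    warning("zero-variance profile(s) get maximal Spearman distance: ",
            paste(utils::head(rownames(m)[zero_var], 5), collapse = ", "))
  }
  rho <- suppressWarnings(
    stats::cor(t(m), method = "spearman", use = "pairwise.complete.obs"))
  d <- 1 - rho
  d[is.na(d)] <- 2
  diag(d) <- 0
  stats::as.dist(d)
}

#' Cluster a drug-response profile matrix
#'
#' Complete-linkage hierarchical clustering of rows (drugs, Spearman
#' distance) and columns (cell lines, Euclidean distance).
#'
#' @param values numeric matrix, rows = compounds, columns = cell lines
#'   (sDSS by default in the pipeline; any response matrix works).
#' @return `cluster_result`: list with `row_hclust`, `col_hclust` (stats
#'   [hclust] objects), `row_order`, `col_order` (leaf orders), `values`.
#' @export
cluster_profiles <- function(values) {
  values <- as.matrix(values)
  if (nrow(values) < 2L || ncol(values) < 2L) {
    stop("need at least 2 rows and 2 columns to cluster")
  }
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("row%d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("col%d", seq_len(ncol(values)))
  }
  rh <- stats::hclust(spearman_dist(values), method = "complete")
  ch <- stats::hclust(stats::dist(t(values)), method = "complete")
  structure(list(row_hclust = rh, col_hclust = ch,
                 row_order = rh$order, col_order = ch$order,
                 values = values),
            class = "cluster_result")
}

# --- TreeView-compatible export ---------------------------------------------

hclust_to_gtr <- function(h, prefix) {
  n <- length(h$order)
  rows <- character(n - 1L)
  node_name <- function(i) {
    if (i < 0) sprintf("%s%dX", prefix, -i - 1L) else sprintf("NODE%dX", i)
  }
  for (k in seq_len(n - 1L)) {
    rows[k] <- paste(sprintf("NODE%dX", k),
                     node_name(h$merge[k, 1]),
                     node_name(h$merge[k, 2]),
                     format(1 - h$height[k], digits = 17),
                     sep = "\t")
  }
  rows
}

gtr_to_merge <- function(lines) {
  parts <- strsplit(lines, "\t", fixed = TRUE)
  n <- length(parts) + 1L
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  parse_node <- function(s) {
    if (startsWith(s, "NODE")) {
      as.integer(sub("NODE(\\d+)X", "\\1", s))
    } else {
      -(as.integer(sub("[A-Z]+(\\d+)X", "\\1", s)) + 1L)
    }
  }
  for (k in seq_len(n - 1L)) {
    merge[k, 1] <- parse_node(parts[[k]][2])
    merge[k, 2] <- parse_node(parts[[k]][3])
    height[k] <- 1 - as.numeric(parts[[k]][4])
  }
  list(merge = merge, height = height)
}

#' Export a clustering to TreeView-compatible files
#'
#' Writes `<basename>.cdt` (the clustered data table, rows and columns in
#' dendrogram leaf order), `<basename>.gtr` (row/gene tree),
#' `<basename>.atr` (column/array tree) and `<basename>.json` (a plain
#' serialization of orders, merges and heights). The similarity column of
#' the tree files is `1 - merge height`, stored at full precision so the
#' round trip through [read_cdt()] is lossless.
#'
#' @param result a [cluster_profiles()] result.
#' @param basename output path without extension.
#' @return invisibly, the paths written.
#' @export
export_cluster_files <- function(result, basename) {
  stopifnot(inherits(result, "cluster_result"))
  v <- result$values
  ro <- result$row_order
  co <- result$col_order
  paths <- paste0(basename, c(".cdt", ".gtr", ".atr", ".json"))

  gene_ids <- sprintf("GENE%dX", seq_len(nrow(v)) - 1L)
  arry_ids <- sprintf("ARRY%dX", seq_len(ncol(v)) - 1L)
  header <- paste(c("GID", "UNIQID", "NAME", "GWEIGHT",
                    colnames(v)[co]), collapse = "\t")
  aid <- paste(c("AID", "", "", "", arry_ids[co]), collapse = "\t")
  eweight <- paste(c("EWEIGHT", "", "", "", rep("1", ncol(v))),
                   collapse = "\t")
  data_rows <- vapply(ro, function(i) {
    paste(c(gene_ids[i], rownames(v)[i], rownames(v)[i], "1",
            format(v[i, co], digits = 17)), collapse = "\t")
  }, character(1))
  tryCatch({
    writeLines(c(header, aid, eweight, data_rows), paths[1])
    writeLines(hclust_to_gtr(result$row_hclust, "GENE"), paths[2])
    writeLines(hclust_to_gtr(result$col_hclust, "ARRY"), paths[3])
    jsonlite::write_json(list(
      row_order = result$row_order, col_order = result$col_order,
      row_merge = result$row_hclust$merge,
      row_height = result$row_hclust$height,
      col_merge = result$col_hclust$merge,
      col_height = result$col_hclust$height,
      rows = rownames(v), cols = colnames(v)
    ), paths[4], digits = NA)
  }, error = function(e) {
    stop("failed writing cluster files at ", basename, ": ",
         conditionMessage(e))
  })
  invisible(paths)
}

#' Read back a CDT (+ GTR/ATR) export
#'
#' @param basename path prefix used in [export_cluster_files()].
#' @return list: `values` (matrix in clustered order), `row_tree`,
#'   `col_tree` (merge matrices + heights, present if the files exist).
#' @export
read_cdt <- function(basename) {
  cdt <- readLines(paste0(basename, ".cdt"))
  header <- strsplit(cdt[1], "\t", fixed = TRUE)[[1]]
  has_aid <- startsWith(cdt[2], "AID")
  body <- cdt[-(1:(2 + has_aid))]
  parts <- strsplit(body, "\t", fixed = TRUE)
  vals <- t(vapply(parts, function(p) as.numeric(p[-(1:4)]),
                   numeric(length(header) - 4L)))
  rownames(vals) <- vapply(parts, `[[`, character(1), 2L)
  colnames(vals) <- header[-(1:4)]
  out <- list(values = vals)
  gtr <- paste0(basename, ".gtr")
  if (file.exists(gtr)) out$row_tree <- gtr_to_merge(readLines(gtr))
  atr <- paste0(basename, ".atr")
  if (file.exists(atr)) out$col_tree <- gtr_to_merge(readLines(atr))
  out
}

# --- responder groups and marker testing ------------------------------------

#' Define responder groups from class-average cytotoxic DSS
#'
#' Averages the (toxicity-readout) DSS of all compounds in a drug class per
#' cell line; lines at or above `threshold` form the sensitive group, the
#' rest the insensitive group.
#'
#' @param dss_records output of [score_screen()].
#' @param library a [make_library()]-style data.frame with `compound_id`
#'   and `drug_class`.
#' @param drug_class class label(s) defining the responder phenotype (e.g.
#'   mitotic or proteasome inhibitors).
#' @param readout readout to average (default `tox_fluor`).
#' @param threshold DSS threshold separating sensitive from insensitive.
#' @return list: `sensitive`, `insensitive` (cell-line ids), `class_mean`
#'   (named per-line means).
#' @export
define_responder_groups <- function(dss_records, library, drug_class,
                                    readout = "tox_fluor", threshold = 5) {
  compounds <- library$compound_id[library$drug_class %in% drug_class]
  if (length(compounds) == 0L) {
    stop("no compounds tagged with class: ",
         paste(drug_class, collapse = ", "))
  }
  sub <- dss_records[dss_records$compound_id %in% compounds &
                       dss_records$readout == readout, ]
  if (nrow(sub) == 0L) stop("no scored records for the requested class/readout")
  mu <- tapply(sub$dss, sub$cell_line, mean)
  sensitive <- names(mu)[mu >= threshold]
  if (length(sensitive) == 0L) {
    warning("no cell line reaches the sensitivity threshold")
  }
  list(sensitive = sensitive,
       insensitive = setdiff(names(mu), sensitive),
       class_mean = mu)
}

# Welch / pooled two-sample t in closed form; handles the zero-variance
# corner (identical values in both groups -> t = 0, p = 1) that
# stats::t.test refuses.
two_sample_t <- function(a, b, var_equal = FALSE) {
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  n1 <- length(a)
  n2 <- length(b)
  m1 <- mean(a)
  m2 <- mean(b)
  v1 <- stats::var(a)
  v2 <- stats::var(b)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- n1 + n2 - 2
  } else {
    se2 <- v1 / n1 + v2 / n2
    df <- if (se2 > 0) {
      se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    } else {
      n1 + n2 - 2
    }
  }
  if (se2 == 0) {
    tstat <- if (m1 == m2) 0 else sign(m1 - m2) * Inf
  } else {
    tstat <- (m1 - m2) / sqrt(se2)
  }
  p <- if (is.infinite(tstat)) 0 else 2 * stats::pt(-abs(tstat), df)
  list(t = tstat, df = df, p = p, mean1 = m1, mean2 = m2)
}

#' Marker-wise two-sample t-tests between responder groups
#'
#' One two-sample t-test per marker (row) comparing the sensitive against
#' the insensitive cell-line group. Welch's unequal-variance form is the
#' default; the pooled-variance form is available with
#' `var_equal = TRUE`. Raw p-values are compared against `alpha`
#' (default 0.05); Benjamini-Hochberg adjusted significance is additionally
#' reported when `adjust = "BH"`.
#'
#' @param marker_table numeric matrix, markers x cell lines.
#' @param groups list with `sensitive` and `insensitive` cell-line ids
#'   (each of size >= 2, all present in the table's columns).
#' @param alpha significance level on raw p-values.
#' @param var_equal use the pooled-variance t-test.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame: `marker`, `mean_sensitive`, `mean_insensitive`,
#'   `t`, `df`, `p`, `significant` (and `p_adj`, `significant_adj` under
#'   BH).
#' @export
marker_ttest <- function(marker_table, groups, alpha = 0.05,
                         var_equal = FALSE, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  g1 <- groups$sensitive
  g2 <- groups$insensitive
  for (nm in c("sensitive", "insensitive")) {
    g <- groups[[nm]]
    if (length(g) < 2L) {
      stop("group '", nm, "' has fewer than 2 cell lines")
    }
    missing_lines <- setdiff(g, colnames(marker_table))
    if (length(missing_lines) > 0L) {
      stop("group '", nm, "' lines absent from marker table: ",
           paste(missing_lines, collapse = ", "))
    }
  }
  res <- lapply(seq_len(nrow(marker_table)), function(i) {
    tt <- two_sample_t(marker_table[i, g1], marker_table[i, g2], var_equal)
    data.frame(marker = rownames(marker_table)[i],
               mean_sensitive = tt$mean1, mean_insensitive = tt$mean2,
               t = tt$t, df = tt$df, p = tt$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$significant <- out$p <= alpha
  if (adjust == "BH") {
    out$p_adj <- stats::p.adjust(out$p, method = "BH")
    out$significant_adj <- out$p_adj <= alpha
  }
  out
}
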