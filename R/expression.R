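#' Two-group expression matrix
#'
#' Container for a log2-scale expression matrix (features x samples) with a
#' case/control label per sample. Values must be finite and each group must
#' hold at least two samples (the two-sample t-test is undefined otherwise).
#'
#' @param values Numeric matrix, rownames = feature ids, colnames = sample
#'   ids, log2 scale.
#' @param labels Named character vector mapping every sample id to `"case"`
#'   or `"control"`.
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, labels) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("values must have feature rownames and sample colnames")
  }
  missing_lab <- setdiff(colnames(values), names(labels))
  if (length(missing_lab)) {
    abort(paste0("samples missing from labels: ",
                 paste(missing_lab, collapse = ", ")))
  }
  labels <- labels[colnames(values)]
  if (!all(labels %in% c("case", "control"))) {
    abort("labels must be 'case' or 'control'")
  }
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    abort(paste0("non-finite expression value at feature '",
                 rownames(values)[bad[1]], "', sample '",
                 colnames(values)[bad[2]], "'"))
  }
  if (sum(labels == "case") < 2 || sum(labels == "control") < 2) {
    abort("each group needs at least 2 samples")
  }
  structure(list(values = values, labels = labels), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("<expr_matrix> ", nrow(x$values), " features x ",
      ncol(x$values), " samples (",
      sum(x$labels == "case"), " case / ",
      sum(x$labels == "control"), " control)\n", sep = "")
  invisible(x)
}

#' @export
tidy.expr_matrix <- function(x, ...) {
  tibble::tibble(
    feature = rep(rownames(x$values), times = ncol(x$values)),
    sample = rep(colnames(x$values), each = nrow(x$values)),
    group = rep(unname(x$labels), each = nrow(x$values)),
    value = as.vector(x$values))
}

#' Load an expression matrix and its sample labels
#'
#' The matrix is delimited text (TSV or CSV by extension), first column
#' feature id, header row sample ids. Labels are a two-column delimited file
#' (sample, group) with group in `case`/`control`; a header row
#' `sample<tab>group` is allowed. Samples present in the matrix but absent
#' from the label file are an error; labelled samples absent from the matrix
#' are ignored.
#'
#' @param matrix_path Path to the expression matrix.
#' @param labels_path Path to the label file.
#' @return An [expr_matrix()].
#' @export
load_expression <- function(matrix_path, labels_path) {
  delim <- if (grepl("\\.csv$", matrix_path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.delim(matrix_path, sep = delim, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 3) abort("expression matrix needs >= 2 sample columns")
  feats <- raw[[1]]
  vals <- suppressWarnings(
    vapply(raw[-1], as.numeric, numeric(nrow(raw))))
  if (nrow(raw) == 1) vals <- matrix(vals, nrow = 1,
                                     dimnames = list(NULL, names(raw)[-1]))
  bad <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(paste0("non-numeric expression value at feature '",
                 feats[bad[1, 1]], "', sample '",
                 colnames(vals)[bad[1, 2]], "' in ", matrix_path))
  }
  rownames(vals) <- feats

  lab_raw <- utils::read.delim(labels_path, sep = "\t", header = FALSE,
                               colClasses = "character",
                               stringsAsFactors = FALSE)
  if (ncol(lab_raw) < 2) abort("label file needs 2 columns (sample, group)")
  if (identical(tolower(lab_raw[1, 1]), "sample")) {
    lab_raw <- lab_raw[-1, , drop = FALSE]
  }
  labels <- setNames(lab_raw[[2]], lab_raw[[1]])
  expr_matrix(vals, labels)
}

#' Collapse probe-level rows to gene-level rows
#'
#' Genes measured by several probes get, per sample, the median across the
#' gene's probes (configurable to the mean, or to the single probe with the
#' largest variance). Probes absent from the map are dropped; the count is
#' attached as attribute `"n_unmapped"`.
#'
#' @param em An [expr_matrix()] with probe-level features.
#' @param probe_map Data frame with columns `probe`, `gene`.
#' @param method `"median"` (default), `"mean"` or `"maxvar"`.
#' @return A gene-level [expr_matrix()].
#' @export
collapse_probes <- function(em, probe_map,
                            method = c("median", "mean", "maxvar")) {
  method <- match.arg(method)
  stopifnot(inherits(em, "expr_matrix"),
            all(c("probe", "gene") %in% names(probe_map)))
  keep <- rownames(em$values) %in% probe_map$probe
  n_unmapped <- sum(!keep)
  if (!any(keep)) abort("no probes left after applying the probe map")
  vals <- em$values[keep, , drop = FALSE]
  gene <- probe_map$gene[match(rownames(vals), probe_map$probe)]
  idx <- split(seq_len(nrow(vals)), gene)
  collapsed <- t(vapply(idx, function(ix) {
    sub <- vals[ix, , drop = FALSE]
    switch(method,
           median = apply(sub, 2, median),
           mean = colMeans(sub),
           maxvar = sub[which.max(apply(sub, 1, stats::var)), ])
  }, numeric(ncol(vals))))
  colnames(collapsed) <- colnames(vals)
  out <- expr_matrix(collapsed, em$labels)
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Fold change from group medians of log2 expression
#'
#' The case-over-control fold change is the ratio of 2 raised to the group
#' medians of log2-scale expression: `f = 2^(case - control)`. Vectorised.
#'
#' @param control_median_log2,case_median_log2 Group medians on log2 scale.
#' @return Linear-scale fold change, > 0.
#' @export
fold_change_from_medians <- function(control_median_log2, case_median_log2) {
  stopifnot(all(is.finite(control_median_log2)),
            all(is.finite(case_median_log2)))
  2^(case_median_log2 - control_median_log2)
}

# vectorised two-sample t-test p-values over matrix rows
row_t_pvalues <- function(values, case_idx, ctrl_idx, var_equal = TRUE) {
  x <- values[, case_idx, drop = FALSE]
  y <- values[, ctrl_idx, drop = FALSE]
  n1 <- length(case_idx); n2 <- length(ctrl_idx)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep.int(n1 + n2 - 2, length(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tt <- (m1 - m2) / se
  p <- 2 * pt(-abs(tt), df)
  # zero within-group variance in both groups: equal means carry no
  # evidence (p = 1); unequal means are maximal evidence (p -> 0)
  degenerate <- se == 0
  p[degenerate & m1 == m2] <- 1
  p[degenerate & m1 != m2] <- .Machine$double.xmin
  unname(p)
}

#' Per-gene fold changes, signs and t-test p-values
#'
#' For each gene: the fold change `f` from group medians
#' ([fold_change_from_medians()]), its binary sign `b` (+1 iff `f > 1`,
#' otherwise -1, so `f = 1` maps to -1), and the two-sided two-sample t-test
#' p-value on the log2 values (pooled variance by default; Welch via
#' `var_equal = FALSE`).
#'
#' @param em A gene-level [expr_matrix()].
#' @param var_equal Use the pooled-variance t-test (default) or Welch.
#' @return Tibble with columns `gene`, `control_median`, `case_median`,
#'   `log2_fc`, `f`, `b`, `pval`.
#' @export
compute_gene_stats <- function(em, var_equal = TRUE) {
  stopifnot(inherits(em, "expr_matrix"))
  case_idx <- which(em$labels == "case")
  ctrl_idx <- which(em$labels == "control")
  med <- row_group_medians(em$values, case_idx, ctrl_idx)
  l2f <- med[, 1] - med[, 2]
  p <- row_t_pvalues(em$values, case_idx, ctrl_idx, var_equal = var_equal)
  tibble::tibble(
    gene = rownames(em$values),
    control_median = med[, 2],
    case_median = med[, 1],
    log2_fc = l2f,
    f = 2^l2f,
    b = ifelse(l2f > 0, 1L, -1L),
    pval = p)
}
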