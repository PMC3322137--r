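#' Shuffle case/control sample labels
#'
#' Uniformly random permutation of the label vector; group sizes are
#' preserved because the labels themselves are only reassigned to samples.
#' Uses the session RNG, so wrap in `set.seed()` for reproducibility.
#'
#' @param labels Named character vector of `"case"`/`"control"` labels.
#' @return Named character vector over the same samples.
#' @export
permute_labels <- function(labels) {
  setNames(sample(unname(labels)), names(labels))
}

#' Permutation null distribution of the statistic S
#'
#' For each permutation the sample labels are shuffled, per-gene statistics
#' (fold change, sign, t-test p-value) are recomputed, the well-defined
#' segment of every original linear subpathway is re-extracted under the new
#' signs, and its S is computed. The bivariate edge model and the
#' path-length distribution are held fixed (they are treated as properties
#' of the pathway corpus); refitting per permutation is available via
#' `refit_model = TRUE`.
#'
#' @param subpaths Unique linear subpathways ([decompose_pathways()]).
#' @param em Gene-level [expr_matrix()].
#' @param model Fitted [fit_edge_model()].
#' @param dist [path_length_distribution()] result.
#' @param n_perm Number of permutations (>= 1; < 100 warns of an unstable
#'   tail).
#' @param mode `"pooled"` pools all permuted S values into one null sample;
#'   `"per_subpathway"` keeps one null row per chain.
#' @param var_equal Pooled-variance t-test (default) or Welch.
#' @param refit_model Refit the edge model to each permutation's fold
#'   changes (slow; default `FALSE`).
#' @param graphs Pathway graphs, required when `refit_model = TRUE`.
#' @return For `"pooled"`: numeric vector of all valid permuted S values,
#'   with attribute `"n_perm"`. For `"per_subpathway"`: a `n_chain x n_perm`
#'   matrix (NA where a permuted chain had no segment).
#' @export
null_distribution <- function(subpaths, em, model, dist, n_perm = 1e4,
                              mode = c("pooled", "per_subpathway"),
                              var_equal = TRUE, refit_model = FALSE,
                              graphs = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(em, "expr_matrix"))
  if (n_perm < 1) abort("n_perm must be >= 1 (empty null pool)")
  if (n_perm < 100) warn("n_perm < 100: unstable null tail")
  if (refit_model && is.null(graphs)) {
    abort("refit_model = TRUE requires `graphs`")
  }
  cc <- compile_chains(subpaths, rownames(em$values))
  lfnum <- log_f_num_table(dist, max(cc$lens))
  labels <- em$labels
  n_case <- sum(labels == "case")
  n_samp <- length(labels)
  X <- em$values

  per <- if (mode == "per_subpathway") {
    matrix(NA_real_, cc$n_chain, n_perm)
  }
  pool <- vector("list", n_perm)
  for (k in seq_len(n_perm)) {
    case_idx <- sample.int(n_samp, n_case)
    ctrl_idx <- seq_len(n_samp)[-case_idx]
    med <- row_group_medians(X, case_idx, ctrl_idx)
    l2f <- med[, 1] - med[, 2]
    b <- ifelse(l2f > 0, 1L, -1L)
    p <- row_t_pvalues(X, case_idx, ctrl_idx, var_equal = var_equal)
    logp <- log(pmax(p, .Machine$double.xmin))
    mdl <- model
    if (refit_model) {
      gs <- tibble::tibble(gene = rownames(X), log2_fc = l2f)
      mdl <- fit_edge_model(graphs, gs)
    }
    sc <- score_compiled(cc, b, logp, l2f, mdl, lfnum)
    if (mode == "pooled") {
      pool[[k]] <- sc$S[!is.na(sc$S)]
    } else {
      per[, k] <- sc$S
    }
  }
  if (mode == "pooled") {
    out <- unlist(pool)
    attr(out, "n_perm") <- n_perm
    out
  } else {
    per
  }
}

#' Empirical permutation p-value
#'
#' `Pr(S >= s)` against the null pool. By default an add-one correction is
#' applied, `p = (1 + #(S_null >= s)) / (1 + N)`, so no p-value is exactly
#' zero; `add_one = FALSE` gives the raw proportion.
#'
#' @param s_observed Observed S value(s); vectorised.
#' @param null_pool Numeric vector of permuted S values.
#' @param add_one Apply the add-one correction (default `TRUE`).
#' @return P-value(s) in (0, 1].
#' @export
empirical_pvalue <- function(s_observed, null_pool, add_one = TRUE) {
  null_pool <- null_pool[!is.na(null_pool)]
  if (length(null_pool) == 0) abort("empty null pool")
  sorted <- sort(null_pool)
  n_ge <- length(sorted) -
    findInterval(s_observed, sorted, left.open = TRUE)
  if (add_one) (1 + n_ge) / (1 + length(sorted)) else n_ge / length(sorted)
}

#' Benjamini-Hochberg FDR q-values
#'
#' Step-up procedure: with sorted p-values `p_(1) <= ... <= p_(N)`,
#' `q_(i) = min_{j >= i} (N * p_(j) / j)` capped at 1, mapped back to the
#' input order.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Q-values in input order.
#' @export
bh_fdr <- function(pvals) {
  stopifnot(all(pvals >= 0 & pvals <= 1))
  n <- length(pvals)
  if (n == 0) return(numeric(0))
  o <- order(pvals)
  q <- rev(cummin(rev(n * pvals[o] / seq_len(n))))
  q <- pmin(q, 1)
  q[order(o)]
}

#' Permutation test over scored subpathways
#'
#' Builds the permutation null of S, then assigns each observed
#' well-defined subpathway an empirical p-value and a Benjamini-Hochberg
#' q-value.
#'
#' @param scored Tibble from [score_subpathways()].
#' @inheritParams null_distribution
#' @param add_one Add-one correction for [empirical_pvalue()].
#' @return `scored` plus `pval`, `qval`, `neg_log10_p`, sorted by `pval`
#'   (ties by S descending); the null pool is kept in attribute `"null"`.
#' @export
permutation_test <- function(scored, subpaths, em, model, dist,
                             n_perm = 1e4,
                             mode = c("pooled", "per_subpathway"),
                             var_equal = TRUE, add_one = TRUE) {
  mode <- match.arg(mode)
  null <- null_distribution(subpaths, em, model, dist, n_perm = n_perm,
                            mode = mode, var_equal = var_equal)
  out <- scored
  if (mode == "pooled") {
    out$pval <- empirical_pvalue(out$S, null, add_one = add_one)
  } else {
    key_order <- match(out$key, subpaths$key)
    out$pval <- vapply(seq_len(nrow(out)), function(i) {
      empirical_pvalue(out$S[i], null[key_order[i], ], add_one = add_one)
    }, numeric(1))
  }
  out$qval <- bh_fdr(out$pval)
  out$neg_log10_p <- -log10(out$pval)
  out <- out[order(out$pval, -out$S), , drop = FALSE]
  attr(out, "null") <- null
  out
}
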