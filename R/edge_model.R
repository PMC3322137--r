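#' Fit the bivariate edge fold-change model and its prior
#'
#' Collects, over every edge of every loaded pathway, the pair (log2 fold
#' change of the source gene, log2 fold change of the sink gene) - expanding
#' multi-gene entries to all gene pairs - and fits a bivariate normal by
#' sample moments. The prior is a univariate normal fitted to the log2 fold
#' changes of all measured genes appearing in the pathways. The conditional
#' densities of this model are the `F_edge` factors of the subpathway
#' statistic.
#'
#' @param graphs A `pathway_graph` or list of them.
#' @param gene_stats Tibble from [compute_gene_stats()].
#' @param min_pairs Minimum number of measured edge pairs required
#'   (default 30).
#' @return An object of class `edge_model` with elements `mu_src`, `mu_snk`,
#'   `sd_src`, `sd_snk`, `rho`, `prior_mean`, `prior_sd`, `n_pairs`,
#'   `n_prior_genes` and the fitted `pairs` tibble.
#' @export
fit_edge_model <- function(graphs, gene_stats, min_pairs = 30) {
  if (inherits(graphs, "pathway_graph")) graphs <- list(graphs)
  l2f <- setNames(gene_stats$log2_fc, gene_stats$gene)

  src_v <- list(); snk_v <- list()
  prior_genes <- character()
  for (g in graphs) {
    gene_sets <- setNames(g$entries$genes, g$entries$entry_id)
    prior_genes <- c(prior_genes, unlist(gene_sets, use.names = FALSE))
    for (i in seq_len(nrow(g$edges))) {
      sg <- intersect(gene_sets[[g$edges$source[i]]], names(l2f))
      kg <- intersect(gene_sets[[g$edges$sink[i]]], names(l2f))
      if (length(sg) && length(kg)) {
        grid <- expand.grid(src = sg, snk = kg, stringsAsFactors = FALSE)
        src_v[[length(src_v) + 1]] <- l2f[grid$src]
        snk_v[[length(snk_v) + 1]] <- l2f[grid$snk]
      }
    }
  }
  xs <- unname(unlist(src_v)); ys <- unname(unlist(snk_v))
  if (length(xs) < min_pairs) {
    abort(paste0("only ", length(xs), " measured edge pairs; ",
                 min_pairs, " required to fit the edge model"))
  }
  sd_src <- sd(xs); sd_snk <- sd(ys)
  if (sd_src == 0 || sd_snk == 0) {
    abort("degenerate edge pairs: zero variance on one margin")
  }
  rho <- cor(xs, ys)
  if (!is.finite(rho) || abs(rho) >= 1) {
    abort("degenerate edge pairs: |correlation| >= 1")
  }
  prior_genes <- intersect(unique(prior_genes), names(l2f))
  prior_vals <- l2f[prior_genes]
  prior_sd <- sd(prior_vals)
  if (!is.finite(prior_sd) || prior_sd == 0) {
    abort("degenerate prior: zero variance of pathway-gene fold changes")
  }
  structure(
    list(mu_src = mean(xs), mu_snk = mean(ys),
         sd_src = sd_src, sd_snk = sd_snk, rho = rho,
         prior_mean = mean(prior_vals), prior_sd = prior_sd,
         n_pairs = length(xs), n_prior_genes = length(prior_vals),
         pairs = tibble::tibble(src = xs, snk = ys)),
    class = "edge_model")
}

#' @export
print.edge_model <- function(x, ...) {
  cat("<edge_model> bivariate normal over (log2 fc source, log2 fc sink)\n")
  cat(sprintf("  mu = (%.3f, %.3f)  sd = (%.3f, %.3f)  rho = %.3f  [%d pairs]\n",
              x$mu_src, x$mu_snk, x$sd_src, x$sd_snk, x$rho, x$n_pairs))
  cat(sprintf("  prior: N(%.3f, %.3f^2)  [%d genes]\n",
              x$prior_mean, x$prior_sd, x$n_prior_genes))
  invisible(x)
}

#' @export
tidy.edge_model <- function(x, ...) {
  tibble::tibble(
    term = c("mu_src", "mu_snk", "sd_src", "sd_snk", "rho",
             "prior_mean", "prior_sd"),
    estimate = c(x$mu_src, x$mu_snk, x$sd_src, x$sd_snk, x$rho,
                 x$prior_mean, x$prior_sd))
}

#' @export
glance.edge_model <- function(x, ...) {
  tibble::tibble(n_pairs = x$n_pairs, n_prior_genes = x$n_prior_genes,
                 rho = x$rho)
}

#' Conditional density of the sink fold change given the source
#'
#' Density of the conditional normal implied by the fitted bivariate model:
#' mean `mu_snk + rho * (sd_snk / sd_src) * (x_source - mu_src)`, variance
#' `sd_snk^2 * (1 - rho^2)`. Vectorised over `x_sink`/`x_source`.
#'
#' @param x_sink,x_source Log2 fold changes of the sink and source gene.
#' @param model An [fit_edge_model()] fit.
#' @param log Return the log density.
#' @return Positive density (or its log).
#' @export
conditional_density <- function(x_sink, x_source, model, log = FALSE) {
  stopifnot(inherits(model, "edge_model"))
  mu <- model$mu_snk +
    model$rho * (model$sd_snk / model$sd_src) * (x_source - model$mu_src)
  dnorm(x_sink, mean = mu, sd = model$sd_snk * sqrt(1 - model$rho^2),
        log = log)
}

#' Prior density of a log2 fold change
#'
#' Univariate normal density fitted over all measured pathway genes; the
#' prior factor at the upstream end of the F_edge Markov chain.
#'
#' @inheritParams conditional_density
#' @param x Log2 fold change.
#' @return Density (or its log).
#' @export
prior_density <- function(x, model, log = FALSE) {
  stopifnot(inherits(model, "edge_model"))
  dnorm(x, mean = model$prior_mean, sd = model$prior_sd, log = log)
}

#' @export
autoplot.edge_model <- function(object, ...) {
  ggplot2::ggplot(object$pairs, ggplot2::aes(x = .data$src, y = .data$snk)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5, colour = "firebrick") +
    ggplot2::labs(x = "log2 fold change (source)",
                  y = "log2 fold change (sink)",
                  title = sprintf("Edge fold-change model (rho = %.2f, %d pairs)",
                                  object$rho, object$n_pairs)) +
    ggplot2::theme_minimal()
}
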