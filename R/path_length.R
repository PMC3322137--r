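#' Empirical path-length distribution from random graphs
#'
#' Simulates directed G(n, m) random graphs (no self-loops), enumerates all
#' simple root-to-leaf paths in each, and pools the path edge counts into an
#' empirical pmf. This pmf is the length-normalisation factor `F_num`: a
#' well-defined segment of `n` nodes is looked up at `n - 1` edges. Lengths
#' the simulation never produced get an additive-smoothing floor
#' `eps = 1 / (total path count + support size)` instead of zero mass.
#'
#' @param n_graphs Number of replicate graphs (default 1000).
#' @param n_nodes Nodes per graph (default 200).
#' @param n_edges Edges per graph (default 100).
#' @param seed Optional integer seed; stored with the result so the
#'   simulation is reproducible.
#' @return An object of class `path_length_dist`: a list with `pmf` (tibble
#'   `k`, `count`, `prob`), `eps`, `total_paths` and `params`.
#' @export
path_length_distribution <- function(n_graphs = 1000, n_nodes = 200,
                                     n_edges = 100, seed = NULL) {
  stopifnot(n_graphs >= 1, n_nodes >= 2, n_edges >= 1)
  if (!is.null(seed)) set.seed(seed)
  counts <- integer(0)
  for (r in seq_len(n_graphs)) {
    ig <- igraph::sample_gnm(n_nodes, n_edges, directed = TRUE)
    indeg <- igraph::degree(ig, mode = "in")
    outdeg <- igraph::degree(ig, mode = "out")
    roots <- which(indeg == 0 & outdeg > 0)
    leaves <- which(outdeg == 0 & indeg > 0)
    if (length(roots) == 0 || length(leaves) == 0) next
    for (rt in roots) {
      vp <- igraph::all_simple_paths(ig, from = rt, to = leaves,
                                     mode = "out")
      if (length(vp)) {
        ks <- lengths(vp) - 1L
        counts <- c(counts, ks)
      }
    }
  }
  tab <- table(counts)
  total <- length(counts)
  pmf <- tibble::tibble(k = as.integer(names(tab)),
                        count = as.integer(tab),
                        prob = as.integer(tab) / total)
  structure(
    list(pmf = pmf,
         eps = 1 / (total + nrow(pmf)),
         total_paths = total,
         params = list(n_graphs = n_graphs, n_nodes = n_nodes,
                       n_edges = n_edges, seed = seed)),
    class = "path_length_dist")
}

#' @export
print.path_length_dist <- function(x, ...) {
  cat("<path_length_dist> ", x$total_paths, " root-to-leaf paths pooled from ",
      x$params$n_graphs, " G(", x$params$n_nodes, ", ", x$params$n_edges,
      ") graphs\n", sep = "")
  cat("  support (edges): ", paste(range(x$pmf$k), collapse = "-"),
      "  floor eps = ", signif(x$eps, 3), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.path_length_dist <- function(x, ...) x$pmf

#' Length-normalisation factor F_num
#'
#' Empirical probability that a random-graph root-to-leaf path has `n - 1`
#' edges, floored at `eps` so unobserved lengths never zero out the total
#' score.
#'
#' @param n Number of nodes in the well-defined segment (>= 2).
#' @param dist A [path_length_distribution()] result.
#' @return Positive probability mass. Vectorised over `n`.
#' @export
f_num <- function(n, dist) {
  stopifnot(inherits(dist, "path_length_dist"), all(n >= 2))
  p <- dist$pmf$prob[match(n - 1L, dist$pmf$k)]
  p[is.na(p)] <- 0
  pmax(p, dist$eps)
}

# log F_num lookup table for n = 2..max_n (internal)
log_f_num_table <- function(dist, max_n) {
  n <- seq(2L, max(2L, max_n))
  c(NA_real_, log(f_num(n, dist)))  # index by n directly: [n]
}

#' @export
autoplot.path_length_dist <- function(object, ...) {
  ggplot2::ggplot(object$pmf, ggplot2::aes(x = .data$k, y = .data$prob)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "path length (edges)", y = "probability",
                  title = "Root-to-leaf path length distribution") +
    ggplot2::theme_minimal()
}

#' Serialize the edge model and path-length distribution to JSON
#'
#' Writes the fitted moments and the pmf (with simulation parameters and
#' seeds) to a small JSON document for bit-reproducible reruns.
#'
#' @param model An `edge_model` (or `NULL`).
#' @param dist A `path_length_dist` (or `NULL`).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model = NULL, dist = NULL, path) {
  out <- list()
  if (!is.null(model)) {
    out$edge_model <- model[c("mu_src", "mu_snk", "sd_src", "sd_snk", "rho",
                              "prior_mean", "prior_sd", "n_pairs",
                              "n_prior_genes")]
  }
  if (!is.null(dist)) {
    out$path_length <- list(pmf = dist$pmf, eps = dist$eps,
                            total_paths = dist$total_paths,
                            params = dist$params)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
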