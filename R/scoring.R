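#' Leaf-anchored rule-consistent segment of a linear subpathway
#'
#' Scanning from the leaf upward, an edge between sink `G_i` and source
#' `G_(i+1)` (with sign `e_i`) is consistent when `e_i * b_i * b_(i+1) = 1`:
#' activation links genes moving in the same direction, repression links
#' genes moving in opposite directions. The well-defined segment is the
#' leaf plus the run of consecutive consistent edges; probing stops at the
#' first violation, so edges beyond it never contribute. A segment needs at
#' least 2 nodes, so a subpathway whose first (leaf-adjacent) edge already
#' violates has no well-defined segment.
#'
#' @param genes Character vector of the chain's genes, root first (the leaf
#'   is the last element).
#' @param edge_signs Integer vector (+1/-1), `edge_signs[j]` signing the
#'   edge `genes[j] -> genes[j + 1]`.
#' @param b Integer vector of per-gene expression signs (+1/-1), aligned
#'   with `genes`.
#' @return `NULL` when no segment of >= 2 nodes exists, else a list with
#'   `n` (segment node count) and `genes` (the segment, leaf first:
#'   `G_1 ... G_n`).
#' @export
well_defined_suffix <- function(genes, edge_signs, b) {
  p <- length(genes)
  stopifnot(p >= 2, length(edge_signs) == p - 1, length(b) == p)
  bl <- rev(b)            # leaf-first signs b_1 ... b_p
  el <- rev(edge_signs)   # e_1 ... e_(p-1), e_i: G_(i+1) -> G_i
  ok <- el * bl[-p] * bl[-1] == 1
  n_edges <- if (all(ok)) p - 1L else which(!ok)[1] - 1L
  if (n_edges < 1L) return(NULL)
  n <- n_edges + 1L
  list(n = n, genes = rev(genes)[seq_len(n)])
}

#' Node score F_node
#'
#' Product of the two-sample t-test p-values of every gene in the
#' well-defined segment. No differential-expression cutoff is applied:
#' strongly and weakly changed genes both enter, and lowering any single
#' p-value lowers F_node (raising the statistic S).
#'
#' @param pvals P-values of the segment genes, each in (0, 1]. A zero
#'   p-value is replaced by the smallest positive double, with a warning.
#' @return Product of the p-values, in (0, 1].
#' @export
f_node <- function(pvals) {
  stopifnot(length(pvals) >= 1, all(pvals >= 0), all(pvals <= 1))
  if (any(pvals == 0)) {
    warn("zero p-value replaced by machine minimum in F_node")
    pvals[pvals == 0] <- .Machine$double.xmin
  }
  prod(pvals)
}

#' Edge score F_edge
#'
#' First-order Markov chain over the segment's log2 fold changes: the
#' density of the upstream end `G_n` under the prior, times the conditional
#' density of each gene given its direct upstream source,
#' `F_edge = Pr(log2 f_n) * prod_i Pr(log2 f_(n-i) | log2 f_(n-(i-1)))`.
#' Densities come from the fitted bivariate normal ([fit_edge_model()]); a
#' sink fold change far from what its source predicts is a rare event with
#' low density, hence a small F_edge and a large S.
#'
#' @param l2f Log2 fold changes of the segment genes, leaf first
#'   (`G_1 ... G_n`), length >= 2.
#' @param model An [fit_edge_model()] fit.
#' @param log Return the log of F_edge.
#' @return Positive real (a product of densities; may exceed 1).
#' @export
f_edge <- function(l2f, model, log = FALSE) {
  n <- length(l2f)
  stopifnot(n >= 2)
  lp <- prior_density(l2f[n], model, log = TRUE) +
    sum(conditional_density(l2f[seq_len(n - 1)], l2f[seq_len(n - 1) + 1],
                            model, log = TRUE))
  if (log) lp else exp(lp)
}

#' Composite subpathway statistic S
#'
#' `S = -ln(F_node * F_edge * F_num)`, computed in log space so that tiny
#' factor products never underflow to zero.
#'
#' @param f_node,f_edge,f_num Positive score factors (see [f_node()],
#'   [f_edge()], [f_num()]).
#' @return The statistic S (a real; larger = stronger coherent signal).
#' @export
total_statistic <- function(f_node, f_edge, f_num) {
  if (any(c(f_node, f_edge, f_num) <= 0)) {
    abort("all score factors must be positive")
  }
  -(log(f_node) + log(f_edge) + log(f_num))
}

#' Extract well-defined segments for a set of subpathways
#'
#' Applies [well_defined_suffix()] to every unique linear subpathway using
#' per-gene signs from `gene_stats`. Chains containing unmeasured genes are
#' skipped (counted in attribute `"n_unmeasured"`) unless `strict = TRUE`,
#' in which case they raise an error naming the gene.
#'
#' @param subpaths Tibble from [decompose_pathways()] /
#'   [deduplicate_subpathways()].
#' @param gene_stats Tibble from [compute_gene_stats()].
#' @param strict Error on unmeasured genes instead of skipping.
#' @return `subpaths` filtered to chains with a segment, plus columns `n`
#'   and `segment` (list of leaf-first gene vectors).
#' @export
extract_well_defined <- function(subpaths, gene_stats, strict = FALSE) {
  b <- setNames(gene_stats$b, gene_stats$gene)
  measured <- purrr::map_lgl(subpaths$genes, ~ all(.x %in% names(b)))
  if (strict && !all(measured)) {
    miss <- setdiff(unlist(subpaths$genes[!measured]), names(b))
    abort(paste0("unmeasured gene(s) on subpathway: ",
                 paste(head(miss, 5), collapse = ", ")))
  }
  kept <- subpaths[measured, , drop = FALSE]
  res <- purrr::map2(kept$genes, kept$edge_signs,
                     ~ well_defined_suffix(.x, .y, unname(b[.x])))
  has <- !purrr::map_lgl(res, is.null)
  out <- kept[has, , drop = FALSE]
  out$n <- purrr::map_int(res[has], "n")
  out$segment <- purrr::map(res[has], "genes")
  attr(out, "n_unmeasured") <- sum(!measured)
  out
}

#' Score well-defined subpathways
#'
#' Computes F_node, F_edge, F_num and `S = -ln(F_node * F_edge * F_num)`
#' for every well-defined segment, in log space.
#'
#' @param wd Tibble from [extract_well_defined()].
#' @param gene_stats Tibble from [compute_gene_stats()].
#' @param model An [fit_edge_model()] fit.
#' @param dist A [path_length_distribution()] result.
#' @return `wd` with columns `log_f_node`, `log_f_edge`, `log_f_num`,
#'   `f_node`, `f_edge`, `f_num`, `S` appended.
#' @export
score_subpathways <- function(wd, gene_stats, model, dist) {
  logp <- setNames(log(pmax(gene_stats$pval, .Machine$double.xmin)),
                   gene_stats$gene)
  l2f <- setNames(gene_stats$log2_fc, gene_stats$gene)
  ln <- purrr::map_dbl(wd$segment, ~ sum(logp[.x]))
  le <- purrr::map_dbl(wd$segment, ~ f_edge(unname(l2f[.x]), model,
                                            log = TRUE))
  lf <- log(f_num(wd$n, dist))
  out <- wd
  out$log_f_node <- ln
  out$log_f_edge <- le
  out$log_f_num <- lf
  out$f_node <- exp(ln)
  out$f_edge <- exp(le)
  out$f_num <- exp(lf)
  out$S <- -(ln + le + lf)
  out
}

# ---- compiled chain set: vectorised re-scoring for the permutation null ----

# Flattens unique chains into node/edge index arrays against the gene order
# of `genes_universe` so a permutation replicate is scored with a handful of
# vectorised operations instead of a per-chain loop.
compile_chains <- function(subpaths, genes_universe) {
  n_chain <- nrow(subpaths)
  lens <- lengths(subpaths$genes)
  stopifnot(all(lens >= 2))
  gi <- lapply(subpaths$genes, function(g) {
    ix <- match(g, genes_universe)
    if (anyNA(ix)) abort("chain gene missing from expression universe")
    rev(ix)  # leaf-first
  })
  el <- lapply(subpaths$edge_signs, rev)  # e_1 ... e_(p-1)

  node_chain <- rep.int(seq_len(n_chain), lens)
  node_pos <- unlist(lapply(lens, seq_len))
  node_gene <- unlist(gi)

  edge_chain <- rep.int(seq_len(n_chain), lens - 1L)
  edge_pos <- unlist(lapply(lens - 1L, seq_len))
  edge_snk <- unlist(lapply(gi, function(x) x[-length(x)]))
  edge_src <- unlist(lapply(gi, function(x) x[-1]))
  edge_sign <- unlist(el)

  gene_at <- matrix(NA_integer_, n_chain, max(lens))
  for (c in seq_len(n_chain)) gene_at[c, seq_len(lens[c])] <- gi[[c]]

  e_first <- match(seq_len(n_chain), edge_chain)
  e_last <- length(edge_chain) + 1L - match(seq_len(n_chain), rev(edge_chain))
  n_first <- match(seq_len(n_chain), node_chain)
  n_last <- length(node_chain) + 1L - match(seq_len(n_chain), rev(node_chain))

  list(n_chain = n_chain, lens = lens,
       node_chain = node_chain, node_pos = node_pos, node_gene = node_gene,
       edge_chain = edge_chain, edge_pos = edge_pos,
       edge_src = edge_src, edge_snk = edge_snk, edge_sign = edge_sign,
       gene_at = gene_at,
       e_first = e_first, e_last = e_last,
       n_first = n_first, n_last = n_last)
}

# Scores every compiled chain for one (b, log p, log2 fc) assignment.
# Returns list(n, S): n = segment node count (1 = no segment, S = NA).
score_compiled <- function(cc, b, logp, l2f, model, lfnum) {
  viol <- cc$edge_sign * b[cc$edge_src] * b[cc$edge_snk] != 1L
  cum <- cumsum(viol)
  base <- cum[cc$e_first] - viol[cc$e_first]
  within <- cum - rep.int(base, cc$lens - 1L)
  prefix_ok <- !viol & within == 0
  cnt <- cumsum(prefix_ok)
  pre <- cnt[cc$e_first] - prefix_ok[cc$e_first]
  n_edges <- cnt[cc$e_last] - pre
  n <- n_edges + 1L
  valid <- n >= 2L

  # F_node: sum of log p over segment nodes (pos <= n)
  contrib <- logp[cc$node_gene] * (cc$node_pos <= n[cc$node_chain])
  csn <- cumsum(contrib)
  s_node <- csn[cc$n_last] - csn[cc$n_first] + contrib[cc$n_first]

  # F_edge conditional terms: exactly the consistent prefix edges
  mu <- model$mu_snk +
    model$rho * (model$sd_snk / model$sd_src) * (l2f[cc$edge_src] - model$mu_src)
  ld <- dnorm(l2f[cc$edge_snk], mean = mu,
              sd = model$sd_snk * sqrt(1 - model$rho^2), log = TRUE)
  contrib_e <- ld * prefix_ok
  cse <- cumsum(contrib_e)
  s_edge <- cse[cc$e_last] - cse[cc$e_first] + contrib_e[cc$e_first]

  # prior at the upstream end G_n
  gene_n <- cc$gene_at[cbind(seq_len(cc$n_chain), pmin(n, cc$lens))]
  s_prior <- dnorm(l2f[gene_n], model$prior_mean, model$prior_sd, log = TRUE)

  S <- -(s_node + s_edge + s_prior + lfnum[n])
  S[!valid] <- NA_real_
  list(n = n, S = S)
}
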