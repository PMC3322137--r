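# Independent oracles used by the unit and acceptance tests. These are
# deliberately written without the package's enumeration/scoring code paths.

# Exhaustive recursive DFS over simple root-to-leaf paths; returns each
# entry-level path as a ">"-joined key.
oracle_simple_paths <- function(graph) {
  ids <- graph$entries$entry_id
  e <- graph$edges
  children <- split(e$sink, factor(e$source, levels = ids))
  indeg <- table(factor(e$sink, levels = ids))
  outdeg <- table(factor(e$source, levels = ids))
  connected <- indeg > 0 | outdeg > 0
  roots <- ids[connected & indeg == 0]
  leaves <- ids[connected & outdeg == 0]
  res <- character(0)
  recurse <- function(path) {
    node <- path[length(path)]
    if (node %in% leaves) {
      if (length(path) >= 2) res <<- c(res, paste(path, collapse = ">"))
      return(invisible(NULL))
    }
    for (ch in sort(children[[node]])) {
      if (!(ch %in% path)) recurse(c(path, ch))
    }
    invisible(NULL)
  }
  for (r in roots) recurse(r)
  res
}

# Dynamic-programming count of root-to-leaf paths in a DAG (topological
# order by construction: edges only go from lower to higher entry index).
oracle_dag_path_count <- function(graph) {
  ids <- graph$entries$entry_id
  e <- graph$edges
  indeg <- table(factor(e$sink, levels = ids))
  outdeg <- table(factor(e$source, levels = ids))
  connected <- indeg > 0 | outdeg > 0
  npaths <- setNames(ifelse(connected & indeg == 0, 1, 0), ids)
  for (v in ids) {  # ids are in topological order for these fixtures
    out_edges <- e$sink[e$source == v]
    for (w in out_edges) npaths[w] <- npaths[w] + npaths[v]
  }
  sum(npaths[connected & outdeg == 0 & indeg > 0])
}

# Random DAG pathway over single-gene entries; edges go forward in index
# order so the graph is acyclic and entry order is topological.
random_dag_graph <- function(n_nodes, p_edge = 0.3, pid = "rnd") {
  ids <- sprintf("n%02d", seq_len(n_nodes))
  pairs <- which(upper.tri(matrix(TRUE, n_nodes, n_nodes)), arr.ind = TRUE)
  keep <- stats::runif(nrow(pairs)) < p_edge
  pairs <- pairs[keep, , drop = FALSE]
  sgn <- sample(c(1L, -1L), nrow(pairs), replace = TRUE)
  pathway_graph(
    pid, pid,
    entries = tibble::tibble(entry_id = ids,
                             genes = as.list(paste0("g_", ids))),
    edges = tibble::tibble(source = ids[pairs[, 1]],
                           sink = ids[pairs[, 2]], sign = sgn))
}

# Bivariate normal joint density (direct formula, independent of the
# package's conditional-density code).
oracle_bvn_density <- function(x, y, mx, my, sx, sy, rho) {
  z <- (x - mx)^2 / sx^2 - 2 * rho * (x - mx) * (y - my) / (sx * sy) +
    (y - my)^2 / sy^2
  exp(-z / (2 * (1 - rho^2))) / (2 * pi * sx * sy * sqrt(1 - rho^2))
}

# KGML fixture written as literal XML text (independent of write_kgml).
write_raw_kgml <- function(path, body,
                           header = '<pathway name="path:test01" title="Test pathway">') {
  writeLines(c('<?xml version="1.0"?>', header, body, "</pathway>"), path)
}

entry_path_key <- function(entry_path) paste(entry_path, collapse = ">")

# Shared heavy objects, computed once per test session.
.oracle_cache <- new.env(parent = emptyenv())

shared_path_length_dist <- function() {
  if (is.null(.oracle_cache$dist)) {
    .oracle_cache$dist <- path_length_distribution(1000, 200, 100, seed = 20260921)
  }
  .oracle_cache$dist
}

# In-memory analysis of one planted-chain fixture seed: returns the rank of
# the planted chain by S and its empirical permutation p-value.
run_planted_seed <- function(seed, dist, n_perm = 1e4) {
  spec <- fixture_spec(
    n_case = 10, n_control = 10,
    planted_chains = list(planted_chain(5, shift = 2, noise_sd = 0.3)),
    seed = seed)
  pw <- generate_pathways(spec)
  ex <- generate_expression(spec, pw)
  em <- collapse_probes(ex$expr, ex$probe_map)
  gs <- compute_gene_stats(em)
  sp <- decompose_pathways(pw)
  wd <- extract_well_defined(sp, gs)
  model <- fit_edge_model(pw, gs)
  sc <- score_subpathways(wd, gs, model, dist)
  set.seed(seed + 500L)
  res <- permutation_test(sc, sp, em, model, dist, n_perm = n_perm)
  is_planted <- vapply(res$genes, function(g) all(startsWith(g, "PLT")),
                       logical(1))
  list(found = any(is_planted),
       rank = if (any(is_planted)) rank(-res$S, ties.method = "min")[is_planted][1] else NA,
       pval = if (any(is_planted)) res$pval[is_planted][1] else NA)
}

# Null fixture (no group effect): p-values of all well-defined chains.
run_null_calibration <- function(seed, n_pathways = 200, n_perm = 1000) {
  spec <- fixture_spec(
    n_pathways = n_pathways, shape = "chain", chain_length_range = c(3, 6),
    n_case = 10, n_control = 10, probes_per_gene = 1, seed = seed)
  pw <- generate_pathways(spec)
  ex <- generate_expression(spec, pw)
  gs <- compute_gene_stats(ex$gene_expr)
  sp <- decompose_pathways(pw)
  wd <- extract_well_defined(sp, gs)
  model <- fit_edge_model(pw, gs)
  dist <- shared_path_length_dist()
  sc <- score_subpathways(wd, gs, model, dist)
  set.seed(seed + 900L)
  res <- permutation_test(sc, sp, ex$gene_expr, model, dist, n_perm = n_perm)
  res$pval
}
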