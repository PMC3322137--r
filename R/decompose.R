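#' Roots and leaves of a pathway graph
#'
#' Roots are entries with in-degree 0 (typically membrane receptors and
#' ligands), leaves entries with out-degree 0 (typically transcription
#' factors). Computed on the cleaned graph; a graph with no roots or no
#' leaves (e.g. a pure cycle) simply yields empty sets.
#'
#' @param graph A [pathway_graph()].
#' @return List with character vectors `roots` and `leaves`.
#' @export
find_roots_and_leaves <- function(graph) {
  ids <- graph$entries$entry_id
  has_in <- ids %in% graph$edges$sink
  has_out <- ids %in% graph$edges$source
  # isolated entries (no edges at all) are not usable path endpoints
  connected <- has_in | has_out
  list(roots = ids[connected & !has_in],
       leaves = ids[connected & !has_out])
}

#' Enumerate linear root-to-leaf subpathways at the entry level
#'
#' Yields every simple directed path from an in-degree-0 root to an
#' out-degree-0 leaf, exactly once, with its edge-sign sequence. Paths are
#' simple (no repeated entry), so cyclic regions contribute only what is
#' reachable without revisiting a node. When a pair of entries is connected
#' by both an activation and a repression edge, one entry path is emitted
#' per sign combination. Enumeration order is deterministic (paths sorted by
#' their entry/sign key).
#'
#' @param graph A [pathway_graph()].
#' @param max_paths Cap on the number of emitted paths; if hit, enumeration
#'   stops and the result carries attribute `truncated = TRUE`.
#' @param strict If `TRUE`, hitting the cap is an error.
#'
#' @return Tibble with columns `pathway_id`, `entry_path` (list of character
#'   vectors, root first) and `edge_signs` (list of integer vectors,
#'   `edge_signs[[i]][j]` signing the edge `entry_path[[i]][j] ->
#'   entry_path[[i]][j + 1]`).
#' @export
enumerate_linear_subpathways <- function(graph, max_paths = 1e6,
                                         strict = FALSE) {
  rl <- find_roots_and_leaves(graph)
  empty <- tibble::tibble(pathway_id = character(),
                          entry_path = list(), edge_signs = list())
  if (length(rl$roots) == 0 || length(rl$leaves) == 0) {
    attr(empty, "truncated") <- FALSE
    return(empty)
  }
  ig <- as_igraph(graph)
  # sign sets per ordered entry pair (parallel opposite-sign edges possible)
  key <- paste(graph$edges$source, graph$edges$sink, sep = "\r")
  sign_sets <- split(graph$edges$sign, key)

  paths <- list()
  truncated <- FALSE
  for (r in sort(rl$roots)) {
    vp <- igraph::all_simple_paths(ig, from = r,
                                   to = sort(rl$leaves), mode = "out")
    for (p in vp) {
      nodes <- igraph::V(ig)$name[as.integer(p)]
      if (length(nodes) < 2) next
      steps <- paste(nodes[-length(nodes)], nodes[-1], sep = "\r")
      combos <- expand.grid(sign_sets[steps], KEEP.OUT.ATTRS = FALSE)
      for (ci in seq_len(nrow(combos))) {
        if (length(paths) >= max_paths) {
          if (strict) abort(paste0("subpathway cap exceeded (max_paths = ",
                                   max_paths, ") in ", graph$pathway_id))
          truncated <- TRUE
          break
        }
        paths[[length(paths) + 1]] <-
          list(nodes = nodes, signs = as.integer(unlist(combos[ci, ])))
      }
      if (truncated) break
    }
    if (truncated) break
  }
  if (length(paths) == 0) {
    attr(empty, "truncated") <- truncated
    return(empty)
  }
  ord <- order(vapply(paths, function(p)
    paste(c(p$nodes, p$signs), collapse = "|"), character(1)))
  paths <- paths[ord]
  out <- tibble::tibble(
    pathway_id = graph$pathway_id,
    entry_path = purrr::map(paths, "nodes"),
    edge_signs = purrr::map(paths, "signs"))
  attr(out, "truncated") <- truncated
  out
}

#' Expand multi-gene entries into gene-level linear subpathways
#'
#' Every entry on a path may carry several gene identifiers; the path is
#' expanded into the Cartesian product of the per-entry gene sets, each
#' product element inheriting the entry path's edge signs. Gene chains are
#' stored root-first; the last element is the leaf.
#'
#' @param graph The [pathway_graph()] the paths came from.
#' @param entry_paths Tibble from [enumerate_linear_subpathways()].
#' @return Tibble with columns `pathway_id`, `genes` (list of character
#'   vectors, root first), `edge_signs` (list of integer vectors).
#' @export
expand_gene_assignments <- function(graph, entry_paths) {
  gene_sets <- setNames(graph$entries$genes, graph$entries$entry_id)
  res_genes <- list()
  res_signs <- list()
  for (i in seq_len(nrow(entry_paths))) {
    sets <- gene_sets[entry_paths$entry_path[[i]]]
    combos <- expand.grid(rev(sets), KEEP.OUT.ATTRS = FALSE,
                          stringsAsFactors = FALSE)
    combos <- combos[, rev(seq_along(sets)), drop = FALSE]
    for (ci in seq_len(nrow(combos))) {
      res_genes[[length(res_genes) + 1]] <- as.character(unlist(combos[ci, ]))
      res_signs[[length(res_signs) + 1]] <- entry_paths$edge_signs[[i]]
    }
  }
  tibble::tibble(
    pathway_id = rep(entry_paths$pathway_id,
                     times = vapply(entry_paths$entry_path, function(p)
                       prod(lengths(gene_sets[p])), numeric(1))),
    genes = res_genes,
    edge_signs = res_signs)
}

subpathway_key <- function(genes, edge_signs) {
  paste(paste(genes, collapse = ">"),
        paste(edge_signs, collapse = ""), sep = "|")
}

#' Deduplicate gene-level subpathways
#'
#' Uniqueness key is the (gene sequence, edge-sign sequence) pair; the
#' pathway provenance of duplicates is merged into a list column so a chain
#' appearing in several pathways is scored once.
#'
#' @param subpaths Tibble from [expand_gene_assignments()] (or a
#'   concatenation over pathways).
#' @return Tibble with columns `genes`, `edge_signs`, `pathways` (list of
#'   character vectors) and `key`.
#' @export
deduplicate_subpathways <- function(subpaths) {
  if (nrow(subpaths) == 0) {
    return(tibble::tibble(genes = list(), edge_signs = list(),
                          pathways = list(), key = character()))
  }
  key <- purrr::map2_chr(subpaths$genes, subpaths$edge_signs, subpathway_key)
  first <- !duplicated(key)
  prov <- lapply(split(subpaths$pathway_id, key), function(p) sort(unique(p)))
  out <- tibble::tibble(
    genes = subpaths$genes[first],
    edge_signs = subpaths$edge_signs[first],
    key = key[first])
  out$pathways <- unname(prov[out$key])
  out[c("genes", "edge_signs", "pathways", "key")]
}

#' Decompose pathway graphs into unique linear subpathways
#'
#' Runs enumeration, gene-assignment expansion and deduplication over a list
#' of graphs. Per-pathway counts (entry paths, expanded chains) are attached
#' as attribute `"counts"`.
#'
#' @param graphs A `pathway_graph` or list of them.
#' @param max_paths Per-pathway cap passed to
#'   [enumerate_linear_subpathways()].
#' @return Deduplicated subpathway tibble (see
#'   [deduplicate_subpathways()]).
#' @export
decompose_pathways <- function(graphs, max_paths = 1e6) {
  if (inherits(graphs, "pathway_graph")) graphs <- list(graphs)
  pieces <- vector("list", length(graphs))
  counts <- vector("list", length(graphs))
  for (i in seq_along(graphs)) {
    ep <- enumerate_linear_subpathways(graphs[[i]], max_paths = max_paths)
    ex <- expand_gene_assignments(graphs[[i]], ep)
    pieces[[i]] <- ex
    counts[[i]] <- tibble::tibble(
      pathway_id = graphs[[i]]$pathway_id,
      n_entry_paths = nrow(ep),
      n_expanded = nrow(ex),
      truncated = isTRUE(attr(ep, "truncated")))
  }
  out <- deduplicate_subpathways(dplyr::bind_rows(pieces))
  attr(out, "counts") <- dplyr::bind_rows(counts)
  out
}
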