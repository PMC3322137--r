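chain_graph <- function(ids = c("A", "B", "C"), signs = NULL) {
  n <- length(ids)
  if (is.null(signs)) signs <- rep(1L, n - 1)
  pathway_graph(
    "chain", "chain",
    entries = tibble::tibble(entry_id = ids,
                             genes = as.list(paste0("g", ids))),
    edges = tibble::tibble(source = ids[-n], sink = ids[-1], sign = signs))
}

diamond_graph <- function() {
  pathway_graph(
    "diamond", "diamond",
    entries = tibble::tibble(entry_id = c("A", "B", "C", "D"),
                             genes = list("gA", "gB", "gC", "gD")),
    edges = tibble::tibble(source = c("A", "A", "B", "C"),
                           sink = c("B", "C", "D", "D"),
                           sign = c(1L, -1L, 1L, 1L)))
}

test_that("roots and leaves are the in-degree-0 / out-degree-0 entries", {
  rl <- find_roots_and_leaves(chain_graph())
  expect_equal(rl$roots, "A")
  expect_equal(rl$leaves, "C")

  rl <- find_roots_and_leaves(diamond_graph())
  expect_equal(rl$roots, "A")
  expect_equal(rl$leaves, "D")

  cyc <- pathway_graph(
    "cyc", "cycle",
    entries = tibble::tibble(entry_id = c("A", "B", "C"),
                             genes = list("gA", "gB", "gC")),
    edges = tibble::tibble(source = c("A", "B", "C"),
                           sink = c("B", "C", "A"), sign = rep(1L, 3)))
  rl <- find_roots_and_leaves(cyc)
  expect_length(rl$roots, 0)
  expect_length(rl$leaves, 0)
  expect_equal(nrow(enumerate_linear_subpathways(cyc)), 0)
})

test_that("chain and diamond enumerate their simple paths with signs", {
  ep <- enumerate_linear_subpathways(chain_graph(signs = c(1L, -1L)))
  expect_equal(nrow(ep), 1)
  expect_equal(ep$entry_path[[1]], c("A", "B", "C"))
  expect_equal(ep$edge_signs[[1]], c(1L, -1L))

  ep <- enumerate_linear_subpathways(diamond_graph())
  expect_equal(nrow(ep), 2)
  keys <- vapply(ep$entry_path, entry_path_key, character(1))
  expect_setequal(keys, c("A>B>D", "A>C>D"))
})

test_that("parallel opposite-sign edges yield one path per sign combination", {
  g <- pathway_graph(
    "par", "parallel",
    entries = tibble::tibble(entry_id = c("A", "B"), genes = list("gA", "gB")),
    edges = tibble::tibble(source = c("A", "A"), sink = c("B", "B"),
                           sign = c(1L, -1L)))
  ep <- enumerate_linear_subpathways(g)
  expect_equal(nrow(ep), 2)
  expect_setequal(vapply(ep$edge_signs, identity, integer(1)), c(1L, -1L))
})

test_that("enumeration agrees with the DFS oracle on random DAGs", {
  set.seed(101)
  for (rep in 1:30) {
    g <- random_dag_graph(sample(4:12, 1), p_edge = 0.3)
    ep <- enumerate_linear_subpathways(g)
    keys <- vapply(ep$entry_path, entry_path_key, character(1))
    expect_setequal(keys, oracle_simple_paths(g))
    expect_equal(nrow(ep), oracle_dag_path_count(g))
    # type invariants
    expect_true(all(lengths(ep$edge_signs) == lengths(ep$entry_path) - 1))
    expect_true(all(vapply(ep$entry_path, anyDuplicated, 0) == 0))
  }
})

test_that("the path cap truncates or errors under strict mode", {
  ep <- enumerate_linear_subpathways(diamond_graph(), max_paths = 1)
  expect_equal(nrow(ep), 1)
  expect_true(attr(ep, "truncated"))
  expect_error(
    enumerate_linear_subpathways(diamond_graph(), max_paths = 1,
                                 strict = TRUE),
    "cap")
})

test_that("gene-assignment expansion is the Cartesian product of gene sets", {
  g <- pathway_graph(
    "mg", "multigene",
    entries = tibble::tibble(entry_id = c("A", "B", "C"),
                             genes = list("a", c("b1", "b2"), "c")),
    edges = tibble::tibble(source = c("A", "B"), sink = c("B", "C"),
                           sign = c(1L, 1L)))
  ep <- enumerate_linear_subpathways(g)
  ex <- expand_gene_assignments(g, ep)
  expect_equal(nrow(ex), 2)
  expect_setequal(vapply(ex$genes, paste, character(1), collapse = ","),
                  c("a,b1,c", "a,b2,c"))
  expect_true(all(vapply(ex$edge_signs, identical, logical(1), c(1L, 1L))))

  g2 <- pathway_graph(
    "mg2", "multigene2",
    entries = tibble::tibble(
      entry_id = c("A", "B", "C"),
      genes = list(c("a1", "a2", "a3"), c("b1", "b2"), c("c1", "c2"))),
    edges = tibble::tibble(source = c("A", "B"), sink = c("B", "C"),
                           sign = c(1L, -1L)))
  ex2 <- expand_gene_assignments(g2, enumerate_linear_subpathways(g2))
  expect_equal(nrow(ex2), 3 * 2 * 2)
  expect_equal(anyDuplicated(vapply(ex2$genes, paste, character(1),
                                    collapse = ",")), 0)

  # all single-gene: expansion is the identity
  ex3 <- expand_gene_assignments(diamond_graph(),
                                 enumerate_linear_subpathways(diamond_graph()))
  expect_equal(nrow(ex3), 2)
})

test_that("expanded counts equal the sum of per-path gene-set products", {
  set.seed(77)
  for (rep in 1:10) {
    g <- random_dag_graph(sample(5:9, 1), p_edge = 0.35)
    # give some entries 2 genes
    multi <- sample(nrow(g$entries), 2)
    g$entries$genes[multi] <- lapply(g$entries$entry_id[multi],
                                     function(id) paste0("g_", id, c("x", "y")))
    ep <- enumerate_linear_subpathways(g)
    ex <- expand_gene_assignments(g, ep)
    sets <- setNames(g$entries$genes, g$entries$entry_id)
    expected <- sum(vapply(ep$entry_path,
                           function(p) prod(lengths(sets[p])), numeric(1)))
    expect_equal(nrow(ex), expected)
  }
})

test_that("deduplication merges provenance and keeps sign variants apart", {
  sp <- tibble::tibble(
    pathway_id = c("p1", "p2", "p1"),
    genes = list(c("a", "b"), c("a", "b"), c("a", "b")),
    edge_signs = list(1L, 1L, -1L))
  dd <- deduplicate_subpathways(sp)
  expect_equal(nrow(dd), 2)
  prov <- dd$pathways[[which(vapply(dd$edge_signs, identical, logical(1), 1L))]]
  expect_equal(prov, c("p1", "p2"))

  empty <- deduplicate_subpathways(sp[0, ])
  expect_equal(nrow(empty), 0)
})
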