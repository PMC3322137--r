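# Signs below are written leaf-first (b1 is the leaf) and converted to the
# root-first storage order at the call.
suffix_n <- function(b_leaf_first, e_leaf_first) {
  p <- length(b_leaf_first)
  res <- well_defined_suffix(genes = paste0("g", rev(seq_len(p))),
                             edge_signs = rev(e_leaf_first),
                             b = rev(b_leaf_first))
  if (is.null(res)) 0L else res$n
}

test_that("well-defined suffix stops at the first rule violation", {
  expect_equal(suffix_n(c(1, 1, 1), c(1, 1)), 3)        # whole path
  expect_equal(suffix_n(c(1, 1, -1), c(1, 1)), 2)       # second edge fails
  expect_equal(suffix_n(c(1, -1, 1), c(1, 1)), 0)       # first edge fails
  expect_equal(suffix_n(c(1, -1, -1), c(-1, 1)), 3)     # repression chain
  # consistent edge after a violation must not resurrect the segment
  expect_equal(suffix_n(c(1, 1, -1, -1), c(1, 1, 1)), 2)

  res <- well_defined_suffix(c("r", "m", "l"), c(1L, 1L), c(1L, 1L, 1L))
  expect_equal(res$genes, c("l", "m", "r"))  # leaf first
})

test_that("every returned segment satisfies the consistency rule", {
  set.seed(44)
  for (rep in 1:200) {
    p <- sample(2:7, 1)
    b <- sample(c(1L, -1L), p, replace = TRUE)
    e <- sample(c(1L, -1L), p - 1, replace = TRUE)
    res <- well_defined_suffix(paste0("g", seq_len(p)), e, b)
    if (!is.null(res)) {
      bl <- rev(b); el <- rev(e)
      n <- res$n
      expect_true(all(el[seq_len(n - 1)] * bl[seq_len(n - 1)] *
                        bl[seq_len(n - 1) + 1] == 1))
      # maximality: the next edge (if any) violates
      if (n < p) expect_false(el[n] * bl[n] * bl[n + 1] == 1)
    }
  }
})

make_pair_model <- function(n = 5000, rho = 0.5, seed = 99) {
  set.seed(seed)
  z1 <- rnorm(n); z2 <- rnorm(n)
  src <- 0.1 + 0.6 * z1
  snk <- -0.2 + 0.8 * (rho * z1 + sqrt(1 - rho^2) * z2)
  genes_src <- sprintf("s%05d", seq_len(n))
  genes_snk <- sprintf("k%05d", seq_len(n))
  g <- pathway_graph(
    "pairs", "pair fixture",
    entries = tibble::tibble(
      entry_id = c(genes_src, genes_snk),
      genes = as.list(c(genes_src, genes_snk))),
    edges = tibble::tibble(source = genes_src, sink = genes_snk,
                           sign = rep(1L, n)))
  gs <- tibble::tibble(gene = c(genes_src, genes_snk),
                       log2_fc = c(src, snk))
  list(graph = g, gene_stats = gs,
       truth = list(mx = 0.1, my = -0.2, sx = 0.6, sy = 0.8, rho = rho))
}

test_that("edge model recovers the generating bivariate normal", {
  fx <- make_pair_model(n = 10000, rho = 0.5)
  m <- fit_edge_model(fx$graph, fx$gene_stats)
  expect_equal(m$rho, fx$truth$rho, tolerance = 0.03)
  expect_equal(m$mu_src, fx$truth$mx, tolerance = 0.05)
  expect_equal(m$sd_snk, fx$truth$sy, tolerance = 0.05)
  expect_equal(m$n_pairs, 10000)
  # prior over all genes: centred near the pooled mean of both margins
  expect_equal(m$prior_mean, mean(fx$gene_stats$log2_fc), tolerance = 1e-12)
})

test_that("degenerate edge fits are rejected", {
  n <- 50
  genes <- sprintf("g%03d", seq_len(n + 1))
  g <- pathway_graph(
    "deg", "degenerate",
    entries = tibble::tibble(entry_id = genes, genes = as.list(genes)),
    edges = tibble::tibble(source = genes[-(n + 1)], sink = genes[-1],
                           sign = rep(1L, n)))
  set.seed(3)
  gs <- tibble::tibble(gene = genes, log2_fc = rnorm(n + 1))
  # chain edges: source and sink values share genes -> fine
  expect_s3_class(fit_edge_model(g, gs), "edge_model")
  # |rho| = 1 when every source equals its sink
  gs_same <- tibble::tibble(gene = genes, log2_fc = seq_len(n + 1) / 10)
  expect_error(fit_edge_model(g, gs_same), "correlation")
  expect_error(fit_edge_model(g, gs[1:5, ], min_pairs = 30), "30")
})

test_that("conditional density matches the joint/marginal ratio and limits", {
  fx <- make_pair_model(n = 4000, rho = 0.35, seed = 17)
  m <- fit_edge_model(fx$graph, fx$gene_stats)
  set.seed(18)
  xs <- rnorm(100, m$mu_src, 2 * m$sd_src)
  ys <- rnorm(100, m$mu_snk, 2 * m$sd_snk)
  cond <- conditional_density(ys, xs, m)
  ratio <- oracle_bvn_density(xs, ys, m$mu_src, m$mu_snk,
                              m$sd_src, m$sd_snk, m$rho) /
    dnorm(xs, m$mu_src, m$sd_src)
  expect_lt(max(abs(cond - ratio) / ratio), 1e-10)

  # at the conditional mean the density is the closed-form mode height
  mu_c <- m$mu_snk + m$rho * m$sd_snk / m$sd_src * (xs[1] - m$mu_src)
  expect_equal(conditional_density(mu_c, xs[1], m),
               1 / (m$sd_snk * sqrt(2 * pi * (1 - m$rho^2))))

  # rho = 0: conditional reduces to the sink marginal
  m0 <- m; m0$rho <- 0
  expect_equal(conditional_density(ys, xs, m0),
               dnorm(ys, m0$mu_snk, m0$sd_snk))
})

test_that("F_edge is the prior times the telescoping conditional chain", {
  fx <- make_pair_model(n = 4000, rho = 0.4, seed = 23)
  m <- fit_edge_model(fx$graph, fx$gene_stats)
  l2f <- c(0.3, -0.5)   # leaf first: G1, G2
  expect_equal(f_edge(l2f, m),
               prior_density(l2f[2], m) *
                 conditional_density(l2f[1], l2f[2], m))
  # 4-node chain: product of joint/marginal ratios telescopes
  l2f4 <- c(0.2, -0.1, 0.7, 0.05)
  joint_chain <- prior_density(l2f4[4], m)
  for (i in 3:1) {
    joint_chain <- joint_chain *
      oracle_bvn_density(l2f4[i + 1], l2f4[i], m$mu_src, m$mu_snk,
                         m$sd_src, m$sd_snk, m$rho) /
      dnorm(l2f4[i + 1], m$mu_src, m$sd_src)
  }
  expect_equal(f_edge(l2f4, m), joint_chain, tolerance = 1e-12)
})

test_that("F_node is the product of segment p-values and is monotone", {
  expect_equal(f_node(c(1, 1, 1)), 1)
  expect_equal(f_node(c(0.1, 0.01)), 1e-3)
  expect_warning(v <- f_node(c(0.5, 0)), "machine minimum")
  expect_gt(v, 0)
  set.seed(9)
  p <- runif(5)
  for (i in seq_along(p)) {
    p2 <- p; p2[i] <- p[i] / 2
    expect_lt(f_node(p2), f_node(p))
  }
})

test_that("F_num looks up the pmf with an epsilon floor", {
  d <- path_length_distribution(50, 40, 25, seed = 2)
  expect_equal(sum(d$pmf$prob), 1)
  expect_true(all(d$pmf$prob >= 0))
  k_obs <- d$pmf$k[1]
  expect_equal(f_num(k_obs + 1, d), max(d$pmf$prob[1], d$eps))
  expect_equal(f_num(max(d$pmf$k) + 5, d), d$eps)
  d2 <- path_length_distribution(50, 40, 25, seed = 2)
  expect_identical(d$pmf, d2$pmf)
})

test_that("random-graph path lengths are mostly short at the 200/100 setting", {
  probs <- matrix(0, 5, 6)
  for (s in 1:5) {
    d <- path_length_distribution(60, 200, 100, seed = 300 + s)
    probs[s, ] <- f_num(2:7, d)
  }
  avg <- colMeans(probs)
  expect_true(all(diff(avg) < 0))  # non-increasing beyond the 1-edge mode
})

test_that("S is the minus log product, computed stably in log space", {
  expect_equal(total_statistic(1, 1, 1), 0)
  expect_equal(total_statistic(exp(-1), exp(-2), exp(-3)), 6)
  expect_error(total_statistic(0, 1, 1), "positive")
  set.seed(13)
  for (rep in 1:100) {
    fs <- runif(3, 1e-6, 1)
    expect_equal(total_statistic(fs[1], fs[2], fs[3]),
                 -log(prod(fs)), tolerance = 1e-12)
  }
})

test_that("score_subpathways composes the factors and matches the fast engine", {
  spec <- fixture_spec(planted_chains = list(planted_chain(4)), seed = 19)
  pw <- generate_pathways(spec)
  ex <- generate_expression(spec, pw)
  gs <- compute_gene_stats(ex$gene_expr)
  sp <- decompose_pathways(pw)
  wd <- extract_well_defined(sp, gs)
  m <- fit_edge_model(pw, gs)
  d <- path_length_distribution(50, 40, 25, seed = 6)
  sc <- score_subpathways(wd, gs, m, d)

  expect_true(all(is.finite(sc$S)))
  expect_equal(sc$S, -(log(sc$f_node) + log(sc$f_edge) + log(sc$f_num)),
               tolerance = 1e-8)
  # per-row recomputation from the exported factor functions
  pv <- setNames(gs$pval, gs$gene)
  l2f <- setNames(gs$log2_fc, gs$gene)
  for (i in seq_len(min(nrow(sc), 20))) {
    seg <- sc$segment[[i]]
    expect_equal(sc$S[i],
                 total_statistic(f_node(pv[seg]),
                                 f_edge(unname(l2f[seg]), m),
                                 f_num(sc$n[i], d)),
                 tolerance = 1e-10)
  }

  # vectorised permutation engine reproduces the observed scores
  cc <- subpathways:::compile_chains(sp, gs$gene)
  lfnum <- subpathways:::log_f_num_table(d, max(cc$lens))
  eng <- subpathways:::score_compiled(
    cc, gs$b, log(pmax(gs$pval, .Machine$double.xmin)),
    gs$log2_fc, m, lfnum)
  idx <- match(sc$key, sp$key)
  expect_equal(eng$n[idx], sc$n)
  expect_equal(eng$S[idx], sc$S, tolerance = 1e-10)
  # chains without a well-defined segment are NA in the engine
  expect_true(all(is.na(eng$S[setdiff(seq_len(nrow(sp)), idx)])))
})

test_that("scores are invariant under sample reordering within groups", {
  spec <- fixture_spec(n_pathways = 2, planted_chains = list(planted_chain(3)),
                       seed = 29)
  pw <- generate_pathways(spec)
  ex <- generate_expression(spec, pw)
  em <- ex$gene_expr
  perm <- c(sample(which(em$labels == "case")),
            sample(which(em$labels == "control")))
  em2 <- expr_matrix(em$values[, perm], em$labels[perm])
  gs1 <- compute_gene_stats(em)
  gs2 <- compute_gene_stats(em2)
  expect_equal(gs1, gs2)
})
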