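#' Specification for a synthetic test fixture
#'
#' Describes a self-contained synthetic study: toy signed pathways plus a
#' two-group log2 expression matrix with optional planted sign-coherent
#' chains. Defaults emulate the design of a small two-group microarray
#' comparison (12 case vs 10 control samples, log2 intensities around 8,
#' a couple of probes per gene) at a scale where the full pipeline with
#' 10^4 permutations runs in minutes on one CPU.
#'
#' @param n_pathways Number of toy pathways.
#' @param nodes_range Integer range of entries per pathway (`shape = "dag"`).
#' @param edges_per_node Edge density: target edge count is
#'   `edges_per_node * n_nodes`.
#' @param activation_fraction Probability an edge is an activation (+1).
#' @param multi_gene_fraction Fraction of entries carrying several genes.
#' @param gene_multiplicity Genes per multi-gene entry.
#' @param n_case,n_control Group sizes (>= 2 each).
#' @param baseline_mean,baseline_sd Per-gene baseline log2 mean is drawn
#'   from `N(baseline_mean, baseline_sd^2)`.
#' @param noise_sd Per-sample log2 noise s.d. for background genes.
#' @param planted_chains List of [planted_chain()] objects.
#' @param probes_per_gene Probes measured per gene.
#' @param probe_noise_sd Probe-level offset s.d. (small, so probe collapse
#'   is exercised without hiding signal).
#' @param shape `"dag"` for random DAG pathways, `"chain"` for pure linear
#'   chains (one subpathway per pathway; useful for calibration studies).
#' @param chain_length_range Node-count range for `shape = "chain"`.
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_pathways = 5, nodes_range = c(20, 30),
                         edges_per_node = 1.3, activation_fraction = 0.7,
                         multi_gene_fraction = 0.2, gene_multiplicity = 2,
                         n_case = 12, n_control = 10,
                         baseline_mean = 8, baseline_sd = 1,
                         noise_sd = 0.3,
                         planted_chains = list(),
                         probes_per_gene = 2, probe_noise_sd = 0.1,
                         shape = c("dag", "chain"),
                         chain_length_range = c(3, 6),
                         seed = 1L) {
  shape <- match.arg(shape)
  stopifnot(n_pathways >= 1, n_case >= 2, n_control >= 2,
            noise_sd > 0, probe_noise_sd > 0, probes_per_gene >= 1)
  structure(
    list(n_pathways = n_pathways, nodes_range = nodes_range,
         edges_per_node = edges_per_node,
         activation_fraction = activation_fraction,
         multi_gene_fraction = multi_gene_fraction,
         gene_multiplicity = gene_multiplicity,
         n_case = n_case, n_control = n_control,
         baseline_mean = baseline_mean, baseline_sd = baseline_sd,
         noise_sd = noise_sd, planted_chains = planted_chains,
         probes_per_gene = probes_per_gene, probe_noise_sd = probe_noise_sd,
         shape = shape, chain_length_range = chain_length_range,
         seed = as.integer(seed)),
    class = "fixture_spec")
}

#' Construct a sign-coherent planted chain
#'
#' Builds a gene chain whose expression signs satisfy the consistency rule
#' `e_i * b_i * b_(i+1) = 1` on every edge by construction: starting from
#' the root sign `b_root`, each downstream sign is `b_sink = e * b_source`.
#' In the expression fixture each chain gene's case group is shifted by
#' `b * shift` log2 units.
#'
#' @param length Number of genes (>= 2).
#' @param shift Per-gene log2 shift magnitude in the case group.
#' @param noise_sd Per-sample noise s.d. for the chain genes.
#' @param edge_signs Root-first edge signs (+1/-1); default alternating
#'   activation/repression.
#' @param b_root Sign of the root gene (+1/-1).
#' @param prefix Gene-name prefix.
#' @return List with `genes` (root first), `edge_signs`, `b`, `shift`,
#'   `noise_sd`; class `planted_chain`.
#' @export
planted_chain <- function(length = 5, shift = 2, noise_sd = 0.3,
                          edge_signs = NULL, b_root = 1L,
                          prefix = "PLT") {
  stopifnot(length >= 2)
  if (is.null(edge_signs)) {
    edge_signs <- rep_len(c(1L, -1L), length - 1)
  }
  stopifnot(length(edge_signs) == length - 1,
            all(edge_signs %in% c(1L, -1L)), b_root %in% c(1L, -1L))
  b <- integer(length)
  b[1] <- b_root
  for (i in seq_len(length - 1)) b[i + 1] <- edge_signs[i] * b[i]
  structure(
    list(genes = sprintf("%s%02d", prefix, seq_len(length)),
         edge_signs = as.integer(edge_signs), b = b,
         shift = shift, noise_sd = noise_sd),
    class = "planted_chain")
}

#' Generate toy signed pathways from a fixture spec
#'
#' `shape = "dag"` pathways are random DAGs (edges only go forward in a
#' random node order, so enumeration always terminates); `shape = "chain"`
#' pathways are single linear chains. Planted chains are embedded as fresh
#' root-to-leaf linear components of the pathways, assigned round-robin, so
#' each one is guaranteed to be enumerated as a subpathway. Deterministic
#' given `spec$seed`.
#'
#' @param spec A [fixture_spec()].
#' @return List of [pathway_graph()] objects.
#' @export
generate_pathways <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  graphs <- vector("list", spec$n_pathways)
  for (p in seq_len(spec$n_pathways)) {
    pid <- sprintf("toy%02d", p)
    if (spec$shape == "chain") {
      n <- sample(spec$chain_length_range[1]:spec$chain_length_range[2], 1)
      genes <- sprintf("P%02dG%03d", p, seq_len(n))
      entries <- tibble::tibble(entry_id = as.character(seq_len(n)),
                                genes = as.list(genes))
      sgn <- ifelse(stats::runif(n - 1) < spec$activation_fraction, 1L, -1L)
      edges <- tibble::tibble(source = as.character(seq_len(n - 1)),
                              sink = as.character(seq_len(n - 1) + 1L),
                              sign = sgn)
    } else {
      n <- sample(spec$nodes_range[1]:spec$nodes_range[2], 1)
      gene_counter <- 0L
      gene_sets <- vector("list", n)
      for (i in seq_len(n)) {
        k <- if (stats::runif(1) < spec$multi_gene_fraction)
          spec$gene_multiplicity else 1L
        gene_sets[[i]] <- sprintf("P%02dG%03d", p,
                                  gene_counter + seq_len(k))
        gene_counter <- gene_counter + k
      }
      entries <- tibble::tibble(entry_id = as.character(seq_len(n)),
                                genes = gene_sets)
      all_pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
      m <- min(nrow(all_pairs), round(spec$edges_per_node * n))
      pick <- all_pairs[sample.int(nrow(all_pairs), m), , drop = FALSE]
      sgn <- ifelse(stats::runif(m) < spec$activation_fraction, 1L, -1L)
      edges <- tibble::tibble(source = as.character(pick[, 1]),
                              sink = as.character(pick[, 2]),
                              sign = sgn)
    }
    # embed planted chains assigned to this pathway as fresh linear parts
    for (ci in seq_along(spec$planted_chains)) {
      if ((ci - 1) %% spec$n_pathways + 1 != p) next
      ch <- spec$planted_chains[[ci]]
      if (length(ch$genes) > max(spec$nodes_range, spec$chain_length_range)
          && spec$shape == "chain") {
        abort("planted chain longer than the pathway allows")
      }
      ids <- paste0("plt", ci, "_", seq_along(ch$genes))
      entries <- dplyr::bind_rows(
        entries,
        tibble::tibble(entry_id = ids, genes = as.list(ch$genes)))
      edges <- dplyr::bind_rows(
        edges,
        tibble::tibble(source = ids[-length(ids)], sink = ids[-1],
                       sign = ch$edge_signs))
    }
    graphs[[p]] <- validate_graph(
      pathway_graph(pid, sprintf("Toy pathway %02d", p), entries, edges))
  }
  graphs
}

#' Generate a two-group expression fixture for toy pathways
#'
#' Each gene's baseline log2 mean is drawn once, then per-sample values are
#' normal around it. Planted-chain genes additionally receive a
#' `b * shift` log2 shift in the case group, so their group-median signs
#' match the chain's planted signs (up to sampling noise). Probe-level rows
#' are the gene value plus small probe offsets. Deterministic given
#' `spec$seed` (an offset of the pathway seed, so topology and expression
#' draws do not interact).
#'
#' @param spec A [fixture_spec()].
#' @param pathways Output of [generate_pathways()] on the same spec.
#' @return List with `expr` (probe-level [expr_matrix()]), `probe_map`
#'   (tibble `probe`, `gene`), `gene_expr` (gene-level [expr_matrix()]) and
#'   `planted_genes`.
#' @export
generate_expression <- function(spec, pathways) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed + 1000L)
  genes <- unique(unlist(lapply(pathways, function(g) unlist(g$entries$genes))))
  n_s <- spec$n_case + spec$n_control
  samples <- c(sprintf("case%02d", seq_len(spec$n_case)),
               sprintf("ctrl%02d", seq_len(spec$n_control)))
  labels <- setNames(rep(c("case", "control"),
                         c(spec$n_case, spec$n_control)), samples)

  mu <- stats::rnorm(length(genes), spec$baseline_mean, spec$baseline_sd)
  sd_g <- rep(spec$noise_sd, length(genes))
  shift_g <- rep(0, length(genes))
  names(mu) <- names(sd_g) <- names(shift_g) <- genes
  planted_genes <- character(0)
  for (ch in spec$planted_chains) {
    ok <- ch$genes %in% genes
    sd_g[ch$genes[ok]] <- ch$noise_sd
    shift_g[ch$genes[ok]] <- ch$b[ok] * ch$shift
    planted_genes <- c(planted_genes, ch$genes[ok])
  }
  vals <- matrix(stats::rnorm(length(genes) * n_s, mean = mu, sd = sd_g),
                 nrow = length(genes), ncol = n_s,
                 dimnames = list(genes, samples))
  case_cols <- which(labels == "case")
  vals[, case_cols] <- vals[, case_cols] + shift_g
  gene_em <- expr_matrix(vals, labels)

  k <- spec$probes_per_gene
  probe <- sprintf("%s_p%d", rep(genes, each = k), rep(seq_len(k), length(genes)))
  pvals <- vals[rep(seq_along(genes), each = k), , drop = FALSE] +
    stats::rnorm(length(probe) * n_s, 0, spec$probe_noise_sd)
  rownames(pvals) <- probe
  list(expr = expr_matrix(pvals, labels),
       probe_map = tibble::tibble(probe = probe,
                                  gene = rep(genes, each = k)),
       gene_expr = gene_em,
       planted_genes = unique(planted_genes))
}

#' Write a complete fixture bundle to disk
#'
#' Emits exactly the file formats the pipeline consumes: one KGML file per
#' pathway, `matrix.tsv` (probe-level), `labels.tsv`, `probe_map.tsv`, and
#' the spec echoed as `spec.json`.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_fixture_bundle <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pathways <- generate_pathways(spec)
  ex <- generate_expression(spec, pathways)
  kgml <- character(length(pathways))
  for (i in seq_along(pathways)) {
    kgml[i] <- file.path(dir, paste0(pathways[[i]]$pathway_id, ".xml"))
    write_kgml(pathways[[i]], kgml[i])
  }
  matrix_path <- file.path(dir, "matrix.tsv")
  m <- ex$expr$values
  readr::write_tsv(
    dplyr::bind_cols(tibble::tibble(feature = rownames(m)),
                     tibble::as_tibble(m)),
    matrix_path)
  labels_path <- file.path(dir, "labels.tsv")
  readr::write_tsv(tibble::tibble(sample = names(ex$expr$labels),
                                  group = unname(ex$expr$labels)),
                   labels_path)
  map_path <- file.path(dir, "probe_map.tsv")
  readr::write_tsv(ex$probe_map, map_path)
  spec_path <- file.path(dir, "spec.json")
  jsonlite::write_json(unclass(spec), spec_path, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(list(kgml = kgml, matrix = matrix_path, labels = labels_path,
                 probe_map = map_path, spec = spec_path))
}
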