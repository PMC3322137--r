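#' Default pipeline configuration
#'
#' Returns the full option list understood by [run_pipeline()]; any subset
#' can be overridden via a named list or a YAML file. Paths: `pathways`
#' (KGML files or a directory), `matrix`, `labels`, `probe_map` (optional),
#' `output_dir` (optional). Method options: `var_equal`, `n_perm`,
#' `null_mode`, `add_one`, `max_paths`, `min_pairs`, `sign_map` overrides,
#' and the random-graph parameters `rg_graphs`/`rg_nodes`/`rg_edges` for
#' F_num. Seeds: `seed` (permutations), `rg_seed` (random graphs).
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    pathways = NULL, matrix = NULL, labels = NULL, probe_map = NULL,
    output_dir = NULL,
    sign_map = NULL,
    var_equal = TRUE,
    collapse = "median",
    n_perm = 1e4,
    null_mode = "pooled",
    add_one = TRUE,
    max_paths = 1e6,
    min_pairs = 30,
    rg_graphs = 1000, rg_nodes = 200, rg_edges = 100,
    seed = 1L, rg_seed = 1L
  )
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  cfg <- utils::modifyList(default_config(), config)
  for (req in c("pathways", "matrix", "labels")) {
    if (is.null(cfg[[req]])) abort(paste0("config is missing '", req, "'"))
  }
  cfg
}

resolve_kgml_paths <- function(pathways) {
  if (length(pathways) == 1 && dir.exists(pathways)) {
    pathways <- sort(list.files(pathways, pattern = "\\.(xml|kgml)$",
                                full.names = TRUE))
  }
  missing <- pathways[!file.exists(pathways)]
  if (length(missing)) {
    abort(paste0("pathway file(s) not found: ",
                 paste(missing, collapse = ", ")))
  }
  if (length(pathways) == 0) abort("no KGML files found")
  pathways
}

#' Format a well-defined subpathway as a signalling-flow string
#'
#' Upstream end first, `->` for activation and `-|` for repression, with
#' each gene's fold change in parentheses, e.g.
#' `"GRB2(1.613)->SOS1(1.624)-|PTEN(0.599)"`.
#'
#' @param segment Leaf-first gene vector (`G_1 ... G_n`).
#' @param edge_signs Root-first edge signs of the parent chain.
#' @param f Named vector of per-gene fold changes.
#' @return Single string.
#' @export
format_chain <- function(segment, edge_signs, f) {
  n <- length(segment)
  up_first <- rev(segment)                   # G_n ... G_1
  el <- rev(edge_signs)[seq_len(n - 1)]      # e_1 ... e_(n-1) (leaf-first)
  arrows <- ifelse(rev(el) == 1L, "->", "-|")
  parts <- sprintf("%s(%.3f)", up_first, f[up_first])
  paste0(paste0(parts[-n], arrows, collapse = ""), parts[n])
}

#' Run the full subpathway analysis pipeline
#'
#' Parse KGML -> decompose into unique linear subpathways -> per-gene
#' statistics -> well-defined segment extraction -> scoring -> permutation
#' null -> FDR. When `config$output_dir` is set, writes `results.tsv`
#' (columns `No.`, `KEGG`, `Title`, `WellDefinedSubpathwayWithFoldChange`,
#' `NumNodes`, `P-value`, `S`, `FDR (q-value)`, `-log10(P-value)`),
#' `report.json` (stage counts, seeds, timings) and `model.json` (fitted
#' moments and path-length pmf).
#'
#' @param config Named list or path to a YAML file; see [default_config()].
#' @param dist Optional precomputed [path_length_distribution()] (otherwise
#'   simulated from the `rg_*` config entries under `rg_seed`).
#' @return An object of class `subpathway_run`: list with `results` (tibble
#'   of scored subpathways with p/q-values), `table` (the formatted results
#'   table), `report`, `null`, `model`, `dist`, `gene_stats`.
#' @export
run_pipeline <- function(config, dist = NULL) {
  cfg <- load_config(config)
  t0 <- Sys.time()
  report <- list(seed = cfg$seed, rg_seed = cfg$rg_seed,
                 n_perm = cfg$n_perm, null_mode = cfg$null_mode)

  sign_map <- default_sign_map()
  if (!is.null(cfg$sign_map)) {
    sm <- normalize_sign_map(cfg$sign_map)
    sign_map[names(sm)] <- sm
  }
  kgml_files <- resolve_kgml_paths(cfg$pathways)
  graphs <- lapply(kgml_files, parse_kgml, sign_map = sign_map)
  report$n_pathways <- length(graphs)

  subpaths <- decompose_pathways(graphs, max_paths = cfg$max_paths)
  counts <- attr(subpaths, "counts")
  report$n_entry_paths <- sum(counts$n_entry_paths)
  report$n_expanded <- sum(counts$n_expanded)
  report$n_unique_chains <- nrow(subpaths)
  if (nrow(subpaths) == 0) abort("decomposition produced no subpathways")

  em <- load_expression(cfg$matrix, cfg$labels)
  if (!is.null(cfg$probe_map)) {
    pm <- utils::read.delim(cfg$probe_map, sep = "\t", header = TRUE,
                            colClasses = "character")
    names(pm)[1:2] <- c("probe", "gene")
    em <- collapse_probes(em, pm, method = cfg$collapse)
  }
  report$n_features <- nrow(em$values)
  report$n_case <- sum(em$labels == "case")
  report$n_control <- sum(em$labels == "control")

  gene_stats <- compute_gene_stats(em, var_equal = cfg$var_equal)
  model <- fit_edge_model(graphs, gene_stats, min_pairs = cfg$min_pairs)
  if (is.null(dist)) {
    dist <- path_length_distribution(cfg$rg_graphs, cfg$rg_nodes,
                                     cfg$rg_edges, seed = cfg$rg_seed)
  }

  # keep only chains fully measured (the permutation engine needs b for
  # every gene); unmeasured chains are counted, matching extract_well_defined
  b <- setNames(gene_stats$b, gene_stats$gene)
  measured <- purrr::map_lgl(subpaths$genes, ~ all(.x %in% names(b)))
  report$n_unmeasured_chains <- sum(!measured)
  subpaths <- subpaths[measured, , drop = FALSE]
  if (nrow(subpaths) == 0) abort("no subpathway is fully measured")

  wd <- extract_well_defined(subpaths, gene_stats)
  report$n_well_defined <- nrow(wd)

  titles <- setNames(vapply(graphs, `[[`, character(1), "title"),
                     vapply(graphs, `[[`, character(1), "pathway_id"))

  if (nrow(wd) > 0) {
    scored <- score_subpathways(wd, gene_stats, model, dist)
    set.seed(cfg$seed)
    results <- permutation_test(scored, subpaths, em, model, dist,
                                n_perm = cfg$n_perm, mode = cfg$null_mode,
                                var_equal = cfg$var_equal,
                                add_one = cfg$add_one)
    null <- attr(results, "null")
    f <- setNames(gene_stats$f, gene_stats$gene)
    tbl <- tibble::tibble(
      `No.` = seq_len(nrow(results)),
      KEGG = purrr::map_chr(results$pathways, paste, collapse = ","),
      Title = purrr::map_chr(results$pathways,
                             ~ paste(titles[.x], collapse = ",")),
      WellDefinedSubpathwayWithFoldChange = purrr::pmap_chr(
        list(results$segment, results$edge_signs),
        function(seg, es) format_chain(seg, es, f)),
      NumNodes = results$n,
      `P-value` = results$pval,
      S = results$S,
      `FDR (q-value)` = results$qval,
      `-log10(P-value)` = results$neg_log10_p)
  } else {
    results <- wd
    null <- numeric(0)
    tbl <- tibble::tibble(
      `No.` = integer(), KEGG = character(), Title = character(),
      WellDefinedSubpathwayWithFoldChange = character(),
      NumNodes = integer(), `P-value` = numeric(), S = numeric(),
      `FDR (q-value)` = numeric(), `-log10(P-value)` = numeric())
  }
  report$n_significant_q05 <- sum(tbl$`FDR (q-value)` < 0.05)
  report$elapsed_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))

  run <- structure(
    list(results = results, table = tbl, report = report, null = null,
         model = model, dist = dist, gene_stats = gene_stats),
    class = "subpathway_run")

  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(tbl, file.path(cfg$output_dir, "results.tsv"))
    jsonlite::write_json(report, file.path(cfg$output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    write_model_json(model, dist, file.path(cfg$output_dir, "model.json"))
  }
  run
}

#' @export
print.subpathway_run <- function(x, ...) {
  r <- x$report
  cat("<subpathway_run>\n")
  cat(sprintf("  %d pathways -> %d unique chains -> %d well-defined (n_perm = %s)\n",
              r$n_pathways, r$n_unique_chains, r$n_well_defined,
              format(r$n_perm, big.mark = ",")))
  cat(sprintf("  %d subpathways with q < 0.05\n", r$n_significant_q05))
  invisible(x)
}

#' @export
tidy.subpathway_run <- function(x, ...) {
  if (nrow(x$results) == 0) return(tibble::as_tibble(x$results))
  tibble::tibble(
    pathways = purrr::map_chr(x$results$pathways, paste, collapse = ","),
    chain = purrr::map_chr(x$results$segment,
                           ~ paste(rev(.x), collapse = ">")),
    n = x$results$n,
    S = x$results$S,
    pval = x$results$pval,
    qval = x$results$qval)
}

#' @export
glance.subpathway_run <- function(x, ...) {
  tibble::as_tibble(x$report[c("n_pathways", "n_unique_chains",
                               "n_well_defined", "n_perm",
                               "n_significant_q05")])
}

#' @export
autoplot.subpathway_run <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = -log10(.data$pval), y = .data$S,
                                  colour = .data$qval < 0.05)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey40"),
                                 name = "q < 0.05") +
    ggplot2::labs(x = expression(-log[10](p)), y = "S",
                  title = "Well-defined subpathway statistics") +
    ggplot2::theme_minimal()
}

#' Null-distribution diagnostic plot
#'
#' Histogram of the permutation null of S with observed values overlaid.
#'
#' @param run A [run_pipeline()] result.
#' @return A ggplot object.
#' @export
plot_null_distribution <- function(run) {
  stopifnot(inherits(run, "subpathway_run"))
  nd <- tibble::tibble(S = as.numeric(run$null))
  ggplot2::ggplot(nd, ggplot2::aes(x = .data$S)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey70") +
    ggplot2::geom_vline(xintercept = run$results$S, colour = "firebrick",
                        alpha = 0.5, linewidth = 0.3) +
    ggplot2::labs(x = "S (permutation null)", y = "count",
                  title = "Permutation null of S with observed values") +
    ggplot2::theme_minimal()
}
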