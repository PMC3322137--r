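#' Signed pathway graph
#'
#' A `pathway_graph` holds the gene-level topology of one pathway: entries
#' (nodes, each carrying one or more gene identifiers) and signed regulatory
#' edges (+1 activation, -1 repression). It is the container produced by
#' [parse_kgml()] and consumed by the decomposition and scoring steps.
#'
#' @param pathway_id Accession-like identifier (e.g. `"hsa04510"`).
#' @param title Free-text pathway title.
#' @param entries Tibble with columns `entry_id` (character, unique) and
#'   `genes` (list of non-empty character vectors).
#' @param edges Tibble with columns `source`, `sink` (entry ids) and `sign`
#'   (integer, +1 or -1).
#'
#' @return An object of class `pathway_graph`.
#' @export
pathway_graph <- function(pathway_id, title = pathway_id,
                          entries = tibble::tibble(entry_id = character(),
                                                   genes = list()),
                          edges = tibble::tibble(source = character(),
                                                 sink = character(),
                                                 sign = integer())) {
  entries <- tibble::as_tibble(entries)
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("entry_id", "genes") %in% names(entries)),
            all(c("source", "sink", "sign") %in% names(edges)))
  if (anyDuplicated(entries$entry_id)) {
    abort("duplicate entry_id in pathway entries")
  }
  if (any(lengths(entries$genes) == 0)) {
    abort("every entry must carry at least one gene identifier")
  }
  edges$sign <- as.integer(edges$sign)
  if (nrow(edges) && !all(edges$sign %in% c(1L, -1L))) {
    abort("edge signs must be +1 or -1")
  }
  structure(
    list(pathway_id = pathway_id, title = title,
         entries = entries, edges = edges),
    class = "pathway_graph"
  )
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat("<pathway_graph> ", x$pathway_id, " - ", x$title, "\n", sep = "")
  cat("  entries: ", nrow(x$entries),
      " (", length(unique(unlist(x$entries$genes))), " genes)",
      "  edges: ", nrow(x$edges),
      " (+", sum(x$edges$sign == 1L), "/-", sum(x$edges$sign == -1L), ")\n",
      sep = "")
  invisible(x)
}

#' Default relation sign map
#'
#' Maps KGML relation subtype names to a regulation sign: `+1` (activation),
#' `-1` (repression) or `0` (drop). Only activation/repression semantics are
#' retained; effect-free subtypes (binding, dissociation, indirect effect,
#' state change, plain phosphorylation, ...) are dropped. Subtypes such as
#' phosphorylation that co-occur with an explicit activation or inhibition
#' subtype inherit that co-subtype's sign through the precedence rule in
#' [simplify_relation()].
#'
#' @return Named integer vector; values in `c(1L, -1L, 0L)`.
#' @export
default_sign_map <- function() {
  c(
    "activation"            = 1L,
    "expression"            = 1L,
    "inhibition"            = -1L,
    "repression"            = -1L,
    "phosphorylation"       = 0L,
    "dephosphorylation"     = 0L,
    "ubiquitination"        = 0L,
    "methylation"           = 0L,
    "glycosylation"         = 0L,
    "binding/association"   = 0L,
    "dissociation"          = 0L,
    "indirect effect"       = 0L,
    "state change"          = 0L,
    "compound"              = 0L,
    "hidden compound"       = 0L,
    "missing interaction"   = 0L
  )
}

normalize_sign_map <- function(sign_map) {
  if (is.list(sign_map)) sign_map <- unlist(sign_map)
  vals <- vapply(sign_map, function(v) {
    if (is.character(v)) {
      switch(v, "+1" = 1L, "1" = 1L, "-1" = -1L, "drop" = 0L, "0" = 0L,
             abort(paste0("invalid sign_map value: ", v)))
    } else {
      v <- as.integer(v)
      if (!v %in% c(1L, -1L, 0L)) abort("sign_map values must be +1, -1 or 0/drop")
      v
    }
  }, integer(1))
  setNames(vals, names(sign_map))
}

#' Simplify a relation's subtype list to a single sign
#'
#' KGML relations may carry several subtype annotations. They are reduced to
#' a single regulation sign with precedence explicit inhibition > explicit
#' activation > drop, so e.g. `phosphorylation + inhibition` maps to -1 and
#' a bare `binding/association` is dropped.
#'
#' @param subtype_names Character vector of subtype names (non-empty).
#' @param sign_map Named vector mapping subtype name to `+1`, `-1` or
#'   `0`/`"drop"`; see [default_sign_map()].
#' @param strict If `TRUE`, an unmapped subtype is an error; otherwise it is
#'   treated as drop.
#'
#' @return `1L`, `-1L` or `0L` (drop).
#' @export
simplify_relation <- function(subtype_names, sign_map = default_sign_map(),
                              strict = FALSE) {
  stopifnot(length(subtype_names) >= 1)
  sign_map <- normalize_sign_map(sign_map)
  unknown <- setdiff(subtype_names, names(sign_map))
  if (length(unknown) && strict) {
    abort(paste0("unknown relation subtype(s): ",
                 paste(unknown, collapse = ", ")))
  }
  signs <- sign_map[intersect(subtype_names, names(sign_map))]
  if (any(signs == -1L)) return(-1L)
  if (any(signs == 1L)) return(1L)
  0L
}

#' Parse a KGML pathway file into a signed graph
#'
#' Reads one KGML (KEGG XML dialect) file, keeps gene-type entries (group
#' entries are expanded to the union of their member genes), maps relation
#' subtypes to +1/-1 via [simplify_relation()], and drops everything else:
#' non-gene entries with their incident edges, relations whose subtypes all
#' map to drop, self-loops and duplicate edges. A parse report with
#' kept/dropped counts is attached as attribute `"report"` (see
#' [graph_report()]).
#'
#' @param path Path to a KGML file.
#' @param sign_map Relation subtype sign map; see [default_sign_map()].
#' @param strict If `TRUE`, unknown relation subtypes raise an error.
#'
#' @return A [pathway_graph()].
#' @export
parse_kgml <- function(path, sign_map = default_sign_map(), strict = FALSE) {
  if (!file.exists(path)) abort(paste0("KGML file not found: ", path))
  doc <- tryCatch(
    xml2::read_xml(path),
    error = function(e) abort(paste0("malformed KGML XML in '", path, "': ",
                                     conditionMessage(e)))
  )
  root <- xml2::xml_find_first(doc, "/pathway")
  if (is.na(root)) abort(paste0("'", path, "' is not a KGML pathway document"))
  pid <- xml2::xml_attr(root, "name")
  if (is.na(pid)) pid <- sub("\\.[^.]*$", "", basename(path))
  pid <- sub("^path:", "", pid)
  title <- xml2::xml_attr(root, "title")
  if (is.na(title)) title <- pid

  entry_nodes <- xml2::xml_find_all(doc, "//entry")
  entry_id <- xml2::xml_attr(entry_nodes, "id")
  entry_type <- xml2::xml_attr(entry_nodes, "type")
  entry_name <- xml2::xml_attr(entry_nodes, "name")

  gene_sets <- setNames(vector("list", length(entry_id)), entry_id)
  for (i in seq_along(entry_nodes)) {
    if (identical(entry_type[i], "gene")) {
      g <- strsplit(trimws(entry_name[i]), "\\s+")[[1]]
      g <- g[nzchar(g) & g != "undefined"]
      gene_sets[[i]] <- unique(g)
    }
  }
  # group entries: union of member gene sets (multiple gene assignment)
  for (i in seq_along(entry_nodes)) {
    if (identical(entry_type[i], "group")) {
      comp <- xml2::xml_attr(
        xml2::xml_find_all(entry_nodes[[i]], "component"), "id")
      gene_sets[[i]] <- unique(unlist(gene_sets[comp]))
    }
  }
  keep <- lengths(gene_sets) > 0
  n_dropped_entries <- sum(!keep)
  entries <- tibble::tibble(entry_id = entry_id[keep],
                            genes = unname(gene_sets[keep]))

  rel_nodes <- xml2::xml_find_all(doc, "//relation")
  src <- xml2::xml_attr(rel_nodes, "entry1")
  snk <- xml2::xml_attr(rel_nodes, "entry2")
  sgn <- integer(length(rel_nodes))
  for (i in seq_along(rel_nodes)) {
    subtypes <- xml2::xml_attr(
      xml2::xml_find_all(rel_nodes[[i]], "subtype"), "name")
    sgn[i] <- if (length(subtypes) == 0) 0L else
      simplify_relation(subtypes, sign_map, strict = strict)
  }
  dropped_by_sign <- sum(sgn == 0L)
  ok <- sgn != 0L & src %in% entries$entry_id & snk %in% entries$entry_id
  dropped_nongene_edge <- sum(sgn != 0L & !ok)
  edges <- tibble::tibble(source = src[ok], sink = snk[ok], sign = sgn[ok])

  g <- pathway_graph(pid, title, entries, edges)
  g <- validate_graph(g)
  rep0 <- attr(g, "report")
  attr(g, "report") <- c(
    list(entries_kept = nrow(entries),
         entries_dropped = n_dropped_entries,
         relations_dropped_by_sign = dropped_by_sign,
         relations_dropped_nongene = dropped_nongene_edge),
    rep0
  )
  g
}

#' Validate and clean a pathway graph
#'
#' Removes edges with dangling endpoints, self-loops, and duplicate
#' `(source, sink, sign)` triples. All issues are reported (attribute
#' `"report"`), never raised.
#'
#' @param graph A [pathway_graph()].
#' @return The cleaned `pathway_graph`, with a report attribute listing
#'   `dangling_edges`, `self_loops`, `duplicate_edges` counts.
#' @export
validate_graph <- function(graph) {
  stopifnot(inherits(graph, "pathway_graph"))
  e <- graph$edges
  dangling <- !(e$source %in% graph$entries$entry_id &
                  e$sink %in% graph$entries$entry_id)
  e <- e[!dangling, , drop = FALSE]
  loops <- e$source == e$sink
  e <- e[!loops, , drop = FALSE]
  dup <- duplicated(e[c("source", "sink", "sign")])
  e <- e[!dup, , drop = FALSE]
  out <- pathway_graph(graph$pathway_id, graph$title, graph$entries, e)
  attr(out, "report") <- list(dangling_edges = sum(dangling),
                              self_loops = sum(loops),
                              duplicate_edges = sum(dup))
  out
}

#' Retrieve the parse/validation report of a graph
#'
#' @param graph A [pathway_graph()] returned by [parse_kgml()] or
#'   [validate_graph()].
#' @return Named list of counts.
#' @export
graph_report <- function(graph) attr(graph, "report")

#' Write a pathway graph as minimal KGML
#'
#' Emits a fixture-grade KGML document (gene-type entries, one relation per
#' edge with an `activation`/`inhibition` subtype) that [parse_kgml()] reads
#' back to an identical graph.
#'
#' @param graph A [pathway_graph()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_kgml <- function(graph, path) {
  stopifnot(inherits(graph, "pathway_graph"))
  doc <- xml2::xml_new_root("pathway",
                            name = graph$pathway_id,
                            title = graph$title)
  for (i in seq_len(nrow(graph$entries))) {
    xml2::xml_add_child(doc, "entry",
                        id = graph$entries$entry_id[i],
                        name = paste(graph$entries$genes[[i]], collapse = " "),
                        type = "gene")
  }
  for (i in seq_len(nrow(graph$edges))) {
    rel <- xml2::xml_add_child(doc, "relation",
                               entry1 = graph$edges$source[i],
                               entry2 = graph$edges$sink[i],
                               type = "PPrel")
    xml2::xml_add_child(
      rel, "subtype",
      name = if (graph$edges$sign[i] == 1L) "activation" else "inhibition",
      value = if (graph$edges$sign[i] == 1L) "-->" else "--|")
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

# igraph view of a pathway_graph (vertices = entry ids, edge attr sign)
as_igraph <- function(graph) {
  ig <- igraph::graph_from_data_frame(
    d = as.data.frame(graph$edges[c("source", "sink", "sign")]),
    directed = TRUE,
    vertices = data.frame(name = graph$entries$entry_id,
                          stringsAsFactors = FALSE))
  ig
}
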