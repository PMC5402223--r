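#' GO level of every term
#'
#' The GO level of a term is the length of the shortest directed is_a path
#' from the term up to its namespace root, with the root itself at level 0.
#' Computed by breadth-first search from the roots along child edges.
#'
#' @param dag a [GODag-class].
#' @return named integer vector over all terms.
#' @export
termLevels <- function(dag) {
  parents <- goParents(dag)
  children <- .children_list(parents)
  lv <- setNames(rep(NA_integer_, length(parents)), names(parents))
  queue <- goRoots(dag)
  lv[queue] <- 0L
  while (length(queue)) {
    id <- queue[[1L]]; queue <- queue[-1L]
    for (ch in children[[id]]) {
      if (is.na(lv[[ch]])) {
        lv[[ch]] <- lv[[id]] + 1L
        queue <- c(queue, ch)
      }
    }
  }
  if (anyNA(lv))
    stop("term(s) cannot reach a namespace root: ",
         paste(head(names(lv)[is.na(lv)], 5L), collapse = ", "),
         call. = FALSE)
  lv
}

#' @rdname termLevels
#' @param term a single term id.
#' @export
termLevel <- function(dag, term) {
  lv <- termLevels(dag)
  if (!term %in% names(lv)) stop("unknown term: ", term, call. = FALSE)
  lv[[term]]
}

#' Build the enrichment graph with visibility and pruning rules
#'
#' Produces the figure-style network view of an enrichment table: one node
#' per reported term, is_a edges between retained terms. Node attributes:
#' \code{level} (shortest is_a path from the namespace root, root = 0),
#' \code{n_genes} (genes across both DE sets carrying the term after
#' propagation, i.e. \code{n_pre + n_mat} — the two sets are disjoint),
#' \code{score} (the enrichment score; positive is the premature pole,
#' negative the mature pole for red/blue rendering), and
#' \code{display_size}. Visibility rules act on \code{display_size} only: a
#' term with level strictly below \code{minLevel} or fewer than
#' \code{minGenes} genes gets \code{display_size = 0}; visible nodes get
#' \code{display_size = n_genes}. Branches without any significantly
#' enriched term are dropped entirely: a node is retained iff some
#' descendant-or-self among the reported terms has
#' \code{|score| >= sigThreshold}.
#'
#' @param dag a [GODag-class].
#' @param enrichment output of [computeEnrichment()].
#' @param minLevel minimum GO level for a visible node (default 2,
#'   strict below).
#' @param minGenes minimum gene count for a visible node (default 150,
#'   strict below).
#' @param sigThreshold significance cutoff on \code{|score|} used for
#'   branch pruning (default 1.0, i.e. a two-fold frequency ratio; the
#'   underlying score is a plain ratio, not a test statistic, so this
#'   cutoff is a rendering convention).
#' @return an [EnrichmentGraph-class].
#' @export
buildEnrichmentGraph <- function(dag, enrichment, minLevel = 2L,
                                 minGenes = 150L, sigThreshold = 1.0) {
  lv <- termLevels(dag)
  anc <- .ancestor_sets(dag)
  terms <- enrichment$term_id
  sig <- terms[abs(enrichment$score) >= sigThreshold]
  keep_ids <- intersect(
    unique(c(sig, unlist(anc[sig], use.names = FALSE))), terms)
  e <- enrichment[match(keep_ids, enrichment$term_id), , drop = FALSE]
  n_genes <- e$n_pre + e$n_mat
  level <- unname(lv[keep_ids])
  visible <- level >= minLevel & n_genes >= minGenes
  nodes <- data.frame(term_id = keep_ids, name = e$name,
                      namespace = e$namespace, level = level,
                      n_genes = n_genes, score = e$score,
                      display_size = ifelse(visible, n_genes, 0),
                      visible = visible, row.names = NULL,
                      stringsAsFactors = FALSE)
  parents <- goParents(dag)
  edges <- do.call(rbind, c(list(
    data.frame(child = character(), parent = character(),
               stringsAsFactors = FALSE)),
    lapply(keep_ids, function(id) {
      p <- intersect(parents[[id]], keep_ids)
      if (length(p)) data.frame(child = id, parent = p,
                                stringsAsFactors = FALSE)
    })))
  new("EnrichmentGraph", nodes = nodes, edges = edges)
}

.fmt_num <- function(x) {
  # shortest %g representation that round-trips each double exactly
  out <- sprintf("%.17g", x)
  for (d in c(15L, 16L)) {
    s <- sprintf(paste0("%.", d, "g"), x)
    ok <- is.finite(x) & suppressWarnings(as.numeric(s)) == x &
      out == sprintf("%.17g", x)
    out[ok] <- s[ok]
  }
  out[is.infinite(x) & x > 0] <- "Infinity"
  out[is.infinite(x) & x < 0] <- "-Infinity"
  out
}

.parse_num <- function(s) {
  out <- suppressWarnings(as.numeric(s))
  out[s == "Infinity"] <- Inf
  out[s == "-Infinity"] <- -Inf
  out
}

#' Export an enrichment graph (GraphML, SIF, node attributes)
#'
#' Writes \code{<prefix>.graphml} with \code{name}, \code{namespace},
#' \code{level}, \code{n_genes}, \code{score}, \code{display_size} and
#' \code{visible} node attributes, a Cytoscape-compatible
#' \code{<prefix>.sif} (\code{child<TAB>is_a<TAB>parent}; isolated nodes
#' as bare ids) and \code{<prefix>_nodes.tsv} with the node table. Numeric
#' attributes are serialized with round-trip precision so
#' [readGraphML()] reproduces the graph exactly.
#'
#' @param graph an [EnrichmentGraph-class].
#' @param prefix output path prefix.
#' @return named character vector of the written paths, invisibly.
#' @export
exportGraph <- function(graph, prefix) {
  nodes <- graphNodes(graph); edges <- graphEdges(graph)
  paths <- c(graphml = paste0(prefix, ".graphml"),
             sif = paste0(prefix, ".sif"),
             nodes = paste0(prefix, "_nodes.tsv"))

  doc <- xml2::xml_new_root(
    "graphml", xmlns = "http://graphml.graphdrawing.org/xmlns")
  keys <- list(c("name", "string"), c("namespace", "string"),
               c("level", "long"), c("n_genes", "long"),
               c("score", "double"), c("display_size", "double"),
               c("visible", "boolean"))
  for (k in keys)
    xml2::xml_add_child(doc, "key", id = k[1], `for` = "node",
                        attr.name = k[1], attr.type = k[2])
  g <- xml2::xml_add_child(doc, "graph", id = "enrichment",
                           edgedefault = "directed")
  for (i in seq_len(nrow(nodes))) {
    nd <- xml2::xml_add_child(g, "node", id = nodes$term_id[i])
    add <- function(key, val)
      xml2::xml_add_child(nd, "data", key = key, val)
    add("name", nodes$name[i])
    add("namespace", nodes$namespace[i])
    add("level", sprintf("%d", nodes$level[i]))
    add("n_genes", sprintf("%d", nodes$n_genes[i]))
    add("score", .fmt_num(nodes$score[i]))
    add("display_size", .fmt_num(nodes$display_size[i]))
    add("visible", if (nodes$visible[i]) "true" else "false")
  }
  for (i in seq_len(nrow(edges)))
    xml2::xml_add_child(g, "edge", source = edges$child[i],
                        target = edges$parent[i])
  xml2::write_xml(doc, paths[["graphml"]])

  sif <- if (nrow(edges))
    paste(edges$child, "is_a", edges$parent, sep = "\t") else character()
  isolated <- setdiff(nodes$term_id, c(edges$child, edges$parent))
  writeLines(c(sif, isolated), paths[["sif"]])

  nt <- nodes
  nt$score <- .fmt_num(nt$score)
  nt$display_size <- .fmt_num(nt$display_size)
  write.table(nt, paths[["nodes"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}

#' Re-read an exported GraphML enrichment graph
#'
#' Inverse of the GraphML half of [exportGraph()]; attribute values
#' round-trip exactly.
#'
#' @param path a \code{.graphml} file written by [exportGraph()].
#' @return an [EnrichmentGraph-class].
#' @export
readGraphML <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  node_xml <- xml2::xml_find_all(doc, ".//g:graph/g:node", ns)
  get_data <- function(nd, key)
    xml2::xml_text(xml2::xml_find_first(
      nd, sprintf("./g:data[@key='%s']", key), ns))
  nodes <- data.frame(
    term_id = xml2::xml_attr(node_xml, "id"),
    name = vapply(node_xml, get_data, character(1), "name"),
    namespace = vapply(node_xml, get_data, character(1), "namespace"),
    level = as.integer(vapply(node_xml, get_data, character(1), "level")),
    n_genes = as.integer(vapply(node_xml, get_data, character(1),
                                "n_genes")),
    score = .parse_num(vapply(node_xml, get_data, character(1), "score")),
    display_size = .parse_num(vapply(node_xml, get_data, character(1),
                                     "display_size")),
    visible = vapply(node_xml, get_data, character(1),
                     "visible") == "true",
    row.names = NULL, stringsAsFactors = FALSE)
  edge_xml <- xml2::xml_find_all(doc, ".//g:graph/g:edge", ns)
  edges <- data.frame(child = xml2::xml_attr(edge_xml, "source"),
                      parent = xml2::xml_attr(edge_xml, "target"),
                      stringsAsFactors = FALSE)
  new("EnrichmentGraph", nodes = nodes, edges = edges)
}
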