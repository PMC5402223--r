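#' @importFrom methods new validObject is slot setValidity show
#' @importFrom stats rnbinom rpois rlnorm runif rbinom setNames
#' @importFrom utils read.delim write.table packageVersion head
NULL

#' Gene Ontology DAG restricted to is_a edges
#'
#' Holds a set of GO terms (identifier, human-readable name, namespace) and,
#' for each term, its direct is_a parents. Only is_a edges are represented;
#' other OBO relationship types (part_of, regulates, ...) are dropped at
#' parse time. The three namespaces are coded \code{"BP"}, \code{"CC"} and
#' \code{"MF"}; each namespace has exactly the terms reachable from its own
#' root and no edge crosses namespaces.
#'
#' @slot terms \code{data.frame} with columns \code{term_id}, \code{name},
#'   \code{namespace} (one of \code{"BP"}, \code{"CC"}, \code{"MF"}).
#' @slot parents named \code{list}; for each \code{term_id}, the character
#'   vector of its direct is_a parents (empty for a namespace root).
#'
#' @seealso [readOBO()], [writeOBO()], [propagateAnnotations()],
#'   [termLevels()]
#' @export
setClass("GODag", representation(terms = "data.frame", parents = "list"))

setValidity("GODag", function(object) {
  msgs <- character()
  tm <- object@terms
  need <- c("term_id", "name", "namespace")
  if (!all(need %in% colnames(tm)))
    return(paste("terms must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(tm$term_id))
    msgs <- c(msgs, "duplicated term_id in terms")
  if (!all(tm$namespace %in% c("BP", "CC", "MF")))
    msgs <- c(msgs, "namespace must be one of BP, CC, MF")
  if (!setequal(names(object@parents), tm$term_id))
    msgs <- c(msgs, "parents list must be named by exactly the term_ids")
  allpar <- unlist(object@parents, use.names = FALSE)
  if (length(allpar) && !all(allpar %in% tm$term_id))
    msgs <- c(msgs, "unresolved parent term_id")
  # parents stay in the child's namespace
  ns <- setNames(tm$namespace, tm$term_id)
  for (id in names(object@parents)) {
    p <- object@parents[[id]]
    if (length(p) && !all(ns[p] == ns[id])) {
      msgs <- c(msgs, sprintf("term %s has a parent in another namespace", id))
      break
    }
  }
  cyc <- .find_cycle_member(object@parents)
  if (!is.null(cyc))
    msgs <- c(msgs, sprintf("is_a graph contains a cycle through %s", cyc))
  if (length(msgs)) msgs else TRUE
})

# Kahn-style elimination on the parent lists; returns NULL when acyclic,
# otherwise the id of one term on a cycle.
.find_cycle_member <- function(parents) {
  remaining <- lengths(parents)
  children <- .children_list(parents)
  queue <- names(remaining)[remaining == 0L]
  seen <- 0L
  while (length(queue)) {
    id <- queue[[1L]]; queue <- queue[-1L]
    seen <- seen + 1L
    for (ch in children[[id]]) {
      remaining[[ch]] <- remaining[[ch]] - 1L
      if (remaining[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen == length(parents)) NULL else names(remaining)[remaining > 0L][1L]
}

.children_list <- function(parents) {
  out <- vector("list", length(parents))
  names(out) <- names(parents)
  for (id in names(parents))
    for (p in parents[[id]]) out[[p]] <- c(out[[p]], id)
  out
}

#' @describeIn GODag number of terms in the DAG
#' @param object,x a \code{GODag}
#' @export
setGeneric("nTerms", function(x) standardGeneric("nTerms"))

#' @rdname GODag
#' @export
setMethod("nTerms", "GODag", function(x) nrow(x@terms))

#' @describeIn GODag term table accessor (\code{data.frame})
#' @export
setGeneric("goTerms", function(x) standardGeneric("goTerms"))

#' @rdname GODag
#' @export
setMethod("goTerms", "GODag", function(x) x@terms)

#' @describeIn GODag direct is_a parent lists, named by term_id
#' @export
setGeneric("goParents", function(x) standardGeneric("goParents"))

#' @rdname GODag
#' @export
setMethod("goParents", "GODag", function(x) x@parents)

#' @describeIn GODag namespace roots (terms with no parent), named by namespace
#' @export
setGeneric("goRoots", function(x) standardGeneric("goRoots"))

#' @rdname GODag
#' @export
setMethod("goRoots", "GODag", function(x) {
  r <- x@terms$term_id[lengths(x@parents[x@terms$term_id]) == 0L]
  setNames(r, x@terms$namespace[match(r, x@terms$term_id)])
})

setMethod("show", "GODag", function(object) {
  ns <- table(object@terms$namespace)
  cat(sprintf("GODag with %d terms (%s), %d is_a edges\n",
              nrow(object@terms),
              paste(sprintf("%s: %d", names(ns), as.integer(ns)),
                    collapse = ", "),
              sum(lengths(object@parents))))
})

#' Result of PCR-duplicate removal
#'
#' Container returned by [dedupReads()]: the retained reads (in input
#' order) plus the removal report. The invariant
#' \code{n_input = n_kept + n_removed} is enforced by the validity method.
#'
#' @slot kept \code{DNAStringSet} of retained reads; qualities, when
#'   present on input, travel in \code{mcols(kept)$qualities}.
#' @slot n_input,n_kept,n_removed integer counts.
#' @slot removed_pairs \code{data.frame} with columns \code{kept_id}
#'   (the retained representative) and \code{removed_id}.
#'
#' @export
setClass("DedupResult",
         representation(kept = "DNAStringSet", n_input = "integer",
                        n_kept = "integer", n_removed = "integer",
                        removed_pairs = "data.frame"))

setValidity("DedupResult", function(object) {
  msgs <- character()
  if (object@n_input != object@n_kept + object@n_removed)
    msgs <- c(msgs, "n_input must equal n_kept + n_removed")
  if (length(object@kept) != object@n_kept)
    msgs <- c(msgs, "length(kept) must equal n_kept")
  if (!all(c("kept_id", "removed_id") %in% colnames(object@removed_pairs)))
    msgs <- c(msgs, "removed_pairs needs columns kept_id, removed_id")
  if (nrow(object@removed_pairs) != object@n_removed)
    msgs <- c(msgs, "nrow(removed_pairs) must equal n_removed")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn DedupResult retained reads accessor
#' @param object,x a \code{DedupResult}
#' @export
setGeneric("keptReads", function(x) standardGeneric("keptReads"))

#' @rdname DedupResult
#' @export
setMethod("keptReads", "DedupResult", function(x) x@kept)

#' @describeIn DedupResult report as a one-row \code{data.frame} plus the
#'   removed pairs in \code{attr(, "removed_pairs")}
#' @export
setGeneric("dedupReport", function(x) standardGeneric("dedupReport"))

#' @rdname DedupResult
#' @export
setMethod("dedupReport", "DedupResult", function(x) {
  out <- data.frame(n_input = x@n_input, n_kept = x@n_kept,
                    n_removed = x@n_removed)
  attr(out, "removed_pairs") <- x@removed_pairs
  out
})

#' @describeIn DedupResult removed (kept_id, removed_id) pairs
#' @export
setGeneric("removedPairs", function(x) standardGeneric("removedPairs"))

#' @rdname DedupResult
#' @export
setMethod("removedPairs", "DedupResult", function(x) x@removed_pairs)

setMethod("show", "DedupResult", function(object) {
  cat(sprintf("DedupResult: %d reads in, %d kept, %d removed as PCR duplicates\n",
              object@n_input, object@n_kept, object@n_removed))
})

#' GO enrichment graph for Cytoscape-style rendering
#'
#' The figure-style view of an enrichment result: one node per GO term that
#' carries genes from either differential-expression set, is_a edges between
#' retained terms, and per-node display attributes (level, gene count,
#' enrichment score, display size, visibility). Visibility rules set
#' \code{display_size} to 0 but never alter \code{score} or \code{n_genes}.
#'
#' @slot nodes \code{data.frame} with columns \code{term_id}, \code{name},
#'   \code{namespace}, \code{level}, \code{n_genes}, \code{score},
#'   \code{display_size}, \code{visible}.
#' @slot edges \code{data.frame} with columns \code{child}, \code{parent};
#'   a subset of the DAG's is_a edges with both endpoints retained.
#'
#' @seealso [buildEnrichmentGraph()], [exportGraph()], [readGraphML()]
#' @export
setClass("EnrichmentGraph",
         representation(nodes = "data.frame", edges = "data.frame"))

setValidity("EnrichmentGraph", function(object) {
  msgs <- character()
  need <- c("term_id", "name", "namespace", "level", "n_genes", "score",
            "display_size", "visible")
  if (!all(need %in% colnames(object@nodes)))
    msgs <- c(msgs, paste("nodes must have columns:",
                          paste(need, collapse = ", ")))
  if (!all(c("child", "parent") %in% colnames(object@edges)))
    msgs <- c(msgs, "edges needs columns child, parent")
  else if (nrow(object@edges) &&
           !all(c(object@edges$child, object@edges$parent) %in%
                object@nodes$term_id))
    msgs <- c(msgs, "every edge endpoint must be a retained node")
  if (length(msgs) == 0L &&
      !all((object@nodes$display_size == 0) == (!object@nodes$visible)))
    msgs <- c(msgs, "display_size must be 0 exactly for invisible nodes")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn EnrichmentGraph node table accessor
#' @param object,x an \code{EnrichmentGraph}
#' @export
setGeneric("graphNodes", function(x) standardGeneric("graphNodes"))

#' @rdname EnrichmentGraph
#' @export
setMethod("graphNodes", "EnrichmentGraph", function(x) x@nodes)

#' @describeIn EnrichmentGraph edge table accessor
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))

#' @rdname EnrichmentGraph
#' @export
setMethod("graphEdges", "EnrichmentGraph", function(x) x@edges)

setMethod("show", "EnrichmentGraph", function(object) {
  cat(sprintf("EnrichmentGraph: %d nodes (%d visible), %d is_a edges\n",
              nrow(object@nodes), sum(object@nodes$visible),
              nrow(object@edges)))
})
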