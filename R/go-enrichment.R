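.NS_LONG <- c(BP = "biological_process", CC = "cellular_component",
              MF = "molecular_function")

#' Read a (minimal) OBO ontology file
#'
#' Parses \code{[Term]} stanzas honoring \code{id}, \code{name},
#' \code{namespace}, \code{is_a} and \code{is_obsolete}; obsolete terms are
#' skipped and every other tag (including \code{relationship: part_of} and
#' friends) is ignored, so the resulting DAG carries is_a edges only.
#' Trailing \code{! comment} text on \code{is_a} lines is stripped.
#'
#' @param path OBO file.
#' @return a [GODag-class].
#' @export
readOBO <- function(path) {
  lines <- readLines(path)
  in_term <- FALSE
  cur <- NULL
  terms <- list()
  flush <- function(cur) {
    if (is.null(cur) || isTRUE(cur$obsolete) || is.null(cur$id)) return(NULL)
    cur
  }
  for (ln in lines) {
    ln <- sub("\\s+$", "", ln)
    if (ln == "[Term]") {
      t <- flush(cur); if (!is.null(t)) terms[[t$id]] <- t
      cur <- list(parents = character()); in_term <- TRUE
    } else if (grepl("^\\[", ln)) {
      t <- flush(cur); if (!is.null(t)) terms[[t$id]] <- t
      cur <- NULL; in_term <- FALSE
    } else if (in_term && nzchar(ln)) {
      key <- sub(":.*$", "", ln)
      val <- sub("^[^:]+:\\s*", "", ln)
      if (key == "id") cur$id <- val
      else if (key == "name") cur$name <- val
      else if (key == "namespace") cur$namespace <- val
      else if (key == "is_a")
        cur$parents <- c(cur$parents, sub("\\s*!.*$", "", val))
      else if (key == "is_obsolete" && grepl("true", val))
        cur$obsolete <- TRUE
    }
  }
  t <- flush(cur); if (!is.null(t)) terms[[t$id]] <- t
  if (!length(terms)) stop("no usable [Term] stanzas in ", path,
                           call. = FALSE)
  ns <- vapply(terms, function(t) t$namespace %||% "", character(1))
  short <- names(.NS_LONG)[match(ns, .NS_LONG)]
  short[is.na(short) & ns %in% names(.NS_LONG)] <-
    ns[is.na(short) & ns %in% names(.NS_LONG)]
  tm <- data.frame(term_id = vapply(terms, `[[`, character(1), "id"),
                   name = vapply(terms, function(t) t$name %||% "",
                                 character(1)),
                   namespace = short, row.names = NULL,
                   stringsAsFactors = FALSE)
  parents <- lapply(terms, `[[`, "parents")
  names(parents) <- tm$term_id
  # obsolete parents may have been skipped: drop dangling references
  parents <- lapply(parents, function(p) p[p %in% tm$term_id])
  new("GODag", terms = tm, parents = parents)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a GODag as a minimal OBO file
#'
#' Emits only \code{id}, \code{name}, \code{namespace} and \code{is_a}
#' stanza lines; [readOBO()] of the output reproduces the DAG.
#'
#' @param dag a [GODag-class].
#' @param path output file.
#' @export
writeOBO <- function(dag, path) {
  tm <- goTerms(dag)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (i in seq_len(nrow(tm))) {
    writeLines(c("", "[Term]",
                 paste0("id: ", tm$term_id[i]),
                 paste0("name: ", tm$name[i]),
                 paste0("namespace: ", .NS_LONG[[tm$namespace[i]]]),
                 paste0("is_a: ", goParents(dag)[[tm$term_id[i]]])), con)
  }
  invisible(path)
}

#' Write / read gene-to-GO annotation tables (\code{gene_id<TAB>go_id})
#'
#' @param annotations named list, gene id -> character vector of term ids.
#' @param path file path.
#' @export
writeAnnotations <- function(annotations, path) {
  df <- data.frame(
    gene_id = rep(names(annotations), lengths(annotations)),
    go_id = unlist(annotations, use.names = FALSE),
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeAnnotations
#' @param genes optional gene universe; genes without any annotation row
#'   appear in the result with an empty term set.
#' @export
readAnnotations <- function(path, genes = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  ann <- split(df$go_id, df$gene_id)
  if (!is.null(genes)) {
    missing <- setdiff(genes, names(ann))
    ann[missing] <- list(character())
    ann <- ann[genes]
  }
  ann
}

# ancestors (excluding self) of every term, computed in one Kahn-style
# topological pass so every parent set is finished before its children
.ancestor_sets <- function(dag) {
  parents <- goParents(dag)
  cyc <- .find_cycle_member(parents)
  if (!is.null(cyc))
    stop("ontology is_a graph contains a cycle through ", cyc,
         call. = FALSE)
  children <- .children_list(parents)
  remaining <- lengths(parents)
  queue <- names(remaining)[remaining == 0L]
  anc <- setNames(vector("list", length(parents)), names(parents))
  while (length(queue)) {
    id <- queue[[1L]]; queue <- queue[-1L]
    p <- parents[[id]]
    anc[[id]] <- unique(c(p, unlist(anc[p], use.names = FALSE)))
    for (ch in children[[id]]) {
      remaining[[ch]] <- remaining[[ch]] - 1L
      if (remaining[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  anc
}

#' Propagate gene annotations over is_a edges
#'
#' Each gene's term set is closed upward: the union of its direct terms and
#' all their is_a ancestors, up to the namespace root. The operation is
#' idempotent and its result is a superset of the direct annotation.
#'
#' @param dag a [GODag-class].
#' @param annotations named list, gene id -> direct term ids (must resolve
#'   in the DAG).
#' @return named list, gene id -> closed term set.
#' @export
propagateAnnotations <- function(dag, annotations) {
  anc <- .ancestor_sets(dag)
  known <- goTerms(dag)$term_id
  bad <- setdiff(unique(unlist(annotations, use.names = FALSE)), known)
  if (length(bad))
    stop("annotation references unknown term(s): ",
         paste(head(bad, 5L), collapse = ", "), call. = FALSE)
  lapply(annotations, function(tt)
    unique(c(tt, unlist(anc[tt], use.names = FALSE))))
}

#' Per-term gene counts within a gene set
#'
#' Counts, for every GO term, the genes of \code{geneSet} whose (typically
#' propagated) annotation contains the term; the total is the number of
#' set genes carrying at least one GO mapping. Genes absent from the
#' annotation table, or annotated to nothing, are dropped from the total
#' and reported via a message.
#'
#' @param geneSet character vector of gene ids.
#' @param annotations named list, gene id -> term ids (use
#'   [propagateAnnotations()] output for hierarchical counts).
#' @return list with \code{counts} (named integer vector over terms seen in
#'   the set) and \code{total} (integer).
#' @export
termCounts <- function(geneSet, annotations) {
  sets <- annotations[intersect(geneSet, names(annotations))]
  n_dropped <- length(geneSet) - sum(lengths(sets) > 0L)
  if (n_dropped > 0L)
    message(n_dropped, " gene(s) without GO annotation dropped from totals")
  sets <- sets[lengths(sets) > 0L]
  counts <- if (length(sets))
    table(unlist(sets, use.names = FALSE)) else table(character())
  list(counts = setNames(as.integer(counts), names(counts)),
       total = length(sets))
}

#' Log2 frequency-ratio enrichment score
#'
#' \deqn{Enrich(GO) = \log_2 \frac{(n_{pre} + p)/(N_{pre} + p)}
#'                               {(n_{mat} + p)/(N_{mat} + p)}}
#' with pseudo-count \eqn{p} (default 0.05) added to all four quantities,
#' which keeps the score finite for any non-negative counts and preserves
#' the antisymmetry \code{Enrich(swap) = -Enrich}. The
#' \code{"counts_only"} placement (pseudo-count on the two term counts
#' only) is available for comparison.
#'
#' @param nPre,nMat per-term gene counts in the premature-up and mature-up
#'   sets.
#' @param nTotalPre,nTotalMat GO-mapped gene totals of the two sets.
#' @param pseudo pseudo-count, > 0.
#' @param placement \code{"all"} (default) or \code{"counts_only"}.
#' @return numeric score(s); vectorized over the count arguments.
#' @examples
#' enrichmentScore(10, 100, 5, 100)   # log2(10.05/5.05) = 0.9928...
#' enrichmentScore(0, 100, 5, 100)    # log2(0.05/5.05)  = -6.658...
#' @export
enrichmentScore <- function(nPre, nTotalPre, nMat, nTotalMat, pseudo = 0.05,
                            placement = c("all", "counts_only")) {
  placement <- match.arg(placement)
  if (any(c(nPre, nTotalPre, nMat, nTotalMat) < 0))
    stop("counts must be non-negative", call. = FALSE)
  if (pseudo <= 0) {
    if (any(nPre == 0 | nMat == 0 | nTotalPre == 0 | nTotalMat == 0))
      stop("pseudo-count must be > 0 when any count is zero", call. = FALSE)
    pseudo <- 0
  }
  tp <- if (placement == "all") pseudo else 0
  log2(((nPre + pseudo) / (nTotalPre + tp)) /
         ((nMat + pseudo) / (nTotalMat + tp)))
}

#' Per-term enrichment between the two DE gene sets
#'
#' Runs annotation propagation (optional), per-set term counting and
#' [enrichmentScore()] over all terms carried by at least one of the two
#' sets. A positive score means the term is relatively more frequent among
#' premature-up genes; results are ordered by namespace, then score
#' descending.
#'
#' @param dag a [GODag-class].
#' @param annotations named list of direct annotations.
#' @param preGenes,matGenes the DE classifier's premature-up and mature-up
#'   gene sets.
#' @param pseudo pseudo-count (default 0.05).
#' @param propagate close annotations over is_a before counting (default
#'   TRUE).
#' @param totalMode \code{"annotated"} (default: totals count set genes
#'   with >= 1 GO mapping) or \code{"all"} (all set genes).
#' @param placement see [enrichmentScore()].
#' @return \code{data.frame}: \code{term_id}, \code{name},
#'   \code{namespace}, \code{n_pre}, \code{n_total_pre}, \code{n_mat},
#'   \code{n_total_mat}, \code{score}.
#' @export
computeEnrichment <- function(dag, annotations, preGenes, matGenes,
                              pseudo = 0.05, propagate = TRUE,
                              totalMode = c("annotated", "all"),
                              placement = c("all", "counts_only")) {
  totalMode <- match.arg(totalMode)
  placement <- match.arg(placement)
  if (!length(preGenes) && !length(matGenes)) {
    warning("both gene sets are empty; returning no enrichment results")
    return(data.frame(term_id = character(), name = character(),
                      namespace = character(), n_pre = integer(),
                      n_total_pre = integer(), n_mat = integer(),
                      n_total_mat = integer(), score = numeric(),
                      stringsAsFactors = FALSE))
  }
  ann <- if (propagate) propagateAnnotations(dag, annotations)
         else annotations
  pre <- termCounts(preGenes, ann)
  mat <- termCounts(matGenes, ann)
  if (totalMode == "all") {
    pre$total <- length(preGenes)
    mat$total <- length(matGenes)
  }
  terms <- union(names(pre$counts), names(mat$counts))
  n_pre <- ifelse(terms %in% names(pre$counts), pre$counts[terms], 0L)
  n_mat <- ifelse(terms %in% names(mat$counts), mat$counts[terms], 0L)
  tm <- goTerms(dag)
  i <- match(terms, tm$term_id)
  out <- data.frame(term_id = terms, name = tm$name[i],
                    namespace = tm$namespace[i],
                    n_pre = as.integer(n_pre), n_total_pre = pre$total,
                    n_mat = as.integer(n_mat), n_total_mat = mat$total,
                    score = enrichmentScore(n_pre, pre$total, n_mat,
                                            mat$total, pseudo = pseudo,
                                            placement = placement),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$namespace, -out$score), , drop = FALSE]
}

#' Write an enrichment table as TSV
#'
#' @param enrichment output of [computeEnrichment()].
#' @param path file path.
#' @export
writeEnrichment <- function(enrichment, path) {
  write.table(enrichment, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
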