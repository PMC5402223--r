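# Independent brute-force oracles used against the package implementations.
# These deliberately share no code with the package: similarity is computed
# on split character vectors, deduplication scans all pairs without prefix
# bucketing, and ontology reachability is a fixpoint expansion.

naive_similarity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  k <- min(length(ca), length(cb))
  sum(ca[seq_len(k)] == cb[seq_len(k)]) / max(length(ca), length(cb))
}

# all-pairs keep-first-in-input-order deduplication
naive_dedup <- function(seqs, ids, prefix_len = 10, thr = 0.90) {
  kept <- integer(0)
  removed <- character(0)
  for (i in seq_along(seqs)) {
    dup <- FALSE
    for (j in kept) {
      if (substr(seqs[i], 1, prefix_len) == substr(seqs[j], 1, prefix_len) &&
          naive_similarity(seqs[i], seqs[j]) > thr) {
        dup <- TRUE
        break
      }
    }
    if (dup) removed <- c(removed, ids[i]) else kept <- c(kept, i)
  }
  list(kept_ids = ids[kept], removed_ids = removed)
}

# transitive ancestors by fixpoint expansion over direct parent lists
naive_ancestors <- function(parents, term) {
  acc <- character(0)
  frontier <- parents[[term]]
  while (length(frontier)) {
    acc <- union(acc, frontier)
    frontier <- setdiff(unique(unlist(parents[frontier],
                                      use.names = FALSE)), acc)
  }
  acc
}

# shortest path to a parentless term, by iterating relaxation to fixpoint
naive_levels <- function(parents) {
  lv <- setNames(ifelse(lengths(parents) == 0L, 0L, NA_integer_),
                 names(parents))
  repeat {
    changed <- FALSE
    for (id in names(parents)) {
      p <- parents[[id]]
      if (!length(p)) next
      cand <- suppressWarnings(min(lv[p], na.rm = TRUE)) + 1L
      if (is.finite(cand) && (is.na(lv[[id]]) || cand < lv[[id]])) {
        lv[[id]] <- cand
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lv
}

# random single-namespace GODag with arbitrary multi-parent shape
random_dag <- function(n_terms, seed, namespace = "BP") {
  set.seed(seed)
  ids <- sprintf("GO:%07d", seq_len(n_terms))
  parents <- setNames(vector("list", n_terms), ids)
  parents[[1]] <- character(0)
  for (k in seq_len(n_terms)[-1]) {
    np <- sample(1:min(3, k - 1), 1)
    parents[[k]] <- ids[sample.int(k - 1, np)]
  }
  terms <- data.frame(term_id = ids,
                      name = paste("term", seq_len(n_terms)),
                      namespace = namespace, stringsAsFactors = FALSE)
  methods::new("GODag", terms = terms, parents = parents)
}

# random direct annotations over a DAG's non-root terms
random_annotations <- function(dag, n_genes, seed) {
  set.seed(seed)
  ids <- goTerms(dag)$term_id
  setNames(lapply(seq_len(n_genes), function(i)
    sample(ids, sample(1:3, 1))), sprintf("gene%03d", seq_len(n_genes)))
}

# small hand-sized FPKM matrix helper
fpkm_matrix <- function(pre, mat, genes = sprintf("g%d", seq_along(pre))) {
  m <- cbind(premature = pre, mature = mat)
  rownames(m) <- genes
  m
}
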