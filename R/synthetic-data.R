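#' Build and validate a simulation configuration
#'
#' The generator emulates the study design the pipeline targets: two ovary
#' conditions ("premature", "mature") with two pooled-RNA replicate samples
#' each, negative-binomially distributed gene counts with planted fold
#' changes, a small three-namespace GO DAG with planted term-frequency skews
#' between the two differentially-expressed gene sets, and fixed-cycle
#' Illumina-style reads containing planted PCR-duplicate clusters plus
#' boundary decoys.
#'
#' Counts use the mean--dispersion negative-binomial parameterization
#' standard in RNA-seq (variance \eqn{\mu + \alpha\mu^2}); the Poisson limit
#' is \code{dispersion} tending to 0. Planted fold changes are applied
#' symmetrically (multiply one condition by \code{sqrt(true_fold)}, divide
#' the other) so that with equal up/down fractions the library compositions
#' balance and the expected FPKM ratio of a planted gene equals
#' \code{true_fold} (and \code{1/true_fold}) essentially exactly.
#'
#' @param n_genes number of gene models.
#' @param length_range integer pair, transcript length bounds in bases.
#' @param n_replicates replicates per condition.
#' @param library_size expected total mapped reads per replicate.
#' @param dispersion negative-binomial dispersion \eqn{\alpha > 0}
#'   (variance \eqn{\mu + \alpha \mu^2}).
#' @param abundance_sdlog sdlog of the log-normal baseline abundance spread
#'   across genes; 0 gives every gene the same expected count.
#' @param between_rep_sd sdlog of an optional per-replicate log-normal
#'   perturbation of gene means; the two replicate samples are pools of
#'   three animals each, so the default assumes no extra between-replicate
#'   biological variance.
#' @param frac_pre_up,frac_mat_up fractions of genes planted as upregulated
#'   in premature resp. mature ovaries; must sum to at most 1.
#' @param true_fold planted expected FPKM ratio for upregulated genes
#'   (must exceed the 1.5 classification threshold).
#' @param n_go_terms total GO terms across the three namespaces (>= 3).
#' @param dag_depth maximum is_a depth below a namespace root.
#' @param n_planted_per_direction planted skewed terms per direction.
#' @param planted_base_freq annotation frequency of a planted term in its
#'   depleted gene set.
#' @param planted_skew frequency multiplier in the enriched set
#'   (\code{planted_base_freq * planted_skew} must be <= 1).
#' @param frac_unannotated fraction of genes left without any GO mapping.
#' @param n_genes_per_set gene-set size when the GO generator runs
#'   standalone (without a count-table truth).
#' @param n_reads number of original (non-duplicate) reads.
#' @param dup_rate fraction of originals that receive one planted PCR
#'   duplicate.
#' @param decoy_rate fraction of originals that receive one near-miss decoy
#'   (identical 10-base prefix, similarity at or below 90\%).
#' @param read_length read length in bases (> 10; default 101, the
#'   fixed-cycle length of the emulated sequencing run).
#' @param mutation_rate per-base mutation probability outside the 10-base
#'   prefix for planted duplicates.
#' @param seed integer seed; every generator is deterministic given the
#'   config.
#'
#' @return a validated list of class \code{"SimulationConfig"}.
#' @examples
#' cfg <- simulationConfig(n_genes = 100, seed = 7)
#' models <- generateGeneModels(cfg)
#' head(models)
#' @export
simulationConfig <- function(n_genes = 2000L,
                             length_range = c(500L, 5000L),
                             n_replicates = 2L,
                             library_size = 200000L,
                             dispersion = 0.1,
                             abundance_sdlog = 1.0,
                             between_rep_sd = 0,
                             frac_pre_up = 0.1,
                             frac_mat_up = 0.1,
                             true_fold = 2,
                             n_go_terms = 120L,
                             dag_depth = 4L,
                             n_planted_per_direction = 3L,
                             planted_base_freq = 0.3,
                             planted_skew = 2,
                             frac_unannotated = 0.05,
                             n_genes_per_set = 200L,
                             n_reads = 400L,
                             dup_rate = 0.2,
                             decoy_rate = 0.1,
                             read_length = 101L,
                             mutation_rate = 0.02,
                             seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              length_range = as.integer(length_range),
              n_replicates = as.integer(n_replicates),
              library_size = as.integer(library_size),
              dispersion = dispersion,
              abundance_sdlog = abundance_sdlog,
              between_rep_sd = between_rep_sd,
              frac_pre_up = frac_pre_up, frac_mat_up = frac_mat_up,
              true_fold = true_fold,
              n_go_terms = as.integer(n_go_terms),
              dag_depth = as.integer(dag_depth),
              n_planted_per_direction = as.integer(n_planted_per_direction),
              planted_base_freq = planted_base_freq,
              planted_skew = planted_skew,
              frac_unannotated = frac_unannotated,
              n_genes_per_set = as.integer(n_genes_per_set),
              n_reads = as.integer(n_reads),
              dup_rate = dup_rate, decoy_rate = decoy_rate,
              read_length = as.integer(read_length),
              mutation_rate = mutation_rate,
              seed = as.integer(seed))
  errs <- .check_sim_config(cfg)
  if (length(errs))
    stop("invalid simulation configuration:\n  ",
         paste(errs, collapse = "\n  "), call. = FALSE)
  class(cfg) <- "SimulationConfig"
  cfg
}

.check_sim_config <- function(cfg) {
  errs <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) errs <<- c(errs, msg)
  chk(cfg$n_genes >= 1L, "n_genes: must be >= 1")
  chk(length(cfg$length_range) == 2L && cfg$length_range[1] >= 1L &&
        cfg$length_range[2] >= cfg$length_range[1],
      "length_range: must be an increasing pair with lower bound >= 1")
  chk(cfg$n_replicates >= 1L, "n_replicates: must be >= 1")
  chk(cfg$library_size >= 1L, "library_size: must be >= 1")
  chk(cfg$dispersion > 0, "dispersion: must be > 0")
  chk(cfg$frac_pre_up >= 0 && cfg$frac_mat_up >= 0 &&
        cfg$frac_pre_up + cfg$frac_mat_up <= 1,
      "frac_pre_up/frac_mat_up: fractions must be in [0,1] and sum to <= 1")
  chk(cfg$true_fold > 1.5, "true_fold: must exceed 1.5")
  chk(cfg$n_go_terms >= 3L, "n_go_terms: must be >= 3 (one root per namespace)")
  chk(cfg$dag_depth >= 1L, "dag_depth: must be >= 1")
  chk(cfg$planted_base_freq > 0 && cfg$planted_base_freq *
        cfg$planted_skew <= 1,
      "planted_base_freq * planted_skew must be in (0,1]")
  chk(cfg$dup_rate >= 0 && cfg$dup_rate <= 1, "dup_rate: must be in [0,1]")
  chk(cfg$decoy_rate >= 0 && cfg$decoy_rate <= 1,
      "decoy_rate: must be in [0,1]")
  chk(cfg$read_length > 10L, "read_length: must be > 10")
  chk(cfg$mutation_rate >= 0 && cfg$mutation_rate <= 1,
      "mutation_rate: must be in [0,1]")
  errs
}

#' Generate gene models (identifier + transcript length)
#'
#' @param config a [simulationConfig()].
#' @return \code{data.frame} with columns \code{gene_id}, \code{length};
#'   lengths are uniform on \code{length_range}.
#' @export
generateGeneModels <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  data.frame(
    gene_id = sprintf("g%05d", seq_len(config$n_genes)),
    length = sample(seq(config$length_range[1], config$length_range[2]),
                    config$n_genes, replace = TRUE),
    stringsAsFactors = FALSE)
}

#' Generate a two-condition count table with planted fold changes
#'
#' Draws negative-binomial counts for a premature-vs-mature two-condition
#' design. A fraction \code{frac_pre_up} of genes is planted with expected
#' premature/mature FPKM ratio \code{true_fold} and \code{frac_mat_up} with
#' ratio \code{1/true_fold}; the remainder are unchanged. Baseline
#' abundances are log-normal; expected counts are proportional to abundance
#' times transcript length (longer transcripts collect more fragments), and
#' fold changes are planted on the length-normalized (FPKM) scale.
#'
#' @param models output of [generateGeneModels()].
#' @param config a [simulationConfig()].
#' @return a \code{SummarizedExperiment}: assay \code{"counts"} (genes x
#'   samples), \code{colData} columns \code{condition} and \code{replicate},
#'   \code{rowData} columns \code{length} and \code{true_class} (the planted
#'   truth: \code{"premature_up"}, \code{"mature_up"} or \code{"unchanged"}).
#' @export
generateCounts <- function(models, config) {
  stopifnot(inherits(config, "SimulationConfig"), nrow(models) >= 1L)
  set.seed(config$seed + 1L)
  n <- nrow(models)
  n_pre <- round(config$frac_pre_up * n)
  n_mat <- round(config$frac_mat_up * n)
  cls <- rep("unchanged", n)
  pick <- sample.int(n, n_pre + n_mat)
  cls[pick[seq_len(n_pre)]] <- "premature_up"
  cls[pick[seq_len(n_mat) + n_pre]] <- "mature_up"

  theta <- rlnorm(n, meanlog = 0, sdlog = config$abundance_sdlog)
  s <- sqrt(config$true_fold)
  f_pre <- ifelse(cls == "premature_up", s, ifelse(cls == "mature_up", 1/s, 1))
  f_mat <- 1 / f_pre
  w <- theta * models$length
  base_mu <- config$library_size * w / sum(w)

  conds <- c("premature", "mature")
  samples <- expand.grid(replicate = seq_len(config$n_replicates),
                         condition = conds, stringsAsFactors = FALSE)
  samples <- samples[, c("condition", "replicate")]
  counts <- matrix(0L, nrow = n, ncol = nrow(samples),
                   dimnames = list(models$gene_id,
                                   sprintf("%s_rep%d", samples$condition,
                                           samples$replicate)))
  size <- 1 / config$dispersion
  for (j in seq_len(nrow(samples))) {
    mu <- base_mu * (if (samples$condition[j] == "premature") f_pre else f_mat)
    if (config$between_rep_sd > 0)
      mu <- mu * rlnorm(n, meanlog = -config$between_rep_sd^2 / 2,
                        sdlog = config$between_rep_sd)
    counts[, j] <- rnbinom(n, mu = mu, size = size)
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(length = models$length, true_class = cls,
                                   row.names = models$gene_id),
    colData = S4Vectors::DataFrame(condition = samples$condition,
                                   replicate = samples$replicate,
                                   row.names = colnames(counts)))
}

#' Generate a synthetic GO DAG with planted term-frequency skews
#'
#' Builds a three-namespace (BP/CC/MF) is_a DAG — one root per namespace,
#' no cross-namespace edges, every non-root term with at least one parent
#' one level up — and a direct gene-to-term annotation table. A configurable
#' number of terms per direction is planted with a frequency skew: such a
#' term annotates genes of its target set at \code{planted_base_freq *
#' planted_skew} and genes of the opposite set at \code{planted_base_freq},
#' so its enrichment score downstream should have the planted sign.
#'
#' @param config a [simulationConfig()].
#' @param genes optional character vector of gene ids; with \code{classes},
#'   ties the annotation to an existing count simulation.
#' @param classes optional per-gene true classes (parallel to \code{genes},
#'   values as in [generateCounts()]); planted premature-direction terms
#'   target the \code{"premature_up"} genes, mature-direction terms the
#'   \code{"mature_up"} genes. When omitted, two synthetic disjoint sets of
#'   \code{n_genes_per_set} genes are created.
#' @return list with \code{dag} (a [GODag-class]), \code{annotations}
#'   (named list: gene id -> character vector of directly annotated terms)
#'   and \code{truth} (\code{data.frame}: \code{term_id}, \code{direction},
#'   \code{expected_sign}).
#' @export
generateGODag <- function(config, genes = NULL, classes = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed + 2L)
  ns_names <- c("BP", "CC", "MF")
  n_extra <- config$n_go_terms - 3L
  per_ns <- diff(round(seq(0, n_extra, length.out = 4L)))

  ids <- sprintf("GO:%07d", seq_len(config$n_go_terms))
  terms <- data.frame(term_id = ids, name = "", namespace = "",
                      stringsAsFactors = FALSE)
  parents <- setNames(vector("list", config$n_go_terms), ids)
  parents[] <- list(character())
  level <- integer(config$n_go_terms)

  k <- 3L
  for (i in seq_along(ns_names)) {
    terms$namespace[i] <- ns_names[i]
    terms$name[i] <- paste0(tolower(ns_names[i]), " root")
    level[i] <- 0L
    n_i <- per_ns[i]
    if (n_i == 0L) next
    # at least one level-1 term, then random levels up to dag_depth
    lv <- c(1L, if (n_i > 1L)
      sort(sample(seq_len(config$dag_depth), n_i - 1L, replace = TRUE)))
    for (j in seq_len(n_i)) {
      k <- k + 1L
      terms$namespace[k] <- ns_names[i]
      terms$name[k] <- sprintf("%s term %d", tolower(ns_names[i]), j)
      level[k] <- lv[j]
      pool <- which(terms$namespace[seq_len(k - 1L)] == ns_names[i] &
                      level[seq_len(k - 1L)] == lv[j] - 1L)
      if (!length(pool))  # no term one level up yet: hang off the root
        pool <- i
      np <- min(length(pool), sample(1:2, 1L))
      parents[[k]] <- ids[pool[sample.int(length(pool), np)]]
    }
  }
  dag <- new("GODag", terms = terms, parents = parents)

  if (is.null(genes)) {
    genes <- c(sprintf("A%04d", seq_len(config$n_genes_per_set)),
               sprintf("B%04d", seq_len(config$n_genes_per_set)))
    classes <- rep(c("premature_up", "mature_up"),
                   each = config$n_genes_per_set)
  }
  stopifnot(length(genes) == length(classes))
  pre_set <- genes[classes == "premature_up"]
  mat_set <- genes[classes == "mature_up"]

  # plant on childless terms at level >= 2: leaves mirror how direct
  # annotations behave, and propagation cannot dilute the planted skew
  # with background annotations inherited from descendants
  has_child <- ids %in% unlist(parents, use.names = FALSE)
  deep <- ids[level >= 2L & !has_child]
  n_pl <- 2L * config$n_planted_per_direction
  if (length(deep) < n_pl)
    stop("not enough childless terms at level >= 2 to plant; ",
         "increase n_go_terms", call. = FALSE)
  planted <- sample(deep, n_pl)
  truth <- data.frame(term_id = planted,
                      direction = rep(c("premature", "mature"),
                                      each = config$n_planted_per_direction),
                      expected_sign = rep(c(1, -1),
                                          each = config$n_planted_per_direction),
                      stringsAsFactors = FALSE)

  background <- setdiff(ids, c(planted, ids[1:3]))
  ann <- setNames(vector("list", length(genes)), genes)
  unannot <- runif(length(genes)) < config$frac_unannotated
  for (g in seq_along(genes)) {
    if (unannot[g]) { ann[[g]] <- character(); next }
    ann[[g]] <- sample(background, min(length(background), sample(1:3, 1L)))
  }
  hi <- config$planted_base_freq * config$planted_skew
  lo <- config$planted_base_freq
  for (r in seq_len(nrow(truth))) {
    tgt <- if (truth$direction[r] == "premature") pre_set else mat_set
    oth <- if (truth$direction[r] == "premature") mat_set else pre_set
    hit <- c(tgt[runif(length(tgt)) < hi], oth[runif(length(oth)) < lo])
    hit <- hit[!unannot[match(hit, genes)]]
    for (g in hit) ann[[g]] <- c(ann[[g]], truth$term_id[r])
  }
  list(dag = dag, annotations = ann, truth = truth)
}

# largest mismatch count still strictly above the similarity threshold,
# and smallest count at or below it, for reads of length L
.dup_mismatch_bounds <- function(L, sim_threshold = 0.90) {
  m_max <- ceiling(L * (1 - sim_threshold)) - 1L
  if ((L - (m_max + 1L)) / L > sim_threshold) m_max <- m_max + 1L
  m_min <- m_max + 1L
  list(max_dup = m_max, min_decoy = m_min)
}

#' Generate reads with planted PCR duplicates and boundary decoys
#'
#' Emits original reads with mutually distinct 10-base prefixes, then for a
#' \code{dup_rate} fraction of them a planted PCR duplicate (identical
#' 10-base prefix; mutations only beyond base 10, capped so whole-read
#' similarity stays strictly above 90\%) and for a \code{decoy_rate}
#' fraction a near-miss decoy (identical prefix, exactly enough mismatches
#' beyond base 10 to push similarity to at most 90\%). Because original
#' prefixes are unique, each original and its planted copies occupy a
#' prefix bucket of their own and the planted truth is exactly recoverable
#' by the duplicate predicate.
#'
#' @param config a [simulationConfig()].
#' @return list with \code{reads} (\code{DNAStringSet}, qualities in
#'   \code{mcols(reads)$qualities}; originals first, planted copies after)
#'   and \code{truth} (\code{data.frame}: \code{read_id},
#'   \code{original_id}, \code{type} in \code{"duplicate"}/\code{"decoy"}).
#' @export
generateReadsWithDuplicates <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed + 3L)
  L <- config$read_length
  n <- config$n_reads
  bases <- c("A", "C", "G", "T")

  if (n > 4^10 / 2)
    stop("n_reads too large for unique 10-base prefixes", call. = FALSE)
  pref_idx <- sample.int(4^10, n) - 1L
  prefixes <- vapply(pref_idx, function(v) {
    paste(bases[(v %/% 4^(9:0)) %% 4 + 1], collapse = "")
  }, character(1))
  suffixes <- vapply(seq_len(n), function(i)
    paste(sample(bases, L - 10L, replace = TRUE), collapse = ""), character(1))
  orig <- paste0(prefixes, suffixes)
  orig_id <- sprintf("read%05d", seq_len(n))

  n_dup <- round(config$dup_rate * n)
  n_dec <- round(config$decoy_rate * n)
  pick <- sample.int(n, min(n, n_dup + n_dec))
  dup_of <- pick[seq_len(n_dup)]
  dec_of <- pick[seq_len(n_dec) + n_dup]
  bounds <- .dup_mismatch_bounds(L)

  mutate_at <- function(seq, m) {
    if (m == 0L) return(seq)
    pos <- sample(11:L, m)
    ch <- strsplit(seq, "")[[1]]
    for (p in pos) ch[p] <- sample(setdiff(bases, ch[p]), 1L)
    paste(ch, collapse = "")
  }
  dups <- vapply(dup_of, function(i) {
    m <- min(rbinom(1L, L - 10L, config$mutation_rate), bounds$max_dup)
    mutate_at(orig[i], m)
  }, character(1))
  decs <- vapply(dec_of, function(i)
    mutate_at(orig[i], bounds$min_decoy), character(1))

  extra_id <- c(if (n_dup) paste0(orig_id[dup_of], "_dup"),
                if (n_dec) paste0(orig_id[dec_of], "_decoy"))
  if (is.null(extra_id)) extra_id <- character(0)
  extra_seq <- c(dups, decs)
  truth <- data.frame(read_id = extra_id,
                      original_id = orig_id[c(dup_of, dec_of)],
                      type = rep(c("duplicate", "decoy"), c(n_dup, n_dec)),
                      stringsAsFactors = FALSE)
  if (length(extra_id)) {
    ord <- sample.int(length(extra_id))
    extra_id <- extra_id[ord]; extra_seq <- extra_seq[ord]
  }
  reads <- Biostrings::DNAStringSet(c(orig, extra_seq))
  names(reads) <- c(orig_id, extra_id)
  S4Vectors::mcols(reads)$qualities <-
    Biostrings::BStringSet(rep(strrep("I", L), length(reads)))
  list(reads = reads, truth = truth)
}

#' Write reads to a FASTQ file
#'
#' @param reads \code{DNAStringSet} with qualities in
#'   \code{mcols(reads)$qualities} (constant Phred 40 is substituted when
#'   absent).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeFastqReads <- function(reads, path) {
  q <- S4Vectors::mcols(reads)$qualities
  if (is.null(q))
    q <- Biostrings::BStringSet(vapply(Biostrings::width(reads),
                                       function(w) strrep("I", w),
                                       character(1)))
  Biostrings::writeXStringSet(reads, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Read a FASTQ file into a DNAStringSet with qualities
#'
#' @param path FASTQ file.
#' @return \code{DNAStringSet}; qualities in \code{mcols()$qualities}.
#' @export
readFastqReads <- function(path) {
  Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
}
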