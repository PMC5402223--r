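#' Assemble a pipeline configuration
#'
#' Collects every stage parameter with the analysis constants as defaults:
#' dedup prefix 10 and similarity threshold 0.90, expressed-gene FPKM
#' cutoff 1, ratio thresholds 1.5 and 0.67, enrichment pseudo-count 0.05,
#' graph level cutoff 2 and gene-count cutoff 150, significance cutoff 1.0,
#' qPCR efficiency 2.0. Unknown arguments are rejected by
#' [validateConfig()].
#'
#' @param ... named overrides of the defaults; \code{sim} may be a
#'   [simulationConfig()] and \code{outdir}/\code{seed} control the run.
#' @return list of class \code{"PipelineConfig"} (not yet validated; see
#'   [validateConfig()]).
#' @export
pipelineConfig <- function(...) {
  cfg <- utils::modifyList(.default_pipeline_config(), list(...))
  class(cfg) <- "PipelineConfig"
  cfg
}

.default_pipeline_config <- function() {
  list(
    stages = c("simulate", "dedup", "quantify", "classify", "enrich",
               "graph", "qpcr"),
    prefix_len = 10L,
    sim_threshold = 0.90,
    expressed_threshold = 1,
    up_ratio = 1.5,
    down_ratio = 0.67,
    pseudo_count = 0.05,
    min_level = 2L,
    min_genes = 150L,
    sig_threshold = 1.0,
    efficiency = 2.0,
    universe = "union",
    propagate = TRUE,
    n_qpcr_genes = 12L,
    sim = NULL,           # simulationConfig(); built from seed when NULL
    inputs = list(),      # paths for non-simulated stages
    outdir = tempfile("ratioGO_run_"),
    seed = 1L)
}

#' Read a pipeline configuration from a YAML file
#'
#' Scalar fields of the YAML map onto [pipelineConfig()] arguments; an
#' optional \code{sim:} map is passed to [simulationConfig()].
#'
#' @param path YAML file.
#' @return a \code{"PipelineConfig"} list.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) y$sim <- do.call(simulationConfig, y$sim)
  do.call(pipelineConfig, y)
}

#' Validate a pipeline configuration
#'
#' Checks every invariant and returns the \emph{complete} list of
#' violations (never just the first), with the offending field named.
#' On success the validated config — defaults filled, simulation config
#' materialized — is returned.
#'
#' @param config a \code{"PipelineConfig"} (or plain list of overrides).
#' @return list with elements \code{config} (validated) and \code{errors}
#'   (character vector, empty when valid).
#' @export
validateConfig <- function(config = pipelineConfig()) {
  if (!inherits(config, "PipelineConfig"))
    config <- do.call(pipelineConfig, as.list(config))
  errs <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) errs <<- c(errs, msg)
  known <- names(.default_pipeline_config())
  extra <- setdiff(names(config), known)
  if (length(extra))
    errs <- c(errs, paste0(extra, ": unknown configuration field"))
  chk(is.numeric(config$prefix_len) && config$prefix_len >= 1,
      "prefix_len: must be >= 1")
  chk(is.numeric(config$sim_threshold) && config$sim_threshold > 0 &&
        config$sim_threshold < 1,
      "sim_threshold: must be in (0, 1)")
  chk(config$expressed_threshold >= 0,
      "expressed_threshold: must be >= 0")
  chk(config$up_ratio > 0, "up_ratio: must be > 0")
  chk(config$down_ratio > 0 && config$down_ratio < config$up_ratio,
      "down_ratio: must be in (0, up_ratio)")
  chk(config$pseudo_count > 0, "pseudo_count: must be > 0")
  chk(config$min_level >= 0, "min_level: must be >= 0")
  chk(config$min_genes >= 0, "min_genes: must be >= 0")
  chk(config$sig_threshold >= 0, "sig_threshold: must be >= 0")
  chk(config$efficiency > 1, "efficiency: must be > 1")
  chk(config$universe %in% c("union", "intersection", "all"),
      "universe: must be union, intersection or all")
  chk(all(config$stages %in% .default_pipeline_config()$stages),
      "stages: unknown stage name")
  if (is.null(config$sim)) {
    sim_try <- tryCatch(simulationConfig(seed = config$seed),
                        error = function(e) conditionMessage(e))
    if (is.character(sim_try)) errs <- c(errs, sim_try)
    else config$sim <- sim_try
  } else {
    sim_errs <- .check_sim_config(config$sim)
    errs <- c(errs, sim_errs)
  }
  list(config = config, errors = errs)
}

.stage_log <- function(manifest, stage, ...) {
  manifest$stages[[stage]] <- list(...)
  message(sprintf("[%s] %s", stage,
                  paste(names(list(...)), unlist(list(...)),
                        sep = "=", collapse = " ")))
  manifest
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order — simulate, dedup, quantify,
#' classify, enrich, graph, qpcr — writing each stage's outputs under
#' \code{config$outdir} and a JSON run manifest with the configuration
#' snapshot, per-stage record counts, package version and timestamps.
#' Given the same configuration and seed, every stage output file is
#' byte-identical across runs (the manifest's timestamps are the only
#' run-specific values).
#'
#' With the \code{"simulate"} stage disabled, input paths are taken from
#' \code{config$inputs} (\code{counts}, \code{models}, \code{obo},
#' \code{annotations}, \code{fastq}, \code{ct} as needed by the enabled
#' stages).
#'
#' @param config a \code{"PipelineConfig"}; validated before running.
#' @return the manifest, invisibly. Output files: \code{models.tsv},
#'   \code{counts.tsv}, \code{truth_genes.tsv}, \code{go.obo},
#'   \code{annotations.tsv}, \code{truth_terms.tsv}, \code{reads.fastq},
#'   \code{reads_truth.tsv}, \code{dedup.fastq}, \code{dedup_report.tsv},
#'   \code{fpkm.tsv}, \code{fpkm_mean.tsv}, \code{de_classes.tsv},
#'   \code{enrichment.tsv}, \code{graph.graphml} (+ \code{.sif},
#'   \code{_nodes.tsv}), \code{qpcr_ct.tsv}, \code{qpcr_fc.tsv},
#'   \code{manifest.json}.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  v <- validateConfig(config)
  if (length(v$errors))
    stop("invalid pipeline configuration:\n  ",
         paste(v$errors, collapse = "\n  "), call. = FALSE)
  config <- v$config
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outdir, f)
  manifest <- list(package = "ratioGO",
                   version = as.character(packageVersion("ratioGO")),
                   started = format(Sys.time(), usetz = TRUE),
                   config = config[setdiff(names(config), "sim")],
                   sim = unclass(config$sim),
                   stages = list())
  on <- function(stage) stage %in% config$stages
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE))
  }

  models <- ann <- dag <- se <- de <- NULL
  if (on("simulate")) run_stage("simulate", {
    sim <- config$sim
    models <- generateGeneModels(sim)
    se <- generateCounts(models, sim)
    writeGeneModels(models, out("models.tsv"))
    writeCountTable(se, out("counts.tsv"))
    truth <- data.frame(gene_id = rownames(se),
                        true_class =
                          SummarizedExperiment::rowData(se)$true_class)
    write.table(truth, out("truth_genes.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    go <- generateGODag(sim, genes = truth$gene_id,
                        classes = truth$true_class)
    dag <- go$dag; ann <- go$annotations
    writeOBO(dag, out("go.obo"))
    writeAnnotations(ann, out("annotations.tsv"))
    write.table(go$truth, out("truth_terms.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    reads <- generateReadsWithDuplicates(sim)
    writeFastqReads(reads$reads, out("reads.fastq"))
    write.table(reads$truth, out("reads_truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    manifest <- .stage_log(manifest, "simulate",
                            n_genes = nrow(models),
                            n_terms = nTerms(dag),
                            n_reads = length(reads$reads))
    models <- models; se <- se; dag <- dag; ann <- ann
  })

  if (on("dedup")) run_stage("dedup", {
    fq <- if (on("simulate")) out("reads.fastq") else config$inputs$fastq
    res <- dedupFastq(fq, out("dedup.fastq"), out("dedup_report.tsv"),
                      prefixLen = config$prefix_len,
                      simThreshold = config$sim_threshold)
    manifest <- .stage_log(manifest, "dedup", n_input = res@n_input,
                            n_kept = res@n_kept,
                            n_removed = res@n_removed)
  })

  if (on("quantify")) run_stage("quantify", {
    if (is.null(se)) {
      models <- readGeneModels(config$inputs$models)
      se <- makeCountSE(readCountTable(config$inputs$counts), models)
    }
    se <- computeFPKM(se)
    fpkm <- SummarizedExperiment::assay(se, "fpkm")
    write.table(data.frame(gene_id = rownames(fpkm), fpkm,
                           check.names = FALSE),
                out("fpkm.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    fm <- averageReplicates(se)
    write.table(data.frame(gene_id = rownames(fm), fm,
                           check.names = FALSE),
                out("fpkm_mean.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    manifest <- .stage_log(manifest, "quantify", n_genes = nrow(fpkm),
                            n_samples = ncol(fpkm))
  })

  if (on("classify")) run_stage("classify", {
    fm <- averageReplicates(se)
    de <- classifyDE(fm, exprThreshold = config$expressed_threshold,
                      upRatio = config$up_ratio,
                      downRatio = config$down_ratio,
                      universe = config$universe)
    write.table(de, out("de_classes.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    tb <- table(factor(de$de_class, levels = c("premature_up",
                                               "mature_up", "neither")))
    expressed <- filterExpressed(fm, config$expressed_threshold)
    manifest <- .stage_log(manifest, "classify",
                            n_universe = nrow(de),
                            n_expressed_premature =
                              length(expressed$premature),
                            n_expressed_mature = length(expressed$mature),
                            n_premature_up = as.integer(tb[["premature_up"]]),
                            n_mature_up = as.integer(tb[["mature_up"]]),
                            n_neither = as.integer(tb[["neither"]]))
  })

  enrichment <- NULL
  if (on("enrich")) run_stage("enrich", {
    if (is.null(dag)) {
      dag <- readOBO(config$inputs$obo)
      ann <- readAnnotations(config$inputs$annotations)
    }
    enrichment <- computeEnrichment(
      dag, ann,
      preGenes = de$gene_id[de$de_class == "premature_up"],
      matGenes = de$gene_id[de$de_class == "mature_up"],
      pseudo = config$pseudo_count, propagate = config$propagate)
    writeEnrichment(enrichment, out("enrichment.tsv"))
    manifest <- .stage_log(manifest, "enrich",
                            n_terms = nrow(enrichment))
  })

  if (on("graph")) run_stage("graph", {
    gr <- buildEnrichmentGraph(dag, enrichment,
                               minLevel = config$min_level,
                               minGenes = config$min_genes,
                               sigThreshold = config$sig_threshold)
    exportGraph(gr, out("graph"))
    manifest <- .stage_log(manifest, "graph",
                            n_nodes = nrow(graphNodes(gr)),
                            n_visible = sum(graphNodes(gr)$visible),
                            n_edges = nrow(graphEdges(gr)))
  })

  if (on("qpcr")) run_stage("qpcr", {
    ct <- if (!is.null(config$inputs$ct)) {
      read.delim(config$inputs$ct, stringsAsFactors = FALSE)
    } else {
      # validation panel emulation: Ct derived deterministically from the
      # averaged FPKM of the strongest DE calls (one cycle per 2-fold)
      panel <- de[order(-abs(log2(pmin(pmax(de$ratio, 1e-6), 1e6)))), ]
      panel <- head(panel, config$n_qpcr_genes)
      data.frame(gene_id = panel$gene_id,
                 ct_premature = 30 - log2(panel$fpkm_pre + 1),
                 ct_mature = 30 - log2(panel$fpkm_mat + 1),
                 stringsAsFactors = FALSE)
    }
    write.table(ct, out("qpcr_ct.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    fc <- qpcrFoldChanges(ct, efficiency = config$efficiency)
    write.table(fc, out("qpcr_fc.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    manifest <- .stage_log(manifest, "qpcr", n_genes = nrow(fc))
  })

  manifest$finished <- format(Sys.time(), usetz = TRUE)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}
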