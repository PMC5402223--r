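se_from_counts <- function(counts, lengths, conditions, replicates) {
  genes <- sprintf("g%d", seq_len(nrow(counts)))
  long <- do.call(rbind, lapply(seq_len(ncol(counts)), function(j)
    data.frame(gene_id = genes, condition = conditions[j],
               replicate = replicates[j], count = counts[, j])))
  makeCountSE(long, data.frame(gene_id = genes, length = lengths))
}

test_that("FPKM matches its definition", {
  # count 100, length 1 kb, library 1e6 -> FPKM 100
  se <- se_from_counts(cbind(c(100, 999900)), c(1000, 3000),
                       "premature", 1)
  fpkm <- SummarizedExperiment::assay(computeFPKM(se), "fpkm")
  expect_equal(fpkm["g1", 1], 100)
  # count 250, length 2.5 kb, library 5e6 -> FPKM 20
  se2 <- se_from_counts(cbind(c(250, 4999750)), c(2500, 1000),
                        "premature", 1)
  expect_equal(SummarizedExperiment::assay(computeFPKM(se2),
                                           "fpkm")["g1", 1], 20)
  # zero count -> zero FPKM
  se3 <- se_from_counts(cbind(c(0, 10)), c(500, 500), "premature", 1)
  expect_equal(SummarizedExperiment::assay(computeFPKM(se3),
                                           "fpkm")["g1", 1], 0)
})

test_that("empty libraries and unknown genes are rejected", {
  se <- se_from_counts(cbind(c(0, 0)), c(500, 500), "premature", 1)
  expect_error(computeFPKM(se), "zero total")
  expect_error(
    makeCountSE(data.frame(gene_id = "gX", condition = "premature",
                           replicate = 1, count = 5),
                data.frame(gene_id = "g1", length = 100)),
    "absent from the gene models")
  expect_error(
    makeCountSE(data.frame(gene_id = "g1", condition = "premature",
                           replicate = 1, count = -2),
                data.frame(gene_id = "g1", length = 100)),
    "non-negative")
})

test_that("FPKM is invariant to scaling a replicate's counts", {
  set.seed(31)
  for (i in 1:20) {
    counts <- matrix(rpois(60, 50) + 1, ncol = 2)
    se <- se_from_counts(counts, sample(500:2000, 30),
                         c("premature", "premature"), c(1, 2))
    f1 <- SummarizedExperiment::assay(computeFPKM(se), "fpkm")
    k <- runif(1, 0.5, 10)
    counts2 <- counts; counts2[, 1] <- counts2[, 1] * k
    se2 <- se_from_counts(counts2, SummarizedExperiment::rowData(se)$length,
                          c("premature", "premature"), c(1, 2))
    f2 <- SummarizedExperiment::assay(computeFPKM(se2), "fpkm")
    expect_equal(f1[, 1], f2[, 1], tolerance = 1e-12)
  }
})

test_that("replicate averaging is the arithmetic mean per condition", {
  counts <- cbind(c(10, 1), c(20, 1), c(0, 1), c(4, 1))
  se <- se_from_counts(counts, c(1000, 1000),
                       c("premature", "premature", "mature", "mature"),
                       c(1, 2, 1, 2))
  # bypass the depth normalization by checking the mean structure directly
  se <- computeFPKM(se)
  fpkm <- SummarizedExperiment::assay(se, "fpkm")
  fm <- averageReplicates(se)
  expect_equal(fm["g1", "premature"],
               mean(fpkm["g1", c("premature_rep1", "premature_rep2")]))
  expect_equal(fm["g1", "mature"],
               mean(fpkm["g1", c("mature_rep1", "mature_rep2")]))
  # single replicate: identity
  se1 <- computeFPKM(se_from_counts(cbind(c(7, 3)), c(500, 800),
                                    "premature", 1))
  expect_equal(averageReplicates(se1)[, "premature"],
               SummarizedExperiment::assay(se1, "fpkm")[, 1])
})

test_that("expressed filter is strictly greater than the threshold", {
  fm <- fpkm_matrix(c(1.0, 1.001, 0, 5), c(2, 0.5, 0, 1.0))
  ex <- filterExpressed(fm)
  expect_false("g1" %in% ex$premature)  # exactly 1.0: excluded
  expect_true("g2" %in% ex$premature)
  expect_false("g3" %in% ex$premature)  # all-zero gene
  expect_false("g3" %in% ex$mature)
  expect_false("g4" %in% ex$mature)     # exactly 1.0 on the mature side
  expect_true("g1" %in% ex$mature)
})

test_that("ratio classification uses the printed thresholds, strictly", {
  fm <- fpkm_matrix(pre = c(3.0, 1.0, 1.5, 2.0, 4.0, 0.0, 0.67 * 2, 1.36),
                    mat = c(1.0, 2.0, 1.0, 3.0, 0.0, 2.0, 2.0, 2.0))
  de <- classifyDE(fm)
  cls <- setNames(de$de_class, de$gene_id)
  expect_equal(cls[["g1"]], "premature_up")   # ratio 3 > 1.5
  expect_equal(cls[["g2"]], "mature_up")      # ratio 0.5 < 0.67
  expect_equal(cls[["g3"]], "neither")        # ratio exactly 1.5
  # 0.67 is taken literally (not 1/1.5): 2/3 = 0.6667 < 0.67 -> mature_up
  expect_equal(cls[["g4"]], "mature_up")
  expect_equal(cls[["g5"]], "premature_up")   # mature 0 -> +Inf ratio
  expect_equal(de$ratio[de$gene_id == "g5"], Inf)
  expect_equal(cls[["g6"]], "mature_up")
  expect_equal(cls[["g7"]], "neither")        # ratio exactly 0.67
  expect_equal(cls[["g8"]], "neither")        # 0.68: inside the band
})

test_that("genes unexpressed in both conditions are outside the universe", {
  fm <- fpkm_matrix(pre = c(0.5, 3), mat = c(0.9, 1))
  de <- classifyDE(fm)
  expect_false("g1" %in% de$gene_id)
  expect_true("g2" %in% de$gene_id)
  # universe variants
  expect_equal(nrow(classifyDE(fm, universe = "all")), 2)
  fm2 <- fpkm_matrix(pre = c(3, 3), mat = c(0.5, 2))
  expect_equal(nrow(classifyDE(fm2, universe = "intersection")), 1)
})

test_that("classes partition the universe for random tables", {
  set.seed(32)
  for (i in 1:50) {
    fm <- fpkm_matrix(pre = round(rlnorm(40, 1, 2), 3),
                      mat = round(rlnorm(40, 1, 2), 3))
    de <- classifyDE(fm)
    expect_equal(nrow(de), sum(fm[, 1] > 1 | fm[, 2] > 1))
    expect_true(all(de$de_class %in%
                      c("premature_up", "mature_up", "neither")))
    tb <- table(factor(de$de_class,
                       c("premature_up", "mature_up", "neither")))
    expect_equal(sum(tb), nrow(de))
  }
})

test_that("label swap maps classes antisymmetrically outside the 1/1.5..0.67 band", {
  set.seed(33)
  fm <- fpkm_matrix(pre = rlnorm(500, 1, 1.5), mat = rlnorm(500, 1, 1.5))
  de <- classifyDE(fm)
  # build the swap explicitly: premature column <- mature and vice versa
  fm_sw <- fm[, c("mature", "premature")]
  colnames(fm_sw) <- c("premature", "mature")
  sw <- classifyDE(fm_sw)
  cls <- setNames(de$de_class, de$gene_id)
  cls_sw <- setNames(sw$de_class, sw$gene_id)
  common <- intersect(names(cls), names(cls_sw))
  r <- setNames(de$ratio, de$gene_id)[common]
  # thresholds are asymmetric: 0.67 is not 1/1.5, so only genes whose
  # ratio avoids (1/1.5, 0.67) on either side swap cleanly
  clean <- r > 1.5 | r < 1 / 1.5
  expected <- ifelse(cls[common] == "premature_up", "mature_up",
                     ifelse(cls[common] == "mature_up", "premature_up",
                            "neither"))
  expect_identical(unname(cls_sw[common][clean]),
                   unname(expected[clean]))
  # inside the asymmetric band the swap is NOT class-symmetric:
  band <- r >= 1 / 1.5 & r < 0.67  # empty by construction (1/1.5 > 0.67)
  expect_equal(sum(band), 0)
})

test_that("planted DE classes are recovered at low dispersion", {
  cfg <- simulationConfig(n_genes = 2000, dispersion = 0.02,
                          abundance_sdlog = 0, true_fold = 2, seed = 34)
  se <- computeFPKM(generateCounts(generateGeneModels(cfg), cfg))
  de <- classifyDE(averageReplicates(se))
  truth <- setNames(SummarizedExperiment::rowData(se)$true_class,
                    rownames(se))
  planted <- names(truth)[truth != "unchanged"]
  got <- setNames(de$de_class, de$gene_id)[planted]
  recovery <- mean(!is.na(got) & got == truth[planted])
  expect_gte(recovery, 0.95)
})

test_that("count tables round-trip through TSV", {
  cfg <- simulationConfig(n_genes = 40, seed = 35)
  se <- generateCounts(generateGeneModels(cfg), cfg)
  tf <- tempfile(fileext = ".tsv")
  writeCountTable(se, tf)
  back <- makeCountSE(readCountTable(tf),
                      data.frame(gene_id = rownames(se),
                                 length =
                                   SummarizedExperiment::rowData(se)$length))
  expect_equal(SummarizedExperiment::assay(back, "counts"),
               SummarizedExperiment::assay(se, "counts") * 1.0)
})
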