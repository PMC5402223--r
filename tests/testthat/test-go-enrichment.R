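# a small hand-checkable DAG:
#   root (BP)
#   ├── a            ├── b
#   │    └── c (also child of b)
#   │         └── d
chain_dag <- function() {
  ids <- c("GO:0000001", "GO:0000002", "GO:0000003", "GO:0000004",
           "GO:0000005")
  names <- c("root", "a", "b", "c", "d")
  parents <- list(character(0), "GO:0000001", "GO:0000001",
                  c("GO:0000002", "GO:0000003"), "GO:0000004")
  names(parents) <- ids
  methods::new("GODag",
               terms = data.frame(term_id = ids, name = names,
                                  namespace = "BP",
                                  stringsAsFactors = FALSE),
               parents = parents)
}

test_that("minimal OBO files round-trip the DAG", {
  g <- generateGODag(simulationConfig(seed = 41))
  tf <- tempfile(fileext = ".obo")
  writeOBO(g$dag, tf)
  back <- readOBO(tf)
  expect_equal(goTerms(back), goTerms(g$dag))
  expect_equal(goParents(back)[goTerms(g$dag)$term_id],
               goParents(g$dag)[goTerms(g$dag)$term_id])
})

test_that("OBO parser skips obsolete terms and strips is_a comments", {
  tf <- tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: root",
    "namespace: biological_process", "",
    "[Term]", "id: GO:0000002", "name: alive",
    "namespace: biological_process",
    "is_a: GO:0000001 ! root", "",
    "[Term]", "id: GO:0000003", "name: gone",
    "namespace: biological_process",
    "is_a: GO:0000001", "is_obsolete: true", "",
    "[Typedef]", "id: part_of"), tf)
  dag <- readOBO(tf)
  expect_setequal(goTerms(dag)$term_id, c("GO:0000001", "GO:0000002"))
  expect_equal(goParents(dag)[["GO:0000002"]], "GO:0000001")
  expect_equal(goTerms(dag)$namespace, c("BP", "BP"))
})

test_that("a cyclic is_a graph is rejected naming a cycle member", {
  ids <- c("GO:0000001", "GO:0000002", "GO:0000003")
  parents <- list(character(0), "GO:0000003", "GO:0000002")
  names(parents) <- ids
  expect_error(
    methods::new("GODag",
                 terms = data.frame(term_id = ids, name = ids,
                                    namespace = "BP"),
                 parents = parents),
    "cycle")
})

test_that("annotation propagation closes over is_a ancestors", {
  dag <- chain_dag()
  ann <- list(g1 = "GO:0000001",            # root only
              g2 = "GO:0000005",            # depth-3 chain member
              g3 = c("GO:0000002", "GO:0000003"))
  prop <- propagateAnnotations(dag, ann)
  expect_setequal(prop$g1, "GO:0000001")
  expect_setequal(prop$g2, c("GO:0000005", "GO:0000004", "GO:0000002",
                             "GO:0000003", "GO:0000001"))
  expect_setequal(prop$g3, c("GO:0000002", "GO:0000003", "GO:0000001"))
  # superset of direct annotation, and idempotent
  for (g in names(ann)) expect_true(all(ann[[g]] %in% prop[[g]]))
  expect_equal(lapply(propagateAnnotations(dag, prop), sort),
               lapply(prop, sort))
  expect_error(propagateAnnotations(dag, list(g = "GO:9999999")),
               "unknown term")
})

test_that("closure equals brute-force reachability on random DAGs", {
  for (seed in 51:56) {
    dag <- random_dag(sample(10:60, 1), seed)
    ann <- random_annotations(dag, 15, seed + 100)
    prop <- propagateAnnotations(dag, ann)
    for (g in names(ann)) {
      expected <- unique(c(ann[[g]],
                           unlist(lapply(ann[[g]], naive_ancestors,
                                         parents = goParents(dag)))))
      expect_setequal(prop[[g]], expected)
    }
  }
})

test_that("term counting matches hand enumeration on a small fixture", {
  dag <- chain_dag()
  ann <- list(g1 = "GO:0000005", g2 = "GO:0000004", g3 = "GO:0000002",
              g4 = "GO:0000003", g5 = character(0))
  prop <- propagateAnnotations(dag, ann)
  expect_message(tc <- termCounts(paste0("g", 1:5), prop), "dropped")
  # hand enumeration: c covers g1,g2; a covers g1,g2,g3; b covers g1,g2,g4
  expect_equal(tc$total, 4)
  expect_equal(tc$counts[["GO:0000001"]], 4)  # root absorbs all annotated
  expect_equal(tc$counts[["GO:0000002"]], 3)
  expect_equal(tc$counts[["GO:0000003"]], 3)
  expect_equal(tc$counts[["GO:0000004"]], 2)
  expect_equal(tc$counts[["GO:0000005"]], 1)
  empty <- termCounts(character(0), prop)
  expect_equal(empty$total, 0)
  expect_equal(length(empty$counts), 0)
})

test_that("enrichment score reproduces its closed form, with zero protection", {
  expect_equal(enrichmentScore(10, 100, 5, 100), log2(10.05 / 5.05),
               tolerance = 1e-15)
  expect_equal(enrichmentScore(10, 100, 5, 100), 0.9928, tolerance = 1e-3)
  expect_equal(enrichmentScore(0, 100, 5, 100), log2((0.05 / 100.05) /
                                                       (5.05 / 100.05)),
               tolerance = 1e-15)
  expect_equal(enrichmentScore(0, 100, 5, 100), -6.658, tolerance = 1e-2)
  # equal frequencies with equal totals: exactly zero
  expect_equal(enrichmentScore(7, 50, 7, 50), 0)
  expect_error(enrichmentScore(0, 10, 1, 10, pseudo = 0), "pseudo")
  expect_error(enrichmentScore(-1, 10, 1, 10), "non-negative")
})

test_that("score approaches the raw frequency ratio as pseudo-count vanishes", {
  raw <- log2((12 / 80) / (30 / 90))
  for (p in c(0.05, 1e-4, 1e-8))
    expect_lt(abs(enrichmentScore(12, 80, 30, 90, pseudo = p) - raw),
              abs(enrichmentScore(12, 80, 30, 90, pseudo = 0.05) - raw) +
                1e-12)
  expect_equal(enrichmentScore(12, 80, 30, 90, pseudo = 1e-10), raw,
               tolerance = 1e-6)
})

test_that("enrichment results cover carried terms only, sorted and antisymmetric", {
  g <- generateGODag(simulationConfig(seed = 42))
  pre <- grep("^A", names(g$annotations), value = TRUE)
  mat <- grep("^B", names(g$annotations), value = TRUE)
  e1 <- suppressMessages(computeEnrichment(g$dag, g$annotations, pre, mat))
  e2 <- suppressMessages(computeEnrichment(g$dag, g$annotations, mat, pre))
  expect_true(all(e1$n_pre + e1$n_mat > 0))
  m <- match(e1$term_id, e2$term_id)
  expect_equal(e1$score, -e2$score[m], tolerance = 1e-12)
  expect_false(is.unsorted(e1$namespace))
  for (ns in unique(e1$namespace))
    expect_false(is.unsorted(-e1$score[e1$namespace == ns]))
  expect_warning(computeEnrichment(g$dag, g$annotations, character(0),
                                   character(0)), "empty")
})

test_that("planted frequency skews score in the planted direction", {
  g <- generateGODag(simulationConfig(seed = 43))
  pre <- grep("^A", names(g$annotations), value = TRUE)
  mat <- grep("^B", names(g$annotations), value = TRUE)
  enr <- suppressMessages(computeEnrichment(g$dag, g$annotations, pre, mat))
  sc <- setNames(enr$score, enr$term_id)[g$truth$term_id]
  expect_true(all(sign(sc) == g$truth$expected_sign))
})

test_that("propagated counts are monotone along is_a edges", {
  g <- generateGODag(simulationConfig(seed = 44))
  pre <- grep("^A", names(g$annotations), value = TRUE)
  prop <- propagateAnnotations(g$dag, g$annotations)
  tc <- suppressMessages(termCounts(pre, prop))
  cnt <- function(id) if (id %in% names(tc$counts)) tc$counts[[id]] else 0L
  for (id in goTerms(g$dag)$term_id)
    for (p in goParents(g$dag)[[id]])
      expect_gte(cnt(p), cnt(id))
})

test_that("annotation tables round-trip through TSV", {
  g <- generateGODag(simulationConfig(seed = 45))
  tf <- tempfile(fileext = ".tsv")
  writeAnnotations(g$annotations, tf)
  back <- readAnnotations(tf, genes = names(g$annotations))
  expect_identical(lapply(g$annotations, sort), lapply(back, sort))
})
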