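---
title: "ratioGO: methods and design notes"
author: "ratioGO authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ratioGO: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratioGO)
```

# The analysis this package implements

ratioGO re-implements, as tested and reusable components, a bulk RNA-seq
comparison of two ovary developmental stages in the ascidian *Ciona
intestinalis* — premature (1.5-month) versus mature (4-month) ovaries, two
pooled-RNA replicate samples per stage. The original analysis chain is:

1. **PCR-duplicate removal** from single-end 101-base reads: two reads are
   duplicates when their first 10 bases are identical and whole-read
   similarity is strictly above 90%.
2. **FPKM quantification** per replicate, arithmetic averaging of the
   replicates within each stage, and an expressed-gene filter at FPKM
   strictly above 1.
3. **Ratio-threshold differential expression**: the premature/mature FPKM
   ratio classifies a gene as premature-upregulated (ratio > 1.5),
   mature-upregulated (ratio < 0.67), or neither.
4. **GO enrichment scoring**: for every GO term, the log2 ratio of its
   frequency among premature-up genes to its frequency among mature-up
   genes, with a fixed pseudo-count of 0.05, rendered on the GO "is_a"
   graph with node size = gene count and node color = score.
5. **ΔCt qPCR validation**: fold change `2^ΔCt` with
   `ΔCt = Ct(mature) − Ct(premature)`.

No statistical test appears anywhere in this chain — the DE calls are pure
ratio thresholds and the enrichment score is a descriptive log-ratio, not a
p-value. The package keeps that character deliberately and adds nothing.

# The enrichment score

For a term $t$, let $n_{pre}(t)$ and $n_{mat}(t)$ be the numbers of
premature-up and mature-up genes annotated (after propagation) to $t$, and
$N_{pre}$, $N_{mat}$ the numbers of genes in each set with at least one GO
mapping. With pseudo-count $p = 0.05$:

$$\mathrm{Enrich}(t) \;=\; \log_2
\frac{\bigl(n_{pre}(t)+p\bigr)\big/\bigl(N_{pre}+p\bigr)}
     {\bigl(n_{mat}(t)+p\bigr)\big/\bigl(N_{mat}+p\bigr)}$$

Design choices that were genuinely open:

* **Pseudo-count placement.** The source method states only that a
  pseudo-count of 0.05 was used. Adding it to all four quantities keeps the
  score finite for any non-negative counts and — more importantly —
  preserves exact antisymmetry: swapping the two gene sets negates every
  score, which is what the red/blue duality of the original graph view
  expresses. A counts-only placement is available
  (`placement = "counts_only"`).
* **Totals.** $N_X$ counts the set-X genes with at least one GO mapping;
  genes without any annotation are dropped from totals and reported via a
  message. `totalMode = "all"` uses the full set sizes instead.
* **Propagation.** Annotations are closed upward over is_a edges before
  counting (`propagate = TRUE`), because counting genes at internal nodes
  of the ontology graph only makes sense hierarchically; the closure makes
  per-term counts monotone along edges (a parent's count is never below a
  child's). Only is_a edges are honored; `part_of` and other OBO relations
  are ignored at parse time. A no-propagation mode exists for direct
  counts.

# Graph view rules

`buildEnrichmentGraph()` reproduces the figure conventions:

* **GO level** is the shortest is_a path from a term up to its namespace
  root, with the root at level 0. (The source does not define "level"; the
  `minLevel` cutoff is a plain parameter, so a root-at-1 convention is one
  knob away.)
* Terms with level < 2 or fewer than 150 genes (strict comparisons, counts
  from both DE sets combined after propagation) are kept in the graph but
  get `display_size = 0`; visibility rules never alter the stored score or
  count.
* Branches with no "significantly enriched" term are pruned. The source
  never defines significance — there is no test in the method — so it is
  operationalized as $|\mathrm{Enrich}| \ge$ `sigThreshold`, default 1.0
  (a two-fold frequency ratio). This default is a package convention, not
  a quantity from the method.
* Export is GraphML plus Cytoscape SIF/attribute files. The writer
  serializes doubles with round-trip (`%.17g`) precision so that
  `readGraphML()` reproduces the graph bit-for-bit; layout and actual
  drawing are left to Cytoscape or any graph viewer.

# Duplicate removal

The duplicate predicate is taken literally: identical 10-base prefix AND
similarity strictly greater than 0.90. Similarity is positional identity —
matching bases at aligned positions divided by the longer read's length —
with no indel alignment, the natural reading for fixed-cycle Illumina
reads; the metric sits behind `readSimilarity()` and can be swapped.
Deduplication buckets reads by prefix and scans each bucket in input
order, keeping the first member of every duplicate cluster; this greedy
policy is deterministic, idempotent, and provably identical to the
brute-force all-pairs keep-first scan (the prefix clause makes buckets
independent), which the test suite verifies against an independently coded
oracle. Adaptor trimming and quality filtering, though part of the
original preprocessing, are out of scope here: no adaptor sequences or
quality thresholds are stated, so there is nothing faithful to implement.

One contradiction in the source description is worth recording: the run is
described as single-end sequencing of 101 cycles, yet the read yield is
described as "101 paired-end reads". The package implements single-end
semantics throughout.

# FPKM and classification

$\mathrm{FPKM}_g = c_g \cdot 10^9 / (L_g \cdot T)$ with $T$ the sum of the
replicate's per-gene counts — the count table itself is the read universe,
the simplest self-contained reading since the original denominator (all
reads vs mapped reads) is unstated. Per-replicate FPKM values are averaged
within a condition; pooling counts before FPKM would halve shot noise
identically and is not separately offered. The classification universe is
the union of the two expressed sets (FPKM > 1 in at least one condition);
intersection and all-genes variants sit behind `universe=`. The thresholds
are used exactly as printed: 1.5 and 0.67 — note 0.67 ≠ 1/1.5, so the
"neither" band is asymmetric and a ratio of 2/3 = 0.6667 *is* a mature-up
call. A zero mature FPKM with positive premature FPKM yields a +Inf ratio
and a premature-up call, keeping the three classes a partition.

# What the synthetic generator emulates

`simulationConfig()` defaults encode the emulated study design: 2
conditions × 2 replicates, 2,000 gene models with lengths uniform on
500–5,000 bases, library size 200,000 (mean count 100 per gene),
negative-binomial counts with dispersion 0.1, 10% of genes planted
two-fold up in each direction, log-normal baseline abundance spread
(sdlog 1), a 120-term three-namespace GO DAG of depth 4 with three terms
per direction planted at a 2× annotation-frequency skew (0.6 vs 0.3), and
400 original 101-base reads with 20% planted duplicates and 10% boundary
decoys. These sizes keep a full pipeline run in seconds while leaving
every per-stage signal comfortably above its detection threshold.

Choices worth explaining:

* **Dispersion parameterization.** Counts are negative-binomial in the
  mean–dispersion form standard in RNA-seq (variance
  $\mu + \alpha\mu^2$); the Poisson limit is $\alpha \to 0$. Dispersion
  0.1 is a typical bulk-tissue value.
* **Fold planting on the FPKM scale.** A planted gene's expected
  premature/mature *FPKM* ratio equals `true_fold`. The fold is applied
  symmetrically ($\sqrt{f}$ up in one condition, $\sqrt{f}$ down in the
  other) and the up/down fractions default to equal, so the two
  conditions' library compositions balance and the depth normalization
  does not shift unchanged genes off ratio 1.
* **A hard limit of ratio-threshold classification.** The per-replicate
  coefficient of variation of NB counts is at least $\sqrt{\alpha}$
  regardless of the mean, so with $\alpha = 0.1$ and two replicates the
  log-ratio of condition means has a standard deviation of ≈ 0.32 natural
  log units. A true two-fold change then clears the 1.5 threshold only
  ~80% of the time, *no matter how deeply one sequences*. The package's
  recovery diagnostics compute exactly this number; near-complete
  (≥ 95%) recovery of two-fold changes requires dispersion ≲ 0.02, which
  the unit suite demonstrates. This is a property of the thresholding
  method itself, worth knowing before using it on real two-replicate
  designs.
* **Planted GO skews sit on childless terms** at level ≥ 2: direct
  annotations in real data land on specific terms, and planting on leaves
  means upward propagation cannot dilute the planted frequency contrast
  with background annotations inherited from descendants.
* **Planted duplicates and decoys.** Originals receive mutually distinct
  10-base prefixes, so each original and its planted copies form their own
  prefix bucket and the planted truth is exactly recoverable. Duplicates
  mutate only beyond base 10, with the mismatch count capped to keep
  similarity strictly above 90%; decoys carry exactly the smallest
  mismatch count that pushes similarity to ≤ 90%, deliberately pinning the
  strict-inequality boundary (9 vs 10 mismatches for 100-base reads).
* **Between-replicate variance** defaults to zero: each replicate sample
  of the emulated design is already a pool of three animals, and the
  source gives no basis for a biological-variance estimate. The
  `between_rep_sd` knob exists for sensitivity exploration.

What the generator does **not** emulate: positional sequencing-error and
quality profiles, adaptor contamination, transcript-level multi-mapping,
correlated annotation structure between related GO terms, or
composition-biased (asymmetric) DE fractions. Passing tests therefore
certify the pipeline's logic and numerics, not its behavior on artifacts
real libraries may carry.

# qPCR quantification

ΔCt = Ct(mature) − Ct(premature), so positive values mean higher premature
expression, and fold change is `efficiency^ΔCt` with ideal per-cycle
doubling (`efficiency = 2`) as the default; no efficiency calibration is
described in the source, and no reference-gene (ΔΔCt) normalization is
applied because plain ΔCt is what is described (equal 10-ng template per
reaction). Measurements at or above the 44-cycle program cap are
non-detects and are excluded with a warning. In the synthetic pipeline the
qPCR stage derives a deterministic Ct panel from the averaged FPKM of the
strongest DE calls (one cycle per two-fold), which makes the stage's fold
changes consistent with the RNA-seq ratios by construction — it validates
plumbing, not measurement noise.

# Numerical and degenerate-input policy

* All threshold comparisons (prefix similarity 0.90, expressed FPKM 1,
  ratios 1.5/0.67, visibility 2/150) are strict, matching their printed
  forms; boundary values fall on the keep/neither/hidden side.
* Zero-total libraries, empty gene sets, unknown gene or term identifiers
  and cyclic ontologies are rejected with named errors; configuration
  validation returns *all* violations at once, naming each field.
* `GODag` validity enforces acyclicity (Kahn elimination), parent
  resolution and namespace closure at construction time.
* The pipeline is deterministic given configuration and seed: every stage
  output file is byte-identical across runs. The run manifest is the one
  exception, as it records wall-clock timestamps.

# Problem sizes used by the test suite

The suite runs entirely on generated data: dedup oracle sweeps use 50
instances of ≤ 200 reads; FPKM scale-invariance uses 1,000 random tables;
enrichment arithmetic is checked on 10,000 random count tuples;
propagation is checked on 100 random DAGs of up to 200 terms; the planted
GO-skew recovery runs 100 seeded simulations with 200 genes per DE set;
DE recovery runs on 2,000-gene simulations. These sizes were chosen so the
whole suite completes in about two minutes while keeping every Monte-Carlo
margin wide.

# Known limitations

* The ratio thresholds carry no error model; see the dispersion discussion
  above for the practical consequence on two-replicate designs.
* The enrichment score has no significance calibration; the `sigThreshold`
  used for branch pruning is a rendering convention.
* Single-end duplicate semantics only; paired-end duplicate logic is out
  of scope.
* The OBO interface is deliberately minimal (`id`, `name`, `namespace`,
  `is_a`, `is_obsolete`); richer ontology features (relationship types,
  cross-namespace links, term subsets) are ignored.
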