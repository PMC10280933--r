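---
title: "Methods: co-dysregulated ceRNA network inference with cernascope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-dysregulated ceRNA network inference with cernascope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The analysis in one paragraph

Competing-endogenous-RNA (ceRNA) analysis asks which lncRNAs could regulate
which mRNAs indirectly, by soaking up the miRNAs that would otherwise repress
those mRNAs. `cernascope` operationalizes this for a two-group (case vs
control) expression study: (1) call differential lncRNAs and mRNAs with
fold-change and p-value gates; (2) among differential genes, keep lncRNA–mRNA
pairs whose expression profiles are almost perfectly correlated; (3) promote a
pair to a ceRNA **triple** (lncRNA, miRNA, mRNA) when user-supplied interaction
tables show the lncRNA and the mRNA share that miRNA; (4) analyze the
resulting tripartite network for hub lncRNAs, and the protein–protein
interaction (PPI) context of its mRNAs for hub genes and dense modules;
(5) score enrichment of the implicated mRNAs; and (6) intersect the evidence
streams into a small set of core genes. A seeded synthetic-data generator
plants every one of these structures with known ground truth, so the full
chain is testable end to end without any external data.

## Differential expression

Expression values are normalized log2 intensities. For each gene the case and
control groups are compared with Welch's unequal-variance t-test; the linear
fold change is the ratio of geometric group means, `2^(mean_case −
mean_ctrl)`. A gene is called **up** when fold change ≥ `fc_up` (default 2.0)
and p < `alpha` (default 0.05), **down** when fold change ≤ `fc_down`
(default 0.5) and p < `alpha`; both fold-change boundaries are inclusive. No
multiple-testing correction is applied at this stage — downstream gates
consume raw p-values, and the fold-change gate is what controls the practical
false-positive rate (at the generator's noise level of 0.25 log2 units, a
null gene essentially never reaches a two-fold mean shift with n = 4 + 4).

Vendor microarray pipelines rarely document their test; Welch's t is used
here as a transparent, assumption-light default, and the moderated
(empirical-Bayes) alternatives are deliberately out of scope. Degenerate
zero-variance inputs follow a stated convention (equal constant groups
→ p = 1; unequal constant groups → p = 0) rather than erroring mid-pipeline.
Non-finite expression values are rejected at load time, never imputed.

## Co-expression screening

Every differential lncRNA is correlated with every differential mRNA across
**all** samples, case and control pooled: the co-dysregulation signal of
interest is precisely the shared group-contrast. Pairs are kept when Pearson
r > 0.97 (strict, signed) and p < 0.01, with p from the exact-null t
transform `t = r·sqrt(n−2)/sqrt(1−r²)`. At n = 8 the r gate already implies
p ≈ 5·10⁻⁵, so the p gate is redundant in the default design but enforced as
stated. Whether such screens should use signed or absolute correlation is
genuinely ambiguous in the field; the signed gate is the default (a ceRNA
relationship predicts positive co-expression) and `use_absolute = TRUE` is
provided for the other reading. Zero-variance genes are skipped with a
message, not an error.

## Triple assembly and network analytics

A triple (l, m, g) is included iff (l, g) survived the co-expression gate,
l→m is in the lncRNA–miRNA table and m→g is in the miRNA–mRNA table. The
network is exactly the union of included triples — no lncRNA–mRNA edges
exist, and every node supports at least one triple. Degree counts incident
edges, so a lncRNA's degree equals its number of distinct mediating miRNAs;
hub lncRNAs are those with degree strictly greater than 20. Interaction
tables are treated as opaque inputs (target prediction is out of scope) and
duplicate rows are silently de-duplicated with a logged count.

The core-gene step is a generic named n-set intersection
(`core_mrnas()`), because published descriptions of this merge vary between
two- and three-set variants; the pipeline's default intersects the mRNAs of
the top hub lncRNA's subnetwork, the hub mRNAs of the ceRNA-restricted PPI
(degree ≥ 4, inclusive), and the whole-PPI hubs (degree > 20, strict).

## PPI modules (MCODE)

PPI edges arrive with a combined confidence score in [0, 1]; edges below 0.7
are dropped (inclusive boundary), duplicates keep the maximum score. Dense
modules are found with a seed-and-grow procedure: each vertex is weighted by
the highest k-core of its closed neighborhood times that core's density;
complexes grow from the highest-weight unused seed, admitting neighbors whose
weight is within `node_score_cutoff` (default 0.2) of the seed's, to a
maximum depth of 100. Modules must contain a 2-core; haircut (default on)
iteratively strips singly-connected members; fluff is off by default. The
degree cutoff 2 / k-core 2 / max depth 100 parameters are the stated
analysis settings, and 0.2/haircut/no-fluff are the algorithm's published
defaults, exposed in the configuration. All tie-breaks are lexicographic in
node id, which makes module membership reproducible regardless of input
order. Module score is density × size.

## Enrichment statistics

Over-representation uses the hypergeometric upper tail
p = P(overlap ≥ k | N, K, n) with Benjamini–Hochberg adjustment across the
tested sets of a collection; the universe defaults to all mRNAs on the
matrix. Gene sets are plain GMT inputs; no ontology-graph propagation is
performed.

GSEA uses the weighted Kolmogorov–Smirnov running sum: hits add
`|metric|^exponent` (normalized over the in-set total), misses subtract
`1/(N − N_set)`; the enrichment score is the signed maximum deviation. The
permutation null reshuffles **gene labels**, not phenotypes: with 4 samples
per group only 35 distinct label splits exist, far too few for a phenotype
null, so gene permutation is the only null offered and this choice is
surfaced prominently rather than buried. Empirical p-values use +1 smoothing
and are therefore never exactly zero. Internally the permuted scores are
computed from hit positions alone (the walk's extremes can only occur
immediately after a hit or immediately before the next one), which is an
exact O(set size) shortcut, verified against the explicit running sum.

## qPCR validation statistics

Relative quantification follows 2^−ΔΔCt with group means (the design is
unpaired): ΔCt = Ct_target − Ct_reference per sample, ΔΔCt = mean ΔCt(case) −
mean ΔCt(control), fold = 2^−ΔΔCt. Group comparison uses the Mann–Whitney U
test: exact when the pooled sample is ≤ 12 and tie-free, otherwise the normal
approximation with tie and continuity correction — an 8 vs 8 validation
cohort therefore takes the approximation branch, and both branches are
tested. Efficiency correction (Pfaffl) is out of scope.

## What the synthetic generator emulates — and what it does not

`generate_dataset()` draws per-gene baseline log2 means uniform on [6, 12]
(a plausible array intensity range) with Gaussian per-sample noise
(sd 0.25), for 2000 mRNAs and 500 lncRNAs over 4 case and 4 control samples.
It plants, with a single RNG stream per seed:

* 60 differential mRNAs and 30 differential lncRNAs shifted by ±2 log2 units
  in the case group, half up, half down;
* co-expressed pairs by **profile sharing** — a paired mRNA copies its
  lncRNA's finished profile plus noise of sd 0.02, guaranteeing the r > 0.97
  gate is reachable at n = 8 and that the pair shares a direction (a
  latent-factor model would make gate attainment a tuning exercise);
* 40 ceRNA triples, of which 30 fan out from one designated hub lncRNA
  through 30 distinct miRNAs over 5 partner mRNAs — so the hub's degree (30)
  clears the > 20 gate while all other planted lncRNAs stay near degree 1;
* an 8-member PPI clique over triple-partner mRNAs with scores in
  [0.90, 1.0), plus ~25 high-confidence "spoke" partners per clique member
  (real PPI hubs are high-degree, and this gives the whole-network
  degree > 20 hub gate something to find) and sparse background edges with
  scores uniform on [0.2, 0.8], most of which the 0.7 filter removes;
* one gene set enriched for up-regulated planted mRNAs among 19 random sets.

miRNAs get no expression values — they enter only through the interaction
tables, mirroring a lncRNA/mRNA array design. Background interaction rows
appear at rate 0.002 per possible pair.

The generator does **not** emulate probe-level artifacts, batch effects,
normalization residue, heavy-tailed noise, correlated null genes, or
miRNA-expression dynamics. Passing recovery tests therefore demonstrates
that the pipeline's gates and graph logic do what they claim under the
stated statistical structure — not that the gates are optimal for any real
platform.

## Numerical and testing choices

* Boundary conventions are taken literally and tested: fold change ≥ 2.0 is
  inclusive, PCC > 0.97 and hub degree > 20 are strict, PPI score ≥ 0.7 and
  ceRNA-PPI degree ≥ 4 are inclusive.
* |r| = 1 maps to p = 0 by convention; r is clamped to [−1, 1] against
  floating-point overshoot before the t transform.
* All output tables are sorted deterministically and floats written with 6
  significant digits; fixed seed + config gives byte-identical output trees
  (verified by checksum in the suite).
* Stage results are cached under the output directory keyed by an md5 of the
  serialized stage inputs; a rerun with unchanged inputs reuses every stage.
* Test problem sizes: oracle checks run on exhaustive small spaces (all
  hypergeometric configurations to N = 15, all tie-free rank patterns to
  n = 12, 500 random graphs to 10 nodes); recovery and calibration checks
  use 20 seeds of the default 2500-gene design (≥ 50,000 null gene-tests),
  and 100,000-draw permutation estimates back the Welch and Pearson
  p-values at n = 50 per group, where asymptotic and permutation nulls
  coincide to Monte-Carlo precision.

## Known limitations

* The co-expression gate at n = 8 is extremely aggressive; with near-perfect
  planted correlation it is reliable, but on real data r > 0.97 at n = 8 has
  wide sampling error and the retained set should be read as candidates, not
  conclusions.
* Same-direction differential genes share the group contrast, so some
  non-planted differential pairs also clear the correlation gate — visible
  in the synthetic runs and inherent to the method, not a defect of the
  implementation.
* Gene-permutation GSEA tests a different null than phenotype-permutation
  GSEA (gene–gene correlation is destroyed); its p-values are well
  calibrated against that null only.
* The MCODE growth rule confines each node to one module; overlapping
  complexes are not represented unless `fluff` is enabled.
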