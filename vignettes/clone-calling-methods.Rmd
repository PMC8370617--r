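---
title: "Clone calling and diversity analysis for SNP-fingerprinted germplasm collections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clone calling and diversity analysis for SNP-fingerprinted germplasm collections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonecall)
```

## The problem

National germplasm collections of clonally propagated crops (cassava,
yam, sweetpotato, banana) are assembled by collecting named varieties from
farmers' fields. Farmer names are unreliable identifiers: the same clone
circulates under many names, and one name can cover several clones. Before
a collection can be conserved, deduplicated material must be identified
from its DNA. This package implements that workflow for biallelic SNP
fingerprints stored as allele dosages (0, 1, 2 copies of the alternate
allele), together with the diversity and farmer-knowledge summaries that
typically accompany such a study.

## The estimator

Two samples of the same clone should be genetically identical, but three
processes separate their fingerprints in practice:

* *heterozygote miscalling*: at low sequencing depth a true heterozygote is
  read as one of the homozygotes (the dominant error mode of
  high-multiplexing, sequence-based genotyping);
* *missing calls*, which change the set of loci a pair is compared on;
* *somatic mutation* between different plants of one clone.

The pairwise **Hamming (allele-sharing) distance** is
$d_{ij} = \sum_l |g_{il} - g_{jl}| \,/\, (2\,n_{ij})$, summed over loci
called in both samples, with $n_{ij}$ the number of such loci. A
heterozygote/homozygote mismatch counts 1 allele, opposite homozygotes
count 2, so $d$ is the fraction of mismatching alleles. Pairwise-complete
normalisation (dividing by the pair's shared loci rather than a global
locus count) follows the identity-by-state convention and keeps the
distance unbiased under per-sample missingness; the price is that the
triangle inequality is not guaranteed, which is why tests assert symmetry
and the $[0,1]$ bound but not metricity.

How far apart can two samples of *one* clone be? That is an empirical
question, and the workflow answers it with **replicate pairs**: biological
replicates (different plants of a named clone) and technical replicates
(repeat genotyping of one plant) carried through the same genotyping run.
The duplicate threshold is calibrated as the smallest multiple of the
reporting granularity (default 0.001) *strictly above* the maximum
replicate-pair distance, so every known same-clone pair falls below it. A
replicate maximum of 0.02112 therefore yields a threshold of 0.022. The
strictly-above rule also resolves the edge case of a maximum sitting
exactly on the grid (0.021 steps up to 0.022).

`call_clones()` then merges every pair with $d <$ threshold and takes
connected components (**single linkage**). Single linkage is the right
reading of "groups of the same clone": duplicate calling must be
transitive, and the dendrogram-cut picture of duplicate groups implies
chained merging. The alternative (complete linkage) would refuse groups in
which two peripheral members happen to exceed the threshold even though
both match the centre well — with genotyping error that situation is
expected for well-collected clones. The result is an S3 object
(`clone_partition`) with `print`, `summary` and `plot` methods; `plot`
draws the average-linkage dendrogram with the threshold line.

Each group is represented by its member with the fewest missing calls
(ties broken by smallest sample id — the rule is not biologically
meaningful, only deterministic). Groups containing a reference landrace
inherit its identity; groups with two distinct references expose reference
synonym pairs; collected samples identical to a reference *breeding line*
are misfiled improved material and are excluded from landrace accounting
before uniqueness is counted.

`zone_summary()` reproduces the standard per-zone accounting: a unique
landrace is counted in every zone where it was collected, so the column
total exceeds the global unique count whenever sharing occurs.

## Diversity and structure

* **Shannon index** is computed on clone-abundance counts per zone,
  $H = -\sum_i p_i \ln p_i$ in nats. Clone abundances (how often each
  multilocus genotype was collected in the zone) are the only reading under
  which the index is bounded by $\ln(\text{clones in zone})$, which is how
  such values are interpreted in collection reports.
* **Fst** defaults to the Weir–Cockerham (1984) estimator: per-locus
  variance components $a$ (among zones), $b$ (among individuals) and $c$
  (within individuals) from dosage-derived genotype counts, combined as the
  multilocus ratio of sums $\hat\theta = \sum_l a_l / \sum_l (a_l+b_l+c_l)$.
  A Nei-style $G_{ST}$ estimator is available as an option. By default the
  estimate uses the deduplicated set (one collected representative per
  clone per zone): clonal copies are repeated observations of one genotype,
  and treating them as independent samples would bias allele frequencies
  toward over-collected clones. A flag restores the all-samples behaviour.
* **Nei's (1972) standard distance** between zone allele-frequency vectors
  uses ratio-of-sums aggregation of the gene identities across loci, the
  standard definition; per-locus $-\ln$ would be undefined at fixed
  differences. When the normalised identity underflows to zero the distance
  is clamped at a configurable maximum (default 10) with a warning.
* **Neighbor joining** is implemented directly (Saitou–Nei agglomeration
  with the Studier–Keppler Q criterion) because the package commits to an
  explicit negative-branch policy: a negative branch arising at a join is
  clamped to zero and its deficit transferred to the sister branch, which
  preserves path lengths through the join. On additive matrices the input
  tree is recovered exactly (tested to 1e-9); `ape::nj` serves as an
  independent cross-check in the test suite.
* **PCA/DAPC**: ordination needs complete data, so missing calls are
  mean-imputed per locus (the default behaviour of the standard DAPC
  tooling); loci are centred, not scaled. DAPC is linear discriminant
  analysis on the retained PCA scores with zones as priors; with $k$ groups
  at most $k-1$ discriminant functions exist and all are retained — no
  axis-count optimisation is attempted since the analysis convention is a
  fixed 100 PCA axes.
* **Minimum spanning network**: the MST over clone representatives (one
  node per multilocus genotype) plus every non-tree edge whose weight ties,
  within a tolerance (default 1e-9), the heaviest edge on the tree path
  between its endpoints — exactly the edges that could replace a tree edge
  in some other minimum spanning tree. Tie detection uses one tree
  traversal per node ($O(n^2)$ total), so collection-sized networks are
  immediate.

## The farmer survey

Key-informant records score nine traits on a 0–5 scale where **0 means
"don't know"**, not "very bad". For correlations the package therefore
treats 0 as missing by default; a policy flag includes them, covering the
other possible reading of published correlation values. Use classification
follows the fresh/flour rule: both uses cited anywhere in the
primary/secondary/tertiary list → dual purpose; one alone → that class;
neither → unknown. Percentages are reported raw and rounded half-up (the
integer style of survey reports). Respondent summaries band land access at
<1, 1–4.9, 5–9.9, ≥10 acres and growing experience at <5, 5–19, 20–49,
≥50 years, with "not stated" kept as a category where surveys report it.

## The synthetic-data generator

There is no public truth for a real collection, so correctness is
demonstrated on generated collections with known clone structure
(`simulate_population()`):

* zone allele frequencies follow the **Balding–Nichols** model,
  $p_z \sim \mathrm{Beta}(p(1-F)/F,\,(1-p)(1-F)/F)$, around an ancestral
  frequency drawn uniformly from 0.05–0.5 (a post-MAF-filter SNP panel)
  with target differentiation $F = 0.05$ by default, inside the 0.01–0.07
  range of zone contrasts reported for such collections;
* founder clones are Binomial(2, $p_z$) draws at their home zone; a default
  12% of clones is also planted in a second zone so sharing statistics have
  known truth, and the copies-per-clone distribution has mean ≈ 1.5
  (a 427-samples-to-277-clones collection ratio);
* every observed copy independently applies the asymmetric error model —
  heterozygotes miscalled as either homozygote with total probability
  ε = 0.01 — and 2% missing calls; biological replicates additionally
  resample each locus with probability μ = 0.001 (somatic mutation). A
  symmetric error option is deliberately absent: the read-depth artifact
  only destroys heterozygotes.
* `simulate_survey()` draws trait scores by thresholding a latent Gaussian
  with a configured correlation matrix into five equal-probability levels,
  then masks scores to 0 at the don't-know rate. The default latent
  cooking-quality/taste correlation of 0.90 gives discretised scores with
  an observed association near 0.82, the strength typical of farmer
  ratings; zone-specific fresh-vs-flour propensities mirror the coastal
  (fresh) versus inland (flour) split.

One root seed drives everything; the survey uses the `seed + 8191`
substream so the two generators can be re-run independently.

What the generator does *not* emulate: linkage disequilibrium between loci,
per-sample quality heterogeneity (every sample shares one ε), population
admixture within zones, and name semantics. Passing recovery tests
therefore demonstrate the estimator's behaviour under the stated error
model, not robustness to structured artifacts in real DArTSeq data.

## Numerical choices and problem sizes

* Threshold grid arithmetic uses a relative tolerance of 1e-6 of the
  granularity so that floating-point representation of a maximum on a grid
  point cannot produce a non-strict threshold.
* Distances are computed with dosage-class indicator matrix products (six
  `tcrossprod` calls), exact and fast at collection scale.
* The clone-recovery experiment in the test suite runs 20 seeds at 1000
  loci with ε = 0.01, μ = 0.001, 5% missing calls and a threshold
  calibrated from five replicate pairs, and requires the true partition
  (ARI = 1) in at least 19 of 20 seeds. In that experiment duplicated
  clones are planted with five collected copies. The choice is deliberate:
  within-clone pair distances follow the same distribution as the
  calibration pairs, so a threshold set just above the maximum of five
  replicate pairs leaves a two-copy clone a non-trivial chance of a false
  split — no threshold rule can simultaneously sit above all same-clone
  pairs and be estimated from five of them. Single linkage makes
  well-collected clones robust (a five-copy clone splits only if a member
  fails against all four others), and heavily duplicated landraces are
  exactly what such collections contain. The study-scale demonstration in
  `scripts/acceptance.R` keeps the realistic copies distribution (mostly
  1–2 copies) and reports the achieved ARI rather than asserting 1.
* The Fst recovery experiment uses 7 zones × 50 founders × 1000 loci × 20
  seeds; the acceptance script's study-scale emulation uses 280 founder
  clones and 5000 loci, sizes at which the whole pipeline completes in
  seconds while keeping Monte-Carlo error well inside the tested
  tolerances.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 42, n_loci = 1000, clones_per_zone = 10,
                  n_reference_landraces = 8, n_breeding_lines = 3,
                  n_breeding_matches = 1)
sim <- simulate_population(cfg)

qc   <- apply_qc(sim$genotypes)
D    <- hamming_distance(qc$genotypes)
rd   <- replicate_pair_distances(D, sim$metadata)
thr  <- calibrate_threshold(rd)
part <- call_clones(D, thr, G = qc$genotypes)
summary(part)
evaluate_recovery(part, sim)

zone_summary(part, sim$metadata)
zone_diversity(part, sim$metadata)
```

## Known limitations

* Clone calling is deterministic given the threshold; no probabilistic
  error model or per-pair confidence is provided.
* Pairwise-complete distances can, in principle, break transitivity of
  near-identity when missingness is extreme; the QC step (5% locus, 5.5%
  sample caps) is what keeps this negligible.
* Fst and Nei distances assume biallelic loci and ignore linkage.
* The survey generator draws respondents independently of genotypes; joint
  genotype-by-knowledge analyses are out of scope.
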