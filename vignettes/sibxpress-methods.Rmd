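---
title: "Models and methods behind sibxpress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sibxpress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sibxpress)
```

# The design and what the package screens for

Two divergently selected chicken breeds (broiler and layer) are crossed,
F1 brother–sister pairs are mated, and F2 progeny are profiled by RNA-seq
(spleen; bone-marrow-derived macrophages with and without 24 h LPS). The
inbreeding step drives alleles hidden by heterozygosity toward
homozygosity. Under Mendelian transmission with the F1 pair drawn at
random (no genotype selection), a variant heterozygous in exactly one
grandparent is homozygous in 1/16 of F2 birds; a variant fixed for
opposite alleles in the two breeds makes every F1 heterozygous, so 1/4 of
F2 birds are homozygous for either allele. `f2_genotype_probs()`
enumerates these probabilities exactly over the 3 × 3 F1 genotype pairs;
`simulate_f2_genotype_freqs()` re-derives them by explicit gene-drop
simulation through a pedigree, one independent F1 sibling pair per
replicate. The two routes agree within binomial error and that agreement
is asserted in the test suite.

A homozygous null expression allele shows up in the transcriptome as a
gene with *extreme variation among birds*: detectable expression in most
individuals (max > 20 TPM) but essentially absent in the homozygous-null
ones (min < 1 TPM). Heterozygotes sit near half of the functional
homozygote level because cis effects on expression are, to good
approximation, additive. The screening statistics in
`expression-stats` formalize that reading; the network stage separates
co-regulated modules (trans effects, contaminating cell types) from
gene-by-gene cis variation.

# The generative model

`simulate_cross()` composes four stages, each reseeded from a named
substream of the master seed so stages are independently reproducible.

**Founders and architecture** (`simulate_founders()`). Each gene gets one
biallelic cis locus. A fraction `breed_fixed_fraction` of loci is
near-fixed for opposite alleles: realized alternative-allele frequency at
least 0.95 in one breed and at most 0.05 in the other, enforced by
construction (the field describes such loci as "almost fixed" without a
number; 0.95/0.05 is the package's operational definition and the
`breed_frequency_contrast()` default). A fraction `het_null_fraction` of
autosomal genes carries a null allele — cis effect exactly 0 — present as
a single heterozygote in one founder, the configuration that produces the
1/16 expectation. `low_expression_allele_effect` turns nulls into
hypomorphs for sensitivity studies. One dedicated breed-fixed autosomal
locus acts as trans regulator of the LPS-inducible module.

**Pedigree and transmission** (`build_pedigree()`, `gene_drop()`). F0
pairs are broiler × layer with alternating cross direction; each family
has one F1 male and one F1 female (full sibs) and its F2 birds, sexes
1:1 at random. Transmission is per-locus Mendelian: one allele per parent
chosen uniformly; sons receive a Z from each parent, daughters the
father's Z and the mother's W. Linkage is not modelled (single-locus
treatment throughout; multi-locus LD is out of scope).

**Expression** (`simulate_expression()`). The expected TPM of gene *g* in
sample *s* is a product of four terms:

* *cis*: the sum of per-allele-copy effects at the gene's cis locus. The
  functional allele contributes baseline/2 per copy (baseline drawn
  log-uniformly on `baseline_tpm_range`), a null allele exactly 0 — so a
  heterozygote is the exact midpoint of the homozygote classes at zero
  noise, and that identity is tested.
* *dosage*: Z genes sum over two copies in males and one in females, the
  female value then multiplied by `dosage_compensation_factor` *d* ∈
  [1, 2]. The expected male/female ratio is 2/*d*: *d* = 1 gives the
  uncompensated 2-fold ratio, *d* = 2 full compensation, *d* = 4/3 (the
  default) the ≈1.5-fold median seen in hatchling spleen. W genes carry
  their full baseline on the single female copy and emit exactly 0 in
  males.
* *LPS*: treated samples multiply by 2^lfc. Responsive genes draw the
  magnitude of lfc from `location + scale·|N(0,1)|` (half-normal above a
  floor, so "induced" genes cannot straddle zero), signed by class. For
  trans-module genes the lfc is multiplied by
  `trans_effect_per_alt_allele` once per alternative allele the bird
  carries at the trans locus, making module induction co-vary across
  birds — the signature the network stage recovers.
* *mesenchyme*: module genes scale with the sample's contamination
  fraction, drawn uniformly on `mesenchyme_fraction_range` (default
  0.2–0.5, a deliberately generous contamination range for primary
  marrow cultures).

The realized value multiplies the expectation by `2^N(0, noise_sd_log2)`.
The default noise SD of 0.2 log2 units reproduces the max/min regime of
stable reference genes (≈1.3–1.6 over ~18 birds, checked against an
order-statistics argument in the tests); no claim is made that real TPM
noise is log-normal — it is simply the simplest multiplicative model, and
counts-level dispersion is out of scope since the pipeline consumes TPM.

**TPM compositionality.** Columns are *not* renormalized to 10^6 by
default: planted effects stay exactly recoverable, which is the point of
a ground-truth simulator. `renormalize_tpm = TRUE` opts into the
compositional coupling of real TPM (non-mesenchyme genes scaled by 1 −
fraction).

**Cohort shape.** The default design is 15 families totalling 28 F2
birds (sizes 6, 2×8, 1×6), each bird profiled once untreated and once
with LPS (56 samples), with 400 autosomal, 200 Z and 20 W genes and 200
non-genic variants. This mirrors the real study's 15-family design and
its 6-versus-22 family contrast while staying small enough that the full
suite runs in seconds; all counts are configurable.

# Thresholds and their boundaries

| Parameter | Default | Semantics |
|---|---|---|
| site quality | 30 | variant kept iff qual ≥ 30 |
| genotype quality | 15 | call masked iff GQ < 15 |
| missingness | 0.20 | variant dropped iff rate > 0.20 |
| near-fixation | 0.95 / 0.05 | AF ≥ 0.95 in one breed, ≤ 0.05 in the other |
| detection | 10 TPM | gene kept iff max ≥ 10 (removal when max < 10) |
| extreme variation | 20 / 1 | max > 20 **and** min < 1, both strict |
| LPS response | 2-fold | induced iff fold > 2, repressed iff fold < 1/2 |
| contrast | 1.5 / 0.67 | up iff ratio > 1.5, down iff ratio < 0.67 |
| contrast eligibility | 1 TPM | at least one group mean > 1 |
| graph threshold | 0.97 / 0.85 | sample-to-sample / gene-to-gene Pearson r |
| MCL inflation | 1.7 | coarse granularity for one cell type |

"Min." thresholds pass at equality; the printed fold and ratio cutoffs
are strict, exactly as written (0.67 is used literally, not 1/1.5 — the
difference is a configurable knob). Every boundary has a dedicated
single-value test.

**Pseudocounts.** Raw max/min ratios are reported without pseudocount,
with an `Inf` sentinel when min = 0 and both extremes preserved; a
finite companion (`ratio_pseudo`, +0.5 TPM on both extremes) sits beside
it. The LPS fold change always adds 0.5 TPM to both group means so the
boundary semantics are uniform; the family contrast adds the pseudocount
only when the denominator mean is exactly 0, keeping the swap symmetry
(target↔rest maps ratio to 1/ratio) exact otherwise.

# Numerical and algorithmic choices

**Dosage grouping** (`classify_dosage_groups()`). Samples are sorted on
log2(TPM + 0.5) and exhaustively partitioned into 1–3 contiguous groups;
the score is the total within-group sum of squares plus `penalty` per
extra group. The default penalty 0.5 (squared log2 units) separates the
two regimes that matter: a spurious split of pure noise at SD 0.2 gains
roughly 0.2, while a true heterozygote/homozygote split (1 log2 unit)
gains at least m₁m₂/(m₁+m₂) ≥ 0.58 even at group sizes 1 and 2. Ties
prefer fewer groups. The additivity score |m_mid − (m_low + m_high)/2| /
m_high is 0 for perfectly additive 0/1/2-copy expression; a group whose
raw mean falls below 1 TPM is the candidate-null class. The exhaustive
search is mirrored by an independent enumeration oracle in the tests.

**MCL** (`mcl()`). Canonical Markov clustering on the weighted adjacency
matrix: self-loop weight equal to the node's maximum incident weight,
column-stochastic normalization, then alternating expansion (matrix
square) and inflation (entrywise power 1.7, renormalization) with
entries below 1e−5 pruned, until successive matrices differ by < 1e−6 in
max-norm (cap 200 iterations; non-convergence returns the current
clustering with a warning, never silently). Clusters are connected
components of the attractor structure, renumbered by size descending
with ties broken by smallest member id; clusters below 3 members are
reported as unclustered, matching the granularity at which cluster
tables are usually read. Edge weights are the correlations themselves
(binarization available by flag, since the graph tool convention is not
documented); correlations are computed on untransformed TPM by default
with a log2(TPM+1) option. An independent, deliberately plain MCL
implementation in the test suite must produce identical partitions on a
battery of clique and planted-partition fixtures.

**Enrichment.** The DAVID-style annotation step is replaced by local
hypergeometric upper-tail tests against a caller-supplied universe with
Benjamini–Hochberg adjustment — exact, offline, and verified against
explicit pmf summation.

**PCA.** Genotypes are coded as 0/1/2 alternative-allele dosage
(hemizygous 0/1), missing calls mean-imputed per variant (frequencies
elsewhere use non-missing denominators instead — imputation is confined
to the PCA), centred, and decomposed with `prcomp`. Constant variants
contribute nothing after centring.

# What the simulator does and does not establish

The generator reproduces the *statistical structure* the analysis
assumes: additive cis effects, Mendelian segregation through the actual
pedigree, partial Z compensation, sex-restricted W expression, a
genotype-modulated inducible module, and a contamination gradient. It
does not attempt read-level realism: no sequencing error, no
count-level dispersion, no TPM compositional coupling (by default), no
linkage, no selection or viability effects (a low-fitness family is an
analysis target, not a simulated mechanism), and no annotation noise.
Passing the recovery tests therefore shows the *screens are correct
given the model*, not that the model captures every property of real
RNA-seq; the variance structure of real TPM noise in particular is a
placeholder the user can tune.

One consequence surfaces in evaluation: W-chromosome genes satisfy the
extreme-variation criterion trivially (structurally zero in males), so
`planted_null_recovery()` tallies flagged W genes separately rather than
as false nulls — the same reason real analyses report chromosome class
next to the flag and treat W-linked max/min outliers as a class of their
own.

# Interfaces

Genotype panels are long tibbles (variant × sample rows with `a1`, `a2`,
`gq`); expression is a wide tibble (`gene` column + one column per
sample) with sample and gene sheets. VCF 4.2 output and vcfR-based input
(multi-allelic records split to biallelic), TSV bundles for expression,
edge lists for graphs. `run_pipeline()` is the end-to-end entry point:
YAML/list configuration with unknown keys rejected, per-stage logging,
deterministic output including a JSON summary carrying the package
version, config hash and seed. The exported functions and this
pipeline are the package's interface; `scripts/acceptance.R` is a thin
shell wrapper that recomputes the headline quantities.

# Problem sizes

The shipped defaults — 28 birds, 620 genes, 200,000 gene-drop
replicates for segregation checks, 200 Z genes for compensation
recovery, 20 fixture graphs for the MCL cross-check — were chosen so
the entire suite completes in well under a minute while keeping
Monte-Carlo error far below the decision thresholds (binomial SE at
200,000 replicates is ~5×10⁻⁴ against a 1/16 target; the compensation
median at 200 genes and noise 0.2 is stable to ±0.02).

# Known limitations

* Single-locus transmission: no recombination map, no linked-marker
  haplotypes, so hitch-hiking effects cannot be simulated.
* The trans model modulates a single module through one locus;
  polygenic trans architectures are out of scope.
* `sex_ratio_analysis()` requires at least two samples per sex and
  works on group means; very small groups make the bootstrap
  compensated-flag conservative.
* MCL inflation monotonicity (more clusters at higher inflation) is a
  known heuristic tendency, observed on the fixtures but not asserted
  as an invariant.
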