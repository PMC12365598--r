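---
title: "Bin-based linkage mapping and QTL analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bin-based linkage mapping and QTL analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`binqtl` implements a genotype-to-QTL pipeline for an F1 progeny of two
outbred parents ("pseudo-testcross" design), built for dense SNP data from
whole-genome resequencing, where the decisive practical problem is the
volume of erroneous and missing genotype calls. The pipeline is:

1. **Filtering and AHB recoding** (`filter_genotypes()`): biallelic sites,
   informative parents, Mendelian masking, offspring missingness,
   segregation-distortion rules; then the split into two 1:1 parental
   datasets and one 1:2:1 combined dataset.
2. **Bin correction** (`phase_markers()`, `build_bins()`, `make_onebin()`):
   the core error-control device — physically contiguous markers sharing
   one segregation pattern are grouped into bins whose consensus genotype
   overrides isolated miscalls.
3. **Map construction** (`group_markers()`, `build_map()`, `detect_ibd()`):
   two-point linkage grouping, Kosambi distances along physical order,
   identity-by-descent (IBD) gap accounting.
4. **QTL analysis** (`scan_interval_mapping()`, `permutation_threshold()`,
   `lod_support_interval()`, `classify_gene_action()`,
   `map_major_gene()`, `report_qtls()`).
5. **Color scoring** (`fit_fcs()`, `cross_validate_fcs()`, `predict_fcs()`):
   a linear model mapping colorimeter CIELAB readings to a continuous
   fruit color score (FCS).
6. **Phenotype statistics** (`trait_summary()`, `trait_correlations()`,
   `broad_sense_h2()`, `early_late_compare()`, `expression_screen()`).
7. **Synthetic data** (`sim_config()`, `simulate_f1_population()`, ...):
   a first-class generator emulating the cross design, so every stage is
   testable without any external download.

# The cross design and marker classes

Both parents of an F1 cross are heterozygous at different subsets of
sites. After AHB coding (A and B the two homozygotes, H the heterozygote),
three marker classes exist:

* heterozygous in parent 1 only — segregates 1:1 in the progeny and maps
  parent 1's meioses (a backcross-like, "BC", design);
* heterozygous in parent 2 only — 1:1, maps parent 2;
* heterozygous in both — 1:2:1 ("F2"-like), informative for both meioses
  at half the per-marker information.

## Filter cascade

Applied in a fixed order (the cascade is idempotent): keep biallelic
records; drop markers with a missing parental call or two homozygous
parents; set progeny calls inconsistent with the parental pair to missing
(e.g. B from A×H); drop markers whose progeny missingness *exceeds* 20%
(a marker at exactly 20% is kept); then drop markers with a single progeny
genotype, f(A) > 0.9, f(A) < 0.1, or f(H) < 0.15, all computed among
non-missing progeny.

One subtlety: the f(A) bounds are stated on the A class, with no mirrored
f(B) rule. Applied to raw reference-oriented calls they would discard every
H×B-type marker (whose progeny segregate {H, B}, so f(A) = 0). The AHB
conversion step therefore orients labels per marker (`recode_ahb()`): at
1:1 markers the homozygous parent's class is relabeled A, a pure renaming
applied consistently to the whole marker. The printed thresholds are then
applied literally.

# Bin correction

## Phasing the 1:1 data

For a 1:1 dataset, each progeny call is H or the homozygote, i.e. one bit
naming which parental haplotype was transmitted — but the bit's sense
flips from marker to marker with the arbitrary allele orientation.
`phase_markers()` automates visual phasing greedily along physical order:
a marker's 0/1 coding is flipped iff more than half of co-called
individuals disagree with the previous phased marker (ties keep the
current phase). After phasing, each individual's state sequence along a
chromosome is piecewise constant except at genuine recombinations and at
genotyping errors. The 1:2:1 dataset is not phased (the two parental
contributions are indistinguishable at class level); `align_f2_labels()`
only harmonizes A/B label orientation between adjacent markers using
homozygous co-calls.

Manual curation of visibly aberrant markers is automated as
`drop_divergent_markers()`: a marker is removed when it disagrees with the
element-wise majority of its four nearest phased neighbours in more than
20% of individuals (a package default, exposed as an argument;
repositioning of markers is deliberately not attempted).

## The double-recombination rule

Within one individual, a run of states that reverts to the flanking state
on both sides implies two recombinations in a short interval — far more
often a genotyping error than a true double crossover. `detect_breakpoints()`
accepts such a run as real only if it contains **at least 2 contiguous
markers** and its first-to-last marker span is **at least 100 kb**;
otherwise all its calls are flagged as errors and absorbed by the
surrounding run. Terminal runs (no reversion) are single recombinations
and are always accepted. Rejection and re-merging iterate to a fixed
point. For three-state (1:2:1) data, a run whose two flanks differ (e.g. H
between A and B) is a genuine transition zone and is never a
double-recombination candidate; a direct A↔B adjacency is treated as
containing an unobserved H, and both flanks are kept.

## Bins and the one-bin matrix

Bin boundaries are the union, over individuals, of accepted breakpoints;
markers between consecutive boundaries form exactly one bin (every marker
belongs to exactly one bin). Each bin's consensus state per individual is
the majority of its non-error, non-missing member calls. The one-bin
matrix (`make_onebin()`) keeps one row per bin named by its first
(topmost) marker; the representative's missing calls, error-flagged
calls, and calls contradicting the majority of the other members are
replaced by that majority (an undefined, tied majority leaves the call
as is, or missing if it was missing). In single-marker bins, calls
flagged as rejected double recombinations become missing — there is no
consensus to overrule them.

The property this machinery buys, verified in the test suite at N = 100
with 500 markers, a 50 cM chromosome, 1% genotyping error and 5% missing
data: the one-bin map length stays close to the simulated truth while the
same map built from unbinned markers inflates several-fold, because every
isolated miscall masquerades as a double recombination.

# Map construction

Two-point recombination fractions: for BC data, the recombinant fraction
among co-called pairs with LOD
$n_R\log_{10}(2\hat r)+n_{NR}\log_{10}(2(1-\hat r))$; for F2 data, EM over
the standard phase-unknown intercross likelihood, with coupling/repulsion
resolved by likelihood and LOD taken against $r=1/2$. Linkage groups are
single-linkage components over pairs with LOD at or above the threshold
(default 19, suited to hundreds of individuals; groups are labeled by
their majority chromosome). Within groups, bins are ordered by physical
position — regression-based marker ordering is intentionally out of
scope, which is a stated limitation: the map inherits any errors of the
physical assembly. Distances accumulate consecutive-pair $\hat r$ through
the Kosambi function $d = 25\ln\frac{1+2r}{1-2r}$ cM; undefined pairs
contribute zero with a warning and $\hat r \ge 0.5$ is clamped at a
configurable 49.9 cM.

Regions without polymorphic markers spanning ≥ 2.5 Mb are reported as
possibly IBD (`detect_ibd()`), including telomeric gaps — the near-whole
chromosome IBD blocks real cultivars show imply end gaps must count.
Coverage is the first-to-last mapped marker span as a percentage of the
declared chromosome length.

# QTL analysis

Interval mapping is implemented as **Haley–Knott regression** — the
standard regression approximation to full interval-mapping maximum
likelihood, near-equivalent at moderate effect sizes: at each scan
position (1 cM step), the phenotype is regressed on the expected additive
score (BC) or expected additive and dominance scores (F2) computed from
flanking-bin genotypes through a no-interference Markov model with
Kosambi-inverted recombination fractions. At a fully observed marker this
reduces exactly to class-mean regression (an oracle test asserts equality
to 1e-9). $\mathrm{LOD} = \frac n2\log_{10}(\mathrm{RSS}_0/\mathrm{RSS}_1)$
and $\%EV = 100(1-\mathrm{RSS}_1/\mathrm{RSS}_0)$.

Effects follow the field conventions: for 1:2:1 data $a = (A-B)/2$ and
$d = H-(A+B)/2$ from fitted class means; for 1:1 data $a = A - H$. Note
that for 1:1 scans the underlying states are phased haplotype labels, so
the *sign* of $a$ is defined only up to the chromosome's phase
orientation. Gene action is classified from $|d/a|$: ≤ 0.25 additive (A),
(0.25, 0.75] partly dominant (PD), (0.75, 1.25] dominant (D), and — a band
the convention leaves open, closed here — > 1.25 overdominant (OD). Band
edges fall to the lower-dominance class; $a = 0$ yields `n/a`.

Significance uses a genome-wide permutation test: phenotypes are permuted
against genotypes jointly across the genome, the maximum LOD per
permutation is recorded, and the threshold is the empirical
$1-\alpha$ quantile (default $\alpha = 0.05$, 10 000 permutations; the
tests use 1000). Support intervals drop one LOD unit from the peak,
mapped to the flanking bins' physical positions, and are truncated at the
beginning of an IBD region when they extend into one. Binary
(major-gene) traits can also be placed directly as pseudo-markers
(`map_major_gene()`), reporting the bin with the fewest mismatches under
a global label swap; a best mismatch rate above 0.20 flags the trait
unlinked (random traits sit near 0.5, true linkage with a few percent
phenotyping error well below 0.05).

When the same region is scanned on all three maps, `report_qtls()`
applies the precedence rules of the design: among maps where the QTL is
significant, report the entry with the highest LOD; discard regions
significant only in the combined map, since a QTL genuinely segregating
in a parent must show in that parent's map.

# Fruit color score

The FCS model is ordinary least squares,
$\mathrm{FCS} = b_0 + b_1 L + b_2 a^* + b_3 b^*$, trained on fruit graded
against a 10-level color card. The protocol is a uniform random 70/30
train/test split (stratified-by-grade splitting is available as an
option since grades are banded), 5-fold cross-validation on the training
subset reporting mean ± sd of $R^2$, MAE and RMSE, and a final refit on
the full training subset evaluated on the held-out 30%. $R^2$ is
$1-\mathrm{SS}_{res}/\mathrm{SS}_{tot}$ on the evaluation set; MAE ≤ RMSE
always (Jensen), asserted in the tests. Prediction is the linear formula;
scores beyond the training grade range are permitted but flagged as
extrapolation.

# Phenotype statistics

Normality is assessed by Shapiro–Wilk; correlations default to Pearson
with pairwise-complete observations. Broad-sense heritability uses a
one-way random-effects decomposition with genotype as the random factor
and years as replicates: $\sigma^2_E = \mathrm{MS}_W$,
$\sigma^2_G = (\mathrm{MS}_B - \mathrm{MS}_W)/n_0$ with the standard
unbalanced-design $n_0$, and $H^2 = \sigma^2_G/(\sigma^2_G+\sigma^2_E)$
clamped to [0, 1]. The source convention behind published $H^2$ values
for such designs is not fully specified, so agreement with any particular
published number is not claimed; the formula is documented and its limit
behaviour ($H^2 \to 1$ for year-stable traits, $\to 0$ for pure noise) is
tested. The early/late maturity comparison dichotomizes at a given
maturity-date cutoff and applies a one-tailed Welch t-test (early darker
than late). The expression screen drops genes whose combined FPKM — the
*sum* of per-stage, per-parent mean FPKM, the literal reading of
"combined", exposed as a switch — is at or below 10, then runs per-stage
Welch t-tests between parents and flags genes with any stage below
$\alpha = 0.05$.

# The synthetic-data generator

`sim_config()` defaults describe the emulated study design: an F1 progeny
of 235 individuals; eight chromosomes with approximate peach chromosome
lengths; Poisson crossover counts per meiosis (default mean 0.6 per
chromosome) placed uniformly with no interference; parent-specific IBD
intervals inside which that parent is homozygous at every marker (one
large block per parent by default, echoing the near-whole-chromosome IBD
of related cultivars); uniform random genotype flips (default 1%) and
missing-data injection (default 5%); QTL effects acting through the
nearest marker's true genotype as +a / d / −a; CIELAB color triplets
generated so a specified linear combination reproduces a latent 1–10
grade, with grading noise on the recorded grade. All randomness flows
from one seed through deterministic per-stage derived seeds, so any stage
can be re-run reproducibly.

Deliberate simplifications, and what they imply about test evidence:

* **Marker density** defaults to 25/Mb — far below resequencing density
  but safely in the regime where bins contain many markers per crossover,
  which is what the binning machinery needs exercised. Conclusions about
  wall-clock behaviour at full resequencing scale do not follow.
* **No crossover interference** (Poisson model): map-function consistency
  checks (Kosambi vs the simulated Haldane-like process) agree closely
  only at the short adjacent-bin distances the pipeline actually uses.
* **Orientation-consistent het markers**: heterozygous sites carry
  alleles with haplotype 1 = allele 0, emulating curated AHB labels that
  are locally consistent with the diplotypes. Raw per-marker random
  reference orientation would make the unphased 1:2:1 class sequences
  non-piecewise-constant; resolving per-parent linkage phase from class
  data alone is the job of full CP-mode phasing, which is out of scope.
  The 1:1 pipeline is unaffected (its phasing step handles orientation).
* **Error model** is a uniform flip to one of the other two states;
  depth-dependent or allele-biased error structure in real callers is not
  emulated.
* Parental genotypes are carried through undegraded — the cascade
  presumes deeply sequenced, curated parents.

# Numerical and design choices

* Missing calls never break runs in breakpoint detection; they are
  skipped, and the boundary is placed immediately before the first marker
  of the new run.
* Bin consensus ties give a missing call rather than an arbitrary state.
* The permutation threshold quantile uses the type-1 (inverse-ECDF)
  definition, so $\alpha = 1$ degenerates to the minimum permutation
  maximum, as a quantile should.
* The F2 two-point estimator restricts EM to coupling and label-swapped
  (repulsion) orientations of a pair; per-parent mixed phase combinations
  are not searched — adjacent one-bin markers from a label-harmonized
  dataset do not produce them. This is a known limitation for arbitrary
  unharmonized marker pairs.
* Problem sizes in the test suite (e.g. N = 100–500 progeny, 1–2
  chromosomes, 1000 permutations, 20 replicates for the QTL-recovery
  property) were chosen as the smallest sizes at which the tested
  statistical properties are stable, and are stated in each test.

# Known limitations

* Marker ordering is physical; the package cannot rescue a misassembled
  reference, and collinearity claims are conditional on the assembly.
* The 1:2:1 pipeline assumes label-consistent AHB input (see above).
* `%EV` is defined as $100(1-\mathrm{RSS}_1/\mathrm{RSS}_0)$; proprietary
  interval-mapping software may print a differently normalized quantity,
  so equality with any published %EV column is not asserted.
* Composite interval mapping, multi-QTL models and epistasis scans are
  out of scope, as are read alignment, variant calling and FPKM
  quantification upstream of the expression matrix.
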