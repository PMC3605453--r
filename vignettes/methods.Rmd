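---
title: "Models and methods behind karyolute"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind karyolute}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette explains the models implemented in karyolute, the
assumptions behind them, the parameters a user may want to change, and
the design choices made where the methodology was genuinely open. It
states no empirical result beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## The genome model

A genome is a vector of copy numbers over 23 chromosome types: the 22
autosome pairs plus a single sex-chromosome slot. A normal diploid has
N = 46 chromosomes and a tetraploid N = 92. We deliberately do not
resolve X from Y: the karyotypes this package deals with are summarised
at whole-chromosome-count level, and a merged sex slot keeps the diploid
and tetraploid anchors exact. `n_types` is configurable (e.g. 24) for
users who need separate sex chromosomes.

A *copy-number profile* (`cn_profile`) discards chromosome identity and
keeps only the counts of types per copy-number class — monosomies,
disomies, trisomies and so on. This is the unit of comparison between
observed tumours and simulations: two stem lines with trisomy 2 and
trisomy 7 are the same profile. Classes are stored exactly, however
high; pooling of "5 and above" is a display convention only, so the
total chromosome number is always exact.

### ISCN parsing

`parse_iscn_numerical()` handles numerical karyotype strings: a modal
count, a sex field, and `+chr`/`−chr` tokens. Structural tokens (`del`,
`dup`, `t`, `add`, `i`, ...) never change whole-chromosome counts;
`dmin`/`hsr` set the clinical-genetic subtype to 2B (taken as equivalent
to MYCN amplification in cytogenetic records), and `inc`/`mar`/`r` set
exclusion flags. The baseline ploidy of a karyotype is the multiple of
23 nearest the modal count. This "nearest multiple" rule is a policy,
not a fact about the data: for hyperdiploid-but-sub-triploid counts the
baseline is genuinely ambiguous, so the policy is exposed (`baseline`
argument) and an explicit ploidy level can be forced per karyotype.
Token arithmetic that disagrees with the declared count beyond a
configurable `slack` flags the record (`inconsistent_count`) rather than
rejecting it, since published karyotypes frequently contain such
inconsistencies.

## The allele-mixture model for clone sizes

For a segment carrying genotype \((n_A, n_B)\) (major allele first) in a
clone occupying a fraction \(f\) of the sampled DNA, against a balanced
background of ploidy \(\pi\),

\[
\mathrm{mBAF}(f) \;=\;
\frac{f\,n_A + (1-f)\,\pi/2}{f\,(n_A+n_B) + (1-f)\,\pi}.
\]

The function is 0.5 at \(f=0\), strictly increasing in \(f\) for any
unbalanced genotype, and inverts in closed form:
\(f = (\pi/2 - m\pi)\,/\,(m(n_A+n_B-\pi) - n_A + \pi/2)\), which
specialises to \(f = 2-1/m\) for a hemizygous deletion, \((2m-1)/(1-m)\)
for a single-copy gain and \(2m-1\) for copy-number-neutral LOH on a
diploid background. `estimate_ac()` inverts the segment's median mBAF
for the point estimate and its min/max for the interval — monotonicity
makes this order-preserving — and clips results to \([0,1]\).

Parameters and defaults:

* `mbaf_imbalance = 0.55` — segments above this are in allelic
  imbalance; `mbaf_call = 0.56` — below this an imbalance is not
  *quantifiable*. At 0.56 the minimal detectable clone fractions are
  3/14 (≈21.4%) for losses and 3/11 (≈27.3%) for single-copy gains.
* `log2_gain = 0.073`, `log2_loss = −0.080`. The loss cutoff is
  sometimes quoted with a positive sign in the SNP-array literature; a
  positive loss cutoff cannot coexist with a gain cutoff at +0.073
  (the three classes must be disjoint), so the default is negative and
  the literal positive value remains settable through
  `clonality_thresholds()`.
* Genotype models for inversion: loss \((1,0)\), gain \((2,1)\),
  CNN-LOH \((2,0)\) on a diploid background, with single-copy analogues
  on other background ploidies. Real aberrant clones may carry other
  genotypes; an explicit `genotype` argument overrides the default.
  Genotypes with more than 5 total copies are refused — amplifications
  compress allelic ratios so strongly that mBAF no longer identifies
  \(f\).

Adjacent same-chromosome segments are fused when the interspersed gap is
below 1 Mb and the mBAF difference below 0.1, re-testing after each
merge. Fused mBAF is the marker-count-weighted mean (length-weighted
when marker counts are absent): marker-level values are unavailable in
segment tables, so a true pooled median cannot be recomputed; the
weighted mean is the closest unbiased summary, and min/max are union
extrema so confidence intervals can only widen under fusion.

Per-case diversity is the *prevalence span*: the difference in AC
between the most and least prevalent aberration, overall and within the
numerical/structural classes (class spans use their own extrema and are
always bounded by the total span). "Majority clone" membership is
operationalised as interval overlap: each call occupies the band
\([\mathrm{AC}_{\min}, \mathrm{AC}_{\max}]\), the majority band is the
call interval overlapping the most calls (ties towards the widest), and
a call is consistent with the majority clone when its band overlaps it.
This is a pragmatic reading of a narrative concept; any definition based
on interval clustering would serve, and this one is the simplest that is
symmetric and deterministic.

## Segregation-error models

All four models evolve 10,000 virtual cells (default `n_virtual`) from a
balanced complement until each reaches the target chromosome number of
the case under evaluation. Chromosomes segregate independently; the
models differ in the elementary error:

* **Loss from tetraploidy** — repeated loss of a single chromatid, drawn
  uniformly over all chromatids (so proportional to current copy
  number), starting from 92 chromosomes. Implementation note: a sequence
  of such losses is distributionally identical to drawing the lost
  chromatids uniformly *without replacement*, i.e. a multivariate
  hypergeometric draw, which is how the simulator vectorises it. The
  alternative weighting (uniform over chromosome types) would change
  the law; copy-number weighting follows from the chromatid-level
  mechanism.
* **Sequential non-disjunction** — each step picks one chromosome type
  uniformly and moves one copy towards the target (the trisomic daughter
  is followed below target, the monosomic one above). Starting ploidy is
  diploid by default, tetraploid optionally.
* **Tripolar, randomized** — one division in which every replicated
  chromatid is assigned to one of three poles with equal probability;
  one daughter is followed. A single division cannot be steered, so
  whole divisions are re-run (rejection sampling) until the daughter
  hits the target, within `max_attempts` batches. Divisions are not
  chained: the elementary event is one multipolar division, and chaining
  would compound an already maximally diffuse outcome distribution.
* **Tripolar, amphitelic + cytokinetic failure** — per chromosome copy
  the sister pair segregates to one of the three pole pairs uniformly;
  cytokinesis fails between two fixed poles, so one daughter collects
  gains (\(c + \mathrm{Bin}(c, 1/3)\) per chromosome) and the other the
  mirror-image losses; a uniformly chosen daughter is followed, with the
  same rejection scheme.

Cells acquiring a nullisomy are eliminated and replaced by sampling from
the remaining population. Because every process here changes each
chromosome monotonically, a finished profile is nullisomy-free exactly
when its path never touched zero, so elimination-during-evolution is
implemented as rejection of finished nullisomic profiles — the two are
the same distribution. With `monosomy_selection`, finished tumours
containing a monosomy are likewise replaced from the monosomy-free
remainder, modelling negative selection against monosomic clones. Note
that at low targets (roughly N ≤ 55 under the loss model) essentially
every virtual tumour is monosomic and the replacement pool can be
empty; this surfaces as an error, which cohort evaluation converts to a
flagged row.

The *expected prevalence* of an observed profile is the fraction of
virtual tumours with the identical per-class profile. Cohort evaluation
aggregates this over cases and compares pooled copy-number class
distributions by Pearson chi-square, pooling classes with expected
count < 5 into the adjacent class with the larger expectation (degrees
of freedom reduced accordingly). A model that cannot reach a case's
chromosome number — a single tripolar division has a narrow reachable
window — assigns that observation probability zero, so such cases enter
the cohort mean as prevalence 0 while staying visible as flagged rows.
Averaging only over reachable cases would let a narrow model compete
only on its easiest cases, which is not a like-for-like comparison.

## Population dynamics

The generational model tracks a synchronised population of fixed size
(default 10,000 cells, 500 generations). Per mitosis a cell undergoes
whole-genome duplication with probability `t` (default 0.06), otherwise
each chromosome independently loses one copy with probability `p`
(default 0.04 per chromosome per mitosis); the two event types are
mutually exclusive within one division. Cells with fewer than 2 copies
of any chromosome or more than 92 chromosomes cannot divide and are
removed before the next generation is resampled (uniformly, with
replacement) from the viable survivors; *net growth* is the viable
fraction. The defaults for `p` and `t` are rates measured in an
unstable MYCN-amplified neuroblastoma cell line; the viability ceiling
of 92 reflects how rarely karyotypes beyond tetraploidy are observed as
majority clones.

Two deliberate simplifications: the population is constant-size rather
than branching (a growing population with pruning is the same process
up to the resampling weights, and constant size keeps memory and
variance flat across generations), and chromosome *gains* outside WGD
are omitted — the elementary events are loss and duplication only.
Recording viable cells only means the reported histograms never contain
the non-dividing monosomic/nullisomic cells produced each generation;
their number per generation is reported separately
(`excluded_monosomy`, `excluded_polyploidy`). A consequence worth
spelling out: under these rules no *viable* cell can ever have fewer
than 46 chromosomes (2 copies × 23 types is the floor), so hypodiploid
karyotypes can only exist transiently among the excluded cells, and the
contrast between the WGD-enabled and control populations shows up in
net growth and exclusion counts rather than in a hypodiploid band of
the viable histogram.

## Synthetic data: what it emulates and what it does not

The generators produce the same tabular formats the analysis consumes,
with truth attached:

* `gen_baf_segments()` draws per-marker mBAF values from a Gaussian
  around the mixture expectation, truncated to \([0.5, 1]\) (default sd
  0.005 per marker, 50–500 markers per segment), summarises segments by
  the marker median and extremes, and derives log2 ratios from the
  total-copy mixture. This emulates a high-quality array with tight
  diploid baseline variation. It does **not** emulate: wavy
  genomic-position artefacts, homozygous-SNP removal, segmentation
  breakpoint error, or constitutional CNVs. Recovery results on these
  tables therefore show correctness of the inversion, not robustness to
  array artefacts.
* `gen_fish_counts()` draws cells from the clone mixture and mis-scores
  a signal by ±1 with probability ε (≤ 0.1), emulating near-perfect
  hybridisation. Real FISH additionally suffers nuclear truncation and
  signal colocalisation, which are not modelled.
* `gen_cohort()` evolves one stem line per case under a chosen
  segregation model, recording the generating model as truth — the
  basis for model-recovery benchmarks. Mean expected prevalence is a
  crude model-selection statistic: it identifies concentrated
  generators (loss from tetraploidy, sequential non-disjunction)
  reliably, but the two tetraploid-start loss-like models (loss from
  tetraploidy and the cytokinetic-failure tripolar daughter) have
  nearly identical outcome distributions, and the randomized tripolar
  model is so diffuse that its own draws can receive higher prevalence
  under a more concentrated model. Recovery of those two should not be
  expected to be stable.

## Numerical choices and degenerate inputs

* AC inversion is closed-form; the identity
  `estimate_ac(expected_mbaf(g, f)) = f` holds to 1e-9 over the
  quantifiable range and is tested as such.
* mBAF values below the calling threshold, genotypes above 5 copies,
  empty FISH tables, empty simulation sets, and all-monosomic
  replacement pools all raise errors rather than returning values.
* Modal-number ties in FISH tables resolve towards the expected ploidy,
  then the lower class, and are flagged; the sample standard deviation
  (n−1) is used for the control threshold.
* Chi-square pooling merges a sparse class into its larger-expectation
  neighbour; with one remaining class the statistic is 0 with no
  degrees of freedom and an undefined p-value.
* All stochastic entry points accept a seed and are bit-reproducible
  under it.

## Problem sizes in the test suite

The shipped tests run the simulators at reduced sizes chosen to keep
Monte-Carlo tolerances honest (assertions use ≥4 standard errors):
expected-prevalence checks against exhaustive enumeration use 20,000
virtual tumours on targets within three losses of tetraploidy;
model-recovery benchmarks use cohorts of 12–15 cases at 1,500–2,000
virtual tumours per case; the population model runs at full defaults
(10,000 cells, 500 generations) for the attractor checks and at
300–2,000 cells for step-level properties.

## Known limitations

Mixed sequences of different error types within one tumour are not
modelled — each simulation commits to a single elementary error. The
ISCN parser covers numerical tokens only. AC estimation assumes one
aberrant genotype per segment against a balanced background; composite
subclonal genotypes on the same segment are not deconvolved. The
population model has no chromosome-specific fitness, spatial structure
or therapy effects.
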