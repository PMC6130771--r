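---
title: "Testing developmental constraints on genome evolution with transcriptome indexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing developmental constraints on genome evolution with transcriptome indexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(devindex)
library(dplyr)
```

## The question

Two classical models describe how evolutionary conservation is distributed
over animal development. Under the *early conservation* model, the earliest
stages are the most conserved and divergence increases monotonically with
developmental time. Under the *hourglass* model, the most conserved window is
in mid-development — the phylotypic period, when body-plan patterning makes
embryos of a phylum most similar — with more divergence both before and
after. `devindex` implements a transcriptome-level test of this dichotomy: it
asks whether genes carrying a particular evolutionary signature (strong
purifying selection, old phyletic age, low duplicability, high protein
connectivity) contribute disproportionately to the transcriptome of middle
versus early development.

## The transcriptome evolutionary index

For a gene-level evolutionary parameter $E_i$ and expression $e_{is}$ of gene
$i$ at stage $s$, the per-stage index is the expression-weighted mean

$$\mathrm{TEI}_s \;=\; \frac{\sum_{i=1}^{n} E_i\, e_{is}}{\sum_{i=1}^{n} e_{is}},$$

computed over the $n$ genes that have both expression and the parameter.
Instantiating $E_i$ gives the familiar family of indexes: $\omega_0$ (the
dN/dS of codons under purifying selection in a branch-site model) yields a
divergence index (TDI), phylostratum a phyletic-age index (TAI), paralog
count a paralog index (TPI), and protein–protein interaction degree a
connectivity index (TCI). Genes missing the parameter are dropped from
numerator and denominator alike; imputing them would pull every stage toward
the imputed value and dilute real signal.

Weights are the *transformed* expression values, `log2(x + 1)` by default.
The pseudocount maps zero expression to zero weight and keeps weights
nonnegative, which the weighted mean requires. The package also supports
square-root and untransformed weights; the `ci_ratio()` diagnostic below is
the reason log2 is the default.

## Bootstrap confidence bands

`tei_profile()` resamples gene identifiers with replacement (10,000 times by
default) and recomputes the whole per-stage curve for each resample; the band
at each stage is the 2.5%–97.5% empirical quantile interval (type-7,
R's default linear interpolation — the convention in this analysis family
names only a quantile range). Two choices deserve explanation:

* **One shared gene resample per replicate across all stages.** Each
  bootstrap replicate is then an internally consistent developmental curve,
  which is what a curve-level diagnostic such as the CI ratio needs. Whether
  the original analyses shared resamples across stages is not documented
  anywhere we know of; we assert this contract as a design decision.
* **The point estimate comes from the original data**, not the bootstrap
  mean, avoiding resampling bias in the displayed curve.

`ci_ratio()` reports `ci_upper / ci_lower` per stage. Because it is unitless,
it lets bands obtained under different weight transforms be compared on one
scale. On heavy-tailed expression data (counts with a lognormal baseline),
untransformed weights let a handful of extremely expressed genes dominate
every stage's index, which makes the ratio curve large and erratic; log2
weights make it flat and close to 1. The acceptance suite quantifies this:
on 100 simulated datasets the across-stage range of the ratio is smaller
under log2 than untransformed weighting in ≥95% of datasets.

## The early-versus-middle permutation test

Stages are first assigned to four blocks: `preMZT` (before the
maternal-to-zygotic transition — the first hours of embryogenesis, when the
transcriptome is maternal and says nothing about zygotic regulation),
`early`, `middle` (the phylotypic period, defined morphologically per
species and consumed here as configuration), and `late`. The test statistic
is

$$\Delta_{e\text{–}m} = \overline{\mathrm{TEI}}_{\text{early}} - \overline{\mathrm{TEI}}_{\text{middle}},$$

with pre-MZT stages excluded from both means and late stages excluded from
the contrast altogether: late development is the most divergent part of the
transcriptome for every parameter examined and is typically sampled much
more densely, so including it would make the test an assay of sampling
design rather than of the early/middle contrast. The test is one-sided
because "early conservation" covers both stronger conservation early and
equal conservation across early and middle development; only a middle-stage
advantage in the predicted direction counts as hourglass evidence.

The null is built by shuffling the parameter values across genes while
leaving expression fixed (`n_perm` = 10,000 by default), and two p-values
are reported: `p_normal`, from a normal approximation to the permuted
statistics (mean and sd of the permutation distribution), and
`p_empirical`, the add-one-corrected permutation p
$(1 + \#\{\Delta^{perm} \text{ at least as extreme}\})/(n_{perm}+1)$, which
can never be exactly zero. For parameters where conservation means *small*
values (ω₀, phylostratum, paralog count) the tested direction is
`middle_lower`; for connectivity, where conserved stages are expected to
express *more* connected genes, the tail flips (`middle_higher`). When the
permutation null has zero spread — e.g. a constant parameter — the result is
flagged degenerate and both p-values are 1.

Internally the statistic is linear in the parameter vector:
$\Delta_{e\text{–}m} = \sum_i E_i a_i$ with $a_i$ the difference of the
gene's mean weight share between early and middle stages, so each
permutation costs one shuffle and one dot product rather than a full index
recomputation. This is an exact algebraic identity, verified in the tests
against the direct route.

## Temporal pleiotropy, Tau, retrogenes, connectivity

**Pleiotropy.** Expression breadth across stages proxies the number of
traits a gene can affect. Genes are called expressed either by an absolute
threshold (`value > 1`, the FPKM convention) or per-stage rank (top
`q` fraction, `ceiling(q * n)` genes per stage; average ranks on ties, so a
tie block straddling the cutoff is kept or dropped as a block). A gene is
pleiotropic when expressed in strictly more than `breadth_threshold` of
stages (default > 50%; > 70% as a sensitivity setting; raising the threshold
can only remove flags, which is tested as a monotonicity property). The
per-stage profile reports the pleiotropic fraction among genes expressed at
that stage; the chi-square goodness-of-fit test uses expected counts
proportional to the per-stage expressed totals — the natural null of a
stage-constant pleiotropic fraction, since no more specific expectation is
standard. All sampled stages count in the breadth denominator by default;
`include_premzt = FALSE` excludes the maternal stages from numerator and
denominator.

**Tau.** $\tau = \sum_i (1 - \hat x_i)/(n - 1)$ with
$\hat x_i = x_i / \max_j x_j$ ranges from 0 (uniform) to 1 (single-tissue).
Negative log-scale values are floored at 0, genes expressed in no tissue are
removed, and a gene is testis-specific when its top tissue is testis and
$\tau \ge 0.8$. Tau is invariant to global rescaling, also a tested
property.

**Retrogene trend.** Retrogenes mostly lack ancestral regulatory elements;
if late development is transcriptionally permissive the way adult testis is,
their median expression should rise over development. The analysis computes
per-stage medians of retrogene expression and a Spearman correlation against
stage rank (stage order, not absolute time, since real series mix hours and
days). Testis-specific genes are excluded when a tissue panel is available,
because testis itself differentiates after mid-development and would
confound the trend. The Spearman p uses the t-approximation, with exact
enumeration over all orderings below five stages, and a concordant-ordering
bound ($2/S!$) when $|\rho| = 1$.

**Connectivity and duplicability.** Dosage balance predicts fewer paralogs
for highly connected proteins, but the empirical relation can rise before it
falls; a single correlation coefficient hides that. The analysis therefore
reports the Spearman correlation *and* the mean paralog count per
connectivity quantile bin (5 bins by default), with an explicit
undefined-correlation flag when connectivity carries no variation.

## The synthetic generator

`simulate_devo_data()` emulates the statistical structure the analyses
assume, so the whole pipeline can be validated without any external
downloads.

* **Timeline**: by default 1 pre-MZT, 3 early, 2 middle and 4 late stages —
  late development oversampled, as in real series.
* **Expression**: each gene gets a peak period; its expected expression is a
  lognormal baseline (median 60, sdlog 1) times a Gaussian bump over the
  stage axis (sd 1.5 stages) plus a 5% floor; maternal (pre-MZT peak) genes
  instead start high and decay exponentially (rate 0.8 per stage). Counts
  are negative binomial with dispersion 0.2 (variance $\mu + 0.2\mu^2$),
  typical of bulk RNA-seq without biological replicates; the lognormal
  option (`sigma_log = 0.5` on log2 intensities) emulates microarray-like
  data.
* **Coupling**: under `hourglass`, genes peaking in the middle period have
  ω₀ and phylostratum shifted down, paralog count down, and connectivity up,
  each by `effect_size` latent standard deviations (ω₀ on its log scale);
  under `early_conservation` the same shifts attach to early-peaking genes;
  under `null` nothing is coupled. The default `effect_size = 1` models a
  strong developmental constraint — the regime in which the test's power,
  not its calibration, is the interesting property.
* **Connectivity–paralog dependence** is generated by a Gaussian copula
  whose latent correlation is calibrated numerically (fixed-seed Monte Carlo
  inverted with `uniroot`) so the *realized* Spearman correlation of the
  discrete count margins matches the target (default −0.3); count margins
  tie heavily at small values and would otherwise attenuate the target by
  ~10%.
* **Retrogenes** are flagged with baseline probability 0.02, the odds
  multiplied by 3 for late-peaking genes. **Testis-specific genes** (10% by
  default) are constructed with all non-testis tissues below 15% of the
  testis value, which forces $\tau \ge 0.85$ by construction.

What the generator does *not* emulate: replicate structure and batch
effects, transcript-length bias, probe saturation, correlated gene modules
(co-expression), and any relation between expression *level* and the
evolutionary parameters beyond the peak-period coupling. Passing tests on
synthetic data therefore demonstrate the statistical machinery — oracle
agreement, calibration, power, direction handling — not that any particular
real species follows either model.

## Numerical and validation choices

* Scales are always declared, never inferred; log2/sqrt transforms of an
  already-log table are refused (double transformation is the classic silent
  failure in this analysis family).
* CPM normalization rescales each stage column to $10^6$ with no
  transcript-length term; the low-expression filter removes genes with mean
  across stages strictly below 1; the expressed call is strictly greater
  than its threshold. All three inequalities are deliberate and tested at
  their boundaries.
* Omega0 duplicate branch values resolve to the post-duplication branch;
  more than two branch records per gene (nested duplications) are an error
  rather than a silent choice.
* Wilcoxon group comparisons use the exact distribution below 25 per group
  without ties, the tie-corrected normal approximation otherwise.
* All randomized functions take an explicit `seed`, restore the caller's RNG
  state, and derive internal substreams from one root seed, so the pipeline
  is bit-reproducible end to end and components keep their draws when other
  components are reconfigured.

## Validation scale

The test suite and `scripts/acceptance.R` validate at desk scale, chosen so
the full suite runs in minutes on one core: oracle equivalence on 100 random
20-gene instances; bootstrap coverage on 500 datasets of 200 i.i.d. genes
(n_boot = 1000), where the population index is known exactly; type-I error
on 500 null datasets of 300 genes (n_perm = 1000); power and
early-conservation specificity on 200 datasets each at the generator's
defaults (2000 genes); p-value agreement on 20 datasets at n_perm = 10,000;
and the CI-ratio transform comparison on 100 datasets. The worked example
(12 genes × 6 stages) is small enough to check by hand and ships with
expected values frozen from an independent loop-based evaluation.

## Known limitations

* Period assignment is consumed as configuration; the package does not
  infer the phylotypic period from data, and results are conditional on that
  assignment.
* The contrast tests early versus middle only. It cannot distinguish
  hourglass from "middle conservation plus late divergence" shapes that
  differ only in late stages, which are excluded by design.
* The chi-square goodness-of-fit p-value treats genes as independent across
  stages; co-expression makes it anti-conservative on real data, so it
  should be read as descriptive.
* One expression column per stage is assumed (no replicate handling);
  replicates should be averaged upstream.
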