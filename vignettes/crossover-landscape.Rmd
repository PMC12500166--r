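---
title: "Analysing meiotic crossover landscapes from F2 genotyping data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing meiotic crossover landscapes from F2 genotyping data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xomap)
```

## The measurement model

In an F2 whole-genome genotyping design, heterozygous F1 females carry one
chromosome from each of two sequenced parental lines.  Each F2 offspring
inherits a single maternal meiotic product, and *diagnostic SNPs* — variants
private to one parental line — reveal, at every informative site, which
parental chromosome that product derives from locally.  A meiotic crossover
appears as a switch in the parent-of-origin of a block of consecutive
diagnostic SNPs.  Drosophila males are achiasmate, so every crossover
observed in this design comes from female meiosis.

`xomap` implements the analysis chain downstream of variant calling: a
chromatid-level crossover caller, genetic-map and rate-track summaries,
centromere/telomere-effect estimators, crossover-interference statistics,
Weinstein tetrad analysis with a meiotic-drive extension, and a forward
simulator of female meiosis that makes every estimator testable by parameter
recovery.

## Crossover calling

A *block* is a maximal run of same-origin diagnostic SNPs with at least
`min_snps = 25` SNPs spanning at least `min_span_bp = 250` kb (for the dot
chromosome the SNP requirement is relaxed to 4, reflecting its much lower
polymorphism density).  Runs failing either threshold are treated as
unassigned noise islands and absorbed into the flanking context, so isolated
miscalls can never create a call: a crossover always requires a validated
block on both sides of the switch.  Span is measured as the distance between
a block's first and last SNP.

Each switch between adjacent validated blocks yields one call whose
uncertainty interval is the gap between the flanking SNPs (0-based
half-open, BED convention; SNP positions themselves are 1-based) and whose
point estimate is the floored interval midpoint.  Two successive calls
closer than `min_separation_bp = 250` kb are most plausibly a single
non-crossover event (for example a gene-conversion tract bounded by two
apparent switches), not a genuine double crossover; both calls are removed
and, under the default `close_mode = "drop"`, the chromatid is flagged.
Removing rather than merging is conservative for every downstream statistic,
and in well-behaved data the choice is immaterial because genuine double
crossovers sit far above the threshold (the minimum observed
inter-crossover distance in the package's reference data is 591 kb).

Arms with fewer than 100 informative diagnostic SNPs (10 for the dot) are
excluded before calling, as are arms of crosses segregating a heterozygous
inversion.

The caller's contract is tested by an end-to-end recovery property: on
simulated data with noise-free genotyping at one SNP per 2 kb, with all true
crossovers at least 500 kb apart and 250 kb from the ends of the detectable
span, called crossover counts equal the simulated truth exactly, and
raising any threshold never increases the number of calls.

## Maps and rates

Per arm, the mean number of crossovers per meiotic product is
$\sum_k k\,N_k / n$ over the chromatid classes $N_k$, and 100 times that
mean is the arm's map length in cM.  The genome-wide mean crossovers per
product is the *sum of per-arm means* rather than total crossovers over
total chromatids, because arms can have unequal chromatid counts when an
arm is excluded from some crosses; with the packaged reference counts this
reproduces the published genome-wide value of 3.34 exactly.

Windowed tracks report cM/Mb per female meiosis: for each window and cross,
$100 \times (\text{COs in window}/\text{chromatids}) / \text{window Mb}$,
averaged over crosses with the per-cross envelope retained.  For
non-overlapping windows the track integrates back to the arm's map length,
which is asserted as an invariant test.  Cross-species or cross-dataset
landscape similarity is summarised by Spearman correlations after
length-weighted rebinning at a ladder of scales; shared broad-scale
structure with independent fine-scale noise produces the characteristic
decay of correlation at fine scales.

The interchromosomal-effect check is a one-way ANOVA on cross-level mean
crossover counts outside the focal arm, comparing inversion-carrier with
standard crosses.  Cross-level rather than individual-level units are the
deliberate default: with eight crosses split 5/3 the test has $F(1,6)$,
which matches the scale of the published worked example
($F = 2.10,\ p \approx 0.20$).

## Centromere and telomere effects

Both estimators place their null on the *crossover-detectable span* (first
to last informative SNP), not the assembly span, since crossovers can only
be observed where diagnostic SNPs exist.  Whether internal assembly gaps
should additionally be masked is not decidable from the data the package
consumes; the simple first-to-last span is the default.

The **proximal-third test** compares the observed crossover count in the
third of the arm nearest the centromere (or telomere) with uniform
placement.  Under the null the proximal count of $n$ uniformly placed
crossovers is exactly $\mathrm{Binomial}(n, 1/3)$, so the Monte Carlo
replicates are drawn as binomial counts (the default $10^7$ replicates cost
well under a second), and the one-sided p-value is the fraction of
replicates at or below the observed count.  Tests assert agreement with the
exact binomial tail within Monte Carlo error.

The **extent scan** estimates the size of the suppressed region without
fixing it in advance: 1-Mb windows slide inward from the arm end in 100-kb
steps, each tested for a deficit with the exact binomial tail
$P(\mathrm{Bin}(N, q_i) \le x_i)$ where $q_i$ is the window's share of the
detectable span.  The scan stops at the first run of five consecutive
non-significant windows; the extent is the distance from the arm end to the
inner edge of the last significant window before that run.  The run-of-five
stopping rule is the multiplicity control; no further correction is added
because overlapping windows make the per-window p-values strongly
dependent.  The alternative boundary convention (start of the terminating
run) differs by at most window minus step and is available via
`boundary = "run_start"`.  Two significance levels, $10^{-6}$ and
$10^{-3}$, are the conventional strict/relaxed choices.  Because the
extent estimate is power-limited, comparisons across datasets use
`subsampled_extent()` to equalise crossover numbers first.

Recovery behaviour: with intensity zero on the proximal 8 Mb of a 28-Mb arm
and 3,000 crossovers, the scan returns 8 ± 1 Mb; with no suppression it
returns 0 in at least 99% of runs.

## Crossover interference

Interference is measured from inter-crossover distances (ICDs) of 2CO
chromatids.  The null is data-driven: pairs of *distinct* 1CO chromatids
are resampled (default $10^6$ pairs) and the distance between their single
crossovers recorded.  Because those positions are real crossovers, the null
inherits centromere/telomere suppression and any other rate heterogeneity,
isolating interference proper from landscape effects.  The default test
statistic is the mean of the observed ICD set against means of equally
sized resampled null sets (`set_mean`); the single-pair variant is kept
because it is the more literal reading of the resampling construction.
Chromatids with three or more crossovers are excluded from the 2CO
statistic by default (an adjacent-gap variant is available).

The gamma model summarises interference intensity by the ML shape $\nu$ of
the ICD distribution, computed by profiling out the scale and solving
$\log\nu - \psi(\nu) = \log\bar{x} - \overline{\log x}$ to $10^{-8}$.
Uniform placement gives $\nu = 1$, but non-uniform landscapes push the
*expected* $\nu$ above 1 even without interference, so the expected shape
is likewise computed from the 1CO-pair null (zero distances dropped with a
count).  Tests pin the estimator against an independent grid-search
likelihood maximiser and against closed-form cases (exponential sample,
triangular $|U_1 - U_2|$ null).  Note that for distributions that are not
actually gamma the ML and moment estimators can disagree substantially:
the triangular null has ML shape $\approx 1.40$ (pulled down by density
mass at zero) but moment shape $\bar{x}^2/s^2 = 2$ exactly;
`fit_gamma_shape(..., method = "moments")` exposes the latter, and
reported "expected $\nu$" values near 2 for broadly uniform landscapes are
characteristic of moment matching.  The shape is scale-invariant, so
uniform suppression that merely narrows the crossover-competent interval
does not change the expected shape — only genuinely non-uniform position
densities do.

The genome-wide row pools observed ICDs across arms and mixes the per-arm
null samples in proportion to their 2CO counts.  The published genome-wide
interference summaries are not reproducible from printed data (they
require the study's unpublished crossover positions and an unstated pooling
scheme), so the package validates interference machinery by simulation
instead: at tetrad-level interference $\nu_{\text{sim}} = 1$ the test's
p-values are uniform; at $\nu_{\text{sim}} \ge 3$ interference is detected
in at least 95% of runs; and the chromatid-level fitted shape rises
monotonically with $\nu_{\text{sim}}$.  Note that the chromatid-level
$\nu$ is *not* numerically equal to $\nu_{\text{sim}}$: segregation mixes
tetrad gap structure into chromatid ICDs.

## Tetrad analysis and meiotic drive

Weinstein's method inverts the observed gamete classes $g_k$ (fractions of
chromatids with $k$ crossovers) to tetrad-class frequencies $E_r$ under
random chromatid involvement and no chromatid interference:
$g_k = \sum_r E_r \binom{r}{k} 2^{-r}$, with the closed-form inverse
$E_r = 2^r \sum_{k \ge r} (-1)^{k-r} \binom{k}{r} g_k$.  The inverse always
sums to 1 but can produce negative entries; these are flagged as
non-physical, the signature that a model assumption fails.

`tetrad_fit()` is the package's estimator in the classic modelling idiom:
it minimises the Pearson chi-square between observed and predicted class
counts over the simplex $\{E_r \ge 0, \sum E_r = 1\}$, by Dirichlet-proposal
random search (with concentration annealing around the incumbent) and
Nelder-Mead on a softmax parameterisation from multiple starts, returning
the better optimum; both routes are asserted to agree on fixtures.  `rmax`
defaults to the highest observed class — more tetrad classes than gamete
classes are algebraically unidentifiable and refused unless constrained.
For the p-value, tail cells are pooled until each expected count reaches 1,
and the degrees of freedom are pooled cells minus one minus free
parameters (reported as `NA` when non-positive).  `profile_E0()` fixes
$E_0$ on a grid and re-optimises the rest, reporting support relative to
the best grid point — the standard display for how strongly the data
constrain crossover assurance.

The MD_CO drive extension models biased meiosis II segregation: each
crossover lands on one sister of the retained dyad independently
($j, r - j$ with probability $\binom{r}{j}2^{-r}$), and when the counts
differ the sister carrying more crossovers is retained with probability
$\beta \in [0.5, 1]$; $\beta = 0.5$ recovers the binomial model exactly.
The retention probability is taken to be independent of the size of the
count difference — the simplest model consistent with "more crossovers are
preferentially retained" — and meiosis I is assumed symmetric.  `beta` is
this package's parameterisation of the drive; a count-difference-dependent
bias would be a model extension.

**Identifiability of the drive model.**  The gamete-class distribution is
linear in the tetrad distribution: $g = M(\beta)E$ with $M(\beta)$ square
and invertible for $\beta > 0$.  Consequently, for *every* $\beta$ in some
feasible interval $[\beta_{\min}, 1]$, the inversion
$E(\beta) = M(\beta)^{-1}g$ lies in the simplex and reproduces the observed
classes with chi-square zero.  From marginal class frequencies alone,
$(E_0, \beta)$ is therefore identified only up to this one-dimensional
ridge: the data determine $\beta_{\min}$ (in particular, whether unbiased
segregation $\beta = 0.5$ is feasible — the evidence for or against an
active drive) and the function $E_0(\beta)$ along the ridge, but not a
point estimate.  `tetrad_fit(..., allow_drive = TRUE)` will return *some*
point on the ridge; `beta_profile = TRUE` exposes the whole ridge, which is
the honest summary.  This is why drive analyses should be reported as
"the no-drive model is (in)feasible, and under drive the data are
consistent with $E_0$ in such-and-such range", not as a recovered
$(E_0, \beta)$ pair.  The package's recovery test for a simulated
$(E_0 = 0.2, \beta = 0.9)$ scenario documents this limit: the no-drive
inversion is driven negative (drive masks crossover-free tetrads), the
ridge contains the truth, but no optimiser can be expected to select the
true point from among the chi-square-equivalent solutions.

```{r drive-ridge, eval = FALSE}
cnt <- c(12788, 24774, 9901, 2251, 286)  # simulated, E0 = 0.2, beta = 0.9
fit <- tetrad_fit(cnt, allow_drive = TRUE, beta_profile = TRUE, seed = 1)
fit$beta_profile  # chi-square ~ 0 for every beta >= ~0.65; E0 rises 0 -> 0.26
```

## The simulator

`simulate_study()` is the package's testbed, emulating the statistical
structure the estimators assume:

* **Tetrad counts** $r$ drawn from a configurable $E$ vector (or a
  truncated-Poisson fallback given a mean), with an optional obligate-
  crossover mode that resamples $r = 0$ tetrads.
* **Positions** drawn on the genetic-map scale (the CDF of a
  piecewise-constant cM/Mb profile, whose zero-rate segments encode
  centromere/telomere suppression) and mapped back to bp by the inverse
  CDF.  Interference acts at the tetrad level, where it acts biologically:
  a proposed set of $r$ uniforms is accepted with probability proportional
  to the product of gamma densities of its $r + 1$ gaps (shape
  $\nu_{\text{sim}}$, mean gap $1/(r+1)$), normalised by the equal-gap
  maximum.  The rejection construction was chosen over a stationary
  renewal process for transparency and exactness at small $r$; the
  attempt cap (10,000) falls back to the best-scoring proposal and marks
  the result, so acceptance failures are visible rather than silent.
  $\nu_{\text{sim}} = 1$ reduces to iid placement.
* **Segregation** assigns each crossover to one sister per homolog with
  probability 1/2 and applies the MD_CO retention rule — an independent
  implementation of the same model as `predict_gamete_classes()`, and the
  two are cross-validated against each other in the test suite.
* **Genotyping** lays down per-cross diagnostic-SNP panels (default
  density one SNP per 2 kb, the density of the motivating study design),
  alternates parent-of-origin at each crossover, and applies independent
  miscall and missing-data noise.

What the simulator does *not* emulate: non-crossover gene conversion
tracts, chromatid interference, viability selection on meiotic products,
assembly gaps within arms, clustering of SNP dropout, or sequence-level
read noise.  Passing recovery tests therefore demonstrate correctness of
the estimators under the stated model, not robustness to every artefact of
real data.

Problem sizes used in the packaged tests were chosen as the smallest that
leave comfortable statistical margins for each property: 50,000 meioses for
the drive scenario (class frequencies to ±0.004), 20 replicate runs of
1,200 meioses per interference level, 3,000 crossovers per extent scan,
and 120 chromatids for the exact-recall caller check.  Null-resampling
sizes in tests (2×10^4 pairs, 2,000 resampled sets) are scaled-down
versions of the module defaults (10^6 and 10^5).

## Numerical choices

* Gamma-shape MLE: profile equation solved by `uniroot` to $10^{-8}$ with
  a method-of-moments bracket; non-convergence is an error, not a warning.
* Chi-square cells: predicted probabilities floored at $10^{-12}$ only
  when an observed count would otherwise divide by zero; such cells are
  structurally misfit and dominate the objective, which is the intended
  behaviour.
* Random search: Dirichlet(1, ..., 1) proposals for 40% of the budget,
  then concentration 50 and 500 around the incumbent; drive proposals
  shrink from uniform on [0.5, 1] to a truncated normal.  Seeds are
  recorded in every fit and pipeline manifest.
* Pipeline seeds: one master seed; stage $k$ of the canonical list derives
  seed $(\text{master} + k \cdot 1000003) \bmod (2^{31} - 1)$, so stages
  rerun independently and reproducibly.
* Crossover point estimates use floored interval midpoints; the interval
  itself is retained in every output so no information is lost.

## Known limitations

* The drive model's ridge non-identifiability (above) is a property of the
  marginal-class data, not of the optimiser; resolving it requires
  information beyond chromatid class frequencies (e.g. joint sister-cell
  genotypes).
* Map lengths are reported from pooled counts; per-cross-weighted map
  lengths (which require per-cross denominators not always published)
  are available but not the default.
* The extent scan's boundary is defined only up to the window/step
  geometry; both conventions are provided.
* `expected_nu()` drops zero null distances, which slightly biases the
  null shape upward when many 1CO positions coincide exactly (only
  plausible at very coarse position resolution).
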