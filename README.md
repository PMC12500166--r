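# xomap

Crossover-landscape analysis for whole-genome F2 genotyping studies of
meiotic recombination, as used for high-resolution crossover mapping in
*Drosophila*.

## The problem

In an F2 design, heterozygous F1 females carry one chromosome from each of
two sequenced parental lines, and each F2 offspring inherits a single
maternal meiotic product.  Diagnostic SNPs (variants private to one
parental line) reveal the local parent-of-origin along that product, so a
meiotic crossover appears as a switch in the origin of a block of
consecutive diagnostic SNPs.  From a few hundred genotyped products one can
reconstruct the genome-wide crossover landscape of female meiosis: genetic
map lengths, windowed cM/Mb rate tracks, the centromere and telomere
effects (suppression of crossovers near chromosome ends), crossover
interference, and — via Weinstein tetrad analysis — the distribution of
crossovers per tetrad, including a test for crossover-associated meiotic
drive (MD_CO), the biased retention at meiosis II of the sister chromatid
carrying more crossovers.

`xomap` implements this full chain for R analysts:

| Stage | Functions |
| --- | --- |
| Genotype tracks & I/O | `read_genotype_table()`, `filter_arms()`, `write_crossovers_bed()` |
| Crossover calling | `detect_blocks()`, `call_crossovers()`, `call_genotype_tables()`, `classify_chromatids()` |
| Maps & rates | `mean_crossovers_per_product()`, `class_frequencies()`, `rate_track()`, `xa_ratio()`, `interchromosomal_test()`, `multiscale_spearman()` |
| Centromere/telomere effects | `proximal_third_test()`, `scan_effect_extent()`, `subsampled_extent()` |
| Interference | `observed_icd()`, `expected_icd_null()`, `icd_interference_test()`, `fit_gamma_shape()`, `expected_nu()`, `interference_summary()` |
| Tetrad analysis | `weinstein_direct()`, `predict_gamete_classes()`, `tetrad_fit()`, `profile_E0()` |
| Simulation | `sim_config()`, `simulate_study()`, `truth_callset()` |
| Orchestration | `run_pipeline()` |

The core estimator is the Weinstein inversion and its constrained
extension.  Writing `g_k` for the fraction of chromatids with `k`
crossovers and `E_r` for the fraction of tetrads with `r` crossovers,
random chromatid involvement gives

    g_k = sum_r E_r * C(r, k) * 2^(-r)

with closed-form inverse

    E_r = 2^r * sum_{k >= r} (-1)^(k - r) * C(k, r) * g_k.

`tetrad_fit()` minimises the Pearson chi-square over the simplex
`E_r >= 0, sum E_r = 1` (random search plus Nelder-Mead), optionally with
the MD_CO retention bias `beta` in `[0.5, 1]`.  A forward simulator of
female meiosis (tetrad-level gamma-gap interference, configurable intensity
profiles, drive, genotyping noise) backs every estimator with
parameter-recovery tests.

## Worked example

```r
library(xomap)

cnt <- dsantomea_class_counts()   # observed chromatid classes per arm
summary(cnt, exclude_arms = "2R")
#> Total crossovers: 2288 on 3364 chromatids
#> Chromatids per crossover class:
#>    0    1    2    3    4
#> 1523 1451  340   43    7
#> Mean crossovers per meiotic product (genome-wide): 3.34
#> Event-class frequencies (excluding 2R):
#>   NCO       44.5%  (95% CI 42.7-46.3)
#>   1CO       43.7%  (95% CI 41.9-45.4)
#>   multiCO   11.8%  (95% CI 10.7-12.9)

weinstein_direct(as.numeric(cnt["X", ]))
#> <tetrad_dist> tetrad crossover-class frequencies (method: direct)
#>     E0     E1     E2     E3     E4
#> 0.1088 0.5782 0.2599 0.0531 0.0000
```

`E0 = 0.109` is the estimated frequency of X-chromosome tetrads with no
crossover: about one X bivalent in nine completes meiosis without a
crossover, a direct measure of (incomplete) crossover assurance.  The
genome-wide mean of 3.34 crossovers per meiotic product and the
44.5% / 11.8% NCO / multi-crossover frequencies are the headline map
statistics of the experiment.

A full simulated study runs end to end with:

```r
cfg <- sim_config(arms = list(X = list(length_bp = 2.2e7, intensity = 2.8)),
                  E = c(0.11, 0.58, 0.26, 0.05), n_meioses = 400)
run_pipeline(cfg, out_dir = "run1", seed = 7)
```

which writes genotype tables, a BED of calls, map/proximal/interference/
tetrad TSVs, a JSON manifest with per-stage seeds, and `summary.txt`.

## Vignette

`vignettes/crossover-landscape.Rmd` documents the models and their
assumptions, every tunable threshold with its default and rationale, the
simulator's scope and its limits, numerical choices, and known
limitations — including the interval-identifiability of the meiotic-drive
model, which is a property of chromatid class-frequency data rather than
of the optimiser.
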