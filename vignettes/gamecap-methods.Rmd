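---
title: "Models and methods behind gamecap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gamecap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gamecap)
```

`gamecap` studies two ways of turning an open-pollinated landrace into
evaluable lines — doubled haploids (DH, the "pure" approach) and gamete
capture (GC, the "admixed" approach) — and the consequences for genetic
variance, molecular diversity and genomic prediction. This vignette
documents the models, the defaults and the numerical choices, and what
the synthetic data generator can and cannot show about real data.

## Genetic model

### Allele coding

All genotypes are coded as counts of the capture-line allele (0/1/2).
After `make_capture_line()` the coding is re-oriented so the capture
line carries allele 1 at every marker. This makes the closed-form
machinery direct: `p` is always the landrace frequency of the
capture-line allele, loci private to the capture line are exactly the
loci with `p = 0`, and signed LD correlations are comparable across
populations without further alignment.

### Per-locus genotypic values

A trait (`assign_trait()`) is a set of QTL with per-locus values

* landrace-allele loci (capture line carries landrace allele A1):
  A1A1 = `+a`, A2A2 = `-a`, A1A2 = `d12` (midpoint plus dominance);
* capture-private loci (landrace fixed for A2, capture carries the novel
  Ax): AxAx = `a + Delta`, A2A2 = `-a`, A2Ax = `Delta/2 + d2x`.

This parameterization reproduces the textbook landrace mean `(p - q)a`
and additive variance `sigma2_A = 2pq a^2` exactly, and the capture-line
contribution enters through `sigma2_A* = 2(qa + Delta/2)^2`. The
dominance collapses at landrace-allele loci (the heterozygote with the
capture allele *is* the A1A2 class) are implicit in the biallelic
representation rather than tracked as separate `d1x`/`d2x` symbols.

Testcross values are computed mechanistically: the value of a testcross
plant is the additive value when the entry gamete matches the
(homozygous) tester allele and the homozygote midpoint plus a
tester-specific dominance term otherwise, and an entry's testcross
performance is the expectation over its gametes. Testcross performance
is therefore linear in allele dosage — purely additive — whatever the
per se dominance, and the familiar coefficient table for population
means and variances applies at the testcross level with effective
additive effects derived from the tester configuration. The tests verify
this as a consequence (e.g. the testcross contrast halves when the
tester equals the capture line) rather than hard-coding it.

### Population expectations and their scope

`expected_population_stats()` evaluates, per locus and summed over QTL,
the expected mean and the additive-variance decomposition (between-entry
"primary" variance, expected within-family variance, total) for the
landrace sample (LS), DH lines, GC-S1:2 entries, fully inbred
GC-S1:inf lines, and the capture line. Two scope decisions matter:

* **Mean cells hold for arbitrary dominance; variance cells are exact
  under additivity.** Per se dispersion of LS and GC-S1:2 with dominance
  involves terms the coefficient table does not carry; the inbred
  generations and all testcrosses are purely additive, so their cells
  are exact regardless. The single-locus enumeration oracle in the test
  suite (HWE distribution, gamete doubling, the selfing transition
  matrix) checks the mean cells at arbitrary `(a, Delta, d)` and the
  variance cells at arbitrary `(a, Delta)` with `d = 0`, on a grid
  `p = 0, 0.1, ..., 1`.
* **Linkage equilibrium between QTL.** The per-locus sums are exact for
  unlinked QTL; with QTL sharing a chromosome the object is flagged
  (`linked_qtl`) and the closed forms are approximations whose quality
  degrades with LD among QTL. Exactness tests therefore use one-QTL or
  one-marker-per-chromosome maps.

An S1:2 entry's value is the expected mean of its S2 family, computed
from the S1 genotype through the selfing transition
(`genotypic_value_s12()`); this is the "true entry value" used whenever
field entries are S1:2 families. A simulated-S2-family mode
(`self_progeny()`) exists for experiments that need the Mendelian
sampling noise of finite families.

### Thresholds

The two boundary frequencies — `p = 1/3`, below which the GC-S1
molecular variance `0.5(1+p)(1-p)` exceeds the landrace value `2p(1-p)`,
and `p = 1/6`, below which the GC between-family genetic variance
exceeds the DH variance when the capture allele is a landrace allele —
are solved by `uniroot()` bisection on the sign of the variance
difference (tolerance `1e-12`) rather than being stated, so any change
to the variance formulas propagates.

## Synthetic-data generator

The generator emulates, at desk scale, the structure of a
landrace-prebreeding genotyping study:

* **Genetic map**: `make_genetic_map()`, uniform marker placement by
  default, 1 cM/Mb unless configured otherwise; all recombination uses
  the cM scale.
* **Ancestral landrace**: `simulate_ancestral_pool()` draws founder
  frequencies from a U-shaped Beta(0.5, 0.5) spectrum truncated to
  [0.02, 0.98] (typical of landrace SNP panels; uniform and fixed
  spectra are available), samples founder gametes in linkage
  equilibrium, then runs a configurable number of random-mating
  generations in a finite pool. Drift during this burn-in creates
  within-chromosome LD that decays with distance while leaving
  cross-chromosome LD at the sampling floor; the pool is a
  Hardy-Weinberg population by construction. The stored `p` is always
  the realized frequency, recomputed from the gametes.
* **Meiosis**: crossover counts are Poisson with mean equal to the
  chromosome length in Morgans, breakpoints uniform in cM, no
  interference — so recombination fractions follow Haldane's map
  function exactly, which the tests verify against 50,000 simulated
  meioses.
* **Capture line**: a configurable fraction of markers (default 3%,
  matching the order of magnitude seen on dense arrays) is made private
  to the capture line; at the remaining markers the capture line is by
  default a random gamete of the pool, i.e. genetically a random DH of
  the landrace — the configuration under which `E[sigma2_A*] =
  sigma2_A` and the GC/DH variance ratio is 1/2.
* **Populations**: LS plants are 2n gametes drawn without replacement;
  DH lines are doubled gametes (drawn directly from the pool or produced
  by meiosis of random plants); GC-S0 plants are half-sibs sharing the
  capture gamete, each S0 family contributing exactly one selfed S1 (one
  plant per ear), with S1:2 entries represented by the genotyped S1
  parent.
* **Trials**: plot phenotypes are `mu + g + env + g:env + error` with
  Gaussian components. When a target entry-mean heritability is given
  (default 0.9, the upper end of what well-run multi-environment trials
  achieve for traits like flowering time), the error and interaction
  variances are back-solved from the `h2` formula at the design
  dimensions (defaults E = 4 environments, R = 2 replicates, the per se
  design; the ratio `sigma2_ge/sigma2_e` defaults to 0.5 and is a
  config knob, as the split is not identified by `h2` alone).

What the generator does **not** emulate: genotyping error and
missingness (the QC filter is exercised on constructed tables), genetic
load and segregation distortion in DH induction, selection during
population development, population admixture in the landrace sample,
epistasis, and realistic coalescent LD (the drift burn-in gives decaying
r² suitable for testing the decay-fit and phase-similarity machinery,
not a calibrated maize LD landscape). Passing tests therefore validate
the theory and the estimators under their own assumptions; they do not
certify numbers for any particular real landrace.

## Estimators and numerics

* **Trial analysis** (`fit_variance_components()`): balanced layouts use
  the closed-form expected-mean-squares solution, which equals REML in
  the interior of the parameter space; standard errors come from the
  chi-square approximation `Var(MS) = 2 MS^2 / df` propagated through
  the linear map to components, and negative method-of-moments
  components are truncated at zero with a flag. Unbalanced layouts fall
  back to iterative REML via `lme4` (component SEs are then not
  reported). With several population tags, components are fitted per
  population (entries are disjoint across populations) and the
  fixed-genotype BLUE model is fitted jointly; in balanced designs the
  BLUE of an entry is its raw mean, which the tests assert exactly.
  Heritability SEs use the delta method on the component covariance.
* **GBLUP** (`fit_gblup()`): after one spectral decomposition of the
  VanRaden method-1 matrix, the restricted likelihood is profiled over
  the variance ratio `delta = sigma2_e/sigma2_g` and maximized by 1-D
  optimization of `log10(delta)` on [-8, 8] (tolerance 1e-10). The
  genomic-variance test is a likelihood-ratio test against the
  variance-only null with a chi-square(1) reference; the
  boundary-corrected 0.5-mixture is available as an option but the plain
  reference is the default, matching common reporting practice.
  Predictions for unphenotyped entries use
  `U[pred, train] (U[train, train] + delta I)^{-1} (y - mu)`; a
  numerically singular system receives a 1e-8 ridge and is flagged. The
  test suite pins the fit to a determinant-based grid-search oracle and
  to ridge regression on centered markers, and the predictions to a
  mixed-model-equations oracle.
* **Accuracy**: `rho = cor(observed, predicted)/sqrt(h2)` with the
  population-level entry-mean `h2` applied to all prediction sets of a
  population (per-set re-estimation is a per-call option); values are
  not clipped at 1, and zero-variance inputs are missing, not zero.
* **LD decay**: the Hill-Weir drift-equilibrium expectation of r² with
  the finite-sample term in the number of gametes is fitted by
  unweighted nonlinear least squares on raw pairs
  (`minpack.lm::nlsLM`; bin-averaged mode available), and the decay
  distance `delta` solves fitted r² = 0.2 by bisection, reported in kb
  and flagged undefined if the curve stays above 0.2 within 10x the data
  range.
* **Linkage-phase similarity**: the default statistic is the proportion
  of marker pairs (polymorphic in both populations, 10-kb half-open
  distance bins up to 1 Mb) whose signed r agrees in sign between
  populations; a correlation-of-signed-r variant is provided because the
  literature uses both, and the output labels the mode.
* **AMOVA**: squared Euclidean allele distances partitioned between and
  within individuals (the two gametes of a plant); method-of-moments
  components are truncated at zero with a flag.
* **QC filter**: markers then individuals above 10% missingness are
  dropped; for DH data, individuals then markers above 5% heterozygous
  calls are dropped (rates recomputed after each step) and residual
  heterozygous calls set to missing. The individual-before-marker order
  in the heterozygosity step keeps a single aberrant individual from
  dragging well-behaved markers out of the panel.

## Seeds and reproducibility

Every stochastic operation takes an explicit integer seed and restores
the caller's RNG state. Pipelines derive independent child seeds from
one master seed via `split_seed()` (the master seed initialises R's RNG
once; child seeds are drawn below `.Machine$integer.max`). `run_study()`
and `scripts/acceptance.R` are bit-reproducible from their single seed.

## Problem sizes

The package's own verification runs at desk scale, chosen so the whole
suite exercises every code path with tight Monte-Carlo error: 200
unlinked QTL with 2,000 DH lines and 20 replicates for the
variance-doubling check; 1,000 diagnostic loci and 500 GC-S1 lines for
the genetic-distance check; 500 `p = 0` loci, 1,000 lines and 10
replicates for the molecular-variance check; 100-entry, E = 4, R = 2
trials with 100-200 replicates for variance-component recovery; and
40-300-entry GBLUP instances for the oracle equivalences. The
cross-validation engine defaults to the full literature configuration
(100 sampling replicates, 10x5-fold, N = 200/50 per se and 75/25
testcross) while tests and the bundled study runner scale the replicate
counts down.

## Known limitations

* Closed forms assume linkage equilibrium between QTL; linked-QTL
  configurations are flagged, not corrected.
* The bivariate per se/testcross REML model is out of scope; the
  genetic correlation between levels is estimated as the (optionally
  attenuation-corrected) correlation of BLUEs.
* The trial model omits lattice/incomplete-block bookkeeping and
  heterogeneous residual variances; this leaves BLUEs, components and
  `h2` unchanged in the balanced designs it simulates.
* Multi-allelic markers, mutation, selection and demographic history
  are not modelled; the LD generator is a drift process, not a
  coalescent.
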