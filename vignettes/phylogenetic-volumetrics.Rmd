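---
title: "Phylogenetically corrected volumetric analysis of brain neuropils"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetically corrected volumetric analysis of brain neuropils}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lepibrain)
```

## The problem

Comparative neuroanatomy asks how the sizes of brain regions (neuropils, in
insects) change across species, and whether those changes track ecology —
for example whether day-active species invest more in visual neuropils than
night-active relatives, or whether migratory species enlarge their compass
circuits. Species are not independent samples: close relatives share most of
their evolutionary history, so their brains are similar for reasons that
have nothing to do with present-day ecology. Every analysis in this package
therefore conditions on a phylogeny.

The package implements the full analysis chain: individual-level volume
records are aggregated to species means, normalised to a reference brain
volume, screened for adequate between- versus within-species dispersion,
tested for phylogenetic signal, fit with phylogenetic regressions
(isometry, grade shifts, slope differences), and clustered by pairwise
scaling behaviour. A synthetic-data generator with the same statistical
structure makes every stage verifiable end to end.

## The model

### Phylogenetic covariance

Under Brownian-motion (BM) trait evolution with rate $\sigma^2$, the
covariance of two tips equals $\sigma^2 C_{ij}$ where $C_{ij}$ is the
branch length shared by their root-to-tip paths (`vcv_matrix()`). $C$ is
symmetric positive semi-definite with root-to-tip depths on the diagonal.
Trees need not be ultrametric, and no branch-length transformation is
applied: the tree is taken as supplied. Polytomies are accepted as-is —
the covariance definition handles them directly. Pruning
(`prune_to_species()`) preserves root-to-tip depths by keeping any
collapsed stem as a root edge, so the covariance of a pruned tree is
exactly the corresponding submatrix of the full tree's covariance.

### Phylogenetic signal: Blomberg's K

For a trait $x$ on $n$ tips, with GLS mean
$\hat a = (1'C^{-1}1)^{-1}1'C^{-1}x$,

$$K = \frac{MSE_0/MSE}{E_{BM}[MSE_0/MSE]}, \quad
MSE_0 = \tfrac{(x-\hat a)'(x-\hat a)}{n-1}, \quad
MSE = \tfrac{(x-\hat a)'C^{-1}(x-\hat a)}{n-1},$$

with $E_{BM}[MSE_0/MSE] = (\mathrm{tr}(C) - n/(1'C^{-1}1))/(n-1)$. $K = 1$
is the BM expectation on the given tree; $K < 1$ means relatives resemble
each other less than BM predicts. K was chosen over likelihood-based
statistics because it behaves well at the small species counts typical of
volumetric studies (here ~15). Two tests accompany it:

* **K = 0** (no signal): a one-sided permutation test that shuffles trait
  values across tips (`permutation_test_k0()`), large K indicating signal.
* **K = 1** (BM): a two-sided test against K values from BM simulation on
  the same tree (`bm_simulation_test_k1()`); K is scale-invariant, so the
  simulation rate is immaterial.

Both use the add-one convention $p = (1 + \#\{\text{as extreme}\})/(n+1)$,
so $p = 0$ is never reported. Defaults are 10,000 replicates each. Traits
enter as $\log_{10}$ relative volumes by default; the choice of scale is a
config switch (`signal_table(scale = )`) because raw and log volumes can
legitimately disagree, and log is the scale on which the regressions
operate.

### Allometry by PGLS

The allometric model $y = a x^b$ is fit on the log scale,
$\log y = \log a + b \log x$, by generalized least squares with residual
covariance $\propto C$:
$\hat\beta = (X'C^{-1}X)^{-1}X'C^{-1}y$. The residual variance uses the
unbiased $n-p$ denominator (an ML variant is available for cross-checks).
$R^2$ is computed on the whitened scale against the intercept-only GLS
model, so with $C = I$ every statistic reduces exactly to ordinary
regression. Estimation is exact GLS under pure BM; Pagel's $\lambda$ or OU
models are deliberately out of scope.

Hypotheses on the coefficients are tested by Wald chi-squared
(`wald_chi2()`): $\chi^2 = (R\hat\beta - r)'[R\,\widehat{cov}\,R']^{-1}
(R\hat\beta - r)$. The asymptotic reference is mildly anticonservative at
$n \approx 15$; calibration on synthetic data puts the realized type-I
rate near 0.05–0.10 at nominal 0.05, and the tests in this package verify
it stays within [0.03, 0.09] for the slope test. Slope-difference tests in
the interaction model run slightly hotter (~0.07–0.10 measured at the
generator defaults); interpret isolated marginal slope differences
accordingly.

Two indices summarise the fits:

* **Slope index** $si = b - b_0$, with $b_0 = 1$ for volume-on-volume
  regressions and $b_0$ configurable (e.g. 3 for a volume-on-length pair
  such as brain volume against wingspan, where the isometric expectation
  for a volume is the cube of a linear measure).
* **Grade-shift index** $gsi = a_1/a_2 - 1$ for a binary ecological
  grouping, computed only at a common slope. The two-step procedure first
  fits group-specific slopes and tests their equality; only when that test
  is non-significant does it refit with a common slope and compare
  intercepts. When slopes genuinely differ, an intercept comparison is an
  extrapolation artifact — the synthetic analysis illustrates this vividly:
  a planted slope difference whose gate test lands just above $\alpha$
  leaks an absurdly large "grade shift", which is precisely why the
  validity flag exists and why reported gsi values should always be read
  together with `gsi_valid` and the slope-difference p-value.

gsi is base-free (an intercept *ratio*), invariant to uniform rescaling of
either axis. Natural logs are used internally throughout.

### Reporting conventions

Per-neuropil tables report raw p-values; no multiple-testing correction is
applied to the headline columns, matching per-region reporting practice in
the field, but Benjamini–Hochberg columns are appended for users who want
them. An adjusted-$R^2 > 0.6$ inclusion flag marks regressions tight
enough to interpret; adjusted $R^2$ is used uniformly (plain $R^2$ is also
reported). The isometry/grade-shift regressions use absolute log
species-mean volumes against the log reference volume; the pairwise
clustering uses log relative volumes. Both conventions are switchable,
because published figures are often ambiguous about which was used.

### Pairwise scaling and clustering

Neuropils that scale together across the phylogeny may form functional
units. `pairwise_slopes()` fits PGLS slopes $b(i \to j)$ for every ordered
pair of neuropils on log relative volumes. Slopes are asymmetric, so each
pair is symmetrized on a common scale,

$$s_{ij} = \tfrac{1}{2}\left(b(i \to j)\frac{sd_j}{sd_i} +
 b(j \to i)\frac{sd_i}{sd_j}\right),$$

where $sd_i$ is the trait's whitened (C-weighted) standard deviation about
the phylogenetic mean; with these scales each term equals the whitened
correlation, so $s_{ij}$ is a signed association. The matrix is normalized
to $[-1, 1]$ by its maximum absolute entry and converted to distances
$d_{ij} = 1 - s_{ij} \in [0, 2]$: strongly negatively associated neuropils
(investment trade-offs) sit farthest apart. Agglomerative clustering
(average linkage by default; complete and Ward available) produces a
dendrogram exportable as Newick. The symmetrization, the transform and the
linkage are all deliberate design choices in territory where published
descriptions are ambiguous; the raw asymmetric slope matrix is always
emitted so users can substitute alternatives. Cells with too little species
overlap are imputed by row/column medians with a warning, or rejected in
strict mode.

### Leverage and the two-factor check

`leverage_screen()` normalises each species' absolute whitened residual by
the total and flags species above mean + 2 SD — a guard against single
species (e.g. the smallest in the dataset) driving a slope.
`two_factor_pgls()` fits both ecological factors (activity period,
migration) on intercept and slope plus their interaction, surfacing
perfectly confounded designs as a rank-deficiency error rather than a
silent drop.

## The synthetic-data generator

`simulate_dataset()` is first-class, tested code, not a fixture. It
emulates the statistical structure the analyses assume:

* an ultrametric pure-birth tree, depth normalised to 1 so the BM rate is
  the expected between-species trait variance regardless of species count
  (default 15 species);
* a log reference volume evolving by BM (rate 0.5 per unit depth, root
  $\log 2 \times 10^7\,\mu m^3$);
* for each of 24 neuropils, species log-mean
  $\log a_g + b_g \log x + \varepsilon$, with group-specific intercepts
  (grade shifts) and slopes plantable per neuropil and an independent BM
  residual (rate 0.05);
* 3 individuals per species (2–6 supported) with multiplicative Gaussian
  noise on the raw scale (CV 0.05, truncated positive), because real
  volumetric tables report raw means ± SD per species;
* paired neuropils emitted as left/right records summing to the
  individual's total, with a lateral fraction ~N(0.5, 0.02);
* the six undefined central-brain regions emitted per specimen in fixed
  proportions, so the reference-normalisation step runs on synthetic data
  exactly as on real tables.

With these defaults the planted between-species log-SD (~0.7) exceeds the
within-species log-SD (0.05) by a factor ~14, mirroring the
order-of-magnitude separation volumetric studies report. A single
15-species × 3-specimen dataset estimates both dispersions with
substantial error, so tests of this property average the dataset-level
median ratio over seeds rather than asserting it per draw.

What the generator does **not** emulate: segmentation error correlated
with neuropil size, missing neuropils (absent regions must be injected by
the caller as missing cells), non-BM evolution (selection regimes, rate
shifts), and wild-versus-lab rearing effects. Passing tests on synthetic
data therefore demonstrate the statistical machinery, not the biological
fidelity of any particular dataset.

All randomness flows from one master seed; per-neuropil streams are derived
deterministically from it, so outputs are bit-reproducible.

## Numerical choices and degenerate inputs

* Covariance and GLS solves go through Cholesky factorization; a singular
  $C$ (e.g. duplicated zero-length terminal branches) is an error, with an
  optional ridge $\varepsilon$ on the diagonal as an explicit opt-in.
* Constant traits make K undefined and are rejected with a clear error,
  not returned as NaN.
* A zero residual vector in the leverage screen yields all-zero statistics
  and no flags.
* Species labels are matched exactly after trimming and underscore/space
  unification; any mismatch between tree and tables is a hard error that
  lists the offending labels.
* `sum_paired()` errors on a lone side of a paired neuropil by default;
  lenient mode keeps it with a warning.
* Species means are computed on raw volumes and then logged (mean-then-log)
  to match how volumetric tables are published; the alternative is a
  sensitivity switch.
* The reference volume is the per-specimen sum of the undefined regions,
  then averaged per species; per-species-first is the switchable
  alternative.

## Problem sizes

The test suite and the acceptance script run the Monte-Carlo checks at the
study's natural scale: 15-tip trees, 1,000 BM replicates for the K
calibration, 500 replicates for slope recovery, 200 for grade-shift
recovery and power, 1,000 for Wald type-I calibration, 500 × 199 for
permutation uniformity, and 100 planted-partition replicates for
clustering recovery. These sizes give Monte-Carlo standard errors several
times smaller than the tolerances being checked.

## Known limitations

* Exact BM GLS only; no $\lambda$/OU optimisation, no measurement-error
  model. With strong non-BM structure the Wald tests inherit whatever
  misspecification the covariance carries.
* Wald chi-squared is asymptotic; at $n \approx 15$ expect realized
  type-I rates up to ~0.1 at nominal 0.05, worse for the interaction
  (slope-difference) tests than for single-slope tests.
* K's sampling distribution under BM is wide at 15 tips: single-trait K
  values of 0.3–3 are unremarkable even when the generating process is
  exactly BM. Mean K over many simulated traits is ~1; a median K well
  below 1 across two dozen empirical traits is not, by itself, evidence
  against BM.
* The clustering transform is one defensible choice among several; the
  emitted slope matrix lets users apply their own.
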