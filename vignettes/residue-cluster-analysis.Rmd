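---
title: "Residue-cluster correlation analysis of per-residue binding-energy decompositions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residue-cluster correlation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resclust)
```

## The problem and the model

End-state binding free-energy methods such as MM-PBSA estimate a single
binding energy per protein–ligand complex. For congeneric inhibitor series
that whole-protein energy often tracks measured potency poorly: much of it
is contributed by residues whose interactions are common to every compound
in the series and therefore carry no activity signal. Per-residue energy
decomposition partitions the binding energy into additive residue
contributions $e_{ij}$ (compound $i$, residue $j$, kJ/mol, negative =
favourable), and the question becomes a feature-selection one: *which subset
of active-site residues carries the activity signal?*

The procedure this package implements is deliberately simple and fully
auditable:

1. **Profile.** For each residue $j$, compute the Pearson product-moment
   correlation $r_j = \mathrm{cor}(e_{\cdot j},\, \mathrm{pIC}_{50})$ across
   compounds. pIC50 is $-\log_{10}$ of the molar IC50, so higher means more
   potent; a residue whose contribution strengthens (becomes more negative)
   with potency gets $r_j < 0$.
2. **Select.** Keep residues with negative correlation, optionally
   restricted by structure–activity (SAR) sites of the binding pocket —
   regions of the pocket associated with particular substituents of the
   ligand scaffold.
3. **Sum and score.** For a candidate cluster $S$, form the cumulative
   binding energy $E_i(S) = \sum_{j \in S} e_{ij}$ per compound and report
   $r(S) = \mathrm{cor}(E(S),\, \mathrm{pIC}_{50})$.

The modelling assumptions are those of the underlying decomposition:
contributions are additive across residues, frame-averaging of the
per-snapshot contributions is an adequate summary of the trajectory, and a
linear (product-moment) association is the right resolution for an
8–30-compound series. Correlation is computed pairing observations by
compound identifier, never by row order, and degenerate inputs
(zero variance, fewer than three compounds) are hard errors, not silent
`NA`s.

Pearson is the default statistic because it reproduces all of the published
per-residue, per-component and cluster correlations of the packaged COX-2
dataset within rounding; a Spearman option (`method = "spearman"`) is
provided for robustness studies but does not reproduce them.

## The packaged COX-2 dataset

`cox2_fixture()` ships the published analysis of eight diarylheterocyclic
COX-2 inhibitors (celecoxib, polmacoxib, valdecoxib, celecoxib-analog,
SC-558, SC-58125, rofecoxib, DuP-697): a 8 × 12 per-residue energy matrix,
pIC50 values, whole-complex MM-PBSA component energies, and a three-site SAR
map (Site-1 = para-substituent pocket of one aryl ring: TYR371, PHE504,
VAL509; Site-2 = sulfonamide/sulfomethyl pocket: GLN178, SER339, ARG499;
Site-3 = central-ring substituent region: TYR341, ALA513).

```{r fixture}
fx <- cox2_fixture()
residue_correlations(fx$energies, fx$activities)
cluster_correlation(fx$energies, fx$activities, fx$cluster)
```

Two data decisions worth recording:

* **DuP-697's pIC50 is 8.04**, taken from the component-energy table where
  it is printed unambiguously; the per-residue table's header renders it
  ambiguously.
* **The published 7-residue cluster contains VAL509** even though VAL509's
  own residue-wise correlation is *positive* (+0.21), so the negative-sign
  rule as stated cannot produce the published cluster. Both behaviours are
  first-class here: `run_cluster_pipeline()` applies the sign rule as
  written (6 residues, r = −0.65), and `cox2_cluster()` is the explicit
  7-residue override reproducing the published r ≈ −0.60. The package takes
  no position on which is "right"; the discrepancy is surfaced, not patched
  over. The correlations were evidently computed on the full-precision
  energies before rounding for print; the fixtures carry the printed
  two-decimal values, and tolerances of ±0.03 (residue/cluster) and ±0.02
  (components) in `reproduce_cox2_study()` absorb that rounding.

## Selection rules and the significance screen

`select_by_sign()` implements the plain rule: keep every residue with
$r_j < 0$ (`strict_zero = TRUE` excludes an exact zero; undefined,
zero-variance correlations are never selected). The plain rule is what the
8-compound analysis used, and it is the default.

The plain rule has a property worth being explicit about: a residue with
*no* true association still lands on the negative side with probability
one-half at any sample size, so the rule's specificity against null
residues plateaus near 0.5 no matter how many compounds are measured.
When enough compounds are available, the natural refinement is to require a
*significant* negative correlation: `alpha = 0.05` keeps residue $j$ only
when its two-sided correlation p-value (exact $t$ transform,
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ df) falls below α. Under the null a
residue then survives with probability α/2 (it must also be negative), so
specificity approaches $1 - \alpha/2 \approx 0.975$, while sensitivity for
a real signal approaches 1 as compounds accumulate. When the goal is
*exact* recovery of a signal set from $p$ candidates, divide α by $p$
(Bonferroni) to control the family-wise false-inclusion rate. At $n = 8$
the screen is of little use — with ρ = −0.6 the per-residue power is small
— which is a fact about small-n decomposition studies, not about the
implementation; `recovery_experiment()` quantifies it.

## Search and inference machinery

The published cluster was hand-picked from SAR reasoning. To stress such a
choice the package adds:

* `search_clusters()` — exhaustive enumeration of all subsets of sizes
  $k_{\min}..k_{\max}$ (budget-capped, default $10^6$ subsets), ranked by
  `most_negative_r` (the favourable-binding convention) or `max_abs_r`, with
  a deterministic tie-break (smaller subset, then lexicographic label).
  Correlations are reported raw along with the number of subsets scored; no
  multiplicity correction is applied, deliberately — the count is the
  context a reader needs.
* `greedy_cluster()` — forward selection for residue counts where
  enumeration is infeasible; never beats the exhaustive optimum at equal
  size, which the tests assert whenever both run.
* `permutation_test()` — activity labels are permuted (`n_perm` times,
  seeded); $p = (b+1)/(n_{\mathrm{perm}}+1)$ with $b$ the count of
  permutations at least as extreme. The +1 smoothing is standard and
  conservative: p is never exactly zero and never below
  $1/(n_{\mathrm{perm}}+1)$. For the published 7-residue cluster at
  $n = 8$, $p \approx 0.13$ — the published correlation of −0.60 is *not*
  individually significant at this sample size, which is precisely the kind
  of statement the original analysis never made and this machinery exists
  to make.
* `bootstrap_ci()` — percentile interval over compound-level resamples;
  degenerate resamples (zero variance) are redrawn and counted.
* `loo_cv()` — each compound is held out, a univariate least-squares line
  pIC50 ~ cluster energy fitted on the rest, and
  $q^2 = 1 - \mathrm{PRESS}/\mathrm{SS}_{\mathrm{tot}}$ reported. For the
  packaged cluster $q^2 \approx -0.39$: at eight compounds the cluster
  energy does not yet predict held-out potency, a sobering and reportable
  number.

All stochastic operations are fully determined by their inputs and a seed;
seeds are echoed in the returned objects.

## The synthetic-data generator

`simulate_decomposition()` emulates exactly the statistical structure the
analysis consumes: activities $a_i \sim N(\mu_a, \sigma_a^2)$ (defaults
7.8, 0.7 — the pIC50 scale of the packaged compounds; a variance-matched
uniform option exists), and per-residue energies

$$e_{ij} = \mu_e + \sigma_e\left(\rho_j z_i + \sqrt{1-\rho_j^2}\,
\varepsilon_{ij}\right),$$

with $z$ the standardised activity vector, $\varepsilon$ i.i.d. standard
normal, and defaults $\mu_e = -8$, $\sigma_e = 3$ kJ/mol matching the scale
of the packaged per-residue energies. The construction makes the population
correlation of residue $j$ with activity exactly $\rho_j$, so recovery
tests have an analytic target; noise residues are independent draws
($\rho = 0$). Every generated dataset embeds its generating parameters.

What the generator does **not** emulate — and therefore what passing tests
do not establish about real data: inter-residue correlation (real
contributions of packed neighbours co-vary), frame-to-frame autocorrelation
and its effect on the frame-averaged values, heavy tails from rare binding
poses, systematic force-field or continuum-solvation bias, and activity
measurement error from heterogeneous assays. Tests against the generator
validate the *statistical machinery*, not MM-PBSA itself.

## Numerical choices and problem sizes

* Correlations clamp to $[-1, 1]$ against floating-point drift; the
  estimator matches a brute-force two-pass covariance oracle to $10^{-12}$.
* Frame aggregation in `read_decomp_contrib()` is the arithmetic mean
  (matching the convention of averaging evenly extracted snapshots), with a
  median option.
* Missing cells in energy tables are errors; zero-filling
  (`fill_missing = 0`) is opt-in only, because decomposition tools omit
  non-contacting residues and silent fills would corrupt correlations.
* LOO-CV uses the closed-form univariate least-squares solution;
  tests cross-check it against `lm()`.
* Calibration studies in the test suite and acceptance script use 1,000
  null datasets × 199 permutations for the size of the permutation test,
  200 replicates at 500 compounds for recovery, and 500 replicates for the
  null $q^2$ study — sizes at which the Monte-Carlo error is comfortably
  inside the asserted bands (e.g. binomial sd ≈ 0.007 around the 0.05
  rejection target).

## Limitations

* With eight compounds, every statistic here is fragile: the permutation
  p of the published cluster is ~0.13 and LOO-CV $q^2 < 0$. The package
  reports this honestly rather than implying the cluster is validated at
  this sample size.
* Cluster scoring is sum-then-correlate by design; multivariate or
  regularised regression of activity on several residue energies is out of
  scope.
* SAR sites are inputs (from manual SAR inspection), not discovered from
  structures; only the residues named in the published site discussion are
  in the packaged site map.
* Exhaustive search reports raw correlations across many subsets; treat
  the top of the ranking as exploratory unless permutation-tested.
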