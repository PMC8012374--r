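---
title: "Modular response analysis with mranet: model, statistics, design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modular response analysis with mranet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mranet)
```

## The model

A network of $n$ modules is observed at steady state. Each module's
activity is summarized by one measured reporter (a transcript abundance, a
luciferase readout, a normalized count). An *elementary perturbation*
$q_k$ changes exactly one module's intrinsic parameter — an siRNA against
one gene, or removal of one ligand — and the system is allowed to relax to
a new steady state. Because only relative changes enter the calculation,
absolute quantitation is unnecessary.

The systems-level (global) response of module $j$ to $q_k$ is estimated by
the symmetric relative difference

$$R_{j,k} = \frac{2\,(x_j' - x_j)}{x_j' + x_j},$$

which is bounded in $(-2, 2)$ for positive abundances and avoids division
by values near zero. These responses confound direct effects with network
propagation. MRA disentangles them: with the convention $r_{i,i} = -1$,
the local (connection) coefficients and perturbation magnitudes satisfy
$rR = -P$ with $P$ diagonal, solved in two steps:

$$P_{i,i} = \frac{1}{(R^{-1})_{i,i}}, \qquad
  r = -\left[\mathrm{diag}(R^{-1})\right]^{-1} R^{-1}.$$

`infer_network()` implements exactly this, enforcing the $-1$ diagonal
after the division rather than leaving it to rounding, and rejecting
matrices whose condition number exceeds `max_condition` (default `1e8`)
instead of silently amplifying noise. Module order is declaration order
throughout; nothing is ever re-sorted alphabetically.

Predictions under a *combined* perturbation with weight vector $c$ (1 =
full elementary strength, fractional weights allowed, linearity assumed)
are $v = -r^{-1} P c$ on the relative-change scale. The abundance scale is
recovered by inverting the symmetric relative difference,

$$x' = x_0\,\frac{2 + v}{2 - v},$$

which is algebraically identical to the form written with $w = -v$,
$x_0\,(2/w - 1)/(1 + 2/w)$, but has no intermediate division by a possibly
tiny $w$; the equivalence is asserted to $10^{-12}$ over a dense grid in
the test-suite. Predicted changes with $|v| \ge 2$ cannot correspond to
any positive abundance and raise a saturation error naming the module.

## Variance estimation for tiny replicate series

The reference design is 3 biological replicates (independent
transfections) × 2 technical replicates. A global response matrix is
computed for each of the 6 replicates by pairing replicate $(i, r)$ of a
perturbed condition with the same $(i, r)$ of the basal condition, so each
cell of $R$ carries a sample of 6 values with a two-level hierarchy.

With so few values, the sample standard deviation is unreliable; the
package uses the range method of statistical process control (SPC)
instead: within each biological subgroup the range of the technical
replicates is taken, and the mean of the subgroup ranges is divided by
Hartley's constant $d_2(n_r)$ — the expected range of $n_r$ standard
normal deviates ($d_2(2) = 1.128$). The constants for subgroup sizes 2–10
are embedded; the test-suite checks them against numerical integration of
the expected normal range.

For duplicate-only designs (RNA-seq), even that is too little, and
variance is learned collectively across a gene population
(`spc_population_sd()`): each gene's replicates form one subgroup, the
pooled mean range is converted to a standard deviation, and genes that are
out of control are excluded iteratively until the retained set no longer
changes. The exclusion rule is pluggable because the exact criterion in
use elsewhere is not standardized:

- `"range"` (default): exclude genes whose subgroup range exceeds
  $D_4(n)\times$ the current mean range — the classical range-chart upper
  control limit ($D_4(2) = 3.267$). The lower limit $D_3(n)$ is zero for
  subgroups of six or fewer, so for typical designs the rule is
  effectively one-sided, flagging only over-dispersed genes.
- `"individuals"`: a $\pm 3\sigma$ criterion on each gene's mean response.
- `"none"`: the plain pooled estimator.

Exclusions are recomputed against the *updated* mean range at every
iteration, making the final set a true fixed point of the joint
estimate-and-exclude map; the loop necessarily terminates because the
retained set shrinks or the loop exits. A configurable floor (default 5
genes) aborts the estimate when the population is too heterogeneous to
pool.

## Bootstrap confidence intervals

Parameter uncertainty is propagated with a parametric bootstrap on the
global response matrix: each cell is drawn from an independent normal with
mean equal to the replicate-averaged $\bar R_{j,k}$ and a cell-specific
standard deviation (cells genuinely differ in variance, so no pooling
across cells is done at this stage). Each draw is inverted into $(r, P)$,
and percentile intervals (plain order statistics with linear
interpolation, no BCa correction) are taken over the valid draws at any
requested level; the production default is $10^6$ draws, with seeded
10,000-draw runs used for routine checks and examples. A coefficient
whose interval excludes 0 has its sign established at the corresponding
significance level, which is how edges are starred in exports.

**Which standard deviation enters the sampler** is the one genuinely open
design choice. The SPC estimate $s^{\text{intra}}_{j,k}$ describes
replicate-level noise; the point estimate, however, is a function of the
*mean* of $k_t n_r$ replicates, whose standard deviation is
$s^{\text{intra}}/\sqrt{k_t n_r}$. We calibrated both options on the
synthetic benchmark (3-module truth, Gaussian response noise
$\sigma = 0.05$, 150 simulated experiments × 3,000 draws) before freezing
the test expectations: sampling at replicate scale yields ≈ 99.9%
empirical coverage of the true coefficients at nominal 95% (the intervals
describe a single future replicate, not the estimate), while sampling at
mean scale yields ≈ 94%. The pipeline therefore uses
`replicate_sd_matrix(..., scale = "mean")`, and the acceptance suite
verifies 92–98% coverage per coefficient over 500 experiments × 10,000
draws. `bootstrap_network()` itself takes `sd_R` as given, so the
replicate-scale variant remains one argument away.

Two further policies the underlying theory does not dictate:

- Draws whose response matrix is singular (or whose inversion produces
  non-finite values) are discarded and counted. Exactly singular Gaussian
  draws have probability zero, so in practice this guards against
  overflow; if the valid fraction falls below `min_valid_fraction`
  (default 0.5) an instability error reports it rather than returning
  percentiles over garbage.
- In prediction propagation (`bootstrap_prediction()`), draws whose
  predicted relative change reaches magnitude 2 are counted invalid under
  the same accounting, since the abundance inversion is undefined there.

Identical seeds give bit-identical results; this is asserted in the
test-suite for every stochastic entry point.

## Unidirectional MRA and weight optimization

A gene that was never perturbed can still be attached to an inferred
network: its outgoing coefficients are fixed at zero (no perturbation data
exist to estimate them) and its incoming coefficients solve the exactly
determined linear system
$u_k = \sum_j r_{\text{gene},j} R_{j,k}$ over the $n$ elementary
perturbations, i.e. a row-vector solve against $R$. Predictions under
combined perturbations follow the same $v = -r^{-1}Pc$ machinery for the
core modules, then $u = \sum_j r_{\text{gene},j} v_j$ and the abundance
inversion.

When elementary perturbations are combined experimentally, their
effective strengths need not match the single-perturbation calibration,
so `optimize_weights()` fits the free entries of $c$ by minimizing the
summed squared *relative* error between predicted and observed core
responses (an absolute-error mode exists for observations near zero,
where relative error is undefined and an informative error says so). The
optimizer is a dense deterministic grid (step 0.05 on $[0, 2]$ per free
weight — exhaustive search is cheap for the 1–2 free weights that occur
in practice) followed by derivative-free local refinement; the full
evaluated trace is returned so the claimed optimum can be audited. Note
that the all-zero weight vector is not an admissible perturbation, so
when the best fit is "no perturbation" the optimum approaches zero
without reaching it.

Naive baseline predictors (`naive_predictors()`) combine the abundances
observed under each single perturbation by mean, geometric mean, and
maximum. They operate on the abundance scale by default — the simplest
reading of averaging two single-siRNA measurements — with a fold-change
mode behind a flag. `benchmark_predictions()` compares methods by
per-gene relative error and paired two-sided Wilcoxon signed-rank tests
(two-sided because no direction is assumed a priori). Whether weight
optimization should be redone per gene is a judgment call; the package
fits once on the core modules and reuses the weights for all genes, with
per-gene refits available by calling the optimizer per gene.

## Screening

To rank candidate genes by proximity to a reference network, each
candidate in turn replaces the reference reporter's row of the response
matrix, a network is inferred, and its connection coefficients are
compared with the reference by Euclidean distance and by
$1 - \text{Pearson correlation}$, both over the off-diagonal entries
flattened in a fixed row-major order. The fixed $-1$ diagonal is excluded
by default — it is constant by construction and would only dilute both
metrics toward agreement — with a flag to restore it for parity
experiments. Perturbation magnitudes do not enter the distances; the
comparison is about connection structure. Candidates whose assembled
matrix is singular (e.g. a gene with no response to any perturbation) are
flagged un-screenable and reported with `NA` distances rather than
aborting the panel; ties rank in panel order, deterministically.

## The synthetic generator

`simulate_dataset()` is the package's oracle: it generates exactly the
data structure the inference assumes, so that the generator and the
inference core are exact inverses in the noiseless limit (asserted at
$10^{-9}$ over 200 random well-conditioned truths of 2–5 modules). A
ground truth fixes $r$ (diagonal $-1$), $P$ (negative for the inhibitory
perturbations typical of siRNA/ligand-removal designs), basal abundances,
and a noise model; it is rejected at construction if the implied
$R = -r^{-1}P$ has any entry outside $(-2, 2)$ (no positive abundances
could realize it) or is ill-conditioned.

Two noise spaces are provided deliberately:

- `"log_abundance"` (default): multiplicative log-normal error on every
  measured value, with a biological component shared by the technical
  replicates of one preparation and an independent technical component.
  Biological noise is drawn per (condition, biological replicate) — each
  treatment well is an independent preparation — rather than shared
  across conditions within a replicate; either reading is defensible, so
  the choice is stated here explicitly. This is the realistic qPCR/RNA-seq
  error model and is *mildly misspecified* relative to the bootstrap's
  assumption.
- `"response"`: additive Gaussian noise directly on the per-replicate
  response coefficients, matching the bootstrap's model exactly (basal
  measurements stay exact so the recomputed replicate matrices are
  exactly truth + noise). Out-of-range cells are redrawn, which matters
  only at noise levels far above those used anywhere in the package.

Default noise levels (`sigma_bio = 0.1`, `sigma_tech = 0.05` in log
space) are ordinary magnitudes for replicated qPCR work; the coverage
benchmark uses pure technical response noise of 0.05 so that the SPC
estimator's assumptions hold exactly and coverage measures the bootstrap,
not model misspecification. Passing tests on this generator demonstrate
correctness of the algebra and calibration of the intervals *under the
assumed model*; they do not certify behaviour under heavy-tailed noise,
count-specific overdispersion, or steady-state violations in real data.

The committed fixture truths (`truth_corepressor3()`,
`truth_crosstalk4()`) are qualitative motifs — mixed-sign edges with a
strong double-inhibition path through a shared upstream module — chosen
to exercise the sign-flip phenomenology that makes global and local
responses differ; their numeric values claim no equality to any measured
system.

## Problem sizes and runtime choices

The test and acceptance workloads are sized to finish in minutes on one
core: 200 random truths for the round-trip bound, 10,000 subgroups for
the SPC bias check, 500 simulated experiments × 10,000 bootstrap draws
for the coverage study (the production bootstrap default remains $10^6$
draws), and 60 genes for the udMRA benchmark. Matrix inversions use
LAPACK via `solve()`; no compiled code is needed at these dimensions
($n \le 5$ modules is the regime MRA is designed for, since it needs one
clean elementary perturbation per module).

## Known limitations

- Edge pruning / topology selection (deciding that a non-significant
  coefficient is absent) is out of scope; intervals are reported and the
  user decides.
- The bootstrap draws cells independently; covariance between cells of
  $R$ is not modeled.
- No nonparametric SPC variant and no formal normality testing are
  included.
- The condition-map grammar treats condition labels as opaque strings;
  `+` is not parsed into factor combinations.
- Inference requires exactly one elementary perturbation per module;
  incomplete perturbation sets are not supported.
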