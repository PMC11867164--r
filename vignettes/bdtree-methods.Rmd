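---
title: "Models and methods behind bdtree"
author: "bdtree authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bdtree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bdtree)
```

This vignette records the models implemented in `bdtree`, the
assumptions they rest on, the numerical and design choices that were
genuinely open, and what the package's own tests do and do not
demonstrate. Nothing here states an empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## 1. The linear birth–death process

The population `Z(t)` evolves with population-level rates `n λ` (birth)
and `n μ` (death) when `Z(t) = n`: individuals behave independently,
each splitting at per-capita rate λ (> 0, per unit time) and dying at
rate μ (≥ 0). All of the closed forms in the package are parameterized
by the pair of functions

- `β(t) = λ(e^{(λ−μ)t} − 1) / (λ e^{(λ−μ)t} − μ)` — the geometric
  parameter of the size law conditional on survival,
- `α(t) = (μ/λ) β(t)` — the probability of extinction by `t`,

with the critical limit `β = α = λt/(1+λt)` when λ = μ. From one
individual, `P(Z(t)=0) = α(t)` and
`P(Z(t)=m) = (1−α)(1−β)β^{m−1}` for m ≥ 1; the mean is `e^{(λ−μ)t}`
and `β′ = λ(1−α)(1−β)`. With μ = 0 (the Yule process) the law is
geometric with success probability `e^{−λt}`, negative binomial from
`r` founders, and a time-varying rate λ(u) enters only through
`ρ(t) = ∫₀ᵗ λ(u) du` (a deterministic time change).

### Numerical choices

- **Critical-case switch.** The direct formula for β has a removable
  singularity at λ = μ and cancels catastrophically nearby; the
  critical closed form is used whenever `|λ − μ| < 1e-8 · λ`. A test
  checks continuity across the switch to 1e-6.
- **Overflow-safe branches.** For λ > μ the formula is rewritten in
  terms of `e^{−(λ−μ)t}` so large horizons cannot overflow; for λ < μ,
  `expm1` keeps small-`t` accuracy.
- **Log-space pmfs.** `dyule`/`dbdp` compute in log space
  (`lchoose`, `log1p`) and exponentiate at the end, so large `n λ t`
  is safe; the `t = 0` point mass is set explicitly rather than left
  to `0 · log 0`.
- **Truncation.** Infinite sums in tests are truncated with
  `bdp_truncation()`, the smallest `m` whose closed-form geometric
  tail mass is below tolerance (default 1e-12).
- **Quadrature.** `ρ(t)` and the family-count integral use
  `stats::integrate` with absolute tolerance 1e-10 (pmf accuracy is
  limited by ρ accuracy, so the integral is held tighter than the
  downstream use).

## 2. Timed trees

A `timed_tree` stores one row per *lineage segment*: birth time, end
time, and why the segment ended (`split`, `death`, or `observed` at the
horizon). This representation makes pruning and mutation-dropping
O(nodes) array work, and converts losslessly to `ape::phylo` (splits
become internal vertices, the root lineage becomes the root edge).

- **Complete trees** are simulated event by event: with `n` extant
  lineages the waiting time is exponential with rate `n(λ+μ)`; a
  uniformly chosen lineage splits with probability `λ/(λ+μ)`, else
  dies. Extinct trees are valid outputs.
- **Pruning** marks every lineage with an observed descendant, keeps
  the marked splits with two marked children, and concatenates
  durations across the suppressed unary nodes. The result is
  ultrametric with the extant lineages as leaves.
- **Direct reconstructed simulation** draws the n−1 split times as
  inverse-CDF transforms of uniforms through
  `G(u) = 1 − β(t−u)/β(t)` (closed-form inverse, no root finding) and
  bifurcates a uniformly chosen lineage at each split. The naive
  rejection route (simulate complete trees, keep those with n extant
  tips) is retained **only in the test suite** as the independent
  oracle; its cost grows like the reciprocal of `P(Z(t)=n)`.

Design choices that were open:

- **Stem convention.** When the most recent common ancestor of the
  observed tips postdates time 0, the stem from 0 to the first
  surviving split is retained as the root branch (so root branches
  always start at time 0). This keeps truncal mutations representable
  in the cell model and makes 2-tip trees well-defined
  (`(1:1,2:1):0;`).
- **Tip labels** follow the creation-order convention: the original
  lineage is species 1; at a split the continuing lineage keeps its
  label and the new one takes the next integer.
- **Ties.** Split-time ties have probability zero; if two collide at
  float resolution the later is nudged by one ulp with a warning.
- **Seeds.** Every stochastic function takes an explicit `seed`
  argument (`set.seed` semantics); one seed, one tree.

## 3. Immigration and family statistics

Families arrive as a homogeneous Poisson process of rate θ and grow as
independent LBDPs from size 1. Marking each arrival with its family
size at `t` makes the per-size counts independent Poissons, giving
`E C_j(t) = (θ/λ) β(t)^j / j`, a Poisson total `F(t)` of live families,
a negative-binomial population size, and — conditional on `Z(t) = n` —
the Ewens sampling formula with concentration `κ = θ/λ`. `dewens`
takes κ directly (the formula depends on the rates only through κ), and
`partition_multiplicities()` enumerates configurations so the formula
can be verified by exhaustive summation.

The family simulator reuses the single-family event-driven engine per
arrival rather than a joint Gillespie over all individuals: this
mirrors the independence structure the closed forms rely on, and it is
the property the tests exercise (independence of `C_1`, `C_2`; Poisson
dispersion of `F`).

The `j = 0` count deserves a note: `E C_0(t) = θt + κ log(1−β(t))` is
the expected number of families *arrived and extinct by t* — a
cumulative quantity that grows with `t`, not the mean of a bounded
count. The package documents it as such, and a test verifies it equals
`θ ∫₀ᵗ p_{10}(u) du`.

## 4. Fisher's two-sample variance

Time is scaled so λ = 1 in this module (general λ is a time rescale).
A "specimen" maps to one birth-or-arrival event in the continuous
embedding — the only reading under which the species count of the first
window is Poisson(θ t₁) and the closed forms close. `F(a,b)` is the
number of families with at least one individual appearing in `(a, b]`;
it is Poisson with mean `θ log(e^b − e^a + 1)`, windows have the
explicit covariance implemented in `overlap_cov`, and together these
give

    E V₂ = ½{ θ log(e^{2t₂−t₁}/D) + θ² log²(e^{t₁}/D) },
    D = e^{t₂} − e^{t₁} + 1.

Sampling times matching expected specimen counts n₁ and n₁+n₂ are
`t₁ = log((n₁+θ)/θ)`, `t₂ = log((n₁+n₂+θ)/θ)`; equal sizes give
`θ log{(2n+θ)/(n+θ)} → θ log 2`. Two readings of the window count
circulate (appearance-in-window vs arrived-before-and-offspring-in-
window); only the appearance-count reading is consistent with the
Poisson mean above and with the V₂ decomposition — at `(a,b,θ) =
(1,2,1)` the alternative would be bounded in mean by θa = 1 while the
formula gives 1.74 — so that is what `simulate_overlap_counts`
implements. `overlap_mean` is restricted to `a > 0`; at `a = 0` the
count degenerates to plain arrivals (mean θb). The replicate-population
scenario (two independent samples of size n, with `E V₂ ~ θ log n`) is
out of scope; only the consecutive-samples scheme is simulated.

## 5. The cell model

Cells age for an exponential time with parameter `event_rate` (default
1, so time is in expected cell lifetimes) and then divide with
probability `p` or die — an LBDP with birth rate `p·event_rate` and
death rate `(1−p)·event_rate`. Growth stops the instant the population
first reaches `N` concurrent cells; runs that die out first are
discarded. A uniform sample of `n` cells is pruned from the population
tree (stem retained), and infinite-sites mutations fall on each branch
as Poisson(θ × branch duration). The site frequency spectrum `f_j`
(mutations carried by exactly j sampled cells) is binned by sample
fraction into `(0,0.1], (0.1,0.2], …, (0.9,1]`; the summary vector is
`(S, b₁..b₉, truncal = f_n)` — `b₁₀` is omitted as redundant given the
rest, and the binning uses integer arithmetic (`ceiling(10j/n)`), so
boundary fractions land deterministically.

Open choices, and how they were fixed:

- **Sample size n.** The default target size is N = 1000; the sample
  size n has no canonical value and defaults to 100, which keeps the
  sampled tree (2n−1 branches) small relative to the population while
  leaving multi-cell frequency classes populated. Both N and n are
  plain config knobs, never hard-coded.
- **Mutation clock.** The default is a time clock (Poisson(θ·length)),
  reading "infinite-sites at rate θ on the branches" as a rate per
  unit branch time; a per-division clock (Poisson(θ × divisions
  spanned by the branch), with divisions counted during pruning) is
  provided as `mutation_model = "division"`.
- **Stem / truncal mutations.** Truncal mutations are those carried by
  all n sampled cells; they arise on the stem (founder → sample MRCA),
  which is retained by default and can be switched off
  (`include_stem = FALSE`) since observed datasets may lack truncal
  mutations entirely.
- **Restarts.** `grow_cell_population()` restarts with the *same*
  parameters until the population survives (expected attempts
  `p/(2p−1)`, which the tests verify), with an attempt cap of 10⁴ —
  only near-critical `p` can approach it.

## 6. Forest-based ABC

The reference table pairs prior draws `(p, θ)` (independent uniforms,
defaults U(0.5, 0.8) and U(10, 20)) with simulated summary vectors.
**Conditioning happens at the (draw, run) level**: an extinct run is
discarded *together with its parameter draw* and fresh parameters are
drawn. Because survival probability increases with p, the realized
p-marginal of the table is biased upward while the θ-marginal stays
uniform — this implicit conditioning is a property of the inference
setup, is deliberately visible (the tests check both marginals), and
differs from the standalone grower, which keeps its parameters across
restarts. Posteriors built from the table answer questions conditional
on reaching N cells.

Three posterior constructions share one weighted-empirical interface:

- **Rejection:** Euclidean distance on per-column standardized
  summaries (standardization constants from the table only, never the
  observation, to avoid leakage), uniform weights on the closest
  fraction.
- **ABC-RF:** a regression forest for a single parameter; the
  posterior weight of a table row averages, over trees, the indicator
  that the row shares the observation's leaf divided by the leaf size.
- **ABC-DRF:** the same leaf-weighting with the bivariate response
  `(p, θ)`, so the weights equip the *joint* empirical posterior.

The forest is implemented in the package (Rcpp tree builder): bootstrap
resamples, `mtry = ⌈d/3⌉` features per split, nodes of ≤ `min_leaf`
(default 5) rows left unsplit, 500 trees by default — conventional
regression-forest settings, stated so results are reproducible. The
split criterion is **variance reduction summed over standardized
response components**; for a univariate response this is exactly CART
regression, and in the bivariate case it is a documented simplification
of distributional splitting — the leaf-weighting scheme, which is what
defines the posterior, is implemented exactly. Kernel-based
distributional split criteria are out of scope. Out-of-bag rows are
tracked per tree for error curves and permutation importance (OOB MSE
increase under within-tree permutation of one covariate; unused
covariates score 0 by construction). A test cross-checks the
univariate forest's OOB predictions against an independent
implementation (`ranger`).

Posterior reporting is weighted-empirical throughout: means, weighted
type-1 quantiles (levels 0 and 1 return the support extremes),
equal-tailed credible intervals, weighted kernel densities (bandwidth
fixed from the unweighted support), a resampled 2-D kernel grid for the
joint, and a quantile–quantile table for comparing two posteriors.

## 7. What the synthetic generator does and does not emulate

The cell-model generator reproduces the stochastic structure of the
study system: supercritical growth conditioned on reaching N, genuine
genealogies, infinite-sites mutation, and the implicit prior
conditioning described above. It does **not** model sequencing noise or
read depth, copy-number changes, selection, or spatial structure, and
the infinite-sites assumption excludes recurrent mutation. Passing
tests therefore certify internal consistency of the laws and the
inference machinery under the model's own assumptions — not robustness
of the summaries to real sequencing artefacts.

A related caveat applies to inference for an externally observed
summary vector: its scale depends on the (unstated) sample size and
clock behind the observation. The acceptance script reports the
DRF posterior means for one published observed vector as a qualitative
check; with an unknown generating `n`, total mutation counts are not
directly commensurable, so those numbers are indicative rather than a
calibrated recovery.

## 8. Problem sizes used in the checks

The package's distributional checks run at sizes chosen to make the
tests sharp but routine on a laptop: 10⁵ event-driven replicates for
the Yule/BDP laws (total-variation band 0.02; chi-square and KS at
level 0.01), 10⁴ conditioned replicates for the split-time
equivalences, 2×10⁵ immigration replicates for the negative-binomial
and Ewens checks, 10⁵ replicates for the Fisher module, and an ABC
study with a 2000-row reference table, 200 trees, 50 held-out synthetic
observations (coverage of 90% intervals, posterior-vs-prior RMSE) and
five importance replicates. `scripts/acceptance.R` re-runs all of this
from a single `--seed`.

## 9. Known limitations

- Only homogeneous rates are simulated (the time-inhomogeneous Yule
  law is provided in closed form, with a thinning simulator used as a
  test oracle); fossilized/serial sampling schemes and the
  fixed-n-stopping sampling scenarios are not implemented.
- `ape::phylo` conversion requires at least one split, so a
  single-lineage tree cannot be written to Newick.
- The DRF split criterion is the stated variance-reduction
  simplification, not a kernel distributional criterion; with strongly
  dependent response components the split choice (not the weighting)
  may differ from distributional-forest implementations.
- Near-critical division probabilities (p → 0.5) make single growth
  runs arbitrarily long; the reference-table conditioning mitigates
  this in the ABC pipeline, but standalone growth at p barely above
  0.5 is expensive by nature.
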