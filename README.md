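# bdtree

Linear birth–death processes (LBDPs) are the workhorse generative models
of phylogenetics and population genetics: each of the `n` current
individuals splits at per-capita rate λ and dies at rate μ, so the
population-level rates are nλ and nμ. `bdtree` collects, in one R
package, the exact distribution theory of these processes, simulators
for the trees they generate, the classical immigration extensions used
for species- and allele-frequency problems, and a modern likelihood-free
inference pipeline — so that every closed form in the package can be
checked against an independent simulation route, and vice versa.

The package is aimed at researchers and students in phylogenetics,
population genetics and cancer evolution who need trustworthy building
blocks: exact laws to test a simulator against, fast simulators to test
an inference method against, and a reference implementation of
random-forest ABC for a tumour-growth model.

## What is inside

**Population-size laws** (`dyule`, `dyule_inhom`, `dbdp`,
`bd_beta_alpha`, `extinction_prob`). For the Yule process (μ = 0) the
size at time *t* is geometric, `P(Z=n) = e^{-λt}(1-e^{-λt})^{n-1}`, and
negative binomial from *r* founders; a time-varying rate λ(u) only
re-clocks time through ρ(t) = ∫λ(u)du. For the general LBDP,

    p_10(t) = α(t),   p_1m(t) = (1-α(t))(1-β(t))β(t)^{m-1},  m ≥ 1,

with β(t) = λ(e^{(λ-μ)t}-1)/(λe^{(λ-μ)t}-μ), α = (μ/λ)β, and the
critical limit β = λt/(1+λt) taken automatically. The identity
β′ = λ(1-α)(1-β) and the extinction probability min{1, (μ/λ)^{z0}} are
exposed and tested.

**Timed trees** (`simulate_complete_tree`, `prune_to_reconstructed`,
`simulate_reconstructed_tree`, `yule_split_times`, `bd_split_cdf`,
`write_newick`/`read_newick`). Complete trees are simulated
event-by-event (rate n(λ+μ), split probability λ/(λ+μ)); pruning removes
lineages with no extant descendant and suppresses unary nodes, giving
the ultrametric reconstructed tree. Reconstructed trees with exactly
*n* tips are sampled directly: the n−1 split times are the order
statistics of i.i.d. draws from the CDF `G(u) = 1 − β(t−u)/β(t)`
(inverse-CDF closed form), avoiding rejection entirely. Trees convert
to `ape::phylo` and round-trip through Newick.

**Immigration / families** (`simulate_family_process`,
`expected_family_count`, `dbdi`, `dewens`). With Poisson(θ) immigration
and LBDP family growth, the number of families of size j is Poisson with
mean (θ/λ)β(t)^j/j, the population size is negative binomial, and
conditional on Z(t) = n the size configuration follows the Ewens
sampling formula with concentration θ/λ.

**Fisher's multiple-sampling problem** (`overlap_mean`, `overlap_cov`,
`ev2_mean_times`, `ev2_mean_sizes`, `simulate_two_sample_v2`). Under
unit-rate Yule growth with immigration, the species counts F₁, F₂ of
two consecutive samples have explicit Poisson means and covariance, and
the expected sample variance EV₂ = E(F₁−F₂)²/2 reduces, for equal
sample sizes n, to θ log{(2n+θ)/(n+θ)} → θ log 2.

**Cell model + ABC** (`cell_config`, `simulate_cell_dataset`,
`abc_reference_table`, `abc_fit`, `variable_importance`). A cell
population grows from one cell (division probability p, else death)
until N cells; n cells are sampled, infinite-sites mutations (rate θ)
fall on the sampled ancestral tree, and the site frequency spectrum is
binned into the summary vector (S, b₁..b₉, truncal count). Inference
for (p, θ) is by rejection ABC, ABC-RF (marginal posteriors) or ABC-DRF
(joint posterior from a bivariate-response forest via leaf weights),
with out-of-bag permutation importance.

## Worked example

```r
library(bdtree)
p <- bd_params(lambda = 1, mu = 0.5)

dbdp(0:5, t = 1, params = p)
#> [1] 0.28236670 0.31236181 0.17640114 0.09961962 0.05625853 0.03177107
```

28.2% of populations started from one individual are extinct by t = 1
(this is α(1)); conditional on survival the size is geometric. A
reconstructed tree with 5 extant tips, sampled directly from the
conditional split-time law:

```r
tr <- simulate_reconstructed_tree(5, t = 1, params = p, seed = 11)
tr
#> Timed reconstructed birth-death tree: 9 nodes, 5 extant leaves, t = 1
```

Fisher's expected two-sample variance for consecutive samples of 50
specimens at θ = 3:

```r
ev2_mean_sizes(50, 50, theta = 3)
#> [1] 1.993311        # = 3 log(103/53), near the large-sample θ log 2
```

Likelihood-free inference in the cell model (here at reduced size so it
runs in seconds; the defaults are N = 1000, n = 100):

```r
cfg <- cell_config(p = 0.7, theta = 15, N = 300, n = 50)
tab <- abc_reference_table(abc_priors(), R = 400, config = cfg, seed = 1)
obs <- simulate_cell_dataset(cell_config(0.722, 11.07, N = 300, n = 50),
                             seed = 99)
round(obs, 3)
#>        S       b1       b2       b3       b4  ...  truncal
#> 2016.000    0.886    0.051    0.048    0.014  ...    1.000

fit <- abc_fit(tab, obs, method = "drf", num_trees = 200, seed = 2)
summary(fit)
#> ABC posterior summary (DRF), 90% equal-tailed intervals
#>          mean     sd   lower  median   upper
#> p      0.7649 0.0339  0.6970  0.7773  0.7980
#> theta 12.2243 1.6537 10.2484 12.1459 14.9765
```

The 90% intervals cover the generating values p = 0.722, θ = 11.07.
`plot(fit)` draws the weighted marginal densities and the joint
contour; `variable_importance(fit)` ranks the summary statistics (the
total mutation count S dominates for θ).

A thin command-line front end wraps the same functions
(`inst/exec/bdtree`): subcommands `pmf`, `simtree`, `immsim`, `esf`,
`fisher`, `cellsim`, `abc`; every stochastic command requires an
explicit `--seed`. See `docs/formats.md` for the file formats.

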