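# linkshrink

Bayesian linear regression with **all two-way interactions** under a
**linked local shrinkage** prior, plus exact **interventional Shapley
values** with posterior credible intervals.

Adding every two-way interaction to a regression model is a classic move in
epidemiological and clinical analyses — and a dimensional trap: with `p`
covariates the number of interaction terms `q = p(p-1)/2` grows
quadratically, so `p + q` quickly reaches the order of the sample size `n`.
`linkshrink` targets exactly that middle regime. It is written for analysts
who want one model fit to deliver estimation, prediction, selection,
uncertainty quantification *and* per-individual variable importance.

## The model

For encoded covariates $x_{ij}$,

$$
Y_i = \alpha + \sum_j \beta_j x_{ij} + \sum_{j<k} \beta_{jk} x_{ij} x_{ik}
      + \varepsilon_i, \qquad \varepsilon_i \sim N(0,\sigma^2),
$$

$$
\beta_j \sim N(0, \sigma^2\tau_j^2),\quad
\beta_{jk} \sim N(0, \sigma^2\tau_j\tau_k\tau_{\mathrm{int}}),\quad
\tau_j \sim C^+(0,1),\quad
\tau_{\mathrm{int}} \sim U(0.01, 1).
$$

The product $\tau_j\tau_k$ *links* the shrinkage of an interaction to its
two parent main effects — a soft heredity principle: interactions of strong
mains are shrunk little, interactions of two null covariates are shrunk
hard, and the global factor $\tau_{\mathrm{int}}$ adapts the overall
strength of the interaction block. Variants: `bayint_star` (pins
$\tau_{\mathrm{int}}=1$), `bay0int` (unshrunk mains), `bayintadd`
(additive scale link $(\tau_j^2+\tau_k^2)/2$).

The posterior is sampled by a blocked Gibbs sampler with exact conditional
updates (multivariate-normal coefficient block, conjugate inverse-gamma
$\sigma^2$, slice updates for the $\tau$'s), cross-validated against an
independent MCMC engine. For a fitted model, the interventional Shapley
value of covariate $j$ for individual $i$ has the exact closed form
(centered covariates)

$$
\phi_{ij} = \beta_j x^*_{ij} + \tfrac12\sum_{k\neq j}\beta_{jk}
  \left(x^*_{ij}x^*_{ik} - E[x_{ij}x_{ik}]\right),
$$

evaluated per posterior draw, so every importance score comes with a
credible interval. A coalition-enumeration oracle validates the closed form
(including grouped players for categorical covariates) in the test suite.

## Worked example

Simulate the built-in design (n = 200, p = 10, q = 45, 18 nonzero
coefficients, noise calibrated so the population R² is 0.5), fit, and
inspect:

```r
library(linkshrink)
library(dplyr)

sim <- simulate_dataset(sim_config("sim1"), seed = 1)
fit <- bayint(sim$data, response = "y",
              chains = 4, warmup = 500, iter = 1250, seed = 1)
fit
#> <bayint_fit> variant = bayint | n = 200 | p_enc = 10 | q = 45
#>  draws = 5000 ( 4 chains x 1250 kept )
#>  max coefficient R-hat: 1.008

tidy(fit) %>% filter(excludes_zero) %>% arrange(desc(abs(estimate)))
#> # A tibble: 2 × 8
#>   term  type  estimate std.error conf.low conf.high excludes_zero score
#> 1 x2    main     1.16      0.212    0.758      1.58 TRUE              1
#> 2 x1    main     0.940     0.214    0.532      1.37 TRUE              1
```

At this sample size the 95 % credible intervals single out the two largest
true main effects (true values 0.75 and 1.0; the posterior is on the
per-replicate standardized scale). `score` is the largest credible level at
which an interval still excludes zero — a sweepable selection ranking.

Shapley values with uncertainty, and global importance:

```r
sh <- shapley(fit, sim$data[1:5, ], thin = 5)
global_importance(sh) %>% arrange(desc(importance)) %>% head(4)
#> # A tibble: 4 × 4
#>   covariate importance importance_main importance_int
#> 1 x2             1.20            1.21          0.257
#> 2 x1             0.715           0.715         0.0956
#> 3 x3             0.502           0.342         0.211
#> 4 x5             0.264           0.230         0.161
```

The importance ordering tracks the true effect sizes, and the
main/interaction split shows where each covariate's contribution comes
from (note the two components need not sum to the total — they can cancel
in sign). `autoplot(sh)` draws the per-individual intervals.

Where is a covariate's effect significant, given an interacting partner?

```r
range_of_significance(fit, "x1", "x2", grid = c(-2, 0, 2))
#> # A tibble: 3 × 5
#>     x_k estimate conf.low conf.high excludes_zero
#> 1    -2    0.658   -0.170      1.47 FALSE
#> 2     0    0.940    0.532      1.37 TRUE
#> 3     2    1.22     0.517      1.98 TRUE
```

The unit-change effect of `x1` is credibly positive at and above the
center of `x2` but not at `x2 = -2` — the interaction widens and shifts
the band.

A command-line wrapper for shell pipelines is installed at
`system.file("cli", "linkshrink.R", package = "linkshrink")` with
`simulate`, `fit` and `shapley` subcommands; all outputs are seeded CSVs
with provenance headers.

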