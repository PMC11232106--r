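---
title: "Linked shrinkage for two-way interaction models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linked shrinkage for two-way interaction models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linkshrink)
```

## The model

For a continuous response $Y_i$ and encoded covariates $x_{ij}$,
$j = 1, \dots, p$, the package fits the linear model with all admissible
two-way interactions,

$$
Y_i = \alpha + \sum_{j} \beta_j x_{ij}
  + \sum_{j < k} \beta_{jk}\, x_{ij} x_{ik} + \varepsilon_i,
\qquad \varepsilon_i \sim N(0, \sigma^2),
$$

under the linked local shrinkage prior

$$
\beta_j \sim N(0, \sigma^2 \tau_j^2), \qquad
\beta_{jk} \sim N(0, \sigma^2 \tau_j \tau_k \tau_{\mathrm{int}}), \qquad
\tau_j \sim C^+(0, 1),
$$

with $\tau_{\mathrm{int}} \sim U(0.01, 1)$, $\alpha \sim N(0, 10^2)$ and
$\sigma^2 \sim \mathrm{IG}(1, 0.001)$ (shape–scale parameterization, density
$\propto (\sigma^2)^{-2} e^{-0.001/\sigma^2}$). The essential idea is the
product $\tau_j \tau_k$: an interaction borrows its prior scale from the
local scales of its two parent main effects, so interactions attached to
strong mains are shrunk little while interactions between two apparently
null covariates are shrunk hard. This is a soft, symmetric version of the
heredity principle — no hard constraint forces a main effect into the model
before its interactions. The global factor $\tau_{\mathrm{int}}$ lets all
interactions be weaker on average than the mains; its lower bound 0.01
prevents the interaction block from being shrunk away entirely in sparse
problems.

The number of interactions $q$ grows quadratically with $p$
($q = p(p-1)/2$ for all-continuous covariates), which is exactly the regime
— $p + q$ of the same order as $n$ — the prior is designed for.

Four variants are available through `prior_spec()` / the `variant` argument
of `bayint()`:

* `bayint` — the model above;
* `bayint_star` — pins $\tau_{\mathrm{int}} = 1$; more power to detect
  strong interactions, usually worse prediction;
* `bay0int` — main effects get a wide fixed $N(0, 10^2)$ prior (no
  shrinkage); the $\tau_j$ remain but act only through the interactions;
* `bayintadd` — replaces $\tau_j \tau_k$ by $(\tau_j^2 + \tau_k^2)/2$, so
  the *stronger* parent dominates. The literature renders this variant's
  scale ambiguously (a square root may or may not be intended); we
  implement the arithmetic mean of the variances, which is dimensionally
  consistent with the geometric-mean form of `bayint`, and document it as
  our reading.

## Covariate coding

`encode_covariates()` applies conventions that make coefficients comparable
and decorrelate mains from their interactions:

* continuous columns are standardized, $(x - \bar{x})/s$ with the $n-1$
  sample s.d. (centering removes most of the collinearity between $x_j$ and
  $x_j x_k$; scaling puts all coefficients on one scale);
* binary columns map their two sorted raw values to $(-1, +1)$ — a
  deterministic convention, standardized in the balanced case;
* a categorical covariate with $L$ levels becomes $L-1$ sum-to-zero
  contrast columns with values in $\{-1, 0, 1\}$, the *last* schema level
  serving as the reference (all its rows are $-1$). The value set is
  fixed by convention in the field; the specific contrast matrix is our
  documented choice, as symmetric treatment of the non-reference levels.
* pairs of contrast columns belonging to one categorical covariate are
  excluded from the interaction set, hence
  $q = \binom{p_{\mathrm{enc}}}{2} - \sum_c \binom{d_c}{2}$ with $d_c$ the
  dummy count of categorical $c$ (e.g. 14 encoded columns with one 4-dummy
  categorical give $91 - 6 = 85$).

Transform statistics are learned once on the training table and frozen
(`design$stats`); new data — for prediction, Shapley values or unit-change
effects — is always encoded with the training statistics, and unknown
levels raise an error naming the offending value.

## Posterior computation

The Gaussian likelihood makes the model conditionally conjugate in its two
large blocks, which we exploit with a blocked Gibbs sampler:

1. $(\alpha, \beta) \mid \tau, \tau_{\mathrm{int}}, \sigma^2$ is exactly
   multivariate normal; we draw it by a Cholesky solve of the posterior
   precision $X^\top X/\sigma^2 + D^{-1}$ — one exact draw of all
   $1 + p + q$ coefficients per sweep, with no tuning and no rejection;
2. $\sigma^2 \mid \beta, \tau$ is conjugate inverse-gamma (the coefficient
   priors are scaled by $\sigma^2$, so the shape collects $n/2$ plus half
   the number of scaled coefficients);
3. each $\tau_j$ (half-Cauchy, non-conjugate) is updated by univariate
   slice sampling on the log scale (stepping-out with unit width, then
   shrinkage); its conditional involves $\beta_j$ and all interactions
   containing $j$;
4. $\tau_{\mathrm{int}}$ is slice-sampled within its bounded support
   $[0.01, 1]$ (or held at 1 for `bayint_star`).

Exact block updates give good mixing here because the strong posterior
correlations are *within* the coefficient block, which is sampled jointly.
We verified the sampler two ways: `log_joint_density()` is tested against
an independently hand-coded sum of textbook log densities, and the full
sampler is cross-checked against an independent MCMC engine (JAGS) fitting
the same joint on the same data, with posterior means agreeing to Monte
Carlo error (see `test-model.R`).

Each chain is seeded as `seed + chain - 1`, so fits are bit-reproducible.
Defaults are 4 chains with 1,000 warmup and 5,250 kept sweeps
($\approx$ 25,000 draws); tests and examples use far fewer (2–4 chains of a
few hundred sweeps), which is adequate for posterior means because every
sweep moves all coefficients. Convergence is summarized by split-$\hat{R}$
and effective sample size per parameter; a maximum coefficient
split-$\hat{R}$ above 1.1 triggers a warning, never silence.
Initialization ($\tau_j = 0.5$, $\tau_{\mathrm{int}}$ at mid-support,
$\sigma^2 = \mathrm{var}(y)$) only affects warmup.

## Interventional Shapley values

For this model class the interventional Shapley value — players are
covariates fixed at the individual's values, non-players are marginalized
*ignoring their dependence on the players* — has an exact closed form. With
centered covariates,

$$
\phi_{ij} = \beta_j x^*_{ij}
 + \tfrac{1}{2} \sum_{k \ne j} \beta_{jk}
   \left( x^*_{ij} x^*_{ik} - E[x_{ij} x_{ik}] \right).
$$

Two derivation details deserve emphasis:

* **The $\tfrac12$ applies to both the product term and the moment term.**
  A two-player enumeration shows this directly: for
  $f(x) = \beta_{12} x_1 x_2$ with centered covariates,
  $\phi_1 = \tfrac12 \beta_{12} (x^*_1 x^*_2 - E[x_1 x_2])$. Placing the
  factor on the product term only would also contradict the fact that
  Shapley values average to zero over the training distribution when
  covariates are centered. The brute-force coalition enumeration
  (`shapley_bruteforce()`, the defining weighted average over all
  $2^{P-1}$ coalitions per player) is the arbiter, and the test suite
  enforces agreement to $10^{-9}$ on random instances.
* **Non-centered columns and categorical covariates.** Binary and contrast
  columns have nonzero means, and a categorical's contrast columns are not
  independently manipulable, so the package treats each *source covariate*
  as one player (all its contrast columns enter or leave a coalition
  together) and uses the general form
  $\phi$-contribution of column $j$:
  $\beta_j (x^*_j - m_j) + \tfrac12 \sum_k \beta_{jk}
  [(x^*_j x^*_k - M_{jk}) + (x^*_j m_k - m_j x^*_k)]$,
  with $m_j = E[x_j]$ and $M_{jk} = E[x_j x_k]$ estimated on the training
  sample (denominator $n$) and frozen at fit time. This reduces to the
  display above when $m = 0$, and is validated against the enumeration
  oracle including grouped players rather than transcribed from any
  external source.

Computed per posterior draw, $\phi_{ij}$ inherits full posterior
uncertainty: a noise covariate should show credible intervals covering zero
for essentially all individuals, which is exactly what the acceptance test
checks on the simulation design with pure-noise columns. The split
$\phi_{ij} = \phi^{\mathrm{main}}_{ij} + \phi^{\mathrm{int}}_{ij}$ is exact
by construction, and the global importance scores
$I_j = \tfrac1n \sum_i |\phi_{ij}|$ (and the analogous component scores)
are computed on posterior means; note $I_j \ne I^{\mathrm{main}}_j +
I^{\mathrm{int}}_j$ in general because components can cancel in sign.

The interventional convention is a modelling choice, not a theorem: when
covariates are strongly dependent, marginalizing non-players from their
marginal law can evaluate the model far from the data. Dependency-aware
(conditional) Shapley values are out of scope.

## Conditional effects

`unit_change_effect()` computes
$E_{ij} = \beta_j + \sum_{k \ne j} \beta_{jk} x_{ik}$ per draw — the slope
of covariate $j$ at individual $i$'s position. $\beta_j$ alone is only the
conditional effect at the covariate center. `range_of_significance()`
isolates one interacting partner: the posterior band of
$\beta_j + \beta_{jk} x_k$ over a grid of $x_k$ (default 41 equally spaced
points across the observed training range — fine enough for plotting,
cheap to compute), flagging where the band excludes zero.

## Selection and evaluation

A coefficient is *selected* when its equal-tailed credible interval at the
chosen level excludes zero. The per-coefficient `score` — the largest level
at which the interval still excludes zero, computed as
$1 - 2\min(\Pr(\beta < 0), \Pr(\beta > 0))$ from the draws — turns the
binary rule into a sweepable ranking, with selection at level $\gamma$
recovered as `score >= gamma`.

`sensitivity_at_fdr()` evaluates such rankings against a known truth: sweep
the threshold, compute at each selection the realized false discovery
proportion $\mathrm{FP}/(\mathrm{FP}+\mathrm{TP})$ and the sensitivity
$\mathrm{TP}/\#\mathrm{positives}$, and report the sensitivity of the
largest selection meeting each FDR bound. Truth labels may be
`"indeterminate"`, which excludes a coefficient from both counts — the
convention needed when "truth" is itself an estimate (e.g. significance in
a very large reference fit). The FDR here is empirical, not a
multiple-testing procedure: the sweep is over the selection score, ties
broken by coefficient index. Estimator accuracy uses the companion
criteria `coef_rmse()` (root mean squared error per coefficient over $B$
replicate training sets) and `msep()` (squared distance
$\lVert X_{\mathrm{test}}\hat\beta - X_{\mathrm{test}}\beta \rVert_2^2$
between fitted and true linear predictors, reported per replicate and
averaged — deliberately not normalized per observation).

## Simulation designs

Two fully specified designs with known truth drive the recovery tests:

* **sim1**: $n = 200$, $p = 10$ standard-normal covariates with
  exchangeable correlation $\rho$, $q = 45$. Five nonzero mains and 13
  nonzero interactions — 6 between two nonzero mains, 4 between a nonzero
  and an absent main, 3 "surprising" ones between absent mains, exactly
  two of the surprising ones sharing a covariate — 18 nonzero coefficients.
* **sim2**: $n = 500$, same structure plus four independent pure-noise
  covariates ($p = 14$, $q = 91$); being sparser, the signal of one main
  and one interaction of each type is increased by half.

Residual noise is calibrated by Monte Carlo ($10^5$ draws of the covariates)
so the *population* $R^2 = \mathrm{Var}(X\beta) /
(\mathrm{Var}(X\beta) + \sigma_\varepsilon^2)$ hits its target (0.5 by
default); the acceptance script re-derives the realized $R^2$ from a fresh
$10^5$-row dataset by OLS.

Quantities the design leaves open were fixed once as package conventions:
"moderate" collinearity as exchangeable $\rho = 0.3$; main effects
$(1.0, 0.75, 0.5, 0.3, 0.15)$ and interactions spanning $0.1$–$0.3$ with
the stated type structure; the boost factor $1.5$ applied in sim2 to the
first (largest) main and the first interaction of each type. All are
arguments of `sim_config()`. The response is generated on the raw
standard-normal covariate scale, which the encoder reproduces up to
sampling error in the per-replicate standardization; recovery is therefore
evaluated on the encoded scale.

A third setting, `helius_like`, emulates a mixed-type epidemiological
covariate table (three continuous, three binary, one 5-level categorical,
four noise columns; 14 encoded columns, $q = 85$) for exercising the
encoding and the grouped-player Shapley path. Its default truth is a small
arbitrary set of plausible effects — a convention for testing, not a fact
about any cohort.

What the generators deliberately do **not** emulate: non-Gaussian or
skewed covariates, missing values, measurement error, nonlinearity on the
covariate scale, and dependence structures beyond exchangeable
correlation. A passing recovery suite therefore demonstrates correctness
of the machinery under the model's own assumptions, not robustness on
messy real data.

With the default sim1 conditions ($R^2 = 0.5$ spread over 18 mostly small
effects at $n = 200$), the posterior-mean-versus-truth correlation over the
nonzero coefficients is inherently noisy — per-coefficient standard errors
are of the same order as the smaller true effects — so replicate-level
recovery correlations fluctuate around the high 0.8s even though the
sampler is exact-in-distribution and clearly beats OLS on the same
criterion. Test problem sizes were chosen as the smallest that make each
property statistically unambiguous: fits in the suite use 2–4 chains of a
few hundred sweeps, Monte Carlo oracles use $10^5$–$2\times10^5$ draws, and
the brute-force Shapley comparisons use $p \le 8$.

## Degenerate inputs and numerical conventions

Constant continuous columns error (scale undefined); binary columns must
show exactly two values in training data; unknown levels in new data error
by name; missing values error (imputation is out of scope). Moments use
denominator $n$, standardization uses $n - 1$; both choices are stated in
the docs and the tests tolerate the $O(1/n)$ gap where relevant.
Out-of-support parameter points yield `-Inf` from `log_joint_density()`
rather than an exception, so samplers and optimizers can probe freely.
Coefficient tables follow the deterministic lexicographic pair order
$(j, k)$, $j < k$, everywhere.

## Limitations

Gaussian likelihood only (no logistic/Cox extensions here); no
higher-order interactions; no variational approximation — the sampler is
exact MCMC, and scales comfortably to the $p + q \approx n$ regime it
targets, not to high-dimensional $p$. Inference for *global* importance
scores (credible statements about $I_j$) is deliberately not provided:
aggregating absolute per-individual scores lacks a natural null, so the
package reports per-individual intervals and leaves global inference to
the analyst.
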