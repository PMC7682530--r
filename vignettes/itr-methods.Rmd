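---
title: "Estimating individualized treatment rules in multi-arm trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating individualized treatment rules in multi-arm trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A randomized trial assigns each of $n$ subjects to one of $K$ arms
($A_i \in \{1, \dots, K\}$, here $K = 3$ with known randomization
probabilities $P(A = a \mid X) = 1/3$), records baseline covariates $X_i$
and a scalar outcome $Y_i$ for which larger is better. An individualized
treatment rule (ITR) $D$ maps covariates to an arm. Its value is the
expected outcome if the whole population were treated according to it,

$$V(D) = E\left\{\frac{I(A = D(X))}{P(A \mid X)}\,Y\right\},$$

estimated by the plug-in inverse-probability-weighted (IPW) sum divided by
$n$ (`ipw_value()`; a Hájek-normalized variant is available behind a flag
but the plug-in form is the default, because it is the estimator as
written). Positivity of the propensities is asserted at construction time.
The goal is the rule maximizing $V$.

The motivating application is a three-arm blood-donation trial in which
male donors were randomized to 12-, 10- or 8-week minimum inter-donation
intervals for two years. The benefit outcome $G$ is the units of whole
blood collected; the risk outcome is the low-hemoglobin deferral rate $R$
(deferral count $\tilde R$ over attendances). The two are combined in the
utility $U = G - b\,\tilde R$, where $b \ge 0$ is the equivalent loss in
collected units per extra deferral; $b$ is swept over $1, \dots, 5$.
Because the framework maximizes, the deferral target is analyzed as
$\arcsin\sqrt{1 - R}$: the arcsine square-root transform stabilizes the
variance of a proportion, and applying it to $1 - R$ makes the target
rank-decreasing in $R$, so maximizing it minimizes the deferral rate.

## The five learners

`itr(data, method = ...)` fits one of five rules; all `predict` methods
break argmax ties toward the smallest arm index. In the donor application
arm 1 is the longest (12-week) interval, so ties resolve toward the safest
option; in the abstract simulations ties have probability zero for
continuous covariates and the choice is a determinism device.

**Penalized least squares (`"pls-gl"`, `"pls-hgl"`).** $E(Y \mid X, A)$ is
fit on the basis $(1, X, A, XA)$ — intercept, covariate main effects,
$K - 1$ arm dummies, and all arm-by-covariate interaction blocks, with
categorical covariates dummy-coded at the factor level — and the rule is
the argmax of the $K$ predicted means. Selection is at the group level: a
categorical covariate's dummies form one group, as does each interaction
block, so a covariate enters or leaves whole. The GL variant penalizes all
non-intercept groups with weights $\sqrt{p_g}$. The HGL variant enforces
strong hierarchy (a selected interaction forces both its parent main
effects in) through the overlapped-group formulation: each interaction
group is augmented with copies of its parent main-effect and arm columns
and the augmented design is solved as an ordinary group lasso, with
coefficients summed over copies afterwards. The solver is block coordinate
descent with within-group orthonormalization, which makes each block
update an exact groupwise soft-threshold; convergence is declared when the
relative objective change falls below $10^{-7}$. The $\lambda$ grid has 50
log-spaced points from $\lambda_{\max}$ (the smallest value zeroing every
penalized group) down four decades, and $\lambda$ is chosen by five-fold
cross-validated mean squared error (minimum rule, not 1-SE: the study
protocol says only that tuning is cross-validated). Zero-variance
directions within a group are dropped; a fully degenerate group is dropped
with a warning. The intercept is unpenalized (absorbed by centering), all
other groups penalized.

**Adaptive contrast weighted learning (`"acwl"`).** Per-arm conditional
means are estimated flexibly (default: gradient-boosted trees, 500 rounds,
depth 3, learning rate 0.05 — ACWL's appeal is robustness to the outcome
model, so the default is flexible; a linear regressor is available) and
corrected into doubly-robust AIPW pseudo-estimates
$\hat\mu_a(X_i) = \tilde\mu_a(X_i) + I(A_i = a)\pi_a^{-1}(Y_i -
\tilde\mu_a(X_i))$. The subject-level pseudo-estimate form is one concrete
reading of the AIPW construction the method's authors cite; it is
oracle-tested here rather than claimed to match their original code. Per
subject the arm means are ordered (ties by arm index, the best label being
the smallest tied arm) and the contrasts $C_1 = \hat\mu_{(K)} -
\hat\mu_{(K-1)}$ and $C_2 = \hat\mu_{(K)} - \hat\mu_{(1)}$ bound the loss
from a suboptimal assignment below and above. The rule is a weighted
classification tree (rpart) predicting each subject's best arm with weight
$C_2$ by default ($C_1$ is implemented; the conservative upper bound is
the reported variant), grown with `cp = 1e-4` and pruned along the
cost-complexity path by five-fold cross-validation with the 1-SE rule;
the minimum leaf size scales as $n/400$ (50 at $n = 20{,}000$). If all
contrast weights are numerically zero the majority label is returned with
a warning.

**Direct learning (`"dlearn"`).** For each unordered arm pair $\{a, i\}$,
with $A_{ai} = +1$ on arm $a$ and $-1$ on arm $i$, the linear decision
function $f_{ai}$ minimizes
$\sum_j \{2 Y_j A_{ai,j} - X_j^\top\beta\}^2 / P(A_j \mid X_j)$; the rule
is $\arg\max_a \sum_{i \ne a} \hat f_{ai}(x)$ using the exact
anti-symmetry $f_{ia} = -f_{ai}$. Under uniform randomization the weights
are constant; they are kept explicit so an observational extension would
have to supply real propensities. Decision functions are linear only (the
nonlinear variant was impractical at this scale); an optional l1 penalty
(cross-validated lasso) is behind a flag and off by default.

**BART (`"bart"`).** A sum-of-trees posterior for $E(Y \mid X, A)$ with
the arm supplied as one-hot dummy inputs so trees may split on any arm
contrast. The sampler is implemented in compiled code: backfitting MCMC
with grow (0.25), prune (0.25) and change (0.5) proposals, conjugate
normal leaf means, and a scaled-inverse-chi-square error variance. Priors
follow the customary defaults: 200 trees, split prior
$0.95(1 + d)^{-2}$, leaf scale $k = 2$ after internally mapping the
outcome to $[-0.5, 0.5]$ (predictions are mapped back), and
$\nu = 3, q = 0.90$ for the variance. Default chain: 100 burn-in sweeps
and 1,000 kept draws; 100 uniformly spaced cutpoints per variable. Kept
draws store the whole forest, so a fitted rule can be applied to new
covariate tables. The rule assigns each subject the arm with the largest
posterior mean.

Two posterior summaries accompany the BART rule. For any rule,
`posterior_itr_effect()` computes per draw the model-based ITR effect —
the predicted outcome under the recommended arm minus the predicted
outcome averaged over the remaining arms, averaged over subjects — and
reports the posterior mean with an equal-tail 95% interval. This
counterfactual form (rather than conditioning on the observed arm) was
chosen because it is monotone in the predicted outcome under the rule,
which gives `optimized_itr_reference()` — the idealized rule that, within
each draw, assigns every subject to that draw's best arm — an exact
draw-by-draw dominance over every fixed rule. The optimized reference is
flagged non-achievable; it is a best-case envelope, not a deployable rule.
Cross-method comparisons report spread across replicates or splits, not
posterior SDs, so the Bayesian and frequentist columns measure the same
thing.

## Evaluation

`misclassification()` scores a rule against the known optimal arms of a
simulated setting. `itr_effect()` is the empirical ITR effect
$\hat\delta(D) = \bar Y_{A = D(X)} - \bar Y_{A \ne D(X)}$; for a
`fixed_rule()` it compares one arm against the pooled others. If either
group is empty the effect is undefined and returned as `NA` with a
warning, deliberately distinct from zero. The identity
$\delta_U = \delta_G - b\,\delta_{\tilde R}$ holds exactly and is tested
exactly.

## Synthetic data

**Simulation settings.** Six data-generating processes with
$Y = m(X) + 0.5\,\Delta_A(X) + \varepsilon$, $\varepsilon \sim N(0, 1)$,
$m(X) = 1 + 0.5X_4 + 0.3X_5$, three equiprobable arms, five independent
covariates, and interaction functions spanning tree-type (1), linear (2),
nonlinear with a covariate product (3), nonlinear (4), discrete-covariate
(5) and trivial single-best-arm (6) structure; $\Delta_3 \equiv 0$
throughout. `sim_trial()` attaches the true optimal arms (brute-force
argmax of the $\Delta$s). The evaluation test set is drawn once per
setting from a seed derived from the master seed and reused across
replicates; the zero spread reported for the trivial setting under
repeated fits is only possible with a fixed test set, which is why that
reading was adopted (it is an inference, not a documented protocol).
`oracle_value()` gives the exact population value of any rule by
Monte-Carlo integration of $m + 0.5\,\Delta_{D(X)}$, a diagnostic the IPW
estimator can be checked against; for the trivial setting the closed form
under the always-arm-1 rule is $1 + 0.5(P(X_1 > 0.5) + 2) = 2.125$.

**Donor cohort.** `gen_donor_cohort()` emulates the application's
structure with no external data: 19 baseline covariates (11 continuous, 8
categorical with realistic level sets), uniform three-arm assignment, a
negative-binomial attendance count over two years (means 5.2 / 6.3 / 8.0
by arm, dispersion 12), and at each attendance a Bernoulli low-Hb deferral
(baseline probabilities 2.0% / 3.3% / 5.2% by arm, modified on the logit
scale by baseline hemoglobin and a sign-preserving arm-step interaction);
a non-deferred attendance collects one unit, so $G = N - \tilde R$ and the
container invariants ($\tilde R \le N$, $G \le N$, $R \in [0, 1]$) hold by
construction. These values were chosen once to make the marginal arm
contrasts land near the application's published fixed-rule effects
(donation effects of roughly $-1.2/-0.1/+1.3$ and deferral-rate effects of
$\mp 0.025$), and are not tuned further. With the default, purely
quantitative configuration the benefit-optimal arm is 8 weeks and the
risk-optimal arm 12 weeks for every donor, so single-outcome analyses
should recover one-size-fits-all rules; the `qualitative_strength` knob
makes frail donors (low hemoglobin, little donation history) attend less
under the 8-week arm, flipping their benefit-optimal interval and
inducing genuine heterogeneity under the utility target. Donors with zero
attendances can occur (about 1%); their undefined deferral rate is set to
0 with a warning, since the application excluded such donors but a
generator must still produce them. The generator does not attempt the
real cohort's joint covariate distribution, nor post-deferral return
behavior; what passing tests show is that the estimation pipeline
recovers known polarity and trend structure, not that it would reproduce
any particular real-data number.

## Orchestration and reproducibility

`run_simulation_study()` evaluates settings × methods × replicates on the
fixed test sets; `run_application()` repeats 4:1 train/validation splits
of a cohort over the three targets and the $b$ grid, reporting assignment
proportions and ITR effects with across-split means and SDs (these SDs
measure repeatability of the data splitting, nothing more). Replicate
$r$ of setting $s$ uses seed $\text{master} + 1000s + r$ and the test set
seed $\text{master} + 77000 + s$, so identical configurations reproduce
identical reports byte for byte. Method failures inside a replicate are
tallied and excluded from that method's summary rather than aborting the
study. Reports serialize to CSV and JSON via `write_report()`; trial
datasets round-trip through CSV with a YAML sidecar declaring column
types, factor levels, arm/outcome columns, propensities and seeds.

## Problem sizes used in the shipped checks

The published study used $n_{\text{train}} = 20{,}000$, a 10,000-subject
test set and 100 replicates (BART: 200 trees, 1,000 kept draws). The
package's own checks keep the training and test sizes but scale down
repetition: 10 replicates for the fast learners and 3 for BART, whose
chains are shortened to 100-300 kept draws after 100-200 burn-in sweeps.
At these sizes the Monte-Carlo spread is well inside the tolerances being
asserted, and the whole suite runs on a single CPU in minutes. Where a
check compares a 3-replicate mean against a published mean with a printed
replicate SD, the band is two published SDs. Unit tests use smaller cohorts (hundreds to a
few thousand subjects) chosen so each property is comfortably identified.

## Known limitations

The linear-basis learners cannot represent the nonlinear boundaries of
settings 3-4 (that failure is part of the reproduced pattern). The ACWL
ordering labels add noise when arm means are nearly tied, which is why
its contrasts, not its labels, carry the weight. The BART sampler uses
grow/prune/change moves only (no swap) and a shared cutpoint grid of 100
points per variable; posterior inference for cross-method comparisons is
deliberately replaced by across-replicate spread. D-learning is linear
only, and the group-lasso path assumes $n$ well above the augmented
design width — no screening rules are implemented. Inference on ITR
effects beyond across-split repeatability (e.g. bootstrap SDs) is out of
scope.
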