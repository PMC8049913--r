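---
title: "Measuring group-ensemble bias in visual working memory: estimators, Bayes factors and design analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring group-ensemble bias in visual working memory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ensemblebias)
```

## The problem

In matched-pair continuous-report experiments on visual working memory,
participants memorize the sizes of colored circles and later adjust a probe
to reproduce one of them. Each *matched pair* shows the identical probe (same
true diameter, in pixels) twice: once surrounded by larger same-colored
circles, once by smaller ones. If memory for an individual item is pulled
toward the ensemble statistics of its group, the reported size should be
larger in the larger-companions context. A default design has 15 matched
pairs (30 trials) per participant.

This package implements the statistical machinery such a study needs — bias
estimators and their type-I-error behavior, the default Bayesian t-test,
fixed-n Bayes Factor Design Analysis (BFDA), and the full pre-planned
analysis pipeline — together with a synthetic-data generator so that every
stage is testable without access to any behavioral data set.

## Three bias scores and why only one of them is safe

Writing $L_j$ and $S_j$ for participant reports of pair $j$ in the
larger- and smaller-companions context, the three per-participant scores are

* **difference**: $\frac{1}{J}\sum_j (L_j - S_j)$, null value 0 px;
* **ratio of averages**: $\bar L / \bar S$, null value 1;
* **averaging ratios**: $\frac{1}{J}\sum_j L_j/S_j$, null value 1.

For the difference score, averaging pair differences and differencing the
context means are the same number, so the order of averaging is irrelevant.
The two ratio scores are different statistics, and both are biased upward
under the null: $E[1/S] > 1/E[S]$ by Jensen's inequality, severely so when
responses can approach zero. A one-sample t-test against 1 therefore
over-rejects — mildly for the ratio of averages at small samples, and near
certainty for averaging ratios. `alpha_error()` measures this by Monte
Carlo: per repetition it generates a null experiment, scores each
participant, and t-tests the scores against the null value.

```{r}
alpha_error("difference", n_participants = 21, reps = 2000, seed = 1)
alpha_error("averaging_ratios", n_participants = 21, reps = 2000, seed = 1)
```

With the default generator, the difference score stays at the nominal .05 at
every sample size, the averaging-ratios score rejects essentially always
(about .99 at 21 participants), and the ratio-of-averages inflation grows
with n (the shrinking standard error exposes the fixed Jensen offset). The
exact ratio-score rejection rates depend on the generating distribution —
they rise as true sizes shrink relative to the noise — so we treat the
ceiling and the ordering, not the third decimal, as the reproducible facts.

## The synthetic generator

`generate_experiment()` works at the response level. For participant $i$ and
pair $j$ with true size $\mu_j$,

$$L_{ij} = \mu_j + b + \varepsilon_{ij1}, \qquad
  S_{ij} = \mu_j - b + \varepsilon_{ij2}, \qquad
  \varepsilon \sim N(0, \sigma^2),$$

truncated below at `clip_min` by redrawing. The half-shift parametrization
makes the expected difference score exactly $2b$, avoiding a factor-2
ambiguity. Defaults, chosen once:

* **true sizes 20–90 px** in steps of 5 (15 pairs): the probe's initial
  diameter in the task is bounded at 15–95 px, and this grid spans that
  range evenly. The original stimulus diameters are not published; these
  are declared stand-ins.
* **noise SD 21 px**: calibrated so the expected mean absolute error is
  $\sigma\sqrt{2/\pi} \approx 16.7$ px, the accuracy level reported for
  well-performing online participants.
* **clip_min 1 px, redraw truncation**: ratio scores need strictly positive
  reports; redrawing (rather than clamping) keeps the noise distribution
  smooth and free of an atom at the boundary. Truncation shifts the mean
  of low-size trials slightly upward; the tests verify this offset against
  a brute-force truncated-normal oracle rather than assuming it away.

The generator does **not** simulate the nine-circle displays, colors,
encoding or retention: only the signed shift the context is hypothesized to
induce, which is all the downstream statistics consume. Consequently,
passing tests show that the *analysis machinery* is correct and calibrated
under its stated model — normal noise, homogeneous across pairs and
participants — not that real data meet those assumptions (real response
distributions are heavier-tailed, participants differ in precision, and
lapses produce outliers the 25-px sanity filter only crudely removes).

## The JZS Bayes factor

The Bayesian t-test places a zero-centered Cauchy prior with scale
$r$ (default $\sqrt{2}/2$) on the standardized effect
$\delta = \mu/\sigma$, with a Jeffreys prior on $\sigma^2$. Using the
mixture representation $\delta \mid g \sim N(0, g)$,
$g \sim \text{Inv-Gamma}(1/2, r^2/2)$, the Bayes factor from the
sufficient statistics $(t, n)$ is a one-dimensional integral over $g$.
`jzs_bf10()` evaluates it in $z = \log g$, where the integrand's width is
$O(1)$ for every $t$ and $n$ (the $g$-space peak sits near $t^2/n$ and can
be extreme). The peak is located on a coarse grid, the integrand is scaled
by its height so that Bayes factors up to $e^{900}$ never overflow, and the
two half-lines around the peak are integrated adaptively with a relative
error budget of $10^{-6}$ (the integrator's own tolerance is $10^{-10}$;
exceeding the budget is an error, never a silent degradation).

```{r}
jzs_bf10(t = 5.83, n = 663)
```

`jzs_posterior()` samples the same model by a three-block Gibbs sampler
with conjugate full conditionals for the location, the variance and $g$,
discarding 10% burn-in. The location draws are summarized in the input's
units (pixels for bias), giving the posterior mean and the central 95%
credible interval; 100,000 retained iterations reproduce interval
endpoints to well under the 0.01-px display precision, and the sampler
refuses to run with fewer than 10,000.

## Power analysis and BFDA

`power_one_sample_t()` uses the noncentral t distribution exactly
(df $= n-1$, noncentrality $d\sqrt n$); `required_n_power()` bisects over
integer n. For evidence-based planning, `bfda_fixed_n_mc()` simulates
standardized samples $N(d, 1)$ and classifies each repetition's BF10
against the bounds (default 0.1 and 10), while `bfda_fixed_n_analytic()`
exploits the strict monotonicity of $|t| \mapsto \mathrm{BF}_{10}$: it
inverts the map at each bound by root-finding and evaluates (non)central-t
tail probabilities at the resulting t thresholds, so its probabilities
carry no Monte-Carlo error and the two engines cross-validate each other.

```{r}
bfda_fixed_n_analytic(d = 0, n = 663)
```

Two numerical edge cases are classified rather than failed: at small n the
Bayes factor at $t = 0$ can already exceed a sub-unit lower bound (the
bound is unreachable; its probability is 0), and at $n = 2$ BF10 grows
only logarithmically in $t$, so a large upper bound is unreachable below
the root-finder's bracket and is likewise assigned probability 0.

**Required n is defined by the analytic engine.** `bfda_required_n()`
bisects the analytic outcome probability over n. This is a deliberate
design choice: near a .80 target the probability curve can be extremely
flat in n — under the null at bounds 0.1/10 it rises by roughly 0.0002 per
participant around n ≈ 650 — so a 10,000-repetition simulation (binomial
SE ≈ .004 per point) cannot resolve the answer to better than a few tens
of participants. The deterministic definition is reproducible; simulation
estimates of it should be read with that resolution limit in mind.

## The pre-planned pipeline

`run_replication_analysis()` chains the registered analysis: per-participant
MAE and one chance-MAE draw each (responses re-paired with a uniformly
permuted set of true sizes — a single draw, as "randomly paired" implies;
averaging over permutations is available but off by default, and a
derangement option excludes fixed points, an $O(1/n)$ refinement), a paired
t-test of actual against chance error, the difference-score bias t-test
with Cohen's $d_z = t/\sqrt n$, the JZS Bayes factor, the posterior
credible interval, the share of positively biased participants, and a
rerun on the sanity subset (MAE strictly below 25 px; if fewer than two
participants survive, the subset analyses are marked unavailable and the
main results stand). The bias method is fixed to the difference score —
the estimator whose t-test is actually calibrated — and the ratio scores
are reachable only by explicit argument, for comparison runs. All
randomness descends deterministically from one seed, fanned out per
participant, so identical input and seed give an identical report.

Degenerate inputs are rejected loudly: a bias sample with zero variance
(exactly constant reports) has no defined t statistic and raises an error
rather than returning NaNs, and tables are validated for balance on every
entry point, naming the offending participant.

## Problem sizes used by the test suite

The packaged tests run the type-I-error study at 100,000 repetitions for
21 participants and 10,000 at 663; BFDA cross-validation at 2,000–10,000
repetitions; posterior checks at 10,000–100,000 iterations; and parameter
recovery on a single 663-participant table plus 120 replicated
25-participant tables for CI coverage. These sizes hold every Monte-Carlo
standard error well below the tolerance of the quantity it checks while
keeping a full run in the low minutes.

## Known limitations

* The generator's homogeneous-normal noise is a model of convenience; the
  ratio-score rejection rates it yields are generator-specific (the
  qualitative ceiling and ordering are not).
* The chance-MAE reference uses one permutation draw per participant, so
  the accuracy test inherits a small extra variance component; the
  averaging option trades fidelity to the registered procedure for
  variance reduction.
* Bayes factors are one-sample/paired JZS only — no directional or
  two-sample variants — matching the analyses the pipeline needs.
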