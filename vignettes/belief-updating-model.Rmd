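---
title: "A Bayesian model of belief updating under social review information"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Bayesian model of belief updating under social review information}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(socbayes)
```

## The problem and the data

In a two-phase rating paradigm, a participant first rates how much they like
each of a set of products on a continuous slider (rating $R_1$, confidence
$C_1$), and later rates the same products again after seeing aggregate
review information — the group's mean star rating, the number of reviewers,
and a 5-bin star histogram — giving $R_2$ and $C_2$. The scientific question
is whether the second judgment integrates the group's opinion with the
participant's own prior belief in a reliability-weighted, Bayesian way:
moving further toward the consensus when one's own confidence is low and
when the group is large.

`socbayes` works on a table with one row per (participant, product): the
four raw slider judgments on $[0, 500]$ plus the product's review summary.
Because participants use the slider idiosyncratically, all four judgment
types are z-scored separately per participant (sample SD, $n-1$) before any
analysis; a constant column is treated as corrupt input and raises an error
rather than silently producing zeros.

## The model

Each participant $i$ holds a Gaussian prior over the value of product $j$:

$$R_1 \sim \mathcal N(\mu_{ij},\; \sigma^2_i + \sigma'_i I_{C_1 > \mathrm{med}(C_1)}),
\qquad \sigma'_i \le 0,$$

so high-confidence trials (initial confidence strictly above the
participant's median) use a narrower prior. The reviews for product $j$ act
as a Gaussian likelihood centred on the group mean $m_j$, perceived as if it
aggregated $v_i + v'_i I_{n_j > \mathrm{med}(n)}$ independent reviews of
variance $\tau^2_i$, i.e. with precision $(v_i + v'_i I)/\tau^2_i$. The
posterior follows by conjugacy, and $R_2$ is modelled as a draw from it.

Only two prior variances and two likelihood precisions are identifiable
from ratings — $\tau^2$, $v$ and $v'$ enter the likelihood solely through
the ratios $v/\tau^2$ and $(v+v')/\tau^2$ — so the package parameterizes
each participant by

* `s2_low`, `s2_high`: prior variance on low/high-confidence trials, with
  $0 < s2_{high} \le s2_{low}$ (equivalent to $\sigma^2, \sigma' \le 0$ but
  numerically better behaved), and
* `w_low`, `w_high`: perceived review precision on few/many-review trials,
  with $0 \le w_{low} \le w_{high}$; $\tau^2$ is fixed to 1 for reporting.

Both median splits use a strict "above": ties map to the low/few category.
The confidence split is computed per participant (confidence scale use is
personal); the review-count split is computed once over the whole stimulus
set (the count is a stimulus property).

**Aligning star means with z-scored ratings.** The likelihood mean is shown
in star units while the model lives on each participant's z-scored rating
scale, and no canonical mapping between the two exists in the task itself.
The package's choice is the minimal monotone one: stars map affinely onto
the raw slider ($1 \to 0$, $5 \to 500$, so $3$ stars is the slider
midpoint), then pass through the participant's own $R_1$ z-transform. The
same product therefore lands at different standardized positions for
different participants, which is exactly what a participant-relative
consensus should do. This is a reconstruction, isolated in
`align_review_means()`, and any alternative monotone alignment can be
swapped in at that single point.

Two derived quantities carry the scientific content per trial:

* the **KL divergence** from prior $p$ to posterior $q$ (both Gaussian),
  $\mathrm{KL}(p\|q) = \log(\sigma_q/\sigma_p) +
  (\sigma_p^2 + (\mu_p-\mu_q)^2)/(2\sigma_q^2) - \tfrac12$ in nats — the
  trial-wise magnitude of belief update; and
* the **resistance** $\pi_{prior}/(\pi_{prior} + \pi_{reviews})$ (precisions
  $\pi$) — the exact weight of the prior mean in the posterior mean: 1 when
  the reviews are ignored, tending to 0 when the prior is discarded.
  Averaged over a participant's products it gives a per-person conformity
  index.

## Fitting

Parameters are estimated independently per participant by maximum
likelihood over both ratings, $\sum_j \log \mathcal N(r_{1j}) + \log
\mathcal N(r_{2j})$. The $n$ product-level prior means are never searched
numerically: for fixed structural parameters the objective is quadratic in
each $\mu_{ij}$, with closed-form optimum
$\mu^\ast = (r_1 + r_2 - (1-a)\,m)/(1+a)$ where $a$ is the prior's
posterior weight. Profiling them out at every evaluation leaves a 4-D
problem, solved on an unconstrained scale
$(\log s2_{high}, \log(s2_{low}-s2_{high}), \log w_{low},
\log(w_{high}-w_{low}))$ so the order constraints hold by construction.
Each of 10 restarts (initial variances log-uniform in $[0.1, 10]$,
precisions in $[0.01, 10]$) runs Nelder–Mead and then a BFGS polish with an
objective tolerance of $10^{-10}$; individual restarts occasionally find a
local optimum, but the best-of-10 is stable to well below $10^{-4}$
log-likelihood units across reruns. Fitted precisions below $10^{-6}$ are
snapped to exactly 0, and a variance floor of $10^{-8}$ (far below
behavioral resolution) guards all divisions. Every stochastic routine takes
an explicit seed and restores the caller's RNG state.

**Incidental-parameter correction.** Profiling one mean per trial leaves a
single residual degree of freedom for each trial's two observations. As a
consequence the raw profile-ML is not consistent: along the scale direction
(all variances multiplied by $c$, all precisions by $1/c$ — which leaves
the weights $a$, the profiled means, the posterior means, the resistance
and the fit-quality correlations untouched) the profiled likelihood is
maximized at $c = \tfrac12$, so every variance converges to half its true
value and every review precision to twice it. This is the classical
Neyman–Scott phenomenon, verified here by simulation at large trial counts.
`fit_participant()` therefore doubles the fitted variances and halves the
fitted precisions by default (`df_correct = TRUE`); with it, structural
parameters are recovered on self-generated cohorts with median relative
error well inside 25%. `df_correct = FALSE` gives the uncorrected
estimator. Note which quantities are affected: KL divergences and reported
variances change scale; weights, posterior means, resistance and all
correlations do not.

Fit quality is summarised per participant by the Pearson correlation
between fitted prior means and first ratings and between posterior means
and second ratings (Spearman available via `cor_method`), and the
out-of-fit check `precision_confidence()` correlates the model's posterior
precision — never fitted to confidence — with the reported $C_2$.

```{r, eval = FALSE}
sim <- simulate_cohort(cohort_spec(seed = 1))
prep <- prepare_trials(sim$trials, sim$reviews)
fit <- fit_belief_model(prep, n_restarts = 10, seed = 1001)
summary(fit)
head(derive_trials(fit))
```

## The regression battery

The behavioral signatures are tested by mixed-effects regressions (lme4,
ML fits since the tests concern fixed effects), on the design table from
`build_design()`: update $R_2 - R_1$ on the deviation from the consensus
$\mathrm{dev} = M - R_1$ and its interactions with the two median-split
indicators; confidence update $C_2 - C_1$ on $|R_1 - M|$; and $C_2$ on
$R_2^2$. Median-split indicators rather than continuous moderators enter
the interactions because the psychological scaling of confidence and crowd
size is unlikely to be linear. Reliability-weighted integration predicts:
dev $> 0$, dev$\times$many-reviews $> 0$, dev$\times$high-confidence
$< 0$, $|R_1-M|$ effect $< 0$, $R_2^2$ effect $> 0$
(`signature_check()`).

The exact random-effects composition behind a 2-df test is a genuinely
open choice; the package uses a participant random intercept plus an
uncorrelated random slope for the focal term, and each likelihood-ratio
test removes the focal fixed effect together with its random-slope
variance (hence 2 df). Singular or failed slope fits fall back to the
intercept-only structure, flagged in the result and reflected in the df.

## What the synthetic generator does and does not emulate

`simulate_cohort()` exists so the full pipeline runs and is testable
without any data download; its defaults are the study conditions: 18
participants, 210 products, review means concentrated near 4 stars
(truncated normal, SD 0.6 on $[1,5]$), heavy-tailed reviewer counts
(log-normal, median ≈ 60, clamped to $[3, 2000]$ — a stand-in, since the
real stimulus set's count distribution is not described), and star
histograms drawn multinomially with bin probabilities exponentially tilted
so their mean equals the product's target exactly (making the drawn
histogram an unbiased, internally consistent summary).

Ratings follow the model's own generative story on the latent z-scale.
Structural parameters are drawn per participant: `s2_low` uniform on
$[0.35, 0.75]$ and `s2_high/s2_low` on $[0.45, 0.85]$ — chosen so the
prior-noise share of rating variance sits in the regime implied by the
published fit-quality correlations (a mean prior–$R_1$ correlation near
0.9 requires prior noise well under half of rating variance) — and review
precisions `w_low` on $[0.2, 0.9]$ with gap $[0.3, 1.5]$, giving mean
resistance in a moderate-conformity range. Prior means are i.i.d.
$\mathcal N(0,1)$, matching the z-scored scale.

The confidence link needs care. A pure conjugate-Gaussian reporter's
posterior precision depends only on the trial's two flags — it is blind to
how much the evidence disagreed with the prior and to where on the scale
the rating sits. Human confidence is not: disagreement costs confidence,
and ratings at the scale ends come with more confidence. The generator's
$C_2$ therefore adds to the precision link (slope 1 on log posterior
precision) a carryover of $C_1$ (0.5), a conflict penalty on
$|R_1 - M|$ (0.4), a centred-$R_2^2$ extremity bonus (0.3) and unit report
noise. The carryover matters for a subtle reason: $C_2 - C_1$ regresses on
$-C_1$ mechanically, and since low-$C_1$ trials use the wider prior and so
sit further from the consensus, a generator without carryover would
produce a *positive* disagreement effect on confidence update — the
opposite of the behavioral signature. These coefficients were set a priori
by variance bookkeeping so that the posterior-precision–$C_2$ correlation
lands in a plausible 0.2–0.45 band and all five signatures are expressed;
they are ordinary `cohort_spec()` fields, not constants.

Raw sliders are reconstructed through participant-specific jittered affine
maps (rating centers $[230, 270]$, scales $[55, 75]$; confidence scales
$[40, 60]$) and clipped to $[0, 500]$, so the z-scoring stage is exercised
non-trivially. Two distortions are therefore present by design: clipping
(rare at these scales) and, more importantly, the pipeline re-z-scores
$R_1$ and $R_2$ with their separate empirical SDs, which rescales the true
parameters by column-specific factors. Parameter-recovery tests score the
fitter against the generator's truth on the latent table
(`simulate_cohort()$latent`), where the comparison is well defined;
end-to-end fit quality through the raw pipeline is what the fit-quality
correlations measure. What the generator does not emulate: real product
content, slider dynamics and response times, sequential or order effects,
participant exclusion pathologies (e.g. heavily skewed raters), or any
dependence of review counts on product quality. Passing tests on this
generator show the machinery is correct and the signatures follow from the
model; they do not certify the model against real behavior.

## Problem sizes and reproducibility

The package's reference checks run the full study geometry (18 × 210, 10
restarts; a few seconds of CPU), with smaller cohorts (3–10 participants,
40–150 products) in focused unit tests. Numerical oracles are independent
of the checked code paths: grid-based Bayes for the conjugate update,
adaptive quadrature for the KL closed form, and a derivative-root search
for the profiled means (exact for a quadratic objective). All pipeline
stages (`run_simulate()`, `run_fit()`, `run_analyze()`, or the
`inst/cli/belief-pipeline.R` script) log their seeds and write their
configuration next to their outputs; the same seed reproduces the same
files byte for byte.

## Known limitations

* The star-to-z alignment of the review mean is a reconstruction (see
  above), as is the 2-df random-effects composition of the reported tests.
* The model is a single conjugate update per product: no learning across
  trials, no non-Gaussian beliefs, no sequential evidence.
* The resistance index summarizes the *fitted* precisions; for a
  participant whose fitted review precisions are ~0 it is exactly 1, and
  such participants are flagged (`zero_weight`) rather than excluded.
* With a very tight prior the likelihood is nearly flat in the review
  precisions (the review weight is ~0 regardless of $w$), so $w$ itself is
  weakly identified there even though every derived quantity (resistance,
  KL, posterior means) is stable.
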