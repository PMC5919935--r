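---
title: "Modelling mood dynamics and their influence on risky choice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling mood dynamics and their influence on risky choice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moodchoice)
library(dplyr)
```

## The scientific problem

Incidental events — getting a quiz question right or wrong — move mood, and
mood in turn tilts unrelated economic decisions. `moodchoice` implements a
complete modelling chain for this phenomenon on a task in which agents
alternate between a quiz with (covertly biased) correct/incorrect feedback
and a choice about whether to attempt a motor-precision challenge for money.
The package provides (i) a family of latent mood dynamics models fitted to
sparse mood ratings, (ii) a family of expected-utility choice models fitted
to accept/decline decisions, (iii) approximate-Bayesian model inversion and
group-level random-effects model selection, and (iv) regression machinery
linking per-trial "ROI baseline" signals to mood and to choice parameters
through a *neural proxy for mood* (NPM). Because the original participant
data are not redistributable, the package ships a synthetic-cohort generator
with known ground truth, and every claim the package makes about itself is a
recovery claim: parameters and model structure planted in simulation are
recovered by the fitting machinery.

## The mood model

The theoretical mood level integrates task events with an exponential decay:

$$\mathrm{TML}(t) = \omega_0
  + \omega_{q1} \sum_{j=1}^{t} \gamma^{\,t-j}\, EV_{quiz}(j)
  + \omega_{q2} \sum_{j=1}^{t} \gamma^{\,t-j}\, RPE_{quiz}(j)
  + \omega_p \sum_{j=1}^{t} \gamma^{\,t-j}\, EV_{choice}(j)
  + \omega_t\, t$$

with $EV_{quiz} = 2\,\mathrm{accuracy} - 1$ (cohort mean accuracy of the
question's difficulty level), $RPE_{quiz}(t) = F(t) - EV_{quiz}(t)$, and
$\gamma \in [0, 1]$ a forgetting factor. Structural options generate the
18-member family (`enumerate_mood_models()`):

* **source** — quiz only, choice only, both, or neither (the null model,
  a pure linear time trend);
* **simplified** — a single feedback weight $\omega_f = \omega_{q1} =
  \omega_{q2}$, under which the two quiz terms collapse to
  $\omega_f \sum_j \gamma^{t-j} F(j)$;
* **asymmetric** — positive feedback coded as a free magnitude $R > 0$
  instead of 1 (losses stay at $-1$);
* **reciprocal** — mood feeds back into the perception of feedback,
  $F(t) = \mathrm{feedback}(t) + \delta\,\mathrm{TML}(t-1)$, additively, so
  that good mood makes any feedback feel better.

Three readings of the equations were genuinely open and were fixed as
follows. The summand of each decaying sum is indexed by $j$ (the only
reading under which the sums integrate history). The initial condition is
$\mathrm{TML}(0) = 0$, which anchors the reciprocal term on the first trial.
And asymmetric coding is applied to the objective feedback *before* the
$\delta\,\mathrm{TML}(t-1)$ term is added, keeping the reciprocal influence
independent of the outcome's sign.

The decaying sums are evaluated by the linear recursion
$S(t) = a\,S(t-1) + x(t)$ (a small compiled kernel, since it sits inside
every likelihood evaluation); for the reciprocal models the feedback loop
through $\mathrm{TML}(t-1)$ is eliminated algebraically, giving an effective
recursion coefficient $\gamma + \delta\,\omega_f$ (or
$\gamma + \delta\,\omega_{q2}$ for the full parameterisation). Tests verify
this against an explicit brute-force double sum to $10^{-12}$.

Ratings are observed only every third trial. Following the primary analysis
convention, ratings are linearly interpolated to one value per trial
(endpoints held constant) and z-scored before fitting
(`prepare_ratings()`); fitting on actually rated trials only is available
via `interpolate = FALSE` as the robustness path. The observation model is
Gaussian with free sd `obs_sd` — the standard assumption of
variational-Laplace schemes for continuous ratings.

## The choice model

On each trial a prospect (gain $G$, loss $L$, target-window size $S$) is
accepted with probability

$$p(\mathrm{accept}, t) = \frac{1}{1 + e^{-(U_{accept} - U_{decline}
  + k_t\,t + k_0)}}, \qquad
U_{accept} = p_s\, k_g\, G^{c_g} - (1 - p_s)\, k_l\, L^{c_l}$$

where the subjective success probability is the Gaussian mass inside the
force-target window, $p_s = \Phi\!\big(\tfrac{S/2}{\sigma}\big) -
\Phi\!\big(-\tfrac{S/2}{\sigma}\big)$, with $\sigma$ the agent's subjective
motor sd. The decline utility uses the same form with both stakes at
0.50 €; when the spec drops it, the constant is absorbed into $k_0$. There
is no separate softmax temperature: the scale is carried by $k_g, k_l, k_0$,
matching the model equations, which contain none. The four pseudo-normative
models (decline utility × curvature) plus all $2^7 = 128$ subsets of
descriptive regressors $\{G, L, S, GL, GS, LS, GLS\}$ (empty set included;
raw, unstandardised products) give the 132-model space
(`enumerate_choice_models()`).

Neural-proxy modulation multiplies parameters per trial,
$k_g'(t) = k_g\,(1 + k_{mg}\,\mathrm{NPM}(t))$ (likewise $k_l$, $\sigma$),
or biases utility additively by $k_{m0}\,\mathrm{NPM}(t)$; all $2^4 = 16$
subsets form the modulation family. $\sigma'$ is floored at $10^{-6}$
because extreme negative modulation could flip its sign, a case the model
equations do not address.

## Inversion and model comparison

`invert_model()` maximises the log-joint (likelihood plus Gaussian prior) on
an unconstrained scale — `log` for $\sigma$, $R$, `obs_sd`; logit for
$\gamma$, $c_g$, $c_l$; identity otherwise — with priors
$\mathcal{N}(0, 3^2)$ on that scale (weakly informative). Optimisation uses
8 starts: the prior mean first (a well-behaved region for every model in the
family, where $\gamma = 0.5$, $\delta = 0$, $R = 1$), then random prior
draws; ties are broken by the smallest parameter norm. The log evidence is
the Laplace approximation
$\log p(y) \approx \log p(y, \hat\theta) + \tfrac{d}{2}\log 2\pi -
\tfrac{1}{2}\log\det H$, with $H$ the negative Hessian of the log-joint at
the mode by central finite differences (step $10^{-4}$; escalating ridge
jitter, recorded in the diagnostics, if $H$ is not positive definite). The
Laplace form was chosen over a full iterative variational scheme because it
realises the same accuracy/complexity trade-off, is exact in the
linear-Gaussian case (where tests pin it against the conjugate closed form
to $10^{-3}$), and the validation surface here is recovery behaviour, not
equality with any particular toolbox's free-energy values.

`group_bms()` treats model identity as a random effect: a Dirichlet prior
(one count per model) is updated by the standard variational scheme on the
agents-by-models evidence matrix, and exceedance probabilities are
Monte-Carlo estimates from $10^5$ Dirichlet draws under a recorded seed (the
two-model case is testable against the exact Beta CDF). Classical, not
protected, exceedance probabilities are reported — the distinction matters
only when the null "all models equally frequent" is plausible, and protected
variants would be a straightforward extension. `family_bms()` aggregates the
same posterior over a disjoint partition (family frequency = sum of member
frequencies, exact for Dirichlet aggregation). Parameter-level inference
across agents uses the summary-statistics approach: one-sample two-tailed
t-tests plus Wilcoxon signed-rank, both always reported. A full
mixed-effects model is deliberately not used: the per-trial ROI proxies here
are scalars by contract, not FIR time courses.

## The synthetic cohort

`gen_quiz_schedule()` reproduces the task's mood-induction structure:
sessions of 32 trials whose 18 middle trials form an easy or hard episode
with feedback bias (wrong answers drawing positive feedback with probability
up to 0.5, more bias for easier episodes), flanked by 7 + 7 unbiased
medium-difficulty trials. Correct feedback is never negative. Per-difficulty
accuracy means default to 0.8/0.6/0.35 (easy/medium/hard) — the design only
requires a monotone spread, and any such spread supports recovery.
`gen_prospects()` draws balanced gain/loss/size sequences re-shuffled until
all pairwise correlations (and correlations with quiz difficulty) are below
0.1 in magnitude. Ratings occur every third trial from within-session trial
2 (11 of 32 trials). Confidence ratings are generated with *no* feedback
dependence, so the null mood model is recoverable on them by construction.

The canonical ground truth (`default_agent_truth()`) is the winning model
structure with $\gamma = 0.77$, $\omega_f = 0.4 > 0$, $\delta = 0.3 > 0$,
$\omega_t = -0.005 < 0$, $R = 1.5$, rating noise 0.3 (on a TML scale of
sd $\approx 1.3$), and choice parameters $k_g = k_l = 1$, $\sigma = 0.08$
(vs window widths 0.05–0.25), $k_t = -0.002$, $k_0 = 0.5$ — moderate,
realistic effect sizes rather than caricatures. Between-agent sds
(`default_population_sd()`) are roughly a third of each mean. ROI proxies
are per-trial scalars: $v(t) = b_v\,\mathrm{TML}(t) + g(t) + \epsilon$,
$a(t) = -b_a\,\mathrm{TML}(t) + g(t) + \epsilon$ with a shared global signal
$g$; generative choice modulation, when enabled, is driven by the
ROI-specific component $v - g$ (resp. $a - g$), so that each ROI carries its
own idiosyncratic modulation signal and per-ROI model comparison has a
correct answer. A generative `mod_loss` of $+0.3$ on the insula proxy means
loss aversion rises with insula activity, i.e. falls with mood — the NPM
read-out of that same effect is a *negative* $k_{ml}$.

What the generator does *not* emulate: BOLD dynamics (no haemodynamics, no
autocorrelated scanner noise), within-trial temporal structure, missed
responses, and rating scale truncation. Passing recovery tests therefore
demonstrate that the estimation machinery is correct and well-calibrated on
data satisfying the model's own assumptions — not that the models are
identifiable under every violation real data can present.

## What recovery can and cannot conclude

With 23 agents and 256 trials, the *source* of mood (quiz feedback vs choice
utilities vs none) is decisively recoverable, and the signs of
$\omega_f$, $\delta$ and $\omega_t$ are recovered by group tests from fits
of the generating model. The finer structural flags are only weakly
identified at these effect sizes, for an algebraic reason worth recording:
after z-scoring, asymmetric coding decomposes as
$\mathrm{coded} = \tfrac{R-1}{2} + \tfrac{R+1}{2}\,\mathrm{feedback}$, whose
first term's decaying sum is nearly constant after burn-in and is absorbed
by $\omega_0$; similarly a moderate $\delta$ mainly raises the effective
decay to $\gamma + \delta\omega_f$, aliasing with $\gamma$. Model selection
consequently spreads mass across quiz-source variants while the quiz-source
*family* wins outright — which is why the package's acceptance checks state
family-level selection, and why parameter sign tests (not model-level
exceedance) carry the inference about $\delta$ and asymmetry.

## Numerical choices

* Acceptance probabilities are clipped to $[10^{-10}, 1 - 10^{-10}]$ inside
  the Bernoulli likelihood.
* Non-finite TML trajectories (explosive reciprocal recursions with
  $\gamma + \delta\omega_f > 1$ at extreme prior draws) score $-\infty$, so
  the optimiser retreats from them.
* `p_s` uses Gaussian CDF differences; adaptive quadrature of the defining
  integral is kept as the test oracle ($|\Delta| < 10^{-8}$).
* BFGS with `reltol` $10^{-10}$, up to 500 iterations, falling back to
  Nelder-Mead if a start errors; non-convergence is flagged in the result's
  diagnostics, never silent.
* Zero data rows return the prior as posterior with evidence 0 (which the
  Laplace identity yields exactly).

## Problem sizes used by the validation suite

The shipped tests and the acceptance script run cohorts of 23 agents with
256-trial sessions ($8 \times 32$) for mood-model recovery and the
confidence-null check, and 128-trial cohorts ($4 \times 32$) for the
choice-modulation analyses — the session counts of the rating and fMRI
experiments respectively, which are comfortably inside what a single desktop
core handles in minutes. Oracle-equivalence checks (quadrature, brute-force
sums, conjugate evidence, Beta-CDF exceedance) run at small $n$ in seconds.

## A worked example

```{r example, eval = FALSE}
cfg <- task_config(n_sessions = 8)
truth <- default_agent_truth()
tab <- simulate_agent(cfg, truth, seed = 1)

# fit the generating mood model and inspect the fit
fit <- invert_model(tab, truth$mood_spec, seed = 1)
tidy(fit)
glance(fit)
autoplot(compute_tml(tab, truth$mood_spec, posterior_params(fit)),
         table = tab)

# compare the full 18-model family across a small cohort
cohort <- gen_cohort(cfg, n_agents = 8, truth,
                     mood_sd = default_population_sd()$mood, seed = 2)
ev <- fit_cohort(cohort$tables, enumerate_mood_models(), keep_fits = FALSE)
bms <- group_bms(ev[c("agent", "model", "log_evidence")])
autoplot(bms, top = 8)
```

## Known limitations

* The Laplace evidence is a local approximation; multimodal posteriors
  (small data, rich models) are summarised by their best mode.
* `k_0` and a constant decline utility trade off in the best choice model;
  both are kept, and only their combination is strongly identified.
* Whether NPM weights should be fitted per agent or at the group level is
  not settled; both are possible with the provided functions, and per-agent
  fitting is the default used by `run_pipeline()`.
* The generator draws population parameters from independent Gaussians
  (truncated to natural domains); correlated individual differences are not
  modelled.
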