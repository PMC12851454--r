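# normtraj

Bayesian developmental trajectories of sharing norms from binary Dictator
Game choices, plus free-list interview analysis.

## The problem

In multi-ethnic communities, children must learn two kinds of cooperation
norms: how to share with members of their own group (*intra*-ethnic) and
how to share with members of the neighbouring group (*inter*-ethnic). A
binary Dictator Game — each participant chooses once per condition between
an equal split (GIVE) and keeping both rewards (KEEP), with the recipient
presented as in-group or out-group — run across a wide age range in two
societies lets us ask *when* each norm is acquired: does children's
behaviour come to match adult behaviour later for out-group norms?

`normtraj` is for researchers who want to fit and probe this analysis:
developmental psychologists and cultural-evolution researchers working
with binary choice data over age, in study designs too small and too
bespoke for off-the-shelf growth-curve software.

## The model

Each choice is a Bernoulli draw from a logistic developmental trajectory

```
P(GIVE | age x) = p_infant + (p_adult − p_infant) / (1 + exp(−b (x − a)))
```

with one infant probability `p_infant` shared across all curves and four
independent curves (two societies × two conditions), each with its own
midpoint age `a`, transition rate `b`, and adult probability `p_adult`.
Gender enters as additive offsets: `a + z·a_g`, `b + z·b_g`,
`invlogit(logit(p_adult) + z·p_g)` with `z = ±0.5`. Priors:
`p_infant ~ Beta(1.5, 1.5)`, `p_adult ~ Beta(0.75, 0.75)`,
`(a, b) ~ MVN([10, 0.2], [[15, 0.75], [0.75, 0.2]])` truncated positive,
offsets `~ N(0, 0.75)`. Posterior sampling uses a componentwise adaptive
random-walk Metropolis sampler (C++ core) on unconstrained space.

Derived statistics: the **completion age** `a + 3/b` (age at which 95% of
the infant-to-adult change has occurred), its posterior mean and 89%
HPDI; the per-society **contrast** (inter − intra completion age) with
the posterior probability of a positive difference, supported when that
probability strictly exceeds 0.75; gender-marginalized sharing rates; and
a simulation-based power study. A synthetic-study generator (205
participants: 122 children 5–16, 83 adults 17+, both conditions
counterbalanced, exclusion fixture 5/5/11/5 → 179 retained) makes the
whole pipeline runnable without field data. Free-list utilities compute
category frequencies, Smith's salience, and first-coded learning-mechanism
tables.

## Worked example

```r
library(normtraj)

trials <- simulate_trials(default_truth(), default_design(), seed = 20260925)
fit <- fit_trajectories(trials,
                        config = sampler_config(chains = 4, iterations = 10000,
                                                seed = 20260926))
marginal_rate(fit, "infant")
completion_posterior(fit, "Bandongo", "intra")
ct <- completion_contrast(fit, "Bandongo")
ct
hypothesis_support(ct)
```

which prints (numbers from this exact run):

```
   which society condition      mean  hpdi_low hpdi_high mass
1 infant    <NA>      <NA> 0.4475399 0.3578221 0.5356524 0.89

   society condition     mean hpdi_low hpdi_high mass
1 Bandongo     intra 128.3832 8.417883   50.0431 0.89

   society      mean  hpdi_low hpdi_high prob_positive mass
1 Bandongo -94.75602 -59.74949   50.2309         0.403 0.89

[1] FALSE
```

The infant sharing rate is the probability of GIVE before socialization,
shared across societies and conditions; here it recovers the generating
value 0.42 within its interval. The completion-age row says at what age
Bandongo children's intra-ethnic choices have essentially reached the
adult rate. The generating curves emulate the study's fitted values and
are nearly flat (infant 0.42 vs adult 0.45), so 205 participants barely
identify the curve shape: the posterior of `b` has mass near zero, `a +
3/b` develops an enormous right tail, and the posterior *mean* lands far
outside the 89% HPDI — the interval, not the mean, is the quantity to
read under this skew. The contrast row is the posterior for "inter-ethnic
norms finish later than intra-ethnic ones"; with `prob_positive` = 0.40,
below the 0.75 threshold, the hypothesis is not supported on these data.

The numbered scripts under `analysis/` run the full workflow — simulate,
fit, derive summaries, free-list tables, power study — and write their
tables, the consolidated `report.md`, and the posterior predictive figure
under `results/`:

```sh
Rscript analysis/01_simulate_study.R
Rscript analysis/02_fit_trajectories.R
Rscript analysis/03_derived_summaries.R
Rscript analysis/04_freelist_salience.R
Rscript analysis/05_power_simulation.R
```

## Layout

- `R/`, `src/` — package code (model, sampler, derived statistics,
  generator, free-list analysis, reporting)
- `analysis/` — numbered workflow drivers writing to `results/`
- `tests/testthat/` — unit, property and end-to-end suites with
  independent oracles
- `vignettes/trajectory-methods.Rmd` — model, priors, sampler, and the
  design rationale for the recovery and power studies
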