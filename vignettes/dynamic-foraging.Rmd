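---
title: "Simulating and analysing dynamic foraging behavior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing dynamic foraging behavior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foragr)
library(dplyr)
```

## The task

`foragr` simulates the two-armed bandit ("dynamic foraging") tasks used to
probe behavioral flexibility in mice, and implements the complete analysis
pipeline used to compare cohorts (e.g. wild-type vs. heterozygous mutants) on
that behavior. A freely moving animal self-initiates trials at a center poke
and chooses between a left and a right reward port. Each port carries a
reward probability, and the identity of the high-probability port reverses
without any cue. The task comes in stages:

* **Single-port shaping** (`training_single_port`): one port always pays; the
  session ends after 100 trials.
* **Deterministic training** (`training_0_100`): probabilities are 100% and
  0%. The high side reverses every 100 trials *or* as soon as the animal
  chose the high port on at least 9 of the 10 previous trials.
* **Probabilistic task** (`full_15_60`): probabilities are 60% vs 15% and
  rewards are *baited* — once a reward is assigned to a port it remains
  available until that port is next chosen. Reversals occur every 80 trials
  regardless of performance. Variants change the block length
  (`block40`, `block100`) or cycle through mixed contingency pairs
  (30/30, 15/45, 10/50 and 50/50, 15/85, 25/75).
* **Head-fixed bandit** (`headfixed_70_10`): a lick-based 70:10 task without
  baiting, with a no-lick waiting period before each trial, a
  performance-plus-random-delay block transition, and termination after 20
  consecutive no-response trials.

Baiting is the scientifically load-bearing detail: because an uncollected
reward persists, the probability that the lean port pays on its first visit
after $k$ skipped trials is $1-(1-p)^k$, which rewards occasional sampling of
the lean side and produces matching-like behavior rather than pure
maximising. The engine draws one independent Bernoulli per port per trial
*before* the choice (the standard convention for baited bandits), and bait
flags survive reversals — only the probability assignment swaps.

### Reversal rules

The 9-of-10 window never reaches back into the previous block, so the
earliest performance-triggered reversal is at trial 10 of a block; a
perfectly tracking agent therefore experiences 10-trial blocks, which is the
regime well-trained animals reach. "Correct" means choosing the
high-probability side regardless of whether a reward was collected (in the
0/100 stage the two coincide). In the probabilistic task the rule is purely
trial-count based, so block length is exactly the cap for any policy — a
useful invariant that the test suite and acceptance checks exploit.

### Head-fixed timing machinery

The no-lick period is drawn from an exponential distribution (rate 1/3 s⁻¹)
truncated to [1, 5] s by inverse-CDF sampling, so draws are bounded by
construction without rejection. Each premature lick adds another draw, and
the *total* number of draws is capped at five; the attainable total is
therefore between 1 and 25 s. We read "repeated for a maximum of five times"
as counting the initial draw, because only that reading honours the printed
1–25 s range.

The block transition arms once the animal has made 10 *cumulative* (not
necessarily consecutive) high-side choices within the block, then fires after
an extra trial count drawn from a geometric distribution. We interpret its
location parameter μ = 11 as the untruncated mean — success probability
$1/(\mu+1)$ on support $\{0,1,2,\dots\}$ — renormalised over [0, 30]. The
alternative reading (μ as the post-truncation mean) has no closed form and
the truncated mean under our reading (≈ 9.9) stays close to the printed
value; the analytic mean is exposed as `block_transition_mean()` so the
choice is auditable.

## Agents

No generative model of mouse behavior is claimed by the analysis the package
supports; agents are explicitly synthetic stand-ins used to exercise the
pipeline at realistic behavioral scales:

* `agent_wsls(eps)` — win-stay/lose-switch with a lapse rate `eps`;
* `agent_q_softmax(alpha, beta)` — delta-rule value learning with softmax
  choice (the "realistic" default: it matches partially and sharpens with
  `beta`);
* `agent_biased_random(bias)`, `agent_alternator()`, `agent_ideal()` —
  reference policies used for calibration and invariant checks.

History-dependent agents choose uniformly at random on the first trial, from
the session RNG. All agents can emit no-responses with probability `p_none`
to exercise the head-fixed termination rule.

Trial-initiation latencies come from `latency_model()`: log-normal, i.e.
strictly positive and right-skewed, parameterised by the outcome-conditional
*median* because the empirical summaries of self-paced intertrial intervals
are medians and interquartile ranges. The defaults (1.8 s after a rewarded
trial, 1.1 s after an unrewarded one, log-SD 0.4) reproduce the reported
wild-type medians and an IQR of roughly 1.4–2.4 s; animals initiating more
slowly after reward is the configured-in motivational signature.

## Synthetic cohorts

`cohort_spec()` + `generate_cohort()` produce a labeled cohort: subjects in
genotype × sex cells (default 12 per cell, i.e. 24 per genotype — the scale
of the motivating study design), a training curriculum run in order
(single-port shaping, then 0/100 training, then the 15/60 task), and one
seeded session per subject, replicate, and stage. Subject seeds derive
deterministically from the master seed, so a spec reproduces its cohort
byte-for-byte.

The genotype effect is a single dial, `effect_size`: 0 generates the null —
both genotypes use identical agent parameters, making every metric
exchangeable across labels — while a positive value slows the HET learning
rate (`alpha * (1 - effect_size)`) or degrades WSLS compliance. The null
default matches the study finding the pipeline is designed to test. A
`seizure_rate` flags a fraction of HET subjects in the metadata with no
behavioral consequence, mirroring how such observations are annotated.

What the generator does **not** emulate: satiety and motivation drift within
a session, side biases and their interaction with training history,
inter-subject parameter heterogeneity beyond session stochasticity, day-to-day
learning (agents reset each session), and any physiological covariates.
Passing tests therefore demonstrate that the pipeline is correct and
calibrated on data with the task's exact reward structure — not that real
mice behave like the agents.

## Metrics

All metric functions take the trial table (the CSV session-log schema) and
return tibbles:

* `learning_curve()` — per subject and day, the fraction of valid-choice
  trials on the high side; days with no valid choices are `NA`, never 0.
* `reversal_aligned()` — probability of choosing the *new* high port at each
  trial position after a reversal. Blocks shorter than $k$ drop out of
  position $k$'s denominator. By default the curve averages within animal
  first and then across animals so each subject carries equal weight;
  `pool = "blocks"` pools blocks directly (both are useful, and they differ
  when subjects contribute unequal block counts).
* `wsls_fractions()` — win-stay and lose-switch fractions over consecutive
  valid-choice pairs; pairs spanning a reversal are *included* (the strategy
  is defined on outcomes, not blocks), pairs broken by a no-response are not.
* `conditional_iti()` — each trial's latency assigned to the previous trial's
  outcome; medians and quartiles use linear interpolation (R quantile
  type 7) so reported IQRs are bit-reproducible.
* `moving_average_choice()` — trailing 10-trial left-choice average, the
  standard single-session matching display, with `contingency_ratio()`
  (e.g. $60/(15+60) = 0.8$) as its programmed reference line.

No-response trials are excluded from every choice-based numerator and
denominator: they carry no choice information.

## Group statistics

`rm_two_way_anova()` implements the mixed-design repeated-measures two-way
ANOVA used for curve comparisons (between factor = group, within factor =
day or trial position), with subject-nested error strata and no sphericity
correction — a documented limitation, matching the analysis the package
mirrors; with two groups the between test has 1 numerator df and is
sphericity-free, and the interaction term is the headline effect reported by
`glance()`. Incomplete designs raise an error rather than being imputed.
`mann_whitney_u()` does pairwise comparisons: exact enumeration p when the
smaller sample is ≤ 8 without ties, otherwise the normal approximation with
continuity and tie corrections. `bonferroni()` corrects the family, and the
package-wide default α is 0.05.

The type-I calibration of the whole chain is checked by
`null_rejection_rate()`: replicate null cohorts → per-subject win-stay and
lose-switch → pairwise Mann–Whitney → Bonferroni, counting replicates with
any corrected rejection. Bonferroni plus the discreteness of the exact U
distribution at 8 subjects per group makes the scheme conservative (empirical
family-wise rate ≈ 0.04 at the sizes below).

## Numerical and design choices

* **RNG discipline** — one seeded stream per session; draw order per trial is
  fixed (bait left, bait right, no-lick, agent, ITI, transition) and baiting
  always consumes two uniforms so the stream never depends on bait state.
* **Tie contingencies** (30/30, 50/50 blocks) have no true high side; the
  label alternates deterministically from the previous block so downstream
  code never sees a missing `high_side`.
* **Degenerate inputs** — zero-denominator fractions are `NA`; empty session
  files parse to empty tibbles; a geometric support of a single point returns
  it; `dispersion = 0` latencies return the median exactly.
* **Problem sizes** — the packaged checks use sessions of 200–10 000 trials,
  Monte-Carlo sizes of 10⁵–10⁶ draws for distributional checks, 100 random
  sessions for brute-force metric cross-checks, and 1 000 replicate null
  cohorts at 8 subjects per group for the type-I calibration; these sizes
  keep Monte-Carlo error well inside the asserted tolerances.

## Worked example

```{r example}
spec <- cohort_spec(
  n_per_cell = 2, sessions_per_subject = 1,
  curriculum = list(full_15_60 = task_preset("full_15_60", max_trials = 400)),
  agent_spec = list(type = "q_softmax", params = list(alpha = 0.2, beta = 3)),
  effect_size = 0, master_seed = 1
)
cohort <- generate_cohort(spec)
cohort

metrics <- wsls_fractions(cohort$trials) |>
  left_join(cohort$subjects, by = "subject_id")
compare_groups(metrics, c("win_stay", "lose_switch"))

reversal_aligned(cohort$trials, n_after = 5, by = "genotype")
```

## Limitations

Beyond the generator caveats above: the ANOVA offers no sphericity
correction (Greenhouse–Geisser) and no unbalanced designs; agents' parameters
are not fitted to data (no model comparison); and the head-fixed shaping
phases before the bandit are modeled only as far as needed to generate
alternation sessions.
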