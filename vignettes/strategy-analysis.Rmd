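---
title: "Dissecting outcome-based and cue-based strategies in two-choice operant learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting outcome-based and cue-based strategies in two-choice operant learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opstrat)
```

## The scientific problem

In a cued two-alternative touchscreen task, an animal can earn rewards in
two fundamentally different ways. It can learn the *cue rule* — the
experimenter-defined mapping from the position of a bright cue (top or
bottom) to the rewarded response side (left or right) — or it can fall back
on *outcome rules*: the four elementary strategies win-stay, win-shift,
lose-stay and lose-shift, which condition the current response only on the
previous trial's response and outcome. Because the task's trial-transition
structure makes several outcome rules genuinely profitable (correction
trials make lose-shift pay with certainty; inserted stay trials make
win-stay pay), overall accuracy alone cannot distinguish a cue-rule learner
from a sophisticated outcome-rule responder. `opstrat` implements the full
analysis chain needed to make that distinction on trial-by-trial choice
logs: descriptive strategy metrics, matched agent-based bootstrap nulls,
trial-by-trial reinforcement-learning (RL) models, and random-effects
Bayesian model selection (BMS) — together with a generative simulator of
the task that serves both as the bootstrap engine and as a first-class
synthetic-data source for validating every stage.

## The task generator

The simulator reproduces a three-phase protocol. Sessions are 40, 50 and
100 trials in phases I–III. Each trial presents a bright target cue
(85% brightness) whose position determines the correct side (top→left,
bottom→right); low-contrast trials add a 20%-brightness distractor on the
opposite position, and ambiguous probe trials (phase III) light both
positions at 50%, with **both** responses rewarded.

Transitions are applied in priority order:

1. **Correction trials** (phases I–II): after an error the same cue
   position is repeated until the correct response occurs. Because the
   correct side is unchanged, shifting away from the just-failed response
   is always rewarded on a correction trial — the structural feature that
   makes lose-shift profitable.
2. **Inserted stay trials**: every shift trial in phase II is followed by
   2 high-contrast stay trials; in phase III one high-contrast stay trial
   follows every non-stay trial (shift or ambiguous). A *stay* trial is one
   whose correct side repeats the previous trial's reference side (the
   previous correct side, or the chosen side after an ambiguous trial).
3. **Enforced position flip** (phase I only): after 3 identical cue
   positions in a row, the next free draw flips the position.
4. **Free draws** otherwise: phase I draws high-contrast stay/shift at .5
   each; phase II stay .5 and high-/low-contrast shift .25 each; phase III
   high-contrast stay at .5 and high-contrast shift, low-contrast shift,
   low-contrast stay and ambiguous at .125 each. The phase III set is not
   fully pinned down by the protocol description ("all other trial types"
   at .125); we adopt the four types that make the distribution sum to 1
   and expose the set in `phase_config()`.

Phases progress at ≥ 80% session accuracy on 2 consecutive sessions, with
caps of 70 (phase I) and 14 (phase II) sessions; phase III runs a fixed 20
sessions. Each simulated animal draws from an independent RNG stream
derived from the master seed, so cohorts are exactly reproducible.

Two boundary conventions are ours: sessions start with a fresh transition
state (the opening trial presents a high-contrast cue at a uniform
position and is excluded from free-draw statistics), and session time
limits are not modelled — sessions end at the trial count only, since no
latency process is in scope.

Agents supply the choices: probability-table agents conditioning only on
the previous outcome or only on the current cue (per day), RL agents
sampling from the softmax of their learned values, constant side-bias
agents, and a random agent.

## Strategy metrics

`cue_accuracy()` is the fraction of rewarded responses; ambiguous trials
are excluded by default (both responses are "correct", so they carry no
information about cue use) and correction trials are included by default
(the animals experienced them; both choices are flags, since accuracy
summaries can reasonably be computed either way).
`outcome_rule_frequencies()` expresses stay/shift responses relative to the
number of previous-win and previous-lose trials, so win-stay + win-shift
= 1 and lose-stay + lose-shift = 1 whenever defined.
`rule_reward_probabilities()` divides the number of times a rule paid by
the number of times it was applied — the reward rate of each strategy from
the animal's perspective. The elementary inferential tools are exact
binomial tests against chance, uncorrected 2×2 Pearson chi-square
comparisons (escape counts of 11/12 vs 4/12 animals give χ² = 8.71 under
the uncorrected convention adopted here; Yates correction is an option),
and Fisher-z transformed Pearson correlations.

One classification rule deserves note: stay/shift labels for *trials*
(as opposed to responses) are taken relative to the previous trial's
**correct** side regardless of the animal's response, and relative to the
chosen (rewarded) side after ambiguous trials. This is the only reading
that covers correction trials (same target repeated ⇒ stay) and ambiguous
trials consistently; it is a package decision where the protocol is
silent.

## The agent-based bootstrap

To test whether an animal's cue-rule performance could be produced by pure
outcome-based responding, `run_bootstrap()` plays a probability-table
agent through the generative task on the animal's own schedule (same days,
phases and trial counts), with the agent's day-specific response
probabilities set to the animal's own observed conditional frequencies —
p(stay|win) and p(stay|lose) per day for the outcome family, p(left | cue
position × contrast) per day for the cue family. Contexts unobserved on a
day fall back to 0.5 (uninformative; carrying forward the previous day is
a config alternative). Replicates (default 1,000) yield per-day percentile
bands (default 90%) of accuracy on stay and on shift trials; replicate
agents face freshly generated task sequences, not a replay of the animal's
literal trial list, matching the design of the original procedure.

Days on which the observed accuracy leaves the band count as *escapes*,
and the escape count is assessed against an upper-tail binomial null. The
pairing of a 90% band with a binomial parameter α = .05 implies a
one-sided reading without stating the direction; we default to
**above-band** escapes with α = .05 for the outcome-family bootstrap
(the question is whether the animal *beats* the best outcome-only agent)
and **either-side** escapes with α = .10 for the cue-family bootstrap,
with both policy and α exposed as arguments.

Calibration caveat: per-day accuracies on a few dozen trials are discrete,
so percentile bands are slightly conservative (measured above-band escape
rate ≈ .044 at nominal .05 in the package's own calibration run). The
`probs` argument lets coverage studies drive the replicates with a known
generating table; when probabilities are instead inferred from the record
under test — the standard analysis path — the bands additionally absorb
part of the animal's day-to-day noise, which makes escapes conservative
rather than anticonservative.

## Reinforcement-learning models

Both RL model families track four state-action values \(V(s,a)\). The
*cue* family's states are the brighter cue's position with actions
left/right; the *outcome* family's states are win/lose (previous trial's
outcome) with actions stay/shift. Learning follows the hybrid
Rescorla–Wagner/Pearce–Hall rule

\[
V_{t+1}(s,a) = V_t(s,a) + \kappa\,\alpha_t\,\delta, \qquad
\delta = r_t - V_t(s,a),
\]
\[
\alpha_{t+1} = (1-\eta)\,\alpha_t + \eta\,|\delta|,
\]

with a constant global learning rate \(\kappa \in [0,1]\) and an
associability \(\alpha_t\) that rises with the magnitude of recent
prediction errors and decays otherwise, at trade-off \(\eta \in [0,1]\).
Choices follow a softmax with a separate inverse temperature \(\beta_k >
0\) per task phase. Reduced variants fix \(\kappa = 1\) (`hybrid_fixed`)
or hold the associability constant (`rw`, a pure Rescorla–Wagner learner
with rate \(\kappa\alpha_0\)); with \(r \in \{0,1\}\) and
\(V_0, \alpha_0 \in [0,1]\), values and associability provably stay in
\([0,1]\).

Defaults the protocol leaves open, chosen once: \(V_0 = 0\) for all pairs
(so the first prediction error equals the reward) and \(\alpha_0 = 1\)
(so \(\kappa\) is the initial learning rate); both are arguments of
`rl_model_spec()`. Values carry across sessions and phases within an
animal — only \(\beta_k\) switches at phase boundaries. Ambiguous trials
(no brighter cue) and each animal's first trial (no previous outcome) are
excluded from the likelihood of **both** families, so the trial count
\(n\) entering BIC is identical across models; ambiguous trials still
update outcome-family values, because the animal experienced their
feedback. Correction trials are included throughout.

`rl_fit()` minimises the negative log-likelihood by bounded L-BFGS-B from
100 random starts by default (\(\kappa,\eta\) uniform in \([0,1]\),
\(\beta\) log-uniform in \([0.01, 50]\); the upper β bound keeps the
optimisation well-posed and is far above any fitted value). The forward
pass is a small compiled kernel, overflow-safe in the softmax; an
independent brute-force reimplementation backs it in the test suite.

## Model selection

Per-animal log model evidence is approximated by \(-\mathrm{BIC}/2\) with
\(\mathrm{BIC} = -2\log L + k \log n\) (k = 5 for the full hybrid, 4 for
each reduced rule). `bms()` estimates the random-effects posterior over
population model frequencies by the variational scheme: per-animal
assignment weights \(u_{nm} \propto \exp(L_{nm} + \psi(\alpha_m) -
\psi(\sum_j \alpha_j))\) are normalised and re-accumulated into Dirichlet
counts \(\alpha_m = \alpha_{0m} + \sum_n g_{nm}\) until the parameters
move less than 1e−6 (cap 10⁴ iterations, non-convergence flagged). The
prior is uniform (\(\alpha_0 = 1\) per model). Exceedance probabilities —
the posterior probability that a model is the most frequent — use the
closed-form Beta tail \(P(\pi_1 > .5)\) for two models and seeded
Monte-Carlo Dirichlet sampling otherwise. `compare_update_rules()`
implements the family-marginalising comparison of update rules: per animal
and rule, the BICs of the cue and outcome models are averaged and the
resulting evidences are passed to the same BMS machinery.

## What the validation runs show — and at what sizes

The package's acceptance suite validates the chain end to end on synthetic
cohorts (all sizes are the package's own validation choices):

- **Structure**: a lose-shift agent is rewarded on 100% of phase I
  correction trials; free-draw frequencies match the configured .25/.125
  probabilities within 3 binomial SE at ≥ 20,000 draws.
- **Recovery**: 12 animals per family generated at κ = .3, η = .4,
  β = (2, 3, 4) with 2,000 trials each (10×40, 12×50, 10×100 sessions),
  fitted at 25 starts. All six β parameters recover within 20% median
  absolute error; outcome-family κ and η within 0.15.
- **Identifiability**: cross-family BMS assigns exceedance ≥ .95 to the
  generating family in both directions, and the BIC-averaging rule
  comparison ranks the full hybrid rule first on hybrid-generated data.
- **Bootstrap**: band calibration within 2 SE of the nominal escape rate
  over 50 animals × 20 days at 200 replicates, and a cue-state RL learner
  escapes its matched outcome bootstrap above band on essentially all
  post-learning days — the qualitative signature the method is built to
  detect.

## Known limitations

- **κ/η identifiability for the cue model.** Cue-state rewards are
  deterministic given the state-action pair, so once values converge the
  prediction errors — and with them the associability dynamics — vanish.
  After early learning the likelihood is nearly flat along a κ–η ridge,
  and at realistic trial counts the cue family's κ and η are not
  individually recoverable (median absolute errors ≈ .22 and .38 at the
  sizes above, with fitted likelihoods *better* than the generating
  parameters'). The β parameters, the model-family comparison and the
  update-rule comparison are unaffected. The outcome family, whose rule
  payoffs remain stochastic, does not share the problem.
- The synthetic task emulates trial-transition structure and reward
  contingencies, not response latencies, satiety or day-to-day motivation
  drift; passing tests demonstrate correctness of the analysis chain, not
  that real animals satisfy any model's assumptions.
- The bootstrap's day-probability inference uses the same record being
  assessed, which is faithful to the original design but mildly
  conservative (see above).
- BMS here uses BIC evidences; free-energy evidence approximations and
  protected exceedance probabilities are out of scope.
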