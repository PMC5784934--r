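---
title: "Memory coherence: the dependency statistic and an emotion-modulated attractor model"
author: "memcoh"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Memory coherence: the dependency statistic and an emotion-modulated attractor model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memcoh)
```

## The scientific problem

An episodic event binds several elements — here a person, a location and an
object — into one memory. If the binding is coherent, a cue from the event
tends to bring back *all* of it: success on one cued association predicts
success on the others. `memcoh` implements (i) the statistic that quantifies
this coherence from forced-choice retrieval data, (ii) generators for the
experimental designs that produce such data, (iii) a rate-coded attractor
network that encodes the same protocols and shows how negative emotional
content can fragment an event by weakening its associations, and (iv)
synthetic responders with known dependency structure for calibrating the
analysis.

The experimental designs covered are: 36 or 72 three-element events, half
*negative* (the person element is aversive; location and object are always
neutral), encoded either as simultaneous triples or as overlapping pairs
across three blocks. In pairs mode each event follows one of two orders —
**person-last** (location–object, person–location, object–person) or
**person-first** (object–person, person–location, location–object) — so the
purely neutral pair is studied either before or after any negative element
has entered the event. Memory is probed with six directed questions per
event (every association, both directions) in a 6-AFC whose six options
always contain three elements from neutral and three from negative events,
with foils drawn from other events of the target's category.

## The dependency statistic

For one participant and condition, let x(A→B) be the 0/1 outcome of cueing
with element A for target B. Six 2×2 contingency tables pair the questions
that share a cue (A→B vs A→C, for each of the three categories as A) or a
target (B→A vs C→A). Each event contributes one count per table.

* **Observed dependency**: D is the proportion of events falling in the
  both-correct or both-incorrect cells, averaged over the six tables with
  equal weight.
* **Independent model**: with P_AB the participant's mean accuracy on
  question A→B within the cell, each table predicts
  `Di = P_AB P_AC + (1 − P_AB)(1 − P_AC)` — the agreement expected when
  retrievals succeed independently at the observed marginals.
* **Dependent model**: each event i is given an episodic factor E_i from the
  four questions *outside* the table: with e_i the event's mean on those
  questions, ē their grand mean and f = P_G/c the guessing floor
  (c = 6 options; P_G is the probability that an unknown answer is a guess,
  default 1),

  E_i = (e_i − f) / (ē − f),   Ṕ_i = E_i (P − f) + f, clamped to [0, 1],

  and the table predicts the mean over events of
  `Ṕ_AB Ṕ_AC + (1 − Ṕ_AB)(1 − Ṕ_AC)`. If every E_i = 1 the Dependent model
  collapses exactly onto the Independent one (this identity is tested to
  1e-12).

D − Di measures excess coherence; D − Dd measures how far the data fall
short of fully event-driven retrieval.

### Why the episodic factor is guessing-corrected

The defining calibration of the Dependent model is that it captures fully
dependent responding: a responder who either knows an entire event or
guesses every question should yield Dd ≈ D. A plain performance ratio
E_i = e_i/ē with the floor applied only inside Ṕ fails this badly — on
all-or-none data with q = 0.5 it *underpredicts* dependency by ~0.15,
because known events are dragged toward the marginal — and would make the
"maximal dependency" benchmark sit below the data. Subtracting the floor
from both numerator and reference restores the benchmark: Ṕ_i then reduces
to the event's observed reference performance, so known events predict ≈ 1
and guessed events ≈ f. E_i can fall below zero for events performing under
the floor; the [0, 1] clamp on Ṕ absorbs this, and with P_G = 0 the
corrected form reduces to the plain ratio.

One bias remains and is intrinsic to any Table-style plug-in: e_i is
estimated from only four binary questions, and the agreement function is
convex in Ṕ, so Dd exceeds D on fully dependent data by
2(1 − q)·Var(e_i) = (1 − q)·g(1 − g)/2 (≈ 0.035 at q = 0.5, g = 1/6). The
test suite asserts this excess at its analytic value rather than pretending
it away; in practice it means Dd is a slightly conservative upper benchmark,
and D − Dd should be compared between conditions rather than read as an
absolute zero test.

### Analysis conventions

* Cells are participant × condition (× encoding order in pairs designs),
  18 events per cell at the default design sizes.
* Events with missing or duplicate questions are rejected with an error
  naming the participant/event; nothing is imputed.
* A cell whose four-question grand mean is at or below the guessing floor
  has no usable reference (E would divide by ≤ 0); it raises a
  degenerate-reference error rather than returning a number.
* P_G defaults to 1 (unknown answers are guesses at the full 1/6 chance
  rate). For model-generated responses, which contain no guessing mechanism
  (foils are never retrieved), `P_G = 0` is the appropriate setting and is
  what the package's own simulation analyses use.

## The attractor network

One neuron per element, fully recurrent, no self-connections. Rates follow
synchronous threshold-linear dynamics

r_i ← clip(I_ext,i + Σ_j w_ij r_j − θ_T, 0, r_max),

with one update step per millisecond over a 1000 ms trial. During encoding
the presented elements receive I_drive = 15 nA; during retrieval the cue
receives 15 nA and the six forced-choice options 5 nA. A trial's weights
update by a Hebbian rule with a BCM-like postsynaptic threshold,
Δw_ij ∝ m·k·r_i·[r_j − θ_p]+, applied with probability p_enc per trial
(one draw shared by both directions of the pair) and capped at the trial
ceiling m·w_max. The modulation factor m drops from 1 to 0.6 whenever any
negative-element neuron fires at or above θ_neg = 1 Hz — whether presented
or incidentally reactivated through associations already learned.

| parameter | meaning | default |
|---|---|---|
| θ_T | activation threshold | 5 nA |
| r_max | peak rate | 10 Hz |
| θ_p | potentiation threshold | 7.5 Hz |
| w_max | weight ceiling | 1 |
| k_neut | neutral learning rate | 1.6e-4 /ms |
| p_enc | per-trial encoding probability | 0.65 |
| m_neg | emotional modulation | 0.6 |
| θ_neg | negative-reactivation threshold | 1 Hz |
| I_drive / I_choice | cue / option currents | 15 / 5 nA |
| θ_ret | retrieval threshold | 5 Hz |
| t_enc, t_ret | trial durations | 1000 ms |
| n_sims | simulated participants | 26 |

The arithmetic that makes the model work is worth laying out. A strong
(w = 1) association retrieves its target directly at 10 Hz; a weak (w = 0.6)
association retrieves directly at 5 + 0.6·10 − 5 = 6 Hz ≥ θ_ret. Pattern
completion through the third element is asymmetric: a weak link *into* a
strong pair ignites a gain-one loop that climbs to saturation (retrieval
succeeds), whereas a strong link followed by a weak one converges below
threshold (3/0.64 ≈ 4.7 Hz < 5), and two weak links fail outright
(0.94 Hz). Hence neutral events — all links strong when encoded — can
complete missing associations (per-question accuracy
p_enc + (1 − p_enc)p_enc² ≈ 0.798), while negative events cannot complete
through their weakened links (location↔object accuracy exactly p_enc = 0.65
under person-last). A single weak link also reactivates the negative person
at exactly 0.6·10 − 5 = 1 Hz during a later neutral-pair trial, which is why
θ_neg comparisons are inclusive: that marginal case must trigger modulation
for the person-first order to weaken the closing location–object pair.

### Design choices the dynamics forced

* **Per-trial weight ceiling m·w_max.** With the printed learning rate and
  1 ms steps, any co-presented pair's integrated increment exceeds 1 within
  a trial, so a single hard cap would erase the strong/weak distinction the
  retrieval asymmetry depends on. The trial ceiling max(w_old, m·w_max)
  preserves the modulation ratio (neutral trials saturate at 1, modulated
  trials at 0.6) and never decrements an existing stronger weight.
* **Potentiation requires both units above θ_p.** The Hebbian product with a
  single postsynaptic threshold would let a sub-threshold reactivated neuron
  (e.g. the negative person at 1–7 Hz) grow weights in one direction,
  breaking weight symmetry and spuriously binding the reactivated element.
  Gating on both rates keeps updates symmetric (both presented neurons fire
  at r_max) and leaves incidentally reactivated neurons untouched, which is
  the functional requirement of the reactivation mechanism.
* **Inclusive thresholds** (≥) everywhere a quantity can land exactly on a
  threshold; see the 1 Hz case above.
* **Rates reset between trials**; no activity carries over.
* **Response rule**: a trial is correct iff the correct option reaches
  θ_ret *and* is strictly the maximum among the six options. Under default
  dynamics no cross-event weight ever forms, foils stay silent, and the
  argmax clause never binds; it guards degenerate parameterisations only.
* **Network size** is 3 × number of events (216 for the default protocol);
  the settle loop multiplies only over currently active neurons and stops at
  an exact fixed point (change < 1e-12), which never truncates the linearly
  climbing gain-one loops (they gain ≥ 0.5 Hz per step until the cap).
* **Seeding**: each simulated participant runs on its own RNG stream derived
  from the master seed, so any single simulation is reproducible in
  isolation.

## Synthetic responders

The generator regimes bracket the dependency spectrum: *independent*
(every question an independent Bernoulli at its marginal — D − Di = 0 in
expectation), *all-or-none* (event known with probability q, else each
question guessed at g = 1/6 — the fully dependent limit, with closed forms
D = q + (1 − q)(g² + (1 − g)²) and Di from p = q + (1 − q)g), and *graded*
(event strength s ~ Beta(2, 2), question accuracy g + s(1 − g) —
intermediate dependency for stress-testing Dd). The Beta(2, 2) default was
chosen once as a realistic mid-spread strength distribution; it is not
fitted to anything.

These responders emulate the *structure* the analysis assumes (six questions
per event, chance 1/6, event-level dependence) but deliberately none of the
content effects in real data: no pair-type differences, no primacy, no
fatigue, no foil-identity confusions, and a guessing process that is
independent across questions. Passing calibration on them shows the
statistic does what it claims on its own terms — not that real data meet its
assumptions.

## What the checks compute, and at what sizes

The package's tests and the `scripts/acceptance.R` summary recompute, from
scratch at fixed seeds chosen in advance: the 6-AFC chance level on ~1e5
guessing trials; schedule counts (216 and 432 test trials for the 36- and
72-event designs); the Dd = Di identity at unit episodic factors (residual
< 1e-12); calibration of D − Di and the all-or-none closed form on 10^4
synthetic events (20 participants × 500 events); agreement between the
network settle routine and an independent scalar fixed-point oracle over all
729 ordered 3-neuron weight configurations in {0, 0.6, 1} at three current
patterns, all 729 symmetric 4-neuron configurations, and seeded random 5–6
neuron configurations; and the full protocol at the study scale (26
simulations × 72 events), whose neutral accuracy must fall in the 99%
interval around the enumerated 0.798 using the exact per-event variance
(within an event the six outcomes share three link draws, so the event — not
the trial — is the independent unit; a trial-level binomial interval would
be miscalibrated by construction), and whose negative person-last
location↔object accuracy is event-level Bernoulli(0.65). The qualitative
pattern — accuracy neutral > negative under both orders, neutral D − Di > 0,
negative person-first D − Di indistinguishable from zero and below negative
person-last — is checked across the 26 simulations.

## Known limitations

* The dependency measures need at least two events per cell, a usable
  (above-floor) reference mean, and complete six-question events; the
  package rejects rather than imputes.
* Dd carries the analytic plug-in excess described above; treat it as an
  upper benchmark.
* The network is deliberately minimal: no inhibition, no spiking, no
  consolidation or delay effects, no anatomical mapping, and abstract
  elements rather than stimuli. Recognition (old/new) responses are
  representable in schedules but not scored.
* The test-schedule interleaving constraint is implemented as "no two
  consecutive trials from the same event" (reshuffle with bounded retries,
  then greedy repair); the minimum spacing is a package choice, as is the
  half/half default split of encoding orders within each condition.
* Inferential statistics on D/Di/Dd (ANOVAs, effect sizes) are out of scope;
  the tidy per-participant output is meant to feed standard tools.
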