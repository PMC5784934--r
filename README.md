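# memcoh

Episodic memories of multi-element events (a person, a location, an object)
are thought to be stored as coherent representations: cueing with one element
triggers pattern completion of the others, so retrieval successes for
different associations of the same event are statistically related. `memcoh`
is an R package for quantifying that coherence and for simulating a neural
mechanism by which negative emotional content can disrupt it. It is aimed at
memory researchers who run multi-element cued-recall experiments (or want to
simulate them) and need the dependency analysis and the attractor-network
model as tested, reusable components.

The package provides four things:

1. **Experiment design** — generators for person–location–object event sets,
   encoding schedules (simultaneous triples, or overlapping pairs across
   three blocks under *person-last* and *person-first* orders), and
   six-alternative forced-choice (6-AFC) test schedules in which every
   within-event association is tested in both directions with
   valence-balanced foils.
2. **Dependency analysis** — the contingency-table coherence statistic. For
   each participant, six 2×2 tables count, over events, joint success of two
   retrievals sharing a cue (A→B vs A→C) or a target (B→A vs C→A). Observed
   dependency is the mean proportion of agreeing outcomes,

   D = mean over tables of (both correct + both incorrect) / n_events,

   compared against an **Independent model**
   Di = P_AB·P_AC + (1−P_AB)(1−P_AC) built from the participant's marginal
   accuracies, and a **Dependent model** Dd in which each event's marginals
   are scaled by an episodic factor E_i (its guessing-corrected performance
   on the four questions outside the table, relative to the cell mean) with a
   guessing floor P_G/c: Ṕ_i = E_i·(P − P_G/c) + P_G/c.
3. **Attractor-network model** — a fully recurrent network of rate-coded,
   threshold-linear neurons (r = clip(I_ext + Σ_j w_ij r_j − θ_T, 0, r_max)),
   one neuron per element. Associations are learned by a probabilistic
   Hebbian rule with a BCM-like postsynaptic threshold θ_p; the learning rate
   is down-modulated (m = 0.6) whenever a neuron coding a negative element is
   active or incidentally reactivated. Weak (modulated) associations support
   direct cued retrieval but not pattern completion through a third element —
   the mechanism that reduces both accuracy and coherence for negative
   events, most strongly when the purely neutral pair is studied last.
4. **Synthetic behaviour** — response-table generators with known
   ground-truth dependency (independent, all-or-none, graded regimes) for
   calibrating and stress-testing the analysis without any external data.

## Worked example

Simulate eight model participants on the 72-event overlapping-pairs protocol
and analyse the coherence of the resulting responses:

```r
library(memcoh)

params <- model_params(n_sims = 8)           # printed model constants
events <- make_events(n_neutral = 36, n_negative = 36)
enc    <- make_encoding_schedule(events, "pairs", assign_orders(events), seed = 1)
test   <- make_test_schedule(events, seed = 2)

rt  <- run_simulation(events, enc, test, params, seed = 3)
round(tapply(rt$correct, list(rt$condition, rt$encoding_order), mean), 3)
#>          person_first person_last
#> negative        0.634       0.725
#> neutral         0.833       0.769

rep <- dependency_report(rt, P_G = 0)        # model responses never guess
rep$summary[, c("condition", "encoding_order", "D_mean", "Di_mean",
                "Dd_mean", "D_minus_Di_mean")]
#>   condition encoding_order D_mean Di_mean Dd_mean D_minus_Di_mean
#> 1  negative   person_first  0.556   0.537   0.669          0.0185
#> 2  negative    person_last  0.657   0.608   0.735          0.0498
#> 3   neutral   person_first  0.847   0.730   0.864          0.1170
#> 4   neutral    person_last  0.824   0.662   0.851          0.1626
```

Accuracy is lower for negative events under both encoding orders, and
coherence tells the mechanistic story: neutral events show substantial excess
dependency over the Independent model (D − Di ≈ 0.12–0.16, pattern
completion at work), negative events encoded person-last retain a reduced
excess (≈ 0.05, carried by the strong location–object association formed
before any negative element appeared), and negative events encoded
person-first sit near the Independent model (≈ 0.02 here; zero in
expectation) because every association was weakened by the presented or
reactivated negative element. With only eight simulated participants the
accuracy cells still carry visible sampling noise (the two neutral orders are
identical in expectation); the 26-simulation runs used by the tests tighten
these estimates.

The same analysis runs on behavioural CSV files via
`read_response_table()` (with a `col_map` option for external layouts), or
from the shell:

```sh
Rscript exec/memcoh simulate-network --sims 8 --seed 1 --out rt.csv
Rscript exec/memcoh analyze --input rt.csv --pg 0 --out results/
```

## Package layout

- `R/experiment_design.R` — events, encoding and test schedules
- `R/network.R`, `R/simulate.R` — attractor dynamics, learning rule,
  encoding/retrieval protocol, link-configuration enumeration
- `R/dependency.R` — D, Di, Dd, episodic factors, reports
- `R/generate.R` — synthetic responders and closed-form truths
- `R/io.R`, `R/cli.R`, `exec/memcoh` — CSV/JSON/YAML formats and the CLI
- `vignettes/memory-coherence.Rmd` — the model, its assumptions, parameter
  meanings, and the package's numerical and design choices
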