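---
title: "A maximally parallel Petri net model of Wnt/β-catenin signaling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A maximally parallel Petri net model of Wnt/β-catenin signaling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wntpetri)
```

## The model

`wntpetri` implements a qualitative place/transition Petri net of the core
Wnt/β-catenin signaling pathway and the discrete, stochastic semantics used
to execute it. Places hold integer token counts standing for the relative
availability of a gene, protein or complex; transitions move tokens along
weighted arcs. The shipped network has 18 places, 11 transitions and 41
arcs:

* **Receptor module.** WNT binds FZD and LRP (t1); DVL joins the complex
  (t2); cytoplasmic AXIN is sequestered to the membrane, forming the
  signalosome (t3). The signalosome dissociates slowly (t4): all three of
  its arcs carry weight 0.1, i.e. one dissociation per ten steps.
* **Destruction module.** AXIN, APC, CK1 and GSK3 assemble the destruction
  complex (t5); the complex binds β-catenin (t6) and degrades it, being
  either reused (t7) or dissociated back into its components (t8). The
  β-catenin token bound in the complex is *not* re-emitted by t7/t8 — the
  degradation is implicit in the consumption.
* **Expression module.** The β-catenin gene produces one protein token per
  step (t9, read-arc gene pattern: the gene token is required and
  reproduced). Free β-catenin translocates to the nucleus and binds TCF/LEF
  (t10) once 3 tokens have accumulated, of which 1 is consumed (in-weight 3,
  out-weight 2), reflecting the destruction complex's higher binding
  affinity. The activator complex drives AXIN2 transcription (t11), whose
  product replenishes the AXIN pool at the feedback weight (0 = no
  feedback, 0.15 = maximal feedback, i.e. three AXIN tokens per 20 steps).

Wildtype initial marking: 5 tokens on each free protein pool (FZD, LRP,
DVL, AXIN, APC, CK1, GSK3), 1 on TCF/LEF and on both gene places, 0 on
every complex and on free β-catenin; WNT starts at 0 and is raised to
model stimulation.

```{r build}
net <- build_wnt_net()
net
validate_net(net)
```

## Execution semantics

One simulation step fires a *maximal* multiset of transitions:

1. A transition is enabled when every input place holds at least
   `ceiling(weight)` unreserved tokens (so a fractional input arc needs one
   waiting token).
2. The step's firing multiset is built by iterated uniform-random
   reservation: among the transitions enabled against the residual
   unreserved marking, one is drawn uniformly at random, its token demand
   for this step is reserved, and its count is incremented; the loop stops
   when nothing is enabled. Competition for a shared token (t3/t5 over
   AXIN, t6/t10 over β-catenin, t7/t8 over the loaded destruction complex)
   is therefore resolved by an unbiased draw, with no special-case
   priorities.
3. Productions land at the step boundary: tokens produced in step *k* are
   first consumable in step *k + 1*, which prevents unbounded within-step
   cascades through loops such as t6→t7.

The sampling scheme is re-evaluated after every reservation. Random conflict
resolution does not by itself pin down a sampling mechanism; per-reservation uniform redraw is the simplest scheme
that satisfies both maximality and the random-draw description, and its
aggregate predictions are checked against the model's reference endpoints
(the exact 100-token and roughly-60-token stabilizations, the degradation
rates) in the acceptance suite.

### Fractional arc weights as exact firing rates

A fractional weight *w = p/q* encodes a rate-limited transfer: each firing
adds *p* to an integer credit numerator kept over the arc's own denominator
*q*, and a whole token moves whenever the numerator reaches *q*. All weight
arithmetic is exact rational arithmetic (weights are parsed once into
reduced `num/den` integer pairs), so a continuously enabled transition with
weight 0.1 transfers *exactly* once every 10 steps, 0.15 exactly three
times per 20 steps (at offsets 7, 14, 20), and 0.05 exactly once per 20
steps — hard equalities, not floating-point approximations. Credit accrues
only on steps in which the transition fires, so a starved transition does
not accumulate rate. Any transition carrying a fractional arc is capped at
one firing per step (fractional credit per firing is only well defined at
one firing per step); the same cap applies to transitions with no input
arcs, which would otherwise make the maximal step unbounded.

```{r rates}
chain <- petri_net(
  tibble::tibble(source = c("src", "t"), target = c("t", "snk"),
                 weight = c(0.1, 0.1)),
  places = c("src", "snk"), transitions = "t", marking = c(src = 100L)
)
tr <- simulate_net(chain, steps = 40, seed = 1)
which(diff(tr$markings[, "snk"]) > 0)
```

## Tunable parameters

All knobs live in `wnt_scenario()`:

| parameter        | unit            | default | meaning                                         |
|------------------|-----------------|---------|-------------------------------------------------|
| `wnt`            | tokens (0–5)    | 0       | initial WNT level; 5 = maximal stimulation      |
| `gsk3`           | tokens (0–5)    | 5       | initial GSK3 level; 0 = complete inhibition     |
| `axin2_feedback` | weight [0,0.15] | 0       | t11→AXIN arc weight; AXIN tokens per t11 firing |
| `apc_weight`     | weight          | 1       | t5→DC production weight; <1 models APC mutants  |
| `steps`          | steps           | 100     | simulation horizon                              |
| `replicates`     | runs            | 100     | ensemble size                                   |
| `seed`           | —               | 1       | base seed; replicate r uses seed + r            |

The defaults are the study conditions: 100 steps × 100 replicates, protein
pools of 5 tokens (large enough to be expressive, small enough to stay
coarse-grained), TCF/LEF at 1 (the lowest transcription rate). Steps and
tokens are deliberately unitless — the model captures the order of events
and relative levels, not physical time or concentrations.

The t11→AXIN arc always exists, at weight 0 in no-feedback mode: a
zero-weight arc transfers nothing and never blocks enabling, and keeping it
in place means the no-feedback and feedback networks differ only in one
number (the arc is also counted among the 41). `validate_net()` normally
flags zero weights; nets record deliberately-zero arcs in their `zero_ok`
set. In APC-mutant mode (`apc_weight < 1`) t5 gains four return arcs of
weight `1 - apc_weight`, so that over `1/apc_weight` firings exactly one
destruction complex forms while the components are otherwise returned.

## The four campaigns

```{r campaigns, eval = FALSE}
wnt_sweep(seed = 1)                       # WNT 0..5, GSK3 5
gsk3_sweep(seed = 1)                      # GSK3 5..0, WNT 0
apc_mutation_scan(seed = 1)               # DC production 0.2, 0.1, 0.05, 0
axin2_feedback_sweep(seed = 1)            # WNT {3,4,5} x feedback {0..0.15}
```

Each returns a tidy tibble (`parameter`, `step`, `mean`, `sd` over the
total-β-catenin observable: free plus destruction-complex-bound plus
TCF/LEF-bound) with `glance()` endpoint summaries and `autoplot()` methods.
Ensemble seeds are derived from the base seed and the swept parameter
*value* (not its grid position), so the feedback sweep at weight 0 is
trace-identical to the WNT sweep under the same base seed.

`degradation_rate()` reports tokens degraded per three steps as three times
the least-squares slope of `step − mean(step)` over steps 40–100 (the late
window excludes the initial transient; both window and the flat-response
threshold of 10 tokens are arguments, not constants).

## What the engine's property tests do and do not show

Engine correctness is checked against an independent brute-force oracle:
on randomly generated nets (≤5 places, ≤4 transitions, integer weights,
`random_net()`), every sampled step outcome must be one of the maximal
firing multisets enumerated by exhaustive search, and on small conflict
nets every enumerated outcome must eventually be sampled. Conservation is
checked on conservative fixtures (equal input/output weight sums per
transition), credits are asserted to stay in `[0, 1)`, and traces are
asserted to be pure functions of `(net, steps, seed)`. These generated nets
exercise the semantics, not the biology: passing them shows the token game
is implemented correctly, while the biological adequacy of the Wnt network
rests on the campaign-level comparisons (flat responses, the ~60 and
exactly-100 token endpoints, degradation rates, APC response ordering).

## Numerical and design choices

* **Exact rationals.** Credits are integer numerators; no floating-point
  drift over arbitrarily many steps. Weights must be exact multiples of
  1/10000 (or `"p/q"` strings), which covers every weight in the study.
* **Replicate seeds** are `base_seed + r (mod 2^31 − 1)` — fixed and
  logged; the sample standard deviation uses the n−1 denominator and is
  reported as 0 with a warning for a single replicate.
* **Degenerate inputs.** A net with no transitions simulates to a constant
  trace; `steps ≤ 0` or `replicates ≤ 0` are argument errors; an invalid
  net is refused by `simulate_net()` with the full violation report.
* **Ties.** There is no tie-breaking order anywhere: every conflict is a
  uniform draw over the currently enabled set.
* **Problem sizes.** The shipped tests run reduced ensembles (5–20
  replicates) for the unit level and the full 100 × 100 study conditions in
  the acceptance suite; a 100 × 100 ensemble of the 18-place net takes a
  few seconds.

## Known limitations

* Uniform per-reservation redraw is one of several samplers consistent
  with resolving token competition by a random draw; other orderings would
  shift the split between destruction-complex reuse and dissociation.
  Degradation rates at GSK3 = 1 and 2 come out near 0.9 and 1.7 tokens per
  three steps, within ±0.5 of the nominal 1 and 2 but not equal to them.
* Transcription (t11) requires but does not consume the TCF/LEF–β-catenin
  complex (read-arc pair; this is what closes the arc count at 41). The
  TCF-bound β-catenin pool is therefore conserved, and under maximal AXIN2
  feedback the total-β-catenin curve declines only shallowly after its
  interior maximum rather than returning all the way to baseline; the peak
  and its later onset at higher WNT levels are reproduced.
* Tokens and steps have no physical scale; only relative comparisons
  between scenarios are meaningful.
* No inhibitor arcs, place capacities, priorities, or continuous-time
  (Gillespie) semantics; within-step production is never consumable in the
  same step.
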