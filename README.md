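# wntpetri

Qualitative Petri net simulation of Wnt/β-catenin signaling.

The Wnt/β-catenin pathway controls cell proliferation and differentiation;
its deregulation drives colorectal and breast cancer. The constitutively
produced β-catenin is degraded by a destruction complex (AXIN, APC, CK1,
GSK3); WNT stimulation sequesters AXIN into a membrane signalosome,
starving the destruction complex and stabilizing β-catenin, which then
activates TCF/LEF target genes including the negative feedback regulator
*AXIN2*. `wntpetri` is for systems biologists who want to simulate this
logic without rate constants: it models the pathway as a place/transition
Petri net (18 places, 11 transitions, 41 arcs) and executes it with a
discrete, stochastic token game.

## The semantics in brief

Each step fires a **maximal** multiset of transitions: repeatedly, among
the transitions enabled against the unreserved marking (every input place
*p* of *t* must hold at least ⌈w(p,t)⌉ unreserved tokens), one is drawn
uniformly at random and its tokens are reserved, until nothing is enabled.
Competition for shared tokens is thus resolved without bias. A fractional
arc weight w = p/q is a firing rate: each firing adds p to an exact integer
credit over q and a token moves when the credit reaches q, so w = 0.1
transfers exactly once per 10 steps and w = 0.15 exactly three times per
20 steps. Productions become consumable at the next step. Ensembles
summarise the total β-catenin observable (free + destruction-complex-bound
+ TCF/LEF-bound) by per-step mean and SD across seeded replicates.

## Worked example

```r
library(wntpetri)

# maximal WNT stimulation, study conditions: 100 steps x 100 replicates
net <- build_wnt_net(wnt_scenario(wnt = 5))
ens <- run_ensemble(net, steps = 100, replicates = 100, seed = 1,
                    observable = total_beta_catenin)
glance(ens)
#> # A tibble: 1 × 5
#>   steps replicates base_seed final_mean final_sd
#>   <int>      <int>     <int>      <dbl>    <dbl>
#> 1   100        100         1       66.3     10.1
```

Maximal stimulation stabilizes ~60–66 β-catenin tokens by step 100: the
signalosome keeps most AXIN away from the destruction complex, so
production (1 token per step from the β-catenin gene) outruns degradation
after an initial delay. Complete GSK3 inhibition removes degradation
entirely and the endpoint is exactly 100 tokens in every replicate:

```r
g0 <- run_ensemble(build_wnt_net(wnt_scenario(gsk3 = 0)),
                   steps = 100, replicates = 100, seed = 1,
                   observable = total_beta_catenin)
glance(g0)[, c("final_mean", "final_sd")]
#> # A tibble: 1 × 2
#>   final_mean final_sd
#>        <dbl>    <dbl>
#> 1        100        0
```

Campaign drivers reproduce the four in-silico experiments as tidy tibbles
with `autoplot()` methods:

```r
wnt_sweep(seed = 1)             # WNT 0..5:   flat for <=2, delayed rise for >=3
gsk3_sweep(seed = 1)            # GSK3 5..0:  flat for >=3; 0 gives exactly 100
apc_mutation_scan(seed = 1)     # four ordered APC-mutant response levels
axin2_feedback_sweep(seed = 1)  # AXIN2 feedback: attenuated, peaked responses
autoplot(gsk3_sweep(seed = 1))
```

Nets interchange via PNML (`read_pnml()` / `write_pnml()`, fractional
weights as decimal inscriptions), and `inst/cli/wntpetri` is a shell entry
point (`simulate`, `sweep`, `export-pnml`, `validate`).

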