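---
title: "Costless secretions, cross-feeding motifs, and chemostat stability: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Costless secretions, cross-feeding motifs, and chemostat stability: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossfeedr)
```

## The question the package answers

Microbes routinely excrete metabolic byproducts. When excreting a compound
does not reduce the producer's growth rate, the secretion is *costless*: it
can persist evolutionarily without invoking altruism, yet it enriches the
environment for other species. `crossfeedr` implements a complete in-silico
pipeline around this idea: detect costless secretions in constraint-based
metabolic models, iterate pairwise "co-culture" experiments in which
secretions feed back into the shared medium, classify the resulting
ecological interactions into motifs, and ask which motifs can support stable
coexistence in a chemostat.

## Costless secretion by two-stage FBA

Flux balance analysis treats a metabolic network at steady state: find a
flux vector $v$ with $S v = 0$ and $v_{\min} \le v \le v_{\max}$ that
maximizes biomass flux. The package computes secretions in two LP stages:

1. maximize biomass flux, giving the optimal growth rate $v_{g,0}$;
2. minimize $\sum_r |v_r|$ (fluxes split into non-negative forward and
   backward parts) subject to the same constraints plus
   $v_{g,s} \ge v_{g,0}$, and read the secretion profile off the exchange
   fluxes of the stage-2 solution.

Stage 2 is the parsimonious-flux heuristic: it suppresses futile cycles and
emulates economical proteome use, so a metabolite exported in this solution
is exported because stoichiometry demands it at optimal growth, not because
the optimizer had slack. By construction every reported secretion satisfies
the defining inequality of costlessness — forcing that exchange flux at the
reported rate cannot reduce the optimal growth rate — and the test suite
re-verifies this with `secretion_cost()` on every secretion it reports over
randomized toy media.

Numerical choices that matter:

* **Secretion/uptake cutoff, 0.01 mmol gDW⁻¹ h⁻¹** (inclusive on both
  sides): guards against solver-noise "secretions". Exchange flux
  convention is secretion-positive/uptake-negative.
* **Growth threshold, 1e-6 h⁻¹**: the binary growth status used by the
  iteration logic; deliberately distinct from the secretion cutoff.
* **Growth floor slack, 1e-9 relative** on $v_{g,s} \ge v_{g,0}$: strict
  equality of two LP optima is numerically brittle.
* **Degeneracy**: flux minimization reduces but does not eliminate
  alternate optima. The solver (a dense two-phase simplex with Bland's
  smallest-index rule, compiled in C++) is fully deterministic, so the
  returned secretion set is *a* minimal-total-flux optimum, reproducible
  run to run. An infeasible program (for example an unsatisfiable
  maintenance flux) reports growth 0 by contract.

All flux bounds are finite (±1000 mmol gDW⁻¹ h⁻¹ caps), so the LPs are
bounded by construction.

## Media and the iterative experiment

A `medium` is a set of external metabolite ids: non-limiting base nutrients
(uptake bound 1000), growth-limiting carbon sources (bound 10, the
experimentally motivated sugar-uptake cap), cross-fed metabolites added
during expansion, and an oxygen flag applied *per organism* at bound time
(so one experiment can mix an oxic and an anoxic partner). The uptake bound
for cross-fed metabolites is not stated in the source framework; the package
defaults it to 10, the same as primary carbon sources, on the grounds that
growth on a partner's byproduct should be physiologically bounded like any
other carbon uptake. It is configurable, and results that hinge on it should
be checked at 1000 as well.

`run_pair_experiment()` iterates: solve both organisms independently on the
current medium (no resource partitioning — each organism sees the full
medium, which is what makes the per-iteration LPs separable), pool their
costless secretions, add the ones new to the medium, repeat. Media grow
monotonically inside a finite metabolite universe, so the loop provably
terminates within (number of distinct external metabolites) iterations; the
final iteration index is $c_s$. Iteration 1 doubles as the solo-growth
record used for obligate-syntrophy calls. Both organisms' secretions enter
the medium in one simultaneous update per iteration, so organism order is
irrelevant by construction (and asserted by a swap-symmetry test).

## Interaction classification

For a pair in which both organisms grew:

* **competition** — some primary carbon source is taken up (flux ≤ −0.01)
  by *both* organisms in the final iteration;
* **exchange edge** $i \xrightarrow{m} j$ — $i$ secreted $m$ costlessly in
  some iteration and $j$ takes $m$ up in its final-iteration minimal-flux
  solution. Receiver-side evidence mirrors the secretion cutoff
  symmetrically (the source framework is silent on the uptake side), with
  no soft margins: a flux of −0.009 is not an edge.
* **class** — N (no edges), C (one direction), M (both directions); the
  motif code appends the number of primary carbon sources consumed by the
  pair and `a`/`b` for competition, e.g. `C1a`, `M2b`.

Water and protons are excluded from edge evidence by default: they are
ubiquitous bookkeeping flows. CO₂ and ammonium are *not* excluded — both
act as genuine enabling byproducts (heterotrophs that need a partner's CO₂
or recycled nitrogen are real motifs in this framework). The exclusion list
is a parameter.

The cooperativity index of two carbon sources is computed exactly as the
printed combinatorial formula: normalized pair-growth frequency minus the
product of normalized single-source frequencies, each normalizer being the
count of organism pairs tested, $\binom{N}{2}$. The operation takes the
counts explicitly so any aggregation convention can be driven from a sweep
table.

## The toy-model generator as ground truth

`toyforge` builds small (≤ 15 reactions), flux-consistent networks whose
optima are hand-derivable, emulating facultative-anaerobe physiology:
fermentation (2 ATP + 2 acetate per glucose), respiration (10 ATP + 6 CO₂,
requires O₂), acetate oxidation, peptide deamination (carbon skeleton plus
excess ammonium), biomass = 1 carbon + 2 ATP + 0.5 NH₄. The worked
fermenter FERM grows anoxically at exactly 5 h⁻¹ secreting 10 acetate,
oxically at 25/3 h⁻¹ secreting 10 CO₂ and no acetate; forcing 1 unit of
acetate oxically costs exactly 1/3 h⁻¹ of growth. These numbers anchor the
acceptance suite.

Eleven of the twelve motif grammar codes are constructible as engineered
toy pairs and are recovered exactly by the full pipeline; `N1a` is not
constructible (with one consumed carbon, no competition and no exchange,
the second organism has nothing to grow on) and errors with an explanation.
CO₂ sits in the toy base medium — as in common minimal-medium definitions —
which is also what makes the worked fermenter/acetate-specialist experiment
complete at $c_s = 2$ rather than bouncing once more on a "new" CO₂
secretion.

Toy stoichiometry is flux-consistent but *not* elementally balanced (no
formula checking); nothing in the pipeline requires elemental formulas.
What a green toy-suite test establishes is that the algorithmic machinery
(two-stage LP, iteration, classification) is correct on networks with known
ground truth; it does not establish anything about any real organism's
secretion profile — for that the package accepts user-supplied curated
models (SBML) harmonized onto a shared namespace.

## Chemostat stability of motifs

Each motif maps to a Monod chemostat: organism abundances $s_i$, primary
resources $m_\alpha, m_\beta$ with additive inflow $I$ and dilution $D$,
cross-fed metabolite pools $\tilde m_i$ produced at $k_{\text{sec}} s_i$
and consumed by the partner. The inflow enters as the printed additive
constant even though its declared unit (g/L) reads like a concentration;
we keep the printed form and note that a classical chemostat would use
$D(\text{feed} - m)$ — with $I = 0.1$ and $D = 0.1$ the two coincide at the
consumer-free steady state.

Two wiring rules were genuinely open and are fixed as follows:

* two primary carbon sources consumed by one organism enter its growth as
  a *product* of Monod terms (the printed two-resource form);
* a cross-fed metabolite is a separate *additive* growth channel
  $\mu_{\max}\,\tilde m/(k_{\tilde m}+\tilde m)$, whose consumption term
  mirrors the production/consumption balance of the cross-fed pool. An
  organism with no primary resource (the `C1a`/`M1a` recipient) grows on
  this channel alone.

The additive choice makes a cross-fed edge always weakly beneficial to the
receiver, which is the reading consistent with the framework's qualitative
claims; making it multiplicative would instead render the partner's
byproduct *essential* and can only shrink stability regions. Under the
additive wiring all the expected structure emerges and is asserted in the
test suite: the shared-resource no-exchange motif `N1b` is competitive
exclusion (stable only in a thin near-diagonal band of the
$\mu_{\max,1} \times \mu_{\max,2}$ grid — width ≤ 2 grid cells at the
default parameters, consistent with the $\sim \ln 2/(T D)$ neutral-decay
estimate); `N2a` is stable exactly where both species individually clear
the closed-form break-even $\mu^* = D(k + I/D)/(I/D) = 0.105$ h⁻¹; `C1a`
is stable even when the recipient's $\mu_{\max}$ exceeds the producer's;
and stable fractions order M ≥ C ≥ N within each motif family.

Parameter defaults ($D = 0.1$, $I = 0.1$, $k = k_{\tilde m} = 0.05$,
$K = K_{\tilde m} = 0.5$, $k_{\text{sec}} = 0.1$, $s_i(0) = 0.1$,
resources at 0, 500 h horizon, 0.05 g/L survival threshold, 51×51 grid over
$\mu_{\max} \in [0,1]$) are order-of-magnitude values from the chemostat
literature; the source framework's exact parameter table is not published
in its main text, so stability maps are qualitative structure, not
figure-for-figure reproductions. Integration is an adaptive Cash–Karp
RK4(5) (rtol 1e-6, atol 1e-9) compiled in C++, with non-negativity enforced
by clipping at zero and clip events counted; the survival test is applied
at exactly $t_{\text{end}}$ with no averaging window. A plain-R
right-hand-side closure is exposed by `build_motif_system()` and the test
suite cross-checks the compiled trajectories against a fine-step RK4 built
on it.

## A worked record

```{r worked}
pr <- make_motif_pair("C1a")
rec <- run_pair_experiment(pr$model_i, pr$model_j, pr$medium,
                           "absent", "absent")
rec
classify_interaction(rec)
obligate_syntrophy(rec)
```

The fermenter grows on glucose at 5 h⁻¹ and secretes acetate at
10 mmol gDW⁻¹ h⁻¹; the acetate specialist cannot grow alone, grows at
10/3 h⁻¹ once acetate is cross-fed, and the pair classifies as `C1a`
(commensal, one carbon source, no competition) with the specialist flagged
as an obligate syntroph.

## Scope and limitations

* Sweep execution is pairwise ($N_M = 2$); `plan_sweep()` enumerates
  larger organism subsets but `run_sweep()` refuses them.
* No metabolite concentrations, depletion, toxicity, pH, regulation, or
  enzyme-cost modeling: interactions are stoichiometric possibilities,
  not kinetic predictions.
* The returned secretion set is one deterministic minimal-total-flux
  optimum; alternate optima with different secretion sets can exist in
  degenerate networks.
* Machine-learning condition classifiers and dynamic-FBA concentration
  sensitivity checks are out of scope by design.
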