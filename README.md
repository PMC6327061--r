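# crossfeedr

Costless metabolic secretions and the cross-feeding interactions they
enable, from constraint-based metabolic models.

## The problem

Cross-feeding — one microbe consuming another's metabolic byproducts — is a
leading explanation for microbial diversity in nutrient-poor environments,
but exchanged metabolites are usually assumed to cost the producer fitness.
A secretion is **costless** when exporting it does not reduce the producer's
optimal growth rate: writing `v_g,0` for the flux-balance-analysis (FBA)
growth optimum and `v_g,s` for the optimum under a forced secretion at rate
`v_s`, the defining condition is `v_g,s >= v_g,0`. Costless secretions need
no altruism, yet they can feed partners, relieve competition, and stabilize
communities.

`crossfeedr` is an R package for systems biologists and synthetic-ecology
designers that implements the full pipeline around this idea:

1. **Two-stage FBA** (`solve_growth()`, `costless_secretions()`): maximize
   biomass flux subject to `S v = 0` and bounds, then minimize `sum(|v|)`
   at fixed optimal growth (parsimonious flux) and read costless
   secretions off the exchange fluxes (cutoff 0.01 mmol/gDW/h). Forced
   secretion probes (`secretion_cost()`) classify any metabolite as
   costly / costless / beneficial / infeasible. Alternative objectives
   (min biomass, max/min ATP) are supported.
2. **Iterative pair experiments** (`run_pair_experiment()`): two organisms
   on a shared medium; each iteration pools newly secreted metabolites
   back into the medium until it stops changing (final iteration `c_s`).
   Oxygen is applied per organism, so hybrid oxic–anoxic pairs work.
3. **Combinatorial sweeps** (`plan_sweep()`, `run_sweep()`): unordered
   organism pairs x carbon-source pairs x oxygen states, checkpointed and
   resumable, with summary tables (`summarize_sweep()`) including a
   Spearman co-secretion matrix and the carbon-source cooperativity index
   `C = g_ab/C(N,2) - [g_a/C(N,2)][g_b/C(N,2)]`.
4. **Interaction motifs** (`classify_interaction()`): competition = both
   organisms consume a primary carbon source; exchange edges from
   secretion + receiver uptake; motif grammar `[NCM][12][ab]` (class,
   carbons consumed, competition).
5. **Chemostat stability** (`stability_map()`): Monod chemostat ODEs wired
   per motif, integrated 500 h over a grid of maximum specific growth
   rates; a cell is stable when both species finish above 0.05 g/L.
6. **Toy-model ground truth** (`make_organism()`, `make_motif_pair()`,
   `make_suite()`): deterministic generators of small metabolic networks
   with hand-derivable optima, used throughout the test suite.

Models are read/written as a documented plain-text JSON dialect or SBML
Level 3 (flux bounds via parameters); cross-model metabolite namespaces are
harmonized with `harmonize()`.

## Worked example

The built-in fermenter `FERM` (fermentation: 2 ATP + 2 acetate per glucose;
respiration: 10 ATP + 6 CO2; biomass: 1 glucose + 2 ATP + 0.5 NH4) on a
glucose minimal medium without oxygen:

```r
library(crossfeedr)
ferm <- make_organism(toy_spec_ferm())$model
med  <- build_medium(c("nh4_e", "co2_e", "h2o_e", "h_e"), "glc_e",
                     oxygen = "absent")
cs <- costless_secretions(ferm, med)
cs$solution$growth_rate   # 5
cs$secretions             # ac_e: 10
```

Growth is exactly 5/h with 10 mmol/gDW/h acetate secreted — fermentation is
the only ATP route, so acetate export is stoichiometrically forced and
therefore costless. With oxygen the same probe shows the context-dependence
of secretion cost:

```r
secretion_cost(ferm, med, "ac_e", 1, oxygen_override = "present")
#> $category       "costly"
#> $delta_growth   -0.3333333
```

(diverting glucose to fermentation costs exactly 1/3 of the 25/3 oxic
optimum). Pairing the fermenter with an acetate specialist that cannot use
glucose:

```r
pr  <- make_motif_pair("C1a")
rec <- run_pair_experiment(pr$model_i, pr$model_j, pr$medium,
                           "absent", "absent")
rec
#> <pair_experiment> FERM + ACSP on {glc_e} (O2: absent/absent): c_s=2, growth 1/1
classify_interaction(rec)
#> <interaction_label> C1a (i->j, 1 edge(s))
obligate_syntrophy(rec)
#>  FERM  ACSP
#> FALSE  TRUE
```

The medium stabilizes after two iterations: the specialist grows only
because of the cross-fed acetate (obligate syntrophy), giving a commensal,
non-competitive, single-carbon motif `C1a`. Its chemostat counterpart:

```r
stability_map("C1a", grid_n = 21)
#> <motif_stability_map> C1a: 21 x 21 grid, stable fraction 0.735
```

and the cooperativity index of a carbon-source pair from sweep counts:

```r
cooperativity_index(45, 30, 60, 14)   # 0.2771404
```

## Command line

```sh
Rscript -e 'crossfeedr::crossfeed_main()' gen-toy --suite 4,6 --seed 7 --out toy
Rscript -e 'crossfeedr::crossfeed_main()' sweep --models toy \
    --carbons toy/carbons.txt --o2 both --out sweep_out
Rscript -e 'crossfeedr::crossfeed_main()' stability --motif C1a --grid 51 --out stab
```

(or use the installed `inst/cli/crossfeed` launcher). Every output
directory receives a `config_snapshot.json` sufficient to reproduce it.

## Vignette

`vignettes/costless-crossfeeding.Rmd` documents the model and its
assumptions, every tunable cutoff with units and defaults, the toy-model
generator's scope, the chemostat wiring choices, and known limitations.
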