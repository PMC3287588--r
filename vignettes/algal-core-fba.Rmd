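---
title: "Compartmentalized algal metabolic models: reconstruction, flux balance analysis and hydrogen studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compartmentalized algal metabolic models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phycoflux)
```

## The modelling framework

phycoflux works with compartmentalized stoichiometric models of algal
primary metabolism. A model is a set of metabolites, each bound to one of
five compartments (cytosol, plastid, mitochondrion, microbody,
extracellular), and a set of reactions with signed stoichiometric
coefficients, flux bounds, gene associations and provenance tags. The
central mathematical object is the stoichiometric matrix $S$
(metabolites $\times$ reactions); a steady-state flux distribution $v$
satisfies

$$ S\,v = 0, \qquad lb \le v \le ub , $$

and flux balance analysis (FBA) optimizes a linear objective $c^\top v$
over this polytope. Two problem families mirror how such models are used
to probe algal physiology:

* **Substrate minimization** ("wild type"): fix the growth flux to an
  observed rate (an equality, lower bound = upper bound) and minimize the
  uptake of the key energy substrate — photons under autotrophic and
  mixotrophic growth, acetate under heterotrophic growth.
* **Product maximization** ("hypothetical producer"): fix growth the same
  way and maximize a secretion flux, here molecular hydrogen.

Exchange fluxes are signed with uptake negative. Flux units are
mmol gDW$^{-1}$ h$^{-1}$; the combined biomass flux is h$^{-1}$, with the
biomass coefficients expressed in mmol gDW$^{-1}$ so the units close.

### Alternate optima

FBA optima are almost never unique. The scalar optimum is the contract;
for the reported flux *vectors* the package solves a secondary LP that
minimizes the total absolute flux at the (locked) optimum, the standard
parsimonious resolution. This makes flux comparisons between scenarios
reproducible and deterministic — repeated runs give identical reports.
The objective is locked into a thin band ($10^{-7}$ relative) below the
optimum rather than an exact equality, to keep the restriction feasible
in floating point.

### The LP engine

The solver is a bounded-variable revised simplex written for this
package: variables sit at a bound or in the basis, so the working
dimension stays at the number of balance rows; two phases with artificial
variables; Dantzig pricing with a Bland's-rule fallback that engages
after runs of degenerate pivots (metabolic polytopes are heavily
degenerate); the basis inverse is refactorized every 250 iterations.
Pivot tolerance is $10^{-9}$; reported feasibility (steady-state
residual, producibility) is checked at $10^{-6}$. Infinite user bounds
are replaced by a $\pm 10^{6}$ box, and a solution pinned to that box
under a declared-infinite bound is reported as `unbounded` rather than
optimal. The test suite cross-checks the engine against exhaustive
vertex enumeration on every network with at most eight reactions.

## The curation pipeline

Raw gene-centric reaction tables become simulation-ready models in four
steps, in this order:

1. **Duplicate-compound resolution** (`merge_duplicate_compounds`):
   non-canonical compound labels (for instance specific versus
   non-specific sugar stereoisomers) are rewritten through a synonym
   table; coefficients that merge within one reaction are summed, and
   reactions whose stoichiometry becomes identical are collapsed with
   their gene associations OR-combined — the union of catalysing genes is
   the conservative choice when two database entries describe one
   transformation.
2. **Polymer rewriting** (`expand_polymer_reactions`): degenerate
   elongation entries (`polymer(n) + monomer -> polymer(n+1)`) are
   rewritten as accumulation of the polymer's monomer unit; species
   carrying the generic "R" group are rejected outright.
3. **Compartment assignment** (`assign_compartments`): per reaction,
   literature localization evidence beats homology evidence beats the
   cytosol default. Multiple literature claims duplicate the reaction,
   one copy per compartment — required to represent, e.g., plastidic and
   cytosolic glycolysis as distinct fluxes. Evidence is applied per
   reaction, not per enzyme, since one enzyme may catalyse reactions in
   several compartments.
4. **Transporter addition** (`add_transporters`): membrane transport is
   poorly annotated and enters from a curated table; intercellular
   (cytosol–extracellular) and inter-organelle transporters are counted
   separately in the model statistics.

The pipeline is idempotent (running it twice equals running it once),
which the test suite asserts. All inputs are offline tab-delimited files;
nothing is fetched from live databases.

## Gap analysis

A reconstruction is functional when every biomass component is
producible. `producibility_screen` solves one LP per component drain and
condition; a component whose maximal drain flux does not exceed
$10^{-6}$ is blocked. For a blocked component, `trace_breakpoints` walks
backward over producing reactions and classifies each non-producible
metabolite it meets: `no_producer` (structural), `missing_transporter`
(the chemical is producible in a sibling compartment),
`irreversibility_conflict` (producible once internal irreversibility is
relaxed), or `blocked_precursor` (the blockage is upstream). Structural
checks run before LP-based ones, and traversal is sorted and cycle-safe
with a depth cap (default 25) to stay desk-scale on large inputs.

Tracing classifies producibility with a flux-consistency sweep:
temporary sinks are attached to every metabolite and the summed sink
flux is maximized repeatedly until no further metabolite activates. A
metabolite the sweep cannot activate cannot carry production flux even
with every other sink open — the standard gap-finding notion, and a few
LPs classify the whole metabolome. The component screen itself keeps the
stricter one-LP-per-drain form. The two notions can differ for
metabolites whose production is coupled to a by-product with no
consumer; on the shipped fixture the blocked sets agree, and the sweep
direction is the sound one for declaring a metabolite blocked.

## The synthetic algal core network

`generate_core_network()` builds the fixture the whole test suite runs
on: ~111 reactions and ~106 metabolites across all five compartments,
every internal reaction elementally balanced against Hill-notation
formulas (reduced electron carriers carry one extra hydrogen per
electron so redox chemistry closes). It contains the qualitative biology
the package's predictions rest on:

* lumped linear electron flow (2 photons per electron; 2 ATP per O$_2$
  evolved for the proton-gradient contribution) and optional cyclic
  electron flow around PSI (2 photons per ATP, consuming reduced
  ferredoxin, no net reductant);
* Calvin cycle with separate RuBisCO carboxylation and oxygenation,
  phosphoglycolate phosphatase, and two photorespiratory fates for
  glycolate: the algal route (mitochondrial glycolate dehydrogenase
  feeding the ubiquinone pool — no H$_2$O$_2$, no catalase) and
  secretion; a plant-style microbody route (glycolate oxidase, catalase,
  recycling to glycerate) can be switched in for contrast experiments;
* acetate assimilation through acetyl-CoA synthetase (cytosol and
  microbody), the microbody glyoxylate cycle (two acetyl-CoA to one
  succinate), the mitochondrial succinate→malate→oxaloacetate leg, PEP
  carboxykinase and gluconeogenesis to G6P, and plastidic starch
  synthesis;
* plastidic and cytosolic glycolysis, the plastidic oxidative pentose
  phosphate pathway (the dark NADPH source), pyruvate–ferredoxin
  oxidoreductase (PFR), ferredoxin hydrogenase, and a plastid
  phosphotransacetylase/acetate kinase leg so dark fermentation can
  regenerate acetate;
* TCA cycle and coupled oxidative phosphorylation (P/O 2.5 for NADH,
  1.5 for ubiquinol), fermentative drains (formate, ethanol, lactate),
  ammonia and phosphate uptake, and four biomass drains (starch glucosyl
  units, alanine, AMP, palmitate) plus a combined biomass equation with
  30 mmol gDW$^{-1}$ growth-associated ATP and a 0.1 mmol gDW$^{-1}$
  h$^{-1}$ maintenance floor;
* no glucose or sucrose uptake — the organism modelled cannot use these
  carbon sources.

Energy parameters (photon stoichiometry, P/O ratios, maintenance
values, the biomass coefficients, a 200 mmol gDW$^{-1}$ h$^{-1}$ photon
cap standing in for constant illumination and 10 mmol gDW$^{-1}$ h$^{-1}$
caps on dissolved uptakes) are documented order-of-magnitude choices,
not literature measurements. The network is deterministic — the
`random_seed` argument exists only for interface stability — and its
SBML serialization is canonical, so two builds are byte-identical.

### Trophic scenarios

`trophic_scenario()` encodes the three growth conditions as bound sets:
autotrophic (CO$_2$ open, acetate closed, photons free up to the cap,
growth 0.059 h$^{-1}$, minimize photons), heterotrophic (acetate open,
CO$_2$ uptake closed with secretion open, photons zero, growth
0.035 h$^{-1}$, minimize acetate), mixotrophic (everything open, growth
0.066 h$^{-1}$, minimize photons). H$_2$ secretion is the
optimization-2 product in all three. Two modelling choices deserve
comment:

* **Dark RuBisCO closure.** The heterotrophic preset also closes both
  RuBisCO activities. RuBisCO is light-regulated and dark-inactive; more
  importantly, without this the LP happily "refixes" respired CO$_2$
  through the Calvin cycle in the dark, using PFR-derived reductant — a
  stoichiometrically legal but biologically spurious bypass that hides
  genuine network gaps.
* **The wild-type cyclic-flow floor.** A reaction knockout can only
  shrink an LP's feasible set, so "disrupting cyclic electron flow
  increases maximal H$_2$" can only hold if the wild type is constrained
  to *run* cyclic flow. The mixotrophic preset therefore imposes a small
  activity floor (2 mmol gDW$^{-1}$ h$^{-1}$) on the cyclic-flow
  reaction, representing the state-transition allocation of PSI activity
  in the wild type; the knockout arm of `h2_study` removes the floor
  along with the reaction. This mirrors the wild-type-versus-mutant
  comparison the study design calls for.

### What the fixture does and does not show

Passing tests on this fixture demonstrate that the machinery — curation,
LP engine, scenario application, gap tracing, serialization — does what
it claims, and that the qualitative flux routing matches the biology
built into the network: glycolate is catabolized or secreted rather than
recycled unless the plant-style route is installed; dark H$_2$ flows
through acetate assimilation, the glyoxylate cycle, gluconeogenesis,
plastidic glycolysis, PFR and the hydrogenase simultaneously; disrupting
cyclic electron flow strictly increases maximal mixotrophic H$_2$ at
fixed growth.

They do not demonstrate quantitative agreement with a genome-scale
reconstruction. Magnitudes (substrate minima, H$_2$ maxima, the
knockout fold change) are properties of the toy stoichiometry and its
documented parameters, not predictions about any organism; the
multi-fold H$_2$ increase reported for real state-transition mutants
lives in a network with far more routing freedom than this one. Two
specific scale limitations are worth naming. At the exact substrate
minimum the fixture has zero spare electrons, so maximizing H$_2$ with
uptake pinned at the minimum yields exactly zero — any slack above the
minimum immediately buys hydrogen. And the wild-type mixotroph covers
its ATP demand through the acetate loop rather than the citrate cycle,
so the "TCA down in the H$_2$ producer" signature of genome-scale
analyses appears here as flat-rather-than-reduced citrate-cycle flux;
the tests assert the direction is never *up*.

## Numerical and interface choices

* Default bounds are the conventional effectively-unbounded box:
  $(-1000, 1000)$ for reversible reactions, $(0, 1000)$ otherwise.
* Compartments are encoded as one-letter id suffixes (`_c`, `_p`, `_m`,
  `_x`, `_e`).
* Individual biomass drains and the combined biomass equation coexist;
  adding the combined equation closes the drains, producibility
  screening re-opens the drain under test, and a scenario activates
  exactly one of the two modes.
* SBML is written as Level 3 Version 1 with flux bounds as global
  parameters and gene associations, reaction kinds, evidence and
  subsystems in reaction notes (`GENE_ASSOCIATION:` lines); reading
  accepts Level 2 and 3, COBRA-style kineticLaw bounds, and falls back
  to reversibility-derived defaults. Serialization sorts everything by
  id and formats numbers canonically, so write∘read∘write is
  byte-identical.
* Unique-reaction statistics count compartmental copies as distinct by
  default; a compartment-stripped mode is exposed for comparison with
  counting conventions that collapse them.
* Flux-change classification (`compare_fluxes`) calls a reaction
  increased when its absolute flux exceeds the reference by more than
  20%, with an absolute floor of $10^{-6}$ standing in for zero
  references; pathway direction tables aggregate absolute flux per
  subsystem under the same rule.
* Problem sizes throughout the tests are chosen to keep the whole suite
  in the minutes range: the vertex-enumeration oracle runs on networks
  of at most eight reactions, and the gap-recovery experiment uses 50
  seeded single-deletion fixtures.

## Known limitations

Charge balance, protonation states and thermodynamic feasibility are out
of scope (the elemental audit is an audit, not an enforcement). Gene
knockouts are per reaction, not per gene through the GPR logic. The
breakpoint cause taxonomy is heuristic where the underlying cause is
ambiguous — under a dark scenario with a severed carbon route, many
upstream metabolites are reported as blocked precursors of one another
before the terminal cause is reached. Fixture energetics are lumped;
anyone needing quantitative predictions should load a genome-scale SBML
reconstruction through `read_sbml()` and work with that.
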