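# admespace

**An ADME property space for drug discovery: consensus QSPR fingerprints on
a self-organizing map.**

`admespace` is an R package for medicinal chemists and ADME modellers who
want to monitor many pharmacokinetic properties of drug-like molecules at
once. Instead of describing a molecule by its structure, it describes it by
its *predicted ADME behaviour*: twenty QSPR classification endpoints —
transporter inhibition/recognition (Pgp, BCRP, OCT2, OATP1B1), Caco-2 and
brain permeability, clearance route, maximum recommended daily dose, CYP
implication and inhibition, and metabolic stability in three species — each
contribute one ternary value

> `+1` positive class · `−1` negative class · `0` uncertain,

and the ordered vector of the twenty values is the molecule's **ADME
fingerprint**. A self-organizing map (SOM) trained on these fingerprints
arranges molecules by ADME similarity: with two decided levels per property
there are 2²⁰ = 1,048,576 possible profiles, which a 50×50 grid (2500
nodes) condenses into a navigable 2D space. Structural analogues with
divergent pharmacokinetics (ADME-cliffs) land in distant regions — exactly
what structure-based spaces miss.

The package implements the full pipeline:

* **Property catalog** — the 20 endpoints, their class meanings, and the
  experimental class-assignment thresholds (with the deliberate grey zone
  labelled `0`).
* **Consensus QSPR classifiers** — ensembles (RF, SVM, AdaBoost, extra
  trees, LDA, gradient boosting, CART, PLS+threshold) that assign a class
  only when ≥ 80% of the members agree (4 of 5 decides; 3 of 5 is `0`),
  with a descriptor-box + centroid-distance applicability domain, and
  accuracy/MCC/coverage validation that never hides abstention.
* **SOM engine** — classical online Kohonen training on the raw ternary
  values, ON/OFF node bookkeeping, per-node ternary fingerprints,
  outlier-aware projection of external molecules, lossless JSON
  serialization.
* **Map layers & region recipes** — per-property layers plus three shipped
  multi-layer triage colorings: permeability/active-transport,
  metabolism/CYP-implication, and bioavailability/DDI-risk; overlays for
  experimental or naive (unmapped) properties; series-dispersion analysis
  for congeneric series.
* **Synthetic data** — archetype-clustered fingerprints and
  class-conditional descriptor clouds, so every stage runs and is tested
  without proprietary descriptor software or private training data.
* **CLI** — `inst/cli/admespace.R` exposes `fit`, `predict`, `train-map`,
  `project`, `layer`, `combine`, `overlay`, `simulate`, `validate`.

## Worked example

Train a map on synthetic archetype-clustered fingerprints, inspect a node,
and run the triage recipes:

```r
library(admespace)

arch <- generate_archetypes(3, seed = 42)          # 3 well-separated profiles
spec <- archetype_spec(arch, flip_rate = 0.05, uncertain_rate = 0.05)
gen  <- generate_fingerprints(spec, 1200, seed = 43)

map <- som_train(som_init(som_config(rows = 20, cols = 20,
                                     epochs = 10, seed = 44)),
                 gen$fingerprints)
map
#> SOM map 20x20 (400 nodes), dim 20, trained: 237 ON (59.2%), outlier cutoff 3.645
archetype_purity(map, gen$fingerprints, gen$archetype)
#> [1] 1
```

About 59% of the nodes are ON (populated); the rest carry no information
and delimit the map's applicability domain. Purity 1 means every molecule
sits in a node dominated by its own archetype. Projecting molecules gives
their node, BMU distance and outlier status:

```r
proj <- som_project(map, gen$fingerprints)
head(proj[, 1:7], 3)
#>   molecule_id row col node_label distance is_outlier node_on
#> 1    SYN00001   0  10       0_10 1.378829      FALSE    TRUE
#> 2    SYN00002  10  17      10_17 1.073583      FALSE    TRUE
#> 3    SYN00003   9   6        9_6 1.407797      FALSE    TRUE

head(interpret_fingerprint(node_fingerprint(map, c(0, 10))), 5)
#>          key         label
#> 1 BCRP_INHIB Non-inhibitor
#> 2 BCRP_RECOG Non-substrate
#> 3 BRAIN_PERM     Permeable
#> 4 CACO2_PERM     Permeable
#> 5      CLEAR     Metabolic
```

Layers and the bioavailability/DDI-risk recipe (a node is *risky* when it
combines low absorption, low metabolic stability, a single implicated CYP
isoform and Pgp recognition; *safe* is the exact opposite):

```r
caco2 <- extract_layer(map, "CACO2_PERM")
caco2
#> Map layer CACO2_PERM (20x20): 228 decided, 9 uncertain, 163 no-data

cyps <- sapply(c("CYP1A2_PERC", "CYP2D6_PERC", "CYP3A4_PERC"),
               extract_layer, map = map, simplify = FALSE)
bioavailability_risk(caco2, extract_layer(map, "METASTAB_human"),
                     extract_layer(map, "PGP_RECOG"), cyps)
#> Region coloring 'bioavailability_risk' (20x20):
#>
#>   risky    safe neutral
#>       3       5     392
```

A property *not used to build the map* (here a synthetic stand-in for
solubility, generated at association 0.9 with Caco-2 permeability) still
paints coherent regions when overlaid — the map anticipates naive ADME
properties linked to the mapped ones:

```r
naive <- generate_correlated_property(gen$fingerprints, "CACO2_PERM",
                                      r = 0.9, seed = 45)
experimental_agreement(caco2, naive_property_overlay(map, proj, naive))
#> [1] 0.9581882
```

See `vignettes/adme-space-methods.Rmd` for the model, its assumptions, the
tunable parameters and the design decisions.

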