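---
title: "Methods: an ADME property space from consensus QSPR fingerprints and self-organizing maps"
author: "admespace package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an ADME property space from consensus QSPR fingerprints and self-organizing maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admespace)
```

## The model

Most chemical-space methods describe molecules by structure (fragments,
physicochemical descriptors). That description is poorly suited to
pharmacokinetics: structurally near-identical analogues can have sharply
different ADME behaviour (ADME-cliffs), and no single structural space
explains absorption, metabolism, transport and toxicity surrogates at once.

This package takes the opposite route: a molecule is described *only* by its
predicted ADME behaviour. Twenty classification endpoints — efflux/influx
transporter inhibition and recognition (Pgp, BCRP, OCT2, OATP1B1), Caco-2 and
blood–brain-barrier permeability, clearance route, maximum recommended daily
dose, CYP implication (1A2, 2D6, 3A4) and inhibition (1A2, 2C9, 2D6, 3A4),
and metabolic stability in human, rat and mouse — each contribute one ternary
value:

* `+1` — the positive class (inhibitor, substrate, permeable, stable, ...),
* `-1` — the negative class,
* `0` — *uncertain*: the classifier abstained or the molecule fell outside
  the model's applicability domain.

The ordered vector of the twenty values is the molecule's **ADME
fingerprint**. With two decided levels per property there are
$2^{20} = 1{,}048{,}576$ possible profiles; a self-organizing map (SOM)
condenses the realized profiles onto a 2D grid whose nodes carry continuous
prototype vectors and, after thresholding, their own ternary fingerprints.
Everything downstream — per-property map layers, region colorings, projection
of new molecules — reads off this grid.

## Consensus classifiers with an abstain class

Each property model is an ensemble of standard classifiers (random forest,
SVM, AdaBoost over stumps, extremely randomized trees, LDA, gradient
boosting, CART, or a PLS-regression-plus-threshold variant) fitted on the
same descriptor matrix. The final class is assigned only when at least
$\lceil a \cdot m \rceil$ of the $m$ members agree, with agreement fraction
$a = 0.8$ by default — so 4 of 5 members decide, while 3 of 5 is a doubtful
case and yields `0`. Because $a > 1/2$, ties are impossible, and with three
members $\lceil 2.4 \rceil = 3$ forces unanimity.

Two further sources of `0` exist: the **applicability domain** (below), and
the grey zone of experimental labeling — class-assignment thresholds such as
"IC$_{50} \le 15\,\mu M$ inhibitor / IC$_{50} > 50\,\mu M$ non-inhibitor"
deliberately leave a band between the classes, and measurements falling there
are labelled `0`. Where a rule accepts two measurement kinds (IC$_{50}$ *or*
percent inhibition) either criterion suffices; if the two conflict, the
conservative result is `0`.

**Applicability domain.** The domain is the intersection of the
descriptor-wise training min/max box and a standardized centroid-distance
ball. The distance cutoff is a quantile of the training distances; the
default quantile is 1.0 (the maximum), so that every training molecule is
inside its own domain — an invariant we consider more important than the
marginally tighter 0.99 ball, which would disown 1% of the training set. The
quantile is a configuration option for users who prefer the tighter rule.
Out-of-domain molecules are assigned `0` unconditionally, before any member
votes are counted.

**Evaluation.** Abstentions (`0`) are excluded from the confusion matrix but
reported as reduced *coverage*, so an apparently accurate model cannot hide
behind heavy abstention. Accuracy is used for balanced sets and the Matthews
correlation coefficient for unbalanced ones; an MCC with a vanishing
denominator (single-class predictions) is defined as 0.

## SOM training

The map is a rectangular, non-toroidal grid (50×50 = 2500 nodes at full
scale; smaller grids for smaller datasets) trained by classical online
Kohonen updates on the raw ternary fingerprints:

* weights initialized uniformly in $[-1, 1]^{20}$ from the seed;
* Gaussian grid neighborhood, initial radius $\max(\text{rows},
  \text{cols})/2$, initial learning rate $0.5$;
* both decay exponentially over the run, to final values $0.5$ (radius) and
  $0.01$ (rate);
* presentation order reshuffled every epoch from the seed; default 10
  epochs;
* weights clamped to $[-1, 1]$, the range of the inputs.

The distance metric is plain Euclidean distance on the ternary values, which
keeps `0` equidistant from both decided classes. Best-matching-unit ties are
broken toward the lexicographically smallest `(row, col)`; grid coordinates
are 0-based and node labels are formatted `row_col`.

After the final epoch every training molecule is assigned to its BMU. Nodes
holding at least one molecule are **ON**; empty nodes are **OFF** — their
prototype is too dissimilar from every real profile, they carry no
information, and together they delimit the map's applicability domain. The
**outlier cutoff** is the maximum BMU distance over the training set: a
projected molecule farther from its BMU than any training molecule is an
outlier and receives no prediction. (A quantile alternative is available but
the max keeps the invariant "no training molecule is an outlier of its own
map".) A tiny relative tolerance ($10^{-9}$) is applied to the cutoff and to
the domain box bounds so that boundary-defining molecules survive a JSON
serialization round trip, which rounds doubles in their last bits.

**Node fingerprints.** A node's ternary profile thresholds its prototype at
$\pm\tau$ with $\tau = 1/3$ by default, splitting $[-1,1]$ into three equal
bands. An alternative would be a majority vote of the node's member
molecules; thresholding was chosen because it is defined for every ON node
regardless of occupancy and is exactly the quantity the per-property layers
display.

## Layers, overlays and region recipes

A **layer** is one coordinate of every node fingerprint arranged on the grid
(OFF nodes carry `NA`). Three multi-layer triage recipes ship with the
package; in all of them an uncertain (`0`) value fails every predicate, so
uncertainty can never place a node in a risky or optimal region:

* **transport/permeability** — among low-Caco-2-permeability nodes: Pgp
  recognition only → purple, BCRP only → orange, both → black, neither →
  uncolored (the low permeability may have other causes, e.g. high
  polarity);
* **metabolism** — among metabolically unstable (human) nodes: exactly one
  highly implicated CYP isoform → that isoform's color (1A2 orange, 2D6
  pink, 3A4 cyan), two or more → black. Only the three modeled isoforms are
  counted;
* **bioavailability/DDI risk** — *risky*: low absorption ∧ low stability ∧
  exactly one implicated CYP ∧ Pgp recognition; *safe*: the exact opposite
  profile. A single implicated enzyme means one inhibited pathway can block
  clearance, hence higher drug–drug-interaction risk.

**Overlays** paint per-molecule labels (experimental measurements, or a
property not used to build the map at all) onto nodes by strict majority of
the decided labels of each node's non-outlier molecules; ties give `0`.
Agreement between a predicted layer and an overlay is computed over nodes
where both sides are decided ($\pm 1$).

**Series dispersion** projects a congeneric series and reports how many
molecules land outside the applicability domain (OFF nodes or outliers —
these are not considered further) plus mean within- and between-group grid
distances, the quantitative signature of an ADME-cliff.

## What the synthetic generator emulates — and what it does not

The original map was trained on ~26,000 proprietary molecules; neither those
fingerprints nor the private descriptor matrices can ship. The generator
therefore produces:

* **archetype-clustered fingerprints** — $k$ binary prototypes kept at
  pairwise Hamming distance ≥ 8/20 by rejection sampling; each molecule
  copies a prototype, flips each coordinate with probability 0.05 and blanks
  it to `0` with probability 0.05. These rates are the package's standing
  study conditions: they give within-cluster diversity comparable to the
  abstention plus error rates a well-performing consensus model produces,
  while keeping clusters unambiguous;
* **class-conditional descriptor clouds** — two unit-variance Gaussians at a
  chosen mean separation with stratified exact class counts and optional
  label noise, shaped after the published dataset sizes where those are
  internally consistent;
* **a correlated naive property** — a mapped property's values flipped with
  probability $(1-r)/2$, so the match coefficient is $r$ (agreement
  $(1+r)/2$), emulating a property linked to, but not part of, the map
  (solubility being the canonical example).

Passing tests on these data show the machinery is correct: clusters of
similar ADME profiles become contiguous pure regions, linked properties
reappear as coherent overlays, and the combinatorial/threshold rules hold
exactly. They do *not* show that real descriptor matrices yield accurate
property models, nor that a real compound collection populates ~60% of a
50×50 grid — those facts depend on proprietary data and chemistry the
generator does not model (no structures, no descriptor physics, no
inter-property correlation beyond the archetypes).

## Numerical choices and problem sizes

* Stochastic suites run at fixed seeds with 3σ Monte-Carlo bands.
* Default test problem sizes, chosen once: archetype-recovery at 3
  archetypes × 1200 molecules on a 20×20 grid (10 epochs); shared layer
  tests at 600 molecules on 12×12; unit tests at 7×7–10×10. A 20×20 grid
  for 1200 molecules keeps the nodes-to-molecules ratio (1:3) close to the
  full-scale design (2500 nodes : 26k molecules ≈ 1:10) while leaving
  enough occupied nodes for region statistics.
* Quantization error is recorded per epoch and is non-increasing (≤1%
  tolerance for stochastic ordering).
* Serialization uses JSON with maximum-precision doubles; round trips are
  lossless to the last serialized digit, and all boundary comparisons carry
  the tolerances noted above.
* Degenerate inputs are rejected with classed conditions
  (`degenerate_training`, `no_training_data`, `malformed_fingerprint`,
  `layer_mismatch`, ...), so callers can distinguish failure modes
  programmatically.

## Known limitations

* The per-model hyperparameters of the original published models are not
  reproduced; members use library defaults. Accuracy claims are therefore
  made only on synthetic data.
* The PLS thresholds used for the OATP1B1 and brain-permeability variants
  are not published; `pls_threshold_classify()` requires them as explicit
  inputs.
* A few printed dataset rows are internally inconsistent (OCT2 class counts;
  the Pgp-inhibition and brain-permeability train/test splits). They are
  shipped as documentation in `adme_dataset_info()` and not reconciled.
* Toroidal or hexagonal grids and batch-SOM training are out of scope.
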