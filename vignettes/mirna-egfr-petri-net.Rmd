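---
title: "Modeling miRNA and anti-miRNA action in the EGFR pathway with hybrid Petri nets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling miRNA and anti-miRNA action in the EGFR pathway with hybrid Petri nets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

miRpetri represents a signaling network with embedded microRNA regulation
as a bipartite Petri net `PN = (P, T, F, W, m, D)`: places `P` are typed
molecular species (genes, transcripts, mature miRNAs, proteins, metabolite
compounds, complexes, and pseudo-objects standing for synthetic
inhibitors), each assigned to one of four compartments (nucleus,
cytoplasm, plasma membrane, extracellular space); transitions `T` are
typed reactions joined to places by weighted substrate, product, enzyme
and inhibitor arcs `F`/`W`; the marking `m` holds one concentration per
place in nM; and `D` is a per-class decay policy on top of the explicit
decay reactions.

Models are assembled from three motifs rather than reaction by reaction:

* **Gene expression**: one-step basal transcription in the nucleus
  (constitutive; no explicit transcription factors), transcript
  translocation to the cytoplasm, translation, and decay reactions for the
  cytoplasmic transcript and the protein. Gene places are clamped at their
  expression level, which is the experimental dial for knockdown,
  over-expression and receptor-level sweeps. The translocation step is
  modeled explicitly because translation is cytoplasmic while
  transcription is nuclear, and mRNA translocation carries its own, slower
  rate constant than generic translocation.
* **miRNA biogenesis**, lumped to two reactions: transcription combined
  with microprocessor (Drosha/DGCR8) cropping, then translocation of the
  mature species to the cytoplasm, plus decay. The canonical five-step
  pathway is deliberately not expanded; the biogenesis machinery itself
  (DICER1, TARBP2, RNASEN, DGCR8) appears in the fixture only as targets
  of a miRNA family, which the target table handles generically.
* **RISC binding**, lumped to one bimolecular reaction: mature miRNA and
  target transcript are consumed into an mRNA–miRNA complex with its own
  decay. Silencing is therefore stoichiometric sequestration; whether the
  physiological complex recycles the miRNA catalytically is left open, and
  the sequestration choice is the conservative one (an over-expressed
  miRNA is in such excess that recycling would only strengthen the same
  qualitative effects).

Anti-miRNA inhibitors (antagomir/LNA-style oligonucleotides) are
pseudo-object places whose concentration is clamped as an experimental
input; a binding reaction titrates the mature miRNA into an inert,
decaying complex. An inhibitor never touches the target mRNAs directly.

Functionally redundant families (MEK = MAP2K1/2, ERK, AKT, PKC, CAMK,
CDKN1, and the five-member miRNA family mir-TRDD) are modeled as single
*set* places; the member lists are metadata for census and reporting, not
expanded to paralogs, matching how such families are usually simulated as
units.

## The update rule

Each step evaluates all transitions against the step's starting marking
(synchronous update) and then applies decay:

1. **Flux.** The default rate law is mass-action-like:
   `f = k * prod(S^w) * prod(E^w) / (1 + 1.5 * sum(w * I))` over
   substrate, enzyme and inhibitor arcs, with 1.5 the inhibitory
   parameter. The flux is exactly zero whenever any substrate or enzyme is
   absent. Individual reactions may instead carry a fixed flux override;
   the packaged one-step firing example uses `f = 0.05` because the firing
   tables pin down the *update rule* precisely while the underlying rate
   law is not identifiable from them.
2. **Truncation.** If the total demand on a place exceeds its marking,
   every drawing reaction is scaled by the most constrained of its input
   places (`min(1, m/demand)` per place). The scaling is computed from the
   start-of-step marking only, so the update is order-independent and no
   concentration ever becomes negative. A transition with positive
   (possibly truncated) flux is *forward*; reversible transitions with
   zero forward flux fire *backward* under the mirrored, product-side
   condition; otherwise they are inactive.
3. **Enzyme arcs.** The printed firing example moves mass along the
   enzyme arc (the catalyst loses the flux amount), and
   `kinetic_config(consume_enzyme = TRUE)` reproduces that exactly. The
   package default is conventional non-consuming catalysis: consuming the
   catalyst couples every enzyme's abundance to its substrate's, which
   introduces a compensating feedback (less substrate leaves more enzyme)
   strong enough to suppress the propagation of miRNA repression through
   a kinase cascade — none of the perturbation phenomena the pipeline
   studies survive it. All perturbation stages therefore run with
   non-consuming catalysis; the convention is a single config switch.
4. **Decay.** Two timescales: proteins and compounds lose
   `0.09 * base` every step; ligand-receptor complexes lose `0.2 * base`
   every 10th step. The base is the start-of-step concentration for
   species that already existed and the post-fire concentration for
   species first created in the step — the only convention consistent
   with all rows of the printed firing tables (`0.95 − 0.09` for a
   pre-existing 1.0, but `0.05 − 0.05*0.09` for a freshly created
   product). Transcripts, mature miRNAs and binding complexes decay
   through their explicit decay reactions (class default `k = 0.02`)
   rather than the policy; the apparent conflict between the tabulated
   decay constant 0.02 and the 0.09/0.2 policy rates is resolved by
   keeping both, in those distinct roles.
5. **Clamps** are re-imposed at the end of every step.

## Kinetic parameters

Class defaults (per step, nM units): complex formation 0.55,
phosphorylation 0.35, dephosphorylation 0.01 (enzyme-driven variant 0.15),
transcription 0.5, translocation 0.8, mRNA translocation 0.5, explicit
decay reactions 0.02, inhibitory parameter 1.5, everything else 0.35.
miRNA transcription inherits the transcription constant, translation and
activation the generic 0.35, and both binding reactions (RISC and
anti-miRNA) the complex-formation constant 0.55, since each *is* a lumped
complex formation.

## Study conditions

The baseline conditions of every experiment: EGF clamped at 1 nM (a
constitutive saturating ligand input), ATP, ADP and PIP2 clamped at 1 nM,
protein-coding genes clamped at 0.1 nM, miRNA genes at 0 (miRNA
expression omitted unless a perturbation turns one on), and every other
species starting from 0 nM. The 0.1 nM gene level was chosen so that
steady-state transcripts settle near 10–20 copies per cell, inside the
reported range for typical mRNAs (most below 100 copies, i.e. below
1 nM); it also keeps total phosphorylation demand safely below the 1 nM
ATP clamp, so metabolite shortage does not distort the cascade, which is
the stated purpose of clamping those compounds.

Experimental defaults: individual miRNA over-expression at a gene level
of 100 nM (miRNA copy numbers range up to >10,000 copies ≈ 2,000 nM, and
the dose scans cover 0–10,000 nM); the anti-miRNA "saturating" dose is
100× the over-expressed miRNA gene level, consistent with the 10–100 nM
functional window the inhibitor dose series shows; heatmap entries with
|log2 ratio| < 0.001 are masked and rendered white; the activation
criterion for threshold scans is an absolute steady state above 0.001 nM
(≈ a tenth of a copy per cell — a conservative detectability floor fixed
before the scans; a fraction-of-maximum criterion is available as an
alternative). Simulations run up to 500 steps with an early stop once the
largest per-step change falls below 1e−9; the fast species (transcripts,
proteins, actives) equilibrate within ~100 steps, while slowly
accumulating inert complexes may still drift harmlessly at the budget.

## Screening statistics

The anti-miRNA screen applies each inhibitor alone, against a control in
which its cognate miRNA is over-expressed alone. Significance of an
inhibitor's effect is a *paired* two-sided t-test across the
concentration changes of all matched model components (the two states
share one component set, which makes the paired variant the natural one;
Welch's unpaired test is available behind a flag). Identical states give
p = 1 by convention. Ranking is ascending by raw p-value with an alpha of
0.05 and lexicographic tie-breaking; a Benjamini–Hochberg column is
reported alongside but does not drive the ranking, matching the original
raw-p ranking practice. Concentrations enter the test untransformed.

## What the generators emulate — and what they do not

The packaged fixture reproduces, at desk scale, every miRNA–target
relation the analyses rely on (mir-192 with 6 targets, mir-181c with 2,
mir-489 with 4, mir-34a with 14, and the mir-TRDD family with its 4
shared biogenesis-machinery targets) around an
EGF+EGFR → PI3K → PIP3 → PDPK1 → AKT cascade with a parallel MEK/ERK
branch and PTEN opposing PIP3. The AKT substrate set closing the cascade
(BAD plus TP53, MDM2, CDKN1) is a documented choice: the exemplar
substrate from the motif description plus the named tumor-suppressor
readouts.

The random-network generator emulates the topology class behind the
screen statistics — a linear cascade behind a ligand-receptor pair, leaf
substrates of the terminal kinase, and miRNA target sets drawn from a
truncated geometric degree distribution (most miRNAs few targets, a tail
with many), with a configurable fraction of miRNAs aimed at key nodes.

Passing the property suite on these generators shows that the *pipeline*
reproduces the qualitative phenomena (repression direction and masking,
dose monotonicity, threshold shifts, inhibitor reversal, and the
target-count/significance association) under controlled kinetics. It
does not show quantitative agreement with the published full-scale
network: that model (901 entities, 1241 reactions, 241 miRNAs), its
curated supplementary target lists and its exact rate-law constants are
not redistributable here, so its printed census, its specific threshold
values (10 pM vs 0.001 pM) and its exact screen p-values (for example
1.90e−06 for the top inhibitor) are out of reach by design. The census
and counting code paths accept a user-supplied SBML file and target
table, and are verified on round-trips and emulated tables instead.

## Known limitations

Only EGFR (ErbB1) is modeled as an isolated receptor — no ErbB2–4
dimerization; transcription is basal with no specific transcription
factors; phosphosites are not resolved; combination (multi-inhibitor)
therapy is out of scope. The discrete-time engine is neither an ODE
integrator nor a stochastic simulator: step size is implicit in the rate
constants, and results are exactly reproducible rather than distributed.

## Problem sizes

The packaged fixture builds to 160 places and 222 transitions. The
property studies run 20 seeded random networks of 8 genes, 5 miRNAs and
cascade depth 3; each steady state is one deterministic run of at most
500 steps. These sizes were chosen so the whole analysis reruns on a
laptop in minutes while still exercising every code path of the full
pipeline.
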