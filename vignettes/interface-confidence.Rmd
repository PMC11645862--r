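---
title: "Scoring predicted protein complexes and assembling composite models with foldscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring predicted protein complexes and assembling composite models with foldscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldscreen)
```

## The problem

Multimer structure predictors (AlphaFold-Multimer and its relatives) make it
practical to screen one bait protein against hundreds of candidate partners
*in silico* and triage the predictions by interface confidence. foldscreen
implements the analysis side of such a screen: it consumes predicted
coordinate models together with their confidence annotations — a per-residue
pLDDT vector (0–100) and a pairwise predicted-aligned-error (PAE) matrix in
Å — and turns them into per-pair interface metrics, confidence calls, and a
ranked candidate table. It also implements the downstream structural
composition step used to interpret screen hits: anchored rigid-body
superposition of binary models onto a larger reference complex, steric clash
assessment, and named-atom distance measurements.

Everything is testable offline: a deterministic generator builds synthetic
complexes with planted interfaces, controllable confidence quality, and
model ensembles with controllable reproducibility.

## Confident inter-chain contacts

The unit of analysis is the *confident inter-chain contact*: an inter-chain
residue pair whose minimum heavy-atom distance is strictly below 5 Å, whose
two residues both have pLDDT strictly above 50, and whose inter-residue PAE
is strictly below 15 Å. All interface statistics (contact count, average
interface pLDDT, average interface PAE) are computed over exactly these
pairs. The three thresholds live in `contact_params()` and every comparison
is strict, so boundary values (a pair at exactly 5 Å, a residue at pLDDT
exactly 50) are excluded.

Two details of the rule are not fully determined by its usual statement, and
both are exposed as parameters rather than guessed:

* **Atom rule.** "Distance" between residues is taken as the minimum over
  all heavy-atom pairs (`atom_rule = "any_heavy"`, the default and the most
  common reading); a β-carbon distance (`"cbeta"`, α-carbon for glycine) is
  selectable.
* **PAE directionality.** PAE(i, j) is the expected error of residue j when
  the prediction is aligned on residue i, and is not symmetric. The default
  combines the two directions permissively as `min(PAE_ij, PAE_ji)`;
  `"mean"` and `"both_must_pass"` are available, and the rule used is
  recorded in every `ContactSet`.

Similarly, the average interface pLDDT is defined over contacts (each
contact contributes the mean of its two residues; a residue in several
contacts counts once per contact), with `plddt_average = "unique_residues"`
as the alternative, since published descriptions do not pin this down.

## Interface confidence metrics

For an ensemble of M independently predicted models of the same pair
(M = 5 by default, matching the usual number of multimer prediction models),
`score_pair()` reports:

* **n_contacts, avg_plddt, avg_pae** — the single-model statistics of the
  *representative* model. The representative is chosen deterministically as
  the model with the highest own average interface pLDDT (ties → lowest
  model position); some deterministic rule is needed because "a
  representative model" is otherwise underdetermined.
* **avg_models** — the ensemble agreement score: over the union U of
  confident contacts seen in any model, the mean fraction of models
  containing each contact,
  $\mathrm{avg\_models} = \frac{1}{|U|} \sum_{c \in U} n_c / M$.
  It ranges from 0 (defined value for an empty union) to 1 (every contact
  in every model). Note an intrinsic property of this union-based
  statistic: a contact that appears in *no* model leaves the union, so if
  contacts appear independently with probability p per model the expected
  score is $p / (1 - (1-p)^M)$, not p — for M = 5 the distortion is
  negligible at p ≥ 0.9 but reaches ≈ +0.10 at p = 0.2. The calibration
  simulations in the test suite measure exactly this.
* **pdockq** — the published pDockQ interface-accuracy estimate,
  $pDockQ(x) = \frac{0.724}{1 + e^{-0.052(x - 152.611)}} + 0.018$ with
  $x = \overline{\mathrm{pLDDT}}_{\mathrm{interface}} \cdot
  \ln(\mathrm{contacts})$, computed with pDockQ's *own* contact definition
  (β-carbon pairs within 8 Å, α-carbon for glycine; unique interface
  residues averaged) — deliberately independent of the 5 Å confident-contact
  rule above, mirroring how the score was designed. Zero contacts give
  exactly 0.
* **classifier** — an optional external scorer hook. Any function mapping
  (metrics, models, confidences) to [0, 1] can be registered — e.g. a
  wrapper around a trained interaction classifier that combines interface
  metrics with orthogonal biological data. None ships with the package; the
  hook only validates and records the score.

`confidence_calls()` applies the published decision thresholds — average
interface pLDDT > 70, avg_models > 0.5, pDockQ > 0.23, classifier > 0.5 —
again all strict.

## Screens and ranking

`run_screen()` maps `score_pair()` over a manifest of candidate pairs and
ranks by one of the four metrics. Ranking is made fully deterministic: ties
break by `pair_id` ascending. A pair whose interface is empty has undefined
(`NA`) average pLDDT/PAE; for ranking purposes this is treated as "no
measurable interface" and sorts below every number rather than erroring,
because a large screen legitimately contains honest negatives. Ranking by
the classifier key, by contrast, errors if any pair lacks a score, since
that indicates the classifier was never run. Per-entry failures (unreadable
files, mismatched confidence vectors) are logged with their reason and
excluded from the ranking rather than aborting a many-hour screen.

The candidate roster of a screen is always user-supplied via the manifest;
the package does not fabricate candidate lists.

## Composite model assembly

Hits from a screen are often interpreted by *composite modelling*: a binary
predicted model is superposed onto an experimental complex via the shared
subunit, then a further experimental structure is superposed onto the placed
prediction via another shared subunit, and so on. `assemble()` implements
this as an ordered sequence of anchored superpositions:

* `superpose()` is a least-squares rigid-body (Kabsch) fit via SVD. When
  the raw orthogonal optimum is a reflection, the smallest singular
  component's sign is flipped, so the returned rotation always has
  det = +1 (tolerance 1e-9) — rigid bodies only, even for mirror-image
  inputs. Inputs with fewer than 3 points or collinear geometry are
  rejected (the rotation would be underdetermined); collinearity is
  detected as a vanishing second singular value of the centred coordinates
  (threshold 1e-8).
* `align_via_chain()` fits on anchor atoms only — α-carbons of residues
  shared by residue number between the two copies of the anchor chain
  (explicit residue pairings and a 4-atom backbone rule are available) —
  and applies the transform to the whole mobile model, reporting anchor
  RMSD and the number of matched atoms.
* `assemble()` chains placements (each step's reference is the base or any
  placed component), records every transform for provenance, and
  disambiguates colliding chain ids by suffixing.

`clash_census()` then judges physical plausibility. The default "major
clash" rule flags inter-component heavy-atom pairs closer than the sum of
their van der Waals radii minus 1.5 Å (Bondi radii, shipped as `VDW_RADII`);
a fixed 2 Å rule is selectable. "Major" is inherently a convention, which is
why the rule is explicit, configurable, and recorded in the report. Anchor
chains are skipped (a placed component's anchor chain is by construction
superposed on its reference counterpart — those overlaps are the method, not
clashes), as are explicitly excluded component pairs. The census runs on a
spatial grid (cell lists at the maximum clash threshold) and is tested to
agree exactly with the naive all-pairs census. Finally,
`measure_distance()` resolves two named atoms in the assembled frame and
returns their separation — the kind of measurement used to ask whether,
say, a DNA strand end emerging from one component aligns with a strand in
another. Such distances on composite models are interpretive, not refined:
the assembly performs no flexible fitting, energy minimisation, or density
docking.

## The synthetic-data generator

All tests run on generated fixtures, so it matters what the generator does
and does not emulate.

`make_interface_pair()` builds a two-chain (optionally k-chain) model on an
idealised coarse trace: residues 7 Å apart along x, one CA and (except
glycine) one CB per residue, chains separated by 25 Å in y. Planted contact
pairs are created by dropping the partner residue to a target distance drawn
from 3.5–4.5 Å; the construction guarantees that *exactly* the planted pairs
are within the 5 Å cutoff and every other inter-chain pair clears it by at
least 2 Å. An `"extended"` (near-straight, z-jittered) and a `"helical"`
(sinusoidally coiled) trace style are available; both preserve the planted
guarantees. The geometry is deliberately not stereochemically valid —
only inter-residue distances and confidence values matter to the analyses
under test.

`make_confidence()` draws pLDDT and PAE from interface vs background normal
distributions, clipped to legal ranges and rounded to 2 decimals (the
precision of real prediction-score files; this also makes the two
confidence-JSON dialects exactly equivalent through the B-factor column).
Defaults — interface pLDDT 90 ± 4 and PAE 4 ± 1.5 Å against background
65 ± 8 and 24 ± 4 Å — emulate a confidently predicted interface on an
otherwise moderately confident model. PAE is drawn independently in each
direction, so the matrices are asymmetric like real ones.

`make_ensemble()` imposes reproducibility p through the confidence
annotations: every true contact is geometrically present in all M models,
but is *rendered confident* in each model independently with probability p.
A non-reproduced contact receives background PAE left-truncated above the
15 Å ceiling, so "absent" is definitive rather than subject to lucky
background draws — without this, the p = 0 endpoint would not be exactly 0.
An optional Poisson decoy rate plants per-model-only spurious contacts.

`make_screen()` combines these into a full screen: by default 100
non-interacting decoys plus 5 strong true interactors (40+40-residue
chains; true pairs: 20 planted contacts, confident annotations, p = 0.9;
decoys: no planted interface, 0.5 spurious contacts per model with
deliberately mediocre confidence, pLDDT ≈ 60 and PAE ≈ 11 Å — values that
pass the contact thresholds but score poorly). Chain lengths and decoy
parameters are synthetic-scale choices: real screens involve full-length
proteins and far messier failure modes (disorder, partial interfaces,
homology to the bait) that the generator does not emulate. Passing the
planted-truth recovery tests therefore demonstrates that the *pipeline*
ranks what it should rank, not that the confidence thresholds themselves are
well calibrated on real predictions — those thresholds are taken from the
literature, not re-derived.

All generators take mandatory seeds and are byte-deterministic per seed;
ensembles draw from a single stream seeded by the ensemble spec.

## Numerical and design choices

* Residue indexing into the PAE matrix is 0-based over residues
  concatenated in file chain order, with half-open per-chain ranges; the
  partition property (disjoint, contiguous, covering) is tested.
* Contacts are stored canonically (residue_a before residue_b by chain id,
  then residue number), so a contact has one representation and all metrics
  are invariant under swapping chain labels.
* Hydrogens are dropped at parse time ("heavy atom" = element other than
  H/D); alternate conformers are reduced to the highest-occupancy one, ties
  resolved toward altloc A.
* Both common confidence-JSON dialects are read (a combined scores file
  with pLDDT + PAE, and a PAE-only file with pLDDT taken from B-factors),
  since screening pipelines encounter both; equivalence of the two routes
  is tested.
* Empty contact sets yield `n_contacts = 0` with undefined (`NA`) averages,
  and an empty contact union yields avg_models = 0, its defined worst
  value.

## Problem sizes used by the test suite

The shipped tests and the acceptance script run entirely on generated data
at sizes chosen to exercise the algorithms while keeping a full run cheap:
contact-extraction cross-checks on 50 fixtures of 30–120 residues per
chain, ensemble calibration on 200-contact pairs over 100 (tests) or 30
(script) seeds, screen recovery on the default 105-pair screen over 100
(tests) or 25 (script) seeds, superposition recovery on 50-atom sets over
100 random motions, and clash-census equivalence on ~20-residue composites.

## Known limitations

* The generator's idealised traces cannot exercise atom-rule subtleties of
  real side chains (e.g. `any_heavy` vs `cbeta` differ little on CA/CB-only
  residues).
* pDockQ coefficients are the published two-chain calibration; for k > 2
  chains the implementation pools all inter-chain pairs, which is a
  convention, not a recalibration.
* The external-classifier hook validates and records scores but ships no
  classifier.
* Composite assembly treats components as rigid; clash counts near anchor
  regions depend on the (configurable, recorded) clash rule.
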