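---
title: "screenfunnel: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{screenfunnel: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models and procedures
it implements, the parameters that matter, the numerical choices made
where the design was genuinely open, and what the synthetic-data tests
do and do not demonstrate about real campaigns.

## The problem

An ultra-large docking screen against a GPCR binding site produces a
score for every library compound (lower is better; a sum of
electrostatic, van der Waals and ligand-desolvation terms from the
docking engine). The scores themselves are ingested, never recomputed
here. Everything downstream of the score list is this package's scope:
selecting a chemically diverse, novel, non-interfering candidate set;
calibrating the docking setup retrospectively with decoys; judging
predicted poses against experimental structures; expanding confirmed
hits into analog series; and analyzing the pharmacology data that come
back.

## The triage funnel

`run_funnel()` applies five stages in a fixed order:

1. **Top-N extraction.** The best `top_n_scores` records by
   `score_total` (default 300,000, matching full-campaign practice).
   Ties are broken by lexicographic molecule id so runs are exactly
   reproducible.
2. **Interference filter.** A molecule is removed iff it matches at
   least one substructure pattern. A small versioned subset of
   well-known PAINS-family motifs ships with the package
   (`pains_patterns()`); any SMARTS table with columns `id`, `smarts`
   can be substituted, since interference lists are campaign-specific.
   Removals are logged with the matched pattern, never silent.
3. **Novelty filter.** A molecule is excluded iff its maximum Tanimoto
   similarity to any known active is *strictly greater* than 0.5; the
   lead-like property comparisons elsewhere are *inclusive* (≤). The
   strict/inclusive distinction follows the inequalities as
   conventionally stated, and matters at the boundary: a candidate at
   Tc = 0.49 to its nearest known ligand survives, one at 0.51 does
   not. Retained molecules carry their max Tc as an annotation.
4. **Leader clustering.** Molecules are processed best score first
   (ties by id). Each joins the first existing cluster whose
   representative is > 0.5 similar to it, else founds a new cluster.
   Two invariants follow and are asserted in tests: every member is
   > cutoff similar to its representative, and representatives are
   pairwise ≤ cutoff similar. Because leaders are seen in score order,
   each representative automatically carries the best score of its
   cluster. Single-pass leader clustering was chosen over complete
   Butina-style sphere exclusion because it is the simplest rule
   consistent with score-aware representative selection; the cluster
   partition is order-independent given the deterministic processing
   order.
5. **Shortlist.** The best `shortlist_n` (default 1500) representatives,
   annotated with cluster size and max Tc to known actives. Visual
   inspection of poses — the manual step that follows in practice — is
   out of computational scope; the annotations and a free-text `flags`
   column are the hook for it.

Per-stage survivor counts are returned as an attribute and are
monotonically non-increasing by construction.

## Properties and the lead-like filter

`compute_properties()` returns molecular weight, cLogP, H-bond donors
and acceptors, rotatable bonds (strict SMARTS definition: non-ring
single bonds between non-terminal atoms, excluding triple-bond
neighbors) and net formal charge. cLogP is OpenBabel's
atomic-contribution logP — a stated, reproducible method; any cLogP
scheme differs from any other by a few tenths, so the 3.5 threshold
should be read as a convention, not a physical constant. The lead-like
filter keeps molecules with cLogP ≤ 3.5 **and** MW ≤ 350 Da, boundaries
inclusive.

## Fingerprints

Morgan (circular, ECFP-style) fingerprints are computed natively over
the molecular graph: initial atom codes hash (atomic number, heavy
degree, total bond order, ring membership); two rounds of neighborhood
hashing with neighbor lists sorted by (bond order, neighbor code) make
the result independent of atom input order; all features fold into 2048
bits. Radius 2 is the ECFP4 equivalent; 2048 bits is the community
default. One subtlety: the parser's kekule assignment of aromatic rings
depends on the written atom order, so SMILES are canonicalized before
fingerprinting — otherwise two spellings of the same molecule could
hash differently. The test suite cross-checks similarity *orderings*
against an independent OpenBabel ECFP4 route; absolute Tc values differ
across fingerprint implementations, which is why the 0.5 cutoffs are
conventions tied to the fingerprint stated here.

## Decoy sets and enrichment

Three decoy modes are generated from a user-supplied pool, seeded and
sampled without replacement, with actives excluded by canonical SMILES:

- **matched**: all properties within bands of an active — MW ± 25 Da,
  cLogP ± 1.0, HBD/HBA/rotatable bonds ± 1, net charge exact. The bands
  are this package's defaults (configurable via `decoy_bands()`);
  published campaigns rarely state theirs.
- **perturbed**: the continuous bands shifted outward by one band width
  (band < |Δ| ≤ 2·band for MW and cLogP; count bands widened by one;
  charge unconstrained). "Property-perturbed" has no standard
  definition; this band-ring construction is this package's
  interpretation and is flagged as such.
- **extrema**: drawn from the pool's property tails (top/bottom deciles
  of MW and cLogP), again an explicit interpretation of an informally
  named practice.

If the pool cannot satisfy the bands, a partial set is returned with a
warning listing the per-active shortfall — never silent padding.

`enrichment()` scores a calibration run. With lower-is-better scores
(a flag negates higher-is-better inputs) and ties broken
pessimistically for actives:

- **EF1%** = (fraction of actives in the top 1% of the pooled
  ranking) / 0.01. Bounded by 100; 0 if no active makes the top 1%.
- **adjusted logAUC**: the ROC curve is integrated against log10(FPR)
  from λ = 0.001 to 1, normalized by log10(1/λ), ×100, and the analytic
  random-ranking area 100·(1−λ)/(ln 10 · log10(1/λ)) ≈ 14.46 is
  subtracted. A random ranking gives 0 in expectation, a perfect one
  85.54. Both limits and the null centring are asserted by simulation
  in the tests. λ = 0.1% is the docking community's convention for
  early-recognition emphasis.

Both metrics are rank-based, hence invariant to strictly monotone score
transforms.

## Pose evaluation

- **Superposition** is least-squares (Kabsch, via SVD with determinant
  correction) on Cα atoms matched across structures by (chain, residue
  number) — the two receptor structures compared in a campaign share
  author numbering, so sequence alignment is unnecessary and is not
  attempted. The default selection is all matched Cα (whole-receptor
  alignment); a residue subset can restrict the fit to a binding site.
  The fitted transform is applied to the whole model including the
  ligand, so ligand RMSD is measured in the frame established by the
  receptor alignment, as is standard.
- **Ligand RMSD** assumes the same molecule with the same atom order in
  both poses and applies no fitting of its own. With
  `symmetry_aware = TRUE` (the default) the RMSD is minimized over all
  automorphisms of the bond graph (computed by VF2 with element
  colors), so chemically indistinguishable flips — a para-disubstituted
  ring turned 180° — are not penalized; the naive mode is retained
  because the automorphism-enumeration oracle in the tests needs it.
  Bonds are taken from input or inferred at ≤ 1.85 Å between heavy
  atoms.
- **Contacts**: a receptor heavy atom is in contact iff its minimum
  distance to any ligand heavy atom is ≤ 4 Å (hydrogens excluded on
  both sides). **Contact recovery** LC = 100·|model ∩ ref|/|ref| is
  directional — the percentage of *experimental* contacts captured by
  the model — because that is the natural reading of "captured
  contacts"; a symmetric Jaccard variant sits behind a flag for
  sensitivity analysis.
- **Polar contacts** use a 3.5 Å donor–acceptor distance and, when
  hydrogen positions exist, a D–H···A angle ≥ 120°. These are common
  hydrogen-bond conventions; structures solved at modest resolution
  rarely justify stricter geometry. In heavy-atom-only mode N and O on
  both sides are treated as donor/acceptor capable and the angle is
  reported as `NA`.

All metrics are invariant under a common rigid transform of both
structures (tested), and `contact_set` is checked against an O(n²)
all-pairs oracle on every test structure.

## Analog patterns

`build_pattern()` turns a hit structure plus a set of variable atom
indices into a SMARTS pattern. Fixed atoms keep element, aromaticity
and ring topology (the SMILES itself serves as the SMARTS backbone).
Variable sites are generalized at two levels: a *terminal* variable
group (one bond to the fixed part, written contiguously in the input
SMILES) collapses to a single `[a;R]` any-aromatic-ring attachment when
the group is aromatic (`*` when aliphatic) — so a pattern built from a
thiophene-bearing hit also matches phenyl or furan analogs of any ring
size; non-terminal variable atoms are generalized in place (`a` / `*`),
preserving topology. Every constructed pattern is validated to match
its own core, and `substructure_search()` re-verifies embeddings, so
false positives cannot pass silently. The contiguity requirement for
collapsed groups is a documented restriction of the text-surgery
approach; writing the variable group as a branch or suffix (the natural
way to write a terminal ring) always satisfies it.

## Pharmacological analysis

Signals are normalized to buffer (0%) and the reference agonist's
maximal response (100%); responses above 100% are never clipped, since
full agonists more efficacious than the reference are real and
expected.

The two-addition primary screen applies the test compound first
(agonist mode) and an EC80 concentration of the reference agonist
second (antagonist mode). Classification: agonist iff step-1 response
≥ 25%; otherwise antagonist iff the step-2 response falls below 50% of
the expected EC80 response (80% of the reference maximum by default);
otherwise inactive. The 25% threshold is the primary-hit convention
this pipeline targets; the 50% suppression threshold is this package's
default where practice says only "absent or significantly decreased",
and both are configurable. The desensitization rule — a compound that
activated the receptor in step 1 is an agonist regardless of its
blunted step-2 response — is asserted property-style over randomized
plates.

Concentration–response curves are fitted on log10 concentration with
the variable-slope four-parameter logistic. Replicates are averaged per
concentration before fitting (SEM-weighted fitting changes little at
triplicate scale and complicates the noiseless recovery contract).
Fitting uses Levenberg–Marquardt with five starts: one data-driven
(bottom/top from the response range, logEC50 at the half-maximal
concentration, hill 1) and four seeded jitters; the best
residual-sum-of-squares fit wins. Non-convergence returns the
best-found parameters flagged `converged = FALSE` — never an exception,
so screening loops over hundreds of curves cannot die on one bad well.
Noiseless curves are recovered to 1e-6 relative error across EC50 ∈
[10 nM, 10 µM] and hill ∈ [0.5, 2]; with 5% response noise at 8
concentrations the median recovered EC50 stays within 1.3-fold of truth
over 100 replicates (both asserted in tests).

`kp_brain()` applies the ×3 plasma-dilution and ×4 brain-homogenate
corrections and reports both the per-animal mean Kp and the
ratio-of-group-means. The two differ (Jensen's inequality) and
published tables rarely print per-animal concentrations, so both modes
are exposed; scalar inputs give the ratio of means.

## The synthetic-data generators

The generators exist to exercise the computation, not to emulate real
structure–activity relationships or docking physics.

- `make_screen()` assembles molecules from a ~30-fragment grammar of
  chain-appendable SMILES, so every generated structure parses and
  fingerprints/substructures are meaningful. Planted actives share a
  thiophene-carboxamide scaffold kept out of the decoy fragment pool.
  Scores are standard normal with actives shifted by
  `-score_advantage`; the defaults (10,000 molecules, 100 actives,
  2 SD advantage) are the package's desk-scale rendition of a large
  screen with a small high-scoring active fraction — big enough for
  stable enrichment statistics, small enough that the full funnel runs
  in seconds to minutes. A heavier-tailed t(5) score model sits behind
  a flag.
- `make_toy_complex()` builds a pocket with an exact number of atoms
  inside the 4 Å contact shell and a rigidly perturbed ligand copy, so
  RMSD and contact truths follow from the construction rather than from
  the code under test.
- `make_pharm_data()` draws plate and CRC signals from the 4PL model
  plus normal noise, anchored to buffer/reference wells, with the
  two-addition design encoded (desensitized agonists, suppressing
  antagonists, intact EC80 response for inactives).
  `synthetic_primary_screen()` is a labelled synthetic stand-in for a
  68-compound primary screen: 14 planted above-threshold agonists of
  which 5 are potent (EC50 0.16–3.6 µM, Emax ≥ 70%) and 9 stay below
  the 50% Emax follow-up criterion.

Truth labels are returned separately and never written into the tables
the pipeline consumes (schema-tested). What passing these tests shows:
the funnel enriches planted signal, metrics hit their closed forms, and
fitting recovers known parameters under the stated noise. What they do
not show: behavior under correlated assay noise, activity cliffs,
score–property confounding, or real chemotype similarity structure —
all properties of real campaigns that the generators deliberately do
not model.

## Problem sizes

The default test run uses libraries of 120–2000 molecules, 20-molecule
clustering fixtures against brute-force oracles, 1000-resample
enrichment nulls, 100 noisy CRC replicates and a 1000-trial
zero-signal shortlist check; it completes in about two minutes on one
CPU. `scripts/acceptance.R` runs the funnel at 10,000 molecules with a
1000-compound triage depth and 150-representative shortlist, in about a
minute.

## Known limitations

- Dock scores are inputs; no rescoring, strain or solvation correction
  is attempted.
- The bundled interference list is a small representative subset;
  production campaigns should supply their full pattern set.
- Ligand RMSD requires identical atom ordering in the two poses;
  cross-format atom matching (beyond bond-graph automorphisms) is not
  implemented.
- `build_pattern()` operates on the written SMILES; collapsed variable
  groups must be contiguous in it.
- Net formal charge is parsed from bracket atoms of the canonical
  SMILES; exotic charge states outside bracket notation are not
  handled.
- Kp analysis is the single-time-point total-concentration ratio; no
  compartmental modeling.
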