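---
title: "Predicting mature polyketides from gene clusters: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting mature polyketides from gene clusters: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pksline)
```

This vignette is the package's account of the science it implements: the
models and procedures, their assumptions, the tunable parameters, and the
design decisions taken where the underlying methodology left choices open.

## The biosynthetic model

A modular type I cis-AT PKS is treated as an ordered list of genes, each a
protein carrying an ordered list of modules, each module an ordered list of
catalytic domains (KS, AT, KR, DH, ER, ACP, TE). All residue coordinates
are 0-based half-open; GenBank input (1-based inclusive) is converted at
the parser boundary. Domain detection itself (HMM profile search) is *not*
re-implemented: the parsers consume pre-annotated inputs (declarative BGC
JSON, or GenBank regions with antiSMASH-style domain features), mirroring
how such annotations are produced by standard genome-mining tools.
Minus-strand genes rely on their annotated translation and are never
re-translated, avoiding codon-table ambiguity. Unknown tailoring-enzyme
tags are carried through and ignored by the modification engine with a
warning rather than an error, so that a cluster annotated with an enzyme
family we have no rule for still yields its unmodified candidates.

## Substrate specificity

The specificity of an AT domain is read from 24 active-site pocket
residues. Extraction aligns each AT sequence globally
(Needleman–Wunsch, BLOSUM62, affine gaps open 10 / extend 1, via
Biostrings) against a single packaged reference with 24 marked columns and
reads off the aligned query residues; reference columns deleted in the
query yield `-`. A pairwise global alignment was chosen over a progressive
multiple alignment because it is deterministic, dependency-free and
per-sequence; the aligner sits behind one function so an external MSA can
be substituted. The packaged reference is a *constructed stand-in*
(`inst/extdata/at_reference_synthetic.fasta`): the canonical published
reference profile and column identities belong to prior work and are not
redistributable here, so the packaged file plants the two hallmark
active-site motifs (GHSQG, AFHS) in a synthetic background and marks 24
pocket-like columns; any user-supplied reference FASTA + column file is
accepted in its place.

Signatures are one-hot encoded: each of 24 positions maps to a
20-dimensional indicator block (480 bits); gaps and the ambiguity code X
encode as all-zero blocks, preserving fixed dimensionality. The
classifier is an extremely-randomized-trees ensemble with 150 trees and
maximum depth 10 (the defaults of the method this package follows),
implemented via `ranger` with `splitrule = "extratrees"`, a single random
split per feature, all features considered at each node, and no
bootstrap — the configuration that corresponds to the original
extra-trees algorithm. Ties in the arg-max label are broken
lexicographically for determinism. Generalisation is measured in
Hamming-distance bins: `Bk+` holds test points at least `k` substitutions
from every training point, so accuracy in high-`k` bins probes exactly
the regime where nearest-neighbour methods fail. Cross-validation uses
five random near-equal folds, repeated over five shuffles, with the
confusion matrix averaged over shuffles and rounded for display. A
self-training hook (`refine_specificity_model`) can fold in confidently
predicted unlabeled signatures, but it is off by default: the procedure
for refining on large unlabeled domain collections is not specified
precisely enough to fix its behaviour, so the hook is provided as an
opt-in experiment only.

## Substrate maturation

Each extension module contributes a two-carbon unit whose β-oxidation
state follows the standard PKS reduction ladder: no active KR → ketone;
KR → hydroxyl; KR + DH → enoyl (water eliminated, α–β olefin);
KR + DH + ER → saturated. The ladder is exactly the chemistry the
KR/DH/ER domains catalyse, and the formula arithmetic is enforced by
tests on every monomer in the library: hydroxyl = ketone + H₂, enoyl =
hydroxyl − H₂O, saturated = enoyl + H₂. Inconsistent domain sets (DH
without KR, ER without DH) fall back to the deepest consistent state with
a warning rather than failing, since annotation noise is common.
Inactive domains are detected by the presence/absence of packaged
catalytic motifs (`inst/extdata/catalytic_motifs.json`: the KR Rossmann
GxGxxG pattern, the DH HxxxGxxxxP active site, and so on). This is a
transparent, editable heuristic: no published algorithm for inactivity
detection is available, so the rule is data, not code, and flags already
set inactive in the input are never overridden. Stereochemistry is not
modelled anywhere in the package; structures are compared by constitution.

Starter units are genuinely unpredictable from sequence. When the first
assembly module lacks an AT, its contribution is skipped and the spectral
stage should run in variable mode, which absorbs the starter's mass as
the global shift Δ. This is the default behaviour of `run_pipeline`'s
`search_mode = "auto"`.

## Assembly order

Docking regions are taken as the first 100 N-terminal residues (head) and
the last 50 C-terminal residues (tail) of each protein. The source
methodology pairs "head (N-terminal)" with an extraction phrase that
reads C-terminus-first; we resolved this internal contradiction in favour
of the structural description (the N-terminal linker contributes three
helical segments, hence the longer region), and both lengths are
arguments throughout. The head of the pathway's first gene and the tail
of its last take no part in docking; since no detection rule is given for
those anchors, we anchor the end at a TE-containing gene and the start at
a gene whose first module lacks a KS, and apply no exclusion when no
anchor is found.

Pair similarity is the sum of head–head and tail–tail Smith–Waterman
bit-scores (BLOSUM62, gap open 11 / extend 1, bits
`(λS − ln K)/ln 2` with the standard gapped-BLOSUM62 constants λ = 0.267,
K = 0.041). For a query pair, the `n = 3` most similar interacting and
non-interacting training pairs provide the features of a logistic
interaction model. The stated feature count (2n) and the described
construction (head and tail scores per neighbour, 4n) disagree; the
package defaults to the richer `per_score` mode (4n = 12 features) and
offers `summed` mode (2n) for literal fidelity. Training balances the
classes by seeded subsampling of the negatives and computes each training
pair's features against the training set *excluding itself*. The
interaction score of an ordered gene pair is the model's probability, so
pathway scores are interpretable and ties are rare.

A candidate order's score sums its consecutive-pair scores, with
multiplicative rewards `W_forward`/`W_backward` (default 1) for pairs
that preserve or invert genomic adjacency — with unit weights this is
algebraically the plain sum, a property tested on random instances. Up
to 9 genes (362,880 permutations) ranking is exhaustive with
lexicographic tie-breaks; beyond that a best-first branch-and-bound with
an admissible per-slot bound (sum of per-gene maximal incoming scores)
returns the top `cap` orders, and its agreement with exhaustive
enumeration is itself a test. Nine genes keeps exhaustive ranking under a
second; the bound exists for the rare larger clusters.

## Core assembly and tailoring modifications

Units are chained by Claisen-type condensation: the α-carbon of each
downstream unit bonds to the carbonyl carbon of the upstream chain.
Release always produces the linear free acid; when a TE is present, one
macrolactone is additionally produced per eligible hydroxyl — a free,
singly-bonded oxygen whose ester ring would have at least 5 atoms. The
ring-size floor is a chemical-plausibility cutoff and is an argument;
macrolactone formulas are the linear formula − H₂O by construction.

Tailoring chemistry lives entirely in data:
`inst/extdata/modification_rules.json` holds 78 rules, each a SMILES
substructure motif plus an ordered graph-edit script (add/remove atom,
add/remove/reorder bond, attach a group) addressed by motif atom indices,
with optional minimum implicit-hydrogen constraints to distinguish, e.g.,
free hydroxyls from ester oxygens. The database was authored from
standard polyketide tailoring chemistry — glycosylations over thirteen
constitutionally distinct sugars, O/N/C-methylations, acylations,
phosphoryl/sulfo transfer, P450 oxygenations, redox steps, halogenations,
amine chemistry, eliminations and ring-forming steps. Every rule is
validated at load by applying its own edit script to its own motif and
requiring a chemically valid product; an invalid rule fails the whole
load, listing offenders. Motif search is subgraph isomorphism (VF2 with
element vertex-colours and bond-order edge-colours) with automorphic
re-mappings collapsed to one representative per matched atom set and a
deterministic match order.

Enumeration semantics follow the closed form `k × Π(m_i + 1)`: each
enzyme either skips or fires once at one of its `m_i` motif sites counted
on the *core* (the only reading consistent with that product formula —
independent per-site application would give `2^m`). Multi-copy enzymes
can be expressed as repeated database entries. Combinations whose edits
collide on shared atoms can be chemically impossible; these are still
counted in the raw total (the closed form is about the choice space) but
skipped in the materialised stream with a notice, and both the raw and
the canonically deduplicated counts are reported. Whether candidate sets
should be deduplicated before spectral search is left open upstream, so
both numbers are available. The stream is generated in deterministic
mixed-radix order and truncated at a configurable cap (default 10⁶).

## Spectral matching and FDR

Fragmentation removes one acyclic single bond, or any two bonds of one
ring, per round, for up to two rounds; open valences are saturated with
hydrogen, and fragment masses are deduplicated at 10⁻⁶ Da. Whether the
bond-breaking operator should restrict cuttable bond types further is an
open question upstream; the operator is isolated in one internal function
for easy revision. Scoring is the shared-peak count: spectrum peaks
(after a 1 % relative-intensity floor) within `frag_tol` of any
singly-protonated fragment ion, each peak counted once. The original
probabilistic scoring model of the spectral-search tool this stage
emulates is deliberately out of scope; the count-based score is its core
and is what the tests exercise. Only [M+H]⁺ adducts are considered
(positive mode; proton mass 1.007276 Da). Defaults `frag_tol` =
`prec_tol` = 0.02 Da and `max_shift` = 400 Da are not dictated by the
methodology and are exposed as arguments; 0.02 Da is a routine
high-resolution instrument window, and 400 Da comfortably covers starter
units and single glycosylations.

Variable mode replaces the precursor gate by the shift
Δ = precursor − molecule mass, |Δ| ≤ `max_shift`, and lets fragments
match at `f` or `f + Δ`; when the candidate declares an attachment atom
the shift is restricted to fragments containing it. With Δ = 0 the match
set equals exact mode — a tested identity.

Decoys apply 25 edge-switching steps on the molecule viewed as a
connected multigraph (bond order = edge multiplicity): two edges swap one
endpoint pair, rejected if it would create a self-loop, exceed bond order
3, or disconnect the graph. Because each multigraph edge moves with
multiplicity 1, every atom keeps its total bond order, hence the decoy
preserves the heavy-atom formula, implicit hydrogens and degree sequence
— properties the tests check exhaustively. Finished decoys colliding
with the target set by InChIKey are regenerated from a fresh seed stream;
a per-step retry budget of 100 guards against graphs with no legal swap.
`FDR = N_decoy / N_target` at a score threshold, `NaN`-flagged when no
target passes.

## Synthetic fixtures: what they do and do not show

All tests run on synthetic data with planted signals: label-determining
residues at three fixed signature positions; cognate 12-residue docking
motifs drawn from a seed-fixed code pool shared between training sets and
fixture BGCs; catalytic motifs embedded in KR/DH/ER/KS/TE blocks; spectra
built from a molecule's own depth-2 fragments with configurable dropout,
m/z jitter and uniform decoy peaks. Default fixture dimensions (3–4
genes, 1–2 modules per gene, 8-code pool, 48 positive / 192 negative
docking pairs, 20–30 signatures per label) keep each generated instance
in the sub-second range while leaving the planted-recovery problems
non-trivial. All randomness flows through R's generator from a single
seed per generator call, so fixtures are bit-reproducible.

Passing on these fixtures demonstrates that the machinery is correct —
encodings, invariants, closed forms, ranking, recovery of signals that
are present — not that the models reach any particular accuracy on real
AT domains or real docking pairs, which depends on external curated
training collections outside this package's scope. The published
benchmark accuracies of the methodology this package implements are
therefore not reproduction targets here; the acceptance script instead
recomputes the desk-scale quantities (permutation-space sizes, database
size, encoding dimensions, algebraic identities, planted recoveries,
decoy/FDR arithmetic, shift recovery) that are fully determined by the
package itself.

## Numerical and degenerate-input choices

* Implicit hydrogens come from fixed valence sets (C 4, N 3, O 2,
  S {2,4,6}, P {3,5}, halogens 1); an atom exceeding every allowed
  valence is an error, which is what makes edit scripts and decoy steps
  safely rejectable.
* Canonicalisation (SMILES, InChIKey) is delegated to Open Babel; all
  internal determinism (match ordering, tie-breaks, mixed-radix
  enumeration) is independent of it.
* Single-gene clusters rank trivially with score 0; empty docking sets,
  empty spectra, records without precursors, and zero-hydroxyl chains all
  degrade to their documented small cases rather than erroring.
* The pathway-score probability column is a softmax over ranked scores,
  provided for interpretability; ranking uses raw scores.
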