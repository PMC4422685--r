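---
title: "Two-domain APEH analysis: models, parameters and design choices"
author: "apehkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-domain APEH analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apehkit)
```

## The scientific setting

Acylpeptide hydrolases (APEH, prolyl-oligopeptidase family, clan SC/S9)
are built from an N-terminal β-propeller and a C-terminal α/β-hydrolase
domain joined by a short (~10-residue) linker. The propeller covers the
Ser–Asp–His catalytic triad, so anything that modulates the mutual
position of the two domains modulates substrate access. For the fish
isoform pairs this package was written around, the working model is
electrostatic: per-domain net charges decide whether the domains attract
(closed) or repel (open), while inter-domain salt bridges and hydrogen
bonds, and the charge character of the triad's immediate environment,
tune the balance. `apehkit` implements that comparative analysis —
charge bookkeeping, geometric interaction detection, catalytic-site
characterisation, and a purely geometric hinge-opening simulation —
together with efficiency-corrected qPCR expression ratios for the
corresponding transcripts, and synthetic generators that make every stage
testable against known ground truth.

## Charge bookkeeping

A residue is *negative* if Asp or Glu, *positive* if His, Lys or Arg,
neutral otherwise; the net charge of a region is `#(H,K,R) − #(D,E)` in
elementary units. Histidine is deliberately counted as positive with no
pKa modelling: the analysis is a sequence-level tally in the convention
of the published domain tables this package mirrors, not a titration
model. Terminal amine/carboxylate charges are not counted, and the linker
is excluded from the protein total by default (its residues belong to
neither domain); `include_linker_in_total = TRUE` restores a
full-sequence total.

Molecular masses use standard average (not monoisotopic) residue masses
plus one water, reported in kDa at one decimal when `kda = TRUE`. The
convention adopted is to compute over the full deduced translation as
given, initiator methionine included; whether a published figure includes
the initiator is a property of that figure's sequence, so the function
takes the sequence verbatim and applies no trimming.

## Interaction detection

**Salt bridges.** A residue pair is counted once (with the closest atom
pair reported) when any Asp OD1/OD2 or Glu OE1/OE2 oxygen lies within a
cutoff of any Lys NZ, Arg NE/NH1/NH2 or His ND1/NE2 nitrogen. The default
cutoff is 4.0 Å — the classical side-chain charged-group criterion used
by common salt-bridge servers; it is a parameter (`cutoff`), and
counts are monotone in it (a property the tests assert). His can be
excluded with `include_his = FALSE`. Residue-pair granularity matches the
scale of published per-protein totals (tens of bridges for ~700-residue
proteins).

**Hydrogen bonds.** Homology models carry no hydrogens, so the default
criterion is heavy-atom: donor–acceptor distance ≤ 3.5 Å over explicit
donor/acceptor tables (backbone amide N except proline, backbone carbonyl
O, and the standard polar side-chain atoms). Where an amide H can be
placed at its ideal position (1.0 Å along the external bisector of
N→CA and N→C of the preceding residue), a D–H···A angle ≥ 90° is also
required. The `"hbplus"` preset instead applies the hydrogen-resolved
convention (H···A ≤ 2.5 Å, D···A ≤ 3.9 Å, angle ≥ 90°) where the H is
placeable. Pairs within one residue and the covalently linked
N(i)–O(i−1) backbone pair are excluded. Each donor–acceptor atom pair is
reported once. Note that a salt bridge at ~3 Å necessarily also
satisfies the H-bond criterion through its N–O contact; the two reports
answer different questions and are not disjoint.

**Domain classification.** Interactions are classed `intra-N`,
`intra-C`, `inter` (one residue in each domain) or `linker` (either
residue in the linker; excluded from both intra and inter tallies, since
linker residues belong to neither domain). Residues outside every region
are an error, not a silent drop.

## Catalytic-site environment

`triad_environment()` lists side-chain atoms (CB and beyond — CB
inclusive is the common practice where no explicit boundary is given;
glycine contributes nothing) of non-triad residues within 3.0 Å of any
triad side-chain atom, with minimum distances, the closest triad atom
(ties broken by atom-name order), and per-atom charge classes
(carboxylate O negative, Lys/Arg/His side-chain N positive). The summary
compares negative vs positive atom counts; ties are "balanced".

## Hinge opening

`rotate_about_bond()` rotates everything strictly C-terminal to a chosen
backbone bond (N–Cα: the hinge residue minus its N; Cα–C: only the
hinge's carbonyl, then all later residues) rigidly about the bond axis.
The moving set is sequence-defined — the C-terminal domain swings away —
which matches the intuitive picture of the propeller lid opening;
there is no energy model and no clash resolution, only a clash count
(inter-segment atom pairs below 2.0 Å, configurable). Rigid-motion
fidelity, invertibility, additive composition and 360°-periodicity are
enforced by tests to 10⁻⁶ Å.

Opening is quantified by (a) the distance between the two domains' atom
centroids, (b) the minimum inter-domain atom distance, (c) a
site-exposure proxy — the number of N-domain atoms within 8 Å of any
triad side-chain atom, so *fewer is more exposed* — and (d) the clash
count. The 8 Å shell is an artifact decision (the source analyses only
state that rotation "exposes" the site); it is configurable
(`shell_radius`) and only ordinal comparisons between conformers of the
same structure are meaningful.

The *opening propensity score* formalises the electrostatic argument as
the product of the two domain net charges: positive product = like
charges = repulsion = open-prone; negative = attraction = closed-prone.
Proteins are ranked ascending, ties broken by total net charge. This is
a deliberately simple heuristic, labelled as such: it reproduces the
headline ranking (the one attract-domain isoform, APEH-1_Ch, is least
open-prone by a wide margin), but it cannot and does not resolve
orderings among like-charged pairs that the published discussion based on
additional considerations — for the two high-positive isoforms the
printed order is the reverse of the score order (63 vs 49), and the
package does not force it.

## Ramachandran quality summaries

Backbone φ/ψ are computed with the IUPAC sign convention (the worked
identity `compute_dihedral((1,0,0),(0,0,0),(0,1,0),(0,1,1)) = −90°` is a
frozen test case). Model quality is summarised as the fraction of
assessed residues in "core + allowed" regions. Published QC tools define
those regions empirically; since only the summary fraction is needed
here, the package uses a transparent rectangle-union map — core covers
the right-handed helical basin (φ ∈ [−180,−20], ψ ∈ [−120,50]) and the
extended/sheet basin (φ ∈ [−180,−20], ψ ∈ [90,180] ∪ [−180,−150]);
allowed adds the bridge strips and the left-handed helical basin
(φ ∈ [20,100], ψ ∈ [−20,100]) — and the map is an argument
(`map = rama_region_map()`), so a user can substitute any classification.
The map is intentionally permissive for φ < −20°; it is a screening
summary, not a residue-level validation. Terminal residues are excluded;
an ideal α-helix scores exactly 1.0.

## Expression ratios

Efficiencies are *fractional*: a primer pair with efficiency e doubles
(base 1 + e = 2) at e = 1. The published per-primer efficiencies
(0.922–1.107, shipped as `apeh_primer_efficiencies()`) therefore give
amplification bases 1.922–2.107, and the relative expression of a target
vs a reference gene is R = (1+e_t)^ΔCt_t / (1+e_r)^ΔCt_r with ΔCt
oriented control − sample. This reading — rather than exponent bases of
0.92–1.11, which would invert the biology — is the standard instrument
convention and the package states it prominently. Replicate Cts are
averaged per (tissue, gene) *before* ΔCt; the aggregation order is an
assumption (the alternative, per-replicate folds averaged afterwards,
differs only at second order in the noise). With exactly two target
genes a per-tissue fold-ratio column is emitted (lexicographically later
gene over earlier, e.g. apeh-2/apeh-1; override with `ratio_genes`).
The control tissue is a user choice — folds are only defined relative to
it.

## Synthetic data: what it emulates, and what it does not

`make_peptide()` builds backbones from ideal internal coordinates
(N–CA 1.458 Å, CA–C 1.525 Å, C–N 1.329 Å, standard angles, ω = 180°) with
user dihedrals, reproducing them on re-measurement to well below
10⁻³ degrees; side chains get one idealised rotamer that carries the
charged/polar group atoms (apolar and aromatic side chains are truncated
at CB). `make_two_domain_toy()` joins two helical "domains" with an
extended linker carrying a double reverse turn, closes them by a rigid
rotation about the central linker N–Cα bond — stopping at a minimum
inter-domain backbone separation (4.6 Å) on the far side of the steric
minimum, so that positive rotation from the returned baseline is a pure,
monotone opening — and then realises designed inter-domain salt bridges
(3.2 Å) and H-bonds (2.9 Å) by placing the functional-group atoms
directly on the CB–CB axis at exact distances. Only designed residues
are charged, contact sites are chosen for clearance (≥ 3.9 Å from any
other polar atom, ≥ 4.3 Å from charged atoms and other contacts), and
the generator audits its own output with a direct distance scan, failing
rather than returning a structure whose ground truth is ambiguous.
`make_ct_table()` inverts the expression relation (flat reference gene,
target Ct shifted by log(fold)/log(1+e)) and adds Gaussian cycle noise
per replicate. All generators are deterministic under a seed and leave
the caller's RNG state untouched.

These generators are test instruments, not decoys: toy domains are
helices, not β-propellers; designed side chains have idealised, partly
non-physical internal geometry; simulated Ct noise is i.i.d. Gaussian
with no pipetting or plate effects. Passing tests therefore demonstrate
that the *detectors, classifiers and estimators are correct given
coordinates and Ct values* — they do not validate homology models or
qPCR chemistry. Conversely, the published absolute interaction totals of
the undeposited fish models (hundreds of H-bonds, tens of bridges)
cannot be regenerated without those models; the package's claim is
detector correctness (exact agreement with brute-force enumeration on
100 seeded structures of 20–60 residues), not coordinate-level
reproduction.

## Numerical choices and degenerate inputs

Dihedrals are undefined (an error, not NaN) for coincident or collinear
points; reversal of the four points leaves the torsion invariant, mirror
reflection negates it — both are property-tested. Rotations by exact
multiples of 360° return bit-identical coordinates. PDB round-trips are
exact in identity and within the format's 10⁻³ Å in coordinates.
Alternate locations other than blank/'A' are dropped on reading;
duplicated atoms keep the first occurrence with a warning; HETATM and
waters are excluded from all analyses. Empty inputs (zero proteins, zero
angles, isolated triads) return empty, well-formed results; missing
triad residues, out-of-partition residues, or a missing reference gene
are errors that name the offender.

## Problem sizes

The validation suite uses 100 seeded 20–60-residue structures for
detector-oracle equivalence, 100 Monte-Carlo draws (3 replicates,
0.1-cycle noise) for fold recovery, and 50-residue two-domain toys for
hinge and classification checks — sizes at which brute-force enumeration
is exact and fast, which is what makes them suitable as oracles.

## Known limitations

- Charge tallies are sequence-level: no pKa, no structure-aware
  electrostatics, His always +1.
- The heavy-atom H-bond criterion over-counts relative to
  hydrogen-resolved detection on hydrogen-bearing structures; use the
  `"hbplus"` preset there.
- Hinge opening is geometric: conformers are not energy-minimised and
  large rotations can clash (reported, not resolved).
- The propensity score is ordinal and heuristic; it should not be read
  as an energy.
- Single-chain analyses: multi-chain inputs need an explicit `chain`
  selection on reading.
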