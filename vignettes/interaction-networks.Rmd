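---
title: "Helix geometry and interaction-energy networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Helix geometry and interaction-energy networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helixnet)
```

helixnet analyses membrane-protein helix bundles at three levels — helix
geometry, residue-pairwise energetics, and interaction networks — with a
synthetic-data module that generates every input with known ground truth.
This vignette documents the models, the parameters that matter, the numerical
conventions, and the design decisions taken where the underlying procedure
admits more than one reading.

## Helix geometry

### The endpoint rule

A helix is reduced to a vector between an N-side and a C-side endpoint. Each
endpoint is the unweighted mean of exactly **11 backbone atoms**, selected as
follows: skip one *gap residue* at the extreme end of the helix range (the
terminal residue of a real TM helix is often frayed), take the C, Cα and N
atoms of the next four residues — one helical turn, 12 atoms — and eliminate
the single *inward* backbone atom, the one covalently closest to the helix
middle (the C atom of the innermost window residue at the N end, the N atom
at the C end). Two readings of this rule were possible and both are settled
here as package conventions:

* *Gap inside the range.* The skipped residue is the first/last residue
  **inside** the declared helix range, not a residue beyond it. This keeps
  the rule well-defined for helices flanked by loops of any length and only
  requires the declared range itself to hold six residues or more.
* *Which atom is "inward".* Dropping the chain-innermost atom of the
  12-atom window is the only choice that (a) produces 11 atoms from 12,
  (b) treats the two termini symmetrically, and (c) never removes an atom at
  the outer face of the turn.

The endpoint is an unweighted coordinate mean rather than a true centre of
mass: C, Cα and N masses differ by ≤ 17 %, the systematic displacement is a
few hundredths of an Ångström, and an unweighted mean keeps the rule exactly
reproducible from coordinates alone.

### Tilt angles

The tilt of a helix is the angle between its N→C endpoint vector and the
membrane normal (+Z): `helix_angle()` returns values in **[0°, 180°]**, not
folded to ≤ 90°, because consecutive TM helices run antiparallel and the
direction carries real information (an up-helix at 10° and a down-helix at
170° are different objects).

A consequence of the discrete endpoint rule worth understanding: the mean of
11 atoms spanning ~1.1 helical turns does not sit exactly on the helix axis,
so even a noise-free ideal helix is measured with a small bias. The bias at
the two endpoints cancels when the two selection windows are separated by a
whole number of turns, which with the canonical 100°/residue twist happens at
a window separation of 18 residues — i.e. a 24-residue helix. The synthetic
bundle therefore defaults to 24-residue helices (also a typical TM span),
where the residual bias is below 0.1°; at unfavourable lengths it can exceed
1°. This is a property of the endpoint definition itself, not of the
implementation: the package's tests therefore assert *absolute* recovery of
planted tilts at 0.5° on the favourable default length, and *exact* (1e-6°)
consistency against a rotation-matrix oracle — rotating a structure rotates
its measured axis identically — which holds at any length.

### RMSD and RMSF

Per-segment RMSD is computed over C, Cα, O, N with **no refitting** after the
single global superposition, so rigid shifts and tilts of one helix are
visible in its RMSD (a pure translation by *t* gives exactly |*t*|, which the
tests use as an identity). The global superposition defaults to the Cα atoms
of all TM residues, loops excluded, so that mobile loops do not drag the
frame. RMSF is per residue over its Cα — the field convention when the atom
set is not otherwise specified — and is configurable. For i.i.d. Gaussian
coordinate noise of standard deviation σ the RMSF converges to σ√3 (three
independent coordinates), which gives the Monte-Carlo acceptance check its
closed form.

Helices with a kink proline are split at a pivot into two compartments
analysed separately. The pivot residue itself starts the **second**
compartment; the package fixes this convention (config-overridable) because
the source procedure names only a "pivot point" without assigning it, and a
deterministic assignment is required for ranges to partition exactly.

### Ballesteros–Weinstein numbering

BW mapping is pure offset arithmetic from each helix's anchor (x.50 by
default; any reference position works): residue = anchor + (position − 50).
No alignment is involved, which matches how published residue/BW pairs for
CB1 relate by residue-count offsets, and makes the mapping exactly
invertible inside a helix range. Insertion codes are rejected at PDB read
time for the same reason: author numbering is the universal key throughout
the package, and silently renumbered or inserted residues would corrupt every
downstream network table.

## Energetics

### Model

Residue-pairwise energies sum three atom-pair terms: Coulomb
k·q_iq_j/(ε_in·r), Lennard-Jones with Rmin/2 combination and geometric-mean
ε, and the generalized-Born polar cross term −k·τ(f)·q_iq_j/f with the
canonical pair function f = √(r² + B_iB_j·exp(−r²/4B_iB_j)). Effective radii
B use Hawkins–Cramer–Truhlar pairwise descreening with OBC-II rescaling
(α = 1, β = 0.8, γ = 4.85). Key constants, all configurable via
`gb_options()`:

| parameter | default | rationale |
|---|---|---|
| ε_in | 1 | vacuum solute interior |
| ε_out | 78.5 | water at 298 K |
| salt | 0.15 mol/L | physiological NaCl; κ = √I/3.047 Å⁻¹ (Debye) |
| radius offset | 0 Å | see below |
| Coulomb constant | 332.0636 kcal·Å/(mol·e²) | standard |

The literature OBC parameterization subtracts a 0.09 Å offset from intrinsic
radii before descreening. The package defaults the offset to **0** so that an
isolated atom's effective radius equals its intrinsic radius exactly and the
one-atom limit reproduces the Born closed form −½(1/ε_in − 1/ε_out)q²/R to
machine precision; set `offset = 0.09` to recover the literature behaviour.
Since the GB variant behind published MM-GBSA decompositions is rarely
stated, all of these constants are treated as documented assumptions, not
facts about any particular study.

Residue self-terms (intra-residue atom pairs plus atomic Born self energies)
are kept in a separate `$self` table and never mixed into off-diagonal
entries; this is what makes the conservation identity testable: unmasked pair
sum + self sum = whole-system potential, verified against an independent
scalar double loop at 1e-6 kcal/mol.

### Exclusion, averaging, import

The i..i+4 sequence-neighbour mask removes the α-helical backbone
hydrogen-bond ladder and adjacent contacts at the **residue** level — the
package deliberately has no atom-level bonded exclusion lists, because the
analysis operates on residue pairs and the i..i+4 rule is the stated
procedure. Masked entries keep their values (masking is a flag, idempotent,
and commutes with replicate averaging); pairs on different chains are never
masked. A window of 4 on a 10-residue chain retains 15 of the 45 unordered
pairs, the enumeration the tests pin down.

The nonpolar (SASA) solvation term is omitted from pairwise entries: surface
area is not pairwise-decomposable in the same sense, and the interaction
networks of interest are driven by electrostatics and hydrogen bonds. The
omission is recorded in each matrix's metadata.

External decomposition tables (the common
residue_i/residue_j/internal/vdw/electrostatic/polar_solv/nonpolar_solv/total
CSV dialect) can be imported in place of the internal energy computation;
duplicate (i,j)/(j,i) rows are symmetrized by averaging with a warning above
1e-6 kcal/mol discrepancy.

## Networks

Residue-wise profiles are row sums over unmasked partners (profile total =
2 × pair total); group matrices aggregate pairs into helix/loop segments with
pivoted helices contributing as their two compartments, and conserve the
unmasked pair total exactly. Difference networks are Δ = E_mut − E_wt on the
residue-number-matched universe; mutated residues stay in the network,
flagged, because an alanine substitution keeps its residue number and its
backbone interactions. Replicate SEMs combine in quadrature.

Thresholds the user should know about (all reported in outputs, none
hard-coded into results):

* **Significance threshold** for mutation-affected residues: default
  1.0 kcal/mol on |Δ residue-wise energy|. No published numeric criterion
  exists for this kind of selection, so the package default is a convention,
  always echoed in the output table.
* **Hydrogen bond**: donor–acceptor heavy-atom distance ≤ 3.5 Å and
  D–H···A ≥ 120°, standard geometric values. When the structure carries no
  hydrogens the angle test is skipped and the contact record is flagged
  `angle_checked = FALSE` (distance-only mode) rather than silently passing.
* **Salt bridge**: minimum distance between opposite-charge side-chain group
  heavy atoms ≤ 4.0 Å; same-sign pairs are never reported.
* **Edge threshold** for rendered networks: default 0.5 kcal/mol; edge stroke
  width is linear in |energy| with a clip, and every figure's numbers are
  also written to a sibling CSV.

## The synthetic-data module

The generator is first-class, tested code, and defines the conditions under
which the pipeline is validated:

* **Ideal helices**: backbone N, Cα, C on a continuous helical curve (rise
  1.5 Å/residue, twist 100°/residue, Cα radius 2.3 Å; all overridable), N and
  C at ±0.35 fractional-residue offsets (bond lengths ≈ 1.48 Å), carbonyl O
  along the axis, side chains as Cβ plus idealized extended chains for
  S/D/N/E/Q/K/R (enough atoms to give polar and charged groups real
  geometry). Rotamers, hydrogens (except in contact fixtures) and nonpolar
  side chains beyond Cβ are out of scope.
* **Bundles**: helices on a circle (default radius 15 Å, a 7TM-like bundle
  diameter) with alternating up/down direction and inward tilt (default
  10°/170°), per-helix residue ranges separated by loop-sized numbering gaps,
  and the matching segment definition emitted alongside. A clash guard
  rejects placements with inter-helix atomic distances ≤ 1.5 Å.
* **Trajectories**: i.i.d. isotropic Gaussian coordinate noise (default
  σ = 0.3 Å, a typical well-equilibrated backbone fluctuation scale) plus
  optional scheduled rigid-body motions of named segments for
  planted-signal-recovery tests. Noise is deliberately uncorrelated —
  collective motions, solvent, and membrane are not emulated — so passing
  tests demonstrate estimator correctness, **not** realism of dynamics.
* **Planted energy systems**: replicate wildtype/mutant matrices =
  baseline (+ deltas) + symmetric Gaussian noise, with the exact planted
  difference returned as ground truth. Default study conditions for recovery
  checks: 3 replicates, σ = 0.1 kcal/mol, planted |Δ| ≥ 1 kcal/mol detected
  at threshold 0.5.
* **Contact fixtures**: minimal two-residue geometries realizing a requested
  donor–acceptor distance and D–H···A angle exactly (solved by root-finding
  on the hydrogen placement circle), used to pin the detector criteria.

One interaction of the defaults deserves a note: the demonstration pipeline
evaluates energies on snapshots with σ = 0.05 Å rather than the geometry
trajectory's σ = 0.3 Å. With uncorrelated per-atom noise, a planted contact
at van-der-Waals distance spends some frames inside the Lennard-Jones wall,
and the pair energy variance is then dominated by an artifact no correlated
physical ensemble produces; energy-decomposition work is correspondingly run
on minimized or averaged snapshots, which the low-noise ensemble emulates.

## Problem sizes and determinism

The shipped test-suite and pipeline fixtures use 3–7 helices of 24 residues
(≈ 500–950 atoms), 8–40 frames, and 3–5 energy/contact frames — sizes chosen
so every validation runs in seconds while still exercising all code paths;
the RMSF convergence check uses 10⁴ frames of a small helix where the
closed-form limit needs the statistics. All generators are deterministic
given a seed; the pipeline seeds each stochastic stage from the configured
seed, records the full configuration and output checksums in a manifest, and
reruns are byte-identical on all tabular outputs (figures are exempt only in
principle — they are deterministic SVG here, but the guarantee is stated for
tables).

## Known limitations

* No molecular dynamics, no PB solver, no entropy or nonpolar ΔG terms, no
  binding-free-energy pipelines: the energetics module decomposes
  configurations it is given.
* XTC trajectories are not read (no installed R reader); use DCD or
  multi-model PDB.
* The packaged CB1 segment YAML carries literature anchors and pivots, but
  its TM first/last residues are approximate reconstructions — replace them
  with your own secondary-structure assignment for quantitative per-segment
  work.
* Hydrogen-bond detection without explicit hydrogens is distance-only and
  systematically more permissive; the flag in the contact table makes this
  visible.
* BW numbering is pure offset and will disagree with alignment-based
  assignments across bulges or deletions.
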