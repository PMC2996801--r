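---
title: "Elastic network models and iterative unfolding for zinc fingers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Elastic network models and iterative unfolding for zinc fingers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enmfold)
```

## The model

`enmfold` analyses small metal-binding folds as elastic networks. Every
residue contributes one node at its C-alpha position and every included metal
ion contributes one further node, appended after the protein nodes. Two
assumptions define everything downstream:

1. **Topology is the signal.** All springs share one force constant γ;
   there is no sequence specificity, no distance weighting, no chemistry.
   What distinguishes a Zn–Cys bond from a hydrophobic contact is only where
   it sits in the connectivity graph.
2. **Fluctuations are Gaussian about the native structure.** The Gaussian
   network model (GNM) gives residue fluctuations from the pseudo-inverse of
   the Kirchhoff matrix Γ (entries −1 for contacting pairs within the cutoff,
   node degree on the diagonal):
   ⟨ΔRᵢ·ΔRⱼ⟩ = (3k_BT/γ)[Γ⁺]ᵢⱼ, and B-factors Bᵢ = (8π²/3)⟨ΔRᵢ²⟩.

A connected network has exactly one zero mode (the all-ones vector); the
pseudo-inverse is taken over the nonzero modes only. Normalized
cross-correlations and the slow/fast mode-shape profiles are read off the
same eigendecomposition.

The anisotropic network model (ANM) extends this to directions: the 3n × 3n
Hessian of the pairwise harmonic potential has, for each in-cutoff pair, the
rank-one block −γ (Δr)(Δr)ᵀ/R², with diagonal blocks set by translation
invariance. Its null space for a generic rigid 3D structure is exactly the 6
rigid-body motions. Two useful degenerate cases, both covered in the test
suite: a two-node system has 5 zero modes and a single internal mode with
eigenvalue 2γ; a perfectly collinear n-node chain has 2n + 1 zero modes,
because central-force springs have no transverse stiffness at equilibrium —
"collinear means 5 zero modes" is true only for n = 2.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| GNM cutoff | 7.3 | Å | contact radius for the Kirchhoff matrix |
| ANM cutoff | 13 | Å | contact radius for the Hessian (directional springs are sparser per mode, so the ANM conventionally uses a larger radius) |
| k_BT/γ | fitted | Å² | the single free scale of all GNM fluctuation magnitudes |
| zero tolerance | 1e-8 | relative | eigenvalues below `tol × max eigenvalue` count as zero modes |
| metal elements | ZN | — | which HETATMs become network nodes |

The scale k_BT/γ is estimated by least-squares regression **through the
origin** of experimental B-factors on the predicted shape 8π²[Γ⁺]ᵢᵢ. The
reported Pearson correlation is scale-invariant, so the choice of regression
convention cannot affect it. Metal nodes participate in the network but are
excluded from the fit: there is no experimental C-alpha B-factor for an ion.

### Experimental B-factors from NMR entries

NMR depositions usually carry a constant (uninformative) B-factor column. In
that case `read_experimental_bfactors()` substitutes the ensemble spread:
every model is superposed onto model 1 by a least-squares rigid fit over all
C-alphas, and Bᵢ = (8π²/3) · varᵢ, where varᵢ is the positional variance of
residue i across models — the **unbiased (n−1) variance**, summed over the
three coordinates. With two models a residue displaced by 1 Å therefore gets
B = (8π²/3) · 0.5 ≈ 13.2 Å². The superposition is an internal Kabsch
implementation rather than a third-party routine because the fit must remain
defined on rank-deficient (e.g. collinear) coordinate sets, which arise in
synthetic fixtures; for such sets the rotation is only partially determined,
but the per-residue spread is invariant to the remaining freedom. A
degenerate ensemble of identical models yields all-zero values with a
warning rather than an error, so pipelines fail explicitly at the fit stage
(zero experimental variance) instead of silently earlier.

## Iterative unfolding

Unfolding is modelled as a sequence of quasi-equilibrium networks under
slowly rising temperature. Each iteration:

1. computes the mean-square distance fluctuation
   ⟨(ΔRᵢⱼ)²⟩ = (3k_BT/γ)([Γ⁺]ᵢᵢ + [Γ⁺]ⱼⱼ − 2[Γ⁺]ᵢⱼ) for every **current
   noncovalent contact** (pairs that are no longer — or never were — contacts
   are not candidates);
2. deletes the contact with the largest fluctuation;
3. rebuilds Γ and repeats until the noncovalent set is empty.

Design decisions where the procedure is underdetermined:

* **Covalent springs are immortal.** Consecutive protein nodes of a chain
  stay connected even if their distance exceeds the cutoff, so the backbone
  never fragments and the scheme is well defined to exhaustion.
* **Tie-breaking.** Candidates within a relative 1e-10 of the maximal
  fluctuation are resolved in favour of the lexicographically smallest
  (i, j). Exact ties occur in symmetric toys; a deterministic rule is
  required for regression tests.
* **Disconnection.** A metal that loses all its contacts becomes an isolated
  component. It simply contributes one extra zero mode; the pseudo-inverse is
  block-wise, cross-component correlations are exactly zero, and the node is
  inert for the rest of the trajectory. Its diagonal entry in the normalized
  cross-correlation map is reported as 1 by convention.
* **The scale cancels.** k_BT/γ multiplies all candidates uniformly, so the
  break order is independent of it; `unfold()` defaults to 1.

Snapshots are indexed by LNNC — the count of noncovalent contacts lost so
far — matching how unfolding progress is usually plotted for this method.

## The synthetic generator

`make_chain()` emulates the architecture class of a classical zinc finger:
a β-hairpin, an α-helix folded back over it, connecting and terminal loops,
and optionally a pseudo-metal node placed at the centroid of four designated
ligand C-alphas (feasible only if all four ligand distances stay below the
7.3 Å cutoff; otherwise the build errors). Geometry constants are fixed:
3.8 Å virtual C-alpha bonds everywhere, ideal α-helix C-alpha geometry
(rise 1.5 Å, 100° twist, radius 2.3 Å), hairpin strands 5 Å apart walked
along a capsule path at exact 3.8 Å chords, loops stepped with a
deterministic ±0.35 rad alternating-axis wobble. A non-initial helix is
placed on an elevated axis folded back toward the centroid of the chain
built so far — that fold-back is what makes a four-ligand metal site
geometrically possible. The constants were chosen once to produce realistic
coarse-grained contact densities (the 32-node fixture has 94 noncovalent
contacts, metal coordination 13 at 7.3 Å, metal–ligand distances
3.6–5.4 Å).

The canonical fixture `toy_zinc_finger()` — hairpin(12) + loop(2) +
helix(12) + loop(5), ligands 5/10/23/27, 32 nodes with the metal last —
is deterministic; randomness enters only through optional coordinate jitter
and through `simulate_bfactors()`, both explicitly seeded.
`simulate_bfactors()` draws Bᵢ = 8π² (k_BT/γ)[Γ⁺]ᵢᵢ + ε, ε ~ N(0, σ),
truncated at zero, which gives the scale-recovery tests a known ground
truth (noiseless data recover the scale to machine precision; at 10% noise
a 50-replicate mean recovers it well within 5%).

What the toy does **not** emulate: real side-chain packing, the actual
coordinates of any deposited structure, heterogeneous contact strengths, or
realistic B-factor noise structure (experimental noise is neither Gaussian
nor independent). Passing tests on the fixture therefore validate the
machinery — matrices, spectra, the unfolding scan, bookkeeping — not the
biological conclusions one would draw from a real structure. One concrete
difference: on the real Cys2His2 finger the Zn bond to the C-terminal-loop
histidine is the first metal contact lost, whereas in the toy the break
order of the four pseudo-metal bonds follows the toy's own topology. The
checks against published values for the real NMR entry are kept separate and
require the deposited file.

A related caution on fast modes: the fastest-mode profile peaks at the most
tightly constrained nodes. In the fixture the pseudo-metal (the
highest-coordination node) and the hairpin/helix ligand region rank near the
top, sometimes through an immediate sequence neighbour where the local
packing maximum sits — but a ligand on a floppy terminal loop does *not*
produce a fast-mode peak, in the toy or in real fingers. The regression test
asserts exactly this pattern rather than "all ligands peak".

## Numerical choices

* Eigendecompositions use the symmetric solver on (M + Mᵀ)/2; matrices that
  fail a 1e-8 symmetry or positive-semidefiniteness check are rejected.
* Zero modes are identified by the relative eigenvalue threshold, not by
  projecting onto analytic rigid-body vectors; a projection-based
  consistency check lives in the test suite.
* Mode-shape profiles are unweighted means of squared eigenvector components
  (each profile sums to 1); an inverse-eigenvalue-weighted variant is
  available via `weighted = TRUE`, and with all nonzero modes it reproduces
  the mean-square-fluctuation shape exactly.
* Hairpin chord placement solves |P(t') − p| = 3.8 by `uniroot` at 1e-12
  tolerance; consecutive spacings are exact to machine precision on line and
  arc segments.
* Simulated B-factors are truncated at zero (B is nonnegative by
  definition); at the default noise levels truncation is almost never
  active, so the regression-through-origin estimator stays unbiased in
  practice.
* TSV output uses 6 significant digits, '.' decimals and LF endings
  regardless of locale, so repeated runs are byte-identical.

## Problem sizes

The test suite and the acceptance script run at desk scale, chosen so the
full suite completes in seconds: the 32-node fixture for pipeline and oracle
checks (its complete 94-event unfolding trajectory is verified event-for-event
against a brute-force reimplementation), random connected networks up to
n = 20 (100 replicates) for pseudo-inverse checks, 6-node random clouds for
finite-difference Hessian checks, and 50 noise replicates for
scale-recovery statistics.

## Known limitations

* One force constant for all springs; no distance-weighted or
  chemistry-aware variants.
* Unfolding is strictly sequential and deterministic: no temperature scale,
  no kinetics, no refolding, and cooperativity can only be read qualitatively
  from events clustering in neighbouring steps.
* PDB input only (no mmCIF), single conformer per altloc group, waters never
  become nodes.
* For NMR entries the "experimental" B-factor is a convention, not a
  measurement; the deposited column and the ensemble-spread surrogate can
  differ, and fitted scales/correlations inherit that ambiguity.
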