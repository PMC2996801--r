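# enmfold

Coarse-grained stability and folding analysis of small metal-binding proteins
with elastic network models, built for Cys2His2 zinc fingers and similar
folds in which a metal cofactor is part of the load-bearing topology.

Zinc fingers fold only when Zn(II) is bound, so questions like "which
Zn-ligand bond is lost first on unfolding?" or "how does the metal couple the
beta-hairpin to the alpha-helix?" are questions about network topology as
much as about chemistry. `enmfold` treats the protein as an elastic network —
one node per residue at its C-alpha, plus one node per metal ion — and
answers them with three related tools:

* **Gaussian network model (GNM).** Nodes within a cutoff `r_c` (7.3 Å by
  default) are joined by identical springs. The Kirchhoff (connectivity)
  matrix Γ has Γᵢⱼ = −1 for contacts and the node degree on the diagonal.
  Residue fluctuations follow from its pseudo-inverse over the nonzero modes:

      ⟨ΔRᵢ·ΔRⱼ⟩ = (3 k_B T / γ) [Γ⁺]ᵢⱼ,   Bᵢ = (8π²/3) ⟨ΔRᵢ²⟩

  The single free parameter, the scale k_B T/γ, is fitted by least squares
  against experimental B-factors (for NMR entries with an uninformative
  B column, against the positional spread of the superposed ensemble).
  Normalized cross-correlations Cᵢⱼ = ⟨ΔRᵢ·ΔRⱼ⟩ / (⟨ΔRᵢ²⟩⟨ΔRⱼ²⟩)^½ and
  slow/fast mode-shape profiles come from the same decomposition.

* **Iterative unfolding.** Thermal unfolding is mimicked as a sequence of
  quasi-equilibrium networks: the mean-square fluctuation of every
  noncovalent contact distance,

      ⟨(ΔRᵢⱼ)²⟩ = (3 k_B T/γ) ([Γ⁺]ᵢᵢ + [Γ⁺]ⱼⱼ − 2[Γ⁺]ᵢⱼ),

  is computed, the most strongly fluctuating contact is broken, Γ is rebuilt,
  and the scan repeats until no noncovalent contact remains. Chain-neighbour
  (covalent) springs never break. The ordered event log — indexed by the
  loss number of noncovalent contacts (LNNC) — is the unfolding pathway, and
  contact-map / cross-correlation snapshots can be taken at any LNNC.

* **Anisotropic network model (ANM).** The 3n x 3n Hessian of the pairwise
  harmonic potential (cutoff 13 Å) yields directional normal modes: per-node
  displacement vectors and magnitudes for the slow collective motions, the
  quantity that cone/porcupine plots display.

A synthetic-structure generator builds small folds from helix / strand /
hairpin / loop segments with an optional pseudo-metal node bound to four
ligand residues, and simulates B-factor observations from a known GNM, so the
entire pipeline has testable ground truth without any structure download.

## Worked example

```r
library(enmfold)

s <- toy_zinc_finger()                  # 31 residues + pseudo-metal node 32
b <- simulate_bfactors(s, kt_over_gamma = 0.068, noise_sd = 0.2, seed = 1)
m <- gnm(s, cutoff = 7.3, bfactors = b)
m
#> Gaussian network model: 32 nodes, cutoff 7.30 A
#>   contacts: 30 covalent, 94 noncovalent; zero modes: 1
#>   fitted kT/gamma = 0.06863 A^2, B-factor correlation = 0.998
```

The fitted scale (0.0686 Å²) recovers the generating value 0.068 Å² to 1%
despite the added noise, and the correlation of 0.998 says the predicted
fluctuation profile matches the observations almost perfectly — as it must
here, since the observations were generated from the same network.

```r
tr <- unfold(s, cutoff = 7.3)
tr
#> Unfolding trajectory: 94 contact-breaking events (cutoff 7.30 A)
#>   first break: (7, 28), fluctuation 1.27 A^2
#>   last break:  (6, 8), fluctuation 2 A^2

bond_break_order(tr, cbind(c(5, 10, 23, 27), 32))
#>    i  j step
#> 3 23 32   56
#> 2 10 32   71
#> 1  5 32   78
#> 4 27 32   82
```

Unfolding starts at the floppy periphery (a hairpin-turn / C-loop contact)
and the four metal-ligand bonds survive more than half of the 94 events —
the metal site is among the most persistent parts of the toy fold. On a real
structure (`read_structure("1sp2.pdb")`) the same call gives the Zn-ligand
breaking order of the actual finger.

```r
a <- anm(s, cutoff = 13)
mode_field(a, 1)
#> ANM mode field: rank 1, eigenvalue 0.00322, 32 nodes
#>   largest magnitude 0.87 at node 31
```

The slowest internal mode is dominated by the C-terminal loop (node 31
carries magnitude 0.87 of the unit-norm mode): the tail swings against the
folded body.

`run_full_analysis()` chains all stages and writes TSV reports; the same
pipeline is scriptable from a shell via `inst/cli/enmfold.R`
(subcommands `gnm`, `anm`, `unfold`, `fit-bfactors`, `simulate`, `run-all`).

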