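---
title: "Fragment localized molecular orbitals and interaction energy decomposition: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment localized molecular orbitals and interaction energy decomposition: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flmoeda)
```

## The model

The package works entirely at the restricted Hartree–Fock (HF) level. For a
closed-shell system the HF energy is

$$E_{\mathrm{HF}} = \mathrm{Tr}[\mathbf{h}\mathbf{D}]
  + \tfrac12 \mathrm{Tr}[\mathbf{G}(\mathbf{D})\mathbf{D}] + h_{\mathrm{nuc}},
  \qquad \mathbf{G}(\mathbf{D}) = \mathbf{J}(\mathbf{D})
  - \tfrac12\mathbf{K}(\mathbf{D}),$$

with $\mathbf{D} = 2\mathbf{C}_{occ}\mathbf{C}_{occ}^T$ the one-particle
density over the atomic-orbital (AO) basis. When the atoms are partitioned
into $N_f$ fragments, the density can be decomposed fragment-wise,
$\mathbf{D} = \sum_i \mathbf{D}^i$, and the energy regrouped exactly as

$$E_{\mathrm{HF}} = \sum_i E^i
  + \sum_{i<j}\left(E_{\mathrm{ele}}^{ij} + E_{\mathrm{ex}}^{ij}\right),$$

where each fragment carries its own one-electron matrix
$\mathbf{h}^i = \mathbf{T} + \mathbf{V}^i$ ($\mathbf{V}^i$: attraction to
fragment $i$'s nuclei only; every $\mathbf{h}^i$ contains the full kinetic
operator $\mathbf{T}$) and its internal nuclear repulsion
$h_{\mathrm{nuc}}^i$:

$$E^i = \mathrm{Tr}[\mathbf{h}^i \mathbf{D}^i]
  + \tfrac12 \mathrm{Tr}[\mathbf{G}(\mathbf{D}^i)\mathbf{D}^i]
  + h_{\mathrm{nuc}}^i.$$

The cross terms form the pair electrostatic and exchange energies

$$E_{\mathrm{ele}}^{ij} = \mathrm{Tr}[\mathbf{V}^j\mathbf{D}^i]
  + \mathrm{Tr}[\mathbf{V}^i\mathbf{D}^j]
  + \mathrm{Tr}[\mathbf{J}(\mathbf{D}^j)\mathbf{D}^i]
  + h_{\mathrm{nuc}}^{ij}, \qquad
  E_{\mathrm{ex}}^{ij} = -\tfrac12\,\mathrm{Tr}[\mathbf{K}(\mathbf{D}^j)\mathbf{D}^i].$$

This grouping is an algebraic identity for any decomposition
$\mathbf{D}=\sum_i \mathbf{D}^i$; the test suite enforces it to
$10^{-8}\,E_h$ on every fixture, and the exchange term is non-positive for
density-like $\mathbf{D}^i$ (it is a positive-semidefinite contraction with
a minus sign).

## Fragment localized molecular orbitals

Canonical occupied orbitals are delocalized, so the individual $E^i$ are
meaningless until the occupied space is rotated to make each fragment's
density as compact as possible. The localization minimizes $\sum_i E^i$ —
equivalently maximizes the inter-fragment repulsion, since the total is
fixed — by $N_f - 1$ sequential SCF steps inside the occupied space:

1. Start from the converged canonical occupied span.
2. For the first fragment, variationally select its $n_i$ occupied orbitals
   from the current span so that $E^i$ is minimized; remove them from the
   span by S-orthogonal projection.
3. Repeat for the next fragment in the requested order; the last fragment
   inherits the final remaining span without optimization.

Rotations inside the occupied space leave the total density — and hence the
total energy — unchanged, which is why the decomposition reproduces the full
HF result identically.

**Per-step operator.** Each step is a projected Roothaan iteration: with the
current fragment density $\mathbf{D}^i$, build
$\mathbf{F}^i = \mathbf{h}^i + \mathbf{G}(\mathbf{D}^i)$, transform it to
the orthonormal basis of the remaining span, diagonalize, occupy the lowest
$n_i$ eigenvectors (aufbau), rebuild $\mathbf{D}^i$, and iterate until the
fragment energy change falls below $10^{-9}\,E_h$ (at most 100 iterations).
Degenerate aufbau ties (eigenvalues within $10^{-10}$) are broken by larger
own-fragment Mulliken population, then by index, so the procedure is fully
deterministic.

**Monotonicity safeguard.** A plain Roothaan step can overshoot. Whenever a
step would raise $E^i$ by more than $10^{-12}\,E_h$, the step is recomputed
with a level shift added to the virtual block of the projected operator
(starting at 0.2 $E_h$ and doubling until the step descends). This subsumes
oscillation damping and guarantees the non-increasing energy traces that the
tests assert.

**Starting guess.** Each step starts from a partial pivoted Cholesky
factorization of (half) the remaining density with pivots restricted to the
fragment's own AOs, followed by Löwdin orthonormalization in the overlap
metric. Cholesky vectors are inherently local to the pivot AOs and lie in
the occupied span by construction, which makes the subsequent minimization
short (typically 5–15 iterations on the bundled fixtures).

**Cut bonds.** When the partition severs a single covalent bond, each
incident fragment receives one electron of the shared pair: the bond orbital
is stored once (total occupation 2) and referenced by both fragments with
weight 1 when their densities are built, so $\sum_i \mathbf{D}^i =
\mathbf{D}$ stays exact and each methyl fragment of the ethane fixture
carries exactly 9 electrons. The shared orbital is extracted from the span
*before* the fragment's variational step, as the span orbital maximizing the
**product** of the Mulliken populations on the two bonded atoms, and is then
held fixed. The product criterion is the design choice that matters here: a
plain joint population on the two atoms cannot distinguish a one-atom core
orbital (population $\approx 1 + 0$) from the shared bond
($\approx 0.5 + 0.5$), and letting the fragment-energy minimization
re-polarize the shared orbital biases it toward one side (we measured
0.35/0.65 on ethane). With pre-extraction by the product criterion the
ethane bond orbital splits 0.500/0.500 and every conservation identity is
untouched.

**Order dependence.** The greedy sequential procedure optimizes the first
fragment against the full span and leaves the last fragment whatever
remains. Totals (energy, density, $E_{\mathrm{int}}^{\mathrm{tot}}$) are
rigorously order-invariant and tested so; the individual $E^i$ are not
exactly. On the inversion-symmetric water dimer fixture the within-run
asymmetry $|E^1 - E^2|$ is about $2\times10^{-5}\,E_h$ at 3.5 Å separation,
while the exact symmetry statement — fragment $i$ under order $(1,2)$ equals
fragment $\mathrm{swap}(i)$ under order $(2,1)$ — holds to machine
precision. The localization order is therefore exposed in the configuration
(default: input order), and the tests measure rather than assert
pair-component order invariance.

## Interaction energy decomposition

With fragment densities in hand, the interaction energy between fragments
$i$ and $j$ is decomposed into the pair electrostatic and exchange terms
above plus an **electronic preparation** energy: the cost of deforming a
fragment's density from its isolated (vacuum) optimum to its in-complex
shape,

$$\Delta E^{\mathrm{el\text{-}prep}}_r = E_{\mathrm{embedded}}(r) -
E_{\mathrm{vacuum}}(r),$$

where the vacuum energy comes from a fresh SCF of $r$ alone — restricted for
closed shells, unrestricted (UHF, high-spin) for open-shell cut-bond
fragments. The global total

$$E_{\mathrm{int}}^{\mathrm{tot}} =
  \sum_{i<j}\left(E_{\mathrm{ele}}^{ij}+E_{\mathrm{ex}}^{ij}\right)
  + \sum_i \Delta E^{\mathrm{el\text{-}prep}}_i\; (+\,E_{\mathrm{disp}})$$

equals $E_{\mathrm{HF}} - \sum_i E_{\mathrm{vac},i}$ — the supermolecular
interaction energy — by construction, and the tests verify this closure
against independent monomer SCF runs.

**Pair totals.** For per-pair totals two conventions exist: add the two
monomer preparation energies (default), or run one extra dimer-in-vacuum
SCF and use the dimer preparation term. Both are implemented
(`pair_prep = "monomer"` / `"dimer"`); only the global closure is asserted,
and reports state which convention produced them. The monomer convention is
the default because for a two-fragment system it closes exactly to
$E_{\mathrm{HF}} - E_{\mathrm{vac},1} - E_{\mathrm{vac},2}$.

**Counterpoise.** Basis-set superposition error is reduced by computing the
vacuum energies in the full AO basis with ghost centers: the supersystem
integral set is reused with only the fragment's nuclei in the one-electron
Hamiltonian. The ghost-basis vacuum energy is variationally below the
monomer-basis one (asserted on every fixture). Counterpoise defaults to on
for noncovalent partitions and off when cut bonds are present — a
ghost-basis methyl radical with a dangling bond is ill-conditioned and of
little interpretive value.

**Orbital-pair resolution.** Because the electron–electron parts of the pair
terms are bilinear in the two densities, they partition exactly over FLMO
pairs: pair $(a \in i, b \in j)$ contributes $w_a w_b (aa|bb)$ to the
Coulomb part and $-\tfrac12 w_a w_b (ab|ab)$ to the exchange. Summed over
all pairs these recover $\mathrm{Tr}[\mathbf{J}(\mathbf{D}^j)\mathbf{D}^i]$
and $E_{\mathrm{ex}}^{ij}$ exactly (tested to $10^{-10}$); the table is
sorted by exchange magnitude, which is how the dominant bonding contacts
(e.g. the donor O–H / acceptor lone-pair pair in the water dimer) surface at
the top. One-electron and nuclear parts of the electrostatics are not
orbital-pairwise and are excluded from this table.

**Dispersion.** HF contains no dispersion; it enters as an additive,
orbital-independent pairwise correction through a pluggable provider
(elements + coordinates in, total + atom-pairwise energies out), aggregated
by fragment membership into a pure partition of the provider's total.
Three-body terms, if a provider emits them, go to the fragment pair holding
two of the three atoms (intra-fragment if all three share one; split equally
over the three pairs if all differ), or can be discarded. No provider ships
with the package: when none is supplied, reports mark dispersion as
unavailable rather than silently zero. A deliberately simple synthetic
$-C_6/r^6$ provider is included for exercising the partitioning machinery in
tests; its numbers have no physical standing.

## Numerical choices

* **SCF**: core-Hamiltonian guess, DIIS (subspace 8), convergence at energy
  change $<10^{-10}\,E_h$ *and* max orbital-gradient element
  $\|\mathbf{FDS}-\mathbf{SDF}\|_\max < 10^{-8}$, at most 200 iterations.
  The tight SCF is needed because downstream conservation checks sit at
  $10^{-8}$. Non-convergence is flagged on the result, not fatal.
* **Linear dependence**: canonical orthogonalization with eigenvalue cutoff
  $10^{-8}$; a minimum overlap eigenvalue below $10^{-10}$ triggers a
  warning.
* **Localization**: $\Delta E^i < 10^{-9}\,E_h$ per fragment, 100-iteration
  cap, level-shift safeguard as described above. Span complements are taken
  through eigenvectors of the projector, which is deterministic.
* **Cholesky guess**: pivot breakdown below $10^{-10}$ raises an error (the
  fragment's AOs cannot support the requested orbital count).
* **Units**: coordinates are stored in Bohr (1 Å = 1.8897259886 Bohr),
  energies in Hartree; human-facing reports add kcal/mol
  (1 $E_h$ = 627.509474 kcal/mol).
* **Integral engine**: McMurchie–Davidson recursions with a
  series/downward-recursion Boys function, implemented in compiled code; the
  full two-electron tensor is stored, which caps practical system size at 64
  AOs — ample for the fixture scale this package targets, and the reason the
  Coulomb/exchange builders can be exact matricized contractions.

## What the fixtures emulate — and what they do not

The bundled fixtures (`he_pair`, `h2_pair`, `water_dimer`,
`water_dimer_symmetric`, `water_trimer`, `hf_dimer`, `ethane_cut`) are
deterministic builders covering the regimes the method distinguishes:
non-interacting limits (wide separations), a realistic near-linear hydrogen
bond, a geometry with exact inversion swap symmetry, a three-fragment ring,
a strong dipolar H-bond, and a homolytically cut single covalent bond. The
problem sizes used throughout the tests and the acceptance script are 2–30
AOs in STO-3G and 6-31G — sizes chosen so the whole suite re-derives every
identity from scratch in well under a minute per fixture.

Passing on these fixtures demonstrates the *identities* of the method
(conservation, partition, closure, negativity, locality) — properties that
hold at any scale because they are algebraic. It does not demonstrate
chemical conclusions about large biomolecular complexes: those require
thousands of AOs, diffuse/polarized bases, and real dispersion parameters,
none of which the desk-scale fixtures probe. Geometry quality also matters
only up to realism: the trimer fixture is a plausible but unoptimized ring,
so its numbers are structurally correct without being benchmark geometry
values.

## Known limitations

* Hartree–Fock only: no DFT, no correlation, no relativistic terms; virtual
  orbitals are not localized.
* Cut bonds are restricted to single bonds (one shared pair); each cut bond
  adds one singly occupied orbital per incident fragment.
* Bundled bases are STO-3G and 6-31G for H, He, C, N, O, F; shells up to
  *d* are supported by the engine but no bundled element uses them.
* The dense ERI tensor caps systems at 64 AOs.
* Greedy sequential localization makes individual fragment energies weakly
  order-dependent (totals are not); see the discussion above.
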