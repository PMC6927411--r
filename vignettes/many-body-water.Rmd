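---
title: "Dissecting liquid-water structure with low-order many-body models"
author: "mbwater"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting liquid-water structure with low-order many-body models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbwater)
```

## The scientific question

The total energy of a system of $N$ water molecules can be decomposed
exactly by the many-body expansion (MBE),

$$E_N = \sum_i E^{1B}(i) + \sum_{i<j} E^{2B}(i,j) +
        \sum_{i<j<k} E^{3B}(i,j,k) + \dots$$

where each $n$-body term is defined recursively as the part of an
$n$-molecule sub-cluster energy not explained by all lower orders,
equivalently by the alternating (Moebius) sum
$E^{nB}(S) = \sum_{T \subseteq S} (-1)^{|S|-|T|} E(T)$.
For water the expansion converges rapidly: the 2B and 3B terms carry
roughly 80% and 15–20% of the interaction energy.  A central question in
modern water modelling is how accurately the 2B and 3B terms must be
represented for simulations to reproduce the structure of the liquid —
and how errors at second and third order can compensate each other to
produce fortuitously correct totals.

Answering this at first-principles scale requires coupled-cluster-quality
reference data and nanosecond path-integral simulations.  This package
reproduces the full computational *chain* at desk scale by replacing the
quantum-chemistry reference with a synthetic analytic "truth" potential
and replacing approximate density functionals with controllably distorted
surrogates.  Every downstream step — MBE decomposition, basis-set
extrapolation arithmetic, permutation-invariant term fitting, term
swapping, path-integral molecular dynamics (PIMD) and structural
diagnostics — is implemented in full.

A green test here therefore establishes that the machinery is correct and
that the qualitative mechanisms (rung-dependent error growth, 2B/3B error
compensation, chemical-accuracy term swapping) behave as described; it
does not establish anything about real water beyond what an analytic toy
model can represent.

## The truth potential and its surrogates

The truth potential plays the role of the CCSD(T)/CBS reference.  It is a
polarizable many-body model:

* **1B**: per-molecule Morse O–H stretches plus a harmonic bend.  The
  Morse well (depth $D = 120$ kcal/mol, $a = \sqrt{k/2D}$ with
  $k = 1059.162$ kcal/mol/Å$^2$) expands to the harmonic constant plus a
  cubic anharmonic correction; the literal harmonic-plus-cubic polynomial
  is unbounded below past ~0.6 Å extension and was rejected for that
  reason.  Zero at the reference geometry $r_{OH} = 0.9572$ Å,
  $\theta_{HOH} = 104.52^\circ$.
* **Baseline (all orders)**: fixed point charges
  ($q_O = -0.84\,e$, $q_H = +0.42\,e$), one isotropic polarizable site per
  oxygen ($\alpha = 1.444$ Å$^3$) solved self-consistently with Thole
  exponential damping (width 1.6 Å), and Tang–Toennies-damped
  $-C_6/r^6$ dispersion on O–O pairs ($C_6 = 450$ kcal mol$^{-1}$ Å$^6$).
* **Short-range 2B**: Born–Mayer O–O repulsion
  $A e^{-br}$ ($A = 3\times10^6$ kcal/mol, $b = 4.8$ Å$^{-1}$) times a
  quintic switch $s(x) = 1 - 10x^3 + 15x^4 - 6x^5$ on
  $r_{OO} \in [5.5, 7.5]$ Å.
* **Short-range 3B**: an Axilrod–Teller–Muto triple-dipole term on O
  triples ($k = 1500$ kcal mol$^{-1}$ Å$^9$) times the product of pair
  switches on $[2.5, 4.5]$ Å.

These constants define the model; they are not a fit to real water.  They
were fixed once, for physical plausibility: the water dimer minimizes at
$r_{OO} = 2.96$ Å with $-5.8$ kcal/mol, the four hexamer templates
(prism, cage, book, cyclic) relax to four *distinct* local minima, a
compact hexamer is 2B-dominant (≈83% 2B, ≈14% 3B), and the 32-molecule
liquid at 0.997 g/cm$^3$ and 298.15 K is hydrogen-bonded and partially
tetrahedral ($\bar q_{tet} \approx 0.55$, first $g_{OO}$ peak near
2.8 Å).  An earlier draft with a softer wall ($b = 3.6$) collapsed all
hexamer isomers into a single over-compressed ring and was rejected on
those physical grounds.  One known unrealism: the toy energy ordering
puts the cyclic hexamer lowest (3-site-like electrostatics favor rings),
where real water prefers the prism.

Surrogates emulate exchange–correlation-functional error by scaling the
short-range 2B repulsion by $(1+\varepsilon_{rep})$, the dispersion
coefficient by $(1+\varepsilon_{disp})$ and the 3B term by
$(1+\varepsilon_{3b})$, leaving the 1B term and the polarizable
electrostatics untouched.  Scaling the distortions (×1, ×2, ×4) produces
the monotone rung-style degradation of 2B/3B errors seen in
correlation-plot RMSDs.

## Fitting swappable terms

Short-range terms are fitted in a permutation-invariant polynomial (PIP)
style basis: monomials of total degree ≤ 3 (2B) or ≤ 2 (3B) in
exponential pair variables $\xi_{ab} = e^{-r_{ab}/\lambda}$ over all
intermolecular atom pairs, averaged over the full permutation group of
identical molecules and of the two hydrogens within each molecule
(explicit orbit sums, so invariance is exact by construction), then
multiplied by the order's switching function.  Ridge-regularized least
squares (default $10^{-8}$; QR on the column-equilibrated augmented
system) determines the coefficients deterministically.

Two choices matter:

* **Residual labels.**  A swappable term must be trained on the n-body
  *residual* after the classical baseline
  (`label_set(..., baseline = baseline_only(truth))`), because the hybrid
  potential keeps the base's baseline at all orders.  Training on raw
  n-body energies would double-count the baseline.
* **Matched decay ($\lambda$).**  The degree-$d$ basis can only reach
  decays up to $d/\lambda$; fitting a wall with $b = 4.8$ Å$^{-1}$ needs
  $\lambda \approx d/b$.  The default $\lambda = 0.65$ Å lowers the 2B
  residual RMSD ~18× versus a mismatched scale at identical basis size
  (0.008 vs 0.14 kcal/mol on the standard training set).

`swap_terms()` then builds the three hybrid families — both terms
swapped, 2B only, 3B only — with "all other terms taken from" the base
potential, and refuses fitted terms whose switching radii disagree with
the base.

## Path-integral molecular dynamics

The PIMD engine works in the normal-mode representation.  The isomorphic
classical ring polymer carries the full physical potential on each of the
$P$ beads and is sampled at temperature $PT$, which fixes the free
ring-polymer frequencies at
$\omega_k = \tfrac{2}{\beta_P \hbar}\sin(k\pi/P)$ with
$\beta_P = \beta/P$.  Each step applies the symmetric splitting: half
thermostat, half momentum kick with bead forces, *exact* free-ring-polymer
evolution in normal modes, half kick, half thermostat.  With $P = 1$ and
thermostats off, the engine reduces to classical velocity Verlet exactly
(bit-for-bit against an independent implementation).

* **Thermostats**: massive Nosé–Hoover chains of four links on every
  Cartesian mode degree of freedom, masses $Q = k_B T_{sim} \tau_k^2$
  with $\tau_k = 1/\omega_k$ for internal modes and $\tau = 50$ fs for
  the centroid; Suzuki–Yoshida 3-term cycles, automatically subdivided
  when the time step is coarse relative to the fastest thermostat.
* **NPT**: an isotropic Martyna-style piston coupled to the centroid mode
  only (box and centroid scale together; internal modes are unaffected),
  with its own 4-link chain and $W = (3N+3)k_B T_{sim}\tau_p^2$,
  $\tau_p = 500$ fs.  Because the per-bead weight in the isomorphic
  ensemble is $\beta_P$, the pressure–volume work term is
  $P_{beads} \cdot P_{ext} V$; the reported pressure estimator divides
  back to physical units, and an ideal gas equilibrates to
  $(N{+}1)k_BT/P_{ext}$ as it must.
* **Estimators**: primitive and centroid-virial quantum kinetic-energy
  estimators; the reported kinetic temperature divides the bead kinetic
  energy by the extra factor $P$ so it estimates the physical $T$.  For a
  harmonic oscillator the finite-$P$ expectation has the closed form
  $\langle KE \rangle_P = \tfrac{k_BT}{2}\sum_k
  \omega^2/(\omega_k^2+\omega^2)$ per degree of freedom, which both
  estimators reproduce within stochastic error at $P = 16$.
* **Electrostatics**: permanent charges use a full Ewald sum (screening
  and reciprocal extent chosen from an accuracy target, default
  $10^{-5}$); induction uses minimum-image damped interactions smoothly
  switched off at the cutoff, neglecting reciprocal-space induction — a
  documented toy-scale approximation.  Dispersion tail corrections are
  omitted (cutoff per protocol).

**Drift vs fluctuation.**  At $\Delta t = 0.2$ fs the conserved quantity
of a stiff flexible-water ring polymer *fluctuates* at the $10^{-3}$
relative level; this is the well-known shadow-Hamiltonian oscillation of
velocity-Verlet splittings and scales as $\Delta t^2$.  "Drift" is
therefore measured as the least-squares secular trend, which is two to
three orders of magnitude smaller and is the quantity bounded by the
energy-conservation check.  The trend estimate itself is stochastic at
the $10^{-5}$-per-$10^4$-steps level across seeds, so that bound is
marginal by nature for this system.

## Structural diagnostics

The tetrahedral order parameter of a molecule is
$q_{tet} = 1 - \tfrac{3}{8}\sum_{j<k\le4}(\cos\psi_{jk} + \tfrac13)^2$
over the four nearest oxygen neighbors (minimum image, ties broken by
index): 1 for a perfect tetrahedron, 0 on average for random directions,
$-3$ for four collinear neighbors.  Distributions $P(q_{tet})$ are
averaged over all molecules, frames and beads and normalized to unit
integral.  Radial distribution functions use same-bead pair distances
(the standard PIMD pair-correlation estimator; cross-bead pairs are
excluded), normalized by ideal-gas shell counts, with intramolecular
pairs excluded.  Default bins: 0.05 Å (RDF), 0.02 ($q_{tet}$).

The scaled-down liquid protocol is 32 molecules at the experimental
ambient density in a 9.87 Å box, which caps the minimum-image range at
4.93 Å; the real-space cutoff is 4.5 Å there (the production 9.0 Å
cutoff cannot coexist with this box), and RDF flatness is asserted on the
farthest accessible window.

## What the generators emulate — and what they do not

`sample_dimer_set()`/`sample_trimer_set()` draw O–O separations uniformly
with uniformly random orientations (quaternion sampling) and small
Gaussian intramolecular distortions (0.02 Å / 2°), rejecting
intermolecular contacts below 1.2 Å.  This covers configuration space
evenly but is *not* Boltzmann sampling; real training sets concentrate
near physically visited geometries.  `build_liquid_box()` packs a
checkerboard-jittered lattice with random orientations (contacts
≥ 1.5 Å) — a starting structure, not an equilibrated liquid, which is
why runs discard an initial melting transient.  Hexamer templates are
geometric skeletons with hydrogen-bond donor patterns appropriate to each
isomer, intended purely as minimization starting points.

## Numerical choices

* Switching: quintic smoothstep everywhere ($C^2$ at both radii).
* Hard floor: interatomic distances below 0.3 Å are an error (exponential
  terms would overflow their validity).
* SCF induction: fixed-point iteration with 0.8 mixing to a $10^{-8}$
  max-norm residual; non-convergence reports the smallest eigenvalue of
  the polarization matrix to diagnose polarization catastrophes.
* Minimization: damped steepest descent with a capped step (keeps
  strained templates inside their basin), then L-BFGS-B polish to a
  max-force tolerance.
* Combinatorial guard: full-order MBE refuses more than 12 molecules
  unless forced.
* Monomer references: in-cluster frozen monomers by default (1B terms
  vanish and the expansion reconstructs the interaction energy);
  isolated-optimized monomers expose 1B deformation energies.  Orders
  ≥ 2 are identical under both conventions.

## Known limitations

* The truth model is a caricature: no charge penetration, no anisotropic
  repulsion, one polarizable site; its hexamer energy ordering is
  ring-first.
* Periodic induction is cutoff-switched minimum image only.
* The NPT virial for the water potential is computed by central
  differences of the energy under centroid scaling (analytic pair virials
  are implemented only for the model potentials).
* Hybrid potentials with fitted terms evaluate those terms in R; fine for
  clusters and isomer tables, slow for long liquid runs (production runs
  use native-term potentials).
* No ring-polymer contraction or multiple time stepping; the time step
  must resolve both the O–H stretch and the fastest ring-polymer mode.

## A worked example

```{r example, eval = FALSE}
library(mbwater)

truth <- make_truth_potential()
surrogate <- make_surrogate_potential(
  truth, distortion_spec(0.05, 0.05, 0.10, "rung2-like"))

## fit swappable 2B/3B terms to surrogate residual labels
base <- baseline_only(truth)
d <- sample_dimer_set(2000, c(2.4, 8.0), seed = 1)
t3 <- sample_trimer_set(2000, c(2.4, 6.5), seed = 2)
f2 <- fit_term(label_set(d, surrogate, 2, baseline = base))
f3 <- fit_term(label_set(t3, surrogate, 3, baseline = base))

## hexamer isomer table under the hybrids
isos <- lapply(hexamer_templates(), local_minimize,
               potential = truth, gtol = 1e-3)
pots <- list(truth = truth, surrogate = surrogate,
             hybrid = swap_terms(truth, f2, f3))
isomer_relative_energies(pots, isos, parents = c(hybrid = "surrogate"))

## a short quantum liquid simulation
box <- build_liquid_box(32, 0.997, seed = 7)
spec <- simulation_spec("nvt", n_beads = 8, n_steps = 5000, cutoff = 4.5,
                        seed = 3)
traj <- pimd_run(box, make_truth_potential(list(cutoff = 4.5)), spec)
compute_rdf(traj, "OO")
q_tet_distribution(traj)
```
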