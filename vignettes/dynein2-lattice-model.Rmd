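---
title: "A coarse-grained model of dynein-2 on tyrosinated and detyrosinated tubulin lattices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coarse-grained model of dynein-2 on tyrosinated and detyrosinated tubulin lattices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

Retrograde intraflagellar transport is driven by dynein-2 along the
A-tubule of the ciliary doublet microtubule.  The A-tubule is enriched
in tyrosinated alpha-tubulin (the genetically encoded C-terminal
tyrosine still present), while the B-tubule is largely detyrosinated.
`dynlattice` models the hypothesis that the microtubule-binding domain
(MTBD) of dynein-2 is tuned to the tyrosinated lattice: a mobile
low-affinity MTBD placed on a small tubulin lattice should stay near
its binding site when the alpha-tubulin C-terminal tails (E-hooks) end
in tyrosine, and detach or wander more readily when the terminal
tyrosine is removed and the terminal glutamate is exposed.

The package has two halves: a coarse-grained Langevin simulator with
its trajectory statistics (occupancy heatmaps, overflow proportion,
residue contact maps), and the bookkeeping arithmetic used for
cryo-electron-tomography annotations (head densities, dimer
configuration classes) and mass-spectrometry peptide tables
(tyrosination fractions, protofilament equivalents).  Everything can be
exercised on synthetic inputs with known ground truth.

## The model

### Representation

One bead per residue.  Tubulin monomers are reduced rigid bodies
(`beads_per_monomer`, default 20; the packaged campaign uses 8) whose
beads are positionally restrained; their exact internal resolution is
irrelevant to the analysis layer.  Each alpha-tubulin carries a fully
flexible tail chain — the E-hook — with one bead per residue of the
C-terminal segment `DFEEVGAESAEGAGEGEGEEY` (the tail of Chlamydomonas
alpha-tubulin ending in the encoded tyrosine).  Tails have bond and
angle terms only, no native contacts: E-hooks are disordered.
Detyrosination (`set_tyrosination(model, "dY")`) removes the terminal
TYR bead if and only if it is present, and reassigns charges.

Charges follow a minimal ionizable-residue rule: ASP/GLU −1, LYS/ARG
+1, everything else (including HIS) 0, plus one extra −1 on each
chain's C-terminal bead for the free carboxylate.  Detyrosination
therefore does not change a tail's net charge: it moves the terminal
−1 onto the glutamate that becomes C-terminal, concentrating −2 on the
exposed tip.  This charge-position shift is the mechanism the
simulations probe.

The motor is a pair of rigid quasi-spherical heads.  The mobile
low-affinity head carries a basic binding face (four +1 beads standing
in for the K2996/R3007/K3077–K3080–R3081 cluster of the dynein-2
MTBD); the high-affinity head is positionally anchored for the whole
run, since only the initial diffusional motion of the newly
low-affinity head is simulated.  The heads are joined by a slack
flat-bottomed tether (rest length 12 nm, 0.2 kcal/mol/nm² beyond it),
a proxy for the dimerization linker: it exerts no force until
stretched.  Three initial placements of the anchored head on the
neighbouring protofilament — backward, lateral, forward (positions 1,
2, 3) — mirror the dimer configurations seen in tomograms.

### Lattice geometry

Idealized and straight: axial rise 8.2 nm per dimer, lateral
protofilament spacing 5.2 nm, B-lattice stagger 0.92 nm, no supertwist
or curvature; four protofilaments of three dimers each (the same lattice
size as the full-scale simulation protocol this package scales down).  All four geometric values are arguments of
`lattice_spec()`.

### Potential

* **Native contacts**: 12–10 structure-based wells
  `eps (5 (r0/r)^12 − 6 (r0/r)^10)`, uniform `eps` (default 0.6
  kcal/mol).  Full atomic-interaction-based coarse-grained force
  fields derive contact-specific parameters from all-atom statistics;
  this package deliberately implements the simplified uniform form —
  the analysis layer and the qualitative Y/dY contrast, not the exact
  energetics, are the reproducible surface.  The mobile low-affinity
  head carries *no* structure-based interface contacts by default: the
  low-affinity state is simulated precisely because it lacks the
  strong canonical interface, so it is held on the lattice by charge
  complementarity alone (its basic face against the surface glutamates
  and E-hooks).  `place_dimer(..., docking_contacts = TRUE)` can
  additionally generate contacts at the placed geometry as a
  docked-pose proxy.
* **Electrostatics**: Debye–Hückel,
  `U = (e²/4πεε₀) q_i q_j exp(−r/λ_D)/r`, relative permittivity 78,
  ionic strength 0.1 M, giving a Debye length of 0.96 nm at 300 K.
  The prefactor is evaluated in its temperature-independent closed
  form so the deterministic zero-temperature testing limit stays
  defined.
* **Excluded volume**: purely repulsive shifted `eps (σ/r)^12`.  Radii
  are residue-dependent: bulky aromatics (TYR, TRP, PHE) take σ = 0.6
  nm against 0.4 nm otherwise, pairs using the arithmetic mean.  This
  is what makes detyrosination more than a bookkeeping change: the
  tyrosine cap holds the tail tip's charge at arm's length from the
  basic face, and removing it exposes the −2 glutamate tip for closer,
  roughly twofold-stronger salt-bridge contact.
* **Bonded terms**: harmonic bonds and angles at the built rest
  geometry; harmonic positional restraints (1000 kcal/mol/nm²) pin
  tubulin bodies, tail anchors and the high-affinity head.

### Integration

Underdamped Langevin dynamics with the BAOAB splitting.  Engine units:
length nm, energy kcal/mol, bead mass 100 engine units, timestep 0.2,
friction 2.0 per time unit — the friction value is carried over from
the full-scale protocol, whose engine-unit mapping is an opaque
convention of its simulation engine, so it is exposed as
configuration.  The random stream is a seeded Mersenne
Twister; a trajectory is a pure function of (system, parameters,
force field, seed).  Before dynamics, a short displacement-capped
steepest descent (500 iterations, 0.05 nm cap) relaxes steric clashes
of the as-built geometry (straight-built tails can cross a placed head
volume); anchored beads do not move during minimization.  Nonbonded
pairs in which both beads are restrained are excluded from the
neighbour list — their geometry is fixed, so the exclusion changes no
observable while keeping the campaign desk-scale.

### Campaign protocol

The full-scale protocol is 20 seeds × 3 positions × 3×10⁷ steps
per tail state with the first 5×10⁶ steps discarded.  The packaged
desk-scale campaign (`run_campaign()`, `campaign_params()`) runs 10
seeds × 3 positions × 10⁵ steps per state with the same 1/6 burn-in
fraction, about 12 minutes on one CPU.  Failed runs (numeric blow-up
is detected against a box bound) are recorded in the manifest and the
campaign continues.

## Trajectory statistics

The mobile head's center of geometry is assigned per frame to one of
nine binding sites — a 3×3 grid of Voronoi cells clipped to the grid
rectangle extended by half a site spacing per axis — or to OVERFLOW
when it leaves that region or rises more than 6 nm above the lattice
surface (detachment).  Neither the capture margin nor the detachment
bound is stated numerically in print; both are configurable.  Overflow
is counted at trajectory level and treated as absorbing (frames after
the first exit contribute no grid mass), because overflow is defined
as a percentage *of trajectories*.  Heatmaps are normalized
over retained frames, per initial position and summed; both
normalizations are emitted since the printed figures do not say which
was used before summing.

Contact maps count residue pairs of the mobile head against tubulin
within 1.0 nm per frame, accumulated over post-burn-in frames; the
differential map subtracts per-frame frequencies
(counts/frames, dY − Y), so campaigns of different lengths compare
fairly, and drops the terminal-TYR columns that cannot exist in dY.

## Quantification arithmetic

* `head_density`: heads per 100 nm of axis arc length per tubule;
  group comparison with a two-sided unpaired Student t test
  (equal-variance, matching common statistics-package defaults; Welch
  by flag).  Densities are computed per doublet and tested across
  doublets.
* `classify_configuration`: the observer stands outside the
  microtubule looking along the minus-end direction with the outward
  normal up, so right = axis × normal.  Right head leading →
  Configuration 1, side by side (axial offset ≤ 4 nm, half a tubulin
  dimer repeat — no printed threshold exists) → 2, right head trailing
  → 3; laterally coincident pairs are degenerate (`other`).  Mirroring
  swaps 1 and 3.
* `classify_ct_peptide` / `ptm_fractions`: suffix-anchored matching
  against the alpha-tubulin C-terminal sequence; tyrosinated and
  detyrosinated fractions over C-terminal records only, glutamylation
  over all records; spectral-count weighting by default (intensity by
  flag — the printed fractions do not state which was used).
* `pf_equivalents`: round-half-up of fraction × 23 protofilaments
  (13-PF A-tubule + 10-PF B-tubule); 33.7% → 8 PFs, 66.3% → 15 PFs.
  Percentages round half-up to one decimal throughout (banker's
  rounding would not reproduce the printed 30.2/25.6/16.3).
* An accessible-protofilament correction (some A-tubule tails are
  buried under the B-tubule) is deliberately not applied by default;
  printed densities are uncorrected.

## Synthetic data and what passing means

Every pipeline input has a generator with embedded ground truth:
`gen_toy_motor`, `gen_tomo_annotations` (Poisson head counts per
tubule, dimers placed to realize sampled configuration classes),
`gen_psm_table` (true suffixes of the reference tail at a chosen
tyrosinated fraction, decoy internal peptides, glutamylation flags),
`gen_random_walk_trajectories` (Gaussian walks with an absorbing
bound, checkable against transition-matrix absorption probabilities).
All are pure functions of (parameters, seed).

The generators emulate the *statistical structure* of the real data —
rates, class proportions, suffix composition, escape kinetics — not
its physical detail: no tomogram noise or missing wedge, no spectral
intensities, no lattice defects, and the toy motor is not a dynein
structure.  Passing tests therefore demonstrates that the estimators
and the simulation machinery are correct and that the modelled
mechanism produces the expected direction of effect at desk scale;
they do not validate the reference effect sizes, which came from a
different force field at 300× the simulated length.

## Numerical choices and limitations

* Exact site-boundary ties assign to the lower site index
  (documented, deterministic).
* Zero-temperature runs are a testing limit: electrostatic lengths are
  then evaluated at 300 K so the potential stays defined.
* The box bound for blow-up detection is 10× the system extent, with
  a 100 nm floor for tiny test systems.
* The MTBD selections used for structural superposition default to the
  construct bounds of human dynein-2 (2962–3126) and dynein-1
  (3266–3429) paired by index offset; the exact residue window behind
  the reference 1.1 Å comparison is not stated, so this is a
  documented guess, and no internal sequence alignment is attempted.
* At timestep 0.2 an occasional trajectory can still blow up in a
  close encounter (about 1 in 60 campaign runs); such runs are
  recorded as failed in the manifest rather than silently dropped.
* The toy model's force field went through two disclosed design
  revisions: residue-dependent excluded-volume radii were introduced
  when a uniform-radius version failed to express the
  tyrosine-shielding mechanism, and the mobile head's docking contacts
  were removed when they proved to be an embellishment beyond the
  placement contract (the low-affinity state has no strong interface).
  No parameter was adjusted against campaign outcomes afterwards.
* What the frozen desk-scale campaign does and does not show (all
  numbers recomputed by `scripts/acceptance.R`): the differential
  contact map reproduces the expected qualitative signature — E-hook
  contacts with the head increase upon detyrosination while body
  contacts barely move — and the overflow ordering (dY above Y) holds,
  but with single-digit overflow counts out of 30 trajectories of 1e5
  steps the ordering is not statistically significant, and the summed
  central occupancy comes out *higher* for dY: at this scale the
  stickier exposed tail tip pins the small toy head near its site
  rather than competing it off a specific docked pose, because the toy
  has no pose-specific interface for the E-hook to disrupt.  The
  full-protocol contrast (10.70% vs 20.09% overflow over 60 runs of
  3e7 steps under the full-scale force field) is out of reach at desk
  scale, and the corresponding acceptance check is expected to fail
  until the model gains a competable docked pose.
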