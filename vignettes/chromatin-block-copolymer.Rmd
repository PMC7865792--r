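---
title: "A sequence-based block-copolymer model of chromatin folding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A sequence-based block-copolymer model of chromatin folding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Interphase chromatin is represented as a coarse-grained bead-spring
polymer: one bead per 100 kbp of sequence, diameter $\sigma_0 = 150$ nm
(the gyration diameter of a 500-nucleosome random-walk segment), energies
in $\epsilon_0 = k_B T_0$ with $T_0 = 308$ K ($\approx 2.6$ kJ/mol). Each
bead carries a two-state sequence class derived from CpG-island density —
CGI-rich *forest* (F) or CGI-poor *prairie* (P) — plus two flags: whether
it lies in a lamina-associated domain (LAD) and whether its bin contains a
TAD boundary. The class mosaic makes the chain a block copolymer; all of
the model's structure formation comes from four interaction terms:

1. **Backbone**: a FENE bond between consecutive beads,
   $U(r) = -\tfrac12 K R_0^2 \ln[1-(r/R_0)^2]$ with $K = 30\,
   \epsilon_0/\sigma_0^2$, $R_0 = 1.5\,\sigma_0$. The divergence at $R_0$
   makes bonds finitely extensible; a configuration at or beyond $R_0$ is
   rejected outright.
2. **Type-dependent attraction**: every bead pair interacts through a
   truncated-and-shifted Lennard-Jones potential cut at
   $r_c = 1.3\,\sigma_0$ (so the interaction acts only on "contacting"
   beads and vanishes continuously at the cutoff), with strength chosen by
   the two classes: $\epsilon_{PP} = 4.6$, $\epsilon_{FF} = 4.3$,
   $\epsilon_{PF} = 3.0$ (all $\epsilon_0$). The ordering
   $\epsilon_{PP} > \epsilon_{FF} > \epsilon_{PF}$ encodes stronger
   heterochromatin–heterochromatin contacts and the weakest cross-class
   contacts, which drives F/P (A/B-compartment) segregation. Admissible
   strengths are 3.0–5.0 $\epsilon_0$, putting the well depth
   $U(r_c) - U(2^{1/6}\sigma_0) = 0.343\,\epsilon$ in the van der
   Waals-like range 1.0–2.0 $\epsilon_0$.
3. **TAD loops**: a weak harmonic bond $U(r) = \epsilon_b r^2$ between
   each pair of *consecutive* TAD-boundary beads of a chain, taken exactly
   as written with zero rest length. A bond is classed F-TAD when a strict
   majority of the beads it spans (endpoints included) are F, else P-TAD
   (ties fall to P), with $\epsilon_{FB} = 0.4 > \epsilon_{PB} = 0.2$
   ($\epsilon_0/\sigma_0^2$, both < 0.5 because boundary bridging is
   transient in reality): F-TADs are smaller and more condensed.
4. **Nucleus**: a rigid spherical container sized so the chromatin
   occupies $\phi = 5\%$ of its volume, with the bead volume taken as a
   sphere of diameter $\sigma_0$:
   $R = (n\,v_{bead}/(\tfrac43\pi\phi))^{1/3}$. LAD beads feel an
   attractive truncated-shifted LJ to the nearest wall point (strength
   $\epsilon_{LC} = 6.7\,\epsilon_0$, 1.5–2 times the pair strengths,
   range 6.0–8.0; cutoff $1.3\,\sigma_0$); all other beads a purely
   repulsive wall term cut at $2^{1/6}\sigma_0$ (WCA-style; its strength,
   fixed at $1.0\,\epsilon_0$, is immaterial to the physics because the
   term is repulsive at any strength — only the cutoff is prescribed).

Because the printed container radii for the published chromosome systems
cannot be re-derived from $\phi = 5\%$ without knowing the exact bead
counts and bead-volume convention used there, `build_container()` exposes
both the formula and a direct `radius_override` (e.g. 16.7 $\sigma_0$ for
a one-chromosome system, 19.8 for two).

What the model leaves out, by design: loop extrusion and any active
(motor-driven) dynamics, binder proteins, nucleoli, chromatin-state
(epigenetic) specificity, anisotropic nuclear shapes, and topological
constraints beyond excluded volume.

## From genomic tracks to beads

`bin_to_beads()` divides the chromosome into 100-kbp segments and assigns
each bead the class covering **strictly more than 50%** of its base pairs.
A bin where neither class reaches a strict majority (ties, uncovered
sequence) falls back to P, the background class — configurable via
`tie_class`. Coordinates are 0-based half-open throughout; strand is
ignored; a trailing partial bin is kept if it spans at least 50 kbp.
`call_lads()` works at the domain level: a maximal run of same-class
beads becomes an LAD as a whole when a strict majority of its beads carry
lamina-association signal, where a bead "has signal" if signal intervals
cover more than half of its bin (the bead-level rule is our choice,
mirroring the majority style of the other rules; the source data are
single-cell contact samples with no canonical bead-level definition).
`mark_tad_boundaries()` flags any bead whose bin overlaps a boundary
position. `drop_centromere()` removes beads whose bin midpoint lies in
the centromere interval and re-indexes the survivors consecutively, so
the polymer is bonded directly across the gap — the model chain is one
contiguous polymer per chromosome.

## The synthetic annotation generator

`generate_annotation()` exists so that every downstream stage is testable
without genomic data. It emulates the *statistics* of real annotations,
not any particular chromosome:

* Alternating F/P blocks. A block is a run of complete TADs: the TAD
  count per block is shifted-geometric, and each TAD length is
  shifted-geometric with class means **4.4 beads (F) and 6.6 beads (P)**
  — the small-condensed-F-TAD / large-loose-P-TAD asymmetry. Geometric
  laws are the maximum-entropy choice given that only means are known.
* Block means default to 16 beads (1.6 Mbp) scaled by `f_fraction` so the
  expected F bead fraction equals the request; megabase-scale blocks are
  what CGI-density segmentation produces. Because a block contains at
  least one whole TAD, a derived block mean below the class TAD mean is
  floored there and the other class rescaled to preserve the requested
  bead ratio (this matters only for strongly skewed chains such as
  F-depleted or F-dominated chromosome mimics).
* The default `f_fraction = 0.5` is a neutral choice; the realized F:P
  ratio of any specific chromosome is not modelled.
* LADs are whole P domains (P domains are the ones that colocalize with
  LADs; `lads_in_f` lifts the restriction) selected until
  `lad_coverage` of P beads is reached — largest-first for
  `concentrated`, smallest-first for `dispersed`, matching the
  sparse-concentrated vs abundant-dispersed single-cell LAD patterns.
  The default coverage of 0.5 of P beads (~25% of the chain) sits in the
  range of mammalian LAD fractions.

What the generator does **not** emulate: long-range correlations in block
sizes, centromere/telomere structure, chromosome-specific LAD placement,
and any correlation between TAD size and LAD status. Tests passing on
synthetic annotations therefore validate the machinery and the generic
physics, not chromosome-specific predictions.

## Dynamics

The engine integrates underdamped Langevin dynamics with the BAOAB
splitting, which is stable and configurationally accurate at the working
timestep $dt = 0.01\,\tau_0$ even with $K = 30$ FENE springs. Reduced
units: $m = 1$, $\gamma = 1\,\tau_0^{-1}$ (neither is prescribed by the
physics; these are the standard bead-spring choices),
$\tau_0 = \sigma_0\sqrt{m/\epsilon_0}$.

* **Initialisation**: each chain grows as a random walk with step
  $1\,\sigma_0$, rejecting beads closer than $0.8\,\sigma_0$ to any
  placed bead or within $1\,\sigma_0$ of the wall, with backtracking. The
  raw walk still contains contacts far up the $r^{-12}$ wall, so a
  displacement-capped steepest-descent relaxation (`minimize_energy()`,
  caps at $0.05\,\sigma_0$ per iteration) removes them before dynamics;
  without it the first annealing steps can overstretch bonds.
* **Annealing**: the thermostat target decreases linearly from
  $5\,T_0$ to $1\,T_0$; the default annealing length is 10% of the
  production run ("gradually" is not otherwise quantified). At $5\,T_0$
  the tail of the velocity distribution can still defeat the FENE barrier
  at $dt = 0.01$, so annealing integrates at $dt/2$ by default
  (`anneal_dt`); production runs at the full step.
* **Production**: fixed $1\,T_0$, frames every 10,000 steps, 4 replicas
  from independent conformations and velocities, replica seeds derived
  from the master seed so results are independent of execution order.
* **Neighbour search**: cell lists compacted by counting sort feed a
  Verlet pair list, rebuilt when the two largest bead displacements since
  the last build could close the skin gap — an exact no-missed-pair
  criterion. The skin (default $0.3\,\sigma_0$) is a pure efficiency
  parameter: forces are identical for any positive value.
* **Randomness**: an internal xoshiro256++ stream with a ziggurat normal
  sampler, so trajectories are bit-reproducible for a given integer seed
  and independent of R's RNG state (moments and tail probabilities of the
  sampler are unit-tested).
* **Failure modes are errors, not warnings**: FENE extension $\ge R_0$,
  a bead outside the container, or non-finite energies abort with the
  offending step number.

### Desk scale versus the published protocol

The package defaults are desk-scale: chains of roughly 300–1000 beads run
for $2\times 10^6$ steps per replica. The full published protocol
($2\times 10^8$ steps) is supported through `export_lammps()`, which
writes a LAMMPS data file and input script (`bond_style hybrid fene
harmonic`). The class pair potential acts on non-bonded pairs only:
directly bonded pairs interact through the FENE bond plus a
unit-strength WCA core, in the native engine and in the LAMMPS script
alike (there, the FENE style's built-in WCA with `special_bonds lj 0 1
1`). Setting `exclude_bonded = FALSE` instead applies the class pair
potential to every pair including bonded ones. The real-time interpretation of
$\tau_0$ is deliberately left out of all computations: the two published
time mappings are mutually inconsistent, so wall-clock claims are
metadata only.

At desk scale the short- and mid-range contact statistics (TAD regime and
compartment regime of $P(N)$) converge well within $2\times10^6$ steps,
but the long-range ($N > 7$ Mbps) flattening reflects slow, global
reorganisation and is not reliably converged; the package fits it on
request but the test suite does not assert its value. The test suite's
reference system is a 1000-bead synthetic chromosome run with the full
four-replica protocol; the parameter-sweep and multi-chromosome
comparisons use 400--500-bead systems with $5\times10^5$ production
steps and 1--3 replicas, which resolves the directional effects (wall
attraction, LAD patterns, boundary-bond strength) without repeating the
full protocol per condition. Exponent contrasts at that scale are
attenuated relative to the full protocol, so the sweep comparisons fit
the equilibrated second half of each trajectory.

## Observables

* **Contact map**: beads are in contact when closer than $2.5\,\sigma_0$
  (strict inequality, as specified); the map entry is the fraction of
  pooled frames (all replicas weighted equally per frame) in contact;
  the diagonal is defined as 1 and excluded from $P(N)$.
* **$P(N)$**: mean contact probability over same-chain pairs at each
  sequential separation ($N \ge 100$ kbps); `class_filter` restricts to
  F–F or P–P pairs. Power-law exponents come from least squares on
  $(\log_{10} N, \log_{10} P)$ over the standard windows 300–700 kbps,
  700 kbps–7 Mbps, 7–20 Mbps (inclusive endpoints; non-positive points
  dropped; fewer than 3 surviving points is an error).
* **Radial profile**: 200 equal-thickness shells; per-frame counts of F
  and P beads divided by shell volume, averaged over frames, plotted
  against $r/R$. Number density per shell volume is used ("density" is
  otherwise ambiguous); the peak structure is insensitive to that choice.
* **Windowed Fourier spectrum**: the 5th diagonal of the contact matrix,
  non-overlapping 20-bead (2 Mbps) windows (the window *step* is our
  choice; only the size is prescribed), mean-subtracted, amplitude
  spectra averaged per window class (F if a strict majority of window
  beads are F). F-TADs being small and sharp, F windows carry more
  high-frequency amplitude than P windows.
* **Chromosome territories**: per chain, the mean contact probability
  over same-chain pairs separated by more than 5 Mbps, against the mean
  over all inter-chain pairs.
* **Experimental comparison**: external $P(N)$ tables are rescaled by a
  single factor so their value at $N = 300$ kbps (nearest grid point if
  absent) matches the simulation; the simulated curve is never touched.

## Numerical choices and degenerate inputs

* $P(N)$ pools frames across replicas rather than averaging per-replica
  curves; at equal frame counts the two are identical.
* The truncated-shifted pair force is discontinuous at $r_c$ (only the
  energy is shifted, as written). This is irrelevant under a thermostat
  but visible in microcanonical tests: the NVE conservation check in the
  test suite therefore uses a configuration whose pair distances never
  cross $r_c$, where the integrator conserves energy to $10^{-4}$
  $\epsilon_0$ per $10^4$ steps.
* Ties in every majority rule (bead class, LAD call, boundary-bond
  class, window class) resolve to P — one consistent convention.
* An empty LAD/boundary track is valid input (no flags); an empty F/P
  track, a centromere covering the whole chromosome, or a chain of fewer
  than 2 beads are errors.
* `fit_power_law` refuses windows with fewer than 3 positive points
  rather than extrapolating.

## Known limitations

* Thermodynamics only: no loop extrusion, no activity, no topology
  enforcement beyond excluded volume — knot formation is possible in
  principle during collapse.
* Desk-scale runs undersample the long-range regime (above).
* The harmonic boundary bond has zero rest length, taken exactly as
  specified; consecutive boundary beads are therefore pulled toward
  coincidence, balanced only by excluded volume.
* The annotation reader trusts its tracks: overlapping F/P intervals are
  summed per bin, not reconciled.
* Single CPU; the engine is serial by design (replicas are the natural
  parallel unit).
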