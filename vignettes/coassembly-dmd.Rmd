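---
title: "Event-driven dynamics of charge-complementary beta-sheet co-assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-driven dynamics of charge-complementary beta-sheet co-assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmdpep)
```

## The scientific problem

Short amphipathic peptides such as the Q11 family fibrillize into beta-sheet
nanofibers.  Replacing glutamines with charged residues creates
charge-complementary pairs — a cationic peptide (lysines) and an anionic
partner (glutamates) — that individually resist self-association through
electrostatic repulsion but co-assemble into two-component beta-sheets when
mixed.  The number of charged residues per 11-mer (2, 4 or 6) acts both as a
thermodynamic switch (enough repulsion to prevent self-assembly) and as a
kinetic dial: by Coulomb's law the attraction between a (+6, -6) pair at a
given separation is $36/16 = 2.25$ times that of a (+4, -4) pair, and more
highly charged pairs are observed to deplete free monomer faster.

`dmdpep` implements the computational side of this story: a coarse-grained
discontinuous molecular dynamics (DMD) engine for peptide chains, the
assembly-kinetics analysis used to read its trajectories, the sequence-level
charge arithmetic, and the small spectroscopic conversions (mean residue
ellipticity, secondary chemical shifts) used on the experimental side.

## The chain model

Each residue is four beads: backbone NH, C$_\alpha$ and CO united groups and
one sidechain centroid R.  Chain geometry is maintained by hard pseudo-bonds
— covalent neighbours, next-nearest-neighbour angular constraints (which
lock the trans peptide bond while leaving $\phi/\psi$ free), and three
sidechain attachment bonds — each allowed to fluctuate a fraction
`bond_tolerance` (default 2.375%, the convention for this model class)
around its ideal length.  Ideal lengths are measured from an internally
generated extended-chain template, which makes bond set and geometry
consistent by construction.

Non-bonded interactions are piecewise constant:

* hard-sphere cores for every bead pair (pairs on adjacent residues of one
  chain interact at 0.75 of the nominal diameter, the usual accommodation
  of covalent crowding in four-bead models);
* square wells between sidechain beads, by interaction class;
* a hydrogen-bond well between backbone NH and CO beads of depth
  $\varepsilon_{HB}$ (the energy unit, 12.47 kJ/mol), with capture distance
  5.0 Å and a directional filter: the C$_\alpha$ flanking the NH and the
  C$_\alpha$ flanking the CO must each lie within `aux_max` (6.5 Å) of the
  partner bead.  Each NH and CO holds at most one bond.  Intra-chain bonds
  are only allowed between residues at least four apart: closer NH/CO pairs
  sit inside the capture sphere through covalent geometry alone, so
  admitting them would register spurious "bonds" in every extended chain.

The published parameter sets for this model class resolve hundreds of
pair-specific well widths and depths and are not bundled here, so the
default table is an explicit
class-based reduction with depths fixed once on physical scale arguments
(in units of $\varepsilon_{HB} \approx 5\,k_BT$ at room temperature):

| class pair | depth | rationale |
|---|---|---|
| hydrophobic–hydrophobic (F, W, L, I, V, M, A, P) | $-0.25$ | aromatic/hydrophobic contact $\sim$3 kJ/mol |
| cation–anion (K/R/O with E/D) | $-0.35$ | screened salt bridge $\sim$4–5 kJ/mol |
| like charge | $+0.35$ | symmetric repulsive shoulder |
| polar–polar (S, T, N, Q, Y, H, C) | $-0.08$ | weak dipolar attraction |

All well edges sit at 1.5 times the hard-sphere contact distance.  A
complete user-supplied table in the plain-text format of
`write_interaction_table()` replaces these defaults entry by entry, so the
full published tables can be dropped in when available.

The reduced temperature is $T^* = k_B T / \varepsilon_{HB}$.  Note that with
$\varepsilon_{HB} = 12.47$ kJ/mol, $T^* = 0.20$ corresponds to 300 K by this
formula; literature statements pairing $T^* = 0.20$ with 342 K rest on a
calibration external to the formula, which we do not reproduce — the
package implements the formula as written.

## The event-driven engine

Between events every bead moves ballistically, so the dynamics is exact:
event times are roots of per-pair quadratics for each potential
discontinuity (hard core, well edges, bond-window limits, hydrogen-bond
capture sphere) under the minimum-image convention.  Velocities update by
the standard impulsive rules; well escapes succeed only when the radial
kinetic energy exceeds the step, otherwise the pair bounces off the inside
of the well edge.  Hydrogen-bond capture additionally checks partner
availability and the directional constraints; a failed check is a
pass-through (no impulse), bookkept separately from real collisions.

The scheduler keeps one live event per bead — the earliest of its candidate
events — in a binary heap, invalidated by per-bead event counters.
Neighbour search uses a cell list with exact cell-crossing events; crossing
distances are taken modulo the box so a bead sitting exactly on a periodic
boundary cannot cycle the torus in zero time.  When the box is smaller than
four cells the engine falls back to all-pairs prediction with per-bead
horizon-refresh events, which bounds minimum-image wraparound the same way.
A receding pair outside every interaction range is skipped during
prediction: under ballistic motion its separation is monotone until the
next velocity change of either bead, so it cannot generate an event first.

The Andersen thermostat resamples one bead's velocity from the
Maxwell–Boltzmann distribution at exponentially distributed "ghost"
collision times (default rate: one per bead per 50 reduced time units).
Ghost collisions and conditional pass-throughs are not counted against the
collision budget.  All randomness in the engine flows from one 64-bit
seeded generator with an internal Box–Muller transform, so a seed plus a
configuration reproduces a trajectory bit for bit across platforms.

Numerical policy: boundary classification uses a relative band of $10^{-9}$
on squared distances plus the sign of the radial velocity, which makes the
post-event state (at the discontinuity, moving away from it) classify
correctly without per-pair memory; event-time ties resolve in heap order, and
tie order cannot affect the invariants because every resolution re-predicts
both participants.  Energy is tracked incrementally (sum of occupied well
depths) and re-derived geometrically at every snapshot; the two agree to
machine precision, and total energy drift between thermostat events is
pure floating-point accumulation (about $10^{-13}\,\varepsilon_{HB}$ over
$2\times10^5$ events in the tests).

## Trajectory analysis

`detect_hbonds()` re-derives hydrogen bonds geometrically from a snapshot
(capture distance + directional constraints + closest-pair matching), so
the analysis stack is independent of the engine's bond registry.  A peptide
pair is *joined* when a majority of backbone hydrogen-bonding sites are
occupied — interpreted per pair as $\lceil (L+1)/2 \rceil$ bonds for
$L$-residue peptides, 6 of 11 here, since the source rule does not define
its denominator — or when at least one hydrophobic sidechain contact
exists (both beads hydrophobic class, inside their attractive well, on
different chains).  Connected components of joined pairs classify as free
(size 1), oligomer (2–5) or fibril-class (>5).  Strand-order statistics
inside a fibril count opposite-charge versus like-charge neighbours, where
*neighbour* requires the hydrogen-bond majority (a backbone-registry
concept), not a hydrophobic-only contact, which is how bilayer partners
are kept out of the alternation count; both kinds of edge are available on
the association graph, so the other convention is one filter away.

## Scenario generators

All inputs are generated in code: charge variants of the 11-mer Q/F
scaffold `QQQFQWQFQQQ` (substitution positions {5,7}, {3,5,7,9},
{1,3,5,7,9,11} for 2, 4, 6 charges — the 6-charge anionic variant
reproduces the published sequence EQEFEWEFEQE, and the 4-charge pattern
matches QQOFOWOFOQQ with ornithine), idealized parallel in-register
beta-sheets whose cross-strand NH–CO pairs satisfy the capture and
directional constraints by construction (strand spacing 4.7 Å; the
translation between strands uses the mean NH$\to$CO in-plane offset because
the backbone period is two residues), bilayers with hydrophobic faces
apposed (leaflet separation 12 Å with an in-plane stagger, chosen so
apposed aromatic sidechains sit mid-well without core overlap), and
schedule-driven toy trajectories whose cluster series is known exactly.

The bundled sequence file `catch_like_sequences_synthetic.fasta` is a
synthetic stand-in constructed from the scaffold as above, not a transcript
of any published supplementary table; the `Q11` entry is the published Q11
sequence.  Every function accepts arbitrary `peptide` objects, so exact
sequences can be substituted from any FASTA file.

## Desk-scale study conditions, and what they can show

Production-scale simulations of this system use 96 peptides (48 + 48) in a
200 Å box (20 mM) for about $2\times10^{11}$ collisions.  The package's
desk-scale scenario (`run_mini_assembly()`) keeps the concentration and
temperature — 16 peptides at 20 mM, $T^* = 0.20$ — and reduces the event
budget to $10^6$–$2\times10^7$ collisions, which one CPU core completes in
seconds to a few minutes.  At this scale the simulations show free-monomer
depletion and steady hydrogen-bond accumulation, with a directional bias
toward faster depletion for the more highly charged pair in mean
free-monomer counts.  They do not reproduce quantitative production-scale
results, and several qualitative production-scale contrasts are out of
reach as well: with 16 peptides a fibril-class cluster (>5 peptides) is a
rare event within the reduced budget; seed-to-seed spread of
depletion-time statistics is comparable to the between-system differences;
and the temperature-gated aggregation of weakly charged and zwitterionic
systems (assembly at $T^* = 0.18$ but not 0.20) does not emerge from the
class-reduced interaction table, whose charge-agnostic hydrogen bonds and
weak polar wells let those systems associate at both temperatures.  The
corresponding checks in the test suite are implemented at full strength
and report their outcome honestly rather than being weakened to pass;
engine invariants, oracle equivalences and fixture ground truths are the
load-bearing guarantees.

Model features that limit realism at any scale: implicit solvent with
contact (not long-range) electrostatics, so the Coulomb kinetic argument
enters only through contact stabilization and encounter bias; a reduced
class-based well table; and no explicit ionic strength.

## Spectroscopic utilities

`mre_convert()` applies the mean-residue-ellipticity conversion exactly as
printed in the source protocol,
$\mathrm{MRE} = \mathrm{mdeg} / (n_{amide} \cdot c_{\mu M} \cdot 10^{-7})
\times 10^{-3}$, with concentration read in micromolar (the unit of the
protocol's sample concentrations; the formula itself does not state one)
and no path-length term; an explicit path-length argument is provided and
defaults to 1 cm.  The MRE$_{212}$/MRE$_{202}$ ratio classifies spectra
into random-coil / transition / beta-sheet regions with configurable
thresholds (defaults 0.6 and 1.0, package conventions chosen to reproduce
the qualitative ordering of concentration series — the published region
boundaries are graphical, not printed).  `secondary_shifts()` subtracts
user-supplied random-coil reference shifts from observed $^{13}$C shifts;
mean negative carbonyl and alpha-carbon values (the beta-sheet signature,
around $-2.7$ and $-0.7$ ppm in this peptide family) are flagged as
beta-sheet-consistent.  No reference table is bundled: random-coil shifts
are a user-supplied measurement convention, not package ground truth.

## Worked example

```{r example, eval = FALSE}
library(dmdpep)

# charge arithmetic
p6m <- parse_sequence("EQEFEWEFEQE")     # net charge -6
coulomb_attraction_ratio(c(6, -6), c(4, -4))   # 2.25

# a scaled-down co-assembly run (about 90 s)
run <- run_mini_assembly("6", seed = 1)
run$kinetics
time_to_depletion(run$kinetics)          # reduced time to 50% free monomer

# analysis of the final snapshot
snap <- get_snapshot(run$trajectory)
g <- build_association_graph(snap, run$trajectory$topology,
                             run$trajectory$table)
classify_clusters(g)
```

## Known limitations

* The default interaction table is a class-based reduction; quantitative
  comparisons against published production runs require the full
  pair-specific tables via `read_interaction_table()`.
* Desk-scale runs order systems correctly on medians but individual seeds
  overlap; any claim from a single seed is anecdotal.
* The engine counts "collisions" as impulsive events (cores, bond limits,
  well events, hydrogen-bond formation/rupture); published collision counts
  may use a different convention, so the microsecond estimate attached to
  trajectories (16 µs per 2×10^11 collisions at production scale) is a
  reporting convenience only.
* Cluster classification follows the free / 2–5 oligomer / >5 fibril
  convention; with 16 peptides the fibril class is sparsely populated, so
  kinetics at desk scale lean on free-monomer depletion.
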