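---
title: "Census methods: sputtered-ejecta accounting and electron track structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Census methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its models and the choices
behind them: what each stage computes, which parameters matter, what the
synthetic generator does and does not emulate, and where the design was
genuinely open.

## Units and data model

Everything internal is nm / ps / amu / eV; kinetic energies convert with
1 amu nm²/ps² = 0.0103642688 eV. A trajectory is an ordered list of frames
(unique integer atom ids, element symbols, positions, velocities) over one
fixed atom universe; bond tables carry per-pair ReaxFF bond orders and may
be saved less often than frames, in which case each frame is paired with
the nearest table and the gap is reported (a gap beyond one frame interval
warns). There is no periodic-boundary handling anywhere: the emulated
sample is an open hemisphere in vacuum and all distances are Euclidean.

## Molecule identification and identity

Molecules are connected components of the graph whose edges are bonds with
bond order strictly above the threshold (default 0.3 — low enough to
tolerate bond stretching at high internal energy, exposed as
`bo_threshold`). Raising the threshold can only split molecules, never
merge them, which the tests assert as a monotonicity property. Formula
masses use conventional atomic masses to three decimals, stored in a
plain-text data file so results are bit-stable; C₁₂H₂₂O₁₁ evaluates to
342.297 amu, printed as 342.3. Species labels are assigned per frame and
purely by formula: the solvent template (H₂O) is `water`, the intact-sample
template is `intact_trehalose`, everything else is `fragment`. A trehalose
that transiently loses a hydrogen is therefore a fragment for that frame;
no attempt is made to smooth over such frames.

Cross-frame identity was an open design point: the natural "majority atom
overlap" rule is ambiguous for near-even splits (the larger half of a
23/22 split holds 51% of the parent and would silently inherit its
identity). We adopted the strictest consistent rule: a stable id persists
exactly when the atom set is preserved one-to-one between consecutive
frames; every split or merge retires the old ids, creates fresh ones, and
is logged as a `scission` or `merge` reaction event at the later frame's
time. On quiescent scenes this logs nothing, and a scripted bond scission
is reported at the first frame at or after its scripted time.

## Clusters and the sputter census

Two molecules are in contact when the smallest distance between their atoms
is below `contact_cutoff` (default 0.3 nm, strict inequality — a pair at
exactly 0.3 nm is not in contact). Clusters are connected components of the
contact graph; a bounding-sphere prefilter accelerates the pair search and
is proven equal to the all-pairs computation by an oracle test. Cluster ids
are deterministic (ordered by smallest member molecule id) so outputs are
reproducible.

The surface reference z₀ is the maximum z among sample atoms in the initial
frame — conservative for a hemisphere, where the apex is the natural
origin; a top-decile mean is available as an alternative. A cluster is
sputtered when its centre of mass is at least `height_min` (15 nm) above z₀
*and* its COM velocity has positive z, evaluated at the end-of-impact frame
(75 ps by default). Lowering `height_min` can only add sputtered clusters.

Yield categories follow the five-way taxonomy — single/multiple bare,
single/multiple solvated, fragments — in multiples of the 342.3 amu
reference mass. Two conventions were left open by the category definitions
and are handled as follows:

* **Mixed fragment/intact clusters.** Fragment molecules' mass is pooled
  into `fragments` and the residual composition is re-categorised, keeping
  the decomposition exhaustive.
* **Water mass in solvated categories.** Included by default (the yield is
  the total ejected mass of the category); a switch
  (`solvated_mass_includes_water = FALSE`) books the adjoining waters under
  the separate pure-water tally instead. Pure-water ejecta are always
  tallied outside the five categories and excluded from the total, which
  the taxonomy treats as trehalose-derived material.

## Complex lifetimes

A complex trace starts at *ejection*: the first frame at which the cluster
around a given trehalose satisfies the sputter criterion while holding
exactly one intact trehalose, at least one water, and no fragments. From
then on, water contact is evaluated every frame as a direct
smallest-distance test against the trehalose with the clustering cutoff.
The stability clock runs from ejection to the first water-free frame
(strict continuity; `allow_gap_frames` can tolerate short gaps for a
"net presence" reading). The clock origin was an open question — impact,
end of impact, or ejection — and we chose ejection because the stability of
a complex is only defined once the complex exists as a free object; the
origin is configurable.

A trace is included when its stable duration reaches `min_stable` (320 ps),
it holds at most `max_final_waters` (1) at the last frame, and it kept
exactly one trehalose throughout. A complex that sheds *all* waters but was
stable long enough is included — the exclusion rule only names complexes
with more than one water at the end — and such traces are flagged
(`end_water_free`) because the reading is ambiguous. Contact durations are
sums over sampled frames with no sub-frame interpolation, so all recovered
times are quantised to the frame cadence; the cutoff sweep
(`sweep_cutoffs()`) exposes the sensitivity of the included count to both
filters and is non-increasing in `min_stable` by construction.

The contact map emits, for every water with at least `min_display` (40 ps)
of total in-trace contact, its centre of mass at the first frame — its
position inside the projectile — plus the summed duration. Waters whose
stable id does not exist at the first frame are tagged `sample-origin`.

## The synthetic generator

The generator scripts kinematics instead of simulating forces: the package
tests the census, not the physics. Defaults encode the emulated study
conditions — a 60 nm hemisphere apex as the surface, 45° incidence in the
xz plane, 20 keV total projectile energy (which fixes the impact speed
through the nominal projectile size), a 75 ps impact phase sampled every
1 ps and an extended phase to 900 ps sampled every 10 ps. The save cadences
are not dictated by the emulated experiments and are set per scene; the
randomized suites use 5/15 ps to keep runtimes in seconds.

Scene contents: a grid of stationary sample trehalose stand-ins (45 atoms,
C₁₂H₂₂O₁₁, two chain halves joined by one C–O bridge whose scission yields
the half-sugar fragments), scripted ejection events (bare, solvated,
multi-molecule, fragmenting, retained, falling debris), and a rebounding
pure-water projectile ball. Bond orders are 0.9 within molecules and absent
between them; a fragmentation drops the bridge bond to 0 at its scripted
time. Adjoining waters approach from a vertically spaced stack on the
projectile's leading face, attach 0.25 nm from their trehalose at 5 ps and
leave at > 0.5 nm within a picosecond of their scripted detachment; all
post-ejection motion is purely vertical so scripted columns never cross,
and generation aborts if any two molecules come within 0.1 nm. The manifest
(expected sputter labels, category masses, stability durations, final water
counts, contact durations and t = 0 positions) is derived from the scripted
memberships and the generated coordinates, quantised to the same frame
grid the census sees, so end-to-end recovery is exact up to one frame.
Random specs (`random_scene_spec()`) draw event mixes, velocities and
detachment times away from the decision boundaries (sputter height,
320 ps) so planted labels are unambiguous at the cadence.

What the generator does **not** emulate: real energy transport (craters,
collective flow, thermal motion), bond-order fluctuations, partial
solvation shells with realistic geometry, redeposition, or any chemistry
beyond scripted scissions. Passing tests therefore demonstrate that the
census recovers whatever a trajectory encodes, not that reactive MD is
reproduced.

## Electron Monte Carlo

The transport engine is entirely table-driven: physics enters through
inverse mean free paths per process on an energy grid, an excitation loss,
a single effective ionization threshold, and secondary-energy / angular
rules. Free paths are exponential in the total inverse MFP, processes
compete proportionally to their rates, secondaries cascade with the same
rules, and each electron ends by escaping the sphere or dropping below the
11 eV solvation threshold inside it. Energies outside the grid clamp to the
nearest grid point. Net cluster charge is ionizations minus electrons
solvated inside (the primary counts if retained); this was the simplest
consistent bookkeeping for the +1 selection, and the campaign records its
acceptance fraction. Exact energy closure — initial energy equals deposited
losses plus all terminal kinetic energies — is checked to 10⁻⁹ eV on every
event, and fixed seeds give bit-identical campaigns.

The module's physics oracle is a toy table (constant ionization rate, fixed
loss, forward scattering, axis entry) whose ionization-count distribution
is a truncated Poisson with an energy-ladder cap; at 10⁵ events the
simulated distribution matches the closed form to total-variation distance
well below 0.01.

`make_water_cross_sections()` is an approximate liquid-water model authored
in this package for use when tabulated condensed-phase cross sections are
not at hand: Binary-Encounter-Bethe ionization summed over the five H₂O
orbitals at liquid density with the BEB-weighted mean binding (≈16 eV) as
the effective threshold, a single 8.4 eV excitation level with a Born-like
shape, a power-law elastic fit scattered isotropically, and a steeply
falling Lorentzian secondary spectrum (scale 13 eV). Its known limitations
matter for the hydronium statistics: isotropic elastic angles overestimate
containment of the primary, the single excitation level understates
sub-ionization energy drain, and vapour orbital constants ignore
condensed-phase screening. Consequently the multi-hydronium fraction
P(k ≥ 2 | net charge +1) for a 7 nm sphere at 100 eV comes out near 0.53 at
the acceptance script's sample size — above the ≈0.2–0.4 band expected from
condensed-phase reference simulations, and the corresponding acceptance
check is left failing rather than retuned. Supplying externally validated
tables through `cross_section_table()` is the intended path for
quantitative work; the transport engine itself is oracle-verified.

## Series comparison

The signal proxy (included complexes per impact) and an experimental
intensity series are joined on projectile size n (not on energy, avoiding
float-equality pitfalls), scaled to their maxima, and compared point-wise;
the contiguous energy region where the absolute deviation exceeds a
threshold (default 0.2, our invention — the agreement was only ever
described qualitatively) is flagged. Normalisation is idempotent and
scale-invariant, and the deviation table is symmetric in the inputs. No
experimental values are hard-coded: the intensity series is user-supplied
and the test suite uses synthetic stand-ins with planted divergences.

## Problem sizes and determinism

The shipped suites use scenes of roughly 900 atoms over 70–160 frames,
120 + 100 randomized oracle instances, 20 randomized end-to-end scenes,
10⁵ toy Monte Carlo events and 3000-event water campaigns — sizes chosen so
the whole suite runs in a few minutes on one core while keeping every
statistical check far from its tolerance. All randomness flows through R's
RNG; the acceptance script derives every sub-seed from its `--seed`
argument.
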