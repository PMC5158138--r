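---
title: "The engulfsim model: cell-wall remodeling at the leading edge of the engulfing membrane"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The engulfsim model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(engulfsim)
```

## The biological problem

During sporulation, *Bacillus subtilis* divides asymmetrically and the
larger mother cell then engulfs the smaller forespore in a
phagocytosis-like process: the mother-cell membrane migrates around the
forespore until it closes at the distal pole. Engulfment happens inside a
thick Gram-positive cell wall under turgor, so the membrane cannot simply
push its way forward; movement requires remodeling of the thin
peptidoglycan (PG) layer that is continuously synthesized ahead of the
leading edge (LE) of the engulfing membrane and degraded behind it.
`engulfsim` implements a coarse-grained, mechanistic model of this
process: new glycan strands are inserted at the LE using the old cell wall
and the previous germ-cell-wall strand as templates, after which the
peptide cross-links joining the two templates are removed
("make-before-break"). Insertion and degradation are performed by an
abstract insertion-degradation complex (IDC), standing for the forespore
PG synthases (PBPs) and the mother-cell SpoIID/SpoIIM/SpoIIP degradation
machinery.

## The mechanical model

The germ-cell-wall sac is a bead-spring network. Glycan strands are
semi-flexible filaments of beads spaced `l0` apart; each simulated
filament represents a bundle of `n_bundle = 7` glycans, with effective
persistence length `lp = n_bundle^2 * lp0` for strongly cross-linked
bundles (1960 nm with `lp0 = 40` nm; the weak rule `n_bundle * lp0` can be
selected). Peptide cross-links are Hookean springs (`kpep`), as are the
glycan backbone bonds (`kgly`). Bead positions follow the overdamped
Langevin equation

    zeta dr_i/dt = F_spring + F_bend + F_pep + F_stoch + F_dp + F_wall

with drag `zeta = 4 pi eta_med l0` uniform across beads. The terms are:
Hookean backbone springs; a discrete worm-like-chain bending potential
`kb (1 - cos(phi - phi0))` with modulus `kb = lp kBT / l0`; Hookean
peptide bonds (cross-links between rings and junction tethers to the
rigid old wall); Gaussian thermal forces with variance `2 kBT zeta / dt`;
a turgor pressure difference `delta_p` distributed over an oriented local
surface triangulation (one third of each incident triangle's area vector
per vertex, so closed surfaces feel zero net force); and a half-harmonic
exclusion (`k_wall`) from the old cell wall, modeled as a rigid cylinder
of radius R capped by a hemispherical pole. Units are nm, s, pN
throughout; pressure is in pN/nm^2 (= MPa), so the literature turgor of
86.31 kPa enters as 0.08631.

Two modeling choices keep a freshly built mesh exactly at rest: every
bond is created at its as-built length (newly inserted peptide bridges
are physically in a relaxed state), and closed hoops carry their natural
polygon angle as spontaneous curvature. The integrator is plain
Euler-Maruyama; a guard aborts if any bead moves farther than `0.5 l0`
in one step. With the defaults (`kgly = 200` pN/nm, `dt = 1e-7` s) the
stability number `k dt / zeta` is about 0.06.

Defaults that the source literature does not fix numerically — `l0 = 25`
nm, ring spacing equal to `l0`, `eta_med = 1e-6` pN s/nm^2,
`kBT = 4.1` pN nm, `k_wall = 100` pN/nm — are package choices, recorded in
`simulation_config()` and overridable. Because of this the package makes
no claim about absolute wall-clock calibration of simulated time beyond
the order-of-magnitude engulfment duration; all quantitative comparisons
are against dimensionless or geometric quantities.

## Stochastic insertion at the leading edge

The kinetic layer is shared between the 2D lattice model and the 3D
simulation. The circumference is discretized into M columns; glycan hoops
stack as rows. The LE height of a column is its *contiguous* filled
height: the membrane junction cannot move past a site whose cross-links
have not been remodeled, so insertion always targets the local front site
(strands conform to the front, diving into lagging columns and climbing
over higher material — there are no cantilevers over missing template).
IDCs move processively around the circumference, one column per event,
consistent with the circumferential motion of the PG biosynthetic
machinery. The old-wall template is imperfect: each site independently
carries a template gap with probability `f0`, which a polymerizing IDC
crosses with probability `ppro`. A failed attempt terminates the strand
and leaves an exposed glycan end that marks the column as a defect;
later attempts there require repair, probability `prep`. An idle IDC
binds a uniformly random column of the LE ring and initiates
polymerization from the glycan end there with probability `prep`.

This rule set is a reconstruction — the original algorithmic details are
not in the available text — constrained by three published limits, which
it reproduces at M = 1570 columns, 500 rows, `f0 = 0.01`:

* at `prep = ppro = 1` the LE is symmetric (maximum roughness across 100
  replicates about 0.003, zero at the precision at which the phase
  diagrams report it);
* roughness rises monotonically as the probabilities drop, roughly
  doubling between 0.9 and 0.7, with the smooth regime above ~0.8;
* at `prep = ppro = 0.9`, changing the number of complexes from 10 to
  100 changes mean roughness by well under 10%.

The transition has a simple reading: a defect heals when one of the ~2
strand passages per row through its column succeeds (probability
`prep * ppro` each), so defects persist and the front roughens once
`2 prep ppro` drops below about 1, i.e. near probabilities of 0.7-0.8.
Because both defect creation and passage frequency scale with the number
of complexes, the roughness statistics are insensitive to NIDC.

Roughness and width are reported as `W = sqrt(mean((h - mean(h))^2))`
(rows) and `W / mean(h)` (dimensionless); both numbers are always
returned so alternative definitions can be post-computed. The stop
criterion uses the mean LE height. `lattice_step()` is the plain-R
reference implementation; `run_to_height()` runs the same rules compiled,
and the suite checks the two statistically against each other.

## The 3D engulfment simulation

`run_engulfment()` maps the same kinetic rules onto the meridian of the
old-wall surface. The septum starts as a flat disc of concentric glycan
hoops spanning the septal plane (about 17 rings at R = 435 nm and
`l0 = 25` nm); the outermost hoop is the initial LE, tethered to the
old-wall rim. Every `l0 / VIDC` seconds each IDC performs one insertion
event (shuffled order): a new bead is created on the old-wall surface at
the local front site, glycan-bonded to its strand, peptide-bonded
("vertical") to the ring below, and tethered ("horizontal" junction) to
the old-wall template. In coupled mode the junction guarding the ring
behind is severed in the same event — the make-before-break invariant is
enforced by construction, the replacement segment always exists first. In
decoupled mode junctions are instead severed after an exponential waiting
time with mean `tau_delay`, and with probability `ppcut` a scheduled cut
erroneously severs the vertical bond of the same bead instead.

Between event rounds the mesh relaxes by `n_relax` Langevin steps — a
quasi-static approximation, since mechanical relaxation (microseconds at
these drag coefficients) is far faster than insertion (seconds). For runs
where the volume/surface response to the elastic constants matters (the
chi-square sweeps), `n_relax = 150` at `dt = 1.2e-7` s relaxes the septal
bulge adequately; kinetics-only questions (phenotype classification)
use smaller values.

The trace records, per round, forespore volume and surface area from a
surface-of-revolution reduction of the sac's meridian profile — the same
reduction the experimental image pipeline applies, so the chi-square
comparison is like-with-like — and percent engulfment from the covered
angle: E = (1 - gap_angle / 2 pi) * 100, where the gap angle is the
opening of the uncovered polar cap as seen from the forespore reference
centre. The flat septum therefore starts near E ~ 33% and completion
approaches 100% as the LE reaches the pole.

The decoupled-mode observable `id_separation()` reports the mean distance
from IDC tips to the most recently severed junction sites (the
degradation front). At `tau_delay = 0` it stays within about one bead
spacing; it grows monotonically over the printed delays (0, 0.9, 9, 18
min).

## Fitting and phenotypes

`chi2()` implements the quality-of-fit
`sum_i [(V_exp - V_sim)^2 / sd^2(V) + (S...)^2/sd^2(S) + (E...)^2/sd^2(E)]`
over experimental time points, with the simulated trace linearly
interpolated to the experimental times (experimental standard deviations
are defined per experimental point). `grid_sweep()` evaluates it over a
(kpep, kgly) grid with replicate seeds; failed cells are reported missing,
never imputed. On synthetic data generated at (25, 200) pN/nm the argmin
recovers the generating cell, and the surface is nearly flat in kgly
above the recovered stiffness, as expected when the glycan backbone is
much stiffer than the peptide cross-links.

`classify_phenotype()` calls a run `stalled` when final engulfment is
below 95% with |dE/dt| < 0.02 %/s, `asymmetric` when the LE angular
height spread (maximum over the trajectory) exceeds 25% of the cell
circumference, and `symmetric` otherwise. The thresholds are design
choices, reported with every call and configurable.

## Contour quantification

The analysis half of the package consumes membrane contours (ordered
(x, y) polylines per compartment, um, CSV) rather than raw images.
Kymographs are built in the mother-forespore frame: angle origin at the
forespore point nearest the mother centre of mass, positive
counter-clockwise, 1 degree bins; per-cell intensities are normalized by
the cell's mean contour intensity and resampled by local third-order
(4-point Lagrange) interpolation with periodic wrap, which reproduces
polynomial profiles up to cubic exactly; bins with no contributing cell
are missing, not zero. Time zero is the onset of septum curving, detected
as the first frame whose septal mid-profile curvature — a quadratic fit in
the frame of the local chord, which is far more robust to point noise
than a circle fit through a near-flat arc — exceeds the flat-septum
baseline by a configurable threshold (0.5 um^-1 default, calibrated on
fixtures). `gap_arc_length()` measures the contour distance between the
two LE points on the uncovered side; it is consistent with
`percent_engulfment()` by construction, E = (1 - gap_angle/2pi) * 100.

## Synthetic fixtures and what they do and do not show

`synth_contour_series()` generates sporangium contour series (capped
cylinder mother, spherical forespore, scheduled E(t), optional septum
curving ramp) together with exact ground truth; `synth_noisy_traces()`
adds per-channel Gaussian noise with recorded sigmas;
`synth_intensity_painting()` paints angular Gaussian intensity profiles
(e.g. an LE-centred peak holding ~70% of total mass, the native
LE-fraction of the degradation machinery). All fixtures are deterministic
under their seed and use exactly the file contracts of real inputs.

The fixture noise for the parameter-recovery study is 1% of the channel
mean for volume and surface area and 1 percentage point for engulfment,
representative of the per-point precision of contour-derived
measurements. Passing round-trip tests on these fixtures demonstrates the
correctness of the geometry and bookkeeping, not the realism of the
underlying shapes: real sporangia deviate from rotational symmetry, real
contours carry correlated segmentation errors, and real population traces
average cells with different onsets. Conclusions about real data rest on
the model structure, not on these tests.

## Problem sizes and numerical tolerances

The package's own studies use the published lattice size (M = 1570,
500 rows, 100 replicates per parameter set; seconds per batch in compiled
code). Three-dimensional studies in the test-suite use a reduced cell
(R = 120 nm, cap extent 60 nm, ~25 angular columns, ~13 rings), 20 seeds
per condition, and a template-gap density `f0 = 0.3` chosen so that the
expected number of gap encounters per ring (~8) remains of the same order
as at full scale (~16) — under naive downscaling the defect mechanism
would be silent. Conservative forces match finite-difference gradients to
1e-6 relative; closed-surface pressure sums vanish to 1e-9 of the total
pressure load; equipartition in a harmonic trap holds to 5% with an
Euler-Maruyama bias below 1% at the default step.

## Known limitations

* No explicit membrane, no SpoIIQ-AH zipper, no membrane fission;
  engulfment completes when the LE reaches the pole.
* The old cell wall is rigid; its degradation behind the LE only removes
  tethers, the excluded-volume surface never changes.
* Glycan-strand-degrading variants (two-for-one, three-for-one) are
  documented alternatives, not implemented.
* The insertion rule set is a constrained reconstruction; its roughness
  at perfect repair is ~3e-3 rather than an identical zero (a few
  strand passages are always in flight when the stop criterion fires).
* Absolute time calibration depends on `eta_med`, `kBT` and `dt`, which
  the source literature does not pin down; only relative and geometric
  quantities should be compared quantitatively.
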