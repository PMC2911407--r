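---
title: "The extended two-angle chromatin fiber model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The extended two-angle chromatin fiber model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(e2afiber)
```

## The model

`e2afiber` simulates 30 nm chromatin fibers as a coarse-grained chain of
nucleosomes built from local geometry alone. Each repeat of the chain
consists of a linker-DNA segment and a nucleosome; the conformation is
determined by two angles per nucleosome — the opening angle $\alpha$
subtended by the incoming and outgoing linker at the nucleosome, and the
dihedral $\beta$ by which the bend plane rotates about the incoming linker
— plus the DNA "pitch" $d$, the offset between the points where the DNA
enters and leaves the nucleosome, measured along the local nucleosome axis.
The octamer center sits on the inside of the linker kink at the wrap
offset. The nucleosome repeat length is fixed at 196 bp (147 bp wrapped,
49 bp linker).

Instead of interaction potentials, the model draws $\alpha$ and $\beta$
(and the effective linker length, below) from probability distributions
and rejects conformations that violate excluded volume: nucleosomes are
hard cylinders (11 nm diameter, 5.5 nm height, decomposed into seven
spheres for fast overlap tests) and DNA is a hard tube of radius 1.2 nm.
The resulting ensemble is athermal: every clash-free conformation
reachable by the generative distributions is equally weighted.

Two histone-depletion defects perturb the regular fiber, each drawn
independently per repeat:

* **linker-histone (H1) skips** (rate 6%): H1 normally clamps the in- and
  outgoing linker into a stem, fixing $\alpha$; without it the opening
  angle is released to a wide uniform interval. The dihedral keeps its
  regular distribution — the stem constrains the opening of the two
  linkers, not the twist between repeats.
* **nucleosome skips** (rate 8%): the whole octamer is missing. A run of
  $k$ consecutive skips leaves a naked-DNA stretch of $k \cdot 196 + 49$
  bp, simulated as a discretized worm-like chain (10 bp segments at the
  B-DNA rise of 0.34 nm/bp, persistence length 50 nm).

A nucleosome skip removes its genomic index from the chain, so pairs
flanking a skip run appear at their true repeat separation; the
`delta_units = "ordinal"` option instead counts placed nucleosomes, which
is the convention under which disturbed-fiber nearest-neighbour tables
average over skip-flanking pairs.

## Calibrated constants and the effective linker geometry

The distributions of $\alpha$, $\beta$ and the linker length are not fixed
by first principles; they are calibration constants of the model, frozen
by `calibrate_defaults()` against the regular-fiber anchors

* nearest-neighbour distance $\langle r_1\rangle = 51.00 \pm 0.63$ nm,
* $\langle r_2\rangle = 37.55 \pm 7.16$ nm and
  $\langle r_{10}\rangle = 125.06$ nm,
* fiber persistence length 280 nm,

and, for the width of the released opening-angle interval, the
disturbed-fiber persistence length of 140 nm. The shipped values (recorded
in `inst/extdata/e2a_defaults.cfg` and tested against the constructor
defaults) reproduce every anchor to within 4%.

Two aspects of this calibration deserve emphasis.

**The effective linker length.** A 49 bp linker of straight B-DNA is 16.7
nm long, while the anchored nearest-neighbour spacing is 51 nm. The two
cannot be reconciled by any choice of angles, so the model carries the
center-to-center linker length as an explicit *effective* geometry
constant (calibrated to 57.6 nm with a 0.56 nm spread). Naked-DNA
stretches always use the physical rise; only the nucleosome-to-nucleosome
link is effective. We deliberately do not rescale the B-DNA rise itself,
which would silently distort the naked-DNA persistence length and every
genomic-to-spatial conversion.

**Where each spread comes from.** The nearest-neighbour spread (0.63 nm)
is dominated by linker-length heterogeneity; the spread at two repeats
(7.16 nm) by the opening-angle SD; the stiffness (280 nm) mostly by the
dihedral SD. Calibrating all three jointly is what keeps the zigzag peaks
of the pair distribution sharp: angle noise alone, forced to produce the
0.63 nm nearest-neighbour spread, would double the higher-order spreads
and wash the peak structure out.

The constrained $\alpha$ is drawn from a Gaussian truncated at $\pm 3$ SD
with an absolute floor of 0.15 rad. The floor is physical: the wrapped DNA
and the H1 stem make near-zero opening angles sterically impossible, and
because in-/outgoing linkers of one nucleosome are bonded neighbours
exempt from the excluded-volume test, unbounded tails would let the chain
fold back through itself. The released interval for H1 skips is
constrained during calibration to be at least as broad as the constrained
distribution ($2.5$ SD half-width), so that losing the linker histone can
never stiffen the fiber.

## Sampling: growth, backtracking, pivot Monte Carlo

Fibers are grown repeat by repeat. Each placement draws its internal
coordinates from the model distributions and is tested against the
excluded volume of everything grown so far (spatial hash grid; sites
closer than one repeat along the genome are bonded and exempt). A clash
triggers a redraw; after 200 failed draws the last 25 elements are removed
and regrown (dead ends of self-avoiding growth), with a global budget of
1000 backtracks and, above that, whole-fiber restarts.

Because redraws resample only the current site, growth is not exactly
unbiased for the athermal target; the bias is second order in the clash
rate, which is below 1% of placements at the calibrated defaults.
`mc_equilibrate()` provides the corresponding Markov chain: a pivot move
picks a chain site uniformly, resamples its internal coordinates from the
same generative distributions, rebuilds the downstream chain rigidly, and
accepts iff the result is clash-free. Since the proposal density equals
the target single-site density, acceptance on clash-freedom alone
satisfies detailed balance. The test suite verifies that long pivot runs
leave the growth ensemble's mean squared end-to-end distance unchanged
within sampling error, which is why `sim_config()` defaults to zero
equilibration sweeps; any number of sweeps can be requested.

All randomness flows through R's RNG; an ensemble is reproducible
bit-for-bit from its seed, and each fiber carries a deterministic sub-seed
so it can be regenerated in isolation.

## Observables

**Pair distribution.** `conditional_probability()` histograms all
nucleosome pair distances (0.2 nm bins by default) up to the analysis
cutoff. The canonical system size is a 40 nm sphere around each
reference nucleosome; a cutoff of `Inf` gives the full-range histogram
used for peak inspection. Two normalizations are provided: unit mass over
the analysis window (the default; curve shapes comparable across
ensembles) and per-total-pair (so the integral equals the fraction of
pairs inside the window). `pair_distribution_3d()` converts to
$g(r) = n(r) / (4\pi r^2 \Delta r\, \bar\rho)$ with $\bar\rho$ the mean
per-reference density inside the cutoff sphere, so $g = 1$ is the mean
density of the bounded system; `pair_distribution_2d()` is the disk
analogue for projected fibers, and `scattering_function()` computes the
isotropic transform
$S(q) = 1 + 4\pi\bar\rho \int_0^R (g-1)\, r^2 \,\mathrm{sinc}(qr)\, dr$
by trapezoidal quadrature (verified against closed forms and a direct
Debye sum).

**Projection.** `project_fiber()` drops the coordinates along a fixed or
per-fiber random axis, as in 2D localization microscopy. Projection can
only shorten distances; the projected pair histogram therefore gains mass
below the 10 nm hard-core limit that the 3D histogram cannot have.

**Peaks.** `detect_peaks()` finds local maxima by topographic prominence
and, given `r_delta_stats()` components, assigns to each peak the genomic
separations whose most-frequent value falls inside the peak's support. On
a noise-free mixture built from the anchored component parameters this
reproduces the canonical allocation (first peak from separation 2, second
from 1 and 3). On simulated ensembles at the calibrated spreads the
separation-2 component appears as a shoulder of the main peak rather than
a separate maximum — a known limitation discussed below.

**Contacts and loops.** Two fiber sites closer than 35 nm form a contact;
the intervening stretch is a loop. Sites are nucleosome centers plus
naked-DNA vertices (nucleosome-only mode available), so depleted fibers
can loop through their naked stretches. The default genomic exclusion is
15 repeats (about 3 kbp), chosen by a clearance rule: a separation is
excluded while the mean spatial distance of its zigzag shell, minus five
standard deviations, still reaches the interaction radius — closer pairs
reflect the fiber's own short-range order, not folding. Contacts
accumulate into symmetric genomic interaction maps (2 kbp bins by
default, per-fiber normalization; per-pair available), from which
`center_cut()` and `gap_width()` quantify the central
zero-interaction gap.

**Stiffness.** `persistence_length()` smooths the nucleosome centers with
a 5-site moving average — the persistence length describes the fiber
axis, not the zigzagging nucleosome chain — and fits the exponential
decay of tangent correlations (weighted least squares on the averaged log
correlations, skipping lags inside the smoothing window and stopping
where correlations fall below 0.15). An end-to-end estimator inverting
the worm-like-chain relation is available as a cross-check; both refuse
rod-like inputs rather than extrapolating. Compaction is genomic length
per axis contour length, and the genomic persistence length is the
product of the two. Confidence intervals come from a bootstrap over
fibers.

## Numerical choices

* Naked DNA is discretized at 10 bp per segment; bend angles are Gaussian
  with variance segment/persistence-length, which reproduces the
  worm-like-chain tangent decay to well below the 35 nm contact scale
  (parameter recovery within 10% is part of the test suite).
* Histogram modes are argmax at 0.2 nm bins with ties broken toward
  smaller distance.
* The excluded-volume grid uses cells of one maximal interaction diameter;
  hash collisions can merge cells, which only ever adds candidate checks,
  and the contact detector deduplicates, so both remain exactly equivalent
  to the brute-force scan (tested on fixtures).
* Degenerate geometry (straight pass-through, parallel tangents) falls
  back smoothly: the center offset vanishes with the kink and frame
  normals are parallel-transported.

## What the simulations do and do not show

The generator emulates the study conditions of the model: dilute,
single-fiber ensembles of 160 kbp to 1.6 Mbp with i.i.d. depletion
defects, calibrated to the regular-fiber distance table and stiffness.
Real chromatin adds everything the model excludes by design: sequence-
dependent nucleosome positioning, inter-fiber crowding and confinement,
nucleosome-nucleosome attraction, repositioning dynamics, and functional
(non-random) looping. Passing tests therefore validate the geometry,
sampling and observable pipeline — not biological predictions beyond the
model's scope.

Known limitations worth stating plainly:

* The calibrated compaction is about 15.5 bp/nm of fiber axis, as implied
  by the anchored distance table itself (125 nm at ten repeats of 196
  bp). The genomic persistence length is then about 4.3 kbp. A fiber with
  a 280 nm persistence length *and* a 13.5 kbp genomic persistence length
  would need 48 bp/nm, which contradicts the same distance table; the two
  statements cannot hold simultaneously, and this package follows the
  distance table throughout.
* At the calibrated spreads, regular fibers show rare fold-back loops of
  8–10 kbp (two-plus genomic persistence lengths of contour) — about one
  fiber in twenty at 160 kbp. Depleted fibers loop one to two orders of
  magnitude more at and below 10 kbp, through their naked-DNA hinges.
* The spread of the separation-3 shell comes out about twice the anchored
  separation-2 spread, so the first two zigzag peaks of p(r) merge into a
  peak-plus-shoulder on simulated ensembles; peak–separation allocation
  is exact on constructed mixtures but partially merged on ensembles.
* The disturbed-fiber nearest-neighbour distance (ordinal convention)
  comes out near 51.5 nm; published disturbed-fiber tables with much
  larger means and spreads could not be reproduced from any defensible
  reading of the depletion model, and we report our value as computed.

## Problem sizes

The package's own analyses and tests run at desk scale: tens to a few
hundred fibers of 160–400 kbp, where the nearest-neighbour means converge
to well under a percent and stiffness estimates to a few percent. The
acceptance script (`scripts/acceptance.R`) uses 60 fibers of 160 kbp for
distance statistics and 100 fibers of 400 kbp for stiffness, completing
in well under a minute; larger runs only tighten the error bars.

```{r example}
cfg <- sim_config(regular_params(), fiber_length_bp = 196 * 100,
                  n_fibers = 4, seed = 1)
ens <- simulate_ensemble(cfg)
r_delta_stats(ens, delta_max = 5)
```
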