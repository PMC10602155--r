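---
title: "The SR-EV chromatin model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The SR-EV chromatin model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the model implemented in **srev**, the assumptions
behind every stage of the pipeline, the tunable parameters and their
defaults, and the design choices made where the procedure was genuinely
open. It states no empirical result beyond what the package's test suite
and acceptance script themselves compute.

## The model

Chromatin is treated as a single linear chain of nucleosome-sized beads
confined to a sphere. Two parameters control everything:

* the **folding parameter** `alpha` (> 1, dimensionless), and
* the **overall volume fraction** `phi`, which fixes the bead count
  through `N = floor(phi * (Rc/r0)^3)`.

Conformations are built in two stages.

### Stage 1: the self-returning random walk (SRRW)

The walk lives in units of the minimum jump `b = 10` nm (about one
nucleosome diameter). At each step it either

1. **returns**, retracing the step currently on top of the backbone
   stack, with probability `P_R(U0) = U0^(-alpha) / alpha`, where `U0` is
   that step's length; or
2. **jumps** in an isotropic random direction with a length drawn from
   the heavy-tailed density `(alpha + 1) U^-(alpha + 2)` on `U > 1`
   (inverse-CDF sampling, `U = (1 - u)^(-1/(alpha+1))`).

Jumps push onto the stack, returns pop it; when the stack is empty a jump
is forced. Frequent short returns build dense tree-like clusters — the
seeds of packing domains — while rare long jumps connect them. Larger
`alpha` means fewer returns and shorter jumps.

Two cutoffs keep the walk physical:

* a **local cutoff** `Umax` (default 30 units = 300 nm) on jump lengths,
  enforced by resampling the length;
* a **global spherical cutoff** `Rc` (default 650 nm): a proposed vertex
  must fall within `Rc` of the centre of mass of all vertices generated
  so far, else the whole jump (direction *and* length) is redrawn, up to
  an attempt cap of 10^4. Rejection (rather than reflection) was chosen
  because it preserves the isotropy of accepted jumps; the centre-of-mass
  reference makes the confinement follow the growing structure. The
  return-step fraction is recorded after cutoff enforcement, since the
  cutoffs shape what sits on the stack.

`Umax` deserves a note: the exact value used in the original formulation
of the walk is not recoverable from the main description, so it is an
explicit, documented knob. At 300 nm it is far into the tail (tail mass
about `30^-(alpha+1)`, i.e. ~0.05% of jumps at `alpha = 1.1`), so
observables are insensitive to its precise value.

### Stage 2: excluded volume (SR-EV)

Returns create exactly coincident vertices. The chain is made physical in
two moves:

1. **Expansion** (`expand_overlaps`): one bead per vertex, coordinates
   scaled to nm; beads sharing a site are displaced by independent
   uniform perturbations within `0.1 r0` — large enough to define
   separation directions, small enough not to distort the cluster.
2. **Relaxation** (`relax_excluded_volume`): overdamped sweeps under a
   soft pairwise repulsion `E = k_rep (2 r0 - r)^2` for non-bonded pairs
   closer than the bead diameter `2 r0 = 9.8` nm (cell list of edge
   `2 r0`), plus weak harmonic bonds about `max(original step, 2 r0)`.
   The run terminates at the first check at which every non-bonded
   distance is at least `2 r0 (1 - tol)`, `tol = 1e-3` — overlap
   resolution, not thermodynamic sampling.

The relaxation constants are the one genuinely open part of the design,
and the defaults were set by a physical argument plus one calibration
target. With bonds as stiff as the repulsion, the system settles into a
static force balance in which stretched bonds hold residual overlaps in
place and the run never terminates. Two choices avoid this:

* **weak bonds** (`k_bond = 0.005` versus `k_rep = 1`): overlap clusters
  inflate freely and bonds stretch rather than trap overlaps;
* a **stall boost**: whenever the minimum non-bonded distance fails to
  improve between checks, overlapping beads receive small zero-mean
  kicks (`noise_amp = 0.1` nm) and the repulsion stiffness is multiplied
  by 1.5 with the step shrunk by the same factor. Growing the
  repulsion-to-bond stiffness ratio squeezes residual overlaps out
  penalty-style while keeping the explicit update stable.

The calibration target is the linker DNA length (below): the mean bond
length after relaxation determines the mean linker, and the defaults were
fixed so that the twelve-condition mean falls at the nucleosome-repeat
values reported across the chromatin literature (high 30s to low 40s of
bp), with the correct trend in `alpha`. Nothing downstream was tuned.

Properties preserved by construction: bead order and count never change;
pair forces are equal and opposite and the kicks are zero-mean, so the
centre of mass drifts by far less than a nanometre; with noise off and no
boost the repulsive energy is non-increasing (asserted in the tests).
There is no confinement wall during relaxation; the final extent is
available from `verify_configuration` so spill beyond `Rc` can be
monitored.

## Genomic annotation

Each bead carries 147 bp of core DNA. A bond of relaxed length `U` nm
carries `round((U - 9.8) / 0.34)` bp of linker, clipped below at zero
(negative linkers are unphysical; bonds can relax slightly under bead
contact within tolerance). Linkers are computed from **relaxed** bond
lengths: cluster expansion stretches bonds, and the linker distribution
is the direct probe of that. Cumulative coordinates make the genomic
separation `s(i, j)` additive along the chain.

## Observables

* **End-to-end distance** `sqrt(<R^2(s)>)`: log-spaced `s` bins (20 per
  decade over 10^3–10^8 bp); pairs subsampled uniformly per bin (bead `i`
  with probability proportional to its eligible partners, partner
  uniform), capped at 10^5 pairs per bin. Ensemble curves average
  `<R^2>` across configurations with equal weight, then take the square
  root; fits are done on the ensemble curve. Single-chain estimates at
  large `s` carry few independent segments, which is why ensemble
  averaging matters there.
* **Contact probability** `Cp(s)`: all pairs within 35 nm enumerated
  exactly by cell list, histogrammed by `s` and divided by the exact
  number of pairs per bin (computed from the cumulative-bp sequence), so
  `Cp` is a true probability.
* **Flory-exponent windows**: intra-domain 2×10^3–3×10^4 bp and
  inter-domain 10^5–10^6 bp, configurable. They bracket the
  intra/inter-domain crossover (~4×10^4 bp) and stay below the
  confinement plateau; the acceptance tests report the sensitivity of the
  fitted exponents to shifting these windows.
* **CVC**: local volume fraction in a 6×6×6 grid of (120 nm)^3 probing
  cubes centred on the configuration centroid (the confinement tracks
  the running centre of mass during generation, so the centroid is the
  natural distinguished point). Beads are assigned to cubes by centre:
  at `r0/edge ≈ 0.04`, analytic sphere–cube overlap would be needless
  precision.
* **G(r) and the packing exponent D**: `G(r)` is the mean cumulative
  neighbour count about reference beads inside a 240 nm sphere about the
  centroid (neighbours counted anywhere); `D` is the log–log slope over
  40–120 nm, fit on the ensemble-mean curve for `<D>` or per
  configuration for `D_i`. `G` is deliberately left unnormalised — any
  constant factor cancels in the slope. The reference-bead restriction
  controls edge bias at full scale (240 + 120 nm < 650 nm); in
  reduced-scale runs the margin shrinks and some truncation bias toward
  lower `D` remains (see Limitations).
* **phi_i**: bead count inside the same 240 nm sphere times
  `(r0/240)^3`, paired with `D_i` per configuration.
* **`resample_di`**: block means of 10 consecutive `D_i`, mimicking
  measurements that average over much larger regions than one analysis
  sphere.

## Density stacks and packing domains

`voxelize` deposits one unit of mass per bead as a product of 1-D
Gaussian integrals over each voxel (differences of normal CDFs), with
`sigma = r0` so the stamp support is about one bead across, voxel edge
5 nm, truncation at 4.5 sigma (per-bead mass deficit < 1e-4; total stack
intensity equals the bead count to well within 0.1%).

Domain identification transposes an image-analysis pipeline to 3-D, with
a 2-D mode (`project_stack`) for comparison work:

1. Gaussian smoothing (5 voxels), then strict local maxima above a
   prominence threshold (default twice the median non-zero intensity)
   with a minimum mutual separation of 50 nm, brighter centre kept.
   Optional CLAHE contrast enhancement applies to the 2-D mode only.
2. `mass_scaling`: for every voxel in an 11-voxel window about a centre,
   `M(r)` = intensity within radius `r`; curves averaged weighted by the
   seed-voxel intensity (window 11×11×11 in 3-D by default; the
   procedure it is transposed from used 11×11 pixels in 2-D).
3. `domain_radius` fits `M(r) = A r^D` on an inner window (10–30 nm) and
   walks outward until one of three stopping criteria fires: (i) the
   curve deviates from the fit by more than 5%; (ii) the local slope
   (five-sample sliding log–log fit) reaches 3; (iii) the radial CVC
   passes a strict local minimum and turns upward. The smallest such
   radius and the criterion are recorded. When an upturn in the radial
   CVC and a slope of 3 fire on the same radial sample — an upturn
   entails a local slope above 3 — the CVC minimum is reported as the
   more specific description. Domains whose curves end before any
   criterion fires are discarded with a reason.

## Reproducibility and scale

Every stochastic stage draws from R's RNG; one configuration = one seed.
Ensembles derive per-replicate seeds from a master seed through a
documented counter scheme (`child_seed`), so runs are order-independent
and bit-reproducible; `run_ensemble` skips completed replicates by
manifest hash and re-runs byte-identically.

Full-scale systems (`Rc = 650` nm, N up to 466,854) run in minutes per
configuration on one core. For ensemble work at desk scale the package
uses reduced systems: at fixed `phi`, `Rc` and `N` shrink together
(`N = floor(phi (Rc/r0)^3)`), which preserves local observables. The
shipped acceptance checks use `Rc = 325` nm (N = 46,685 at `phi = 0.16`)
for the packing-exponent ensembles, `Rc = 225` nm for the
twelve-condition grid, and full scale where the observable demands it
(the 10^5–10^6 bp end-to-end window; the 88 Mbp genome-size check).

## What the synthetic fixtures do and do not show

Oracle tests use point sets with closed-form behaviour: uniform balls
(`G ∝ r^3`), planes (`r^2`), power-law blobs with radial density
`∝ r^(D0-3)` (cumulative count `r^D0`), freely jointed chains (Flory
exponent 1/2), and lattices (first-neighbour distance). These validate
the estimators — binning, cell lists versus brute force, fit windows —
not the model; agreement on fixtures says nothing about chromatin.
Conversely the model-level checks (return fractions, linker lengths,
`D` ranges, Flory regimes) exercise the full pipeline but inherit every
design choice above, most sensitively the relaxation constants.

## Known limitations

* The relaxation protocol is a design choice calibrated on linker
  lengths; packing-sensitive quantities shift by a few hundredths in `D`
  under alternative (stiffer-bond, slower) protocols.
* Reduced-scale `D` is biased low by edge truncation of the reference
  sphere plus finite-size effects (fewer independent domains), by
  roughly 0.1 at `Rc = 325` nm; comparisons of reduced-scale `D` against
  full-scale reference values should expect that shortfall.
* Single-configuration curves at large genomic separation are noisy
  (few independent segments); use ensembles.
* The chain has no genomic identity: no sequence, no loop extrusion, no
  CTCF/cohesin, no epigenomic marks. Contact curves are generic, not
  chromosome-specific. The inter-domain contact-probability decay is
  steeper than −1 under the default relaxation protocol (measured
  ≈ −1.5 over 10^5–10^6 bp on a full-scale configuration, versus −0.89
  intra-domain), another quantity sensitive to the protocol choice.
* No thermodynamic sampling: relaxation stops at overlap resolution, so
  configurations are single draws from the generative process, not an
  equilibrium ensemble of a Hamiltonian.
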