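---
title: "Models and methods behind sclamella"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sclamella}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sclamella)
library(dplyr)
```

## The problem

The stratum corneum — the outermost layer of skin — owes its barrier
function to stacked, highly ordered lamellae of ceramides (CER), cholesterol
(CHOL) and free fatty acids (FFA).  Atomistic simulation of these
multilamellar gel phases is prohibitively expensive, so coarse-grained (CG)
models that group 2–4 heavy atoms (or four waters) into one bead are the
workhorse.  `sclamella` packages the computational machinery around such
models for four ceramide subclasses (NS, NP, AS, AP, all with a 24-carbon
acyl chain and an 18-carbon sphingoid base), CHOL, FFA C24 and water:

* CG bead mappings and mass-conserving molecule templates,
* forward mapping of atomistic frames onto beads,
* Boltzmann inversion of Gaussian bond/angle distributions into harmonic
  parameters,
* the lamellar structural-metric suite (APL, NLA, tilt, thickness, S2,
  interdigitation, extended-conformation fraction, hydration),
* the shape-annealing protocol arithmetic, and
* synthetic gel-phase configurations with exact ground truth so that every
  metric is testable without molecular dynamics.

## CG mappings

Chains map three carbons to a `TAIL` bead; a chain whose remaining length is
2 mod 3 terminates instead in a two-carbon `TER2` bead.  An 18-carbon chain
therefore ends in a TAIL bead and a 24-carbon acyl chain in TER2.  Lengths
with remainder 1 mod 3 are unmappable and rejected.

Ceramide headgroups map to `MHEAD2` (the sphingoid C1–C3 backbone), `AMIDE`
(N–H plus the carbonyl carbon and oxygen — assigning the carbonyl carbon to
AMIDE is what makes the acyl carbon bookkeeping close at 7×TAIL + TER2), and
one bead per hydroxyl: `OH1`/`OH2` on C1/C3 of every subclass, `OH3` on the
phytosphingosine C4 (NP, AP), `OH4` on the α-hydroxy acyl C2 (AS, AP).
Keeping each hydroxyl as its own bead preserves the directional
hydrogen-bonding differences that drive subclass-specific packing.  FFA maps
its carboxyl group to `HEAD`; CHOL uses an inherited sterol mapping encoded
here generically as `CHEAD` plus ring/tail beads with a documented,
mass-closing hydrogen partition (the exact pictorial assignment lives in the
original CG work; only masses matter to this package).  A `W` bead carries
four water molecules (72.06 amu with standard atomic masses).

Every template asserts two invariants: the atom groups partition the
molecule exactly, and bead masses sum to the molecular formula mass within
0.01 amu.  Atom-to-bead assignments for hydroxyl hydrogens are
figure-derived in the source models and are marked as such in the template
tables — they affect only which bead carries 1 amu of hydrogen.

## Boltzmann inversion

A harmonic bonded term with force constant $k$ sampled at temperature $T$
produces a Gaussian distribution
$y \propto \exp[-k(x-x_0)^2 / (2 k_B T)]$, so the observed width gives the
force constant directly:

$$k = \frac{k_B T}{\sigma^2}, \qquad k_B = 0.0019872041\ \mathrm{kcal/(mol\,K)}.$$

Design choices:

* **k from the variance**, not from a log-density regression: exact for a
  true Gaussian and robust to sparse tails (a log-density fit would weight
  empty far bins).  The least-squares Gaussian fit refines moment estimates
  of the histogram.
* **Sheppard's correction**: fitting a binned histogram inflates the
  variance by $h^2/12$ (bin width $h$); the fitted width is corrected so
  that stiff bonds (narrow distributions on 0.01 Å bins) do not read ~1–2%
  soft.  Round-trip tests recover $k \in [15, 900]$ within 0.5%.
* **Histogram defaults** follow the derivation convention: 0.01 Å bins for
  bonds, 1° for angles.  Gaussian-kernel smoothing is applied only for peak
  detection, never for fitting.
* **Bimodal distributions** (the TAIL–OH4 bond and two headgroup angles are
  bimodal when atomistic frames are mapped to beads) are deliberately fitted
  with a single Gaussian and flagged `multimodal` when a secondary smoothed
  peak exceeds 20% of the main peak; multi-harmonic fits are rejected for
  speed, matching CG practice.
* **Angles** are handled in degrees at the user surface but converted to
  radians for inversion, so angle force constants are reported in
  kcal/(mol rad²).  The source tables do not print angle-constant units;
  kcal/(mol rad²) is the recorded assumption.  No $\sin\theta$ Jacobian is
  applied to angle distributions, matching the plain-Gaussian convention of
  the parent models (a switchable correction would be a one-line change in
  `derive_bonded_table()`).

Terms backed by fewer than 100 samples are excluded with a warning rather
than fitted.

## Structural metrics

All metrics consume a `cg_frame` — a tibble of beads with an orthorhombic
box attribute — and follow the reporting conventions of multilayer studies:

* **Leaflets** are found by 1-D k-means on per-lipid mean headgroup z with
  deterministic quantile initialization; leaflets are numbered bottom to
  top.  For six-leaflet stacks the *inner* leaflets (2–5) carry APL, NLA
  and the extended fraction; the *central pair* (3, 4) carries tilt,
  thickness, S2, interdigitation and hydration.
* **APL** is box cross-section over lipids per leaflet; **NLA** divides APL
  by the mole-fraction-weighted effective tail count (FFA 1, CER 2,
  CHOL 1.9), computed per frame and then averaged (per-frame first is the
  default; the alternative order is a trivial pipeline change).
* **Tilt** of each lipid is the angle between z and the eigenvector of the
  smallest eigenvalue of the mass-weighted inertia tensor of its tail
  beads, folded to [0°, 90°] because a director is headless.  Its
  dispersion is reported as the pooled per-molecule standard deviation
  across leaflets, frames and replicates (the standard pooled formula); all
  other metrics report the SD across replicate means, `NA` (not zero) for a
  single replicate.
* **S2** is the largest eigenvalue of
  $Q = \tfrac{3}{2}\langle u\,u^{\top}\rangle - \tfrac{1}{2}I$ over the same
  molecular directors, bounded in $[-0.5, 1]$; parallel directors give 1,
  planar-isotropic 0.25, isotropic 0.
* **Thickness** is the peak-to-peak distance of the total mass density
  profile (not a headgroup-only profile), with 3-point parabolic refinement
  of each peak.  On each side of the profile's mass midpoint the *flanking*
  (outermost) maximum reaching half that side's tallest maximum is used:
  interdigitating chains can raise a midplane ridge comparable to the
  headgroup peaks, and the flanking rule keeps the measurement anchored to
  the headgroup planes without ever smoothing the profile.
* **Interdigitation** integrates the density-overlap functional
  $\lambda = 4\int \rho_t\rho_b/(\rho_t+\rho_b)^2\,dz$ by the trapezoidal
  rule over the shared grid, with the integrand defined 0 where both
  densities vanish.  Top/bottom lipids are split by headgroup position
  relative to the pair midpoint, recomputed per frame.  $\lambda$ is
  symmetric, vanishes for disjoint profiles and equals $w$ for identical
  rectangles of width $w$.
* **Extended fraction**: a ceramide is extended when the angle between its
  two tail direction vectors exceeds 90°.  Each vector runs from the chain's
  first (headgroup-proximal) tail bead to the chain's center of mass — the
  anchor point is not pinned down in the source description; first-tail-bead
  → tail-COM is the documented default.
* Directors and extended-conformation vectors unwrap each molecule by the
  minimum-image convention first, so wrapped frames are handled exactly.

## Synthetic configurations and their ground truth

`gen_bilayer()`/`gen_multilayer()` place lipids on a hexagonal lattice with
the box sized so the requested APL is exact, straight chains at a collective
tilt, headgroup planes at the requested spacing (pairs separated by a 0.4 nm
gap in multilayers), an exact count of extended ceramides, water slabs only
at the outer faces, and isotropic Gaussian positional noise added last.
Defaults are fixed at the study conditions the metrics target: APL
0.40 nm² (pure CER gel phase), 5.3 nm leaflet-pair spacing, 10 four-water
beads per lipid, 0.1 nm positional noise (a typical gel-phase RMS
displacement).

Geometry choices that make recovery exact rather than approximate:

* The two ceramide chains share the same *mass-weighted* mean depth and
  their lateral separation lies along the in-plane normal to the chain
  axis, so the least-inertia axis equals the chain direction identically at
  any tilt; extended ceramides flip the sphingoid chain through the
  headgroup plane collinearly with the acyl rod.
* The C24 acyl chain (and FFA) carries the midplane overlap
  (`overlap`/2 past the midplane each side); the shorter sphingoid base and
  the sterol rod stop 0.45 and 0.7 nm short.  The interdigitation band
  therefore carries single-chain density, the way tapering chain ends do in
  real lamellae, instead of an artificial doubled-density ridge.
* A per-molecule uniform protrusion of the chains along their own axis
  (±0.2 nm) smooths the bead comb in density profiles without moving
  headgroups or rotating axes.

The geometric `overlap` parameter is not numerically identical to the
overlap functional $\lambda$ on discrete-bead profiles (edge blur saturates
the integrand; bead combs deflate it), so the generator emits as ground
truth the exact $\lambda$ of the *expected* profiles — the ideal bead
positions convolved with the noise kernel on a 0.005 nm grid.  That is the
quantity the binned single-frame estimator converges to, and a pre-freeze
design study showed 0.1 nm bins recover it within a few percent at the
default noise; the recipe's `overlap` remains the monotone control.

What the generator does *not* emulate: thermodynamics (no energies, no
self-assembly), conformational disorder beyond the protrusion jitter,
headgroup rotameric structure, undulations, or CHOL geometric realism (a
short rigid rod with tail factor 1.9 suffices for every implemented
metric).  Passing recovery tests therefore validates the *measurement*
pipeline, not any force field.

Problem sizes used by the test suite and acceptance script — a 500-lipid
pure-CER bilayer and an 1800-lipid six-leaflet 1:0.5:1 CER:CHOL:FFA
multilayer, 10⁶-sample inversion round trips — mirror the study systems'
lipid counts.

## Protocol arithmetic

`estimate_area()` gives the shape-annealing target
$A_{est} = APL_{est} \cdot N_{lipids}/N_{leaflets}$ (0.34 nm² × 1800 / 6 =
102 nm²); `initial_box()` sizes the random packing from a lipid density of
0.8 g/cm³ and water at 1 g/cm³; `build_schedule()` emits the full protocol
as data: two displacement-capped NVE preludes, 10 ns NPT density
equilibration, constant-volume expansion to 2.5 A_est over 150 ns at 500 K,
compression back to A_est with a linear 500→305 K ramp over 150 ns, an NPT
305→400→305 K defect anneal (100 + 50 ns) and 150 ns production at 305 K
and 1 bar — a 600 ns core.  Schedules are engine-agnostic structured text;
the displacement-cap details of the NVE preludes are engine-specific and
carried as annotations only.

## Numerical conventions

* Internal lengths are nm; bond samples convert to Å at the inversion
  boundary; masses are amu; temperatures K.
* Printed-table comparisons round half away from zero (`round_half_up()`):
  base R's half-to-even would turn 0.405/2 = 0.2025 into 0.202 where the
  field's tables print 0.203.
* k-means leaflet clustering is initialized at evenly spaced quantiles, so
  the assignment is deterministic; degenerate inputs (fewer distinct
  headgroup levels than leaflets) error with the found count.
* Composition ratios resolve to counts by largest-remainder rounding and
  error if any species drifts more than one molecule from its exact share.
* All generators take an integer seed and are bit-reproducible per seed.

## Known limitations

* The metric suite assumes lamellae normal to z with an orthorhombic box
  (the geometry the self-assembly protocol enforces); tilted or curved
  phases are out of scope.
* Nonbonded (pair-potential) derivation — the MS-IBI iteration itself — is
  deliberately out of scope; only bonded terms are derived here.
* Bimodal bonded distributions keep a flagged single-Gaussian compromise;
  multi-harmonic representations are not offered.
* The GRO reader is minimal (fixed-width columns, single frame); PDB and
  DCD go through bio3d when installed.  XTC is not supported in this stack.
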