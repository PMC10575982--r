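---
title: "Models and methods behind nanospringr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nanospringr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanospringr)
```

# The system

A DNA origami nanospring is a bundle of repeating origami modules whose
inter-module junctions can contract (G-quadruplex formation in the G-rich
bridge strand, in K⁺) or over-extend (hybridisation of an anti-GQ strand
into a stiff 21 bp duplex). Either event bends every junction the same way,
so the whole mesoscale object coils into a helix. `nanospringr` implements
the quantitative analyses such an experiment needs: force-extension and
force-jump analysis from optical tweezers, curvature/turn/chirality
statistics from AFM height maps, RMSD/RMSF and helix fitting for
coarse-grained (oxDNA-format) trajectories, and junction force estimates —
plus seeded generators that emulate each input class so the entire pipeline
is testable without instrument data.

# Mechanical model

The dsDNA handles follow the extensible (stretch-modulus corrected)
worm-like chain,

$$F = \frac{k_BT}{L_p}\left[\frac{1}{4\left(1 - x/L_0 + F/K_0\right)^2}
  - \frac14 + \frac{x}{L_0} - \frac{F}{K_0}\right],$$

with persistence length $L_p$ (nm), contour length $L_0$ (nm), stretch
modulus $K_0$ (pN) and $k_BT = 4.114$ pN·nm (298.15 K; the temperature is
configurable but fixed by default because no fitting temperature is stated
for this system). The force appears on both sides;
`wlc_force_at_extension()` solves the balance self-consistently by
bracketed root finding (the right-hand side is strictly decreasing in $F$,
so the root is unique), and `wlc_extension_at_force()` inverts it: writing
$u = x/L_0 - F/K_0$ and $c = F L_p / k_BT$, the balance becomes the cubic
$4v^3 + (4c-3)v^2 - 1 = 0$ in $v = 1-u$ with exactly one positive root,
found by a safeguarded Newton iteration started at the exact zero-force
solution $v = 1$.

The nanospring itself is a Hooke spring, $x_s(F) = x_0 + F/k$, and the full
construct is the series sum after force calibration:

$$x(F) = f_{\mathrm{WLC}}(F - F_0) + \frac{F - F_0}{k} + x_0 .$$

Note on conventions: one printed form of the spring law reads
$F = k(x + x_0)$, which is dimensionally consistent but disagrees in sign
with the construct equation above (which *adds* $x_0$ to the extension at
zero force). We implement $F = k(x_s - x_0)$, the only reading under which
the construct equation is the sum of its parts; likewise the squared
denominator of the WLC balance is implemented with $x/L_0$ (a printed
variant shows $x_0/L$ there, which would make the balance insoluble).

## A structural non-identifiability

The solution of the extensible WLC has the exact form
$x(F) = L_0\,u(F; L_p, k_BT) + F\,L_0/K_0$: the stretch modulus enters
*only* through a linear compliance $L_0/K_0$, which is perfectly collinear
with the Hooke compliance $1/k$ at every force. A fit of the construct
model therefore determines only the **total compliance**
$L_0/K_0 + 1/k$; the split between $K_0$ and $k$ is decided by the
optimiser's path, not the data. In practice the consequence is mild —
$1/k \approx 25$ nm/pN dominates $L_0/K_0 \approx 1$ nm/pN, so $k$ lands
within a couple of percent of truth — but fitted $K_0$ values from this
model should never be interpreted quantitatively. Tests assert recovery of
the identifiable parameters and of the compliance combination.

## Two-stage fitting and what precision to expect

`fit_construct()` mirrors the two-step procedure: stage 1
(`calibrate_force_offset()`) holds all mechanical parameters at supplied
values and fits only $F_0$, removing instrumental deviation near zero
force; stage 2 refits everything by bounded nonlinear least squares on the
extension residuals (the model is written as $x(F)$, so residuals are in
extension) within the 0.1–8.2 pN window where the Hooke description of the
nanospring holds. Bounds
($L_p \in [10, 100]$ nm, $K_0 \in [200, 5000]$ pN, $L_0$ within a factor 2
of its start, $k \le 10$ pN/nm, $F_0 \in [-2, 2]$ pN) keep the fit
identifiable on low-force data. Because a stage-1 $F_0$ computed against
badly wrong held parameters can sit at its search bound, stage 2 is
restarted from both that value and $F_0 = 0$ and the better basin is kept;
descent uses L-BFGS-B with parameter scaling followed by a `nls("port")`
polish (which also supplies standard errors). Port's "singular
convergence" code is accepted as converged — it is the expected diagnosis
of the $K_0/k$ ridge above.

A Cramér–Rao analysis at the synthetic stated world (500 points over
0.1–8.2 pN, extension noise $\sigma = 2$ nm, all parameters free) puts the
*statistical floor* on the zero-force length at
$\mathrm{SE}(x_0) \approx 29$ nm with constant-velocity sampling
(`ramp_force_grid()`, dense at low force where the information lives) and
$\approx 58$ nm with force-uniform sampling. Quoted experimental
precisions of a few nm therefore imply either far more data points or
externally pinned handle parameters; the package's recovery tests assert
the bound its own stated world supports (median error < 25 nm over seeds)
rather than an unattainable one. The spring constant, by contrast, is
determined to ~1–3% at the same design.

## Hysteresis

`hysteresis_area()` resamples stretch and relax curves onto a 200-point
uniform force grid by linear interpolation (raw traces are unevenly
sampled) and integrates their extension difference by the trapezoidal
rule. The area is signed — positive when the stretch curve lies at larger
extension — and antisymmetric under swapping its arguments. With unfolding
rips on the stretch branch the *relax* branch carries the released contour
down to lower forces, so the signed area of that physical situation is
negative; ordering comparisons in the tests use magnitudes.

# Force-jump analysis

`detect_jump_events()` cuts a temporal trace at force setpoint changes
≥ 0.4 pN, starting each analysed segment after a 10 ms settle interval
(the jump completion time). For each event, `measure_event()` defines

* $\Delta L$ — distance between the extension at segment start and the
  median extension of the final 10% of the segment;
* $t_{eq}$ — first time the extension enters a $2\sigma$ band around that
  final median and stays there; the band test is applied to a ~0.1 s
  running median because with Gaussian noise ~5% of raw samples exceed
  $2\sigma$ forever, which would otherwise push $t_{eq}$ to the segment
  end;
* rate $= \Delta L / t_{eq}$, a mean recoiling/uncoiling velocity (whether
  published kinetics are mean velocities or initial slopes is not stated;
  the mean-velocity convention is implemented).

`spring_constants_from_events()` regresses final force on $\Delta L$
(Hooke's $F/\Delta L$; the spring constant is the absolute slope)
separately below and above the 2 pN regime breakpoint — the entropic /
enthalpic bifurcation — with ties assigned to the low (entropic) regime.
Protocol *reset* jumps (returns to the holding force) share a final force
but not a reference state and must be excluded before regression; the
recommended filter keeps events starting at the measurement hold (e.g.
recoils with `F_start > 25`).

The synthetic generator relaxes the spring exponentially toward the
equilibrium of a bilinear spring law while the handles re-equilibrate
instantly; the ~2% of the amplitude relaxing during the settle interval is
the price of the segment-start convention and stays well inside the 5%
recovery tolerance with the repeated-schedule defaults.

# AFM topology

Images use the image convention (origin top-left, x along columns, y down
rows, positions in nm = pixel index × pixel size). `trace_backbone()`
thresholds, keeps the largest 8-connected component, thins it with the
Zhang–Suen algorithm and orders the skeleton along its longest path (two
BFS sweeps); branches are dropped with a warning. `curvature_radius()`
uses a Taubin algebraic circle fit refined geometrically, guarded against
collinear input via the covariance condition number; turns are arclength
over circumference, $2\pi r$ — the only formula consistent with counting
turns "from the curvature radius"; its exact relation to the published
histogram procedure is not documented, which is why the convention is
stated here.

Handedness on a surface is read at a bundle crossing: a tip can image
uphill flanks reliably but parachutes downhill, so `uphill_slope()`
regresses height on distance over the 20–80% band of the ascending flank
only (window bounds are a package choice; the published analysis does not
state its own). The statistic is $\Delta = s_{AB} - s_{CD}$ with the
convention that the A-B line lies along the bundle that passes underneath
when the helix is right-handed: $\Delta > 0 \Rightarrow$ right-handed.
Section lines are user-supplied (as in the original analysis); a helper
locates the crossing as the smoothed height maximum. The generator renders
two Gaussian-profile ridges; the overpassing bundle climbs over the other
on a ramp `bend_factor` (default 2) times the bundle width — a deliberate
simplification of tip–sample convolution that is adequate because only the
*relative* uphill slopes are consumed downstream.

# Trajectory analysis

`read_oxdna()` parses the standard topology/configuration text layout
(three header lines per frame, 15 floats per nucleotide, positions kept)
converting 0.8518 nm per length unit — the community-standard constant;
only the 3.03 ps time unit is stated for this system — and 3.03 ps per
time unit. RMSD is computed, per the definition used for equilibration
monitoring, as the root mean squared per-entity distance from the *first
frame with no superposition* (so a rigid 5 nm translation reads exactly
5 nm; an aligned variant exists but is off by default). RMSF uses each
entity's window-mean reference over the 2000–3000 ns window, which selects
exactly 100 frames at 10 ns spacing (half-open interval).

`fit_helix()` follows the HELFIT idea: estimate the axis (initialised from
the mean cross product of successive chords, which is exact for uniform
sampling over full turns), project points onto the axis-normal plane, fit
a circle (Taubin) for radius/centre, unwrap the phase and fit axial
displacement linearly against it for the pitch; the axis is refined by
direct search on the combined radial-plus-axial residual to tolerance
1e-10. Handedness is the sign of the mean chord-tangent triple product
against the axis oriented along the point ordering, reported
indeterminate when the residual RMS is not smaller than the radius. Which
26 entities constitute "backbone" and "pier" is design-specific, so index
pairs are a required user input; `average_guide_points()` reduces them to
13 midpoints. `compare_backbone_pier()` reports $r_{pier} - r_{backbone}$:
positive means the backbone runs inside the coil (over-extended junctions
push piers outward), negative outside (contracted junctions pull piers
inward). Outliers are not excluded automatically — published analyses did
so manually, and that judgement is left to the caller.

# Synthetic data: what a green test establishes

All generators are pure functions of their seed (same seed, bit-identical
output; the caller's RNG stream is untouched) and add iid Gaussian noise
on the observed coordinate — the simplest model sufficient for recovery
testing, since no instrument noise model is published. Rip amplitudes for
hysteresis emulation (default: ~8 nm contour per junction event, spread
over the unfolding force range) are illustrative, not measured values.
The generators reproduce the statistical *structure* the analyses assume —
not drift, tip convolution, force-dependent noise, or real polymer
dynamics. A green recovery test therefore establishes correctness of the
estimators on their stated model, not instrument-grade validity.

Default generator parameters are the system's published operating points:
the GQ-NS truth set (Lp 50 nm, L0 1244 nm, K0 1298 pN, k 0.04 pN/nm,
x0 189 nm), 30 pN holds with 0.5–10 pN jump targets, 2 pN regime
breakpoint, coil radii 25.8/43.9 nm, 3.5/1.7 turns, pitch 39 nm. Where no
value is stated we chose once: relaxation constant τ = 0.5–0.7 s (matches
the tens-of-seconds-scale recoil events at the published ~29 nm/s mean
velocity), extension noise 1–2 nm, force channel noise 0.05 pN, sampling
5 ms, AFM bundle height 2 nm / width 4 nm / pixel 1 nm / tip blur 2 nm.

# Numerical choices

* WLC root finding: bracket grown geometrically, relative tolerance 1e-9;
  inversion by vectorised Newton with bisection fallback.
* Circle fit: Taubin characteristic polynomial solved by Newton from 0,
  then geometric refinement (BFGS on the centre); collinearity rejected at
  condition number 1e8.
* Helix axis search: Nelder-Mead over two tangent-plane angles, reltol
  1e-10.
* Hysteresis resampling: 200-point uniform force grid, linear
  interpolation, `ties = mean`.
* Tie-breaks: jump events at exactly the breakpoint go to the entropic
  regime; chirality calls within `tolerance` (default 1e-3 nm/nm) of zero
  are indeterminate.

# Known limitations

* Fitted $K_0$ (and the exact $K_0/k$ split) is not meaningful — see the
  non-identifiability note.
* Zero-force length recovery is information-limited at desk-scale noise;
  see the Cramér–Rao discussion.
* TIFF input is not supported in this build (no TIFF reader available
  among the permitted dependencies); AFM images use whitespace-delimited
  text matrices.
* No drift correction, tip deconvolution, or automated molecule detection;
  rip (unfolding event) detection is out of scope.
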