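---
title: "Methods: selectivity-filter collapse analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: selectivity-filter collapse analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfcollapse)
```

This vignette is the package's account of its methods: the models and
conventions behind each analysis, the tunable parameters with their
defaults and units, what the synthetic generators emulate (and do not),
and the numerical choices made where the underlying experimental
literature leaves the design open.

## The collapse coordinate

C-type inactivation of hERG is modelled as a conformational change of the
selectivity filter (SF, residues S624–G628) from a conductive geometry
(analogous to the high-K⁺ KcsA crystal form) toward a collapsed geometry
(the low-K⁺ form). The package condenses that transition into one scalar.

Given two reference conformations A (conductive) and B (collapsed),
`build_reaction_coordinate()` superposes B onto A on a chosen atom
selection (default: the SF backbone, `"resnum 624-628 and name N CA C O"`)
using a proper-rotation Kabsch fit, and takes

$$u = \frac{B - A}{\lVert B - A\rVert}, \qquad
  s(x) = \frac{(x - A)\cdot u}{\lVert B - A\rVert},$$

after superposing the frame $x$ onto A on the same selection. For a
two-structure ensemble the first principal component *is* the mean-centred
difference direction, so the coordinate is implemented as the explicit
normalized difference: numerically exact, with no eigen-solver sign
ambiguity (the sign is fixed so the collapsed reference maps to +1). An
eigen-decomposition implementation exists only as an independent oracle in
the test suite, where the two must agree to $|\cos| \ge 1 - 10^{-9}$.

Conventions and parameters:

* $s$ is dimensionless with $s(A) = 0$ and $s(B) = 1$; excursions outside
  $[0, 1]$ are legitimate and preserved. Because the axis units of
  published projection traces are not fixed by convention, the raw
  displacement in Å ($s \cdot \lVert B-A\rVert$) is emitted alongside.
* Frames are aligned on the reaction-coordinate selection itself (the SF
  backbone) before projection, matching the restrained-reference protocol
  of the simulations this analysis is designed for. Aligning on a larger
  region instead is possible by building the coordinate from a different
  selection; the choice is exposed, not guessed.
* `endpoint_projection()` averages $s$ over frames with $t \ge$
  `burn_in`; the default burn-in is 40 ns (40000 ps), the convention for
  discarding the approach transient so that the endpoint characterizes
  the plateau. It is configurable per call and per manifest.
* `ensemble_trace()` combines runs by nearest-frame matching on a declared
  common grid and reports mean and SEM $= \mathrm{sd}/\sqrt{n}$ per time
  point. Single-run traces are never smoothed. With the typical $n = 4$
  runs a $\pm 2\,\mathrm{SEM}$ band is a $t_3$ interval with true coverage
  0.861, not 0.95 — the tests assert the former.
* `build_reaction_coordinate(..., superpose_refs = FALSE)` skips the
  B-onto-A fit. The default (`TRUE`) removes any rigid-body difference
  between the references, which also means a single-atom displacement is
  partially absorbed into the fit; the raw-difference mode is provided for
  references already expressed in one frame where the literal displacement
  norm is wanted.

## RMSF against the distance scan

`rmsf()` uses the standard two-pass procedure: every frame is superposed
(on the alignment selection, default = the measured selection) onto frame
1, the mean structure is computed, all frames are refit onto that mean,
and $\mathrm{RMSF}_i = \sqrt{\langle \lvert r_i - \langle r_i\rangle
\rvert^2\rangle}$. Fitting to the mean rather than to an arbitrary frame
removes the reference-frame bias of a single-pass fit; the alignment
selection for published RMSF analyses is rarely stated, so it is a
parameter. No mass weighting is applied (the analysed atoms are typically
all carbonyl oxygens). For isotropic Gaussian positional noise of
standard deviation $\sigma$ per coordinate the expected RMSF is
$\sigma\sqrt{3}$, which the tests exploit as a closed-form oracle.
Per-residue aggregates are arithmetic means over the four subunits, with
per-chain values retained; `rmsf_vs_scan()` tabulates them against the
scan label $d$.

## Hydrogen-bond switch classification

Published H-bond counts rarely state the geometric criterion used. The
package defaults to the common MD-analysis convention and documents it as
a package choice, configurable via `hbond_criteria()`:

* donor–acceptor heavy-atom distance $\le 3.5$ Å;
* with explicit hydrogens, deviation of H from the D→A line $\le 30°$;
* without hydrogens (`heavy` mode, the default), an antecedent angle
  C–D···A $\ge 90°$ suppresses geometric false positives;
* self pairs, same-residue pairs and covalently bonded pairs
  (d < 1.6 Å) are excluded.

`hbond_series()` counts, per frame, bonds in which the focal residue's
polar side-chain atoms (N629's amide group by default, as donor *or*
acceptor) participate, summed over the four chains and split intra- versus
inter-subunit. "Neighboring subunit" means *any other chain*, not only the
ring-adjacent one. Raw integer counts are the primary output; rolling-mean
smoothing (`smooth_hbond_series()`) is presentation-layer with the window
as a parameter. `contact_fraction()` reports windowed intra/inter
fractions; frames without bonds contribute to neither numerator nor
denominator, and an entirely bond-free window yields `NA` rather than a
fabricated fraction.

## Side-pocket accessibility

`grid_accessibility()` implements probe-center accessibility: a cubic grid
(spacing 0.5 Å by default, anchored at the region center so results are
translation-reproducible) is laid over a spherical region (default radius
18 Å, the receptor-region convention around S620), and a point is
accessible iff its distance to every protein heavy atom is at least that
atom's van der Waals radius plus the probe radius (1.4 Å, a water-sized
probe; Bondi-style radii shipped with the package, unknown elements
rejected rather than defaulted). Accessible points are partitioned into
26-connected components; volumes are point counts times the cell volume.
This is deliberately *not* a molecular-surface volume: probe-center
accessibility is the simplest operational reading of "accessible to a
water-sized molecule" and has an analytic ground truth (a spherical shell
of atoms leaves a spherical accessible interior), which makes the
implementation testable to within grid-discretization error — 5% at 0.5 Å
spacing and 2% at 0.25 Å for a 4.6 Å cavity, improving under refinement.
`pocket_timeseries()` reports the largest-component volume per frame and
an open fraction; the open/closed threshold defaults to half the first
frame's volume, a reference-state convention chosen because no published
number exists — it is a parameter, and the underlying volume series is
always available.

## The distance-scan pipeline

`run_scan()` consumes a manifest (in-memory list or YAML/JSON file)
grouping trajectories by the S620–N629 Cβ–Cβ restraint target $d$. The
scan label and the realized distance are distinct quantities that are easy
to conflate: $d$ is kept as the group label, and the mean realized Cβ–Cβ
separation is re-measured from the trajectories (`pair_distance_by_chain`)
and reported alongside as `d_measured`. Per group the pipeline computes
the endpoint projection, RMSF summary and H-bond fractions, then fits
`s_endpoint ~ d` by OLS over a declared window. The default window is
5–11 Å: beyond 11 Å the filter backbone over-stretches and the
response changes regime, so the 12 Å point is excluded from the default
fit. The fit is a diagnostic summary of near-linearity, not a mechanistic
model. Missing trajectory files abort before any computation, and
identical manifests plus seeds produce byte-identical output tables (no
timestamps are written into files).

## Electrophysiology fits

The Boltzmann form is $f(V) = 1/(1 + \exp((V_{1/2} - V)/k))$ with $k > 0$
for activation (ascending: depolarization increases conductance) and the
descending branch $1/(1 + \exp((V - V_{1/2})/k))$ for steady-state
inactivation. Published equation typography varies; these signs are fixed
by the biology. Fits use Levenberg–Marquardt least squares with
deterministic initialization — $V_{1/2}$ from the half-maximum crossing of
the linearly interpolated data, $k$ from the 25–75% span divided by
$\operatorname{logit}(0.75) - \operatorname{logit}(0.25) = 2.197$ — so
results are reproducible without hidden state. A residual-sd lack-of-fit
check (default 0.15 on the normalized scale) flags two-phase conductance
curves instead of silently fitting them; a fixed-slope mode
(`k_fixed`) supports midpoint estimation from few points under the
assumption that a mutation leaves the slope unchanged.

Deactivation is fit as $A e^{-t/\tau} + C$. The steady-state inactivation
measure is the ratio of the current remaining 100 ms after pulse onset to
the instantaneous current at onset; the instantaneous amplitude is the
linear extrapolation of the first 5 samples to the onset time (synthetic
traces are capacitive-transient-free, so no transient rejection is
implemented), and the remaining amplitude is linearly interpolated at
onset + window. With densely sampled onsets the extrapolation error is
negligible (the $e^{-t/50\,\mathrm{ms}}$ closed-form check holds to
$10^{-6}$).

## What the synthetic generators emulate

The generators produce every input class the analyses consume, with exact
sidecar ground truth; downstream tests read truth only from sidecars.

* `make_reference_pair()` builds an idealized four-chain SF stand-in
  (residues 624–628 backbone, S620 with Cβ/Oγ, N629 with Cβ and amide
  group), 4-fold symmetric about z. The collapsed form pinches the central
  carbonyl oxygens (625/626) radially inward by 0.7 Å per atom. The
  carbonyl oxygens sit at tangential offset zero by construction, so the
  displacement field has zero net translation and zero net torque over the
  ring and the programmed span ($0.7\sqrt{8} \approx 1.98$ Å) survives the
  reference superposition exactly.
* `make_collapse_trajectory()` follows a programmed path $s_\mathrm{true}(t)$
  (default: linear rise to the plateau at 40 ns, constant to 50 ns, in
  1-ns frames — mirroring the time scale on which collapse is observed)
  plus iid $N(0, \sigma^2)$ noise per coordinate, default
  $\sigma = 0.3$ Å, a realistic thermal positional spread for backbone
  atoms. `make_scan_ensemble()` programs the plateau as
  $s_\mathrm{true}(d) = (10 - d)/5$ — collapse at 5 Å, conductive at
  10 Å, slope −0.2/Å — with 4 runs per $d$, the simulation count per scan
  point in the study design this emulates.
* `make_hbond_toggle()` switches all four N629 amide donors between the
  own-chain S620 Oγ (intra) and the next chain's G628 carbonyl (inter)
  by a seeded per-frame Bernoulli draw, with all competing donor–acceptor
  distances kept beyond the cutoff so the classification is unambiguous.
* `make_cavity_structure()` places shell atoms on a Fibonacci sphere at
  ~0.5 Å spacing — dense enough that a 1.4 Å probe cannot leak — giving an
  analytically known accessible interior.
* `make_recordings()` produces activation tables over −90..+40 mV in
  10-mV steps (the standard pulse protocol) from a Boltzmann with
  $V_{1/2} = -28.5$ mV, $k = 7.41$ mV, deactivation traces with
  $\tau = 73.2$ ms, and inactivation test pulses whose 100-ms ratios
  follow a descending Boltzmann with $V_{1/2} = -18.8$ mV; the
  inactivation slope factor (7 mV) and fast inactivation time constant
  (20 ms) are typical wild-type hERG magnitudes chosen once, since the
  emulated protocol does not pin them down.

What they do **not** emulate: force-field physics, ions and water,
membrane context, side-chain packing realism, capacitive transients or
leak currents. Passing recovery tests therefore demonstrates that the
*analysis chain* is correct and unbiased at known signal-to-noise, not
that real trajectories will be as clean; on real data the same code paths
apply but statistical error is set by the simulations themselves.

Each generator seeds one Mersenne–Twister stream (R's default RNG) from
its `seed` argument and is bit-reproducible.

## Numerical choices and degenerate inputs

* Superposition is Kabsch via SVD with the determinant correction, so a
  reflection is never returned; near-collinear point sets (second singular
  value below $10^{-12}$ of the first) are rejected.
* Reference pairs that coincide after superposition (span $< 10^{-6}$ Å)
  raise a degenerate-coordinate error rather than producing an unstable
  unit vector.
* PDB parsing is strict fixed-column: `HETATM` ignored, altloc other than
  blank/`A` dropped, insertion codes rejected, malformed lines reported
  with their line number, and atom counts must agree across `MODEL`
  blocks. Atoms are canonically ordered (chain, residue number, then N,
  CA, C, O before side-chain atoms alphabetically) so coordinate vectors
  are congruent across files. Trajectory frame times default to
  0, 1, 2, … ps and are preserved across round trips via `REMARK 250
  TIME` records.
* Grid volumes are reported from raw point counts; no surface smoothing
  or partial-cell correction is applied, keeping the discretization error
  analysable.
* Single-frame RMSF, empty contact windows, constant-amplitude Boltzmann
  input, non-decaying exponential input and zero instantaneous amplitude
  are all explicit errors (or `NA` where a denominator is legitimately
  empty), never silent numbers.

## Problem sizes used in the validation suite

The shipped tests and `scripts/acceptance.R` validate at sizes chosen to
give tight statistical power while remaining desk-scale: 10⁴ frames for
the RMSF closed form (2% tolerance on $\sigma\sqrt 3$), 2000 frames for
the Bernoulli H-bond toggle (binomial 95% CI on 0.30), six scan distances
× 4 runs × 51 frames for the scan recovery (slope within 10% of −0.2),
a ~3000-atom shell at 0.25 Å grid spacing for the cavity volume, and 200
Monte-Carlo repeats for the noisy Boltzmann bias bound (±0.5 mV at noise
sd 0.02). Full-scale MD observables (multi-100-ns trajectories of a
solvated membrane protein) are out of scope by design.

## Known limitations

* Multi-model PDB is the only trajectory interchange format; binary MD
  formats would enter through external conversion.
* H-bond detection has no energetic model and no water-mediated bridges.
* The two-structure coordinate cannot resolve motions orthogonal to the
  A→B difference (by construction they project to zero); it is a collapse
  gauge, not a free-energy coordinate.
* The pocket module measures accessibility, not binding: no docking,
  scoring or ligand parameterization.
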