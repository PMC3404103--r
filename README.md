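# sfcollapse

Trajectory and electrophysiology analysis for potassium-channel
selectivity-filter (SF) inactivation, centred on the hERG channel.

C-type inactivation of hERG is thought to proceed through a conformational
collapse of the selectivity filter, toggled by an intra-subunit contact
between S620 and N629 behind the filter. `sfcollapse` provides the analysis
chain with which that mechanism is characterized from molecular-dynamics
trajectories and two-electrode voltage-clamp recordings:

- **Collapse coordinate** — a collective coordinate between a conductive
  (high-K⁺, 1K4C-like) and a collapsed (low-K⁺, 1K4D-like) reference
  geometry of the SF backbone. After superposing B onto A, the coordinate
  of a frame *x* is the projection onto the normalized difference vector

  *s* = ((x − A) · u) / |B − A|, with u = (B − A)/|B − A|,

  so *s* = 0 at the conductive and *s* = 1 at the collapsed reference (for
  a two-structure set this direction is exactly the first principal
  component of the pair). Post-burn-in endpoints (default 40 ns) and
  ensemble mean ± SEM traces summarize simulations.
- **RMSF profiles** — two-pass (mean-structure) root-mean-square
  fluctuations of selected atoms, e.g. the carbonyl oxygens of S624–F627,
  tabulated against a restraint-distance scan label *d*.
- **Hydrogen-bond switch** — geometric H-bond detection (D–A ≤ 3.5 Å plus
  an angle criterion) with intra- versus inter-subunit classification of a
  focal side chain (N629 by default), as per-frame counts and windowed
  fractions.
- **Side-pocket volume** — grid-based probe-center accessibility (water-
  sized probe, 1.4 Å; Bondi vdW radii) in a spherical region, with
  26-connected component analysis and per-frame volume series.
- **Scan pipeline** — groups trajectories by the S620–N629 Cβ–Cβ distance
  *d*, computes endpoints, RMSF and H-bond fractions per *d*, and fits
  *s*(d) by ordinary least squares over a declared window (default
  5–11 Å).
- **Electrophysiology fits** — Boltzmann conductance–voltage relations
  *f(V) = 1/(1 + exp((V½ − V)/k))* (descending branch for steady-state
  inactivation, optionally with fixed slope), single-exponential
  deactivation *A·exp(−t/τ) + C*, and the 100-ms steady-state inactivation
  ratio (remaining / instantaneous current).
- **Synthetic generators** — every input above can be generated in-package
  with known ground truth (programmed collapse paths, Bernoulli H-bond
  toggles, analytic shell cavities, Boltzmann/exponential recordings), so
  all analyses are validated by parameter recovery.

Structures and trajectories are fixed-column (multi-model) PDB; tabular
output is TSV with `#` parameter headers.

## Worked example

```r
library(sfcollapse)

refs <- make_reference_pair()                      # conductive + collapsed SF
rc <- build_reaction_coordinate(refs$conductive, refs$collapsed,
                                refs$sf_selection)
rc
#> <reaction_coordinate> 80 atoms, span 1.980 A, selection "resnum 624-628 and name N CA C O"

# synthetic distance scan: s_true(d) = (10 - d)/5, 4 runs per d, 0.3 A noise
man <- make_scan_ensemble(5:10, runs = 4, sigma = 0.3, seed = 1)
report <- run_scan(man)
report
#> <scan_report> 6 scan point(s), burn-in 40000 ps
#>  d_target d_measured  s_endpoint s_endpoint_sem rmsf_mean ...
#>         5   5.028429  1.00149277    0.011152170 0.5401778
#>         6   6.037992  0.78867618    0.017785559 0.5258612
#>         7   7.055125  0.59724526    0.020561746 0.5205839
#>         8   8.010288  0.37213275    0.035104745 0.5183994
#>         9   9.005229  0.20609264    0.015730073 0.5066396
#>        10  10.027213 -0.03630576    0.002606696 0.5142177
#> linear fit over d = 5-11 A: slope -0.2046, intercept 2.0229

rec <- make_recordings(noise_sd = 0)               # synthetic recordings
fit_boltzmann(rec$iv$V, rec$iv$amplitude)
#> <boltzmann_fit> ascending: V_half = -28.50 mV, k = 7.41 mV (rss 5.05e-32)
fit_exponential(rec$deactivation$time, rec$deactivation$current)
#> <exp_fit> tau = 73.20 ms, A = 1, offset = 4.008e-11 (rss 5.4e-19)
```

Reading the scan report: at the shortest S620–N629 separation (d = 5 Å)
the filter reaches the collapsed state (endpoint s ≈ 1), at d = 10 Å it
stays conductive (s ≈ 0), and the endpoint falls almost linearly in
between — slope −0.205 per Å against the programmed −0.2. The `rmsf_mean`
column is the mean carbonyl-oxygen RMSF in Å (here set by the generator's
0.3 Å positional noise: 0.3·√3 ≈ 0.52). The electrophysiology fits return
the generator's parameters (V½ = −28.5 mV, k = 7.41 mV, τ = 73.2 ms)
exactly in the noiseless case.

A command-line wrapper with subcommands `simulate`, `project`, `rmsf`,
`hbonds`, `pocket`, `scan` and `ephys-fit` is installed at
`inst/cli/sfcollapse.R`:

```sh
Rscript inst/cli/sfcollapse.R simulate --d-values 5,10 --runs 2 --seed 3 --out-dir demo
Rscript inst/cli/sfcollapse.R scan --manifest demo/manifest.yaml --out-dir demo/out
```

## Selection grammar

Selections are conjunctions of clauses joined by `and`; each clause is a
keyword followed by one or more values:
`chain A B`, `resnum 624-627` (ranges or lists), `resname SER ASN`,
`name N CA C O`, `element N O`. Example:
`"resnum 624-628 and name N CA C O"` — the SF backbone.

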