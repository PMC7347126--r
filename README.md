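# kdelclust

Quantification and stochastic modelling of membrane receptor clustering.

A sub-population of KDEL receptors (KDELRs) resides at the plasma
membrane, where binding of K/HDEL-bearing cargo induces the formation of
bright receptor clusters that can be followed by live-cell fluorescence
microscopy. Whether clusters form at all — and how fast, and with what
size statistics — depends on the balance between receptor internalization
(endocytosis) and vesicular delivery back to the surface (exocytosis),
and on how strongly delivery is focused on preferred docking sites.
`kdelclust` provides the complete computational tool chain for studying
this phenomenon, for microscopists quantifying cluster dynamics and for
modellers exploring the underlying rate theory:

* **Imaging pipeline** — grayscale conversion, anisotropic Gaussian
  background estimation, peak-to-background ratio thresholding,
  Hoshen–Kopelman (union–find) cluster labeling with 4/8-connectivity
  and optional periodic boundaries, log-binned cluster-size
  distributions P(A) with power-law fits P(A) ∼ A^(−α), perimeter-scaled
  density time series, and segmentation of the time course into
  transient, exponential-growth and steady-state regimes.
* **Lattice simulator** — continuous-time Monte Carlo of receptor loss
  and delivery on a periodic square lattice (5 nm sites): endocytosis
  excises random discs of 5–10 sites radius (50–100 nm clathrin
  vesicles); exocytosis delivers receptors into discs centered at
  multi-peaked Gaussian hot spots. Event rates are calibrated so the
  realized per-receptor loss rate is κ_endo and the per-internal-receptor
  delivery rate is κ_exo.
* **Master-equation theory** — the surface fraction f obeys
  ḟ = −κ_endo f + κ_exo (1 − f), with steady level
  f_s = κ_exo/(κ_endo + κ_exo), characteristic time
  t_s = 1/(κ_endo + κ_exo), and solution
  f(t) = f_s + (f0 − f_s) e^(−t/t_s). The module exposes the
  (κ_endo, κ_exo) phase-space border lines, the detectability threshold
  line κ_endo = (−1 + 1/f_s^c) κ_exo, and the effective rate
  κ′_endo = n κ_endo.
* **Preferential-attachment growth model** — arriving receptors dock at
  an existing cluster with efficiency β (choosing it proportionally to
  its size A_i/ΣA_j) or seed a new cluster; the size distribution decays
  as P(A) ∼ A^(−α) with α = 1 + 1/β.
* **Synthetic-microscopy generator** — renders ground-truth time-lapse
  stacks (power-law cluster sizes at hot spots, a master-equation-shaped
  density course, Gaussian PSF and camera noise), so every pipeline
  stage is testable end to end without experimental data.

## Worked example

Generate a synthetic recording (80 frames, 10 s apart, planted exponent
α = 2, transient 50 s, saturation time t_s = 100 s) and quantify it:

```r
library(kdelclust)

sc    <- scenario(seed = 1)          # study conditions; all fields tunable
gt    <- build_ground_truth(sc)
stack <- render_stack(gt)
stack
#> frame_stack: 80 frames of 192 x 192 px, pixel size 0.1 um
#>   time span 0 .. 790 s

res <- analyze_stack(stack, cell_mask = gt$geometry$cell_mask,
                     threshold_ratio = sc$threshold_ratio,
                     widths = sc$bg_widths, min_frame = 56,
                     fit_range = c(16, 1e4))
res
#> cluster_analysis: 80 frames, 3084 cluster detections
#>   size-distribution exponent alpha = 1.940 (se 0.106)
#>   regimes: transient to 60 s, growth to 150 s, steady 18.78
```

The fitted exponent (1.94 ± 0.11) recovers the planted α = 2; the
transient end (60 s) and growth end (150 s) recover the planted change
points (50 s and 50 + 100 s) to one frame interval; the steady density
(18.8 occupied px per µm of cell perimeter) is the plateau about which
the signal fluctuates.

On the theory side, at the reference rates of cluster-forming cells
(κ_endo = 1e−4/s, κ_exo = 0.5e−4/s):

```r
steady_state_fraction(reference_rates())   # 0.333
characteristic_time(reference_rates())     # 6667 s
required_endo_rate(0.5e-4, fs_c = 0.02)    # 24.5e-4 /s  (~25x reference)
characteristic_time(rate_pair(24.5e-4, 0.5e-4))  # 400 s (~7 min)
```

i.e. pushing the steady surface fraction below the detectability
threshold f_s^c = 0.02 — the non-clustering (macrophage-like) phenotype —
requires a ~25-fold higher endocytosis rate (or, via
`required_exo_rate()`, a ~25-fold lower exocytosis rate), and such a
cell relaxes to its steady state within minutes.

A thin command-line wrapper for the imaging pipeline ships in
`inst/scripts/analyze.R`.

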