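# sptdiff

Diffusion-coefficient estimation for 2D single-particle tracking (SPT).

Single-molecule imaging reduces a membrane molecule — a receptor, a fixed
fluorophore — to a trajectory: fitted positions $(x_i, y_i)$ in µm at frame
interval $\Delta t$. Estimating the diffusion coefficient $D$ from such a
track is complicated by static localization noise (each position carries a
per-axis Gaussian error $\sigma$) and by motion blur (the camera averages
the position over its exposure, summarised by the blur coefficient $R$;
$R = 1/6$ for continuous illumination). `sptdiff` is for SPT practitioners
who want both of the standard per-trajectory estimators, and a principled
way to compare them:

* **MSD**: ordinary least squares through the first three points of the
  time-averaged mean-square-displacement curve, $D = \mathrm{slope}/4$,
  free $y$-intercept; sign-unconstrained.
* **MLE**: joint maximum likelihood for $(D, \sigma)$ under the Gaussian
  displacement model with tridiagonal Toeplitz covariance
  $\Sigma_{ii} = 2D\Delta t - 2(2DR\Delta t - \sigma^2)$,
  $\Sigma_{i,i\pm1} = 2DR\Delta t - \sigma^2$, maximising
  $L = -\log|\Sigma| - \frac12\Delta x^\top\Sigma^{-1}\Delta x -
  \frac12\Delta y^\top\Sigma^{-1}\Delta y$ over $D \ge 0$, $\sigma \ge 0$.
  Long tracks (> 1,000 frames) switch to an FFT-based circulant
  approximation of the same likelihood.

Around the estimators: a seeded Brownian-trajectory simulator with
localization noise and substep-averaged motion blur, trajectory CSV I/O, a
≥15-frame quality filter, convex-hull track areas, group summaries
(mean/SD/CoV), Kolmogorov–Smirnov group comparisons, length histograms, and
scripted simulation studies with plots. See
`vignettes/diffusion-estimation.Rmd` for the model, conventions and
numerical choices.

## Worked example

Simulate one condition (slow particles, realistic noise), estimate every
track by both methods, and summarise:

```r
library(sptdiff)
cfg <- sim_config(D_true = 0.05, eps = 0.1, dt = 0.033, n_frames = 501,
                  n_traj = 200, blur = TRUE, seed = 42)
tracks <- simulate_set(cfg)
tab <- run_method_comparison(tracks)
summarize_groups(tab)
#>   group method   n n_failed   mean      sd   cov
#> 1   all    MSD 200        0 0.0502 0.00904 0.180
#> 2   all    MLE 200        0 0.0500 0.00623 0.125
```

Both estimators recover the true $D = 0.05$ µm²/s in the mean, but the
MLE's coefficient of variation (0.125) is markedly smaller than the MSD's
(0.180): modelling the noise explicitly pays off exactly where diffusion is
slow relative to the localization error. Per-track results carry the
secondary parameter of each method — the MSD intercept (which absorbs noise
and blur) and the MLE's noise estimate $\hat\sigma$:

```r
fit_mle(tracks[[1]])
#> <mle_result: D = 0.04936 um^2/s, sigma = 0.09879 um, loglik = 1550 (direct)>
fit_msd(tracks[[1]])
#> <msd_fit: D = 0.05157 um^2/s, intercept = 0.03654 um^2 (lags 1,2,3)>
hull_area(tracks[[1]])
#> [1] 3.17  # um^2
```

$\hat\sigma \approx 0.099$ µm recovers the simulated 100 nm localization
error. Measured trajectories enter through the same door: a long-format CSV
with columns `traj_id, frame, x_um, y_um` (extra columns become
per-trajectory metadata, e.g. treatment groups), read with
`read_trajectories(path, dt = ...)`, filtered with `filter_by_length()`,
compared across groups with `compare_groups_ks()`. A thin command-line
front end (`inst/cli/sptdiff.R`) exposes `simulate`, `estimate` and
`compare` subcommands over the same functions.

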