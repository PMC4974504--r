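# fretdyn

Quantifying two-state open/close conformational dynamics of proteins
from single-molecule fluorescence: corrected smFRET
efficiency/distance distributions with two-Gaussian decomposition and
per-trajectory state classification, FRET-FCCS correlation analysis
with separate and global (shared-parameter) model fitting including an
intramolecular-dynamics time constant, and two-state kinetic rate
extraction.  Written for single-molecule biophysicists analysing
proteins like the SNARE Ykt6, whose longin domain and SNARE core
exchange between a closed and an open arrangement on the ~200 µs
timescale, and whose dynamics can be switched off by lipid binding.

Because such studies rarely deposit raw photon data, the package also
ships seeded simulators — a Brownian-dynamics confocal photon-stream
generator (two-state switching, triplet blinking, crosstalk,
background) and a binned TIRF trajectory generator with single-step
photobleaching — so the entire pipeline runs and is tested end to end
on data it can generate itself.

## The models

**smFRET.** Per 100 ms bin with donor/acceptor counts $I_D, I_A$:

$$E = \frac{I_A - \beta I_D}{(I_A - \beta I_D) + \gamma I_D},
\qquad R = R_0\,(1/E - 1)^{1/6},$$

with crosstalk fraction $\beta$, relative brightness factor
$\gamma = (\phi_A\eta_A)/(\phi_D\eta_D)$ and Förster radius $R_0$
(51 Å for Alexa 555/647).  Pooled distance histograms are decomposed
into two Gaussians (closed = smaller distance); each trajectory is
classified closed-only / open-only / both by per-bin posterior
assignment.

**FCS/FCCS.**  Each correlation curve follows the 3D-Gaussian
diffusion law
$D(\tau) = (1+\tau/\tau_D)^{-1}(1+\tau/(p^2\tau_D))^{-1/2}$ with a
triplet factor $1 + \tfrac{f}{1-f}e^{-\tau/\tau_T}$ on the
autocorrelations.  The global model shares the amplitude $N$, transit
time $\tau_D$ and intramolecular dynamics time $\tau_I$ across the
four curves and multiplies in the FRET-dynamics terms
$1+\alpha e^{-\tau/\tau_I}+\beta$ (AC-d),
$1+\gamma e^{-\tau/\tau_I}+\delta$ (AC-a), and
$1-\sqrt{\alpha\gamma}e^{-\tau/\tau_I}+\sqrt{\beta\delta}$ (CC).

**Kinetics.**  $\tau_I$ is the two-state relaxation time:
$k_{open} = P_{open}/\tau_I$, $k_{close} = (1-P_{open})/\tau_I$.

See the methods vignette (`vignettes/fret-fccs-methods.Rmd`) for
assumptions, defaults and numerical choices.

## Worked example

Fit the separate model to a noise-free autocorrelation generated from
the bundled apo reference parameters, then run the global four-curve
fit and convert to rates:

```r
library(fretdyn)

ref <- fccs_reference_params("apo", "separate")[["AC-d"]]
lag <- log_lags(1e-6, 10, 200)
curve <- data.frame(lag = lag, G = eval_separate(lag, ref))
fit_separate(curve, kind = "AC", init = ref)
#> Separate AC correlation fit
#>   N = 7.287, f = 0.282, tau_D = 208.5 us, p = 6.9, tau_T = 3.813 us
#>   rss = 4.245e-33, converged: TRUE (22 iterations)

gp <- fccs_reference_params("apo", "global")
curves <- synthesize_correlation_set(gp, log_lags(1e-6, 1, 160))
gfit <- fit_global(curves, init = gp,
                   fixed = list(f_d = gp$f_d, tau_T_d = gp$tau_T_d,
                                f_a = gp$f_a, tau_T_a = gp$tau_T_a,
                                p = gp$p))
gfit
#> Global shared-parameter FCCS fit (AC-d, AC-a, CC-da, CC-ad)
#>   N = 9.11, tau_D = 220 us, tau_I = 190 us
#>   alpha = 0.13, beta = 0.12, gamma = 0.000101, delta = 0.25, ...
#>   rss = 5.29e-20, converged: TRUE (200 iterations)

rates_from_relaxation(gfit$params$tau_I, p_open = 0.45)
#> Two-state exchange kinetics
#>   k_open  (closed -> open): 2368.42 1/s
#>   k_close (open -> closed): 2894.74 1/s
#>   P_open = 0.4500, P_closed = 0.5500
#>   relaxation time tau_r = 190 us
```

The separate fit recovers the exact generating row (transit time
208.5 µs through the focus, 28% triplet at 3.8 µs); the global fit
recovers the shared amplitude (`N` ≈ 9.1 molecules), transit time and
the 190 µs intramolecular relaxation, which combined with a 55/45
closed/open population splits into the two rate constants shown.

A simulated smFRET cohort (26 static molecules at the apo peak
positions, seed 42) and its decomposition:

```r
rs <- fret_reference_states("apo")
cfg <- trajectory_sim_config(n_trajectories = rs$n_trajectories,
                             state_distance_means = rs$means,
                             state_weights = rs$weights, seed = 42)
trajs <- simulate_fret_trajectories(cfg)
cls <- classify_cohort(trajs, fret_corrections(0.05, 1.2),
                       init = list(weights = rs$weights,
                                   means = rs$means, sds = rs$sds),
                       anchor = TRUE)
cls$pair
#> Two-Gaussian distance decomposition (R0 units)
#>   closed: w = 0.629, mu = 0.884, sd = 0.066
#>   open:   w = 0.371, mu = 1.334, sd = 0.071
cls$counts
#>  closed_only    open_only         both unclassified
#>           14           12            0            0
```

A single 26-molecule cohort carries ±10-point sampling noise on the
closed-state weight (here 63% against a 55% generating value); the
reproducible quantity is the median over seeded replicates, which the
acceptance script computes.  No static molecule is classified as
visiting both peaks.

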