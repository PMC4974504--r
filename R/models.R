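#' Parameter set for the separate (per-curve) correlation model
#'
#' The single-species 3D-Gaussian diffusion model with a triplet term,
#' fitted independently to each correlation curve:
#' \deqn{G(\tau) = \frac{1}{N}\,T(\tau)\,
#'   \left(1+\tau/\tau_D\right)^{-1}\left(1+\tau/(p^2\tau_D)\right)^{-1/2}}
#' with triplet factor \eqn{T(\tau) = 1 + \frac{f}{1-f} e^{-\tau/\tau_T}}.
#' Cross-correlation curves carry no triplet term (`f` is ignored for
#' `kind = "CC"`).  All times are seconds.
#'
#' @param N mean number of molecules in the focal volume (> 0).
#' @param f triplet amplitude in [0, 1).
#' @param tau_D transit (diffusion) time through the focus, seconds.
#' @param p lateral/axial aspect ratio of the focus (> 0).
#' @param tau_T triplet time constant, seconds.
#' @return A list of class `separate_params`.
#' @export
separate_params <- function(N, f = 0, tau_D, p, tau_T = 1e-6) {
  stopifnot(N > 0, f >= 0, f < 1, tau_D > 0, p > 0, tau_T > 0)
  structure(list(N = N, f = f, tau_D = tau_D, p = p, tau_T = tau_T),
            class = "separate_params")
}

#' Parameter set for the global (shared-parameter) FCCS model
#'
#' Four correlation curves (donor/acceptor autocorrelations AC-d, AC-a
#' and the two cross-correlations CC-da, CC-ad) are described with a
#' shared amplitude `N`, a shared transit time `tau_D` and a shared
#' intramolecular-dynamics time constant `tau_I`:
#' \deqn{AC_d(\tau) = \tfrac{1}{N} T_d(\tau) D(\tau;\tau_D)
#'   \left(1 + \alpha e^{-\tau/\tau_I} + \beta\right)}
#' \deqn{AC_a(\tau) = \tfrac{1}{N} T_a(\tau) D(\tau;\tau_D+\Delta)
#'   \left(1 + \gamma e^{-\tau/\tau_I} + \delta\right)}
#' \deqn{CC(\tau) = \tfrac{1}{N} D(\tau;\tau_D)
#'   \left(1 - \sqrt{\alpha\gamma}\, e^{-\tau/\tau_I} +
#'   \sqrt{\beta\delta}\right)}
#' where `D` is the 3D-Gaussian diffusion factor of [separate_params()].
#' `alpha`/`gamma` scale the FRET-dynamics term on the donor/acceptor
#' autocorrelation, `beta`/`delta` are static contributions from FRET
#' states that interchange far slower than the transit time, and `Delta`
#' is a fixed additive transit-time correction for AC-a.  Both static
#' and dynamic terms enter the cross-correlations through the geometric
#' mean of their channel-specific amplitudes, which keeps the
#' two-channel model internally consistent and the shared amplitude `N`
#' identifiable.  The triplet factors `T_d`, `T_a` use the per-channel
#' constants `f_d`/`tau_T_d` and `f_a`/`tau_T_a`, fixed from reference
#' measurements; cross-correlations carry no triplet term.
#'
#' @param N shared amplitude (mean molecules in focus, > 0).
#' @param tau_D shared transit time, seconds.
#' @param tau_I intramolecular dynamics time constant, seconds.
#' @param alpha,gamma dynamic-term scales (>= 0) for AC-d and AC-a.
#' @param beta,delta static contributions (>= 0) for AC-d and AC-a.
#' @param Delta additive transit-time correction for AC-a, seconds
#'   (free sign).
#' @param f_d,tau_T_d,f_a,tau_T_a per-channel triplet constants.
#' @param p lateral/axial focus aspect ratio.
#' @return A list of class `global_params`.
#' @export
global_params <- function(N, tau_D, tau_I, alpha = 0, beta = 0,
                          gamma = 0, delta = 0, Delta = 0,
                          f_d = 0, tau_T_d = 1e-6,
                          f_a = 0, tau_T_a = 1e-6, p = 6.9) {
  stopifnot(N > 0, tau_D > 0, tau_I > 0, alpha >= 0, beta >= 0,
            gamma >= 0, delta >= 0, f_d >= 0, f_d < 1, f_a >= 0,
            f_a < 1, tau_T_d > 0, tau_T_a > 0, p > 0)
  if (tau_D + Delta <= 0) stop("tau_D + Delta must stay positive")
  structure(list(N = N, tau_D = tau_D, tau_I = tau_I, alpha = alpha,
                 beta = beta, gamma = gamma, delta = delta, Delta = Delta,
                 f_d = f_d, tau_T_d = tau_T_d, f_a = f_a,
                 tau_T_a = tau_T_a, p = p),
            class = "global_params")
}

# diffusion factor of the 3D-Gaussian focus
diff_factor <- function(lag, tau_D, p) {
  1 / ((1 + lag / tau_D) * sqrt(1 + lag / (p^2 * tau_D)))
}

# triplet factor; f = 0 gives 1
triplet_factor <- function(lag, f, tau_T) {
  if (f <= 0) return(rep(1, length(lag)))
  1 + f / (1 - f) * exp(-lag / tau_T)
}

#' Evaluate the separate correlation model
#'
#' @param lag lag times in seconds (> 0).
#' @param params a [separate_params()] object.
#' @param kind `"AC"` (with triplet term) or `"CC"` (triplet-free).
#' @return Correlation values `G(lag)` (fluctuation normalization,
#'   `G -> 0` as `lag -> Inf`).
#' @examples
#' p <- separate_params(N = 7.287, f = 0.282, tau_D = 208.477e-6,
#'                      p = 6.9, tau_T = 3.813e-6)
#' eval_separate(1e-9, p)   # ~ 1/(N (1 - f)) = 0.1911
#' @export
eval_separate <- function(lag, params, kind = c("AC", "CC")) {
  kind <- match.arg(kind)
  stopifnot(inherits(params, "separate_params"))
  if (any(lag <= 0)) stop("lags must be positive")
  f <- if (kind == "AC") params$f else 0
  (1 / params$N) * triplet_factor(lag, f, params$tau_T) *
    diff_factor(lag, params$tau_D, params$p)
}

#' Evaluate the global FCCS model for one curve
#'
#' @param lag lag times in seconds (> 0).
#' @param params a [global_params()] object.
#' @param pair one of `"AC-d"`, `"AC-a"`, `"CC-da"`, `"CC-ad"` (the two
#'   cross-correlations are identical by construction).
#' @return Correlation values `G(lag)`.
#' @export
eval_global <- function(lag, params,
                        pair = c("AC-d", "AC-a", "CC-da", "CC-ad")) {
  pair <- match.arg(pair)
  stopifnot(inherits(params, "global_params"))
  if (any(lag <= 0)) stop("lags must be positive")
  with(params, switch(
    pair,
    "AC-d" = (1 / N) * triplet_factor(lag, f_d, tau_T_d) *
      diff_factor(lag, tau_D, p) *
      (1 + alpha * exp(-lag / tau_I) + beta),
    "AC-a" = (1 / N) * triplet_factor(lag, f_a, tau_T_a) *
      diff_factor(lag, tau_D + Delta, p) *
      (1 + gamma * exp(-lag / tau_I) + delta),
    (1 / N) * diff_factor(lag, tau_D, p) *
      (1 - sqrt(alpha * gamma) * exp(-lag / tau_I) + sqrt(beta * delta))
  ))
}

#' Reference FCCS parameter sets for rYkt6 Delta-C
#'
#' Published parameter estimates for the SNARE protein Ykt6 (construct
#' rYkt6 Delta-C, FCCS with Alexa 488/647) bundled as ready-made
#' [separate_params()] / [global_params()] objects.  They serve as
#' simulation ground truths and round-trip fixtures.  `"apo"` is the
#' lipid-free condition; `"dpc"` the saturated Ykt6:DPC = 1:2 condition.
#' The separate sets carry one entry per curve (`AC-d`, `AC-a`,
#' `CC-da`, `CC-ad`); the global sets share `N`, `tau_D`, `tau_I` across
#' curves, fix the triplet constants at the separate-fit values and set
#' the unreported `Delta` to 0.
#'
#' @param condition `"apo"` or `"dpc"`.
#' @param model `"separate"` or `"global"`.
#' @return For `model = "separate"` a named list of [separate_params()]
#'   (times in seconds); for `model = "global"` a [global_params()].
#' @export
fccs_reference_params <- function(condition = c("apo", "dpc"),
                                  model = c("separate", "global")) {
  condition <- match.arg(condition)
  model <- match.arg(model)
  us <- 1e-6
  sep <- if (condition == "apo") list(
    "AC-d"  = separate_params(7.287, 0.282, 208.477 * us, 6.900, 3.813 * us),
    "AC-a"  = separate_params(45.001, 0.331, 191.845 * us, 6.900, 8.827 * us),
    "CC-da" = separate_params(110.008, 0, 454.090 * us, 6.853),
    "CC-ad" = separate_params(99.619, 0, 469.967 * us, 6.900)
  ) else list(
    "AC-d"  = separate_params(8.066, 0.284, 209.990 * us, 6.900, 3.224 * us),
    "AC-a"  = separate_params(34.240, 0.343, 175.049 * us, 6.850, 5.247 * us),
    "CC-da" = separate_params(95.760, 0, 210.056 * us, 6.898),
    "CC-ad" = separate_params(68.955, 0, 229.725 * us, 6.898)
  )
  if (model == "separate") return(sep)
  acd <- sep[["AC-d"]]; aca <- sep[["AC-a"]]
  if (condition == "apo")
    global_params(N = 9.11, tau_D = 220 * us, tau_I = 190 * us,
                  alpha = 0.13, beta = 0.12, gamma = 1.01e-4,
                  delta = 0.25, Delta = 0, f_d = acd$f,
                  tau_T_d = acd$tau_T, f_a = aca$f, tau_T_a = aca$tau_T,
                  p = 6.9)
  else
    global_params(N = 8.87, tau_D = 224 * us, tau_I = 15 * us,
                  alpha = 0.04, beta = 0.07, gamma = 0.10e-2,
                  delta = 0.15, Delta = 0, f_d = acd$f,
                  tau_T_d = acd$tau_T, f_a = aca$f, tau_T_a = aca$tau_T,
                  p = 6.9)
}

#' Reference smFRET state parameters for rYkt6 Delta-C
#'
#' Peak centres (units of the Foerster radius R0), state weights and
#' cohort sizes of the published two-Gaussian distance decompositions:
#' apo condition, closed/open peaks at 0.87/1.38 R0 with a 55% closed
#' population over 26 trajectories; DPC condition (Ykt6:DPC = 1:10),
#' peaks at 0.80/1.10 R0 with 71% closed over 28 trajectories.  Peak
#' widths are not published; the default sd of 0.08 R0 resolves the two
#' apo peaks cleanly.
#'
#' @param condition `"apo"` or `"dpc"`.
#' @return List with `means` (closed, open), `weights` (closed, open),
#'   `sds`, `n_trajectories`, `mean_length` (s) and `bin_width` (s).
#' @export
fret_reference_states <- function(condition = c("apo", "dpc")) {
  condition <- match.arg(condition)
  if (condition == "apo")
    list(means = c(0.87, 1.38), weights = c(0.55, 0.45),
         sds = c(0.08, 0.08), n_trajectories = 26L,
         mean_length = 8.8, bin_width = 0.1)
  else
    list(means = c(0.80, 1.10), weights = c(0.71, 0.29),
         sds = c(0.08, 0.08), n_trajectories = 28L,
         mean_length = 8.8, bin_width = 0.1)
}
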