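#' Fit the separate (per-curve) correlation model
#'
#' Bounded Levenberg-Marquardt least squares of the single-species
#' diffusion + triplet model (see [separate_params()]) to one
#' correlation curve.  Robustness against bad basins (the triplet and
#' diffusion times can exchange roles) comes from a seeded multi-start:
#' `n_starts` initial vectors jittered multiplicatively around `init`,
#' keeping the lowest residual sum of squares.
#'
#' @param curve a `correlation_curve` (see [multitau_correlate()]) or a
#'   data frame with columns `lag`, `G` and optionally `n_samples`.
#' @param kind `"AC"` or `"CC"`; by default inferred from the curve's
#'   `pair` attribute (cross-correlations carry no triplet term).
#' @param init a [separate_params()] object or named list with starting
#'   values (`N`, `f`, `tau_D`, `p`, `tau_T`, seconds); `NULL` for a
#'   heuristic start derived from the curve.
#' @param fixed named list of parameters to hold fixed (e.g.
#'   `list(p = 6.9, f = 0.282, tau_T = 3.813e-6)` from reference
#'   measurements).
#' @param lower,upper named bound overrides for the free parameters.
#' @param weights per-point residual weights; the default (equal
#'   weights on the quasi-logarithmic lag grid, i.e. roughly equal
#'   weight per lag decade) is the common practice for multi-tau FCS
#'   data, whose per-point noise is dominated by shot noise rather
#'   than by the averaging count.
#' @param n_starts number of jittered starts (default 5).
#' @param jitter multiplicative jitter range for the starts (default
#'   `c(0.5, 2)`; `c(1, 1)` starts every run exactly at `init`).
#' @param seed seed for the start jitter (fits are deterministic).
#' @return Object of class `c("fcs_sep_fit", "fcs_fit")` with elements
#'   `params` ([separate_params()]), `se` (standard errors, free
#'   parameters), `rss`, `converged`, `niter`, `fixed`, `kind`, `curve`.
#'   Methods: `print`, `summary`, `coef`, `predict`, `fitted`,
#'   `residuals`, `plot`.
#' @examples
#' truth <- separate_params(7.287, 0.282, 208.477e-6, 6.9, 3.813e-6)
#' lag <- log_lags(1e-6, 10, 200)
#' crv <- data.frame(lag = lag, G = eval_separate(lag, truth))
#' fit <- fit_separate(crv, kind = "AC", init = truth)
#' coef(fit)["tau_D"] * 1e6   # ~ 208.477 us
#' @export
fit_separate <- function(curve, kind = NULL, init = NULL, fixed = list(),
                         lower = NULL, upper = NULL, weights = NULL,
                         n_starts = 5L, jitter = c(0.5, 2),
                         seed = 1L) {
  curve <- as.data.frame(curve)
  if (!all(c("lag", "G") %in% names(curve)))
    stop("curve must have columns 'lag' and 'G'")
  lag <- curve$lag; G <- curve$G
  ok <- is.finite(lag) & is.finite(G) & lag > 0
  lag <- lag[ok]; G <- G[ok]
  if (length(lag) < 10L)
    stop("need at least 10 usable lag points")
  if (log10(max(lag) / min(lag)) < 2)
    stop("lag range must span at least two decades")
  if (stats::sd(G) == 0) stop("degenerate (constant) correlation curve")
  if (is.null(kind)) {
    pr <- attr(curve, "pair")
    kind <- if (!is.null(pr) && grepl("^CC", pr)) "CC" else "AC"
  }
  kind <- match.arg(kind, c("AC", "CC"))
  if (kind == "CC") fixed <- utils::modifyList(fixed,
                                               list(f = 0, tau_T = 1e-6))

  weights <- if (is.null(weights)) rep(1, length(lag))
  else weights[ok]
  weights <- weights / mean(weights)

  g0 <- max(G)
  heur <- list(N = 1 / max(g0, 1e-12), f = 0.1,
               tau_D = lag[which.min(abs(G - g0 / 2))],
               p = 5, tau_T = 3e-6)
  init <- if (is.null(init)) heur else
    utils::modifyList(heur, unclass(init))

  par_names <- c("N", "f", "tau_D", "p", "tau_T")
  full_lower <- c(N = 1e-6, f = 0, tau_D = 1e-7, p = 1, tau_T = 1e-7)
  full_upper <- c(N = 1e6, f = 0.999, tau_D = 1, p = 20, tau_T = 1e-3)
  for (nm in names(lower)) full_lower[nm] <- lower[[nm]]
  for (nm in names(upper)) full_upper[nm] <- upper[[nm]]
  free <- setdiff(par_names, names(fixed))
  p0 <- unlist(init[par_names])
  p0[names(fixed)] <- unlist(fixed)
  start <- pmin(pmax(p0[free], full_lower[free]), full_upper[free])

  make_params <- function(v) {
    full <- p0
    full[free] <- v
    separate_params(full[["N"]], full[["f"]], full[["tau_D"]],
                    full[["p"]], full[["tau_T"]])
  }
  resid_fn <- function(v)
    (eval_separate(lag, make_params(v), kind) - G) * weights

  best <- lm_multistart(start, full_lower[free], full_upper[free],
                        resid_fn, n_starts = n_starts,
                        jitter_range = jitter, seed = seed)
  est <- best$fit$par
  names(est) <- free
  J <- fd_jacobian(resid_fn, est)
  se <- se_from_jacobian(J, best$rss, length(lag))
  names(se) <- free

  structure(list(params = make_params(est), se = se, rss = best$rss,
                 converged = best$converged,
                 niter = best$fit$niter, fixed = fixed, kind = kind,
                 pair = attr(curve, "pair"),
                 curve = data.frame(lag = lag, G = G,
                                    weights = weights)),
            class = c("fcs_sep_fit", "fcs_fit"))
}

#' Build the relative-amplitude report from separate fits
#'
#' Given per-curve separate fits, derive the comparison columns of a
#' separate-fit report: `rel_N = N_x / N_ACd` (relative molecule
#' number) and `dtau_D = tau_D_x - tau_D_ACd` (transit-time difference,
#' reported in microseconds), with the donor autocorrelation as the
#' reference row.
#'
#' @param fits named list of `fcs_sep_fit` objects (or
#'   [separate_params()] objects); must contain an `"AC-d"` entry.
#' @return Data frame of class `fcs_sep_report` with one row per curve:
#'   `pair`, `N`, `f`, `tau_D_us`, `p`, `tau_T_us`, `rel_N`,
#'   `dtau_D_us`.
#' @examples
#' ref <- fccs_reference_params("apo", "separate")
#' rep <- build_separate_report(ref)
#' rep$rel_N[rep$pair == "AC-a"]      # 6.176
#' @export
build_separate_report <- function(fits) {
  if (!("AC-d" %in% names(fits)))
    stop("an 'AC-d' result is required as the reference row")
  get_par <- function(x) if (inherits(x, "fcs_fit")) x$params else x
  ref <- get_par(fits[["AC-d"]])
  rows <- lapply(names(fits), function(nm) {
    p <- get_par(fits[[nm]])
    data.frame(pair = nm, N = p$N, f = p$f, tau_D_us = 1e6 * p$tau_D,
               p = p$p, tau_T_us = 1e6 * p$tau_T,
               rel_N = p$N / ref$N,
               dtau_D_us = 1e6 * (p$tau_D - ref$tau_D))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("fcs_sep_report", "data.frame")
  out
}
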