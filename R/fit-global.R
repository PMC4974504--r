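#' Global shared-parameter fit of four FCCS curves
#'
#' Simultaneous bounded least squares of the global FCCS model (see
#' [global_params()]) over the concatenated residual vector of the four
#' curves AC-d, AC-a, CC-da and CC-ad, with the amplitude `N`, transit
#' time `tau_D` and intramolecular-dynamics time `tau_I` shared across
#' curves.  The triplet constants and the focus aspect ratio `p` are
#' held fixed, typically at values from prior separate fits of
#' reference measurements.  As in [fit_separate()], a seeded
#' multi-start with multiplicative jitter guards against bad basins.
#'
#' @param curves named list with elements `"AC-d"`, `"AC-a"`, `"CC-da"`,
#'   `"CC-ad"`, each a `correlation_curve` or data frame with `lag`,
#'   `G` and optionally `n_samples`.  Lag ranges must overlap.
#' @param init a [global_params()] object or named list of starting
#'   values; `NULL` for a heuristic start.
#' @param fixed named list for the fixed constants `f_d`, `tau_T_d`,
#'   `f_a`, `tau_T_a`, `p` (and optionally any free parameter, e.g.
#'   `Delta = 0`).  Missing entries default to the values in `init`.
#' @param lower,upper named bound overrides.  Defaults:
#'   `tau_I` in \[1 us, 10 ms\], scale/static terms in \[0, 1\],
#'   `Delta` in \[-1 ms, 1 ms\].
#' @param weights `NULL` for equal per-point weights on the
#'   quasi-logarithmic lag grid (see [fit_separate()]), or a named
#'   list of numeric vectors per pair.
#' @param n_starts,jitter,seed multi-start control, as in
#'   [fit_separate()].
#' @return Object of class `c("fcs_global_fit", "fcs_fit")` with
#'   `params` ([global_params()]), `se`, `rss`, `converged`, `niter`,
#'   `fixed`, `curves`.  The usual methods apply; `predict` takes a
#'   `pair` argument.
#' @export
fit_global <- function(curves, init = NULL, fixed = list(),
                       lower = NULL, upper = NULL, weights = NULL,
                       n_starts = 5L, jitter = c(0.5, 2),
                       seed = 1L) {
  pairs <- c("AC-d", "AC-a", "CC-da", "CC-ad")
  missing_p <- setdiff(pairs, names(curves))
  if (length(missing_p))
    stop("missing curve(s): ", paste(missing_p, collapse = ", "))
  dat <- lapply(pairs, function(pr) {
    cv <- as.data.frame(curves[[pr]])
    ok <- is.finite(cv$lag) & is.finite(cv$G) & cv$lag > 0
    cv <- cv[ok, , drop = FALSE]
    w <- if (!is.null(weights)) weights[[pr]][ok] else rep(1, nrow(cv))
    list(lag = cv$lag, G = cv$G, w = w / mean(w))
  })
  names(dat) <- pairs
  lo_max <- max(vapply(dat, function(d) min(d$lag), 0))
  hi_min <- min(vapply(dat, function(d) max(d$lag), 0))
  if (lo_max >= hi_min) stop("curve lag ranges do not overlap")

  g0 <- max(dat[["AC-d"]]$G)
  heur <- list(N = 1 / max(g0, 1e-12),
               tau_D = dat[["AC-d"]]$lag[
                 which.min(abs(dat[["AC-d"]]$G - g0 / 2))],
               tau_I = 1e-4, alpha = 0.1, beta = 0.1, gamma = 0.01,
               delta = 0.1, Delta = 0, f_d = 0, tau_T_d = 3e-6,
               f_a = 0, tau_T_a = 3e-6, p = 6.9)
  init <- if (is.null(init)) heur else
    utils::modifyList(heur, unclass(init))

  par_names <- c("N", "tau_D", "tau_I", "alpha", "beta", "gamma",
                 "delta", "Delta")
  const_names <- c("f_d", "tau_T_d", "f_a", "tau_T_a", "p")
  consts <- init[const_names]
  for (nm in intersect(names(fixed), const_names))
    consts[[nm]] <- fixed[[nm]]
  fixed_free <- fixed[intersect(names(fixed), par_names)]

  full_lower <- c(N = 1e-6, tau_D = 1e-7, tau_I = 1e-6, alpha = 0,
                  beta = 0, gamma = 0, delta = 0, Delta = -1e-3)
  full_upper <- c(N = 1e6, tau_D = 1, tau_I = 1e-2, alpha = 1,
                  beta = 1, gamma = 1, delta = 1, Delta = 1e-3)
  for (nm in names(lower)) full_lower[nm] <- lower[[nm]]
  for (nm in names(upper)) full_upper[nm] <- upper[[nm]]
  free <- setdiff(par_names, names(fixed_free))
  p0 <- unlist(init[par_names])
  p0[names(fixed_free)] <- unlist(fixed_free)
  start <- pmin(pmax(p0[free], full_lower[free]), full_upper[free])

  make_params <- function(v) {
    full <- p0
    full[free] <- v
    do.call(global_params, c(as.list(full), consts))
  }
  resid_fn <- function(v) {
    full <- p0
    full[free] <- v
    if (full[["tau_D"]] + full[["Delta"]] <= 1e-8)
      return(rep(1e3, sum(vapply(dat, function(d) length(d$lag), 0L))))
    pm <- do.call(global_params, c(as.list(full), consts))
    unlist(lapply(pairs, function(pr) {
      d <- dat[[pr]]
      (eval_global(d$lag, pm, pr) - d$G) * d$w
    }), use.names = FALSE)
  }

  best <- lm_multistart(start, full_lower[free], full_upper[free],
                        resid_fn, n_starts = n_starts,
                        jitter_range = jitter, seed = seed)
  est <- best$fit$par
  names(est) <- free
  n_res <- sum(vapply(dat, function(d) length(d$lag), 0L))
  J <- fd_jacobian(resid_fn, est)
  se <- se_from_jacobian(J, best$rss, n_res)
  names(se) <- free

  structure(list(params = make_params(est), se = se, rss = best$rss,
                 converged = best$converged,
                 niter = best$fit$niter,
                 fixed = c(fixed_free, consts), curves = dat),
            class = c("fcs_global_fit", "fcs_fit"))
}
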