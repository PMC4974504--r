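#' Two-Gaussian decomposition of a FRET distance distribution
#'
#' Builds a histogram density of pooled dye separations (R0 units) and
#' fits the two-component Gaussian mixture density
#' `w N(mu1, sigma1) + (1 - w) N(mu2, sigma2)` to it by bounded least
#' squares, mirroring the histogram-fitting workflow used for smFRET
#' distance distributions.  Components are reported in ascending-mean
#' order; the smaller-distance component is the closed state.
#'
#' @param distances numeric sample of distances, R0 units (>= 100
#'   values).
#' @param bin_width histogram bin width, R0 units (default 0.025).
#' @param init optional list/`gaussian_pair` with starting `weights`,
#'   `means`, `sds`; a quantile-based heuristic otherwise.  When the
#'   approximate peak positions are known (e.g. fitting a measured
#'   condition whose two states are established), passing them here
#'   with `anchor = TRUE` keeps each component on its own peak.
#' @param anchor when `TRUE` (and `init` is given), bound each
#'   component mean within `anchor_halfwidth` of its starting value,
#'   preventing component swallowing on small lumpy cohorts.
#' @param anchor_halfwidth half-width of the mean bounds, R0 units.
#' @param n_starts,seed multi-start control as in [fit_separate()].
#' @return Object of class `gaussian_pair`: `weights` (sum to 1),
#'   `means`, `sds` (ascending-mean order), `converged`, `overlapping`
#'   (TRUE when the fitted components are not resolved:
#'   `|mu2 - mu1| < (sigma1 + sigma2)`), `rss` and the histogram used.
#' @examples
#' set.seed(7)
#' d <- c(rnorm(1300, 0.87, 0.08), rnorm(1000, 1.38, 0.08))
#' fit_two_gaussians(d)$weights[1]   # ~ 0.565
#' @export
fit_two_gaussians <- function(distances, bin_width = 0.025,
                              init = NULL, anchor = FALSE,
                              anchor_halfwidth = 0.15, n_starts = 5L,
                              seed = 1L) {
  distances <- distances[is.finite(distances)]
  if (length(distances) < 100L)
    stop("need at least 100 distance samples")
  lo <- floor(min(distances) / bin_width) * bin_width
  hi <- ceiling(max(distances) / bin_width) * bin_width
  breaks <- seq(lo, hi + bin_width / 2, by = bin_width)
  h <- graphics::hist(distances, breaks = breaks, plot = FALSE)
  x <- h$mids; y <- h$density

  if (is.null(init)) {
    qs <- stats::quantile(distances, c(0.25, 0.75))
    init <- list(weights = c(0.5, 0.5), means = as.numeric(qs),
                 sds = rep(stats::sd(distances) / 2, 2))
  }
  p0 <- c(w = min(max(init$weights[1], 0.05), 0.95),
          mu1 = init$means[1], mu2 = init$means[2],
          s1 = init$sds[1], s2 = init$sds[2])
  lower <- c(w = 0, mu1 = lo, mu2 = lo, s1 = bin_width / 4,
             s2 = bin_width / 4)
  upper <- c(w = 1, mu1 = hi, mu2 = hi, s1 = hi - lo, s2 = hi - lo)
  if (isTRUE(anchor)) {
    if (is.null(init)) stop("'anchor = TRUE' needs an explicit init")
    lower[c("mu1", "mu2")] <- p0[c("mu1", "mu2")] - anchor_halfwidth
    upper[c("mu1", "mu2")] <- p0[c("mu1", "mu2")] + anchor_halfwidth
    upper[c("s1", "s2")] <- pmin(upper[c("s1", "s2")],
                                 3 * p0[c("s1", "s2")])
  }
  resid_fn <- function(v)
    v[1] * stats::dnorm(x, v[2], v[4]) +
    (1 - v[1]) * stats::dnorm(x, v[3], v[5]) - y

  best <- lm_multistart(p0, lower, upper, resid_fn,
                        n_starts = n_starts, seed = seed,
                        jitter_range = c(0.8, 1.25))
  v <- best$fit$par
  w <- c(v[1], 1 - v[1]); mu <- c(v[2], v[3]); sd_ <- c(v[4], v[5])
  ord <- order(mu)
  structure(list(weights = as.numeric(w[ord]),
                 means = as.numeric(mu[ord]),
                 sds = as.numeric(sd_[ord]),
                 converged = best$converged,
                 overlapping = abs(diff(mu)) < sum(sd_),
                 rss = best$rss,
                 hist = data.frame(mid = x, density = y),
                 n = length(distances)),
            class = "gaussian_pair")
}

#' Two-Gaussian decomposition by expectation-maximization
#'
#' Sample-level EM fit of the same mixture as [fit_two_gaussians()],
#' provided as an independent cross-check of the histogram-based fit
#' (EM sees the raw samples and is free of binning artifacts).
#'
#' @param distances numeric sample (>= 100 values).
#' @param init optional starting `weights`, `means`, `sds`.
#' @param max_iter,tol EM iteration control.
#' @return A `gaussian_pair` (without histogram).
#' @export
fit_two_gaussians_em <- function(distances, init = NULL,
                                 max_iter = 500L, tol = 1e-10) {
  x <- distances[is.finite(distances)]
  if (length(x) < 100L) stop("need at least 100 distance samples")
  if (is.null(init)) {
    qs <- stats::quantile(x, c(0.25, 0.75))
    init <- list(weights = c(0.5, 0.5), means = as.numeric(qs),
                 sds = rep(stats::sd(x) / 2, 2))
  }
  w <- init$weights; mu <- init$means; s <- pmax(init$sds, 1e-4)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(x, mu[1], s[1])
    d2 <- w[2] * stats::dnorm(x, mu[2], s[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    r1 <- d1 / tot
    w <- c(mean(r1), 1 - mean(r1))
    mu <- c(sum(r1 * x) / sum(r1), sum((1 - r1) * x) / sum(1 - r1))
    s <- sqrt(c(sum(r1 * (x - mu[1])^2) / sum(r1),
                sum((1 - r1) * (x - mu[2])^2) / sum(1 - r1)))
    s <- pmax(s, 1e-6)
    ll <- sum(log(tot))
    if (is.finite(ll) && abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  ord <- order(mu)
  structure(list(weights = w[ord], means = mu[ord], sds = s[ord],
                 converged = it < max_iter, overlapping =
                   abs(diff(mu)) < sum(s), rss = NA_real_,
                 n = length(x)),
            class = "gaussian_pair")
}

#' @export
print.gaussian_pair <- function(x, ...) {
  cat("Two-Gaussian distance decomposition (R0 units)\n")
  cat(sprintf("  closed: w = %.3f, mu = %.3f, sd = %.3f\n",
              x$weights[1], x$means[1], x$sds[1]))
  cat(sprintf("  open:   w = %.3f, mu = %.3f, sd = %.3f\n",
              x$weights[2], x$means[2], x$sds[2]))
  if (isTRUE(x$overlapping))
    cat("  note: components overlap (effectively single-peaked)\n")
  invisible(x)
}

#' @export
coef.gaussian_pair <- function(object, ...)
  c(w_closed = object$weights[1], w_open = object$weights[2],
    mu_closed = object$means[1], mu_open = object$means[2],
    sd_closed = object$sds[1], sd_open = object$sds[2])

#' @export
predict.gaussian_pair <- function(object, x, ...)
  object$weights[1] * stats::dnorm(x, object$means[1], object$sds[1]) +
  object$weights[2] * stats::dnorm(x, object$means[2], object$sds[2])

#' @export
plot.gaussian_pair <- function(x, ...) {
  if (is.null(x$hist)) stop("no histogram stored (EM fit)")
  graphics::plot(x$hist$mid, x$hist$density, type = "h",
                 xlab = "distance (R0)", ylab = "density", ...)
  xx <- seq(min(x$hist$mid), max(x$hist$mid), length.out = 400)
  graphics::lines(xx, predict(x, xx), col = "darkgreen", lwd = 2)
  invisible(x)
}

#' Classify a trajectory by state-peak occupancy
#'
#' Assigns each bin's distance to the closed or open component of a
#' fitted [fit_two_gaussians()] pair by posterior probability (ties go
#' to the closed, smaller-distance component) and labels the
#' trajectory `"both"` when at least `min_bins` bins fall in each
#' component, otherwise by its dominant component, or
#' `"unclassified"` when shorter than `min_bins`.
#'
#' @param distances per-bin distances of one trajectory (R0 units).
#' @param pair a `gaussian_pair`.
#' @param min_bins minimum bins per component (default 3).
#' @return List of class `trajectory_class`: `label` in
#'   `{"closed_only", "open_only", "both", "unclassified"}`,
#'   `n_closed`, `n_open`.
#' @export
classify_trajectory <- function(distances, pair, min_bins = 3L) {
  stopifnot(inherits(pair, "gaussian_pair"), min_bins >= 1L)
  d <- distances[is.finite(distances)]
  d1 <- pair$weights[1] * stats::dnorm(d, pair$means[1], pair$sds[1])
  d2 <- pair$weights[2] * stats::dnorm(d, pair$means[2], pair$sds[2])
  closed <- d1 >= d2          # posterior >= 0.5; ties toward closed
  n1 <- sum(closed); n2 <- sum(!closed)
  label <- if (length(d) < min_bins) "unclassified"
  else if (n1 >= min_bins && n2 >= min_bins) "both"
  else if (n1 >= n2) "closed_only" else "open_only"
  structure(list(label = label, n_closed = n1, n_open = n2),
            class = "trajectory_class")
}

#' @export
print.trajectory_class <- function(x, ...) {
  cat(sprintf("trajectory class: %s (closed %d, open %d bins)\n",
              x$label, x$n_closed, x$n_open))
  invisible(x)
}

#' Classify a cohort of trajectories
#'
#' Applies [compute_efficiency()], the distance conversion and
#' [classify_trajectory()] to every trajectory of a simulated or read
#' cohort, against a mixture fitted to the pooled distances.
#'
#' @param trajs list of `binned_trajectory`.
#' @param corr a [fret_corrections()].
#' @param pair optional pre-fitted `gaussian_pair`; fitted to the
#'   pooled distances when `NULL`.
#' @param min_bins see [classify_trajectory()].
#' @param ... passed to [fit_two_gaussians()] (e.g. `init`, `anchor`).
#' @return List with `pair`, `classes` (per-trajectory labels),
#'   `counts` (table of labels) and `distances` (per-trajectory list).
#' @export
classify_cohort <- function(trajs, corr = fret_corrections(),
                            pair = NULL, min_bins = 3L, ...) {
  dist_list <- lapply(trajs, function(tr) {
    e <- compute_efficiency(tr, corr)
    e <- e[e > 0 & e < 1]
    efficiency_to_distance(e)
  })
  pooled <- unlist(dist_list)
  if (is.null(pair)) pair <- fit_two_gaussians(pooled, ...)
  classes <- vapply(dist_list, function(d)
    classify_trajectory(d, pair, min_bins)$label, character(1))
  list(pair = pair, classes = classes,
       counts = table(factor(classes,
                             levels = c("closed_only", "open_only",
                                        "both", "unclassified"))),
       distances = dist_list)
}
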