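#' Multi-tau correlation of a photon stream
#'
#' Estimates the normalized auto- or cross-correlation function of the
#' photon counts of a stream over lags spanning microseconds to
#' seconds.  Photons are binned at `resolution`; per level the counts
#' are correlated at `points_per_level` lag offsets and then coarsened
#' by a factor 2, the classic multi-tau scheme.  Normalization is the
#' symmetric fluctuation form
#' `G(tau) = <dI_a(t) dI_b(t + tau)> / (<I_a><I_b>)`, so `G -> 0` for
#' uncorrelated signals and the zero-lag amplitude of a diffusing
#' species is `1/N`.
#'
#' @param stream a `photon_stream` (see [simulate_photon_stream()] or
#'   [read_photon_csv()]).
#' @param pair `"AC-d"`, `"AC-a"`, `"CC-da"` or `"CC-ad"`.
#' @param points_per_level lag offsets per level (even, default 16).
#' @param n_levels number of coarsening levels (default 20: 1 us base
#'   resolution covers lags up to ~8 s).
#' @param resolution base bin width in seconds (default 1e-6).
#' @return A `correlation_curve`: data frame with columns `lag`
#'   (seconds, strictly increasing), `G`, `n_samples` (averaging terms
#'   per lag), with attributes `pair` and `duration`.  Lags beyond a
#'   quarter of the stream duration are dropped with a warning.
#' @export
multitau_correlate <- function(stream, pair = c("AC-d", "AC-a",
                                                "CC-da", "CC-ad"),
                               points_per_level = 16L, n_levels = 20L,
                               resolution = 1e-6) {
  pair <- match.arg(pair)
  stopifnot(points_per_level >= 2L, points_per_level %% 2L == 0L,
            n_levels >= 1L, resolution > 0)
  ch <- channel_indices(stream, pair)
  counts_a <- bin_photons(stream$times[stream$channel == ch[1]],
                          resolution, stream$duration)
  counts_b <- if (ch[1] == ch[2]) counts_a else
    bin_photons(stream$times[stream$channel == ch[2]],
                resolution, stream$duration)
  res <- multitau_cpp(counts_a, counts_b, as.integer(points_per_level),
                      as.integer(n_levels))
  lag <- res$lag_bins * resolution
  keep <- lag <= stream$duration / 4
  if (any(!keep))
    warning("lags beyond duration/4 truncated (",
            sum(!keep), " points)")
  new_correlation_curve(lag[keep], res$G[keep], res$n_samples[keep],
                        pair, stream$duration)
}

#' Brute-force correlation at explicit lags
#'
#' Exact binned-intensity correlation with the same normalization as
#' [multitau_correlate()], evaluated at the requested lags.  Quadratic
#' cost; guarded to streams of at most `max_bins` binned samples.  This
#' is the oracle against which the multi-tau scheme is validated.
#'
#' @inheritParams multitau_correlate
#' @param lags lag times in seconds (each >= `resolution`).
#' @param max_bins guard on the binned length (default 1e6).
#' @return A `correlation_curve` (empty for an empty lag list).
#' @export
direct_correlate <- function(stream, pair = c("AC-d", "AC-a",
                                              "CC-da", "CC-ad"),
                             lags, resolution = 1e-6,
                             max_bins = 1e6) {
  pair <- match.arg(pair)
  nb <- ceiling(stream$duration / resolution)
  if (nb > max_bins)
    stop("stream too long for the brute-force correlator (",
         nb, " > ", max_bins, " bins)")
  if (length(lags) == 0L)
    return(new_correlation_curve(numeric(0), numeric(0), numeric(0),
                                 pair, stream$duration))
  ch <- channel_indices(stream, pair)
  counts_a <- bin_photons(stream$times[stream$channel == ch[1]],
                          resolution, stream$duration)
  counts_b <- if (ch[1] == ch[2]) counts_a else
    bin_photons(stream$times[stream$channel == ch[2]],
                resolution, stream$duration)
  kb <- as.integer(round(lags / resolution))
  res <- direct_correlate_cpp(counts_a, counts_b, kb)
  new_correlation_curve(kb * resolution, res$G, res$n_samples, pair,
                        stream$duration)
}

#' Smooth a correlation curve by adjacent-lag averaging
#'
#' Merges runs of `factor` adjacent lags into single points:
#' `G` is averaged weighted by `n_samples`, lags are combined by their
#' geometric mean, `n_samples` add.
#'
#' @param curve a `correlation_curve`.
#' @param factor integer >= 1; must not exceed the curve length.
#' @return A `correlation_curve` of reduced length.
#' @export
smooth_curve <- function(curve, factor) {
  stopifnot(factor >= 1, factor == round(factor))
  n <- nrow(curve)
  if (factor > n) stop("smoothing factor exceeds curve length")
  if (factor == 1) return(curve)
  grp <- (seq_len(n) - 1L) %/% factor
  w <- curve$n_samples
  lag <- exp(tapply(log(curve$lag), grp, mean))
  G <- tapply(curve$G * w, grp, sum) / tapply(w, grp, sum)
  ns <- tapply(w, grp, sum)
  new_correlation_curve(as.numeric(lag), as.numeric(G),
                        as.numeric(ns), attr(curve, "pair"),
                        attr(curve, "duration"))
}

new_correlation_curve <- function(lag, G, n_samples, pair, duration) {
  out <- data.frame(lag = lag, G = G, n_samples = n_samples)
  attr(out, "pair") <- pair
  attr(out, "duration") <- duration
  class(out) <- c("correlation_curve", "data.frame")
  out
}

channel_indices <- function(stream, pair) {
  ch <- switch(pair,
               "AC-d" = c(1L, 1L), "AC-a" = c(2L, 2L),
               "CC-da" = c(1L, 2L), "CC-ad" = c(2L, 1L))
  for (i in unique(ch)) {
    nm <- if (i == 1L) "donor" else "acceptor"
    if (!any(stream$channel == i))
      stop("stream has no photons in the ", nm, " channel")
  }
  ch
}

bin_photons <- function(times, resolution, duration) {
  nb <- as.integer(ceiling(duration / resolution))
  idx <- pmin(as.integer(floor(times / resolution)) + 1L, nb)
  tabulate(idx, nbins = nb)
}

#' @export
print.correlation_curve <- function(x, ...) {
  cat(sprintf("Correlation curve %s: %d lags in [%.3g, %.3g] s\n",
              attr(x, "pair") %||% "", nrow(x),
              if (nrow(x)) min(x$lag) else NA,
              if (nrow(x)) max(x$lag) else NA))
  invisible(x)
}

#' @export
plot.correlation_curve <- function(x, ...) {
  graphics::plot(x$lag, x$G, log = "x", type = "l",
                 xlab = "lag (s)", ylab = "G",
                 main = attr(x, "pair") %||% "correlation", ...)
  invisible(x)
}
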