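#' Synthesize a four-curve FCCS data set from global model parameters
#'
#' Evaluates the global model (see [global_params()]) for AC-d, AC-a,
#' CC-da and CC-ad on a common lag grid and optionally adds i.i.d.
#' Gaussian noise — the inverse of [fit_global()], used for round-trip
#' validation and as a lightweight stand-in for measured curves.
#'
#' @param params a [global_params()] object.
#' @param lags positive, strictly increasing lag grid in seconds.
#' @param noise_sd per-point Gaussian noise standard deviation
#'   (0 gives exact model curves).
#' @param seed RNG seed for the noise (ignored when `noise_sd = 0`).
#' @return Named list of four `correlation_curve` objects.
#' @examples
#' ps <- fccs_reference_params("apo", "global")
#' crv <- synthesize_correlation_set(ps, log_lags(1e-6, 1, 160))
#' @export
synthesize_correlation_set <- function(params, lags, noise_sd = 0,
                                       seed = NULL) {
  stopifnot(inherits(params, "global_params"))
  if (any(lags <= 0) || is.unsorted(lags, strictly = TRUE))
    stop("lags must be positive and strictly increasing")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  pairs <- c("AC-d", "AC-a", "CC-da", "CC-ad")
  make <- function(pr, eps) {
    g <- eval_global(lags, params, pr) + eps
    new_correlation_curve(lags, g, rep(1, length(lags)), pr, NA_real_)
  }
  if (noise_sd == 0) {
    out <- lapply(pairs, make, eps = 0)
  } else {
    out <- with_seed(seed, lapply(pairs, function(pr)
      make(pr, stats::rnorm(length(lags), 0, noise_sd))))
  }
  names(out) <- pairs
  out
}
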