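# S3 methods for fitted FCS/FCCS model objects

#' @export
coef.fcs_fit <- function(object, ...) unlist(unclass(object$params))

#' @export
print.fcs_sep_fit <- function(x, ...) {
  cat(sprintf("Separate %s correlation fit%s\n", x$kind,
              if (!is.null(x$pair)) paste0(" (", x$pair, ")") else ""))
  p <- x$params
  cat(sprintf("  N = %.4g, f = %.4g, tau_D = %.4g us, p = %.4g, tau_T = %.4g us\n",
              p$N, p$f, 1e6 * p$tau_D, p$p, 1e6 * p$tau_T))
  cat(sprintf("  rss = %.4g, converged: %s (%d iterations)\n",
              x$rss, x$converged, x$niter))
  invisible(x)
}

#' @export
print.fcs_global_fit <- function(x, ...) {
  p <- x$params
  cat("Global shared-parameter FCCS fit (AC-d, AC-a, CC-da, CC-ad)\n")
  cat(sprintf("  N = %.4g, tau_D = %.4g us, tau_I = %.4g us\n",
              p$N, 1e6 * p$tau_D, 1e6 * p$tau_I))
  cat(sprintf("  alpha = %.4g, beta = %.4g, gamma = %.4g, delta = %.4g, Delta = %.4g us\n",
              p$alpha, p$beta, p$gamma, p$delta, 1e6 * p$Delta))
  cat(sprintf("  rss = %.4g, converged: %s (%d iterations)\n",
              x$rss, x$converged, x$niter))
  invisible(x)
}

#' @export
summary.fcs_fit <- function(object, ...) {
  est <- coef(object)
  free <- names(object$se)
  tab <- data.frame(estimate = est[free], std_error = object$se,
                    row.names = free)
  # times to microseconds for readability
  tus <- grep("^tau|^Delta$", rownames(tab))
  tab[tus, ] <- tab[tus, ] * 1e6
  rownames(tab)[tus] <- paste0(rownames(tab)[tus], "_us")
  out <- list(coefficients = tab, rss = object$rss,
              converged = object$converged, fixed = object$fixed,
              flagged = rownames(tab)[!is.finite(tab$std_error) |
                                        tab$std_error > abs(tab$estimate)])
  class(out) <- "summary.fcs_fit"
  out
}

#' @export
print.summary.fcs_fit <- function(x, ...) {
  print(round(x$coefficients, 6))
  cat(sprintf("rss = %.4g, converged: %s\n", x$rss, x$converged))
  if (length(x$flagged))
    cat("poorly determined (se >= |estimate|): ",
        paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}

#' @export
predict.fcs_sep_fit <- function(object, lag = NULL, ...) {
  if (is.null(lag)) lag <- object$curve$lag
  eval_separate(lag, object$params, object$kind)
}

#' @export
predict.fcs_global_fit <- function(object, lag = NULL, pair = "AC-d",
                                   ...) {
  if (is.null(lag)) lag <- object$curves[[pair]]$lag
  eval_global(lag, object$params, pair)
}

#' @export
fitted.fcs_sep_fit <- function(object, ...)
  predict(object, object$curve$lag)

#' @export
residuals.fcs_sep_fit <- function(object, ...)
  object$curve$G - fitted(object)

#' @export
residuals.fcs_global_fit <- function(object, ...) {
  out <- lapply(names(object$curves), function(pr)
    object$curves[[pr]]$G - predict(object, object$curves[[pr]]$lag, pr))
  names(out) <- names(object$curves)
  out
}

#' @export
plot.fcs_sep_fit <- function(x, ...) {
  graphics::plot(x$curve$lag, x$curve$G, log = "x", pch = 16,
                 cex = 0.5, xlab = "lag (s)", ylab = "G",
                 main = paste("separate fit", x$pair %||% ""), ...)
  lg <- log_lags(min(x$curve$lag), max(x$curve$lag), 300)
  graphics::lines(lg, predict(x, lg), col = 2, lwd = 2)
  invisible(x)
}

#' @export
plot.fcs_global_fit <- function(x, ...) {
  cols <- c("AC-d" = "darkgreen", "AC-a" = "red", "CC-da" = "black",
            "CC-ad" = "blue")
  rng <- range(unlist(lapply(x$curves, function(d) d$lag)))
  ylim <- range(unlist(lapply(x$curves, function(d) d$G)))
  graphics::plot(NA, xlim = rng, ylim = ylim, log = "x",
                 xlab = "lag (s)", ylab = "G",
                 main = "global FCCS fit", ...)
  for (pr in names(x$curves)) {
    d <- x$curves[[pr]]
    graphics::points(d$lag, d$G, col = cols[pr], pch = 16, cex = 0.4)
    lg <- log_lags(min(d$lag), max(d$lag), 300)
    graphics::lines(lg, predict(x, lg, pr), col = cols[pr], lwd = 2)
  }
  graphics::legend("topright", legend = names(cols), col = cols,
                   lwd = 2, bty = "n")
  invisible(x)
}

#' Simulate noisy correlation curves from a fitted global model
#'
#' @param object a fitted `fcs_global_fit`.
#' @param nsim number of replicate curve sets.
#' @param seed RNG seed.
#' @param lags lag grid (default: the fitted AC-d lags).
#' @param noise_sd per-point Gaussian noise sd.
#' @return A list of `nsim` curve sets as produced by
#'   [synthesize_correlation_set()].
#' @export
simulate.fcs_global_fit <- function(object, nsim = 1, seed = NULL,
                                    lags = NULL, noise_sd = 0, ...) {
  if (is.null(lags)) lags <- object$curves[["AC-d"]]$lag
  sd0 <- if (is.null(seed)) 1L else as.integer(seed)
  lapply(seq_len(nsim), function(i)
    synthesize_correlation_set(object$params, lags, noise_sd,
                               seed = sd0 + i - 1L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
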