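#' Two-state kinetics from relaxation time and open-state population
#'
#' For a molecule interconverting between a closed and an open conformation
#' (closed -> open at `k_open`, open -> closed at `k_close`) the correlation
#' relaxation time is `tau_r = 1/(k_open + k_close)` and the equilibrium
#' open fraction is `P_open = k_open/(k_open + k_close)`.  This inverts those
#' relations: given the relaxation time measured by FRET-FCCS and the state
#' populations measured by smFRET, it returns the rate constants.
#'
#' @param tau_r relaxation time in seconds (> 0).
#' @param p_open equilibrium open-state fraction, strictly inside (0, 1).
#' @return An object of class `two_state_kinetics`: a list with elements
#'   `k_open`, `k_close` (1/s), `p_open`, `p_closed` and `tau_r` (s).
#' @examples
#' rates_from_relaxation(200e-6, 0.45)  # k_open 2250/s, k_close 2750/s
#' @seealso [kinetics_from_rates()] for the inverse conversion.
#' @export
rates_from_relaxation <- function(tau_r, p_open) {
  stopifnot(is.numeric(tau_r), length(tau_r) == 1L, is.finite(tau_r),
            is.numeric(p_open), length(p_open) == 1L, is.finite(p_open))
  if (tau_r <= 0) stop("'tau_r' must be positive")
  if (p_open <= 0 || p_open >= 1)
    stop("'p_open' must lie strictly inside (0, 1)")
  new_two_state_kinetics(k_open = p_open / tau_r,
                         k_close = (1 - p_open) / tau_r)
}

#' Two-state kinetics from rate constants
#'
#' @param k_open closed -> open rate constant (1/s, > 0).
#' @param k_close open -> closed rate constant (1/s, > 0).
#' @return An object of class `two_state_kinetics`; see
#'   [rates_from_relaxation()].
#' @examples
#' kinetics_from_rates(2250, 2750)  # p_open 0.45, tau_r 200 us
#' @export
kinetics_from_rates <- function(k_open, k_close) {
  stopifnot(is.numeric(k_open), length(k_open) == 1L, is.finite(k_open),
            is.numeric(k_close), length(k_close) == 1L, is.finite(k_close))
  if (k_open <= 0 || k_close <= 0) stop("rate constants must be positive")
  new_two_state_kinetics(k_open = k_open, k_close = k_close)
}

new_two_state_kinetics <- function(k_open, k_close) {
  ksum <- k_open + k_close
  p_open <- k_open / ksum
  # complement, not k_close/ksum: keeps P_open + P_closed exactly 1
  structure(list(k_open = k_open, k_close = k_close,
                 p_open = p_open, p_closed = 1 - p_open,
                 tau_r = 1 / ksum),
            class = "two_state_kinetics")
}

#' @export
print.two_state_kinetics <- function(x, ...) {
  cat("Two-state exchange kinetics\n")
  cat(sprintf("  k_open  (closed -> open): %.6g 1/s\n", x$k_open))
  cat(sprintf("  k_close (open -> closed): %.6g 1/s\n", x$k_close))
  cat(sprintf("  P_open = %.4f, P_closed = %.4f\n", x$p_open, x$p_closed))
  cat(sprintf("  relaxation time tau_r = %.6g us\n", 1e6 * x$tau_r))
  invisible(x)
}

#' @export
as.list.two_state_kinetics <- function(x, ...) unclass(x)
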