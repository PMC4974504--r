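# internal helpers

# evaluate `code` under a temporary RNG seed, restoring the caller's state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(),
                       inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Logarithmically spaced lag grid
#'
#' @param from,to first and last lag, seconds.
#' @param n number of points.
#' @return Strictly increasing numeric vector.
#' @export
log_lags <- function(from = 1e-6, to = 1, n = 200L) {
  stopifnot(from > 0, to > from, n >= 2L)
  exp(seq(log(from), log(to), length.out = n))
}

# finite-difference Jacobian of a residual function at `par`
fd_jacobian <- function(fn, par, eps = 1e-6) {
  r0 <- fn(par)
  J <- matrix(0, length(r0), length(par))
  for (j in seq_along(par)) {
    h <- eps * max(abs(par[j]), 1e-12)
    pj <- par; pj[j] <- pj[j] + h
    J[, j] <- (fn(pj) - r0) / h
  }
  J
}

# standard errors from a residual vector and Jacobian; singular or nearly
# singular directions get Inf (parameter unidentifiable from these data)
se_from_jacobian <- function(J, rss, n_res) {
  k <- ncol(J)
  dof <- max(n_res - k, 1L)
  sigma2 <- rss / dof
  JtJ <- crossprod(J)
  sv <- svd(JtJ)
  tol <- max(sv$d) * 1e-12
  pos <- sv$d > tol
  se <- rep(Inf, k)
  if (any(pos)) {
    inv <- sv$v[, pos, drop = FALSE] %*%
      (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
    dg <- pmax(diag(inv), 0)
    ok <- dg > 0
    if (any(!pos)) {
      # parameters loading on a singular direction are unidentifiable
      null_load <- rowSums(sv$v[, !pos, drop = FALSE]^2)
      ok <- ok & null_load < 0.5
    }
    se[ok] <- sqrt(sigma2 * dg[ok])
  }
  se
}

# multiplicative jitter of a start vector, clipped into bounds
jitter_start <- function(par, lower, upper, range = c(0.5, 2)) {
  fac <- stats::runif(length(par), range[1], range[2])
  out <- ifelse(par == 0, par, par * fac)
  pmin(pmax(out, lower), upper)
}

# run nls.lm from several seeded jittered starts, keep best RSS
lm_multistart <- function(init, lower, upper, resid_fn,
                          n_starts = 5L, jitter_range = c(0.5, 2),
                          seed = 1L, maxiter = 200L) {
  starts <- with_seed(seed, lapply(seq_len(n_starts), function(i)
    jitter_start(init, lower, upper, jitter_range)))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = s, lower = lower, upper = upper,
                           fn = resid_fn,
                           control = minpack.lm::nls.lm.control(
                             maxiter = maxiter, ftol = 1e-13,
                             ptol = 1e-13,
                             maxfev = 100 * (length(init) + 1) * 10))),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss)
      best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("all optimizer starts failed")
  # an exhausted iteration budget with an essentially zero residual is
  # a solved problem, not a failure
  best$converged <- best$fit$info %in% 1:4 ||
    best$rss < 1e-16 * max(1, length(best$fit$fvec))
  best
}
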