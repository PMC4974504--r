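#' Read and write photon streams as CSV
#'
#' Plain-text interchange for time-tagged photon data: a two-column
#' CSV (`time_s`, `channel` with values `donor`/`acceptor`) plus a
#' JSON sidecar (`<path>.json`) echoing resolution, duration, seed and
#' the generating configuration.
#'
#' @param stream a `photon_stream`.
#' @param path CSV file path.
#' @return `write_photon_csv` returns `path` invisibly;
#'   `read_photon_csv` returns a `photon_stream`.
#' @export
write_photon_csv <- function(stream, path) {
  stopifnot(inherits(stream, "photon_stream"))
  df <- data.frame(time_s = stream$times,
                   channel = c("donor", "acceptor")[stream$channel])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(resolution = stream$resolution,
               duration = stream$duration, seed = stream$seed,
               config = config_to_json_list(stream$config))
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_photon_csv
#' @export
read_photon_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "channel") %in% names(df)))
    stop("photon CSV needs columns 'time_s' and 'channel'")
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  ch <- match(df$channel, c("donor", "acceptor"))
  if (anyNA(ch)) stop("unknown channel labels in ", path)
  ord <- order(df$time_s)
  structure(list(times = df$time_s[ord], channel = ch[ord],
                 duration = meta$duration %||% max(df$time_s),
                 resolution = meta$resolution %||% 1e-6,
                 config = meta$config, seed = meta$seed %||% NA_integer_),
            class = "photon_stream")
}

#' Read and write correlation curve sets as CSV
#'
#' Long-format CSV with columns `pair`, `lag_s`, `G`, `n_samples`; the
#' reader tolerates extra columns and returns a named list of
#' `correlation_curve` objects split by pair.
#'
#' @param curves a `correlation_curve` or named list of them.
#' @param path CSV file path.
#' @export
write_curves_csv <- function(curves, path) {
  if (inherits(curves, "correlation_curve")) curves <- list(curves)
  rows <- lapply(curves, function(cv)
    data.frame(pair = attr(cv, "pair"), lag_s = cv$lag, G = cv$G,
               n_samples = cv$n_samples))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_curves_csv
#' @export
read_curves_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("pair", "lag_s", "G")
  if (!all(need %in% names(df)))
    stop("curve CSV needs columns: ", paste(need, collapse = ", "))
  if (is.null(df$n_samples)) df$n_samples <- 1
  out <- lapply(split(df, df$pair), function(d)
    new_correlation_curve(d$lag_s, d$G, d$n_samples, d$pair[1],
                          NA_real_))
  out[order(match(names(out), c("AC-d", "AC-a", "CC-da", "CC-ad")))]
}

#' Read and write binned trajectories as CSV
#'
#' Long-format CSV with columns `trajectory_id`, `bin_index`, `I_D`,
#' `I_A`; the generating configuration is echoed to a JSON sidecar.
#' On reading, bleach indices are recovered with [detect_bleach()].
#'
#' @param trajs list of `binned_trajectory`.
#' @param path CSV file path.
#' @export
write_trajectories_csv <- function(trajs, path) {
  rows <- lapply(trajs, function(tr)
    data.frame(trajectory_id = tr$trajectory_id,
               bin_index = seq_along(tr$I_D),
               I_D = tr$I_D, I_A = tr$I_A))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  cf <- attr(trajs, "config")
  if (!is.null(cf))
    jsonlite::write_json(config_to_json_list(cf),
                         paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}

#' @rdname write_trajectories_csv
#' @export
read_trajectories_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trajectory_id", "bin_index", "I_D", "I_A")
  if (!all(need %in% names(df)))
    stop("trajectory CSV needs columns: ", paste(need, collapse = ", "))
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  bw <- meta$bin_width %||% 0.1
  trajs <- lapply(split(df, df$trajectory_id), function(d) {
    d <- d[order(d$bin_index), ]
    tr <- list(trajectory_id = d$trajectory_id[1], bin_width = bw,
               I_D = d$I_D, I_A = d$I_A)
    tr$bleach_index <- if (length(d$I_D) >= 5L)
      detect_bleach(tr) else NA_integer_
    class(tr) <- "binned_trajectory"
    tr
  })
  trajs <- trajs[order(as.numeric(names(trajs)))]
  attr(trajs, "config") <- meta
  trajs
}

config_to_json_list <- function(cf) {
  out <- unclass(cf)
  if (!is.null(out$brightness)) {
    out$brightness <- as.data.frame(out$brightness)
  }
  out
}
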