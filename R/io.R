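#' Write / read a phase series as delimited text
#'
#' CSV with columns `t_s`, `phase_rad` and a JSON sidecar (`<path>.json`)
#' holding rate, wavelength and origin bin.
#'
#' @param series A [phase_series()].
#' @param path Output CSV path.
#' @export
write_phase_series <- function(series, path) {
  stopifnot(inherits(series, "phase_series"))
  t <- (seq_along(series$values) - 1) / series$rate
  write.csv(data.frame(t_s = t, phase_rad = series$values), path,
            row.names = FALSE)
  jsonlite::write_json(list(rate = series$rate,
                            wavelength = series$wavelength,
                            origin_bin = series$origin_bin),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_phase_series
#' @return `read_phase_series` returns the restored [phase_series()].
#' @export
read_phase_series <- function(path) {
  d <- read.csv(path)
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side,
                                                     simplifyVector = TRUE)
  else list(rate = 1 / diff(d$t_s[1:2]), wavelength = NA, origin_bin = NA)
  phase_series(d$phase_rad, meta$rate,
               if (is.null(meta$wavelength)) NA_real_ else meta$wavelength,
               if (is.null(meta$origin_bin)) NA_integer_
               else as.integer(meta$origin_bin))
}

#' Write / read an IF cube as delimited text
#'
#' One row per chirp; complex fast-time samples serialized as
#' alternating re/im columns. A JSON sidecar records the chirp
#' configuration and, when present, the generating scenario.
#'
#' @param cube An `if_cube`.
#' @param path Output CSV path.
#' @export
write_if_cube <- function(cube, path) {
  stopifnot(inherits(cube, "if_cube"))
  s <- cube$samples
  flat <- matrix(0, nrow(s), 2 * ncol(s))
  flat[, seq(1, 2 * ncol(s), 2)] <- Re(s)
  flat[, seq(2, 2 * ncol(s), 2)] <- Im(s)
  utils::write.table(flat, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  cfg <- unclass(cube$config)
  truth <- if (!is.null(cube$truth)) unclass(cube$truth)
  jsonlite::write_json(list(config = cfg, truth = truth,
                            noise_sd = cube$noise_sd),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_if_cube
#' @return `read_if_cube` returns the restored `if_cube`.
#' @export
read_if_cube <- function(path) {
  flat <- as.matrix(utils::read.table(path, sep = ","))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cfg <- do.call(chirp_config, meta$config[setdiff(names(meta$config),
                                                   "wavelength")])
  re <- flat[, seq(1, ncol(flat), 2), drop = FALSE]
  im <- flat[, seq(2, ncol(flat), 2), drop = FALSE]
  samples <- matrix(complex(real = re, imaginary = im), nrow(flat))
  truth <- if (!is.null(meta$truth) && length(meta$truth))
    do.call(displacement_scenario,
            c(meta$truth[setdiff(names(meta$truth), "rbm_events")],
              list(rbm_events = if (length(meta$truth$rbm_events))
                apply(meta$truth$rbm_events, 1, identity, simplify = FALSE)
                else list())))
  structure(list(samples = samples, config = cfg, truth = truth,
                 noise_sd = meta$noise_sd),
            class = "if_cube")
}

#' Read a displacement scenario from YAML or JSON
#'
#' Top-level keys are [displacement_scenario()] arguments; `rbm_events` is
#' a list of 3-element lists `(start, duration, amplitude)`.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A [displacement_scenario()].
#' @export
read_scenario <- function(path) {
  spec <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required to read YAML scenarios")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(spec$rbm_events)) {
    ev <- spec$rbm_events
    rows <- if (is.matrix(ev) || is.data.frame(ev)) {
      lapply(seq_len(nrow(ev)), function(i) as.numeric(unlist(ev[i, ])))
    } else if (is.list(ev) && length(ev) && !is.list(ev[[1]]) &&
                 all(lengths(ev) == 1)) {
      list(as.numeric(unlist(ev)))   # a single flattened (start, dur, amp)
    } else {
      lapply(ev, function(e) as.numeric(unlist(e)))
    }
    spec$rbm_events <- rows
  }
  do.call(displacement_scenario, spec)
}

#' Write an ECG record as CSV with a JSON sidecar
#'
#' @param record An [ecg_record()].
#' @param path Output CSV path (`t_s`, `mv` columns).
#' @export
write_ecg_csv <- function(record, path) {
  stopifnot(inherits(record, "ecg_record"))
  t <- (seq_along(record$samples) - 1) / record$rate
  write.csv(data.frame(t_s = t, mv = record$samples), path,
            row.names = FALSE)
  jsonlite::write_json(list(rate = record$rate, gain = record$gain,
                            baseline = record$baseline, label = record$label),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
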