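#' Band-limited noise spike-rate input
#'
#' Monte-Carlo generation of the model's external drive: Gaussian white
#' noise low-pass filtered at `spec$cutoff` (zero-phase second-order
#' Butterworth, applied forward and backward), scaled to an sd of
#' `sd_frac * mean_rate`, shifted to the target mean, clipped at zero
#' (rates cannot be negative) and finally rescaled multiplicatively so the
#' realized mean equals `mean_rate` exactly. The reference conditions are
#' low-magnitude (1 AP/sec) 20 Hz-cutoff noise for cortico-cortical and
#' non-stimulated thalamic input, and high-magnitude (50 AP/sec) 50
#' Hz-cutoff noise for the stimulated thalamic condition.
#'
#' @param spec an [lcm_stimulus()].
#' @param duration length, sec.
#' @param dt sample step, ms.
#' @param n_targets number of series (columns of the returned matrix).
#' @param seed integer; with `spec$synchronous = TRUE` all targets share one
#'   series, otherwise each target gets an independently seeded series.
#' @return numeric matrix, `round(duration * 1000 / dt)` rows x `n_targets`
#'   columns, non-negative, in AP/sec.
#' @export
generate_noise <- function(spec, duration, dt, n_targets = 1, seed = 1) {
  if (duration <= 0) stop_fmt("duration must be > 0")
  fs <- 1000 / dt
  if (spec$cutoff >= fs / 2)
    stop_fmt("cutoff %g Hz must be below the Nyquist rate %g Hz",
             spec$cutoff, fs / 2)
  n <- as.integer(round(duration * 1000 / dt))
  if (!isTRUE(spec$active) || spec$mean_rate == 0)
    return(matrix(0, n, n_targets))
  bf <- signal::butter(2, spec$cutoff / (fs / 2), type = "low")
  one_series <- function(s) {
    set.seed(s)
    x <- stats::rnorm(n)
    x <- signal::filtfilt(bf, x)
    x <- x / stats::sd(x) * spec$sd_frac * spec$mean_rate + spec$mean_rate
    x <- pmax(x, 0)
    x * spec$mean_rate / mean(x)
  }
  if (spec$synchronous) {
    s <- one_series(derive_seed(seed, "series/shared"))
    matrix(s, n, n_targets)
  } else {
    vapply(seq_len(n_targets),
           function(j) one_series(derive_seed(seed, paste0("series/", j))),
           numeric(n))
  }
}

#' Realize all external input series for a run
#'
#' Produces one rate series per source group and column: cortico-cortical
#' background (`CC`, independent per column) and sensory/thalamic input
#' (`SI`, one shared series), under the non-stimulated or stimulated
#' condition. The cortico-cortical seed does not depend on the condition,
#' so paired stimulated/non-stimulated runs share their background noise.
#'
#' @param config an [lcm_config()].
#' @param duration total length, sec (warmup + record for a full run).
#' @param seed master seed.
#' @param condition `"non_stimulated"` or `"stimulated"`; the latter swaps
#'   the `thalamic` stimulus for `thalamic_stimulated` when present.
#' @return named list of matrices (steps x columns), one per source group
#'   present in the configuration.
#' @export
realize_inputs <- function(config, duration, seed,
                           condition = c("non_stimulated", "stimulated")) {
  condition <- match.arg(condition)
  n_col <- config$geometry$n_x * config$geometry$n_y
  dt <- config$geometry$dt
  out <- list()
  specs <- config$stimuli
  if (!is.null(specs$cortical) && !is.null(config$groups$CC))
    out$CC <- generate_noise(specs$cortical, duration, dt, n_col,
                             derive_seed(seed, "stimulus/cortical"))
  th <- if (condition == "stimulated" && !is.null(specs$thalamic_stimulated))
    specs$thalamic_stimulated else specs$thalamic
  if (!is.null(th) && !is.null(config$groups$SI))
    out$SI <- generate_noise(th, duration, dt, n_col,
                             derive_seed(seed, "stimulus/thalamic"))
  out
}
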