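#' Override synaptic gains or inhibitory physiology of a configuration
#'
#' Pure helpers used by every protocol: they return a modified copy, never
#' touch the input, and leave the connectivity-relevant fields (geometry,
#' synapse map) untouched, so a prebuilt [build_connectivity()] table stays
#' valid.
#'
#' @param config an [lcm_config()].
#' @param g_E,g_I replacement gains, uV/(mV*Hz) (`NULL` keeps the current
#'   value).
#' @return the modified `lcm_config`.
#' @export
set_gains <- function(config, g_E = NULL, g_I = NULL) {
  if (!is.null(g_E)) config$gains$g_E <- g_E
  if (!is.null(g_I)) config$gains$g_I <- g_I
  config
}

#' @rdname set_gains
#' @param F_max,V_HMF replacement values applied to every inhibitory
#'   (non-source) neuron group; excitatory groups are untouched.
#' @export
override_inhibitory <- function(config, F_max = NULL, V_HMF = NULL) {
  for (nm in names(config$groups)) {
    g <- config$groups[[nm]]
    if (g$polarity == "inhibitory" && !isTRUE(g$is_source)) {
      if (!is.null(F_max)) config$groups[[nm]]$F_max <- F_max
      if (!is.null(V_HMF)) config$groups[[nm]]$V_HMF <- V_HMF
    }
  }
  config
}

#' @rdname set_gains
#' @param V_rev replacement GABA reversal potential, mV.
#' @export
set_gaba_reversal <- function(config, V_rev) {
  if (is.null(config$receptors$GABA)) stop_fmt("no GABA receptor defined")
  config$receptors$GABA$V_rev <- V_rev
  config
}

# run one cell and summarise it; errors become a status string
run_cell <- function(config, conn, seed, condition, warmup, record,
                     msc_block = 10L) {
  tryCatch({
    rec <- run_simulation(config, conn = conn, seed = seed,
                          warmup = warmup, record = record,
                          condition = condition)
    an <- analyze(rec, config, msc_block = msc_block)
    data.frame(MFR = an$MFR, PSD_L = an$PSD_L, PSD_H = an$PSD_H,
               MSC_L = an$MSC_L, MSC_H = an$MSC_H, status = "ok",
               stringsAsFactors = FALSE)
  }, error = function(e)
    data.frame(MFR = NA_real_, PSD_L = NA_real_, PSD_H = NA_real_,
               MSC_L = NA_real_, MSC_H = NA_real_,
               status = conditionMessage(e), stringsAsFactors = FALSE))
}

cell_cached <- function(cache_dir, key, compute) {
  if (is.null(cache_dir)) return(compute())
  if (!dir.exists(cache_dir)) dir.create(cache_dir, recursive = TRUE)
  f <- file.path(cache_dir, paste0(key, ".rds"))
  if (file.exists(f)) return(readRDS(f))
  val <- compute()
  saveRDS(val, f)
  val
}

#' Sweep the synaptic-gain plane
#'
#' Runs one simulation per (`g_E`, `g_I`, condition, replicate) cell and
#' summarises each with MFR, band PSDs and band MSCs. Replicates use
#' different derived seeds ("different random number kernels": new wiring
#' draws and new noise); within a replicate the connectivity is built once
#' and shared across cells, since it does not depend on the gains.
#'
#' @param config an [lcm_config()].
#' @param g_E_values,g_I_values grid values, uV/(mV*Hz).
#' @param conditions subset of `c("non_stimulated", "stimulated")`.
#' @param n_replicates replicate runs per cell.
#' @param seed master seed.
#' @param warmup,record durations, sec (defaults from `config$run`).
#' @param cache_dir optional directory; finished cells are cached by
#'   configuration hash and reused on resume.
#' @param msc_block see [analyze()].
#' @return an `lcm_phase_map`: data.frame with one row per cell x condition
#'   x replicate (columns `g_E`, `g_I`, `condition`, `replicate`, `MFR`,
#'   `PSD_L`, `PSD_H`, `MSC_L`, `MSC_H`, `status`).
#' @export
sweep_gains <- function(config, g_E_values, g_I_values,
                        conditions = "non_stimulated", n_replicates = 1,
                        seed = 1, warmup = config$run$warmup,
                        record = config$run$record, cache_dir = NULL,
                        msc_block = 10L) {
  stopifnot(length(g_E_values) >= 1, length(g_I_values) >= 1)
  rows <- list()
  for (rep_i in seq_len(n_replicates)) {
    rseed <- derive_seed(seed, paste0("replicate/", rep_i))
    conn <- build_connectivity(config, rseed)
    for (gI in g_I_values) for (gE in g_E_values) for (cond in conditions) {
      cfg <- set_gains(config, gE, gI)
      key <- config_hash(list(h = config_hash(cfg), cond = cond,
                              seed = rseed, warmup = warmup,
                              record = record))
      cell <- cell_cached(cache_dir, key, function()
        run_cell(cfg, conn, rseed, cond, warmup, record, msc_block))
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(g_E = gE, g_I = gI, condition = cond,
                   replicate = rep_i), cell)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("lcm_phase_map", "data.frame")
  attr(out, "seed") <- seed
  out
}

#' @export
summary.lcm_phase_map <- function(object, ...) {
  d <- as.data.frame(object)
  key <- interaction(d$g_E, d$g_I, d$condition, drop = TRUE)
  agg <- do.call(rbind, lapply(split(d, key), function(s) {
    data.frame(g_E = s$g_E[1], g_I = s$g_I[1], condition = s$condition[1],
               n = nrow(s), MFR = mean(s$MFR),
               MFR_sd = if (nrow(s) >= 2) stats::sd(s$MFR) else NA_real_,
               PSD_L = mean(s$PSD_L), PSD_H = mean(s$PSD_H),
               MSC_L = mean(s$MSC_L), MSC_H = mean(s$MSC_H))
  }))
  rownames(agg) <- NULL
  agg
}

#' @export
plot.lcm_phase_map <- function(x, statistic = "MFR",
                               condition = unique(x$condition)[1], ...) {
  d <- summary(x)
  d <- d[d$condition == condition, ]
  gE <- sort(unique(d$g_E)); gI <- sort(unique(d$g_I))
  z <- matrix(NA_real_, length(gE), length(gI))
  for (i in seq_len(nrow(d)))
    z[match(d$g_E[i], gE), match(d$g_I[i], gI)] <- d[[statistic]][i]
  graphics::image(gE, gI, log10(z + 1e-6), xlab = "g_E (uV/(mV*Hz))",
                  ylab = "g_I (uV/(mV*Hz))",
                  main = paste0("log10 ", statistic, " (", condition, ")"),
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

#' Locate the critical excitatory gain by bisection
#'
#' At fixed `g_I`, the mean firing rate jumps discontinuously from the
#' quiescent to the active branch as `g_E` crosses its critical value.
#' `find_critical_gain` bisects on `MFR(g_E) > jump_threshold` until the
#' bracketing interval is narrower than `tol` and returns its midpoint.
#' Every evaluation reuses the same wiring and noise seed, so the scanned
#' quantity is a deterministic function of `g_E`.
#'
#' @param config an [lcm_config()].
#' @param g_I inhibitory gain, uV/(mV*Hz).
#' @param interval length-2 search interval for `g_E`.
#' @param jump_threshold rate separating the two branches, AP/sec (5, well
#'   between the quiescent < 0.4 and active > 10 regimes).
#' @param tol interval width at which bisection stops, uV/(mV*Hz) (0.003,
#'   the finest grid spacing used in the reference maps).
#' @param seed master seed for wiring and noise.
#' @param warmup,record durations per evaluation, sec.
#' @param conn optional prebuilt connectivity.
#' @param mfr_fn optional replacement for the simulation: a function
#'   `g_E -> MFR` (used in tests against step-function oracles).
#' @return list of class `lcm_critical_gain`: `g_E_C` (midpoint), `interval`
#'   (final bracket), `evaluations` (data.frame of `g_E`, `MFR`).
#' @export
find_critical_gain <- function(config, g_I, interval, jump_threshold = 5,
                               tol = 0.003, seed = 1,
                               warmup = config$run$warmup,
                               record = config$run$record, conn = NULL,
                               mfr_fn = NULL) {
  if (is.null(mfr_fn)) {
    if (is.null(conn)) conn <- build_connectivity(config, seed)
    mfr_fn <- function(gE) {
      cfg <- set_gains(config, gE, g_I)
      rec <- run_simulation(cfg, conn = conn, seed = seed, warmup = warmup,
                            record = record)
      mean_firing_rate(column_excitation(rec, cfg)[, centre_col(cfg$geometry)])
    }
  }
  lo <- min(interval); hi <- max(interval)
  evals <- data.frame(g_E = numeric(), MFR = numeric())
  f <- function(gE) {
    m <- mfr_fn(gE)
    evals <<- rbind(evals, data.frame(g_E = gE, MFR = m))
    m
  }
  flo <- f(lo); fhi <- f(hi)
  if (!(flo < jump_threshold && fhi > jump_threshold))
    stop_fmt("no boundary in range: MFR(%g) = %.3g, MFR(%g) = %.3g do not straddle %g AP/sec",
             lo, flo, hi, fhi, jump_threshold)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > jump_threshold) hi <- mid else lo <- mid
  }
  structure(list(g_E_C = (lo + hi) / 2, interval = c(lo, hi), g_I = g_I,
                 jump_threshold = jump_threshold, tol = tol,
                 evaluations = evals),
            class = "lcm_critical_gain")
}

#' @export
print.lcm_critical_gain <- function(x, ...) {
  cat(sprintf("<lcm_critical_gain> g_E,C = %.4g uV/(mV*Hz) at g_I = %g (bracket [%.4g, %.4g], %d runs)\n",
              x$g_E_C, x$g_I, x$interval[1], x$interval[2],
              nrow(x$evaluations)))
  invisible(x)
}

#' Fit the critical boundary line
#'
#' Ordinary least squares of the critical excitatory gain on the inhibitory
#' gain, `g_EC = slope * g_I + intercept`. Also reports the algebraically
#' inverted form `g_IC = (1/slope) * g_E + (-intercept/slope)` for
#' comparison with boundary statements made on the other axis.
#'
#' @param points data.frame with columns `g_I` and `g_E_C` (>= 3 rows).
#' @return object of class `lcm_boundary` with `coef()` (named
#'   `intercept`, `slope`), `inverted`, `residuals` and the underlying
#'   [stats::lm()] fit.
#' @export
fit_boundary <- function(points) {
  if (nrow(points) < 3) stop_fmt("boundary fit needs >= 3 points, got %d",
                                 nrow(points))
  if (stats::sd(points$g_I) == 0)
    stop_fmt("degenerate boundary fit: all g_I equal")
  fit <- stats::lm(g_E_C ~ g_I, data = points)
  co <- stats::coef(fit)
  structure(list(points = points, fit = fit,
                 slope = unname(co[2]), intercept = unname(co[1]),
                 inverted = c(slope = unname(1 / co[2]),
                              intercept = unname(-co[1] / co[2])),
                 residuals = unname(stats::residuals(fit))),
            class = "lcm_boundary")
}

#' @export
coef.lcm_boundary <- function(object, ...)
  c(intercept = object$intercept, slope = object$slope)

#' @export
print.lcm_boundary <- function(x, ...) {
  cat(sprintf("<lcm_boundary> g_E,C = %.4g * g_I + %.4g  (n = %d, rms residual %.2g)\n",
              x$slope, x$intercept, nrow(x$points),
              sqrt(mean(x$residuals^2))))
  cat(sprintf("  inverted: g_I,C = %.4g * g_E + %.4g\n",
              x$inverted[["slope"]], x$inverted[["intercept"]]))
  invisible(x)
}

#' @export
plot.lcm_boundary <- function(x, ...) {
  graphics::plot(x$points$g_I, x$points$g_E_C, xlab = "g_I (uV/(mV*Hz))",
                 ylab = "critical g_E (uV/(mV*Hz))", pch = 19, ...)
  graphics::abline(x$intercept, x$slope, lty = 2)
  invisible(x)
}

#' Transient gain perturbation with paired baseline
#'
#' Runs the network twice with identical wiring and noise: once unperturbed
#' and once with one gain changed by `delta` during
#' `[start, start + duration]` seconds of the recording window, restored
#' afterwards. Returns both records, the central-column excitation
#' difference trace, and a hysteresis flag: whether the perturbed network
#' failed to return to the baseline state after restoration (mean absolute
#' difference over the post-restoration tail, from 0.1 s after restoration
#' onward, exceeding 5% of the peak difference during the window).
#'
#' @param config an [lcm_config()].
#' @param which `"g_E"` or `"g_I"`.
#' @param delta gain change, uV/(mV*Hz) (negative weakens).
#' @param start,duration window, sec (relative to recording start).
#' @param seed master seed shared by both runs.
#' @param warmup,record durations, sec.
#' @param conn optional prebuilt connectivity.
#' @param settle_delay,settle_frac tail start after restoration (sec) and
#'   the hysteresis threshold as a fraction of the peak difference.
#' @return list of class `lcm_transient`: `time` (sec), `base`, `perturbed`
#'   (central-column excitation), `diff`, `hysteresis` (logical),
#'   `tail_diff`, `peak_diff`, `window`.
#' @export
transient_gain_protocol <- function(config, which = c("g_E", "g_I"), delta,
                                    start, duration, seed = 1,
                                    warmup = config$run$warmup,
                                    record = config$run$record, conn = NULL,
                                    settle_delay = 0.1, settle_frac = 0.05) {
  which <- match.arg(which)
  if (start < 0 || start + duration > record)
    stop_fmt("perturbation window [%g, %g] s outside the recording window",
             start, start + duration)
  if (is.null(conn)) conn <- build_connectivity(config, seed)
  inputs <- realize_inputs(config, warmup + record, seed)
  base <- run_simulation(config, conn, inputs, seed = seed, warmup = warmup,
                         record = record)
  prot <- protocol_window(which, start, start + duration, delta, "delta")
  pert <- run_simulation(config, conn, inputs, protocol = prot, seed = seed,
                         warmup = warmup, record = record)
  cc <- centre_col(config$geometry)
  b <- column_excitation(base, config)[, cc]
  p <- column_excitation(pert, config)[, cc]
  d <- p - b
  tt <- (seq_along(d) - 1) * config$geometry$dt / 1000
  in_win <- tt >= start & tt <= start + duration
  tail_sel <- tt >= start + duration + settle_delay
  peak <- max(abs(d[in_win | tail_sel]), 0)
  tail_diff <- if (any(tail_sel)) mean(abs(d[tail_sel])) else NA_real_
  structure(list(time = tt, base = b, perturbed = p, diff = d,
                 window = c(start, start + duration), which = which,
                 delta = delta, peak_diff = peak, tail_diff = tail_diff,
                 hysteresis = isTRUE(tail_diff > settle_frac * peak &&
                                       peak > 0),
                 base_record = base, perturbed_record = pert),
            class = "lcm_transient")
}

#' @export
print.lcm_transient <- function(x, ...) {
  cat(sprintf("<lcm_transient> %s %+g for %g s: peak |diff| %.3g, post-restoration |diff| %.3g AP/sec -> hysteresis: %s\n",
              x$which, x$delta, diff(x$window), x$peak_diff, x$tail_diff,
              x$hysteresis))
  invisible(x)
}

#' @export
plot.lcm_transient <- function(x, ...) {
  graphics::plot(x$time, x$base, type = "l", xlab = "time (s)",
                 ylab = "central-column excitation (AP/sec)", ...)
  graphics::lines(x$time, x$perturbed, col = 2)
  graphics::abline(v = x$window, lty = 3)
  invisible(x)
}

#' Inhibitory reversal-potential shift map
#'
#' Like [sweep_gains()], but the second axis overrides the GABA reversal
#' potential instead of the excitatory gain; `g_E` stays at the
#' configuration's value.
#'
#' @inheritParams sweep_gains
#' @param V_rev_values GABA reversal potentials, mV.
#' @return `lcm_phase_map`-style data.frame with columns `g_I`, `V_rev`,
#'   and the cell statistics.
#' @export
reversal_shift_protocol <- function(config, g_I_values, V_rev_values,
                                    seed = 1, warmup = config$run$warmup,
                                    record = config$run$record,
                                    msc_block = 10L) {
  rseed <- derive_seed(seed, "replicate/1") # matches sweep_gains
  conn <- build_connectivity(config, rseed)
  rows <- list()
  for (vr in V_rev_values) for (gI in g_I_values) {
    cfg <- set_gaba_reversal(set_gains(config, g_I = gI), vr)
    cell <- run_cell(cfg, conn, rseed, "non_stimulated", warmup, record,
                     msc_block)
    rows[[length(rows) + 1L]] <-
      cbind(data.frame(g_I = gI, V_rev = vr), cell)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("lcm_phase_map", "data.frame")
  out
}

#' SCN1A mutation scans
#'
#' Emulate biophysical consequences of SCN1A loss-of-function mutations in
#' inhibitory neurons: `scn1a_fmax_protocol` scans impaired firing
#' capability (maximum firing rate of every inhibitory group reduced from
#' 200 to 40 AP/sec in steps of 10); `scn1a_vhmf_protocol` scans a positive
#' shift of the firing threshold (half-maximum-firing voltage raised from
#' -45 to -19 mV in steps of 2). Excitatory groups are never modified.
#'
#' @param config an [lcm_config()].
#' @param values scan values (defaults above).
#' @param gain_pairs data.frame with columns `g_E`, `g_I`; one scan per row.
#' @param seed master seed.
#' @param warmup,record durations, sec.
#' @param msc_block see [analyze()].
#' @param conn optional prebuilt [build_connectivity()] table; when given,
#'   the master seed is used directly instead of the first-replicate
#'   derivation, so scans share wiring with other conn-pinned calls.
#' @return `lcm_phase_map`-style data.frame with the scan value, gains and
#'   cell statistics.
#' @export
scn1a_fmax_protocol <- function(config, values = seq(200, 40, by = -10),
                                gain_pairs = data.frame(g_E = config$gains$g_E,
                                                        g_I = config$gains$g_I),
                                seed = 1, warmup = config$run$warmup,
                                record = config$run$record, msc_block = 10L,
                                conn = NULL) {
  scn1a_scan(config, values, "F_max", gain_pairs, seed, warmup, record,
             msc_block, conn)
}

#' @rdname scn1a_fmax_protocol
#' @export
scn1a_vhmf_protocol <- function(config, values = seq(-45, -19, by = 2),
                                gain_pairs = data.frame(g_E = config$gains$g_E,
                                                        g_I = config$gains$g_I),
                                seed = 1, warmup = config$run$warmup,
                                record = config$run$record, msc_block = 10L,
                                conn = NULL) {
  scn1a_scan(config, values, "V_HMF", gain_pairs, seed, warmup, record,
             msc_block, conn)
}

scn1a_scan <- function(config, values, field, gain_pairs, seed, warmup,
                       record, msc_block, conn = NULL) {
  # default wiring matches sweep_gains' first replicate; a prebuilt table
  # pins the scan to that wiring and uses the master seed directly
  rseed <- if (is.null(conn)) derive_seed(seed, "replicate/1") else seed
  if (is.null(conn)) conn <- build_connectivity(config, rseed)
  rows <- list()
  for (i in seq_len(nrow(gain_pairs))) for (v in values) {
    cfg <- set_gains(config, gain_pairs$g_E[i], gain_pairs$g_I[i])
    cfg <- if (field == "F_max") override_inhibitory(cfg, F_max = v)
           else override_inhibitory(cfg, V_HMF = v)
    cell <- run_cell(cfg, conn, rseed, "non_stimulated", warmup, record,
                     msc_block)
    row <- data.frame(value = v, g_E = gain_pairs$g_E[i],
                      g_I = gain_pairs$g_I[i])
    names(row)[1] <- field
    rows[[length(rows) + 1L]] <- cbind(row, cell)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("lcm_phase_map", "data.frame")
  out
}

#' Stimulation response at fixed gains
#'
#' Paired runs under the non-stimulated and stimulated thalamic input
#' conditions, sharing the cortico-cortical noise and the wiring, and the
#' differences of the summary statistics between them.
#'
#' @param config an [lcm_config()].
#' @param gain_pairs data.frame with columns `g_E`, `g_I`.
#' @param seed master seed.
#' @param warmup,record durations, sec.
#' @param msc_block see [analyze()].
#' @param conn optional prebuilt connectivity (see [scn1a_fmax_protocol()]).
#' @return data.frame with per-pair statistics under both conditions and
#'   their differences (`dMFR`, `dPSD_L`, `dPSD_H`, `dMSC_L`, `dMSC_H`).
#' @export
stimulation_response <- function(config,
                                 gain_pairs = data.frame(g_E = config$gains$g_E,
                                                         g_I = config$gains$g_I),
                                 seed = 1, warmup = config$run$warmup,
                                 record = config$run$record,
                                 msc_block = 10L, conn = NULL) {
  rseed <- if (is.null(conn)) derive_seed(seed, "replicate/1") else seed
  if (is.null(conn)) conn <- build_connectivity(config, rseed)
  rows <- list()
  for (i in seq_len(nrow(gain_pairs))) {
    cfg <- set_gains(config, gain_pairs$g_E[i], gain_pairs$g_I[i])
    ns <- run_cell(cfg, conn, rseed, "non_stimulated", warmup, record,
                   msc_block)
    st <- run_cell(cfg, conn, rseed, "stimulated", warmup, record, msc_block)
    rows[[length(rows) + 1L]] <- data.frame(
      g_E = gain_pairs$g_E[i], g_I = gain_pairs$g_I[i],
      MFR_ns = ns$MFR, MFR_stim = st$MFR, dMFR = st$MFR - ns$MFR,
      dPSD_L = st$PSD_L - ns$PSD_L, dPSD_H = st$PSD_H - ns$PSD_H,
      dMSC_L = st$MSC_L - ns$MSC_L, dMSC_H = st$MSC_H - ns$MSC_H,
      status = ifelse(ns$status == "ok" && st$status == "ok", "ok",
                      paste(ns$status, st$status)))
  }
  do.call(rbind, rows)
}

#' Quasi-static hysteresis sweep
#'
#' Sweeps `g_E` stepwise across its critical value without re-initialising
#' the network: a single run applies each gain value for `hold` seconds
#' (absolute protocol windows back to back) and the plateau MFR is measured
#' over the trailing `measure_frac` of each window. Run once with the
#' values ascending and once descending (same wiring and noise); near a
#' first-order transition the two branches disagree over a finite gain
#' interval and agree far from it.
#'
#' @param config an [lcm_config()].
#' @param g_E_values gain plateau values (given in ascending order).
#' @param g_I fixed inhibitory gain.
#' @param hold plateau duration, sec.
#' @param measure_frac trailing fraction of each plateau used for the MFR.
#' @param seed master seed.
#' @param warmup warmup before the first plateau, sec.
#' @param conn optional prebuilt connectivity.
#' @return data.frame with `g_E`, `MFR_up`, `MFR_down` and the absolute
#'   branch difference `gap`.
#' @export
hysteresis_sweep <- function(config, g_E_values, g_I, hold = 2,
                             measure_frac = 0.5, seed = 1,
                             warmup = config$run$warmup, conn = NULL) {
  g_E_values <- sort(g_E_values)
  if (is.null(conn)) conn <- build_connectivity(config, seed)
  one_dir <- function(vals) {
    n <- length(vals)
    sched <- do.call(rbind, lapply(seq_len(n), function(i)
      protocol_window("g_E", (i - 1) * hold, i * hold, vals[i], "absolute")))
    # warm up on the first plateau's gain so the sweep starts on the branch
    # selected by its own initial value, not by the config default
    cfg <- set_gains(config, g_E = vals[1], g_I = g_I)
    rec <- run_simulation(cfg, conn, seed = seed, warmup = warmup,
                          record = n * hold, protocol = sched)
    ex <- column_excitation(rec, cfg)[, centre_col(cfg$geometry)]
    steps_per <- as.integer(round(hold * 1000 / cfg$geometry$dt))
    vapply(seq_len(n), function(i) {
      i1 <- i * steps_per
      i0 <- i1 - as.integer(measure_frac * steps_per) + 1L
      mean_firing_rate(ex[i0:i1])
    }, 0)
  }
  up <- one_dir(g_E_values)
  down <- rev(one_dir(rev(g_E_values)))
  data.frame(g_E = g_E_values, MFR_up = up, MFR_down = down,
             gap = abs(up - down))
}
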