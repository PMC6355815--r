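#' Column excitation series
#'
#' The excitation level of a cortical column is the unweighted mean firing
#' rate of its excitatory neuron groups at each time step; all rate
#' summaries (MFR, PSD, MSC) are computed from these series. Thalamic
#' groups (layer `"TH"`) belong to the thalamic sheet, not to a cortical
#' column, and are excluded.
#'
#' @param record an `lcm_record`.
#' @param config the matching [lcm_config()] (resolves group polarity).
#' @return matrix, time steps x columns, AP/sec.
#' @export
column_excitation <- function(record, config) {
  pol <- vapply(config$groups, `[[`, "", "polarity")
  src <- vapply(config$groups, function(g) isTRUE(g$is_source), TRUE)
  lay <- vapply(config$groups, `[[`, "", "layer")
  exc <- names(config$groups)[pol == "excitatory" & !src & lay != "TH"]
  exc <- intersect(exc, unique(record$units$group))
  if (length(exc) == 0) stop_fmt("record contains no excitatory neuron groups")
  n_col <- max(record$units$col)
  out <- matrix(0, nrow(record$rates), n_col)
  for (g in exc) {
    sel <- record$units$group == g
    out <- out + record$rates[, sel, drop = FALSE][, order(record$units$col[sel]),
                                                   drop = FALSE]
  }
  out / length(exc)
}

# tapered-cosine (Tukey) window; a = total taper fraction
tukey_window <- function(n, a = 0.25) {
  if (n == 1) return(1)
  w <- rep(1, n)
  edge <- floor(a * (n - 1) / 2)
  if (edge > 0) {
    i <- 0:edge
    w[i + 1] <- 0.5 * (1 + cos(pi * (2 * i / (a * (n - 1)) - 1)))
    w[n - i] <- w[i + 1]
  }
  w
}

#' Tapered-cosine-weighted temporal mean firing rate
#'
#' Temporal mean of a rate series weighted by a Tukey (tapered cosine)
#' window with taper fraction `taper`, normalised to unit total weight. The
#' taper suppresses cut-off effects of oscillatory series at the window
#' edges; a constant series returns its value exactly for any taper.
#'
#' @param series numeric rate series, AP/sec.
#' @param taper total taper fraction in `[0, 1]`.
#' @return scalar MFR, AP/sec.
#' @export
mean_firing_rate <- function(series, taper = 0.25) {
  if (length(series) == 0) stop_fmt("empty series")
  w <- tukey_window(length(series), taper)
  sum(w * series) / sum(w)
}

# Welch segmentation shared by PSD and MSC: ten segments, 50% overlap,
# Hamming window, per-segment mean removal. Returns the one-sided rFFT of
# every segment plus the density normalisation.
welch_fft <- function(x, dt, n_segments = 10) {
  n <- if (is.matrix(x)) nrow(x) else length(x)
  x <- as.matrix(x)
  L <- floor(2 * n / (n_segments + 1))
  if (L < 8) stop_fmt("series too short for %d Welch segments", n_segments)
  step <- floor(L / 2)
  fs <- 1000 / dt
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(L - 1)) / (L - 1)) # Hamming
  U <- sum(w^2)
  nf <- floor(L / 2) + 1
  X <- array(0i, dim = c(nf, n_segments, ncol(x)))
  for (s in seq_len(n_segments)) {
    i0 <- (s - 1) * step
    seg <- x[(i0 + 1):(i0 + L), , drop = FALSE]
    seg <- sweep(seg, 2, colMeans(seg)) * w
    F <- stats::mvfft(seg)
    X[, s, ] <- F[seq_len(nf), ]
  }
  scale <- 2 / (fs * U) # one-sided density; DC & Nyquist halved below
  list(X = X, freq = (seq_len(nf) - 1) * fs / L, scale = scale, L = L)
}

#' Welch power spectral density
#'
#' PSD of a rate series by Welch's method: the series is split into ten
#' equal-length segments with 50% overlap, each segment is mean-removed and
#' Hamming-windowed, and the one-sided density-scaled periodograms are
#' averaged.
#'
#' @param series numeric series (AP/sec).
#' @param dt sample step, ms.
#' @param n_segments number of segments.
#' @return `data.frame` with `freq` (Hz) and `power` ((AP/sec)^2/Hz).
#' @export
welch_psd <- function(series, dt, n_segments = 10) {
  wf <- welch_fft(series, dt, n_segments)
  p <- apply(Mod(wf$X[, , 1, drop = FALSE])^2, 1, mean) * wf$scale
  p[1] <- p[1] / 2
  if (wf$L %% 2 == 0) p[length(p)] <- p[length(p)] / 2
  data.frame(freq = wf$freq, power = p)
}

#' Magnitude-squared coherence across columns
#'
#' Mean MSC over all unordered column pairs, estimated with the same Welch
#' segmentation as [welch_psd()]: per pair,
#' `|CPSD(F_i, F_j)|^2 / (PSD(F_i) PSD(F_j))` with segment-averaged cross-
#' and auto-spectra. With `corrected = FALSE` the denominator uses
#' `PSD(F_i)^2` instead (the uncorrected published form, under which the
#' estimate is not bounded by 1); the corrected form is the default and
#' always lies in `[0, 1]`.
#'
#' @param series matrix, time x columns (>= 2 columns).
#' @param dt sample step, ms.
#' @param max_freq discard frequencies above this, Hz (the coherence bands
#'   of interest end at 50 Hz; `Inf` keeps the full spectrum).
#' @param corrected use the symmetric denominator (default).
#' @param n_segments Welch segments.
#' @return `data.frame` with `freq` (Hz), `msc`, and `n_pairs` attribute.
#' @export
msc <- function(series, dt, max_freq = Inf, corrected = TRUE,
                n_segments = 10) {
  if (!is.matrix(series) || ncol(series) < 2)
    stop_fmt("msc needs a matrix with at least 2 column series")
  wf <- welch_fft(series, dt, n_segments)
  keep <- wf$freq <= max_freq
  X <- wf$X[keep, , , drop = FALSE]
  nf <- dim(X)[1]; ns <- dim(X)[2]; nc <- dim(X)[3]
  auto <- matrix(0, nf, nc)
  for (j in seq_len(nc)) auto[, j] <- rowSums(Mod(X[, , j, drop = FALSE])^2) / ns
  dead <- colSums(auto) <= 0
  if (any(dead)) {
    warning(sprintf("%d zero-power column(s) skipped in MSC", sum(dead)))
    if (sum(!dead) < 2) stop_fmt("fewer than 2 columns with power")
  }
  live <- which(!dead)
  acc <- numeric(nf); npair <- 0L
  for (a in seq_along(live)) {
    i <- live[a]
    if (a == length(live)) break
    js <- live[(a + 1):length(live)]
    # segment-averaged cross-spectra of column i against all later columns
    Xi <- X[, , i]
    for (j in js) {
      cross <- rowSums(Xi * Conj(X[, , j])) / ns
      den <- if (corrected) auto[, i] * auto[, j] else auto[, i]^2
      acc <- acc + Mod(cross)^2 / den
      npair <- npair + 1L
    }
  }
  out <- data.frame(freq = wf$freq[keep], msc = acc / npair)
  attr(out, "n_pairs") <- npair
  out
}

#' Band mean of a spectrum
#'
#' Mean of the spectral values at the frequency bins whose centre lies in
#' `[band[1], band[2]]`. The reference bands are 2-15 Hz (low) and 16-50 Hz
#' (high).
#'
#' @param spectrum `data.frame` with `freq` and one value column (the second
#'   column is used).
#' @param band numeric length-2, Hz.
#' @return scalar band mean.
#' @export
band_mean <- function(spectrum, band) {
  sel <- spectrum$freq >= band[1] & spectrum$freq <= band[2]
  if (!any(sel))
    stop_fmt("band [%g, %g] Hz contains no frequency bins", band[1], band[2])
  mean(spectrum[[2]][sel])
}

#' Standard summary statistics of a rate record
#'
#' MFR and Welch PSD are computed from the excitation series of the sheet's
#' geometric centre column; the MSC is computed across the excitation series
#' of the central 10 x 10 block (all columns, with a note, when the sheet is
#' smaller). Band means use the 2-15 Hz (low) and 16-50 Hz (high) bands.
#'
#' @param record an `lcm_record`.
#' @param config the matching [lcm_config()].
#' @param msc_block edge length of the central block used for coherence.
#' @return an object of class `lcm_analysis`: list with `MFR`, `PSD`
#'   (data.frame), `PSD_L`, `PSD_H`, `MSC` (data.frame), `MSC_L`, `MSC_H`,
#'   `n_columns_used`.
#' @export
analyze <- function(record, config, msc_block = 10L) {
  ex <- column_excitation(record, config)
  centre <- centre_col(config$geometry)
  mfr <- mean_firing_rate(ex[, centre])
  psd <- welch_psd(ex[, centre], record$dt)
  block <- central_block(config$geometry, msc_block, msc_block)
  note <- NULL
  if (length(block) < msc_block^2)
    note <- sprintf("sheet smaller than %dx%d: MSC over all %d columns",
                    msc_block, msc_block, length(block))
  ms <- if (length(block) >= 2)
    msc(ex[, block, drop = FALSE], record$dt, max_freq = 60) else NULL
  res <- list(MFR = mfr, PSD = psd,
              PSD_L = band_mean(psd, c(2, 15)),
              PSD_H = band_mean(psd, c(16, 50)),
              MSC = ms,
              MSC_L = if (is.null(ms)) NA_real_ else band_mean(ms, c(2, 15)),
              MSC_H = if (is.null(ms)) NA_real_ else band_mean(ms, c(16, 50)),
              n_columns_used = length(block), note = note)
  class(res) <- "lcm_analysis"
  res
}

#' @export
print.lcm_analysis <- function(x, ...) {
  cat(sprintf("<lcm_analysis> MFR = %.3g AP/sec | PSD_L = %.3g, PSD_H = %.3g (AP/sec)^2/Hz | MSC_L = %.3g, MSC_H = %.3g\n",
              x$MFR, x$PSD_L, x$PSD_H, x$MSC_L, x$MSC_H))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Correlations of rate statistics with the gains, by phase region
#'
#' Partitions the cells of a gain-sweep phase map into the subcritical
#' region (`g_E <= g_EC(g_I) - delta`) and the supercritical region
#' (`g_E >= g_EC(g_I) + delta`) using a fitted critical boundary, excluding
#' cells within `delta` of the line, and reports the Pearson correlation of
#' each statistic against each gain within each region.
#'
#' @param map an `lcm_phase_map` (see [sweep_gains()]).
#' @param boundary an `lcm_boundary` (see [fit_boundary()]).
#' @param delta exclusion margin around the boundary, uV/(mV*Hz).
#' @param stats statistic columns to correlate.
#' @return `data.frame` with columns `statistic`, `gain`, `region`, `r`,
#'   `n`; `r` is `NA` (with a note) where a statistic is constant.
#' @export
region_correlations <- function(map, boundary, delta = 0.002,
                                stats = c("MFR", "PSD_L", "PSD_H",
                                          "MSC_L", "MSC_H")) {
  cells <- as.data.frame(map)
  bc <- stats::coef(boundary)
  gc <- bc[["intercept"]] + bc[["slope"]] * cells$g_I
  region <- ifelse(cells$g_E <= gc - delta, "region1",
                   ifelse(cells$g_E >= gc + delta, "region2", NA))
  out <- list()
  for (st in intersect(stats, names(cells)))
    for (gn in c("g_E", "g_I"))
      for (rg in c("region1", "region2")) {
        sel <- !is.na(region) & region == rg & is.finite(cells[[st]])
        r <- if (sum(sel) >= 3 && stats::sd(cells[[st]][sel]) > 0 &&
                 stats::sd(cells[[gn]][sel]) > 0)
          stats::cor(cells[[gn]][sel], cells[[st]][sel]) else NA_real_
        out[[length(out) + 1L]] <- data.frame(
          statistic = st, gain = gn, region = rg, r = r, n = sum(sel))
      }
  do.call(rbind, out)
}
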