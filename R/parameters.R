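#' @title Model parameter objects
#' @description Constructors, validation and (de)serialization for the full
#'   parameter set of the laminar cortex model: column-sheet geometry, neuron
#'   group physiology, receptor kinetics, the quantitative synaptic
#'   connection map, synaptic gains, stimulus specifications and run control.
#'
#' Internal unit system: mV, ms, um, AP/sec. Synaptic gains are configured in
#' uV/(mV*Hz) -- the unit every printed gain value uses -- and converted to
#' mV per (mV * AP/sec) inside the engine (factor 1e-3).
#' @name parameters
NULL

#' Neuron group specification
#'
#' A neuron group is all neurons of one type inside one cortical column,
#' treated as a single mean-field unit with one membrane potential and one
#' output spike rate.
#'
#' @param name group label, e.g. `"P2/3"`, `"I4"`, `"RLGN"`.
#' @param layer lamina label: `"I"`, `"II/III"`, `"IV"`, `"V"`, `"VI"` or
#'   `"TH"` (thalamus).
#' @param polarity `"excitatory"` or `"inhibitory"`; decides whether the
#'   group's outgoing synapses are scaled by the excitatory gain `g_E`
#'   (AMPA + NMDA) or the inhibitory gain `g_I` (GABA).
#' @param F_max maximum firing rate, AP/sec.
#' @param k firing gain (sigmoid steepness), 1/mV.
#' @param V_HMF membrane potential at half-maximum firing, mV.
#' @param V_rest resting potential, mV.
#' @param tau_m membrane time constant, ms.
#' @param density relative neurons per column (bookkeeping only).
#' @param pyramidal logical; pyramidal morphology (sets the default spatial
#'   spread of outgoing connections to 80 um rather than 40 um).
#' @param is_source logical; `TRUE` marks an external input source (a rate
#'   series injected by a stimulus, with no membrane dynamics of its own).
#' @param provenance `"published"` for values with a published reference,
#'   `"fixture-assumed"` for values this package chooses itself (the
#'   quantitative physiology and synapse tables are not redistributed
#'   with it); `"mixed"` where a record combines both.
#' @return a list of class `lcm_group`.
#' @export
lcm_group <- function(name, layer, polarity, F_max = NA_real_, k = NA_real_,
                      V_HMF = NA_real_, V_rest = -65, tau_m = NA_real_,
                      density = 1, pyramidal = FALSE, is_source = FALSE,
                      provenance = "fixture-assumed") {
  g <- list(name = name, layer = layer, polarity = polarity,
            F_max = as.numeric(F_max), k = as.numeric(k),
            V_HMF = as.numeric(V_HMF), V_rest = as.numeric(V_rest),
            tau_m = as.numeric(tau_m), density = as.numeric(density),
            pyramidal = isTRUE(pyramidal), is_source = isTRUE(is_source),
            provenance = provenance)
  class(g) <- "lcm_group"
  g
}

#' Receptor specification
#'
#' Kinetics of one neurotransmitter receptor class. The postsynaptic time
#' course is a bi-exponential kernel with transmission delay `tau_0`, rise
#' constant `tau_r` and fall constant `tau_f`, normalised to unit time
#' integral (see [receptor_kernel()]). `lambda_adapt` is the spike-adaptation
#' parameter: the synaptic drive is `phi * exp(-lambda_adapt * phi)`, maximal
#' at an afferent rate of `1/lambda_adapt` AP/sec.
#'
#' @param name `"AMPA"`, `"NMDA"` or `"GABA"` (other labels allowed).
#' @param tau_0 synaptic transmission delay, ms.
#' @param tau_r,tau_f rise and fall time constants, ms.
#' @param lambda_adapt adaptation parameter, sec.
#' @param V_rev reversal potential, mV (0 for AMPA/NMDA, -70 for GABA).
#' @param provenance see [lcm_group()].
#' @return a list of class `lcm_receptor`.
#' @export
lcm_receptor <- function(name, tau_0, tau_r, tau_f, lambda_adapt, V_rev,
                         provenance = "fixture-assumed") {
  r <- list(name = name, tau_0 = as.numeric(tau_0), tau_r = as.numeric(tau_r),
            tau_f = as.numeric(tau_f), lambda_adapt = as.numeric(lambda_adapt),
            V_rev = as.numeric(V_rev), provenance = provenance)
  class(r) <- "lcm_receptor"
  r
}

#' One row of the synaptic connection map
#'
#' `N_qp` is the mean number of synapses a postsynaptic neuron of
#' `post_group` receives from presynaptic neurons of `pre_group`, summed over
#' all columns; [build_connectivity()] distributes it over columns with a
#' Gaussian spatial kernel. `receptor_mix` gives the fraction of those
#' synapses expressed through each receptor (must sum to 1).
#'
#' @param pre_group,post_group group labels.
#' @param N_qp mean synapse count per postsynaptic neuron (>= 0).
#' @param receptor_mix named numeric vector of receptor fractions.
#' @param sigma_synp spatial spread (sd) of presynaptic neuron positions, um;
#'   defaults at config assembly to 80 um for pyramidal presynaptic groups
#'   and 40 um otherwise.
#' @param s_dend synapse-to-soma dendritic distance, um.
#' @param provenance see [lcm_group()].
#' @return one-row `data.frame` with columns `pre_group`, `post_group`,
#'   `N_qp`, `frac_<receptor>`..., `sigma_synp`, `s_dend`, `provenance`.
#' @export
lcm_synapse_rule <- function(pre_group, post_group, N_qp, receptor_mix,
                             sigma_synp = NA_real_, s_dend = 50,
                             provenance = "fixture-assumed") {
  stopifnot(length(receptor_mix) >= 1, !is.null(names(receptor_mix)))
  out <- data.frame(pre_group = pre_group, post_group = post_group,
                    N_qp = as.numeric(N_qp), stringsAsFactors = FALSE)
  for (rc in names(receptor_mix))
    out[[paste0("frac_", rc)]] <- as.numeric(receptor_mix[[rc]])
  out$sigma_synp <- as.numeric(sigma_synp)
  out$s_dend <- as.numeric(s_dend)
  out$provenance <- provenance
  out
}

#' Stack synapse rules into a connection map
#'
#' `rbind()` for [lcm_synapse_rule()] rows whose receptor mixes name
#' different receptor subsets: missing `frac_<receptor>` columns are filled
#' with 0.
#'
#' @param ... one-row rule data.frames (or already-stacked maps).
#' @return a single connection-map `data.frame`.
#' @export
bind_rules <- function(...) {
  pieces <- list(...)
  frac_cols <- unique(unlist(lapply(pieces, function(p)
    grep("^frac_", names(p), value = TRUE))))
  pieces <- lapply(pieces, function(p) {
    for (fc in setdiff(frac_cols, names(p))) p[[fc]] <- 0
    p[, c("pre_group", "post_group", "N_qp", sort(frac_cols),
          "sigma_synp", "s_dend", "provenance")]
  })
  do.call(rbind, pieces)
}

#' Sheet geometry and global physical constants
#'
#' @param n_x,n_y number of columns along each axis of the sheet.
#' @param column_size column width, um (56 in the reference configuration).
#' @param layer_depths named numeric vector, mid-depth of each lamina in um
#'   (key `"TH"` for the thalamic sheet).
#' @param thalamus_distance effective cortex-thalamus axonal path length, um
#'   (sets the thalamocortical conduction delay).
#' @param v_AP action-potential propagation speed, m/sec.
#' @param lambda_PSP dendritic PSP decay length, um.
#' @param dt integration step, ms. The step is a model constant (0.5 ms);
#'   synaptic drive is injected per step, so `dt` is not a free
#'   discretization parameter.
#' @return a list of class `lcm_geometry`.
#' @export
lcm_geometry <- function(n_x, n_y, column_size = 56,
                         layer_depths = c("I" = 100, "II/III" = 450,
                                          "IV" = 900, "V" = 1300,
                                          "VI" = 1700, "TH" = 0),
                         thalamus_distance = 10000, v_AP = 1.0,
                         lambda_PSP = 300, dt = 0.5) {
  layer_depths <- stats::setNames(as.numeric(layer_depths),
                                  names(layer_depths))
  g <- list(n_x = as.integer(n_x), n_y = as.integer(n_y),
            column_size = as.numeric(column_size),
            layer_depths = layer_depths,
            thalamus_distance = as.numeric(thalamus_distance),
            v_AP = as.numeric(v_AP), lambda_PSP = as.numeric(lambda_PSP),
            dt = as.numeric(dt))
  class(g) <- "lcm_geometry"
  g
}

#' Synaptic gains
#'
#' @param g_E excitatory gain, uV/(mV*Hz); scales AMPA and NMDA PSPs.
#' @param g_I inhibitory gain, uV/(mV*Hz); scales GABA PSPs.
#' @return a list of class `lcm_gains`.
#' @export
lcm_gains <- function(g_E, g_I) {
  g <- list(g_E = as.numeric(g_E), g_I = as.numeric(g_I))
  class(g) <- "lcm_gains"
  g
}

#' Stimulus specification
#'
#' Band-limited Gaussian noise spike-rate input (see [generate_noise()]).
#' Cortico-cortical background is independent per column (asynchronous);
#' thalamic/sensory input is one shared series for all columns (synchronous).
#'
#' @param target `"cortical"` (routed to the `CC` source group) or
#'   `"thalamic"` (routed to the `SI` source group).
#' @param mean_rate target mean rate, AP/sec.
#' @param cutoff low-pass cutoff, Hz (must be below the Nyquist rate of the
#'   simulation step).
#' @param synchronous logical; one shared series vs independent per column.
#' @param active logical; inactive stimuli produce all-zero series.
#' @param sd_frac sd of the filtered noise before clipping, as a fraction of
#'   `mean_rate`.
#' @return a list of class `lcm_stimulus`.
#' @export
lcm_stimulus <- function(target, mean_rate, cutoff, synchronous = FALSE,
                         active = TRUE, sd_frac = 0.5) {
  s <- list(target = target, mean_rate = as.numeric(mean_rate),
            cutoff = as.numeric(cutoff), synchronous = isTRUE(synchronous),
            active = isTRUE(active), sd_frac = as.numeric(sd_frac))
  class(s) <- "lcm_stimulus"
  s
}

#' Assemble a full model configuration
#'
#' @param geometry an [lcm_geometry()].
#' @param groups list of [lcm_group()] objects.
#' @param receptors list of [lcm_receptor()] objects.
#' @param connection_map `data.frame` of stacked [lcm_synapse_rule()] rows.
#' @param gains an [lcm_gains()].
#' @param stimuli named list of [lcm_stimulus()] objects; by convention the
#'   names `cortical`, `thalamic` (non-stimulated condition) and
#'   `thalamic_stimulated` (stimulated condition) are used by the protocols.
#' @param run list with `warmup` (sec, discarded), `record` (sec, analysed)
#'   and `seed`.
#' @param validate run [validate_config()] before returning.
#' @return a list of class `lcm_config`.
#' @export
lcm_config <- function(geometry, groups, receptors, connection_map, gains,
                       stimuli = list(), run = list(warmup = 10,
                                                    record = 5.12, seed = 1),
                       validate = TRUE) {
  names(groups) <- vapply(groups, `[[`, "", "name")
  names(receptors) <- vapply(receptors, `[[`, "", "name")
  # default spatial spread: 80 um for pyramidal presynaptic groups, 40 um
  # for spiny stellate / inhibitory / source groups
  if (nrow(connection_map) > 0 && anyNA(connection_map$sigma_synp)) {
    idx <- is.na(connection_map$sigma_synp)
    pyr <- vapply(connection_map$pre_group[idx], function(p) {
      !is.null(groups[[p]]) && isTRUE(groups[[p]]$pyramidal)
    }, logical(1))
    connection_map$sigma_synp[idx] <- ifelse(pyr, 80, 40)
  }
  cfg <- list(geometry = geometry, groups = groups, receptors = receptors,
              connection_map = connection_map, gains = gains,
              stimuli = stimuli,
              run = list(warmup = as.numeric(run$warmup %||% 10),
                         record = as.numeric(run$record %||% 5.12),
                         seed = as.integer(run$seed %||% 1)))
  class(cfg) <- "lcm_config"
  if (validate) validate_config(cfg)
  cfg
}

#' Validate a model configuration
#'
#' Checks required fields, positivity/range invariants and cross-references
#' (every connection-map row must name defined groups; every nonzero receptor
#' fraction must name a defined receptor; receptor fractions must sum to 1).
#' Errors name the offending field.
#'
#' @param config an `lcm_config`.
#' @return `config`, invisibly, on success.
#' @export
validate_config <- function(config) {
  geo <- config$geometry
  for (f in c("n_x", "n_y", "column_size", "thalamus_distance", "v_AP",
              "lambda_PSP", "dt"))
    if (is.null(geo[[f]]) || is.na(geo[[f]]))
      stop_fmt("geometry: missing required field '%s'", f)
  if (geo$n_x < 1 || geo$n_y < 1) stop_fmt("geometry: n_x, n_y must be >= 1")
  if (geo$dt <= 0) stop_fmt("geometry: dt must be > 0")
  if (geo$v_AP <= 0) stop_fmt("geometry: v_AP must be > 0")
  if (geo$lambda_PSP <= 0) stop_fmt("geometry: lambda_PSP must be > 0")

  for (g in config$groups) {
    for (f in c("name", "layer", "polarity"))
      if (is.null(g[[f]]) || is.na(g[[f]]))
        stop_fmt("group '%s': missing required field '%s'",
                 g$name %||% "?", f)
    if (!g$polarity %in% c("excitatory", "inhibitory"))
      stop_fmt("group '%s': polarity must be excitatory|inhibitory", g$name)
    if (!isTRUE(g$is_source)) {
      for (f in c("F_max", "k", "V_HMF", "V_rest", "tau_m"))
        if (is.null(g[[f]]) || is.na(g[[f]]))
          stop_fmt("group '%s': missing required field '%s'", g$name, f)
      if (g$F_max <= 0) stop_fmt("group '%s': F_max must be > 0", g$name)
      if (g$k <= 0) stop_fmt("group '%s': k must be > 0", g$name)
      if (g$tau_m <= 0) stop_fmt("group '%s': tau_m must be > 0", g$name)
    }
    if (!g$layer %in% names(geo$layer_depths))
      stop_fmt("group '%s': layer '%s' has no entry in layer_depths",
               g$name, g$layer)
  }

  for (r in config$receptors) {
    for (f in c("tau_0", "tau_r", "tau_f", "lambda_adapt", "V_rev"))
      if (is.null(r[[f]]) || is.na(r[[f]]))
        stop_fmt("receptor '%s': missing required field '%s'", r$name, f)
    if (r$tau_r <= 0 || r$tau_f <= 0)
      stop_fmt("receptor '%s': tau_r and tau_f must be > 0", r$name)
    if (r$tau_0 < 0) stop_fmt("receptor '%s': tau_0 must be >= 0", r$name)
  }

  cm <- config$connection_map
  frac_cols <- grep("^frac_", names(cm), value = TRUE)
  for (fc in frac_cols) {
    rc <- sub("^frac_", "", fc)
    if (any(cm[[fc]] > 0, na.rm = TRUE) && is.null(config$receptors[[rc]]))
      stop_fmt("connection map: unknown receptor '%s'", rc)
  }
  if (nrow(cm) > 0) {
    fr <- as.matrix(cm[frac_cols])
    fr[is.na(fr)] <- 0
    if (any(fr < 0 | fr > 1))
      stop_fmt("connection map: receptor fractions must lie in [0, 1]")
    bad <- abs(rowSums(fr) - 1) > 1e-8
    if (any(bad))
      stop_fmt("connection map row %d (%s -> %s): receptor fractions sum to %g, not 1",
               which(bad)[1], cm$pre_group[which(bad)[1]],
               cm$post_group[which(bad)[1]], rowSums(fr)[which(bad)[1]])
    for (i in seq_len(nrow(cm))) {
      if (is.null(config$groups[[cm$pre_group[i]]]))
        stop_fmt("connection map row %d: unknown pre_group '%s'",
                 i, cm$pre_group[i])
      if (is.null(config$groups[[cm$post_group[i]]]))
        stop_fmt("connection map row %d: unknown post_group '%s'",
                 i, cm$post_group[i])
    }
    if (any(cm$N_qp < 0)) stop_fmt("connection map: N_qp must be >= 0")
    if (any(cm$sigma_synp <= 0)) stop_fmt("connection map: sigma_synp must be > 0")
    if (any(cm$s_dend < 0)) stop_fmt("connection map: s_dend must be >= 0")
  }

  if (is.null(config$gains$g_E) || is.null(config$gains$g_I) ||
      config$gains$g_E < 0 || config$gains$g_I < 0)
    stop_fmt("gains: g_E and g_I must be present and >= 0")

  nyq <- 1000 / (2 * geo$dt)
  for (nm in names(config$stimuli)) {
    s <- config$stimuli[[nm]]
    if (!s$target %in% c("cortical", "thalamic"))
      stop_fmt("stimulus '%s': target must be cortical|thalamic", nm)
    if (s$mean_rate < 0) stop_fmt("stimulus '%s': mean_rate must be >= 0", nm)
    if (s$cutoff >= nyq)
      stop_fmt("stimulus '%s': cutoff %g Hz is not below Nyquist (%g Hz)",
               nm, s$cutoff, nyq)
    src <- source_group_for(s$target)
    if (is.null(config$groups[[src]]))
      stop_fmt("stimulus '%s': source group '%s' is not defined", nm, src)
  }

  if (is.null(config$run$warmup) || is.null(config$run$record) ||
      config$run$record <= 0 || config$run$warmup < 0)
    stop_fmt("run: warmup must be >= 0 and record > 0")
  invisible(config)
}

# conventional source-group labels
source_group_for <- function(target) {
  switch(target, cortical = "CC", thalamic = "SI",
         stop_fmt("unknown stimulus target '%s'", target))
}

#' @export
print.lcm_config <- function(x, ...) {
  dyn <- Filter(function(g) !g$is_source, x$groups)
  cat(sprintf("<lcm_config> %d x %d columns, %d neuron groups (+%d sources), %d connection rules\n",
              x$geometry$n_x, x$geometry$n_y, length(dyn),
              length(x$groups) - length(dyn), nrow(x$connection_map)))
  cat(sprintf("  gains: g_E = %g, g_I = %g uV/(mV*Hz); dt = %g ms\n",
              x$gains$g_E, x$gains$g_I, x$geometry$dt))
  cat(sprintf("  run: %g s warmup + %g s record, seed %s\n",
              x$run$warmup, x$run$record, format(x$run$seed)))
  invisible(x)
}

#' Write a configuration to a JSON file
#'
#' The on-disk format is plain JSON with full-precision decimal numbers, so
#' that [load_config()] round-trips every numeric field exactly.
#'
#' @param config an `lcm_config`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  obj <- list(
    geometry = unclass(config$geometry),
    groups = lapply(config$groups, function(g)
      Filter(function(x) !(length(x) == 1 && is.na(x)), unclass(g))),
    receptors = lapply(config$receptors, unclass),
    connection_map = config$connection_map,
    gains = unclass(config$gains),
    stimuli = lapply(config$stimuli, unclass),
    run = config$run
  )
  obj$geometry$layer_depths <- as.list(obj$geometry$layer_depths)
  writeLines(jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE,
                              na = "null", dataframe = "columns",
                              pretty = TRUE), path)
  invisible(path)
}

#' Load and validate a configuration from a JSON file
#'
#' @param path file written by [write_config()] (or hand-authored to the same
#'   schema).
#' @return a validated `lcm_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_fmt("config file not found: %s", path)
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = TRUE)
  geo <- obj$geometry
  geometry <- lcm_geometry(geo$n_x, geo$n_y, geo$column_size,
                           unlist(geo$layer_depths), geo$thalamus_distance,
                           geo$v_AP, geo$lambda_PSP, geo$dt)
  groups <- lapply(obj$groups, function(g)
    lcm_group(g$name, g$layer, g$polarity, g$F_max %||% NA, g$k %||% NA,
              g$V_HMF %||% NA, g$V_rest %||% -65, g$tau_m %||% NA,
              g$density %||% 1, g$pyramidal %||% FALSE,
              g$is_source %||% FALSE, g$provenance %||% "fixture-assumed"))
  receptors <- lapply(obj$receptors, function(r)
    lcm_receptor(r$name, r$tau_0 %||% NA, r$tau_r %||% NA, r$tau_f %||% NA,
                 r$lambda_adapt %||% NA, r$V_rev %||% NA,
                 r$provenance %||% "fixture-assumed"))
  cm <- as.data.frame(obj$connection_map, stringsAsFactors = FALSE)
  for (col in setdiff(names(cm), c("pre_group", "post_group", "provenance")))
    cm[[col]] <- as.numeric(cm[[col]])
  stimuli <- lapply(obj$stimuli, function(s)
    lcm_stimulus(s$target, s$mean_rate, s$cutoff, s$synchronous %||% FALSE,
                 s$active %||% TRUE, s$sd_frac %||% 0.5))
  lcm_config(geometry, groups, receptors, cm, lcm_gains(obj$gains$g_E,
                                                        obj$gains$g_I),
             stimuli, run = obj$run)
}
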