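#' Sigmoid firing-rate function
#'
#' Mean spike rate of a neuron group at membrane potential `V`:
#' `F_max / (1 + exp(-k (V - V_HMF)))`. Strictly increasing in `V`, bounded
#' in `(0, F_max)`, with `F(V_HMF) = F_max / 2`.
#'
#' @param V absolute membrane potential, mV (vectorised).
#' @param group an [lcm_group()] (or any list with `F_max`, `k`, `V_HMF`).
#' @return firing rate, AP/sec.
#' @export
firing_rate <- function(V, group) {
  group$F_max / (1 + exp(-group$k * (V - group$V_HMF)))
}

#' PSP amplitude at the synapse
#'
#' Amplitude of the postsynaptic potential generated by an afferent spike
#' rate `phi_p` through `N_qp` synapses of one receptor:
#' `-gain * N_qp * (V_q - V_rev) * phi_p * exp(-lambda * phi_p)`.
#' Depolarizing for excitatory receptors while `V_q < V_rev = 0` and
#' hyperpolarizing for GABA while `V_q > V_rev = -70` mV; zero at the
#' reversal potential or at zero afferent rate; the adaptation factor makes
#' the drive maximal at `phi_p = 1/lambda`.
#'
#' @param V_q postsynaptic membrane potential, mV.
#' @param phi_p afferent spike rate, AP/sec (>= 0).
#' @param gain synaptic gain, uV/(mV*Hz).
#' @param N_qp synapse count.
#' @param rcpt an [lcm_receptor()] (uses `V_rev` and `lambda_adapt`).
#' @return PSP amplitude, uV.
#' @export
psp_amplitude <- function(V_q, phi_p, gain, N_qp, rcpt) {
  if (any(phi_p < 0)) stop_fmt("phi_p must be >= 0")
  -gain * N_qp * (V_q - rcpt$V_rev) * phi_p * exp(-rcpt$lambda_adapt * phi_p)
}

# ---------------------------------------------------------------------------
# engine internals

# Precompute everything the per-step loop needs. Units are (group, column)
# pairs indexed (g-1)*n_col + c, in config group order.
compile_engine <- function(config, conn) {
  geo <- config$geometry
  n_col <- geo$n_x * geo$n_y
  gnames <- names(config$groups)
  n_grp <- length(gnames)
  n_units <- n_grp * n_col
  gidx <- stats::setNames(seq_len(n_grp), gnames)

  is_src <- vapply(config$groups, function(g) isTRUE(g$is_source), TRUE)
  inh <- vapply(config$groups, function(g)
    g$polarity == "inhibitory" && !isTRUE(g$is_source), TRUE)

  per_unit <- function(field, default = 0) {
    v <- vapply(config$groups, function(g) {
      x <- g[[field]]
      if (is.null(x) || is.na(x)) default else as.numeric(x)
    }, 0)
    rep(v, each = n_col)
  }
  dt <- geo$dt
  tau <- per_unit("tau_m", default = Inf)
  eng <- list(
    n_col = n_col, n_grp = n_grp, n_units = n_units, dt = dt,
    gnames = gnames, is_src = is_src,
    src_groups = gnames[is_src],
    dyn_units = which(rep(!is_src, each = n_col)),
    inh_units = which(rep(inh, each = n_col)),
    Fmax = per_unit("F_max"), k = per_unit("k"),
    VHMF = per_unit("V_HMF"), Vrest = per_unit("V_rest", -65),
    decay = exp(-dt / tau),
    # exact integration of the membrane ODE over one step: the aggregate
    # PSP enters as a constant current C^-1 I_E over the interval, so its
    # per-step contribution is dV * tau/dt * (1 - exp(-dt/tau))
    beta = ifelse(is.finite(tau), tau / dt * (1 - exp(-dt / tau)), 1)
  )
  eng$src_units <- lapply(eng$src_groups,
                          function(g) (gidx[[g]] - 1L) * n_col + seq_len(n_col))

  # receptor filters and per-(receptor, lag) weight matrices
  rnames <- names(config$receptors)
  eng$receptors <- rnames
  eng$iir <- lapply(config$receptors, kernel_iir, dt = dt)
  eng$lambda <- vapply(config$receptors, `[[`, 0, "lambda_adapt")
  eng$Vrev <- vapply(config$receptors, `[[`, 0, "V_rev")
  eng$gclass <- ifelse(rnames == "GABA", "I", "E") # gain routing
  names(eng$gclass) <- rnames

  tab <- conn$table
  pre_u <- (gidx[tab$pre_group] - 1L) * n_col + tab$pre_col
  post_u <- (gidx[tab$post_group] - 1L) * n_col + tab$post_col
  w <- tab$weight * tab$attenuation
  eng$W <- list(); eng$lags <- list()
  max_lag <- 0L
  for (r in rnames) {
    sel <- tab$receptor == r
    if (!any(sel)) { eng$W[[r]] <- list(); eng$lags[[r]] <- integer(); next }
    lag <- tab$delay_steps[sel] + eng$iir[[r]]$n0
    ul <- sort(unique(lag))
    eng$W[[r]] <- lapply(ul, function(d) {
      i <- sel & (tab$delay_steps + eng$iir[[r]]$n0) == d
      Matrix::sparseMatrix(i = post_u[i], j = pre_u[i], x = w[i],
                           dims = c(n_units, n_units))
    })
    eng$lags[[r]] <- as.integer(ul)
    max_lag <- max(max_lag, max(ul))
  }
  eng$depth <- max_lag + 1L
  eng
}

# assemble the (steps x source-unit) input matrix in engine unit order
stack_inputs <- function(eng, inputs, n_steps) {
  if (length(eng$src_groups) == 0) return(NULL)
  mats <- lapply(eng$src_groups, function(g) {
    m <- inputs[[g]]
    if (is.null(m))
      stop_fmt("no input series provided for source group '%s'", g)
    if (nrow(m) < n_steps)
      stop_fmt("input series for '%s' covers %d steps, need %d",
               g, nrow(m), n_steps)
    m[seq_len(n_steps), , drop = FALSE]
  })
  do.call(cbind, mats)
}

# protocol schedule -> per-step events; times are seconds relative to the
# start of the recording window (negative values reach into the warmup)
protocol_events <- function(protocol, warmup_steps, n_total, dt) {
  if (is.null(protocol) || nrow(protocol) == 0) return(NULL)
  needed <- c("start", "end", "param", "value", "mode")
  if (!all(needed %in% names(protocol)))
    stop_fmt("protocol schedule needs columns: %s",
             paste(needed, collapse = ", "))
  ev <- list()
  for (i in seq_len(nrow(protocol))) {
    s <- warmup_steps + as.integer(round(protocol$start[i] * 1000 / dt)) + 1L
    e <- warmup_steps + as.integer(round(protocol$end[i] * 1000 / dt)) + 1L
    if (s < 1 || e > n_total + 1 || e < s)
      stop_fmt("protocol window [%g, %g] s lies outside the simulated interval",
               protocol$start[i], protocol$end[i])
    ev[[length(ev) + 1L]] <- list(step = s, param = protocol$param[i],
                                  value = protocol$value[i],
                                  mode = protocol$mode[i], off = FALSE)
    ev[[length(ev) + 1L]] <- list(step = e, param = protocol$param[i],
                                  value = NA_real_, mode = "restore",
                                  off = TRUE)
  }
  ev
}

#' One protocol window
#'
#' Convenience constructor for rows of a perturbation schedule. Addressable
#' parameters: `"g_E"`, `"g_I"` (synaptic gains), `"V_rev_GABA"` (inhibitory
#' reversal potential), `"F_max_inh"` and `"V_HMF_inh"` (maximum firing rate
#' / half-maximum-firing voltage of every inhibitory neuron group). Times
#' are seconds relative to the start of the recording window; the parameter
#' is restored to its baseline at `end`.
#'
#' @param param parameter name (above).
#' @param start,end window, sec.
#' @param value delta added to the baseline (`mode = "delta"`) or absolute
#'   replacement (`mode = "absolute"`).
#' @param mode `"delta"` or `"absolute"`.
#' @return one-row `data.frame`; `rbind()` windows into a schedule.
#' @export
protocol_window <- function(param, start, end, value,
                            mode = c("delta", "absolute")) {
  mode <- match.arg(mode)
  stopifnot(param %in% c("g_E", "g_I", "V_rev_GABA", "F_max_inh",
                         "V_HMF_inh"))
  data.frame(start = start, end = end, param = param, value = value,
             mode = mode, stringsAsFactors = FALSE)
}

#' Run the simulation engine
#'
#' Advances the network from rest through `warmup + record` seconds in
#' `dt` steps. Each step: (i) every group emits its sigmoid rate into the
#' delay history (sources emit their stimulus series); (ii) delayed,
#' adaptation-weighted afferent rates are aggregated through the per-link
#' weights and the receptor kernels; (iii) the aggregate PSP
#' `-g (V_q - V_rev)` x drive is summed over receptors; (iv) the membrane
#' relaxes one step of the leaky ODE with the aggregate PSP as a constant
#' current over the interval:
#' `u <- u exp(-dt/tau_m) + dV * (tau_m/dt) (1 - exp(-dt/tau_m))` (the
#' exact exponential-integrator form of the iteration equation; the
#' correction factor is 0.975 at tau_m = 10 ms). Membrane potentials
#' start at rest and
#' history buffers are pre-filled with the resting rates, so a zero-gain
#' network is exactly stationary. The warmup is discarded; the recording
#' window is returned.
#'
#' @param config an [lcm_config()].
#' @param conn an [build_connectivity()] table; built from `seed` when `NULL`.
#' @param inputs named list of source-series matrices (as from
#'   [realize_inputs()]); realized from `seed` when `NULL`.
#' @param protocol perturbation schedule (rows from [protocol_window()]),
#'   or `NULL`.
#' @param seed master seed; identical seeds give bit-identical records.
#' @param warmup,record durations, sec (defaults from `config$run`).
#' @param condition input condition passed to [realize_inputs()].
#' @param u0 optional initial relative membrane potential, mV: a single
#'   number for every dynamic unit or a named vector per group (default 0,
#'   i.e. all groups start at rest).
#' @param record_potentials also keep the relative membrane potentials `u`.
#' @param check_every steps between finite-ness checks of `u`.
#' @return an object of class `lcm_record`: list with `rates` (matrix,
#'   recorded steps x dynamic units, AP/sec), `units` (data.frame mapping
#'   columns of `rates` to group and column), `dt` (ms), and `meta`
#'   (seed, hashes, protocol, condition). With `record_potentials`, also
#'   `u` (same shape as `rates`, mV relative to rest).
#' @export
run_simulation <- function(config, conn = NULL, inputs = NULL,
                           protocol = NULL, seed = config$run$seed %||% 1,
                           warmup = config$run$warmup,
                           record = config$run$record,
                           condition = c("non_stimulated", "stimulated"),
                           u0 = NULL, record_potentials = FALSE,
                           check_every = 256L) {
  condition <- match.arg(condition)
  if (is.null(conn)) conn <- build_connectivity(config, seed)
  eng <- compile_engine(config, conn)
  dt <- eng$dt
  n_warm <- as.integer(round(warmup * 1000 / dt))
  n_rec <- as.integer(round(record * 1000 / dt))
  n_total <- n_warm + n_rec
  if (is.null(inputs))
    inputs <- realize_inputs(config, warmup + record, seed, condition)
  S <- stack_inputs(eng, inputs, n_total)
  src_all <- unlist(eng$src_units)

  # runtime parameter state (protocols may override between steps)
  par <- new.env(parent = emptyenv())
  par$gE <- config$gains$g_E; par$gI <- config$gains$g_I
  par$Vrev <- eng$Vrev
  par$Fmax <- eng$Fmax; par$VHMF <- eng$VHMF
  base <- list(gE = par$gE, gI = par$gI, Vrev = eng$Vrev,
               Fmax = eng$Fmax, VHMF = eng$VHMF)
  apply_event <- function(ev) {
    if (ev$mode == "restore") {
      par$gE <- base$gE; par$gI <- base$gI; par$Vrev <- base$Vrev
      par$Fmax <- base$Fmax; par$VHMF <- base$VHMF
      return(invisible())
    }
    set_val <- function(cur, b, v) if (ev$mode == "delta") b + v else v
    if (ev$param == "g_E") par$gE <- set_val(par$gE, base$gE, ev$value)
    else if (ev$param == "g_I") par$gI <- set_val(par$gI, base$gI, ev$value)
    else if (ev$param == "V_rev_GABA")
      par$Vrev["GABA"] <- set_val(par$Vrev["GABA"], base$Vrev["GABA"],
                                  ev$value)
    else if (ev$param == "F_max_inh")
      par$Fmax[eng$inh_units] <- set_val(NULL, base$Fmax[eng$inh_units],
                                         ev$value)
    else if (ev$param == "V_HMF_inh")
      par$VHMF[eng$inh_units] <- set_val(NULL, base$VHMF[eng$inh_units],
                                         ev$value)
    else stop_fmt("unknown protocol parameter '%s'", ev$param)
  }
  events <- protocol_events(protocol, n_warm, n_total, dt)
  ev_steps <- if (is.null(events)) integer() else
    vapply(events, `[[`, 0L, "step")

  # state
  D <- eng$depth
  u <- numeric(eng$n_units)
  if (!is.null(u0)) {
    if (length(u0) == 1 && is.null(names(u0))) {
      u[eng$dyn_units] <- u0
    } else {
      for (g in names(u0)) {
        gi <- match(g, eng$gnames)
        if (is.na(gi)) stop_fmt("u0 names unknown group '%s'", g)
        u[(gi - 1L) * eng$n_col + seq_len(eng$n_col)] <- u0[[g]]
      }
    }
  }
  r0 <- eng$Fmax / (1 + exp(-eng$k * (eng$Vrest - eng$VHMF)))
  if (length(src_all)) r0[src_all] <- colMeans(S)
  B <- P <- Q <- list()
  for (r in eng$receptors) {
    f0 <- r0 * exp(-eng$lambda[[r]] * r0)
    B[[r]] <- matrix(f0, eng$n_units, D)
    x0 <- numeric(eng$n_units)
    for (j in seq_along(eng$lags[[r]]))
      x0 <- x0 + as.vector(eng$W[[r]][[j]] %*% f0)
    P[[r]] <- x0 / (1 - eng$iir[[r]]$a_f)
    Q[[r]] <- x0 / (1 - eng$iir[[r]]$a_b)
  }

  rates_out <- matrix(NA_real_, n_rec, length(eng$dyn_units))
  u_out <- if (record_potentials) matrix(NA_real_, n_rec,
                                         length(eng$dyn_units)) else NULL
  ptr <- 0L
  gvec <- function() ifelse(eng$gclass == "I", par$gI, par$gE) * 1e-3

  for (t in seq_len(n_total)) {
    if (length(ev_steps) && any(ev_steps == t))
      for (ev in events[ev_steps == t]) apply_event(ev)
    ptr <- if (ptr == D) 1L else ptr + 1L
    V <- eng$Vrest + u
    Ft <- par$Fmax / (1 + exp(-eng$k * (V - par$VHMF)))
    if (length(src_all)) Ft[src_all] <- S[t, ]
    g <- gvec()
    dV <- numeric(eng$n_units)
    for (r in eng$receptors) {
      B[[r]][, ptr] <- Ft * exp(-eng$lambda[[r]] * Ft)
      lags <- eng$lags[[r]]
      if (length(lags) == 0) next
      x <- numeric(eng$n_units)
      for (j in seq_along(lags)) {
        col <- ptr - lags[j]
        if (col < 1L) col <- col + D
        x <- x + as.vector(eng$W[[r]][[j]] %*% B[[r]][, col])
      }
      io <- eng$iir[[r]]
      P[[r]] <- io$a_f * P[[r]] + x
      Q[[r]] <- io$a_b * Q[[r]] + x
      drive <- io$norm * (P[[r]] - Q[[r]]) * dt
      dV <- dV - g[[r]] * (V - par$Vrev[[r]]) * drive
    }
    u <- u * eng$decay + dV * eng$beta
    if (t %% check_every == 0L && any(!is.finite(u[eng$dyn_units]))) {
      bad <- eng$dyn_units[!is.finite(u[eng$dyn_units])][1]
      stop_fmt("simulation aborted at step %d: non-finite potential in group '%s', column %d",
               t, eng$gnames[(bad - 1L) %/% eng$n_col + 1L],
               (bad - 1L) %% eng$n_col + 1L)
    }
    if (t > n_warm) {
      rates_out[t - n_warm, ] <- Ft[eng$dyn_units]
      if (record_potentials) u_out[t - n_warm, ] <- u[eng$dyn_units]
    }
  }

  units <- data.frame(
    group = eng$gnames[(eng$dyn_units - 1L) %/% eng$n_col + 1L],
    col = (eng$dyn_units - 1L) %% eng$n_col + 1L,
    stringsAsFactors = FALSE)
  structure(list(rates = rates_out, u = u_out, units = units, dt = dt,
                 meta = list(seed = seed, warmup = warmup, record = record,
                             condition = condition,
                             config_hash = config_hash(config),
                             protocol = protocol)),
            class = "lcm_record")
}

#' @export
print.lcm_record <- function(x, ...) {
  cat(sprintf("<lcm_record> %d steps x %d units (%.3g s at %g ms), seed %s\n",
              nrow(x$rates), ncol(x$rates), nrow(x$rates) * x$dt / 1000,
              x$dt, format(x$meta$seed)))
  invisible(x)
}

#' @export
summary.lcm_record <- function(object, ...) {
  by_grp <- tapply(colMeans(object$rates), object$units$group, mean)
  cat("<lcm_record> mean rate by group (AP/sec):\n")
  print(round(by_grp, 3))
  invisible(by_grp)
}

#' Save / load a rate record
#'
#' Binary container (RDS) plus a JSON metadata sidecar; [export_record_csv()]
#' writes the long-format audit CSV (time, column, group, rate).
#'
#' @param record an `lcm_record`.
#' @param path output path (`.rds`).
#' @return `path` (save) or an `lcm_record` (load).
#' @export
save_record <- function(record, path) {
  saveRDS(record, path)
  writeLines(jsonlite::toJSON(record$meta, auto_unbox = TRUE, digits = NA,
                              null = "null"),
             paste0(path, ".meta.json"))
  invisible(path)
}

#' @rdname save_record
#' @export
load_record <- function(path) readRDS(path)

#' @rdname save_record
#' @param csv_path output CSV path.
#' @export
export_record_csv <- function(record, csv_path) {
  n <- nrow(record$rates)
  long <- data.frame(
    time = rep((seq_len(n) - 1) * record$dt / 1000, ncol(record$rates)),
    column = rep(record$units$col, each = n),
    group = rep(record$units$group, each = n),
    rate = as.vector(record$rates))
  utils::write.csv(long, csv_path, row.names = FALSE)
  invisible(csv_path)
}

#' @export
plot.lcm_record <- function(x, config = NULL, ...) {
  tt <- (seq_len(nrow(x$rates)) - 1) * x$dt / 1000
  if (!is.null(config)) {
    y <- column_excitation(x, config)[, centre_col(config$geometry)]
    ylab <- "central-column excitatory rate (AP/sec)"
  } else {
    y <- rowMeans(x$rates)
    ylab <- "mean rate (AP/sec)"
  }
  graphics::plot(tt, y, type = "l", xlab = "time (s)", ylab = ylab, ...)
  invisible(x)
}
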