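# Independent reference implementations used as oracles. These are written
# directly from the model equations with none of the engine's machinery
# (no ring buffers, no recursive kernel filters): brute-force FIR
# convolution at a finer time step, and a damped fixed-point solver for
# steady states. Deliberately slow and simple.

# Integrate the delayed membrane/rate equations at dt/refine, treating the
# engine's per-step PSP injection as a continuous drive of ΔV/dt. Only
# supports single-column configs (the tiny fixture and variants).
fine_step_reference <- function(config, conn, cc_rate, duration_ms,
                                refine = 10) {
  geo <- config$geometry
  stopifnot(geo$n_x == 1, geo$n_y == 1)
  dt <- geo$dt
  dtf <- dt / refine
  groups <- config$groups
  gnames <- names(groups)
  dyn <- gnames[!vapply(groups, function(g) isTRUE(g$is_source), TRUE)]
  n_fine <- as.integer(round(duration_ms / dtf))

  # receptor kernels sampled on the fine grid, truncated where the
  # continuous tail is negligible, numerically normalised
  kern <- list()
  for (r in names(config$receptors)) {
    rc <- config$receptors[[r]]
    horizon <- rc$tau_0 + 12 * rc$tau_f
    tt <- seq(0, horizon, by = dtf)
    s <- tt - rc$tau_0
    kk <- ifelse(s >= 0, exp(-s / rc$tau_f) * (1 - exp(-s / rc$tau_r)), 0)
    kern[[r]] <- kk / (sum(kk) * dtf)
  }
  maxlen <- max(vapply(kern, length, 0L))

  tab <- conn$table
  lead <- maxlen + max(tab$delay_steps) * refine + 1L
  # rate history per group, prefilled with the resting rates
  hist <- matrix(0, lead + n_fine, length(gnames))
  colnames(hist) <- gnames
  for (g in gnames) {
    gr <- groups[[g]]
    hist[, g] <- if (isTRUE(gr$is_source)) cc_rate
                 else firing_rate(gr$V_rest, gr)
  }
  lam <- vapply(config$receptors, `[[`, 0, "lambda_adapt")
  vrev <- vapply(config$receptors, `[[`, 0, "V_rev")
  g_of <- function(r) if (r == "GABA") config$gains$g_I else config$gains$g_E

  u <- stats::setNames(numeric(length(dyn)), dyn)
  u_trace <- matrix(NA_real_, n_fine, length(dyn))
  colnames(u_trace) <- dyn
  decay <- exp(-dtf / vapply(groups[dyn], `[[`, 0, "tau_m"))

  for (n in seq_len(n_fine)) {
    now <- lead + n - 1L   # history rows strictly before the current time
    V <- vapply(dyn, function(g) groups[[g]]$V_rest, 0) + u
    dV <- stats::setNames(numeric(length(dyn)), dyn)
    for (i in seq_len(nrow(tab))) {
      post <- tab$post_group[i]
      if (!post %in% dyn) next
      r <- tab$receptor[i]
      K <- kern[[r]]
      d_fine <- tab$delay_steps[i] * refine
      # afferent rates over the kernel support, most recent first
      idx <- now - d_fine - seq_along(K) + 1L
      phi <- hist[idx, tab$pre_group[i]]
      drive <- sum(K * phi * exp(-lam[[r]] * phi)) * dtf
      dV[post] <- dV[post] -
        g_of(r) * 1e-3 * tab$weight[i] * tab$attenuation[i] *
        (V[post] - vrev[[r]]) * drive
    }
    # engine injects dV once per coarse step; as a continuous-time drive
    # that is dV/dt, integrated here with an exponential-Euler fine step
    u <- u * decay + dV * (dtf / dt)
    for (g in dyn) hist[lead + n, g] <- firing_rate(groups[[g]]$V_rest +
                                                      u[g], groups[[g]])
    u_trace[n, ] <- u
  }
  list(u = u_trace[seq(refine, n_fine, by = refine), , drop = FALSE],
       rates = hist[lead + seq(refine, n_fine, by = refine), dyn,
                    drop = FALSE])
}

# Damped fixed-point solver for the steady state of a single-column config
# under constant source rates: solves u = a * dV(u) with a the steady-state
# amplification of the exponential membrane update.
solve_fixed_point <- function(config, conn, cc_rate, damp = 0.05,
                              iters = 20000, tol = 1e-12) {
  groups <- config$groups
  gnames <- names(groups)
  dyn <- gnames[!vapply(groups, function(g) isTRUE(g$is_source), TRUE)]
  dt <- config$geometry$dt
  tab <- conn$table
  lam <- vapply(config$receptors, `[[`, 0, "lambda_adapt")
  vrev <- vapply(config$receptors, `[[`, 0, "V_rev")
  g_of <- function(r) if (r == "GABA") config$gains$g_I else config$gains$g_E
  # steady-state amplification of the exponential-integrator map:
  # u* = dV * beta / (1 - decay) = dV * tau_m / dt
  a <- stats::setNames(vapply(groups[dyn], `[[`, 0, "tau_m") / dt, dyn)
  rate_of <- function(g, u) {
    gr <- groups[[g]]
    if (isTRUE(gr$is_source)) cc_rate else firing_rate(gr$V_rest + u[g], gr)
  }
  u <- stats::setNames(numeric(length(dyn)), dyn)
  for (it in seq_len(iters)) {
    V <- vapply(dyn, function(g) groups[[g]]$V_rest, 0) + u
    dV <- stats::setNames(numeric(length(dyn)), dyn)
    for (i in seq_len(nrow(tab))) {
      post <- tab$post_group[i]
      if (!post %in% dyn) next
      r <- tab$receptor[i]
      phi <- rate_of(tab$pre_group[i], u)
      dV[post] <- dV[post] -
        g_of(r) * 1e-3 * tab$weight[i] * tab$attenuation[i] *
        (V[post] - vrev[[r]]) * phi * exp(-lam[[r]] * phi)
    }
    un <- (1 - damp) * u + damp * (a * dV)
    if (max(abs(un - u)) < tol) { u <- un; break }
    u <- un
  }
  rates <- vapply(dyn, function(g) rate_of(g, u), 0)
  list(u = u, rates = rates)
}

# a tiny one-column two-group config with randomised physiology and
# weights, stable at its low state (used for the reduction property test)
rand_tiny_config <- function(seed) {
  set.seed(seed)
  cfg <- fixture_config("tiny", seed = seed)
  cfg$groups$E$tau_m <- runif(1, 6, 15)
  cfg$groups$I$tau_m <- runif(1, 6, 15)
  cfg$groups$E$k <- runif(1, 0.4, 0.6)
  cfg$groups$I$k <- runif(1, 0.25, 0.4)
  cm <- cfg$connection_map
  cm$N_qp <- cm$N_qp * runif(nrow(cm), 0.6, 1.2)
  cfg$connection_map <- cm
  cfg$gains <- lcm_gains(runif(1, 0.25, 0.45), runif(1, 1, 3))
  validate_config(cfg)
  cfg
}
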