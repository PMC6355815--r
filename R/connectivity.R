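#' Axonal conduction delay in integer time steps
#'
#' Spike rates propagate unchanged along axons and arrive after
#' `distance / v_AP`, rounded to the nearest integer number of simulation
#' steps.
#'
#' @param distance axon length, um (>= 0).
#' @param v_AP propagation speed, m/sec (> 0).
#' @param dt step, ms (> 0).
#' @return integer step count (>= 0).
#' @export
conduction_delay_steps <- function(distance, v_AP, dt) {
  if (v_AP <= 0) stop_fmt("v_AP must be > 0")
  if (dt <= 0) stop_fmt("dt must be > 0")
  if (any(distance < 0)) stop_fmt("distance must be >= 0")
  as.integer(round(distance / (v_AP * 1000) / dt))
}

#' Dendritic attenuation factor
#'
#' PSP amplitudes decay exponentially while conducted from the synapse to
#' the soma: `exp(-s_dend / lambda_PSP)`.
#'
#' @param s_dend synapse-to-soma distance, um (>= 0).
#' @param lambda_PSP decay length, um (> 0).
#' @return factor in (0, 1].
#' @export
dendritic_attenuation <- function(s_dend, lambda_PSP) {
  if (lambda_PSP <= 0) stop_fmt("lambda_PSP must be > 0")
  if (any(s_dend < 0)) stop_fmt("s_dend must be >= 0")
  exp(-s_dend / lambda_PSP)
}

#' Planar Gaussian density of presynaptic neurons
#'
#' The density of presynaptic neurons at horizontal distance `s_qp` from
#' the target neuron: `X / (2 pi sigma^2) * exp(-s_qp^2 / (2 sigma^2))`.
#' Integrates over the plane to `X`.
#'
#' @param s_qp distance, um.
#' @param sigma_synp spatial sd, um (> 0).
#' @param X multiplicative wiring factor (Gaussian with mean 1, sd 0.2 when
#'   drawn by [build_connectivity()]).
#' @return density, 1/um^2.
#' @export
spatial_kernel <- function(s_qp, sigma_synp, X = 1) {
  if (sigma_synp <= 0) stop_fmt("sigma_synp must be > 0")
  X / (2 * pi * sigma_synp^2) * exp(-s_qp^2 / (2 * sigma_synp^2))
}

#' Expand the connection map into a column-resolved connectivity table
#'
#' For every synapse rule and every postsynaptic column, the rule's `N_qp`
#' synapses are distributed over presynaptic columns proportionally to the
#' Gaussian spatial kernel evaluated at inter-column centre distances,
#' truncated at `trunc_radius * sigma` and renormalised over the included
#' columns (so `N_qp` is conserved exactly on the open-boundary sheet), then
#' scaled by one truncated-Gaussian wiring draw `X` per (rule, post column)
#' and split across receptors by the rule's receptor fractions. Axonal
#' delays use the 3-D distance (horizontal centre offset and laminar depth
#' difference in quadrature; cortex-thalamus links use the configured
#' `thalamus_distance`); dendritic attenuation is
#' `exp(-s_dend / lambda_PSP)`.
#'
#' Rules whose presynaptic group is an external source (`is_source`) connect
#' within-column only, with no spatial spread and no `X` draw: their rates
#' are stimulus realizations, not spatially wired populations.
#'
#' @param config an [lcm_config()].
#' @param seed integer; drives the `X` draws (one per rule x post column,
#'   in fixed order, so rebuilding is bit-identical).
#' @param x_sd sd of the wiring factor `X` (mean 1); `0` fixes `X = 1`.
#' @param x_min lower truncation of `X` draws (guards against non-physical
#'   negative synapse counts; affects < 1e-4 of draws at `x_sd = 0.2`).
#' @param trunc_radius spatial truncation radius in units of `sigma_synp`.
#' @return an object of class `lcm_connectivity`: a list with `table` (one
#'   row per post column x pre column x rule x receptor link) and `meta`.
#' @export
build_connectivity <- function(config, seed = config$run$seed %||% 1,
                               x_sd = 0.2, x_min = 0.2, trunc_radius = 3) {
  geo <- config$geometry
  n_col <- geo$n_x * geo$n_y
  cx <- (seq_len(n_col) - 1L) %% geo$n_x   # 0-based coordinates
  cy <- (seq_len(n_col) - 1L) %/% geo$n_x
  cm <- config$connection_map
  frac_cols <- grep("^frac_", names(cm), value = TRUE)
  set.seed(derive_seed(seed, "connectivity"))
  pieces <- vector("list", nrow(cm))

  for (i in seq_len(nrow(cm))) {
    rule <- cm[i, ]
    pre <- config$groups[[rule$pre_group]]
    post <- config$groups[[rule$post_group]]
    atten <- dendritic_attenuation(rule$s_dend, geo$lambda_PSP)
    thalamic_link <- xor(pre$layer == "TH", post$layer == "TH")
    z <- if (thalamic_link) geo$thalamus_distance else
      abs(geo$layer_depths[[pre$layer]] - geo$layer_depths[[post$layer]])

    if (isTRUE(pre$is_source)) {
      # within-column afferent: all N_qp on the home column, X = 1
      base <- data.frame(post_col = seq_len(n_col), pre_col = seq_len(n_col),
                         w0 = 1, X = 1)
      dist3 <- sqrt(z^2) # no horizontal offset
      base$delay_steps <- conduction_delay_steps(dist3, geo$v_AP, geo$dt)
    } else {
      rad <- trunc_radius * rule$sigma_synp
      max_off <- floor(rad / geo$column_size)
      offs <- expand.grid(dx = -max_off:max_off, dy = -max_off:max_off)
      offs$h <- geo$column_size * sqrt(offs$dx^2 + offs$dy^2)
      offs <- offs[offs$h <= rad, , drop = FALSE]
      if (nrow(offs) == 0)
        stop_fmt("rule %s -> %s: truncation radius excludes every column",
                 rule$pre_group, rule$post_group)
      offs$w0 <- spatial_kernel(offs$h, rule$sigma_synp)
      offs$delay_steps <- conduction_delay_steps(sqrt(offs$h^2 + z^2),
                                                 geo$v_AP, geo$dt)
      X <- pmax(stats::rnorm(n_col, 1, x_sd), x_min)
      # expand (post column) x (offset), keep pre columns on the sheet
      pc <- rep(seq_len(n_col), each = nrow(offs))
      px <- cx[pc] + offs$dx
      py <- cy[pc] + offs$dy
      ok <- px >= 0 & px < geo$n_x & py >= 0 & py < geo$n_y
      base <- data.frame(post_col = pc[ok],
                         pre_col = (py[ok] * geo$n_x + px[ok]) + 1L,
                         w0 = rep(offs$w0, n_col)[ok],
                         delay_steps = rep(offs$delay_steps, n_col)[ok])
      # renormalise kernel mass per post column, then scale by X
      tot <- rowsum(base$w0, base$post_col)
      base$w0 <- base$w0 / tot[base$post_col, 1]
      base$X <- X[base$post_col]
    }

    for (fc in frac_cols) {
      fr <- rule[[fc]]
      if (is.na(fr) || fr <= 0) next
      pieces[[length(pieces) + 1L]] <- data.frame(
        post_col = base$post_col, post_group = rule$post_group,
        pre_col = base$pre_col, pre_group = rule$pre_group,
        receptor = sub("^frac_", "", fc),
        weight = rule$N_qp * fr * base$w0 * base$X,
        delay_steps = base$delay_steps, attenuation = atten,
        rule = i, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, pieces[!vapply(pieces, is.null, TRUE)])
  rownames(tab) <- NULL
  structure(list(table = tab,
                 meta = list(seed = seed, x_sd = x_sd, x_min = x_min,
                             trunc_radius = trunc_radius,
                             delay_rounding = "nearest",
                             boundary = "open",
                             config_hash = config_hash(config))),
            class = "lcm_connectivity")
}

#' @export
print.lcm_connectivity <- function(x, ...) {
  cat(sprintf("<lcm_connectivity> %d links, %d receptors, max delay %d steps (seed %s)\n",
              nrow(x$table), length(unique(x$table$receptor)),
              max(x$table$delay_steps), format(x$meta$seed)))
  invisible(x)
}

#' Export / import a connectivity table
#'
#' Tabular cache format (gzipped CSV plus a JSON metadata sidecar) for reuse
#' across runs.
#'
#' @param conn an `lcm_connectivity`.
#' @param path output path (`.csv.gz`).
#' @return `path` (write) or an `lcm_connectivity` (load).
#' @export
write_connectivity <- function(conn, path) {
  con <- gzfile(path, "w")
  utils::write.csv(conn$table, con, row.names = FALSE)
  close(con)
  writeLines(jsonlite::toJSON(conn$meta, auto_unbox = TRUE, digits = NA),
             paste0(path, ".meta.json"))
  invisible(path)
}

#' @rdname write_connectivity
#' @export
load_connectivity <- function(path) {
  tab <- utils::read.csv(gzfile(path), stringsAsFactors = FALSE)
  meta <- jsonlite::fromJSON(paste0(path, ".meta.json"))
  structure(list(table = tab, meta = meta), class = "lcm_connectivity")
}

# geometric centre column (1-based index) of the sheet
centre_col <- function(geometry) {
  x0 <- floor((geometry$n_x - 1) / 2)
  y0 <- floor((geometry$n_y - 1) / 2)
  as.integer(y0 * geometry$n_x + x0 + 1L)
}

# 0-based coordinates of the central nx-by-ny block (used for coherence)
central_block <- function(geometry, nx = 10L, ny = 10L) {
  nx <- min(nx, geometry$n_x); ny <- min(ny, geometry$n_y)
  x0 <- floor((geometry$n_x - nx) / 2)
  y0 <- floor((geometry$n_y - ny) / 2)
  xs <- x0:(x0 + nx - 1L); ys <- y0:(y0 + ny - 1L)
  as.integer(outer(xs, ys, function(x, y) y * geometry$n_x + x) + 1L)
}
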