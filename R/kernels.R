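#' Discretized receptor kernel
#'
#' The postsynaptic time course of a receptor is the bi-exponential
#' \deqn{R(t) = A e^{-(t-\tau_0)/\tau_f} [1 - e^{-(t-\tau_0)/\tau_r}]
#'   H(t-\tau_0),}
#' with \eqn{A = (\tau_f+\tau_r)/\tau_f^2} the normalising constant that
#' makes the continuous kernel integrate to 1, and \eqn{H} the Heaviside
#' step. The kernel's analytic peak lies at
#' \eqn{\tau_0 + \tau_r \log(1 + \tau_f/\tau_r)}.
#'
#' `receptor_kernel()` samples the kernel on the simulation grid, truncates
#' at `horizon` and renormalises the discrete sum so that
#' `sum(kernel) * dt == 1` exactly. The simulation engine itself evaluates
#' the same kernel through its exact two-pole recursive form (no horizon);
#' the sampled version is the reference used in tests and for inspection.
#'
#' @param rcpt an [lcm_receptor()].
#' @param dt sample step, ms.
#' @param horizon kernel length, ms; must exceed `tau_0` and leave a
#'   continuous tail mass below `1e-4` (roughly `tau_0 + 10 * tau_f`).
#' @return numeric vector of kernel samples at `t = 0, dt, 2 dt, ...`
#'   (1/ms), with attributes `t` (sample times) and `tail_mass` (continuous
#'   mass beyond the horizon, before renormalisation).
#' @export
receptor_kernel <- function(rcpt, dt, horizon) {
  if (horizon <= rcpt$tau_0)
    stop_fmt("receptor '%s': horizon (%g ms) must exceed tau_0 (%g ms)",
             rcpt$name, horizon, rcpt$tau_0)
  t <- seq(0, horizon, by = dt)
  s <- t - rcpt$tau_0
  A <- (rcpt$tau_f + rcpt$tau_r) / rcpt$tau_f^2
  k <- ifelse(s >= 0,
              A * exp(-s / rcpt$tau_f) * (1 - exp(-s / rcpt$tau_r)), 0)
  # continuous mass beyond the horizon (analytic)
  sh <- horizon - rcpt$tau_0
  tail <- A * (rcpt$tau_f * exp(-sh / rcpt$tau_f) -
               1 / (1 / rcpt$tau_f + 1 / rcpt$tau_r) *
                 exp(-sh * (1 / rcpt$tau_f + 1 / rcpt$tau_r)))
  tot <- sum(k) * dt
  if (tot <= 0) stop_fmt("receptor '%s': degenerate kernel", rcpt$name)
  k <- k / tot
  structure(k, t = t, tail_mass = tail)
}

# Exact recursive representation of the discrete kernel.
#
# On the step grid the kernel is K[m] = A' (a_f^m - a_b^m) for samples
# taken m steps after the transmission delay, with a_f = exp(-dt/tau_f)
# and a_b = exp(-dt (1/tau_f + 1/tau_r)). A' normalises the infinite
# discrete sum: sum_m K[m] dt = 1. Convolution with K is then two leaky
# accumulators (geometric series), which the engine updates in O(1) per
# step -- exact, with no horizon truncation.
kernel_iir <- function(rcpt, dt) {
  a_f <- exp(-dt / rcpt$tau_f)
  a_b <- exp(-dt * (1 / rcpt$tau_f + 1 / rcpt$tau_r))
  norm <- 1 / (dt * (1 / (1 - a_f) - 1 / (1 - a_b)))
  list(a_f = a_f, a_b = a_b, norm = norm,
       n0 = as.integer(round(rcpt$tau_0 / dt)))
}
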