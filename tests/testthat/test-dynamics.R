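test_that("sigmoid firing rate has the right midpoint, limits and values", {
  g <- lcm_group("x", "IV", "excitatory", F_max = 200, k = 0.2,
                 V_HMF = -45, tau_m = 10)
  expect_equal(firing_rate(-45, g), 100) # half-maximum at V_HMF
  expect_equal(firing_rate(-1e4, g), 0)
  expect_equal(firing_rate(1e4, g), 200)
  expect_equal(firing_rate(-65, g), 200 / (1 + exp(4)), tolerance = 1e-12)
  expect_equal(firing_rate(-65, g), 3.594, tolerance = 1e-3)
  V <- seq(-90, 10, by = 0.5)
  expect_true(all(diff(firing_rate(V, g)) > 0)) # strictly increasing
})

test_that("PSP amplitude vanishes at reversal and peaks at phi = 1/lambda", {
  rA <- lcm_receptor("AMPA", 1, 0.5, 2.4, lambda_adapt = 0.005, V_rev = 0)
  rG <- lcm_receptor("GABA", 1, 0.5, 7, lambda_adapt = 0.005, V_rev = -70)
  expect_equal(psp_amplitude(0, 37, 0.4, 10, rA), 0)
  expect_equal(psp_amplitude(-70, 37, 2, 10, rG), 0)
  expect_equal(psp_amplitude(-55, 0, 0.4, 10, rA), 0)
  expect_gt(psp_amplitude(-65, 10, 0.4, 10, rA), 0)   # EPSP depolarizes
  expect_lt(psp_amplitude(-60, 10, 2, 10, rG), 0)     # IPSP above -70
  # adaptation maximum on a dense rate grid
  phi <- seq(0.5, 1000, by = 0.5)
  amp <- psp_amplitude(-65, phi, 0.4, 1, rA)
  expect_equal(phi[which.max(abs(amp))], 1 / rA$lambda_adapt,
               tolerance = 0.01)
  # lambda -> 0: linear rate scaling, 0.4 * 65 * 10 = 260 uV
  r0 <- lcm_receptor("AMPA", 1, 0.5, 2.4, lambda_adapt = 0, V_rev = 0)
  expect_equal(psp_amplitude(-65, 10, 0.4, 1, r0), 260)
  expect_error(psp_amplitude(-65, -1, 0.4, 1, rA), "phi_p")
})

test_that("zero-gain network is a fixed point with closed-form decay", {
  cfg <- set_gains(fixture_config("tiny", seed = 1), 0, 0)
  conn <- build_connectivity(cfg, 1)
  rec <- run_simulation(cfg, conn, seed = 1, warmup = 0, record = 0.25,
                        record_potentials = TRUE)
  expect_true(all(rec$u == 0))
  f0 <- firing_rate(-65, cfg$groups$E)
  expect_true(all(abs(rec$rates[, rec$units$group == "E"] - f0) < 1e-12))

  # with all gains zero, an initial deflection decays as
  # u(n) = u0 exp(-n dt / tau_m), exactly
  rec2 <- run_simulation(cfg, conn, seed = 1, warmup = 0, record = 0.05,
                         u0 = 10, record_potentials = TRUE)
  n <- nrow(rec2$u)
  tau <- cfg$groups$E$tau_m
  expect_equal(rec2$u[, rec2$units$group == "E"],
               10 * exp(-(1:n) * 0.5 / tau), tolerance = 1e-12)
})

test_that("engine matches a dt/10 brute-force reference integration", {
  cfg <- fixture_config("tiny", seed = 1)
  conn <- build_connectivity(cfg, 1)
  dur_ms <- 100
  inputs <- list(CC = matrix(1, 2 * dur_ms, 1)) # constant 1 AP/sec drive
  rec <- run_simulation(cfg, conn, inputs = inputs, seed = 1, warmup = 0,
                        record = dur_ms / 1000, record_potentials = TRUE)
  ref <- fine_step_reference(cfg, conn, cc_rate = 1, duration_ms = dur_ms)
  uE <- rec$u[, rec$units$group == "E"]
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(rms(uE - ref$u[, "E"]) / rms(ref$u[, "E"]), 0.02)
  uI <- rec$u[, rec$units$group == "I"]
  expect_lt(rms(uI - ref$u[, "I"]) / rms(ref$u[, "I"]), 0.02)
})

test_that("two-group reduction tracks the reference across random draws", {
  for (s in 1:10) {
    cfg <- rand_tiny_config(s)
    conn <- build_connectivity(cfg, s)
    inputs <- list(CC = matrix(1, 160, 1))
    rec <- run_simulation(cfg, conn, inputs = inputs, seed = s, warmup = 0,
                          record = 0.08, record_potentials = TRUE)
    ref <- fine_step_reference(cfg, conn, cc_rate = 1, duration_ms = 80)
    rms <- function(x) sqrt(mean(x^2))
    err <- rms(rec$u[, rec$units$group == "E"] - ref$u[, "E"]) /
      rms(ref$u[, "E"])
    expect_lt(err, 0.02, label = sprintf("draw %d", s))
  }
})

test_that("constant drive settles onto the self-consistent fixed point", {
  cfg <- fixture_config("tiny", seed = 1)
  conn <- build_connectivity(cfg, 1)
  inputs <- list(CC = matrix(1, 8000, 1))
  rec <- run_simulation(cfg, conn, inputs = inputs, seed = 1, warmup = 3.5,
                        record = 0.5)
  fp <- solve_fixed_point(cfg, conn, cc_rate = 1)
  term <- colMeans(rec$rates)
  expect_equal(unname(term[rec$units$group == "E"]), unname(fp$rates["E"]),
               tolerance = 0.01)
  expect_equal(unname(term[rec$units$group == "I"]), unname(fp$rates["I"]),
               tolerance = 0.01)
})

test_that("records are bit-identical for identical seeds", {
  cfg <- fixture_config("small", seed = 6)
  r1 <- run_simulation(cfg, seed = 6, warmup = 0.2, record = 0.3)
  r2 <- run_simulation(cfg, seed = 6, warmup = 0.2, record = 0.3)
  expect_identical(r1$rates, r2$rates)
  r3 <- run_simulation(cfg, seed = 7, warmup = 0.2, record = 0.3)
  expect_false(identical(r1$rates, r3$rates))
})

test_that("a zero-magnitude protocol window changes nothing", {
  cfg <- fixture_config("small", seed = 6)
  conn <- build_connectivity(cfg, 6)
  inputs <- realize_inputs(cfg, 0.5, 6)
  base <- run_simulation(cfg, conn, inputs, seed = 6, warmup = 0.2,
                         record = 0.3)
  prot <- protocol_window("g_E", 0.05, 0.25, 0, "delta")
  same <- run_simulation(cfg, conn, inputs, protocol = prot, seed = 6,
                         warmup = 0.2, record = 0.3)
  expect_identical(base$rates, same$rates)
})

test_that("rates stay within [0, F_max] and potentials finite", {
  cfg <- fixture_config("small", seed = 1)
  rec <- run_simulation(set_gains(cfg, 0.43, 2), seed = 1, warmup = 2,
                        record = 1, record_potentials = TRUE)
  fmax <- max(unlist(lapply(cfg$groups, `[[`, "F_max")), na.rm = TRUE)
  expect_true(all(rec$rates >= 0 & rec$rates <= fmax))
  expect_true(all(is.finite(rec$u)))
})

test_that("shifting the inputs shifts the response (time invariance)", {
  cfg <- fixture_config("tiny", seed = 3)
  conn <- build_connectivity(cfg, 3)
  m <- 40L # shift, steps
  n <- 1200L
  x <- generate_noise(cfg$stimuli$cortical, n * 0.5 / 1000, 0.5, 1, seed = 3)
  shifted <- rbind(matrix(x[1, 1], m, 1), x[seq_len(n - m), , drop = FALSE])
  r1 <- run_simulation(cfg, conn, inputs = list(CC = x), seed = 3,
                       warmup = 0.1, record = n * 5e-4 - 0.1)
  r2 <- run_simulation(cfg, conn, inputs = list(CC = shifted), seed = 3,
                       warmup = 0.1, record = n * 5e-4 - 0.1)
  a <- r1$rates[seq_len(nrow(r1$rates) - m), ]
  b <- r2$rates[-seq_len(m), ]
  expect_equal(b, a, tolerance = 1e-4)
})

test_that("protocol windows outside the simulated interval are rejected", {
  cfg <- fixture_config("tiny", seed = 1)
  prot <- protocol_window("g_E", 5, 9, 0.01)
  expect_error(run_simulation(cfg, seed = 1, warmup = 0.1, record = 0.5,
                              protocol = prot), "outside")
})

test_that("runaway activity aborts with a diagnostic", {
  cfg <- fixture_config("small", seed = 1)
  expect_error(run_simulation(set_gains(cfg, 3, 6), seed = 1, warmup = 0.5,
                              record = 0.5), "non-finite")
})
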