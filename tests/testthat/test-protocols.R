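# protocol mechanics are tested on mocks and very short runs; the full
# phase-structure behaviour lives in test-acceptance.R

test_that("bisection recovers the step location of a mock rate curve", {
  cfg <- fixture_config("small")
  step_fn <- function(gE) if (gE < 0.4) 0.3 else 60
  cg <- find_critical_gain(cfg, g_I = 2, interval = c(0.3, 0.5),
                           mfr_fn = step_fn)
  expect_lt(abs(cg$g_E_C - 0.4), 0.003)
  expect_lte(diff(cg$interval), 0.003)

  expect_error(find_critical_gain(cfg, 2, c(0.1, 0.2),
                                  mfr_fn = function(g) 0.1),
               "no boundary in range")
  expect_error(find_critical_gain(cfg, 2, c(0.1, 0.2),
                                  mfr_fn = function(g) 60),
               "no boundary in range")
})

test_that("boundary fit recovers an exact line and reports both forms", {
  pts <- data.frame(g_I = c(0.5, 1, 2, 3, 4),
                    g_E_C = 0.018 * c(0.5, 1, 2, 3, 4) + 0.376)
  b <- fit_boundary(pts)
  expect_equal(unname(coef(b)), c(0.376, 0.018), tolerance = 1e-12)
  expect_equal(unname(b$inverted["slope"]), 1 / 0.018, tolerance = 1e-9)
  expect_equal(unname(b$inverted["intercept"]), -0.376 / 0.018,
               tolerance = 1e-9)
  expect_equal(round(b$inverted[["slope"]], 1), 55.6)
  expect_equal(round(-b$inverted[["intercept"]], 1), 20.9)
  expect_lt(max(abs(b$residuals)), 1e-12)

  expect_error(fit_boundary(pts[1:2, ]), ">= 3 points")
  expect_error(fit_boundary(data.frame(g_I = c(2, 2, 2),
                                       g_E_C = c(0.4, 0.41, 0.42))),
               "degenerate")
})

test_that("gain sweeps populate every cell and sd needs replicates", {
  cfg <- fixture_config("small", seed = 1)
  map <- sweep_gains(cfg, g_E_values = c(0.30, 0.42),
                     g_I_values = c(1, 2), seed = 1,
                     warmup = 0.3, record = 0.64, msc_block = 2)
  expect_s3_class(map, "lcm_phase_map")
  expect_equal(nrow(map), 4)
  expect_true(all(map$status == "ok"))
  agg <- summary(map)
  expect_true(all(is.na(agg$MFR_sd))) # single replicate: no sd

  map2 <- sweep_gains(cfg, 0.42, 2, n_replicates = 2, seed = 1,
                      warmup = 0.3, record = 0.64, msc_block = 2)
  expect_false(anyNA(summary(map2)$MFR_sd))
})

test_that("sweep cells are cached and reused bit-identically", {
  cfg <- fixture_config("small", seed = 1)
  cache <- withr::local_tempdir()
  m1 <- sweep_gains(cfg, c(0.30, 0.42), 2, seed = 1, warmup = 0.3,
                    record = 0.64, cache_dir = cache, msc_block = 2)
  expect_gt(length(list.files(cache)), 0)
  t0 <- system.time(
    m2 <- sweep_gains(cfg, c(0.30, 0.42), 2, seed = 1, warmup = 0.3,
                      record = 0.64, cache_dir = cache, msc_block = 2))
  expect_identical(m1$MFR, m2$MFR)
  expect_lt(t0[["elapsed"]], 2) # cache hit, no simulation
})

test_that("failed cells are recorded without aborting the sweep", {
  cfg <- fixture_config("small", seed = 1)
  map <- sweep_gains(cfg, g_E_values = c(0.30, 3), g_I_values = 6,
                     seed = 1, warmup = 0.5, record = 0.64, msc_block = 2)
  expect_equal(nrow(map), 2)
  expect_equal(map$status[1], "ok")
  expect_match(map$status[2], "non-finite")
  expect_true(is.na(map$MFR[2]))
})

test_that("zero-delta transients leave no trace; protocols restore state", {
  cfg <- fixture_config("small", seed = 2)
  tr <- transient_gain_protocol(cfg, "g_E", delta = 0, start = 0.1,
                                duration = 0.2, seed = 2, warmup = 0.2,
                                record = 0.5)
  expect_true(all(tr$diff == 0))
  expect_false(tr$hysteresis)
  expect_error(transient_gain_protocol(cfg, "g_E", 0.01, start = 0.4,
                                       duration = 0.3, seed = 2,
                                       warmup = 0.2, record = 0.5),
               "outside")
})

test_that("SCN1A scan defaults follow the mutation protocols", {
  expect_equal(eval(formals(scn1a_fmax_protocol)$values), seq(200, 40, -10))
  expect_equal(eval(formals(scn1a_vhmf_protocol)$values), seq(-45, -19, 2))
  expect_length(eval(formals(scn1a_vhmf_protocol)$values), 14)

  cfg <- fixture_config("small", seed = 1)
  scan <- scn1a_fmax_protocol(cfg, values = c(200, 120), seed = 1,
                              warmup = 0.3, record = 0.64, msc_block = 2)
  expect_equal(scan$F_max, c(200, 120))
  expect_true(all(scan$status == "ok"))
})

test_that("reversal-shift grid has full bookkeeping and a baseline column", {
  cfg <- fixture_config("small", seed = 1)
  grid <- reversal_shift_protocol(cfg, g_I_values = c(1, 2),
                                  V_rev_values = c(-70, -60), seed = 1,
                                  warmup = 0.3, record = 0.64, msc_block = 2)
  expect_equal(nrow(grid), 4)
  # V_rev = -70 column equals a plain sweep at the same gains
  base <- sweep_gains(cfg, cfg$gains$g_E, c(1, 2), seed = 1,
                      warmup = 0.3, record = 0.64, msc_block = 2)
  expect_equal(grid$MFR[grid$V_rev == -70], base$MFR, tolerance = 1e-12)
})

test_that("identical stimulus conditions give identically zero differences", {
  cfg <- fixture_config("small", seed = 3)
  # make the stimulated condition identical to the background condition
  cfg$stimuli$thalamic_stimulated <- cfg$stimuli$thalamic
  sr <- stimulation_response(cfg, data.frame(g_E = 0.35, g_I = 2),
                             seed = 3, warmup = 0.3, record = 0.64,
                             msc_block = 2)
  expect_equal(sr$dMFR, 0)
  expect_equal(sr$dPSD_L, 0)
  expect_equal(sr$dMSC_H, 0)
})
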