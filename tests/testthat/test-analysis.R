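# build a synthetic record directly (no simulation) for analysis tests
synth_record <- function(mat, groups = "E", dt = 0.5) {
  n_col <- ncol(mat) / length(groups)
  structure(list(rates = mat, u = NULL,
                 units = data.frame(group = rep(groups, each = n_col),
                                    col = rep(seq_len(n_col),
                                              length(groups))),
                 dt = dt, meta = list(seed = 0)),
            class = "lcm_record")
}

synth_config <- function(n_x, n_y, groups = list(c("E", "excitatory"))) {
  gs <- lapply(groups, function(g)
    lcm_group(g[1], "II/III", g[2], F_max = 200, k = 0.3, V_HMF = -45,
              tau_m = 10))
  lcm_config(lcm_geometry(n_x, n_y), gs,
             list(lcm_receptor("AMPA", 1, 0.5, 2.4, 0.005, 0)),
             lcm_synapse_rule("E", "E", 0, c(AMPA = 1)),
             lcm_gains(0.4, 2), validate = FALSE)
}

test_that("column excitation averages cortical excitatory groups only", {
  cfg <- synth_config(2, 1, list(c("E", "excitatory"), c("I", "inhibitory"),
                                 c("E2", "excitatory")))
  m <- cbind(matrix(10, 50, 2), matrix(99, 50, 2), matrix(30, 50, 2))
  rec <- synth_record(m, groups = c("E", "I", "E2"))
  ex <- column_excitation(rec, cfg)
  expect_equal(dim(ex), c(50, 2))
  expect_true(all(ex == 20)) # mean of 10 and 30; interneurons excluded

  # a single excitatory group passes through unchanged
  cfg1 <- synth_config(2, 1, list(c("E", "excitatory")))
  rec1 <- synth_record(cbind(matrix(4, 10, 1), matrix(6, 10, 1)))
  ex1 <- column_excitation(rec1, cfg1)
  expect_true(all(ex1[, 1] == 4) && all(ex1[, 2] == 6))

  cfgI <- synth_config(1, 1, list(c("I", "inhibitory")))
  recI <- synth_record(matrix(1, 10, 1), groups = "I")
  expect_error(column_excitation(recI, cfgI), "excitatory")
})

test_that("tapered-cosine MFR is exact for constants and near-exact for sines", {
  expect_equal(mean_firing_rate(rep(3.7, 1000)), 3.7)
  expect_equal(mean_firing_rate(rep(3.7, 1000), taper = 0.9), 3.7)
  expect_equal(mean_firing_rate(numeric(5)), 0)
  t <- seq_len(4000)
  s <- 12 + 5 * sin(2 * pi * t / 200) # 20 whole periods
  expect_equal(mean_firing_rate(s), 12, tolerance = 0.01)
  expect_error(mean_firing_rate(numeric(0)), "empty")
})

test_that("Welch PSD satisfies Parseval on known signals", {
  dt <- 0.5
  n <- 10240 # 5.12 s at 2 kHz
  t <- (seq_len(n) - 1) * dt / 1000
  sine <- sin(2 * pi * 10 * t)
  psd <- welch_psd(sine, dt)
  df <- diff(psd$freq[1:2])
  expect_equal(sum(psd$power) * df, 0.5, tolerance = 0.05 * 0.5)
  # mass concentrated near 10 Hz
  peak <- psd$freq[which.max(psd$power)]
  expect_lt(abs(peak - 10), df)
  near <- abs(psd$freq - 10) <= 3 * df
  expect_gt(sum(psd$power[near]) / sum(psd$power), 0.95)

  set.seed(42)
  wn <- rnorm(n, sd = 2)
  pw <- welch_psd(wn, dt)
  expect_equal(sum(pw$power) * df, 4, tolerance = 0.4)

  pc <- welch_psd(rep(5, n), dt)
  expect_lt(max(pc$power), 1e-20) # mean removal kills a constant

  expect_error(welch_psd(rnorm(40), dt), "short")
})

test_that("MSC is 1 for identical columns and small for independent noise", {
  dt <- 0.5
  set.seed(1)
  x <- as.vector(arima.sim(list(ar = 0.95), 4000))
  same <- cbind(x, x, x)
  ms <- msc(same, dt)
  expect_true(all(ms$msc > 1 - 1e-9))
  expect_true(all(ms$msc <= 1 + 1e-9))

  indep <- matrix(rnorm(4000 * 10), ncol = 10)
  mi <- msc(indep, dt, max_freq = 60)
  expect_equal(attr(mi, "n_pairs"), 45L)
  expect_lt(band_mean(mi, c(2, 15)), 0.25)
  expect_lt(band_mean(mi, c(16, 50)), 0.25)
  expect_true(all(mi$msc >= 0 & mi$msc <= 1 + 1e-9))

  two <- msc(indep[, 1:2], dt)
  expect_equal(attr(two, "n_pairs"), 1L)
  expect_error(msc(indep[, 1, drop = FALSE], dt), "2 column")
})

test_that("uncorrected MSC denominator reproduces the asymmetric form", {
  set.seed(2)
  a <- rnorm(3000); b <- 3 * a + rnorm(3000, sd = 0.1)
  sym <- msc(cbind(a, b), 0.5)
  asym <- msc(cbind(a, b), 0.5, corrected = FALSE)
  expect_true(all(sym$msc <= 1 + 1e-9))
  expect_gt(max(asym$msc), 1) # PSD_i^2 denominator is not bounded
})

test_that("band means honour bin-centre edges", {
  sp <- data.frame(freq = seq(0, 100, by = 1), power = 7)
  expect_equal(band_mean(sp, c(2, 15)), 7)
  expect_equal(band_mean(sp, c(16, 50)), 7)
  sp2 <- data.frame(freq = c(2, 15, 15.5, 16), power = c(1, 1, 99, 5))
  expect_equal(band_mean(sp2, c(16, 50)), 5) # 15.5 lies outside
  expect_error(band_mean(sp, c(200, 300)), "no frequency bins")
})

test_that("analyze uses the central column and central block", {
  geo <- lcm_geometry(20, 20)
  blk <- lcmr:::central_block(geo, 10, 10)
  xy <- cbind((blk - 1) %% 20, (blk - 1) %/% 20)
  expect_equal(sort(unique(xy[, 1])), 5:14) # 0-based block coordinates
  expect_equal(sort(unique(xy[, 2])), 5:14)
  expect_length(blk, 100)

  # on a small sheet the MSC falls back to every column
  cfg <- fixture_config("small", seed = 1)
  rec <- run_simulation(cfg, seed = 1, warmup = 0.5, record = 5.12)
  an <- analyze(rec, cfg)
  expect_equal(an$n_columns_used, 16)
  expect_match(an$note, "all")
  expect_true(an$MSC_L >= 0 && an$MSC_L <= 1)
  expect_true(all(an$PSD$power >= 0))
  # pure function: same record, same result
  expect_identical(an$MFR, analyze(rec, cfg)$MFR)
})

test_that("region correlations partition by the boundary and flag constants", {
  # synthetic map around a known line g_EC = 0.02 g_I + 0.38
  set.seed(3)
  cells <- expand.grid(g_E = seq(0.30, 0.46, by = 0.02),
                       g_I = seq(0.5, 3, by = 0.5))
  gc <- 0.02 * cells$g_I + 0.38
  cells$MFR <- ifelse(cells$g_E <= gc, 50 * cells$g_E + rnorm(nrow(cells),
                                                              sd = 1e-4),
                      100)
  cells$PSD_L <- 1; cells$PSD_H <- 1; cells$MSC_L <- 1; cells$MSC_H <- 1
  cells$condition <- "non_stimulated"; cells$replicate <- 1L
  class(cells) <- c("lcm_phase_map", "data.frame")
  bnd <- fit_boundary(data.frame(g_I = c(0.5, 1.5, 3),
                                 g_E_C = 0.02 * c(0.5, 1.5, 3) + 0.38))
  rc <- region_correlations(cells, bnd, delta = 0.002)
  r1 <- rc[rc$statistic == "MFR" & rc$gain == "g_E" &
             rc$region == "region1", ]
  expect_gt(r1$r, 0.99)
  # constant statistic -> undefined correlation, reported as NA
  rP <- rc[rc$statistic == "PSD_L" & rc$region == "region1", ]
  expect_true(all(is.na(rP$r)))
  # cells within delta of the line are excluded from both regions
  n_used <- sum(rc[rc$statistic == "MFR" & rc$gain == "g_E", "n"])
  expect_lt(n_used, nrow(cells))
})
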