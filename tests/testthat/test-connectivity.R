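test_that("conduction delays follow distance / speed, rounded to steps", {
  expect_identical(conduction_delay_steps(1000, 1.0, 0.5), 2L) # 1 ms
  expect_identical(conduction_delay_steps(0, 1.0, 0.5), 0L)
  expect_identical(conduction_delay_steps(140, 1.0, 0.5), 0L)  # 0.14 ms
  expect_error(conduction_delay_steps(100, 0, 0.5), "v_AP")
  expect_error(conduction_delay_steps(-1, 1, 0.5), "distance")
})

test_that("dendritic attenuation is exponential and monotone", {
  expect_equal(dendritic_attenuation(0, 300), 1)
  expect_equal(dendritic_attenuation(300, 300), exp(-1))
  s <- seq(0, 500, by = 25)
  expect_true(all(diff(dendritic_attenuation(s, 120)) < 0))
  expect_error(dendritic_attenuation(-5, 300), "s_dend")
})

test_that("spatial kernel has Gaussian shape and unit planar mass", {
  expect_equal(spatial_kernel(0, 80, X = 1), 1 / (2 * pi * 6400))
  expect_equal(spatial_kernel(80, 80), exp(-0.5) * spatial_kernel(0, 80))
  expect_equal(spatial_kernel(50, 40), spatial_kernel(-50, 40)) # symmetry
  # numerical quadrature of the planar integral out to 6 sigma
  for (X in c(1, 0.7)) {
    h <- 1
    g <- seq(-480, 480, by = h)
    grid <- expand.grid(x = g, y = g)
    mass <- sum(spatial_kernel(sqrt(grid$x^2 + grid$y^2), 80, X)) * h^2
    expect_equal(mass, X, tolerance = 1e-3)
  }
})

test_that("per-column weights conserve N_qp x receptor fraction x X", {
  cfg <- fixture_config("small", seed = 2)
  # with the wiring factor fixed at 1, the sum over presynaptic columns
  # must equal N_qp times the receptor fraction exactly
  conn <- build_connectivity(cfg, seed = 2, x_sd = 0)
  tab <- conn$table
  key <- interaction(tab$rule, tab$post_col, tab$receptor, drop = TRUE)
  sums <- tapply(tab$weight, key, sum)
  cm <- cfg$connection_map
  frac_cols <- grep("^frac_", names(cm), value = TRUE)
  for (k in names(sums)) {
    p <- strsplit(k, ".", fixed = TRUE)[[1]]
    rule <- as.integer(p[1])
    frac <- cm[[paste0("frac_", p[3])]][rule]
    expect_equal(unname(sums[[k]]), cm$N_qp[rule] * frac, tolerance = 1e-12)
  }
})

test_that("wiring factor X has mean 1 and sd 0.2 over many draws", {
  cfg <- fixture_config("paper", seed = 3)
  conn <- build_connectivity(cfg, seed = 3)
  tab <- conn$table
  src <- vapply(cfg$groups, function(g) isTRUE(g$is_source), TRUE)
  tab <- tab[!tab$pre_group %in% names(cfg$groups)[src], ]
  cm <- cfg$connection_map
  frac_of <- function(rule, rcpt) cm[[paste0("frac_", rcpt)]][rule]
  key <- interaction(tab$rule, tab$post_col, tab$receptor, drop = TRUE)
  sums <- tapply(tab$weight, key, sum)
  meta <- do.call(rbind, strsplit(names(sums), ".", fixed = TRUE))
  rule <- as.integer(meta[, 1])
  x_hat <- unname(sums) / (cm$N_qp[rule] * mapply(frac_of, rule, meta[, 3]))
  # one draw per (rule, post column); receptors within a rule share it
  per_link <- tapply(x_hat, paste(meta[, 1], meta[, 2]), function(v) {
    expect_lt(diff(range(v)), 1e-10)
    v[1]
  })
  expect_gt(length(per_link), 1e4)
  expect_equal(mean(per_link), 1, tolerance = 0.01)
  expect_equal(sd(per_link), 0.2, tolerance = 0.01)
  expect_true(all(per_link >= 0.2)) # truncation floor
})

test_that("single-column fixture self-assigns all weight with laminar delay", {
  cfg <- fixture_config("tiny", seed = 1)
  conn <- build_connectivity(cfg, seed = 1)
  expect_true(all(conn$table$pre_col == 1 & conn$table$post_col == 1))
  # both groups share a lamina and column: zero axonal distance
  expect_true(all(conn$table$delay_steps == 0L))
})

test_that("rebuilds are bit-identical for a seed and spatially identical across seeds", {
  cfg <- fixture_config("small", seed = 4)
  c1 <- build_connectivity(cfg, seed = 4)
  c2 <- build_connectivity(cfg, seed = 4)
  expect_identical(c1$table, c2$table)
  c3 <- build_connectivity(cfg, seed = 99)
  expect_false(identical(c1$table$weight, c3$table$weight))
  # only the X draw differs: geometry-derived columns are unchanged
  expect_identical(c1$table[c("post_col", "post_group", "pre_col",
                              "pre_group", "receptor", "delay_steps",
                              "attenuation")],
                   c3$table[c("post_col", "post_group", "pre_col",
                              "pre_group", "receptor", "delay_steps",
                              "attenuation")])
  expect_true(all(c1$table$weight >= 0) && all(c3$table$weight >= 0))
})

test_that("connectivity tables export and reload through the tabular cache", {
  cfg <- fixture_config("tiny", seed = 1)
  conn <- build_connectivity(cfg, seed = 1)
  path <- withr::local_tempfile(fileext = ".csv.gz")
  write_connectivity(conn, path)
  back <- load_connectivity(path)
  expect_equal(back$table, conn$table)
  expect_equal(back$meta$seed, conn$meta$seed)
})
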