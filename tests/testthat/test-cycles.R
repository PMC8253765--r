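test_that("extraction round-trips the simulator's ground-truth event log", {
  sim <- simulate_lineages(small_cfg(regime = "dynamic_adder"), seed = 21)
  cyc <- extract_cycles(sim)
  ev <- sim$events
  expect_equal(nrow(cyc), nrow(ev))
  i <- match(cyc$cell_id, ev$mother_id)
  expect_false(anyNA(i))
  # exact recovery of the division arithmetic from the sampled trajectory
  expect_identical(cyc$S_premitosis, ev$S_premitosis[i])
  expect_identical(cyc$S_cytokinesis, ev$S_meta[i])
  expect_identical(cyc$S_preabscission, ev$S_cyt[i])
  expect_identical(cyc$sibling_ratio, ev$sibling_ratio[i])
  expect_true(all(cyc$T_mitotic == 15))
  expect_equal(cyc$T_gen, (ev$t[i] - cyc$t_birth) / 60)
  expect_equal(cyc$T_gen, cyc$T_interphase + cyc$T_mitotic / 60)
  # daughters' birth areas equal the event log's split exactly
  d <- match(ev$daughter1_id, cyc$cell_id)
  obs <- cyc$x[d[!is.na(d)]]
  expect_identical(obs, ev$daughter1_area[!is.na(d)])
})

test_that("trajectories without divisions yield no cycle records", {
  sim <- simulate_lineages(sim_config(n_lineages = 2L, n_generations = 0L),
                           seed = 1)
  expect_equal(nrow(extract_cycles(sim)), 0)
})

test_that("phase-order violations are reported with their row", {
  traj <- synthetic_cell_traj("c1", function(t) 400 * 2^(t / 100))
  traj$phase[50] <- "cytokinesis" # cytokinesis before metaphase
  expect_error(extract_cycles(traj), "phase order.*row")
})

test_that("sibling statistics match hand arithmetic", {
  st <- sibling_stats(data.frame(sibling_ratio = c(1.05, 1.15)))
  expect_equal(st$mean, 10)
  expect_equal(st$sd, sd(c(5, 15)))
  expect_equal(st$n, 2)
  st1 <- sibling_stats(data.frame(sibling_ratio = c(1, 1, 1)))
  expect_equal(st1$mean, 0)
  expect_equal(st1$sd, 0)
})

test_that("calibrated asymmetry noise reproduces the ~7% sibling deviation", {
  cfg <- sim_config(n_lineages = 8L, n_generations = 5L)
  sim <- simulate_lineages(cfg, seed = 31)
  st <- sibling_stats(sim$events)
  expect_gte(st$n, 227)
  expect_equal(st$mean, 7.02, tolerance = 1.0 / 7.02)
})

test_that("growth-law fit is exactly log-linear on exponential data", {
  # hand-built: two cells doubling exactly over the normalized interphase
  traj <- rbind(
    synthetic_cell_traj("c1", function(t) 400 * 2^(t / 100)),
    synthetic_cell_traj("c2", function(t) 500 * 2^(t / 100), lineage_id = 2L)
  )
  gf <- fit_growth_law(traj)
  expect_equal(gf$slope, log10(2) / 100, tolerance = 1e-12)
  expect_equal(gf$r_squared, 1, tolerance = 1e-9)

  # noiseless simulator output is exactly exponential within each cycle
  sim <- simulate_lineages(noiseless_cfg(n_lineages = 2L, n_generations = 1L),
                           seed = 1)
  gf2 <- fit_growth_law(sim)
  expect_equal(gf2$r_squared, 1, tolerance = 1e-9)
  expect_equal(gf2$slope, log10(2) / 100, tolerance = 0.01)

  traj_bad <- traj
  traj_bad$area_um2[3] <- -1
  expect_error(fit_growth_law(traj_bad), "non-positive")
})

test_that("linear growth leaves a concave residual pattern on the log scale", {
  traj <- synthetic_cell_traj("c1", function(t) 400 + 4 * t)
  gf <- fit_growth_law(traj)
  expect_lt(gf$r_squared, 1 - 1e-6)
  r <- gf$residuals[order(gf$time_norm)]
  n <- length(r)
  expect_lt(r[1], 0) # ends below the line
  expect_lt(r[n], 0)
  expect_gt(r[round(n / 2)], 0) # middle above: concavity
})

test_that("growth rate scales with size under exponential growth only", {
  # constant-rate (linear) cells of different sizes: slope exactly 0
  lin <- do.call(rbind, lapply(1:4, function(i) {
    synthetic_cell_traj(paste0("c", i), function(t) 100 * i + 2 * t,
                        lineage_id = i)
  }))
  gf <- fit_rate_vs_size(lin, window = 10)
  expect_equal(gf$slope, 0, tolerance = 1e-9)

  # exponential cells: fitted slope recovers the growth constant
  cfg <- noiseless_cfg(sigma_birth0 = 0.2, n_lineages = 8L,
                       n_generations = 2L)
  sim <- simulate_lineages(cfg, seed = 5)
  gf2 <- fit_rate_vs_size(sim, window = 10)
  expect_equal(gf2$slope, cfg$k, tolerance = 0.05)
  expect_gt(gf2$slope, 0)

  expect_error(fit_rate_vs_size(lin, window = 1), "two sample intervals")
  expect_error(fit_rate_vs_size(lin, window = 150), "longer than the interphase")
})

test_that("size classes converge toward the mean under adder control", {
  cfg <- sim_config(sigma_birth0 = 0.3, n_lineages = 40L, n_generations = 2L)
  sim <- simulate_lineages(cfg, seed = 8)
  cyc <- extract_cycles(sim)
  sc <- size_class_summary(cyc)
  expect_setequal(sc$class, c("small", "average", "large"))
  small <- sc[sc$class == "small", ]
  large <- sc[sc$class == "large", ]
  avg <- sc[sc$class == "average", ]
  expect_gt(small$n, 0)
  expect_gt(large$n, 0)
  # displaced classes move toward C_ave within one generation
  expect_lt(abs(small$x2_mean - 400), abs(small$x1_mean - 400))
  expect_lt(abs(large$x2_mean - 400), abs(large$x1_mean - 400))
  # the average class's 2nd pre-division area is close to twice its birth area
  expect_equal(avg$ratio_cyt2_birth1, 1.94, tolerance = 0.05)
})

test_that("identical cells give equal class summaries with zero deviation", {
  sim <- simulate_lineages(noiseless_cfg(n_lineages = 3L, n_generations = 2L),
                           seed = 1)
  cyc <- extract_cycles(sim)
  sc <- size_class_summary(cyc)
  avg <- sc[sc$class == "average", ]
  expect_equal(avg$x1_sd, 0, tolerance = 1e-9)
  expect_equal(avg$x2_sd, 0, tolerance = 1e-9)
  expect_equal(sc[sc$class == "small", "n"], 0)
  expect_equal(sc[sc$class == "large", "n"], 0)
})
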