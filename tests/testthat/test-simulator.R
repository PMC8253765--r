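test_that("interphase growth follows the exponential closed form", {
  cfg <- noiseless_cfg()
  st <- new_cell_state(400, cfg, k_cell = 0, control_target = 400)
  expect_equal(step_interphase(st, 10)$S, 400) # zero growth is the identity

  st <- new_cell_state(400, cfg, k_cell = log(2) / 232.2, control_target = 400)
  st2 <- step_interphase(st, 232.2)
  expect_equal(st2$S, 800)
  expect_equal(st2$t, 232.2)

  st$k_cell <- 1e6
  expect_error(step_interphase(st, 1e6), "non-finite.*L1\\.C1")
})

test_that("division triggers implement the three control rules", {
  adder <- noiseless_cfg(regime = "adder")
  st <- new_cell_state(400, adder, control_target = 400)
  st$S <- 799
  expect_false(division_trigger(st, adder))
  st$S <- 800
  expect_true(division_trigger(st, adder))

  # sizer: threshold on absolute area, independent of birth size
  sizer <- noiseless_cfg(regime = "sizer")
  for (x0 in c(350, 450)) {
    st <- new_cell_state(x0, sizer, control_target = 800)
    st$S <- 800
    expect_true(division_trigger(st, sizer))
    st$S <- 799
    expect_false(division_trigger(st, sizer))
  }

  # timer: threshold on elapsed time, independent of area
  timer <- noiseless_cfg(regime = "timer")
  st <- new_cell_state(123, timer, control_target = 232.2)
  st$t <- st$t_birth + 232.2
  st$S <- 1 # arbitrarily small
  expect_true(division_trigger(st, timer))
  st$t <- st$t_birth + 232.1
  expect_false(division_trigger(st, timer))
})

test_that("division arithmetic chain matches hand multiplication", {
  cfg <- noiseless_cfg(delta_post = 0.868)
  st <- new_cell_state(400, cfg, control_target = 400)
  st$S <- 800
  div <- apply_division(st, cfg, r = 1)
  ev <- div$event
  expect_equal(ev$S_meta, 776) # 800 * 0.97
  expect_equal(ev$S_cyt, 931.2) # 776 * 1.2
  expect_equal(ev$S_post, 808.2816) # 931.2 * 0.868
  expect_equal(ev$daughter1_area, 404.1408)
  expect_equal(ev$daughter2_area, 404.1408)
  # event invariants
  expect_identical(ev$daughter1_area + ev$daughter2_area, ev$S_post)
  expect_equal(ev$S_cyt / ev$S_meta, cfg$g_cyto)
  expect_equal(ev$S_meta / ev$S_premitosis, 1 - cfg$eps_meta)
  # the sampled mitotic path spans exactly m_duration minutes
  expect_equal(nrow(div$path), 15)
  expect_equal(div$daughter1$t_birth - st$t, 15)

  bad <- cfg
  bad$delta_post <- 1.6
  st2 <- new_cell_state(400, cfg, control_target = 400)
  st2$S <- 800
  expect_error(apply_division(st2, bad, r = 1), "delta_post")
})

test_that("symmetric division splits daughters exactly evenly", {
  cfg <- noiseless_cfg()
  st <- new_cell_state(400, cfg, control_target = 400)
  st$S <- 800
  div <- apply_division(st, cfg) # sigma_asym = 0 so r = 1
  expect_equal(div$event$sibling_ratio, 1)
  expect_identical(div$event$daughter1_area, div$event$daughter2_area)
})

test_that("phagocytic flux bookkeeping is Poisson and size-independent", {
  cfg <- sim_config(regime = "dynamic_adder")
  st <- new_cell_state(400, cfg, control_target = 400)
  st0 <- simulate_fluxes(st, 0, cfg)
  expect_identical(st0$cum_exo, 0) # zero-length step changes nothing
  expect_identical(st0$cum_endo, 0)

  set.seed(401)
  m_int <- mean(simulate_phago_windows(600, 10, cfg, "interphase"))
  expect_equal(m_int, 19.1, tolerance = 0.6 / 19.1)
  m_mit <- mean(simulate_phago_windows(600, 10, cfg, "mitosis"))
  expect_equal(m_mit, 1.53, tolerance = 0.2 / 1.53)

  # the event rate does not depend on S: identical draws, identical uptake
  big <- new_cell_state(4000, cfg, control_target = 400)
  sml <- new_cell_state(40, cfg, control_target = 400)
  set.seed(5)
  b <- simulate_fluxes(big, 10, cfg)
  set.seed(5)
  s <- simulate_fluxes(sml, 10, cfg)
  expect_identical(b$cum_endo, s$cum_endo)

  bad <- cfg
  bad$lambda_phago_I <- -1
  expect_error(simulate_fluxes(st, 1, bad), "negative phagocytosis rate")
})

test_that("lineage simulation is deterministic and respects run geometry", {
  cfg <- small_cfg()
  s1 <- simulate_lineages(cfg, seed = 11)
  s2 <- simulate_lineages(cfg, seed = 11)
  expect_identical(s1$trajectories, s2$trajectories)
  expect_identical(s1$events, s2$events)
  s3 <- simulate_lineages(cfg, seed = 12)
  expect_false(identical(s1$trajectories, s3$trajectories))

  # n_generations = 0: founders only, no divisions
  s0 <- simulate_lineages(sim_config(n_lineages = 4L, n_generations = 0L),
                          seed = 1)
  expect_equal(nrow(s0$events), 0)
  expect_equal(nrow(s0$trajectories), 4)

  # full binary trees: 2^g - 1 divisions per lineage
  expect_equal(nrow(s1$events), cfg$n_lineages * (2^cfg$n_generations - 1))
})

test_that("adder birth sizes are stationary at the calibrated fixed point", {
  cfg <- sim_config(follow = "one", n_lineages = 20L, n_generations = 20L)
  sim <- simulate_lineages(cfg, seed = 2)
  cyc <- extract_cycles(sim)
  late <- cyc[cyc$generation >= 3, ]
  # steady state of x' = f_M * (x + C_ave) / 2 with f_M = 1 is C_ave
  expect_equal(mean(late$x), cfg$C_ave, tolerance = 0.05)
})

test_that("runaway growth under timer control aborts with a diagnostic", {
  cfg <- sim_config(regime = "timer", T_ave = 40, k = log(2) / 217.2,
                    n_lineages = 1L, n_generations = 2L)
  expect_error(simulate_lineages(cfg, seed = 1), "runaway.*timer")
})
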