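ideal_cases <- list(
  list(model = "adder", kind = "dS_vs_x", slope = 0),
  list(model = "sizer", kind = "dS_vs_x", slope = -1),
  list(model = "timer", kind = "dS_vs_x", slope = 1),
  list(model = "adder", kind = "Scyt_vs_x", slope = 1),
  list(model = "sizer", kind = "Scyt_vs_x", slope = 0),
  list(model = "adder", kind = "logT_vs_logx", slope = -1),
  list(model = "timer", kind = "logT_vs_logx", slope = 0)
)

test_that("ideal-model datasets recover their defining slopes exactly", {
  for (cs in ideal_cases) {
    d <- ideal_dataset(cs$model, cs$kind)
    fit <- fit_diagnostic(d, cs$kind, n_bootstrap = 200, seed = 9)
    expect_equal(fit$slope, cs$slope, tolerance = 1e-9,
                 label = sprintf("%s / %s slope", cs$model, cs$kind))
    # noiseless data: every bootstrap resample lies on the same line
    expect_lt(fit$ci_high - fit$ci_low, 1e-9)
    expect_gte(fit$slope, fit$ci_low)
    expect_lte(fit$slope, fit$ci_high)
  }
})

test_that("model/diagnostic combinations the theory does not define error out", {
  expect_error(ideal_dataset("timer", "Scyt_vs_x"), "unsupported combination")
  expect_error(ideal_dataset("sizer", "logT_vs_logx"), "unsupported combination")
})

test_that("slope diagnostics are invariant under area rescaling", {
  sim <- simulate_lineages(small_cfg(), seed = 13)
  cyc <- extract_cycles(sim)
  scaled <- cyc
  for (f in c("x", "S_premitosis", "S_cytokinesis", "S_preabscission",
              "dS_whole", "dS_interphase")) {
    scaled[[f]] <- scaled[[f]] * 3
  }
  for (kind in c("dS_vs_x", "Scyt_vs_x", "logT_vs_logx")) {
    a <- fit_diagnostic(cyc, kind, n_bootstrap = 0)
    b <- fit_diagnostic(scaled, kind, n_bootstrap = 0)
    expect_equal(b$slope, a$slope, tolerance = 1e-9, label = kind)
  }
  # the raw-scale intercepts shift; the log-diagnostic intercept moves by
  # (1 - slope) * log10(3)
  a3 <- fit_diagnostic(cyc, "logT_vs_logx", n_bootstrap = 0)
  b3 <- fit_diagnostic(scaled, "logT_vs_logx", n_bootstrap = 0)
  expect_equal(b3$intercept - a3$intercept, -a3$slope * log10(3),
               tolerance = 1e-9)
})

test_that("binned display means respect the minimum occupancy", {
  sim <- simulate_lineages(small_cfg(), seed = 14)
  cyc <- extract_cycles(sim)
  fit <- fit_diagnostic(cyc, "dS_vs_x", n_bootstrap = 0)
  expect_true(all(fit$binned$n >= 5))
  expect_equal(sum(fit$binned$n), fit$n)
})

test_that("classification maps slope triples to regimes", {
  expect_equal(classify(0, 1, -1)$label, "adder")
  expect_equal(classify(-1, 0, -1.44)$label, "sizer")
  expect_equal(classify(1, 1.94, 0)$label, "timer")
  # the observed whole-cycle slopes fall in the adder family
  expect_true(classify(-0.15, 0.85, -1.24)$label %in%
                c("adder", "near_adder"))
  # beyond the strict threshold but within the near band
  expect_equal(classify(-0.3, 0.7, -0.72)$label, "near_adder")
  # equidistant between adder and sizer
  expect_equal(classify(-0.6, 0.45, -1)$label, "indeterminate")
  expect_error(classify(0, NULL, -1), "missing diagnostic")
})

test_that("classification is deterministic and order-invariant", {
  sim <- simulate_lineages(small_cfg(), seed = 17)
  cyc <- extract_cycles(sim)
  fit3 <- function(records) {
    classify(
      fit_diagnostic(records, "dS_vs_x", n_bootstrap = 0),
      fit_diagnostic(records, "Scyt_vs_x", n_bootstrap = 0),
      fit_diagnostic(records, "logT_vs_logx", n_bootstrap = 0)
    )
  }
  a <- fit3(cyc)
  set.seed(99)
  b <- fit3(cyc[sample(nrow(cyc)), ])
  expect_equal(b$slopes, a$slopes, tolerance = 1e-12)
  expect_identical(b$label, a$label)
})

test_that("mitotic-duration diagnostic separates clock from size scaling", {
  sim <- simulate_lineages(small_cfg(), seed = 19)
  cyc <- extract_cycles(sim)
  d <- mitotic_duration_diagnostic(cyc, n_bootstrap = 200, seed = 1)
  expect_equal(d$slope, 0, tolerance = 1e-12) # constant mitotic clock
  expect_lte(d$ci_low, 1e-12)
  expect_gte(d$ci_high, -1e-12)

  # duration proportional to size: log-log slope exactly 1
  prop <- data.frame(S_cytokinesis = seq(300, 900, length.out = 20))
  prop$T_mitotic <- 0.02 * prop$S_cytokinesis
  d1 <- mitotic_duration_diagnostic(prop, n_bootstrap = 0)
  expect_equal(d1$slope, 1, tolerance = 1e-9)

  zero <- data.frame(S_cytokinesis = seq(300, 900, length.out = 20),
                     T_mitotic = 0)
  expect_error(mitotic_duration_diagnostic(zero, n_bootstrap = 0),
               "non-positive")
})
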