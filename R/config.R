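#' Simulation configuration for the cell-surface-area lineage simulator
#'
#' Builds and validates the full parameter set of the lineage simulator:
#' the division-control regime, the growth and division arithmetic, the
#' membrane-flux (phagocytosis) rates, the noise magnitudes, and the run
#' geometry (number of lineages, generations, seed).
#'
#' Defaults are calibrated to single-cell measurements of amoeboid cells
#' growing on bacteria: mean birth surface area `C_ave = 400` um^2, mean
#' birth-to-birth generation time `T_ave = 3.87` h with CV about 0.30, a
#' slight (3\%) metaphase shrinkage followed by a 20\% surface gain during
#' cytokinesis, near-symmetric division (mean percent deviation of the
#' larger/smaller sibling ratio about 7.02), and Poisson phagocytosis at
#' 19.1 events per 10 min in interphase versus 1.53 per 10 min in mitosis,
#' each event internalizing `a_bact = 9` um^2 of membrane.
#'
#' The growth constant defaults to `log(2) / (60 * T_ave - m_duration)`
#' per minute, so that interphase doubles the area and the full cycle
#' (interphase plus the fixed mitotic phase) averages `T_ave` hours.
#'
#' `delta_post`, the post-abscission area factor, defaults to the value
#' returned by [calibrate_delta_post()], which makes the whole-division
#' multiplicative chain `delta_post * g_cyto * (1 - eps_meta)` equal 1 so
#' that birth areas are stationary at `C_ave` under the adder regime.
#'
#' @param regime division-control regime: `"adder"`, `"sizer"`, `"timer"`,
#'   or `"dynamic_adder"` (adder control plus explicit exocytosis /
#'   endocytosis bookkeeping).
#' @param C_ave mean cell surface area at birth, um^2.
#' @param T_ave mean generation time, hours.
#' @param m_duration duration of the mitotic phase (cell rounding to
#'   abscission), minutes; identical for all cells regardless of size.
#' @param m_meta metaphase (rounding) sub-duration, minutes; the remainder
#'   `m_duration - m_meta` is cytokinesis.
#' @param k exponential growth-rate constant, per minute.
#' @param dt simulation time step, minutes.
#' @param eps_meta fractional area decrease over metaphase.
#' @param g_cyto multiplicative area gain factor over cytokinesis (> 1);
#'   the default 1.20 is the observed ~20\% gain.
#' @param delta_post post-abscission area factor applied to the
#'   pre-abscission area; `NULL` (default) derives it with
#'   [calibrate_delta_post()].
#' @param sigma_target SD of the division-control target as a fraction of
#'   its mean.
#' @param sigma_k CV of the per-cycle lognormal growth-rate multiplier;
#'   default 1.15/3.87 matches the observed generation-time CV.
#' @param sigma_asym scale of the half-normal sibling-asymmetry noise on
#'   (ratio - 1); the default makes the mean percent deviation 7.02.
#' @param sigma_birth0 SD (fraction of `C_ave`) of founder birth areas.
#' @param lambda_phago_I phagocytosis rate in interphase, events/min.
#' @param lambda_phago_M phagocytosis rate in mitosis, events/min.
#' @param a_bact membrane area internalized per phagocytic event, um^2.
#' @param n_lineages number of independent lineage trees.
#' @param n_generations number of generations simulated per tree (founders
#'   are generation 0; cells of generation `n_generations` are recorded at
#'   birth but not followed).
#' @param follow `"both"` tracks both daughters after every division (a
#'   full binary tree); `"one"` follows a single randomly chosen daughter
#'   (the other still receives a birth sample), emulating single-cell
#'   following over many generations.
#' @param seed default integer seed used by [simulate_lineages()].
#'
#' @return An object of class `"sim_config"`: a named list of validated
#'   parameters (plus the derived fields `m_cyto` and `sdlog_k`).
#' @seealso [simulate_lineages()], [calibrate_delta_post()]
#' @examples
#' cfg <- sim_config(regime = "adder", n_lineages = 2, n_generations = 3)
#' cfg$k * 60  # growth constant per hour
#' @export
sim_config <- function(regime = c("adder", "sizer", "timer", "dynamic_adder"),
                       C_ave = 400,
                       T_ave = 3.87,
                       m_duration = 15,
                       m_meta = 5,
                       k = log(2) / (60 * T_ave - m_duration),
                       dt = 1,
                       eps_meta = 0.03,
                       g_cyto = 1.20,
                       delta_post = NULL,
                       sigma_target = 0.15,
                       sigma_k = 1.15 / 3.87,
                       sigma_asym = 0.0702 * sqrt(pi / 2),
                       sigma_birth0 = 0.10,
                       lambda_phago_I = 1.91,
                       lambda_phago_M = 0.153,
                       a_bact = 9.0,
                       n_lineages = 5L,
                       n_generations = 4L,
                       follow = c("both", "one"),
                       seed = 1L) {
  regime <- match.arg(regime)
  follow <- match.arg(follow)
  if (is.null(delta_post)) {
    delta_post <- calibrate_delta_post(g_cyto = g_cyto, eps_meta = eps_meta)
  }
  cfg <- list(
    regime = regime, C_ave = C_ave, T_ave = T_ave,
    m_duration = m_duration, m_meta = m_meta, m_cyto = m_duration - m_meta,
    k = k, dt = dt,
    eps_meta = eps_meta, g_cyto = g_cyto, delta_post = delta_post,
    sigma_target = sigma_target, sigma_k = sigma_k,
    sigma_asym = sigma_asym, sigma_birth0 = sigma_birth0,
    lambda_phago_I = lambda_phago_I, lambda_phago_M = lambda_phago_M,
    a_bact = a_bact,
    n_lineages = as.integer(n_lineages),
    n_generations = as.integer(n_generations),
    follow = follow,
    seed = as.integer(seed)
  )
  # lognormal growth-rate multiplier: sdlog from the CV, meanlog such that
  # E[1/multiplier] = 1 so mean generation times are unbiased
  cfg$sdlog_k <- sqrt(log(1 + sigma_k^2))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Derive the post-abscission area factor that makes birth areas stationary
#'
#' The division arithmetic multiplies the pre-mitosis area by
#' `(1 - eps_meta)` over metaphase, by `g_cyto` over cytokinesis, and by
#' `delta_post` at abscission.  With the adder control (mean added area
#' `C_ave`) the deterministic birth-to-birth map is
#' `x' = f_M * (x + C_ave) / 2` with `f_M = delta_post * g_cyto * (1 -
#' eps_meta)`, whose fixed point equals `C_ave` exactly when `f_M = 1`.
#' This returns `1 / (g_cyto * (1 - eps_meta))`.
#'
#' @param g_cyto cytokinesis gain factor.
#' @param eps_meta metaphase shrink fraction.
#' @return The calibrated `delta_post` (about 0.859 at the defaults).
#' @examples
#' calibrate_delta_post(1.20, 0.03)
#' @export
calibrate_delta_post <- function(g_cyto = 1.20, eps_meta = 0.03) {
  stopifnot(g_cyto > 1, eps_meta >= 0, eps_meta < 1)
  1 / (g_cyto * (1 - eps_meta))
}

#' Validate a simulation configuration
#'
#' Checks all invariants of a [sim_config()] object and stops with an
#' informative message on the first violation.  Returns the object
#' invisibly so it can be used in pipelines.
#'
#' @param cfg a `"sim_config"` object (or a plain list with its fields).
#' @return `cfg`, invisibly.
#' @export
validate_sim_config <- function(cfg) {
  chk <- function(ok, msg) if (!isTRUE(ok)) stop("invalid configuration: ", msg, call. = FALSE)
  chk(cfg$regime %in% c("adder", "sizer", "timer", "dynamic_adder"),
      sprintf("unknown regime '%s'", cfg$regime))
  for (f in c("C_ave", "T_ave", "k", "dt", "g_cyto", "a_bact",
              "m_duration", "m_meta", "m_cyto")) {
    chk(is.numeric(cfg[[f]]) && length(cfg[[f]]) == 1 && is.finite(cfg[[f]]) && cfg[[f]] > 0,
        sprintf("'%s' must be a single positive number", f))
  }
  for (f in c("sigma_target", "sigma_k", "sigma_asym", "sigma_birth0",
              "lambda_phago_I", "lambda_phago_M")) {
    chk(is.numeric(cfg[[f]]) && length(cfg[[f]]) == 1 && is.finite(cfg[[f]]) && cfg[[f]] >= 0,
        sprintf("'%s' must be a single non-negative number", f))
  }
  chk(cfg$eps_meta >= 0 && cfg$eps_meta < 1, "'eps_meta' must lie in [0, 1)")
  chk(cfg$g_cyto > 1, "'g_cyto' must exceed 1")
  chk(cfg$delta_post > 0 && cfg$delta_post < 1.5,
      "'delta_post' must lie in (0, 1.5)")
  chk(cfg$dt <= cfg$m_duration / 3,
      "'dt' must not exceed m_duration/3 (the mitotic path needs >= 3 samples)")
  chk(abs(cfg$m_meta / cfg$dt - round(cfg$m_meta / cfg$dt)) < 1e-9 &&
        abs(cfg$m_cyto / cfg$dt - round(cfg$m_cyto / cfg$dt)) < 1e-9,
      "'dt' must divide both mitotic sub-durations")
  chk(cfg$n_lineages >= 0, "'n_lineages' must be non-negative")
  chk(cfg$n_generations >= 0, "'n_generations' must be non-negative")
  chk(cfg$follow %in% c("both", "one"), "'follow' must be 'both' or 'one'")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Lineage simulation configuration\n")
  cat(sprintf("  regime        : %s\n", x$regime))
  cat(sprintf("  C_ave / T_ave : %.4g um^2 / %.4g h\n", x$C_ave, x$T_ave))
  cat(sprintf("  growth k      : %.6g /min (doubling over %.1f min)\n",
              x$k, log(2) / x$k))
  cat(sprintf("  mitosis       : %g min (%g metaphase + %g cytokinesis), eps_meta=%.3g, g_cyto=%.3g, delta_post=%.4g\n",
              x$m_duration, x$m_meta, x$m_cyto, x$eps_meta, x$g_cyto, x$delta_post))
  cat(sprintf("  noise         : sigma_target=%.3g, sigma_k(CV)=%.3g, sigma_asym=%.4g\n",
              x$sigma_target, x$sigma_k, x$sigma_asym))
  cat(sprintf("  phagocytosis  : %.3g /min interphase, %.3g /min mitosis, %.3g um^2/event\n",
              x$lambda_phago_I, x$lambda_phago_M, x$a_bact))
  cat(sprintf("  run           : %d lineage(s) x %d generation(s), follow=%s, seed=%d\n",
              x$n_lineages, x$n_generations, x$follow, x$seed))
  invisible(x)
}

# Fields permitted in an on-disk config document (m_cyto and sdlog_k are
# derived, seed/follow are part of the surface).
config_file_fields <- function() {
  c("regime", "C_ave", "T_ave", "m_duration", "m_meta", "k", "dt",
    "eps_meta", "g_cyto", "delta_post", "sigma_target", "sigma_k",
    "sigma_asym", "sigma_birth0", "lambda_phago_I", "lambda_phago_M",
    "a_bact", "n_lineages", "n_generations", "follow", "seed")
}
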