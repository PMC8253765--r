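#' Create a cell state
#'
#' A cell state is the minimal per-cell bookkeeping carried through a
#' cycle: identity, clock, current surface area, birth area, phase,
#' cumulative gross membrane fluxes, the per-cycle growth constant and the
#' regime-specific division-control target.
#'
#' @param S_birth surface area at birth, um^2.
#' @param config a [sim_config()] object.
#' @param t_birth birth time, minutes.
#' @param k_cell per-cycle growth constant (defaults to `config$k`).
#' @param control_target regime-specific division threshold; by default
#'   drawn with [draw_control_target()] (consumes random numbers).
#' @param cell_id,lineage_id,generation identity fields.
#' @return A list of class `"cell_state"`.
#' @export
new_cell_state <- function(S_birth, config, t_birth = 0,
                           k_cell = config$k,
                           control_target = draw_control_target(config, S_birth),
                           cell_id = "L1.C1", lineage_id = 1L,
                           generation = 0L) {
  stopifnot(is.finite(S_birth), S_birth > 0)
  structure(list(
    cell_id = cell_id, lineage_id = lineage_id, generation = generation,
    t = t_birth, t_birth = t_birth,
    S = S_birth, S_birth = S_birth,
    phase = "interphase",
    cum_exo = 0, cum_endo = 0,
    k_cell = k_cell,
    control_target = control_target
  ), class = "cell_state")
}

#' Draw a division-control target for a newborn cell
#'
#' The target is sampled at birth from a normal distribution whose mean is
#' set by the regime and whose SD is `sigma_target` times that mean:
#' * adder / dynamic adder: target added area, mean `C_ave`; division when
#'   `S - S_birth >= target`.
#' * sizer: target absolute area, mean `2 * C_ave`; division when
#'   `S >= target`.
#' * timer: target interphase duration, mean `60 * T_ave - m_duration`
#'   minutes (so the full generation time averages `T_ave` hours);
#'   division when `t - t_birth >= target`.
#'
#' Draws are truncated below at 5\% of the mean to keep targets positive.
#'
#' @param config a [sim_config()] object.
#' @param S_birth birth area (unused by the current regimes; kept so
#'   size-dependent control rules can be added without changing callers).
#' @return A single positive number (um^2 for adder/sizer, minutes for
#'   timer).
#' @export
draw_control_target <- function(config, S_birth = config$C_ave) {
  mu <- switch(config$regime,
    adder = ,
    dynamic_adder = config$C_ave,
    sizer = 2 * config$C_ave,
    timer = 60 * config$T_ave - config$m_duration,
    stop("unknown regime '", config$regime, "'", call. = FALSE)
  )
  max(stats::rnorm(1L, mu, config$sigma_target * mu), 0.05 * mu)
}

#' Advance a cell through one interphase step of exponential growth
#'
#' Interphase growth is deterministic exponential at the cell's per-cycle
#' constant: `S <- S * exp(k_cell * dt)`.
#'
#' @param state a `"cell_state"`.
#' @param dt step duration, minutes (> 0).
#' @param config a [sim_config()] object (unused by the growth law itself;
#'   accepted for interface symmetry with the other step operations).
#' @return The advanced `"cell_state"`.
#' @export
step_interphase <- function(state, dt, config = NULL) {
  stopifnot(identical(state$phase, "interphase"), dt >= 0)
  S_new <- state$S * exp(state$k_cell * dt)
  if (!is.finite(S_new)) {
    stop(sprintf("simulation error: non-finite area for cell %s at t = %g min",
                 state$cell_id, state$t + dt), call. = FALSE)
  }
  state$S <- S_new
  state$t <- state$t + dt
  state
}

#' Test whether a cell's division criterion is met
#'
#' Applies the regime rule to the current state: adder / dynamic adder
#' divide when the added area `S - S_birth` reaches the control target,
#' sizer when the absolute area `S` reaches it, timer when the elapsed
#' interphase time reaches it.
#'
#' @param state a `"cell_state"` in interphase.
#' @param config a [sim_config()] object.
#' @return `TRUE` exactly when the criterion is met.
#' @export
division_trigger <- function(state, config) {
  stopifnot(identical(state$phase, "interphase"))
  switch(config$regime,
    adder = ,
    dynamic_adder = (state$S - state$S_birth) >= state$control_target,
    sizer = state$S >= state$control_target,
    timer = (state$t - state$t_birth) >= state$control_target,
    stop("unknown regime '", config$regime, "'", call. = FALSE)
  )
}

#' Advance the gross membrane fluxes over one step (dynamic adder)
#'
#' Draws the number of phagocytic events in the step from a Poisson
#' distribution with rate `lambda_phago_I` (interphase) or
#' `lambda_phago_M` (mitotic phases) per minute -- the rate does not
#' depend on cell size.  Each event internalizes `a_bact` um^2 of
#' membrane (endocytic flux); the exocytic flux is the endocytic flux
#' plus the net area change of the step, so the net trajectory equals the
#' non-flux regimes' trajectory:
#' `cum_endo += n * a_bact`, `cum_exo += n * a_bact + dS_step`.
#'
#' @param state a `"cell_state"`.
#' @param dt step duration, minutes (0 allowed: no events, no change).
#' @param config a [sim_config()] object with non-negative rates.
#' @param dS_step the net area change of this step; by default the
#'   interphase growth increment `S * (exp(k_cell * dt) - 1)`.
#' @return The state with `cum_exo` and `cum_endo` advanced (area and
#'   clock are advanced by [step_interphase()], not here).
#' @export
simulate_fluxes <- function(state, dt, config,
                            dS_step = state$S * (exp(state$k_cell * dt) - 1)) {
  if (config$lambda_phago_I < 0 || config$lambda_phago_M < 0) {
    stop("invalid configuration: negative phagocytosis rate", call. = FALSE)
  }
  stopifnot(dt >= 0)
  lambda <- if (identical(state$phase, "interphase")) {
    config$lambda_phago_I
  } else {
    config$lambda_phago_M
  }
  n <- if (dt > 0) stats::rpois(1L, lambda * dt) else 0L
  state$cum_endo <- state$cum_endo + n * config$a_bact
  state$cum_exo <- state$cum_exo + n * config$a_bact + dS_step
  state
}

#' Simulate independent phagocytosis observation windows
#'
#' Steps the Poisson phagocytosis process over `n_windows` independent
#' windows of `duration` minutes each, at the configured per-minute rate
#' for the given phase, and returns the event count per window.  This is
#' the in-silico analogue of counting internalized bacteria after a fixed
#' feeding window.
#'
#' @param n_windows number of windows.
#' @param duration window length, minutes.
#' @param config a [sim_config()] object.
#' @param phase `"interphase"` or `"mitosis"`.
#' @return Integer vector of length `n_windows`.
#' @examples
#' cfg <- sim_config()
#' set.seed(1)
#' mean(simulate_phago_windows(87, 10, cfg))  # about 19.1
#' @export
simulate_phago_windows <- function(n_windows, duration, config,
                                   phase = c("interphase", "mitosis")) {
  phase <- match.arg(phase)
  stopifnot(n_windows >= 1, duration > 0)
  lambda <- if (phase == "interphase") config$lambda_phago_I else config$lambda_phago_M
  n_steps <- max(1L, as.integer(round(duration / config$dt)))
  counts <- stats::rpois(n_windows * n_steps, lambda * (duration / n_steps))
  as.integer(rowSums(matrix(counts, nrow = n_windows, byrow = TRUE)))
}

# --- mitotic arithmetic -----------------------------------------------------

# Deterministic M-phase chain from the pre-mitosis area:
#   metaphase:   linear descent to S_meta = (1 - eps_meta) * S_premitosis
#   cytokinesis: linear ascent to  S_cyt  = g_cyto * S_meta
#   abscission:  S_post = delta_post * S_cyt, split r/(1+r) : 1/(1+r)
# Returns the sampled path (excluding the trigger sample itself) and the
# division quantities.
mitosis_chain <- function(S_premitosis, r, config) {
  if (config$delta_post <= 0 || config$delta_post >= 1.5) {
    stop("invalid configuration: 'delta_post' must lie in (0, 1.5)", call. = FALSE)
  }
  stopifnot(r >= 1)
  n_meta <- as.integer(round(config$m_meta / config$dt))
  n_cyt <- as.integer(round(config$m_cyto / config$dt))
  S_meta_path <- S_premitosis * (1 - config$eps_meta * seq_len(n_meta) / n_meta)
  S_meta <- S_meta_path[n_meta]
  S_cyt_path <- S_meta * (1 + (config$g_cyto - 1) * seq_len(n_cyt) / n_cyt)
  S_cyt <- S_cyt_path[n_cyt]
  S_post <- config$delta_post * S_cyt
  d1 <- S_post * r / (1 + r)
  d2 <- S_post - d1 # exact complement: daughters sum to S_post exactly
  list(
    S_path = c(S_meta_path, S_cyt_path),
    phase = c(rep("metaphase", n_meta), rep("cytokinesis", n_cyt)),
    S_meta = S_meta, S_cyt = S_cyt, S_post = S_post,
    daughter_areas = c(d1, d2), sibling_ratio = d1 / d2
  )
}

#' Execute a division: M-phase arithmetic and daughter creation
#'
#' Runs the mitotic arithmetic chain from the triggering (pre-mitosis)
#' area -- a linear descent to `(1 - eps_meta)` of it over metaphase, a
#' linear ascent to `g_cyto` times the metaphase area over cytokinesis,
#' then an instantaneous drop to `delta_post` times the pre-abscission
#' area -- and splits the result between two daughters with sibling ratio
#' `r >= 1` drawn as `1 + |N(0, sigma_asym)|` (half-normal).  The mitotic
#' duration is `m_duration` for every cell regardless of size.
#'
#' @param state a `"cell_state"` whose division criterion has been met.
#' @param config a [sim_config()] object.
#' @param r sibling ratio (larger/smaller); drawn by default.
#' @param daughter_ids character ids for the two daughters.
#' @return A list with elements `daughter1`, `daughter2` (new
#'   `"cell_state"`s, larger first; their control targets are drawn,
#'   consuming random numbers), `event` (a one-row `data.frame` division
#'   event) and `path` (a `data.frame` of the sampled mitotic trajectory:
#'   `time_min`, `area_um2`, `phase`).
#' @examples
#' cfg <- sim_config(sigma_asym = 0, sigma_target = 0)
#' st <- new_cell_state(400, cfg, control_target = 400)
#' st$S <- 800
#' div <- apply_division(st, cfg, r = 1)
#' div$event$S_cyt / div$event$S_meta  # the 20% cytokinesis gain
#' @export
apply_division <- function(state, config,
                           r = 1 + abs(stats::rnorm(1L, 0, config$sigma_asym)),
                           daughter_ids = paste0(state$cell_id, c(".1", ".2"))) {
  mc <- mitosis_chain(state$S, r, config)
  n_m <- length(mc$S_path)
  t_path <- state$t + config$dt * seq_len(n_m)
  t_absc <- t_path[n_m]
  mk_daughter <- function(S0, id) {
    new_cell_state(S0, config,
      t_birth = t_absc,
      k_cell = config$k, # overwritten by the lineage engine
      cell_id = id, lineage_id = state$lineage_id,
      generation = state$generation + 1L
    )
  }
  d1 <- mk_daughter(mc$daughter_areas[1], daughter_ids[1])
  d2 <- mk_daughter(mc$daughter_areas[2], daughter_ids[2])
  event <- data.frame(
    t = t_absc, lineage_id = state$lineage_id, mother_id = state$cell_id,
    generation = state$generation,
    S_premitosis = state$S, S_meta = mc$S_meta, S_cyt = mc$S_cyt,
    S_post = mc$S_post,
    daughter1_id = daughter_ids[1], daughter2_id = daughter_ids[2],
    daughter1_area = mc$daughter_areas[1], daughter2_area = mc$daughter_areas[2],
    sibling_ratio = mc$sibling_ratio,
    stringsAsFactors = FALSE
  )
  list(
    daughter1 = d1, daughter2 = d2, event = event,
    path = data.frame(time_min = t_path, area_um2 = mc$S_path,
                      phase = mc$phase, stringsAsFactors = FALSE)
  )
}

# --- lineage engine ---------------------------------------------------------

# One complete cycle, vectorized over the time grid.  Consumes random
# numbers in a fixed, documented order:
#   1. growth-rate multiplier  2. control target
#   3. phagocytosis counts (dynamic_adder only; interphase then mitosis)
#   4. sibling asymmetry
# Returns the per-sample trajectory columns plus the division event.
sim_cycle <- function(x, t0, cfg, lineage_id, cell_id, mother_gen_id) {
  m <- exp(stats::rnorm(1L, cfg$sdlog_k^2 / 2, cfg$sdlog_k))
  k_cell <- cfg$k * m
  tgt <- draw_control_target(cfg, x)
  n_int <- switch(cfg$regime,
    adder = ,
    dynamic_adder = ceiling(log1p(tgt / x) / (k_cell * cfg$dt)),
    sizer = ceiling(log(max(tgt / x, 1)) / (k_cell * cfg$dt)),
    timer = ceiling(tgt / cfg$dt)
  )
  n_int <- max(1L, as.integer(n_int))
  S_int <- x * exp(k_cell * cfg$dt * (0:n_int))
  S_pre <- S_int[n_int + 1L]
  if (!all(is.finite(S_int))) {
    stop(sprintf("simulation error: non-finite area for cell %s", cell_id),
         call. = FALSE)
  }
  if (S_pre > 100 * cfg$C_ave) {
    stop(sprintf(paste0(
      "runaway cell size under the '%s' regime: cell %s reached %.3g um^2 ",
      "(> 100 * C_ave); expected for timer control with exponential growth"),
      cfg$regime, cell_id, S_pre), call. = FALSE)
  }
  n_meta <- as.integer(round(cfg$m_meta / cfg$dt))
  n_cyt <- as.integer(round(cfg$m_cyto / cfg$dt))
  n_mit <- n_meta + n_cyt
  S_meta_path <- S_pre * (1 - cfg$eps_meta * seq_len(n_meta) / n_meta)
  S_meta <- S_meta_path[n_meta]
  S_cyt_path <- S_meta * (1 + (cfg$g_cyto - 1) * seq_len(n_cyt) / n_cyt)
  S_cyt <- S_cyt_path[n_cyt]
  S_all <- c(S_int, S_meta_path, S_cyt_path)
  n_all <- length(S_all)
  if (cfg$regime == "dynamic_adder") {
    counts <- stats::rpois(n_all - 1L,
      c(rep(cfg$lambda_phago_I, n_int), rep(cfg$lambda_phago_M, n_mit)) * cfg$dt)
    endo_inc <- counts * cfg$a_bact
    exo_inc <- endo_inc + diff(S_all)
    cum_endo <- c(0, cumsum(endo_inc))
    cum_exo <- c(0, cumsum(exo_inc))
  } else {
    cum_endo <- cum_exo <- numeric(n_all)
  }
  r <- 1 + abs(stats::rnorm(1L, 0, cfg$sigma_asym))
  S_post <- cfg$delta_post * S_cyt
  d1 <- S_post * r / (1 + r)
  d2 <- S_post - d1
  tt <- t0 + cfg$dt * (0:(n_all - 1L))
  list(
    traj = list(
      lineage_id = rep.int(lineage_id, n_all),
      cell_id = rep.int(cell_id, n_all),
      parent_id = rep.int(mother_gen_id$parent, n_all),
      generation = rep.int(mother_gen_id$gen, n_all),
      time_min = tt,
      area_um2 = S_all,
      phase = c(rep("interphase", n_int + 1L),
                rep("metaphase", n_meta), rep("cytokinesis", n_cyt)),
      cum_exo_um2 = cum_exo,
      cum_endo_um2 = cum_endo
    ),
    t_absc = tt[n_all],
    daughter_areas = c(d1, d2),
    event = list(
      t = tt[n_all], lineage_id = lineage_id, mother_id = cell_id,
      generation = mother_gen_id$gen,
      S_premitosis = S_pre, S_meta = S_meta, S_cyt = S_cyt, S_post = S_post,
      daughter1_area = d1, daughter2_area = d2, sibling_ratio = d1 / d2
    )
  )
}

#' Simulate lineage trees of total cell surface area
#'
#' Generates `n_lineages` independent lineage trees, each started from a
#' founder (generation 0) with birth area drawn from
#' `Normal(C_ave, sigma_birth0 * C_ave)`, and followed for
#' `n_generations` generations under the configured division-control
#' regime.  Cells grow exponentially through interphase at a per-cycle
#' noisy rate, divide through the fixed-duration mitotic arithmetic chain
#' (metaphase shrink, cytokinesis gain, post-abscission drop, near-even
#' split), and -- under the dynamic-adder regime -- carry explicit gross
#' exocytosis/endocytosis flux bookkeeping driven by Poisson
#' phagocytosis.
#'
#' Reproducibility: all randomness flows from `seed`.  A per-lineage
#' sub-seed is drawn up front (`sample.int` after `set.seed(seed)`), and
#' each lineage is simulated under its own stream with cells processed in
#' breadth-first birth order, so adding lineages does not reorder the
#' draws of existing ones.
#'
#' @param config a [sim_config()] object.
#' @param seed integer seed; defaults to `config$seed`.
#' @return An object of class `"cell_lineages"`: a list with
#'   * `trajectories`: `data.frame` with one row per 1-min sample and
#'     columns `lineage_id`, `cell_id`, `parent_id`, `generation`,
#'     `time_min`, `area_um2`, `phase`, `cum_exo_um2`, `cum_endo_um2`;
#'   * `events`: `data.frame` with one row per division;
#'   * `config`, `seed`.
#' @examples
#' sim <- simulate_lineages(sim_config(n_lineages = 1, n_generations = 2))
#' nrow(sim$events)  # 3 divisions: founder + two daughters
#' @export
simulate_lineages <- function(config, seed = config$seed) {
  validate_sim_config(config)
  if (config$n_lineages < 1) {
    stop("'n_lineages' must be at least 1 to simulate", call. = FALSE)
  }
  set.seed(as.integer(seed))
  lin_seeds <- sample.int(2147483646L, config$n_lineages)
  traj_parts <- vector("list", config$n_lineages)
  event_parts <- vector("list", config$n_lineages)
  for (li in seq_len(config$n_lineages)) {
    set.seed(lin_seeds[li])
    res <- sim_one_lineage(li, config)
    traj_parts[[li]] <- res$traj
    event_parts[[li]] <- res$events
  }
  traj <- do.call(rbind, traj_parts)
  events <- do.call(rbind, event_parts)
  if (is.null(events)) {
    events <- empty_events()
  }
  rownames(traj) <- NULL
  rownames(events) <- NULL
  structure(list(trajectories = traj, events = events,
                 config = config, seed = as.integer(seed)),
            class = "cell_lineages")
}

empty_events <- function() {
  data.frame(
    t = numeric(0), lineage_id = integer(0), mother_id = character(0),
    generation = integer(0), S_premitosis = numeric(0), S_meta = numeric(0),
    S_cyt = numeric(0), S_post = numeric(0),
    daughter1_id = character(0), daughter2_id = character(0),
    daughter1_area = numeric(0), daughter2_area = numeric(0),
    sibling_ratio = numeric(0), stringsAsFactors = FALSE
  )
}

sim_one_lineage <- function(li, cfg) {
  x0 <- max(stats::rnorm(1L, cfg$C_ave, cfg$sigma_birth0 * cfg$C_ave),
            0.05 * cfg$C_ave)
  counter <- 0L
  next_id <- function() {
    counter <<- counter + 1L
    sprintf("L%d.C%d", li, counter)
  }
  queue <- list(list(id = next_id(), parent = NA_character_, gen = 0L,
                     t0 = 0, x = x0))
  traj_cols <- list()
  events <- list()
  while (length(queue) > 0L) {
    cell <- queue[[1L]]
    queue <- queue[-1L]
    if (cell$gen >= cfg$n_generations) {
      # terminal cell: record its birth sample only
      traj_cols[[length(traj_cols) + 1L]] <- list(
        lineage_id = li, cell_id = cell$id, parent_id = cell$parent,
        generation = cell$gen, time_min = cell$t0, area_um2 = cell$x,
        phase = "interphase", cum_exo_um2 = 0, cum_endo_um2 = 0
      )
      next
    }
    cyc <- sim_cycle(cell$x, cell$t0, cfg, li, cell$id,
                     list(parent = cell$parent, gen = cell$gen))
    traj_cols[[length(traj_cols) + 1L]] <- cyc$traj
    ids <- c(next_id(), next_id())
    ev <- cyc$event
    ev$daughter1_id <- ids[1]
    ev$daughter2_id <- ids[2]
    events[[length(events) + 1L]] <- ev
    daughters <- list(
      list(id = ids[1], parent = cell$id, gen = cell$gen + 1L,
           t0 = cyc$t_absc, x = cyc$daughter_areas[1]),
      list(id = ids[2], parent = cell$id, gen = cell$gen + 1L,
           t0 = cyc$t_absc, x = cyc$daughter_areas[2])
    )
    if (cfg$follow == "both") {
      queue <- c(queue, daughters)
    } else {
      pick <- sample.int(2L, 1L)
      # the untracked sibling still receives a birth-only sample so that
      # sibling ratios remain extractable from the trajectory table
      queue <- c(queue, daughters[pick])
      other <- daughters[[3L - pick]]
      traj_cols[[length(traj_cols) + 1L]] <- list(
        lineage_id = li, cell_id = other$id, parent_id = other$parent,
        generation = other$gen, time_min = other$t0, area_um2 = other$x,
        phase = "interphase", cum_exo_um2 = 0, cum_endo_um2 = 0
      )
    }
  }
  nm <- c("lineage_id", "cell_id", "parent_id", "generation", "time_min",
          "area_um2", "phase", "cum_exo_um2", "cum_endo_um2")
  traj <- as.data.frame(
    stats::setNames(lapply(nm, function(f) {
      unlist(lapply(traj_cols, `[[`, f), use.names = FALSE)
    }), nm),
    stringsAsFactors = FALSE
  )
  ev_df <- if (length(events) > 0L) {
    do.call(rbind, lapply(events, function(e) {
      as.data.frame(e, stringsAsFactors = FALSE)
    }))
  } else {
    NULL
  }
  if (!is.null(ev_df)) {
    ev_df <- ev_df[c("t", "lineage_id", "mother_id", "generation",
                     "S_premitosis", "S_meta", "S_cyt", "S_post",
                     "daughter1_id", "daughter2_id",
                     "daughter1_area", "daughter2_area", "sibling_ratio")]
  }
  list(traj = traj, events = ev_df)
}

#' @export
print.cell_lineages <- function(x, ...) {
  cat("Simulated cell lineages\n")
  cat(sprintf("  regime: %s, seed: %d\n", x$config$regime, x$seed))
  cat(sprintf("  %d lineage(s), %d cell(s), %d division(s), %d samples\n",
              length(unique(x$trajectories$lineage_id)),
              length(unique(x$trajectories$cell_id)),
              nrow(x$events), nrow(x$trajectories)))
  invisible(x)
}
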