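# Shared fixtures: all synthetic inputs are generated in code.

# small calibrated run (default noise), ~45 completed cycles
small_cfg <- function(...) {
  sim_config(n_lineages = 3L, n_generations = 4L, ...)
}

# noise switched off: deterministic growth, symmetric division,
# exact control targets (any field can still be overridden)
noiseless_cfg <- function(...) {
  args <- utils::modifyList(
    list(sigma_target = 0, sigma_k = 0, sigma_asym = 0, sigma_birth0 = 0),
    list(...)
  )
  do.call(sim_config, args)
}

# hand-built labeled trajectory for one cell growing S(t) over t_int
# minutes of interphase followed by a canned 15-min mitosis
synthetic_cell_traj <- function(cell_id, S_fun, t_int = 100,
                                parent_id = NA_character_,
                                lineage_id = 1L, generation = 0L,
                                with_mitosis = TRUE) {
  t <- 0:t_int
  S <- S_fun(t)
  phase <- rep("interphase", length(t))
  if (with_mitosis) {
    S_pre <- S[length(S)]
    S_meta <- S_pre * (1 - 0.03 * (1:5) / 5)
    S_cyt <- S_meta[5] * (1 + 0.20 * (1:10) / 10)
    t <- c(t, t_int + 1:15)
    S <- c(S, S_meta, S_cyt)
    phase <- c(phase, rep("metaphase", 5), rep("cytokinesis", 10))
  }
  data.frame(
    lineage_id = lineage_id, cell_id = cell_id, parent_id = parent_id,
    generation = generation, time_min = t, area_um2 = S, phase = phase,
    cum_exo_um2 = 0, cum_endo_um2 = 0, stringsAsFactors = FALSE
  )
}
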