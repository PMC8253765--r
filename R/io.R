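# CSV serialization policy: numeric columns are written with 6 significant
# digits ('%.6g') so repeated runs produce byte-identical files.

format_num_cols <- function(df) {
  for (nm in names(df)) {
    if (is.numeric(df[[nm]])) {
      df[[nm]] <- sprintf("%.6g", df[[nm]])
    }
  }
  df
}

write_csv6 <- function(df, path) {
  utils::write.table(format_num_cols(df), path,
                     sep = ",", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

traj_columns <- function() {
  c("lineage_id", "cell_id", "parent_id", "generation", "time_min",
    "area_um2", "phase", "cum_exo_um2", "cum_endo_um2")
}

#' Write / read a trajectory table
#'
#' The trajectory CSV carries one row per time sample with columns
#' `lineage_id, cell_id, parent_id, generation, time_min, area_um2,
#' phase, cum_exo_um2, cum_endo_um2` (header required, UTF-8, `.` decimal
#' separator).  Numeric values are serialized with 6 significant digits.
#' Reading validates the schema and canonicalizes row order by
#' `(lineage_id, cell_id, time_min)`, so on-disk row order is
#' insignificant.
#'
#' @param x a trajectory `data.frame` or a `"cell_lineages"` object.
#' @param path file path.
#' @return `write_trajectories()` returns `path` invisibly;
#'   `read_trajectories()` returns the validated, sorted `data.frame`.
#' @export
write_trajectories <- function(x, path) {
  df <- if (inherits(x, "cell_lineages")) x$trajectories else x
  miss <- setdiff(traj_columns(), names(df))
  if (length(miss) > 0) {
    stop("trajectory table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  write_csv6(df[traj_columns()], path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(cell_id = "character",
                                       parent_id = "character"))
  miss <- setdiff(traj_columns(), names(df))
  if (length(miss) > 0) {
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df$parent_id[df$parent_id %in% c("", "NA")] <- NA_character_
  bad <- which(!is.finite(df$area_um2) | df$area_um2 <= 0)
  if (length(bad) > 0) {
    stop("non-positive area at data row ", bad[1], " of ", path, call. = FALSE)
  }
  df <- df[order(df$lineage_id, df$cell_id, df$time_min), , drop = FALSE]
  cid <- df$cell_id
  same <- cid[-1] == cid[-length(cid)]
  nm <- which(same & diff(df$time_min) <= 0)
  if (length(nm) > 0) {
    stop("non-monotone time within cell '", cid[nm[1] + 1L],
         "' at data row ", nm[1] + 1L, call. = FALSE)
  }
  rownames(df) <- NULL
  df
}

cycle_columns <- function() {
  c("lineage_id", "cell_id", "parent_id", "generation", "x", "S_premitosis",
    "S_cytokinesis", "S_preabscission", "dS_whole", "dS_interphase",
    "T_gen", "T_interphase", "T_mitotic", "dS_exo", "dS_endo",
    "sibling_ratio", "t_birth")
}

#' Write / read a cycle-record table
#'
#' One row per completed cell cycle, columns named exactly as the fields
#' of the cycle record (see [extract_cycles()]).
#'
#' @param x a `"cell_cycles"` table.
#' @param path file path.
#' @return `write_cycles()` returns `path` invisibly; `read_cycles()`
#'   returns a `"cell_cycles"` `data.frame`.
#' @export
write_cycles <- function(x, path) {
  df <- as.data.frame(x)
  miss <- setdiff(cycle_columns(), names(df))
  if (length(miss) > 0) {
    stop("cycle table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  write_csv6(df[cycle_columns()], path)
}

#' @rdname write_cycles
#' @export
read_cycles <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(cell_id = "character",
                                       parent_id = "character"))
  miss <- setdiff(cycle_columns(), names(df))
  if (length(miss) > 0) {
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df$parent_id[df$parent_id %in% c("", "NA")] <- NA_character_
  class(df) <- c("cell_cycles", "data.frame")
  df
}

#' Write / read a simulation configuration file
#'
#' The configuration file is a flat JSON document whose keys are exactly
#' the [sim_config()] field names; unknown keys are an error (catching
#' typos early), and missing keys fall back to the defaults.
#'
#' @param config a `"sim_config"` object.
#' @param path file path.
#' @return `write_sim_config()` returns `path` invisibly;
#'   `read_sim_config()` returns a validated `"sim_config"`.
#' @export
write_sim_config <- function(config, path) {
  fields <- config_file_fields()
  jsonlite::write_json(config[fields], path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(raw), config_file_fields())
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(sim_config, raw)
}

#' Run the full analysis pipeline and write all artifacts
#'
#' Executes simulate -> extract -> assess -> budget and writes, under
#' `out_dir`: `trajectories.csv`, `events.csv`, `cycles.csv`,
#' `assessment.json`, `budget.json` and `manifest.json`.  The manifest
#' records the configuration snapshot, the seed, the package version and
#' an MD5 digest of every output, so a rerun with the same configuration
#' and seed can be verified byte-for-byte (the manifest's own timestamp
#' aside).
#'
#' @param config a `"sim_config"` object.
#' @param out_dir output directory (created if absent).
#' @param seed integer seed; defaults to `config$seed`.
#' @param scope diagnostic scope for the assessment, `"whole"` or
#'   `"interphase"`.
#' @param n_bootstrap bootstrap replicates for the slope CIs.
#' @param quiet suppress the per-stage log lines.
#' @return Invisibly, a list with the in-memory `sim`, `cycles`,
#'   `assessment`, `budget` and the `manifest`.
#' @export
run_pipeline <- function(config, out_dir, seed = config$seed,
                         scope = c("whole", "interphase"),
                         n_bootstrap = 1000, quiet = FALSE) {
  scope <- match.arg(scope)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  sim <- stage("simulate", simulate_lineages(config, seed = seed))
  say("simulate: %d cells, %d divisions, %d samples",
      length(unique(sim$trajectories$cell_id)), nrow(sim$events),
      nrow(sim$trajectories))
  cycles <- stage("extract", extract_cycles(sim))
  say("extract: %d completed cycles", nrow(cycles))
  assessment <- stage("assess", {
    d1 <- fit_diagnostic(cycles, "dS_vs_x", scope, n_bootstrap, seed)
    d2 <- fit_diagnostic(cycles, "Scyt_vs_x", scope, n_bootstrap, seed)
    d3 <- fit_diagnostic(cycles, "logT_vs_logx", scope, n_bootstrap, seed)
    dm <- mitotic_duration_diagnostic(cycles, n_bootstrap = n_bootstrap,
                                      seed = seed)
    cl <- classify(d1, d2, d3)
    list(classification = cl, mitotic = dm)
  })
  say("assess: label '%s'", assessment$classification$label)
  # non-flux regimes carry no endocytosis bookkeeping; their budget uses
  # the configured uptake rate instead of simulated flux totals
  budget <- stage("budget", if (config$regime == "dynamic_adder") {
    budget_from_cycles(cycles)
  } else {
    membrane_budget(
      uptake_per_interval = config$lambda_phago_I * 10 * config$a_bact,
      interval = 10, duration = mean(cycles$T_interphase) * 60,
      total_area = mean(cycles$x),
      dS_net = mean(cycles$dS_interphase)
    )
  })
  say("budget: mean endocytosed %.4g um^2/cycle, refresh count %g",
      budget$dS_endo, budget$refresh_count)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, c("trajectories.csv", "events.csv",
                                "cycles.csv", "assessment.json",
                                "budget.json"))
  names(paths) <- c("trajectories", "events", "cycles", "assessment",
                    "budget")
  write_trajectories(sim, paths["trajectories"])
  write_csv6(sim$events, paths["events"])
  write_cycles(cycles, paths["cycles"])
  cl <- assessment$classification
  assessment_json <- list(
    label = cl$label,
    slopes = as.list(cl$slopes),
    distances = as.list(cl$distances),
    diagnostics = lapply(
      stats::setNames(cl$diagnostics, c("dS_vs_x", "Scyt_vs_x", "logT_vs_logx")),
      function(d) {
        list(kind = d$kind, scope = d$scope, slope = d$slope,
             intercept = d$intercept, ci_low = d$ci_low, ci_high = d$ci_high,
             r_squared = d$r_squared, n = d$n, binned_means = d$binned)
      }),
    mitotic_duration = list(slope = assessment$mitotic$slope,
                            ci_low = assessment$mitotic$ci_low,
                            ci_high = assessment$mitotic$ci_high,
                            n = assessment$mitotic$n)
  )
  jsonlite::write_json(assessment_json, paths["assessment"],
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  jsonlite::write_json(unclass(budget), paths["budget"],
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  manifest <- list(
    package = "dynadder",
    version = as.character(utils::packageVersion("dynadder")),
    seed = as.integer(seed),
    scope = scope,
    n_bootstrap = n_bootstrap,
    config = config[config_file_fields()],
    outputs = as.list(stats::setNames(unname(tools::md5sum(unname(paths))),
                                      basename(unname(paths)))),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  say("wrote %d artifacts to %s", length(paths) + 1L, out_dir)
  invisible(list(sim = sim, cycles = cycles, assessment = assessment,
                 budget = budget, manifest = manifest,
                 paths = c(paths, manifest = manifest_path)))
}
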