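#' Net added membrane area from gross fluxes
#'
#' Under rapid membrane turnover the added surface area is the gross
#' exocytic supply minus the gross endocytic uptake:
#' `dS = dS_exo - dS_endo`.  The result may be negative (a net-shrinking
#' cell is representable); the gross fluxes themselves must be
#' non-negative.
#'
#' @param dS_exo gross exocytosed membrane area, um^2 (>= 0).
#' @param dS_endo gross endocytosed membrane area, um^2 (>= 0).
#' @return `dS_exo - dS_endo` (vectorized).
#' @examples
#' net_added_area(500, 400)
#' @export
net_added_area <- function(dS_exo, dS_endo) {
  if (any(dS_exo < 0) || any(dS_endo < 0)) {
    stop("gross flux areas must be non-negative", call. = FALSE)
  }
  dS_exo - dS_endo
}

#' Membrane area internalized by phagocytosis
#'
#' @param count number of phagocytic events (>= 0; need not be integer,
#'   e.g. a mean rate).
#' @param a_bact membrane area internalized per event, um^2 (> 0).
#' @return `count * a_bact` (vectorized).
#' @examples
#' phagocytic_uptake_area(20, 9)   # 180
#' phagocytic_uptake_area(19.1, 9) # 171.9
#' @export
phagocytic_uptake_area <- function(count, a_bact = 9.0) {
  if (any(count < 0)) stop("'count' must be non-negative", call. = FALSE)
  if (any(a_bact <= 0)) stop("'a_bact' must be positive", call. = FALSE)
  count * a_bact
}

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' How many times the membrane is refreshed over a period
#'
#' The cumulative endocytosed area over `duration` at a constant uptake
#' of `uptake_per_interval` um^2 per `interval` minutes, divided by the
#' total membrane area -- i.e. how many times the whole cell membrane
#' turns over.  Rounded half away from zero to the nearest integer by
#' default (so 6.6 -> 7 and 13.2 -> 13).
#'
#' @param uptake_per_interval membrane uptake per interval, um^2.
#' @param interval uptake reporting interval, minutes (> 0).
#' @param duration period length, minutes (> 0).
#' @param total_area total cell membrane area, um^2 (> 0).
#' @param rounded return the nearest-integer count (default) or the raw
#'   ratio.
#' @return Refresh count (>= 0).
#' @examples
#' refresh_count(180, 10, 220, 300) # 13
#' refresh_count(180, 10, 220, 600) # 7
#' @export
refresh_count <- function(uptake_per_interval, interval, duration, total_area,
                          rounded = TRUE) {
  if (any(total_area <= 0)) stop("'total_area' must be positive", call. = FALSE)
  if (any(interval <= 0) || any(duration <= 0)) {
    stop("'interval' and 'duration' must be positive", call. = FALSE)
  }
  if (any(uptake_per_interval < 0)) {
    stop("'uptake_per_interval' must be non-negative", call. = FALSE)
  }
  rc <- (duration / interval) * uptake_per_interval / total_area
  if (rounded) round_half_away(rc) else rc
}

#' Fraction of the total membrane internalized per interval
#'
#' @inheritParams refresh_count
#' @return Percentage `100 * uptake_per_interval / total_area`.
#' @examples
#' uptake_fraction(180, 300) # 60
#' uptake_fraction(180, 600) # 30
#' @export
uptake_fraction <- function(uptake_per_interval, total_area) {
  if (any(total_area <= 0)) stop("'total_area' must be positive", call. = FALSE)
  if (any(uptake_per_interval < 0)) {
    stop("'uptake_per_interval' must be non-negative", call. = FALSE)
  }
  100 * uptake_per_interval / total_area
}

#' Assemble a membrane-turnover budget
#'
#' Combines the flux arithmetic into one record: given a per-interval
#' uptake, a period and a total membrane area, computes the cumulative
#' endocytosed area, the implied exocytosed area (`dS_net + dS_endo`),
#' the refresh count and the per-interval uptake fraction.
#'
#' @param uptake_per_interval membrane uptake per `interval`, um^2.
#' @param interval reporting interval, minutes.
#' @param duration period (e.g. interphase) length, minutes.
#' @param total_area total cell membrane area, um^2.
#' @param dS_net net added area over the period, um^2; defaults to
#'   `total_area` (the membrane doubles over one interphase).
#' @return An object of class `"membrane_budget"` with fields `dS_exo`,
#'   `dS_endo`, `dS_net`, `uptake_per_interval`, `interval`, `duration`,
#'   `total_area`, `refresh_count`, `uptake_fraction`.
#' @examples
#' membrane_budget(180, 10, 220, 300)
#' @export
membrane_budget <- function(uptake_per_interval, interval = 10,
                            duration = 220, total_area,
                            dS_net = total_area) {
  dS_endo <- (duration / interval) * uptake_per_interval
  dS_exo <- dS_net + dS_endo
  if (dS_exo < 0) {
    stop("implied exocytic flux is negative; check 'dS_net'", call. = FALSE)
  }
  structure(list(
    dS_exo = dS_exo, dS_endo = dS_endo,
    dS_net = net_added_area(dS_exo, dS_endo),
    uptake_per_interval = uptake_per_interval,
    interval = interval, duration = duration, total_area = total_area,
    refresh_count = refresh_count(uptake_per_interval, interval, duration,
                                  total_area),
    uptake_fraction = uptake_fraction(uptake_per_interval, total_area)
  ), class = "membrane_budget")
}

#' Aggregate simulated per-cycle fluxes into a membrane budget
#'
#' Summarizes the interphase gross fluxes recorded in a `"cell_cycles"`
#' table from a dynamic-adder simulation: mean exocytosed, endocytosed
#' and net added areas per cycle, the mean uptake per `interval`, and the
#' refresh count / uptake fraction evaluated at a reference total
#' membrane area.
#'
#' @param records a `"cell_cycles"` table with `dS_exo`/`dS_endo`
#'   columns (a dynamic-adder run).
#' @param interval reporting interval, minutes.
#' @param total_area reference total membrane area, um^2; defaults to the
#'   mean birth area of the records.
#' @return A `"membrane_budget"` whose `duration` is the mean interphase
#'   duration (minutes) of the records.
#' @export
budget_from_cycles <- function(records, interval = 10, total_area = NULL) {
  df <- as.data.frame(records)
  if (nrow(df) == 0) stop("no cycle records", call. = FALSE)
  if (all(df$dS_endo == 0)) {
    warning("records carry no endocytic flux; was the simulation run under ",
            "the dynamic_adder regime?")
  }
  if (is.null(total_area)) total_area <- mean(df$x)
  dur <- mean(df$T_interphase) * 60
  uptake <- mean(df$dS_endo) / dur * interval
  b <- membrane_budget(uptake, interval, dur, total_area,
                       dS_net = mean(df$dS_exo) - mean(df$dS_endo))
  b$n_cycles <- nrow(df)
  b
}

#' @export
print.membrane_budget <- function(x, ...) {
  cat("Membrane turnover budget\n")
  cat(sprintf("  period: %.4g min, uptake %.4g um^2 per %g min\n",
              x$duration, x$uptake_per_interval, x$interval))
  cat(sprintf("  gross fluxes: exo %.4g um^2, endo %.4g um^2, net %.4g um^2\n",
              x$dS_exo, x$dS_endo, x$dS_net))
  cat(sprintf("  total area %.4g um^2: refreshed %g time(s), %.3g%% internalized per interval\n",
              x$total_area, x$refresh_count, x$uptake_fraction))
  invisible(x)
}
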