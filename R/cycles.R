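#' Extract per-cycle records from area trajectories
#'
#' Converts a labeled trajectory table (one row per time sample, as
#' produced by [simulate_lineages()] or read with [read_trajectories()])
#' into one record per completed cell cycle.  A cycle is complete when the
#' cell's trajectory runs through interphase, metaphase and cytokinesis;
#' cells truncated by the observation window (no cytokinesis samples) are
#' dropped.
#'
#' Definitions (um^2, minutes/hours):
#' * `x` -- birth area, the first post-abscission sample;
#' * `S_premitosis` -- last interphase sample (mitosis entry);
#' * `S_cytokinesis` -- area immediately before cytokinesis, i.e. the last
#'   metaphase (shrunken) sample, before the cytokinesis gain begins;
#' * `S_preabscission` -- last cytokinesis sample (the pre-abscission
#'   maximum);
#' * `dS_whole = S_cytokinesis - x`; `dS_interphase = S_premitosis - x`
#'   (both stored so the whole-cycle vs interphase choice is auditable);
#' * `T_interphase` (h), `T_mitotic` (min, rounding to abscission),
#'   `T_gen = T_interphase + T_mitotic/60` (h, birth to next birth);
#' * `dS_exo`, `dS_endo` -- cumulative gross fluxes over interphase
#'   (zero except under the dynamic-adder regime);
#' * `sibling_ratio` -- larger/smaller birth area of the two daughters,
#'   recovered through `parent_id` links (NA if daughters are absent).
#'
#' @param trajectories a trajectory `data.frame` or a `"cell_lineages"`
#'   object.
#' @return A `data.frame` of class `"cell_cycles"`, one row per completed
#'   cycle.
#' @export
extract_cycles <- function(trajectories) {
  df <- if (inherits(trajectories, "cell_lineages")) {
    trajectories$trajectories
  } else {
    trajectories
  }
  req <- c("lineage_id", "cell_id", "parent_id", "generation",
           "time_min", "area_um2", "phase")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) {
    stop("trajectory table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"cum_exo_um2" %in% names(df)) df$cum_exo_um2 <- 0
  if (!"cum_endo_um2" %in% names(df)) df$cum_endo_um2 <- 0
  df <- df[order(df$lineage_id, df$cell_id, df$time_min), , drop = FALSE]
  if (nrow(df) == 0) {
    return(empty_cycles())
  }
  cid <- df$cell_id
  code <- match(df$phase, c("interphase", "metaphase", "cytokinesis"))
  if (anyNA(code)) {
    stop("parse error: unknown phase label at row ",
         which(is.na(code))[1], call. = FALSE)
  }
  same_cell <- cid[-1] == cid[-length(cid)]
  bad <- which(same_cell & diff(code) < 0)
  if (length(bad) > 0) {
    stop("parse error: phase order violated (phases must run interphase -> ",
         "metaphase -> cytokinesis) at row ", bad[1] + 1L, call. = FALSE)
  }

  first_i <- which(!duplicated(cid))
  cells <- cid[first_i]
  # last row of a given phase for each cell
  last_of <- function(sel) {
    i <- which(sel)
    i <- i[!duplicated(cid[i], fromLast = TRUE)]
    stats::setNames(i, cid[i])
  }
  li_int <- last_of(code == 1L)
  li_meta <- last_of(code == 2L)
  li_cyt <- last_of(code == 3L)

  complete <- cells[cells %in% names(li_cyt) & cells %in% names(li_meta) &
                      cells %in% names(li_int)]
  # daughter birth areas keyed by parent
  d_first <- first_i
  d_parent <- df$parent_id[d_first]
  d_area <- df$area_um2[d_first]
  ratio_of <- function(cell) {
    a <- d_area[!is.na(d_parent) & d_parent == cell]
    if (length(a) == 2) max(a) / min(a) else NA_real_
  }
  if (length(complete) == 0) {
    return(empty_cycles())
  }
  fi <- stats::setNames(first_i, cells)[complete]
  ii <- li_int[complete]
  mi <- li_meta[complete]
  yi <- li_cyt[complete]
  x <- df$area_um2[fi]
  t_birth <- df$time_min[fi]
  t_pre <- df$time_min[ii]
  t_absc <- df$time_min[yi]
  rec <- data.frame(
    lineage_id = df$lineage_id[fi],
    cell_id = complete,
    parent_id = df$parent_id[fi],
    generation = df$generation[fi],
    x = x,
    S_premitosis = df$area_um2[ii],
    S_cytokinesis = df$area_um2[mi],
    S_preabscission = df$area_um2[yi],
    dS_whole = df$area_um2[mi] - x,
    dS_interphase = df$area_um2[ii] - x,
    T_gen = (t_absc - t_birth) / 60,
    T_interphase = (t_pre - t_birth) / 60,
    T_mitotic = t_absc - t_pre,
    dS_exo = df$cum_exo_um2[ii],
    dS_endo = df$cum_endo_um2[ii],
    sibling_ratio = vapply(complete, ratio_of, numeric(1)),
    t_birth = t_birth,
    stringsAsFactors = FALSE
  )
  rec <- rec[order(rec$lineage_id, rec$t_birth, rec$cell_id), , drop = FALSE]
  rownames(rec) <- NULL
  class(rec) <- c("cell_cycles", "data.frame")
  rec
}

empty_cycles <- function() {
  rec <- data.frame(
    lineage_id = integer(0), cell_id = character(0), parent_id = character(0),
    generation = integer(0), x = numeric(0), S_premitosis = numeric(0),
    S_cytokinesis = numeric(0), S_preabscission = numeric(0),
    dS_whole = numeric(0), dS_interphase = numeric(0), T_gen = numeric(0),
    T_interphase = numeric(0), T_mitotic = numeric(0), dS_exo = numeric(0),
    dS_endo = numeric(0), sibling_ratio = numeric(0), t_birth = numeric(0),
    stringsAsFactors = FALSE
  )
  class(rec) <- c("cell_cycles", "data.frame")
  rec
}

#' Fit the interphase growth law on pooled, time-normalized trajectories
#'
#' Pools the interphase portion of every cell with at least three
#' interphase samples, maps each cell's interphase onto a relative time
#' axis 0--100 (birth to the last interphase sample), and fits ordinary
#' least squares of `log10(area / birth area)` on relative time (the
#' relative-area scale removes birth-size differences between cells so
#' the pooled line reflects the within-cycle growth law alone).  A
#' straight pooled line (R^2 near 1) indicates exponential growth;
#' linear growth leaves a concave residual pattern.
#'
#' @param trajectories a trajectory `data.frame` or `"cell_lineages"`.
#' @return A list of class `"growth_fit"` with `slope` (per unit of
#'   relative time), `intercept`, `r_squared`, `n` (points), `n_cells`,
#'   `scope = "log_area_vs_time"` and `residuals`.
#' @export
fit_growth_law <- function(trajectories) {
  df <- if (inherits(trajectories, "cell_lineages")) {
    trajectories$trajectories
  } else {
    trajectories
  }
  df <- df[order(df$lineage_id, df$cell_id, df$time_min), , drop = FALSE]
  int <- df[df$phase == "interphase", , drop = FALSE]
  if (any(int$area_um2 <= 0)) {
    stop("non-positive area encountered before log transform", call. = FALSE)
  }
  cid <- int$cell_id
  n_per <- table(cid)
  keep <- names(n_per)[n_per >= 3]
  int <- int[cid %in% keep, , drop = FALSE]
  if (nrow(int) < 3) stop("need at least 3 interphase samples", call. = FALSE)
  t0 <- stats::ave(int$time_min, int$cell_id, FUN = min)
  t1 <- stats::ave(int$time_min, int$cell_id, FUN = max)
  tn <- 100 * (int$time_min - t0) / (t1 - t0)
  a0 <- stats::ave(int$area_um2, int$cell_id, FUN = function(z) z[1])
  y <- log10(int$area_um2 / a0)
  fit <- stats::lm(y ~ tn)
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = r_squared_of(fit, y),
    n = length(y), n_cells = length(unique(int$cell_id)),
    scope = "log_area_vs_time",
    residuals = unname(stats::residuals(fit)),
    time_norm = tn
  ), class = "growth_fit")
}

#' Regress the instantaneous growth rate on cell size
#'
#' For every completed cycle the instantaneous growth rate is estimated by
#' the finite difference `(S(t_pre) - S(t_pre - window)) / window` over
#' the final `window` minutes of interphase, and regressed (OLS) on the
#' area immediately before cytokinesis.  A positive slope close to the
#' growth constant `k` indicates exponential (size-proportional) growth;
#' a slope of zero indicates linear growth.
#'
#' @param trajectories a trajectory `data.frame` or `"cell_lineages"`.
#' @param window differentiation window, minutes (must cover at least two
#'   samples and fit inside every used interphase).
#' @return A list of class `"growth_fit"` with `slope` (per minute),
#'   `intercept`, `r_squared`, `n`, `scope = "rate_vs_size"`, and the
#'   per-cycle `rates` and `sizes`.
#' @export
fit_rate_vs_size <- function(trajectories, window = 10) {
  df <- if (inherits(trajectories, "cell_lineages")) {
    trajectories$trajectories
  } else {
    trajectories
  }
  df <- df[order(df$lineage_id, df$cell_id, df$time_min), , drop = FALSE]
  cid <- df$cell_id
  code <- match(df$phase, c("interphase", "metaphase", "cytokinesis"))
  ii <- which(code == 1L)
  ii_last <- ii[!duplicated(cid[ii], fromLast = TRUE)]
  mi <- which(code == 2L)
  mi_last <- mi[!duplicated(cid[mi], fromLast = TRUE)]
  has_mit <- cid[ii_last] %in% cid[mi_last]
  ii_last <- ii_last[has_mit]
  dt_grid <- if (nrow(df) > 1) min(diff(sort(unique(df$time_min)))) else 1
  if (window < 2 * dt_grid) {
    stop("'window' must span at least two sample intervals", call. = FALSE)
  }
  rates <- numeric(0)
  sizes <- numeric(0)
  s_cyt <- stats::setNames(df$area_um2[mi_last], cid[mi_last])
  for (i in ii_last) {
    cell <- cid[i]
    t_end <- df$time_min[i]
    rows <- which(cid == cell & code == 1L)
    t_cell <- df$time_min[rows]
    if (t_end - window < t_cell[1]) {
      stop("'window' longer than the interphase of cell ", cell, call. = FALSE)
    }
    j <- rows[which.min(abs(t_cell - (t_end - window)))]
    rate <- (df$area_um2[i] - df$area_um2[j]) / (t_end - df$time_min[j])
    rates <- c(rates, rate)
    sizes <- c(sizes, s_cyt[[cell]])
  }
  if (length(rates) < 3) stop("need at least 3 completed cycles", call. = FALSE)
  fit <- stats::lm(rates ~ sizes)
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = r_squared_of(fit, rates),
    n = length(rates), scope = "rate_vs_size",
    rates = rates, sizes = sizes
  ), class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("Growth fit (%s): slope = %.6g, intercept = %.6g, R^2 = %.4f, n = %d\n",
              x$scope, x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Size-class convergence summary across consecutive generations
#'
#' Splits mother cells into three birth-size classes -- smaller than
#' `bounds[1]`, average (between the bounds), larger than `bounds[2]` --
#' and summarizes, for each class, the mother's birth area (`x1`) and
#' pre-division area (`Scyt1`), the daughter's birth area (`x2`) and
#' pre-division area (`Scyt2`), and the ratios `x2/x1` and `Scyt2/x1`.
#' Under adder or sizer control the displaced classes converge: large
#' daughters shrink toward the mean and small daughters grow toward it,
#' while the average class doubles (`Scyt2/x1` close to 2).
#'
#' @param records a `"cell_cycles"` table with mother-daughter links
#'   spanning at least two generations.
#' @param bounds numeric length-2 class bounds in um^2, default
#'   `c(350, 450)`.
#' @return A `data.frame` with one row per class (`small`, `average`,
#'   `large`): `n`, mean/SD of `x1`, `Scyt1`, `x2`, `Scyt2` and the mean
#'   ratios `ratio_birth` (`x2/x1`) and `ratio_cyt2_birth1` (`Scyt2/x1`).
#'   Empty classes are reported with `n = 0` and `NA` summaries.
#' @export
size_class_summary <- function(records, bounds = c(350, 450)) {
  stopifnot(length(bounds) == 2, bounds[1] < bounds[2])
  recs <- as.data.frame(records)
  kid <- match(recs$parent_id, recs$cell_id)
  has_kid <- !is.na(kid)
  # pair: mother = recs[kid[i]], daughter = recs[i]
  mother <- recs[kid[has_kid], , drop = FALSE]
  daughter <- recs[has_kid, , drop = FALSE]
  if (nrow(mother) == 0) {
    stop("records contain no linked mother-daughter cycle pairs", call. = FALSE)
  }
  cls <- cut(mother$x, c(-Inf, bounds, Inf),
             labels = c("small", "average", "large"))
  out <- lapply(levels(cls), function(lv) {
    i <- which(cls == lv)
    if (length(i) == 0) {
      return(data.frame(class = lv, n = 0L, x1_mean = NA_real_, x1_sd = NA_real_,
                        Scyt1_mean = NA_real_, Scyt1_sd = NA_real_,
                        x2_mean = NA_real_, x2_sd = NA_real_,
                        Scyt2_mean = NA_real_, Scyt2_sd = NA_real_,
                        ratio_birth = NA_real_, ratio_cyt2_birth1 = NA_real_,
                        stringsAsFactors = FALSE))
    }
    data.frame(
      class = lv, n = length(i),
      x1_mean = mean(mother$x[i]), x1_sd = stats::sd(mother$x[i]),
      Scyt1_mean = mean(mother$S_cytokinesis[i]),
      Scyt1_sd = stats::sd(mother$S_cytokinesis[i]),
      x2_mean = mean(daughter$x[i]), x2_sd = stats::sd(daughter$x[i]),
      Scyt2_mean = mean(daughter$S_cytokinesis[i]),
      Scyt2_sd = stats::sd(daughter$S_cytokinesis[i]),
      ratio_birth = mean(daughter$x[i] / mother$x[i]),
      ratio_cyt2_birth1 = mean(daughter$S_cytokinesis[i] / mother$x[i]),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Summary statistics of sibling division asymmetry
#'
#' Reports the mean, SD and count of the percent deviation
#' `(sibling_ratio - 1) * 100`, where `sibling_ratio` is the larger
#' daughter's birth area over the smaller's.
#'
#' @param records a `"cell_cycles"` table (rows with `NA` ratios, i.e.
#'   divisions whose daughters were not both observed, are skipped), or an
#'   events table with a `sibling_ratio` column.
#' @return A list with `mean`, `sd`, `n`.
#' @examples
#' sibling_stats(data.frame(sibling_ratio = c(1.05, 1.15)))
#' @export
sibling_stats <- function(records) {
  r <- records$sibling_ratio
  r <- r[!is.na(r)]
  if (length(r) == 0) stop("no divisions with observed sibling pairs", call. = FALSE)
  dev <- (r - 1) * 100
  list(mean = mean(dev), sd = if (length(dev) > 1) stats::sd(dev) else 0,
       n = length(dev))
}
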