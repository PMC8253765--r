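#' Generate a noiseless ideal-model dataset for a slope diagnostic
#'
#' Builds `(x, y)` pairs lying exactly on the relation a perfect sizer,
#' timer or adder implies for the chosen diagnostic:
#'
#' * `dS_vs_x` (added area over the cycle vs birth area): adder
#'   `dS = C_ave` (slope 0); sizer `dS = 2*C_ave - x` (slope -1); timer,
#'   under exponential growth, `dS = x` (slope +1).
#' * `Scyt_vs_x` (area immediately before cytokinesis vs birth area):
#'   adder `S_cyt = x + C_ave` (slope +1); sizer `S_cyt = 2*C_ave`
#'   (slope 0); undefined for the timer.
#' * `logT_vs_logx` (generation time vs birth area, both axes
#'   log-transformed before fitting): adder `T = C_ave * T_ave / x`
#'   (log-log slope -1); timer `T = T_ave` (slope 0); undefined for the
#'   sizer.
#'
#' @param model `"adder"`, `"sizer"` or `"timer"`.
#' @param kind diagnostic: `"dS_vs_x"`, `"Scyt_vs_x"` or `"logT_vs_logx"`.
#' @param C_ave mean birth area, um^2.
#' @param T_ave mean generation time, hours.
#' @param x_range range of birth areas, um^2.
#' @param n_points number of evenly spaced points (>= 2).
#' @return A `data.frame` with columns `x` and `y` on the *raw* scale
#'   (log transforms are applied by the fitting functions).
#' @examples
#' d <- ideal_dataset("sizer", "dS_vs_x")
#' coef(lm(y ~ x, d))[2]  # exactly -1
#' @export
ideal_dataset <- function(model = c("adder", "sizer", "timer"),
                          kind = c("dS_vs_x", "Scyt_vs_x", "logT_vs_logx"),
                          C_ave = 400, T_ave = 3.87,
                          x_range = c(200, 800), n_points = 100) {
  model <- match.arg(model)
  kind <- match.arg(kind)
  stopifnot(n_points >= 2, all(x_range > 0), x_range[1] < x_range[2])
  x <- seq(x_range[1], x_range[2], length.out = n_points)
  y <- switch(kind,
    dS_vs_x = switch(model,
      adder = rep(C_ave, n_points),
      sizer = 2 * C_ave - x,
      timer = x
    ),
    Scyt_vs_x = switch(model,
      adder = x + C_ave,
      sizer = rep(2 * C_ave, n_points),
      timer = stop("unsupported combination: the timer model defines no ",
                   "pre-cytokinesis-area relation", call. = FALSE)
    ),
    logT_vs_logx = switch(model,
      adder = C_ave * T_ave / x,
      timer = rep(T_ave, n_points),
      sizer = stop("unsupported combination: the sizer model defines no ",
                   "generation-time relation", call. = FALSE)
    )
  )
  data.frame(x = x, y = y)
}

#' Fit an OLS slope with a percentile-bootstrap confidence interval
#'
#' The core estimator behind all slope diagnostics: ordinary least squares
#' of `y` on `x`, a seeded percentile bootstrap over case resampling for
#' the slope CI, and equal-width binned means for display.
#'
#' @param x,y numeric vectors of equal length (>= 3 finite pairs).
#' @param kind,scope labels stored on the result.
#' @param n_bootstrap bootstrap replicates (0 disables the CI, which is
#'   then set to the point estimate).
#' @param seed integer seed for the bootstrap resampling.
#' @param conf confidence level.
#' @param bin_min minimum points per display bin; equal-width bins across
#'   the range of `x` are merged inward from the edges until every bin
#'   holds at least this many points.
#' @param n_bins initial number of equal-width bins.
#' @return An object of class `"slope_diagnostic"`: `slope`, `intercept`,
#'   `ci_low`, `ci_high`, `r_squared`, `n`, `kind`, `scope`,
#'   `binned` (`data.frame`: `center`, `mean`, `sd`, `n`).
#' @export
fit_slope <- function(x, y, kind = "custom", scope = "whole",
                      n_bootstrap = 1000, seed = 1L, conf = 0.95,
                      bin_min = 5, n_bins = 8) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 finite (x, y) pairs", call. = FALSE)
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  r2 <- r_squared_of(fit, y)
  if (n_bootstrap > 0) {
    set.seed(as.integer(seed))
    idx <- matrix(sample.int(n, n * n_bootstrap, replace = TRUE), nrow = n)
    xb <- matrix(x[idx], nrow = n)
    yb <- matrix(y[idx], nrow = n)
    mx <- colMeans(xb)
    my <- colMeans(yb)
    sxy <- colMeans(xb * yb) - mx * my
    sxx <- colMeans(xb * xb) - mx * mx
    bs <- sxy / sxx
    bs <- bs[is.finite(bs)] # drop degenerate resamples (all x identical)
    alpha <- (1 - conf) / 2
    ci <- unname(stats::quantile(bs, c(alpha, 1 - alpha), names = FALSE))
  } else {
    ci <- c(slope, slope)
  }
  structure(list(
    kind = kind, scope = scope,
    slope = slope, intercept = intercept,
    ci_low = min(ci[1], slope), ci_high = max(ci[2], slope),
    r_squared = r2, n = n,
    binned = binned_means(x, y, bin_min = bin_min, n_bins = n_bins)
  ), class = "slope_diagnostic")
}

# coefficient of determination without summary.lm (which warns on exact
# fits); a zero-variance response is a perfect fit by convention
r_squared_of <- function(fit, y) {
  sst <- sum((y - mean(y))^2)
  if (sst <= 0) return(1)
  max(0, min(1, 1 - sum(stats::residuals(fit)^2) / sst))
}

# Equal-width bins over range(x); sparse bins are merged inward from the
# edges until every non-empty bin holds >= bin_min points.
binned_means <- function(x, y, bin_min = 5, n_bins = 8) {
  n_bins <- max(1L, min(as.integer(n_bins), floor(length(x) / bin_min)))
  if (n_bins <= 1L || diff(range(x)) == 0) {
    return(data.frame(center = mean(x), mean = mean(y),
                      sd = if (length(y) > 1) stats::sd(y) else 0,
                      n = length(y)))
  }
  br <- seq(min(x), max(x), length.out = n_bins + 1L)
  g <- findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(g, nbins = n_bins)
  # merge from the left edge
  grp <- seq_len(n_bins)
  while (length(unique(grp)) > 1) {
    tab <- tapply(counts, grp, sum)
    small <- names(tab)[tab < bin_min & tab > 0]
    if (length(small) == 0) break
    s <- as.integer(small[1])
    ids <- sort(unique(grp))
    pos <- match(s, ids)
    nb <- if (pos == 1) ids[2] else ids[pos - 1]
    grp[grp == s] <- nb
  }
  gg <- grp[g]
  keep <- sort(unique(gg[!is.na(gg)]))
  out <- lapply(keep, function(k) {
    i <- which(gg == k)
    data.frame(center = mean(x[i]), mean = mean(y[i]),
               sd = if (length(i) > 1) stats::sd(y[i]) else 0,
               n = length(i))
  })
  do.call(rbind, out)
}

#' Fit a slope diagnostic on per-cycle records
#'
#' Maps a `"cell_cycles"` table onto the `(x, y)` pairs of the requested
#' diagnostic and scope and fits it with [fit_slope()]:
#'
#' * `dS_vs_x`: `y = dS_whole` (whole scope, added area up to immediately
#'   before cytokinesis) or `dS_interphase` (up to mitosis entry);
#' * `Scyt_vs_x`: `y = S_cytokinesis` (whole) or `S_premitosis`
#'   (interphase);
#' * `logT_vs_logx`: `y = log10(T_gen)` (whole) or `log10(T_interphase)`
#'   (interphase) against `log10(x)`;
#' * `logTmit_vs_logS`: `y = log10(T_mitotic)` against
#'   `log10(S_cytokinesis)` (see [mitotic_duration_diagnostic()]).
#'
#' @param records a `"cell_cycles"` table with at least 10 rows, or any
#'   `data.frame` with columns `x` and `y` (used as-is, e.g. an
#'   [ideal_dataset()]).
#' @param kind diagnostic kind (see above).
#' @param scope `"whole"` or `"interphase"`.
#' @param n_bootstrap,seed,conf,bin_min,n_bins passed to [fit_slope()].
#' @return A `"slope_diagnostic"` object.
#' @export
fit_diagnostic <- function(records,
                           kind = c("dS_vs_x", "Scyt_vs_x", "logT_vs_logx",
                                    "logTmit_vs_logS"),
                           scope = c("whole", "interphase"),
                           n_bootstrap = 1000, seed = 1L, conf = 0.95,
                           bin_min = 5, n_bins = 8) {
  kind <- match.arg(kind)
  scope <- match.arg(scope)
  df <- as.data.frame(records)
  if (all(c("x", "y") %in% names(df)) && !"dS_whole" %in% names(df)) {
    xv <- df$x
    yv <- if (kind == "logT_vs_logx" || kind == "logTmit_vs_logS") {
      check_log_positive(df$y, df, "y")
      log10(df$y)
    } else {
      df$y
    }
    if (kind %in% c("logT_vs_logx", "logTmit_vs_logS")) {
      check_log_positive(xv, df, "x")
      xv <- log10(xv)
    }
    return(fit_slope(xv, yv, kind = kind, scope = scope,
                     n_bootstrap = n_bootstrap, seed = seed, conf = conf,
                     bin_min = bin_min, n_bins = n_bins))
  }
  if (nrow(df) < 10) stop("need at least 10 cycle records", call. = FALSE)
  if (kind == "logTmit_vs_logS") {
    check_log_positive(df$T_mitotic, df, "T_mitotic")
    check_log_positive(df$S_cytokinesis, df, "S_cytokinesis")
    return(fit_slope(log10(df$S_cytokinesis), log10(df$T_mitotic),
                     kind = kind, scope = "mphase",
                     n_bootstrap = n_bootstrap, seed = seed, conf = conf,
                     bin_min = bin_min, n_bins = n_bins))
  }
  yv <- switch(kind,
    dS_vs_x = if (scope == "whole") df$dS_whole else df$dS_interphase,
    Scyt_vs_x = if (scope == "whole") df$S_cytokinesis else df$S_premitosis,
    logT_vs_logx = if (scope == "whole") df$T_gen else df$T_interphase
  )
  xv <- df$x
  if (kind == "logT_vs_logx") {
    check_log_positive(xv, df, "x")
    check_log_positive(yv, df, if (scope == "whole") "T_gen" else "T_interphase")
    xv <- log10(xv)
    yv <- log10(yv)
  }
  fit_slope(xv, yv, kind = kind, scope = scope,
            n_bootstrap = n_bootstrap, seed = seed, conf = conf,
            bin_min = bin_min, n_bins = n_bins)
}

check_log_positive <- function(v, df, what) {
  bad <- which(!is.finite(v) | v <= 0)
  if (length(bad) > 0) {
    id <- if ("cell_id" %in% names(df)) df$cell_id[bad[1]] else bad[1]
    stop(sprintf("cannot log-transform non-positive '%s' (record %s)",
                 what, id), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.slope_diagnostic <- function(x, ...) {
  cat(sprintf("Slope diagnostic %s [%s]: slope = %.4g (%d%% CI %.4g .. %.4g), n = %d, R^2 = %.3f\n",
              x$kind, x$scope, x$slope, 95, x$ci_low, x$ci_high, x$n,
              x$r_squared))
  invisible(x)
}

# Ideal slopes per diagnostic for each model; NA where the model defines
# no relation for that diagnostic.
ideal_slopes <- function() {
  rbind(
    adder = c(dS_vs_x = 0, Scyt_vs_x = 1, logT_vs_logx = -1),
    sizer = c(dS_vs_x = -1, Scyt_vs_x = 0, logT_vs_logx = NA),
    timer = c(dS_vs_x = 1, Scyt_vs_x = NA, logT_vs_logx = 0)
  )
}

#' Classify the homeostasis regime from the three slope diagnostics
#'
#' Compares the fitted slopes of the added-area, pre-cytokinesis-area and
#' log-generation-time diagnostics with the ideal triples -- adder
#' `(0, +1, -1)`, sizer `(-1, 0, --)`, timer `(+1, --, 0)` -- and labels
#' the regime:
#'
#' 1. `"adder"` if all three distances to the adder ideals are within
#'    `tau_adder`;
#' 2. `"near_adder"` if all are within `tau_near`;
#' 3. otherwise the model minimizing the weighted mean absolute slope
#'    distance over its defined diagnostics, or `"indeterminate"` when
#'    the two best models are within `tie_tol` of each other.
#'
#' The generation-time diagnostic is down-weighted by default (weight
#' 0.5): for exponential growth the exact adder generation time is
#' `T = log(1 + C_ave/x)/k`, whose local log-log slope at `x = C_ave` is
#' `-1/(2 log 2)` (about -0.72) rather than the -1 of the linearized
#' ideal, so this diagnostic is systematically the least sharp.
#'
#' @param d1 `"slope_diagnostic"` (or bare slope) for `dS_vs_x`.
#' @param d2 likewise for `Scyt_vs_x`.
#' @param d3 likewise for `logT_vs_logx`.
#' @param tau_adder strict adder threshold.
#' @param tau_near near-adder threshold.
#' @param tie_tol tie tolerance on the mean-distance scale.
#' @param weights per-diagnostic weights for the distance aggregation.
#' @return An object of class `"model_assessment"`: `label`, `slopes`,
#'   `distances` (weighted mean absolute distance per model),
#'   `diagnostics` (the inputs, when full objects were supplied) and the
#'   thresholds used.
#' @examples
#' classify(0, 1, -1)$label    # "adder"
#' classify(-1, 0, -1.4)$label # "sizer"
#' @export
classify <- function(d1, d2, d3, tau_adder = 0.25, tau_near = 0.5,
                     tie_tol = 0.05, weights = c(1, 1, 0.5)) {
  get_slope <- function(d, nm) {
    if (is.null(d)) stop("missing diagnostic '", nm, "'", call. = FALSE)
    if (inherits(d, "slope_diagnostic")) d$slope else as.numeric(d)
  }
  s <- c(get_slope(d1, "dS_vs_x"), get_slope(d2, "Scyt_vs_x"),
         get_slope(d3, "logT_vs_logx"))
  if (any(!is.finite(s))) stop("missing diagnostic slope", call. = FALSE)
  ideals <- ideal_slopes()
  dist_to <- function(model) {
    ref <- ideals[model, ]
    use <- !is.na(ref)
    sum(weights[use] * abs(s[use] - ref[use])) / sum(weights[use])
  }
  d_adder_each <- abs(s - ideals["adder", ])
  distances <- vapply(rownames(ideals), dist_to, numeric(1))
  label <- if (all(d_adder_each <= tau_adder)) {
    "adder"
  } else if (all(d_adder_each <= tau_near)) {
    "near_adder"
  } else {
    ord <- order(distances)
    if (distances[ord[2]] - distances[ord[1]] <= tie_tol) {
      "indeterminate"
    } else {
      names(distances)[ord[1]]
    }
  }
  diags <- list(d1, d2, d3)
  structure(list(
    label = label,
    slopes = stats::setNames(s, c("dS_vs_x", "Scyt_vs_x", "logT_vs_logx")),
    distances = distances,
    diagnostics = if (all(vapply(diags, inherits, logical(1),
                                 "slope_diagnostic"))) diags else NULL,
    tau_adder = tau_adder, tau_near = tau_near, tie_tol = tie_tol,
    weights = weights
  ), class = "model_assessment")
}

#' @export
print.model_assessment <- function(x, ...) {
  cat("Cell size homeostasis model assessment\n")
  cat(sprintf("  slopes: dS~x = %.3g, Scyt~x = %.3g, logT~logx = %.3g\n",
              x$slopes[1], x$slopes[2], x$slopes[3]))
  cat(sprintf("  distances: adder %.3g, sizer %.3g, timer %.3g\n",
              x$distances["adder"], x$distances["sizer"], x$distances["timer"]))
  cat(sprintf("  label: %s\n", x$label))
  invisible(x)
}

#' Mitotic-duration size-independence diagnostic
#'
#' Ordinary least squares of `log10(T_mitotic)` on
#' `log10(S_cytokinesis)`.  A slope of zero indicates a size-independent
#' mitotic clock; a slope of one would indicate duration proportional to
#' size.
#'
#' @param records a `"cell_cycles"` table with at least 10 rows and
#'   strictly positive mitotic durations.
#' @param ... passed to [fit_slope()] (`n_bootstrap`, `seed`, ...).
#' @return A `"slope_diagnostic"` with `kind = "logTmit_vs_logS"`.
#' @export
mitotic_duration_diagnostic <- function(records, ...) {
  fit_diagnostic(records, kind = "logTmit_vs_logS", ...)
}
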