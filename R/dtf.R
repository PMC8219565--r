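# Differential test functioning between calibrated mode groups: expected
# test score (test scoring) functions, signed/unsigned DTF integrated over a
# proficiency density, region-conditional DTF curves, and confidence
# intervals from item-parameter sampling under the asymptotic covariance.

#' Expected test scoring function
#'
#' `TS(theta) = sum_j w_j E[X_j | theta]` with `w_j` the score weight per
#' category step (1 point for dichotomous, half a point for polytomous
#' items), evaluated on a proficiency grid.
#'
#' @param params an `item_params` object on the common scale.
#' @param grid numeric vector of proficiency values (default: 201 points
#'   over `mu +- 5 sd` of the group's latent distribution).
#' @return object of class `test_scoring_fn`: list with `grid`, `ts`,
#'   `group`, `max_score`, `mu`, `sigma2`.
#' @export
test_scoring_function <- function(params, grid = NULL) {
  if (is.null(grid))
    grid <- seq(params$mu - 5 * sqrt(params$sigma2),
                params$mu + 5 * sqrt(params$sigma2), length.out = 201L)
  if (!length(grid)) stop("empty proficiency grid")
  ts <- numeric(length(grid))
  for (j in seq_along(params$delta))
    ts <- ts + params$weight[j] * pcm_moments(params$delta[[j]], grid)$e
  structure(list(grid = grid, ts = ts, group = params$group,
                 max_score = sum(params$weight * params$n_steps),
                 mu = params$mu, sigma2 = params$sigma2),
            class = "test_scoring_fn")
}

trapezoid_weights <- function(grid) {
  n <- length(grid)
  d <- diff(grid)
  c(d[1] / 2, (d[-(n - 1)] + d[-1]) / 2, d[n - 1] / 2)
}

resolve_density <- function(density, grid, comp) {
  if (is.null(density)) density <- list(mu = comp$mu, sigma2 = comp$sigma2)
  if (is.list(density) && !is.null(density$mu))
    return(stats::dnorm(grid, density$mu, sqrt(density$sigma2)))
  if (is.function(density)) return(density(grid))
  if (is.numeric(density)) {
    if (length(density) != length(grid))
      stop("density vector must match the grid length")
    return(density)
  }
  stop("unsupported density specification")
}

#' Signed and unsigned differential test functioning
#'
#' `sDTF = int (TS_ref - TS_comp) f(theta) dtheta` and
#' `uDTF = int |TS_ref - TS_comp| f(theta) dtheta` by trapezoid quadrature
#' on the shared grid, with `uDTF%% = 100 uDTF / max score`. Positive `sDTF`
#' means higher expected scores in the reference group at equal proficiency.
#' The default integration density is the comparison (focal) group's
#' estimated latent distribution.
#'
#' @param ref,comp `test_scoring_fn` objects on a shared grid.
#' @param density `NULL` (focal group's normal), a `list(mu, sigma2)`, a
#'   density function, or a vector of density values on the grid.
#' @return object of class `dtf_result` with `sdtf`, `udtf`, `udtf_pct`.
#' @export
compute_dtf <- function(ref, comp, density = NULL) {
  if (length(ref$grid) != length(comp$grid) ||
      max(abs(ref$grid - comp$grid)) > 1e-10)
    stop("reference and comparison scoring functions need a shared grid")
  f <- resolve_density(density, ref$grid, comp)
  tw <- trapezoid_weights(ref$grid)
  mass <- sum(tw * f)
  if (abs(mass - 1) > 0.01) {
    warning("integration density not normalized on the grid; renormalizing")
  }
  f <- f / mass
  diff_ts <- ref$ts - comp$ts
  sdtf <- sum(tw * f * diff_ts)
  udtf <- sum(tw * f * abs(diff_ts))
  structure(list(reference = ref$group, comparison = comp$group,
                 sdtf = sdtf, udtf = udtf,
                 udtf_pct = 100 * udtf / ref$max_score,
                 max_score = ref$max_score,
                 ci = NULL, conditional = NULL, n_draws = 0L),
            class = "dtf_result")
}

#' Region-conditional signed DTF curve
#'
#' Pointwise `TS_ref(theta) - TS_comp(theta)` at requested proficiency
#' values, localizing where on the latent scale the test functions
#' differently between groups.
#'
#' @param ref_params,comp_params `item_params` on the common scale.
#' @param theta_points proficiency values (default -3..3 in 0.5 steps).
#' @return data frame with `theta` and `sdtf`.
#' @export
conditional_sdtf <- function(ref_params, comp_params,
                             theta_points = seq(-3, 3, by = 0.5)) {
  tr <- test_scoring_function(ref_params, theta_points)
  tc <- test_scoring_function(comp_params, theta_points)
  data.frame(theta = theta_points, sdtf = tr$ts - tc$ts)
}

nearest_psd <- function(V) {
  e <- eigen((V + t(V)) / 2, symmetric = TRUE)
  if (all(e$values >= -1e-10)) return((V + t(V)) / 2)
  warning("covariance not positive semidefinite; projecting to nearest PSD")
  vals <- pmax(e$values, 0)
  e$vectors %*% (vals * t(e$vectors))
}

draw_params <- function(params, n_draws) {
  flat <- unlist(params$delta)
  V <- nearest_psd(params$vcov)
  if (max(abs(V)) < 1e-14) {
    draws <- matrix(flat, n_draws, length(flat), byrow = TRUE)
  } else {
    draws <- MASS::mvrnorm(n_draws, flat, V)
    if (is.null(dim(draws))) draws <- matrix(draws, nrow = n_draws)
  }
  ends <- cumsum(params$n_steps)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  lapply(seq_len(n_draws), function(d) {
    p <- params
    p$delta <- lapply(seq_along(ends), function(j)
      draws[d, starts[j]:ends[j]])
    p
  })
}

#' DTF with parameter-uncertainty confidence intervals
#'
#' Repeats the DTF computation `n_draws` times with both groups' item
#' parameters drawn from multivariate normal distributions around their
#' estimates (using the asymptotic covariance from calibration), and forms
#' percentile 95 percent intervals for `sDTF`, `uDTF`, `uDTF%%` and
#' pointwise for the conditional curve.
#'
#' @inheritParams conditional_sdtf
#' @param density integration density passed to [compute_dtf()].
#' @param n_draws number of parameter draws.
#' @param seed integer seed for the draws.
#' @param grid integration grid (default from the comparison group).
#' @param theta_points reporting points for the conditional curve.
#' @return a `dtf_result` whose `ci` element holds the percentile bounds,
#'   `conditional` the curve with pointwise bounds, and `n_draws` the number
#'   of recomputations performed.
#' @export
dtf_uncertainty <- function(ref_params, comp_params, density = NULL,
                            n_draws = 100L, seed = 1L, grid = NULL,
                            theta_points = seq(-3, 3, by = 0.5)) {
  if (is.null(grid))
    grid <- seq(comp_params$mu - 5 * sqrt(comp_params$sigma2),
                comp_params$mu + 5 * sqrt(comp_params$sigma2),
                length.out = 201L)
  point <- compute_dtf(test_scoring_function(ref_params, grid),
                       test_scoring_function(comp_params, grid), density)
  point$conditional <- conditional_sdtf(ref_params, comp_params, theta_points)
  set.seed(seed)
  ref_draws <- draw_params(ref_params, n_draws)
  comp_draws <- draw_params(comp_params, n_draws)
  stat <- matrix(NA_real_, n_draws, 3L,
                 dimnames = list(NULL, c("sdtf", "udtf", "udtf_pct")))
  curves <- matrix(NA_real_, n_draws, length(theta_points))
  for (d in seq_len(n_draws)) {
    r <- compute_dtf(test_scoring_function(ref_draws[[d]], grid),
                     test_scoring_function(comp_draws[[d]], grid), density)
    stat[d, ] <- c(r$sdtf, r$udtf, r$udtf_pct)
    curves[d, ] <- conditional_sdtf(ref_draws[[d]], comp_draws[[d]],
                                    theta_points)$sdtf
  }
  qs <- apply(stat, 2L, stats::quantile, probs = c(0.025, 0.975))
  point$ci <- list(sdtf = qs[, "sdtf"], udtf = qs[, "udtf"],
                   udtf_pct = qs[, "udtf_pct"])
  cq <- apply(curves, 2L, stats::quantile, probs = c(0.025, 0.975))
  point$conditional$ci_lower <- cq[1L, ]
  point$conditional$ci_upper <- cq[2L, ]
  point$n_draws <- n_draws
  point$draws <- stat
  point
}

#' @export
print.dtf_result <- function(x, ...) {
  fmt <- function(v, ci) {
    if (is.null(ci)) sprintf("%.3f", v)
    else sprintf("%.3f [%.3f, %.3f]", v, ci[1], ci[2])
  }
  cat(sprintf("DTF %s (reference) vs %s (comparison)\n",
              x$reference, x$comparison))
  cat("  sDTF    ", fmt(x$sdtf, x$ci$sdtf), "\n")
  cat("  uDTF    ", fmt(x$udtf, x$ci$udtf), "\n")
  cat("  uDTF%   ", fmt(x$udtf_pct, x$ci$udtf_pct), "\n")
  if (x$n_draws > 0L)
    cat(sprintf("  (percentile CIs from %d parameter draws)\n", x$n_draws))
  invisible(x)
}

#' DTF for all ordered group pairs
#'
#' @param calibration a `mode_calibration`.
#' @param n_draws parameter draws per pair (0 for point estimates only).
#' @param seed integer seed.
#' @param density integration density (default: focal group's distribution).
#' @return data frame with one row per ordered pair (reference before
#'   comparison in PBA, CBA, WBA, WBA_switch order): point estimates and CI
#'   bounds.
#' @export
dtf_pairs <- function(calibration, n_draws = 100L, seed = 1L, density = NULL) {
  gs <- names(calibration$groups)
  ord <- intersect(c("PBA", "CBA", "WBA", "WBA_switch"), gs)
  rows <- list()
  for (i in seq_along(ord)) for (j in seq_along(ord)) {
    if (i >= j) next
    ref <- calibration$groups[[ord[i]]]
    comp <- calibration$groups[[ord[j]]]
    r <- if (n_draws > 0L) {
      dtf_uncertainty(ref, comp, density, n_draws,
                      seed = seed + 7L * i + j)
    } else {
      grid <- seq(comp$mu - 5 * sqrt(comp$sigma2),
                  comp$mu + 5 * sqrt(comp$sigma2), length.out = 201L)
      compute_dtf(test_scoring_function(ref, grid),
                  test_scoring_function(comp, grid), density)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      reference = ord[i], comparison = ord[j],
      sdtf = r$sdtf,
      sdtf_lower = if (is.null(r$ci)) NA_real_ else r$ci$sdtf[1],
      sdtf_upper = if (is.null(r$ci)) NA_real_ else r$ci$sdtf[2],
      udtf = r$udtf,
      udtf_lower = if (is.null(r$ci)) NA_real_ else r$ci$udtf[1],
      udtf_upper = if (is.null(r$ci)) NA_real_ else r$ci$udtf[2],
      udtf_pct = r$udtf_pct,
      udtf_pct_lower = if (is.null(r$ci)) NA_real_ else r$ci$udtf_pct[1],
      udtf_pct_upper = if (is.null(r$ci)) NA_real_ else r$ci$udtf_pct[2])
  }
  do.call(rbind, rows)
}
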