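# Self-selection analysis and propensity-score nonresponse correction:
# four single nonresponse logits (one per mode, including the switch stage),
# a pooled interaction model contrasting selection effects between modes,
# pseudo-R2 comparison of the main-effect and interaction models, and the
# inverse-participation-probability weights used by all downstream stages.

mode_outcome <- function(modes, m) {
  # rows entering mode m's nonresponse model and their 0/1 outcome
  if (m == "WBA_switch") {
    idx <- which(modes$offered_switch)
    y <- as.integer(modes$participated_switch[idx])
  } else {
    idx <- which(modes$assigned_mode == m)
    y <- as.integer(modes$participated_first_stage[idx])
  }
  list(idx = idx, y = y)
}

predictor_columns <- function(tab) {
  setdiff(names(tab), c("student_id"))
}

# fit one logit, dropping separated predictors (|z| coef with huge SE)
safe_logit <- function(df, outcome = "y") {
  rhs <- setdiff(names(df), outcome)
  repeat {
    fml <- stats::reformulate(rhs, response = outcome)
    fit <- suppressWarnings(stats::glm(fml, data = df, family = stats::binomial()))
    sm <- summary(fit)$coefficients
    se <- sm[, "Std. Error"]
    bad <- names(se)[se > 50 | !is.finite(se)]
    bad <- unique(unlist(lapply(rhs, function(v)
      if (any(startsWith(bad, v))) v else NULL)))
    if (!length(bad)) return(fit)
    warning("dropping predictor(s) with separation/aliasing: ",
            paste(bad, collapse = ", "))
    rhs <- setdiff(rhs, bad)
    if (!length(rhs)) return(suppressWarnings(
      stats::glm(stats::reformulate("1", response = outcome), data = df,
                 family = stats::binomial())))
  }
}

# single complete-data fits pool silently (between-variance NA by design)
pool_quiet <- function(est, va) {
  if (length(est) == 1L) suppressWarnings(rubin_pool(est, va))
  else rubin_pool(est, va)
}

pool_glm_coefs <- function(fits) {
  # Rubin-pool coefficients across imputation fits (union of terms)
  terms <- unique(unlist(lapply(fits, function(f) names(stats::coef(f)))))
  res <- lapply(terms, function(tm) {
    est <- vapply(fits, function(f) {
      cf <- stats::coef(f); if (tm %in% names(cf)) cf[[tm]] else NA_real_
    }, 1.0)
    va <- vapply(fits, function(f) {
      V <- stats::vcov(f)
      if (tm %in% rownames(V)) V[tm, tm] else NA_real_
    }, 1.0)
    ok <- is.finite(est) & is.finite(va)
    if (!any(ok)) return(NULL)
    p <- pool_quiet(est[ok], va[ok])
    data.frame(term = tm, estimate = p$estimate, se = p$se,
               ci_lower = p$ci[1], ci_upper = p$ci[2], df = p$df,
               p_value = 2 * stats::pt(-abs(p$estimate / p$se),
                                       min(p$df, 1e6)))
  })
  do.call(rbind, res)
}

# intercept-only binomial log-likelihood, avoiding a refit
null_loglik <- function(fit) {
  y <- fit$y
  p <- mean(y)
  sum(y * log(p) + (1 - y) * log(1 - p))
}

mcfadden_r2 <- function(fit) {
  1 - as.numeric(stats::logLik(fit)) / null_loglik(fit)
}

#' Fit the four mode-specific nonresponse models
#'
#' For each mode (PBA, CBA, WBA first-stage assignment; the switch stage on
#' the pool of first-stage supervised nonresponders), a logit of
#' participation (0 = nonresponse, 1 = participation) on all covariates is
#' fitted per imputation copy and Rubin-pooled. Predictors significant at
#' p < .05 (pooled) are flagged; the flagged subset later conditions the
#' propensity-score predictions.
#'
#' @param imputations an `imputation_set` of the covariate table (or a plain
#'   complete data frame, treated as a single copy).
#' @param modes filled mode records.
#' @return object of class `nonresponse_fits`: per-mode list with the pooled
#'   coefficient table (`pooled`), per-imputation `glm` fits (`fits`), the
#'   significant predictor names (`significant`), `n`, and a McFadden
#'   pseudo-R2 averaged over copies.
#' @export
fit_mode_nonresponse_models <- function(imputations, modes) {
  copies <- imputation_copies(imputations)
  out <- list()
  for (m in MODES) {
    mo <- mode_outcome(modes, m)
    if (!length(mo$idx)) stop("empty subgroup for mode ", m)
    if (length(unique(mo$y)) < 2L)
      stop("degenerate outcome in mode ", m, ": all ",
           if (mo$y[1] == 1L) "participate" else "refuse")
    fits <- lapply(copies, function(cp) {
      df <- cp[mo$idx, predictor_columns(cp), drop = FALSE]
      df$y <- mo$y
      safe_logit(df)
    })
    pooled <- pool_glm_coefs(fits)
    sig <- pooled$term[pooled$p_value < 0.05 & pooled$term != "(Intercept)"]
    # map factor-dummy terms back to their source columns
    src <- predictor_columns(copies[[1]])
    sig_cols <- unique(unlist(lapply(src, function(v)
      if (any(startsWith(sig, v))) v else NULL)))
    out[[m]] <- list(mode = m, pooled = pooled, fits = fits,
                     significant = sig_cols, n = length(mo$idx),
                     pseudo_r2 = mean(vapply(fits, mcfadden_r2, 1.0)))
  }
  structure(out, class = "nonresponse_fits")
}

imputation_copies <- function(imputations) {
  if (inherits(imputations, "imputation_set")) imputations$copies
  else if (is.data.frame(imputations)) list(imputations)
  else imputations
}

#' @export
print.nonresponse_fits <- function(x, ...) {
  cat("Mode-specific nonresponse models (participation logits)\n")
  for (m in names(x))
    cat(sprintf("  %-10s n = %5d, pseudo-R2 = %.3f, significant: %s\n",
                m, x[[m]]$n, x[[m]]$pseudo_r2,
                paste(x[[m]]$significant, collapse = ", ")))
  invisible(x)
}

#' Fit the pooled mode-interaction selection model
#'
#' Stacks the three randomly assigned arms and fits a single logit with
#' per-mode intercepts and per-mode conditional covariate effects
#' (`y ~ 0 + mode + mode:covariates`), per imputation copy, Rubin-pooled.
#' Between-mode differences of conditional effects (the interaction
#' contrasts) are derived from the coefficient vector and covariance of each
#' copy and pooled the same way.
#'
#' @inheritParams fit_mode_nonresponse_models
#' @return object of class `selection_interaction_fit` with elements
#'   `conditional` (per-mode conditional effects), `contrasts` (pairwise
#'   between-mode differences), `fits`, and `pseudo_r2`.
#' @export
fit_interaction_selection_model <- function(imputations, modes) {
  copies <- imputation_copies(imputations)
  first <- which(!is.na(modes$participated_first_stage))
  md <- droplevels(modes$assigned_mode[first])
  if (nlevels(md) < 2L) stop("need at least two modes for interaction model")
  y <- as.integer(modes$participated_first_stage[first])
  fits <- lapply(copies, function(cp) {
    df <- cp[first, predictor_columns(cp), drop = FALSE]
    covs <- names(df)
    df$mode <- md
    df$y <- y
    fml <- stats::as.formula(paste(
      "y ~ 0 + mode +",
      paste(sprintf("mode:%s", covs), collapse = " + ")))
    suppressWarnings(stats::glm(fml, data = df, family = stats::binomial()))
  })
  conditional <- pool_glm_coefs(fits)
  # pairwise differences of per-mode conditional effects per covariate
  contr <- pool_interaction_contrasts(fits, levels(md))
  structure(list(conditional = conditional, contrasts = contr, fits = fits,
                 pseudo_r2 = mean(vapply(fits, mcfadden_r2, 1.0)),
                 modes = levels(md)),
            class = "selection_interaction_fit")
}

pool_interaction_contrasts <- function(fits, mode_levels) {
  cf1 <- stats::coef(fits[[1]])
  # terms look like "modeCBA:gender"; collect covariates present
  inter <- grep(":", names(cf1), value = TRUE)
  covs <- unique(sub("^mode[^:]*:", "", inter))
  rows <- list()
  for (v in covs) {
    for (i in seq_along(mode_levels)) for (j in seq_along(mode_levels)) {
      if (i >= j) next
      t1 <- paste0("mode", mode_levels[i], ":", v)
      t2 <- paste0("mode", mode_levels[j], ":", v)
      est <- va <- rep(NA_real_, length(fits))
      for (k in seq_along(fits)) {
        cf <- stats::coef(fits[[k]]); V <- stats::vcov(fits[[k]])
        if (all(c(t1, t2) %in% names(cf))) {
          est[k] <- cf[[t1]] - cf[[t2]]
          va[k] <- V[t1, t1] + V[t2, t2] - 2 * V[t1, t2]
        }
      }
      ok <- is.finite(est) & is.finite(va)
      if (!any(ok)) next
      p <- pool_quiet(est[ok], va[ok])
      rows[[length(rows) + 1L]] <- data.frame(
        covariate = v, contrast = paste(mode_levels[i], "vs", mode_levels[j]),
        estimate = p$estimate, se = p$se,
        ci_lower = p$ci[1], ci_upper = p$ci[2],
        p_value = 2 * stats::pt(-abs(p$estimate / p$se), min(p$df, 1e6)))
    }
  }
  do.call(rbind, rows)
}

#' Pseudo-R2 gain of the interaction selection model
#'
#' Compares the stacked main-effects selection model (mode + covariates) with
#' the interaction model (per-mode conditional effects) on identical data and
#' returns both pseudo-R2 values and their difference.
#'
#' @inheritParams fit_mode_nonresponse_models
#' @param interaction_fit optionally, a previously fitted
#'   `selection_interaction_fit` on the same data.
#' @param type `"mcfadden"` (default) or `"nagelkerke"`.
#' @return list with `r2_main`, `r2_interaction`, `delta`.
#' @export
interaction_variance_gain <- function(imputations, modes,
                                      interaction_fit = NULL,
                                      type = c("mcfadden", "nagelkerke")) {
  type <- match.arg(type)
  copies <- imputation_copies(imputations)
  if (is.null(interaction_fit))
    interaction_fit <- fit_interaction_selection_model(imputations, modes)
  first <- which(!is.na(modes$participated_first_stage))
  md <- droplevels(modes$assigned_mode[first])
  y <- as.integer(modes$participated_first_stage[first])
  r2 <- function(fit) {
    if (type == "mcfadden") return(mcfadden_r2(fit))
    n <- length(fit$y)
    ll <- as.numeric(stats::logLik(fit))
    ll0 <- null_loglik(fit)
    (1 - exp(2 * (ll0 - ll) / n)) / (1 - exp(2 * ll0 / n))
  }
  main_r2 <- vapply(copies, function(cp) {
    df <- cp[first, predictor_columns(cp), drop = FALSE]
    covs <- names(df)
    df$mode <- md; df$y <- y
    fml <- stats::reformulate(c("mode", covs), response = "y")
    r2(suppressWarnings(stats::glm(fml, data = df, family = stats::binomial())))
  }, 1.0)
  int_r2 <- vapply(interaction_fit$fits, r2, 1.0)
  list(r2_main = mean(main_r2), r2_interaction = mean(int_r2),
       delta = mean(int_r2) - mean(main_r2))
}

#' Propensity weight for one participation path
#'
#' The displayed weight formula: inverse participation probability for the
#' directly assigned modes, and `(1 - p_first)^-1 * p_switch^-1` for switch
#' participants (nonresponse in the originally assigned supervised mode,
#' then participation in the switch stage).
#'
#' @param path one of `"PBA"`, `"CBA"`, `"WBA"`, `"switch_from_PBA"`,
#'   `"switch_from_CBA"`.
#' @param p_first first-stage participation probability in the assigned mode.
#' @param p_switch switch-stage participation probability (switch paths only).
#' @return the weight (vectorized over probabilities).
#' @export
propensity_weight <- function(path, p_first, p_switch = NULL) {
  path <- match.arg(path, c("PBA", "CBA", "WBA",
                            "switch_from_PBA", "switch_from_CBA"))
  if (path %in% c("PBA", "CBA", "WBA")) return(1 / p_first)
  1 / ((1 - p_first) * p_switch)
}

#' Propensity-score weights from the nonresponse models
#'
#' Participation probabilities are predicted for every participant from the
#' significant-predictor subset of each mode's nonresponse model (refitted on
#' that subset per imputation copy and averaged across copies), and inverted:
#' `w = p1^-1` (PBA), `p2^-1` (CBA), `p3^-1` (WBA), and
#' `(1 - p1)^-1 p4^-1` or `(1 - p2)^-1 p4^-1` for switch participants coming
#' from PBA or CBA respectively. Weights above the trimming quantile are
#' truncated (set `trim = 1` to reproduce the pure formula).
#'
#' @param fits a `nonresponse_fits` object.
#' @param modes filled mode records.
#' @param imputations the imputation set used for `fits`.
#' @param trim quantile (per effective mode) at which weights are truncated.
#' @return data frame of class `propensity_weights`: `student_id`,
#'   `effective_mode`, path probabilities `p_first` and `p_switch`, `weight`.
#' @export
compute_weights <- function(fits, modes, imputations, trim = 0.99) {
  copies <- imputation_copies(imputations)
  part <- which(modes$effective_mode != "none")
  stage_p <- function(mode_key, rows) {
    # averaged (over copies) probability from the significant-subset refit
    sig <- fits[[mode_key]]$significant
    mo <- mode_outcome(modes, mode_key)
    pm <- matrix(0, length(rows), length(copies))
    for (k in seq_along(copies)) {
      cp <- copies[[k]]
      df <- cp[mo$idx, , drop = FALSE]
      df$y <- mo$y
      fml <- if (length(sig)) stats::reformulate(sig, response = "y")
             else stats::as.formula("y ~ 1")
      fit <- suppressWarnings(stats::glm(fml, data = df,
                                         family = stats::binomial()))
      pm[, k] <- stats::predict(fit, newdata = cp[rows, , drop = FALSE],
                                type = "response")
    }
    rowMeans(pm)
  }
  res <- data.frame(student_id = modes$student_id[part],
                    effective_mode = droplevels(modes$effective_mode[part]),
                    p_first = NA_real_, p_switch = NA_real_,
                    weight = NA_real_)
  for (m in c("PBA", "CBA", "WBA")) {
    rows <- part[modes$effective_mode[part] == m]
    if (!length(rows)) next
    p <- stage_p(m, rows)
    sel <- res$effective_mode == m
    res$p_first[sel] <- p
    res$weight[sel] <- 1 / p
  }
  sw <- part[modes$effective_mode[part] == "WBA_switch"]
  if (length(sw)) {
    origin <- as.character(modes$assigned_mode[sw])
    p1 <- rep(NA_real_, length(sw))
    for (m in c("PBA", "CBA")) {
      o <- origin == m
      if (any(o)) p1[o] <- stage_p(m, sw[o])
    }
    p4 <- stage_p("WBA_switch", sw)
    sel <- res$effective_mode == "WBA_switch"
    res$p_first[sel] <- p1
    res$p_switch[sel] <- p4
    res$weight[sel] <- 1 / ((1 - p1) * p4)
  }
  bad <- !is.finite(res$weight)
  if (any(bad)) {
    warning(sum(bad), " undefined weight(s) from boundary probabilities; ",
            "set to the trimmed maximum")
    res$weight[bad] <- NA
  }
  if (trim < 1) {
    for (m in levels(res$effective_mode)) {
      sel <- res$effective_mode == m
      cap <- stats::quantile(res$weight[sel], trim, na.rm = TRUE)
      res$weight[sel & (res$weight > cap | is.na(res$weight))] <- cap
    }
  }
  class(res) <- c("propensity_weights", "data.frame")
  res
}

#' Tabulate response rates per mode
#'
#' @param modes filled mode records.
#' @return data frame with `mode`, `assigned`, `participated`, `rate_percent`
#'   (one decimal), including the switch row (offered as assigned count).
#' @export
tabulate_response_rates <- function(modes) {
  rows <- lapply(MODES, function(m) {
    mo <- mode_outcome(modes, m)
    assigned <- length(mo$idx)
    took <- sum(mo$y)
    rate <- if (assigned > 0) round(100 * took / assigned, 1) else NA_real_
    if (assigned == 0) warning("zero assigned in mode ", m, "; rate undefined")
    data.frame(mode = m, assigned = assigned, participated = took,
               rate_percent = rate)
  })
  do.call(rbind, rows)
}
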