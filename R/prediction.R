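# Prediction-bias regressions on the natural-science subsample: moderated
# linear models of z-standardized criteria on z-standardized literacy
# scores, mode dummies (PBA reference), their interactions and effect-coded
# covariates, pooled over criterion imputations; plus omega reliability for
# the criterion scales.

#' Moderated regression for mode-specific prediction bias
#'
#' Ordinary least squares of the z-standardized criterion on the
#' z-standardized literacy score, three mode dummies (PBA as reference),
#' literacy-by-mode interactions, and effect-coded sex (-0.5 = male,
#' 0.5 = female) and teacher education (-0.5 = teacher education,
#' 0.5 = other), fitted per imputation copy of the criterion data and pooled
#' by Rubin's rules. Standardization uses the analysis subsample, per copy,
#' before interaction terms are formed. `Delta R^2` is the average
#' difference in R-squared between the full model and the model without the
#' interaction block.
#'
#' @param data analysis data frame with columns `literacy` (person score),
#'   `mode` (factor with reference level PBA), `sex_eff`, `teacher_eff`, and
#'   the criterion column; or a list of such frames / an `imputation_set`
#'   over the criterion columns.
#' @param criterion name of the criterion column.
#' @param weights optional case weights (not applied by default).
#' @return object of class `prediction_fit`: coefficient table with pooled
#'   standardized estimates, 95 percent CIs and significance flags, plus
#'   `r2`, `delta_r2`, `criterion`, `n`.
#' @export
fit_prediction_model <- function(data, criterion, weights = NULL) {
  copies <- if (inherits(data, "imputation_set")) data$copies
    else if (is.data.frame(data)) list(data) else data
  n <- nrow(copies[[1]])
  if (n == 0L) stop("empty analysis subsample")
  if (nlevels(droplevels(copies[[1]]$mode)) < 2L)
    stop("need at least two modes for prediction-bias analysis")
  fits <- lapply(copies, function(cp) {
    cp$mode <- droplevels(factor(cp$mode))
    if (!"PBA" %in% levels(cp$mode))
      stop("reference mode PBA absent from the subsample")
    cp$mode <- stats::relevel(cp$mode, "PBA")
    y <- cp[[criterion]]
    if (anyNA(y) || anyNA(cp$literacy))
      stop("criterion/literacy missing values must be imputed first")
    cp$y_z <- (y - mean(y)) / stats::sd(y)
    cp$lit_z <- (cp$literacy - mean(cp$literacy)) / stats::sd(cp$literacy)
    fml <- y_z ~ lit_z * mode + sex_eff + teacher_eff
    full <- if (is.null(weights)) stats::lm(fml, data = cp)
      else stats::lm(fml, data = cp, weights = weights)
    red <- stats::update(full, . ~ . - lit_z:mode)
    list(full = full,
         r2 = summary(full)$r.squared,
         delta_r2 = summary(full)$r.squared - summary(red)$r.squared)
  })
  terms <- names(stats::coef(fits[[1]]$full))
  k <- length(terms)
  coefs <- do.call(rbind, lapply(terms, function(tm) {
    est <- vapply(fits, function(f) stats::coef(f$full)[[tm]], 1.0)
    va <- vapply(fits, function(f) stats::vcov(f$full)[tm, tm], 1.0)
    p <- if (length(est) == 1L) suppressWarnings(rubin_pool(est, va,
                                                            dfcom = n - k))
         else rubin_pool(est, va, dfcom = n - k)
    data.frame(term = tm, estimate = p$estimate, se = p$se,
               ci_lower = p$ci[1], ci_upper = p$ci[2],
               significant = p$ci[1] > 0 | p$ci[2] < 0)
  }))
  structure(list(coefficients = coefs,
                 r2 = mean(vapply(fits, `[[`, 1.0, "r2")),
                 delta_r2 = mean(vapply(fits, `[[`, 1.0, "delta_r2")),
                 criterion = criterion, n = n, m = length(fits)),
            class = "prediction_fit")
}

#' @export
print.prediction_fit <- function(x, ...) {
  cat(sprintf("Prediction-bias regression: %s (n = %d, m = %d)\n",
              x$criterion, x$n, x$m))
  cf <- x$coefficients
  for (i in seq_len(nrow(cf)))
    cat(sprintf("  %-22s %6.2f%s [%5.2f, %5.2f]\n", cf$term[i],
                cf$estimate[i], ifelse(cf$significant[i], "*", " "),
                cf$ci_lower[i], cf$ci_upper[i]))
  cat(sprintf("  R2 = %.3f, Delta R2 (moderation block) = %.3f\n",
              x$r2, x$delta_r2))
  invisible(x)
}

#' Omega reliability of a criterion scale
#'
#' One-factor maximum likelihood fit (on listwise-complete rows) with
#' `omega = (sum lambda)^2 / ((sum lambda)^2 + sum uniquenesses)` on the
#' standardized scale. With exactly two items the loading is the square root
#' of their correlation.
#'
#' @param item_responses data frame or matrix of scale items (>= 2 columns).
#' @param label scale label carried into the report.
#' @return object of class `omega_report`: `label`, `omega`, `loadings`,
#'   `n_items`, `n`.
#' @export
omega_reliability <- function(item_responses, label = "scale") {
  X <- as.matrix(item_responses)
  X <- X[stats::complete.cases(X), , drop = FALSE]
  k <- ncol(X)
  if (k < 2L) stop("omega needs at least two items")
  if (k == 2L) {
    r <- stats::cor(X[, 1], X[, 2])
    lam <- rep(sqrt(max(r, 0)), 2L)
  } else {
    fa <- tryCatch(stats::factanal(X, factors = 1L),
                   error = function(e)
                     stop("one-factor fit failed: ", conditionMessage(e)))
    lam <- abs(as.numeric(fa$loadings))
  }
  uniq <- pmax(1 - lam^2, 1e-6)
  omega <- sum(lam)^2 / (sum(lam)^2 + sum(uniq))
  structure(list(label = label, omega = omega, loadings = lam,
                 n_items = k, n = nrow(X)),
            class = "omega_report")
}

#' @export
print.omega_report <- function(x, ...) {
  cat(sprintf("Omega reliability (%s): %.2f (%d items, n = %d)\n",
              x$label, x$omega, x$n_items, x$n))
  invisible(x)
}

#' Assemble the prediction-bias analysis frame
#'
#' Restricts to participants in the configured subsample flag, joins the
#' person literacy scores, effective mode, effect-coded sex and teacher
#' education, and the criterion columns.
#'
#' @param persons `person_estimates` (all groups combined).
#' @param modes filled mode records.
#' @param covariates covariate table (complete columns used for coding).
#' @param criteria criterion table from [simulate_criteria()].
#' @param subsample_flag covariate column restricting the analysis sample
#'   (`NULL` for all participants).
#' @return data frame ready for [fit_prediction_model()] (criterion columns
#'   may still contain missing values to be imputed).
#' @export
prediction_frame <- function(persons, modes, covariates, criteria,
                             subsample_flag = "natural_science") {
  part <- modes$effective_mode != "none" & !is.na(modes$effective_mode)
  keep <- part
  if (!is.null(subsample_flag)) {
    flag <- covariates[[subsample_flag]]
    flag[is.na(flag)] <- 0
    keep <- keep & flag == 1
  }
  ids <- modes$student_id[keep]
  df <- data.frame(
    student_id = ids,
    literacy = persons$theta[match(ids, persons$student_id)],
    mode = droplevels(modes$effective_mode[keep]),
    sex_eff = ifelse(covariates$gender[match(ids, covariates$student_id)] == 1,
                     0.5, -0.5),
    teacher_eff = ifelse(
      covariates$teacher_education[match(ids, covariates$student_id)] == 1,
      -0.5, 0.5)
  )
  crit_cols <- setdiff(names(criteria), "student_id")
  df[crit_cols] <- criteria[match(ids, criteria$student_id), crit_cols]
  df[!is.na(df$literacy), , drop = FALSE]
}
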