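# Multiple imputation by chained equations: column-by-column Gibbs-style
# updating with sequential regression trees for continuous variables
# (draws from the fitted leaf, Burgette-Reiter style) and polytomous
# regression draws for categorical variables, plus Rubin's rules with
# Barnard-Rubin small-sample degrees of freedom for pooling.

#' Multiple imputation by chained equations
#'
#' For each of `m` copies, missing cells are initialized by random draws from
#' each column's observed marginal and then updated column by column for
#' `n_iterations` sweeps. Continuous columns are imputed by a regression tree
#' on all other columns, drawing (with replacement) from the observed values
#' in the donor leaf; alternatively by Bayesian-style linear regression with
#' residual noise (`method = "norm"`). Categorical columns are imputed by
#' multinomial-logit draws; if the multinomial fit fails, the column falls
#' back to observed-frequency draws with a warning.
#'
#' @param table data frame; columns numeric or factor. An id column named
#'   `student_id` is carried along but never used as a predictor.
#' @param m number of completed copies.
#' @param n_iterations chained-equation sweeps per copy.
#' @param method_map optional named character vector mapping incomplete
#'   columns to `"tree"`, `"norm"` or `"polyreg"`; defaults to `"tree"` for
#'   numeric and `"polyreg"` for factor columns.
#' @param seed integer seed.
#' @param tree_control `rpart` control for tree imputation.
#' @return an object of class `imputation_set`: list with `copies` (list of
#'   `m` completed data frames), `mask` (logical missingness matrix), `m`,
#'   `n_iterations`, `seed`.
#' @export
chained_impute <- function(table, m = 20L, n_iterations = 10L,
                           method_map = NULL, seed = 1L,
                           tree_control = rpart::rpart.control(
                             cp = 1e-4, minbucket = 5L, maxdepth = 10L)) {
  stopifnot(m >= 1L, n_iterations >= 1L)
  id <- table[["student_id"]]
  dat <- table[setdiff(names(table), "student_id")]
  mask <- as.data.frame(lapply(dat, is.na))
  incomplete <- names(dat)[colSums(mask) > 0L]
  for (v in incomplete)
    if (all(is.na(dat[[v]])))
      stop("unimputable: column '", v, "' has no observed values")
  if (is.null(method_map)) {
    method_map <- vapply(dat[incomplete],
                         function(x) if (is.numeric(x)) "tree" else "polyreg",
                         character(1))
  } else {
    missing_methods <- setdiff(incomplete, names(method_map))
    if (length(missing_methods))
      stop("method_map does not cover: ", paste(missing_methods, collapse = ", "))
    method_map <- method_map[incomplete]
  }
  set.seed(seed)
  copies <- vector("list", m)
  for (copy in seq_len(m)) {
    cur <- dat
    # initial fill from the observed marginal of each column
    for (v in incomplete) {
      obs <- cur[[v]][!mask[[v]]]
      cur[[v]][mask[[v]]] <- sample(obs, sum(mask[[v]]), replace = TRUE)
    }
    if (length(incomplete)) {
      for (it in seq_len(n_iterations)) {
        for (v in incomplete) {
          cur[[v]] <- impute_column(cur, v, mask[[v]], method_map[[v]],
                                    tree_control)
        }
      }
    }
    if (!is.null(id)) cur <- cbind(student_id = id, cur)
    copies[[copy]] <- cur
  }
  structure(list(copies = copies, mask = mask, m = m,
                 n_iterations = n_iterations, seed = seed,
                 methods = method_map),
            class = "imputation_set")
}

impute_column <- function(cur, v, miss, method, tree_control) {
  y <- cur[[v]]
  rhs <- setdiff(names(cur), v)
  fml <- stats::reformulate(rhs, response = v)
  fit_data <- cur
  fit_data[[v]][miss] <- NA  # fit on observed rows only
  out <- y
  newdata <- cur[miss, rhs, drop = FALSE]
  if (method %in% c("tree")) {
    fit <- rpart::rpart(fml, data = fit_data[!miss, , drop = FALSE],
                        method = "anova", control = tree_control)
    # donor draw: sample observed values from the predicted leaf
    leaf_obs <- fit$where
    pred_leaf <- leaf_of(fit, newdata)
    obs_y <- y[!miss]
    for (lf in unique(pred_leaf)) {
      donors <- obs_y[leaf_obs == lf]
      if (!length(donors)) donors <- obs_y
      sel <- pred_leaf == lf
      out[miss][sel] <- sample(donors, sum(sel), replace = TRUE)
    }
  } else if (method == "norm") {
    fit <- stats::lm(fml, data = fit_data[!miss, , drop = FALSE])
    mu <- stats::predict(fit, newdata = newdata)
    out[miss] <- mu + stats::rnorm(sum(miss), 0, stats::sigma(fit))
  } else if (method == "polyreg") {
    probs <- tryCatch({
      fit <- nnet::multinom(fml, data = fit_data[!miss, , drop = FALSE],
                            trace = FALSE, maxit = 200L)
      p <- stats::predict(fit, newdata = newdata, type = "probs")
      if (is.null(dim(p))) p <- cbind(1 - p, p)  # two-level response
      p
    }, error = function(e) NULL)
    lv <- levels(factor(y[!miss]))
    if (is.null(probs)) {
      warning("multinomial fit failed for '", v,
              "'; falling back to observed-frequency draws")
      tb <- table(y[!miss])
      probs <- matrix(as.numeric(tb) / sum(tb), sum(miss), length(tb),
                      byrow = TRUE)
      lv <- names(tb)
    } else if (ncol(probs) == 2L && is.factor(y)) {
      lv <- levels(y[!miss, drop = TRUE])
    } else if (!is.null(colnames(probs))) {
      lv <- colnames(probs)
    }
    draw <- lv[draw_categories(probs) + 1L]
    if (is.factor(y)) {
      out[miss] <- factor(draw, levels = levels(y))
    } else {
      out[miss] <- as(draw, class(y))
    }
  } else {
    stop("unknown imputation method '", method, "'")
  }
  out
}

# leaf id of new observations in an rpart tree (matching fit$where coding)
leaf_of <- function(fit, newdata) {
  if (nrow(fit$frame) == 1L) return(rep(1L, nrow(newdata)))
  node <- rpart_predict_nodes(fit, newdata)
  match(node, as.integer(rownames(fit$frame)))
}

rpart_predict_nodes <- function(fit, newdata) {
  # row numbers of fit$frame are node numbers; descend manually
  preds <- stats::predict(fit, newdata = newdata)
  frame <- fit$frame
  leaves <- as.integer(rownames(frame))[frame$var == "<leaf>"]
  yval <- frame$yval[frame$var == "<leaf>"]
  # map each prediction to the leaf with that fitted value (unique per leaf
  # up to ties; ties share identical donor pools in expectation)
  leaves[match(preds, yval)]
}

#' Extract one completed copy
#'
#' @param imp an `imputation_set`.
#' @param i copy index.
#' @return the i-th completed data frame.
#' @export
complete_copy <- function(imp, i = 1L) {
  stopifnot(inherits(imp, "imputation_set"), i >= 1L, i <= imp$m)
  imp$copies[[i]]
}

#' @export
print.imputation_set <- function(x, ...) {
  cat(sprintf("Chained-equations imputation: m = %d copies, %d sweeps\n",
              x$m, x$n_iterations))
  inc <- names(x$methods)
  if (length(inc))
    cat("  imputed columns:",
        paste(sprintf("%s (%s)", inc, x$methods), collapse = ", "), "\n")
  else cat("  no missing values; copies identical to the input\n")
  invisible(x)
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Pooled estimate is the mean of the per-copy estimates; total variance is
#' the within-imputation mean plus `(1 + 1/m)` times the between-imputation
#' variance; degrees of freedom follow Barnard-Rubin when a complete-data df
#' is supplied and the classical large-sample formula otherwise.
#'
#' @param estimates numeric vector of per-copy estimates.
#' @param variances numeric vector of per-copy squared standard errors.
#' @param dfcom complete-data degrees of freedom (`Inf` for the classical
#'   formula).
#' @return list with `estimate`, `se`, `total_variance`, `within`, `between`,
#'   `df`, `ci` (95 percent), `m`.
#' @export
rubin_pool <- function(estimates, variances, dfcom = Inf) {
  stopifnot(length(estimates) == length(variances))
  m <- length(estimates)
  qbar <- mean(estimates)
  wbar <- mean(variances)
  if (m == 1L) {
    warning("m = 1: between-imputation variance undefined; total = within")
    se <- sqrt(wbar)
    return(list(estimate = qbar, se = se, total_variance = wbar,
                within = wbar, between = NA_real_, df = dfcom,
                ci = qbar + c(-1, 1) * stats::qt(0.975, min(dfcom, 1e6)) * se,
                m = m))
  }
  b <- stats::var(estimates)
  total <- wbar + (1 + 1 / m) * b
  if (b > 0) {
    r <- (1 + 1 / m) * b / wbar
    df_old <- (m - 1) * (1 + 1 / r)^2
  } else {
    df_old <- Inf
  }
  if (is.finite(dfcom) && is.finite(df_old)) {
    gamma <- (1 + 1 / m) * b / total
    df_obs <- (dfcom + 1) / (dfcom + 3) * dfcom * (1 - gamma)
    df <- 1 / (1 / df_old + 1 / df_obs)
  } else {
    df <- df_old
  }
  se <- sqrt(total)
  tcrit <- stats::qt(0.975, min(df, 1e6))
  list(estimate = qbar, se = se, total_variance = total, within = wbar,
       between = b, df = df, ci = qbar + c(-1, 1) * tcrit * se, m = m)
}
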