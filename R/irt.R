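# Propensity-weighted one-parameter IRT calibration (Rasch / partial credit)
# by marginal maximum likelihood with Gauss-Hermite quadrature and an EM
# algorithm; weighted maximum likelihood (Warm) person scores; empirical
# reliability; weighted mean-square (infit) item fit.
#
# Scale linking across mode groups relies on the design's identification:
# after propensity weighting, the latent distributions of the mode groups
# are exchangeable up to their variances, so all group means are fixed at 0.
# Step 1 fits a multi-group model with item parameters constrained equal
# across groups and group variances free; step 2 re-estimates the item
# parameters freely per group holding each group's latent distribution
# fixed. Group differences in the resulting test scoring functions are then
# attributable to measurement (mode) bias, which is what DTF quantifies.

as_response_matrix <- function(responses, item_names) {
  if (is.data.frame(responses)) {
    X <- as.matrix(responses[, item_names, drop = FALSE])
  } else {
    X <- as.matrix(responses)
  }
  storage.mode(X) <- "integer"
  X
}

# N x Q log-likelihood contributions and posterior over quadrature nodes
pcm_estep <- function(X, deltas, theta_q, log_wq) {
  N <- nrow(X); Q <- length(theta_q)
  LL <- matrix(log_wq, N, Q, byrow = TRUE)
  for (j in seq_len(ncol(X))) {
    logP <- log(pmax(pcm_probs(deltas[[j]], theta_q), 1e-300))  # Q x (K+1)
    lp <- t(logP)[X[, j] + 1L, , drop = FALSE]                  # N x Q
    if (anyNA(X[, j])) lp[is.na(lp)] <- 0
    LL <- LL + lp
  }
  mx <- LL[, 1L]
  for (q in seq_len(Q)[-1L]) mx <- pmax(mx, LL[, q])
  P <- exp(LL - mx)
  s <- rowSums(P)
  list(post = P / s, ll = mx + log(s))
}

# expected weighted category counts per item: list of Q x (K+1) matrices
pcm_counts <- function(X, wpost) {
  lapply(seq_len(ncol(X)), function(j) {
    K <- max(X[, j], na.rm = TRUE)
    R <- matrix(0, ncol(wpost), K + 1L)
    for (k in 0:K) {
      idx <- which(X[, j] == k)
      if (length(idx)) R[, k + 1L] <- colSums(wpost[idx, , drop = FALSE])
    }
    R
  })
}

# Partial M-step: damped Newton steps on the expected complete-data
# log-likelihood, which is concave in the step thresholds (exponential
# family). One step per EM cycle yields a standard generalized EM.
mstep_item <- function(delta, R, theta_q, n_newton = 1L) {
  K <- length(delta)
  if (ncol(R) != K + 1L) {
    R2 <- matrix(0, nrow(R), K + 1L)
    R2[, seq_len(ncol(R))] <- R
    R <- R2
  }
  nq <- rowSums(R)
  rge <- rev(cumsum(rev(colSums(R))))  # observed counts of X >= l, l = 0..K
  for (it in seq_len(n_newton)) {
    P <- pcm_probs(delta, theta_q)
    # S[, l] = P(X >= l | node q)
    S <- t(apply(P[, (K + 1L):1L, drop = FALSE], 1L, cumsum))[, K:1L,
                                                              drop = FALSE]
    if (K == 1L) S <- matrix(P[, 2L], ncol = 1L)
    g <- drop(nq %*% S) - rge[-1L]  # d loglik / d delta_l
    H <- matrix(0, K, K)
    for (l in seq_len(K)) for (m in l:K) {
      v <- -sum(nq * (S[, m] - S[, l] * S[, m]))
      H[l, m] <- H[m, l] <- v
    }
    step <- tryCatch(solve(H, g), error = function(e) g / diag(H))
    nrm <- sqrt(sum(step^2))
    if (nrm > 2) step <- step * 2 / nrm
    delta <- delta - step
  }
  # guard against divergence of thresholds for empty extreme categories
  pmin(pmax(delta, -12), 12)
}

new_item_params <- function(delta, bank, mu, sigma2, vcov, group, converged,
                            loglik, n_nodes, n) {
  structure(list(delta = delta, n_steps = bank$n_steps, weight = bank$weight,
                 names = bank$names, mu = mu, sigma2 = sigma2, vcov = vcov,
                 group = group, converged = converged, loglik = loglik,
                 n_nodes = n_nodes, n = n),
            class = "item_params")
}

#' @export
print.item_params <- function(x, ...) {
  cat(sprintf("One-parameter IRT calibration (%s): %d items, n = %d\n",
              if (is.null(x$group)) "single group" else x$group,
              length(x$delta), x$n))
  cat(sprintf("  latent N(%.3f, %.3f), %d quadrature nodes, %s\n",
              x$mu, x$sigma2, x$n_nodes,
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  invisible(x)
}

# analytic per-person score vectors for the step thresholds (and optionally
# the latent variance), used for the empirical-Fisher covariance
pcm_scores <- function(X, deltas, post, theta_q, sigma2 = NULL) {
  N <- nrow(X)
  npar <- sum(vapply(deltas, length, 1L))
  S <- matrix(0, N, npar + as.integer(!is.null(sigma2)))
  pos <- 0L
  for (j in seq_along(deltas)) {
    K <- length(deltas[[j]])
    P <- pcm_probs(deltas[[j]], theta_q)
    x <- X[, j]
    for (l in seq_len(K)) {
      Sl <- rowSums(P[, (l + 1L):(K + 1L), drop = FALSE])  # P(X >= l | q)
      sc <- drop(post %*% Sl) - as.numeric(x >= l)
      sc[is.na(x)] <- 0
      S[, pos + l] <- sc
    }
    pos <- pos + K
  }
  if (!is.null(sigma2)) {
    v2 <- drop(post %*% (theta_q^2))
    S[, npar + 1L] <- (v2 - sigma2) / (2 * sigma2^2)
  }
  S
}

#' Calibrate one group's item parameters
#'
#' Marginal maximum likelihood for the one-parameter (Rasch / partial
#' credit) model via Gauss-Hermite quadrature and EM, with each person's
#' log-likelihood contribution multiplied by its case (propensity) weight.
#' The latent distribution is `N(mu, sigma2)`; `sigma2` can be estimated
#' (`est_sigma = TRUE`) or held fixed, `mu` is always fixed (scale
#' identification). The asymptotic covariance of the step thresholds is the
#' inverse of the weighted empirical Fisher information (cross-product of
#' per-person score vectors).
#'
#' @param responses response data frame (or integer matrix) with the bank's
#'   item columns; categories `0..K_j`.
#' @param weights positive case weights (default 1).
#' @param bank item bank describing the columns.
#' @param mu,sigma2 latent mean and (initial) variance.
#' @param est_sigma estimate the latent variance alongside the items?
#' @param n_nodes Gauss-Hermite nodes.
#' @param maxit,tol EM iteration cap and parameter-change tolerance.
#' @param group optional group label.
#' @return an `item_params` object.
#' @export
fit_group_model <- function(responses, weights = NULL,
                            bank = default_item_bank(),
                            mu = 0, sigma2 = 1, est_sigma = FALSE,
                            n_nodes = 61L, maxit = 350L, tol = 1e-4,
                            group = NULL) {
  X <- as_response_matrix(responses, bank$names)
  keep <- rowSums(!is.na(X)) > 0L
  X <- X[keep, , drop = FALSE]
  N <- nrow(X)
  if (N == 0L) stop("empty calibration sample")
  w <- if (is.null(weights)) rep(1, N) else weights[keep]
  if (any(w <= 0)) stop("case weights must be positive")
  # items need at least two observed categories
  nobs_cat <- vapply(seq_len(ncol(X)), function(j)
    length(unique(stats::na.omit(X[, j]))), 1L)
  if (any(nobs_cat < 2L)) {
    drop_items <- bank$names[nobs_cat < 2L]
    warning("excluding item(s) with a single observed category: ",
            paste(drop_items, collapse = ", "))
    keep_j <- nobs_cat >= 2L
    bank <- list(n_steps = bank$n_steps[keep_j], weight = bank$weight[keep_j],
                 delta = bank$delta[keep_j], names = bank$names[keep_j])
    X <- X[, keep_j, drop = FALSE]
  }
  deltas <- lapply(bank$n_steps, function(k) seq(-0.5, 0.5, length.out = k))
  gh <- gauss_hermite(n_nodes)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    theta_q <- mu + sqrt(sigma2) * gh$nodes
    es <- pcm_estep(X, deltas, theta_q, log(gh$weights))
    wpost <- es$post * w
    Rj <- pcm_counts(X, wpost)
    new_deltas <- lapply(seq_along(deltas), function(j)
      mstep_item(deltas[[j]], Rj[[j]], theta_q))
    delta_change <- max(abs(unlist(new_deltas) - unlist(deltas)))
    sig_change <- 0
    if (est_sigma) {
      v2 <- drop(es$post %*% (theta_q^2))
      new_sigma2 <- sum(w * v2) / sum(w)
      sig_change <- abs(new_sigma2 - sigma2)
      sigma2 <- new_sigma2
    }
    deltas <- new_deltas
    if (max(delta_change, sig_change) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("EM did not converge in ", maxit, " iterations (last change ",
            signif(delta_change, 3), ")")
  theta_q <- mu + sqrt(sigma2) * gh$nodes
  es <- pcm_estep(X, deltas, theta_q, log(gh$weights))
  S <- pcm_scores(X, deltas, es$post, theta_q,
                  sigma2 = if (est_sigma) sigma2 else NULL)
  info <- crossprod(S * w, S)
  V <- tryCatch(solve(info), error = function(e) MASS::ginv(info))
  npar <- sum(bank$n_steps)
  bank_out <- bank
  bank_out$delta <- deltas
  out <- new_item_params(deltas, bank_out, mu, sigma2,
                         vcov = V[seq_len(npar), seq_len(npar), drop = FALSE],
                         group = group, converged = converged,
                         loglik = sum(w * es$ll), n_nodes = n_nodes, n = N)
  if (est_sigma) out$sigma2_se <- sqrt(max(V[npar + 1L, npar + 1L], 0))
  out
}

#' Concurrent multi-group calibration (equal items, free variances)
#'
#' Fits the one-parameter model to several groups at once with item
#' parameters constrained equal across groups, all latent means fixed at 0,
#' and a free latent variance per group. Standard errors for the group
#' variances come from the joint weighted empirical Fisher information of
#' all parameters.
#'
#' @inheritParams fit_group_model
#' @param group factor of group membership, one entry per response row.
#' @return list with `delta` (common thresholds), `sigma2` (named vector),
#'   `sigma2_se`, `sigma2_ci` (normal-approximation 95 percent bounds),
#'   `converged`, `loglik`.
#' @export
fit_multigroup_model <- function(responses, group, weights = NULL,
                                 bank = default_item_bank(),
                                 n_nodes = 61L, maxit = 350L, tol = 1e-4) {
  X <- as_response_matrix(responses, bank$names)
  group <- droplevels(factor(group))
  keep <- rowSums(!is.na(X)) > 0L
  X <- X[keep, , drop = FALSE]; group <- group[keep]
  w <- if (is.null(weights)) rep(1, nrow(X)) else weights[keep]
  G <- nlevels(group)
  gidx <- lapply(levels(group), function(g) which(group == g))
  deltas <- lapply(bank$n_steps, function(k) seq(-0.5, 0.5, length.out = k))
  sigma2 <- rep(1, G)
  gh <- gauss_hermite(n_nodes)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    theta_g <- lapply(seq_len(G), function(g) sqrt(sigma2[g]) * gh$nodes)
    es_g <- vector("list", G)
    Rj_all <- NULL
    for (g in seq_len(G)) {
      es <- pcm_estep(X[gidx[[g]], , drop = FALSE], deltas, theta_g[[g]],
                      log(gh$weights))
      es_g[[g]] <- es
      Rj <- pcm_counts(X[gidx[[g]], , drop = FALSE], es$post * w[gidx[[g]]])
      Rj_all <- if (is.null(Rj_all)) Rj
        else lapply(seq_along(Rj), function(j) {
          a <- Rj_all[[j]]; b <- Rj[[j]]
          if (ncol(a) < ncol(b)) { a2 <- matrix(0, nrow(a) , ncol(b)); a2[, seq_len(ncol(a))] <- a; a <- a2 }
          if (ncol(b) < ncol(a)) { b2 <- matrix(0, nrow(b), ncol(a)); b2[, seq_len(ncol(b))] <- b; b <- b2 }
          rbind(a, b)
        })
    }
    theta_all <- unlist(theta_g)
    new_deltas <- lapply(seq_along(deltas), function(j)
      mstep_item(deltas[[j]], Rj_all[[j]], theta_all))
    new_sigma2 <- vapply(seq_len(G), function(g) {
      v2 <- drop(es_g[[g]]$post %*% (theta_g[[g]]^2))
      sum(w[gidx[[g]]] * v2) / sum(w[gidx[[g]]])
    }, 1.0)
    change <- max(abs(unlist(new_deltas) - unlist(deltas)),
                  abs(new_sigma2 - sigma2))
    deltas <- new_deltas
    sigma2 <- new_sigma2
    if (change < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("multi-group EM did not converge in ", maxit, " iterations")
  # joint empirical Fisher: common deltas + per-group sigma2
  npar <- sum(bank$n_steps)
  Sfull <- matrix(0, nrow(X), npar + G)
  ll <- 0
  for (g in seq_len(G)) {
    th <- sqrt(sigma2[g]) * gh$nodes
    es <- pcm_estep(X[gidx[[g]], , drop = FALSE], deltas, th, log(gh$weights))
    Sg <- pcm_scores(X[gidx[[g]], , drop = FALSE], deltas, es$post, th,
                     sigma2 = sigma2[g])
    Sfull[gidx[[g]], seq_len(npar)] <- Sg[, seq_len(npar)]
    Sfull[gidx[[g]], npar + g] <- Sg[, npar + 1L]
    ll <- ll + sum(w[gidx[[g]]] * es$ll)
  }
  info <- crossprod(Sfull * w, Sfull)
  V <- tryCatch(solve(info), error = function(e) MASS::ginv(info))
  s2_se <- sqrt(pmax(diag(V)[npar + seq_len(G)], 0))
  names(sigma2) <- names(s2_se) <- levels(group)
  list(delta = deltas, sigma2 = sigma2, sigma2_se = s2_se,
       sigma2_ci = cbind(lower = sigma2 - 1.96 * s2_se,
                         upper = sigma2 + 1.96 * s2_se),
       converged = converged, loglik = ll, n = nrow(X),
       groups = levels(group))
}

#' Two-step mode-group calibration on a common scale
#'
#' Step 1: concurrent multi-group fit (equal items, latent means fixed at 0,
#' free group variances) yielding the group latent distributions on a common
#' scale. Step 2: per-group free item calibration holding each group's
#' latent distribution fixed, yielding the group-specific test scoring
#' functions (with asymptotic covariances) that the DTF statistics compare.
#'
#' @param responses response data frame including `student_id`.
#' @param modes filled mode records aligned with `responses`.
#' @param weights optional `propensity_weights` (or a numeric vector aligned
#'   with the response rows).
#' @inheritParams fit_group_model
#' @return object of class `mode_calibration`: list with `groups` (named list
#'   of `item_params`), `variance_table` (latent variances with 95 percent
#'   CIs), and the step-1 `multigroup` fit.
#' @export
calibrate_modes <- function(responses, modes, weights = NULL,
                            bank = default_item_bank(), n_nodes = 61L,
                            maxit = 350L, tol = 1e-4) {
  part <- which(modes$effective_mode != "none" & !is.na(modes$effective_mode))
  X <- responses[match(modes$student_id[part], responses$student_id), ,
                 drop = FALSE]
  grp <- droplevels(modes$effective_mode[part])
  w <- rep(1, length(part))
  if (!is.null(weights)) {
    if (inherits(weights, "propensity_weights") || is.data.frame(weights)) {
      w <- weights$weight[match(modes$student_id[part], weights$student_id)]
      w[is.na(w)] <- 1
    } else w <- weights
  }
  step1 <- fit_multigroup_model(X, grp, w, bank, n_nodes, maxit, tol)
  groups <- list()
  for (g in levels(grp)) {
    sel <- grp == g
    # free items and free variance per group; the mean fixed at 0 carries
    # the linking, the step-1 variance serves as the starting value
    groups[[g]] <- fit_group_model(X[sel, , drop = FALSE], w[sel], bank,
                                   mu = 0, sigma2 = step1$sigma2[[g]],
                                   est_sigma = TRUE, n_nodes = n_nodes,
                                   maxit = maxit, tol = tol, group = g)
  }
  s2 <- vapply(groups, `[[`, 1.0, "sigma2")
  s2se <- vapply(groups, `[[`, 1.0, "sigma2_se")
  vt <- data.frame(group = names(groups), variance = unname(s2),
                   ci_lower = unname(s2 - 1.96 * s2se),
                   ci_upper = unname(s2 + 1.96 * s2se))
  structure(list(groups = groups, variance_table = vt, multigroup = step1),
            class = "mode_calibration")
}

#' @export
print.mode_calibration <- function(x, ...) {
  cat("Two-step mode-group calibration\n")
  vt <- x$variance_table
  for (i in seq_len(nrow(vt)))
    cat(sprintf("  %-10s variance %.2f [%.2f, %.2f]\n", vt$group[i],
                vt$variance[i], vt$ci_lower[i], vt$ci_upper[i]))
  invisible(x)
}

# summed conditional moments of the response vector at person-specific theta
test_moments <- function(params, theta, X = NULL) {
  J <- length(params$delta)
  E <- I <- M3 <- numeric(length(theta))
  for (j in seq_len(J)) {
    mo <- pcm_moments(params$delta[[j]], theta)
    if (!is.null(X)) {
      obs <- !is.na(X[, j])
      E <- E + ifelse(obs, mo$e, 0)
      I <- I + ifelse(obs, mo$v, 0)
      M3 <- M3 + ifelse(obs, mo$m3, 0)
    } else {
      E <- E + mo$e; I <- I + mo$v; M3 <- M3 + mo$m3
    }
  }
  list(e = E, i = I, m3 = M3)
}

#' Weighted maximum likelihood (Warm) person scores
#'
#' Maximizes the Warm-penalized likelihood `l(theta) + log(I(theta)) / 2`
#' per person, by a coarse grid scan followed by Newton iterations on the
#' penalized score equation `r - E(theta) + I'(theta) / (2 I(theta)) = 0`
#' (with `r` the raw category score over observed items). Estimates are
#' finite for perfect and zero scores; the standard error is
#' `1 / sqrt(I(theta_hat))`.
#'
#' @param responses response data frame or matrix for one calibrated group.
#' @param params the group's `item_params`.
#' @param bounds search interval on the latent scale.
#' @return data frame of class `person_estimates`: `student_id` (if
#'   available), `theta`, `se`, `raw_score` (weighted), `n_items`.
#' @export
estimate_wle <- function(responses, params, bounds = c(-8, 8)) {
  X <- as_response_matrix(responses, params$names)
  ids <- if (is.data.frame(responses) && "student_id" %in% names(responses))
    responses$student_id else seq_len(nrow(X))
  n_obs <- rowSums(!is.na(X))
  est <- rep(NA_real_, nrow(X)); se <- rep(NA_real_, nrow(X))
  act <- which(n_obs > 0L)
  if (length(act)) {
    Xa <- X[act, , drop = FALSE]
    r <- rowSums(Xa, na.rm = TRUE)
    # coarse penalized-likelihood grid scan for starting values
    grid <- seq(bounds[1], bounds[2], by = 0.25)
    pen <- matrix(0, length(act), length(grid))
    for (j in seq_along(params$delta)) {
      logP <- log(pmax(pcm_probs(params$delta[[j]], grid), 1e-300))
      lp <- t(logP)[Xa[, j] + 1L, , drop = FALSE]
      if (anyNA(Xa[, j])) lp[is.na(lp)] <- 0
      pen <- pen + lp
    }
    info_grid <- test_moments(params, grid)$i
    pen <- pen + matrix(0.5 * log(info_grid), length(act), length(grid),
                        byrow = TRUE)
    th <- grid[max.col(pen, ties.method = "first")]
    warm_score <- function(theta) {
      mo <- test_moments(params, theta, Xa)
      r - mo$e + mo$m3 / (2 * mo$i)
    }
    h <- 1e-4
    for (iter in 1:25) {
      s0 <- warm_score(th)
      d <- (warm_score(th + h) - warm_score(th - h)) / (2 * h)
      d[!is.finite(d) | d > -1e-8] <- -1e-8
      step <- pmin(pmax(s0 / d, -0.75), 0.75)
      th <- pmin(pmax(th - step, bounds[1]), bounds[2])
      if (max(abs(step)) < 1e-8) break
    }
    est[act] <- th
    se[act] <- 1 / sqrt(test_moments(params, th, Xa)$i)
  }
  out <- data.frame(student_id = ids, theta = est, se = se,
                    raw_score = drop(ifelse(is.na(X), 0, X) %*% params$weight),
                    n_items = n_obs)
  out$raw_score[n_obs == 0L] <- NA_real_
  class(out) <- c("person_estimates", "data.frame")
  out
}

#' Empirical (WLE-based) reliability
#'
#' `1 - mean(SE^2) / var(theta_hat)`, optionally case-weighted.
#'
#' @param persons a `person_estimates` data frame.
#' @param weights optional positive case weights.
#' @return reliability scalar.
#' @export
empirical_reliability <- function(persons, weights = NULL) {
  ok <- is.finite(persons$theta)
  if (sum(ok) < 2L) stop("need at least two person estimates")
  th <- persons$theta[ok]; s2 <- persons$se[ok]^2
  w <- if (is.null(weights)) rep(1, sum(ok)) else weights[ok]
  m <- sum(w * th) / sum(w)
  v <- sum(w * (th - m)^2) / sum(w)
  if (v <= 0) stop("zero variance of person estimates; reliability undefined")
  1 - sum(w * s2) / sum(w) / v
}

#' Weighted mean-square (infit) item fit
#'
#' Information-weighted mean of squared residuals per item, evaluated at the
#' WLE person scores: `sum_i w_i (x_ij - E_ij)^2 / sum_i w_i W_ij` with
#' `E_ij` and `W_ij` the model-implied conditional mean and variance.
#' Values below 1.20 are flagged acceptable.
#'
#' @param responses response data frame or matrix.
#' @param params the group's `item_params`.
#' @param persons matching `person_estimates`.
#' @param weights optional case weights.
#' @param cutoff acceptability threshold.
#' @return data frame: `item`, `infit`, `acceptable`.
#' @export
infit_wms <- function(responses, params, persons, weights = NULL,
                      cutoff = 1.20) {
  X <- as_response_matrix(responses, params$names)
  ok <- is.finite(persons$theta)
  X <- X[ok, , drop = FALSE]
  th <- persons$theta[ok]
  w <- if (is.null(weights)) rep(1, sum(ok)) else weights[ok]
  out <- lapply(seq_along(params$delta), function(j) {
    obs <- !is.na(X[, j])
    if (!any(obs)) return(NULL)
    mo <- pcm_moments(params$delta[[j]], th[obs])
    infit <- sum(w[obs] * (X[obs, j] - mo$e)^2) / sum(w[obs] * mo$v)
    data.frame(item = params$names[j], infit = infit,
               acceptable = infit < cutoff)
  })
  do.call(rbind, out)
}
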