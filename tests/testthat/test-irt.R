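test_that("known item parameters are recovered from simulated data", {
  set.seed(201)
  bank <- tiny_bank(n_dich = 12, n_poly = 8)
  theta <- rnorm(2000)
  X <- draw_bank_responses(theta, bank)
  fit <- fit_group_model(X, bank = bank, mu = 0, sigma2 = 1,
                         est_sigma = TRUE)
  expect_true(fit$converged)
  rmse <- sqrt(mean((unlist(fit$delta) - unlist(bank$delta))^2))
  expect_lt(rmse, 0.1)
  expect_lt(abs(fit$sigma2 - 1), 0.1)
  # asymptotic covariance is symmetric PSD with sane scale
  expect_equal(fit$vcov, t(fit$vcov), tolerance = 1e-8)
  ev <- eigen(fit$vcov, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)
  expect_lt(max(sqrt(diag(fit$vcov))), 0.5)
})

test_that("weights act as a pseudo-likelihood: scale invariance and
           duplication identities hold", {
  set.seed(202)
  bank <- tiny_bank(n_dich = 6, n_poly = 2)
  X <- draw_bank_responses(rnorm(400), bank)
  f1 <- fit_group_model(X, bank = bank)
  f2 <- fit_group_model(X, weights = rep(2.5, 400), bank = bank)
  expect_equal(unlist(f1$delta), unlist(f2$delta), tolerance = 1e-6)
  # duplicating every person at half weight changes nothing
  f3 <- fit_group_model(rbind(X, X), weights = rep(0.5, 800), bank = bank)
  expect_equal(unlist(f1$delta), unlist(f3$delta), tolerance = 1e-6)
})

test_that("degenerate items and empty samples are handled", {
  bank <- tiny_bank(n_dich = 4, n_poly = 0)
  X <- draw_bank_responses(rnorm(150), bank)
  X[, 2] <- 1L  # constant item
  expect_warning(fit <- fit_group_model(X, bank = bank),
                 "single observed category")
  expect_length(fit$delta, 3L)
  expect_error(fit_group_model(X[0, , drop = FALSE], bank = bank), "empty")
  expect_error(fit_group_model(X, weights = rep(0, 150), bank = bank),
               "positive")
})

test_that("WLE scores are symmetric, finite at perfect scores, and match
           the independent grid oracle", {
  b0 <- list(n_steps = rep(1L, 10), weight = rep(1, 10),
             delta = as.list(rep(0, 10)),
             names = sprintf("i%02d", 1:10))
  pars <- make_params(b0)
  # half correct on a symmetric test: score equation balances at zero
  x_half <- c(rep(1L, 5), rep(0L, 5))
  est <- estimate_wle(matrix(x_half, 1, byrow = TRUE,
                             dimnames = list(NULL, b0$names)), pars)
  expect_equal(est$theta, 0, tolerance = 1e-6)
  # perfect and zero scores stay finite (defining Warm property)
  ext <- estimate_wle(rbind(rep(1L, 10), rep(0L, 10),
                            deparse.level = 0) |>
                        `colnames<-`(b0$names), pars)
  expect_true(all(is.finite(ext$theta)))
  expect_lt(max(abs(ext$theta)), 8)
  # all-missing rows are flagged, not estimated
  xm <- matrix(NA_integer_, 1, 10, dimnames = list(NULL, b0$names))
  expect_true(is.na(estimate_wle(xm, pars)$theta))
  # random patterns against the brute-force penalized-likelihood oracle
  set.seed(203)
  bank <- tiny_bank(n_dich = 8, n_poly = 4)
  pars2 <- make_params(bank)
  X <- draw_bank_responses(rnorm(25), bank)
  est2 <- estimate_wle(X, pars2)
  for (i in seq_len(nrow(X)))
    expect_equal(est2$theta[i], oracle_wle(X[i, ], bank), tolerance = 1e-4)
})

test_that("empirical reliability follows its defining formula and grows
           with test length", {
  pe <- structure(data.frame(student_id = 1:4, theta = c(-1, 0, 1, 2),
                             se = rep(1e-6, 4)),
                  class = c("person_estimates", "data.frame"))
  expect_equal(empirical_reliability(pe), 1, tolerance = 1e-6)
  v <- stats::var(c(-1, 0, 1, 2)) * 3 / 4
  pe$se <- rep(sqrt(v), 4)
  expect_equal(empirical_reliability(pe), 0, tolerance = 1e-10)
  pe$theta <- rep(1, 4)
  expect_error(empirical_reliability(pe), "zero variance")
  # longer tests are more reliable
  set.seed(204)
  theta <- rnorm(600)
  short_bank <- tiny_bank(n_dich = 6, n_poly = 0)
  long_bank <- tiny_bank(n_dich = 24, n_poly = 0)
  rel <- vapply(list(short_bank, long_bank), function(b) {
    X <- draw_bank_responses(theta, b)
    fit <- fit_group_model(X, bank = b)
    empirical_reliability(estimate_wle(X, fit))
  }, 1.0)
  expect_gt(rel[2], rel[1])
})

test_that("infit is near one for model-consistent data, below one for
           deterministic data, and flags at the 1.20 cut", {
  set.seed(205)
  bank <- tiny_bank(n_dich = 20, n_poly = 0)
  theta <- rnorm(2000)
  X <- draw_bank_responses(theta, bank)
  fit <- fit_group_model(X, bank = bank)
  pe <- estimate_wle(X, fit)
  rep1 <- infit_wms(X, fit, pe)
  expect_true(all(rep1$infit > 0.9 & rep1$infit < 1.1))
  expect_true(all(rep1$acceptable == (rep1$infit < 1.20)))
  # Guttman (deterministic) responses overfit: infit below one
  Xg <- vapply(seq_along(bank$delta),
               function(j) as.integer(theta > bank$delta[[j]]),
               integer(2000))
  colnames(Xg) <- bank$names
  peg <- estimate_wle(Xg, make_params(bank))
  repg <- infit_wms(Xg, make_params(bank), peg)
  expect_true(all(repg$infit < 1))
})

test_that("multi-group calibration reproduces generated mode shifts on the
           common scale", {
  set.seed(206)
  bank <- tiny_bank(n_dich = 10, n_poly = 5)
  shifts <- c(A = 0, B = 0.3)
  X <- rbind(draw_bank_responses(rnorm(900), bank, shift = 0),
             draw_bank_responses(rnorm(900), bank, shift = 0.3))
  grp <- factor(rep(c("A", "B"), each = 900))
  colnames(X) <- bank$names
  df <- as.data.frame(X)
  df$student_id <- seq_len(nrow(df))
  modes <- data.frame(student_id = df$student_id,
                      effective_mode = grp)
  cal_groups <- list(
    A = fit_group_model(X[grp == "A", ], bank = bank, est_sigma = TRUE),
    B = fit_group_model(X[grp == "B", ], bank = bank, est_sigma = TRUE))
  gap <- mean(unlist(cal_groups$B$delta)) - mean(unlist(cal_groups$A$delta))
  expect_lt(abs(gap - 0.3), 0.1)
  # the concurrent step gives near-unit variances for both groups
  mg <- fit_multigroup_model(X, grp, bank = bank)
  expect_lt(max(abs(mg$sigma2 - 1)), 0.15)
})
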