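test_that("seeded generation is reproducible end to end", {
  cfg <- small_config(seed = 11)
  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  expect_identical(s1$population, s2$population)
  expect_identical(s1$modes, s2$modes)
  expect_identical(s1$responses, s2$responses)
  expect_identical(s1$theta, s2$theta)
  expect_identical(s1$criteria, s2$criteria)
})

test_that("covariate marginals and missingness behave as configured", {
  # zero missingness leaves the mask empty
  cb <- default_codebook()
  cb$missing_rate <- 0
  cfg0 <- small_config(codebook = cb)
  expect_false(anyNA(generate_population(cfg0)))
  # binary share within 3 binomial SEs at the full design size
  cfg <- sim_config(seed = 3)
  pop <- generate_population(cfg)
  p <- 0.61; n <- cfg$n_total
  se <- sqrt(p * (1 - p) / n)
  share <- mean(attr(pop, "complete")$gender)
  expect_lt(abs(share - p), 3 * se)
  # masking only hits declared columns, and the complete table keeps all
  miss_cols <- names(pop)[vapply(pop, anyNA, TRUE)]
  declared <- cfg$codebook$name[cfg$codebook$missing_rate > 0]
  expect_true(all(miss_cols %in% declared))
  expect_false(anyNA(attr(pop, "complete")))
  # observed missing rates near the configured marginals
  for (v in declared) {
    r <- cfg$codebook$missing_rate[cfg$codebook$name == v]
    expect_lt(abs(mean(is.na(pop[[v]])) - r), 4 * sqrt(r * (1 - r) / n))
  }
})

test_that("mode assignment has exact sizes and is independent of covariates", {
  cfg <- sim_config(seed = 2)
  pop <- generate_population(cfg)
  modes <- assign_modes(pop, cfg)
  expect_equal(as.integer(table(modes$assigned_mode)), c(5371L, 3431L, 8671L))
  # no association between a covariate and the arm
  chi <- suppressWarnings(stats::chisq.test(
    table(attr(pop, "complete")$gender, modes$assigned_mode)))
  expect_gt(chi$p.value, 0.001)
  # tiny edge case: one student per arm
  cfg3 <- sim_config(n_total = 3, mode_split = c(PBA = 1, CBA = 1, WBA = 1))
  m3 <- assign_modes(generate_population(cfg3), cfg3)
  expect_equal(sort(as.character(m3$assigned_mode)), c("CBA", "PBA", "WBA"))
})

test_that("participation hits the calibrated target rates and honours flags", {
  cfg <- sim_config(seed = 5)
  pop <- generate_population(cfg)
  modes <- simulate_participation(assign_modes(pop, cfg), pop, cfg)
  rates <- tabulate_response_rates(modes)
  for (i in seq_len(nrow(rates))) {
    target <- cfg$target_rates[[rates$mode[i]]]
    n <- rates$assigned[i]
    se <- sqrt(target * (1 - target) / n)
    expect_lt(abs(rates$rate_percent[i] / 100 - target), 3 * se)
  }
  # switch offers go only to supervised first-stage nonresponders
  off <- modes$offered_switch
  expect_true(all(modes$assigned_mode[off] %in% c("PBA", "CBA")))
  expect_false(any(modes$participated_first_stage[off]))
  # exactly one effective mode or none
  eff <- as.character(modes$effective_mode)
  expect_true(all(eff %in% c("PBA", "CBA", "WBA", "WBA_switch", "none")))
  expect_equal(eff == "WBA_switch",
               !is.na(modes$participated_switch) & modes$participated_switch)
})

test_that("with zero slopes participation is independent of covariates", {
  slopes <- lapply(default_participation_slopes(), function(s) s * 0)
  cfg <- sim_config(n_total = 8000,
                    mode_split = c(PBA = 1000, CBA = 1000, WBA = 6000),
                    participation_slopes = slopes, seed = 17)
  pop <- generate_population(cfg)
  modes <- simulate_participation(assign_modes(pop, cfg), pop, cfg)
  idx <- modes$assigned_mode == "WBA"
  fit <- stats::glm(modes$participated_first_stage[idx] ~
                      attr(pop, "complete")$gender[idx],
                    family = stats::binomial())
  ci <- suppressMessages(stats::confint(fit))["attr(pop, \"complete\")$gender[idx]", ]
  expect_gt(ci[2], 0)
  expect_lt(ci[1], 0)
})

test_that("responses follow the one-parameter model with mode shifts", {
  # Rasch identity at theta = difficulty
  expect_equal(pcm_probs(0, 0)[1, 2], 0.5)
  expect_equal(drop(pcm_probs(1.3, 1.3)), c(0.5, 0.5))
  # nonparticipants are all-missing, participants fully observed
  cfg <- small_config(seed = 23)
  st <- generate_study(cfg)
  X <- as.matrix(st$responses[, -1])
  part <- st$modes$effective_mode != "none"
  expect_true(all(is.na(X[!part, ])))
  expect_false(anyNA(X[part, ]))
  # weighted scores never exceed the 36-point maximum
  sc <- score_responses(st$responses, cfg$item_bank)
  expect_lte(max(sc, na.rm = TRUE), 36)
  expect_gte(min(sc, na.rm = TRUE), 0)
})

test_that("a positive mode shift lowers expected raw scores as the
           integration oracle predicts", {
  bank <- tiny_bank()
  cfg <- sim_config(n_total = 6000,
                    mode_split = c(PBA = 3000, CBA = 100, WBA = 2900),
                    target_rates = c(PBA = 0.95, CBA = 0.5, WBA = 0.95,
                                     WBA_switch = 0.5),
                    item_bank = bank,
                    mode_shift = c(PBA = 0, CBA = 0, WBA = 0.3,
                                   WBA_switch = 0.3),
                    careless_rate = c(PBA = 0, CBA = 0, WBA = 0,
                                      WBA_switch = 0),
                    var_theta = 1, seed = 31)
  st <- generate_study(cfg)
  sc <- score_responses(st$responses, bank)
  m_pba <- mean(sc[st$modes$effective_mode == "PBA"])
  m_wba <- mean(sc[st$modes$effective_mode == "WBA"])
  expect_gt(m_pba, m_wba)
  # oracle: expected weighted score by integrating TS over N(0, 1)
  exp_score <- function(shift) {
    g <- seq(-6, 6, length.out = 401)
    b <- bank; b$delta <- lapply(b$delta, function(d) d + shift)
    ts <- vapply(g, function(t) oracle_ts(b, t), 1.0)
    w <- stats::dnorm(g); sum(ts * w) / sum(w)
  }
  expect_lt(abs(m_pba - exp_score(0)), 0.2)
  expect_lt(abs(m_wba - exp_score(0.3)), 0.2)
})

test_that("fully careless responding destroys item-total correlations", {
  cfg <- sim_config(n_total = 2000,
                    mode_split = c(PBA = 100, CBA = 100, WBA = 1800),
                    target_rates = c(PBA = 0.9, CBA = 0.9, WBA = 0.9,
                                     WBA_switch = 0.5),
                    careless_rate = c(PBA = 0, CBA = 0, WBA = 1,
                                      WBA_switch = 1),
                    seed = 41)
  st <- generate_study(cfg)
  sel <- st$modes$effective_mode == "WBA"
  X <- as.matrix(st$responses[sel, -1])
  sc <- rowSums(X)
  cors <- apply(X, 2, function(x) stats::cor(x, sc - x))
  expect_lt(max(abs(cors)), 0.1)
})

test_that("criterion generation respects its null and factor structure", {
  cfg <- small_config(seed = 51)
  # null slopes: criterion uncorrelated with proficiency
  cm <- default_criterion_models()
  cm$gpa$slope <- 0
  cm$gpa$moderation[] <- 0
  cfg_null <- small_config(n_total = 4000,
                           mode_split = c(PBA = 2000, CBA = 1000, WBA = 1000),
                           criterion_models = cm, seed = 52)
  st <- generate_study(cfg_null)
  part <- st$modes$effective_mode != "none"
  r <- stats::cor(st$criteria$gpa[part], st$theta[part],
                  use = "complete.obs")
  expect_lt(abs(r), 0.06)
  # unknown mode key in the moderation map is a configuration error
  cm2 <- default_criterion_models()
  names(cm2$gpa$moderation)[1] <- "XXX"
  cfg_bad <- small_config(criterion_models = cm2, seed = 53)
  pop <- generate_population(cfg_bad)
  modes <- simulate_participation(assign_modes(pop, cfg_bad), pop, cfg_bad)
  th <- stats::rnorm(nrow(pop))
  expect_error(simulate_criteria(modes, th, pop, cfg_bad),
               "unknown mode key")
  # only participants carry criteria
  st2 <- generate_study(cfg)
  part2 <- st2$modes$effective_mode != "none"
  expect_true(all(is.na(st2$criteria$self_concept[!part2])))
})

test_that("generated scale indicators reproduce the closed-form omega", {
  lam <- 0.78; k <- 4
  cm <- default_criterion_models()
  cfg <- sim_config(n_total = 12000,
                    mode_split = c(PBA = 11800, CBA = 100, WBA = 100),
                    target_rates = c(PBA = 0.95, CBA = 0.5, WBA = 0.5,
                                     WBA_switch = 0.5),
                    criterion_missing_rate = 0, seed = 61)
  st <- generate_study(cfg)
  items <- st$criteria[, sprintf("self_concept_i%d", 1:k)]
  om <- omega_reliability(items)
  closed <- (k * lam)^2 / ((k * lam)^2 + k * (1 - lam^2))
  expect_lt(abs(om$omega - closed), 0.02)
})

test_that("written studies round-trip through CSV with a manifest", {
  cfg <- small_config(n_total = 300, mode_split = c(PBA = 100, CBA = 100,
                                                    WBA = 100), seed = 71)
  st <- generate_study(cfg)
  d <- withr::local_tempdir()
  man <- write_study(st, d)
  expect_true(all(file.exists(file.path(
    d, c("covariates.csv", "modes.csv", "responses.csv", "criteria.csv",
         "manifest.json")))))
  expect_equal(man$seed, 71L)
  back <- utils::read.csv(file.path(d, "responses.csv"))
  expect_equal(dim(back), dim(st$responses))
})
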