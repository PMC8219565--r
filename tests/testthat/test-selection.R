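test_that("the propensity weight formula is exact on all paths", {
  expect_equal(propensity_weight("PBA", 0.5), 2)
  expect_equal(propensity_weight("CBA", 0.25), 4)
  expect_equal(propensity_weight("WBA", 1), 1)
  # switch path: nonresponse probability times switch participation, inverted
  expect_equal(propensity_weight("switch_from_PBA", 0.8, 0.5), 10)
  expect_equal(propensity_weight("switch_from_CBA", 0.5, 0.5), 4)
})

test_that("response-rate tabulation divides and rounds as reported", {
  rec <- make_mode_records(assigned = c(PBA = 5371, CBA = 3431, WBA = 8671),
                           participated = c(PBA = 1374, CBA = 623,
                                            WBA = 4701),
                           switch_participated = 1744)
  tab <- tabulate_response_rates(rec)
  expect_equal(tab$rate_percent, c(25.6, 18.2, 54.2, 25.6))
  # zero participation gives 0.0 percent
  rec0 <- make_mode_records(assigned = c(PBA = 10, CBA = 10, WBA = 10),
                            participated = c(PBA = 0, CBA = 5, WBA = 5))
  expect_equal(tabulate_response_rates(rec0)$rate_percent[1], 0)
})

test_that("known selection slopes are recovered by the pooled logits", {
  cfg <- sim_config(n_total = 9000,
                    mode_split = c(PBA = 500, CBA = 500, WBA = 8000),
                    seed = 101)
  pop <- generate_population(cfg)
  modes <- simulate_participation(assign_modes(pop, cfg), pop, cfg)
  imp <- chained_impute(pop, m = 2, n_iterations = 2, seed = 102)
  fits <- fit_mode_nonresponse_models(imp, modes)
  wba <- fits$WBA$pooled
  g <- wba[wba$term == "gender", ]
  expect_gt(0.36, g$ci_lower)
  expect_lt(0.36, g$ci_upper)
  a <- wba[wba$term == "applied_sciences", ]
  expect_gt(-0.23, a$ci_lower)
  expect_lt(-0.23, a$ci_upper)
})

test_that("null covariates are flagged significant at about the nominal rate", {
  cfg <- sim_config(n_total = 12000,
                    mode_split = c(PBA = 3000, CBA = 3000, WBA = 6000),
                    seed = 111)
  pop <- generate_population(cfg)
  modes <- simulate_participation(assign_modes(pop, cfg), pop, cfg)
  imp <- chained_impute(pop, m = 2, n_iterations = 2, seed = 112)
  fits <- fit_mode_nonresponse_models(imp, modes)
  null_covs <- c(paste0("bg_b", 1:9), paste0("bg_c", 1:9))
  flags <- unlist(lapply(fits, function(f) null_covs %in% f$significant))
  # 72 null tests at the 5% level: expect few rejections
  expect_lte(sum(flags), stats::qbinom(0.999, length(flags), 0.05))
})

test_that("degenerate subgroups raise errors", {
  rec <- make_mode_records(assigned = c(PBA = 20, CBA = 20, WBA = 20),
                           participated = c(PBA = 20, CBA = 10, WBA = 10))
  tab <- data.frame(student_id = rec$student_id, x = rnorm(nrow(rec)))
  expect_error(fit_mode_nonresponse_models(tab, rec), "degenerate|all")
  # single mode for the interaction model
  rec2 <- rec[rec$assigned_mode == "CBA", ]
  expect_error(fit_interaction_selection_model(tab[rec$assigned_mode == "CBA", ],
                                               rec2),
               "at least two modes")
})

test_that("interaction contrasts equal differences of conditional effects", {
  cfg <- sim_config(n_total = 6000,
                    mode_split = c(PBA = 2000, CBA = 2000, WBA = 2000),
                    seed = 121)
  pop <- generate_population(cfg)
  modes <- simulate_participation(assign_modes(pop, cfg), pop, cfg)
  imp <- list(attr(pop, "complete"))  # single complete copy
  ia <- fit_interaction_selection_model(imp, modes)
  cc <- ia$conditional
  for (v in c("gender", "applied_sciences")) {
    b_cba <- cc$estimate[cc$term == paste0("modeCBA:", v)]
    b_wba <- cc$estimate[cc$term == paste0("modeWBA:", v)]
    d <- ia$contrasts[ia$contrasts$covariate == v &
                        ia$contrasts$contrast == "CBA vs WBA", ]
    expect_equal(d$estimate, b_cba - b_wba, tolerance = 1e-10)
  }
})

test_that("interaction pseudo-R2 gain is near zero without interactions and
           grows with them", {
  slopes <- default_participation_slopes()
  # same selection process in every mode: no mode-specific effects
  slopes$PBA <- slopes$CBA <- slopes$WBA
  cfg <- sim_config(n_total = 9000,
                    mode_split = c(PBA = 3000, CBA = 3000, WBA = 3000),
                    participation_slopes = slopes, seed = 131)
  pop <- generate_population(cfg)
  modes <- simulate_participation(assign_modes(pop, cfg), pop, cfg)
  imp <- list(attr(pop, "complete"))
  vg_null <- interaction_variance_gain(imp, modes)
  expect_lt(vg_null$delta, 0.01)
  expect_gte(vg_null$delta, 0)
  # strong mode-specific selection: visible gain
  slopes$CBA["applied_sciences"] <- -2
  slopes$WBA["applied_sciences"] <- 1
  cfg2 <- sim_config(n_total = 9000,
                     mode_split = c(PBA = 3000, CBA = 3000, WBA = 3000),
                     participation_slopes = slopes, seed = 132)
  pop2 <- generate_population(cfg2)
  modes2 <- simulate_participation(assign_modes(pop2, cfg2), pop2, cfg2)
  vg_strong <- interaction_variance_gain(list(attr(pop2, "complete")), modes2)
  expect_gt(vg_strong$delta, vg_null$delta)
})

test_that("weighting restores the assigned-sample composition", {
  cfg <- sim_config(n_total = 12000,
                    mode_split = c(PBA = 4000, CBA = 4000, WBA = 4000),
                    seed = 141)
  pop <- generate_population(cfg)
  modes <- simulate_participation(assign_modes(pop, cfg), pop, cfg)
  imp <- list(attr(pop, "complete"))
  fits <- fit_mode_nonresponse_models(imp, modes)
  w <- compute_weights(fits, modes, imp, trim = 1)
  expect_s3_class(w, "propensity_weights")
  expect_true(all(w$weight >= 1 - 1e-8))
  comp <- attr(pop, "complete")
  for (m in c("PBA", "CBA", "WBA")) {
    sel <- w$effective_mode == m
    ids <- w$student_id[sel]
    # Horvitz-Thompson: weighted participant count near the assigned count
    expect_lt(abs(sum(w$weight[sel]) - sum(modes$assigned_mode == m)) /
                sum(modes$assigned_mode == m), 0.1)
    # weighted covariate mean near the full-arm mean for a selective covariate
    full <- mean(comp$gender[modes$assigned_mode == m])
    wtd <- stats::weighted.mean(comp$gender[match(ids, comp$student_id)],
                                w$weight[sel])
    raw <- mean(comp$gender[match(ids, comp$student_id)])
    expect_lt(abs(wtd - full), max(abs(raw - full), 0.03))
  }
})
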