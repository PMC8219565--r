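# Synthetic-study generator: a population of students with background
# covariates, random assignment to three assessment modes with a web-based
# switch offer for first-stage nonresponders, covariate-dependent
# participation, a mixed dichotomous/polytomous proficiency test generated
# from a one-parameter IRT model with mode-specific difficulty shifts and
# careless responding in the unsupervised arms, and four criterion variables
# linked to proficiency with mode-moderated slopes.

MODES <- c("PBA", "CBA", "WBA", "WBA_switch")

# deterministic per-stage seed derived from the master seed (kept < 2^31)
stage_seed <- function(seed, stage) {
  offset <- match(stage, c("population", "modes", "participation",
                           "responses", "criteria", "imputation",
                           "selection", "calibration", "dtf", "prediction"))
  ((as.integer(seed) %% 199999991L) * 10L + offset) %% 2147483647L
}

#' Generate a synthetic student population
#'
#' Draws `n_total` students with covariates following the configured
#' codebook, then applies missing-at-random masking: the missingness
#' probability of each maskable covariate depends on the always-observed
#' gender and standardized-age columns (falling back to the configured
#' marginal rate when those columns are absent). The complete (pre-masking)
#' table is kept in the attribute `"complete"` so that downstream generation
#' stages can condition on the true values.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; defaults to a stage seed derived from
#'   `config$seed`.
#' @return data frame with `student_id` and one column per covariate;
#'   masked cells are `NA`.
#' @export
generate_population <- function(config, seed = stage_seed(config$seed, "population")) {
  validate_sim_config(config)
  set.seed(seed)
  n <- config$n_total
  cb <- config$codebook
  tab <- data.frame(student_id = seq_len(n))
  for (i in seq_len(nrow(cb))) {
    tab[[cb$name[i]]] <- switch(cb$type[i],
      binary = stats::rbinom(n, 1L, cb$p[i]),
      continuous = stats::rnorm(n),
      categorical = factor(sample(paste0("L", seq_len(cb$levels[i])), n,
                                  replace = TRUE),
                           levels = paste0("L", seq_len(cb$levels[i])))
    )
  }
  complete <- tab
  # MAR masking driven by fully observed covariates
  g <- if ("gender" %in% names(tab)) tab$gender - mean(tab$gender) else 0
  a <- if ("age_std" %in% names(tab)) tab$age_std else 0
  for (i in seq_len(nrow(cb))) {
    r <- cb$missing_rate[i]
    if (r <= 0) next
    pmiss <- stats::plogis(stats::qlogis(r) + 0.4 * g + 0.3 * a)
    miss <- stats::runif(n) < pmiss
    tab[[cb$name[i]]][miss] <- NA
  }
  attr(tab, "complete") <- complete
  tab
}

#' Randomly assign students to assessment modes
#'
#' Assignment is a uniformly random permutation into groups of exactly the
#' configured sizes, independent of all covariates. Fractional splits are
#' converted to counts summing to `n_total`.
#'
#' @inheritParams generate_population
#' @param table a covariate table from [generate_population()].
#' @return data frame of mode records: `student_id`, `assigned_mode`, and
#'   (unset) participation flags and `effective_mode`.
#' @export
assign_modes <- function(table, config, seed = stage_seed(config$seed, "modes")) {
  n <- nrow(table)
  split <- config$mode_split[c("PBA", "CBA", "WBA")]
  if (all(split <= 1) && abs(sum(split) - 1) < 1e-6) {
    counts <- floor(split * n)
    rem <- n - sum(counts)
    if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1L
  } else {
    counts <- as.integer(split)
    if (sum(counts) != n)
      stop("configuration error: mode_split does not sum to the table size")
  }
  set.seed(seed)
  assigned <- sample(rep(c("PBA", "CBA", "WBA"), counts))
  data.frame(
    student_id = table$student_id,
    assigned_mode = factor(assigned, levels = c("PBA", "CBA", "WBA")),
    participated_first_stage = NA,
    offered_switch = NA,
    participated_switch = NA,
    effective_mode = factor(NA, levels = c(MODES, "none"))
  )
}

# calibrate a logit intercept so that mean(plogis(a + lp)) hits `target`
calibrate_intercept <- function(lp, target) {
  stats::uniroot(function(a) mean(stats::plogis(a + lp)) - target,
                 interval = c(-15, 15), tol = 1e-10)$root
}

# linear predictor of a slope vector on (complete) covariates
participation_lp <- function(table, slopes) {
  lp <- numeric(nrow(table))
  for (nm in names(slopes)) {
    if (!nm %in% names(table))
      stop("configuration error: participation slope on unknown covariate ", nm)
    x <- table[[nm]]
    if (is.factor(x))
      stop("configuration error: slopes on categorical covariates are not supported")
    lp <- lp + slopes[[nm]] * x
  }
  lp
}

#' Simulate participation and the switch stage
#'
#' First-stage participation is drawn from a per-mode logit on the (true)
#' covariates, with the intercept calibrated so the marginal participation
#' rate equals the configured target. First-stage nonresponders in the
#' supervised modes (PBA, CBA) are offered a web-based switch and draw a
#' second, independent participation decision from the switch-stage logit.
#'
#' @inheritParams assign_modes
#' @param records mode records from [assign_modes()].
#' @return the mode records with all flags and `effective_mode` filled.
#' @export
simulate_participation <- function(records, table, config,
                                   seed = stage_seed(config$seed, "participation")) {
  complete <- attr(table, "complete")
  if (is.null(complete)) complete <- table
  if (anyNA(complete[vapply(complete, is.numeric, TRUE)]))
    stop("participation requires complete covariates; supply the generator's table")
  set.seed(seed)
  records$participated_first_stage <- NA
  for (m in c("PBA", "CBA", "WBA")) {
    idx <- which(records$assigned_mode == m)
    if (!length(idx)) next
    lp <- participation_lp(complete[idx, , drop = FALSE],
                           config$participation_slopes[[m]])
    a <- calibrate_intercept(lp, config$target_rates[[m]])
    p <- stats::plogis(a + lp)
    records$participated_first_stage[idx] <- stats::runif(length(idx)) < p
  }
  records$offered_switch <- records$assigned_mode %in% c("PBA", "CBA") &
    !records$participated_first_stage
  records$participated_switch <- NA
  idx <- which(records$offered_switch)
  if (length(idx)) {
    lp <- participation_lp(complete[idx, , drop = FALSE],
                           config$participation_slopes[["WBA_switch"]])
    a <- calibrate_intercept(lp, config$target_rates[["WBA_switch"]])
    p <- stats::plogis(a + lp)
    records$participated_switch[idx] <- stats::runif(length(idx)) < p
  }
  eff <- rep("none", nrow(records))
  eff[records$participated_first_stage] <-
    as.character(records$assigned_mode[records$participated_first_stage])
  eff[which(records$participated_switch)] <- "WBA_switch"
  records$effective_mode <- factor(eff, levels = c(MODES, "none"))
  records
}

# vectorized categorical draw from a probability matrix (rows sum to one)
draw_categories <- function(P) {
  cum <- t(apply(P, 1L, cumsum))
  u <- stats::runif(nrow(P))
  rowSums(u > cum)
}

#' Simulate test responses from the one-parameter model
#'
#' True proficiency is drawn from the configured normal distribution for all
#' students. Participants respond to every item of the bank under the partial
#' credit model, with every step threshold shifted by the additive difficulty
#' shift of their effective mode; with the per-mode careless probability a
#' response is replaced by a uniformly random category. Nonparticipants are
#' all-missing.
#'
#' @inheritParams assign_modes
#' @param records filled mode records from [simulate_participation()].
#' @param theta optional vector of true proficiencies (drawn if `NULL`).
#' @return list with `responses` (data frame: `student_id` + one integer
#'   column per item, `NA` for nonparticipants) and `theta`.
#' @export
simulate_responses <- function(records, config,
                               seed = stage_seed(config$seed, "responses"),
                               theta = NULL) {
  set.seed(seed)
  n <- nrow(records)
  bank <- config$item_bank
  J <- length(bank$n_steps)
  if (is.null(theta))
    theta <- stats::rnorm(n, config$mu_theta, sqrt(config$var_theta))
  X <- matrix(NA_integer_, n, J)
  for (m in MODES) {
    idx <- which(records$effective_mode == m)
    if (!length(idx)) next
    deltas <- shift_bank(bank$delta, config$mode_shift[[m]])
    cr <- config$careless_rate[[m]]
    for (j in seq_len(J)) {
      P <- pcm_probs(deltas[[j]], theta[idx])
      x <- draw_categories(P)
      if (cr > 0) {
        careless <- stats::runif(length(idx)) < cr
        x[careless] <- sample(0:bank$n_steps[j], sum(careless), replace = TRUE)
      }
      X[idx, j] <- as.integer(x)
    }
  }
  resp <- data.frame(student_id = records$student_id, X)
  names(resp)[-1L] <- bank$names
  list(responses = resp, theta = theta)
}

#' Weighted raw scores for a response matrix
#'
#' @param responses response data frame from [simulate_responses()].
#' @param bank item bank (defaults to [default_item_bank()]).
#' @return numeric vector of weighted raw scores (NA for all-missing rows).
#' @export
score_responses <- function(responses, bank = default_item_bank()) {
  X <- as.matrix(responses[, bank$names, drop = FALSE])
  drop(X %*% bank$weight)
}

#' Simulate criterion variables
#'
#' Each criterion is a linear function of standardized proficiency with a
#' mode-moderated slope, mode main effects, effect-coded sex and
#' teacher-education effects and Gaussian noise, mapped onto its response
#' scale (clipped to the scale range). Scale indicators for omega reliability
#' are generated from a one-factor model with the configured loading. Only
#' participants receive criteria; a missing-at-random mask (gender-dependent)
#' removes whole criterion records at the configured rate.
#'
#' @inheritParams assign_modes
#' @param records filled mode records.
#' @param theta proficiency scores driving the criteria (the true latent
#'   values in the standard pipeline).
#' @return data frame: `student_id`, one scale-score column per criterion,
#'   and item-indicator columns `<criterion>_i<k>`.
#' @export
simulate_criteria <- function(records, theta, table, config,
                              seed = stage_seed(config$seed, "criteria")) {
  set.seed(seed)
  complete <- attr(table, "complete")
  if (is.null(complete)) complete <- table
  n <- nrow(records)
  part <- records$effective_mode != "none" & !is.na(records$effective_mode)
  theta_z <- (theta - mean(theta[part])) / stats::sd(theta[part])
  sex <- ifelse(complete$gender == 1, 0.5, -0.5)
  teach <- ifelse(complete$teacher_education == 1, -0.5, 0.5)
  out <- data.frame(student_id = records$student_id)
  for (nm in names(config$criterion_models)) {
    cm <- config$criterion_models[[nm]]
    if (!all(names(cm$moderation) %in% c("CBA", "WBA", "WBA_switch")))
      stop("configuration error: unknown mode key in moderation map for ", nm)
    slope_m <- cm$slope + ifelse(part,
      ifelse(as.character(records$effective_mode) %in% names(cm$moderation),
             cm$moderation[as.character(records$effective_mode)], 0), 0)
    main_m <- ifelse(as.character(records$effective_mode) %in% names(cm$mode_main),
                     cm$mode_main[as.character(records$effective_mode)], 0)
    y_z <- slope_m * theta_z + main_m + cm$beta_sex * sex +
      cm$beta_teacher * teach + stats::rnorm(n, 0, cm$noise_sd)
    score <- cm$scale_mean + cm$scale_sd * y_z
    score <- pmin(pmax(score, cm$range[1]), cm$range[2])
    score[!part] <- NA
    if (cm$n_items > 1L) {
      lam <- cm$loading
      for (k in seq_len(cm$n_items)) {
        it <- lam * y_z + sqrt(1 - lam^2) * stats::rnorm(n)
        it[!part] <- NA
        out[[sprintf("%s_i%d", nm, k)]] <- it
      }
    }
    out[[nm]] <- score
  }
  # MAR criterion missingness per criterion record
  r <- config$criterion_missing_rate
  if (r > 0) {
    g <- complete$gender - mean(complete$gender)
    for (nm in names(config$criterion_models)) {
      pmiss <- stats::plogis(stats::qlogis(r) + 0.3 * g)
      miss <- part & stats::runif(n) < pmiss
      cols <- grep(paste0("^", nm), names(out), value = TRUE)
      out[miss, cols] <- NA
    }
  }
  out
}

#' Generate a complete synthetic study
#'
#' Runs all generator stages in order under per-stage seeds derived from the
#' configuration's master seed.
#'
#' @param config a [sim_config()].
#' @return list with `population`, `modes`, `responses`, `theta`, `criteria`,
#'   and the `config`.
#' @export
generate_study <- function(config = sim_config()) {
  pop <- generate_population(config)
  modes <- assign_modes(pop, config)
  modes <- simulate_participation(modes, pop, config)
  rsp <- simulate_responses(modes, config)
  crit <- simulate_criteria(modes, rsp$theta, pop, config)
  list(population = pop, modes = modes, responses = rsp$responses,
       theta = rsp$theta, criteria = crit, config = config)
}

# small stable FNV-1a hash of a serialized object, as a hex string
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483648), b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483648))
}

#' Write a generated study to CSV files
#'
#' Emits `covariates.csv`, `modes.csv`, `responses.csv` (wide),
#' `criteria.csv`, `theta.csv`, and a `manifest.json` recording the seed and
#' a configuration hash.
#'
#' @param study result of [generate_study()].
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest list.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(study$population, file.path(dir, "covariates.csv"),
                   row.names = FALSE)
  utils::write.csv(study$modes, file.path(dir, "modes.csv"), row.names = FALSE)
  utils::write.csv(study$responses, file.path(dir, "responses.csv"),
                   row.names = FALSE)
  utils::write.csv(study$criteria, file.path(dir, "criteria.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(student_id = study$modes$student_id,
                              theta = study$theta),
                   file.path(dir, "theta.csv"), row.names = FALSE)
  manifest <- list(seed = study$config$seed,
                   config_hash = config_hash(study$config),
                   n_total = study$config$n_total)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}
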