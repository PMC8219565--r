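#' Study configuration for the synthetic mode experiment
#'
#' Builds a validated configuration describing a three-arm mode experiment
#' (paper-based PBA, computer-based CBA, and web-based WBA assessment, with a
#' WBA switch offer for first-stage nonresponders), the covariate codebook
#' used by the nonresponse models, the mixed dichotomous/polytomous item bank
#' (maximum weighted score 36), mode-specific difficulty shifts, careless
#' responding rates, and the criterion models observed about six months after
#' the assessment.
#'
#' All defaults mirror the design quantities of the emulated mode experiment:
#' arm sizes 5371/3431/8671 (17,473 students in total), target participation
#' rates 25.6/18.2/54.2 percent in the randomly assigned arms and 25.6 percent
#' in the switch stage, a latent proficiency variance of 0.73, additive
#' difficulty shifts of about +0.09 logits for supervised computerized
#' testing and +0.25 logits for unsupervised web-based testing (calibrated
#' so the signed DTF lands near 0.4 and 0.9 raw-score points on this bank),
#' and careless responding only in the unsupervised arms.
#'
#' @param n_total total number of students.
#' @param mode_split integer vector of arm sizes, names `PBA`, `CBA`, `WBA`;
#'   must sum to `n_total`.
#' @param target_rates marginal participation rates used to calibrate the
#'   participation intercepts, names `PBA`, `CBA`, `WBA`, `WBA_switch`.
#' @param codebook covariate codebook, see [default_codebook()].
#' @param participation_slopes named list (one element per mode, including
#'   `WBA_switch`) of named slope vectors on covariates; covariates not named
#'   get slope 0.
#' @param mu_theta,var_theta mean and variance of the latent proficiency.
#' @param item_bank item bank, see [default_item_bank()].
#' @param mode_shift named additive difficulty shift in logits per effective
#'   mode.
#' @param careless_rate named per-mode probability that a response is replaced
#'   by a uniformly random category.
#' @param criterion_models named list of criterion model definitions, see
#'   [default_criterion_models()].
#' @param criterion_missing_rate probability that a participant's criterion
#'   record is missing.
#' @param seed integer seed stored with the configuration.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_total = 17473L,
                       mode_split = c(PBA = 5371L, CBA = 3431L, WBA = 8671L),
                       target_rates = c(PBA = 0.256, CBA = 0.182,
                                        WBA = 0.542, WBA_switch = 0.256),
                       codebook = default_codebook(),
                       participation_slopes = default_participation_slopes(),
                       mu_theta = 0,
                       var_theta = 0.73,
                       item_bank = default_item_bank(),
                       mode_shift = c(PBA = 0, CBA = 0.085, WBA = 0.245,
                                      WBA_switch = 0.245),
                       careless_rate = c(PBA = 0, CBA = 0, WBA = 0.1,
                                         WBA_switch = 0.1),
                       criterion_models = default_criterion_models(),
                       criterion_missing_rate = 0.1,
                       seed = 1L) {
  cfg <- structure(list(
    n_total = as.integer(n_total),
    mode_split = mode_split,
    target_rates = target_rates,
    codebook = codebook,
    participation_slopes = participation_slopes,
    mu_theta = mu_theta,
    var_theta = var_theta,
    item_bank = item_bank,
    mode_shift = mode_shift,
    careless_rate = careless_rate,
    criterion_models = criterion_models,
    criterion_missing_rate = criterion_missing_rate,
    seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' @param cfg a `sim_config`.
#' @return `cfg`, invisibly; stops with a configuration error otherwise.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_total <= 0L)
    stop("configuration error: n_total must be positive")
  ms <- cfg$mode_split
  if (!all(c("PBA", "CBA", "WBA") %in% names(ms)))
    stop("configuration error: mode_split needs names PBA, CBA, WBA")
  if (any(ms < 0))
    stop("configuration error: mode_split counts must be non-negative")
  tol <- 1e-8
  if (all(ms <= 1 + tol) && abs(sum(ms) - 1) < 1e-6) {
    # fractions are allowed; they must sum to one
  } else if (sum(ms) != cfg$n_total) {
    stop("configuration error: mode_split must sum to n_total (or to 1)")
  }
  if (any(cfg$careless_rate < 0 | cfg$careless_rate > 1))
    stop("configuration error: careless_rate must lie in [0, 1]")
  if (any(cfg$target_rates <= 0 | cfg$target_rates >= 1))
    stop("configuration error: target_rates must lie in (0, 1)")
  cb <- cfg$codebook
  if (anyDuplicated(cb$name))
    stop("configuration error: duplicated covariate names in codebook")
  if (!all(cb$type %in% c("binary", "continuous", "categorical")))
    stop("configuration error: invalid covariate type in codebook")
  if (any(cb$missing_rate < 0 | cb$missing_rate > 1))
    stop("configuration error: missing_rate must lie in [0, 1]")
  bank <- cfg$item_bank
  if (any(bank$n_steps < 1L))
    stop("configuration error: items need at least one score step")
  if (length(bank$delta) != length(bank$n_steps))
    stop("configuration error: one threshold vector per item required")
  nst <- vapply(bank$delta, length, 1L)
  if (!all(nst == bank$n_steps))
    stop("configuration error: threshold count must equal category count - 1")
  if (cfg$var_theta <= 0)
    stop("configuration error: var_theta must be positive")
  invisible(cfg)
}

#' Default covariate codebook
#'
#' Twenty-eight background variables: named sociodemographic and study
#' covariates that carry the mode-specific selection effects (gender, having
#' children, attending a university of applied sciences, non-traditional
#' university admission, teacher education, enrolment in natural sciences), a
#' prior competence and a self-esteem score, a standardized age, one
#' categorical field-of-study variable, and eighteen generic background
#' scores. A subset carries missing-at-random missingness driven by the
#' always-observed gender and age columns.
#'
#' @return a data frame with columns `name`, `type`, `p` (binary success
#'   probability), `levels` (number of categorical levels), and
#'   `missing_rate`.
#' @export
default_codebook <- function() {
  named <- data.frame(
    name = c("gender", "has_children", "applied_sciences",
             "nontraditional_admission", "teacher_education",
             "natural_science", "prior_competence", "self_esteem",
             "age_std", "field_of_study"),
    type = c(rep("binary", 6), rep("continuous", 3), "categorical"),
    p = c(0.61, 0.07, 0.32, 0.06, 0.20, 0.216, NA, NA, NA, NA),
    levels = c(rep(NA_integer_, 9), 4L),
    missing_rate = c(0, 0.06, 0, 0, 0, 0, 0.12, 0.10, 0, 0.08),
    stringsAsFactors = FALSE
  )
  generic <- data.frame(
    name = c(paste0("bg_b", 1:9), paste0("bg_c", 1:9)),
    type = c(rep("binary", 9), rep("continuous", 9)),
    p = c(rep(0.5, 9), rep(NA, 9)),
    levels = NA_integer_,
    missing_rate = c(0.05, rep(0, 8), 0.05, rep(0, 8)),
    stringsAsFactors = FALSE
  )
  rbind(named, generic)
}

#' Default participation slope sets
#'
#' Logit slopes of first-stage participation (and the switch stage) on the
#' covariates, per mode. The named covariates carry the selection effects the
#' nonresponse analysis is meant to detect: gender participates more strongly
#' in WBA (0.36) than in PBA/CBA (0.19/0.18), having children lowers
#' participation everywhere, attending a university of applied sciences
#' suppresses participation far more in CBA (-1.02) than in WBA (-0.23), and
#' a non-traditional admission certificate raises PBA participation (1.18).
#'
#' @return named list of named numeric vectors.
#' @export
default_participation_slopes <- function() {
  list(
    PBA = c(gender = 0.19, has_children = -0.79, applied_sciences = -0.30,
            nontraditional_admission = 1.18, teacher_education = 0.15,
            prior_competence = 0.10, self_esteem = 0.05, age_std = -0.05),
    CBA = c(gender = 0.18, has_children = -0.88, applied_sciences = -1.02,
            nontraditional_admission = 0.30, teacher_education = 0.10,
            prior_competence = 0.10, self_esteem = 0.05, age_std = -0.05),
    WBA = c(gender = 0.36, has_children = -0.50, applied_sciences = -0.23,
            nontraditional_admission = 0.18, teacher_education = 0.05,
            prior_competence = 0.10, self_esteem = 0.05, age_std = -0.05),
    WBA_switch = c(gender = 0.25, has_children = -0.50,
                   applied_sciences = -0.30, nontraditional_admission = 0.40,
                   teacher_education = 0.10, prior_competence = 0.10,
                   self_esteem = 0.05, age_std = -0.05)
  )
}

#' Default item bank
#'
#' Sixteen dichotomous items (one point each) and thirteen polytomous
#' partial-credit items (twelve with four categories, one with five; half a
#' point per category step), so the weighted maximum score is
#' 16 + 0.5 * (12 * 3 + 4) = 36 points. Dichotomous difficulties are spread
#' over \[-4.5, 4.5\] logits and polytomous item locations over
#' \[-3.2, 3.2\] with ordered step thresholds around each location; the wide
#' spread keeps the test's information level at the moderate empirical
#' reliabilities typical of broad literacy assessments (around .8) rather
#' than the higher values a narrowly targeted bank would give.
#'
#' @return a list with elements `n_steps` (categories minus one per item),
#'   `weight` (score points per category step), and `delta` (list of step
#'   threshold vectors, in logits).
#' @export
default_item_bank <- function() {
  b_dich <- seq(-4.5, 4.5, length.out = 16)
  loc_poly <- seq(-3.2, 3.2, length.out = 13)
  delta <- c(
    as.list(b_dich),
    lapply(loc_poly[1:12], function(c) c + c(-1.5, 0, 1.5)),
    list(loc_poly[13] + c(-1.875, -0.6, 0.6, 1.875))
  )
  list(
    n_steps = c(rep(1L, 16), rep(3L, 12), 4L),
    weight = c(rep(1, 16), rep(0.5, 13)),
    delta = delta,
    names = c(sprintf("dich%02d", 1:16), sprintf("poly%02d", 1:13))
  )
}

#' Default criterion model definitions
#'
#' Four criteria collected about six months after the assessment: grade point
#' average (reverse-coded, higher = better), academic self-concept,
#' study-related helplessness, and intention to quit. Each criterion is a
#' linear function of standardized latent proficiency with mode-moderated
#' slopes, mode main effects, effect-coded sex and teacher-education effects,
#' and Gaussian noise, then mapped onto its reported response scale.
#' Latent slopes are the targeted measured-scale standardized coefficients
#' divided by the end-to-end attenuation that measurement error in the
#' person scores induces for a test of this reliability: about 0.75 for
#' main effects and about 0.65 for interaction (moderation) terms, which
#' errors-in-variables attenuate more strongly. With these factors,
#' regressions on measured scores land near the targeted magnitudes.
#'
#' The scale indicators (for omega reliability) load on the criterion with a
#' common loading chosen so that omega equals its targeted value: .86 for the
#' four self-concept items, .87 for the three helplessness items, and .86 for
#' the five intention-to-quit items.
#'
#' @return named list of criterion definitions.
#' @export
default_criterion_models <- function() {
  att <- 0.75    # attenuation of main-effect slopes on measured scores
  att_m <- 0.65  # stronger attenuation of interaction terms
  list(
    gpa = list(
      slope = 0.21 / att,
      moderation = c(CBA = -0.09, WBA = -0.13, WBA_switch = -0.04) / att_m,
      mode_main = c(CBA = -0.21, WBA = -0.07, WBA_switch = -0.11),
      beta_sex = -0.22, beta_teacher = -0.09,
      noise_sd = 0.95, scale_mean = 3.70, scale_sd = 0.55,
      range = c(1, 5), n_items = 1L, loading = NA_real_
    ),
    self_concept = list(
      slope = 0.46 / att,
      moderation = c(CBA = -0.33, WBA = -0.36, WBA_switch = -0.26) / att_m,
      mode_main = c(CBA = 0.29, WBA = 0.17, WBA_switch = 0.09),
      beta_sex = 0.10, beta_teacher = -0.05,
      noise_sd = 0.85, scale_mean = 4.91, scale_sd = 0.90,
      range = c(1, 7), n_items = 4L, loading = 0.78
    ),
    helplessness = list(
      slope = -0.22 / att,
      moderation = c(CBA = 0.01, WBA = 0.09, WBA_switch = 0.09) / att_m,
      mode_main = c(CBA = -0.06, WBA = -0.11, WBA_switch = -0.09),
      beta_sex = -0.05, beta_teacher = -0.01,
      noise_sd = 0.95, scale_mean = 1.99, scale_sd = 0.86,
      range = c(1, 5), n_items = 3L, loading = 0.831
    ),
    quit = list(
      slope = -0.09 / att,
      moderation = c(CBA = 0.09, WBA = -0.05, WBA_switch = -0.12) / att_m,
      mode_main = c(CBA = 0.07, WBA = 0.05, WBA_switch = 0.18),
      beta_sex = -0.15, beta_teacher = 0.01,
      noise_sd = 0.98, scale_mean = 1.46, scale_sd = 0.55,
      range = c(1, 4), n_items = 5L, loading = 0.742
    )
  )
}

#' Read a simulation configuration from YAML
#'
#' Only scalar and simple vector fields can be overridden from YAML; the
#' codebook, item bank, slope sets and criterion models fall back to their
#' defaults unless present in the file as equivalent structures.
#'
#' @param path path to a YAML file with `sim_config` fields.
#' @return a `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("configuration error: unknown config keys: ",
         paste(unknown, collapse = ", "))
  args <- raw[intersect(names(raw), known)]
  for (nm in c("mode_split", "target_rates", "mode_shift", "careless_rate"))
    if (!is.null(args[[nm]])) args[[nm]] <- unlist(args[[nm]])
  if (!is.null(args$codebook))
    args$codebook <- as.data.frame(args$codebook, stringsAsFactors = FALSE)
  if (!is.null(args$participation_slopes))
    args$participation_slopes <- lapply(args$participation_slopes, unlist)
  do.call(sim_config, args)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic mode-experiment configuration\n")
  cat(sprintf("  students: %d (PBA %s / CBA %s / WBA %s)\n", x$n_total,
              x$mode_split[["PBA"]], x$mode_split[["CBA"]],
              x$mode_split[["WBA"]]))
  cat(sprintf("  target participation rates: %s\n",
              paste(sprintf("%s %.1f%%", names(x$target_rates),
                            100 * x$target_rates), collapse = ", ")))
  cat(sprintf("  covariates: %d (%d with missingness)\n",
              nrow(x$codebook), sum(x$codebook$missing_rate > 0)))
  cat(sprintf("  items: %d (max weighted score %g)\n",
              length(x$item_bank$n_steps),
              sum(x$item_bank$weight * x$item_bank$n_steps)))
  cat(sprintf("  mode difficulty shifts (logits): %s\n",
              paste(sprintf("%s %+.2f", names(x$mode_shift), x$mode_shift),
                    collapse = ", ")))
  invisible(x)
}
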