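# End-to-end orchestration: generate -> impute -> select/weight ->
# calibrate -> dtf -> predict -> report, with CSV outputs, a JSON run
# manifest, and per-stage seeds derived from the master seed.

PIPELINE_STAGES <- c("generate", "impute", "select", "calibrate", "dtf",
                     "predict", "report")

#' Run the full mode-effect evaluation pipeline
#'
#' Executes the requested stages in dependency order against one synthetic
#' study, writing each stage's tables to `out_dir` and recording seeds,
#' output files and timestamps in `run_manifest.json`. Stage results are
#' also returned in memory. All randomness derives from `config$seed`; a
#' repeated run with an unchanged configuration reproduces identical
#' outputs.
#'
#' @param config a [sim_config()] (or path to a YAML file for
#'   [read_sim_config()]).
#' @param out_dir output directory.
#' @param stages subset of `generate`, `impute`, `select`, `calibrate`,
#'   `dtf`, `predict`, `report` (default: all). Later stages require the
#'   outputs of earlier ones from the same call.
#' @param m_imputations imputation copies for covariates and criteria.
#' @param imputation_sweeps chained-equation sweeps.
#' @param n_nodes quadrature nodes for calibration.
#' @param dtf_draws parameter draws for the DTF confidence intervals.
#' @param log message progress?
#' @return invisibly, a list with the run `manifest` and all stage results.
#' @export
run_study <- function(config = sim_config(), out_dir,
                      stages = PIPELINE_STAGES,
                      m_imputations = 20L, imputation_sweeps = 10L,
                      n_nodes = 61L, dtf_draws = 100L, log = TRUE) {
  if (is.character(config)) config <- read_sim_config(config)
  validate_sim_config(config)
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  need <- function(s) s %in% stages
  say <- function(...) if (log) message(sprintf(...))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config_hash = config_hash(config), seed = config$seed,
                   stage_seeds = list(), stages = stages, outputs = list(),
                   version = as.character(utils::packageVersion("modeeffects")),
                   timestamps = list())
  res <- list(config = config)
  register <- function(stage, files) {
    manifest$outputs[[stage]] <<- files
    manifest$timestamps[[stage]] <<- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  }

  if (need("generate")) {
    say("stage generate: n = %d students", config$n_total)
    res$study <- generate_study(config)
    write_study(res$study, out_dir)
    register("generate", c("covariates.csv", "modes.csv", "responses.csv",
                           "criteria.csv", "theta.csv", "manifest.json"))
  }
  study <- res$study
  if (is.null(study) && any(vapply(setdiff(PIPELINE_STAGES[-1], "report"),
                                   need, TRUE)))
    stop("dependency error: later stages require the 'generate' stage")

  if (need("impute")) {
    seed <- stage_seed(config$seed, "imputation")
    manifest$stage_seeds$impute <- seed
    say("stage impute: m = %d copies, %d sweeps", m_imputations,
        imputation_sweeps)
    res$imputations <- chained_impute(study$population, m = m_imputations,
                                      n_iterations = imputation_sweeps,
                                      seed = seed)
    long <- do.call(rbind, lapply(seq_len(res$imputations$m), function(i)
      cbind(.copy = i, res$imputations$copies[[i]])))
    utils::write.csv(long, file.path(out_dir, "imputations.csv"),
                     row.names = FALSE)
    register("impute", "imputations.csv")
  }

  if (need("select")) {
    if (is.null(res$imputations))
      stop("dependency error: 'select' requires the 'impute' stage")
    say("stage select: nonresponse models and propensity weights")
    res$rates <- tabulate_response_rates(study$modes)
    res$nonresponse <- fit_mode_nonresponse_models(res$imputations,
                                                   study$modes)
    res$interaction <- fit_interaction_selection_model(res$imputations,
                                                       study$modes)
    res$variance_gain <- interaction_variance_gain(
      res$imputations, study$modes, interaction_fit = res$interaction)
    res$weights <- compute_weights(res$nonresponse, study$modes,
                                   res$imputations)
    utils::write.csv(res$rates, file.path(out_dir, "table1_rates.csv"),
                     row.names = FALSE)
    utils::write.csv(res$weights, file.path(out_dir, "weights.csv"),
                     row.names = FALSE)
    utils::write.csv(res$interaction$conditional,
                     file.path(out_dir, "selection_report.csv"),
                     row.names = FALSE)
    utils::write.csv(res$interaction$contrasts,
                     file.path(out_dir, "selection_contrasts.csv"),
                     row.names = FALSE)
    register("select", c("table1_rates.csv", "weights.csv",
                         "selection_report.csv", "selection_contrasts.csv"))
  }

  if (need("calibrate")) {
    if (is.null(res$weights))
      stop("dependency error: 'calibrate' requires the 'select' stage")
    say("stage calibrate: weighted two-step calibration per mode group")
    res$calibration <- calibrate_modes(study$responses, study$modes,
                                       res$weights, config$item_bank,
                                       n_nodes = n_nodes)
    files <- character(0)
    rel <- data.frame(group = character(0), reliability = numeric(0))
    res$persons <- list(); res$itemfit <- list()
    for (g in names(res$calibration$groups)) {
      pars <- res$calibration$groups[[g]]
      sel <- study$modes$effective_mode == g
      resp_g <- study$responses[match(study$modes$student_id[sel],
                                      study$responses$student_id), ,
                                drop = FALSE]
      pe <- estimate_wle(resp_g, pars)
      fitrep <- infit_wms(resp_g, pars, pe)
      res$persons[[g]] <- pe
      res$itemfit[[g]] <- fitrep
      rel <- rbind(rel, data.frame(
        group = g, reliability = empirical_reliability(pe)))
      ip <- data.frame(item = pars$names, n_steps = pars$n_steps,
                       weight = pars$weight,
                       delta = vapply(pars$delta, paste, "", collapse = ";"))
      for (nm in c("item_params", "persons", "itemfit")) {
        f <- sprintf("%s_%s.csv", nm, g)
        obj <- switch(nm, item_params = ip, persons = pe, itemfit = fitrep)
        utils::write.csv(obj, file.path(out_dir, f), row.names = FALSE)
        files <- c(files, f)
      }
      fv <- sprintf("cov_params_%s.csv", g)
      utils::write.csv(as.data.frame(pars$vcov), file.path(out_dir, fv),
                       row.names = FALSE)
      files <- c(files, fv)
    }
    res$reliability <- rel
    tab2 <- merge(res$calibration$variance_table, rel, by = "group")
    utils::write.csv(tab2,
                     file.path(out_dir, "table2_variance_reliability.csv"),
                     row.names = FALSE)
    register("calibrate", c(files, "table2_variance_reliability.csv"))
  }

  if (need("dtf")) {
    if (is.null(res$calibration))
      stop("dependency error: 'dtf' requires the 'calibrate' stage")
    seed <- stage_seed(config$seed, "dtf")
    manifest$stage_seeds$dtf <- seed
    say("stage dtf: %d parameter draws per group pair", dtf_draws)
    res$dtf <- dtf_pairs(res$calibration, n_draws = dtf_draws, seed = seed)
    utils::write.csv(res$dtf, file.path(out_dir, "table3_dtf.csv"),
                     row.names = FALSE)
    gs <- names(res$calibration$groups)
    grid <- seq(-4, 4, length.out = 201L)
    ts_long <- do.call(rbind, lapply(gs, function(g) {
      tsf <- test_scoring_function(res$calibration$groups[[g]], grid)
      data.frame(group = g, theta = tsf$grid, ts = tsf$ts)
    }))
    utils::write.csv(ts_long, file.path(out_dir, "fig4_ts_curves.csv"),
                     row.names = FALSE)
    cond <- do.call(rbind, lapply(gs[-1], function(g) {
      cbind(reference = gs[1], comparison = g,
            conditional_sdtf(res$calibration$groups[[gs[1]]],
                             res$calibration$groups[[g]]))
    }))
    utils::write.csv(cond, file.path(out_dir, "fig5_conditional_sdtf.csv"),
                     row.names = FALSE)
    register("dtf", c("table3_dtf.csv", "fig4_ts_curves.csv",
                      "fig5_conditional_sdtf.csv"))
  }

  if (need("predict")) {
    if (is.null(res$persons))
      stop("dependency error: 'predict' requires the 'calibrate' stage")
    seed <- stage_seed(config$seed, "prediction")
    manifest$stage_seeds$predict <- seed
    say("stage predict: moderated regressions on the subsample")
    persons_all <- do.call(rbind, res$persons)
    pf <- prediction_frame(persons_all, study$modes, study$population,
                           study$criteria)
    crit_names <- names(config$criterion_models)
    item_cols <- grep("_i[0-9]+$", names(pf), value = TRUE)
    impute_cols <- c("literacy", "sex_eff", "teacher_eff", crit_names,
                     item_cols)
    crit_imp <- chained_impute(
      cbind(pf["student_id"], pf[impute_cols]),
      m = m_imputations, n_iterations = imputation_sweeps, seed = seed)
    copies <- lapply(crit_imp$copies, function(cp) {
      cp$mode <- pf$mode
      cp
    })
    res$prediction <- list()
    files <- character(0)
    for (cr in crit_names) {
      fit <- fit_prediction_model(copies, cr)
      res$prediction[[cr]] <- fit
      f <- sprintf("prediction_%s.csv", cr)
      out <- fit$coefficients
      out$criterion <- cr; out$r2 <- fit$r2; out$delta_r2 <- fit$delta_r2
      utils::write.csv(out, file.path(out_dir, f), row.names = FALSE)
      files <- c(files, f)
    }
    omg <- list()
    for (cr in crit_names) {
      cols <- grep(sprintf("^%s_i[0-9]+$", cr), names(pf), value = TRUE)
      if (length(cols) >= 2L)
        omg[[cr]] <- omega_reliability(pf[cols], label = cr)
    }
    res$omega <- omg
    if (length(omg)) {
      utils::write.csv(data.frame(
        scale = names(omg),
        omega = vapply(omg, `[[`, 1.0, "omega"),
        n_items = vapply(omg, `[[`, 1L, "n_items")),
        file.path(out_dir, "omega.csv"), row.names = FALSE)
      files <- c(files, "omega.csv")
    }
    register("predict", files)
  }

  if (need("report")) {
    say("stage report: assembling report tables")
    res$report <- make_report(out_dir)
    register("report", res$report$files)
  }

  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}

#' Assemble the report tables from a pipeline output directory
#'
#' Collects the stage outputs into the canonical report files
#' (`table1_rates.csv`, `table2_variance_reliability.csv`,
#' `table3_dtf.csv`, `table4_prediction.csv`, `fig4_ts_curves.csv`,
#' `fig5_conditional_sdtf.csv`). Missing stage outputs are noted in
#' `report_log.txt` rather than failing.
#'
#' @param out_dir a pipeline output directory.
#' @return list with `files` (report files present) and `missing` (report
#'   sections whose stage outputs were absent).
#' @export
make_report <- function(out_dir) {
  present <- character(0); missing <- character(0)
  note <- function(f) {
    if (file.exists(file.path(out_dir, f))) present <<- c(present, f)
    else missing <<- c(missing, f)
  }
  for (f in c("table1_rates.csv", "table2_variance_reliability.csv",
              "table3_dtf.csv", "fig4_ts_curves.csv",
              "fig5_conditional_sdtf.csv"))
    note(f)
  pred_files <- list.files(out_dir, pattern = "^prediction_.*\\.csv$")
  if (length(pred_files)) {
    tab4 <- do.call(rbind, lapply(pred_files, function(f)
      utils::read.csv(file.path(out_dir, f))))
    utils::write.csv(tab4, file.path(out_dir, "table4_prediction.csv"),
                     row.names = FALSE)
    present <- c(present, "table4_prediction.csv")
  } else {
    missing <- c(missing, "table4_prediction.csv")
  }
  log_lines <- c(sprintf("report assembled %s",
                         format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                 sprintf("present: %s", paste(present, collapse = ", ")),
                 if (length(missing))
                   sprintf("missing sections (stage not run): %s",
                           paste(missing, collapse = ", ")))
  writeLines(log_lines, file.path(out_dir, "report_log.txt"))
  list(files = c(present, "report_log.txt"), missing = missing)
}
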