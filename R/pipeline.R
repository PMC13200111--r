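#' Configuration for a full synthetic QA experiment
#'
#' Bundles every stage's settings: campaign shape, tolerance configuration,
#' model configuration, dose-comparison settings and the single global seed
#' from which all randomness (simulation substream, model substream) is
#' derived.
#'
#' @param out_dir Output directory for logs, tables and the JSON summary.
#' @param seed Global integer seed.
#' @param spots_per_layer Fixture-plan spots per layer (725 = full scale;
#'   smaller values run the identical pipeline at reduced size).
#' @param include_fault Schedule the faulted session?
#' @param tolerances A [tolerance_config()].
#' @param model A [model_config()] (its seed is replaced by a derived
#'   substream of `seed`).
#' @param dose_enabled Run the dose-comparison stage?
#' @param dose_spacing Voxel spacing (mm) for the dose stage.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(out_dir, seed = 1L, spots_per_layer = 100L,
                              include_fault = TRUE,
                              tolerances = tolerance_config(),
                              model = model_config(),
                              dose_enabled = TRUE, dose_spacing = 4.0) {
  .assert(is.character(out_dir) && length(out_dir) == 1L, "out_dir must be a path")
  .assert(.is_count(seed), "seed must be an integer")
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 spots_per_layer = as.integer(spots_per_layer),
                 include_fault = isTRUE(include_fault), tolerances = tolerances,
                 model = model, dose_enabled = isTRUE(dose_enabled),
                 dose_spacing = dose_spacing),
            class = "experiment_config")
}

#' Read an experiment configuration from a YAML file
#'
#' Recognized keys: `out_dir`, `seed`, `spots_per_layer`, `include_fault`,
#' `tolerances: {annual_mm, daily_mm, window}`, `model: {n_trees,
#' learning_rate}`, `dose: {enabled, spacing}`.
#'
#' @param path YAML file path.
#' @param out_dir Override for the output directory.
#' @return An [experiment_config()].
#' @export
read_experiment_config <- function(path, out_dir = NULL) {
  cfg <- yaml::read_yaml(path)
  tol <- do.call(tolerance_config, cfg$tolerances %||% list())
  mdl <- do.call(model_config, cfg$model %||% list())
  experiment_config(
    out_dir = out_dir %||% cfg$out_dir %||% ".",
    seed = cfg$seed %||% 1L,
    spots_per_layer = cfg$spots_per_layer %||% 100L,
    include_fault = cfg$include_fault %||% TRUE,
    tolerances = tol, model = mdl,
    dose_enabled = (cfg$dose %||% list())$enabled %||% TRUE,
    dose_spacing = (cfg$dose %||% list())$spacing %||% 4.0
  )
}

.stage_msg <- function(verbose, stage, fmt, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

.stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    .stop_fmt("experiment stage '%s' failed: %s", stage, conditionMessage(e))
  })
}

#' Run the full synthetic QA experiment
#'
#' One-command reproduction of the paper-shaped campaign: simulate the
#' campaign and write PQA1 logs, read them back, synchronize with the plan
#' (round-tripped through DICOM), compute deviations, run distribution
#' summaries, factor analyses and moving-window flagging, train and evaluate
#' the per-axis position models on the final-month temporal split, and (if
#' enabled) compare planned vs predicted dose for one test session. All
#' tabular outputs and a JSON summary are written under `config$out_dir`,
#' together with a manifest recording the seed for exact re-runs.
#'
#' @param config An [experiment_config()].
#' @param verbose Emit per-stage progress messages?
#' @return Invisibly, a list with elements `plan`, `manifest`, `deviations`,
#'   `summaries`, `factors`, `flags`, `split_counts`, `evaluation`,
#'   `importance`, `dose`, `files`.
#' @export
run_experiment <- function(config, verbose = TRUE) {
  .assert(inherits(config, "experiment_config"), "config must be an experiment_config")
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  f <- projection_factors()

  spec <- .stage("simulate", paper_campaign(spots_per_layer = config$spots_per_layer,
                                            seed = derive_seed(config$seed, "simulation"),
                                            include_fault = config$include_fault))
  plan_path <- file.path(out, "plan.dcm")
  .stage("plan-io", {
    write_ion_plan(spec$plan, plan_path)
  })
  plan <- .stage("plan-io", read_ion_plan(plan_path))
  .stage_msg(verbose, "plan-io", "fixture plan: %d layers, %d spots, %.4f MU",
             n_layers(plan), n_spots(plan), plan$total_mu)

  manifest <- .stage("simulate", simulate_campaign(spec, file.path(out, "logs"), f = f))
  .stage_msg(verbose, "simulate", "%d sessions written (%d faulted)",
             nrow(manifest), sum(manifest$faulted))

  sessions <- .stage("compare", lapply(manifest$file, read_log))
  deviations <- .stage("compare", bind_deviations(
    lapply(sessions, function(s) compute_deviations(match_spots(plan, s), f))
  ))
  utils::write.csv(deviations, file.path(out, "deviations.csv"), row.names = FALSE)
  .stage_msg(verbose, "compare", "%d spot deviations", nrow(deviations))

  summaries <- .stage("stats", lapply(
    stats::setNames(nm = c("dx", "dy", "dmu", "d2")),
    function(v) summarize_deviations(deviations[[v]])
  ))
  factors <- .stage("stats", {
    grid <- expand.grid(factor = c("energy", "date", "room"),
                        response = c("dx", "dy"), stringsAsFactors = FALSE)
    res <- Map(function(fa, re) factor_analysis(deviations, fa, re),
               grid$factor, grid$response)
    names(res) <- paste(grid$response, "by", grid$factor)
    res
  })
  flags <- .stage("stats", moving_window_flags(deviations, config$tolerances))
  utils::write.csv(flags$summary, file.path(out, "flags.csv"), row.names = FALSE)
  .stage_msg(verbose, "stats", "%d spots flagged at annual tier across %d sessions",
             sum(flags$summary$n_annual), sum(flags$summary$n_annual > 0))

  features <- .stage("train", build_features(plan, sessions, f))
  split <- .stage("train", temporal_split(features))
  mcfg <- config$model
  mcfg$seed <- derive_seed(config$seed, "model")
  model_x <- .stage("train", train_axis_model(split$train, "x", mcfg))
  model_y <- .stage("train", train_axis_model(split$train, "y", mcfg))
  evaluation <- .stage("evaluate", evaluate_models(model_x, model_y, split$test))
  importance <- .stage("evaluate", list(x = feature_importance(model_x),
                                        y = feature_importance(model_y)))
  utils::write.csv(evaluation$by_session, file.path(out, "eval_by_session.csv"),
                   row.names = FALSE)
  utils::write.csv(evaluation$by_energy, file.path(out, "eval_by_energy.csv"),
                   row.names = FALSE)
  .stage_msg(verbose, "evaluate", "test R^2: x %.6f, y %.6f (n = %d)",
             evaluation$overall["r2_x"], evaluation$overall["r2_y"], evaluation$n)

  dose_cmp <- NULL
  if (config$dose_enabled) {
    dose_cmp <- .stage("dose", {
      bm <- beam_model(plan$energies)
      test_sessions <- which(format(as.Date(manifest$date), "%Y-%m") == split$test_month &
                               !manifest$faulted)
      s <- sessions[[test_sessions[1L]]]
      pred_rows <- features[features$room == s$room & features$date == s$date, ]
      delivered_mu <- match_spots(plan, s)$mu
      pred_plan <- spots_to_plan(
        data.frame(x = predict(model_x, pred_rows), y = predict(model_y, pred_rows),
                   meterset = delivered_mu),
        plan, f
      )
      grid <- default_grid(plan, bm, spacing = config$dose_spacing)
      compare_dose(compute_dose(plan, bm, grid), compute_dose(pred_plan, bm, grid))
    })
    .stage_msg(verbose, "dose", "max abs voxel diff %.4g Gy",
               dose_cmp$max_abs_voxel_diff)
  }

  report <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("protonqa")),
    n_sessions = nrow(manifest),
    n_spots = nrow(deviations),
    split_counts = c(train = nrow(split$train), test = nrow(split$test)),
    summaries = summaries,
    flags = flags$summary,
    evaluation = list(overall = as.list(evaluation$overall),
                      cross_axis_r = evaluation$cross_axis_r, n = evaluation$n),
    importance = importance,
    dose = if (!is.null(dose_cmp)) {
      list(mean_abs_diff_of_means = dose_cmp$mean_abs_diff_of_means,
           max_abs_voxel_diff = dose_cmp$max_abs_voxel_diff,
           sd_voxel_diff = dose_cmp$sd_voxel_diff)
    }
  )
  json_path <- file.path(out, "summary.json")
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest_path <- file.path(out, "manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE)

  invisible(list(plan = plan, manifest = manifest, deviations = deviations,
                 summaries = summaries, factors = factors, flags = flags,
                 split_counts = report$split_counts, evaluation = evaluation,
                 importance = importance, dose = dose_cmp,
                 files = c(plan = plan_path, summary = json_path,
                           manifest = manifest_path)))
}
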