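#' Pipeline configuration
#'
#' Exactly one data source is used: paths to `formulations.csv` /
#' `profiles.csv` / `properties.csv`, or a synthetic study (the default),
#' or the built-in reference tables (`source = "fixtures"`, which runs the
#' stages the printed tables support: mixture models and the
#' observed-versus-predicted profile comparison).
#'
#' @param source `"synthetic"`, `"files"`, or `"fixtures"`.
#' @param paths Named list of file paths (`formulations`, `profiles`,
#'   optionally `properties`) when `source = "files"`.
#' @param n_synthetic,truth Synthetic-study size and [ground_truth()].
#' @param seed Master seed; stage seeds are derived from it.
#' @param out_dir Output directory for the results bundle.
#' @param stages Character vector of stages to run, any of
#'   `"mixture"`, `"kinetics"`, `"surrogate"`, `"optimize"`, `"compare"`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(source = c("synthetic", "files", "fixtures"),
                            paths = list(), n_synthetic = 11,
                            truth = ground_truth(), seed = 1L,
                            out_dir = NULL,
                            stages = c("mixture", "kinetics", "surrogate",
                                       "optimize", "compare")) {
  source <- match.arg(source)
  if (source == "files") {
    needed <- c("formulations", "profiles")
    if (!all(needed %in% names(paths))) {
      stop("source = 'files' needs paths$formulations and paths$profiles",
           call. = FALSE)
    }
  }
  structure(list(source = source, paths = paths,
                 n_synthetic = n_synthetic, truth = truth,
                 seed = as.integer(seed), out_dir = out_dir,
                 stages = stages),
            class = "pipeline_config")
}

pipeline_mixture_stage <- function(formulations, properties) {
  responses <- c(weight = "weight_mg", hardness = "hardness_n",
                 drug_load = "drug_load_mg")
  out <- list()
  for (nm in names(responses)) {
    col <- responses[[nm]]
    if (!col %in% names(properties)) next
    y <- properties[[col]][match(formulations$id, properties$id)]
    keep <- !is.na(y)
    if (sum(keep) < 4) next
    all_fits <- fit_all_degrees(formulations[keep, ], y[keep], nm)
    sel <- select_model(all_fits$fits)
    out[[nm]] <- list(summary = all_fits$summary, selected = sel$degree,
                      coefficients = as.list(sel$chosen$coefficients),
                      r2 = sel$chosen$r2, adj_r2 = sel$chosen$adj_r2,
                      pred_r2 = sel$chosen$pred_r2,
                      press = sel$chosen$press)
  }
  out
}

#' Run the full formulation-design pipeline
#'
#' Stages, in order: Scheffe mixture-model fitting and selection for each
#' tablet property; kinetic-model fitting and mechanism classification per
#' dissolution profile; training of a release surrogate (a single-hidden-
#' layer all-linear MLP on composition inputs); desirability optimization
#' of the composition against the extended-release goals; and
#' model-independent comparison (f1, f2, R-squared) of the optimized
#' composition's reference curve against the surrogate prediction. With
#' the built-in reference tables the surrogate stages are skipped (the
#' printed data carry no per-formulation curves) and the comparison uses
#' the published experimental-versus-predicted values.
#'
#' All seeds and settings are recorded in the results bundle; a rerun with
#' the same config writes byte-identical results.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_result` with per-stage results and
#'   `settings`. When `config$out_dir` is set, also writes `results.json`
#'   and per-stage CSVs there.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  results <- list(settings = list(
    source = config$source, seed = config$seed,
    n_synthetic = config$n_synthetic, stages = config$stages,
    truth = if (config$source == "synthetic") unclass(config$truth)))

  properties <- NULL
  truth_profiles <- NULL
  if (config$source == "synthetic") {
    study <- run_stage("simulate",
                       generate_study(config$n_synthetic, config$truth,
                                      seed = config$seed))
    formulations <- study$formulations
    profiles <- study$profiles
    truth_profiles <- study
  } else if (config$source == "files") {
    formulations <- run_stage("load",
                              load_formulation_table(config$paths$formulations))
    profiles <- run_stage("load", load_profile_table(config$paths$profiles))
    if (!is.null(config$paths$properties)) {
      properties <- run_stage("load",
                              load_properties_table(config$paths$properties))
    }
  } else {
    fx <- builtin_fixtures()
    formulations <- fx$formulations[fx$formulations$design_point, ]
    profiles <- NULL
    properties <- fx$tablet_properties
  }

  if ("mixture" %in% config$stages && !is.null(properties)) {
    results$mixture <- run_stage("fit-mixture",
                                 pipeline_mixture_stage(formulations,
                                                        properties))
  }

  if ("kinetics" %in% config$stages && !is.null(profiles)) {
    results$kinetics <- run_stage("fit-kinetics", {
      rows <- lapply(profiles, function(p) fit_release_kinetics(p)$summary)
      do.call(rbind, rows)
    })
  }

  surrogate <- NULL
  surrogate_times <- if (!is.null(profiles)) profiles[[1]]$times
  if ("surrogate" %in% config$stages && !is.null(profiles)) {
    surrogate <- run_stage("train-ann", {
      x <- as.matrix(formulations[, component_names()])
      y <- t(vapply(profiles, function(p) p$released,
                    numeric(length(profiles[[1]]$times))))
      n <- nrow(x)
      n_val <- max(1L, round(0.2 * n))
      val_idx <- seq_len(n_val)  # deterministic split: first rows held out
      tr <- setdiff(seq_len(n), val_idx)
      cfg <- mlp_config(c(3, 8, ncol(y)), "linear", max_epochs = 5000,
                        patience = 200, seed = config$seed)
      net <- train_backprop(init_mlp(cfg), x[tr, ], y[tr, ],
                            x[val_idx, , drop = FALSE],
                            y[val_idx, , drop = FALSE])
      net$times <- surrogate_times
      net
    })
    results$surrogate <- list(
      architecture = surrogate$config$layer_sizes,
      rms = surrogate$metrics$rms, r2 = surrogate$metrics$r2,
      best_epoch = surrogate$metrics$best_epoch)
  }

  opt <- NULL
  if ("optimize" %in% config$stages && !is.null(surrogate)) {
    opt <- run_stage("optimize", {
      goals <- Filter(function(g) g$time %in% surrogate_times,
                      default_release_goals())
      optimize_formulation(surrogate, goals = goals,
                           seed = config$seed + 1L)
    })
    results$optimization <- list(
      composition = as.list(opt$composition[, c("pegda", "peg400",
                                                "water")]),
      overall_D = opt$overall_D, per_goal_d = opt$per_goal_d,
      predicted = as.list(opt$predicted_profile))
  }

  if ("compare" %in% config$stages) {
    results$comparison <- run_stage("compare-profiles", {
      if (config$source == "fixtures") {
        fx <- builtin_fixtures()$optimal_comparison
        rbind(
          cbind(network = "nn1",
                compare_profiles(fx$time_h, fx$experimental,
                                 fx$predicted_nn1)),
          cbind(network = "nn2",
                compare_profiles(fx$time_h, fx$experimental,
                                 fx$predicted_nn2)))
      } else if (!is.null(opt) && !is.null(truth_profiles)) {
        # reference: the ground-truth (noiseless) release of the
        # optimized composition; test: the surrogate prediction
        pred <- opt$predicted_profile
        p <- truth_params(config$truth, opt$composition)
        ref <- pmin(p$k * pred$time_h^p$n, 100)
        cbind(network = "surrogate",
              compare_profiles(pred$time_h, ref, pred$released_pct))
      }
    })
  }

  results <- structure(results, class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_results(results, config)
  results
}

write_pipeline_results <- function(results, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(results),
                       file.path(config$out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  if (!is.null(results$kinetics)) {
    utils::write.csv(results$kinetics,
                     file.path(config$out_dir, "kinetics.csv"),
                     row.names = FALSE)
  }
  if (!is.null(results$comparison)) {
    utils::write.csv(results$comparison,
                     file.path(config$out_dir, "comparison.csv"),
                     row.names = FALSE)
  }
  if (!is.null(results$mixture)) {
    rows <- lapply(names(results$mixture), function(nm) {
      cbind(response = nm, results$mixture[[nm]]$summary)
    })
    utils::write.csv(do.call(rbind, rows),
                     file.path(config$out_dir, "mixture_models.csv"),
                     row.names = FALSE)
  }
  invisible(config$out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline results (source:", x$settings$source, "| seed:",
      x$settings$seed, ")\n")
  if (!is.null(x$mixture)) {
    cat(" mixture models:",
        paste(names(x$mixture), vapply(x$mixture, function(m) m$selected,
                                       character(1)), sep = "=",
              collapse = ", "), "\n")
  }
  if (!is.null(x$kinetics)) {
    cat(" kinetics: best model per profile:",
        paste(utils::head(x$kinetics$best_model, 5), collapse = ", "),
        if (nrow(x$kinetics) > 5) "...", "\n")
  }
  if (!is.null(x$surrogate)) {
    cat(sprintf(" surrogate: %s, val RMS %.4g, R2 %.4f\n",
                paste(x$surrogate$architecture, collapse = "-"),
                x$surrogate$rms, x$surrogate$r2))
  }
  if (!is.null(x$optimization)) {
    cat(sprintf(" optimum: PEGDA %.2f / PEG400 %.2f / water %.2f, D %.4f\n",
                x$optimization$composition$pegda,
                x$optimization$composition$peg400,
                x$optimization$composition$water,
                x$optimization$overall_D))
  }
  if (!is.null(x$comparison)) {
    print(x$comparison)
  }
  invisible(x)
}
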