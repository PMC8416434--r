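#' Assemble a pipeline run configuration
#'
#' A run configuration fully determines a pipeline run: the input (a
#' directory of recordings with a manifest, or a synthetic cohort
#' description), the model, the grid options, the permutation budget and
#' the master seed. Serializable to/from YAML; outputs embed the config
#' hash so reruns can be verified.
#'
#' @param input Either `list(manifest = "<dir>")` pointing at a cohort
#'   written by [write_cohort()], or `list(cohort = <cohort_config
#'   fields>, effects_preset = "<name>", multiplier = <x>)` for synthetic
#'   input.
#' @param method Classifier method (see [model_spec()]).
#' @param model Extra [model_spec()] arguments as a named list.
#' @param adjust_iq Include IQ as covariate.
#' @param n_perm Permutations for the significance test (0 skips it).
#' @param survival_threshold Survival rule threshold. Default 7.
#' @param amplitude_limit Artifact rejection threshold, uV.
#' @param seed Master seed.
#' @param out_dir Output directory.
#' @return An object of class `qeeg_run_config`.
#' @export
run_config <- function(input, method = "en", model = list(),
                       adjust_iq = FALSE, n_perm = 200,
                       survival_threshold = 7, amplitude_limit = 100,
                       seed = 1, out_dir = tempfile("qeeg_run_")) {
  structure(
    list(input = input, method = method, model = model,
         adjust_iq = isTRUE(adjust_iq), n_perm = n_perm,
         survival_threshold = survival_threshold,
         amplitude_limit = amplitude_limit,
         seed = as.integer(seed), out_dir = out_dir),
    class = "qeeg_run_config"
  )
}

#' @rdname run_config
#' @param path YAML file holding the fields of `run_config()`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

#' @rdname run_config
#' @param config A `qeeg_run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

load_cohort_manifest <- function(dir) {
  manifest <- tibble::as_tibble(utils::read.csv(file.path(dir, "manifest.csv")))
  recs <- purrr::map(manifest$file, function(f) load_recording(file.path(dir, f)))
  list(recordings = recs,
       covariates = manifest[, c("subject_id", "label", "age", "sex",
                                 "education", "iq")])
}

pipeline_input <- function(config) {
  inp <- config$input
  if (!is.null(inp$manifest)) {
    return(load_cohort_manifest(inp$manifest))
  }
  if (!is.null(inp$cohort)) {
    cc_args <- inp$cohort
    cc_args$seed <- cc_args$seed %||% config$seed
    cc <- do.call(cohort_config, cc_args)
    eff <- NULL
    if (!is.null(inp$effects_preset)) {
      eff <- if (!is.null(inp$multiplier)) {
        preset_effects(inp$effects_preset, multiplier = inp$multiplier)
      } else preset_effects(inp$effects_preset)
    }
    return(generate_cohort(cc, eff))
  }
  qeeg_abort("config$input must carry either $manifest or $cohort",
             "qeeg_error_validation")
}

#' Run the full classification pipeline
#'
#' Stage order: ingest/simulate, artifact rejection, cross-spectra,
#' feature extraction, combination sweep, feature survival (elastic net),
#' permutation test, report. The extracted feature table is cached in the
#' output directory keyed by a hash of the input configuration, so
#' permutation-heavy reruns skip the spectral stages. All outputs are
#' tidy CSVs; progress and per-stage timing go to stderr.
#'
#' @param config A [run_config()] or path to its YAML form.
#' @return An object of class `qeeg_run`: the sweep, best CV, survival
#'   report, permutation result and output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "qeeg_run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- hash_object(unclass(config))
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    out <- tryCatch(expr, error = function(e) {
      qeeg_abort(paste0("stage '", name, "' failed: ", conditionMessage(e)),
                 "qeeg_error_stage", parent = e)
    })
    message(sprintf("[qeeg] %-12s %6.1f s", name, proc.time()[3] - t0))
    out
  }

  input_hash <- hash_object(list(config$input, config$amplitude_limit,
                                 config$seed))
  cache <- file.path(config$out_dir, paste0("features_", input_hash, ".rds"))
  if (file.exists(cache)) {
    message("[qeeg] features     cached (", input_hash, ")")
    feats <- readRDS(cache)
  } else {
    cohort <- stage("ingest", pipeline_input(config))
    feats <- stage("features",
                   cohort_features(cohort, amplitude_limit = config$amplitude_limit))
    saveRDS(feats, cache)
  }

  spec <- do.call(model_spec, c(list(method = config$method, seed = config$seed),
                                config$model))
  sweep <- stage("sweep",
                 combination_sweep(feats$features, feats$covariates, spec,
                                   adjust_iq = config$adjust_iq))
  survival <- NULL
  if (spec$method == "en") {
    survival <- stage("survival",
                      extract_survival(sweep$best_cv,
                                       threshold = config$survival_threshold))
  }
  permutation <- NULL
  if (config$n_perm > 0) {
    best_combo <- sweep$best_cv$combo
    fm <- build_feature_matrix(feats$features, feats$covariates, best_combo)
    permutation <- stage("permutation",
                         permutation_test(fm, spec, n_perm = config$n_perm,
                                          seed = derive_seed(config$seed, "perm")))
  } else {
    message("[qeeg] permutation  skipped (n_perm = 0)")
  }

  paths <- stage("report", {
    p <- list(
      sweep = file.path(config$out_dir, "sweep.csv"),
      best_cv = file.path(config$out_dir, "best_cv_folds.csv"),
      survival = file.path(config$out_dir, "survival.csv"),
      permutation = file.path(config$out_dir, "permutation.csv"),
      config = file.path(config$out_dir, "run_config.yaml")
    )
    utils::write.csv(dplyr::mutate(tidy(sweep), config_hash = cfg_hash),
                     p$sweep, row.names = FALSE)
    utils::write.csv(dplyr::mutate(tidy(sweep$best_cv), config_hash = cfg_hash),
                     p$best_cv, row.names = FALSE)
    if (!is.null(survival)) {
      utils::write.csv(dplyr::mutate(survival, config_hash = cfg_hash),
                       p$survival, row.names = FALSE)
    }
    if (!is.null(permutation)) {
      utils::write.csv(
        dplyr::mutate(glance(permutation), config_hash = cfg_hash),
        p$permutation, row.names = FALSE)
    }
    write_run_config(config, p$config)
    p
  })
  structure(
    list(sweep = sweep, best_cv = sweep$best_cv, survival = survival,
         permutation = permutation, config = config, config_hash = cfg_hash,
         paths = paths),
    class = "qeeg_run"
  )
}

#' @export
print.qeeg_run <- function(x, ...) {
  cat("<qeeg_run> hash ", x$config_hash, "\n", sep = "")
  print(x$sweep)
  if (!is.null(x$permutation)) print(x$permutation)
  invisible(x)
}
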