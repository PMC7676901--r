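#' Pipeline configuration
#'
#' Collects every estimator parameter of the simulate - extract - pca -
#' model pipeline with the conventional defaults, plus stage toggles and
#' the single seed that governs all stochastic stages. The configuration
#' is serialized (JSON) into the run directory so every output carries
#' its provenance.
#'
#' @param out_dir Output directory for the run.
#' @param seed Master seed.
#' @param stages Character vector of stages to execute, in dependency
#'   order, from `c("simulate", "extract", "pca", "model")`.
#' @param n_participants,fs,n_channels,fragment_duration_s Cohort layout
#'   (see [cohort_spec()]).
#' @param tasks,backgrounds Condition levels.
#' @param topics_per_background Lecture topics per background.
#' @param alpha_center_hz,alpha_power,alpha_bandwidth_hz,envelope_hurst
#'   Base alpha-oscillator parameters.
#' @param onef_exponent Background spectral exponent.
#' @param features Feature names for the registry (NULL = full set).
#' @param k_pcs Components carried to the statistics stage.
#' @param exam_mode `"fixed"` or `"mixed"` exam-prediction family.
#' @param alpha_level Significance level for post-hoc flags.
#' @param plan An [effect_plan()] describing planted effects.
#' @param write_edf Also write each fragment as an EDF file.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            stages = c("simulate", "extract", "pca", "model"),
                            n_participants = 8, fs = 256, n_channels = 12,
                            fragment_duration_s = c(LA = 60, BA = 60, BUA = 60),
                            tasks = c("LA", "BA", "BUA"),
                            backgrounds = c("PK", "MT", "HW", "FT"),
                            topics_per_background = 1,
                            alpha_center_hz = 10, alpha_power = 4,
                            alpha_bandwidth_hz = 2, envelope_hurst = 0.7,
                            onef_exponent = 1, features = NULL,
                            k_pcs = 9, exam_mode = "fixed",
                            alpha_level = 0.05, plan = effect_plan(),
                            write_edf = FALSE) {
  structure(as.list(environment()), class = "pipeline_config")
}

config_hash <- function(config) {
  plain <- config
  plain$plan <- unclass(plain$plan)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(plain, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tf)
  unname(tools::md5sum(tf))
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in dependency order, writing each stage's
#' outputs (CSV/JSON) into the run directory together with a manifest
#' carrying the configuration and its hash. Stages never mutate the
#' outputs of earlier stages; rerunning with the same configuration and
#' seed reproduces the outputs bit-identically.
#'
#' @param config A [pipeline_config()].
#' @param verbose Log stage progress.
#' @return Invisibly, a list with the in-memory stage results (`cohort`,
#'   `exam`, `features`, `pca`, `subscores`, `prediction`) for the
#'   stages that ran.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(...) if (verbose) message(sprintf(...))
  res <- list()
  hash <- config_hash(config)
  outputs <- character(0)

  need <- function(stage, file) {
    if (!file.exists(file)) {
      stop("stage '", stage, "' needs missing upstream output: ", file)
    }
  }
  pth <- function(f) file.path(config$out_dir, f)

  if ("simulate" %in% config$stages) {
    log_msg("stage simulate: %d participants", config$n_participants)
    spec <- cohort_spec(
      n_participants = config$n_participants, tasks = config$tasks,
      backgrounds = config$backgrounds,
      fragment_duration_s = config$fragment_duration_s,
      fs = config$fs, n_channels = config$n_channels,
      topics_per_background = config$topics_per_background,
      seed = config$seed
    )
    osc <- oscillator_spec(
      center_hz = config$alpha_center_hz, peak_power = config$alpha_power,
      bandwidth_hz = config$alpha_bandwidth_hz,
      envelope_hurst = config$envelope_hurst
    )
    res$cohort <- simulate_cohort(spec, osc, config$plan,
                                  onef_exponent = config$onef_exponent)
    res$exam <- generate_exam_table(res$cohort)
    write.csv(res$cohort$manifest, pth("manifest.csv"), row.names = FALSE)
    write.csv(res$cohort$truth, pth("ground_truth.csv"), row.names = FALSE)
    write.csv(res$exam, pth("exam.csv"), row.names = FALSE)
    outputs <- c(outputs, "manifest.csv", "ground_truth.csv", "exam.csv")
    if (isTRUE(config$write_edf)) {
      dir.create(pth("edf"), showWarnings = FALSE)
      for (fid in res$cohort$manifest$fragment_id) {
        fr <- realize_fragment(res$cohort, fid)
        write_edf(fr$recording, pth(file.path("edf", paste0(fid, ".edf"))))
      }
      outputs <- c(outputs, "edf/")
    }
  }

  if ("extract" %in% config$stages) {
    if (is.null(res$cohort)) stop("stage 'extract' needs the simulate stage")
    log_msg("stage extract: %d fragments", nrow(res$cohort$manifest))
    registry <- feature_registry(include = config$features)
    res$features <- cohort_features(res$cohort, registry)
    write.csv(res$features, pth("features.csv"), row.names = FALSE)
    meta <- list(config_hash = hash, registry = registry,
                 welch = list(window_s = 1, overlap_s = 0.5, nfft = 2^14))
    writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                                dataframe = "rows"),
               pth("features_meta.json"))
    outputs <- c(outputs, "features.csv", "features_meta.json")
  }

  if ("pca" %in% config$stages) {
    if (is.null(res$features)) {
      need("pca", pth("features.csv"))
      res$features <- read.csv(pth("features.csv"), stringsAsFactors = FALSE)
    }
    log_msg("stage pca")
    registry <- feature_registry(include = config$features)
    fm <- build_matrix(res$features, registry)
    res$pca <- fit_pca(fm)
    res$subscores <- subregion_scores(
      res$pca, subregion_map(scalp_labels(config$n_channels)), k = config$k_pcs
    )
    write.csv(cbind(feature = rownames(res$pca$loadings),
                    as.data.frame(res$pca$loadings)),
              pth("loadings.csv"), row.names = FALSE)
    write.csv(cbind(res$pca$keys, as.data.frame(res$pca$scores)),
              pth("scores.csv"), row.names = FALSE)
    write.csv(cbind(feature = rownames(res$pca$contributions),
                    as.data.frame(res$pca$contributions)),
              pth("contributions.csv"), row.names = FALSE)
    write.csv(data.frame(PC = seq_along(res$pca$explained_var),
                         explained_var = res$pca$explained_var),
              pth("explained_variance.csv"), row.names = FALSE)
    write.csv(res$subscores, pth("subregion_scores.csv"), row.names = FALSE)
    outputs <- c(outputs, "loadings.csv", "scores.csv", "contributions.csv",
                 "explained_variance.csv", "subregion_scores.csv")
  }

  if ("model" %in% config$stages) {
    if (is.null(res$subscores) || is.null(res$exam)) {
      stop("stage 'model' needs the pca and simulate stages")
    }
    log_msg("stage model (%s)", config$exam_mode)
    examz <- exam_zscores(res$exam)
    la <- res$subscores[res$subscores$task == "LA", ]
    res$prediction <- predict_exam(examz, la, mode = config$exam_mode,
                                   k = config$k_pcs)
    write.csv(data.frame(model = names(res$prediction$aic),
                         AIC = unname(res$prediction$aic)),
              pth("model_aic.csv"), row.names = FALSE)
    cmp <- do.call(rbind, lapply(names(res$prediction$comparisons), function(nm) {
      cm <- res$prediction$comparisons[[nm]]
      data.frame(comparison = nm, chisq = cm$chisq, df = cm$df,
                 p_value = cm$p_value, delta_aic = cm$delta_aic)
    }))
    write.csv(cmp, pth("model_comparisons.csv"), row.names = FALSE)
    writeLines(res$prediction$stepwise$retained, pth("stepwise_terms.txt"))
    outputs <- c(outputs, "model_aic.csv", "model_comparisons.csv",
                 "stepwise_terms.txt")
  }

  manifest <- list(config = unclass(config), config_hash = hash,
                   stages_run = config$stages, outputs = outputs)
  manifest$config$plan <- unclass(manifest$config$plan)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              force = TRUE, pretty = TRUE),
             pth("run_manifest.json"))
  invisible(res)
}
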