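#' Pipeline configuration
#'
#' Collects every tunable parameter of the end-to-end run in one object that
#' round-trips losslessly through YAML. A single master seed fans out to
#' per-stage seeds by fixed offsets, so each stage is independently
#' reproducible.
#'
#' @param n_per_class synthetic clips per context (default 10).
#' @param frame_len,hop STFT framing in samples (defaults 256/80).
#' @param conf_threshold pitch-confidence floor (default 0.15).
#' @param fmin,fmax pitch search range, Hz.
#' @param alpha ANOVA screen significance level (default 0.05).
#' @param standardize z-score kept features before exemplar distances.
#' @param chisq_correction Yates' correction in survey chi-squares.
#' @param pca_mode `"correlation"` or `"covariance"`.
#' @param pca_subset `"correct_only"` or `"all"`.
#' @param n_participants cohort size (default 225).
#' @param seed master integer seed.
#' @return object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(n_per_class = 10, frame_len = 256, hop = 80,
                            conf_threshold = 0.15, fmin = 100, fmax = 1000,
                            alpha = 0.05, standardize = TRUE,
                            chisq_correction = FALSE,
                            pca_mode = "correlation", pca_subset = "correct_only",
                            n_participants = 225, seed = 1L) {
  structure(
    list(
      n_per_class = as.integer(n_per_class), frame_len = as.integer(frame_len),
      hop = as.integer(hop), conf_threshold = conf_threshold,
      fmin = fmin, fmax = fmax, alpha = alpha,
      standardize = isTRUE(standardize),
      chisq_correction = isTRUE(chisq_correction),
      pca_mode = pca_mode, pca_subset = pca_subset,
      n_participants = as.integer(n_participants), seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `write_config`: `path` invisibly; `read_config`: the config.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

# short stable hash of a config (md5 of its canonical YAML)
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_config(config, tmp)
  unname(substr(tools::md5sum(tmp), 1, 12))
}

# CSV writer that stamps every output file with the config hash on a comment
# line; read back with read_report_csv().
write_report_csv <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# catvoc config %s", hash), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline report CSV (skipping the config-hash comment line)
#'
#' @param path CSV path written by [run_pipeline()].
#' @return data.frame.
#' @export
read_report_csv <- function(path) {
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Run the end-to-end analysis pipeline
#'
#' Executes, in order: synthetic corpus generation, acoustic feature
#' extraction, ANOVA screen + exemplar selection, synthetic cohort
#' generation, the survey statistical battery, and the descriptor PCA. All
#' tables are written as CSV (stamped with the config hash), the statistical
#' report as JSON, and a manifest records versions, seeds and every
#' parameter. Reruns with the same config are byte-identical on all CSV
#' outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return (invisibly) list with the in-memory stage results: `corpus`,
#'   `features`, `selection`, `cohort`, `report`, `pca`, `valence`,
#'   `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  corpus <- stage("synth_audio",
    synth_corpus(n_per_class = config$n_per_class, seed = config$seed + 1L))

  features <- stage("features", corpus_features(
    corpus, frame_len = config$frame_len, hop = config$hop,
    conf_threshold = config$conf_threshold,
    fmin = config$fmin, fmax = config$fmax
  ))
  write_report_csv(features, file.path(out_dir, "features.csv"), hash)
  write_report_csv(corpus$labels, file.path(out_dir, "labels.csv"), hash)

  selection <- stage("select_exemplars", screen_and_select(
    features, alpha = config$alpha, standardize = config$standardize
  ))
  write_report_csv(selection$screen, file.path(out_dir, "screen.csv"), hash)
  write_report_csv(selection$family_summary, file.path(out_dir, "screen_families.csv"), hash)
  write_report_csv(selection$exemplars, file.path(out_dir, "exemplars.csv"), hash)

  cohort <- stage("synth_cohort", synth_cohort(cohort_spec(
    n_participants = config$n_participants, seed = config$seed + 2L
  )))
  write_report_csv(cohort$participants, file.path(out_dir, "participants.csv"), hash)
  write_report_csv(cohort$responses, file.path(out_dir, "responses.csv"), hash)

  report <- stage("analyze", survey_report(
    cohort$responses, cohort$participants,
    chisq_correction = config$chisq_correction
  ))
  report$config_hash <- hash
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  pca <- stage("pca", pca_descriptors(
    cohort$responses, subset = config$pca_subset, mode = config$pca_mode
  ))
  vs <- valence_summary(pca)
  write_report_csv(
    data.frame(descriptor = rownames(pca$loadings), round(pca$loadings, 10)),
    file.path(out_dir, "pca_loadings.csv"), hash
  )
  write_report_csv(
    data.frame(pca$metadata, round(pca$scores[, 1:2, drop = FALSE], 10)),
    file.path(out_dir, "pca_scores.csv"), hash
  )
  write_report_csv(
    data.frame(component = seq_along(pca$explained_variance_pct),
               explained_pct = round(pca$explained_variance_pct, 10)),
    file.path(out_dir, "pca_explained.csv"), hash
  )
  write_report_csv(vs$context_summary, file.path(out_dir, "pca_valence_contexts.csv"), hash)
  write_report_csv(vs$loading_table, file.path(out_dir, "pca_valence_loadings.csv"), hash)

  manifest <- list(
    package = "catvoc",
    version = as.character(utils::packageVersion("catvoc")),
    config = unclass(config),
    config_hash = hash,
    stage_seeds = list(synth_audio = config$seed + 1L, synth_cohort = config$seed + 2L),
    files = list.files(out_dir)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(
    corpus = corpus, features = features, selection = selection,
    cohort = cohort, report = report, pca = pca, valence = vs,
    out_dir = out_dir
  ))
}
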