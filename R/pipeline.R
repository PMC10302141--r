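#' Default pipeline configuration
#'
#' All tunables of the seeded end-to-end run. Defaults reproduce the study
#' conditions: cohort of 212 subjects (female fraction 121/212), Table-style
#' marginals and correlation calibration, 137-subject development split,
#' SPSS-style stepwise thresholds 0.05/0.10, 100–500 Hz 4th-order zero-phase
#' band-pass, 3-s contractions at 4096 Hz with a 0.25-s edge exclusion.
#'
#' @param ... named overrides of any default entry.
#' @return Named list of configuration values.
#' @export
default_pipeline_config <- function(...) {
  cfg <- list(
    seed = 1,
    n_subjects = 212, # "n" would be a YAML 1.1 boolean literal as a bare key
    marginals_group = "total",
    marginals_csv = NULL,      # optional user CSV: variable, mean, sd, lower
    fill_rule = "anchor_product",
    sex_fraction_female = NULL, # default: study fraction of marginals_group
    sampling_rate = 4096,
    duration = 3,
    filter_low = 100,
    filter_high = 500,
    filter_order = 4,
    window_edge = 0.25,
    p_enter = 0.05,
    p_exit = 0.10,
    n_development = 137,
    render_signals = FALSE,
    render_subjects = NULL,    # NULL = all subjects when rendering
    write_signal_files = FALSE,
    out_dir = NULL
  )
  modifyList(cfg, list(...))
}

#' Load a pipeline configuration from YAML
#'
#' Unknown keys are rejected; referenced files must exist at load time.
#'
#' @param path YAML file path.
#' @return Configuration list (defaults filled in).
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  user <- yaml::read_yaml(path)
  known <- names(default_pipeline_config())
  bad <- setdiff(names(user), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(default_pipeline_config, user)
}

validate_config <- function(cfg) {
  stopifnot(cfg$n_subjects >= 0, cfg$duration > 0, cfg$sampling_rate >= 1024,
            cfg$p_enter <= cfg$p_exit, cfg$window_edge >= 0)
  if (!(cfg$filter_low > 0 && cfg$filter_low < cfg$filter_high &&
        cfg$filter_high < cfg$sampling_rate / 2))
    stop("invalid filter band: need 0 < low < high < sampling_rate/2")
  if (!is.null(cfg$marginals_csv) && !file.exists(cfg$marginals_csv))
    stop("marginals_csv does not exist: ", cfg$marginals_csv)
  if (cfg$n_subjects > 0 && cfg$n_development >= cfg$n_subjects)
    stop("n_development must be smaller than n")
  invisible(cfg)
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> (optionally render + re-process signals) -> features
#' -> correlate -> fit -> validate, writing every table plus a run manifest to
#' `out_dir`. All randomness flows from `config$seed` through named child
#' streams, so two runs with an identical configuration produce byte-identical
#' outputs.
#'
#' @param config list from [default_pipeline_config()] or
#'   [read_pipeline_config()].
#' @return Invisibly, a list with `cohort`, `split`, `correlations`, `model`,
#'   `validation`, `roundtrip` (NULL unless signals were rendered) and
#'   `manifest`.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  cfg <- validate_config(config)
  out_dir <- cfg$out_dir %||% tempfile("semgmass_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- list(
    package = "semgmass",
    version = as.character(packageVersion("semgmass")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = cfg[!vapply(cfg, is.null, logical(1))],
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    status = "running"
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)

  stage <- "simulate"
  result <- tryCatch({
    marginals <- if (!is.null(cfg$marginals_csv)) {
      read.csv(cfg$marginals_csv, stringsAsFactors = FALSE)
    } else study_marginals(cfg$marginals_group)
    sexf <- cfg$sex_fraction_female %||% study_sex_fraction(cfg$marginals_group)
    target <- correlation_target(study_correlation_entries(),
                                 fill_rule = cfg$fill_rule,
                                 assumed = study_assumed_correlations())
    cohort <- sample_cohort(cfg$n_subjects, marginals, target, sexf, seed = cfg$seed)

    roundtrip <- NULL
    if (cfg$render_signals) {
      stage <- "process"
      rendered <- render_cohort_features(cohort, cfg, out_dir)
      cohort <- rendered$cohort
      roundtrip <- rendered$roundtrip
      write.csv(roundtrip, file.path(out_dir, "feature_roundtrip.csv"),
                row.names = FALSE)
    }
    write_cohort(cohort, file.path(out_dir, "cohort.csv"))

    stage <- "correlate"
    cors <- correlation_table(cohort)
    write.csv(cors, file.path(out_dir, "correlations.csv"), row.names = FALSE)

    stage <- "fit"
    cohort$female <- as.numeric(cohort$sex == "female")
    sp <- split_cohort(cohort, cfg$n_development, seed = cfg$seed)
    pool <- c("age", "female", "height", "weight",
              paste0("mean_rms_", MANEUVERS), paste0("max_rms_", MANEUVERS),
              paste0("ratio_rms_", MANEUVERS))
    model <- stepwise_ols(sp$development, "asm", pool,
                          p_enter = cfg$p_enter, p_exit = cfg$p_exit)
    write.csv(cbind(model$terms,
                    vif = c(NA, unname(model$vif))[seq_len(nrow(model$terms))]),
              file.path(out_dir, "model_terms.csv"), row.names = FALSE)

    stage <- "validate"
    val <- cross_validate(model, sp$validation)

    report <- c(
      utils::capture.output(print(model)),
      utils::capture.output(print(val))
    )
    writeLines(report, file.path(out_dir, "report.txt"))
    list(cohort = cohort, split = sp, correlations = cors, model = model,
         validation = val, roundtrip = roundtrip)
  }, error = function(e) {
    manifest$status <<- paste0("failed at stage '", stage, "': ",
                               conditionMessage(e))
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })

  files <- setdiff(list.files(out_dir, full.names = TRUE), manifest_path)
  manifest$status <- "complete"
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  manifest$checksums <- as.list(md5sum(sort(files)))
  names(manifest$checksums) <- basename(names(manifest$checksums))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  result$manifest <- manifest
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# render raw signals for (a subset of) subjects, reprocess them through the
# signal pipeline and overwrite the tabular features with the recovered ones
render_cohort_features <- function(cohort, cfg, out_dir) {
  idx <- seq_len(nrow(cohort))
  if (!is.null(cfg$render_subjects))
    idx <- head(idx, cfg$render_subjects)
  spec <- filter_spec(cfg$filter_low, cfg$filter_high, cfg$filter_order)
  window <- analysis_window(cfg$window_edge,
                            cfg$window_edge + cfg$duration)
  rt <- list()
  for (i in idx) {
    row <- cohort[i, ]
    for (m in MANEUVERS) {
      trials <- suppressWarnings(
        render_trial_signals(row, m, sampling_rate = cfg$sampling_rate,
                             duration = cfg$duration, seed = cfg$seed))
      if (isTRUE(cfg$write_signal_files))
        write_signals(trials, file.path(
          out_dir, sprintf("signals_%s_%s.csv", row$subject_id, m)))
      feat <- subject_features(trials, spec = spec, window = window)
      target_max <- max(row[[paste0("max_rms_", m)]],
                        row[[paste0("mean_rms_", m)]])
      rt[[length(rt) + 1]] <- data.frame(
        subject_id = row$subject_id, maneuver = m,
        rel_err_mean = abs(feat$mean_rms / row[[paste0("mean_rms_", m)]] - 1),
        rel_err_max = abs(feat$max_rms / target_max - 1),
        rel_err_ratio = abs(feat$ratio_rms / row[[paste0("ratio_rms_", m)]] - 1),
        stringsAsFactors = FALSE)
      cohort[i, paste0("mean_rms_", m)] <- feat$mean_rms
      cohort[i, paste0("max_rms_", m)] <- feat$max_rms
      cohort[i, paste0("ratio_rms_", m)] <- feat$ratio_rms
    }
  }
  list(cohort = cohort, roundtrip = do.call(rbind, rt))
}
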