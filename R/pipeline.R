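# End-to-end pipeline: simulate -> write/read EDF -> detect spindles ->
# sigma power -> cohort simulation -> trajectory fits, driven by one YAML
# configuration and recorded in a reproducibility manifest.

#' Default pipeline configuration
#'
#' Every tunable of the published pipeline appears under `detector` and
#' `spectral` with its published default (spindle band 10-16 Hz, onset
#' ratio 3 over 5 windows, offset 1.5 / 20% within 5 s; 2.56-s Hann windows,
#' 22 per epoch, sigma band 11.33-14.84 Hz, band limit 0.3-30 Hz order 8).
#'
#' @param out_dir Output directory.
#' @param n_subjects Number of simulated recordings (ignored when the
#'   configuration's `input_dir` is set, in which case every `*.edf` in that
#'   directory, with its `_hypnogram.tsv` / `_annotations.tsv` sidecars, is
#'   processed instead of simulating).
#' @param cohort_n Cohort size for the trajectory stage.
#' @param seed Master seed; per-subject seeds are derived from it.
#' @return Nested configuration list of class `run_config`.
#' @export
default_run_config <- function(out_dir = "spindletraj_run", n_subjects = 2,
                               cohort_n = 500, seed = 1L) {
  structure(list(
    out_dir = out_dir, input_dir = NULL, n_subjects = n_subjects,
    cohort_n = cohort_n,
    seed = as.integer(seed), reference = "auto", log_level = "info",
    eeg_sim = unclass(eeg_sim_config()),
    detector = unclass(detector_config()),
    spectral = unclass(spectral_config()),
    statistics = list(
      outcomes = c("density", "frequency", "power", "fast_percent",
                   "sigma_power"),
      covariates = DEFAULT_COVARIATES,
      segments = list(c(6, 10), c(11, 14), c(15, 17), c(18, 21)),
      mode = "cross_sectional")
  ), class = "run_config")
}

#' Write / read a pipeline configuration (YAML)
#'
#' Serialization round-trips: `read_run_config(write_run_config(cfg))`
#' reproduces `cfg`.
#'
#' @param config A `run_config`.
#' @param path YAML file path.
#' @return `path` / the configuration.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(strip_config(unclass(config)), path)
  path
}

strip_config <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_config)
  } else if (is.data.frame(x)) {
    x <- as.list(x)
  }
  x
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$eeg_sim$stage_sequence <- as.data.frame(cfg$eeg_sim$stage_sequence)
  structure(cfg, class = "run_config")
}

plog <- function(config, fmt, ...) {
  if (identical(config$log_level, "quiet")) return(invisible())
  message(sprintf(paste0("[spindletraj] ", fmt), ...))
}

list_to_config <- function(x, ctor) {
  args <- x[names(x) %in% names(formals(ctor))]
  do.call(ctor, args)
}

#' Run the full pipeline
#'
#' Simulates `n_subjects` recordings (seed-derived per subject), persists
#' them as EDF plus sidecar tables, re-reads each from disk, detects
#' spindles and computes sigma power, writes per-subject events and metric
#' tables, simulates a cohort and fits covariate-adjusted age trajectories
#' for each configured outcome, and writes a manifest (config hash, seed,
#' versions). A failing subject is logged and skipped; the run then exits
#' with nonzero status while retaining the other subjects' outputs.
#'
#' @param config A `run_config` (or path to one written by
#'   [write_run_config()]).
#' @return List: `status` (0 on full success), `outputs` (paths),
#'   `failures` (named character vector of error messages), `manifest`.
#' @export
run_pipeline <- function(config = default_run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(config$out_dir, "config.yaml")
  write_run_config(config, cfg_path)

  det_cfg <- list_to_config(config$detector, detector_config)
  spc_cfg <- list_to_config(config$spectral, spectral_config)

  # subjects: either pre-existing EDFs in input_dir, or seed-derived
  # simulations persisted to out_dir and re-read from disk
  if (!is.null(config$input_dir)) {
    edfs <- sort(list.files(config$input_dir, "\\.edf$", full.names = TRUE))
    ids <- sub("\\.edf$", "", basename(edfs))
  } else {
    ids <- sprintf("subject%02d", seq_len(config$n_subjects))
  }

  failures <- character(0)
  metrics_rows <- list()
  sigma_rows <- list()
  for (i in seq_along(ids)) {
    id <- ids[i]
    res <- tryCatch({
      if (is.null(config$input_dir)) {
        sim_cfg <- list_to_config(config$eeg_sim, eeg_sim_config)
        sim_cfg$seed <- config$seed + i
        sim <- simulate_sleep_eeg(sim_cfg)
        paths <- write_simulated_recording(sim, config$out_dir, id)
      } else {
        paths <- c(edf = file.path(config$input_dir, paste0(id, ".edf")),
                   hypnogram = file.path(config$input_dir,
                                         paste0(id, "_hypnogram.tsv")),
                   annotations = file.path(config$input_dir,
                                           paste0(id, "_annotations.tsv")))
        if (!file.exists(paths["annotations"])) paths["annotations"] <- NA
      }
      loaded <- read_recording(paths["edf"], paths["hypnogram"],
                               if (!is.na(paths["annotations"]))
                                 paths["annotations"] else NULL)
      policy <- if (identical(config$reference, "ipsilateral")) {
        "ipsilateral_only"
      } else "prefer_contralateral"
      sel <- select_central_channels(loaded$recording, policy)
      chans <- c(sel$left, sel$right)
      grid <- epoch_grid(loaded$recording, loaded$hypnogram,
                         loaded$annotations)
      events <- detect_spindles(loaded$recording, loaded$hypnogram,
                                loaded$annotations, det_cfg, chans)
      write.table(events, file.path(config$out_dir,
                                    paste0(id, "_spindles.tsv")),
                  sep = "\t", row.names = FALSE, quote = FALSE)
      met <- summarize_metrics(events, grid, chans)
      met$subject_id <- id
      sig <- sigma_power_analysis(loaded$recording, loaded$hypnogram,
                                  loaded$annotations, spc_cfg, chans)
      sig$subject_id <- id
      plog(config, "%s: %d spindles kept, sigma %.2f uV^2",
           id, sum(events$rejected_reason == ""),
           sig$sigma_power_uv2[sig$channel == "average"])
      list(metrics = met, sigma = sig)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[id] <- conditionMessage(res)
      plog(config, "%s FAILED at recording stage: %s", id, failures[id])
    } else {
      metrics_rows[[id]] <- res$metrics
      sigma_rows[[id]] <- res$sigma
    }
  }

  outputs <- c(config = cfg_path)
  if (length(metrics_rows)) {
    metrics <- do.call(rbind, metrics_rows)
    outputs["metrics"] <- file.path(config$out_dir, "metrics.csv")
    write.csv(metrics, outputs["metrics"], row.names = FALSE)
    sigma <- do.call(rbind, sigma_rows)
    outputs["sigma"] <- file.path(config$out_dir, "sigma.csv")
    write.csv(sigma, outputs["sigma"], row.names = FALSE)
  }

  cohort <- simulate_cohort(
    cohort_sim_config(n_subjects = config$cohort_n, seed = config$seed),
    mode = config$statistics$mode)
  outputs["cohort"] <- file.path(config$out_dir, "cohort.csv")
  write.csv(cohort$table, outputs["cohort"], row.names = FALSE)

  fits <- list()
  curves <- list()
  for (oc in config$statistics$outcomes) {
    tf <- fit_age_trajectory(cohort$table, oc,
                             covariates = config$statistics$covariates)
    ext <- locate_extrema(tf)
    fits[[oc]] <- list(degree = tf$degree, r_squared = tf$r_squared,
                       coefficients = as.data.frame(tf$coefficients),
                       age_at_min = ext$age_at_min,
                       age_at_max = ext$age_at_max)
    cv <- predict_mean_curve(tf, seq(6, 21, by = 0.5))
    cv$outcome <- oc
    curves[[oc]] <- cv
  }
  outputs["fits"] <- file.path(config$out_dir, "fits.json")
  jsonlite::write_json(fits, outputs["fits"], auto_unbox = TRUE, digits = NA)
  outputs["curves"] <- file.path(config$out_dir, "curves.csv")
  write.csv(do.call(rbind, curves), outputs["curves"], row.names = FALSE)

  manifest <- list(
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    package_version = as.character(packageVersion("spindletraj")),
    r_version = R.version.string,
    n_subjects_ok = length(metrics_rows),
    n_subjects_failed = length(failures),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  outputs["manifest"] <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, outputs["manifest"], auto_unbox = TRUE)

  list(status = if (length(failures)) 1L else 0L, outputs = outputs,
       failures = failures, manifest = manifest)
}
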