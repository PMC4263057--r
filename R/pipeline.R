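#' Validate a run configuration
#'
#' Configurations drive [run_pipeline()] and the command-line wrapper
#' (\code{inst/cli/pcmri.R}). They are YAML (or an equivalent named list)
#' with a \code{task} plus the keys that task needs; unknown keys are
#' rejected outright so typos fail before any computation.
#'
#' Recognized keys: \code{task} (simulate | validate | segment | analyze |
#' cohort | report), \code{seed}, \code{out}, \code{phantom} (arguments for
#' [phantom_spec()]), \code{series_dir}, \code{masks_file}, \code{roi_box},
#' \code{seed_point}, \code{pressures} (\code{ps}, \code{pd} in mmHg),
#' \code{flags} (\code{eoa_averaging}, \code{smooth_area}),
#' \code{records_csv}, \code{metrics}, \code{group_levels}.
#'
#' @param config path to a YAML file, or a named list.
#' @return The validated configuration list (class \code{run_config}), with
#'   its hash attached as attribute \code{"hash"}.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      stop_invalid_spec(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config) || is.null(names(config)))
    stop_invalid_spec("config must be a named list or a YAML file")
  known <- c("task", "seed", "out", "phantom", "series_dir", "masks_file",
             "roi_box", "seed_point", "pressures", "flags", "records_csv",
             "metrics", "group_levels")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop_invalid_spec(paste0("unknown config keys: ",
                             paste(unknown, collapse = ", ")))
  tasks <- c("simulate", "validate", "segment", "analyze", "cohort", "report")
  if (is.null(config$task) || !config$task %in% tasks)
    stop_invalid_spec(paste0("config$task must be one of: ",
                             paste(tasks, collapse = ", ")))
  if (!is.null(config$flags)) {
    fl_known <- c("eoa_averaging", "smooth_area")
    fl_unknown <- setdiff(names(config$flags), fl_known)
    if (length(fl_unknown))
      stop_invalid_spec(paste0("unknown flags: ",
                               paste(fl_unknown, collapse = ", ")))
  }
  if (!is.null(config$pressures) &&
      !all(c("ps", "pd") %in% names(config$pressures)))
    stop_invalid_spec("pressures must provide 'ps' and 'pd' (mmHg)")
  config$seed <- as.integer(config$seed %||% 1L)
  attr(config, "hash") <- config_hash(config)
  class(config) <- c("run_config", "list")
  config
}

write_stamped_json <- function(x, path, hash) {
  x$config_hash <- hash
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  invisible(path)
}

metrics_as_list <- function(res) {
  el <- res$elasticity
  list(
    q_max = res$flow$q_max, q_mean = res$flow$q_mean,
    peak_frame = res$flow$peak_frame,
    v_max = res$orifice$v_max, a_orifice = res$orifice$a_orifice,
    a_sinus = res$orifice$a_sinus, orifice_ratio = res$orifice$orifice_ratio,
    a_sinus_source = res$orifice$a_sinus_source,
    elasticity = if (!is.null(el)) unclass(el),
    units = list(q = "ml/s", v = "cm/s", area = "cm^2",
                 compliance = "mm^2.mmHg^-1.1e-3",
                 distensibility = "mmHg^-1.1e-3",
                 beta = "cm^-1 (beta_normalized dimensionless)")
  )
}

#' Run one pipeline task
#'
#' Executes the task described by a validated configuration and writes its
#' artifacts under \code{config$out}; every JSON artifact carries the
#' configuration hash, and identical configuration plus seed yields
#' identical outputs.
#'
#' @param config a [run_config()] (or anything it accepts).
#' @return Invisibly, a list of the artifact paths written (and, where
#'   meaningful, the computed object).
#' @export
run_pipeline <- function(config) {
  config <- run_config(config)
  hash <- attr(config, "hash")
  out <- config$out %||% "."
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  fl <- config$flags %||% list()

  load_masks <- function(series) {
    if (is.null(config$masks_file)) return(NULL)
    arr <- as.array(RNifti::readNifti(config$masks_file))
    segment_lumen(series, masks = array(arr > 0.5, dim(arr)))
  }

  switch(config$task,
    simulate = {
      ph_args <- config$phantom %||% list()
      ph_args$seed <- ph_args$seed %||% config$seed
      spec <- do.call(phantom_spec, ph_args)
      ph <- generate_phantom(spec)
      sdir <- file.path(out, "series")
      write_series(ph$series, sdir)
      tr <- unclass(ph$truth)
      write_stamped_json(tr, file.path(out, "truth.json"), hash)
      invisible(list(series_dir = sdir,
                     truth = file.path(out, "truth.json"),
                     phantom = ph))
    },
    validate = {
      series <- read_series(config$series_dir)
      invisible(list(ok = TRUE, n_frames = dim(series$magnitude)[3]))
    },
    segment = {
      series <- read_series(config$series_dir)
      masks <- segment_lumen(series, roi_box = config$roi_box,
                             seed_point = config$seed_point)
      mpath <- file.path(out, "masks.nii.gz")
      RNifti::writeNifti(RNifti::asNifti(masks$masks * 1L), mpath)
      aw <- area_waveform(masks, smooth = isTRUE(fl$smooth_area))
      utils::write.csv(data.frame(frame = seq_along(aw), area_cm2 = aw),
                       file.path(out, "area.csv"), row.names = FALSE)
      invisible(list(masks_file = mpath, area = aw))
    },
    analyze = {
      series <- read_series(config$series_dir)
      p <- if (!is.null(config$pressures))
        pressure_pair(config$pressures$ps, config$pressures$pd)
      res <- analyze_series(
        series, pressures = p, masks = load_masks(series),
        roi_box = config$roi_box, seed_point = config$seed_point,
        eoa_averaging = fl$eoa_averaging %||% "signed",
        smooth_area = isTRUE(fl$smooth_area))
      mpath <- file.path(out, "metrics.json")
      write_stamped_json(metrics_as_list(res), mpath, hash)
      utils::write.csv(
        data.frame(frame = seq_along(res$flow$q), time_ms = res$flow$times,
                   q_mls = res$flow$q, area_cm2 = res$area),
        file.path(out, "waveform.csv"), row.names = FALSE)
      invisible(list(metrics = mpath, result = res))
    },
    cohort = ,
    report = {
      records <- utils::read.csv(config$records_csv, stringsAsFactors = FALSE)
      sm <- summarize_cohort(records, metrics = config$metrics,
                             group_levels = config$group_levels)
      utils::write.csv(as.data.frame(sm), file.path(out, "cohort_summary.csv"),
                       row.names = FALSE)
      if (config$task == "report") {
        txt <- utils::capture.output(print(format_group_summary(sm)))
        writeLines(c(sprintf("# config %s", hash), txt),
                   file.path(out, "cohort_report.txt"))
      }
      invisible(list(summary = sm,
                     csv = file.path(out, "cohort_summary.csv")))
    })
}
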