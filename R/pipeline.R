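# Config schema: allowed keys per section. Unknown keys are collected and
# reported all at once so a config can be repaired in one pass.
.config_schema <- list(
  top = c("seed", "out_dir", "protocol", "calcium", "sv", "cohort", "scene",
          "correction", "fitting", "summary"),
  protocol = c("pulses", "neuron_class", "total_duration", "frame_interval"),
  calcium = c("baseline", "suppressed_level", "overshoot_gain",
              "overshoot_rise_time", "overshoot_decay_tau", "transition_tau"),
  sv = c("pool_size", "k_exo_basal", "k_exo_ca_gain", "k_ret_basal",
         "k_ret_fast", "accel_window", "accel_ca_threshold", "fluor_scale",
         "dark_offset", "finite_pool"),
  cohort = c("groups", "output", "trace_noise_sd"),
  groups = c("name", "n_trials", "k_exo_scale", "k_ret_scale"),
  scene = c("image_shape", "n_puncta", "punctum_sigma", "punctum_amplitudes",
            "axon_axis", "background_level", "axon_line_frac", "bleach_slope",
            "drift_step_sd", "read_noise_sd", "shot_noise", "max_intensity",
            "seed"),
  correction = c("bleach_drop_threshold", "bleach_span", "f_o_floor",
                 "reference_window", "window_length"),
  fitting = c("max_terms", "complexity_threshold", "fit_window", "n_starts"),
  summary = c("k_sd"))

#' Validate a pipeline configuration
#'
#' Checks every section of the configuration against the schema and raises a
#' single error listing all unknown keys, or returns the config invisibly.
#'
#' @param config named list (parsed YAML/JSON).
#' @return `config`, invisibly.
#' @export
validate_config <- function(config) {
  stopifnot(is.list(config))
  problems <- character(0)
  check <- function(x, allowed, where) {
    if (is.null(x) || !is.list(x)) return()
    bad <- setdiff(names(x), allowed)
    if (length(bad) > 0L) {
      problems <<- c(problems,
                     sprintf("unknown key '%s' in %s", bad, where))
    }
  }
  check(config, .config_schema$top, "config")
  for (sec in c("protocol", "calcium", "sv", "cohort", "scene",
                "correction", "fitting", "summary")) {
    check(config[[sec]], .config_schema[[sec]], sec)
  }
  if (!is.null(config$cohort$groups)) {
    for (i in seq_along(config$cohort$groups)) {
      check(config$cohort$groups[[i]], .config_schema$groups,
            sprintf("cohort$groups[[%d]]", i))
    }
  }
  if (length(problems) > 0L) {
    stop("invalid config:\n  ", paste(problems, collapse = "\n  "))
  }
  if (is.null(config$protocol)) stop("invalid config:\n  missing `protocol`")
  invisible(config)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path file ending in `.yaml`/`.yml` or `.json`.
#' @return validated config list.
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.(ya?ml)$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  validate_config(cfg)
  cfg
}

config_protocol <- function(config) {
  p <- config$protocol
  stimulus_protocol(
    pulses = p$pulses %||% list(),
    neuron_class = p$neuron_class %||% "awc_like",
    total_duration = p$total_duration,
    frame_interval = p$frame_interval %||% 0.2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

args_from <- function(x, fn) {
  if (is.null(x)) return(list())
  x[intersect(names(x), names(formals(fn)))]
}

config_objects <- function(config) {
  ca_cfg <- config$calcium
  if (!is.null(ca_cfg$overshoot_gain)) {
    ca_cfg$overshoot_gain <- as.data.frame(ca_cfg$overshoot_gain)
  }
  list(protocol = config_protocol(config),
       ca = do.call(calcium_params, args_from(ca_cfg, calcium_params)),
       sv = do.call(sv_cycle_params, args_from(config$sv, sv_cycle_params)),
       correction = do.call(correction_config,
                            args_from(config$correction, correction_config)))
}

# movie -> dF/F: register, segment, background ROIs, extract, correct
process_movie_to_dff <- function(movie, protocol, correction,
                                 rolling_ball_radius = 10,
                                 anterior_only = protocol$neuron_class ==
                                   "ash_like") {
  reg <- register_xy(movie)
  seg <- make_segmentation_image(reg$movie,
                                 rolling_ball_radius = rolling_ball_radius)
  mask <- segment_axon(seg)
  rois <- place_background_rois(mask, anterior_only = anterior_only)
  traces <- extract_traces(reg$movie, mask, rois,
                           drop_frames = which(reg$flagged))
  corr <- correct_traces(traces, protocol, correction,
                         anterior_only = anterior_only)
  attr(corr, "registration") <- reg$shifts
  attr(corr, "mask_area") <- mask$area
  corr
}

#' Run the full pipeline from a configuration
#'
#' Executes simulate -> (process) -> correct -> fit -> summarize and writes
#' per-trial dF/F tables (CSV), fit reports (JSON), a cohort summary (CSV),
#' and a run manifest (JSON, with all per-trial seeds) under `out_dir`.
#' Rerunning with an identical config and seed reproduces every output
#' byte-for-byte.
#'
#' @param config configuration list (see [validate_config()]) or a path to a
#'   YAML/JSON file.
#' @param out_dir output directory; overrides `config$out_dir`.
#' @param seed master seed; overrides `config$seed`.
#' @return (invisibly) list with `manifest`, `trials` (per-trial summaries),
#'   and `summary` per group.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  if (is.character(config)) config <- read_config(config)
  validate_config(config)
  seed <- as.integer(seed %||% config$seed %||% 1L)
  out_dir <- out_dir %||% config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  obj <- config_objects(config)
  cohort_cfg <- config$cohort %||%
    list(groups = list(list(name = "wt", n_trials = 3L)))
  output <- cohort_cfg$output %||% "traces"
  scene <- if (output == "movies") {
    do.call(scene_config, args_from(config$scene, scene_config))
  }
  cohort <- make_cohort(cohort_cfg$groups, obj$protocol, obj$ca, obj$sv,
                        output = output, scene = scene,
                        trace_noise_sd = cohort_cfg$trace_noise_sd %||% 150,
                        seed = seed)
  fit_cfg <- config$fitting %||% list()
  k_sd <- (config$summary %||% list())$k_sd %||% 3

  rows <- list()
  dff_by_group <- list()
  for (i in seq_along(cohort$trials)) {
    tr <- cohort$trials[[i]]
    corr <- if (!is.null(tr$movie)) {
      process_movie_to_dff(tr$movie, tr$protocol, obj$correction)
    } else {
      compute_dff(tr$recording$fluor, tr$recording$time_s, tr$protocol,
                  obj$correction)
    }
    responder <- if (isTRUE(corr$flags$low_F_o)) NA else {
      tryCatch(classify_responder(corr$dff, corr$time, tr$protocol,
                                  k_sd = k_sd),
               error = function(e) NA)
    }
    ep <- decay_epoch_for_pulse(tr$protocol, 1L,
                                fit_window = fit_cfg$fit_window %||% 20)
    idx <- corr$time >= ep[1L] & corr$time <= ep[2L]
    fit <- if (isTRUE(corr$flags$low_F_o)) NULL else {
      tryCatch(select_decay_model(
        corr$dff[idx], corr$time[idx],
        max_terms = fit_cfg$max_terms %||% 1L,
        complexity_threshold = fit_cfg$complexity_threshold %||% 0.95,
        n_starts = fit_cfg$n_starts %||% 5L)$fit,
        error = function(e) NULL)
    }
    pk <- tryCatch(peak_response(corr$dff, corr$time,
                                 tr$protocol$pulses$t_on[1L],
                                 window = 30),
                   error = function(e) list(peak = NA_real_))
    rows[[i]] <- data.frame(
      group = tr$group, trial = tr$trial, seed = tr$seed,
      F_o = corr$F_o, peak_dff = pk$peak,
      tau_s = if (is.null(fit) || !fit$converged) NA_real_ else fit$tau[1L],
      n_terms = if (is.null(fit)) NA_integer_ else fit$n_terms,
      responder = responder,
      low_F_o = isTRUE(corr$flags$low_F_o))
    dff_by_group[[tr$group]] <- c(dff_by_group[[tr$group]],
                                  list(corr$dff))
    if (!is.null(out_dir)) {
      utils::write.csv(
        data.frame(time_s = corr$time, F = corr$F, dff = corr$dff),
        file.path(out_dir, sprintf("trace_%s_%02d.csv", tr$group, tr$trial)),
        row.names = FALSE)
    }
  }
  trial_table <- do.call(rbind, rows)
  summaries <- lapply(names(dff_by_group), function(g) {
    resp <- trial_table$responder[trial_table$group == g]
    aggregate_trials(dff_by_group[[g]],
                     responders = resp[!is.na(resp)])
  })
  names(summaries) <- names(dff_by_group)

  if (!is.null(out_dir)) {
    utils::write.csv(trial_table, file.path(out_dir, "trials.csv"),
                     row.names = FALSE)
    utils::write.csv(cohort$manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(seed = seed, n_trials = nrow(cohort$manifest),
           groups = lapply(cohort_cfg$groups, function(g) g$name),
           package_version = as.character(utils::packageVersion("svflux"))),
      file.path(out_dir, "run_manifest.json"), auto_unbox = TRUE)
  }
  invisible(list(manifest = cohort$manifest, trials = trial_table,
                 summary = summaries))
}
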