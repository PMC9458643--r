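experiment_kinds <- c("simulate", "landscape", "lead-sweep", "silence",
                      "rmax-sweep", "persistence")

#' Experiment configuration
#'
#' A declarative description of one experiment run: model preset and
#' overrides, stimulus protocol, grid, classifier settings and the
#' experiment selector. Configurations round-trip losslessly through
#' YAML/JSON via [write_experiment_config()] and
#' [read_experiment_config()] and drive [run_experiment()].
#'
#' @param experiment One of `"simulate"`, `"landscape"`, `"lead-sweep"`,
#'   `"silence"`, `"rmax-sweep"`, `"persistence"`.
#' @param preset Parameter preset (`"adjusted"` or `"jovanic"`).
#' @param w_iLNa,w_iLNb Input weights for single-point simulation.
#' @param r_max Optional saturation-ceiling override.
#' @param protocol Named list of [stimulus_protocol()] arguments.
#' @param grid Named list of [grid_spec()] arguments.
#' @param thresholds Named list of [classifier_thresholds()] arguments.
#' @param silenced Character vector of neurons silenced in
#'   simulate/landscape runs.
#' @param intervals Lead intervals for `"lead-sweep"`.
#' @param targets List of neuron sets for `"silence"`.
#' @param r_max_values Saturation ceilings for `"rmax-sweep"`.
#' @param dt Integration step.
#' @param seed Optional integer, recorded with the outputs; the model is
#'   deterministic, the field is reserved for stochastic extensions.
#' @return An object of class `experiment_config`.
#' @examples
#' cfg <- experiment_config("simulate", w_iLNa = 0.95, w_iLNb = 2.45,
#'                          protocol = list(pulse_amplitude = 0.45))
#' @export
experiment_config <- function(experiment = "simulate",
                              preset = "adjusted",
                              w_iLNa = 1, w_iLNb = 2,
                              r_max = NULL,
                              protocol = list(),
                              grid = list(),
                              thresholds = list(),
                              silenced = character(),
                              intervals = c(10, 30, 50),
                              targets = list("iLNa", "Hb"),
                              r_max_values = c(15, 20),
                              dt = 0.05,
                              seed = NULL) {
  if (!experiment %in% experiment_kinds)
    abort(paste0("config field `experiment` must be one of: ",
                 paste(experiment_kinds, collapse = ", ")))
  if (!preset %in% c("adjusted", "jovanic"))
    abort("config field `preset` must be \"adjusted\" or \"jovanic\"")
  if (!is.numeric(dt) || dt <= 0) abort("config field `dt` must be > 0")
  if (!is.null(grid$increment) && grid$increment <= 0)
    abort("config field `grid.increment` must be > 0")
  if (!is.list(protocol)) abort("config field `protocol` must be a list")
  if (experiment != "simulate" && is.null(protocol$pulse_amplitude))
    protocol$pulse_amplitude <- if (experiment == "silence") 2 else 0.45
  if (experiment == "simulate" && is.null(protocol$pulse_amplitude))
    protocol$pulse_amplitude <- 0.45
  structure(list(experiment = experiment, preset = preset,
                 w_iLNa = w_iLNa, w_iLNb = w_iLNb, r_max = r_max,
                 protocol = protocol, grid = grid, thresholds = thresholds,
                 silenced = as.character(silenced),
                 intervals = intervals, targets = targets,
                 r_max_values = r_max_values, dt = dt, seed = seed),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML or JSON
#'
#' @param path File path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  raw <- raw[!vapply(raw, is.null, logical(1))]
  if (!is.null(raw$targets)) raw$targets <- as.list(unlist(raw$targets))
  known <- names(formals(experiment_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    abort(paste0("unknown config field(s): ", paste(unknown, collapse = ", ")))
  do.call(experiment_config, raw)
}

#' Write an experiment configuration to YAML or JSON
#'
#' @param config An [experiment_config()].
#' @param path Destination path (`.yaml`/`.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_experiment_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  x <- unclass(config)
  x <- x[!vapply(x, function(e) is.null(e) ||
                   (is.list(e) && length(e) == 0) ||
                   (is.character(e) && length(e) == 0), logical(1))]
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  else yaml::write_yaml(x, path)
  invisible(path)
}

config_objects <- function(config) {
  params <- circuit_parameters(config$preset,
                               w_iLNa = config$w_iLNa,
                               w_iLNb = config$w_iLNb,
                               r_max = config$r_max)
  list(params = params,
       protocol = do.call(stimulus_protocol, config$protocol),
       grid = do.call(grid_spec, config$grid),
       thresholds = do.call(classifier_thresholds, config$thresholds))
}

write_table <- function(x, path) {
  readr::write_csv(x, path)
  path
}

#' Run a configured experiment and write its artifacts
#'
#' Dispatches on the configuration's experiment selector, runs it through
#' the package's simulation and landscape functions, and writes all
#' outputs into `out_dir`: the fully resolved configuration
#' (`resolved-config.yaml`), a run log (`run-info.txt`), the result
#' tables (CSV/JSON) and a manifest with MD5 checksums of every written
#' file (`manifest.csv`). Outputs are deterministic: re-running an
#' identical configuration reproduces byte-identical tables.
#'
#' @param config An [experiment_config()] (or a path readable by
#'   [read_experiment_config()]).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with `files` (written paths) and `result`
#'   (the main computed object).
#' @export
run_experiment <- function(config, out_dir) {
  if (is.character(config)) config <- read_experiment_config(config)
  stopifnot(inherits(config, "experiment_config"))
  obj <- config_objects(config)  # validates before anything is written
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  files <- character()
  keep <- function(p) { files <<- c(files, p); p }

  kind <- config$experiment
  result <- switch(kind,
    simulate = {
      traj <- simulate_circuit(obj$params, obj$protocol,
                               silenced = config$silenced, dt = config$dt)
      out <- classify_behaviour(traj, thresholds = obj$thresholds)
      tab <- as_tibble(traj)[, c("time", neuron_labels)]
      names(tab) <- c("time", paste0("r_", neuron_labels))
      keep(write_table(tab, file.path(out_dir, "trajectory.csv")))
      keep(write_table(
        mutate(out$labels, label = as.character(.data$label)),
        file.path(out_dir, "labels.csv")))
      jsonlite::write_json(
        list(label = out$label,
             bouts = out$bouts,
             window = as.list(out$window),
             parameters = list(preset = obj$params$preset,
                               w_iLNa = obj$params$w_iLNa,
                               w_iLNb = obj$params$w_iLNb,
                               r_max = obj$params$r_max),
             silenced = config$silenced),
        keep(file.path(out_dir, "outcome.json")),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
      out
    },
    landscape = {
      land <- sweep_landscape(obj$grid, obj$params, obj$protocol,
                              silenced = config$silenced,
                              thresholds = obj$thresholds, dt = config$dt)
      keep(write_table(mutate(tidy(land), label = as.character(.data$label)),
                       file.path(out_dir, "landscape.csv")))
      keep(write_table(glance(land), file.path(out_dir, "fractions.csv")))
      land
    },
    "lead-sweep" = {
      sw <- lead_interval_sweep(obj$grid, obj$params, obj$protocol,
                                intervals = config$intervals,
                                thresholds = obj$thresholds, dt = config$dt)
      keep(write_table(sw, file.path(out_dir, "lead_sweep.csv")))
      sw
    },
    silence = {
      sil <- silencing_experiment(obj$grid, obj$params, obj$protocol,
                                  targets = config$targets,
                                  thresholds = obj$thresholds, dt = config$dt)
      keep(write_table(sil, file.path(out_dir, "silencing.csv")))
      sil
    },
    "rmax-sweep" = {
      rx <- rmax_experiment(obj$grid, obj$params, obj$protocol,
                            r_max_values = config$r_max_values,
                            thresholds = obj$thresholds, dt = config$dt)
      keep(write_table(rx, file.path(out_dir, "rmax_sweep.csv")))
      rx
    },
    persistence = {
      prot <- obj$protocol
      if (!prot$prepulse)
        abort("config field `protocol.prepulse` must be TRUE for persistence")
      pm <- persistence_map(obj$grid, obj$params, prot,
                            silenced = config$silenced, dt = config$dt)
      keep(write_table(
        mutate(pm, neuron = as.character(.data$neuron)),
        file.path(out_dir, "persistence.csv")))
      pm
    })

  keep(write_experiment_config(config, file.path(out_dir, "resolved-config.yaml")))
  info <- c(
    paste("experiment:", kind),
    paste("preset:", config$preset),
    paste("dt:", config$dt),
    paste("grid_points:", if (kind == "simulate") 1 else nrow(grid_points(obj$grid))),
    paste("wall_clock_s:", round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3)))
  writeLines(info, keep(file.path(out_dir, "run-info.txt")))

  manifest <- tibble(file = basename(files),
                     md5 = unname(tools::md5sum(files)))
  write_table(manifest, file.path(out_dir, "manifest.csv"))
  invisible(list(files = c(files, file.path(out_dir, "manifest.csv")),
                 result = result))
}
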