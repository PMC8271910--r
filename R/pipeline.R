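#' Reproducible pipeline configuration
#'
#' `default_run_config()` returns the configuration the method is defined
#' with: forward-solver relative-residual tolerance `1e-6` with up to six
#' multigrid levels, nine electrodes, a 6 mm source lattice, 100 test
#' dipoles, the SNR grid `{0, 10, 20, 30, Inf}` dB with 1000 noise
#' patterns, and 1.9 m/s ventricular conduction speed for tracking.
#' `load_run_config()` reads a YAML file and fills unset fields from the
#' defaults (the YAML strings `"Inf"`/`".inf"` are accepted for infinite
#' SNR).
#'
#' @param path YAML configuration path.
#' @return A nested configuration list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    model = list(phantom = list(dims = c(40, 40, 40), pitch_mm = 2),
                 path = NULL),
    electrodes = NULL,                      # NULL = phantom layout (9 sites)
    solver = list(tol = 1e-6, levels = 6, omega = 1.5, method = "direct"),
    lfm = list(spacing_mm = 6),
    study = list(n_dipoles = 100, snr_db = Inf, seed = 1),
    sweep = list(snr_grid = c(0, 10, 20, 30, Inf), n_noise = 1000),
    track = list(v_m_s = 1.9, dt_s = 0.001, n_steps = 20,
                 Q = NULL, R = NULL, x0_mm = NULL)
  ), class = "run_config")
}

#' @rdname default_run_config
#' @export
load_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- modify_defaults(unclass(default_run_config()), user)
  cfg$study$snr_db <- parse_snr(cfg$study$snr_db)
  cfg$sweep$snr_grid <- parse_snr(cfg$sweep$snr_grid)
  structure(cfg, class = "run_config")
}

modify_defaults <- function(def, user) {
  for (nm in names(user)) {
    if (is.list(def[[nm]]) && is.list(user[[nm]])) {
      def[[nm]] <- modify_defaults(def[[nm]], user[[nm]])
    } else {
      def[[nm]] <- user[[nm]]
    }
  }
  def
}

parse_snr <- function(x) {
  vapply(x, function(v) {
    if (is.character(v) && tolower(v) %in% c("inf", ".inf", "infinity")) Inf
    else as.numeric(v)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Run the localization pipeline end-to-end
#'
#' Executes the configured stages — conductor model (phantom generation
#' or file load), lead-field construction, dipole study, SNR sweep,
#' trajectory tracking — writing versioned CSV/JSON artifacts and a
#' manifest (configuration, seeds, package version, per-stage status) to
#' `out_dir`. Runs are deterministic: the same configuration produces
#' byte-identical study tables.
#'
#' @param config A `run_config` (default [default_run_config()]).
#' @param out_dir Output directory (created if needed).
#' @param stages Which stages to run, in order; `"track"` and `"sweep"`
#'   are opt-in since they dominate runtime.
#' @return Invisibly, a list with the in-memory artifacts (model, lfm,
#'   study, ...) and the manifest.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir,
                         stages = c("model", "lfm", "study")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "cardiosource",
                   version = as.character(utils::packageVersion("cardiosource")),
                   config = config, stages = list())
  res <- list()
  status <- function(stage, ok, note = NULL) {
    manifest$stages[[stage]] <<- list(ok = ok, note = note)
  }

  spec <- do.call(phantom_spec, config$model$phantom %||% list())
  if (!is.null(config$model$path)) {
    res$model <- load_model(config$model$path)
  } else {
    res$model <- make_block_torso(spec)
  }
  res$electrodes <- if (is.null(config$electrodes)) {
    phantom_electrodes(spec)
  } else {
    electrode_set(config$electrodes)
  }
  status("model", TRUE)

  if ("lfm" %in% stages || any(c("study", "sweep", "track") %in% stages)) {
    grid <- select_source_points(res$model, config$lfm$spacing_mm)
    res$lfm <- build_lfm(res$model, res$electrodes, grid,
                         solver = config$solver)
    save_lfm(res$lfm, file.path(out_dir, "leadfield"))
    status("lfm", TRUE, sprintf("%d points", nrow(grid)))
  }

  if ("study" %in% stages) {
    res$study <- run_dipole_study(res$model, res$lfm,
                                  n_dipoles = config$study$n_dipoles,
                                  snr_db = config$study$snr_db,
                                  seed = config$study$seed)
    write.csv(tidy(res$study), file.path(out_dir, "study.csv"),
              row.names = FALSE)
    jsonlite::write_json(as.list(glance(res$study)),
                         file.path(out_dir, "study_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    status("study", TRUE)
  }

  if ("sweep" %in% stages) {
    res$sweep <- run_snr_sweep(res$model, res$lfm,
                               n_dipoles = config$study$n_dipoles,
                               snr_grid = config$sweep$snr_grid,
                               n_noise = config$sweep$n_noise,
                               seed = config$study$seed)
    write.csv(glance(res$sweep), file.path(out_dir, "snr_sweep.csv"),
              row.names = FALSE)
    status("sweep", TRUE)
  }

  if ("track" %in% stages) {
    tc <- config$track
    start <- tc$x0_mm %||%
      ((spec$heart_center - 1) * spec$pitch_mm)   # cardiac-centre default
    traj <- make_trajectory(res$model, start,
                            directions = c(1, 0, 0),
                            v_m_s = tc$v_m_s, dt_s = tc$dt_s,
                            n_steps = tc$n_steps)
    obs <- synthesize_observations(traj, res$lfm, res$model,
                                   snr_db = config$study$snr_db,
                                   seed = config$study$seed)
    Q <- tc$Q %||% estimate_Q(res$study %||%
                                run_dipole_study(res$model, res$lfm,
                                                 n_dipoles = 20,
                                                 seed = config$study$seed))
    R <- tc$R %||% estimate_R(res$lfm,
                              subset_size = min(500, nrow(res$lfm$points)),
                              seed = config$study$seed)
    cfgk <- track_config(start, v_m_s = tc$v_m_s, dt_s = tc$dt_s,
                         Q = Q, R = R)
    res$track <- track_source(obs, cfgk)
    write.csv(tidy(res$track), file.path(out_dir, "track.csv"),
              row.names = FALSE)
    status("track", TRUE)
  }

  manifest$config <- serializable_config(config)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(c(res, list(manifest = manifest)))
}

# JSON cannot carry Inf; stringify for the manifest
serializable_config <- function(x) {
  rapply(unclass(x), function(v) {
    if (is.numeric(v) && any(is.infinite(v))) as.character(v) else v
  }, how = "replace")
}
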