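#' Default run configuration
#'
#' Flat key-value configuration driving the simulate/quantify/stats
#' commands. Thresholds default to the study conventions (dip 1.75e-4,
#' overshoot 3.5e-4, condensed 2.5e-4 dR/R), smoothing to half-width 5 px,
#' alpha to 0.05 with Sidak-corrected contrasts.
#'
#' @param ... Named overrides of any default.
#' @return Named list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    out_dir = "isoi_out",
    seed = 1L,
    groups = "1,2,3,4,5",
    n_per_group = 8L,
    img_px = 64L,
    trials_sparse = 4L,
    trials_condensed = 4L,
    noise_sd = 3e-3,
    threshold_dip = 1.75e-4,
    threshold_overshoot = 3.5e-4,
    threshold_condensed = 2.5e-4,
    half_width = 5,
    infarct_intercept = 5,
    infarct_slope = 3,
    infarct_noise_sd = 0.5,
    group5_p_protected = 0.5,
    edema_factor = 1.08,
    alpha = 0.05,
    correction = "sidak",
    log_level = "INFO"
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Read a flat YAML run configuration
#'
#' Unknown keys are an error; missing keys fall back to
#' [default_config()] values. Every threshold must be positive.
#'
#' @param path YAML file of flat key-value pairs.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  cfg <- do.call(default_config, vals)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  thr <- c(cfg$threshold_dip, cfg$threshold_overshoot, cfg$threshold_condensed)
  if (any(thr <= 0)) stop("every threshold must be > 0")
  if (cfg$half_width <= 0) stop("half_width must be > 0")
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

config_groups <- function(cfg) {
  as.integer(strsplit(as.character(cfg$groups), ",")[[1]])
}

config_design <- function(cfg) {
  study_design(
    n_per_group = cfg$n_per_group,
    infarct_intercept = cfg$infarct_intercept,
    infarct_slope = cfg$infarct_slope,
    infarct_noise_sd = cfg$infarct_noise_sd,
    group5_p_protected = cfg$group5_p_protected,
    edema_factor = cfg$edema_factor
  )
}

config_study <- function(cfg) {
  make_study(
    config_design(cfg), seed = cfg$seed, groups = config_groups(cfg),
    img_px = cfg$img_px,
    n_trials = c(sparse = as.integer(cfg$trials_sparse),
                 condensed = as.integer(cfg$trials_condensed)),
    noise_sd = cfg$noise_sd
  )
}

log_msg <- function(cfg, level, ...) {
  levels <- c(DEBUG = 0, INFO = 1, WARNING = 2, ERROR = 3)
  if (levels[[level]] >= levels[[cfg$log_level]])
    message(sprintf("[%s] %s", level, paste0(...)))
}
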