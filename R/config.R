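#' Analysis configuration
#'
#' Bundles the thresholds and switches used across the pipeline: the proximity
#' buffer width, the correlated-random-walk null-model settings, the LFT event
#' rules, the travel filter, and bootstrap defaults.
#'
#' @param buffer_m Proximity buffer half-width in meters. A position is "near"
#'   a feature when its distance is strictly below this value. Default 10;
#'   5 and 15 are the usual sensitivity settings.
#' @param n_controls Number of correlated-random-walk control trajectories
#'   simulated per case trajectory.
#' @param min_positions Minimum number of in-buffer positions for an LFT
#'   event (rule b).
#' @param min_distance_m Minimum total path distance in meters for an LFT
#'   event (rule c).
#' @param min_ddr Minimum displacement-to-distance ratio, exceeded strictly,
#'   for an LFT event (rule d).
#' @param sinuosity_max Travel filter: maximum burst sinuosity (m^(-1/2))
#'   retained.
#' @param speed_min_mps Travel filter: minimum burst mean speed (m/s)
#'   retained.
#' @param min_bursts_for_inclusion A feature type enters an individual's
#'   path-selection model only if encountered in at least this many bursts.
#' @param bootstrap_B Bootstrap replicates for confidence intervals.
#' @param nominal_dt Nominal inter-fix interval within a burst, seconds.
#' @param gap_s Inter-fix gap above which a new burst starts when bursts must
#'   be segmented from a plain position stream. Default twice `nominal_dt`.
#' @param exclusion_s Post-release exclusion window, seconds (default one
#'   day).
#' @param strict_and_filter If `TRUE`, the travel filter excludes a burst only
#'   when it is both too sinuous and too slow; the default excludes when
#'   either criterion fails.
#' @param joint_step_resampling If `TRUE`, control trajectories resample
#'   (length, turn) pairs jointly rather than independently.
#' @param rng_seed Optional integer seed recorded with the configuration.
#'
#' @return An object of class `lft_config` (a named list).
#' @export
lft_config <- function(buffer_m = 10, n_controls = 10, min_positions = 3,
                       min_distance_m = 35, min_ddr = 0.5,
                       sinuosity_max = 0.5, speed_min_mps = 0.1,
                       min_bursts_for_inclusion = 5, bootstrap_B = 1000,
                       nominal_dt = 15, gap_s = 2 * nominal_dt,
                       exclusion_s = 86400, strict_and_filter = FALSE,
                       joint_step_resampling = FALSE, rng_seed = NULL) {
  cfg <- list(buffer_m = buffer_m, n_controls = n_controls,
              min_positions = min_positions, min_distance_m = min_distance_m,
              min_ddr = min_ddr, sinuosity_max = sinuosity_max,
              speed_min_mps = speed_min_mps,
              min_bursts_for_inclusion = min_bursts_for_inclusion,
              bootstrap_B = bootstrap_B, nominal_dt = nominal_dt,
              gap_s = gap_s, exclusion_s = exclusion_s,
              strict_and_filter = strict_and_filter,
              joint_step_resampling = joint_step_resampling,
              rng_seed = rng_seed)
  num <- c("buffer_m", "n_controls", "min_positions", "min_distance_m",
           "min_ddr", "sinuosity_max", "speed_min_mps",
           "min_bursts_for_inclusion", "bootstrap_B", "nominal_dt", "gap_s",
           "exclusion_s")
  for (f in num) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("`", f, "` must be a single positive number", call. = FALSE)
  }
  if (cfg$n_controls < 1) stop("`n_controls` must be >= 1", call. = FALSE)
  if (cfg$gap_s <= cfg$nominal_dt)
    stop("`gap_s` must exceed `nominal_dt`", call. = FALSE)
  structure(cfg, class = "lft_config")
}

#' @export
print.lft_config <- function(x, ...) {
  cat("<lft_config>\n")
  for (f in names(x)) {
    v <- x[[f]]
    cat(sprintf("  %-26s %s\n", f,
                if (is.null(v)) "NULL" else paste(format(v), collapse = ", ")))
  }
  invisible(x)
}

#' Read a configuration from a YAML file
#'
#' Field names mirror [lft_config()]; unknown fields are an error so that
#' typos do not silently fall back to defaults.
#'
#' @param path Path to a YAML file.
#' @return An `lft_config` object.
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the `yaml` package is required to read YAML configurations",
         call. = FALSE)
  vals <- yaml::read_yaml(path)
  known <- names(formals(lft_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(lft_config, vals)
}

#' Canonical linear feature types
#'
#' The feature types the analysis distinguishes, in the conventional order
#' used throughout the package (roads are the reference level in the models).
#'
#' @return Character vector `c("road", "forest_edge", "stream")`.
#' @export
lft_feature_types <- function() c("road", "forest_edge", "stream")
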