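#' Wrap an angle to (-pi, pi]
#' @param theta Angle(s) in radians.
#' @return Wrapped angle(s).
#' @export
wrap_angle <- function(theta) {
  w <- (theta + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

#' Per-step kinematics of a burst
#'
#' Computes step lengths, durations, absolute bearings and relative turning
#' angles between consecutive fixes. Zero-length steps have no defined
#' bearing; turns are computed between consecutive *defined* bearings, which
#' amounts to merging zero-length steps with their successor.
#'
#' @param burst A data frame of fixes from one burst with columns `t`, `x`,
#'   `y`, ordered by time.
#' @return A tibble with one row per step: `length`, `duration`, `bearing`,
#'   `turn` (NA where undefined; the first step never has a turn).
#' @export
compute_steps <- function(burst) {
  n <- nrow(burst)
  if (n < 2)
    stop("a burst needs at least 2 fixes for kinematics", call. = FALSE)
  if (is.unsorted(burst$t, strictly = TRUE))
    stop("fix times must be strictly increasing within a burst",
         call. = FALSE)
  dx <- diff(burst$x); dy <- diff(burst$y)
  len <- sqrt(dx^2 + dy^2)
  dur <- diff(burst$t)
  bearing <- ifelse(len > 0, atan2(dy, dx), NA_real_)
  turn <- rep(NA_real_, n - 1L)
  def <- which(!is.na(bearing))
  if (length(def) >= 2) {
    turn[def[-1]] <- wrap_angle(diff(bearing[def]))
  }
  tibble::tibble(length = len, duration = dur, bearing = bearing,
                 turn = turn)
}

#' Corrected sinuosity of a burst
#'
#' The corrected sinuosity index
#' \deqn{S = 2 \left[ p \left( \frac{1+c}{1-c} + b^2 \right) \right]^{-1/2}}
#' with \eqn{p} the mean step length (m), \eqn{c} the mean cosine of turning
#' angles and \eqn{b} the coefficient of variation of step length. Units are
#' m^(-1/2); low values indicate directed travel. The perfectly straight
#' limit (\eqn{c \to 1}) maps to 0 and the perfectly reversing limit
#' (\eqn{c \to -1}) to `Inf`.
#'
#' @param steps A step tibble from [compute_steps()].
#' @return Sinuosity in m^(-1/2).
#' @export
burst_sinuosity <- function(steps) {
  len <- steps$length
  if (all(len == 0))
    stop("sinuosity is undefined for an all-stationary burst",
         call. = FALSE)
  turns <- steps$turn[!is.na(steps$turn)]
  if (nrow(steps) < 2 || length(turns) < 1)
    stop("sinuosity needs at least 2 steps with a defined turn",
         call. = FALSE)
  p <- mean(len)
  cbar <- mean(cos(turns))
  b <- stats::sd(len) / p
  if (cbar >= 1 - 1e-9) return(0)
  if (cbar <= -1 + 1e-9) return(Inf)
  2 / sqrt(p * ((1 + cbar) / (1 - cbar) + b^2))
}

#' Mean movement speed of a burst
#'
#' Mean over steps of per-step speed (length / duration).
#'
#' @param steps A step tibble from [compute_steps()].
#' @return Speed in m/s.
#' @export
burst_mean_speed <- function(steps) {
  if (nrow(steps) < 1) stop("no steps", call. = FALSE)
  if (any(steps$duration <= 0))
    stop("non-positive step duration", call. = FALSE)
  mean(steps$length / steps$duration)
}

#' Drop positions from the post-release acclimation window
#'
#' Removes fixes collected before `release_time + exclusion_s` to avoid
#' behavioural artefacts of capture and handling (default: the first day).
#'
#' @param fixes Fix tibble for a single individual (or several, with a named
#'   `release_time` vector per individual).
#' @param release_time Epoch seconds of release; either a single value or a
#'   named vector keyed by `individual_id`.
#' @param exclusion_s Exclusion window in seconds (default 86400).
#' @return The filtered fix tibble.
#' @export
exclude_initial_period <- function(fixes, release_time, exclusion_s = 86400) {
  if (length(release_time) == 1 && is.null(names(release_time))) {
    keep <- fixes$t >= release_time + exclusion_s
  } else {
    rt <- release_time[fixes$individual_id]
    if (any(is.na(rt)))
      stop("missing release_time for individual(s): ",
           paste(unique(fixes$individual_id[is.na(rt)]), collapse = ", "),
           call. = FALSE)
    keep <- fixes$t >= rt + exclusion_s
  }
  fixes[keep, , drop = FALSE]
}

#' Per-burst kinematics table
#'
#' @param fixes Fix tibble with `burst_id` assigned.
#' @return A tibble with one row per burst: `individual_id`, `burst_id`,
#'   `n_fixes`, `sinuosity`, `mean_speed`.
#' @export
burst_kinematics <- function(fixes) {
  rows <- lapply(split(fixes, fixes$burst_id), function(b) {
    b <- b[order(b$t), ]
    sinu <- NA_real_; spd <- NA_real_
    if (nrow(b) >= 2) {
      st <- compute_steps(b)
      spd <- burst_mean_speed(st)
      sinu <- tryCatch(burst_sinuosity(st), error = function(e) NA_real_)
      if (is.na(sinu) && all(st$length == 0)) sinu <- Inf  # stationary
      if (is.na(sinu)) sinu <- 0  # straight burst with no defined turn
    }
    tibble::tibble(individual_id = b$individual_id[1],
                   burst_id = b$burst_id[1], n_fixes = nrow(b),
                   sinuosity = sinu, mean_speed = spd)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Travel filter over bursts
#'
#' Retains bursts that represent directed travel: sinuosity at most
#' `sinuosity_max` (default 0.5 m^(-1/2)) and mean speed at least
#' `speed_min_mps` (default 0.1 m/s). With `strict_and_filter = TRUE` a burst
#' is excluded only when it fails both criteria.
#'
#' @param fixes Fix tibble with `burst_id` assigned.
#' @param config An [lft_config()].
#' @return A list with `fixes` (retained fixes), `kinematics` (per-burst
#'   table with `is_travel` and `exclude_reason`).
#' @export
filter_travel_bursts <- function(fixes, config = lft_config()) {
  kin <- burst_kinematics(fixes)
  too_few <- kin$n_fixes < 2
  sin_bad <- !too_few & kin$sinuosity > config$sinuosity_max
  spd_bad <- !too_few & kin$mean_speed < config$speed_min_mps
  if (config$strict_and_filter) {
    excl <- too_few | (sin_bad & spd_bad)
  } else {
    excl <- too_few | sin_bad | spd_bad
  }
  reason <- rep(NA_character_, nrow(kin))
  reason[spd_bad] <- "speed"
  reason[sin_bad] <- "sinuosity"
  reason[sin_bad & spd_bad] <- "sinuosity+speed"
  reason[too_few] <- "too_few_fixes"
  reason[!excl] <- NA_character_
  kin$is_travel <- !excl
  kin$exclude_reason <- reason
  list(fixes = fixes[fixes$burst_id %in% kin$burst_id[!excl], ,
                     drop = FALSE],
       kinematics = kin)
}
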