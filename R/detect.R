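#' Proximity profile of a burst
#'
#' Per fix and feature type: minimum distance to the features of that type
#' and an in-buffer indicator (strictly closer than `buffer_m`). The `any`
#' column is the union over the three types.
#'
#' @param burst Fix data frame for one burst, ordered by time.
#' @param fs An `lft_features` object.
#' @param config An [lft_config()] (supplies `buffer_m`).
#' @return A tibble with columns `dist_<ftype>`, `in_<ftype>` and `in_any`.
#' @export
proximity_profile <- function(burst, fs, config = lft_config()) {
  d <- feature_min_distances(cbind(burst$x, burst$y), fs)
  out <- tibble::tibble(.rows = nrow(burst))
  for (ft in lft_feature_types()) {
    out[[paste0("dist_", ft)]] <- d[, ft]
    out[[paste0("in_", ft)]] <- d[, ft] < config$buffer_m
  }
  out$in_any <- out$in_road | out$in_forest_edge | out$in_stream
  out
}

.in_flags <- function(profile, ftype) {
  col <- if (ftype == "any") "in_any" else paste0("in_", ftype)
  if (!col %in% names(profile)) stop("unknown feature type: ", ftype,
                                     call. = FALSE)
  profile[[col]]
}

#' Extract the case trajectory of a burst
#'
#' The observed ("case") trajectory is the suffix of the burst from the first
#' position inside the proximity buffer of the given feature context (one of
#' the three types or `"any"`) to the end of the burst.
#'
#' @param burst Fix data frame for one burst, ordered by time.
#' @param profile The burst's [proximity_profile()].
#' @param ftype Feature context: `"road"`, `"forest_edge"`, `"stream"` or
#'   `"any"`.
#' @return A list with `fixes` (the suffix), `entry_index` (0-based
#'   seq_index of the first in-buffer fix), `ftype`; or `NULL` when no fix is
#'   in the buffer.
#' @export
extract_case_trajectory <- function(burst, profile, ftype = "any") {
  flags <- .in_flags(profile, ftype)
  first <- which(flags)[1]
  if (is.na(first)) return(NULL)
  list(burst_id = burst$burst_id[1], ftype = ftype,
       fixes = burst[first:nrow(burst), , drop = FALSE],
       entry_index = first - 1L)
}

#' Displacement-to-distance ratio
#'
#' Mean straight-line displacement of all subsequent points from the first
#' point of a sequence, divided by the mean distance moved between
#' consecutive points. Values near or above 1 indicate directed travel;
#' localized wandering scores low.
#'
#' @param points An n x 2 matrix of ordered planar points (n >= 2).
#' @return The ratio (dimensionless).
#' @export
displacement_distance_ratio <- function(points) {
  if (is.data.frame(points)) points <- as.matrix(points)
  stopifnot(is.matrix(points), ncol(points) == 2, nrow(points) >= 2)
  n <- nrow(points)
  steps <- sqrt(rowSums((points[-1, , drop = FALSE] -
                         points[-n, , drop = FALSE])^2))
  if (all(steps == 0))
    stop("displacement-to-distance ratio undefined: all steps have zero ",
         "length", call. = FALSE)
  disp <- sqrt(rowSums((points[-1, , drop = FALSE] -
                        matrix(points[1, ], n - 1, 2, byrow = TRUE))^2))
  mean(disp) / mean(steps)
}

#' Detect LFT events in a burst
#'
#' Maximal contiguous runs of in-buffer positions are candidate events; a
#' candidate qualifies as a linear-feature-tracking event when it (a) lies
#' entirely inside the buffer, (b) has at least `min_positions` positions,
#' (c) covers a total path distance of at least `min_distance_m`, and (d) has
#' a displacement-to-distance ratio strictly above `min_ddr`. Several
#' disjoint events per burst are allowed.
#'
#' @param burst Fix data frame for one burst, ordered by time, with
#'   `seq_index`.
#' @param profile The burst's [proximity_profile()].
#' @param ftype Feature context (a type or `"any"`).
#' @param config An [lft_config()].
#' @return A tibble of events (possibly empty) with columns `individual_id`,
#'   `burst_id`, `ftype`, `start_index`, `end_index`, `n_positions`,
#'   `path_distance_m`, `ddr`, `start_known`, `censored`, `duration_s`,
#'   `mean_speed_mps`, `t_start`, `t_end`.
#' @export
detect_lft_events <- function(burst, profile, ftype = "any",
                              config = lft_config()) {
  flags <- .in_flags(profile, ftype)
  n <- nrow(burst)
  empty <- tibble::tibble(
    individual_id = character(), burst_id = character(), ftype = character(),
    start_index = integer(), end_index = integer(), n_positions = integer(),
    path_distance_m = double(), ddr = double(), start_known = logical(),
    censored = logical(), duration_s = double(), mean_speed_mps = double(),
    t_start = double(), t_end = double())
  if (n == 0 || !any(flags)) return(empty)
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  rows <- list()
  for (k in which(r$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    m <- i1 - i0 + 1L
    if (m < config$min_positions) next
    pts <- cbind(burst$x[i0:i1], burst$y[i0:i1])
    steps <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                           pts[-m, , drop = FALSE])^2))
    path <- sum(steps)
    if (path < config$min_distance_m) next
    if (all(steps == 0)) next
    ddr <- displacement_distance_ratio(pts)
    if (ddr <= config$min_ddr) next
    censored <- (i1 == n)
    dur <- if (censored) burst$t[n] - burst$t[i0] else
      burst$t[i1 + 1L] - burst$t[i0]
    sp <- mean(steps / diff(burst$t[i0:i1]))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      individual_id = burst$individual_id[1], burst_id = burst$burst_id[1],
      ftype = ftype, start_index = burst$seq_index[i0],
      end_index = burst$seq_index[i1], n_positions = m,
      path_distance_m = path, ddr = ddr,
      start_known = burst$seq_index[i0] > 0L, censored = censored,
      duration_s = dur, mean_speed_mps = sp,
      t_start = burst$t[i0],
      t_end = burst$t[i0] + dur)
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Convert LFT events to survival records
#'
#' Events whose starting point is unknown (the burst's first position was
#' already inside the buffer) are excluded. For observed departures the time
#' is from the first position of the sequence to the first position outside
#' the buffer (event = 1); sequences running to the end of the burst are
#' right-censored at the last fix (event = 0).
#'
#' @param events Event tibble from [detect_lft_events()].
#' @return A tibble with `individual_id`, `burst_id`, `ftype`, `time_s`,
#'   `event`.
#' @export
events_to_survival_records <- function(events) {
  ev <- events[events$start_known, , drop = FALSE]
  tibble::tibble(individual_id = ev$individual_id, burst_id = ev$burst_id,
                 ftype = ev$ftype, time_s = ev$duration_s,
                 event = as.integer(!ev$censored))
}

#' Mean travel speed during an event
#'
#' Mean of per-step speeds over the event's in-buffer steps; consistent with
#' [burst_mean_speed()] applied to the event's sub-series.
#'
#' @param event One event row.
#' @param burst The event's burst fix data frame.
#' @return Speed in m/s.
#' @export
event_mean_speed <- function(event, burst) {
  i0 <- match(event$start_index, burst$seq_index)
  i1 <- match(event$end_index, burst$seq_index)
  b <- burst[i0:i1, , drop = FALSE]
  burst_mean_speed(compute_steps(b))
}
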