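#' Run the LFT analysis pipeline on a position table
#'
#' Travel-filters the bursts, computes proximity profiles against the
#' feature set, detects LFT events per feature type (and for the combined
#' `any` feature), and converts per-type events to survival records.
#'
#' @param fixes Fix tibble with `individual_id`, `burst_id`, `seq_index`,
#'   `t`, `x`, `y` (use [segment_bursts()] first if bursts are unlabelled).
#' @param fs An `lft_features` object.
#' @param config An [lft_config()].
#' @return A list with `kinematics` (per-burst travel filter table),
#'   `events` (all detected events, per-type and `any`), `records`
#'   (survival records from per-type events), `n_travel_bursts`,
#'   `n_encounter_bursts` (travel bursts with an in-buffer position).
#' @export
run_lft_pipeline <- function(fixes, fs, config = lft_config()) {
  flt <- filter_travel_bursts(fixes, config)
  events <- list()
  n_enc <- 0L
  for (b in split(flt$fixes, flt$fixes$burst_id)) {
    b <- b[order(b$t), ]
    prof <- proximity_profile(b, fs, config)
    if (any(prof$in_any)) n_enc <- n_enc + 1L
    for (ft in c(lft_feature_types(), "any")) {
      ev <- detect_lft_events(b, prof, ft, config)
      if (nrow(ev)) events[[length(events) + 1L]] <- ev
    }
  }
  events <- if (length(events)) do.call(rbind, events) else
    detect_lft_events(flt$fixes[0, ], tibble::tibble(in_any = logical()),
                      "any", config)
  per_type <- events[events$ftype != "any", , drop = FALSE]
  list(kinematics = flt$kinematics, events = events,
       records = events_to_survival_records(per_type),
       n_travel_bursts = sum(flt$kinematics$is_travel),
       n_encounter_bursts = n_enc)
}

#' Score detected events against simulated truth
#'
#' A true tracking episode counts as recovered when a detected event of the
#' same individual and feature type overlaps at least `min_overlap` of the
#' part of the episode that falls inside observed bursts. Only episodes
#' longer than `min_episode_s` that overlap at least one burst are scored.
#'
#' @param events Detected events (per-type rows) with `t_start`, `t_end`.
#' @param truth An `lft_sim_truth`.
#' @param fixes The observed fix tibble (defines burst windows).
#' @param min_episode_s Minimum true episode duration scored (s).
#' @param min_overlap Required overlap fraction.
#' @return A list with `n_scored`, `n_recovered`, `recall`, and the scored
#'   episode tibble (`recovered` flag per episode).
#' @export
score_event_recovery <- function(events, truth, fixes, min_episode_s = 60,
                                 min_overlap = 0.5) {
  eps <- do.call(rbind, lapply(truth, `[[`, "episodes"))
  eps <- eps[eps$t_end - eps$t_start > min_episode_s, , drop = FALSE]
  bw <- do.call(rbind, lapply(split(fixes, fixes$burst_id), function(b)
    data.frame(individual_id = b$individual_id[1], t0 = min(b$t),
               t1 = max(b$t))))
  scored <- list()
  for (k in seq_len(nrow(eps))) {
    e <- eps[k, ]
    w <- bw[bw$individual_id == e$individual_id, , drop = FALSE]
    ov <- pmax(0, pmin(w$t1, e$t_end) - pmax(w$t0, e$t_start))
    in_burst <- sum(ov)
    if (in_burst <= 0) next
    cand <- events[events$individual_id == e$individual_id &
                     events$ftype == e$ftype, , drop = FALSE]
    got <- FALSE
    if (nrow(cand)) {
      eov <- pmax(0, pmin(cand$t_end, e$t_end) -
                    pmax(cand$t_start, e$t_start))
      got <- any(eov / in_burst >= min_overlap)
    }
    e$recovered <- got
    scored[[length(scored) + 1L]] <- e
  }
  if (!length(scored))
    return(list(n_scored = 0L, n_recovered = 0L, recall = NA_real_,
                episodes = NULL))
  sc <- do.call(rbind, scored)
  list(n_scored = nrow(sc), n_recovered = sum(sc$recovered),
       recall = mean(sc$recovered), episodes = sc)
}
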