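#' Kaplan-Meier curve for time to feature abandonment
#'
#' Product-limit estimate of the probability that a tracking episode is still
#' ongoing at time t, under right censoring at burst end. Ties between
#' events and censorings at the same time are resolved events-first.
#'
#' @param records Survival records with `time_s` and `event` (1 = departure
#'   observed, 0 = censored).
#' @return An object of class `lft_km`: a tibble with `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv` (rows at every distinct observed time).
#' @export
km_fit <- function(records) {
  stopifnot(nrow(records) >= 1, all(records$time_s > 0),
            all(records$event %in% c(0, 1)))
  sf <- survival::survfit(
    survival::Surv(time_s, event) ~ 1,
    data = as.data.frame(records))
  out <- tibble::tibble(time = sf$time, n_risk = sf$n.risk,
                        n_event = sf$n.event, n_censor = sf$n.censor,
                        surv = sf$surv)
  class(out) <- c("lft_km", class(out))
  out
}

#' Median time to abandonment from a Kaplan-Meier curve
#'
#' The smallest event time at which the survival estimate has reached 0.5 or
#' below — the time by which half of the tracking episodes have ended.
#' `NA` when the curve never reaches 0.5.
#'
#' @param curve An `lft_km` curve.
#' @return Seconds, or `NA_real_`.
#' @export
km_median <- function(curve) {
  hit <- curve$n_event > 0 & curve$surv <= 0.5 + 1e-12
  if (!any(hit)) return(NA_real_)
  min(curve$time[hit])
}

# Fast product-limit median used inside bootstrap loops; equivalent to
# km_median(km_fit(.)) and tested against it.
.pl_median <- function(time, event) {
  o <- order(time, -event)
  time <- time[o]; event <- event[o]
  n <- length(time)
  ut <- unique(time[event == 1])
  if (!length(ut)) return(NA_real_)
  s <- 1
  for (tt in ut) {
    at_risk <- sum(time >= tt)
    d <- sum(time == tt & event == 1)
    s <- s * (1 - d / at_risk)
    if (s <= 0.5 + 1e-12) return(tt)
  }
  NA_real_
}

#' Hierarchical bootstrap confidence interval
#'
#' Percentile bootstrap that respects the grouping of records: individuals
#' are resampled with replacement, then bursts with replacement within each
#' sampled individual, keeping all records of a sampled burst together.
#' Replicates with an undefined statistic (for example a Kaplan-Meier curve
#' that never reaches 0.5) are dropped and counted.
#'
#' @param records Records with `individual_id`, `burst_id` and the columns
#'   the statistic needs (`time_s`/`event` for `"median"`, `value` for
#'   `"mean"`).
#' @param statistic `"median"` (Kaplan-Meier median of `time_s`, `event`) or
#'   `"mean"` (mean of a `value` column), or a function taking a data frame
#'   and returning a scalar.
#' @param B Number of bootstrap replicates (>= 200 recommended).
#' @return A list with `lower`, `upper` (2.5/97.5 percentiles), `B_used`,
#'   `n_undefined`, `unreliable` (TRUE when over half the replicates were
#'   undefined), and `replicates`.
#' @export
hierarchical_bootstrap_ci <- function(records, statistic = "median",
                                      B = 1000) {
  stopifnot(B >= 1)
  d <- as.data.frame(records)
  # row indices grouped by individual, then burst within individual
  idx_tree <- lapply(split(seq_len(nrow(d)), d$individual_id), function(i)
    split(i, d$burst_id[i]))
  n_ind <- length(idx_tree)
  reps <- numeric(B)
  fast <- identical(statistic, "median") || identical(statistic, "mean")
  stat_fn <- if (is.function(statistic)) statistic
  else if (fast) NULL
  else stop("unknown statistic", call. = FALSE)
  for (b in seq_len(B)) {
    inds <- sample.int(n_ind, n_ind, replace = TRUE)
    idx <- unlist(lapply(inds, function(i) {
      bl <- idx_tree[[i]]
      unlist(bl[sample.int(length(bl), length(bl), replace = TRUE)],
             use.names = FALSE)
    }), use.names = FALSE)
    reps[b] <- if (is.null(stat_fn)) {
      if (identical(statistic, "median"))
        .pl_median(d$time_s[idx], d$event[idx])
      else mean(d$value[idx])
    } else stat_fn(d[idx, , drop = FALSE])
  }
  ok <- reps[!is.na(reps)]
  n_undef <- B - length(ok)
  if (!length(ok))
    return(list(lower = NA_real_, upper = NA_real_, B_used = 0L,
                n_undefined = n_undef, unreliable = TRUE,
                replicates = reps))
  q <- stats::quantile(ok, c(0.025, 0.975), names = FALSE, type = 7)
  list(lower = q[1], upper = q[2], B_used = length(ok),
       n_undefined = n_undef, unreliable = n_undef > B / 2,
       replicates = reps)
}

#' Cox proportional-hazards contrasts between feature types
#'
#' Stratified partial likelihood (individual = stratum) with Breslow tie
#' handling and a cluster-robust sandwich variance over bursts. Hazard
#' ratios above 1 mean faster abandonment than on the reference feature
#' type.
#'
#' @param records Survival records with `ftype`, `individual_id`,
#'   `burst_id`, `time_s`, `event`.
#' @param reference_ftype Reference level (default `"road"`).
#' @return A tibble with one row per non-reference type: `ftype`, `coef`,
#'   `hazard_ratio`, `robust_se`, `z`, `p`; attribute `n_events`.
#' @export
cox_fit <- function(records, reference_ftype = "road") {
  df <- as.data.frame(records)
  ev_by_type <- tapply(df$event, df$ftype, sum)
  dead <- names(ev_by_type)[ev_by_type == 0]
  if (length(dead)) {
    warning("dropping feature type(s) with no observed departures: ",
            paste(dead, collapse = ", "), call. = FALSE)
    df <- df[!df$ftype %in% dead, , drop = FALSE]
  }
  present <- unique(df$ftype)
  if (length(present) < 2)
    stop("Cox contrasts need at least two feature types with events",
         call. = FALSE)
  lev <- c(reference_ftype, setdiff(
    lft_feature_types()[lft_feature_types() %in% present],
    reference_ftype))
  df$ftype <- factor(df$ftype, levels = lev)
  fit <- survival::coxph(
    survival::Surv(time_s, event) ~ ftype +
      survival::strata(individual_id),
    data = df, cluster = burst_id, ties = "breslow")
  beta <- stats::coef(fit)
  se <- sqrt(diag(fit$var))
  z <- beta / se
  out <- tibble::tibble(
    ftype = sub("^ftype", "", names(beta)), coef = unname(beta),
    hazard_ratio = unname(exp(beta)), robust_se = unname(se),
    z = unname(z), p = unname(2 * stats::pnorm(-abs(z))))
  attr(out, "n_events") <- sum(df$event)
  attr(out, "reference") <- reference_ftype
  out
}

#' Mixed model for travel speed during tracking
#'
#' Linear mixed model on natural-log event mean speed with feature type as
#' fixed effect and nested random intercepts (burst within individual),
#' fitted by REML. With a single individual the model falls back to a
#' burst-only random intercept.
#'
#' @param events LFT events with positive `mean_speed_mps`, plus
#'   `individual_id`, `burst_id`, `ftype`.
#' @param reference_ftype Reference level (default `"road"`).
#' @return A list of class `lft_speed_model` with `fixed` (term, estimate,
#'   se, t), `varcomp` (individual, burst, residual variances), and `fit`
#'   (the underlying `lmerMod`).
#' @export
fit_speed_model <- function(events, reference_ftype = "road") {
  df <- as.data.frame(events)
  stopifnot(all(df$mean_speed_mps > 0))
  present <- unique(df$ftype)
  lev <- c(reference_ftype, setdiff(
    lft_feature_types()[lft_feature_types() %in% present],
    reference_ftype))
  df$ftype <- factor(df$ftype, levels = lev)
  df$log_speed <- log(df$mean_speed_mps)
  single <- length(unique(df$individual_id)) < 2
  # a burst-level intercept is identifiable only when some burst carries
  # more than one event
  burst_ok <-
    length(unique(paste(df$individual_id, df$burst_id))) < nrow(df)
  if (single) {
    warning("single individual: variance components for individuals are ",
            "not identifiable; using a burst-only random intercept",
            call. = FALSE)
    if (!burst_ok)
      stop("single individual with one event per burst: no random effect ",
           "is identifiable", call. = FALSE)
    fml <- log_speed ~ ftype + (1 | burst_id)
  } else if (burst_ok) {
    fml <- log_speed ~ ftype + (1 | individual_id / burst_id)
  } else {
    fml <- log_speed ~ ftype + (1 | individual_id)
  }
  fit <- suppressMessages(lme4::lmer(fml, data = df, REML = TRUE))
  cf <- summary(fit)$coefficients
  vc <- as.data.frame(lme4::VarCorr(fit))
  getv <- function(g) {
    v <- vc$vcov[vc$grp == g]
    if (length(v)) v else 0
  }
  structure(list(
    fixed = tibble::tibble(term = sub("^ftype", "", rownames(cf)),
                           estimate = unname(cf[, "Estimate"]),
                           se = unname(cf[, "Std. Error"]),
                           t = unname(cf[, "t value"])),
    varcomp = c(
      individual = if (single) NA_real_ else getv("individual_id"),
      burst = if (!burst_ok) NA_real_ else if (single) getv("burst_id")
      else getv("burst_id:individual_id"),
      residual = getv("Residual")),
    reference = reference_ftype,
    fit = fit), class = "lft_speed_model")
}

#' @export
print.lft_speed_model <- function(x, ...) {
  cat("<lft_speed_model> log-speed mixed model, reference:", x$reference,
      "\nFixed effects:\n")
  print(as.data.frame(x$fixed), row.names = FALSE)
  cat("Variance components:\n")
  print(round(x$varcomp, 5))
  invisible(x)
}
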