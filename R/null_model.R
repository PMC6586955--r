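#' Empirical step distributions of a case trajectory
#'
#' The step-length and relative-turn samples that parameterise the
#' correlated-random-walk null model for a burst. A case with no defined
#' turn (fewer than 3 distinct positions) falls back to a degenerate turn
#' sample of \{0\}.
#'
#' @param case A case trajectory from [extract_case_trajectory()].
#' @return A list with `lengths` (m) and `turns` (radians in (-pi, pi]).
#' @export
empirical_step_distributions <- function(case) {
  fx <- case$fixes
  if (nrow(fx) < 2)
    stop("a case trajectory needs at least 2 points to define a null model",
         call. = FALSE)
  st <- compute_steps(fx)
  turns <- st$turn[!is.na(st$turn)]
  if (!length(turns)) turns <- 0
  list(lengths = st$length, turns = turns)
}

#' Simulate correlated-random-walk control trajectories
#'
#' Each control starts at the case trajectory's first point with a uniform
#' initial bearing; subsequent bearings accumulate turns resampled (with
#' replacement) from the case's empirical turn sample, and step lengths are
#' resampled independently from its empirical length sample — or jointly as
#' (length, turn) pairs when `joint = TRUE`. Controls have the same number
#' of points as the case.
#'
#' @param case A case trajectory.
#' @param dists Output of [empirical_step_distributions()].
#' @param n_controls Number of controls.
#' @param joint Resample length/turn pairs jointly.
#' @return A list of n x 2 point matrices, one per control.
#' @export
simulate_crw_controls <- function(case, dists, n_controls = 10,
                                  joint = FALSE) {
  stopifnot(n_controls >= 1)
  n_steps <- nrow(case$fixes) - 1L
  start <- c(case$fixes$x[1], case$fixes$y[1])
  # index-based resampling (sample() on a scalar would misbehave)
  draw <- function(v, n) v[sample.int(length(v), n, replace = TRUE)]
  lapply(seq_len(n_controls), function(k) {
    b0 <- stats::runif(1, -pi, pi)
    if (n_steps == 1L) {
      lens <- draw(dists$lengths, 1L)
      bearings <- b0
    } else if (joint && length(dists$lengths) >= 2) {
      # pair turn_i with the length of the step it precedes
      idx <- sample.int(length(dists$turns), n_steps - 1L, replace = TRUE)
      lens <- c(draw(dists$lengths, 1L),
                dists$lengths[pmin(idx + 1L, length(dists$lengths))])
      bearings <- cumsum(c(b0, dists$turns[idx]))
    } else {
      lens <- draw(dists$lengths, n_steps)
      turns <- draw(dists$turns, n_steps - 1L)
      bearings <- cumsum(c(b0, turns))
    }
    x <- start[1] + cumsum(lens * cos(bearings))
    y <- start[2] + cumsum(lens * sin(bearings))
    cbind(c(start[1], x), c(start[2], y))
  })
}

#' Build the case-control table for one burst
#'
#' One row per position per trajectory (case and controls). Covariates are
#' the in-buffer indicators per feature type at that position plus their
#' union (`in_any`). The burst is the stratum of the conditional likelihood;
#' positions of the same sequence (the case trajectory or one control
#' trajectory) share a cluster id, so the robust variance accounts for
#' serial correlation along each path.
#'
#' @param case A case trajectory.
#' @param controls Control point matrices from [simulate_crw_controls()].
#' @param fs An `lft_features` object.
#' @param config An [lft_config()].
#' @param individual_id Individual the burst belongs to.
#' @return A tibble of case-control rows.
#' @export
build_case_control_table <- function(case, controls, fs,
                                     config = lft_config(),
                                     individual_id = NA_character_) {
  pts <- rbind(cbind(case$fixes$x, case$fixes$y),
               do.call(rbind, controls))
  npt <- nrow(case$fixes)
  n_traj <- 1L + length(controls)
  d <- feature_min_distances(pts, fs)
  inb <- d < config$buffer_m
  traj <- rep(0:(n_traj - 1L), each = npt)
  tibble::tibble(
    individual_id = individual_id,
    stratum_id = case$burst_id,
    cluster_id = paste0(case$burst_id, "_t", traj),
    control_index = rep(0:(n_traj - 1L), each = npt),
    y = as.integer(rep(c(1L, rep(0L, length(controls))), each = npt)),
    in_road = as.integer(inb[, "road"]),
    in_forest_edge = as.integer(inb[, "forest_edge"]),
    in_stream = as.integer(inb[, "stream"]),
    in_any = as.integer(inb[, "road"] | inb[, "forest_edge"] |
                          inb[, "stream"]))
}

#' Case-control data for a set of travel bursts
#'
#' For every burst with at least one position inside the (any-feature)
#' proximity buffer, extracts the case trajectory, simulates
#' `config$n_controls` CRW controls, and stacks the case-control rows.
#'
#' @param fixes Travel-filtered fix tibble with `burst_id` and `seq_index`.
#' @param fs An `lft_features` object.
#' @param config An [lft_config()].
#' @return A tibble of case-control rows over all encounter bursts.
#' @export
case_control_data <- function(fixes, fs, config = lft_config()) {
  fixes <- as.data.frame(fixes)
  ord <- order(fixes$burst_id, fixes$t)
  fixes <- fixes[ord, , drop = FALSE]
  # one batched distance query for all observed fixes
  dall <- feature_min_distances(cbind(fixes$x, fixes$y), fs)
  in_any <- rowSums(dall < config$buffer_m) > 0
  idx_by_burst <- split(seq_len(nrow(fixes)), fixes$burst_id)
  meta <- list(); ctrl_pts <- list()
  for (bi in idx_by_burst) {
    if (length(bi) < 2) next
    first <- which(in_any[bi])[1]
    if (is.na(first) || first == length(bi)) next
    ci <- bi[first:length(bi)]
    case <- list(burst_id = fixes$burst_id[ci[1]],
                 fixes = fixes[ci, , drop = FALSE])
    dists <- empirical_step_distributions(case)
    ctrls <- simulate_crw_controls(case, dists, config$n_controls,
                                   joint = config$joint_step_resampling)
    meta[[length(meta) + 1L]] <- list(
      individual_id = fixes$individual_id[ci[1]],
      burst_id = fixes$burst_id[ci[1]], case_idx = ci,
      npt = length(ci))
    ctrl_pts[[length(ctrl_pts) + 1L]] <- do.call(rbind, ctrls)
  }
  if (length(meta)) {
    # one batched distance query for all control points
    dctrl <- feature_min_distances(do.call(rbind, ctrl_pts), fs)
    out <- list()
    cpos <- 0L
    for (m in meta) {
      npt <- m$npt
      n_traj <- 1L + config$n_controls
      dmat <- rbind(dall[m$case_idx, , drop = FALSE],
                    dctrl[cpos + seq_len(npt * config$n_controls), ,
                          drop = FALSE])
      cpos <- cpos + npt * config$n_controls
      inb <- dmat < config$buffer_m
      traj <- rep(0:(n_traj - 1L), each = npt)
      out[[length(out) + 1L]] <- tibble::tibble(
        individual_id = m$individual_id,
        stratum_id = m$burst_id,
        cluster_id = paste0(m$burst_id, "_t", traj),
        control_index = rep(0:(n_traj - 1L), each = npt),
        y = as.integer(rep(c(1L, rep(0L, config$n_controls)), each = npt)),
        in_road = as.integer(inb[, "road"]),
        in_forest_edge = as.integer(inb[, "forest_edge"]),
        in_stream = as.integer(inb[, "stream"]),
        in_any = as.integer(rowSums(inb) > 0))
    }
  } else out <- list()
  if (!length(out)) {
    return(tibble::tibble(
      individual_id = character(), stratum_id = character(),
      cluster_id = character(), control_index = integer(), y = integer(),
      in_road = integer(), in_forest_edge = integer(),
      in_stream = integer(), in_any = integer()))
  }
  do.call(rbind, out)
}

#' Conditional logistic path-selection fit
#'
#' Maximises the stratified conditional likelihood (burst = stratum) by the
#' Breslow risk-set equivalence via [survival::coxph()], with a
#' cluster-robust sandwich variance over sequence (trajectory) clusters.
#' Covariates are in-buffer indicators.
#'
#' @param rows Case-control rows from [case_control_data()].
#' @param covariates Character vector of covariate column names, e.g.
#'   `c("in_road", "in_forest_edge")` or `"in_any"`.
#' @return A tibble with one row per covariate: `term`, `coef`, `robust_se`,
#'   `z`, `p`, `ci_lower`, `ci_upper`, plus attributes `loglik`, `n_strata`,
#'   `n_rows`, `converged`.
#' @export
fit_conditional_logistic <- function(rows, covariates = "in_any") {
  stopifnot(nrow(rows) > 0, all(covariates %in% names(rows)))
  df <- as.data.frame(rows)
  fml <- stats::as.formula(paste(
    "survival::Surv(rep(1, nrow(df)), y) ~",
    paste(covariates, collapse = " + "),
    "+ survival::strata(stratum_id)"))
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, cluster = cluster_id,
                    ties = "breslow"),
    warning = function(w) {
      if (grepl("infinite|converge|singular", conditionMessage(w)))
        converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)
  if (any(!is.finite(beta)) || any(abs(beta) > 15)) converged <- FALSE
  se <- sqrt(diag(fit$var))
  z <- beta / se
  out <- tibble::tibble(
    term = names(beta), coef = unname(beta), robust_se = unname(se),
    z = unname(z), p = unname(2 * stats::pnorm(-abs(z))),
    ci_lower = unname(beta - 1.96 * se), ci_upper = unname(beta + 1.96 * se))
  attr(out, "loglik") <- unname(fit$loglik[length(fit$loglik)])
  attr(out, "n_strata") <- length(unique(df$stratum_id))
  attr(out, "n_rows") <- nrow(df)
  attr(out, "converged") <- converged
  out
}

#' Per-individual path-selection models
#'
#' Fits one conditional logistic model per individual. In the per-type model
#' a feature type enters an individual's model only when its buffer was
#' encountered by the case trajectory in at least
#' `config$min_bursts_for_inclusion` distinct bursts; the `any` model uses
#' the single combined covariate.
#'
#' @param rows Case-control rows (all individuals).
#' @param config An [lft_config()].
#' @param model `"types"` (per-feature dummies) or `"any"`.
#' @return A tibble of per-individual coefficient rows with `individual_id`,
#'   `term`, `n_encounter_bursts`, `coef`, `robust_se`, `z`, `p`, CI bounds
#'   and `converged`.
#' @export
fit_path_selection <- function(rows, config = lft_config(),
                               model = c("types", "any")) {
  model <- match.arg(model)
  out <- list()
  for (d in split(rows, rows$individual_id)) {
    case_rows <- d[d$y == 1, , drop = FALSE]
    types <- lft_feature_types()
    enc <- vapply(types, function(ft)
      length(unique(case_rows$stratum_id[
        case_rows[[paste0("in_", ft)]] == 1])), 0L)
    if (model == "types") {
      qual <- types[enc >= config$min_bursts_for_inclusion]
      if (!length(qual)) next
      covs <- paste0("in_", qual)
      nenc <- enc[qual]
    } else {
      n_any <- length(unique(case_rows$stratum_id[case_rows$in_any == 1]))
      if (n_any < config$min_bursts_for_inclusion) next
      covs <- "in_any"
      nenc <- n_any
    }
    # a covariate constant within every stratum carries no information
    keep <- vapply(covs, function(cv)
      any(stats::ave(d[[cv]], d$stratum_id, FUN = function(v)
        length(unique(v))) > 1), TRUE)
    if (!any(keep)) next
    covs <- covs[keep]; nenc <- nenc[keep]
    ft <- fit_conditional_logistic(d, covs)
    ft$individual_id <- d$individual_id[1]
    ft$n_encounter_bursts <- as.integer(nenc[match(ft$term, covs)])
    ft$converged <- attr(ft, "converged")
    out[[length(out) + 1L]] <- ft[, c("individual_id", "term",
                                      "n_encounter_bursts", "coef",
                                      "robust_se", "z", "p", "ci_lower",
                                      "ci_upper", "converged")]
  }
  if (!length(out))
    return(tibble::tibble(individual_id = character(), term = character(),
                          n_encounter_bursts = integer(), coef = double(),
                          robust_se = double(), z = double(), p = double(),
                          ci_lower = double(), ci_upper = double(),
                          converged = logical()))
  do.call(rbind, out)
}

#' Exact conditional log-likelihood by subset enumeration
#'
#' Independent oracle for the stratified conditional likelihood: within each
#' stratum with case set C of size m among n rows, the contribution is
#' exp(beta' sum_C x) / sum over all size-m subsets S of exp(beta' sum_S x).
#' Enumeration is refused for strata beyond 12 rows or 4 cases.
#'
#' @param rows Case-control rows with `stratum_id`, `y` and covariate
#'   columns.
#' @param beta Coefficient vector, named or ordered as `covariates`.
#' @param covariates Covariate column names.
#' @return The exact conditional log-likelihood.
#' @export
exact_conditional_loglik <- function(rows, beta, covariates = "in_any") {
  stopifnot(length(beta) == length(covariates))
  ll <- 0
  for (d in split(as.data.frame(rows), rows$stratum_id)) {
    n <- nrow(d); m <- sum(d$y == 1)
    if (n > 12 || m > 4)
      stop("stratum too large for exact enumeration (", n, " rows, ", m,
           " cases); limit is 12 rows / 4 cases", call. = FALSE)
    X <- as.matrix(d[, covariates, drop = FALSE])
    eta <- drop(X %*% beta)
    num <- sum(eta[d$y == 1])
    subs <- utils::combn(n, m)
    denom <- log(sum(exp(colSums(matrix(eta[subs], nrow = m)))))
    ll <- ll + num - denom
  }
  ll
}
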