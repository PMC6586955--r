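test_that("empirical step distributions count lengths and turns correctly", {
  # straight 4-point case with 10 m steps
  case <- list(burst_id = "b1",
               fixes = make_burst(x = c(0, 10, 20, 30), y = rep(0, 4)))
  d <- empirical_step_distributions(case)
  expect_equal(d$lengths, rep(10, 3))
  expect_equal(d$turns, c(0, 0))

  # 2-point case: single length, degenerate turn sample {0}
  case2 <- list(burst_id = "b2", fixes = make_burst(x = c(0, 7), y = c(0, 0)))
  d2 <- empirical_step_distributions(case2)
  expect_equal(d2$lengths, 7)
  expect_equal(d2$turns, 0)

  # n_lengths = n_points - 1, n_turns = n_points - 2
  set.seed(4)
  for (n in c(3, 5, 12)) {
    cs <- list(burst_id = "b",
               fixes = make_burst(x = cumsum(stats::runif(n, 1, 5)),
                                  y = cumsum(stats::runif(n, 1, 5))))
    dd <- empirical_step_distributions(cs)
    expect_length(dd$lengths, n - 1)
    expect_length(dd$turns, n - 2)
  }

  case1 <- list(burst_id = "b", fixes = make_burst(x = 0, y = 0))
  expect_error(empirical_step_distributions(case1), "at least 2")
})

test_that("CRW controls conserve the empirical multisets and start point", {
  set.seed(9)
  case <- list(burst_id = "b1",
               fixes = make_burst(x = cumsum(c(0, stats::runif(9, 5, 30))),
                                  y = cumsum(c(0, stats::rnorm(9, 0, 10)))))
  d <- empirical_step_distributions(case)
  ctrls <- simulate_crw_controls(case, d, n_controls = 10)
  expect_length(ctrls, 10)
  for (m in ctrls) {
    expect_equal(nrow(m), nrow(case$fixes))
    expect_equal(m[1, ], c(case$fixes$x[1], case$fixes$y[1]))
    steps <- sqrt(rowSums(diff(m)^2))
    # every control step length is a member of the empirical sample
    expect_true(all(vapply(steps, function(s)
      any(abs(s - d$lengths) < 1e-9), TRUE)))
    st <- compute_steps(make_burst(x = m[, 1], y = m[, 2]))
    turns <- st$turn[!is.na(st$turn)]
    expect_true(all(vapply(turns, function(tu)
      any(abs(wrap_angle(tu - d$turns)) < 1e-9), TRUE)))
  }

  # all-zero turns: controls are straight rays of permuted-length steps
  straight <- list(burst_id = "b2",
                   fixes = make_burst(x = c(0, 10, 25, 45), y = rep(0, 4)))
  ds <- empirical_step_distributions(straight)
  for (m in simulate_crw_controls(straight, ds, 5)) {
    st <- compute_steps(make_burst(x = m[, 1], y = m[, 2]))
    expect_equal(st$turn[!is.na(st$turn)], rep(0, 2))
  }

  # single-step case: every control is one empirical-length step
  one <- list(burst_id = "b3", fixes = make_burst(x = c(0, 10), y = c(0, 0)))
  for (m in simulate_crw_controls(one, empirical_step_distributions(one), 5))
    expect_equal(sqrt(sum(diff(m)^2)), 10)
})

test_that("control step lengths reproduce the empirical mean (Monte Carlo)", {
  set.seed(21)
  case <- list(burst_id = "b",
               fixes = make_burst(x = cumsum(c(0, stats::rgamma(20, 4, 0.2))),
                                  y = cumsum(c(0, stats::rnorm(20, 0, 5)))))
  d <- empirical_step_distributions(case)
  ctrls <- simulate_crw_controls(case, d, n_controls = 550)
  lens <- unlist(lapply(ctrls, function(m) sqrt(rowSums(diff(m)^2))))
  expect_gt(length(lens), 10000)
  se <- stats::sd(d$lengths) / sqrt(length(lens))
  # resampling mean within 2 SE-equivalents of the empirical mean
  expect_lt(abs(mean(lens) - mean(d$lengths)),
            2 * stats::sd(d$lengths) / sqrt(length(lens)) +
              4 * se)
  expect_lt(abs(mean(lens) - mean(d$lengths)), 0.05 * mean(d$lengths))
})

test_that("case-control tables have the right shape and covariates", {
  fs <- road_along_x()
  cfg <- lft_config()
  case <- list(burst_id = "b1",
               fixes = burst_on_road(n = 8))
  d <- empirical_step_distributions(case)
  set.seed(2)
  ctrls <- simulate_crw_controls(case, d, 10)
  tab <- build_case_control_table(case, ctrls, fs, cfg, "fox1")
  expect_equal(nrow(tab), 88)  # 8 x (1 case + 10 controls)
  expect_equal(sum(tab$y), 8)
  # one cluster per sequence: the case and each control trajectory
  expect_equal(length(unique(tab$cluster_id)), 11)
  expect_equal(as.integer(table(tab$cluster_id)), rep(8L, 11))
  # a point 2 m from the road has the road covariate set
  expect_true(all(tab$in_road[tab$y == 1] == 1))
  # the any covariate is the union of the three flags
  expect_equal(tab$in_any,
               as.integer(tab$in_road | tab$in_forest_edge | tab$in_stream))
})

test_that("exact conditional log-likelihood matches closed forms", {
  # beta = 0: -sum log C(n_s, m_s)
  rows <- tibble::tibble(
    stratum_id = rep(c("s1", "s2"), c(4, 6)),
    y = c(1, 0, 0, 0, 1, 1, 0, 0, 0, 0),
    in_any = c(1, 0, 1, 0, 0, 1, 1, 0, 1, 0))
  expect_equal(exact_conditional_loglik(rows, 0, "in_any"),
               -log(choose(4, 1)) - log(choose(6, 2)))

  # 1 case among 3 rows, covariate (1,0,0), beta = 1 -> log(e/(e+2))
  r2 <- tibble::tibble(stratum_id = "s", y = c(1, 0, 0), in_any = c(1, 0, 0))
  expect_equal(exact_conditional_loglik(r2, 1, "in_any"),
               log(exp(1) / (exp(1) + 2)))

  # refuses over-large strata
  big <- tibble::tibble(stratum_id = "s", y = rep(c(1, 0), c(2, 12)),
                        in_any = rep(0:1, 7))
  expect_error(exact_conditional_loglik(big, 0, "in_any"), "too large")
})

test_that("Breslow fit equals exact enumeration with one case per stratum", {
  set.seed(5)
  n_strata <- 15
  rows <- do.call(rbind, lapply(seq_len(n_strata), function(s) {
    n <- 11
    tibble::tibble(
      individual_id = "fox1", stratum_id = sprintf("s%02d", s),
      cluster_id = sprintf("s%02d_c%d", s, seq_len(n)),
      control_index = seq_len(n) - 1L,
      y = as.integer(seq_len(n) == 1),
      in_any = stats::rbinom(n, 1, 0.4))
  }))
  # make sure there is variation
  rows$in_any[rows$y == 1 & rows$stratum_id == "s01"] <- 1L
  ft <- fit_conditional_logistic(rows, "in_any")
  bhat <- ft$coef[1]
  ll_fit <- attr(ft, "loglik")
  ll_exact <- exact_conditional_loglik(rows, bhat, "in_any")
  # with a single case row per stratum the Breslow partial likelihood IS the
  # exact conditional likelihood
  expect_equal(ll_fit, ll_exact, tolerance = 1e-8)
  # and the MLE maximizes the exact likelihood too
  expect_lt(exact_conditional_loglik(rows, bhat + 0.05, "in_any"), ll_exact)
  expect_lt(exact_conditional_loglik(rows, bhat - 0.05, "in_any"), ll_exact)
})

test_that("a covariate with no within-stratum contrast is uninformative", {
  rows <- tibble::tibble(
    stratum_id = rep(c("s1", "s2"), each = 6),
    y = rep(c(1, 0, 0, 0, 0, 0), 2),
    in_any = rep(c(1L, 0L), each = 6))  # constant within stratum
  # flat likelihood: identical at any beta
  l0 <- exact_conditional_loglik(rows, 0, "in_any")
  expect_equal(exact_conditional_loglik(rows, 1, "in_any"), l0)
  expect_equal(exact_conditional_loglik(rows, -2, "in_any"), l0)
})

test_that("path selection recovers attraction and respects inclusion rules", {
  set.seed(31)
  lcfg <- lft_config()
  scfg <- sim_config(n_individuals = 2, duration_s = 12 * 3600)
  ds <- simulate_dataset(scfg, seed = 31)
  flt <- filter_travel_bursts(ds$fixes, lcfg)
  cc <- case_control_data(flt$fixes, ds$features, lcfg)
  fit <- fit_path_selection(cc, lcfg, model = "any")
  expect_gt(nrow(fit), 0)
  # with tracking switched on, feature attraction must be detected
  expect_true(all(fit$coef > 0))
  expect_true(all(fit$p < 0.05))
  # inclusion rule: every reported model had at least 5 encounter bursts
  expect_true(all(fit$n_encounter_bursts >= 5))

  # per-type model reports only included types
  fit_t <- fit_path_selection(cc, lcfg, model = "types")
  expect_true(all(fit_t$n_encounter_bursts >= 5))
  expect_true(all(fit_t$term %in%
                    paste0("in_", lft_feature_types())))
})

test_that("control generation and fits are reproducible under a seed", {
  lcfg <- lft_config()
  scfg <- sim_config(n_individuals = 1, duration_s = 4 * 3600)
  run <- function() {
    ds <- simulate_dataset(scfg, seed = 77)
    set.seed(101)
    cc <- case_control_data(filter_travel_bursts(ds$fixes, lcfg)$fixes,
                            ds$features, lcfg)
    cc
  }
  cc1 <- run(); cc2 <- run()
  expect_identical(cc1, cc2)
})
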