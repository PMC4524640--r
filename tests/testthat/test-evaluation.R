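test_that("sensitivity, TIW, FP/day and DWW match brute-force interval oracles", {
  set.seed(30)
  for (rep in 1:20) {
    nw <- sample(0:6, 1)
    ws <- sort(stats::runif(nw, 0, 9 * 86400))
    w <- cbind(ws, ws + stats::runif(nw, 600, 12 * 3600))
    w <- interval_merge(w)
    onsets <- sort(stats::runif(sample(1:6, 1), 0, 10 * 86400))
    catalog <- seizure_catalog(onsets, onsets + 60)
    monitored <- cbind(0, 10 * 86400)

    hit <- vapply(onsets, function(t)
      any(t >= w[, 1] & t < w[, 2]), logical(1L))
    expect_equal(compute_sensitivity(w, catalog), mean(hit))

    # TIW via 1-minute grid quadrature
    grid <- seq(30, 10 * 86400 - 30, by = 60)
    covered <- vapply(grid, function(t)
      any(t >= w[, 1] & t < w[, 2]), logical(1L))
    expect_lt(abs(compute_tiw(w, monitored) - mean(covered)), 2e-3)

    fp <- if (nrow(w)) sum(vapply(seq_len(nrow(w)), function(k)
      !any(onsets >= w[k, 1] & onsets < w[k, 2]), logical(1L))) else 0L
    expect_equal(compute_fp_per_day(w, catalog, monitored), fp / 10)

    dww <- sum(vapply(0:9, function(d) {
      lo <- d * 86400; hi <- lo + 86400
      !any(w[, 1] < hi & w[, 2] > lo)
    }, logical(1L)))
    expect_equal(compute_dww(w, c(0, 10 * 86400)), dww)
  }
})

test_that("trivial metric identities hold", {
  w <- cbind(0, 5 * 86400)
  catalog <- seizure_catalog(c(1, 2, 3) * 86400)
  expect_equal(compute_sensitivity(w, catalog), 1)
  expect_equal(compute_sensitivity(matrix(numeric(0), ncol = 2), catalog), 0)
  expect_equal(compute_tiw(w, cbind(0, 10 * 86400)), 0.5)
  expect_equal(compute_tiw(matrix(numeric(0), ncol = 2),
                           cbind(0, 10 * 86400)), 0)
  # overlapping raw warnings count once
  expect_equal(compute_tiw(rbind(c(0, 3600), c(1800, 5400)), cbind(0, 7200)),
               0.75)
  expect_equal(compute_dww(matrix(numeric(0), ncol = 2), c(0, 10 * 86400)),
               10)
  expect_equal(compute_dww(cbind(0, 10 * 86400), c(0, 10 * 86400)), 0)
  expect_equal(compute_fp_per_day(cbind(0, 3600), seizure_catalog(),
                                  cbind(0, 86400)), 1)
  expect_equal(compute_fp_per_day(cbind(0, 3600), seizure_catalog(600),
                                  cbind(0, 86400)), 0)
})

test_that("Poisson chance-predictor p-values: identities and monotonicity", {
  expect_equal(poisson_p_value(5, 5, 1), 1)
  expect_equal(poisson_p_value(1, 1, 0.3), 0.3)
  expect_equal(poisson_p_value(10, 0, 0.2), 1)
  expect_equal(poisson_p_value(3, 2, 0), 0)
  # strong performance vastly exceeds chance
  expect_lt(poisson_p_value(40, 30, 0.25), 0.001)
  # non-increasing in k, non-decreasing in tiw
  p_k <- vapply(0:10, function(k) poisson_p_value(10, k, 0.3), numeric(1L))
  expect_true(all(diff(p_k) <= 0))
  p_t <- vapply(seq(0.05, 0.95, by = 0.1),
                function(tiw) poisson_p_value(10, 6, tiw), numeric(1L))
  expect_true(all(diff(p_t) >= 0))
  expect_error(poisson_p_value(5, 6, 0.3), "k must")
})

test_that("analytic p-value agrees with a simulated Poisson-triggered predictor", {
  # simulate the chance predictor itself: warnings of length W issued at
  # Poisson times with rate matched to the target TIW, over a timeline with
  # n seizures spaced far apart; compare tail frequencies
  W <- 90 * 60
  set.seed(31)
  for (cell in list(c(5, 0.1), c(5, 0.4), c(20, 0.25))) {
    n <- cell[1]; tiw <- cell[2]
    lambda <- -log(1 - tiw) / W
    span <- 10 * W
    t_seiz <- span * seq_len(n) - span / 2
    horizon <- span * n
    nrep <- 2000
    hits <- vapply(seq_len(nrep), function(r) {
      m <- stats::rpois(1, lambda * horizon)
      starts <- stats::runif(m, 0, horizon)
      sum(vapply(t_seiz, function(ts)
        any(starts > ts - W & starts <= ts), logical(1L)))
    }, numeric(1L))
    for (k in unique(round(c(n * tiw, n * tiw + 2)))) {
      if (k < 1 || k > n) next
      emp <- mean(hits >= k)
      ana <- poisson_p_value(n, k, tiw, W / 60)
      se <- sqrt(max(emp * (1 - emp), 1e-4) / nrep)
      expect_lt(abs(emp - ana), 3 * se + 0.005)
    }
  }
})

test_that("ROC sweep is monotone, order-invariant, with sane AUC endpoints", {
  set.seed(32)
  n <- 1000
  t <- 60 * (seq_len(n) - 1)
  onsets <- c(200, 500, 800) * 60
  catalog <- seizure_catalog(onsets)
  lead <- identify_lead_seizures(catalog, synth_lab_config(),
                                 rec_start = -13 * 3600)
  monitored <- cbind(0, n * 60)
  calls <- data.frame(time = t, call = stats::runif(n) < 0.3)
  roc <- roc_curve(calls, lead, monitored, window_len = 30)
  o <- order(roc$tiw)
  expect_true(all(diff(roc$sensitivity[o]) >= -1e-9))
  roc_rev <- roc_curve(calls, lead, monitored, window_len = 30,
                       thresholds = rev(seq_len(30)))
  expect_equal(attr(roc, "auc"), attr(roc_rev, "auc"))
  # perfectly informative calls: preictal exactly before each seizure
  perfect <- points_in_intervals(t, cbind(onsets - 35 * 60, onsets - 5 * 60))
  roc_p <- roc_curve(data.frame(time = t, call = perfect), lead, monitored,
                     window_len = 30)
  expect_equal(attr(roc_p, "auc"), 1, tolerance = 0.05)
})

test_that("threshold tuning picks the largest TIW under the target", {
  roc <- data.frame(threshold = 1:4, tiw = c(0.45, 0.31, 0.28, 0.12),
                    sensitivity = c(0.9, 0.8, 0.7, 0.4))
  expect_equal(tune_threshold_to_tiw(roc, 0.30), 3L)
  # monotone grid: unique answer by exhaustive search
  set.seed(33)
  tiw <- sort(stats::runif(20), decreasing = TRUE)
  roc2 <- data.frame(threshold = 1:20, tiw = tiw,
                     sensitivity = sort(stats::runif(20), decreasing = TRUE))
  got <- tune_threshold_to_tiw(roc2, 0.5)
  want <- min(roc2$threshold[roc2$tiw <= 0.5])
  expect_equal(got, want)
  # nothing under the target: smallest-TIW point, with a message
  roc3 <- data.frame(threshold = 1:3, tiw = c(0.9, 0.8, 0.7),
                     sensitivity = c(1, 1, 1))
  expect_message(th <- tune_threshold_to_tiw(roc3, 0.3), "no threshold")
  expect_equal(th, 3L)
})

test_that("five-fold plan gives contiguous equal blocks covering every bin", {
  f <- fold_plan(1000)
  expect_equal(as.numeric(table(f)), rep(200, 5))
  expect_true(!is.unsorted(f))
  f2 <- fold_plan(1003)
  expect_equal(range(table(f2)), c(200, 201))
  expect_error(fold_plan(3), "fewer bins")
})

test_that("cross-validation classifies every bin exactly once and assembles metrics", {
  cfg <- sim_config(duration_hours = 48, seizure_rate = 3,
                    signature_strength = 0.5, gap_rate = 0, seed = 40)
  ds <- generate_feature_level(cfg)
  res <- crossval_forecast(ds$features, ds$seizures, ds$gaps,
                           c(0, 48 * 3600), synth_lab_config())
  expect_false(anyNA(res$calls$call))
  expect_equal(nrow(res$calls), nrow(ds$features$values))
  expect_equal(sort(res$calls$time), sort(ds$features$time))
  # assembled metrics equal metrics recomputed from the assembled calls
  redo <- evaluate_warnings(res$calls[, c("time", "call")], ds$seizures,
                            ds$gaps, c(0, 48 * 3600), synth_lab_config())
  expect_equal(res$lead_sensitivity, redo$lead_sensitivity)
  expect_equal(res$tiw, redo$tiw)
  expect_equal(res$p_value, redo$p_value)
  expect_lte(res$tiw, 0.30 + 1e-9)
  expect_true(res$n_hit <= res$n_lead)
})
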