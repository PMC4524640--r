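test_that("generators are deterministic given a seed and leave the RNG alone", {
  cfg <- sim_config(duration_hours = 24, seizure_rate = 3,
                    signature_strength = 0.4, seed = 99)
  set.seed(123); before <- stats::runif(1)
  set.seed(123)
  a <- generate_feature_level(cfg)
  expect_identical(stats::runif(1), before)  # global RNG stream untouched
  b <- generate_feature_level(cfg)
  expect_identical(a$features$values, b$features$values)
  expect_identical(a$seizures, b$seizures)
  expect_identical(a$gaps, b$gaps)

  raw_cfg <- small_raw_config(duration_hours = 0.5)
  r1 <- generate_recording(raw_cfg)
  r2 <- generate_recording(raw_cfg)
  expect_identical(r1$segments[[1]]$data, r2$segments[[1]]$data)
})

test_that("invalid simulation configs fail loudly", {
  expect_error(sim_config(duration_hours = 1), "too short")
  expect_error(sim_config(signature_len = 300), "shorter than refractory")
  expect_error(sim_config(signature_strength = -1), ">= 0")
  expect_error(sim_config(signature_band = c(100, 250), sampling_rate = 400),
               "sampling_rate/2")
  expect_error(sim_config(signature_pairs = data.frame(i = 1L, j = 99L)),
               "montage")
})

test_that("dataset invariants hold: events inside timeline, refractory, gaps", {
  for (seed in 1:5) {
    cfg <- sim_config(duration_hours = 96, seizure_rate = 3, gap_rate = 2,
                      seed = seed)
    ds <- generate_feature_level(cfg)
    dur_s <- cfg$duration_hours * 3600
    expect_true(all(ds$seizures$onset >= 0 & ds$seizures$onset < dur_s))
    expect_true(all(ds$gaps$start >= 0 & ds$gaps$end <= dur_s))
    if (nrow(ds$seizures) > 1L)
      expect_true(all(diff(ds$seizures$onset) >= cfg$refractory * 60))
    expect_false(any(points_in_intervals(ds$seizures$onset,
                                         as.matrix(ds$gaps))))
  }
})

test_that("seizure counts match an independent thinned-Poisson oracle", {
  # oracle: fresh thinning simulation of a 2/day Poisson process with a 4 h
  # refractory over 10 days
  thin_sim <- function() {
    t <- 0; last <- -Inf; cnt <- 0L
    repeat {
      t <- t + stats::rexp(1L, 2 / 86400)
      if (t >= 10 * 86400) break
      if (t - last >= 4 * 3600) { cnt <- cnt + 1L; last <- t }
    }
    cnt
  }
  set.seed(42)
  oracle <- replicate(1000, thin_sim())
  got <- vapply(1:300, function(s)
    length(preictal:::draw_seizure_onsets(2, 10 * 86400, 4 * 3600)),
    numeric(1L))
  se <- sqrt(stats::var(oracle) / 1000 + stats::var(got) / 300)
  expect_lt(abs(mean(got) - mean(oracle)), 3 * se)
})

test_that("zero seizures requested yields no preictal bins", {
  cfg <- sim_config(duration_hours = 6, seizure_rate = 0, gap_rate = 0,
                    seed = 2)
  ds <- generate_feature_level(cfg)
  expect_equal(nrow(ds$seizures), 0L)
  lab <- label_bins(c(0, 6 * 3600), ds$seizures, ds$gaps, synth_lab_config())
  expect_equal(sum(lab$label == "preictal"), 0L)
})

test_that("null feature-level data shows no preictal/interictal separation", {
  # two-sample t-test on the would-be signature column across replicates:
  # under the null the rejection rate at alpha = 0.05 stays near 0.05
  alpha <- 0.05
  n_rep <- 40
  pvals <- vapply(seq_len(n_rep), function(s) {
    cfg <- sim_config(duration_hours = 48, seizure_rate = 3,
                      signature_strength = 0, gap_rate = 0, seed = 1000 + s)
    ds <- generate_feature_level(cfg)
    lab <- label_bins(c(0, 48 * 3600), ds$seizures, ds$gaps,
                      synth_lab_config())
    l <- lab$label[match(ds$features$time, lab$time)]
    sig <- which(ds$features$columns$i == 1 & ds$features$columns$j == 2 &
                   ds$features$columns$band == 5)
    pre <- which(l == "preictal"); int <- which(l == "interictal")
    if (length(pre) < 5L) return(NA_real_)  # replicate drew no lead seizure
    stats::t.test(ds$features$values[pre, sig],
                  ds$features$values[int, sig])$p.value
  }, numeric(1L))
  rate <- mean(pvals < alpha, na.rm = TRUE)
  expect_lt(rate, alpha + 3 * sqrt(alpha * (1 - alpha) / n_rep))
})

test_that("a large injected effect separates classes with column AUC > 0.9", {
  cfg <- sim_config(duration_hours = 48, seizure_rate = 3,
                    signature_strength = 0.5, gap_rate = 0, seed = 5)
  ds <- generate_feature_level(cfg)
  lab <- label_bins(c(0, 48 * 3600), ds$seizures, ds$gaps, synth_lab_config())
  l <- lab$label[match(ds$features$time, lab$time)]
  sig <- which(ds$features$columns$i == 1 & ds$features$columns$j == 2 &
                 ds$features$columns$band == 5)
  use <- l %in% c("preictal", "interictal")
  auc <- rank_auc(ds$features$values[use, sig], l[use] == "preictal")
  expect_gt(auc, 0.9)
  # a non-signature column stays uninformative
  ctrl <- which(ds$features$columns$i == 9 & ds$features$columns$j == 10 &
                  ds$features$columns$band == 5)
  auc0 <- rank_auc(ds$features$values[use, ctrl], l[use] == "preictal")
  expect_lt(abs(auc0 - 0.5), 0.1)
})

test_that("effect size in the signature column is monotone in signature_strength", {
  grid <- c(0, 0.15, 0.4)
  eff <- vapply(grid, function(str) {
    d <- vapply(1:6, function(s) {
      cfg <- sim_config(duration_hours = 48, seizure_rate = 3,
                        signature_strength = str, gap_rate = 0,
                        seed = 7000 + s)
      ds <- generate_feature_level(cfg)
      lab <- label_bins(c(0, 48 * 3600), ds$seizures, ds$gaps,
                        synth_lab_config())
      l <- lab$label[match(ds$features$time, lab$time)]
      sig <- which(ds$features$columns$i == 1 & ds$features$columns$j == 2 &
                     ds$features$columns$band == 5)
      mean(ds$features$values[l == "preictal", sig]) -
        mean(ds$features$values[l == "interictal", sig])
    }, numeric(1L))
    mean(d)
  }, numeric(1L))
  expect_true(all(diff(eff) > 0))
})

test_that("bin_ar induces the requested lag-1 autocorrelation without changing margins", {
  cfg <- sim_config(duration_hours = 48, seizure_rate = 0, gap_rate = 0,
                    bin_ar = 0.8, seed = 17)
  ds <- generate_feature_level(cfg)
  v <- ds$features$values
  r1 <- mean(vapply(seq_len(ncol(v)), function(j)
    stats::cor(v[-1, j], v[-nrow(v), j]), numeric(1L)))
  expect_equal(r1, 0.8, tolerance = 0.05)
  # marginal spread unchanged relative to the iid generator's sd range
  sds <- apply(v, 2L, stats::sd)
  expect_true(all(sds > 1 & sds < 5.5))
  expect_error(sim_config(bin_ar = 1), "bin_ar")
})

test_that("raw-signal and feature-level modes agree on the injected structure", {
  # features extracted from raw signals show the shift in the designated
  # band/pair (alpha = 0.01), and only there
  cfg <- small_raw_config(strength = 1, seed = 21)
  ds <- generate_recording(cfg)
  bank <- design_filter_bank(filter_bank_spec(small_edges(), taps = 257L),
                             cfg$sampling_rate)
  fm <- correlation_features(ds$segments, bank = bank)
  lab <- label_bins(c(0, cfg$duration_hours * 3600), ds$seizures, ds$gaps,
                    small_raw_lab_config())
  l <- lab$label[match(fm$time, lab$time)]
  sig <- which(fm$columns$i == 1 & fm$columns$j == 2 & fm$columns$band == 3)
  ctrl <- which(fm$columns$i == 9 & fm$columns$j == 10 & fm$columns$band == 3)
  p_sig <- stats::t.test(fm$values[which(l == "preictal"), sig],
                         fm$values[which(l == "interictal"), sig])$p.value
  p_ctrl <- stats::t.test(fm$values[which(l == "preictal"), ctrl],
                          fm$values[which(l == "interictal"), ctrl])$p.value
  expect_lt(p_sig, 0.01)
  expect_gt(p_ctrl, 0.01)
})

test_that("null raw data carries no information downstream (classifier AUC ~ 0.5)", {
  # few bins per record -> high AUC variance: average held-out AUC over seeds
  aucs <- vapply(c(31, 32, 33), function(seed) {
    cfg <- small_raw_config(strength = 0, seed = seed)
    ds <- generate_recording(cfg)
    bank <- design_filter_bank(filter_bank_spec(small_edges(), taps = 257L),
                               cfg$sampling_rate)
    fm <- correlation_features(ds$segments, bank = bank)
    lab <- label_bins(c(0, cfg$duration_hours * 3600), ds$seizures, ds$gaps,
                      small_raw_lab_config())
    l <- lab$label[match(fm$time, lab$time)]
    use <- which(l %in% c("preictal", "interictal"))
    half <- use[seq_len(floor(length(use) / 2))]
    rest <- setdiff(use, half)
    model <- train_classifier(fm$values[half, ], droplevels(l[half]))
    pred <- classify_bins(model, fm$values[rest, ])
    rank_auc(pred$decision, l[rest] == "preictal")
  }, numeric(1L))
  expect_lt(abs(mean(aucs) - 0.5), 0.2)
})
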