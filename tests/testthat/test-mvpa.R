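test_that("label shifting translates events onto the scan grid", {
  events <- tibble::tibble(onset = 0, duration = 8, label = "scene")
  scans <- seq(0, 18, by = 2)
  # zero shift: labels equal raw event coverage
  l0 <- shift_labels(events, scans, shift = 0)
  expect_equal(l0$label[scans < 8], rep("scene", 4))
  expect_true(all(is.na(l0$label[scans >= 8])))
  # 6-s shift: an event at 0-8 s labels scans at 6-14 s
  l6 <- shift_labels(events, scans, shift = 6)
  covered <- scans[!is.na(l6$label)]
  expect_equal(covered, c(6, 8, 10, 12))
  expect_true(is.na(l6$label[scans == 2])) # pre-onset scan is unlabeled
  expect_equal(attr(l6, "shift_applied"), 6)
  expect_error(shift_labels(events, scans, shift = 3),
               class = "pcitr_misaligned_shift")
})

ts_from_labels <- function(n_voxels, labels, informative, effect = 1,
                           noise = 0.3, seed = 1, blocks = NULL) {
  n <- length(labels)
  if (is.null(blocks)) blocks <- rep(1, n)
  withr::with_seed(seed, {
    data <- matrix(rnorm(n_voxels * n, 0, noise), n_voxels, n)
    for (v in informative) {
      data[v, labels == "face"] <- data[v, labels == "face"] + effect
      data[v, labels == "scene"] <- data[v, labels == "scene"] - effect
    }
  })
  roi_timeseries(data, 2, seq(0, by = 2, length.out = n), blocks)
}

test_that("ANOVA feature selection finds informative voxels and respects alpha", {
  labels <- tibble::tibble(onset = seq(0, by = 2, length.out = 90),
                           label = rep(c("face", "scene", "rest"), 30))
  ts <- ts_from_labels(100, labels$label, informative = 1:10, effect = 1.5)
  mask <- select_features(ts, labels, alpha = 0.05)
  expect_true(all(1:10 %in% mask))
  # alpha = 1 selects everything
  expect_equal(select_features(ts, labels, alpha = 1), 1:100)
  # under the null the selected fraction is ~alpha (Monte Carlo over seeds)
  frac <- vapply(1:20, function(s) {
    ts0 <- ts_from_labels(100, labels$label, informative = integer(0),
                          seed = s)
    length(select_features(ts0, labels, alpha = 0.05)) / 100
  }, numeric(1))
  expect_lt(abs(mean(frac) - 0.05), 0.03)
  # vectorized F-test agrees with per-voxel anova(lm()) to near machine
  p_fast <- pcitr:::anova_feature_p(ts$data, seq_along(labels$label),
                                    labels$label)
  p_ref <- vapply(1:20, function(v) {
    stats::anova(lm(ts$data[v, ] ~ factor(labels$label)))$`Pr(>F)`[1]
  }, numeric(1))
  expect_equal(p_fast[1:20], p_ref, tolerance = 1e-10)
  # a zero-variance voxel is excluded, not a crash
  ts$data[55, ] <- 2
  expect_false(55 %in% select_features(ts, labels, alpha = 0.99))
})

test_that("penalized logistic training matches a brute-force oracle and its limits", {
  # separable toy: strong training evidence at small lambda
  labels <- tibble::tibble(onset = seq(0, 22, 2),
                           label = rep(c("face", "scene", "rest"), 4))
  ts <- ts_from_labels(2, labels$label, informative = 1:2, effect = 3,
                       noise = 0.05)
  model <- train_classifier(ts, labels, lambda = 0.01, feature_mask = 1:2)
  ev <- decode(model, ts)
  expect_gt(min(ev$face[labels$label == "face"]), 0.9)
  # huge lambda: weights ~ 0, evidence ~ intercept-only base rate
  m_big <- train_classifier(ts, labels, lambda = 1e9, feature_mask = 1:2)
  expect_lt(max(abs(m_big$weights)), 1e-5)
  ev_big <- decode(m_big, ts)
  expect_equal(unique(round(ev_big$face, 4)), round(1 / 3, 4))
  # objective equivalence with an independent gradient-descent oracle
  withr::with_seed(11, {
    X <- matrix(rnorm(10 * 3), 10, 3)
    y <- rep(c(0, 1), 5)
  })
  fit <- pcitr:::fit_l2_logistic(X, y, lambda = 5)
  oracle <- oracle_l2_logistic(X, y, lambda = 5)
  expect_equal(fit$objective, oracle$objective, tolerance = 1e-6)
  expect_error(
    train_classifier(ts, dplyr::mutate(labels,
      label = dplyr::if_else(label == "rest", NA_character_, label)),
      lambda = 1, feature_mask = 1:2),
    class = "pcitr_empty_class"
  )
})

test_that("decoding produces bounded evidence and honors the model", {
  labels <- tibble::tibble(onset = seq(0, 58, 2),
                           label = rep(c("face", "scene", "rest"), 10))
  ts <- ts_from_labels(5, labels$label, informative = 1:3)
  model <- train_classifier(ts, labels, lambda = 10, feature_mask = 1:5)
  ev <- decode(model, ts)
  for (cl in c("face", "scene", "rest")) {
    expect_true(all(ev[[cl]] >= 0 & ev[[cl]] <= 1))
  }
  expect_true(all(abs(ev$scene_minus_face) <= 1))
  expect_equal(ev$scene_minus_face, ev$scene - ev$face)
  # all-zero weights: evidence is the intercept rate for every scan
  m0 <- model
  m0$weights[] <- 0
  ev0 <- decode(m0, ts)
  expect_equal(unique(ev0$face), plogis(unname(model$intercepts["face"])))
  # voxel-count mismatch is rejected
  small_ts <- roi_timeseries(ts$data[1:2, ], 2, ts$scan_onsets, ts$block)
  expect_error(decode(model, small_ts), class = "pcitr_voxel_mismatch")
})

test_that("cross-validation partitions scans and never leaks the test block", {
  cfg <- small_cfg(n_participants = 1, seed = 31)
  p1 <- generate_phase1(cfg, seed = 31)
  cv <- crossvalidate(p1$ts, p1$labels)
  # every scan tested exactly once, in its own block's fold
  expect_equal(sort(cv$evidence$onset), sort(p1$ts$scan_onsets))
  expect_equal(cv$evidence$fold, cv$evidence$block)
  expect_equal(nrow(cv$folds), 4)
  # no-leakage: the fold-1 result equals training a model by hand on
  # blocks 2-4 only and decoding block 1
  tr <- p1$ts$block != 1
  ts_tr <- roi_timeseries(p1$ts$data[, tr], 2, p1$ts$scan_onsets[tr],
                          p1$ts$block[tr])
  lab_tr <- p1$labels[tr, ]
  mask <- select_features(ts_tr, lab_tr)
  model <- train_classifier(ts_tr, lab_tr, 50, mask)
  te <- p1$ts$block == 1
  ts_te <- roi_timeseries(p1$ts$data[, te], 2, p1$ts$scan_onsets[te],
                          p1$ts$block[te])
  ev1 <- decode(model, ts_te)
  fold1 <- cv$evidence[cv$evidence$fold == 1, names(ev1)]
  expect_equal(as.data.frame(fold1), as.data.frame(ev1), tolerance = 1e-10)
  expect_error(crossvalidate(ts_te, p1$labels[te, ]),
               class = "pcitr_few_blocks")
})

test_that("decoding accuracy is high on signal and at chance on shuffled labels", {
  cfg <- small_cfg(n_participants = 1, seed = 17)
  p1 <- generate_phase1(cfg, seed = 17)
  cv <- crossvalidate(p1$ts, p1$labels)
  expect_gt(cv$accuracy_face_scene, 0.9)
  shuffled <- p1$labels
  idx <- which(!is.na(shuffled$label))
  shuffled$label[idx] <- withr::with_seed(5, sample(shuffled$label[idx]))
  cv0 <- crossvalidate(p1$ts, shuffled)
  n <- sum(!is.na(shuffled$label))
  # binomial 99.9% band around chance = 1/3
  expect_lt(abs(cv0$accuracy - 1 / 3), 3.3 * sqrt(1 / 3 * 2 / 3 / n))
})

test_that("window averages are exact scan-count means over half-open windows", {
  trials <- tibble::tibble(trial_id = 1:2, onset = c(20, 48), duration = 28,
                           participant_id = 1)
  onsets <- seq(0, 98, 2)
  ev <- tibble::tibble(
    onset = onsets, block = 1,
    face = seq_along(onsets) / 100, scene = 0.5, rest = 0.1
  )
  ev$scene_minus_face <- ev$scene - ev$face
  wins <- experiment_design()$windows
  wa <- window_average(ev, trials, wins)
  # pre-switch [4,12): exactly scans at +4,+6,+8,+10; probe [20,24): 2 scans
  t0 <- 20
  pre_scans <- which(onsets %in% (t0 + c(4, 6, 8, 10)))
  expect_equal(wa$pre_switch_face[1], mean(ev$face[pre_scans]))
  probe_scans <- which(onsets %in% (t0 + c(20, 22)))
  expect_equal(wa$probe_face[1], mean(ev$face[probe_scans]))
  # constant trace: every window mean equals the constant
  expect_equal(wa$pre_switch_scene, c(0.5, 0.5))
  expect_equal(wa$post_switch_scene, c(0.5, 0.5))
  expect_error(
    window_average(ev, trials, list(bad = c(20, 32))),
    class = "pcitr_window_outside_trial"
  )
})

test_that("noiseless decoding reproduces the pre/post sign inversion", {
  # trial-averaged scene-face evidence is positive before the switch and
  # negative after it; individual trials vary because the amplitude
  # mixtures overlap (a few trials are genuinely face-dominant pre-switch)
  cfg <- small_cfg(n_participants = 1, noise_sd = 0, seed = 23)
  st <- generate_dataset(cfg)
  items <- decode_study(st)
  expect_gt(mean(items$pre_switch_smf), 0)
  expect_lt(mean(items$post_switch_smf), 0)
  expect_gt(mean(items$pre_switch_smf > 0), 0.9)
  expect_gt(mean(items$post_switch_smf < 0), 0.9)
  # noise-free decoded trial signs follow the latent amplitude signs
  expect_gt(cor(items$pre_switch_smf, st$trials$diff_pre), 0.9)
})
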