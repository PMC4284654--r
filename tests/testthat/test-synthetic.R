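test_that("generation is deterministic under a fixed seed and varies with it", {
  cfg <- small_cfg(n_participants = 1, seed = 99, n_voxels = 60,
                   n_informative = 20)
  s1 <- generate_dataset(cfg)
  s2 <- generate_dataset(cfg)
  expect_identical(s1, s2)
  s3 <- generate_dataset(small_cfg(n_participants = 1, seed = 100,
                                   n_voxels = 60, n_informative = 20))
  # different seed: different noise, identical trial structure
  expect_false(identical(s1$participants[[1]]$phase1$ts$data,
                         s3$participants[[1]]$phase1$ts$data))
  expect_equal(s1$trials[, c("trial_id", "block", "onset", "duration")],
               s3$trials[, c("trial_id", "block", "onset", "duration")])
})

test_that("noiseless phase 1 delay scans are exact template multiples", {
  cfg <- small_cfg(n_participants = 1, noise_sd = 0,
                   p1_amp = c(mean = 1, sd = 0))
  p1 <- generate_phase1(cfg, seed = 5)
  tpl <- make_templates <- pcitr:::make_templates(cfg)
  ev <- p1$events
  # a face trial's shifted delay-window scan is exactly the face template
  face_trial <- ev[ev$trial_type == "p1_face", ][1, ]
  scan <- which(p1$ts$scan_onsets == face_trial$onset + cfg$lag_p1 + 2)
  expect_equal(p1$ts$data[, scan], tpl$face, tolerance = 1e-12)
  expect_error(
    ground_truth_config(n_voxels = 10, n_informative = 11),
    class = "pcitr_bad_config"
  )
})

test_that("phase 1 training labels have matched per-class counts", {
  cfg <- small_cfg(n_participants = 1)
  p1 <- generate_phase1(cfg, seed = 3)
  counts <- table(p1$labels$label)
  expected <- training_label_counts(cfg$design)
  expect_equal(as.integer(counts[expected$label]), expected$n_scans)
})

test_that("degenerate phase 2 mixtures give latent scene-face of +1 pre and -1 post", {
  cfg <- small_cfg(
    n_participants = 1, noise_sd = 0, participant_sd = 0,
    pre_mix = list(scene = c(mean = 1, sd = 0), face = c(mean = 0, sd = 0)),
    post_mix = list(scene = c(mean = 0, sd = 0), face = c(mean = 1, sd = 0))
  )
  p2 <- generate_phase2_switch(cfg, seed = 4)
  expect_true(all(p2$latent$diff_pre == 1))
  expect_true(all(p2$latent$diff_post == -1))
  expect_equal(nrow(p2$trials), 36)
})

test_that("default mixtures produce opposite-signed pre/post evidence distributions", {
  st <- generate_dataset(small_cfg(n_participants = 3, seed = 21))
  expect_gt(mean(st$trials$diff_pre), 0)
  expect_lt(mean(st$trials$diff_post), 0)
  # rescaled learning events span the curve domain
  expect_equal(range(c(st$trials$e_pre, st$trials$e_post)), c(-1, 1))
})

test_that("the canonical study pools 21 x 36 = 756 switch-trial items", {
  st <- generate_dataset(ground_truth_config(seed = 1))
  expect_equal(nrow(st$trials), 756)
  expect_equal(as.integer(table(st$trials$participant_id)), rep(36L, 21))
  expect_equal(nrow(st$new_items), 756)
})

test_that("behavior generation follows the ground-truth curve model", {
  # flat curve, no response noise: all memory probabilities identical and
  # responses determined solely by the binning rule
  flat <- plasticity_curve(c(-1, 0, 0.5, 1), c(0, 0, 0, 0))
  cfg0 <- small_cfg(true_curve = flat, response_noise = 0, beta0_mem = 0.5)
  lat <- tibble::tibble(e_pre = runif(50, -1, 1), e_post = runif(50, -1, 1),
                        e_face_probe = runif(50, -1, 1))
  beh <- generate_behavior(cfg0, lat, seed = 1)
  expect_equal(unique(beh$p_mem), plogis(0.5))
  expect_equal(unique(beh$response), "unsure_old") # plogis(0.5) in (0.5, .75]
  # out-of-domain evidence is rejected
  expect_error(
    generate_behavior(cfg0, dplyr::mutate(lat, e_pre = e_pre * 2), seed = 1),
    class = "pcitr_domain"
  )
})

test_that("a U-shaped truth depresses memory for mid-range evidence", {
  cfg <- small_cfg(response_noise = 0.05)
  withr::with_seed(6, {
    lat <- tibble::tibble(e_pre = runif(3000, -1, 1),
                          e_post = runif(3000, -1, 1),
                          e_face_probe = runif(3000, -1, 1))
  })
  beh <- generate_behavior(cfg, lat, seed = 2)
  terc <- cut(beh$e_pre, c(-1.01, -1 / 3, 1 / 3, 1.01),
              labels = c("low", "mid", "high"))
  m <- tapply(beh$strength, terc, mean)
  expect_lt(m["mid"], m["low"])
  expect_lt(m["mid"], m["high"])
})

test_that("null working-memory coupling yields a near-zero fitted slope", {
  cfg <- small_cfg(gamma1 = 0)
  withr::with_seed(7, {
    lat <- tibble::tibble(e_pre = runif(400, -1, 1),
                          e_post = runif(400, -1, 1),
                          e_face_probe = runif(400, -1, 1))
  })
  beh <- generate_behavior(cfg, lat, seed = 3)
  fit <- wm_logistic(beh$e_face_probe, beh$wm_correct, n_boot = 200,
                     seed = 4)
  expect_true(fit$ci95[1] <= 0 && 0 <= fit$ci95[2])
})

test_that("double-gamma hemodynamics are available behind the config flag", {
  cfg <- small_cfg(n_participants = 1, hrf = "double_gamma", n_voxels = 60,
                   n_informative = 20)
  p2 <- generate_phase2_switch(cfg, seed = 8)
  expect_s3_class(p2$ts, "roi_timeseries")
  expect_equal(ncol(p2$ts$data), 6 * (20 + 6 * 28) / 2)
})

test_that("ROI timeseries round-trip through the text + sidecar format", {
  cfg <- small_cfg(n_participants = 1, n_voxels = 20, n_informative = 5)
  st <- generate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_study(st, dir)
  back <- read_roi_timeseries(file.path(dir, "sub01_phase2"))
  orig <- st$participants[[1]]$phase2$ts
  expect_equal(back$data, orig$data, tolerance = 1e-12)
  expect_equal(back$block, orig$block)
  trials <- read_events(file.path(dir, "trials.tsv"))
  expect_equal(nrow(trials), nrow(st$trials))
})
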