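test_that("compiled curve evaluation matches approx() over random curves", {
  curves <- sample_curves(200, seed = 3)
  x <- seq(-1, 1, length.out = 53)
  fast <- pcitr:::eval_curves(curves, x)
  m <- as.matrix(curves)
  for (i in c(1, 7, 50, 200)) {
    ref <- approx(c(-1, m[i, 1], m[i, 2], 1), m[i, 3:6], xout = x,
                  ties = "ordered")$y
    expect_equal(fast[, i], ref, tolerance = 1e-12)
  }
})

test_that("item log-likelihood follows the fractional-Bernoulli form", {
  flat <- plasticity_curve(c(-1, 0, 0.5, 1), c(0, 0, 0, 0))
  # flat curve, zero intercept: p = 0.5 regardless of outcome
  for (y in c(0, 1 / 3, 2 / 3, 1)) {
    expect_equal(item_loglik(flat, c(0.2, -0.5), y, beta0 = 0), log(0.5))
  }
  # saturation: y = 1 with a large positive linear predictor
  expect_gt(item_loglik(flat, 0, 1, beta0 = 9), -1e-3)
  expect_lt(item_loglik(flat, 0, 1, beta0 = 9), 0)
  # 3-item toy against hand arithmetic
  cv <- plasticity_curve(c(-1, 0, 0.5, 1), c(-0.5, 0.5, 0, 1))
  ev <- list(c(-0.5, 0.25), c(0, 0.75), c(1, -1))
  ys <- c(1, 2 / 3, 0)
  hand <- 0
  for (i in 1:3) {
    d <- sum(curve_eval(cv, ev[[i]]))
    p <- 1 / (1 + exp(-(0.3 + d)))
    hand <- hand + ys[i] * log(p) + (1 - ys[i]) * log(1 - p)
  }
  got <- sum(vapply(1:3, function(i) item_loglik(cv, ev[[i]], ys[i], 0.3),
                    numeric(1)))
  expect_equal(got, hand, tolerance = 1e-12)
})

test_that("intercept profiling matches a 1-D optimize() oracle", {
  withr::with_seed(4, {
    delta <- matrix(rnorm(30 * 8, 0, 1.2), 30, 8)
    y <- sample(c(0, 1 / 3, 2 / 3, 1), 30, replace = TRUE)
  })
  prof <- pcitr:::profile_beta0(delta, y)
  for (j in 1:8) {
    f <- function(b) {
      p <- pmin(pmax(plogis(b + delta[, j]), 1e-12), 1 - 1e-12)
      sum(y * log(p) + (1 - y) * log(1 - p))
    }
    ref <- optimize(f, c(-10, 10), maximum = TRUE, tol = 1e-10)
    expect_equal(prof$loglik[j], ref$objective, tolerance = 1e-8)
    expect_equal(prof$beta0[j], ref$maximum, tolerance = 1e-4)
  }
  # flat-curve weight reduces to the intercept-only maximum: the profiled
  # intercept is the empirical logit
  prof0 <- pcitr:::profile_beta0(matrix(0, 30, 1), y)
  expect_equal(prof0$beta0[1], qlogis(mean(y)), tolerance = 1e-6)
})

test_that("importance weights favor consistent curves for U-generated items", {
  items <- u_items(150, seed = 2)
  wc <- importance_weights(sample_curves(2000, seed = 5), items,
                           events = c("e_pre", "e_post"),
                           outcome = "outcome")
  w <- exp(wc$log_weight)
  expect_equal(sum(w), 1, tolerance = 1e-9)
  expect_gt(mean(w[wc$consistent]), mean(w[!wc$consistent]))
  # identical curves receive identical weights
  two <- dplyr::bind_rows(wc[1, 1:6], wc[1, 1:6], wc[2, 1:6])
  w2 <- importance_weights(two, items, events = c("e_pre", "e_post"),
                           outcome = "outcome")
  expect_equal(w2$log_weight[1], w2$log_weight[2])
})

test_that("posterior summaries respect weighting and ordering", {
  curves <- sample_curves(500, seed = 9)
  # all weight on one curve: mean is that curve, band has zero width
  lw <- rep(-1e6, 500)
  lw[137] <- 0
  wc <- dplyr::mutate(curves, log_weight = lw - pcitr:::log_sum_exp(lw))
  post <- summarize_posterior(wc, grid = seq(-1, 1, 0.1))
  target <- pcitr:::eval_curves(curves[137, ], seq(-1, 1, 0.1))[, 1]
  expect_equal(post$mean, target, tolerance = 1e-8)
  expect_equal(post$lo, post$hi)
  # uniform weights over the symmetric prior: mean ~ 0 within MC error
  wcu <- dplyr::mutate(sample_curves(20000, seed = 2),
                       log_weight = -log(20000))
  postu <- summarize_posterior(wcu, grid = seq(-1, 1, 0.25))
  expect_lt(max(abs(postu$mean)), 0.05)
  # the band always contains the pointwise weighted median and mean
  items <- u_items(80, seed = 3)
  wc2 <- importance_weights(sample_curves(1000, seed = 4), items,
                            events = c("e_pre", "e_post"),
                            outcome = "outcome")
  post2 <- summarize_posterior(wc2)
  G <- pcitr:::eval_curves(wc2[, 1:6], post2$x)
  w <- exp(wc2$log_weight)
  med <- vapply(seq_along(post2$x), function(i) {
    pcitr:::weighted_quantile(G[i, ], w, 0.5)
  }, numeric(1))
  expect_true(all(post2$lo <= med & med <= post2$hi))
  expect_true(all(post2$lo <= post2$mean & post2$mean <= post2$hi))
})

test_that("log Bayes factor matches hand computation and caps at zero mass", {
  withr::with_seed(10, {
    curves <- sample_curves(20, seed = 10)
    ll <- rnorm(20)
  })
  cons <- curve_consistency(curves)
  wc <- dplyr::mutate(curves, log_weight = ll - pcitr:::log_sum_exp(ll),
                      consistent = cons)
  hand <- log(sum(exp(wc$log_weight[cons])) /
                sum(exp(wc$log_weight[!cons]))) -
    log(mean(cons) / mean(!cons))
  got <- log_bayes_factor(wc)
  expect_equal(got$log_bf, hand, tolerance = 1e-10)
  expect_false(got$capped)
  # all posterior mass on one class: capped with a flag
  wc2 <- wc
  wc2$log_weight <- ifelse(cons, -0.5, -2000)
  wc2$log_weight <- wc2$log_weight - pcitr:::log_sum_exp(wc2$log_weight)
  got2 <- log_bayes_factor(wc2)
  expect_equal(got2$log_bf, 10)
  expect_true(got2$capped)
  # flat likelihood: posterior = prior, log BF exactly 0
  wc3 <- dplyr::mutate(curves, log_weight = -log(20), consistent = cons)
  expect_equal(log_bayes_factor(wc3)$log_bf, 0, tolerance = 1e-12)
  expect_error(log_bayes_factor(dplyr::mutate(wc, consistent = TRUE)),
               class = "pcitr_one_class")
})

test_that("P-CIT agrees with the dense-grid enumeration oracle on few items", {
  items <- u_items(18, seed = 6)
  grid <- grid_curve_set()
  # route 1: the package engine run on the enumerated grid must match the
  # independent loop/optimize oracle exactly
  wc <- importance_weights(grid, items, events = c("e_pre", "e_post"),
                           outcome = "outcome", rescale = FALSE)
  pkg_grid_bf <- log_bayes_factor(wc, cap = 50)$log_bf
  oracle <- oracle_pcit(grid, items, c("e_pre", "e_post"), "outcome")
  expect_equal(pkg_grid_bf, oracle$log_bf, tolerance = 1e-6)
  expect_identical(wc$consistent, oracle$cons)
  # route 2: the Monte-Carlo sampler converges to the same neighborhood;
  # tolerance = 4 split-half SEs plus a fixed allowance for the coarse grid
  fit <- pcit(items, events = c("e_pre", "e_post"), outcome = "outcome",
              n_samples = 20000, seed = 8, rescale = FALSE)
  tol <- max(0.5, 4 * fit$mc_se_log_bf)
  expect_lt(abs(fit$log_bayes_factor - oracle$log_bf), tol)
})

test_that("pcit fits are deterministic and structurally sound", {
  items <- u_items(60, seed = 12)
  f1 <- pcit(items, c("e_pre", "e_post"), "outcome", n_samples = 800,
             seed = 5)
  f2 <- pcit(items, c("e_pre", "e_post"), "outcome", n_samples = 800,
             seed = 5)
  expect_equal(glance(f1), glance(f2))
  expect_identical(f1$posterior, f2$posterior)
  expect_true(all(f1$posterior$lo <= f1$posterior$mean))
  expect_true(all(f1$posterior$mean <= f1$posterior$hi))
  expect_gt(f1$prior_consistent_fraction, 0)
  expect_lt(f1$prior_consistent_fraction, 1)
  expect_s3_class(tidy(f1), "tbl_df")
  expect_s3_class(autoplot(f1), "ggplot")
  expect_error(pcit(items[0, ], c("e_pre", "e_post"), "outcome"),
               class = "pcitr_no_items")
  bad <- dplyr::mutate(items, outcome = outcome + 2)
  expect_error(pcit(bad, c("e_pre", "e_post"), "outcome", n_samples = 10),
               class = "pcitr_bad_outcome")
})

test_that("Monte-Carlo error of the log Bayes factor shrinks with sample size", {
  items <- u_items(100, seed = 14)
  se_small <- mean(vapply(1:3, function(s) {
    pcit(items, c("e_pre", "e_post"), "outcome", n_samples = 1000,
         seed = s)$mc_se_log_bf
  }, numeric(1)))
  se_large <- mean(vapply(1:3, function(s) {
    pcit(items, c("e_pre", "e_post"), "outcome", n_samples = 10000,
         seed = s)$mc_se_log_bf
  }, numeric(1)))
  expect_lt(se_large, se_small)
})

test_that("the predictive chi-squared test controls false positives and has power", {
  # null: items independent of evidence. Posterior shrinkage makes the
  # statistic conservative (the posterior-mean curve is near flat under the
  # symmetric prior), so the check is type-I control, not exact uniformity.
  ps <- vapply(1:30, function(r) {
    items <- null_items(80, seed = 400 + r)
    fit <- pcit(items, "evidence", "outcome", n_samples = 400, seed = r)
    fit$chi2_p
  }, numeric(1))
  expect_lte(mean(ps < 0.05), 0.1)
  expect_gt(median(ps), 0.3)
  # power: strong U-shaped generator at moderate n
  items <- u_items(300, seed = 15, noise = 0.08)
  fit <- pcit(items, c("e_pre", "e_post"), "outcome", n_samples = 2000,
              seed = 2)
  expect_lt(fit$chi2_p, 0.01)
  expect_gte(fit$chi2_stat, 0)
})
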