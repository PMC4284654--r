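#' Region-of-interest timeseries container
#'
#' Holds a voxels-by-scans data matrix with its acquisition metadata. Scan
#' onsets are session-global seconds on the TR grid.
#'
#' @param data Numeric matrix, voxels x scans, no missing values.
#' @param tr_seconds Repetition time.
#' @param scan_onsets Onset (s) of each scan.
#' @param block Block id per scan.
#' @param phase Optional phase tag (`"P1"`/`"P2"`).
#' @return A `roi_timeseries` object.
#' @export
roi_timeseries <- function(data, tr_seconds, scan_onsets, block,
                           phase = NULL) {
  data <- as.matrix(data)
  stopifnot(!anyNA(data), ncol(data) == length(scan_onsets),
            length(block) == length(scan_onsets))
  for (b in unique(block)) {
    if (is.unsorted(scan_onsets[block == b])) {
      stop_pcitr("scans must be time-ordered within block",
                 "pcitr_unordered_scans")
    }
  }
  structure(
    list(data = data, tr_seconds = tr_seconds,
         scan_onsets = as.numeric(scan_onsets),
         block = block, phase = phase),
    class = "roi_timeseries"
  )
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat("<roi_timeseries> ", nrow(x$data), " voxels x ", ncol(x$data),
      " scans (TR = ", x$tr_seconds, " s, ",
      length(unique(x$block)), " blocks)\n", sep = "")
  invisible(x)
}

#' Shift event labels onto the scan grid
#'
#' Assigns each scan the label of the event active at `t - shift`, the
#' standard device for aligning labels with the hemodynamically lagged BOLD
#' response. Scans preceding the first shifted event are unlabeled (`NA`).
#'
#' @param events Tibble with columns `onset`, `duration`, `label`.
#' @param scan_onsets Scan onset times (s).
#' @param shift Forward shift in seconds; must be a multiple of `tr_seconds`.
#' @param tr_seconds Repetition time.
#' @return A tibble with columns `onset`, `label`, carrying the applied
#'   shift as the `shift_applied` attribute.
#' @export
shift_labels <- function(events, scan_onsets, shift = 6, tr_seconds = 2) {
  if (shift %% tr_seconds != 0) {
    stop_pcitr("label shift must be a multiple of the TR",
               "pcitr_misaligned_shift")
  }
  events <- dplyr::arrange(tibble::as_tibble(events), .data$onset)
  t0 <- scan_onsets - shift
  idx <- findInterval(t0, events$onset)
  lab <- rep(NA_character_, length(t0))
  ok <- idx >= 1
  ok[ok] <- t0[ok] < events$onset[idx[ok]] + events$duration[idx[ok]]
  lab[ok] <- events$label[idx[ok]]
  out <- tibble::tibble(onset = scan_onsets, label = lab)
  attr(out, "shift_applied") <- shift
  out
}

# vectorized one-way ANOVA F p-values across voxels (rows of `data`)
# for the scans in `idx` grouped by `g`; zero-variance voxels get p = 1
anova_feature_p <- function(data, idx, g) {
  X <- data[, idx, drop = FALSE]
  g <- factor(g)
  k <- nlevels(g)
  n <- length(g)
  stopifnot(k >= 2, all(table(g) >= 2))
  grand <- rowMeans(X)
  ss_tot <- rowSums((X - grand)^2)
  ss_b <- numeric(nrow(X))
  for (lev in levels(g)) {
    sel <- g == lev
    ss_b <- ss_b + sum(sel) * (rowMeans(X[, sel, drop = FALSE]) - grand)^2
  }
  ss_w <- pmax(ss_tot - ss_b, 0)
  f <- (ss_b / (k - 1)) / (ss_w / (n - k))
  p <- pf(f, k - 1, n - k, lower.tail = FALSE)
  # zero-variance voxels (ss_tot ~ 0) carry no signal: p = 1, never an error;
  # an infinite F (noiseless separation) is a legitimate p = 0
  p[is.na(f) | ss_tot < 1e-24] <- 1
  p
}

#' ANOVA feature selection
#'
#' Selects the voxels whose activity differs across the face/scene/rest
#' training classes (one-way ANOVA, p < `alpha`) on the provided training
#' scans only. Zero-variance voxels are excluded (p treated as 1), never an
#' error.
#'
#' @param ts A [roi_timeseries()].
#' @param labels Label series from [shift_labels()] (scan-aligned; `NA` =
#'   unlabeled).
#' @param alpha Selection threshold (default 0.05).
#' @return Integer vector of selected voxel indices.
#' @export
select_features <- function(ts, labels, alpha = 0.05) {
  stopifnot(inherits(ts, "roi_timeseries"))
  lab <- labels$label
  idx <- which(!is.na(lab))
  stopifnot(length(idx) >= 4)
  p <- anova_feature_p(ts$data, idx, lab[idx])
  which(p < alpha)
}

# L2-penalized logistic regression: minimize
#   -sum_i [y_i log p_i + (1 - y_i) log(1 - p_i)] + (lambda / 2) * ||w||^2
# (intercept unpenalized), by BFGS with analytic gradient
fit_l2_logistic <- function(X, y, lambda) {
  p <- ncol(X)
  obj <- function(par) {
    eta <- par[1] + X %*% par[-1]
    -sum(frac_bernoulli_ll(y, plogis(eta))) + lambda / 2 * sum(par[-1]^2)
  }
  grad <- function(par) {
    r <- as.vector(plogis(par[1] + X %*% par[-1])) - y
    c(sum(r), crossprod(X, r) + lambda * par[-1])
  }
  fit <- optim(rep(0, p + 1), obj, grad, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-12))
  list(intercept = fit$par[1], weights = fit$par[-1],
       objective = fit$value, converged = fit$convergence == 0)
}

#' Train the three category detectors
#'
#' Fits one-versus-other L2-penalized logistic detectors for face, scene and
#' rest on the labeled training scans (features already restricted to
#' `feature_mask`). The penalty `lambda * ||w||^2 / 2` is applied to the
#' summed (unnormalized) log-likelihood; the intercept is unpenalized. Fits
#' are deterministic given the data and `lambda`.
#'
#' @param ts A [roi_timeseries()].
#' @param labels Scan-aligned label series (`NA` = unlabeled).
#' @param lambda L2 penalty (default 50).
#' @param feature_mask Integer voxel indices from [select_features()].
#' @param classes Detector classes, fixed order (also the accuracy
#'   tie-break order).
#' @return An `mvpa_model`: weight matrix (features x classes), intercepts,
#'   `lambda`, `feature_mask`.
#' @export
train_classifier <- function(ts, labels, lambda = 50, feature_mask,
                             classes = c("face", "scene", "rest")) {
  stopifnot(inherits(ts, "roi_timeseries"), lambda >= 0,
            length(feature_mask) >= 1)
  lab <- labels$label
  idx <- which(!is.na(lab))
  g <- lab[idx]
  missing <- setdiff(classes, unique(g))
  if (length(missing)) {
    stop_pcitr(paste("no training scans for class:",
                     paste(missing, collapse = ", ")),
               "pcitr_empty_class")
  }
  X <- t(ts$data[feature_mask, idx, drop = FALSE])
  W <- matrix(0, length(feature_mask), length(classes),
              dimnames = list(NULL, classes))
  b <- stats::setNames(numeric(length(classes)), classes)
  obj <- b
  for (cl in classes) {
    fit <- fit_l2_logistic(X, as.numeric(g == cl), lambda)
    W[, cl] <- fit$weights
    b[cl] <- fit$intercept
    obj[cl] <- fit$objective
  }
  structure(
    list(weights = W, intercepts = b, lambda = lambda,
         feature_mask = feature_mask, classes = classes, objective = obj),
    class = "mvpa_model"
  )
}

#' Decode evidence timecourses
#'
#' Applies the trained detectors to every scan. Each detector's output is
#' its raw logistic probability in `[0, 1]` (the three detectors are
#' independent and need not sum to 1); `scene_minus_face` is their
#' difference, the index of competitive balance between the two
#' working-memory representations.
#'
#' @param model An `mvpa_model`.
#' @param ts A [roi_timeseries()] containing the model's masked voxels.
#' @return A tibble: `onset`, `block`, one evidence column per class,
#'   `scene_minus_face`.
#' @export
decode <- function(model, ts) {
  stopifnot(inherits(model, "mvpa_model"), inherits(ts, "roi_timeseries"))
  if (max(model$feature_mask) > nrow(ts$data)) {
    stop_pcitr("timeseries has fewer voxels than the model's feature mask",
               "pcitr_voxel_mismatch")
  }
  X <- t(ts$data[model$feature_mask, , drop = FALSE])
  P <- plogis(sweep(X %*% model$weights, 2, model$intercepts, `+`))
  out <- tibble::as_tibble(as.data.frame(P))
  out <- dplyr::bind_cols(
    tibble::tibble(onset = ts$scan_onsets, block = ts$block), out
  )
  out$scene_minus_face <- out$scene - out$face
  out
}

#' Block-wise cross-validated decoding
#'
#' Leave-one-block-out cross-validation: each block is scored exactly once
#' by detectors never trained on it. By default feature selection is re-run
#' inside each fold's training scans so the accuracy estimate is free of
#' selection leakage; `refit_features = FALSE` selects once on all labeled
#' scans instead. Accuracy is the fraction of labeled test scans whose true
#' class attains the maximum evidence (ties broken by fixed class order
#' face, scene, rest).
#'
#' @inheritParams train_classifier
#' @param alpha Feature-selection threshold.
#' @param refit_features Re-run feature selection within each fold.
#' @return A list: `evidence` (per-scan tibble with `fold`, `label`,
#'   evidence columns and `correct`), `accuracy` (all labeled scans),
#'   `accuracy_face_scene` (face/scene scans only), `folds` (per-fold
#'   accuracy tibble).
#' @export
crossvalidate <- function(ts, labels, alpha = 0.05, lambda = 50,
                          refit_features = TRUE,
                          classes = c("face", "scene", "rest")) {
  stopifnot(inherits(ts, "roi_timeseries"))
  blocks <- unique(ts$block)
  if (length(blocks) < 2) {
    stop_pcitr("cross-validation needs at least 2 blocks", "pcitr_few_blocks")
  }
  global_mask <- if (!refit_features) select_features(ts, labels, alpha)
  fold_res <- purrr::map(blocks, function(b) {
    tr_idx <- ts$block != b
    tr_lab <- labels
    tr_lab$label[!tr_idx] <- NA_character_
    tr_ts <- roi_timeseries(ts$data[, tr_idx, drop = FALSE], ts$tr_seconds,
                            ts$scan_onsets[tr_idx], ts$block[tr_idx],
                            ts$phase)
    tr_lab_f <- labels[tr_idx, ]
    if (!all(classes %in% tr_lab_f$label[!is.na(tr_lab_f$label)])) {
      stop_pcitr(paste0("fold for block ", b, " is missing a class"),
                 "pcitr_empty_class")
    }
    mask <- if (refit_features) select_features(tr_ts, tr_lab_f, alpha)
            else global_mask
    model <- train_classifier(tr_ts, tr_lab_f, lambda, mask, classes)
    te_idx <- which(ts$block == b)
    te_ts <- roi_timeseries(ts$data[, te_idx, drop = FALSE], ts$tr_seconds,
                            ts$scan_onsets[te_idx], ts$block[te_idx],
                            ts$phase)
    ev <- decode(model, te_ts)
    ev$fold <- b
    ev$label <- labels$label[te_idx]
    ev
  })
  ev <- dplyr::bind_rows(fold_res)
  scored <- !is.na(ev$label)
  pred <- classes[max.col(as.matrix(ev[, classes]), ties.method = "first")]
  ev$correct <- NA
  ev$correct[scored] <- pred[scored] == ev$label[scored]
  fs <- scored & ev$label %in% c("face", "scene")
  folds <- dplyr::summarise(
    dplyr::group_by(ev[scored, ], .data$fold),
    accuracy = mean(.data$correct), .groups = "drop"
  )
  list(
    evidence = ev,
    accuracy = mean(ev$correct[scored]),
    accuracy_face_scene = mean(ev$correct[fs]),
    folds = folds
  )
}

#' Average evidence within trial windows
#'
#' Computes, for each trial and each half-open window `[a, b)` (seconds from
#' trial onset), the arithmetic mean of the per-scan evidence values whose
#' onsets fall in the window. The canonical windows are pre-switch
#' `[4, 12)` (4 scans), post-switch `[16, 20)` (2 scans) and probe
#' `[20, 24)` (2 scans), none shifted for hemodynamic lag.
#'
#' @param evidence Per-scan evidence tibble from [decode()].
#' @param trials Tibble with columns `trial_id`, `onset`, `duration` (and
#'   any id columns to carry through, e.g. `participant_id`).
#' @param windows Named list of `c(a, b)` windows; defaults to the design's.
#' @return A wide tibble, one row per trial: id columns then
#'   `<window>_face`, `<window>_scene`, `<window>_smf` means.
#' @export
window_average <- function(evidence, trials,
                           windows = experiment_design()$windows) {
  trials <- tibble::as_tibble(trials)
  stopifnot(all(c("trial_id", "onset", "duration") %in% names(trials)))
  for (wn in names(windows)) {
    w <- windows[[wn]]
    if (w[1] < 0 || w[2] > min(trials$duration)) {
      stop_pcitr(paste0("window '", wn, "' extends outside the trial"),
                 "pcitr_window_outside_trial")
    }
  }
  per_trial <- purrr::map(seq_len(nrow(trials)), function(i) {
    t0 <- trials$onset[i]
    row <- trials[i, setdiff(names(trials), c("onset", "duration"))]
    for (wn in names(windows)) {
      w <- windows[[wn]]
      sel <- evidence$onset >= t0 + w[1] & evidence$onset < t0 + w[2]
      if (!any(sel)) {
        stop_pcitr(paste0("no scans in window '", wn, "' of trial ",
                          trials$trial_id[i]), "pcitr_window_outside_trial")
      }
      row[[paste0(wn, "_face")]] <- mean(evidence$face[sel])
      row[[paste0(wn, "_scene")]] <- mean(evidence$scene[sel])
      row[[paste0(wn, "_smf")]] <- mean(evidence$scene_minus_face[sel])
    }
    row
  })
  dplyr::bind_rows(per_trial)
}
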