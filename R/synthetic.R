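#' Ground-truth configuration for synthetic studies
#'
#' Defines every parameter of the synthetic-study generator: the ROI signal
#' model (category templates over informative voxels, per-trial amplitude
#' mixtures, Gaussian voxel noise, hemodynamic lag), the true plasticity
#' curve linking summed learning-event evidence to recognition, and the
#' working-memory probe model. The defaults encode the canonical study
#' conditions: 21 participants, 36 switch trials each (756 pooled items),
#' scene-dominant pre-switch and face-dominant post-switch evidence
#' mixtures, and a U-shaped true curve.
#'
#' @param design An [experiment_design()].
#' @param n_participants Number of participants (default 21).
#' @param n_voxels ROI size (default 200).
#' @param n_informative Voxels carrying category signal (default 50; must
#'   not exceed `n_voxels`).
#' @param noise_sd Gaussian voxel noise SD (signal templates are unit-norm).
#' @param p1_amp `c(mean, sd)` of the phase 1 per-trial signal amplitude.
#' @param pre_mix,post_mix Per-trial amplitude distributions
#'   (`list(scene = c(mean, sd), face = c(mean, sd))`) for the pre- and
#'   post-switch periods; pre is scene-dominant and post face-dominant by
#'   default. Amplitudes are truncated at 0.
#' @param participant_sd SD of per-participant random offsets on the
#'   mixture means (between-subject heterogeneity for the bootstrap).
#' @param true_curve The ground-truth plasticity curve
#'   ([plasticity_curve()]); U-shaped by default.
#' @param beta0_mem Memory-model intercept (logit scale).
#' @param beta0_new Logit recognition strength of novel lure scenes (sets
#'   the false-alarm side of the ROC analysis).
#' @param response_noise SD of the latent-strength perturbation before
#'   quartile binning into the four graded responses.
#' @param gamma0,gamma1 Working-memory probe accuracy model
#'   `plogis(gamma0 + gamma1 * face_probe_evidence)`; `gamma1 >= 0`.
#' @param lag_p1,lag_p2 Hemodynamic lag (s) applied as an onset shift of
#'   the signal boxcar in phases 1 and 2. Phase 1 defaults to 6 s (matching
#'   the 6-s training label shift); phase 2 defaults to 4 s (matching the
#'   analysis windows, which start 4 s after their triggering events).
#' @param hrf `"shift"` (pure boxcar onset shift, default) or
#'   `"double_gamma"` (convolution with a canonical double-gamma response).
#' @param seed Master seed; all generator randomness derives substreams
#'   from it.
#' @return A `ground_truth_config` list.
#' @export
ground_truth_config <- function(design = experiment_design(),
                                n_participants = 21,
                                n_voxels = 200,
                                n_informative = 50,
                                noise_sd = 0.2,
                                p1_amp = c(mean = 1, sd = 0.15),
                                pre_mix = list(scene = c(mean = 1, sd = 0.25),
                                               face = c(mean = 0.3, sd = 0.25)),
                                post_mix = list(scene = c(mean = 0.3, sd = 0.25),
                                                face = c(mean = 1, sd = 0.25)),
                                participant_sd = 0.1,
                                true_curve = plasticity_curve(
                                  c(-1, -0.2, 0.2, 1),
                                  c(0.8, -0.8, -0.8, 0.8)
                                ),
                                beta0_mem = 0.5,
                                beta0_new = -1,
                                response_noise = 0.15,
                                gamma0 = 1.5,
                                gamma1 = 2,
                                lag_p1 = 6,
                                lag_p2 = 4,
                                hrf = c("shift", "double_gamma"),
                                seed = 1L) {
  hrf <- match.arg(hrf)
  if (n_informative > n_voxels) {
    stop_pcitr("n_informative must not exceed n_voxels", "pcitr_bad_config")
  }
  stopifnot(inherits(design, "experiment_design"), noise_sd >= 0,
            gamma1 >= 0, inherits(true_curve, "plasticity_curve"),
            lag_p1 %% design$tr_seconds == 0)
  structure(
    list(design = design, n_participants = n_participants,
         n_voxels = n_voxels, n_informative = n_informative,
         noise_sd = noise_sd, p1_amp = p1_amp, pre_mix = pre_mix,
         post_mix = post_mix, participant_sd = participant_sd,
         true_curve = true_curve, beta0_mem = beta0_mem,
         beta0_new = beta0_new,
         response_noise = response_noise, gamma0 = gamma0,
         gamma1 = gamma1, lag_p1 = lag_p1, lag_p2 = lag_p2, hrf = hrf,
         seed = seed),
    class = "ground_truth_config"
  )
}

# unit-norm category templates supported on the informative voxels
make_templates <- function(cfg) {
  with_stream_seed(cfg$seed, 1L, {
    idx <- seq_len(cfg$n_informative)
    tf <- ts <- numeric(cfg$n_voxels)
    tf[idx] <- rnorm(cfg$n_informative)
    ts[idx] <- rnorm(cfg$n_informative)
    list(face = tf / sqrt(sum(tf^2)), scene = ts / sqrt(sum(ts^2)),
         informative = idx)
  })
}

# canonical double-gamma hemodynamic response sampled on the TR grid,
# peak-normalized
hrf_double_gamma <- function(tr, length_s = 30) {
  t <- seq(0, length_s, by = tr)
  h <- stats::dgamma(t, 6, 1) - stats::dgamma(t, 16, 1) / 6
  h / max(h)
}

# place a per-scan neural amplitude timecourse onto the scan grid either by
# pure onset shift (already applied by the caller) or by double-gamma
# convolution within block
apply_hrf <- function(amp_by_scan, block, cfg) {
  if (cfg$hrf == "shift") return(amp_by_scan)
  kern <- hrf_double_gamma(cfg$design$tr_seconds)
  out <- numeric(length(amp_by_scan))
  for (b in unique(block)) {
    sel <- which(block == b)
    conv <- stats::convolve(amp_by_scan[sel], rev(kern), type = "open")
    out[sel] <- conv[seq_along(sel)]
  }
  out
}

#' Generate one participant's phase 1 data
#'
#' Emits an ROI timeseries for the phase 1 delayed-recognition task: each
#' trial's category template (face or scene), scaled by a per-trial
#' amplitude, is active over the target-plus-delay period and shifted by
#' the hemodynamic lag; Gaussian voxel noise is added everywhere. Also
#' returns the scan-aligned training labels: face/scene on the shifted
#' final-6-s delay window, rest subsampled per block from the shifted
#' intertrial intervals so all three classes have equal counts.
#'
#' @param cfg A [ground_truth_config()].
#' @param seed Seed for this participant's phase 1 randomness.
#' @param templates Optional precomputed templates (internal reuse).
#' @return A list: `ts` ([roi_timeseries()]), `labels` (scan-aligned label
#'   tibble), `events`, `amplitudes`.
#' @export
generate_phase1 <- function(cfg, seed = cfg$seed, templates = NULL) {
  stopifnot(inherits(cfg, "ground_truth_config"))
  d <- cfg$design
  tr <- d$tr_seconds
  if (is.null(templates)) templates <- make_templates(cfg)
  events <- design_events(d, "P1", seed = derive_seed(seed, 1L))
  block_len <- block_duration(d, "P1")
  onsets <- as.vector(vapply(seq_len(d$p1_blocks), function(b) {
    seq((b - 1) * block_len, b * block_len - tr, by = tr)
  }, numeric(block_len / tr)))
  block <- rep(seq_len(d$p1_blocks), each = block_len / tr)
  n_scans <- length(onsets)

  amps <- with_stream_seed(seed, 2L,
    pmax(rnorm(nrow(events), cfg$p1_amp["mean"], cfg$p1_amp["sd"]), 0))
  signal_amp <- matrix(0, 2, n_scans) # rows: scene, face neural amplitude
  active_len <- 1 + 7 # target + delay
  for (i in seq_len(nrow(events))) {
    a <- events$onset[i] + if (cfg$hrf == "shift") cfg$lag_p1 else 0
    sel <- which(onsets >= a & onsets < a + active_len)
    r <- if (events$trial_type[i] == "p1_scene") 1 else 2
    signal_amp[r, sel] <- signal_amp[r, sel] + amps[i]
  }
  signal_amp[1, ] <- apply_hrf(signal_amp[1, ], block, cfg)
  signal_amp[2, ] <- apply_hrf(signal_amp[2, ], block, cfg)
  data <- outer(templates$scene, signal_amp[1, ]) +
    outer(templates$face, signal_amp[2, ])
  if (cfg$noise_sd > 0) {
    data <- data + with_stream_seed(seed, 3L,
      matrix(rnorm(cfg$n_voxels * n_scans, 0, cfg$noise_sd),
             cfg$n_voxels, n_scans))
  }
  ts <- roi_timeseries(data, tr, onsets, block, phase = "P1")

  # training labels: category on the final train_window of the delay,
  # rest candidates on the intertrial blank, both hemodynamically shifted
  delay_end <- 1 + 7
  lab_events <- dplyr::bind_rows(
    tibble::tibble(
      onset = events$onset + delay_end - d$train_window_seconds,
      duration = d$train_window_seconds,
      label = ifelse(events$trial_type == "p1_scene", "scene", "face")
    ),
    tibble::tibble(
      onset = events$onset + delay_end + 2, # after the 2-s probe
      duration = 6,
      label = "rest"
    )
  )
  labels <- shift_labels(lab_events, onsets, d$label_shift_seconds, tr)
  labels <- match_rest_counts(labels, block, derive_seed(seed, 4L))
  list(ts = ts, labels = labels, events = events, amplitudes = amps)
}

# subsample rest-labeled scans within each block so that rest count equals
# the face (= scene) count in that block
match_rest_counts <- function(labels, block, seed) {
  lab <- labels$label
  withr::with_seed(seed, {
    for (b in unique(block)) {
      sel <- which(block == b)
      n_face <- sum(lab[sel] == "face", na.rm = TRUE)
      rest <- sel[!is.na(lab[sel]) & lab[sel] == "rest"]
      if (length(rest) > n_face) {
        drop <- sample(rest, length(rest) - n_face)
        lab[drop] <- NA_character_
      }
    }
  })
  labels$label <- lab
  labels
}

#' Generate one participant's phase 2 switch-trial data
#'
#' Each 28-s switch trial mixes both category templates. Per-trial
#' amplitudes for (scene, face) are drawn from the scene-dominant `pre_mix`
#' for the target-plus-delay period (0-12 s) and from the face-dominant
#' `post_mix` from the switch cue onward (12-28 s); the mixture boxcars are
#' shifted by the phase 2 hemodynamic lag. Only switch trials are emitted
#' (the downstream analyses use only switch trials).
#'
#' @inheritParams generate_phase1
#' @param participant_offset Additive offset on all mixture means for this
#'   participant (between-subject heterogeneity).
#' @return A list: `ts`, `trials` (tibble with `trial_id`, `block`,
#'   `onset`, `duration`, `scene_id`), `latent` (per-trial noise-free
#'   amplitudes and derived scene-face differences).
#' @export
generate_phase2_switch <- function(cfg, seed = cfg$seed,
                                   participant_offset = 0,
                                   templates = NULL) {
  stopifnot(inherits(cfg, "ground_truth_config"))
  d <- cfg$design
  tr <- d$tr_seconds
  if (is.null(templates)) templates <- make_templates(cfg)
  n_trials_block <- d$p2_switch_per_block
  trial_dur <- trial_duration("switch")
  block_len <- d$dummy_seconds_per_block + n_trials_block * trial_dur
  onsets <- as.vector(vapply(seq_len(d$p2_blocks), function(b) {
    seq((b - 1) * block_len, b * block_len - tr, by = tr)
  }, numeric(block_len / tr)))
  block <- rep(seq_len(d$p2_blocks), each = block_len / tr)
  n_scans <- length(onsets)

  trials <- tibble::tibble(
    block = rep(seq_len(d$p2_blocks), each = n_trials_block),
    onset = as.vector(vapply(seq_len(d$p2_blocks), function(b) {
      (b - 1) * block_len + d$dummy_seconds_per_block +
        trial_dur * (seq_len(n_trials_block) - 1)
    }, numeric(n_trials_block))),
    duration = trial_dur
  )
  trials$trial_id <- seq_len(nrow(trials))
  trials$scene_id <- sprintf("p2_scene_%03d", trials$trial_id)

  n <- nrow(trials)
  draw <- function(par, stream) {
    with_stream_seed(seed, stream,
      pmax(rnorm(n, par["mean"] + participant_offset, par["sd"]), 0))
  }
  s_pre <- draw(cfg$pre_mix$scene, 11L)
  f_pre <- draw(cfg$pre_mix$face, 12L)
  s_post <- draw(cfg$post_mix$scene, 13L)
  f_post <- draw(cfg$post_mix$face, 14L)

  lag <- if (cfg$hrf == "shift") cfg$lag_p2 else 0
  switch_at <- 4 + 8 # target + first delay
  signal_amp <- matrix(0, 2, n_scans)
  for (i in seq_len(n)) {
    t0 <- trials$onset[i]
    pre_sel <- which(onsets >= t0 + lag & onsets < t0 + switch_at + lag)
    post_sel <- which(onsets >= t0 + switch_at + lag &
                        onsets < t0 + trial_dur)
    signal_amp[1, pre_sel] <- signal_amp[1, pre_sel] + s_pre[i]
    signal_amp[2, pre_sel] <- signal_amp[2, pre_sel] + f_pre[i]
    signal_amp[1, post_sel] <- signal_amp[1, post_sel] + s_post[i]
    signal_amp[2, post_sel] <- signal_amp[2, post_sel] + f_post[i]
  }
  signal_amp[1, ] <- apply_hrf(signal_amp[1, ], block, cfg)
  signal_amp[2, ] <- apply_hrf(signal_amp[2, ], block, cfg)
  data <- outer(templates$scene, signal_amp[1, ]) +
    outer(templates$face, signal_amp[2, ])
  if (cfg$noise_sd > 0) {
    data <- data + with_stream_seed(seed, 15L,
      matrix(rnorm(cfg$n_voxels * n_scans, 0, cfg$noise_sd),
             cfg$n_voxels, n_scans))
  }
  latent <- tibble::tibble(
    trial_id = trials$trial_id,
    scene_amp_pre = s_pre, face_amp_pre = f_pre,
    scene_amp_post = s_post, face_amp_post = f_post,
    diff_pre = s_pre - f_pre, diff_post = s_post - f_post,
    face_probe = f_post
  )
  list(ts = roi_timeseries(data, tr, onsets, block, phase = "P2"),
       trials = trials, latent = latent)
}

#' Generate behavioral outcomes from latent evidence
#'
#' Applies the ground-truth plasticity curve to each trial's rescaled
#' pre- and post-switch learning events and sums the effects:
#' `p = plogis(beta0_mem + f(e_pre) + f(e_post))`. A latent strength
#' (`p` plus Gaussian response noise) is binned at fixed thresholds
#' 0.25/0.5/0.75 into the four graded recognition responses. Working-memory
#' probe accuracy is Bernoulli with success probability
#' `plogis(gamma0 + gamma1 * e_face_probe)`.
#'
#' @param cfg A [ground_truth_config()].
#' @param latent Tibble with columns `e_pre`, `e_post`, `e_face_probe`, all
#'   already rescaled to `[-1, 1]` by the caller (errors otherwise).
#' @param seed Seed.
#' @return `latent` extended with `p_mem`, `response`, `strength`,
#'   `wm_correct`.
#' @export
generate_behavior <- function(cfg, latent, seed = cfg$seed) {
  stopifnot(inherits(cfg, "ground_truth_config"))
  latent <- tibble::as_tibble(latent)
  ev <- c(latent$e_pre, latent$e_post, latent$e_face_probe)
  if (anyNA(ev)) stop_pcitr("missing latent evidence", "pcitr_missing_evidence")
  if (any(ev < -1 | ev > 1)) {
    stop_pcitr("latent evidence outside [-1, 1]; rescale before calling",
               "pcitr_domain")
  }
  f <- cfg$true_curve
  delta <- curve_eval(f, latent$e_pre) + curve_eval(f, latent$e_post)
  p <- plogis(cfg$beta0_mem + delta)
  n <- nrow(latent)
  s <- p + if (cfg$response_noise > 0) {
    with_stream_seed(seed, 21L, rnorm(n, 0, cfg$response_noise))
  } else 0
  resp <- cut(s, c(-Inf, 0.25, 0.5, 0.75, Inf),
              labels = c("sure_new", "unsure_new", "unsure_old", "sure_old"))
  wm_p <- plogis(cfg$gamma0 + cfg$gamma1 * latent$e_face_probe)
  wm <- with_stream_seed(seed, 22L, as.integer(runif(n) < wm_p))
  latent$p_mem <- p
  latent$response <- as.character(resp)
  latent$strength <- code_memory_strength(latent$response)
  latent$wm_correct <- wm
  latent
}

#' Generate a complete synthetic study
#'
#' Composes the phase 1, phase 2 and behavior generators over all
#' participants under one master seed (every stage draws from a documented
#' substream, so the whole study is reproducible and stages are mutually
#' independent). Latent scene-face differences are pooled over the whole
#' study and rescaled to `[-1, 1]` (pre and post pooled jointly; probe-face
#' separately) before the true curve is applied.
#'
#' @param cfg A [ground_truth_config()].
#' @return A `synthetic_study`: `participants` (list of per-participant
#'   `phase1`/`phase2` data), `trials` (pooled trial table with latent
#'   evidence, rescaled learning events and behavioral outcomes),
#'   `ground_truth` (config, templates, participant offsets). The latent
#'   columns exist for recovery tests; the analysis stages never read them.
#' @export
generate_dataset <- function(cfg = ground_truth_config()) {
  stopifnot(inherits(cfg, "ground_truth_config"))
  templates <- make_templates(cfg)
  offsets <- with_stream_seed(cfg$seed, 2L,
    rnorm(cfg$n_participants, 0, cfg$participant_sd))
  participants <- purrr::map(seq_len(cfg$n_participants), function(p) {
    list(
      participant_id = p,
      phase1 = generate_phase1(cfg, seed = derive_seed(cfg$seed, 100L + p),
                               templates = templates),
      phase2 = generate_phase2_switch(
        cfg, seed = derive_seed(cfg$seed, 200L + p),
        participant_offset = offsets[p], templates = templates
      )
    )
  })
  trials <- dplyr::bind_rows(purrr::map(participants, function(pp) {
    dplyr::bind_cols(
      tibble::tibble(participant_id = pp$participant_id),
      dplyr::left_join(pp$phase2$trials, pp$phase2$latent, by = "trial_id")
    )
  }))
  trials$item_id <- sprintf("s%02d_%s", trials$participant_id,
                            trials$scene_id)
  pooled <- rescale_evidence(c(trials$diff_pre, trials$diff_post))
  trials$e_pre <- pooled[seq_len(nrow(trials))]
  trials$e_post <- pooled[nrow(trials) + seq_len(nrow(trials))]
  trials$e_face_probe <- rescale_evidence(trials$face_probe)
  trials <- generate_behavior(cfg, trials, seed = derive_seed(cfg$seed, 3L))
  # novel lure scenes for the phase 3 recognition test (one per old item)
  n_new <- nrow(trials)
  s_new <- plogis(cfg$beta0_new) + if (cfg$response_noise > 0) {
    with_stream_seed(cfg$seed, 4L, rnorm(n_new, 0, cfg$response_noise))
  } else 0
  resp_new <- cut(s_new, c(-Inf, 0.25, 0.5, 0.75, Inf),
                  labels = c("sure_new", "unsure_new", "unsure_old",
                             "sure_old"))
  new_items <- tibble::tibble(
    item_id = sprintf("lure_%03d", seq_len(n_new)),
    response = as.character(resp_new),
    strength = code_memory_strength(as.character(resp_new))
  )
  structure(
    list(participants = participants, trials = trials,
         new_items = new_items,
         ground_truth = list(config = cfg, templates = templates,
                             participant_offsets = offsets)),
    class = "synthetic_study"
  )
}

#' @export
print.synthetic_study <- function(x, ...) {
  cfg <- x$ground_truth$config
  cat("<synthetic_study> ", cfg$n_participants, " participants, ",
      nrow(x$trials), " switch trials, ", cfg$n_voxels, " voxels (",
      cfg$n_informative, " informative), noise sd ", cfg$noise_sd,
      "\n", sep = "")
  invisible(x)
}

#' Write a study's ROI timeseries and trial tables to disk
#'
#' Matrices go to plain whitespace-delimited text with a JSON sidecar
#' header (TR, onsets, blocks); trial and item tables to tab-separated
#' files.
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (pp in study$participants) {
    for (ph in c("phase1", "phase2")) {
      ts <- pp[[ph]]$ts
      base <- file.path(dir, sprintf("sub%02d_%s", pp$participant_id, ph))
      utils::write.table(ts$data, paste0(base, "_bold.txt"),
                         row.names = FALSE, col.names = FALSE)
      jsonlite::write_json(
        list(tr_seconds = ts$tr_seconds, scan_onsets = ts$scan_onsets,
             block = ts$block, phase = ts$phase),
        paste0(base, "_bold.json"), digits = NA
      )
    }
  }
  readr::write_tsv(study$trials, file.path(dir, "trials.tsv"))
  invisible(dir)
}

#' Read an ROI timeseries written by [write_study()]
#'
#' @param base Path prefix (without `_bold.txt` / `_bold.json`).
#' @return A [roi_timeseries()].
#' @export
read_roi_timeseries <- function(base) {
  data <- as.matrix(utils::read.table(paste0(base, "_bold.txt")))
  hdr <- jsonlite::read_json(paste0(base, "_bold.json"),
                             simplifyVector = TRUE)
  roi_timeseries(unname(data), hdr$tr_seconds, hdr$scan_onsets, hdr$block,
                 hdr$phase)
}
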