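#' Canonical trial specifications
#'
#' The experiment has four trial types. Phase 1 delayed-recognition trials
#' (one face or one scene target) run target (1 s), delay (7 s), probe (2 s),
#' blank (6 s). Phase 2 trials present a face and a scene together: stay
#' trials run target (4 s), delay (8 s), probe (2 s), blank (6 s); switch
#' trials insert an additional 8 s retro-cue delay after the first delay,
#' during which attention switches from the scene to the face.
#'
#' @param trial_type One of `"p1_face"`, `"p1_scene"`, `"stay"`, `"switch"`.
#' @return A `trial_spec` object: phase, trial type, and an ordered named
#'   vector of segment durations in seconds.
#' @examples
#' trial_spec("switch")
#' trial_duration(trial_spec("stay"))
#' @export
trial_spec <- function(trial_type) {
  segs <- switch(trial_type,
    p1_face  = ,
    p1_scene = c(target = 1, delay = 7, probe = 2, blank = 6),
    stay     = c(target = 4, delay = 8, probe = 2, blank = 6),
    switch   = c(target = 4, delay = 8, switch_delay = 8, probe = 2, blank = 6),
    stop_pcitr(
      paste0("unknown trial type: '", trial_type, "'"),
      "pcitr_unknown_trial_type"
    )
  )
  structure(
    list(
      phase = if (startsWith(trial_type, "p1_")) "P1" else "P2",
      trial_type = trial_type,
      segment_durations = segs
    ),
    class = "trial_spec"
  )
}

#' Duration of a trial in seconds
#'
#' @param spec A [trial_spec()] object or a trial-type string.
#' @return Total duration in seconds (sum of segment durations).
#' @export
trial_duration <- function(spec) {
  if (is.character(spec)) spec <- trial_spec(spec)
  stopifnot(inherits(spec, "trial_spec"))
  sum(spec$segment_durations)
}

#' Experiment design parameters
#'
#' Encodes the scanning-session structure as data: phase 1 has four 20-trial
#' blocks (even face/scene split), phase 2 has six 18-trial blocks (12 stay,
#' 6 switch), every block is preceded by 20 s of dummy pulses, and the
#' repetition time (TR) is 2 s. Analysis windows are half-open `[a, b)`
#' intervals in seconds from trial onset, so the 4-12 s pre-switch window at
#' TR = 2 contains the four scans acquired at 4, 6, 8 and 10 s.
#'
#' @param tr_seconds Repetition time in seconds.
#' @param p1_blocks,p1_trials_per_block Phase 1 block structure.
#' @param p2_blocks,p2_trials_per_block Phase 2 block structure.
#' @param p2_stay_per_block,p2_switch_per_block Stay/switch counts per
#'   phase 2 block (2:1 ratio in the canonical design).
#' @param dummy_seconds_per_block Dummy-pulse lead-in per block.
#' @param windows Named list of half-open `[a, b)` analysis windows
#'   (seconds from trial onset): `pre_switch`, `post_switch`, `probe`.
#' @param label_shift_seconds Forward shift applied to training labels to
#'   account for hemodynamic lag.
#' @param train_window_seconds Length of the end-of-delay window whose scans
#'   are used as face/scene training exemplars.
#' @return An `experiment_design` list.
#' @examples
#' d <- experiment_design()
#' block_duration(d, "P1") # 340 s
#' session_scan_time(d)    # 3928 s
#' @export
experiment_design <- function(tr_seconds = 2,
                              p1_blocks = 4,
                              p1_trials_per_block = 20,
                              p2_blocks = 6,
                              p2_trials_per_block = 18,
                              p2_stay_per_block = 12,
                              p2_switch_per_block = 6,
                              dummy_seconds_per_block = 20,
                              windows = list(
                                pre_switch = c(4, 12),
                                post_switch = c(16, 20),
                                probe = c(20, 24)
                              ),
                              label_shift_seconds = 6,
                              train_window_seconds = 6) {
  stopifnot(
    tr_seconds > 0,
    p2_stay_per_block + p2_switch_per_block == p2_trials_per_block,
    p1_trials_per_block %% 2 == 0
  )
  for (w in windows) {
    stopifnot(length(w) == 2, w[1] < w[2],
              w[1] %% tr_seconds == 0, w[2] %% tr_seconds == 0)
  }
  structure(
    list(
      tr_seconds = tr_seconds,
      p1_blocks = p1_blocks,
      p1_trials_per_block = p1_trials_per_block,
      p2_blocks = p2_blocks,
      p2_trials_per_block = p2_trials_per_block,
      p2_stay_per_block = p2_stay_per_block,
      p2_switch_per_block = p2_switch_per_block,
      dummy_seconds_per_block = dummy_seconds_per_block,
      windows = windows,
      label_shift_seconds = label_shift_seconds,
      train_window_seconds = train_window_seconds
    ),
    class = "experiment_design"
  )
}

#' Duration of one scanning block
#'
#' Sum of the block's trial durations plus the dummy-pulse lead-in. In the
#' canonical design this reproduces the printed run lengths: 340 s
#' (5 min 40 s) for phase 1 and 428 s (7 min 8 s) for phase 2.
#'
#' @param design An [experiment_design()].
#' @param phase `"P1"` or `"P2"`.
#' @return Duration in seconds.
#' @export
block_duration <- function(design, phase) {
  stopifnot(inherits(design, "experiment_design"))
  phase <- match.arg(phase, c("P1", "P2"))
  trial_sum <- if (phase == "P1") {
    design$p1_trials_per_block * trial_duration("p1_face")
  } else {
    design$p2_stay_per_block * trial_duration("stay") +
      design$p2_switch_per_block * trial_duration("switch")
  }
  trial_sum + design$dummy_seconds_per_block
}

#' Total functional scanning time for phases 1 and 2
#'
#' @inheritParams block_duration
#' @return Seconds (3928 s = 65 min 28 s for the canonical design).
#' @export
session_scan_time <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  design$p1_blocks * block_duration(design, "P1") +
    design$p2_blocks * block_duration(design, "P2")
}

#' Per-class classifier training scan counts
#'
#' Face and scene exemplars are the scans from the final
#' `train_window_seconds` of each phase 1 delay period (after the
#' hemodynamic label shift); rest exemplars are subsampled from the
#' intertrial intervals to match the face/scene count within each block, so
#' all three classes contribute equally (120 scans each in the canonical
#' design).
#'
#' @inheritParams block_duration
#' @return A tibble with columns `label` and `n_scans`.
#' @export
training_label_counts <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  if (design$train_window_seconds %% design$tr_seconds != 0) {
    stop_pcitr("training window is not aligned to the TR grid",
               "pcitr_misaligned_window")
  }
  scans_per_trial <- design$train_window_seconds / design$tr_seconds
  n_face_trials <- design$p1_blocks * design$p1_trials_per_block / 2
  n <- n_face_trials * scans_per_trial
  tibble::tibble(
    label = c("face", "scene", "rest"),
    n_scans = as.integer(rep(n, 3))
  )
}

#' Build the phase 3 recognition-test roster
#'
#' Every phase 2 scene target that appeared exactly once during phase 2 is
#' eligible for the surprise recognition test: all switch-trial scenes (the
#' scene never reappears in a switch-trial probe stream) plus the
#' stay-trial scenes that did not reappear in their probe stream. An equal
#' number of novel lure scenes is drawn for the "new" list.
#'
#' @param p2_trials A data frame with one row per phase 2 trial and columns
#'   `scene_id`, `trial_type` (`"stay"`/`"switch"`), and `scene_probed`
#'   (logical; whether the scene target reappeared in the probe stream).
#' @param new_pool Optional character vector of unused scene ids to sample
#'   the new list from; defaults to generated lure ids.
#' @param seed Seed for the new-list draw.
#' @return A tibble with columns `scene_id`, `status` (`"old"`/`"new"`) and,
#'   for old items, the source `trial_type`.
#' @export
phase3_roster <- function(p2_trials, new_pool = NULL, seed = 1L) {
  p2_trials <- tibble::as_tibble(p2_trials)
  if (nrow(p2_trials) == 0) {
    return(tibble::tibble(scene_id = character(), status = character(),
                          trial_type = character()))
  }
  stopifnot(all(c("scene_id", "trial_type", "scene_probed") %in%
                  names(p2_trials)))
  if (anyDuplicated(p2_trials$scene_id)) {
    stop_pcitr("duplicate scene ids across phase 2 trials",
               "pcitr_duplicate_scene")
  }
  old <- dplyr::filter(
    p2_trials,
    .data$trial_type == "switch" |
      (.data$trial_type == "stay" & !.data$scene_probed)
  )
  n_old <- nrow(old)
  if (is.null(new_pool)) {
    new_pool <- sprintf("lure_scene_%03d", seq_len(n_old))
  }
  stopifnot(length(new_pool) >= n_old,
            !any(new_pool %in% p2_trials$scene_id))
  new_ids <- with_stream_seed(seed, 0L, sample(new_pool, n_old))
  dplyr::bind_rows(
    tibble::tibble(scene_id = old$scene_id, status = "old",
                   trial_type = old$trial_type),
    tibble::tibble(scene_id = new_ids, status = "new",
                   trial_type = NA_character_)
  )
}

#' Generate a trial roster (events table) for one phase
#'
#' Lays out trials sequentially within blocks after the dummy-pulse lead-in,
#' with trial types shuffled within block under a seeded RNG. The result is
#' a BIDS-events-like table (onsets in seconds, within-session global time).
#'
#' For phase 2, `scene_probed` marks the half of the stay trials whose scene
#' target reappears in the probe stream (switch-trial scenes never do).
#'
#' @inheritParams block_duration
#' @param phase `"P1"` or `"P2"`.
#' @param seed Seed for within-block trial-order shuffling.
#' @return A tibble with columns `onset`, `duration`, `trial_type`, `block`,
#'   `stimulus_id` (and `scene_probed` for phase 2).
#' @export
design_events <- function(design, phase, seed = 1L) {
  stopifnot(inherits(design, "experiment_design"))
  phase <- match.arg(phase, c("P1", "P2"))
  block_len <- block_duration(design, phase)
  n_blocks <- if (phase == "P1") design$p1_blocks else design$p2_blocks
  rows <- purrr::map(seq_len(n_blocks), function(b) {
    types <- if (phase == "P1") {
      rep(c("p1_face", "p1_scene"), design$p1_trials_per_block / 2)
    } else {
      rep(c("stay", "switch"),
          c(design$p2_stay_per_block, design$p2_switch_per_block))
    }
    types <- with_stream_seed(seed, b, sample(types))
    durs <- vapply(types, trial_duration, numeric(1))
    onsets <- (b - 1) * block_len + design$dummy_seconds_per_block +
      cumsum(c(0, head(durs, -1)))
    tibble::tibble(onset = onsets, duration = durs, trial_type = types,
                   block = b)
  })
  ev <- dplyr::bind_rows(rows)
  ev$stimulus_id <- sprintf("%s_%s_%03d", tolower(phase),
                            ifelse(ev$trial_type %in% c("stay", "switch"),
                                   "scene", sub("^p1_", "", ev$trial_type)),
                            seq_len(nrow(ev)))
  if (phase == "P2") {
    stay_idx <- which(ev$trial_type == "stay")
    probed <- with_stream_seed(seed, 999L,
                               sample(stay_idx, floor(length(stay_idx) / 2)))
    ev$scene_probed <- FALSE
    ev$scene_probed[probed] <- TRUE
  }
  ev
}

#' Serialize / deserialize an experiment design
#'
#' Designs round-trip through a flat JSON key/value file; windows are stored
#' as two-element arrays.
#'
#' @param design An [experiment_design()].
#' @param path File path.
#' @return `write_design()` returns `path` invisibly; `read_design()`
#'   returns an `experiment_design`.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "experiment_design"))
  jsonlite::write_json(unclass(design), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$windows <- lapply(raw$windows, as.numeric)
  do.call(experiment_design, raw)
}

#' Write an events table as tab-separated text
#'
#' @param events A tibble from [design_events()] (or compatible).
#' @param path File path.
#' @export
write_events <- function(events, path) {
  readr::write_tsv(events, path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
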