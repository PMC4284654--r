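#' Decode a synthetic study into per-item learning-event records
#'
#' Runs the full decoding stage for every participant: ANOVA feature
#' selection on all phase 1 labeled scans, training of the three detectors
#' (penalty `lambda`), continuous decoding of the phase 2 switch-trial
#' timeseries, and window averaging into pre-switch / post-switch / probe
#' evidence. Decoded evidence is joined with the behavioral outcomes to
#' give one row per scene item.
#'
#' @param study A `synthetic_study` from [generate_dataset()].
#' @param lambda L2 penalty (default 50).
#' @param alpha Feature-selection threshold (default 0.05).
#' @return A tibble, one row per item: ids, decoded window evidence
#'   (`pre_switch_*`, `post_switch_*`, `probe_*` for face/scene/smf),
#'   behavioral columns (`strength`, `response`, `wm_correct`).
#' @export
decode_study <- function(study, lambda = 50, alpha = 0.05) {
  stopifnot(inherits(study, "synthetic_study"))
  windows <- study$ground_truth$config$design$windows
  decoded <- purrr::map(study$participants, function(pp) {
    p1 <- pp$phase1
    mask <- select_features(p1$ts, p1$labels, alpha)
    model <- train_classifier(p1$ts, p1$labels, lambda, mask)
    ev <- decode(model, pp$phase2$ts)
    trials <- dplyr::mutate(pp$phase2$trials,
                            participant_id = pp$participant_id)
    window_average(ev, trials[, c("trial_id", "participant_id", "onset",
                                  "duration")], windows)
  })
  evidence <- dplyr::bind_rows(decoded)
  beh <- study$trials[, c("participant_id", "trial_id", "item_id",
                          "scene_id", "response", "strength", "wm_correct")]
  dplyr::left_join(beh, evidence, by = c("participant_id", "trial_id"))
}

#' Cross-validated decoding accuracy for every participant
#'
#' @param study A `synthetic_study`.
#' @param ... Passed to [crossvalidate()].
#' @return A tibble: `participant_id`, `accuracy`, `accuracy_face_scene`.
#' @export
crossvalidate_study <- function(study, ...) {
  stopifnot(inherits(study, "synthetic_study"))
  dplyr::bind_rows(purrr::map(study$participants, function(pp) {
    cv <- crossvalidate(pp$phase1$ts, pp$phase1$labels, ...)
    tibble::tibble(participant_id = pp$participant_id,
                   accuracy = cv$accuracy,
                   accuracy_face_scene = cv$accuracy_face_scene)
  }))
}

PCIT_VARIANTS <- c("combined", "pre_only", "post_only",
                   "post_partial_pre", "pre_partial_post")

# event-column spec per analysis variant; partialed variants add a
# residualized column first
variant_items <- function(items, variant,
                          pre = "pre_switch_smf", post = "post_switch_smf") {
  switch(variant,
    combined = list(items = items, events = c(pre, post)),
    pre_only = list(items = items, events = pre),
    post_only = list(items = items, events = post),
    post_partial_pre = {
      items$post_resid <- partial_out(items[[post]], items[[pre]])
      list(items = items, events = "post_resid")
    },
    pre_partial_post = {
      items$pre_resid <- partial_out(items[[pre]], items[[post]])
      list(items = items, events = "pre_resid")
    },
    stop_pcitr(paste("unknown analysis variant:", variant),
               "pcitr_bad_config")
  )
}

#' Validate and normalize a run configuration
#'
#' Fills documented defaults (lambda = 50, alpha = 0.05, 5000 curve
#' samples, 200 permutations, 200 bootstrap replicates, 1000
#' working-memory bootstrap resamples, all analysis variants) and reports
#' every violation at once; on any violation nothing is normalized.
#'
#' @param config A named list. Recognized fields: `mode`
#'   (`"synthetic"`/`"tables"`), `cfg` (a [ground_truth_config()];
#'   synthetic mode), `items_path` (TSV path; tables mode), `events`,
#'   `outcome`, `variants`, `n_samples`, `n_perm`, `n_boot`, `wm_boot`,
#'   `lambda`, `alpha`, `seed`, `out_dir`.
#' @return A list `list(config = <normalized>, errors = <character>)`;
#'   `errors` is empty when valid.
#' @export
validate_config <- function(config = list()) {
  defaults <- list(
    mode = if (!is.null(config$items_path)) "tables" else "synthetic",
    cfg = NULL, items_path = NULL,
    events = c("pre_switch_smf", "post_switch_smf"),
    outcome = "strength",
    variants = PCIT_VARIANTS,
    n_samples = 5000, n_perm = 200, n_boot = 200, wm_boot = 1000,
    lambda = 50, alpha = 0.05, seed = 1L, out_dir = NULL
  )
  cfg <- modifyList(defaults, config)
  errors <- character()
  if (!cfg$mode %in% c("synthetic", "tables")) {
    errors <- c(errors, paste("unknown mode:", cfg$mode))
  }
  if (!is.null(cfg$cfg) && !is.null(cfg$items_path)) {
    errors <- c(errors, "both input modes set: provide cfg or items_path, not both")
  }
  if (cfg$mode == "tables" && is.null(cfg$items_path)) {
    errors <- c(errors, "tables mode needs items_path")
  }
  if (cfg$mode == "synthetic" && is.null(cfg$cfg)) {
    cfg$cfg <- ground_truth_config(seed = cfg$seed)
  }
  if (!is.null(cfg$cfg) && !inherits(cfg$cfg, "ground_truth_config")) {
    errors <- c(errors, "cfg must be a ground_truth_config")
  }
  bad_var <- setdiff(cfg$variants, PCIT_VARIANTS)
  if (length(bad_var)) {
    errors <- c(errors, paste("unknown variant(s):",
                              paste(bad_var, collapse = ", ")))
  }
  if (cfg$lambda < 0) errors <- c(errors, "lambda must be non-negative")
  if (cfg$alpha <= 0 || cfg$alpha > 1) {
    errors <- c(errors, "alpha must be in (0, 1]")
  }
  for (fld in c("n_samples", "wm_boot")) {
    if (cfg[[fld]] < 1) errors <- c(errors, paste(fld, "must be >= 1"))
  }
  for (fld in c("n_perm", "n_boot")) {
    if (cfg[[fld]] < 0) errors <- c(errors, paste(fld, "must be >= 0"))
  }
  if (length(errors)) {
    return(list(config = config, errors = errors))
  }
  list(config = cfg, errors = character())
}

#' Run the full analysis pipeline
#'
#' Orchestrates generate (or load) -> decode -> behavioral coding -> curve
#' induction -> permutation / bootstrap for every requested analysis
#' variant, under one master seed with per-stage substreams. In synthetic
#' mode the study is generated from `config$cfg`; in tables mode per-item
#' records are read from `config$items_path` (tab-separated, with the event
#' and outcome columns named in the config) and the decoding stages are
#' skipped.
#'
#' @param config A configuration list; see [validate_config()].
#' @return A `pcitr_run` bundle: `config`, `cv` (decoding accuracy),
#'   `items`, `variants` (per variant: `fit`, `permutation`, `bootstrap`),
#'   `wm` (working-memory regressions), `auc`, `manifest`. If
#'   `config$out_dir` is set, tables and a JSON report are written there.
#' @export
run_study <- function(config = list()) {
  v <- validate_config(config)
  if (length(v$errors)) {
    stop_pcitr(paste0("invalid configuration:\n  ",
                      paste(v$errors, collapse = "\n  ")),
               "pcitr_bad_config")
  }
  cfg <- v$config
  if (cfg$mode == "synthetic") {
    study <- generate_dataset(cfg$cfg)
    cv <- crossvalidate_study(study, lambda = cfg$lambda, alpha = cfg$alpha)
    items <- decode_study(study, lambda = cfg$lambda, alpha = cfg$alpha)
    auc <- roc_auc(items$strength, study$new_items$strength)
    wm <- wm_regressions(items, n_boot = cfg$wm_boot,
                         seed = derive_seed(cfg$seed, 7L))
  } else {
    study <- NULL
    cv <- NULL
    items <- readr::read_tsv(cfg$items_path, show_col_types = FALSE)
    auc <- NULL
    wm <- NULL
  }
  items <- build_supersubject(items)
  variants <- purrr::map(stats::setNames(cfg$variants, cfg$variants),
                         function(vn) {
    vi <- variant_items(items, vn, pre = cfg$events[1],
                        post = cfg$events[length(cfg$events)])
    fit <- pcit(vi$items, events = vi$events, outcome = cfg$outcome,
                n_samples = cfg$n_samples, seed = derive_seed(cfg$seed, 5L))
    perm <- if (cfg$n_perm > 0) {
      permutation_test(vi$items, events = vi$events, outcome = cfg$outcome,
                       n_samples = cfg$n_samples, n_perm = cfg$n_perm,
                       seed = derive_seed(cfg$seed, 6L))
    }
    boot <- if (cfg$n_boot > 0) {
      bootstrap_reliability(vi$items, events = vi$events,
                            outcome = cfg$outcome,
                            n_samples = cfg$n_samples, n_boot = cfg$n_boot,
                            seed = derive_seed(cfg$seed, 8L))
    }
    list(fit = fit, permutation = perm, bootstrap = boot)
  })
  out <- structure(
    list(config = cfg, cv = cv, items = items, variants = variants,
         wm = wm, auc = auc,
         manifest = list(seed = cfg$seed,
                         package_version = as.character(
                           utils::packageVersion("pcitr")),
                         timestamp = format(Sys.time(), tz = "UTC"))),
    class = "pcitr_run"
  )
  if (!is.null(cfg$out_dir)) write_run(out, cfg$out_dir)
  out
}

# working-memory logistic regressions for each window x evidence measure
wm_regressions <- function(items, n_boot = 1000, seed = 1L) {
  combos <- tidyr::expand_grid(
    window = c("pre_switch", "post_switch", "probe"),
    measure = c("face", "scene", "smf")
  )
  purrr::pmap_dfr(combos, function(window, measure) {
    col <- paste0(window, "_", measure)
    fit <- wm_logistic(items[[col]], items$wm_correct, n_boot = n_boot,
                       seed = seed, predictor_name = col)
    glance(fit)
  })
}

#' @export
print.pcitr_run <- function(x, ...) {
  cat("pcitr pipeline run (", x$config$mode, " mode, seed ",
      x$config$seed, ")\n", sep = "")
  if (!is.null(x$cv)) {
    cat(sprintf("  decoding accuracy (face/scene, CV): %.1f%%\n",
                100 * mean(x$cv$accuracy_face_scene)))
  }
  for (vn in names(x$variants)) {
    v <- x$variants[[vn]]
    cat(sprintf("  %-18s log BF = %6.3f  chi2 = %6.2f (p = %.3g)",
                vn, v$fit$log_bayes_factor, v$fit$chi2_stat, v$fit$chi2_p))
    if (!is.null(v$permutation)) {
      cat(sprintf("  perm frac >= obs: %.3f", v$permutation$fraction_geq))
    }
    if (!is.null(v$bootstrap)) {
      cat(sprintf("  boot frac > 0: %.3f", v$bootstrap$fraction_positive))
    }
    cat("\n")
  }
  invisible(x)
}

# serialize a run bundle: TSV tables plus one JSON report (timestamps are
# isolated to the manifest so result files are diffable)
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(run$items, file.path(dir, "items.tsv"))
  if (!is.null(run$cv)) readr::write_tsv(run$cv, file.path(dir, "cv.tsv"))
  if (!is.null(run$wm)) readr::write_tsv(run$wm, file.path(dir, "wm.tsv"))
  report <- list(
    manifest = run$manifest,
    auc = run$auc,
    variants = purrr::map(run$variants, function(v) {
      out <- as.list(glance(v$fit))
      if (!is.null(v$permutation)) {
        out$permutation_fraction_geq <- v$permutation$fraction_geq
        out$permutation_null_log_bfs <- v$permutation$null_log_bfs
      }
      if (!is.null(v$bootstrap)) {
        out$bootstrap_fraction_positive <- v$bootstrap$fraction_positive
        out$bootstrap_log_bfs <- v$bootstrap$log_bfs
      }
      out
    })
  )
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  for (vn in names(run$variants)) {
    readr::write_tsv(tidy(run$variants[[vn]]$fit),
                     file.path(dir, paste0("posterior_", vn, ".tsv")))
  }
  invisible(dir)
}
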