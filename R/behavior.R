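#' Graded memory-strength coding
#'
#' Maps the four recognition responses onto an equally spaced `[0, 1]`
#' scale: sure old = 1, unsure old = 2/3, unsure new = 1/3, sure new = 0.
#' Values are exact thirds internally (the conventional 0.667/0.333 are
#' 3-decimal renderings), which keeps likelihood sums free of rounding
#' accumulation.
#'
#' @param response Character vector of responses: `"sure_old"`,
#'   `"unsure_old"`, `"unsure_new"`, `"sure_new"`.
#' @return Numeric strengths in `{0, 1/3, 2/3, 1}`.
#' @export
code_memory_strength <- function(response) {
  map <- c(sure_old = 1, unsure_old = 2 / 3, unsure_new = 1 / 3,
           sure_new = 0)
  bad <- setdiff(unique(response), names(map))
  if (length(bad)) {
    stop_pcitr(paste("unknown response label(s):", paste(bad, collapse = ", ")),
               "pcitr_unknown_response")
  }
  unname(map[response])
}

#' Recognition sensitivity as ROC area
#'
#' The probability that a randomly chosen old item receives a higher memory
#' strength than a randomly chosen new item, with ties counted 1/2 — the
#' Mann-Whitney formulation of the area under the ROC curve built from the
#' graded confidence scale.
#'
#' @param old_scores,new_scores Non-empty numeric score vectors.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(old_scores, new_scores) {
  if (length(old_scores) == 0 || length(new_scores) == 0) {
    stop_pcitr("old and new score lists must be non-empty", "pcitr_no_items")
  }
  n1 <- length(old_scores)
  n2 <- length(new_scores)
  r <- rank(c(old_scores, new_scores)) # mid-ranks handle ties as 1/2
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Working-memory probe logistic regression
#'
#' Fits accuracy on a single-trial evidence score by maximum-likelihood
#' logistic regression and attaches a seeded percentile bootstrap 95%
#' confidence interval over trials. Complete separation is reported with a
#' flag, not an error: the slope is capped at +/- `slope_cap` (the logistic
#' likelihood is flat beyond that scale).
#'
#' @param evidence Per-trial scalar evidence.
#' @param accuracy Per-trial binary outcome (0/1).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Bootstrap seed.
#' @param conf_level Confidence level (default 0.95).
#' @param slope_cap Documented bound applied under separation.
#' @param predictor_name Label carried into the result.
#' @return A `wm_logistic` object: `beta1`, `ci95`, `significant`
#'   (CI excludes 0), `separation`, `n_boot`.
#' @export
wm_logistic <- function(evidence, accuracy, n_boot = 1000, seed = 1L,
                        conf_level = 0.95, slope_cap = 30,
                        predictor_name = "evidence") {
  stopifnot(length(evidence) == length(accuracy))
  if (length(evidence) < 10) {
    stop_pcitr("need at least 10 trials", "pcitr_few_trials")
  }
  if (length(unique(accuracy)) < 2) {
    stop_pcitr("accuracy outcomes are all identical; slope is undefined",
               "pcitr_degenerate_outcome")
  }
  fit_slope <- function(ev, acc) {
    fit <- suppressWarnings(
      stats::glm(acc ~ ev, family = stats::binomial())
    )
    b <- unname(stats::coef(fit)[2])
    # complete separation: the MLE diverges; glm stalls with fitted
    # probabilities at the boundary
    probs <- stats::fitted(fit)
    sep <- !is.finite(b) || abs(b) > slope_cap ||
      (any(probs > 1 - 1e-8) && any(probs < 1e-8))
    if (sep && (!is.finite(b) || abs(b) > slope_cap)) {
      b <- sign(b) * slope_cap
    }
    list(beta1 = b, separation = sep)
  }
  obs <- fit_slope(evidence, accuracy)
  n <- length(evidence)
  boots <- with_stream_seed(seed, 0L, {
    vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, replace = TRUE)
      if (length(unique(accuracy[idx])) < 2 ||
          sd(evidence[idx]) < 1e-12) {
        return(NA_real_)
      }
      fit_slope(evidence[idx], accuracy[idx])$beta1
    }, numeric(1))
  })
  a <- (1 - conf_level) / 2
  ci <- unname(stats::quantile(boots, c(a, 1 - a), na.rm = TRUE))
  structure(
    list(beta1 = obs$beta1, ci95 = ci,
         significant = ci[1] > 0 || ci[2] < 0,
         separation = obs$separation,
         n_boot = n_boot, n_dropped = sum(is.na(boots)),
         predictor_name = predictor_name, seed = seed),
    class = "wm_logistic"
  )
}

#' @export
print.wm_logistic <- function(x, ...) {
  cat("Working-memory logistic regression (", x$predictor_name, ")\n",
      sep = "")
  cat(sprintf("  beta1 = %.3f [%.3f, %.3f]%s%s\n", x$beta1, x$ci95[1],
              x$ci95[2], if (x$significant) " *" else "",
              if (x$separation) " (separation; slope capped)" else ""))
  invisible(x)
}

#' @rdname wm_logistic
#' @param x A `wm_logistic` object.
#' @param ... Unused.
#' @export
glance.wm_logistic <- function(x, ...) {
  tibble::tibble(
    predictor = x$predictor_name,
    beta1 = x$beta1,
    conf_low = x$ci95[1],
    conf_high = x$ci95[2],
    significant = x$significant,
    separation = x$separation,
    n_boot = x$n_boot
  )
}
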