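#' Plot the induced plasticity curve
#'
#' Posterior mean curve with its 90% credible ribbon on the rescaled
#' evidence axis, annotated with the log Bayes factor.
#'
#' @param object A `pcit` fit.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pcit <- function(object, ...) {
  ggplot2::ggplot(object$posterior, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean), colour = "steelblue4",
                       linewidth = 1) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(
      x = "classifier evidence (rescaled)",
      y = "change in memory strength",
      title = "Induced plasticity curve (posterior mean, 90% band)",
      subtitle = sprintf("log Bayes factor = %.2f", object$log_bayes_factor)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a permutation null distribution
#'
#' @param object A `pcit_permutation` result.
#' @param ... Unused.
#' @return A ggplot: null log Bayes factors with the observed value marked.
#' @export
autoplot.pcit_permutation <- function(object, ...) {
  ggplot2::ggplot(tibble::tibble(log_bf = object$null_log_bfs),
                  ggplot2::aes(x = .data$log_bf)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed_log_bf,
                        colour = "firebrick", linewidth = 1) +
    ggplot2::labs(
      x = "log Bayes factor (permuted outcomes)", y = "count",
      title = "Permutation null of the log Bayes factor",
      subtitle = sprintf("observed = %.2f; fraction >= observed: %.3f",
                         object$observed_log_bf, object$fraction_geq)
    ) +
    ggplot2::theme_minimal()
}

#' Plot bootstrap reliability of the curve shape
#'
#' @param object A `pcit_bootstrap` result.
#' @param ... Unused.
#' @return A ggplot of the bootstrap log Bayes factor distribution.
#' @export
autoplot.pcit_bootstrap <- function(object, ...) {
  ggplot2::ggplot(tibble::tibble(log_bf = object$log_bfs),
                  ggplot2::aes(x = "", y = .data$log_bf)) +
    ggplot2::geom_violin(fill = "seagreen3", alpha = 0.5) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::stat_summary(fun = mean, geom = "point", size = 2,
                          colour = "white") +
    ggplot2::labs(
      x = NULL, y = "log Bayes factor (participant bootstrap)",
      title = "Population-level reliability of the curve shape",
      subtitle = sprintf("fraction of replicates with log BF > 0: %.2f",
                         object$fraction_positive)
    ) +
    ggplot2::theme_minimal()
}

#' Trial-averaged evidence timecourse plot
#'
#' Averages decoded evidence across trials at each within-trial scan onset
#' and plots the face, scene and scene-minus-face traces; with the
#' canonical design, scene evidence dominates before the switch cue and
#' face evidence after it.
#'
#' @param evidence Per-scan evidence tibble from [decode()].
#' @param trials Trial table with `onset` and `duration`.
#' @return A ggplot.
#' @export
plot_evidence_timecourse <- function(evidence, trials) {
  rel <- purrr::map_dfr(seq_len(nrow(trials)), function(i) {
    sel <- evidence$onset >= trials$onset[i] &
      evidence$onset < trials$onset[i] + trials$duration[i]
    dplyr::mutate(evidence[sel, ], rel_onset = .data$onset - trials$onset[i])
  })
  avg <- rel |>
    dplyr::group_by(.data$rel_onset) |>
    dplyr::summarise(face = mean(.data$face), scene = mean(.data$scene),
                     `scene - face` = mean(.data$scene_minus_face),
                     .groups = "drop") |>
    tidyr::pivot_longer(-"rel_onset", names_to = "trace",
                        values_to = "evidence")
  ggplot2::ggplot(avg, ggplot2::aes(x = .data$rel_onset,
                                    y = .data$evidence,
                                    colour = .data$trace)) +
    ggplot2::geom_line(linewidth = 1) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "time from trial onset (s)", y = "classifier evidence",
                  colour = NULL,
                  title = "Trial-averaged decoded evidence") +
    ggplot2::theme_minimal()
}
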