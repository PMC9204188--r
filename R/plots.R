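# ggplot2 displays for the result types.

#' @export
autoplot.dblkit_scores <- function(object, ...) {
  thr <- attr(object, "threshold")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$score,
                                            fill = .data$class)) +
    ggplot2::geom_histogram(bins = 50, boundary = 0) +
    ggplot2::scale_fill_manual(values = c(singlet = "grey60",
                                          doublet = "firebrick")) +
    ggplot2::labs(x = "doublet score", y = "droplets") +
    ggplot2::theme_minimal()
  if (is.numeric(thr) && length(thr) == 1 && is.finite(thr)) {
    p <- p + ggplot2::geom_vline(xintercept = thr, linetype = "dashed")
  }
  p
}

#' @export
autoplot.dblkit_metrics <- function(object, which = c("pr", "roc"), ...) {
  which <- match.arg(which)
  if (which == "pr") {
    ggplot2::ggplot(object$pr, ggplot2::aes(x = .data$recall,
                                            y = .data$precision)) +
      ggplot2::geom_step(direction = "hv") +
      ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
      ggplot2::labs(title = sprintf("AUPRC = %.3f", object$auprc)) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
      ggplot2::geom_line() +
      ggplot2::geom_abline(linetype = "dotted") +
      ggplot2::labs(title = sprintf("AUROC = %.3f", object$auroc)) +
      ggplot2::theme_minimal()
  }
}

#' @export
autoplot.dblkit_enrichment <- function(object, ...) {
  dat <- mutate(object,
                pair = sprintf("%s+%s", .data$cluster_a, .data$cluster_b))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$expected, y = .data$observed,
                                    label = .data$pair)) +
    ggplot2::geom_abline(linetype = "dotted") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "expected doublets (random pairing)",
                  y = "observed doublets") +
    ggplot2::theme_minimal()
}

#' Threshold-scan diagnostic plot
#'
#' Shows the misclassification rates and deviation penalty across candidate
#' thresholds, with the selected threshold marked.
#'
#' @param scores `dblkit_scores` result carrying a threshold `context`.
#' @return a ggplot object.
#' @export
plot_threshold_scan <- function(scores) {
  ctx <- attr(scores, "context")
  if (is.null(ctx)) abort("scores carry no threshold context")
  thr <- attr(scores, "threshold")
  long <- tidyr::pivot_longer(ctx, c("fnr", "fpr", "cost"),
                              names_to = "component")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = thr, linetype = "dashed") +
    ggplot2::labs(x = "candidate threshold", y = NULL) +
    ggplot2::theme_minimal()
}
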