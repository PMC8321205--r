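#' Plot the per-iteration metric distribution of a bootstrap run
#'
#' One panel of points per metric across bootstrap iterations, with the
#' aggregate mean marked, so the spread of the evaluation protocol is
#' visible at a glance.
#'
#' @param object An `lf_boot` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lf_boot
#' @export
autoplot.lf_boot <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tidy(object), cols = dplyr::any_of(c("tpr", "tnr", "ppv", "npv", "acc", "f1p", "f1n", "mcc")),
    names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.08, height = 0, alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 18, size = 3,
                          colour = "firebrick") +
    ggplot2::labs(x = NULL, y = "value",
                  title = "Bootstrap metric distribution",
                  subtitle = "points: iterations; diamond: mean") +
    ggplot2::ylim(min(0, min(long$value, na.rm = TRUE)), 1)
}

#' Plot the decision/score matrices behind one fused prediction
#'
#' Tile map of the classifier-by-feature score matrix, signed by the
#' decision (+1 melanoma / -1 not-melanoma), with the winning feature
#' column framed.
#'
#' @param object An `lf_fusion` object from [fuse()].
#' @param D,S The decision and score matrices that were fused.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_fusion <- function(object, D, S, ...) {
  D <- as.matrix(D); S <- as.matrix(S)
  df <- tibble(
    classifier = rep(rownames(D) %||% paste0("c", seq_len(nrow(D))), ncol(D)),
    feature = rep(colnames(D) %||% paste0("f", seq_len(ncol(D))), each = nrow(D)),
    decision = factor(c(D), levels = c(-1, 1), labels = c("not-melanoma", "melanoma")),
    score = c(S)
  )
  win <- (colnames(D) %||% paste0("f", seq_len(ncol(D))))[object$winning_feature]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$feature, y = .data$classifier)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$decision, alpha = .data$score),
                       colour = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$score)), size = 3) +
    ggplot2::scale_fill_manual(values = c("not-melanoma" = "steelblue",
                                          "melanoma" = "firebrick")) +
    ggplot2::scale_alpha(range = c(0.25, 1), guide = "none") +
    ggplot2::labs(title = sprintf("Fused decision: %+d @ %.3f (winner: %s)",
                                  object$final_label, object$final_score, win))
}

#' @importFrom rlang .data
NULL
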