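#' Positional variance heatmap
#'
#' Renders one subtype's positional variance matrix — the posterior
#' probability that each z-score event occupies each stage — as a tile
#' heatmap, events on the vertical axis ordered by their maximum-likelihood
#' position.
#'
#' @param pv a [positional_variance()] object.
#' @param subtype subtype index or name.
#' @return a ggplot object.
#' @export
plot_positional_variance <- function(pv, subtype = 1) {
  P <- pv[[subtype]]
  ml_pos <- apply(P, 1L, which.max)
  ev <- factor(rownames(P), levels = rownames(P)[order(ml_pos,
                                                       decreasing = TRUE)])
  df <- data.frame(
    event = rep(ev, times = ncol(P)),
    stage = rep(seq_len(ncol(P)), each = nrow(P)),
    prob = as.vector(P))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$event,
                                   fill = .data$prob)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1), name = "P(event at stage)") +
    ggplot2::labs(x = "stage", y = NULL,
                  title = paste0("Positional variance: ",
                                 names(pv)[if (is.numeric(subtype)) subtype
                                           else match(subtype, names(pv))])) +
    ggplot2::theme_minimal(base_size = 9)
}

#' Baseline vs follow-up stage scatter
#'
#' @param report a [consistency()] report.
#' @return a ggplot object; points on or above the identity line progressed
#'   or held their stage.
#' @export
plot_stage_progression <- function(report) {
  df <- report$stage_pairs
  ggplot2::ggplot(df, ggplot2::aes(x = .data$baseline_stage,
                                   y = .data$followup_stage,
                                   colour = .data$interval_years)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_viridis_c(name = "interval (y)") +
    ggplot2::labs(x = "baseline stage", y = "follow-up stage") +
    ggplot2::theme_minimal(base_size = 10)
}
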