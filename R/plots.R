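#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_boxplot labs
#'   scale_x_continuous theme_minimal
NULL

#' Plot simulated pulse trajectories
#'
#' One line per decay rate; the legend is ordered from least to most stable.
#'
#' @param object A `kin_trajectories` tibble from [run_figure1_simulation()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot kin_trajectories
#' @export
autoplot.kin_trajectories <- function(object, ...) {
  df <- as_tibble(object)
  df$t_half <- factor(
    sprintf("alpha = %g (T1/2 = %.2f h)", df$alpha, log(2) / df$alpha),
    levels = unique(sprintf("alpha = %g (T1/2 = %.2f h)",
                            sort(unique(df$alpha), decreasing = TRUE),
                            log(2) / sort(unique(df$alpha), decreasing = TRUE)))
  )
  ggplot(df, aes(x = .data$time_h, y = .data$level, colour = .data$t_half)) +
    geom_line() +
    labs(x = "time after stimulation (h)", y = "mRNA level (a.u.)",
         colour = NULL) +
    theme_minimal()
}

#' Plot mean normalised profiles of kinetic clusters
#'
#' @param object A `kinetic_clusters` tibble from [kinetic_clusters()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot kinetic_clusters
#' @export
autoplot.kinetic_clusters <- function(object, ...) {
  df <- as_tibble(object)
  df$cluster <- factor(
    sprintf("%g h (n = %d)", df$response_time, df$n_genes),
    levels = unique(sprintf("%g h (n = %d)", df$response_time, df$n_genes))
  )
  ggplot(df, aes(x = .data$time_h, y = .data$mean_profile, colour = .data$cluster)) +
    geom_line() +
    labs(x = "time after stimulation (h)",
         y = "mean normalised log2 fold change",
         colour = "first crossing") +
    theme_minimal()
}

#' Box plot of atlas half-lives by kinetic cluster
#'
#' @param rt Response-time table from [assign_response_time()].
#' @param atlas Half-life atlas tibble.
#' @return A ggplot object.
#' @export
plot_half_life_by_cluster <- function(rt, atlas) {
  resp <- rt[rt$direction != "none", , drop = FALSE]
  idx <- match(tolower(resp$gene_id), tolower(atlas$gene_id))
  resp <- resp[!is.na(idx), , drop = FALSE]
  resp$t_half_hours <- atlas$t_half_hours[idx[!is.na(idx)]]
  resp$cluster <- factor(resp$response_time)
  ggplot(resp, aes(x = .data$cluster, y = .data$t_half_hours)) +
    geom_boxplot(outlier.size = 0.4) +
    ggplot2::scale_y_log10() +
    labs(x = "response time (h)", y = "half-life (h, log scale)") +
    theme_minimal()
}

#' @export
ggplot2::autoplot
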