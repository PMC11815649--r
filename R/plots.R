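#' @import ggplot2
NULL

#' Plot deconvolved channel abundances
#'
#' Bar chart of the solved channel abundances of one PSM.
#'
#' @param object A `channel_fit` from [solve_channels()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.channel_fit <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = factor(.data$channel, levels = .data$channel),
                 y = .data$abundance)) +
    geom_col(fill = "steelblue") +
    labs(x = "complement channel", y = "abundance (ion units)",
         subtitle = sprintf("residual %.3g, total S/N %.3g",
                            object$residual, object$total_sn)) +
    theme_minimal()
}

#' Plot clustered protein trajectories
#'
#' Member trajectories (thin) and cluster centers (thick) per cluster panel,
#' on the fractional profile scale used for clustering.
#'
#' @param object An `hkmeans_fit` from [hkmeans_cluster()].
#' @param max_lines Maximum member trajectories drawn per cluster.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hkmeans_fit <- function(object, max_lines = 50, ...) {
  m <- object$data
  stages <- colnames(m)
  long <- as_tibble(m, rownames = "protein") |>
    left_join(object$clusters, by = "protein") |>
    group_by(.data$cluster) |>
    filter(row_number() <= max_lines) |>
    ungroup() |>
    tidyr::pivot_longer(dplyr::all_of(stages),
                        names_to = "stage", values_to = "value") |>
    mutate(stage = match(.data$stage, stages))
  centers <- as_tibble(object$centers) |>
    mutate(cluster = row_number()) |>
    tidyr::pivot_longer(dplyr::all_of(stages),
                        names_to = "stage", values_to = "value") |>
    mutate(stage = match(.data$stage, stages))
  ggplot(long, aes(.data$stage, .data$value, group = .data$protein)) +
    geom_line(alpha = 0.2, linewidth = 0.3) +
    geom_line(data = centers, aes(group = NULL), color = "firebrick",
              linewidth = 1) +
    facet_wrap(~cluster) +
    labs(x = "stage", y = "fractional signal") +
    theme_minimal()
}

#' Reporter versus complement interference comparison
#'
#' For a simulated run, compares a channel-pair ratio measured from
#' reporter ions (interference-prone) and from deconvolved complement
#' clusters (interference-free) against the design value.
#'
#' @param sim A `tmt_sim` from [simulate_interference_sample()].
#' @param quant Output of [quantify_psms()] on the same run.
#' @param num,den Channel names of the ratio (default `"c4"` / `"c2"`).
#' @return A ggplot.
#' @export
plot_interference_comparison <- function(sim, quant, num = "c4", den = "c2") {
  rep_ratio <- vapply(seq_len(nrow(sim$spectra)), function(i) {
    r <- quantify_reporters(sim$spectra$peaks[[i]], sim$channels)
    r[[num]] / r[[den]]
  }, numeric(1))
  df <- bind_rows(
    tibble(method = "reporter ions",
           ratio = rep_ratio[match(quant$scan, sim$spectra$scan)]),
    tibble(method = "complement ions", ratio = quant[[num]] / quant[[den]])
  ) |> filter(is.finite(.data$ratio))
  truth <- sim$truth[[paste0("truth_", num)]][1] /
    sim$truth[[paste0("truth_", den)]][1]
  ggplot(df, aes(.data$method, .data$ratio)) +
    geom_boxplot(outlier.alpha = 0.3) +
    geom_hline(yintercept = truth, linetype = 2, color = "firebrick") +
    labs(y = sprintf("measured %s:%s ratio", num, den), x = NULL) +
    theme_minimal()
}
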