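# ggplot2 autoplot methods for the main result types.

#' @export
autoplot.growth_curve <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble(n = object$n, pan = object$pan_mean, core = object$core_mean,
           pan_sd = object$pan_sd, core_sd = object$core_sd),
    cols = c("pan", "core"), names_to = "curve", values_to = "families")
  df$sd <- ifelse(df$curve == "pan", df$pan_sd, df$core_sd)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$families,
                                   colour = .data$curve)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$families - .data$sd,
                                      ymax = .data$families + .data$sd,
                                      fill = .data$curve),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "accessions added", y = "gene families",
                  title = "Pan- and core-genome growth") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.window_stats <- function(object, statistic = "pi_ratio", ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = (.data$start + .data$end) / 2,
                               y = .data[[statistic]])) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = statistic) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.assoc_result <- function(object, p_line = NULL, ...) {
  df <- object %>%
    arrange(match(.data$chrom, unique(.data$chrom)), .data$pos) %>%
    mutate(logp = -log10(.data$p))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$logp,
                                        colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.6, na.rm = TRUE) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (bp)", y = expression(-log[10](italic(p)))) +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
  if (!is.null(p_line)) {
    p <- p + ggplot2::geom_hline(yintercept = -log10(p_line),
                                 linetype = "dashed")
  }
  p
}

#' @export
autoplot.prediction_report <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$r)) +
    ggplot2::geom_histogram(bins = 20, na.rm = TRUE) +
    ggplot2::labs(x = "Pearson r (held-out)", y = "replicates",
                  title = "Genomic-prediction precision") +
    ggplot2::theme_minimal()
}
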