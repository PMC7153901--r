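#' Plot genotype intensity profiles along the gonad axis
#'
#' Mean +/- SD per cell diameter, one colour per genotype: the standard
#' presentation of distal-proximal accumulation profiles.
#'
#' @param summary A `profile_summary` tibble (see [summarize_profiles()]).
#' @param ribbon Draw the SD as a ribbon instead of error bars?
#' @return A ggplot object.
#' @export
plot_profiles <- function(summary, ribbon = TRUE) {
  stopifnot(is.data.frame(summary),
            all(c("genotype", "cd", "mean", "sd") %in% names(summary)))
  ylab <- if (identical(summary$state[1], "normalized")) {
    "level (% of control peak)"
  } else "fluorescence intensity (AU)"
  p <- ggplot2::ggplot(summary, ggplot2::aes(
    x = .data$cd, y = .data$mean,
    colour = .data$genotype, fill = .data$genotype))
  p <- if (ribbon) {
    p + ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd),
                             alpha = 0.2, colour = NA)
  } else {
    p + ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                            ymax = .data$mean + .data$sd),
                               width = 0.3)
  }
  p + ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "cell diameters from distal tip", y = ylab) +
    ggplot2::theme_classic()
}

#' Plot a spatial mRNA density profile
#'
#' Per-cd mean focus count (+/- SD) across germlines, with the two
#' comparison windows shaded.
#'
#' @param density A `foci_density` from [foci_density_summary()].
#' @return A ggplot object.
#' @export
plot_foci_density <- function(density) {
  stopifnot(inherits(density, "foci_density"))
  s <- density$summary
  shade <- tibble::tibble(
    xmin = vapply(density$windows, min, numeric(1)) - 0.5,
    xmax = vapply(density$windows, max, numeric(1)) + 0.5,
    window = c("window 1", "window 2"))
  ggplot2::ggplot(s, ggplot2::aes(x = .data$cd, y = .data$mean)) +
    ggplot2::geom_rect(data = shade,
                       ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                    ymin = -Inf, ymax = Inf,
                                    fill = .data$window),
                       alpha = 0.12, inherit.aes = FALSE) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = pmax(.data$mean - .data$sd, 0),
                                        ymax = .data$mean + .data$sd),
                           width = 0.3) +
    ggplot2::labs(x = "cell diameters from distal tip",
                  y = "smFISH foci per cd",
                  subtitle = sprintf("window comparison: p = %.3g (%s)",
                                     density$comparison$p_value,
                                     density$comparison$tier)) +
    ggplot2::theme_classic()
}

#' Volcano-style view of a differential expression table
#'
#' log2 fold change vs -log10 FDR with the filtering thresholds drawn, and
#' genes passing [filter_regulated()] highlighted.
#'
#' @param table A [de_table()] result.
#' @param direction,fc_min,fdr_max,cpm_min Passed to [filter_regulated()].
#' @return A ggplot object.
#' @export
plot_de <- function(table, direction = "up", fc_min = 2.0, fdr_max = 0.05,
                    cpm_min = 2.0) {
  hits <- filter_regulated(table, direction, fc_min, fdr_max, cpm_min)
  df <- dplyr::mutate(table, regulated = .data$gene_id %in% hits)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(.data$fdr),
                                   colour = .data$regulated)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * log2(fc_min),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(fdr_max), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 FDR") +
    ggplot2::theme_classic()
}
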