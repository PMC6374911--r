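#' Plot a methylation profile curve
#'
#' Mean level per bin with a `mean +/- SEM` ribbon; gene-scaled curves
#' are drawn over the upstream/body/downstream bins, one line per group.
#'
#' @param object a `profile_curve`.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.profile_curve <- function(object, ...) {
  df <- as_tibble(object)
  if (identical(attr(object, "anchor_mode"), "tss_tes_scaled")) {
    p <- ggplot(df, aes(x = .data$bin, y = .data$mean,
                        colour = if ("group" %in% names(df)) .data$group else NULL))
    if ("group" %in% names(df)) {
      p <- p + aes(group = .data$group) + labs(colour = "group")
    }
    fb <- attr(object, "flank_bins")
    bb <- attr(object, "body_bins")
    p +
      geom_vline(xintercept = c(fb + 0.5, fb + bb + 0.5), linetype = 3) +
      geom_line(na.rm = TRUE) +
      labs(x = "scaled position (upstream | TSS..TES | downstream)",
           y = "methylation level") +
      theme_minimal()
  } else {
    ggplot(df, aes(x = .data$offset_mid, y = .data$mean)) +
      geom_ribbon(aes(ymin = .data$mean - .data$sem,
                      ymax = .data$mean + .data$sem),
                  alpha = 0.25, na.rm = TRUE) +
      geom_line(na.rm = TRUE) +
      labs(x = "distance from anchor centre (bp)", y = "methylation level") +
      theme_minimal()
  }
}

#' Plot a normalised DMS frequency curve
#'
#' @param object a `frequency_curve`.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.frequency_curve <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$offset_mid, y = .data$normalized)) +
    geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    geom_line(na.rm = TRUE) +
    labs(x = "distance from anchor centre (bp)",
         y = "DMS frequency / genome average") +
    theme_minimal()
}

#' Dot plot of enrichment results
#'
#' Log2 odds ratio per label, point size by -log10 p.
#'
#' @param x enrichment tibble (label or cell_type/direction, odds_ratio, p).
#' @return a ggplot.
#' @export
plot_enrichment <- function(x) {
  df <- as_tibble(x)
  if (!"label" %in% names(df) && all(c("cell_type", "direction") %in% names(df))) {
    df$label <- paste(df$cell_type, df$direction)
  }
  ggplot(df, aes(x = log2(.data$odds_ratio), y = .data$label,
                 size = -log10(pmax(.data$p, 1e-300)))) +
    geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    geom_point(na.rm = TRUE) +
    labs(x = "log2 odds ratio", y = NULL, size = "-log10 p") +
    theme_minimal()
}

#' Module methylation profiles with a mean +/- sd band
#'
#' @param summary output of [module_profile_summary()].
#' @return a ggplot.
#' @export
plot_module_profiles <- function(summary) {
  df <- summary |> mutate(methylome = factor(.data$methylome,
                                             levels = unique(.data$methylome)))
  ggplot(df, aes(x = as.integer(.data$methylome), y = .data$mean)) +
    geom_ribbon(aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
                alpha = 0.25) +
    geom_line(linetype = 3) +
    facet_wrap(~module, labeller = label_both) +
    scale_x_continuous(breaks = seq_along(levels(df$methylome)),
                       labels = levels(df$methylome)) +
    labs(x = NULL, y = "methylation level") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 60, hjust = 1))
}
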