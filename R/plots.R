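#' Paired boxplots of encounter rates
#'
#' Reproduces the structure of the standard paired-concession figure:
#' boxplots of concession-level encounter rates by certification status,
#' grey lines joining the members of each pair, red points/lines for the
#' model-estimated marginal means, faceted by group when the rate table is
#' grouped.
#'
#' @param rates Concession-level rate table from [encounter_rate()].
#' @param contrasts Optional matching [certification_ratios()] table whose
#'   marginal means are overlaid in red.
#' @return A ggplot object.
#' @export
plot_rate_pairs <- function(rates, contrasts = NULL) {
  assert_columns(rates, c("status", "pair_id", "encounter_rate", "group"), "rate table")
  p <- ggplot2::ggplot(rates, ggplot2::aes(x = .data$status, y = .data$encounter_rate)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_line(ggplot2::aes(group = .data$pair_id), colour = "grey60") +
    ggplot2::geom_point(colour = "grey30", size = 1.6) +
    ggplot2::labs(
      x = NULL, y = "Encounter rate (observations per camera-trap day)"
    ) +
    ggplot2::theme_minimal()
  if (dplyr::n_distinct(rates$group) > 1) {
    p <- p + ggplot2::facet_wrap(~group, scales = "free_y")
  }
  if (!is.null(contrasts)) {
    mm <- tibble::as_tibble(contrasts) |>
      tidyr::pivot_longer(
        c("mean_nonfsc", "mean_fsc"),
        names_to = "status", values_to = "mean_rate"
      ) |>
      dplyr::mutate(status = factor(
        ifelse(.data$status == "mean_fsc", "FSC", "non-FSC"),
        levels = c("non-FSC", "FSC")
      ))
    p <- p +
      ggplot2::geom_line(
        data = mm,
        ggplot2::aes(x = .data$status, y = .data$mean_rate, group = .data$group),
        colour = "red", linewidth = 0.8
      ) +
      ggplot2::geom_point(
        data = mm,
        ggplot2::aes(x = .data$status, y = .data$mean_rate),
        colour = "red", size = 2
      )
  }
  p
}

#' @describeIn plot_rate_pairs Forest-style plot of FSC:non-FSC ratios with
#'   adjusted significance annotations.
#' @param object A `ctp_contrasts` table.
#' @param ... Unused.
#' @method autoplot ctp_contrasts
#' @export
autoplot.ctp_contrasts <- function(object, ...) {
  d <- tibble::as_tibble(object) |>
    dplyr::mutate(
      lo = .data$ratio - 1.96 * .data$ratio_se,
      hi = .data$ratio + 1.96 * .data$ratio_se,
      sig = dplyr::case_when(
        .data$p.adjusted < 0.001 ~ "***",
        .data$p.adjusted < 0.01 ~ "**",
        .data$p.adjusted < 0.05 ~ "*",
        TRUE ~ ""
      )
    )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ratio, y = .data$group)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$lo, xmax = .data$hi), height = 0.15
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(
      ggplot2::aes(label = .data$sig), nudge_y = 0.25, size = 5
    ) +
    ggplot2::labs(
      x = "FSC : non-FSC encounter-rate ratio", y = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_rate_pairs Overview panel for a full result bundle: the
#'   paired rate plot for one grouping level with model means overlaid.
#' @param level Grouping level to draw (`"all"`, `"body_mass_class"`,
#'   `"iucn"` or `"taxon"`).
#' @method autoplot ctp_results
#' @export
autoplot.ctp_results <- function(object, level = "body_mass_class", ...) {
  level <- match.arg(level, analysis_levels)
  plot_rate_pairs(
    object$rates[[paste0(level, "_concession")]],
    object$ratios[[level]]
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
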