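# ggplot2 visualisations for the main result types.

#' @importFrom ggplot2 ggplot aes geom_rect geom_col geom_boxplot geom_step
#'   geom_vline labs theme_minimal facet_wrap autoplot scale_fill_brewer
#' @export
ggplot2::autoplot

#' Ideogram of a homology map
#'
#' Each target chromosome is drawn as a bar of its ordered reference-unit
#' segments (equal widths for structure-only maps), the standard way gross
#' genomic structure against a reference karyotype is displayed.
#'
#' @param object A `karyo_homology_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.karyo_homology_map <- function(object, ...) {
  d <- as_tibble(object) %>%
    group_by(.data$tgt_chrom) %>%
    mutate(
      seg = row_number(),
      x0 = if (all(is.na(.data$tgt_start))) .data$seg - 1
           else .data$tgt_start / 1e6,
      x1 = if (all(is.na(.data$tgt_start))) .data$seg
           else .data$tgt_end / 1e6
    ) %>%
    ungroup()
  ggplot(d, aes(xmin = .data$x0, xmax = .data$x1, ymin = 0, ymax = 1,
                fill = .data$ref_unit)) +
    geom_rect(colour = "grey20", linewidth = 0.2) +
    facet_wrap(~tgt_chrom, ncol = 4) +
    labs(x = if (all(is.na(d$tgt_start))) "segment" else "position (Mb)",
         y = NULL, fill = "reference\nunit") +
    theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Calibration curve: agreement vs spanning-pair threshold
#'
#' @param object A `karyo_calibration`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.karyo_calibration <- function(object, ...) {
  ggplot(object$candidates, aes(.data$threshold, .data$agreement)) +
    geom_step() +
    geom_vline(xintercept = object$threshold, linetype = 2, colour = "red") +
    labs(x = "spanning-pair threshold", y = "PCR agreement",
         title = paste0("selected threshold = ", object$threshold)) +
    theme_minimal()
}

#' CNE densities in EBRs vs flanking windows
#'
#' @param object A `karyo_flank_contrast`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.karyo_flank_contrast <- function(object, ...) {
  d <- object$per_window %>%
    mutate(role = factor(.data$role, levels = c("-2", "-1", "ebr", "+1", "+2")))
  ggplot(d, aes(.data$role, .data$density)) +
    geom_boxplot(outlier.size = 0.5) +
    labs(x = "window relative to EBR", y = "CNE base fraction") +
    theme_minimal()
}

#' Per-class mean CNE density from a window scan
#'
#' @param object A `karyo_window_scan`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.karyo_window_scan <- function(object, ...) {
  lev <- c("msHSB", "genome", "rest", "intrachromosomal", "fusion", "fission")
  d <- object$report %>%
    mutate(class = factor(.data$class, levels = intersect(lev, .data$class)))
  ggplot(d, aes(.data$class, .data$mean_density)) +
    geom_col(fill = "steelblue") +
    labs(x = NULL, y = "mean CNE density per window") +
    theme_minimal()
}
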