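# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a threshold calibration
#'
#' @param x A `karyo_calibration`.
#' @param ... Unused.
#' @return The candidate-threshold/agreement tibble.
#' @export
tidy.karyo_calibration <- function(x, ...) x$candidates

#' @rdname tidy.karyo_calibration
#' @export
glance.karyo_calibration <- function(x, ...) {
  tibble(threshold = x$threshold, agreement = x$agreement,
         n_tested = x$n_tested,
         agreement_rate = x$agreement / x$n_tested)
}

#' Tidy interchromosomal event counts
#'
#' @param x A `karyo_event_counts`.
#' @param ... Unused.
#' @return Per-target-chromosome junction counts.
#' @export
tidy.karyo_event_counts <- function(x, ...) x$junctions

#' @rdname tidy.karyo_event_counts
#' @export
glance.karyo_event_counts <- function(x, ...) {
  tibble(n_fusions = x$n_fusions, n_fissions = x$n_fissions,
         n_targets = x$n_targets, n_units = x$n_units,
         n_intact_units = x$n_intact_units,
         n_intact_homologs = x$n_intact_homologs,
         identity_holds = x$identity_holds)
}

#' Tidy an EBR flank contrast
#'
#' @param x A `karyo_flank_contrast`.
#' @param ... Unused.
#' @return Per-EBR, per-window densities.
#' @export
tidy.karyo_flank_contrast <- function(x, ...) x$per_window

#' @rdname tidy.karyo_flank_contrast
#' @export
glance.karyo_flank_contrast <- function(x, ...) {
  tests <- x$tests
  tibble(
    n_ebrs = x$n_ebrs,
    mean_ebr_density = x$summary$mean_density[x$summary$role == "ebr"],
    mean_flank_density = mean(x$summary$mean_density[x$summary$role != "ebr"]),
    kw_p = tests$p_value[tests$test == "kruskal_wallis"],
    mwu_p = tests$p_value[grepl("mann_whitney", tests$test)][1]
  )
}

#' Tidy a genome-wide window scan
#'
#' @param x A `karyo_window_scan`.
#' @param ... Unused.
#' @return The per-window tibble.
#' @export
tidy.karyo_window_scan <- function(x, ...) x$windows

#' @rdname tidy.karyo_window_scan
#' @export
glance.karyo_window_scan <- function(x, ...) {
  tidyr::pivot_wider(
    select(x$report, "class", "mean_density"),
    names_from = "class", values_from = "mean_density",
    names_prefix = "density_"
  )
}

#' Tidy an anchored assembly
#'
#' @param x A `karyo_assembly`.
#' @param ... Unused.
#' @return Placed PCFs with chromosome, rank, strand and length.
#' @export
tidy.karyo_assembly <- function(x, ...) {
  x$chromosomes %>%
    left_join(x$pcf_set$pcfs[c("pcf_id", "length")], by = "pcf_id")
}

#' @rdname tidy.karyo_assembly
#' @export
glance.karyo_assembly <- function(x, ...) {
  tibble(n_chromosomes = length(unique(x$chromosomes$chrom)),
         n_placed = nrow(x$chromosomes),
         n_oriented = sum(x$chromosomes$strand != "?"),
         n_disagreements = nrow(x$disagreements))
}
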