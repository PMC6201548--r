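# Curated homology-map fixtures for the three chromosome-level avian
# assemblies (ostrich, budgerigar, saker falcon) against the chicken
# reference. Maps are structure-only (no coordinates): per target
# chromosome, the ordered list of reference homolog units. Arm-level labels
# (4p, 4q) are stored raw and collapsed by the species' unit-set
# convention on load.

fixture_chain <- function(tgt, units, note = NA_character_) {
  tibble(tgt_chrom = tgt, tgt_start = NA_real_, tgt_end = NA_real_,
         ref_unit = units, ref_start = NA_real_, ref_end = NA_real_,
         strand = "+", note = note)
}

micro_unit_labels <- c("10", "11", "12", "13", "14", "15", "17", "18", "19",
                       "20", "21", "22", "23", "24", "26", "27", "28")

fixture_tables <- function(species) {
  switch(species,
    saker = bind_rows(
      fixture_chain("FCH1", "1"),
      fixture_chain("FCH2", "1"),
      fixture_chain("FCH3", c("2", "21", "23")),
      fixture_chain("FCH4", c("2", "28", "14", "12")),
      fixture_chain("FCH5", "3"),
      fixture_chain("FCH6", "3"),
      fixture_chain("FCH7", c("4q", "15", "19", "18")),
      fixture_chain("FCH8", "4p"),
      fixture_chain("FCH9", c("5", "10")),
      fixture_chain("FCH10", c("5", "20")),
      fixture_chain("FCH11", c("6", "17")),
      fixture_chain("FCH12", c("7", "13")),
      fixture_chain("FCH13", "8"),
      fixture_chain("FCH14", "9"),
      fixture_chain("FCH15", "11"),
      fixture_chain("FCH16", "22"),
      fixture_chain("FCH17", "24"),
      fixture_chain("FCH18", "26"),
      fixture_chain("FCH19", "27"),
      fixture_chain("FCHZ", "Z")
    ),
    budgerigar = bind_rows(
      fixture_chain("MUN1", "2"),
      fixture_chain("MUN2", c("3", "17")),
      fixture_chain("MUN3", "1"),
      fixture_chain("MUN4", c("5", "6", "7"),
                    note = "which GGA5/GGA7 arm pairs with which partner is uncertain"),
      fixture_chain("MUN5", c("8", "9", "4p")),
      fixture_chain("MUN6", "1"),
      fixture_chain("MUN7", "4q"),
      fixture_chain("MUN8", c("5", "7", "14"),
                    note = "which GGA5/GGA7 arm pairs with which partner is uncertain"),
      fixture_chain("MUN9", c("10", "12")),
      fixture_chain("MUN10", c("13", "20")),
      fixture_chain("MUN11", "11"),
      fixture_chain("MUN12", "15"),
      fixture_chain("MUN13", "18"),
      fixture_chain("MUN14", "19"),
      fixture_chain("MUN15", "21"),
      fixture_chain("MUN16", "22"),
      fixture_chain("MUN17", "23"),
      fixture_chain("MUN18", "24"),
      fixture_chain("MUN19", "26"),
      fixture_chain("MUN20", "27"),
      fixture_chain("MUN21", "28"),
      fixture_chain("MUNZ", "Z")
    ),
    ostrich = {
      singles <- c("1", "2", "3", "5", "6", "7", "8", "9", micro_unit_labels, "Z")
      bind_rows(
        purrr::map_dfr(singles, function(u) {
          fixture_chain(paste0("SCA", u), u)
        }),
        fixture_chain("SCA4", "4q"),
        fixture_chain("SCA4m", "4p",
                      note = "microchromosome homologous to the GGA4 p-arm")
      )
    },
    abort("unknown species (use ostrich, budgerigar or saker)")
  )
}

#' Load a packaged species homology-map fixture
#'
#' Structure-only homology maps for the three chromosome-level avian
#' assemblies versus the chicken reference. The saker and ostrich maps use
#' chicken units (homolog 4 = one unit); the budgerigar map uses ancestral
#' units (the GGA4 p-arm is its own microchromosome unit), matching the
#' conventions under which each species' published event counts are
#' stated. Attributes: `species`, `unit_set`, `micro_units` (the mapped
#' microchromosome homolog units under that convention).
#'
#' @param species `"ostrich"`, `"budgerigar"` or `"saker"`.
#' @param units Override the default unit-set convention
#'   (see [unit_set()]).
#' @return A `karyo_homology_map` tibble.
#' @examples
#' m <- load_fixture("saker")
#' count_interchromosomal_events(m)
#' @export
load_fixture <- function(species = c("ostrich", "budgerigar", "saker"),
                         units = NULL) {
  species <- match.arg(species)
  default_set <- switch(species, saker = "chicken", ostrich = "chicken",
                        budgerigar = "ancestral")
  if (is.null(units)) units <- default_set
  segs <- fixture_tables(species)
  m <- build_homology_map(segs, units = units)
  micro <- micro_unit_labels
  if (identical(units, "ancestral")) micro <- c("4p", micro)
  attr(m, "species") <- species
  attr(m, "micro_units") <- micro
  m
}

#' Fusion/intact breakdown of microchromosome units
#'
#' @param map A `karyo_homology_map`.
#' @param micro_units Character vector of microchromosome unit labels
#'   (defaults to the map's `micro_units` attribute).
#' @return List: `fused_units` (microchromosome units sharing a target
#'   chromosome with another unit), `intact_units` (constituting a whole
#'   target chromosome alone), `n_fused`, `n_intact`.
#' @export
microchromosome_summary <- function(map, micro_units = attr(map, "micro_units")) {
  if (is.null(micro_units)) abort("no microchromosome unit set available")
  map <- as_tibble(map)
  by_target <- map %>%
    group_by(.data$tgt_chrom) %>%
    summarise(units = list(unique(.data$ref_unit)), .groups = "drop")
  fused <- intact <- character(0)
  for (u in intersect(micro_units, unique(map$ref_unit))) {
    hosts <- by_target$units[vapply(by_target$units, function(x) u %in% x,
                                    logical(1))]
    if (any(vapply(hosts, length, integer(1)) > 1)) fused <- c(fused, u)
    if (length(hosts) == 1 && length(hosts[[1]]) == 1) intact <- c(intact, u)
  }
  list(fused_units = fused, intact_units = intact,
       n_fused = length(fused), n_intact = length(intact))
}
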