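# Anchoring predicted chromosome fragments to chromosomes with BAC/FISH
# observations: map BAC reference coordinates through the SF coordinate map
# onto PCF offsets, place each PCF on the chromosome where its BACs are
# seen, orient it by concordance of offsets with observed order, and export
# the chromosome-level assembly as AGP.

#' Map BAC markers onto PCFs
#'
#' Each BAC's reference position is located in a syntenic fragment, pushed
#' through to scaffold coordinates (strand-aware) and then to an offset on
#' the PCF containing that scaffold fragment. BACs falling in reference
#' space not covered by any SF are reported unmapped; a BAC interval
#' crossing an SF or PCF-member boundary is flagged.
#'
#' @param bacs Tibble `bac_id`, `ref_chrom`, `ref_pos` (or
#'   `ref_start`/`ref_end`, in which case the midpoint is used and spanning
#'   is checked).
#' @param pcf_set A `karyo_pcf_set` (carries its SF table).
#' @return Tibble `bac_id`, `pcf_id`, `offset`, `mapped`, `boundary`.
#' @export
locate_bacs_on_pcfs <- function(bacs, pcf_set) {
  sfs <- pcf_set$sfs
  members <- pcf_set$members
  bacs <- as_tibble(bacs)
  if (!"ref_pos" %in% names(bacs)) {
    bacs$ref_pos <- floor((bacs$ref_start + bacs$ref_end) / 2)
  }
  span_lo <- if ("ref_start" %in% names(bacs)) bacs$ref_start else bacs$ref_pos
  span_hi <- if ("ref_end" %in% names(bacs)) bacs$ref_end else bacs$ref_pos + 1

  out <- vector("list", nrow(bacs))
  for (i in seq_len(nrow(bacs))) {
    pos <- bacs$ref_pos[i]
    sf <- sfs[sfs$ref_chrom == bacs$ref_chrom[i] &
                sfs$ref_start <= pos & pos < sfs$ref_end, ]
    if (nrow(sf) == 0) {
      out[[i]] <- tibble(bac_id = bacs$bac_id[i], pcf_id = NA_character_,
                         offset = NA_real_, mapped = FALSE, boundary = FALSE)
      next
    }
    sf <- sf[1, ]
    boundary <- span_lo[i] < sf$ref_start || span_hi[i] > sf$ref_end
    s <- if (sf$strand == "+") sf$s_start + (pos - sf$ref_start)
         else sf$s_end - 1 - (pos - sf$ref_start)
    mem <- members[members$scaffold_id == sf$scaffold_id &
                     members$s_start <= s & s < members$s_end, ]
    if (nrow(mem) == 0) {
      out[[i]] <- tibble(bac_id = bacs$bac_id[i], pcf_id = NA_character_,
                         offset = NA_real_, mapped = FALSE, boundary = boundary)
      next
    }
    mem <- mem[1, ]
    off <- if (mem$strand == "+") mem$pcf_start + (s - mem$s_start)
           else mem$pcf_start + (mem$s_end - 1 - s)
    out[[i]] <- tibble(bac_id = bacs$bac_id[i], pcf_id = mem$pcf_id,
                       offset = off, mapped = TRUE, boundary = boundary)
  }
  bind_rows(out)
}

#' Anchor PCFs to chromosomes with FISH observations
#'
#' A PCF is placed on the chromosome where its BACs are observed and
#' oriented by comparing PCF offsets with the observed order: fully
#' concordant pairs give `+`, fully discordant give `-`, fewer than two
#' distinct offsets leave it `?` (unoriented). PCFs whose BACs hit several
#' chromosomes, or whose offset/order relation is non-monotone, are
#' recorded as disagreements and left unplaced. Placed PCFs are ordered
#' along each chromosome by the median observed index of their BACs.
#'
#' @param pcf_set A `karyo_pcf_set`.
#' @param bac_locations Output of [locate_bacs_on_pcfs()].
#' @param observations Tibble `bac_id`, `chrom`, `order_index` (FISH order
#'   per chromosome).
#' @return An object of class `karyo_assembly`: list with `chromosomes`
#'   (tibble `chrom`, `rank`, `pcf_id`, `strand`), `disagreements` (tibble
#'   `pcf_id`, `reason`), `unplaced` (PCF ids without observations), and
#'   the `pcf_set`.
#' @export
anchor <- function(pcf_set, bac_locations, observations) {
  observations <- as_tibble(observations)
  if (nrow(observations) == 0) abort("no FISH observations")
  unknown <- setdiff(observations$bac_id, bac_locations$bac_id)
  if (length(unknown) > 0) abort("observation references unknown BAC")
  d <- observations %>%
    left_join(filter(bac_locations, .data$mapped), by = "bac_id") %>%
    filter(!is.na(.data$pcf_id))

  placed <- list(); disagreements <- list()
  for (p in unique(d$pcf_id)) {
    dd <- filter(d, .data$pcf_id == p)
    if (length(unique(dd$chrom)) > 1) {
      disagreements[[length(disagreements) + 1]] <-
        tibble(pcf_id = p, reason = "multiple_chromosomes")
      next
    }
    dd <- distinct(dd, .data$offset, .data$order_index, .keep_all = TRUE)
    strand <- "?"
    if (length(unique(dd$offset)) >= 2) {
      ct <- stats::cor(dd$offset, dd$order_index, method = "kendall")
      if (isTRUE(all.equal(ct, 1))) strand <- "+"
      else if (isTRUE(all.equal(ct, -1))) strand <- "-"
      else {
        disagreements[[length(disagreements) + 1]] <-
          tibble(pcf_id = p, reason = "non_monotone_order")
        next
      }
    }
    placed[[length(placed) + 1]] <- tibble(
      chrom = dd$chrom[1], pcf_id = p, strand = strand,
      median_index = stats::median(dd$order_index)
    )
  }
  chromosomes <- bind_rows(placed)
  if (nrow(chromosomes) > 0) {
    chromosomes <- chromosomes %>%
      arrange(.data$chrom, .data$median_index) %>%
      group_by(.data$chrom) %>%
      mutate(rank = row_number()) %>%
      ungroup() %>%
      select("chrom", "rank", "pcf_id", "strand")
  } else {
    chromosomes <- tibble(chrom = character(), rank = integer(),
                          pcf_id = character(), strand = character())
  }
  dis <- if (length(disagreements)) bind_rows(disagreements) else
    tibble(pcf_id = character(), reason = character())
  structure(list(
    chromosomes = chromosomes,
    disagreements = dis,
    unplaced = setdiff(pcf_set$pcfs$pcf_id,
                       c(chromosomes$pcf_id, dis$pcf_id)),
    pcf_set = pcf_set
  ), class = "karyo_assembly")
}

#' @export
print.karyo_assembly <- function(x, ...) {
  cat("<karyo_assembly> ", length(unique(x$chromosomes$chrom)),
      " chromosomes, ", nrow(x$chromosomes), " PCFs placed (",
      sum(x$chromosomes$strand != "?"), " oriented), ",
      nrow(x$disagreements), " disagreements\n", sep = "")
  invisible(x)
}

#' Placement and orientation statistics
#'
#' @param assembly A `karyo_assembly`.
#' @param scaffolds Original scaffold tibble (`scaffold_id`, `length`).
#' @return One-row tibble: `n_placed`, `n_oriented`, `placed_length`,
#'   `oriented_length`, `pct_placed`, `pct_oriented` (percent of the
#'   original scaffold total).
#' @export
anchoring_stats <- function(assembly, scaffolds) {
  pl <- assembly$pcf_set$pcfs %>%
    left_join(assembly$chromosomes, by = "pcf_id") %>%
    filter(!is.na(.data$chrom))
  orig <- sum(scaffolds$length)
  tibble(
    n_placed = nrow(pl),
    n_oriented = sum(pl$strand != "?"),
    placed_length = sum(pl$length),
    oriented_length = sum(pl$length[pl$strand != "?"]),
    pct_placed = percent_of_assembly(sum(pl$length), orig),
    pct_oriented = percent_of_assembly(sum(pl$length[pl$strand != "?"]), orig)
  )
}

#' Project an anchored assembly onto reference coordinates
#'
#' Walks each chromosome's placed PCFs in order, composing the member and
#' SF coordinate maps into target-chromosome segments on the reference:
#' the raw input for homology-map construction.
#'
#' @param assembly A `karyo_assembly`.
#' @return Tibble `tgt_chrom`, `tgt_start`, `tgt_end`, `ref_unit`,
#'   `ref_start`, `ref_end`, `strand`, ordered by target coordinate.
#' @export
assembly_segments <- function(assembly) {
  pcf_set <- assembly$pcf_set
  members <- pcf_set$members
  sfs <- pcf_set$sfs
  out <- list()
  for (ch in unique(assembly$chromosomes$chrom)) {
    rows <- assembly$chromosomes %>%
      filter(.data$chrom == ch) %>% arrange(.data$rank)
    chrom_off <- 0
    for (i in seq_len(nrow(rows))) {
      p <- rows$pcf_id[i]
      pstrand <- rows$strand[i]
      plen <- pcf_set$pcfs$length[pcf_set$pcfs$pcf_id == p]
      mem <- members %>% filter(.data$pcf_id == p)
      for (j in seq_len(nrow(mem))) {
        m <- mem[j, ]
        ssf <- sfs %>%
          filter(.data$scaffold_id == m$scaffold_id,
                 .data$s_start >= m$s_start, .data$s_end <= m$s_end)
        for (k in seq_len(nrow(ssf))) {
          sf <- ssf[k, ]
          # scaffold -> PCF coordinates
          if (m$strand == "+") {
            x1 <- m$pcf_start + (sf$s_start - m$s_start)
            x2 <- m$pcf_start + (sf$s_end - m$s_start)
          } else {
            x1 <- m$pcf_start + (m$s_end - sf$s_end)
            x2 <- m$pcf_start + (m$s_end - sf$s_start)
          }
          # PCF -> chromosome coordinates ('?' treated as '+')
          if (pstrand == "-") {
            t1 <- chrom_off + (plen - x2); t2 <- chrom_off + (plen - x1)
          } else {
            t1 <- chrom_off + x1; t2 <- chrom_off + x2
          }
          sgn <- (if (sf$strand == "+") 1 else -1) *
                 (if (m$strand == "+") 1 else -1) *
                 (if (pstrand == "-") -1 else 1)
          out[[length(out) + 1]] <- tibble(
            tgt_chrom = ch, tgt_start = t1, tgt_end = t2,
            ref_unit = sf$ref_chrom, ref_start = sf$ref_start,
            ref_end = sf$ref_end, strand = if (sgn > 0) "+" else "-"
          )
        }
      }
      chrom_off <- chrom_off + plen
    }
  }
  bind_rows(out) %>% arrange(.data$tgt_chrom, .data$tgt_start)
}

# ---- AGP --------------------------------------------------------------------

# component table underlying the AGP export (1-based inclusive coordinates)
agp_components <- function(assembly) {
  pcf_set <- assembly$pcf_set
  out <- list()
  for (ch in unique(assembly$chromosomes$chrom)) {
    rows <- assembly$chromosomes %>%
      filter(.data$chrom == ch) %>% arrange(.data$rank)
    pos <- 0 # 0-based cursor on the object
    part <- 0
    first <- TRUE
    for (i in seq_len(nrow(rows))) {
      p <- rows$pcf_id[i]; pstrand <- rows$strand[i]
      mem <- pcf_set$members %>% filter(.data$pcf_id == p) %>% arrange(.data$rank)
      if (pstrand == "-") {
        mem <- mem[rev(seq_len(nrow(mem))), ]
        mem$strand <- ifelse(mem$strand == "+", "-", "+")
      }
      for (j in seq_len(nrow(mem))) {
        m <- mem[j, ]
        if (!first) {
          part <- part + 1
          out[[length(out) + 1]] <- tibble(
            object = ch, object_beg = pos + 1, object_end = pos + 100,
            part_number = part, component_type = "N",
            component_id = NA_character_, component_beg = NA_real_,
            component_end = NA_real_, orientation = NA_character_,
            gap_length = 100
          )
          pos <- pos + 100
        }
        first <- FALSE
        part <- part + 1
        len <- m$s_end - m$s_start
        ori <- if (pstrand == "?") "?" else m$strand
        out[[length(out) + 1]] <- tibble(
          object = ch, object_beg = pos + 1, object_end = pos + len,
          part_number = part, component_type = "W",
          component_id = m$scaffold_id,
          component_beg = m$s_start + 1, component_end = m$s_end,
          orientation = ori, gap_length = NA_real_
        )
        pos <- pos + len
      }
    }
  }
  bind_rows(out)
}

#' Export a chromosome-level assembly as AGP v2.1
#'
#' One `W` component row per scaffold fragment and a 100-bp `N` gap row
#' (gap type `contig`, evidence `map`) between consecutive components.
#' Coordinates are 1-based inclusive; unoriented components carry
#' orientation `?`.
#'
#' @param assembly A `karyo_assembly`.
#' @param path Optional file to write.
#' @return Character vector of AGP lines (invisibly when `path` given).
#' @export
export_agp <- function(assembly, path = NULL) {
  comp <- agp_components(assembly)
  if (any(duplicated(comp[c("object", "object_beg")]))) {
    abort("overlapping components")
  }
  lines <- c("##agp-version 2.1", vapply(seq_len(nrow(comp)), function(i) {
    r <- comp[i, ]
    if (r$component_type == "W") {
      paste(r$object, r$object_beg, r$object_end, r$part_number, "W",
            r$component_id, r$component_beg, r$component_end, r$orientation,
            sep = "\t")
    } else {
      paste(r$object, r$object_beg, r$object_end, r$part_number, "N",
            r$gap_length, "contig", "yes", "map", sep = "\t")
    }
  }, character(1)))
  if (!is.null(path)) {
    readr::write_lines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Parse AGP v2.1 lines back into a component table
#'
#' The inverse of [export_agp()]: `parse_agp(export_agp(x))` reproduces the
#' component table of `x`.
#'
#' @param lines Character vector of AGP lines, or a file path.
#' @return Component tibble (see [export_agp()]).
#' @export
parse_agp <- function(lines) {
  if (length(lines) == 1 && file.exists(lines)) lines <- readr::read_lines(lines)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  rows <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (f[5] %in% c("N", "U")) {
      tibble(object = f[1], object_beg = as.numeric(f[2]),
             object_end = as.numeric(f[3]), part_number = as.integer(f[4]),
             component_type = f[5], component_id = NA_character_,
             component_beg = NA_real_, component_end = NA_real_,
             orientation = NA_character_, gap_length = as.numeric(f[6]))
    } else {
      tibble(object = f[1], object_beg = as.numeric(f[2]),
             object_end = as.numeric(f[3]), part_number = as.integer(f[4]),
             component_type = f[5], component_id = f[6],
             component_beg = as.numeric(f[7]), component_end = as.numeric(f[8]),
             orientation = f[9], gap_length = NA_real_)
    }
  })
  bind_rows(rows)
}
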