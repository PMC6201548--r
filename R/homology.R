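# Homology maps: per target chromosome, the ordered, signed list of
# reference homolog segments. Interchromosomal events are counted with
# explicit unit conventions (junction-based fusions, piece-based fissions),
# evolutionary breakpoint regions are located on the reference, and
# inversion counts are estimated from signed segment orders.

#' Built-in reference unit sets
#'
#' Unit-set conventions resolve how arm-level labels collapse into counting
#' units: `"chicken"` treats the two arms of homolog 4 (`4p`, `4q`) as one
#' unit `4` (the chicken chromosome); `"ancestral"` keeps `4p` as its own
#' microchromosome unit (the ancestral state) and relabels `4q` as `4`.
#' Any named character vector (`old = new`) is also accepted wherever a
#' unit set is taken.
#'
#' @param name `"chicken"`, `"ancestral"`, or `"identity"`.
#' @return Named character vector mapping raw unit labels.
#' @export
unit_set <- function(name = c("identity", "chicken", "ancestral")) {
  name <- match.arg(name)
  switch(name,
    identity = character(0),
    chicken = c("4p" = "4", "4q" = "4"),
    ancestral = c("4q" = "4")
  )
}

apply_unit_set <- function(units, set) {
  if (is.character(set) && length(set) == 1) set <- unit_set(set)
  if (length(set) == 0) return(units)
  hit <- units %in% names(set)
  units[hit] <- set[units[hit]]
  units
}

# chicken-homolog label of a unit: arm suffixes collapse (4p, 4q -> 4)
homolog_of <- function(units) sub("[pq]$", "", units)

#' Build a homology map from assembly segments
#'
#' Relabels reference units per the unit-set convention, drops segments
#' below the minimum size, and merges adjacent same-unit colinear segments
#' (same strand, reference gap within tolerance). The result is the
#' per-target-chromosome ordered, signed segment list used for event
#' counting and breakpoint detection.
#'
#' @param segments Tibble `tgt_chrom`, `tgt_start`, `tgt_end`, `ref_unit`,
#'   `ref_start`, `ref_end`, `strand` (coordinates may be `NA` for
#'   structure-only maps).
#' @param units A unit-set name (see [unit_set()]) or named mapping vector.
#' @param min_size Minimum segment length on the target (bp); smaller
#'   segments are dropped before merging. Ignored for coordinate-free maps.
#' @param merge_gap Maximum reference gap merged between colinear
#'   same-unit neighbours (default `min_size`).
#' @return A tibble of class `karyo_homology_map`, ordered by target
#'   coordinate, with attribute `unit_set`.
#' @export
build_homology_map <- function(segments, units = "identity",
                               min_size = 150000, merge_gap = min_size) {
  segments <- as_tibble(segments)
  segments$ref_unit <- as.character(segments$ref_unit)
  set_name <- if (is.character(units) && length(units) == 1) units else "custom"
  segments$ref_unit <- apply_unit_set(segments$ref_unit, units)

  has_coords <- !all(is.na(segments$tgt_start))
  if (has_coords) {
    segments <- segments %>%
      filter(.data$tgt_end - .data$tgt_start >= min_size) %>%
      arrange(.data$tgt_chrom, .data$tgt_start)
    # merge adjacent colinear same-unit segments
    merged <- list()
    for (ch in unique(segments$tgt_chrom)) {
      ss <- filter(segments, .data$tgt_chrom == ch)
      cur <- ss[1, ]
      add <- function(row) merged[[length(merged) + 1]] <<- row
      for (i in seq_len(nrow(ss))[-1]) {
        r <- ss[i, ]
        gap <- if (cur$strand == "+") r$ref_start - cur$ref_end
               else cur$ref_start - r$ref_end
        colinear <- r$ref_unit == cur$ref_unit && r$strand == cur$strand &&
          !is.na(gap) && gap > -merge_gap && gap < merge_gap
        if (colinear) {
          cur$tgt_end <- r$tgt_end
          cur$ref_start <- min(cur$ref_start, r$ref_start)
          cur$ref_end <- max(cur$ref_end, r$ref_end)
        } else {
          add(cur)
          cur <- r
        }
      }
      add(cur)
    }
    segments <- bind_rows(merged) %>%
      arrange(.data$tgt_chrom, .data$tgt_start)
  }
  structure(segments, class = c("karyo_homology_map", class(segments)),
            unit_set = set_name)
}

#' Count interchromosomal rearrangement events in a homology map
#'
#' Fusions are junction-based: a target chromosome concatenating `k`
#' distinct reference units contributes `k - 1` fusion junctions. Fissions
#' are piece-based: a unit present on `m` target chromosomes contributes
#' `m - 1`. A unit is intact when it sits alone on a single target
#' chromosome; homolog-level intactness additionally requires all arms of
#' a homolog (e.g. `4` and `4p`) to share one target chromosome carrying
#' nothing else. For complete maps the identity
#' `#targets = #units + fissions - fusions` holds.
#'
#' @param map A `karyo_homology_map` (or segment tibble with `tgt_chrom`
#'   and `ref_unit`).
#' @return An object of class `karyo_event_counts`: list with `n_fusions`,
#'   `n_fissions`, `n_targets`, `n_units`, `intact_units`,
#'   `n_intact_units`, `intact_homologs`, `n_intact_homologs`,
#'   `identity_holds`, and the per-chromosome `junctions` tibble.
#' @export
count_interchromosomal_events <- function(map) {
  map <- as_tibble(map)
  if (nrow(map) == 0) abort("empty homology map")
  # collapse consecutive same-unit segments (intrachromosomal structure)
  runs <- map %>%
    group_by(.data$tgt_chrom) %>%
    mutate(new_run = .data$ref_unit != dplyr::lag(.data$ref_unit,
                                                  default = "\r")) %>%
    filter(.data$new_run) %>%
    ungroup()
  junctions <- runs %>%
    group_by(.data$tgt_chrom) %>%
    summarise(n_units = n(), n_junctions = n() - 1, .groups = "drop")
  n_fusions <- sum(junctions$n_junctions)

  per_unit <- runs %>%
    group_by(.data$ref_unit) %>%
    summarise(n_targets = length(unique(.data$tgt_chrom)), .groups = "drop")
  n_fissions <- sum(per_unit$n_targets - 1)

  units <- sort(unique(map$ref_unit))
  targets <- unique(map$tgt_chrom)
  # units alone on a single target chromosome
  unit_targets <- split(runs$tgt_chrom, runs$ref_unit)
  target_units <- split(runs$ref_unit, runs$tgt_chrom)
  intact <- vapply(units, function(u) {
    tg <- unique(unit_targets[[u]])
    length(tg) == 1 && length(unique(target_units[[tg]])) == 1
  }, logical(1))
  intact_units <- units[intact]

  homologs <- sort(unique(homolog_of(units)))
  intact_h <- vapply(homologs, function(h) {
    uu <- units[homolog_of(units) == h]
    tg <- unique(unlist(unit_targets[uu]))
    length(tg) == 1 &&
      all(homolog_of(unique(target_units[[tg]])) == h)
  }, logical(1))
  intact_homologs <- homologs[intact_h]

  structure(list(
    n_fusions = n_fusions,
    n_fissions = n_fissions,
    n_targets = length(targets),
    n_units = length(units),
    intact_units = intact_units,
    n_intact_units = length(intact_units),
    intact_homologs = intact_homologs,
    n_intact_homologs = length(intact_homologs),
    identity_holds = length(targets) ==
      length(units) + n_fissions - n_fusions,
    junctions = junctions
  ), class = "karyo_event_counts")
}

#' @export
print.karyo_event_counts <- function(x, ...) {
  cat("<karyo_event_counts> ", x$n_fusions, " fusions, ", x$n_fissions,
      " fissions; ", x$n_targets, " target chromosomes over ", x$n_units,
      " units; ", x$n_intact_units, " intact units (",
      x$n_intact_homologs, " intact homologs)\n", sep = "")
  if (!x$identity_holds) cat("  WARNING: chromosome-count identity violated\n")
  invisible(x)
}

#' Detect and classify evolutionary breakpoint regions
#'
#' Projects each unit's segments onto the reference and emits an EBR at
#' every discontinuity: ref-consecutive segments on different target
#' chromosomes give a `fission` EBR spanning the reference gap;
#' target-adjacent but order/strand-broken same-unit neighbours give an
#' `intrachromosomal` EBR; each distinct-unit junction on a target
#' chromosome gives a `fusion` EBR at the broken reference end of both
#' flanking segments. Intervals are clipped to at least 1 bp. EBRs longer
#' than `max_len` are flagged `excluded` from CNE analysis.
#'
#' @param map A `karyo_homology_map` with reference coordinates.
#' @param max_len Maximum EBR length used in CNE analysis (bp).
#' @param genome Optional reference [karyo_genome()] for clipping at
#'   chromosome ends.
#' @return Tibble `chrom`, `start`, `end`, `class`, `excluded` in reference
#'   coordinates (class one of `fusion`, `fission`, `intrachromosomal`).
#' @export
detect_ebrs <- function(map, max_len = 100000, genome = NULL) {
  map <- as_tibble(map)
  if (any(is.na(map$ref_start))) abort("EBR detection needs reference coordinates")
  clen <- if (!is.null(genome)) {
    stats::setNames(genome$chroms$length, genome$chroms$chrom)
  } else NULL
  clip <- function(chrom, start, end) {
    start <- max(0, start)
    if (!is.null(clen) && !is.na(clen[chrom])) end <- min(end, clen[chrom])
    if (end <= start) { start <- max(0, end - 1); end <- start + 1 }
    tibble(chrom = chrom, start = start, end = end)
  }
  out <- list()
  emit <- function(chrom, start, end, class) {
    iv <- clip(chrom, start, end)
    out[[length(out) + 1]] <<- mutate(iv, class = class)
  }

  # reference-space discontinuities within each unit
  for (u in unique(map$ref_unit)) {
    ss <- map %>% filter(.data$ref_unit == u) %>% arrange(.data$ref_start)
    if (nrow(ss) >= 2) {
      # target-order index for adjacency testing
      ss <- ss %>%
        group_by(.data$tgt_chrom) %>%
        mutate(tgt_rank = rank(.data$tgt_start)) %>%
        ungroup()
      for (i in seq_len(nrow(ss) - 1)) {
        a <- ss[i, ]; b <- ss[i + 1, ]
        if (a$tgt_chrom != b$tgt_chrom) {
          emit(u, a$ref_end, b$ref_start, "fission")
        } else {
          target_adjacent <- abs(a$tgt_rank - b$tgt_rank) == 1
          colinear <- target_adjacent && a$strand == b$strand &&
            ((a$strand == "+" && a$tgt_start < b$tgt_start) ||
               (a$strand == "-" && a$tgt_start > b$tgt_start))
          if (!colinear) emit(u, a$ref_end, b$ref_start, "intrachromosomal")
        }
      }
    }
  }

  # fusion junctions: broken reference ends of distinct-unit neighbours
  for (ch in unique(map$tgt_chrom)) {
    ss <- map %>% filter(.data$tgt_chrom == ch) %>% arrange(.data$tgt_start)
    if (nrow(ss) < 2) next
    for (i in seq_len(nrow(ss) - 1)) {
      a <- ss[i, ]; b <- ss[i + 1, ]
      if (a$ref_unit == b$ref_unit) next
      qa <- if (a$strand == "+") a$ref_end else a$ref_start
      qb <- if (b$strand == "+") b$ref_start else b$ref_end
      emit(a$ref_unit, qa, qa + 1, "fusion")
      emit(b$ref_unit, qb, qb + 1, "fusion")
    }
  }

  if (length(out) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  class = character(), excluded = logical()))
  }
  bind_rows(out) %>%
    mutate(excluded = (.data$end - .data$start) > max_len) %>%
    arrange(.data$chrom, .data$start)
}

# ---- signed reversal distance ----------------------------------------------

perm_key <- function(p) paste(p, collapse = ",")

reversal_neighbors <- function(p) {
  n <- length(p)
  out <- vector("list", n * (n + 1) / 2)
  k <- 0
  for (i in 1:n) for (j in i:n) {
    q <- p
    q[i:j] <- -rev(p[i:j])
    k <- k + 1
    out[[k]] <- q
  }
  out
}

# full-space BFS from the identity; distance is symmetric because every
# reversal is an involution
reversal_distance_table <- function(n) {
  env <- new.env(hash = TRUE, size = 2^14)
  id <- seq_len(n)
  assign(perm_key(id), 0L, envir = env)
  frontier <- list(id)
  d <- 0L
  while (length(frontier) > 0) {
    d <- d + 1L
    nxt <- list()
    for (p in frontier) {
      for (q in reversal_neighbors(p)) {
        k <- perm_key(q)
        if (!exists(k, envir = env, inherits = FALSE)) {
          assign(k, d, envir = env)
          nxt[[length(nxt) + 1]] <- q
        }
      }
    }
    frontier <- nxt
  }
  env
}

.karyo_cache <- new.env(parent = emptyenv())

signed_breakpoint_bound <- function(p) {
  ext <- c(0L, p, length(p) + 1L)
  b <- sum(diff(ext) != 1L)
  ceiling(b / 2)
}

#' Minimum reversals sorting a signed permutation
#'
#' Exact signed sorting-by-reversals distance via breadth-first search for
#' up to 7 segments (a cached full-space table per size) and per-input BFS
#' up to 10 segments; larger inputs return the signed breakpoint lower
#' bound, labelled as an estimate in the `method` attribute.
#'
#' @param perm Signed integer vector whose absolute values are a
#'   permutation of `1..n`.
#' @param max_states State cap for the per-input search before falling
#'   back to the lower bound.
#' @return Integer distance with attribute `method` (`"exact"` or
#'   `"lower_bound"`).
#' @examples
#' estimate_inversions(c(1, -2, 3)) # 1
#' @export
estimate_inversions <- function(perm, max_states = 5e5) {
  perm <- as.integer(perm)
  n <- length(perm)
  if (n == 0 || !setequal(abs(perm), seq_len(n))) {
    abort("input is not a signed permutation of 1..n")
  }
  if (all(perm == seq_len(n))) return(structure(0L, method = "exact"))
  if (n <= 7) {
    key <- paste0("revtab", n)
    if (is.null(.karyo_cache[[key]])) {
      .karyo_cache[[key]] <- reversal_distance_table(n)
    }
    d <- get(perm_key(perm), envir = .karyo_cache[[key]])
    return(structure(as.integer(d), method = "exact"))
  }
  if (n <= 10) {
    env <- new.env(hash = TRUE, size = 2^16)
    assign(perm_key(perm), 0L, envir = env)
    frontier <- list(perm)
    d <- 0L
    states <- 1L
    id_key <- perm_key(seq_len(n))
    while (length(frontier) > 0 && states < max_states) {
      d <- d + 1L
      nxt <- list()
      for (p in frontier) {
        for (q in reversal_neighbors(p)) {
          k <- perm_key(q)
          if (k == id_key) return(structure(d, method = "exact"))
          if (!exists(k, envir = env, inherits = FALSE)) {
            assign(k, d, envir = env)
            nxt[[length(nxt) + 1]] <- q
            states <- states + 1L
          }
        }
      }
      frontier <- nxt
    }
  }
  structure(signed_breakpoint_bound(perm), method = "lower_bound")
}

#' Estimate inversion counts per unit from a homology map
#'
#' For each reference unit, segments are ranked by reference position,
#' signed by strand, and read in target order per target chromosome; the
#' reversal distance of each resulting signed permutation (minimised over
#' reading direction) is summed.
#'
#' @param map A `karyo_homology_map` with coordinates.
#' @return Tibble `ref_unit`, `tgt_chrom`, `n_segments`, `inversions`,
#'   `method`.
#' @export
inversions_from_map <- function(map) {
  map <- as_tibble(map)
  out <- list()
  for (u in unique(map$ref_unit)) {
    ss <- map %>% filter(.data$ref_unit == u)
    for (ch in unique(ss$tgt_chrom)) {
      sc <- ss %>% filter(.data$tgt_chrom == ch) %>% arrange(.data$tgt_start)
      if (nrow(sc) < 2) next
      r <- rank(sc$ref_start)
      signed <- ifelse(sc$strand == "+", r, -r)
      rev_read <- -rev(signed)
      d1 <- estimate_inversions(signed)
      d2 <- estimate_inversions(rev_read)
      use <- if (d2 < d1) d2 else d1
      out[[length(out) + 1]] <- tibble(
        ref_unit = u, tgt_chrom = ch, n_segments = nrow(sc),
        inversions = as.integer(use), method = attr(use, "method")
      )
    }
  }
  if (length(out) == 0) {
    return(tibble(ref_unit = character(), tgt_chrom = character(),
                  n_segments = integer(), inversions = integer(),
                  method = character()))
  }
  bind_rows(out)
}
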