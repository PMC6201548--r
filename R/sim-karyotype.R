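# Derived karyotypes are piecewise maps to ancestor coordinates: each derived
# chromosome is an ordered run of signed ancestor segments. Every
# rearrangement operates on that segment list, so CNE/msHSB tracks and BAC
# markers can be carried through exactly.

new_karyotype <- function(segments, chrom_order) {
  structure(list(segments = as_tibble(segments), chrom_order = chrom_order),
            class = "karyo_karyotype")
}

#' Identity karyotype over a genome
#'
#' One segment per ancestor chromosome; the starting point for planting
#' rearrangements.
#'
#' @param genome A [karyo_genome()].
#' @return A `karyo_karyotype`.
#' @export
karyotype_identity <- function(genome) {
  segs <- tibble(
    chrom = genome$chroms$chrom,
    anc_chrom = genome$chroms$chrom,
    anc_start = 0,
    anc_end = genome$chroms$length,
    strand = "+"
  )
  new_karyotype(segs, genome$chroms$chrom)
}

#' @export
print.karyo_karyotype <- function(x, ...) {
  lens <- karyotype_lengths(x)
  cat("<karyo_karyotype> ", nrow(lens), " chromosomes, ",
      format(sum(lens$length), big.mark = ","), " bp, ",
      nrow(x$segments), " segments\n", sep = "")
  invisible(x)
}

#' Derived chromosome lengths
#' @param karyotype A `karyo_karyotype`.
#' @return Tibble `chrom`, `length` in karyotype order.
#' @export
karyotype_lengths <- function(karyotype) {
  sg <- karyotype$segments
  len <- tapply(sg$anc_end - sg$anc_start, sg$chrom, sum)
  ord <- intersect(karyotype$chrom_order, names(len))
  tibble(chrom = ord, length = as.numeric(len[ord]))
}

# Segments of one chromosome with derived-coordinate bounds attached.
segs_with_bounds <- function(karyotype, chrom) {
  sg <- karyotype$segments
  s <- sg[sg$chrom == chrom, ]
  w <- s$anc_end - s$anc_start
  s$d_start <- cumsum(c(0, w))[seq_len(nrow(s))]
  s$d_end <- s$d_start + w
  s
}

# Split one chromosome's segment run at derived position pos (0 < pos < len).
split_segments_at <- function(segs, pos) {
  left <- segs[segs$d_end <= pos, ]
  right <- segs[segs$d_start >= pos, ]
  mid <- which(segs$d_start < pos & pos < segs$d_end)
  if (length(mid) == 1) {
    r <- segs[mid, ]
    off <- pos - r$d_start
    a <- r; b <- r
    if (r$strand == "+") {
      a$anc_end <- r$anc_start + off
      b$anc_start <- r$anc_start + off
    } else {
      a$anc_start <- r$anc_end - off
      b$anc_end <- r$anc_end - off
    }
    a$d_end <- pos; b$d_start <- pos
    left <- bind_rows(left, a)
    right <- bind_rows(b, right)
  }
  list(left = left, right = right)
}

reverse_segments <- function(segs) {
  if (nrow(segs) == 0) return(segs)
  segs <- segs[rev(seq_len(nrow(segs))), ]
  segs$strand <- ifelse(segs$strand == "+", "-", "+")
  segs
}

# Map a derived position to ancestor coordinates.
derived_to_anc <- function(karyotype, chrom, pos) {
  s <- segs_with_bounds(karyotype, chrom)
  i <- which(s$d_start <= pos & pos <= s$d_end)[1]
  if (is.na(i)) abort("position outside chromosome")
  r <- s[i, ]
  off <- pos - r$d_start
  list(chrom = r$anc_chrom,
       pos = if (r$strand == "+") r$anc_start + off else r$anc_end - off)
}

#' Project an ancestor-coordinate track into derived coordinates
#'
#' @param karyotype A `karyo_karyotype`.
#' @param track Interval tibble in ancestor coordinates.
#' @return Interval tibble in derived coordinates (merged).
#' @export
map_track_to_derived <- function(karyotype, track) {
  if (nrow(track) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  out <- list()
  for (ch in karyotype$chrom_order) {
    s <- segs_with_bounds(karyotype, ch)
    for (i in seq_len(nrow(s))) {
      r <- s[i, ]
      tr <- filter(track, .data$chrom == r$anc_chrom,
                   .data$end > r$anc_start, .data$start < r$anc_end)
      if (nrow(tr) == 0) next
      x <- pmax(tr$start, r$anc_start); y <- pmin(tr$end, r$anc_end)
      if (r$strand == "+") {
        out[[length(out) + 1]] <- tibble(chrom = ch,
                                         start = r$d_start + (x - r$anc_start),
                                         end = r$d_start + (y - r$anc_start))
      } else {
        out[[length(out) + 1]] <- tibble(chrom = ch,
                                         start = r$d_start + (r$anc_end - y),
                                         end = r$d_start + (r$anc_end - x))
      }
    }
  }
  merge_intervals(bind_rows(out))
}

#' Realise a karyotype as a genome with mapped tracks
#'
#' @param karyotype A `karyo_karyotype`.
#' @param ancestor The ancestor [karyo_genome()] supplying the tracks.
#' @return A [karyo_genome()] in derived coordinates.
#' @export
karyotype_as_genome <- function(karyotype, ancestor) {
  g <- karyo_genome(karyotype_lengths(karyotype))
  for (nm in names(ancestor$tracks)) {
    g <- set_track(g, nm, map_track_to_derived(karyotype, ancestor$tracks[[nm]]))
  }
  g
}

# derived-orientation end coordinates of a segment run
run_left_end <- function(segs) {
  r <- segs[1, ]
  list(chrom = r$anc_chrom, pos = if (r$strand == "+") r$anc_start else r$anc_end)
}
run_right_end <- function(segs) {
  r <- segs[nrow(segs), ]
  list(chrom = r$anc_chrom, pos = if (r$strand == "+") r$anc_end else r$anc_start)
}

#' Plant fissions, fusions and inversions on a genome
#'
#' Applies the configured event counts (fissions, then fusions, then
#' inversions) to the identity karyotype. Fission and inversion breakpoints
#' are drawn from 1-kb candidate windows with probability proportional to
#' `(1 - CNE fraction)^(gamma * class weight)`, so breakpoint classes show
#' a graded CNE depletion (fissions strongest by default). Fusions join two
#' chromosomes at original (ancestral) telomeric ends, whose subtelomeric
#' CNE depletion gives fusion breakpoints an intermediate density. All
#' interval tracks are carried through the coordinate maps, conserving
#' total sequence and CNE bases.
#'
#' @param genome Ancestor [karyo_genome()].
#' @param config A [sim_config()].
#' @return A list: `karyotype` (`karyo_karyotype`) and `truth` (tibble of
#'   planted events with ancestor-coordinate breakpoints).
#' @export
apply_rearrangements <- function(genome, config) {
  stopifnot(inherits(config, "sim_config"))
  k <- karyotype_identity(genome)
  n0 <- length(k$chrom_order)
  if (config$n_fusions > n0 - 1) {
    abort("more fusions than joinable original chromosome ends")
  }
  anc_len <- stats::setNames(genome$chroms$length, genome$chroms$chrom)
  events <- list()
  next_id <- 1
  new_name <- function() {
    nm <- sprintf("K%d", next_id); next_id <<- next_id + 1; nm
  }
  margin <- config$min_inversion_size
  record <- function(type, bp1 = NULL, bp2 = NULL) {
    events[[length(events) + 1]] <<- tibble(
      event = length(events) + 1, type = type,
      anc_chrom1 = if (is.null(bp1)) NA_character_ else bp1$chrom,
      anc_pos1 = if (is.null(bp1)) NA_real_ else bp1$pos,
      anc_chrom2 = if (is.null(bp2)) NA_character_ else bp2$chrom,
      anc_pos2 = if (is.null(bp2)) NA_real_ else bp2$pos
    )
  }

  # ancestor-coordinate candidate windows, computed once: the CNE landscape
  # is invariant under rearrangement, so sampling an ancestor window and
  # mapping it through the current karyotype is equivalent to sampling in
  # derived coordinates
  wins <- tile_windows(genome, 1000)
  wfrac <- cne_fraction(wins, genome)
  if (config$exclude_mshsb_breakpoints) {
    wfrac[interval_covered_bases(wins, genome$tracks$msHSB) > 0] <- NA
  }
  class_exp <- function(class) {
    w <- config$gamma_class_weights
    config$breakpoint_gamma * (if (class %in% names(w)) w[[class]] else 1)
  }
  # derived location of an ancestor position under the current karyotype
  locate_anc <- function(chrom, pos) {
    sg <- k$segments
    hit <- which(sg$anc_chrom == chrom & sg$anc_start <= pos &
                   pos < sg$anc_end)[1]
    dch <- sg$chrom[hit]
    s <- segs_with_bounds(k, dch)
    ri <- which(s$anc_chrom == chrom & s$anc_start == sg$anc_start[hit] &
                  s$anc_end == sg$anc_end[hit])[1]
    d <- if (s$strand[ri] == "+") s$d_start[ri] + (pos - s$anc_start[ri])
         else s$d_start[ri] + (s$anc_end[ri] - pos)
    list(chrom = dch, pos = d)
  }
  draw_anc_bp <- function(class, idx = seq_len(nrow(wins))) {
    wt <- (1 - wfrac[idx])^class_exp(class)
    wt[is.na(wt)] <- 0
    if (sum(wt) <= 0) abort("all breakpoint window weights are zero")
    i <- idx[sample.int(length(idx), 1, prob = wt)]
    list(chrom = wins$chrom[i],
         pos = floor(stats::runif(1, wins$start[i], wins$end[i])))
  }

  for (i in seq_len(config$n_fissions)) {
    ok <- FALSE
    for (try in 1:200) {
      anc <- draw_anc_bp("fission")
      bp <- locate_anc(anc$chrom, anc$pos)
      lens <- karyotype_lengths(k)
      len <- lens$length[lens$chrom == bp$chrom]
      if (bp$pos < margin || bp$pos > len - margin) next
      segs <- segs_with_bounds(k, bp$chrom)
      sp <- split_segments_at(segs, bp$pos)
      a <- new_name(); b <- new_name()
      keep <- filter(k$segments, .data$chrom != bp$chrom)
      left <- mutate(sp$left, chrom = a)[names(k$segments)]
      right <- mutate(sp$right, chrom = b)[names(k$segments)]
      ord <- k$chrom_order
      pos_in <- match(bp$chrom, ord)
      k <- new_karyotype(bind_rows(keep, left, right),
                         append(ord[-pos_in], c(a, b), after = pos_in - 1))
      record("fission", anc)
      ok <- TRUE
      break
    }
    if (!ok) abort("could not place fission breakpoint")
  }

  # free original-telomere ends: outward ancestor coordinate of a terminal
  # segment coincides with an ancestral chromosome terminus
  free_ends <- function() {
    ch_v <- character(0); side_v <- character(0)
    ac_v <- character(0); ap_v <- numeric(0)
    sg <- k$segments
    for (ch in k$chrom_order) {
      idx <- which(sg$chrom == ch)
      f <- idx[1]; l <- idx[length(idx)]
      lpos <- if (sg$strand[f] == "+") sg$anc_start[f] else sg$anc_end[f]
      if (lpos == 0 || lpos == anc_len[sg$anc_chrom[f]]) {
        ch_v <- c(ch_v, ch); side_v <- c(side_v, "L")
        ac_v <- c(ac_v, sg$anc_chrom[f]); ap_v <- c(ap_v, lpos)
      }
      rpos <- if (sg$strand[l] == "+") sg$anc_end[l] else sg$anc_start[l]
      if (rpos == 0 || rpos == anc_len[sg$anc_chrom[l]]) {
        ch_v <- c(ch_v, ch); side_v <- c(side_v, "R")
        ac_v <- c(ac_v, sg$anc_chrom[l]); ap_v <- c(ap_v, rpos)
      }
    }
    tibble(chrom = ch_v, side = side_v, anc_chrom = ac_v, anc_pos = ap_v)
  }

  for (i in seq_len(config$n_fusions)) {
    ends <- free_ends()
    if (nrow(ends) == 0 || length(unique(ends$chrom)) < 2) {
      abort("no joinable original chromosome ends left")
    }
    e1 <- ends[sample.int(nrow(ends), 1), ]
    others <- filter(ends, .data$chrom != e1$chrom)
    e2 <- others[sample.int(nrow(others), 1), ]
    s1 <- segs_with_bounds(k, e1$chrom)[names(k$segments)]
    s2 <- segs_with_bounds(k, e2$chrom)[names(k$segments)]
    if (e1$side == "L") s1 <- reverse_segments(s1) # junction at s1's right
    if (e2$side == "R") s2 <- reverse_segments(s2) # junction at s2's left
    nm <- new_name()
    fused <- bind_rows(mutate(s1, chrom = nm), mutate(s2, chrom = nm))
    keep <- filter(k$segments, !.data$chrom %in% c(e1$chrom, e2$chrom))
    k <- new_karyotype(bind_rows(keep, fused),
                       c(setdiff(k$chrom_order, c(e1$chrom, e2$chrom)), nm))
    record("fusion", list(chrom = e1$anc_chrom, pos = e1$anc_pos),
           list(chrom = e2$anc_chrom, pos = e2$anc_pos))
  }

  # windows currently on one derived chromosome (by window centre);
  # per-ancestor-chromosome index + sorted centres allow range lookups
  win_idx_by_chrom <- split(seq_len(nrow(wins)), wins$chrom)
  win_ctr <- (wins$start + wins$end) / 2
  windows_on_chrom <- function(ch) {
    s <- segs_with_bounds(k, ch)
    idx <- integer(0)
    for (j in seq_len(nrow(s))) {
      ii <- win_idx_by_chrom[[s$anc_chrom[j]]]
      if (is.null(ii)) next
      ctr <- win_ctr[ii] # sorted ascending within a chromosome
      lo <- findInterval(s$anc_start[j] - 0.5, ctr) + 1
      hi <- findInterval(s$anc_end[j] - 0.5, ctr)
      if (hi >= lo) idx <- c(idx, ii[lo:hi])
    }
    idx
  }

  for (i in seq_len(config$n_inversions)) {
    ok <- FALSE
    for (try in 1:200) {
      anc1 <- draw_anc_bp("inversion")
      bp1 <- locate_anc(anc1$chrom, anc1$pos)
      lens <- karyotype_lengths(k)
      len <- lens$length[lens$chrom == bp1$chrom]
      if (len < 2 * margin + config$min_inversion_size) next
      idx <- windows_on_chrom(bp1$chrom)
      anc2 <- draw_anc_bp("inversion", idx)
      bp2 <- locate_anc(anc2$chrom, anc2$pos)
      if (bp2$chrom != bp1$chrom) next
      p1 <- min(bp1$pos, bp2$pos); p2 <- max(bp1$pos, bp2$pos)
      if (p1 < margin || len - p2 < margin) next
      if (p2 - p1 < config$min_inversion_size) next
      segs <- segs_with_bounds(k, bp1$chrom)
      # keep each event's signature attributable: the inverted interval
      # must not span a pre-existing breakpoint (segment boundary)
      host <- which(segs$d_start <= p1 & p2 <= segs$d_end)
      if (length(host) == 0) next
      sp1 <- split_segments_at(segs, p1)
      w <- sp1$right
      w$d_start <- cumsum(c(0, w$anc_end - w$anc_start))[seq_len(nrow(w))] + p1
      w$d_end <- w$d_start + (w$anc_end - w$anc_start)
      sp2 <- split_segments_at(w, p2)
      inv <- bind_rows(sp1$left, reverse_segments(sp2$left),
                       sp2$right)[names(k$segments)]
      keep <- filter(k$segments, .data$chrom != bp1$chrom)
      k <- new_karyotype(bind_rows(keep, mutate(inv, chrom = bp1$chrom)),
                         k$chrom_order)
      record("inversion", anc1, anc2)
      ok <- TRUE
      break
    }
    if (!ok) abort("could not place inversion breakpoints")
  }

  list(karyotype = k, truth = bind_rows(events))
}

#' Planted events as breakpoint-region intervals
#'
#' Converts a truth log into reference-coordinate EBR intervals (1 bp at
#' each planted breakpoint: one per fission, two per fusion and per
#' inversion), the ground-truth counterpart of [detect_ebrs()] output.
#'
#' @param truth Event tibble from [apply_rearrangements()].
#' @param genome Ancestor [karyo_genome()] for end clipping.
#' @return Tibble `chrom`, `start`, `end`, `class`, `excluded`.
#' @export
truth_to_ebrs <- function(truth, genome) {
  clen <- stats::setNames(genome$chroms$length, genome$chroms$chrom)
  rows <- list()
  add <- function(chrom, pos, class) {
    s <- min(max(pos, 0), clen[chrom] - 1)
    rows[[length(rows) + 1]] <<- tibble(chrom = chrom, start = s, end = s + 1,
                                        class = class)
  }
  for (i in seq_len(nrow(truth))) {
    e <- truth[i, ]
    cls <- switch(e$type, fission = "fission", fusion = "fusion",
                  inversion = "intrachromosomal")
    add(e$anc_chrom1, e$anc_pos1, cls)
    if (!is.na(e$anc_chrom2)) add(e$anc_chrom2, e$anc_pos2, cls)
  }
  bind_rows(rows) %>% mutate(excluded = FALSE)
}
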