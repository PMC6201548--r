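# Simplified reference-assisted chromosome assembly: merge alignment blocks
# into syntenic fragments (SFs), flag scaffold joins whose flanking SFs
# conflict on the reference, calibrate the spanning-pair split threshold
# against PCR verdicts, and chain scaffold fragments into predicted
# chromosome fragments (PCFs) using reference order plus adjacency evidence.

#' Assembly parameters
#'
#' @param window_size Block window (kept for interface compatibility with
#'   the two-round assembly procedure; unused by the simplified chainer).
#' @param resolution Merging/conflict resolution (bp). SF merging allows
#'   gaps below this on both genomes; SFs shorter than this are discarded.
#' @param min_intracov Absolute spanning-pair threshold below which a
#'   conflicting join is split (set from [calibrate_threshold()]).
#' @return A list of class `assembly_params`.
#' @export
assembly_params <- function(window_size = 10, resolution = 150000,
                            min_intracov = NULL) {
  stopifnot(resolution > 0, is.null(min_intracov) || min_intracov >= 0)
  structure(list(window_size = window_size, resolution = resolution,
                 min_intracov = min_intracov), class = "assembly_params")
}

#' Merge alignment blocks into syntenic fragments
#'
#' Consecutive blocks on the same (scaffold, reference chromosome, strand)
#' with gaps below `resolution` on both genomes and consistent colinear
#' geometry are merged; merged fragments shorter than `resolution` (on the
#' scaffold) are discarded.
#'
#' @param blocks Tibble `ref_chrom ref_start ref_end tgt_scaffold tgt_start
#'   tgt_end strand`.
#' @param params An [assembly_params()].
#' @return SF tibble: `sf_id`, `scaffold_id`, `s_start`, `s_end`,
#'   `ref_chrom`, `ref_start`, `ref_end`, `strand`, `resolution`.
#' @export
build_syntenic_fragments <- function(blocks, params = assembly_params()) {
  blocks <- as_tibble(blocks)
  if (nrow(blocks) == 0) abort("no alignment blocks")
  if (any(blocks$ref_end <= blocks$ref_start) ||
      any(blocks$tgt_end <= blocks$tgt_start)) {
    abort("malformed alignment block (non-positive span)")
  }
  res <- params$resolution
  b <- arrange(blocks, .data$tgt_scaffold, .data$tgt_start)
  brk <- function(prev, cur) {
    if (prev$tgt_scaffold != cur$tgt_scaffold) return(TRUE)
    if (prev$ref_chrom != cur$ref_chrom || prev$strand != cur$strand) return(TRUE)
    if (cur$tgt_start - prev$tgt_end >= res) return(TRUE)
    gap <- if (cur$strand == "+") cur$ref_start - prev$ref_end
           else prev$ref_start - cur$ref_end
    if (gap < 0 || gap >= res) return(TRUE) # non-colinear or distant
    FALSE
  }
  grp <- integer(nrow(b)); grp[1] <- 1
  for (i in seq_len(nrow(b))[-1]) {
    grp[i] <- if (brk(b[i - 1, ], b[i, ])) grp[i - 1] + 1 else grp[i - 1]
  }
  sfs <- b %>%
    mutate(.grp = grp) %>%
    group_by(.data$.grp) %>%
    summarise(
      scaffold_id = first(.data$tgt_scaffold),
      s_start = min(.data$tgt_start), s_end = max(.data$tgt_end),
      ref_chrom = first(.data$ref_chrom),
      ref_start = min(.data$ref_start), ref_end = max(.data$ref_end),
      strand = first(.data$strand), .groups = "drop"
    ) %>%
    filter(.data$s_end - .data$s_start >= res) %>%
    arrange(.data$scaffold_id, .data$s_start) %>%
    mutate(sf_id = sprintf("SF%04d", row_number()), resolution = res) %>%
    select("sf_id", "scaffold_id", "s_start", "s_end",
           "ref_chrom", "ref_start", "ref_end", "strand", "resolution")
  sfs
}

#' Flag scaffold joins with conflicting comparative evidence
#'
#' A join between consecutive SFs within a scaffold is conflicting when the
#' flanking SFs map to different reference chromosomes, to the same
#' chromosome non-adjacently (reference gap beyond `resolution`), or with
#' inconsistent strand geometry.
#'
#' @param sfs SF tibble from [build_syntenic_fragments()].
#' @param params An [assembly_params()].
#' @return Join tibble: `scaffold_id`, `junction_offset` (scaffold
#'   coordinate of the left SF's end), `span` (unaligned bp between the
#'   SFs), `conflict` flag and a `reason`.
#' @export
find_conflicting_joins <- function(sfs, params = assembly_params()) {
  res <- params$resolution
  out <- list()
  for (sc in unique(sfs$scaffold_id)) {
    ss <- sfs %>% filter(.data$scaffold_id == sc) %>% arrange(.data$s_start)
    if (nrow(ss) < 2) next
    for (i in seq_len(nrow(ss) - 1)) {
      a <- ss[i, ]; b <- ss[i + 1, ]
      reason <- NA_character_
      if (a$ref_chrom != b$ref_chrom) {
        reason <- "different_chromosome"
      } else if (a$strand != b$strand) {
        reason <- "strand_flip"
      } else {
        gap <- if (a$strand == "+") b$ref_start - a$ref_end
               else a$ref_start - b$ref_end
        if (gap < -res) reason <- "order_inconsistent"
        else if (gap > res) reason <- "reference_gap"
      }
      out[[length(out) + 1]] <- tibble(
        scaffold_id = sc, junction_offset = a$s_end,
        span = b$s_start - a$s_end,
        left_sf = a$sf_id, right_sf = b$sf_id,
        conflict = !is.na(reason), reason = reason
      )
    }
  }
  if (length(out) == 0) {
    return(tibble(scaffold_id = character(), junction_offset = numeric(),
                  span = numeric(), left_sf = character(),
                  right_sf = character(), conflict = logical(),
                  reason = character()))
  }
  bind_rows(out)
}

#' Calibrate the spanning-pair split threshold against PCR
#'
#' Scans candidate thresholds `T` in `{0} U {c + 1 : c observed}` and
#' scores `agreement(T) = #(confirmed joins with coverage >= T) + #(refuted
#' joins with coverage < T)`; returns the smallest maximising threshold
#' (the most conservative split rule with the highest agreement between
#' scaffolds and PCR results). Untestable joins contribute nothing.
#'
#' @param joins Tibble with `coverage` and `pcr_status` in
#'   \{`confirmed`, `refuted`, `untestable`\}.
#' @return An object of class `karyo_calibration`: list with `threshold`,
#'   `agreement`, `n_tested`, and the scanned `candidates` tibble.
#' @export
calibrate_threshold <- function(joins) {
  joins <- as_tibble(joins)
  tested <- filter(joins, .data$pcr_status %in% c("confirmed", "refuted"))
  if (nrow(tested) == 0) abort("no PCR-tested joins")
  cand <- sort(unique(c(0, tested$coverage + 1)))
  agree <- vapply(cand, function(T) {
    sum(tested$pcr_status == "confirmed" & tested$coverage >= T) +
      sum(tested$pcr_status == "refuted" & tested$coverage < T)
  }, numeric(1))
  best <- cand[which(agree == max(agree))[1]]
  structure(list(threshold = best, agreement = max(agree),
                 n_tested = nrow(tested),
                 candidates = tibble(threshold = cand, agreement = agree)),
            class = "karyo_calibration")
}

#' @export
print.karyo_calibration <- function(x, ...) {
  cat("<karyo_calibration> threshold ", x$threshold, " (agreement ",
      x$agreement, "/", x$n_tested, " PCR-tested joins)\n", sep = "")
  invisible(x)
}

# match a (scaffold, offset) against a table of offsets with tolerance;
# returns row index or NA
match_offset <- function(scaffold, offset, table, tol) {
  idx <- which(table$scaffold_id == scaffold &
                 abs(table$junction_offset - offset) <= tol)
  if (length(idx) == 0) NA_integer_ else idx[which.min(
    abs(table$junction_offset[idx] - offset))]
}

#' Assemble predicted chromosome fragments
#'
#' Splits scaffolds at conflicting joins whose spanning-pair coverage falls
#' below the threshold (PCR-confirmed structures are never split), then
#' orders the resulting scaffold fragments along each reference chromosome
#' by SF midpoint and chains consecutive fragments into PCFs wherever
#' read-pair adjacency evidence (or an intact scaffold) supports the join.
#' A fragment whose SFs span two reference chromosomes (an intact scaffold
#' across a species-specific fusion) links its two chains into one PCF.
#'
#' @param scaffolds Tibble `scaffold_id`, `length`.
#' @param sfs SF tibble from [build_syntenic_fragments()].
#' @param coverage Tibble `scaffold_id`, `junction_offset`,
#'   `spanning_pairs` (intra-scaffold physical coverage).
#' @param params An [assembly_params()]; `min_intracov` must be set (e.g.
#'   from [calibrate_threshold()]) unless `threshold` is given.
#' @param confirmed Optional tibble `scaffold_id`, `junction_offset` of
#'   PCR-confirmed joins, exempt from splitting.
#' @param adjacency Optional adjacency-support tibble (`scaffold_a`,
#'   `a_pos`, `scaffold_b`, `b_pos`, `spanning_pairs`); without it, chains
#'   follow reference order unconditionally within each chromosome.
#' @param threshold Spanning-pair threshold; overrides `params$min_intracov`.
#' @return An object of class `karyo_pcf_set`: list with `pcfs` (tibble
#'   `pcf_id`, `n_members`, `length`, `ref_chroms`), `members` (tibble
#'   `pcf_id`, `rank`, `scaffold_id`, `s_start`, `s_end`, `strand`,
#'   `pcf_start`, `pcf_end`), and `splits` (registry of split joins).
#' @export
assemble_pcfs <- function(scaffolds, sfs, coverage, params = assembly_params(),
                          confirmed = NULL, adjacency = NULL,
                          threshold = params$min_intracov) {
  if (is.null(threshold)) abort("no split threshold: calibrate or supply one")
  res <- params$resolution
  joins <- find_conflicting_joins(sfs, params)
  conf <- filter(joins, .data$conflict)

  # coverage lookup (tolerance = resolution); missing coverage counts as 0
  cov_at <- numeric(nrow(conf))
  for (i in seq_len(nrow(conf))) {
    j <- match_offset(conf$scaffold_id[i], conf$junction_offset[i], coverage, res)
    if (is.na(j)) {
      warn(paste0("no coverage for conflicting join at ", conf$scaffold_id[i],
                  ":", conf$junction_offset[i], "; treating as 0"))
      cov_at[i] <- 0
    } else cov_at[i] <- coverage$spanning_pairs[j]
  }
  conf$coverage <- cov_at
  is_confirmed <- rep(FALSE, nrow(conf))
  if (!is.null(confirmed) && nrow(confirmed) > 0) {
    for (i in seq_len(nrow(conf))) {
      is_confirmed[i] <- !is.na(match_offset(conf$scaffold_id[i],
                                             conf$junction_offset[i],
                                             confirmed, res))
    }
  }
  conf$split <- conf$coverage < threshold & !is_confirmed
  splits <- filter(conf, .data$split)

  # fragment scaffolds at split offsets, over the SF-covered extent
  frags <- list()
  for (sc in unique(sfs$scaffold_id)) {
    ss <- sfs %>% filter(.data$scaffold_id == sc) %>% arrange(.data$s_start)
    cuts <- sort(splits$junction_offset[splits$scaffold_id == sc])
    bounds <- c(-Inf, cuts, Inf)
    for (j in seq_len(length(bounds) - 1)) {
      part <- filter(ss, .data$s_start >= bounds[j], .data$s_end <= bounds[j + 1])
      if (nrow(part) == 0) next
      frags[[length(frags) + 1]] <- list(
        scaffold_id = sc,
        s_start = min(part$s_start), s_end = max(part$s_end),
        sfs = part
      )
    }
  }
  if (length(frags) == 0) abort("no scaffold fragments (no SFs survived)")
  for (i in seq_along(frags)) frags[[i]]$id <- i

  # per-reference-chromosome order of fragment appearances
  appearances <- purrr::map_dfr(frags, function(f) {
    f$sfs %>%
      group_by(.data$ref_chrom) %>%
      summarise(mid = stats::median((.data$ref_start + .data$ref_end) / 2),
                .groups = "drop") %>%
      mutate(frag = f$id)
  })

  has_adj <- !is.null(adjacency) && nrow(adjacency) > 0

  # reference-space coordinates of a fragment's two scaffold ends
  frag_ends <- function(f) {
    sl <- f$sfs[which.min(f$sfs$s_start), ]
    sr <- f$sfs[which.max(f$sfs$s_end), ]
    list(
      L = list(chrom = sl$ref_chrom,
               pos = if (sl$strand == "+") sl$ref_start else sl$ref_end),
      R = list(chrom = sr$ref_chrom,
               pos = if (sr$strand == "+") sr$ref_end else sr$ref_start)
    )
  }
  end_dist <- function(e1, e2) {
    if (e1$chrom != e2$chrom) Inf else abs(e1$pos - e2$pos)
  }
  ends_of <- lapply(frags, frag_ends)

  # all fragment ends lying at a scaffold coordinate. After a split, the
  # junction coordinate is an end of both resulting fragments, so matches
  # can be ambiguous; the edge builder disambiguates by reference distance.
  frag_end_candidates <- function(scaffold, pos) {
    out <- list()
    for (f in frags) {
      if (f$scaffold_id != scaffold) next
      if (abs(pos - f$s_start) <= res) {
        out[[length(out) + 1]] <- list(id = f$id, side = "L")
      }
      if (abs(pos - f$s_end) <= res) {
        out[[length(out) + 1]] <- list(id = f$id, side = "R")
      }
    }
    out
  }
  best_end_pair <- function(cas, cbs) {
    best <- NULL; bd <- Inf
    for (ca in cas) for (cb in cbs) {
      if (ca$id == cb$id) next
      d <- end_dist(ends_of[[ca$id]][[ca$side]], ends_of[[cb$id]][[cb$side]])
      if (d < bd) { bd <- d; best <- list(a = ca, b = cb, dist = d) }
    }
    best
  }

  # chain edges: (fragment, side) pairs. With adjacency evidence, an edge
  # is a read-pair-supported scaffold-end adjacency; without it, chains
  # fall back to reference-consecutive order within each chromosome.
  edges <- list()
  if (has_adj) {
    # supported adjacencies to scaffolds absent from the SF set (too short
    # to align) are kept dangling and bridged pairwise below, so a chain
    # continues across a short unplaceable scaffold
    dangling <- list()
    for (i in seq_len(nrow(adjacency))) {
      r <- adjacency[i, ]
      if (r$spanning_pairs < threshold) next
      cas <- frag_end_candidates(r$scaffold_a, r$a_pos)
      cbs <- frag_end_candidates(r$scaffold_b, r$b_pos)
      if (length(cas) > 0 && length(cbs) > 0) {
        bp <- best_end_pair(cas, cbs)
        if (!is.null(bp)) {
          edges[[length(edges) + 1]] <- list(a = bp$a$id, sa = bp$a$side,
                                             b = bp$b$id, sb = bp$b$side)
        }
      } else if (length(cas) > 0 && length(cbs) == 0) {
        dangling[[length(dangling) + 1]] <- list(absent = r$scaffold_b,
                                                 cands = cas)
      } else if (length(cas) == 0 && length(cbs) > 0) {
        dangling[[length(dangling) + 1]] <- list(absent = r$scaffold_a,
                                                 cands = cbs)
      }
    }
    if (length(dangling) > 0) {
      absent_ids <- vapply(dangling, function(d) d$absent, character(1))
      for (sc in unique(absent_ids)) {
        dd <- dangling[absent_ids == sc]
        if (length(dd) == 2) {
          bp <- best_end_pair(dd[[1]]$cands, dd[[2]]$cands)
          # bridge only across a plausibly short gap on one chromosome
          if (!is.null(bp) && bp$dist <= 10 * res) {
            edges[[length(edges) + 1]] <- list(a = bp$a$id, sa = bp$a$side,
                                               b = bp$b$id, sb = bp$b$side)
          }
        }
      }
    }
  } else {
    # geometric fallback: reference-consecutive fragments, facing ends
    # chosen by smallest reference-space separation (computed below once
    # frag_ends is defined); stored with sides resolved lazily
    for (ch in unique(appearances$ref_chrom)) {
      ord <- appearances %>% filter(.data$ref_chrom == ch) %>% arrange(.data$mid)
      if (nrow(ord) < 2) next
      for (i in seq_len(nrow(ord) - 1)) {
        a <- ord$frag[i]; b <- ord$frag[i + 1]
        if (a == b) next
        edges[[length(edges) + 1]] <- list(a = a, sa = NA, b = b, sb = NA)
      }
    }
  }

  # resolve facing sides for geometric fallback edges
  for (i in seq_along(edges)) {
    e <- edges[[i]]
    if (!is.na(e$sa)) next
    combos <- expand.grid(a = c("L", "R"), b = c("L", "R"),
                          stringsAsFactors = FALSE)
    d <- apply(combos, 1, function(cc) {
      end_dist(ends_of[[e$a]][[cc[["a"]]]], ends_of[[e$b]][[cc[["b"]]]])
    })
    best <- combos[which.min(d), ]
    edges[[i]]$sa <- best$a
    edges[[i]]$sb <- best$b
  }
  # drop duplicate edges between the same fragment pair
  if (length(edges) > 0) {
    keys <- vapply(edges, function(e) {
      paste(sort(c(e$a, e$b)), collapse = "-")
    }, character(1))
    edges <- edges[!duplicated(keys)]
  }

  # connected components -> PCFs
  parent <- seq_along(frags)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (e in edges) parent[find(e$a)] <- find(e$b)
  comp <- vapply(seq_along(frags), find, integer(1))

  # per-fragment incident edges as (neighbour, own side, neighbour side)
  inc <- vector("list", length(frags))
  for (e in edges) {
    inc[[e$a]] <- c(inc[[e$a]], list(list(nbr = e$b, side = e$sa, nside = e$sb)))
    inc[[e$b]] <- c(inc[[e$b]], list(list(nbr = e$a, side = e$sb, nside = e$sa)))
  }
  # walk a component as a path, tracking the side each fragment is entered
  # through; returns ids and entry/exit sides
  order_component <- function(ids) {
    if (length(ids) == 1) {
      return(list(path = ids, entry = NA_character_, exit = NA_character_))
    }
    deg <- vapply(ids, function(i) length(inc[[i]]), integer(1))
    start <- ids[which(deg <= 1)][1]
    if (is.na(start)) start <- ids[1] # cycle fallback
    path <- start
    entry <- NA_character_
    exit <- character(0)
    cur <- start
    cur_entry <- NA_character_
    repeat {
      nxt <- NULL
      for (e in inc[[cur]]) {
        if (e$nbr %in% path) next
        if (!is.na(cur_entry) && e$side == cur_entry) next # leave by other side
        nxt <- e
        break
      }
      if (is.null(nxt)) {
        # allow leaving through any unvisited edge (fallback)
        for (e in inc[[cur]]) {
          if (!(e$nbr %in% path)) { nxt <- e; break }
        }
      }
      if (is.null(nxt)) break
      exit <- c(exit, nxt$side)
      path <- c(path, nxt$nbr)
      entry <- c(entry, nxt$nside)
      cur <- nxt$nbr
      cur_entry <- nxt$nside
    }
    list(path = c(path, setdiff(ids, path)),
         entry = entry, exit = c(exit, rep(NA_character_, 1)))
  }

  members <- list(); pcf_rows <- list()
  comp_ids <- unique(comp)
  # stable ordering of PCFs: by reference chromosome then midpoint
  first_app <- appearances %>%
    group_by(.data$frag) %>% slice(1) %>% ungroup()
  comp_key <- vapply(comp_ids, function(cid) {
    fa <- first_app %>% filter(.data$frag %in% which(comp == cid)) %>%
      arrange(.data$ref_chrom, .data$mid)
    paste0(fa$ref_chrom[1], sprintf("%015.0f", fa$mid[1]))
  }, character(1))
  comp_ids <- comp_ids[order(comp_key)]

  for (pi in seq_along(comp_ids)) {
    ids <- which(comp == comp_ids[pi])
    oc <- order_component(ids)
    path <- oc$path
    pcf_id <- sprintf("PCF%03d", pi)
    offset <- 0
    for (ri in seq_along(path)) {
      f <- frags[[path[ri]]]
      flen <- f$s_end - f$s_start
      # member strand = direction of scaffold coordinates along the PCF:
      # '+' when the chain enters at the scaffold fragment's low end (or,
      # for the first member, leaves from its high end)
      m <- if (length(path) == 1) "+"
           else if (ri == 1) {
             if (!is.na(oc$exit[1]) && oc$exit[1] == "L") "-" else "+"
           } else {
             if (!is.na(oc$entry[ri]) && oc$entry[ri] == "R") "-" else "+"
           }
      members[[length(members) + 1]] <- tibble(
        pcf_id = pcf_id, rank = ri, scaffold_id = f$scaffold_id,
        s_start = f$s_start, s_end = f$s_end, strand = m,
        pcf_start = offset, pcf_end = offset + flen
      )
      offset <- offset + flen
    }
    chroms <- unique(unlist(lapply(path, function(i) frags[[i]]$sfs$ref_chrom)))
    pcf_rows[[pi]] <- tibble(pcf_id = pcf_id, n_members = length(path),
                             length = offset,
                             ref_chroms = paste(chroms, collapse = ","))
  }

  structure(list(pcfs = bind_rows(pcf_rows), members = bind_rows(members),
                 splits = splits, threshold = threshold, sfs = sfs),
            class = "karyo_pcf_set")
}

#' @export
print.karyo_pcf_set <- function(x, ...) {
  cat("<karyo_pcf_set> ", nrow(x$pcfs), " PCFs, ",
      format(sum(x$pcfs$length), big.mark = ","), " bp, ",
      nrow(x$splits), " split joins (threshold ", x$threshold, ")\n", sep = "")
  invisible(x)
}

#' Assembly statistics for a PCF set
#'
#' @param pcf_set A `karyo_pcf_set`.
#' @param scaffolds Original scaffold tibble (`scaffold_id`, `length`).
#' @return One-row [assembly_stats()] tibble (percent relative to the
#'   original scaffold total).
#' @export
pcf_stats <- function(pcf_set, scaffolds) {
  assembly_stats(pcf_set$pcfs$length, sum(scaffolds$length))
}
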