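# Cutting a derived karyotype into scaffolds, injecting chimeric joins, and
# emitting everything a reference-assisted assembler would observe:
# alignment blocks, spanning-pair coverage, adjacency support, an in-silico
# PCR oracle and a BAC/FISH panel.

#' Fragment a karyotype into scaffolds and emit observables
#'
#' Cuts every derived chromosome into scaffold pieces at random positions.
#' With probability `chimera_rate`, two pieces from non-adjacent loci
#' (different chromosomes, or >= 1 Mb apart) are concatenated into a single
#' chimeric scaffold whose junction is registered. Emits:
#' \itemize{
#'   \item `scaffolds`: `scaffold_id`, `length`;
#'   \item `blocks`: alignment blocks `ref_chrom ref_start ref_end
#'     tgt_scaffold tgt_start tgt_end strand` (0-based half-open), tiling
#'     each scaffold exactly;
#'   \item `coverage`: spanning-pair physical coverage at every
#'     intra-scaffold junction, Poisson(`lambda_true`) at true joins and
#'     Poisson(`lambda_chim`) at chimeric joins;
#'   \item `adjacency`: spanning-pair support across consecutive scaffold
#'     ends in the derived karyotype (the read-pair evidence used to chain
#'     scaffolds into predicted chromosome fragments);
#'   \item `truth`: join registry (`chimeric` flag per junction), piece map
#'     and derived loci, for recovery tests.
#' }
#'
#' @param karyotype A `karyo_karyotype` (see [apply_rearrangements()]).
#' @param config A [sim_config()].
#' @return A list as described above.
#' @export
fragment_and_observe <- function(karyotype, config) {
  stopifnot(inherits(config, "sim_config"))
  lens <- karyotype_lengths(karyotype)
  n_chrom <- nrow(lens)
  if (config$n_scaffolds < n_chrom) abort("fewer scaffolds than chromosomes")

  extra <- config$n_scaffolds - n_chrom
  alloc <- if (extra > 0) {
    as.vector(stats::rmultinom(1, extra, prob = lens$length))
  } else rep(0, n_chrom)

  pieces <- list()
  pid <- 0
  for (i in seq_len(n_chrom)) {
    L <- lens$length[i]
    k <- alloc[i]
    cuts <- sort(unique(floor(stats::runif(k, 1, L - 1))))
    bounds <- c(0, cuts, L)
    for (j in seq_len(length(bounds) - 1)) {
      pid <- pid + 1
      pieces[[pid]] <- tibble(piece_id = pid, chrom = lens$chrom[i],
                              d_start = bounds[j], d_end = bounds[j + 1],
                              piece_rank = j)
    }
  }
  pieces <- bind_rows(pieces)
  n_pieces <- nrow(pieces)

  # pair pieces into chimeric scaffolds
  n_chim <- min(round(config$chimera_rate * n_pieces), floor(n_pieces / 2))
  unassigned <- pieces$piece_id
  chim_pairs <- list()
  while (length(chim_pairs) < n_chim && length(unassigned) >= 2) {
    placed <- FALSE
    for (try in 1:50) {
      pr <- sample(unassigned, 2)
      a <- pieces[pieces$piece_id == pr[1], ]
      b <- pieces[pieces$piece_id == pr[2], ]
      apart <- a$chrom != b$chrom ||
        max(a$d_start, b$d_start) - min(a$d_end, b$d_end) >= 1e6
      if (apart) {
        chim_pairs[[length(chim_pairs) + 1]] <- pr
        unassigned <- setdiff(unassigned, pr)
        placed <- TRUE
        break
      }
    }
    if (!placed) break
  }

  # scaffold membership: scaffold_id, piece order, flip
  memb <- list()
  sid <- 0
  for (pr in chim_pairs) {
    sid <- sid + 1
    memb[[sid]] <- tibble(scaffold = sid, piece_id = pr,
                          s_rank = 1:2,
                          flipped = stats::runif(2) < 0.5)
  }
  for (p in unassigned) {
    sid <- sid + 1
    memb[[sid]] <- tibble(scaffold = sid, piece_id = p, s_rank = 1, flipped = FALSE)
  }
  memb <- bind_rows(memb)
  # shuffle public scaffold ids so ids carry no positional signal
  ids <- sample(sprintf("S%04d", seq_len(sid)))
  memb$scaffold_id <- ids[memb$scaffold]
  memb <- left_join(memb, pieces, by = "piece_id") %>%
    mutate(piece_len = .data$d_end - .data$d_start) %>%
    arrange(.data$scaffold, .data$s_rank) %>%
    group_by(.data$scaffold) %>%
    mutate(s_start = cumsum(c(0, .data$piece_len))[seq_len(n())],
           s_end = .data$s_start + .data$piece_len) %>%
    ungroup()

  scaffolds <- memb %>%
    group_by(.data$scaffold_id) %>%
    summarise(length = sum(.data$piece_len), .groups = "drop")

  # alignment blocks: decompose each piece through the karyotype segment map
  blocks <- list()
  for (ch in unique(memb$chrom)) {
    segs <- segs_with_bounds(karyotype, ch)
    mm <- filter(memb, .data$chrom == ch)
    for (i in seq_len(nrow(mm))) {
      p <- mm[i, ]
      ov <- filter(segs, .data$d_end > p$d_start, .data$d_start < p$d_end)
      for (j in seq_len(nrow(ov))) {
        r <- ov[j, ]
        x <- pmax(r$d_start, p$d_start); y <- pmin(r$d_end, p$d_end)
        # ancestor interval of derived [x, y)
        if (r$strand == "+") {
          ra <- r$anc_start + (x - r$d_start); rb <- r$anc_start + (y - r$d_start)
        } else {
          rb <- r$anc_end - (x - r$d_start); ra <- r$anc_end - (y - r$d_start)
        }
        # scaffold interval of derived [x, y)
        if (!p$flipped) {
          ta <- p$s_start + (x - p$d_start); tb <- p$s_start + (y - p$d_start)
          strand <- r$strand
        } else {
          ta <- p$s_start + (p$d_end - y); tb <- p$s_start + (p$d_end - x)
          strand <- if (r$strand == "+") "-" else "+"
        }
        blocks[[length(blocks) + 1]] <- tibble(
          ref_chrom = r$anc_chrom, ref_start = ra, ref_end = rb,
          tgt_scaffold = p$scaffold_id, tgt_start = ta, tgt_end = tb,
          strand = strand
        )
      }
    }
  }
  blocks <- bind_rows(blocks) %>% arrange(.data$tgt_scaffold, .data$tgt_start)

  # intra-scaffold junctions: every internal block boundary; chimeric ones
  # are the piece1|piece2 seams
  two_piece <- memb %>%
    group_by(.data$scaffold_id) %>%
    filter(n() == 2) %>%
    ungroup()
  chim_offsets <- if (nrow(two_piece) > 0) {
    two_piece %>%
      group_by(.data$scaffold_id) %>%
      summarise(junction_offset = min(.data$s_end), .groups = "drop")
  } else {
    tibble(scaffold_id = character(), junction_offset = numeric())
  }
  junctions <- blocks %>%
    group_by(.data$tgt_scaffold) %>%
    arrange(.data$tgt_start, .by_group = TRUE) %>%
    mutate(is_last = row_number() == n()) %>%
    ungroup() %>%
    filter(!.data$is_last) %>%
    transmute(scaffold_id = .data$tgt_scaffold, junction_offset = .data$tgt_end)
  junctions <- junctions %>%
    left_join(mutate(chim_offsets, chimeric = TRUE),
              by = c("scaffold_id", "junction_offset")) %>%
    mutate(chimeric = !is.na(.data$chimeric))
  junctions$spanning_pairs <- stats::rpois(
    nrow(junctions),
    ifelse(junctions$chimeric, config$lambda_chim, config$lambda_true)
  )
  coverage <- junctions[c("scaffold_id", "junction_offset", "spanning_pairs")]

  # inter-scaffold adjacency support along the derived karyotype
  adj <- list()
  memb_by_piece <- memb[match(pieces$piece_id, memb$piece_id), ]
  for (ch in lens$chrom) {
    pp <- pieces %>% filter(.data$chrom == ch) %>% arrange(.data$piece_rank)
    if (nrow(pp) < 2) next
    for (i in seq_len(nrow(pp) - 1)) {
      a <- memb_by_piece[match(pp$piece_id[i], memb_by_piece$piece_id), ]
      b <- memb_by_piece[match(pp$piece_id[i + 1], memb_by_piece$piece_id), ]
      a_pos <- if (!a$flipped) a$s_end else a$s_start
      b_pos <- if (!b$flipped) b$s_start else b$s_end
      adj[[length(adj) + 1]] <- tibble(
        scaffold_a = a$scaffold_id, a_pos = a_pos,
        scaffold_b = b$scaffold_id, b_pos = b_pos,
        spanning_pairs = stats::rpois(1, config$lambda_true)
      )
    }
  }
  adjacency <- bind_rows(adj)
  if (length(adj) == 0) {
    adjacency <- tibble(scaffold_a = character(), a_pos = numeric(),
                        scaffold_b = character(), b_pos = numeric(),
                        spanning_pairs = numeric())
  }

  list(
    scaffolds = scaffolds,
    blocks = blocks,
    coverage = coverage,
    adjacency = adjacency,
    truth = list(
      joins = junctions[c("scaffold_id", "junction_offset", "chimeric")],
      pieces = memb[c("scaffold_id", "s_rank", "flipped", "chrom",
                      "d_start", "d_end", "s_start", "s_end")]
    )
  )
}

#' In-silico PCR verdicts for scaffold split regions
#'
#' Mirrors the wet-lab testability rule: split regions spanning 6 kbp or
#' more cannot be reliably amplified and are `untestable`; below that, the
#' verdict is `confirmed` for true joins and `refuted` for chimeric joins,
#' optionally flipped at `error_rate`.
#'
#' @param joins Tibble with `scaffold_id`, `junction_offset` and `span` (bp
#'   between the flanking syntenic fragments).
#' @param truth The `truth` element returned by [fragment_and_observe()].
#' @param error_rate Probability of a flipped verdict (default 0).
#' @param tol Offset tolerance (bp) when matching junctions to the registry.
#' @return `joins` with a `pcr_status` column in
#'   \{`confirmed`, `refuted`, `untestable`\}.
#' @export
pcr_oracle <- function(joins, truth, error_rate = 0, tol = 0) {
  joins <- as_tibble(joins)
  reg <- truth$joins
  status <- character(nrow(joins))
  for (i in seq_len(nrow(joins))) {
    hit <- reg[reg$scaffold_id == joins$scaffold_id[i] &
                 abs(reg$junction_offset - joins$junction_offset[i]) <= tol, ]
    if (nrow(hit) == 0) abort("pcr_oracle: unknown join")
    if (joins$span[i] >= 6000) {
      status[i] <- "untestable"
    } else {
      status[i] <- if (hit$chimeric[1]) "refuted" else "confirmed"
      if (error_rate > 0 && stats::runif(1) < error_rate) {
        status[i] <- if (status[i] == "confirmed") "refuted" else "confirmed"
      }
    }
  }
  joins$pcr_status <- status
  joins
}

#' Emit a BAC marker panel and FISH-style observations
#'
#' Markers are placed every ~`spacing` bp on the ancestor; the observed
#' order per derived chromosome is the marker order after applying the
#' karyotype coordinate map (what a FISH experiment would report).
#'
#' @param karyotype A `karyo_karyotype`.
#' @param spacing Marker spacing on the ancestor (bp).
#' @param dropout Fraction of markers removed from the observation set.
#' @return A list: `bacs` (`bac_id`, `ref_chrom`, `ref_pos`),
#'   `observations` (`bac_id`, `chrom`, `order_index`), and
#'   `truth_positions` (derived coordinates per marker).
#' @export
emit_bac_panel <- function(karyotype, spacing, dropout = 0) {
  stopifnot(spacing > 0)
  segs <- karyotype$segments
  anc_lens <- segs %>%
    group_by(chrom = .data$anc_chrom) %>%
    summarise(length = max(.data$anc_end), .groups = "drop")
  bacs <- purrr::pmap_dfr(anc_lens, function(chrom, length) {
    if (spacing / 2 >= length) return(tibble())
    pos <- seq(spacing / 2, length - 1, by = spacing)
    tibble(ref_chrom = chrom, ref_pos = floor(pos))
  })
  if (nrow(bacs) == 0) abort("spacing larger than every chromosome")
  bacs$bac_id <- sprintf("BAC%04d", seq_len(nrow(bacs)))
  bacs <- bacs[c("bac_id", "ref_chrom", "ref_pos")]

  # derived position of each marker
  dpos <- list()
  for (ch in karyotype$chrom_order) {
    s <- segs_with_bounds(karyotype, ch)
    for (i in seq_len(nrow(s))) {
      r <- s[i, ]
      inb <- filter(bacs, .data$ref_chrom == r$anc_chrom,
                    .data$ref_pos >= r$anc_start, .data$ref_pos < r$anc_end)
      if (nrow(inb) == 0) next
      d <- if (r$strand == "+") r$d_start + (inb$ref_pos - r$anc_start)
           else r$d_start + (r$anc_end - 1 - inb$ref_pos)
      dpos[[length(dpos) + 1]] <- tibble(bac_id = inb$bac_id, chrom = ch, pos = d)
    }
  }
  truth_positions <- bind_rows(dpos)

  obs <- truth_positions %>%
    group_by(.data$chrom) %>%
    arrange(.data$pos, .by_group = TRUE) %>%
    mutate(order_index = row_number()) %>%
    ungroup() %>%
    select("bac_id", "chrom", "order_index")
  if (dropout > 0) {
    keep <- stats::runif(nrow(obs)) >= dropout
    obs <- obs[keep, ] %>%
      group_by(.data$chrom) %>%
      arrange(.data$order_index, .by_group = TRUE) %>%
      mutate(order_index = row_number()) %>%
      ungroup()
  }
  list(bacs = bacs, observations = obs, truth_positions = truth_positions)
}
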