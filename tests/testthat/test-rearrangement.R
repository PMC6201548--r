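seg_row <- function(tgt, ts, te, unit, rs, re, strand = "+") {
  tibble::tibble(tgt_chrom = tgt, tgt_start = ts, tgt_end = te,
                 ref_unit = unit, ref_start = rs, ref_end = re,
                 strand = strand)
}

test_that("homology maps merge colinear same-unit segments and drop slivers", {
  segs <- dplyr::bind_rows(
    seg_row("t1", 0, 4e5, "u1", 0, 4e5),
    seg_row("t1", 4e5, 8e5, "u1", 4e5, 8e5),        # colinear: merges
    seg_row("t1", 8e5, 8.4e5, "u2", 0, 4e4),        # sliver: dropped
    seg_row("t1", 8.4e5, 1.2e6, "u2", 2e6, 2.36e6)  # distinct unit
  )
  m <- build_homology_map(segs, min_size = 1e5)
  expect_equal(nrow(m), 2)
  expect_equal(m$ref_end[1], 8e5)
  expect_equal(m$ref_unit, c("u1", "u2"))
  # a strand flip blocks merging
  segs2 <- dplyr::bind_rows(seg_row("t1", 0, 4e5, "u1", 0, 4e5),
                            seg_row("t1", 4e5, 8e5, "u1", 4e5, 8e5, "-"))
  expect_equal(nrow(build_homology_map(segs2, min_size = 1e5)), 2)
  # unit-set relabelling collapses arms
  segs3 <- dplyr::bind_rows(seg_row("t1", 0, 4e5, "4q", 0, 4e5),
                            seg_row("t2", 0, 4e5, "4p", 0, 4e5))
  m3 <- build_homology_map(segs3, units = "chicken", min_size = 1e5)
  expect_equal(unique(m3$ref_unit), "4")
})

test_that("event counting applies junction and piece conventions", {
  # identity: nothing
  id <- build_homology_map(dplyr::bind_rows(
    seg_row("t1", 0, 1e6, "u1", 0, 1e6), seg_row("t2", 0, 1e6, "u2", 0, 1e6)))
  ec0 <- count_interchromosomal_events(id)
  expect_equal(c(ec0$n_fusions, ec0$n_fissions), c(0, 0))
  expect_setequal(ec0$intact_units, c("u1", "u2"))
  # one chromosome concatenating 3 units: 2 fusions; a unit on 2 targets: 1 fission
  m <- build_homology_map(dplyr::bind_rows(
    seg_row("t1", 0, 1e6, "a", 0, 1e6),
    seg_row("t1", 1e6, 2e6, "b", 0, 1e6),
    seg_row("t1", 2e6, 3e6, "c", 0, 1e6),
    seg_row("t2", 0, 1e6, "d", 0, 1e6),
    seg_row("t3", 0, 1e6, "d", 1e6, 2e6)))
  ec <- count_interchromosomal_events(m)
  expect_equal(ec$n_fusions, 2)
  expect_equal(ec$n_fissions, 1)
  expect_equal(ec$n_intact_units, 0)
  expect_true(ec$identity_holds) # 3 targets = 4 units + 1 - 2
  # adjacent same-unit segments (inversion structure) are not junctions
  m2 <- build_homology_map(dplyr::bind_rows(
    seg_row("t1", 0, 1e6, "a", 0, 1e6),
    seg_row("t1", 1e6, 2e6, "a", 1e6, 2e6, "-"),
    seg_row("t1", 2e6, 3e6, "a", 2e6, 3e6)))
  expect_equal(count_interchromosomal_events(m2)$n_fusions, 0)
  expect_error(count_interchromosomal_events(id[0, ]))
})

test_that("EBR detection recovers planted breakpoints with classes", {
  # colinear map -> empty set
  id <- build_homology_map(seg_row("t1", 0, 1e6, "u1", 0, 1e6))
  expect_equal(nrow(detect_ebrs(id)), 0)
  # one inversion -> two intrachromosomal EBRs at the planted breakpoints
  p1 <- 4e5; p2 <- 7e5
  m_inv <- build_homology_map(dplyr::bind_rows(
    seg_row("t1", 0, p1, "u1", 0, p1),
    seg_row("t1", p1, p2, "u1", p1, p2, "-"),
    seg_row("t1", p2, 1e6, "u1", p2, 1e6)), min_size = 1e5)
  e1 <- detect_ebrs(m_inv)
  expect_equal(nrow(e1), 2)
  expect_true(all(e1$class == "intrachromosomal"))
  for (p in c(p1, p2)) {
    expect_true(any(e1$start >= p - 1 & e1$end <= p + 1))
  }
  # one fission -> one fission EBR containing the cut
  m_fis <- build_homology_map(dplyr::bind_rows(
    seg_row("tA", 0, 6e5, "u1", 0, 6e5),
    seg_row("tB", 0, 4e5, "u1", 6e5, 1e6)), min_size = 1e5)
  e2 <- detect_ebrs(m_fis)
  expect_equal(e2$class, "fission")
  expect_true(e2$start <= 6e5 && e2$end >= 6e5 - 1)
  # fusion: one EBR at each flanking reference breakpoint
  m_fus <- build_homology_map(dplyr::bind_rows(
    seg_row("t1", 0, 6e5, "u1", 0, 6e5),
    seg_row("t1", 6e5, 1e6, "u2", 2e5, 6e5)), min_size = 1e5)
  e3 <- detect_ebrs(m_fus)
  expect_equal(sort(e3$class), c("fusion", "fusion"))
  expect_setequal(e3$chrom, c("u1", "u2"))
  # oversize EBRs are kept but flagged excluded
  m_gap <- build_homology_map(dplyr::bind_rows(
    seg_row("t1", 0, 6e5, "u1", 0, 6e5),
    seg_row("t1", 6e5, 1e6, "u1", 9e5, 1.3e6)), min_size = 1e5)
  e4 <- detect_ebrs(m_gap, max_len = 1e5)
  expect_true(all(e4$excluded))
  expect_false(any(detect_ebrs(m_gap, max_len = 1e6)$excluded))
})

test_that("planted events and EBRs correspond one-to-one on clean runs", {
  set.seed(40)
  for (r in 1:3) {
    cfg <- test_sim_config(chimera_rate = 0, n_inversions = 2, n_fusions = 2,
                           n_fissions = 1)
    g <- generate_ancestor(cfg)
    rr <- apply_rearrangements(g, cfg)
    obs <- fragment_and_observe(rr$karyotype, cfg)
    p <- test_params()
    sfs <- build_syntenic_fragments(obs$blocks, p)
    pcfs <- assemble_pcfs(obs$scaffolds, sfs, obs$coverage, p,
                          adjacency = obs$adjacency, threshold = 100)
    panel <- emit_bac_panel(rr$karyotype, cfg$bac_spacing)
    asm <- anchor(pcfs, locate_bacs_on_pcfs(panel$bacs, pcfs),
                  panel$observations)
    map <- build_homology_map(assembly_segments(asm),
                              min_size = p$resolution,
                              merge_gap = p$resolution)
    found <- detect_ebrs(map, genome = g)
    planted <- truth_to_ebrs(rr$truth, g)
    expect_equal(nrow(found), nrow(planted))
    # each planted breakpoint has exactly one detected EBR nearby, same class
    tol <- 3 * p$resolution
    for (i in seq_len(nrow(planted))) {
      hit <- found[found$chrom == planted$chrom[i] &
                     found$start < planted$end[i] + tol &
                     found$end > planted$start[i] - tol, ]
      expect_equal(nrow(hit), 1)
      expect_equal(hit$class, planted$class[i])
    }
    # classes partition the set
    expect_true(all(found$class %in% c("fusion", "fission", "intrachromosomal")))
  }
})

test_that("reversal distances are exact for small permutations", {
  expect_equal(as.numeric(estimate_inversions(c(1, 2, 3))), 0)
  expect_equal(as.numeric(estimate_inversions(c(1, -2, 3))), 1)
  expect_equal(as.numeric(estimate_inversions(c(-3, -2, -1))), 1)
  expect_equal(attr(estimate_inversions(c(1, -2, 3)), "method"), "exact")
  expect_error(estimate_inversions(c(1, 3)))
  expect_error(estimate_inversions(integer(0)))
  # exhaustive agreement with an independent per-input BFS for n <= 3
  for (p in all_signed_perms(3)) {
    expect_equal(as.numeric(estimate_inversions(p)), reversal_bfs_oracle(p))
  }
  # beyond the exact range the labelled breakpoint bound is returned
  big <- c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9, 12, 11)
  est <- estimate_inversions(big)
  expect_equal(attr(est, "method"), "lower_bound")
  expect_true(as.numeric(est) >= 1)
})

test_that("per-unit inversion estimates read signed segment order", {
  m <- build_homology_map(dplyr::bind_rows(
    seg_row("t1", 0, 4e5, "u1", 0, 4e5),
    seg_row("t1", 4e5, 7e5, "u1", 4e5, 7e5, "-"),
    seg_row("t1", 7e5, 1e6, "u1", 7e5, 1e6)), min_size = 1e5)
  iv <- inversions_from_map(m)
  expect_equal(iv$inversions, 1L)
  expect_equal(iv$method, "exact")
})
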