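block_row <- function(rc, rs, re, sc, ts, te, strand = "+") {
  tibble::tibble(ref_chrom = rc, ref_start = rs, ref_end = re,
                 tgt_scaffold = sc, tgt_start = ts, tgt_end = te,
                 strand = strand)
}

test_that("syntenic fragments merge colinear blocks and break on strand", {
  p <- assembly_params(resolution = 150000)
  # single block -> one SF equal to the block
  b1 <- block_row("r1", 0, 5e5, "s1", 0, 5e5)
  sf1 <- build_syntenic_fragments(b1, p)
  expect_equal(nrow(sf1), 1)
  expect_equal(sf1$s_end - sf1$s_start, 5e5)
  # two colinear 200-kb blocks with 50-kb gaps merge across the gap
  b2 <- dplyr::bind_rows(block_row("r1", 0, 2e5, "s1", 0, 2e5),
                         block_row("r1", 2.5e5, 4.5e5, "s1", 2.5e5, 4.5e5))
  sf2 <- build_syntenic_fragments(b2, p)
  expect_equal(nrow(sf2), 1)
  expect_equal(c(sf2$ref_start, sf2$ref_end), c(0, 4.5e5))
  # opposite strands never merge
  b3 <- dplyr::bind_rows(block_row("r1", 0, 2e5, "s1", 0, 2e5),
                         block_row("r1", 2e5, 4e5, "s1", 2e5, 4e5, "-"))
  expect_equal(nrow(build_syntenic_fragments(b3, p)), 2)
  # sub-resolution fragments are discarded; malformed blocks error
  b4 <- dplyr::bind_rows(block_row("r1", 0, 5e5, "s1", 0, 5e5),
                         block_row("r2", 0, 1e4, "s2", 0, 1e4))
  expect_equal(build_syntenic_fragments(b4, p)$scaffold_id, "s1")
  expect_error(build_syntenic_fragments(block_row("r1", 5, 2, "s1", 0, 3), p))
})

test_that("conflicting joins are flagged by chromosome, gap and strand rules", {
  p <- assembly_params(resolution = 150000)
  mk <- function(...) build_syntenic_fragments(dplyr::bind_rows(...), p)
  # adjacent and colinear: no conflict
  ok <- find_conflicting_joins(mk(
    block_row("r1", 0, 3e5, "s1", 0, 3e5),
    block_row("r1", 3e5, 6e5, "s1", 3.5e5, 6.5e5)), p)
  expect_false(any(ok$conflict))
  # different reference chromosomes
  j1 <- find_conflicting_joins(mk(
    block_row("r1", 0, 3e5, "s1", 0, 3e5),
    block_row("r2", 0, 3e5, "s1", 3e5, 6e5)), p)
  expect_true(j1$conflict)
  expect_equal(j1$reason, "different_chromosome")
  # same chromosome, 5-Mb reference gap
  j2 <- find_conflicting_joins(mk(
    block_row("r1", 0, 3e5, "s1", 0, 3e5),
    block_row("r1", 5.3e6, 5.6e6, "s1", 3e5, 6e5)), p)
  expect_true(j2$conflict)
  expect_equal(j2$reason, "reference_gap")
  # strand geometry
  j3 <- find_conflicting_joins(mk(
    block_row("r1", 0, 3e5, "s1", 0, 3e5),
    block_row("r1", 3e5, 6e5, "s1", 3e5, 6e5, "-")), p)
  expect_equal(j3$reason, "strand_flip")
  # single-SF scaffolds yield no joins
  expect_equal(nrow(find_conflicting_joins(mk(block_row("r1", 0, 3e5, "s1", 0, 3e5)), p)), 0)
})

test_that("threshold calibration maximises PCR agreement, smallest tie-break", {
  j <- tibble::tibble(coverage = c(10, 50, 100),
                      pcr_status = c("refuted", "confirmed", "confirmed"))
  cal <- calibrate_threshold(j)
  expect_equal(cal$threshold, 11)
  expect_equal(cal$agreement, 3)
  # all confirmed -> nothing split (threshold 0)
  j2 <- tibble::tibble(coverage = c(5, 50), pcr_status = "confirmed")
  expect_equal(calibrate_threshold(j2)$threshold, 0)
  # untestable joins contribute nothing
  j3 <- dplyr::bind_rows(j, tibble::tibble(coverage = 1, pcr_status = "untestable"))
  expect_equal(calibrate_threshold(j3)$threshold, 11)
  expect_equal(calibrate_threshold(j3)$n_tested, 3)
  expect_error(calibrate_threshold(tibble::tibble(coverage = 1,
                                                  pcr_status = "untestable")))
  # glance/tidy surface
  expect_equal(glance(cal)$agreement_rate, 1)
  expect_true(all(tidy(cal)$agreement <= cal$agreement))
})

test_that("calibration separates the two Poisson coverage regimes", {
  set.seed(20)
  hits <- 0
  for (r in 1:25) {
    n_chim <- rbinom(1, 30, 0.4)
    cov <- c(rpois(30 - n_chim, 400), rpois(max(n_chim, 1), 5))
    st <- c(rep("confirmed", 30 - n_chim), rep("refuted", max(n_chim, 1)))
    cal <- calibrate_threshold(tibble::tibble(coverage = cov, pcr_status = st))
    if (cal$threshold > 5 && cal$threshold <= 400 &&
        cal$agreement == length(cov)) hits <- hits + 1
  }
  expect_gte(hits, 24)
})

test_that("clean simulations assemble without splits and keep every SF base", {
  set.seed(21)
  cfg <- test_sim_config(chimera_rate = 0)
  g <- generate_ancestor(cfg)
  rr <- apply_rearrangements(g, cfg)
  obs <- fragment_and_observe(rr$karyotype, cfg)
  p <- test_params()
  sfs <- build_syntenic_fragments(obs$blocks, p)
  pcfs <- assemble_pcfs(obs$scaffolds, sfs, obs$coverage, p,
                        adjacency = obs$adjacency, threshold = 100)
  expect_equal(nrow(pcfs$splits), 0)
  # no base lost or duplicated relative to the SF-covered scaffold space
  sf_bases <- sum(sfs$s_end - sfs$s_start)
  expect_equal(sum(pcfs$members$s_end - pcfs$members$s_start), sf_bases)
  expect_false(any(duplicated(pcfs$members[c("scaffold_id", "s_start")])))
  # one PCF per derived chromosome region (here: per derived chromosome)
  expect_equal(nrow(pcfs$pcfs), nrow(karyotype_lengths(rr$karyotype)))
  st <- pcf_stats(pcfs, obs$scaffolds)
  expect_equal(st$pct_placed,
               round(100 * sum(pcfs$pcfs$length) / sum(obs$scaffolds$length), 2))
})

test_that("planted chimeras are split and thresholds act monotonically", {
  set.seed(22)
  cfg <- test_sim_config(chimera_rate = 0.15, n_scaffolds = 60)
  g <- generate_ancestor(cfg)
  rr <- apply_rearrangements(g, cfg)
  obs <- fragment_and_observe(rr$karyotype, cfg)
  p <- test_params()
  sfs <- build_syntenic_fragments(obs$blocks, p)
  pcfs <- assemble_pcfs(obs$scaffolds, sfs, obs$coverage, p,
                        adjacency = obs$adjacency, threshold = 100)
  truth_ch <- obs$truth$joins[obs$truth$joins$chimeric, ]
  # every split corresponds to a true chimeric junction
  m <- dplyr::inner_join(pcfs$splits, truth_ch,
                         by = c("scaffold_id", "junction_offset"))
  expect_equal(nrow(m), nrow(pcfs$splits))
  # raising the threshold never decreases the number of splits
  n_at <- vapply(c(0, 2, 50, 100), function(thr) {
    nrow(assemble_pcfs(obs$scaffolds, sfs, obs$coverage, p,
                       adjacency = obs$adjacency, threshold = thr)$splits)
  }, numeric(1))
  expect_true(all(diff(n_at) >= 0))
  # PCR-confirmed joins are never split even under the threshold
  conf <- truth_ch[c("scaffold_id", "junction_offset")]
  kept <- assemble_pcfs(obs$scaffolds, sfs, obs$coverage, p,
                        confirmed = conf, adjacency = obs$adjacency,
                        threshold = 100)
  expect_equal(nrow(kept$splits), 0)
})
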