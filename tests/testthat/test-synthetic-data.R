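test_that("generate_ancestor hits the target CNE density and is deterministic", {
  cfg <- sim_config(n_macro = 1, n_micro = 0, macro_len_range = c(1e7, 1e7),
                    seed = 42)
  g <- generate_ancestor(cfg)
  realized <- sum(g$tracks$CNE$end - g$tracks$CNE$start) / genome_length(g)
  expect_true(realized >= 0.082 && realized <= 0.092)
  # same seed, identical interval sets
  g2 <- generate_ancestor(cfg)
  expect_identical(g$tracks$CNE, g2$tracks$CNE)
  expect_identical(g$tracks$msHSB, g2$tracks$msHSB)
  # zero target -> empty track; infeasible density errors
  g0 <- generate_ancestor(sim_config(cne_target_density = 0, seed = 1))
  expect_equal(nrow(g0$tracks$CNE), 0)
  expect_error(sim_config(cne_target_density = 1.2))
})

test_that("msHSBs are CNE-enriched at about the configured ratio", {
  set.seed(5)
  g <- generate_ancestor(sim_config(seed = 5))
  ms <- g$tracks$msHSB
  d_in <- sum(cne_fraction(ms, g) * (ms$end - ms$start)) / sum(ms$end - ms$start)
  expect_gt(d_in, 0.095)
  expect_lt(d_in, 0.12)
})

test_that("sample_breakpoint is uniform at gamma 0 and avoids CNEs as gamma grows", {
  set.seed(6)
  g <- generate_ancestor(sim_config(n_macro = 2, n_micro = 0,
                                    macro_len_range = c(2e6, 3e6), seed = 6))
  # gamma = 0: chi-squared GOF against the uniform over windows
  bp <- sample_breakpoint(g, gamma = 0, n = 1e4)
  w <- tile_windows(g, 1000)
  # aggregate windows into 25 equal-probability bins for a stable GOF test
  wkey <- paste(w$chrom, w$start %/% 1000)
  bin <- cut(match(paste(bp$chrom, bp$pos %/% 1000), wkey), breaks = 25)
  expect_gt(stats::chisq.test(table(bin))$p.value, 0.01)
  # all mass on the CNE-free window when the other is saturated
  g2 <- karyo_genome(tibble::tibble(chrom = "c", length = 2000),
                     tracks = list(CNE = tibble::tibble(chrom = "c", start = 0,
                                                        end = 1000)))
  bp2 <- sample_breakpoint(g2, gamma = 1, n = 200)
  expect_true(all(bp2$pos >= 1000))
  # larger gamma lowers the mean sampled CNE density
  d_at <- function(gam) {
    bp <- sample_breakpoint(g, gamma = gam, n = 1e4)
    win <- tibble::tibble(chrom = bp$chrom, start = (bp$pos %/% 1000) * 1000,
                          end = (bp$pos %/% 1000) * 1000 + 1000)
    mean(cne_fraction(win, g))
  }
  set.seed(7)
  expect_lt(d_at(8), d_at(2))
  # degenerate: every window fully covered
  g3 <- karyo_genome(tibble::tibble(chrom = "c", length = 1000),
                     tracks = list(CNE = tibble::tibble(chrom = "c", start = 0,
                                                        end = 1000)))
  expect_error(sample_breakpoint(g3, gamma = 1))
})

test_that("rearrangements conserve sequence and CNE content", {
  set.seed(8)
  cfg <- test_sim_config(n_inversions = 3, n_fusions = 2, n_fissions = 2)
  g <- generate_ancestor(cfg)
  rr <- apply_rearrangements(g, cfg)
  dg <- karyotype_as_genome(rr$karyotype, g)
  expect_equal(genome_length(dg), genome_length(g))
  expect_equal(sum(dg$tracks$CNE$end - dg$tracks$CNE$start),
               sum(g$tracks$CNE$end - g$tracks$CNE$start))
  expect_equal(nrow(rr$truth), 7)
  tab <- table(rr$truth$type)
  expect_equal(as.numeric(tab[c("fission", "fusion", "inversion")]), c(2, 2, 3))
  # zero events: identity
  rr0 <- apply_rearrangements(g, test_sim_config(n_inversions = 0,
                                                 n_fusions = 0, n_fissions = 0))
  expect_equal(karyotype_lengths(rr0$karyotype)$length, g$chroms$length)
  # one fusion: one fewer chromosome, total length conserved
  rr1 <- apply_rearrangements(g, test_sim_config(n_inversions = 0,
                                                 n_fusions = 1, n_fissions = 0))
  expect_equal(nrow(karyotype_lengths(rr1$karyotype)), nrow(g$chroms) - 1)
  expect_equal(sum(karyotype_lengths(rr1$karyotype)$length), genome_length(g))
  # inversions keep per-chromosome lengths
  rr2 <- apply_rearrangements(g, test_sim_config(n_inversions = 1,
                                                 n_fusions = 0, n_fissions = 0))
  expect_equal(sort(karyotype_lengths(rr2$karyotype)$length),
               sort(g$chroms$length))
  expect_error(apply_rearrangements(g, test_sim_config(n_fusions = 50)))
})

test_that("fragmentation tiles scaffolds exactly and registers chimeras", {
  set.seed(9)
  cfg <- test_sim_config(chimera_rate = 0.15)
  g <- generate_ancestor(cfg)
  rr <- apply_rearrangements(g, cfg)
  obs <- fragment_and_observe(rr$karyotype, cfg)
  # block sets tile each scaffold with no gaps or overlaps
  by_sc <- split(obs$blocks, obs$blocks$tgt_scaffold)
  for (sc in names(by_sc)) {
    b <- by_sc[[sc]][order(by_sc[[sc]]$tgt_start), ]
    expect_equal(b$tgt_start[1], 0)
    expect_equal(b$tgt_end[nrow(b)],
                 obs$scaffolds$length[obs$scaffolds$scaffold_id == sc])
    if (nrow(b) > 1) expect_equal(b$tgt_start[-1], b$tgt_end[-nrow(b)])
  }
  expect_gt(sum(obs$truth$joins$chimeric), 0)
  expect_equal(sum(obs$scaffolds$length), genome_length(g))
  # chimera_rate 0 -> empty registry
  obs0 <- fragment_and_observe(rr$karyotype, test_sim_config(chimera_rate = 0))
  expect_equal(sum(obs0$truth$joins$chimeric), 0)
  expect_error(fragment_and_observe(rr$karyotype,
                                    test_sim_config(n_scaffolds = 2)))
})

test_that("junction coverage follows the two Poisson regimes", {
  set.seed(10)
  lam_t <- 400; lam_c <- 5
  cfg <- test_sim_config(chimera_rate = 0.25, n_scaffolds = 220,
                         lambda_true = lam_t, lambda_chim = lam_c)
  g <- generate_ancestor(cfg)
  rr <- apply_rearrangements(g, cfg)
  obs <- fragment_and_observe(rr$karyotype, cfg)
  j <- dplyr::left_join(obs$coverage, obs$truth$joins,
                        by = c("scaffold_id", "junction_offset"))
  ct <- j$spanning_pairs[j$chimeric]
  tt <- j$spanning_pairs[!j$chimeric]
  expect_gt(length(ct), 10)
  expect_lt(abs(mean(ct) - lam_c), 3 * sqrt(lam_c / length(ct)))
  if (length(tt) > 3) {
    expect_lt(abs(mean(tt) - lam_t), 4 * sqrt(lam_t / length(tt)))
  }
  expect_true(all(obs$adjacency$spanning_pairs >= 0))
})

test_that("the PCR oracle honours the 6-kb testability boundary", {
  set.seed(11)
  cfg <- test_sim_config(chimera_rate = 0.2)
  g <- generate_ancestor(cfg)
  rr <- apply_rearrangements(g, cfg)
  obs <- fragment_and_observe(rr$karyotype, cfg)
  joins <- obs$truth$joins
  joins$span <- 2000
  res <- pcr_oracle(joins, obs$truth)
  expect_true(all(res$pcr_status[res$chimeric] == "refuted"))
  expect_true(all(res$pcr_status[!res$chimeric] == "confirmed"))
  joins$span <- 6000 # the boundary itself is untestable
  expect_true(all(pcr_oracle(joins, obs$truth)$pcr_status == "untestable"))
  bad <- tibble::tibble(scaffold_id = "nope", junction_offset = 1, span = 100)
  expect_error(pcr_oracle(bad, obs$truth))
})

test_that("BAC panels report derived marker order, reversed under inversion", {
  set.seed(12)
  cfg <- test_sim_config(n_inversions = 0, n_fusions = 0, n_fissions = 0)
  g <- generate_ancestor(cfg)
  k_id <- apply_rearrangements(g, cfg)$karyotype
  panel <- emit_bac_panel(k_id, spacing = 2e5)
  # identity karyotype: observed order equals reference order per chromosome
  joined <- dplyr::inner_join(panel$observations, panel$bacs, by = "bac_id")
  for (ch in unique(joined$chrom)) {
    d <- joined[joined$chrom == ch, ]
    expect_equal(order(d$order_index), order(d$ref_pos))
  }
  # a planted inversion reverses the spanned markers
  cfg1 <- test_sim_config(n_inversions = 1, n_fusions = 0, n_fissions = 0,
                          min_inversion_size = 8e5)
  rr <- apply_rearrangements(g, cfg1)
  inv <- rr$truth[rr$truth$type == "inversion", ]
  panel1 <- emit_bac_panel(rr$karyotype, spacing = 1e5)
  j1 <- dplyr::inner_join(panel1$observations, panel1$bacs, by = "bac_id")
  inside <- j1[j1$ref_chrom == inv$anc_chrom1 & j1$ref_pos > inv$anc_pos1 &
                 j1$ref_pos < inv$anc_pos2, ]
  expect_gt(nrow(inside), 1)
  expect_true(all(diff(inside$order_index[order(inside$ref_pos)]) < 0))
  # dropout extremes
  expect_equal(nrow(emit_bac_panel(k_id, 2e5, dropout = 1)$observations), 0)
  expect_error(emit_bac_panel(k_id, spacing = 1e9))
})

test_that("same seed reproduces the whole observation layer bitwise", {
  run <- function() {
    cfg <- test_sim_config(seed = 99, chimera_rate = 0.1)
    g <- generate_ancestor(cfg)
    rr <- apply_rearrangements(g, cfg)
    obs <- fragment_and_observe(rr$karyotype, cfg)
    bp <- emit_bac_panel(rr$karyotype, cfg$bac_spacing)
    list(g = g, rr = rr, obs = obs, bp = bp)
  }
  a <- run(); b <- run()
  expect_identical(a$g, b$g)
  expect_identical(a$rr$truth, b$rr$truth)
  expect_identical(a$obs$blocks, b$obs$blocks)
  expect_identical(a$obs$coverage, b$obs$coverage)
  expect_identical(a$bp$observations, b$bp$observations)
})
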