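test_that("mann_whitney_u exact path matches enumeration, with ties", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1) # 2 * 1/20
  expect_equal(mann_whitney_u(1, 1)$p_value, 1)
  expect_error(mann_whitney_u(numeric(0), 1))
  # all size pairs up to pooled 10, random data with ties, vs an
  # independent enumeration oracle
  set.seed(50)
  for (n1 in 1:5) for (n2 in n1:(10 - n1)) {
    for (rep in 1:3) {
      x <- sample(1:4, n1, replace = TRUE)
      y <- sample(1:4, n2, replace = TRUE)
      for (s in c("two.sided", "less", "greater")) {
        expect_equal(mann_whitney_u(x, y, sides = s)$p_value,
                     mwu_oracle(x, y, sides = s), tolerance = 1e-12)
      }
    }
  }
  # tie-free exact p agrees with wilcox.test's exact distribution
  set.seed(51)
  for (rep in 1:10) {
    x <- rnorm(4); y <- rnorm(5)
    expect_equal(mann_whitney_u(x, y)$p_value,
                 wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-10)
  }
})

test_that("normal-approximation path tracks exact enumeration at n = 6 + 6", {
  set.seed(52)
  for (rep in 1:10) {
    x <- rnorm(6); y <- rnorm(6, mean = 0.5)
    exact <- mann_whitney_u(x, y, exact_max = 12)$p_value
    approx <- mann_whitney_u(x, y, exact_max = 0)$p_value
    expect_lt(abs(exact - approx), 0.02)
    # the approximation is the standard continuity-corrected one
    expect_equal(approx,
                 suppressWarnings(wilcox.test(x, y, exact = FALSE)$p.value),
                 tolerance = 1e-10)
  }
})

test_that("kruskal_wallis reproduces the rank formula and degenerate case", {
  kw <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(kw$statistic, 12 / 42 * 89.5 - 21, tolerance = 1e-6)
  expect_equal(kw$df, 2)
  kw0 <- kruskal_wallis(list(c(2, 2), c(2, 2)))
  expect_equal(kw0$statistic, 0)
  expect_equal(kw0$p_value, 1)
  expect_error(kruskal_wallis(list(1:3)))
  expect_error(kruskal_wallis(list(1:3, numeric(0))))
  # agrees with the base implementation on untied data
  set.seed(53)
  g <- list(rnorm(8), rnorm(8, 1), rnorm(8))
  base <- kruskal.test(unlist(g), rep(1:3, each = 8))
  ours <- kruskal_wallis(g)
  expect_equal(ours$statistic, unname(base$statistic))
  expect_equal(ours$p_value, base$p.value)
})

test_that("flank sets abut the EBR with the extension rule and truncation flags", {
  g <- karyo_genome(tibble::tibble(chrom = "c", length = 1e6))
  fs <- make_flank_set(list(chrom = "c", start = 10000, end = 12000), g)
  expect_equal(fs$start[fs$role == "-2"], 6000)
  expect_equal(fs$start[fs$role == "-1"], 8000)
  expect_equal(fs$end[fs$role == "+1"], 14000)
  expect_equal(fs$end[fs$role == "+2"], 16000)
  expect_false(any(fs$truncated))
  # flanks tile exactly twice the EBR length on each side
  L <- 2000
  expect_equal(sum((fs$end - fs$start)[fs$role %in% c("-2", "-1")]), 2 * L)
  # sub-kb EBRs are first extended by 1 kb both ways
  fs2 <- make_flank_set(list(chrom = "c", start = 50000, end = 50400), g)
  expect_equal(fs2$end[fs2$role == "ebr"] - fs2$start[fs2$role == "ebr"], 2400)
  expect_equal(fs2$end[fs2$role == "+2"] - fs2$start[fs2$role == "+2"], 2400)
  # chromosome-start EBR truncates upstream windows
  fs3 <- make_flank_set(list(chrom = "c", start = 0, end = 2000), g)
  expect_true(all(fs3$truncated[fs3$role %in% c("-2", "-1")]))
  expect_error(make_flank_set(list(chrom = "c", start = 999000, end = 1000001), g))
})

test_that("flank contrast detects planted depletion and degenerates gracefully", {
  set.seed(54)
  g <- generate_ancestor(sim_config(seed = 54))
  bp <- sample_breakpoint(g, gamma = 8, n = 60)
  ebrs <- tibble::tibble(chrom = bp$chrom, start = bp$pos, end = bp$pos + 1)
  fc <- ebr_flank_contrast(ebrs, g)
  expect_lt(glance(fc)$mean_ebr_density, glance(fc)$mean_flank_density)
  expect_lt(glance(fc)$mwu_p, 0.01)
  # empty CNE track: densities all zero, p reported as 1
  g0 <- karyo_genome(g$chroms)
  fc0 <- ebr_flank_contrast(ebrs, g0)
  expect_true(all(fc0$per_window$density == 0))
  expect_equal(fc0$tests$p_value, c(1, 1))
  expect_error(ebr_flank_contrast(ebrs[0, ], g))
})

test_that("the window scan partitions classes and matches hand counts", {
  # 10-kb toy chromosome: mean CNE bases per window by hand = 110
  g <- karyo_genome(tibble::tibble(chrom = "c", length = 10000),
                    tracks = list(CNE = tibble::tibble(
                      chrom = "c", start = c(1000, 5500), end = c(2000, 5600))))
  sc <- scan_1kb_windows(g)
  expect_equal(nrow(sc$windows), 10)
  expect_equal(sc$report$mean_cne_bases[sc$report$class == "genome"], 110)
  # classification is a partition of usable windows
  set.seed(55)
  cfg <- test_sim_config(n_fissions = 2, n_fusions = 2, n_inversions = 2)
  gg <- generate_ancestor(cfg)
  rr <- apply_rearrangements(gg, cfg)
  sc2 <- scan_1kb_windows(gg, truth_to_ebrs(rr$truth, gg))
  wu <- sc2$windows[sc2$windows$usable, ]
  expect_equal(sum(sc2$report$n_windows[sc2$report$class != "genome"]), nrow(wu))
  # genome-wide mean equals the class-size-weighted mean (conservation)
  cls <- sc2$report[sc2$report$class != "genome", ]
  expect_equal(sum(cls$mean_density * cls$n_windows) / sum(cls$n_windows),
               sc2$report$mean_density[sc2$report$class == "genome"])
  # all windows inside one msHSB: class mean equals genome mean
  g3 <- karyo_genome(tibble::tibble(chrom = "c", length = 10000),
                     tracks = list(
                       CNE = tibble::tibble(chrom = "c", start = 2000, end = 2500),
                       msHSB = tibble::tibble(chrom = "c", start = 0, end = 10000)))
  sc3 <- scan_1kb_windows(g3, mshsb_min = 5000)
  expect_equal(sc3$report$mean_density[sc3$report$class == "msHSB"],
               sc3$report$mean_density[sc3$report$class == "genome"])
  # excluded chromosomes are left out; gap-heavy windows dropped
  g4 <- set_track(g, "gap", tibble::tibble(chrom = "c", start = 0, end = 1501))
  sc4 <- scan_1kb_windows(g4)
  expect_equal(sum(!sc4$windows$usable), 2) # 100% and 50.1% gapped
})

test_that("distance to msHSB-level density is a per-chromosome window count", {
  # densities along the chromosome: 0, 0, 0.2 with msHSB average 0.1
  g <- karyo_genome(
    tibble::tibble(chrom = c("c", "m"), length = c(3000, 2000)),
    tracks = list(
      CNE = tibble::tibble(chrom = c("c", "m"), start = c(2000, 0),
                           end = c(2200, 200)),
      msHSB = tibble::tibble(chrom = "m", start = 0, end = 2000)))
  sc <- scan_1kb_windows(g, mshsb_min = 1000)
  d <- distance_to_mshsb_density(sc)
  dc <- d[d$chrom == "c", ]
  expect_equal(dc$distance[order(dc$start)], c(2, 1))
  # zero-density window with no qualifying window on its chromosome -> NA
  g2 <- karyo_genome(
    tibble::tibble(chrom = c("c", "m"), length = c(2000, 2000)),
    tracks = list(
      CNE = tibble::tibble(chrom = "m", start = 0, end = 400),
      msHSB = tibble::tibble(chrom = "m", start = 0, end = 2000)))
  sc2 <- scan_1kb_windows(g2, mshsb_min = 1000)
  d2 <- distance_to_mshsb_density(sc2)
  expect_true(all(is.na(d2$distance[d2$chrom == "c"])))
  # no msHSB windows at all -> error
  sc3 <- scan_1kb_windows(karyo_genome(tibble::tibble(chrom = "c", length = 3000)))
  expect_error(distance_to_mshsb_density(sc3))
})
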