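# Synthetic ancestral genomes: avian-like karyotypes (few macro-, many
# microchromosomes) carrying CNE and msHSB tracks at configurable densities.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults emulate a
#' scaled-down avian genome: a handful of macrochromosomes plus
#' microchromosomes, a genome-wide CNE density of 0.087 with msHSBs enriched
#' by 0.107/0.087, and spanning-pair coverage regimes of 400 (true joins)
#' vs 5 (chimeric joins) read pairs.
#'
#' @param n_macro,n_micro Chromosome counts.
#' @param macro_len_range,micro_len_range Length ranges (bp).
#' @param cne_target_density Genome-wide CNE base fraction target.
#' @param cne_len_mean Mean CNE length (bp); lengths are gamma-distributed
#'   (shape 2) with a 20 bp floor.
#' @param mshsb_count Number of msHSB blocks to place (macrochromosomes).
#' @param mshsb_len_range msHSB length range (bp); minimum must exceed
#'   1.5 Mb, the size class used as the stable-genome contrast.
#' @param mshsb_enrichment CNE density ratio inside msHSBs vs genome-wide.
#' @param n_inversions,n_fusions,n_fissions Planted event counts.
#' @param breakpoint_gamma Non-negative bias exponent: breakpoint windows are
#'   chosen with probability proportional to `(1 - CNE fraction)^gamma`, so
#'   larger values concentrate breakpoints in CNE-poor sequence.
#' @param gamma_class_weights Relative bias strength per event class
#'   (effective exponent = `breakpoint_gamma * weight`). The default makes
#'   fission breakpoints the most strongly CNE-avoidant and inversion
#'   breakpoints the least, reproducing the empirically observed density
#'   gradient fission < fusion < intrachromosomal among breakpoint classes.
#' @param telomere_depletion_len,telomere_depletion_factor Length (bp) of
#'   the subtelomeric region at every ancestral chromosome end and the
#'   factor by which its CNE density is reduced. Fusions join original
#'   telomeric ends, so fusion breakpoint regions inherit this depletion.
#' @param min_inversion_size Minimum inverted-segment length (bp); sampled
#'   breakpoint pairs closer than this are redrawn so planted events stay
#'   resolvable at assembly resolution.
#' @param exclude_mshsb_breakpoints Disallow breakpoints inside msHSBs.
#' @param n_scaffolds Number of scaffold pieces the karyotype is cut into.
#' @param chimera_rate Fraction of pieces concatenated into chimeric
#'   scaffolds joining non-adjacent loci.
#' @param lambda_true,lambda_chim Poisson means for spanning-pair physical
#'   coverage at true vs chimeric joins.
#' @param bac_spacing Approximate BAC marker spacing on the ancestor (bp).
#' @param bac_dropout Fraction of BAC markers lost before observation.
#' @param pcr_error_rate Probability the in-silico PCR flips its verdict.
#' @param seed Optional integer; when set, [generate_ancestor()] seeds the
#'   RNG so a full simulation round is reproducible.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_macro = 4, n_micro = 6,
                       macro_len_range = c(4e6, 8e6),
                       micro_len_range = c(6e5, 2e6),
                       cne_target_density = 0.087,
                       cne_len_mean = 300,
                       mshsb_count = 4,
                       mshsb_len_range = c(1.5e6, 2.5e6),
                       mshsb_enrichment = 0.107 / 0.087,
                       n_inversions = 3, n_fusions = 2, n_fissions = 1,
                       breakpoint_gamma = 8,
                       gamma_class_weights = c(fission = 1, inversion = 0.12),
                       telomere_depletion_len = 5e4,
                       telomere_depletion_factor = 0.45,
                       min_inversion_size = 2e5,
                       exclude_mshsb_breakpoints = FALSE,
                       n_scaffolds = 60,
                       chimera_rate = 0.08,
                       lambda_true = 400, lambda_chim = 5,
                       bac_spacing = 1e5,
                       bac_dropout = 0,
                       pcr_error_rate = 0,
                       seed = NULL) {
  cfg <- as.list(environment())
  stopifnot(
    cfg$n_macro >= 0, cfg$n_micro >= 0, cfg$n_macro + cfg$n_micro >= 1,
    cfg$cne_target_density >= 0, cfg$cne_target_density <= 1,
    cfg$breakpoint_gamma >= 0,
    cfg$chimera_rate >= 0, cfg$chimera_rate <= 1,
    cfg$bac_dropout >= 0, cfg$bac_dropout <= 1,
    cfg$pcr_error_rate >= 0, cfg$pcr_error_rate <= 1,
    cfg$n_inversions >= 0, cfg$n_fusions >= 0, cfg$n_fissions >= 0
  )
  structure(cfg, class = "sim_config")
}

# Place non-overlapping intervals in [lo, hi) at a target base density.
# Lengths are drawn, then separated by Dirichlet-distributed gaps, so the
# realised density matches the target up to integer rounding.
place_intervals_at_density <- function(chrom, lo, hi, density, len_mean) {
  span <- hi - lo
  target <- density * span
  if (target <= 0 || span <= 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  if (density > 0.95) abort("infeasible interval density")
  lens <- numeric(0)
  while (sum(lens) < target) {
    k <- max(10, ceiling((target - sum(lens)) / len_mean))
    lens <- c(lens, pmax(20, round(stats::rgamma(k, shape = 2, scale = len_mean / 2))))
  }
  # trim overshoot past the target
  keep <- which(cumsum(lens) <= target + len_mean)
  lens <- lens[keep]
  if (length(lens) == 0) lens <- max(1, min(round(target), span - 1))
  gap_total <- span - sum(lens)
  if (gap_total < 0) { # saturation: density near feasibility limit
    lens <- lens[cumsum(lens) <= span]
    gap_total <- span - sum(lens)
  }
  w <- stats::rexp(length(lens) + 1)
  gaps <- gap_total * w / sum(w)
  starts <- lo + cumsum(gaps)[seq_along(lens)] + c(0, cumsum(lens))[seq_along(lens)]
  tibble(chrom = chrom, start = round(starts), end = round(starts) + lens) %>%
    filter(.data$end <= hi, .data$start >= lo)
}

#' Generate a synthetic ancestral genome
#'
#' Draws chromosome lengths from the configured macro/micro ranges, places
#' msHSB blocks on macrochromosomes, then lays down a non-overlapping CNE
#' track so that CNE density inside msHSBs exceeds the outside density by
#' the configured enrichment ratio while the genome-wide density matches
#' `cne_target_density` (within +/- 0.005 unless placement saturates).
#'
#' @param config A [sim_config()].
#' @return A [karyo_genome()] with `CNE` and `msHSB` tracks.
#' @export
generate_ancestor <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  if (config$cne_target_density > 1) abort("infeasible CNE density")
  n <- config$n_macro + config$n_micro
  lens <- round(c(
    stats::runif(config$n_macro, config$macro_len_range[1], config$macro_len_range[2]),
    stats::runif(config$n_micro, config$micro_len_range[1], config$micro_len_range[2])
  ))
  chroms <- tibble(
    chrom = c(sprintf("A%d", seq_len(config$n_macro)),
              sprintf("M%d", seq_len(config$n_micro)))[seq_len(n)],
    length = lens
  )
  g <- karyo_genome(chroms)

  # msHSBs: on macrochromosomes, non-overlapping, clear of subtelomeres
  tel <- config$telomere_depletion_len
  mshsb <- tibble(chrom = character(), start = numeric(), end = numeric())
  if (config$mshsb_count > 0 && config$n_macro > 0) {
    macro <- chroms[seq_len(config$n_macro), ]
    rows <- list()
    occupied <- stats::setNames(vector("list", nrow(macro)), macro$chrom)
    for (i in seq_len(config$mshsb_count)) {
      for (try in 1:50) {
        ch <- sample(macro$chrom, 1, prob = macro$length)
        len <- round(stats::runif(1, config$mshsb_len_range[1], config$mshsb_len_range[2]))
        clen <- macro$length[macro$chrom == ch]
        if (len >= clen - 2 * tel) next
        s <- round(stats::runif(1, tel, clen - tel - len))
        occ <- occupied[[ch]]
        clash <- any(vapply(occ, function(iv) s < iv[2] && s + len > iv[1], logical(1)))
        if (!clash) {
          occupied[[ch]] <- c(occ, list(c(s, s + len)))
          rows[[length(rows) + 1]] <- tibble(chrom = ch, start = s, end = s + len)
          break
        }
      }
    }
    mshsb <- bind_rows(rows)
  }
  g <- set_track(g, "msHSB", mshsb)

  # CNE densities: enriched inside msHSBs, depleted in subtelomeres, with
  # the remaining background solving the genome-wide target
  d <- config$cne_target_density
  if (d > 0) {
    G <- genome_length(g)
    tf <- config$telomere_depletion_factor
    in_len <- sum(mshsb$end - mshsb$start)
    tel_len <- sum(pmin(chroms$length, 2 * tel))
    d_in <- min(d * config$mshsb_enrichment, 0.9)
    rest_len <- G - in_len - tel_len
    d_out <- (d * G - d_in * in_len) / (rest_len + tf * tel_len)
    if (d_out < 0) { d_out <- 0; d_in <- d * G / max(in_len, 1) }
    cne <- list()
    for (i in seq_len(nrow(chroms))) {
      ch <- chroms$chrom[i]; L <- chroms$length[i]
      blocks <- mshsb %>% filter(.data$chrom == ch) %>% arrange(.data$start)
      # piecewise density regions: subtelomere | background | msHSB ...
      cuts <- sort(unique(pmin(pmax(
        c(0, min(tel, L), max(L - tel, 0),
          as.vector(t(as.matrix(blocks[c("start", "end")]))), L), 0), L)))
      for (j in seq_len(length(cuts) - 1)) {
        lo <- cuts[j]; hi <- cuts[j + 1]
        if (hi <= lo) next
        mid <- (lo + hi) / 2
        subtel <- mid < tel || mid > L - tel
        dd <- if (any(blocks$start <= mid & mid < blocks$end)) d_in
              else if (subtel) tf * d_out
              else d_out
        # subtelomeric elements are correspondingly shorter, so their
        # per-window density is thinned rather than made sparser
        lm <- if (subtel) max(30, config$cne_len_mean * tf) else config$cne_len_mean
        cne[[length(cne) + 1]] <-
          place_intervals_at_density(ch, lo, hi, dd, lm)
      }
    }
    g <- set_track(g, "CNE", bind_rows(cne))
  }
  g
}

#' Tile a genome into fixed-size candidate windows
#'
#' Non-overlapping windows from position 0 on each chromosome; the final
#' partial window is dropped.
#'
#' @param genome A [karyo_genome()].
#' @param window_size Window size in bp (default 1000).
#' @param chroms Optional subset of chromosomes.
#' @return Tibble `chrom`, `start`, `end`.
#' @export
tile_windows <- function(genome, window_size = 1000, chroms = NULL) {
  cc <- genome$chroms
  if (!is.null(chroms)) cc <- filter(cc, .data$chrom %in% chroms)
  purrr::pmap_dfr(cc, function(chrom, length) {
    k <- floor(length / window_size)
    if (k == 0) return(tibble(chrom = character(), start = numeric(), end = numeric()))
    tibble(chrom = chrom,
           start = (seq_len(k) - 1) * window_size,
           end = seq_len(k) * window_size)
  })
}

#' Sample rearrangement breakpoints with a CNE-poor bias
#'
#' The genome is tiled into 1-kb windows; a window is chosen with
#' probability proportional to `(1 - CNE fraction)^gamma` and the breakpoint
#' is then uniform within the window. `gamma = 0` gives a uniform
#' distribution over windows; larger `gamma` avoids CNE-dense sequence,
#' reproducing the empirical depletion of conserved elements in
#' evolutionary breakpoint regions.
#'
#' @param genome A [karyo_genome()] with a `CNE` track.
#' @param gamma Non-negative bias exponent.
#' @param n Number of breakpoints to draw.
#' @param exclude_mshsb Exclude windows overlapping msHSBs.
#' @param window_size Candidate window size (bp).
#' @param chroms Optional chromosome subset to sample from.
#' @return Tibble `chrom`, `pos` with `n` rows.
#' @export
sample_breakpoint <- function(genome, gamma, n = 1, exclude_mshsb = FALSE,
                              window_size = 1000, chroms = NULL) {
  stopifnot(gamma >= 0, n >= 1)
  w <- tile_windows(genome, window_size, chroms)
  if (nrow(w) == 0) abort("no candidate windows")
  frac <- cne_fraction(w, genome)
  wt <- (1 - frac)^gamma
  if (exclude_mshsb) {
    hit <- interval_covered_bases(w, genome$tracks$msHSB) > 0
    wt[hit] <- 0
  }
  if (sum(wt) <= 0) abort("all breakpoint window weights are zero")
  idx <- sample.int(nrow(w), n, replace = TRUE, prob = wt)
  tibble(chrom = w$chrom[idx],
         pos = floor(stats::runif(n, w$start[idx], w$end[idx])))
}
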