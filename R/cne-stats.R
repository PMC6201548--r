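# CNE-density statistics: flank-window contrasts around evolutionary
# breakpoint regions, the genome-wide 1-kb window scan with class averages,
# the distance-to-msHSB-density metric, and the rank-based tests.

#' Mann-Whitney U test
#'
#' Exact p-values by enumeration of all assignments when
#' `n_x + n_y <= exact_max` (ties handled by mid-ranks within each
#' enumerated split); otherwise the normal approximation with tie and
#' continuity corrections. The statistic is `U = R_x - n_x(n_x+1)/2`
#' (number of (x, y) pairs with x > y, counting ties as 1/2).
#'
#' @param x,y Numeric samples.
#' @param sides `"two.sided"`, `"less"` (x stochastically smaller) or
#'   `"greater"`.
#' @param exact_max Largest pooled size for the exact path (default 12).
#' @return One-row tibble: `statistic` (U), `p_value`, `method`.
#' @export
mann_whitney_u <- function(x, y, sides = c("two.sided", "less", "greater"),
                           exact_max = 12) {
  sides <- match.arg(sides)
  if (length(x) == 0 || length(y) == 0) abort("empty sample")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2

  if (N <= exact_max) {
    idx <- utils::combn(N, n1)
    us <- apply(idx, 2, function(ii) sum(r[ii]) - n1 * (n1 + 1) / 2)
    eps <- 1e-9
    p_less <- mean(us <= u_obs + eps)
    p_greater <- mean(us >= u_obs - eps)
    p <- switch(sides,
      less = p_less, greater = p_greater,
      two.sided = min(1, 2 * min(p_less, p_greater))
    )
    return(tibble(statistic = u_obs, p_value = p, method = "exact"))
  }

  mu <- n1 * n2 / 2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) {
    return(tibble(statistic = u_obs, p_value = 1, method = "normal"))
  }
  cc <- 0.5
  z_less <- (u_obs - mu + cc) / sqrt(sigma2)
  z_greater <- (u_obs - mu - cc) / sqrt(sigma2)
  p <- switch(sides,
    less = stats::pnorm(z_less),
    greater = stats::pnorm(z_greater, lower.tail = FALSE),
    two.sided = min(1, 2 * min(stats::pnorm(z_less),
                               stats::pnorm(z_greater, lower.tail = FALSE)))
  )
  tibble(statistic = u_obs, p_value = p, method = "normal")
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H with the chi-squared approximation (`k - 1` degrees of
#' freedom). When every observation is equal the statistic is defined as 0
#' with p = 1.
#'
#' @param groups List of two or more non-empty numeric vectors.
#' @return One-row tibble: `statistic` (H), `df`, `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) abort("need >= 2 groups")
  if (any(vapply(groups, length, integer(1)) == 0)) abort("empty group")
  vals <- unlist(groups)
  if (length(unique(vals)) == 1) {
    return(tibble(statistic = 0, df = length(groups) - 1, p_value = 1))
  }
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  kt <- stats::kruskal.test(vals, g)
  tibble(statistic = unname(kt$statistic), df = unname(kt$parameter),
         p_value = kt$p.value)
}

#' Flanking windows around an EBR
#'
#' EBRs shorter than 1 kb are first extended by 1 kb on both ends; two
#' abutting windows of the (extended) EBR's length are then laid on each
#' side (`-2`, `-1` upstream; `+1`, `+2` downstream). Windows clipped at a
#' chromosome end are flagged truncated.
#'
#' @param ebr One-row tibble/list with `chrom`, `start`, `end`.
#' @param genome Reference [karyo_genome()] (for chromosome bounds).
#' @return Tibble `role` (`-2`,`-1`,`ebr`,`+1`,`+2`), `chrom`, `start`,
#'   `end`, `truncated`.
#' @export
make_flank_set <- function(ebr, genome) {
  clen <- genome$chroms$length[genome$chroms$chrom == ebr$chrom]
  if (length(clen) == 0) abort("EBR on unknown chromosome")
  s <- ebr$start; e <- ebr$end
  if (e > clen || s < 0) abort("EBR outside chromosome")
  if (e - s < 1000) { s <- s - 1000; e <- e + 1000 }
  s <- max(0, s); e <- min(clen, e)
  L <- e - s
  raw <- tibble(
    role = c("-2", "-1", "ebr", "+1", "+2"),
    start = c(s - 2 * L, s - L, s, e, e + L),
    end = c(s - L, s, e, e + L, e + 2 * L)
  )
  raw %>%
    mutate(chrom = ebr$chrom,
           clip_start = pmax(0, .data$start),
           clip_end = pmin(clen, .data$end),
           truncated = .data$clip_start > .data$start |
             .data$clip_end < .data$end |
             (.data$role != "ebr" & .data$clip_end - .data$clip_start < L)) %>%
    transmute(role = .data$role, chrom = .data$chrom,
              start = .data$clip_start,
              end = pmax(.data$clip_end, .data$clip_start),
              truncated = .data$truncated)
}

#' CNE-density contrast between EBRs and their flanking windows
#'
#' For each EBR (at most `max_len` long) the CNE base fraction is computed
#' in the (extended) EBR and its four same-size flanking windows; a
#' Kruskal-Wallis test across the five window roles is followed by a
#' Mann-Whitney U test of EBR densities against the pooled flank densities.
#'
#' @param ebrs Tibble `chrom`, `start`, `end` (a `class` column is carried
#'   through; rows with `excluded = TRUE` are dropped).
#' @param genome Reference [karyo_genome()] with a `CNE` track.
#' @param max_len EBRs longer than this are excluded (default 100 kb).
#' @param sides Sidedness of the Mann-Whitney comparison (default
#'   `"less"`: depletion in EBRs).
#' @param min_untruncated Minimum number of EBRs with fully untruncated
#'   flanks required.
#' @return An object of class `karyo_flank_contrast`: list with
#'   `per_window` (densities per EBR and role), `summary` (per-role means)
#'   and `tests`.
#' @export
ebr_flank_contrast <- function(ebrs, genome, max_len = 100000,
                               sides = "less", min_untruncated = 2) {
  ebrs <- as_tibble(ebrs)
  if ("excluded" %in% names(ebrs)) ebrs <- filter(ebrs, !.data$excluded)
  ebrs <- filter(ebrs, .data$end - .data$start <= max_len)
  if (nrow(ebrs) == 0) abort("no eligible EBRs")
  per <- purrr::map_dfr(seq_len(nrow(ebrs)), function(i) {
    fs <- make_flank_set(ebrs[i, ], genome)
    fs$ebr_id <- i
    fs
  })
  usable_ids <- per %>%
    group_by(.data$ebr_id) %>%
    summarise(ok = !any(.data$truncated), .groups = "drop") %>%
    filter(.data$ok) %>% pull(.data$ebr_id)
  if (length(usable_ids) < min_untruncated) {
    abort("too few EBRs with untruncated flanks")
  }
  per <- filter(per, .data$ebr_id %in% usable_ids)
  per$density <- cne_fraction(per[c("chrom", "start", "end")], genome)

  groups <- split(per$density, per$role)
  ebr_d <- per$density[per$role == "ebr"]
  flank_d <- per$density[per$role != "ebr"]
  degenerate <- length(unique(per$density)) == 1
  kw <- if (degenerate) tibble(statistic = 0, df = 4, p_value = 1)
        else kruskal_wallis(groups)
  mw <- if (degenerate) tibble(statistic = NA_real_, p_value = 1,
                               method = "degenerate")
        else mann_whitney_u(ebr_d, flank_d, sides = sides)

  summary <- per %>%
    group_by(.data$role) %>%
    summarise(n = n(), mean_density = mean(.data$density), .groups = "drop")
  structure(list(
    per_window = per,
    summary = summary,
    tests = bind_rows(
      tibble(test = "kruskal_wallis", statistic = kw$statistic,
             p_value = kw$p_value),
      tibble(test = paste0("mann_whitney_", sides), statistic = mw$statistic,
             p_value = mw$p_value)
    ),
    n_ebrs = length(usable_ids)
  ), class = "karyo_flank_contrast")
}

#' @export
print.karyo_flank_contrast <- function(x, ...) {
  cat("<karyo_flank_contrast> ", x$n_ebrs, " EBRs\n", sep = "")
  print(x$summary)
  print(x$tests)
  invisible(x)
}

#' Genome-wide 1-kb window scan with class averages
#'
#' Tiles the genome (minus excluded chromosomes) into fixed windows from
#' position 0, drops final partial windows and windows with half or more
#' of their bases in assembly gaps, classifies each usable window
#' (precedence: fission > fusion > intrachromosomal EBR > msHSB > rest;
#' any overlap with an EBR makes it an EBR window), and reports per-class
#' mean CNE bases and densities plus the genome-wide mean.
#'
#' @param genome Reference [karyo_genome()] with `CNE` (and optionally
#'   `msHSB`, `gap`) tracks.
#' @param ebrs EBR tibble (`chrom`, `start`, `end`, `class`); rows with
#'   `excluded = TRUE` are ignored.
#' @param window_size Window size in bp (default 1000).
#' @param exclude_chroms Chromosomes left out of the scan.
#' @param mshsb_min Minimum msHSB length considered (default 1.5 Mb).
#' @return An object of class `karyo_window_scan`: list with `windows`
#'   (per-window class and CNE bases) and `report` (per-class means,
#'   including a `genome` row over all usable windows).
#' @export
scan_1kb_windows <- function(genome, ebrs = NULL, window_size = 1000,
                             exclude_chroms = character(),
                             mshsb_min = 1.5e6) {
  keep <- setdiff(genome$chroms$chrom, exclude_chroms)
  w <- tile_windows(genome, window_size, chroms = keep)
  if (nrow(w) == 0) abort("no windows")
  gap <- genome$tracks$gap
  usable <- if (!is.null(gap) && nrow(gap) > 0) {
    avail <- 1 - interval_covered_bases(w, gap) / window_size
    avail > 0.5
  } else rep(TRUE, nrow(w))

  w$cne_bases <- interval_covered_bases(w, genome$tracks$CNE)
  w$density <- w$cne_bases / window_size

  cls <- rep("rest", nrow(w))
  mshsb <- genome$tracks$msHSB
  if (!is.null(mshsb) && nrow(mshsb) > 0) {
    big <- filter(mshsb, .data$end - .data$start > mshsb_min)
    if (nrow(big) > 0) cls[interval_covered_bases(w, big) > 0] <- "msHSB"
  }
  if (!is.null(ebrs) && nrow(ebrs) > 0) {
    ebrs <- as_tibble(ebrs)
    if ("excluded" %in% names(ebrs)) ebrs <- filter(ebrs, !.data$excluded)
    for (k in c("intrachromosomal", "fusion", "fission")) {
      ee <- filter(ebrs, .data$class == k)
      if (nrow(ee) > 0) {
        cls[interval_covered_bases(w, merge_intervals(ee)) > 0] <- k
      }
    }
  }
  w$class <- cls
  w$usable <- usable
  wu <- filter(w, .data$usable)

  report <- wu %>%
    group_by(.data$class) %>%
    summarise(n_windows = n(),
              mean_cne_bases = mean(.data$cne_bases),
              mean_density = mean(.data$density), .groups = "drop") %>%
    bind_rows(tibble(class = "genome", n_windows = nrow(wu),
                     mean_cne_bases = mean(wu$cne_bases),
                     mean_density = mean(wu$density)))
  structure(list(windows = w, report = report, window_size = window_size),
            class = "karyo_window_scan")
}

#' @export
print.karyo_window_scan <- function(x, ...) {
  cat("<karyo_window_scan> ", nrow(x$windows), " windows of ",
      x$window_size, " bp (", sum(x$windows$usable), " usable)\n", sep = "")
  print(x$report)
  invisible(x)
}

#' Distance from CNE-empty windows to msHSB-level density
#'
#' For every usable window with zero CNE bases, the minimum number of
#' windows (along the same chromosome) to a window whose density reaches
#' the average msHSB density; unreachable windows are `NA`.
#'
#' @param scan A `karyo_window_scan` with a non-empty msHSB class.
#' @return Tibble of zero-density usable windows with a `distance` column
#'   (window counts).
#' @export
distance_to_mshsb_density <- function(scan) {
  w <- filter(scan$windows, .data$usable)
  ms <- filter(w, .data$class == "msHSB")
  if (nrow(ms) == 0) abort("no msHSB windows to define the reference density")
  avg <- mean(ms$density)
  out <- list()
  for (ch in unique(w$chrom)) {
    wc <- w %>% filter(.data$chrom == ch) %>% arrange(.data$start)
    idx <- wc$start / scan$window_size
    qual <- idx[wc$density >= avg]
    zero <- wc[wc$cne_bases == 0, ]
    if (nrow(zero) == 0) next
    zidx <- zero$start / scan$window_size
    zero$distance <- if (length(qual) == 0) NA_real_ else {
      vapply(zidx, function(i) min(abs(i - qual)), numeric(1))
    }
    out[[length(out) + 1]] <- zero
  }
  if (length(out) == 0) {
    return(mutate(w[0, ], distance = numeric(0)))
  }
  bind_rows(out)
}
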