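#' @importFrom dplyr %>% arrange mutate filter select group_by ungroup summarise
#'   bind_rows left_join n row_number across all_of rename distinct pull slice
#'   transmute first last if_else
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom rlang .data abort warn
NULL

# ---- interval primitives ----------------------------------------------------
# All coordinates are 0-based, half-open [start, end). Conversion to 1-based
# inclusive happens only at AGP/report boundaries.

#' Validate an interval tibble
#'
#' Checks a `chrom`/`start`/`end` tibble for the coordinate invariants used
#' throughout the package: integer-valued positions, `0 <= start < end`, and,
#' when a genome is supplied, `end` within the chromosome length.
#'
#' @param x A data frame with columns `chrom`, `start`, `end` (0-based,
#'   half-open).
#' @param genome Optional [karyo_genome()] providing chromosome lengths.
#' @return `x` invisibly, as a tibble.
#' @export
validate_intervals <- function(x, genome = NULL) {
  x <- as_tibble(x)
  req <- c("chrom", "start", "end")
  if (!all(req %in% names(x))) {
    abort(paste0("interval table needs columns: ", paste(req, collapse = ", ")))
  }
  if (nrow(x) > 0) {
    if (any(x$start < 0) || any(x$start >= x$end)) {
      abort("intervals must satisfy 0 <= start < end")
    }
    if (!is.null(genome)) {
      len <- stats::setNames(genome$chroms$length, genome$chroms$chrom)
      bad <- is.na(len[x$chrom]) | x$end > len[x$chrom]
      if (any(bad)) abort("interval outside its chromosome")
    }
  }
  invisible(x)
}

#' Merge overlapping or bookended intervals within each chromosome
#'
#' Normalises an interval track so that per-chromosome intervals are sorted,
#' non-overlapping and deduplicated. Density computations presuppose a
#' normalised track; all track loaders call this.
#'
#' @param x Interval tibble (`chrom`, `start`, `end`).
#' @return A tibble with the same columns, normalised.
#' @export
merge_intervals <- function(x) {
  x <- as_tibble(x)[c("chrom", "start", "end")]
  if (nrow(x) == 0) return(x)
  validate_intervals(x)
  x <- arrange(x, .data$chrom, .data$start, .data$end)
  # a new run starts whenever start exceeds the running max end seen so far
  x <- x %>%
    group_by(.data$chrom) %>%
    mutate(
      cummax_end = cummax(.data$end),
      new_run = .data$start > dplyr::lag(.data$cummax_end, default = -1),
      run = cumsum(.data$new_run)
    ) %>%
    group_by(.data$chrom, .data$run) %>%
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop") %>%
    select("chrom", "start", "end") %>%
    arrange(.data$chrom, .data$start)
  x
}

# Per-chromosome prefix-coverage lookup. Returns, for each query interval,
# the number of bases covered by the (normalised) track. Vectorised via
# findInterval on the sorted track; O((n+q) log n).
interval_covered_bases <- function(queries, track) {
  queries <- as_tibble(queries)
  if (nrow(queries) == 0) return(numeric(0))
  validate_intervals(queries)
  out <- numeric(nrow(queries))
  if (nrow(track) == 0) return(out)
  track_by <- split(track, track$chrom)
  q_split <- split(seq_len(nrow(queries)), queries$chrom)
  for (ch in names(q_split)) {
    tr <- track_by[[ch]]
    if (is.null(tr) || nrow(tr) == 0) next
    tr <- tr[order(tr$start), ] # tolerate unsorted (but merged) tracks
    idx <- q_split[[ch]]
    s <- tr$start; e <- tr$end
    pre <- c(0, cumsum(e - s)) # covered bases strictly before interval i
    covered_upto <- function(x) {
      # total track bases in [0, x)
      i <- findInterval(x, s) # number of intervals with start <= x... start < x handled below
      # findInterval gives start <= x; for half-open this is what we want
      base <- pre[pmax(i, 0) + 1]
      inside <- ifelse(i >= 1, pmax(0, pmin(x, e[pmax(i, 1)]) - s[pmax(i, 1)]), 0)
      base - ifelse(i >= 1, e[pmax(i, 1)] - s[pmax(i, 1)], 0) + inside
    }
    out[idx] <- covered_upto(queries$end[idx]) - covered_upto(queries$start[idx])
  }
  out
}

# ---- genome container -------------------------------------------------------

#' Construct a coordinate-only genome
#'
#' A `karyo_genome` holds chromosome lengths plus named interval tracks
#' (at minimum `"CNE"` and `"msHSB"`; `"gap"` marks bases with no sequence
#' data). Tracks are normalised on construction: overlapping intervals are
#' merged and duplicates removed, so per-base density is well defined.
#'
#' @param chroms A data frame with columns `chrom` and `length` (bp), in
#'   karyotype order.
#' @param tracks Named list of interval tibbles (`chrom`, `start`, `end`).
#' @return An object of class `karyo_genome`: a list with elements `chroms`
#'   (tibble) and `tracks` (named list of normalised tibbles).
#' @examples
#' g <- karyo_genome(
#'   tibble::tibble(chrom = "chr1", length = 10000),
#'   tracks = list(CNE = tibble::tibble(chrom = "chr1", start = 100, end = 300))
#' )
#' genome_length(g)
#' @export
karyo_genome <- function(chroms, tracks = list()) {
  chroms <- as_tibble(chroms)
  stopifnot(all(c("chrom", "length") %in% names(chroms)))
  if (any(chroms$length <= 0)) abort("chromosome lengths must be positive")
  if (anyDuplicated(chroms$chrom)) abort("duplicate chromosome ids")
  chroms$chrom <- as.character(chroms$chrom)
  g <- structure(list(chroms = chroms[c("chrom", "length")], tracks = list()),
                 class = "karyo_genome")
  for (nm in names(tracks)) g <- set_track(g, nm, tracks[[nm]])
  for (nm in c("CNE", "msHSB")) {
    if (is.null(g$tracks[[nm]])) {
      g$tracks[[nm]] <- tibble(chrom = character(), start = numeric(), end = numeric())
    }
  }
  g
}

#' @export
print.karyo_genome <- function(x, ...) {
  cat("<karyo_genome> ", nrow(x$chroms), " chromosomes, ",
      format(sum(x$chroms$length), big.mark = ","), " bp\n", sep = "")
  for (nm in names(x$tracks)) {
    tr <- x$tracks[[nm]]
    cat("  track ", nm, ": ", nrow(tr), " intervals, ",
        format(sum(tr$end - tr$start), big.mark = ","), " bp\n", sep = "")
  }
  invisible(x)
}

#' @rdname karyo_genome
#' @param genome A `karyo_genome`.
#' @export
genome_length <- function(genome) sum(genome$chroms$length)

#' Attach a normalised track to a genome
#'
#' @param genome A [karyo_genome()].
#' @param name Track name (e.g. `"CNE"`).
#' @param intervals Interval tibble; merged and validated against chromosome
#'   bounds.
#' @return The genome with the track replaced.
#' @export
set_track <- function(genome, name, intervals) {
  iv <- merge_intervals(intervals)
  validate_intervals(iv, genome)
  if (any(!iv$chrom %in% genome$chroms$chrom)) abort("track on unknown chromosome")
  genome$tracks[[name]] <- iv
  genome
}

#' Fraction of window bases covered by a track
#'
#' The per-window base-level density primitive: for each window, the number
#' of bases covered by the track divided by window length. Used for CNE
#' density in breakpoint regions, flanking windows and genome-wide 1-kb
#' scans.
#'
#' @param windows Interval tibble (`chrom`, `start`, `end`), or a
#'   single-interval list.
#' @param track A normalised interval tibble (see [merge_intervals()]), or a
#'   [karyo_genome()] plus `track_name`.
#' @param track_name When `track` is a genome, the track to use (default
#'   `"CNE"`).
#' @return Numeric vector of fractions in `[0, 1]`, one per window.
#' @examples
#' w <- tibble::tibble(chrom = "c", start = 0, end = 1000)
#' tr <- tibble::tibble(chrom = "c", start = c(100, 900), end = c(200, 950))
#' cne_fraction(w, tr) # 0.15
#' @export
cne_fraction <- function(windows, track, track_name = "CNE") {
  if (inherits(track, "karyo_genome")) track <- track$tracks[[track_name]]
  windows <- as_tibble(windows)
  if (nrow(windows) == 0) return(numeric(0))
  if (any(windows$end - windows$start <= 0)) abort("zero-length window")
  interval_covered_bases(windows, track) / (windows$end - windows$start)
}

# ---- assembly statistics ----------------------------------------------------

#' N50 of a set of unit lengths
#'
#' The length L such that units of length >= L contain at least half of the
#' summed length, scanning in decreasing order.
#'
#' @param lengths Numeric vector of positive unit lengths (bp).
#' @return The N50 (bp).
#' @examples
#' compute_n50(c(8, 5, 3, 2)) # 5
#' @export
compute_n50 <- function(lengths) {
  if (length(lengths) == 0) abort("compute_n50: empty input")
  if (any(lengths <= 0)) abort("compute_n50: lengths must be positive")
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' Percentage of an original assembly represented
#'
#' @param part_length Total placed/represented length (bp).
#' @param original_length Total original assembly length (bp), > 0.
#' @return `100 * part / original`, rounded half-even to 2 decimals.
#' @export
percent_of_assembly <- function(part_length, original_length) {
  if (any(original_length <= 0)) abort("original length must be positive")
  if (any(part_length < 0) || any(part_length > original_length)) {
    abort("part length must lie in [0, original]")
  }
  round(100 * part_length / original_length, 2)
}

#' Assembly summary statistics
#'
#' @param lengths Unit lengths (bp) of the assembly under evaluation.
#' @param original_length Total length of the original scaffold set (bp).
#' @param oriented_length Optional total oriented length (bp); defaults to
#'   `sum(lengths)` (everything oriented).
#' @return One-row tibble: `n_units`, `total_length`, `n50`, `pct_placed`,
#'   `pct_oriented`.
#' @export
assembly_stats <- function(lengths, original_length, oriented_length = sum(lengths)) {
  tibble(
    n_units = length(lengths),
    total_length = sum(lengths),
    n50 = if (length(lengths)) compute_n50(lengths) else NA_real_,
    pct_placed = percent_of_assembly(sum(lengths), original_length),
    pct_oriented = percent_of_assembly(oriented_length, original_length)
  )
}

# ---- IO ---------------------------------------------------------------------

#' Read a BED3 track
#'
#' Tab-separated, 0-based half-open, no header required; `track` and
#' `browser` lines are skipped. Extra columns beyond the first three are
#' ignored.
#'
#' @param path File path.
#' @return Normalised interval tibble (`chrom`, `start`, `end`).
#' @export
read_bed <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  merge_intervals(tibble(
    chrom = vapply(f, `[`, "", 1),
    start = as.numeric(vapply(f, `[`, "", 2)),
    end = as.numeric(vapply(f, `[`, "", 3))
  ))
}

#' Write a BED track (optionally with a name column)
#'
#' @param x Interval tibble; a `name` column, if present, becomes BED column 4.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  cols <- intersect(c("chrom", "start", "end", "name"), names(x))
  readr::write_tsv(as_tibble(x)[cols], path, col_names = FALSE)
  invisible(path)
}

#' Read a genome description (chrom, length TSV)
#'
#' @param path Two-column tab-separated file: chromosome id, length in bp.
#' @return A [karyo_genome()] with empty tracks.
#' @export
read_genome_tsv <- function(path) {
  d <- readr::read_tsv(path, col_names = c("chrom", "length"),
                       col_types = "cd", comment = "#")
  karyo_genome(d)
}
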