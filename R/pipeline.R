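# End-to-end orchestration: simulate a rearranged genome, assemble PCFs
# with PCR-calibrated splitting, anchor them with FISH, classify EBRs and
# run the CNE-density analyses, writing every stage artifact plus a
# manifest with checksums.

#' Pipeline configuration
#'
#' @param sim A [sim_config()] for the synthetic-data stage.
#' @param resolution Assembly resolution (bp); also the homology-map
#'   minimum segment size. Scaled to the synthetic genome (the interface
#'   default of 150 kb suits full-size genomes).
#' @param units Unit-set convention for event counting.
#' @param window_size Window size for the genome-wide CNE scan (bp).
#' @param stages Stages to run, a prefix of
#'   `c("simulate", "assemble", "anchor", "rearrange", "cnestats")`.
#' @param seed Integer seed for the whole run.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), resolution = 10000,
                            units = "identity", window_size = 1000,
                            stages = c("simulate", "assemble", "anchor",
                                       "rearrange", "cnestats"),
                            seed = 1) {
  all_stages <- c("simulate", "assemble", "anchor", "rearrange", "cnestats")
  if (!all(stages %in% all_stages)) abort("unknown stage")
  if (length(stages) > 0 &&
      !identical(stages, all_stages[seq_along(stages)])) {
    abort("stages must be a prefix of simulate/assemble/anchor/rearrange/cnestats")
  }
  structure(list(sim = sim, resolution = resolution, units = units,
                 window_size = window_size, stages = stages, seed = seed),
            class = "pipeline_config")
}

write_tsv_artifact <- function(x, dir, name, files) {
  path <- file.path(dir, name)
  readr::write_tsv(x, path)
  c(files, path)
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order — simulate (ancestor,
#' rearrangements, scaffolds, coverage, BAC panel), assemble (SFs,
#' conflict detection, PCR calibration, PCF chaining), anchor (FISH
#' placement, AGP export), rearrange (homology map, event counts, EBRs)
#' and cnestats (flank contrast, window scan) — writing stage artifacts
#' and a manifest (seed, parameters, checksums) to `out_dir`. Re-running
#' with the same configuration reproduces identical artifacts.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with all in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  files <- character(0)
  res <- list(config = config)
  params <- assembly_params(resolution = config$resolution)

  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      jsonlite::write_json(
        list(stage = name, error = conditionMessage(e)),
        file.path(out_dir, "error.json"), auto_unbox = TRUE
      )
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }

  if ("simulate" %in% config$stages) {
    run_stage("simulate", function() {
      res$ancestor <<- generate_ancestor(config$sim)
      rr <- apply_rearrangements(res$ancestor, config$sim)
      res$karyotype <<- rr$karyotype
      res$truth_events <<- rr$truth
      res$obs <<- fragment_and_observe(res$karyotype, config$sim)
      bp <- emit_bac_panel(res$karyotype, config$sim$bac_spacing,
                           config$sim$bac_dropout)
      res$bacs <<- bp
      files <<- write_tsv_artifact(res$ancestor$chroms, out_dir, "genome.tsv", files)
      write_bed(res$ancestor$tracks$CNE, file.path(out_dir, "cne.bed"))
      write_bed(res$ancestor$tracks$msHSB, file.path(out_dir, "mshsb.bed"))
      files <<- c(files, file.path(out_dir, c("cne.bed", "mshsb.bed")))
      files <<- write_tsv_artifact(res$truth_events, out_dir, "truth_events.tsv", files)
      files <<- write_tsv_artifact(res$obs$scaffolds, out_dir, "scaffolds.tsv", files)
      files <<- write_tsv_artifact(res$obs$blocks, out_dir, "blocks.tsv", files)
      files <<- write_tsv_artifact(res$obs$coverage, out_dir, "coverage.tsv", files)
      files <<- write_tsv_artifact(res$obs$adjacency, out_dir, "adjacency.tsv", files)
      files <<- write_tsv_artifact(res$bacs$bacs, out_dir, "bacs.tsv", files)
      files <<- write_tsv_artifact(res$bacs$observations, out_dir, "fish.tsv", files)
    })
  }

  if ("assemble" %in% config$stages) {
    run_stage("assemble", function() {
      res$sfs <<- build_syntenic_fragments(res$obs$blocks, params)
      joins <- find_conflicting_joins(res$sfs, params)
      conflicting <- filter(joins, .data$conflict)
      if (nrow(conflicting) > 0) {
        pcr <- pcr_oracle(conflicting, res$obs$truth,
                          error_rate = config$sim$pcr_error_rate,
                          tol = config$resolution)
        cov <- numeric(nrow(pcr))
        for (i in seq_len(nrow(pcr))) {
          j <- match_offset(pcr$scaffold_id[i], pcr$junction_offset[i],
                            res$obs$coverage, config$resolution)
          cov[i] <- if (is.na(j)) 0 else res$obs$coverage$spanning_pairs[j]
        }
        pcr$coverage <- cov
        res$pcr <<- pcr
        tested <- filter(pcr, .data$pcr_status %in% c("confirmed", "refuted"))
        res$calibration <<- if (nrow(tested) > 0) calibrate_threshold(pcr) else NULL
      } else {
        res$pcr <<- joins
        res$calibration <<- NULL
      }
      threshold <- if (!is.null(res$calibration)) res$calibration$threshold else 0
      confirmed <- if (nrow(conflicting) > 0) {
        filter(res$pcr, .data$pcr_status == "confirmed")[
          c("scaffold_id", "junction_offset")]
      } else NULL
      res$pcfs <<- assemble_pcfs(res$obs$scaffolds, res$sfs, res$obs$coverage,
                                 params, confirmed = confirmed,
                                 adjacency = res$obs$adjacency,
                                 threshold = threshold)
      res$pcf_stats <<- pcf_stats(res$pcfs, res$obs$scaffolds)
      files <<- write_tsv_artifact(res$sfs, out_dir, "sfs.tsv", files)
      files <<- write_tsv_artifact(res$pcr, out_dir, "joins.tsv", files)
      files <<- write_tsv_artifact(res$pcfs$members, out_dir, "pcf_members.tsv", files)
      files <<- write_tsv_artifact(res$pcfs$splits, out_dir, "splits.tsv", files)
      jsonlite::write_json(
        list(threshold = threshold,
             agreement = if (!is.null(res$calibration)) res$calibration$agreement else NA,
             n_tested = if (!is.null(res$calibration)) res$calibration$n_tested else 0),
        file.path(out_dir, "calibration.json"), auto_unbox = TRUE, digits = NA)
      files <<- c(files, file.path(out_dir, "calibration.json"))
    })
  }

  if ("anchor" %in% config$stages) {
    run_stage("anchor", function() {
      loc <- locate_bacs_on_pcfs(res$bacs$bacs, res$pcfs)
      res$bac_locations <<- loc
      res$assembly <<- anchor(res$pcfs, loc, res$bacs$observations)
      res$anchoring_stats <<- anchoring_stats(res$assembly, res$obs$scaffolds)
      files <<- write_tsv_artifact(res$assembly$chromosomes, out_dir,
                                   "chromosomes.tsv", files)
      export_agp(res$assembly, file.path(out_dir, "assembly.agp"))
      files <<- c(files, file.path(out_dir, "assembly.agp"))
    })
  }

  if ("rearrange" %in% config$stages) {
    run_stage("rearrange", function() {
      segs <- assembly_segments(res$assembly)
      res$homology_map <<- build_homology_map(segs, units = config$units,
                                              min_size = config$resolution,
                                              merge_gap = config$resolution)
      res$event_counts <<- count_interchromosomal_events(res$homology_map)
      res$ebrs <<- detect_ebrs(res$homology_map, genome = res$ancestor)
      files <<- write_tsv_artifact(as_tibble(res$homology_map), out_dir,
                                   "homology_map.tsv", files)
      write_bed(mutate(res$ebrs, name = .data$class),
                file.path(out_dir, "ebrs.bed"))
      files <<- c(files, file.path(out_dir, "ebrs.bed"))
      ec <- res$event_counts
      jsonlite::write_json(
        list(fusions = ec$n_fusions, fissions = ec$n_fissions,
             targets = ec$n_targets, units = ec$n_units,
             intact_units = ec$n_intact_units,
             intact_homologs = ec$n_intact_homologs,
             identity_holds = ec$identity_holds),
        file.path(out_dir, "event_counts.json"), auto_unbox = TRUE, digits = NA)
      files <<- c(files, file.path(out_dir, "event_counts.json"))
    })
  }

  if ("cnestats" %in% config$stages) {
    run_stage("cnestats", function() {
      res$scan <<- scan_1kb_windows(res$ancestor, res$ebrs,
                                    window_size = config$window_size)
      res$flank <<- tryCatch(
        ebr_flank_contrast(res$ebrs, res$ancestor),
        error = function(e) NULL
      )
      files <<- write_tsv_artifact(res$scan$report, out_dir,
                                   "window_report.tsv", files)
      if (!is.null(res$flank)) {
        jsonlite::write_json(
          purrr::transpose(res$flank$tests),
          file.path(out_dir, "flank_tests.json"), auto_unbox = TRUE, digits = NA)
        files <<- c(files, file.path(out_dir, "flank_tests.json"))
      }
    })
  }

  manifest <- list(
    package = "karyoforge",
    version = as.character(utils::packageVersion("karyoforge")),
    seed = config$seed,
    stages = config$stages,
    resolution = config$resolution,
    window_size = config$window_size,
    sim = unclass(config$sim),
    checksums = as.list(tools::md5sum(sort(files)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

#' Report tables from a pipeline run directory
#'
#' Re-reads stage artifacts and lays out three report blocks: split-region
#' statistics (tested/confirmed/refuted joins and the selected spanning
#' threshold), assembly statistics (original scaffolds, PCFs, anchored
#' chromosomes), and the CNE-density class table. Missing stage outputs
#' yield partial reports with explicit `NA` gaps. Regeneration is
#' idempotent.
#'
#' @param run_dir Directory written by [run_pipeline()].
#' @param write Write `report_*.tsv` files into `run_dir`.
#' @return Named list of tibbles: `split_regions`, `assembly`,
#'   `cne_density`.
#' @export
report_tables <- function(run_dir, write = TRUE) {
  rd <- function(name, coltypes = NULL) {
    p <- file.path(run_dir, name)
    if (!file.exists(p)) return(NULL)
    readr::read_tsv(p, show_col_types = FALSE)
  }
  joins <- rd("joins.tsv")
  calib <- {
    p <- file.path(run_dir, "calibration.json")
    if (file.exists(p)) jsonlite::read_json(p) else NULL
  }
  split_regions <- if (!is.null(joins) && nrow(joins) > 0) {
    tested <- joins[joins$pcr_status %in% c("confirmed", "refuted"), ]
    tibble(
      statistic = c("physical coverage range (tested joins)",
                    "no. conflicting joins", "no. tested split regions",
                    "no. confirmed joins", "no. refuted joins",
                    "selected spanning threshold"),
      value = c(
        if (nrow(tested)) paste0(min(tested$coverage), "-", max(tested$coverage))
        else NA_character_,
        as.character(sum(joins$conflict)),
        as.character(nrow(tested)),
        as.character(sum(joins$pcr_status == "confirmed")),
        as.character(sum(joins$pcr_status == "refuted")),
        as.character(if (!is.null(calib)) calib$threshold else NA)
      )
    )
  } else tibble(statistic = character(), value = character())

  scaffolds <- rd("scaffolds.tsv")
  members <- rd("pcf_members.tsv")
  chroms <- rd("chromosomes.tsv")
  assembly <- if (!is.null(scaffolds)) {
    orig <- assembly_stats(scaffolds$length, sum(scaffolds$length))
    rows <- mutate(orig, set = "original scaffolds")
    if (!is.null(members)) {
      pcf_lens <- members %>%
        group_by(.data$pcf_id) %>%
        summarise(length = sum(.data$s_end - .data$s_start), .groups = "drop")
      rows <- bind_rows(rows, mutate(
        assembly_stats(pcf_lens$length, sum(scaffolds$length)), set = "PCFs"))
      if (!is.null(chroms) && nrow(chroms) > 0) {
        placed <- pcf_lens %>% filter(.data$pcf_id %in% chroms$pcf_id)
        oriented <- pcf_lens %>%
          filter(.data$pcf_id %in% chroms$pcf_id[chroms$strand != "?"])
        rows <- bind_rows(rows, mutate(
          assembly_stats(placed$length, sum(scaffolds$length),
                         oriented_length = sum(oriented$length)),
          set = "anchored chromosomes"))
      }
    }
    select(rows, "set", dplyr::everything())
  } else tibble()

  window_report <- rd("window_report.tsv")
  cne_density <- if (!is.null(window_report)) window_report else {
    tibble(class = c("msHSB", "intrachromosomal", "fusion", "fission",
                     "rest", "genome"),
           n_windows = NA_integer_, mean_cne_bases = NA_real_,
           mean_density = NA_real_)
  }

  out <- list(split_regions = split_regions, assembly = assembly,
              cne_density = cne_density)
  if (write) {
    readr::write_tsv(split_regions, file.path(run_dir, "report_split_regions.tsv"))
    if (nrow(assembly) > 0) {
      readr::write_tsv(assembly, file.path(run_dir, "report_assembly.tsv"))
    }
    readr::write_tsv(cne_density, file.path(run_dir, "report_cne_density.tsv"))
  }
  out
}
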