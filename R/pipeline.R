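## End-to-end orchestration: simulate -> refine -> call -> ploidy ->
## summarize, and the PCD mapping loop, with truth-based recovery scoring.

default_run_config <- function() {
  list(seed = 42L, n_mutants = 10L, mean_depth = 100, error_rate = 0,
       noise = "none", group = "BYxRM-like",
       caller = caller_params(), ploidy = ploidy_params(),
       out_dir = NULL, with_truth = TRUE)
}

#' Run the full screen analysis on a synthetic cohort
#'
#' Generates (or accepts) a cohort fixture, refines the progenitor reference
#' from the base genome, calls and classifies each mutant's point mutations,
#' deduplicates them across the cohort, classifies every chromosome's ploidy
#' from scaled windowed coverage, summarizes arm-disomy for the focal arm,
#' and — when truth is present — scores recovery.
#'
#' @param config list overriding [default_run_config()] entries (seed,
#'   n_mutants, mean_depth, error_rate, noise, group, caller, ploidy,
#'   out_dir, with_truth, fixture).
#' @return `screen_report` list; written as JSON/TSVs when `out_dir` is set.
#' @export
run_screen_analysis <- function(config = list()) {
  cfg <- utils::modifyList(default_run_config(), config)
  fixture <- cfg$fixture %||% cohort_fixture(cfg$seed, cfg$n_mutants)

  provider <- function(genome) {
    simulate_pileup(fixture$progenitor, genome, mean_depth = cfg$mean_depth,
                    error_rate = cfg$error_rate, noise = cfg$noise,
                    seed = cfg$seed + 1000L)
  }
  refined <- refine_reference(fixture$base, provider, max_cycles = 10L,
                              params = cfg$caller)

  all_calls <- list(); ploidy_calls <- list()
  for (i in seq_along(fixture$mutants)) {
    id <- names(fixture$mutants)[i]
    model <- fixture$mutants[[i]]
    pu <- simulate_pileup(model, refined$genome, mean_depth = cfg$mean_depth,
                          error_rate = cfg$error_rate, noise = cfg$noise,
                          seed = cfg$seed + i)
    calls <- call_mutations(pu, refined, cfg$caller, mutant_id = id)
    if (nrow(calls))
      calls$effect_class <- classify_effect(calls, fixture$annotation,
                                            refined$genome)
    all_calls[[id]] <- calls
    track <- scale_track(windowed_coverage(pu, cfg$ploidy))
    pc <- do.call(rbind, lapply(names(refined$genome), function(ch)
      classify_ploidy(track, ch, cfg$ploidy)))
    pc$mutant_id <- id
    pc$group <- cfg$group
    ploidy_calls[[id]] <- pc
  }
  calls <- do.call(rbind, c(all_calls, list(make.row.names = FALSE)))
  pcalls <- do.call(rbind, c(ploidy_calls, list(make.row.names = FALSE)))
  uniq <- unique_mutations(calls)
  focal <- pcalls[pcalls$chrom == fixture$focal_chrom, , drop = FALSE]
  cohort <- summarize_cohort(focal, fixture$focal_arm)

  report <- list(seed = cfg$seed,
                 parameters = list(mean_depth = cfg$mean_depth,
                                   error_rate = cfg$error_rate,
                                   noise = cfg$noise,
                                   min_fraction = cfg$caller$min_fraction,
                                   min_depth = cfg$caller$min_depth,
                                   window_bp = cfg$ploidy$window_bp),
                 refinement = list(cycles_run = refined$cycles_run,
                                   converged = refined$converged,
                                   variants_per_cycle = refined$variants_per_cycle),
                 n_mutants = length(fixture$mutants),
                 mutation_calls = calls,
                 unique_mutations = uniq$unique,
                 n_unique = uniq$n_unique,
                 counts_by_effect = as.list(uniq$counts),
                 ploidy_calls = pcalls,
                 cohort_summary = cohort)

  if (isTRUE(cfg$with_truth))
    report$recovery <- score_recovery(fixture, calls, pcalls)
  class(report) <- "screen_report"

  if (!is.null(cfg$out_dir)) write_screen_report(report, cfg$out_dir)
  report
}

score_recovery <- function(fixture, calls, pcalls) {
  tp <- 0L; planted <- 0L
  for (id in names(fixture$mutants)) {
    tr <- fixture$mutants[[id]]$truth
    pts <- tr[tr$event_type %in% c("snv", "indel"), , drop = FALSE]
    mine <- calls[calls$mutant_id == id, , drop = FALSE]
    planted <- planted + nrow(pts)
    if (nrow(pts))
      tp <- tp + sum(paste(pts$chrom, pts$start) %in% paste(mine$chrom, mine$pos))
  }
  called <- nrow(calls)

  dis_tp <- 0L; dis_planted <- 0L; dis_called <- 0L
  for (id in names(fixture$mutants)) {
    tr <- fixture$mutants[[id]]$truth
    dis <- tr$chrom[tr$event_type %in% c("disomy", "segmental_dup")]
    pc <- pcalls[pcalls$mutant_id == id & pcalls$scope != "euploid", , drop = FALSE]
    dis_planted <- dis_planted + length(dis)
    dis_called <- dis_called + nrow(pc)
    dis_tp <- dis_tp + sum(pc$chrom %in% dis)
  }
  list(point_sensitivity = if (planted) tp / planted else NA_real_,
       point_precision = if (called) tp / called else NA_real_,
       ploidy_sensitivity = if (dis_planted) dis_tp / dis_planted else NA_real_,
       ploidy_precision = if (dis_called) dis_tp / dis_called else NA_real_)
}

write_screen_report <- function(report, out_dir) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stopf("cannot create output directory %s", out_dir)
  json <- report
  class(json) <- NULL
  jsonlite::write_json(json, file.path(out_dir, "screen_report.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = 10,
                       na = "null", pretty = TRUE)
  data.table::fwrite(report$mutation_calls,
                     file.path(out_dir, "mutation_calls.tsv"), sep = "\t")
  data.table::fwrite(report$ploidy_calls,
                     file.path(out_dir, "ploidy_calls.tsv"), sep = "\t")
  data.table::fwrite(report$cohort_summary,
                     file.path(out_dir, "cohort_summary.tsv"), sep = "\t")
  invisible(out_dir)
}

#' Run PCD causal-interval mapping
#'
#' Infers the causal interval from a truncation-panel results table, lists
#' the annotation features it contains, and plans the next tiling round.
#'
#' @param config list with entries: `results` (data.frame strain_id /
#'   insertion_pos / reverted, or a TSV path), `region` (list chrom, lower,
#'   upper), optional `genome` (genome or FASTA path), optional `annotation`
#'   (data.frame or BED path), `target_spacing_bp` for the next round,
#'   optional `out_dir`.
#' @return `pcd_report` list: interval, interval_length_kb, features,
#'   next_tiling.
#' @export
run_pcd_mapping <- function(config) {
  results <- config$results
  if (is.character(results)) {
    results <- data.table::fread(results, sep = "\t", header = TRUE)
    data.table::setDF(results)
  }
  if (is.null(results) || nrow(results) == 0L)
    stopf("empty truncation results table; nothing to map")
  annotation <- config$annotation
  if (is.character(annotation)) annotation <- read_annotation_bed(annotation)

  interval <- infer_interval(results, config$region)
  spacing <- config$target_spacing_bp %||% 50000L
  next_spacing <- max(500L, as.integer(round(spacing / 5)))
  report <- list(
    interval = list(chrom = interval$chrom, lower = interval$lower,
                    upper = interval$upper, length_bp = interval$length_bp,
                    censored = interval$censored),
    interval_length_kb = round(interval$length_bp / 1000),
    next_tiling = plan_tiling(list(chrom = interval$chrom,
                                   lower = interval$lower,
                                   upper = interval$upper),
                              target_spacing_bp = next_spacing))
  if (!is.null(annotation)) {
    g <- genes_in_interval(annotation, interval)
    report$features <- g$features
    report$n_genes <- g$n_genes
    report$n_dubious <- g$n_dubious
  }
  class(report) <- "pcd_report"
  if (!is.null(config$out_dir)) {
    if (!dir.exists(config$out_dir) &&
        !dir.create(config$out_dir, recursive = TRUE))
      stopf("cannot create output directory %s", config$out_dir)
    json <- report; class(json) <- NULL
    jsonlite::write_json(json, file.path(config$out_dir, "pcd_mapping.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = 10,
                         na = "null", pretty = TRUE)
  }
  report
}
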