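## Screen phenotype arithmetic: MIC determination, the two-stage tolerance
## filter, tolerance gains, replicate summaries and relative qPCR copy number.

#' Screen filter parameters
#'
#' The screen retains mutants whose MIC exceeds their progenitor's by at
#' least 1 mM at the initial pass and 0.5 mM at side-by-side confirmation.
#'
#' @param stage1_delta_mM initial-screen MIC gain threshold (mM).
#' @param stage2_delta_mM confirmation-stage MIC gain threshold (mM).
#' @export
screen_params <- function(stage1_delta_mM = 1.0, stage2_delta_mM = 0.5) {
  if (stage1_delta_mM <= 0 || stage2_delta_mM <= 0)
    stopf("screen thresholds must be > 0")
  structure(list(stage1_delta_mM = stage1_delta_mM,
                 stage2_delta_mM = stage2_delta_mM),
            class = "screen_params")
}

#' Minimum inhibitory concentration from a dose-response table
#'
#' The MIC is the lowest dose at which the strain could not grow. Growth at
#' every tested dose yields a right-censored result (`> max dose`). A
#' non-monotone pattern (growth above a no-growth dose) still returns the
#' literal lowest no-growth dose, with a warning recorded.
#'
#' @param dr data.frame with columns dose_mM and grew (logical or 0/1);
#'   optionally strain_id.
#' @return `mic_result` list: strain_id, mic_mM (NA when censored),
#'   censored, max_dose_mM, warnings.
#' @export
compute_mic <- function(dr) {
  if (nrow(dr) == 0L) stopf("empty dose list")
  if (any(dr$dose_mM < 0)) stopf("doses must be >= 0")
  if (anyDuplicated(dr$dose_mM)) stopf("doses must be unique")
  dr <- dr[order(dr$dose_mM), , drop = FALSE]
  grew <- as.logical(dr$grew)
  strain <- if ("strain_id" %in% names(dr)) dr$strain_id[1] else NA_character_
  warnings <- character()
  if (!any(!grew)) {
    return(structure(list(strain_id = strain, mic_mM = NA_real_,
                          censored = TRUE, max_dose_mM = max(dr$dose_mM),
                          warnings = warnings),
                     class = "mic_result"))
  }
  mic <- min(dr$dose_mM[!grew])
  if (any(grew & dr$dose_mM > mic))
    warnings <- "non-monotone growth: growth observed above the MIC"
  structure(list(strain_id = strain, mic_mM = mic, censored = FALSE,
                 max_dose_mM = max(dr$dose_mM), warnings = warnings),
            class = "mic_result")
}

#' MIC table for many strains
#'
#' @param doses data.frame with columns strain, cross (optional), dose_mM,
#'   grew.
#' @return data.frame: strain, cross, mic_mM, censored, warnings.
#' @export
mic_table <- function(doses) {
  split_by <- doses$strain
  rows <- lapply(split(doses, split_by), function(d) {
    r <- compute_mic(data.frame(strain_id = d$strain[1], dose_mM = d$dose_mM,
                                grew = d$grew))
    data.frame(strain = d$strain[1],
               cross = if ("cross" %in% names(d)) d$cross[1] else NA_character_,
               mic_mM = r$mic_mM, censored = r$censored,
               warnings = paste(r$warnings, collapse = "; "))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$cross, out$strain), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Two-stage tolerance filter
#'
#' Keeps a candidate iff its MIC exceeds the progenitor's by at least the
#' stage threshold (inclusive at the boundary). A censored candidate MIC
#' (growth at every tested dose) is always kept, flagged.
#'
#' @param candidates data.frame with columns strain, mic_mM, censored (from
#'   [mic_table()]).
#' @param progenitor `mic_result` (or one-row data.frame with mic_mM,
#'   censored) for the progenitor; must not be censored.
#' @param params a [screen_params()].
#' @param stage `"initial"` (1 mM) or `"confirmation"` (0.5 mM).
#' @return `candidates` with added columns delta_mM, kept, reason.
#' @export
screen_filter <- function(candidates, progenitor, params = screen_params(),
                          stage = c("confirmation", "initial")) {
  stage <- match.arg(stage)
  prog_mic <- if (inherits(progenitor, "mic_result")) progenitor$mic_mM
              else progenitor$mic_mM[1]
  prog_cens <- if (inherits(progenitor, "mic_result")) progenitor$censored
               else isTRUE(progenitor$censored[1])
  if (prog_cens || is.na(prog_mic))
    stopf("progenitor MIC is censored; the filter threshold is undefined")
  delta_req <- if (stage == "initial") params$stage1_delta_mM else params$stage2_delta_mM

  out <- candidates
  out$delta_mM <- out$mic_mM - prog_mic
  eps <- 1e-9
  out$kept <- (!is.na(out$delta_mM) & out$delta_mM >= delta_req - eps) | out$censored
  out$reason <- ifelse(out$censored, "censored MIC above tested range: kept, flagged",
                       ifelse(out$kept,
                              sprintf("MIC gain >= %.1f mM", delta_req),
                              sprintf("MIC gain below %.1f mM", delta_req)))
  out
}

#' Tolerance gain of a mutant over its progenitor
#'
#' @param mutant,progenitor `mic_result`s (or numbers); neither censored.
#' @return list with delta_mM and percent (100 x delta / progenitor MIC).
#' @export
tolerance_gain <- function(mutant, progenitor) {
  m <- if (inherits(mutant, "mic_result")) mutant$mic_mM else mutant
  p <- if (inherits(progenitor, "mic_result")) progenitor$mic_mM else progenitor
  if (is.na(m) || is.na(p)) stopf("tolerance gain undefined for censored MICs")
  if (p == 0) stopf("progenitor MIC of 0 mM: percent gain undefined")
  list(delta_mM = m - p, percent = 100 * (m - p) / p)
}

#' qPCR quantification parameters
#'
#' @param efficiency amplification efficiency (2 = perfect doubling per
#'   cycle).
#' @param reference_gene label of the internal reference gene.
#' @param calibrator label of the calibrator (1-copy) sample.
#' @export
qpcr_params <- function(efficiency = 2.0, reference_gene = "ACT1",
                        calibrator = "calibrator") {
  if (efficiency <= 1) stopf("efficiency must be > 1")
  structure(list(efficiency = efficiency, reference_gene = reference_gene,
                 calibrator = calibrator),
            class = "qpcr_params")
}

#' Relative quantification of a target locus (delta-delta Cq)
#'
#' `dCq = mean(target Cq) - mean(reference Cq)` within each sample; the
#' relative quantity is `efficiency^-(dCq_sample - dCq_calibrator)`, so a
#' duplicated locus in the sample gives ~2 at efficiency 2.
#'
#' @param sample_cq data.frame with columns target, cq for the test sample
#'   (reference-gene rows identified by `params$reference_gene`).
#' @param calibrator_cq same layout for the calibrator sample.
#' @param params a [qpcr_params()].
#' @return list: relative_quantity, dcq_sample, dcq_calibrator, target.
#' @export
qpcr_relative <- function(sample_cq, calibrator_cq, params = qpcr_params()) {
  dcq <- function(tab, who) {
    ref <- tab$cq[tab$target == params$reference_gene]
    tgt <- tab$cq[tab$target != params$reference_gene]
    if (length(ref) == 0L)
      stopf("%s: no Cq replicates for reference gene %s", who,
            params$reference_gene)
    if (length(tgt) == 0L) stopf("%s: no Cq replicates for the target", who)
    list(d = mean(tgt) - mean(ref),
         target = unique(tab$target[tab$target != params$reference_gene])[1])
  }
  s <- dcq(sample_cq, "sample")
  c <- dcq(calibrator_cq, "calibrator")
  list(relative_quantity = params$efficiency^-(s$d - c$d),
       dcq_sample = s$d, dcq_calibrator = c$d, target = s$target)
}

#' Summarize biological replicates with a 95% t confidence interval
#'
#' Technical replicates are averaged within each biological replicate first;
#' the CI is `mean +/- t(0.975, n-1) * sd / sqrt(n)` over biological
#' replicates. With a single biological replicate the mean is returned and
#' the CI flagged undefined.
#'
#' @param values numeric vector of biological-replicate values (ignored when
#'   `technical_reps` is given).
#' @param technical_reps optional list of numeric vectors, one per
#'   biological replicate.
#' @return list: mean, ci_low, ci_high, n_biological, ci_defined.
#' @export
summarize_replicates <- function(values = NULL, technical_reps = NULL) {
  if (!is.null(technical_reps))
    values <- vapply(technical_reps, mean, numeric(1))
  if (is.null(values) || length(values) == 0L) stopf("no replicate values")
  n <- length(values)
  m <- mean(values)
  if (n < 2L)
    return(list(mean = m, ci_low = NA_real_, ci_high = NA_real_,
                n_biological = n, ci_defined = FALSE))
  half <- stats::qt(0.975, n - 1L) * stats::sd(values) / sqrt(n)
  list(mean = m, ci_low = m - half, ci_high = m + half, n_biological = n,
       ci_defined = TRUE)
}
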