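## Coverage-based detection of whole-chromosome disomies and terminal
## segmental duplications in haploid strains.

#' Ploidy-detection parameters
#'
#' @param window_bp genomic window size in bp.
#' @param baseline_estimator how the euploid (copy-1) coverage level is
#'   estimated: `"median_of_chrom_medians"` (robust to one large disomic
#'   chromosome inflating the mean) or `"genome_mean"`.
#' @param whole_chrom_fraction fraction of windows that must share a modal
#'   copy number > 1 for a whole-chromosome call.
#' @param min_segment_windows minimum windows per segment for segmental
#'   detection.
#' @param cn_max largest copy number considered.
#' @param half_band scaled values within this distance of a half-integer
#'   multiple of baseline are flagged low-confidence.
#' @export
ploidy_params <- function(window_bp = 1000L,
                          baseline_estimator = c("median_of_chrom_medians",
                                                 "genome_mean"),
                          whole_chrom_fraction = 0.95,
                          min_segment_windows = 10L, cn_max = 4L,
                          half_band = 0.15) {
  baseline_estimator <- match.arg(baseline_estimator)
  if (window_bp < 1) stopf("window_bp must be >= 1")
  if (whole_chrom_fraction <= 0 || whole_chrom_fraction > 1)
    stopf("whole_chrom_fraction must be in (0, 1]")
  structure(list(window_bp = as.integer(window_bp),
                 baseline_estimator = baseline_estimator,
                 whole_chrom_fraction = whole_chrom_fraction,
                 min_segment_windows = as.integer(min_segment_windows),
                 cn_max = as.integer(cn_max), half_band = half_band),
            class = "ploidy_params")
}

#' Windowed sequencing coverage from a pileup
#'
#' Window means are the arithmetic mean of per-site depths; the final partial
#' window of each chromosome is kept with its true length. A chromosome
#' shorter than one window yields a single window spanning it.
#'
#' @param pileup dense pileup data.frame (zero-filled where uncovered).
#' @param params a [ploidy_params()].
#' @return A `coverage_track`: list with `windows` (chrom, start, end,
#'   n_sites, mean_depth, scaled_value) and `genome_mean_depth`.
#' @export
windowed_coverage <- function(pileup, params = ploidy_params()) {
  dt <- data.table::as.data.table(pileup[, c("chrom", "pos", "depth")])
  wb <- params$window_bp
  dt[, win := (pos - 1L) %/% wb]
  w <- dt[, list(start = win[1L] * wb + 1L, end = max(pos), n_sites = .N,
                 mean_depth = mean(depth)),
          by = c("chrom", "win")]
  w[, win := NULL]
  data.table::setDF(w)
  w$scaled_value <- NA_real_
  structure(list(windows = w, genome_mean_depth = mean(dt$depth),
                 scaled = FALSE),
            class = "coverage_track")
}

#' Scale a coverage track to the genome-wide per-site mean
#'
#' Each window mean is divided by the genome-wide average per-site coverage,
#' so a euploid region sits at 1 and the length-weighted mean of scaled
#' values over the genome is exactly 1.
#'
#' @param track a `coverage_track`.
#' @return The track with `scaled_value` filled in.
#' @export
scale_track <- function(track) {
  if (!inherits(track, "coverage_track")) stopf("not a coverage_track")
  if (is.na(track$genome_mean_depth) || track$genome_mean_depth <= 0)
    stopf("genome mean depth is zero; cannot scale")
  track$windows$scaled_value <- track$windows$mean_depth / track$genome_mean_depth
  track$scaled <- TRUE
  track
}

track_baseline <- function(track, params) {
  if (params$baseline_estimator == "genome_mean") return(1)
  med <- tapply(track$windows$scaled_value, track$windows$chrom, stats::median)
  stats::median(med)
}

euploid_call <- function(chrom) {
  data.frame(chrom = chrom, copy_number = 1L, scope = "euploid",
             breakpoint = NA_integer_, dup_start = NA_integer_,
             dup_end = NA_integer_, duplicated_span_bp = 0L,
             duplicated_fraction = 0, n_low_confidence = 0L)
}

#' Classify a chromosome's ploidy from scaled coverage
#'
#' The euploid baseline is estimated from the whole track (by default the
#' median of per-chromosome median scaled values). Per-window copy numbers
#' are the baseline-relative values rounded to the nearest integer and
#' clipped to `[1, cn_max]`. If at least `whole_chrom_fraction` of windows
#' share a modal copy number above 1 the chromosome is called a whole
#' duplication; otherwise a single-changepoint segmental scan is attempted;
#' otherwise the chromosome is euploid.
#'
#' @param track a scaled `coverage_track` covering the whole genome.
#' @param chrom chromosome to classify.
#' @param params a [ploidy_params()].
#' @return One-row data.frame: chrom, copy_number, scope
#'   (euploid/whole/segmental), breakpoint, dup_start, dup_end,
#'   duplicated_span_bp, duplicated_fraction, n_low_confidence.
#' @export
classify_ploidy <- function(track, chrom, params = ploidy_params()) {
  if (!isTRUE(track$scaled)) stopf("track must be scaled first (scale_track)")
  w <- track$windows[track$windows$chrom == chrom, , drop = FALSE]
  if (nrow(w) == 0L) stopf("no windows for chromosome '%s'", chrom)
  b <- track_baseline(track, params)
  rel <- w$scaled_value / b
  cn <- pmin(pmax(as.integer(round(rel)), 1L), params$cn_max)
  half_dist <- abs(rel - (floor(rel) + 0.5))
  n_low <- sum(half_dist <= params$half_band)

  tab <- table(cn)
  modal <- as.integer(names(tab)[which.max(tab)])
  chrom_len <- max(w$end)

  if (modal > 1L && mean(cn == modal) >= params$whole_chrom_fraction) {
    return(data.frame(chrom = chrom, copy_number = modal, scope = "whole",
                      breakpoint = NA_integer_, dup_start = 1L,
                      dup_end = chrom_len, duplicated_span_bp = chrom_len,
                      duplicated_fraction = 1, n_low_confidence = n_low))
  }
  if (nrow(w) < params$min_segment_windows) {
    warnf("%s: only %d windows; segmental detection skipped", chrom, nrow(w))
    out <- euploid_call(chrom)
    out$copy_number <- modal
    if (modal > 1L) {
      out$scope <- "whole"
      out$dup_start <- 1L; out$dup_end <- chrom_len
      out$duplicated_span_bp <- chrom_len; out$duplicated_fraction <- 1
    }
    out$n_low_confidence <- n_low
    return(out)
  }
  if (nrow(w) >= 2L * params$min_segment_windows) {
    seg <- detect_segmental(track, chrom, params)
    if (seg$scope == "segmental") {
      seg$n_low_confidence <- n_low
      return(seg)
    }
  }
  out <- euploid_call(chrom)
  out$n_low_confidence <- n_low
  out
}

#' Detect a single terminal/internal-boundary segmental duplication
#'
#' Scans every admissible single changepoint for the two-level
#' piecewise-constant fit minimizing the total squared error of the window
#' values (leftmost changepoint on ties). A segmental call is returned iff
#' the two segments round to different copy numbers against the baseline and
#' each segment has at least `min_segment_windows` windows; the breakpoint is
#' the left edge (start coordinate) of the right segment.
#'
#' @inheritParams classify_ploidy
#' @return One-row ploidy-call data.frame (scope `"segmental"`, or a fallback
#'   euploid row when no two-level structure is found).
#' @export
detect_segmental <- function(track, chrom, params = ploidy_params()) {
  if (!isTRUE(track$scaled)) stopf("track must be scaled first (scale_track)")
  w <- track$windows[track$windows$chrom == chrom, , drop = FALSE]
  w <- w[order(w$start), , drop = FALSE]
  W <- nrow(w)
  msw <- params$min_segment_windows
  if (W < 2L * msw) return(euploid_call(chrom))
  v <- w$scaled_value
  b <- track_baseline(track, params)

  cum <- cumsum(v); cum2 <- cumsum(v^2)
  ks <- msw:(W - msw)
  sse_l <- cum2[ks] - cum[ks]^2 / ks
  sse_r <- (cum2[W] - cum2[ks]) - (cum[W] - cum[ks])^2 / (W - ks)
  total <- sse_l + sse_r
  k <- ks[which.min(total)]                 # which.min takes the leftmost tie

  mean_l <- cum[k] / k
  mean_r <- (cum[W] - cum[k]) / (W - k)
  cn_l <- pmin(pmax(as.integer(round(mean_l / b)), 1L), params$cn_max)
  cn_r <- pmin(pmax(as.integer(round(mean_r / b)), 1L), params$cn_max)
  if (cn_l == cn_r) return(euploid_call(chrom))

  chrom_len <- max(w$end)
  breakpoint <- w$start[k + 1L]
  if (cn_r > cn_l) {
    dup_start <- breakpoint; dup_end <- chrom_len; cn <- cn_r
  } else {
    dup_start <- w$start[1L]; dup_end <- breakpoint - 1L; cn <- cn_l
  }
  span <- dup_end - dup_start + 1L
  data.frame(chrom = chrom, copy_number = cn, scope = "segmental",
             breakpoint = breakpoint, dup_start = dup_start, dup_end = dup_end,
             duplicated_span_bp = span,
             duplicated_fraction = span / chrom_len, n_low_confidence = 0L)
}

#' Summarize arm-disomy across a mutant cohort
#'
#' A mutant counts as disomic for the focal arm when its call reaches copy
#' number >= 2 and covers the whole arm: any whole-chromosome call, or a
#' segmental call whose duplicated span contains the arm. Percentages are
#' rounded to the nearest integer. An `all` row aggregates the entire screen.
#'
#' @param calls data.frame with columns mutant_id, group plus the ploidy-call
#'   columns of [classify_ploidy()] for the focal chromosome.
#' @param focal_arm list with chrom, start, end (1-based inclusive).
#' @return data.frame: group, n_mutants, n_arm_disomic, fraction_percent.
#' @export
summarize_cohort <- function(calls, focal_arm) {
  if (nrow(calls) == 0L) stopf("empty cohort")
  hit <- calls$copy_number >= 2L & calls$chrom == focal_arm$chrom &
    (calls$scope == "whole" |
       (calls$scope == "segmental" &
          !is.na(calls$dup_start) & calls$dup_start <= focal_arm$start &
          calls$dup_end >= focal_arm$end))
  groups <- c(unique(calls$group), "all")
  rows <- lapply(groups, function(g) {
    sel <- if (g == "all") rep(TRUE, nrow(calls)) else calls$group == g
    data.frame(group = g, n_mutants = sum(sel), n_arm_disomic = sum(hit[sel]),
               fraction_percent = as.integer(round(100 * mean(hit[sel]))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Plot a genome-wide scaled coverage track
#'
#' One panel per chromosome, scaled coverage against position, with guide
#' lines at 1x and 2x the genome average.
#'
#' @param track a scaled `coverage_track`.
#' @param path optional file to save to (png/pdf by extension).
#' @return The ggplot object, invisibly.
#' @export
plot_coverage <- function(track, path = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stopf("plot_coverage requires the ggplot2 package")
  w <- track$windows
  w$mid <- (w$start + w$end) / 2
  p <- ggplot2::ggplot(w, ggplot2::aes(x = mid / 1e3, y = scaled_value)) +
    ggplot2::geom_hline(yintercept = c(1, 2), linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_point(size = 0.3) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (kb)", y = "coverage / genome mean") +
    ggplot2::theme_bw()
  if (!is.null(path)) ggplot2::ggsave(path, p, width = 10, height = 6)
  invisible(p)
}
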