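## PCR-mediated chromosomal deletion (PCD): construct design, staggered
## truncation panels, and causal-interval inference.
##
## A PCD construct truncates a chromosome at an insertion point: everything
## distal (telomere-proximal) to the integration site is lost and a new
## telomere is nucleated by a synthetic seed. A truncation at position p that
## reverts the phenotype implies the causal element lies at or beyond p.

#' PCD design parameters
#'
#' @param arm_len homology-arm length in bp (300-600).
#' @param fusion_tail_len length of the overlap-fusion tails in bases.
#' @param telomere_motif repeated telomere-seed motif.
#' @param telomere_repeats number of motif repeats.
#' @param cassette_id label of the selection cassette.
#' @export
pcd_params <- function(arm_len = 450L, fusion_tail_len = 30L,
                       telomere_motif = "CCCCAA", telomere_repeats = 6L,
                       cassette_id = "kanMX") {
  if (arm_len < 300 || arm_len > 600)
    stopf("arm_len must be in [300, 600] bp, got %s", arm_len)
  if (fusion_tail_len < 1) stopf("fusion_tail_len must be >= 1")
  structure(list(arm_len = as.integer(arm_len),
                 fusion_tail_len = as.integer(fusion_tail_len),
                 telomere_motif = telomere_motif,
                 telomere_repeats = as.integer(telomere_repeats),
                 cassette_id = cassette_id),
            class = "pcd_params")
}

#' Packaged synthetic kanMX-like cassette sequence
#'
#' A deterministic synthetic stand-in for a kanMX selection cassette (the
#' real cassette can be supplied to [design_construct()] instead).
#'
#' @return Single DNA string.
#' @export
kanmx_cassette <- function() {
  path <- system.file("extdata", "kanmx_synthetic.fa", package = "aneuscreen",
                      mustWork = TRUE)
  unname(read_genome_fasta(path)[1])
}

#' Design a PCD truncation construct
#'
#' The construct carries, in order: a homology arm ending at the insertion
#' position, the selection cassette, and a synthetic telomere seed. Primers
#' are emitted 5'->3'; the arm reverse and cassette forward primers carry
#' `fusion_tail_len`-base tails identical to their fusion partner's terminus
#' so the pieces can be joined by overlap fusion.
#'
#' @param genome genome (named character vector).
#' @param chrom chromosome carrying the insertion site.
#' @param insertion_pos 1-based position; sequence distal to it is deleted.
#' @param params a [pcd_params()].
#' @param cassette_seq cassette DNA string; defaults to [kanmx_cassette()].
#' @param anneal_len primer annealing length in bases.
#' @return `pcd_construct` list: coordinates, segment sequences, primers and
#'   the assembled construct sequence.
#' @export
design_construct <- function(genome, chrom, insertion_pos,
                             params = pcd_params(), cassette_seq = NULL,
                             anneal_len = 20L) {
  if (!chrom %in% names(genome)) stopf("unknown chromosome '%s'", chrom)
  arm_start <- insertion_pos - params$arm_len + 1L
  if (arm_start < 1L)
    stopf("insertion at %s:%d is too close to the chromosome start for a %d bp arm",
          chrom, insertion_pos, params$arm_len)
  if (insertion_pos > nchar(genome[[chrom]]))
    stopf("insertion position %d beyond end of %s", insertion_pos, chrom)
  cassette_seq <- cassette_seq %||% kanmx_cassette()
  tl <- params$fusion_tail_len
  if (nchar(cassette_seq) < tl + anneal_len)
    stopf("cassette too short for %d-base fusion tails", tl)

  arm_seq <- substr(genome[[chrom]], arm_start, insertion_pos)
  seed_seq <- strrep(params$telomere_motif, params$telomere_repeats)

  arm_tail <- substr(arm_seq, nchar(arm_seq) - tl + 1L, nchar(arm_seq))
  cassette_head <- substr(cassette_seq, 1L, tl)
  cassette_tail20 <- substr(cassette_seq, nchar(cassette_seq) - anneal_len + 1L,
                            nchar(cassette_seq))

  primers <- list(
    arm_fwd = substr(arm_seq, 1L, anneal_len),
    ## reverse primer for the arm, 5'-tailed with identity to the cassette:
    ## revcomp(arm_end + cassette_head) = revcomp(cassette_head) + revcomp(arm_end)
    arm_rev = revcomp(paste0(substr(arm_seq, nchar(arm_seq) - anneal_len + 1L,
                                    nchar(arm_seq)), cassette_head)),
    ## forward primer for the cassette, tailed with the arm's terminus
    cassette_fwd = paste0(arm_tail, substr(cassette_seq, 1L, anneal_len)),
    ## reverse primer appending the telomere seed to the cassette
    cassette_rev = revcomp(paste0(cassette_tail20, seed_seq))
  )

  structure(list(chrom = chrom, insertion_pos = as.integer(insertion_pos),
                 arm_start = arm_start, arm_end = as.integer(insertion_pos),
                 arm_seq = arm_seq, cassette_id = params$cassette_id,
                 cassette_seq = cassette_seq, telomere_seed_seq = seed_seq,
                 fusion_tail_len = tl, primers = primers,
                 construct_seq = paste0(arm_seq, cassette_seq, seed_seq)),
            class = "pcd_construct")
}

#' Plan a staggered panel of truncation positions
#'
#' Positions are evenly spaced across the region, always including both
#' ends; when the region is shorter than the target spacing only the two
#' endpoints are returned.
#'
#' @param region list with chrom, lower (1-based inclusive), upper
#'   (exclusive).
#' @param target_spacing_bp desired mean spacing between truncations.
#' @return Strictly increasing integer vector of insertion positions.
#' @export
plan_tiling <- function(region, target_spacing_bp = 50000L) {
  len <- region$upper - region$lower
  if (len < 1) stopf("region must have length >= 1")
  if (len <= target_spacing_bp)
    return(as.integer(c(region$lower, region$upper)))
  n_gaps <- max(1L, as.integer(round(len / target_spacing_bp)))
  pos <- unique(as.integer(round(seq(region$lower, region$upper,
                                     length.out = n_gaps + 1L))))
  pos
}

#' Infer the causal interval from a truncation panel
#'
#' Truncation at p deletes `[p, telomere]`, so phenotype reversion implies
#' the causal element lies at or distal to p. The interval is
#' `[max reverting position, min retaining position beyond it)` — half-open
#' because the retaining truncation's own deletion did not remove the causal
#' element. A non-monotone pattern (a retaining truncation proximal to a
#' reverting one) is an error naming the conflicting strains.
#'
#' @param results data.frame with columns strain_id, insertion_pos, reverted
#'   (logical or 0/1; TRUE = tolerance lost upon truncation).
#' @param region list with chrom, lower, upper bounding the mapped region.
#' @return `causal_interval` list: chrom, lower (inclusive), upper
#'   (exclusive), length_bp, censored.
#' @export
infer_interval <- function(results, region) {
  if (nrow(results) == 0L) stopf("empty truncation results table")
  rev_flag <- as.logical(results$reverted)
  if (!any(rev_flag))
    stopf("no reverting truncation: the causal element lies proximal to every tested position; extend the panel toward the centromere")
  lower <- max(results$insertion_pos[rev_flag])
  bad <- !rev_flag & results$insertion_pos <= lower
  if (any(bad))
    stopf("non-monotone phenotype pattern: strain(s) %s retained the phenotype proximal to a reverting truncation",
          paste(results$strain_id[bad], collapse = ", "))
  retain_beyond <- results$insertion_pos[!rev_flag & results$insertion_pos > lower]
  censored <- length(retain_beyond) == 0L
  upper <- if (censored) as.integer(region$upper) else min(retain_beyond)
  structure(list(chrom = region$chrom, lower = as.integer(lower),
                 upper = as.integer(upper),
                 length_bp = as.integer(upper - lower), censored = censored),
            class = "causal_interval")
}

#' Features overlapping a causal interval
#'
#' Any-overlap rule: a feature straddling either boundary is included.
#'
#' @param annotation annotation data.frame.
#' @param interval a `causal_interval` (or list with chrom, lower, upper).
#' @return list with `features` (data.frame), `n_genes`, `n_dubious`.
#' @export
genes_in_interval <- function(annotation, interval) {
  sel <- annotation$chrom == interval$chrom &
    annotation$start <= interval$upper - 1L &
    annotation$end >= interval$lower
  feats <- annotation[sel, , drop = FALSE]
  rownames(feats) <- NULL
  list(features = feats,
       n_genes = sum(feats$feature_type == "gene"),
       n_dubious = sum(feats$feature_type == "dubious_ORF"))
}
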