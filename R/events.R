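## Planting mutations into a progenitor genome and generating gene annotations.
##
## Mutant strains are haploid segregants: the copy-number baseline is 1, a
## whole-chromosome disomy raises a chromosome to 2, and a segmental
## duplication raises a contiguous interval to 2.

#' Build a mutation plan
#'
#' @param snvs data.frame with columns chrom, pos, ref, alt and optionally
#'   effect_class (truth label).
#' @param indels data.frame with columns chrom, pos, seq, type
#'   (`"ins"`/`"del"`). `pos` is the anchor base: an insertion places `seq`
#'   immediately after `pos`; a deletion removes the bases at
#'   `pos + 1 .. pos + nchar(seq)` (which must equal `seq`).
#' @param disomies character vector of chromosomes present in two copies.
#' @param segmental_dups data.frame with columns chrom, start, end for
#'   duplicated intervals.
#' @return An object of class `mutation_plan`.
#' @export
mutation_plan <- function(snvs = NULL, indels = NULL, disomies = character(),
                          segmental_dups = NULL) {
  empty_snv <- data.frame(chrom = character(), pos = integer(), ref = character(),
                          alt = character(), effect_class = character())
  empty_ind <- data.frame(chrom = character(), pos = integer(), seq = character(),
                          type = character())
  empty_seg <- data.frame(chrom = character(), start = integer(), end = integer())
  snvs <- snvs %||% empty_snv
  if (is.null(snvs$effect_class)) snvs$effect_class <- NA_character_
  indels <- indels %||% empty_ind
  segmental_dups <- segmental_dups %||% empty_seg
  if (nrow(snvs) && anyDuplicated(snvs[c("chrom", "pos")]))
    stopf("mutation_plan: two SNVs at the same (chrom, pos)")
  if (nrow(indels) && !all(indels$type %in% c("ins", "del")))
    stopf("mutation_plan: indel type must be 'ins' or 'del'")
  if (nrow(indels) && any(nchar(indels$seq) > 50))
    stopf("mutation_plan: indels are restricted to <= 50 bp")
  if (nrow(segmental_dups) && any(segmental_dups$start > segmental_dups$end))
    stopf("mutation_plan: segmental duplication with start > end")
  structure(list(snvs = snvs, indels = indels,
                 disomies = as.character(disomies),
                 segmental_dups = segmental_dups),
            class = "mutation_plan")
}

## Convert a plan's point events to anchored variant records
## (chrom, pos, ref, alt, type) against the given genome.
plan_to_variants <- function(plan, genome) {
  lens <- genome_lengths(genome)
  v <- list()
  if (nrow(plan$snvs)) {
    s <- plan$snvs
    bad <- !s$chrom %in% names(genome) | s$pos < 1 | s$pos > lens[s$chrom]
    if (any(bad))
      stopf("SNV out of bounds at %s:%d", s$chrom[bad][1], s$pos[bad][1])
    have <- substr_vec(genome, s$chrom, s$pos, s$pos)
    mism <- have != s$ref
    if (any(mism))
      stopf("SNV ref mismatch at %s:%d (genome has %s, plan says %s)",
            s$chrom[mism][1], s$pos[mism][1], have[mism][1], s$ref[mism][1])
    v$snv <- data.frame(chrom = s$chrom, pos = s$pos, ref = s$ref, alt = s$alt,
                        type = "snv")
  }
  if (nrow(plan$indels)) {
    d <- plan$indels
    anchor <- substr_vec(genome, d$chrom, d$pos, d$pos)
    is_del <- d$type == "del"
    if (any(is_del)) {
      del_have <- substr_vec(genome, d$chrom[is_del], d$pos[is_del] + 1L,
                             d$pos[is_del] + nchar(d$seq[is_del]))
      mism <- del_have != d$seq[is_del]
      if (any(mism))
        stopf("deletion sequence mismatch at %s:%d",
              d$chrom[is_del][mism][1], d$pos[is_del][mism][1])
    }
    ref <- ifelse(is_del, paste0(anchor, d$seq), anchor)
    alt <- ifelse(is_del, anchor, paste0(anchor, d$seq))
    v$indel <- data.frame(chrom = d$chrom, pos = d$pos, ref = ref, alt = alt,
                          type = ifelse(is_del, "deletion", "insertion"))
  }
  out <- do.call(rbind, v)
  if (is.null(out))
    out <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), type = character())
  rownames(out) <- NULL
  out
}

substr_vec <- function(genome, chrom, start, end) {
  mapply(function(ch, s, e) substr(genome[[ch]], s, e), chrom, start, end,
         USE.NAMES = FALSE)
}

#' Plant planned events into a progenitor genome
#'
#' Applies the plan's SNVs and small indels to the progenitor haplotype and
#' records disomies/segmental duplications in a copy-number map. Every planned
#' event is mirrored by exactly one truth record so recovery can be scored.
#'
#' @param progenitor a genome (named character vector).
#' @param plan a [mutation_plan()].
#' @return An object of class `mutant_model`: list with `genome` (the mutant
#'   haplotype), `copy_number` (data.frame chrom/start/end/copy_number tiling
#'   each chromosome), `truth` (data.frame of planted events) and
#'   `coordinate_map` (progenitor -> mutant positions).
#' @export
plant_events <- function(progenitor, plan) {
  if (!inherits(plan, "mutation_plan")) stopf("plan must be a mutation_plan")
  lens <- genome_lengths(progenitor)
  bad <- setdiff(plan$disomies, names(progenitor))
  if (length(bad)) stopf("disomy of unknown chromosome '%s'", bad[1])
  if (nrow(plan$segmental_dups)) {
    sd <- plan$segmental_dups
    if (any(!sd$chrom %in% names(progenitor)) ||
        any(sd$start < 1) || any(sd$end > lens[sd$chrom]))
      stopf("segmental duplication outside chromosome bounds")
    if (any(sd$chrom %in% plan$disomies))
      stopf("segmental duplication overlaps a whole-chromosome disomy on %s",
            intersect(sd$chrom, plan$disomies)[1])
  }

  variants <- plan_to_variants(plan, progenitor)
  if (nrow(variants)) {
    res <- integrate_variants(progenitor, variants)
    genome <- res$genome
    cmap <- res$coordinate_map
  } else {
    genome <- progenitor
    cmap <- empty_coordinate_map(names(progenitor))
  }

  cn <- copy_number_map(progenitor, plan$disomies, plan$segmental_dups)

  truth <- list()
  if (nrow(plan$snvs))
    truth$snv <- data.frame(event_type = "snv", chrom = plan$snvs$chrom,
                            start = plan$snvs$pos, end = plan$snvs$pos,
                            alt = plan$snvs$alt, copy_number = 1L,
                            effect_class = plan$snvs$effect_class,
                            fraction = NA_real_)
  if (nrow(plan$indels))
    truth$indel <- data.frame(event_type = "indel", chrom = plan$indels$chrom,
                              start = plan$indels$pos, end = plan$indels$pos,
                              alt = paste0(plan$indels$type, ":", plan$indels$seq),
                              copy_number = 1L, effect_class = "not_applicable",
                              fraction = NA_real_)
  if (length(plan$disomies))
    truth$disomy <- data.frame(event_type = "disomy", chrom = plan$disomies,
                               start = 1L, end = unname(lens[plan$disomies]),
                               alt = NA_character_, copy_number = 2L,
                               effect_class = NA_character_, fraction = 1)
  if (nrow(plan$segmental_dups)) {
    sd <- plan$segmental_dups
    truth$seg <- data.frame(event_type = "segmental_dup", chrom = sd$chrom,
                            start = sd$start, end = sd$end, alt = NA_character_,
                            copy_number = 2L, effect_class = NA_character_,
                            fraction = (sd$end - sd$start + 1) / lens[sd$chrom])
  }
  truth <- do.call(rbind, truth)
  if (is.null(truth))
    truth <- data.frame(event_type = character(), chrom = character(),
                        start = integer(), end = integer(), alt = character(),
                        copy_number = integer(), effect_class = character(),
                        fraction = numeric())
  rownames(truth) <- NULL

  structure(list(genome = genome, copy_number = cn, truth = truth,
                 coordinate_map = cmap, plan = plan),
            class = "mutant_model")
}

## Tile every chromosome with copy-number intervals (baseline 1).
copy_number_map <- function(genome, disomies, segmental_dups) {
  lens <- genome_lengths(genome)
  rows <- lapply(names(genome), function(ch) {
    n <- unname(lens[ch])
    if (ch %in% disomies)
      return(data.frame(chrom = ch, start = 1L, end = n, copy_number = 2L))
    sd <- segmental_dups[segmental_dups$chrom == ch, , drop = FALSE]
    if (nrow(sd) == 0L)
      return(data.frame(chrom = ch, start = 1L, end = n, copy_number = 1L))
    sd <- sd[order(sd$start), , drop = FALSE]
    if (nrow(sd) > 1L && any(sd$start[-1] <= sd$end[-nrow(sd)]))
      stopf("overlapping segmental duplications on %s", ch)
    bounds <- sort(unique(c(1L, sd$start, sd$end + 1L, n + 1L)))
    bounds <- bounds[bounds <= n + 1L]
    seg <- data.frame(chrom = ch, start = bounds[-length(bounds)],
                      end = bounds[-1] - 1L)
    seg$copy_number <- ifelse(seg$start %in% sd$start |
                                vapply(seg$start, function(p)
                                  any(p >= sd$start & p <= sd$end), logical(1)),
                              2L, 1L)
    seg
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## Per-site copy-number vector for one chromosome (reference coordinates).
copy_number_vector <- function(cn_map, chrom, n) {
  v <- rep(1L, n)
  seg <- cn_map[cn_map$chrom == chrom, , drop = FALSE]
  for (k in seq_len(nrow(seg)))
    if (seg$copy_number[k] != 1L)
      v[seg$start[k]:min(seg$end[k], n)] <- seg$copy_number[k]
  v
}

#' Generate a random non-overlapping gene annotation
#'
#' Features are placed left-to-right with random gaps; ORF lengths are
#' multiples of 3 so coding effects can be classified by codon translation.
#' Dubious ORFs are annotated the same way but labelled `dubious_ORF`.
#'
#' @param genome a genome.
#' @param n_genes number of `gene` features to place.
#' @param seed integer seed.
#' @param n_dubious number of `dubious_ORF` features.
#' @param length_range ORF length range in bp (rounded to codon multiples).
#' @param min_gap minimum intergenic gap in bp.
#' @return data.frame with columns feature_id, chrom, start, end, strand,
#'   feature_type.
#' @export
generate_annotation <- function(genome, n_genes, seed = 1L, n_dubious = 0L,
                                length_range = c(300L, 900L), min_gap = 200L) {
  lens <- genome_lengths(genome)
  n_total <- n_genes + n_dubious
  with_seed(seed, {
    types <- sample(c(rep("gene", n_genes), rep("dubious_ORF", n_dubious)))
    share <- round(n_total * lens / sum(lens))
    ## fix rounding drift
    while (sum(share) > n_total) share[which.max(share)] <- share[which.max(share)] - 1L
    while (sum(share) < n_total) share[which.min(share)] <- share[which.min(share)] + 1L
    rows <- list(); idx <- 1L
    for (ch in names(genome)) {
      k <- share[[ch]]
      if (k == 0L) next
      pos <- 1L + sample.int(min_gap, 1L)
      for (g in seq_len(k)) {
        len <- sample(seq(length_range[1], length_range[2]), 1L)
        len <- as.integer(3L * ceiling(len / 3L))
        if (pos + len - 1L > lens[[ch]])
          stopf("chromosome %s too small to place %d features", ch, k)
        rows[[length(rows) + 1L]] <- data.frame(
          feature_id = sprintf("%s%04d", ifelse(types[idx] == "gene", "GENE", "DUB"), idx),
          chrom = ch, start = pos, end = pos + len - 1L,
          strand = sample(c("+", "-"), 1L), feature_type = types[idx])
        pos <- pos + len + min_gap + sample.int(min_gap, 1L)
        idx <- idx + 1L
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
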