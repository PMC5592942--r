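## Allele-fraction thresholded calling and iterative reference refinement.
##
## The decision rule: a site is called when its depth reaches `min_depth`
## and a single non-reference allele (base, insertion or deletion) accounts
## for at least `min_fraction` of the reads — inclusive at the boundary.

#' Caller parameters
#'
#' @param min_fraction minimum supporting read fraction for a call
#'   (default 0.90, inclusive).
#' @param min_depth minimum site depth for a call; guards against one-read
#'   "100%" calls at shallow sites.
#' @param max_indel_bp largest indel length considered small (bp).
#' @export
caller_params <- function(min_fraction = 0.90, min_depth = 10L,
                          max_indel_bp = 50L) {
  if (min_fraction <= 0 || min_fraction > 1)
    stopf("min_fraction must be in (0, 1], got %s", min_fraction)
  if (min_depth < 1) stopf("min_depth must be >= 1")
  structure(list(min_fraction = min_fraction, min_depth = as.integer(min_depth),
                 max_indel_bp = as.integer(max_indel_bp)),
            class = "caller_params")
}

#' Call differences between a pileup and its reference
#'
#' Evaluates every non-reference allele at every site independently; at most
#' one allele can reach the threshold. A tie of two alternate alleles each
#' below the threshold yields no call.
#'
#' @param pileup pileup data.frame (package dialect).
#' @param reference genome the pileup was computed against.
#' @param params a [caller_params()].
#' @return VariantSet data.frame: chrom, pos, ref, alt, type, fraction, depth.
#' @export
call_differences <- function(pileup, reference, params = caller_params()) {
  n <- nrow(pileup)
  empty <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), type = character(),
                      fraction = numeric(), depth = integer())
  if (n == 0L) return(empty)

  ## verify the pileup's reference column against the genome
  for (ch in unique(pileup$chrom)) {
    rows <- which(pileup$chrom == ch)
    chars <- chrom_chars(reference, ch)
    bad <- which(chars[pileup$pos[rows]] != pileup$ref[rows])
    if (length(bad))
      stopf("pileup reference base disagrees with genome at %s:%d", ch,
            pileup$pos[rows[bad[1]]])
  }

  m <- as.matrix(pileup[, DNA_BASES])
  ridx <- match(pileup$ref, DNA_BASES)
  alt_m <- m
  alt_m[cbind(seq_len(n), ridx)] <- -1L
  best <- max.col(alt_m, ties.method = "first")
  best_count <- alt_m[cbind(seq_len(n), best)]

  depth <- pileup$depth
  eligible <- depth >= params$min_depth
  eps <- 1e-12
  calls <- list()

  snv_hit <- eligible & best_count / pmax(depth, 1L) >= params$min_fraction - eps
  if (any(snv_hit)) {
    idx <- which(snv_hit)
    calls$snv <- data.frame(chrom = pileup$chrom[idx], pos = pileup$pos[idx],
                            ref = pileup$ref[idx], alt = DNA_BASES[best[idx]],
                            type = "snv",
                            fraction = best_count[idx] / depth[idx],
                            depth = depth[idx])
  }

  has_ins <- which(pileup$ins != "." & nzchar(pileup$ins))
  if (length(has_ins)) {
    sp <- strsplit(pileup$ins[has_ins], ":", fixed = TRUE)
    seqs <- vapply(sp, `[`, character(1), 1L)
    cnt <- as.integer(vapply(sp, `[`, character(1), 2L))
    keep <- eligible[has_ins] & cnt / pmax(depth[has_ins], 1L) >= params$min_fraction - eps &
      nchar(seqs) <= params$max_indel_bp
    if (any(keep)) {
      idx <- has_ins[keep]
      calls$ins <- data.frame(chrom = pileup$chrom[idx], pos = pileup$pos[idx],
                              ref = pileup$ref[idx],
                              alt = paste0(pileup$ref[idx], seqs[keep]),
                              type = "insertion",
                              fraction = cnt[keep] / depth[idx],
                              depth = depth[idx])
    }
  }

  has_del <- which(pileup$del != "." & nzchar(pileup$del))
  if (length(has_del)) {
    sp <- strsplit(pileup$del[has_del], ":", fixed = TRUE)
    len <- as.integer(vapply(sp, `[`, character(1), 1L))
    cnt <- as.integer(vapply(sp, `[`, character(1), 2L))
    keep <- eligible[has_del] & cnt / pmax(depth[has_del], 1L) >= params$min_fraction - eps &
      len <= params$max_indel_bp
    if (any(keep)) {
      idx <- has_del[keep]
      deleted <- substr_vec(reference, pileup$chrom[idx], pileup$pos[idx] + 1L,
                            pileup$pos[idx] + len[keep])
      calls$del <- data.frame(chrom = pileup$chrom[idx], pos = pileup$pos[idx],
                              ref = paste0(pileup$ref[idx], deleted),
                              alt = pileup$ref[idx], type = "deletion",
                              fraction = cnt[keep] / depth[idx],
                              depth = depth[idx])
    }
  }

  out <- do.call(rbind, calls)
  if (is.null(out)) return(empty)
  out <- out[order(match(out$chrom, names(reference)), out$pos), ]
  rownames(out) <- NULL
  out
}

#' Integrate called variants into a reference genome
#'
#' SNVs are substituted in place; indels are applied right-to-left so earlier
#' coordinates remain valid, and a coordinate map records how positions shift.
#'
#' @param reference genome.
#' @param variants VariantSet data.frame (chrom, pos, ref, alt, type).
#' @return list with `genome` (updated) and `coordinate_map` (old -> new).
#' @export
integrate_variants <- function(reference, variants) {
  events <- stats::setNames(vector("list", length(reference)), names(reference))
  genome <- reference
  if (nrow(variants)) {
    span_end <- variants$pos + nchar(variants$ref) - 1L
    for (ch in unique(variants$chrom)) {
      v <- variants[variants$chrom == ch, , drop = FALSE]
      v <- v[order(v$pos), , drop = FALSE]
      se <- v$pos + nchar(v$ref) - 1L
      if (nrow(v) > 1L && any(v$pos[-1] <= se[-nrow(v)]))
        stopf("overlapping variants on %s near position %d", ch,
              v$pos[which(v$pos[-1] <= se[-nrow(v)])[1] + 1L])
      chars <- chrom_chars(genome, ch)
      have <- vapply(seq_len(nrow(v)), function(k)
        paste(chars[v$pos[k]:se[k]], collapse = ""), character(1))
      if (any(have != v$ref))
        stopf("variant ref mismatch at %s:%d", ch, v$pos[which(have != v$ref)[1]])

      sn <- v[v$type == "snv", , drop = FALSE]
      chars[sn$pos] <- sn$alt
      ind <- v[v$type != "snv", , drop = FALSE]
      ev <- NULL
      if (nrow(ind)) {
        ev <- data.frame(pos = ind$pos,
                         type = ind$type,
                         len = abs(nchar(ind$alt) - nchar(ind$ref)))
        for (k in rev(seq_len(nrow(ind)))) {      # right-to-left
          p <- ind$pos[k]
          if (ind$type[k] == "deletion") {
            dlen <- nchar(ind$ref[k]) - 1L
            chars <- chars[-((p + 1L):(p + dlen))]
          } else {
            insert <- strsplit(substr(ind$alt[k], 2L, nchar(ind$alt[k])), "",
                               fixed = TRUE)[[1]]
            chars <- append(chars, insert, after = p)
          }
        }
      }
      genome[[ch]] <- paste(chars, collapse = "")
      events[[ch]] <- ev
    }
  }
  list(genome = genome,
       coordinate_map = structure(list(events = events), class = "coordinate_map"))
}

empty_coordinate_map <- function(chrom_names) {
  structure(list(events = stats::setNames(vector("list", length(chrom_names)),
                                          chrom_names)),
            class = "coordinate_map")
}

#' Map old reference positions to their post-integration coordinates
#'
#' Positions removed by a deletion map to `NA`.
#'
#' @param cmap a `coordinate_map` (from [integrate_variants()]) or a
#'   `coordinate_map_chain` (from [refine_reference()]).
#' @param chrom chromosome name.
#' @param pos integer vector of 1-based positions in the old coordinates.
#' @return integer vector of new positions (NA where deleted).
#' @export
map_position <- function(cmap, chrom, pos) {
  if (inherits(cmap, "coordinate_map_chain")) {
    for (m in cmap$maps) pos <- map_position(m, chrom, pos)
    return(pos)
  }
  if (!inherits(cmap, "coordinate_map")) stopf("not a coordinate map")
  ev <- cmap$events[[chrom]]
  new <- as.integer(pos)
  if (is.null(ev) || nrow(ev) == 0L) return(new)
  old <- as.integer(pos)
  for (k in seq_len(nrow(ev))) {
    if (ev$type[k] == "deletion") {
      dead <- !is.na(new) & old > ev$pos[k] & old <= ev$pos[k] + ev$len[k]
      new[dead] <- NA_integer_
      shift <- !is.na(new) & old > ev$pos[k] + ev$len[k]
      new[shift] <- new[shift] - ev$len[k]
    } else {
      shift <- !is.na(new) & old > ev$pos[k]
      new[shift] <- new[shift] + ev$len[k]
    }
  }
  new
}

#' Iteratively refine a reference toward a progenitor
#'
#' Alternates difference calling and variant integration: differences between
#' the progenitor's pileup and the current reference are integrated, the
#' progenitor's reads are conceptually remapped to the updated genome (via
#' `pileup_provider`), and the loop repeats until a cycle finds no variants
#' or `max_cycles` is reached.
#'
#' @param base starting genome.
#' @param pileup_provider function(genome) returning the progenitor's pileup
#'   against that genome; must be deterministic for a fixed genome.
#' @param max_cycles cycle cap (default 10).
#' @param params a [caller_params()].
#' @return `refined_reference`: list with `genome`, `cycles_run`, `converged`,
#'   `variants_per_cycle` and `coordinate_map` (base -> refined positions).
#' @export
refine_reference <- function(base, pileup_provider, max_cycles = 10L,
                             params = caller_params()) {
  genome <- base
  maps <- list()
  vpc <- integer()
  converged <- FALSE
  for (cycle in seq_len(max_cycles)) {
    pu <- pileup_provider(genome)
    vs <- call_differences(pu, genome, params)
    vpc <- c(vpc, nrow(vs))
    if (nrow(vs) == 0L) { converged <- TRUE; break }
    res <- integrate_variants(genome, vs)
    genome <- res$genome
    maps <- c(maps, list(res$coordinate_map))
  }
  structure(list(genome = genome, cycles_run = length(vpc),
                 converged = converged, variants_per_cycle = vpc,
                 coordinate_map = structure(list(maps = maps),
                                            class = "coordinate_map_chain")),
            class = "refined_reference")
}

#' Call a mutant's mutations against its refined progenitor reference
#'
#' Same decision rule as [call_differences()]; adds the mutant label and an
#' effect-class column left unset pending [classify_effect()].
#'
#' @param mutant_pileup pileup of the mutant against the progenitor reference.
#' @param progenitor_reference refined progenitor genome (or a
#'   `refined_reference`, whose genome is used).
#' @param params a [caller_params()].
#' @param mutant_id label attached to each call.
#' @return data.frame of mutation calls.
#' @export
call_mutations <- function(mutant_pileup, progenitor_reference,
                           params = caller_params(), mutant_id = "mutant") {
  if (inherits(progenitor_reference, "refined_reference"))
    progenitor_reference <- progenitor_reference$genome
  calls <- call_differences(mutant_pileup, progenitor_reference, params)
  calls$effect_class <- ifelse(calls$type == "snv", NA_character_,
                               "not_applicable")
  calls$mutant_id <- rep(mutant_id, nrow(calls))
  calls
}

#' Classify the coding effect of SNV calls
#'
#' A SNV outside every annotated feature is intergenic; inside a feature the
#' affected codon is translated on the feature's strand with the standard
#' genetic code and compared between the reference and alternate alleles.
#' Indel calls are labelled `not_applicable`.
#'
#' @param calls VariantSet/mutation-call data.frame.
#' @param annotation annotation data.frame ([generate_annotation()] layout).
#' @param genome the genome the calls' coordinates refer to.
#' @return character vector of effect classes, one per call.
#' @export
classify_effect <- function(calls, annotation, genome) {
  vapply(seq_len(nrow(calls)), function(k) {
    if (calls$type[k] != "snv") return("not_applicable")
    classify_one_snv(calls$chrom[k], calls$pos[k], calls$ref[k], calls$alt[k],
                     annotation, genome)
  }, character(1))
}

classify_one_snv <- function(chrom, pos, ref, alt, annotation, genome) {
  feat <- annotation[annotation$chrom == chrom & annotation$start <= pos &
                       annotation$end >= pos, , drop = FALSE]
  if (nrow(feat) == 0L) return("intergenic")
  feat <- feat[1L, ]
  len <- feat$end - feat$start + 1L
  if (len %% 3L != 0L)
    stopf("feature %s has length %d, not a codon multiple", feat$feature_id, len)
  if (feat$strand == "+") {
    off <- pos - feat$start
    cstart <- feat$start + 3L * (off %/% 3L)
    codon <- substr(genome[[chrom]], cstart, cstart + 2L)
    within <- off %% 3L + 1L
    alt_codon <- codon
    substr(alt_codon, within, within) <- alt
  } else {
    off <- feat$end - pos
    gstart <- feat$end - 3L * (off %/% 3L) - 2L
    codon <- revcomp(substr(genome[[chrom]], gstart, gstart + 2L))
    within <- off %% 3L + 1L
    alt_codon <- codon
    substr(alt_codon, within, within) <- revcomp(alt)
  }
  if (substr(codon, within, within) != (if (feat$strand == "+") ref else revcomp(ref)))
    stopf("reference base mismatch inside %s at %s:%d", feat$feature_id, chrom, pos)
  if (translate_codon(codon) == translate_codon(alt_codon)) "synonymous"
  else "nonsynonymous"
}

#' Deduplicate mutation calls across a mutant cohort
#'
#' The deduplication key is (chrom, pos, ref, alt); identical calls shared by
#' several mutants count once. Per-effect-class counts are tallied over the
#' unique set.
#'
#' @param cohort data.frame of mutation calls across mutants.
#' @return list with `unique` (one row per unique mutation, with an
#'   `n_mutants` column), `n_unique` and `counts` (named by effect class).
#' @export
unique_mutations <- function(cohort) {
  if (nrow(cohort) == 0L)
    return(list(unique = cohort, n_unique = 0L, counts = integer()))
  key <- paste(cohort$chrom, cohort$pos, cohort$ref, cohort$alt, sep = "\r")
  first <- !duplicated(key)
  uni <- cohort[first, , drop = FALSE]
  uni$n_mutants <- as.integer(table(key)[key[first]])
  uni <- uni[order(match(uni$chrom, unique(cohort$chrom)), uni$pos), ]
  rownames(uni) <- NULL
  counts <- table(uni$effect_class, useNA = "ifany")
  list(unique = uni, n_unique = nrow(uni),
       counts = stats::setNames(as.integer(counts), names(counts)))
}
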