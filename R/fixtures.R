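## Packaged synthetic fixtures with known truth, and fixture file I/O.
##
## The cohort fixture plants the screen's point-mutation composition
## (39 unique: 22 nonsynonymous, 8 synonymous, 9 intergenic) across a small
## mutant cohort; the screen fixture plants the per-cross confirmation
## structure (14 + 9 + 14 retained). Sizes are miniature so that full runs
## finish in seconds; compositions are fixed, not tunable knobs.

codon_at <- function(genome, feat, ci) {
  if (feat$strand == "+") {
    gpos <- feat$start + 3L * (ci - 1L) + 0:2
    codon <- substr(genome[[feat$chrom]], gpos[1], gpos[3])
  } else {
    gpos <- feat$end - 3L * (ci - 1L) - 0:2
    codon <- revcomp(substr(genome[[feat$chrom]], gpos[3], gpos[1]))
  }
  list(codon = codon, gpos = gpos)
}

## Pick an SNV inside a gene whose codon change is (non)synonymous.
pick_coding_snv <- function(genome, feat, want, max_tries = 50L) {
  n_codons <- (feat$end - feat$start + 1L) %/% 3L
  for (try in seq_len(max_tries)) {
    ci <- sample(2:(n_codons - 1L), 1L)
    info <- codon_at(genome, feat, ci)
    aa0 <- translate_codon(info$codon)
    j <- if (want == "synonymous") 3L else sample(1:2, 1L)
    for (y in sample(setdiff(DNA_BASES, substr(info$codon, j, j)))) {
      alt_codon <- info$codon
      substr(alt_codon, j, j) <- y
      aa1 <- translate_codon(alt_codon)
      ok <- if (want == "synonymous") aa1 == aa0 else aa1 != aa0
      if (ok) {
        pos <- info$gpos[j]
        x <- substr(info$codon, j, j)
        ref <- if (feat$strand == "+") x else revcomp(x)
        alt <- if (feat$strand == "+") y else revcomp(y)
        return(data.frame(chrom = feat$chrom, pos = pos, ref = ref, alt = alt,
                          effect_class = want))
      }
    }
  }
  NULL
}

#' Packaged synthetic mutant-cohort fixture
#'
#' A four-chromosome miniature genome (the largest chromosome a 1/10-scale
#' chromosome IV); a progenitor differing from the base reference by SNVs
#' and small indels; and a cohort of mutants carrying 39 unique planted
#' point mutations (22 nonsynonymous, 8 synonymous, 9 intergenic), three of
#' them shared between two mutants to exercise deduplication, plus two
#' whole-chromosome disomies and one terminal segmental duplication of the
#' focal chromosome.
#'
#' @param seed integer seed; the packaged fixture uses 42.
#' @param n_mutants cohort size.
#' @return list: base genome, `progenitor` (mutant_model vs base),
#'   annotation, `mutants` (named list of mutant_models vs the progenitor),
#'   `snv_truth`, `expected` counts, and the focal chromosome/arm.
#' @export
cohort_fixture <- function(seed = 42L, n_mutants = 10L) {
  spec <- genome_spec(c("chrI", "chrII", "chrIII", "chrIV"),
                      c(40000L, 60000L, 30000L, 153193L),
                      gc_fraction = 0.38, seed = seed)
  base <- simulate_genome(spec)

  ## progenitor: 8 SNVs + 2 small indels relative to the base reference
  prog_plan <- with_seed(seed + 1L, {
    lens <- genome_lengths(base)
    pos_pool <- list()
    pick_pos <- function(chrom, n, min_dist = 500L) {
      taken <- pos_pool[[chrom]] %||% integer()
      out <- integer()
      while (length(out) < n) {
        p <- sample(1000:(lens[[chrom]] - 1000L), 1L)
        if (all(abs(p - c(taken, out)) >= min_dist)) out <- c(out, p)
      }
      pos_pool[[chrom]] <<- c(taken, out)
      out
    }
    snv_pos <- c(pick_pos("chrI", 2L), pick_pos("chrII", 2L),
                 pick_pos("chrIII", 2L), pick_pos("chrIV", 2L))
    snv_chrom <- rep(c("chrI", "chrII", "chrIII", "chrIV"), each = 2L)
    ref <- substr_vec(base, snv_chrom, snv_pos, snv_pos)
    alt <- vapply(ref, function(r) sample(setdiff(DNA_BASES, r), 1L), character(1))
    ins_pos <- pick_pos("chrI", 1L)
    del_pos <- pick_pos("chrII", 1L)
    del_seq <- substr(base[["chrII"]], del_pos + 1L, del_pos + 2L)
    mutation_plan(
      snvs = data.frame(chrom = snv_chrom, pos = snv_pos, ref = ref, alt = alt),
      indels = data.frame(chrom = c("chrI", "chrII"), pos = c(ins_pos, del_pos),
                          seq = c("ACT", del_seq), type = c("ins", "del")))
  })
  progenitor <- plant_events(base, prog_plan)
  prog <- progenitor$genome

  annotation <- generate_annotation(prog, n_genes = 70L, seed = seed + 2L,
                                    n_dubious = 6L)

  composition <- c(nonsynonymous = 22L, synonymous = 8L, intergenic = 9L)
  snvs <- with_seed(seed + 3L, {
    genes <- annotation[annotation$feature_type == "gene", , drop = FALSE]
    gene_order <- sample(nrow(genes))
    picked <- list(); gi <- 1L
    for (class in c("nonsynonymous", "synonymous")) {
      need <- composition[[class]]
      got <- 0L
      while (got < need) {
        if (gi > nrow(genes)) stopf("ran out of genes while planting %s SNVs", class)
        feat <- genes[gene_order[gi], ]
        gi <- gi + 1L
        hit <- pick_coding_snv(prog, feat, class)
        if (!is.null(hit)) { picked[[length(picked) + 1L]] <- hit; got <- got + 1L }
      }
    }
    lens <- genome_lengths(prog)
    chosen <- do.call(rbind, picked)
    need <- composition[["intergenic"]]
    got <- 0L
    while (got < need) {
      ch <- sample(names(prog), 1L)
      p <- sample(200:(lens[[ch]] - 200L), 1L)
      in_feat <- any(annotation$chrom == ch & annotation$start - 5L <= p &
                       annotation$end + 5L >= p)
      near <- any(chosen$chrom == ch & abs(chosen$pos - p) < 150L)
      if (!in_feat && !near) {
        ref <- substr(prog[[ch]], p, p)
        picked[[length(picked) + 1L]] <-
          data.frame(chrom = ch, pos = p, ref = ref,
                     alt = sample(setdiff(DNA_BASES, ref), 1L),
                     effect_class = "intergenic")
        chosen <- do.call(rbind, picked)
        got <- got + 1L
      }
    }
    out <- do.call(rbind, picked)
    out$snv_id <- sprintf("snv%02d", seq_len(nrow(out)))
    ## scatter across the cohort; the first three are shared by two mutants
    out$owner <- sample(n_mutants, nrow(out), replace = TRUE)
    out$owner2 <- NA_integer_
    out$owner2[1:3] <- vapply(out$owner[1:3], function(o)
      sample(setdiff(seq_len(n_mutants), o), 1L), integer(1))
    out
  })

  mutant_ids <- sprintf("m%02d", seq_len(n_mutants))
  disomic <- mutant_ids[1:2]
  segmental <- mutant_ids[3]
  mutants <- lapply(seq_len(n_mutants), function(i) {
    mine <- snvs[snvs$owner == i | (!is.na(snvs$owner2) & snvs$owner2 == i), ,
                 drop = FALSE]
    plan <- mutation_plan(
      snvs = if (nrow(mine)) mine[, c("chrom", "pos", "ref", "alt", "effect_class")]
             else NULL,
      disomies = if (mutant_ids[i] %in% disomic) "chrIV" else character(),
      segmental_dups = if (mutant_ids[i] == segmental)
        data.frame(chrom = "chrIV", start = 44001L, end = 153193L) else NULL)
    plant_events(prog, plan)
  })
  names(mutants) <- mutant_ids

  list(base = base, progenitor = progenitor, annotation = annotation,
       mutants = mutants, snv_truth = snvs,
       expected = list(n_unique = sum(composition), counts = composition),
       focal_chrom = "chrIV",
       focal_arm = list(chrom = "chrIV", start = 44972L, end = 153193L))
}

#' Packaged synthetic hydrogen-peroxide screen fixture
#'
#' Dose-response tables for candidate isolates from three crosses, planted
#' so that 14, 9 and 14 candidates per cross pass the 0.5 mM
#' confirmation-stage MIC-gain filter (37 in total), alongside candidates
#' that fail it. Doses follow a 0.5 mM grid.
#'
#' @param seed integer seed; the packaged fixture uses 42.
#' @return list: `doses` (strain, cross, dose_mM, grew), `progenitors`
#'   (cross, strain, mic_mM), `truth` per strain, and expected pass counts.
#' @export
screen_fixture <- function(seed = 42L) {
  crosses <- data.frame(cross = c("BYxRM", "RMxYPS", "BYxYPS"),
                        prog_mic = c(7.0, 8.5, 8.5),
                        n_pass = c(14L, 9L, 14L),
                        n_fail = c(10L, 15L, 10L))
  with_seed(seed, {
    doses <- list(); truth <- list()
    for (k in seq_len(nrow(crosses))) {
      cr <- crosses$cross[k]; pm <- crosses$prog_mic[k]
      gains_pass <- sample(c(0.5, 1, 1.5, 2, 2.5), crosses$n_pass[k], replace = TRUE)
      gains_fail <- sample(c(-1, -0.5, 0), crosses$n_fail[k], replace = TRUE)
      mics <- pm + c(gains_pass, gains_fail)
      n <- length(mics)
      strain <- sprintf("%s_c%02d", cr, seq_len(n))
      grid <- seq(0.5, pm + 3, by = 0.5)
      doses[[cr]] <- data.frame(
        strain = rep(strain, each = length(grid)), cross = cr,
        dose_mM = rep(grid, n),
        grew = as.integer(rep(grid, n) < rep(mics, each = length(grid))))
      truth[[cr]] <- data.frame(strain = strain, cross = cr, planted_mic = mics,
                                passes_confirmation = c(rep(TRUE, crosses$n_pass[k]),
                                                        rep(FALSE, crosses$n_fail[k])))
    }
    list(doses = do.call(rbind, c(doses, list(make.row.names = FALSE))),
         progenitors = data.frame(cross = crosses$cross,
                                  strain = paste0("prog_", crosses$cross),
                                  mic_mM = crosses$prog_mic),
         truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
         expected_total = sum(crosses$n_pass),
         expected_by_cross = stats::setNames(crosses$n_pass, crosses$cross))
  })
}

#' Synthetic qPCR Cq fixture for a duplicated locus
#'
#' Replicate Cq values for a target gene and the reference gene in a
#' calibrator (1-copy) and a test (duplicated) sample, with Gaussian Cq
#' noise. At efficiency 2 a 2-copy locus lowers the target Cq by one cycle.
#'
#' @param seed integer seed.
#' @param true_ratio planted copy-number ratio of the test sample.
#' @param cq_sd Gaussian Cq noise standard deviation (cycles).
#' @param n_reps replicates per gene per sample.
#' @param efficiency amplification efficiency.
#' @return list: `cq` (sample, target, cq), `true_ratio`.
#' @export
qpcr_fixture <- function(seed = 1L, true_ratio = 2, cq_sd = 0.1, n_reps = 4L,
                         efficiency = 2) {
  with_seed(seed, {
    base <- c(ACT1 = 15, TSA2 = 20)
    rows <- list()
    for (s in c("calibrator", "disomic")) {
      shift <- if (s == "disomic") -log(true_ratio, base = efficiency) else 0
      rows[[length(rows) + 1L]] <- data.frame(
        sample = s, target = "ACT1",
        cq = base[["ACT1"]] + stats::rnorm(n_reps, sd = cq_sd))
      rows[[length(rows) + 1L]] <- data.frame(
        sample = s, target = "TSA2",
        cq = base[["TSA2"]] + shift + stats::rnorm(n_reps, sd = cq_sd))
    }
    list(cq = do.call(rbind, rows), true_ratio = true_ratio)
  })
}

#' Read / write annotations as BED
#'
#' BED is 0-based half-open; the in-memory annotation is 1-based inclusive.
#' Columns: chrom, start, end, name, score, strand, feature_type.
#'
#' @param annotation annotation data.frame.
#' @param path file path.
#' @export
write_annotation_bed <- function(annotation, path) {
  bed <- data.frame(annotation$chrom, annotation$start - 1L, annotation$end,
                    annotation$feature_id, 0L, annotation$strand,
                    annotation$feature_type)
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_annotation_bed
#' @export
read_annotation_bed <- function(path) {
  bed <- data.table::fread(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "start0", "end", "feature_id",
                                         "score", "strand", "feature_type"))
  data.table::setDF(bed)
  data.frame(feature_id = bed$feature_id, chrom = bed$chrom,
             start = bed$start0 + 1L, end = bed$end, strand = bed$strand,
             feature_type = bed$feature_type)
}

#' Read / write a truth table as JSON
#'
#' @param truth truth data.frame (from a `mutant_model`).
#' @param path file path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "rows", na = "null",
                       digits = NA)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  jsonlite::fromJSON(path)
}

#' Write the full fixture file set for a mutant model
#'
#' Emits a genome FASTA, a dense pileup TSV, an annotation BED, a truth
#' JSON, a screen MIC TSV and a qPCR Cq TSV into `out_dir`; reading each
#' file back reproduces the in-memory object.
#'
#' @param model a `mutant_model`.
#' @param annotation annotation data.frame.
#' @param out_dir destination directory (created if needed).
#' @param reference genome the pileup is simulated against (defaults to the
#'   model's own genome).
#' @param mean_depth,seed pileup simulation settings.
#' @return Named character vector of written paths, invisibly.
#' @export
write_fixtures <- function(model, annotation, out_dir, reference = NULL,
                           mean_depth = 100, seed = 1L) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stopf("cannot create output directory %s", out_dir)
  reference <- reference %||% model$genome
  paths <- c(genome = file.path(out_dir, "genome.fa"),
             pileup = file.path(out_dir, "pileup.tsv"),
             annotation = file.path(out_dir, "annotation.bed"),
             truth = file.path(out_dir, "truth.json"),
             screen = file.path(out_dir, "screen_mic.tsv"),
             qpcr = file.path(out_dir, "qpcr_cq.tsv"))
  write_genome_fasta(model$genome, paths[["genome"]])
  write_pileup_tsv(simulate_pileup(model, reference, mean_depth = mean_depth,
                                   seed = seed),
                   paths[["pileup"]])
  write_annotation_bed(annotation, paths[["annotation"]])
  write_truth_json(model$truth, paths[["truth"]])
  data.table::fwrite(screen_fixture(seed)$doses, paths[["screen"]], sep = "\t")
  data.table::fwrite(qpcr_fixture(seed)$cq, paths[["qpcr"]], sep = "\t")
  invisible(paths)
}
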