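## Pileup simulation and I/O.
##
## A pileup is a data.frame with one row per reference site:
##   chrom, pos (1-based), ref, depth, A, C, G, T, ins, del
## where `ins` holds "SEQ:count" for an observed insertion immediately after
## the site, `del` holds "LEN:count" for an observed deletion of the next LEN
## bases, and both are "." when no indel was observed. depth = A + C + G + T.

#' Simulate a pileup of a mutant strain against a reference genome
#'
#' Per-site expected depth is `mean_depth x copy_number`; with `noise =
#' "none"` the depth is exact, with `"poisson"` it is Poisson distributed.
#' Sequencing errors replace a true base by one of the three other bases
#' uniformly at rate `error_rate`. Strain-vs-reference differences are
#' recovered with [diff_genomes()]: SNV sites show the alternate base,
#' insertion/deletion anchors carry the indel observation, and reference
#' positions deleted in the strain get depth 0.
#'
#' @param mutant a `mutant_model` from [plant_events()] (or a bare genome,
#'   treated as fully euploid).
#' @param reference genome the pileup is reported against.
#' @param mean_depth expected per-copy sequencing depth (> 0).
#' @param error_rate per-base error probability in `[0, 1)`.
#' @param noise `"none"` or `"poisson"`.
#' @param seed integer seed (used for noise and errors).
#' @return A pileup data.frame.
#' @export
simulate_pileup <- function(mutant, reference, mean_depth = 100,
                            error_rate = 0, noise = c("none", "poisson"),
                            seed = NULL) {
  noise <- match.arg(noise)
  if (mean_depth <= 0) stopf("mean_depth must be > 0, got %s", mean_depth)
  if (error_rate < 0 || error_rate >= 1) stopf("error_rate must be in [0, 1)")
  if (!inherits(mutant, "mutant_model")) {
    if (!is.character(mutant)) stopf("mutant must be a mutant_model or genome")
    empty_sd <- data.frame(chrom = character(), start = integer(), end = integer())
    mutant <- structure(list(genome = mutant,
                             copy_number = copy_number_map(mutant, character(), empty_sd)),
                        class = "mutant_model")
  }
  with_seed(seed, {
    parts <- lapply(names(reference), function(ch) {
      simulate_pileup_chrom(mutant, reference, ch, mean_depth, error_rate, noise)
    })
    out <- data.table::rbindlist(parts)
    data.table::setDF(out)
    out
  })
}

simulate_pileup_chrom <- function(mutant, reference, chrom, mean_depth,
                                  error_rate, noise) {
  ref_chars <- chrom_chars(reference, chrom)
  n <- length(ref_chars)
  variants <- if (identical(reference[[chrom]], mutant$genome[[chrom]])) {
    NULL
  } else {
    diff_genomes(reference[chrom], mutant$genome[chrom])
  }

  cn <- copy_number_vector(mutant$copy_number, chrom, n)
  depth <- if (noise == "poisson") stats::rpois(n, mean_depth * cn)
           else as.integer(round(mean_depth * cn))

  ## the base each read truly carries at this reference position
  true_base <- ref_chars
  ins_col <- rep(".", n)
  del_col <- rep(".", n)
  if (!is.null(variants) && nrow(variants)) {
    sn <- variants[variants$type == "snv", , drop = FALSE]
    true_base[sn$pos] <- sn$alt
    dl <- variants[variants$type == "deletion", , drop = FALSE]
    for (k in seq_len(nrow(dl))) {
      len <- nchar(dl$ref[k]) - 1L
      del_col[dl$pos[k]] <- paste0(len, ":", depth[dl$pos[k]])
      dead <- (dl$pos[k] + 1L):(dl$pos[k] + len)
      depth[dead] <- 0L
    }
    im <- variants[variants$type == "insertion", , drop = FALSE]
    if (nrow(im))
      ins_col[im$pos] <- paste0(substr(im$alt, 2L, nchar(im$alt)), ":",
                                depth[im$pos])
  }

  counts <- matrix(0L, nrow = n, ncol = 4L, dimnames = list(NULL, DNA_BASES))
  tidx <- match(true_base, DNA_BASES)
  err_n <- if (error_rate > 0) stats::rbinom(n, depth, error_rate) else integer(n)
  counts[cbind(seq_len(n), tidx)] <- depth - err_n
  if (any(err_n > 0L)) {
    ## split errors uniformly over the three non-true bases
    e1 <- stats::rbinom(n, err_n, 1 / 3)
    e2 <- stats::rbinom(n, err_n - e1, 1 / 2)
    e3 <- err_n - e1 - e2
    others <- rbind(c(2L, 3L, 4L), c(1L, 3L, 4L), c(1L, 2L, 4L), c(1L, 2L, 3L))
    idx <- cbind(seq_len(n), others[tidx, 1L])
    counts[idx] <- counts[idx] + e1
    idx <- cbind(seq_len(n), others[tidx, 2L])
    counts[idx] <- counts[idx] + e2
    idx <- cbind(seq_len(n), others[tidx, 3L])
    counts[idx] <- counts[idx] + e3
  }

  data.table::data.table(chrom = chrom, pos = seq_len(n), ref = ref_chars,
                         depth = as.integer(depth),
                         A = counts[, "A"], C = counts[, "C"],
                         G = counts[, "G"], T = counts[, "T"],
                         ins = ins_col, del = del_col)
}

#' Read / write the pileup TSV dialect
#'
#' Ten tab-separated columns with header
#' `chrom pos ref depth A C G T ins del`; positions are 1-based.
#'
#' @param pileup a pileup data.frame.
#' @param path file path.
#' @export
write_pileup_tsv <- function(pileup, path) {
  data.table::fwrite(pileup, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_pileup_tsv
#' @export
read_pileup_tsv <- function(path) {
  need <- c("chrom", "pos", "ref", "depth", "A", "C", "G", "T", "ins", "del")
  pu <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = c("chrom", "ref", "ins", "del")))
  if (!all(need %in% names(pu)))
    stopf("pileup TSV %s lacks required columns: %s", path,
          paste(setdiff(need, names(pu)), collapse = ", "))
  data.table::setDF(pu)
  pu[need]
}

#' Adapter: convert `samtools mpileup` text output to the package pileup
#'
#' Parses the standard 6-column mpileup format (chrom, pos, ref, depth, read
#' bases, base qualities). Read-start (`^` plus mapping quality), read-end
#' (`$`), reference skips (`<`/`>`) and deletion placeholders (`*`) are
#' handled per the mpileup conventions; `+N`/`-N` indel tokens following a
#' read base are tallied, and the most frequent indel observation at a site
#' is reported in the `ins`/`del` columns.
#'
#' @param path path to an mpileup text file.
#' @return A pileup data.frame in the package dialect.
#' @export
read_mpileup <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  rows <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 5L) stopf("malformed mpileup line: %s", ln)
    ref <- toupper(f[3])
    parsed <- parse_mpileup_bases(f[5], ref)
    data.frame(chrom = f[1], pos = as.integer(f[2]), ref = ref,
               depth = as.integer(f[4]),
               A = parsed$counts[["A"]], C = parsed$counts[["C"]],
               G = parsed$counts[["G"]], T = parsed$counts[["T"]],
               ins = parsed$ins, del = parsed$del)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

parse_mpileup_bases <- function(bases, ref) {
  counts <- c(A = 0L, C = 0L, G = 0L, T = 0L)
  ins_obs <- character(); del_obs <- integer()
  chars <- strsplit(bases, "", fixed = TRUE)[[1]]
  i <- 1L; n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "^") { i <- i + 2L; next }                # start marker + mapq
    if (ch == "$" || ch %in% c("<", ">", "*")) { i <- i + 1L; next }
    base <- if (ch %in% c(".", ",")) ref else toupper(ch)
    if (base %in% DNA_BASES) counts[base] <- counts[base] + 1L
    i <- i + 1L
    if (i <= n && chars[i] %in% c("+", "-")) {          # indel follows this read
      sign <- chars[i]; i <- i + 1L
      num <- ""
      while (i <= n && grepl("[0-9]", chars[i])) { num <- paste0(num, chars[i]); i <- i + 1L }
      len <- as.integer(num)
      seq <- toupper(paste(chars[i:(i + len - 1L)], collapse = ""))
      i <- i + len
      if (sign == "+") ins_obs <- c(ins_obs, seq) else del_obs <- c(del_obs, len)
    }
  }
  ins <- "."
  if (length(ins_obs)) {
    tab <- sort(table(ins_obs), decreasing = TRUE)
    ins <- paste0(names(tab)[1], ":", tab[1])
  }
  del <- "."
  if (length(del_obs)) {
    tab <- sort(table(del_obs), decreasing = TRUE)
    del <- paste0(names(tab)[1], ":", tab[1])
  }
  list(counts = counts, ins = ins, del = del)
}
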