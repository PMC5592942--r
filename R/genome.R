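## Genome simulation and sequence-level utilities.
##
## A genome is represented throughout the package as a named character vector:
## one element per chromosome, each a string over {A,C,G,T}. Coordinates are
## 1-based and inclusive everywhere except BED output.

#' Specify a genome to simulate
#'
#' @param chrom_names character vector of unique chromosome labels.
#' @param chrom_lengths integer vector of chromosome lengths in bp (>= 1).
#' @param gc_fraction expected G+C proportion in `[0, 1]`.
#' @param seed integer seed making the simulated sequence reproducible.
#' @return An object of class `genome_spec`.
#' @export
genome_spec <- function(chrom_names, chrom_lengths, gc_fraction = 0.38, seed = 1L) {
  if (length(chrom_names) != length(chrom_lengths))
    stopf("chrom_names and chrom_lengths differ in length")
  if (anyDuplicated(chrom_names))
    stopf("chrom_names: duplicated chromosome name '%s'",
          chrom_names[duplicated(chrom_names)][1])
  if (any(chrom_lengths < 1))
    stopf("chrom_lengths: all lengths must be >= 1")
  if (gc_fraction < 0 || gc_fraction > 1)
    stopf("gc_fraction: must lie in [0, 1], got %s", gc_fraction)
  structure(list(chrom_names = as.character(chrom_names),
                 chrom_lengths = as.integer(chrom_lengths),
                 gc_fraction = gc_fraction,
                 seed = as.integer(seed)),
            class = "genome_spec")
}

#' Default miniature yeast-like genome specification
#'
#' Sixteen chromosomes whose lengths are a 1/10-scale miniature of the
#' S. cerevisiae nuclear karyotype (~1.2 Mb total), so that full
#' simulate/refine/call/ploidy runs finish in seconds.
#'
#' @param seed integer seed.
#' @return A `genome_spec`.
#' @export
default_genome_spec <- function(seed = 1L) {
  full <- c(chrI = 230218L, chrII = 813184L, chrIII = 316620L, chrIV = 1531933L,
            chrV = 576874L, chrVI = 270161L, chrVII = 1090940L, chrVIII = 562643L,
            chrIX = 439888L, chrX = 745751L, chrXI = 666816L, chrXII = 1078177L,
            chrXIII = 924431L, chrXIV = 784333L, chrXV = 1091291L, chrXVI = 948066L)
  genome_spec(names(full), as.integer(round(full / 10)), gc_fraction = 0.38,
              seed = seed)
}

#' Simulate a random haploid genome
#'
#' Bases are drawn i.i.d. with P(G) = P(C) = gc_fraction/2 and
#' P(A) = P(T) = (1 - gc_fraction)/2, so base composition matches
#' `gc_fraction` in expectation.
#'
#' @param spec a [genome_spec()].
#' @return Named character vector of chromosome sequences (a genome).
#' @export
simulate_genome <- function(spec) {
  if (!inherits(spec, "genome_spec")) stopf("spec must be a genome_spec")
  p <- c((1 - spec$gc_fraction) / 2, spec$gc_fraction / 2,
         spec$gc_fraction / 2, (1 - spec$gc_fraction) / 2)
  with_seed(spec$seed, {
    seqs <- vapply(spec$chrom_lengths, function(n) {
      paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
    }, character(1))
    names(seqs) <- spec$chrom_names
    seqs
  })
}

genome_lengths <- function(genome) {
  stats::setNames(nchar(genome), names(genome))
}

## Split a chromosome into a character vector of single bases.
chrom_chars <- function(genome, chrom) {
  if (!chrom %in% names(genome)) stopf("unknown chromosome '%s'", chrom)
  strsplit(genome[[chrom]], "", fixed = TRUE)[[1]]
}

#' Write / read a genome as FASTA
#'
#' @param genome named character vector of sequences.
#' @param path file path.
#' @return `read_genome_fasta` returns a genome; `write_genome_fasta` returns
#'   `path` invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  set <- Biostrings::DNAStringSet(genome)
  names(set) <- names(genome)
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(set), names(set))
}

#' Diff two genomes that differ by sparse SNVs and small indels
#'
#' Recovers, per chromosome, the variant records (in reference coordinates,
#' VCF-style anchoring for indels) that turn `reference` into `subject`.
#' Events must be separated by at least `anchor` matching bases and indels
#' must not exceed `max_indel` bp; within those limits the greedy anchored
#' walk is exact.
#'
#' @param reference,subject genomes with identical chromosome names.
#' @param max_indel largest indel length considered (bp).
#' @param anchor number of downstream matching bases required to accept an
#'   event interpretation.
#' @return data.frame with columns chrom, pos, ref, alt, type
#'   (snv/insertion/deletion).
#' @export
diff_genomes <- function(reference, subject, max_indel = 50L, anchor = 20L) {
  if (!setequal(names(reference), names(subject)))
    stopf("reference and subject have different chromosome sets")
  out <- lapply(names(reference), function(chrom) {
    if (identical(reference[[chrom]], subject[[chrom]])) return(NULL)
    diff_chrom(chrom_chars(reference, chrom), chrom_chars(subject, chrom),
               chrom, max_indel = max_indel, anchor = anchor)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), type = character())
  rownames(out) <- NULL
  out
}

diff_chrom <- function(r, s, chrom, max_indel = 50L, anchor = 20L) {
  recs <- list()
  push <- function(pos, ref, alt, type) {
    recs[[length(recs) + 1L]] <<- data.frame(chrom = chrom, pos = as.integer(pos),
                                             ref = ref, alt = alt, type = type)
  }
  i <- 1L; j <- 1L
  nr <- length(r); ns <- length(s)
  repeat {
    remr <- nr - i + 1L; rems <- ns - j + 1L
    m <- min(remr, rems)
    k <- if (m > 0L) which(r[i:(i + m - 1L)] != s[j:(j + m - 1L)])[1] else NA_integer_
    if (is.na(k)) {
      if (remr == rems) break
      if (rems > remr) {          # trailing insertion after last reference base
        push(nr, r[nr], paste(c(r[nr], s[(j + m):ns]), collapse = ""), "insertion")
      } else {                    # trailing deletion of reference bases
        push(i + m - 1L, paste(r[(i + m - 1L):nr], collapse = ""), r[i + m - 1L],
             "deletion")
      }
      break
    }
    ii <- i + k - 1L; jj <- j + k - 1L
    la <- min(anchor, nr - ii, ns - jj)
    if (la == 0L || all(r[(ii + 1L):(ii + la)] == s[(jj + 1L):(jj + la)])) {
      push(ii, r[ii], s[jj], "snv")
      i <- ii + 1L; j <- jj + 1L
      next
    }
    if (ii == 1L) stopf("%s: cannot anchor an indel at position 1", chrom)
    matched <- FALSE
    for (d in seq_len(max_indel)) {
      if (ii + d <= nr) {         # deletion of d reference bases at ii..ii+d-1
        la2 <- min(anchor, nr - ii - d + 1L, ns - jj + 1L)
        if (la2 > 0L && all(r[(ii + d):(ii + d + la2 - 1L)] == s[jj:(jj + la2 - 1L)])) {
          push(ii - 1L, paste(r[(ii - 1L):(ii + d - 1L)], collapse = ""), r[ii - 1L],
               "deletion")
          i <- ii + d; j <- jj
          matched <- TRUE; break
        }
      }
      if (jj + d <= ns) {         # insertion of d subject bases before ii
        la2 <- min(anchor, ns - jj - d + 1L, nr - ii + 1L)
        if (la2 > 0L && all(s[(jj + d):(jj + d + la2 - 1L)] == r[ii:(ii + la2 - 1L)])) {
          push(ii - 1L, r[ii - 1L],
               paste(c(r[ii - 1L], s[jj:(jj + d - 1L)]), collapse = ""), "insertion")
          i <- ii; j <- jj + d
          matched <- TRUE; break
        }
      }
    }
    if (!matched)
      stopf("%s: sequences diverge at reference position %d beyond the %d bp indel limit",
            chrom, ii, max_indel)
  }
  if (length(recs) == 0L) return(NULL)
  do.call(rbind, recs)
}
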