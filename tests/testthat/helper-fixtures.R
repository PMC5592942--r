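# Shared helpers: tiny genomes and hand-built pileup rows used across tests.

# Four-chromosome toy genome; largest chromosome plays the focal role.
tiny_genome <- function(seed = 3L, lengths = c(c1 = 40000L, c2 = 30000L,
                                               c3 = 20000L, cIV = 153193L)) {
  simulate_genome(genome_spec(names(lengths), unname(lengths), seed = seed))
}

# Single-chromosome reference of repeated base, for hand-built pileup sites.
flat_reference <- function(n, chrom = "c", base = "A") {
  stats::setNames(strrep(base, n), chrom)
}

# One pileup row with explicit base counts.
pileup_site <- function(pos, ref, counts, chrom = "c", ins = ".", del = ".") {
  full <- c(A = 0L, C = 0L, G = 0L, T = 0L)
  full[names(counts)] <- as.integer(counts)
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref,
             depth = sum(full), A = full[["A"]], C = full[["C"]],
             G = full[["G"]], T = full[["T"]], ins = ins, del = del)
}

# Coverage track built directly from window means (sites per window given),
# for ploidy tests that do not need base-level pileups.
make_track <- function(chrom, means, window_bp = 1000L, sites = NULL) {
  stopifnot(length(chrom) == length(means))
  sites <- sites %||% rep(window_bp, length(means))
  parts <- split(seq_along(means), chrom)
  rows <- lapply(names(parts), function(ch) {
    idx <- parts[[ch]]
    k <- seq_along(idx)
    data.frame(chrom = ch, start = (k - 1L) * window_bp + 1L,
               end = (k - 1L) * window_bp + sites[idx],
               n_sites = sites[idx], mean_depth = means[idx],
               scaled_value = NA_real_)
  })
  w <- do.call(rbind, rows)
  gm <- sum(w$mean_depth * w$n_sites) / sum(w$n_sites)
  structure(list(windows = w, genome_mean_depth = gm, scaled = FALSE),
            class = "coverage_track")
}

substr_heads <- function(genome, chroms, pos) {
  mapply(function(ch, p) substr(genome[[ch]], p, p), chroms, pos,
         USE.NAMES = FALSE)
}

revcomp_str <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

chrom_diff_positions <- function(a, b) {
  which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
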