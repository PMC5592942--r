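test_that("the 90% read-fraction rule is inclusive at the boundary", {
  ref <- flat_reference(10)
  called_9 <- call_differences(pileup_site(1, "A", c(A = 1L, C = 9L)), ref)
  expect_identical(nrow(called_9), 1L)
  expect_equal(called_9$fraction, 0.9)
  called_8 <- call_differences(pileup_site(1, "A", c(A = 2L, C = 8L)), ref)
  expect_identical(nrow(called_8), 0L)
})

test_that("call decisions match the direct inequality for all depths <= 20", {
  ref <- flat_reference(1)
  params <- caller_params()
  for (d in 1:20) for (k in 0:d) {
    pu <- pileup_site(1, "A", c(A = d - k, C = k))
    got <- nrow(call_differences(pu, ref, params)) == 1L
    want <- (k / d >= 0.9) && (d >= params$min_depth)
    expect_identical(got, want,
                     info = sprintf("depth %d alt %d", d, k))
  }
})

test_that("ceil(0.9 d) alternate reads are called and one fewer is not", {
  ref <- flat_reference(1)
  for (d in c(10L, 11L, 37L, 100L, 137L, 200L)) {
    k <- as.integer(ceiling(0.9 * d))
    expect_identical(nrow(call_differences(
      pileup_site(1, "A", c(A = d - k, C = k)), ref)), 1L)
    if ((k - 1) / d < 0.9)
      expect_identical(nrow(call_differences(
        pileup_site(1, "A", c(A = d - k + 1L, C = k - 1L)), ref)), 0L)
  }
})

test_that("two alternate alleles below threshold yield no call", {
  ref <- flat_reference(1)
  pu <- pileup_site(1, "A", c(C = 50L, G = 50L))
  expect_identical(nrow(call_differences(pu, ref)), 0L)
})

test_that("a half-fraction variant (one copy of a disomic pair) is not called", {
  ref <- flat_reference(1)
  pu <- pileup_site(1, "A", c(A = 100L, G = 100L))
  expect_identical(nrow(call_differences(pu, ref)), 0L)
})

test_that("pileup/reference disagreement raises an error with the coordinate", {
  ref <- flat_reference(10)
  expect_error(call_differences(pileup_site(3, "G", c(G = 100L)), ref), "c:3")
})

test_that("integrate_variants does SNV and indel coordinate arithmetic", {
  g <- c(chr = "AAAAAAAAAA")
  res <- integrate_variants(g, data.frame(
    chrom = "chr", pos = 2L, ref = "A", alt = "G", type = "snv"))
  expect_identical(res$genome[["chr"]], "AGAAAAAAAA")
  expect_identical(nchar(res$genome[["chr"]]), 10L)

  res <- integrate_variants(g, data.frame(
    chrom = "chr", pos = 3L, ref = "AAA", alt = "A", type = "deletion"))
  expect_identical(nchar(res$genome[["chr"]]), 8L)
  expect_identical(map_position(res$coordinate_map, "chr", 8L), 6L)
  expect_identical(map_position(res$coordinate_map, "chr", 4L), NA_integer_)

  res <- integrate_variants(g, data.frame(
    chrom = "chr", pos = 3L, ref = "A", alt = "ACT", type = "insertion"))
  expect_identical(nchar(res$genome[["chr"]]), 12L)
  expect_identical(map_position(res$coordinate_map, "chr", 4L), 6L)
})

test_that("overlapping variants are rejected with the collision named", {
  g <- c(chr = "AAAAAAAAAA")
  expect_error(integrate_variants(g, data.frame(
    chrom = "chr", pos = c(3L, 4L), ref = c("AAA", "A"), alt = c("A", "C"),
    type = c("deletion", "snv"))), "overlap")
})

test_that("integration reaches a fixed point against error-free pileups", {
  g <- tiny_genome(lengths = c(c1 = 20000L, c2 = 15000L, c3 = 12000L,
                               c4 = 10000L))
  plan <- mutation_plan(
    snvs = data.frame(chrom = c("c1", "c2", "c3"), pos = c(500L, 900L, 4000L),
                      ref = substr_heads(g, c("c1", "c2", "c3"),
                                         c(500L, 900L, 4000L)),
                      alt = c("A", "C", "G")),
    indels = data.frame(chrom = c("c1", "c4"), pos = c(3000L, 2000L),
                        seq = c("TTG", substr(g[["c4"]], 2001, 2002)),
                        type = c("ins", "del")))
  plan$snvs$alt <- mapply(function(r, a) if (r == a) "T" else a,
                          plan$snvs$ref, plan$snvs$alt)
  m <- plant_events(g, plan)
  pu <- simulate_pileup(m, g, 100)
  vs <- call_differences(pu, g)
  res <- integrate_variants(g, vs)
  expect_identical(res$genome, m$genome)
  pu2 <- simulate_pileup(m, res$genome, 100)
  expect_identical(nrow(call_differences(pu2, res$genome)), 0L)
})

test_that("refinement converges and recovers a planted progenitor", {
  g <- tiny_genome(lengths = c(c1 = 20000L, c2 = 15000L, c3 = 12000L,
                               c4 = 10000L))
  # progenitor identical to base: one cycle, zero variants
  rr0 <- refine_reference(g, function(genome) simulate_pileup(g, genome, 100))
  expect_identical(rr0$cycles_run, 1L)
  expect_true(rr0$converged)
  expect_identical(sum(rr0$variants_per_cycle), 0L)

  pos <- c(600L, 2500L, 7000L, 1200L, 5200L)
  ch <- c("c1", "c1", "c1", "c2", "c3")
  ref <- substr_heads(g, ch, pos)
  alt <- vapply(ref, function(r) setdiff(c("A", "C", "G", "T"), r)[1], "")
  m <- plant_events(g, mutation_plan(
    snvs = data.frame(chrom = ch, pos = pos, ref = ref, alt = alt)))
  rr <- refine_reference(g, function(genome) simulate_pileup(m, genome, 100))
  expect_true(rr$converged)
  expect_lte(rr$cycles_run, 2L)
  expect_identical(rr$genome, m$genome)
})

test_that("an adversarial provider stops at exactly 10 cycles, unconverged", {
  g <- c(chrA = strrep("A", 200))
  provider <- function(genome) {
    base <- substr(genome[["chrA"]], 1, 1)
    alt <- setdiff(c("A", "C", "G", "T"), base)[1]
    pileup_site(1, base, stats::setNames(100L, alt), chrom = "chrA")
  }
  rr <- refine_reference(g, provider)
  expect_identical(rr$cycles_run, 10L)
  expect_false(rr$converged)
  expect_identical(rr$variants_per_cycle, rep(1L, 10L))
})

test_that("a planted SNV survives 5% sequencing error at 100x", {
  g <- simulate_genome(genome_spec("chr1", 2000L, seed = 12L))
  ref <- substr(g[["chr1"]], 1000, 1000)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  m <- plant_events(g, mutation_plan(
    snvs = data.frame(chrom = "chr1", pos = 1000L, ref = ref, alt = alt)))
  pu <- simulate_pileup(m, g, 100, error_rate = 0.05, seed = 5L)
  calls <- call_mutations(pu, g, mutant_id = "mA")
  hit <- calls[calls$pos == 1000L, ]
  expect_identical(nrow(hit), 1L)
  expect_gte(hit$fraction, 0.9)
  expect_lt(abs(hit$fraction - 0.95), 0.08)
})

test_that("all nine substitutions of a codon classify as translation says", {
  # gene on + strand: ATG | GGA | TGC | TAA starting at position 11
  gene_seq <- "ATGGGATGCTAA"
  g <- c(chr = paste0(strrep("T", 10), gene_seq, strrep("T", 10)))
  ann <- data.frame(feature_id = "G1", chrom = "chr", start = 11L, end = 22L,
                    strand = "+", feature_type = "gene")
  for (within in 1:3) for (alt in c("A", "C", "G", "T")) {
    pos <- 13L + within             # codon 2 occupies positions 14-16
    ref <- substr(g[["chr"]], pos, pos)
    if (alt == ref) next
    call <- data.frame(chrom = "chr", pos = pos, ref = ref, alt = alt,
                       type = "snv")
    got <- classify_effect(call, ann, g)
    # independent oracle: translate the whole mutated ORF with Biostrings
    mut <- gene_seq
    substr(mut, pos - 10L, pos - 10L) <- alt
    p0 <- as.character(Biostrings::translate(Biostrings::DNAString(gene_seq)))
    p1 <- as.character(Biostrings::translate(Biostrings::DNAString(mut)))
    expect_identical(got, if (p0 == p1) "synonymous" else "nonsynonymous",
                     info = sprintf("pos %d alt %s", pos, alt))
  }
})

test_that("minus-strand codons are classified on the feature's strand", {
  # reverse-complement ORF embedded on the minus strand
  orf <- "ATGCATGAAGGTTAA"
  g <- c(chr = paste0(strrep("A", 6), revcomp_str(orf), strrep("A", 6)))
  ann <- data.frame(feature_id = "G1", chrom = "chr", start = 7L,
                    end = 6L + nchar(orf), strand = "-", feature_type = "gene")
  # third position of codon 2 (CAT -> CAC is synonymous His)
  # codon 2 position 3 sits at genome coordinate end - 5
  pos <- ann$end - 5L
  ref <- substr(g[["chr"]], pos, pos)
  alt <- revcomp_str("C")
  call <- data.frame(chrom = "chr", pos = pos, ref = ref, alt = alt, type = "snv")
  expect_identical(classify_effect(call, ann, g), "synonymous")
})

test_that("SNVs outside all features are intergenic; indels not applicable", {
  g <- c(chr = strrep("A", 100))
  ann <- data.frame(feature_id = "G1", chrom = "chr", start = 40L, end = 60L,
                    strand = "+", feature_type = "gene")[0, ]
  calls <- data.frame(chrom = "chr", pos = c(10L, 20L), ref = c("A", "AT"),
                      alt = c("G", "A"), type = c("snv", "deletion"))
  expect_identical(classify_effect(calls, ann, g),
                   c("intergenic", "not_applicable"))
})

test_that("a feature whose length is not a codon multiple raises an error", {
  g <- c(chr = strrep("ATG", 40))
  ann <- data.frame(feature_id = "BAD", chrom = "chr", start = 10L, end = 20L,
                    strand = "+", feature_type = "gene")
  call <- data.frame(chrom = "chr", pos = 12L, ref = "A", alt = "C", type = "snv")
  expect_error(classify_effect(call, ann, g), "codon multiple")
})

test_that("cross-mutant deduplication keys on (chrom, pos, ref, alt)", {
  shared <- data.frame(chrom = "c1", pos = 10L, ref = "A", alt = "G",
                       type = "snv", fraction = 1, depth = 100L,
                       effect_class = "nonsynonymous")
  cohort <- rbind(cbind(shared, mutant_id = "m1"),
                  cbind(shared, mutant_id = "m2"))
  u <- unique_mutations(cohort)
  expect_identical(u$n_unique, 1L)
  expect_identical(u$unique$n_mutants, 2L)

  a <- data.frame(chrom = "c1", pos = 1:3 * 10L, ref = "A", alt = "G",
                  type = "snv", fraction = 1, depth = 100L,
                  effect_class = "synonymous", mutant_id = "m1")
  b <- data.frame(chrom = "c2", pos = 1:4 * 10L, ref = "A", alt = "T",
                  type = "snv", fraction = 1, depth = 100L,
                  effect_class = "intergenic", mutant_id = "m2")
  u2 <- unique_mutations(rbind(a, b))
  expect_identical(u2$n_unique, 7L)
  expect_identical(u2$counts[["synonymous"]], 3L)
  expect_identical(u2$counts[["intergenic"]], 4L)
})

test_that("the mpileup adapter parses the standard token stream", {
  lines <- c(
    "chr1\t5\tA\t10\t.,.,.,.,..\tIIIIIIIIII",
    "chr1\t6\tG\t10\t.TTTTTTTTt\tIIIIIIIIII",
    "chr1\t7\tC\t6\t^].,.+2AG..,$\tIIIIII",
    "chr1\t8\tT\t5\t.,-1a..\tIIIII")
  path <- withr::local_tempfile(lines = lines, fileext = ".mp")
  pu <- read_mpileup(path)
  expect_identical(pu$A[1], 10L)
  expect_identical(pu$T[2], 9L)
  expect_identical(pu$G[2], 1L)
  expect_identical(pu$ins[3], "AG:1")
  expect_identical(pu$C[3], 6L)
  expect_identical(pu$del[4], "1:1")
})
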