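test_that("window tiling keeps the final partial window with its true length", {
  g <- c(chr = strrep("A", 2500))
  pu <- simulate_pileup(g, g, 100)
  tr <- windowed_coverage(pu, ploidy_params(window_bp = 1000L))
  w <- tr$windows
  expect_identical(w$start, c(1L, 1001L, 2001L))
  expect_identical(w$end, c(1000L, 2000L, 2500L))
  expect_identical(w$n_sites, c(1000L, 1000L, 500L))
  expect_true(all(w$mean_depth == 100))
})

test_that("window means equal a per-site brute-force average", {
  set.seed(21)
  n <- 3473L
  pu <- data.frame(chrom = "chr", pos = seq_len(n), ref = "A",
                   depth = rpois(n, 50))
  tr <- windowed_coverage(pu, ploidy_params(window_bp = 500L))
  for (k in seq_len(nrow(tr$windows))) {
    w <- tr$windows[k, ]
    expect_equal(w$mean_depth, mean(pu$depth[pu$pos >= w$start & pu$pos <= w$end]))
  }
  expect_equal(tr$genome_mean_depth, mean(pu$depth))
})

test_that("scaling matches the closed form for a partly disomic genome", {
  # one chromosome with fraction f of the genome at depth 2c, rest at c:
  # scaled values 2/(1+f) there and 1/(1+f) elsewhere
  f <- 0.127
  n_dup <- 127L; n_rest <- 873L
  tr <- make_track(c(rep("dup", n_dup), rep("rest", n_rest)),
                   c(rep(200, n_dup), rep(100, n_rest)))
  tr <- scale_track(tr)
  sv <- tr$windows$scaled_value
  expect_equal(unique(sv[tr$windows$chrom == "dup"]), 2 / (1 + f),
               tolerance = 1e-12)
  expect_equal(unique(sv[tr$windows$chrom == "rest"]), 1 / (1 + f),
               tolerance = 1e-12)
})

test_that("scaled tracks have length-weighted mean 1 to machine precision", {
  set.seed(4)
  for (rep in 1:5) {
    means <- rgamma(60, shape = 20, rate = 0.2)
    sites <- sample(200:1000, 60, replace = TRUE)
    tr <- scale_track(make_track(rep(c("a", "b", "c"), each = 20), means,
                                 sites = sites))
    w <- tr$windows
    expect_equal(sum(w$scaled_value * w$n_sites) / sum(w$n_sites), 1,
                 tolerance = 1e-9)
  }
  expect_error(scale_track(make_track(rep("a", 20), rep(0, 20))), "zero")
})

test_that("noiseless whole-chromosome duplication is called copy number 2", {
  g <- tiny_genome(lengths = c(c1 = 30000L, c2 = 25000L, c3 = 20000L,
                               cIV = 40000L))
  m <- plant_events(g, mutation_plan(disomies = "cIV"))
  tr <- scale_track(windowed_coverage(simulate_pileup(m, g, 100)))
  call <- classify_ploidy(tr, "cIV")
  expect_identical(call$copy_number, 2L)
  expect_identical(call$scope, "whole")
  expect_equal(call$duplicated_fraction, 1)
  eu <- classify_ploidy(tr, "c1")
  expect_identical(eu$copy_number, 1L)
  expect_identical(eu$scope, "euploid")
})

test_that("disomy is recovered in 100/100 Poisson simulations", {
  # window means of Poisson per-site coverage: sum of site counts is Poisson
  wb <- 1000L
  hits <- 0L
  for (s in 1:100) {
    set.seed(s)
    chroms <- c(rep("bg1", 60), rep("bg2", 60), rep("bg3", 60), rep("dis", 200))
    lambda <- ifelse(chroms == "dis", 200, 100)
    means <- rpois(length(chroms), lambda * wb) / wb
    tr <- scale_track(make_track(chroms, means, window_bp = wb))
    call <- classify_ploidy(tr, "dis")
    if (call$copy_number == 2L && call$scope == "whole") hits <- hits + 1L
  }
  expect_identical(hits, 100L)
})

test_that("a noiseless coverage step is found at the exact window boundary", {
  tr <- scale_track(make_track(c(rep("bg", 120), rep("seg", 100)),
                               c(rep(100, 120), rep(100, 60), rep(200, 40))))
  call <- detect_segmental(tr, "seg")
  expect_identical(call$scope, "segmental")
  expect_identical(call$breakpoint, 60L * 1000L + 1L)
  expect_identical(call$copy_number, 2L)
  expect_equal(call$duplicated_fraction, 0.4)
})

test_that("the printed terminal-duplication geometry yields 58%", {
  g <- simulate_genome(genome_spec(c("bg1", "bg2", "bg3", "chrD"),
                                   c(300000L, 250000L, 200000L, 1534000L),
                                   seed = 13L))
  m <- plant_events(g, mutation_plan(
    segmental_dups = data.frame(chrom = "chrD", start = 644001L,
                                end = 1534000L)))
  tr <- scale_track(windowed_coverage(simulate_pileup(m, g, 100)))
  call <- classify_ploidy(tr, "chrD")
  expect_identical(call$scope, "segmental")
  expect_identical(call$breakpoint, 644001L)
  expect_identical(call$duplicated_span_bp, 890000L)
  expect_equal(round(100 * call$duplicated_fraction), 58)
})

test_that("changepoint choice equals exhaustive scan on noisy short tracks", {
  wb <- 1000L
  msw <- ploidy_params()$min_segment_windows
  for (s in 1:20) {
    set.seed(100 + s)
    W <- sample(seq(2L * msw, 50L), 1)
    k_true <- sample(msw:(W - msw), 1)
    lambda <- c(rep(100, k_true), rep(200, W - k_true))
    means <- rpois(W, lambda * wb) / wb
    bg <- rpois(120, 100 * wb) / wb
    tr <- scale_track(make_track(c(rep(c("bg1", "bg2", "bg3"), each = 40),
                                   rep("seg", W)),
                                 c(bg, means), window_bp = wb))
    call <- detect_segmental(tr, "seg")
    # brute-force oracle over every admissible split
    v <- tr$windows$scaled_value[tr$windows$chrom == "seg"]
    sse <- vapply(msw:(W - msw), function(k) {
      sum((v[1:k] - mean(v[1:k]))^2) + sum((v[(k + 1):W] - mean(v[(k + 1):W]))^2)
    }, numeric(1))
    k_best <- (msw:(W - msw))[which.min(sse)]
    expect_identical(call$breakpoint, k_best * wb + 1L)
    expect_identical(call$scope, "segmental")
  }
})

test_that("median-of-medians baseline is robust to a few disomic chromosomes", {
  chroms <- rep(sprintf("chr%02d", 1:16), each = 30)
  means <- rep(100, length(chroms))
  means[chroms %in% c("chr01", "chr05", "chr11")] <- 200
  tr <- scale_track(make_track(chroms, means))
  b <- aneuscreen:::track_baseline(tr, ploidy_params())
  true_level <- 100 / tr$genome_mean_depth
  expect_lt(abs(b - true_level) / true_level, 0.01)
})

test_that("planted events are recovered exactly on noiseless data", {
  g <- tiny_genome(lengths = c(c1 = 30000L, c2 = 25000L, c3 = 20000L,
                               cIV = 50000L))
  m <- plant_events(g, mutation_plan(
    disomies = "c2",
    segmental_dups = data.frame(chrom = "cIV", start = 30001L, end = 50000L)))
  tr <- scale_track(windowed_coverage(simulate_pileup(m, g, 100)))
  d <- classify_ploidy(tr, "c2")
  expect_identical(d$scope, "whole"); expect_identical(d$copy_number, 2L)
  s <- classify_ploidy(tr, "cIV")
  expect_identical(s$scope, "segmental")
  expect_lte(abs(s$breakpoint - 30001L), 1000L)
  expect_identical(s$copy_number, 2L)
})

test_that("cohort arm-disomy summary reproduces the 86% arithmetic", {
  whole <- data.frame(chrom = "chrIV", copy_number = 2L, scope = "whole",
                      breakpoint = NA_integer_, dup_start = 1L,
                      dup_end = 153193L, duplicated_span_bp = 153193L,
                      duplicated_fraction = 1, n_low_confidence = 0L)
  seg <- transform(whole, scope = "segmental", breakpoint = 44001L,
                   dup_start = 44001L, duplicated_span_bp = 109193L,
                   duplicated_fraction = 109193 / 153193)
  eu <- transform(whole, copy_number = 1L, scope = "euploid",
                  dup_start = NA_integer_, dup_end = NA_integer_,
                  duplicated_span_bp = 0L, duplicated_fraction = 0)
  calls <- do.call(rbind, c(rep(list(whole), 11), list(seg), rep(list(eu), 2)))
  calls$mutant_id <- sprintf("m%02d", 1:14)
  calls$group <- "BYxRM"
  arm <- list(chrom = "chrIV", start = 44972L, end = 153193L)
  out <- summarize_cohort(calls, arm)
  expect_identical(out$fraction_percent[out$group == "BYxRM"], 86L)

  calls$group <- "one"
  expect_identical(summarize_cohort(calls[1, ], arm)$fraction_percent[1], 100L)
  expect_identical(summarize_cohort(transform(calls, copy_number = 1L,
                                              scope = "euploid"),
                                    arm)$fraction_percent[1], 0L)
})
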