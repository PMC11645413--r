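# helper: PWM that is an exact indicator for a short word
indicator_pwm <- function(word) {
  bases <- c("A", "C", "G", "T")
  L <- nchar(word)
  p <- matrix(0, L, 4, dimnames = list(NULL, bases))
  for (j in seq_len(L)) p[j, match(substr(word, j, j), bases)] <- 1
  pwm(p, name = word)
}

test_that("load_motif normalizes counts with pseudocount", {
  f <- withr::local_tempfile(fileext = ".pfm")
  writeLines(c(">toy", "A [ 10 0 5 2 ]", "C [ 0 10 5 2 ]",
               "G [ 0 0 0 2 ]", "T [ 0 0 0 4 ]"), f)
  m <- load_motif(f)
  expect_s3_class(m, "PositionWeightMatrix")
  expect_equal(unname(rowSums(m$probs)), rep(1, 4))
  # zero-count column with pseudocount 0.25 is uniform at position 3? no --
  # position with all-zero counts: construct directly
  writeLines(c("A [ 0 1 1 1 ]", "C [ 0 1 1 1 ]", "G [ 0 1 1 1 ]",
               "T [ 0 1 1 1 ]"), f)
  m2 <- load_motif(f, pseudocount = 0.25)
  expect_equal(unname(m2$probs[1, ]), rep(0.25, 4))
  writeLines(c("A [ 1 2 ]", "C [ 1 ]", "G [ 1 2 ]", "T [ 1 2 ]"), f)
  expect_error(load_motif(f), "ragged")
  writeLines(c("A [ 1 -2 1 1 ]", "C [ 1 1 1 1 ]", "G [ 1 1 1 1 ]",
               "T [ 1 1 1 1 ]"), f)
  expect_error(load_motif(f), "negative")
})

test_that("palindromic PWM equals its own reverse complement", {
  # GGTACAnnnTGTTCT is not palindromic; build a true palindrome ACGT-style
  pal <- matrix(c(
    0.7, 0.1, 0.1, 0.1,
    0.1, 0.7, 0.1, 0.1,
    0.1, 0.1, 0.7, 0.1,
    0.1, 0.1, 0.1, 0.7), 4, 4, byrow = TRUE,
    dimnames = list(NULL, c("A", "C", "G", "T")))
  p <- pwm(pal, name = "pal")
  expect_equal(pwm_revcomp(p)$probs, p$probs)
})

test_that("scan_motif finds indicator hits with strand symmetry", {
  p <- indicator_pwm("ACGT")  # palindromic word
  h <- scan_motif(p, "AAACGTTT", threshold = 0)
  expect_equal(h$position, 2)
  expect_equal(h$strand, "+")  # palindrome dedups to '+'
  expect_equal(h$score, 8)     # 4 positions x log2(1/0.25)
  pg <- indicator_pwm("ACCA")
  h1 <- scan_motif(pg, "TTACCATT", threshold = 0)
  expect_equal(h1$strand, "+")
  expect_equal(h1$position, 2)
  h2 <- scan_motif(pg, "AATGGTAA", threshold = 0)  # reverse complement
  expect_equal(h2$strand, "-")
  expect_equal(h2$position, 2)
  expect_equal(h2$score, h1$score)
  # sequence shorter than motif: empty, not an error
  expect_equal(nrow(scan_motif(pg, "AC", threshold = 0)), 0)
  # N windows are skipped
  expect_equal(nrow(scan_motif(pg, "TTANCATT", threshold = 0)), 0)
})

test_that("scan_motif equals the exhaustive oracle on random sequences", {
  set.seed(5)
  for (rep in 1:50) {
    s <- paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE),
               collapse = "")
    thr <- 5
    got <- scan_motif(are_pwm, s, threshold = thr)
    want <- oracle_scan(are_pwm, s, threshold = thr)
    expect_equal(got$position, want$position)
    expect_equal(got$strand, want$strand)
    expect_equal(got$score, want$score, tolerance = 1e-10)
  }
})

test_that("score_threshold calibrates the background FPR", {
  # empirical check: fraction of random offsets scoring above the default
  # threshold should be at most ~1e-4 per strand
  set.seed(9)
  s <- paste(sample(c("A", "C", "G", "T"), 200000, replace = TRUE),
             collapse = "")
  x <- cistromere:::.seq_to_int(s)
  sc <- cistromere:::.scan_scores(are_pwm$lom, x)
  fpr <- mean(sc >= are_pwm$default_threshold)
  expect_lt(fpr, 3e-4)
  # and the threshold is not absurdly conservative: some signal passes
  expect_lt(are_pwm$default_threshold, sum(apply(are_pwm$lom, 1, max)))
})

test_that("peak_has_motif respects the central window", {
  g <- make_genome(c(chr1 = 5000), seed = 2)
  # plant a consensus site at position 2500 (peak center) and another
  # 300 bp away
  site <- pwm_consensus(are_pwm)
  g2 <- cistromere:::.genome_replace(g, "chr1", 2493, site)
  pk <- peak_set("chr1", 2400, 2600)
  expect_true(peak_has_motif(pk, g2, are_pwm))
  g3 <- cistromere:::.genome_replace(g, "chr1", 2800, site)
  expect_false(peak_has_motif(pk, g3, are_pwm, window = 100))
  expect_true(peak_has_motif(pk, g3, are_pwm, window = 1000))
  expect_error(peak_has_motif(peak_set("chrX", 0, 10), g3, are_pwm),
               "absent")
})

test_that("fraction_with_motif recounts peak_has_motif and hits planted
           fractions exactly", {
  g <- make_genome(c(chr1 = 20000), seed = 3)
  sim <- make_peak_sets(g, n_peaks = 10, are_fraction = 0.7, pwm = are_pwm,
                        seed = 4)
  expect_equal(fraction_with_motif(sim$peaks, sim$genome, are_pwm), 0.7)
  flags <- peak_has_motif(sim$peaks, sim$genome, are_pwm)
  expect_equal(mean(flags), 0.7)
  expect_equal(sort(sim$peaks$intervals$name[flags]),
               sort(sim$truth$positive_peaks))
  expect_error(fraction_with_motif(peak_set(character(), numeric(),
                                            numeric()), g, are_pwm),
               "empty")
})

test_that("compare_fractions matches enumeration oracles", {
  # unpaired {1,2,3} vs {4,5,6}: exact two-sided p = 2 / C(6,3) = 0.1
  r <- compare_fractions(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p_value, 0.1)
  # paired, 8 concordant pairs: p = 2 / 2^8
  r2 <- compare_fractions(seq(0.4, 0.47, by = 0.01),
                          seq(0.4, 0.47, by = 0.01) - 0.1, paired = TRUE)
  expect_equal(r2$p_value, 2 / 2^8)
  # identical groups paired: all differences zero -> p = 1
  r3 <- compare_fractions(c(1, 2, 3), c(1, 2, 3), paired = TRUE)
  expect_equal(r3$p_value, 1)
  expect_error(compare_fractions(1:3, 1:4, paired = TRUE), "equal")
})

test_that("paired exact p equals full 2^n sign enumeration with ties", {
  set.seed(21)
  for (rep in 1:5) {
    d <- round(stats::rnorm(7), 1)
    d <- d[d != 0]
    n <- length(d)
    # enumerate all sign vectors
    r <- rank(abs(d))
    v_obs <- sum(r[d > 0])
    signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
    vs <- apply(signs, 1, function(s) sum(r[unlist(s)]))
    ev <- sum(r) / 2
    p_oracle <- mean(abs(vs - ev) >= abs(v_obs - ev) - 1e-12)
    got <- compare_fractions(d, rep(0, n), paired = TRUE)$p_value
    # two-sided doubling convention vs symmetric-distance enumeration agree
    # for the symmetric signed-rank distribution
    expect_equal(got, p_oracle, tolerance = 1e-12)
  }
})

test_that("motif density profile puts planted central hits in the center
           bin at 0.1 per bp per peak", {
  g <- make_genome(c(chr1 = 100000), seed = 6)
  sim <- make_peak_sets(g, n_peaks = 20, are_fraction = 1, pwm = are_pwm,
                        seed = 6, width = 300)
  prof <- motif_density_profile(sim$peaks, sim$genome, are_pwm)
  expect_equal(length(prof$values), 240)
  # every peak has its planted hit starting at center - floor(L/2) = -7,
  # i.e. in the bin covering [-10, 0)
  central <- which(prof$offsets == -10)
  expect_gte(prof$values[central], 1 / 10)
  # integral equals mean hits per peak within the window
  hits_per_peak <- sum(prof$values * prof$bin)
  expect_gte(hits_per_peak, 1)
  expect_error(motif_density_profile(sim$peaks, sim$genome, are_pwm,
                                     window = 2400, bin = 7), "divide")
})

test_that("differential density subtracts and smoothing preserves the mean", {
  g <- make_genome(c(chr1 = 100000), seed = 8)
  sim <- make_peak_sets(g, n_peaks = 10, are_fraction = 1, pwm = are_pwm,
                        seed = 8, width = 300)
  a <- motif_density_profile(sim$peaks, sim$genome, are_pwm)
  d0 <- differential_density(a, a)
  expect_true(all(d0$values == 0))
  # center-enriched a vs flat zero b: positive central signal
  b <- a; b$values <- rep(0, length(a$values))
  class(b) <- "DensityProfile"
  d1 <- differential_density(a, b)
  expect_true(d1$values[a$offsets == -10] > 0)
  # smoothing preserves the mean exactly (circular symmetric kernel)
  d2 <- differential_density(a, b, smooth = TRUE)
  expect_equal(mean(d2$values), mean(d1$values), tolerance = 1e-12)
  bad <- a; bad$bin <- 20
  expect_error(differential_density(a, bad), "geometry")
})

test_that("motif_enrichment builds the right table and flags significance", {
  g <- make_genome(c(chr1 = 60000, chr2 = 60000), seed = 10)
  fg <- make_peak_sets(g, 50, are_fraction = 0.9, pwm = are_pwm, seed = 11,
                       chrom = "chr1")
  bg <- make_peak_sets(fg$genome, 50, are_fraction = 0.1, pwm = are_pwm,
                       seed = 12, chrom = "chr2")
  enr <- motif_enrichment(fg$peaks, bg$peaks, bg$genome, are_pwm)
  expect_equal(unname(enr$table[, "foreground"]), c(45, 5))
  expect_equal(unname(enr$table[, "background"]), c(5, 45))
  expect_equal(enr$odds_ratio, 81)
  expect_equal(enr$p_value,
               oracle_hyper_upper(45, 5, 5, 45), tolerance = 1e-12)
  expect_false(enr$significant)  # fifty peaks cannot reach 1e-20
  # equal fractions: odds ratio 1
  enr2 <- motif_enrichment(fg$peaks, fg$peaks, fg$genome, are_pwm)
  expect_equal(enr2$odds_ratio, 1)
  expect_false(enr2$significant)
})
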