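test_that("peak_set validates and sorts intervals", {
  ps <- peak_set(c("chr2", "chr1", "chr1"), c(5, 100, 10),
                 c(20, 200, 40), sample_id = "s")
  df <- as.data.frame(ps)
  expect_equal(df$chrom, c("chr1", "chr1", "chr2"))
  expect_equal(df$start, c(10, 100, 5))
  expect_equal(n_peaks(ps), 3)
  expect_error(peak_set("chr1", 100, 50), "invalid interval")
  expect_error(peak_set("chr1", -1, 50), "invalid interval")
  expect_error(peak_set("chr1", 1.5, 50), "integer")
})

test_that("BED round trip is identity on the first 6 columns", {
  ps <- peak_set(c("chr1", "chr1", "chr2"), c(0, 50, 10), c(10, 80, 30),
                 name = c("a", "b", "c"), score = c(1, 2.5, 3),
                 strand = c("+", "-", "."))
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed(ps, f)
  back <- read_bed(f)
  expect_equal(as.data.frame(back), as.data.frame(ps))
})

test_that("read_bed handles empty files and reports bad lines", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(character(0), f)
  expect_equal(n_peaks(read_bed(f)), 0)
  writeLines("chr1\t100\t50", f)
  expect_error(read_bed(f), "line 1")
  writeLines(c("chr1\t0\t10", "chr1\tx\t20"), f)
  expect_error(read_bed(f), "line 2")
})

test_that("overlaps_any implements the >=1 bp half-open rule", {
  a <- peak_set("chr1", 10, 20)
  expect_true(overlaps_any(a, peak_set("chr1", 19, 30)))
  expect_false(overlaps_any(a, peak_set("chr1", 20, 30)))
  expect_false(overlaps_any(a, peak_set("chr2", 10, 20)))
  expect_error(overlaps_any(a, a, min_overlap = 0), "min_overlap")
  # min_overlap larger than the shared span
  expect_false(overlaps_any(a, peak_set("chr1", 15, 30), min_overlap = 6))
  expect_true(overlaps_any(a, peak_set("chr1", 15, 30), min_overlap = 5))
})

test_that("overlaps_any agrees with the all-pairs brute-force oracle", {
  set.seed(11)
  for (rep in 1:5) {
    a <- random_peakset(40)
    b <- random_peakset(40)
    got <- overlaps_any(a, b)
    da <- as.data.frame(a); db <- as.data.frame(b)
    want <- vapply(seq_len(nrow(da)), function(i) {
      any(db$chrom == da$chrom[i] &
            pmin(db$end, da$end[i]) - pmax(db$start, da$start[i]) >= 1)
    }, logical(1))
    expect_identical(got, want)
  }
})

test_that("subtract splits intervals per-base", {
  a <- peak_set("chr1", 0, 10)
  r <- as.data.frame(subtract(a, peak_set("chr1", 3, 5)))
  expect_equal(r$start, c(0, 5))
  expect_equal(r$end, c(3, 10))
  # disjoint b leaves a unchanged
  expect_equal(as.data.frame(subtract(a, peak_set("chr1", 50, 60))),
               as.data.frame(a))
  # b covering a empties it
  expect_equal(n_peaks(subtract(a, peak_set("chr1", 0, 20))), 0)
})

test_that("subtract and intersection partition a, per base (oracle)", {
  set.seed(42)
  for (rep in 1:10) {
    a <- random_peakset(30)
    b <- random_peakset(30)
    d <- subtract(a, b)
    for (ch in c("chrA", "chrB")) {
      ca <- oracle_base_cover(a, ch, 600)
      cb <- oracle_base_cover(b, ch, 600)
      cd <- oracle_base_cover(d, ch, 600)
      expect_identical(cd, ca & !cb)
    }
  }
})

test_that("consensus_peaks keeps blocks supported by >= min_support sets", {
  s1 <- peak_set("chr1", c(100, 500), c(200, 600), sample_id = "s1")
  s2 <- peak_set("chr1", 100, 200, sample_id = "s2")
  s3 <- peak_set("chr1", 900, 950, sample_id = "s3")
  cons <- consensus_peaks(list(s1, s2, s3))
  df <- as.data.frame(cons)
  expect_equal(nrow(df), 1)  # shared peak kept, singletons dropped
  expect_equal(df$start, 100)
  expect_equal(df$score, 2)  # support count
  expect_error(consensus_peaks(list(s1), min_support = 2), "min_support")
})

test_that("consensus_peaks agrees with the per-base support oracle and is
           order-invariant", {
  set.seed(7)
  for (rep in 1:10) {
    sets <- lapply(1:4, function(i) random_peakset(15, sample_id = paste0("s", i)))
    cons <- consensus_peaks(sets, min_support = 2)
    # oracle: merged blocks from per-base union; block support = number of
    # sets covering any base of the block
    for (ch in c("chrA", "chrB")) {
      covers <- lapply(sets, oracle_base_cover, chrom = ch, limit = 600)
      un <- Reduce(`|`, covers)
      r <- rle(un)
      ends <- cumsum(r$lengths); starts <- c(0, ends[-length(ends)])
      blocks <- data.frame(start = starts[r$values], end = ends[r$values])
      support <- vapply(seq_len(nrow(blocks)), function(k) {
        idx <- (blocks$start[k] + 1):blocks$end[k]
        sum(vapply(covers, function(cv) any(cv[idx]), logical(1)))
      }, numeric(1))
      want <- blocks[support >= 2, , drop = FALSE]
      got <- as.data.frame(cons)
      got <- got[got$chrom == ch, , drop = FALSE]
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$score, support[support >= 2])
    }
    perm <- sample(4)
    cons2 <- consensus_peaks(sets[perm], min_support = 2)
    expect_equal(as.data.frame(cons2)[, c("chrom", "start", "end", "score")],
                 as.data.frame(cons)[, c("chrom", "start", "end", "score")])
  }
})

test_that("peak_center floors odd spans", {
  expect_equal(peak_center(peak_set("c", 10, 20)), 15)
  expect_equal(peak_center(peak_set("c", 10, 21)), 15)
  expect_equal(peak_center(peak_set("c", 0, 2)), 1)
})

test_that("annotate_context applies promoter > exon > intron > intergenic", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start = 10000,
                      end = 20000, strand = "+")
  exons <- data.frame(gene_id = "g1", chrom = "chr1",
                      start = c(10000, 15000), end = c(11000, 16000))
  gm <- gene_model(genes, exons)
  pk <- peak_set(rep("chr1", 4), c(9400, 13000, 15400, 50000),
                 c(9600, 13200, 15600, 50200))
  expect_equal(annotate_context(pk, gm),
               c("promoter", "intron", "exon", "intergenic"))
  # empty gene model warns, classifies all intergenic
  gm0 <- gene_model(genes[0, ], exons[0, ])
  expect_warning(ctx <- annotate_context(pk, gm0), "empty gene model")
  expect_true(all(ctx == "intergenic"))
})

test_that("gene model round-trips through minimal GFF3", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t10001\t20000\t.\t+\t.\tID=g1",
    "chr1\tsrc\texon\t10001\t11000\t.\t+\t.\tParent=g1"), f)
  gm <- read_gene_model(f)
  expect_equal(gm$genes$start, 10000)  # converted to 0-based
  expect_equal(gm$genes$end, 20000)
  expect_equal(gm$genes$tss, 10000)
  expect_equal(gm$exons$start, 10000)
})
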