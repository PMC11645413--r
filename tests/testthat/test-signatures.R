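toy_expr <- function() {
  set.seed(100)
  v <- matrix(rnorm(50 * 8, 8, 1), 50, 8,
              dimnames = list(sprintf("gene_%04d", 1:50),
                              sprintf("s%d", 1:8)))
  expression_matrix(v, groups = rep(c("control", "treated"), each = 4))
}

test_that("surrogate_de computes Welch t with BH adjustment", {
  ex <- toy_expr()
  de <- surrogate_de(ex, "control", "treated")
  expect_setequal(names(de), c("gene", "log2fc", "p", "padj"))
  expect_true(all(de$p >= 0 & de$p <= 1))
  expect_true(all(de$padj >= de$p - 1e-12))
  # BH monotone in p-rank
  expect_true(all(diff(de$padj[order(de$p)]) >= -1e-12))
  # identical groups: log2FC identically zero
  v <- matrix(rep(rnorm(20), 4), 20, 4,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:4)))
  ex2 <- expression_matrix(v, groups = rep(c("a", "b"), each = 2))
  de2 <- surrogate_de(ex2, "a", "b")
  expect_true(all(de2$log2fc == 0))
  expect_true(all(de2$p == 1))
  expect_error(surrogate_de(ex, "control", "nope"), "2 samples")
})

test_that("null simulation holds the type-I error near 5%", {
  set.seed(55)
  hits <- 0; total <- 0
  for (r in 1:5) {
    sim <- make_expression_cohort(300, 12, character(), character(),
                                  rep(c("control", "treated"), each = 6),
                                  effect = 0, seed = 1000 + r)
    de <- surrogate_de(sim$expr, "control", "treated")
    hits <- hits + sum(de$p < 0.05); total <- total + nrow(de)
  }
  ci <- qbinom(c(0.0025, 0.9975), total, 0.05) / total
  expect_gte(hits / total, ci[1])
  expect_lte(hits / total, ci[2])
})

test_that("derive_signature applies both thresholds", {
  de <- data.frame(gene = c("a", "b", "c", "d"),
                   log2fc = c(2, -3, 5, 0.5),
                   p = c(0.001, 0.001, 0.15, 0.001),
                   padj = c(0.01, 0.01, 0.2, 0.01))
  sig <- derive_signature(de, name = "s")
  expect_equal(sig$up, "a")     # padj 0.2 excludes c despite log2fc 5
  expect_equal(sig$down, "b")   # |log2fc| 0.5 excludes d
  expect_error(derive_signature(de, lfc_cut = 10), "no gene")
})

test_that("planted large-effect cohort gives exact signature recovery", {
  genes <- sprintf("gene_%04d", 1:400)
  up <- genes[1:10]; down <- genes[11:20]
  sim <- make_expression_cohort(400, 12, up, down,
                                rep(c("control", "treated"), each = 6),
                                effect = 4, noise_sd = 0.5, seed = 77)
  de <- surrogate_de(sim$expr, "control", "treated")
  sig <- derive_signature(de, name = "planted")
  expect_setequal(sig$up, up)
  expect_setequal(sig$down, down)
  # treated mean score exceeds control mean by construction
  sc <- score_signature(sim$expr, sig)
  expect_gt(mean(sc[sim$expr$groups == "treated"]),
            mean(sc[sim$expr$groups == "control"]))
})

test_that("score_signature matches the hand-computed worked example and
           its invariances", {
  v <- matrix(c(1, 2, 3), 1, 3,
              dimnames = list("g1", c("s1", "s2", "s3")))
  ex <- expression_matrix(v)
  sig <- gene_signature("one_up", up = "g1")
  # z of (1,2,3) with sample sd (= 1) is (-1, 0, 1)
  expect_equal(unname(as.numeric(score_signature(ex, sig))), c(-1, 0, 1))
  # swapping up and down flips signs
  sigd <- gene_signature("one_dn", down = "g1")
  expect_equal(as.numeric(score_signature(ex, sigd)),
               -as.numeric(score_signature(ex, sig)))
  # per-gene affine change leaves scores unchanged
  v2 <- matrix(c(1, 2, 3, 4, 6, 8), 2, 3, byrow = TRUE,
               dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  ex2 <- expression_matrix(v2)
  sig2 <- gene_signature("two_up", up = c("g1", "g2"))
  v3 <- v2; v3["g2", ] <- v3["g2", ] * 10 + 100
  ex3 <- expression_matrix(v3)
  expect_equal(as.numeric(score_signature(ex2, sig2)),
               as.numeric(score_signature(ex3, sig2)))
  # absent genes are dropped with a message; all absent errors
  expect_message(score_signature(ex2, gene_signature("m", up = c("g1", "zz"))),
                 "dropped 1")
  expect_error(suppressMessages(
    score_signature(ex2, gene_signature("m", up = "zz"))), "no signature")
})

test_that("ora_fisher matches the hypergeometric enumeration oracle", {
  u <- sprintf("g%03d", 1:100)
  hits <- u[1:20]; path <- u[c(1:10, 21:30)]
  r <- ora_fisher(hits, path, u)
  expect_equal(r$table["in_pathway", "hit"], 10)
  expect_equal(r$p_value, oracle_fisher_two_sided(10, 10, 10, 70),
               tolerance = 1e-9)
  expect_equal(r$odds_ratio, 7)
  # independence: proportional table -> odds ratio 1
  r2 <- ora_fisher(u[1:50], u[seq(1, 100, 2)], u)
  expect_equal(r2$odds_ratio, 1)
  expect_error(ora_fisher(hits, path, character()), "empty")
  expect_error(ora_fisher("zz", path, u), "subsets")
})

test_that("quartile_stratify breaks at interpolated quartiles with ties
           going low", {
  q <- quartile_stratify(1:8)
  expect_equal(as.vector(table(q)), c(2, 2, 2, 2))
  expect_equal(as.character(q[1:2]), c("Q1", "Q1"))
  # monotone transform preserves labels
  expect_equal(quartile_stratify(exp(1:8)), q)
  # ties at a break go to the lower quartile
  x <- c(1, 2, 2, 3, 4, 5, 6, 7)
  qq <- quartile_stratify(x)
  expect_equal(sum(qq == "Q1"), 3)
  expect_error(quartile_stratify(rep(1, 8)), "all scores equal")
  expect_error(quartile_stratify(1:3), "4 samples")
})

test_that("GMT round trip preserves signatures", {
  sigs <- list(gene_signature("sigA", up = c("a", "b"), down = "c"),
               gene_signature("sigB", up = "d"))
  f <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sigs, f)
  back <- read_gmt(f)
  expect_equal(back$sigA$up, c("a", "b"))
  expect_equal(back$sigA$down, "c")
  expect_equal(back$sigB$up, "d")
})
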