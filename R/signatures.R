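#' Construct an expression matrix with group metadata
#'
#' @param values Numeric matrix, genes x samples, log2-scale expression.
#' @param groups Character vector of group labels, one per sample.
#' @return Object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, groups = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("values must have unique gene-id rownames")
  if (any(!is.finite(values))) stop("expression values must be finite")
  if (!is.null(groups) && length(groups) != ncol(values))
    stop("one group label per sample required")
  structure(list(values = values, groups = groups),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Surrogate differential expression (Welch t-test per gene)
#'
#' An explicit, simple stand-in for a full DE engine, used to exercise
#' signature derivation on synthetic cohorts: per-gene Welch t-test on log2
#' values with log2FC = mean(B) - mean(A) and Benjamini-Hochberg adjustment.
#' It is not a replacement for count-based DE models on real data.
#'
#' @param expr An `ExpressionMatrix`.
#' @param group_a,group_b Group labels present in `expr$groups`, each with
#'   >= 2 samples.
#' @return data.frame with `gene`, `log2fc`, `p`, `padj`, sorted by `p`.
#' @export
surrogate_de <- function(expr, group_a, group_b) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  ia <- which(expr$groups == group_a)
  ib <- which(expr$groups == group_b)
  if (length(ia) < 2 || length(ib) < 2)
    stop("each group needs at least 2 samples")
  A <- expr$values[, ia, drop = FALSE]
  B <- expr$values[, ib, drop = FALSE]
  na <- ncol(A); nb <- ncol(B)
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- apply(A, 1, stats::var); vb <- apply(B, 1, stats::var)
  se2 <- va / na + vb / nb
  tstat <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  # zero-variance genes with zero difference are null, not significant
  p[!is.finite(tstat)] <- 1
  p[se2 == 0 & mb == ma] <- 1
  out <- data.frame(gene = rownames(expr$values), log2fc = mb - ma,
                    p = p, padj = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  out
}

#' Derive an up/down gene signature from a DE table
#'
#' Up-genes satisfy `padj <= padj_cut` and `log2fc >= lfc_cut`; down-genes
#' `padj <= padj_cut` and `log2fc <= -lfc_cut`.
#'
#' @param de data.frame with `gene`, `log2fc`, `padj`.
#' @param lfc_cut Absolute log2 fold-change threshold (default 1).
#' @param padj_cut Adjusted-p threshold (default 0.05).
#' @param name Signature name.
#' @return Object of class `GeneSignature` with `name`, `up`, `down`.
#' @export
derive_signature <- function(de, lfc_cut = 1.0, padj_cut = 0.05,
                             name = "signature") {
  up <- de$gene[de$padj <= padj_cut & de$log2fc >= lfc_cut]
  down <- de$gene[de$padj <= padj_cut & de$log2fc <= -lfc_cut]
  if (length(up) == 0 && length(down) == 0)
    stop("no gene passed the thresholds; relax lfc_cut/padj_cut")
  gene_signature(name, up, down)
}

#' Construct a gene signature
#' @param name Signature name.
#' @param up,down Character vectors of gene ids; must be disjoint and not
#'   both empty.
#' @return Object of class `GeneSignature`.
#' @export
gene_signature <- function(name, up = character(), down = character()) {
  if (length(intersect(up, down)) > 0)
    stop("up and down gene sets must be disjoint")
  if (length(up) == 0 && length(down) == 0)
    stop("a signature needs at least one gene")
  structure(list(name = name, up = unique(up), down = unique(down)),
            class = "GeneSignature")
}

#' @export
print.GeneSignature <- function(x, ...) {
  cat(sprintf("GeneSignature '%s': %d up, %d down\n", x$name,
              length(x$up), length(x$down)))
  invisible(x)
}

#' Score samples with a gene signature
#'
#' Implements `score = sum(z over up-genes) - sum(z over down-genes)` where
#' z-scores are computed per gene across the scored cohort's samples using
#' the sample standard deviation (n - 1 divisor). Genes absent from the
#' matrix or with zero variance are dropped (count reported via message).
#'
#' @param expr An `ExpressionMatrix` with >= 3 samples.
#' @param signature A `GeneSignature`.
#' @return Named numeric vector of per-sample scores (class
#'   `SignatureScores` attributes record signature name and dropped genes).
#' @export
score_signature <- function(expr, signature) {
  stopifnot(inherits(expr, "ExpressionMatrix"),
            inherits(signature, "GeneSignature"))
  if (ncol(expr$values) < 3) stop("need >= 3 samples to compute z-scores")
  pick <- function(gs) gs[gs %in% rownames(expr$values)]
  up <- pick(signature$up); down <- pick(signature$down)
  dropped <- length(signature$up) + length(signature$down) -
    length(up) - length(down)
  zrow <- function(g) {
    v <- expr$values[g, ]
    s <- stats::sd(v)
    if (s == 0) return(NULL)
    (v - mean(v)) / s
  }
  zsum <- function(gs) {
    rows <- Filter(Negate(is.null), lapply(gs, zrow))
    dropped <<- dropped + length(gs) - length(rows)
    if (length(rows) == 0) return(rep(0, ncol(expr$values)))
    Reduce(`+`, rows)
  }
  if (length(up) == 0 && length(down) == 0)
    stop("no signature gene present in the expression matrix")
  score <- zsum(up) - zsum(down)
  if (dropped > 0)
    message(sprintf("score_signature: dropped %d absent/zero-variance gene(s)",
                    dropped))
  names(score) <- colnames(expr$values)
  attr(score, "signature") <- signature$name
  attr(score, "dropped") <- dropped
  score
}

#' Over-representation test (Fisher's exact)
#'
#' Tests whether DE hits are enriched in a pathway relative to a gene
#' universe via the 2x2 table (hit/non-hit x in/out pathway).
#'
#' @param hits Character vector of hit genes (subset of `universe`).
#' @param pathway Character vector of pathway genes (subset of `universe`).
#' @param universe Character vector of all considered genes.
#' @return List with `table`, `odds_ratio` (sample OR), `p_value`
#'   (two-sided Fisher).
#' @export
ora_fisher <- function(hits, pathway, universe) {
  if (length(universe) == 0) stop("empty universe")
  if (!all(hits %in% universe) || !all(pathway %in% universe))
    stop("hits and pathway must be subsets of the universe")
  inh <- universe %in% hits
  inp <- universe %in% pathway
  a <- sum(inh & inp); b <- sum(inh & !inp)
  c <- sum(!inh & inp); d <- sum(!inh & !inp)
  tab <- matrix(c(a, b, c, d), 2, 2,
                dimnames = list(c("in_pathway", "out"), c("hit", "non_hit")))
  p <- stats::fisher.test(matrix(c(a, b, c, d), 2, 2))$p.value
  list(table = tab, odds_ratio = (a * d) / (b * c), p_value = p)
}

#' Quartile stratification of signature scores
#'
#' Breaks at the 25th/50th/75th percentiles (linear-interpolation
#' quantiles); values tied with a break go to the lower quartile. Q1 is the
#' lowest-score group.
#'
#' @param scores Numeric vector, length >= 4, not all equal.
#' @return Factor with levels `Q1` < `Q2` < `Q3` < `Q4`.
#' @export
quartile_stratify <- function(scores) {
  if (length(scores) < 4) stop("need >= 4 samples to stratify")
  if (length(unique(scores)) == 1)
    stop("all scores equal: no stratification possible")
  qs <- stats::quantile(scores, c(0.25, 0.5, 0.75), type = 7)
  cut(scores, breaks = c(-Inf, qs, Inf), labels = paste0("Q", 1:4),
      right = TRUE, ordered_result = TRUE)
}

#' Write signatures as GMT (two rows per signature: NAME_UP, NAME_DN)
#' @param signatures List of `GeneSignature` objects.
#' @param path Output GMT path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(signatures, path) {
  lines <- unlist(lapply(signatures, function(s) {
    c(paste(c(paste0(s$name, "_UP"), "na", s$up), collapse = "\t"),
      paste(c(paste0(s$name, "_DN"), "na", s$down), collapse = "\t"))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GMT file into gene signatures
#'
#' Rows named `X_UP` / `X_DN` are paired into one signature `X`; other rows
#' become up-only signatures.
#'
#' @param path GMT path.
#' @return Named list of `GeneSignature` objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  f <- strsplit(lines, "\t")
  nm <- vapply(f, `[`, "", 1)
  genes <- lapply(f, function(x) x[-(1:2)])
  base <- sub("_(UP|DN)$", "", nm)
  out <- list()
  for (bn in unique(base)) {
    iu <- which(nm == paste0(bn, "_UP"))
    id <- which(nm == paste0(bn, "_DN"))
    if (length(iu) || length(id)) {
      out[[bn]] <- gene_signature(bn,
        up = if (length(iu)) genes[[iu[1]]] else character(),
        down = if (length(id)) genes[[id[1]]] else character())
    } else {
      i <- which(base == bn)[1]
      out[[bn]] <- gene_signature(bn, up = genes[[i]])
    }
  }
  out
}
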