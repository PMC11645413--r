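#' Construct a position weight matrix
#'
#' The PWM is the probabilistic model of a DNA motif (here, canonically, the
#' full-site androgen response element). Scanning scores windows by the
#' log-odds sum `sum(log2(p_base / bg_base))` in bits.
#'
#' @param probs Numeric matrix, L rows (positions) by 4 columns (A, C, G, T);
#'   each row must sum to 1 within 1e-9. L must be >= 4.
#' @param background Background base probabilities (A, C, G, T), summing
#'   to 1. Default uniform.
#' @param pseudocount Pseudocount used when the matrix was derived from
#'   counts (stored for provenance).
#' @param name Motif name.
#' @param fpr Per-position false-positive rate used to calibrate the default
#'   scan threshold under the background model (default 1e-4).
#' @return An object of class `PositionWeightMatrix` with elements `probs`,
#'   `background`, `lom` (log-odds matrix, bits), `default_threshold`.
#' @export
pwm <- function(probs, background = rep(0.25, 4), pseudocount = 0,
                name = "motif", fpr = 1e-4) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 4) stop("probs must have 4 columns (A, C, G, T)")
  if (nrow(probs) < 4) stop("motif length must be >= 4")
  if (any(probs < 0)) stop("probabilities must be non-negative")
  if (any(abs(rowSums(probs) - 1) > 1e-9))
    stop("each PWM row must sum to 1")
  if (abs(sum(background) - 1) > 1e-9) stop("background must sum to 1")
  colnames(probs) <- c("A", "C", "G", "T")
  # clamp zeros so indicator matrices get large negative (finite) penalties
  lom <- log2(pmax(probs, 1e-9) / rep(background, each = nrow(probs)))
  obj <- structure(list(name = name, probs = probs, background = background,
                        pseudocount = pseudocount, lom = lom),
                   class = "PositionWeightMatrix")
  obj$default_threshold <- score_threshold(obj, fpr = fpr)
  obj
}

#' @export
print.PositionWeightMatrix <- function(x, ...) {
  cat(sprintf("PositionWeightMatrix '%s': length %d, default threshold %.3f bits\n",
              x$name, nrow(x$probs), x$default_threshold))
  invisible(x)
}

#' Motif length
#' @param x A `PositionWeightMatrix`.
#' @return Integer motif length L.
#' @export
pwm_length <- function(x) nrow(x$probs)

#' Consensus sequence (highest-probability base per position)
#' @param x A `PositionWeightMatrix`.
#' @return Character string of length L.
#' @export
pwm_consensus <- function(x) {
  paste(colnames(x$probs)[max.col(x$probs, ties.method = "first")],
        collapse = "")
}

#' Reverse complement of a PWM
#' @param x A `PositionWeightMatrix`.
#' @return A `PositionWeightMatrix` modelling the opposite strand.
#' @export
pwm_revcomp <- function(x) {
  p <- x$probs[rev(seq_len(nrow(x$probs))), c("T", "G", "C", "A"),
               drop = FALSE]
  colnames(p) <- c("A", "C", "G", "T")
  bg <- x$background[c(4, 3, 2, 1)]
  pwm(p, background = bg, pseudocount = x$pseudocount,
      name = paste0(x$name, "_rc"))
}

#' Load a JASPAR-style position frequency matrix
#'
#' Accepts the JASPAR PFM layout: an optional `>name` header followed by four
#' rows (A, C, G, T), each either `A [ 1 2 3 ]` or plain whitespace-separated
#' counts. Counts are converted to probabilities with a pseudocount.
#'
#' @param path PFM file.
#' @param pseudocount Added to every count before normalization
#'   (default 0.25).
#' @param background Background base probabilities.
#' @return A `PositionWeightMatrix`.
#' @export
load_motif <- function(path, pseudocount = 0.25,
                       background = rep(0.25, 4)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  name <- "motif"
  if (grepl("^>", lines[1])) {
    name <- sub("^>\\s*", "", strsplit(lines[1], "[ \t]+")[[1]][1])
    name <- sub("^>", "", name)
    lines <- lines[-1]
  }
  if (length(lines) != 4) stop("expected 4 count rows (A, C, G, T)")
  parse_row <- function(s) {
    s <- gsub("^[ACGTacgt]\\s*", "", s)
    s <- gsub("[\\[\\]]", " ", s, perl = TRUE)
    v <- suppressWarnings(as.numeric(strsplit(trimws(s), "\\s+")[[1]]))
    if (any(is.na(v))) stop("non-numeric count in PFM")
    v
  }
  rows <- lapply(lines, parse_row)
  if (length(unique(lengths(rows))) != 1) stop("ragged PFM: unequal row lengths")
  counts <- do.call(rbind, rows)  # 4 x L
  if (any(counts < 0)) stop("negative count in PFM")
  counts <- counts + pseudocount
  probs <- t(counts) / colSums(counts)  # L x 4
  pwm(probs, background = background, pseudocount = pseudocount,
      name = name)
}

# Score every offset of an integer-coded sequence against a log-odds matrix.
# Returns numeric vector of length n - L + 1; windows containing N
# (NA codes) score -Inf.
.scan_scores <- function(lom, x) {
  L <- nrow(lom)
  n <- length(x) - L + 1
  if (n < 1) return(numeric(0))
  s <- numeric(n)
  bad <- logical(n)
  idx0 <- seq_len(n)
  for (j in seq_len(L)) {
    b <- x[idx0 + j - 1]
    miss <- is.na(b)
    bad <- bad | miss
    b[miss] <- 1L
    s <- s + lom[j, b]
  }
  s[bad] <- -Inf
  s
}

#' Scan a sequence for motif hits on both strands
#'
#' Every offset is scored on the forward strand with the PWM and on the
#' reverse strand with its reverse complement; offsets reaching `threshold`
#' are reported. When both strands hit at the same offset, only the
#' higher-scoring strand is kept (ties break to `+`). Windows containing `N`
#' score `-Inf`.
#'
#' @param pwm A `PositionWeightMatrix`.
#' @param sequence DNA string over A, C, G, T, N.
#' @param threshold Minimum log-odds score in bits; `NULL` uses the PWM's
#'   calibrated default.
#' @return data.frame with columns `position` (0-based hit start), `strand`,
#'   `score`. A sequence shorter than the motif yields zero rows.
#' @export
scan_motif <- function(pwm, sequence, threshold = NULL) {
  stopifnot(inherits(pwm, "PositionWeightMatrix"))
  if (is.null(threshold)) threshold <- pwm$default_threshold
  x <- .seq_to_int(sequence)
  fw <- .scan_scores(pwm$lom, x)
  if (length(fw) == 0)
    return(data.frame(position = integer(), strand = character(),
                      score = numeric()))
  # reverse-strand score at offset i equals the forward score of the
  # window's reverse complement: lom_rc[j, b] = lom[L+1-j, comp(b)]
  L <- nrow(pwm$lom)
  lom_rc <- pwm$lom[rev(seq_len(L)), c(4, 3, 2, 1), drop = FALSE]
  rv <- .scan_scores(lom_rc, x)
  pos <- seq_along(fw) - 1L
  hit_f <- fw >= threshold
  hit_r <- rv >= threshold
  both <- hit_f & hit_r
  # dedup same-offset double hits: keep higher score, tie -> '+'
  keep_f <- hit_f & (!hit_r | rv <= fw)
  keep_r <- hit_r & (!hit_f | rv > fw)
  out <- rbind(
    data.frame(position = pos[keep_f], strand = rep("+", sum(keep_f)),
               score = fw[keep_f]),
    data.frame(position = pos[keep_r], strand = rep("-", sum(keep_r)),
               score = rv[keep_r]))
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Calibrate a log-odds threshold from a target false-positive rate
#'
#' Computes the distribution of the forward-strand score of a random
#' background window by dynamic programming over positions (scores
#' discretized to 0.001 bits) and returns the smallest score whose
#' exceedance probability is at most `fpr`.
#'
#' @param pwm A `PositionWeightMatrix`.
#' @param fpr Target per-position false-positive rate (default 1e-4).
#' @param granularity Score discretization in bits (default 0.001).
#' @return Threshold in bits.
#' @export
score_threshold <- function(pwm, fpr = 1e-4, granularity = 0.001) {
  lom <- pwm$lom
  bg <- pwm$background
  # integer score grid; clamp huge negatives (from clamped zero probs) so
  # the grid stays bounded -- anything below -50 bits never reaches a
  # realistic threshold anyway. Per-position scores round UP so the grid
  # distribution stochastically dominates the true one and the returned
  # threshold is a guaranteed FPR bound.
  q <- ceiling(pmax(lom, -50) / granularity)
  dist <- 1; dmin <- 0  # dist[i] = P(score units == dmin + i - 1)
  for (j in seq_len(nrow(q))) {
    vals <- q[j, ]
    ndmin <- dmin + min(vals)
    ndmax <- dmin + length(dist) - 1 + max(vals)
    nd <- numeric(ndmax - ndmin + 1)
    for (b in 1:4) {
      at <- (dmin + vals[b]) - ndmin + 1
      idx <- at:(at + length(dist) - 1)
      nd[idx] <- nd[idx] + dist * bg[b]
    }
    dist <- nd; dmin <- ndmin
  }
  tail_p <- rev(cumsum(rev(dist)))
  ok <- which(tail_p <= fpr)
  if (length(ok) == 0) return((dmin + length(dist)) * granularity)
  (dmin + ok[1] - 1) * granularity
}
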