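# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's vectorized code paths: plain loops, per-base sets,
# direct probability sums.

# The bundled canonical-ARE stand-in PFM, loaded once.
are_pwm <- load_motif(system.file("extdata", "ARE_synthetic.pfm",
                                  package = "cistromere"))

# ---- motif scanning ---------------------------------------------------------

# Score one window (character vector of bases) against a PWM, forward only.
oracle_window_score <- function(p, win) {
  bases <- c("A", "C", "G", "T")
  s <- 0
  for (j in seq_along(win)) {
    b <- match(win[j], bases)
    if (is.na(b)) return(-Inf)
    s <- s + log2(max(p$probs[j, b], 1e-9) / p$background[b])
  }
  s
}

# All-offset, both-strand exhaustive scanner; same dedup rule as the
# implementation contract:
# same-offset double hits keep the higher score, ties -> '+'.
oracle_scan <- function(p, sequence, threshold) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  bases <- strsplit(toupper(sequence), NULL)[[1]]
  L <- nrow(p$probs)
  out <- list()
  if (length(bases) < L) {
    return(data.frame(position = integer(), strand = character(),
                      score = numeric()))
  }
  for (i in seq_len(length(bases) - L + 1)) {
    win <- bases[i:(i + L - 1)]
    fs <- oracle_window_score(p, win)
    rs <- oracle_window_score(p, rev(unname(comp[win])))
    hf <- fs >= threshold; hr <- rs >= threshold
    if (hf && hr) {
      if (rs > fs) hf <- FALSE else hr <- FALSE
    }
    if (hf) out[[length(out) + 1]] <-
        data.frame(position = i - 1L, strand = "+", score = fs)
    if (hr) out[[length(out) + 1]] <-
        data.frame(position = i - 1L, strand = "-", score = rs)
  }
  if (length(out) == 0) {
    return(data.frame(position = integer(), strand = character(),
                      score = numeric()))
  }
  do.call(rbind, out)
}

# ---- interval algebra -------------------------------------------------------

# Per-base coverage of a PeakSet's intervals on one chromosome as a logical
# vector over [0, limit).
oracle_base_cover <- function(ps, chrom, limit) {
  v <- logical(limit)
  df <- as.data.frame(ps)
  df <- df[df$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(df))) {
    v[(df$start[i] + 1):df$end[i]] <- TRUE
  }
  v
}

# Random small PeakSet on given chromosomes within [0, space).
random_peakset <- function(n, chroms = c("chrA", "chrB"), space = 500,
                           max_width = 30, sample_id = "r") {
  ch <- sample(chroms, n, replace = TRUE)
  st <- sample.int(space - max_width, n, replace = TRUE) - 1
  w <- sample.int(max_width, n, replace = TRUE)
  peak_set(ch, st, st + w, sample_id = sample_id)
}

# ---- hypergeometric ---------------------------------------------------------

# Two-sided Fisher p for table (a, b, c, d) by enumeration over the support:
# sum the probabilities of all tables (fixed margins) no more likely than
# the observed one.
oracle_fisher_two_sided <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  pobs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# One-sided (enrichment) p: explicit sum over x >= a.
oracle_hyper_upper <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  hi <- min(k, m)
  if (a > hi) return(0)
  sum(stats::dhyper(a:hi, m, n, k))
}

# ---- survival ---------------------------------------------------------------

# Hungarian-free label matching for 2-state models: best of the two
# permutations.
match_two_state <- function(estimate, truth) {
  d1 <- max(abs(estimate - truth))
  d2 <- max(abs(estimate[2:1, , drop = FALSE] - truth))
  if (d1 <= d2) list(perm = 1:2, err = d1) else list(perm = 2:1, err = d2)
}
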