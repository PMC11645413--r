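#' Does each peak contain a motif near its center?
#'
#' A peak is motif-positive when scanning the `window`-bp sequence centered
#' on the peak center (total width; clipped at chromosome edges) yields at
#' least one hit at or above the threshold. The 100 bp default reflects the
#' convention of calling ARE presence within a 100 bp window of the AR peak
#' center.
#'
#' @param peaks A `PeakSet`.
#' @param genome A `genome` (named character vector, see [read_genome()]).
#' @param pwm A `PositionWeightMatrix`.
#' @param window Total window width in bp (default 100).
#' @param threshold Log-odds threshold in bits; `NULL` uses the PWM default.
#' @return Logical vector over peaks.
#' @export
peak_has_motif <- function(peaks, genome, pwm, window = 100,
                           threshold = NULL) {
  stopifnot(inherits(peaks, "PeakSet"))
  ctr <- peak_center(peaks)
  ch <- peaks$intervals$chrom
  half <- window / 2
  vapply(seq_along(ctr), function(i) {
    w <- .get_window(genome, ch[i], ctr[i] - half, ctr[i] + half)
    nrow(scan_motif(pwm, w$seq, threshold = threshold)) > 0
  }, logical(1))
}

#' Fraction of peaks containing a motif
#'
#' The headline cistrome statistic: the proportion of peaks whose central
#' window contains at least one motif hit.
#'
#' @inheritParams peak_has_motif
#' @return Fraction between 0 and 1.
#' @export
fraction_with_motif <- function(peaks, genome, pwm, window = 100,
                                threshold = NULL) {
  if (n_peaks(peaks) == 0) stop("empty peak set")
  mean(peak_has_motif(peaks, genome, pwm, window, threshold))
}

#' Compare motif fractions between two groups of peak sets
#'
#' Unpaired comparisons use the Mann-Whitney U test; paired comparisons
#' (e.g. matched tumor/normal samples from the same patients) use the
#' Wilcoxon signed-rank test on within-pair differences with zero
#' differences dropped. Exact enumeration is used when the total sample size
#' is at most 25 and there are no ties; otherwise the normal approximation
#' with tie correction. All-zero paired differences return p = 1 by
#' convention.
#'
#' @param group_a,group_b Numeric vectors of per-sample fractions.
#' @param paired Logical; requires equal lengths when `TRUE`.
#' @return List with `statistic`, `p_value`, `method`.
#' @export
compare_fractions <- function(group_a, group_b, paired = FALSE) {
  if (paired && length(group_a) != length(group_b))
    stop("paired comparison requires equal group lengths")
  if (paired) {
    d <- group_a - group_b
    d <- d[d != 0]
    if (length(d) == 0)
      return(list(statistic = 0, p_value = 1,
                  method = "Wilcoxon signed-rank (all differences zero)"))
    v <- sum(rank(abs(d))[d > 0])
    if (length(d) <= 25) {
      p <- .signed_rank_exact_p(d)
    } else {
      p <- suppressWarnings(
        stats::wilcox.test(d, exact = FALSE, correct = FALSE)$p.value)
    }
    list(statistic = v, p_value = p,
         method = "Wilcoxon signed-rank, two-sided")
  } else {
    n <- length(group_a) + length(group_b)
    exact <- n <= 25 && !anyDuplicated(c(group_a, group_b))
    ht <- suppressWarnings(
      stats::wilcox.test(group_a, group_b, exact = exact,
                         correct = !exact))
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         method = "Mann-Whitney U, two-sided")
  }
}

#' Motif density profile around peak centers
#'
#' Counts motif hits in a window (default 2,400 bp total) around each peak
#' center, binned by hit-start offset (default 10 bp bins), and normalizes
#' to hits per bp per peak ("frequency/bp/peak").
#'
#' @inheritParams peak_has_motif
#' @param window Total profile width in bp (default 2400).
#' @param bin Bin width in bp (default 10); must divide `window`.
#' @return Object of class `DensityProfile`: list with `values` (per-bin
#'   density), `offsets` (bin-start offsets relative to center), `window`,
#'   `bin`, `n_peaks`.
#' @export
motif_density_profile <- function(peaks, genome, pwm, window = 2400,
                                  bin = 10, threshold = NULL) {
  if (n_peaks(peaks) == 0) stop("empty peak set")
  if (window %% bin != 0) stop("bin must divide window")
  nb <- window / bin
  half <- window / 2
  L <- pwm_length(pwm)
  counts <- numeric(nb)
  ctr <- peak_center(peaks)
  ch <- peaks$intervals$chrom
  for (i in seq_along(ctr)) {
    # extend right by L-1 so hits *starting* in the last bin are scorable
    w <- .get_window(genome, ch[i], ctr[i] - half, ctr[i] + half + L - 1)
    hits <- scan_motif(pwm, w$seq, threshold = threshold)
    if (nrow(hits) == 0) next
    off <- hits$position + w$start - ctr[i]  # offset of hit start vs center
    off <- off[off >= -half & off < half]
    if (length(off) == 0) next
    bidx <- floor((off + half) / bin) + 1
    tab <- table(bidx)
    counts[as.integer(names(tab))] <- counts[as.integer(names(tab))] + tab
  }
  structure(list(values = counts / (bin * length(ctr)),
                 offsets = seq(-half, half - bin, by = bin),
                 window = window, bin = bin, n_peaks = length(ctr)),
            class = "DensityProfile")
}

#' @export
print.DensityProfile <- function(x, ...) {
  cat(sprintf("DensityProfile: %d bins of %d bp over %d bp, %d peaks\n",
              length(x$values), x$bin, x$window, x$n_peaks))
  invisible(x)
}

# Exact two-sided signed-rank p by enumeration over all 2^n sign vectors,
# computed with the shift algorithm on doubled midranks (handles ties).
.signed_rank_exact_p <- function(d) {
  r2 <- round(2 * rank(abs(d)))
  tot <- sum(r2)
  dist <- numeric(tot + 1)
  dist[1] <- 1
  for (w in r2) {
    nd <- dist
    nd[(w + 1):(tot + 1)] <- nd[(w + 1):(tot + 1)] + dist[1:(tot + 1 - w)]
    dist <- nd
  }
  dist <- dist / 2^length(r2)
  v2 <- sum(r2[d > 0])
  p_le <- sum(dist[seq_len(v2 + 1)])
  p_ge <- sum(dist[(v2 + 1):(tot + 1)])
  min(1, 2 * min(p_le, p_ge))
}

# Savitzky-Golay quadratic smoothing, window 5, applied circularly so the
# symmetric unit-sum kernel preserves the profile mean exactly.
.sg_smooth5 <- function(v) {
  k <- c(-3, 12, 17, 12, -3) / 35
  n <- length(v)
  if (n < 5) return(v)
  vp <- c(v[(n - 1):n], v, v[1:2])
  vapply(seq_len(n), function(i) sum(k * vp[i:(i + 4)]), numeric(1))
}

#' Differential motif density between two conditions
#'
#' Subtracts one density profile from another bin-by-bin; values above zero
#' indicate enrichment in `a`, below zero depletion. Optional second-degree
#' (Savitzky-Golay, 5-bin window) curve smoothing.
#'
#' @param a,b `DensityProfile` objects with identical window/bin geometry.
#' @param smooth Apply quadratic smoothing (default `FALSE`).
#' @return A signed `DensityProfile` (`n_peaks` = NA).
#' @export
differential_density <- function(a, b, smooth = FALSE) {
  stopifnot(inherits(a, "DensityProfile"), inherits(b, "DensityProfile"))
  if (a$window != b$window || a$bin != b$bin)
    stop("density profiles have mismatched window/bin geometry")
  v <- a$values - b$values
  if (smooth) v <- .sg_smooth5(v)
  structure(list(values = v, offsets = a$offsets, window = a$window,
                 bin = a$bin, n_peaks = NA_integer_,
                 smoothing = if (smooth) "savitzky-golay-2/5" else "none"),
            class = "DensityProfile")
}

#' Background-matched motif enrichment between peak sets
#'
#' Builds the 2x2 table of motif-positive/negative peak counts in a
#' foreground versus a background peak set and computes the one-sided
#' (enrichment) hypergeometric p-value along with the sample odds ratio. A
#' result is flagged significant when p <= 1e-20, the conventional cutoff
#' for background-matched motif enrichment.
#'
#' @param foreground,background Non-empty `PeakSet` objects.
#' @inheritParams peak_has_motif
#' @param p_cutoff Significance cutoff (default 1e-20).
#' @return List with `table` (2x2 counts), `odds_ratio`, `p_value`
#'   (one-sided), `significant`.
#' @export
motif_enrichment <- function(foreground, background, genome, pwm,
                             window = 100, threshold = NULL,
                             p_cutoff = 1e-20) {
  if (n_peaks(foreground) == 0 || n_peaks(background) == 0)
    stop("both peak sets must be non-empty")
  fg <- peak_has_motif(foreground, genome, pwm, window, threshold)
  bg <- peak_has_motif(background, genome, pwm, window, threshold)
  a <- sum(fg); b <- sum(!fg); c <- sum(bg); d <- sum(!bg)
  or <- (a * d) / (b * c)
  p <- stats::phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
  list(table = matrix(c(a, b, c, d), 2, 2,
                      dimnames = list(c("motif+", "motif-"),
                                      c("foreground", "background"))),
       odds_ratio = or, p_value = p, significant = p <= p_cutoff)
}
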