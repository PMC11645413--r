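#' Construct a binned signal track
#'
#' @param values Named list, one numeric vector per chromosome; element `k`
#'   is the value over `[(k-1)*bin_size, k*bin_size)`.
#' @param bin_size Bin resolution in bp (>= 1).
#' @param sample_id Sample identifier.
#' @param normalization `"raw"` or `"RPKM"`.
#' @return Object of class `SignalTrack`.
#' @export
signal_track <- function(values, bin_size, sample_id = NA_character_,
                         normalization = "raw") {
  if (bin_size < 1) stop("bin_size must be >= 1")
  if (!is.list(values)) stop("values must be a named list of numeric vectors")
  if (length(values) && is.null(names(values))) stop("values must be named")
  for (v in values) {
    if (any(!is.finite(v)) || any(v < 0))
      stop("track values must be finite and non-negative")
  }
  structure(list(values = values, bin_size = bin_size,
                 sample_id = sample_id, normalization = normalization),
            class = "SignalTrack")
}

#' @export
print.SignalTrack <- function(x, ...) {
  cat(sprintf("SignalTrack (%s, %d bp bins): %d chromosome(s)\n",
              x$normalization, x$bin_size, length(x$values)))
  invisible(x)
}

#' Read a bedGraph file onto a fixed bin grid
#'
#' Each record's value is distributed over the bins it covers; a bin's value
#' is the coverage-length-weighted mean with uncovered bases contributing 0.
#' Overlapping records are rejected.
#'
#' @param path bedGraph file (chrom, start, end, value).
#' @param bin_size Target bin resolution in bp.
#' @param sample_id Sample identifier for the track.
#' @return A `SignalTrack`.
#' @export
read_bedgraph <- function(path, bin_size, sample_id = NA_character_) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0)
    return(signal_track(stats::setNames(list(), character()), bin_size,
                        sample_id))
  f <- strsplit(lines, "[ \t]+")
  if (any(lengths(f) < 4)) stop("bedGraph requires 4 columns")
  d <- data.frame(chrom = vapply(f, `[`, "", 1),
                  start = as.numeric(vapply(f, `[`, "", 2)),
                  end = as.numeric(vapply(f, `[`, "", 3)),
                  value = as.numeric(vapply(f, `[`, "", 4)),
                  stringsAsFactors = FALSE)
  if (any(is.na(d$start) | is.na(d$end) | is.na(d$value)))
    stop("malformed bedGraph record")
  if (any(d$start < 0 | d$start >= d$end)) stop("invalid bedGraph interval")
  vals <- list()
  for (ch in unique(d$chrom)) {
    dd <- d[d$chrom == ch, ]
    dd <- dd[order(dd$start), ]
    if (nrow(dd) > 1 && any(dd$start[-1] < dd$end[-nrow(dd)]))
      stop(sprintf("overlapping bedGraph records on %s", ch))
    nbin <- ceiling(max(dd$end) / bin_size)
    acc <- numeric(nbin)
    for (i in seq_len(nrow(dd))) {
      b0 <- floor(dd$start[i] / bin_size)
      b1 <- ceiling(dd$end[i] / bin_size) - 1
      for (b in b0:b1) {
        ov <- min(dd$end[i], (b + 1) * bin_size) - max(dd$start[i],
                                                       b * bin_size)
        acc[b + 1] <- acc[b + 1] + dd$value[i] * ov
      }
    }
    vals[[ch]] <- acc / bin_size
  }
  signal_track(vals, bin_size, sample_id)
}

#' Write a SignalTrack as bedGraph
#'
#' Adjacent equal-valued bins are merged into runs; zero-valued runs are
#' retained so the round trip is exact on grid-aligned input.
#'
#' @param track A `SignalTrack`.
#' @param path Output path.
#' @param header_note Optional `#` comment line (records e.g. seeds).
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(track, path, header_note = NULL) {
  stopifnot(inherits(track, "SignalTrack"))
  out <- character(0)
  if (!is.null(header_note)) out <- paste0("# ", header_note)
  b <- track$bin_size
  for (ch in names(track$values)) {
    v <- track$values[[ch]]
    if (length(v) == 0) next
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- c(0, ends[-length(ends)])
    out <- c(out, sprintf("%s\t%d\t%d\t%g", ch, starts * b, ends * b,
                          r$values))
  }
  writeLines(out, path)
  invisible(path)
}

#' RPKM-normalize a raw count track
#'
#' value = count / ((bin_size/1000) * (total_mapped_reads/1e6)), i.e. reads
#' per kilobase per million mapped reads.
#'
#' @param track A raw-count `SignalTrack`.
#' @param total_mapped_reads Library size (> 0).
#' @return An RPKM-tagged `SignalTrack`.
#' @export
rpkm <- function(track, total_mapped_reads) {
  stopifnot(inherits(track, "SignalTrack"))
  if (total_mapped_reads <= 0) stop("total_mapped_reads must be > 0")
  denom <- (track$bin_size / 1000) * (total_mapped_reads / 1e6)
  signal_track(lapply(track$values, function(v) v / denom),
               track$bin_size, track$sample_id, normalization = "RPKM")
}

# Length-weighted mean of track signal over [s, e); parts of the range
# outside the track's covered extent are NA-excluded. Returns NA if the
# whole range is outside.
.track_mean <- function(track, chrom, s, e) {
  v <- track$values[[chrom]]
  if (is.null(v)) return(NA_real_)
  b <- track$bin_size
  chrom_end <- length(v) * b
  cs <- max(0, s); ce <- min(chrom_end, e)
  if (cs >= ce) return(NA_real_)
  b0 <- floor(cs / b); b1 <- ceiling(ce / b) - 1
  w <- pmin(ce, (b0:b1 + 1) * b) - pmax(cs, (b0:b1) * b)
  sum(v[(b0:b1) + 1] * w) / sum(w)
}

#' Signal matrix around peak anchors
#'
#' Rows are peaks, columns are position bins relative to the peak center.
#' Window parts beyond the chromosome (or track) extent are `NA`, not zero,
#' so edge peaks do not drag profiles toward zero.
#'
#' @param track A `SignalTrack`.
#' @param peaks A `PeakSet`; row order of the result matches the sorted
#'   peak order.
#' @param window Total window width in bp (default 4000).
#' @param bin Column bin width in bp (default 50); must divide `window`.
#' @return Object of class `SignalMatrix`: list with `matrix`, `offsets`,
#'   `window`, `bin`.
#' @export
signal_matrix <- function(track, peaks, window = 4000, bin = 50) {
  stopifnot(inherits(track, "SignalTrack"), inherits(peaks, "PeakSet"))
  if (window %% bin != 0) stop("bin must divide window")
  ctr <- peak_center(peaks)
  ch <- peaks$intervals$chrom
  if (!any(ch %in% names(track$values)))
    stop("no peak lies on any track chromosome")
  nb <- window / bin
  half <- window / 2
  m <- matrix(NA_real_, nrow = length(ctr), ncol = nb)
  for (i in seq_along(ctr)) {
    s0 <- ctr[i] - half
    for (j in seq_len(nb)) {
      m[i, j] <- .track_mean(track, ch[i], s0 + (j - 1) * bin, s0 + j * bin)
    }
  }
  structure(list(matrix = m, offsets = seq(-half, half - bin, by = bin),
                 window = window, bin = bin),
            class = "SignalMatrix")
}

#' Aggregate profile: per-bin mean across peaks
#' @param x A `SignalMatrix`.
#' @return Numeric vector of per-bin means (`NA` cells excluded).
#' @export
mean_profile <- function(x) {
  stopifnot(inherits(x, "SignalMatrix"))
  colMeans(x$matrix, na.rm = TRUE)
}

#' PCA of samples over mean signal at consensus regions
#'
#' Computes the mean signal of every track over every region, centers
#' region-wise, and returns principal-component coordinates per sample.
#' Component signs are fixed by making each component's largest-magnitude
#' region loading positive, so results are deterministic across platforms.
#'
#' @param tracks List of >= 2 `SignalTrack` objects.
#' @param regions A `PeakSet` with >= 2 regions.
#' @return List with `coordinates` (samples x components),
#'   `explained_variance` (fractions, non-increasing), `loadings`.
#' @export
sample_pca <- function(tracks, regions) {
  if (length(tracks) < 2) stop("need at least 2 tracks")
  if (n_peaks(regions) < 2) stop("need at least 2 regions")
  df <- regions$intervals
  M <- vapply(tracks, function(tr) {
    vapply(seq_len(nrow(df)), function(i) {
      v <- .track_mean(tr, df$chrom[i], df$start[i], df$end[i])
      if (is.na(v)) 0 else v
    }, numeric(1))
  }, numeric(nrow(df)))  # regions x samples
  X <- t(M)  # samples x regions
  X <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(X)
  # fix component signs deterministically
  for (k in seq_along(sv$d)) {
    j <- which.max(abs(sv$v[, k]))
    if (sv$v[j, k] < 0) {
      sv$v[, k] <- -sv$v[, k]
      sv$u[, k] <- -sv$u[, k]
    }
  }
  coords <- sv$u %*% diag(sv$d, nrow = length(sv$d))
  ids <- vapply(tracks, function(t) t$sample_id, "")
  rownames(coords) <- ids
  colnames(coords) <- paste0("PC", seq_len(ncol(coords)))
  ev <- sv$d^2 / max(sum(sv$d^2), .Machine$double.eps)
  list(coordinates = coords, explained_variance = ev, loadings = sv$v)
}
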