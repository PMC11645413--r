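#' Construct a PeakSet
#'
#' A `PeakSet` holds a sorted collection of genomic intervals (peaks) in
#' 0-based half-open BED convention, together with sample and condition
#' metadata. It is the unit of all cistrome statistics in this package.
#'
#' @param chrom Character vector of chromosome names (non-empty strings).
#' @param start Integer vector, 0-based inclusive start coordinates.
#' @param end Integer vector, exclusive end coordinates; must satisfy
#'   `start < end`.
#' @param name Optional peak names (default `"."`).
#' @param score Optional numeric scores (default 0).
#' @param strand Optional strand in `+`, `-`, `.` (default `"."`). Strand is
#'   carried through I/O but ignored by all overlap arithmetic: AR binding
#'   sites are unstranded.
#' @param sample_id Sample identifier string.
#' @param condition Free-form condition label (e.g. `"normal"`, `"tumor"`,
#'   `"Neutral"`, `"Repressive"`, `"Activating"`).
#' @return An object of class `PeakSet`. Intervals are sorted by
#'   `(chrom, start, end)`.
#' @examples
#' ps <- peak_set("chr1", c(100, 500), c(200, 700), sample_id = "s1")
#' n_peaks(ps)
#' @export
peak_set <- function(chrom, start, end, name = NULL, score = NULL,
                     strand = NULL, sample_id = NA_character_,
                     condition = NA_character_) {
  n <- length(start)
  if (length(chrom) == 1 && n > 1) chrom <- rep(chrom, n)
  if (length(chrom) != n || length(end) != n)
    stop("chrom, start, end must have equal length")
  start <- as.numeric(start); end <- as.numeric(end)
  if (n > 0) {
    if (any(is.na(start)) || any(is.na(end)) ||
        any(start != floor(start)) || any(end != floor(end)))
      stop("coordinates must be integers")
    bad <- which(start < 0 | start >= end | !nzchar(chrom))
    if (length(bad))
      stop(sprintf("invalid interval at row %d: %s:%s-%s",
                   bad[1], chrom[bad[1]], start[bad[1]], end[bad[1]]))
  }
  if (is.null(name)) name <- rep(".", n)
  if (is.null(score)) score <- rep(0, n)
  if (is.null(strand)) strand <- rep(".", n)
  if (n > 0 && !all(strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   name = as.character(name), score = as.numeric(score),
                   strand = as.character(strand), stringsAsFactors = FALSE)
  o <- order(df$chrom, df$start, df$end)
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  structure(list(sample_id = sample_id, condition = condition,
                 intervals = df),
            class = "PeakSet")
}

#' @export
print.PeakSet <- function(x, ...) {
  cat(sprintf("PeakSet: %d peaks | sample=%s condition=%s\n",
              nrow(x$intervals), x$sample_id, x$condition))
  if (nrow(x$intervals) > 0) print(utils::head(x$intervals, 5))
  invisible(x)
}

#' @export
as.data.frame.PeakSet <- function(x, ...) x$intervals

#' Number of peaks in a PeakSet
#' @param x A `PeakSet`.
#' @return Integer count of intervals.
#' @export
n_peaks <- function(x) {
  stopifnot(inherits(x, "PeakSet"))
  nrow(x$intervals)
}

#' Read a BED file into a PeakSet
#'
#' Accepts BED3 to BED6. Coordinates are 0-based half-open; any violating
#' line aborts with its line number.
#'
#' @param path Path to a (possibly empty) BED file.
#' @param sample_id,condition Metadata attached to the result.
#' @return A `PeakSet`, sorted.
#' @export
read_bed <- function(path, sample_id = NA_character_,
                     condition = NA_character_) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0)
    return(peak_set(character(), numeric(), numeric(),
                    sample_id = sample_id, condition = condition))
  fields <- strsplit(lines, "[ \t]+")
  ncols <- lengths(fields)
  if (any(ncols < 3)) stop(sprintf("line %d: fewer than 3 BED columns",
                                   which(ncols < 3)[1]))
  chrom <- vapply(fields, `[`, "", 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3)))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) |
               end != floor(end))
  if (length(bad)) stop(sprintf("line %d: non-integer coordinate", bad[1]))
  bad <- which(start < 0 | start >= end)
  if (length(bad))
    stop(sprintf("line %d: invalid interval (start >= end or negative)",
                 bad[1]))
  pick <- function(i, default) {
    v <- rep(default, length(fields))
    has <- ncols >= i
    v[has] <- vapply(fields[has], `[`, "", i)
    v
  }
  name <- pick(4, ".")
  score <- suppressWarnings(as.numeric(pick(5, "0")))
  score[is.na(score)] <- 0
  strand <- pick(6, ".")
  strand[!strand %in% c("+", "-", ".")] <- "."
  peak_set(chrom, start, end, name, score, strand,
           sample_id = sample_id, condition = condition)
}

#' Write a PeakSet as BED6
#' @param x A `PeakSet`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(x, path) {
  stopifnot(inherits(x, "PeakSet"))
  df <- x$intervals
  lines <- sprintf("%s\t%d\t%d\t%s\t%g\t%s", df$chrom, df$start, df$end,
                   df$name, df$score, df$strand)
  writeLines(lines, path)
  invisible(path)
}

# Split interval rows by chromosome into matrices of (start, end).
.by_chrom <- function(df) split(df[, c("start", "end")], df$chrom)

#' Which intervals of one set overlap any interval of another
#'
#' Overlap follows the cistrome-comparison convention: two peaks overlap
#' when they share at least `min_overlap` bases (>= 1 bp by default).
#'
#' @param a,b `PeakSet` objects.
#' @param min_overlap Minimum number of shared bases (>= 1).
#' @return Logical vector over the intervals of `a` (in their sorted order).
#' @export
overlaps_any <- function(a, b, min_overlap = 1) {
  stopifnot(inherits(a, "PeakSet"), inherits(b, "PeakSet"))
  if (min_overlap < 1) stop("min_overlap must be >= 1")
  da <- a$intervals; db <- b$intervals
  out <- logical(nrow(da))
  if (nrow(da) == 0 || nrow(db) == 0) return(out)
  bsplit <- .by_chrom(db)
  for (ch in unique(da$chrom)) {
    ia <- which(da$chrom == ch)
    bb <- bsplit[[ch]]
    if (is.null(bb)) next
    # overlap width of [s1,e1) and [s2,e2) is min(e1,e2) - max(s1,s2)
    for (i in ia) {
      w <- pmin(da$end[i], bb$end) - pmax(da$start[i], bb$start)
      if (any(w >= min_overlap)) out[i] <- TRUE
    }
  }
  out
}

# Merge sorted intervals (matrix-style data.frame with start/end) into
# maximal non-overlapping blocks; touching blocks ([0,5) + [5,9)) merge only
# if merge_touching.
.merge_runs <- function(start, end, merge_touching = FALSE) {
  if (length(start) == 0) return(list(start = numeric(), end = numeric()))
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  outs <- numeric(); oute <- numeric()
  for (i in seq_along(start)[-1]) {
    joined <- if (merge_touching) start[i] <= me else start[i] < me
    if (joined) {
      me <- max(me, end[i])
    } else {
      outs <- c(outs, ms); oute <- c(oute, me)
      ms <- start[i]; me <- end[i]
    }
  }
  list(start = c(outs, ms), end = c(oute, me))
}

#' Per-base subtraction of one peak set from another
#'
#' Removes every base of `b` from every interval of `a`; intervals of `a`
#' may split into multiple fragments (bedtools-subtract semantics).
#'
#' @param a,b `PeakSet` objects.
#' @return A `PeakSet` carrying `a`'s metadata; fragment names inherit the
#'   parent peak's name.
#' @export
subtract <- function(a, b) {
  stopifnot(inherits(a, "PeakSet"), inherits(b, "PeakSet"))
  da <- a$intervals; db <- b$intervals
  if (nrow(da) == 0 || nrow(db) == 0) return(a)
  res <- list()
  bsplit <- split(seq_len(nrow(db)), db$chrom)
  for (i in seq_len(nrow(da))) {
    ch <- da$chrom[i]
    ib <- bsplit[[ch]]
    if (is.null(ib)) {
      res[[length(res) + 1]] <- da[i, ]
      next
    }
    m <- .merge_runs(pmax(db$start[ib], da$start[i]),
                     pmin(db$end[ib], da$end[i]), merge_touching = TRUE)
    keep <- m$start < m$end
    bs <- m$start[keep]; be <- m$end[keep]
    if (length(bs) == 0) {
      res[[length(res) + 1]] <- da[i, ]
      next
    }
    # complementary gaps within [start_i, end_i)
    gs <- c(da$start[i], be)
    ge <- c(bs, da$end[i])
    ok <- gs < ge
    if (any(ok)) {
      frag <- da[rep(i, sum(ok)), ]
      frag$start <- gs[ok]; frag$end <- ge[ok]
      res[[length(res) + 1]] <- frag
    }
  }
  if (length(res) == 0)
    return(peak_set(character(), numeric(), numeric(),
                    sample_id = a$sample_id, condition = a$condition))
  out <- do.call(rbind, res)
  peak_set(out$chrom, out$start, out$end, out$name, out$score, out$strand,
           sample_id = a$sample_id, condition = a$condition)
}

#' Consensus peaks shared by multiple datasets
#'
#' Merges the union of all intervals into maximal non-overlapping blocks and
#' retains each block iff intervals from at least `min_support` distinct
#' input sets overlap it by >= 1 bp. Overlapping peaks within one input set
#' are merged first, so a set contributes at most one vote per block.
#'
#' @param sets List of `PeakSet` objects.
#' @param min_support Minimum number of distinct supporting sets (default 2,
#'   the "shared among 2 or more datasets" rule).
#' @return A `PeakSet` of consensus blocks; `score` records the support
#'   count.
#' @export
consensus_peaks <- function(sets, min_support = 2) {
  if (!is.list(sets) || !all(vapply(sets, inherits, TRUE, "PeakSet")))
    stop("sets must be a list of PeakSet objects")
  if (min_support > length(sets))
    stop("min_support exceeds the number of peak sets")
  all_df <- do.call(rbind, lapply(seq_along(sets), function(i) {
    df <- sets[[i]]$intervals
    if (nrow(df) == 0) return(NULL)
    cbind(df[, c("chrom", "start", "end")], set = i)
  }))
  if (is.null(all_df) || nrow(all_df) == 0)
    return(peak_set(character(), numeric(), numeric(),
                    condition = "consensus"))
  outs <- list()
  for (ch in sort(unique(all_df$chrom))) {
    d <- all_df[all_df$chrom == ch, ]
    # per-base union: touching intervals form one block
    m <- .merge_runs(d$start, d$end, merge_touching = TRUE)
    support <- integer(length(m$start))
    for (k in seq_along(m$start)) {
      hit <- d$start < m$end[k] & d$end > m$start[k]
      support[k] <- length(unique(d$set[hit]))
    }
    keep <- support >= min_support
    if (any(keep))
      outs[[ch]] <- data.frame(chrom = ch, start = m$start[keep],
                               end = m$end[keep], support = support[keep])
  }
  if (length(outs) == 0)
    return(peak_set(character(), numeric(), numeric(),
                    condition = "consensus"))
  out <- do.call(rbind, outs)
  peak_set(out$chrom, out$start, out$end,
           name = sprintf("consensus_%d", seq_len(nrow(out))),
           score = out$support, condition = "consensus")
}

#' Center position of peaks
#'
#' The center of a 0-based half-open interval is `floor((start + end) / 2)`;
#' odd spans round down.
#'
#' @param x A `PeakSet` or a data.frame with `start`/`end`.
#' @return Numeric vector of center coordinates.
#' @export
peak_center <- function(x) {
  df <- if (inherits(x, "PeakSet")) x$intervals else x
  floor((df$start + df$end) / 2)
}

#' Build a gene model for peak annotation
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (gene body, 0-based half-open).
#' @param exons data.frame with columns `gene_id`, `chrom`, `start`, `end`;
#'   each exon must lie within its gene body.
#' @return An object of class `GeneModel`. The TSS is `start` on `+` and
#'   `end - 1` on `-` strand.
#' @export
gene_model <- function(genes, exons) {
  need <- c("gene_id", "chrom", "start", "end", "strand")
  if (!all(need %in% names(genes))) stop("genes missing required columns")
  if (!all(c("gene_id", "chrom", "start", "end") %in% names(exons)))
    stop("exons missing required columns")
  if (nrow(exons) > 0) {
    idx <- match(exons$gene_id, genes$gene_id)
    if (any(is.na(idx))) stop("exon references unknown gene")
    if (any(exons$start < genes$start[idx] | exons$end > genes$end[idx]))
      stop("exon outside its gene body")
  }
  genes$tss <- ifelse(genes$strand == "-", genes$end - 1, genes$start)
  structure(list(genes = genes, exons = exons), class = "GeneModel")
}

#' Read a minimal GFF3 gene model (gene and exon features only)
#' @param path GFF3 file; `gene` rows need an `ID=` attribute, `exon` rows a
#'   `Parent=` attribute. GFF3 1-based closed coordinates are converted to
#'   0-based half-open at this boundary.
#' @return A `GeneModel`.
#' @export
read_gene_model <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  f <- strsplit(lines, "\t")
  if (any(lengths(f) < 9)) stop("malformed GFF3: expected 9 columns")
  type <- vapply(f, `[`, "", 3)
  attr_get <- function(s, key) {
    m <- regmatches(s, regexpr(paste0(key, "=[^;]+"), s))
    if (length(m) == 0) NA_character_ else sub(paste0(key, "="), "", m)
  }
  gi <- type == "gene"; ei <- type == "exon"
  genes <- data.frame(
    gene_id = vapply(f[gi], function(x) attr_get(x[9], "ID"), ""),
    chrom = vapply(f[gi], `[`, "", 1),
    start = as.numeric(vapply(f[gi], `[`, "", 4)) - 1,
    end = as.numeric(vapply(f[gi], `[`, "", 5)),
    strand = vapply(f[gi], `[`, "", 7), stringsAsFactors = FALSE)
  exons <- data.frame(
    gene_id = vapply(f[ei], function(x) attr_get(x[9], "Parent"), ""),
    chrom = vapply(f[ei], `[`, "", 1),
    start = as.numeric(vapply(f[ei], `[`, "", 4)) - 1,
    end = as.numeric(vapply(f[ei], `[`, "", 5)), stringsAsFactors = FALSE)
  gene_model(genes, exons)
}

#' Genomic context of peak centers
#'
#' Classifies each peak by the location of its center with precedence
#' promoter > exon > intron > intergenic. A promoter is the window of
#' `promoter_halfwidth` bp on each side of a TSS.
#'
#' @param peaks A `PeakSet`.
#' @param genes A `GeneModel`.
#' @param promoter_halfwidth Promoter half-width in bp (default 2000).
#' @return Character vector (factor levels promoter/exon/intron/intergenic)
#'   per peak.
#' @export
annotate_context <- function(peaks, genes, promoter_halfwidth = 2000) {
  stopifnot(inherits(peaks, "PeakSet"), inherits(genes, "GeneModel"))
  ctr <- peak_center(peaks)
  ch <- peaks$intervals$chrom
  n <- length(ctr)
  out <- rep("intergenic", n)
  g <- genes$genes
  if (nrow(g) == 0) {
    warning("empty gene model: all peaks classified intergenic")
    return(out)
  }
  e <- genes$exons
  for (i in seq_len(n)) {
    gi <- g$chrom == ch[i]
    if (!any(gi)) next
    if (any(abs(ctr[i] - g$tss[gi]) <= promoter_halfwidth)) {
      out[i] <- "promoter"
    } else if (nrow(e) > 0 &&
               any(e$chrom == ch[i] & e$start <= ctr[i] & ctr[i] < e$end)) {
      out[i] <- "exon"
    } else if (any(gi & g$start <= ctr[i] & ctr[i] < g$end)) {
      out[i] <- "intron"
    }
  }
  out
}
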