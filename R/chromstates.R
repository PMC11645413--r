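#' Construct a binarized histone-mark matrix
#'
#' The observation object for chromatin-state segmentation: for each
#' chromosome, a logical matrix of genomic bins (rows) by histone marks
#' (columns) recording whether a significant peak call of that mark touches
#' the bin.
#'
#' @param bins Named list (by chromosome) of logical matrices with identical
#'   column (mark) names and order.
#' @param bin_size Bin width in bp (default 200, the conventional
#'   segmentation resolution).
#' @return Object of class `BinarizedMarkMatrix` with `bins`, `bin_size`,
#'   `marks`.
#' @export
binarized_mark_matrix <- function(bins, bin_size = 200) {
  if (bin_size < 1) stop("bin_size must be >= 1")
  if (!is.list(bins) || length(bins) == 0 || is.null(names(bins)))
    stop("bins must be a non-empty named list of logical matrices")
  marks <- colnames(bins[[1]])
  if (is.null(marks) || anyDuplicated(marks))
    stop("mark names must be present and unique")
  for (m in bins) {
    if (!identical(colnames(m), marks))
      stop("all chromosomes must share the same mark order")
  }
  structure(list(bins = lapply(bins, function(m) {
    storage.mode(m) <- "logical"; m
  }), bin_size = bin_size, marks = marks),
  class = "BinarizedMarkMatrix")
}

#' @export
print.BinarizedMarkMatrix <- function(x, ...) {
  cat(sprintf("BinarizedMarkMatrix: %d bins x %d marks (%d bp bins)\n",
              sum(vapply(x$bins, nrow, 0L)), length(x$marks), x$bin_size))
  invisible(x)
}

#' Binarize mark peak calls into fixed bins
#'
#' A bin is `TRUE` for a mark iff any peak of that mark overlaps the bin by
#' at least 1 bp — presence/absence of a significant peak call, the
#' binarization the segmentation model consumes.
#'
#' @param mark_peaks Named list mark -> `PeakSet`.
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param bin_size Bin width in bp (default 200).
#' @return A `BinarizedMarkMatrix`.
#' @export
binarize_from_peaks <- function(mark_peaks, chrom_lengths, bin_size = 200) {
  if (bin_size < 1) stop("bin_size must be >= 1")
  if (!is.list(mark_peaks) || is.null(names(mark_peaks)))
    stop("mark_peaks must be a named list of PeakSet objects")
  marks <- names(mark_peaks)
  bins <- list()
  for (ch in names(chrom_lengths)) {
    nb <- ceiling(chrom_lengths[[ch]] / bin_size)
    m <- matrix(FALSE, nrow = nb, ncol = length(marks),
                dimnames = list(NULL, marks))
    for (k in seq_along(marks)) {
      df <- mark_peaks[[k]]$intervals
      df <- df[df$chrom == ch, , drop = FALSE]
      for (i in seq_len(nrow(df))) {
        b0 <- floor(df$start[i] / bin_size)
        b1 <- min(nb - 1, ceiling(df$end[i] / bin_size) - 1)
        if (b0 <= b1) m[(b0:b1) + 1, k] <- TRUE
      }
    }
    bins[[ch]] <- m
  }
  binarized_mark_matrix(bins, bin_size)
}

# Per-bin log emission likelihood matrix (T x K) under independent
# Bernoulli emissions. X is T x M logical, emis K x M.
.bernoulli_logB <- function(X, emis) {
  lp <- t(log(emis)); lq <- t(log(1 - emis))  # M x K
  X %*% lp + (1 - X) %*% lq
}

#' Construct a chromatin-state model
#'
#' @param initial Initial state distribution (length K, sums to 1).
#' @param transition K x K row-stochastic transition matrix.
#' @param emission K x M matrix of per-mark Bernoulli emission
#'   probabilities; column names are the mark names.
#' @param loglik_trace Optional EM log-likelihood trace.
#' @return Object of class `ChromatinStateModel`.
#' @export
chromatin_state_model <- function(initial, transition, emission,
                                  loglik_trace = numeric(0)) {
  K <- length(initial)
  if (abs(sum(initial) - 1) > 1e-6) stop("initial must sum to 1")
  if (!all(dim(transition) == c(K, K))) stop("transition must be K x K")
  if (any(abs(rowSums(transition) - 1) > 1e-6))
    stop("transition rows must sum to 1")
  if (nrow(emission) != K) stop("emission must have K rows")
  if (any(emission < 0 | emission > 1)) stop("emissions must lie in [0,1]")
  structure(list(K = K, initial = initial, transition = transition,
                 emission = emission, marks = colnames(emission),
                 loglik_trace = loglik_trace),
            class = "ChromatinStateModel")
}

#' @export
print.ChromatinStateModel <- function(x, ...) {
  cat(sprintf("ChromatinStateModel: %d states x %d marks\n", x$K,
              ncol(x$emission)))
  print(round(x$emission, 3))
  invisible(x)
}

#' Fit a Bernoulli-emission HMM to binarized marks
#'
#' Baum-Welch EM for a hidden Markov model whose per-state emissions are
#' conditionally independent Bernoullis per mark (the model class of
#' ChromHMM-style segmentation). Chromosomes are treated as independent
#' sequences. The best of `n_restarts` runs (uniform-plus-jitter
#' initialization, seeded for reproducibility) by final log-likelihood is
#' returned.
#'
#' @param x A `BinarizedMarkMatrix` with at least `10 * K` total bins.
#' @param K Number of states (default 6).
#' @param seed Integer seed controlling all restarts.
#' @param n_restarts Number of EM restarts (default 5).
#' @param max_iter Maximum EM iterations per restart (default 500).
#' @param tol Convergence: stop when log-likelihood gain < `tol`.
#' @return A `ChromatinStateModel` with `loglik_trace` of the winning
#'   restart.
#' @export
fit_chromatin_states <- function(x, K = 6, seed = 1, n_restarts = 5,
                                 max_iter = 500, tol = 1e-4) {
  stopifnot(inherits(x, "BinarizedMarkMatrix"))
  Xs <- lapply(x$bins, function(m) { storage.mode(m) <- "double"; m })
  total <- sum(vapply(Xs, nrow, 0))
  M <- length(x$marks)
  if (all(vapply(Xs, function(m) all(m == 0), TRUE)))
    stop("degenerate input: no mark is ever present")
  if (K < 2) {
    warning("K < 2: returning the closed-form single-state model")
    em <- matrix(colMeans(do.call(rbind, Xs)), nrow = 1,
                 dimnames = list(NULL, x$marks))
    return(chromatin_state_model(1, matrix(1, 1, 1), em))
  }
  if (total < 10 * K) stop("too few bins to fit: need >= 10 * K")
  eps <- 1e-4
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r - 1)
    colm <- colMeans(do.call(rbind, Xs))
    emis <- matrix(rep(colm, each = K), K, M,
                   dimnames = list(NULL, x$marks))
    emis <- pmin(pmax(emis + matrix(stats::runif(K * M, -0.25, 0.25),
                                    K, M, dimnames = dimnames(emis)),
                      eps), 1 - eps)
    A <- matrix(1 / K, K, K) + matrix(stats::runif(K * K, 0, 0.1), K, K)
    A <- A / rowSums(A)
    pi0 <- rep(1 / K, K)
    trace <- numeric(0)
    prev <- -Inf
    for (it in seq_len(max_iter)) {
      logA <- log(A); logpi <- log(pi0)
      ll <- 0
      xi_sum <- matrix(0, K, K)
      g1 <- numeric(K)
      num <- matrix(0, K, M); den <- numeric(K)
      for (X in Xs) {
        logB <- .bernoulli_logB(X, emis)
        fb <- .hmm_forward_backward(logB, logpi, logA)
        ll <- ll + fb$loglik
        xi_sum <- xi_sum + fb$xi_sum
        g1 <- g1 + fb$gamma[1, ]
        num <- num + t(fb$gamma) %*% X
        den <- den + colSums(fb$gamma)
      }
      trace <- c(trace, ll)
      if (is.finite(prev) && ll - prev < tol) break
      prev <- ll
      pi0 <- g1 / sum(g1)
      pi0 <- pmax(pi0, 1e-12); pi0 <- pi0 / sum(pi0)
      A <- xi_sum / pmax(rowSums(xi_sum), .Machine$double.xmin)
      A <- pmax(A, 1e-12); A <- A / rowSums(A)
      emis <- pmin(pmax(num / den, eps), 1 - eps)
    }
    if (is.null(best) || trace[length(trace)] > best$ll) {
      best <- list(ll = trace[length(trace)], pi = pi0, A = A,
                   emis = emis, trace = trace)
    }
  }
  chromatin_state_model(best$pi, best$A, best$emis,
                        loglik_trace = best$trace)
}

#' Decode chromatin states
#'
#' @param model A `ChromatinStateModel`.
#' @param x A `BinarizedMarkMatrix` with the model's mark order.
#' @param method `"viterbi"` (default, most probable path) or
#'   `"posterior"` (per-bin argmax of the smoothed posterior).
#' @return Object of class `StateAnnotation`: `states` (named list of
#'   1-based state index vectors per chromosome), `posterior` (list of
#'   T x K matrices when `method = "posterior"`), `bin_size`, `K`.
#' @export
decode_states <- function(model, x, method = c("viterbi", "posterior")) {
  stopifnot(inherits(model, "ChromatinStateModel"),
            inherits(x, "BinarizedMarkMatrix"))
  method <- match.arg(method)
  if (!identical(model$marks, x$marks))
    stop("mark order of matrix does not match the model")
  logpi <- log(pmax(model$initial, 1e-300))
  logA <- log(pmax(model$transition, 1e-300))
  emis <- pmin(pmax(model$emission, 1e-12), 1 - 1e-12)
  states <- list(); post <- list()
  for (ch in names(x$bins)) {
    X <- x$bins[[ch]]; storage.mode(X) <- "double"
    logB <- .bernoulli_logB(X, emis)
    if (method == "viterbi") {
      states[[ch]] <- as.integer(.hmm_viterbi(logB, logpi, logA))
    } else {
      fb <- .hmm_forward_backward(logB, logpi, logA)
      post[[ch]] <- fb$gamma
      states[[ch]] <- as.integer(max.col(fb$gamma, ties.method = "first"))
    }
  }
  structure(list(states = states,
                 posterior = if (method == "posterior") post else NULL,
                 bin_size = x$bin_size, K = model$K, method = method),
            class = "StateAnnotation")
}

#' Order states from heterochromatin-like to active-like
#'
#' Ranks states by the sum of their active-mark emission probabilities minus
#' the sum of their repressive-mark emissions; ties break by total emission
#' mass. The lowest-scoring state is labelled `E1` (heterochromatin /
#' quiescent end) and the highest `EK` (active promoters/enhancers). The
#' numeric transformation maps each original state index to its rank 1..K.
#'
#' @param model A `ChromatinStateModel`.
#' @param active_marks,repressive_marks Character vectors; must be subsets
#'   of the model's marks.
#' @return List with `order` (original state indices from E1 to EK),
#'   `labels` (per original state index, e.g. `"E3"`), `numeric`
#'   (per original state index, the 1..K rank).
#' @export
order_states <- function(model, active_marks, repressive_marks) {
  stopifnot(inherits(model, "ChromatinStateModel"))
  if (!all(active_marks %in% model$marks) ||
      !all(repressive_marks %in% model$marks))
    stop("active/repressive marks must be subsets of the model's marks")
  e <- model$emission
  score <- rowSums(e[, active_marks, drop = FALSE]) -
    rowSums(e[, repressive_marks, drop = FALSE])
  total <- rowSums(e)
  ord <- order(score, total)  # ascending: E1 first
  rank <- integer(model$K)
  rank[ord] <- seq_len(model$K)
  list(order = ord, labels = paste0("E", rank), numeric = rank)
}

#' Per-state fractions of bins overlapped by a peak set
#'
#' Restricts the decoded annotation to bins touched (>= 1 bp) by any peak
#' and tabulates the state composition of that bin subset.
#'
#' @param annotation A `StateAnnotation`.
#' @param peaks A `PeakSet` on the annotation's chromosomes.
#' @return Named numeric vector of length K summing to 1.
#' @export
state_frequencies_at <- function(annotation, peaks) {
  stopifnot(inherits(annotation, "StateAnnotation"),
            inherits(peaks, "PeakSet"))
  b <- annotation$bin_size
  counts <- numeric(annotation$K)
  any_bin <- FALSE
  for (ch in names(annotation$states)) {
    st <- annotation$states[[ch]]
    df <- peaks$intervals
    df <- df[df$chrom == ch, , drop = FALSE]
    if (nrow(df) == 0) next
    hit <- logical(length(st))
    for (i in seq_len(nrow(df))) {
      b0 <- floor(df$start[i] / b)
      b1 <- min(length(st) - 1, ceiling(df$end[i] / b) - 1)
      if (b0 <= b1) hit[(b0:b1) + 1] <- TRUE
    }
    if (any(hit)) {
      any_bin <- TRUE
      tab <- tabulate(st[hit], nbins = annotation$K)
      counts <- counts + tab
    }
  }
  if (!any_bin) stop("peaks overlap no annotated bins")
  out <- counts / sum(counts)
  names(out) <- paste0("state", seq_along(out))
  out
}

#' Serialize / restore a chromatin-state model as JSON
#' @param model A `ChromatinStateModel`.
#' @param path JSON path.
#' @return `write_state_model` returns `path` invisibly;
#'   `read_state_model` returns a `ChromatinStateModel`.
#' @export
write_state_model <- function(model, path) {
  stopifnot(inherits(model, "ChromatinStateModel"))
  obj <- list(K = model$K, initial = model$initial,
              transition = model$transition, emission = model$emission,
              marks = model$marks, loglik_trace = model$loglik_trace)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_state_model
#' @export
read_state_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  em <- matrix(as.numeric(obj$emission), nrow = obj$K,
               dimnames = list(NULL, obj$marks))
  tr <- matrix(as.numeric(obj$transition), nrow = obj$K)
  chromatin_state_model(as.numeric(obj$initial), tr, em,
                        loglik_trace = as.numeric(obj$loglik_trace))
}
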