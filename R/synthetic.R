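#' Simulate an i.i.d. random genome
#'
#' Bases are drawn independently with the stated GC content:
#' `P(G) = P(C) = gc/2`, `P(A) = P(T) = (1 - gc)/2`. The default GC of 0.41
#' matches the human genome average.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths
#'   (each >= 1000 bp).
#' @param gc GC fraction in (0, 1]; `gc = 1` yields G/C-only sequence.
#' @param seed Integer seed; output is deterministic given the seed.
#' @param path Optional FASTA path; the seed is recorded in each header.
#' @return A `genome` (named character vector).
#' @export
make_genome <- function(chrom_lengths, gc = 0.41, seed = 1, path = NULL) {
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be positive")
  if (any(chrom_lengths < 1000)) stop("chromosome lengths must be >= 1000")
  if (gc <= 0 || gc > 1) stop("gc must lie in (0, 1]")
  set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  g <- vapply(chrom_lengths, function(len) {
    paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
  }, "")
  names(g) <- names(chrom_lengths)
  class(g) <- "genome"
  if (!is.null(path))
    write_genome(g, path, header_note = sprintf("seed=%d gc=%g", seed, gc))
  g
}

# Replace genome bases on [start, start + nchar(s)) with s (0-based).
.genome_replace <- function(genome, chrom, start, s) {
  substr(genome[[chrom]], start + 1, start + nchar(s)) <- s
  genome
}

#' Simulate a peak set with a planted motif fraction
#'
#' Places `n_peaks` non-overlapping peaks of fixed width on the first
#' chromosome and plants the PWM consensus (maximum-scoring site) at the
#' center of exactly `round(n_peaks * are_fraction)` of them. The central
#' scan window of every non-planted peak is rejection-sampled against the
#' scan threshold so the planted fraction is recovered exactly by
#' [fraction_with_motif()].
#'
#' @param genome A `genome`; modified copies are returned (peak sequence is
#'   written into it).
#' @param n_peaks Number of peaks.
#' @param width Peak width in bp (default 200).
#' @param are_fraction Planted motif-positive fraction between 0 and 1.
#' @param pwm A `PositionWeightMatrix`.
#' @param seed Integer seed.
#' @param scan_window Central window (bp) used for presence calls
#'   (default 100); rejection sampling clears this window.
#' @param threshold Scan threshold; `NULL` uses the PWM default.
#' @param sample_id,condition PeakSet metadata.
#' @param chrom Chromosome to place peaks on (default: the genome's first).
#' @return List with `peaks` (`PeakSet`), `genome` (modified), `truth`
#'   (`SimulationTruth` with the planted fraction and positive peak names).
#' @export
make_peak_sets <- function(genome, n_peaks, width = 200, are_fraction = 0.5,
                           pwm, seed = 1, scan_window = 100,
                           threshold = NULL, sample_id = "sim",
                           condition = "synthetic",
                           chrom = names(genome)[1]) {
  if (are_fraction < 0 || are_fraction > 1)
    stop("are_fraction must lie in [0, 1]")
  if (!chrom %in% names(genome)) stop("chrom not in genome")
  if (is.null(threshold)) threshold <- pwm$default_threshold
  set.seed(seed)
  len <- nchar(genome[[chrom]])
  margin <- scan_window  # keep scan windows away from chromosome ends
  gap <- 10
  span <- n_peaks * (width + gap)
  if (len - 2 * margin < span)
    stop("genome too small for the requested peaks")
  # sorted random starts with guaranteed spacing
  slack <- len - 2 * margin - span
  offs <- sort(sample.int(slack + 1, n_peaks, replace = TRUE)) - 1
  starts <- margin + offs + (seq_len(n_peaks) - 1) * (width + gap)
  ends <- starts + width
  centers <- floor((starts + ends) / 2)
  L <- pwm_length(pwm)
  half <- scan_window / 2
  n_pos <- round(n_peaks * are_fraction)
  pos_idx <- if (n_pos > 0) sort(sample.int(n_peaks, n_pos)) else integer(0)
  consensus <- pwm_consensus(pwm)
  p_bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  for (i in seq_len(n_peaks)) {
    ws <- centers[i] - half
    wlen <- scan_window
    if (i %in% pos_idx) {
      # plant the max-score site so the hit starts at the window center
      site_start <- centers[i] - floor(L / 2)
      genome <- .genome_replace(genome, chrom, site_start, consensus)
    } else {
      # rejection-sample the scan window until it is motif-free
      repeat {
        sq <- paste(sample(names(p_bg), wlen, replace = TRUE, prob = p_bg),
                    collapse = "")
        if (nrow(scan_motif(pwm, sq, threshold = threshold)) == 0) break
      }
      genome <- .genome_replace(genome, chrom, ws, sq)
    }
  }
  peaks <- peak_set(rep(chrom, n_peaks), starts, ends,
                    name = sprintf("peak_%d", seq_len(n_peaks)),
                    sample_id = sample_id, condition = condition)
  truth <- structure(list(
    planted_are_fraction = n_pos / n_peaks,
    n_positive = n_pos,
    positive_peaks = sprintf("peak_%d", pos_idx),
    seed = seed), class = "SimulationTruth")
  list(peaks = peaks, genome = genome, truth = truth)
}

#' Simulate a matched normal/tumor motif-fraction cohort
#'
#' Per-patient pairs of fraction-with-motif values where the tumor value is
#' the normal value minus a fixed depletion plus Gaussian noise, clipped to
#' 0 and 1. Emulates matched tumor/normal cistrome pairs in which AREs are
#' depleted from the tumor AR cistrome.
#'
#' @param n_patients Number of pairs (>= 2).
#' @param normal_mean Mean normal-tissue fraction.
#' @param depletion Tumor depletion; must satisfy
#'   `0 <= depletion < normal_mean`.
#' @param noise_sd Gaussian noise SD on both members of each pair.
#' @param seed Integer seed.
#' @return data.frame with `patient`, `normal`, `tumor`; attribute `truth`
#'   records the parameters.
#' @export
make_matched_cohort <- function(n_patients, normal_mean = 0.4,
                                depletion = 0.15, noise_sd = 0.03,
                                seed = 1) {
  if (n_patients < 2) stop("need >= 2 patients")
  if (depletion < 0 || depletion >= normal_mean)
    stop("depletion must satisfy 0 <= depletion < normal_mean")
  set.seed(seed)
  clip <- function(v) pmin(1, pmax(0, v))
  normal <- clip(normal_mean + stats::rnorm(n_patients, 0, noise_sd))
  tumor <- clip(normal - depletion + stats::rnorm(n_patients, 0, noise_sd))
  out <- data.frame(patient = sprintf("P%02d", seq_len(n_patients)),
                    normal = normal, tumor = tumor)
  attr(out, "truth") <- structure(list(normal_mean = normal_mean,
                                       depletion = depletion,
                                       noise_sd = noise_sd, seed = seed),
                                  class = "SimulationTruth")
  out
}

#' Sample binarized mark tracks from a known chromatin-state model
#'
#' Draws a state sequence from the model's Markov chain and, per bin,
#' independent Bernoulli mark calls from the state's emission
#' probabilities.
#'
#' @param true_model A `ChromatinStateModel` (rows of transition sum to 1).
#' @param n_bins Number of bins (>= 10 * K).
#' @param bin_size Bin width in bp (default 200).
#' @param seed Integer seed.
#' @param chrom Chromosome name for the simulated sequence.
#' @param dir Optional directory; if given, one 0/1 bedGraph per mark is
#'   written there (seed recorded in the header).
#' @return List with `matrix` (`BinarizedMarkMatrix`), `states` (true state
#'   index per bin), `truth` (`SimulationTruth`).
#' @export
make_mark_tracks <- function(true_model, n_bins, bin_size = 200, seed = 1,
                             chrom = "chrSim", dir = NULL) {
  stopifnot(inherits(true_model, "ChromatinStateModel"))
  K <- true_model$K
  if (n_bins < 10 * K) stop("n_bins must be >= 10 * K")
  set.seed(seed)
  st <- integer(n_bins)
  st[1] <- sample.int(K, 1, prob = true_model$initial)
  for (t in 2:n_bins)
    st[t] <- sample.int(K, 1, prob = true_model$transition[st[t - 1], ])
  M <- ncol(true_model$emission)
  p <- true_model$emission[st, , drop = FALSE]
  X <- matrix(stats::runif(n_bins * M) < p, n_bins, M,
              dimnames = list(NULL, true_model$marks))
  mat <- binarized_mark_matrix(stats::setNames(list(X), chrom), bin_size)
  if (!is.null(dir)) {
    for (m in true_model$marks) {
      tr <- signal_track(stats::setNames(list(as.numeric(X[, m])), chrom),
                         bin_size, sample_id = m)
      write_bedgraph(tr, file.path(dir, paste0(m, ".bedGraph")),
                     header_note = sprintf("mark=%s seed=%d", m, seed))
    }
  }
  truth <- structure(list(true_model = true_model, seed = seed),
                     class = "SimulationTruth")
  list(matrix = mat, states = st, truth = truth)
}

#' Simulate an expression cohort with planted signature genes
#'
#' Gene baselines are Normal (log2 scale); planted up-genes gain `+effect`
#' and down-genes `-effect` log2 units in the treated group, on top of
#' per-sample Gaussian noise.
#'
#' @param n_genes,n_samples Matrix dimensions.
#' @param up_genes,down_genes Character vectors of planted gene ids (must be
#'   disjoint; drawn from `gene_0001`-style names).
#' @param group_labels Length-`n_samples` labels; effects apply to samples
#'   labelled `treated_label`.
#' @param effect Planted shift in log2 units (default 2).
#' @param noise_sd Per-observation Gaussian noise SD (default 0.5).
#' @param seed Integer seed.
#' @param treated_label Label receiving the effect (default `"treated"`).
#' @param baseline_mean,baseline_sd Distribution of gene-level baseline
#'   means (defaults 8 and 2 log2 units, typical of log2 TPM).
#' @return List with `expr` (`ExpressionMatrix`), `truth`.
#' @export
make_expression_cohort <- function(n_genes, n_samples,
                                   up_genes = character(),
                                   down_genes = character(),
                                   group_labels, effect = 2,
                                   noise_sd = 0.5, seed = 1,
                                   treated_label = "treated",
                                   baseline_mean = 8, baseline_sd = 2) {
  if (length(intersect(up_genes, down_genes)) > 0)
    stop("up_genes and down_genes must be disjoint")
  if (length(group_labels) != n_samples)
    stop("group_labels must have one label per sample")
  set.seed(seed)
  genes <- sprintf("gene_%04d", seq_len(n_genes))
  if (!all(c(up_genes, down_genes) %in% genes))
    stop("planted genes must be gene_%04d names within n_genes")
  base <- stats::rnorm(n_genes, baseline_mean, baseline_sd)
  vals <- matrix(stats::rnorm(n_genes * n_samples, 0, noise_sd),
                 n_genes, n_samples) + base
  treated <- group_labels == treated_label
  vals[match(up_genes, genes), treated] <-
    vals[match(up_genes, genes), treated] + effect
  vals[match(down_genes, genes), treated] <-
    vals[match(down_genes, genes), treated] - effect
  rownames(vals) <- genes
  colnames(vals) <- sprintf("sample_%03d", seq_len(n_samples))
  truth <- structure(list(up_genes = up_genes, down_genes = down_genes,
                          effect = effect, noise_sd = noise_sd,
                          seed = seed), class = "SimulationTruth")
  list(expr = expression_matrix(vals, groups = group_labels),
       truth = truth)
}

#' Simulate survival times from a proportional-hazards model on scores
#'
#' Event times are exponential with hazard
#' `baseline_hazard * exp(beta * z)` where `z` is the standardized score.
#' Censoring is independent exponential, calibrated so that the expected
#' censored fraction is approximately `censor_rate` under the null.
#'
#' @param scores Per-sample signature scores.
#' @param beta Log-hazard per standardized score unit.
#' @param baseline_hazard Baseline hazard per month (default 0.02).
#' @param censor_rate Target censored fraction in [0, 1).
#' @param seed Integer seed.
#' @return A `SurvivalCohort` with columns `score` (standardized) and the
#'   planted parameters in attribute `truth`.
#' @export
make_survival <- function(scores, beta, baseline_hazard = 0.02,
                          censor_rate = 0.2, seed = 1) {
  if (censor_rate < 0 || censor_rate >= 1)
    stop("censor_rate must lie in [0, 1)")
  set.seed(seed)
  z <- as.numeric(scale(scores))
  n <- length(z)
  h <- baseline_hazard * exp(beta * z)
  t_event <- stats::rexp(n, rate = h)
  if (censor_rate == 0) {
    time <- t_event; event <- rep(1, n)
  } else {
    c_rate <- baseline_hazard * censor_rate / (1 - censor_rate)
    t_cens <- stats::rexp(n, rate = c_rate)
    time <- pmin(t_event, t_cens)
    event <- as.numeric(t_event <= t_cens)
  }
  cohort <- survival_cohort(time, event,
                            covariates = data.frame(score = z))
  attr(cohort, "truth") <- structure(list(beta = beta,
                                          baseline_hazard = baseline_hazard,
                                          censor_rate = censor_rate,
                                          seed = seed),
                                     class = "SimulationTruth")
  cohort
}

#' Write a SimulationTruth sidecar as JSON
#' @param truth A `SimulationTruth`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "SimulationTruth"))
  obj <- lapply(unclass(truth), function(x) {
    if (inherits(x, "ChromatinStateModel"))
      list(K = x$K, initial = x$initial, transition = x$transition,
           emission = x$emission, marks = x$marks)
    else x
  })
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}
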