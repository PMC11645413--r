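#' Default pipeline configuration
#'
#' Parameters for an end-to-end run on synthetic data: a small simulated
#' genome, two peak sets with different planted ARE fractions, a matched
#' cohort, mark tracks sampled from a known state model, an expression
#' cohort with planted signature genes, and a survival cohort driven by the
#' signature score.
#'
#' @param outdir Output directory for the run.
#' @param seed Master seed; every stage derives its seed from it.
#' @return Named list of parameters (see fields in source).
#' @export
default_config <- function(outdir = tempfile("cistromere_run_"), seed = 1) {
  list(
    outdir = outdir,
    seed = seed,
    genome = list(length = 200000, gc = 0.41),
    peaks = list(n_peaks = 50, width = 200,
                 fraction_normal = 0.40, fraction_tumor = 0.15),
    matched = list(n_patients = 8, normal_mean = 0.40, depletion = 0.15,
                   noise_sd = 0.02),
    motif = list(pfm = system.file("extdata", "ARE_synthetic.pfm",
                                   package = "cistromere"),
                 window = 100, density_window = 2400, density_bin = 10),
    chromstate = list(K = 3, n_bins = 5000, bin_size = 200,
                      n_restarts = 2),
    expression = list(n_genes = 400, n_samples = 12, n_up = 15, n_down = 15,
                      effect = 4, noise_sd = 0.5),
    survival = list(n_patients = 200, beta = -0.75,
                    baseline_hazard = 0.02, censor_rate = 0.2)
  )
}

#' Validate a pipeline configuration
#'
#' Checks referenced paths and parameter ranges before any stage runs.
#'
#' @param config A config list ([default_config()]) or path to a JSON file
#'   with the same structure.
#' @return The validated config list, invisibly usable downstream.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  need <- c("outdir", "seed", "genome", "peaks", "matched", "motif",
            "chromstate", "expression", "survival")
  miss <- setdiff(need, names(config))
  if (length(miss)) stop("config missing fields: ",
                         paste(miss, collapse = ", "))
  if (!file.exists(config$motif$pfm))
    stop("motif PFM not found: ", config$motif$pfm)
  if (config$genome$length < 1000) stop("genome length must be >= 1000")
  with(config$peaks, {
    if (fraction_normal < 0 || fraction_normal > 1 ||
        fraction_tumor < 0 || fraction_tumor > 1)
      stop("planted fractions must lie in [0, 1]")
  })
  if (config$chromstate$K < 2) stop("chromstate K must be >= 2")
  config
}

.write_tsv <- function(df, path, params = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(params))
    writeLines(sprintf("# %s=%s", names(params),
                       vapply(params, format, "")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full synthetic-data analysis pipeline
#'
#' Executes the stages in dependency order (simulate, motif statistics,
#' density profiles, chromatin states, signatures, survival), writing each
#' stage's outputs under `config$outdir` and a JSON manifest recording the
#' package version, seeds, parameters and input checksums. Any stage
#' failure aborts with the stage name; prior outputs are preserved.
#'
#' @param config A config list or JSON path (see [default_config()]).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = default_config()) {
  config <- validate_config(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$outdir, ...)
  seed <- config$seed
  manifest <- list(package = "cistromere",
                   version = as.character(utils::packageVersion("cistromere")),
                   seed = seed, parameters = config, stages = list())
  stage <- function(name, fun) {
    t0 <- Sys.time()
    message(sprintf("[%s] starting", name))
    res <- tryCatch(fun(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    manifest$stages[[name]] <<- list(
      elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
      outputs = res)
    message(sprintf("[%s] done", name))
  }

  are <- load_motif(config$motif$pfm)
  env <- new.env()

  stage("simulate", function() {
    g1 <- make_genome(c(chrSim = config$genome$length),
                      gc = config$genome$gc, seed = seed)
    g2 <- make_genome(c(chrSim = config$genome$length),
                      gc = config$genome$gc, seed = seed + 1)
    pn <- make_peak_sets(g1, config$peaks$n_peaks, config$peaks$width,
                         config$peaks$fraction_normal, are, seed = seed,
                         sample_id = "normal_sim", condition = "normal")
    pt <- make_peak_sets(g2, config$peaks$n_peaks, config$peaks$width,
                         config$peaks$fraction_tumor, are, seed = seed + 1,
                         sample_id = "tumor_sim", condition = "tumor")
    env$normal <- pn; env$tumor <- pt
    write_genome(pn$genome, out("genome_normal.fa"),
                 header_note = sprintf("seed=%d", seed))
    write_bed(pn$peaks, out("peaks_normal.bed"))
    write_bed(pt$peaks, out("peaks_tumor.bed"))
    write_truth(pn$truth, out("truth_normal.json"))
    write_truth(pt$truth, out("truth_tumor.json"))
    env$matched <- make_matched_cohort(
      config$matched$n_patients, config$matched$normal_mean,
      config$matched$depletion, config$matched$noise_sd, seed = seed)
    .write_tsv(env$matched, out("matched_cohort.tsv"),
               params = c(seed = seed))
    K <- config$chromstate$K
    marks <- paste0("mark", seq_len(3))
    emis <- matrix(0.1, K, 3, dimnames = list(NULL, marks))
    for (k in seq_len(K)) emis[k, ((k - 1) %% 3) + 1] <- 0.9
    A <- matrix(0.05 / (K - 1), K, K); diag(A) <- 0.95
    env$true_model <- chromatin_state_model(rep(1 / K, K), A, emis)
    env$tracks <- make_mark_tracks(env$true_model,
                                   config$chromstate$n_bins,
                                   config$chromstate$bin_size,
                                   seed = seed, dir = config$outdir)
    genes <- sprintf("gene_%04d", seq_len(config$expression$n_genes))
    env$up <- genes[seq_len(config$expression$n_up)]
    env$down <- genes[config$expression$n_up +
                      seq_len(config$expression$n_down)]
    grp <- rep(c("control", "treated"),
               each = config$expression$n_samples / 2)
    env$cohort <- make_expression_cohort(
      config$expression$n_genes, config$expression$n_samples,
      env$up, env$down, grp, effect = config$expression$effect,
      noise_sd = config$expression$noise_sd, seed = seed)
    .write_tsv(cbind(gene = rownames(env$cohort$expr$values),
                     as.data.frame(env$cohort$expr$values)),
               out("expression.tsv"), params = c(seed = seed))
    c("genome_normal.fa", "peaks_normal.bed", "peaks_tumor.bed",
      "matched_cohort.tsv", "expression.tsv")
  })

  stage("motif_stats", function() {
    fn <- fraction_with_motif(env$normal$peaks, env$normal$genome, are,
                              window = config$motif$window)
    ft <- fraction_with_motif(env$tumor$peaks, env$tumor$genome, are,
                              window = config$motif$window)
    cmp <- compare_fractions(env$matched$normal, env$matched$tumor,
                             paired = TRUE)
    # the two sets live on separate simulated genomes, so assemble the
    # 2x2 motif-enrichment table from per-set presence calls
    hn <- peak_has_motif(env$normal$peaks, env$normal$genome, are,
                         window = config$motif$window)
    ht <- peak_has_motif(env$tumor$peaks, env$tumor$genome, are,
                         window = config$motif$window)
    a <- sum(hn); b <- sum(!hn); cc <- sum(ht); d <- sum(!ht)
    enr <- list(odds_ratio = (a * d) / (b * cc),
                p_value = stats::phyper(a - 1, a + cc, b + d, a + b,
                                        lower.tail = FALSE))
    enr$significant <- enr$p_value <= 1e-20
    env$fractions <- data.frame(
      set = c("normal", "tumor"), fraction = c(fn, ft))
    .write_tsv(env$fractions, out("motif_fractions.tsv"),
               params = c(window = config$motif$window))
    .write_tsv(data.frame(statistic = cmp$statistic, p_value = cmp$p_value,
                          method = cmp$method),
               out("matched_wilcoxon.tsv"))
    .write_tsv(data.frame(odds_ratio = enr$odds_ratio,
                          p_value = enr$p_value,
                          significant = enr$significant),
               out("motif_enrichment.tsv"))
    c("motif_fractions.tsv", "matched_wilcoxon.tsv",
      "motif_enrichment.tsv")
  })

  stage("density", function() {
    dn <- motif_density_profile(env$normal$peaks, env$normal$genome, are,
                                window = config$motif$density_window,
                                bin = config$motif$density_bin)
    dt <- motif_density_profile(env$tumor$peaks, env$tumor$genome, are,
                                window = config$motif$density_window,
                                bin = config$motif$density_bin)
    dd <- differential_density(dn, dt, smooth = TRUE)
    .write_tsv(data.frame(offset = dn$offsets, normal = dn$values,
                          tumor = dt$values, differential = dd$values),
               out("motif_density.tsv"),
               params = c(window = config$motif$density_window,
                          bin = config$motif$density_bin,
                          smoothing = dd$smoothing))
    "motif_density.tsv"
  })

  stage("chromstate", function() {
    fit <- fit_chromatin_states(env$tracks$matrix,
                                K = config$chromstate$K, seed = seed,
                                n_restarts = config$chromstate$n_restarts)
    ann <- decode_states(fit, env$tracks$matrix)
    ord <- order_states(fit, active_marks = fit$marks[1],
                        repressive_marks = fit$marks[2])
    write_state_model(fit, out("state_model.json"))
    st <- ann$states[[1]]
    .write_tsv(data.frame(bin = seq_along(st) - 1, state = st,
                          label = ord$labels[st],
                          numeric = ord$numeric[st]),
               out("state_map.tsv"),
               params = c(K = config$chromstate$K, seed = seed))
    env$state_fit <- fit
    c("state_model.json", "state_map.tsv")
  })

  stage("signatures", function() {
    de <- surrogate_de(env$cohort$expr, "control", "treated")
    sig <- derive_signature(de, name = "ARE_activation")
    sc <- suppressMessages(score_signature(env$cohort$expr, sig))
    env$sig <- sig
    .write_tsv(de, out("differential_expression.tsv"))
    write_gmt(list(sig), out("signatures.gmt"))
    .write_tsv(data.frame(sample = names(sc), score = as.numeric(sc),
                          group = env$cohort$expr$groups),
               out("signature_scores.tsv"))
    env$scores <- sc
    c("differential_expression.tsv", "signatures.gmt",
      "signature_scores.tsv")
  })

  stage("survival", function() {
    set.seed(seed)
    n <- config$survival$n_patients
    sc <- stats::rnorm(n)  # independent patient cohort scored afresh
    cohort <- make_survival(sc, beta = config$survival$beta,
                            baseline_hazard = config$survival$baseline_hazard,
                            censor_rate = config$survival$censor_rate,
                            seed = seed)
    q <- quartile_stratify(cohort$score)
    lr <- logrank(cohort, q)
    cx <- cox_fit(cohort, "score")
    km <- km_curve(cohort, q)
    .write_tsv(km$curves, out("km_curves.tsv"))
    .write_tsv(cbind(cx, logrank_chisq = lr$chisq,
                     logrank_p = lr$p_value),
               out("survival_fit.tsv"),
               params = c(beta = config$survival$beta, seed = seed))
    c("km_curves.tsv", "survival_fit.tsv")
  })

  inputs <- list.files(config$outdir, full.names = TRUE)
  manifest$checksums <- as.list(tools::md5sum(inputs))
  names(manifest$checksums) <- basename(inputs)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(manifest)
}
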