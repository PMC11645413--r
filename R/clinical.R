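#' Construct a survival cohort
#'
#' @param time Positive follow-up times (months).
#' @param event Event indicator: 1 = event, 0 = censored.
#' @param covariates Optional data.frame of per-patient covariates.
#' @param quartile Optional ordered factor of score quartiles (Q1..Q4).
#' @param id Optional patient identifiers.
#' @return Object of class `SurvivalCohort` (a data.frame).
#' @export
survival_cohort <- function(time, event, covariates = NULL,
                            quartile = NULL, id = NULL) {
  if (any(time <= 0)) stop("follow-up times must be positive")
  if (!all(event %in% c(0, 1))) stop("event must be 0 or 1")
  d <- data.frame(id = if (is.null(id)) seq_along(time) else id,
                  time = time, event = event)
  if (!is.null(covariates)) {
    if (nrow(covariates) != length(time))
      stop("covariates must have one row per patient")
    d <- cbind(d, covariates)
  }
  if (!is.null(quartile)) d$quartile <- quartile
  class(d) <- c("SurvivalCohort", "data.frame")
  d
}

#' Kaplan-Meier curves per group
#'
#' Product-limit estimator per group with censoring marks retained.
#'
#' @param cohort A `SurvivalCohort`.
#' @param group_labels Vector of group labels, one per patient; `NULL` fits
#'   a single pooled curve.
#' @return Object of class `SurvivalFit`: list with `curves` (data.frame of
#'   group, time, survival, n_risk, n_event, n_censor) and the underlying
#'   `survfit` object.
#' @export
km_curve <- function(cohort, group_labels = NULL) {
  stopifnot(inherits(cohort, "SurvivalCohort"))
  d <- as.data.frame(cohort)
  if (is.null(group_labels)) group_labels <- rep("all", nrow(d))
  if (any(table(group_labels) == 0) || length(group_labels) != nrow(d))
    stop("group_labels must label every patient")
  d$grp <- as.factor(group_labels)
  fit <- survival::survfit(survival::Surv(time, event) ~ grp, data = d)
  sm <- summary(fit, censored = TRUE)
  grp <- if (is.null(sm$strata)) rep(levels(d$grp)[1], length(sm$time))
         else sub("^grp=", "", as.character(sm$strata))
  curves <- data.frame(group = grp, time = sm$time, survival = sm$surv,
                       n_risk = sm$n.risk, n_event = sm$n.event,
                       n_censor = sm$n.censor)
  structure(list(curves = curves, survfit = fit), class = "SurvivalFit")
}

#' @export
print.SurvivalFit <- function(x, ...) {
  cat("SurvivalFit (Kaplan-Meier)\n")
  print(utils::head(x$curves, 10))
  invisible(x)
}

#' Log-rank test across groups
#'
#' Observed-minus-expected chi-square over pooled event times with
#' `df = groups - 1`.
#'
#' @param cohort A `SurvivalCohort` with at least one event.
#' @param group_labels Group label per patient; >= 2 distinct groups.
#' @return List with `chisq`, `df`, `p_value`.
#' @export
logrank <- function(cohort, group_labels) {
  stopifnot(inherits(cohort, "SurvivalCohort"))
  d <- as.data.frame(cohort)
  grp <- as.factor(group_labels)
  if (nlevels(grp) < 2) stop("log-rank needs >= 2 groups")
  if (sum(d$event) < 1) stop("log-rank needs >= 1 event")
  d$grp <- grp
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp, data = d)
  df <- nlevels(grp) - 1
  list(chisq = unname(sd$chisq), df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood maximization with Efron tie handling; Wald confidence
#' intervals. Refuses clearly under-powered designs (fewer than
#' `covariates + 5` events) and reports non-converged covariates.
#'
#' @param cohort A `SurvivalCohort`.
#' @param covariates Character vector of covariate column names in `cohort`.
#' @return data.frame, one row per model coefficient: `term`, `beta`, `hr`,
#'   `ci_lower`, `ci_upper`, `p_value`.
#' @export
cox_fit <- function(cohort, covariates) {
  stopifnot(inherits(cohort, "SurvivalCohort"))
  d <- as.data.frame(cohort)
  missing_cov <- setdiff(covariates, names(d))
  if (length(missing_cov))
    stop("unknown covariate(s): ", paste(missing_cov, collapse = ", "))
  if (sum(d$event) < length(covariates) + 5)
    stop("too few events for ", length(covariates),
         " covariate(s): need >= covariates + 5")
  fm <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                paste(covariates, collapse = " + ")))
  fit <- tryCatch(
    survival::coxph(fm, data = d, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite",
                conditionMessage(w)))
        stop("Cox fit failed to converge for covariates: ",
             paste(covariates, collapse = ", "), call. = FALSE)
      suppressWarnings(survival::coxph(fm, data = d, ties = "efron"))
    })
  s <- summary(fit)
  co <- s$coefficients
  data.frame(term = rownames(co), beta = co[, "coef"],
             hr = exp(co[, "coef"]),
             ci_lower = exp(co[, "coef"] - 1.96 * co[, "se(coef)"]),
             ci_upper = exp(co[, "coef"] + 1.96 * co[, "se(coef)"]),
             p_value = co[, "Pr(>|z|)"], row.names = NULL)
}

#' Kruskal-Wallis association between a continuous value and groups
#' @param values Numeric vector (not constant).
#' @param group_labels Group label per value; >= 2 groups.
#' @return List with `H`, `df`, `p_value` (tie-corrected).
#' @export
group_association <- function(values, group_labels) {
  grp <- as.factor(group_labels)
  if (nlevels(grp) < 2) stop("need >= 2 groups")
  if (length(unique(values)) == 1) stop("constant input")
  kt <- stats::kruskal.test(values, grp)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value)
}

#' Spearman rank correlation
#' @param x,y Numeric vectors of equal length >= 3, neither constant.
#' @return List with `rho`, `p_value` (two-sided; exact for small untied
#'   samples).
#' @export
correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need >= 3 paired observations")
  if (length(unique(x)) == 1 || length(unique(y)) == 1)
    stop("constant input")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}
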