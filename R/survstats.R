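# Survival statistics: Kaplan-Meier with logrank comparison, TMA
# positive-fraction computation, cluster-robust Cox regression on marker
# fractions, and phenotype concordance across mouse replicates.

#' Kaplan-Meier curves and logrank test between groups
#'
#' Product-limit estimates per group and the standard logrank chi-square
#' (ties handled by the aggregated risk-set formula, as in
#' `survival::survdiff`).
#'
#' @param records data.frame with `time`, `event` and the grouping column.
#' @param groups name of the grouping column (default `"group"`).
#' @return list: `fit` (a `survfit`), `chi2`, `df`, `p`.
#' @export
km_logrank <- function(records, groups = "group") {
  g <- factor(records[[groups]])
  if (nlevels(g) < 2) stop("logrank needs at least 2 groups (df would be 0)")
  sv <- survival::Surv(records$time, records$event)
  fit <- survival::survfit(sv ~ g)
  sd <- survival::survdiff(sv ~ g)
  df <- length(sd$n) - 1
  list(fit = fit, chi2 = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Positive-cell fractions per TMA core by fixed intensity thresholds
#'
#' fraction = count(intensity >= threshold) / count(nuclei), with one
#' fixed threshold per marker applied across all cores.
#'
#' @param nuclei data.frame: `patient`, `core`, `marker`, `intensity`.
#' @param thresholds named vector, one threshold per marker.
#' @return data.frame: patient, core, marker, n_nuclei, fraction.
#' @export
tma_fractions <- function(nuclei, thresholds) {
  if (!all(unique(nuclei$marker) %in% names(thresholds)))
    stop("missing threshold for marker: ",
         paste(setdiff(unique(nuclei$marker), names(thresholds)),
               collapse = ", "))
  key <- interaction(nuclei$patient, nuclei$core, nuclei$marker,
                     drop = TRUE)
  res <- lapply(split(nuclei, key), function(d) {
    thr <- thresholds[[d$marker[1]]]
    data.frame(patient = d$patient[1], core = d$core[1],
               marker = d$marker[1], n_nuclei = nrow(d),
               fraction = mean(d$intensity >= thr))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Cluster-robust Cox regression of survival on a marker fraction
#'
#' Multivariate Cox proportional hazards with the per-core positive
#' fraction (percentage-point scale, 0-100) as predictor and age, sex and
#' transcriptional subtype (baseline: classical) as covariates; multiple
#' cores per patient are handled by cluster-robust variance on patient
#' id. The reported hazard ratio is per percentage point.
#'
#' @param records data.frame with one row per core: `time`, `event`,
#'   `fraction` (0-1 proportion; converted to percentage points), `age`,
#'   `sex`, `subtype`, `patient`.
#' @return list: `fit`, `HR`, `ci` (95%), `p`, `log_hr`, `robust_se`.
#' @export
cox_marker <- function(records) {
  if (sum(records$event) == 0) stop("no events in the data")
  d <- records
  d$fraction_pct <- 100 * d$fraction
  d$subtype <- stats::relevel(factor(d$subtype), ref = "classical")
  single_cluster <- length(unique(d$patient)) < 2
  if (single_cluster) {
    warning("all records share one patient cluster; ",
            "robust variance reduces to the naive variance")
    fit <- survival::coxph(
      survival::Surv(time, event) ~ fraction_pct + age + sex + subtype,
      data = d)
  } else {
    fit <- survival::coxph(
      survival::Surv(time, event) ~ fraction_pct + age + sex + subtype,
      data = d, cluster = patient)
  }
  sm <- summary(fit)
  co <- sm$coefficients["fraction_pct", ]
  se <- if (single_cluster) co[["se(coef)"]] else co[["robust se"]]
  beta <- co[["coef"]]
  ci <- exp(beta + c(-1, 1) * stats::qnorm(0.975) * se)
  if (any(is.na(stats::coef(fit)))) warning("collinear covariates dropped")
  list(fit = fit, HR = exp(beta), ci = ci,
       p = co[["Pr(>|z|)"]], log_hr = beta, robust_se = se)
}

#' Phenotype concordance across mouse replicates
#'
#' For each phenotype, the fraction of mouse replicates within a cell
#' line agreeing with the line's modal call, averaged over lines, as a
#' percentage.
#'
#' @param calls data.frame: `line`, `phenotype`, `call` (one row per
#'   mouse x phenotype).
#' @return data.frame: phenotype, concordance (percent).
#' @export
phenotype_concordance <- function(calls) {
  res <- lapply(split(calls, calls$phenotype), function(d) {
    per_line <- vapply(split(d$call, d$line), function(v) {
      tab <- table(v)
      max(tab) / length(v)
    }, 0)
    data.frame(phenotype = d$phenotype[1],
               concordance = 100 * mean(per_line))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
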