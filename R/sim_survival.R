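# Synthetic survival and tissue-microarray data: exponential event times
# with planted group and marker log-hazards, and per-core bimodal nucleus
# intensities yielding a known positive fraction under thresholding.

#' Survival/TMA specification
#'
#' @param n_subjects number of subjects (split evenly over two groups).
#' @param group_effect log-hazard of group "perivascular" vs "diffuse".
#' @param marker_beta log-hazard per percentage point of marker-positive
#'   fraction.
#' @param cores_per_subject TMA cores per subject.
#' @param nuclei_per_core nuclei per core.
#' @param censor_rate proportion of subjects censored (in [0, 1)).
#' @param baseline_hazard events per day at fraction 0 in the reference
#'   group.
#' @param fraction_range range of true marker-positive fractions (0-1).
#' @param intensity_means,intensity_sd negative/positive nucleus staining
#'   intensity modes and their sd (well separated by default).
#' @param seed integer seed.
#' @export
survival_spec <- function(n_subjects = 150L, group_effect = 0.8,
                          marker_beta = 0.02, cores_per_subject = 4L,
                          nuclei_per_core = 200L, censor_rate = 0.2,
                          baseline_hazard = 1 / 400,
                          fraction_range = c(0.1, 0.6),
                          intensity_means = c(60, 180), intensity_sd = 15,
                          seed = 1L) {
  if (n_subjects < 4) stop("need at least 2 subjects per group")
  if (censor_rate < 0 || censor_rate >= 1)
    stop("censor_rate must be in [0, 1)")
  structure(list(n_subjects = as.integer(n_subjects),
                 group_effect = group_effect, marker_beta = marker_beta,
                 cores_per_subject = as.integer(cores_per_subject),
                 nuclei_per_core = as.integer(nuclei_per_core),
                 censor_rate = censor_rate,
                 baseline_hazard = baseline_hazard,
                 fraction_range = fraction_range,
                 intensity_means = intensity_means,
                 intensity_sd = intensity_sd, seed = as.integer(seed)),
            class = "survival_spec")
}

#' Generate a survival table and per-core nucleus-intensity table
#'
#' Event times are exponential with log-hazard
#' `group_effect * I(group = perivascular) + marker_beta * fraction_pct`
#' plus small age/sex/subtype effects set to zero. Nucleus intensities per
#' core are a two-mode Gaussian mixture with exactly
#' `round(fraction * nuclei_per_core)` nuclei in the positive mode, so
#' thresholding midway between the well-separated modes recovers the
#' planted fraction.
#'
#' @param spec a [survival_spec()].
#' @return list: `survival` (subject table: time, event, group,
#'   covariates, true fraction), `nuclei` (per-nucleus intensities with
#'   patient/core ids), `threshold` (the midpoint intensity threshold),
#'   and `truth`.
#' @export
gen_survival_tma <- function(spec) {
  stopifnot(inherits(spec, "survival_spec"))
  with_seed(spec$seed, {
    n <- spec$n_subjects
    group <- rep(c("perivascular", "diffuse"), length.out = n)
    age <- round(stats::rnorm(n, 62, 9))
    sex <- sample(c("F", "M"), n, replace = TRUE)
    subtype <- factor(sample(c("classical", "mesenchymal", "proneural"),
                             n, replace = TRUE),
                      levels = c("classical", "mesenchymal", "proneural"))
    frac <- stats::runif(n, spec$fraction_range[1], spec$fraction_range[2])
    lh <- log(spec$baseline_hazard) +
      spec$group_effect * (group == "perivascular") +
      spec$marker_beta * (100 * frac)
    time <- stats::rexp(n, rate = exp(lh))
    event <- rep(1L, n)
    cens <- stats::runif(n) < spec$censor_rate
    time[cens] <- time[cens] * stats::runif(sum(cens))
    event[cens] <- 0L
    surv <- data.frame(patient = sprintf("P%03d", seq_len(n)),
                       time = pmax(time, 0.5), event = event,
                       group = group, age = age, sex = sex,
                       subtype = subtype, true_fraction = frac)

    m <- spec$nuclei_per_core; k <- spec$cores_per_subject
    pat <- rep(surv$patient, each = k * m)
    core <- rep(as.vector(vapply(seq_len(n), function(i)
      sprintf("%s_c%d", surv$patient[i], seq_len(k)), character(k))),
      each = m)
    n_pos <- round(frac * m)
    pos <- as.vector(vapply(rep(n_pos, each = k), function(np)
      sample(seq_len(m) <= np), logical(m)))
    nuclei <- data.frame(
      patient = pat, core = core,
      intensity = stats::rnorm(n * k * m,
                               spec$intensity_means[1 + pos],
                               spec$intensity_sd),
      marker = "marker1")
    list(survival = surv, nuclei = nuclei,
         threshold = mean(spec$intensity_means),
         truth = list(fraction = stats::setNames(frac, surv$patient),
                      group_effect = spec$group_effect,
                      marker_beta = spec$marker_beta))
  })
}
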