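#' Cox proportional-hazards fit for signature scores
#'
#' Partial-likelihood fit with Efron tie handling (via
#' `survival::coxph`), modeling survival on the signature score plus
#' optional demographic covariates, mirroring the standard bulk-cohort
#' validation of an expression signature. Samples with a missing covariate
#' are dropped listwise and the count reported.
#'
#' @param records Survival `data.frame` with columns `time`, `event` and
#'   the requested covariates (e.g. `score`, `age`, `sex`, `purity`).
#' @param covariates Covariate names (default `"score"` plus whichever of
#'   age, sex, purity are present).
#' @return `data.frame` (class `CoxFit`), one row per covariate: beta, hr,
#'   ci_low, ci_high (95%), wald_p; attribute `"n_dropped"`.
#' @export
cox_fit <- function(records, covariates = NULL) {
  if (is.null(covariates)) {
    covariates <- intersect(c("score", "age", "sex", "purity"), names(records))
  }
  missing_cov <- setdiff(covariates, names(records))
  if (length(missing_cov) > 0)
    stopf("covariate(s) absent: %s", paste(missing_cov, collapse = ", "))
  keep <- stats::complete.cases(records[, c("time", "event", covariates)])
  n_dropped <- sum(!keep)
  df <- records[keep, , drop = FALSE]
  if (sum(df$event) < 2) stopf("need >= 2 events")
  for (cv in covariates) {
    vals <- df[[cv]]
    if (length(unique(vals)) < 2)
      stopf("covariate '%s' is constant", cv)
  }
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(covariates, collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = "efron")
  if (any(abs(stats::coef(fit)) > 15))
    stopf("monotone likelihood (perfect separation?): |beta| > 15 for %s",
          paste(names(stats::coef(fit))[abs(stats::coef(fit)) > 15],
                collapse = ", "))
  sm <- summary(fit)
  out <- data.frame(covariate = rownames(sm$coefficients),
                    beta = sm$coefficients[, "coef"],
                    hr = sm$coefficients[, "exp(coef)"],
                    ci_low = sm$conf.int[, "lower .95"],
                    ci_high = sm$conf.int[, "upper .95"],
                    wald_p = sm$coefficients[, "Pr(>|z|)"],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  attr(out, "n_used") <- nrow(df)
  class(out) <- c("CoxFit", "data.frame")
  out
}

#' Median split into high and low score groups
#'
#' `high` = score strictly above the median; samples at or below the median
#' (including exact ties) go to `low`, so the split is deterministic and
#' invariant to monotone transforms of the scores. Group sizes are reported
#' in the `"sizes"` attribute.
#'
#' @param scores Named numeric vector, >= 2 samples, not all identical.
#' @return Named character vector of `"high"` / `"low"` labels.
#' @export
km_median_split <- function(scores) {
  if (length(scores) < 2) stopf("need >= 2 samples")
  if (length(unique(scores)) == 1) stopf("all scores identical: no split")
  med <- stats::median(scores)
  grp <- ifelse(scores > med, "high", "low")
  out <- stats::setNames(grp, names(scores))
  attr(out, "sizes") <- table(grp)
  out
}

#' Log-rank test between score groups
#'
#' @param records Survival `data.frame` with `time`, `event`, one row per
#'   sample in the order of `groups`.
#' @param groups Group labels from [km_median_split()].
#' @return Log-rank p-value.
#' @export
km_logrank <- function(records, groups) {
  sd <- survival::survdiff(survival::Surv(records$time, records$event) ~ groups)
  stats::pchisq(sd$chisq, df = length(sd$n) - 1, lower.tail = FALSE)
}

#' One-sample t-test on log hazard ratios
#'
#' Tests whether the distribution of `ln(hr)` across cohorts differs from 0
#' (default alternative: greater, i.e. hazard ratios systematically above 1).
#'
#' @param hrs Positive hazard ratios, >= 2 values, not all equal.
#' @param alternative `"greater"` (default), `"less"` or `"two_sided"`.
#' @return List with `t`, `df`, `p`.
#' @export
pooled_log_hr_test <- function(hrs, alternative = c("greater", "less",
                                                    "two_sided")) {
  alternative <- match.arg(alternative)
  if (length(hrs) < 2) stopf("need >= 2 hazard ratios")
  if (any(hrs <= 0)) stopf("hazard ratios must be positive")
  lhr <- log(hrs)
  if (stats::var(lhr) == 0) stopf("zero variance in log hazard ratios")
  alt <- c(greater = "greater", less = "less", two_sided = "two.sided")[alternative]
  ht <- stats::t.test(lhr, mu = 0, alternative = alt)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Compare signature scores between two outcome groups
#'
#' Reports which group scores higher, the Wilcoxon rank-sum p and Cohen's
#' d, the comparison used for relapse-time / progression contrasts.
#'
#' @param scores Per-sample numeric scores.
#' @param labels Binary outcome labels, same length.
#' @param alternative Passed to [wilcoxon_rank_sum()] (default two-sided).
#' @return List: `higher` (label of the higher-mean group), `p`,
#'   `cohens_d` (first level minus second level).
#' @export
compare_outcome_groups <- function(scores, labels,
                                   alternative = "two_sided") {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stopf("labels must have exactly 2 levels")
  x <- scores[labels == levels(labels)[1]]
  y <- scores[labels == levels(labels)[2]]
  if (length(x) == 0 || length(y) == 0) stopf("both groups must be non-empty")
  w <- wilcoxon_rank_sum(x, y, alternative)
  d <- cohens_d(x, y)
  list(higher = if (mean(x) >= mean(y)) levels(labels)[1] else levels(labels)[2],
       p = w$p, cohens_d = d)
}
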