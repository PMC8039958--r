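#' Pearson correlation of true vs predicted hypoxia fraction, per cohort
#'
#' For each cohort (train/val/test), the sample Pearson correlation between
#' the per-slice true hypoxia fraction (PIMO-positive fraction) and the
#' predicted hypoxia fraction, with the two-sided p-value and the regression
#' line (a non-zero intercept is expected from patch-based window labeling,
#' so a regression line rather than the identity line is the right visual).
#'
#' @param pairs data frame with columns `cohort`, `true_fraction`,
#'   `predicted_fraction` (and optionally `slice_id`).
#' @return data frame with one row per cohort: `cohort`, `n`, `r`, `p`,
#'   `slope`, `intercept`. Cohorts with zero variance in either variable get
#'   `NA` correlation.
#' @export
pearson_by_cohort <- function(pairs) {
  stopifnot(all(c("cohort", "true_fraction", "predicted_fraction") %in% names(pairs)))
  res <- lapply(split(pairs, pairs$cohort), function(d) {
    if (nrow(d) < 3L)
      stop("cohort '", d$cohort[1], "' has fewer than 3 slices")
    if (sd(d$true_fraction) == 0 || sd(d$predicted_fraction) == 0) {
      warning("zero variance in cohort '", d$cohort[1],
              "'; correlation undefined", call. = FALSE)
      return(data.frame(cohort = d$cohort[1], n = nrow(d), r = NA_real_,
                        p = NA_real_, slope = NA_real_, intercept = NA_real_))
    }
    ct <- cor.test(d$true_fraction, d$predicted_fraction)
    fit <- lm(predicted_fraction ~ true_fraction, data = d)
    data.frame(cohort = d$cohort[1], n = nrow(d),
               r = unname(ct$estimate), p = ct$p.value,
               slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

.scores_labels <- function(records) {
  if (is.data.frame(records)) {
    stopifnot(all(c("pre_therapy_fraction", "responder") %in% names(records)))
    list(scores = records$pre_therapy_fraction,
         labels = as.integer(records$responder))
  } else {
    stop("`records` must be a data frame of response records")
  }
}

#' Area under the ROC curve (rank formulation)
#'
#' AUROC of the pre-therapy predicted hypoxia fraction for responder status,
#' computed with the rank (Mann-Whitney) formulation; ties are handled by
#' midranks.
#'
#' @param records data frame with columns `pre_therapy_fraction` and
#'   `responder` (0/1 or logical).
#' @return numeric AUROC in `[0, 1]`.
#' @export
auroc <- function(records) {
  sl <- .scores_labels(records)
  y <- sl$labels
  if (length(unique(y)) < 2L) stop("both responder classes must be present")
  r <- rank(sl$scores)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Optimal cutoff by Youden's index
#'
#' Scans the observed fractions as candidate cutoffs (rule: predict responder
#' when the fraction is at or above the cutoff) and returns the cutoff
#' maximizing sensitivity + specificity - 1, with ties resolved toward the
#' lowest cutoff.
#'
#' @inheritParams auroc
#' @return list with `cutoff`, `sensitivity`, `specificity`, `youden`.
#' @export
youden_cutoff <- function(records) {
  sl <- .scores_labels(records)
  y <- sl$labels
  if (length(unique(y)) < 2L) stop("both responder classes must be present")
  x <- sl$scores
  cand <- sort(unique(x))
  best <- list(cutoff = NA_real_, youden = -Inf)
  for (cc in cand) {
    pred <- x >= cc
    sens <- sum(pred & y == 1) / sum(y == 1)
    spec <- sum(!pred & y == 0) / sum(y == 0)
    j <- sens + spec - 1
    if (j > best$youden + 1e-12) {
      best <- list(cutoff = cc, sensitivity = sens, specificity = spec,
                   youden = j)
    }
  }
  best
}

#' Dichotomize survival into responder status
#'
#' @param survival_days non-negative integer vector.
#' @param cutoff_days survival cutoff defining response (cohort-dependent;
#'   e.g. the 14-day median-survival dichotomy).
#' @return integer 0/1 responder indicator (`survival_days > cutoff_days`).
#' @export
responder_from_survival <- function(survival_days, cutoff_days = 14) {
  if (any(survival_days < 0)) stop("survival_days must be non-negative")
  as.integer(survival_days > cutoff_days)
}

#' Longitudinal hypoxia-fraction table
#'
#' Tidies time-indexed hypoxia fractions into one row per (subject, day) with
#' the change from the pre-therapy (earliest) measurement, ready for standard
#' survival/longitudinal tooling and for pre-vs-last-day comparisons.
#'
#' @param fractions data frame with columns `subject`, `day`,
#'   `hypoxia_fraction`.
#' @return data frame `(subject, day, hypoxia_fraction, delta)` ordered by
#'   subject and day; `delta` is the difference from each subject's first
#'   timepoint.
#' @export
longitudinal_table <- function(fractions) {
  stopifnot(all(c("subject", "day", "hypoxia_fraction") %in% names(fractions)))
  if (nrow(fractions) < 1L) stop("at least one timepoint is required")
  out <- fractions[order(fractions$subject, fractions$day),
                   c("subject", "day", "hypoxia_fraction")]
  base <- tapply(seq_len(nrow(out)), out$subject, function(i) i[1])
  pre <- out$hypoxia_fraction[base[as.character(out$subject)]]
  out$delta <- out$hypoxia_fraction - pre
  rownames(out) <- NULL
  out
}
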