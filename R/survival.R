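# Survival analysis: Kaplan-Meier curves, log-rank tests, score-based group
# assignment within subtype, and random-gene-set permutation of prognostic
# power. Estimation and testing run through the survival package behind this
# module's surface.

#' Kaplan-Meier estimate
#'
#' Product-limit estimator of the survival function for one group, with the
#' median survival time where the curve crosses 0.5 (NA when it never does).
#'
#' @param times non-negative survival/censoring times.
#' @param events event indicator (1 = event, 0 = censored).
#' @param group label attached to the curve (default `"all"`).
#' @return a `KMCurve` data frame (time, n_risk, n_event, n_censor, surv)
#'   with attributes `median` and `group`.
#' @export
km_estimate <- function(times, events, group = "all") {
  if (any(times < 0)) stop("times must be >= 0")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  df <- data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                   n_censor = fit$n.censor, surv = fit$surv)
  med <- unname(summary(fit)$table["median"])
  structure(df, median = med, group = group, class = c("KMCurve", class(df)))
}

#' Survival probability at a time point
#' @param curve a `KMCurve`.
#' @param t time point.
#' @return estimated S(t) (1 before the first event time).
#' @export
km_surv_at <- function(curve, t) {
  idx <- which(curve$time <= t)
  if (length(idx) == 0L) return(1)
  curve$surv[max(idx)]
}

#' Log-rank test
#'
#' Standard log-rank comparison of k groups: per event time, observed versus
#' hypergeometric-expected events; the statistic is chi-squared with k - 1
#' degrees of freedom.
#'
#' @param times,events survival data.
#' @param groups group label per subject (>= 2 groups, each non-empty).
#' @return list: statistic, df, p.
#' @export
logrank_test <- function(times, events, groups) {
  groups <- as.character(groups)
  if (length(unique(groups)) < 2L) stop("need >= 2 groups")
  sd_ <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- length(sd_$n) - 1L
  list(statistic = unname(sd_$chisq), df = df,
       p = stats::pchisq(sd_$chisq, df = df, lower.tail = FALSE))
}

#' Assign survival groups by score within a subtype
#'
#' Within the subtype of interest, samples are median-split into high/low
#' score groups (ties go to low); samples of every other subtype keep their
#' subtype as their own group. The same operation serves signature-score and
#' single-gene stratification.
#'
#' @param scores named numeric (or `ActivityScores`) vector over samples.
#' @param cohort a `CohortTable`.
#' @param subtype_of_interest subtype to split (e.g. `"LumA"`); `NULL` splits
#'   the whole cohort into high/low.
#' @return character vector of group labels aligned to `cohort$sample_id`.
#' @export
assign_groups <- function(scores, cohort, subtype_of_interest = NULL) {
  s <- as.numeric(scores)[match(cohort$sample_id, names(scores))]
  if (anyNA(s)) stop("every cohort sample needs a score")
  in_sub <- if (is.null(subtype_of_interest)) rep(TRUE, nrow(cohort)) else {
    cohort$subtype == subtype_of_interest
  }
  if (!any(in_sub)) stop("no sample in the subtype of interest")
  ssub <- s[in_sub]
  if (stats::sd(ssub) == 0) stop("all scores equal within the subtype: no split possible")
  med <- stats::median(ssub)
  lab <- if (is.null(subtype_of_interest)) "" else paste0(subtype_of_interest, "_")
  out <- cohort$subtype
  out[in_sub] <- ifelse(ssub > med, paste0(lab, "high"), paste0(lab, "low"))
  out
}

#' Random-gene-set permutation of prognostic power
#'
#' Computes the log-rank p of the stratification induced by the classifier's
#' mean z-expression, then repeats the identical procedure for `n_iter`
#' uniform random gene sets of the same size; the empirical p is
#' `(1 + #\{null p <= observed p\}) / (n_iter + 1)`.
#'
#' @param matrix gene x sample `ExpressionMatrix`.
#' @param cohort a `CohortTable` (samples matched by id).
#' @param classifier character vector of classifier gene ids.
#' @param n_iter number of random sets (default 1000).
#' @param seed integer seed.
#' @param subtype_of_interest passed to [assign_groups()].
#' @return a `PrognosticPermutation`: observed_p, null_p, empirical_p,
#'   percentile.
#' @export
sigcheck_permutation <- function(matrix, cohort, classifier, n_iter = 1000L,
                                 seed = 17L, subtype_of_interest = NULL) {
  z <- zscore_by_gene(matrix)
  genes <- rownames(z)
  cl <- intersect(unique(classifier), genes)
  if (length(cl) == 0L) stop("no classifier gene present in the matrix")
  p_of <- function(set) {
    sc <- activity_score(z, set, zscored = TRUE)
    grp <- assign_groups(sc, cohort, subtype_of_interest)
    logrank_test(cohort$time, cohort$event, grp)$p
  }
  observed <- p_of(cl)
  null_p <- with_seed(seed, {
    vapply(seq_len(n_iter), function(i) p_of(sample(genes, length(cl))), numeric(1))
  })
  emp <- (1 + sum(null_p <= observed)) / (n_iter + 1)
  structure(list(observed_p = observed, null_p = null_p, empirical_p = emp,
                 percentile = mean(null_p > observed)),
            class = "PrognosticPermutation")
}

#' @export
print.PrognosticPermutation <- function(x, ...) {
  cat(sprintf("PrognosticPermutation: observed log-rank p %.3g, empirical p %.4g (%d nulls)\n",
              x$observed_p, x$empirical_p, length(x$null_p)))
  invisible(x)
}
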