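# Median-split survival analysis: Kaplan-Meier product-limit curves and a
# two-group log-rank test, the in-package replacement for web-portal
# survival screens of candidate genes.

#' Construct a survival cohort
#'
#' Per-sample expression value, follow-up time (days) and event indicator
#' (1 = event observed, 0 = censored).
#'
#' @param records data.frame with columns `sample`, `expression`, `time`,
#'   `event`.
#' @return a `survival_cohort` (validated data.frame).
#' @export
survival_cohort <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("sample", "expression", "time", "event")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols))
    stop("cohort lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  records <- records[, need]
  records$sample <- as.character(records$sample)
  records$expression <- as.numeric(records$expression)
  records$time <- as.numeric(records$time)
  records$event <- as.integer(records$event)
  if (anyDuplicated(records$sample))
    stop("duplicate sample ids: ",
         paste(unique(records$sample[duplicated(records$sample)]),
               collapse = ", "), call. = FALSE)
  if (any(is.na(records$time)) || any(records$time < 0))
    stop("follow-up times must be non-negative", call. = FALSE)
  if (!all(records$event %in% c(0L, 1L)))
    stop("event indicator must be 0 (censored) or 1 (event)", call. = FALSE)
  if (any(is.na(records$expression)))
    stop("expression values must not be missing", call. = FALSE)
  rownames(records) <- NULL
  structure(records, class = c("survival_cohort", "data.frame"))
}

#' Split a cohort at the median expression value
#'
#' Dichotomizes the cohort into a high-expression group (expression
#' strictly above the median) and a low-expression group (expression at or
#' below the median; ties go to the low group, deterministically).
#'
#' @param cohort a [survival_cohort] with at least 4 samples.
#' @return list with elements `high`, `low` (both `survival_cohort`) and
#'   `cutoff` (the median used).
#' @export
median_split <- function(cohort) {
  cohort <- survival_cohort(cohort)
  if (nrow(cohort) < 4L)
    stop("median split needs at least 4 samples", call. = FALSE)
  med <- stats::median(cohort$expression)
  hi <- cohort$expression > med
  if (!any(hi) || all(hi))
    stop("expression values admit no median split (all on one side)",
         call. = FALSE)
  list(high = survival_cohort(cohort[hi, , drop = FALSE]),
       low = survival_cohort(cohort[!hi, , drop = FALSE]),
       cutoff = med)
}

#' Kaplan-Meier product-limit curve
#'
#' The nonparametric survival estimate S(t) = prod over event times t_i <= t
#' of (1 - d_i / n_i), where d_i is the number of events and n_i the number
#' at risk at t_i; censored samples leave the risk set after their
#' follow-up time. Computed with [survival::survfit()].
#'
#' @param group a nonempty [survival_cohort].
#' @return a `km_curve`: data.frame with columns `time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival` (right-continuous step function;
#'   S = 1 before the first event).
#' @export
km_estimate <- function(group) {
  group <- survival_cohort(group)
  if (nrow(group) == 0L)
    stop("cannot estimate a survival curve on an empty group", call. = FALSE)
  fit <- survival::survfit(
    survival::Surv(time, event) ~ 1,
    data = as.data.frame(group)
  )
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    survival = fit$surv, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("km_curve", "data.frame"))
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' @param curve a `km_curve`.
#' @param times numeric vector of evaluation times.
#' @return numeric vector S(times) (1 before the first curve time).
#' @export
km_survival_at <- function(curve, times) {
  stopifnot(inherits(curve, "km_curve"))
  vapply(times, function(t) {
    i <- which(curve$time <= t)
    if (length(i) == 0L) 1 else curve$survival[max(i)]
  }, numeric(1))
}

#' Two-group log-rank test
#'
#' Standard Mantel-Haenszel log-rank test: at each distinct event time the
#' risk sets are pooled, expected events are allotted proportionally to
#' each group's at-risk share, and the chi-square statistic (1 df) compares
#' observed with expected totals using the hypergeometric variance.
#' Computed with [survival::survdiff()].
#'
#' @param g1,g2 nonempty [survival_cohort]s with at least one event in
#'   total.
#' @param alpha significance threshold for the `significant` flag
#'   (default 0.1, the screening convention this replaces).
#' @return a `logrank_result`: list with `observed`, `expected` (length-2
#'   numeric), `chi_square`, `p_value`, `significant`, `alpha`.
#' @export
logrank_test <- function(g1, g2, alpha = 0.1) {
  g1 <- survival_cohort(g1); g2 <- survival_cohort(g2)
  if (nrow(g1) == 0L || nrow(g2) == 0L)
    stop("both groups must be nonempty", call. = FALSE)
  if (sum(g1$event) + sum(g2$event) == 0L)
    stop("log-rank test needs at least one event across the groups",
         call. = FALSE)
  df <- rbind(
    data.frame(time = g1$time, event = g1$event, group = 1L),
    data.frame(time = g2$time, event = g2$event, group = 2L)
  )
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  chi <- as.numeric(sd$chisq)
  p <- stats::pchisq(chi, df = 1, lower.tail = FALSE)
  structure(
    list(observed = as.numeric(sd$obs), expected = as.numeric(sd$exp),
         chi_square = chi, p_value = p, significant = p < alpha,
         alpha = alpha),
    class = "logrank_result"
  )
}

#' @export
print.logrank_result <- function(x, ...) {
  cat("<logrank_result>\n")
  cat(sprintf("  observed events: %s\n",
              paste(format(x$observed), collapse = " vs ")))
  cat(sprintf("  expected events: %s\n",
              paste(format(round(x$expected, 2)), collapse = " vs ")))
  cat(sprintf("  chi-square = %.4f, p = %.4g (%ssignificant at %.2g)\n",
              x$chi_square, x$p_value, if (x$significant) "" else "not ",
              x$alpha))
  invisible(x)
}

#' Median-split survival screen for one gene
#'
#' Convenience wrapper: [median_split()] the cohort, fit both
#' Kaplan-Meier curves and run the log-rank test.
#'
#' @param cohort a [survival_cohort].
#' @inheritParams logrank_test
#' @return list with `high_curve`, `low_curve` (`km_curve`), `logrank`
#'   (`logrank_result`), `cutoff`, and group sizes `n_high`, `n_low`.
#' @export
survival_screen <- function(cohort, alpha = 0.1) {
  sp <- median_split(cohort)
  list(high_curve = km_estimate(sp$high),
       low_curve = km_estimate(sp$low),
       logrank = logrank_test(sp$high, sp$low, alpha = alpha),
       cutoff = sp$cutoff,
       n_high = nrow(sp$high), n_low = nrow(sp$low))
}
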