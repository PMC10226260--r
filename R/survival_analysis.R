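## Kaplan-Meier estimation, two-group log-rank testing, and expression
## dichotomization by median or best cut-off. Estimation and testing are
## delegated to the survival package behind a validated interface.

.check_surv <- function(time, event) {
  if (!is.numeric(time) || any(!is.finite(time)) || any(time < 0))
    stop("survival times must be finite and >= 0", call. = FALSE)
  if (!all(event %in% c(0, 1)))
    stop("events must be 0 (censored) or 1 (event)", call. = FALSE)
  if (length(time) != length(event))
    stop("time and event lengths differ", call. = FALSE)
}

#' Kaplan-Meier product-limit curve
#'
#' @param time Follow-up times (days), >= 0.
#' @param event 1 = event, 0 = censored.
#' @return data.frame with columns time, n_risk, n_event, surv; S(0) = 1
#'   is implicit, the curve is non-increasing, and censored-only data give
#'   S identically 1.
#' @export
km_curve <- function(time, event) {
  .check_surv(time, event)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             surv = fit$surv)
}

#' Two-group log-rank test
#'
#' Standard log-rank: statistic (sum(O) - sum(E))^2 / sum(V) over event
#' times, referred to chi-square with 1 df.
#'
#' @param time,event As in [km_curve()].
#' @param group Two-level group labels.
#' @return List with `statistic`, `p_value`, `observed`, `expected` (per
#'   group).
#' @export
logrank_test <- function(time, event, group) {
  .check_surv(time, event)
  g <- factor(group)
  if (nlevels(g) != 2L || any(table(g) == 0L))
    stop("need exactly two non-empty groups", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ g)
  list(statistic = unname(sd$chisq),
       p_value = stats::pchisq(sd$chisq, df = 1L, lower.tail = FALSE),
       observed = sd$obs, expected = sd$exp)
}

#' Dichotomize survival by expression
#'
#' Median mode splits at the median of log2-transformed expression
#' (high = strictly greater). Best-cutoff mode evaluates every distinct
#' observed value between the 10th and 90th percentile (the median always
#' included), picks the cutoff minimizing the log-rank p-value, and
#' returns that unadjusted p flagged as optimization-biased: minimizing p
#' over a grid is anti-conservative and the returned p-value must not be
#' read as a calibrated test.
#'
#' A gene whose expression sum across samples falls below
#' `expr_filter_min_sum` (the usual at-least-1-FPKM-in-sum filter) is
#' reported as filtered out, not an error.
#'
#' @param values Per-sample expression, aligned with `time`/`event`;
#'   linear scale unless `log_transform = FALSE`.
#' @param time,event Survival data as in [km_curve()].
#' @param method "median" or "best_cutoff".
#' @param expr_filter_min_sum Minimum expression sum (default 1).
#' @param log_transform Apply log2(v + 1) before splitting (default TRUE).
#' @return List with `passed_filter`, and when TRUE: `labels`
#'   ("low"/"high"), `cutoff` (on the analysis scale), `p_value`,
#'   `statistic`, `method`, `optimization_biased`.
#' @export
split_by_expression <- function(values, time, event,
                                method = c("median", "best_cutoff"),
                                expr_filter_min_sum = 1,
                                log_transform = TRUE) {
  method <- match.arg(method)
  .check_surv(time, event)
  if (length(values) != length(time))
    stop("expression values not aligned with survival data", call. = FALSE)
  if (sum(values) < expr_filter_min_sum)
    return(list(passed_filter = FALSE, method = method))
  v <- if (log_transform) log2(values + 1) else values
  if (stats::sd(v) == 0)
    stop("constant expression: no valid split", call. = FALSE)
  split_p <- function(cut) {
    hi <- v > cut
    if (!any(hi) || all(hi)) return(NULL)
    lr <- logrank_test(time, event, ifelse(hi, "high", "low"))
    list(cut = cut, p = lr$p_value, stat = lr$statistic, hi = hi)
  }
  if (method == "median") {
    res <- split_p(stats::median(v))
    if (is.null(res)) stop("median split leaves an empty group", call. = FALSE)
  } else {
    qq <- stats::quantile(v, c(0.1, 0.9), names = FALSE)
    cands <- sort(unique(c(v[v >= qq[1L] & v <= qq[2L]], stats::median(v))))
    fits <- Filter(Negate(is.null), lapply(cands, split_p))
    if (!length(fits)) stop("no candidate cutoff yields two groups", call. = FALSE)
    res <- fits[[which.min(vapply(fits, `[[`, 0, "p"))]]
  }
  list(passed_filter = TRUE,
       labels = ifelse(res$hi, "high", "low"),
       cutoff = res$cut, p_value = res$p, statistic = res$stat,
       method = method, optimization_biased = method == "best_cutoff")
}
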