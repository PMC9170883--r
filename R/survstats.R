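# Survival validation statistics: Kaplan-Meier curves, log-rank tests,
# univariate Cox hazard ratios, reverse-KM follow-up. KM and Cox estimation
# delegate to the survival package; the log-rank statistic is computed
# in-package because the cutpoint scan needs it as a fast primitive.

#' Kaplan-Meier curve
#'
#' Product-limit estimate of the survival function. At tied times, events are
#' handled before censorings (the standard convention).
#'
#' @param times Nonnegative follow-up times (months).
#' @param events Logical (or 0/1) event indicators.
#' @return A `km_curve` object: list with `event_times` (distinct times with
#'   at least one event, sorted), `survival_probs` (the estimate just after
#'   each event time), `at_risk` (numbers at risk at each event time),
#'   `n_events` (events at each event time), `censor_times`, `n` and
#'   `max_time`.
#' @export
km_curve <- function(times, events) {
  events <- as.logical(events)
  if (length(times) == 0) stop("empty survival input", call. = FALSE)
  stopifnot(length(times) == length(events), all(is.finite(times)),
            all(times >= 0))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "none")
  keep <- fit$n.event > 0
  structure(list(
    event_times = fit$time[keep],
    survival_probs = fit$surv[keep],
    at_risk = fit$n.risk[keep],
    n_events = fit$n.event[keep],
    censor_times = sort(times[!events]),
    n = length(times),
    max_time = max(times)
  ), class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> n = %d, %d event times, median %s months\n",
              x$n, length(x$event_times), format(km_median(x))))
  invisible(x)
}

#' Survival probability at a time point
#'
#' Evaluates the right-continuous Kaplan-Meier step function.
#'
#' @param curve A `km_curve`.
#' @param t Time (months), nonnegative; vectorized.
#' @return Numeric vector of survival probabilities. Queries beyond the last
#'   observed time return the last value and set the attribute
#'   `"extrapolated"` to a logical vector flagging them.
#' @export
survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"), all(t >= 0))
  if (length(curve$event_times) == 0) {
    out <- rep(1, length(t))
  } else {
    f <- stats::stepfun(curve$event_times, c(1, curve$survival_probs),
                        right = FALSE)
    out <- f(t)
  }
  extrap <- t > curve$max_time
  if (any(extrap)) {
    warning("survival queried beyond the last observed time; returning the last estimate",
            call. = FALSE)
  }
  attr(out, "extrapolated") <- extrap
  out
}

#' Kaplan-Meier median (with IQR-style quantiles)
#'
#' @param curve A `km_curve`.
#' @param p Probability levels (default median plus quartiles).
#' @return Named numeric vector of the times at which survival first drops to
#'   `1 - p`; `NA` when the curve never reaches that level.
#' @export
km_median <- function(curve, p = c(0.25, 0.5, 0.75)) {
  stopifnot(inherits(curve, "km_curve"))
  out <- vapply(p, function(pp) {
    idx <- which(curve$survival_probs <= 1 - pp)
    if (length(idx) == 0) NA_real_ else curve$event_times[min(idx)]
  }, numeric(1))
  names(out) <- paste0("q", format(p))
  out
}

# Fast two-group log-rank chi-square. `grp` is logical (TRUE = group 1).
# Vectorized over distinct event times: O - E with hypergeometric variance.
logrank2_chisq <- function(times, events, grp) {
  ord <- order(times)
  t_s <- times[ord]; e_s <- events[ord]; g_s <- grp[ord]
  n <- length(t_s)
  # at-risk counts just before each sorted position
  risk_total <- n - seq_len(n) + 1L
  risk_g1 <- rev(cumsum(rev(g_s)))
  ev_idx <- which(e_s)
  if (length(ev_idx) == 0) return(c(chisq = NA_real_, o_minus_e = NA_real_, var = NA_real_))
  tf <- factor(t_s[ev_idx], levels = unique(t_s[ev_idx]))
  d <- as.vector(rowsum(rep(1L, length(ev_idx)), tf))          # events at t
  d1 <- as.vector(rowsum(as.integer(g_s[ev_idx]), tf))         # group-1 events
  first_idx <- ev_idx[!duplicated(t_s[ev_idx])]
  # at risk at each distinct event time = counts at first occurrence of that time
  first_at_time <- match(t_s[first_idx], t_s)                  # first row with that time
  N <- risk_total[first_at_time]
  N1 <- risk_g1[first_at_time]
  E1 <- d * N1 / N
  Vt <- d * (N1 / N) * (1 - N1 / N) * (N - d) / pmax(N - 1, 1)
  o_minus_e <- sum(d1 - E1)
  v <- sum(Vt)
  chisq <- if (v > 0) o_minus_e^2 / v else 0
  c(chisq = chisq, o_minus_e = o_minus_e, var = v)
}

#' Log-rank test
#'
#' Standard observed-minus-expected chi-square with hypergeometric variance,
#' on two or more groups; degrees of freedom one less than the number of
#' groups.
#'
#' @param groups A list with one element per group, each a list (or data
#'   frame) holding `times` and `events`.
#' @return A `logrank_result` list: `chi_square`, `p_value`, `df`,
#'   `observed` and `expected` event counts per group, `n` per group.
#' @export
logrank_test <- function(groups) {
  k <- length(groups)
  if (k < 2) stop("at least two groups required", call. = FALSE)
  ns <- vapply(groups, function(g) length(g$times), integer(1))
  if (any(ns == 0)) stop("empty group", call. = FALSE)
  times <- unlist(lapply(groups, function(g) as.numeric(g$times)))
  events <- unlist(lapply(groups, function(g) as.logical(g$events)))
  gid <- rep(seq_len(k), ns)
  if (!any(events)) stop("no events in any group", call. = FALSE)

  ord <- order(times)
  t_s <- times[ord]; e_s <- events[ord]; g_s <- gid[ord]
  n <- length(t_s)
  ev_times <- unique(t_s[e_s])
  O <- numeric(k); E <- numeric(k)
  V <- matrix(0, k, k)
  for (t in ev_times) {
    at_risk <- t_s >= t
    N <- sum(at_risk)
    d <- sum(e_s & t_s == t)
    nj <- vapply(seq_len(k), function(j) sum(at_risk & g_s == j), numeric(1))
    dj <- vapply(seq_len(k), function(j) sum(e_s & t_s == t & g_s == j), numeric(1))
    O <- O + dj
    E <- E + d * nj / N
    if (N > 1) {
      mult <- d * (N - d) / (N^2 * (N - 1))
      V <- V + mult * (N * diag(nj, k) - outer(nj, nj))
    }
  }
  x <- (O - E)[-k]
  Vsub <- V[-k, -k, drop = FALSE]
  chisq <- tryCatch(as.numeric(t(x) %*% solve(Vsub, x)),
                    error = function(e) {
                      # singular variance (e.g. a group with no one at risk at
                      # event times): fall back to a generalized inverse
                      sv <- svd(Vsub)
                      pos <- sv$d > max(sv$d) * 1e-12
                      as.numeric(t(x) %*% sv$v[, pos, drop = FALSE] %*%
                                   diag(1 / sv$d[pos], sum(pos)) %*%
                                   t(sv$u[, pos, drop = FALSE]) %*% x)
                    })
  df <- k - 1
  structure(list(
    chi_square = chisq,
    p_value = stats::pchisq(chisq, df = df, lower.tail = FALSE),
    df = df, observed = O, expected = E, n = ns
  ), class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("<logrank> chi-square = %.3f on %d df, p = %.4g\n",
              x$chi_square, x$df, x$p_value))
  invisible(x)
}

#' Univariate Cox proportional-hazards model on a binary indicator
#'
#' Partial-likelihood estimate with Efron tie handling, Wald confidence
#' interval and p-value — the hazard ratio of indicator-positive patients
#' (e.g. responders) versus the rest.
#'
#' @param indicator Logical vector (e.g. responder flag).
#' @param times Follow-up times (months).
#' @param events Event indicators.
#' @param conf_level Confidence level for the Wald interval (default 0.95).
#' @return A `cox_result` list: `hazard_ratio`, `ci_low`, `ci_high`,
#'   `p_value`, `log_hr`, `se_log_hr`, `n`, `n_events`.
#' @export
cox_univariate <- function(indicator, times, events, conf_level = 0.95) {
  indicator <- as.logical(indicator)
  events <- as.logical(events)
  stopifnot(length(indicator) == length(times),
            length(times) == length(events))
  if (length(unique(indicator)) < 2) {
    stop("both indicator levels must be present", call. = FALSE)
  }
  if (!any(events)) stop("no events", call. = FALSE)
  ev_by_level <- tapply(events, indicator, sum)
  if (any(ev_by_level == 0)) {
    warning("one indicator level has no events: the partial likelihood is monotone and the estimate may diverge",
            call. = FALSE)
  }
  fit <- survival::coxph(survival::Surv(times, events) ~ indicator,
                         ties = "efron")
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(
    hazard_ratio = exp(beta),
    ci_low = exp(beta - z * se),
    ci_high = exp(beta + z * se),
    p_value = 2 * stats::pnorm(-abs(beta / se)),
    log_hr = beta, se_log_hr = se,
    n = length(times), n_events = sum(events)
  ), class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("<cox> HR = %.3f (%.3f, %.3f), p = %.4g, %d events / %d\n",
              x$hazard_ratio, x$ci_low, x$ci_high, x$p_value,
              x$n_events, x$n))
  invisible(x)
}

#' Median follow-up by the reverse Kaplan-Meier estimate
#'
#' Swaps the roles of events and censorings: censored observations become the
#' "events" of a follow-up distribution whose KM median estimates the median
#' follow-up duration.
#'
#' @param times Follow-up times (months).
#' @param events Event indicators (the original endpoint events).
#' @return List with `median_months` (`NA` when undefined) and `status`
#'   (`"ok"` or `"undefined"` when no observation is censored).
#' @export
reverse_km_followup <- function(times, events) {
  events <- as.logical(events)
  if (!any(!events)) {
    return(list(median_months = NA_real_, status = "undefined"))
  }
  curve <- km_curve(times, !events)
  med <- unname(km_median(curve, p = 0.5))
  list(median_months = med, status = "ok")
}

#' Survival rates at landmark times
#'
#' @param times,events Survival input.
#' @param at Landmark times in months (default 12, 24, 36 — the 1/2/3-year
#'   rates).
#' @return Tibble with `time_months` and `survival`.
#' @export
survival_rates <- function(times, events, at = c(12, 24, 36)) {
  curve <- km_curve(times, events)
  s <- suppressWarnings(survival_at(curve, at))
  tibble::tibble(time_months = at, survival = as.numeric(s))
}
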