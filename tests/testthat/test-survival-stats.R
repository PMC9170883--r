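test_that("KM matches the hand product-limit on the textbook six-subject set", {
  # {6, 6, 6, 7+, 10, 10+}: S(6) = 1 - 3/6 = 0.5; S(10) = 0.5 * (1 - 1/2) = 0.25
  curve <- km_curve(c(6, 6, 6, 7, 10, 10), c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(curve$event_times, c(6, 10))
  expect_equal(curve$survival_probs, c(0.5, 0.25))
  expect_equal(curve$at_risk, c(6, 2))
})

test_that("KM degenerate cases: all censored, all events, empty input", {
  all_cens <- km_curve(c(5, 8, 12), c(FALSE, FALSE, FALSE))
  expect_equal(as.numeric(survival_at(all_cens, c(0, 4, 12))), c(1, 1, 1))
  all_ev <- km_curve(c(1, 2, 3), c(TRUE, TRUE, TRUE))
  expect_equal(tail(all_ev$survival_probs, 1), 0)
  expect_error(km_curve(numeric(0), logical(0)), "empty")
})

test_that("KM without censoring equals the empirical survival function", {
  set.seed(501)
  for (rep in 1:3) {
    times <- round(rexp(40, 1 / 20), 1)
    curve <- km_curve(times, rep(TRUE, 40))
    at <- sort(unique(times))
    expect_equal(as.numeric(survival_at(curve, at)),
                 vapply(at, function(t) mean(times > t), numeric(1)))
  }
})

test_that("survival_at is right-continuous and flags extrapolation", {
  curve <- km_curve(c(6, 6, 6, 7, 10, 10), c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(as.numeric(survival_at(curve, 0)), 1)
  expect_equal(as.numeric(survival_at(curve, 5.999)), 1)
  expect_equal(as.numeric(survival_at(curve, 6)), 0.5)
  expect_warning(out <- survival_at(curve, 15), "beyond")
  expect_equal(as.numeric(out), 0.25)
  expect_true(attr(out, "extrapolated"))
})

test_that("S(median) of an exponential cohort is near one half", {
  set.seed(77)
  times <- rexp(4000, rate = log(2) / 18)
  curve <- km_curve(times, rep(TRUE, 4000))
  expect_equal(as.numeric(survival_at(curve, 18)), 0.5, tolerance = 0.05)
})

test_that("log-rank agrees with the from-scratch O/E oracle and survdiff", {
  set.seed(31)
  for (rep in 1:5) {
    n <- 60
    grp <- rep(c(TRUE, FALSE), each = n / 2)
    times <- round(rexp(n, ifelse(grp, 1 / 30, 1 / 15)), 0) + 1
    events <- runif(n) < 0.8
    lr <- logrank_test(list(
      list(times = times[grp], events = events[grp]),
      list(times = times[!grp], events = events[!grp])))
    expect_equal(lr$chi_square, oracle_logrank2(times, events, grp),
                 tolerance = 1e-10)
    sd_fit <- survival::survdiff(survival::Surv(times, events) ~ grp)
    expect_equal(lr$chi_square, sd_fit$chisq, tolerance = 1e-8)
    # observed totals match expected totals
    expect_equal(sum(lr$observed), sum(lr$expected))
  }
})

test_that("log-rank is symmetric in group order and zero for identical groups", {
  times <- c(3, 5, 8, 11, 14, 20)
  events <- c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE)
  same <- logrank_test(list(list(times = times, events = events),
                            list(times = times, events = events)))
  expect_equal(same$chi_square, 0, tolerance = 1e-12)
  a <- list(times = times, events = events)
  b <- list(times = times * 1.5 + 1, events = rev(events))
  expect_equal(logrank_test(list(a, b))$chi_square,
               logrank_test(list(b, a))$chi_square, tolerance = 1e-12)
  # invariant to a monotone rescaling of time
  a2 <- list(times = times^2, events = events)
  b2 <- list(times = (times * 1.5 + 1)^2, events = rev(events))
  expect_equal(logrank_test(list(a, b))$chi_square,
               logrank_test(list(a2, b2))$chi_square, tolerance = 1e-12)
})

test_that("Cox estimate matches a grid-search of the Efron partial likelihood", {
  times <- c(1, 2, 3, 4, 5, 6, 7, 9)
  events <- c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE)
  x <- c(1, 0, 1, 0, 1, 0, 0, 1)
  fit <- cox_univariate(x == 1, times, events)
  # agreement limited by the oracle's 1e-3 grid resolution
  expect_lt(abs(fit$log_hr - oracle_cox_grid(times, events, x)), 1e-3)
})

test_that("Cox on a null indicator gives HR near 1 and warns under monotone likelihood", {
  set.seed(99)
  n <- 3000
  ind <- rep(c(TRUE, FALSE), n / 2)
  times <- rexp(n, 1 / 20)
  fit <- cox_univariate(ind, times, rep(TRUE, n))
  expect_equal(fit$hazard_ratio, 1, tolerance = 0.1)
  expect_true(fit$ci_low <= fit$hazard_ratio && fit$hazard_ratio <= fit$ci_high)
  w <- capture_warnings(
    cox_univariate(c(TRUE, TRUE, FALSE, FALSE), c(5, 6, 2, 3),
                   c(FALSE, FALSE, TRUE, TRUE)))
  expect_true(any(grepl("monotone", w)))
  expect_error(cox_univariate(rep(TRUE, 4), 1:4, rep(TRUE, 4)), "both indicator levels")
})

test_that("two-group log-rank p approaches the Cox score-test p for large n", {
  set.seed(123)
  n <- 1000
  grp <- rep(c(TRUE, FALSE), each = n / 2)
  times <- rexp(n, ifelse(grp, 0.6 / 18, 1 / 18))
  cens <- runif(n, 12, 60)
  obs <- pmin(times, cens)
  ev <- times <= cens
  lr <- logrank_test(list(list(times = obs[grp], events = ev[grp]),
                          list(times = obs[!grp], events = ev[!grp])))
  cx <- survival::coxph(survival::Surv(obs, ev) ~ grp)
  score_p <- summary(cx)$sctest["pvalue"]
  expect_equal(lr$p_value, unname(score_p), tolerance = 1e-3)
})

test_that("reverse KM recovers follow-up duration with roles swapped", {
  # all censored at one time: that time is the follow-up median
  rk <- reverse_km_followup(rep(52.8, 10), rep(FALSE, 10))
  expect_equal(rk$median_months, 52.8)
  expect_identical(rk$status, "ok")
  # no censored observations: undefined
  rk2 <- reverse_km_followup(c(3, 8, 13), c(TRUE, TRUE, TRUE))
  expect_identical(rk2$status, "undefined")
  expect_true(is.na(rk2$median_months))
  # mixed data equal the KM median of the flipped indicator
  times <- c(4, 9, 12, 15, 22, 30, 41, 55)
  events <- c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE)
  rk3 <- reverse_km_followup(times, events)
  oracle <- unname(km_median(km_curve(times, !events), p = 0.5))
  expect_equal(rk3$median_months, oracle)
})
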