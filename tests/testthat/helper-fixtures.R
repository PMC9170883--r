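# Fixture builders and independent oracles used across the suite.

# One-lesion-per-patient cohort from per-patient scalars. afp_bl/afp_fu may be
# NA (missing AFP); percent_viable may be NA (missing pathology).
make_cohort <- function(sld_bl, sld_fu,
                        viable_bl = sld_bl * 0.8, viable_fu = sld_fu * 0.8,
                        afp_bl = rep(100, length(sld_bl)),
                        afp_fu = afp_bl,
                        new_lesions = FALSE,
                        nontarget_status = "absent",
                        rfs_months = rep(24, length(sld_bl)),
                        rfs_event = rep(TRUE, length(sld_bl)),
                        os_months = rfs_months + 6,
                        os_event = rfs_event,
                        percent_viable = rep(NA_real_, length(sld_bl)),
                        reader1 = NA_character_, reader2 = NA_character_,
                        ids = sprintf("P%03d", seq_along(sld_bl))) {
  n <- length(sld_bl)
  patients <- tibble::tibble(
    patient_id = ids,
    new_lesions = rep_len(new_lesions, n),
    nontarget_status = rep_len(nontarget_status, n),
    afp_bl = afp_bl, afp_fu = afp_fu,
    rfs_months = rfs_months, rfs_event = rfs_event,
    os_months = os_months, os_event = os_event,
    percent_viable = percent_viable,
    reader1_category = rep_len(reader1, n),
    reader2_category = rep_len(reader2, n))
  lesions <- rbind(
    tibble::tibble(patient_id = ids, lesion_id = paste0(ids, "_L1"),
                   organ = "liver", timepoint = "baseline",
                   longest_diameter_mm = sld_bl, viable_diameter_mm = viable_bl,
                   is_target = TRUE),
    tibble::tibble(patient_id = ids, lesion_id = paste0(ids, "_L1"),
                   organ = "liver", timepoint = "followup",
                   longest_diameter_mm = sld_fu, viable_diameter_mm = viable_fu,
                   is_target = TRUE))
  new_cohort(patients, lesions)
}

# The three worked-example patients: size changes -42.0%, -34.0%, -17.0% with
# AFP changes -95.8%, -15.0%, -97.4%.
worked_examples_cohort <- function() {
  make_cohort(
    sld_bl = c(100, 100, 100), sld_fu = c(58, 66, 83),
    afp_bl = c(1000, 100, 1000), afp_fu = c(42, 85, 26))
}

# From-scratch two-group log-rank oracle: explicit loop over event times,
# O - E for group 1 with hypergeometric variance. Independent of the package's
# vectorized path.
oracle_logrank2 <- function(times, events, grp) {
  ev_times <- sort(unique(times[events]))
  o_minus_e <- 0
  v <- 0
  for (t in ev_times) {
    at_risk <- times >= t
    N <- sum(at_risk)
    N1 <- sum(at_risk & grp)
    d <- sum(events & times == t)
    d1 <- sum(events & times == t & grp)
    o_minus_e <- o_minus_e + d1 - d * N1 / N
    if (N > 1) v <- v + d * (N1 / N) * (1 - N1 / N) * (N - d) / (N - 1)
  }
  if (v <= 0) return(0)
  o_minus_e^2 / v
}

# Brute-force cutpoint oracle: recompute the log-rank statistic at every
# admissible split with survival::survdiff, apply the same tie-break.
oracle_cutpoint <- function(values, times, events, min_frac = 0.10) {
  n <- length(values)
  u <- sort(unique(values))
  mids <- (u[-1] + u[-length(u)]) / 2
  floor_n <- max(floor(min_frac * n), 1L)
  chis <- rep(NA_real_, length(mids))
  n_low <- integer(length(mids))
  for (i in seq_along(mids)) {
    g <- values <= mids[i]
    n_low[i] <- sum(g)
    if (sum(g) < floor_n || sum(!g) < floor_n) next
    sd <- survival::survdiff(survival::Surv(times, events) ~ g)
    chis[i] <- sd$chisq
  }
  keep <- !is.na(chis)
  mids <- mids[keep]; chis <- chis[keep]; n_low <- n_low[keep]
  best_chi <- max(chis)
  tied <- which(chis == best_chi)
  if (length(tied) > 1) {
    balance <- abs(n_low[tied] - n / 2)
    tied <- tied[balance == min(balance)]
    tied <- tied[which.min(mids[tied])]
  }
  list(cutoff = mids[tied[1]], chi_square = best_chi)
}

# Efron partial log-likelihood for a binary covariate, maximized by grid
# search — the oracle for cox_univariate on tiny data.
oracle_efron_loglik <- function(beta, times, events, x) {
  ll <- 0
  for (t in sort(unique(times[events]))) {
    D <- which(events & times == t)
    R <- which(times >= t)
    d <- length(D)
    sum_risk <- sum(exp(beta * x[R]))
    sum_tied <- sum(exp(beta * x[D]))
    ll <- ll + beta * sum(x[D])
    for (l in seq_len(d) - 1) {
      ll <- ll - log(sum_risk - (l / d) * sum_tied)
    }
  }
  ll
}

oracle_cox_grid <- function(times, events, x, grid = seq(-4, 4, by = 1e-3)) {
  ll <- vapply(grid, oracle_efron_loglik, numeric(1),
               times = times, events = events, x = x)
  grid[which.max(ll)]
}
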