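# Synthetic cohort generator. Emulates the statistical structure the analysis
# assumes — lesion diameters, correlated size/AFP responses, censored
# exponential survival with a responder hazard reduction — so every pipeline
# stage is testable without patient data. Distribution anchors: about half of
# patients with baseline AFP >= 200 ng/ml, median baseline tumor burden 70 mm,
# mostly a single target lesion, responder hazard ratio 0.31, AFP-change step
# at -0.76 in step-hazard mode.

#' Parameters of the synthetic cohort generator
#'
#' All parameters have calibrated defaults; `n` and `seed` must be supplied.
#' Size and AFP changes are normal mixtures over a latent responder flag,
#' truncated at -1 (nothing shrinks by more than 100%). Baseline AFP is
#' lognormal with the log-mean chosen so that a fraction `afp_bl_frac_ge_200`
#' of patients exceed 200 ng/ml. Recurrence times are exponential; the hazard
#' is multiplied by `responder_hr` for latent responders (`mode = "latent"`)
#' or for patients with AFP change at or below `planted_afp_cutoff`
#' (`mode = "step-hazard"`). Censoring is uniform over `censor_window`.
#'
#' @param n Number of patients.
#' @param seed Integer seed; mandatory — the generator never touches hidden
#'   global random state (it runs under [withr::with_seed()]).
#' @param mode `"latent"` or `"step-hazard"`.
#' @param responder_prob Probability of the latent responder flag.
#' @param size_change_responder,size_change_nonresponder `c(mean, sd)` of the
#'   fractional SLD change in each mixture component.
#' @param afp_delta_responder,afp_delta_nonresponder `c(mean, sd)` of the
#'   fractional AFP change.
#' @param afp_bl_sdlog Log-sd of baseline AFP.
#' @param afp_bl_frac_ge_200 Calibration anchor: target fraction of patients
#'   with baseline AFP >= 200 ng/ml.
#' @param baseline_sld_median_mm,baseline_sld_sdlog Lognormal baseline SLD.
#' @param two_lesion_prob Probability of a second target lesion.
#' @param viable_frac_range Uniform range of the baseline viable fraction of
#'   each lesion's diameter.
#' @param viable_extra_responder,viable_extra_nonresponder `c(mean, sd)` of
#'   the additional (nonnegative) shrinkage of the viable diameter beyond the
#'   total-size change.
#' @param responder_hr Hazard ratio applied to the favorable group.
#' @param base_median_rfs_months Median recurrence-free survival of the
#'   unfavorable group.
#' @param censor_window `c(min, max)` months of the uniform censoring time.
#' @param os_increment_mean_months Mean of the exponential increment from
#'   recurrence to death.
#' @param pathology_beta `c(shape1, shape2)` of the Beta distribution of
#'   percent viable tumor (drawn independently of response).
#' @param planted_afp_cutoff Step location on the AFP change in step-hazard
#'   mode.
#' @param reader2_flip_prob Adjacent-category flip probability used by
#'   [generate_reader_pair()].
#' @return A `generator_params` list.
#' @export
generator_params <- function(n, seed,
                             mode = c("latent", "step-hazard"),
                             responder_prob = 0.5,
                             size_change_responder = c(-0.35, 0.12),
                             size_change_nonresponder = c(-0.05, 0.10),
                             afp_delta_responder = c(-0.85, 0.10),
                             afp_delta_nonresponder = c(-0.30, 0.25),
                             afp_bl_sdlog = 1.5,
                             afp_bl_frac_ge_200 = 0.487,
                             baseline_sld_median_mm = 70,
                             baseline_sld_sdlog = 0.49,
                             two_lesion_prob = 0.05,
                             viable_frac_range = c(0.6, 0.95),
                             viable_extra_responder = c(0.15, 0.05),
                             viable_extra_nonresponder = c(0.02, 0.02),
                             responder_hr = 0.31,
                             base_median_rfs_months = 18,
                             censor_window = c(12, 60),
                             os_increment_mean_months = 12,
                             pathology_beta = c(2, 1.6),
                             planted_afp_cutoff = -0.76,
                             reader2_flip_prob = 0.025) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(n), length(n) == 1, n >= 0, n == floor(n))
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop("seed is mandatory and must be a single integer", call. = FALSE)
  }
  check_prob <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
      stop(nm, " must be a probability in [0, 1]", call. = FALSE)
    }
  }
  check_prob(responder_prob, "responder_prob")
  check_prob(two_lesion_prob, "two_lesion_prob")
  check_prob(reader2_flip_prob, "reader2_flip_prob")
  check_prob(afp_bl_frac_ge_200, "afp_bl_frac_ge_200")
  for (nm in c("size_change_responder", "size_change_nonresponder",
               "afp_delta_responder", "afp_delta_nonresponder",
               "viable_extra_responder", "viable_extra_nonresponder")) {
    v <- get(nm)
    if (length(v) != 2 || !all(is.finite(v)) || v[2] <= 0) {
      stop(nm, " must be c(mean, sd) with sd > 0", call. = FALSE)
    }
  }
  stopifnot(responder_hr > 0, base_median_rfs_months > 0,
            length(censor_window) == 2, censor_window[1] > 0,
            censor_window[2] >= censor_window[1],
            baseline_sld_median_mm >= 10, baseline_sld_sdlog > 0,
            afp_bl_sdlog > 0, os_increment_mean_months > 0,
            length(viable_frac_range) == 2,
            viable_frac_range[1] > 0, viable_frac_range[2] <= 1,
            all(pathology_beta > 0),
            is.finite(planted_afp_cutoff), planted_afp_cutoff > -1,
            planted_afp_cutoff < 0)
  structure(list(
    n = n, seed = seed, mode = mode, responder_prob = responder_prob,
    size_change_responder = size_change_responder,
    size_change_nonresponder = size_change_nonresponder,
    afp_delta_responder = afp_delta_responder,
    afp_delta_nonresponder = afp_delta_nonresponder,
    afp_bl_sdlog = afp_bl_sdlog, afp_bl_frac_ge_200 = afp_bl_frac_ge_200,
    baseline_sld_median_mm = baseline_sld_median_mm,
    baseline_sld_sdlog = baseline_sld_sdlog,
    two_lesion_prob = two_lesion_prob,
    viable_frac_range = viable_frac_range,
    viable_extra_responder = viable_extra_responder,
    viable_extra_nonresponder = viable_extra_nonresponder,
    responder_hr = responder_hr,
    base_median_rfs_months = base_median_rfs_months,
    censor_window = censor_window,
    os_increment_mean_months = os_increment_mean_months,
    pathology_beta = pathology_beta,
    planted_afp_cutoff = planted_afp_cutoff,
    reader2_flip_prob = reader2_flip_prob
  ), class = "generator_params")
}

rnorm_trunc <- function(n, mean, sd, lower) pmax(stats::rnorm(n, mean, sd), lower)

#' Generate a synthetic cohort
#'
#' Deterministic given the seed in `params`. Per patient: a latent responder
#' flag; one (occasionally two) baseline target lesion(s) with follow-up
#' diameters from the size-change mixture; viable diameters shrinking faster
#' than total size in responders; an AFP pair from the baseline lognormal and
#' the AFP-change mixture; exponential recurrence-free survival with the
#' hazard reduced in the favorable group, an exponential increment to death,
#' and independent uniform censoring; pathology drawn independently of
#' response.
#'
#' @param params A `generator_params` object.
#' @return An `rc_cohort`; `provenance` carries the parameters and the latent
#'   responder flags.
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "generator_params"))
  p <- params
  n <- as.integer(p$n)
  if (n == 0) {
    empty_p <- tibble::tibble(
      patient_id = character(0), new_lesions = logical(0),
      nontarget_status = character(0), afp_bl = numeric(0),
      afp_fu = numeric(0), rfs_months = numeric(0), rfs_event = logical(0),
      os_months = numeric(0), os_event = logical(0),
      percent_viable = numeric(0), reader1_category = character(0),
      reader2_category = character(0))
    empty_l <- tibble::tibble(
      patient_id = character(0), lesion_id = character(0),
      organ = character(0), timepoint = character(0),
      longest_diameter_mm = numeric(0), viable_diameter_mm = numeric(0),
      is_target = logical(0))
    return(new_cohort(empty_p, empty_l,
                      provenance = list(generator = p,
                                        latent_responder = logical(0))))
  }
  withr::with_seed(as.integer(p$seed), {
    pid <- sprintf("P%04d", seq_len(n))
    responder <- stats::runif(n) < p$responder_prob

    draw_mix <- function(par_r, par_nr) {
      rnorm_trunc(n, ifelse(responder, par_r[1], par_nr[1]),
                  ifelse(responder, par_r[2], par_nr[2]), lower = -1)
    }
    size_change <- draw_mix(p$size_change_responder, p$size_change_nonresponder)
    afp_change <- draw_mix(p$afp_delta_responder, p$afp_delta_nonresponder)

    sld_bl <- pmax(stats::rlnorm(n, log(p$baseline_sld_median_mm),
                                 p$baseline_sld_sdlog), 10)
    two <- stats::runif(n) < p$two_lesion_prob
    split_frac <- stats::runif(n, 0.5, 2 / 3)
    # a second lesion only when both parts stay measurable (>= 10 mm)
    two <- two & (sld_bl * pmin(split_frac, 1 - split_frac) >= 10)

    afp_meanlog <- log(200) - stats::qnorm(1 - p$afp_bl_frac_ge_200) * p$afp_bl_sdlog
    afp_bl <- stats::rlnorm(n, afp_meanlog, p$afp_bl_sdlog)
    afp_fu <- afp_bl * (1 + afp_change)

    extra <- pmax(rnorm_trunc(
      n,
      ifelse(responder, p$viable_extra_responder[1], p$viable_extra_nonresponder[1]),
      ifelse(responder, p$viable_extra_responder[2], p$viable_extra_nonresponder[2]),
      lower = -Inf), 0)
    viable_change <- pmax(size_change - extra, -1)
    viable_frac <- stats::runif(n, p$viable_frac_range[1], p$viable_frac_range[2])

    rate0 <- log(2) / p$base_median_rfs_months
    favorable <- if (p$mode == "latent") responder else
      afp_change <= p$planted_afp_cutoff
    t_rec <- stats::rexp(n, rate0 * ifelse(favorable, p$responder_hr, 1))
    t_death <- t_rec + stats::rexp(n, 1 / p$os_increment_mean_months)
    cens <- stats::runif(n, p$censor_window[1], p$censor_window[2])
    rfs_months <- pmin(t_rec, cens)
    rfs_event <- t_rec <= cens
    os_months <- pmin(t_death, cens)
    os_event <- t_death <= cens

    percent_viable <- stats::rbeta(n, p$pathology_beta[1], p$pathology_beta[2])

    patients <- tibble::tibble(
      patient_id = pid, new_lesions = FALSE, nontarget_status = "absent",
      afp_bl = afp_bl, afp_fu = afp_fu,
      rfs_months = rfs_months, rfs_event = rfs_event,
      os_months = os_months, os_event = os_event,
      percent_viable = percent_viable,
      reader1_category = NA_character_, reader2_category = NA_character_)

    n_les <- ifelse(two, 2L, 1L)
    les_pid <- rep(pid, n_les)
    les_num <- unlist(lapply(n_les, seq_len))
    frac <- ifelse(les_num == 1, rep(split_frac, n_les), 1 - rep(split_frac, n_les))
    frac[rep(!two, n_les)] <- 1
    ld_bl <- rep(sld_bl, n_les) * frac
    chg <- rep(size_change, n_les)
    vfrac <- rep(viable_frac, n_les)
    vchg <- rep(viable_change, n_les)
    ld_fu <- pmax(ld_bl * (1 + chg), 0)
    vd_bl <- vfrac * ld_bl
    vd_fu <- pmin(pmax(vd_bl * (1 + vchg), 0), ld_fu)
    base_rows <- tibble::tibble(
      patient_id = les_pid,
      lesion_id = sprintf("%s_L%d", les_pid, les_num),
      organ = "liver", timepoint = "baseline",
      longest_diameter_mm = ld_bl, viable_diameter_mm = vd_bl,
      is_target = TRUE)
    fu_rows <- base_rows
    fu_rows$timepoint <- "followup"
    fu_rows$longest_diameter_mm <- ld_fu
    fu_rows$viable_diameter_mm <- vd_fu
    lesions <- rbind(base_rows, fu_rows)
    lesions <- lesions[order(match(lesions$patient_id, pid),
                             lesions$lesion_id, lesions$timepoint), ]

    new_cohort(patients, lesions,
               provenance = list(generator = p, latent_responder = responder))
  })
}

#' Latent responder flags of a generated cohort
#'
#' @param cohort A cohort produced by [generate_cohort()].
#' @return Logical vector aligned with `cohort$patients`.
#' @export
latent_responders <- function(cohort) {
  stopifnot(inherits(cohort, "rc_cohort"))
  lr <- cohort$provenance$latent_responder
  if (is.null(lr)) stop("cohort carries no latent responder flags", call. = FALSE)
  lr
}

#' Attach a simulated second-reader rating
#'
#' Reader 1 is the true classification under the chosen criterion; reader 2
#' repeats it with independent adjacent-category flips (one step along the
#' CR/PR/SD/PD order, direction random, inward at the ends) at probability
#' `flip_prob`. Non-evaluable patients keep `NA` ratings.
#'
#' @param cohort An `rc_cohort`.
#' @param criterion Criterion name or `criterion_spec` (default alpha-RECIST).
#' @param flip_prob Flip probability between 0 and 1.
#' @param seed Integer seed.
#' @return The cohort with `reader1_category` / `reader2_category` filled in.
#' @export
generate_reader_pair <- function(cohort, criterion = "alpha-RECIST",
                                 flip_prob, seed) {
  stopifnot(inherits(cohort, "rc_cohort"))
  if (!is.numeric(flip_prob) || flip_prob < 0 || flip_prob > 1) {
    stop("flip_prob must lie in [0, 1]", call. = FALSE)
  }
  if (is.character(criterion)) criterion <- resolve_criteria(criterion)[[1]]
  cats <- response_categories()
  eval_tbl <- evaluate_cohort(cohort, specs = list(criterion))
  r1 <- eval_tbl[[criterion$ascii]]
  r1[r1 == "NE"] <- NA_character_
  r2 <- withr::with_seed(as.integer(seed), {
    idx <- match(r1, cats)
    flip <- stats::runif(length(r1)) < flip_prob & !is.na(idx)
    dir <- sample(c(-1L, 1L), length(r1), replace = TRUE)
    new_idx <- idx + ifelse(flip, dir, 0L)
    new_idx <- pmin(pmax(new_idx, 1L), length(cats))
    # at the scale ends a flip always moves inward
    at_end <- flip & new_idx == idx
    new_idx[at_end] <- idx[at_end] + ifelse(idx[at_end] == 1L, 1L, -1L)
    cats[new_idx]
  })
  cohort$patients$reader1_category <- r1
  cohort$patients$reader2_category <- r2
  cohort$provenance$reader_pair <- list(criterion = criterion$ascii,
                                        flip_prob = flip_prob, seed = seed)
  cohort
}
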