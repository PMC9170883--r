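# Full-analysis orchestration: classify -> discover cutoffs -> validate
# survival -> agreement -> pathology concordance, exporting CSV tables and a
# run manifest. CSV tables are the canonical outputs; plots are optional
# artifacts layered on top of them.

#' Waterfall table of per-patient changes
#'
#' One row per patient, sorted descending by the chosen quantity (the order
#' bars appear in a waterfall plot), with threshold-crossing annotations: the
#' -30% / +20% size thresholds for the SLD quantities, the -76% AFP threshold
#' for the AFP change. Ties preserve input order; patients with a missing
#' quantity are kept at the bottom with `missing = TRUE`, never dropped.
#'
#' @param cohort An `rc_cohort`.
#' @param quantity `"sld_change"`, `"viable_change"` or `"afp_delta"`.
#' @param pr_cutoff,pd_cutoff,afp_cutoff Annotation thresholds.
#' @return Tibble: `patient_id`, `value`, `missing`, and the threshold flags.
#' @export
waterfall_table <- function(cohort,
                            quantity = c("sld_change", "viable_change", "afp_delta"),
                            pr_cutoff = -0.30, pd_cutoff = 0.20,
                            afp_cutoff = -0.76) {
  quantity <- match.arg(quantity)
  ids <- cohort$patients$patient_id
  vals <- unname(vapply(ids, function(pid) {
    s <- summarize_changes(patient_record(cohort, pid))
    s[[quantity]]
  }, numeric(1)))
  if (all(is.na(vals))) stop("quantity not computable for any patient", call. = FALSE)
  ord <- order(-vals, na.last = TRUE)   # stable: ties keep input order
  out <- tibble::tibble(
    patient_id = ids[ord],
    value = vals[ord],
    missing = is.na(vals[ord])
  )
  if (quantity == "afp_delta") {
    out$below_afp_threshold <- !out$missing & out$value <= afp_cutoff
  } else {
    out$below_pr_threshold <- !out$missing & out$value <= pr_cutoff
    out$above_pd_threshold <- !out$missing & out$value >= pd_cutoff
  }
  out
}

write_stage <- function(df, out_dir, name) {
  path <- file.path(out_dir, paste0(name, ".csv"))
  readr::write_csv(df, path, na = "")
  path
}

#' Run the full response-evaluation analysis
#'
#' Orchestrates every stage on one cohort: per-criterion classification with
#' marginal category counts, waterfall tables of the size and AFP changes,
#' AFP cutoff discovery against the survival endpoint, Kaplan-Meier /
#' log-rank / Cox validation of each criterion's responder split, inter-reader
#' agreement when two reader columns are present, and the response-pathology
#' concordance. All tables are written as CSV under `out_dir` together with a
#' JSON run manifest (seed/provenance, settings, row counts, collected
#' warnings).
#'
#' @param cohort An `rc_cohort` (load one with [load_cohort()] or simulate one
#'   with [generate_cohort()]).
#' @param criteria Criteria selection for [resolve_criteria()] (default
#'   `"all"`).
#' @param endpoint `"rfs"` or `"os"`.
#' @param min_frac Minimum group fraction of the cutpoint scan.
#' @param correction Cutpoint p-value correction, `"miller-siegmund"` or
#'   `"none"`.
#' @param out_dir Output directory (created if needed); `NULL` skips writing.
#' @return (Invisibly) a list: `response` (per-patient table), `counts`,
#'   `waterfalls`, `cutpoints`, `survival`, `agreement`, `pathology`,
#'   `manifest`.
#' @export
run_full_analysis <- function(cohort, criteria = "all",
                              endpoint = c("rfs", "os"),
                              min_frac = 0.10,
                              correction = "miller-siegmund",
                              out_dir = NULL) {
  stopifnot(inherits(cohort, "rc_cohort"))
  endpoint <- match.arg(endpoint)
  specs <- resolve_criteria(criteria)
  warnings_log <- character(0)
  note <- function(msg) warnings_log <<- c(warnings_log, msg)

  p <- cohort$patients
  times <- p[[paste0(endpoint, "_months")]]
  events <- p[[paste0(endpoint, "_event")]]

  ## stage 1: classification
  response <- evaluate_cohort(cohort, specs)
  counts <- attr(response, "counts")
  n_ne <- sum(vapply(specs, function(sp) sum(response[[sp$ascii]] == "NE"),
                     numeric(1)))
  if (n_ne > 0) note(sprintf("%d non-evaluable classifications (missing AFP)", n_ne))

  ## stage 2: waterfall tables
  waterfalls <- list(
    sld_change = waterfall_table(cohort, "sld_change"),
    viable_change = waterfall_table(cohort, "viable_change"),
    afp_delta = waterfall_table(cohort, "afp_delta")
  )

  ## stage 3: cutoff discovery on the AFP markers
  cutpoints <- list()
  afp_ok <- !is.na(p$afp_bl)
  if (any(events[afp_ok]) && sum(afp_ok) >= 4) {
    delta <- response$afp_delta[afp_ok]
    cutpoints$afp_delta <- optimal_cutpoint(delta, times[afp_ok],
                                            events[afp_ok], min_frac,
                                            correction)
    cutpoints$afp_bl <- optimal_cutpoint(p$afp_bl[afp_ok], times[afp_ok],
                                         events[afp_ok], min_frac, correction)
  } else {
    note("cutpoint stage skipped: too few AFP measurements or no events")
  }

  ## stage 4: survival validation per criterion
  surv_rows <- lapply(specs, function(sp) {
    resp <- response[[paste0("responder_", sp$ascii)]]
    ok <- !is.na(resp)
    if (length(unique(resp[ok])) < 2 || !any(events[ok])) {
      note(sprintf("survival stage: criterion %s has a degenerate responder split", sp$name))
      return(tibble::tibble(
        criterion = sp$name, ascii = sp$ascii, n = sum(ok),
        n_responders = sum(resp[ok]), logrank_chisq = NA_real_,
        logrank_p = NA_real_, hazard_ratio = NA_real_, hr_ci_low = NA_real_,
        hr_ci_high = NA_real_, hr_p = NA_real_,
        s12_resp = NA_real_, s24_resp = NA_real_, s36_resp = NA_real_,
        s12_nonresp = NA_real_, s24_nonresp = NA_real_, s36_nonresp = NA_real_))
    }
    lr <- logrank_test(list(
      list(times = times[ok & resp], events = events[ok & resp]),
      list(times = times[ok & !resp], events = events[ok & !resp])))
    cx <- withCallingHandlers(
      cox_univariate(resp[ok], times[ok], events[ok]),
      warning = function(w) {
        note(sprintf("criterion %s: %s", sp$name, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    rate <- function(keep) {
      if (!any(events[keep])) return(rep(NA_real_, 3))
      suppressWarnings(survival_rates(times[keep], events[keep])$survival)
    }
    sr <- rate(ok & resp)
    sn <- rate(ok & !resp)
    tibble::tibble(
      criterion = sp$name, ascii = sp$ascii, n = sum(ok),
      n_responders = sum(resp[ok]),
      logrank_chisq = lr$chi_square, logrank_p = lr$p_value,
      hazard_ratio = cx$hazard_ratio, hr_ci_low = cx$ci_low,
      hr_ci_high = cx$ci_high, hr_p = cx$p_value,
      s12_resp = sr[1], s24_resp = sr[2], s36_resp = sr[3],
      s12_nonresp = sn[1], s24_nonresp = sn[2], s36_nonresp = sn[3])
  })
  survival_tbl <- do.call(rbind, surv_rows)

  ## stage 5: inter-reader agreement
  agreement <- NULL
  have_readers <- !all(is.na(p$reader1_category)) &&
    !all(is.na(p$reader2_category))
  if (have_readers) {
    ok <- !is.na(p$reader1_category) & !is.na(p$reader2_category)
    cm <- confusion_matrix(p$reader1_category[ok], p$reader2_category[ok])
    kp <- weighted_kappa(cm)
    agreement <- list(
      matrix = cm,
      table = tibble::tibble(
        n = sum(ok), agreement_n = sum(diag(unclass(cm))),
        agreement_pct = 100 * kp$percent_agreement,
        kappa = kp$kappa, kappa_ci_low = kp$ci_low,
        kappa_ci_high = kp$ci_high, weighting = kp$weighting))
  }

  ## stage 6: pathology concordance (alpha-RECIST responder vs pathologic
  ## major/minor response)
  pathology <- NULL
  alpha_col <- intersect("responder_alpha_delta_recist", names(response))
  if (length(alpha_col) == 1 && !all(is.na(p$percent_viable))) {
    ok <- !is.na(p$percent_viable) & !is.na(response[[alpha_col]])
    if (sum(ok) >= 3) {
      path_cat <- pathologic_category(p$percent_viable[ok])
      resp <- response[[alpha_col]][ok]
      # ordinal codes: response PR=1/SD=2; pathology complete<major<minor
      x <- ifelse(resp, 1, 2)
      y <- match(path_cat, c("complete", "major", "minor"))
      rho <- spearman_correlation(x, y)
      pathology <- list(
        cross_table = table(response = ifelse(resp, "responder", "non-responder"),
                            pathology = path_cat),
        spearman = rho)
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("alphaRECIST")),
    n_patients = nrow(p),
    criteria = unname(vapply(specs, `[[`, character(1), "name")),
    endpoint = endpoint, min_frac = min_frac, correction = correction,
    provenance = lapply(
      cohort$provenance[setdiff(names(cohort$provenance), "latent_responder")],
      function(x) if (is.list(x)) unclass(x) else x),
    warnings = warnings_log
  )

  result <- list(response = response, counts = counts,
                 waterfalls = waterfalls, cutpoints = cutpoints,
                 survival = survival_tbl, agreement = agreement,
                 pathology = pathology, manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_stage(response, out_dir, "response_table")
    write_stage(counts, out_dir, "criterion_counts")
    for (nm in names(waterfalls)) {
      write_stage(waterfalls[[nm]], out_dir, paste0("waterfall_", nm))
    }
    if (length(cutpoints) > 0) {
      cp_tbl <- do.call(rbind, lapply(names(cutpoints), function(nm) {
        cp <- cutpoints[[nm]]
        tibble::tibble(marker = nm, cutoff = cp$cutoff,
                       chi_square = cp$chi_square, naive_p = cp$naive_p,
                       corrected_p = cp$corrected_p, status = cp$status)
      }))
      write_stage(cp_tbl, out_dir, "cutpoints")
      for (nm in names(cutpoints)) {
        write_stage(cutpoints[[nm]]$candidates, out_dir,
                    paste0("cutpoint_scan_", nm))
      }
    }
    write_stage(survival_tbl, out_dir, "survival_by_criterion")
    if (!is.null(agreement)) write_stage(agreement$table, out_dir, "agreement")
    if (!is.null(pathology)) {
      sp <- pathology$spearman
      write_stage(tibble::tibble(rho = sp$rho, ci_low = sp$ci_low,
                                 ci_high = sp$ci_high, p_value = sp$p_value,
                                 n = sp$n),
                  out_dir, "pathology_concordance")
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(result)
}
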