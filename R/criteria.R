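# Response-category engines: RECIST 1.1, mRECIST, and the AFP-composite
# criteria that overlay an AFP rule (fractional change or baseline level) on a
# size-based criterion via OR / AND combination.

#' Ordered response categories
#'
#' The four categories in their fixed order CR > PR > SD > PD. The order
#' matters for weighted-kappa agreement (adjacent categories earn partial
#' credit). `"NE"` (non-evaluable) is used in cohort tables for patients whose
#' AFP is missing under an AFP-composite criterion; it is not part of the
#' ordered scale.
#'
#' @return Character vector `c("CR", "PR", "SD", "PD")`.
#' @export
response_categories <- function() c("CR", "PR", "SD", "PD")

#' Is a category a responder?
#'
#' Responders are patients with complete or partial response (CR or PR);
#' non-responders are SD or PD.
#'
#' @param category Character vector of categories (`"NE"` and `NA` give `NA`).
#' @return Logical vector.
#' @export
is_responder <- function(category) {
  out <- category %in% c("CR", "PR")
  out[is.na(category) | category == "NE"] <- NA
  out
}

#' Define a response criterion
#'
#' A criterion is a base size rule (RECIST 1.1 on total diameters, or mRECIST
#' on viable/arterially-enhancing diameters) optionally combined with an AFP
#' component: the fractional AFP change (`"delta"`, response condition
#' AFP change <= `afp_delta_cutoff`) or the baseline AFP level (`"baseline"`,
#' response condition AFP_BL >= `afp_bl_cutoff`), joined by `"or"` or `"and"`.
#' The default delta cutoff -0.76 (a 76% decrease) with base RECIST 1.1 and
#' OR combination is the alpha-RECIST criterion.
#'
#' @param name Display name of the criterion.
#' @param base `"RECIST11"` or `"mRECIST"`.
#' @param afp_component `"none"`, `"delta"` or `"baseline"`.
#' @param combiner `"none"`, `"or"` or `"and"`.
#' @param afp_delta_cutoff Fractional AFP change at or below which the AFP
#'   condition holds (default -0.76).
#' @param afp_bl_cutoff Baseline AFP level (ng/ml) at or above which the AFP
#'   condition holds (default 54.4).
#' @param size_pr_cutoff Fractional size change at or below which the size
#'   rule grants PR (default -0.30).
#' @param size_pd_cutoff Fractional size increase from nadir at or above which
#'   PD is declared (default +0.20).
#' @param pd_abs_mm Minimum absolute increase in mm additionally required for
#'   PD under RECIST 1.1 (default 5).
#' @param ascii Column-safe identifier; derived from `name` if omitted.
#' @return A `criterion_spec` object (named list).
#' @export
criterion_spec <- function(name, base = c("RECIST11", "mRECIST"),
                           afp_component = c("none", "delta", "baseline"),
                           combiner = c("none", "or", "and"),
                           afp_delta_cutoff = -0.76, afp_bl_cutoff = 54.4,
                           size_pr_cutoff = -0.30, size_pd_cutoff = 0.20,
                           pd_abs_mm = 5, ascii = NULL) {
  base <- match.arg(base)
  afp_component <- match.arg(afp_component)
  combiner <- match.arg(combiner)
  if (afp_component == "none" && combiner != "none") {
    stop("combiner requires an AFP component", call. = FALSE)
  }
  if (afp_component != "none" && combiner == "none") {
    stop("an AFP component requires a combiner ('or' or 'and')", call. = FALSE)
  }
  stopifnot(is.finite(afp_delta_cutoff), is.finite(afp_bl_cutoff),
            is.finite(size_pr_cutoff), is.finite(size_pd_cutoff),
            is.finite(pd_abs_mm))
  if (!(size_pr_cutoff < 0 && size_pd_cutoff > 0)) {
    stop("size_pr_cutoff must be negative and size_pd_cutoff positive",
         call. = FALSE)
  }
  if (is.null(ascii)) {
    ascii <- gsub("[^a-z0-9]+", "_", tolower(name))
  }
  structure(list(
    name = name, ascii = ascii, base = base, afp_component = afp_component,
    combiner = combiner, afp_delta_cutoff = afp_delta_cutoff,
    afp_bl_cutoff = afp_bl_cutoff, size_pr_cutoff = size_pr_cutoff,
    size_pd_cutoff = size_pd_cutoff, pd_abs_mm = pd_abs_mm
  ), class = "criterion_spec")
}

#' @export
print.criterion_spec <- function(x, ...) {
  afp_part <- switch(x$afp_component,
    none = "",
    delta = sprintf(" %s AFP change <= %g", toupper(x$combiner), x$afp_delta_cutoff),
    baseline = sprintf(" %s AFP_BL >= %g ng/ml", toupper(x$combiner), x$afp_bl_cutoff))
  cat(sprintf("<criterion_spec> %s: base %s%s\n", x$name, x$base, afp_part))
  invisible(x)
}

#' Registry of the ten study criteria
#'
#' The two base criteria plus the eight AFP composites: every combination of
#' base (RECIST 1.1 / mRECIST), AFP component (change / baseline level) and
#' combiner (OR / AND), at the default cutoffs (76% AFP decrease,
#' 54.4 ng/ml baseline AFP). The delta-OR-RECIST entry is the alpha-RECIST
#' criterion.
#'
#' @return Named list of `criterion_spec` objects, keyed by ASCII identifier.
#' @export
criterion_registry <- function() {
  specs <- list(
    criterion_spec("RECIST 1.1", base = "RECIST11", ascii = "recist11"),
    criterion_spec("mRECIST", base = "mRECIST", ascii = "mrecist"),
    criterion_spec("αΔ-RECIST", base = "RECIST11",
                   afp_component = "delta", combiner = "or",
                   ascii = "alpha_delta_recist"),
    criterion_spec("αΔ-mRECIST", base = "mRECIST",
                   afp_component = "delta", combiner = "or",
                   ascii = "alpha_delta_mrecist"),
    criterion_spec("α&Δ-RECIST", base = "RECIST11",
                   afp_component = "delta", combiner = "and",
                   ascii = "alpha_and_delta_recist"),
    criterion_spec("α&Δ-mRECIST", base = "mRECIST",
                   afp_component = "delta", combiner = "and",
                   ascii = "alpha_and_delta_mrecist"),
    criterion_spec("αBL-RECIST", base = "RECIST11",
                   afp_component = "baseline", combiner = "or",
                   ascii = "alpha_bl_recist"),
    criterion_spec("αBL-mRECIST", base = "mRECIST",
                   afp_component = "baseline", combiner = "or",
                   ascii = "alpha_bl_mrecist"),
    criterion_spec("α&BL-RECIST", base = "RECIST11",
                   afp_component = "baseline", combiner = "and",
                   ascii = "alpha_and_bl_recist"),
    criterion_spec("α&BL-mRECIST", base = "mRECIST",
                   afp_component = "baseline", combiner = "and",
                   ascii = "alpha_and_bl_mrecist")
  )
  names(specs) <- vapply(specs, `[[`, character(1), "ascii")
  specs
}

criterion_aliases <- function() {
  reg <- criterion_registry()
  display <- vapply(reg, `[[`, character(1), "name")
  al <- c(
    stats::setNames(names(reg), names(reg)),
    stats::setNames(names(reg), display),
    "alpha-RECIST" = "alpha_delta_recist",
    "alpha-recist" = "alpha_delta_recist",
    "α-RECIST" = "alpha_delta_recist",
    "alpha-delta-RECIST" = "alpha_delta_recist",
    "alpha-delta-mRECIST" = "alpha_delta_mrecist",
    "alpha-and-delta-RECIST" = "alpha_and_delta_recist",
    "alpha-and-delta-mRECIST" = "alpha_and_delta_mrecist",
    "alpha-bl-RECIST" = "alpha_bl_recist",
    "alpha-bl-mRECIST" = "alpha_bl_mrecist",
    "alpha-and-bl-RECIST" = "alpha_and_bl_recist",
    "alpha-and-bl-mRECIST" = "alpha_and_bl_mrecist",
    "RECIST1.1" = "recist11",
    "RECIST 1.1" = "recist11",
    "mRECIST" = "mrecist"
  )
  al
}

#' Look up criteria by name or alias
#'
#' @param names Character vector of criterion names — ASCII identifiers,
#'   display names, or documented aliases (e.g. `"alpha-RECIST"`); `"all"`
#'   selects the full registry.
#' @return Named list of `criterion_spec`s.
#' @export
resolve_criteria <- function(names = "all") {
  reg <- criterion_registry()
  if (identical(names, "all")) return(reg)
  al <- criterion_aliases()
  keys <- al[names]
  if (anyNA(keys)) {
    stop("unknown criterion name(s): ",
         paste(names[is.na(keys)], collapse = ", "), call. = FALSE)
  }
  reg[unname(keys)]
}

#' Select target lesions under the RECIST 1.1 limits
#'
#' From the baseline lesion rows, keeps measurable lesions (longest diameter
#' at least 10 mm), preferring the largest, subject to at most two lesions per
#' organ and five overall. Ties are broken by lesion id, making the selection
#' deterministic.
#'
#' @param lesions Tibble of lesion-timepoint rows (as in an `rc_cohort`).
#' @return Character vector of selected `lesion_id`s, largest first.
#'   Errors when no lesion is eligible.
#' @export
select_target_lesions <- function(lesions) {
  bl <- lesions[lesions$timepoint == "baseline", ]
  if (nrow(bl) == 0) stop("no baseline lesion measurements", call. = FALSE)
  elig <- bl[is.finite(bl$longest_diameter_mm) & bl$longest_diameter_mm >= 10, ]
  if (nrow(elig) == 0) {
    stop("no target lesion: no baseline lesion reaches the 10 mm minimum",
         call. = FALSE)
  }
  ord <- order(-elig$longest_diameter_mm, elig$lesion_id)
  elig <- elig[ord, ]
  chosen <- character(0)
  organ_count <- integer(0)
  for (k in seq_len(nrow(elig))) {
    if (length(chosen) >= 5) break
    org <- elig$organ[k]
    cnt <- if (org %in% names(organ_count)) organ_count[[org]] else 0L
    if (cnt >= 2) next
    chosen <- c(chosen, elig$lesion_id[k])
    organ_count[[org]] <- cnt + 1L
  }
  chosen
}

#' Fractional AFP change
#'
#' The AFP change is defined as (AFP_FU - AFP_BL) / AFP_BL: a signed fraction,
#' -0.76 meaning a 76% decrease.
#'
#' @param afp List with `afp_bl` (> 0) and `afp_fu` (>= 0), as in a patient
#'   record.
#' @return Signed fraction; at least -1 when `afp_fu >= 0`.
#' @export
afp_delta <- function(afp) {
  if (is.null(afp)) stop("AFP measurements are missing", call. = FALSE)
  if (!is.finite(afp$afp_bl) || afp$afp_bl <= 0) {
    stop("afp_bl must be finite and > 0", call. = FALSE)
  }
  (afp$afp_fu - afp$afp_bl) / afp$afp_bl
}

#' Summarize per-patient size and AFP changes
#'
#' Sums the longest diameters (SLD) and the viable (arterially enhancing)
#' diameters of the target lesions at baseline and follow-up, and derives the
#' fractional changes used by every criterion. With a single follow-up the
#' nadir reference for progression equals the baseline sum.
#'
#' @param record A patient record from [patient_record()].
#' @return A `change_summary` list: `sld_bl`, `sld_fu`, `sld_change`,
#'   `viable_sld_bl`, `viable_sld_fu`, `viable_change`, `afp_delta` (`NA`
#'   when AFP is missing).
#' @export
summarize_changes <- function(record) {
  les <- record$lesions
  bl <- les[les$timepoint == "baseline" & les$is_target, ]
  if (nrow(bl) == 0) stop("no baseline target lesions", call. = FALSE)
  fu <- les[les$timepoint == "followup" & les$lesion_id %in% bl$lesion_id, ]
  unmatched <- setdiff(bl$lesion_id, fu$lesion_id)
  if (length(unmatched) > 0) {
    stop("no follow-up measurement for target lesion(s): ",
         paste(unmatched, collapse = ", "), call. = FALSE)
  }
  sld_bl <- sum(bl$longest_diameter_mm)
  sld_fu <- sum(fu$longest_diameter_mm)
  v_bl <- sum(bl$viable_diameter_mm)
  v_fu <- sum(fu$viable_diameter_mm)
  if (sld_bl <= 0) {
    stop("baseline SLD is zero: no measurable baseline disease", call. = FALSE)
  }
  structure(list(
    sld_bl = sld_bl, sld_fu = sld_fu,
    sld_change = (sld_fu - sld_bl) / sld_bl,
    viable_sld_bl = v_bl, viable_sld_fu = v_fu,
    viable_change = if (v_bl > 0) (v_fu - v_bl) / v_bl else NA_real_,
    afp_delta = if (is.null(record$afp)) NA_real_ else afp_delta(record$afp)
  ), class = "change_summary")
}

# Shared CR/PR/SD/PD cascade on a (change, absolute increase) pair.
# All thresholds inclusive, compared on exact fractions (no pre-rounding).
classify_size_rule <- function(change_from_bl, change_from_nadir, abs_increase_mm,
                               sum_fu, new_lesions, nontarget_status,
                               pr_cutoff, pd_cutoff, pd_abs_mm,
                               require_abs_for_pd) {
  pd_size <- is.finite(change_from_nadir) && change_from_nadir >= pd_cutoff &&
    (!require_abs_for_pd || abs_increase_mm >= pd_abs_mm)
  if (isTRUE(new_lesions) || identical(nontarget_status, "PD") || pd_size) {
    return("PD")
  }
  if (sum_fu == 0 && nontarget_status %in% c("CR", "absent")) return("CR")
  if (is.finite(change_from_bl) && change_from_bl <= pr_cutoff) return("PR")
  "SD"
}

#' Classify under RECIST 1.1
#'
#' Decision cascade on the total-diameter SLD: PD when new lesions appear,
#' non-target disease progresses, or the SLD grows by at least 20% from nadir
#' with an absolute increase of at least 5 mm; else CR when all target lesions
#' disappear (SLD 0) with no non-target residue; else PR at a decrease of 30%
#' or more; else SD. With one follow-up the nadir is the baseline.
#'
#' @param summary A `change_summary` from [summarize_changes()].
#' @param new_lesions Logical: any new lesion at follow-up.
#' @param nontarget_status One of `"CR"`, `"non-CR/non-PD"`, `"PD"`,
#'   `"absent"`.
#' @param spec Optional `criterion_spec` carrying the thresholds (defaults
#'   30%/20%/5 mm).
#' @return A category string: `"CR"`, `"PR"`, `"SD"` or `"PD"`.
#' @export
classify_recist11 <- function(summary, new_lesions, nontarget_status,
                              spec = criterion_spec("RECIST 1.1")) {
  classify_size_rule(
    change_from_bl = summary$sld_change,
    change_from_nadir = summary$sld_change,  # nadir = baseline, single follow-up
    abs_increase_mm = summary$sld_fu - summary$sld_bl,
    sum_fu = summary$sld_fu,
    new_lesions = new_lesions, nontarget_status = nontarget_status,
    pr_cutoff = spec$size_pr_cutoff, pd_cutoff = spec$size_pd_cutoff,
    pd_abs_mm = spec$pd_abs_mm, require_abs_for_pd = TRUE
  )
}

#' Classify under mRECIST
#'
#' Same cascade as [classify_recist11()] but on the viable (arterially
#' enhancing) diameters: CR when arterial enhancement disappears in all target
#' lesions (viable SLD 0), PR at a 30% decrease of the viable SLD from
#' baseline, PD at a 20% increase from the smallest prior viable SLD (the
#' baseline when there is a single follow-up), with no absolute-mm condition.
#'
#' @inheritParams classify_recist11
#' @return A category string.
#' @export
classify_mrecist <- function(summary, new_lesions, nontarget_status,
                             spec = criterion_spec("mRECIST", base = "mRECIST")) {
  classify_size_rule(
    change_from_bl = summary$viable_change,
    change_from_nadir = summary$viable_change,
    abs_increase_mm = summary$viable_sld_fu - summary$viable_sld_bl,
    sum_fu = summary$viable_sld_fu,
    new_lesions = new_lesions, nontarget_status = nontarget_status,
    pr_cutoff = spec$size_pr_cutoff, pd_cutoff = spec$size_pd_cutoff,
    pd_abs_mm = spec$pd_abs_mm, require_abs_for_pd = FALSE
  )
}

classify_base <- function(summary, new_lesions, nontarget_status, spec) {
  if (spec$base == "RECIST11") {
    classify_recist11(summary, new_lesions, nontarget_status, spec)
  } else {
    classify_mrecist(summary, new_lesions, nontarget_status, spec)
  }
}

#' Classify under a composite (AFP + size) criterion
#'
#' Applies the base size criterion, then overlays the AFP condition. A base PD
#' (new lesions or progression) always vetoes response. The AFP condition is
#' AFP change <= cutoff (delta component, default -0.76) or baseline
#' AFP >= cutoff (baseline component, default 54.4 ng/ml). With the `"or"`
#' combiner a patient responds when either the size rule (base CR/PR) or the
#' AFP condition holds; with `"and"`, both are required. Responders keep CR
#' when the base category was CR, and are labeled PR otherwise;
#' non-responders are labeled SD. Patients with missing AFP are non-evaluable
#' (`"NE"`) under any AFP composite.
#'
#' @param record A patient record from [patient_record()].
#' @param spec A `criterion_spec`.
#' @param summary Optional precomputed `change_summary`.
#' @return A category string among `"CR"`, `"PR"`, `"SD"`, `"PD"`, `"NE"`.
#' @export
classify_composite <- function(record, spec, summary = NULL) {
  if (is.null(summary)) summary <- summarize_changes(record)
  base_cat <- classify_base(summary, record$new_lesions,
                            record$nontarget_status, spec)
  if (spec$afp_component == "none") return(base_cat)
  if (base_cat == "PD") return("PD")
  if (is.null(record$afp)) return("NE")
  afp_ok <- switch(spec$afp_component,
    delta = afp_delta(record$afp) <= spec$afp_delta_cutoff,
    baseline = record$afp$afp_bl >= spec$afp_bl_cutoff)
  size_ok <- base_cat %in% c("CR", "PR")
  responder <- if (spec$combiner == "or") size_ok || afp_ok else size_ok && afp_ok
  if (!responder) return("SD")
  if (base_cat == "CR") "CR" else "PR"
}

#' Classify every patient under a set of criteria
#'
#' @param cohort An `rc_cohort`.
#' @param specs Criteria to apply: a named list of `criterion_spec`s (default
#'   the full ten-criterion registry) or a character vector accepted by
#'   [resolve_criteria()].
#' @return Tibble with `patient_id`, the change summary columns (`sld_change`,
#'   `viable_change`, `afp_delta`), one category column per criterion (named
#'   by its ASCII id), and one `responder_<id>` logical column per criterion
#'   (`NA` for non-evaluable). The attribute `"counts"` holds the per-criterion
#'   CR/PR/SD/PD/NE marginal counts as a tibble.
#' @export
evaluate_cohort <- function(cohort, specs = criterion_registry()) {
  stopifnot(inherits(cohort, "rc_cohort"))
  if (is.character(specs)) specs <- resolve_criteria(specs)
  ids <- cohort$patients$patient_id
  records <- lapply(ids, function(pid) patient_record(cohort, pid))
  summaries <- lapply(records, summarize_changes)
  out <- tibble::tibble(
    patient_id = ids,
    sld_change = vapply(summaries, `[[`, numeric(1), "sld_change"),
    viable_change = vapply(summaries, `[[`, numeric(1), "viable_change"),
    afp_delta = vapply(summaries, `[[`, numeric(1), "afp_delta")
  )
  for (sp in specs) {
    cats <- vapply(seq_along(records), function(i) {
      classify_composite(records[[i]], sp, summary = summaries[[i]])
    }, character(1))
    out[[sp$ascii]] <- cats
    out[[paste0("responder_", sp$ascii)]] <- is_responder(cats)
  }
  counts <- do.call(rbind, lapply(specs, function(sp) {
    cats <- out[[sp$ascii]]
    tibble::tibble(
      criterion = sp$name, ascii = sp$ascii,
      CR = sum(cats == "CR"), PR = sum(cats == "PR"),
      SD = sum(cats == "SD"), PD = sum(cats == "PD"),
      NE = sum(cats == "NE")
    )
  }))
  attr(out, "counts") <- counts
  out
}
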