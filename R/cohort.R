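# Cohort container and delimited-text I/O.
#
# A cohort is stored as two tidy tables: one row per patient, and one row per
# lesion-timepoint. Internal conventions: diameters in millimetres, times in
# months, AFP in ng/ml, changes as signed fractions (-0.42 = 42% decrease).

PATIENT_COLS <- c(
  "patient_id", "new_lesions", "nontarget_status", "afp_bl", "afp_fu",
  "rfs_months", "rfs_event", "os_months", "os_event", "percent_viable",
  "reader1_category", "reader2_category"
)

LESION_COLS <- c(
  "patient_id", "lesion_id", "organ", "timepoint",
  "longest_diameter_mm", "viable_diameter_mm", "is_target"
)

NONTARGET_LEVELS <- c("CR", "non-CR/non-PD", "PD", "absent")

#' Construct a cohort object
#'
#' Bundles a patient-level table and a lesion-level table into a validated
#' `rc_cohort` object, the container consumed by every downstream stage
#' (classification, cutpoint search, survival validation, agreement).
#'
#' @param patients Data frame with one row per patient. Required columns:
#'   `patient_id`, `new_lesions`, `nontarget_status`, `afp_bl`, `afp_fu`,
#'   `rfs_months`, `rfs_event`, `os_months`, `os_event`, `percent_viable`,
#'   `reader1_category`, `reader2_category`. Missing values are `NA` (written
#'   as empty cells), never sentinel numbers.
#' @param lesions Data frame with one row per lesion-timepoint. Required
#'   columns: `patient_id`, `lesion_id`, `organ`, `timepoint` (`"baseline"` or
#'   `"followup"`), `longest_diameter_mm`, `viable_diameter_mm`, `is_target`.
#' @param provenance Optional list of metadata (source path, generator seed and
#'   parameters) carried along for run manifests.
#' @param validate If `TRUE` (default), reject the cohort when any patient
#'   record violates an invariant.
#'
#' @return An object of class `rc_cohort`: a list with elements `patients`,
#'   `lesions` (tibbles) and `provenance`.
#' @export
new_cohort <- function(patients, lesions, provenance = list(), validate = TRUE) {
  patients <- tibble::as_tibble(patients)
  lesions <- tibble::as_tibble(lesions)
  missing_p <- setdiff(PATIENT_COLS, names(patients))
  if (length(missing_p) > 0) {
    stop("patient table is missing required column(s): ",
         paste(missing_p, collapse = ", "), call. = FALSE)
  }
  missing_l <- setdiff(LESION_COLS, names(lesions))
  if (length(missing_l) > 0) {
    stop("lesion table is missing required column(s): ",
         paste(missing_l, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(patients$patient_id)) {
    dup <- unique(patients$patient_id[duplicated(patients$patient_id)])
    stop("duplicate patient_id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  orphan <- setdiff(lesions$patient_id, patients$patient_id)
  if (length(orphan) > 0) {
    stop("lesion rows reference unknown patient_id: ",
         paste(unique(orphan), collapse = ", "), call. = FALSE)
  }
  cohort <- structure(
    list(patients = patients, lesions = lesions, provenance = provenance),
    class = "rc_cohort"
  )
  if (validate) {
    viol <- validate_cohort(cohort)
    if (nrow(viol) > 0) {
      msg <- paste(sprintf("[%s] %s", viol$patient_id, viol$violation),
                   collapse = "\n  ")
      stop("cohort failed validation:\n  ", msg, call. = FALSE)
    }
  }
  cohort
}

#' @export
print.rc_cohort <- function(x, ...) {
  cat(sprintf("<rc_cohort> %d patients, %d lesion-timepoint rows\n",
              nrow(x$patients), nrow(x$lesions)))
  if (length(x$provenance) > 0) {
    cat("provenance:", paste(names(x$provenance), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of patients in a cohort
#' @param x An `rc_cohort`.
#' @export
n_patients <- function(x) {
  stopifnot(inherits(x, "rc_cohort"))
  nrow(x$patients)
}

#' Extract a single patient record
#'
#' @param cohort An `rc_cohort`.
#' @param patient_id Identifier of the patient to extract.
#' @return A list with components `patient_id`, `lesions` (tibble of this
#'   patient's lesion-timepoint rows), `new_lesions`, `nontarget_status`,
#'   `afp` (list with `afp_bl`, `afp_fu`, or `NULL` when AFP is missing),
#'   `survival` (list with `rfs_months`, `rfs_event`, `os_months`,
#'   `os_event`), `pathology` (list with `percent_viable`, or `NULL`), and
#'   `reader_categories` (named character vector, possibly empty).
#' @export
patient_record <- function(cohort, patient_id) {
  stopifnot(inherits(cohort, "rc_cohort"))
  i <- match(patient_id, cohort$patients$patient_id)
  if (is.na(i)) stop("unknown patient_id: ", patient_id, call. = FALSE)
  p <- cohort$patients[i, ]
  afp <- if (is.na(p$afp_bl) && is.na(p$afp_fu)) NULL else
    list(afp_bl = p$afp_bl, afp_fu = p$afp_fu)
  pathology <- if (is.na(p$percent_viable)) NULL else
    list(percent_viable = p$percent_viable)
  readers <- c(reader1 = p$reader1_category, reader2 = p$reader2_category)
  readers <- readers[!is.na(readers)]
  list(
    patient_id = p$patient_id,
    lesions = cohort$lesions[cohort$lesions$patient_id == p$patient_id, ],
    new_lesions = p$new_lesions,
    nontarget_status = p$nontarget_status,
    afp = afp,
    survival = list(rfs_months = p$rfs_months, rfs_event = p$rfs_event,
                    os_months = p$os_months, os_event = p$os_event),
    pathology = pathology,
    reader_categories = readers
  )
}

#' Validate one patient record
#'
#' Checks every type invariant of the data model and returns the violations as
#' text rather than raising, so callers can collect and report them. Rules
#' enforced: AFP baseline strictly positive (it is the denominator of the AFP
#' fractional change) and follow-up nonnegative; diameters finite and
#' nonnegative with viable diameter never exceeding the total diameter;
#' baseline target lesions at least 10 mm; at most two target lesions per
#' organ and five in total; each baseline target lesion matched by a
#' follow-up measurement; survival times nonnegative with recurrence-free not
#' exceeding overall survival time; pathology percent viable between 0 and 1;
#' category labels drawn from CR/PR/SD/PD.
#'
#' @param record A patient record as returned by [patient_record()].
#' @return Character vector of violation descriptions; empty when the record
#'   satisfies every invariant. Never raises.
#' @export
validate_record <- function(record) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)

  les <- record$lesions
  if (!is.null(les) && nrow(les) > 0) {
    bad_tp <- setdiff(unique(les$timepoint), c("baseline", "followup"))
    if (length(bad_tp) > 0) {
      add(sprintf("timepoint: unknown value(s) %s (must be baseline/followup)",
                  paste(bad_tp, collapse = ", ")))
    }
    for (k in seq_len(nrow(les))) {
      ld <- les$longest_diameter_mm[k]
      vd <- les$viable_diameter_mm[k]
      id <- les$lesion_id[k]
      if (!is.finite(ld) || ld < 0) {
        add(sprintf("lesion %s: longest_diameter_mm must be finite and >= 0", id))
      }
      if (!is.finite(vd) || vd < 0) {
        add(sprintf("lesion %s: viable_diameter_mm must be finite and >= 0", id))
      } else if (is.finite(ld) && vd > ld) {
        add(sprintf("lesion %s: viable_diameter_mm exceeds longest_diameter_mm", id))
      }
    }
    bl <- les[les$timepoint == "baseline" & les$is_target, ]
    fu <- les[les$timepoint == "followup", ]
    if (nrow(bl) > 0) {
      small <- bl$lesion_id[is.finite(bl$longest_diameter_mm) &
                              bl$longest_diameter_mm < 10]
      for (id in small) {
        add(sprintf("lesion %s: baseline target lesion below the 10 mm minimum", id))
      }
      if (nrow(bl) > 5) {
        add(sprintf("target lesions: %d selected, exceeding the limit of five lesions in total",
                    nrow(bl)))
      }
      per_organ <- table(bl$organ)
      for (org in names(per_organ)[per_organ > 2]) {
        add(sprintf("target lesions: %d in organ '%s', exceeding the limit of two lesions per organ",
                    per_organ[[org]], org))
      }
      unmatched <- setdiff(bl$lesion_id, fu$lesion_id)
      for (id in unmatched) {
        add(sprintf("lesion %s: baseline target lesion has no matched follow-up measurement", id))
      }
    }
  }

  if (!is.null(record$afp)) {
    bl <- record$afp$afp_bl
    fu <- record$afp$afp_fu
    if (is.na(bl) || is.na(fu)) {
      add("afp: afp_bl and afp_fu must both be present or both missing")
    } else {
      if (!is.finite(bl) || bl <= 0) {
        add("afp_bl: must be finite and > 0 (denominator of the AFP change)")
      }
      if (!is.finite(fu) || fu < 0) add("afp_fu: must be finite and >= 0")
    }
  }

  s <- record$survival
  if (!is.null(s)) {
    if (!is.na(s$rfs_months) && (!is.finite(s$rfs_months) || s$rfs_months < 0)) {
      add("rfs_months: must be finite and >= 0")
    }
    if (!is.na(s$os_months) && (!is.finite(s$os_months) || s$os_months < 0)) {
      add("os_months: must be finite and >= 0")
    }
    if (!is.na(s$rfs_months) && !is.na(s$os_months) &&
        s$rfs_months > s$os_months) {
      add("survival: rfs_months exceeds os_months")
    }
  }

  if (!is.null(record$pathology)) {
    pv <- record$pathology$percent_viable
    if (!is.finite(pv) || pv < 0 || pv > 1) {
      add("percent_viable: must lie in [0, 1]")
    }
  }

  if (!is.na(record$nontarget_status) &&
      !record$nontarget_status %in% NONTARGET_LEVELS) {
    add(sprintf("nontarget_status: '%s' not one of %s", record$nontarget_status,
                paste(NONTARGET_LEVELS, collapse = "/")))
  }
  for (rd in names(record$reader_categories)) {
    cat_i <- record$reader_categories[[rd]]
    if (!cat_i %in% response_categories()) {
      add(sprintf("%s_category: '%s' not one of CR/PR/SD/PD", rd, cat_i))
    }
  }
  v
}

#' Validate every record of a cohort
#'
#' @param cohort An `rc_cohort`.
#' @return Tibble with columns `patient_id` and `violation`; zero rows when
#'   the cohort is fully valid.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "rc_cohort"))
  out <- lapply(cohort$patients$patient_id, function(pid) {
    v <- validate_record(patient_record(cohort, pid))
    if (length(v) == 0) return(NULL)
    tibble::tibble(patient_id = pid, violation = v)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) {
    return(tibble::tibble(patient_id = character(0), violation = character(0)))
  }
  do.call(rbind, out)
}

cohort_paths <- function(path) {
  list(patients = paste0(path, "_patients.csv"),
       lesions = paste0(path, "_lesions.csv"))
}

patient_col_types <- readr::cols(
  patient_id = readr::col_character(),
  new_lesions = readr::col_logical(),
  nontarget_status = readr::col_character(),
  afp_bl = readr::col_double(),
  afp_fu = readr::col_double(),
  rfs_months = readr::col_double(),
  rfs_event = readr::col_logical(),
  os_months = readr::col_double(),
  os_event = readr::col_logical(),
  percent_viable = readr::col_double(),
  reader1_category = readr::col_character(),
  reader2_category = readr::col_character()
)

lesion_col_types <- readr::cols(
  patient_id = readr::col_character(),
  lesion_id = readr::col_character(),
  organ = readr::col_character(),
  timepoint = readr::col_character(),
  longest_diameter_mm = readr::col_double(),
  viable_diameter_mm = readr::col_double(),
  is_target = readr::col_logical()
)

#' Read a cohort from its CSV pair
#'
#' The on-disk layout is two UTF-8 CSV files sharing a path stem:
#' `<path>_patients.csv` (one row per patient) and `<path>_lesions.csv` (one
#' row per lesion-timepoint). Missing values are empty cells. Numeric fields
#' round-trip at full precision through [write_cohort()].
#'
#' @param path Path stem (without the `_patients.csv` / `_lesions.csv`
#'   suffix).
#' @param validate Validate all records after parsing (default `TRUE`).
#' @return An `rc_cohort`, row order preserved.
#' @export
load_cohort <- function(path, validate = TRUE) {
  fp <- cohort_paths(path)
  for (f in unlist(fp)) {
    if (!file.exists(f)) stop("cohort file not found: ", f, call. = FALSE)
  }
  read_one <- function(file, types, required) {
    header <- names(readr::read_csv(file, n_max = 0, col_types = readr::cols(),
                                    show_col_types = FALSE))
    missing <- setdiff(required, header)
    if (length(missing) > 0) {
      stop(sprintf("%s is missing required column(s): %s", file,
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    df <- suppressWarnings(
      readr::read_csv(file, col_types = types, na = c("", "NA"),
                      show_col_types = FALSE))
    probs <- readr::problems(df)
    if (nrow(probs) > 0) {
      stop(sprintf("%s: parse error at row %d, column '%s' (expected %s, got '%s')",
                   file, probs$row[1], header[probs$col[1]],
                   probs$expected[1], probs$actual[1]), call. = FALSE)
    }
    df
  }
  patients <- read_one(fp$patients, patient_col_types, PATIENT_COLS)
  lesions <- read_one(fp$lesions, lesion_col_types, LESION_COLS)
  new_cohort(patients, lesions,
             provenance = list(source = path), validate = validate)
}

#' Write a cohort to its CSV pair
#'
#' Inverse of [load_cohort()]: `load_cohort(write_cohort(cohort, path))`
#' reproduces the cohort exactly, with missing values written as empty cells
#' (never zero) and doubles serialized with a round-trip-exact representation.
#'
#' @param cohort An `rc_cohort`.
#' @param path Path stem; `<path>_patients.csv` and `<path>_lesions.csv` are
#'   created (directories must exist).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "rc_cohort"))
  fp <- cohort_paths(path)
  readr::write_csv(cohort$patients[, PATIENT_COLS], fp$patients, na = "")
  readr::write_csv(cohort$lesions[, LESION_COLS], fp$lesions, na = "")
  invisible(path)
}
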