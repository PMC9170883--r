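mk_summary <- function(sld_bl, sld_fu, viable_bl = sld_bl * 0.8,
                       viable_fu = sld_fu * 0.8, afp_delta = NA_real_) {
  structure(list(
    sld_bl = sld_bl, sld_fu = sld_fu,
    sld_change = (sld_fu - sld_bl) / sld_bl,
    viable_sld_bl = viable_bl, viable_sld_fu = viable_fu,
    viable_change = if (viable_bl > 0) (viable_fu - viable_bl) / viable_bl
                    else NA_real_,
    afp_delta = afp_delta
  ), class = "change_summary")
}

mk_record <- function(afp_bl = NA, afp_fu = NA, new_lesions = FALSE,
                      nontarget_status = "absent") {
  list(new_lesions = new_lesions, nontarget_status = nontarget_status,
       afp = if (is.na(afp_bl)) NULL else list(afp_bl = afp_bl, afp_fu = afp_fu))
}

test_that("target-lesion selection keeps the largest within organ limits", {
  one <- tibble::tibble(patient_id = "X", lesion_id = "L1", organ = "liver",
                        timepoint = "baseline", longest_diameter_mm = 70,
                        viable_diameter_mm = 50, is_target = TRUE)
  expect_identical(select_target_lesions(one), "L1")

  liver3 <- tibble::tibble(
    patient_id = "X", lesion_id = c("L1", "L2", "L3"), organ = "liver",
    timepoint = "baseline", longest_diameter_mm = c(40, 30, 20),
    viable_diameter_mm = 10, is_target = TRUE)
  expect_identical(select_target_lesions(liver3), c("L1", "L2"))

  # sub-centimetre lesions are not eligible
  small <- one
  small$longest_diameter_mm <- 8
  expect_error(select_target_lesions(small), "no target lesion")
})

test_that("selection of 7 lesions over 4 organs maximizes the diameter sum under the limits", {
  set.seed(404)
  for (rep in 1:5) {
    organs <- sample(c("liver", "lung", "node", "adrenal"), 7, replace = TRUE)
    while (length(unique(organs)) < 4) {
      organs <- sample(c("liver", "lung", "node", "adrenal"), 7, replace = TRUE)
    }
    les <- tibble::tibble(
      patient_id = "X", lesion_id = sprintf("L%d", 1:7), organ = organs,
      timepoint = "baseline",
      longest_diameter_mm = round(runif(7, 10, 90), 1),
      viable_diameter_mm = 5, is_target = TRUE)
    sel <- select_target_lesions(les)
    expect_length(sel, 5)
    expect_true(all(table(les$organ[les$lesion_id %in% sel]) <= 2))
    # brute force over all feasible 5-subsets: greedy must attain the max sum
    combos <- utils::combn(7, 5)
    feas_sum <- apply(combos, 2, function(idx) {
      if (any(table(les$organ[idx]) > 2)) return(NA_real_)
      sum(les$longest_diameter_mm[idx])
    })
    expect_equal(sum(les$longest_diameter_mm[les$lesion_id %in% sel]),
                 max(feas_sum, na.rm = TRUE))
  }
})

test_that("change summaries sum target lesions and derive fractions", {
  cohort <- make_cohort(sld_bl = 100, sld_fu = 58,
                        afp_bl = 1000, afp_fu = 42)
  s <- summarize_changes(patient_record(cohort, "P001"))
  expect_equal(s$sld_change, -0.42)
  expect_equal(s$afp_delta, -0.958)

  # two lesions (50,50) -> (40,20): overall -40%
  les <- rbind(
    tibble::tibble(patient_id = "X", lesion_id = c("A", "B"), organ = "liver",
                   timepoint = "baseline", longest_diameter_mm = c(50, 50),
                   viable_diameter_mm = c(40, 40), is_target = TRUE),
    tibble::tibble(patient_id = "X", lesion_id = c("A", "B"), organ = "liver",
                   timepoint = "followup", longest_diameter_mm = c(40, 20),
                   viable_diameter_mm = c(30, 10), is_target = TRUE))
  rec <- list(lesions = les, afp = NULL)
  s2 <- summarize_changes(rec)
  expect_equal(s2$sld_bl, 100)
  expect_equal(s2$sld_change, -0.40)

  # identical measurements -> zero change
  same <- make_cohort(sld_bl = 60, sld_fu = 60)
  s3 <- summarize_changes(patient_record(same, "P001"))
  expect_equal(s3$sld_change, 0)
  expect_equal(s3$viable_change, 0)
})

test_that("afp_delta is the signed fractional change with a positive baseline", {
  expect_equal(afp_delta(list(afp_bl = 200, afp_fu = 48)), -0.76)
  expect_equal(afp_delta(list(afp_bl = 100, afp_fu = 100)), 0)
  expect_equal(afp_delta(list(afp_bl = 50, afp_fu = 100)), 1)
  expect_error(afp_delta(list(afp_bl = 0, afp_fu = 10)), "afp_bl")
  expect_error(afp_delta(NULL), "missing")
})

test_that("RECIST 1.1 cascade: PD veto, CR on disappearance, 30%/20%/5mm thresholds", {
  expect_identical(classify_recist11(mk_summary(100, 58), FALSE, "absent"), "PR")
  # +24% but only +2.4 mm: the 5 mm absolute rule blocks PD
  expect_identical(classify_recist11(mk_summary(10, 12.4), FALSE, "absent"), "SD")
  # +22% and +11 mm: PD
  expect_identical(classify_recist11(mk_summary(50, 61), FALSE, "absent"), "PD")
  expect_identical(classify_recist11(mk_summary(100, 0, 80, 0), FALSE, "absent"), "CR")
  # new lesions always veto
  expect_identical(classify_recist11(mk_summary(100, 58), TRUE, "absent"), "PD")
  expect_identical(classify_recist11(mk_summary(100, 58), FALSE, "PD"), "PD")
  # residual non-target disease downgrades target disappearance to PR
  expect_identical(classify_recist11(mk_summary(100, 0, 80, 0), FALSE,
                                     "non-CR/non-PD"), "PR")
})

test_that("mRECIST classifies on the viable (enhancing) diameters", {
  # enhancement disappears while size persists: mRECIST CR, RECIST SD
  s <- mk_summary(80, 60, viable_bl = 80, viable_fu = 0)
  expect_identical(classify_mrecist(s, FALSE, "absent"), "CR")
  expect_identical(classify_recist11(s, FALSE, "absent"), "SD")
  expect_identical(classify_mrecist(mk_summary(100, 90, 100, 65), FALSE, "absent"), "PR")
  expect_identical(classify_mrecist(mk_summary(100, 90, 100, 125), TRUE, "absent"), "PD")
  # no absolute-mm condition for viable PD
  expect_identical(classify_mrecist(mk_summary(20, 20, 10, 12.5), FALSE, "absent"), "PD")
})

test_that("boundary values are inclusive and not pre-rounded", {
  expect_identical(classify_recist11(mk_summary(100, 70), FALSE, "absent"), "PR")
  expect_identical(classify_recist11(mk_summary(100, 70 + 1e-9), FALSE, "absent"), "SD")
  # +20% with exactly 5.0 mm
  expect_identical(classify_recist11(mk_summary(25, 30), FALSE, "absent"), "PD")
  sp <- resolve_criteria("alpha-RECIST")[[1]]
  rec <- mk_record(afp_bl = 100, afp_fu = 24)  # exactly -76%
  expect_identical(classify_composite(rec, sp, mk_summary(100, 90, afp_delta = -0.76)), "PR")
  rec2 <- mk_record(afp_bl = 100, afp_fu = 24 + 1e-6)
  expect_identical(classify_composite(rec2, sp, mk_summary(100, 90)), "SD")
})

test_that("the OR composite admits all three responder patterns and AND requires both", {
  alpha <- resolve_criteria("alpha-RECIST")[[1]]
  and_spec <- resolve_criteria("alpha-and-delta-RECIST")[[1]]
  cases <- list(  # (size change, afp change) from the three worked examples
    c(-0.42, -0.958), c(-0.34, -0.15), c(-0.17, -0.974))
  for (cs in cases) {
    rec <- mk_record(afp_bl = 1000, afp_fu = 1000 * (1 + cs[2]))
    s <- mk_summary(100, 100 * (1 + cs[1]))
    expect_identical(classify_composite(rec, alpha, s), "PR")
  }
  # neither threshold met
  rec <- mk_record(afp_bl = 100, afp_fu = 50)
  expect_identical(classify_composite(rec, alpha, mk_summary(100, 83)), "SD")
  # AND rejects a size-only response
  rec <- mk_record(afp_bl = 100, afp_fu = 85)
  expect_identical(classify_composite(rec, and_spec, mk_summary(100, 58)), "SD")
  # base PD vetoes even a large AFP drop
  rec <- mk_record(afp_bl = 1000, afp_fu = 10, new_lesions = TRUE)
  expect_identical(classify_composite(rec, alpha, mk_summary(100, 58)), "PD")
  # missing AFP is non-evaluable, not SD
  rec <- mk_record()
  expect_identical(classify_composite(rec, alpha, mk_summary(100, 58)), "NE")
})

test_that("baseline-AFP composites count AFP_BL >= 54.4 ng/ml toward response as printed", {
  bl_or <- resolve_criteria("alpha-bl-RECIST")[[1]]
  rec_hi <- mk_record(afp_bl = 54.4, afp_fu = 54.4)
  rec_lo <- mk_record(afp_bl = 54.3, afp_fu = 54.3)
  s_sd <- mk_summary(100, 90)
  expect_identical(classify_composite(rec_hi, bl_or, s_sd), "PR")
  expect_identical(classify_composite(rec_lo, bl_or, s_sd), "SD")
})

test_that("monotonicity: growing tumors never improve, falling AFP never worsens", {
  rank_of <- function(cat) match(cat, c("CR", "PR", "SD", "PD"))
  fus <- seq(0, 130, by = 2.5)
  cats <- vapply(fus, function(fu) {
    classify_recist11(mk_summary(100, fu), FALSE, "absent")
  }, character(1))
  expect_true(all(diff(rank_of(cats)) >= 0))

  alpha <- resolve_criteria("alpha-RECIST")[[1]]
  afp_fus <- seq(200, 0, by = -5)
  cats2 <- vapply(afp_fus, function(fu) {
    classify_composite(mk_record(afp_bl = 200, afp_fu = fu), alpha,
                       mk_summary(100, 85))
  }, character(1))
  expect_true(all(diff(rank_of(cats2)) <= 0))
})

test_that("criterion algebra holds on PD-free cohorts", {
  for (seed in c(21, 22)) {
    cohort <- generate_cohort(generator_params(n = 100, seed = seed))
    tbl <- evaluate_cohort(cohort, resolve_criteria(
      c("RECIST 1.1", "alpha-RECIST", "alpha-and-delta-RECIST")))
    expect_true(all(tbl$recist11 %in% c("CR", "PR", "SD")))  # generator plants no PD
    base <- tbl$responder_recist11
    or_r <- tbl$responder_alpha_delta_recist
    and_r <- tbl$responder_alpha_and_delta_recist
    expect_true(all(!and_r | base))   # AND subset of base
    expect_true(all(!base | or_r))    # base subset of OR
    afp_ok <- tbl$afp_delta <= -0.76
    expect_equal(sum(or_r) + sum(and_r), sum(base) + sum(afp_ok))
  }
})

test_that("eight AFP-only responders reclassify base SD patients without losing base responders", {
  # 5 size responders (AFP flat), 8 size-SD with deep AFP drops, 7 plain SD
  sld_fu <- c(rep(60, 5), rep(90, 15))
  afp_fu <- c(rep(90, 5), rep(10, 8), rep(80, 7))
  cohort <- make_cohort(sld_bl = rep(100, 20), sld_fu = sld_fu,
                        afp_bl = rep(100, 20), afp_fu = afp_fu)
  tbl <- evaluate_cohort(cohort, resolve_criteria(c("RECIST 1.1", "alpha-RECIST")))
  expect_equal(sum(tbl$responder_recist11), 5)
  expect_equal(sum(tbl$responder_alpha_delta_recist), 13)
  expect_true(all(!tbl$responder_recist11 | tbl$responder_alpha_delta_recist))
})

test_that("evaluate_cohort emits marginal counts and flags non-evaluable patients", {
  cohort <- make_cohort(sld_bl = c(100, 100, 100), sld_fu = c(58, 66, 83),
                        afp_bl = c(1000, NA, 1000), afp_fu = c(42, NA, 26))
  tbl <- evaluate_cohort(cohort)
  expect_identical(tbl$alpha_delta_recist, c("PR", "NE", "PR"))
  expect_true(is.na(tbl$responder_alpha_delta_recist[2]))
  counts <- attr(tbl, "counts")
  row <- counts[counts$ascii == "alpha_delta_recist", ]
  expect_equal(row$PR, 2)
  expect_equal(row$NE, 1)
  # RECIST 1.1 needs no AFP
  expect_identical(tbl$recist11, c("PR", "PR", "SD"))
})

test_that("criterion names resolve through display names and ASCII aliases", {
  reg <- criterion_registry()
  expect_length(reg, 10)
  expect_identical(resolve_criteria("alpha-RECIST")[[1]]$ascii, "alpha_delta_recist")
  expect_identical(resolve_criteria("αΔ-RECIST")[[1]]$ascii, "alpha_delta_recist")
  expect_identical(resolve_criteria("all"), reg)
  expect_error(resolve_criteria("no-such-criterion"), "unknown criterion")
  # the published alpha-RECIST is the delta-OR variant at the default cutoffs
  alpha <- reg$alpha_delta_recist
  expect_identical(alpha$base, "RECIST11")
  expect_identical(alpha$combiner, "or")
  expect_equal(alpha$afp_delta_cutoff, -0.76)
})
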