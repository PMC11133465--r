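test_that("LMD classification follows the diagnostic definitions", {
  rec <- function(cyt, pcr, mri, sym) {
    tibble::tibble(cytology_positive = cyt, egfr_csf_pcr_positive = pcr,
                   mri_unequivocal_lmd = mri, progressive_symptoms = sym)
  }
  # positive cytology: definitive and EANO-confirmed, whatever else holds
  out <- classify_lmd(rec(TRUE, FALSE, FALSE, FALSE))
  expect_equal(out$study_category, "definitive")
  expect_equal(out$eano_esmo, "confirmed")
  # MRI + symptoms without cytology: definitive but only probable
  out <- classify_lmd(rec(FALSE, FALSE, TRUE, TRUE))
  expect_equal(out$study_category, "definitive")
  expect_equal(out$eano_esmo, "probable")
  # symptoms alone: possible in both schemes
  out <- classify_lmd(rec(FALSE, FALSE, FALSE, TRUE))
  expect_equal(out$study_category, "possible")
  expect_equal(out$eano_esmo, "possible")
  # PCR alone: definitive by the study rule, no EANO category
  out <- classify_lmd(rec(FALSE, TRUE, FALSE, FALSE))
  expect_equal(out$study_category, "definitive")
  expect_equal(out$eano_esmo, "none")
})

test_that("unknown fields default to negative with completeness flags", {
  d <- tibble::tibble(cytology_positive = c(NA, NA),
                      egfr_csf_pcr_positive = c(TRUE, NA),
                      mri_unequivocal_lmd = c(NA, NA),
                      progressive_symptoms = c(TRUE, NA))
  expect_warning(out <- classify_lmd(d),
                 class = "csftdna_incomplete_clinical")
  expect_equal(out$study_category, c("definitive", "non_lmd"))
  expect_false(any(out$data_complete))
})

test_that("modality sensitivity reports numerator and denominator", {
  d <- tibble::tibble(
    study_category = c(rep("definitive", 12), rep("possible", 5)),
    csf_tdna = c(rep(TRUE, 11), FALSE, rep(TRUE, 5)),
    cytology = c(rep(TRUE, 9), FALSE, FALSE, NA, rep(NA, 5)),
    mri = c(rep(FALSE, 12), rep(NA, 5))
  )
  out <- modality_sensitivity(d, "csf_tdna", "cytology", "mri")
  tdna <- out[out$modality == "csf_tdna", ]
  expect_equal(tdna$sensitivity, 11 / 12) # 91.7%
  expect_equal(tdna$n_evaluable, 12L)
  cyt <- out[out$modality == "cytology", ]
  expect_equal(cyt$sensitivity, 9 / 11) # 81.8%
  mri <- out[out$modality == "mri", ]
  expect_equal(mri$sensitivity, 0)
  # possible-LMD rows never enter the denominator
  expect_true(all(out$n_evaluable <= 12))
  # adding a positive definitive case never decreases sensitivity
  d2 <- dplyr::bind_rows(d, tibble::tibble(study_category = "definitive",
                                           csf_tdna = TRUE, cytology = TRUE,
                                           mri = TRUE))
  out2 <- modality_sensitivity(d2, "csf_tdna", "cytology", "mri")
  expect_true(all(out2$sensitivity >= out$sensitivity))
  # empty denominator: undefined
  d0 <- tibble::tibble(study_category = "definitive", x = NA)
  expect_warning(s0 <- modality_sensitivity(d0, "x"),
                 class = "csftdna_undefined_result")
  expect_true(is.na(s0$sensitivity))
})

test_that("median dichotomization uses the midpoint and inclusive lower group", {
  g <- dichotomize_by_median(c(1, 2, 3, 4))
  expect_equal(attr(g, "threshold"), 2.5)
  expect_equal(as.character(g), c("at_or_below", "at_or_below",
                                  "above", "above"))
  g2 <- dichotomize_by_median(c(1, 2, 2, 5, 9)) # median 2, tie at median
  expect_equal(as.character(g2)[2:3], c("at_or_below", "at_or_below"))
  expect_error(dichotomize_by_median(c(3, 3, 3)), "identical")
  expect_error(dichotomize_by_median(2), ">= 2")
})

test_that("median split of simulated on-treatment VAFs sits near 4.8%", {
  # osimertinib-cohort-like marker: log-normal around a 4.8% median
  set.seed(61)
  reps <- replicate(200, {
    v <- exp(log(0.048) + 0.8 * rnorm(24))
    attr(dichotomize_by_median(v), "threshold")
  })
  expect_lt(abs(median(reps) - 0.048) / 0.048, 0.1)
})

test_that("rank statistics match hand-computed oracles", {
  expect_equal(spearman_corr(1:5, 2 * (1:5) + 3)$estimate, 1)
  expect_equal(spearman_corr(1:5, rev(1:5))$estimate, -1)
  # 6-pair fixture, hand-ranked: x ranks 1..6, y values rank to
  # (2,3,1,5,6,4); sum d^2 = 12, rho = 1 - 6*12/210
  x <- c(10, 20, 30, 40, 50, 60)
  y <- c(1.2, 1.5, 0.9, 3.1, 4.0, 2.2)
  expect_equal(spearman_corr(x, y)$estimate, 1 - 72 / 210)
  expect_warning(spearman_corr(rep(1, 5), 1:5),
                 class = "csftdna_undefined_result")
  expect_error(spearman_corr(1:2, 1:2), ">= 3")

  mw <- mann_whitney(c(1, 2, 3), c(10, 11, 12))
  # complete separation of 3 vs 3: exact two-sided p = 2/choose(6,3) = 0.1
  expect_equal(mw$p_value, 0.1)
  expect_equal(mw$statistic, 0) # all a below b
})

test_that("drug penetration and VAF change arithmetic", {
  expect_equal(penetration_rate(5, 100), 5)
  expect_equal(penetration_rate(100, 100), 100)
  expect_equal(penetration_rate(2.5, 250), 1)
  expect_warning(pr <- penetration_rate(5, 0),
                 class = "csftdna_undefined_result")
  expect_true(is.na(pr))

  expect_equal(vaf_percent_change(0.10, 0.20), 100)
  expect_equal(vaf_percent_change(0.10, 0.10), 0)
  expect_equal(vaf_percent_change(0.04, 0.01), -75)
  expect_warning(vc <- vaf_percent_change(0, 0.05),
                 class = "csftdna_new_detection")
  expect_true(is.na(vc))
})
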