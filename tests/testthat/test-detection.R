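test_that("mean VAF is the unweighted mean over covered reporters", {
  panel <- tiny_panel()
  reps <- panel[1:3, c("chrom", "pos", "ref", "alt")]
  s <- make_counts(panel[1:3, ], "s", depth = c(100, 100, 100),
                   alt_count = c(10, 20, 30))
  expect_equal(as.numeric(mean_vaf(s, reps)), 0.2)

  s2 <- make_counts(panel[1:2, ], "s", depth = c(100, 200),
                    alt_count = c(1, 4))
  expect_equal(as.numeric(mean_vaf(s2, panel[1:2, ])), 0.015)

  s0 <- make_counts(panel[1:3, ], "s", depth = 100, alt_count = 0)
  expect_equal(as.numeric(mean_vaf(s0, reps)), 0)

  # depth-0 reporters are excluded and counted
  s3 <- make_counts(panel[1:3, ], "s", depth = c(100, 0, 100),
                    alt_count = c(10, 0, 30))
  mv <- mean_vaf(s3, reps)
  expect_equal(as.numeric(mv), 0.2)
  expect_equal(attr(mv, "n_evaluated"), 2L)
  expect_equal(attr(mv, "n_excluded"), 1L)

  # zero evaluable reporters: undefined, not 0
  s4 <- make_counts(panel[1:3, ], "s", depth = 0, alt_count = 0)
  expect_warning(mv4 <- mean_vaf(s4, reps),
                 class = "csftdna_undefined_result")
  expect_true(is.na(mv4))
})

test_that("detection index behaves as a randomized p-value", {
  panel <- tiny_panel()
  prof <- flat_profile(panel, rate = 1e-4)
  reps <- panel[1:10, c("chrom", "pos", "ref", "alt")]

  # observed mean VAF of 0 can never beat the null
  s0 <- make_counts(panel, "s0", depth = 1000, alt_count = 0)
  idx0 <- detection_index(s0, reps, prof, B = 1000, seed = 1)
  expect_equal(as.numeric(idx0), 1)

  # overwhelming signal achieves the lower bound 1/(B+1)
  s5 <- make_counts(panel, "s5", depth = 1000, alt_count = 500)
  idx5 <- detection_index(s5, reps, prof, B = 10000, seed = 1)
  expect_equal(as.numeric(idx5), 1 / 10001)
  # oracle: chance any of B*10 null draws reaches VAF 0.5 is bounded by
  # B * 10 * P(Binom(1000, 1e-4) >= 500) << 1
  expect_lt(1e5 * pbinom(499, 1000, 1e-4, lower.tail = FALSE), 1e-200)

  # determinism and substream isolation
  expect_identical(as.numeric(detection_index(s5, reps, prof, B = 2000,
                                              seed = 9)),
                   as.numeric(detection_index(s5, reps, prof, B = 2000,
                                              seed = 9)))
  expect_error(detection_index(s5, reps, prof, B = 10),
               ">= 1000")
})

test_that("a larger observed mean VAF never yields a larger index", {
  panel <- tiny_panel()
  prof <- flat_profile(panel, rate = 5e-3)
  reps <- panel[1:6, c("chrom", "pos", "ref", "alt")]
  alts <- c(0, 1, 3, 8, 20, 60)
  idx <- vapply(alts, function(a) {
    s <- make_counts(panel, "sA", depth = 500, alt_count = a)
    as.numeric(detection_index(s, reps, prof, B = 4000, seed = 77))
  }, numeric(1))
  expect_true(all(diff(idx) <= 0))
})

test_that("reporters missing from the profile are a hard error", {
  panel <- tiny_panel()
  prof <- flat_profile(panel[1:4, ])
  s <- make_counts(panel, "s", 100, 1)
  expect_error(detection_index(s, panel[1:6, ], prof, B = 1000),
               "missing from the error profile")
})

test_that("detection boundary is inclusive at the cutoff", {
  expect_true(classify_detection(0.05))
  expect_false(classify_detection(0.0501))
  expect_false(classify_detection(1.0))
  expect_true(classify_detection(0.002))
  expect_error(classify_detection(0.5, cutoff = 0))
})

test_that("detect_tdna summarizes every sample with annotation", {
  co <- shared_cohort()
  prof <- shared_profile()
  truth <- co$truth
  pid <- truth$patients$patient_id[1]
  reps <- truth$reporters[truth$reporters$patient_id == pid, ]
  ids <- co$sample_sheet$sample_id[co$sample_sheet$patient_id == pid &
                                     co$sample_sheet$compartment != "germline"]
  out <- detect_tdna(co$counts[co$counts$sample_id %in% ids, ], reps, prof,
                     sample_sheet = co$sample_sheet, B = 1000, seed = 5)
  expect_setequal(out$sample_id, ids)
  expect_true(all(c("patient_id", "compartment", "mean_vaf",
                    "detection_index", "detected") %in% names(out)))
  expect_true(all(out$detection_index >= 1 / 1001 &
                    out$detection_index <= 1, na.rm = TRUE))
  expect_equal(out$detected, out$detection_index <= 0.05)
})

test_that("mean VAF estimates are unbiased for tumor fraction x clonal VAF", {
  cfg <- sim_config(panel_size = 200, seed = 17)
  panel <- simulate_panel(cfg)
  reps <- panel[seq(1, 200, by = 10), ] # 20 reporters
  tv <- tibble::tibble(chrom = reps$chrom, pos = reps$pos, vaf = 0.5)
  tf <- 0.3
  est <- purrr::map_dbl(1:150, function(i) {
    s <- simulate_sample_counts(panel, tf, depth_mean = 150,
                                truth_vafs = tv, seed = 4000 + i)
    as.numeric(mean_vaf(s, reps))
  })
  true_val <- tf * 0.5
  expect_lt(abs(mean(est) - true_val) / true_val, 0.05)
})
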