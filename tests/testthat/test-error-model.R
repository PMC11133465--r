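test_that("error rates pool control counts with the recorded pseudocounts", {
  panel <- tiny_panel()[1, ]
  ctl <- dplyr::bind_rows(
    make_counts(panel, "c1", depth = 1000, alt_count = 1),
    make_counts(panel, "c2", depth = 1000, alt_count = 3)
  )
  prof0 <- estimate_error_profile(ctl, pseudocounts = c(0, 0))
  expect_equal(prof0$error_rate, 4 / 2000)
  expect_equal(prof0$total_depth, 2000L)

  ctl0 <- dplyr::bind_rows(
    make_counts(panel, "c1", depth = 5000, alt_count = 0),
    make_counts(panel, "c2", depth = 5000, alt_count = 0)
  )
  profj <- estimate_error_profile(ctl0, pseudocounts = c(0.5, 1))
  expect_equal(profj$error_rate, 0.5 / 10001)
  expect_gt(profj$error_rate, 0)
  expect_equal(attr(profj, "pseudocounts"), c(alt = 0.5, depth = 1))
})

test_that("zero-depth positions are flagged unusable, not silently zero", {
  panel <- tiny_panel()[1:2, ]
  ctl <- dplyr::bind_rows(
    make_counts(panel, "c1", depth = c(1000, 0), alt_count = 0),
    make_counts(panel, "c2", depth = c(1000, 0), alt_count = 0)
  )
  prof <- estimate_error_profile(ctl)
  expect_equal(prof$usable, c(TRUE, FALSE))
  expect_true(is.na(prof$error_rate[2]))
  expect_error(estimate_error_profile(make_counts(panel, "only_one", 10, 0)),
               "2 control")
})

test_that("estimated mean error matches the generating Beta mean", {
  cfg <- sim_config(panel_size = 2000, error_beta_shape1 = 0.5,
                    error_beta_shape2 = 4999.5, seed = 31)
  panel <- simulate_panel(cfg)
  ctl <- purrr::map_dfr(sprintf("c%d", 1:8), function(id) {
    simulate_sample_counts(panel, 0, depth_mean = 2000, sample_id = id,
                           seed = derive_seed(31, id))
  })
  prof <- estimate_error_profile(ctl, pseudocounts = c(0, 0))
  est <- mean(prof$error_rate)
  # SE of the mean estimated rate across 2000 Beta-distributed positions
  se <- sd(prof$error_rate) / sqrt(nrow(prof))
  expect_lt(abs(est - 1e-4), 3 * se)
})

test_that("binomial caller separates true signal from background", {
  panel_big <- tibble::tibble(.rows = 100000) # Bonferroni family only
  panel <- tiny_panel()
  prof <- flat_profile(panel, rate = 1e-4)
  s <- make_counts(panel[1, ], "s", depth = 1000, alt_count = 50)
  called <- call_variants_tumor_naive(s, prof, panel, alpha = 0.05,
                                      n_tests = 1e5)
  expect_equal(nrow(called), 1)
  # oracle: exact binomial tail is far below the Bonferroni threshold
  expect_lt(pbinom(49, 1000, 1e-4, lower.tail = FALSE), 0.05 / 1e5)

  prof3 <- flat_profile(panel, rate = 1e-3)
  s1 <- make_counts(panel[1, ], "s", depth = 1000, alt_count = 1)
  expect_equal(nrow(call_variants_tumor_naive(s1, prof3, panel)), 0)
  # oracle: P(X >= 1 | n=1000, p=1e-3) ~ 0.63, never below any threshold
  expect_equal(pbinom(0, 1000, 1e-3, lower.tail = FALSE), 0.6323,
               tolerance = 1e-3)

  s0 <- make_counts(panel, "s", depth = 1000, alt_count = 0)
  expect_equal(nrow(call_variants_tumor_naive(s0, prof, panel)), 0)
})

test_that("positions missing from the profile are excluded and counted", {
  panel <- tiny_panel()
  prof <- flat_profile(panel[1:5, ])
  s <- make_counts(panel, "s", depth = 1000, alt_count = 100)
  called <- call_variants_tumor_naive(s, prof, panel)
  expect_equal(attr(called, "qc")$n_missing_profile, 5)
  expect_true(all(called$pos %in% panel$pos[1:5]))
})

test_that("germline exclusion applies an inclusive VAF boundary", {
  panel <- tiny_panel()
  prof <- flat_profile(panel)
  cand <- call_variants_tumor_naive(
    make_counts(panel[1:3, ], "s", depth = 1000, alt_count = c(100, 90, 80)),
    prof, panel)
  expect_equal(nrow(cand), 3)
  # germline VAFs: heterozygous 0.49, zero, exactly at an 0.005 threshold
  germ <- make_counts(panel[1:3, ], "g", depth = 1000,
                      alt_count = c(490, 0, 5))
  kept <- exclude_germline(cand, germ, vaf_threshold = 0.005)
  expect_equal(kept$pos, panel$pos[2])
  removed <- attr(kept, "removed")
  expect_setequal(removed$pos, panel$pos[c(1, 3)])
  expect_true(all(removed$reason == "germline_vaf"))

  # default 0.02 threshold keeps the 0.005-VAF site
  kept2 <- exclude_germline(cand, germ)
  expect_setequal(kept2$pos, panel$pos[2:3])
})

test_that("germline exclusion is idempotent and honors the missing policy", {
  panel <- tiny_panel()
  prof <- flat_profile(panel)
  cand <- call_variants_tumor_naive(
    make_counts(panel[1:4, ], "s", depth = 1000, alt_count = 60),
    prof, panel)
  germ <- make_counts(panel[1:4, ], "g", depth = 1000,
                      alt_count = c(500, 0, 0, 0))
  once <- exclude_germline(cand, germ)
  twice <- exclude_germline(once, germ)
  expect_equal(nrow(once), nrow(twice))
  expect_identical(once$pos, twice$pos)
  expect_identical(once$alt_count, twice$alt_count)

  expect_error(exclude_germline(cand, NULL, missing_policy = "fail"),
               "germline")
  expect_warning(
    passed <- exclude_germline(cand, NULL, missing_policy = "pass"),
    class = "csftdna_missing_germline")
  expect_equal(nrow(passed), nrow(cand))
  expect_true(all(!passed$germline_checked))
})

test_that("coding filter keeps exactly the coding candidates, in order", {
  panel <- tiny_panel() # positions 5 and 10 are non-coding
  cand <- make_counts(panel[c(2, 5, 7, 10, 3), ], "s", 100, 10)
  kept <- filter_coding(cand, panel)
  expect_equal(kept$pos, panel$pos[c(2, 7, 3)]) # order preserved
  expect_equal(nrow(attr(kept, "removed")), 2)
  empty <- filter_coding(cand[0, ], panel)
  expect_equal(nrow(empty), 0)
  # unannotated position treated as non-coding
  stray <- cand[1, ]; stray$pos <- 999999L
  expect_equal(nrow(filter_coding(stray, panel)), 0)
})

test_that("reporter sets union calls across samples with set semantics", {
  panel <- tiny_panel()
  prof <- flat_profile(panel)
  # tumor sample calls EGFR@101; CSF calls EGFR@101 and TP53@201
  tumor <- make_counts(panel, "tumor", 1000, 0)
  tumor$alt_count[1] <- 300L
  csf <- make_counts(panel, "csf", 1000, 0)
  csf$alt_count[c(1, 7)] <- c(250L, 200L)
  germ <- make_counts(panel, "germ", 1000, 0)
  rs <- build_reporter_set(dplyr::bind_rows(tumor, csf), prof, panel,
                           germline = germ, patient_id = "P1")
  expect_s3_class(rs, "csf_reporter_set")
  expect_equal(nrow(rs), 2)
  expect_setequal(rs$gene, c("EGFR", "TP53"))
  shared <- rs$sources[[match(panel$pos[1], rs$pos)]]
  expect_setequal(shared, c("csf", "tumor"))
  expect_true(all(rs$coding))

  # order invariance
  rs_rev <- build_reporter_set(dplyr::bind_rows(csf, tumor), prof, panel,
                               germline = germ, patient_id = "P1")
  expect_equal(tibble::as_tibble(rs), tibble::as_tibble(rs_rev))

  # disjoint calls across two samples: union size = sum
  s1 <- make_counts(panel, "s1", 1000, 0); s1$alt_count[2] <- 200L
  s2 <- make_counts(panel, "s2", 1000, 0); s2$alt_count[3] <- 200L
  rs2 <- build_reporter_set(dplyr::bind_rows(s1, s2), prof, panel,
                            germline = germ)
  expect_equal(nrow(rs2), 2)

  # empty union is a valid zero-variant reporter set
  quiet <- make_counts(panel, "q", 1000, 0)
  rs0 <- build_reporter_set(quiet, prof, panel, germline = germ)
  expect_equal(nrow(rs0), 0)
})

test_that("caller respects family-wise error control on null data", {
  co <- shared_cohort()
  prof <- shared_profile()
  panel <- co$panel
  n_sim <- 60
  fw <- vapply(seq_len(n_sim), function(i) {
    s <- simulate_sample_counts(panel, 0, depth_mean = 150,
                                nb_size = co$config$nb_size,
                                sample_id = "null", seed = 7000 + i)
    nrow(call_variants_tumor_naive(s, prof, panel)) > 0
  }, logical(1))
  # Bonferroni guarantees FWER <= alpha; discreteness makes it conservative
  expect_lte(mean(fw), 0.05 + 3 * sqrt(0.05 * 0.95 / n_sim))
})
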