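test_that("the same seed reproduces a cohort exactly", {
  cfg <- sim_config(n_patients = 3, n_controls = 2, panel_size = 120,
                    seed = 7)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$truth$reporters, b$truth$reporters)
  # a different seed changes the data
  c2 <- simulate_cohort(sim_config(n_patients = 3, n_controls = 2,
                                   panel_size = 120, seed = 8))
  expect_false(identical(a$counts$alt_count, c2$counts$alt_count))
})

test_that("invalid configurations are rejected with the field named", {
  expect_error(sim_config(n_patients = 0), "n_patients")
  expect_error(sim_config(csf_negative_fraction = 1.5),
               "csf_negative_fraction")
  expect_error(sim_config(panel_size = 4, reporters_per_patient = 10),
               "panel_size")
  expect_error(sim_config(depth_by_compartment = c(CSF = -1, plasma = 10,
                                                   germline = 10)),
               "depth_by_compartment")
  expect_error(sim_config(csf_vaf_median = 0.9, clonal_vaf = 0.5),
               "clonal_vaf")
})

test_that("cohort structure matches the sampling plan", {
  co <- shared_cohort()
  sheet <- co$sample_sheet[!grepl("^CTRL", co$sample_sheet$patient_id), ]
  per_pat <- split(sheet, sheet$patient_id)
  for (p in per_pat) {
    expect_equal(sum(p$compartment == "germline"), 1)
    expect_gte(sum(p$compartment == "CSF"), 1)
    expect_gte(sum(p$compartment == "plasma"), 1)
  }
  expect_equal(sum(grepl("^CTRL", co$sample_sheet$patient_id)),
               co$config$n_controls)
  # every truth reporter lies in the panel, with positive clonal VAF
  key <- paste(co$panel$chrom, co$panel$pos)
  expect_true(all(paste(co$truth$reporters$chrom,
                        co$truth$reporters$pos) %in% key))
  expect_true(all(co$truth$reporters$vaf > 0 &
                    co$truth$reporters$vaf <= 1))
})

test_that("alt counts never exceed depth anywhere", {
  co <- shared_cohort()
  expect_true(all(co$counts$alt_count <= co$counts$depth))
  expect_true(all(co$counts$alt_count >= 0))
})

test_that("amplified_gene_fraction = 0 yields no amplification truth", {
  co <- simulate_cohort(sim_config(n_patients = 4, n_controls = 2,
                                   panel_size = 120,
                                   amplified_gene_fraction = 0, seed = 5))
  expect_true(all(is.na(co$truth$patients$amp_gene)))
})

test_that("tumor-free samples fluctuate at the background error scale", {
  cfg <- sim_config(panel_size = 2000, seed = 13)
  panel <- simulate_panel(cfg)
  # tall sample: replicate the panel positions via repeated draws
  reps <- purrr::map_dfr(1:50, function(i) {
    simulate_sample_counts(panel, tumor_fraction = 0, depth_mean = 1000,
                           nb_size = 8, sample_id = "null", seed = 100 + i)
  })
  observed <- sum(reps$alt_count) / sum(reps$depth)
  expected <- mean(panel$true_error_rate)
  # ~1e5 position draws: law of large numbers puts the pooled VAF within
  # 3 binomial standard errors of the mean generating rate
  se <- sqrt(expected / sum(as.numeric(reps$depth)))
  expect_lt(abs(observed - expected), 3 * se + 0.2 * expected)
})

test_that("a pure-tumor clonal variant is observed near its VAF", {
  panel <- tiny_panel()
  panel$true_error_rate <- rep(1e-9, nrow(panel))
  tv <- tibble::tibble(chrom = panel$chrom, pos = panel$pos, vaf = 0.5)
  s <- simulate_sample_counts(panel, tumor_fraction = 1, depth_mean = 5000,
                              truth_vafs = tv, seed = 3)
  vaf <- sum(s$alt_count) / sum(s$depth)
  se <- sqrt(0.25 / sum(s$depth))
  expect_lt(abs(vaf - 0.5), 4 * se)
})

test_that("expected mean VAF rises strictly with tumor fraction", {
  panel <- tiny_panel()
  tv <- tibble::tibble(chrom = panel$chrom[1:4], pos = panel$pos[1:4],
                       vaf = 0.5)
  mean_by_tf <- vapply(c(0.05, 0.2, 0.5, 0.9), function(tf) {
    reps <- purrr::map_dbl(1:200, function(i) {
      s <- simulate_sample_counts(panel, tf, depth_mean = 400,
                                  truth_vafs = tv,
                                  seed = round(tf * 1000) + i)
      j <- s[1:4, ]
      mean(j$alt_count / pmax(j$depth, 1))
    })
    mean(reps)
  }, numeric(1))
  expect_true(all(diff(mean_by_tf) > 0))
})

test_that("truth positions outside the panel are rejected", {
  panel <- tiny_panel()
  tv <- tibble::tibble(chrom = "chrX", pos = 1, vaf = 0.5)
  expect_error(simulate_sample_counts(panel, 0.5, 100, truth_vafs = tv),
               "outside the panel")
})

test_that("configured CSF and plasma VAF medians are recovered in simulation", {
  co <- simulate_cohort(sim_config(n_patients = 100, n_controls = 2,
                                   panel_size = 200,
                                   csf_negative_fraction = 0,
                                   resistance_scenario_fraction = 0,
                                   amplified_gene_fraction = 0, seed = 21))
  truth <- co$truth
  # score observed per-sample mean VAF over that patient's true reporters
  obs <- purrr::map_dfr(seq_len(nrow(truth$patients)), function(i) {
    pid <- truth$patients$patient_id[i]
    rep_i <- truth$reporters[truth$reporters$patient_id == pid, ]
    csf <- co$counts[co$counts$sample_id == paste0(pid, "_CSF_0"), ]
    pla <- co$counts[co$counts$sample_id == paste0(pid, "_plasma_0"), ]
    tibble::tibble(
      csf_vaf = as.numeric(mean_vaf(csf, rep_i)),
      plasma_vaf = as.numeric(mean_vaf(pla, rep_i))
    )
  })
  expect_lt(abs(median(obs$csf_vaf) - 0.327) / 0.327, 0.25)
  expect_lt(abs(median(obs$plasma_vaf) - 0.018) / 0.018, 0.25)
})

test_that("clinical simulation honors hazards, horizon and validation", {
  truth <- list(patients = tibble::tibble(
    patient_id = c("A", "B"), csf_tf = c(0.3, 0), plasma_tf = 0.01,
    tdna_detected = c(TRUE, FALSE)))
  expect_error(simulate_clinical(truth, list(baseline_hazard = -1,
                                             hr_detected = 2)),
               "baseline_hazard")
  expect_error(simulate_clinical(truth, list(baseline_hazard = 0.001,
                                             hr_detected = 0)),
               "hr_detected")
  cl0 <- simulate_clinical(truth, list(baseline_hazard = 0.001,
                                       hr_detected = 2, horizon_days = 0),
                           seed = 1)
  expect_true(all(cl0$os_time_days == 0))
  expect_true(all(!cl0$os_event))
})
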