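#' Operating-characteristic studies of the detection pipeline
#'
#' Simulation studies that measure the pipeline's statistical behavior
#' under known truth: null calibration and power of the Monte Carlo
#' detection index, quantification recovery, caller error control,
#' copy-number calling performance, and hazard-ratio recovery. Each
#' study generates its own data from the synthetic cohort machinery
#' under a caller-supplied seed, so results are reproducible and
#' independent across studies.
#'
#' `calibration_study()` fits a background error model to simulated
#' tumor-free controls, then scores `n_samples` tumor-free samples
#' (each with `n_reporters` reporters at `depth` mean coverage) and
#' reports the fraction detected at the cutoff — the empirical type-I
#' error of the detection index.
#'
#' Two null designs are available. `null_from = "fitted"` (default)
#' draws the tumor-free samples from the same fitted error model the
#' index tests against: this isolates the validity of the Monte Carlo
#' p-value itself, whose type-I error should sit at the cutoff up to
#' Monte Carlo noise. `null_from = "true"` draws the samples from the
#' generating (true) error rates while the index still uses the fitted
#' model: this end-to-end variant additionally absorbs estimation
#' error and the deliberate pseudocount inflation of fitted rates, and
#' is therefore conservative (a lower detection rate).
#'
#' @param n_samples Number of simulated samples scored.
#' @param n_reporters Reporters per sample.
#' @param depth Mean deduplicated depth of the scored samples.
#' @param B Monte Carlo iterations per sample.
#' @param cutoff Detection cutoff.
#' @param n_controls,control_depth Control cohort used to fit the error
#'   model.
#' @param panel_size Panel positions.
#' @param null_from `"fitted"` or `"true"` (see Details).
#' @param seed Master seed.
#' @return `calibration_study()`: list with `rate` (fraction detected),
#'   `n`, and the vector of indices.
#' @export
calibration_study <- function(n_samples = 1000, n_reporters = 20,
                              depth = 150, B = 10000, cutoff = 0.05,
                              n_controls = 12, control_depth = 1099,
                              panel_size = 2000,
                              null_from = c("fitted", "true"), seed = 1) {
  null_from <- match.arg(null_from)
  cfg <- sim_config(panel_size = panel_size, seed = seed)
  panel <- simulate_panel(cfg)
  prof <- fit_simulated_profile(panel, n_controls, control_depth, cfg, seed)
  if (null_from == "fitted") {
    fitted_rates <- prof$error_rate[match(
      variant_key(panel$chrom, panel$pos, panel$ref, panel$alt),
      variant_key(prof$chrom, prof$pos, prof$ref, prof$alt))]
  }
  idx <- vapply(seq_len(n_samples), function(i) {
    sub <- derive_seed(seed, "calib", i)
    rep_idx <- with_seed(sub, sample(nrow(panel), n_reporters))
    s <- simulate_sample_counts(
      panel[rep_idx, ], 0, depth, nb_size = cfg$nb_size,
      error_rates = if (null_from == "fitted") fitted_rates[rep_idx],
      sample_id = paste0("null", i),
      seed = derive_seed(seed, "calibcounts", i))
    as.numeric(detection_index(s, panel[rep_idx, ], prof, B = B,
                               seed = derive_seed(seed, "calibmc", i)))
  }, numeric(1))
  list(rate = mean(classify_detection(idx, cutoff)), n = n_samples,
       indices = idx)
}

#' @param true_mean_vaf True mean VAF of the scored samples (power
#'   study).
#' @rdname calibration_study
#' @return `power_study()`: list with `power` (fraction detected) and
#'   `n`.
#' @export
power_study <- function(n_samples = 200, true_mean_vaf = 0.01,
                        n_reporters = 20, depth = 150, B = 10000,
                        cutoff = 0.05, n_controls = 12,
                        control_depth = 1099, panel_size = 2000,
                        seed = 1) {
  cfg <- sim_config(panel_size = panel_size, seed = seed)
  panel <- simulate_panel(cfg)
  prof <- fit_simulated_profile(panel, n_controls, control_depth, cfg, seed)
  tf <- true_mean_vaf / cfg$clonal_vaf
  det <- vapply(seq_len(n_samples), function(i) {
    sub <- derive_seed(seed, "power", i)
    rep_idx <- with_seed(sub, sample(nrow(panel), n_reporters))
    tv <- tibble::tibble(chrom = panel$chrom[rep_idx],
                         pos = panel$pos[rep_idx], vaf = cfg$clonal_vaf)
    s <- simulate_sample_counts(panel[rep_idx, ], tf, depth,
                                truth_vafs = tv, nb_size = cfg$nb_size,
                                sample_id = paste0("pow", i),
                                seed = derive_seed(seed, "powcounts", i))
    classify_detection(as.numeric(
      detection_index(s, panel[rep_idx, ], prof, B = B,
                      seed = derive_seed(seed, "powmc", i))), cutoff)
  }, logical(1))
  list(power = mean(det), n = n_samples)
}

fit_simulated_profile <- function(panel, n_controls, control_depth, cfg,
                                  seed) {
  ctl <- purrr::map_dfr(seq_len(n_controls), function(i) {
    simulate_sample_counts(panel, 0, control_depth, nb_size = cfg$nb_size,
                           sample_id = sprintf("ctl%02d", i),
                           seed = derive_seed(seed, "control", i))
  })
  estimate_error_profile(ctl)
}

#' Quantification recovery across a simulated cohort
#'
#' Simulates a full cohort, scores every baseline CSF and plasma sample
#' over the patient's true reporters, and compares estimated mean VAF
#' with the known tumor fraction.
#'
#' @param n_patients Cohort size.
#' @param seed Master seed.
#' @return List with `spearman_rho` (true tumor fraction vs estimated
#'   mean VAF across samples), `relative_bias` (mean signed relative
#'   error of mean VAF against tumor_fraction x clonal VAF at >= 150x),
#'   and `n` samples scored.
#' @export
recovery_study <- function(n_patients = 100, seed = 1) {
  co <- simulate_cohort(sim_config(
    n_patients = n_patients, n_controls = 2, panel_size = 400,
    csf_negative_fraction = 0, resistance_scenario_fraction = 0,
    amplified_gene_fraction = 0, seed = seed))
  truth <- co$truth
  rows <- purrr::map_dfr(seq_len(n_patients), function(i) {
    pid <- truth$patients$patient_id[i]
    reps <- truth$reporters[truth$reporters$patient_id == pid, ]
    purrr::map_dfr(c("CSF", "plasma"), function(comp) {
      s <- co$counts[co$counts$sample_id == paste0(pid, "_", comp, "_0"), ]
      tf <- if (comp == "CSF") truth$patients$csf_tf[i] else
        truth$patients$plasma_tf[i]
      tibble::tibble(compartment = comp, true_tf = tf,
                     est = as.numeric(mean_vaf(s, reps)))
    })
  })
  rho <- stats::cor(rows$true_tf, rows$est, method = "spearman")
  pos <- rows[rows$true_tf > 0, ]
  rel_bias <- mean(pos$est / (pos$true_tf * co$config$clonal_vaf) - 1)
  list(spearman_rho = rho, relative_bias = rel_bias, n = nrow(rows))
}

#' Variant-caller error control and sensitivity
#'
#' Simulates tumor-free samples to measure the family-wise false-call
#' rate under Bonferroni control, and spiked samples carrying one
#' variant at a given VAF/depth to measure call sensitivity.
#'
#' @param n_sim Simulations per arm.
#' @param depth Depth of the scored samples (null arm).
#' @param spike_vaf,spike_depth The planted variant.
#' @param panel_size,n_controls,control_depth,seed As elsewhere.
#' @return List with `fwer`, `sensitivity`, `n`.
#' @export
caller_study <- function(n_sim = 200, depth = 150, spike_vaf = 0.05,
                         spike_depth = 1000, panel_size = 2000,
                         n_controls = 12, control_depth = 1099, seed = 1) {
  cfg <- sim_config(panel_size = panel_size, seed = seed)
  panel <- simulate_panel(cfg)
  prof <- fit_simulated_profile(panel, n_controls, control_depth, cfg, seed)
  fw <- vapply(seq_len(n_sim), function(i) {
    s <- simulate_sample_counts(panel, 0, depth, nb_size = cfg$nb_size,
                                sample_id = "null",
                                seed = derive_seed(seed, "fwer", i))
    nrow(call_variants_tumor_naive(s, prof, panel)) > 0
  }, logical(1))
  hit <- vapply(seq_len(n_sim), function(i) {
    pos_i <- ((i - 1) %% nrow(panel)) + 1
    tv <- tibble::tibble(chrom = panel$chrom[pos_i], pos = panel$pos[pos_i],
                         vaf = spike_vaf)
    s <- simulate_sample_counts(panel, 1, spike_depth, truth_vafs = tv,
                                nb_size = cfg$nb_size, sample_id = "spike",
                                seed = derive_seed(seed, "spike", i))
    calls <- call_variants_tumor_naive(s, prof, panel)
    panel$pos[pos_i] %in% calls$pos
  }, logical(1))
  list(fwer = mean(fw), sensitivity = mean(hit), n = n_sim)
}

#' Copy-number calling performance
#'
#' Measures (i) the fraction of simulated samples carrying a focal
#' `fold`-change amplification that are called at `z >= z_amp` against
#' a simulated background cohort, and (ii) the leave-one-out z-score
#' moments of background samples (calibration of the z machinery).
#'
#' @param n_sim Amplified samples scored.
#' @param fold Depth fold change of the amplified gene.
#' @param depth Mean depth.
#' @param n_background Background cohort size.
#' @param n_loo_reps Independent background replicates for the
#'   leave-one-out moments.
#' @param gene Amplified gene.
#' @param z_amp Calling threshold.
#' @param panel_size,seed As elsewhere.
#' @return List with `amp_call_rate`, `loo_mean`, `loo_sd`, `n`.
#' @export
scna_study <- function(n_sim = 200, fold = 3, depth = 150,
                       n_background = 20, n_loo_reps = 100, gene = "MET",
                       z_amp = 3, panel_size = 400, seed = 1) {
  cfg <- sim_config(panel_size = panel_size, seed = seed)
  panel <- simulate_panel(cfg)
  bg <- purrr::map_dfr(seq_len(n_background), function(i) {
    dplyr::mutate(normalize_depth(
      simulate_sample_counts(panel, 0, depth, nb_size = cfg$nb_size,
                             sample_id = sprintf("bg%02d", i),
                             seed = derive_seed(seed, "bg", i)), panel),
      sample_id = sprintf("bg%02d", i), .before = 1)
  })
  hits <- vapply(seq_len(n_sim), function(i) {
    s <- simulate_sample_counts(panel, 0, depth, nb_size = cfg$nb_size,
                                gene_fold = setNames(fold, gene),
                                sample_id = "amp",
                                seed = derive_seed(seed, "amp", i))
    calls <- call_scna(scna_zscores(normalize_depth(s, panel), bg),
                       z_amp = z_amp, cnv_genes = gene, sample_id = "amp")
    isTRUE(calls$call[calls$gene == gene] == "amplification")
  }, logical(1))
  zs <- purrr::map_dfr(seq_len(n_loo_reps), function(r) {
    bgr <- purrr::map_dfr(seq_len(n_background), function(i) {
      dplyr::mutate(normalize_depth(
        simulate_sample_counts(panel, 0, depth, nb_size = cfg$nb_size,
                               sample_id = sprintf("b%02d", i),
                               seed = derive_seed(seed, "loo", r, i)),
        panel), sample_id = sprintf("b%02d", i), .before = 1)
    })
    scna_background_zscores(bgr)
  })
  list(amp_call_rate = mean(hits), loo_mean = mean(zs$z, na.rm = TRUE),
       loo_sd = sd(zs$z, na.rm = TRUE), n = n_sim)
}

#' Hazard-ratio recovery from simulated survival data
#'
#' Simulates cohorts whose overall-survival hazard is multiplied by
#' `hr` for tumor-DNA-positive patients, fits [km_logrank()] per
#' cohort, and reports the median hazard-ratio estimates across
#' replicates. The Cox estimate is the recovery metric; the log-rank
#' O/E form is also reported for reference since it attenuates toward
#' the null as the high-risk arm depletes.
#'
#' @param hr Generating hazard ratio.
#' @param n_reps Simulated cohorts.
#' @param n_per_group Patients per arm.
#' @param baseline_hazard,horizon_days Survival generation parameters.
#' @param seed Master seed.
#' @return List with `median_cox_hr`, `median_logrank_hr`, `n`.
#' @export
hr_recovery_study <- function(hr, n_reps = 200, n_per_group = 20,
                              baseline_hazard = log(2) / 900,
                              horizon_days = 1500, seed = 1) {
  est <- purrr::map_dfr(seq_len(n_reps), function(r) {
    truth <- list(patients = tibble::tibble(
      patient_id = sprintf("P%03d", seq_len(2 * n_per_group)),
      csf_tf = 0.3,
      tdna_detected = rep(c(FALSE, TRUE), each = n_per_group)))
    cl <- simulate_clinical(truth, list(baseline_hazard = baseline_hazard,
                                        hr_detected = hr,
                                        horizon_days = horizon_days),
                            seed = derive_seed(seed, "hrrec", hr, r))
    g <- factor(ifelse(truth$patients$tdna_detected, "detected",
                       "not_detected"),
                levels = c("not_detected", "detected"))
    fit <- suppressWarnings(km_logrank(cl$os_time_days, cl$os_event, g))
    tibble::tibble(cox = fit$cox_hazard_ratio, mh = fit$hazard_ratio)
  })
  list(median_cox_hr = median(est$cox, na.rm = TRUE),
       median_logrank_hr = median(est$mh, na.rm = TRUE), n = n_reps)
}
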