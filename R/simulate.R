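#' Configuration for the synthetic CSF/plasma cohort generator
#'
#' Builds and validates the parameter set used by [simulate_cohort()]. The
#' defaults emulate a lumbar-puncture cohort of advanced lung
#' adenocarcinoma patients evaluated for leptomeningeal disease (LMD):
#' tumor DNA is far more concentrated in cerebrospinal fluid than in
#' plasma (target median per-sample mean VAF 32.7% in CSF vs 1.8% in
#' plasma), deduplicated depths differ strongly by compartment (CSF 150x,
#' plasma 1879x, germline 1099x), background substitution error is
#' position specific with mean near 1e-4, a subset of patients carry a
#' focal amplification, a subset acquire a plasma-restricted resistance
#' clone after TKI therapy, and overall survival hazard is multiplied by
#' a configurable ratio when CSF tumor DNA is truly present.
#'
#' @param n_patients Number of patients.
#' @param n_controls Number of tumor-free control samples used to fit the
#'   background error model.
#' @param panel_size Number of targeted positions in the selector panel.
#' @param reporters_per_patient Number of true tumor reporter mutations
#'   per patient.
#' @param n_snps_per_patient Number of germline SNPs planted per patient
#'   (heterozygous or homozygous), present in every compartment.
#' @param csf_vaf_median,csf_vaf_sdlog Log-normal parameters (median on
#'   the natural scale, sigma on the log scale) of the target per-sample
#'   mean VAF in CSF.
#' @param plasma_vaf_median,plasma_vaf_sdlog Same, for plasma.
#' @param csf_plasma_rho Log-scale correlation between the CSF and plasma
#'   tumor levels of a patient.
#' @param clonal_vaf VAF of clonal reporters in pure tumor DNA; the
#'   per-sample tumor-DNA fraction is derived as (target VAF)/clonal_vaf.
#' @param subclonal_fraction Fraction of reporters carried by a subclone
#'   at half the clonal VAF.
#' @param csf_negative_fraction Fraction of patients with no tumor DNA in
#'   CSF (suspected LMD not confirmed molecularly).
#' @param depth_by_compartment Named vector of mean deduplicated depths.
#' @param nb_size Negative-binomial size (inverse over-dispersion) of
#'   per-position depths.
#' @param error_beta_shape1,error_beta_shape2 Beta parameters of the
#'   per-position background error-rate distribution.
#' @param coding_fraction Fraction of panel positions flagged as coding.
#' @param amplified_gene_fraction Fraction of patients carrying a focal
#'   amplification of one of `cnv_genes`.
#' @param amp_fold Copy-number fold change of the amplified gene in the
#'   tumor compartment.
#' @param tumor_sample_fraction Fraction of patients with a baseline
#'   tumor-tissue sample.
#' @param tumor_tf Tumor-DNA fraction assumed for tissue samples.
#' @param resistance_scenario_fraction Fraction of patients that acquire
#'   a plasma-restricted emergent resistance mutation post-TKI.
#' @param resistance_timepoint_days Day of the post-TKI sample pair.
#' @param cytology_intercept,cytology_slope Logistic model (in log10
#'   tumor fraction) for the probability of positive CSF cytology.
#' @param survival List with `baseline_hazard` (events/day for patients
#'   without CSF tumor DNA), `hr_detected` (hazard ratio applied when
#'   tumor DNA is truly present), `horizon_days` (administrative
#'   censoring), and the same three for the CNS-progression endpoint
#'   (`cns_baseline_hazard`, `cns_hr`, using the shared horizon).
#' @param osimertinib List with `plasma_median_nM`, `plasma_sdlog`,
#'   `csf_penetration` (expected CSF/plasma concentration ratio) and
#'   `noise_sdlog`.
#' @param snv_whitelist,cnv_genes Resistance gene whitelists used when
#'   planting emergent alterations.
#' @param seed Master seed; all substreams derive from it.
#' @return A validated list of class `csf_sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_patients = 4, n_controls = 3, panel_size = 200)
#' cfg$csf_vaf_median
sim_config <- function(n_patients = 24,
                       n_controls = 12,
                       panel_size = 2000,
                       reporters_per_patient = 8,
                       n_snps_per_patient = 25,
                       csf_vaf_median = 0.327,
                       csf_vaf_sdlog = 0.9,
                       plasma_vaf_median = 0.018,
                       plasma_vaf_sdlog = 1.0,
                       csf_plasma_rho = 0.45,
                       clonal_vaf = 0.5,
                       subclonal_fraction = 0,
                       csf_negative_fraction = 0.15,
                       depth_by_compartment = c(CSF = 150, plasma = 1879,
                                                tumor = 500,
                                                pleural_effusion = 500,
                                                germline = 1099),
                       nb_size = 8,
                       error_beta_shape1 = 0.5,
                       error_beta_shape2 = 4999.5,
                       coding_fraction = 0.85,
                       amplified_gene_fraction = 0.25,
                       amp_fold = 3,
                       tumor_sample_fraction = 0.2,
                       tumor_tf = 0.6,
                       resistance_scenario_fraction = 0.3,
                       resistance_timepoint_days = 180,
                       cytology_intercept = 1.6,
                       cytology_slope = 1.5,
                       survival = list(baseline_hazard = log(2) / 900,
                                       hr_detected = 6.6,
                                       horizon_days = 1500,
                                       cns_baseline_hazard = log(2) / 600,
                                       cns_hr = 6.2),
                       osimertinib = list(plasma_median_nM = 500,
                                          plasma_sdlog = 0.4,
                                          csf_penetration = 0.025,
                                          noise_sdlog = 0.3),
                       snv_whitelist = c("EGFR", "PIK3CA", "KRAS", "CDKN2A",
                                         "RB1", "ALK", "KIT", "MET"),
                       cnv_genes = c("MET", "ERBB2", "EGFR"),
                       seed = 7) {
  cfg <- list(
    n_patients = n_patients, n_controls = n_controls,
    panel_size = panel_size, reporters_per_patient = reporters_per_patient,
    n_snps_per_patient = n_snps_per_patient,
    csf_vaf_median = csf_vaf_median, csf_vaf_sdlog = csf_vaf_sdlog,
    plasma_vaf_median = plasma_vaf_median, plasma_vaf_sdlog = plasma_vaf_sdlog,
    csf_plasma_rho = csf_plasma_rho,
    clonal_vaf = clonal_vaf, subclonal_fraction = subclonal_fraction,
    csf_negative_fraction = csf_negative_fraction,
    depth_by_compartment = depth_by_compartment, nb_size = nb_size,
    error_beta_shape1 = error_beta_shape1,
    error_beta_shape2 = error_beta_shape2,
    coding_fraction = coding_fraction,
    amplified_gene_fraction = amplified_gene_fraction, amp_fold = amp_fold,
    tumor_sample_fraction = tumor_sample_fraction, tumor_tf = tumor_tf,
    resistance_scenario_fraction = resistance_scenario_fraction,
    resistance_timepoint_days = resistance_timepoint_days,
    cytology_intercept = cytology_intercept, cytology_slope = cytology_slope,
    survival = survival, osimertinib = osimertinib,
    snv_whitelist = snv_whitelist, cnv_genes = cnv_genes,
    seed = seed
  )
  validate_sim_config(cfg)
  structure(cfg, class = "csf_sim_config")
}

validate_sim_config <- function(cfg) {
  chk_count <- function(field, min = 1) {
    x <- cfg[[field]]
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < min ||
        x != floor(x)) {
      abort(sprintf("invalid configuration: `%s` must be an integer >= %d",
                    field, min))
    }
  }
  chk_frac <- function(field) {
    x <- cfg[[field]]
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 0 || x > 1) {
      abort(sprintf("invalid configuration: `%s` must lie in [0, 1]", field))
    }
  }
  chk_pos <- function(field, x = cfg[[field]]) {
    if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
      abort(sprintf("invalid configuration: `%s` must be positive", field))
    }
  }
  chk_count("n_patients"); chk_count("n_controls", min = 2)
  chk_count("panel_size"); chk_count("reporters_per_patient")
  chk_count("n_snps_per_patient", min = 0)
  for (f in c("subclonal_fraction", "csf_negative_fraction",
              "amplified_gene_fraction", "tumor_sample_fraction",
              "resistance_scenario_fraction")) chk_frac(f)
  for (f in c("csf_vaf_median", "plasma_vaf_median", "clonal_vaf",
              "tumor_tf")) {
    chk_frac(f); chk_pos(f)
  }
  chk_pos("depth_by_compartment")
  chk_pos("nb_size"); chk_pos("amp_fold")
  chk_pos("error_beta_shape1"); chk_pos("error_beta_shape2")
  if (!all(c("CSF", "plasma", "germline") %in%
           names(cfg$depth_by_compartment))) {
    abort("invalid configuration: `depth_by_compartment` must name at least CSF, plasma and germline")
  }
  if (cfg$panel_size < cfg$reporters_per_patient) {
    abort("invalid configuration: `panel_size` must be >= `reporters_per_patient`")
  }
  if (abs(cfg$csf_plasma_rho) > 1) {
    abort("invalid configuration: `csf_plasma_rho` must lie in [-1, 1]")
  }
  if (cfg$csf_vaf_median > cfg$clonal_vaf || cfg$plasma_vaf_median > cfg$clonal_vaf) {
    abort("invalid configuration: `csf_vaf_median`/`plasma_vaf_median` cannot exceed `clonal_vaf`")
  }
  chk_pos("survival$baseline_hazard", cfg$survival$baseline_hazard)
  chk_pos("survival$hr_detected", cfg$survival$hr_detected)
  invisible(cfg)
}

# Approximate hg19 anchors; only relative panel layout matters downstream.
panel_genes <- function() {
  tibble::tribble(
    ~gene,     ~chrom,   ~anchor,
    "EGFR",    "chr7",   55086714,
    "TP53",    "chr17",  7571720,
    "KRAS",    "chr12",  25358180,
    "PIK3CA",  "chr3",   178866311,
    "MET",     "chr7",   116312444,
    "ERBB2",   "chr17",  37844393,
    "ALK",     "chr2",   29415640,
    "CDKN2A",  "chr9",   21967751,
    "RB1",     "chr13",  48877883,
    "KIT",     "chr4",   55524095,
    "BRAF",    "chr7",   140419127,
    "STK11",   "chr19",  1205798,
    "KEAP1",   "chr19",  10596796,
    "NF1",     "chr17",  29421945,
    "SMAD4",   "chr18",  48556583,
    "CTNNB1",  "chr3",   41236328,
    "PTEN",    "chr10",  89622870,
    "NRAS",    "chr1",   115247085,
    "MAP2K1",  "chr15",  66679211,
    "FGFR1",   "chr8",   38268656
  )
}

#' Simulate a targeted selector panel
#'
#' Lays `panel_size` positions out as one contiguous region per gene of a
#' lung-cancer-style panel, assigns each position a reference base, one
#' canonical alternate allele, a coding flag and a position-specific
#' background substitution error rate drawn from the configured Beta
#' distribution.
#'
#' @param config A [sim_config()] object.
#' @return Tibble with columns `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `gene`, `coding`, `true_error_rate`.
#' @export
simulate_panel <- function(config) {
  genes <- panel_genes()
  n_genes <- nrow(genes)
  base_n <- config$panel_size %/% n_genes
  sizes <- rep(base_n, n_genes)
  extra <- config$panel_size - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  genes <- genes[sizes > 0, , drop = FALSE]
  sizes <- sizes[sizes > 0]
  with_seed(derive_seed(config$seed, "panel"), {
    bases <- c("A", "C", "G", "T")
    panel <- purrr::map2_dfr(seq_len(nrow(genes)), sizes, function(i, k) {
      tibble::tibble(
        chrom = genes$chrom[i],
        pos = genes$anchor[i] + seq_len(k),
        gene = genes$gene[i]
      )
    })
    panel$ref <- sample(bases, nrow(panel), replace = TRUE)
    panel$alt <- purrr::map_chr(panel$ref, function(r) {
      sample(setdiff(bases, r), 1)
    })
    panel$coding <- runif(nrow(panel)) < config$coding_fraction
    panel$true_error_rate <- rbeta(nrow(panel), config$error_beta_shape1,
                                   config$error_beta_shape2)
    dplyr::select(panel, "chrom", "pos", "ref", "alt", "gene", "coding",
                  "true_error_rate")
  })
}

#' Simulate per-position counts for one sample
#'
#' Draws a deduplicated depth at every panel position from a
#' negative-binomial distribution around the compartment mean (optionally
#' scaled per gene to emulate a focal copy-number change), then draws the
#' alternate-allele count binomially with success probability
#' `tumor_fraction * truth_vaf + error_rate` (clipped to `[0, 1]`).
#' Germline variants (rows of `truth_vafs` with `scaled = FALSE`) are not
#' scaled by the tumor fraction: their VAF is a property of all cell-free
#' DNA in the sample.
#'
#' @param panel Panel tibble (see [simulate_panel()]); its
#'   `true_error_rate` column supplies the background error unless
#'   `error_rates` is given.
#' @param tumor_fraction Tumor-DNA fraction of the sample, in `[0, 1]`.
#' @param depth_mean Mean deduplicated depth.
#' @param truth_vafs Tibble with `chrom`, `pos`, `vaf` and optionally
#'   `scaled` (default `TRUE`) giving true variant allele fractions in
#'   pure tumor DNA; every row must fall inside the panel.
#' @param error_rates Optional numeric vector of per-position background
#'   error rates, parallel to `panel`.
#' @param nb_size Negative-binomial size parameter for depth.
#' @param gene_fold Optional named numeric vector of per-gene depth fold
#'   changes (focal amplification/deletion).
#' @param sample_id Sample identifier stamped on the output.
#' @param seed Seed for this sample's substream.
#' @return Counts tibble: `sample_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `depth`, `alt_count`.
#' @export
#' @examples
#' cfg <- sim_config(panel_size = 100, n_patients = 2, n_controls = 2)
#' panel <- simulate_panel(cfg)
#' truth <- panel[1:3, c("chrom", "pos")]
#' truth$vaf <- 0.5
#' cts <- simulate_sample_counts(panel, tumor_fraction = 0.4,
#'                               depth_mean = 150, truth_vafs = truth,
#'                               seed = 1)
simulate_sample_counts <- function(panel, tumor_fraction, depth_mean,
                                   truth_vafs = NULL, error_rates = NULL,
                                   nb_size = 8, gene_fold = NULL,
                                   sample_id = "S1", seed = 1) {
  if (!is.numeric(tumor_fraction) || tumor_fraction < 0 || tumor_fraction > 1) {
    abort("`tumor_fraction` must lie in [0, 1]")
  }
  if (depth_mean <= 0) abort("`depth_mean` must be positive")
  error_rates <- error_rates %||% panel$true_error_rate
  if (is.null(error_rates)) abort("no error rates: supply `error_rates` or a panel with `true_error_rate`")
  stopifnot(length(error_rates) == nrow(panel))

  p <- pmin(pmax(error_rates, 0), 1)
  if (!is.null(truth_vafs) && nrow(truth_vafs) > 0) {
    key <- paste(panel$chrom, panel$pos)
    tkey <- paste(truth_vafs$chrom, truth_vafs$pos)
    idx <- match(tkey, key)
    if (anyNA(idx)) {
      abort(sprintf("truth variant position(s) outside the panel: %s",
                    paste(head(tkey[is.na(idx)], 3), collapse = ", ")))
    }
    scaled <- if ("scaled" %in% names(truth_vafs)) truth_vafs$scaled else TRUE
    contrib <- ifelse(rep(scaled, length.out = nrow(truth_vafs)),
                      tumor_fraction * truth_vafs$vaf, truth_vafs$vaf)
    p[idx] <- pmin(p[idx] + contrib, 1)
  }

  mu <- rep(depth_mean, nrow(panel))
  if (!is.null(gene_fold) && length(gene_fold) > 0) {
    hit <- panel$gene %in% names(gene_fold)
    mu[hit] <- mu[hit] * unname(gene_fold[panel$gene[hit]])
  }
  with_seed(seed, {
    depth <- rnbinom(nrow(panel), mu = mu, size = nb_size)
    alt_draw <- rbinom(nrow(panel), size = depth, prob = p)
    tibble::tibble(
      sample_id = sample_id,
      chrom = panel$chrom, pos = panel$pos,
      ref = panel$ref, alt = panel$alt,
      depth = as.integer(depth), alt_count = as.integer(alt_draw)
    )
  })
}

draw_correlated_vafs <- function(n, cfg) {
  rho <- cfg$csf_plasma_rho
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  csf <- pmin(exp(log(cfg$csf_vaf_median) + cfg$csf_vaf_sdlog * z1),
              cfg$clonal_vaf)
  plasma <- pmin(exp(log(cfg$plasma_vaf_median) + cfg$plasma_vaf_sdlog * z2),
                 cfg$clonal_vaf)
  list(csf = csf, plasma = plasma)
}

#' Simulate a complete cohort with ground truth
#'
#' Generates the selector panel, tumor-free control samples for error
#' model fitting, per-patient reporter mutations and germline SNPs,
#' per-sample count tables for every compartment and timepoint, clinical
#' records, and a ground-truth object against which every downstream
#' stage can be scored.
#'
#' Each patient gets one germline, one baseline CSF and one baseline
#' plasma sample; a configurable fraction additionally get a baseline
#' tumor-tissue sample, and patients in the resistance scenario get a
#' time-matched post-TKI CSF/plasma pair carrying a plasma-restricted
#' emergent mutation from the resistance gene whitelist.
#'
#' @param config A [sim_config()] object.
#' @return List of class `csf_cohort` with elements `panel`, `counts`
#'   (all samples, long), `sample_sheet`, `clinical`, `truth` and
#'   `config`.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_patients = 3, n_controls = 3,
#'                                      panel_size = 200, seed = 1))
#' dplyr::count(cohort$sample_sheet, compartment)
simulate_cohort <- function(config) {
  if (!inherits(config, "csf_sim_config")) config <- do.call(sim_config, config)
  cfg <- config
  panel <- simulate_panel(cfg)
  coding_idx <- which(panel$coding)
  if (length(coding_idx) < cfg$reporters_per_patient + 1) {
    abort("invalid configuration: `panel_size`/`coding_fraction` leave too few coding positions for reporters")
  }

  ids <- sprintf("LUP%03d", seq_len(cfg$n_patients))
  pat <- with_seed(derive_seed(cfg$seed, "patients"), {
    vafs <- draw_correlated_vafs(cfg$n_patients, cfg)
    csf_neg <- runif(cfg$n_patients) < cfg$csf_negative_fraction
    vafs$csf[csf_neg] <- 0
    has_tumor <- runif(cfg$n_patients) < cfg$tumor_sample_fraction
    amp <- runif(cfg$n_patients) < cfg$amplified_gene_fraction
    amp_gene <- ifelse(amp, sample(cfg$cnv_genes, cfg$n_patients,
                                   replace = TRUE), NA_character_)
    res <- runif(cfg$n_patients) < cfg$resistance_scenario_fraction
    res_gene <- ifelse(res, sample(cfg$snv_whitelist, cfg$n_patients,
                                   replace = TRUE), NA_character_)
    tibble::tibble(
      patient_id = ids,
      csf_tf = vafs$csf / cfg$clonal_vaf,
      plasma_tf = vafs$plasma / cfg$clonal_vaf,
      tumor_tf = ifelse(has_tumor, cfg$tumor_tf, NA_real_),
      tdna_detected = vafs$csf > 0,
      amp_gene = amp_gene,
      amp_fold = ifelse(amp, cfg$amp_fold, NA_real_),
      resistance_gene = res_gene
    )
  })

  # Reporters (coding, patient-specific) and germline SNPs (anywhere);
  # a patient's SNPs never collide with their reporters.
  per_patient <- with_seed(derive_seed(cfg$seed, "variants"), {
    purrr::map(seq_len(cfg$n_patients), function(i) {
      rep_idx <- sample(coding_idx, cfg$reporters_per_patient)
      snp_pool <- setdiff(seq_len(nrow(panel)), rep_idx)
      snp_idx <- sample(snp_pool, min(cfg$n_snps_per_patient, length(snp_pool)))
      sub <- runif(cfg$reporters_per_patient) < cfg$subclonal_fraction
      res_gene <- pat$resistance_gene[i]
      res_idx <- NA_integer_
      if (!is.na(res_gene)) {
        pool <- setdiff(intersect(coding_idx,
                                  which(panel$gene == res_gene)),
                        c(rep_idx, snp_idx))
        if (length(pool) > 0) res_idx <- sample(pool, 1)
      }
      list(
        reporters = tibble::tibble(
          patient_id = ids[i],
          chrom = panel$chrom[rep_idx], pos = panel$pos[rep_idx],
          ref = panel$ref[rep_idx], alt = panel$alt[rep_idx],
          gene = panel$gene[rep_idx],
          vaf = ifelse(sub, cfg$clonal_vaf / 2, cfg$clonal_vaf)
        ),
        snps = tibble::tibble(
          patient_id = ids[i],
          chrom = panel$chrom[snp_idx], pos = panel$pos[snp_idx],
          ref = panel$ref[snp_idx], alt = panel$alt[snp_idx],
          gene = panel$gene[snp_idx],
          vaf = ifelse(runif(length(snp_idx)) < 0.2, 1, 0.5)
        ),
        emergent = if (!is.na(res_idx)) tibble::tibble(
          patient_id = ids[i], type = "SNV",
          chrom = panel$chrom[res_idx], pos = panel$pos[res_idx],
          ref = panel$ref[res_idx], alt = panel$alt[res_idx],
          gene = panel$gene[res_idx],
          compartment = "plasma",
          vaf = cfg$clonal_vaf / 2
        ) else NULL
      )
    })
  })
  reporters <- purrr::map_dfr(per_patient, "reporters")
  snps <- purrr::map_dfr(per_patient, "snps")
  emergent <- purrr::map_dfr(per_patient, "emergent")

  control_ids <- sprintf("CTRL%02d", seq_len(cfg$n_controls))
  control_counts <- purrr::map_dfr(control_ids, function(id) {
    simulate_sample_counts(
      panel, tumor_fraction = 0,
      depth_mean = cfg$depth_by_compartment[["germline"]],
      nb_size = cfg$nb_size,
      sample_id = paste0(id, "_germline_0"),
      seed = derive_seed(cfg$seed, id, "germline", 0)
    )
  })
  control_sheet <- tibble::tibble(
    sample_id = paste0(control_ids, "_germline_0"),
    patient_id = control_ids, compartment = "germline",
    timepoint_days = 0, treatment_state = "control"
  )

  sample_plan <- purrr::map_dfr(seq_len(cfg$n_patients), function(i) {
    rows <- tibble::tibble(
      patient_id = ids[i],
      compartment = c("germline", "CSF", "plasma"),
      timepoint_days = 0, treatment_state = "pre_TKI"
    )
    if (!is.na(pat$tumor_tf[i])) {
      rows <- dplyr::bind_rows(rows, tibble::tibble(
        patient_id = ids[i], compartment = "tumor",
        timepoint_days = 0, treatment_state = "pre_TKI"
      ))
    }
    if (!is.na(pat$resistance_gene[i])) {
      rows <- dplyr::bind_rows(rows, tibble::tibble(
        patient_id = ids[i], compartment = c("CSF", "plasma"),
        timepoint_days = cfg$resistance_timepoint_days,
        treatment_state = "post_TKI"
      ))
    }
    rows
  })
  sample_plan$sample_id <- paste(sample_plan$patient_id,
                                 sample_plan$compartment,
                                 sample_plan$timepoint_days, sep = "_")
  sample_plan <- dplyr::select(sample_plan, "sample_id", "patient_id",
                               "compartment", "timepoint_days",
                               "treatment_state")

  counts <- purrr::pmap_dfr(sample_plan, function(sample_id, patient_id,
                                                  compartment,
                                                  timepoint_days,
                                                  treatment_state) {
    i <- match(patient_id, ids)
    tf <- switch(compartment,
                 germline = 0,
                 CSF = pat$csf_tf[i],
                 plasma = pat$plasma_tf[i],
                 tumor = pat$tumor_tf[i],
                 pleural_effusion = pat$tumor_tf[i])
    tv <- dplyr::bind_rows(
      if (compartment != "germline") {
        dplyr::mutate(reporters[reporters$patient_id == patient_id, ],
                      scaled = TRUE)
      },
      dplyr::mutate(snps[snps$patient_id == patient_id, ], scaled = FALSE)
    )
    if (treatment_state == "post_TKI" && nrow(emergent) > 0) {
      em <- emergent[emergent$patient_id == patient_id &
                       emergent$compartment == compartment, ]
      if (nrow(em) > 0) {
        tv <- dplyr::bind_rows(tv, dplyr::mutate(
          dplyr::select(em, "chrom", "pos", "vaf"), scaled = TRUE))
      }
    }
    fold <- NULL
    if (!is.na(pat$amp_gene[i]) && compartment %in% c("CSF", "tumor",
                                                      "pleural_effusion")) {
      # observed fold in cfDNA is diluted by the non-tumor fraction
      fold <- setNames(1 + tf * (pat$amp_fold[i] - 1), pat$amp_gene[i])
    }
    simulate_sample_counts(
      panel, tumor_fraction = tf,
      depth_mean = cfg$depth_by_compartment[[compartment]],
      truth_vafs = tv, nb_size = cfg$nb_size, gene_fold = fold,
      sample_id = sample_id,
      seed = derive_seed(cfg$seed, patient_id, compartment, timepoint_days)
    )
  })

  truth <- list(
    patients = pat, reporters = reporters, snps = snps, emergent = emergent,
    panel_error_rates = panel$true_error_rate,
    survival = cfg$survival
  )
  clinical <- simulate_clinical(truth, cfg$survival,
                                seed = derive_seed(cfg$seed, "clinical"),
                                config = cfg)

  structure(list(
    panel = panel,
    counts = dplyr::bind_rows(control_counts, counts),
    sample_sheet = dplyr::bind_rows(control_sheet, sample_plan),
    clinical = clinical,
    truth = truth,
    config = cfg
  ), class = "csf_cohort")
}

#' Simulate clinical records from ground truth
#'
#' Event times are exponential, with the hazard multiplied by the
#' configured ratio for patients whose CSF truly carries tumor DNA;
#' administrative censoring is applied at the configured horizon.
#' Cytology positivity follows a logistic model in log10 CSF tumor
#' fraction, so low-burden patients can be cytology-negative yet
#' molecularly positive. Osimertinib plasma concentrations are
#' log-normal; CSF concentrations apply the configured penetration ratio
#' with multiplicative noise.
#'
#' @param truth Ground-truth list from [simulate_cohort()] (needs
#'   `$patients`).
#' @param survival_params List with `baseline_hazard`, `hr_detected`,
#'   `horizon_days`, and optionally `cns_baseline_hazard` / `cns_hr`.
#' @param seed Integer seed.
#' @param config Optional [sim_config()] supplying the cytology and drug
#'   models; defaults are used otherwise.
#' @return Tibble with one row per patient: LMD work-up fields, survival
#'   and CNS-progression times/events, and osimertinib concentrations.
#' @export
simulate_clinical <- function(truth, survival_params, seed = 1,
                              config = NULL) {
  pat <- truth$patients
  sp <- survival_params
  if (is.null(sp$baseline_hazard) || sp$baseline_hazard <= 0) {
    abort("`survival_params$baseline_hazard` must be positive")
  }
  if (is.null(sp$hr_detected) || sp$hr_detected <= 0) {
    abort("`survival_params$hr_detected` must be positive")
  }
  horizon <- sp$horizon_days %||% 1500
  cns_h0 <- sp$cns_baseline_hazard %||% (sp$baseline_hazard * 1.5)
  cns_hr <- sp$cns_hr %||% sp$hr_detected
  cyt_a <- if (!is.null(config)) config$cytology_intercept else 1.6
  cyt_b <- if (!is.null(config)) config$cytology_slope else 1.5
  osi <- if (!is.null(config)) config$osimertinib else {
    list(plasma_median_nM = 500, plasma_sdlog = 0.4,
         csf_penetration = 0.025, noise_sdlog = 0.3)
  }

  with_seed(seed, {
    n <- nrow(pat)
    tf <- pat$csf_tf
    p_cyt <- ifelse(tf > 0, plogis(cyt_a + cyt_b * log10(tf)), 0.02)
    cytology <- runif(n) < p_cyt
    p_pcr <- ifelse(tf > 0, plogis(0.5 + 1.2 * log10(tf)), 0.01)
    pcr <- runif(n) < p_pcr
    p_mri <- ifelse(tf > 0, plogis(1.2 + 1.0 * log10(tf)), 0.15)
    mri <- runif(n) < p_mri
    symptoms <- runif(n) < ifelse(tf > 0, 0.9, 0.7)

    haz <- sp$baseline_hazard * ifelse(pat$tdna_detected, sp$hr_detected, 1)
    t_os <- rexp(n, rate = haz)
    os_event <- t_os <= horizon
    os_time <- pmin(t_os, horizon)

    haz_c <- cns_h0 * ifelse(pat$tdna_detected, cns_hr, 1)
    t_cns <- rexp(n, rate = haz_c)
    cns_event <- t_cns <= horizon & t_cns <= os_time
    cns_time <- pmin(t_cns, os_time, horizon)

    plasma_nM <- exp(log(osi$plasma_median_nM) + osi$plasma_sdlog * rnorm(n))
    csf_nM <- plasma_nM * osi$csf_penetration *
      exp(osi$noise_sdlog * rnorm(n))

    tibble::tibble(
      patient_id = pat$patient_id,
      cytology_positive = cytology,
      egfr_csf_pcr_positive = pcr,
      mri_unequivocal_lmd = mri,
      progressive_symptoms = symptoms,
      os_time_days = os_time, os_event = os_event,
      cns_progression_time_days = cns_time, cns_event = cns_event,
      csf_osimertinib_nM = csf_nM, plasma_osimertinib_nM = plasma_nM
    )
  })
}

#' @export
print.csf_cohort <- function(x, ...) {
  cat("<csf_cohort>\n")
  cat(sprintf("  %d patients, %d control samples, %d panel positions\n",
              x$config$n_patients, x$config$n_controls, nrow(x$panel)))
  cat(sprintf("  %d samples, %d count rows\n",
              nrow(x$sample_sheet), nrow(x$counts)))
  invisible(x)
}
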