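#' Pipeline parameter set
#'
#' Collects every tunable threshold with its default: detection cutoff
#' 0.05 (inclusive), Monte Carlo iterations B, germline VAF threshold
#' 0.02, z thresholds 3, the 14-day plasma/CSF time-matching window,
#' the Bonferroni alpha, and the minimum pre-TKI depth guard for
#' emergent calls. Output headers and logs report exactly these values.
#'
#' @param detection_cutoff,B,germline_vaf_threshold,alpha Detection and
#'   calling thresholds.
#' @param z_amp,z_del,cnv_genes SCNA thresholds and gene restriction.
#' @param snv_whitelist Resistance SNV gene whitelist.
#' @param time_match_days Maximum plasma/CSF sampling gap.
#' @param min_pre_depth Pre-TKI coverage guard for emergent calls.
#' @param seed Seed for every stochastic stage.
#' @return Named list of class `csf_pipeline_params`.
#' @export
pipeline_params <- function(detection_cutoff = 0.05, B = 10000,
                            germline_vaf_threshold = 0.02, alpha = 0.05,
                            z_amp = 3, z_del = 3,
                            cnv_genes = cnv_resistance_genes(),
                            snv_whitelist = snv_resistance_genes(),
                            time_match_days = 14, min_pre_depth = 50,
                            seed = 7) {
  if (detection_cutoff <= 0 || detection_cutoff >= 1) {
    abort("`detection_cutoff` must lie in (0, 1)")
  }
  structure(list(detection_cutoff = detection_cutoff, B = B,
                 germline_vaf_threshold = germline_vaf_threshold,
                 alpha = alpha, z_amp = z_amp, z_del = z_del,
                 cnv_genes = cnv_genes, snv_whitelist = snv_whitelist,
                 time_match_days = time_match_days,
                 min_pre_depth = min_pre_depth, seed = seed),
            class = "csf_pipeline_params")
}

scna_to_cnv_calls <- function(scna_calls) {
  hits <- dplyr::filter(scna_calls, .data$call %in% c("amplification",
                                                      "deletion"))
  tibble::tibble(type = rep("CNV", nrow(hits)), gene = hits$gene,
                 direction = hits$call)
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order on a cohort: background error model
#' from the control samples, tumor-naive calling with germline and
#' coding filters, patient reporter sets, per-sample mean VAF and Monte
#' Carlo detection, gene-level SCNA calls, emergent-resistance
#' comparison between post-TKI plasma and CSF, LMD classification and
#' the diagnostic/prognostic statistics. Reruns with the same inputs
#' and seed reproduce every output exactly.
#'
#' @param cohort A `csf_cohort` from [simulate_cohort()], or a list of
#'   paths with elements `counts`, `sample_sheet`, `clinical` and
#'   optionally `panel_bed` (then read from disk; the BED carries no
#'   ref/alt, which are taken from the counts).
#' @param params A [pipeline_params()] object.
#' @param out_dir Optional directory; when given, every report table is
#'   written there as TSV plus a `summary.json` and a `run_log.json`.
#' @return List of class `csf_report`: `profile`, `reporters` (named
#'   list), `detection`, `scna`, `resistance`, `concordance`,
#'   `clinical`, `sensitivity`, `survival` (a `csf_survcomp` or NULL),
#'   `associations`, `flags` (per-patient issues), `log`.
#' @export
run_pipeline <- function(cohort, params = pipeline_params(),
                         out_dir = NULL) {
  if (!inherits(cohort, "csf_cohort") && is.list(cohort) &&
      !is.null(cohort$counts) && is.character(cohort$counts)) {
    counts <- read_counts_tsv(cohort$counts)
    sheet <- read_sample_sheet(cohort$sample_sheet)
    clinical <- read_clinical(cohort$clinical)
    panel <- if (!is.null(cohort$panel_bed)) {
      bed <- read_bed(cohort$panel_bed)
      alleles <- dplyr::distinct(counts, .data$chrom, .data$pos, .data$ref,
                                 .data$alt)
      dplyr::left_join(bed, alleles, by = c("chrom", "pos"))
    } else {
      abort("path input needs `panel_bed`")
    }
    cohort <- list(panel = panel, counts = counts, sample_sheet = sheet,
                   clinical = clinical)
  }
  panel <- cohort$panel
  counts <- cohort$counts
  sheet <- cohort$sample_sheet
  clinical <- cohort$clinical

  is_control <- sheet$treatment_state == "control" |
    grepl("^CTRL", sheet$patient_id)
  control_ids <- sheet$sample_id[is_control]
  if (length(control_ids) < 2) abort("pipeline stage error-model: < 2 control samples")
  control_counts <- counts[counts$sample_id %in% control_ids, ]
  profile <- estimate_error_profile(control_counts)

  patients <- unique(sheet$patient_id[!is_control])
  flags <- list()
  reporters <- list()
  detection <- list()
  scna <- list()
  resistance <- list()
  concordance <- list()

  for (pid in patients) {
    psheet <- sheet[sheet$patient_id == pid & !is_control, ]
    germ_id <- psheet$sample_id[psheet$compartment == "germline"]
    germline <- if (length(germ_id) > 0) {
      counts[counts$sample_id %in% germ_id[1], ]
    } else {
      NULL
    }
    if (is.null(germline)) {
      flags[[pid]] <- c(flags[[pid]], "missing_germline")
    }
    base_ids <- psheet$sample_id[psheet$timepoint_days == 0 &
                                   psheet$compartment != "germline"]
    if (length(base_ids) == 0) {
      flags[[pid]] <- c(flags[[pid]], "no_baseline_sample")
      next
    }
    rset <- withCallingHandlers(
      build_reporter_set(counts[counts$sample_id %in% base_ids, ], profile,
                         panel, germline = germline, patient_id = pid,
                         vaf_threshold = params$germline_vaf_threshold,
                         alpha = params$alpha, missing_policy = "pass"),
      csftdna_missing_germline = function(w) invokeRestart("muffleWarning")
    )
    reporters[[pid]] <- rset

    all_ids <- psheet$sample_id[psheet$compartment != "germline"]
    detection[[pid]] <- detect_tdna(
      counts[counts$sample_id %in% all_ids, ], rset, profile,
      sample_sheet = sheet, B = params$B,
      cutoff = params$detection_cutoff, seed = params$seed
    )
    scna[[pid]] <- scna_analysis(
      counts[counts$sample_id %in% all_ids, ], control_counts, panel,
      z_amp = params$z_amp, z_del = params$z_del,
      cnv_genes = params$cnv_genes
    )

    post <- psheet[psheet$treatment_state == "post_TKI", ]
    if (nrow(post) > 0) {
      pre_pref <- c("tumor", "pleural_effusion", "CSF", "plasma")
      pre_rows <- psheet[psheet$timepoint_days == 0 &
                           psheet$compartment != "germline", ]
      pre_rows <- pre_rows[order(match(pre_rows$compartment, pre_pref)), ]
      pre_id <- pre_rows$sample_id[1]
      pre_counts <- counts[counts$sample_id == pre_id, ]
      pre_snv <- call_sample_filtered(pre_counts, profile, panel, germline,
                                      params)
      pre_cnv <- scna_to_cnv_calls(scna[[pid]][scna[[pid]]$sample_id == pre_id, ])
      pre_calls <- dplyr::bind_rows(
        dplyr::mutate(pre_snv, type = "SNV"), pre_cnv)
      em <- list()
      for (comp in c("plasma", "CSF")) {
        prow <- post[post$compartment == comp, ]
        if (nrow(prow) == 0) next
        pc <- counts[counts$sample_id == prow$sample_id[1], ]
        post_snv <- call_sample_filtered(pc, profile, panel, germline, params)
        post_cnv <- scna_to_cnv_calls(
          scna[[pid]][scna[[pid]]$sample_id == prow$sample_id[1], ])
        post_calls <- dplyr::bind_rows(
          dplyr::mutate(post_snv, type = "SNV"), post_cnv)
        post_calls$compartment <- comp
        post_calls$timepoint_days <- prow$timepoint_days[1]
        em[[comp]] <- emergent_variants(
          pre_calls, post_calls, snv_whitelist = params$snv_whitelist,
          cnv_whitelist = params$cnv_genes, pre_counts = pre_counts,
          min_pre_depth = params$min_pre_depth, patient_id = pid
        )
      }
      resistance[[pid]] <- dplyr::bind_rows(em)
      if (!is.null(em$plasma) && !is.null(em$CSF)) {
        gap <- abs(post$timepoint_days[post$compartment == "plasma"][1] -
                     post$timepoint_days[post$compartment == "CSF"][1])
        if (is.finite(gap) && gap > params$time_match_days) {
          flags[[pid]] <- c(flags[[pid]], "time_match_violation")
        } else {
          concordance[[pid]] <- compare_compartments(
            em$plasma, em$CSF, max_gap_days = params$time_match_days)
        }
      }
    }
  }

  detection_tbl <- dplyr::bind_rows(detection)
  scna_tbl <- dplyr::bind_rows(purrr::imap(scna, function(x, pid) {
    dplyr::mutate(x, patient_id = pid, .before = 1)
  }))
  resistance_tbl <- dplyr::bind_rows(resistance)
  concordance_tbl <- dplyr::bind_rows(purrr::map(concordance,
                                                 tibble::as_tibble))

  clin <- classify_lmd(clinical)
  base_csf <- detection_tbl[detection_tbl$compartment == "CSF" &
                              detection_tbl$timepoint_days == 0, ]
  clin <- dplyr::left_join(
    clin,
    dplyr::select(base_csf, "patient_id", csf_tdna_detected = "detected",
                  csf_mean_vaf = "mean_vaf"),
    by = "patient_id"
  )
  base_plasma <- detection_tbl[detection_tbl$compartment == "plasma" &
                                 detection_tbl$timepoint_days == 0, ]
  clin <- dplyr::left_join(
    clin,
    dplyr::select(base_plasma, "patient_id",
                  plasma_ctdna_detected = "detected",
                  plasma_mean_vaf = "mean_vaf"),
    by = "patient_id"
  )

  sens <- modality_sensitivity(clin, "cytology_positive",
                               "mri_unequivocal_lmd", "csf_tdna_detected")

  surv <- NULL
  def <- dplyr::filter(clin, .data$study_category == "definitive",
                       !is.na(.data$csf_tdna_detected),
                       !is.na(.data$os_time_days))
  if (nrow(def) >= 2 && dplyr::n_distinct(def$csf_tdna_detected) == 2) {
    surv <- km_logrank(
      def$os_time_days, def$os_event,
      factor(ifelse(def$csf_tdna_detected, "detected", "not_detected"),
             levels = c("not_detected", "detected")),
      endpoint = "OS"
    )
  }

  assoc <- NULL
  paired <- dplyr::filter(clin, !is.na(.data$csf_mean_vaf),
                          !is.na(.data$plasma_mean_vaf))
  if (nrow(paired) >= 3 &&
      dplyr::n_distinct(paired$csf_mean_vaf) > 1 &&
      dplyr::n_distinct(paired$plasma_mean_vaf) > 1) {
    assoc <- dplyr::mutate(
      spearman_corr(paired$csf_mean_vaf, paired$plasma_mean_vaf),
      comparison = "csf_vs_plasma_mean_vaf", .before = 1)
  }

  log <- list(
    package_version = as.character(utils::packageVersion("csftdna")),
    seed = params$seed,
    params = params[setdiff(names(params), NULL)],
    config_hash = derive_seed(0, paste(deparse(params), collapse = "")),
    n_patients = length(patients), n_controls = length(control_ids),
    flags = flags,
    timestamp = format(Sys.time(), tz = "UTC")
  )

  report <- structure(list(
    profile = profile, reporters = reporters, detection = detection_tbl,
    scna = scna_tbl, resistance = resistance_tbl,
    concordance = concordance_tbl, clinical = clin, sensitivity = sens,
    survival = surv, associations = assoc, flags = flags, log = log
  ), class = "csf_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

call_sample_filtered <- function(sample, profile, panel, germline, params) {
  cand <- call_variants_tumor_naive(sample, profile, panel,
                                    alpha = params$alpha)
  cand <- withCallingHandlers(
    exclude_germline(cand, germline,
                     vaf_threshold = params$germline_vaf_threshold,
                     missing_policy = "pass"),
    csftdna_missing_germline = function(w) invokeRestart("muffleWarning")
  )
  filter_coding(cand, panel)
}

#' Write a report bundle to disk
#'
#' @param report A `csf_report`.
#' @param dir Output directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(report$detection, file.path(dir, "detection.tsv"))
  readr::write_tsv(report$scna, file.path(dir, "scna.tsv"))
  if (nrow(report$resistance %||% tibble::tibble()) > 0) {
    readr::write_tsv(report$resistance, file.path(dir, "resistance.tsv"))
  }
  if (nrow(report$concordance %||% tibble::tibble()) > 0) {
    readr::write_tsv(report$concordance, file.path(dir, "concordance.tsv"))
  }
  readr::write_tsv(report$sensitivity, file.path(dir, "sensitivity.tsv"))
  readr::write_tsv(report$clinical, file.path(dir, "clinical_classified.tsv"))
  summary <- list(
    sensitivity = report$sensitivity,
    survival = if (!is.null(report$survival)) glance(report$survival),
    associations = report$associations
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(report$log, file.path(dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}

#' @export
print.csf_report <- function(x, ...) {
  cat("<csf_report>\n")
  cat(sprintf("  detection: %d samples; SCNA: %d gene calls; resistance: %d alterations\n",
              nrow(x$detection), nrow(x$scna),
              nrow(x$resistance %||% tibble::tibble())))
  if (!is.null(x$survival)) print(x$survival)
  invisible(x)
}
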