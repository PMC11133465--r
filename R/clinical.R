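#' Classify leptomeningeal disease status
#'
#' Study categories: LMD is *definitive* when CSF cytology or the
#' clinical EGFR CSF PCR is positive, or when MRI shows unequivocal LMD
#' together with progressive neurological symptoms; *possible* when not
#' definitive but symptoms are present; *non_lmd* otherwise. EANO-ESMO
#' mapping: *confirmed* on positive cytology; *probable* on negative
#' cytology with positive MRI and symptoms; *possible* on negative
#' cytology and MRI with symptoms; *none* otherwise. Unknown (`NA`)
#' fields are treated as negative and the record is flagged incomplete.
#'
#' @param clinical Tibble with logical (or `NA`) columns
#'   `cytology_positive`, `egfr_csf_pcr_positive`,
#'   `mri_unequivocal_lmd`, `progressive_symptoms`.
#' @return Input with `study_category`, `eano_esmo` and
#'   `data_complete` columns appended. Records with all four fields
#'   unknown classify as `non_lmd` and trigger a data-completeness
#'   warning.
#' @export
#' @examples
#' classify_lmd(tibble::tibble(cytology_positive = c(TRUE, FALSE),
#'                             egfr_csf_pcr_positive = FALSE,
#'                             mri_unequivocal_lmd = c(FALSE, TRUE),
#'                             progressive_symptoms = TRUE))
classify_lmd <- function(clinical) {
  need <- c("cytology_positive", "egfr_csf_pcr_positive",
            "mri_unequivocal_lmd", "progressive_symptoms")
  missing <- setdiff(need, names(clinical))
  if (length(missing) > 0) {
    abort(sprintf("clinical table lacks column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  fields <- clinical[need]
  complete <- stats::complete.cases(fields)
  all_unknown <- rowSums(!is.na(fields)) == 0
  if (any(all_unknown)) {
    warn(sprintf("%d record(s) with every LMD work-up field unknown classified as non_lmd",
                 sum(all_unknown)), class = "csftdna_incomplete_clinical")
  }
  cyt <- dplyr::coalesce(clinical$cytology_positive, FALSE)
  pcr <- dplyr::coalesce(clinical$egfr_csf_pcr_positive, FALSE)
  mri <- dplyr::coalesce(clinical$mri_unequivocal_lmd, FALSE)
  sym <- dplyr::coalesce(clinical$progressive_symptoms, FALSE)
  definitive <- cyt | pcr | (mri & sym)
  dplyr::mutate(clinical,
    study_category = dplyr::case_when(
      definitive ~ "definitive",
      sym ~ "possible",
      TRUE ~ "non_lmd"
    ),
    eano_esmo = dplyr::case_when(
      cyt ~ "confirmed",
      mri & sym ~ "probable",
      !mri & sym ~ "possible",
      TRUE ~ "none"
    ),
    data_complete = complete
  )
}

#' Sensitivity of a diagnostic modality for definitive LMD
#'
#' Sensitivity = positive results / evaluable definitive-LMD patients,
#' reported with its numerator and denominator so denominators behind
#' cohort percentages stay auditable.
#'
#' @param data Tibble with a `study_category` column (see
#'   [classify_lmd()]) and one logical result column per modality.
#' @param ... Tidy-selected modality result columns (e.g.
#'   `cytology_positive`); `NA` results are not evaluable.
#' @return Tibble `modality`, `n_positive`, `n_evaluable`,
#'   `sensitivity` (fraction). Zero evaluable cases yield `NA` with a
#'   classed warning.
#' @export
#' @examples
#' d <- tibble::tibble(study_category = rep("definitive", 12),
#'                     csf_tdna_detected = c(rep(TRUE, 11), FALSE))
#' modality_sensitivity(d, csf_tdna_detected)$sensitivity # 11/12
modality_sensitivity <- function(data, ...) {
  cols <- names(dplyr::select(data, ...))
  def <- dplyr::filter(data, .data$study_category == "definitive")
  purrr::map_dfr(cols, function(col) {
    x <- def[[col]]
    n_eval <- sum(!is.na(x))
    if (n_eval == 0) {
      warn(sprintf("no evaluable definitive-LMD case for `%s`: sensitivity undefined",
                   col), class = "csftdna_undefined_result")
      return(tibble::tibble(modality = col, n_positive = 0L,
                            n_evaluable = 0L, sensitivity = NA_real_))
    }
    tibble::tibble(modality = col, n_positive = sum(x, na.rm = TRUE),
                   n_evaluable = n_eval,
                   sensitivity = sum(x, na.rm = TRUE) / n_eval)
  })
}

#' Dichotomize a continuous marker at its median
#'
#' Splits at the sample median (midpoint convention for even n); ties
#' at the median go to the `at_or_below` group, so the factor's second
#' level (`above`) is the higher-marker group in downstream hazard
#' ratios.
#'
#' @param values Numeric vector (>= 2 non-missing values).
#' @return Factor with levels `at_or_below`, `above` and a `threshold`
#'   attribute.
#' @export
#' @examples
#' dichotomize_by_median(c(1, 2, 3, 4))
dichotomize_by_median <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 2) abort("median dichotomization needs >= 2 values")
  m <- median(v)
  if (all(v == v[1])) abort("all values identical: no median split exists")
  out <- factor(ifelse(values > m, "above", "at_or_below"),
                levels = c("at_or_below", "above"))
  structure(out, threshold = m)
}

#' Rank-based association tests
#'
#' `spearman_corr()` computes Spearman's rank correlation with average
#' ranks for ties and a two-sided p-value; `mann_whitney()` compares
#' two groups by the Mann-Whitney U test (exact when both groups
#' together hold at most 20 untied observations, normal approximation
#' with tie correction otherwise).
#'
#' @param x,y Paired numeric vectors (complete pairs used; n >= 3).
#' @return One-row tibble `method`, `statistic`, `estimate` (rho; `NA`
#'   for the U test), `p_value`, `n`. A constant vector makes the
#'   correlation undefined (`NA` + classed warning).
#' @export
#' @examples
#' spearman_corr(1:6, c(2, 3, 1, 5, 6, 4))
spearman_corr <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("Spearman correlation needs >= 3 complete pairs")
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    warn("constant vector: Spearman correlation undefined",
         class = "csftdna_undefined_result")
    return(tibble::tibble(method = "spearman", statistic = NA_real_,
                          estimate = NA_real_, p_value = NA_real_,
                          n = length(x)))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         alternative = "two.sided"))
  tibble::tibble(method = "spearman", statistic = unname(ct$statistic),
                 estimate = unname(ct$estimate),
                 p_value = ct$p.value, n = length(x))
}

#' @param a,b Numeric vectors for the two groups.
#' @rdname spearman_corr
#' @export
mann_whitney <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 1 || length(b) < 1) abort("both groups need observations")
  exact <- (length(a) + length(b)) <= 20 && !any(duplicated(c(a, b)))
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  tibble::tibble(method = "mann_whitney", statistic = unname(wt$statistic),
                 estimate = NA_real_, p_value = wt$p.value,
                 n = length(a) + length(b))
}

#' CSF drug penetration rate
#'
#' CSF concentration as a percentage of the time-matched plasma
#' concentration. Undefined (NA, classed warning) when the plasma
#' concentration is zero or missing.
#'
#' @param csf_nM,plasma_nM Concentrations in nM (vectorized).
#' @return Percentage vector.
#' @export
#' @examples
#' penetration_rate(5, 100) # 5
penetration_rate <- function(csf_nM, plasma_nM) {
  bad <- is.na(plasma_nM) | plasma_nM <= 0
  if (any(bad & !is.na(csf_nM))) {
    warn("plasma concentration zero/missing: penetration rate undefined",
         class = "csftdna_undefined_result")
  }
  ifelse(bad, NA_real_, 100 * csf_nM / plasma_nM)
}

#' Percent change in VAF between two timepoints
#'
#' `100 * (post - pre) / pre`. A pre-treatment VAF of zero with a
#' positive post-treatment VAF is not a percent change but a new
#' detection: reported as `NA` with a classed warning.
#'
#' @param pre_vaf,post_vaf VAF fractions (vectorized).
#' @return Percentage vector.
#' @export
#' @examples
#' vaf_percent_change(0.04, 0.01) # -75
vaf_percent_change <- function(pre_vaf, post_vaf) {
  new_det <- !is.na(pre_vaf) & pre_vaf == 0 & !is.na(post_vaf) & post_vaf > 0
  if (any(new_det)) {
    warn(sprintf("%d pair(s) with pre VAF 0 and positive post VAF: new detection, percent change undefined",
                 sum(new_det)), class = "csftdna_new_detection")
  }
  ifelse(is.na(pre_vaf) | pre_vaf <= 0, NA_real_,
         100 * (post_vaf - pre_vaf) / pre_vaf)
}
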