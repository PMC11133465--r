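#' Estimate position-specific background error from control samples
#'
#' Pools alternate-allele and total depths across tumor-free control
#' samples per substitution (chrom, pos, ref, alt) and estimates the
#' background error rate as `(sum alt + a) / (sum depth + b)`. The
#' pseudocounts keep every usable rate strictly positive, which the
#' Monte Carlo detection null requires.
#'
#' @param controls Counts tibble covering >= 2 control samples
#'   (`sample_id`, `chrom`, `pos`, `ref`, `alt`, `depth`, `alt_count`).
#' @param pseudocounts Numeric `c(alt, depth)` added to the pooled
#'   numerator and denominator; default Jeffreys-like `c(0.5, 1)`.
#' @return Tibble of class `csf_error_profile`: one row per substitution
#'   with `total_alt`, `total_depth`, `n_controls`, `error_rate` and
#'   `usable` (positions with zero pooled depth are flagged unusable,
#'   never silently assigned a rate). The pseudocount policy is recorded
#'   in the `pseudocounts` attribute.
#' @export
#' @examples
#' ctl <- tibble::tibble(sample_id = rep(c("c1", "c2"), each = 1),
#'                       chrom = "chr7", pos = 100, ref = "A", alt = "T",
#'                       depth = c(1000L, 1000L), alt_count = c(1L, 3L))
#' estimate_error_profile(ctl, pseudocounts = c(0, 0))$error_rate # 0.002
estimate_error_profile <- function(controls, pseudocounts = c(0.5, 1)) {
  assert_counts(controls, "controls")
  if (dplyr::n_distinct(controls$sample_id) < 2) {
    abort("error-model estimation needs at least 2 control samples")
  }
  stopifnot(length(pseudocounts) == 2, all(pseudocounts >= 0))
  a <- pseudocounts[1]; b <- pseudocounts[2]
  prof <- controls |>
    dplyr::group_by(.data$chrom, .data$pos, .data$ref, .data$alt) |>
    dplyr::summarise(
      total_alt = sum(.data$alt_count),
      total_depth = sum(.data$depth),
      n_controls = dplyr::n_distinct(.data$sample_id),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      usable = .data$total_depth > 0,
      error_rate = dplyr::if_else(.data$usable,
                                  (.data$total_alt + a) / (.data$total_depth + b),
                                  NA_real_)
    ) |>
    dplyr::arrange(.data$chrom, .data$pos, .data$ref, .data$alt)
  structure(prof, class = c("csf_error_profile", class(prof)),
            pseudocounts = c(alt = a, depth = b))
}

#' Tumor-naive variant calling against the background error model
#'
#' At every covered position a one-sided binomial tail probability of
#' observing at least the seen alternate count under the position's
#' background error rate is computed; a candidate is called when that
#' p-value is at or below the Bonferroni-adjusted threshold
#' `alpha / n_tests` (family-wise control over the panel).
#'
#' @param sample Counts tibble for one sample.
#' @param profile [estimate_error_profile()] output covering the
#'   sample's positions.
#' @param panel Panel tibble supplying gene/coding annotation; its row
#'   count sets the Bonferroni family size unless `n_tests` is given.
#' @param alpha Family-wise error target (default 0.05).
#' @param n_tests Override for the number of tests.
#' @return Tibble of called candidates sorted by position, with `vaf`,
#'   `error_rate`, `p_value`, and gene/coding annotation. Positions
#'   missing from the profile (or unusable there) are excluded and
#'   counted in the `qc` attribute (`n_missing_profile`).
#' @export
call_variants_tumor_naive <- function(sample, profile, panel,
                                      alpha = 0.05, n_tests = NULL) {
  assert_counts(sample, "sample")
  n_tests <- n_tests %||% nrow(panel)
  stopifnot(n_tests >= 1, alpha > 0, alpha < 1)
  usable <- dplyr::filter(profile, .data$usable)
  joined <- dplyr::left_join(
    sample,
    dplyr::select(usable, "chrom", "pos", "ref", "alt", "error_rate"),
    by = c("chrom", "pos", "ref", "alt")
  )
  n_missing <- sum(is.na(joined$error_rate))
  joined <- dplyr::filter(joined, !is.na(.data$error_rate))
  threshold <- alpha / n_tests
  out <- joined |>
    dplyr::mutate(
      vaf = dplyr::if_else(.data$depth > 0,
                           .data$alt_count / .data$depth, NA_real_),
      p_value = pbinom(.data$alt_count - 1, .data$depth, .data$error_rate,
                       lower.tail = FALSE)
    ) |>
    dplyr::filter(.data$alt_count > 0, .data$p_value <= threshold) |>
    dplyr::left_join(dplyr::select(panel, "chrom", "pos", "gene", "coding"),
                     by = c("chrom", "pos")) |>
    dplyr::arrange(.data$chrom, .data$pos)
  structure(out, qc = list(n_missing_profile = n_missing,
                           threshold = threshold, n_tests = n_tests,
                           alpha = alpha))
}

#' Exclude germline SNPs from candidate variants
#'
#' A candidate is removed when its VAF in the matched germline sample is
#' at or above `vaf_threshold` (inclusive boundary: heterozygous and
#' homozygous SNPs are both caught) or, when a profile is supplied, when
#' the same binomial test calls it in the germline sample.
#'
#' @param candidates Candidate tibble from [call_variants_tumor_naive()].
#' @param germline Counts tibble of the patient's germline sample, or
#'   `NULL`.
#' @param vaf_threshold Germline VAF at or above which a candidate is an
#'   SNP (default 0.02).
#' @param profile,alpha,n_tests Optional: also exclude candidates the
#'   binomial caller would call in germline.
#' @param missing_policy What to do when `germline` is `NULL` or a
#'   candidate position is uncovered there: `"fail"` aborts,
#'   `"pass"` retains candidates and flags `germline_checked = FALSE`
#'   with a warning.
#' @return Filtered candidates; removals (with reasons) are recorded in
#'   the `removed` attribute. Idempotent.
#' @export
exclude_germline <- function(candidates, germline, vaf_threshold = 0.02,
                             profile = NULL, alpha = 0.05, n_tests = NULL,
                             missing_policy = c("fail", "pass")) {
  missing_policy <- match.arg(missing_policy)
  if (nrow(candidates) == 0) {
    return(structure(dplyr::mutate(candidates, germline_checked = logical(0)),
                     removed = candidates))
  }
  if (is.null(germline) || nrow(germline) == 0) {
    if (missing_policy == "fail") {
      abort("no germline sample available for SNP exclusion (missing_policy = \"fail\")")
    }
    warn("no germline sample: candidates pass through unchecked",
         class = "csftdna_missing_germline")
    out <- dplyr::mutate(candidates, germline_checked = FALSE)
    return(structure(out, removed = candidates[0, ]))
  }
  g <- dplyr::select(germline, "chrom", "pos", "ref", "alt",
                     g_depth = "depth", g_alt = "alt_count")
  joined <- dplyr::left_join(candidates, g,
                             by = c("chrom", "pos", "ref", "alt"))
  joined$g_vaf <- ifelse(!is.na(joined$g_depth) & joined$g_depth > 0,
                         joined$g_alt / joined$g_depth, NA_real_)
  snp <- !is.na(joined$g_vaf) & joined$g_vaf >= vaf_threshold
  reason <- ifelse(snp, "germline_vaf", NA_character_)
  if (!is.null(profile)) {
    # same binomial test, applied to the germline counts at each candidate
    pr <- dplyr::select(dplyr::filter(profile, .data$usable),
                        "chrom", "pos", "ref", "alt", "error_rate")
    names(pr)[names(pr) == "error_rate"] <- "g_error_rate"
    joined <- dplyr::left_join(joined, pr,
                               by = c("chrom", "pos", "ref", "alt"))
    thr <- alpha / (n_tests %||% 1)
    p_g <- pbinom(joined$g_alt - 1, joined$g_depth, joined$g_error_rate,
                  lower.tail = FALSE)
    in_g <- !is.na(p_g) & !is.na(joined$g_alt) & joined$g_alt > 0 & p_g <= thr
    reason[is.na(reason) & in_g] <- "germline_called"
    snp <- snp | in_g
  }
  uncovered <- is.na(joined$g_vaf)
  if (any(uncovered) && missing_policy == "fail") {
    abort(sprintf("%d candidate position(s) uncovered in germline (missing_policy = \"fail\")",
                  sum(uncovered)))
  }
  keep <- candidates[!snp, , drop = FALSE]
  keep$germline_checked <- !uncovered[!snp]
  if (any(uncovered[!snp])) {
    warn(sprintf("%d candidate(s) uncovered in germline retained unchecked",
                 sum(uncovered[!snp])), class = "csftdna_missing_germline")
  }
  removed <- candidates[snp, , drop = FALSE]
  if (nrow(removed) > 0) removed$reason <- reason[snp]
  structure(keep, removed = removed)
}

#' Retain protein-coding candidates
#'
#' Keeps candidates at positions flagged coding in the panel;
#' unannotated positions are treated as non-coding and recorded in the
#' `removed` attribute. Input order is preserved.
#'
#' @param candidates Candidate tibble.
#' @param panel Panel tibble with `coding` flags.
#' @return Coding candidates.
#' @export
filter_coding <- function(candidates, panel) {
  if (nrow(candidates) == 0) return(structure(candidates, removed = candidates))
  coding_col <- if ("coding" %in% names(candidates)) candidates$coding
  if (is.null(coding_col)) {
    idx <- match(paste(candidates$chrom, candidates$pos),
                 paste(panel$chrom, panel$pos))
    coding_col <- panel$coding[idx]
  }
  coding_col[is.na(coding_col)] <- FALSE
  structure(candidates[coding_col, , drop = FALSE],
            removed = candidates[!coding_col, , drop = FALSE])
}

#' Build the patient-level joint reporter set
#'
#' Calls variants in each of the patient's baseline (pre-treatment,
#' non-germline) samples, removes germline SNPs and non-coding
#' positions, and takes the union across samples. Each variant records
#' the samples it was called in (`sources`); a variant called in several
#' samples appears once. The result is invariant to the order in which
#' samples are supplied.
#'
#' @param samples Counts tibble holding one or more baseline samples
#'   (distinct `sample_id`s) of one patient.
#' @param profile Background error profile.
#' @param panel Panel tibble.
#' @param germline Counts tibble of the patient's germline sample
#'   (`NULL` allowed with `missing_policy = "pass"`).
#' @param patient_id Patient identifier stamped on the output.
#' @param vaf_threshold,alpha,missing_policy Passed to the calling and
#'   germline-exclusion steps.
#' @return Tibble of class `csf_reporter_set`: `patient_id`, `chrom`,
#'   `pos`, `ref`, `alt`, `gene`, `coding`, `sources` (list-column),
#'   sorted by position. May have zero rows.
#' @export
build_reporter_set <- function(samples, profile, panel, germline = NULL,
                               patient_id = NA_character_,
                               vaf_threshold = 0.02, alpha = 0.05,
                               missing_policy = c("fail", "pass")) {
  missing_policy <- match.arg(missing_policy)
  assert_counts(samples, "samples")
  ids <- unique(samples$sample_id)
  if (length(ids) < 1) abort("reporter-set construction needs >= 1 sample")
  calls <- purrr::map_dfr(ids, function(id) {
    cand <- call_variants_tumor_naive(samples[samples$sample_id == id, ],
                                      profile, panel, alpha = alpha)
    cand <- exclude_germline(cand, germline, vaf_threshold = vaf_threshold,
                             missing_policy = missing_policy)
    filter_coding(cand, panel)
  })
  if (nrow(calls) == 0) {
    out <- tibble::tibble(patient_id = character(), chrom = character(),
                          pos = integer(), ref = character(),
                          alt = character(), gene = character(),
                          coding = logical(), sources = list())
    return(structure(out, class = c("csf_reporter_set", class(out))))
  }
  out <- calls |>
    dplyr::group_by(.data$chrom, .data$pos, .data$ref, .data$alt) |>
    dplyr::summarise(
      gene = .data$gene[1], coding = .data$coding[1],
      sources = list(sort(unique(.data$sample_id))),
      .groups = "drop"
    ) |>
    dplyr::mutate(patient_id = patient_id, .before = 1) |>
    dplyr::arrange(.data$chrom, .data$pos, .data$ref, .data$alt)
  structure(out, class = c("csf_reporter_set", class(out)))
}
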