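#' Mean variant allele fraction over a patient's reporter set
#'
#' The sample-level tumor DNA quantification: the unweighted arithmetic
#' mean of `alt_count / depth` over the patient's reporter mutations
#' that have non-zero depth in this sample. Reporters uncovered in the
#' sample (depth 0, or absent from the counts) are excluded and counted.
#'
#' @param sample Counts tibble for one sample.
#' @param reporters Reporter set (see [build_reporter_set()]) or any
#'   tibble with `chrom`, `pos`, `ref`, `alt`.
#' @return Mean VAF as a single fraction, with attributes
#'   `n_evaluated` and `n_excluded`. When no reporter is evaluable the
#'   result is `NA` with a classed warning (`csftdna_undefined_result`)
#'   rather than a silent 0.
#' @export
#' @examples
#' s <- tibble::tibble(sample_id = "s", chrom = "chr1", pos = 1:2,
#'                     ref = "A", alt = "T", depth = c(100L, 200L),
#'                     alt_count = c(1L, 4L))
#' mean_vaf(s, s[, c("chrom", "pos", "ref", "alt")]) # 0.015
mean_vaf <- function(sample, reporters) {
  j <- dplyr::left_join(
    dplyr::select(reporters, "chrom", "pos", "ref", "alt"),
    dplyr::select(sample, "chrom", "pos", "ref", "alt", "depth", "alt_count"),
    by = c("chrom", "pos", "ref", "alt")
  )
  eval_ok <- !is.na(j$depth) & j$depth > 0
  if (!any(eval_ok)) {
    warn("no evaluable reporter (all depth 0 or uncovered): mean VAF undefined",
         class = "csftdna_undefined_result")
    return(structure(NA_real_, n_evaluated = 0L,
                     n_excluded = nrow(j)))
  }
  structure(mean(j$alt_count[eval_ok] / j$depth[eval_ok]),
            n_evaluated = sum(eval_ok), n_excluded = sum(!eval_ok))
}

#' Monte Carlo tumor DNA detection index
#'
#' Empirical tail probability of the observed mean reporter VAF under
#' the background-error null. For each of `B` iterations, a null
#' alternate count is drawn at every evaluable reporter as
#' `Binomial(observed depth, background error rate)` (the null
#' conditions on observed depths) and the null mean VAF is formed; the
#' index is `(1 + #{null >= observed}) / (B + 1)`, a valid randomized
#' p-value bounded below by `1/(B+1)`.
#'
#' @param sample Counts tibble for one sample.
#' @param reporters Reporter set.
#' @param profile Background error profile; every reporter must have a
#'   usable rate.
#' @param B Monte Carlo iterations (>= 1000).
#' @param seed Master seed; the draw uses a substream keyed by the
#'   sample id and the reporter-set hash, so adding samples to a cohort
#'   never perturbs another sample's index.
#' @return Detection index in `(0, 1]` with attributes `mean_vaf`,
#'   `n_evaluated`, `B`, `seed`. `NA` (with a
#'   `csftdna_undefined_result` warning) when no reporter is evaluable.
#' @export
detection_index <- function(sample, reporters, profile, B = 10000, seed = 1) {
  if (B < 1000) abort("`B` must be >= 1000 for a stable detection index")
  rep_keys <- variant_key(reporters$chrom, reporters$pos,
                          reporters$ref, reporters$alt)
  usable <- dplyr::filter(profile, .data$usable)
  prof_idx <- match(rep_keys, variant_key(usable$chrom, usable$pos,
                                          usable$ref, usable$alt))
  if (anyNA(prof_idx)) {
    abort(sprintf("reporter(s) missing from the error profile: %s",
                  paste(head(rep_keys[is.na(prof_idx)], 5), collapse = ", ")))
  }
  j <- dplyr::left_join(
    dplyr::select(reporters, "chrom", "pos", "ref", "alt"),
    dplyr::select(sample, "chrom", "pos", "ref", "alt", "depth", "alt_count"),
    by = c("chrom", "pos", "ref", "alt")
  )
  rates <- usable$error_rate[prof_idx]
  eval_ok <- !is.na(j$depth) & j$depth > 0
  if (!any(eval_ok)) {
    warn("no evaluable reporter: detection index undefined",
         class = "csftdna_undefined_result")
    return(structure(NA_real_, mean_vaf = NA_real_, n_evaluated = 0L,
                     B = B, seed = seed))
  }
  depth <- j$depth[eval_ok]
  alt <- j$alt_count[eval_ok]
  rate <- rates[eval_ok]
  n <- length(depth)
  obs <- mean(alt / depth)
  sub_seed <- derive_seed(seed, unique(sample$sample_id)[1],
                          paste(sort(rep_keys), collapse = ";"))
  null_ge <- with_seed(sub_seed, {
    draws <- rbinom(B * n, size = rep(depth, each = B),
                    prob = rep(rate, each = B))
    null_mean <- rowMeans(matrix(draws / rep(depth, each = B), nrow = B))
    sum(null_mean >= obs)
  })
  structure((1 + null_ge) / (B + 1), mean_vaf = obs,
            n_evaluated = n, B = B, seed = seed)
}

#' Classify a detection index against the cutoff
#'
#' Tumor DNA is classified as detected when the index is at or below
#' the cutoff (boundary inclusive, default 0.05) and as not detected
#' above it.
#'
#' @param index Detection index in `(0, 1]` (NA allowed, propagated).
#' @param cutoff Detection cutoff (default 0.05).
#' @return Logical.
#' @export
#' @examples
#' classify_detection(c(0.05, 0.0501, 1)) # TRUE FALSE FALSE
classify_detection <- function(index, cutoff = 0.05) {
  stopifnot(cutoff > 0, cutoff < 1)
  index <= cutoff
}

#' Quantify tumor DNA across samples
#'
#' Per-sample wrapper: computes the mean reporter VAF, the Monte Carlo
#' detection index and the detected flag for every sample in `counts`
#' against the patient's reporter set.
#'
#' @param counts Counts tibble (any number of samples).
#' @param reporters Reporter set shared by these samples (one patient),
#'   or a named list of reporter sets keyed by `patient_id` when
#'   `sample_sheet` is given.
#' @param profile Background error profile.
#' @param sample_sheet Optional sample sheet; its `patient_id`,
#'   `compartment` and `timepoint_days` are carried into the result.
#' @param B,cutoff,seed See [detection_index()] and
#'   [classify_detection()].
#' @return Tibble with one row per sample: `sample_id`, annotation
#'   columns when available, `n_reporters`, `mean_vaf`,
#'   `detection_index`, `detected`.
#' @export
detect_tdna <- function(counts, reporters, profile, sample_sheet = NULL,
                        B = 10000, cutoff = 0.05, seed = 1) {
  ids <- unique(counts$sample_id)
  res <- purrr::map_dfr(ids, function(id) {
    s <- counts[counts$sample_id == id, ]
    rset <- reporters
    if (!inherits(reporters, "data.frame")) {
      pid <- sample_sheet$patient_id[match(id, sample_sheet$sample_id)]
      rset <- reporters[[pid]]
    }
    if (is.null(rset) || nrow(rset) == 0) {
      return(tibble::tibble(sample_id = id, n_reporters = 0L,
                            mean_vaf = NA_real_, detection_index = NA_real_,
                            detected = NA))
    }
    idx <- withCallingHandlers(
      detection_index(s, rset, profile, B = B, seed = seed),
      csftdna_undefined_result = function(w) invokeRestart("muffleWarning")
    )
    tibble::tibble(
      sample_id = id,
      n_reporters = attr(idx, "n_evaluated"),
      mean_vaf = attr(idx, "mean_vaf"),
      detection_index = as.numeric(idx),
      detected = classify_detection(as.numeric(idx), cutoff)
    )
  })
  if (!is.null(sample_sheet)) {
    res <- dplyr::left_join(
      res,
      dplyr::select(sample_sheet, "sample_id", "patient_id", "compartment",
                    "timepoint_days"),
      by = "sample_id"
    ) |>
      dplyr::relocate("patient_id", "compartment", "timepoint_days",
                      .after = "sample_id")
  }
  res
}
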