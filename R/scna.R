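#' Gene-level normalized depth
#'
#' Divides the mean deduplicated depth over each gene's targeted
#' positions by the mean depth over all panel positions in the sample,
#' removing library size so samples are comparable.
#'
#' @param sample Counts tibble for one sample.
#' @param panel Panel tibble (`chrom`, `pos`, `gene`).
#' @return Tibble `gene`, `normalized_depth`. Genes with no covered
#'   position are absent and listed in the `dropped_genes` attribute.
#' @export
normalize_depth <- function(sample, panel) {
  j <- dplyr::inner_join(
    dplyr::select(sample, "chrom", "pos", "depth"),
    dplyr::select(panel, "chrom", "pos", "gene"),
    by = c("chrom", "pos")
  )
  overall <- mean(j$depth)
  if (!is.finite(overall) || overall <= 0) {
    abort("sample has no usable depth over the panel")
  }
  covered <- j |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(normalized_depth = mean(.data$depth) / overall,
                     n_pos = dplyr::n(), .groups = "drop")
  dropped <- setdiff(unique(panel$gene), covered$gene)
  structure(dplyr::select(covered, "gene", "normalized_depth"),
            dropped_genes = dropped)
}

#' Copy-number z-scores against a background cohort
#'
#' For each gene, `z = (x - mean_bg) / sd_bg` with the unbiased
#' background standard deviation, and `log2_ratio = log2(x / mean_bg)`,
#' capturing region-specific depth variability via the background set.
#'
#' @param sample_norm Output of [normalize_depth()] for the test sample.
#' @param background_norms Tibble `sample_id`, `gene`,
#'   `normalized_depth` covering >= 3 background samples per gene.
#' @return Tibble `gene`, `normalized_depth`, `z`, `log2_ratio`,
#'   `callable` (`FALSE` when the background is degenerate: sd 0 or
#'   fewer than 3 samples).
#' @export
scna_zscores <- function(sample_norm, background_norms) {
  bg <- background_norms |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(bg_mean = mean(.data$normalized_depth),
                     bg_sd = sd(.data$normalized_depth),
                     bg_n = dplyr::n(), .groups = "drop")
  sample_norm |>
    dplyr::left_join(bg, by = "gene") |>
    dplyr::mutate(
      callable = !is.na(.data$bg_sd) & .data$bg_sd > 0 & .data$bg_n >= 3,
      z = dplyr::if_else(.data$callable,
                         (.data$normalized_depth - .data$bg_mean) / .data$bg_sd,
                         NA_real_),
      log2_ratio = dplyr::if_else(.data$callable & .data$normalized_depth > 0,
                                  log2(.data$normalized_depth / .data$bg_mean),
                                  NA_real_)
    ) |>
    dplyr::select("gene", "normalized_depth", "z", "log2_ratio", "callable")
}

#' Leave-one-out z-scores of the background samples themselves
#'
#' Self-scores each background sample against the remaining ones
#' (leave-one-out mean and unbiased sd). Used to verify that the
#' background behaves approximately standard normal, i.e. that the
#' z-score machinery is calibrated.
#'
#' @param background_norms Tibble `sample_id`, `gene`,
#'   `normalized_depth`.
#' @return Tibble `sample_id`, `gene`, `z`.
#' @export
scna_background_zscores <- function(background_norms) {
  background_norms |>
    dplyr::group_by(.data$gene) |>
    dplyr::group_modify(function(d, key) {
      n <- nrow(d)
      z <- vapply(seq_len(n), function(i) {
        rest <- d$normalized_depth[-i]
        s <- sd(rest)
        if (n < 4 || !is.finite(s) || s == 0) return(NA_real_)
        (d$normalized_depth[i] - mean(rest)) / s
      }, numeric(1))
      tibble::tibble(sample_id = d$sample_id, z = z)
    }) |>
    dplyr::ungroup() |>
    dplyr::select("sample_id", "gene", "z")
}

#' Call focal amplifications and deletions
#'
#' Applies symmetric-by-default z thresholds: amplification at
#' `z >= z_amp`, deletion at `z <= -z_del`, neutral otherwise.
#'
#' @param zmap Output of [scna_zscores()].
#' @param z_amp,z_del Positive thresholds (default 3, conventional
#'   3-sigma focal-event calling).
#' @param cnv_genes Optional gene restriction list; `NULL` calls every
#'   panel gene.
#' @param sample_id Optional identifier stamped on the output.
#' @return Tibble `sample_id`, `gene`, `normalized_depth`, `z`,
#'   `log2_ratio`, `call` (amplification / deletion / neutral;
#'   un-callable genes get `NA`).
#' @export
#' @examples
#' zt <- tibble::tibble(gene = "MET", normalized_depth = 3, z = 5.2,
#'                      log2_ratio = log2(3), callable = TRUE)
#' call_scna(zt)$call # "amplification"
call_scna <- function(zmap, z_amp = 3, z_del = 3, cnv_genes = NULL,
                      sample_id = NA_character_) {
  stopifnot(z_amp > 0, z_del > 0)
  out <- zmap
  if (!is.null(cnv_genes)) out <- dplyr::filter(out, .data$gene %in% cnv_genes)
  out |>
    dplyr::mutate(
      sample_id = sample_id,
      call = dplyr::case_when(
        !.data$callable ~ NA_character_,
        .data$z >= z_amp ~ "amplification",
        .data$z <= -z_del ~ "deletion",
        TRUE ~ "neutral"
      )
    ) |>
    dplyr::select("sample_id", "gene", "normalized_depth", "z",
                  "log2_ratio", "call")
}

#' End-to-end SCNA calling for a set of samples
#'
#' Normalizes depth for each test sample and each background sample,
#' scores genes by z against the background, and calls events.
#'
#' @param counts Counts tibble of the test samples.
#' @param background_counts Counts tibble of the background cohort
#'   (>= 3 samples).
#' @param panel Panel tibble.
#' @param z_amp,z_del,cnv_genes See [call_scna()].
#' @return Tibble of calls over all test samples.
#' @export
scna_analysis <- function(counts, background_counts, panel,
                          z_amp = 3, z_del = 3, cnv_genes = NULL) {
  bg_ids <- unique(background_counts$sample_id)
  if (length(bg_ids) < 3) abort("SCNA background needs >= 3 samples")
  bg_norms <- purrr::map_dfr(bg_ids, function(id) {
    dplyr::mutate(normalize_depth(
      background_counts[background_counts$sample_id == id, ], panel),
      sample_id = id, .before = 1)
  })
  purrr::map_dfr(unique(counts$sample_id), function(id) {
    nm <- normalize_depth(counts[counts$sample_id == id, ], panel)
    call_scna(scna_zscores(nm, bg_norms), z_amp = z_amp, z_del = z_del,
              cnv_genes = cnv_genes, sample_id = id)
  })
}
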