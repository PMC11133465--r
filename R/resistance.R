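#' Default resistance gene whitelists
#'
#' Genes in which post-TKI alterations are considered candidate
#' resistance mechanisms: exonic SNVs in EGFR, PIK3CA, KRAS, CDKN2A,
#' RB1, ALK, KIT and MET; copy-number changes in MET, ERBB2 and EGFR.
#'
#' @name resistance_whitelists
#' @export
snv_resistance_genes <- function() {
  c("EGFR", "PIK3CA", "KRAS", "CDKN2A", "RB1", "ALK", "KIT", "MET")
}

#' @rdname resistance_whitelists
#' @export
cnv_resistance_genes <- function() c("MET", "ERBB2", "EGFR")

alteration_key <- function(calls) {
  ifelse(calls$type == "CNV",
         paste("CNV", calls$gene, calls$direction, sep = ":"),
         variant_key(calls$chrom, calls$pos, calls$ref, calls$alt))
}

normalize_alteration_calls <- function(calls) {
  calls <- tibble::as_tibble(calls)
  if (!"type" %in% names(calls)) calls$type <- "SNV"
  for (col in c("chrom", "ref", "alt", "direction", "gene")) {
    if (!col %in% names(calls)) calls[[col]] <- NA_character_
  }
  if (!"pos" %in% names(calls)) calls$pos <- NA_integer_
  if (!"coding" %in% names(calls)) calls$coding <- TRUE
  calls
}

#' Identify emergent resistance alterations
#'
#' Restricts post-therapy calls to the resistance gene whitelists
#' (exonic SNVs via the panel coding flag; copy-number events by gene)
#' and flags as emergent those absent from the pre-therapy calls. SNVs
#' are matched by (chrom, pos, ref, alt), copy-number events by
#' (gene, direction). When pre-therapy counts are supplied, an SNV is
#' only declared emergent if the pre sample covered its position at
#' `min_pre_depth` or more; otherwise absence could merely reflect
#' missing coverage and the call is flagged `low_pre_depth`.
#'
#' @param pre_calls Calls in the pre-TKI sample (CSF, tumor or pleural
#'   effusion). A missing pre-TKI sample (`NULL`) is an error: such
#'   patients are excluded from the analysis.
#' @param post_calls Calls in the post-TKI sample, with `compartment`
#'   and `timepoint_days` columns if available.
#' @param snv_whitelist,cnv_whitelist Gene whitelists.
#' @param pre_counts Optional counts tibble of the pre-TKI sample for
#'   the coverage guard.
#' @param min_pre_depth Minimum pre-TKI depth for an emergent SNV call.
#' @param patient_id Stamped on the output.
#' @return Tibble of class `csf_resistance`: one row per
#'   whitelist-restricted post-TKI alteration with `present_pre`,
#'   `present_post`, `emergent` and `note` (`"low_pre_depth"` when the
#'   coverage guard withheld the emergent flag).
#' @export
emergent_variants <- function(pre_calls, post_calls,
                              snv_whitelist = snv_resistance_genes(),
                              cnv_whitelist = cnv_resistance_genes(),
                              pre_counts = NULL, min_pre_depth = 50,
                              patient_id = NA_character_) {
  if (is.null(pre_calls)) {
    abort("no pre-TKI sample: patient excluded from the resistance analysis",
          class = "csftdna_missing_pre_tki")
  }
  pre <- normalize_alteration_calls(pre_calls)
  post <- normalize_alteration_calls(post_calls)
  keep <- (post$type == "SNV" & post$gene %in% snv_whitelist & post$coding) |
    (post$type == "CNV" & post$gene %in% cnv_whitelist)
  post <- post[keep, , drop = FALSE]
  if (nrow(post) == 0) {
    out <- tibble::tibble(patient_id = character(), type = character(),
                          gene = character(), chrom = character(),
                          pos = integer(), ref = character(),
                          alt = character(), direction = character(),
                          compartment = character(),
                          timepoint_days = numeric(),
                          present_pre = logical(), present_post = logical(),
                          emergent = logical(), note = character())
    return(structure(out, class = c("csf_resistance", class(out))))
  }
  present_pre <- alteration_key(post) %in% alteration_key(pre)
  note <- rep(NA_character_, nrow(post))
  emergent <- !present_pre
  if (!is.null(pre_counts)) {
    is_snv <- post$type == "SNV"
    idx <- match(paste(post$chrom, post$pos),
                 paste(pre_counts$chrom, pre_counts$pos))
    pre_depth <- pre_counts$depth[idx]
    shallow <- is_snv & !present_pre &
      (is.na(pre_depth) | pre_depth < min_pre_depth)
    emergent[shallow] <- FALSE
    note[shallow] <- "low_pre_depth"
  }
  out <- tibble::tibble(
    patient_id = patient_id, type = post$type, gene = post$gene,
    chrom = post$chrom, pos = post$pos, ref = post$ref, alt = post$alt,
    direction = post$direction,
    compartment = if ("compartment" %in% names(post)) post$compartment else NA_character_,
    timepoint_days = if ("timepoint_days" %in% names(post)) post$timepoint_days else NA_real_,
    present_pre = present_pre, present_post = TRUE,
    emergent = emergent, note = note
  )
  structure(out, class = c("csf_resistance", class(out)))
}

#' Compare emergent alterations between plasma and CSF
#'
#' Assigns each emergent alteration of a time-matched plasma/CSF pair
#' to exactly one category: `plasma_only`, `csf_only` or `shared`. The
#' pair must satisfy the study's time-matching rule: samples collected
#' within `max_gap_days` of each other (default 14, inclusive).
#'
#' @param plasma_emergent,csf_emergent Outputs of [emergent_variants()]
#'   for the two compartments (only rows with `emergent = TRUE` are
#'   used).
#' @param max_gap_days Maximum timepoint gap between the two samples.
#' @return Tibble: one row per emergent alteration with `category`,
#'   plus a `summary` attribute counting categories per patient.
#' @export
compare_compartments <- function(plasma_emergent, csf_emergent,
                                 max_gap_days = 14) {
  pl_all <- tibble::as_tibble(plasma_emergent)
  cs_all <- tibble::as_tibble(csf_emergent)
  pl <- dplyr::filter(pl_all, .data$emergent)
  cs <- dplyr::filter(cs_all, .data$emergent)
  tp_p <- unique(pl_all$timepoint_days[!is.na(pl_all$timepoint_days)])
  tp_c <- unique(cs_all$timepoint_days[!is.na(cs_all$timepoint_days)])
  if (length(tp_p) == 1 && length(tp_c) == 1 &&
      abs(tp_p - tp_c) > max_gap_days) {
    abort(sprintf("plasma/CSF pair rejected: %g day gap exceeds the %g-day time-matching window",
                  abs(tp_p - tp_c), max_gap_days),
          class = "csftdna_time_mismatch")
  }
  keys <- union(alteration_key(pl), alteration_key(cs))
  if (length(keys) == 0) {
    out <- tibble::tibble(patient_id = character(), type = character(),
                          gene = character(), alteration = character(),
                          category = character())
    return(structure(out, summary = dplyr::count(out, .data$patient_id,
                                                 .data$category)))
  }
  src <- dplyr::bind_rows(pl, cs)
  src$alteration <- alteration_key(src)
  meta <- src[!duplicated(src$alteration),
              c("patient_id", "type", "gene", "alteration")]
  meta <- meta[match(keys, meta$alteration), , drop = FALSE]
  in_pl <- keys %in% alteration_key(pl)
  in_cs <- keys %in% alteration_key(cs)
  out <- dplyr::mutate(meta, category = dplyr::case_when(
    in_pl & in_cs ~ "shared",
    in_pl ~ "plasma_only",
    TRUE ~ "csf_only"
  ))
  structure(tibble::as_tibble(out),
            summary = dplyr::count(out, .data$patient_id, .data$category))
}
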