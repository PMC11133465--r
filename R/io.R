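#' Read and write per-position count tables
#'
#' Tab-separated with header
#' `sample_id chrom pos ref alt depth alt_count`; `pos` is 1-based and
#' one alternate allele is recorded per row. Reading validates the
#' table and reports the file, line number and offending field of the
#' first malformed row (`alt_count > depth`, negative counts).
#'
#' @param path File path.
#' @return `read_counts_tsv()` returns a counts tibble.
#' @export
read_counts_tsv <- function(path) {
  counts <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(), chrom = readr::col_character(),
    pos = readr::col_integer(), ref = readr::col_character(),
    alt = readr::col_character(), depth = readr::col_integer(),
    alt_count = readr::col_integer()
  ), progress = FALSE)
  bad <- which(counts$alt_count > counts$depth | counts$alt_count < 0 |
                 counts$depth < 0)
  if (length(bad) > 0) {
    abort(sprintf("%s line %d: alt_count (%d) exceeds depth (%d) or is negative",
                  path, bad[1] + 1L, counts$alt_count[bad[1]],
                  counts$depth[bad[1]]))
  }
  counts
}

#' @param counts Counts tibble.
#' @rdname read_counts_tsv
#' @export
write_counts_tsv <- function(counts, path) {
  assert_counts(counts)
  readr::write_tsv(counts[, c("sample_id", "chrom", "pos", "ref", "alt",
                              "depth", "alt_count")], path)
  invisible(path)
}

#' Read and write the selector panel as BED
#'
#' BED uses 0-based half-open coordinates; the per-position panel uses
#' 1-based positions, and the conversion happens in this layer only
#' (region `(start, end)` covers positions `start+1 .. end`).
#' Contiguous runs with the same gene and coding status become one BED
#' row; the `name` field carries the gene and the `score` field the
#' coding flag (1/0). Reading uses `rtracklayer`.
#'
#' @param path File path.
#' @return `read_bed()` returns a per-position tibble `chrom`, `pos`,
#'   `gene`, `coding`.
#' @export
read_bed <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("reading BED requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "BED")
  starts <- BiocGenerics::start(gr) # already 1-based in GRanges
  ends <- BiocGenerics::end(gr)
  chroms <- as.character(GenomeInfoDb::seqnames(gr))
  scores <- gr$score %||% rep(0, length(gr))
  scores[is.na(scores)] <- 0
  purrr::map_dfr(seq_along(gr), function(i) {
    tibble::tibble(
      chrom = chroms[i],
      pos = seq(starts[i], ends[i]),
      gene = gr$name[i],
      coding = scores[i] >= 1
    )
  }) |> dplyr::arrange(.data$chrom, .data$pos)
}

#' @param panel Per-position panel tibble.
#' @rdname read_bed
#' @export
write_bed <- function(panel, path) {
  runs <- panel |>
    dplyr::arrange(.data$chrom, .data$pos) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(brk = cumsum(
      c(TRUE, diff(.data$pos) != 1) |
        .data$gene != dplyr::lag(.data$gene, default = dplyr::first(.data$gene)) |
        .data$coding != dplyr::lag(.data$coding,
                                   default = dplyr::first(.data$coding))
    )) |>
    dplyr::group_by(.data$chrom, .data$brk) |>
    dplyr::summarise(start = min(.data$pos) - 1L, end = max(.data$pos),
                     name = .data$gene[1],
                     score = as.integer(.data$coding[1]),
                     .groups = "drop") |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::mutate(strand = "+") |>
    dplyr::select("chrom", "start", "end", "name", "score", "strand")
  readr::write_tsv(runs, path, col_names = FALSE)
  invisible(path)
}

#' Read and write the sample sheet
#'
#' Columns: `sample_id`, `patient_id`, `compartment`,
#' `timepoint_days`, `treatment_state`.
#'
#' @param path File path.
#' @export
read_sample_sheet <- function(path) {
  sheet <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(), patient_id = readr::col_character(),
    compartment = readr::col_character(),
    timepoint_days = readr::col_double(),
    treatment_state = readr::col_character()
  ), progress = FALSE)
  valid <- c("CSF", "plasma", "tumor", "pleural_effusion", "germline")
  bad <- which(!sheet$compartment %in% valid)
  if (length(bad) > 0) {
    abort(sprintf("%s line %d: unknown compartment \"%s\"",
                  path, bad[1] + 1L, sheet$compartment[bad[1]]))
  }
  sheet
}

#' @param sheet Sample sheet tibble.
#' @rdname read_sample_sheet
#' @export
write_sample_sheet <- function(sheet, path) {
  readr::write_tsv(sheet, path)
  invisible(path)
}

#' Read and write the clinical table
#'
#' @param path File path.
#' @export
read_clinical <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    patient_id = readr::col_character(),
    cytology_positive = readr::col_logical(),
    egfr_csf_pcr_positive = readr::col_logical(),
    mri_unequivocal_lmd = readr::col_logical(),
    progressive_symptoms = readr::col_logical(),
    os_event = readr::col_logical(),
    cns_event = readr::col_logical(),
    .default = readr::col_double()
  ), progress = FALSE)
}

#' @param clinical Clinical tibble.
#' @rdname read_clinical
#' @export
write_clinical <- function(clinical, path) {
  readr::write_tsv(clinical, path)
  invisible(path)
}

#' Write variant calls as VCF 4.2
#'
#' Minimal single-sample-free VCF export of called candidates:
#' `INFO` carries `VAF`, `DEPTH`, `ALTC` (alternate count) and `PBIN`
#' (binomial tail p-value); the `FILTER` column carries `PASS` or the
#' reason a candidate was filtered (`germline`, `noncoding`,
#' `background`).
#'
#' @param calls Tibble with `chrom`, `pos`, `ref`, `alt`, `vaf`,
#'   `depth`, `alt_count`, `p_value` and optionally `filter`.
#' @param path Output path.
#' @export
write_vcf <- function(calls, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=csftdna",
    "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Variant allele fraction\">",
    "##INFO=<ID=DEPTH,Number=1,Type=Integer,Description=\"Deduplicated depth\">",
    "##INFO=<ID=ALTC,Number=1,Type=Integer,Description=\"Alternate allele count\">",
    "##INFO=<ID=PBIN,Number=1,Type=Float,Description=\"Binomial tail p-value vs background error\">",
    "##FILTER=<ID=germline,Description=\"Germline SNP\">",
    "##FILTER=<ID=noncoding,Description=\"Not protein coding\">",
    "##FILTER=<ID=background,Description=\"Not above background error\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  filt <- if ("filter" %in% names(calls)) calls$filter else "PASS"
  body <- sprintf(
    "%s\t%d\t.\t%s\t%s\t.\t%s\tVAF=%.6g;DEPTH=%d;ALTC=%d;PBIN=%.6g",
    calls$chrom, calls$pos, calls$ref, calls$alt,
    rep(filt, length.out = nrow(calls)),
    calls$vaf, calls$depth, calls$alt_count, calls$p_value
  )
  writeLines(c(header, if (nrow(calls) > 0) body), path)
  invisible(path)
}

#' Read a VCF written by [write_vcf()]
#'
#' @param path VCF path.
#' @return Calls tibble with `chrom`, `pos`, `ref`, `alt`, `filter`,
#'   `vaf`, `depth`, `alt_count`, `p_value`.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0) {
    return(tibble::tibble(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          filter = character(), vaf = numeric(),
                          depth = integer(), alt_count = integer(),
                          p_value = numeric()))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  info <- purrr::map(f, function(x) {
    kv <- strsplit(strsplit(x[8], ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
    setNames(as.numeric(vapply(kv, `[`, "", 2)),
             vapply(kv, `[`, "", 1))
  })
  tibble::tibble(
    chrom = vapply(f, `[`, "", 1),
    pos = as.integer(vapply(f, `[`, "", 2)),
    ref = vapply(f, `[`, "", 4),
    alt = vapply(f, `[`, "", 5),
    filter = vapply(f, `[`, "", 7),
    vaf = vapply(info, `[[`, 0, "VAF"),
    depth = as.integer(vapply(info, `[[`, 0, "DEPTH")),
    alt_count = as.integer(vapply(info, `[[`, 0, "ALTC")),
    p_value = vapply(info, `[[`, 0, "PBIN")
  )
}

#' Write a simulated cohort to disk
#'
#' Emits the selector BED, the counts TSV, the sample sheet, the
#' clinical TSV and the ground truth (JSON) into a directory.
#'
#' @param cohort A `csf_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_bed(cohort$panel, file.path(dir, "selector.bed"))
  write_counts_tsv(cohort$counts, file.path(dir, "counts.tsv"))
  write_sample_sheet(cohort$sample_sheet, file.path(dir, "sample_sheet.tsv"))
  write_clinical(cohort$clinical, file.path(dir, "clinical.tsv"))
  truth <- cohort$truth
  truth$survival <- as.list(truth$survival)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
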