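# Shared fixtures, all generated in code.

# Minimal hand-written panel: two genes, known layout.
tiny_panel <- function() {
  tibble::tibble(
    chrom = c(rep("chr7", 6), rep("chr17", 4)),
    pos = c(101:106, 201:204),
    ref = c("A", "C", "G", "T", "A", "C", "G", "T", "A", "C"),
    alt = c("T", "G", "A", "C", "G", "T", "C", "A", "T", "G"),
    gene = c(rep("EGFR", 6), rep("TP53", 4)),
    coding = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE),
    true_error_rate = rep(1e-4, 10)
  )
}

make_counts <- function(panel, sample_id, depth, alt_count) {
  tibble::tibble(
    sample_id = sample_id,
    chrom = panel$chrom, pos = panel$pos, ref = panel$ref, alt = panel$alt,
    depth = as.integer(rep(depth, length.out = nrow(panel))),
    alt_count = as.integer(rep(alt_count, length.out = nrow(panel)))
  )
}

# Flat error profile over a panel at a fixed rate (no pseudocount effects).
flat_profile <- function(panel, rate = 1e-4, depth = 100000L) {
  prof <- tibble::tibble(
    chrom = panel$chrom, pos = panel$pos, ref = panel$ref, alt = panel$alt,
    total_alt = as.integer(round(rate * depth)), total_depth = depth,
    n_controls = 2L, usable = TRUE, error_rate = rate
  )
  structure(prof, class = c("csf_error_profile", class(prof)),
            pseudocounts = c(alt = 0, depth = 0))
}

# One small simulated cohort reused across test files.
shared_cohort <- local({
  value <- NULL
  function() {
    if (is.null(value)) {
      value <<- simulate_cohort(sim_config(
        n_patients = 6, n_controls = 4, panel_size = 400,
        resistance_scenario_fraction = 0.4, seed = 42))
    }
    value
  }
})

shared_profile <- local({
  value <- NULL
  function() {
    if (is.null(value)) {
      co <- shared_cohort()
      ctl <- co$counts[grepl("^CTRL", co$counts$sample_id), ]
      value <<- estimate_error_profile(ctl)
    }
    value
  }
})

make_snv_call <- function(gene, chrom, pos, ref, alt, compartment = NA,
                          timepoint_days = NA_real_) {
  tibble::tibble(type = "SNV", gene = gene, chrom = chrom, pos = pos,
                 ref = ref, alt = alt, coding = TRUE,
                 compartment = compartment, timepoint_days = timepoint_days)
}

make_cnv_call <- function(gene, direction = "amplification",
                          compartment = NA, timepoint_days = NA_real_) {
  tibble::tibble(type = "CNV", gene = gene, direction = direction,
                 compartment = compartment, timepoint_days = timepoint_days)
}

# Case-vignette fixtures: plasma-restricted emergent resistance.
kras_emergent_case <- function() {
  pre <- dplyr::bind_rows(
    make_snv_call("EGFR", "chr7", 55242465, "GGAATTAAGAGAAGC", "G"),  # del19
    make_snv_call("TP53", "chr17", 7577538, "C", "T")                 # R248W
  )
  post_plasma <- dplyr::bind_rows(
    make_snv_call("EGFR", "chr7", 55242465, "GGAATTAAGAGAAGC", "G",
                  compartment = "plasma", timepoint_days = 400),
    make_snv_call("TP53", "chr17", 7577538, "C", "T",
                  compartment = "plasma", timepoint_days = 400),
    make_snv_call("KRAS", "chr12", 25398284, "C", "G",
                  compartment = "plasma", timepoint_days = 400)  # G12A
  )
  post_csf <- dplyr::bind_rows(
    make_snv_call("EGFR", "chr7", 55242465, "GGAATTAAGAGAAGC", "G",
                  compartment = "CSF", timepoint_days = 400),
    make_snv_call("TP53", "chr17", 7577538, "C", "T",
                  compartment = "CSF", timepoint_days = 400)
  )
  list(pre = pre, post_plasma = post_plasma, post_csf = post_csf)
}

t790m_erbb2_case <- function() {
  pre <- make_snv_call("EGFR", "chr7", 55242465, "GGAATTAAGAGAAGC", "G")
  post_plasma <- dplyr::bind_rows(
    make_snv_call("EGFR", "chr7", 55242465, "GGAATTAAGAGAAGC", "G",
                  compartment = "plasma", timepoint_days = 300),
    make_snv_call("EGFR", "chr7", 55249071, "C", "T",
                  compartment = "plasma", timepoint_days = 300),  # T790M
    make_cnv_call("ERBB2", "amplification", compartment = "plasma",
                  timepoint_days = 300)
  )
  post_csf <- make_snv_call("EGFR", "chr7", 55242465, "GGAATTAAGAGAAGC",
                            "G", compartment = "CSF",
                            timepoint_days = 305)
  list(pre = pre, post_plasma = post_plasma, post_csf = post_csf)
}
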