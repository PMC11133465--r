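#' Derive a reproducible substream seed
#'
#' Hashes a master seed together with an arbitrary set of string/numeric
#' labels (patient, compartment, timepoint, ...) into a 31-bit integer seed,
#' so that each simulated sample and each Monte Carlo run draws from its own
#' deterministic stream: adding samples to a cohort never perturbs the
#' stream of another sample.
#'
#' @param seed Integer master seed.
#' @param ... Labels (coerced to character) identifying the substream.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(7, "LUP001", "CSF", 0)
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  key <- paste(c(format(seed, scientific = FALSE), as.character(unlist(list(...)))),
               collapse = "")
  codes <- utf8ToInt(key)
  m <- 2147483647 # 2^31 - 1, prime; 31*h + c stays exact in doubles
  h <- 0
  for (cc in codes) h <- (h * 31 + cc) %% m
  as.integer(h)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Position key used wherever (chrom, pos, ref, alt) identifies a substitution.
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

assert_counts <- function(counts, arg = "counts") {
  needed <- c("sample_id", "chrom", "pos", "ref", "alt", "depth", "alt_count")
  missing <- setdiff(needed, names(counts))
  if (length(missing) > 0) {
    abort(sprintf("`%s` lacks required columns: %s", arg,
                  paste(missing, collapse = ", ")))
  }
  bad <- which(counts$alt_count > counts$depth)
  if (length(bad) > 0) {
    abort(sprintf("`%s` has alt_count > depth at %d row(s), first at row %d",
                  arg, length(bad), bad[1]))
  }
  invisible(counts)
}
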