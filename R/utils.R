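#' @noRd
`%||%` <- function(x, y) if (is.null(x)) y else x

# Run `expr` under a locally seeded RNG without disturbing the caller's state.
#' @noRd
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

#' @noRd
assert_fraction <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must be a fraction in [0, 1].", name))
  }
  invisible(x)
}

# Genome sequences move around as a named character vector or a
# Biostrings::DNAStringSet; normalise to named character.
#' @noRd
as_genome_chr <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    stats::setNames(as.character(genome), names(genome))
  } else if (is.character(genome)) {
    if (is.null(names(genome))) names(genome) <- paste0("chr", seq_along(genome))
    genome
  } else {
    abort("`genome` must be a DNAStringSet or a named character vector.")
  }
}

# 0-based half-open region tibble helper; accepts "chr:start-end" too.
#' @noRd
as_region <- function(region) {
  if (is.character(region) && length(region) == 1L) {
    m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
    if (length(m) != 4L) abort("region string must look like 'chr:start-end'.")
    return(tibble(chrom = m[2], start = as.integer(m[3]), end = as.integer(m[4])))
  }
  region <- as_tibble(region)
  stopifnot(all(c("chrom", "start", "end") %in% names(region)))
  region
}

# Merge overlapping 0-based half-open intervals on one chromosome.
#' @noRd
merge_intervals <- function(start, end) {
  ir <- IRanges::reduce(IRanges::IRanges(start = start + 1L, end = end))
  tibble(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

# TRUE for each query interval that overlaps >= min_overlap bp of any subject
# interval (same chromosome handled by caller). 0-based half-open in, out.
#' @noRd
overlaps_any <- function(q_start, q_end, s_start, s_end, min_overlap = 1L) {
  if (length(s_start) == 0L || length(q_start) == 0L) {
    return(rep(FALSE, length(q_start)))
  }
  q <- IRanges::IRanges(start = q_start + 1L, end = q_end)
  s <- IRanges::IRanges(start = s_start + 1L, end = s_end)
  hits <- IRanges::findOverlaps(q, s, minoverlap = min_overlap)
  seq_along(q_start) %in% S4Vectors::queryHits(hits)
}
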