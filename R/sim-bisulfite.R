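# Bisulfite clone simulation: each clone is one allele of one molecule put
# through bisulfite conversion — unmethylated cytosines read as T, methylated
# CpG cytosines are protected and read as C.

#' Simulate bisulfite sequencing clones from a region
#'
#' Each clone samples a parental allele by `allele_weights`, then converts the
#' top-strand region sequence: non-CpG cytosines C->T with probability
#' `conversion_rate`; CpG cytosines C->T at the same rate only where the
#' sampled allele is unmethylated. True allele labels are recorded for
#' downstream truth checks.
#'
#' @param sim A `cgi_sim` from [simulate_genome()].
#' @param region Amplicon as `"chr:start-end"` or a one-row tibble
#'   (`chrom`, `start`, `end`, 0-based half-open). Must contain >= 1 CpG.
#' @param n_clones Number of clones.
#' @param allele_weights Length-2 numeric `(maternal, paternal)`, summing
#'   to 1.
#' @param conversion_rate Bisulfite conversion efficiency in \[0, 1\].
#' @param seed Integer seed.
#' @return A `clone_sim` list: `clones` (named character vector of clone
#'   sequences), `truth` (tibble `clone`, `allele`), `reference` (unconverted
#'   region sequence), `cpg_positions` (genomic 0-based C positions),
#'   `region`.
#' @export
simulate_bisulfite_clones <- function(sim, region, n_clones,
                                      allele_weights = c(0.5, 0.5),
                                      conversion_rate = 0.99, seed = 1) {
  stopifnot(inherits(sim, "cgi_sim"), n_clones >= 1)
  assert_fraction(conversion_rate, "conversion_rate")
  if (abs(sum(allele_weights) - 1) > 1e-8 || any(allele_weights < 0)) {
    abort("`allele_weights` must be non-negative and sum to 1.")
  }
  region <- as_region(region)[1, ]
  ref <- substr(as_genome_chr(sim$genome)[[region$chrom]],
                region$start + 1L, region$end)
  me <- sim$methylome[
    sim$methylome$chrom == region$chrom &
      sim$methylome$pos >= region$start & sim$methylome$pos < region$end - 1L, ]
  if (nrow(me) == 0L) abort("region contains no CpG dinucleotide.")
  ref_chars <- strsplit(ref, "")[[1]]
  c_idx <- which(ref_chars == "C")                       # 1-based, region-local
  cpg_local <- me$pos - region$start + 1L
  is_cpg_c <- c_idx %in% cpg_local
  meth_by_allele <- list(
    maternal = stats::setNames(me$maternal, cpg_local),
    paternal = stats::setNames(me$paternal, cpg_local)
  )
  with_seed(seed, {
    alleles <- sample(c("maternal", "paternal"), n_clones,
                      replace = TRUE, prob = allele_weights)
    clones <- vapply(seq_len(n_clones), function(i) {
      chars <- ref_chars
      meth <- meth_by_allele[[alleles[i]]]
      convertible <- !is_cpg_c | (meth[as.character(c_idx)] %in% 0)
      convert <- convertible & (runif(length(c_idx)) < conversion_rate)
      chars[c_idx[convert]] <- "T"
      paste(chars, collapse = "")
    }, character(1))
    names(clones) <- paste0("clone_", seq_len(n_clones))
    structure(list(
      clones = clones,
      truth = tibble(clone = names(clones), allele = alleles),
      reference = ref, cpg_positions = me$pos, region = region
    ), class = "clone_sim")
  })
}
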