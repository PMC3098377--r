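# CpG-island prediction: sliding-window GC / observed-expected CpG criteria.

#' GC fraction of a DNA sequence
#'
#' Fraction of non-N bases that are C or G. N bases are excluded from both
#' numerator and denominator.
#'
#' @param seq A single DNA string (A/C/G/T/N alphabet, case-insensitive).
#' @return A number in \[0, 1\].
#' @examples
#' gc_fraction("GCGC") # 1
#' gc_fraction("ATAT") # 0
#' @export
gc_fraction <- function(seq) {
  counts <- base_counts(seq)
  non_n <- counts[["len"]] - counts[["N"]]
  if (non_n == 0L) abort("sequence is all N; GC fraction undefined.")
  (counts[["C"]] + counts[["G"]]) / non_n
}

#' Observed/expected CpG ratio
#'
#' The classical CpG-island statistic: `(#CpG * L) / (#C * #G)` where L is the
#' number of non-N bases. Returns 0 when the sequence has no C or no G.
#'
#' @inheritParams gc_fraction
#' @return A non-negative ratio (1 means CpG occurs at the rate expected from
#'   base composition; promoter islands approach or exceed 1, bulk vertebrate
#'   DNA sits near 0.2 due to CpG deamination).
#' @examples
#' cpg_oe_ratio("CGCGCG") # 2
#' @export
cpg_oe_ratio <- function(seq) {
  counts <- base_counts(seq)
  non_n <- counts[["len"]] - counts[["N"]]
  if (non_n == 0L) abort("sequence is all N; O/E ratio undefined.")
  if (counts[["C"]] == 0L || counts[["G"]] == 0L) return(0)
  counts[["CG"]] * non_n / (counts[["C"]] * counts[["G"]])
}

#' @noRd
base_counts <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) abort("sequence is empty.")
  s <- Biostrings::DNAString(toupper(seq))
  lf <- Biostrings::letterFrequency(s, letters = c("C", "G", "N"))
  c(
    C = lf[["C"]], G = lf[["G"]], N = lf[["N"]],
    CG = Biostrings::countPattern("CG", s), len = length(s)
  )
}

#' Predict CpG islands by sliding-window criteria
#'
#' Scans each chromosome with a fixed-width window; windows passing all of the
#' GC, observed/expected CpG and (implicitly) length criteria are merged into
#' maximal runs, and each merged interval is trimmed until the interval itself
#' passes the thresholds. This is the classical sliding-window CpG-island
#' definition (200-bp window, GC >= 0.5, O/E >= 0.6, length >= 200 bp), with
#' every threshold exposed.
#'
#' @param genome Named character vector or `Biostrings::DNAStringSet` of
#'   chromosome sequences.
#' @param min_length Minimum reported island length in bp.
#' @param min_gc Minimum GC fraction.
#' @param min_oe Minimum observed/expected CpG ratio.
#' @param window Sliding-window width in bp.
#' @param step Window step in bp (1 = every position).
#' @return A tibble with one row per predicted island: `chrom`, `start`, `end`
#'   (0-based half-open), `length`, `gc`, `oe`, `island` (CGI_k), and an
#'   `assoc` column initialised to NA (see [classify_islands()]).
#' @seealso [classify_islands()], [island_strength()]
#' @export
detect_islands <- function(genome, min_length = 200, min_gc = 0.50,
                           min_oe = 0.60, window = 200, step = 1) {
  stopifnot(min_length >= 1, window >= 2, step >= 1)
  assert_fraction(min_gc, "min_gc")
  genome <- as_genome_chr(genome)
  out <- purrr::map2_dfr(genome, names(genome), function(seq, chrom) {
    detect_islands_chrom(seq, chrom, min_length, min_gc, min_oe, window, step)
  })
  if (nrow(out) == 0L) {
    return(tibble(
      chrom = character(), start = integer(), end = integer(),
      length = integer(), gc = double(), oe = double(),
      island = character(), assoc = character()
    ))
  }
  out <- arrange(out, .data$chrom, .data$start)
  out$island <- paste0("CGI_", seq_len(nrow(out)))
  out$assoc <- NA_character_
  out
}

#' @noRd
detect_islands_chrom <- function(seq, chrom, min_length, min_gc, min_oe,
                                 window, step) {
  empty <- tibble(
    chrom = character(), start = integer(), end = integer(),
    length = integer(), gc = double(), oe = double()
  )
  L <- nchar(seq)
  if (window > L) return(empty)
  b <- charToRaw(toupper(seq))
  is_c <- b == charToRaw("C")
  is_g <- b == charToRaw("G")
  is_n <- !(is_c | is_g | b == charToRaw("A") | b == charToRaw("T"))
  is_cg <- c(is_c[-L] & is_g[-1L], FALSE)
  cs <- list(
    C = c(0, cumsum(is_c)), G = c(0, cumsum(is_g)),
    N = c(0, cumsum(is_n)), CG = c(0, cumsum(is_cg))
  )
  win_stats <- function(s0, s1) { # 0-based half-open [s0, s1)
    nC <- cs$C[s1 + 1L] - cs$C[s0 + 1L]
    nG <- cs$G[s1 + 1L] - cs$G[s0 + 1L]
    nN <- cs$N[s1 + 1L] - cs$N[s0 + 1L]
    # CG dinucleotides fully inside the window: starts in [s0, s1 - 1)
    nCG <- cs$CG[s1] - cs$CG[s0 + 1L]
    non_n <- (s1 - s0) - nN
    gc <- ifelse(non_n > 0, (nC + nG) / non_n, 0)
    oe <- ifelse(nC * nG > 0, nCG * non_n / (nC * nG), 0)
    list(gc = gc, oe = oe, n_frac = nN / (s1 - s0))
  }
  starts <- seq.int(0L, L - window, by = step)
  st <- win_stats(starts, starts + window)
  ok <- st$n_frac <= 0.5 & st$gc >= min_gc & st$oe >= min_oe
  if (!any(ok)) return(empty)
  merged <- merge_intervals(starts[ok], starts[ok] + window)
  # trim merged spans until the interval itself satisfies the thresholds
  keep <- purrr::pmap_dfr(merged, function(start, end) {
    repeat {
      if (end - start < min_length) return(empty)
      s <- win_stats(start, end)
      if (s$gc >= min_gc && s$oe >= min_oe) break
      # drop 10 bp from whichever end leaves the better margin
      dl <- win_stats(min(start + 10L, end - 1L), end)
      dr <- win_stats(start, max(end - 10L, start + 1L))
      margin <- function(x) min(x$gc - min_gc, (x$oe - min_oe) / max(min_oe, 1e-9))
      if (margin(dl) >= margin(dr)) start <- min(start + 10L, end - 1L)
      else end <- max(end - 10L, start + 1L)
    }
    s <- win_stats(start, end)
    tibble(
      chrom = chrom, start = as.integer(start), end = as.integer(end),
      length = as.integer(end - start), gc = s$gc, oe = s$oe
    )
  })
  keep
}

#' Classify islands by gene association
#'
#' Labels each island `TSS` if it overlaps any transcription start site
#' +/- `tss_window` bp, else `TES` by the same rule at transcription end
#' sites, else `other`. TSS takes precedence over TES.
#'
#' @param islands Island tibble from [detect_islands()] (or the simulator's
#'   truth table): needs `chrom`, `start`, `end`.
#' @param genes Gene tibble with `chrom`, `start`, `end`, `strand`.
#' @param tss_window Half-window in bp around each TSS/TES.
#' @return `islands` with its `assoc` column filled with
#'   `"TSS"`, `"TES"` or `"other"`.
#' @export
classify_islands <- function(islands, genes, tss_window = 1000) {
  islands <- as_tibble(islands)
  genes <- as_tibble(genes)
  stopifnot("strand" %in% names(genes))
  tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  tes <- ifelse(genes$strand == "+", genes$end - 1L, genes$start)
  assoc <- rep("other", nrow(islands))
  for (chr in unique(islands$chrom)) {
    qi <- which(islands$chrom == chr)
    gi <- which(genes$chrom == chr)
    hit_site <- function(site) {
      overlaps_any(
        islands$start[qi], islands$end[qi],
        pmax(site[gi] - tss_window, 0L), site[gi] + tss_window + 1L
      )
    }
    at_tss <- hit_site(tss)
    at_tes <- hit_site(tes)
    assoc[qi][at_tes] <- "TES"
    assoc[qi][at_tss] <- "TSS"
  }
  islands$assoc <- assoc
  islands
}

#' Split islands into strong and weak by a length-by-O/E score
#'
#' A stand-in for the "strong versus weak CpG island" distinction: islands are
#' scored `length * oe` and split at the set median. Purely descriptive.
#'
#' @param islands Tibble from [detect_islands()].
#' @return `islands` with `score` and `strength` (`"strong"`/`"weak"`) columns.
#' @export
island_strength <- function(islands) {
  islands <- as_tibble(islands)
  islands$score <- islands$length * islands$oe
  islands$strength <- ifelse(islands$score >= stats::median(islands$score),
                             "strong", "weak")
  islands
}
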