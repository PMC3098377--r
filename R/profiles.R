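# Tag densities and meta-profiles. A tag is a single-end read 5' position +
# strand; for density purposes each tag is extended fragment_length bp
# 3'-ward of its 5' end (the sequenced fragment), and density is
# extended-fragment bp per bp (per anchor, for profiles).

# Fragment intervals (0-based half-open) for one chromosome's tags.
#' @noRd
fragment_ranges <- function(tags, chrom, fl) {
  tg <- tags[tags$chrom == chrom, , drop = FALSE]
  if (nrow(tg) == 0L) return(IRanges::IRanges())
  start0 <- ifelse(tg$strand == "+", tg$pos, tg$pos - fl + 1L)
  # truncate at the chromosome start without shifting the 3' end
  IRanges::IRanges(start = pmax(start0, 0L) + 1L, end = start0 + fl)
}

# Per-base fragment coverage as an Rle covering [0, upto) of `chrom`.
#' @noRd
fragment_coverage <- function(tags, chrom, fl, upto) {
  fr <- fragment_ranges(tags, chrom, fl)
  fr <- IRanges::restrict(fr, start = 1L, end = as.integer(upto))
  IRanges::coverage(fr, width = as.integer(upto))
}

#' Binned tag density over a region
#'
#' Each tag is extended `fragment_length` bp 3'-ward from its 5' end; each
#' bin's value is the extended-fragment bp overlapping the bin divided by
#' `bin_size` (so a bin fully covered by one fragment scores 1). Half-open
#' bins tile the region from its start; a final partial bin is kept (still
#' divided by `bin_size`).
#'
#' @param tags A [tag_collection()] (or tibble with `chrom`, `pos`,
#'   `strand`).
#' @param region `"chr:start-end"` or one-row tibble (`chrom`, `start`,
#'   `end`).
#' @param bin_size Bin width in bp (>= 1).
#' @param fragment_length Override for the collection's fragment length.
#' @return A tibble: `start`, `end` (bin bounds, 0-based half-open),
#'   `density`.
#' @export
tag_density <- function(tags, region, bin_size = 1, fragment_length = NULL) {
  stopifnot(bin_size >= 1)
  region <- as_region(region)[1, ]
  fl <- frag_len(tags, fragment_length)
  cov <- fragment_coverage(tags, region$chrom, fl, region$end)
  per_base <- as.numeric(S4Vectors::window(cov, start = region$start + 1L,
                                         end = region$end))
  bins <- seq.int(region$start, region$end - 1L, by = bin_size)
  idx <- rep(seq_along(bins), each = bin_size, length.out = length(per_base))
  dens <- as.vector(tapply(per_base, idx, sum)) / bin_size
  tibble(
    start = as.integer(bins),
    end = as.integer(pmin(bins + bin_size, region$end)),
    density = dens
  )
}

#' TSS-anchored meta-profile
#'
#' Averages per-base tag density over a window around every gene's
#' transcription start site; minus-strand windows are reversed so upstream is
#' always to the left. Genes whose window would run off the chromosome start
#' (or past `chrom_lengths` when given) are dropped and counted.
#'
#' @inheritParams tag_density
#' @param genes Tibble with `chrom`, `start`, `end`, `strand`.
#' @param half_window Half-window around the TSS in bp (default 2000, a 4-kb
#'   view).
#' @param chrom_lengths Optional named vector of chromosome lengths for
#'   right-edge checks.
#' @return A `meta_profile` tibble: `position` (bp offset from the TSS, from
#'   `-half_window` to `half_window - 1`), `density` (mean fragment-bp per bp
#'   per gene); attributes `anchor = "TSS"`, `n_anchors`, `n_dropped`.
#' @export
tss_metaprofile <- function(tags, genes, half_window = 2000,
                            fragment_length = NULL, chrom_lengths = NULL) {
  genes <- as_tibble(genes)
  if (nrow(genes) == 0L) abort("no genes supplied.")
  fl <- frag_len(tags, fragment_length)
  tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  lo <- tss - half_window
  hi <- tss + half_window # half-open
  usable <- lo >= 0
  if (!is.null(chrom_lengths)) {
    usable <- usable & hi <= chrom_lengths[genes$chrom]
  }
  if (!any(usable)) abort("no gene has a full TSS window inside the genome.")
  acc <- NULL
  for (chr in unique(genes$chrom[usable])) {
    gi <- which(usable & genes$chrom == chr)
    cov <- fragment_coverage(tags, chr, fl, max(hi[gi]))
    for (k in gi) {
      v <- as.numeric(S4Vectors::window(cov, start = lo[k] + 1L, end = hi[k]))
      if (genes$strand[k] == "-") v <- rev(v)
      acc <- if (is.null(acc)) v else acc + v
    }
  }
  n <- sum(usable)
  structure(
    tibble(position = seq.int(-half_window, half_window - 1L),
           density = acc / n),
    class = c("meta_profile", class(tibble())),
    anchor = "TSS", n_anchors = n, n_dropped = nrow(genes) - n
  )
}

#' Length-scaled CpG-island meta-profile
#'
#' Maps each island onto the unit interval (start = 0, end = 1) in
#' `n_bins_island` bins, with flanks of `flank_lengths` island-lengths on
#' each side mapped to \[-flank_lengths, 0) and (1, 1 + flank_lengths\], then
#' averages per-bin density across islands. Islands shorter than the bin
#' count contribute to the bins their bases fall in (empty bins are ignored
#' in the average).
#'
#' @inheritParams tag_density
#' @param islands Tibble with `chrom`, `start`, `end`.
#' @param n_bins_island Number of bins across the island body.
#' @param flank_lengths Flank size in units of island length (scaled-flank
#'   mode; use 0 for no flanks).
#' @return A `meta_profile` tibble: `x` (scaled coordinate, island body in
#'   \[0, 1\]), `density`; attributes `anchor = "scaled_island"`,
#'   `n_anchors`.
#' @export
scaled_island_metaprofile <- function(tags, islands, n_bins_island = 50,
                                      flank_lengths = 1,
                                      fragment_length = NULL) {
  islands <- as_tibble(islands)
  if (nrow(islands) == 0L) abort("no islands supplied.")
  fl <- frag_len(tags, fragment_length)
  n_flank <- round(n_bins_island * flank_lengths)
  n_tot <- n_bins_island + 2L * n_flank
  sums <- numeric(n_tot)
  cnts <- numeric(n_tot)
  for (chr in unique(islands$chrom)) {
    isl <- islands[islands$chrom == chr, ]
    span_end <- max(isl$end + flank_lengths * (isl$end - isl$start))
    cov <- fragment_coverage(tags, chr, fl, ceiling(span_end))
    for (k in seq_len(nrow(isl))) {
      L <- isl$end[k] - isl$start[k]
      fLen <- round(flank_lengths * L)
      s0 <- isl$start[k] - fLen
      e0 <- isl$end[k] + fLen
      v <- numeric(e0 - s0)
      inside <- max(s0, 0L):(e0 - 1L)
      v[inside - s0 + 1L] <- as.numeric(
        S4Vectors::window(cov, start = max(s0, 0L) + 1L, end = e0)
      )
      breaks <- c(
        round(seq(0, fLen, length.out = n_flank + 1L))[-(n_flank + 1L)],
        fLen + round(seq(0, L, length.out = n_bins_island + 1L))[-(n_bins_island + 1L)],
        fLen + L + round(seq(0, fLen, length.out = n_flank + 1L))
      )
      for (b in seq_len(n_tot)) {
        if (breaks[b + 1L] > breaks[b]) {
          sums[b] <- sums[b] + mean(v[(breaks[b] + 1L):breaks[b + 1L]])
          cnts[b] <- cnts[b] + 1
        }
      }
    }
  }
  # scaled x: island bins at bin centres in (0,1); flanks beyond
  centre <- function(n, a, b) a + (seq_len(n) - 0.5) / n * (b - a)
  x <- c(centre(n_flank, -flank_lengths, 0), centre(n_bins_island, 0, 1),
         centre(n_flank, 1, 1 + flank_lengths))
  structure(
    tibble(x = x, density = ifelse(cnts > 0, sums / cnts, 0)),
    class = c("meta_profile", class(tibble())),
    anchor = "scaled_island", n_anchors = nrow(islands)
  )
}
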