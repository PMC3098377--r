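# ChIP tag simulation: tags are drawn from per-base sampling weights encoding
# the binding model — the ZF-CxxC protein tracks local nonmethylated-CpG
# density (methylation blocks binding), H3K36me2 is depleted where it binds,
# H3K36me3 sits over expressed gene bodies, input and H3 are uniform.

#' Track specification for the ChIP tag simulator
#'
#' @param track One of "KDM2A", "input", "H3", "H3K36me1", "H3K36me2",
#'   "H3K36me3".
#' @param n_tags Number of tags to draw (exactly this many are emitted).
#' @param fold KDM2A island fold-enrichment: weight = 1 + `fold` x local
#'   nonmethylated-CpG density / reference island CpG density, so a typical
#'   nonmethylated island carries roughly `fold + 1` times background weight.
#' @param depletion H3K36me2 multiplicative factor inside nonmethylated
#'   islands, in (0, 1]; imprinted islands get `(depletion + 1)/2`.
#' @param body_factor Extra H3K36me2 factor over expressed gene bodies.
#' @param body_gain H3K36me3 additive gain over expressed gene bodies (on a
#'   0.1 background weight).
#' @param fragment_length Fragment extension in bp (single-end tags).
#' @param cpg_density_ref Reference CpG density (CpGs/bp) that normalises the
#'   KDM2A fold; default 0.105, the analytic density of a GC 0.65 / O-E 1.0
#'   island.
#' @return A `track_spec` list.
#' @export
track_spec <- function(track = c("KDM2A", "input", "H3", "H3K36me1",
                                 "H3K36me2", "H3K36me3"),
                       n_tags = 1e5, fold = 20, depletion = 0.3,
                       body_factor = 0.5, body_gain = 5,
                       fragment_length = 150, cpg_density_ref = 0.105) {
  track <- match.arg(track)
  if (n_tags <= 0) abort("`n_tags` must be > 0.")
  if (fold < 1) abort("`fold` must be >= 1.")
  if (depletion <= 0 || depletion > 1) abort("`depletion` must be in (0, 1].")
  structure(list(
    track = track, n_tags = as.integer(n_tags), fold = fold,
    depletion = depletion, body_factor = body_factor, body_gain = body_gain,
    fragment_length = as.integer(fragment_length),
    cpg_density_ref = cpg_density_ref
  ), class = "track_spec")
}

#' Simulate a ChIP tag track
#'
#' Draws `n_tags` single-end tags from a per-base multinomial whose weights
#' encode the track's biology (see [track_spec()]). Fragment midpoints are
#' sampled from the weights; each tag's 5' end sits `fragment_length/2`
#' upstream (on its strand) of the midpoint, strands 50/50.
#'
#' @param sim A `cgi_sim` from [simulate_genome()].
#' @param spec A [track_spec()].
#' @param seed Integer seed.
#' @return A `tag_collection`: a tibble (`chrom`, `pos` = 0-based 5' position,
#'   `strand`) with attributes `track`, `fragment_length`, `total_tags`.
#' @export
simulate_chip_tags <- function(sim, spec, seed = 1) {
  stopifnot(inherits(sim, "cgi_sim"), inherits(spec, "track_spec"))
  chrom_len <- stats::setNames(Biostrings::width(sim$genome), names(sim$genome))
  weights <- purrr::imap(as.list(chrom_len), function(L, chr) {
    track_weights(sim, spec, chr, L)
  })
  total_w <- vapply(weights, sum, double(1))
  if (sum(total_w) <= 0) abort("total sampling weight is zero for this track.")
  with_seed(seed, {
    n_per <- as.vector(stats::rmultinom(1, spec$n_tags, total_w))
    fl <- spec$fragment_length
    tags <- purrr::map_dfr(seq_along(weights), function(ci) {
      n <- n_per[ci]
      if (n == 0L) return(NULL)
      cw <- cumsum(weights[[ci]])
      mid <- findInterval(runif(n) * cw[length(cw)], cw) # 0-based midpoint
      strand <- ifelse(runif(n) < 0.5, "+", "-")
      pos <- ifelse(strand == "+", mid - floor(fl / 2), mid + floor(fl / 2))
      L <- chrom_len[ci]
      tibble(
        chrom = names(chrom_len)[ci],
        pos = as.integer(pmin(pmax(pos, 0L), L - 1L)),
        strand = strand
      )
    })
    tag_collection(tags, track = spec$track, fragment_length = fl)
  })
}

#' @noRd
track_weights <- function(sim, spec, chr, L) {
  w <- rep(1, L)
  if (spec$track %in% c("input", "H3", "H3K36me1")) return(w)
  isl <- sim$islands[sim$islands$chrom == chr, , drop = FALSE]
  genes <- sim$genes[sim$genes$chrom == chr, , drop = FALSE]
  if (spec$track == "KDM2A") {
    me <- sim$methylome[sim$methylome$chrom == chr, ]
    nonmeth <- 1 - (me$maternal + me$paternal) / 2
    dens <- local_density(me$pos[nonmeth > 0], nonmeth[nonmeth > 0], L, 200L)
    return(1 + spec$fold * dens / spec$cpg_density_ref)
  }
  if (spec$track == "H3K36me2") {
    for (k in seq_len(nrow(isl))) {
      if (isl$methylation[k] == "full") next
      f <- if (isl$methylation[k] == "imprinted_50_50") (spec$depletion + 1) / 2
           else spec$depletion
      w[(isl$start[k] + 1L):isl$end[k]] <- w[(isl$start[k] + 1L):isl$end[k]] * f
    }
    for (k in which(genes$expressed)) {
      idx <- (genes$start[k] + 1L):genes$end[k]
      w[idx] <- w[idx] * spec$body_factor
    }
    return(w)
  }
  # H3K36me3: concentrated over expressed gene bodies
  w <- rep(0.1, L)
  for (k in which(genes$expressed)) {
    idx <- (genes$start[k] + 1L):genes$end[k]
    w[idx] <- w[idx] + spec$body_gain
  }
  w
}

# Windowed sum of site weights (count of nonmethylated CpGs within +/-
# window/2 of each base), per bp.
#' @noRd
local_density <- function(pos, site_w, L, window) {
  counts <- numeric(L)
  if (length(pos) > 0) counts[pos + 1L] <- site_w
  cs <- c(0, cumsum(counts))
  half <- window %/% 2L
  i <- seq_len(L)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + half, L)
  (cs[hi + 1L] - cs[lo]) / window
}

#' Construct a tag collection
#'
#' @param tags Tibble with `chrom`, `pos` (0-based 5' position), `strand`.
#' @param track Track name.
#' @param fragment_length Fragment extension in bp applied 3'-ward of each 5'
#'   end by density computations.
#' @return The tibble with class `tag_collection` and the track metadata as
#'   attributes.
#' @export
tag_collection <- function(tags, track = "track", fragment_length = 150) {
  tags <- as_tibble(tags)
  stopifnot(all(c("chrom", "pos", "strand") %in% names(tags)),
            all(tags$strand %in% c("+", "-")))
  tags <- arrange(tags, .data$chrom, .data$pos)
  structure(tags,
    class = c("tag_collection", class(tibble())),
    track = track, fragment_length = as.integer(fragment_length),
    total_tags = nrow(tags)
  )
}

#' @noRd
frag_len <- function(tags, fragment_length = NULL) {
  fragment_length %||% attr(tags, "fragment_length") %||% 150L
}
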