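# Windowed Poisson peak calling against input, and island-occupancy
# reporting.

#' Call enriched regions against an input track
#'
#' Slides windows along each chromosome, counts IP and input fragment
#' midpoints per window, and scores each window by the Poisson upper-tail
#' probability of the IP count given a lambda equal to the library-size-scaled
#' input count, floored at the genome-wide IP background rate. Window
#' p-values are BH-corrected; windows passing the FDR and minimum fold are
#' merged when they overlap.
#'
#' @param ip,input [tag_collection()]s (input must be non-empty; there is no
#'   input-free mode).
#' @param window,step Window width and step in bp.
#' @param fdr Benjamini-Hochberg FDR threshold on window q-values.
#' @param min_fold Minimum IP/lambda fold enrichment.
#' @param chrom_lengths Optional named chromosome lengths; inferred from the
#'   tags otherwise.
#' @param fragment_length Override for fragment extension (summit coverage
#'   and midpoints).
#' @return A tibble of peaks: `chrom`, `start`, `end`, `peak` (peak_k),
#'   `ip_count`, `input_scaled`, `fold`, `p_value`, `q_value`, `summit`
#'   (0-based position of maximal IP fragment coverage).
#' @export
call_peaks <- function(ip, input, window = 500, step = 250, fdr = 0.05,
                       min_fold = 2, chrom_lengths = NULL,
                       fragment_length = NULL) {
  if (nrow(ip) == 0L || nrow(input) == 0L) {
    abort("both IP and input tracks must be non-empty.")
  }
  fl_ip <- frag_len(ip, fragment_length)
  fl_in <- frag_len(input, fragment_length)
  chroms <- union(unique(ip$chrom), unique(input$chrom))
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(chroms, function(chr) {
      max(ip$pos[ip$chrom == chr], input$pos[input$chrom == chr], 0L) +
        max(fl_ip, fl_in)
    }, double(1))
  }
  mid <- function(tags, fl) {
    ifelse(tags$strand == "+", tags$pos + fl / 2, tags$pos - fl / 2)
  }
  ip_mid <- mid(ip, fl_ip)
  in_mid <- mid(input, fl_in)
  ratio <- nrow(ip) / nrow(input)
  genome_size <- sum(chrom_lengths)
  bg <- nrow(ip) * window / genome_size

  wins <- purrr::map_dfr(chroms, function(chr) {
    L <- chrom_lengths[[chr]]
    if (L < window) return(NULL)
    starts <- seq.int(0, L - window, by = step)
    cnt <- function(mids) {
      m <- sort(mids)
      findInterval(starts + window - 0.5, m) - findInterval(starts - 0.5, m)
    }
    tibble(
      chrom = chr, start = starts, end = starts + window,
      ip_count = cnt(ip_mid[ip$chrom == chr]),
      input_count = cnt(in_mid[input$chrom == chr])
    )
  })
  wins <- wins %>%
    mutate(
      lambda = pmax(.data$input_count * ratio, bg),
      fold = .data$ip_count / .data$lambda,
      p_value = ppois(.data$ip_count - 1, .data$lambda, lower.tail = FALSE),
      q_value = p.adjust(.data$p_value, method = "BH")
    )
  hits <- filter(wins, .data$q_value <= fdr, .data$fold >= min_fold)
  if (nrow(hits) == 0L) {
    return(tibble(
      chrom = character(), start = integer(), end = integer(),
      peak = character(), ip_count = integer(), input_scaled = double(),
      fold = double(), p_value = double(), q_value = double(),
      summit = integer()
    ))
  }
  peaks <- purrr::map_dfr(unique(hits$chrom), function(chr) {
    h <- hits[hits$chrom == chr, ]
    m <- merge_intervals(h$start, h$end)
    ipm <- sort(ip_mid[ip$chrom == chr])
    inm <- sort(in_mid[input$chrom == chr])
    cov <- fragment_coverage(ip, chr, fl_ip, chrom_lengths[[chr]])
    purrr::pmap_dfr(m, function(start, end) {
      cnt_ip <- findInterval(end - 0.5, ipm) - findInterval(start - 0.5, ipm)
      cnt_in <- findInterval(end - 0.5, inm) - findInterval(start - 0.5, inm)
      lam <- max(cnt_in * ratio, bg * (end - start) / window)
      member <- h$start < end & h$end > start
      v <- as.numeric(S4Vectors::window(cov, start + 1L, end))
      tibble(
        chrom = chr, start = start, end = end,
        ip_count = cnt_ip, input_scaled = cnt_in * ratio,
        fold = cnt_ip / lam,
        p_value = min(h$p_value[member]), q_value = min(h$q_value[member]),
        summit = as.integer(start + which.max(v) - 1L)
      )
    })
  }) %>% arrange(.data$chrom, .data$start)
  peaks$peak <- paste0("peak_", seq_len(nrow(peaks)))
  select(peaks, "chrom", "start", "end", "peak", dplyr::everything())
}

#' Island occupancy by called peaks
#'
#' Counts islands touched by at least `min_overlap` bp of any peak, overall
#' and restricted to TSS-associated islands, and annotates non-island peaks
#' with the GC fraction and CpG O/E of their spans when the genome is given.
#'
#' @param peaks Peak tibble from [call_peaks()].
#' @param islands Island tibble carrying `assoc` labels (see
#'   [classify_islands()]).
#' @param genome Optional genome (for non-island peak GC / O-E annotation).
#' @param min_overlap Minimum overlap in bp (default 1).
#' @return An `occupancy_report` list: `n_islands`, `n_occupied`, `fraction`,
#'   `n_tss`, `n_tss_occupied`, `fraction_tss`, `islands` (with `occupied`
#'   column), `nonisland_peaks`.
#' @export
island_occupancy <- function(peaks, islands, genome = NULL, min_overlap = 1) {
  islands <- as_tibble(islands)
  if (nrow(islands) == 0L) abort("empty island set.")
  occupied <- rep(FALSE, nrow(islands))
  peak_in_island <- rep(FALSE, nrow(peaks))
  for (chr in unique(c(islands$chrom, peaks$chrom))) {
    qi <- which(islands$chrom == chr)
    pi <- which(peaks$chrom == chr)
    occupied[qi] <- overlaps_any(
      islands$start[qi], islands$end[qi],
      peaks$start[pi], peaks$end[pi], min_overlap
    )
    peak_in_island[pi] <- overlaps_any(
      peaks$start[pi], peaks$end[pi],
      islands$start[qi], islands$end[qi], min_overlap
    )
  }
  islands$occupied <- occupied
  non <- peaks[!peak_in_island, , drop = FALSE]
  if (!is.null(genome) && nrow(non) > 0) {
    gseq <- as_genome_chr(genome)
    spans <- vapply(seq_len(nrow(non)), function(i) {
      substr(gseq[[non$chrom[i]]], non$start[i] + 1L, non$end[i])
    }, character(1))
    non$gc <- vapply(spans, gc_fraction, double(1), USE.NAMES = FALSE)
    non$oe <- vapply(spans, cpg_oe_ratio, double(1), USE.NAMES = FALSE)
  }
  is_tss <- islands$assoc %in% "TSS"
  structure(list(
    n_islands = nrow(islands), n_occupied = sum(occupied),
    fraction = mean(occupied),
    n_tss = sum(is_tss), n_tss_occupied = sum(occupied & is_tss),
    fraction_tss = if (any(is_tss)) mean(occupied[is_tss]) else NA_real_,
    islands = islands, nonisland_peaks = non
  ), class = "occupancy_report")
}

#' @export
print.occupancy_report <- function(x, ...) {
  cat(sprintf(
    "<occupancy_report> %d/%d islands occupied (%.1f%%); TSS-associated %d/%d (%.1f%%); %d non-island peaks\n",
    x$n_occupied, x$n_islands, 100 * x$fraction,
    x$n_tss_occupied, x$n_tss, 100 * x$fraction_tss,
    nrow(x$nonisland_peaks)
  ))
  invisible(x)
}

#' @rdname island_occupancy
#' @param x An `occupancy_report`.
#' @param ... Unused.
#' @export
glance.occupancy_report <- function(x, ...) {
  tibble(
    n_islands = x$n_islands, n_occupied = x$n_occupied,
    percent_occupied = 100 * x$fraction,
    n_tss = x$n_tss, n_tss_occupied = x$n_tss_occupied,
    percent_tss_occupied = 100 * x$fraction_tss,
    n_nonisland_peaks = nrow(x$nonisland_peaks)
  )
}
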