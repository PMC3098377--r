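# Bisulfite clone methylation calling, allele classification, the allele
# enrichment test, and lollipop rendering. Top-strand chemistry only: clones
# are full-length amplicon reads compared ungapped to the reference.

#' Call per-CpG methylation from bisulfite clone sequences
#'
#' Each clone is compared position-by-position to the unconverted reference.
#' At each reference CpG cytosine: C = methylated, T = unmethylated, anything
#' else missing. Conversion efficiency is the T/(T+C) fraction at non-CpG
#' reference cytosines; clones below `min_conversion` are rejected (failed
#' conversion would masquerade as methylation), as are clones mismatching
#' the reference too often at non-cytosine positions.
#'
#' @param clones Named character vector (or `DNAStringSet`, or a `clone_sim`
#'   from [simulate_bisulfite_clones()]) of clone sequences, same length as
#'   the reference.
#' @param reference Unconverted top-strand amplicon sequence; taken from a
#'   `clone_sim` automatically.
#' @param region Optional amplicon location (`"chr:start-end"` or tibble);
#'   makes reported CpG positions genomic (0-based) instead of local.
#' @param min_conversion Conversion-efficiency QC cutoff (default 0.95).
#' @param max_mismatch Maximum mismatch fraction at non-cytosine reference
#'   positions before a clone is rejected as unaligned.
#' @return A `clone_set` list: `calls` (kept-clones x CpGs matrix, 1 =
#'   methylated, 0 = unmethylated, NA = missing), `cpg_positions`,
#'   `conversion` (per kept clone), `rejected` (tibble `clone`, `reason`,
#'   `conversion`), `region`, `reference`.
#' @export
call_methylation <- function(clones, reference = NULL, region = NULL,
                             min_conversion = 0.95, max_mismatch = 0.1) {
  if (inherits(clones, "clone_sim")) {
    reference <- reference %||% clones$reference
    region <- region %||% clones$region
    clones <- clones$clones
  }
  if (is(clones, "DNAStringSet")) {
    clones <- stats::setNames(as.character(clones), names(clones))
  }
  if (is.null(reference)) abort("`reference` is required.")
  if (is.null(names(clones))) names(clones) <- paste0("clone_", seq_along(clones))
  ref <- strsplit(toupper(reference), "")[[1]]
  L <- length(ref)
  cpg_c <- which(ref == "C" & c(ref[-1], "") == "G")       # local 1-based
  if (length(cpg_c) == 0L) abort("reference contains no CpG dinucleotide.")
  other_c <- setdiff(which(ref == "C"), cpg_c)
  non_c <- which(ref != "C")
  pos_out <- cpg_c - 1L
  if (!is.null(region)) {
    region <- as_region(region)[1, ]
    pos_out <- pos_out + region$start
  }

  calls <- list()
  conv_kept <- c()
  rejected <- tibble(clone = character(), reason = character(),
                     conversion = double())
  for (nm in names(clones)) {
    cl <- strsplit(toupper(clones[[nm]]), "")[[1]]
    if (length(cl) != L) {
      rejected <- bind_rows(rejected, tibble(
        clone = nm, reason = "length mismatch", conversion = NA_real_
      ))
      next
    }
    mm <- mean(cl[non_c] != ref[non_c])
    if (length(non_c) > 0 && mm > max_mismatch) {
      rejected <- bind_rows(rejected, tibble(
        clone = nm, reason = "alignment failure", conversion = NA_real_
      ))
      next
    }
    nT <- sum(cl[other_c] == "T")
    nC <- sum(cl[other_c] == "C")
    conv <- if (nT + nC > 0) nT / (nT + nC) else NA_real_
    if (!is.na(conv) && conv < min_conversion) {
      rejected <- bind_rows(rejected, tibble(
        clone = nm, reason = "low conversion", conversion = conv
      ))
      next
    }
    v <- rep(NA_integer_, length(cpg_c))
    v[cl[cpg_c] == "C"] <- 1L
    v[cl[cpg_c] == "T"] <- 0L
    calls[[nm]] <- v
    conv_kept[nm] <- conv
  }
  mat <- if (length(calls)) do.call(rbind, calls) else
    matrix(integer(), 0, length(cpg_c))
  colnames(mat) <- paste0("CpG_", seq_along(cpg_c))
  structure(list(
    calls = mat, cpg_positions = pos_out, conversion = conv_kept,
    rejected = rejected, region = region, reference = reference
  ), class = "clone_set")
}

#' @export
print.clone_set <- function(x, ...) {
  cat(sprintf("<clone_set> %d clones x %d CpGs (%d rejected)\n",
              nrow(x$calls), ncol(x$calls), nrow(x$rejected)))
  invisible(x)
}

#' @rdname call_methylation
#' @param x A `clone_set`.
#' @param ... Unused.
#' @export
tidy.clone_set <- function(x, ...) {
  if (nrow(x$calls) == 0L) {
    return(tibble(clone = character(), pos = integer(), call = character()))
  }
  tibble(
    clone = rep(rownames(x$calls), each = ncol(x$calls)),
    pos = rep(x$cpg_positions, nrow(x$calls)),
    call = c("unmethylated", "methylated")[t(x$calls) + 1L]
  )
}

#' Classify clones into methylated / nonmethylated alleles
#'
#' A clone is called methylated when its fraction of methylated CpGs (over
#' non-missing calls) is at least `hi`, nonmethylated when at most `lo`, and
#' partial otherwise. Partial (mosaic) clones are reported, never dropped.
#' `percent_methylated` is computed over the classified (non-partial) clones,
#' on a 0-100 scale.
#'
#' @param clone_set A `clone_set` from [call_methylation()].
#' @param hi,lo Classification thresholds (defaults 0.8 / 0.2).
#' @return One-row tibble: `n_clones`, `n_methylated`, `n_nonmethylated`,
#'   `n_partial`, `percent_methylated`.
#' @export
classify_clones <- function(clone_set, hi = 0.8, lo = 0.2) {
  m <- clone_set$calls
  if (nrow(m) == 0L) abort("no clones survive QC; nothing to classify.")
  frac <- rowMeans(m, na.rm = TRUE)
  n_meth <- sum(frac >= hi)
  n_non <- sum(frac <= lo)
  n_part <- nrow(m) - n_meth - n_non
  tibble(
    n_clones = nrow(m), n_methylated = n_meth, n_nonmethylated = n_non,
    n_partial = n_part,
    percent_methylated = 100 * n_meth / (n_meth + n_non)
  )
}

#' Allele-specific ChIP enrichment test
#'
#' Compares the nonmethylated-allele fraction among ChIP-derived clones with
#' that among input clones: reports their ratio and a two-sided Fisher exact
#' p-value on the 2x2 methylated/nonmethylated clone-count table. A ZF-CxxC
#' ChIP at an imprinted island should enrich the nonmethylated allele
#' (ratio > 1).
#'
#' @param chip,input One-row summaries from [classify_clones()].
#' @return One-row tibble: `ratio`, `p_value`, `n_chip`, `n_input`,
#'   `method`.
#' @export
allele_enrichment_test <- function(chip, input) {
  counts <- function(s) c(s$n_methylated[1], s$n_nonmethylated[1])
  a <- counts(chip)
  b <- counts(input)
  if (sum(a) == 0 || sum(b) == 0) {
    abort("both summaries need >= 1 classified clone.")
  }
  ratio <- (a[2] / sum(a)) / (b[2] / sum(b))
  ft <- fisher.test(matrix(c(a, b), nrow = 2, byrow = TRUE))
  tibble(ratio = ratio, p_value = ft$p.value,
         n_chip = sum(a), n_input = sum(b), method = "Fisher exact")
}

#' Render a clone set as a text lollipop diagram
#'
#' One line per clone: filled circles for methylated CpGs, empty circles for
#' unmethylated, a middle dot for missing calls; columns follow
#' `cpg_positions`.
#'
#' @param clone_set A `clone_set`.
#' @return Character vector of lines, named by clone.
#' @export
lollipop_render <- function(clone_set) {
  m <- clone_set$calls
  if (nrow(m) == 0L) abort("no clones to render.")
  glyph <- function(v) {
    out <- rep("·", length(v))
    out[v %in% 1L] <- "●"
    out[v %in% 0L] <- "○"
    paste(out, collapse = "")
  }
  stats::setNames(apply(m, 1, glyph), rownames(m))
}

#' @rdname lollipop_render
#' @param lines Character vector produced by `lollipop_render()`.
#' @return For `lollipop_parse()`, the clones x CpGs call matrix.
#' @export
lollipop_parse <- function(lines) {
  m <- do.call(rbind, lapply(strsplit(lines, ""), function(ch) {
    v <- rep(NA_integer_, length(ch))
    v[ch == "●"] <- 1L
    v[ch == "○"] <- 0L
    v
  }))
  rownames(m) <- names(lines)
  colnames(m) <- paste0("CpG_", seq_len(ncol(m)))
  m
}
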