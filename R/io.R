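# Plain-text interchange: BED6 (0-based half-open), FASTA, TSV.

#' Read / write BED6
#'
#' BED6 columns: chrom, start, end, name, score, strand; coordinates 0-based
#' half-open.
#'
#' @param x Tibble with at least `chrom`, `start`, `end`; `name`, `score`,
#'   `strand` are filled with ".", 0, "." when absent.
#' @param path File path.
#' @return `read_bed()` returns a tibble with the six BED columns.
#' @export
write_bed <- function(x, path) {
  x <- as_tibble(x)
  out <- tibble(
    chrom = x$chrom, start = as.integer(x$start), end = as.integer(x$end),
    name = if ("name" %in% names(x)) x$name else ".",
    score = if ("score" %in% names(x)) x$score else 0L,
    strand = if ("strand" %in% names(x)) x$strand else "."
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  readr::read_tsv(path,
    col_names = c("chrom", "start", "end", "name", "score", "strand"),
    col_types = "ciicdc"
  )
}

#' Write island predictions as BED6 + annotation TSV
#'
#' BED names are the island ids, scores `round(1000 * oe)` clamped to 1000;
#' a sibling `.tsv` carries `gc`, `oe`, `length`, `assoc`.
#'
#' @param islands Tibble from [detect_islands()].
#' @param path Output BED path; the TSV lands next to it.
#' @export
write_islands <- function(islands, path) {
  bed <- islands %>%
    mutate(name = .data$island,
           score = pmin(round(1000 * .data$oe), 1000), strand = ".")
  write_bed(bed, path)
  readr::write_tsv(
    select(islands, "island", "chrom", "start", "end", "length",
           "gc", "oe", "assoc"),
    sub("\\.bed$", ".tsv", path)
  )
  invisible(path)
}

#' Write / read a tag track as BED6
#'
#' Each tag is written as its extended-fragment interval; the 5' end is the
#' interval start for + tags and `end - 1` for - tags, so reading recovers
#' the tag exactly.
#'
#' @param tags A [tag_collection()].
#' @param path BED path.
#' @param fragment_length Used when reading, to label the collection.
#' @export
write_tags <- function(tags, path) {
  fl <- frag_len(tags)
  out <- tibble(
    chrom = tags$chrom,
    start = ifelse(tags$strand == "+", tags$pos, tags$pos - fl + 1L),
    end = ifelse(tags$strand == "+", tags$pos + fl, tags$pos + 1L),
    name = attr(tags, "track") %||% "tag", score = 0L, strand = tags$strand
  )
  write_bed(out, path)
  invisible(path)
}

#' @rdname write_tags
#' @export
read_tags <- function(path, fragment_length = 150) {
  bed <- read_bed(path)
  tag_collection(
    tibble(
      chrom = bed$chrom,
      pos = as.integer(ifelse(bed$strand == "+", bed$start, bed$end - 1L)),
      strand = bed$strand
    ),
    track = bed$name[1] %||% "tag", fragment_length = fragment_length
  )
}

#' Write a simulation to disk
#'
#' Writes `genome.fa` (60-column FASTA), `islands_truth.bed` (+ `.tsv`),
#' `genes.bed`, `methylome.tsv` (chrom, 0-based CpG C position, maternal,
#' paternal), so downstream steps can run file-based.
#'
#' @param sim A `cgi_sim`.
#' @param dir Output directory (created if needed).
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(sim$genome, fa, width = 60)
  if (nrow(sim$islands) > 0) {
    write_islands(sim$islands, file.path(dir, "islands_truth.bed"))
  }
  if (nrow(sim$genes) > 0) {
    write_bed(mutate(sim$genes, name = .data$gene, score = 0L),
              file.path(dir, "genes.bed"))
  }
  readr::write_tsv(sim$methylome, file.path(dir, "methylome.tsv"))
  invisible(dir)
}

#' Read a genome FASTA
#'
#' @param path FASTA path.
#' @return A `Biostrings::DNAStringSet`.
#' @export
read_genome <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Write clone sequences as FASTA
#'
#' @param clone_sim A `clone_sim` (or named character vector of sequences).
#' @param path FASTA path.
#' @export
write_clones <- function(clone_sim, path) {
  seqs <- if (inherits(clone_sim, "clone_sim")) clone_sim$clones else clone_sim
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = 60)
  invisible(path)
}
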