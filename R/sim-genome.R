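# Synthetic genome + methylome generator.
#
# The generated world mirrors the biology under study: a CpG-depleted,
# fully methylated background genome carrying GC/CpG-rich islands that are
# normally nonmethylated; islands can sit at gene 5' ends (TSS), 3' ends
# (TES), or away from genes (orphan); one island may be imprinted
# (maternal allele methylated, paternal not) and one fully methylated (the
# state of some islands in differentiated cells).

#' Build an island specification table
#'
#' One row per island to be placed. Defaults give 60% TSS-associated, 20%
#' TES-associated and 20% orphan islands, all nonmethylated except one
#' imprinted (50/50 by allele) and one fully methylated island.
#'
#' @param n Number of islands.
#' @param length,gc,oe Island length (bp), GC fraction and CpG O/E targets;
#'   recycled to `n`.
#' @param assoc Character vector in `{"TSS","TES","orphan"}`, recycled; NULL
#'   for the default 60/20/20 split.
#' @param methylation Character vector in `{"none","full","imprinted_50_50"}`,
#'   recycled; NULL for all-"none" plus one imprinted and one full island
#'   (when `n >= 3`).
#' @return A tibble with columns `length`, `gc`, `oe`, `assoc`, `methylation`.
#' @export
island_specs <- function(n = 20, length = 1000, gc = 0.65, oe = 1.0,
                         assoc = NULL, methylation = NULL) {
  if (n == 0) {
    return(tibble(length = integer(), gc = double(), oe = double(),
                  assoc = character(), methylation = character()))
  }
  if (is.null(assoc)) {
    n_tss <- ceiling(0.6 * n)
    n_tes <- floor(0.2 * n)
    assoc <- c(rep("TSS", n_tss), rep("TES", n_tes),
               rep("orphan", n - n_tss - n_tes))
  }
  if (is.null(methylation)) {
    methylation <- rep("none", n)
    if (n >= 3) {
      methylation[1] <- "imprinted_50_50"
      methylation[n] <- "full"
    }
  }
  tibble(
    length = as.integer(rep_len(length, n)), gc = rep_len(gc, n),
    oe = rep_len(oe, n), assoc = rep_len(assoc, n),
    methylation = rep_len(methylation, n)
  )
}

#' Simulation configuration
#'
#' Validates and bundles the parameters of the synthetic genome.
#'
#' @param genome_length Total genome size in bp (split evenly over chroms).
#' @param n_chroms Number of chromosomes.
#' @param island_specs Tibble from [island_specs()].
#' @param background_gc,background_oe GC fraction and CpG O/E of the
#'   CpG-depleted background (defaults 0.40 / 0.2, typical of bulk
#'   vertebrate DNA).
#' @param n_genes Number of genes; island-associated genes are created first,
#'   the remainder placed away from islands.
#' @param frac_expressed Fraction of genes marked expressed, independent of
#'   island association.
#' @param gene_length Gene length in bp.
#' @param mosaic_fraction Per-site probability that a background CpG is
#'   nonmethylated on both alleles (mosaic methylation of weak sites);
#'   default 0.
#' @param seed Integer seed; identical config + seed gives byte-identical
#'   output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(genome_length = 1e6, n_chroms = 1,
                       island_specs = islandscape::island_specs(),
                       background_gc = 0.40, background_oe = 0.2,
                       n_genes = 40, frac_expressed = 0.5,
                       gene_length = 5000, mosaic_fraction = 0, seed = 1) {
  assert_fraction(background_gc, "background_gc")
  assert_fraction(frac_expressed, "frac_expressed")
  assert_fraction(mosaic_fraction, "mosaic_fraction")
  if (background_oe < 0) abort("`background_oe` must be >= 0.")
  island_specs <- as_tibble(island_specs)
  if (nrow(island_specs) > 0) {
    assert_fraction(island_specs$gc, "island gc")
    if (any(island_specs$length < 200)) abort("island lengths must be >= 200 bp.")
    stopifnot(all(island_specs$assoc %in% c("TSS", "TES", "orphan")),
              all(island_specs$methylation %in% c("none", "full", "imprinted_50_50")))
  }
  structure(list(
    genome_length = genome_length, n_chroms = as.integer(n_chroms),
    island_specs = island_specs, background_gc = background_gc,
    background_oe = background_oe, n_genes = as.integer(n_genes),
    frac_expressed = frac_expressed, gene_length = as.integer(gene_length),
    mosaic_fraction = mosaic_fraction, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Generate a synthetic genome, islands, genes and methylome
#'
#' Background sequence is drawn from a Markov chain calibrated to the
#' background GC / CpG O-E; island sequences are drawn likewise against their
#' own targets (rejection-sampled to within 0.05) and spliced in at
#' non-overlapping positions. Genes are placed so their TSS (or TES) falls at
#' the midpoint of islands so labelled; remaining genes avoid all islands.
#' The methylome assigns both alleles methylated at every background CpG,
#' both nonmethylated inside `methylation = "none"` islands, maternal-only
#' methylation inside imprinted islands, and both methylated inside "full"
#' islands.
#'
#' @param config A [sim_config()].
#' @return A list of class `cgi_sim`: `genome` (`DNAStringSet`), `islands`
#'   (truth tibble with measured `gc`/`oe` and `assoc`/`methylation`),
#'   `genes` (tibble with `strand`, `expressed`), `methylome` (tibble
#'   `chrom`, `pos` of the CpG "C" on the top strand, 0-based; `maternal`,
#'   `paternal` in {0,1}), and `config`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_genome_impl(config))
}

#' @noRd
simulate_genome_impl <- function(config) {
  chrom_len <- rep(floor(config$genome_length / config$n_chroms), config$n_chroms)
  chroms <- paste0("chr", seq_len(config$n_chroms))
  specs <- config$island_specs
  edge <- 5000L

  # --- island placement: non-overlapping, buffered, bounded retries
  placed <- tibble(chrom = character(), start = integer(), end = integer())
  if (nrow(specs) > 0) {
    spec_chrom <- rep_len(seq_len(config$n_chroms), nrow(specs))
    for (k in seq_len(nrow(specs))) {
      len <- specs$length[k]
      ci <- spec_chrom[k]
      ok <- FALSE
      for (try in 1:200) {
        s <- floor(runif(1, edge, chrom_len[ci] - edge - len))
        clash <- overlaps_any(
          s, s + len,
          placed$start[placed$chrom == chroms[ci]] - 2000L,
          placed$end[placed$chrom == chroms[ci]] + 2000L
        )
        if (!any(clash)) {
          placed <- bind_rows(placed, tibble(
            chrom = chroms[ci], start = as.integer(s), end = as.integer(s + len)
          ))
          ok <- TRUE
          break
        }
      }
      if (!ok) abort(sprintf("could not place island spec %d after 200 tries.", k))
    }
  }
  islands <- bind_cols(placed, specs[, c("gc", "oe", "assoc", "methylation")])

  # --- sequence: background per chrom, islands spliced in
  seqs <- vapply(seq_along(chroms), function(ci) {
    draw_markov_seq(chrom_len[ci], config$background_gc, config$background_oe)
  }, character(1))
  names(seqs) <- chroms
  if (nrow(islands) > 0) {
    for (k in seq_len(nrow(islands))) {
      isl_seq <- draw_seq_calibrated(
        islands$end[k] - islands$start[k], islands$gc[k], islands$oe[k]
      )
      substr(seqs[[islands$chrom[k]]], islands$start[k] + 1L, islands$end[k]) <- isl_seq
    }
    islands$gc <- vapply(seq_len(nrow(islands)), function(k) {
      gc_fraction(substr(seqs[[islands$chrom[k]]], islands$start[k] + 1L, islands$end[k]))
    }, double(1))
    islands$oe <- vapply(seq_len(nrow(islands)), function(k) {
      cpg_oe_ratio(substr(seqs[[islands$chrom[k]]], islands$start[k] + 1L, islands$end[k]))
    }, double(1))
    islands$length <- islands$end - islands$start
    islands$island <- paste0("truth_", seq_len(nrow(islands)))
  } else {
    islands <- tibble(
      chrom = character(), start = integer(), end = integer(), gc = double(),
      oe = double(), assoc = character(), methylation = character(),
      length = integer(), island = character()
    )
  }

  # --- genes
  genes <- place_genes(config, islands, chroms, chrom_len, edge)

  # --- methylome: every CG dinucleotide gets an entry
  methylome <- purrr::map_dfr(chroms, function(chr) {
    pos <- Biostrings::start(
      Biostrings::matchPattern("CG", Biostrings::DNAString(seqs[[chr]]))
    ) - 1L # 0-based C position
    mat <- rep(1L, length(pos))
    pat <- rep(1L, length(pos))
    if (config$mosaic_fraction > 0) {
      mosaic <- runif(length(pos)) < config$mosaic_fraction
      mat[mosaic] <- 0L
      pat[mosaic] <- 0L
    }
    isl <- islands[islands$chrom == chr, ]
    for (k in seq_len(nrow(isl))) {
      inside <- pos >= isl$start[k] & pos < isl$end[k]
      if (isl$methylation[k] == "none") {
        mat[inside] <- 0L
        pat[inside] <- 0L
      } else if (isl$methylation[k] == "imprinted_50_50") {
        mat[inside] <- 1L
        pat[inside] <- 0L
      } else { # full
        mat[inside] <- 1L
        pat[inside] <- 1L
      }
    }
    tibble(chrom = chr, pos = pos, maternal = mat, paternal = pat)
  })

  structure(list(
    genome = Biostrings::DNAStringSet(seqs), islands = islands,
    genes = genes, methylome = methylome, config = config
  ), class = "cgi_sim")
}

#' @noRd
place_genes <- function(config, islands, chroms, chrom_len, edge) {
  glen <- config$gene_length
  rows <- list()
  gi <- 0L
  add_gene <- function(chrom, start, end, strand, assoc_island) {
    gi <<- gi + 1L
    rows[[gi]] <<- tibble(
      chrom = chrom, start = as.integer(max(start, 0L)),
      end = as.integer(min(end, chrom_len[match(chrom, chroms)])),
      strand = strand, gene = paste0("gene_", gi), assoc_island = assoc_island
    )
  }
  for (k in seq_len(nrow(islands))) {
    if (islands$assoc[k] == "orphan") next
    mid <- floor((islands$start[k] + islands$end[k]) / 2)
    strand <- sample(c("+", "-"), 1)
    if (islands$assoc[k] == "TSS") {
      if (strand == "+") add_gene(islands$chrom[k], mid, mid + glen, "+", islands$island[k])
      else add_gene(islands$chrom[k], mid - glen + 1L, mid + 1L, "-", islands$island[k])
    } else { # TES at island midpoint
      if (strand == "+") add_gene(islands$chrom[k], mid - glen + 1L, mid + 1L, "+", islands$island[k])
      else add_gene(islands$chrom[k], mid, mid + glen, "-", islands$island[k])
    }
  }
  n_extra <- max(config$n_genes - gi, 0L)
  for (j in seq_len(n_extra)) {
    for (try in 1:200) {
      ci <- sample.int(length(chroms), 1)
      s <- floor(runif(1, edge, chrom_len[ci] - edge - glen))
      # both gene ends must stay clear of every island (+/- 2 kb buffer)
      isl <- islands[islands$chrom == chroms[ci], ]
      near <- overlaps_any(
        c(s, s + glen - 1L), c(s + 1L, s + glen),
        isl$start - 2000L, isl$end + 2000L
      )
      if (!any(near)) {
        add_gene(chroms[ci], s, s + glen, sample(c("+", "-"), 1), NA_character_)
        break
      }
    }
  }
  genes <- bind_rows(rows)
  if (nrow(genes) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), gene = character(),
                  assoc_island = character(), expressed = logical()))
  }
  genes$expressed <- runif(nrow(genes)) < config$frac_expressed
  genes
}

#' @export
print.cgi_sim <- function(x, ...) {
  cat(sprintf(
    "<cgi_sim> %d chrom(s), %s bp; %d islands; %d genes; %s CpG sites\n",
    length(x$genome), format(sum(Biostrings::width(x$genome)), big.mark = ","),
    nrow(x$islands), nrow(x$genes), format(nrow(x$methylome), big.mark = ",")
  ))
  invisible(x)
}
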