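# Shared fixtures, built once per test run.

# 400-kb single-chrom world: 20 islands (12 TSS / 4 TES / 4 orphan; one
# imprinted, one fully methylated), 20 genes.
tiny_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_genome(
        sim_config(genome_length = 4e5, n_genes = 20, seed = 42)
      )
    }
    cache
  }
})

tiny_chrom_len <- function(sim = tiny_sim()) {
  stats::setNames(Biostrings::width(sim$genome), names(sim$genome))
}

# Independent character-level oracles (kept free of the package's
# Biostrings-based counting path).
oracle_gc <- function(seq) {
  ch <- strsplit(toupper(seq), "")[[1]]
  ch <- ch[ch != "N"]
  sum(ch %in% c("C", "G")) / length(ch)
}

oracle_oe <- function(seq) {
  ch <- strsplit(toupper(seq), "")[[1]]
  n_cg <- sum(ch[-length(ch)] == "C" & ch[-1] == "G")
  keep <- ch != "N"
  nc <- sum(ch == "C")
  ng <- sum(ch == "G")
  if (nc * ng == 0) return(0)
  n_cg * sum(keep) / (nc * ng)
}

# Brute-force per-base fragment coverage over [start, end) of one chrom.
oracle_coverage <- function(tags, chrom, start, end, fl) {
  v <- numeric(end - start)
  tg <- tags[tags$chrom == chrom, ]
  for (i in seq_len(nrow(tg))) {
    f0 <- if (tg$strand[i] == "+") tg$pos[i] else tg$pos[i] - fl + 1
    f1 <- f0 + fl
    lo <- max(f0, start, 0)
    hi <- min(f1, end)
    if (hi > lo) v[(lo - start + 1):(hi - start)] <- v[(lo - start + 1):(hi - start)] + 1
  }
  v
}

# Promoter amplicon inside each TSS island; body amplicon 2-2.5 kb into the
# gene, strand-aware.
promoter_body_amplicons <- function(sim) {
  genes <- dplyr::filter(sim$genes, !is.na(assoc_island))
  isl <- sim$islands[match(genes$assoc_island, sim$islands$island), ]
  mid <- as.integer((isl$start + isl$end) / 2)
  tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  body_start <- ifelse(genes$strand == "+", tss + 2000L, tss - 2500L)
  tibble::tibble(
    chrom = rep(genes$chrom, 2),
    start = c(mid - 250L, as.integer(body_start)),
    end = c(mid + 250L, as.integer(body_start + 500L)),
    gene = rep(genes$gene, 2),
    region = rep(c("promoter", "body"), each = nrow(genes))
  )
}

random_seq <- function(n, seed = 1) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = ""))
}
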