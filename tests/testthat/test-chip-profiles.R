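# Tag densities, meta-profiles, percent input, H3 normalization.

test_that("tag_density matches the single-tag closed form and strand mirror", {
  tg <- tag_collection(tibble::tibble(chrom = "chr1", pos = 500L, strand = "+"),
                       fragment_length = 150)
  d <- tag_density(tg, "chr1:0-1000", bin_size = 1)
  expect_equal(d$density, as.numeric(seq(0, 999) %in% 500:649))
  # minus-strand tag whose 5' end mirrors around the same base
  tm <- tag_collection(tibble::tibble(chrom = "chr1", pos = 500L, strand = "-"),
                       fragment_length = 150)
  dm <- tag_density(tm, "chr1:0-1000", bin_size = 1)
  expect_equal(dm$density, as.numeric(seq(0, 999) %in% 351:500))
  expect_equal(sum(dm$density), sum(d$density))
})

test_that("tag_density agrees exactly with the per-base brute-force oracle", {
  for (seed in 1:3) {
    tags <- withr::with_seed(seed, tag_collection(tibble::tibble(
      chrom = "chr1", pos = sample.int(10000, 300),
      strand = sample(c("+", "-"), 300, TRUE)
    ), fragment_length = 150))
    oracle <- oracle_coverage(tags, "chr1", 0, 10000, 150)
    d1 <- tag_density(tags, "chr1:0-10000", bin_size = 1)
    expect_equal(d1$density, oracle)
    d25 <- tag_density(tags, "chr1:0-10000", bin_size = 25)
    expect_equal(d25$density * 25, as.vector(tapply(oracle, rep(1:400, each = 25), sum)))
    # conservation: total binned bp equals total per-base bp
    expect_equal(sum(d25$density) * 25, sum(oracle))
  }
})

test_that("TSS metaprofile: n = 1 identity, uniformity, additivity over parts", {
  gene <- tibble::tibble(chrom = "chr1", start = 5000L, end = 8000L,
                         strand = "+", gene = "g1")
  tg <- tag_collection(tibble::tibble(chrom = "chr1", pos = 5100L, strand = "+"))
  prof <- tss_metaprofile(tg, gene, half_window = 500)
  dens <- tag_density(tg, "chr1:4500-5500", bin_size = 1)
  expect_equal(prof$density, dens$density)

  # evenly spaced tags give a flat central profile
  even <- tag_collection(tibble::tibble(
    chrom = "chr1", pos = seq(0L, 20000L, by = 10L), strand = "+"
  ))
  pf <- tss_metaprofile(even, gene, half_window = 1000)
  expect_lt(diff(range(pf$density)) / mean(pf$density), 0.1)

  # splitting the collection: profiles add (density is linear in tags)
  sim <- tiny_sim()
  kt <- simulate_chip_tags(sim, track_spec("KDM2A", n_tags = 20000), seed = 3)
  half1 <- tag_collection(kt[seq(1, nrow(kt), 2), ], fragment_length = 150)
  half2 <- tag_collection(kt[seq(2, nrow(kt), 2), ], fragment_length = 150)
  whole <- tss_metaprofile(kt, sim$genes, chrom_lengths = tiny_chrom_len())
  parts <- tss_metaprofile(half1, sim$genes, chrom_lengths = tiny_chrom_len())$density +
    tss_metaprofile(half2, sim$genes, chrom_lengths = tiny_chrom_len())$density
  expect_equal(whole$density, parts)
})

test_that("island gene set out-profiles non-island genes at the TSS on CxxC tags", {
  sim <- tiny_sim()
  kt <- simulate_chip_tags(sim, track_spec("KDM2A", n_tags = 1e5), seed = 4)
  isl_genes <- dplyr::filter(sim$genes, !is.na(assoc_island))
  non_genes <- dplyr::filter(sim$genes, is.na(assoc_island))
  p_isl <- tss_metaprofile(kt, isl_genes, chrom_lengths = tiny_chrom_len())
  p_non <- tss_metaprofile(kt, non_genes, chrom_lengths = tiny_chrom_len())
  centre <- abs(p_isl$position) <= 200
  expect_gt(mean(p_isl$density[centre]), 3 * mean(p_non$density[centre]))
})

test_that("scaled island metaprofile: uniform flat, enriched peak inside [0,1]", {
  sim <- tiny_sim()
  isl <- dplyr::filter(sim$islands, methylation != "full")
  even <- tag_collection(tibble::tibble(
    chrom = "chr1", pos = seq(0L, 399999L, by = 20L), strand = "+"
  ))
  pf <- scaled_island_metaprofile(even, isl)
  expect_lt(diff(range(pf$density)) / mean(pf$density), 0.15)

  kt <- simulate_chip_tags(sim, track_spec("KDM2A", n_tags = 1e5), seed = 5)
  for (cls in c("TSS", "TES", "orphan")) {
    sub <- dplyr::filter(isl, assoc == cls)
    pk <- scaled_island_metaprofile(kt, sub)
    body <- pk$x >= 0 & pk$x <= 1
    expect_gt(mean(pk$density[body]), mean(pk$density[!body]))
  }
  # reciprocal H3K36me2 dip inside the island body
  me2 <- simulate_chip_tags(sim, track_spec("H3K36me2", n_tags = 1e5), seed = 6)
  pm <- scaled_island_metaprofile(me2, isl)
  expect_true(pm$x[which.min(pm$density)] >= 0 && pm$x[which.min(pm$density)] <= 1)
  pkall <- scaled_island_metaprofile(kt, isl)
  expect_true(pkall$x[which.max(pkall$density)] >= 0 &&
                pkall$x[which.max(pkall$density)] <= 1)

  # one island, no tags: zero profile
  none <- tag_collection(tibble::tibble(chrom = "chr9", pos = 1L, strand = "+"))
  z <- scaled_island_metaprofile(none, isl[1, ])
  expect_true(all(z$density == 0))
  expect_equal(attr(z, "n_anchors"), 1)
})

test_that("percent_input identities: self = 100, empty IP = 0, duplication invariant", {
  sim <- tiny_sim()
  it <- simulate_chip_tags(sim, track_spec("input", n_tags = 20000), seed = 7)
  amps <- tibble::tibble(
    chrom = "chr1", start = c(1000L, 2e5L), end = c(1500L, 2e5L + 500L),
    gene = c("a", "b"), region = "promoter"
  )
  self <- percent_input(it, it, amps)
  expect_equal(self$percent_input, c(100, 100))
  empty <- tag_collection(tibble::tibble(chrom = character(), pos = integer(),
                                         strand = character()))
  expect_equal(percent_input(empty, it, amps)$percent_input, c(0, 0))
  kt <- simulate_chip_tags(sim, track_spec("KDM2A", n_tags = 20000), seed = 8)
  once <- percent_input(kt, it, amps)
  dup <- percent_input(
    tag_collection(dplyr::bind_rows(kt, kt), fragment_length = 150),
    tag_collection(dplyr::bind_rows(it, it), fragment_length = 150), amps
  )
  expect_equal(dup$percent_input, once$percent_input)
})

test_that("island amplicons are enriched relative to background in percent input", {
  sim <- tiny_sim()
  isl <- dplyr::filter(sim$islands, methylation == "none")[1, ]
  kt <- simulate_chip_tags(sim, track_spec("KDM2A", n_tags = 2e5, fold = 20), seed = 9)
  it <- simulate_chip_tags(sim, track_spec("input", n_tags = 2e5), seed = 10)
  amps <- tibble::tibble(
    chrom = "chr1",
    start = c(as.integer((isl$start + isl$end) / 2 - 250), 10000L),
    end = c(as.integer((isl$start + isl$end) / 2 + 250), 10500L),
    gene = c("island", "background"), region = "promoter"
  )
  tab <- percent_input(kt, it, amps)
  ratio <- tab$percent_input[1] / tab$percent_input[2]
  expect_gt(ratio, 5)   # 21x expected weight ratio, within sampling error
  expect_lt(ratio, 80)
})

test_that("h3_normalize arithmetic and scale invariance", {
  amps <- tibble::tibble(chrom = "chr1", start = c(0L, 1000L), end = c(500L, 1500L),
                         gene = c("g", "g"), region = c("promoter", "body"))
  mk <- function(p) tibble::tibble(
    chrom = amps$chrom, start = amps$start, end = amps$end, gene = amps$gene,
    region = amps$region, track = "x", percent_input = p, undefined = FALSE
  )
  same <- h3_normalize(mk(c(40, 70)), mk(c(40, 70)))
  expect_equal(same$h3_normalized, c(1, 1))
  dep <- h3_normalize(mk(c(10, 30)), mk(c(30, 30)))
  expect_equal(dep$h3_normalized[1] / dep$h3_normalized[2], 1 / 3)
  doubled <- h3_normalize(mk(2 * c(10, 30)), mk(2 * c(30, 30)))
  expect_equal(doubled$h3_normalized, dep$h3_normalized)
  # zero H3 flagged undefined
  z <- h3_normalize(mk(c(10, 30)), mk(c(0, 30)))
  expect_true(z$undefined[1])
  expect_true(is.na(z$h3_normalized[1]))
})

test_that("promoter_body_test handles the degenerate equal case and rejects depletion", {
  flat <- tibble::tibble(gene = rep(letters[1:5], each = 2),
                         region = rep(c("promoter", "body"), 5),
                         h3_normalized = 1, undefined = FALSE)
  res <- promoter_body_test(flat)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  dep <- tibble::tibble(
    gene = rep(paste0("g", 1:9), each = 2),
    region = rep(c("promoter", "body"), 9),
    h3_normalized = rep(c(0.33, 1), 9) *
      withr::with_seed(1, exp(rnorm(18, 0, 0.15)))
  )
  expect_lt(promoter_body_test(dep)$p_value, 0.01)
  expect_error(promoter_body_test(flat[1:4, ]), ">= 3 genes")
})
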