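# The synthetic world: genome composition, methylome, tag sampling weights,
# clones, sensorgrams, expression.

test_that("same config and seed give byte-identical output; empty case works", {
  cfg <- sim_config(genome_length = 5e4, island_specs = island_specs(2),
                    n_genes = 4, seed = 9)
  a <- simulate_genome(cfg)
  b <- simulate_genome(cfg)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$methylome, b$methylome)
  expect_identical(a$islands, b$islands)

  empty <- simulate_genome(sim_config(
    genome_length = 5e4, island_specs = island_specs(0), n_genes = 3, seed = 2
  ))
  expect_equal(nrow(empty$islands), 0)
  expect_true(all(empty$methylome$maternal == 1))
  expect_true(all(empty$methylome$paternal == 1))
})

test_that("island sequence composition hits its targets (counting oracle)", {
  cfg <- sim_config(
    genome_length = 1e5,
    island_specs = island_specs(1, length = 1000, gc = 0.65, oe = 1.0,
                                assoc = "orphan", methylation = "none"),
    n_genes = 0, seed = 3
  )
  sim <- simulate_genome(cfg)
  isl <- sim$islands[1, ]
  seq <- substr(as.character(sim$genome[[1]]), isl$start + 1, isl$end)
  expect_lt(abs(oracle_gc(seq) - 0.65), 0.05)
  expect_lt(abs(oracle_oe(seq) - 1.0), 0.05)
  # background composition, measured away from the island
  bg <- substr(as.character(sim$genome[[1]]), 1, isl$start - 2000)
  expect_lt(abs(oracle_gc(bg) - 0.40), 0.05)
  expect_lt(abs(oracle_oe(bg) - 0.20), 0.05)
})

test_that("methylome covers every CG dinucleotide and encodes island states", {
  sim <- tiny_sim()
  seq <- as.character(sim$genome[[1]])
  ch <- strsplit(seq, "")[[1]]
  cg_pos <- which(ch[-length(ch)] == "C" & ch[-1] == "G") - 1L # 0-based
  expect_identical(sort(sim$methylome$pos), sort(cg_pos))

  imp <- sim$islands[sim$islands$methylation == "imprinted_50_50", ][1, ]
  inside <- sim$methylome$pos >= imp$start & sim$methylome$pos < imp$end
  expect_true(all(sim$methylome$maternal[inside] == 1))
  expect_true(all(sim$methylome$paternal[inside] == 0))

  none <- sim$islands[sim$islands$methylation == "none", ][1, ]
  inside <- sim$methylome$pos >= none$start & sim$methylome$pos < none$end
  expect_true(all(sim$methylome$maternal[inside] == 0))
})

test_that("tag simulation conserves n_tags and input is uniform", {
  sim <- tiny_sim()
  it <- simulate_chip_tags(sim, track_spec("input", n_tags = 10000), seed = 5)
  expect_equal(nrow(it), 10000)
  counts <- table(cut(it$pos, seq(0, 4e5, by = 1e3)))
  gof <- suppressWarnings(chisq.test(counts))
  expect_gt(gof$p.value, 0.001)
})

test_that("methylation blocks simulated binding; fold drives island enrichment", {
  specs <- island_specs(4, assoc = "orphan", methylation = "full")
  cfg <- sim_config(genome_length = 2e5, island_specs = specs,
                    n_genes = 0, seed = 6)
  sim_full <- simulate_genome(cfg)
  kt <- simulate_chip_tags(sim_full, track_spec("KDM2A", n_tags = 10000), seed = 7)
  isl_bp <- sum(sim_full$islands$end - sim_full$islands$start)
  in_isl <- mapply(function(s, e) sum(kt$pos >= s & kt$pos < e),
                   sim_full$islands$start, sim_full$islands$end)
  dens_ratio <- (sum(in_isl) / isl_bp) / ((nrow(kt) - sum(in_isl)) / (2e5 - isl_bp))
  expect_lt(dens_ratio, 2)
  expect_gt(dens_ratio, 0.5)

  specs$methylation <- "none"
  sim_non <- simulate_genome(sim_config(genome_length = 2e5,
                                        island_specs = specs, n_genes = 0, seed = 6))
  kt2 <- simulate_chip_tags(sim_non, track_spec("KDM2A", n_tags = 1e5, fold = 20),
                            seed = 7)
  in_isl2 <- mapply(function(s, e) sum(kt2$pos >= s & kt2$pos < e),
                    sim_non$islands$start, sim_non$islands$end)
  ratio2 <- (sum(in_isl2) / isl_bp) / ((nrow(kt2) - sum(in_isl2)) / (2e5 - isl_bp))
  expect_gt(ratio2, 5)
})

test_that("per-bin KDM2A tag counts match the analytic sampling weights", {
  sim <- tiny_sim()
  spec <- track_spec("KDM2A", n_tags = 2e5)
  kt <- simulate_chip_tags(sim, spec, seed = 8)
  # rebuild the analytic per-base weight and bin both at 2 kb
  me <- sim$methylome
  nonmeth <- 1 - (me$maternal + me$paternal) / 2
  w <- numeric(4e5)
  idx <- me$pos[nonmeth > 0] + 1L
  w[idx] <- nonmeth[nonmeth > 0]
  cs <- c(0, cumsum(w))
  i <- seq_len(4e5)
  dens <- (cs[pmin(i + 100L, 4e5) + 1L] - cs[pmax(i - 100L, 1L)]) / 200
  wt <- 1 + spec$fold * dens / spec$cpg_density_ref
  bins <- cut(seq_len(4e5) - 1L, seq(0, 4e5, by = 2000), right = FALSE)
  exp_p <- tapply(wt, bins, sum) / sum(wt)
  # fragment midpoints are what the weights generate
  mid <- ifelse(kt$strand == "+", kt$pos + 75, kt$pos - 75)
  obs <- table(cut(mid, seq(0, 4e5, by = 2000), right = FALSE))
  gof <- suppressWarnings(chisq.test(obs, p = as.vector(exp_p)))
  expect_gt(gof$p.value, 0.001)
})

test_that("bisulfite clone simulation respects conversion and allele weights", {
  sim <- tiny_sim()
  none <- sim$islands[sim$islands$methylation == "none", ][1, ]
  reg <- sprintf("chr1:%d-%d", none$start, none$start + 300)
  # full conversion, nonmethylated island: no C left at CpG positions
  cs <- simulate_bisulfite_clones(sim, reg, 5, conversion_rate = 1, seed = 1)
  local_cpg <- cs$cpg_positions - none$start + 1L
  for (cl in cs$clones) {
    expect_true(all(strsplit(cl, "")[[1]][local_cpg] != "C"))
  }
  # maternal-only sampling at an imprinted island keeps every CpG methylated
  imp <- sim$islands[sim$islands$methylation == "imprinted_50_50", ][1, ]
  regi <- sprintf("chr1:%d-%d", imp$start, imp$start + 300)
  cm <- simulate_bisulfite_clones(sim, regi, 8, allele_weights = c(1, 0),
                                  conversion_rate = 1, seed = 2)
  cpg_i <- cm$cpg_positions - imp$start + 1L
  for (cl in cm$clones) {
    expect_true(all(strsplit(cl, "")[[1]][cpg_i] == "C"))
  }
  # 50/50 imprinting: methylated-origin fraction is binomial around 0.5
  cb <- simulate_bisulfite_clones(sim, regi, 1000, allele_weights = c(0.5, 0.5),
                                  conversion_rate = 0.99, seed = 3)
  expect_lt(abs(mean(cb$truth$allele == "maternal") - 0.5), 0.05)
  expect_error(
    simulate_bisulfite_clones(sim, "chr1:0-1", 2, seed = 1),
    "no CpG"
  )
})

test_that("sensorgram closed form obeys plateau, origin and half-life identities", {
  p <- kinetic_params(kon = 1e5, koff = 0.064)
  sg <- simulate_sensorgrams(p, concentrations = 1e-6, t_assoc = 600,
                             t_dissoc = 60, noise_sd = 0)
  plateau <- max(sg$response[sg$phase == "association"])
  expect_equal(plateau, 100 * 1e-6 / (1e-6 + p$kd), tolerance = 1e-6)
  expect_equal(sg$response[sg$time == 0], 0)
  # dissociation half-life
  r0 <- langmuir_response(0, 1e-6, p, "dissociation", r0 = 50)
  rh <- langmuir_response(log(2) / p$koff, 1e-6, p, "dissociation", r0 = 50)
  expect_lt(abs(rh - r0 / 2), 1e-9)
  expect_error(simulate_sensorgrams(p, 1e-6, noise_sd = -1), "noise_sd")
})

test_that("expression simulation: knockdown arithmetic, null calibration, independence", {
  genes <- tibble::tibble(gene = paste0("g", 1:1000))
  # exact knockdown arithmetic at zero noise
  ex0 <- simulate_expression(tibble::tibble(gene = "g1"), knockdown_fraction = 0.6,
                             noise_sd = 0, seed = 1)
  m <- tapply(ex0$expr[ex0$gene == "KDM2A"], ex0$condition[ex0$gene == "KDM2A"], mean)
  expect_equal(unname(m["knockdown"] / m["control"]), 0.4, tolerance = 1e-12)
  expect_error(simulate_expression(genes, knockdown_fraction = 1.5), "knockdown")
  # null: no knockdown anywhere -> ~5% of transcripts at p < 0.05
  exn <- simulate_expression(genes, knockdown_fraction = 0, seed = 4)
  v <- volcano(exn)
  expect_gt(mean(v$p_value < 0.05), 0.02)
  expect_lt(mean(v$p_value < 0.05), 0.09)
  # expression is independent of island association by construction
  ex <- simulate_expression(genes, seed = 5)
  ctl <- dplyr::filter(ex, condition == "control", gene != "KDM2A")
  mean_expr <- tapply(log2(ctl$expr), ctl$gene, mean)
  island_flag <- withr::with_seed(6, rbinom(length(mean_expr), 1, 0.5))
  expect_lt(abs(cor(mean_expr, island_flag)), 0.1)
})
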