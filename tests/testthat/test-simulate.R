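test_that("identical seeds reproduce all simulation outputs byte for byte", {
  cfg <- sim_config(n_genes = 6L, seed = 99L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- simulate_genome(cfg); r1 <- simulate_reads(cfg, s1)
  s2 <- simulate_genome(cfg); r2 <- simulate_reads(cfg, s2)
  write_simulation(s1, r1, d1)
  write_simulation(s2, r2, d2)
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7))
  }
})

test_that("artifact rate zero plants no traps; traps always defeat the filter", {
  clean <- simulate_genome(sim_config(n_genes = 10L, artifact_rate = 0,
                                      seed = 4L))
  expect_false(any(clean$truth_sites$is_artifact))

  trapped <- simulate_genome(sim_config(n_genes = 10L, artifact_rate = 1,
                                        seed = 4L))
  art <- trapped$truth_sites[trapped$truth_sites$is_artifact, ]
  expect_equal(nrow(art), 10L)
  verdict <- filter_sites(data.frame(chrom = art$chrom, strand = art$strand,
                                     position = art$position, n = 1),
                          trapped$genome)
  expect_true(all(verdict$verdicts$is_artifact))
  expect_true(all(verdict$verdicts$max_A_run >= 8))
})

test_that("the canonical signal is planted upstream of every true PAS", {
  s <- simulate_genome(sim_config(n_genes = 15L, seed = 8L))
  truth <- s$truth_sites[!s$truth_sites$is_artifact, ]
  flanks <- extract_flanks(truth[, c("chrom", "strand")] |>
                             cbind(center = truth$position), s$genome)
  dens <- signal_density(flanks)
  expect_equal(dens$n[dens$offset == -21L], nrow(truth))
  expect_true(all(grepl("AATAAA", flanks$flank, fixed = TRUE)))
})

test_that("reads concentrate exactly on the PAS when jitter is zero", {
  cfg <- sim_config(n_genes = 5L, pas_per_gene = 1L, jitter_sd = 0,
                    artifact_rate = 0, stages = "hESC",
                    replicates_per_stage = 1L, reads_per_gene = 100,
                    seed = 12L)
  sim <- simulate_genome(cfg)
  reads <- simulate_reads(cfg, sim)
  bed <- reads$samples[[1]]
  expect_equal(nrow(bed), 5L)  # one position per gene
  expect_equal(sort(bed$position),
               sort(sim$truth_sites$position))
  # conservation: per-gene counts equal the drawn depths
  expect_equal(unname(bed$count[match(sim$truth_sites$chrom, bed$chrom)]),
               unname(reads$depths[, 1]))
})

test_that("allocation follows the configured usage fractions", {
  usage <- matrix(c(0.8, 0.2), nrow = 1,
                  dimnames = list("hESC", NULL))
  cfg <- sim_config(n_genes = 1L, pas_per_gene = 2L, usage_by_stage = usage,
                    jitter_sd = 0, artifact_rate = 0, stages = "hESC",
                    replicates_per_stage = 1L, reads_per_gene = 10000,
                    seed = 31L)
  sim <- simulate_genome(cfg)
  reads <- simulate_reads(cfg, sim)
  bed <- reads$samples[[1]]
  prox_pos <- sim$truth_sites$position[sim$truth_sites$pas_index == 1L]
  frac <- bed$count[bed$position == prox_pos] / sum(bed$count)
  expect_equal(frac, 0.8, tolerance = 0.0125)  # binomial 99% interval
})

test_that("expected directions derive from true usage via the RED rule", {
  usage <- list(matrix(c(0.8, 0.2, 0.2, 0.8), nrow = 2, byrow = TRUE,
                       dimnames = list(c("hESC", "NPC"), NULL)))
  cfg <- sim_config(n_genes = 4L, pas_per_gene = 2L, usage_by_stage = usage,
                    stages = c("hESC", "NPC"), seed = 2L)
  sim <- simulate_genome(cfg)
  # by hand: DPUI = (0.2-0.8, 0.8-0.2); distal - proximal = 0.6-(-0.6) = 1.2
  expect_true(all(sim$truth_genes$dir_NPC_vs_hESC == "lengthening"))

  flat <- list(matrix(c(0.5, 0.5, 0.52, 0.48), nrow = 2, byrow = TRUE))
  cfg2 <- sim_config(n_genes = 2L, pas_per_gene = 2L, usage_by_stage = flat,
                     stages = c("hESC", "NPC"), seed = 2L)
  expect_true(all(simulate_genome(cfg2)$truth_genes$dir_NPC_vs_hESC ==
                    "unclassified"))
})

test_that("oversized structures are rejected with a sizing message", {
  expect_error(simulate_genome(sim_config(n_genes = 2L, gene_length = 500L,
                                          seed = 1L)),
               "too short")
  expect_error(sim_config(jitter_sd = -1))
  expect_error(sim_config(usage_by_stage = matrix(c(0.5, 0.6), nrow = 1),
                          stages = "hESC"), "sum to 1")
})
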