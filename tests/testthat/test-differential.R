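two_group_counts <- function(k) {
  # k: matrix PACs x 4 with columns t1,t2,c1,c2
  colnames(k) <- c("t1", "t2", "c1", "c2")
  k
}

test_that("gene retention needs two PACs with >5 reads in each group", {
  counts <- two_group_counts(rbind(c(3, 3, 3, 3), c(3, 3, 3, 3)))
  pacs <- make_pacs("g1", c(100L, 200L), counts)
  expect_equal(nrow(retain_genes(pacs, c("t1", "t2"), c("c1", "c2"))), 2L)

  # exactly 5 in one group fails the strict inequality
  counts2 <- two_group_counts(rbind(c(50, 50, 3, 3), c(3, 2, 3, 3)))
  pacs2 <- make_pacs("g1", c(100L, 200L), counts2)
  expect_equal(nrow(retain_genes(pacs2, c("t1", "t2"), c("c1", "c2"))), 0L)

  single <- make_pacs("g1", 100L, two_group_counts(rbind(c(50, 50, 50, 50))))
  expect_equal(nrow(retain_genes(single, c("t1", "t2"), c("c1", "c2"))), 0L)
})

test_that("PSU is the per-sample within-gene usage fraction", {
  counts <- two_group_counts(rbind(c(30, 25, 10, 0), c(70, 75, 90, 0)))
  pacs <- make_pacs("g1", c(100L, 200L), counts)
  psu <- compute_psu(pacs, c("t1", "t2", "c1", "c2"))
  expect_equal(psu$psu_t1, c(0.3, 0.7))
  expect_equal(psu$psu_t2, c(0.25, 0.75))
  # zero gene total in a sample -> missing, not zero
  expect_true(all(is.na(psu$psu_c2)))
  # normalization: PSU sums to 1 per gene per observed sample
  expect_equal(sum(psu$psu_t1), 1)
  expect_equal(sum(psu$psu_c1), 1)
})

test_that("Wald test matches the closed form and degenerates safely", {
  same <- wald_test(30, 100, 30, 100)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)

  w <- wald_test(70, 100, 30, 100)
  z_expected <- 0.4 / sqrt(0.7 * 0.3 / 100 + 0.3 * 0.7 / 100)
  expect_equal(w$z, z_expected)
  expect_equal(w$z, 6.1721, tolerance = 1e-4)
  expect_equal(w$p, 2 * pnorm(-z_expected))
  expect_lt(w$p, 1e-9)

  # variance floor: all reads at one PAS in both groups
  degen <- wald_test(100, 100, 100, 100)
  expect_equal(degen$z, 0)
  # zero group total -> missing
  expect_true(is.na(wald_test(0, 0, 5, 10)$p))
})

test_that("event significance requires both |DPUI| and p thresholds", {
  # construct three genes with engineered DPUI/p combinations
  counts <- two_group_counts(rbind(
    c(2080, 2080, 2000, 2000), c(1920, 1920, 2000, 2000), # dpui 0.04, tiny p
    c(7, 7, 4, 4), c(7, 7, 10, 10),                 # dpui 0.28, weak p
    c(200, 200, 500, 500), c(800, 800, 500, 500)))  # dpui -0.3, tiny p
  pacs <- make_pacs(rep(c("g1", "g2", "g3"), each = 2),
                    rep(c(100L, 300L), 3), counts)
  ev <- call_events(pacs, c("t1", "t2"), c("c1", "c2"))
  g1 <- ev[ev$gene_id == "g1", ]
  expect_true(all(abs(g1$dpui) < 0.05) && all(g1$p < 0.05))
  expect_false(any(g1$significant))
  g3 <- ev[ev$gene_id == "g3", ]
  expect_true(any(g3$dpui <= -0.3) && all(g3$p < 0.05))
  expect_true(all(g3$significant))
})

test_that("RED orients proximal/distal by the terminal-exon anchor", {
  m <- make_models(utr3 = c(500L, 1500L))
  counts <- two_group_counts(rbind(c(200, 200, 500, 500),
                                   c(800, 800, 500, 500)))
  pacs <- make_pacs("G1", c(600L, 1200L), counts)
  ev <- call_events(pacs, c("t1", "t2"), c("c1", "c2"))
  red <- call_red(ev, m)
  expect_equal(red$proximal, 600L)
  expect_equal(red$distal, 1200L)
  expect_equal(red$red, red$dpui_distal - red$dpui_proximal)
  expect_equal(red$red, 0.6, tolerance = 1e-9)
  expect_equal(red$direction, "lengthening")

  # swapped counts shorten
  pacs2 <- make_pacs("G1", c(600L, 1200L), counts[2:1, ])
  red2 <- call_red(call_events(pacs2, c("t1", "t2"), c("c1", "c2")), m)
  expect_equal(red2$red, -0.6, tolerance = 1e-9)
  expect_equal(red2$direction, "shortening")

  # a sub-threshold RED is unclassified: force |DPUI| ~ 0.015 with a
  # significant companion? then no RedCall unless one event is significant,
  # so use a large-n tiny-shift design
  counts3 <- two_group_counts(rbind(c(5150, 5150, 5000, 5000),
                                    c(4850, 4850, 5000, 5000)))
  pacs3 <- make_pacs("G1", c(600L, 1200L), counts3)
  ev3 <- call_events(pacs3, c("t1", "t2"), c("c1", "c2"), dpui_th = 0.01)
  red3 <- call_red(ev3, m)
  expect_equal(red3$direction, "unclassified")

  # minus-strand gene: proximal is the higher-coordinate PAC
  mm <- make_models(gene_id = "GM", strand = "-", utr3 = c(100L, 1100L),
                    exon2_cds = c(1100L, 1200L), intron = c(1200L, 1300L),
                    exon1_cds = c(1300L, 1400L), utr5 = c(1400L, 1500L))
  pacs4 <- make_pacs("GM", c(200L, 900L), counts, strand = "-")
  red4 <- call_red(call_events(pacs4, c("t1", "t2"), c("c1", "c2")), mm)
  expect_equal(red4$proximal, 900L)
  expect_equal(red4$distal, 200L)
})

test_that("swapping treat and ctrl negates DPUI and RED and flips direction", {
  s <- small_sim(n_genes = 20L, seed = 3L, artifact_rate = 0)
  sites <- merge_endsites(s$reads$samples)
  ps <- cluster_sites(sites)
  d <- withr::local_tempdir()
  p <- write_simulation(s$sim, NULL, d)
  m <- read_genemodels(p$gtf)
  pacs <- assign_region(ps$pacs, m)
  tr <- c("NSC_rep1", "NSC_rep2"); ct <- c("hESC_rep1", "hESC_rep2")
  fwd <- call_events(pacs, tr, ct)
  rev <- call_events(pacs, ct, tr)
  expect_equal(rev$dpui, -fwd$dpui)
  expect_equal(rev$p, fwd$p)
  red_f <- call_red(fwd, m)
  red_r <- call_red(rev, m)
  expect_equal(red_r$red, -red_f$red)
  flip <- c(lengthening = "shortening", shortening = "lengthening",
            unclassified = "unclassified")
  expect_equal(red_r$direction, unname(flip[red_f$direction]))
})

test_that("pattern classification is the four-way intersection map", {
  red1 <- data.frame(gene_id = c("a", "b", "c", "d", "e", "f"),
                     direction = c("lengthening", "lengthening", "shortening",
                                   "shortening", "lengthening", "unclassified"),
                     stringsAsFactors = FALSE)
  red2 <- data.frame(gene_id = c("a", "b", "c", "d", "g"),
                     direction = c("lengthening", "shortening", "shortening",
                                   "lengthening", "shortening"),
                     stringsAsFactors = FALSE)
  pat <- classify_patterns(red1, red2)
  got <- setNames(pat$pattern, pat$gene_id)
  expect_equal(unname(got[c("a", "b", "c", "d")]), c("1", "2", "3", "4"))
  expect_equal(unname(got[c("e", "f", "g")]), rep("none", 3))
  # partition: every gene in the universe gets exactly one label
  expect_setequal(pat$gene_id, union(red1$gene_id, red2$gene_id))
  expect_false(any(duplicated(pat$gene_id)))
})
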