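test_that("region assignment follows the gene model and precedence rules", {
  m <- make_models()
  pacs <- data.frame(chrom = "chr1", strand = "+",
                     center = c(600L, 350L, 150L, 250L, 5000L),
                     stringsAsFactors = FALSE)
  ann <- assign_region(pacs, m)
  expect_equal(ann$region, c("3UTR", "intron", "5UTR", "exon", "intergenic"))
  expect_equal(ann$gene_id[1], "G1")
  expect_true(is.na(ann$gene_id[5]))

  # overlapping genes: 3UTR of A wins over intron of B
  a <- make_models(gene_id = "A")
  b <- make_models(gene_id = "B", utr5 = c(450L, 550L), exon1_cds = c(550L, 580L),
                   intron = c(580L, 800L), exon2_cds = c(800L, 900L),
                   utr3 = c(900L, 1000L))
  both <- combine_models(a, b)
  ann2 <- assign_region(data.frame(chrom = "chr1", strand = "+", center = 600L),
                        both)
  expect_equal(ann2$region, "3UTR")
  expect_equal(ann2$gene_id, "A")
})

test_that("downstream extension captures unannotated distal 3'UTR PACs", {
  m <- make_models()  # tx ends at 699 (0-based last base)
  near <- assign_region(data.frame(chrom = "chr1", strand = "+", center = 1500L), m)
  expect_equal(near$region, "3UTR")
  expect_equal(near$gene_id, "G1")
  far <- assign_region(data.frame(chrom = "chr1", strand = "+", center = 1701L), m)
  expect_equal(far$region, "intergenic")

  # minus strand: downstream is genomically upstream
  mm <- make_models(gene_id = "GM", strand = "-", utr3 = c(50L, 500L),
                    exon2_cds = c(500L, 600L), intron = c(600L, 700L),
                    exon1_cds = c(700L, 800L), utr5 = c(800L, 900L))
  down <- assign_region(data.frame(chrom = "chr1", strand = "-", center = 30L), mm)
  expect_equal(down$region, "3UTR")
})

test_that("strand-mismatched sites are never assigned", {
  m <- make_models()
  ann <- assign_region(data.frame(chrom = "chr1", strand = "-", center = 600L), m)
  expect_equal(ann$region, "intergenic")
})

test_that("mirror test: reflecting genome and annotation preserves labels", {
  L <- 2000L
  m_plus <- make_models()
  centers <- c(600L, 350L, 150L, 250L)
  ann_plus <- assign_region(data.frame(chrom = "chr1", strand = "+",
                                       center = centers), m_plus)
  # mirrored coordinates: x -> L - 1 - x, intervals [s,e) -> [L-e, L-s)
  m_minus <- make_models(strand = "-",
                         utr3 = c(L - 700L, L - 500L),
                         exon2_cds = c(L - 500L, L - 400L),
                         intron = c(L - 400L, L - 300L),
                         exon1_cds = c(L - 300L, L - 200L),
                         utr5 = c(L - 200L, L - 100L))
  ann_minus <- assign_region(data.frame(chrom = "chr1", strand = "-",
                                        center = L - 1L - centers), m_minus)
  expect_equal(ann_minus$region, ann_plus$region)
})

test_that("reference matching classifies exact, matched and novel sites", {
  refs <- data.frame(chrom = "chr1", strand = "+", position = c(100L, 500L),
                     stringsAsFactors = FALSE)
  pacs <- data.frame(chrom = "chr1", strand = "+",
                     center = c(100L, 110L, 530L), stringsAsFactors = FALSE)
  mt <- match_reference(pacs, refs, match_window = 24L)
  expect_equal(mt$status, c("exact_match", "matched", "novel"))
  expect_equal(mt$ref_distance, c(0, -10, -30))

  # minus strand flips the sign convention (downstream = lower coordinate)
  mneg <- match_reference(data.frame(chrom = "chr1", strand = "-",
                                     center = 110L),
                          data.frame(chrom = "chr1", strand = "-",
                                     position = 100L))
  expect_equal(mneg$ref_distance, 10)
  expect_equal(mneg$status, "matched")

  none <- match_reference(pacs, refs[0, ])
  expect_true(all(none$status == "novel"))
  expect_true(all(!is.finite(none$ref_distance)))
})

test_that("matched fraction tracks the configured reference coverage", {
  s <- small_sim(n_genes = 40L, seed = 13L, jitter_sd = 0, artifact_rate = 0)
  sites <- merge_endsites(s$reads$samples)
  ps <- cluster_sites(sites)
  mt <- match_reference(ps$pacs, s$sim$ref_pas)
  frac <- mean(mt$status != "novel")
  in_ref <- mean(s$sim$truth_sites$in_reference)
  expect_equal(frac, in_ref, tolerance = 0.15)
  # with zero jitter every reference hit is exact
  expect_true(all(mt$status[mt$status != "novel"] == "exact_match"))
})
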