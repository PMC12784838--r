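test_that("nucleotide profile is a one-hot matrix for a single PAS", {
  set.seed(17)
  seq <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  genome <- c(chr1 = seq)
  pac <- data.frame(chrom = "chr1", strand = "+", center = 150L)
  prof <- nt_profile(pac, genome, halfwidth = 100L)
  expect_equal(nrow(prof), 201L)
  bases <- strsplit(substr(seq, 51, 251), "")[[1]]
  onehot <- vapply(seq_len(201), function(i) {
    prof[i, bases[i]] == 1 && sum(prof[i, c("A", "C", "G", "T")]) == 1
  }, TRUE)
  expect_true(all(onehot))
})

test_that("profile frequencies sum to one at every covered offset", {
  s <- small_sim(n_genes = 10L, seed = 23L)
  sites <- merge_endsites(s$reads$samples)
  ps <- cluster_sites(sites)
  prof <- nt_profile(ps$pacs, s$sim$genome, halfwidth = 50L)
  sums <- rowSums(prof[, c("A", "C", "G", "T")])
  expect_true(all(abs(sums[prof$n > 0] - 1) < 1e-9))
})

test_that("flank extraction is strand-correct (mirror test)", {
  set.seed(19)
  fwd <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
  pac_p <- data.frame(chrom = "c", strand = "+", center = 200L)
  pac_m <- data.frame(chrom = "c", strand = "-", center = 400L - 1L - 200L)
  fl_p <- extract_flanks(pac_p, c(c = fwd))
  fl_m <- extract_flanks(pac_m, c(c = rc))
  expect_equal(fl_p$flank, fl_m$flank)
  prof_p <- nt_profile(pac_p, c(c = fwd), halfwidth = 30L)
  prof_m <- nt_profile(pac_m, c(c = rc), halfwidth = 30L)
  expect_equal(prof_p, prof_m)
})

test_that("signal density counts every occurrence at its upstream offset", {
  flank <- paste0(strrep("C", 29), "AATAAA", strrep("C", 15))  # starts at -21
  flanks <- structure(data.frame(chrom = "c", strand = "+", center = 100L,
                                 flank = flank, clipped = FALSE),
                      upstream = 50L, class = c("flank_set", "data.frame"))
  dens <- signal_density(flanks)
  expect_equal(sum(dens$n), 1L)
  expect_equal(dens$offset[dens$n == 1L], -21L)

  none <- flanks
  none$flank <- strrep("C", 50)
  expect_equal(sum(signal_density(none)$n), 0L)

  # overlapping occurrences are all counted
  multi <- flanks
  multi$flank <- paste0(strrep("C", 20), "AATAAAATAAA", strrep("C", 19))
  dm <- signal_density(multi)
  expect_equal(sum(dm$n), 2L)
})

test_that("planted AATAAA is recovered as the top enriched k-mer", {
  s <- small_sim(n_genes = 25L, seed = 29L, artifact_rate = 0)
  sites <- merge_endsites(s$reads$samples)
  ps <- cluster_sites(sites)
  genome <- s$sim$genome
  flanks <- extract_flanks(ps$pacs, genome)
  rep <- kmer_enrichment(flanks, seed = 7)
  expect_equal(rep$kmer[1], "AATAAA")
  expect_equal(rep$fg_frac[rep$kmer == "AATAAA"], 1)
  # a k-mer absent from every flank has zero occurrence (no report row)
  if (!any(grepl("GGGGGG", flanks$flank, fixed = TRUE))) {
    expect_false("GGGGGG" %in% rep$kmer)
  }
  # every reported k-mer is genuinely contained in at least one flank
  expect_true(all(vapply(rep$kmer[1:10], function(k)
    any(grepl(k, flanks$flank, fixed = TRUE)), TRUE)))

  dens <- signal_density(flanks)
  mass <- sum(dens$n[dens$offset >= -30 & dens$offset <= -20]) / sum(dens$n)
  expect_gt(mass, 0.95)
})

test_that("k-mer enrichment is seed-deterministic and calibrated under the null", {
  set.seed(37)
  flanks <- structure(data.frame(chrom = "c", strand = "+",
                                 center = seq_len(60),
                                 flank = random_dna(60, 50), clipped = FALSE),
                      upstream = 50L, class = c("flank_set", "data.frame"))
  r1 <- kmer_enrichment(flanks, seed = 5)
  r2 <- kmer_enrichment(flanks, seed = 5)
  expect_identical(r1, r2)
  # random foreground vs its own shuffled background: nothing survives BH
  expect_lte(mean(r1$q < 0.05), 0.01)
})
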