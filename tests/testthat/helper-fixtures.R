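# In-code fixtures: tiny genomes, site tables and gene models built at test
# time; nothing is read from disk except through the package's own writers.

make_sites <- function(position, count, chrom = "chr1", strand = "+",
                       sample = "s1") {
  df <- data.frame(chrom = chrom, strand = strand, position = as.integer(position),
                   stringsAsFactors = FALSE)
  df[[sample]] <- count
  df
}

# A single-gene gene_models object with explicit region intervals
# (0-based half-open, transcription order implied by strand).
make_models <- function(gene_id = "G1", chrom = "chr1", strand = "+",
                        utr5 = c(100L, 200L), exon1_cds = c(200L, 300L),
                        intron = c(300L, 400L), exon2_cds = c(400L, 500L),
                        utr3 = c(500L, 700L), coding = TRUE) {
  if (strand == "+") {
    anchor <- utr3[1L] - 1L         # 3' end of last CDS-bearing exon
    tx_end3 <- utr3[2L] - 1L
    start <- utr5[1L]; end <- utr3[2L]
  } else {
    anchor <- utr3[2L]
    tx_end3 <- utr3[1L]
    start <- utr3[1L]; end <- utr5[2L]
  }
  iv <- rbind(
    data.frame(region = "5UTR", start = utr5[1L], end = utr5[2L]),
    data.frame(region = "exon", start = exon1_cds[1L], end = exon1_cds[2L]),
    data.frame(region = "intron", start = intron[1L], end = intron[2L]),
    data.frame(region = "exon", start = exon2_cds[1L], end = exon2_cds[2L]),
    data.frame(region = "3UTR", start = utr3[1L], end = utr3[2L]))
  structure(list(
    genes = data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                       start = start, end = end, tx_end3 = tx_end3,
                       anchor = if (coding) anchor else NA_integer_,
                       coding = coding, stringsAsFactors = FALSE),
    intervals = data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                           iv, stringsAsFactors = FALSE)),
    class = "gene_models")
}

combine_models <- function(...) {
  ms <- list(...)
  structure(list(genes = do.call(rbind, lapply(ms, `[[`, "genes")),
                 intervals = do.call(rbind, lapply(ms, `[[`, "intervals"))),
            class = "gene_models")
}

# two-group PAC table for differential tests: counts is a matrix with one row
# per PAC and named sample columns
make_pacs <- function(gene_id, center, counts, chrom = "chr1", strand = "+",
                      region = "3UTR") {
  df <- data.frame(pac_id = sprintf("PAC%05d", seq_along(center)),
                   chrom = chrom, strand = strand,
                   center = as.integer(center), gene_id = gene_id,
                   region = region, stringsAsFactors = FALSE)
  cbind(df, as.data.frame(counts))
}

small_sim <- function(n_genes = 12L, seed = 42L, ...) {
  cfg <- sim_config(n_genes = n_genes, seed = seed, ...)
  sim <- simulate_genome(cfg)
  reads <- simulate_reads(cfg, sim)
  list(cfg = cfg, sim = sim, reads = reads)
}
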