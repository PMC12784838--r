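# Genomic annotation of PACs: gene/region assignment by center PAS, and
# known/novel classification against a reference poly(A) site table.

REGION_PRECEDENCE <- c("3UTR" = 1L, "exon" = 2L, "intron" = 3L, "5UTR" = 4L)

#' Assign each PAC to a gene and genomic region
#'
#' The region is determined by the center PAS position against the
#' representative gene model, with precedence 3UTR > exon/CDS > intron > 5UTR
#' when annotations overlap (polyadenylation evidence most plausibly
#' terminates a 3' UTR). A center within `extension` nt downstream of an
#' annotated transcript end (in transcription direction, same strand) is
#' labelled 3UTR (extended). Everything else is intergenic; intergenic PACs
#' are retained but carry no gene id.
#'
#' @param pacs PAC data.frame (needs `chrom`, `strand`, `center`).
#' @param models A `gene_models` object from [read_genemodels()].
#' @param extension Downstream extension in nt for unannotated distal 3'UTR
#'   PACs (default 1000).
#' @return `pacs` with `gene_id` (NA for intergenic) and `region` (one of
#'   3UTR, exon, intron, 5UTR, intergenic) columns.
#' @export
assign_region <- function(pacs, models, extension = 1000L) {
  iv <- models$intervals
  gn <- models$genes
  # downstream extension windows, one per gene, lowest precedence of 3UTR hits
  ext <- data.frame(gene_id = gn$gene_id, chrom = gn$chrom, strand = gn$strand,
                    region = "3UTR",
                    start = ifelse(gn$strand == "+", gn$tx_end3 + 1L,
                                   pmax(gn$tx_end3 - extension, 0L)),
                    end = ifelse(gn$strand == "+", gn$tx_end3 + 1L + extension,
                                 gn$tx_end3), stringsAsFactors = FALSE)
  ext <- ext[ext$end > ext$start, , drop = FALSE]
  iv_all <- rbind(cbind(iv, extended = FALSE),
                  cbind(ext, extended = TRUE))
  q <- GenomicRanges::GRanges(pacs$chrom,
                              IRanges::IRanges(pacs$center + 1L, width = 1L),
                              strand = pacs$strand)
  s <- GenomicRanges::GRanges(iv_all$chrom,
                              IRanges::IRanges(iv_all$start + 1L, iv_all$end),
                              strand = iv_all$strand)
  hits <- GenomicRanges::findOverlaps(q, s)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  gene_id <- rep(NA_character_, nrow(pacs))
  region <- rep("intergenic", nrow(pacs))
  if (length(qh)) {
    cand <- data.frame(q = qh,
                       prec = REGION_PRECEDENCE[iv_all$region[sh]],
                       ext = iv_all$extended[sh],
                       gene = iv_all$gene_id[sh],
                       reg = iv_all$region[sh], stringsAsFactors = FALSE)
    # annotated intervals beat extension windows; then region precedence;
    # then gene id for determinism
    cand <- cand[order(cand$q, cand$ext, cand$prec, cand$gene), , drop = FALSE]
    cand <- cand[!duplicated(cand$q), , drop = FALSE]
    gene_id[cand$q] <- cand$gene
    region[cand$q] <- cand$reg
  }
  pacs$gene_id <- gene_id
  pacs$region <- region
  pacs
}

#' Classify PACs as known or novel against a reference PAS table
#'
#' Computes the signed distance from each center PAS to the closest
#' same-strand reference site (positive = reference lies downstream in
#' transcription direction) and classifies: `exact_match` (distance 0),
#' `matched` (|distance| <= `match_window`), otherwise `novel`.
#'
#' @param pacs PAC data.frame with `chrom`, `strand`, `center`.
#' @param refs Reference PAS data.frame from [read_refpas()].
#' @param match_window Matching window in nt (default 24, the clustering
#'   scale).
#' @return `pacs` with `ref_distance` (signed; Inf when no same-strand
#'   reference exists) and `status` columns.
#' @export
match_reference <- function(pacs, refs, match_window = 24L) {
  n <- nrow(pacs)
  dist <- rep(Inf, n)
  if (nrow(refs) > 0L && n > 0L) {
    pk <- paste(pacs$chrom, pacs$strand, sep = "\r")
    rk <- paste(refs$chrom, refs$strand, sep = "\r")
    for (g in intersect(unique(pk), unique(rk))) {
      qi <- which(pk == g)
      rp <- sort(refs$position[rk == g])
      ctr <- pacs$center[qi]
      lo <- findInterval(ctr, rp)
      d_lo <- ifelse(lo >= 1L, ctr - rp[pmax(lo, 1L)], Inf)
      d_hi <- ifelse(lo < length(rp), rp[pmin(lo + 1L, length(rp))] - ctr, Inf)
      nearest <- ifelse(d_lo <= d_hi, -d_lo, d_hi)  # genomic signed distance
      sign <- ifelse(pacs$strand[qi] == "+", 1, -1)
      dist[qi] <- nearest * sign  # downstream in transcription = positive
    }
  }
  pacs$ref_distance <- dist
  pacs$status <- ifelse(!is.finite(dist) | abs(dist) > match_window, "novel",
                        ifelse(dist == 0, "exact_match", "matched"))
  pacs
}

#' Histogram of center-to-reference distances
#'
#' @param pacs Output of [match_reference()].
#' @param breaks Bin width in nt (default 1) over finite distances.
#' @return data.frame `distance`, `n` (one row per observed distance bin).
#' @export
ref_distance_hist <- function(pacs, breaks = 1L) {
  d <- pacs$ref_distance[is.finite(pacs$ref_distance)]
  if (length(d) == 0L) return(data.frame(distance = integer(), n = integer()))
  b <- breaks * floor(d / breaks)
  tb <- table(b)
  data.frame(distance = as.integer(names(tb)), n = as.integer(tb))
}
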