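# Internal coordinate convention: all positions are 0-based. An end-site
# `position` is the genomic coordinate of the transcriptionally last base of
# the read (for minus-strand records this is the genomic 5'-most base, i.e.
# the BED start). Intervals are 0-based half-open [start, end). GTF I/O
# converts to/from 1-based inclusive exactly once, at the file boundary.

STRANDS <- c("+", "-")

#' Read aligned-read 3' end sites from a BED6 file
#'
#' Each BED record encodes one observed read 3'-end position: the BED start
#' field is the 0-based coordinate of the transcriptionally last base, the
#' score field its read count. Records sharing (chrom, strand, position) are
#' merged by summing counts.
#'
#' @param path Path to a BED6 file (tab-separated; columns chrom, start, end,
#'   name, score, strand).
#' @param sample_id Sample label attached to the result (attribute
#'   `sample_id`).
#' @return A data.frame with columns `chrom`, `strand`, `position` (0-based
#'   integer) and `count` (integer), sorted by chrom, strand, position.
#' @export
read_endsites <- function(path, sample_id = "sample") {
  df <- read_bed6(path, need_score = TRUE)
  if (nrow(df) == 0L) {
    out <- data.frame(chrom = character(), strand = character(),
                      position = integer(), count = integer(),
                      stringsAsFactors = FALSE)
    attr(out, "sample_id") <- sample_id
    return(out)
  }
  key <- paste(df$chrom, df$strand, df$start, sep = "\r")
  cnt <- rowsum(df$score, key)
  first <- !duplicated(key)
  out <- data.frame(chrom = df$chrom[first], strand = df$strand[first],
                    position = df$start[first],
                    count = as.integer(cnt[match(key[first], rownames(cnt)), 1L]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$strand, out$position), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "sample_id") <- sample_id
  out
}

#' Write end sites to a BED6 file
#'
#' Inverse of [read_endsites()]: one line per site, score = count, name =
#' sample id. Output is sorted and deterministic.
#'
#' @param sites data.frame with `chrom`, `strand`, `position`, `count`.
#' @param path Output path.
#' @param sample_id Name field written for every record.
#' @return `path`, invisibly.
#' @export
write_endsites <- function(sites, path, sample_id = attr(sites, "sample_id")) {
  if (is.null(sample_id)) sample_id <- "sample"
  sites <- sites[order(sites$chrom, sites$strand, sites$position), , drop = FALSE]
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                   sites$chrom, sites$position, sites$position + 1L,
                   sample_id, sites$count, sites$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read a reference poly(A) site table (BED6)
#'
#' Positions follow the same convention as end sites (BED start = 0-based site
#' coordinate). Duplicate (chrom, strand, position) entries are collapsed.
#'
#' @param path Path to a BED6 file.
#' @return data.frame with columns `chrom`, `strand`, `position`, sorted.
#' @export
read_refpas <- function(path) {
  df <- read_bed6(path, need_score = FALSE)
  out <- unique(data.frame(chrom = df$chrom, strand = df$strand,
                           position = df$start, stringsAsFactors = FALSE))
  out <- out[order(out$chrom, out$strand, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a reference poly(A) site table (BED6)
#' @param refs data.frame with `chrom`, `strand`, `position`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_refpas <- function(refs, path) {
  refs <- refs[order(refs$chrom, refs$strand, refs$position), , drop = FALSE]
  lines <- sprintf("%s\t%d\t%d\tPAS\t0\t%s",
                   refs$chrom, refs$position, refs$position + 1L, refs$strand)
  writeLines(lines, path)
  invisible(path)
}

# Shared strict BED6 reader with line-numbered diagnostics.
read_bed6 <- function(path, need_score = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      strand = character(), score = integer(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6L)) {
    bad <- lineno[which(nf < 6L)[1L]]
    stop(sprintf("malformed BED line %d in %s: expected >= 6 fields", bad, path),
         call. = FALSE)
  }
  m <- matrix(unlist(lapply(fields, `[`, 1:6)), ncol = 6L, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 2L]))
  end <- suppressWarnings(as.integer(m[, 3L]))
  score <- suppressWarnings(as.numeric(m[, 5L]))
  strand <- m[, 6L]
  bad <- which(is.na(start) | is.na(end) | start < 0L | end <= start |
                 !(strand %in% STRANDS) | (need_score & is.na(score)))
  if (length(bad)) {
    stop(sprintf("malformed BED line %d in %s", lineno[bad[1L]], path),
         call. = FALSE)
  }
  if (need_score && any(score < 0)) {
    bad <- lineno[which(score < 0)[1L]]
    stop(sprintf("negative count on BED line %d in %s", bad, path), call. = FALSE)
  }
  data.frame(chrom = m[, 1L], start = start, strand = strand,
             score = if (need_score) as.integer(round(score)) else 0L,
             stringsAsFactors = FALSE)
}

#' Combine per-sample end-site tables into one multi-sample table
#'
#' @param site_list Named list of per-sample end-site data.frames (as returned
#'   by [read_endsites()]); names are sample ids.
#' @return data.frame with `chrom`, `strand`, `position` and one integer count
#'   column per sample (absent positions filled with 0), sorted.
#' @export
merge_endsites <- function(site_list) {
  stopifnot(is.list(site_list), length(site_list) > 0L,
            !is.null(names(site_list)), all(nzchar(names(site_list))))
  keys <- lapply(site_list, function(d) paste(d$chrom, d$strand, d$position, sep = "\r"))
  all_keys <- sort(unique(unlist(keys)))
  parts <- strsplit(all_keys, "\r", fixed = TRUE)
  out <- data.frame(chrom = vapply(parts, `[`, "", 1L),
                    strand = vapply(parts, `[`, "", 2L),
                    position = as.integer(vapply(parts, `[`, "", 3L)),
                    stringsAsFactors = FALSE)
  for (s in names(site_list)) {
    v <- integer(length(all_keys))
    idx <- match(keys[[s]], all_keys)
    v[idx] <- site_list[[s]]$count
    out[[s]] <- v
  }
  out <- out[order(out$chrom, out$strand, out$position), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "samples") <- names(site_list)
  out
}

#' Read gene models from a GTF file
#'
#' One representative transcript is chosen per gene: the one with the 3'-most
#' annotated end in transcription order (ties broken by transcript length,
#' then id). Introns are derived as gaps between consecutive exons. Region
#' intervals (5UTR / exon / intron / 3UTR) are taken from
#' five_prime_utr / CDS / three_prime_utr features where present; genes
#' without CDS keep plain exon/intron labels and are flagged non-coding.
#'
#' @param path Path to a GTF file (1-based inclusive coordinates).
#' @return An object of class `gene_models`: a list with `genes` (one row per
#'   gene: gene_id, chrom, strand, start, end, tx_end3 = 0-based position of
#'   the annotated transcriptional last base, anchor = 0-based position of the
#'   3' end of the last CDS-bearing exon in transcription order (NA for
#'   non-coding), coding flag) and `intervals` (gene_id, chrom, strand,
#'   region in 5UTR/exon/intron/3UTR, start, end; 0-based half-open).
#' @export
read_genemodels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "gtf")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,  # -> 0-based half-open
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   type = as.character(gr$type),
                   gene_id = as.character(gr$gene_id),
                   tx_id = if (!is.null(gr$transcript_id))
                     as.character(gr$transcript_id) else NA_character_,
                   stringsAsFactors = FALSE)
  ex <- df[df$type == "exon" & !is.na(df$tx_id), , drop = FALSE]
  if (nrow(ex) == 0L) stop("no exon features in GTF: ", path, call. = FALSE)

  # Pick the representative transcript per gene: 3'-most end, then longest.
  txs <- ex
  txs$tx_start <- stats::ave(txs$start, txs$tx_id, FUN = min)
  txs$tx_end <- stats::ave(txs$end, txs$tx_id, FUN = max)
  tx1 <- txs[!duplicated(txs$tx_id), c("gene_id", "tx_id", "chrom", "strand",
                                       "tx_start", "tx_end"), drop = FALSE]
  tx1$end3 <- ifelse(tx1$strand == "+", tx1$tx_end, -tx1$tx_start)
  tx1$len <- tx1$tx_end - tx1$tx_start
  tx1 <- tx1[order(tx1$gene_id, -tx1$end3, -tx1$len, tx1$tx_id), , drop = FALSE]
  rep_tx <- tx1[!duplicated(tx1$gene_id), , drop = FALSE]

  genes <- data.frame(gene_id = rep_tx$gene_id, chrom = rep_tx$chrom,
                      strand = rep_tx$strand, start = rep_tx$tx_start,
                      end = rep_tx$tx_end,
                      tx_end3 = ifelse(rep_tx$strand == "+",
                                       rep_tx$tx_end - 1L, rep_tx$tx_start),
                      stringsAsFactors = FALSE)

  iv_list <- vector("list", nrow(genes))
  anchor <- rep(NA_integer_, nrow(genes))
  coding <- logical(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    tid <- rep_tx$tx_id[i]
    fx <- df[!is.na(df$tx_id) & df$tx_id == tid, , drop = FALSE]
    exi <- fx[fx$type == "exon", , drop = FALSE]
    exi <- exi[order(exi$start), , drop = FALSE]
    cds <- fx[fx$type == "CDS", , drop = FALSE]
    coding[i] <- nrow(cds) > 0L
    utr5 <- fx[fx$type %in% c("five_prime_utr", "5UTR"), , drop = FALSE]
    utr3 <- fx[fx$type %in% c("three_prime_utr", "3UTR"), , drop = FALSE]

    iv <- NULL
    if (coding[i]) {
      add <- function(d, lab) if (nrow(d)) data.frame(
        region = lab, start = d$start, end = d$end, stringsAsFactors = FALSE)
      iv <- rbind(add(utr5, "5UTR"), add(cds, "exon"), add(utr3, "3UTR"))
      # exon sequence not covered by CDS/UTR features (e.g. stop codon) -> exon
      covered <- iv
      for (j in seq_len(nrow(exi))) {
        s <- exi$start[j]; e <- exi$end[j]
        ov <- covered[covered$end > s & covered$start < e, , drop = FALSE]
        if (nrow(ov) == 0L) {
          iv <- rbind(iv, data.frame(region = "exon", start = s, end = e,
                                     stringsAsFactors = FALSE))
        } else {
          cuts <- sort(unique(c(s, e, pmax(pmin(c(ov$start, ov$end), e), s))))
          for (k in seq_len(length(cuts) - 1L)) {
            cs <- cuts[k]; ce <- cuts[k + 1L]
            if (!any(ov$start <= cs & ov$end >= ce)) {
              iv <- rbind(iv, data.frame(region = "exon", start = cs, end = ce,
                                         stringsAsFactors = FALSE))
            }
          }
        }
      }
      last_cds <- if (g$strand == "+") max(cds$end) - 1L else min(cds$start)
      # anchor: 3' end (transcription order) of the last CDS-bearing exon
      host <- exi[exi$start <= last_cds & exi$end > last_cds, , drop = FALSE]
      anchor[i] <- if (nrow(host)) {
        if (g$strand == "+") host$end[1L] - 1L else host$start[1L]
      } else last_cds
    } else {
      iv <- data.frame(region = "exon", start = exi$start, end = exi$end,
                       stringsAsFactors = FALSE)
    }
    if (nrow(exi) > 1L) {
      iv <- rbind(iv, data.frame(region = "intron",
                                 start = exi$end[-nrow(exi)],
                                 end = exi$start[-1L], stringsAsFactors = FALSE))
    }
    iv <- iv[iv$end > iv$start, , drop = FALSE]
    iv <- iv[order(iv$start, iv$end), , drop = FALSE]
    iv_list[[i]] <- data.frame(gene_id = g$gene_id, chrom = g$chrom,
                               strand = g$strand, iv,
                               stringsAsFactors = FALSE)
  }
  genes$anchor <- anchor
  genes$coding <- coding
  intervals <- do.call(rbind, iv_list)
  rownames(intervals) <- NULL
  structure(list(genes = genes, intervals = intervals), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes (%d coding), %d region intervals\n",
              nrow(x$genes), sum(x$genes$coding), nrow(x$intervals)))
  invisible(x)
}

#' Transcription-ordered region intervals of one gene
#'
#' Utility for strand-aware inspection: intervals sorted 5' to 3' in
#' transcription order (reverse genomic order on the minus strand).
#'
#' @param models A `gene_models` object.
#' @param gene_id Gene identifier.
#' @return Interval data.frame sorted in transcription order.
#' @export
gene_intervals <- function(models, gene_id) {
  iv <- models$intervals[models$intervals$gene_id == gene_id, , drop = FALSE]
  if (nrow(iv) == 0L) stop("unknown gene: ", gene_id, call. = FALSE)
  if (iv$strand[1L] == "+") iv[order(iv$start), , drop = FALSE]
  else iv[order(-iv$end), , drop = FALSE]
}

#' Read a genome FASTA
#' @param path Path to a FASTA file.
#' @return Named character vector of chromosome sequences (uppercase).
#' @export
read_genome <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(x))
  names(seqs) <- sub("\\s.*$", "", names(x))
  seqs
}

#' Write a genome FASTA (wrapped at 60 columns)
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

# Deterministic TSV writer used by every stage: fixed column order, no quotes,
# sorted by the caller, "NA" for missing.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path) {
  if (!file.exists(path)) stop("missing input file: ", path, call. = FALSE)
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "", quote = "")
}
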