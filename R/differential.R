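# Differential PAS usage between two groups of samples.
#
# For one comparison (treat vs ctrl):
#   PSU  = per-sample fraction of a gene's reads ending at one PAC
#   DPUI = mean PSU(treat) - mean PSU(ctrl)        (replicate means)
#   Wald = two-proportion z test on counts pooled within each group
#   significant <=> |DPUI| >= 0.05 and p <= 0.05
# For 3'UTR APA, the two PACs with the largest |DPUI| per gene give
#   RED = DPUI_distal - DPUI_proximal
# with the proximal PAC the one nearer the terminal exon in transcription
# order; RED >= 0.05 is 3'UTR lengthening, RED <= -0.05 shortening.

#' Retain genes with enough informative PACs for a comparison
#'
#' A PAC qualifies when its summed read count strictly exceeds `min_reads`
#' in EACH of the two groups; a gene is retained when it has at least
#' `min_pas` qualifying PACs. Intergenic PACs never qualify.
#'
#' @param pacs Annotated PAC data.frame (needs `gene_id` and per-sample count
#'   columns).
#' @param treat,ctrl Character vectors of sample column names for the two
#'   groups.
#' @param min_reads Per-group read threshold, strict (default 5, i.e. >5).
#' @param min_pas Minimum qualifying PACs per gene (default 2).
#' @return Subset of `pacs`: the qualifying PACs of retained genes.
#' @export
retain_genes <- function(pacs, treat, ctrl, min_reads = 5, min_pas = 2L) {
  k1 <- rowSums(as.matrix(pacs[, treat, drop = FALSE]))
  k2 <- rowSums(as.matrix(pacs[, ctrl, drop = FALSE]))
  qual <- !is.na(pacs$gene_id) & k1 > min_reads & k2 > min_reads
  q <- pacs[qual, , drop = FALSE]
  keep_genes <- names(which(table(q$gene_id) >= min_pas))
  out <- q[q$gene_id %in% keep_genes, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-sample percentage of site usage (PSU)
#'
#' PSU of a PAC in a sample is its read count divided by the summed count of
#' all retained PACs of the same gene in that sample. A sample in which the
#' gene has zero total reads yields NA (excluded from group means).
#'
#' @param pacs Retained PAC data.frame (from [retain_genes()]).
#' @param samples Sample column names.
#' @return data.frame: `gene_id`, `center`, plus one `psu_<sample>` column per
#'   sample.
#' @export
compute_psu <- function(pacs, samples) {
  out <- data.frame(gene_id = pacs$gene_id, center = pacs$center,
                    stringsAsFactors = FALSE)
  for (s in samples) {
    tot <- stats::ave(pacs[[s]], pacs$gene_id, FUN = sum)
    out[[paste0("psu_", s)]] <- ifelse(tot > 0, pacs[[s]] / tot, NA_real_)
  }
  out
}

#' Two-proportion Wald test on pooled group counts
#'
#' z = (k1/n1 - k2/n2) / sqrt(p1(1-p1)/n1 + p2(1-p2)/n2) with unpooled
#' variances and a two-sided normal p-value. An estimated variance term of 0
#' (proportion exactly 0 or 1) is floored at 0.5/n of that group.
#'
#' @param k1,n1 PAC count and gene total in the treatment group (pooled over
#'   replicates). Vectorized.
#' @param k2,n2 Same for the control group.
#' @return data.frame with `z` and `p` (NA where a group total is 0).
#' @export
wald_test <- function(k1, n1, k2, n2) {
  m <- max(length(k1), length(n1), length(k2), length(n2))
  k1 <- rep_len(k1, m); n1 <- rep_len(n1, m)
  k2 <- rep_len(k2, m); n2 <- rep_len(n2, m)
  p1 <- ifelse(n1 > 0, k1 / n1, NA_real_)
  p2 <- ifelse(n2 > 0, k2 / n2, NA_real_)
  v1 <- p1 * (1 - p1) / n1
  v2 <- p2 * (1 - p2) / n2
  v1 <- ifelse(!is.na(v1) & v1 == 0, 0.5 / n1, v1)
  v2 <- ifelse(!is.na(v2) & v2 == 0, 0.5 / n2, v2)
  z <- (p1 - p2) / sqrt(v1 + v2)
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(z = z, p = p)
}

#' Call differential APA events for one two-group comparison
#'
#' Runs retention, PSU, DPUI and the Wald test and applies the joint
#' significance rule |DPUI| >= `dpui_th` and p <= `p_th`. Raw p-values are
#' the headline call; Benjamini-Hochberg q-values are reported alongside.
#'
#' @inheritParams retain_genes
#' @param dpui_th Absolute DPUI threshold (default 0.05).
#' @param p_th P-value threshold (default 0.05).
#' @return data.frame of class `apa_events`: one row per tested PAC with
#'   gene_id, pac_id, chrom, strand, center, region, psu_treat, psu_ctrl,
#'   dpui, z, p, q, significant. Attribute `comparison` records the groups.
#' @export
call_events <- function(pacs, treat, ctrl, min_reads = 5, min_pas = 2L,
                        dpui_th = 0.05, p_th = 0.05) {
  ret <- retain_genes(pacs, treat, ctrl, min_reads = min_reads,
                      min_pas = min_pas)
  psu <- compute_psu(ret, c(treat, ctrl))
  mean_psu <- function(group) {
    m <- as.matrix(psu[, paste0("psu_", group), drop = FALSE])
    rowMeans(m, na.rm = TRUE)
  }
  psu_t <- mean_psu(treat)
  psu_c <- mean_psu(ctrl)
  k1 <- rowSums(as.matrix(ret[, treat, drop = FALSE]))
  k2 <- rowSums(as.matrix(ret[, ctrl, drop = FALSE]))
  n1 <- stats::ave(k1, ret$gene_id, FUN = sum)
  n2 <- stats::ave(k2, ret$gene_id, FUN = sum)
  w <- wald_test(k1, n1, k2, n2)
  dpui <- psu_t - psu_c
  ev <- data.frame(gene_id = ret$gene_id,
                   pac_id = if ("pac_id" %in% names(ret)) ret$pac_id else NA,
                   chrom = ret$chrom, strand = ret$strand, center = ret$center,
                   region = if ("region" %in% names(ret)) ret$region else NA,
                   psu_treat = psu_t, psu_ctrl = psu_c, dpui = dpui,
                   z = w$z, p = w$p,
                   q = stats::p.adjust(w$p, method = "BH"),
                   stringsAsFactors = FALSE)
  ev$significant <- !is.na(ev$p) & abs(ev$dpui) >= dpui_th & ev$p <= p_th
  ev <- ev[order(ev$gene_id, ev$chrom, ev$center), , drop = FALSE]
  rownames(ev) <- NULL
  attr(ev, "comparison") <- list(treat = treat, ctrl = ctrl)
  class(ev) <- c("apa_events", "data.frame")
  ev
}

#' Relative end-offset (RED) calls of 3'UTR lengthening and shortening
#'
#' For each gene with at least two tested 3'UTR PACs and at least one
#' significant 3'UTR event, selects the two PACs with the largest |DPUI|,
#' orients them as proximal/distal by transcription-order distance from the
#' 3' end of the last CDS-bearing exon (the terminal-exon anchor), and
#' computes RED = DPUI_distal - DPUI_proximal. RED >= `red_th` is
#' lengthening, RED <= -`red_th` shortening, otherwise unclassified.
#'
#' @param events An `apa_events` data.frame from [call_events()].
#' @param models A `gene_models` object.
#' @param red_th RED threshold (default 0.05).
#' @return data.frame: gene_id, proximal, distal (center positions),
#'   dpui_proximal, dpui_distal, red, direction.
#' @export
call_red <- function(events, models, red_th = 0.05) {
  ev3 <- events[!is.na(events$region) & events$region == "3UTR", , drop = FALSE]
  out <- data.frame(gene_id = character(), proximal = integer(),
                    distal = integer(), dpui_proximal = numeric(),
                    dpui_distal = numeric(), red = numeric(),
                    direction = character(), stringsAsFactors = FALSE)
  if (nrow(ev3) == 0L) return(out)
  gn <- models$genes
  rows <- list()
  for (g in sort(unique(ev3$gene_id))) {
    e <- ev3[ev3$gene_id == g, , drop = FALSE]
    if (nrow(e) < 2L || !any(e$significant)) next
    gi <- match(g, gn$gene_id)
    if (is.na(gi) || is.na(gn$anchor[gi])) next
    top <- e[order(-abs(e$dpui), e$center), , drop = FALSE][1:2, ]
    sgn <- if (gn$strand[gi] == "+") 1 else -1
    tdist <- (top$center - gn$anchor[gi]) * sgn
    prox <- which.min(tdist)
    dist_i <- 3L - prox
    red <- top$dpui[dist_i] - top$dpui[prox]
    dir <- if (red >= red_th) "lengthening"
           else if (red <= -red_th) "shortening" else "unclassified"
    rows[[g]] <- data.frame(gene_id = g, proximal = top$center[prox],
                            distal = top$center[dist_i],
                            dpui_proximal = top$dpui[prox],
                            dpui_distal = top$dpui[dist_i],
                            red = red, direction = dir,
                            stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(out)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

PATTERN_MAP <- c("lengthening.lengthening" = 1L, "lengthening.shortening" = 2L,
                 "shortening.shortening" = 3L, "shortening.lengthening" = 4L)

#' Classify genes into four 3'UTR dynamic patterns across two comparisons
#'
#' Intersects RED calls from two successive stage comparisons: pattern 1 =
#' persistent lengthening, 2 = lengthening then shortening, 3 = persistent
#' shortening, 4 = shortening then lengthening. Genes with a directional call
#' in only one comparison (or unclassified in either) get pattern "none".
#'
#' @param red1 RED calls for the first comparison (e.g. NSC vs hESC).
#' @param red2 RED calls for the second comparison (e.g. NPC vs NSC).
#' @return data.frame: gene_id, direction1, direction2, pattern (character
#'   "1".."4" or "none"), covering the union of genes in either call set.
#' @export
classify_patterns <- function(red1, red2) {
  genes <- sort(union(red1$gene_id, red2$gene_id))
  d1 <- red1$direction[match(genes, red1$gene_id)]
  d2 <- red2$direction[match(genes, red2$gene_id)]
  key <- paste(d1, d2, sep = ".")
  pat <- PATTERN_MAP[key]
  data.frame(gene_id = genes,
             direction1 = ifelse(is.na(d1), "absent", d1),
             direction2 = ifelse(is.na(d2), "absent", d2),
             pattern = ifelse(is.na(pat), "none", as.character(pat)),
             stringsAsFactors = FALSE)
}
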