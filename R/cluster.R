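# PAC calling: iterative 24-nt clustering of filtered 3'-end sites, weighted
# density-peak refinement into sub-PACs, and center-PAS selection.

sample_cols <- function(sites) {
  cand <- setdiff(names(sites), c("chrom", "strand", "position", "pac_id"))
  cand[vapply(sites[cand], is.numeric, TRUE)]
}

site_totals <- function(sites, samples = sample_cols(sites)) {
  if (length(samples) == 1L) sites[[samples]]
  else rowSums(as.matrix(sites[, samples, drop = FALSE]))
}

#' Primary clustering of end sites (iterative, count-ordered)
#'
#' Greedy iterative scheme, per (chrom, strand): repeatedly take the
#' unassigned site with the highest summed count (ties broken toward the
#' 5'-most position in transcription order) as a seed, and absorb every
#' unassigned site within `width` nt of it into one PAC. Sites are never
#' re-assigned, so membership is independent of input order.
#'
#' @param sites Multi-sample end-site data.frame.
#' @param width Absorption radius in nt around each seed (default 24).
#' @param samples Count column names (default: all numeric columns).
#' @return `sites` with an integer `cluster` column (cluster labels are
#'   per-call, ordered by chrom, strand, then cluster start).
#' @export
cluster_primary <- function(sites, width = 24L, samples = sample_cols(sites)) {
  stopifnot(width >= 1L)
  n <- nrow(sites)
  out <- sites
  out$cluster <- rep(NA_integer_, n)
  if (n == 0L) return(out)
  tot <- site_totals(sites, samples)
  grp <- paste(sites$chrom, sites$strand, sep = "\r")
  next_id <- 0L
  for (g in unique(grp)) {
    idx <- which(grp == g)
    pos <- sites$position[idx]
    ct <- tot[idx]
    fiveprime <- if (sites$strand[idx[1L]] == "+") pos else -pos
    unas <- rep(TRUE, length(idx))
    cl <- integer(length(idx))
    while (any(unas)) {
      cand <- which(unas)
      seed <- cand[order(-ct[cand], fiveprime[cand])][1L]
      mem <- cand[abs(pos[cand] - pos[seed]) <= width]
      next_id <- next_id + 1L
      cl[mem] <- next_id
      unas[mem] <- FALSE
    }
    out$cluster[idx] <- cl
  }
  # relabel deterministically by (chrom, strand, span start)
  start <- stats::ave(out$position, out$cluster, FUN = min)
  ord <- order(out$chrom, out$strand, start, out$cluster)
  lab <- out$cluster[ord][!duplicated(out$cluster[ord])]
  out$cluster <- match(out$cluster, lab)
  out
}

#' Split one PAC into sub-PACs by weighted density-peak clustering
#'
#' Each member's density is the count-weighted triangular-kernel sum
#' `rho_i = sum_j count_j * max(0, 1 - |pos_i - pos_j| / bandwidth)`.
#' Peak candidates are members whose density exceeds `min_peak_frac` times
#' the maximum density and whose distance to any higher-density member is at
#' least `min_sep` nt. Every member is assigned to its nearest peak (ties to
#' the 5'-most peak in transcription order). A unimodal PAC yields a single
#' sub-PAC identical to the input.
#'
#' @param positions Member positions (0-based).
#' @param counts Member summed counts.
#' @param strand "+" or "-" (tie-break orientation).
#' @param bandwidth Kernel half-width in nt (default 8).
#' @param min_peak_frac Minimum density of a peak relative to the maximum
#'   (default 0.1).
#' @param min_sep Minimum separation between peaks in nt (default 8).
#' @return Integer vector of sub-cluster ids (1..k) per member, numbered in
#'   genomic order of their peaks.
#' @export
refine_subpacs <- function(positions, counts, strand = "+", bandwidth = 8,
                           min_peak_frac = 0.1, min_sep = 8) {
  n <- length(positions)
  if (n <= 1L) return(rep(1L, n))
  d <- abs(outer(positions, positions, "-"))
  w <- 1 - d / bandwidth
  w[w < 0] <- 0
  rho <- as.vector(w %*% counts)
  delta <- vapply(seq_len(n), function(i) {
    higher <- which(rho > rho[i])
    if (length(higher) == 0L) Inf else min(d[i, higher])
  }, 0)
  peaks <- which(rho > min_peak_frac * max(rho) & delta >= min_sep)
  if (length(peaks) <= 1L) return(rep(1L, n))
  peaks <- peaks[order(positions[peaks])]
  dp <- d[, peaks, drop = FALSE]
  assign <- integer(n)
  fp <- if (strand == "+") positions[peaks] else -positions[peaks]
  for (i in seq_len(n)) {
    near <- which(dp[i, ] == min(dp[i, ]))
    assign[i] <- near[order(fp[near])][1L]
  }
  match(assign, sort(unique(assign)))
}

#' Select the center PAS of a cluster
#'
#' The representative position of a PAC: the member with the maximal summed
#' count, ties broken toward the 5'-most member in transcription order.
#'
#' @inheritParams refine_subpacs
#' @return The center position (scalar).
#' @export
select_center <- function(positions, counts, strand = "+") {
  stopifnot(length(positions) > 0L)
  fp <- if (strand == "+") positions else -positions
  positions[order(-counts, fp)][1L]
}

#' Cluster filtered end sites into PACs
#'
#' Runs [cluster_primary()] and then, when `refine = TRUE`, splits each
#' primary cluster into sub-PACs with [refine_subpacs()]. Each final PAC is
#' summarized by its span, center PAS ([select_center()]) and per-sample
#' counts.
#'
#' @inheritParams cluster_primary
#' @param refine Apply density-peak refinement (default TRUE).
#' @inheritParams refine_subpacs
#' @return An object of class `pac_set`: list with `pacs` (pac_id, chrom,
#'   strand, start, end, center, n_sites, total, one count column per sample)
#'   and `sites` (input rows plus `pac_id`).
#' @export
cluster_sites <- function(sites, width = 24L, refine = TRUE, bandwidth = 8,
                          min_peak_frac = 0.1, min_sep = 8,
                          samples = sample_cols(sites)) {
  cl <- cluster_primary(sites, width = width, samples = samples)
  tot <- site_totals(cl, samples)
  key <- cl$cluster
  sub <- integer(nrow(cl))
  if (refine && nrow(cl) > 0L) {
    for (k in unique(key)) {
      idx <- which(key == k)
      sub[idx] <- refine_subpacs(cl$position[idx], tot[idx],
                                 strand = cl$strand[idx[1L]],
                                 bandwidth = bandwidth,
                                 min_peak_frac = min_peak_frac,
                                 min_sep = min_sep)
    }
  } else {
    sub <- rep(1L, nrow(cl))
  }
  final <- paste(key, sub, sep = ".")
  # summarize
  if (nrow(cl) == 0L) {
    pacs <- data.frame(pac_id = character(), chrom = character(),
                       strand = character(), start = integer(),
                       end = integer(), center = integer(),
                       n_sites = integer(), total = numeric(),
                       stringsAsFactors = FALSE)
    cl$pac_id <- character(0)
    cl$cluster <- NULL
    return(structure(list(pacs = pacs, sites = cl), class = "pac_set"))
  }
  groups <- split(seq_len(nrow(cl)), final)
  rows <- lapply(groups, function(idx) {
    st <- cl$strand[idx[1L]]
    data.frame(chrom = cl$chrom[idx[1L]], strand = st,
               start = min(cl$position[idx]), end = max(cl$position[idx]),
               center = select_center(cl$position[idx], tot[idx], st),
               n_sites = length(idx), total = sum(tot[idx]),
               stringsAsFactors = FALSE)
  })
  pacs <- do.call(rbind, rows)
  for (s in samples) {
    pacs[[s]] <- vapply(groups, function(idx) as.numeric(sum(cl[[s]][idx])), 0)
  }
  ord <- order(pacs$chrom, pacs$strand, pacs$start, pacs$end)
  pacs <- pacs[ord, , drop = FALSE]
  pacs <- cbind(pac_id = sprintf("PAC%05d", seq_len(nrow(pacs))), pacs,
                stringsAsFactors = FALSE)
  rownames(pacs) <- NULL
  cl$pac_id <- pacs$pac_id[match(final, names(groups)[ord])]
  cl$cluster <- NULL
  attr(pacs, "samples") <- samples
  structure(list(pacs = pacs, sites = cl), class = "pac_set")
}

#' @export
print.pac_set <- function(x, ...) {
  cat(sprintf("pac_set: %d PACs from %d end sites (%s total reads)\n",
              nrow(x$pacs), nrow(x$sites),
              format(sum(x$pacs$total), big.mark = ",")))
  invisible(x)
}
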