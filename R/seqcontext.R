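# Sequence-context QC of PASs: nucleotide composition around centers,
# canonical poly(A)-signal positional density, and exact k-mer enrichment in
# upstream flanks against a dinucleotide-shuffled background.

#' Extract sense-strand upstream flanks of PAC centers
#'
#' The `upstream` bases immediately 5' of the center PAS (excluding the site
#' base), oriented in transcription sense. Flanks truncated at a chromosome
#' boundary are clipped and flagged.
#'
#' @param pacs PAC data.frame with `chrom`, `strand`, `center`.
#' @param genome Named character vector of chromosome sequences.
#' @param upstream Flank length in nt (default 50).
#' @return data.frame of class `flank_set`: chrom, strand, center, flank,
#'   clipped. Offsets within a flank run from -`upstream` to -1 relative to
#'   the PAS.
#' @export
extract_flanks <- function(pacs, genome, upstream = 50L) {
  missing_chr <- setdiff(unique(pacs$chrom), names(genome))
  if (length(missing_chr)) {
    stop("chromosome not in genome: ", paste(missing_chr, collapse = ", "),
         call. = FALSE)
  }
  chrlen <- nchar(genome)[pacs$chrom]
  plus <- pacs$strand == "+"
  from <- ifelse(plus, pacs$center - upstream, pacs$center + 1L)
  to <- ifelse(plus, pacs$center - 1L, pacs$center + upstream)
  cf <- pmax(from, 0L)
  ct <- pmin(to, chrlen - 1L)
  seqs <- substr(genome[pacs$chrom], cf + 1L, ct + 1L)
  if (any(!plus)) seqs[!plus] <- revcomp(seqs[!plus])
  out <- data.frame(chrom = pacs$chrom, strand = pacs$strand,
                    center = pacs$center, flank = unname(seqs),
                    clipped = unname(cf != from | ct != to),
                    stringsAsFactors = FALSE)
  attr(out, "upstream") <- upstream
  class(out) <- c("flank_set", "data.frame")
  out
}

#' Nucleotide composition profile around PAC centers
#'
#' Per offset in [-halfwidth, +halfwidth] relative to the center PAS
#' (transcription sense), the frequency of each base among all PACs covering
#' that offset; 'N' and clipped positions are excluded from the denominator,
#' so frequencies sum to 1 at every covered offset.
#'
#' @inheritParams extract_flanks
#' @param halfwidth Window half-width in nt (default 100).
#' @return data.frame: offset, A, C, G, T, n (PACs contributing).
#' @export
nt_profile <- function(pacs, genome, halfwidth = 100L) {
  chrlen <- nchar(genome)[pacs$chrom]
  from <- pmax(pacs$center - halfwidth, 0L)
  to <- pmin(pacs$center + halfwidth, chrlen - 1L)
  seqs <- substr(genome[pacs$chrom], from + 1L, to + 1L)
  width <- 2L * halfwidth + 1L
  counts <- matrix(0L, nrow = width, ncol = 4L,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  for (i in seq_along(seqs)) {
    s <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
    # pad to the full window, then orient in transcription sense
    pad_l <- (pacs$center[i] - halfwidth) - from[i]
    full <- rep("N", width)
    full[seq_along(s) - pad_l] <- s
    if (pacs$strand[i] == "-") {
      full <- rev(c(A = "T", C = "G", G = "C", T = "A", N = "N")[full])
    }
    for (b in c("A", "C", "G", "T")) {
      counts[, b] <- counts[, b] + (full == b)
    }
  }
  n <- rowSums(counts)
  freq <- counts / ifelse(n > 0, n, 1)
  data.frame(offset = seq(-halfwidth, halfwidth), freq, n = n)
}

#' Positional density of a poly(A)-signal motif in upstream flanks
#'
#' Histogram of motif start offsets relative to the PAS over
#' [-upstream, -1]; every occurrence in every flank is counted.
#'
#' @param flanks A `flank_set` from [extract_flanks()].
#' @param motif Motif sequence (default "AATAAA").
#' @return data.frame: offset (motif start, negative = upstream), n.
#' @export
signal_density <- function(flanks, motif = "AATAAA") {
  upstream <- attr(flanks, "upstream")
  if (is.null(upstream)) upstream <- max(nchar(flanks$flank))
  counts <- integer(upstream)
  names(counts) <- as.character(seq(-upstream, -1L))
  for (i in seq_len(nrow(flanks))) {
    fl <- flanks$flank[i]
    hits <- gregexpr(paste0("(?=", motif, ")"), fl, perl = TRUE)[[1L]]
    if (hits[1L] == -1L) next
    # right-align clipped flanks: last flank base sits at offset -1
    off <- hits - nchar(fl) - 1L
    for (o in off) {
      key <- as.character(o)
      if (key %in% names(counts)) counts[key] <- counts[key] + 1L
    }
  }
  data.frame(offset = seq(-upstream, -1L), n = unname(counts))
}

#' Exact k-mer enrichment in flanks vs a dinucleotide-shuffled background
#'
#' For every k-mer (k in `k_min`..`k_max`) present in the flanks, reports the
#' fraction of flanks containing it and a one-sided binomial p-value against
#' the containment rate in `n_shuffles` dinucleotide-shuffled copies of each
#' flank. This is an exact-containment stand-in for de novo motif discovery:
#' the question answered is whether a motif such as AATAAA is enriched, and
#' where, not what its PWM is.
#'
#' @param flanks A `flank_set`.
#' @param k_min,k_max k-mer width range (defaults 4 and 6).
#' @param n_shuffles Shuffled copies per flank (default 10).
#' @param seed Seed for the shuffles (default 1); results are
#'   seed-deterministic.
#' @return data.frame ranked by p then descending foreground fraction: kmer,
#'   k, fg_frac, bg_frac, p, q (BH within the report).
#' @export
kmer_enrichment <- function(flanks, k_min = 4L, k_max = 6L, n_shuffles = 10L,
                            seed = 1L) {
  seqs <- flanks$flank[nchar(flanks$flank) >= k_max]
  n_fg <- length(seqs)
  if (n_fg == 0L) {
    return(data.frame(kmer = character(), k = integer(), fg_frac = numeric(),
                      bg_frac = numeric(), p = numeric(), log10_p = numeric(),
                      q = numeric()))
  }
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  bg <- unlist(lapply(seqs, function(s) {
    vapply(seq_len(n_shuffles), function(i) dinuc_shuffle(s), "")
  }))
  fg_tab <- containment_table(seqs, k_min, k_max)
  bg_tab <- containment_table(bg, k_min, k_max)
  kmers <- names(fg_tab)
  fg_frac <- as.numeric(fg_tab) / n_fg
  bg_rate <- as.numeric(bg_tab[kmers]) / length(bg)
  bg_rate[is.na(bg_rate)] <- 0
  # floor the background rate so planted motifs absent from every shuffle get
  # a finite, conservative p
  bg_floor <- 0.5 / (length(bg) + 1)
  # log-scale p avoids underflow ties between a planted motif and its
  # substrings, so ranking stays informative at large n
  log_p <- stats::pbinom(as.numeric(fg_tab) - 1L, n_fg,
                         pmax(bg_rate, bg_floor), lower.tail = FALSE,
                         log.p = TRUE)
  p <- exp(log_p)
  out <- data.frame(kmer = kmers, k = nchar(kmers), fg_frac = fg_frac,
                    bg_frac = bg_rate, p = p, log10_p = log_p / log(10),
                    q = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$log10_p, -out$fg_frac, out$kmer), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# number of sequences containing each k-mer at least once
containment_table <- function(seqs, k_min, k_max) {
  per_seq <- lapply(seqs, function(s) {
    w <- nchar(s)
    ks <- k_min:min(k_max, w)
    unique(unlist(lapply(ks, function(k) {
      substring(s, seq_len(w - k + 1L), seq_len(w - k + 1L) + k - 1L)
    })))
  })
  table(unlist(per_seq))
}

# Dinucleotide-preserving shuffle: rejection-sampled Eulerian walk over the
# dinucleotide transition graph (retry cap, plain shuffle fallback).
dinuc_shuffle <- function(s, max_tries = 100L) {
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  if (n <= 2L) return(s)
  edges <- split(ch[-1L], factor(ch[-n], levels = unique(ch)))
  for (try in seq_len(max_tries)) {
    pool <- lapply(edges, sample)
    used <- stats::setNames(integer(length(pool)), names(pool))
    walk <- character(n)
    walk[1L] <- ch[1L]
    ok <- TRUE
    for (i in 2:n) {
      v <- walk[i - 1L]
      u <- used[v] + 1L
      if (is.na(u) || u > length(pool[[v]])) { ok <- FALSE; break }
      walk[i] <- pool[[v]][u]
      used[v] <- u
    }
    if (ok) return(paste(walk, collapse = ""))
  }
  paste(sample(ch), collapse = "")
}
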