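# Internal-priming artifact detection.
#
# Oligo(dT) primers can anneal to genomically encoded A-rich stretches inside
# a transcript, creating spurious 3'-end signals. Sites whose flanking genomic
# sequence (sense strand) contains >= 6 consecutive adenines, or >= 7
# adenines within any 10-nt sliding window, are flagged as internal-priming
# artifacts and removed before clustering.

#' Extract the sense-strand window around each end site
#'
#' Returns the 21-nt window spanning `flank` nt upstream and downstream of
#' each site (including the site base), oriented in transcription sense:
#' minus-strand windows are reverse-complemented. Windows truncated by a
#' chromosome boundary are clipped and flagged.
#'
#' @param sites data.frame with `chrom`, `strand`, `position` (0-based).
#' @param genome Named character vector of chromosome sequences
#'   (see [read_genome()]).
#' @param flank Bases on each side of the site (default 10, giving 21 nt).
#' @return data.frame of `sites` plus `window` (character) and `clipped`
#'   (logical).
#' @export
extract_window <- function(sites, genome, flank = 10L) {
  missing_chr <- setdiff(unique(sites$chrom), names(genome))
  if (length(missing_chr)) {
    stop("chromosome not in genome: ", paste(missing_chr, collapse = ", "),
         call. = FALSE)
  }
  chrlen <- nchar(genome)[sites$chrom]
  from <- pmax(sites$position - flank, 0L)
  to <- pmin(sites$position + flank, chrlen - 1L)
  win <- substr(genome[sites$chrom], from + 1L, to + 1L)
  minus <- sites$strand == "-"
  if (any(minus)) win[minus] <- revcomp(win[minus])
  out <- sites
  out$window <- unname(win)
  out$clipped <- unname(from != sites$position - flank |
                          to != sites$position + flank)
  out
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Classify sequences by the internal-priming A-content rules
#'
#' For each sequence, computes the longest run of 'A' and the maximal number
#' of 'A's over every length-10 window (stride 1; sequences shorter than 10
#' use the whole sequence as the single window). 'N' and lowercase bases
#' never count as adenine.
#'
#' @param seqs Character vector of sense-strand window sequences.
#' @return data.frame with `max_A_run`, `max_A_in_10nt` and `is_artifact`
#'   (`max_A_run >= run_th | max_A_in_10nt >= win_th`).
#' @param run_th Consecutive-A threshold (default 6).
#' @param win_th A-per-10-nt threshold (default 7).
#' @param window Sliding-window width (default 10).
#' @export
classify_priming <- function(seqs, run_th = 6L, win_th = 7L, window = 10L) {
  n <- length(seqs)
  max_run <- integer(n)
  max_win <- integer(n)
  widths <- nchar(seqs)
  for (w in unique(widths)) {
    idx <- which(widths == w)
    if (w == 0L) next
    m <- matrix(unlist(strsplit(seqs[idx], "", fixed = TRUE), use.names = FALSE),
                ncol = w, byrow = TRUE) == "A"
    run <- integer(length(idx)); best <- integer(length(idx))
    cum <- matrix(0L, nrow = length(idx), ncol = w + 1L)
    for (j in seq_len(w)) {
      run <- ifelse(m[, j], run + 1L, 0L)
      best <- pmax(best, run)
      cum[, j + 1L] <- cum[, j] + m[, j]
    }
    max_run[idx] <- best
    if (w <= window) {
      max_win[idx] <- cum[, w + 1L]
    } else {
      wb <- integer(length(idx))
      for (j in seq_len(w - window + 1L)) {
        wb <- pmax(wb, cum[, j + window] - cum[, j])
      }
      max_win[idx] <- wb
    }
  }
  data.frame(max_A_run = max_run, max_A_in_10nt = max_win,
             is_artifact = max_run >= run_th | max_win >= win_th)
}

#' Partition end sites into kept sites and internal-priming artifacts
#'
#' Applies [extract_window()] and [classify_priming()] to every site; the
#' partition is exhaustive and disjoint, and filtering the kept set again
#' removes nothing.
#'
#' @param sites Multi-sample end-site data.frame (see [merge_endsites()]); any
#'   extra columns are carried through.
#' @param genome Named character vector of chromosome sequences.
#' @inheritParams classify_priming
#' @param flank Bases on each side of the site scanned (default 10).
#' @return list with `kept` and `artifacts` (row subsets of `sites`) and
#'   `verdicts` (chrom, strand, position, window_sequence, max_A_run,
#'   max_A_in_10nt, is_artifact).
#' @export
filter_sites <- function(sites, genome, flank = 10L, run_th = 6L, win_th = 7L) {
  if (nrow(sites) == 0L) {
    return(list(kept = sites, artifacts = sites,
                verdicts = data.frame(chrom = character(), strand = character(),
                                      position = integer(),
                                      window_sequence = character(),
                                      max_A_run = integer(),
                                      max_A_in_10nt = integer(),
                                      is_artifact = logical())))
  }
  win <- extract_window(sites, genome, flank = flank)
  cls <- classify_priming(win$window, run_th = run_th, win_th = win_th)
  verdicts <- data.frame(chrom = sites$chrom, strand = sites$strand,
                         position = sites$position,
                         window_sequence = win$window,
                         max_A_run = cls$max_A_run,
                         max_A_in_10nt = cls$max_A_in_10nt,
                         is_artifact = cls$is_artifact,
                         stringsAsFactors = FALSE)
  list(kept = sites[!cls$is_artifact, , drop = FALSE],
       artifacts = sites[cls$is_artifact, , drop = FALSE],
       verdicts = verdicts)
}
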