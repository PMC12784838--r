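# Independent oracles used to cross-check the implementation. These are
# deliberately written in a different style (explicit enumeration, O(n^2)
# scans) and share no code with the package internals.

# Priming oracle, scalar: enumerate every substring; the longest all-A
# substring and the max A count over all length-10 windows.
oracle_priming_one <- function(s, run_th = 6L, win_th = 7L, window = 10L) {
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  is_a <- ch == "A"
  max_run <- 0L
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (all(is_a[i:j])) max_run <- max(max_run, j - i + 1L)
    }
  }
  if (n <= window) {
    max_win <- sum(is_a)
  } else {
    max_win <- 0L
    for (i in seq_len(n - window + 1L)) {
      max_win <- max(max_win, sum(is_a[i:(i + window - 1L)]))
    }
  }
  c(max_A_run = max_run, max_A_in_10nt = max_win,
    is_artifact = max_run >= run_th || max_win >= win_th)
}

# Vectorized enumeration oracle for equal-width sequences: tests every
# (start, length) substring via row sums of the A-indicator matrix.
oracle_priming_matrix <- function(seqs, run_th = 6L, win_th = 7L,
                                  window = 10L) {
  w <- nchar(seqs[1L])
  stopifnot(all(nchar(seqs) == w))
  A <- matrix(unlist(strsplit(seqs, "", fixed = TRUE)), ncol = w,
              byrow = TRUE) == "A"
  n <- length(seqs)
  max_run <- integer(n)
  for (i in seq_len(w)) {
    for (len in seq_len(w - i + 1L)) {
      sub <- A[, i:(i + len - 1L), drop = FALSE]
      hit <- rowSums(sub) == len
      max_run[hit & max_run < len] <- len
    }
  }
  max_win <- integer(n)
  if (w <= window) {
    max_win <- rowSums(A)
  } else {
    for (i in seq_len(w - window + 1L)) {
      max_win <- pmax(max_win, rowSums(A[, i:(i + window - 1L), drop = FALSE]))
    }
  }
  data.frame(max_A_run = max_run, max_A_in_10nt = as.integer(max_win),
             is_artifact = max_run >= run_th | max_win >= win_th)
}

# Clustering oracle: explicit distance matrix and linear scans for the
# highest-count unassigned seed.
oracle_cluster <- function(pos, cnt, strand = "+", width = 24L) {
  n <- length(pos)
  D <- abs(outer(pos, pos, "-"))
  assigned <- rep(0L, n)
  cl <- 0L
  while (any(assigned == 0L)) {
    un <- which(assigned == 0L)
    best <- un[1L]
    for (i in un) {
      if (cnt[i] > cnt[best]) {
        best <- i
      } else if (cnt[i] == cnt[best]) {
        if (strand == "+" && pos[i] < pos[best]) best <- i
        if (strand == "-" && pos[i] > pos[best]) best <- i
      }
    }
    cl <- cl + 1L
    for (i in un) if (D[best, i] <= width) assigned[i] <- cl
  }
  assigned
}

# canonical form of a partition: sorted list of sorted member position sets
partition_sets <- function(pos, labels) {
  sets <- lapply(split(pos, labels), sort)
  unname(sets[order(vapply(sets, min, 0))])
}

random_dna <- function(n, width, alphabet = c("A", "C", "G", "T")) {
  vapply(seq_len(n), function(i) {
    paste(sample(alphabet, width, replace = TRUE), collapse = "")
  }, "")
}
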