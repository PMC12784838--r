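# Synthetic ONT-style 3'-end data with ground truth.
#
# Each gene lives on its own chromosome and carries a fixed two-exon coding
# structure (5'UTR, CDS exon, intron, CDS exon, 3'UTR). True PASs sit in the
# 3'UTR at a configurable spacing; per-stage usage fractions, read-end jitter,
# internal-priming traps (genomic A-runs) and planted AATAAA signals are all
# recorded in a truth table so every downstream stage can be scored.

#' Build a simulation configuration
#'
#' Defaults describe a three-stage neural-differentiation-style design
#' (hESC -> NSC -> NPC, two replicates per stage) with ONT-like positional
#' jitter of read ends.
#'
#' @param n_genes Number of genes (one per synthetic chromosome).
#' @param stages Ordered stage labels.
#' @param replicates_per_stage Replicates per stage.
#' @param pas_per_gene Either a single count in 1..3 applied to all genes, or
#'   a probability vector over 1, 2, 3 PASs per gene. The default reflects a
#'   transcriptome in which roughly 43% of genes have two or more PACs.
#' @param usage_by_stage Per-gene stage-by-PAS usage proportions: NULL (drawn
#'   from a symmetric Dirichlet per stage), one matrix (rows = stages, columns
#'   = PASs; requires fixed `pas_per_gene`) applied to every gene, or a list
#'   of such matrices recycled over genes. Rows must each sum to 1.
#' @param reads_per_gene Mean sequencing depth per gene per sample (Poisson).
#' @param jitter_sd SD (nt) of the discretized Gaussian scatter of read ends
#'   around the true PAS.
#' @param artifact_rate Fraction of genes given a genomic A-run trap that
#'   attracts internal-priming reads.
#' @param artifact_frac Reads at the artifact site, as a fraction of the
#'   gene's drawn depth.
#' @param motif_offset AATAAA is planted starting this many nt upstream of
#'   each non-artifact true PAS (default 21, matching the canonical 20-30 nt
#'   positioning).
#' @param pas_spacing Spacing between consecutive true PASs in nt.
#' @param ref_frac Fraction of true PASs copied into the reference PAS BED;
#'   the rest are "novel".
#' @param gene_length Optional fixed chromosome length; must be large enough
#'   to host the gene structure.
#' @param seed Random seed; identical seeds give byte-identical outputs.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 50L,
                       stages = c("hESC", "NSC", "NPC"),
                       replicates_per_stage = 2L,
                       pas_per_gene = c(0.57, 0.35, 0.08),
                       usage_by_stage = NULL,
                       reads_per_gene = 300,
                       jitter_sd = 3,
                       artifact_rate = 0.1,
                       artifact_frac = 0.2,
                       motif_offset = 21L,
                       pas_spacing = 100L,
                       ref_frac = 0.5,
                       gene_length = NULL,
                       seed = 1L) {
  cfg <- structure(list(n_genes = as.integer(n_genes), stages = stages,
                        replicates_per_stage = as.integer(replicates_per_stage),
                        pas_per_gene = pas_per_gene,
                        usage_by_stage = usage_by_stage,
                        reads_per_gene = reads_per_gene,
                        jitter_sd = jitter_sd,
                        artifact_rate = artifact_rate,
                        artifact_frac = artifact_frac,
                        motif_offset = as.integer(motif_offset),
                        pas_spacing = as.integer(pas_spacing),
                        ref_frac = ref_frac,
                        gene_length = gene_length,
                        seed = as.integer(seed)),
                   class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_genes >= 1L, cfg$replicates_per_stage >= 1L,
            length(cfg$stages) >= 1L, !anyDuplicated(cfg$stages),
            cfg$jitter_sd >= 0, cfg$reads_per_gene >= 1,
            cfg$artifact_rate >= 0, cfg$artifact_rate <= 1,
            cfg$ref_frac >= 0, cfg$ref_frac <= 1,
            cfg$motif_offset >= 6L, cfg$pas_spacing >= 1L)
  p <- cfg$pas_per_gene
  if (length(p) == 1L) {
    stopifnot(p %in% 1:3)
  } else {
    stopifnot(length(p) == 3L, all(p >= 0), abs(sum(p) - 1) < 1e-9)
  }
  if (!is.null(cfg$usage_by_stage)) {
    mats <- cfg$usage_by_stage
    if (is.matrix(mats)) mats <- list(mats)
    for (m in mats) {
      stopifnot(is.matrix(m), nrow(m) == length(cfg$stages))
      if (any(abs(rowSums(m) - 1) > 1e-9)) {
        stop("usage_by_stage rows must each sum to 1", call. = FALSE)
      }
    }
  }
  invisible(cfg)
}

# Fixed structural sizes (transcription coordinates within a chromosome).
SIM_LAYOUT <- list(flank5 = 200L, utr5 = 100L, cds1 = 150L, intron = 200L,
                   cds2 = 150L, utr3_head = 80L, utr3_tail = 120L,
                   flank3 = 1500L, clean_radius = 40L, arun_len = 10L)

sim_gene_layout <- function(npas, spacing) {
  L <- SIM_LAYOUT
  utr3_len <- L$utr3_head + spacing * (npas - 1L) + L$utr3_tail
  tx_start <- L$flank5
  cds1_start <- tx_start + L$utr5
  intron_start <- cds1_start + L$cds1
  cds2_start <- intron_start + L$intron
  utr3_start <- cds2_start + L$cds2
  tx_end <- utr3_start + utr3_len                       # half-open
  list(len = tx_end + L$flank3,
       tx_start = tx_start, tx_end = tx_end,
       exon1 = c(tx_start, intron_start),
       exon2 = c(cds2_start, tx_end),
       cds1 = c(cds1_start, intron_start),
       cds2 = c(cds2_start, utr3_start),
       utr5 = c(tx_start, cds1_start),
       utr3 = c(utr3_start, tx_end),
       pas = utr3_start + L$utr3_head - 1L + spacing * (seq_len(npas) - 1L),
       artifact = utr3_start + L$utr3_head - 1L + spacing * npas)
}

#' Simulate a genome, gene models, reference PAS table and truth table
#'
#' Builds one chromosome per gene (strands alternating + / -), plants the
#' canonical AATAAA signal upstream of every non-artifact true PAS, embeds a
#' 10-nt genomic A-run at the artifact site of artifact genes, and derives
#' the gene-level expected lengthening/shortening directions and four-pattern
#' label from the configured true usage fractions via the RED rule.
#'
#' Sequence within 40 nt of a true PAS is drawn A-free before the signal is
#' planted, so true sites never trip the internal-priming filter by chance;
#' the methods vignette discusses this idealization.
#'
#' @param config A `sim_config`.
#' @return List of class `apa_sim`: `config`, `genome` (named character),
#'   `gtf` (character lines), `ref_pas` (data.frame), `truth_sites`,
#'   `truth_genes` (data.frames).
#' @export
simulate_genome <- function(config) {
  validate_sim_config(config)
  L <- SIM_LAYOUT
  set.seed(config$seed)
  ng <- config$n_genes
  stages <- config$stages

  npas_vec <- if (length(config$pas_per_gene) == 1L) {
    rep(as.integer(config$pas_per_gene), ng)
  } else {
    sample(1:3, ng, replace = TRUE, prob = config$pas_per_gene)
  }
  is_artifact_gene <- stats::runif(ng) < config$artifact_rate
  strands <- rep(c("+", "-"), length.out = ng)

  usage_mats <- config$usage_by_stage
  if (!is.null(usage_mats) && is.matrix(usage_mats)) usage_mats <- list(usage_mats)

  genome <- character(ng)
  gtf <- character(0)
  site_rows <- vector("list", ng)
  gene_rows <- vector("list", ng)
  chroms <- sprintf("chr%04d", seq_len(ng))
  gene_ids <- sprintf("G%04d", seq_len(ng))

  ncomp <- max(length(stages) - 1L, 0L)

  for (i in seq_len(ng)) {
    npas <- npas_vec[i]
    lay <- sim_gene_layout(npas, config$pas_spacing)
    if (!is.null(config$gene_length)) {
      if (config$gene_length < lay$len) {
        stop(sprintf(paste0("gene_length %d too short to host the gene ",
                            "structure (needs >= %d nt for %d PASs)"),
                     config$gene_length, lay$len, npas), call. = FALSE)
      }
      lay$len <- as.integer(config$gene_length)
    }
    # sense-strand sequence in transcription coordinates
    s <- sample(c("A", "C", "G", "T"), lay$len, replace = TRUE)
    for (p in lay$pas) {
      zone <- max(0L, p - L$clean_radius):min(lay$len - 1L, p + L$clean_radius)
      s[zone + 1L] <- sample(c("C", "G", "T"), length(zone), replace = TRUE)
    }
    for (p in lay$pas) {
      m0 <- p - config$motif_offset
      s[(m0:(m0 + 5L)) + 1L] <- c("A", "A", "T", "A", "A", "A")
    }
    art_pos <- NA_integer_
    if (is_artifact_gene[i]) {
      a <- lay$artifact
      s[((a - 4L):(a + 5L)) + 1L] <- "A"
      art_pos <- a
    }
    sense <- paste(s, collapse = "")
    st <- strands[i]
    genome[i] <- if (st == "+") sense else revcomp(sense)

    # usage matrix (stages x npas)
    if (is.null(usage_mats)) {
      u <- matrix(stats::rgamma(length(stages) * npas, shape = 3),
                  nrow = length(stages))
      u <- u / rowSums(u)
    } else {
      u <- usage_mats[[((i - 1L) %% length(usage_mats)) + 1L]]
      if (ncol(u) != npas) {
        stop("usage_by_stage has ", ncol(u), " columns but gene ", gene_ids[i],
             " has ", npas, " PASs; fix pas_per_gene", call. = FALSE)
      }
    }
    rownames(u) <- stages

    # genomic coordinates
    tmap <- function(iv) {   # [s,e) transcription -> genomic
      if (st == "+") iv else c(lay$len - iv[2L], lay$len - iv[1L])
    }
    pmap <- function(p) if (st == "+") p else lay$len - 1L - p
    gpas <- pmap(lay$pas)

    # GTF lines (1-based inclusive)
    feat <- function(type, iv) {
      g <- tmap(iv)
      sprintf(paste0("%s\tapalong_sim\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; ",
                     "transcript_id \"%s.t1\";"),
              chroms[i], type, g[1L] + 1L, g[2L], st, gene_ids[i], gene_ids[i])
    }
    gtf <- c(gtf,
             feat("gene", c(lay$tx_start, lay$tx_end)),
             feat("transcript", c(lay$tx_start, lay$tx_end)),
             feat("exon", lay$exon1), feat("exon", lay$exon2),
             feat("CDS", lay$cds1), feat("CDS", lay$cds2),
             feat("five_prime_utr", lay$utr5), feat("three_prime_utr", lay$utr3))

    usage_cols <- as.data.frame(t(u))
    names(usage_cols) <- paste0("usage_", stages)
    site_rows[[i]] <- data.frame(gene_id = gene_ids[i], chrom = chroms[i],
                                 strand = st, position = gpas,
                                 pas_index = seq_len(npas), region = "3UTR",
                                 is_artifact = FALSE, usage_cols,
                                 stringsAsFactors = FALSE)
    if (is_artifact_gene[i]) {
      art <- data.frame(gene_id = gene_ids[i], chrom = chroms[i], strand = st,
                        position = pmap(art_pos), pas_index = NA_integer_,
                        region = "3UTR", is_artifact = TRUE,
                        stringsAsFactors = FALSE)
      for (cn in names(usage_cols)) art[[cn]] <- NA_real_
      site_rows[[i]] <- rbind(site_rows[[i]], art)
    }

    # expected direction per consecutive stage pair, and pattern
    dirs <- character(ncomp)
    for (k in seq_len(ncomp)) {
      dirs[k] <- true_red_direction(u[k + 1L, ], u[k, ])
    }
    pat <- if (ncomp >= 2L) {
      pk <- unname(PATTERN_MAP[paste(dirs[1L], dirs[2L], sep = ".")])
      if (is.na(pk)) "none" else as.character(pk)
    } else NA_character_
    gr <- data.frame(gene_id = gene_ids[i], chrom = chroms[i], strand = st,
                     n_pas = npas, has_artifact = is_artifact_gene[i],
                     stringsAsFactors = FALSE)
    for (k in seq_len(ncomp)) {
      gr[[paste0("dir_", stages[k + 1L], "_vs_", stages[k])]] <- dirs[k]
    }
    gr$expected_pattern <- pat
    gene_rows[[i]] <- gr
  }

  names(genome) <- chroms
  truth_sites <- do.call(rbind, site_rows)
  rownames(truth_sites) <- NULL
  truth_genes <- do.call(rbind, gene_rows)
  rownames(truth_genes) <- NULL

  true_sites <- truth_sites[!truth_sites$is_artifact, , drop = FALSE]
  in_ref <- stats::runif(nrow(true_sites)) < config$ref_frac
  ref_pas <- true_sites[in_ref, c("chrom", "strand", "position"), drop = FALSE]
  ref_pas <- ref_pas[order(ref_pas$chrom, ref_pas$strand, ref_pas$position), ,
                     drop = FALSE]
  rownames(ref_pas) <- NULL
  truth_sites$in_reference <- FALSE
  truth_sites$in_reference[!truth_sites$is_artifact] <- in_ref

  structure(list(config = config, genome = genome, gtf = gtf,
                 ref_pas = ref_pas, truth_sites = truth_sites,
                 truth_genes = truth_genes),
            class = "apa_sim")
}

# Direction implied by true usage fractions: RED rule applied to the exact
# per-stage proportions (treat = u2, ctrl = u1).
true_red_direction <- function(u_treat, u_ctrl, red_th = 0.05) {
  npas <- length(u_treat)
  if (npas < 2L) return("none")
  dpui <- u_treat - u_ctrl
  top <- order(-abs(dpui), seq_len(npas))[1:2]
  prox <- min(top)   # PAS indices are in transcription order; 1 = most proximal
  dist <- max(top)
  red <- dpui[dist] - dpui[prox]
  if (red >= red_th) "lengthening"
  else if (red <= -red_th) "shortening" else "unclassified"
}

#' @export
print.apa_sim <- function(x, ...) {
  cat(sprintf("apa_sim: %d genes, %d true PASs (%d artifact traps), seed %d\n",
              nrow(x$truth_genes), sum(!x$truth_sites$is_artifact),
              sum(x$truth_sites$is_artifact), x$config$seed))
  invisible(x)
}

#' Simulate per-sample 3'-end count tables
#'
#' Per sample, each gene's read total is drawn Poisson around
#' `reads_per_gene`, allocated multinomially over the gene's true PASs by the
#' stage's usage fractions, and each read end is scattered by rounded
#' Gaussian jitter (`jitter_sd`), clamped to the chromosome. Artifact genes
#' additionally receive `artifact_frac` x depth reads at the exact trap
#' position (internal priming anchors at the genomic A-run, so these reads
#' carry no jitter).
#'
#' @param config The `sim_config` used for [simulate_genome()].
#' @param sim The `apa_sim` object it produced.
#' @return List of class `apa_reads`: `samples` (named list of end-site
#'   data.frames chrom/strand/position/count), `sample_table` (sample, stage,
#'   replicate) and `depths` (genes x samples matrix of simulated totals,
#'   artifact reads included).
#' @export
simulate_reads <- function(config, sim) {
  stopifnot(inherits(sim, "apa_sim"))
  validate_sim_config(config)
  set.seed(config$seed + 7919L)
  ts <- sim$truth_sites
  chrlen <- nchar(sim$genome)
  stages <- config$stages
  sample_table <- data.frame(
    sample = paste0(rep(stages, each = config$replicates_per_stage), "_rep",
                    rep(seq_len(config$replicates_per_stage), length(stages))),
    stage = rep(stages, each = config$replicates_per_stage),
    replicate = rep(seq_len(config$replicates_per_stage), length(stages)),
    stringsAsFactors = FALSE)

  genes <- unique(ts$gene_id)
  depths <- matrix(0L, nrow = length(genes), ncol = nrow(sample_table),
                   dimnames = list(genes, sample_table$sample))
  out <- vector("list", nrow(sample_table))
  names(out) <- sample_table$sample

  for (j in seq_len(nrow(sample_table))) {
    stage <- sample_table$stage[j]
    ucol <- paste0("usage_", stage)
    pos_all <- integer(0); chr_all <- character(0); str_all <- character(0)
    for (g in genes) {
      rows <- ts[ts$gene_id == g, , drop = FALSE]
      true_rows <- rows[!rows$is_artifact, , drop = FALSE]
      depth <- stats::rpois(1L, config$reads_per_gene)
      alloc <- if (depth > 0L) {
        as.vector(stats::rmultinom(1L, depth, true_rows[[ucol]]))
      } else integer(nrow(true_rows))
      n_art <- 0L
      if (any(rows$is_artifact)) {
        n_art <- as.integer(round(config$artifact_frac * depth))
      }
      depths[g, j] <- depth + n_art
      if (depth + n_art == 0L) next
      ends <- rep(true_rows$position, alloc)
      if (length(ends) && config$jitter_sd > 0) {
        ends <- ends + as.integer(round(stats::rnorm(length(ends), 0,
                                                     config$jitter_sd)))
        ends <- pmin(pmax(ends, 0L), chrlen[[rows$chrom[1L]]] - 1L)
      }
      if (n_art > 0L) {
        ends <- c(ends, rep(rows$position[rows$is_artifact][1L], n_art))
      }
      pos_all <- c(pos_all, ends)
      chr_all <- c(chr_all, rep(rows$chrom[1L], length(ends)))
      str_all <- c(str_all, rep(rows$strand[1L], length(ends)))
    }
    key <- paste(chr_all, str_all, pos_all, sep = "\r")
    tb <- table(key)
    parts <- strsplit(names(tb), "\r", fixed = TRUE)
    df <- data.frame(chrom = vapply(parts, `[`, "", 1L),
                     strand = vapply(parts, `[`, "", 2L),
                     position = as.integer(vapply(parts, `[`, "", 3L)),
                     count = as.integer(tb), stringsAsFactors = FALSE)
    df <- df[order(df$chrom, df$strand, df$position), , drop = FALSE]
    rownames(df) <- NULL
    attr(df, "sample_id") <- sample_table$sample[j]
    out[[j]] <- df
  }
  structure(list(samples = out, sample_table = sample_table, depths = depths),
            class = "apa_reads")
}

#' @export
print.apa_reads <- function(x, ...) {
  cat(sprintf("apa_reads: %d samples (%s), %s reads total\n",
              nrow(x$sample_table),
              paste(unique(x$sample_table$stage), collapse = "/"),
              format(sum(x$depths), big.mark = ",")))
  invisible(x)
}

#' Write a simulation to disk
#'
#' Emits genome.fa (60-column FASTA), genes.gtf, ref_pas.bed,
#' truth_sites.tsv, truth_genes.tsv, samples.tsv and one BED6 per sample
#' under `reads/`. All outputs are sorted and byte-deterministic.
#'
#' @param sim An `apa_sim` object.
#' @param reads An `apa_reads` object (optional).
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_simulation <- function(sim, reads = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(genome = file.path(dir, "genome.fa"),
                gtf = file.path(dir, "genes.gtf"),
                ref_pas = file.path(dir, "ref_pas.bed"),
                truth_sites = file.path(dir, "truth_sites.tsv"),
                truth_genes = file.path(dir, "truth_genes.tsv"))
  write_genome(sim$genome, paths$genome)
  writeLines(sim$gtf, paths$gtf)
  write_refpas(sim$ref_pas, paths$ref_pas)
  write_tsv(sim$truth_sites, paths$truth_sites)
  write_tsv(sim$truth_genes, paths$truth_genes)
  if (!is.null(reads)) {
    rd <- file.path(dir, "reads")
    dir.create(rd, showWarnings = FALSE)
    paths$samples_tsv <- file.path(dir, "samples.tsv")
    write_tsv(reads$sample_table, paths$samples_tsv)
    paths$reads <- character(0)
    for (s in names(reads$samples)) {
      p <- file.path(rd, paste0(s, ".bed"))
      write_endsites(reads$samples[[s]], p, sample_id = s)
      paths$reads[s] <- p
    }
  }
  invisible(paths)
}
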