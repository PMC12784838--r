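# Stage orchestration: a declarative run configuration, file-based stage
# runners (each reads the previous stage's outputs from the run directory),
# and run_all() gluing them into one deterministic end-to-end analysis.

#' Build a run configuration
#'
#' Every tunable defaults to the pipeline's canonical value (24-nt cluster
#' width, priming thresholds 6 and 7, |DPUI| and p thresholds 0.05, RED
#' threshold 0.05, >5 reads and >=2 PASs retention, 24-nt reference match
#' window). A config echo is written to the run directory so no threshold can
#' deviate silently.
#'
#' @param outdir Run directory; all stage outputs land here.
#' @param genome,gtf,ref_pas Paths to the genome FASTA, gene-model GTF and
#'   (optional) reference PAS BED. Filled automatically by [run_simulate()].
#' @param samples data.frame with columns `sample`, `stage`, `bed` (per-sample
#'   3'-end BED paths). Filled automatically by [run_simulate()].
#' @param stages Ordered stage labels; consecutive pairs define the
#'   comparisons (later stage = treatment).
#' @param sim Optional [sim_config()]; when present, [run_simulate()] (or
#'   [run_all()]) generates the inputs.
#' @param cluster_width,bandwidth,min_peak_frac,min_sep Clustering tunables.
#' @param run_th,win_th Internal-priming thresholds (consecutive A; A per
#'   10 nt).
#' @param dpui_th,p_th,red_th Differential thresholds.
#' @param min_reads,min_pas Gene retention thresholds.
#' @param match_window Reference-PAS matching window (nt).
#' @param extension Downstream 3'UTR extension (nt).
#' @param upstream,halfwidth,kmer_min,kmer_max,n_shuffles Sequence-context
#'   tunables.
#' @param seed Seed for every stochastic step.
#' @return List of class `run_config`.
#' @export
run_config <- function(outdir, genome = NULL, gtf = NULL, ref_pas = NULL,
                       samples = NULL, stages = c("hESC", "NSC", "NPC"),
                       sim = NULL, cluster_width = 24L, run_th = 6L,
                       win_th = 7L, bandwidth = 8, min_peak_frac = 0.1,
                       min_sep = 8, dpui_th = 0.05, p_th = 0.05,
                       red_th = 0.05, min_reads = 5, min_pas = 2L,
                       match_window = 24L, extension = 1000L, upstream = 50L,
                       halfwidth = 100L, kmer_min = 4L, kmer_max = 6L,
                       n_shuffles = 10L, seed = 1L) {
  cfg <- structure(as.list(environment()), class = "run_config")
  if (!is.null(cfg$sim)) {
    # derived input paths are deterministic, so stage runners can be invoked
    # one at a time after `simulate` has written <outdir>/sim
    simdir <- file.path(outdir, "sim")
    if (is.null(cfg$genome)) cfg$genome <- file.path(simdir, "genome.fa")
    if (is.null(cfg$gtf)) cfg$gtf <- file.path(simdir, "genes.gtf")
    if (is.null(cfg$ref_pas)) cfg$ref_pas <- file.path(simdir, "ref_pas.bed")
    if (is.null(cfg$samples)) {
      st <- rep(cfg$sim$stages, each = cfg$sim$replicates_per_stage)
      sm <- paste0(st, "_rep", rep(seq_len(cfg$sim$replicates_per_stage),
                                   length(cfg$sim$stages)))
      cfg$samples <- data.frame(sample = sm, stage = st,
                                bed = file.path(simdir, "reads",
                                                paste0(sm, ".bed")),
                                stringsAsFactors = FALSE)
    }
    cfg$stages <- cfg$sim$stages
  }
  if (!is.null(cfg$samples)) {
    stopifnot(all(c("sample", "stage", "bed") %in% names(cfg$samples)))
  }
  cfg
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; `samples` is a list of
#' mappings with `sample`, `stage` and `bed`; `sim` is a mapping passed to
#' [sim_config()].
#'
#' @param path YAML file.
#' @param outdir Optional override of the configured output directory.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, outdir = NULL) {
  if (!file.exists(path)) stop("missing config file: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  if (!is.null(outdir)) y$outdir <- outdir
  if (is.null(y$outdir)) stop("config field missing: outdir", call. = FALSE)
  if (!is.null(y$samples)) {
    y$samples <- do.call(rbind, lapply(y$samples, function(s)
      data.frame(sample = s$sample, stage = s$stage, bed = s$bed,
                 stringsAsFactors = FALSE)))
  }
  if (!is.null(y$sim)) y$sim <- do.call(sim_config, y$sim)
  do.call(run_config, y)
}

config_echo <- function(cfg) {
  out <- cfg
  # relativize paths under the run directory so the echo is byte-stable
  rel <- function(p) if (is.null(p)) NULL else
    sub(paste0("^", gsub("([][{}()+*^$\\\\.|?])", "\\\\\\1",
                         normalizePath(cfg$outdir, mustWork = FALSE)), "/?"),
        "", normalizePath(p, mustWork = FALSE))
  out$outdir <- "."
  out$genome <- rel(cfg$genome)
  out$gtf <- rel(cfg$gtf)
  out$ref_pas <- rel(cfg$ref_pas)
  if (!is.null(cfg$samples)) {
    s <- cfg$samples
    s$bed <- vapply(s$bed, rel, "")
    out$samples <- lapply(seq_len(nrow(s)), function(i) as.list(s[i, ]))
  }
  out$sim <- if (is.null(cfg$sim)) NULL else unclass(cfg$sim)
  class(out) <- NULL
  yaml::write_yaml(out, file.path(cfg$outdir, "config_echo.yaml"))
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

need_file <- function(path, stage) {
  if (is.null(path) || !file.exists(path)) {
    stop(sprintf("[%s] missing input file: %s", stage,
                 if (is.null(path)) "(unset path)" else path), call. = FALSE)
  }
  path
}

out_path <- function(cfg, ...) file.path(cfg$outdir, ...)

#' Generate synthetic inputs for a run
#'
#' Runs [simulate_genome()] and [simulate_reads()] with `cfg$sim`, writes the
#' outputs under `<outdir>/sim/` and returns the config with `genome`, `gtf`,
#' `ref_pas` and `samples` pointing at them.
#'
#' @param cfg A `run_config` with a non-NULL `sim`.
#' @return The updated `run_config`, invisibly.
#' @export
run_simulate <- function(cfg) {
  if (is.null(cfg$sim)) stop("config field missing: sim", call. = FALSE)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_genome(cfg$sim)
  reads <- simulate_reads(cfg$sim, sim)
  paths <- write_simulation(sim, reads, out_path(cfg, "sim"))
  cfg$genome <- paths$genome
  cfg$gtf <- paths$gtf
  cfg$ref_pas <- paths$ref_pas
  cfg$samples <- data.frame(sample = reads$sample_table$sample,
                            stage = reads$sample_table$stage,
                            bed = unname(paths$reads), stringsAsFactors = FALSE)
  cfg$stages <- cfg$sim$stages
  stage_log("simulate", sprintf("%d genes, %d samples -> %s",
                                cfg$sim$n_genes, nrow(cfg$samples),
                                out_path(cfg, "sim")))
  invisible(cfg)
}

#' Filter internal-priming artifacts (stage runner)
#'
#' Loads all sample BEDs, merges them into a multi-sample site table, applies
#' [filter_sites()] against the genome and writes `sites_kept.tsv`,
#' `sites_artifacts.tsv` and `priming_verdicts.tsv`.
#'
#' @param cfg A `run_config` with `genome` and `samples` set.
#' @return The kept-site table, invisibly.
#' @export
run_filter <- function(cfg) {
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(cfg$samples)) stop("config field missing: samples", call. = FALSE)
  genome <- read_genome(need_file(cfg$genome, "filter-ip"))
  site_list <- lapply(seq_len(nrow(cfg$samples)), function(i) {
    read_endsites(need_file(cfg$samples$bed[i], "filter-ip"),
                  cfg$samples$sample[i])
  })
  names(site_list) <- cfg$samples$sample
  sites <- merge_endsites(site_list)
  res <- filter_sites(sites, genome, run_th = cfg$run_th, win_th = cfg$win_th)
  names(res$verdicts)[names(res$verdicts) == "window_sequence"] <-
    "window_sequence"
  write_tsv(res$kept, out_path(cfg, "sites_kept.tsv"))
  write_tsv(res$artifacts, out_path(cfg, "sites_artifacts.tsv"))
  write_tsv(res$verdicts, out_path(cfg, "priming_verdicts.tsv"))
  stage_log("filter-ip", sprintf(
    "%d sites in, %d kept, %d artifacts (A-run >= %d or %d A / 10 nt)",
    nrow(sites), nrow(res$kept), nrow(res$artifacts), cfg$run_th, cfg$win_th))
  invisible(res$kept)
}

#' Cluster kept sites into PACs (stage runner)
#'
#' Reads `sites_kept.tsv`, applies [cluster_sites()] and writes `pacs.tsv`
#' and `site_assignments.tsv`.
#'
#' @param cfg A `run_config`.
#' @return The `pac_set`, invisibly.
#' @export
run_cluster <- function(cfg) {
  sites <- read_tsv(need_file(out_path(cfg, "sites_kept.tsv"), "cluster"))
  ps <- cluster_sites(sites, width = cfg$cluster_width,
                      bandwidth = cfg$bandwidth,
                      min_peak_frac = cfg$min_peak_frac,
                      min_sep = cfg$min_sep)
  write_tsv(ps$pacs, out_path(cfg, "pacs.tsv"))
  write_tsv(ps$sites, out_path(cfg, "site_assignments.tsv"))
  stage_log("cluster", sprintf("%d sites -> %d PACs (width %d nt)",
                               nrow(ps$sites), nrow(ps$pacs),
                               cfg$cluster_width))
  invisible(ps)
}

#' Annotate PACs (stage runner)
#'
#' Reads `pacs.tsv`, assigns genes/regions from the GTF and, when a reference
#' PAS BED is configured, known/novel status; writes `pacs_annotated.tsv` and
#' `ref_distance_hist.tsv`.
#'
#' @param cfg A `run_config`.
#' @return The annotated PAC data.frame, invisibly.
#' @export
run_annotate <- function(cfg) {
  pacs <- read_tsv(need_file(out_path(cfg, "pacs.tsv"), "annotate"))
  models <- read_genemodels(need_file(cfg$gtf, "annotate"))
  pacs <- assign_region(pacs, models, extension = cfg$extension)
  if (!is.null(cfg$ref_pas) && file.exists(cfg$ref_pas)) {
    refs <- read_refpas(cfg$ref_pas)
    pacs <- match_reference(pacs, refs, match_window = cfg$match_window)
    write_tsv(ref_distance_hist(pacs), out_path(cfg, "ref_distance_hist.tsv"))
  }
  write_tsv(pacs, out_path(cfg, "pacs_annotated.tsv"))
  tab <- table(pacs$region)
  stage_log("annotate", paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                              collapse = " "))
  invisible(pacs)
}

comparisons_of <- function(stages) {
  if (length(stages) < 2L) return(list())
  lapply(seq_len(length(stages) - 1L), function(k)
    list(treat = stages[k + 1L], ctrl = stages[k],
         name = paste0(stages[k + 1L], "_vs_", stages[k])))
}

#' Differential APA and RED calls (stage runner)
#'
#' For each consecutive stage pair (later stage = treatment), calls
#' differential events with [call_events()] and 3'UTR RED directions with
#' [call_red()]; writes `events_<cmp>.tsv` and `red_<cmp>.tsv`.
#'
#' @param cfg A `run_config`.
#' @return Named list of `list(events, red)` per comparison, invisibly.
#' @export
run_diff <- function(cfg) {
  pacs <- read_tsv(need_file(out_path(cfg, "pacs_annotated.tsv"), "diff"))
  models <- read_genemodels(need_file(cfg$gtf, "diff"))
  if (is.null(cfg$samples)) stop("config field missing: samples", call. = FALSE)
  res <- list()
  for (cmp in comparisons_of(cfg$stages)) {
    treat <- cfg$samples$sample[cfg$samples$stage == cmp$treat]
    ctrl <- cfg$samples$sample[cfg$samples$stage == cmp$ctrl]
    ev <- call_events(pacs, treat, ctrl, min_reads = cfg$min_reads,
                      min_pas = cfg$min_pas, dpui_th = cfg$dpui_th,
                      p_th = cfg$p_th)
    red <- call_red(ev, models, red_th = cfg$red_th)
    write_tsv(as.data.frame(ev), out_path(cfg, paste0("events_", cmp$name, ".tsv")))
    write_tsv(red, out_path(cfg, paste0("red_", cmp$name, ".tsv")))
    stage_log("diff", sprintf(
      "%s: %d PACs tested, %d significant, %d lengthening / %d shortening",
      cmp$name, nrow(ev), sum(ev$significant),
      sum(red$direction == "lengthening"), sum(red$direction == "shortening")))
    res[[cmp$name]] <- list(events = ev, red = red)
  }
  invisible(res)
}

#' Four-pattern classification (stage runner)
#'
#' Intersects the RED calls of the first two comparisons and writes
#' `patterns.tsv`.
#'
#' @param cfg A `run_config` (needs >= 3 stages).
#' @return The pattern data.frame, invisibly.
#' @export
run_patterns <- function(cfg) {
  cmps <- comparisons_of(cfg$stages)
  if (length(cmps) < 2L) {
    stop("pattern classification needs at least 3 stages", call. = FALSE)
  }
  red1 <- read_tsv(need_file(out_path(cfg, paste0("red_", cmps[[1L]]$name, ".tsv")),
                             "patterns"))
  red2 <- read_tsv(need_file(out_path(cfg, paste0("red_", cmps[[2L]]$name, ".tsv")),
                             "patterns"))
  pat <- classify_patterns(red1, red2)
  write_tsv(pat, out_path(cfg, "patterns.tsv"))
  tab <- table(factor(pat$pattern, levels = c("1", "2", "3", "4", "none")))
  stage_log("patterns", paste(sprintf("pattern%s=%d", names(tab),
                                      as.integer(tab)), collapse = " "))
  invisible(pat)
}

#' Sequence-context QC (stage runner)
#'
#' Reads the annotated PACs and writes the nucleotide profile
#' (`nt_profile.tsv`), the AATAAA/ATTAAA positional densities
#' (`signal_density.tsv`) and the k-mer enrichment report
#' (`kmer_report.tsv`).
#'
#' @param cfg A `run_config`.
#' @return List with `profile`, `density`, `kmers`, invisibly.
#' @export
run_seqcontext <- function(cfg) {
  pacs <- read_tsv(need_file(out_path(cfg, "pacs_annotated.tsv"), "seqcontext"))
  genome <- read_genome(need_file(cfg$genome, "seqcontext"))
  prof <- nt_profile(pacs, genome, halfwidth = cfg$halfwidth)
  flanks <- extract_flanks(pacs, genome, upstream = cfg$upstream)
  dens <- signal_density(flanks, "AATAAA")
  dens$n_ATTAAA <- signal_density(flanks, "ATTAAA")$n
  names(dens)[names(dens) == "n"] <- "n_AATAAA"
  kmers <- kmer_enrichment(flanks, k_min = cfg$kmer_min, k_max = cfg$kmer_max,
                           n_shuffles = cfg$n_shuffles, seed = cfg$seed)
  write_tsv(prof, out_path(cfg, "nt_profile.tsv"))
  write_tsv(dens, out_path(cfg, "signal_density.tsv"))
  write_tsv(kmers, out_path(cfg, "kmer_report.tsv"))
  stage_log("seqcontext", sprintf(
    "%d flanks, top k-mer %s (%.1f%% of flanks)", nrow(flanks),
    if (nrow(kmers)) kmers$kmer[1L] else "-",
    if (nrow(kmers)) 100 * kmers$fg_frac[1L] else 0))
  invisible(list(profile = prof, density = dens, kmers = kmers))
}

#' Run the full pipeline
#'
#' Executes simulate (when configured), filter, cluster, annotate,
#' differential + RED, patterns (when >= 3 stages) and sequence context in
#' order, writes a machine-readable `summary.json`, a `config_echo.yaml` and
#' a `manifest.tsv`, and returns an `apa_run` object. With a fixed seed the
#' output tree is byte-identical across runs.
#'
#' @param cfg A `run_config`.
#' @return Object of class `apa_run`: config, pacs, events/red per
#'   comparison, patterns, seqcontext tables and the summary list.
#' @export
run_all <- function(cfg) {
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(cfg$sim)) cfg <- run_simulate(cfg)
  run_filter(cfg)
  ps <- run_cluster(cfg)
  pacs <- run_annotate(cfg)
  diffs <- run_diff(cfg)
  pat <- if (length(cfg$stages) >= 3L) run_patterns(cfg) else NULL
  sq <- run_seqcontext(cfg)

  summary <- list(
    n_sites_kept = nrow(ps$sites),
    n_pacs = nrow(pacs),
    pacs_per_region = as.list(table(pacs$region)),
    pacs_per_status = if ("status" %in% names(pacs))
      as.list(table(pacs$status)) else NULL,
    events = lapply(diffs, function(d) list(
      tested = nrow(d$events),
      significant = sum(d$events$significant),
      lengthening = sum(d$red$direction == "lengthening"),
      shortening = sum(d$red$direction == "shortening"))),
    genes_per_pattern = if (!is.null(pat))
      as.list(table(factor(pat$pattern,
                           levels = c("1", "2", "3", "4", "none")))) else NULL)
  jsonlite::write_json(summary, out_path(cfg, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  config_echo(cfg)
  files <- sort(setdiff(list.files(cfg$outdir, recursive = TRUE),
                        "manifest.tsv"))
  write_tsv(data.frame(file = files, stringsAsFactors = FALSE),
            out_path(cfg, "manifest.tsv"))
  structure(list(config = cfg, pacs = pacs, comparisons = diffs,
                 patterns = pat, seqcontext = sq, summary = summary),
            class = "apa_run")
}

#' @export
print.apa_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf("apa_run: %d PACs from %d kept end sites\n",
              s$n_pacs, s$n_sites_kept))
  reg <- unlist(s$pacs_per_region)
  cat("  regions: ", paste(sprintf("%s=%d", names(reg), reg), collapse = " "),
      "\n", sep = "")
  for (nm in names(s$events)) {
    e <- s$events[[nm]]
    cat(sprintf("  %s: %d tested, %d significant, %dL/%dS\n", nm, e$tested,
                e$significant, e$lengthening, e$shortening))
  }
  if (!is.null(s$genes_per_pattern)) {
    gp <- unlist(s$genes_per_pattern)
    cat("  patterns: ", paste(sprintf("%s=%d", names(gp), gp), collapse = " "),
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.apa_run <- function(object, ...) object$summary
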