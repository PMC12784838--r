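---
title: "Methods: calling and comparing polyadenylation sites from long-read 3' ends"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling and comparing polyadenylation sites from long-read 3' ends}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apalong)
```

## The problem

Most mammalian genes carry more than one polyadenylation site (PAS).
Alternative polyadenylation (APA) — the choice among these sites during
pre-mRNA 3'-end processing — shortens or lengthens the 3' UTR (or, for
upstream-region sites, truncates the coding sequence) and thereby rewires
miRNA and RNA-binding-protein regulation. Long-read sequencing observes each
transcript's 3' end directly, so a table of read 3'-end positions with counts
is, in principle, a direct measurement of PAS usage. Three obstacles stand
between the raw table and a usable PAS catalog:

1. **internal priming** — oligo(dT) primers anneal to genomically encoded
   A-stretches inside transcripts, producing spurious "3' ends";
2. **positional scatter** — true cleavage is heterogeneous and basecalling
   adds noise, so one PAS appears as a cluster of nearby end positions;
3. **usage, not expression** — the biological signal is the *fraction* of a
   gene's transcripts using each site, which must be compared across
   conditions with a significance test on proportions.

`apalong` implements the full path: artifact filtering, clustering into
polyadenylation site clusters (PACs), annotation, differential usage
statistics, and sequence-context QC, together with a synthetic-data
generator that makes every stage testable against known truth.

## Internal-priming filter

For every raw end site the 21-nt sense-strand window — 10 nt upstream, the
site base, 10 nt downstream — is extracted (reverse-complemented for
minus-strand sites). A site is an artifact when the window contains **6 or
more consecutive adenines** or **7 or more adenines within any 10-nt sliding
window** (stride 1). `N` and lowercase bases never count as adenine.

Two reading choices were genuinely open and are fixed as follows:

* *Window width.* "10 nt upstream and downstream" could mean 20 or 21 nt;
  the symmetric, site-inclusive 21-nt reading is used. The thresholds are
  insensitive to the one-base difference, which the enumeration tests
  confirm.
* *Strand.* The scan runs on the transcription-sense sequence, because
  internal priming is oligo(dT) annealing to A-stretches in the *mRNA*; a
  genomic T-run under a minus-strand gene is therefore caught exactly like
  the mirrored A-run on the plus strand (a property test asserts this
  symmetry).

Sites at a chromosome edge get a clipped window and are flagged; the rules
apply to whatever sequence exists.

## Clustering into PACs

**Primary clustering** is an iterative, count-ordered greedy scheme with a
24-nt radius, applied per (chromosome, strand): repeatedly take the
unassigned site with the highest summed count as a seed (ties: 5'-most in
transcription order) and absorb all unassigned sites within 24 nt. Because
seeds are chosen by count, the result is independent of input order — a
property verified against a brute-force reimplementation on a thousand
random instances. The highest-count-first reading also makes the later
"highest peak is the center PAS" rule coherent.

**Sub-PAC refinement** splits wide primary clusters with weighted
density-peak clustering. Each member's density is a count-weighted
triangular kernel sum,

$$\rho_i = \sum_j c_j \max\!\left(0,\ 1 - \frac{|x_i - x_j|}{h}\right),$$

with bandwidth $h$ = 8 nt. Peaks are members whose density exceeds 10% of
the maximum and that are at least 8 nt from any higher-density member; every
member joins its nearest peak (ties to the 5'-most peak). The kernel,
bandwidth, peak fraction and separation are this package's declared
defaults — chosen so sub-PACs resolve structure finer than the 24-nt primary
scale — and all are exposed as configuration keys. A unimodal cluster is
returned unchanged.

The **center PAS** of each final PAC is the member with the maximal summed
count, ties to the 5'-most member.

## Annotation

Each PAC is assigned by its center against one representative transcript per
gene (the transcript with the 3'-most annotated end; ties to the longest).
Region precedence when annotations overlap is **3UTR > exon/CDS > intron >
5UTR** — polyadenylation evidence most plausibly terminates a 3' UTR. A
center within 1,000 nt downstream of an annotated transcript end (same
strand, transcription direction) is labelled 3UTR (extended); everything
else is intergenic and excluded from gene-level statistics.

Against a reference PAS table, each center receives a signed distance to the
nearest same-strand reference site (downstream in transcription = positive;
ties to the transcriptionally upstream site). Status is `exact_match` at
distance 0, `matched` within 24 nt (the clustering scale), otherwise
`novel`. The exact-match count is reported separately because a perfect hit
is qualitatively different from a near hit.

## Differential usage

Only genes with at least two PACs having **more than 5 reads** (strict) in
*each* comparison group are retained; the strictness prevents a site absent
from one condition from entering the test. Percentage of site usage (PSU)
is, per sample, a PAC's count divided by the gene's total over retained
PACs. The differential PSU index is

$$\mathrm{DPUI} = \overline{\mathrm{PSU}}_{\mathrm{treat}} -
\overline{\mathrm{PSU}}_{\mathrm{ctrl}},$$

the difference of replicate-mean PSUs. Significance comes from a
two-proportion Wald test on counts **pooled across replicates within each
group**: with two replicates a replicate-level variance estimate is
degenerate, so the pooled sampling unit is the only well-posed choice; the
pooling is recorded in the output metadata. The statistic is

$$z = \frac{\hat p_1 - \hat p_2}
{\sqrt{\hat p_1(1-\hat p_1)/n_1 + \hat p_2(1-\hat p_2)/n_2}},$$

two-sided normal p-value; a variance term that is exactly zero (proportion 0
or 1) is floored at $0.5/n$ of its group, which is deliberately
conservative. An event is significant when $|\mathrm{DPUI}| \ge 0.05$ and
$p \le 0.05$; headline calls use raw p-values, with Benjamini–Hochberg
q-values emitted alongside for users who want them. Null calibration on
synthetic data (2,000 genes, 100 reads per group) puts the rejection rate
near the nominal 5%, and the joint rule can only remove calls.

For 3' UTR APA, the two 3'UTR PACs with the largest $|\mathrm{DPUI}|$ in
each gene (requiring at least one significant 3'UTR event) give the relative
end offset

$$\mathrm{RED} = \mathrm{DPUI}_{\mathrm{distal}} -
\mathrm{DPUI}_{\mathrm{proximal}},$$

with proximal/distal decided by transcription-order distance from the 3' end
of the last CDS-bearing exon (the terminal-exon anchor — strand-uniform and
defined for every coding gene). $\mathrm{RED} \ge 0.05$ is 3' UTR
lengthening, $\le -0.05$ shortening, otherwise unclassified. Swapping the
groups negates every DPUI and RED and flips every direction exactly.

Across a three-stage design, the two successive comparisons are intersected
into four dynamic patterns: persistent lengthening (1), lengthening then
shortening (2), persistent shortening (3), shortening then lengthening (4);
genes with a directional call in only one comparison are "none". The five
labels partition the gene universe.

## Sequence-context QC

Nucleotide composition is profiled over ±100 nt around each center
(sense-oriented; N and clipped positions leave the denominator). The
canonical signal's positional density is a histogram of AATAAA start
offsets, overlapping occurrences included, over the 50-nt upstream flank.

For motif *enrichment* the package deliberately does not re-implement a
PWM/E-M discovery tool. Instead it asks the same question with a
transparent, testable statistic: for every exact k-mer (k = 4–6), the
fraction of flanks containing it, against the containment rate in ten
dinucleotide-shuffled copies of each flank, with a one-sided binomial test.
P-values are computed on the log scale so that a planted motif and its
substrings do not collapse into an underflow tie; the motif with the lowest
background rate then ranks first, as it should. Shuffles preserve
dinucleotide composition (rejection-sampled Eulerian walks with a plain
shuffle fallback) and are seed-deterministic.

## The synthetic-data generator

The generator is first-class, tested code; its defaults describe the study
design the pipeline targets: three stages (hESC → NSC → NPC), two
replicates each, Poisson depth around 300 reads per gene per sample, and a
PAS-count distribution under which roughly 43% of genes have two or more
sites. Each gene occupies its own chromosome (strands alternating, which
forces strand-correctness everywhere downstream) with a fixed two-exon
coding structure and 100-nt spacing between true PASs. Per-stage usage is
either user-specified (stage × PAS matrices) or drawn from a symmetric
Dirichlet. Read ends scatter around the true PAS with discretized Gaussian
jitter (sd 3 nt by default) — matching the unimodal end-scatter that
motivates 24-nt clustering without inventing a platform error model.
Replicate noise is multinomial resampling. AATAAA is planted starting 21 nt
upstream of every true PAS, inside the canonical 20–30 nt positioning
window. Artifact genes (10% by default) carry a 10-nt genomic A-run in the
3' UTR that receives 20% of the gene's depth as internal-priming reads.

The gene-level truth (expected lengthening/shortening per comparison and the
four-pattern label) is derived by applying the RED rule to the exact usage
fractions, so recovery tests compare the pipeline against an analytically
known answer.

Two idealizations matter for interpreting test results. First, sequence
within 40 nt of a true PAS is drawn A-free (before the signal is planted),
so a true site never trips the priming filter by chance; real 3' UTRs are
A-rich enough that a genuine PAS occasionally fails the rule, and the
filter's false-negative cost on real data is *not* measured here. Second,
artifact reads carry no positional jitter — priming anchors at the genomic
A-tract — so "100% artifact removal" on synthetic data reflects the planted
trap exactly, not the fuzzier boundary behaviour of real mispriming.
Likewise the generator makes no attempt at ONT basecall error profiles,
poly(A)-tail lengths, or isoform-level splicing; passing tests demonstrate
the correctness of the algorithms under the stated model, not end-to-end
accuracy on real ONT runs.

## Numerical and degenerate-input choices

* All internal coordinates are 0-based (BED convention); GTF I/O converts to
  1-based inclusive exactly once at the file boundary. A minus-strand read's
  3' end is the BED start of its record, i.e. positions always name the
  transcriptionally last base.
* Ties everywhere break toward the 5'-most position in transcription order
  (highest genomic coordinate on the minus strand), making all outputs
  deterministic and strand-symmetric.
* A sample in which a retained gene has zero reads yields missing PSU,
  excluded from the group mean; a group with zero gene total yields a
  missing p-value.
* Empty inputs propagate as empty outputs (no errors); filtering is
  idempotent; clustering partitions its input exactly.
* Every stochastic step (simulation, shuffles) takes an explicit seed, and a
  fixed seed reproduces all outputs byte-for-byte, including across the
  file-based stage runners.

## Problem sizes used in the checks

The packaged verification suite runs: enumeration-oracle agreement on
10,000 random 21-nt windows plus all 65,536 length-8 cores in fixed flanks;
clustering-oracle agreement on 1,000 random instances of up to 30 sites;
PAS recovery and artifact removal on a 200-gene genome (jitter sd 3);
Wald calibration on 2,000 null genes at 100 reads per group; RED direction
recovery on 500 genes with a planted 0.3 usage shift at 200 reads per
group; four-pattern recovery on 4 × 50 genes at 300 reads per stage; and a
30-gene end-to-end determinism run. These sizes give binomial standard
errors comfortably below the asserted margins while keeping the whole suite
interactive.

## Known limitations

* One representative transcript per gene: transcript-level APA within a gene
  (e.g. alternative last exons of minor isoforms) is collapsed onto the
  representative model.
* The density-peak refinement parameters are declared defaults, not values
  inferred from data; very closely spaced true PASs (< ~8 nt) merge.
* The k-mer statistic reports containment enrichment, not a motif model; it
  will not discover degenerate motifs that never repeat an exact word.
* Non-coding genes have no terminal-exon anchor and therefore receive no
  RED call.
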