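---
title: "Methods: statistics and sequence mining for normalized EST surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: statistics and sequence mining for normalized EST surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(estsurvey)
```

This vignette records the modeling and algorithmic decisions behind
`estsurvey`. The package implements the analytical core of a classic
expressed-sequence-tag (EST) survey — normalization, quality trimming,
clustering, redundancy statistics, completeness classification,
microsatellite (SSR) mining, and candidate-SNP calling — together with a
synthetic survey generator so that every stage can be validated against
known truth.

## The DSN normalization model

cDNA normalization with a duplex-specific nuclease (DSN) depletes abundant
transcripts because reassociation after denaturation follows second-order
kinetics: the double-stranded (destroyed) fraction of transcript *i* grows
with its concentration. We model the surviving single-stranded fraction of
a transcript with relative abundance $p_i$ as

$$s_i = \frac{1}{1 + \theta\, p_i},$$

where $\theta$ aggregates concentration, time and rate constant
($\theta = k C_0 t$). The normalized abundance profile is
$q_i \propto p_i s_i$, renormalized to sum to one.

`calibrate_theta(p, gene, target_fold)` solves for the $\theta$ that
reduces gene's *normalized share* by the requested fold, using
`stats::uniroot` on the bracket $[0, 10^{12}]$. Because the $q_i$ are
renormalized, the achievable fold on a share is bounded: as
$\theta \to \infty$, $q_i \to 1/n$ for an $n$-gene profile, so the largest
achievable fold for gene $g$ is $p_g \cdot n$. Requests beyond that limit
are an error rather than a silent clamp.

```{r}
p <- sample_abundances(2000, log_mean = 0, log_sd = 3, seed = 9)
g <- which.max(p)
theta <- calibrate_theta(p, g, target_fold = 40)
q <- dsn_normalize(p, theta)
p[g] / q[g]
```

This mirrors the laboratory verification of normalization by colony blots:
a 40-fold drop of a dominant transcript's clone frequency
(`fold_reduction(360, 9000, 9, 9000)`).

## The synthetic survey generator

`make_transcriptome()` draws gene lengths (normal, default 900 ± 150 nt)
and lognormal abundances, and plants ground truth into each gene pair of
haplotypes: perfect SSR tracts (units such as AC, AAT, ATCC, 7–12 copies,
with flanking bases randomized so the planted tract stays maximal) and one
biallelic SNP per selected gene, placed away from the SSR tract. A coding
region spans 15–75% of each transcript. `simulate_reads()` samples genes by
abundance, 5'-anchors each read with a small geometric offset (sequencing
from the 5' end of oligo-dT-primed clones), and decays base quality
linearly with position plus noise; bases are miscalled with probability
$10^{-Q/10}$. Everything is returned with a truth table, and
`write_survey()` emits FASTQ plus truth TSV.

## Quality trimming

Three rules, following the Lucy conventions:

* **bracket rule** — both terminal bases of the kept interval must have
  error probability at most 0.001 (Q30);
* **window rule** — every 10-base window inside the kept interval must
  have mean error at most 0.063 (intervals shorter than a window are held
  to the bound on their own mean);
* **pass rule** — a read passes if it retains 100 contiguous bases with
  mean quality at least Q20.

`trim_read()` returns the longest (leftmost on ties) interval satisfying
the bracket and window rules *jointly*. We chose this global semantics
over "bracket first, then windows" because the sequential reading is not
idempotent: the window stage can select an interval whose new terminal
base violates the bracket bound, so trimming the trimmed read would trim
again. The global interval is provably idempotent and monotone in quality,
and the test suite checks both properties plus exact agreement with an
exhaustive interval search.

## Clustering

Reads are clustered single-linkage on shared canonical 16-mers (a k-mer
and its reverse complement count as one), with an edge requiring at least
3 shared k-mers. Two design points matter:

* k-mers within 2 mismatches of a period-1..4 tandem repeat are excluded
  from indexing. Without this filter, two unrelated genes that both carry
  an AC-repeat (or a sequencing error inside one) are spuriously linked —
  exactly the low-complexity masking an assembler would apply.
* union–find plus a per-read gather over an integer k-mer index keeps the
  clusterer near-linear; no quadratic pair counting.

`summarize_clusters()` reduces an assignment to the survey quantities
(reads $n$, distinct sequences $d$, singletons $n_1$, contigs). Real
assemblies can be imported from ACE files (`read_ace()`) or membership
TSVs.

## Redundancy statistics

Two estimators of library coverage are provided:

* empirical: $1 - d/n$, the in-sample redundancy used for the published
  per-library table (default);
* Good–Turing: $1 - n_1/n$, the probability that the *next* read hits an
  already-seen gene, which the suite verifies is nearly unbiased
  (|bias| < 0.01 at $n = 5000$ over 100 simulated libraries).

The reads-per-discovery statistic is $n/d = 1/(1-\text{coverage})$.
Recomputing the 19 published library rows from their printed counts
reproduces every printed coverage value and 18 of 19 printed discovery
values; the remaining row (library Re4, printed 1.309) contradicts its own
printed counts (11,298/7,468 = 1.513) and printed coverage (0.3390 implies
1.513). The package reports the self-consistent value and
`tilapia_library_counts()` documents the discrepancy.

## Completeness, SSRs, SNPs

**Completeness.** For each EST's best protein hit (lowest e-value, then
highest subject coverage, then lexicographic subject id), the EST is
complete at the 5' end if the hit starts within 10 residues of the
protein's N-terminus and at the 3' end if it ends within 10 residues of
the C-terminus; proportions are tabulated by protein size class (≤250,
251–500, 501–750, 751–1000, >1000 residues).

**SSRs.** `find_ssrs()` reports maximal perfect tandem repeats of 2–4 bp
units with tract length ≥ 24 bp (the Sputnik-style configuration),
excluding homopolymer-equivalent units, breaking tracts at N, reporting
each tract at its smallest generating unit, and resolving overlaps
longest-first. Motifs are canonicalized over rotations and reverse
complement, so GT-repeats and AC-repeats pool. The finder is tested for
exact agreement with a brute-force anchor-and-extend oracle on hundreds of
repeat-rich random sequences, and for recovery of every planted tract.

**SNPs.** `call_variant_columns()` scans alignment columns; gaps and N
never count as alleles. A candidate column has ≥ 2 distinct bases; the
confidence filter keeps it when at least two alleles are each seen ≥ 2
times; three well-supported alleles mark the column multiallelic, which is
excluded from the transition/transversion ratio. On error-free synthetic
surveys the filtered calls coincide exactly with the planted sites that
have two covering reads of each haplotype, and the number of passing sites
matches the binomial prediction $1 - 2(1+k)/2^k$ (for $k$ covering reads)
within 3σ.

## Problem sizes and runtime

The full test suite (module tests plus acceptance) runs in a few minutes
on one CPU: oracle-equivalence suites use >1,000 random instances
(trimming 400+, SSR 350+, SNP 300+ in the acceptance block alone, with
further instances in the module tests), simulated surveys use 10–60 genes
and 120–1,200 reads, and the Good–Turing bias study uses 100 libraries of
5,000 reads over 2,000 genes.

## Limitations

* The generator's positional alignments sidestep real assembly; CAP3-class
  alignment is out of scope (ACE import covers the real case).
* The DSN model treats transcripts independently (no cross-hybridization).
* The completeness stage synthesizes protein hits from simulation truth
  when no external search results are supplied; it parses standard
  12-column tabular hits when they are.
* Published aggregate counts are reproduced by arithmetic, not by re-running
  the original pipeline on the original reads, which are not bundled.
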