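---
title: "Building abundance unitig matrices from multi-sample sequencing data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building abundance unitig matrices from multi-sample sequencing data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(unitigr)
```

## The problem

A k-mer matrix — rows are the distinct canonical k-mers seen anywhere in a
cohort, columns are samples, cells are abundance counts — is a powerful
reference-free representation of a collection of sequencing samples, but a
hugely redundant one: consecutive k-mers of the same genomic locus carry
nearly identical rows. Unitigs, the maximal non-branching paths of the de
Bruijn graph over those k-mers, remove exactly that redundancy: each locus
that is internally unambiguous collapses to a single sequence. `unitigr`
builds, for a set of samples given as FASTA/FASTQ files, a **unitig
matrix** in which each cell holds two numbers per unitig $u$ and sample
$S$: the fraction of $u$'s constituent k-mers that are present in $S$,

$$f(u,S) = \frac{1}{N}\sum_{i=1}^{N} x_i,$$

where $N$ is the number of k-mers in $u$ and $x_i$ indicates whether the
$i$-th k-mer has a non-zero count in $S$, and their average abundance,

$$A(u,S) = \frac{1}{N}\sum_{i=1}^{N} c_i,$$

where $c_i$ is the count of the $i$-th k-mer in $S$. Averaging counts along
a unitig is a robust estimate of the locus' abundance in the sample, and
$f$ quantifies how completely the sample supports the unitig, which matters
because a unitig is assembled from the *union* of all samples and need not
be fully present in any one of them.

## Pipeline and model assumptions

The pipeline has four stages, each exposed as an ordinary function (and as
a CLI subcommand in `inst/cli/unitigr.R`):

1. **Counting** (`kmer_count_matrix()`). Every sample's reads are scanned
   with a rolling 2-bit encoder; each window of size $k$ inside a maximal
   A/C/G/T run is canonicalized (the lexicographic minimum of the k-mer and
   its reverse complement under A<C<G<T) and tallied. Counts below
   `min_abundance` are zeroed at counting time, so a sub-floor k-mer is
   absent from that sample for every downstream purpose — there is exactly
   one notion of presence in the package, count > 0 in the matrix.
2. **Filtering** (`filter_kmer_matrix()`). Only k-mers that can
   discriminate between samples are kept: present in at least
   `min_present` of the samples *and* absent in at least `min_absent` of
   them (defaults 10% / 10%, either side optionally an absolute count).
3. **Compaction** (`build_unitigs()`, `filter_unitigs()`). The surviving
   canonical k-mers are the nodes of a bidirected de Bruijn graph;
   maximal non-branching paths are spelled out as unitigs, and unitigs
   shorter than `2k - 1` bp (fewer than $k$ k-mers) are dropped by
   default, with their k-mers recorded so the matrix rows can be skipped.
4. **Aggregation** (`unitig_index()`, `unitig_matrix()`). An exact
   dictionary maps every k-mer to its unique (unitig, offset, strand); the
   filtered matrix is streamed row by row into per-unitig presence and
   abundance accumulators, finalized by dividing by $N$.

The central modelling assumptions are: odd $k$ (no self-reverse-complement
k-mers, which would break the bidirected graph logic), $k \le 31$ (one
64-bit word per k-mer), and strand-symmetric data (forward and reverse
reads must count identically, hence canonicalization).

## Parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 31 | k-mer size, odd, 3–31 |
| `min_abundance` | 2 | per-sample count floor at counting; singletons are overwhelmingly sequencing errors. Set to 1 to keep everything |
| `min_present`, `min_absent` | 0.1, 0.1 | discriminative-filter thresholds, fractions of the cohort (or absolute counts via `abs_present`/`abs_absent`) |
| `min_unitig_length` | `2k - 1` bp | minimum unitig length; anything shorter carries fewer than $k$ k-mers |
| `min_frac` (binarization) | 0.8 | a unitig counts as present in a sample when ≥ 80% of its k-mers are; in real cohorts the per-sample mean fraction of present k-mers sits near 80% regardless of unitig length, so this bar separates genuinely carried unitigs from partial overlaps |

Fractional thresholds resolve to counts with a ceiling, floored at one:
"at least 10%" of 15 samples is 2 samples, never 1 — a strict reading that
never rounds a requirement down. The two resolved thresholds must satisfy
$t_{present} + t_{absent} \le n$, otherwise no row can pass and the
configuration is rejected before any work is done.

## Design choices where the design was open

**Canonicalization and non-ACGT policy.** Canonical form is the
lexicographic minimum of a k-mer and its reverse complement; this is the
dominant convention among k-mer counters, so the matrices interoperate.
Windows that span an N or any other non-ACGT character are skipped
entirely — ambiguous bases must not fabricate k-mers. Lowercase
(soft-masked) bases are accepted and uppercased.

**Compaction conventions.** Adjacency is never stored: neighbors of an
oriented k-mer are found by membership queries on its four one-base
extensions, so memory is proportional to the k-mer set. A path is extended
from oriented node $x$ to $y$ only under mutual uniqueness — $y$ is $x$'s
only forward neighbor *and* $x$ is $y$'s only backward neighbor; anything
weaker would merge across branches and break the k-mer→unitig bijection
that aggregation relies on. Edges from a node to its own reverse
complement (hairpins) or to itself (homopolymer loops) arise from
canonical identification rather than from the underlying sequence and are
excluded from adjacency; including them would spuriously split the unitig
spelling, e.g., the locus `ACGGT`. Isolated simple cycles are linearized
starting at their smallest canonical k-mer (a cycle of $m$ nodes yields
one unitig of $m + k - 1$ bp, the wrap-around overlap not duplicated).
Every unitig is reported in its canonical orientation (min of sequence and
reverse complement — odd $k$ makes ties impossible) and unitigs are sorted
by sequence with dense 0-based ids. These conventions make the output a
deterministic function of the k-mer set: byte-identical across runs,
insertion orders, thread counts, and strand flips of the input.

**The index.** The k-mer→unitig dictionary is an exact hash over the
packed codes rather than a minimal-perfect-hash structure; at the scales
this package targets, the space optimization buys nothing and exactness
simplifies the defensive checks (a duplicated k-mer across unitigs is
reported with both locations).

**Matrix dialects.** The k-mer matrix is one line per k-mer — the
canonical string and one count per sample, single-space separated,
optionally gzipped, with an optional `#kmer ...` header. The unitig matrix
is written as two parallel files, `<prefix>.frac.mat` and
`<prefix>.abundance.mat` (ids match the unitig FASTA headers exactly),
with an optional combined `f:a` file; values are formatted to 2 decimals
by default for compact deterministic files, with full precision behind
`digits = NULL`.

## The synthetic-data generator

`sim_dataset()` emulates a small cohort: one ancestral random genome
(i.i.d. uniform bases), one variant per sample obtained by per-base
substitutions (`snp_rate`) and single-base indels (`indel_rate`), and
fixed-length reads with independent substitution errors (`error_rate`).
Reads are placed at evenly spaced start positions at the requested depth:
with uniformly random placement the first and last windows of a linear
genome are covered only by reads starting at one exact position, so
error-free reconstruction of a genome would fail at its ends with
appreciable probability at any realistic depth; tiling makes stated
coverage a guarantee that every window is sampled, while strand choice and
errors remain random. All randomness flows from one explicit integer seed
(per-sample seeds are derived deterministically), so every dataset is a
pure function of its arguments.

Defaults (10 samples, 10 kb genome, SNP rate 0.005, indel rate 5e-4,
depth 10, 100 bp reads, error rate 0.001) describe a small bacterial-style
cohort with strain-level divergence — enough variation that the
discriminative filter retains a meaningful k-mer set.

What the generator does *not* emulate: realistic error and quality
profiles, coverage biases, repeats beyond what i.i.d. sequence produces,
contamination, or ancient-DNA damage. Passing tests on this data show the
pipeline's algebra and determinism are right; they do not certify
behaviour on real libraries with structured artefacts.

## Numerical and degenerate-input behaviour

* Counts are integers throughout; $f$ and $A$ are exact ratios of integer
  accumulators to $N$, so `f * N` and `A * N` are integers before
  formatting, and $f = 0 \iff A = 0$.
* An empty filtered matrix is not an error: the pipeline warns and writes
  empty downstream files with a complete manifest.
* A sample with no k-mers above the floor yields a valid empty table plus
  a warning.
* Matrix rows whose k-mer belongs to a length-filtered unitig are skipped
  during aggregation and counted in the manifest
  (`kmer_rows_skipped_in_aggregation`); index k-mers never seen in the
  matrix contribute zeros implicitly.
* Parallelism (`threads`) applies to per-sample counting only, and tables
  are merged in manifest order, so results are independent of the thread
  count.

## Worked example

```{r example}
u <- build_unitigs(c("ACC", "ACG", "CCG"), k = 3)
u$sequence                      # one unitig "ACCGT", N = 3 k-mers

m <- merge_tables(list(tibble::tibble(kmer = c("ACC", "CCG"),
                                      count = c(2L, 4L))), "s1", k = 3)
um <- unitig_matrix(m, unitig_index(u))
um                               # f = 2/3, A = (2 + 4 + 0) / 3 = 2
```

Two of the unitig's three k-mers are present in the sample, giving
$f = 0.67$ after formatting; their counts 2, 4 and 0 average to
$A = 2.00$.

## Test problem sizes

The shipped test-suite and acceptance script size their simulations for a
single CPU: compaction is cross-checked against a brute-force
maximal-path oracle on 200 random k-mer sets (k ∈ {3, 5}, up to 200
k-mers); genome reconstruction uses 50 random genomes of 300–2000 bp with
error-free reads at depth 10; the SNP-scaling study uses a 20 kb ancestor
with three variants at rates 0.001/0.005/0.01 over three seeds. These
sizes exercise every code path while keeping a full run under a minute.

## Known limitations

* $k \le 31$, single-word codes; no multi-word or spaced seeds.
* Counting is in-memory per sample; the package targets desk-scale
  cohorts, not terabyte collections (no external-memory partitioning).
* The matrix cannot be updated incrementally when a sample is added; the
  graph is a union over the cohort and must be rebuilt.
* Aggressive filtering can, as in any union-graph method, yield chimeric
  unitigs spliced from different samples' haplotypes; $f(u,S)$ is the
  diagnostic to watch.
* `kmer_encode()`/`kmer_decode()` expose integer codes only for
  $k \le 26$, where R doubles are exact; the pipeline itself identifies
  k-mers by canonical strings at the R boundary and is unaffected.
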