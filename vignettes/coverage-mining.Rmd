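---
title: "Mining irreducible regions of expression from RNA-seq coverage"
author: "covmine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining irreducible regions of expression from RNA-seq coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(covmine)
```

## The model

`covmine` treats bulk RNA-seq as a per-nucleotide *coverage function*: the
number of aligned reads overlapping each position of the genome. Reads are
reduced to their minimal attribute set — chromosome, start, end, strand — so
the pipeline is independent of the sequencing platform, the mapper and its
settings, and works for unstranded protocols (`strand_mode = "ignore"`).
Alignments are treated as single ungapped blocks; junction reads and
split-alignment modelling are deliberately out of scope, which makes every
operation exact under chunked whole-chromosome scans (a read contributes its
clipped overlap to each chunk).

Internally every coordinate is 0-based and half-open. The 1-based inclusive
conventions of SAM, GTF/GFF3 and the plain read table are converted exactly
at the I/O boundary and nowhere else; BED and bedGraph pass through natively.

### Irreducible regions

Fix a coverage threshold $\mu \ge 0$. A window $v_1,\dots,v_n$ of the
coverage vector is *irreducible* at level $\mu$ when every split point
leaves both sides with mean $\ge \mu$; equivalently, all prefix means and
all suffix means are $\ge \mu$. Two consequences follow directly and are
enforced as tested invariants:

* an irreducible region starts and ends with a value $\ge \mu$;
* two overlapping (or abutting) irreducible intervals merge into a larger
  irreducible interval, so *maximal* irreducible regions are pairwise
  disjoint.

`find_irreducible_regions()` returns exactly the maximal irreducible
intervals, then filters them to width $\ge$ `minsup`. Maximality is decided
*before* the width filter, so a sub-interval of a long region is never
reported just to pass `minsup`.

The implementation (C++, `src/mining.cpp`) scans the prefix sums
$S_k = \sum_{i \le k}(v_i - \mu)$: the interval $[i, j)$ is irreducible iff
$S_i$ is the minimum and $S_j$ the maximum of $S$ on $[i..j]$. A greedy
left-to-right scan opens a region at any position with $v \ge \mu$,
extends it to the last admissible maximum of $S$, and continues after it.
The exact window bookkeeping is intentionally *not* part of the contract:
the contract is "output identical to exhaustive enumeration", and
`brute_force_regions()` — a pure-R oracle that tests the definition on every
sub-interval — is kept in the package and compared against the scanner on
thousands of random Poisson and negative-binomial vectors in the test suite.
The oracle refuses vectors longer than a guard (default 10,000) because its
enumeration is quadratic.

### Why this fits exons

The definition encodes three behaviors that matter in practice, all covered
by dedicated tests:

* **local dips are bridged** — coverage may fall below $\mu$ inside an exon
  (GC bias, mappability) without splitting the region, as long as the
  flanking coverage carries the means;
* **lone artifact peaks are rejected** — a duplicate-read stack narrower
  than `minsup` yields no region; the default `minsup` = read length + 1
  (51 for 50 bp reads) makes a single stack exactly too narrow;
* **boundaries are conservative** — regions can only start and end at
  positions with coverage $\ge \mu$.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `mu` | 5 | detection threshold on coverage (reads/base); 5 is a common choice for "expressed at all". Adaptive resolvers `mu_fraction_of_max()` / `mu_fraction_of_min()` compute $\mu$ from the current track slice instead. |
| `minsup` | 51 nt | minimum region width; set just above the read length so one duplicated stack cannot form a region |
| `f` | 0.1 | lowess span for optional pre-mining smoothing; stabilizes boundaries and damps amplification peaks. Negative fitted values are clipped to 0 so smoothed tracks remain valid miner input. |
| `pseudocount` | 1 | additive guard in fold change and splicing index for zero-coverage positions |
| `mu_si` | 1.0 | threshold on \|SI\|; 1 means a two-fold relative inclusion change |
| `flank` | 1000 nt | widening of gene bodies in the `extended` discovery category (typical UTR-extension range) |
| `chunk_size` / `chunk_overlap` | 2 Mb / 10 kb | bounded-memory scan windows; the overlap far exceeds plausible region lengths |

Comparisons with $\mu$ are non-strict (mean $\ge \mu$). Coverage is integer
(or lowess-smoothed rational), so ties with integer $\mu$ are common, and
the single-element base case ($[v]$ irreducible iff $v \ge \mu$) forces the
non-strict reading for consistency. Whether the historical convention was
strict is not decidable from the literature we follow, so a `strict` flag
exists for parity experiments; both modes are oracle-verified. A numeric
tolerance of $10^{-9}$ absorbs floating-point noise on smoothed tracks;
negative input values are a domain error (mine $|SI|$, not SI).

### Splicing index

For two samples with per-nucleotide coverages $E1_n, E2_n$ and read counts
$G1, G2$ in the enclosing gene,

$$SI_n = \log_2 \frac{(E1_n + p)/G1}{(E2_n + p)/G2}.$$

This is the exon-array splicing-index convention carried to nucleotide
granularity: normalizing by the gene-level counts cancels overall expression
differences, so $|SI| \ge 1$ flags positions whose *relative* inclusion
changes at least two-fold. Two reconstruction decisions are worth stating
plainly: the pseudocount $p$ (default 1, configurable) guards the frequent
zero-coverage positions, and $G1, G2$ are per-region scalars — a
per-nucleotide gene count has no evident meaning. Mining a signed SI track
uses $|SI|$ with threshold `mu_si` and reports each region with the sign of
its mean SI, because the miner needs a non-negative magnitude.

## Discovery mode

`discover()` implements the top-down scan: per chromosome and strand, three
region categories are searched — annotated **gene** bodies, genes
**extended** by `flank`, and the **intergenic** complement of the (merged)
genes. Long intervals are chunked with overlap; chunk results are merged by
dropping regions equal to or contained in a region from another chunk.
Because irreducibility depends only on an interval's own values, every
maximal region shorter than the overlap lies intact in at least one chunk
and every chunk-boundary fragment is a strict sub-interval of some maximal
region, so the merged result equals the unchunked one — an equality the
tests assert rather than assume.

A region overlapping any annotated gene is labeled *genic* no matter which
scan found it, keeping category assignment unambiguous. Cross-sample
*support* — the number of samples in which a gene (or novel locus) contains
at least one mined region — is the main robustness filter; a gene counts
once per sample regardless of how many regions it holds. The support
summary (`support_table()`) tabulates, per $(\mu,$ `minsup`$)$, how many
genes have regions in at least $X$ of $N$ samples; it is monotone
non-increasing in $X$, in $\mu$ and in `minsup` by construction, and the
tests verify the monotonicity on data.

Counts for the surviving genes and novel loci are exported as a
regions-by-samples integer table (`write_counts_tsv()`), the input format of
count-based differential-expression tools; significance testing itself is
deliberately delegated to them.

## The simulator

`simulate_reads()` is first-class, tested code, not a fixture: it defines
the conditions under which the package's guarantees are demonstrated. The
default configuration models one 2 Mb chromosome with 50 non-overlapping
genes (2–4 exons of 150–300 nt) on both strands, 6 samples and 50 bp reads:

* per-exon read counts are negative-binomial with mean 350 and dispersion
  0.2 (variance $= m + 0.2 m^2$), the over-dispersion bulk RNA-seq counts
  show; read starts are uniform inside the exon, so coverage plateaus near
  $100\times$ with linear ramps of one read length at the exon edges;
* background reads fall uniformly over the chromosome on both strands at
  20 reads/kb, i.e. about $0.5\times$ coverage per strand — a tenth of the
  default detection threshold;
* with probability 0.1 per gene and sample, one exon position receives a
  stack of 25 duplicate reads, mimicking over-amplification;
* introns (10–15 kb) and intergenic gaps ($\ge$ 10 kb) receive no
  transcript reads. The lengths are realistic for mammalian genes, and they
  also guarantee separability: bridging a gap of length $L$ costs the miner
  $\mu L$ in surplus, which at these expression levels exceeds any exon's
  surplus, so two exons are never mined as one region.

Under these conditions mining at $(\mu = 5,$ `minsup` $= 51)$ recovers
planted exons at $\ge 95\%$ base-level sensitivity and precision with
boundary errors below one read length — the package's acceptance bar. The
residual sensitivity loss is exactly the predicted edge effect: the first
$\approx \mu r / C$ bases of each exon ramp (read length $r$, plateau $C$)
sit below $\mu$.

What the simulator does *not* model — junction reads, GC and mappability
bias, fragment-length effects, positional ramps from degradation — bounds
what the passing tests show: they validate the algorithmic contract and the
statistical design on idealized data, not performance on any particular
library preparation. On real data the practical levers remain $\mu$
(against the experiment's overall depth), `minsup` (against read length and
expected exon length) and lowess pre-smoothing.

## Numerical and design choices

* **Containers**: S4 classes mirror the analysis objects — `ReadSet` for
  raw reads in a region, `CoverageTrack` (region + per-sample value matrix
  + a value-kind tag) for everything derived from them. The kind tag
  (`counts`, `normalized`, `smoothed`, `fold_change`, `splicing_index`,
  `region_based`) travels through bedGraph track lines so round-trips are
  lossless. Mined regions are plain data.frames: they are results, not
  processes.
* **Back-ends**: BAM via `Rsamtools::scanBam` (indexed random access;
  alignment end taken as `pos + qwidth - 1` under the single-block read
  model), read TSV and in-memory tables behind the same `fetch_reads()`
  surface, with a per-chromosome start-sorted index so interval queries
  cost $O(\log n + \mathrm{hits})$ — per-gene iteration stays linear in
  the number of genes, and any pipeline result is bit-identical across
  back-ends (tested).
* **Unstranded reads** (`strand = "."`) count in both same-strand pileups:
  the protocol-agnostic default.
* **Counting rule** defaults to any-overlap, matching read-count
  denominators where every mapped read in a locus contributes; a
  `contained` rule is available.
* **Fixed flank** for extended regions rather than adaptive growth until
  coverage falls below $\mu$; adaptive extension would couple the category
  definition to the mining parameters and is left as a variant.
* **Library-size normalization** is reads-per-million only; between-sample
  quantile/TMM normalization belongs to the downstream DE tool.
* **Problem sizes in the tests** (random-vector lengths $\le 200$ for the
  oracle comparisons, a 2 Mb chromosome with 50 genes for recovery, 0.3 Mb
  for back-end equivalence) were chosen so the exhaustive oracle remains
  exact and each property is exercised at a scale where failures would be
  interpretable.

## Limitations

Junction-spanning reads are not modelled, so spliced isoform structure
cannot be resolved — regions describe contiguous expressed DNA, not
transcripts. Mining is per-sample (cross-sample evidence enters only
through support counts, not joint mining). Regions carry no p-values by
design; significance belongs to the count-based tools downstream. Lowess
smoothing trades boundary sharpness for stability, and very short exons
(below `minsup`) are invisible at the default settings.
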