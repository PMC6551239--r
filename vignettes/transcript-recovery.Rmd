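---
title: "Recovering similar transcripts directly from the de Bruijn graph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recovering similar transcripts directly from the de Bruijn graph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txrecover)
```

## The problem and the idea

De novo transcriptome studies of non-model organisms usually assemble reads
into predicted transcripts and only then search a related organism's
database for similar sequences. Transcript prediction collapses the
branching structure of the data and tends to drop low-coverage isoforms, so
the downstream similarity search starts from an impoverished input.
`txrecover` instead searches the *condensed de Bruijn graph* itself: for
each database transcript it looks for the graph path with the most
significant local-alignment hit, so that evolutionary evidence — not
coverage heuristics — decides which paths are spelled out. Each recovered
path doubles as a predicted transcript of the sequenced organism.

## The graph

Given reads and an odd k, every k-mer occurring in the reads (either
strand) is a vertex, counted under its *canonical* form (the lexicographic
minimum of the k-mer and its reverse complement); two k-mers are joined by
a directed edge when the (k-1)-suffix of one equals the (k-1)-prefix of
the other. Maximal non-branching chains are condensed into single nodes.
Each node is stored once per *twin pair*: the "+" orientation spells the
stored sequence, the "-" orientation its reverse complement, and every edge
has its twin mirror, so strand symmetry is structural rather than
bookkeeping. Two guards keep spelled sequences well defined: a chain never
continues into the twin of the k-mer it just left (a *fold-back*, which at
palindromic (k-1)-overlaps would fuse a node with its own twin — such
hairpins remain as explicit node-to-twin edges), and never around a cycle.

Simplification mirrors what short-read assemblers do before reporting
contigs: short dead-end *tips* (spelled length below `tipLen`, default 2k,
with a sibling branch at their attachment point) are removed iteratively,
then a coverage cutoff `c` drops nodes whose *average* k-mer coverage
(summed k-mer count divided by the number of k-mers) falls below `c`, and
the graph is re-condensed to a fixpoint. `c` trades sensitivity for graph
cleanliness: the larger data sets in this problem domain are typically run
at k = 25 or 31 with `c` between 3 and 50. Graphs serialize to GFA 1.0
(`writeGFA`/`readGFA`) with k-mer counts in `KC` tags and k in a header
tag, round-tripping bit-exactly.

Reads are quality-trimmed first (`trimReads`): every position from the
first base with Phred quality below 15 onward is removed, the rule used on
the 100 bp libraries (trimmed to 71 bp) that motivated the defaults here.
k-mers containing N are excluded during counting; how N-containing reads
were treated upstream is not specified anywhere authoritative, and
excluding the affected windows is the least committal choice.

## The alignment engine and its statistics

The engine is an exact Smith-Waterman local aligner with affine gaps
(a gap of length L costs `gapOpen + L * gapExtend`), run either
nucleotide-against-nucleotide over both query strands (`ntScheme`:
+2/-3, gaps 5/2) or translated-against-protein over all six reading frames
with BLOSUM62 (`txScheme`: gaps 11/1), stops scored by the matrix's `*`
column. Raw scores S become bit scores S' = (lambda S - ln K)/ln 2 and
e-values E = m n 2^(-S'), with m the query length as searched (nucleotides,
or floor(nt/3) in translated mode) and n the total database length. For
nucleotide schemes lambda is solved from the ungapped Karlin-Altschul
identity (`solveLambda`); K is preset (0.41), as are the published gapped
BLOSUM62 constants (lambda 0.267, K 0.041) in translated mode. No
edge-effect length correction is applied; the algorithm only ever compares
e-values of nested searches, for which monotonicity, not calibration, is
what matters. Because e-values of strong hits underflow double precision,
every internal comparison happens on log10(E); the `evalue` column is
derived and may print as 0.

Two deliberate consequences of E = m n 2^(-S'): at fixed search space the
e-value is strictly decreasing in the bit score, and lengthening a query
without improving its raw score strictly *worsens* its e-value. The greedy
extension below relies on both.

The engine sits behind a narrow contract — `searchDb(query, db, scheme,
eCut)` returning one best hit per subject in deterministic order — so a
tabular-output wrapper around an external aligner could replace it
(`readTabularHits` ingests outfmt-6-like TSV); the internal engine is the
tested default.

## Seed selection and greedy extension

For each database transcript, every graph node is aligned against the
database (`selectSeeds`) and the `nSeeds` (default 8) nodes with the best
e-value at most `ei` are kept as seeds. `ei` is deliberately *lenient*
(default 1e-6 translated, 1e-15 nucleotide) so that short,
isoform-specific nodes can seed even though they will only become
significant after extension; the stringent cutoff `ef` (1e-20 / 1e-100) is
applied only at reporting time.

From each seed, `extendSeed` runs the greedy loop (`extendForward`) in one
direction: spell every one-node extension along outgoing edges, align each
against the whole database (every such alignment also updates the running
per-transcript best pool, whatever transcripts it hits), and accept the
extension with the best e-value *to the seeding transcript* iff it is
strictly better (relative tolerance 1e-12; ties broken by bit score, then
shorter spelled length, then lexicographically smallest oriented id list —
all tie-breaks fixed so runs are deterministic). The loop stops at a dead
end, at no improvement, or at `maxSteps`. The same is done from the twin
node in the opposite direction; the twin of that backward path (minus its
seed step) is concatenated with the forward path, and the merged path is
searched once more. Merged paths are not re-extended. Extending in one
best direction only keeps the work linear where exploring all directions
would be exponential; isoforms are still separable because extension
starts independently from up to `nSeeds` nodes per transcript, some of
them isoform-specific. Strict improvement bounds every extension — on
cyclic graphs (genomic repeats shorter than a transcript) the e-value
cannot improve forever, and `maxSteps` is a safety net.

One failure mode of pure one-node greediness: a *very short* node (an
exon-skipping junction node contributes only k-1 new bases, for example)
may add too little aligned sequence to improve the e-value on its own,
stalling the extension one step before a long matching node. The exact
remedy used historically is unstated, so the package's stand-in is
explicit and tunable: when the best one-node step fails *and* some
candidate contributes fewer than `shortLen` (default k) new bases,
`shortNodeLookahead` explores up to `lookahead` (default 2; 0 or 1
disables) nodes through the short candidate and commits the whole
multi-node step only if its terminal e-value improves on the pre-step
best. Everything explored still feeds the pool.

Duplicate work is avoided twice over: (seed node, transcript) pairs are
memoized across the run, and hit tables are cached by spelled path
sequence, since seeds of the same gene repeatedly spell identical
candidate paths.

## Reporting

`finalizeTranscripts` reports, per database transcript with pool e-value
at most `ef`, the best path trimmed to the aligned nodes: steps whose
spelled interval does not intersect the aligned query interval are dropped
from both ends (interior nodes always stay). Different transcripts may
legitimately report the same path. `subject_coverage` is the aligned
subject span over the subject length — amino acids in translated mode, so
it reads as coverage of the coding region; counting records with coverage
at least 0.8 (`fullLengthCount`) is the usual near-full-length metric, 1.0
the strict variant. `nodesOnlyBaseline` reports the best *single-node* hit
per transcript in the same record shape: the contig-level result an
assembler-then-search pipeline would get from these data, and the
comparator the extension must beat. Internally all coordinates are 0-based
half-open; `writeResultsTsv` converts to 1-based inclusive at the file
boundary, and FASTA headers (`<transcript>|<node list>|e=<evalue>`) trace
each sequence back to the graph.

## The synthetic-data generator

`simulateDataset` produces the regime the method targets, scaled to a
desk: multi-exon genes (4-7 exons of 120-399 nt by default), isoforms by
skipping one internal exon (the structure that makes bubbles — alternative
donors/acceptors are not simulated), clean ORFs so protein orthologs are
well defined; an ortholog database at a stated residue identity (default
85%, protein mode — amino acids of the translated ORF are substituted
directly, the protein being what a translated search aligns against); and
single-end 71 bp reads with per-base qualities at a log-normal
per-transcript coverage (default meanlog log 30). Reads are laid as one
deterministic tiling pass (stride readLen/3, emulating even fragmentation)
topped up with uniform random starts to exactly round(cov·len/readLen)
reads, so that error-free coverage of 15x or more observes every k-mer of
every transcript — the planted path demonstrably exists in the graph
before any cutoff. Substitution errors and low-quality Q2 tails (which
exercise the trimming rule without changing bases) are configurable;
indels and paired ends are not simulated. Everything is deterministic
under the config seed.

What passing on these data does and does not show: recovery and isoform
resolution are demonstrated under uniform coverage, substitution-only
errors and a divergence model of i.i.d. residue substitution. Real
libraries have coverage that varies along transcripts, indels, chimeras
and domain-level divergence heterogeneity; results there will be
correspondingly weaker, and the graph-simplification parameters (c,
tipLen) matter far more than they do on clean simulations.

## Numerical and design choices

* k must be odd (no self-complementary k-mers), matching standard
  assembler practice.
* Improvement means strictly smaller e-value beyond a relative 1e-12
  (4.3e-13 in log10 units); pool ties keep the first hit encountered, in
  the fixed deterministic iteration order.
* The extension objective is the e-value to the seeding transcript, not
  the whole-database best — the per-transcript reading of the procedure —
  while the pool nevertheless collects every subject each alignment hits.
* Node ids are assigned by sorting node sequences, so identical inputs
  give identical graphs, pools and reports.
* Degenerate inputs: an empty read set or a cutoff that removes everything
  yields an empty graph (with a warning) and empty results, not errors;
  reads shorter than k simply contribute nothing; a hit whose coordinates
  miss the path entirely is an internal-consistency error.
* Problem sizes used by the test-suite and the acceptance script — 50
  single-isoform genes for nucleotide-mode recovery, 20 two-isoform genes
  for the translated comparison, 100 twelve-node graphs for the
  exhaustive-path audit — were chosen so the full validation runs in
  minutes on one core while still exercising every code path at the
  parameter values the method is normally run with.

## Known limitations

The aligner reports one best local alignment per subject (no HSP chaining
or sum statistics, no composition-based adjustment, no low-complexity
masking). Effective search-space lengths are uncorrected, so absolute
e-values are systematically optimistic relative to edge-corrected ones —
consistently so on both sides of every comparison the algorithm makes.
Bubble popping and read tracking are out of scope for the graph; the
baseline is the package's own nodes-only search, not an external
assembler's contigs. Greedy extension can miss the optimal path by
construction; the exhaustive-path audit in the test suite checks soundness
(never better than the optimum, always a real path), not optimality.
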