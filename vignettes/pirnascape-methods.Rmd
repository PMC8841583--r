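---
title: "Methods: piRNA cluster and transposon landscape analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: piRNA cluster and transposon landscape analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pirnascape)
```

`pirnascape` analyses gonadal small-RNA libraries against a genome: it
selects piRNA-sized reads, maps them under a seed-constrained mismatch rule,
quantifies the ping-pong and 1U/10A signatures, calls piRNA clusters,
classifies the genome into repeat/gene categories, builds transposon
divergence landscapes on a molecular-clock axis, and tests synteny of
cluster loci between genomes. This vignette explains each model, the
parameters that matter, and the design decisions taken where conventions
are genuinely open. It states no empirical result beyond what the package's
tests and acceptance script themselves compute.

## Read selection

Two filters turn a raw small-RNA library into piRNA candidates:

* `exclude_annotated_rna()` removes a read iff its sequence is an **exact
  substring, in either orientation**, of any supplied ncRNA/mRNA reference.
  Annotation cascades used by small-RNA annotators involve tool-specific
  heuristics; exact substring matching is the reproducible core of that
  step. Whether near-matches (≤ 1 mismatch) should also be removed is not
  settled; we deliberately do not guess, and the matcher stays exact.
* `length_filter()` keeps reads of 24–32 nt inclusive — the canonical piRNA
  size range, distinguishing piRNAs from miRNAs/siRNAs (~21–23 nt).

U and T are interchangeable throughout. Counts ride along unchanged; both
filters are idempotent and order-independent.

## Alignment model

`enumerate_alignments()` reports *every* genomic occurrence of a read, on
both strands, that satisfies `valid_mismatch_pattern()`:

* positions 1–18 from the read's 5′ end (the seed) must match exactly;
* the last two positions must match exactly;
* at most 2 mismatches in between.

The 18-nt seed with zero mismatches mirrors a Bowtie `-l 18 -n 0` seed
policy; the seed length, mismatch budget and protected 3′ length are all
arguments. Reads shorter than seed + protected + 1 = 21 nt cannot satisfy
the rule and are dropped with a diagnostic. Internally, seeds are located
with a Biostrings dictionary match and verified in read coordinates; an
exhaustive sliding-window scan serves as the independent oracle in the test
suite.

`select_min_mismatch()` keeps, per read, the full minimum-mismatch stratum.
Keeping a single arbitrary alignment would make the subsequent multimapper
reallocation meaningless, so ties are retained and resolved by weighting.

`reallocate_weights()` assigns every uniquely-mapping read its full count
and splits a multimapper's count across its retained loci proportionally to
`U(locus)` — the summed count of uniquely-mapped reads whose 5′ ends lie
within half a window (default window 10 000 bases, i.e. ±5 kb) of the locus
5′ end — with a uniform split when `U = 0` everywhere. Weights per read sum
to the count exactly; total weight equals total library count, which the
tests assert. The reference reallocation tool's parameter string admits
several readings of window/resolution/rounds; we implement a single-pass
±5 kb unique-density weighting and expose the window.

## Ping-pong and base-bias statistics

All 5′ positions are genomic: a plus-strand alignment's 5′ end is its
leftmost base, a minus-strand alignment's its rightmost. For a plus 5′ at
`p` and minus 5′ at `q ≥ p` on one chromosome, the overlap length is
`d = q − p + 1`, so an exact ping-pong pair gives `d = 10`. The overlap
score is the **product of plus and minus weights**, accumulated over all
such pairs for `d = 1..30`:

\[ S_d = \sum_{\text{pairs at } d} w^+ \, w^- . \]

The background range caps at 30 because read lengths cap meaningful overlap
near 32. Ratios `r_d = S_d / \sum S` are standardised with the mean and
**population** standard deviation over `d`:
`z_d = (r_d − \bar r)/\mathrm{sd}(r)`, with all `z = 0` when the scores are
zero or constant. `z_10` is the ping-pong signature; a one-hot profile
yields the maximum attainable `z_10 = √29 ≈ 5.385`. Pair enumeration uses
per-chromosome 5′-position weight tables (linear in distinct positions);
an all-pairs quadratic oracle checks it in the tests.

`base_bias()` extracts the 10 genomic bases under each read's 5′ end (in
read orientation) and accumulates weight-weighted frequencies; the
position-1 U and position-10 A frequencies summarise the 1U/10A biases.
Length histograms are normalised by `10^7 / total mapped` so libraries of
different depth are comparable.

## Cluster detection

Two complementary detectors:

* `detect_density()` chains mapped 5′ loci whose successive positions are
  ≤ 5 kb apart (equivalently, the union of occupied 5-kb windows), trims
  candidates to their outermost loci, and keeps those with **≥ 1 distinct
  locus per kb** and **≥ 10 distinct loci** — the two operative filters of
  probabilistic wide-region cluster finders. The 5-kb window is our choice
  and is configurable.
* `detect_assembly()` is a transcript-assembly-style chain for narrow
  clusters: stage 1 chains alignment intervals with gaps ≤ 50 b and drops
  fragments < 50 b; stage 2 merges fragments ≤ 250 b apart and keeps merged
  clusters ≥ 500 b with summed weight ≥ 50. The weight floor replaces an
  FPKM floor, which is undefined without library normalisation. A
  `min_frag = 150` variant suits assemblies riddled with short gaps.

`union_clusters()` merges overlapping detections into their union interval
("and/or" of the two detectors; an intersection can be obtained by
filtering `method == "merged"`), recomputing locus counts and weights.
`common_clusters()` compares two samples: a pair is common when the overlap
exceeds half of the **shorter** cluster — the permissive reading of "more
than half of the overlapped sequences", which does not specify a
denominator; a reciprocal mode is provided. Cluster strandedness is
annotated from the weighted strand ratio but never used for filtering.

## Genome composition

`classify_genome()` partitions every base into eight categories with the
priority **transposon → gene/exon → other**: disjoint repeat categories
first (DNA transposon, retrotransposon, satellite, simple repeat, unknown
repeat), then exon, then intron (gene minus exon), then `other`. Before
classification, `resolve_repeat_overlaps()` settles overlapping repeat
annotations in favour of the family with the **lower diversity score**
(mean pairwise K2P among its copies, `family_diversity()`), with ties
broken by earlier start then family name; a per-base brute-force assignment
is the oracle. Diversity is mean pairwise distance rather than a tree
statistic: it needs no tree builder and induces the same ordering in the
regimes tested. piRNA weight is attributed to the category of the
alignment's **5′ base**, so a boundary-spanning read counts once; fractions
always sum to 1.

## Transposon landscapes and the clock

`kimura2p()` implements `K = −½ ln((1−2P−Q)√(1−2Q))` for transition and
transversion proportions `P`, `Q`; it is undefined (saturation error) when
`1−2P−Q ≤ 0` or `1−2Q ≤ 0`. `copy_divergence()` counts `P` and `Q` over
aligned, unambiguous sites of a copy against its family consensus.
`build_landscape()` lets each copy contribute its base length to the single
0.01-wide bin containing its `K` (no smoothing — the stacked-histogram
convention) and normalises by genome length, so bins read as genome
fractions; per-group bin masses sum to the group's genome fraction exactly.
No CpG adjustment is applied.

`time_axis()` converts distance to age linearly: `age = (K/0.01)·c` Mya.
The default `c = 3.4` anchors 0.05 ↔ 17 Mya and 0.10 ↔ 34 Mya — the
hybridisation and speciation times of the L/S subgenome ancestors in
allotetraploid *Xenopus* — while the literature clock range for these frogs
is 3.23–3.33 Mya per 0.01 substitutions. The figure-consistent anchoring
and the published range cannot both hold exactly; we default to the
anchoring and expose `clock_params()`.

## Synteny of cluster loci

Only clusters longer than 1 kb are screened. `flanking_exons()` takes the
10 nearest exons up- and downstream; `local_similarity_search()` finds each
exon in the partner genome by exact k-mer seeding (k = 12, stride 4),
diagonal banding, and Smith–Waterman rescoring (match +1, mismatch −2, gap
open −5, extend −2 — fixed defaults for reproducibility, all configurable),
discarding hits whose aligned query span is below 10 % of the query length
("relative size" is read as aligned-span over query length). Best hits are
grouped within a 1-Mb target span (`group_hits()`, which also flags
non-collinear groups; the span bound is not quantified by any convention we
know of and is an argument). `call_synteny()` declares a cluster syntenic
when one region holds at least 4 homologous anchor exons — "more than
three" read literally as ≥ 4, with the threshold exposed for the ≥ 3
alternative — and separately reports whether a partner-genome cluster lies
near the matched region and whether the cluster body sequence itself
survives there (`cluster_body_conserved`), distinguishing conserved
clusters from cluster turnover at conserved loci. Bit scores are summed to
rank candidate regions, never thresholded.

## The synthetic-data generator

`simulate_genome()` builds a uniform-random background sequence and plants,
without overlaps: mutated TE copies per family, genes with exon/intron
structure, optional tandem repeats, and piRNA clusters; truth tables record
every planted interval, locus and read origin. Features are laid out in
random order with at least a 10-b gap — clusters with a 6-kb margin, since
piRNA clusters are discrete, well-separated loci and abutting planted
clusters would merge into a single read-density run by construction rather
than by biology. `simulate_pirna_reads()` then emits, per cluster, `depth`
read instances: primary reads from the planted 5′ loci, a
`pingpong_fraction` of opposite-strand partners whose 5′ ends overlap a
primary locus by exactly 10 nt, and an `antisense_fraction` of background
reads from opposite-strand loci placed at a few fixed non-ping-pong 5′–5′
registers. The structured background matters: with it, the off-10 overlap
distribution is non-uniform (as in real libraries) and `z_10` grows with
the planted ping-pong fraction instead of saturating immediately.

Mutation model: per-copy substitutions follow a K2P process with
transition:transversion odds κ (default 2) and **stratified placement** —
the transition/transversion counts are fixed at the integers whose realised
K2P distance is the smallest achievable value at or above the target, while
positions and transversion directions stay random. A binomial per-site
process has the same expectation but scatters realised divergences around
the target; since families are planted *at* bin edges (e.g. 0.02 with
0.01-wide bins), that scatter would split a family across two bins and make
its modal bin a coin flip. Stratified placement keeps planted ages exactly
recoverable, which is the generator's purpose. No indels, no rate
heterogeneity, no CpG effect, and no sequencing error — mismatch-rule tests
plant controlled mismatches explicitly instead.

1U/10A realisation: the generator edits the genomic base under each
planted 5′ end (U on the read's strand with probability `u1_fraction`) and
under each read's position 10 (A with probability `a10_fraction`). For an
exact ping-pong pair the partner's position 10 *is* the complement of the
primary's first base, so for paired reads the realised 10A rate equals
`u1_fraction` and the partner's 1U rate equals `a10_fraction`; with
`u1 = a10` (the regime all shipped conditions use) every bias is realised
at its nominal rate. 5′-end edits take precedence over position-10 edits at
collision sites, and primary loci are sampled so that no two sit exactly in
the pair register. Multimapping is created by duplicating the first
cluster's final sequence at extra loci.

What the generator does *not* emulate: chromosome-scale genomes, indel
evolution, nested/fragmented repeat copies, expression-level realism,
sequencing error, or assembly gaps. Passing tests therefore demonstrate
that the statistics recover what was planted under clean conditions — not
that they are robust to artefacts of real libraries and assemblies.

## Numerical choices and degenerate inputs

* Population (not sample) standard deviation in `z`; `z = 0` when scores
  are zero or constant; empty alignment sets give empty profiles or
  explicit errors (`base_bias()`).
* Overlap-resolution ties: earlier start, then lexicographic family name.
* `detect_density()` trims candidates to outermost loci and includes the
  trailing locus base (half-open intervals); density is computed on the
  trimmed span.
* K2P saturation and exon-outside-gene annotations raise errors rather
  than returning silently wrong numbers; alignments running off a
  chromosome end are skipped and counted.
* All intervals are 0-based half-open in tibbles; GFF3 output converts to
  1-based closed. Seeds make every simulation and the whole pipeline
  bit-reproducible; `run_pipeline()` writes a manifest (parameters, seed,
  md5 checksums) sufficient to reproduce any output.

## Problem sizes

The shipped tests and acceptance script run on toy scales chosen to
exercise every code path with tight statistical margins: genomes of 1 kb
(composition arithmetic) to 500 kb (cluster recovery, 20 planted clusters,
10^4 reads), libraries of 10^4 instances for signature recovery, 50 copies
× 2 kb per family for landscape recovery, and 100-replicate nulls for the
ping-pong significance check.

## Known limitations

The mismatch rule assumes ungapped alignment; the in-package similarity
search is adequate at toy scale but a dedicated search engine should
replace it for chromosome-scale genomes (the scoring hook accepts any
scheme); ncRNA exclusion is exact-match only; and the clock is a single
linear constant — any rate variation across lineages or repeat classes
shifts the age axis, not the landscape shapes.
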