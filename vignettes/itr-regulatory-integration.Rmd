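---
title: "Detecting transposon ITR remnants and integrating them with binding and expression data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting transposon ITR remnants and integrating them with binding and expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itrtools)
```

## The scientific problem

DNA transposons of the mariner family left thousands of decayed copies in
the human genome. Each copy carried a 28 bp inverted terminal repeat (ITR)
at either end — the binding site of its transposase. Almost half of the
Hsmar1 remnants are Made1 elements: miniature derivatives in which just
6 bp are flanked by a pair of ITRs. When a transposase is domesticated into
a host protein (as the Hsmar1 transposase was, fused to a SET-domain
methylase to form SETMAR in anthropoid primates), its DNA-binding domain
can keep targeting those remnant ITRs, turning a fossil repeat family into
a dispersed set of regulatory anchor points.

Testing that idea computationally requires a chain of analyses: find the
decayed ITR copies in the genome; classify the remnant architecture; ask
whether protein-binding peaks (ChIP) sit at ITRs; derive per-gene binding
classes; join those with differential-expression (DE) calls between cell
lines; quantify over-representation with hypergeometric tail tests; and
summarise chromatin accessibility as coverage metaprofiles around ITR
centres. `itrtools` implements that chain as composable, tibble-first
functions plus a seed-deterministic synthetic-data generator, so the whole
pipeline is testable end-to-end without any external download.

## Coordinate and distance conventions

Everything inside the package is 0-based half-open (BED-native); GFF3 is
converted at the boundary. A single convention removes the classic
off-by-one bug class. Distances are edge-to-edge gaps: overlapping or
abutting features are at distance 0, otherwise the count of bases strictly
between them. "Within *X* bp" is inclusive (`gap <= X`); "< 150 bp" is
strict. Strand is carried but ignored for distance and intersection — an
inverted repeat is biologically equivalent in either orientation. Peak
distances are measured from feature edges; a summit-based convention was
considered and rejected as the default because peak inputs here are
intervals, not summit calls, but `assign_peaks()` operates on whatever
intervals it is given, so summit mode is one `mutate()` away (collapse
peaks to 1 bp summits first).

## The ITR scanner

`scan_consensus()` aligns a consensus ITR locally (Smith–Waterman with
affine gaps) against both strands of every sequence, in compiled code. The
default scoring — match +1, mismatch −1, first gap base −2, each further
gap base −1 — approximates the megablast regime; no published score set
exists for this filter, so the scores are exposed in `pipeline_config()`.

A hit is retained when **two** separate filters pass:

* `aligned_consensus_frac` = aligned consensus positions / consensus
  length ≥ 0.80, and
* `identity` = matching columns / alignment columns ≥ 0.80.

The classical phrase "retaining at least 80% of the length and identity"
conflates the two quantities; requiring both is the strictest faithful
reading. On a 28 bp consensus the identity filter separates 5 interior
substitutions (23/28 = 0.821, retained) from 6 (22/28 = 0.786, rejected).
Substitutions at the very ends behave differently: a local aligner trims a
terminal mismatch whenever that raises the score, so identity is then
computed over 27 columns. `N` bases never match and score as mismatches
when aligned.

Implementation notes that matter for correctness:

* Candidate end positions are pruned with a score cutoff that is a provable
  lower bound for any alignment passing both filters, so pruning can never
  lose a reportable hit.
* Exact filters are applied per candidate alignment first; then overlapping
  retained hits are merged keeping the best score (ties: leftmost, then `+`
  strand). Filtering before merging guarantees a locus is never discarded
  because its best-scoring alignment happens to fail identity while a
  slightly weaker passing alignment exists.
* Chance matters: in uniform random sequence, gapped alignments of ~23-27
  columns pass both 80% filters roughly once per 50-100 kb. Tests therefore
  check equivalence against an independent aligner rather than assuming
  "only planted copies are found".

`classify_remnants()` pairs sorted hits greedily left-to-right: adjacent
inverted hits with a gap of 6 ± 2 bp form a Made1 annotation (the ±2 bp
tolerance absorbs indel decay and is configurable); inverted pairs with
gaps up to `pair_span` (default 1500 bp, since the full-length element is
~1.3 kb) form a paired remnant; everything else is a solo ITR. Greedy
pairing is deterministic and each hit belongs to exactly one annotation.
`census_report()` then tabulates classes by genomic context (exonic,
intronic, intergenic) against gene models.

## PWM construction and scanning

De novo motif discovery is out of scope; `build_pwm()` is the verifiable
stand-in. Peak sequences are anchored on their best consensus hit
(`peak_pwm()`), stacked, and converted to per-position probabilities with a
pseudocount (default 0.25 per base) and a background (default uniform —
neither value has a published source, so both are parameters).
`pwm_scan()` reports log-odds scores at every offset on both strands;
information content is `2 + sum(p log2 p)` bits per position. PWMs
serialise to MEME minimal text format.

## ChIP and expression integration

`assign_peaks()` tiers every peak by gap to its nearest ITR: `overlap`
(0), `lt150` (strict), `le500` (inclusive), `gt500`, or
`no_itr_on_chrom`. The headline "peaks within 500 bp of an ITR" statistic
is the sum of the first three tiers. The bound-ITR set is every ITR with
at least one peak within 500 bp — deliberately not nearest-only, because a
single peak straddling a Made1 element genuinely binds both of its ITRs.

`classify_genes()` assigns every peak-bearing gene (a peak overlapping its
TSS-to-poly(A) span; overlapping genes each receive the peak) one class in
priority order: `bound_itr` (a peak within 500 bp of an intragenic ITR),
then `distal_peak_with_itr`, then `peak_no_itr`. "Intragenic ITR" means
overlapping the gene span by default; an intron-only mode is a switch,
since the two published phrasings ("intronic" vs "between the TSS and
poly(A) site") differ and the span reading is the one consistent with the
reported counts.

On the expression side, `apply_de_thresholds()` calls a gene `up` when its
fold-change strictly exceeds 2 and its adjusted P is at most 0.05 (missing
adjusted P means not-significant — those are count-filtered genes, not
errors). DE model fitting itself is consumed, never re-fit: the tables are
the interface. `compute_fpkm()` uses union-exon lengths (overlapping exon
records are merged first); `direction_concordance()` crosses the called
genes of two conditions and reports how many flipped direction.
`gene_integration()` joins everything into one record per gene, keeping
`has_itr` and `near_itr_10kb` (an ITR-less gene within 10 kb of an ITR)
mutually exclusive.

## Enrichment statistics

`hypergeom_tail()` computes one-sided tail probabilities — `P(X >= k)` for
over-representation, `P(X <= k)` for under — by summing log-gamma terms in
log space, so tails near 1e−80 (the scale of the strongest published
binding enrichments) keep full relative precision, and `log10_p` is
returned alongside `p`. Both tails are inclusive of `k`; inclusivity is a
convention choice made once and tested via the complementarity identity
`over(k) + under(k−1) = 1`. No multiple-testing correction is applied:
these are single planned tests reported raw. The population defaults to
the genes in the integration records — in a transcriptome analysis, the
genes with detectable expression (~16,776 at the published scale) — and is
the caller's choice otherwise.

`mann_whitney_u()` uses midranks for ties, exhaustive enumeration of all
group-label assignments for pooled sizes up to 20 (exact even with ties),
and above that a normal approximation with tie and continuity corrections
matching the standard implementation.

## Metaprofiles

`profile_matrix()` averages per-base coverage in fixed bins (default
10 bp) around reference-point midpoints (`floor((start+end)/2)`), one row
per point, columns reading 5′→3′ (minus-strand rows are reversed). Points
whose window would cross a sequence edge are dropped with a message —
zero-padding would bias the mean toward zero at the flanks. The row
summary is the mean (the cited tooling's default); median is available.
`normalize_track()` implements 1× genome coverage (RPGC) and RPKM
scalings, both linear. `subtract_input()` takes IP − input cell-wise and
refuses mismatched geometry. bedGraph text is the interchange format so
tests can be bit-exact; binary bigWig is out of scope. The default profile
half-width is 2 kb, chosen because nucleosome phasing around ITRs extends
roughly 1 kb to either side.

## The synthetic-data generator

`simulate_genome()` is first-class, tested code, not a fixture. It plants
solo ITRs, Made1 elements (two inverted decayed ITR copies around a 6 bp
spacer) and longer paired remnants into an i.i.d. uniform background,
decays each copy by per-site substitutions (probability `divergence`) and
rarer indels (`divergence/10`, geometric lengths of mean 1 — decay stays
mostly substitutional, the regime the identity filter addresses), and
builds gene models so a chosen fraction of elements (default two-thirds)
sits inside an intron. Elements occupy disjoint slots with ~2 kb
margins, so planted features never overlap, every intragenic element's
gene fits in its own slot, and recovery tests have unambiguous ground
truth. i.i.d. background is a deliberate non-goal boundary: it suffices
for correctness testing, but it has no isochores, no repeat families and
no compositional bias, so passing tests demonstrate algorithmic
correctness, not performance on real heterochromatin.

`simulate_chip()` centres a chosen fraction of peaks within ±150 bp of
randomly selected ITRs (all of them therefore inside the 500 bp bound
distance) and scatters the rest uniformly; uniform background peaks land
within 500 bp of an ITR by chance at the ITR-density-dependent collision
rate, which is part of the model, not an error. Optional tracks are
Poisson background (IP and input) plus a triangular kernel at peak
centres. `simulate_de()` plants DE calls with an odds multiplier for
ITR-carrying genes entering the up-regulated set, gives called genes
fold-changes strictly above threshold and adjusted P at most 0.05, shares
a fixed number of DE genes between two conditions and flips each shared
gene's direction with a given probability. All generators are
seed-deterministic to the byte.

Two presets define the package's study conditions. `small` (200 kb, 25
elements, 8% divergence, 60 peaks, DE over the simulated genes) runs every
stage in seconds and is the end-to-end test scale. `paper_scale` is a
coordinate-only layout at the published geometry: a 2×10⁸ bp genome with
410 ITRs (the human-genome ITR density of ~2 per Mb), 875 peaks of which
34% are planted at ITRs, and 16,776-gene DE tables with 1,477 DE genes
(65% up), 103 shared between conditions, 74% of those reversed. At that
scale the sequence itself is never materialised (`sequence = FALSE`);
peak and expression stages need only coordinates. The DE defaults
(carriers = 1,342 genes, odds multiplier 1.6) were set so the expected
ITR-carrier count among up-regulated genes lands near the published 117;
weighted sampling without replacement depletes high-weight genes slightly,
so realised enrichment varies around that target across seeds.

## Numerical and design choices

* Alignment traceback prefers diagonal over gap states on ties, making
  reported identity deterministic.
* Tie-breaking everywhere is lexicographic (leftmost start, then name,
  then `+` strand) so outputs are order-stable and re-runs byte-identical.
* `expression_bins()` uses half-open bins `[e_i, e_{i+1})` with an
  implicit final bin to infinity; a value exactly on an edge belongs to
  the upper bin.
* Percentages in summaries are rounded to the nearest integer, matching
  how such tables are conventionally reported.
* The hypergeometric functions raise errors on impossible counts
  (`k > K`, `k > n`, counts exceeding `N`) rather than returning 0 or 1.

## Problem sizes used in the test suite

The suite runs the scanner-vs-oracle comparison on one hundred 20 kb
genomes with boundary-case plants, the hypergeometric enumeration on the
complete grid of populations up to N = 25 plus transcriptome-scale
log-precision checks and 1,000 null calibration draws, and the
paper-scale closure on twenty seeds of the `paper_scale` preset. These
sizes make the statistical bands tight (pooled binomial standard errors
under half a percentage point) while every stage stays at desk scale.

## Known limitations

* The scanner targets short (≲ 50 bp) consensus units; it merges
  overlapping hits to the single best window and never chains them, so it
  is not a general repeat annotator and will not reconstruct full-length
  1.3 kb elements from fragments (the remnant classifier works at the
  annotation level instead).
* The synthetic background is compositionally uniform; false-positive
  rates on real genomes (CpG islands, low-complexity DNA) will differ.
* DE tables are consumed as given; no shrinkage or dispersion modelling
  is revisited, and the fold-change threshold is applied to whatever
  fold-changes the table carries.
* `read_annotation()` expects gene/exon features with `gene_id`-style
  attributes (or BED12 blocks); it is not a full GFF3 ontology parser.
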