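---
title: "Methods: a multi-evidence screen for prokaryote-to-metazoan horizontal gene transfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a multi-evidence screen for prokaryote-to-metazoan horizontal gene transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alienscreen)
```

## The problem

Animal genome assemblies — sponges above all — contain protein-coding genes
whose closest relatives are bacterial or archaeal. Two very different
histories produce this signal: genuine horizontal gene transfer (HGT) into
the host germ line, and DNA from microbial symbionts that co-assembled with
the host. A single detection method cannot separate the two, so this
package combines four independent detection routes with a set of
contamination filters built on the observation that a *bona fide* transfer,
having resided in the host genome, progressively adopts host traits
(*amelioration*): host-like GC content, host-like codon usage, spliceosomal
introns, placement on well-assembled contigs among ordinary host genes, and
measurable expression.

Everything operates on tabular inputs — gene models, contigs, and
12-column homology-search result tables — so the screen is agnostic to
which search engine produced the hits.

## Detection routes

**Alien Index (AI).** For each gene, with `bm` the best (smallest) e-value
among metazoan protein hits and `bn` the best among non-metazoan hits,

$$\mathrm{AI} = \ln(b_m + \varepsilon) - \ln(b_n + \varepsilon),
\qquad \varepsilon = 10^{-200}.$$

A category with no hit contributes e-value 1 (the conventional
"no homology" value), e-values above 1 are capped at 1, and the
pseudocount guards reported zero e-values, so AI is finite, bounded, and 0
when neither side has a hit. Genes with AI at or above 45 *and* a best
overall hit (minimum e-value; ties broken by higher bit score, then
subject id) that is prokaryotic are flagged. The second condition matters:
a gene whose non-metazoan affinity is driven by a fungus can clear the AI
threshold, but its best hit is not prokaryotic and it is not flagged.

**Consensus taxonomy.** Each gene is assigned the consensus phylum of its
top 10 hits at e-value ≤ 1e-5 (most frequent phylum; ties resolved in
favour of the best-ranked tied phylum). A gene is flagged when the
consensus is prokaryotic and *no* eukaryotic hit anywhere in its table
reaches the threshold. The exclusivity clause is the mechanical version of
a manual inspection step: it is what makes this route specific, since many
deeply conserved genes have both bacterial and animal homologs. The top-10
list is not deduplicated by subject organism; `top_hits_for_consensus` and
the threshold are configurable.

**External gene-family evidence.** Ancestral-genome reconstruction methods
flag gene families shared exclusively between the host and prokaryotes.
That computation is a separately published method; the screen consumes its
per-gene verdicts as a two-column flag table. With no flag file supplied,
the route contributes nothing and the support metric effectively maxes at 3.

**Nucleotide screen.** The assembly is cut into non-overlapping 1 kb
windows (the last window of each contig truncated). Windows are compared
between a prokaryotic and a eukaryotic nucleotide search (both at e-value
≤ 1e-5): a window is *harvested* when its best prokaryotic bit score
strictly exceeds its best eukaryotic one (absent eukaryotic score = no
competition). Runs of adjacent harvested windows merge into regions. A
region is flagged when

* the union of prokaryotic alignment intervals clipped to the region
  exceeds 100 bp (a union, so splitting one alignment into abutting
  fragments changes nothing),
* the maximum per-window prokaryote-minus-eukaryote bit-score difference
  exceeds 25 (absent eukaryotic score treated as 0 — the most permissive
  reading consistent with "prokaryotic score greater than eukaryotic"),
* and the contig is longer than 50 kb, because short contigs are where
  mis-assembled and symbiont-derived sequence concentrates.

Genes overlapping a flagged region by ≥ 1 bp are flagged. Low-complexity
sequence is masked first with a windowed-entropy masker (64 bp windows,
stride 1, mononucleotide Shannon entropy below 1.5 bits masked, merged);
windows more than half masked are never harvested. This masker is a
deterministic, documented component of this package: its parameters are
exposed, and any masker with the same contract (a set of intervals)
preserves the pipeline's logic.

## Compositional amelioration

Per gene the screen computes GC% (ambiguous bases excluded from numerator
and denominator), GC13% — the GC fraction over the pooled bases at codon
positions 1 and 3 (the pooled fraction was chosen over the mean of GC1 and
GC3; with equal position counts the two differ only when ambiguous bases
are unevenly distributed) — and the codon-usage profile over the 59
informative sense codons (the 61 sense codons minus ATG and TGG, which
have no synonymous alternative; stops excluded).

Correspondence analysis of the gene × codon count table is computed the
standard way: the relative-frequency table's chi-square standardized
residuals are decomposed by SVD and coordinates are reported in principal
scaling, so per-axis inertias are squared singular values and total
inertia equals the table's chi-square statistic divided by its grand
total. Axis 1 — the dominant codon-usage trend — gets its sign fixed by
forcing a positive correlation with per-gene GC3, which makes coordinates
reproducible across linear-algebra backends; remaining axes are anchored
by their largest-magnitude coordinate. Genes with zero counted codons are
excluded from the decomposition and reported; genes with fewer than 30
counted codons are flagged low-information but retained. The analysis
uses raw codon counts (an RSCU variant would weight synonymous families
equally; raw counts match the default behaviour of the classic
codon-usage tools this emulates).

Two operational rules convert composition into host membership:

* **GC13 band** — mean ± 2 SD of GC13 over all genes with defined GC13.
  The rule is two-sided: "more than two standard deviations from the
  majority" is read as distance in either direction, since a transfer may
  deviate either way.
* **Codon cluster** — the two major codon-usage groups are
  operationalized as deterministic 2-means on axis 1 (initial centers at
  the 10th and 90th percentiles, Lloyd iterations capped at 100); the
  larger cluster is the host. Degenerate axes (no spread, or an empty
  cluster) collapse to "everything host", which is the correct reading of
  an assembly with no compositional outliers. Fewer than 10 genes is an
  error: a band estimated from less is meaningless.

## Post-filters and classification

Four filters remove likely symbiont contamination from the route union.
Their boundary semantics follow the elimination rules exactly: genes are
*eliminated* when GC13 falls outside the band, when the contig is shorter
than 50 kb (a contig of exactly 50,000 bp survives), or when mean rpkm
across samples is strictly below 10 (a gene absent from the expression
table counts as 0 and fails). The fourth filter — flanking host genes on
either side, the classic eyeball check for a transfer embedded in host
chromatin — is automated as: at least one gene flagged by *no* detection
route exists on each side on the same contig. Genes at contig ends fail
it, deliberately: a candidate at the edge of a contig has no genomic
context vouching for it.

Each gene then receives two counts: `n_supporting`, the number of routes
flagging it (≤ 4), estimating how likely the transfer is real; and
`n_hostlike`, the number of host-like features — GC13 band, host codon
cluster, ≥ 2 exons, and a homolog (e-value strictly below 1e-5) in each
of two comparison sponge transcriptomes (≤ 5) — estimating how long it
has resided in the host. A *final candidate* is any gene with at least
one supporting route that passes all four filters; individual filter
outcomes are retained in the output so that flag-but-report analyses
(e.g. candidates failing only the expression filter) remain possible.

## Functional enrichment

Genes inherit the GO terms of their best protein hit at e-value ≤ 1e-4
(ties: higher bit score, then subject id). Each term annotating at least
one background gene is tested for over-representation among the final
candidates with the one-sided Fisher's exact test — the hypergeometric
upper tail $P(X \ge k)$, the only reading consistent with "enrichment" —
and Benjamini-Hochberg q-values. The background is restricted to
annotated genes (and the candidate count to annotated candidates): an
unannotated gene cannot contribute to any term and would only deflate
every test. Plain per-term tests are used rather than GO-graph
decorrelation (elim/weight); the map is accepted as given, with no
ancestor propagation.

## The synthetic study

Real screens of this kind depend on a specific assembly and a specific
reference database, neither of which is reproducible at desk scale. The
generator therefore builds a study with the statistical structure the
method assumes, plus a truth table, so recovery is measurable:

* **host** (500) — GC3 ~ N(0.45, 0.05), host codon preferences, 1 +
  Poisson(4) exons, strong metazoan protein hits (log10 e-value uniform
  in [−180, −80]) over weaker prokaryotic ones ([−30, −6]), expression
  log-normal around 30 rpkm, homologs in both comparison transcriptomes
  with probability 0.95.
* **ancient_hgt** (30) — fully ameliorated: host composition and introns,
  but strong prokaryotic hits ([−150, −60]) and at most weak metazoan
  ones ([−4, −2], above the 1e-5 threshold); homolog probability 0.9;
  about half carry the external gene-family flag.
* **recent_hgt** (20) — single exon, partially ameliorated GC3 ~
  N(0.50, 0.05), the same prokaryotic protein-hit profile, and strong
  prokaryotic *nucleotide* hits over their loci ([−185, −85], bit
  scores 200–400 against a eukaryotic background tiling of 70–150).
  Their nucleotide-level foreignness is carried by the hit tables, which
  is the contract the screen actually consumes. A recent transfer with
  *fully* alien composition would be eliminated by the GC13 filter as
  indistinguishable from contamination — by design the filters cannot
  tell those apart, and the class here models the recent transfers that
  a screen of this kind can retain.
* **symbiont** (40) — the contamination model: fully alien composition
  (GC3 ~ N(0.65, 0.05), independent codon preferences), a lone
  single-exon gene on a short (5–40 kb) contig, essentially silent
  expression (log-normal around 0.3 rpkm), homolog probability 0.05.

Implanted transfers are placed in contig-interior positions with host
genes at both contig ends: a genuine transfer lies inside a host gene
neighbourhood, which is precisely the evidence the flanking filter
encodes. Bit scores follow `2·(−log10 e) + 30`. One designated GO term is
enriched among transfer/symbiont best-hit subjects at 10× its 0.05
baseline (setting `enrichment_odds = 1` produces a null dataset for
false-discovery checks); the class-conditional e-value ranges are
deliberately non-overlapping so recovery tests are sharp — overlapping
ranges, and any weaker signal regime, can be dialed in through
`hit_profile` to study failure modes.

What the generator does **not** model: real database composition and
taxon sampling, alignment mechanics (hits are drawn parametrically from
the truth, not produced by aligning the simulated sequence), DUST-exact
masking, intron sequence realism beyond exon counts, genome evolution, or
assembly error. Passing recovery tests therefore demonstrates that the
screen's logic is correct under its own assumptions — not that those
assumptions hold for any particular real assembly.

## Numerical choices

* e-value pseudocount 1e-200 inside each log; e-values capped at 1; a
  missing hit category contributes 1.
* All internal coordinates are 0-based half-open; conversion happens only
  at file boundaries (GFF3 and tabular hit coordinates are 1-based
  inclusive on disk; BED output needs no conversion).
* Ambiguous bases are excluded from every GC numerator and denominator.
* All orderings use locale-independent (radix) sorting with documented
  tie-breaks, so outputs are byte-stable across platforms.
* CA retains axes with singular values above a relative tolerance of
  `100 · max(dim) · eps`; a rank-0 (homogeneous) table yields zero
  inertia and all-zero coordinates rather than an error.
* The simulation consumes three seeded RNG streams (genome, hit tables,
  auxiliary tables) derived from one user seed by fixed offsets, so each
  stage is independently reproducible.

## Problem sizes

The package's own test suite runs the full 590-gene study once and
reuses it (about 10 s to simulate and screen), a down-scaled 76-gene
variant wherever several independent runs are needed (threshold
monotonicity, determinism, knob checks), 1,000-table fuzzing for the
Alien Index oracle, and exhaustive hypergeometric verification up to a
background of 30 genes. These sizes were chosen to make every check sharp
while keeping a complete run comfortably interactive.

## Known limitations

* The flanking filter trusts route flags to define "host-like
  neighbour"; in a heavily contaminated region where every neighbour is
  itself flagged, a true transfer fails the filter.
* The GC13 band is estimated from all genes, contaminants included; with
  heavy contamination the band widens and the filter loosens. Estimating
  it from the host codon cluster instead would tighten it at the cost of
  coupling two filters.
* Consensus taxonomy votes over phylum strings as provided; no
  taxonomy-tree reconciliation or lineage-weighted voting is attempted.
* The screen reports evidence counts, not probabilities; `n_supporting`
  treats correlated routes (the two protein-based ones in particular) as
  independent votes.
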