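---
title: "Detecting stop codon readthrough from ribosome profiling data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting stop codon readthrough from ribosome profiling data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribostop)
library(dplyr)
```

## The problem

Ribosome profiling sequences the ~25–35 nt mRNA fragments protected from
nuclease digestion by translating 80S ribosomes, giving a genome-wide map
of ribosome positions. When a ribosome decodes a stop codon as sense
(*stop codon readthrough*), it continues in frame into the 3'UTR until the
next in-frame stop, producing a C-terminally extended protein. In
profiling data this leaves a distinctive signature: footprint density
between the annotated stop and the next in-frame stop, at a level equal to
the fraction of ribosomes that read through, terminating again with a
characteristic ribosome peak at the downstream stop.

`ribostop` turns this signature into a quantitative pipeline: fractional
coverage from alignments, a countable coordinate space, candidate
extension enumeration with density/coverage/release filters, readthrough
rates and their differential regulation, orthogonal translation
diagnostics, artifact exclusion (polymorphisms, RNA editing), and an
evolutionary coding-character classifier. A seeded synthetic-data
generator supplies ground-truth datasets so every stage is validated
without external downloads.

## Density mapping

Footprint alignments are mapped to their estimated P-sites by pruning 12
nt from each end of the alignment and spreading one read evenly over the
remaining $n = l - 24$ positions (a 25-mer maps to a single position, a
26-mer contributes 0.5 reads to each of two positions). Randomly fragmented
mRNA reads are spread $1/l$ over their full alignment. Only uniquely
mapped reads of at least 25 nt are counted, and total track weight always
equals the number of counted reads (asserted to $10^{-6}$ per read).
Expression is reported as RPKM (reads per kilobase of countable feature
positions per million aligned reads) and translation efficiency as the
footprint/mRNA density ratio; coverage evenness is summarised by the area
under the Lorenz curve of per-position weights (0.5 for perfectly uniform
coverage).

## The countable coordinate space

Reads from repeated sequence cannot be placed uniquely, so a position is
masked as *degenerate* when the 29-mer centred on it occurs elsewhere in
the genome with zero mismatches. Reverse-complement occurrences count by
default (aligners map both strands; a forward-only switch exists because
the convention is not universal). Positions closer than 14 nt to a contig
end cannot form the centred window and are treated the same way.

Genes whose transcripts share exons (e.g. polycistronic annotations) are
collapsed into merged loci by transitive closure of same-strand exon
overlap; genomic positions attributed to two or more loci are excluded
from all of them. Positions are labelled 5'UTR / CDS / 3'UTR only when
every isoform containing them agrees, otherwise they stay exonic but
*ambiguous* and are excluded from region-specific analyses. A locus is
*countable* when at least 95% of its positions are non-degenerate, at
least 60 nt survive the exclusions, and none of its genes is an abundant
non-translated biotype (rRNA, tRNA, sn/snoRNA, miRNA).

## Candidate extensions and readthrough rates

For every coding transcript with an annotated 3'UTR the candidate
extension runs from the 3' edge of the annotated stop codon to the next
in-frame stop, both stops excluded. Candidates are kept when the extension
is at least 5 codons long, overlaps no annotated CDS, 5'UTR or excluded
non-coding RNA, has no methionine in its first three codons (initiation
inside the 3'UTR would mimic readthrough; a whitelist covers
experimentally validated exceptions), and is not explained by an isoform
that omits the stop codon. One candidate is emitted per unique (stop, next
stop) pair, plus a second-tier candidate beyond the extension's stop for
double-readthrough scanning (depth 2).

The readthrough rate is
$$\rho = \frac{\text{extension RPKM}}{\text{CDS RPKM}}$$
computed over peak-masked coordinates: within the CDS the 12 nt following
the start codon and the 15 nt preceding the stop are excluded, and the
start and stop codons themselves are excluded as well, because the
initiation and termination peaks are centred on them; within the
extension the first 9 nt (termination-peak bleedthrough from the
annotated stop) and the last 15 nt (the extension's own stop peak) are
excluded. Extensions of 24 nt or less have no unmasked positions and are
flagged rate-unmeasurable. A CDS floor of 128 footprint reads (the
reproducibility threshold used throughout) gates testability, and among
isoforms sharing an extension the isoform minimising $\rho$ is reported,
making the estimate conservative.

Candidates then pass through six filters: (a) extension density at least
0.2 RPKM, (b) $\rho \ge 0.001$, (c) at least 10% of extension positions
covered, (d) first covered position within the first quartile of the
extension, (e) last covered position within the last quartile, and (f) a
density drop of at least 75% into the first 114 nt of the distal 3'UTR
(extended in uninterrupted genomic coordinates when the annotated UTR is
shorter). Scoring operationalises what would otherwise be a visual
judgement: a candidate is called `readthrough` when (a), (b), (f) hold and
coverage is even — filters (c)–(e) plus a maximum covered-position gap of
50% of the extension length; when coverage is sparse the evenness
requirement is waived if the extension's stop codon carries a peak of at
least 2 reads (terminating ribosomes pause there). Candidates without
credible density (failing a or b), or failing the drop criterion or two or
more coverage criteria, are `negative`; a single narrow coverage miss is
`ambiguous`. Borderline candidates can legitimately differ from a manual
call; the thresholds are exposed as arguments.

Differential readthrough between two samples uses, per eligible gene (one
CDS across isoforms, 128+ CDS footprints in both samples, positive score
in either), the 2×2 table of peak-masked CDS and extension footprint
counts, a two-sided exact Fisher test, Benjamini–Hochberg control at 5%,
and the $\log_{10}$ fold change of $\rho$ (sample 2 over sample 1).
Fractional masked counts are rounded to integers for the exact test.

## Translation signatures

Four diagnostics distinguish genuine elongation from protected structures,
RNA-binding-protein footprints or frameshift products:

* **Metagene profiles** — per-ROI coverage vectors are normalised to the
  mean CDS density excluding a 3-codon buffer at the anchored codon, and
  the per-offset median across ROIs is reported (median, so a single
  high-expression gene cannot dominate, and per-ROI scaling cancels).
  ROIs require a unique start/stop, isoform-identical window positions, no
  degenerate positions, and at least 10 reads in the coding subregion.
  The default window is 50 nt each side of the anchor.
* **Ribosome release scores** — the ratio of footprint counts in the
  5-codon window immediately downstream of a codon to the window
  immediately upstream; near zero at efficient termination sites.
  Undefined (no pseudocount) when the upstream window is empty.
* **Read-length distributions** — footprints protected by 80S ribosomes
  share one length distribution wherever they derive from; regions are
  compared by total variation distance.
* **Triplet phasing** — for nuclease regimes that cut precisely (RNase
  I-like), footprint positions show 3-nt periodicity. Frames are tallied
  for one read length (28-mers by default, the best-phased population)
  using the 5'-most pruned P-site position relative to the host CDS frame,
  and tested against the frame proportions of matched mRNA fragments (the
  control for cloning bias; a uniform null is available) with a Pearson
  chi-squared goodness-of-fit test, 2 degrees of freedom.

## Artifact exclusion

Apparent readthrough can be mimicked by a genomic polymorphism or an
A-to-I editing event that removes the stop codon from the mRNA. For each
stop codon nucleotide the package tabulates matching and mismatching
covering reads (mismatch classes in mRNA sense) in three datasets: mRNA
fragments, all footprints, and the footprints whose P-sites have passed
the position — i.e. ribosomes that have demonstrably translated the stop.
The first aligned base of every read is excluded from both tallies because
reverse transcriptase frequently adds a non-templated nucleotide there;
the exclusion is applied to matches as well so the denominator stays
consistent.

Positions are tested against the per-offset global mismatch rate with a
one-sided (greater) exact binomial test under BH control at 5%.
Significant positions whose dominant substitution accounts for roughly
half (0.35–0.65, heterozygous) or at least 90% (homozygous) of covering
reads are genomic polymorphisms — further split by whether the mutated
codon remains a stop; stop-to-sense transcripts are flagged for exclusion
from the readthrough set. Of the remainder, only adenine positions with a
dominant A>G class are editing candidates; everything else is sequencing
error. The zygosity bands are configurable since only the idealised 50%
and 100% expectations are principled.

Finally, the editing *null* test provides positive evidence: if editing
drove the observed readthrough, conservatively 90% of A-site-passed
footprints should carry the edited base; each covered adenine is tested
for significantly fewer A>G mismatches (one-sided binomial, Bonferroni
over tested positions). Rejection at a position is evidence that editing
does not explain readthrough there.

## Coding character and selection

The 189-variable phase-specific Z-curve maps a window's k-mer composition
(k = 1–3, with frequencies of each final base conditional on its prefix
at each codon phase) onto (x, y, z) purine/amino/weak–strong axes. Counts
are taken cyclically — a k-mer running past the window end wraps to the
start — so every phase contributes the same number of k-mers for every k
and the features are exactly invariant under in-frame repetition; a
trailing partial codon is dropped first. Windows must be at least 81 nt:
shorter windows make the classifier error-prone. Conditional
(prefix-normalised) frequencies are the default, with a joint-frequency
switch, because the literature is not explicit and both parameterisations
satisfy the dimensionality and range contracts.

The classifier itself is a Fisher linear discriminant (via `MASS::lda`)
behind a small strategy surface, trained on coding vs distal-3'UTR
windows with k-fold cross-validation (default 4) reported before the
final all-data fit; the fitted object supports `tidy()`, `glance()`,
`predict()` and a flat-text serialisation. Region groups are scored on
one seeded random 81-nt window each (an option excludes the last 50 UTR
bases to dodge polyadenylation signals) and compared with Mann–Whitney
rank-sum tests.

SNP synonymy asks whether segregating variation avoids amino acid
changes: each SNP is mapped to its host codon and frame (CDS frames from
the annotation; extension and distal frames continue the CDS frame), the
substitution is called synonymous or not under the standard genetic code,
and regional proportions are compared with one-sided Fisher tests. The
ER-retention scan flags peptides whose C-terminus matches `[KH]DEL`.

## Exact statistics

The shared primitives — Fisher's exact test (two-sided by the
probability-mass convention; the differential test is two-sided, the SNP
test one-sided), exact binomial tails (term-by-term log-coefficient sums,
no normal approximation), BH step-up FDR, chi-squared goodness of fit,
and the Mann–Whitney test (midranks; full enumeration of assignments up
to 20 combined observations, tie-corrected normal approximation beyond) —
are implemented in the package so each step is auditable against closed
forms, and the test suite cross-checks them against independent base-R
implementations and brute-force enumeration.

## The synthetic-data generator

`sim_config()` + `generate_transcriptome()` + `simulate_reads()` define a
forward model of the statistical structure the analysis assumes. Each
gene lives on its own toy chromosome (plus strand, single exon) with a
5'UTR, an ATG-initiated CDS built from a fixed moderately biased codon
usage (one preferred codon per amino acid; the bias produces the phased
composition that separates coding from non-coding sequence), a stop
codon, and a 3'UTR that, for genes with a configured readthrough rate,
begins with a stop-free in-frame extension (no ATG in its first three
codons) followed by its own stop and a distal tail.

Footprints are drawn from a codon-occupancy model: CDS codons at weight
1, extension codons at the gene's readthrough rate $r$ (second extension
at $r^2$ for double-readthrough genes), an initiation peak over the three
codons around the start, and — only when termination is blocked during
harvesting (`include_termination_peaks`, modelling flash-frozen samples;
absent when ribosomes release during harvest) — a termination pause on
the codon 5' of each stop, where the paused ribosome holds the stop in
its A site. This placement matters: putting pause density on or past the
stop codon itself would leak footprint weight beyond the stop and into
the release-score and extension windows, which is not what paused
terminating ribosomes produce. Peak heights (defaults: initiation 8,
termination 6 times mean CDS codon occupancy) and the 3'UTR background
(default 0) are free parameters of the model — no quantitative values
exist for them — and are documented as such.

Within a codon the P-site nucleotide takes frame 0/1/2 with weights
90/5/5. In `phased` mode (RNase I-like) the read starts exactly 12 nt 5'
of the P-site, so the 5'-most pruned position recovers the frame; in
`blurred` mode (MNase-like positional uncertainty) the pruned window is
centred on the P-site with ±2 nt jitter, destroying sub-codon
information, as MNase's cutting bias does. Read lengths follow a
configurable 25–35 nt distribution peaked at 29–30 nt. Sequencing errors
are injected per base (default 0.001), and configured polymorphism and
editing sites flip covering reads at their allele fraction, for both
footprints and mRNA fragments. Optional contaminants add +1-frameshifted
3'UTR density or a structure-protected pile-up; optional uORFs add 5'UTR
density. Every footprint carries exactly one provenance label (CDS, uORF,
extension, contaminant); exactly the requested read counts are emitted;
and everything is deterministic given the config, including its seed.

What the generator does **not** emulate: sequence-dependent nuclease
bias, realistic base-call error profiles, rRNA contamination, spliced
reads, isoform mixtures, or uneven elongation (pausing) along the CDS.
Passing tests therefore demonstrate that the pipeline's logic and
statistics behave as specified under the assumed generative structure —
not that real libraries satisfy those assumptions.

## Validation scale and reproducibility

The test suite validates rate recovery on 20 seeded simulations of five
genes (true rates 0.005–0.2 plus a zero-rate control) at roughly $10^5$
footprints per gene, requiring estimates within three binomial standard
errors of truth in at least 95% of cases, sensitivity of at least 0.9 at
rates of 0.01 and above, and no positive calls at rate zero. Artifact
detection is validated on 20 seeded simulations each for injected
homozygous stop-to-sense polymorphisms and sub-zygosity editing sites at
20× coverage or more, plus 20 null simulations for empirical
false-positive control. These sizes keep the full suite to a few minutes
on one core while leaving binomial noise well below the tested margins.
`scripts/acceptance.R --seed <s> --out <path>` re-runs the worked
examples and a deep single-gene recovery from scratch and writes the
resulting numbers as JSON.

## Known limitations

* Splice-aware handling covers multi-exon annotations and block-aligned
  reads in the coverage layer, but the simulator emits only unspliced
  single-exon genes, so junction-spanning behaviour is exercised by unit
  fixtures rather than end-to-end simulation.
* The P-site offset is the fixed symmetric 12-nt trim; no length- or
  nuclease-specific offset calibration is attempted.
* Scoring thresholds reproduce documented values where they exist; the
  evenness gap proxy (50% of extension length) stands in for a visual
  judgement and borderline candidates may differ from manual calls.
* Phylogenetic codon-substitution scoring, SECIS-element detection and
  localisation-signal prediction are external analyses; their outputs can
  be joined onto the candidate table but are not reimplemented here.

## A compact worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1, n_genes = 4,
                  readthrough_rate = c(g001 = 0.05, g002 = 0),
                  total_footprints = 2e5, total_mrna_fragments = 5e4)
tr  <- generate_transcriptome(cfg)
sim <- simulate_reads(cfg, tr$genome, tr$annotation)
trk <- coverage_track(sim$footprints, "footprint")
cand <- enumerate_candidates(tr$annotation, tr$genome,
                             candidate_exclusion_positions(tr$annotation))
rec <- detect_readthrough(cand, tr$annotation, trk,
                          library_size = nrow(sim$footprints))
rec |> filter(tier == 1) |> select(gene_id, rho, score)
```
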