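---
title: "circscan: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{circscan: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Exonic circular RNAs (circRNAs) arise by back-splicing: a downstream splice
donor is joined to an upstream splice acceptor, producing a covalently closed
circle. In RNA-seq data the only direct evidence for a circle is a read that
spans the back-splice junction — its 5' part matches the genome *downstream*
of where its 3' part matches, the reverse of any linear transcript. circscan
implements a complete analysis chain around that signal: strict anchor-based
junction detection, removal of junctions that also map linearly to the genome
(mis-annotations), normalization against host-gene expression, statistics on
the introns flanking circularized exons and on complementary SINE repeat
pairs within them, end-anchored cross-species conservation with an in-silico
control null, and expression-profile analytics (clustered heatmap matrices,
circ/host correlation, hot-spot genes).

Every stage is exercised on synthetic genomes with planted ground truth; the
package makes no network access and needs no reference downloads.

## Detection model

A read of length $L$ (default 100 nt) is split into two terminal anchors of
$k$ nt (default 20). Each anchor must have **exactly one exact** genomic
occurrence — the strictest mapping-quality contract, equivalent to demanding
an exact match to both termini of the circularized exons. Both hits must lie
on one chromosome, on one strand, with the 3' anchor genomically upstream of
the 5' anchor (the back-splice signature) within `max_span` (default 100 kb).
The anchors are then extended toward the read interior to find a breakpoint
that

1. explains every read base with at most 2 substitutions outside the anchors
   (never inside them), and
2. places a canonical splice signal at the inferred intron edges — GT after
   the donor and AG before the acceptor in forward coordinates for a
   plus-strand circ, or their reverse complements (CT / AC) for a
   minus-strand circ.

The circ strand is fixed by which signal orientation validates, not by which
genome strand the read happened to match: a reverse-complemented read of a
plus-strand junction evidences the same junction, and both orientations
group together. Among signal-consistent breakpoints the one with the fewest
mismatches wins — the usual maximal-scoring-alignment rule; if no breakpoint
validates, or several tie at the best score, the read is rejected, never
guessed. The GT/AG requirement makes such ties vanishingly rare: a
breakpoint shifted by one position would need the donor G of the true
signal to double as the A of a shifted AG, which is impossible, and an
equal-scoring alternative needs a splice-signal coincidence *and* an exact
sequence echo at the shifted position.

Junctions are then grouped by (chromosome, start, end, strand) and reported
only with **two or more supporting reads within a single sample**. One read
in each of two samples never suffices.

Reads with a full-length contiguous (near-)exact genomic match are removed
before anchor analysis; a candidate can therefore never originate from a
linearly explained read.

## Mis-annotation filter

Some apparent back-splice junctions are artifacts of repetitive exonic
sequence or high-homology neighboring genes: their junction-spanning
sequence also maps to the genome *in a linear manner*. circscan builds a
junction probe of $J$ nt from each side of the back-splice (default
$J = 80$, the maximal context a 100-nt read can assert) following the
spliced circular sequence when gene models are available, and aligns it to
the genome with an 11-mer seeded, ungapped, diagonal-extension scheme. The
probe is deemed linear when a single diagonal, or two colinear diagonals
separated by a plausible intron (≥ 20 nt, genomic order matching probe
order), cover ≥ 90 % of the probe at ≥ 90 % identity; such candidates are
removed. The back-splice locus itself is masked. The identity/coverage
thresholds are configuration values because no canonical values exist for
this step; they were fixed a priori and all tests run at the defaults.

## Quantification

* **RPM** — back-splice junction reads per million raw reads:
  $\mathrm{RPM} = s \cdot 10^6 / N$ for $s$ junction reads in $N$ raw reads.
  The default expression floor of 0.05 RPM demands more than one read at a
  21-million-read sample, consistent with the two-read support rule.
* **pseudo-RPKM** — RPM made comparable to host-gene FPKM by dividing by the
  effective detectable junction length and scaling per kilobase. With
  100-nt reads and 20-nt anchors a junction is detectable from reads
  starting up to 80 nt away on each side, so the effective length is
  $2(L - k) = 160$ nt and pseudo-RPKM $= \mathrm{RPM} \cdot 1000 / 160
  = 6.25 \cdot \mathrm{RPM}$ exactly.
* **Hosts** — a circRNA's host is the gene whose interval overlaps it the
  most on the same strand; antisense overlaps are recorded but never
  assigned, and intergenic circs keep an undefined circ/host ratio (never 0
  or infinity). On synthetic data host FPKM comes from a simple exon-union
  counter (reads placed by a unique terminal-anchor hit, FPKM
  $= r \cdot 10^9 / (N \cdot \ell_{union})$); transcript assembly is out of
  scope and real-data FPKM tables can be supplied directly.
* **Summary** — per sample and for an "All" column (union of per-sample
  calls): expressed circRNAs (≥ 0.05 RPM), expressed genes (≥ 1 FPKM), genes
  producing circRNAs, circRNAs above their host (pseudo-RPKM strictly
  greater than host FPKM), and hot-spot genes (≥ 3 circRNA isoforms).
* **Pathway candidate export** — circRNAs above 0.15 RPM at the first time
  point with a ≥ 2-fold decrease at the second (a zero second value counts
  as an infinite fold, flagged); unique host genes are exported with a
  background list of expressed genes for external enrichment tools, which
  are themselves out of scope.

## Flanking-intron and SINE statistics

For each circRNA whose outer splice sites coincide with annotated exon
boundaries, the introns immediately upstream of the acceptor and downstream
of the donor are extracted (transcript orientation); circs starting at a
first exon or ending at a last exon are excluded. Controls are the internal,
never-circularized exons of circ-hosting genes under the same exclusion.
CircRNAs are tiered by RPM: low (0.05–0.5], medium (0.5–2.5], high (> 2.5).

Intron lengths (both flanks contribute) are compared tier-vs-control with
the two-sided Kolmogorov–Smirnov test. SINE elements falling in the two
flanking introns are paired across the circ; a pair is **complementary**
when both elements share a repeat family and lie on opposite genomic strands
— the configuration able to base-pair across the circularized exons.
Cross-family pairs count as non-complementary. Three statistics follow:

* a bar analysis of complementary vs non-complementary pairs whose elements
  lie within 500 bp of the circ-facing intron ends, with a Pearson
  chi-squared test against the control group (no continuity correction;
  small expected counts are flagged);
* a cumulative distance analysis, where pair distance is the genomic gap
  between the elements' circ-facing edges minus the donor-to-acceptor span,
  using each circ's minimum-distance complementary pair (to avoid
  long-intron pair-count inflation), KS-tested against control;
* the fraction of circs with a complementary pair within 1500 bp.

Pairs are formed across the two introns only; within-intron pairing — the
known confounder that counteracts circularization — is out of scope.

## Conservation

Intronic sequence diverges quickly between species, so lifting a whole
multi-exon circRNA through an alignment chain usually fails. circscan
instead lifts the terminal 20 bp of each end independently through a UCSC
chain (rtracklayer), requires both ends to map completely inside single
blocks to one chromosome and strand with their order preserved, and
recombines the outermost lifted coordinates. Conservation is counted as
exact coordinate identity against the other species' circ set (strand
checking on by default, configurable), with the successfully lifted set as
denominator.

Significance comes from an in-silico null: every contiguous exon run of
every transcript of genes above 10 FPKM is enumerated ($n(n+1)/2$ runs for
an $n$-exon transcript, deduplicated by outer coordinates), detected
circRNAs are removed, and candidates are drawn at random until as many
controls lift as real circRNAs did. Observed vs control identity counts are
compared with a 2×2 Pearson chi-squared test.

## Profiling

The top-N circRNAs by maximum RPM (default 200) are log2-transformed; absent
values take the lowest observed log2 score in the selected matrix before
each row is centered on its mean. Clustering is average-linkage on
$1 - r$ (Pearson); rows are pre-sorted lexicographically by id so the merge
sequence is invariant under input permutation, and zero-variance rows get
the maximal distance 2, flagged. Circ/host correlation pools all paired,
transformed profile values into a single Pearson coefficient. Hot-spot
genes (≥ 3 isoforms) are classified by whether all isoforms share the
splice donor, the acceptor, or neither, where on the plus strand the
acceptor is the start coordinate and the donor the end (reversed on minus).

## The synthetic-data generator

The generator lays out non-overlapping multi-exon genes on both strands,
with canonical GT..AG introns (genomic CT..AC for minus-strand genes), and
plants:

* **circRNAs** on internal contiguous exon runs (so both flanking introns
  exist), at most one per gene, with log-uniform target abundances;
* **long flanking introns**: the two introns flanking a planted circ are
  drawn from a long-length class (1.5–6 kb log-uniform) against a short
  background class (0.2–0.8 kb) — the intron-length correlate the feature
  analysis is designed to detect. A homogeneous mode (`flank_intron_class
  = "same"`) exists for null calibration;
* **SINEs**: a fixed 160-bp consensus inserted into introns at a Poisson
  background density with random strands and families, plus — with
  probability `complementary_flank_bias` — a same-family opposite-strand
  pair within 500 bp of the circ-facing ends of the two flanking introns.
  The default bias of 0.5 mirrors the observation that roughly half of
  circRNAs carry proximal complementary SINEs;
* **decoys**: internal exon runs of otherwise circ-free genes whose 160-bp
  junction probe is copied *exactly* into intergenic sequence. Such a locus
  makes the junction linearly mappable (the mis-annotation filter's target)
  while its duplicated anchors also demonstrate why the strict
  unique-anchor rule rejects reads from the mimic itself;
* **an ortholog genome**: an indel-mutated copy (indels confined to
  intergenic gaps) with a valid chain file and its exact inverse; exactly
  $\lceil f \cdot n \rceil$ planted circs appear as identical junctions in
  the ortholog annotation for a configurable conserved fraction $f$.

Reads are simulated single-end at 100 nt (the detection math treats reads
independently; paired-end modeling adds nothing here). The raw sequencing
depth (`total_raw_reads`, default $10^6$) — the RPM denominator and the
basis for junction-read counts, $\mathrm{count} = \mathrm{round}(
\mathrm{RPM_{target}} \cdot N / 10^6)$ — is a parameter separate from the
number of linear reads actually emitted, so desk-scale runs keep exact RPM
semantics without writing millions of reads. Junction reads span the
back-splice with at least one full anchor on both sides; qualities are a
constant Phred 'I' and are never used. What the generator does **not**
emulate: realistic base-quality and error profiles, PCR duplicates,
fragment-size distributions, rRNA contamination, within-intron repeat
pairing, alternative transcript isoforms, and sequence-level homology
between SINE copies and their flanking context. Passing tests therefore
demonstrate algorithmic correctness on idealized data, not performance on
real libraries.

## Numerical choices and degenerate inputs

* Coordinates are 1-based closed inside the package (the GRanges/IRanges
  convention used by every container here); GTF is emitted 1-based closed
  and BED 0-based half-open per their standards. Junction ids are
  `chrom:start-end:strand` in internal coordinates.
* Pearson chi-squared tests run without continuity correction; degenerate
  2×2 margins raise errors rather than silent NaNs.
* The KS test assumes continuous distributions: bp-rounded intron lengths
  introduce ties (conservative p-values), and at equal group sizes the
  two-sample statistic lives on a coarse lattice, so calibration studies use
  the continuous length model and unequal (coprime) group sizes.
* pseudo-RPKM is computed as `rpm * (1000 / 160)` so the slope is exactly
  6.25 in floating point.
* Circs shorter than 40 nt cannot yield a junction probe (error); probes on
  circs shorter than $2J$ truncate each side to half the circular sequence
  length and are flagged.
* A planted circ whose target RPM rounds to zero reads warns and stays in
  the truth table only. All-zero expression matrices and empty control
  groups are errors, not empty results.
* Determinism: all generators run under a private, restored RNG state keyed
  by their `seed`; identical seeds give byte-identical files.

## Problem sizes

The test-suite and acceptance-script runs use, as the package's chosen
study sizes: detection on 5 chromosomes × 100 kb with 60 genes and 25
planted circRNAs at 0.5–20 RPM and $10^6$ raw-read depth; the
mis-annotation filter on 40 genuine circs plus 10 decoys; feature analysis
on 5 × 280 kb with 140 genes, 90 circRNAs spanning all three expression
tiers, and a SINE density of 12 per 10 kb (chosen so the control group
carries enough in-window SINE pairs for a well-posed chi-squared test);
conservation on 200 planted circRNAs at a conserved fraction of 0.5. The
oracle-equivalence check runs on a single 50-kb chromosome where brute-force
enumeration of every junction window is exhaustive.

## Known limitations

* The detector requires canonical GT/AG junctions; non-canonical
  back-splices and trans-chromosomal fusions are out of scope by design.
* Unique-exact-anchor matching discards reads whose anchors land in recent
  repeats or paralogs — the deliberate trade of sensitivity for precision.
* The mis-annotation check is an ungapped two-block emulation of BLAT, not
  a full local aligner (no translated search, no near-mers, at most one
  intron-like gap).
* Host FPKM on synthetic data uses anchor placement, which misassigns the
  small fraction of reads whose terminal anchor crosses a splice junction.
* Chain support covers plain block mappings (one net per chromosome, no
  overlapping target blocks), which is what the simulator emits; real
  genome-browser chains with nested nets are untested territory.
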