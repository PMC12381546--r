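---
title: "Methods: pangenome gene-family characterization with panfam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pangenome gene-family characterization with panfam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panfam)
```

# Overview

Gene-family surveys built on annotated protein databases inherit every
weakness of the annotations: projected gene models miss exons, frameshift
alleles vanish from protein sets, and unannotated paralogs are invisible.
`panfam` implements an assembly-first characterization pipeline for
multi-genotype pangenomes, with the CCT-motif family of barley
(CONSTANS/CONSTANS-LIKE/TOC1; subfamilies CMF, CO, PRR, GATA and ZCCT,
the VRN2-like zinc-finger class) as the motivating system:

1. **Domain scanning and classification.** Proteins are scanned with
   per-domain position-specific scoring matrices (PSSMs); the overlap of
   domain hits assigns a subfamily (CCT alone gives CMF; CCT plus B-box,
   CO; CCT plus a pseudo-response-regulator receiver domain, PRR; CCT
   plus GATA or zinc finger, GATA or ZCCT). Proteins retaining a
   companion domain but no CCT hit are flagged as potential CCT-domain
   deletions.
2. **Assembly-level validation.** Each gene's genomic sequence is
   searched against every genotype assembly by seed-and-extend; merged
   loci give copy counts, yielding a presence/absence-and-copy-number
   (PAV/CNV) matrix and the core/dispensable partition.
3. **Frameshift analysis.** The reference coding sequence is aligned
   exon-by-exon to each recovered locus; signed indels, the net frame
   shift, premature stops, and downstream in-frame ATG rescue are
   evaluated, and genome-level evidence is reconciled with the
   annotation into one status per gene and genotype.
4. **Phylogeny.** Neighbor-joining trees on pairwise-alignment
   p-distances, used for clade-consistency checks and reference-based
   copy labeling.
5. **Genotype-level variation.** Peptide 3-mer frequency PCA with cos²
   contributions, a leave-family-out rerun, and a centroid-distance
   driver ranking.

Because real pangenome assemblies are far beyond desk scale, the package
carries its own synthetic pangenome generator that plants every
phenomenon the pipeline claims to detect — with a machine-readable truth
table — so each stage is verifiable end to end.

# The synthetic pangenome

`simulatePangenome()` builds one founder gene per family on an i.i.d.
uniform nucleotide background (genes non-overlapping, at least 2 kb
apart, so no accidental homology confounds seed search) and then evolves
each genotype independently.

**Founder genes.** Each founder has 170–230 residues, a CDS that starts
with ATG and ends with a stop, and 3–4 exons by default (introns 80–300
bp, GT..AG). Domain instances are stamped from a fixed template library
(CCT, B-box, PRR receiver, zinc finger, GATA; pairwise global-alignment
identity below 40%) with a per-column substitution tolerance of 0.08 at
non-anchor positions. Three structural choices make downstream phenomena
well-posed:

* the CCT domain is encoded entirely within the **last exon**, companion
  domains within interior exons, so removing the terminal exons from the
  annotation reproduces the "intact gene, CCT-truncated annotation"
  misannotation pattern;
* an in-frame methionine sits 4–8 residues upstream of the CCT domain,
  a natural alternative translation start preceding the domain;
* domains are placed away from exon boundaries, so partial-domain
  deletions stay within one exon.

**Events.** Per gene and genotype, events are drawn independently at the
configured rates (defaults: deletion 5%, tandem duplication 5%,
dispersed duplication 3%, 1-bp coding indel 5%, partial domain deletion
3%, annotation truncation 5%). A deletion suppresses all other events on
that gene; of the three mutually incompatible coding events at most one
applies (indel, then domain deletion, then truncation). Tandem
duplicates land 200–2000 bp downstream of the source gene, dispersed
duplicates at least 50 kb away; both derive from the founder sequence
diverged at 2% per site, and both are deliberately left **unannotated**
— novel copies must be discovered from the assembly, as in real
pangenomes. Partial domain deletions remove an in-frame block covering
60% of the CCT domain. Annotation truncations leave the genomic sequence
untouched and drop the first and last exon from the GFF3 and the
protein output.

**Neutral divergence.** Intergenic and intronic sites substitute freely
at 2% per site (the ≤ 5% regime the DNA search is specified for). Inside
coding sequence, neutral divergence is applied as *synonymous* codon
substitutions at the same per-codon rate. This is a deliberate
simplification: it exercises the genomic search at realistic divergence
while keeping protein-level truth exact, so a failed domain scan is
always a planted event, never background noise. Consequently the
simulation does **not** emulate nonsynonymous drift, codon-usage bias,
transposable elements, recombination or assembly error — passing tests
demonstrate correctness of the machinery under clean planted variation,
not robustness to every feature of real data.

**Indels.** 1-bp indels are planted at interior coding positions at
least 12 bp from exon boundaries: an indel at a splice boundary acts as
a splice-site mutation, a different phenomenon whose spliced-CDS
interpretation is inherently ambiguous to any aligner. Positions are
left-normalized through homopolymer runs (the same canonicalization VCF
uses) in both the truth table and the detector, so positions compare
exactly.

**Determinism.** One RNG stream per genotype is derived from the master
seed; identical configurations give byte-identical FASTA/GFF3/TSV
output.

# Alignment and search

Pairwise global and local alignment use affine gap costs where a gap of
length $L$ costs $\mathrm{open} + L\cdot\mathrm{ext}$ (defaults: DNA
+1/−1 with −5/−1; protein BLOSUM62 with −11/−1). The implementation is
delegated to `Biostrings::pairwiseAlignment`, whose gap convention
matches exactly; the test suite proves score equality against an
independent pure-R three-state dynamic program, itself validated against
exhaustive enumeration of all alignments at tiny lengths. Identity is
the fraction of alignment columns (gap columns included) with equal
residues. Tie-breaking among equal-score tracebacks follows the C
library's deterministic order; because equally scoring indel placements
are genuinely interchangeable, reported 1-bp indel positions are
canonicalized by left-normalization rather than by constraining the
traceback.

`seedExtendSearch()` is the package's nucleotide homology search: exact
15-mer seeds located through a sorted 2-bit numeric index of each
assembly (`kmerIndex()`, built once per genotype), chained into
candidate loci by diagonal bands of half-width $20 + 0.05\,|q|$, then
extended by local alignment of the query against the padded candidate
window. Hits require identity ≥ 0.9 and query coverage ≥ 0.8 by default
— the presence-calling thresholds are exposed because no canonical
values exist for this step; at ≤ 5% planted divergence recovery is
complete with ample margin.

**Locus merging.** `mergeHits()` merges hits on the same replicon and
strand within 2 kb *provided their query spans are complementary*
(overlap below half the shorter span). The guard matters: merging exists
to reunite fragments of one copy's alignment, while two nearby tandem
copies — each covering the whole query — must remain separate loci,
since the locus count is the copy count. A pure interval rule with a
2 kb gap would fuse tandem copies planted 200–2000 bp apart.

# Domain models and the exclusion threshold

PSSMs are built from sampled domain instances with a
background-proportional pseudocount (log-odds in bits). Scanning slides
the model along the protein, greedily keeps non-overlapping windows by
descending score, and excludes windows below a calibrated threshold.
Calibration is Monte-Carlo: decoy sequences drawn from the background
are scanned, and the threshold is set where the expected number of
decoy hits — rescaled to the size of the real query set — equals one,
mirroring the "exclude expected-false-positive counts above 1" rule
used with homology-search E-values. The threshold estimator is a tail
order statistic; it is stable (±0.5 bits under doubling of the decoy
sample) when decoy windows exceed the query-set size many-fold, the
intended operating regime.

One subtlety separates *significance* from *intactness*: a domain
remnant left by a 60% deletion can still score far above the calibrated
threshold — it is a real, significant homology — yet the domain is
functionally gone. Status assignment therefore counts a domain as
*retained* only when its hit scores at least 0.7× the reference
protein's hit for that domain. Any fraction between roughly 0.45 (the
designed remnant) and 0.9 (a tolerantly substituted full domain)
separates the two regimes; 0.7 is the midpoint.

# Frameshift detection, rescue and status

`exonAwareAlignCds()` anchors each reference exon in the locus by local
alignment, then re-aligns the full exon end-to-end (exon-global,
locus-local) inside the anchor window, concatenating per-exon results.
Unanchored exons (local identity < 0.75 or exon coverage < 0.5, or
out-of-order anchors) are reported as missing intervals. The net frame
shift is the signed indel sum modulo 3; a premature stop is the first
stop before 90% of the reference protein length (the cut-off is a
package decision — no canonical value exists). The status decision
table checks domain loss *before* the premature-stop rule, because an
in-frame deletion shortens the protein and would otherwise masquerade
as a stop variant.

Rescue scans ATG codons downstream of the last frame-disrupting indel
that are in the frame of the reference stop codon (anchored at the 3'
end of the variant CDS), takes the 5'-most one whose translation
reaches the stop uninterrupted — maximizing the retained product —
translates, and re-scans domains. Only ATG is considered; near-cognate
starts are out of scope.

When a genotype carries both a coding variant and a duplicate copy, the
best-scoring locus may be the intact duplicate; status and frameshift
analysis therefore use the locus overlapping the *annotated* gene
position whenever an annotation exists, falling back to the
best-scoring locus otherwise.

# Phylogeny and copy labeling

Distances are p-distances (1 − identity) on global alignments — monotone
with divergence at simulation scale, so no rate correction is applied.
Trees are standard neighbor-joining (`ape::nj` behind `njTree()`, with
negative branch-length estimates clamped to zero), which provably
recovers additive matrices exactly; maximum-likelihood inference and
bootstrap support are out of scope because the package's claims concern
clade membership, not support values. Copy labeling assigns each locus
the reference with the highest global-alignment identity, returning
AMBIGUOUS when the lead over the runner-up is below 0.5 percentage
points.

# k-mer PCA and driver ranking

Proteins are pooled per genotype and overlapping peptide 3-mers counted
(k-mers containing non-standard residues skipped); rows are normalized
by the genotype's total k-mer count so PAV, CNV and partial deletions
express themselves as frequency shifts. The PCA centers but does not
scale by default: rows are already normalized frequencies, and
near-constant k-mer columns make unit-variance scaling unstable; a
`scale` flag is provided because PCA front-ends commonly standardize,
and neither behavior is asserted as canonical. Explained variance is the
eigenvalue share in percent; cos² of a genotype on a dimension is its
squared coordinate over its squared distance from the centroid, and the
reported plane value sums dimensions 1–2 (the aggregation used for
point coloring is a package decision). Identical rows give a flagged
degenerate result with zero coordinates.

`rankDriverGenes()` formalizes the manual "build a phylogeny of
contrasting genotypes and see which family separates them" step: for
each family, genotype profiles computed from that family's sequences
alone are averaged within each contrast group, and families are ranked
by the Euclidean distance between group centroids (ties alphabetical;
families absent from an entire group are flagged, with the zero profile
as their centroid). It is a methodological substitute for, not a
reproduction of, the manual tree contrast.

# Problem sizes and verification

The reference verification condition used throughout the test suite and
the acceptance script is 12 genotypes × 8 families on 0.5 Mb assemblies
at ≤ 5% divergence — large enough that every event class occurs several
times, small enough to analyze in about a minute. Under that condition
the package recovers planted truth exactly: PAV recall and precision 1,
exact copy counts, every 1-bp indel with correct sign and position,
every truncation flagged as a misannotation candidate, every deletion
as a true deletion; aligner scores match brute force on hundreds of
random pairs; NJ reconstructs 50 random additive matrices to 1e−9. The
test suite computes all of these afresh on every run.

Known limitations: the simulator's clean-background assumptions above;
single-transcript gene models (no UTRs or alternative splicing); ORF
finding reports every ATG-to-stop reading frame rather than predicting
gene structure; E-value-style calibration assumes an i.i.d. background;
and the k-mer PCA treats genotypes as bags of family proteins, ignoring
within-genotype paralog identity.
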