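---
title: "Profiling nrDNA polymorphism and the ITS-CAPS assay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling nrDNA polymorphism and the ITS-CAPS assay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nrpoly)
```

## The biological model

Nuclear ribosomal DNA in plants is a tandem array of hundreds of copies of
one repeat unit; in mulberry the unit is 5814 bp: 18S (1808 bp), ITS1
(215 bp), 5.8S (163 bp), ITS2 (233 bp), 26S (3395 bp). Concerted
evolution tends to homogenise the copies, so a deep-sequenced accession
usually shows one allele per site. When homogenisation is incomplete, a
site can carry the reference base in some rDNA copies and an alternative
base in others of the *same individual*. `nrpoly` represents this with a
two-state zygosity model on VCF-style genotype observations:

* **homogeneous** — only the alternative allele observed (1/1-like calls);
* **heterogeneous** — reference and alternative co-occur (0/1-like calls);
* **absent** — only the reference (0/0), i.e. not a variant of that
  accession.

All coordinates are 1-based inclusive internally; the BED writer converts
to 0-based half-open on export. InDels are anchored at their leftmost
reference base (VCF convention), and the anchor decides their region.

## Variant profiling

Records are screened with the standard hard-filter expressions for
site-level annotations (SNPs: QD < 2, MQ < 40, FS > 60, SOR > 3,
QUAL < 30, MQRankSum < −12.5, ReadPosRankSum < −8; InDels relax FS to 200
and SOR to 10). A missing annotation can never fail its criterion — the
same convention variant-filtration engines use for unevaluable
expressions — and `apply_hard_filters()` reports every violated criterion
by name, so filtering is monotone: worsening one annotation can only move
a record from pass to fail.

The species tally counts *distinct loci*, not calls: a locus observed in
at least one accession of a species contributes once, to the column of
its region (ITS1/5.8S/ITS2 pooled as "ITS") and to a zygosity class. A
locus heterozygous in any member accession is counted as heterogeneous
for the species, otherwise homogeneous. The study-style tables report one
label per species-locus without stating the aggregation rule; "any
heterozygous member wins" is the choice here because a single
heterozygous observation already proves unhomogenised copies in the
species, whereas the converse cannot be inferred from one accession.

## IUPAC haplotypes and clustering

The haplotype panel is the union of SNP loci across the cohort, sorted by
position; sequences cover the panel sites only (the conversion mirrors
vcf2phylip-style SNP-matrix extraction, with no realignment). Per locus:
absent → reference base, homogeneous → alternative base, heterozygous →
the two-base ambiguity code (R, Y, K, M, S, W). Deduplication is exact
string matching; groups order by size with ties broken by first
occurrence. Missing genotypes are not modelled — every accession is
assumed covered at every panel locus, which the >2600-fold coverage of
rDNA arrays makes realistic.

Distances between haplotypes are the fraction of columns whose IUPAC base
sets are disjoint. This makes a heterozygous R identical (distance 0) to
both A and G — deliberately conservative: a partially homogenised site is
never evidence of divergence. The cost is that the triangle inequality
can fail, which is why the tree builder asserts symmetry and a zero
diagonal but not metricity.

Trees come from Saitou–Nei neighbor joining, written in-package so its
degenerate-case behaviour is pinned down:

* the Q-minimising pair is joined; among ties the pair with the smallest
  distance wins, then the first pair in row-major order. The secondary
  tie-break matters: cohorts of near-identical haplotypes produce large
  zero-distance blocks whose Q scores tie with cross-block pairs, and
  preferring the zero-distance pair keeps identical haplotypes
  coalescing before anything attaches between them;
* negative branch lengths are clamped to zero with the length moved to
  the sibling branch (so the pairwise distance of the joined cherry is
  preserved);
* additive matrices are recovered exactly (tested against enumeration-free
  round-trips on random 5–8 leaf trees and cross-checked against the
  independent implementation in `ape`).

Species clusters are counted on the midpoint-rooted tree: every leaf is
assigned to its highest species-pure ancestor; the resulting clades
partition the leaves. Midpoint rooting is used because the procedure
needs *a* root and the data provide no outgroup. Maximum-likelihood
inference, model selection and bootstrap support are out of scope; the
NJ stand-in is asserted only on the synthetic cohort, never claimed to
reproduce an ML topology on real data.

## Insertion read counting

The 13 bp / 16 bp ITS1 insertion at position 1862 is detected directly in
raw reads with flank-anchored regular expressions; the printed patterns
contain a spaced ". + " which is implemented as the regex `.+` (one or
more bases), the only reading under which they match anything. Both
insertion sequences end in `AATGCG`, so the insertion pattern
`TCGAAACC.+AATGCGCCCCAACCCC` (and its reverse complement) recognises both
alleles. Every insertion-matching read also matches the looser reference
pattern, so classification checks the insertion patterns first — without
that precedence each insertion read would be double-counted as reference.
Reads are taken as given; the pattern pair already encodes both
orientations, so no extra reverse-complement pass is run, and no
deduplication or end-anchoring is applied. The per-allele evidence
threshold `min_reads` defaults to 1 (an accession with even one read of
each allele is called `mixed`), configurable for stricter calling.

## The ITS-CAPS assay

In-silico PCR finds the forward primer on the plus strand and the reverse
complement of the reverse primer downstream; binding must be unique
(no site → error; several candidate products → ambiguity error), and
matching is exact by default (`max_mismatch = 0`) since the primers are
species-group specific by design. Digestion scans the plus strand for
the recognition motifs with N matching any base; both motifs (GGTNACC,
TGCGCA) are palindromic under IUPAC complement, so plus-strand scanning
accounts for all double-strand cuts. Cut offsets follow the enzymes'
chemistry: BstEII cuts after the first base of its site (G^GTNACC), MstI
is blunt after the third (TGC^GCA). Fragments are consecutive differences
of the cut positions and always sum to the amplicon length.

The banding classifier keys only on robust bands: the ~449 bp BstEII band
(the *M. alba* diagnostic), the ~602–604 bp MstI band (the nigra-group
diagnostic), and complete resistance to both enzymes (*M. notabilis*).
The 91/100 bp fragments are ignored — on a 1.5 % agarose gel they are
often too faint to score. The band tolerance defaults to 5 bp because
length differences below that are not resolvable on such gels; it is a
parameter, not a constant. An accession with a heterozygous insertion is
digested as the union of its two allele templates' fragment multisets,
mimicking a mixed gel lane, and calls `heterogeneous_indel` when both
diagnostic bands co-occur.

## What the synthetic study emulates

The generator rebuilds the study conditions rather than the study's raw
data:

* **Reference (5814 bp).** Uniform-random background plus fixed islands:
  the primer sites placed so the amplicon carries 41 bp of 18S and 37 bp
  of 26S (total 689 bp for the insertion-free allele), the regex flanks
  and first BstEII site around position 1862, the second BstEII site in
  ITS2, and G-free/CC-free filler zones hosting every InDel anchor.
  Background windows matching any enzyme or primer motif are
  rejection-resampled, so the audit passes for every seed; since the
  filler zones cannot form a motif under any insertion or deletion, and
  alternative alleles for ITS SNPs are chosen against the species
  template context, no edit can create or destroy an unintended site.
  Sequence content beyond these constraints is immaterial to every
  result the package computes, which is why uniform background suffices.
* **Species profiles.** Six profiles whose per-region SNP/InDel counts
  and homogeneous/heterogeneous splits equal the study tables
  (e.g. *M. notabilis*: 11/34/32 SNPs in 18S/ITS/26S, 72 + 5 zygosity
  split, 16 bp insertion homogeneous). SNP positions are evenly spaced
  inside motif-free windows; alternative alleles are transitions unless a
  transition would create a recognition site locally. The small InDels
  around the 13/16 bp insertion realise the published fragment geometry:
  e.g. *M. nigra* = insertion + a 1 bp deletion upstream (MstI band
  99 bp), +2 bp between insertion and the ITS2 BstEII site (cut at 554)
  and −1 bp after it (amplicon 702).
* **Cohort (542 accessions).** Thirty-one haplotypes: nine repeated
  groups (457, 21, 13, 13, 6, 4, 2, 2, 2) plus 22 singletons; 514
  alba-clade accessions, 16 *M. notabilis* (13 sharing one haplotype,
  matching the single shared heterozygous SNP reported for them), 5
  *M. celtidifolia*, 3 *M. nigra*, 3 *M. rubra*, 1 *M. serrata*. The 22
  singletons fall out as 7 alba-clade + 3 + 5 + 3 + 3 + 1 wild
  accessions, which also makes the count of variant-bearing alba-clade
  accessions exactly 57. Within a species, haplotypes share all
  homogeneous loci and differ in nested subsets of the heterozygous
  ones; species attribution of the singletons is a documented default,
  not a claim about the original accessions.
* **Reads.** Error-free 150 bp reads drawn uniformly over start positions
  covering the full flank span, in both orientations, from the
  reference-local context around 1862 (the flanks are conserved across
  species, so one context serves all accessions); 539 accessions are
  simulated `mixed`, the three *M. notabilis* singletons pure-insertion.
  Sequencing error, base quality and realistic coverage profiles are
  *not* modelled, so passing tests show the counting logic is correct,
  not that it is robust to noisy reads.

Within a seed every output is byte-reproducible; across seeds the
background changes but every audited quantity is invariant.

## Problem sizes and numerical choices

The test suite and the acceptance script run the full 542-accession
cohort (about 2000 variant records, a 276-locus panel, 31 × 31 distance
matrix) and 27 100 simulated reads — small enough that the whole suite
completes in well under a minute per component on one CPU, while still
exercising every code path at study scale. Property checks use bounded
randomisation under fixed seeds: 1000 random 2 kb sequences against a
windowed-motif digestion oracle, random 5–8 leaf additive trees for NJ
recovery, random pattern-spliced reads against a substring-search
classification oracle.

Degenerate inputs are defined, not accidental: empty read sets are
`nocall`; an empty cohort tallies to an empty table; a 2-taxon matrix,
an asymmetric matrix, an unlabelled leaf, out-of-range coordinates and
length-mismatched haplotypes all raise typed errors.

## Known limitations

* The cohort simulator treats species profiles independently; the real
  cohort's 158 genome-wide SNPs share loci across species in ways the
  tables do not determine, so the synthetic panel (276 loci) is a
  superset-style stand-in with the same per-species counts.
* The published narrative is internally inconsistent in two places (a
  species' conclusions-section SNP counts vs its tables; one haplotype
  group described as homogeneous while the species' zygosity table has
  zero homogeneous SNPs). The packaged profiles follow the tables, which
  are the quantities the tallies are audited against.
* The ambiguity-aware distance saturates: accessions differing only in
  heterozygous sites are indistinguishable from the reference. That is
  faithful to the coding but means intra-clade structure among
  heterozygous-only haplotypes is not resolvable by design.
* Physical ordering of the 91/449/149 fragments along the amplicon is not
  determined by band lengths alone; the packaged geometry (cuts after
  amplicon positions 91 and 540, insertion after position 95) satisfies
  all published sums simultaneously, but other orderings would too.
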