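---
title: "Post-processing de novo transcriptome meta-assemblies with ContigForge"
author: "ContigForge authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Post-processing de novo transcriptome meta-assemblies with ContigForge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model of the problem

De novo transcriptome projects for non-model organisms (the motivating case
is a marine bivalve with around a hundred RNA-seq libraries spanning
developmental stages, tissues and stressors) typically assemble each sample
with a de Bruijn assembler at several k-mer sizes and then face a
*meta-assembly* problem: the union of all per-k-mer, per-sample contig sets
is massively redundant, contains assembly artifacts (antisense chimeras,
spurious indels), and must be reduced to one non-redundant reference contig
set before expression quantification, variant calling and differential
analysis make sense.

ContigForge implements that post-assembly pipeline as composable stages:

1. **Read cleansing** — per read, keep the longest sub-sequence free of
   undetermined calls (`N`); discard the read (and its mate) when that run
   does not exceed half the read length. Optionally downsample
   over-represented reads by digital normalization.
2. **Per-sample merging** — per-locus representative selection from
   assembler headers, antisense-chimera split/removal, greedy nucleotide
   dedup at 0.98 identity, overlap merging (≥ 60 bp at ≥ 0.96 identity),
   a 200 bp length floor, read remapping with spurious-indel correction,
   and a ≥ 2 reads-per-million (RPM) coverage filter.
3. **Cross-sample merging** — sample-prefixed renaming, longest-ORF
   clustering at 0.90 identity on the ORF products with the
   longest-ORF / longest-contig representative rule, a final nucleotide
   dedup at 0.95, a second remap + RPM filter.
4. **Quantification** — a contigs × libraries count matrix
   (`ContigCounts`, a `SummarizedExperiment`) whose per-library totals are
   the RPM denominators.
5. **Variants** — pileup-based SNP/indel calling, the
   depth ≥ 6 / depth ≤ 10000 / alt ≥ 2 / MAF ≥ 0.15 filter chain, and
   transcript-coordinate effect classification against per-contig gene
   models (5'UTR / CDS / 3'UTR from the longest ORF).
6. **Differential tools** — pooled-library digital differential display
   (DDD) with an exact two-sided Fisher test and Benjamini–Hochberg
   control, and presence/absence Venn region assignment.

# Key parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `keepAtHalf` | `FALSE` | Boundary of the cleansing rule. The rule is read literally: a longest N-free run that does *not exceed* half the read length is removed, i.e. removal at `2·L_sub ≤ L`, compared in exact integer arithmetic so odd lengths need no rounding convention. The flag flips the boundary for users who prefer keeping the exact half. |
| `normK`, `normMaxCoverage` | 25, 30 | Digital normalization: a read is dropped when the *median* count of its canonical k-mers over previously accepted reads already exceeds the ceiling. Counting is exact (no sketch) — appropriate at the scale this package targets — so results are deterministic given input order. |
| `locusKey` | `"len,depth"` | Per-locus representative: longest transcript first, assembler read depth as tie-break (`"depth,len"` swaps the keys). Remaining ties go to the lowest transcript index, then the smallest id. |
| `chimeraMinMatch`, `chimeraMinIdentity` | 60, 0.95 | An antisense chimera is called when two non-overlapping blocks of a contig are reverse complements of each other over at least `minMatch` bases. These thresholds deliberately echo the overlap-merge thresholds. The junction is placed at the midpoint between the blocks' inner boundaries; the contig is split when both fragments reach the 200 bp floor, removed otherwise. |
| `dedupIdentity`, `finalIdentity` | 0.98, 0.95 | Greedy incremental clustering identity thresholds for the per-sample and final nucleotide dedup passes. Identity is the cd-hit convention: identical aligned positions divided by the length of the *shorter* sequence, best of the two orientations at nucleotide level. |
| `overlapMinLen`, `overlapIdentity` | 60, 0.96 | Overlap merge: dovetail/containment overlaps found by exact-seed anchoring and ungapped diagonal comparison; components with consistent layouts are merged by majority consensus, ties taking the longest contributor's base. |
| `orfIdentity`, `orfLevel` | 0.90, `"aa"` | The ORF clustering pass. Whether the original workflow clustered protein or nucleotide ORF sequences is not determinable from its description; protein is the default (matching cd-hit rather than cd-hit-est semantics) and `orfLevel = "nt"` is the switch. |
| `orfMinLen` | 90 | Minimum ORF span (30 codons); ORFs are ATG-initiated by default, with a `between-stops` mode for sensitivity. 3'-incomplete ORFs count toward longest-ORF selection. |
| `rpmThreshold`, `rpmDenominator` | 2, `"cleaned"` | A contig is kept when `count / total × 10⁶ ≥ 2` — exactly 2 RPM is kept, only strictly fewer than two reads per million are excluded. The denominator is the cleaned-read total by default ("mapped" is the alternative); the cleaned total is the stable choice because it does not change when the contig set changes. |
| `varMinDepth`, `varMaxDepth`, `varMinAlt`, `varMinMaf` | 6, 10000, 2, 0.15 | The variant filter chain, all boundaries inclusive on the passing side; failures are labelled by the first failing rule in that order. MAF is the site's minor-allele fraction `min(alt, depth − alt)/depth`. |
| `altStartCodons` | none | Initiator-codon SNPs are `start_lost` unless the alternate codon is in this set (then `initiator_codon_variant`); the empty default reflects how rarely the category occurs in practice. `{TTG, CTG, GTG}` is the usual non-empty choice. |

# Design choices in detail

**Coordinates.** Everything internal is 0-based half-open; only the VCF and
SAM surfaces are 1-based, and a single conversion pair implements the
shift. Indels are VCF-anchored (REF/ALT share a leading anchor base) and
left-aligned by the standard trim/extend normalization.

**The built-in mapper replaces a gapped aligner on purpose.** Reads are
placed by exact-seed anchoring plus ungapped mismatch counting (budget 4%
of the read length), with fully deterministic tie-breaking (lowest contig
id, then position, then `+` strand) instead of random placement of
multi-mappers. Ambiguous best placements get mapping quality 3 and are
therefore excluded from pileups by the `minMapq = 30` rule while still
counting in the expression matrix. The consequence to be aware of: the
built-in mapper emits no gapped alignments, so the spurious-indel
correction stage acts on imported SAM alignments (or constructed pileups);
with built-in mapping only, reads spanning a true indel in a contig simply
fail their mismatch budget. Externally produced SAM is the escape hatch
for real data.

**Indel correction.** At columns of depth ≥ 4, a contig base is deleted
when more than half of the covering reads support its deletion, and a
single inserted string supported by more than half of the junction-spanning
reads is inserted. Conflicting majority edits at one column cancel and are
logged. Edits apply right-to-left so positions stay valid; substitutions
are deliberately never corrected (only insertion/deletion artifacts are
targeted).

**Variant calling is a transparent threshold caller.** The
genotype-likelihood machinery of general-purpose callers is not the point
of this pipeline; its biological filters are. A site is emitted whenever
any non-reference allele has a single supporting read, and the filter
chain carries all the semantics. This keeps every decision exactly
testable.

**Effect classification.** Variants are mapped into transcript orientation
(reverse-complementing position and alleles for `-`-strand gene models)
and classified by region. CDS SNPs are resolved at codon level; the CDS
SNP classes (synonymous, missense, stop gained/lost/retained, start lost,
initiator codon) partition all possible substitutions, which is enforced
by an exhaustive enumeration test. For indels: length not divisible by 3
is a frameshift; divisible by 3 is in-frame, "disruptive" when not aligned
to codon boundaries. Compound categories are added when the edit destroys
the initiator or terminal stop codon or writes a novel stop at the
junction — a codon-aligned in-frame deletion rewrites no codon, so the
original terminal stop moving closer is *not* a stop gain. A deletion
spanning the entire CDS maps to `chromosome_number_variation`, mirroring
how whole-feature losses are labelled in SnpEff-style vocabularies.
Splice-region categories are intentionally absent: contigs carry no intron
models, so no splice junction can be defined on them. A new upstream ATG
created by a 5'UTR SNP must lie wholly within the UTR to count as a
premature start gain.

**Fisher test.** The two-sided p-value follows the "sum of all tables with
probability not exceeding the observed" convention, computed in log space
from cumulative log-factorials, with a `1 + 10⁻⁷` relative tolerance on
the comparison to absorb floating-point ties. The DDD 2×2 table is raw
pooled counts against pooled totals — the construction a Fisher test on
count data implies; no normalization is applied before testing.
Benjamini–Hochberg control (via `p.adjust`) is applied across all tested
contigs by default because a transcriptome-wide request tests thousands of
contigs; `mtMethod` disables or changes it.

**Determinism.** Every ordering that touches ids uses byte-wise (C-locale)
comparison, so results do not depend on the session's collation settings;
no stage uses randomness; artifact files contain no timestamps. Running
the pipeline twice on the same inputs yields byte-identical artifact
directories, which the test suite asserts via checksums.

# The synthetic-data generator

`makeTranscriptome()` builds transcripts as 5'UTR + CDS + 3'UTR with an
ATG-initiated, internally stop-free CDS, rejection-sampled so the designed
ORF is the unique longest — every generated gene model is recoverable by
construction. `makeReads()` draws uniform-start reads with independent
substitution errors and `N` injections and records per-transcript designed
counts. `plantDuplicates()` emulates the partial re-assemblies produced by
other k-mer settings: variants are windows of 90% of the base length with
substitutions to a designed identity, so the full-length base is always
the longest family member and hence the expected cluster representative.
`plantChimeras()` concatenates a transcript with the reverse complement of
its leading portion (the full length by default), the artifact an
assembler produces when sense and antisense paths join; the true junction
is the transcript length. `plantVariants()` plus `applyVariantAlleles()`
give each covering read the alternate allele with probability equal to the
designed frequency.

One parent seed fans out to fixed per-stage child seeds, so stages can be
regenerated independently and the whole study is reproducible
byte-for-byte.

**What the generator does not emulate** — and therefore what passing tests
do not show about real data: quality-dependent and indel sequencing
errors, non-uniform coverage along transcripts, splice isoforms sharing
exons, fragmented or misassembled contigs beyond the two planted artifact
types, and library sizes anywhere near real studies. The smoke-scale
checks demonstrate the pipeline's *correctness contracts* (recovery of
planted truth, exact counting, determinism), not its behaviour under real
noise.

# Problem sizes used by the checks

The package's own verification runs at sizes chosen to exercise every
stage while remaining quick on a single CPU: 20 transcripts of 400–700 bp
with two 80 bp read libraries at 10× depth for the end-to-end study; 10
planted families × 5 variants of 500-mers for clustering recovery; 100
random 10 kb sequences against a brute-force six-frame scanner for ORF
finding; 500 random 2×2 tables (margins ≤ 60) against a full-enumeration
hypergeometric oracle for the Fisher test; exhaustive enumeration for the
cleansing boundary (all read lengths ≤ 50), the variant filter grid and
every possible SNP on a worked 13 nt contig.

# Known limitations

* The mapper is ungapped and single-threaded; at real-data scale an
  external aligner should produce SAM for import.
* Greedy clustering aligns candidate pairs exactly; the shared-word
  prefilter accelerates but the design targets desk-scale inputs, not
  millions of contigs.
* Paired-end information is used for cleansing (mate removal) but mates
  are mapped independently; no insert-size model.
* Effect classification annotates against the single longest ORF per
  contig; overlapping or secondary ORFs are not reported.
* The DDD test inherits Fisher-test conservatism at tiny counts; counts
  of 0 vs 0 return p = 1 by convention.
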