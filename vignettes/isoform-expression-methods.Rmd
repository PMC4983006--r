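---
title: "Methods: isoform-level expression summaries, major-isoform calling, and expression-aware variant annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isoform-level expression summaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isomajor)
```

## The problem

A gene with several splice isoforms has no single expression level: the
mixture of transcripts differs by tissue, by disease state, and between a
tumor and its matched normal tissue.  Two practical consequences drive this
package.  First, the *major isoform* — the transcript contributing the most
expression in a given sample group — is often not the *canonical* isoform
that databases (UniProt, the UCSC known-gene set) or the APPRIS principal
assignment designate as representative; and the major isoform can *switch*
between normal and tumor tissue.  Second, a DNA variant is interpreted at
the protein level relative to a transcript backbone, and the same genomic
position can be a missense codon on one backbone, a synonymous site on
another, and 3'UTR or intron on a third.  Choosing the backbone by
expression rather than by convention changes the interpretation of a
substantial fraction of coding variants.

`isomajor` implements this pipeline for RSEM-style isoform quantifications:
per-group expression summaries, major-isoform calling, tumor-specific
isoform inference, a major-vs-canonical consistency census, and VCF
annotation with expression-ranked isoform lists.

## Expression model and statistics

Input values are RSEM *fraction of transcripts* estimates: for each
isoform and sample, the estimated fraction of the sample's transcript pool
contributed by that isoform, a unitless number in $[0, 1]$.  The pipeline
never renormalizes these; the only scaling is

$$\mathrm{mTPM} = \mathrm{median}(\text{fractions in the group}) \times 10^6,$$

the *median TPM* of an isoform in one (cohort, tumor/normal) group.  When a
patient contributed replicate samples to the same group, the replicates are
averaged first, so each patient counts once (`collapse_replicates()`).

Per group, `group_summary()` reports the seven boxplot statistics: lower
outliers, whisker minimum, Q1, median, Q3, whisker maximum, upper outliers.
Numerical choices, made once:

* **Quantiles** use linear interpolation between order statistics
  (`stats::quantile` type 7, the most common default).  The source
  procedure does not state a convention; all designed fixtures use odd
  patient counts so that medians are order statistics and no acceptance
  value depends on the interpolation rule.
* **Outliers** are points strictly outside the Tukey fences
  $Q1 - 1.5\,\mathrm{IQR}$ and $Q3 + 1.5\,\mathrm{IQR}$.
* **Whiskers** are the extreme *non-outlier* points, so raw min/max are
  recoverable by unioning whiskers with the outlier lists.
* A caveat these definitions force: with interpolated quartiles on small
  samples, Q3 can exceed every non-outlier point (e.g. fractions
  0.5, 0.5, 0.5, 0.99 give Q3 = 0.6225 with 0.99 outside the fence), so the
  intuitive ordering "whisker max at or above Q3" is not a theorem and is
  not asserted; the tested invariants are $Q1 \le \mathrm{median} \le Q3$
  plus exact fence/outlier consistency.

The **major isoform** of a gene in a group is the isoform with the highest
median TPM (`call_major()`).  If every isoform's median TPM is zero, Q3
values are compared instead (`basis = "q3_tiebreak"`); residual exact ties
fall to the lexicographically smallest transcript id, which makes the call
total, deterministic, and permutation-invariant.  An isoform's
**expression percentage** is its share of the gene's summed median TPM in
that group; a fully silent gene reports all zeros rather than dividing by
zero.  This ratio-of-group-medians reading (rather than a median of
per-sample ratios) is used consistently everywhere a percentage appears.

## Tumor-specific isoform inference

`screen_gene()` classifies each isoform of a gene in one cohort, provided
the cohort has at least `min_normal_samples` (default 10) matched normal
patients:

* **Type I** — expressed in tumor, absent in normal:
  $\mathrm{mTPM}_{tumor} > 10^{-6}$ and
  $\mathrm{mTPM}_{normal} \le 10^{-6}$.  Subclass **strong** when
  $\mathrm{mTPM}_{tumor} \ge 1.0$ **and** the tumor expression percentage
  is $\ge 10\%$ (both inclusive); otherwise **weak**.
* **Type II** — major-isoform switch: the isoform is the tumor-group major,
  is not the normal-group major, and its fold change
  $\mathrm{mTPM}_{tumor}/\mathrm{mTPM}_{normal}$ is strictly greater
  than 2.  An infinite fold change (normal absent) passes the gate; 0/0 is
  an undefined sentinel and never passes.

The source material states the fold gate both as "> 2" (Methods) and "at
least 2-fold" (Discussion); the Methods wording is implemented and the
threshold is a parameter (`thresholds(type2_min_fold = ...)`).  An isoform
meeting both definitions is reported as Type I: with no normal expression
the fold change is degenerate, so the Type II evidence is weaker than the
Type I evidence it duplicates.  All thresholds live in one `thresholds()`
object, are strictly positive, and are overridable from the CLI and config
file.

## Consistency census

`consistency_check()` partitions all genes of one group into four buckets:
silent (no isoform with median TPM above zero); expressed but with no
canonical or principal isoform defined (`nokCanon`); expressed with the
major isoform matching *at least one* of the UniProt canonical, UCSC
canonical, or APPRIS principal transcripts (`matched`); and expressed with
a defined canonical that the major isoform misses.  The four counts sum to
the gene total by construction, and each expressed bucket carries a
parallel count restricted to genes whose major isoform has median TPM
$\ge 1$.  `percent_increase()` reports the normal-to-tumor growth of the
mismatched bucket at one decimal, rounding half away from zero (the display
convention of the published census, which `round()`'s half-to-even rule
would not reproduce).

## Variant annotation

Coordinates are 0-based half-open internally (the genePred convention);
the **only** 1-based conversion happens at VCF ingestion, in one place, to
prevent off-by-one drift.

`locate_element()` maps a genomic position onto one transcript:
`OTR` outside `[txStart, txEnd)`; `E<n>` inside an exon and the CDS (or any
exon of a non-coding transcript); `5U`/`3U` for exonic positions outside
the CDS, oriented by strand; `I<n>` between exons.  Exons and introns are
numbered from the transcription start site, so on the minus strand the
genomically last exon is exon 1, and an intron takes the ordinal of the
exon preceding it *in transcription order*.  UTR labels are rendered
without an exon number, but the containing exon's ordinal is retained
internally for backbone comparison.

`predict_consequence()` handles SNVs: the affected codon is cut from the
spliced CDS (exon ∩ CDS segments concatenated in genomic order, reverse
complemented on the minus strand), the alternate base is complemented on
minus-strand transcripts, both codons are translated with the standard
nuclear genetic code, and the change is classified as synonymous, missense,
nonsense, or stop-lost.  Indels and MNVs receive element locations but the
consequence kind `unsupported_allele`.  A CDS whose length is not a
multiple of three is used as-is for complete codons; positions in the
trailing partial codon report `noncoding_position`.  A REF allele that
disagrees with the genome stops the run, naming the position.

`annotate_vcf()` adds four header fields (tissue `IE_TS`, cohort `IE_CA`,
sample class `IE_SA`, patient count `IE_SN`) and five INFO keys per record
(`IE_GE`, `IE_UP`, `IE_UC`, `IE_AP`, `IE_IS`).  `IE_IS` lists every isoform
of the overlapped gene sorted by median TPM descending (ties by descending
Q3, then id), each entry
`id|biotype|element|medianTPM|UniProt:x&RefSeq:x&Ensembl:x&CCDS:x` with
missing ids as `.` and median TPM at six significant digits.  Multi-gene
overlaps join blocks with `&`; intergenic variants get `.` and no isoform
list.  The writer re-emits untouched fields verbatim, so reruns and
read/write round trips are byte-identical.

`compare_backbones()` and `summarize_discordance()` implement the
major-vs-canonical comparison: of the variants whose major isoform is not
the canonical one, how many canonical-coding positions stay coding on the
major backbone versus relocating to intron/5'UTR/3'UTR/outside; of the
still-coding ones, how many keep their exon ordinal; and how many change
their amino-acid interpretation (a synonymous/non-synonymous flip counts as
a change; two synonymous calls on different codons do not, since the
protein is unaffected either way).  An `OTR` relocation bucket exists even
though the motivating analysis observed none.  One reported ratio deserves
a note: the source text prints "743 (0.6 % of 12,226)" where the counts
give 6.1 %; the summarizer reports the computed value, and that figure is
excluded from acceptance checks.

## The synthetic world

The fixture generator states a small, fully designed world rather than a
realistic one:

* two chromosomes (9 kb / 6 kb) of uniform random sequence;
* six genes, fourteen transcripts, hand-placed to cover every behavior:
  a five-isoform switch gene (tumor-only isoform at a designed 0.40 TPM;
  tumor major at 29.3-fold over its normal level, 66.4 % of tumor
  expression, with a different normal major at 77.6 %), a two-isoform gene
  whose shared position falls in exon 4 versus exon 5 with a shifted
  reading frame, a gene where a canonically coding position is 3'UTR on
  the higher-expressed isoform, a minus-strand gene, a non-coding isoform,
  a silent gene, and an expressed gene with no canonical assignment;
* an eligible cohort with 11 tumor / 11 normal patients (odd counts make
  the designed medians exact sample medians; 11 clears the 10-normal
  eligibility floor) and a second cohort with 5/5 to exercise the
  ineligibility error;
* expression values jittered uniformly within ±20 % of the designed median
  for the non-median ranks — order statistics stay controlled and the
  median is exact by construction; one patient contributes two replicate
  samples whose mean equals the patient value;
* a VCF whose REF alleles are read from the generated genome, with one
  variant per element category (coding exon, intron, 5'UTR, 3'UTR,
  outside-transcript, intergenic, minus-strand coding).

Everything is deterministic under the design seed.  What this world does
**not** emulate: RSEM's estimation noise and uncertainty, correlated
expression across isoforms, realistic gene/exon length distributions,
overlapping genes, multi-allelic or indel-heavy VCFs, and cohort sizes in
the hundreds.  A green test therefore establishes the *logic* of each
operation (classification boundaries, coordinate arithmetic, partition
identities, determinism), not statistical performance on real tumor data —
the published biological counts derive from a 10,000-sample consortium
dataset and are reproduced only where they are pure arithmetic on printed
numbers.

## Degenerate inputs and tie-breaks

* Empty value vectors are domain errors everywhere; an all-zero gene is
  not an error but a defined bucket (silent; all percentages 0).
* `fold_change(x, 0)` is `Inf` for `x > 0` and `NaN` for `x = 0`.
* Major-call ties: median, then Q3, then lexicographic id — total order,
  no randomness.
* Gene symbols occurring on several chromosomes are split into distinct
  registry entries with a `_<chrom>` suffix; locus queries match by any
  overlap with the gene span, not containment.
* A transcript's protein-coding status defers to the peptide-availability
  flag when a cross-reference row exists; CDS emptiness is only the
  fallback.

## Known limitations

GTF/GFF input, splice-site effects, protein-domain mapping, statistical
tests for differential isoform usage, and haplotype/alt-contig handling are
out of scope.  Consequence prediction covers SNVs only.  The VCF layer
targets well-formed, uncompressed single-sample files; it preserves rather
than validates FORMAT/sample columns.
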