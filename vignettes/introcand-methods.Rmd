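---
title: "Detecting wild introgressions and prioritizing candidate genes with introcand"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting wild introgressions and prioritizing candidate genes with introcand}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(introcand)
```

## The analysis model

`introcand` implements a candidate-gene prioritization workflow for an
introgression-bred crop line resequenced against its cultivated
reference genome. The statistical core is simple and deliberately
transparent:

* **Variant filtering.** Calls are kept when site quality and mean
  depth both reach their thresholds (defaults `minQ = 15`,
  `min mean DP = 15`, inclusive) and, for the single-sample focal call
  set, when the genotype is homozygous-alternate. Thresholds are
  inclusive because that is the conventional semantics of the standard
  filtering tools' `--minQ`/`--min-meanDP` options; nothing downstream
  is sensitive to the boundary case. Multi-allelic records are split
  into one record per ALT allele *before* filtering, so the genotype
  rule acts per allele.
* **Window densities and polymorphic regions.** SNPs and InDels are
  counted in 1-Mb non-overlapping windows (window *i* covers
  `[(i-1)e6 + 1, i*1e6]`, 1-based inclusive). A window qualifies when
  its SNP count *or* InDel count strictly exceeds its threshold; runs
  of qualifying windows separated by at most one non-qualifying window
  are merged. Published descriptions of this kind of analysis give
  absolute per-window counts whose provenance (per window, per region,
  or quantile) is not stated; we therefore default to a *relative*
  threshold -- `fold = 3` times the genome-wide mean per-window count,
  separately for SNPs and InDels -- and accept absolute counts via
  `region_config(mode = "absolute")`. A per-window reading is the only
  one consistent with multi-megabase regions assembled from 1-Mb
  windows. The one-window gap tolerance reconciles contiguous printed
  regions with Poisson noise at the window scale.
* **Genotype-concordance distance and neighbor joining.** The distance
  between two samples is the fraction of co-observed sites (non-missing
  in both) at which their alternate-allele dosages differ. This is the
  simplest statistic consistent with NJ input when the upstream tool's
  distance is unspecified, and it is documented prominently as a
  package definition rather than a reproduction of any tool's
  internals. Trees are built per chromosome (sites subset by
  chromosome) with the canonical Saitou-Nei agglomeration: Q-criterion
  pair choice, standard branch-length and distance-update formulas.
  On additive matrices the reconstruction is exact; on noisy matrices
  negative branch lengths can arise and are clamped to zero with the
  deficit moved to the sibling branch so that emitted Newick always has
  nonnegative lengths. Origin assignment ranks species by minimum tree
  path length from the focal leaf to a species member, breaking ties by
  the size of the smallest split containing both, then alphabetically.
  The assignment is defined on the unrooted tree: rooting for display
  is a presentation choice we avoid depending on.
* **Effect annotation.** A compact re-implementation of the standard
  annotation semantics: strand-aware codon translation for CDS SNPs
  (synonymous / missense / stop gained / stop lost, standard nuclear
  code only), frame arithmetic for CDS indels (frameshift when the
  length change is not a multiple of 3; in-frame indels are
  *conservative* when the edit aligns on codon boundaries and
  *disruptive* otherwise), fixed splice-site rules (first/last two
  intron bases are donor/acceptor, HIGH; within 3 bp of a junction is
  splice region), strand-aware UTR sidedness, and 5-kb up/downstream
  flanks (the annotation tools' convention). Each effect term maps to
  exactly one impact tier via a fixed total map. When a variant
  overlaps several genes, one annotation per gene is emitted; summaries
  count each variant once at its most severe impact. A deletion whose
  span covers CDS of two opposite-strand genes is reported as a
  bidirectional gene fusion -- minimal semantics for that term, flagged
  as approximate. Start-codon edge cases are annotated as missense, a
  documented simplification.
* **Candidate lists and prioritization.** Keyword screens are
  case-insensitive substring matches on the functional description
  only. A gene is prioritized when it is on a list, carries at least
  one HIGH or MODERATE variant, and lies in a detected polymorphic
  region or overlaps a QTL whose trait class is flower-related. The
  default flower classes are {flower number, flowers per inflorescence,
  inflorescence number, flowering time}: curated candidate tables in
  this domain include flowering-time QTL colocalizations, so the
  narrow "flower number only" reading (available as
  `flower_trait_classes(strict = TRUE)`) would drop rows that the
  broader reading reproduces.
* **Promoters and donor sharing.** Promoters are the 3000 bp upstream
  of the transcript start (strand-aware; `from = "cds"` switches the
  anchor to the translation start). Motif scanning expands IUPAC codes
  in the consensus only -- an `N` in the sequence never matches a
  non-N consensus symbol -- and reports overlapping hits on both
  strands. "Mutated motif" is a package definition: a hit whose
  footprint covers at least one aligned column at which the two
  promoters differ, or a hit present in exactly one promoter, under an
  end-gap-free global alignment (match 1, mismatch -1, gap -2).
  Donor sharing is exact `(chrom, pos, ref, alt)` key equality --
  both call sets are against the same reference build, which makes key
  comparison exact and order-free -- and per-gene percent identity is
  computed from a global affine-gap alignment (match 1, mismatch -1,
  gap open -2, extend -1) as identical columns over all alignment
  columns.

## The synthetic data generator

No individual resequencing dataset is bundled with the package, so the
generator is the package's reference workload and ground-truth source.
Its defaults define the study conditions and are chosen once:

| parameter | default | rationale |
|---|---|---|
| genome | 6 chromosomes x 10 Mb | desk-scale analogue of a 12 x ~65 Mb plant genome |
| background density | 50 variants/Mb | typical within-species resequencing background |
| introgression density | 1000 variants/Mb (20x) | wild-relative segments are an order of magnitude denser; 20x makes the contrast unambiguous at 1-Mb windows |
| InDel fraction | 0.12 | matches the SNP:InDel ratio of large filtered call sets (~1.76M : 0.24M) |
| introgressions | chr2:2-9 Mb, chr5:1-8 Mb | two segments covering ~70% of their chromosomes, so those chromosomes cluster with the donor in per-chromosome trees, while the genome-wide introgressed fraction (~23%) keeps the 3x-mean window threshold well below the introgressed density |
| panel | 4 species x 3 accessions + focal | enough structure for species-level clustering without coalescent machinery |
| species divergence | 0.2/site/branch | separates species by ~0.3 in concordance distance, an order of magnitude above the 0.02 accession-level noise |

Variant placement is a Poisson process (counts Poisson at the segment
rate, positions uniform), matching the independence the window-count
analysis assumes; there is no interaction, recombination map or
mutation-spectrum realism, and no read-level simulation. The panel
genealogy is a fixed star-like species structure with accession noise,
not a coalescent: the analysis consumes only species-level clustering.
Donor alleles in introgressed focal segments are copied exactly from
the designated wild donor, which gives the shared/private
classification and the percent-identity comparison exact ground truth.

Two structural choices keep the truth set exact. First, background
density variants avoid gene transcript spans; all coding-region
variants are planted explicitly by `plant_effect_variants()`, which
constructs, for each requested effect term, a variant whose
re-annotation yields exactly that term (the construction path -- codon
table search, boundary-placed indels -- is independent of the
annotation path, so round-trip agreement is informative). The masked
fraction is ~1% of the genome and immaterial to 1-Mb window counts.
Second, promoter cis elements are planted at recorded offsets on the
promoter's own strand, never including the HSE consensus, so both the
scanner's recovery and the absence of HSE hits are checkable.

What passing tests on this generator do *not* show: robustness to
coalescent variance, segmental duplications, reference bias, indel
normalization differences between callers, or annotation-isoform
ambiguity. Real data bring all of these; the generator validates the
logic, not the upstream calling.

All randomness flows from the single integer seed in `sim_config()`;
identical configurations produce byte-identical output files (the
writers emit no timestamps), which the test suite checks by hashing.

## Numerical and degenerate-input choices

* Filtering treats missing QUAL/DP as failing any positive threshold.
* `detect_polymorphic_regions` rejects unsorted or non-tiling window
  tables rather than silently reordering.
* NJ tie-breaks (equal Q values) take the first pair in row order;
  permutation invariance is property-tested on generic matrices where
  ties do not arise.
* A pair of samples with zero co-observed sites is an error naming the
  pair, not a silent `NaN`.
* `percent_identity` is reported to two decimals; equality with 100 is
  used as the `fully_donor` flag, so only perfect identity qualifies.
* Promoters truncate with a warning at chromosome edges; empty
  sequences are errors in the comparison functions.
* Equal background and introgression rates are a legal degenerate
  configuration (the truth set is still emitted); region recovery is
  then not expected, and the false-positive rate at the 3x-mean
  threshold is checked to be below 0.1 regions per genome.

## Problem sizes used by the validation suite

The suite exercises the full default generator once (about 17,000
variants, 180 genes, 13-sample panel) and reuses it across test files;
region-recovery and origin-assignment checks run 20 seeded replicates
of the variant placement and panel stages only, and the
false-positive control runs 100 replicates at background density.
These sizes were chosen so that every distributional claim is tested
with enough replication to be stable under reseeding while the whole
suite stays interactive.

## Limitations

* The effect annotator covers the vocabulary listed in
  `effect_impact_map()`; it is not a full SnpEff replacement (no HGVS,
  no NMD prediction, no isoform ranking, no regulatory-region terms).
* Region detection is thresholding plus gap-merging, not an HMM or
  changepoint model; boundaries are window-quantized by construction.
* The bidirectional-gene-fusion call uses minimal span semantics.
* Promoter "mutated motif" counts depend on this package's footprint
  definition and are not claimed to equal counts from web services
  whose collapsing rules are unpublished.
* `summarize_impacts` percentages are computed per variant at its most
  severe impact; tools that count per annotation will differ.
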