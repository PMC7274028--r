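---
title: "Methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

snpscope explores large SNP/INDEL panels one region at a time. This
vignette records the statistical and algorithmic choices behind each
component, the parameters that matter, and what the test suite does and
does not establish.

## The intermediate genotype matrix

Every analysis consumes one object: the genotype matrix for a resolved
region × sample selection. Cells are classified four ways — REF_HOM,
HET, ALT_HOM, MISSING — as a pure function of the allele indices: both
zero, equal non-zero, unequal present, or any missing allele. Half-calls
(`./1`) are treated as MISSING: it is the simplest rule consistent with
the four-class encoding, and avoids inventing an allele count for a call
the genotyper itself left ambiguous. Haploid genotypes are promoted to
homozygous diploid with a warning; everything downstream assumes diploidy.
Multi-allelic records are kept as single records with allele indices —
splitting them would silently change per-sample semantics (a `1/2` call
has no faithful representation across two biallelic rows).

Phasing (`|` vs `/`) is recorded and re-emitted in raw table exports but
never interpreted: all analyses here are genotype-level.

## Retrieval

The storage contract is VCF text plus a positional (tabix) index; a
bgzipped, indexed copy is used when present. Indexed queries go through a
direct tabix fetch with a minimal record parser; unindexed files are read
whole (via `VariantAnnotation::readVcf`) and filtered. These are two
genuinely distinct code paths and the test suite holds them to identical
output on hundreds of random regions — the one route audits the other.
Records with symbolic ALT alleles are outside scope and skipped with a
warning; `*` (overlapping-deletion) alleles count as ALT for frequency
purposes but are never substituted into consensus sequences.

## Filters

Allele frequencies use diploid allele counting over non-missing alleles
only: counting missing calls as reference would bias frequencies downward
exactly where the data are weakest. MAF is defined as one minus the
frequency of the most common allele — the standard population-genetics
convention, which reduces to `min(p, 1-p)` for biallelic sites — because
a multi-allelic "minor allele frequency" is otherwise ambiguous. A site
left with zero non-missing alleles is assigned MAF 0 (and an NA
frequency), so `maf_min = 0, missing_max = 1` is exactly the identity
filter and monomorphic sites are kept at `maf_min = 0`.

The three sample-category filters read "samples must …" as a conjunction
over the focal set (every focal sample must vary / must match the
reference), with MISSING failing both constrained categories; an
`any`-sample mode is exposed but not the default.

## Haplotypes and the network

With unphased data, a "haplotype" is an equivalence class of samples
with identical genotype signatures across the kept sites; HET is its own
state. This is the only phase-free definition, and it is what the
genotype heatmap visualizes. The default missing-data policy excludes any
sample with a missing call at a kept site (reported in the output):
wildcard-matching a missing cell can merge signatures that are actually
distinct, and silent merging is worse than an explicit exclusion. The
alternative `missing_as_state` policy is available when panels are too
sparse for exclusion.

The network is the minimum spanning tree of pairwise Hamming distances
between haplotype signatures, built with Kruskal's algorithm and edges
sorted by (weight, lexicographic node-id pair), so ties never make the
output depend on input order. Median-joining networks (which insert
inferred intermediate haplotypes) are deliberately not implemented: the
MST is the deterministic, assumption-free core, and an inferred-node
method would need its own epsilon calibration. When equal-weight
spanning trees exist only the single deterministic MST is emitted.

Heatmap ordering clusters samples within each group by average-linkage
hierarchical clustering on normalized Hamming distance with pairwise
deletion (a pair with no comparable site gets distance 1); groups keep
their given order, and leaf-order ties follow input order.

## Distances, trees, ordination

The sample distance is identity-by-state: per comparable site
`1 − (shared alleles)/2`, i.e. 0 / 0.5 / 1 for identical / half-shared /
opposite genotypes, averaged with pairwise deletion. IBS is the standard
genotype-level metric for unphased diploid panels; a stricter
any-difference p-distance is a flag. A pair with zero comparable sites is
set to the maximal distance 1 with a warning rather than failing the
whole query.

Neighbour joining is implemented in the package (classical Q-criterion
agglomeration) rather than delegated, for two reasons: the tie rule —
merge the pair whose smallest contained leaf labels sort first — makes
results bit-reproducible and input-order invariant, and the
implementation is held to an external oracle (path-length matrices of
random additive trees, recovered to 1e-9) rather than to another
library's output. Negative branch-length estimates are clamped to zero
with the raw values kept as an attribute. Trees are returned as `ape`
"phylo" objects so the standard toolbox (plot layouts, cophenetic
distances) applies; the various layouts are rendering options over the
same tree. The Newick writer is in-package because labels may contain
spaces (display names) and must be quoted; round-trips are checked
through `ape::read.tree`.

Principal coordinates wrap `stats::cmdscale` (Torgerson double centering,
coordinates scaled by the square root of each eigenvalue) with two
conventions on top: genotype-derived distances are generally not
Euclidean, so small negative eigenvalues warn and truncate at zero
(their axes are all-zero) instead of failing; and each axis is sign-fixed
so its largest-magnitude coordinate is positive, making coordinates
reproducible across platforms whose eigensolvers differ by sign.

## Effect annotation

The annotator is a deliberately minimal, codon-level classifier — enough
to colour frequency plots and recover planted classes, not a re-creation
of a full effect predictor. For a CDS SNP the affected codon is rebuilt
from the reference (strand-aware, honouring CDS phase and exon-spanning
codons) and translated with the standard genetic code: same amino acid →
synonymous, new stop → stop gained, lost stop → stop lost, otherwise
missense. CDS indels are frameshift unless the length change is a
multiple of three (then reported in the missense class with an "inframe"
tag). The splice-region window is the 2 intronic bases adjacent to each
exon boundary — narrower than the common 3-exonic/8-intronic convention;
this is a documented simplification, not an attempt at parity. Ambiguous
(N) codon context yields class "unknown", excluded from severity
colouring. When the VCF already carries `INFO/ANN` strings those take
precedence (configurable), mapped onto the same classes.

Severity for summarising multi-transcript or multi-allele sites is the
fixed total order frameshift > stop gained > stop lost > missense >
splice region > synonymous > non-coding exon > intron > intergenic >
unknown. Per-group frequencies use the same allele-counting convention
as MAF, and a group with no non-missing call at a site is reported as
*absent* (NA) — a real distinction from an observed frequency of zero,
since "we saw no variant" and "we saw nothing" mean different things at
low coverage.

## Consensus sequences

Variants are applied in descending reference position, which makes indel
coordinate handling trivially correct (no offset tracking, no drift).
Heterozygous SNPs become IUPAC ambiguity codes by default — faithful to
"consensus" semantics — with `alt` and `ref` modes for primer-design
workflows; heterozygous indels keep the reference and are logged, since
no single sequence can represent them. Missing calls silently keep the
reference, and this is exactly why every result carries an
applied/skipped ledger: a consensus built from low-coverage data may not
reflect the real sequence, and the ledger makes that auditable. Variants
whose REF span crosses the region boundary are skipped; when applied
spans would overlap, the rightmost (applied first) wins and the conflict
is logged. The `#RAW` token returns the untouched reference slice.

## Geography

One site's genotype classes are joined to per-sample collection
coordinates and merged into circles: repeatedly seed at the unassigned
point with the most unassigned neighbours within the merge radius (ties
by accession name), absorb everything within the radius of the seed, and
centre the circle on the seed. Greedy seeding was chosen over clustering
because the operation is presentational — stable, interpretable circles
matter more than optimality — and the tie rules make it deterministic
and label-permutation invariant. Distances are haversine with Earth
radius 6371 km. Rendering is a plain scatter without map tiles; tile
services would break offline reproducibility.

## The synthetic world

`fixture_spec()` defaults describe a small but fully featured panel: two
contigs (20 kb + 6 kb), 24 samples in two groups, 200 variant sites (10%
indels), 3 planted haplotype classes at 30% per-site divergence, 2%
per-call genotype noise, 5% heterozygous and 5% missing calls, and three
geographic clusters with 100 km spread. These are one-time choices of
what a small diversity panel plausibly looks like — large enough to
exercise every filter and analysis, small enough that the whole suite
runs in seconds — and tests that need special conditions (noise-free
planting, iid allele draws at a stated frequency, 1,000-site filter
oracles) say so explicitly in their own specs.

The generator plants hard haplotype-class assignments with independent
per-call noise/het/missing flips, unlinked sites, and Gaussian
geographic scatter. It deliberately does **not** emulate linkage
disequilibrium, coalescent genealogies, indel-length spectra, or
realistic error covariance. A green test therefore establishes
correctness of the computations on well-defined inputs — collapse really
recovers planted classes, filters really match a recount — not that any
biological inference is well calibrated on real panels. Truth tables are
written beside the fixtures so tests never re-derive ground truth from
the generator's internals.

## Numerical and interface conventions

* Coordinates are 1-based inclusive at every interface; the last colon
  splits contig from coordinates, so contig names may contain dots and
  underscores (but not colons). Thousands separators are rejected.
* Flanking lengths apply only to gene-derived regions, never to explicit
  coordinates.
* Sample tokens in query expressions match accession names only; vcfIDs
  are storage identity, display names are output labels. Duplicate
  display labels are disambiguated with " (2)", " (3)", … suffixes.
  `#ALL` and `#RAW` are reserved.
* NJ recovery is asserted to 1e-9 on additive inputs; PCoA
  reconstruction to 1e-6 on planar configurations; these are numerical
  slack for double-precision eigen/agglomeration arithmetic, not model
  tolerances.
* All outputs are byte-deterministic given identical inputs; the only
  non-reproducible content is the ISO-8601 time stamp on figures and
  FASTA headers, and `--no-stamp` removes it.

## Known limitations

* Diploid only; polyploid genotypes are out of scope (wheat-scale panels
  are typically distributed as diploidized calls per subgenome).
* No BCF writer and no VCF 4.3 symbolic/breakend records.
* The annotator ignores UTR subclasses, regulatory features, and
  non-standard codon tables.
* Consensus output is a single sequence; phased dual-haplotype output is
  not attempted.
* The haplotype network has no reticulation or inferred median vectors.
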