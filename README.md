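# snpscope

Region-scoped querying and analysis of SNP/INDEL variation panels in R.

Resequencing studies now routinely genotype hundreds of accessions, and the
resulting VCFs are far too large to explore interactively as a whole. Most
day-to-day questions, however, are local: *which haplotypes of this gene
exist in my panel, and who carries them? how do allele frequencies at this
locus differ between landraces and cultivars? what does this SNP do to the
protein? what is the actual sequence of accession X across this region?*
snpscope answers exactly these questions. It retrieves a small slice of a
large call set (VCF + reference FASTA + GFF3 annotation + sample metadata),
holds it as an in-memory genotype matrix, and runs lightweight analyses on
that slice — it is deliberately **not** a genome-wide analysis toolkit (no
GWAS, no genome scans).

It is aimed at researchers and breeders working with diversity panels in
any species with an assembled genome, and at developers who need a scripted,
reproducible equivalent of interactive variant-browser workflows.

## What it computes

Every analysis runs off one intermediate object, the genotype matrix
`G` (sites × samples) with cells in the four-way encoding
`0/0` (REF_HOM), `0/1` (HET), `1/1` (ALT_HOM), `./.` (MISSING):

* **Site filters** — minor allele frequency
  `MAF = 1 − max_a f_a` over non-missing alleles (diploid counting, so each
  call contributes two alleles; `min(p, 1−p)` when biallelic) and maximum
  missing-call fraction; plus the three sample-category filters (all focal
  samples must vary / must match the reference / no constraint).
* **Haplotype network** — samples with identical genotype signatures across
  the kept sites collapse into haplotypes; nodes are sized by carrier count
  and carry per-group pie fractions; edges form the minimum spanning tree of
  pairwise Hamming distances (deterministic Kruskal with lexicographic tie
  breaks).
* **Distance tree / ordination** — identity-by-state distance
  `d(i,j) = mean_site (1 − shared alleles / 2)` with pairwise deletion,
  then classical neighbour joining (Saitou–Nei Q-criterion; exact on
  additive matrices) or principal-coordinates analysis (Torgerson double
  centering, eigenvalue-scaled axes).
* **Effect classes** — codon-level SNP classification against GFF3
  transcript models with the standard genetic code (synonymous / missense /
  stop gained / stop lost), frameshift vs in-frame indels, splice-region
  (2 bp intronic window), intron, non-coding exon, intergenic — plus
  per-group allele frequencies for lollipop-style displays, where an
  all-missing group is reported as *absent* rather than frequency zero.
* **Geographic pies** — one site's genotype classes projected onto sample
  collection coordinates, with nearby accessions greedily merged into
  circles by a great-circle (haversine) radius.
* **Consensus sequences** — a sample's variants substituted into the
  reference slice (descending-position application; heterozygous SNPs as
  IUPAC codes by default; missing calls keep the reference, logged), with a
  reference↔consensus coordinate map and a full applied/skipped ledger.

A synthetic-fixture generator (`generate_fixture()`) emits a coherent
VCF/FASTA/GFF3/metadata set with planted haplotype classes, effect variants
of every class, and geographic clusters — plus machine-readable truth
tables — so the whole toolchain is testable offline.

## Worked example

```r
library(snpscope)

fx       <- generate_fixture(fixture_spec(seed = 1), "demo_panel")
catalog  <- read_sample_catalog(fx$paths$samples, fx$paths$groups)
gene_idx <- parse_gff3(fx$paths$gff)$gene_index

region <- parse_region_spec("gene1", gene_idx, flank = 500)
region
#> <region_query> 1A:1500-3099 (gene: gene1 +/-500)

sel <- parse_sample_expression("#ALL", catalog)
rec <- read_variants(fx$paths$vcf_gz, region, catalog_vcf_ids(catalog, sel$members))
m   <- build_matrix(rec, sel, catalog)
mf  <- filter_sites(m, maf_min = 0.05, missing_max = 0.2)
mf
#> <genotype_matrix> 14 site(s) x 24 sample(s)
head(site_stats(mf), 3)
#>     altFreq       maf missingRate
#> 1 0.3695652 0.3695652  0.04166667
#> 2 0.3478261 0.3478261  0.04166667
#> 3 0.6818182 0.3181818  0.08333333

net <- build_network(collapse_haplotypes(filter_sites(m, 0, 0),
         selection_groups(sel, catalog, c("grpA", "grpB"))))
net
#> <haplotype_network> 5 node(s), 4 edge(s), 0 excluded
net$edges
#>    a  b w
#> 1 H1 H4 1
#> 2 H2 H3 1
#> 3 H2 H5 1
#> 4 H1 H3 6

tree <- neighbor_joining(ibs_distance_matrix(mf,
          labels = unname(resolve_display(mf$samples, catalog))))
write_newick(tree)
#> ('Line 20':0,'Line 23':0,('Line 17':0.06006753663,('Line 14':0.0168254055,((('Li ...

cons <- make_consensus(region, make_reference_fetch(fx$paths$fasta),
                       build_matrix(rec, "S01", catalog))
cons
#> <consensus_result> S01 1A:1500-3099: 1601 bp, 9 applied, 0 skipped
head(cons$applied, 3)
#>    pos ref alt zygosity     action
#> 1 1582   T   K      het      iupac
#> 2 1618   A   T      hom substitute
#> 3 1942   A   C      hom substitute
```

Reading the output: the gene query resolved to a 1.6 kb window; 14 of 18
sites survive the MAF ≥ 0.05 / missing ≤ 0.2 filter; the noise-free subset
of samples collapses into 5 haplotypes whose spanning tree separates one
divergent haplotype (6 differences) from a tight cluster; and the consensus
for accession S01 applied 9 of its variants, one as the IUPAC code `K`
(G/T heterozygote).

## Command line

The same operations are exposed as subcommands
(`validate`, `fixtures`, `vartable`, `heatmap`, `hapnet`, `phylotree`,
`snpfreq`, `hapmap`, `seqmaker`) through `run_cli()` or the installed
`inst/cli/snpscope` script:

```sh
snpscope vartable --vcf calls.vcf.gz --fasta ref.fa --samples-tsv samples.tsv \
         --region 1A:1500-3099 --samples "#ALL" --maf 0.05 --out vartable.csv
snpscope seqmaker --vcf calls.vcf.gz --fasta ref.fa --samples-tsv samples.tsv \
         --region 1A:1-800 --samples "#RAW,S01" --het iupac --out consensus.fa
```

Tables are CSV, networks/frequencies/maps are JSON, trees are Newick,
sequences are FASTA. Figures (`--png`, `--pdf`) and FASTA headers carry an
ISO-8601 time stamp and the main parameters; `--no-stamp` suppresses it so
outputs are byte-reproducible. Exit codes: 0 success, 1 runtime/validation
error, 2 usage error.

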