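# Shared test fixtures, all built in code at test time.

# 60 bp contig used by the hand-crafted instance
TINY_SEQ <- "ACGTACGTAGGCTAGCTAACCGATCGATCGTTGACCTGAAGCTTACGGATACGTACGTAA"

# Hand-crafted minimal instance: 3 samples, 3 sites (one multi-allelic,
# one deletion), one plus- and one minus-strand gene. Memoised per session.
tiny_instance <- local({
  cache <- NULL
  function() {
    if (!is.null(cache) && dir.exists(cache$dir)) return(cache)
    dir <- file.path(tempdir(), "snpscope-tiny")
    dir.create(dir, showWarnings = FALSE)
    fasta <- file.path(dir, "ref.fa")
    writeLines(c(">1A tiny contig", TINY_SEQ), fasta)
    gff <- file.path(dir, "genes.gff3")
    writeLines(c(
      "##gff-version 3",
      "1A\ttest\tgene\t10\t40\t.\t+\t.\tID=g1",
      "1A\ttest\tmRNA\t10\t40\t.\t+\t.\tID=m1;Parent=g1",
      "1A\ttest\texon\t10\t20\t.\t+\t.\tParent=m1",
      "1A\ttest\texon\t30\t40\t.\t+\t.\tParent=m1",
      "1A\ttest\tCDS\t12\t20\t.\t+\t0\tID=c1;Parent=m1",
      "1A\ttest\tCDS\t30\t38\t.\t+\t0\tID=c1;Parent=m1",
      "1A\ttest\tgene\t45\t58\t.\t-\t.\tID=g2",
      "1A\ttest\tmRNA\t45\t58\t.\t-\t.\tID=m2;Parent=g2",
      "1A\ttest\texon\t45\t58\t.\t-\t.\tParent=m2",
      "1A\ttest\tCDS\t46\t57\t.\t-\t0\tID=c2;Parent=m2"), gff)
    vcf <- file.path(dir, "calls.vcf")
    writeLines(c(
      "##fileformat=VCFv4.2",
      "##contig=<ID=1A,length=60>",
      "##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional annotations\">",
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
      "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Quality\">",
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
              "FORMAT", "v1", "v2", "v3"), collapse = "\t"),
      paste(c("1A", "3", ".", "G", "T", "50", "PASS",
              "ANN=T|missense_variant|MODERATE|g1|g1|transcript|m1|protein_coding|1|n.3G>T",
              "GT:DP:GQ", "0/1:17:60", "1|1:20:80", "./.:.:."), collapse = "\t"),
      paste(c("1A", "15", ".", "G", "C,GA", "50", "PASS", ".",
              "GT:DP:GQ", "0/2:11:55", "0/0:9:43", "1/2:14:70"), collapse = "\t"),
      paste(c("1A", "25", ".", "CGA", "C", "50", "PASS", ".",
              "GT:DP:GQ", "1/1:22:90", "0/1:13:50", "0/0:8:35"), collapse = "\t")),
      vcf)
    samples <- file.path(dir, "samples.tsv")
    writeLines(c(
      "vcfID\taccessionName\tdisplayName\tcountry\tlatitude\tlongitude",
      "v1\tS01\tChinese Spring\tCN\t0\t0",
      "v2\tS02\t\tFR\t0\t0.5",
      "v3\tS03\tChinese Spring\tMX\t0\t2"), samples)
    groups <- file.path(dir, "groups.tsv")
    writeLines("landrace\tS01,S02", groups)
    cache <<- list(dir = dir, fasta = fasta, gff = gff, vcf = vcf,
                   samples = samples, groups = groups)
    cache
  }
})

tiny_catalog <- function() {
  t <- tiny_instance()
  read_sample_catalog(t$samples, t$groups)
}

# Default seed-1 generated fixture, memoised per session.
shared_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache) && file.exists(cache$paths$vcf)) return(cache)
    cache <<- generate_fixture(fixture_spec(seed = 1),
                               file.path(tempdir(), "snpscope-fx1"))
    cache
  }
})

# Build a genotype_matrix directly from genotype strings (sites x samples),
# going through the real VCF writer/reader path.
matrix_from_gt <- function(gt, ref = NULL, alt = NULL, pos = NULL) {
  gt <- base::matrix(gt, ncol = if (is.matrix(gt)) ncol(gt) else length(gt),
                     byrow = !is.matrix(gt))
  ns <- nrow(gt); n <- ncol(gt)
  ref <- ref %||% rep("A", ns)
  alt <- alt %||% rep("T", ns)
  pos <- pos %||% seq(5L, by = 10L, length.out = ns)
  ids <- sprintf("t%02d", seq_len(n))
  dir <- tempfile("gtmat")
  dir.create(dir)
  vcf <- file.path(dir, "m.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=1A,length=%d>", max(pos) + 10L),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t"),
    vapply(seq_len(ns), function(i)
      paste(c("1A", pos[i], ".", ref[i], alt[i], ".", ".", ".", "GT", gt[i, ]),
            collapse = "\t"), character(1))), vcf)
  smp <- file.path(dir, "s.tsv")
  writeLines(c("vcfID\taccessionName\tdisplayName",
               sprintf("%s\t%s\t%s", ids, ids, ids)), smp)
  catalog <- read_sample_catalog(smp)
  build_matrix(read_variants(vcf), ids, catalog)
}

# independent per-site recount of altFreq/maf/missingRate from GT strings
recount_site <- function(gts) {
  alleles <- integer(0); miss <- 0L
  for (g in gts) {
    p <- strsplit(g, "[/|]")[[1L]]
    if (length(p) == 1L) p <- c(p, p)
    if (any(p == ".")) { miss <- miss + 1L } else { alleles <- c(alleles, as.integer(p)) }
  }
  if (length(alleles)) {
    tab <- table(alleles)
    list(altFreq = mean(alleles != 0L), maf = 1 - max(tab) / length(alleles),
         missingRate = miss / length(gts))
  } else {
    list(altFreq = NA_real_, maf = 0, missingRate = 1)
  }
}
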