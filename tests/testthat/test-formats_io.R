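test_that("read_fasta_region slices 1-based inclusive intervals", {
  t <- tiny_instance()
  expect_identical(read_fasta_region(t$fasta, "1A", 3, 6),
                   substr(TINY_SEQ, 3, 6))
  expect_identical(read_fasta_region(t$fasta, "1A", 1, 60), TINY_SEQ)
  expect_error(read_fasta_region(t$fasta, "1A", 58, 61),
               class = "snpscope_range-error")
  expect_error(read_fasta_region(t$fasta, "9Z", 1, 5),
               class = "snpscope_unknown-contig")
  # property: every single-base query returns the k-th character
  for (k in seq_len(60)) {
    expect_identical(read_fasta_region(t$fasta, "1A", k, k),
                     substr(TINY_SEQ, k, k))
  }
})

test_that("parse_gff3 builds transcript models and a gene index", {
  t <- tiny_instance()
  g <- parse_gff3(t$gff)
  expect_named(g$transcripts, c("m1", "m2"))
  m1 <- g$transcripts$m1
  expect_identical(m1$geneId, "g1")
  expect_equal(m1$exons, data.frame(start = c(10L, 30L), end = c(20L, 40L)))
  expect_equal(m1$cds$phase, c(0L, 0L))
  # minus-strand exons are still stored ascending
  expect_identical(g$transcripts$m2$strand, "-")
  expect_true(all(diff(g$transcripts$m2$exons$start) >= 0))
  gi <- g$gene_index
  expect_equal(gi[gi$geneId == "g1", c("chrom", "start", "end", "strand")],
               data.frame(chrom = "1A", start = 10L, end = 40L, strand = "+"),
               ignore_attr = TRUE)
})

test_that("parse_gff3 rejects orphan CDS and duplicate gene ids", {
  bad <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "1A\tt\tgene\t1\t100\t.\t+\t.\tID=g1",
               "1A\tt\tmRNA\t1\t100\t.\t+\t.\tID=m1;Parent=g1",
               "1A\tt\tCDS\t5\t90\t.\t+\t0\tID=c;Parent=mMISSING"), bad)
  expect_error(parse_gff3(bad), class = "snpscope_gff-parse")
  dup <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "1A\tt\tgene\t1\t100\t.\t+\t.\tID=g1",
               "1A\tt\tgene\t200\t300\t.\t+\t.\tID=g1"), dup)
  expect_error(parse_gff3(dup), class = "snpscope_duplicate-gene")
})

test_that("read_variants honours regions, genotype classes and payloads", {
  t <- tiny_instance()
  r <- read_variants(t$vcf, parse_region_spec("1A:10-20"))
  expect_identical(r$pos, 15L)
  # phased separator accepted, class unchanged
  full <- read_variants(t$vcf)
  expect_identical(unname(full$klass[1L, "v2"]), "ALT_HOM")
  expect_true(full$phased[1L, "v2"])
  expect_false(full$phased[1L, "v1"])
  expect_identical(full$klass[1L, ], c(v1 = "HET", v2 = "ALT_HOM", v3 = "MISSING"))
  # multi-allelic record kept whole
  expect_identical(full$alts[[2L]], c("C", "GA"))
  expect_identical(unname(full$klass[2L, "v3"]), "HET")  # 1/2
  expect_identical(unname(full$dp[1L, "v1"]), 17L)
  expect_match(full$ann[[1L]], "missense_variant")
  expect_error(read_variants(t$vcf, vcf_ids = c("v1", "nope")),
               class = "snpscope_unknown-sample")
})

test_that("read_variants over a partition equals the whole-contig read", {
  t <- tiny_instance()
  whole <- read_variants(t$vcf, parse_region_spec("1A:1-60"))
  parts <- lapply(c("1A:1-10", "1A:11-24", "1A:25-60"), function(rg)
    read_variants(t$vcf, parse_region_spec(rg)))
  expect_identical(unlist(lapply(parts, `[[`, "pos")), whole$pos)
  expect_identical(do.call(rbind, lapply(parts, `[[`, "gt")), whole$gt)
})

test_that("read_sample_catalog parses triple names, groups and passports", {
  cat_ <- tiny_catalog()
  expect_identical(catalog_accessions(cat_), c("S01", "S02", "S03"))
  expect_identical(cat_$groups, list(landrace = c("S01", "S02")))
  expect_equal(cat_$entries$longitude, c(0, 0.5, 2))
  expect_identical(catalog_vcf_ids(cat_, c("S03", "S01")), c("v3", "v1"))
})

test_that("read_sample_catalog rejects reserved and duplicate names", {
  bad <- tempfile(); writeLines(c("vcfID\taccessionName\tdisplayName",
                                  "v1\t#RAW\tx"), bad)
  expect_error(read_sample_catalog(bad), class = "snpscope_reserved-name")
  dup <- tempfile(); writeLines(c("vcfID\taccessionName\tdisplayName",
                                  "v1\tS01\tx", "v2\tS01\ty"), dup)
  expect_error(read_sample_catalog(dup), class = "snpscope_validation")
  t <- tiny_instance()
  badg <- tempfile(); writeLines("g1\tS01,S99", badg)
  expect_error(read_sample_catalog(t$samples, badg), class = "snpscope_validation")
})

test_that("validate_instance flags inconsistencies and tolerates missing ANN", {
  t <- tiny_instance()
  rep <- validate_instance(t$vcf, t$fasta, t$gff, t$samples, t$groups)
  expect_true(rep$ok)
  expect_false(any(rep$findings$severity == "error"))
  # a VCF contig absent from the FASTA is an error
  vcf2 <- tempfile(fileext = ".vcf")
  lines <- readLines(t$vcf)
  writeLines(append(lines, "##contig=<ID=2B,length=99>", after = 2L), vcf2)
  rep2 <- validate_instance(vcf2, t$fasta, t$gff, t$samples, t$groups)
  expect_false(rep2$ok)
  expect_true("contig-mismatch" %in% rep2$findings$code)
  # missing ANN on the generated fixture: warning only
  fx <- shared_fixture()
  rep3 <- validate_instance(fx$paths$vcf, fx$paths$fasta, fx$paths$gff,
                            fx$paths$samples, fx$paths$groups)
  expect_true(rep3$ok)
  expect_true("ann-missing" %in% rep3$findings$code)
})

test_that("genotype classes survive a CSV round trip", {
  t <- tiny_instance()
  cat_ <- tiny_catalog()
  m <- build_matrix(read_variants(t$vcf), catalog_accessions(cat_), cat_)
  tab <- export_table(m, genotype_form = "raw")
  f <- tempfile(fileext = ".csv")
  write.csv(tab, f, row.names = FALSE)
  back <- read.csv(f, check.names = FALSE, colClasses = "character")
  for (s in m$samples) {
    expect_identical(genotype_class(back[[s]]), unname(m$klass[, s]))
  }
})
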