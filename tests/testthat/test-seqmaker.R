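# 8-bp reference world for the hand examples
ref8_world <- function(vcf_rows) {
  dir <- tempfile("ref8"); dir.create(dir)
  fasta <- file.path(dir, "r.fa")
  writeLines(c(">1A", "ACGTACGT"), fasta)
  vcf <- file.path(dir, "v.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1A,length=8>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "v1"), collapse = "\t"),
    vcf_rows), vcf)
  smp <- file.path(dir, "s.tsv")
  writeLines(c("vcfID\taccessionName\tdisplayName", "v1\tS01\tSample One"), smp)
  catalog <- read_sample_catalog(smp)
  m <- build_matrix(read_variants(vcf), "S01", catalog)
  list(fetch = make_reference_fetch(fasta), matrix = m, catalog = catalog)
}
row8 <- function(pos, ref, alt, gt)
  paste(c("1A", pos, ".", ref, alt, ".", ".", ".", "GT", gt), collapse = "\t")

test_that("make_consensus applies substitutions, indels and IUPAC hets", {
  region <- parse_region_spec("1A:1-8")
  # hom SNP pos 3 G->T
  w <- ref8_world(row8(3, "G", "T", "1/1"))
  r <- make_consensus(region, w$fetch, w$matrix)
  expect_identical(r$sequence, "ACTTACGT")
  expect_identical(r$applied$action, "substitute")
  # hom insertion pos 4 T -> TAA: length 10, refPos 5 maps to consensus 7
  w <- ref8_world(row8(4, "T", "TAA", "1/1"))
  r <- make_consensus(region, w$fetch, w$matrix)
  expect_identical(r$sequence, "ACGTAAACGT")
  expect_equal(nchar(r$sequence), 8 + sum(nchar(r$applied$alt) - nchar(r$applied$ref)))
  cm <- r$coordMap
  expect_equal(cm$consPos[cm$refPos == 5], 7)
  # het SNP pos 3 G/T under iupac -> K
  w <- ref8_world(row8(3, "G", "T", "0/1"))
  r <- make_consensus(region, w$fetch, w$matrix)
  expect_identical(r$sequence, "ACKTACGT")
  expect_identical(r$applied$action, "iupac")
  # het policies: alt substitutes, ref keeps
  expect_identical(make_consensus(region, w$fetch, w$matrix, "alt")$sequence,
                   "ACTTACGT")
  rr <- make_consensus(region, w$fetch, w$matrix, "ref")
  expect_identical(rr$sequence, "ACGTACGT")
  expect_identical(rr$skipped$reason, "het_policy_ref")
  # het indel keeps reference, logged as skipped
  w <- ref8_world(row8(4, "T", "TAA", "0/1"))
  r <- make_consensus(region, w$fetch, w$matrix)
  expect_identical(r$sequence, "ACGTACGT")
  expect_identical(r$skipped$reason, "het_indel")
  # missing keeps reference, logged
  w <- ref8_world(row8(3, "G", "T", "./."))
  r <- make_consensus(region, w$fetch, w$matrix)
  expect_identical(r$sequence, "ACGTACGT")
  expect_identical(r$skipped$reason, "missing")
})

test_that("boundary-crossing variants are skipped and deletions shift the map", {
  # deletion pos 6 REF "CG" crosses the 1A:1-6 boundary -> skipped
  w <- ref8_world(row8(6, "CG", "C", "1/1"))
  region6 <- parse_region_spec("1A:1-6")
  r <- make_consensus(region6, w$fetch, w$matrix)
  expect_identical(r$sequence, "ACGTAC")
  expect_identical(r$skipped$reason, "boundary")
  # inside the full region the deletion applies
  region <- parse_region_spec("1A:1-8")
  r2 <- make_consensus(region, w$fetch, w$matrix)
  expect_identical(r2$sequence, "ACGTACT")
  expect_equal(r2$coordMap$consPos[r2$coordMap$refPos == 8], 7)
  # multi-sample input is a parameter error
  t <- tiny_instance(); cat_ <- tiny_catalog()
  m2 <- build_matrix(read_variants(t$vcf), c("S01", "S02"), cat_)
  expect_error(make_consensus(region, w$fetch, m2), class = "snpscope_parameter")
})

test_that("raw sequence equals the reference and anchors the diff oracle", {
  w <- ref8_world(row8(3, "G", "T", "1/1"))
  region <- parse_region_spec("1A:1-8")
  expect_identical(raw_sequence(region, w$fetch), "ACGTACGT")
  # consensus with zero variants is the identity
  w0 <- ref8_world(row8(3, "G", "T", "0/0"))
  r0 <- make_consensus(region, w0$fetch, w0$matrix)
  expect_identical(r0$sequence, raw_sequence(region, w0$fetch))
  expect_equal(nrow(r0$applied), 0L)
  # raw and consensus differ exactly at the applied position
  r <- make_consensus(region, w$fetch, w$matrix)
  raw <- raw_sequence(region, w$fetch)
  diffs <- which(strsplit(r$sequence, "")[[1L]] != strsplit(raw, "")[[1L]])
  expect_identical(diffs, 3L)
})

test_that("consensus FASTA export writes stamped, wrapped, re-readable records", {
  w <- ref8_world(row8(3, "G", "T", "1/1"))
  region <- parse_region_spec("1A:1-8")
  r <- make_consensus(region, w$fetch, w$matrix)
  f <- tempfile(fileext = ".fa")
  write_consensus_fasta(list(r), f, labels = c(S01 = "Sample One"))
  lines <- readLines(f)
  expect_length(lines, 2L)
  expect_match(lines[[1L]], "^>Sample One 1A:1-8 het=iupac timestamp=")
  back <- Biostrings::readDNAStringSet(f)
  expect_identical(as.character(back[[1L]]), r$sequence)
  # --no-stamp form is deterministic
  f2 <- tempfile(); f3 <- tempfile()
  write_consensus_fasta(list(r), f2, stamp = FALSE)
  write_consensus_fasta(list(r), f3, stamp = FALSE)
  expect_identical(readLines(f2), readLines(f3))
  # long sequences wrap at 60 columns
  long <- r; long$sequence <- strrep("ACGT", 40)
  f4 <- tempfile()
  write_consensus_fasta(list(long), f4, stamp = FALSE)
  expect_equal(nchar(readLines(f4)[[2L]]), 60L)
})
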