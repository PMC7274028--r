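
test_that("codon-level SNP classification matches hand examples", {
  # ATG -> ATA: missense M->I (third base G->A, plus strand)
  w <- codon_world("ATG")
  a <- annotate_variant(list(chrom = "c1", pos = 6L, ref = "G", alts = "A"),
                        list(w$tm), w$fetch)
  expect_identical(a$effectClass, "missense")
  expect_identical(a$aaChange, "M1I")
  # GGA -> GGG: synonymous
  w <- codon_world("GGA")
  a <- annotate_variant(list(chrom = "c1", pos = 6L, ref = "A", alts = "G"),
                        list(w$tm), w$fetch)
  expect_identical(a$effectClass, "synonymous")
  # CAG -> TAG: stop gained
  w <- codon_world("CAG")
  a <- annotate_variant(list(chrom = "c1", pos = 4L, ref = "C", alts = "T"),
                        list(w$tm), w$fetch)
  expect_identical(a$effectClass, "stop_gained")
  # TAA -> CAA: stop lost
  w <- codon_world("TAA")
  a <- annotate_variant(list(chrom = "c1", pos = 4L, ref = "T", alts = "C"),
                        list(w$tm), w$fetch)
  expect_identical(a$effectClass, "stop_lost")
  # minus strand: the codon's first genomic base is its THIRD coding
  # position; genomic C->T there reads as coding G->A (ATG -> ATA)
  w <- codon_world("ATG", strand = "-")
  expect_identical(substr(w$seq, 4L, 6L), "CAT")
  a <- annotate_variant(list(chrom = "c1", pos = 4L, ref = "C", alts = "T"),
                        list(w$tm), w$fetch)
  expect_identical(a$effectClass, "missense")
  expect_identical(a$aaChange, "M1I")
})

test_that("indels, splice sites, introns and intergenic regions classify", {
  t <- tiny_instance()
  g <- parse_gff3(t$gff)
  fetch <- make_reference_fetch(t$fasta)
  ann_of <- function(pos, ref, alt)
    annotate_variant(list(chrom = "1A", pos = pos, ref = ref, alts = alt),
                     g$transcripts, fetch)
  base_at <- function(p) substr(TINY_SEQ, p, p)
  # 1-bp insertion in CDS -> frameshift; 3-bp in-frame -> missense/inframe
  fs <- ann_of(14L, base_at(14L), paste0(base_at(14L), "A"))
  expect_identical(fs$effectClass[fs$transcriptId == "m1"], "frameshift")
  inf <- ann_of(14L, base_at(14L), paste0(base_at(14L), "ACT"))
  expect_identical(inf$effectClass[inf$transcriptId == "m1"], "missense")
  expect_identical(inf$aaChange[inf$transcriptId == "m1"], "inframe")
  # first two intronic bases after exon 1 (ends at 20) are splice region
  expect_identical(ann_of(21L, base_at(21L), "A")$effectClass[1L], "splice_region")
  expect_identical(ann_of(22L, base_at(22L), "A")$effectClass[1L], "splice_region")
  expect_identical(ann_of(25L, base_at(25L), "A")$effectClass[1L], "intron")
  # exon but upstream of the CDS -> non-coding exon
  expect_identical(ann_of(10L, base_at(10L), "A")$effectClass[1L], "non_coding_exon")
  # outside both genes
  expect_identical(ann_of(42L, base_at(42L), "A")$effectClass[1L], "intergenic")
})

test_that("parse_ann_field maps effect terms and skips malformed entries", {
  a <- parse_ann_field(list(ann = "T|missense_variant|MODERATE|g1|g1|transcript|m1|pc|1|n.3G>T"))
  expect_identical(a$effectClass, "missense")
  expect_identical(a$transcriptId, "m1")
  expect_identical(parse_ann_field(list(ann = "T|synonymous_variant|LOW|g1|g1|transcript|m1"))$effectClass,
                   "synonymous")
  # unknown terms pass through as raw labels
  expect_identical(parse_ann_field(list(ann = "T|weird_term|x|g1|g1|t|m1"))$effectClass,
                   "weird_term")
  expect_identical(nrow(parse_ann_field(list(ann = character(0)))), 0L)
  expect_warning(out <- parse_ann_field(list(ann = c("garbage", "T|intron_variant|x|g|g|t|m"))),
                 class = "snpscope_ann-malformed")
  expect_identical(out$effectClass, "intron")
})

test_that("group frequencies count alleles per group and flag absent data", {
  gt <- rbind(c("0/0", "0/1", "1/1", "./.", "0/0", "0/0"),
              c("0/0", "0/0", "0/0", "0/0", "./.", "./."))
  m <- matrix_from_gt(gt)
  groups <- list(A = c("t01", "t02", "t03", "t04"), B = c("t05", "t06"))
  fr <- group_frequencies(m, groups)
  a1 <- fr[fr$groupId == "A" & fr$pos == m$sites$pos[1L], ]
  expect_equal(a1$altFreq, 0.5)        # (1 + 2) / 6 non-missing alleles
  expect_equal(a1$missingRate, 0.25)
  # all REF_HOM: present zero, not absent
  a2 <- fr[fr$groupId == "A" & fr$pos == m$sites$pos[2L], ]
  expect_equal(a2$altFreq, 0)
  # entirely missing group: absent (NA), distinguished from zero
  b2 <- fr[fr$groupId == "B" & fr$pos == m$sites$pos[2L], ]
  expect_true(is.na(b2$altFreq))
  expect_error(group_frequencies(m, list(A = character(0))),
               class = "snpscope_parameter")
  # allele-count conservation: sum over groups of freq * alleles = total ALT
  for (i in seq_len(nrow(m$sites))) {
    tot <- 0
    for (g in names(groups)) {
      row <- fr[fr$groupId == g & fr$pos == m$sites$pos[i], ]
      nonmiss <- 2 * length(groups[[g]]) * (1 - row$missingRate)
      if (!is.na(row$altFreq)) tot <- tot + row$altFreq * nonmiss
    }
    oracle <- sum(vapply(strsplit(gt[i, ], "[/|]"), function(p)
      sum(suppressWarnings(as.integer(p)) > 0L, na.rm = TRUE), integer(1)))
    expect_equal(tot, oracle)
  }
})

test_that("lollipop data picks the most severe effect class per site", {
  region <- parse_region_spec("1A:1-100")
  freqs <- data.frame(chrom = "1A", pos = c(10L, 10L), ref = "A", alt = "T",
                      groupId = c("g1", "g2"), altFreq = c(0.5, NA),
                      missingRate = 0, nSamples = 4)
  ann <- data.frame(pos = c(10L, 10L),
                    effectClass = c("synonymous", "stop_gained"))
  ld <- lollipop_data(region, freqs, ann, list())
  expect_identical(ld$sites$effectClass, "stop_gained")
  expect_equal(ld$sites$stem.g1, 0.5)
  expect_true(is.na(ld$sites$stem.g2))
  # severity is a strict total order over all known classes
  expect_identical(anyDuplicated(EFFECT_SEVERITY), 0L)
  sev <- match(c("missense", "splice_region", "frameshift"), EFFECT_SEVERITY)
  expect_identical(order(sev), c(3L, 1L, 2L))
})
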