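# Codon-level variant effect classification against transcript models (a
# deliberately minimal stand-in for a full effect predictor) and per-group
# site frequencies for lollipop-style displays.

#' Effect classes ordered by decreasing severity
#'
#' The total order used to colour lollipop stems and to summarize
#' multi-transcript sites: frameshift > stop_gained > stop_lost > missense
#' > splice_region > synonymous > non_coding_exon > intron > intergenic >
#' unknown.
#' @export
EFFECT_SEVERITY <- c("frameshift", "stop_gained", "stop_lost", "missense",
                     "splice_region", "synonymous", "non_coding_exon",
                     "intron", "intergenic", "unknown")

# number of intronic bases adjacent to an exon boundary that count as
# splice region (narrower than SnpEff's 3-exonic/8-intronic window)
SPLICE_WINDOW <- 2L

# coding-order CDS intervals and cumulative coding coordinates
coding_frame <- function(tm) {
  cds <- tm$cds
  if (!nrow(cds)) return(NULL)
  if (tm$strand == "-") cds <- cds[rev(seq_len(nrow(cds))), , drop = FALSE]
  len <- cds$end - cds$start + 1L
  list(cds = cds, offset = c(0L, cumsum(len))[seq_len(nrow(cds))],
       phase0 = cds$phase[[1L]], total = sum(len))
}

# 1-based coding coordinate of genomic position pos, or NA if not in CDS
coding_pos <- function(frame, strand, pos) {
  for (i in seq_len(nrow(frame$cds))) {
    iv <- frame$cds[i, ]
    if (pos >= iv$start && pos <= iv$end) {
      within <- if (strand == "-") iv$end - pos else pos - iv$start
      return(frame$offset[[i]] + within + 1L)
    }
  }
  NA_integer_
}

# genomic position of 1-based coding coordinate cpos
genomic_pos <- function(frame, strand, cpos) {
  for (i in seq_len(nrow(frame$cds))) {
    iv <- frame$cds[i, ]
    len <- iv$end - iv$start + 1L
    if (cpos > frame$offset[[i]] && cpos <= frame$offset[[i]] + len) {
      within <- cpos - frame$offset[[i]] - 1L
      return(if (strand == "-") iv$end - within else iv$start + within)
    }
  }
  NA_integer_
}

translate_codon <- function(codon) {
  if (grepl("[^ACGT]", codon)) return(NA_character_)
  unname(Biostrings::GENETIC_CODE[[codon]])
}

annotate_one_transcript <- function(chrom, pos, ref, alt, tm, reference_fetch) {
  span <- pos:(pos + nchar(ref) - 1L)
  in_iv <- function(df, p) any(p >= df$start & p <= df$end)
  in_cds <- nrow(tm$cds) > 0L && any(vapply(span, function(p) in_iv(tm$cds, p), logical(1)))
  eff <- NULL; aa <- NA_character_
  if (in_cds) {
    if (nchar(ref) == 1L && nchar(alt) == 1L && alt %in% c("A", "C", "G", "T")) {
      frame <- coding_frame(tm)
      cpos <- coding_pos(frame, tm$strand, pos)
      cpos0 <- cpos - frame$phase0
      if (is.na(cpos) || cpos0 < 1L) {
        eff <- "unknown"
      } else {
        codon_idx <- (cpos0 - 1L) %/% 3L
        within <- (cpos0 - 1L) %% 3L
        cstart <- codon_idx * 3L + 1L + frame$phase0
        if (cstart + 2L > frame$total) {
          eff <- "unknown"     # incomplete terminal codon
        } else {
          bases <- vapply(cstart:(cstart + 2L), function(cp) {
            gp <- genomic_pos(frame, tm$strand, cp)
            b <- reference_fetch(chrom, gp, gp)
            if (tm$strand == "-") comp_base(b) else b
          }, character(1))
          ref_codon <- paste(bases, collapse = "")
          alt_base <- if (tm$strand == "-") comp_base(alt) else alt
          alt_codon <- ref_codon
          substr(alt_codon, within + 1L, within + 1L) <- alt_base
          ref_aa <- translate_codon(ref_codon)
          alt_aa <- translate_codon(alt_codon)
          if (is.na(ref_aa) || is.na(alt_aa)) {
            eff <- "unknown"
          } else if (ref_aa == alt_aa) {
            eff <- "synonymous"
          } else if (alt_aa == "*") {
            eff <- "stop_gained"
          } else if (ref_aa == "*") {
            eff <- "stop_lost"
          } else {
            eff <- "missense"
          }
          aa <- sprintf("%s%d%s", ref_aa, codon_idx + 1L, alt_aa)
        }
      }
    } else {
      delta <- nchar(alt) - nchar(ref)
      if (delta %% 3L != 0L) {
        eff <- "frameshift"
      } else {
        eff <- "missense"; aa <- "inframe"  # in-frame indel, missense-class
      }
    }
  } else if (nrow(tm$exons) && any(vapply(span, function(p) in_iv(tm$exons, p), logical(1)))) {
    eff <- "non_coding_exon"
  } else if (pos >= tm$span[[1L]] && pos <= tm$span[[2L]]) {
    # intronic: splice region when within SPLICE_WINDOW of an exon boundary
    dists <- c(pos - tm$exons$end, tm$exons$start - pos)
    dists <- dists[dists > 0L]
    eff <- if (length(dists) && min(dists) <= SPLICE_WINDOW) "splice_region" else "intron"
  } else {
    return(NULL)  # outside this transcript
  }
  list(transcriptId = tm$transcriptId, geneId = tm$geneId,
       effectClass = eff, aaChange = aa)
}

#' Classify the effect of a variant against transcript models
#'
#' SNPs inside a CDS are translated strand-aware with the standard genetic
#' code (same amino acid: synonymous; new stop: stop_gained; lost stop:
#' stop_lost; otherwise missense, with the `aaChange` string recorded).
#' CDS indels are frameshift when the length change is not a multiple of
#' three, in-frame otherwise (missense class, `aaChange = "inframe"`).
#' Intronic positions within 2 bp of an exon boundary are splice_region;
#' other intronic positions are intron; exonic non-CDS positions are
#' non_coding_exon; a variant overlapping no transcript is intergenic.
#' Multi-allelic records are classified per ALT and summarized per
#' transcript by maximum severity.
#'
#' @param record list with `chrom`, `pos`, `ref`, `alts` (or a single
#'   `alt`); one row of a `genotype_matrix`'s `sites` works
#' @param transcripts named list of transcript models from [parse_gff3()]
#' @param reference_fetch `function(chrom, start, end)` returning reference
#'   sequence (see [make_reference_fetch()])
#' @return data.frame: `transcriptId`, `geneId`, `effectClass`, `aaChange`,
#'   `alt`; a single `intergenic` row when no transcript overlaps
#' @export
annotate_variant <- function(record, transcripts, reference_fetch) {
  alts <- record$alts %||% record$alt
  if (is.null(alts)) ss_stop("parameter", "record has no ALT allele")
  alts <- unlist(strsplit(as.character(alts), ",", fixed = TRUE))
  rows <- list()
  for (alt in alts) {
    if (alt %in% c("*", ".")) next  # spanning-deletion marker: no effect call
    for (tm in transcripts) {
      if (tm$chrom != record$chrom) next
      a <- annotate_one_transcript(record$chrom, record$pos, record$ref, alt,
                                   tm, reference_fetch)
      if (!is.null(a)) rows[[length(rows) + 1L]] <- c(a, list(alt = alt))
    }
  }
  if (!length(rows)) {
    return(data.frame(transcriptId = NA_character_, geneId = NA_character_,
                      effectClass = "intergenic", aaChange = NA_character_,
                      alt = alts[[1L]] %||% NA_character_,
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(transcriptId = r$transcriptId, geneId = r$geneId,
               effectClass = r$effectClass, aaChange = r$aaChange,
               alt = r$alt, stringsAsFactors = FALSE)))
  # one row per (transcript) pair: keep the most severe alt
  sev <- match(df$effectClass, EFFECT_SEVERITY)
  sev[is.na(sev)] <- length(EFFECT_SEVERITY) + 1L
  df <- df[order(df$transcriptId, sev), , drop = FALSE]
  df <- df[!duplicated(df$transcriptId), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# SnpEff-style ANN effect terms -> internal classes
ANN_TERM_MAP <- c(
  missense_variant = "missense", synonymous_variant = "synonymous",
  stop_gained = "stop_gained", stop_lost = "stop_lost",
  frameshift_variant = "frameshift", splice_region_variant = "splice_region",
  intron_variant = "intron", intergenic_region = "intergenic",
  intergenic_variant = "intergenic",
  non_coding_transcript_exon_variant = "non_coding_exon",
  `5_prime_UTR_variant` = "non_coding_exon",
  `3_prime_UTR_variant` = "non_coding_exon")

#' Map a record's INFO/ANN entries to effect annotations
#'
#' Pipe-delimited entries (`allele|effect|impact|gene|...|transcript|...`)
#' are mapped onto the internal effect classes; unknown effect terms pass
#' through as raw labels. Malformed entries are skipped with a warning.
#' An empty/absent ANN yields an empty data.frame (callers then fall back
#' to [annotate_variant()]).
#'
#' @param record list with an `ann` character vector (may be NULL/empty)
#' @return data.frame `transcriptId`, `geneId`, `effectClass`, `aaChange`, `alt`
#' @export
parse_ann_field <- function(record) {
  ann <- record$ann
  empty <- data.frame(transcriptId = character(0), geneId = character(0),
                      effectClass = character(0), aaChange = character(0),
                      alt = character(0), stringsAsFactors = FALSE)
  if (is.null(ann) || !length(ann)) return(empty)
  rows <- lapply(ann, function(entry) {
    f <- strsplit(entry, "|", fixed = TRUE)[[1L]]
    if (length(f) < 2L || !nzchar(f[[2L]])) {
      ss_warn("ann-malformed", sprintf("skipping malformed ANN entry '%s'", entry))
      return(NULL)
    }
    terms <- strsplit(f[[2L]], "&", fixed = TRUE)[[1L]]
    mapped <- unname(ifelse(terms %in% names(ANN_TERM_MAP), ANN_TERM_MAP[terms], terms))
    sev <- match(mapped, EFFECT_SEVERITY); sev[is.na(sev)] <- length(EFFECT_SEVERITY) + 1L
    data.frame(transcriptId = if (length(f) >= 7L && nzchar(f[[7L]])) f[[7L]] else NA_character_,
               geneId = if (length(f) >= 4L && nzchar(f[[4L]])) f[[4L]] else NA_character_,
               effectClass = mapped[[which.min(sev)]],
               aaChange = if (length(f) >= 11L && nzchar(f[[11L]])) f[[11L]] else NA_character_,
               alt = f[[1L]], stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-group allele frequencies at every site
#'
#' Frequencies use allele counting over non-missing alleles within each
#' group (consistent with the MAF convention). A group that is entirely
#' missing at a site gets `altFreq = NA` — "undetected" is distinguished
#' from an observed frequency of zero.
#'
#' @param matrix a `genotype_matrix`
#' @param groups named list groupId -> accession members (non-empty,
#'   members drawn from `matrix$samples`)
#' @return data.frame `chrom, pos, ref, alt, groupId, altFreq, missingRate,
#'   nSamples`
#' @export
group_frequencies <- function(matrix, groups) {
  if (!length(groups)) ss_stop("parameter", "no groups supplied")
  for (g in names(groups)) {
    mem <- groups[[g]]
    if (!length(mem)) ss_stop("parameter", sprintf("group '%s' is empty", g))
    bad <- setdiff(mem, matrix$samples)
    if (length(bad))
      ss_stop("unknown-name", sprintf("group '%s' member(s) not in matrix: %s",
                                      g, paste(bad, collapse = ", ")))
  }
  out <- list()
  for (g in names(groups)) {
    mem <- groups[[g]]
    a1 <- matrix$a1[, mem, drop = FALSE]; a2 <- matrix$a2[, mem, drop = FALSE]
    nonmiss <- rowSums(!is.na(a1)) * 2L
    altc <- rowSums(a1 > 0L, na.rm = TRUE) + rowSums(a2 > 0L, na.rm = TRUE)
    out[[g]] <- data.frame(
      chrom = matrix$sites$chrom, pos = matrix$sites$pos,
      ref = matrix$sites$ref, alt = matrix$sites$alt,
      groupId = g,
      altFreq = ifelse(nonmiss > 0L, altc / nonmiss, NA_real_),
      missingRate = rowMeans(is.na(a1)),
      nSamples = length(mem), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assemble plot-ready lollipop data for a region
#'
#' Per site: the x position, one stem per group with height `altFreq`
#' (NA when the group is entirely missing), and the colour class = most
#' severe effect over the site's annotations. Transcript tracks carry the
#' exon/CDS intervals and strand, in annotation order.
#'
#' @param region a `region_query`
#' @param freqs result of [group_frequencies()]
#' @param annotations data.frame with `pos` and `effectClass` (e.g. rbind
#'   of [annotate_variant()] results tagged with their positions)
#' @param transcripts named list of transcript models on the region
#' @return list: `region`, `sites` (data.frame with `stem.<group>` columns
#'   and `effectClass`), `groups`, `transcripts`
#' @export
lollipop_data <- function(region, freqs, annotations, transcripts) {
  gids <- unique(freqs$groupId)
  base <- unique(freqs[, c("chrom", "pos", "ref", "alt")])
  base <- base[order(base$pos), , drop = FALSE]
  for (g in gids) {
    f <- freqs[freqs$groupId == g, ]
    base[[paste0("stem.", g)]] <- f$altFreq[match(base$pos, f$pos)]
  }
  cls <- vapply(base$pos, function(p) {
    eff <- annotations$effectClass[annotations$pos == p]
    eff <- eff[!is.na(eff)]
    if (!length(eff)) return("unknown")
    sev <- match(eff, EFFECT_SEVERITY); sev[is.na(sev)] <- length(EFFECT_SEVERITY) + 1L
    eff[[which.min(sev)]]
  }, character(1))
  base$effectClass <- cls
  rownames(base) <- NULL
  tr <- lapply(transcripts, function(tm)
    list(transcriptId = tm$transcriptId, geneId = tm$geneId, strand = tm$strand,
         exons = tm$exons, cds = tm$cds))
  list(region = format_region(region), sites = base, groups = gids,
       transcripts = unname(tr))
}

#' Annotate every site of a genotype matrix
#'
#' Uses INFO/ANN when present (and `prefer_ann = TRUE`), falling back to
#' the built-in codon-level annotator otherwise.
#'
#' @param matrix a `genotype_matrix`
#' @param transcripts transcript models from [parse_gff3()]
#' @param reference_fetch reference lookup closure
#' @param prefer_ann use VCF ANN entries when available
#' @return data.frame of per-(site, transcript) annotations with `pos`
#' @export
annotate_matrix <- function(matrix, transcripts, reference_fetch, prefer_ann = TRUE) {
  rows <- lapply(seq_len(nrow(matrix$sites)), function(i) {
    rec <- list(chrom = matrix$sites$chrom[[i]], pos = matrix$sites$pos[[i]],
                ref = matrix$sites$ref[[i]], alts = matrix$alts[[i]],
                ann = matrix$ann[[i]])
    a <- if (prefer_ann) parse_ann_field(rec) else NULL
    if (is.null(a) || !nrow(a))
      a <- annotate_variant(rec, transcripts, reference_fetch)
    a$pos <- rec$pos
    a
  })
  out <- do.call(rbind, rows) %||%
    data.frame(transcriptId = character(0), geneId = character(0),
               effectClass = character(0), aaChange = character(0),
               alt = character(0), pos = integer(0))
  rownames(out) <- NULL
  out
}
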