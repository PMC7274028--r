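# Input readers (FASTA, GFF3, VCF, metadata TSVs), instance validation and
# the CSV/JSON writers shared by the analysis modules.
#
# Coordinates are 1-based inclusive at every interface in this package.

# ---------------------------------------------------------------- FASTA ----

# Per-session cache of parsed FASTA files keyed by normalized path; fixture
# genomes are small so whole-file reads are cheap, and an .fai-indexed route
# via Rsamtools is used when available to honour the random-access contract.
.fasta_cache <- new.env(parent = emptyenv())

load_fasta <- function(fasta_path) {
  key <- normalizePath(fasta_path, mustWork = TRUE)
  hit <- .fasta_cache[[key]]
  mt <- as.numeric(file.mtime(key))
  if (!is.null(hit) && identical(hit$mtime, mt)) return(hit$seqs)
  seqs <- Biostrings::readDNAStringSet(key)
  names(seqs) <- sub("\\s.*$", "", names(seqs))  # first token of header
  .fasta_cache[[key]] <- list(mtime = mt, seqs = seqs)
  seqs
}

#' Extract a reference subsequence
#'
#' Returns the uppercase reference sequence for a 1-based inclusive interval.
#' When a samtools-style `.fai` index sits next to the FASTA the slice is
#' fetched by random access; otherwise the (cached) in-memory copy is used.
#'
#' @param fasta_path path to the reference FASTA
#' @param chrom contig name (first whitespace-separated token of the header)
#' @param start,end 1-based inclusive interval, `1 <= start <= end`
#' @return character scalar of length `end - start + 1`
#' @export
read_fasta_region <- function(fasta_path, chrom, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || start > end)
    ss_stop("malformed-region", sprintf("invalid interval %s-%s", start, end))
  fai <- paste0(fasta_path, ".fai")
  if (file.exists(fai)) {
    fa <- Rsamtools::FaFile(fasta_path)
    idx <- Rsamtools::seqinfo(fa)
    if (!chrom %in% GenomeInfoDb::seqnames(idx))
      ss_stop("unknown-contig", sprintf("contig '%s' not present in %s", chrom, fasta_path))
    clen <- GenomeInfoDb::seqlengths(idx)[[chrom]]
    if (end > clen)
      ss_stop("range-error", sprintf("%s:%d-%d exceeds contig length %d", chrom, start, end, clen))
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
    return(toupper(as.character(Rsamtools::getSeq(fa, gr)[[1L]])))
  }
  seqs <- load_fasta(fasta_path)
  if (!chrom %in% names(seqs))
    ss_stop("unknown-contig", sprintf("contig '%s' not present in %s", chrom, fasta_path))
  clen <- length(seqs[[chrom]])
  if (end > clen)
    ss_stop("range-error", sprintf("%s:%d-%d exceeds contig length %d", chrom, start, end, clen))
  toupper(as.character(Biostrings::subseq(seqs[[chrom]], start, end)))
}

#' Build a reference-fetch closure over one FASTA
#'
#' Several operations (effect annotation, consensus building) need repeated
#' small reference lookups; this returns `function(chrom, start, end)`
#' wrapping [read_fasta_region()] with the path fixed.
#'
#' @param fasta_path path to the reference FASTA
#' @export
make_reference_fetch <- function(fasta_path) {
  force(fasta_path)
  function(chrom, start, end) read_fasta_region(fasta_path, chrom, start, end)
}

# ----------------------------------------------------------------- GFF3 ----

#' Parse a GFF3 annotation into transcript models
#'
#' Reads gene/mRNA/exon/CDS features linked by `ID`/`Parent` and returns one
#' transcript model per mRNA plus a gene index. Exon and CDS intervals are
#' stored sorted ascending regardless of strand; CDS phase is kept per
#' interval. A gene's span is the union of its mRNA spans.
#'
#' @param gff_path path to a GFF3 file
#' @return list with `transcripts` (named list of transcript models:
#'   `geneId`, `transcriptId`, `chrom`, `strand`, `exons`, `cds` with phase)
#'   and `gene_index` (data.frame `geneId, chrom, start, end, strand`)
#' @export
parse_gff3 <- function(gff_path) {
  df <- as.data.frame(rtracklayer::readGFF(gff_path,
    columns = c("seqid", "type", "start", "end", "strand", "phase"),
    tags = c("ID", "Parent")))
  df$Parent <- vapply(df$Parent, function(p) if (length(p)) p[[1L]] else NA_character_, character(1))
  df$seqid <- as.character(df$seqid); df$type <- as.character(df$type)
  genes <- df[df$type == "gene", , drop = FALSE]
  if (anyDuplicated(genes$ID))
    ss_stop("duplicate-gene", sprintf("duplicate gene id(s): %s",
      paste(unique(genes$ID[duplicated(genes$ID)]), collapse = ", ")))
  mrnas <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  exons <- df[df$type == "exon", , drop = FALSE]
  cdss  <- df[df$type == "CDS", , drop = FALSE]
  if (any(is.na(cdss$Parent)) || !all(cdss$Parent %in% mrnas$ID))
    ss_stop("gff-parse", "CDS feature without a parent mRNA")
  if (any(is.na(exons$Parent)) || !all(exons$Parent %in% mrnas$ID))
    ss_stop("gff-parse", "exon feature without a parent mRNA")

  transcripts <- list()
  for (i in seq_len(nrow(mrnas))) {
    m <- mrnas[i, ]
    ex <- exons[exons$Parent == m$ID, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    cd <- cdss[cdss$Parent == m$ID, , drop = FALSE]
    cd <- cd[order(cd$start), , drop = FALSE]
    tm <- list(
      geneId = m$Parent, transcriptId = m$ID,
      chrom = m$seqid, strand = as.character(m$strand),
      span = c(m$start, m$end),
      exons = data.frame(start = ex$start, end = ex$end),
      cds = data.frame(start = cd$start, end = cd$end,
                       phase = ifelse(is.na(cd$phase), 0L, as.integer(cd$phase)))
    )
    if (nrow(tm$cds) && !all(tm$cds$phase %in% 0:2))
      ss_stop("gff-parse", sprintf("invalid CDS phase for %s", m$ID))
    transcripts[[m$ID]] <- tm
  }
  # gene span = union of its mRNA spans (fallback: the gene's own record)
  gi <- lapply(unique(genes$ID), function(g) {
    mg <- mrnas[!is.na(mrnas$Parent) & mrnas$Parent == g, , drop = FALSE]
    row <- genes[genes$ID == g, ][1L, ]
    if (nrow(mg)) {
      data.frame(geneId = g, chrom = row$seqid, start = min(mg$start),
                 end = max(mg$end), strand = as.character(row$strand))
    } else {
      data.frame(geneId = g, chrom = row$seqid, start = row$start,
                 end = row$end, strand = as.character(row$strand))
    }
  })
  gene_index <- do.call(rbind, gi) %||% data.frame(
    geneId = character(0), chrom = character(0),
    start = integer(0), end = integer(0), strand = character(0))
  list(transcripts = transcripts, gene_index = gene_index)
}

# ------------------------------------------------------------------ VCF ----

# classify a pair of allele indices into the four-way genotype encoding
classify_alleles <- function(a1, a2) {
  k <- rep("MISSING", length(a1))
  ok <- !is.na(a1) & !is.na(a2)
  k[ok & a1 == 0L & a2 == 0L] <- "REF_HOM"
  k[ok & a1 == a2 & a1 > 0L] <- "ALT_HOM"
  k[ok & a1 != a2] <- "HET"
  k
}

parse_gt_strings <- function(gt) {
  # haploid entries are promoted to homozygous diploid; half-calls -> MISSING
  gt <- as.character(gt)
  phased <- grepl("|", gt, fixed = TRUE)
  parts <- strsplit(gt, "[/|]")
  lens <- lengths(parts)
  if (any(lens == 1L & gt != "." & !is.na(gt)))
    ss_warn("haploid-promoted", "haploid GT entries promoted to homozygous diploid")
  a1 <- vapply(parts, function(p) if (length(p) >= 1L) p[[1L]] else ".", character(1))
  a2 <- vapply(parts, function(p) if (length(p) >= 2L) p[[2L]] else p[[1L]], character(1))
  a1 <- suppressWarnings(as.integer(a1)); a2 <- suppressWarnings(as.integer(a2))
  half <- xor(is.na(a1), is.na(a2))
  a1[half] <- NA_integer_; a2[half] <- NA_integer_
  list(a1 = a1, a2 = a2, phased = phased)
}

# per-session cache of parsed VCF headers (sample columns, declared fields)
.vcf_header_cache <- new.env(parent = emptyenv())

vcf_header_info <- function(vcf_path) {
  key <- normalizePath(vcf_path, mustWork = TRUE)
  hit <- .vcf_header_cache[[key]]
  if (!is.null(hit)) return(hit)
  hdr <- VariantAnnotation::scanVcfHeader(vcf_path)
  fmt <- rownames(VariantAnnotation::geno(hdr))
  info <- list(samples = VariantAnnotation::samples(hdr),
               has_ann = "ANN" %in% rownames(VariantAnnotation::info(hdr)),
               has_dp = "DP" %in% fmt, has_gq = "GQ" %in% fmt)
  .vcf_header_cache[[key]] <- info
  info
}

# assemble a variant_records object from parsed columns
new_variant_records <- function(chrom, pos, ref, alts, gt, dp, gq, ann, vcf_ids) {
  n <- length(pos)
  parsed <- parse_gt_strings(as.vector(gt))
  dims <- list(NULL, vcf_ids)
  structure(list(
    chrom = chrom, pos = pos, ref = ref, alts = alts,
    gt = gt,
    a1 = matrix(parsed$a1, n, length(vcf_ids), dimnames = dims),
    a2 = matrix(parsed$a2, n, length(vcf_ids), dimnames = dims),
    phased = matrix(parsed$phased, n, length(vcf_ids), dimnames = dims),
    klass = matrix(classify_alleles(parsed$a1, parsed$a2), n, length(vcf_ids),
                   dimnames = dims),
    dp = dp, gq = gq, ann = ann, vcf_ids = vcf_ids
  ), class = "variant_records")
}

# fast region fetch: tabix random access + direct record parsing.
# Semantics match the readVcf route exactly (checked by the dual-route
# region-query test): same GT strings, integer DP/GQ with "." as NA,
# INFO/ANN split on commas, symbolic-ALT records skipped.
read_variants_tabix <- function(vcf_gz, region, vcf_ids) {
  hdr <- vcf_header_info(vcf_gz)
  which <- GenomicRanges::GRanges(region$chrom,
                                  IRanges::IRanges(region$start, region$end))
  tf <- Rsamtools::TabixFile(vcf_gz)
  open(tf); on.exit(close(tf))
  lines <- tryCatch(Rsamtools::scanTabix(tf, param = which)[[1L]],
                    error = function(e) character(0))  # chrom absent from index
  n0 <- length(lines)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  col_idx <- match(vcf_ids, hdr$samples) + 9L
  chrom <- character(n0); pos <- integer(n0); ref <- character(n0)
  alts <- vector("list", n0); ann <- vector("list", n0)
  gt <- base::matrix(NA_character_, n0, length(vcf_ids))
  dp <- base::matrix(NA_integer_, n0, length(vcf_ids))
  gq <- base::matrix(NA_integer_, n0, length(vcf_ids))
  keep <- logical(n0)
  for (i in seq_len(n0)) {
    f <- fields[[i]]
    p <- as.integer(f[[2L]])
    if (p < region$start || p > region$end) next
    a <- strsplit(f[[5L]], ",", fixed = TRUE)[[1L]]
    if (any(grepl("^<|\\[|\\]", a))) {
      ss_warn("symbolic-alt", sprintf("record at %s:%d with symbolic ALT skipped",
                                      f[[1L]], p))
      next
    }
    keep[i] <- TRUE
    chrom[i] <- f[[1L]]; pos[i] <- p; ref[i] <- f[[4L]]; alts[[i]] <- a
    if (hdr$has_ann) {
      m <- regmatches(f[[8L]], regexec("(?:^|;)ANN=([^;]*)", f[[8L]]))[[1L]]
      ann[[i]] <- if (length(m)) strsplit(m[[2L]], ",", fixed = TRUE)[[1L]]
                  else character(0)
    }
    fmt <- strsplit(f[[9L]], ":", fixed = TRUE)[[1L]]
    gt_k <- match("GT", fmt); dp_k <- match("DP", fmt); gq_k <- match("GQ", fmt)
    if (is.na(gt_k)) ss_stop("vcf-parse", sprintf("no GT at %s:%d", f[[1L]], p))
    cells <- strsplit(f[col_idx], ":", fixed = TRUE)
    gt[i, ] <- vapply(cells, `[[`, character(1), gt_k)
    num_at <- function(cell, k) {
      if (is.na(k) || length(cell) < k || cell[[k]] == ".") NA_integer_
      else as.integer(cell[[k]])
    }
    dp[i, ] <- vapply(cells, num_at, integer(1), dp_k)
    gq[i, ] <- vapply(cells, num_at, integer(1), gq_k)
  }
  ord <- order(pos[keep])
  sel <- which(keep)[ord]
  dims <- list(NULL, vcf_ids)
  gt <- gt[sel, , drop = FALSE]; dimnames(gt) <- dims
  dp <- dp[sel, , drop = FALSE]; dimnames(dp) <- dims
  gq <- gq[sel, , drop = FALSE]; dimnames(gq) <- dims
  new_variant_records(chrom[sel], pos[sel], ref[sel], alts[sel],
                      gt,
                      if (hdr$has_dp) dp else NULL,
                      if (hdr$has_gq) gq else NULL,
                      if (hdr$has_ann) ann[sel] else NULL, vcf_ids)
}

#' Read variant records for a region
#'
#' Region-scoped retrieval from a VCF. Bgzipped, tabix-indexed files are
#' sliced by random access (a direct tabix fetch, so repeated small
#' queries stay fast); plain-text VCFs are read whole and filtered, with
#' identical semantics. Records are returned position-sorted, with
#' genotype calls restricted to the requested sample columns and per-sample
#' DP/GQ plus INFO/ANN captured when present. Records with symbolic ALT
#' alleles (e.g. `<DEL>`) are skipped with a warning.
#'
#' @param vcf_path path to a VCF (`.vcf` or `.vcf.gz`)
#' @param region optional region query (see [parse_region_spec()]) or NULL
#'   for the whole file
#' @param vcf_ids optional character vector of VCF sample columns to keep
#'   (default: all, in header order)
#' @return a `variant_records` object: columnar container with one row per
#'   record (`chrom`, `pos`, `ref`, `alts` list, per-sample genotype
#'   matrices `a1`/`a2`/`phased`/`klass`, optional `dp`/`gq`, `ann` list)
#' @export
read_variants <- function(vcf_path, region = NULL, vcf_ids = NULL) {
  hdr <- VariantAnnotation::scanVcfHeader(vcf_path)
  hdr_samples <- VariantAnnotation::samples(hdr)
  if (is.null(vcf_ids)) vcf_ids <- hdr_samples
  missing_ids <- setdiff(vcf_ids, hdr_samples)
  if (length(missing_ids))
    ss_stop("unknown-sample", sprintf("sample id(s) not in VCF header: %s",
                                      paste(missing_ids, collapse = ", ")))
  has_tbi <- grepl("\\.(gz|bgz)$", vcf_path) &&
    (file.exists(paste0(vcf_path, ".tbi")) || file.exists(paste0(vcf_path, ".csi")))
  if (!is.null(region) && has_tbi) {
    return(read_variants_tabix(vcf_path, region, vcf_ids))
  }
  v <- suppressWarnings(VariantAnnotation::readVcf(vcf_path, genome = "unknown"))
  rr <- SummarizedExperiment::rowRanges(v)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  keep <- rep(TRUE, length(pos))
  if (!is.null(region)) {
    keep <- chrom == region$chrom & pos >= region$start & pos <= region$end
  }
  alts <- lapply(VariantAnnotation::alt(v), as.character)
  symbolic <- vapply(alts, function(a) any(grepl("^<|\\[|\\]", a)), logical(1))
  if (any(symbolic & keep))
    ss_warn("symbolic-alt", sprintf("%d record(s) with symbolic ALT skipped", sum(symbolic & keep)))
  keep <- keep & !symbolic
  v <- v[keep, ]
  ord <- order(as.character(GenomicRanges::seqnames(SummarizedExperiment::rowRanges(v))),
               GenomicRanges::start(SummarizedExperiment::rowRanges(v)))
  v <- v[ord, ]

  rr <- SummarizedExperiment::rowRanges(v)
  n <- length(rr)
  geno <- VariantAnnotation::geno(v)
  gt <- geno$GT
  if (is.null(gt)) ss_stop("vcf-parse", "VCF has no GT in FORMAT")
  gt <- gt[, vcf_ids, drop = FALSE]
  dimnames(gt) <- list(NULL, vcf_ids)
  if (n == 0L) gt <- matrix(character(0), 0, length(vcf_ids), dimnames = list(NULL, vcf_ids))
  parsed <- parse_gt_strings(as.vector(gt))
  dims <- list(NULL, vcf_ids)
  a1 <- matrix(parsed$a1, n, length(vcf_ids), dimnames = dims)
  a2 <- matrix(parsed$a2, n, length(vcf_ids), dimnames = dims)
  phased <- matrix(parsed$phased, n, length(vcf_ids), dimnames = dims)
  klass <- matrix(classify_alleles(parsed$a1, parsed$a2), n, length(vcf_ids), dimnames = dims)
  dp <- if (!is.null(geno$DP)) {
    m <- geno$DP[, vcf_ids, drop = FALSE]; storage.mode(m) <- "integer"
    dimnames(m) <- list(NULL, vcf_ids); m
  }
  gq <- if (!is.null(geno$GQ)) {
    m <- geno$GQ[, vcf_ids, drop = FALSE]; storage.mode(m) <- "integer"
    dimnames(m) <- list(NULL, vcf_ids); m
  }
  ann <- if ("ANN" %in% names(VariantAnnotation::info(v))) {
    lapply(seq_len(n), function(i) as.character(VariantAnnotation::info(v)$ANN[[i]]))
  } else NULL
  structure(list(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(VariantAnnotation::ref(v)),
    alts = lapply(VariantAnnotation::alt(v), as.character),
    gt = gt, a1 = a1, a2 = a2, phased = phased, klass = klass,
    dp = dp, gq = gq, ann = ann, vcf_ids = vcf_ids
  ), class = "variant_records")
}

#' @export
print.variant_records <- function(x, ...) {
  cat(sprintf("<variant_records> %d record(s) x %d sample(s)\n",
              length(x$pos), length(x$vcf_ids)))
  invisible(x)
}

n_records <- function(records) length(records$pos)

# ------------------------------------------------------------- metadata ----

#' Read the sample catalog (triple names, groups, passport columns)
#'
#' The samples TSV must carry `vcfID`, `accessionName`, `displayName`
#' columns; extra columns become passport metadata, with `latitude` /
#' `longitude` parsed as decimal degrees. The optional groups TSV has lines
#' `groupID<TAB>acc1,acc2,...`.
#'
#' @param samples_tsv path to the sample TSV
#' @param groups_tsv optional path to the group-definition TSV
#' @return a `sample_catalog`: `entries` data.frame plus named list `groups`
#' @export
read_sample_catalog <- function(samples_tsv, groups_tsv = NULL) {
  df <- read.delim(samples_tsv, stringsAsFactors = FALSE, check.names = FALSE,
                   colClasses = "character")
  need <- c("vcfID", "accessionName", "displayName")
  if (!all(need %in% names(df)))
    ss_stop("validation", sprintf("samples TSV must have columns: %s",
                                  paste(need, collapse = ", ")))
  for (col in need) {
    bad <- df[[col]][is_reserved_name(df[[col]])]
    if (length(bad))
      ss_stop("reserved-name", sprintf("reserved name '%s' used in column %s", bad[[1L]], col))
  }
  if (anyDuplicated(df$vcfID))
    ss_stop("validation", "duplicate vcfID in samples TSV")
  if (anyDuplicated(df$accessionName))
    ss_stop("validation", "duplicate accessionName in samples TSV")
  for (col in c("latitude", "longitude")) {
    if (col %in% names(df)) df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  groups <- list()
  if (!is.null(groups_tsv)) {
    lines <- readLines(groups_tsv)
    lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
    for (ln in lines) {
      fields <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
      if (length(fields) < 2L)
        ss_stop("validation", sprintf("malformed group line: '%s'", ln))
      gid <- trimws(fields[[1L]])
      if (is_reserved_name(gid) || is_reserved_name(paste0("#", gid)))
        ss_stop("reserved-name", sprintf("reserved group id '%s'", gid))
      if (gid %in% names(groups))
        ss_stop("validation", sprintf("duplicate group id '%s'", gid))
      members <- trimws(strsplit(fields[[2L]], ",", fixed = TRUE)[[1L]])
      unknown <- setdiff(members, df$accessionName)
      if (length(unknown))
        ss_stop("validation", sprintf("group '%s' references unknown accession(s): %s",
                                      gid, paste(unknown, collapse = ", ")))
      groups[[gid]] <- members
    }
  }
  structure(list(entries = df, groups = groups), class = "sample_catalog")
}

#' @export
print.sample_catalog <- function(x, ...) {
  cat(sprintf("<sample_catalog> %d sample(s), %d group(s)\n",
              nrow(x$entries), length(x$groups)))
  invisible(x)
}

#' Accession names of a catalog, in catalog order
#' @param catalog a `sample_catalog`
#' @export
catalog_accessions <- function(catalog) catalog$entries$accessionName

#' Map accession names to their VCF column ids
#' @param catalog a `sample_catalog`
#' @param accessions accession names to map
#' @return character vector of vcfIDs, in `accessions` order
#' @export
catalog_vcf_ids <- function(catalog, accessions) {
  idx <- match(accessions, catalog$entries$accessionName)
  if (anyNA(idx))
    ss_stop("unknown-name", sprintf("unknown accession(s): %s",
                                    paste(accessions[is.na(idx)], collapse = ", ")))
  catalog$entries$vcfID[idx]
}

# ----------------------------------------------------------- validation ----

#' Cross-validate a full instance (VCF + FASTA + GFF3 + metadata)
#'
#' Errors: VCF contig absent from the FASTA; catalog vcfID absent from the
#' VCF header; duplicate gene ids in the GFF3. Warnings: VCF sample without
#' a catalog row; missing INFO/ANN declaration (effect classes will be
#' computed by the built-in annotator).
#'
#' @param vcf_path,fasta_path,gff_path,samples_tsv,groups_tsv input paths
#' @return a `validation_report`: `ok` flag plus `findings` data.frame
#'   (`severity`, `code`, `message`)
#' @export
validate_instance <- function(vcf_path, fasta_path, gff_path,
                              samples_tsv, groups_tsv = NULL) {
  for (p in c(vcf_path, fasta_path, gff_path, samples_tsv, groups_tsv)) {
    if (!is.null(p) && !file.exists(p))
      ss_stop("io", sprintf("cannot read '%s'", p))
  }
  findings <- data.frame(severity = character(0), code = character(0),
                         message = character(0), stringsAsFactors = FALSE)
  add <- function(severity, code, message) {
    findings[nrow(findings) + 1L, ] <<- list(severity, code, message)
  }
  hdr <- tryCatch(VariantAnnotation::scanVcfHeader(vcf_path), error = function(e) {
    add("error", "vcf-parse", conditionMessage(e)); NULL
  })
  fasta_contigs <- tryCatch(names(load_fasta(fasta_path)), error = function(e) {
    add("error", "fasta-parse", conditionMessage(e)); character(0)
  })
  if (!is.null(hdr)) {
    vcf_contigs <- rownames(VariantAnnotation::meta(hdr)$contig)
    if (is.null(vcf_contigs)) {
      # header lacks contig lines: fall back to the records themselves
      vcf_contigs <- unique(read_variants(vcf_path)$chrom)
    }
    for (ct in setdiff(vcf_contigs, fasta_contigs))
      add("error", "contig-mismatch", sprintf("VCF contig '%s' absent from FASTA", ct))
    fmt <- VariantAnnotation::geno(hdr)
    if (!"GT" %in% rownames(fmt)) add("error", "vcf-parse", "no GT declared in FORMAT")
    if (!"ANN" %in% rownames(VariantAnnotation::info(hdr)))
      add("warning", "ann-missing",
          "no INFO/ANN field: variant effects will be computed internally")
    cat_ok <- tryCatch({
      catalog <- read_sample_catalog(samples_tsv, groups_tsv)
      vcf_samples <- VariantAnnotation::samples(hdr)
      for (s in setdiff(catalog$entries$vcfID, vcf_samples))
        add("error", "unknown-sample", sprintf("catalog vcfID '%s' absent from VCF header", s))
      for (s in setdiff(vcf_samples, catalog$entries$vcfID))
        add("warning", "uncatalogued-sample", sprintf("VCF sample '%s' has no catalog row", s))
      TRUE
    }, snpscope_error = function(e) {
      add("error", "catalog", conditionMessage(e)); FALSE
    })
    invisible(cat_ok)
  }
  tryCatch(invisible(parse_gff3(gff_path)), snpscope_error = function(e) {
    add("error", "gff", conditionMessage(e))
  })
  structure(list(ok = !any(findings$severity == "error"), findings = findings),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> ok=%s\n", x$ok))
  if (nrow(x$findings)) {
    for (i in seq_len(nrow(x$findings)))
      cat(sprintf("  [%s] %s: %s\n", x$findings$severity[i],
                  x$findings$code[i], x$findings$message[i]))
  }
  invisible(x)
}
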