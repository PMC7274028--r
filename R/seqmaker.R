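# Sample-specific consensus sequences: substitute one sample's variants
# into the reference slice for a region.
#
# Variants are applied in descending reference position so earlier edits
# never shift the coordinates of later ones. Missing calls silently keep
# the reference (the ledger makes this auditable: a consensus built from
# low-coverage data may not reflect the real sequence).

#' Build a sample-specific consensus sequence
#'
#' For one sample: homozygous-ALT SNPs and indels are substituted;
#' heterozygous SNPs become IUPAC ambiguity codes under the default
#' `het_policy = "iupac"` (`"alt"` substitutes the ALT, `"ref"` keeps the
#' reference); heterozygous indels keep the reference and are logged as
#' skipped; missing calls keep the reference and are logged. Variants
#' whose REF span crosses the region boundary are skipped, and when two
#' applied spans would overlap the rightmost (applied first) wins.
#'
#' @param region a `region_query`
#' @param reference_fetch reference lookup closure
#' @param sample_matrix a `genotype_matrix` restricted to exactly one sample
#' @param het_policy `"iupac"` (default), `"alt"` or `"ref"`
#' @return a `consensus_result`: `sequence`, `coordMap` (data.frame of
#'   `refPos` -> `consPos` anchors at every variant boundary), `applied`
#'   and `skipped` ledgers, `region`, `sample`, `het_policy`
#' @export
make_consensus <- function(region, reference_fetch, sample_matrix,
                           het_policy = c("iupac", "alt", "ref")) {
  het_policy <- match.arg(het_policy)
  if (length(sample_matrix$samples) != 1L)
    ss_stop("parameter", "consensus requires records restricted to exactly one sample")
  seq <- reference_fetch(region$chrom, region$start, region$end)
  applied <- data.frame(pos = integer(0), ref = character(0), alt = character(0),
                        zygosity = character(0), action = character(0),
                        stringsAsFactors = FALSE)
  skipped <- data.frame(pos = integer(0), ref = character(0), alt = character(0),
                        reason = character(0), stringsAsFactors = FALSE)
  add_applied <- function(pos, ref, alt, zyg, action)
    applied[nrow(applied) + 1L, ] <<- list(pos, ref, alt, zyg, action)
  add_skipped <- function(pos, ref, alt, reason)
    skipped[nrow(skipped) + 1L, ] <<- list(pos, ref, alt, reason)

  ord <- order(sample_matrix$sites$pos, decreasing = TRUE)
  applied_left <- Inf  # leftmost ref position already covered by an applied edit
  for (i in ord) {
    pos <- sample_matrix$sites$pos[[i]]
    ref <- sample_matrix$sites$ref[[i]]
    klass <- sample_matrix$klass[i, 1L]
    a <- sort(c(sample_matrix$a1[i, 1L], sample_matrix$a2[i, 1L]))
    span_end <- pos + nchar(ref) - 1L
    if (pos < region$start || span_end > region$end || pos > region$end) {
      if (klass %in% c("HET", "ALT_HOM"))
        add_skipped(pos, ref, NA_character_, "boundary")
      next
    }
    if (klass == "MISSING") {
      add_skipped(pos, ref, NA_character_, "missing")
      next
    }
    if (klass == "REF_HOM") next
    alts <- sample_matrix$alts[[i]]
    if (span_end >= applied_left) {
      add_skipped(pos, ref, NA_character_, "overlap_conflict")
      next
    }
    off <- pos - region$start + 1L
    if (klass == "ALT_HOM") {
      alt <- alts[[a[[2L]]]]
      if (grepl("[^ACGTN]", alt)) {
        add_skipped(pos, ref, alt, "symbolic_alt")
        next
      }
      seq <- paste0(substr(seq, 1L, off - 1L), alt,
                    substr(seq, off + nchar(ref), nchar(seq)))
      add_applied(pos, ref, alt, "hom", "substitute")
      applied_left <- pos
    } else {  # HET
      allele_seq <- function(k) if (k == 0L) ref else alts[[k]]
      b1 <- allele_seq(a[[1L]]); b2 <- allele_seq(a[[2L]])
      is_snp <- nchar(ref) == 1L && nchar(b1) == 1L && nchar(b2) == 1L
      if (het_policy == "ref") {
        add_skipped(pos, ref, b2, "het_policy_ref")
      } else if (!is_snp) {
        add_skipped(pos, ref, b2, "het_indel")
      } else if (het_policy == "iupac") {
        code <- iupac_code(c(b1, b2))
        if (is.na(code)) {
          add_skipped(pos, ref, b2, "ambiguous_alleles")
        } else {
          substr(seq, off, off) <- code
          add_applied(pos, ref, code, "het", "iupac")
          applied_left <- pos
        }
      } else {  # het_policy == "alt"
        alt <- if (a[[2L]] > 0L) allele_seq(a[[2L]]) else b1
        seq <- paste0(substr(seq, 1L, off - 1L), alt,
                      substr(seq, off + nchar(ref), nchar(seq)))
        add_applied(pos, ref, alt, "het", "substitute")
        applied_left <- pos
      }
    }
  }
  applied <- applied[order(applied$pos), , drop = FALSE]
  rownames(applied) <- NULL
  skipped <- skipped[order(skipped$pos), , drop = FALSE]
  rownames(skipped) <- NULL
  # coordinate anchors at every applied-variant boundary
  coordMap <- data.frame(refPos = region$start, consPos = 1L)
  offset <- 0L
  for (i in seq_len(nrow(applied))) {
    p <- applied$pos[[i]]
    rl <- nchar(applied$ref[[i]]); al <- nchar(applied$alt[[i]])
    coordMap[nrow(coordMap) + 1L, ] <- list(p, p - region$start + 1L + offset)
    offset <- offset + (al - rl)
    coordMap[nrow(coordMap) + 1L, ] <- list(p + rl, p + rl - region$start + 1L + offset)
  }
  coordMap[nrow(coordMap) + 1L, ] <- list(region$end + 1L,
                                          region$end + 1L - region$start + 1L + offset)
  coordMap <- unique(coordMap)
  rownames(coordMap) <- NULL
  structure(list(sequence = seq, coordMap = coordMap, applied = applied,
                 skipped = skipped, region = format_region(region),
                 sample = sample_matrix$samples[[1L]], het_policy = het_policy),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("<consensus_result> %s %s: %d bp, %d applied, %d skipped\n",
              x$sample, x$region, nchar(x$sequence), nrow(x$applied), nrow(x$skipped)))
  invisible(x)
}

#' Raw reference sequence for a region
#'
#' The `#RAW` query token resolves to this: the unmodified reference
#' slice.
#' @param region a `region_query`
#' @param reference_fetch reference lookup closure
#' @return character scalar
#' @export
raw_sequence <- function(region, reference_fetch) {
  reference_fetch(region$chrom, region$start, region$end)
}

#' Write consensus results as FASTA
#'
#' One record per result; headers carry the display label, the query
#' region verbatim, the het policy and (unless `stamp = FALSE`) an
#' ISO-8601 time stamp. Sequences wrap at 60 columns.
#'
#' @param results list of `consensus_result` (or a single one); raw
#'   sequences can be included as `list(sequence=, sample=, region=)`
#' @param path output path
#' @param labels optional named map accession -> display label
#' @param stamp append a time stamp to each header
#' @return the path, invisibly
#' @export
write_consensus_fasta <- function(results, path, labels = NULL, stamp = TRUE) {
  if (inherits(results, "consensus_result")) results <- list(results)
  if (!length(results)) ss_stop("parameter", "no sequences to write")
  out <- character(0)
  for (r in results) {
    lab <- r$sample
    if (!is.null(labels) && lab %in% names(labels)) lab <- labels[[lab]]
    hdr <- sprintf(">%s %s het=%s", lab, r$region, r$het_policy %||% "none")
    if (stamp) hdr <- paste0(hdr, " timestamp=", iso_stamp())
    out <- c(out, hdr, wrap_seq(r$sequence))
  }
  writeLines(out, path)
  invisible(path)
}
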