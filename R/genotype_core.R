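# The in-memory genotype matrix and the site filters applied to it.
#
# Every analysis runs off this one intermediate table: sites in rows
# (strictly increasing position within a chromosome), selected samples in
# columns (selection order), cells holding the four-way genotype classes
# plus allele indices, and optional DP/GQ/ANN payloads carried through.

#' Build the genotype matrix for a selection
#'
#' Columns are ordered exactly as `selection$members` (accession names);
#' the mapping to VCF columns goes through the catalog's vcfIDs. Sites with
#' all-missing calls are retained — nothing is dropped before an explicit
#' filter.
#'
#' @param records a [read_variants()] result covering the selection's vcfIDs
#' @param selection a [parse_sample_expression()] result (or character
#'   vector of accession names)
#' @param catalog the sample catalog
#' @return a `genotype_matrix`
#' @export
build_matrix <- function(records, selection, catalog) {
  members <- if (inherits(selection, "sample_selection")) selection$members else selection
  vcf_ids <- catalog_vcf_ids(catalog, members)
  missing_cols <- setdiff(vcf_ids, records$vcf_ids)
  if (length(missing_cols))
    ss_stop("unknown-sample", sprintf("records lack sample column(s): %s",
                                      paste(missing_cols, collapse = ", ")))
  take <- function(m) if (is.null(m)) NULL else {
    out <- m[, vcf_ids, drop = FALSE]; colnames(out) <- members; out
  }
  n <- length(records$pos)
  structure(list(
    sites = data.frame(chrom = records$chrom, pos = records$pos,
                       ref = records$ref,
                       alt = vapply(records$alts, paste, character(1), collapse = ","),
                       stringsAsFactors = FALSE),
    alts = records$alts,
    ann = records$ann %||% vector("list", n),
    samples = members, vcf_ids = vcf_ids,
    gt = take(records$gt), a1 = take(records$a1), a2 = take(records$a2),
    phased = take(records$phased), klass = take(records$klass),
    dp = take(records$dp), gq = take(records$gq)
  ), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d site(s) x %d sample(s)\n",
              nrow(x$sites), length(x$samples)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) c(nrow(x$sites), length(x$samples))

#' Subset a genotype matrix to a logical/integer site index
#' @param matrix a `genotype_matrix`
#' @param idx logical mask or integer indices over sites
#' @export
subset_sites <- function(matrix, idx) {
  sub <- function(m) if (is.null(m)) NULL else m[idx, , drop = FALSE]
  structure(list(
    sites = matrix$sites[idx, , drop = FALSE],
    alts = matrix$alts[idx], ann = matrix$ann[idx],
    samples = matrix$samples, vcf_ids = matrix$vcf_ids,
    gt = sub(matrix$gt), a1 = sub(matrix$a1), a2 = sub(matrix$a2),
    phased = sub(matrix$phased), klass = sub(matrix$klass),
    dp = sub(matrix$dp), gq = sub(matrix$gq)
  ), class = "genotype_matrix")
}

#' Per-site allele-frequency and missingness statistics
#'
#' Allele counting is diploid: every non-missing call contributes two
#' alleles; missing calls are excluded from the denominator. `altFreq` is
#' the frequency of non-REF alleles; `maf` is one minus the frequency of
#' the most common allele (min(p, 1-p) when biallelic) over non-missing
#' alleles; a fully missing site gets `maf = 0` and `altFreq = NA`.
#'
#' @param matrix a `genotype_matrix`
#' @return data.frame with `altFreq`, `maf`, `missingRate` per site
#' @export
site_stats <- function(matrix) {
  n <- nrow(matrix$sites)
  if (!length(matrix$samples)) ss_stop("parameter", "empty sample set")
  out <- data.frame(altFreq = rep(NA_real_, n), maf = rep(0, n),
                    missingRate = rep(0, n))
  for (i in seq_len(n)) {
    alleles <- c(matrix$a1[i, ], matrix$a2[i, ])
    miss <- is.na(matrix$a1[i, ]) | is.na(matrix$a2[i, ])
    out$missingRate[i] <- mean(miss)
    alleles <- alleles[!is.na(alleles)]
    if (length(alleles)) {
      out$altFreq[i] <- mean(alleles != 0L)
      out$maf[i] <- 1 - max(tabulate(alleles + 1L, nbins = max(alleles) + 1L)) / length(alleles)
    }
  }
  out
}

#' Filter sites on minor allele frequency and missingness
#'
#' Keeps sites with `maf >= maf_min` and `missingRate <= missing_max`,
#' preserving order. `maf_min = 0, missing_max = 1` is the identity (in
#' particular, monomorphic sites are kept at `maf_min = 0`).
#'
#' @param matrix a `genotype_matrix`
#' @param maf_min minimum minor allele frequency, in `[0, 0.5]`
#' @param missing_max maximum fraction of missing calls, in `[0, 1]`
#' @export
filter_sites <- function(matrix, maf_min = 0, missing_max = 1) {
  if (maf_min < 0 || maf_min > 0.5) ss_stop("parameter", "maf_min must be in [0, 0.5]")
  if (missing_max < 0 || missing_max > 1) ss_stop("parameter", "missing_max must be in [0, 1]")
  st <- site_stats(matrix)
  subset_sites(matrix, st$maf >= maf_min & st$missingRate <= missing_max)
}

#' Genotype-category site mask over a focal sample set
#'
#' The three export categories: `must_vary` keeps sites where every focal
#' sample differs from the reference (HET or ALT_HOM); `must_match_ref`
#' keeps sites where every focal sample is REF_HOM; `unfiltered` keeps all.
#' A MISSING focal call fails both constrained categories. `mode = "any"`
#' relaxes the conjunction to an existential check.
#'
#' @param matrix a `genotype_matrix`
#' @param category one of `"unfiltered"`, `"must_vary"`, `"must_match_ref"`
#' @param focal_accessions subset of `matrix$samples` the category applies to
#' @param mode `"all"` (default) or `"any"`
#' @return logical site mask
#' @export
sample_category_filter <- function(matrix,
                                   category = c("unfiltered", "must_vary", "must_match_ref"),
                                   focal_accessions = matrix$samples,
                                   mode = c("all", "any")) {
  category <- tryCatch(match.arg(category),
                       error = function(e) ss_stop("parameter",
                         sprintf("unknown category '%s'", category[[1L]])))
  mode <- match.arg(mode)
  if (category == "unfiltered") return(rep(TRUE, nrow(matrix$sites)))
  bad <- setdiff(focal_accessions, matrix$samples)
  if (length(bad))
    ss_stop("unknown-name", sprintf("focal accession(s) not in matrix: %s",
                                    paste(bad, collapse = ", ")))
  k <- matrix$klass[, focal_accessions, drop = FALSE]
  hit <- if (category == "must_vary") k == "HET" | k == "ALT_HOM" else k == "REF_HOM"
  if (mode == "all") rowSums(hit) == ncol(hit) else rowSums(hit) > 0L
}

# map allele index to its base string for one site ("." for missing)
allele_string <- function(ref, alts, a) {
  ifelse(is.na(a), ".", ifelse(a == 0L, ref, alts[pmax(a, 1L)]))
}

#' Export the genotype matrix as a CSV-serializable table
#'
#' One row per site with columns `chrom,pos,ref,alt`, optional `ann`, then
#' one genotype column per sample headed by its display label. With
#' `genotype_form = "raw"` cells hold VCF-style strings (`0/0`, `0/1`,
#' `1/1`, `./.`); with `"bases"` the allele indices are substituted by
#' their bases (`A/T`). DP/GQ payloads become parallel `<label>.DP` /
#' `<label>.GQ` columns; requesting an absent payload warns and emits
#' blanks.
#'
#' @param matrix a `genotype_matrix`
#' @param include_depth,include_quality,include_ann include optional payloads
#' @param genotype_form `"raw"` or `"bases"`
#' @param catalog optional catalog for display labels (default: accessions)
#' @return data.frame ready for [utils::write.csv()]
#' @export
export_table <- function(matrix, include_depth = FALSE, include_quality = FALSE,
                         include_ann = FALSE, genotype_form = c("raw", "bases"),
                         catalog = NULL) {
  genotype_form <- match.arg(genotype_form)
  labels <- if (is.null(catalog)) setNames(matrix$samples, matrix$samples)
            else resolve_display(matrix$samples, catalog)
  if (include_depth && is.null(matrix$dp))
    ss_warn("payload-missing", "DP requested but absent; emitting blanks")
  if (include_quality && is.null(matrix$gq))
    ss_warn("payload-missing", "GQ requested but absent; emitting blanks")
  out <- matrix$sites
  if (include_ann) {
    out$ann <- vapply(matrix$ann, function(a)
      paste(a %||% character(0), collapse = ";"), character(1))
  }
  n <- nrow(out)
  for (j in seq_along(matrix$samples)) {
    acc <- matrix$samples[[j]]
    if (genotype_form == "raw") {
      sep <- ifelse(matrix$phased[, j], "|", "/")
      a1 <- ifelse(is.na(matrix$a1[, j]), ".", matrix$a1[, j])
      a2 <- ifelse(is.na(matrix$a2[, j]), ".", matrix$a2[, j])
      cells <- paste0(a1, sep, a2)
    } else {
      cells <- vapply(seq_len(n), function(i) {
        paste(allele_string(matrix$sites$ref[i], matrix$alts[[i]],
                            c(matrix$a1[i, j], matrix$a2[i, j])),
              collapse = "/")
      }, character(1))
      if (!n) cells <- character(0)
    }
    out[[labels[[acc]]]] <- cells
    if (include_depth) {
      out[[paste0(labels[[acc]], ".DP")]] <-
        if (is.null(matrix$dp)) rep("", n) else matrix$dp[, j]
    }
    if (include_quality) {
      out[[paste0(labels[[acc]], ".GQ")]] <-
        if (is.null(matrix$gq)) rep("", n) else matrix$gq[, j]
    }
  }
  rownames(out) <- NULL
  out
}

#' Four-way genotype class of a VCF-style genotype string
#'
#' Classifies `"0/0"`-style strings (either separator) into
#' REF_HOM / HET / ALT_HOM / MISSING; half-calls count as MISSING.
#' @param gt character vector of genotype strings
#' @return character vector of classes
#' @export
genotype_class <- function(gt) {
  p <- parse_gt_strings(gt)
  classify_alleles(p$a1, p$a2)
}
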