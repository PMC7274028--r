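# shared internal helpers: classed conditions, IUPAC table, small utilities

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signal a classed snpscope error
#'
#' All user-facing failures carry condition class `snpscope_<code>` (plus
#' `snpscope_error`) so callers and tests can match on the failure kind
#' rather than on message text.
#'
#' @param code short kebab-case failure code, e.g. `"unknown-sample"`
#' @param msg human-readable message
#' @noRd
ss_stop <- function(code, msg, call. = FALSE) {
  cond <- structure(
    class = c(paste0("snpscope_", code), "snpscope_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  )
  stop(cond)
}

ss_warn <- function(code, msg) {
  cond <- structure(
    class = c(paste0("snpscope_", code), "snpscope_warning", "warning", "condition"),
    list(message = msg, call = NULL)
  )
  warning(cond)
}

# Reserved query tokens that can never be user-supplied names.
RESERVED_IDS <- c("#ALL", "#RAW", "ALL", "RAW")

is_reserved_name <- function(x) x %in% c("#ALL", "#RAW")

#' IUPAC ambiguity code for a set of bases
#' @param bases character vector of A/C/G/T (length >= 1)
#' @return single ambiguity letter, or NA if any base is invalid
#' @noRd
iupac_code <- function(bases) {
  bases <- sort(unique(toupper(bases)))
  if (!all(bases %in% c("A", "C", "G", "T"))) return(NA_character_)
  key <- paste(bases, collapse = "")
  map <- c(A = "A", C = "C", G = "G", T = "T",
           AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
           ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N")
  unname(map[key])
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

comp_base <- function(b) {
  unname(c(A = "T", C = "G", G = "C", T = "A", N = "N")[toupper(b)])
}

#' ISO-8601 time stamp used in exported figures and FASTA headers
#' @noRd
iso_stamp <- function() format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")

# wrap a sequence string at `width` columns
wrap_seq <- function(seq, width = 60L) {
  n <- nchar(seq)
  if (n == 0L) return(character(0))
  starts <- seq.int(1L, n, by = width)
  substring(seq, starts, pmin(starts + width - 1L, n))
}

# format a region as the canonical "chrom:start-end" string
format_region <- function(region) {
  sprintf("%s:%d-%d", region$chrom, region$start, region$end)
}
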