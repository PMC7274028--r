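# Query grammar: region/gene specifications and sample expressions.

#' Parse a region specification
#'
#' Accepts `"chrom:start-end"`, `"chrom:pos"`, or a gene id known to
#' `gene_index`. Gene ids resolve to the gene span widened by `flank` bp on
#' both sides (clipped at 1); the flank never applies to explicit
#' coordinates. The last colon splits contig from coordinates, so contig
#' names may contain letters, digits, underscore and dot. Thousands
#' separators are rejected.
#'
#' @param text the query string
#' @param gene_index optional gene index from [parse_gff3()]
#' @param flank non-negative bp added on each side of a gene span
#' @return a `region_query` list: `chrom`, `start`, `end`, `origin`
#'   (`"explicit"` or `"gene"`), `geneId`, `flank`
#' @export
parse_region_spec <- function(text, gene_index = NULL, flank = 0L) {
  stopifnot(length(text) == 1L)
  text <- trimws(text)
  flank <- as.integer(flank)
  if (is.na(flank) || flank < 0L) ss_stop("parameter", "flank must be >= 0")
  m <- regmatches(text, regexec("^(.+):([0-9]+)(-([0-9]+))?$", text))[[1L]]
  if (length(m)) {
    chrom <- m[[2L]]
    if (!grepl("^[A-Za-z0-9_.]+$", chrom))
      ss_stop("malformed-region", sprintf("invalid contig name '%s'", chrom))
    start <- as.integer(m[[3L]])
    end <- if (nzchar(m[[5L]])) as.integer(m[[5L]]) else start
    if (is.na(start) || is.na(end))
      ss_stop("malformed-region", sprintf("coordinates out of range in '%s'", text))
    if (start > end)
      ss_stop("malformed-region", sprintf("start > end in '%s'", text))
    if (start < 1L)
      ss_stop("malformed-region", "positions are 1-based; start must be >= 1")
    return(structure(list(chrom = chrom, start = start, end = end,
                          origin = "explicit", geneId = NULL, flank = 0L),
                     class = "region_query"))
  }
  if (!is.null(gene_index) && text %in% gene_index$geneId) {
    g <- gene_index[gene_index$geneId == text, ][1L, ]
    return(structure(list(chrom = g$chrom,
                          start = max(1L, as.integer(g$start) - flank),
                          end = as.integer(g$end) + flank,
                          origin = "gene", geneId = text, flank = flank),
                     class = "region_query"))
  }
  ss_stop("unresolvable-query",
          sprintf("'%s' is neither a coordinate region nor a known gene id", text))
}

#' @export
print.region_query <- function(x, ...) {
  cat(sprintf("<region_query> %s (%s%s)\n", format_region(x),
              x$origin, if (x$origin == "gene") paste0(": ", x$geneId, " +/-", x$flank) else ""))
  invisible(x)
}

#' Parse a sample expression
#'
#' The expression is a comma-separated mix of accession names, `#groupId`
#' references and inline group definitions `Name{a, b, c}`. `#ALL` expands
#' to every catalog accession in catalog order. Duplicates are removed,
#' keeping the first occurrence. Inline definitions are expanded into the
#' member list and also returned in `definedGroups`; an inline name that
#' collides with a catalog group id (or a reserved id) is an error.
#'
#' @param text the sample expression
#' @param catalog a [read_sample_catalog()] result
#' @return a `sample_selection`: `members` (ordered accession names) and
#'   `definedGroups` (named list)
#' @export
parse_sample_expression <- function(text, catalog) {
  stopifnot(length(text) == 1L)
  # split on commas that are not inside braces
  chars <- strsplit(text, "")[[1L]]
  depth <- 0L; tokens <- character(0); buf <- character(0)
  for (ch in chars) {
    if (ch == "{") depth <- depth + 1L
    if (ch == "}") depth <- depth - 1L
    if (depth < 0L) ss_stop("parse", "unbalanced '}' in sample expression")
    if (ch == "," && depth == 0L) {
      tokens <- c(tokens, paste(buf, collapse = "")); buf <- character(0)
    } else buf <- c(buf, ch)
  }
  if (depth != 0L) ss_stop("parse", "unbalanced '{' in sample expression")
  tokens <- trimws(c(tokens, paste(buf, collapse = "")))
  tokens <- tokens[nzchar(tokens)]
  if (!length(tokens)) ss_stop("parse", "empty sample expression")

  accs <- catalog_accessions(catalog)
  members <- character(0)
  defined <- list()
  for (tok in tokens) {
    if (tok == "#ALL") {
      members <- c(members, accs)
    } else if (startsWith(tok, "#")) {
      gid <- substring(tok, 2L)
      if (!gid %in% names(catalog$groups))
        ss_stop("unknown-name", sprintf("unknown group '%s'", tok))
      members <- c(members, catalog$groups[[gid]])
    } else if (grepl("\\{", tok)) {
      m <- regmatches(tok, regexec("^([^{}]+)\\{([^{}]*)\\}$", tok))[[1L]]
      if (!length(m)) ss_stop("parse", sprintf("malformed inline group '%s'", tok))
      gid <- trimws(m[[2L]])
      if (is_reserved_name(gid) || is_reserved_name(paste0("#", gid)))
        ss_stop("reserved-name", sprintf("'%s' is reserved", gid))
      if (gid %in% names(catalog$groups) || gid %in% names(defined))
        ss_stop("name-collision", sprintf("group '%s' already defined", gid))
      inner <- trimws(strsplit(m[[3L]], ",", fixed = TRUE)[[1L]])
      inner <- inner[nzchar(inner)]
      unknown <- setdiff(inner, accs)
      if (length(unknown))
        ss_stop("unknown-name", sprintf("unknown accession(s) in %s{}: %s",
                                        gid, paste(unknown, collapse = ", ")))
      defined[[gid]] <- inner
      members <- c(members, inner)
    } else {
      if (!tok %in% accs)
        ss_stop("unknown-name", sprintf("unknown accession '%s'", tok))
      members <- c(members, tok)
    }
  }
  structure(list(members = members[!duplicated(members)], definedGroups = defined),
            class = "sample_selection")
}

#' @export
print.sample_selection <- function(x, ...) {
  cat(sprintf("<sample_selection> %d sample(s)%s\n", length(x$members),
              if (length(x$definedGroups))
                paste0(", inline groups: ", paste(names(x$definedGroups), collapse = ", "))
              else ""))
  invisible(x)
}

#' Map accession names to display labels
#'
#' Output artifacts (tables, tree tips, network nodes) are labelled with
#' display names; an empty display name falls back to the accession name,
#' and duplicated display names are disambiguated by suffixing `" (2)"`,
#' `" (3)"`, ... in selection order so labels stay unique.
#'
#' @param selection a `sample_selection` or a character vector of accessions
#' @param catalog a [read_sample_catalog()] result
#' @return named character vector: accessionName -> display label
#' @export
resolve_display <- function(selection, catalog) {
  members <- if (inherits(selection, "sample_selection")) selection$members else selection
  idx <- match(members, catalog$entries$accessionName)
  if (anyNA(idx))
    ss_stop("unknown-name", sprintf("unknown accession(s): %s",
                                    paste(members[is.na(idx)], collapse = ", ")))
  disp <- catalog$entries$displayName[idx]
  disp[!nzchar(trimws(disp))] <- members[!nzchar(trimws(disp))]
  # disambiguate duplicates
  for (lab in unique(disp[duplicated(disp)])) {
    hits <- which(disp == lab)
    disp[hits[-1L]] <- sprintf("%s (%d)", lab, seq_along(hits[-1L]) + 1L)
  }
  setNames(disp, members)
}

#' Resolve the effective grouping of a selection
#'
#' Groups used by analyses: inline definitions from the expression first,
#' then any catalog groups explicitly referenced, restricted to selected
#' members; falls back to a single `#ALL` group covering the selection.
#' @param selection a `sample_selection`
#' @param catalog the sample catalog
#' @param group_ids optional character vector of catalog group ids to use
#' @return named list groupId -> accession members (non-empty)
#' @export
selection_groups <- function(selection, catalog, group_ids = NULL) {
  groups <- selection$definedGroups
  if (!is.null(group_ids)) {
    for (gid in group_ids) {
      g <- sub("^#", "", gid)
      if (!g %in% names(catalog$groups))
        ss_stop("unknown-name", sprintf("unknown group '%s'", gid))
      groups[[g]] <- catalog$groups[[g]]
    }
  }
  groups <- lapply(groups, intersect, selection$members)
  groups <- groups[lengths(groups) > 0L]
  if (!length(groups)) groups <- list(`#ALL` = selection$members)
  groups
}
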