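# Haplotype collapsing, the minimum-spanning-tree haplotype network, and
# within-group sample ordering for the genotype heatmap.
#
# Data are unphased, so a "haplotype" here is an equivalence class of
# samples with identical genotype signatures across the kept sites: HET is
# its own state rather than being split into two phases.

# canonical per-cell genotype state: sorted allele pair, "./." for missing
genotype_states <- function(matrix) {
  lo <- pmin(matrix$a1, matrix$a2)
  hi <- pmax(matrix$a1, matrix$a2)
  s <- matrix(paste0(lo, "/", hi), nrow(matrix$sites), length(matrix$samples))
  s[is.na(lo)] <- "./."
  dimnames(s) <- list(NULL, matrix$samples)
  s
}

#' Collapse samples into haplotypes
#'
#' Samples sharing an identical per-site genotype signature form one
#' haplotype. Under the default `exclude_samples` policy any sample with a
#' missing call at a kept site is set aside (wildcard matching could merge
#' distinct haplotypes ambiguously); `missing_as_state` instead treats
#' `./.` as a state of its own. Haplotype ids `H1, H2, ...` are assigned by
#' descending carrier count, ties by first appearance in column order.
#'
#' @param matrix a `genotype_matrix` with at least one site
#' @param groups named list groupId -> accession members (default: one
#'   `#ALL` group over all samples); used for the per-node pie composition
#' @param missing_policy `"exclude_samples"` or `"missing_as_state"`
#' @return list with `haplotypes` (each: `hapId`, `signature`, `members`,
#'   `groupCounts`) and `excluded` (data.frame `accessionName`, `reason`)
#' @export
collapse_haplotypes <- function(matrix, groups = NULL,
                                missing_policy = c("exclude_samples", "missing_as_state")) {
  missing_policy <- match.arg(missing_policy)
  if (nrow(matrix$sites) == 0L)
    ss_stop("empty-region", "no sites left in region after filtering")
  if (is.null(groups)) groups <- list(`#ALL` = matrix$samples)
  states <- genotype_states(matrix)
  excluded <- data.frame(accessionName = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  keep <- matrix$samples
  if (missing_policy == "exclude_samples") {
    has_missing <- colSums(states == "./.") > 0L
    if (any(has_missing)) {
      excluded <- data.frame(accessionName = matrix$samples[has_missing],
                             reason = "missing_call", stringsAsFactors = FALSE)
      keep <- matrix$samples[!has_missing]
    }
  }
  if (!length(keep))
    ss_stop("empty-region", "all samples excluded for missingness")
  sigs <- vapply(keep, function(s) paste(states[, s], collapse = "|"), character(1))
  first_seen <- match(unique(sigs), sigs)
  classes <- unique(sigs)
  members <- lapply(classes, function(sg) keep[sigs == sg])
  ord <- order(-lengths(members), first_seen)
  haplotypes <- lapply(seq_along(ord), function(r) {
    i <- ord[[r]]
    mem <- members[[i]]
    gc <- vapply(groups, function(g) length(intersect(mem, g)), integer(1))
    list(hapId = paste0("H", r),
         signature = strsplit(classes[[i]], "|", fixed = TRUE)[[1L]],
         members = mem, groupCounts = gc)
  })
  list(haplotypes = haplotypes, excluded = excluded)
}

#' Hamming distance between two haplotype signatures
#'
#' Counts positions whose genotype states differ; signatures must have
#' equal length.
#' @param hapA,hapB haplotypes from [collapse_haplotypes()] (or bare
#'   signature vectors)
#' @return non-negative integer
#' @export
hamming <- function(hapA, hapB) {
  a <- if (is.list(hapA)) hapA$signature else hapA
  b <- if (is.list(hapB)) hapB$signature else hapB
  if (length(a) != length(b))
    ss_stop("invariant", "haplotype signatures differ in length")
  sum(a != b)
}

#' Build the minimum-spanning-tree haplotype network
#'
#' Kruskal's algorithm over the complete pairwise Hamming graph, with edges
#' sorted by (weight, lexicographic hapId pair) so ties resolve
#' deterministically. Node sizes are carrier counts; `pies` give the group
#' composition fractions used for pie-chart nodes.
#'
#' @param haplotypes result of [collapse_haplotypes()] (the full list, or
#'   just its `haplotypes` element)
#' @return a `haplotype_network`: `nodes` (id, size, members, pies),
#'   `edges` data.frame (`a`, `b`, `w`), `excluded`
#' @export
build_network <- function(haplotypes) {
  excluded <- data.frame(accessionName = character(0), reason = character(0))
  haps <- haplotypes
  if (!is.null(haplotypes$haplotypes)) {
    haps <- haplotypes$haplotypes
    excluded <- haplotypes$excluded
  }
  if (!length(haps)) ss_stop("parameter", "need at least one haplotype")
  ids <- vapply(haps, `[[`, character(1), "hapId")
  n <- length(haps)
  edges <- data.frame(a = character(0), b = character(0), w = integer(0),
                      stringsAsFactors = FALSE)
  if (n > 1L) {
    pairs <- utils::combn(n, 2L)
    cand <- data.frame(
      a = ids[pairs[1L, ]], b = ids[pairs[2L, ]],
      w = apply(pairs, 2L, function(p) hamming(haps[[p[1L]]], haps[[p[2L]]])),
      stringsAsFactors = FALSE)
    # deterministic Kruskal: weight, then lexicographic id pair
    lo <- pmin(cand$a, cand$b); hi <- pmax(cand$a, cand$b)
    cand <- cand[order(cand$w, lo, hi), , drop = FALSE]
    parent <- seq_len(n); names(parent) <- ids
    find <- function(x) { while (parent[[x]] != match(x, ids)) x <- ids[[parent[[x]]]]; x }
    for (i in seq_len(nrow(cand))) {
      ra <- find(cand$a[[i]]); rb <- find(cand$b[[i]])
      if (ra != rb) {
        parent[[ra]] <- match(rb, ids)
        edges <- rbind(edges, cand[i, , drop = FALSE])
        if (nrow(edges) == n - 1L) break
      }
    }
  }
  rownames(edges) <- NULL
  nodes <- lapply(haps, function(h) {
    size <- length(h$members)
    list(id = h$hapId, size = size, members = h$members,
         pies = if (size) h$groupCounts / size else h$groupCounts)
  })
  structure(list(nodes = nodes, edges = edges, excluded = excluded),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat(sprintf("<haplotype_network> %d node(s), %d edge(s), %d excluded\n",
              length(x$nodes), nrow(x$edges), nrow(x$excluded)))
  invisible(x)
}

#' Serialize a haplotype network to JSON
#' @param network a `haplotype_network`
#' @param path optional output path; when NULL the JSON string is returned
#' @export
write_network_json <- function(network, path = NULL) {
  obj <- list(
    nodes = lapply(network$nodes, function(nd)
      list(id = nd$id, size = nd$size, members = nd$members,
           pies = as.list(nd$pies))),
    edges = if (nrow(network$edges))
      lapply(seq_len(nrow(network$edges)), function(i)
        list(a = network$edges$a[[i]], b = network$edges$b[[i]],
             w = network$edges$w[[i]]))
    else list(),
    excluded = if (nrow(network$excluded))
      lapply(seq_len(nrow(network$excluded)), function(i)
        list(accessionName = network$excluded$accessionName[[i]],
             reason = network$excluded$reason[[i]]))
    else list()
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

# pairwise-deletion normalized Hamming distance between sample columns
sample_hamming_dist <- function(states) {
  n <- ncol(states)
  d <- matrix(0, n, n, dimnames = list(colnames(states), colnames(states)))
  if (n < 2L) return(d)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    cmp <- states[, i] != "./." & states[, j] != "./."
    d[i, j] <- d[j, i] <- if (any(cmp))
      sum(states[cmp, i] != states[cmp, j]) / sum(cmp) else 1
  }
  d
}

#' Order samples for the genotype heatmap
#'
#' Within each group, samples are ordered by the leaf order of
#' average-linkage hierarchical clustering on normalized Hamming distance
#' (pairwise deletion over comparable sites); groups keep their given
#' order. The grid holds the four genotype classes.
#'
#' @param matrix a `genotype_matrix`
#' @param groups named list partitioning `matrix$samples` (default: one
#'   group of all samples)
#' @param orientation `"sites_by_rows"` (default) or `"transposed"`
#' @return list: `sample_order`, `site_order`, `grid` (class matrix in the
#'   requested orientation), `group_of` (named vector)
#' @export
heatmap_layout <- function(matrix, groups = NULL,
                           orientation = c("sites_by_rows", "transposed")) {
  orientation <- match.arg(orientation)
  if (is.null(groups)) groups <- list(`#ALL` = matrix$samples)
  states <- genotype_states(matrix)
  sample_order <- character(0)
  for (g in names(groups)) {
    mem <- intersect(groups[[g]], matrix$samples)
    if (length(mem) <= 2L) {
      sample_order <- c(sample_order, mem)
      next
    }
    d <- sample_hamming_dist(states[, mem, drop = FALSE])
    hc <- hclust(as.dist(d), method = "average")
    sample_order <- c(sample_order, mem[hc$order])
  }
  group_of <- setNames(rep(names(groups), vapply(groups, function(g)
    length(intersect(g, matrix$samples)), integer(1))), NULL)
  names(group_of) <- unlist(lapply(groups, intersect, matrix$samples), use.names = FALSE)
  grid <- matrix$klass[, sample_order, drop = FALSE]
  rownames(grid) <- paste0(matrix$sites$chrom, ":", matrix$sites$pos)
  if (orientation == "transposed") grid <- t(grid)
  list(sample_order = sample_order, site_order = seq_len(nrow(matrix$sites)),
       grid = grid, group_of = group_of)
}
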