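# Sample distance matrices, neighbour-joining and principal coordinates.
#
# Neighbour-joining is implemented here (classical Q-criterion
# agglomeration with an explicit lexicographic tie rule) rather than
# delegated, so tree construction is reproducible bit-for-bit; trees are
# returned as ape "phylo" objects so the ape toolbox (plot layouts,
# cophenetic distances, tree comparison) applies directly.

#' Identity-by-state distance matrix between samples
#'
#' Per comparable site (both calls non-missing) the distance is
#' `1 - shared_alleles/2` where `shared_alleles` is the multiset overlap of
#' the two diploid genotypes (`0/0` vs `0/0` -> 0, `0/0` vs `0/1` -> 0.5,
#' `0/0` vs `1/1` -> 1, `0/1` vs `0/1` -> 0). The pair distance is the mean
#' over comparable sites (pairwise deletion); a pair with no comparable
#' site gets distance 1 with a warning. `method = "pdist"` instead scores
#' any genotype-state difference as 1.
#'
#' @param matrix a `genotype_matrix` with >= 2 samples and >= 1 site
#' @param method `"ibs"` (default) or `"pdist"`
#' @param labels optional output labels (default: accession names)
#' @return symmetric numeric matrix with zero diagonal
#' @export
ibs_distance_matrix <- function(matrix, method = c("ibs", "pdist"), labels = NULL) {
  method <- match.arg(method)
  n <- length(matrix$samples)
  if (n < 2L) ss_stop("parameter", "need at least two samples for a distance matrix")
  if (nrow(matrix$sites) < 1L) ss_stop("parameter", "need at least one site")
  labels <- labels %||% matrix$samples
  a1 <- matrix$a1; a2 <- matrix$a2
  lo <- pmin(a1, a2); hi <- pmax(a1, a2)
  d <- base::matrix(0, n, n, dimnames = list(labels, labels))
  warned <- FALSE
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    cmp <- !is.na(lo[, i]) & !is.na(lo[, j])
    if (!any(cmp)) {
      if (!warned) { ss_warn("no-comparable-sites",
        "sample pair(s) with no comparable site: distance set to 1"); warned <- TRUE }
      d[i, j] <- d[j, i] <- 1
      next
    }
    if (method == "ibs") {
      # multiset overlap of two allele pairs = max over the two pairings
      s1 <- (a1[cmp, i] == a1[cmp, j]) + (a2[cmp, i] == a2[cmp, j])
      s2 <- (a1[cmp, i] == a2[cmp, j]) + (a2[cmp, i] == a1[cmp, j])
      d[i, j] <- d[j, i] <- mean(1 - pmax(s1, s2) / 2)
    } else {
      d[i, j] <- d[j, i] <- mean(lo[cmp, i] != lo[cmp, j] | hi[cmp, i] != hi[cmp, j])
    }
  }
  d
}

# assemble an ape phylo from an edge list with arbitrary node ids
# leaves: character ids present in `tip_labels` (in tip order)
as_phylo_edges <- function(edges, tip_labels, root_id) {
  n <- length(tip_labels)
  kids <- split(seq_len(nrow(edges)), edges$parent)
  new_id <- setNames(seq_len(n), tip_labels)
  next_internal <- n + 1L
  edge_mat <- base::matrix(0L, nrow(edges), 2L)
  edge_len <- numeric(nrow(edges))
  k <- 0L
  assign_id <- function(node) {
    if (node %in% tip_labels) return(new_id[[node]])
    id <- next_internal; next_internal <<- next_internal + 1L
    new_id[[node]] <<- id
    id
  }
  walk <- function(node) {
    for (e in kids[[node]] %||% integer(0)) {
      child <- edges$child[[e]]
      k <<- k + 1L; my_k <- k
      edge_mat[my_k, 1L] <<- new_id[[node]]
      edge_mat[my_k, 2L] <<- assign_id(child)
      edge_len[my_k] <<- edges$length[[e]]
      if (!child %in% tip_labels) walk(child)
    }
  }
  assign_id(root_id)
  walk(root_id)
  structure(list(edge = edge_mat, edge.length = edge_len,
                 tip.label = tip_labels, Nnode = next_internal - n - 1L),
            class = "phylo", order = "cladewise")
}

#' Neighbour-joining tree from a distance matrix
#'
#' Classical neighbour joining (Saitou & Nei Q-criterion) with a fixed tie
#' rule: among pairs minimizing Q, the pair whose smallest contained leaf
#' labels sort first lexicographically is merged, so the result is
#' deterministic and invariant to input row order. Negative branch-length
#' estimates are clamped to zero; the original values are kept in
#' `attr(tree, "raw_lengths")`. On an additive matrix the generating
#' topology and branch lengths are recovered exactly.
#'
#' @param D symmetric distance matrix with labelled dimnames, >= 3 taxa
#' @return an unrooted ape `phylo` object
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  n0 <- nrow(D)
  if (n0 < 3L) ss_stop("parameter", "neighbour joining needs at least 3 taxa")
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
    ss_stop("invariant", "distance matrix is not symmetric")
  labels <- rownames(D) %||% paste0("t", seq_len(n0))
  rownames(D) <- colnames(D) <- labels
  active <- labels              # working node ids
  reps <- setNames(labels, labels)  # lexicographically smallest leaf under each node
  edges <- data.frame(parent = character(0), child = character(0),
                      length = numeric(0), stringsAsFactors = FALSE)
  raw_lengths <- numeric(0)
  inode <- 0L
  add_edge <- function(parent, child, len) {
    raw_lengths <<- c(raw_lengths, len)
    edges[nrow(edges) + 1L, ] <<- list(parent, child, max(0, len))
  }
  while (length(active) > 3L) {
    m <- length(active)
    Dm <- D[active, active]
    r <- rowSums(Dm)
    Q <- (m - 2) * Dm - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    ties <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    ties <- ties[ties[, 1L] < ties[, 2L], , drop = FALSE]
    tie_lo <- pmin(reps[active[ties[, 1L]]], reps[active[ties[, 2L]]])
    tie_hi <- pmax(reps[active[ties[, 1L]]], reps[active[ties[, 2L]]])
    pick <- order(tie_lo, tie_hi)[[1L]]
    i <- active[[ties[pick, 1L]]]; j <- active[[ties[pick, 2L]]]
    inode <- inode + 1L
    u <- paste0(".nj", inode)
    li <- D[i, j] / 2 + (r[[i]] - r[[j]]) / (2 * (m - 2))
    lj <- D[i, j] - li
    add_edge(u, i, li); add_edge(u, j, lj)
    duk <- (D[i, active] + D[j, active] - D[i, j]) / 2
    D <- rbind(cbind(D, 0), 0)
    rownames(D)[nrow(D)] <- colnames(D)[ncol(D)] <- u
    D[u, active] <- duk; D[active, u] <- duk; D[u, u] <- 0
    reps[[u]] <- min(reps[[i]], reps[[j]])
    active <- c(setdiff(active, c(i, j)), u)
  }
  # join the last three nodes at the final internal vertex
  inode <- inode + 1L
  root <- paste0(".nj", inode)
  a <- active[[1L]]; b <- active[[2L]]; c3 <- active[[3L]]
  add_edge(root, a, (D[a, b] + D[a, c3] - D[b, c3]) / 2)
  add_edge(root, b, (D[a, b] + D[b, c3] - D[a, c3]) / 2)
  add_edge(root, c3, (D[a, c3] + D[b, c3] - D[a, b]) / 2)
  tree <- as_phylo_edges(edges, labels, root)
  attr(tree, "raw_lengths") <- raw_lengths
  tree
}

#' Classical multidimensional scaling (principal coordinates)
#'
#' Torgerson double centering of `-0.5 * D^2` followed by the top-`k`
#' eigenpairs, coordinates scaled by the square root of each (non-negative)
#' eigenvalue. Small negative eigenvalues — expected when genotype IBS
#' distances are not exactly Euclidean — trigger a warning and are
#' truncated at zero (the corresponding axes are all-zero). Axis signs are
#' fixed so the largest-magnitude coordinate on each axis is positive.
#'
#' @param D symmetric distance matrix (>= 2 points)
#' @param k number of output dimensions, `1 <= k < nrow(D)`
#' @return numeric matrix (points x k) with row labels
#' @export
classical_mds <- function(D, k = 2L) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (k < 1L || k >= n) ss_stop("parameter", "need 1 <= k < number of points")
  fit <- suppressWarnings(cmdscale(as.dist(D), k = k, eig = TRUE))
  if (any(fit$eig < -1e-8 * max(abs(fit$eig), 1)))
    ss_warn("negative-eigenvalues",
            "distance matrix is not Euclidean; negative eigenvalues truncated at 0")
  pts <- fit$points
  out <- base::matrix(0, n, k, dimnames = list(rownames(D) %||% paste0("p", seq_len(n)),
                                               paste0("axis", seq_len(k))))
  if (!is.null(pts) && ncol(pts)) out[, seq_len(ncol(pts))] <- pts
  for (ax in seq_len(k)) {
    v <- out[, ax]
    if (length(v) && any(v != 0) && v[[which.max(abs(v))]] < 0) out[, ax] <- -v
  }
  out
}

# quote a Newick label when it contains characters unsafe for bare tokens
newick_label <- function(lab) {
  if (grepl("[][ \t(),:;']", lab))
    paste0("'", gsub("'", "''", lab), "'")
  else lab
}

#' Serialize a tree to Newick
#'
#' Branch lengths are always written; labels containing spaces or Newick
#' metacharacters are single-quoted. The string round-trips through
#' standard parsers such as [ape::read.tree()].
#'
#' @param tree an ape `phylo` object
#' @param path optional file path; when given the string is also written
#' @param digits significant digits for branch lengths
#' @return the Newick string (invisibly when `path` is given)
#' @export
write_newick <- function(tree, path = NULL, digits = 10L) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  fmt_len <- function(x) sprintf("%.*g", digits, x)
  rec <- function(node) {
    if (node <= n) return(newick_label(tree$tip.label[[node]]))
    parts <- vapply((kids[[as.character(node)]]) %||% integer(0), function(e) {
      paste0(rec(tree$edge[e, 2L]), ":", fmt_len(tree$edge.length[[e]]))
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  root <- setdiff(unique(tree$edge[, 1L]), tree$edge[, 2L])[[1L]]
  s <- paste0(rec(root), ";")
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}
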