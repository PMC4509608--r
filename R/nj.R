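#' Neighbor-joining tree from a distance matrix
#'
#' Classic neighbor-joining agglomeration using the Q criterion
#' `Q(i,j) = (r - 2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)`, with negative
#' branch lengths clamped to zero and deterministic tie-breaking (the
#' earliest pair in current row order wins). Returns an `ape` "phylo" tree
#' (unrooted topology; for 3 taxa the unique star resolution with
#' three-point branch lengths).
#'
#' @param D Symmetric numeric distance matrix with named rows/columns (or a
#'   `dist`), at least 3 taxa, zero diagonal, non-negative entries.
#' @return An object of class `phylo`.
#' @export
nj_tree <- function(D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  stopifnot(is.matrix(D), nrow(D) >= 3)
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix is not symmetric")
  if (any(D < -1e-12)) stop("distance matrix has negative entries")
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <- paste0("t", seq_len(nrow(D)))
  lab <- rownames(D)
  # each active node carries its newick subtree string
  node <- lab
  d <- D
  while (length(node) > 3) {
    r <- nrow(d)
    rs <- rowSums(d)
    Q <- (r - 2) * d - outer(rs, rs, `+`)
    diag(Q) <- Inf
    ij <- which(Q == min(Q), arr.ind = TRUE)
    ij <- ij[ij[, 1] < ij[, 2], , drop = FALSE]
    i <- ij[1, 1]; j <- ij[1, 2]
    li <- d[i, j] / 2 + (rs[i] - rs[j]) / (2 * (r - 2))
    lj <- d[i, j] - li
    li <- max(0, li); lj <- max(0, lj)
    new_lab <- sprintf("(%s:%.10g,%s:%.10g)", node[i], li, node[j], lj)
    dk <- pmax(0, (d[i, ] + d[j, ] - d[i, j]) / 2)
    keep <- setdiff(seq_len(r), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    node <- c(node[keep], new_lab)
    d <- d2
  }
  # final three-point resolution
  la <- max(0, (d[1, 2] + d[1, 3] - d[2, 3]) / 2)
  lb <- max(0, (d[1, 2] + d[2, 3] - d[1, 3]) / 2)
  lc <- max(0, (d[1, 3] + d[2, 3] - d[1, 2]) / 2)
  txt <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 node[1], la, node[2], lb, node[3], lc)
  ape::read.tree(text = txt)
}

# Canonical bipartition keys of the internal edges of an unrooted tree:
# root at the first taxon of `taxa`, then every internal-node clade of size
# 2..n-2 is one side of an internal bipartition.
bipartition_keys <- function(tree, taxa) {
  tr <- ape::root(tree, outgroup = taxa[1], resolve.root = TRUE)
  n <- length(tr$tip.label)
  keys <- character()
  for (nd in (n + 1):(n + tr$Nnode)) {
    tips <- ape::extract.clade(tr, nd)$tip.label
    if (length(tips) >= 2 && length(tips) <= n - 2)
      keys <- c(keys, paste(sort(tips), collapse = "|"))
  }
  unique(keys)
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree from
#' p-distances for each replicate, and reports for every internal
#' bipartition of the full-data tree the percentage of replicates
#' containing it. Supports are attached as internal node labels.
#'
#' @param alignment A character matrix (taxa x aligned columns) or a named
#'   character vector of equal-length aligned sequences.
#' @param n_replicates Number of bootstrap replicates (default 1000).
#' @param seed Integer seed; fixed seeds give identical supports.
#' @return A list: `tree` (the full-data `phylo` with node labels set to
#'   supports, root label empty), `supports` (named numeric vector keyed by
#'   bipartition).
#' @export
bootstrap_supports <- function(alignment, n_replicates = 1000, seed = 1) {
  M <- as_alignment_matrix(alignment)
  taxa <- rownames(M)
  main <- nj_tree(p_distance(M))
  keys_main <- bipartition_keys(main, taxa)
  counts <- stats::setNames(numeric(length(keys_main)), keys_main)
  with_seed(seed, {
    for (b in seq_len(n_replicates)) {
      cols <- sample.int(ncol(M), ncol(M), replace = TRUE)
      bt <- nj_tree(p_distance(M[, cols, drop = FALSE]))
      kb <- bipartition_keys(bt, taxa)
      hit <- keys_main %in% kb
      counts[hit] <- counts[hit] + 1
    }
  })
  supports <- 100 * counts / n_replicates
  main <- annotate_supports(main, taxa, supports)
  list(tree = main, supports = supports)
}

# Attach supports as node labels on a rooted-at-reference-leaf view of the
# tree (the unrooted topology is unchanged; Newick output keeps supports).
annotate_supports <- function(tree, taxa, supports) {
  rooted <- ape::root(tree, outgroup = taxa[1], resolve.root = TRUE)
  n <- length(rooted$tip.label)
  labs <- character(rooted$Nnode)
  for (k in seq_len(rooted$Nnode)) {
    tips <- sort(ape::extract.clade(rooted, n + k)$tip.label)
    key <- paste(tips, collapse = "|")
    labs[k] <- if (key %in% names(supports)) sprintf("%g", supports[[key]]) else ""
  }
  rooted$node.label <- labs
  rooted
}

as_alignment_matrix <- function(alignment) {
  if (is.matrix(alignment)) return(alignment)
  alignment <- as_named_seqs(alignment)
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1) stop("aligned sequences must share one length")
  M <- do.call(rbind, strsplit(alignment, ""))
  rownames(M) <- names(alignment)
  M
}

# p-distance between rows of a character matrix (gap-free columns assumed).
p_distance <- function(M) {
  n <- nrow(M)
  d <- matrix(0, n, n, dimnames = list(rownames(M), rownames(M)))
  if (n < 2) return(d)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <- mean(M[i, ] != M[j, ])
  d
}

#' Write a tree with supports to Newick
#'
#' @param tree A `phylo` object (supports, when present, are node labels).
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
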