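# Neighbor-joining trees, bootstrap support, rooting and newick I/O.
# Tree objects are ape "phylo" structures throughout.

# Coerce mca_dist / dist / matrix to a symmetric labelled matrix.
.dist_matrix <- function(D) {
  if (inherits(D, "mca_dist")) D <- D$matrix
  if (inherits(D, "dist")) D <- as.matrix(D)
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  if (is.null(rownames(D))) {
    rownames(D) <- colnames(D) <- paste0("t", seq_len(nrow(D)))
  }
  D
}

# Clamp negative NJ branch lengths to zero, transferring the deficit to the
# sibling edge so path lengths through the parent are preserved where
# possible; any remaining negatives are clamped outright.
.clamp_negative_edges <- function(phy) {
  neg <- which(phy$edge.length < 0)
  for (e in neg) {
    parent <- phy$edge[e, 1]
    sibs <- setdiff(which(phy$edge[, 1] == parent), e)
    if (length(sibs)) {
      phy$edge.length[sibs[1]] <- phy$edge.length[sibs[1]] +
        phy$edge.length[e]
    }
    phy$edge.length[e] <- 0
  }
  phy$edge.length[phy$edge.length < 0] <- 0
  phy
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration (via ape's exact implementation) on a distance
#' matrix; on an additive (tree-like) matrix the path lengths of the result
#' reproduce the input distances exactly. Negative branch-length estimates
#' are clamped to zero with the deficit moved to the sibling edge.
#'
#' @param D an `mca_dist`, `dist`, or symmetric numeric matrix with at least
#'   3 labels.
#' @return an unrooted `phylo` tree.
#' @export
nj_tree <- function(D) {
  m <- .dist_matrix(D)
  if (nrow(m) < 3L) {
    stop("invalid-input: neighbor joining needs >= 3 labels", call. = FALSE)
  }
  if (any(!is.finite(m))) {
    stop("invalid-input: non-finite distances", call. = FALSE)
  }
  .clamp_negative_edges(ape::nj(stats::as.dist(m)))
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the
#' distance-matrix + NJ tree per replicate, and reports, for each internal
#' bipartition of the point-estimate tree, the percentage of replicates
#' containing it (stored in `node.label`). Replicates with an undefined
#' distance (saturation or no comparable sites) are skipped and counted.
#'
#' @param msa an `mca_msa` with >= 4 rows.
#' @param n_replicates bootstrap replicates (0 returns the point tree
#'   without supports).
#' @param seed integer seed making the resampling reproducible.
#' @param model,deletion passed to [distances()].
#' @return the point-estimate `phylo` with `node.label` holding supports in
#'   \[0, 100\] (`NA` on the arbitrary root node) and attributes
#'   `n_replicates` (usable replicates) and `n_skipped`.
#' @export
bootstrap_support <- function(msa, n_replicates = 1000L, seed = 1L,
                              model = "poisson", deletion = "pairwise") {
  stopifnot(inherits(msa, "mca_msa"))
  if (nrow(msa$mat) < 4L && n_replicates > 0L) {
    stop("invalid-input: bootstrap needs >= 4 rows", call. = FALSE)
  }
  point <- nj_tree(distances(msa, model = model, deletion = deletion))
  if (n_replicates == 0L) {
    attr(point, "n_replicates") <- 0L
    attr(point, "n_skipped") <- 0L
    return(point)
  }
  L <- ncol(msa$mat)
  .with_seed(seed, {
    reps <- vector("list", n_replicates)
    skipped <- 0L
    for (b in seq_len(n_replicates)) {
      cols <- sample.int(L, L, replace = TRUE)
      sub <- new_msa(stats::setNames(
        apply(msa$mat[, cols, drop = FALSE], 1, paste, collapse = ""),
        msa$labels))
      t <- tryCatch(nj_tree(distances(sub, model = model,
                                      deletion = deletion)),
                    error = function(e) NULL)
      if (is.null(t)) skipped <- skipped + 1L else reps[[b]] <- t
    }
    reps <- reps[!vapply(reps, is.null, logical(1))]
    counts <- ape::prop.clades(point, reps, rooted = FALSE)
    support <- round(100 * counts / length(reps))
    point$node.label <- support
    attr(point, "n_replicates") <- length(reps)
    attr(point, "n_skipped") <- skipped
    point
  })
}

# Descendant tip-label sets of each internal node.
.node_tip_sets <- function(phy) {
  pp <- ape::prop.part(phy)
  lapply(pp, function(ix) attr(pp, "labels")[ix])
}

#' Support of the edge separating a tip set from the rest
#'
#' Looks up the internal bipartition `{tips | rest}` in a tree whose
#' `node.label` carries bootstrap supports and returns its support, or `NA`
#' when the tree does not contain that bipartition.
#'
#' @param tree a `phylo` with `node.label` supports.
#' @param tips character vector of tip labels.
#' @return support value or `NA`.
#' @export
clade_support <- function(tree, tips) {
  sets <- .node_tip_sets(tree)
  all_tips <- tree$tip.label
  for (k in seq_along(sets)) {
    s <- sets[[k]]
    if (setequal(s, tips) || setequal(setdiff(all_tips, s), tips)) {
      lab <- tree$node.label[k]
      return(suppressWarnings(as.numeric(lab)))
    }
  }
  NA_real_
}

# TRUE when {tips | rest} is a bipartition of the (possibly unrooted) tree.
.is_split <- function(phy, tips) {
  all_tips <- phy$tip.label
  if (length(tips) <= 1L || length(tips) >= length(all_tips) - 1L) {
    return(TRUE)
  }
  sets <- .node_tip_sets(phy)
  any(vapply(sets, function(s) {
    setequal(s, tips) || setequal(setdiff(all_tips, s), tips)
  }, logical(1)))
}

#' Root a tree on an outgroup
#'
#' Places the root on the edge separating the outgroup from the ingroup;
#' bootstrap supports on internal edges are preserved. The outgroup must
#' form one side of a bipartition of the unrooted tree.
#'
#' @param tree a `phylo`.
#' @param outgroup character vector of outgroup tip labels.
#' @return a rooted `phylo`.
#' @export
root_with_outgroup <- function(tree, outgroup) {
  missing <- setdiff(outgroup, tree$tip.label)
  if (length(missing)) {
    stop("outgroup label(s) not in tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!.is_split(tree, outgroup)) {
    stop("non-clade-outgroup: outgroup is not monophyletic in the tree",
         call. = FALSE)
  }
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE, edgelabel = TRUE)
}

#' Newick serialization
#'
#' Round-trips topology, branch lengths (at least 6 significant digits) and
#' internal-node support labels.
#'
#' @param tree a `phylo`.
#' @param text newick string.
#' @return `to_newick` returns a newick string; `from_newick` a `phylo`.
#' @export
to_newick <- function(tree) {
  ape::write.tree(tree, digits = 10)
}

#' @rdname to_newick
#' @export
from_newick <- function(text) {
  depth <- 0L
  chars <- .residues(text)
  for (k in seq_along(chars)) {
    if (chars[k] == "(") depth <- depth + 1L
    if (chars[k] == ")") depth <- depth - 1L
    if (depth < 0L) {
      stop("newick parse error at position ", k, ": unbalanced ')'",
           call. = FALSE)
    }
  }
  if (depth != 0L) {
    stop("newick parse error at position ", nchar(text),
         ": unbalanced '('", call. = FALSE)
  }
  tr <- tryCatch(ape::read.tree(text = text), error = function(e) NULL,
                 warning = function(w) NULL)
  if (is.null(tr)) stop("newick parse error at position 1", call. = FALSE)
  tr
}
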