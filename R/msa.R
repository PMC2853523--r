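# Progressive multiple alignment and alignment distances.

#' Construct a multiple-alignment object
#'
#' @param rows named character vector of equal-length gapped sequences
#'   (`-` as the gap character); names must be unique.
#' @return an object of class `mca_msa` with elements `labels`, `rows` and
#'   `mat` (residue character matrix, sequences in rows).
#' @export
new_msa <- function(rows) {
  stopifnot(is.character(rows), !is.null(names(rows)),
            !anyDuplicated(names(rows)))
  if (length(unique(nchar(rows))) != 1L) {
    stop("alignment rows must all have the same length", call. = FALSE)
  }
  mat <- do.call(rbind, strsplit(unname(rows), "", fixed = TRUE))
  rownames(mat) <- names(rows)
  structure(list(labels = names(rows), rows = rows, mat = mat),
            class = "mca_msa")
}

#' @export
print.mca_msa <- function(x, ...) {
  cat(sprintf("<mca_msa: %d sequences x %d columns>\n", length(x$labels),
              ncol(x$mat)))
  invisible(x)
}

# 20 x L residue-frequency profile of a set of gapped rows (gap mass
# excluded, so gap-vs-residue column scores are 0 before gap penalties).
.msa_profile <- function(mat) {
  L <- ncol(mat)
  P <- matrix(0, nrow = 20L, ncol = L, dimnames = list(.AA20, NULL))
  n <- nrow(mat)
  for (a in .AA20) {
    P[a, ] <- colSums(mat == a) / n
  }
  P
}

# Align two groups of gapped rows (character matrices) with the Gotoh
# profile aligner; returns the merged matrix.
.merge_groups <- function(m1, m2, S, gap_open, gap_extend) {
  P1 <- .msa_profile(m1)
  P2 <- .msa_profile(m2)
  C <- t(P1) %*% S[.AA20, .AA20] %*% P2
  path <- .gotoh_global(C, gap_open, gap_extend)
  L <- length(path)
  out <- matrix("-", nrow = nrow(m1) + nrow(m2), ncol = L)
  rownames(out) <- c(rownames(m1), rownames(m2))
  i <- 0L; j <- 0L
  for (k in seq_len(L)) {
    mv <- path[k]
    if (mv != 3L) { i <- i + 1L; out[seq_len(nrow(m1)), k] <- m1[, i] }
    if (mv != 2L) { j <- j + 1L; out[nrow(m1) + seq_len(nrow(m2)), k] <- m2[, j] }
  }
  out
}

# Pairwise global alignment p-distance used for the guide tree.
.pair_pdist <- function(s1, s2, S, gap_open, gap_extend) {
  r1 <- .residues(s1); r2 <- .residues(s2)
  C <- S[r1, r2, drop = FALSE]
  path <- .gotoh_global(C, gap_open, gap_extend)
  i <- 0L; j <- 0L; comp <- 0L; mism <- 0L
  for (mv in path) {
    if (mv == 1L) {
      i <- i + 1L; j <- j + 1L
      comp <- comp + 1L
      if (r1[i] != r2[j]) mism <- mism + 1L
    } else if (mv == 2L) i <- i + 1L else j <- j + 1L
  }
  if (!comp) 1 else mism / comp
}

#' Progressive multiple sequence alignment
#'
#' ClustalX-style progressive alignment: pairwise global alignments give
#' p-distances, a UPGMA guide tree orders the merges, and groups are merged
#' by profile-profile global alignment under affine gap penalties. The
#' default scheme follows the classic protein-alignment setting of gap
#' opening 10 and gap extension 0.2 with a log-odds weight matrix (PAM250).
#' Deterministic.
#'
#' @param sequences named character vector (>= 1 sequence; a single sequence
#'   aligns trivially to itself).
#' @param scheme a [scoring_scheme()]; only the matrix and gap penalties are
#'   used.
#' @return an `mca_msa` with rows in the input order.
#' @export
progressive_align <- function(sequences,
                              scheme = scoring_scheme("PAM250", 10, 0.2)) {
  if (!length(sequences)) {
    stop("invalid-input: no sequences to align", call. = FALSE)
  }
  if (is.null(names(sequences)) || anyDuplicated(names(sequences))) {
    stop("sequences must have unique names", call. = FALSE)
  }
  for (s in sequences) .check_protein(s)
  n <- length(sequences)
  if (n == 1L) return(new_msa(sequences))
  S <- scheme$matrix
  go <- scheme$gap_open; ge <- scheme$gap_extend

  if (n == 2L) {
    groups <- lapply(sequences, function(s) {
      m <- matrix(.residues(s), nrow = 1L); rownames(m) <- NULL; m
    })
    names(groups) <- NULL
    m1 <- groups[[1]]; rownames(m1) <- names(sequences)[1]
    m2 <- groups[[2]]; rownames(m2) <- names(sequences)[2]
    merged <- .merge_groups(m1, m2, S, go, ge)
  } else {
    D <- matrix(0, n, n, dimnames = list(names(sequences), names(sequences)))
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- .pair_pdist(sequences[[i]], sequences[[j]],
                                        S, go, ge)
    }
    guide <- stats::hclust(stats::as.dist(D), method = "average")
    nodes <- vector("list", nrow(guide$merge))
    leaf <- function(k) {
      m <- matrix(.residues(sequences[[k]]), nrow = 1L)
      rownames(m) <- names(sequences)[k]
      m
    }
    for (step in seq_len(nrow(guide$merge))) {
      a <- guide$merge[step, 1]; b <- guide$merge[step, 2]
      ga <- if (a < 0) leaf(-a) else nodes[[a]]
      gb <- if (b < 0) leaf(-b) else nodes[[b]]
      nodes[[step]] <- .merge_groups(ga, gb, S, go, ge)
    }
    merged <- nodes[[length(nodes)]]
  }
  merged <- merged[names(sequences), , drop = FALSE]
  new_msa(stats::setNames(apply(merged, 1, paste, collapse = ""),
                          rownames(merged)))
}

#' Pairwise distances from an alignment
#'
#' p-distance (mismatches over compared sites) or its Poisson correction
#' `-log(1 - p)`, with pairwise deletion of gap-containing columns (the
#' default) or complete deletion of every column containing any gap.
#'
#' @param msa an `mca_msa`.
#' @param model `"poisson"` (default) or `"p-distance"`.
#' @param deletion `"pairwise"` (default) or `"complete"`.
#' @return an object of class `mca_dist`: `labels`, `matrix` (symmetric,
#'   zero diagonal), `model`.
#' @export
distances <- function(msa, model = c("poisson", "p-distance"),
                      deletion = c("pairwise", "complete")) {
  stopifnot(inherits(msa, "mca_msa"))
  model <- match.arg(model)
  deletion <- match.arg(deletion)
  mat <- msa$mat
  n <- nrow(mat)
  if (n < 2L) stop("invalid-input: need >= 2 rows", call. = FALSE)
  if (deletion == "complete") {
    keep <- colSums(mat == "-") == 0L
    mat <- mat[, keep, drop = FALSE]
  }
  D <- matrix(0, n, n, dimnames = list(msa$labels, msa$labels))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- mat[i, ] != "-" & mat[j, ] != "-"
    nc <- sum(ok)
    if (!nc) {
      stop("undefined-distance: no comparable sites between '",
           msa$labels[i], "' and '", msa$labels[j], "'", call. = FALSE)
    }
    p <- sum(mat[i, ok] != mat[j, ok]) / nc
    d <- if (model == "p-distance") p else {
      if (p >= 1) {
        stop("undefined-distance: saturated Poisson distance between '",
             msa$labels[i], "' and '", msa$labels[j], "' (p = 1)",
             call. = FALSE)
      }
      -log(1 - p)
    }
    D[i, j] <- D[j, i] <- d
  }
  structure(list(labels = msa$labels, matrix = D, model = model),
            class = "mca_dist")
}

#' @export
print.mca_dist <- function(x, ...) {
  cat(sprintf("<mca_dist: %d labels, model %s>\n", length(x$labels), x$model))
  invisible(x)
}

#' Write / read an alignment as aligned FASTA
#'
#' @param msa an `mca_msa`.
#' @param path file path.
#' @return `write_msa_fasta` returns `path` invisibly; `read_msa_fasta`
#'   returns an `mca_msa`.
#' @export
write_msa_fasta <- function(msa, path) {
  stopifnot(inherits(msa, "mca_msa"))
  writeLines(as.vector(rbind(paste0(">", msa$labels), unname(msa$rows))),
             path)
  invisible(path)
}

#' @rdname write_msa_fasta
#' @export
read_msa_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  new_msa(stats::setNames(as.character(x), names(x)))
}
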