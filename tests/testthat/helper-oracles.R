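# Independent oracles used by the tests. These deliberately re-derive
# results by different means than the package code: the alignment oracle is
# a top-down memoized recursion (the package delegates to Biostrings'
# bottom-up C implementation), the TM oracle recomputes window means from
# scratch, and phylogeny checks go through ape's path-length and
# tree-comparison utilities on trees the package never saw.

# Best Smith-Waterman score under affine gaps (a gap of length L costs
# open + L * ext), via memoized recursion over (i, j, state). States:
# M = alignment ends in a substitution at (i, j); X = ends in a gap
# consuming query residue i; Y = ends in a gap consuming subject residue j.
oracle_local_score <- function(query, subject, scheme) {
  a <- strsplit(query, "")[[1]]
  b <- strsplit(subject, "")[[1]]
  S <- scheme$matrix
  go <- scheme$gap_open
  ge <- scheme$gap_extend
  memo <- new.env(parent = emptyenv())
  f <- function(i, j, st) {
    if (i < 1L || j < 1L) return(-Inf)
    key <- paste0(st, i, ".", j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    val <- switch(st,
      M = S[a[i], b[j]] +
        max(0, f(i - 1L, j - 1L, "M"), f(i - 1L, j - 1L, "X"),
            f(i - 1L, j - 1L, "Y")),
      X = max(f(i - 1L, j, "M") - go - ge, f(i - 1L, j, "X") - ge),
      Y = max(f(i, j - 1L, "M") - go - ge, f(i, j - 1L, "Y") - ge))
    memo[[key]] <- val
    val
  }
  best <- 0
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      best <- max(best, f(i, j, "M"), f(i, j, "X"), f(i, j, "Y"))
    }
  }
  best
}

# Kyte-Doolittle hydropathy window means, recomputed with a plain loop.
oracle_tm_windows <- function(sequence, window = 19L, threshold = 1.6) {
  kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
          E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
          M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
          Y = -1.3, V = 4.2)
  v <- kd[strsplit(sequence, "")[[1]]]
  n <- length(v)
  if (n < window) return(integer(0))
  means <- vapply(seq_len(n - window + 1L),
                  function(i) mean(v[i:(i + window - 1L)]), numeric(1))
  which(means >= threshold)
}

# Random unrooted additive tree with positive branch lengths.
random_additive_tree <- function(n_leaves) {
  tr <- ape::rtree(n_leaves, rooted = FALSE)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 1)
  tr
}

# Random protein over a reduced alphabet.
rand_seq <- function(n, alphabet = c("A", "C", "D", "E", "G", "K", "W")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# P20 cassettes of one lineage consensus with a few random substitutions
# outside the catalytic-context positions, for two-clade tree tests.
varied_cassettes <- function(variant, k, n_subs = 8L) {
  vapply(seq_len(k), function(i) {
    s <- strsplit(plant_p20_cassette(variant = variant)$segment, "")[[1]]
    ok <- setdiff(seq_along(s), c(61:65, 201:205))
    ix <- sample(ok, n_subs)
    s[ix] <- sample(c("A", "G", "S", "T", "L", "V", "K", "E"), n_subs,
                    replace = TRUE)
    paste(s, collapse = "")
  }, character(1))
}
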