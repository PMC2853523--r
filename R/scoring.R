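#' Alignment scoring scheme
#'
#' Bundles a substitution matrix, affine gap penalties (a gap of length L
#' costs `gap_open + L * gap_extend`) and Karlin-Altschul parameters for
#' E-value estimation. The default is the standard gapped BLOSUM62 / open 11
#' / extend 1 setting with its published gapped parameters (lambda = 0.267,
#' K = 0.041). Ambiguity residue `X` scores 0 against everything.
#'
#' @param matrix_name one of `"BLOSUM62"`, `"BLOSUM45"`, `"BLOSUM50"`,
#'   `"BLOSUM80"`, `"PAM250"`, `"PAM120"`, or a symmetric numeric matrix
#'   with amino-acid dimnames.
#' @param gap_open non-negative gap opening penalty.
#' @param gap_extend non-negative gap extension penalty
#'   (`gap_open >= gap_extend` required).
#' @param karlin_lambda,karlin_K positive Karlin-Altschul parameters.
#' @return an object of class `scoring_scheme`.
#' @export
#' @examples
#' scoring_scheme()                      # search default
#' scoring_scheme("PAM250", 10, 0.2)     # guide-alignment setting
scoring_scheme <- function(matrix_name = "BLOSUM62", gap_open = 11,
                           gap_extend = 1, karlin_lambda = 0.267,
                           karlin_K = 0.041) {
  if (is.matrix(matrix_name)) {
    mat <- matrix_name
    name <- "custom"
  } else {
    name <- match.arg(matrix_name, c("BLOSUM62", "BLOSUM45", "BLOSUM50",
                                     "BLOSUM80", "PAM250", "PAM120"))
    e <- new.env()
    utils::data(list = name, package = "Biostrings", envir = e)
    mat <- get(name, envir = e)
  }
  keep <- intersect(c(.AA20, "X"), rownames(mat))
  if (!all(.AA20 %in% keep)) {
    stop("substitution matrix must cover the 20 standard amino acids",
         call. = FALSE)
  }
  mat <- mat[keep, keep]
  if ("X" %in% rownames(mat)) {
    mat["X", ] <- 0
    mat[, "X"] <- 0
  } else {
    mat <- rbind(cbind(mat, X = 0), X = 0)
  }
  if (!isTRUE(all.equal(mat, t(mat)))) {
    stop("substitution matrix must be symmetric", call. = FALSE)
  }
  if (gap_open < 0 || gap_extend < 0 || gap_open < gap_extend) {
    stop("gap penalties must satisfy gap_open >= gap_extend >= 0",
         call. = FALSE)
  }
  if (karlin_lambda <= 0 || karlin_K <= 0) {
    stop("Karlin-Altschul parameters must be positive", call. = FALSE)
  }
  structure(list(matrix_name = name, matrix = mat, gap_open = gap_open,
                 gap_extend = gap_extend, karlin_lambda = karlin_lambda,
                 karlin_K = karlin_K),
            class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf("<scoring_scheme %s open=%g extend=%g lambda=%g K=%g>\n",
              x$matrix_name, x$gap_open, x$gap_extend, x$karlin_lambda,
              x$karlin_K))
  invisible(x)
}

#' Karlin-Altschul E-value
#'
#' Expected number of local alignments of at least the given score between a
#' query of `m` residues and a database of `n` residues:
#' `E = K * m * n * exp(-lambda * score)`.
#'
#' @param score alignment score.
#' @param m residues in the query (>= 1).
#' @param n residues in the database (>= 1).
#' @param scheme a [scoring_scheme()] supplying lambda and K.
#' @return the E-value (strictly decreasing in score, linear in `m * n`).
#' @export
evalue <- function(score, m, n, scheme = scoring_scheme()) {
  if (any(m < 1) || any(n < 1)) {
    stop("invalid-input: m and n must be >= 1", call. = FALSE)
  }
  scheme$karlin_K * m * n * exp(-scheme$karlin_lambda * score)
}
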