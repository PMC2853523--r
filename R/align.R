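#' Optimal affine-gap local alignment
#'
#' Exact Smith-Waterman/Gotoh local alignment of two protein sequences,
#' computed through Biostrings' pairwise aligner under the gap convention of
#' [scoring_scheme()] (a gap of length L costs `gap_open + L * gap_extend`).
#' Unlike a heuristic database search, the returned score is the true
#' optimum.
#'
#' @param query,subject protein strings (non-empty; `X` tolerated and scored
#'   0 against everything).
#' @param scheme a [scoring_scheme()].
#' @return an object of class `mca_alignment`: `score`, `query_span` and
#'   `subject_span` (1-based inclusive), `query_aln`/`subject_aln` (gapped
#'   strings), `evalue` (`NA` until set by a caller that knows the database
#'   size).
#' @export
#' @examples
#' local_align("HEAGAWGHEE", "PAWHEAE")
local_align <- function(query, subject, scheme = scoring_scheme()) {
  .check_protein(query, "query")
  .check_protein(subject, "subject")
  pa <- Biostrings::pairwiseAlignment(
    pattern = query, subject = subject, type = "local",
    substitutionMatrix = scheme$matrix,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend)
  p <- Biostrings::pattern(pa)
  s <- Biostrings::subject(pa)
  structure(list(
    score = Biostrings::score(pa),
    query_span = c(Biostrings::start(p), Biostrings::end(p)),
    subject_span = c(Biostrings::start(s), Biostrings::end(s)),
    query_aln = as.character(p),
    subject_aln = as.character(s),
    evalue = NA_real_), class = "mca_alignment")
}

#' @export
print.mca_alignment <- function(x, ...) {
  cat(sprintf("<local alignment score %g, query %d-%d, subject %d-%d>\n",
              x$score, x$query_span[1], x$query_span[2],
              x$subject_span[1], x$subject_span[2]))
  cat(" ", x$query_aln, "\n ", x$subject_aln, "\n")
  invisible(x)
}

# Vectorized score-only local alignment of many queries against one subject.
.local_scores <- function(queries, subject, scheme) {
  Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(queries), subject = subject,
    type = "local", substitutionMatrix = scheme$matrix,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend,
    scoreOnly = TRUE)
}
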