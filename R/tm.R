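#' Detect transmembrane segments by hydropathy
#'
#' Kyte-Doolittle sliding-window scan: positions where the mean hydropathy
#' over a window of `window` residues reaches `threshold` seed a segment;
#' overlapping windows are merged. The defaults (window 19, cutoff 1.6) are
#' the classic heuristic for membrane-spanning helices.
#'
#' @param sequence protein string.
#' @param window window width in residues (default 19).
#' @param threshold mean-hydropathy cutoff (default 1.6).
#' @return data.frame of hits (`domain_type` = "TM"); sequences shorter than
#'   the window yield zero hits. Unknown residue `X` has hydropathy 0.
#' @export
#' @examples
#' detect_tm(paste0(strrep("D", 30), strrep("I", 25), strrep("D", 30)))
detect_tm <- function(sequence, window = 19L, threshold = 1.6) {
  .check_protein(sequence)
  res <- .residues(sequence)
  L <- length(res)
  if (L < window) return(.empty_hits())
  kd <- c(.KD_HYDROPATHY, X = 0)[res]
  cs <- cumsum(c(0, kd))
  means <- (cs[(window + 1L):(L + 1L)] - cs[seq_len(L - window + 1L)]) / window
  hot <- which(means >= threshold)
  if (!length(hot)) return(.empty_hits())
  # merge overlapping/adjacent windows into maximal runs
  gaps <- which(diff(hot) > window)
  run_start <- hot[c(1L, gaps + 1L)]
  run_end <- hot[c(gaps, length(hot))] + window - 1L
  score <- vapply(seq_along(run_start), function(i) {
    max(means[run_start[i]:(run_end[i] - window + 1L)])
  }, numeric(1))
  data.frame(domain_type = "TM", start = run_start, end = run_end,
             score = score, copies = 1L, stringsAsFactors = FALSE)
}
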