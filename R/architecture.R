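#' Parse a domain-architecture string
#'
#' Architecture strings are comma-separated domain tokens with an optional
#' repeat multiplicity in parentheses, e.g. `"NACHT, WD40(13)"` or
#' `"Pentapeptide(4)"`. Blank input yields an empty table.
#'
#' @param text architecture string (or `NA`).
#' @return data.frame with columns `domain_type`, `copies`.
#' @export
#' @examples
#' parse_architecture("NACHT, WD40(13)")
parse_architecture <- function(text) {
  empty <- data.frame(domain_type = character(), copies = integer(),
                      stringsAsFactors = FALSE)
  if (is.null(text) || is.na(text) || !nzchar(trimws(text))) return(empty)
  toks <- trimws(strsplit(text, ",", fixed = TRUE)[[1]])
  toks <- toks[nzchar(toks)]
  out <- lapply(toks, function(tk) {
    m <- regmatches(tk, regexec("^([A-Za-z0-9-]+)(\\((\\d+)\\))?$", tk))[[1]]
    if (!length(m)) {
      stop("unknown-domain: cannot parse architecture token '", tk, "'",
           call. = FALSE)
    }
    type <- m[2]
    known <- .ADDITIONAL_DOMAIN_TYPES[
      tolower(.ADDITIONAL_DOMAIN_TYPES) == tolower(type)]
    if (!length(known)) {
      stop("unknown-domain: '", type, "' is not a known domain type",
           call. = FALSE)
    }
    copies <- if (nzchar(m[4])) as.integer(m[4]) else 1L
    data.frame(domain_type = known, copies = copies, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Render a domain table as an architecture string
#'
#' Inverse of [parse_architecture()]: copies greater than one are written as
#' a `(n)` suffix.
#'
#' @param domains data.frame with `domain_type` and `copies`.
#' @return a character scalar (empty for zero rows).
#' @export
render_architecture <- function(domains) {
  if (!nrow(domains)) return("")
  paste(ifelse(domains$copies > 1L,
               paste0(domains$domain_type, "(", domains$copies, ")"),
               domains$domain_type), collapse = ", ")
}

#' Annotate the domain architecture of a protein
#'
#' Combines the P20 (CASc) profile scan, single-copy accessory-domain scans,
#' repeat-unit counting and transmembrane detection into one architecture
#' call. The CASc position is `"C-terminal"` when the midpoint of the P20
#' hit lies in the C-terminal half of the protein, `"N-terminal"` otherwise,
#' and `"none"` without a P20 hit. Both packaged P20 variants are scanned
#' and the best-scoring hit is kept.
#'
#' @param sequence protein string.
#' @param gene_id optional identifier stored in the result.
#' @param models model set from [builtin_models()].
#' @param tm_window,tm_threshold transmembrane scan parameters
#'   (see [detect_tm()]).
#' @param min_copies repeat-report floor (see [detect_repeats()]).
#' @param strict when `TRUE`, a P20 hit must also cover at least
#'   `min_coverage` of the model's expected domain length (a two-detector
#'   agreement surrogate; weak marginal hits are dropped).
#' @param min_coverage coverage fraction for strict mode.
#' @return an object of class `domain_architecture`: `gene_id`, `length`,
#'   `hits` (data.frame sorted by `start`), `casc_position`, `has_tm`.
#' @export
annotate <- function(sequence, gene_id = NA_character_,
                     models = builtin_models(), tm_window = 19L,
                     tm_threshold = 1.6, min_copies = 3L, strict = FALSE,
                     min_coverage = 0.5) {
  if (is.null(models$p20) || !length(models$p20)) {
    stop("invalid-model: P20 model missing from model set", call. = FALSE)
  }
  .check_protein(sequence)
  L <- nchar(sequence)

  p20_hits <- lapply(models$p20, function(m) scan_profile(sequence, m))
  p20_hits <- do.call(rbind, p20_hits)
  p20 <- NULL
  if (nrow(p20_hits)) {
    p20 <- p20_hits[which.max(p20_hits$score), , drop = FALSE]
    if (strict) {
      width <- p20$end - p20$start + 1L
      exp_len <- max(vapply(models$p20, function(m) m$expected_length, 1))
      if (width < min_coverage * exp_len) p20 <- NULL
    }
  }
  if (!is.null(p20)) p20$domain_type <- "CASc"

  singles <- do.call(rbind, lapply(models$singles,
                                   function(m) scan_profile(sequence, m)))
  reps <- do.call(rbind, lapply(models$repeats, function(m) {
    detect_repeats(sequence, m, min_copies = min_copies)
  }))
  tm <- detect_tm(sequence, window = tm_window, threshold = tm_threshold)

  hits <- rbind(p20, singles, reps, tm)
  if (is.null(hits)) hits <- .empty_hits()
  hits <- hits[order(hits$start), , drop = FALSE]
  rownames(hits) <- NULL

  casc_position <- "none"
  if (!is.null(p20)) {
    mid <- (p20$start + p20$end) / 2
    casc_position <- if (mid > L / 2) "C-terminal" else "N-terminal"
  }
  structure(list(gene_id = gene_id, length = L, hits = hits,
                 casc_position = casc_position,
                 has_tm = any(hits$domain_type == "TM")),
            class = "domain_architecture")
}

#' @export
print.domain_architecture <- function(x, ...) {
  cat(sprintf("<domain_architecture %s: %d aa, CASc %s%s>\n",
              x$gene_id, x$length, x$casc_position,
              if (x$has_tm) ", TM" else ""))
  if (nrow(x$hits)) print(x$hits)
  invisible(x)
}

# Accessory (non-CASc, non-TM) hits of an architecture.
.additional_hits <- function(arch) {
  arch$hits[arch$hits$domain_type %in% .ADDITIONAL_DOMAIN_TYPES, ,
            drop = FALSE]
}

# The P20 hit of an architecture (one row or NULL).
.p20_hit <- function(arch) {
  h <- arch$hits[arch$hits$domain_type == "CASc", , drop = FALSE]
  if (nrow(h)) h[1, , drop = FALSE] else NULL
}
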