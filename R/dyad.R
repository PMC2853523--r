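# Catalytic His/Cys dyad scanning.
#
# Metacaspases carry their catalytic His and Cys in short conserved contexts,
# (Y/F)SGxG and QAx(R/Q)G, with x the catalytic slot. The tolerated
# substitution vocabulary is His->Tyr and Cys->Ser/Asn/Gln/Gly; any other
# slot residue (or a missing context) is reported as `absent`.

.HIS_STATES <- c(H = "intact", Y = "Tyr")
.CYS_STATES <- c(C = "intact", S = "Ser", N = "Asn", Q = "Gln", G = "Gly")
.CYS_LETTER <- c(Ser = "S", Asn = "N", Gln = "Q", Gly = "G")

#' The catalytic-dyad context pattern
#'
#' @return a list with the His- and Cys-context regular expressions (one
#'   capture group on the catalytic slot) and the allowed slot residues.
#' @export
dyad_pattern <- function() {
  list(his_regex = "[YF]SG([A-Z])G", his_slot_offset = 3L,
       his_allowed = .HIS_STATES,
       cys_regex = "QA([A-Z])[RQ]G", cys_slot_offset = 2L,
       cys_allowed = .CYS_STATES)
}

.new_dyad_status <- function(his_state, cys_state, his_pos, cys_pos) {
  structure(list(
    his_state = his_state, cys_state = cys_state,
    his_position = his_pos, cys_position = cys_pos,
    mutated = !(his_state %in% c("intact", "absent")) ||
      !(cys_state %in% c("intact", "absent"))),
    class = "dyad_status")
}

#' @export
print.dyad_status <- function(x, ...) {
  cat(sprintf("<dyad_status His=%s@%s Cys=%s@%s%s>\n", x$his_state,
              x$his_position %||% "-", x$cys_state, x$cys_position %||% "-",
              if (x$mutated) " mutated" else ""))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# first regex match position within a string, or NA
.first_match <- function(text, regex, from = 1L) {
  if (from > nchar(text)) return(NA_integer_)
  m <- regexpr(regex, substring(text, from), perl = TRUE)
  if (m[1] == -1L) NA_integer_ else as.integer(m[1]) + from - 1L
}

#' Scan a sequence for the catalytic His/Cys dyad
#'
#' Finds the first His-context match, then the first Cys-context match
#' downstream of it (first-match-wins in both cases), and classifies each
#' catalytic slot as `intact`, a tolerated substitution, or `absent`.
#' Positions are 1-based indices of the slot residue in the full sequence.
#'
#' @param sequence protein string.
#' @param pattern a [dyad_pattern()].
#' @param span optional 1-based inclusive `c(start, end)` interval confining
#'   the search (typically the P20 hit span); `NULL` scans the whole
#'   sequence.
#' @return a `dyad_status`: `his_state`, `cys_state`, `his_position`,
#'   `cys_position`, `mutated`.
#' @export
#' @examples
#' scan_dyad("AAAYSGHGAAAQACRGAAA")
scan_dyad <- function(sequence, pattern = dyad_pattern(), span = NULL) {
  .check_protein(sequence)
  L <- nchar(sequence)
  if (is.null(span)) span <- c(1L, L)
  if (length(span) != 2L || span[1] < 1L || span[2] > L || span[1] > span[2]) {
    stop("invalid-span: search span [", span[1], ", ", span[2],
         "] outside sequence of length ", L, call. = FALSE)
  }
  region <- substring(sequence, span[1], span[2])
  his_state <- "absent"; his_pos <- NULL
  m <- .first_match(region, pattern$his_regex)
  if (!is.na(m)) {
    slot <- substring(region, m + pattern$his_slot_offset,
                      m + pattern$his_slot_offset)
    if (slot %in% names(pattern$his_allowed)) {
      his_state <- unname(pattern$his_allowed[slot])
      his_pos <- span[1] + m + pattern$his_slot_offset - 1L
    }
  }
  cys_state <- "absent"; cys_pos <- NULL
  cys_from <- if (is.null(his_pos)) 1L else (his_pos - span[1] + 1L) + 1L
  m <- .first_match(region, pattern$cys_regex, from = cys_from)
  if (!is.na(m)) {
    slot <- substring(region, m + pattern$cys_slot_offset,
                      m + pattern$cys_slot_offset)
    if (slot %in% names(pattern$cys_allowed)) {
      cys_state <- unname(pattern$cys_allowed[slot])
      cys_pos <- span[1] + m + pattern$cys_slot_offset - 1L
    }
  }
  .new_dyad_status(his_state, cys_state, his_pos, cys_pos)
}

#' Render a dyad status as a site string
#'
#' Produces the compact substituted-site notation used in the census tables:
#' empty when both sites are intact, `"H-Y"` for a His->Tyr substitution and
#' `"C-S"`/`"C-N"`/`"C-Q"`/`"C-G"` for the Cys substitutions, His fragment
#' first.
#'
#' @param status a `dyad_status`.
#' @return a character scalar.
#' @export
render_sites <- function(status) {
  stopifnot(inherits(status, "dyad_status"))
  frags <- character(0)
  if (status$his_state == "Tyr") frags <- c(frags, "H-Y")
  if (!status$cys_state %in% c("intact", "absent")) {
    frags <- c(frags, paste0("C-", .CYS_LETTER[[status$cys_state]]))
  }
  paste(frags, collapse = " ")
}

#' Parse a site string back to His/Cys states
#'
#' Inverse of [render_sites()] for the vocabulary used in the packaged
#' census fixture: `""` means both sites intact.
#'
#' @param text site string such as `"H-Y C-S"` or `"C-G"`.
#' @return list with `his_state` and `cys_state`.
#' @export
parse_sites <- function(text) {
  if (is.na(text)) text <- ""
  his <- "intact"; cys <- "intact"
  toks <- strsplit(trimws(text), "\\s+")[[1]]
  toks <- toks[nzchar(toks)]
  for (tk in toks) {
    if (tk == "H-Y") his <- "Tyr"
    else if (grepl("^C-[SNQG]$", tk)) {
      cys <- names(.CYS_LETTER)[.CYS_LETTER == substring(tk, 3, 3)]
    } else stop("unknown site token: ", tk, call. = FALSE)
  }
  list(his_state = his, cys_state = cys)
}

#' Census of catalytic-site substitutions
#'
#' Counts genes whose dyad carries at least one tolerated substitution,
#' overall and per strain.
#'
#' @param dyads data.frame with columns `gene_id`, `strain`, and either a
#'   logical `mutated` column or `his_state`/`cys_state` columns.
#' @return list with `n_mutated` (total) and `per_strain` (data.frame
#'   `strain`, `n_mutated`).
#' @export
census_mutations <- function(dyads) {
  stopifnot(is.data.frame(dyads), all(c("gene_id", "strain") %in% names(dyads)))
  if (anyDuplicated(dyads$gene_id)) {
    stop("duplicate-record: duplicated gene_id in dyad table: ",
         dyads$gene_id[duplicated(dyads$gene_id)][1], call. = FALSE)
  }
  mut <- if ("mutated" %in% names(dyads)) dyads$mutated else {
    !(dyads$his_state %in% c("intact", "absent")) |
      !(dyads$cys_state %in% c("intact", "absent"))
  }
  per <- stats::aggregate(list(n_mutated = as.integer(mut)),
                          by = list(strain = dyads$strain), FUN = sum)
  list(n_mutated = sum(mut), per_strain = per[order(per$strain), ,
                                              drop = FALSE])
}
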