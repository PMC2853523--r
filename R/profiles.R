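# Packaged profile models.
#
# The package has no network access to conserved-domain services, so each
# domain type is represented by a small synthetic profile model: a fixed
# consensus sequence compiled to per-position log-odds columns. The P20
# consensus strings were generated once from background frequencies under
# three constraints: exactly one His context ([Y/F]SGxG, slot 64) and one
# Cys context (QAx[R/Q]G, slot 203) under every tolerated slot substitution,
# and no transmembrane-like hydropathy window. They are synthetic stand-ins
# for the caspase P20 (COG4249/KOG1546-type) seed models, not curated
# alignments. Two P20 variants (~25% divergent) give the alpha and beta
# families distinct catalytic-domain lineages.

.CONS_P20_ALPHA <- paste0(
  "AKPEFRQVGQLEIIVEHRYIIMEKWFWGVVLMTNDKLESHKYDIEEFSIIDLCSPMDKGA",
  "YSGHGEKLIPDEVLPPLNCVYGFKADFVQTGAIDIACDAVESRLYCDRVTKYFCSPYGLH",
  "SAADSLIDNNKAENDIFCRLLPCKKGMSLRGKAENMGDQHTKDIPGSYSYTIDCKLKGAP",
  "LIFITYLVTPETVDEEQVCLQACRGVLDATGPELRKDVKIMGNTSSGRKTCSYNGLTAMK",
  "FISGRPLESEISEECSNNDILVLRSMKRELQFKDYAWHPKNGKFPVLFKTIIRGKGGPDA",
  "MRILNPRGLNITNTEVGRTVGEVNQYGIMLTGPAICARTV"
)
.CONS_P20_BETA <- paste0(
  "ASKETRQRGQLEIIVEHQYIILEKGFEGPVLMANQKLESHKYDIEEESIVDLCEPMDKGA",
  "YSGHGEKLIPDEVGPPLNCVYGFKRDFVQTLAYDQACDAVEFRLYCDRVTKYFCSPYELN",
  "SLAESLIKNVKQETDDFCRLLTCKKGSSNRGNAEVMVKQSTKDEMGPYSYTPDAKLKKAE",
  "LIFIHLLGDLEDVDAEQVCLQACRGVLDATGIELRKEYKIMGNTSSGRKLSSYNGLTAMK",
  "FISGRPLESEISPECSENNIEVTRSMNRELLEKDYLWHLKEVKFPVIIKTMIRGPLVPQA",
  "MRILNPRGLNIENTEIQRARGEVVNYGIMTTSPAICIRTV"
)

# Positions of the catalytic slots within the P20 consensus (1-based).
.P20_HIS_SLOT <- 64L
.P20_CYS_SLOT <- 203L

.CONS_WD40 <- "YLRSKNSNAFTCCGATNSPNIDKRSMPSHIQLTCLLAYKS"
.CONS_PENTAPEPTIDE <- "SHNREEIDHRDTCKEENFYH"
.CONS_EZHEAT <- "ASDQAVVATERIIHLSNRSAEVMKFVIRLH"
.CONS_ANFRECEPTOR <-
  "NALYDDRTRVEAIVEASTKGGDVTGPPDLGRTLFVAKSELRKHLDYSMVGSINPESNVVY"
.CONS_GUN4 <- "NLPLAMSDVLEGLMCHLDTEMLFELPADGQMLCRDSELITVELLLPEPGP"
.CONS_NACHT <-
  "RGYVQKTGQQTVDNIQSSAEPVGGVYSPFNKRRRSGQSKLQAMSELYFKIHCRNEKGLGL"
.CONS_DUF323 <- "VNGWVFVSRKTIPGWRRISPTQHFLMLNPVANTTRYPQIIYVYKI"
.CONS_CHASE2 <- "AEMGAATGRSEYGDVADIDPKYAAVDVLLEAHMYWHGGSSTAEEMPELEL"
.CONS_DEXDC <- "ASFTKSVKYKFLFFYNNGSVTLVYFDRRIYEFRTGLILYAAQGLF"
.CONS_HELICC <- "ASGAPTKDHAERIIDVNPAQKYRNVVYNKELLYTFNMAVLRTVLT"

#' Build a log-odds profile model from a consensus sequence
#'
#' Each consensus position becomes a column of log2-odds scores against the
#' background frequencies, with the consensus residue given probability
#' `p_cons`. Positions named in `slots` distribute `p_cons` uniformly over an
#' allowed residue set, so tolerated substitutions score as well as the
#' canonical residue (used for the catalytic His/Cys slots of the P20 model).
#'
#' @param name model name (also used as the reported domain type).
#' @param consensus consensus protein string.
#' @param p_cons probability mass assigned to the consensus residue(s).
#' @param threshold_frac hit threshold as a fraction of the maximal window
#'   score.
#' @param expected_length expected full-domain length (metadata used by the
#'   strict-coverage option of [annotate()]); defaults to the model width.
#' @param slots named list: position (as character) -> allowed residue set.
#' @return an object of class `profile_model` with elements `name`, `scores`
#'   (residue x position log-odds matrix, `X` scoring 0), `threshold`,
#'   `max_score`, `expected_length`, `consensus`.
#' @export
profile_from_consensus <- function(name, consensus, p_cons = 0.6,
                                   threshold_frac = 0.5,
                                   expected_length = nchar(consensus),
                                   slots = list()) {
  .check_protein(consensus, "consensus", allow_x = FALSE)
  cols <- .residues(consensus)
  w <- length(cols)
  scores <- matrix(0, nrow = 21L, ncol = w,
                   dimnames = list(c(.AA20, "X"), NULL))
  for (i in seq_len(w)) {
    allowed <- slots[[as.character(i)]]
    if (is.null(allowed)) allowed <- cols[i]
    p <- .BG_FREQS * (1 - p_cons) / (1 - sum(.BG_FREQS[allowed]))
    p[allowed] <- p_cons / length(allowed)
    scores[.AA20, i] <- log2(p / .BG_FREQS)
  }
  max_score <- sum(apply(scores[.AA20, , drop = FALSE], 2, max))
  structure(list(name = name, scores = scores,
                 threshold = threshold_frac * max_score,
                 max_score = max_score,
                 expected_length = expected_length,
                 consensus = consensus),
            class = "profile_model")
}

#' @export
print.profile_model <- function(x, ...) {
  cat(sprintf("<profile_model %s: %d columns, threshold %.1f / max %.1f>\n",
              x$name, ncol(x$scores), x$threshold, x$max_score))
  invisible(x)
}

# Allowed residues at the two catalytic slots (canonical + tolerated).
.P20_SLOTS <- list("64" = c("H", "Y"), "203" = c("C", "S", "N", "Q", "G"))

#' Packaged P20 (CASc) profile models
#'
#' Two ~25%-divergent synthetic P20 profiles standing in for the alpha- and
#' beta-family catalytic-domain lineages. Both tolerate the catalytic-slot
#' substitutions (His->Tyr; Cys->Ser/Asn/Gln/Gly) at full score, so a
#' substituted dyad does not hide the domain.
#'
#' @param variant `"alpha"` or `"beta"`.
#' @return a `profile_model` (see [profile_from_consensus()]).
#' @export
p20_profile <- function(variant = c("alpha", "beta")) {
  variant <- match.arg(variant)
  cons <- if (variant == "alpha") .CONS_P20_ALPHA else .CONS_P20_BETA
  profile_from_consensus(paste0("CASc-", variant), cons,
                         threshold_frac = 0.3, slots = .P20_SLOTS)
}

.models_cache <- new.env(parent = emptyenv())

#' All packaged domain models
#'
#' @return a list with elements `p20` (alpha and beta CASc profiles),
#'   `repeats` (WD40, Pentapeptide and EZ-HEAT unit models, scanned with
#'   [detect_repeats()]) and `singles` (the seven single-copy accessory
#'   domain models).
#' @export
builtin_models <- function() {
  if (!is.null(.models_cache$models)) return(.models_cache$models)
  singles <- list(
    "ANF-receptor" = .CONS_ANFRECEPTOR, "GUN4" = .CONS_GUN4,
    "NACHT" = .CONS_NACHT, "DUF323" = .CONS_DUF323,
    "CHASE2" = .CONS_CHASE2, "DEXDc" = .CONS_DEXDC, "HELICc" = .CONS_HELICC)
  units <- list("WD40" = .CONS_WD40, "Pentapeptide" = .CONS_PENTAPEPTIDE,
                "EZ-HEAT" = .CONS_EZHEAT)
  m <- list(
    p20 = list(alpha = p20_profile("alpha"), beta = p20_profile("beta")),
    repeats = lapply(stats::setNames(names(units), names(units)),
                     function(nm) profile_from_consensus(nm, units[[nm]])),
    singles = lapply(stats::setNames(names(singles), names(singles)),
                     function(nm) profile_from_consensus(nm, singles[[nm]])))
  .models_cache$models <- m
  m
}

# Zero-row hit table with the DomainHit columns.
.empty_hits <- function() {
  data.frame(domain_type = character(), start = integer(), end = integer(),
             score = numeric(), copies = integer(), stringsAsFactors = FALSE)
}

#' Scan a sequence with a profile model
#'
#' Slides the model along the sequence; windows whose summed column scores
#' reach the model threshold are reported greedily by descending score,
#' without overlap. Coordinates are 1-based inclusive.
#'
#' @param sequence protein string.
#' @param model a `profile_model`.
#' @return data.frame of hits with columns `domain_type`, `start`, `end`,
#'   `score`, `copies` (always 1 here).
#' @export
scan_profile <- function(sequence, model) {
  if (!inherits(model, "profile_model") || ncol(model$scores) < 1L) {
    stop("invalid-model: profile model must have at least one column",
         call. = FALSE)
  }
  .check_protein(sequence)
  res <- .residues(sequence)
  idx <- match(res, rownames(model$scores))
  L <- length(res)
  w <- ncol(model$scores)
  if (L < w) return(.empty_hits())
  n_off <- L - w + 1L
  win <- numeric(n_off)
  for (j in seq_len(w)) {
    win <- win + model$scores[idx[j:(j + n_off - 1L)], j]
  }
  cand <- which(win >= model$threshold)
  if (!length(cand)) return(.empty_hits())
  cand <- cand[order(-win[cand], cand)]
  taken <- rep(FALSE, L)
  starts <- integer(0)
  for (o in cand) {
    span <- o:(o + w - 1L)
    if (!any(taken[span])) {
      taken[span] <- TRUE
      starts <- c(starts, o)
    }
  }
  starts <- sort(starts)
  data.frame(domain_type = model$name, start = starts,
             end = starts + w - 1L, score = win[starts], copies = 1L,
             stringsAsFactors = FALSE)
}

#' Count tandem repeat units
#'
#' Scans with a repeat-unit model and collapses the non-overlapping unit
#' hits into a single hit whose `copies` field is the unit count. Nothing is
#' reported below `min_copies`.
#'
#' @param sequence protein string.
#' @param repeat_model unit `profile_model` (e.g. `builtin_models()$repeats$WD40`).
#' @param min_copies minimum number of unit hits to report (default 3).
#' @return data.frame with zero rows or one row (`copies` = unit count,
#'   span covering the first to the last unit, score summed over units).
#' @export
detect_repeats <- function(sequence, repeat_model, min_copies = 3L) {
  hits <- scan_profile(sequence, repeat_model)
  if (nrow(hits) < min_copies) return(.empty_hits())
  data.frame(domain_type = repeat_model$name, start = min(hits$start),
             end = max(hits$end), score = sum(hits$score),
             copies = nrow(hits), stringsAsFactors = FALSE)
}
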