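# Shared residue-level constants.

# The 20 standard amino acids, one-letter codes.
.AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# UniProt-like background amino-acid frequencies (normalized).
.BG_FREQS <- local({
  f <- c(A = 0.0826, R = 0.0553, N = 0.0406, D = 0.0546, C = 0.0137,
         Q = 0.0393, E = 0.0674, G = 0.0708, H = 0.0227, I = 0.0593,
         L = 0.0966, K = 0.0582, M = 0.0241, F = 0.0386, P = 0.0472,
         S = 0.0660, T = 0.0535, W = 0.0110, Y = 0.0292, V = 0.0687)
  f / sum(f)
})

# Kyte-Doolittle hydropathy index.
.KD_HYDROPATHY <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
                    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
                    L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
                    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

# The ten accessory domain types that can be fused to a metacaspase
# (everything other than the CASc/P20 catalytic domain and TM segments).
.ADDITIONAL_DOMAIN_TYPES <- c("ANF-receptor", "WD40", "GUN4", "NACHT",
                              "DUF323", "CHASE2", "Pentapeptide", "DEXDc",
                              "HELICc", "EZ-HEAT")

# Domain types whose hits carry a repeat multiplicity.
.REPEAT_DOMAIN_TYPES <- c("WD40", "Pentapeptide", "EZ-HEAT")

#' Round half away from zero
#'
#' Fixed-point rounding where exact halves round up (0.125 -> 0.13 at two
#' digits), matching how percentages are conventionally printed in
#' comparative-genomics tables. Base `round()` rounds halves to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(0.125, 2)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Split a protein string into a character vector of residues.
.residues <- function(sequence) {
  strsplit(sequence, "", fixed = TRUE)[[1]]
}

# Validate a protein sequence over the 20-letter alphabet (+ optional X).
.check_protein <- function(sequence, what = "sequence", allow_x = TRUE) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      nchar(sequence) == 0L) {
    stop("invalid-input: ", what, " must be a non-empty protein string",
         call. = FALSE)
  }
  ok <- c(.AA20, if (allow_x) "X")
  bad <- setdiff(unique(.residues(sequence)), ok)
  if (length(bad)) {
    stop("invalid-alphabet: ", what, " contains unknown residue letter(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(sequence)
}

# Run code under a temporary RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
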