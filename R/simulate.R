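# Synthetic proteome generator.
#
# Stands in for a set of sequenced genomes: each simulated strain is a FASTA
# proteome of background-sampled decoys plus planted metacaspases of known
# subfamily, dyad state and accessory-domain cassette, together with a
# ground-truth table, so identification, annotation, classification and
# phylogeny can all be scored without any downloads.

#' Simulation configuration
#'
#' Defaults reflect the composition observed in the cyanobacterial census:
#' the family mix approximates the published subfamily proportions
#' (alpha-I 2%, alpha-TM 9%, alpha-other 34%, alpha-C 2%, beta 53%), the
#' dyad mutation rate the observed 17/58 share, and WD40 cassettes carry
#' 7-15 copies. Sizes (3 strains x 40 proteins x 4 planted metacaspases) are
#' a desk-scale stand-in for a multi-genome survey.
#'
#' @param seed integer seed; all randomness flows from it.
#' @param n_strains number of simulated strains.
#' @param proteins_per_strain proteins per strain (decoys + plants).
#' @param mca_per_strain planted metacaspases per strain.
#' @param family_mix named proportions over
#'   `c("alpha-I","alpha-TM","alpha-other","alpha-C","beta")`; must sum
#'   to 1.
#' @param dyad_mutation_rate probability that a planted dyad carries a
#'   tolerated substitution.
#' @param mutation_choices list with `his` and `cys` substitution sets
#'   (defaults: Tyr; Ser/Asn/Gln/Gly).
#' @param wd40_copy_range integer interval of WD40 copies per cassette,
#'   within \[1, 30\].
#' @param background amino-acid background frequencies (20 values, sum 1).
#' @param protein_length_range integer interval of decoy lengths.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_strains = 3L, proteins_per_strain = 40L,
                       mca_per_strain = 4L,
                       family_mix = c("alpha-I" = 0.02, "alpha-TM" = 0.09,
                                      "alpha-other" = 0.34, "alpha-C" = 0.02,
                                      "beta" = 0.53),
                       dyad_mutation_rate = 0.3,
                       mutation_choices = list(
                         his = "Tyr", cys = c("Ser", "Asn", "Gln", "Gly")),
                       wd40_copy_range = c(7L, 15L),
                       background = NULL,
                       protein_length_range = c(380L, 560L)) {
  if (is.null(background)) background <- .BG_FREQS
  if (!length(family_mix)) {
    stop("invalid-config: empty family_mix", call. = FALSE)
  }
  if (!all(names(family_mix) %in% c(.SUBFAMILIES, "beta"))) {
    stop("invalid-config: unknown family_mix labels", call. = FALSE)
  }
  if (abs(sum(family_mix) - 1) > 1e-9 || any(family_mix < 0)) {
    stop("invalid-config: family_mix must be non-negative and sum to 1",
         call. = FALSE)
  }
  if (n_strains < 0 || proteins_per_strain < 0 || mca_per_strain < 0) {
    stop("invalid-config: counts must be >= 0", call. = FALSE)
  }
  if (mca_per_strain > proteins_per_strain) {
    stop("invalid-config: mca_per_strain exceeds proteins_per_strain",
         call. = FALSE)
  }
  if (wd40_copy_range[1] < 1 || wd40_copy_range[2] > 30 ||
      wd40_copy_range[1] > wd40_copy_range[2]) {
    stop("invalid-config: wd40_copy_range must lie within [1, 30]",
         call. = FALSE)
  }
  if (dyad_mutation_rate < 0 || dyad_mutation_rate > 1) {
    stop("invalid-config: dyad_mutation_rate must be in [0, 1]",
         call. = FALSE)
  }
  if (length(background) != 20L || any(background < 0) ||
      abs(sum(background) - 1) > 1e-6) {
    stop("invalid-config: background must be 20 non-negative frequencies",
         " summing to 1", call. = FALSE)
  }
  names(background) <- .AA20
  structure(list(seed = as.integer(seed), n_strains = as.integer(n_strains),
                 proteins_per_strain = as.integer(proteins_per_strain),
                 mca_per_strain = as.integer(mca_per_strain),
                 family_mix = family_mix,
                 dyad_mutation_rate = dyad_mutation_rate,
                 mutation_choices = mutation_choices,
                 wd40_copy_range = as.integer(wd40_copy_range),
                 background = background,
                 protein_length_range = as.integer(protein_length_range)),
            class = "sim_config")
}

#' Plant a P20 cassette with a chosen dyad state
#'
#' Returns the packaged P20 consensus (pure consensus, no per-position
#' sampling, so plants are maximally detectable and the cassette is
#' deterministic) with the catalytic slots set to the requested states.
#'
#' @param his_state `"intact"` or `"Tyr"`.
#' @param cys_state `"intact"`, `"Ser"`, `"Asn"`, `"Gln"` or `"Gly"`.
#' @param variant which P20 lineage consensus to use (`"alpha"`/`"beta"`).
#' @return list with `segment` (340-aa string), `his_position` and
#'   `cys_position` (1-based slot indices within the segment).
#' @export
#' @examples
#' cass <- plant_p20_cassette("Tyr", "Ser")
#' scan_dyad(cass$segment)
plant_p20_cassette <- function(his_state = "intact", cys_state = "intact",
                               variant = c("alpha", "beta")) {
  variant <- match.arg(variant)
  his_ok <- c(intact = "H", Tyr = "Y")
  cys_ok <- c(intact = "C", Ser = "S", Asn = "N", Gln = "Q", Gly = "G")
  if (!his_state %in% names(his_ok)) {
    stop("invalid-spec: unknown his_state '", his_state, "'", call. = FALSE)
  }
  if (!cys_state %in% names(cys_ok)) {
    stop("invalid-spec: unknown cys_state '", cys_state, "'", call. = FALSE)
  }
  cons <- if (variant == "alpha") .CONS_P20_ALPHA else .CONS_P20_BETA
  v <- .residues(cons)
  v[.P20_HIS_SLOT] <- his_ok[[his_state]]
  v[.P20_CYS_SLOT] <- cys_ok[[cys_state]]
  list(segment = paste(v, collapse = ""),
       his_position = .P20_HIS_SLOT, cys_position = .P20_CYS_SLOT)
}

.sample_bg <- function(n, bg) {
  if (n <= 0L) return("")
  paste(sample(names(bg), n, replace = TRUE, prob = bg), collapse = "")
}

# TRUE when a His context and a Cys context co-occur within `dist` residues.
.has_dyad_pair <- function(s, dist = 40L) {
  h <- gregexpr("(?=[YF]SG.G)", s, perl = TRUE)[[1]]
  cc <- gregexpr("(?=QA.[RQ]G)", s, perl = TRUE)[[1]]
  if (h[1] == -1L || cc[1] == -1L) return(FALSE)
  any(abs(outer(as.integer(h), as.integer(cc), "-")) <= dist)
}

.has_tm_window <- function(s, window = 19L, threshold = 1.6) {
  nrow(detect_tm(s, window = window, threshold = threshold)) > 0L
}

# Background segment free of dyad contexts (and, optionally, of
# transmembrane-like hydropathy windows); used for decoy bodies and the
# flanks of planted proteins.
.clean_segment <- function(n, bg, forbid_tm = TRUE, forbid_any_context = TRUE,
                           max_tries = 200L) {
  if (n <= 0L) return("")
  for (i in seq_len(max_tries)) {
    s <- .sample_bg(n, bg)
    bad_ctx <- if (forbid_any_context) {
      grepl("[YF]SG.G", s) || grepl("QA.[RQ]G", s)
    } else .has_dyad_pair(s)
    if (!bad_ctx && (!forbid_tm || !.has_tm_window(s))) return(s)
  }
  stop("could not sample a clean background segment", call. = FALSE)
}

# Strongly hydrophobic 25-residue segment (cannot form a dyad context).
.tm_segment <- function() {
  paste(sample(c("I", "L", "V", "F", "A", "M"), 25, replace = TRUE,
               prob = c(.3, .25, .2, .1, .1, .05)), collapse = "")
}

# Accessory-domain cassette menu for beta-family plants, with weights
# loosely following the observed census (WD40 dominant; NACHT always fused
# to a WD40 cassette; DEXDc and HELICc fused together).
.beta_cassette <- function(cfg) {
  arch_kind <- sample(c("WD40", "DUF323", "GUN4", "Pentapeptide",
                        "NACHT+WD40", "DEXDc+HELICc", "CHASE2",
                        "ANF-receptor", "EZ-HEAT"), 1,
                      prob = c(.50, .12, .07, .07, .06, .05, .04, .04, .05))
  wd_copies <- function() sample(cfg$wd40_copy_range[1]:cfg$wd40_copy_range[2], 1)
  dom <- switch(arch_kind,
    "WD40" = data.frame(domain_type = "WD40", copies = wd_copies()),
    "DUF323" = data.frame(domain_type = "DUF323", copies = 1L),
    "GUN4" = data.frame(domain_type = "GUN4", copies = 1L),
    "Pentapeptide" = data.frame(domain_type = "Pentapeptide",
                                copies = sample(3:4, 1)),
    "NACHT+WD40" = data.frame(domain_type = c("NACHT", "WD40"),
                              copies = c(1L, wd_copies())),
    "DEXDc+HELICc" = data.frame(domain_type = c("DEXDc", "HELICc"),
                                copies = c(1L, 1L)),
    "CHASE2" = data.frame(domain_type = "CHASE2", copies = 1L),
    "ANF-receptor" = data.frame(domain_type = "ANF-receptor", copies = 1L),
    "EZ-HEAT" = data.frame(domain_type = "EZ-HEAT", copies = 15L))
  dom
}

.domain_consensus <- function(type) {
  switch(type,
         "WD40" = .CONS_WD40, "Pentapeptide" = .CONS_PENTAPEPTIDE,
         "EZ-HEAT" = .CONS_EZHEAT, "ANF-receptor" = .CONS_ANFRECEPTOR,
         "GUN4" = .CONS_GUN4, "NACHT" = .CONS_NACHT,
         "DUF323" = .CONS_DUF323, "CHASE2" = .CONS_CHASE2,
         "DEXDc" = .CONS_DEXDC, "HELICc" = .CONS_HELICC,
         stop("unknown domain type ", type, call. = FALSE))
}

# Sequence of an accessory cassette: tandem consensus copies per domain,
# short clean linkers between domains.
.cassette_sequence <- function(dom, bg) {
  parts <- vapply(seq_len(nrow(dom)), function(i) {
    strrep(.domain_consensus(dom$domain_type[i]), dom$copies[i])
  }, character(1))
  paste(parts, collapse = .clean_segment(6L, bg))
}

# One planted metacaspase; returns sequence + truth fields.
.plant_protein <- function(subfamily, cfg) {
  mutated <- stats::runif(1) < cfg$dyad_mutation_rate
  his_state <- "intact"; cys_state <- "intact"
  if (mutated) {
    cys_state <- sample(cfg$mutation_choices$cys, 1)
    if (stats::runif(1) < 0.85) his_state <- sample(cfg$mutation_choices$his, 1)
  }
  variant <- if (subfamily == "beta") "beta" else "alpha"
  cass <- plant_p20_cassette(his_state, cys_state, variant = variant)
  bg <- cfg$background
  dom <- parse_architecture("")
  repeat {
    if (subfamily == "alpha-I") {
      nterm <- sample(0:10, 1)
      tail <- .clean_segment(sample(max(nterm + 1L, 15L):45L, 1), bg)
    } else if (subfamily == "alpha-TM") {
      nterm <- sample(0:10, 1)
      tail <- paste0(.clean_segment(8L, bg), .tm_segment(),
                     .clean_segment(8L, bg))
    } else if (subfamily == "alpha-other") {
      nterm <- sample(0:30, 1)
      tail <- .clean_segment(sample(60:180, 1), bg)
    } else if (subfamily == "alpha-C") {
      nterm <- sample(60:180, 1)
      tail <- .clean_segment(sample(0:10, 1), bg)
    } else if (subfamily == "beta") {
      nterm <- sample(0:20, 1)
      dom <- .beta_cassette(cfg)
      tail <- paste0(.clean_segment(10L, bg), .cassette_sequence(dom, bg),
                     .clean_segment(10L, bg))
    } else stop("unknown subfamily ", subfamily, call. = FALSE)
    seq <- paste0(.clean_segment(nterm, bg), cass$segment, tail)
    # re-draw if flank junctions created an unplanted TM-like window
    planted_tm <- subfamily == "alpha-TM"
    if (planted_tm || !.has_tm_window(seq)) break
  }
  list(sequence = seq, family = subfamily, his_state = his_state,
       cys_state = cys_state, mutated = mutated,
       domains = render_architecture(dom),
       p20_start = nterm + 1L, p20_end = nterm + nchar(cass$segment))
}

#' Generate synthetic strain proteomes with planted metacaspases
#'
#' Deterministic for a fixed seed. Each strain receives
#' `proteins_per_strain` proteins of which `mca_per_strain` are planted
#' metacaspases (subfamily drawn from `family_mix`, dyad substituted with
#' probability `dyad_mutation_rate`, beta plants carrying an
#' accessory-domain cassette); the rest are background decoys that contain
#' no P20 cassette and never both dyad contexts within 40 residues of each
#' other.
#'
#' @param config a [sim_config()].
#' @return an object of class `mca_simulation`: `proteomes` (per-strain
#'   named character vectors), `truth` (data.frame `gene_id`, `strain`,
#'   `is_mca`, `family`, `his_state`, `cys_state`, `domains`, `p20_start`,
#'   `p20_end`), `n_mutated_planted` (generator's own count of substituted
#'   planted dyads), `config`.
#' @export
generate_proteome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed, {
    proteomes <- list()
    truth_rows <- list()
    n_mutated <- 0L
    for (s in seq_len(config$n_strains)) {
      strain <- sprintf("strain%02d", s)
      ids <- sprintf("%s_g%03d", strain, seq_len(config$proteins_per_strain))
      mca_idx <- sort(sample(seq_len(config$proteins_per_strain),
                             config$mca_per_strain))
      seqs <- character(config$proteins_per_strain)
      for (i in seq_len(config$proteins_per_strain)) {
        if (i %in% mca_idx) {
          subfam <- sample(names(config$family_mix), 1,
                           prob = config$family_mix)
          p <- .plant_protein(subfam, config)
          seqs[i] <- p$sequence
          n_mutated <- n_mutated + as.integer(p$mutated)
          truth_rows[[length(truth_rows) + 1L]] <- data.frame(
            gene_id = ids[i], strain = strain, is_mca = TRUE,
            family = p$family, his_state = p$his_state,
            cys_state = p$cys_state, domains = p$domains,
            p20_start = p$p20_start, p20_end = p$p20_end,
            stringsAsFactors = FALSE)
        } else {
          n <- sample(config$protein_length_range[1]:
                        config$protein_length_range[2], 1)
          seqs[i] <- .clean_segment(n, config$background, forbid_tm = FALSE,
                                    forbid_any_context = FALSE)
          truth_rows[[length(truth_rows) + 1L]] <- data.frame(
            gene_id = ids[i], strain = strain, is_mca = FALSE,
            family = NA_character_, his_state = NA_character_,
            cys_state = NA_character_, domains = "",
            p20_start = NA_integer_, p20_end = NA_integer_,
            stringsAsFactors = FALSE)
        }
      }
      proteomes[[strain]] <- stats::setNames(seqs, ids)
    }
    structure(list(proteomes = proteomes,
                   truth = do.call(rbind, truth_rows),
                   n_mutated_planted = n_mutated, config = config),
              class = "mca_simulation")
  })
}

#' @export
print.mca_simulation <- function(x, ...) {
  cat(sprintf("<mca_simulation: %d strains x %d proteins, %d planted MCAs>\n",
              length(x$proteomes), x$config$proteins_per_strain,
              sum(x$truth$is_mca)))
  invisible(x)
}

#' Packaged seed query set
#'
#' Two deterministic query proteins, one per P20 lineage consensus, playing
#' the role of the proven metacaspases used to start the iterative search.
#'
#' @return named character vector of length 2.
#' @export
seed_query_set <- function() {
  .with_seed(990331L, {
    bg <- .BG_FREQS
    mk <- function(variant) {
      paste0(.clean_segment(12L, bg),
             plant_p20_cassette("intact", "intact", variant)$segment,
             .clean_segment(60L, bg))
    }
    c(query_alpha = mk("alpha"), query_beta = mk("beta"))
  })
}

#' Write a simulation to disk
#'
#' One FASTA per strain (`<strain>.fasta`) plus `truth.tsv`; output is
#' byte-stable for a fixed simulation.
#'
#' @param sim an [generate_proteome()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_proteome <- function(sim, dir) {
  stopifnot(inherits(sim, "mca_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (strain in names(sim$proteomes)) {
    p <- file.path(dir, paste0(strain, ".fasta"))
    seqs <- sim$proteomes[[strain]]
    writeLines(as.vector(rbind(paste0(">", names(seqs)), unname(seqs))), p)
    paths <- c(paths, p)
  }
  tp <- file.path(dir, "truth.tsv")
  utils::write.table(sim$truth, tp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(paths, tp))
}

#' Read strain proteomes from FASTA files
#'
#' @param dir directory holding one `*.fasta` per strain.
#' @return named list (strain = file stem) of named character vectors.
#' @export
read_proteome_fasta <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.fasta$", full.names = TRUE))
  if (!length(files)) stop("no .fasta files found in ", dir, call. = FALSE)
  out <- lapply(files, function(f) {
    x <- Biostrings::readAAStringSet(f)
    stats::setNames(as.character(x), names(x))
  })
  stats::setNames(out, sub("\\.fasta$", "", basename(files)))
}
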