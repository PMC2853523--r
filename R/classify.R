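.SUBFAMILIES <- c("alpha-I", "alpha-TM", "alpha-other", "alpha-C")

#' Acceptance rule for a putative metacaspase
#'
#' A protein is accepted when its architecture contains a P20 (CASc) hit and
#' both catalytic sites are present: intact, or carrying a tolerated
#' substitution (His->Tyr; Cys->Ser/Asn/Gln/Gly). In strict mode both sites
#' must be intact.
#'
#' @param architecture a [annotate()] result.
#' @param dyad a [scan_dyad()] result for the same gene.
#' @param strict require an intact dyad.
#' @return list with `accepted` (logical) and `reason` (`"none"`,
#'   `"no-P20"`, `"dyad-absent"`, or `"dyad-substituted-strict"`).
#' @export
validate_metacaspase <- function(architecture, dyad, strict = FALSE) {
  if (is.null(.p20_hit(architecture))) {
    return(list(accepted = FALSE, reason = "no-P20"))
  }
  if (dyad$his_state == "absent" || dyad$cys_state == "absent") {
    return(list(accepted = FALSE, reason = "dyad-absent"))
  }
  if (strict && (dyad$his_state != "intact" || dyad$cys_state != "intact")) {
    return(list(accepted = FALSE, reason = "dyad-substituted-strict"))
  }
  list(accepted = TRUE, reason = "none")
}

#' Assign the alpha/beta family and alpha subfamily
#'
#' A metacaspase with at least one accessory domain (of the ten recognized
#' types; transmembrane segments do not count) is family beta. Otherwise it
#' is family alpha, with subfamily by precedence: `alpha-C` when the CASc
#' domain sits in the C-terminal half; else `alpha-TM` when a TM segment is
#' present; else `alpha-other` when an unannotated C-terminal extension of
#' at least `extension_min` residues follows the P20 hit; else `alpha-I`
#' (catalytic domain only).
#'
#' @param architecture a [annotate()] result containing a P20 hit.
#' @param extension_min minimum C-terminal extension, in residues, for
#'   `alpha-other` (default 50).
#' @return list with `family` (`"alpha"`/`"beta"`) and `subfamily`
#'   (one of `alpha-I`, `alpha-TM`, `alpha-other`, `alpha-C`, or `NA` for
#'   family beta).
#' @export
assign_family <- function(architecture, extension_min = 50L) {
  p20 <- .p20_hit(architecture)
  if (is.null(p20)) {
    stop("not-a-metacaspase: architecture has no P20 hit", call. = FALSE)
  }
  if (nrow(.additional_hits(architecture))) {
    return(list(family = "beta", subfamily = NA_character_))
  }
  sub <- if (architecture$casc_position == "C-terminal") "alpha-C"
  else if (architecture$has_tm) "alpha-TM"
  else if (architecture$length - p20$end >= extension_min) "alpha-other"
  else "alpha-I"
  list(family = "alpha", subfamily = sub)
}

#' Full per-protein classification
#'
#' Convenience wrapper: annotates the sequence, scans the dyad within the
#' P20 span (whole sequence when no P20 hit), applies the acceptance rule
#' and, when accepted, the family rule.
#'
#' @param sequence protein string.
#' @param gene_id identifier carried into the result.
#' @param strain strain label carried into the result.
#' @param models model set from [builtin_models()].
#' @param strict strict acceptance (see [validate_metacaspase()]).
#' @param extension_min see [assign_family()].
#' @param ... further arguments to [annotate()].
#' @return one-row data.frame: `gene_id`, `strain`, `accepted`, `reason`,
#'   `family`, `subfamily`, `his_state`, `cys_state`, `mutated`, `sites`,
#'   `domains` (rendered accessory architecture), `p20_start`, `p20_end`.
#' @export
classify_protein <- function(sequence, gene_id = NA_character_,
                             strain = NA_character_,
                             models = builtin_models(), strict = FALSE,
                             extension_min = 50L, ...) {
  arch <- annotate(sequence, gene_id = gene_id, models = models, ...)
  p20 <- .p20_hit(arch)
  span <- if (is.null(p20)) NULL else c(p20$start, p20$end)
  dyad <- scan_dyad(sequence, span = span)
  v <- validate_metacaspase(arch, dyad, strict = strict)
  fam <- list(family = NA_character_, subfamily = NA_character_)
  if (v$accepted) fam <- assign_family(arch, extension_min = extension_min)
  add <- .additional_hits(arch)
  data.frame(gene_id = gene_id, strain = strain, accepted = v$accepted,
             reason = v$reason, family = fam$family,
             subfamily = fam$subfamily, his_state = dyad$his_state,
             cys_state = dyad$cys_state, mutated = dyad$mutated,
             sites = render_sites(dyad),
             domains = render_architecture(add),
             p20_start = if (is.null(p20)) NA_integer_ else p20$start,
             p20_end = if (is.null(p20)) NA_integer_ else p20$end,
             stringsAsFactors = FALSE)
}

#' Per-strain and global metacaspase summary
#'
#' Reconstructs the comparative census from a classification table: per
#' strain, the metacaspase count, its percentage of the proteome (half-up to
#' two decimals), the number of genes with substituted catalytic sites and
#' the accessory-domain total after repeat expansion; globally, the family
#' split, the beta share (half-up to one decimal), the accessory-domain type
#' inventory, per-type copy totals and the per-protein WD40 copy range.
#'
#' @param records data.frame of accepted metacaspases with columns
#'   `gene_id`, `strain`, `family` (`"alpha"`/`"beta"`), `subfamily`,
#'   `mutated` (logical), `domains` (architecture string).
#' @param strain_meta data.frame with columns `strain` and `total_proteins`
#'   covering every strain in `records` (strains without records are
#'   reported with zero counts).
#' @return list with `per_strain` (data.frame `strain`, `total_proteins`,
#'   `n_mca`, `pct_mca`, `n_mutated`, `n_additional_domains`) and `totals`
#'   (list: `n_total`, `n_alpha`, `n_beta`, `pct_beta`, per-subfamily
#'   counts, `n_mutated`, `domain_types`, `n_domain_types`,
#'   `n_additional_domains`, `per_type_totals`, `wd40_copy_min`,
#'   `wd40_copy_max`).
#' @export
summarize_mca <- function(records, strain_meta) {
  stopifnot(is.data.frame(records), is.data.frame(strain_meta),
            all(c("strain", "total_proteins") %in% names(strain_meta)))
  missing <- setdiff(unique(records$strain), strain_meta$strain)
  if (length(missing)) {
    stop("missing-strain: no metadata for strain(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  parsed <- lapply(records$domains, parse_architecture)
  n_copies <- vapply(parsed, function(d) sum(d$copies), numeric(1))

  per <- strain_meta[, c("strain", "total_proteins")]
  idx <- split(seq_len(nrow(records)), records$strain)
  per$n_mca <- vapply(per$strain, function(s) length(idx[[s]]), integer(1))
  per$pct_mca <- round_half_up(100 * per$n_mca / per$total_proteins, 2)
  per$n_mutated <- vapply(per$strain, function(s) {
    sum(records$mutated[idx[[s]]])
  }, numeric(1))
  per$n_additional_domains <- vapply(per$strain, function(s) {
    sum(n_copies[idx[[s]]])
  }, numeric(1))

  all_domains <- do.call(rbind, c(parsed, list(parse_architecture(""))))
  per_type <- if (nrow(all_domains)) {
    tapply(all_domains$copies, all_domains$domain_type, sum)
  } else numeric(0)
  wd40 <- all_domains$copies[all_domains$domain_type == "WD40"]
  n_total <- nrow(records)
  n_beta <- sum(records$family == "beta")
  totals <- list(
    n_total = n_total,
    n_alpha = sum(records$family == "alpha"),
    n_beta = n_beta,
    pct_beta = if (n_total) round_half_up(100 * n_beta / n_total, 1) else 0,
    n_alpha_I = sum(records$subfamily %in% "alpha-I"),
    n_alpha_TM = sum(records$subfamily %in% "alpha-TM"),
    n_alpha_other = sum(records$subfamily %in% "alpha-other"),
    n_alpha_C = sum(records$subfamily %in% "alpha-C"),
    n_mutated = sum(records$mutated),
    domain_types = sort(unique(all_domains$domain_type)),
    n_domain_types = length(unique(all_domains$domain_type)),
    n_additional_domains = sum(all_domains$copies),
    per_type_totals = per_type,
    wd40_copy_min = if (length(wd40)) min(wd40) else NA_integer_,
    wd40_copy_max = if (length(wd40)) max(wd40) else NA_integer_)
  list(per_strain = per, totals = totals)
}
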