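# Packaged census fixtures: the published per-gene metacaspase table and the
# per-strain metadata table, stored as plain TSV under inst/extdata.

.FAMILY_LABELS <- c("cbMCa-I" = "alpha-I", "cbMCa-TM" = "alpha-TM",
                    "cbMCa-other" = "alpha-other", "cbMCa-C" = "alpha-C",
                    "cbMCb" = "beta")

#' Path to a packaged fixture file
#'
#' @param file file name under the package's `extdata` directory.
#' @return absolute path.
#' @export
mca_fixture_path <- function(file = "table2_mca.tsv") {
  p <- system.file("extdata", file, package = "cbmca")
  if (!nzchar(p)) stop("fixture not found: ", file, call. = FALSE)
  p
}

#' Load the per-gene metacaspase census fixture
#'
#' The packaged table lists the 58 published cyanobacterial metacaspases
#' (gene identifier, strain, family/subfamily label, substituted-site string,
#' accessory-domain architecture, free-text annotation). Site and
#' architecture strings are parsed on load; the derived `family`,
#' `subfamily`, `his_state`, `cys_state` and `mutated` columns feed
#' [summarize_mca()] directly. A gene is counted as dyad-substituted exactly
#' when its printed site string is non-empty.
#'
#' @param path TSV path (defaults to the packaged fixture).
#' @return data.frame with one row per gene.
#' @export
load_table2_fixture <- function(path = mca_fixture_path("table2_mca.tsv")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = NULL)
  need <- c("gene_id", "strain", "family", "sites", "domains", "annotation")
  if (!identical(names(df), need)) {
    stop("fixture must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!nrow(df)) {
    warning("empty fixture: zero records loaded")
    df$subfamily <- df$his_state <- df$cys_state <- character(0)
    df$mutated <- logical(0)
    return(df)
  }
  for (r in seq_len(nrow(df))) {
    if (!df$family[r] %in% names(.FAMILY_LABELS)) {
      stop("row ", r, ": unknown family label '", df$family[r], "'",
           call. = FALSE)
    }
    states <- tryCatch(parse_sites(df$sites[r]), error = function(e) {
      stop("row ", r, ": ", conditionMessage(e), call. = FALSE)
    })
    tryCatch(parse_architecture(df$domains[r]), error = function(e) {
      stop("row ", r, ": ", conditionMessage(e), call. = FALSE)
    })
    df$his_state[r] <- states$his_state
    df$cys_state[r] <- states$cys_state
  }
  lbl <- .FAMILY_LABELS[df$family]
  df$subfamily <- ifelse(lbl == "beta", NA_character_, unname(lbl))
  df$family <- ifelse(lbl == "beta", "beta", "alpha")
  df$mutated <- nzchar(df$sites)
  df
}

#' Load the per-strain metadata fixture
#'
#' Strain name, habitat descriptor, proteome size, and the published
#' per-strain census values (metacaspase count, percentage, substituted-dyad
#' count, accessory-domain total) for the 33 surveyed genomes.
#'
#' @param path TSV path (defaults to the packaged fixture).
#' @return data.frame with one row per strain.
#' @export
load_strain_table <- function(path = mca_fixture_path("table1_strains.tsv")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  need <- c("strain", "key_feature", "total_proteins", "n_mca", "pct_mca",
            "n_mutated", "n_additional_domains")
  if (!identical(names(df), need)) {
    stop("strain table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df
}
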