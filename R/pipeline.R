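# End-to-end orchestration: configuration, the two execution modes
# (fixture and sequence), structured logging, and report emission.

#' Pipeline configuration
#'
#' Flat configuration for [run_pipeline()]. Two execution modes are
#' supported: `"fixture"` replays the packaged published census tables
#' (sequence-level stages are disabled), `"sequence"` runs the full
#' search -> annotate -> dyad -> classify -> summarize -> phylogeny chain on
#' strain FASTA proteomes.
#'
#' @param mode `"fixture"` or `"sequence"`.
#' @param out_dir output directory for the report bundle.
#' @param fixture_table2,fixture_table1 fixture TSV paths (fixture mode).
#' @param fasta_dir directory with one `<strain>.fasta` per strain
#'   (sequence mode).
#' @param round_thresholds,max_rounds see [search_config()].
#' @param extension_min see [assign_family()].
#' @param tm_window,tm_threshold see [detect_tm()].
#' @param distance_model,deletion see [distances()].
#' @param bootstrap_replicates bootstrap replicates for the tree (0 emits
#'   the point tree without supports).
#' @param seed integer seed for the bootstrap resampling.
#' @param strict strict dyad acceptance (see [validate_metacaspase()]).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("fixture", "sequence"),
                            out_dir = tempfile("mca_run_"),
                            fixture_table2 = mca_fixture_path("table2_mca.tsv"),
                            fixture_table1 = mca_fixture_path("table1_strains.tsv"),
                            fasta_dir = NULL,
                            round_thresholds = c(1e-10, 1e-10, 2e-20),
                            max_rounds = 20L,
                            extension_min = 50L,
                            tm_window = 19L,
                            tm_threshold = 1.6,
                            distance_model = c("poisson", "p-distance"),
                            deletion = c("pairwise", "complete"),
                            bootstrap_replicates = 200L,
                            seed = 1L,
                            strict = FALSE) {
  mode <- match.arg(mode)
  distance_model <- match.arg(distance_model)
  deletion <- match.arg(deletion)
  if (mode == "sequence" && is.null(fasta_dir)) {
    stop("invalid-config: sequence mode requires fasta_dir", call. = FALSE)
  }
  if (bootstrap_replicates < 0) {
    stop("invalid-config: bootstrap_replicates must be >= 0", call. = FALSE)
  }
  if (extension_min < 0) {
    stop("invalid-config: extension_min must be >= 0", call. = FALSE)
  }
  if (tm_window < 1 || tm_threshold <= 0) {
    stop("invalid-config: tm_window must be >= 1 and tm_threshold > 0",
         call. = FALSE)
  }
  search_config(round_thresholds, max_rounds)  # validates the search fields
  structure(list(mode = mode, out_dir = out_dir,
                 fixture_table2 = fixture_table2,
                 fixture_table1 = fixture_table1,
                 fasta_dir = fasta_dir,
                 round_thresholds = round_thresholds,
                 max_rounds = as.integer(max_rounds),
                 extension_min = as.integer(extension_min),
                 tm_window = as.integer(tm_window),
                 tm_threshold = tm_threshold,
                 distance_model = distance_model, deletion = deletion,
                 bootstrap_replicates = as.integer(bootstrap_replicates),
                 seed = as.integer(seed), strict = strict),
            class = "pipeline_config")
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Validation callback used by the sequence-mode search: a candidate is a
# genuine metacaspase when it carries a P20 hit with an acceptable dyad.
.make_validator <- function(config, models) {
  function(gene_id, sequence) {
    arch <- annotate(sequence, gene_id = gene_id, models = models,
                     tm_window = config$tm_window,
                     tm_threshold = config$tm_threshold)
    p20 <- .p20_hit(arch)
    span <- if (is.null(p20)) NULL else c(p20$start, p20$end)
    dyad <- scan_dyad(sequence, span = span)
    validate_metacaspase(arch, dyad, strict = config$strict)$accepted
  }
}

#' Run the full pipeline and write a report bundle
#'
#' Fixture mode loads the packaged per-gene census and strain metadata and
#' reproduces the comparative summary. Sequence mode runs the iterative
#' homology search from the packaged seed queries over the FASTA proteomes,
#' annotates and classifies every accepted hit, summarizes per strain, then
#' aligns the hits' catalytic regions and emits a bootstrapped
#' neighbor-joining tree. Outputs (classification TSV, strain-summary TSV,
#' newick tree in sequence mode, search log, run log) are byte-stable for a
#' fixed config and seed.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list: `classification` (data.frame),
#'   `summary` (see [summarize_mca()]), `tree` (`phylo` or `NULL`),
#'   `search` (sequence mode only), `paths` (named vector of files written),
#'   `log` (character vector of log lines).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  inputs <- if (config$mode == "fixture") {
    c(config$fixture_table2, config$fixture_table1)
  } else config$fasta_dir
  missing <- inputs[!file.exists(inputs)]
  if (length(missing)) {
    stop("invalid-config: missing input(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  note <- function(...) log_lines[[length(log_lines) + 1L]] <<- sprintf(...)
  note("mode=%s", config$mode)
  paths <- character(0)
  tree <- NULL
  search <- NULL

  if (config$mode == "fixture") {
    records <- load_table2_fixture(config$fixture_table2)
    strains <- load_strain_table(config$fixture_table1)
    note("stage=load records_in=%d strains=%d", nrow(records), nrow(strains))
    smry <- summarize_mca(records, strains)
    note("stage=summarize n_total=%d n_alpha=%d n_beta=%d",
         smry$totals$n_total, smry$totals$n_alpha, smry$totals$n_beta)
    note("stage=phylogeny skipped (fixture mode has no sequences)")
    classification <- records
  } else {
    proteomes <- read_proteome_fasta(config$fasta_dir)
    strain_of <- rep(names(proteomes), lengths(proteomes))
    database <- unlist(unname(proteomes))
    names(strain_of) <- names(database)
    if (anyDuplicated(names(database))) {
      stop("invalid-input: duplicate gene ids across proteomes",
           call. = FALSE)
    }
    note("stage=load strains=%d proteins=%d", length(proteomes),
         length(database))

    models <- builtin_models()
    search <- iterative_search(
      seed_query_set(), database,
      config = search_config(config$round_thresholds, config$max_rounds),
      scheme = scoring_scheme(),
      validate = .make_validator(config, models))
    note("stage=search rounds=%d hits=%d converged=%s",
         search$rounds, length(search$hits), search$converged)
    note("stage=search excluded=%d (below threshold or lacking catalytic domain)",
         length(database) - length(search$hits))

    classification <- do.call(rbind, lapply(search$hits, function(gid) {
      classify_protein(database[[gid]], gene_id = gid,
                       strain = strain_of[[gid]], models = models,
                       strict = config$strict,
                       extension_min = config$extension_min,
                       tm_window = config$tm_window,
                       tm_threshold = config$tm_threshold)
    }))
    if (is.null(classification)) {
      classification <- classify_protein(strrep("A", 10))[0, ]
    }
    note("stage=classify in=%d accepted=%d", nrow(classification),
         sum(classification$accepted))

    strain_meta <- data.frame(strain = names(proteomes),
                              total_proteins = lengths(proteomes),
                              stringsAsFactors = FALSE, row.names = NULL)
    accepted <- classification[classification$accepted, , drop = FALSE]
    smry <- summarize_mca(accepted, strain_meta)
    note("stage=summarize n_total=%d n_alpha=%d n_beta=%d",
         smry$totals$n_total, smry$totals$n_alpha, smry$totals$n_beta)

    if (nrow(accepted) >= 3L) {
      p20_seqs <- stats::setNames(
        substr(database[accepted$gene_id], accepted$p20_start,
               accepted$p20_end),
        accepted$gene_id)
      msa <- progressive_align(p20_seqs)
      if (config$bootstrap_replicates == 0L || nrow(accepted) < 4L) {
        tree <- nj_tree(distances(msa, model = config$distance_model,
                                  deletion = config$deletion))
        note("stage=phylogeny tips=%d bootstrap skipped (replicates=%d)",
             nrow(accepted), config$bootstrap_replicates)
      } else {
        tree <- bootstrap_support(msa,
                                  n_replicates = config$bootstrap_replicates,
                                  seed = config$seed,
                                  model = config$distance_model,
                                  deletion = config$deletion)
        note("stage=phylogeny tips=%d replicates=%d skipped_replicates=%d",
             nrow(accepted), attr(tree, "n_replicates"),
             attr(tree, "n_skipped"))
      }
    } else {
      note("stage=phylogeny skipped (fewer than 3 accepted hits)")
    }
    paths["search_log"] <- .write_tsv(search$log,
                                      file.path(config$out_dir,
                                                "search_log.tsv"))
  }

  paths["classification"] <- .write_tsv(
    classification, file.path(config$out_dir, "classification.tsv"))
  paths["strain_summary"] <- .write_tsv(
    smry$per_strain, file.path(config$out_dir, "strain_summary.tsv"))
  if (!is.null(tree)) {
    tp <- file.path(config$out_dir, "tree.nwk")
    writeLines(to_newick(tree), tp)
    paths["tree"] <- tp
  }
  lp <- file.path(config$out_dir, "run_log.txt")
  writeLines(log_lines, lp)
  paths["run_log"] <- lp

  invisible(list(classification = classification, summary = smry,
                 tree = tree, search = search, paths = paths,
                 log = log_lines))
}
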