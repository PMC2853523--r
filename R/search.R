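#' Iterative-search configuration
#'
#' Round-structured E-value ceilings for the query-expansion search: the
#' published procedure uses 1e-10 for the first two rounds and 2e-20
#' afterwards; rounds beyond the end of the list reuse its last entry.
#'
#' @param round_thresholds positive E-value ceilings by round.
#' @param max_rounds maximum number of rounds (>= 1).
#' @return an object of class `search_config`.
#' @export
search_config <- function(round_thresholds = c(1e-10, 1e-10, 2e-20),
                          max_rounds = 20L) {
  if (!length(round_thresholds) || any(round_thresholds <= 0)) {
    stop("round thresholds must be positive", call. = FALSE)
  }
  if (max_rounds < 1L) stop("max_rounds must be >= 1", call. = FALSE)
  structure(list(round_thresholds = round_thresholds,
                 max_rounds = as.integer(max_rounds)),
            class = "search_config")
}

#' Iterative homology search with query expansion
#'
#' Emulates an iterative BLASTp protocol: in each round, every database
#' protein not yet in the hit set is aligned against the current queries
#' (exact local alignment); proteins whose best E-value is at or below the
#' round's ceiling become candidate hits; candidates passing the validation
#' callback join both the hit set and the query set. The procedure stops
#' when a round adds no new protein (or the whole database is accepted), or
#' after `max_rounds` rounds, in which case the result is flagged truncated.
#' E-values use the actual residue counts: `m` = query length, `n` = total
#' residues in the database.
#'
#' @param initial_queries named character vector of query proteins.
#' @param database named character vector of database proteins (names are
#'   gene identifiers; may overlap the queries).
#' @param config a [search_config()].
#' @param scheme a [scoring_scheme()].
#' @param validate optional callback `function(gene_id, sequence)` returning
#'   `TRUE` to accept a candidate as a genuine family member (e.g. a P20 +
#'   dyad check); `NULL` accepts every candidate. Rejected candidates are
#'   never revisited (validation is deterministic in the sequence).
#' @return list with `hits` (accepted gene ids, in order of acceptance),
#'   `log` (data.frame `round`, `threshold`, `gene_id`, `best_score`,
#'   `best_evalue`, `added_by_query`), `rounds` (rounds executed),
#'   `converged` (`FALSE` only when truncated at `max_rounds`).
#' @export
iterative_search <- function(initial_queries, database,
                             config = search_config(),
                             scheme = scoring_scheme(), validate = NULL) {
  if (!length(initial_queries)) {
    stop("invalid-input: empty query set", call. = FALSE)
  }
  if (is.null(names(database)) || is.null(names(initial_queries))) {
    stop("queries and database must be named", call. = FALSE)
  }
  for (s in database) .check_protein(s, "database sequence")
  for (s in initial_queries) .check_protein(s, "query sequence")
  n_db <- sum(nchar(database))
  db_ids <- names(database)

  best_score <- stats::setNames(rep(NA_real_, length(database)), db_ids)
  best_ev <- stats::setNames(rep(Inf, length(database)), db_ids)
  best_query <- stats::setNames(rep(NA_character_, length(database)), db_ids)
  hits <- character(0)
  rejected <- character(0)
  queries <- initial_queries
  new_queries <- initial_queries
  log_rows <- list()
  converged <- FALSE
  r <- 0L

  while (r < config$max_rounds) {
    r <- r + 1L
    thr <- config$round_thresholds[min(r, length(config$round_thresholds))]
    pending <- setdiff(db_ids, c(hits, rejected))
    # score pending proteins against queries added since the previous round;
    # the best (lowest) E-value per protein accumulates across rounds
    if (length(new_queries) && length(pending)) {
      for (gid in pending) {
        sc <- .local_scores(new_queries, database[[gid]], scheme)
        ev <- evalue(sc, m = nchar(new_queries), n = n_db, scheme = scheme)
        i <- which.min(ev)
        if (ev[i] < best_ev[gid]) {
          best_ev[gid] <- ev[i]
          best_score[gid] <- sc[i]
          best_query[gid] <- names(new_queries)[i]
        }
      }
    }
    cand <- pending[best_ev[pending] <= thr]
    added <- character(0)
    for (gid in cand) {
      ok <- if (is.null(validate)) TRUE else {
        isTRUE(validate(gid, database[[gid]]))
      }
      if (ok) added <- c(added, gid) else rejected <- c(rejected, gid)
    }
    if (length(added)) {
      hits <- c(hits, added)
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        round = r, threshold = thr, gene_id = added,
        best_score = unname(best_score[added]),
        best_evalue = unname(best_ev[added]),
        added_by_query = unname(best_query[added]),
        stringsAsFactors = FALSE)
    }
    # hits with sequences not already in the query set become new queries
    new_ids <- setdiff(added, names(queries))
    new_queries <- database[new_ids]
    queries <- c(queries, new_queries)
    if (!length(added) || !length(setdiff(db_ids, c(hits, rejected)))) {
      converged <- TRUE
      break
    }
  }
  log <- if (length(log_rows)) do.call(rbind, log_rows) else {
    data.frame(round = integer(), threshold = numeric(),
               gene_id = character(), best_score = numeric(),
               best_evalue = numeric(), added_by_query = character(),
               stringsAsFactors = FALSE)
  }
  list(hits = hits, log = log, rounds = r, converged = converged)
}
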