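#' Match taxa across count tables by representative sequence
#'
#' Denoising pipelines infer exact amplicon sequence variants (ASVs), so a
#' true ASV found by one pipeline should also be found by another. This
#' function identifies groups of taxa — one per input table — that
#' represent the same ASV, by comparing representative sequences. A group
#' is formed only when a match is found in *every* table.
#'
#' Matching modes:
#' \describe{
#'   \item{`exact`}{sequence equality after uppercasing (default).}
#'   \item{`subsequence`}{one sequence contained in the other; tolerates
#'     pipelines trimming reads to different lengths.}
#'   \item{`edit_distance`}{Levenshtein distance <= `k` (via
#'     [utils::adist()]); `k = 0` is equivalent to `exact`.}
#'   \item{`identifier`}{fallback matching on taxon ids, for tables
#'     without sequences; must be requested explicitly.}
#' }
#' If a sequence matches several candidates in another table, the match
#' with minimal edit distance wins, ties broken by higher read count; the
#' event is reported via `message()`.
#'
#' @param tables list of >= 2 [count_table()]s; all must carry sequences
#'   unless `mode = "identifier"`.
#' @param mode matching mode, see Details.
#' @param k maximum Levenshtein distance for `mode = "edit_distance"`.
#' @return a data.frame with one row per matched group and one column per
#'   table, holding the taxon id of the group member in that table.
#' @export
match_taxa <- function(tables,
                       mode = c("exact", "subsequence", "edit_distance",
                                "identifier"),
                       k = 0L) {
  mode <- match.arg(mode)
  if (!is.list(tables) || length(tables) < 2L) {
    stop("need a list of >= 2 count tables", call. = FALSE)
  }
  if (is.null(names(tables))) {
    names(tables) <- paste0("table_", seq_along(tables))
  }
  if (mode == "identifier") {
    keys <- lapply(tables, rownames)
  } else {
    keys <- lapply(tables, sequences_of)
    no_seq <- vapply(keys, is.null, logical(1L))
    if (any(no_seq)) {
      stop("table(s) without sequences: ",
           paste(names(tables)[no_seq], collapse = ", "),
           "; attach sequences or use mode = \"identifier\"", call. = FALSE)
    }
    incomplete <- mapply(function(s, t) length(s) < nrow(t), keys, tables)
    if (any(incomplete)) {
      stop("table(s) with taxa lacking a sequence: ",
           paste(names(tables)[incomplete], collapse = ", "), call. = FALSE)
    }
  }

  ref_ids <- rownames(tables[[1L]])
  ref_keys <- if (mode == "identifier") ref_ids else unname(keys[[1L]][ref_ids])

  rows <- lapply(seq_along(ref_ids), function(i) {
    members <- character(length(tables))
    members[1L] <- ref_ids[i]
    for (j in seq_along(tables)[-1L]) {
      hit <- match_one(ref_keys[i], keys[[j]], tables[[j]], mode, k)
      if (is.na(hit)) return(NULL)
      members[j] <- hit
    }
    members
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  out <- as.data.frame(do.call(rbind, c(rows, list(matrix(character(), 0L, length(tables))))),
                       stringsAsFactors = FALSE)
  names(out) <- names(tables)
  out
}

# Find the taxon in one table matching a reference key; NA if none.
match_one <- function(key, keys_j, table_j, mode, k) {
  ids_j <- if (is.null(names(keys_j))) keys_j else names(keys_j)
  if (mode == "identifier") {
    hit <- which(keys_j == key)
    return(if (length(hit)) ids_j[hit[1L]] else NA_character_)
  }
  seqs_j <- unname(keys_j[rownames(table_j)])
  ids_j <- rownames(table_j)
  cand <- switch(mode,
    exact = which(seqs_j == key),
    subsequence = which(seqs_j == key |
                          vapply(seqs_j, grepl, logical(1L), pattern = key,
                                 fixed = TRUE) |
                          vapply(seqs_j, function(s) grepl(s, key, fixed = TRUE),
                                 logical(1L))),
    edit_distance = which(utils::adist(key, seqs_j)[1L, ] <= k)
  )
  if (!length(cand)) return(NA_character_)
  if (length(cand) > 1L) {
    d <- utils::adist(key, seqs_j[cand])[1L, ]
    cand <- cand[d == min(d)]
    if (length(cand) > 1L) {
      reads <- rowSums(unclass(table_j))[ids_j[cand]]
      cand <- cand[order(-reads)]
    }
    message("ambiguous sequence match resolved to ", ids_j[cand[1L]])
  }
  ids_j[cand[1L]]
}

#' Infer a consensus count table from several pipelines' tables
#'
#' Identifies the set of taxa detected in *all* input tables (via
#' [match_taxa()]), computes for each table the fraction of its reads
#' mapped to that shared set, retains the table with the highest fraction,
#' discards its non-shared taxa, and returns the subsetted table as the
#' consensus. Counts in the consensus come from exactly one input table;
#' abundances are never merged across tables. Fractions are computed on
#' the raw counts as given (rarefy afterwards, not before).
#'
#' A fraction tie between tables is broken toward the table with fewer
#' taxa, then by input order.
#'
#' @inheritParams match_taxa
#' @return an object of class `consensus_result`: a list with
#'   `shared_taxa` (the data.frame from [match_taxa()]),
#'   `per_table_fraction`, `retained_table_id`, and `consensus`
#'   (a [count_table()]).
#' @export
consensus_table <- function(tables,
                            mode = c("exact", "subsequence", "edit_distance",
                                     "identifier"),
                            k = 0L) {
  mode <- match.arg(mode)
  if (is.null(names(tables))) names(tables) <- paste0("table_", seq_along(tables))
  groups <- match_taxa(tables, mode = mode, k = k)
  if (nrow(groups) == 0L) {
    stop("no taxa shared by all input tables; consensus is empty", call. = FALSE)
  }
  fractions <- vapply(seq_along(tables), function(j) {
    m <- unclass(tables[[j]])
    sum(m[groups[[j]], , drop = FALSE]) / sum(m)
  }, numeric(1L))
  names(fractions) <- names(tables)

  best <- max(fractions)
  tied <- which(fractions >= best - 1e-12)
  if (length(tied) > 1L) {
    sizes <- vapply(tables[tied], nrow, integer(1L))
    tied <- tied[order(sizes)]
    message("fraction tie; retaining ", names(tables)[tied[1L]],
            " (fewer taxa / first by input order)")
  }
  keep <- tied[1L]
  retained <- tables[[keep]]
  cons <- unclass(retained)[groups[[keep]], , drop = FALSE]
  seqs <- sequences_of(retained)
  if (!is.null(seqs)) seqs <- seqs[intersect(names(seqs), rownames(cons))]
  structure(list(
    shared_taxa = groups,
    per_table_fraction = fractions,
    retained_table_id = names(tables)[keep],
    consensus = count_table(cons, sequences = seqs)
  ), class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("consensus of ", length(x$per_table_fraction), " tables: ",
      nrow(x$shared_taxa), " shared taxa\n", sep = "")
  for (id in names(x$per_table_fraction)) {
    cat(sprintf("  %s: %.1f%% of reads on shared taxa%s\n", id,
                100 * x$per_table_fraction[[id]],
                if (id == x$retained_table_id) "  [retained]" else ""))
  }
  invisible(x)
}
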