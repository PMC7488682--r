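#' Construct a count table
#'
#' A count table holds non-negative integer read counts for a set of taxa
#' (OTUs/ASVs, rows) observed in a set of samples (columns), optionally
#' together with a representative nucleotide sequence per taxon. It is the
#' basic container every analysis in this package operates on.
#'
#' All-zero taxon rows are pruned at construction time (with a message):
#' a taxon observed in no sample carries no information for any diversity
#' or dissimilarity index computed here.
#'
#' @param counts numeric matrix of non-negative integers with unique
#'   rownames (taxon ids) and unique colnames (sample ids).
#' @param sequences optional named character vector mapping taxon ids to
#'   nucleotide sequences (alphabet ACGTUN, case-insensitive; stored
#'   uppercased). Names must be a subset of the taxon ids; sequences whose
#'   name matches no taxon trigger a warning and are dropped.
#' @return An object of class `count_table`: the integer matrix with the
#'   sequences attached as the `"sequences"` attribute.
#' @examples
#' m <- matrix(c(5L, 3L, 0L, 0L, 3L, 7L), nrow = 3,
#'             dimnames = list(c("t1", "t2", "t3"), c("s1", "s2")))
#' ct <- count_table(m)
#' sample_depths(ct)
#' @export
count_table <- function(counts, sequences = NULL) {
  if (!is.matrix(counts)) {
    stop("`counts` must be a matrix of read counts", call. = FALSE)
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` needs taxon ids as rownames and sample ids as colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate taxon ids in count table", call. = FALSE)
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate sample ids in count table", call. = FALSE)
  }
  if (any(!is.finite(counts))) {
    stop("count table contains missing or non-finite cells", call. = FALSE)
  }
  if (any(counts < 0)) {
    stop("count table contains negative cells", call. = FALSE)
  }
  if (any(counts != round(counts))) {
    stop("count table contains non-integer cells; read counts must be whole numbers",
         call. = FALSE)
  }
  storage.mode(counts) <- "integer"

  zero <- rowSums(counts) == 0L
  if (any(zero)) {
    message("pruned ", sum(zero), " all-zero taxon row(s): ",
            paste(utils::head(rownames(counts)[zero], 5L), collapse = ", "),
            if (sum(zero) > 5L) ", ..." else "")
    counts <- counts[!zero, , drop = FALSE]
  }

  out <- structure(counts, sequences = NULL, class = c("count_table", "matrix"))
  attach_sequences(out, sequences)
}

#' @export
print.count_table <- function(x, ...) {
  cat("count table: ", nrow(x), " taxa x ", ncol(x), " samples",
      if (!is.null(attr(x, "sequences"))) ", with sequences" else "",
      "\n", sep = "")
  m <- unclass(x)
  attr(m, "sequences") <- NULL
  print(utils::head(m, 10L))
  if (nrow(x) > 10L) cat("... ", nrow(x) - 10L, " more taxa\n", sep = "")
  invisible(x)
}

#' @rdname count_table
#' @param x a `count_table`.
#' @export
taxon_ids <- function(x) rownames(x)

#' @rdname count_table
#' @export
sample_ids <- function(x) colnames(x)

#' @rdname count_table
#' @export
sample_depths <- function(x) colSums(unclass(x))

#' Attach representative sequences to a count table
#'
#' @param table a `count_table`.
#' @param sequences named character vector of nucleotide sequences keyed by
#'   taxon id, e.g. as returned by [read_sequences()].
#' @return The table with validated, uppercased sequences attached.
#' @export
attach_sequences <- function(table, sequences) {
  if (is.null(sequences)) return(table)
  if (is.null(names(sequences)) || anyDuplicated(names(sequences))) {
    stop("sequences must be uniquely named by taxon id", call. = FALSE)
  }
  sequences <- toupper(sequences)
  bad <- grepl("[^ACGTUN]", sequences)
  if (any(bad)) {
    stop("illegal character in sequence(s): ",
         paste(utils::head(names(sequences)[bad], 5L), collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(names(sequences), rownames(table))
  if (length(unknown)) {
    warning(length(unknown), " sequence record(s) match no taxon id and were dropped: ",
            paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
    sequences <- sequences[setdiff(names(sequences), unknown)]
  }
  attr(table, "sequences") <- sequences
  table
}

#' @rdname attach_sequences
#' @export
sequences_of <- function(table) attr(table, "sequences")

#' Read a count table from a tab-separated file
#'
#' Expects a UTF-8 TSV with a header row; the first column holds taxon ids,
#' the remaining columns hold per-sample read counts. Cells must be
#' non-negative integers: rarefaction and the null model are defined on
#' read counts, so real-valued tables are rejected rather than rounded.
#'
#' @param path path to the TSV file.
#' @param transpose set to `TRUE` only if the file has samples as rows and
#'   taxa as columns; the table is then transposed on read. There is no
#'   silent auto-detection.
#' @return a [count_table()].
#' @export
read_count_table <- function(path, transpose = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L) stop("empty count table file: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = NA,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) {
    stop("malformed count table header: need a taxon-id column plus >= 1 sample column",
         call. = FALSE)
  }
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate taxon ids in ", path, call. = FALSE)
  num <- df[, -1L, drop = FALSE]
  nonnum <- !vapply(num, is.numeric, logical(1L))
  if (any(nonnum)) {
    warning("ignoring non-numeric column(s) (taxonomy?): ",
            paste(names(num)[nonnum], collapse = ", "), call. = FALSE)
    num <- num[, !nonnum, drop = FALSE]
    if (ncol(num) == 0L) stop("no numeric sample columns in ", path, call. = FALSE)
  }
  m <- as.matrix(num)
  rownames(m) <- ids
  if (transpose) m <- t(m)
  count_table(m)
}

#' Write a count table to a tab-separated file
#'
#' Inverse of [read_count_table()]: the written file round-trips counts
#' bit-exactly.
#'
#' @param table a `count_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path) {
  df <- data.frame(taxon_id = rownames(table),
                   unclass(table)[, , drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read representative sequences from a FASTA file
#'
#' @param path path to a FASTA file of nucleotide sequences keyed by taxon id.
#' @return named character vector of uppercased sequences.
#' @export
read_sequences <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate record id(s) in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  bad <- grepl("[^ACGTUN]", seqs)
  if (any(bad)) {
    stop("illegal character in FASTA record(s): ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  }
  seqs
}

#' Read sample metadata (sample to category mapping)
#'
#' Expects a two-column TSV with a header, first column sample ids, second
#' column a category label.
#'
#' @param path path to the TSV file.
#' @param table optional `count_table`; if given, every sample id in the
#'   metadata must exist in the table.
#' @return named character vector mapping sample id to category.
#' @export
read_sample_metadata <- function(path, table = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("metadata needs sample_id and category columns", call. = FALSE)
  meta <- stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
  if (anyDuplicated(names(meta))) stop("duplicate sample ids in metadata", call. = FALSE)
  if (!is.null(table)) {
    missing <- setdiff(names(meta), colnames(table))
    if (length(missing)) {
      stop("metadata sample(s) absent from count table: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  meta
}

#' Relative abundances of one sample
#'
#' Converts one sample column of a count table into the relative-abundance
#' vector p, with p_i the fraction of the sample's reads assigned to taxon
#' i. These fractions are the input to every Hill number.
#'
#' @param table a `count_table` (or a bare counts matrix with dimnames).
#' @param sample_id the sample column to normalize.
#' @return named numeric vector summing to 1.
#' @export
to_relative_abundance <- function(table, sample_id) {
  if (!sample_id %in% colnames(table)) {
    stop("unknown sample id: ", sample_id, call. = FALSE)
  }
  counts <- unclass(table)[, sample_id]
  total <- sum(counts)
  if (total <= 0) {
    stop("sample '", sample_id, "' has zero reads; cannot normalize", call. = FALSE)
  }
  counts / total
}
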