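#' Build a regional taxon pool from a count table
#'
#' The regional pool is the set of taxa detected in a chosen set of pool
#' samples, together with each taxon's occurrence frequency (the number of
#' pool samples in which it is detected) and its total read count summed
#' over the pool samples. Null samples are assembled from this pool: the
#' occurrence frequencies weight which taxa are picked and the read totals
#' weight how reads are distributed among them.
#'
#' @param table a [count_table()].
#' @param pool_sample_ids sample ids defining the pool; defaults to all
#'   samples in the table.
#' @return an object of class `regional_pool`: a list with `taxon_ids`,
#'   `frequency`, `total_reads`, `pool_sample_ids`.
#' @export
build_pool <- function(table, pool_sample_ids = colnames(table)) {
  if (length(pool_sample_ids) < 1L) stop("empty pool", call. = FALSE)
  missing <- setdiff(pool_sample_ids, colnames(table))
  if (length(missing)) {
    stop("pool sample(s) absent from table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  m <- unclass(table)[, pool_sample_ids, drop = FALSE]
  if (any(colSums(m) <= 0)) stop("pool sample(s) with zero reads", call. = FALSE)
  detected <- rowSums(m) > 0
  m <- m[detected, , drop = FALSE]
  structure(list(
    taxon_ids = rownames(m),
    frequency = rowSums(m > 0),
    total_reads = rowSums(m),
    pool_sample_ids = pool_sample_ids
  ), class = "regional_pool")
}

#' @export
print.regional_pool <- function(x, ...) {
  cat("regional pool: ", length(x$taxon_ids), " taxa over ",
      length(x$pool_sample_ids), " sample(s)\n", sep = "")
  invisible(x)
}

#' Randomly assemble a null sample from a regional pool
#'
#' Assembles one null counterpart of a real sample: exactly `richness`
#' distinct taxa are drawn from the pool without replacement, with
#' selection probability proportional to their occurrence frequency
#' (`scheme = "frequency"`) or to their pool-wide read totals
#' (`scheme = "abundance"`). Each selected taxon is then seeded with one
#' read, and the remaining `depth - richness` reads are distributed
#' multinomially over the selected taxa with probabilities proportional to
#' their pool-wide read totals (renormalized over the selected taxa).
#' The null sample therefore preserves the template's richness and read
#' depth exactly.
#'
#' @param pool a `regional_pool` from [build_pool()].
#' @param richness number of distinct taxa the null sample must contain.
#' @param depth total number of reads the null sample must contain
#'   (`depth >= richness`).
#' @param scheme taxon-selection weighting, `"frequency"` or `"abundance"`.
#' @return named integer vector of reads over all pool taxa (zeros for
#'   unselected taxa), summing to `depth` with `richness` positive entries.
#' @export
randomize_sample <- function(pool, richness, depth,
                             scheme = c("frequency", "abundance")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(pool, "regional_pool"))
  n_pool <- length(pool$taxon_ids)
  if (richness < 1L || richness > n_pool) {
    stop("richness must be in [1, pool size = ", n_pool, "]", call. = FALSE)
  }
  if (depth < richness) {
    stop("depth (", depth, ") smaller than richness (", richness, ")",
         call. = FALSE)
  }
  w <- if (scheme == "frequency") pool$frequency else pool$total_reads
  sel <- sample.int(n_pool, size = richness, replace = FALSE, prob = w)
  reads <- integer(n_pool)
  reads[sel] <- 1L
  extra <- depth - richness
  if (extra > 0L) {
    probs <- pool$total_reads[sel]
    reads[sel] <- reads[sel] +
      as.integer(stats::rmultinom(1L, size = extra, prob = probs))
  }
  names(reads) <- pool$taxon_ids
  reads
}

#' Generalized Raup-Crick null model for one sample pair
#'
#' Compares the observed dissimilarity between two samples with the
#' distribution of dissimilarities between randomly assembled counterparts.
#' In every iteration both samples of the pair are independently
#' re-assembled from the regional pool (each preserving its own observed
#' richness and read depth, see [randomize_sample()]) and their
#' dissimilarity is computed with the chosen index at diversity order q.
#' The Raup-Crick index is
#' \deqn{^qRC = \frac{N_{[d_{exp} < d_{obs}]} + 0.5\, N_{[d_{exp} = d_{obs}]}}{N_{TOT}},}
#' the fraction of randomizations with null dissimilarity below the
#' observed one, ties counted half. Values near 0 mean the samples are
#' more similar than random assembly from the pool would produce; values
#' near 1 mean more dissimilar.
#'
#' Equality in the tie count uses an absolute tolerance of 1e-10: at low
#' q the dissimilarities take few discrete values, so ties are real and
#' frequent, and a strict floating-point comparison would undercount them.
#'
#' @param table a [count_table()].
#' @param pair character vector of two sample ids.
#' @param q diversity order.
#' @param index dissimilarity index, see [pair_dissimilarity()].
#' @param pool_sample_ids samples defining the regional pool (default: all
#'   samples in `table`).
#' @param iterations number of randomizations N_TOT (default 199).
#' @param scheme taxon-selection weighting, see [randomize_sample()].
#' @param seed optional integer seed for reproducibility; the caller's RNG
#'   state is left untouched.
#' @return an object of class `raup_crick_result`: a list with `pair`,
#'   `q`, `index`, `observed`, `null_values`, `rc`, `n_less`, `n_equal`,
#'   `iterations`, `seed`.
#' @export
raup_crick <- function(table, pair, q = 1, index = "local",
                       pool_sample_ids = colnames(table),
                       iterations = 199L,
                       scheme = c("frequency", "abundance"),
                       seed = NULL) {
  scheme <- match.arg(scheme)
  index <- match.arg(index, dissimilarity_indices())
  check_order(q)
  if (length(pair) != 2L || !all(pair %in% colnames(table))) {
    stop("`pair` must name two samples of the table", call. = FALSE)
  }
  if (iterations < 1L) stop("iterations must be >= 1", call. = FALSE)

  pool <- build_pool(table, pool_sample_ids)
  m <- unclass(table)
  x <- m[, pair[1L]]
  y <- m[, pair[2L]]
  observed <- pair_dissimilarity(x, y, index = index, q = q)

  null_values <- with_seed(seed, {
    vapply(seq_len(iterations), function(i) {
      nx <- randomize_sample(pool, sum(x > 0), sum(x), scheme)
      ny <- randomize_sample(pool, sum(y > 0), sum(y), scheme)
      pair_dissimilarity(nx, ny, index = index, q = q)
    }, numeric(1L))
  })

  tally <- rc_tally(observed, null_values)
  structure(list(pair = pair, q = q, index = index,
                 observed = observed, null_values = null_values,
                 rc = tally$rc, n_less = tally$n_less, n_equal = tally$n_equal,
                 iterations = iterations, seed = seed),
            class = "raup_crick_result")
}

rc_tally <- function(observed, null_values, tol = 1e-10) {
  n_less <- sum(null_values < observed - tol)
  n_equal <- sum(abs(null_values - observed) <= tol)
  list(n_less = n_less, n_equal = n_equal,
       rc = (n_less + 0.5 * n_equal) / length(null_values))
}

#' @export
print.raup_crick_result <- function(x, ...) {
  cat(sprintf("Raup-Crick (%s, q = %g): %s vs %s\n",
              x$index, x$q, x$pair[1L], x$pair[2L]))
  cat(sprintf("  observed d = %.4f, null = %.4f +/- %.4f (%d randomizations)\n",
              x$observed, mean(x$null_values), stats::sd(x$null_values),
              x$iterations))
  cat(sprintf("  RC = %.4f (rescaled %.4f)\n", x$rc, rescale_rc(x$rc)))
  invisible(x)
}

#' Rescale a Raup-Crick index from \[0, 1\] to \[-1, 1\]
#'
#' Subtracts 0.5 and multiplies by 2, mapping the null expectation 0.5 to
#' 0, "more similar than null" toward -1 and "more dissimilar" toward 1.
#'
#' @param rc Raup-Crick value(s) in \[0, 1\].
#' @return value(s) in \[-1, 1\].
#' @export
rescale_rc <- function(rc) {
  if (any(!is.finite(rc)) || any(rc < 0) || any(rc > 1)) {
    stop("rc must lie in [0, 1]", call. = FALSE)
  }
  2 * (rc - 0.5)
}

#' Raup-Crick profiles over sample pairs and a grid of diversity orders
#'
#' Runs the null model of [raup_crick()] for every listed sample pair and
#' every diversity order on a grid. For each pair, one shared set of null
#' assemblies is generated and reused across the whole q grid, so the
#' profile is internally consistent (and cheaper than re-assembling per q).
#'
#' @inheritParams raup_crick
#' @param pairs two-column matrix of sample id pairs, e.g. from
#'   [sample_pairs()].
#' @param q_grid vector of diversity orders.
#' @return a data.frame of class `rc_profile` with one row per pair and
#'   order: columns `sample_1`, `sample_2`, `q`, `observed`, `null_mean`,
#'   `null_sd`, `rc`, `rc_rescaled`.
#' @export
rc_profile <- function(table, pairs, q_grid = c(0, 1, 2), index = "local",
                       pool_sample_ids = colnames(table),
                       iterations = 199L,
                       scheme = c("frequency", "abundance"),
                       seed = NULL) {
  scheme <- match.arg(scheme)
  index <- match.arg(index, dissimilarity_indices())
  pairs <- as.matrix(pairs)
  if (nrow(pairs) < 1L) stop("empty pair list", call. = FALSE)
  pool <- build_pool(table, pool_sample_ids)
  m <- unclass(table)

  rows <- with_seed(seed, {
    out <- vector("list", nrow(pairs))
    for (k in seq_len(nrow(pairs))) {
      x <- m[, pairs[k, 1L]]
      y <- m[, pairs[k, 2L]]
      # one set of null assemblies per pair, shared across the q grid
      assemblies <- replicate(iterations, list(
        nx = randomize_sample(pool, sum(x > 0), sum(x), scheme),
        ny = randomize_sample(pool, sum(y > 0), sum(y), scheme)
      ), simplify = FALSE)
      out[[k]] <- do.call(rbind, lapply(q_grid, function(q) {
        observed <- pair_dissimilarity(x, y, index = index, q = q)
        nulls <- vapply(assemblies, function(a) {
          pair_dissimilarity(a$nx, a$ny, index = index, q = q)
        }, numeric(1L))
        tally <- rc_tally(observed, nulls)
        data.frame(sample_1 = pairs[k, 1L], sample_2 = pairs[k, 2L], q = q,
                   observed = observed,
                   null_mean = mean(nulls), null_sd = stats::sd(nulls),
                   rc = tally$rc, rc_rescaled = rescale_rc(tally$rc),
                   stringsAsFactors = FALSE)
      }))
    }
    out
  })
  structure(do.call(rbind, rows),
            iterations = iterations, index = index, seed = seed,
            class = c("rc_profile", "data.frame"))
}

# Run `code` under a temporary RNG seed, restoring the caller's RNG state.
# With seed = NULL the current RNG stream is used (and advanced) as usual.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
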