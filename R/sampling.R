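#' Rarefy a count table to a common read depth
#'
#' Randomly subsamples each sample's reads *without replacement* down to a
#' common depth, so that all samples are compared at equal sequencing
#' effort. Per column this is a multivariate hypergeometric draw: each
#' taxon's rarefied count never exceeds its original count, and every
#' column sums exactly to `depth`. Rarefaction is a single draw (with a
#' reproducible seed), not an average over draws.
#'
#' @param table a [count_table()].
#' @param depth target depth: a positive integer, or `"min"` (default) for
#'   the read count of the smallest sample.
#' @param seed optional integer seed; the caller's RNG state is preserved.
#' @return a rarefied [count_table()]; taxa reduced to zero reads in every
#'   sample are pruned (with a message).
#' @export
rarefy <- function(table, depth = "min", seed = NULL) {
  m <- unclass(table)
  totals <- colSums(m)
  if (identical(depth, "min")) depth <- min(totals)
  depth <- as.integer(depth)
  if (depth < 1L) stop("depth must be >= 1", call. = FALSE)
  short <- totals < depth
  if (any(short)) {
    stop("sample(s) with fewer than ", depth, " reads: ",
         paste(colnames(m)[short], collapse = ", "), call. = FALSE)
  }
  out <- with_seed(seed, {
    vapply(seq_len(ncol(m)), function(j) {
      col <- m[, j]
      if (sum(col) == depth) return(as.integer(col))
      reads <- rep.int(seq_along(col), col)
      kept <- sample(reads, depth, replace = FALSE)
      as.integer(tabulate(kept, nbins = length(col)))
    }, integer(nrow(m)))
  })
  dimnames(out) <- dimnames(m)
  count_table(out, sequences = sequences_of(table))
}

#' Simulate the effect of sequencing depth on replicate dissimilarity
#'
#' Draws sets of replicate samples from a known "true" relative-abundance
#' distribution by multinomial sampling (random sampling with replacement)
#' at each of several sequencing depths, then computes pairwise
#' dissimilarity profiles between the replicates at each depth. Because
#' every replicate comes from the same underlying community, the true
#' dissimilarity is 0; any dissimilarity observed is pure random-sampling
#' (undersampling) bias. For long-tailed communities this bias is large
#' at q = 0 and shrinks both with depth and with increasing q.
#'
#' @param truth named numeric vector of true relative abundances (sums
#'   to 1), e.g. from [make_lognormal_community()].
#' @param depths vector of sequencing depths (reads per sample).
#' @param replicates number of replicate samples per depth (>= 2).
#' @param q_grid diversity orders for the dissimilarity profiles.
#' @param index dissimilarity index for the profiles.
#' @param seed optional integer seed.
#' @return an object of class `depth_simulation`: a list with `depths`,
#'   `replicates`, `detected` (matrix of detected-taxon counts, depths x
#'   replicates), `profiles` (one [dissimilarity_profile()] per depth),
#'   and `seed`.
#' @export
simulate_depth <- function(truth, depths = c(1e4, 3e4, 1e5, 3e5, 1e6),
                           replicates = 6L, q_grid = c(0, 1, 2),
                           index = "local", seed = NULL) {
  truth <- check_abundances(truth)
  if (is.null(names(truth))) names(truth) <- paste0("taxon_", seq_along(truth))
  if (replicates < 2L) stop("need >= 2 replicates per depth", call. = FALSE)
  depths <- as.integer(sort(depths))
  if (any(depths < 1L)) stop("depths must be >= 1", call. = FALSE)

  res <- with_seed(seed, {
    lapply(depths, function(d) {
      counts <- stats::rmultinom(replicates, size = d, prob = truth)
      dimnames(counts) <- list(names(truth), paste0("rep_", seq_len(replicates)))
      # taxa undetected at this depth are expected; prune quietly
      tab <- suppressMessages(count_table(counts))
      list(detected = colSums(counts > 0),
           profile = dissimilarity_profile(tab, q_grid = q_grid, index = index))
    })
  })
  detected <- do.call(rbind, lapply(res, `[[`, "detected"))
  rownames(detected) <- as.character(depths)
  structure(list(
    depths = depths,
    replicates = replicates,
    detected = detected,
    profiles = stats::setNames(lapply(res, `[[`, "profile"),
                               as.character(depths)),
    seed = seed
  ), class = "depth_simulation")
}

#' @export
print.depth_simulation <- function(x, ...) {
  cat("sequencing-depth simulation: ", length(x$depths), " depths x ",
      x$replicates, " replicates\n", sep = "")
  for (d in as.character(x$depths)) {
    pr <- x$profiles[[d]]
    cat(sprintf("  depth %s: detected %.0f taxa (mean), d(q=%g) = %.4f\n",
                d, mean(x$detected[d, ]), pr$q[1L], pr$mean[1L]))
  }
  invisible(x)
}
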