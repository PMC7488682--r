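#' Hill number (effective number of taxa) of a community
#'
#' The Hill number of order q of a relative-abundance vector p is
#' \deqn{^qD = \left(\sum_i p_i^q\right)^{1/(1-q)}}{qD = (sum p_i^q)^(1/(1-q))}
#' for q != 1, and its limit \eqn{\exp(-\sum_i p_i \ln p_i)} at q = 1.
#' The diversity order q sets the weight given to relative abundance:
#' q = 0 counts detected taxa (richness), q = 1 weighs taxa exactly by
#' abundance (exponential Shannon entropy), q > 1 emphasizes dominant taxa.
#' A community of S equally abundant taxa has \eqn{^qD = S} for every q.
#'
#' Zero-abundance entries are excluded from the sum at every order,
#' including q = 0: richness counts only detected taxa.
#'
#' @param p numeric vector of relative abundances (non-negative, summing
#'   to 1 within 1e-9).
#' @param q diversity order, a single real >= 0.
#' @return the effective number of taxa, a value in \[1, S\].
#' @examples
#' hill_number(rep(1 / 8, 8), q = 2)       # uniform: always S = 8
#' hill_number(c(0.5, 0.25, 0.25), q = 0)  # richness: 3
#' @export
hill_number <- function(p, q) {
  check_order(q)
  p <- check_abundances(p)
  p <- p[p > 0]
  if (is_unit_order(q)) {
    return(exp(-sum(p * log(p))))
  }
  # log-space: (sum p^q)^(1/(1-q)) = exp(log(sum exp(q log p)) / (1-q))
  exp(log(sum(exp(q * log(p)))) / (1 - q))
}

#' Decompose diversity of N communities into alpha, gamma and beta
#'
#' Computes the equal-weight alpha/gamma/beta decomposition of Hill
#' numbers for N >= 2 communities over a common taxon universe. Gamma
#' diversity is the Hill number of the pooled community
#' \eqn{\bar p_i = (1/N)\sum_j p_{ij}}; alpha diversity is the effective
#' number of taxa per community,
#' \deqn{^qD_\alpha = \frac{1}{N}\left[\sum_i \sum_j (p_{ij}/N)^q\right]^{1/(1-q)}}
#' (with the corresponding entropy limit at q = 1); and beta diversity is
#' their ratio \eqn{^qD_\beta = {}^qD_\gamma / {}^qD_\alpha}, the effective
#' number of distinct communities. Beta ranges from 1 (all communities
#' identical) to N (no shared taxa).
#'
#' @param p numeric matrix of relative abundances, taxa as rows and the
#'   N >= 2 communities as columns; every column sums to 1.
#' @param q diversity order >= 0.
#' @return an object of class `hill_decomposition`: a list with elements
#'   `q`, `N`, `alpha`, `gamma`, `beta`.
#' @seealso [local_dissimilarity()], [regional_dissimilarity()] for the
#'   transforms of beta onto \[0, 1\].
#' @export
hill_decompose <- function(p, q) {
  check_order(q)
  if (is.data.frame(p)) p <- as.matrix(p)
  if (!is.matrix(p) || ncol(p) < 2L) {
    stop("`p` must be a matrix with >= 2 community columns", call. = FALSE)
  }
  for (j in seq_len(ncol(p))) check_abundances(p[, j])
  n <- ncol(p)

  gamma <- hill_number(rowMeans(p), q)

  pw <- p / n                 # p_ij / N, equal community weights
  pw <- pw[pw > 0]
  if (is_unit_order(q)) {
    alpha <- exp(-sum(pw * log(pw))) / n
  } else {
    alpha <- exp(log(sum(exp(q * log(pw)))) / (1 - q)) / n
  }

  beta <- gamma / alpha
  # guard against floating-point excursions just outside [1, N]
  if (beta < 1 && beta > 1 - 1e-9) beta <- 1
  if (beta > n && beta < n + 1e-9) beta <- n

  structure(list(q = q, N = n, alpha = alpha, gamma = gamma, beta = beta),
            class = "hill_decomposition")
}

#' @export
print.hill_decomposition <- function(x, ...) {
  cat(sprintf("Hill decomposition (q = %g, N = %d)\n", x$q, x$N))
  cat(sprintf("  alpha = %.6g  gamma = %.6g  beta = %.6g\n",
              x$alpha, x$gamma, x$beta))
  invisible(x)
}

#' Local and regional dissimilarity transforms of beta diversity
#'
#' Both transforms map the effective number of distinct communities
#' \eqn{^qD_\beta \in [1, N]} onto a dissimilarity in \[0, 1\]
#' (dissimilarity = 1 - overlap). The *local* dissimilarity
#' \deqn{^qd = \frac{(^qD_\beta)^{1-q} - 1}{N^{1-q} - 1}}
#' measures the effective average proportion of a community's taxa *not
#' shared* with the other communities; at q = 0 it equals the Sørensen
#' dissimilarity. The *regional* dissimilarity
#' \deqn{\frac{(^qD_\beta)^{q-1} - 1}{N^{q-1} - 1}}
#' measures the effective proportion of the pooled community's taxa not
#' shared by all; at q = 0 it equals the Jaccard dissimilarity. Both share
#' the limit \eqn{\ln(^qD_\beta)/\ln(N)} at q = 1.
#'
#' @param decomp a `hill_decomposition` from [hill_decompose()].
#' @return a dissimilarity value in \[0, 1\].
#' @export
local_dissimilarity <- function(decomp) {
  beta_transform(decomp, regional = FALSE)
}

#' @rdname local_dissimilarity
#' @export
regional_dissimilarity <- function(decomp) {
  beta_transform(decomp, regional = TRUE)
}

beta_transform <- function(decomp, regional) {
  stopifnot(inherits(decomp, "hill_decomposition"))
  beta <- decomp$beta
  n <- decomp$N
  q <- decomp$q
  e <- if (regional) q - 1 else 1 - q
  d <- if (is_unit_order(q)) {
    log(beta) / log(n)
  } else {
    (beta^e - 1) / (n^e - 1)
  }
  min(max(d, 0), 1)
}

#' Classic incidence- and abundance-based dissimilarity indices
#'
#' `jaccard()` and `sorensen()` are incidence-based: with C taxa shared
#' between samples of richness Sx and Sy (union U), Jaccard dissimilarity
#' is 1 - C/U and Sørensen dissimilarity is 1 - 2C/(Sx + Sy).
#' `bray_curtis()` operates on relative abundances:
#' \eqn{\frac{1}{2}\sum_i |p_{ix} - p_{iy}|}. All three lie in \[0, 1\].
#'
#' @param x,y for the incidence indices, vectors over a common taxon
#'   universe (counts or logical presence); for Bray-Curtis,
#'   relative-abundance vectors each summing to 1.
#' @return a dissimilarity value in \[0, 1\].
#' @export
jaccard <- function(x, y) {
  inc <- check_incidence(x, y)
  1 - sum(inc$x & inc$y) / sum(inc$x | inc$y)
}

#' @rdname jaccard
#' @export
sorensen <- function(x, y) {
  inc <- check_incidence(x, y)
  1 - 2 * sum(inc$x & inc$y) / (sum(inc$x) + sum(inc$y))
}

#' @rdname jaccard
#' @export
bray_curtis <- function(x, y) {
  x <- check_abundances(x)
  y <- check_abundances(y)
  if (length(x) != length(y)) {
    stop("abundance vectors must share a common taxon universe", call. = FALSE)
  }
  0.5 * sum(abs(x - y))
}

check_incidence <- function(x, y) {
  if (length(x) != length(y)) {
    stop("incidence vectors must share a common taxon universe", call. = FALSE)
  }
  x <- x > 0
  y <- y > 0
  if (!any(x) || !any(y)) stop("empty sample in dissimilarity computation", call. = FALSE)
  list(x = x, y = y)
}

#' Dissimilarity between one pair of count vectors
#'
#' Low-level worker used by [dissimilarity_matrix()], the profiles and the
#' null model: computes one named index between two count (or abundance)
#' vectors over a common taxon universe. Pairwise Hill-based indices use
#' the N = 2 decomposition of [hill_decompose()].
#'
#' @param x,y count vectors over a common taxon universe.
#' @param index one of `"local"`, `"regional"`, `"jaccard"`, `"sorensen"`,
#'   `"bray_curtis"`.
#' @param q diversity order (used by the Hill-based indices only).
#' @return dissimilarity in \[0, 1\].
#' @export
pair_dissimilarity <- function(x, y, index = "local", q = 1) {
  index <- match.arg(index, dissimilarity_indices())
  sx <- sum(x); sy <- sum(y)
  if (sx <= 0 || sy <= 0) stop("empty sample in dissimilarity computation", call. = FALSE)
  switch(index,
    local = local_dissimilarity(hill_decompose(cbind(x / sx, y / sy), q)),
    regional = regional_dissimilarity(hill_decompose(cbind(x / sx, y / sy), q)),
    jaccard = jaccard(x, y),
    sorensen = sorensen(x, y),
    bray_curtis = bray_curtis(x / sx, y / sy)
  )
}

dissimilarity_indices <- function() {
  c("local", "regional", "jaccard", "sorensen", "bray_curtis")
}

#' Pairwise dissimilarity matrix of all samples in a count table
#'
#' Applies one dissimilarity index to every pair of samples. Hill-based
#' indices decompose each pair with N = 2 communities.
#'
#' @param table a [count_table()].
#' @param index index name, see [pair_dissimilarity()].
#' @param q diversity order for the Hill-based indices.
#' @return an object of class `dissimilarity_matrix`: a symmetric numeric
#'   matrix with zero diagonal, sample ids as dimnames, and attributes
#'   `index` and (for Hill indices) `q`.
#' @export
dissimilarity_matrix <- function(table, index = "local", q = 1) {
  index <- match.arg(index, dissimilarity_indices())
  m <- unclass(table)
  if (ncol(m) < 2L) stop("need at least 2 samples", call. = FALSE)
  depths <- colSums(m)
  if (any(depths <= 0)) {
    stop("sample(s) with zero reads: ",
         paste(colnames(m)[depths <= 0], collapse = ", "), call. = FALSE)
  }
  n <- ncol(m)
  out <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      d <- pair_dissimilarity(m[, i], m[, j], index = index, q = q)
      out[i, j] <- d
      out[j, i] <- d
    }
  }
  structure(out, index = index,
            q = if (index %in% c("local", "regional")) q else NULL,
            class = c("dissimilarity_matrix", "matrix"))
}

#' Enumerate sample pairs, optionally by metadata category
#'
#' Builds the list of sample pairs used by [dissimilarity_profile()] and
#' [rc_profile()]. With no metadata, all pairs. With `within`, all pairs
#' inside one category; with `between`, all cross pairs of two categories.
#'
#' @param table a `count_table` (only sample ids are used).
#' @param metadata named character vector mapping sample id to category
#'   (see [read_sample_metadata()]).
#' @param within a single category label.
#' @param between character vector of two category labels.
#' @return a two-column character matrix of sample id pairs.
#' @export
sample_pairs <- function(table, metadata = NULL, within = NULL, between = NULL) {
  ids <- colnames(table)
  if (is.null(within) && is.null(between)) {
    idx <- utils::combn(ids, 2L)
    return(t(idx))
  }
  if (is.null(metadata)) stop("metadata required for category pairs", call. = FALSE)
  if (!is.null(within)) {
    grp <- ids[ids %in% names(metadata)[metadata == within]]
    if (length(grp) < 2L) stop("category '", within, "' has < 2 samples", call. = FALSE)
    return(t(utils::combn(grp, 2L)))
  }
  stopifnot(length(between) == 2L)
  a <- ids[ids %in% names(metadata)[metadata == between[1L]]]
  b <- ids[ids %in% names(metadata)[metadata == between[2L]]]
  if (!length(a) || !length(b)) {
    stop("empty category in `between`", call. = FALSE)
  }
  as.matrix(expand.grid(a, b, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE))
}

#' Dissimilarity-versus-q profile over a set of sample pairs
#'
#' Computes the mean and standard deviation of a pairwise dissimilarity
#' index over a list of sample pairs, for every diversity order on a grid.
#' These profiles (dissimilarity as a function of q) show how taxa of
#' different relative abundance contribute to the dissimilarity between
#' communities: incidence-driven dissimilarity appears at q near 0,
#' dominant-taxon-driven dissimilarity at q near 2.
#'
#' @param table a [count_table()].
#' @param pairs two-column matrix of sample id pairs, e.g. from
#'   [sample_pairs()].
#' @param q_grid increasing vector of diversity orders (default 0 to 2 in
#'   steps of 0.05).
#' @param index index name; the classic indices give flat profiles.
#' @return an object of class `dissimilarity_profile`: a data.frame with
#'   columns `q`, `mean`, `sd` and attribute `pair_count`.
#' @export
dissimilarity_profile <- function(table, pairs = sample_pairs(table),
                                  q_grid = seq(0, 2, by = 0.05),
                                  index = "local") {
  index <- match.arg(index, dissimilarity_indices())
  pairs <- as.matrix(pairs)
  if (nrow(pairs) < 1L) stop("empty pair list", call. = FALSE)
  if (length(q_grid) < 1L) stop("empty q grid", call. = FALSE)
  if (is.unsorted(q_grid, strictly = TRUE)) stop("q_grid must be increasing", call. = FALSE)
  m <- unclass(table)
  vals <- matrix(NA_real_, nrow = length(q_grid), ncol = nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    x <- m[, pairs[k, 1L]]
    y <- m[, pairs[k, 2L]]
    vals[, k] <- vapply(q_grid, function(q) pair_dissimilarity(x, y, index, q),
                        numeric(1L))
  }
  out <- data.frame(
    q = q_grid,
    mean = rowMeans(vals),
    sd = apply(vals, 1L, function(v) if (length(v) > 1L) stats::sd(v) else 0)
  )
  structure(out, pair_count = nrow(pairs), index = index,
            class = c("dissimilarity_profile", "data.frame"))
}

#' @export
print.dissimilarity_profile <- function(x, ...) {
  cat("dissimilarity profile (", attr(x, "index"), ", ",
      attr(x, "pair_count"), " pair(s))\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.dissimilarity_profile <- function(x, ylim = c(0, 1), type = "l",
                                       xlab = "diversity order (q)",
                                       ylab = "dissimilarity", ...) {
  graphics::plot(x$q, x$mean, type = type, ylim = ylim,
                 xlab = xlab, ylab = ylab, ...)
  if (any(x$sd > 0)) {
    graphics::arrows(x$q, x$mean - x$sd, x$q, x$mean + x$sd,
                     angle = 90, code = 3, length = 0.02, col = "grey50")
  }
  invisible(x)
}

# ---- shared input checks ----

check_order <- function(q) {
  if (!is.numeric(q) || length(q) != 1L || !is.finite(q) || q < 0) {
    stop("diversity order q must be a single finite value >= 0", call. = FALSE)
  }
  invisible(q)
}

is_unit_order <- function(q) abs(q - 1) < 1e-9

check_abundances <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0)) {
    stop("relative abundances must be finite and non-negative", call. = FALSE)
  }
  s <- sum(p)
  if (abs(s - 1) > 1e-9) {
    stop("relative abundances must sum to 1 (got ", format(s), ")", call. = FALSE)
  }
  p
}
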