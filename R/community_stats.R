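#' Mantel permutation test between two dissimilarity matrices
#'
#' Correlates the upper-triangle entries of two dissimilarity matrices
#' over the same samples and assesses significance by simultaneously
#' permuting the rows and columns of the second matrix. The p-value uses
#' the +1 correction, p = (number of permuted statistics >= observed + 1) /
#' (permutations + 1), counting the observed arrangement among the
#' permutations and so never reaching 0.
#'
#' @param m1,m2 symmetric dissimilarity matrices (e.g. from
#'   [dissimilarity_matrix()]) over identical sample sets in identical
#'   order.
#' @param method correlation type, `"pearson"` (default) or `"spearman"`.
#' @param permutations number of permutations (>= 99; default 999).
#' @param seed optional integer seed.
#' @return an object of class `permutation_test`: a list with `statistic`
#'   (Mantel r), `p_value`, `permutations`, `method`, `seed`.
#' @export
mantel_test <- function(m1, m2, method = c("pearson", "spearman"),
                        permutations = 999L, seed = NULL) {
  method <- match.arg(method)
  m1 <- as.matrix(m1); m2 <- as.matrix(m2)
  if (!identical(dim(m1), dim(m2)) ||
      !identical(rownames(m1), rownames(m2))) {
    stop("matrices must cover identical sample sets in identical order",
         call. = FALSE)
  }
  if (permutations < 99L) stop("use at least 99 permutations", call. = FALSE)
  n <- nrow(m1)
  ut <- upper.tri(m1)
  r_obs <- stats::cor(m1[ut], m2[ut], method = method)
  r_perm <- with_seed(seed, {
    vapply(seq_len(permutations), function(i) {
      idx <- sample.int(n)
      stats::cor(m1[ut], m2[idx, idx][ut], method = method)
    }, numeric(1L))
  })
  p <- (sum(r_perm >= r_obs) + 1) / (permutations + 1)
  structure(list(statistic = r_obs, p_value = p,
                 permutations = permutations, method = method, seed = seed,
                 test = "Mantel"),
            class = "permutation_test")
}

#' One-way permanova on a dissimilarity matrix
#'
#' Permutational multivariate analysis of variance: partitions the total
#' sum of squared dissimilarities into between- and within-group
#' components and forms the pseudo-F statistic
#' \deqn{F = \frac{SS_{between}/(a - 1)}{SS_{within}/(n - a)}}
#' with a groups and n samples, where
#' \eqn{SS_{total} = \frac{1}{n}\sum_{i<j} d_{ij}^2} and
#' \eqn{SS_{within} = \sum_g \frac{1}{n_g}\sum_{i<j \in g} d_{ij}^2}
#' (the Gower-centered form, computed directly from the dissimilarities).
#' Significance comes from permuting the group labels; the p-value uses
#' the +1 correction, so with 999 permutations the smallest attainable
#' p is 0.001.
#'
#' @param d symmetric dissimilarity matrix with sample ids as dimnames.
#' @param groups named character vector mapping every sample id of `d` to
#'   a group label; >= 2 groups with >= 2 samples each.
#' @param permutations number of label permutations (default 999).
#' @param seed optional integer seed.
#' @return an object of class `permutation_test`: a list with `statistic`
#'   (pseudo-F), `p_value`, `permutations`, `df` and `seed`.
#' @export
permanova <- function(d, groups, permutations = 999L, seed = NULL) {
  d <- as.matrix(d)
  ids <- rownames(d)
  if (is.null(ids) || !all(ids %in% names(groups))) {
    stop("`groups` must label every sample of `d`", call. = FALSE)
  }
  g <- factor(groups[ids])
  tab <- table(g)
  if (nlevels(g) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (any(tab < 2L)) {
    stop("singleton group(s): ", paste(names(tab)[tab < 2L], collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(d)
  a <- nlevels(g)
  d2 <- d^2
  ss_total <- sum(d2[upper.tri(d2)]) / n

  pseudo_f <- function(g) {
    ss_within <- 0
    for (lev in levels(g)) {
      idx <- which(g == lev)
      ss_within <- ss_within +
        sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
    }
    ((ss_total - ss_within) / (a - 1)) / (ss_within / (n - a))
  }

  f_obs <- pseudo_f(g)
  f_perm <- with_seed(seed, {
    vapply(seq_len(permutations), function(i) pseudo_f(sample(g)),
           numeric(1L))
  })
  p <- (sum(f_perm >= f_obs) + 1) / (permutations + 1)
  structure(list(statistic = f_obs, p_value = p,
                 permutations = permutations,
                 df = c(between = a - 1L, within = n - a), seed = seed,
                 test = "permanova"),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("%s test: statistic = %.4f, p = %.4g (%d permutations)\n",
              x$test, x$statistic, x$p_value, x$permutations))
  invisible(x)
}
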