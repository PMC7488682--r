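#' Structured toy count table with known sharing patterns
#'
#' Builds a small theoretical count table of eight samples (S0-S7) whose
#' pairwise sharing structure makes the behavior of every dissimilarity
#' index predictable, for demonstrations and tests:
#'
#' * S0-S3 each contain exactly 2 abundant, 4 intermediate and 8 rare
#'   taxa (richness 14), with identical class abundances, so any taxon
#'   shared between two of them has the same relative abundance in both.
#' * S1 shares 1 abundant, 2 intermediate and 4 rare taxa with S0
#'   (exactly half of each class): its dissimilarity to S0 is 0.5 at
#'   every diversity order.
#' * S2 shares no abundant but 2 intermediate and 4 rare taxa with S0:
#'   dissimilarity rises toward 1 with q.
#' * S3 shares 1 abundant, all 4 intermediate and 1 rare taxon with S0:
#'   the profile has a valley at intermediate q.
#' * S4 contains the same 14 taxa as S0 but with a different (ramp)
#'   abundance distribution.
#' * S5, S6, S7 have richness 2: their two (equally abundant) taxa are
#'   drawn from S0's abundant, intermediate and rare class respectively.
#' * Taxa of S1-S3 not shared with S0 are unique to each sample.
#'
#' Class relative abundances are parameters constrained by
#' `2a + 4i + 8r = 1` and `a > i > r > 0`; each class abundance times
#' `depth` must be a whole read count.
#'
#' @param abundances numeric vector `c(abundant, intermediate, rare)` of
#'   per-taxon class relative abundances.
#' @param depth read depth of samples S0-S3 and S5-S7.
#' @return a [count_table()] with samples S0..S7; passes an internal
#'   self-check of every class size and sharing count before returning.
#' @export
make_structured_table <- function(abundances = c(abundant = 0.25,
                                           intermediate = 0.075,
                                           rare = 0.025),
                            depth = 1000L) {
  a <- abundances[[1L]]; i <- abundances[[2L]]; r <- abundances[[3L]]
  if (abs(2 * a + 4 * i + 8 * r - 1) > 1e-12) {
    stop("class abundances must satisfy 2a + 4i + 8r = 1", call. = FALSE)
  }
  if (!(a > i && i > r && r > 0)) {
    stop("class abundances must satisfy a > i > r > 0", call. = FALSE)
  }
  depth <- as.integer(depth)
  if (depth < 2L || depth %% 2L != 0L) {
    stop("depth must be a positive even integer", call. = FALSE)
  }
  cc <- depth * c(a, i, r)
  if (any(abs(cc - round(cc)) > 1e-9)) {
    stop("class abundances times depth must be whole read counts", call. = FALSE)
  }
  ca <- round(cc[1L]); ci <- round(cc[2L]); cr <- round(cc[3L])

  taxa <- c(sprintf("A%02d", 1:6), sprintf("I%02d", 1:8), sprintf("R%02d", 1:23))
  samples <- paste0("S", 0:7)
  m <- matrix(0L, length(taxa), length(samples),
              dimnames = list(taxa, samples))

  fill <- function(sample, abundant, intermediate, rare) {
    m[abundant, sample] <<- ca
    m[intermediate, sample] <<- ci
    m[rare, sample] <<- cr
  }
  fill("S0", c("A01", "A02"), sprintf("I%02d", 1:4), sprintf("R%02d", 1:8))
  # half of each class shared with S0, the rest unique
  fill("S1", c("A01", "A03"), sprintf("I%02d", c(1, 2, 5, 6)),
       sprintf("R%02d", c(1:4, 9:12)))
  # no abundant shared, half of intermediate and rare shared
  fill("S2", c("A04", "A05"), sprintf("I%02d", c(1, 2, 7, 8)),
       sprintf("R%02d", c(1:4, 13:16)))
  # 1 abundant, all 4 intermediate, 1 rare shared
  fill("S3", c("A01", "A06"), sprintf("I%02d", 1:4),
       sprintf("R%02d", c(1, 17:23)))
  # same taxa as S0, ramp abundance distribution
  s0_taxa <- c("A01", "A02", sprintf("I%02d", 1:4), sprintf("R%02d", 1:8))
  m[s0_taxa, "S4"] <- as.integer(seq(140L, 10L, by = -10L))
  # richness-2 samples drawn from S0's classes
  m[c("A01", "A02"), "S5"] <- depth %/% 2L
  m[c("I01", "I02"), "S6"] <- depth %/% 2L
  m[c("R01", "R02"), "S7"] <- depth %/% 2L

  tab <- count_table(m)
  structured_self_check(tab, ca, ci, cr)
  tab
}

# Assert every class size and sharing count the fixture promises.
structured_self_check <- function(tab, ca, ci, cr) {
  m <- unclass(tab)
  class_of <- function(s) {
    v <- m[, s]
    list(a = names(v)[v == ca], i = names(v)[v == ci], r = names(v)[v == cr])
  }
  shared <- function(s1, s2) sum(m[, s1] > 0 & m[, s2] > 0)
  for (s in paste0("S", 0:3)) {
    cl <- class_of(s)
    stopifnot(length(cl$a) == 2L, length(cl$i) == 4L, length(cl$r) == 8L,
              sum(m[, s] > 0) == 14L)
  }
  s0 <- class_of("S0")
  s1 <- class_of("S1"); s2 <- class_of("S2"); s3 <- class_of("S3")
  stopifnot(
    length(intersect(s0$a, s1$a)) == 1L,
    length(intersect(s0$i, s1$i)) == 2L,
    length(intersect(s0$r, s1$r)) == 4L,
    length(intersect(s0$a, s2$a)) == 0L,
    length(intersect(s0$i, s2$i)) == 2L,
    length(intersect(s0$r, s2$r)) == 4L,
    length(intersect(s0$a, s3$a)) == 1L,
    length(intersect(s0$i, s3$i)) == 4L,
    length(intersect(s0$r, s3$r)) == 1L,
    shared("S0", "S4") == 14L, sum(m[, "S4"] > 0) == 14L,
    all(vapply(paste0("S", 5:7), function(s) sum(m[, s] > 0), integer(1L)) == 2L),
    all(names(which(m[, "S5"] > 0)) %in% s0$a),
    all(names(which(m[, "S6"] > 0)) %in% s0$i),
    all(names(which(m[, "S7"] > 0)) %in% s0$r)
  )
  # shared taxa between S0 and S1-S3 have identical relative abundance
  p <- sweep(m, 2L, colSums(m), "/")
  for (s in c("S1", "S2", "S3")) {
    both <- m[, "S0"] > 0 & m[, s] > 0
    stopifnot(all(abs(p[both, "S0"] - p[both, s]) < 1e-12))
  }
  invisible(tab)
}

#' Long-tailed (lognormal) community abundance distribution
#'
#' Generates a parametric stand-in for the species-abundance distribution
#' of a real amplicon data set: S taxa with relative abundances drawn from
#' a lognormal distribution with log-scale standard deviation `sigma`,
#' sorted from most to least abundant and normalized to sum to 1.
#' `sigma = 0` gives a uniform community; larger `sigma` gives a longer
#' tail of rare taxa (lower evenness).
#'
#' @param S number of taxa (>= 1).
#' @param sigma lognormal shape parameter (>= 0).
#' @param seed optional integer seed.
#' @return named numeric vector of relative abundances, length S,
#'   decreasing, summing to 1.
#' @export
make_lognormal_community <- function(S, sigma = 2, seed = NULL) {
  if (!is.numeric(S) || length(S) != 1L || S < 1) {
    stop("S must be a positive integer", call. = FALSE)
  }
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  S <- as.integer(S)
  ab <- with_seed(seed, {
    if (sigma == 0) rep(1, S) else sort(stats::rlnorm(S, 0, sigma),
                                        decreasing = TRUE)
  })
  p <- ab / sum(ab)
  names(p) <- sprintf("taxon_%04d", seq_len(S))
  p
}

#' Replicate samples drawn from a known community
#'
#' Draws `n` replicate samples of `depth` reads each from a true
#' relative-abundance distribution by multinomial sampling, emulating
#' repeated sequencing of aliquots from one microbial community.
#'
#' @param truth named relative-abundance vector (sums to 1).
#' @param n number of replicate samples.
#' @param depth reads per sample.
#' @param seed optional integer seed.
#' @return a [count_table()] with n sample columns, each summing to
#'   `depth`.
#' @export
make_replicate_tables <- function(truth, n = 6L, depth = 1e4, seed = NULL) {
  truth <- check_abundances(truth)
  if (is.null(names(truth))) names(truth) <- paste0("taxon_", seq_along(truth))
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  counts <- with_seed(seed, stats::rmultinom(n, size = as.integer(depth),
                                             prob = truth))
  dimnames(counts) <- list(names(truth), paste0("rep_", seq_len(n)))
  # undetected tail taxa are expected in shallow draws; prune quietly
  suppressMessages(count_table(counts))
}
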