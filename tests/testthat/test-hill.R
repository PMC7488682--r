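test_that("Hill numbers match hand-computed and limiting values", {
  # uniform community: qD = S at every order
  for (q in c(0, 0.5, 1, 2, 3)) {
    expect_equal(hill_number(rep(1 / 8, 8), q), 8, tolerance = 1e-12)
  }
  expect_equal(hill_number(c(0.5, 0.25, 0.25), 0), 3)
  # 1/(0.25 + 0.0625 + 0.0625)
  expect_equal(hill_number(c(0.5, 0.25, 0.25), 2), 1 / 0.375, tolerance = 1e-12)
  # zero-abundance taxa never count, including at q = 0
  expect_equal(hill_number(c(0.5, 0.5, 0), 0), 2)
  expect_error(hill_number(c(0.5, 0.5), -1), "q")
  expect_error(hill_number(c(0.5, 0.4), 1), "sum to 1")
})

test_that("alpha/gamma/beta decomposition hits its boundary cases", {
  p <- c(0.5, 0.3, 0.2)
  for (q in c(0, 0.5, 1, 2)) {
    dec <- hill_decompose(cbind(p, p), q)
    expect_equal(dec$beta, 1, tolerance = 1e-12)
    expect_equal(local_dissimilarity(dec), 0, tolerance = 1e-12)
  }
  disjoint <- cbind(c(0.6, 0.4, 0, 0), c(0, 0, 0.7, 0.3))
  for (q in c(0, 0.5, 1, 2)) {
    dec <- hill_decompose(disjoint, q)
    expect_equal(dec$beta, 2, tolerance = 1e-12)
    expect_equal(local_dissimilarity(dec), 1, tolerance = 1e-12)
    expect_equal(regional_dissimilarity(dec), 1, tolerance = 1e-12)
  }
  expect_error(hill_decompose(matrix(p, ncol = 1), 1), ">= 2")
})

test_that("structured half-shared pair gives beta = 1.5 at q = 0", {
  tab <- make_structured_table()
  p <- cbind(to_relative_abundance(tab, "S0"), to_relative_abundance(tab, "S1"))
  dec <- hill_decompose(p, 0)
  # 21 pooled taxa over (14 + 14)/2 = 14 effective per-sample taxa
  expect_equal(dec$gamma, 21)
  expect_equal(dec$alpha, 14)
  expect_equal(dec$beta, 1.5, tolerance = 1e-12)
})

test_that("transforms of beta agree with a literal evaluation and stay in [0,1]", {
  # q=2, N=2, beta=1.5 -> (1.5-1)/(2-1) = 0.5 for the regional transform
  dec <- structure(list(q = 2, N = 2, alpha = 2, gamma = 3, beta = 1.5),
                   class = "hill_decomposition")
  expect_equal(regional_dissimilarity(dec), 0.5)

  set.seed(7)
  for (i in 1:40) {
    tab <- random_table(n_taxa = sample(3:10, 1L), n_samples = 2L)
    px <- to_relative_abundance(tab, "s01")
    py <- to_relative_abundance(tab, "s02")
    for (q in c(0, 0.5, 1, 2)) {
      dec <- hill_decompose(cbind(px, py), q)
      expect_gte(dec$beta, 1 - 1e-9)
      expect_lte(dec$beta, 2 + 1e-9)
      expect_lte(dec$alpha, dec$gamma + 1e-9)
      for (f in list(local_dissimilarity, regional_dissimilarity)) {
        d <- f(dec)
        expect_gte(d, 0); expect_lte(d, 1)
      }
      o <- oracle_decompose2(px, py, q)
      expect_equal(dec$beta, o$beta, tolerance = 1e-12)
      expect_lt(abs(local_dissimilarity(dec) -
                      min(max(oracle_local(o$beta, 2, q), 0), 1)), 1e-10)
      expect_lt(abs(regional_dissimilarity(dec) -
                      min(max(oracle_regional(o$beta, 2, q), 0), 1)), 1e-10)
    }
  }
})

test_that("at q = 0 local equals Sorensen and regional equals Jaccard", {
  set.seed(11)
  for (i in 1:50) {
    tab <- random_table(n_taxa = sample(3:15, 1L), n_samples = 2L)
    x <- unclass(tab)[, 1L]; y <- unclass(tab)[, 2L]
    expect_equal(pair_dissimilarity(x, y, "local", 0), sorensen(x, y),
                 tolerance = 1e-12)
    expect_equal(pair_dissimilarity(x, y, "regional", 0), jaccard(x, y),
                 tolerance = 1e-12)
  }
})

test_that("both transforms are continuous across q = 1", {
  set.seed(3)
  for (i in 1:10) {
    tab <- random_table(n_taxa = 8L, n_samples = 2L)
    x <- unclass(tab)[, 1L]; y <- unclass(tab)[, 2L]
    for (index in c("local", "regional")) {
      d1 <- pair_dissimilarity(x, y, index, 1)
      expect_lt(abs(pair_dissimilarity(x, y, index, 1 + 1e-6) - d1), 1e-5)
      expect_lt(abs(pair_dissimilarity(x, y, index, 1 - 1e-6) - d1), 1e-5)
    }
  }
})

test_that("classic indices satisfy their definitions and bounds", {
  x <- c(a = 3, b = 2, c = 0, d = 1)
  y <- c(a = 1, b = 0, c = 4, d = 2)
  # shared {a,d}, union {a,b,c,d}
  expect_equal(jaccard(x, y), 1 - 2 / 4)
  expect_equal(sorensen(x, y), 1 - 2 * 2 / (3 + 3))
  expect_equal(bray_curtis(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 1)), 1)
  expect_error(jaccard(c(0, 0), c(1, 0)), "empty")
  # identical and disjoint endpoints for all three
  expect_equal(jaccard(x, x), 0)
  expect_equal(sorensen(x, x), 0)
  xd <- c(1, 1, 0, 0); yd <- c(0, 0, 1, 1)
  expect_equal(jaccard(xd, yd), 1)
  expect_equal(sorensen(xd, yd), 1)
})

test_that("Bray-Curtis equals q=1 local dissimilarity on matched-distribution pairs", {
  set.seed(19)
  for (i in 1:30) {
    pr <- matched_pair()
    bc <- bray_curtis(pr$x, pr$y)
    d1 <- local_dissimilarity(hill_decompose(cbind(pr$x, pr$y), 1))
    expect_equal(bc, d1, tolerance = 1e-10)
  }
  # on generic pairs inequality is permitted and typically observed
  set.seed(20)
  diffs <- replicate(20, {
    tab <- random_table(n_taxa = 8L, n_samples = 2L)
    px <- to_relative_abundance(tab, "s01")
    py <- to_relative_abundance(tab, "s02")
    abs(bray_curtis(px, py) -
          local_dissimilarity(hill_decompose(cbind(px, py), 1)))
  })
  expect_gt(max(diffs), 1e-6)
})

test_that("all indices are invariant under taxon reordering", {
  set.seed(5)
  tab <- random_table(n_taxa = 10L, n_samples = 2L)
  x <- unclass(tab)[, 1L]; y <- unclass(tab)[, 2L]
  perm <- sample(seq_along(x))
  for (index in c("local", "regional", "jaccard", "sorensen", "bray_curtis")) {
    for (q in c(0, 1, 2)) {
      expect_equal(pair_dissimilarity(x, y, index, q),
                   pair_dissimilarity(x[perm], y[perm], index, q),
                   tolerance = 1e-12)
    }
  }
})

test_that("dissimilarity matrices are symmetric, zero-diagonal and track sample order", {
  tab <- make_structured_table()
  m <- dissimilarity_matrix(tab, "local", q = 0)
  expect_true(isSymmetric(unclass(m)[, ]))
  expect_equal(unname(diag(m)), rep(0, ncol(tab)))
  expect_true(all(m >= 0 & m <= 1))
  # matches the per-pair worker
  raw <- unclass(tab)
  for (pr in list(c("S0", "S1"), c("S0", "S2"), c("S2", "S3"))) {
    expect_equal(m[pr[1L], pr[2L]],
                 pair_dissimilarity(raw[, pr[1L]], raw[, pr[2L]], "local", 0))
  }
  # permuting sample columns permutes rows/columns consistently
  perm <- c("S3", "S0", "S2", "S1")
  sub <- suppressMessages(count_table(raw[, perm]))
  m2 <- dissimilarity_matrix(sub, "local", q = 0)
  expect_equal(unclass(m2)[, ], unclass(m)[perm, perm])

  z <- matrix(c(1L, 0L), 1, 2, dimnames = list("t", c("ok", "empty")))
  zt <- count_table(z)
  expect_error(dissimilarity_matrix(zt, "local", 1), "empty")
})

test_that("profiles average the requested pairs per q", {
  truth <- make_lognormal_community(50, sigma = 1.5, seed = 4)
  reps <- make_replicate_tables(truth, n = 6L, depth = 2000, seed = 5)
  pairs <- sample_pairs(reps)
  expect_equal(nrow(pairs), 15L)
  prof <- dissimilarity_profile(reps, pairs, q_grid = c(0, 1, 2))
  expect_equal(attr(prof, "pair_count"), 15L)
  expect_true(all(prof$sd >= 0))

  single <- dissimilarity_profile(reps, pairs[1, , drop = FALSE],
                                  q_grid = c(0, 1, 2))
  expect_equal(single$sd, rep(0, 3))

  tab <- make_structured_table()
  flat <- dissimilarity_profile(tab, matrix(c("S0", "S1"), 1),
                                q_grid = seq(0, 2, 0.25))
  expect_equal(flat$mean, rep(0.5, 9), tolerance = 1e-10)

  expect_error(dissimilarity_profile(tab, pairs[0, , drop = FALSE]), "empty")
  expect_error(dissimilarity_profile(tab, matrix(c("S0", "S1"), 1),
                                     q_grid = numeric()), "empty")
})

test_that("sample_pairs enumerates within- and between-category pairs", {
  m <- matrix(1L, 1, 6, dimnames = list("t", paste0("s", 1:6)))
  ct <- count_table(m)
  meta <- setNames(rep(c("A", "B"), each = 3), paste0("s", 1:6))
  expect_equal(nrow(sample_pairs(ct)), 15L)
  expect_equal(nrow(sample_pairs(ct, meta, within = "A")), 3L)
  btw <- sample_pairs(ct, meta, between = c("A", "B"))
  expect_equal(nrow(btw), 9L)
  expect_error(sample_pairs(ct, meta, within = "C"), "< 2 samples")
})
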