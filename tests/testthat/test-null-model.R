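test_that("regional pools record detection frequency and read totals", {
  tab <- make_structured_table()
  pool <- build_pool(tab, c("S0", "S1", "S2", "S3"))
  m <- unclass(tab)[, c("S0", "S1", "S2", "S3")]
  detected <- rowSums(m) > 0
  expect_setequal(pool$taxon_ids, rownames(m)[detected])
  # hand-tallied frequencies on the structured fixture
  expect_equal(unname(pool$frequency["A01"]), 3L)  # S0, S1, S3
  expect_equal(unname(pool$frequency["I01"]), 4L)  # all four
  expect_equal(unname(pool$frequency["R09"]), 1L)  # S1 only
  expect_equal(pool$total_reads[pool$taxon_ids],
               rowSums(m)[pool$taxon_ids])
  # taxa with zero pool reads are excluded
  expect_false(any(rowSums(m[pool$taxon_ids, ]) == 0))
  expect_error(build_pool(tab, character()), "empty")
  expect_error(build_pool(tab, "nope"), "absent")
})

test_that("null samples preserve template richness and depth exactly", {
  set.seed(100)
  tab <- random_table(n_taxa = 20L, n_samples = 6L, max_count = 30L)
  pool <- build_pool(tab)
  for (i in 1:100) {
    rich <- sample(1:length(pool$taxon_ids), 1L)
    depth <- rich + sample(0:500, 1L)
    ns <- randomize_sample(pool, rich, depth)
    expect_equal(sum(ns > 0), rich)
    expect_equal(sum(ns), depth)
    expect_true(all(ns[ns > 0] >= 1L))
  }
  expect_error(randomize_sample(pool, length(pool$taxon_ids) + 1L, 1000),
               "richness")
  expect_error(randomize_sample(pool, 5L, 3L), "depth")
  # richness = pool size selects every taxon
  full <- randomize_sample(pool, length(pool$taxon_ids),
                           length(pool$taxon_ids) * 2L)
  expect_true(all(full > 0))
})

test_that("frequency scheme picks taxa proportionally to occurrence", {
  # pool with frequencies (3, 1): single-taxon draws should split ~ 3:1
  m <- matrix(c(5L, 0L, 4L, 0L, 6L, 0L, 0L, 3L), 2, 4,
              dimnames = list(c("common", "scarce"), paste0("s", 1:4)))
  pool <- build_pool(count_table(m))
  expect_equal(unname(pool$frequency[c("common", "scarce")]), c(3L, 1L))
  set.seed(21)
  n <- 1e4
  picks <- replicate(n, names(which(randomize_sample(pool, 1L, 5L) > 0)))
  phat <- mean(picks == "common")
  se <- sqrt(0.75 * 0.25 / n)
  expect_lt(abs(phat - 0.75), 3 * se)
})

test_that("the Raup-Crick tally identity and bounds hold", {
  set.seed(31)
  tab <- random_table(n_taxa = 15L, n_samples = 6L, max_count = 25L)
  for (q in c(0, 1, 2)) {
    res <- raup_crick(tab, c("s01", "s02"), q = q, iterations = 99L, seed = 7)
    expect_gte(res$rc, 0); expect_lte(res$rc, 1)
    expect_equal(res$rc * res$iterations,
                 res$n_less + 0.5 * res$n_equal, tolerance = 1e-12)
    expect_lte(res$n_less + res$n_equal, res$iterations)
    expect_length(res$null_values, 99L)
  }
})

test_that("identical sample pairs cannot exceed RC = 0.5", {
  set.seed(32)
  tab <- random_table(n_taxa = 12L, n_samples = 4L, max_count = 20L)
  m <- unclass(tab)
  dup <- cbind(m, copy = m[, "s01"])
  colnames(dup)[ncol(dup)] <- "s01_copy"
  tab2 <- suppressMessages(count_table(dup))
  for (q in c(0, 1, 2)) {
    res <- raup_crick(tab2, c("s01", "s01_copy"), q = q,
                      iterations = 99L, seed = 13)
    expect_equal(res$observed, 0)
    expect_lte(res$rc, 0.5)
  }
})

test_that("RC is reproducible under a seed and leaves the caller's RNG alone", {
  set.seed(33)
  tab <- random_table(n_taxa = 12L, n_samples = 4L)
  before <- runif(1)
  set.seed(33); tab2 <- random_table(n_taxa = 12L, n_samples = 4L)
  a <- raup_crick(tab, c("s01", "s02"), q = 1, iterations = 49L, seed = 99)
  b <- raup_crick(tab2, c("s01", "s02"), q = 1, iterations = 49L, seed = 99)
  expect_identical(a$null_values, b$null_values)
  expect_identical(a$rc, b$rc)

  set.seed(44); x1 <- runif(1)
  set.seed(44); invisible(raup_crick(tab, c("s01", "s02"), q = 1,
                                     iterations = 9L, seed = 1)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("RC separates constructed similar and dissimilar pairs", {
  # heterogeneous pool of 3 community types; a within-type pair should look
  # more similar than random assembly (rc near 0), an anti-correlated pair
  # more dissimilar (rc near 1) under an abundance-weighted index
  set.seed(55)
  taxa <- sprintf("t%02d", 1:15)
  block <- function(idx, depth = 300L) {
    v <- setNames(integer(15), taxa)
    v[idx] <- as.integer(stats::rmultinom(1, depth, rep(1, length(idx))))
    v
  }
  cols <- cbind(
    a1 = block(1:5), a2 = block(1:5),        # same habitat type
    b1 = block(6:10), b2 = block(6:10),
    c1 = block(11:15), c2 = block(11:15)
  )
  tab <- suppressMessages(count_table(cols))
  similar <- raup_crick(tab, c("a1", "a2"), q = 1, iterations = 199L, seed = 3)
  dissimilar <- raup_crick(tab, c("a1", "b1"), q = 1, iterations = 199L, seed = 3)
  expect_lt(similar$rc, 0.1)
  expect_gt(dissimilar$rc, 0.9)
})

test_that("rescaling maps [0,1] RC onto [-1,1] linearly", {
  expect_equal(rescale_rc(0.5), 0)
  expect_equal(rescale_rc(1), 1)
  expect_equal(rescale_rc(0), -1)
  expect_equal(rescale_rc(0.75), 0.5)
  expect_error(rescale_rc(1.2), "0, 1")
})

test_that("rc_profile reuses one set of assemblies across the q grid", {
  set.seed(66)
  tab <- random_table(n_taxa = 15L, n_samples = 5L, max_count = 25L)
  pairs <- matrix(c("s01", "s02"), 1)
  prof <- rc_profile(tab, pairs, q_grid = c(0, 1, 2), iterations = 49L,
                     seed = 8)
  expect_equal(nrow(prof), 3L)
  expect_true(all(prof$rc >= 0 & prof$rc <= 1))
  expect_equal(prof$rc_rescaled, 2 * (prof$rc - 0.5))

  # shared assemblies match per-q recomputation under the same seed:
  # the q = 0 row of the profile equals a standalone run at q = 0
  single <- rc_profile(tab, pairs, q_grid = 0, iterations = 49L, seed = 8)
  expect_equal(prof$rc[prof$q == 0], single$rc)
  expect_equal(prof$null_mean[prof$q == 0], single$null_mean)

  # multiple pairs produce one row per pair and q
  prof2 <- rc_profile(tab, sample_pairs(tab)[1:3, ], q_grid = c(0, 2),
                      iterations = 19L, seed = 9)
  expect_equal(nrow(prof2), 6L)
})
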