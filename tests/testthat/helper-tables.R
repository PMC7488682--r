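# Shared test helpers: random table generators and independent oracles.

# Random count table using the current RNG stream; every sample is
# guaranteed at least one read.
random_table <- function(n_taxa = 8L, n_samples = 4L, max_count = 20L) {
  m <- matrix(rbinom(n_taxa * n_samples, max_count, 0.4),
              n_taxa, n_samples,
              dimnames = list(sprintf("t%02d", seq_len(n_taxa)),
                              sprintf("s%02d", seq_len(n_samples))))
  for (j in seq_len(n_samples)) {
    if (sum(m[, j]) == 0L) m[sample.int(n_taxa, 1L), j] <- 1L
  }
  suppressMessages(count_table(m))
}

# ---- independent oracle: literal transcription of the defining formulas ----

oracle_hill <- function(p, q) {
  p <- p[p > 0]
  if (q == 1) exp(-sum(p * log(p))) else sum(p^q)^(1 / (1 - q))
}

oracle_decompose2 <- function(px, py, q) {
  pooled <- (px + py) / 2
  gamma <- oracle_hill(pooled, q)
  w <- c(px, py) / 2
  w <- w[w > 0]
  alpha <- if (q == 1) exp(-sum(w * log(w))) / 2 else sum(w^q)^(1 / (1 - q)) / 2
  list(alpha = alpha, gamma = gamma, beta = gamma / alpha)
}

oracle_local <- function(beta, N, q) {
  if (q == 1) log(beta) / log(N) else (beta^(1 - q) - 1) / (N^(1 - q) - 1)
}

oracle_regional <- function(beta, N, q) {
  if (q == 1) log(beta) / log(N) else (beta^(q - 1) - 1) / (N^(q - 1) - 1)
}

# ---- matched-distribution pair generator ----
# Two samples with the same species-abundance distribution where every
# shared taxon has identical relative abundance in both: the precondition
# under which Bray-Curtis equals the q = 1 local dissimilarity.
matched_pair <- function() {
  n_class <- sample(1:3, 1L)
  values <- sample(1:50, n_class)
  sizes <- sample(1:4, n_class, replace = TRUE)
  shared <- vapply(sizes, function(n) sample(0:n, 1L), integer(1L))
  ids_shared <- list()
  x <- c(); y <- c()
  for (c in seq_len(n_class)) {
    s <- shared[c]; u <- sizes[c] - s
    sh <- if (s > 0) paste0("c", c, "_sh", seq_len(s)) else character()
    ux <- if (u > 0) paste0("c", c, "_x", seq_len(u)) else character()
    uy <- if (u > 0) paste0("c", c, "_y", seq_len(u)) else character()
    x[c(sh, ux)] <- values[c]
    y[c(sh, uy)] <- values[c]
  }
  taxa <- union(names(x), names(y))
  px <- setNames(numeric(length(taxa)), taxa)
  py <- px
  px[names(x)] <- x
  py[names(y)] <- y
  list(x = px / sum(px), y = py / sum(py))
}
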