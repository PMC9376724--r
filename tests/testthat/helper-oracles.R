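# Independent oracles used to check the estimators.  These are deliberately
# simple and slow: plug-in discrete MI from contingency tables, quantile
# binning for continuous data, and exhaustive enumeration over small
# discrete fixtures.  They share no code with the package's estimation path.

# plug-in MI (bits) between two discrete variables given as vectors or
# matrices of codes (matrix columns are jointly encoded)
oracle_mi_discrete <- function(x, y) {
  key <- function(m) {
    if (is.matrix(m)) apply(m, 1, paste, collapse = "\r") else as.character(m)
  }
  tab <- table(key(x), key(y))
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  s <- 0
  for (i in seq_along(px)) for (j in seq_along(py)) {
    if (p[i, j] > 0) s <- s + p[i, j] * log2(p[i, j] / (px[i] * py[j]))
  }
  s
}

# quantile-bin each column, then plug-in MI on the joint codes
oracle_mi_binned <- function(x, y, bins = 8L) {
  bincol <- function(v) {
    if (length(unique(v)) <= bins) return(match(v, sort(unique(v))))
    br <- unique(stats::quantile(v, probs = seq(0, 1, length.out = bins + 1)))
    as.integer(cut(v, br, include.lowest = TRUE))
  }
  bm <- function(m) {
    m <- if (is.matrix(m)) m else matrix(m, ncol = 1)
    apply(m, 2, bincol)
  }
  oracle_mi_discrete(bm(x), bm(y))
}

# an estimator-shaped wrapper so decomposition/search functions can be
# driven by an oracle instead of the neural estimator
oracle_estimator <- function(mi_fun = oracle_mi_binned) {
  function(x, y, config, labels = c("x", "y")) {
    list(value = mi_fun(x, y), spread = 0, failed = FALSE)
  }
}

# --- exhaustively solvable discrete fixture -------------------------------
#
# Five binary genes; the phenotype proxy is y = (g1 XOR g2) + 2 * g3, so
#   I(g1; y) = I(g2; y) = 0         (each XOR input alone is uninformative)
#   I(g3; y) = I(g4; y) = 1 bit     (g4 duplicates g3)
#   I(g5; y) = 0                    (pure noise)
#   I({g1,g2}; y) = 1  -> SRI(g1,g2) = +1  (synergy)
#   I({g3,g4}; y) = 1  -> SRI(g3,g4) = -1  (full redundancy)
#   I(all; y) = H(y) = 2 bits
make_discrete_fixture <- function(n = 4000L, seed = 77L) {
  set.seed(seed)
  g1 <- rbinom(n, 1, 0.5); g2 <- rbinom(n, 1, 0.5)
  g3 <- rbinom(n, 1, 0.5); g4 <- g3
  g5 <- rbinom(n, 1, 0.5)
  counts <- cbind(g1 = g1, g2 = g2, g3 = g3, g4 = g4, g5 = g5)
  y <- matrix(as.numeric(xor(g1, g2) + 2 * g3), ncol = 1,
              dimnames = list(NULL, "y"))
  # global z-scoring (the pipeline contract) is an affine map per modality,
  # so the discrete codes stay discrete and every exact MI is unchanged,
  # while the neural estimator gets centered inputs
  preprocess(paired_dataset(counts, y, preprocessing_state = "raw"))
}

# exact MI (bits) between a gene subset and y for the fixture above, by
# enumeration over all 2^5 equiprobable (g1,g2,g3,g5) x duplicated-g4 states
discrete_fixture_exact_mi <- function(subset) {
  states <- expand.grid(g1 = 0:1, g2 = 0:1, g3 = 0:1, g5 = 0:1)
  states$g4 <- states$g3
  states <- states[, c("g1", "g2", "g3", "g4", "g5")]
  y <- xor(states$g1, states$g2) + 2 * states$g3
  p <- rep(1 / nrow(states), nrow(states))
  key <- apply(states[, subset, drop = FALSE], 1, paste, collapse = ",")
  # I(S; Y) = H(Y) - sum_s p(s) H(Y | s)
  hy <- ent_bits(tapply(p, y, sum))
  cond <- 0
  for (s in unique(key)) {
    sel <- key == s
    ps <- sum(p[sel])
    cond <- cond + ps * ent_bits(tapply(p[sel] / ps, y[sel], sum))
  }
  hy - cond
}

ent_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# cheap estimator settings for tests: enough budget to resolve ~1-2 bit
# structures on small fixtures without dominating the suite runtime
test_config <- function(...) {
  mine_config(n_iterations = 800L, batch_size = 128L, n_replicates = 2L,
              n_jackknife = 0L, seed = 42L, ...)
}
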