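# Most tests here drive the decomposition bookkeeping with exact or binned
# oracles so they are fast and deterministic; the neural estimator's own
# accuracy is covered in test-mine.R and test-acceptance.R.

exact_est <- oracle_estimator(function(x, y) oracle_mi_discrete(x, y))

test_that("per-gene MI ranks genes exactly as the enumeration oracle", {
  ds <- make_discrete_fixture()
  pg <- per_gene_mi(ds, mine_config(), estimator = exact_est)
  expect_equal(pg$n_failed, 0)
  tab <- pg$table
  # informative duplicated pair at the top, XOR inputs and noise at ~0
  expect_setequal(tail(tab$gene, 2), c("g3", "g4"))
  expect_lt(max(tab$mi[tab$gene %in% c("g1", "g2", "g5")]), 0.05)
  expect_equal(tab$mi[tab$gene == "g3"],
               discrete_fixture_exact_mi("g3"), tolerance = 0.02)
  # cumulative sum is over the descending order
  expect_equal(pg$cumulative$cumulative_mi[1], max(tab$mi))
  expect_equal(max(pg$cumulative$cumulative_mi), pg$total_sum,
               tolerance = 1e-9)
  # duplicated genes get identical estimates
  expect_equal(tab$mi[tab$gene == "g3"], tab$mi[tab$gene == "g4"],
               tolerance = 1e-9)
})

test_that("gene-gene MI links informativeness about genes and phenotype", {
  set.seed(61)
  # one latent factor loads on half the genes
  n <- 3000
  u <- rbinom(n, 1, 0.5)
  flip <- function(v, p) ifelse(runif(n) < p, 1 - v, v)
  counts <- cbind(a = flip(u, 0.1), b = flip(u, 0.15), c = flip(u, 0.2),
                  d = rbinom(n, 1, 0.5), e = rbinom(n, 1, 0.5))
  y <- matrix(as.numeric(flip(u, 0.05)), ncol = 1)
  ds <- paired_dataset(counts, y)
  gg <- gene_gene_mi(ds, mine_config(), estimator = exact_est)
  M <- gg$matrix
  expect_equal(M, t(M))
  expect_true(all(is.na(diag(M))))
  # loaded genes talk to each other, unloaded ones do not
  expect_gt(M["a", "b"], 0.2)
  expect_lt(M["d", "e"], 0.02)
  expect_gt(gg$mean_to_others[["a"]], gg$mean_to_others[["d"]])
  expect_gt(gg$spearman$estimate, 0.5)
})

test_that("SRI bookkeeping is exact given its constituent estimates", {
  # canned estimator: the SRI must be exactly the difference of the three
  # constituents, with spreads combined in quadrature
  canned <- function(x, y, config, labels = c("x", "y")) {
    v <- if (ncol(x) == 2) 1.2 else if (identical(labels[1], "gA")) 0.9
         else 0.5
    list(value = v, spread = 0.1, failed = FALSE)
  }
  ds <- paired_dataset(cbind(gA = c(0, 1, 0, 1), gB = c(0, 0, 1, 1)),
                       matrix(rnorm(4), ncol = 1))
  p <- sri_pair(ds, 1, 2, mine_config(), estimator = canned)
  expect_equal(p$sri, 1.2 - 0.9 - 0.5, tolerance = 1e-12)
  expect_equal(p$spread, sqrt(3 * 0.1^2), tolerance = 1e-12)
  expect_error(sri_pair(ds, 2, 2), "distinct")
})

test_that("SRI matches exact enumeration on the discrete fixture", {
  ds <- make_discrete_fixture()
  sm <- sri_matrix(ds, mine_config(), estimator = exact_est)
  # XOR pair: +1 bit of synergy
  expect_equal(sm$values["g1", "g2"], 1, tolerance = 0.05)
  # duplicated pair: fully redundant, SRI = -I(g3; y) = -1
  expect_equal(sm$values["g3", "g4"], -1, tolerance = 0.05)
  # diagonal is the duplicate-gene limit -I(G_i; Ca)
  expect_equal(unname(diag(sm$values)["g3"]),
               -discrete_fixture_exact_mi("g3"), tolerance = 0.02)
  # independent-contribution pairs sit near zero
  expect_lt(abs(sm$values["g3", "g5"]), 0.05)
  expect_equal(sm$values, t(sm$values))
})

test_that("an all-redundant fixture has negative SRI everywhere", {
  set.seed(71)
  n <- 3000
  u <- rbinom(n, 1, 0.5)
  flip <- function(v, p) ifelse(runif(n) < p, 1 - v, v)
  counts <- sapply(c(0.05, 0.1, 0.15, 0.1), function(p) flip(u, p))
  colnames(counts) <- paste0("r", 1:4)
  ds <- paired_dataset(counts, matrix(as.numeric(u), ncol = 1))
  sm <- sri_matrix(ds, mine_config(), estimator = exact_est)
  off <- sm$values[upper.tri(sm$values)]
  expect_true(all(off < 0))
  expect_lt(sm$mean_sri, -0.2)
  # the more informative a gene, the more redundant with others: its mean
  # SRI (signed synergy) is the most negative, so the rank correlation
  # between per-gene MI and per-gene mean SRI is negative
  expect_lt(sm$rank_spearman$estimate, 0)
})

test_that("annotation summaries aggregate pairs by label", {
  ds <- make_discrete_fixture()
  sm <- sri_matrix(ds, mine_config(), estimator = exact_est)

  # all genes one label: the single cell is the global mean SRI
  one <- annotation_sri_summary(sm, setNames(rep("all", 5), sm$gene_labels))
  expect_equal(one$matrix["all", "all"], sm$mean_sri, tolerance = 1e-12)

  # cross-label synergy: the XOR genes straddle the labels while the
  # redundant duplicated pair sits inside label A
  map <- c(g1 = "A", g2 = "B", g3 = "A", g4 = "A", g5 = "B")
  two <- annotation_sri_summary(sm, map)
  expect_gt(two$matrix["A", "B"], max(two$matrix["A", "A"],
                                      two$matrix["B", "B"]))
  # label invariance under gene permutation
  perm <- c(3L, 5L, 1L, 2L, 4L)
  ds_p <- paired_dataset(ds$counts[, perm], ds$traces,
                         preprocessing_state = "normalized")
  sm_p <- sri_matrix(ds_p, mine_config(), estimator = exact_est)
  two_p <- annotation_sri_summary(sm_p, map)
  expect_equal(two$matrix, two_p$matrix, tolerance = 1e-9)

  # single-gene labels have no within-label pair
  lone <- annotation_sri_summary(sm, c(g1 = "solo", g2 = "rest",
                                       g3 = "rest", g4 = "rest",
                                       g5 = "rest"))
  expect_true("solo" %in% lone$undefined)
  expect_error(annotation_sri_summary(sm, c(g1 = "x")), "labeled")
})

test_that("NRI and redundancy-explained follow the set-size arithmetic", {
  # worked example: n = 4, E[I] = {1: 0.5, 2: 0.8, 4: 1.0}, full = 1.0
  rc <- redundancy_explained(c("1" = 0.5, "2" = 0.8, "4" = 1.0),
                             full_mi = 1.0, n = 4)
  cv <- rc$curve
  expect_equal(cv$nri[cv$size == 1], 2.0)
  expect_equal(cv$nri[cv$size == 2], 1.6)
  expect_equal(cv$nri[cv$size == 4], 1.0)
  expect_equal(cv$redundancy_explained[cv$size == 1], 0)
  expect_equal(cv$redundancy_explained[cv$size == 2], 0.4)
  expect_equal(cv$redundancy_explained[cv$size == 4], 1)

  # no superfluous information: RE undefined
  expect_error(redundancy_explained(c("1" = 0.2, "4" = 1), 1, 4),
               "superfluous")
  expect_error(redundancy_explained(c("2" = 0.8), 1, 4), "k = 1")
})

test_that("PC-phenotype information plateaus at the coupled subspace", {
  set.seed(81)
  n <- 4000
  z <- rnorm(n) # single coupled latent dimension
  counts <- cbind(z + rnorm(n, sd = 0.3), z + rnorm(n, sd = 0.3),
                  -z + rnorm(n, sd = 0.3), rnorm(n), rnorm(n))
  y <- matrix(z + rnorm(n, sd = 0.4), ncol = 1)
  ds <- paired_dataset(abs(round(counts * 10)), y,
                       preprocessing_state = "raw")
  ds$counts <- counts # continuous stand-in, PCA-friendly
  pm <- pc_phenotype_mi(ds, mine_config(), max_components = 4,
                        estimator = oracle_estimator(
                          function(x, y) oracle_mi_binned(x[, 1:min(2, ncol(x))], y, bins = 6)))
  tab <- pm$table
  expect_equal(pm$n_failed, 0)
  # the first component carries essentially all phenotype information
  expect_gt(tab$mi[1], 0.3)
  expect_lt(max(tab$mi) - tab$mi[1], 0.15)
  expect_equal(max(tab$mi_norm, na.rm = TRUE), 1)
  expect_equal(tab$entropy_norm[nrow(tab)], 1)
})
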