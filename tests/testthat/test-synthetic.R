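test_that("sampled paired datasets satisfy their structural invariants", {
  spec <- paired_sim_spec(n_cells = 300L, n_genes = 8L, n_timepoints = 60L,
                          seed = 4L)
  ds <- sample_paired_dataset(spec)
  expect_s3_class(ds, "paired_dataset")
  expect_true(all(ds$counts >= 0))
  expect_true(all(ds$counts == round(ds$counts)))
  expect_equal(dim(ds$counts), c(300L, 8L))
  expect_equal(ncol(ds$traces), 60L)
  gt <- attr(ds, "ground_truth")
  expect_equal(dim(gt$latent), c(300L, 3L))

  # bit-identical reproducibility
  ds2 <- sample_paired_dataset(spec)
  expect_identical(ds$counts, ds2$counts)
  expect_identical(ds$traces, ds2$traces)

  expect_error(paired_sim_spec(n_genes = 0), "positive integers")
  expect_error(paired_sim_spec(synergy_pairs = list(c(1, 1))), "distinct")
})

test_that("per-component sub-seeding isolates genes from one another", {
  s8 <- paired_sim_spec(n_cells = 150L, n_genes = 8L, n_timepoints = 40L,
                        seed = 12L)
  s9 <- paired_sim_spec(n_cells = 150L, n_genes = 9L, n_timepoints = 40L,
                        seed = 12L)
  d8 <- sample_paired_dataset(s8)
  d9 <- sample_paired_dataset(s9)
  # adding a ninth gene must not perturb the first eight columns
  expect_identical(d8$counts, d9$counts[, 1:8])
})

test_that("zero coupling makes expression and traces independent", {
  spec <- paired_sim_spec(n_cells = 800L, n_genes = 5L, n_timepoints = 50L,
                          gene_loading = matrix(0, 5, 3), seed = 21L)
  ds <- sample_paired_dataset(spec)
  # permutation test on binned MI between each gene and the leading trace PC
  pc1 <- pca_decompose(ds$traces, n_components = 1)$scores[, 1]
  set.seed(99)
  for (g in c(1L, 4L)) {
    obs <- oracle_mi_binned(ds$counts[, g], pc1, bins = 5)
    null <- replicate(200, oracle_mi_binned(ds$counts[, g], sample(pc1),
                                            bins = 5))
    expect_gt(mean(null >= obs), 0.05) # accept the null at alpha = 0.05
  }
})

test_that("increasing a gene's loading does not decrease its binned MI", {
  base <- matrix(0, 4, 3)
  mk <- function(strength) {
    L <- base; L[1, 1] <- strength
    spec <- paired_sim_spec(n_cells = 1500L, n_genes = 4L,
                            n_timepoints = 60L, gene_loading = L,
                            trace_noise_sd = 0.05, seed = 33L)
    ds <- sample_paired_dataset(spec)
    par <- attr(ds, "ground_truth")$trace_params
    oracle_mi_binned(ds$counts[, 1], par[, "amplitude"], bins = 6)
  }
  mis <- vapply(c(0, 0.3, 0.8), mk, numeric(1))
  expect_true(all(diff(mis) > -0.02))
  expect_gt(mis[3], mis[1] + 0.1)
})

test_that("identical loadings yield redundancy, synergy pairs synergy", {
  # two genes with identical loading rows: redundant (negative SRI)
  L <- matrix(0, 4, 3); L[1, 1] <- L[2, 1] <- 0.8
  spec <- paired_sim_spec(n_cells = 3000L, n_genes = 4L, n_timepoints = 60L,
                          gene_loading = L, trace_noise_sd = 0.05,
                          dispersion = 0.05, seed = 44L)
  ds <- sample_paired_dataset(spec)
  amp <- attr(ds, "ground_truth")$trace_params[, "amplitude"]
  mi1 <- oracle_mi_binned(ds$counts[, 1], amp, bins = 5)
  mi2 <- oracle_mi_binned(ds$counts[, 2], amp, bins = 5)
  mi12 <- oracle_mi_binned(ds$counts[, 1:2], amp, bins = 5)
  expect_gt(mi1, 0.1) # the genes are individually informative
  expect_lt(mi12 - mi1 - mi2, -0.05) # and jointly redundant

  # synergy pair: the centered product drives frequency, the margins do not
  spec2 <- paired_sim_spec(n_cells = 4000L, n_genes = 4L,
                           n_timepoints = 60L,
                           gene_loading = matrix(0, 4, 3),
                           synergy_pairs = list(c(1L, 2L)),
                           synergy_gene_scale = 2,
                           synergy_trace_scale = 0.5,
                           dispersion = 0.01, seed = 55L)
  ds2 <- sample_paired_dataset(spec2)
  freq <- attr(ds2, "ground_truth")$trace_params[, "frequency"]
  s1 <- oracle_mi_binned(ds2$counts[, 1], freq, bins = 4)
  s2 <- oracle_mi_binned(ds2$counts[, 2], freq, bins = 4)
  s12 <- oracle_mi_binned(ds2$counts[, 1:2], freq, bins = 4)
  expect_gt(s12 - s1 - s2, 0.05) # positive SRI
})

test_that("datasets round-trip through the delimited writers", {
  spec <- paired_sim_spec(n_cells = 40L, n_genes = 4L, n_timepoints = 20L,
                          seed = 2L)
  ds <- sample_paired_dataset(spec)
  dir <- withr::local_tempdir()
  paths <- write_paired_dataset(ds, dir)
  expect_true(all(file.exists(paths)))
  back <- load_paired(paths["counts"], paths["traces"])
  expect_equal(unname(back$counts), unname(ds$counts))
  expect_equal(unname(back$traces), unname(ds$traces), tolerance = 1e-9)
  expect_identical(back$cell_ids, ds$cell_ids)
  gt <- jsonlite::read_json(paths["ground_truth"], simplifyVector = TRUE)
  expect_equal(dim(gt$latent), c(40L, 3L))
})
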