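sinusoid_traces <- function(freqs, n_cells = 4, nt = 128, amp = 1) {
  tt <- seq_len(nt) - 1
  do.call(rbind, lapply(seq_len(n_cells), function(i)
    rowSums(sapply(freqs, function(f) amp * sin(2 * pi * f * tt)))))
}

test_that("periodogram concentrates power where the signal lives", {
  tr <- sinusoid_traces(10 / 128)
  p <- periodogram(tr)
  expect_s3_class(p, "spectral_density")
  expect_equal(sum(p$power), 1, tolerance = 1e-12)
  expect_true(all(diff(p$frequencies) > 0))
  # pure sinusoid: all power in the bin containing f0
  expect_equal(p$power[which.max(p$power)], 1, tolerance = 1e-9)
  expect_equal(p$frequencies[which.max(p$power)], 10 / 128)

  # two equal-amplitude sinusoids: two bins each ~0.5, matching a direct
  # DFT evaluation of the same signal
  tr2 <- sinusoid_traces(c(10 / 128, 30 / 128))
  p2 <- periodogram(tr2)
  direct <- Mod(fft(tr2[1, ]))^2 / 128
  direct <- direct[2:65] / sum(direct[2:65])
  expect_equal(p2$power, direct, tolerance = 1e-9)
  expect_equal(sort(p2$power, decreasing = TRUE)[1:2], c(0.5, 0.5),
               tolerance = 1e-9)

  # white noise: approximately flat
  set.seed(1)
  pw <- periodogram(matrix(rnorm(200 * 256), 200))
  expect_lt(max(abs(pw$power - 1 / length(pw$power))),
            3 / length(pw$power))

  expect_error(periodogram(matrix(2, 3, 10)), "degenerate")
})

test_that("spectral entropy matches closed forms and is scale/DC invariant", {
  expect_equal(spectral_entropy(c(1, 0, 0)), 0)
  expect_equal(spectral_entropy(rep(1 / 8, 8)), 3)
  expect_equal(spectral_entropy(c(0.5, 0.25, 0.25)), 1.5)
  expect_error(spectral_entropy(c(0.5, 0.2)), "normalized")

  tr <- sinusoid_traces(c(5 / 128, 13 / 128)) +
    matrix(rnorm(4 * 128, sd = 0.1), 4)
  h <- spectral_entropy(periodogram(tr))
  # amplitude scaling cancels in the normalization
  expect_equal(spectral_entropy(periodogram(10 * tr)), h, tolerance = 1e-12)
  # the DC bin is excluded, so a constant offset changes nothing
  expect_equal(spectral_entropy(periodogram(tr + 7)), h, tolerance = 1e-9)
  # appending duplicate cells leaves the ensemble average unchanged
  expect_equal(spectral_entropy(periodogram(rbind(tr, tr))), h,
               tolerance = 1e-12)
})

test_that("spectral entropy plateaus with sampling frequency", {
  nt <- 200
  tt <- (seq_len(nt) - 1) / nt
  tr <- rbind(sin(2 * pi * 8 * tt), sin(2 * pi * 8 * tt + 0.4))
  sweep <- spectral_entropy_fs_sweep(tr, fs_values = c(50, 100, 200, 400),
                                     fs_native = nt)
  expect_equal(nrow(sweep), 4)
  # plateau: the two largest sampling frequencies agree closely
  expect_lt(abs(sweep$entropy_bits[4] - sweep$entropy_bits[3]), 0.05)
  # scale invariance holds at every fs
  sweep10 <- spectral_entropy_fs_sweep(10 * tr,
                                       fs_values = c(50, 100, 200, 400),
                                       fs_native = nt)
  expect_equal(sweep$entropy_bits, sweep10$entropy_bits, tolerance = 1e-9)
})

test_that("PCA decomposition has orthonormal loadings and sane variance", {
  set.seed(42)
  # isotropic data: all fractions comparable
  x <- matrix(rnorm(2000 * 6), 2000)
  pc <- pca_decompose(x)
  expect_equal(unname(crossprod(pc$components)), diag(6), tolerance = 1e-8)
  expect_true(all(diff(pc$explained_variance_fraction) < 1e-12 + 1e-9))
  expect_equal(sum(pc$explained_variance_fraction), 1, tolerance = 1e-12)
  expect_true(all(abs(pc$explained_variance_fraction - 1 / 6) < 0.05))

  # rank-1 structure dominates
  u <- rnorm(500)
  x1 <- outer(u, c(1, 2, -1)) + matrix(rnorm(1500, sd = 1e-9), 500)
  pc1 <- pca_decompose(x1, n_components = 1)
  expect_gt(pc1$explained_variance_fraction[1], 0.999)
  expect_error(pca_decompose(x1, n_components = 3), "rank")
})

test_that("differential entropy matches the Gaussian closed form", {
  h1 <- 0.5 * log2(2 * pi * exp(1))
  expect_equal(differential_entropy(diag(1)), h1, tolerance = 1e-12)
  expect_equal(differential_entropy(diag(c(1, 4))), 2 * h1 + 1,
               tolerance = 1e-12)
  # rotation invariance: det is basis-free
  set.seed(7)
  x <- matrix(rnorm(3000 * 4), 3000) %*% diag(c(2, 1, 0.5, 0.2))
  q <- qr.Q(qr(matrix(rnorm(16), 4)))
  h_a <- differential_entropy(pca_decompose(x))
  h_b <- differential_entropy(pca_decompose(x %*% q))
  expect_equal(h_a, h_b, tolerance = 1e-6)
  expect_error(differential_entropy(diag(c(1, 0))), "singular")
})

test_that("variance and entropy curves disagree in the expected way", {
  set.seed(3)
  # one dominant direction plus many equal small ones: variance plateaus
  # immediately while entropy keeps accruing near-linearly
  sds <- c(10, rep(0.5, 9))
  x <- matrix(rnorm(4000 * 10), 4000) %*% diag(sds)
  cv <- variance_entropy_curves(x)
  expect_equal(cv$explained_variance_norm[nrow(cv)], 1)
  expect_equal(cv$entropy_norm[nrow(cv)], 1)
  # explained variance has non-increasing increments (sorted eigenvalues)
  expect_true(all(diff(diff(cv$explained_variance)) < 1e-8))
  # variance saturates at k=1; entropy still grows markedly afterwards
  expect_gt(cv$explained_variance[1], 0.95)
  ent_inc <- diff(cv$differential_entropy)
  expect_gt(min(ent_inc[2:9]), 0.5 * max(ent_inc[2:9])) # near-linear rise
})

test_that("pairwise gene correlations flag degenerate genes", {
  x <- cbind(a = c(1, 2, 3), b = c(2, 4, 6), c = c(5, 1, 4))
  pg <- pairwise_gene_correlations(x)
  expect_equal(pg$matrix["a", "b"], 1, tolerance = 1e-12)
  expect_equal(diag(pg$matrix), c(a = 1, b = 1, c = 1))

  set.seed(11)
  xi <- matrix(rnorm(5000 * 8), 5000)
  expect_lt(pairwise_gene_correlations(xi)$mean_abs_r, 0.05)

  xz <- cbind(x, d = c(2, 2, 2))
  pz <- pairwise_gene_correlations(xz)
  expect_identical(pz$undefined_genes, "d")
  expect_true(all(is.na(pz$matrix["d", ])))
})
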