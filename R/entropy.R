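#' Ensemble periodogram of a set of traces
#'
#' Computes the raw (unwindowed) periodogram of every trace via the discrete
#' Fourier transform, averages the per-cell periodograms across cells, and
#' normalizes the result to sum to one over the positive frequencies up to
#' the Nyquist limit \code{fs/2}.  The zero-frequency (DC) bin is excluded,
#' so the spectral entropy downstream is invariant to the signal mean as
#' well as to amplitude rescaling.
#'
#' @param traces Numeric matrix, cells x timepoints (a single trace may be
#'   given as a vector).
#' @param fs Sampling frequency (samples per unit time).
#' @param detrend If TRUE, subtract each trace's mean before transforming
#'   (the DC bin is dropped either way; detrending additionally reduces
#'   leakage of the mean into neighbouring bins).
#' @return An object of class \code{spectral_density}: list with
#'   \code{frequencies} (strictly increasing, positive, up to fs/2),
#'   \code{power} (non-negative, sums to 1), \code{fs}, \code{n_timepoints}.
#' @export
periodogram <- function(traces, fs = 1, detrend = FALSE) {
  if (is.vector(traces)) traces <- matrix(traces, nrow = 1L)
  traces <- as_matrix2(traces, "traces")
  nt <- ncol(traces)
  if (nt < 2) stop("traces need at least 2 timepoints")
  stopifnot_scalar_pos(fs, "fs")
  if (detrend) traces <- traces - rowMeans(traces)
  nf <- nt %/% 2L
  # per-cell raw periodograms |DFT|^2 / nt, positive frequencies only
  ft <- stats::mvfft(t(traces))
  pw <- Mod(ft[seq_len(nf) + 1L, , drop = FALSE])^2 / nt
  power <- rowMeans(pw)
  tot <- sum(power)
  dc <- mean(Mod(ft[1L, ])^2 / nt)
  if (!is.finite(tot) || tot <= 1e-10 * (tot + dc) || tot == 0)
    stop("traces are constant: zero total power, spectral density degenerate")
  structure(list(frequencies = seq_len(nf) * fs / nt,
                 power = power / tot,
                 fs = fs,
                 n_timepoints = nt),
            class = "spectral_density")
}

#' Spectral entropy of a normalized power spectral density
#'
#' Shannon entropy of the normalized power spectral density,
#' \deqn{H = -\sum_{f=1}^{fs/2} P(f) \log_2 P(f),}
#' with the convention \eqn{0 \log 0 = 0}.  Because the PSD is normalized,
#' the result is invariant to amplitude scaling of the underlying signal; it
#' is bounded by \eqn{\log_2} of the number of frequency bins.
#'
#' @param psd A \code{\link{periodogram}} result, or a numeric vector of
#'   normalized spectral weights.
#' @return Entropy in bits.
#' @export
spectral_entropy <- function(psd) {
  p <- if (inherits(psd, "spectral_density")) psd$power else as.numeric(psd)
  if (any(p < -1e-12)) stop("spectral density must be non-negative")
  if (abs(sum(p) - 1) > 1e-6)
    stop("spectral density must be normalized to sum to 1; ",
         "pass a periodogram() result")
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Per-cell averaged spectral entropy
#'
#' Alternative ensemble summary: the spectral entropy of each cell's own
#' normalized periodogram, averaged across cells (rather than averaging
#' periodograms first and taking one entropy, as
#' \code{\link{periodogram}} + \code{\link{spectral_entropy}} do).
#'
#' @inheritParams periodogram
#' @return Mean per-cell spectral entropy in bits.
#' @export
per_cell_spectral_entropy <- function(traces, fs = 1, detrend = FALSE) {
  traces <- as_matrix2(traces, "traces")
  mean(apply(traces, 1L, function(tr)
    spectral_entropy(periodogram(tr, fs = fs, detrend = detrend))))
}

#' Spectral entropy across sampling frequencies
#'
#' Treats each trace as samples of a continuous signal of fixed duration and
#' recomputes the spectral entropy after resampling (linear interpolation) to
#' each requested sampling frequency.  Above a sufficiently large frequency
#' the entropy plateaus, since extra bins beyond the signal's bandwidth carry
#' essentially no power.
#'
#' @param traces Cells x timepoints matrix, natively sampled at
#'   \code{fs_native}.
#' @param fs_values Increasing vector of sampling frequencies to evaluate.
#' @param fs_native Sampling frequency of the input traces (defines the
#'   duration \code{ncol(traces) / fs_native}).
#' @return data.frame with columns \code{fs} and \code{entropy_bits}.
#' @export
spectral_entropy_fs_sweep <- function(traces, fs_values, fs_native = 1) {
  traces <- as_matrix2(traces, "traces")
  if (is.unsorted(fs_values, strictly = TRUE))
    stop("'fs_values' must be strictly increasing")
  nt <- ncol(traces)
  duration <- nt / fs_native
  t_native <- (seq_len(nt) - 1L) / fs_native
  ent <- vapply(fs_values, function(fs) {
    m <- max(4L, floor(fs * duration))
    t_new <- (seq_len(m) - 1L) / fs
    res <- t(apply(traces, 1L, function(tr)
      stats::approx(t_native, tr, xout = pmin(t_new, max(t_native)),
                    rule = 2)$y))
    spectral_entropy(periodogram(res, fs = fs))
  }, numeric(1))
  data.frame(fs = fs_values, entropy_bits = ent)
}

#' Principal-component decomposition of an expression matrix
#'
#' Standard PCA via eigendecomposition of the sample covariance (centered,
#' unscaled -- the pipeline z-scores each modality globally beforehand).
#' Deterministic up to component sign.
#'
#' @param expression Cells x genes numeric matrix.
#' @param n_components Number of components to retain (defaults to the full
#'   rank).
#' @return An object of class \code{pc_decomposition}: \code{components}
#'   (orthonormal loadings, genes x k), \code{scores} (cells x k),
#'   \code{explained_variance_fraction} (of total variance, non-increasing),
#'   \code{variances} (per-component), \code{covariance} (diagonal k x k
#'   covariance of the transformed data), \code{n_components}.
#' @export
pca_decompose <- function(expression, n_components = NULL) {
  expression <- as_matrix2(expression, "expression")
  k_max <- min(nrow(expression) - 1L, ncol(expression))
  n_components <- as.integer(n_components %||% k_max)
  if (n_components < 1 || n_components > k_max)
    stop(sprintf("'n_components' must lie in 1..%d", k_max))
  pc <- stats::prcomp(expression, center = TRUE, scale. = FALSE)
  vars <- pc$sdev^2
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-8)
  if (n_components > rank)
    stop(sprintf("'n_components' (%d) exceeds the data rank (%d)",
                 n_components, rank))
  k <- seq_len(n_components)
  structure(list(components = pc$rotation[, k, drop = FALSE],
                 scores = pc$x[, k, drop = FALSE],
                 explained_variance_fraction = vars[k] / sum(vars),
                 variances = vars[k],
                 covariance = diag(vars[k], nrow = n_components),
                 n_components = n_components),
            class = "pc_decomposition")
}

#' Gaussian differential entropy of retained principal components
#'
#' Approximates the differential entropy of the transformed data assuming
#' normality of the components (each principal component is a weighted sum of
#' many variables, motivating a central-limit argument):
#' \deqn{h = \tfrac n2 \log_2 (2\pi e) + \tfrac12 \log_2 \det \Sigma_{PC}}
#' in bits, where \eqn{n} is the number of retained components and
#' \eqn{\Sigma_{PC}} their covariance.
#'
#' @param pc A \code{\link{pca_decompose}} result, or a covariance matrix of
#'   transformed data.
#' @return Differential entropy in bits.
#' @export
differential_entropy <- function(pc) {
  S <- if (inherits(pc, "pc_decomposition")) pc$covariance
       else as_matrix2(pc, "pc")
  n <- nrow(S)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0))
    stop("component covariance is singular; differential entropy undefined")
  n / 2 * log2(2 * pi * exp(1)) + 0.5 * sum(log2(ev))
}

#' Explained-variance and differential-entropy curves over component count
#'
#' For each number of retained components k, the cumulative explained
#' variance fraction and the Gaussian differential entropy of the first k
#' components, both raw and normalized by their value at the maximum k.
#' The contrast between the two curves shows how variance concentrates in a
#' few components while entropy keeps accruing across many.
#'
#' @param expression Cells x genes matrix (z-scored upstream).
#' @param max_components Largest k (defaults to the data rank).
#' @return data.frame with columns \code{k}, \code{explained_variance},
#'   \code{differential_entropy}, \code{explained_variance_norm},
#'   \code{entropy_norm}.
#' @export
variance_entropy_curves <- function(expression, max_components = NULL) {
  expression <- as_matrix2(expression, "expression")
  pc_full <- stats::prcomp(expression, center = TRUE, scale. = FALSE)
  vars <- pc_full$sdev^2
  rank <- sum(pc_full$sdev > max(pc_full$sdev) * 1e-8)
  kk <- seq_len(min(max_components %||% rank, rank))
  cum_var <- cumsum(vars)[kk] / sum(vars)
  ent <- vapply(kk, function(k)
    k / 2 * log2(2 * pi * exp(1)) + 0.5 * sum(log2(vars[seq_len(k)])),
    numeric(1))
  data.frame(k = kk,
             explained_variance = cum_var,
             differential_entropy = ent,
             explained_variance_norm = cum_var / cum_var[length(kk)],
             entropy_norm = ent / ent[length(kk)])
}

#' Pairwise gene-gene Pearson correlations
#'
#' @param expression Cells x genes matrix with at least 2 cells.
#' @return List with \code{matrix} (gene x gene correlations, diagonal 1,
#'   zero-variance genes NA), \code{mean_r} and \code{mean_abs_r} (upper
#'   triangle, NA-dropped), \code{undefined_genes} (zero-variance gene
#'   names/indices).
#' @export
pairwise_gene_correlations <- function(expression) {
  expression <- as_matrix2(expression, "expression")
  if (nrow(expression) < 2) stop("need at least 2 cells")
  sds <- apply(expression, 2L, stats::sd)
  flat <- which(sds == 0)
  cm <- suppressWarnings(stats::cor(expression))
  cm[flat, ] <- NA_real_
  cm[, flat] <- NA_real_
  diag(cm) <- ifelse(seq_len(ncol(cm)) %in% flat, NA_real_, 1)
  up <- cm[upper.tri(cm)]
  list(matrix = cm,
       mean_r = mean(up, na.rm = TRUE),
       mean_abs_r = mean(abs(up), na.rm = TRUE),
       undefined_genes = if (length(flat))
         (colnames(expression) %||% seq_len(ncol(expression)))[flat]
       else character(0))
}
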