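#' Closed-form mutual information of a multivariate Gaussian
#'
#' For a jointly Gaussian pair \eqn{(X, Y)} with joint covariance
#' \eqn{\Sigma}, the mutual information has the closed form
#' \deqn{I(X;Y) = \tfrac12 \log_2 \frac{\det\Sigma_X \, \det\Sigma_Y}
#'   {\det\Sigma}}
#' in bits, where \eqn{\Sigma_X} and \eqn{\Sigma_Y} are the marginal
#' covariance blocks.  This is the ground truth against which the neural
#' lower-bound estimator is calibrated.
#'
#' @param cov Joint covariance matrix (symmetric positive definite).
#' @param dim_x Number of leading dimensions belonging to the X block.
#' @return Mutual information in bits (non-negative scalar).
#' @examples
#' rho <- 0.9
#' gaussian_mi_closed_form(matrix(c(1, rho, rho, 1), 2), 1) # 1.198 bits
#' @export
gaussian_mi_closed_form <- function(cov, dim_x) {
  cov <- as_matrix2(cov, "cov")
  d <- nrow(cov)
  if (ncol(cov) != d || max(abs(cov - t(cov))) > 1e-8)
    stop("'cov' must be a symmetric square matrix")
  if (dim_x < 1 || dim_x >= d)
    stop("'dim_x' must split 'cov' into two non-empty blocks")
  ch <- tryCatch(chol(cov), error = function(e) NULL)
  if (is.null(ch))
    stop("'cov' is not positive definite; mutual information is undefined")
  ix <- seq_len(dim_x)
  ld <- function(m) as.numeric(determinant(m, logarithm = TRUE)$modulus)
  mi <- 0.5 * (ld(cov[ix, ix, drop = FALSE]) +
               ld(cov[-ix, -ix, drop = FALSE]) - ld(cov)) / log(2)
  max(mi, 0)
}

#' Specify a Gaussian validation suite
#'
#' Describes a collection of multivariate Gaussian datasets used to calibrate
#' the neural mutual-information estimator against the closed form.  Each
#' dataset pairs a dimension split with a cross-correlation level
#' \eqn{\rho}: matched coordinates of the X and Y blocks share correlation
#' \eqn{\rho}, all other cross-correlations are zero, and the marginal blocks
#' are identity, giving true MI
#' \eqn{-\tfrac m2 \log_2 (1-\rho^2)} for \eqn{m = \min(d_x, d_y)} matched
#' pairs.
#'
#' @param dimension_pairs List of integer pairs \code{c(dim_x, dim_y)}.
#' @param coupling_levels Numeric vector of correlations in (-1, 1).
#' @param n_samples Samples per dataset.
#' @param seed Integer seed; the suite is reproducible bit-for-bit.
#' @return An object of class \code{gaussian_suite_spec}.
#' @export
gaussian_suite_spec <- function(dimension_pairs = list(c(1L, 1L)),
                                coupling_levels = c(0, 0.3, 0.5, 0.7,
                                                    0.8, 0.9, 0.95, 0.98),
                                n_samples = 5000L,
                                seed = 1L) {
  if (!is.list(dimension_pairs) || length(dimension_pairs) == 0)
    stop("'dimension_pairs' must be a non-empty list of (dim_x, dim_y) pairs")
  for (p in dimension_pairs) {
    if (length(p) != 2L || any(p < 1) || any(p != round(p)))
      stop("each dimension pair must be two positive integers")
  }
  if (any(abs(coupling_levels) >= 1))
    stop("coupling levels must lie strictly inside (-1, 1)")
  stopifnot_scalar_pos(n_samples, "n_samples")
  # every (pair, rho) joint covariance must be positive definite, and the
  # closed-form MI finite and non-negative; checked at construction
  for (p in dimension_pairs) {
    for (rho in coupling_levels) {
      S <- suite_covariance(p[1], p[2], rho)
      mi <- gaussian_mi_closed_form(S, p[1])
      if (!is.finite(mi) || mi < 0)
        stop(sprintf("coupling %.3f yields invalid closed-form MI", rho))
    }
  }
  structure(list(dimension_pairs = dimension_pairs,
                 coupling_levels = coupling_levels,
                 n_samples = as.integer(n_samples),
                 seed = as.integer(seed)),
            class = "gaussian_suite_spec")
}

# block covariance: identity marginals, rho on the matched diagonal
suite_covariance <- function(dx, dy, rho) {
  d <- dx + dy
  S <- diag(d)
  m <- min(dx, dy)
  for (i in seq_len(m)) {
    S[i, dx + i] <- rho
    S[dx + i, i] <- rho
  }
  S
}

#' Sample a Gaussian validation suite
#'
#' Draws one dataset per (dimension pair, coupling level) combination of the
#' spec, together with its closed-form mutual information.
#'
#' @param spec A \code{\link{gaussian_suite_spec}}.
#' @return A list with one element per dataset, each a list with entries
#'   \code{x}, \code{y} (sample matrices), \code{true_mi_bits}, \code{rho},
#'   \code{dim_x}, \code{dim_y}.
#' @export
sample_gaussian_suite <- function(spec) {
  stopifnot(inherits(spec, "gaussian_suite_spec"))
  out <- list()
  k <- 0L
  for (p in spec$dimension_pairs) {
    for (rho in spec$coupling_levels) {
      k <- k + 1L
      dx <- p[1]; dy <- p[2]
      if (spec$n_samples < 10 * (dx + dy))
        warning(sprintf(
          "n_samples = %d is below 10x the total dimension (%d); ",
          spec$n_samples, dx + dy),
          "the estimator may be unconstrained")
      S <- suite_covariance(dx, dy, rho)
      Z <- with_seed(sub_seed(spec$seed, k), {
        matrix(stats::rnorm(spec$n_samples * (dx + dy)),
               nrow = spec$n_samples)
      })
      XY <- Z %*% chol(S)
      out[[k]] <- list(x = XY[, seq_len(dx), drop = FALSE],
                       y = XY[, dx + seq_len(dy), drop = FALSE],
                       true_mi_bits = gaussian_mi_closed_form(S, dx),
                       rho = rho, dim_x = dx, dim_y = dy)
    }
  }
  out
}
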