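#' Specify a synthetic paired count/trace dataset
#'
#' Describes a generative model for paired single-cell data emulating the
#' structure of a MERFISH-plus-live-imaging experiment: per-cell transcript
#' counts for a panel of genes together with an oscillatory signaling trace
#' from the same cell.  A low-dimensional latent cell state couples the two
#' modalities: counts are negative-binomial around a log-mean affine in the
#' latent state, and traces are damped oscillations whose parameters
#' (amplitude, frequency, decay, baseline) are affine in the same latent
#' state, plus noise.  Synergy pairs inject an interaction: two genes receive
#' independent private latent deviations whose centered product (not either
#' deviation alone) drives a trace parameter, so each gene is marginally
#' uninformative while the pair is informative -- an XOR-like construction
#' with known positive synergy.
#'
#' @param n_cells,n_genes,n_timepoints,n_latent Dimensions of the dataset
#'   and of the shared latent cell state.  Defaults give a desk-scale
#'   dataset (2000 x 20 x 100) large enough to constrain the neural MI
#'   estimator.
#' @param gene_loading Genes x latent matrix mapping latent state to
#'   log-mean expression; \code{NULL} assigns each gene to one latent
#'   dimension round-robin at strength \code{default_loading_strength}.
#' @param default_loading_strength Loading used when \code{gene_loading} is
#'   NULL.
#' @param base_log_mean Per-gene intercept of the log count mean (scalar or
#'   length n_genes); default log(20) counts.
#' @param dispersion Per-gene negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); scalar recycled.
#' @param trace_loading 4 x n_latent matrix mapping latent state to the
#'   trace parameters, rows (amplitude, frequency, decay, baseline);
#'   \code{NULL} gives a default that spreads the latent dimensions across
#'   parameters.
#' @param trace_intercept Length-4 intercepts for (amplitude, frequency,
#'   decay, baseline); frequency is in cycles per timepoint.
#' @param trace_noise_sd Additive Gaussian noise on the traces.
#' @param synergy_pairs List of integer gene-index pairs given the XOR-like
#'   interaction described above.
#' @param synergy_gene_scale Loading of each synergy gene on its private
#'   latent deviation.
#' @param synergy_trace_scale Coefficient of the centered product on the
#'   driven trace parameter.
#' @param synergy_target Which trace parameter the interaction drives.
#' @param seed Integer seed; expanded into per-component sub-seeds via a
#'   counter, so adding a gene never perturbs draws for the others.
#' @return An object of class \code{paired_sim_spec}.
#' @export
paired_sim_spec <- function(n_cells = 2000L,
                            n_genes = 20L,
                            n_timepoints = 100L,
                            n_latent = 3L,
                            gene_loading = NULL,
                            default_loading_strength = 0.4,
                            base_log_mean = log(20),
                            dispersion = 0.3,
                            trace_loading = NULL,
                            trace_intercept = c(amplitude = 1, frequency = 0.1,
                                                decay = 0.02, baseline = 0),
                            trace_noise_sd = 0.1,
                            synergy_pairs = list(),
                            synergy_gene_scale = 0.5,
                            synergy_trace_scale = 0.04,
                            synergy_target = c("frequency", "amplitude",
                                               "decay", "baseline"),
                            seed = 1L) {
  for (v in c(n_cells, n_genes, n_timepoints, n_latent))
    if (v < 1 || v != round(v)) stop("dimensions must be positive integers")
  synergy_target <- match.arg(synergy_target)
  if (is.null(gene_loading)) {
    gene_loading <- matrix(0, n_genes, n_latent)
    for (g in seq_len(n_genes))
      gene_loading[g, ((g - 1L) %% n_latent) + 1L] <- default_loading_strength
  }
  gene_loading <- as_matrix2(gene_loading, "gene_loading")
  if (!all(dim(gene_loading) == c(n_genes, n_latent)))
    stop("'gene_loading' must be n_genes x n_latent")
  if (is.null(trace_loading)) {
    scales <- c(amplitude = 0.3, frequency = 0.03, decay = 0.008,
                baseline = 0.2)
    trace_loading <- matrix(0, 4, n_latent,
                            dimnames = list(names(scales), NULL))
    for (j in seq_len(n_latent)) {
      p <- ((j - 1L) %% 4L) + 1L
      trace_loading[p, j] <- scales[p]
    }
  }
  trace_loading <- as_matrix2(trace_loading, "trace_loading")
  if (!all(dim(trace_loading) == c(4L, n_latent)))
    stop("'trace_loading' must be 4 x n_latent (amplitude, frequency, decay, baseline)")
  rownames(trace_loading) <- c("amplitude", "frequency", "decay", "baseline")
  dispersion <- rep_len(dispersion, n_genes)
  if (any(dispersion <= 0)) stop("'dispersion' must be positive")
  base_log_mean <- rep_len(base_log_mean, n_genes)
  if (length(trace_intercept) != 4L)
    stop("'trace_intercept' must have length 4")
  for (p in synergy_pairs) {
    if (length(p) != 2L || any(p < 1) || any(p > n_genes) || p[1] == p[2])
      stop("each synergy pair must be two distinct gene indices")
  }
  structure(list(n_cells = as.integer(n_cells),
                 n_genes = as.integer(n_genes),
                 n_timepoints = as.integer(n_timepoints),
                 n_latent = as.integer(n_latent),
                 gene_loading = gene_loading,
                 base_log_mean = base_log_mean,
                 dispersion = dispersion,
                 trace_loading = trace_loading,
                 trace_intercept = stats::setNames(
                   as.numeric(trace_intercept),
                   c("amplitude", "frequency", "decay", "baseline")),
                 trace_noise_sd = trace_noise_sd,
                 synergy_pairs = synergy_pairs,
                 synergy_gene_scale = synergy_gene_scale,
                 synergy_trace_scale = synergy_trace_scale,
                 synergy_target = synergy_target,
                 seed = as.integer(seed)),
            class = "paired_sim_spec")
}

#' Sample a synthetic paired dataset
#'
#' Draws a \code{\link{paired_dataset}} from a \code{\link{paired_sim_spec}}:
#' a latent state per cell, negative-binomial counts around
#' loading-determined means, and traces
#' \deqn{y(t) = baseline + amplitude \cdot e^{-decay\, t}
#'   \sin(2\pi\, frequency\, t) + \epsilon}
#' with parameters affine in the latent state (plus centered-product
#' interaction terms for synergy pairs).  The generating latent values and
#' per-cell trace parameters are attached as ground truth for oracle use.
#'
#' @param spec A \code{\link{paired_sim_spec}}.
#' @return A \code{paired_dataset}; the generating values are in
#'   \code{attr(x, "ground_truth")}.
#' @export
sample_paired_dataset <- function(spec) {
  stopifnot(inherits(spec, "paired_sim_spec"))
  nc <- spec$n_cells; ng <- spec$n_genes
  nt <- spec$n_timepoints; nl <- spec$n_latent

  z <- with_seed(sub_seed(spec$seed, 1L),
                 matrix(stats::rnorm(nc * nl), nc, nl))

  # private latent deviations for synergy genes (independent of z)
  syn_u <- list()
  syn_genes <- integer(0)
  for (k in seq_along(spec$synergy_pairs)) {
    p <- spec$synergy_pairs[[k]]
    syn_u[[k]] <- with_seed(sub_seed(spec$seed, 10L + k),
                            matrix(stats::rnorm(nc * 2L), nc, 2L))
    syn_genes <- c(syn_genes, p)
  }

  log_mu <- sweep(z %*% t(spec$gene_loading), 2L, spec$base_log_mean, `+`)
  for (k in seq_along(spec$synergy_pairs)) {
    p <- spec$synergy_pairs[[k]]
    log_mu[, p[1]] <- log_mu[, p[1]] + spec$synergy_gene_scale * syn_u[[k]][, 1]
    log_mu[, p[2]] <- log_mu[, p[2]] + spec$synergy_gene_scale * syn_u[[k]][, 2]
  }

  counts <- matrix(0L, nc, ng)
  for (g in seq_len(ng)) {
    counts[, g] <- with_seed(sub_seed(spec$seed, 100L + g),
      stats::rnbinom(nc, size = 1 / spec$dispersion[g], mu = exp(log_mu[, g])))
  }
  gene_labels <- sprintf("gene%02d", seq_len(ng))
  colnames(counts) <- gene_labels

  # per-cell trace parameters, affine in latent state
  par <- sweep(z %*% t(spec$trace_loading), 2L, spec$trace_intercept, `+`)
  colnames(par) <- rownames(spec$trace_loading)
  for (k in seq_along(spec$synergy_pairs)) {
    # centered product: E[u1 u2 | u1] = 0, so marginal dependence vanishes
    inter <- syn_u[[k]][, 1] * syn_u[[k]][, 2]
    par[, spec$synergy_target] <-
      par[, spec$synergy_target] + spec$synergy_trace_scale * inter
  }
  par[, "amplitude"] <- pmax(par[, "amplitude"], 0.05)
  par[, "frequency"] <- pmax(par[, "frequency"], 0.005)
  par[, "decay"] <- pmax(par[, "decay"], 0)

  tt <- seq_len(nt) - 1L
  traces <- par[, "baseline"] +
    par[, "amplitude"] * exp(-par[, "decay"] %o% tt) *
    sin(2 * pi * (par[, "frequency"] %o% tt))
  noise <- with_seed(sub_seed(spec$seed, 2L),
                     matrix(stats::rnorm(nc * nt, sd = spec$trace_noise_sd),
                            nc, nt))
  traces <- traces + noise
  colnames(traces) <- sprintf("t%03d", tt)

  ds <- paired_dataset(counts = counts, traces = traces,
                       gene_labels = gene_labels,
                       cell_ids = sprintf("cell%05d", seq_len(nc)))
  attr(ds, "ground_truth") <- list(latent = z,
                                   synergy_latents = syn_u,
                                   trace_params = par,
                                   spec = spec)
  ds
}

#' Write a paired dataset to delimited tables
#'
#' Writes the counts and traces as tab-delimited tables keyed by cell id
#' (counts columns are gene names, trace columns timepoint indices), and, if
#' ground truth is attached, a JSON sidecar with the generating latent
#' values and loadings.
#'
#' @param dataset A \code{paired_dataset}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_paired_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "paired_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cpath <- file.path(dir, "counts.tsv")
  tpath <- file.path(dir, "traces.tsv")
  utils::write.table(
    data.frame(cell_id = dataset$cell_ids, dataset$counts,
               check.names = FALSE),
    cpath, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(cell_id = dataset$cell_ids, dataset$traces,
               check.names = FALSE),
    tpath, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(counts = cpath, traces = tpath)
  gt <- attr(dataset, "ground_truth")
  if (!is.null(gt)) {
    gpath <- file.path(dir, "ground_truth.json")
    jsonlite::write_json(
      list(latent = gt$latent,
           trace_params = gt$trace_params,
           gene_loading = gt$spec$gene_loading,
           trace_loading = gt$spec$trace_loading,
           synergy_pairs = gt$spec$synergy_pairs,
           seed = gt$spec$seed),
      gpath, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
    paths <- c(paths, ground_truth = gpath)
  }
  invisible(paths)
}
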