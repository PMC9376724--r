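# Gene-set construction strategies over set size: greedy most-informative
# (upper bound), greedy least-informative (lower bound), and random
# sampling.  Candidate scanning during the greedy searches runs at a reduced
# estimation budget; the chosen nested sets are then re-evaluated at the
# full budget for the reported curve.

#' Reduced-budget configuration for greedy candidate scanning
#'
#' Halves the iteration budget and drops replicates and the jackknife; used
#' only to rank candidate additions, never for reported values.
#'
#' @param config A \code{\link{mine_config}}.
#' @return A cheaper \code{mine_config}.
#' @export
scan_config <- function(config) {
  config$n_iterations <- max(200L, config$n_iterations %/% 2L)
  config$n_replicates <- 1L
  config$n_jackknife <- 0L
  config
}

#' Greedy most/least-informative gene-set search
#'
#' Builds a nested family of gene sets: starting from the single most
#' (least) informative gene, each step evaluates the joint MI of the current
#' set plus every remaining candidate and keeps the argmax (argmin).  Ties
#' break to the smallest gene index.  The maximize direction traces an upper
#' bound on the information in sets of each size reachable by forward
#' selection; the minimize direction traces a lower bound whose growth
#' reflects the unique information added per gene.
#'
#' @param dataset A normalized \code{\link{paired_dataset}}.
#' @param config Full-budget \code{\link{mine_config}} used to re-evaluate
#'   the chosen sets.
#' @param direction \code{"maximize"} or \code{"minimize"}.
#' @param max_size Stop after sets of this size (default all genes).
#' @param scan A reduced-budget config for candidate scanning (default
#'   \code{\link{scan_config}(config)}).
#' @param estimator Injectable MI estimator (see
#'   \code{\link{per_gene_mi}}).
#' @return Object of class \code{set_search_trace}: \code{strategy},
#'   \code{order} (genes as added), \code{mi_by_size} (size, mi, spread from
#'   the full-budget re-evaluation), \code{scan_log} (every candidate
#'   evaluation).
#' @export
greedy_search <- function(dataset, config = mine_config(),
                          direction = c("maximize", "minimize"),
                          max_size = NULL, scan = NULL,
                          estimator = default_estimator) {
  stopifnot(inherits(dataset, "paired_dataset"))
  direction <- match.arg(direction)
  ng <- ncol(dataset$counts)
  if (ng < 2) stop("need at least 2 genes")
  max_size <- min(max_size %||% ng, ng)
  scan <- scan %||% scan_config(config)
  better <- if (direction == "maximize") `>` else `<`

  chosen <- integer(0)
  log_rows <- list()
  step_counter <- 0L
  while (length(chosen) < max_size) {
    candidates <- setdiff(seq_len(ng), chosen)
    best_g <- NA_integer_; best_v <- NA_real_
    for (g in candidates) {
      step_counter <- step_counter + 1L
      est <- estimator(dataset$counts[, c(chosen, g), drop = FALSE],
                       dataset$traces,
                       clone_config_seed(scan, 50000L + step_counter),
                       labels = c(sprintf("set+%s", dataset$gene_labels[g]),
                                  "Ca"))
      v <- if (isTRUE(est$failed)) NA_real_ else est$value
      log_rows[[step_counter]] <- data.frame(
        set_size = length(chosen) + 1L, candidate = dataset$gene_labels[g],
        mi = v, failed = isTRUE(est$failed))
      if (is.na(v)) next # failed candidate: skipped with record
      if (is.na(best_v) || better(v, best_v)) { best_v <- v; best_g <- g }
    }
    if (is.na(best_g)) stop("all candidate evaluations failed at size ",
                            length(chosen) + 1L)
    chosen <- c(chosen, best_g)
  }

  # re-evaluate the chosen nested sets at the full budget
  mi <- spread <- rep(NA_real_, max_size)
  for (k in seq_len(max_size)) {
    est <- estimator(dataset$counts[, chosen[seq_len(k)], drop = FALSE],
                     dataset$traces,
                     clone_config_seed(config, 60000L + k),
                     labels = c(sprintf("%s-set k=%d", direction, k), "Ca"))
    if (!isTRUE(est$failed)) {
      mi[k] <- est$value
      spread[k] <- est$spread %||% NA_real_
    }
  }
  structure(list(strategy = if (direction == "maximize") "upper" else "lower",
                 direction = direction,
                 order = dataset$gene_labels[chosen],
                 order_idx = chosen,
                 mi_by_size = data.frame(size = seq_len(max_size),
                                         mi = mi, spread = spread),
                 scan_log = do.call(rbind, log_rows)),
            class = "set_search_trace")
}

#' Random gene-set sampling across sizes
#'
#' Uniformly samples gene subsets (without replacement within a set) at each
#' requested size and estimates their joint MI with the phenotype; the
#' per-size mean feeds the redundancy-explained curve and the per-size
#' median/quartiles summarize the distribution.
#'
#' @inheritParams greedy_search
#' @param sizes Integer set sizes within 1..n_genes.
#' @param samples_per_size Random sets drawn per size (a single sample is
#'   used when size equals the number of genes -- there is only one such
#'   set).
#' @return Object of class \code{set_search_trace} with \code{samples}
#'   (size, sample, mi, members) and \code{by_size} (size, mean_mi,
#'   median_mi, q25, q75).
#' @export
random_sets <- function(dataset, config = mine_config(), sizes,
                        samples_per_size = 4L,
                        estimator = default_estimator) {
  stopifnot(inherits(dataset, "paired_dataset"))
  ng <- ncol(dataset$counts)
  sizes <- as.integer(sizes)
  if (any(sizes < 1 | sizes > ng)) stop("sizes must lie in 1..n_genes")
  rows <- list()
  ctr <- 0L
  for (k in sizes) {
    ns <- if (k == ng) 1L else samples_per_size
    for (s in seq_len(ns)) {
      ctr <- ctr + 1L
      members <- with_seed(sub_seed(config$seed, 70000L + ctr),
                           sort(sample.int(ng, k)))
      est <- estimator(dataset$counts[, members, drop = FALSE],
                       dataset$traces,
                       clone_config_seed(config, 71000L + ctr),
                       labels = c(sprintf("random k=%d #%d", k, s), "Ca"))
      rows[[ctr]] <- data.frame(
        size = k, sample = s,
        mi = if (isTRUE(est$failed)) NA_real_ else est$value,
        members = paste(dataset$gene_labels[members], collapse = "+"),
        failed = isTRUE(est$failed))
    }
  }
  samples <- do.call(rbind, rows)
  ok <- samples[!samples$failed & is.finite(samples$mi), ]
  by_size <- do.call(rbind, lapply(split(ok, ok$size), function(d)
    data.frame(size = d$size[1], mean_mi = mean(d$mi),
               median_mi = stats::median(d$mi),
               q25 = unname(stats::quantile(d$mi, 0.25)),
               q75 = unname(stats::quantile(d$mi, 0.75)),
               n = nrow(d))))
  rownames(by_size) <- NULL
  structure(list(strategy = "random",
                 order = NULL,
                 mi_by_size = by_size[, c("size", "median_mi")],
                 samples = samples,
                 by_size = by_size),
            class = "set_search_trace")
}

#' Slope of the lower-bound search trace
#'
#' Least-squares slope of joint MI versus set size over the linear region of
#' a minimize-direction greedy trace: the average unique information
#' contributed per gene.  The default region drops the last 5 sizes, where
#' the most informative genes enter and the growth steepens.
#'
#' @param trace A minimize-direction \code{\link{greedy_search}} trace.
#' @param region Optional integer vector of sizes to fit over.
#' @return List with \code{slope_bits_per_gene}, \code{region}, \code{fit}
#'   (the lm object).
#' @export
lower_bound_slope <- function(trace, region = NULL) {
  stopifnot(inherits(trace, "set_search_trace"))
  if (!identical(trace$strategy, "lower"))
    stop("slope is defined for the minimize-direction (lower-bound) trace")
  d <- trace$mi_by_size
  region <- region %||% {
    if (nrow(d) > 8) d$size[seq_len(nrow(d) - 5L)] else d$size
  }
  d <- d[d$size %in% region & is.finite(d$mi), ]
  if (nrow(d) < 3) stop("need at least 3 sizes to fit a slope")
  fit <- stats::lm(mi ~ size, data = d)
  list(slope_bits_per_gene = unname(stats::coef(fit)[2]),
       region = d$size, fit = fit)
}
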