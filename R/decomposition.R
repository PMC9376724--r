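# All estimation in this file goes through an injectable `estimator`
# (signature: function(x, y, config, labels) -> list with value, spread,
# failed) so the same decomposition bookkeeping can be driven either by the
# neural DV-bound estimator (the default) or by an exact oracle on small
# discrete fixtures.

default_estimator <- function(x, y, config, labels = c("x", "y")) {
  estimate_mi(x, y, config, labels = labels)
}

clone_config_seed <- function(config, counter) {
  config$seed <- sub_seed(config$seed, counter)
  config
}

#' Mutual information between each gene and the phenotype
#'
#' Estimates I(G_i; Ca) for every gene (single-column x against the full
#' trace block y), plus the summaries used downstream: the sorted list, the
#' cumulative sum sorted descending (how much information genes would carry
#' if none of it overlapped), and the mean per-gene MI.
#'
#' @param dataset A normalized \code{\link{paired_dataset}}.
#' @param config A \code{\link{mine_config}}.
#' @param estimator MI estimator function (see source); defaults to
#'   \code{\link{estimate_mi}}.
#' @return Object of class \code{per_gene_mi}: \code{table} (gene, mi,
#'   spread, converged -- sorted ascending by mi), \code{cumulative}
#'   (descending-sorted cumulative sum), \code{mean_mi}, \code{total_sum},
#'   \code{n_failed}.
#' @export
per_gene_mi <- function(dataset, config = mine_config(),
                        estimator = default_estimator) {
  stopifnot(inherits(dataset, "paired_dataset"))
  ng <- ncol(dataset$counts)
  rows <- vector("list", ng)
  for (g in seq_len(ng)) {
    est <- estimator(dataset$counts[, g, drop = FALSE], dataset$traces,
                     clone_config_seed(config, 1000L + g),
                     labels = c(dataset$gene_labels[g], "Ca"))
    rows[[g]] <- data.frame(gene = dataset$gene_labels[g],
                            mi = est$value,
                            spread = est$spread %||% NA_real_,
                            converged = !isTRUE(est$failed))
  }
  tab <- do.call(rbind, rows)
  ok <- tab$converged & is.finite(tab$mi)
  tab_sorted <- tab[order(tab$mi), ]
  desc <- sort(tab$mi[ok], decreasing = TRUE)
  structure(list(table = tab_sorted,
                 cumulative = data.frame(rank = seq_along(desc),
                                         cumulative_mi = cumsum(desc)),
                 mean_mi = mean(tab$mi[ok]),
                 total_sum = sum(tab$mi[ok]),
                 n_failed = sum(!ok)),
            class = "per_gene_mi")
}

#' Pairwise gene-gene mutual information
#'
#' Estimates I(G_i; G_j) for all gene pairs and asks whether genes that are
#' informative about other genes are also informative about the phenotype:
#' the Spearman rank correlation between each gene's mean MI to the other
#' genes and its MI to the phenotype.
#'
#' @inheritParams per_gene_mi
#' @param per_gene Optional precomputed \code{\link{per_gene_mi}} result
#'   (computed if absent).
#' @return List with \code{matrix} (symmetric, diagonal NA), \code{spread}
#'   matrix, \code{mean_to_others} per gene, \code{spearman}
#'   (\code{cor.test} result, or NULL when degenerate), \code{n_failed}.
#' @export
gene_gene_mi <- function(dataset, config = mine_config(),
                         per_gene = NULL,
                         estimator = default_estimator) {
  stopifnot(inherits(dataset, "paired_dataset"))
  ng <- ncol(dataset$counts)
  if (ng < 2) stop("need at least 2 genes")
  M <- matrix(NA_real_, ng, ng,
              dimnames = list(dataset$gene_labels, dataset$gene_labels))
  S <- M
  n_failed <- 0L
  for (i in seq_len(ng - 1L)) {
    for (j in seq.int(i + 1L, ng)) {
      est <- estimator(dataset$counts[, i, drop = FALSE],
                       dataset$counts[, j, drop = FALSE],
                       clone_config_seed(config, 20000L + i * 100L + j),
                       labels = dataset$gene_labels[c(i, j)])
      if (isTRUE(est$failed)) { n_failed <- n_failed + 1L; next }
      M[i, j] <- M[j, i] <- est$value
      S[i, j] <- S[j, i] <- est$spread %||% NA_real_
    }
  }
  mean_to_others <- rowMeans(M, na.rm = TRUE)
  if (is.null(per_gene)) per_gene <- per_gene_mi(dataset, config, estimator)
  mi_ca <- per_gene$table$mi[match(dataset$gene_labels,
                                   per_gene$table$gene)]
  sp <- NULL
  if (stats::sd(mean_to_others, na.rm = TRUE) > 1e-12 &&
      stats::sd(mi_ca, na.rm = TRUE) > 1e-12) {
    sp <- suppressWarnings(
      stats::cor.test(mean_to_others, mi_ca, method = "spearman"))
  }
  list(matrix = M, spread = S, mean_to_others = mean_to_others,
       mi_to_phenotype = mi_ca, spearman = sp, n_failed = n_failed)
}

#' Synergy-redundancy index of one gene pair
#'
#' The pairwise synergy-redundancy index conditioned on the phenotype:
#' \deqn{SRI(G_i, G_j | Ca) = I(\{G_i,G_j\}; Ca) - I(G_i; Ca) - I(G_j; Ca).}
#' Negative values mean the two genes carry overlapping (redundant)
#' information about the phenotype; positive values mean the pair is more
#' informative than its parts (synergy); zero means unique or uninformative.
#' Spreads of the three constituent estimates propagate in quadrature.
#'
#' @inheritParams gene_gene_mi
#' @param i,j Distinct gene indices.
#' @return List with \code{sri} (bits), \code{spread}, the three constituent
#'   estimates, and \code{converged} (FALSE, with \code{sri} NA, when any
#'   constituent failed).
#' @export
sri_pair <- function(dataset, i, j, config = mine_config(),
                     per_gene = NULL, estimator = default_estimator) {
  stopifnot(inherits(dataset, "paired_dataset"))
  if (i == j) stop("'i' and 'j' must be distinct genes")
  single <- function(g) {
    if (!is.null(per_gene)) {
      row <- per_gene$table[match(dataset$gene_labels[g],
                                  per_gene$table$gene), ]
      list(value = row$mi, spread = row$spread, failed = !row$converged)
    } else {
      estimator(dataset$counts[, g, drop = FALSE], dataset$traces,
                clone_config_seed(config, 1000L + g),
                labels = c(dataset$gene_labels[g], "Ca"))
    }
  }
  ei <- single(i); ej <- single(j)
  epair <- estimator(dataset$counts[, c(i, j), drop = FALSE],
                     dataset$traces,
                     clone_config_seed(config, 30000L + i * 100L + j),
                     labels = c(paste(dataset$gene_labels[c(i, j)],
                                      collapse = "+"), "Ca"))
  if (isTRUE(ei$failed) || isTRUE(ej$failed) || isTRUE(epair$failed)) {
    return(list(sri = NA_real_, spread = NA_real_, pair_mi = epair$value,
                mi_i = ei$value, mi_j = ej$value, converged = FALSE))
  }
  sq <- function(s) if (is.null(s) || is.na(s)) 0 else s^2
  list(sri = epair$value - ei$value - ej$value,
       spread = sqrt(sq(epair$spread) + sq(ei$spread) + sq(ej$spread)),
       pair_mi = epair$value, mi_i = ei$value, mi_j = ej$value,
       converged = TRUE)
}

#' Synergy-redundancy matrix over all gene pairs
#'
#' Computes \code{\link{sri_pair}} for every unique pair, reusing one cached
#' set of single-gene MI estimates for all pairs so that every SRI uses
#' consistent constituents.  The diagonal is defined as
#' \eqn{-I(G_i; Ca)} (the duplicate-gene limit) and excluded from all
#' summaries.
#'
#' @inheritParams gene_gene_mi
#' @return Object of class \code{sri_matrix}: \code{values} (symmetric gene
#'   x gene, bits), \code{spread}, \code{gene_labels}, \code{mean_sri}
#'   (off-diagonal mean), \code{per_gene_mean_sri}, \code{rank_spearman}
#'   (test between per-gene MI and per-gene mean SRI ranks, or NULL),
#'   \code{n_failed}.
#' @export
sri_matrix <- function(dataset, config = mine_config(),
                       per_gene = NULL, estimator = default_estimator) {
  stopifnot(inherits(dataset, "paired_dataset"))
  ng <- ncol(dataset$counts)
  if (is.null(per_gene) || inherits(per_gene, "stage_failure"))
    per_gene <- per_gene_mi(dataset, config, estimator)
  V <- matrix(NA_real_, ng, ng,
              dimnames = list(dataset$gene_labels, dataset$gene_labels))
  S <- V
  n_failed <- 0L
  for (i in seq_len(ng - 1L)) {
    for (j in seq.int(i + 1L, ng)) {
      p <- sri_pair(dataset, i, j, config, per_gene = per_gene,
                    estimator = estimator)
      if (!p$converged) { n_failed <- n_failed + 1L; next }
      V[i, j] <- V[j, i] <- p$sri
      S[i, j] <- S[j, i] <- p$spread
    }
  }
  mi_ca <- per_gene$table$mi[match(dataset$gene_labels,
                                   per_gene$table$gene)]
  diag(V) <- -mi_ca
  per_gene_mean <- vapply(seq_len(ng), function(i)
    mean(V[i, -i], na.rm = TRUE), numeric(1))
  off <- V[upper.tri(V)]
  sp <- NULL
  if (stats::sd(per_gene_mean, na.rm = TRUE) > 1e-12 &&
      stats::sd(mi_ca, na.rm = TRUE) > 1e-12)
    sp <- suppressWarnings(
      stats::cor.test(mi_ca, per_gene_mean, method = "spearman"))
  structure(list(values = V, spread = S,
                 gene_labels = dataset$gene_labels,
                 mean_sri = mean(off, na.rm = TRUE),
                 per_gene_mean_sri = stats::setNames(per_gene_mean,
                                                     dataset$gene_labels),
                 per_gene_mi = stats::setNames(mi_ca, dataset$gene_labels),
                 rank_spearman = sp,
                 n_failed = n_failed),
            class = "sri_matrix")
}

#' Annotation-level summary of the SRI matrix
#'
#' Averages pairwise SRI values over annotation-label combinations: cell
#' (A, B) is the mean SRI over all gene pairs with one gene labeled A and
#' the other B; diagonal cells use within-label pairs.  Labels with a single
#' gene have no within-label pair and are flagged.
#'
#' @param sri A \code{\link{sri_matrix}} result.
#' @param annotation_map Named character vector gene -> label covering every
#'   gene (a catch-all label such as "Other" is allowed).
#' @return List with \code{matrix} (label x label mean SRI),
#'   \code{n_pairs}, \code{undefined} (labels whose within-label cell is
#'   undefined).
#' @export
annotation_sri_summary <- function(sri, annotation_map) {
  stopifnot(inherits(sri, "sri_matrix"))
  genes <- sri$gene_labels
  if (!all(genes %in% names(annotation_map)))
    stop("every gene must be labeled: missing ",
         paste(setdiff(genes, names(annotation_map)), collapse = ", "))
  lab <- annotation_map[genes]
  labels <- sort(unique(lab))
  K <- length(labels)
  M <- matrix(NA_real_, K, K, dimnames = list(labels, labels))
  NP <- matrix(0L, K, K, dimnames = list(labels, labels))
  ng <- length(genes)
  acc <- array(0, dim = c(K, K))
  for (i in seq_len(ng - 1L)) {
    for (j in seq.int(i + 1L, ng)) {
      v <- sri$values[i, j]
      if (is.na(v)) next
      a <- match(lab[i], labels); b <- match(lab[j], labels)
      lo <- min(a, b); hi <- max(a, b)
      acc[lo, hi] <- acc[lo, hi] + v
      NP[lo, hi] <- NP[lo, hi] + 1L
    }
  }
  for (a in seq_len(K)) for (b in seq.int(a, K)) {
    if (NP[a, b] > 0) M[a, b] <- M[b, a] <- acc[a, b] / NP[a, b]
    NP[b, a] <- NP[a, b]
  }
  list(matrix = M, n_pairs = NP,
       undefined = labels[is.na(diag(M))])
}

#' Nonredundant information and redundancy explained over set size
#'
#' From the mean joint MI of gene sets of size k, extrapolates the total
#' information the panel would carry if sets contained no overlap,
#' \deqn{NRI(k) = E[I(\{G_1..G_k\}; Ca)] \cdot n / k,}
#' and the fraction of the redundancy gap closed at size k,
#' \deqn{RE(k) = 1 - \frac{NRI(k) - I(G; Ca)}{NRI(1) - I(G; Ca)}.}
#' By construction RE(1) = 0 and RE(n) = 1.
#'
#' @param mean_set_mi_by_k Named numeric vector: names are set sizes k,
#'   values the mean joint MI of sampled sets of that size (bits).  Must
#'   include k = 1 and k = n.
#' @param full_mi Joint MI of all n genes with the phenotype (bits).
#' @param n Total number of genes.
#' @return Object of class \code{redundancy_curve}: \code{curve} data.frame
#'   (size, mean_set_mi, nri, redundancy_explained), \code{full_mi},
#'   \code{n}.
#' @export
redundancy_explained <- function(mean_set_mi_by_k, full_mi, n) {
  k <- as.integer(names(mean_set_mi_by_k))
  if (anyNA(k)) stop("'mean_set_mi_by_k' must be named by set size")
  if (!1L %in% k) stop("mean set MI at k = 1 is required")
  ord <- order(k)
  k <- k[ord]
  ei <- as.numeric(mean_set_mi_by_k)[ord]
  nri <- ei * n / k
  nri1 <- nri[k == 1L]
  if (nri1 <= full_mi)
    stop(sprintf(paste0(
      "NRI(1) = %.3f does not exceed the full MI = %.3f: no superfluous ",
      "information, redundancy explained undefined"), nri1, full_mi))
  re <- 1 - (nri - full_mi) / (nri1 - full_mi)
  structure(list(curve = data.frame(size = k, mean_set_mi = ei, nri = nri,
                                    redundancy_explained = re),
                 full_mi = full_mi, n = n),
            class = "redundancy_curve")
}

#' Mutual information between leading principal components and the phenotype
#'
#' Computes I(PC_1..k; Ca) for k = 1..max_components via the injected
#' estimator, alongside the differential-entropy curve of the same
#' components, both raw and normalized by their maxima -- the comparison
#' shows how quickly phenotypic information saturates relative to
#' phenotype-agnostic entropy.
#'
#' @inheritParams per_gene_mi
#' @param max_components Largest number of leading components.
#' @return List with \code{table} (k, mi, spread, mi_norm,
#'   differential_entropy, entropy_norm), \code{n_failed}.
#' @export
pc_phenotype_mi <- function(dataset, config = mine_config(),
                            max_components = 6L,
                            estimator = default_estimator) {
  stopifnot(inherits(dataset, "paired_dataset"))
  pc <- pca_decompose(dataset$counts,
                      n_components = min(max_components,
                                         ncol(dataset$counts)))
  kk <- seq_len(pc$n_components)
  mi <- spread <- rep(NA_real_, length(kk))
  n_failed <- 0L
  for (k in kk) {
    est <- estimator(pc$scores[, seq_len(k), drop = FALSE], dataset$traces,
                     clone_config_seed(config, 40000L + k),
                     labels = c(sprintf("PC1..%d", k), "Ca"))
    if (isTRUE(est$failed)) { n_failed <- n_failed + 1L; next }
    mi[k] <- est$value
    spread[k] <- est$spread %||% NA_real_
  }
  ent <- vapply(kk, function(k)
    k / 2 * log2(2 * pi * exp(1)) + 0.5 * sum(log2(pc$variances[seq_len(k)])),
    numeric(1))
  mx <- max(mi, na.rm = TRUE)
  list(table = data.frame(k = kk, mi = mi, spread = spread,
                          mi_norm = mi / mx,
                          differential_entropy = ent,
                          entropy_norm = ent / ent[length(kk)]),
       n_failed = n_failed)
}
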