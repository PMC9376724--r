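#' Construct a paired dataset
#'
#' The universal input container: row-aligned per-cell transcript counts
#' (cells x genes, non-negative) and signaling traces (cells x timepoints,
#' continuous), with gene labels, optional gene annotations and a
#' preprocessing state.
#'
#' @param counts Cells x genes matrix of non-negative counts.
#' @param traces Cells x timepoints numeric matrix.
#' @param gene_labels Character vector of gene names (defaults to counts
#'   column names).
#' @param annotation_map Optional named character vector gene -> annotation
#'   label.
#' @param cell_ids Character vector of cell identifiers.
#' @param preprocessing_state \code{"raw"} or \code{"normalized"}.
#' @return An object of class \code{paired_dataset}.
#' @export
paired_dataset <- function(counts, traces, gene_labels = NULL,
                           annotation_map = NULL, cell_ids = NULL,
                           preprocessing_state = c("raw", "normalized")) {
  counts <- as_matrix2(counts, "counts")
  traces <- as_matrix2(traces, "traces")
  preprocessing_state <- match.arg(preprocessing_state)
  if (nrow(counts) != nrow(traces))
    stop("counts and traces must have identical row counts (aligned cells)")
  if (preprocessing_state == "raw" && any(counts < 0))
    stop("raw counts must be non-negative")
  gene_labels <- gene_labels %||% colnames(counts) %||%
    sprintf("gene%02d", seq_len(ncol(counts)))
  if (length(gene_labels) != ncol(counts))
    stop("'gene_labels' length must match the number of genes")
  cell_ids <- cell_ids %||% rownames(counts) %||%
    sprintf("cell%05d", seq_len(nrow(counts)))
  if (anyDuplicated(cell_ids))
    stop("duplicated cell ids: ",
         paste(unique(cell_ids[duplicated(cell_ids)]), collapse = ", "))
  colnames(counts) <- gene_labels
  structure(list(counts = counts, traces = traces,
                 gene_labels = gene_labels,
                 annotation_map = annotation_map,
                 cell_ids = cell_ids,
                 preprocessing_state = preprocessing_state,
                 normalization = NULL),
            class = "paired_dataset")
}

#' @export
print.paired_dataset <- function(x, ...) {
  cat(sprintf("<paired_dataset> %d cells, %d genes, %d timepoints (%s)\n",
              nrow(x$counts), ncol(x$counts), ncol(x$traces),
              x$preprocessing_state))
  invisible(x)
}

#' Load a paired dataset from delimited tables
#'
#' Reads the counts and traces tables (tab- or comma-delimited, first column
#' the cell id, header row of gene names / timepoint labels), aligns rows by
#' cell id, and optionally attaches a two-column gene -> annotation map.
#' Cells present in only one table, or duplicated ids, are rejected with the
#' offending ids listed.
#'
#' @param counts_path,traces_path Paths to the two tables.
#' @param annotations_path Optional path to a two-column table (gene, label).
#' @param sep Field separator (default tab).
#' @return A raw \code{\link{paired_dataset}}; genes with zero total count
#'   are flagged in \code{attr(x, "zero_count_genes")}.
#' @export
load_paired <- function(counts_path, traces_path, annotations_path = NULL,
                        sep = "\t") {
  rd <- function(p) utils::read.table(p, header = TRUE, sep = sep,
                                      check.names = FALSE,
                                      stringsAsFactors = FALSE)
  ct <- rd(counts_path); tr <- rd(traces_path)
  cid_c <- as.character(ct[[1]]); cid_t <- as.character(tr[[1]])
  for (ids in list(counts = cid_c, traces = cid_t)) {
    if (anyDuplicated(ids))
      stop("duplicated cell ids: ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  only_c <- setdiff(cid_c, cid_t); only_t <- setdiff(cid_t, cid_c)
  if (length(only_c) || length(only_t))
    stop("cell ids present in only one table: ",
         paste(c(only_c, only_t), collapse = ", "))
  tr <- tr[match(cid_c, cid_t), , drop = FALSE]
  counts <- as.matrix(ct[, -1, drop = FALSE])
  traces <- as.matrix(tr[, -1, drop = FALSE])
  rownames(counts) <- rownames(traces) <- NULL
  ann <- NULL
  if (!is.null(annotations_path)) {
    at <- utils::read.table(annotations_path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE)
    ann <- stats::setNames(as.character(at[[2]]), as.character(at[[1]]))
  }
  ds <- paired_dataset(counts, traces, gene_labels = colnames(counts),
                       annotation_map = ann, cell_ids = cid_c)
  attr(ds, "zero_count_genes") <- colnames(counts)[colSums(counts) == 0]
  ds
}

#' Globally z-score each modality of a paired dataset
#'
#' Normalizes each modality with ONE global mean and standard deviation over
#' its entire matrix -- not per column.  This preserves the relative
#' magnitude across genes and across timepoints (a gene with 10x the counts
#' of another keeps ~10x its centered magnitude), which per-column scaling
#' would destroy.  The transformation parameters are stored for inversion.
#' Idempotent: preprocessing an already-normalized dataset returns it
#' unchanged.
#'
#' @param dataset A raw \code{\link{paired_dataset}}.
#' @return The dataset with both matrices z-scored (global mean 0, sd 1 per
#'   modality) and \code{preprocessing_state = "normalized"}.
#' @export
preprocess <- function(dataset) {
  stopifnot(inherits(dataset, "paired_dataset"))
  if (dataset$preprocessing_state == "normalized") return(dataset)
  zscore <- function(m, what) {
    mu <- mean(m); sdv <- stats::sd(as.vector(m))
    if (sdv == 0) stop(sprintf("%s matrix has zero global variance", what))
    list(mat = (m - mu) / sdv, mean = mu, sd = sdv)
  }
  zc <- zscore(dataset$counts, "counts")
  zt <- zscore(dataset$traces, "traces")
  dataset$counts <- zc$mat
  dataset$traces <- zt$mat
  dataset$preprocessing_state <- "normalized"
  dataset$normalization <- list(counts = zc[c("mean", "sd")],
                                traces = zt[c("mean", "sd")])
  dataset
}

# hash of a configuration for provenance stamps; stable across sessions
config_hash <- function(x) {
  raw <- serialize(x, connection = NULL, version = 2L)
  # FNV-1a over the serialized payload (skip the header, which encodes
  # the R version used for serialization)
  raw <- as.integer(raw[-seq_len(14L)])
  h <- 2166136261
  for (b in raw) h <- ((bitwXor(as.integer(h %% 2^31), b)) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Run the full information-theoretic analysis
#'
#' Orchestrates the complete pipeline on a paired dataset: modality-global
#' z-scoring; pairwise gene correlations; explained-variance versus
#' differential-entropy curves; ensemble spectral entropy of the traces;
#' per-gene MI; total MI of all genes; the pairwise synergy-redundancy
#' matrix with annotation summary; random-set sampling and greedy searches
#' over gene-set size; the redundancy-explained curve; and MI between
#' leading principal components and the traces.  Stages that fail are
#' isolated; stages depending on a failed output are skipped with reasons.
#' Every artifact carries the config hash and seed.
#'
#' @param dataset A \code{\link{paired_dataset}} (raw or normalized).
#' @param config A \code{\link{mine_config}} for all MI estimation.
#' @param stages Character vector of stage names to run (default all):
#'   "entropy", "per_gene_mi", "total_mi", "sri", "set_search",
#'   "redundancy", "pc_mi".
#' @param max_components Components for the PC-MI curve (default
#'   min(6, genes)).
#' @param samples_per_size Random sets per size for the redundancy curve.
#' @param set_sizes Sizes at which random sets are sampled (default a grid
#'   over 1..n_genes).
#' @param output_dir Optional directory; each stage's tables are written
#'   there as TSV with a provenance header line.
#' @param estimator Injectable MI estimator (see \code{\link{per_gene_mi}});
#'   defaults to the neural DV-bound estimator.
#' @param verbose Print stage progress.
#' @return A list of stage results plus a \code{summary} data.frame of
#'   headline quantities (total MI, mean per-gene MI, mean SRI, spectral
#'   entropy, set size reaching half the total MI), with provenance in
#'   \code{config_hash} and \code{seed}.
#' @export
run_full_analysis <- function(dataset, config = mine_config(),
                              stages = c("entropy", "per_gene_mi",
                                         "total_mi", "sri", "set_search",
                                         "redundancy", "pc_mi"),
                              max_components = NULL,
                              samples_per_size = 4L,
                              set_sizes = NULL,
                              output_dir = NULL,
                              estimator = default_estimator,
                              verbose = TRUE) {
  stopifnot(inherits(dataset, "paired_dataset"))
  stages <- match.arg(stages, several.ok = TRUE)
  say <- function(...) if (verbose) message(...)
  hash <- config_hash(list(config = config, stages = stages))
  res <- list(config_hash = hash, seed = config$seed)
  ds <- preprocess(dataset)
  ng <- ncol(ds$counts)

  run_stage <- function(name, fun) {
    say("stage: ", name)
    tryCatch(fun(), error = function(e) {
      warning(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
              call. = FALSE)
      structure(list(error = conditionMessage(e)), class = "stage_failure")
    })
  }
  failed <- function(x) inherits(x, "stage_failure")

  if ("entropy" %in% stages) {
    res$correlations <- run_stage("correlations", function()
      pairwise_gene_correlations(ds$counts))
    res$curves <- run_stage("variance_entropy_curves", function()
      variance_entropy_curves(ds$counts))
    res$spectral <- run_stage("spectral_entropy", function() {
      psd <- periodogram(ds$traces)
      list(psd = psd, entropy_bits = spectral_entropy(psd))
    })
  }
  if ("per_gene_mi" %in% stages)
    res$per_gene_mi <- run_stage("per_gene_mi", function()
      per_gene_mi(ds, config, estimator = estimator))
  if ("total_mi" %in% stages)
    res$total_mi <- run_stage("total_mi", function() {
      cfg <- config; cfg$seed <- sub_seed(config$seed, 90001L)
      estimator(ds$counts, ds$traces, cfg, labels = c("G", "Ca"))
    })
  if ("sri" %in% stages) {
    if (failed(res$per_gene_mi %||% NULL)) {
      res$sri <- structure(list(error = "skipped: per_gene_mi failed"),
                           class = "stage_failure")
    } else {
      res$sri <- run_stage("sri_matrix", function()
        sri_matrix(ds, config, per_gene = res$per_gene_mi %||% NULL,
                   estimator = estimator))
      if (!failed(res$sri) && !is.null(ds$annotation_map))
        res$annotation_sri <- run_stage("annotation_sri", function()
          annotation_sri_summary(res$sri, ds$annotation_map))
    }
  }
  if ("set_search" %in% stages || "redundancy" %in% stages) {
    sizes <- set_sizes %||% unique(round(seq(1, ng, length.out = min(ng, 8L))))
    res$random_sets <- run_stage("random_sets", function()
      random_sets(ds, config, sizes = sizes,
                  samples_per_size = samples_per_size,
                  estimator = estimator))
  }
  if ("set_search" %in% stages) {
    res$greedy_upper <- run_stage("greedy_maximize", function()
      greedy_search(ds, config, direction = "maximize",
                    estimator = estimator))
    res$greedy_lower <- run_stage("greedy_minimize", function()
      greedy_search(ds, config, direction = "minimize",
                    estimator = estimator))
  }
  if ("redundancy" %in% stages) {
    dep_ok <- !failed(res$random_sets %||% NULL) &&
      !failed(res$total_mi %||% NULL) && !is.null(res$total_mi)
    res$redundancy <- if (!dep_ok)
      structure(list(error = "skipped: needs random_sets and total_mi"),
                class = "stage_failure")
    else run_stage("redundancy_explained", function() {
      eik <- stats::aggregate(mi ~ size, data = res$random_sets$samples,
                              FUN = mean)
      redundancy_explained(stats::setNames(eik$mi, eik$size),
                           full_mi = res$total_mi$value, n = ng)
    })
  }
  if ("pc_mi" %in% stages)
    res$pc_mi <- run_stage("pc_phenotype_mi", function()
      pc_phenotype_mi(ds, config,
                      max_components = max_components %||% min(6L, ng),
                      estimator = estimator))

  res$summary <- analysis_summary(res, ng)
  if (!is.null(output_dir)) write_analysis(res, output_dir, hash, config)
  res
}

analysis_summary <- function(res, n_genes) {
  failed <- function(x) is.null(x) || inherits(x, "stage_failure")
  val <- function(x) if (is.null(x) || !is.finite(x)) NA_real_ else x
  tot <- if (!failed(res$total_mi)) res$total_mi$value else NA_real_
  mean_pg <- if (!failed(res$per_gene_mi)) res$per_gene_mi$mean_mi
             else NA_real_
  mean_sri <- if (!failed(res$sri)) res$sri$mean_sri else NA_real_
  spec_ent <- if (!failed(res$spectral)) res$spectral$entropy_bits
              else NA_real_
  half_size <- NA_real_
  if (!failed(res$random_sets) && is.finite(tot)) {
    med <- res$random_sets$by_size
    reach <- med$size[med$median_mi >= tot / 2]
    if (length(reach)) half_size <- min(reach)
  }
  data.frame(quantity = c("total_mi_bits", "mean_per_gene_mi_bits",
                          "mean_sri_bits", "spectral_entropy_bits",
                          "random_set_size_at_half_total_mi", "n_genes"),
             value = c(val(tot), val(mean_pg), val(mean_sri), val(spec_ent),
                       half_size, n_genes))
}

write_analysis <- function(res, dir, hash, config) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- sprintf("# config_hash=%s seed=%d", hash, config$seed)
  wt <- function(df, name) {
    p <- file.path(dir, paste0(name, ".tsv"))
    writeLines(stamp, p)
    suppressWarnings(utils::write.table(df, p, sep = "\t", quote = FALSE,
                                        row.names = FALSE, append = TRUE))
  }
  wt(res$summary, "summary")
  if (!inherits(res$per_gene_mi %||% 1, "stage_failure") &&
      !is.null(res$per_gene_mi)) wt(res$per_gene_mi$table, "per_gene_mi")
  if (!inherits(res$curves %||% 1, "stage_failure") &&
      !is.null(res$curves)) wt(res$curves, "variance_entropy_curves")
  if (!inherits(res$sri %||% 1, "stage_failure") && !is.null(res$sri))
    wt(as.data.frame(res$sri$values), "sri_matrix")
  if (!inherits(res$redundancy %||% 1, "stage_failure") &&
      !is.null(res$redundancy)) wt(res$redundancy$curve, "redundancy_curve")
  invisible(dir)
}
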