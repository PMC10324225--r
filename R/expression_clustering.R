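#' @title Expression filtering and gene clustering
#' @description Expression-side filters applied before regulator inference:
#'   the fragments-per-million (FPM) detectability filter, selection of
#'   differentially expressed genes (DEGs) with direction labels, and k-means
#'   partitioning of the DEGs into functional clusters (k = 4 by default).
#' @name expression_clustering
NULL

#' FPM detectability filter
#'
#' A gene is retained iff strictly more than `min_fpm` FPM is observed in at
#' least `min_samples` samples. The FPM comparison is strict ("above"), the
#' sample count is not.
#'
#' @param fpm genes x samples numeric matrix (rownames = gene ids).
#' @param min_fpm FPM threshold (default 0.1).
#' @param min_samples minimum number of samples exceeding it (default 4).
#' @return character vector of retained gene ids.
#' @export
fpm_filter <- function(fpm, min_fpm = 0.1, min_samples = 4) {
  fpm <- as.matrix(fpm)
  if (ncol(fpm) < min_samples) {
    stop("FPM matrix has ", ncol(fpm), " samples; at least ", min_samples,
         " required")
  }
  if (any(fpm < 0)) stop("negative FPM values")
  n_above <- rowSums(fpm > min_fpm)
  kept <- rownames(fpm)[n_above >= min_samples]
  message("fpm_filter: ", length(kept), " of ", nrow(fpm), " genes retained")
  kept
}

#' Select differentially expressed genes with direction
#'
#' DE calls use adjusted p <= `alpha` (the threshold is an attained upper
#' bound, so a gene at exactly `alpha` passes). Direction is the sign of
#' log2FC; significant genes with log2FC exactly 0 are flagged and excluded
#' from both direction lists.
#'
#' @param de_table data.frame with columns gene, log2FC, padj.
#' @param alpha adjusted-p threshold (default 0.05).
#' @param retained optional character vector of genes surviving [fpm_filter()];
#'   others are ignored.
#' @return list with character vectors `up`, `down`, `zero_lfc` and a
#'   data.frame `table` of the DE calls.
#' @export
select_degs <- function(de_table, alpha = 0.05, retained = NULL) {
  req <- c("gene", "log2FC", "padj")
  missing <- setdiff(req, names(de_table))
  if (length(missing)) {
    stop("DE table missing column(s): ", paste(missing, collapse = ", "))
  }
  tab <- de_table
  if (!is.null(retained)) tab <- tab[tab$gene %in% retained, , drop = FALSE]
  sig <- !is.na(tab$padj) & tab$padj <= alpha
  up <- tab$gene[sig & tab$log2FC > 0]
  down <- tab$gene[sig & tab$log2FC < 0]
  zero <- tab$gene[sig & tab$log2FC == 0]
  if (length(zero)) {
    message("select_degs: ", length(zero),
            " significant gene(s) with log2FC == 0 excluded from direction labels")
  }
  message("select_degs: ", length(up), " up, ", length(down), " down at padj <= ",
          alpha)
  list(up = up, down = down, zero_lfc = zero,
       table = tab[sig, , drop = FALSE])
}

# k-means++ seeding: first center uniform, subsequent centers sampled with
# probability proportional to squared distance to the nearest chosen center.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums((x - matrix(x[centers[1], ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1L)) {
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j + 1L] <- sample.int(n, 1, prob = probs)
    d2new <- rowSums((x - matrix(x[centers[j + 1L], ], n, ncol(x),
                                 byrow = TRUE))^2)
    d2 <- pmin(d2, d2new)
  }
  x[centers, , drop = FALSE]
}

#' Cluster DE genes by k-means
#'
#' Euclidean k-means with k-means++ initialization, `restarts` restarts and
#' the best within-cluster sum of squares kept. Rows are genes; the default
#' feature space is standardized per-sample expression, but any caller-
#' supplied feature matrix (e.g. a network embedding) is accepted, so
#' externally derived cluster assignments can be reproduced through the same
#' file contract.
#'
#' @param features numeric matrix, rows = DE genes (rownames = gene ids).
#' @param k number of clusters (default 4).
#' @param seed RNG seed controlling initialization.
#' @param restarts number of k-means++ restarts (default 10).
#' @param iter_max maximum Lloyd iterations per restart (default 300).
#' @param standardize center/scale columns first (default TRUE; constant
#'   columns are left unscaled).
#' @return named integer vector gene -> cluster in 1..k.
#' @export
cluster_genes <- function(features, k = 4, seed = 1, restarts = 10,
                          iter_max = 300, standardize = TRUE) {
  x <- as.matrix(features)
  if (is.null(rownames(x))) stop("feature matrix needs gene rownames")
  if (k > nrow(x)) stop("k = ", k, " exceeds number of genes (", nrow(x), ")")
  x <- x[order(rownames(x)), , drop = FALSE]  # gene-order invariance
  if (standardize) {
    mu <- colMeans(x)
    sdv <- apply(x, 2, stats::sd)
    sdv[sdv == 0 | is.na(sdv)] <- 1
    x <- sweep(sweep(x, 2, mu), 2, sdv, "/")
  }
  if (k == 1L) {
    cl <- setNames(rep(1L, nrow(x)), rownames(x))
    return(cl)
  }
  best <- NULL
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed))
  set.seed(seed)
  for (r in seq_len(restarts)) {
    centers <- kmeanspp_centers(x, k)
    fit <- suppressWarnings(
      stats::kmeans(x, centers = centers, iter.max = iter_max,
                    algorithm = "Lloyd")
    )
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (any(tabulate(best$cluster, k) == 0)) {
    stop("k-means produced an empty cluster; reduce k")
  }
  setNames(as.integer(best$cluster), rownames(x))
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
}
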