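#' @title Regulator inference and cluster-wise TF effect scores
#' @description Predicts which transcription factors drive the direction of
#'   differential expression by elastic-net logistic regression of the
#'   up/down label on per-gene TF affinity quotients (mixing parameter close
#'   to ridge), with nested cross-validation: an inner CV selects the penalty
#'   strength, an outer CV reports held-out accuracy. Fitted coefficients are
#'   normalized by their maximum absolute value and thresholded to select
#'   candidate regulators. For the gene clusters, the per-TF median log2
#'   affinity quotient Q[t, i] over the DE genes of cluster i is contrasted
#'   against the mean of the medians of the other clusters to give the effect
#'   score E[t, i] = Q[t, i] - mean_{j != i} Q[t, j].
#' @name regulator_inference
NULL

# stratified fold assignment: each class is spread as evenly as possible
stratified_folds <- function(labels, k) {
  folds <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k && length(idx) < 2L) {
      stop("class '", cl, "' has fewer than 2 observations; cannot stratify")
    }
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

#' Fit the regularized regression of DE direction on affinity quotients
#'
#' Elastic-net logistic regression (glmnet) with mixing parameter
#' `alpha` = 0.01 (mostly ridge). Features are the per-gene TF log2 affinity
#' quotients, standardized to zero mean / unit variance. The penalty is chosen
#' by `Ifolds`-fold inner CV over a 50-point log grid; `Ofolds`-fold outer CV
#' (stratified by label) reports held-out classification accuracy; final
#' coefficients come from a fit on all data at the inner-CV-selected penalty.
#'
#' @param q TFs x genes quotient matrix (see [affinity_quotient()]).
#' @param labels named character/factor vector over genes with values
#'   "up"/"down"; only genes present in both `q` and `labels` are used.
#' @param Ofolds outer folds (default 10).
#' @param Ifolds inner folds (default 6).
#' @param alpha elastic-net mixing parameter (default 0.01).
#' @param seed RNG seed controlling fold assignment.
#' @param lambda penalty grid (default 50 log-spaced values, 1e2 down to 1e-4).
#' @return list of class `dynamite_fit` with elements `coef` (named per-TF),
#'   `normalized` (|coef| / max |coef|), `outer_accuracy` (length `Ofolds`),
#'   `lambda`, and `settings`.
#' @export
fit_dynamite <- function(q, labels, Ofolds = 10, Ifolds = 6, alpha = 0.01,
                         seed = 1, lambda = 10^seq(2, -4, length.out = 50)) {
  genes <- intersect(colnames(q), names(labels))
  if (length(genes) < 4L) stop("need at least 4 labelled genes")
  y <- factor(as.character(labels[genes]), levels = c("down", "up"))
  if (any(is.na(y))) stop("labels must be 'up' or 'down'")
  if (min(table(y)) < 2L) stop("need at least 2 genes per direction label")
  x <- t(q[, genes, drop = FALSE])
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv == 0 | is.na(sdv)] <- 1
  x <- sweep(sweep(x, 2, mu), 2, sdv, "/")

  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed))
  set.seed(seed)

  outer <- stratified_folds(y, Ofolds)
  acc <- numeric(Ofolds)
  for (f in seq_len(Ofolds)) {
    tr <- outer != f
    te <- !tr
    inner_id <- stratified_folds(y[tr], Ifolds)
    cvfit <- glmnet::cv.glmnet(x[tr, , drop = FALSE], y[tr],
                               family = "binomial", alpha = alpha,
                               lambda = lambda, foldid = inner_id,
                               standardize = FALSE)
    pred <- stats::predict(cvfit, newx = x[te, , drop = FALSE],
                           s = "lambda.min", type = "class")
    acc[f] <- mean(pred == as.character(y[te]))
  }

  inner_id <- stratified_folds(y, Ifolds)
  cvfit <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = alpha,
                             lambda = lambda, foldid = inner_id,
                             standardize = FALSE)
  beta <- as.numeric(stats::coef(cvfit, s = "lambda.min"))[-1]  # drop intercept
  names(beta) <- colnames(x)
  mx <- max(abs(beta))
  normalized <- if (mx > 0) abs(beta) / mx else abs(beta)
  structure(
    list(coef = beta, normalized = normalized, outer_accuracy = acc,
         lambda = cvfit$lambda.min,
         settings = list(Ofolds = Ofolds, Ifolds = Ifolds, alpha = alpha,
                         seed = seed)),
    class = "dynamite_fit"
  )
}

#' @export
print.dynamite_fit <- function(x, ...) {
  cat("regularized regression of DE direction on TF affinity quotients\n")
  cat(sprintf("  mean outer-fold accuracy: %.3f\n", mean(x$outer_accuracy)))
  top <- utils::head(sort(x$normalized, decreasing = TRUE), 5)
  cat("  top TFs:", paste(names(top), collapse = ", "), "\n")
  invisible(x)
}

#' Rank TFs by normalized absolute coefficient
#'
#' @param fit a `dynamite_fit`.
#' @param threshold selection threshold on the normalized absolute
#'   coefficient (default 0.125; selection is >= threshold).
#' @return data.frame sorted by normalized coefficient descending (ties by TF
#'   name) with columns tf, coef, normalized, selected.
#' @export
rank_tfs <- function(fit, threshold = 0.125) {
  df <- data.frame(tf = names(fit$coef), coef = fit$coef,
                   normalized = fit$normalized, stringsAsFactors = FALSE)
  df <- df[order(-df$normalized, df$tf), ]
  df$selected <- df$normalized >= threshold
  rownames(df) <- NULL
  df
}

#' Per-cluster median log2 affinity quotients
#'
#' Q[t, i] is the median over the DE genes of cluster i of the log2 affinity
#' quotient of TF t. Only DE genes enter; even cardinality takes the mean of
#' the two central values (stats::median).
#'
#' @param q TFs x genes quotient matrix.
#' @param clusters named integer vector gene -> cluster (DE genes only).
#' @return TFs x clusters matrix Q (columns named by cluster index).
#' @export
median_quotient <- function(q, clusters) {
  ks <- sort(unique(clusters))
  Q <- matrix(NA_real_, nrow = nrow(q), ncol = length(ks),
              dimnames = list(rownames(q), as.character(ks)))
  for (j in seq_along(ks)) {
    genes <- intersect(names(clusters)[clusters == ks[j]], colnames(q))
    if (length(genes) == 0L) {
      stop("cluster ", ks[j], " has no genes in the quotient matrix")
    }
    Q[, j] <- apply(q[, genes, drop = FALSE], 1, stats::median)
  }
  Q
}

#' Cluster-wise TF effect score
#'
#' E[t, i] = Q[t, i] - mean of Q[t, j] over the other clusters j != i
#' (divisor K - 1). Each TF's row of E sums to zero by construction. A
#' positive effect score means the TF's binding gain in the treatment
#' condition is stronger for that cluster's genes than for the rest.
#'
#' @param Q TFs x clusters median-quotient matrix (see [median_quotient()]).
#' @param divisor "others" (default; divide by K - 1) or "all" (divide by K,
#'   kept for sensitivity analysis).
#' @return matrix E with the same dimnames as Q.
#' @export
effect_score <- function(Q, divisor = c("others", "all")) {
  divisor <- match.arg(divisor)
  K <- ncol(Q)
  if (K < 2L) stop("effect score needs at least 2 clusters")
  denom <- if (divisor == "others") K - 1L else K
  rs <- rowSums(Q)
  # mean over others = (rowsum - Q[,i]) / denom
  E <- Q - (rs - Q) / denom
  dimnames(E) <- dimnames(Q)
  E
}
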