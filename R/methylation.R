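#' @title DNA methylation analysis
#' @description The methylation arm of the pipeline: chromatogram-derived
#'   methylation indices h(M)/(h(M)+h(UM)) and their panel-wise [0,100]
#'   normalization, the differential-methylation filter chain for bisulfite
#'   count data (coverage, mean difference, group variance, FDR), selection of
#'   aging-associated loci, low-coverage masking, and classification of each
#'   locus's aging-versus-diet concordance from two contrasts.
#' @name methylation
NULL

#' Chromatogram methylation index
#'
#' index = h_M / (h_M + h_UM), from the heights of the methylated and
#' unmethylated chromatogram peaks. Scale-invariant: multiplying both heights
#' by a constant leaves the index unchanged.
#'
#' @param h_M,h_UM nonnegative peak heights (vectorized).
#' @return methylation fraction(s) in \[0, 1\].
#' @export
methylation_index <- function(h_M, h_UM) {
  if (any(h_M < 0 | h_UM < 0)) stop("peak heights must be nonnegative")
  tot <- h_M + h_UM
  if (any(tot == 0)) stop("undefined methylation call: h(M) + h(UM) = 0")
  h_M / tot
}

#' Normalize methylation indices to the range \[0, 100\]
#'
#' Affine min-max rescaling over a locus panel: the minimum maps to 0, the
#' maximum to 100. Invariant under affine transformation of the input. A
#' constant vector maps to all-0 with a warning.
#'
#' @param x numeric vector of indices.
#' @return rescaled vector on \[0, 100\].
#' @export
normalize_index <- function(x) {
  if (length(x) < 2L) stop("need at least 2 values to normalize a panel")
  rng <- range(x)
  if (diff(rng) == 0) {
    warning("constant index vector; normalized to 0")
    return(rep(0, length(x)))
  }
  100 * (x - rng[1]) / diff(rng)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Internal step-up implementation: sorted p-values are multiplied by n/rank
#' and a running minimum is taken from the largest rank down.
#'
#' @param p numeric vector of p-values in \[0, 1\] (NA passed through).
#' @return adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  if (length(ok) == 0L) return(out)
  pv <- p[ok]
  n <- length(pv)
  ord <- order(pv, decreasing = TRUE)
  adj <- pmin(1, cummin(n / (n:1) * pv[ord]))
  out[ok][ord] <- adj
  out
}

# per-site two-group comparison of methylation fractions: Welch's two-sided t
# on arcsine-sqrt transformed betas (variance-stabilizing for proportions).
# This is a stand-in for a moderated linear-model test; moderation is omitted
# at the small group sizes this pipeline targets.
beta_group_test <- function(beta1, beta2) {
  t1 <- asin(sqrt(pmin(pmax(beta1, 0), 1)))
  t2 <- asin(sqrt(pmin(pmax(beta2, 0), 1)))
  if (stats::sd(t1) == 0 && stats::sd(t2) == 0) {
    return(if (mean(t1) == mean(t2)) 1 else 0)
  }
  tryCatch(stats::t.test(t1, t2)$p.value, error = function(e) NA_real_)
}

# long count table -> per-site summary for one two-group contrast
summarize_sites <- function(table, groups) {
  req <- c("site", "sample", "group", "meth_reads", "total_reads")
  missing <- setdiff(req, names(table))
  if (length(missing)) {
    stop("methylation table missing column(s): ", paste(missing, collapse = ", "))
  }
  tab <- table[table$group %in% groups, , drop = FALSE]
  for (g in groups) {
    if (length(unique(tab$sample[tab$group == g])) < 2L) {
      stop("group '", g, "' has fewer than 2 samples")
    }
  }
  tab$beta <- ifelse(tab$total_reads > 0, tab$meth_reads / tab$total_reads, NA)
  tab
}

#' Differential-methylation filter chain
#'
#' A CpG site is kept iff (i) its coverage is at least `min_cov` reads in
#' every sample of both groups, (ii) the absolute difference of group mean
#' methylation fractions is at least `min_diff`, (iii) the unbiased sample
#' variance of the per-sample fractions is below `max_var` in BOTH groups,
#' and (iv) its BH-FDR-adjusted p-value (two-sided Welch t on arcsine-sqrt
#' fractions, see Details) is below `alpha`. FDR adjustment is computed over
#' the coverage-passing sites.
#'
#' @param table long data.frame with columns site, sample, group, meth_reads,
#'   total_reads.
#' @param groups length-2 character vector naming the contrast groups, first
#'   minus second for the sign of delta_beta.
#' @param min_cov minimum per-sample coverage (default 5; set
#'   `cov_mode = "group_mean"` to require it of the group mean instead).
#' @param min_diff minimum |delta beta| (default 0.05, inclusive).
#' @param max_var maximum group variance of beta (default 0.05, exclusive).
#' @param alpha FDR threshold (default 0.05, exclusive).
#' @param cov_mode "per_sample" (default, strictest reading) or "group_mean".
#' @return data.frame with one row per site: group means, delta_beta,
#'   variances, p, fdr and logical flags covered, passes_diff, passes_var,
#'   passes_fdr, significant.
#' @export
differential_cpgs <- function(table, groups, min_cov = 5, min_diff = 0.05,
                              max_var = 0.05, alpha = 0.05,
                              cov_mode = c("per_sample", "group_mean")) {
  cov_mode <- match.arg(cov_mode)
  stopifnot(length(groups) == 2L)
  tab <- summarize_sites(table, groups)
  sites <- unique(tab$site)
  res <- data.frame(site = sites, mean1 = NA_real_, mean2 = NA_real_,
                    delta_beta = NA_real_, var1 = NA_real_, var2 = NA_real_,
                    p = NA_real_, fdr = NA_real_, covered = FALSE,
                    passes_diff = FALSE, passes_var = FALSE,
                    passes_fdr = FALSE, significant = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_along(sites)) {
    st <- tab[tab$site == sites[i], , drop = FALSE]
    b1 <- st$beta[st$group == groups[1]]
    b2 <- st$beta[st$group == groups[2]]
    cov1 <- st$total_reads[st$group == groups[1]]
    cov2 <- st$total_reads[st$group == groups[2]]
    res$covered[i] <- if (cov_mode == "per_sample") {
      all(c(cov1, cov2) >= min_cov)
    } else {
      mean(cov1) >= min_cov && mean(cov2) >= min_cov
    }
    res$mean1[i] <- mean(b1)
    res$mean2[i] <- mean(b2)
    res$delta_beta[i] <- res$mean1[i] - res$mean2[i]
    res$var1[i] <- stats::var(b1)
    res$var2[i] <- stats::var(b2)
    if (res$covered[i]) res$p[i] <- beta_group_test(b1, b2)
  }
  res$fdr <- bh_adjust(res$p)
  res$passes_diff <- !is.na(res$delta_beta) & abs(res$delta_beta) >= min_diff
  res$passes_var <- !is.na(res$var1) & !is.na(res$var2) &
    res$var1 < max_var & res$var2 < max_var
  res$passes_fdr <- !is.na(res$fdr) & res$fdr < alpha
  res$significant <- res$covered & res$passes_diff & res$passes_var &
    res$passes_fdr
  message("differential_cpgs: ", sum(res$significant), " of ", nrow(res),
          " sites pass all filters")
  res
}

#' Select aging-associated loci
#'
#' Strict thresholds: |delta beta| strictly greater than `min_abs_diff` and
#' FDR-adjusted p strictly below `fdr`.
#'
#' @param contrast data.frame as returned by [differential_cpgs()] for the
#'   young-versus-aged contrast.
#' @param min_abs_diff absolute methylation-difference threshold
#'   (default 0.30, exclusive).
#' @param fdr FDR threshold (default 0.1, exclusive).
#' @return character vector of selected site ids.
#' @export
select_aging_loci <- function(contrast, min_abs_diff = 0.30, fdr = 0.1) {
  keep <- !is.na(contrast$delta_beta) & !is.na(contrast$fdr) &
    abs(contrast$delta_beta) > min_abs_diff & contrast$fdr < fdr
  contrast$site[keep]
}

#' Mask sites with insufficient read coverage
#'
#' A site is excluded from reporting when any required sample covers it with
#' fewer than `min_reads` reads ("below 3" excludes 2, retains 3).
#'
#' @param table long count table (site, sample, total_reads).
#' @param min_reads coverage floor (default 3).
#' @return character vector of excluded site ids.
#' @export
coverage_mask <- function(table, min_reads = 3) {
  stopifnot(all(c("site", "total_reads") %in% names(table)))
  bad <- tapply(table$total_reads, table$site, function(v) any(v < min_reads))
  names(bad)[bad]
}

#' Classify aging-versus-diet concordance per locus
#'
#' Each locus carries a direction (sign of delta) and a significance call in
#' both contrasts. Classes: `concordant` (both significant, same sign),
#' `discordant` (both significant, opposite sign), `age_only`, `diet_only`,
#' `neither`. Loci missing from either contrast are skipped with a message.
#'
#' @param age_contrast,diet_contrast data.frames with columns site,
#'   delta_beta and either `significant` (logical) or `p` compared against
#'   `alpha`.
#' @param loci optional site ids to classify (default: intersection).
#' @param alpha significance level used when a `significant` column is absent
#'   (default 0.05).
#' @return data.frame site / age_delta / diet_delta / age_sig / diet_sig /
#'   class.
#' @export
concordance <- function(age_contrast, diet_contrast, loci = NULL,
                        alpha = 0.05) {
  sig_of <- function(df) {
    if ("significant" %in% names(df)) df$significant
    else !is.na(df$p) & df$p < alpha
  }
  if (is.null(loci)) loci <- union(age_contrast$site, diet_contrast$site)
  ia <- match(loci, age_contrast$site)
  id <- match(loci, diet_contrast$site)
  skip <- is.na(ia) | is.na(id)
  if (any(skip)) {
    message("concordance: skipping ", sum(skip),
            " locus/loci missing from a contrast")
  }
  loci <- loci[!skip]; ia <- ia[!skip]; id <- id[!skip]
  a_sig <- sig_of(age_contrast)[ia]
  d_sig <- sig_of(diet_contrast)[id]
  a_delta <- age_contrast$delta_beta[ia]
  d_delta <- diet_contrast$delta_beta[id]
  cls <- ifelse(a_sig & d_sig,
                ifelse(sign(a_delta) == sign(d_delta), "concordant", "discordant"),
                ifelse(a_sig, "age_only", ifelse(d_sig, "diet_only", "neither")))
  data.frame(site = loci, age_delta = a_delta, diet_delta = d_delta,
             age_sig = a_sig, diet_sig = d_sig, class = cls,
             stringsAsFactors = FALSE)
}

#' Two-group comparison of per-sample methylation measurements
#'
#' One comparison engine shared by the chromatogram-based, deep-sequencing
#' and bisulfite technologies: an unpaired two-sided parametric t-test on the
#' per-sample methylation values of two groups.
#'
#' @param values numeric per-sample methylation measurements.
#' @param group group label per value (exactly 2 levels used).
#' @param groups which two levels to compare, first minus second.
#' @return list with delta (difference of group means), p, and group means.
#' @export
compare_groups <- function(values, group, groups = NULL) {
  if (is.null(groups)) groups <- unique(group)[1:2]
  v1 <- values[group == groups[1]]
  v2 <- values[group == groups[2]]
  if (length(v1) < 2L || length(v2) < 2L) stop("each group needs >= 2 values")
  p <- if (stats::sd(v1) == 0 && stats::sd(v2) == 0) {
    if (mean(v1) == mean(v2)) 1 else 0
  } else {
    tryCatch(stats::t.test(v1, v2)$p.value, error = function(e) NA_real_)
  }
  list(delta = mean(v1) - mean(v2), p = p,
       means = setNames(c(mean(v1), mean(v2)), groups))
}
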