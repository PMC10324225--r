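# Independent brute-force oracles. These deliberately re-derive every
# quantity along a different code path than the package (per-character
# products instead of vectorized log-odds sums, all-pairs scans instead of
# interval trees) so agreement is evidence, not tautology.

COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

oracle_revcomp <- function(s) {
  paste(rev(COMP[strsplit(toupper(s), "")[[1]]]), collapse = "")
}

# TRAP site probability via the product form:
# K = R0 * prod_j (f(site_j) / f(consensus_j))^(1/lambda), p = K/(1+K).
# N bases use the background frequency (factor 1 relative to background,
# i.e. f = 0.25 here).
oracle_site_affinity <- function(counts, s, pos, strand = "+",
                                 pseudo = 1, lambda = 0.7) {
  W <- ncol(counts)
  reg <- counts + pseudo
  freq <- sweep(reg, 2, colSums(reg), "/")
  site <- substr(s, pos, pos + W - 1)
  if (strand == "-") site <- oracle_revcomp(site)
  chars <- strsplit(toupper(site), "")[[1]]
  ratio <- 1
  for (j in seq_len(W)) {
    fmax <- max(freq[, j])
    # relative to consensus; N contributes the background frequency 0.25
    fj <- if (chars[j] == "N") 0.25 else freq[chars[j], j]
    ratio <- ratio * (fj / fmax)^(1 / lambda)
  }
  R0 <- exp(0.584 * W - 5.66)
  K <- R0 * ratio
  unname(K / (1 + K))
}

oracle_region_affinity <- function(counts, s, pseudo = 1, lambda = 0.7) {
  W <- ncol(counts)
  L <- nchar(s)
  if (L < W) return(0)
  total <- 0
  for (pos in seq_len(L - W + 1)) {
    for (strand in c("+", "-")) {
      total <- total + oracle_site_affinity(counts, s, pos, strand,
                                            pseudo, lambda)
    }
  }
  total
}

# all-pairs TF-gene score: sum region affinities of every peak whose
# interval [start, end) intersects [tss - window, tss + window)
oracle_gene_scores <- function(peaks, seqs, genes, counts_list, window) {
  A <- matrix(0, nrow = length(counts_list), ncol = nrow(genes),
              dimnames = list(names(counts_list), genes$gene_id))
  for (g in seq_len(nrow(genes))) {
    lo <- genes$tss[g] - window
    hi <- genes$tss[g] + window
    for (p in seq_len(nrow(peaks))) {
      if (peaks$chrom[p] != genes$chrom[g]) next
      if (peaks$start[p] < hi && peaks$end[p] > lo) {
        for (t in seq_along(counts_list)) {
          A[t, g] <- A[t, g] + oracle_region_affinity(counts_list[[t]], seqs[p])
        }
      }
    }
  }
  A
}

# classical BH definition: adj p of the i-th smallest p is
# min over k >= i of p_(k) * n / k, capped at 1
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- numeric(n)
  for (i in seq_len(n)) {
    k <- which(ord == i)  # rank of p[i]
    cand <- vapply(k:n, function(kk) p[ord[kk]] * n / kk, numeric(1))
    adj[i] <- min(1, min(cand))
  }
  adj
}

# gap between two 0-based half-open intervals on the same chromosome
oracle_interval_distance <- function(s1, e1, s2, e2) {
  max(0, s2 - e1, s1 - e2)
}

# adjusted Rand index between two labelings
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  (sij - expected) / (maxi - expected)
}

random_pwm_counts <- function(W, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(sample(0:20, 4 * W, replace = TRUE), nrow = 4,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  m
}

random_dna_string <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

tiny_cfg <- function(seed = 1, ...) {
  args <- list(seed = seed, n_genes = 40, n_de_genes = 24,
               genome_length = 2e6, n_peaks = 40, n_cpgs = 40,
               n_planted_age = 6, n_planted_diet = 6, n_opposite = 4)
  over <- list(...)
  args[names(over)] <- over
  do.call(synthetic_config, args)
}
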