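#' @title TRAP-style transcription factor binding affinity
#' @description Biophysical affinity scoring of open-chromatin sequence with
#'   position weight matrices, following the TRAP model: each putative site is
#'   assigned a binding probability p = K / (1 + K) with K = R0 * exp(-E /
#'   lambda), where E is the mismatch energy of the site relative to the
#'   motif's consensus. Site probabilities are summed over all positions on
#'   both strands of a region, and region affinities are summed over all peaks
#'   within a window around each gene's TSS to give the per-condition TF-gene
#'   score A[t, g].
#' @name tf_affinity
NULL

BASES <- c("A", "C", "G", "T")

#' Construct a position weight model
#'
#' Holds a motif's count matrix, the column-stochastic frequency matrix after
#' pseudo-count regularization, and the natural-log odds matrix against a
#' uniform background. The mismatch energy of a site is the consensus log-odds
#' sum minus the site log-odds sum, so the consensus site has energy 0.
#'
#' @param name TF identifier.
#' @param counts 4 x W nonnegative matrix with rownames A, C, G, T.
#' @param pseudo pseudo-count added to every cell before normalization
#'   (default 1; prevents -Inf log-odds).
#' @param background vector of 4 background base frequencies (uniform default).
#' @return an object of class `pwm` with elements name, counts, freq,
#'   log_odds, width, background.
#' @export
pwm <- function(name, counts, pseudo = 1, background = rep(0.25, 4)) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("PWM count matrix must have 4 rows (A/C/G/T)")
  if (is.null(rownames(counts))) rownames(counts) <- BASES
  counts <- counts[BASES, , drop = FALSE]
  if (any(counts < 0)) stop("negative counts in PWM '", name, "'")
  background <- background / sum(background)
  reg <- counts + pseudo
  freq <- sweep(reg, 2, colSums(reg), "/")
  if (any(abs(colSums(freq) - 1) > 1e-9)) stop("PWM columns failed to normalize")
  log_odds <- log(freq / background)
  structure(
    list(name = name, counts = counts, freq = freq, log_odds = log_odds,
         width = ncol(counts), background = background),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM", x$name, " width", x$width, "\n")
  cat("consensus:", pwm_consensus(x), "\n")
  invisible(x)
}

#' Consensus sequence of a PWM (ties broken A<C<G<T)
#' @param p a [pwm()].
#' @return character scalar of length `p$width`.
#' @export
pwm_consensus <- function(p) {
  paste(BASES[apply(p$freq, 2, which.max)], collapse = "")
}

#' Reverse complement of a PWM
#' @param p a [pwm()].
#' @return a `pwm` scoring the reverse strand of the same motif.
#' @export
pwm_revcomp <- function(p) {
  rc <- p$counts[4:1, rev(seq_len(p$width)), drop = FALSE]
  rownames(rc) <- BASES
  out <- p
  out$counts <- rc
  out$freq <- p$freq[4:1, rev(seq_len(p$width)), drop = FALSE]
  rownames(out$freq) <- BASES
  out$log_odds <- p$log_odds[4:1, rev(seq_len(p$width)), drop = FALSE]
  rownames(out$log_odds) <- BASES
  out
}

# TRAP defaults (exposed through trap_params): lambda = 0.7 and
# ln R0 = 0.584 * W - 5.66, with W the motif width.
#' TRAP scoring parameters
#' @param lambda energy scale of the mismatch term.
#' @param r0_slope,r0_intercept coefficients of ln R0 = slope * W + intercept.
#' @return named list used by the affinity functions.
#' @export
trap_params <- function(lambda = 0.7, r0_slope = 0.584, r0_intercept = -5.66) {
  list(lambda = lambda, r0_slope = r0_slope, r0_intercept = r0_intercept)
}

# encode a DNA string into 1..4 (A,C,G,T); anything else (incl. N) -> 5
encode_seq <- function(sequence) {
  v <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  m <- match(v, BASES)
  m[is.na(m)] <- 5L
  m
}

# per-position site log-odds sums for one strand; enc is the encoded sequence,
# LO the 4 x W log-odds with a 5th zero row appended for N (background base).
site_logodds_vector <- function(enc, LO) {
  W <- ncol(LO)
  L <- length(enc)
  n_sites <- L - W + 1L
  if (n_sites < 1L) return(numeric(0))
  LO5 <- rbind(LO, 0)
  acc <- numeric(n_sites)
  for (j in seq_len(W)) {
    acc <- acc + LO5[cbind(enc[j:(j + n_sites - 1L)], j)]
  }
  acc
}

#' TRAP binding probability of one site
#'
#' Scores the W-mer starting at `position` (1-based) of `sequence` on the
#' given strand. Both strands of a region are treated as separate sites; no
#' max over strands is taken. N bases contribute the background frequency
#' (zero log-odds).
#'
#' @param p a [pwm()].
#' @param sequence DNA string over A/C/G/T/N.
#' @param position 1-based start of the site.
#' @param strand "+" scores the forward W-mer, "-" its reverse complement.
#' @param params [trap_params()].
#' @return binding probability in \[0, 1\].
#' @export
site_affinity <- function(p, sequence, position, strand = "+",
                          params = trap_params()) {
  enc <- encode_seq(sequence)
  W <- p$width
  if (position < 1L || position + W - 1L > length(enc)) {
    stop("site position ", position, " out of range for sequence of length ",
         length(enc))
  }
  LO <- if (strand == "+") p$log_odds else pwm_revcomp(p)$log_odds
  LO5 <- rbind(LO, 0)
  site <- sum(LO5[cbind(enc[position:(position + W - 1L)], seq_len(W))])
  consensus <- sum(apply(p$log_odds, 2, max))
  E <- consensus - site
  lnR0 <- params$r0_slope * W + params$r0_intercept
  K <- exp(lnR0) * exp(-E / params$lambda)
  K / (1 + K)
}

#' TRAP affinity of a region
#'
#' Sum of site binding probabilities over every position of the region on
#' both strands. Regions shorter than the motif width score 0 (logged as a
#' warning, not an error): no site fits.
#'
#' @param p a [pwm()].
#' @param sequence region DNA string.
#' @param params [trap_params()].
#' @return nonnegative real affinity.
#' @export
region_affinity <- function(p, sequence, params = trap_params()) {
  enc <- encode_seq(sequence)
  W <- p$width
  if (length(enc) < W) {
    warning("region of length ", length(enc), " shorter than motif width ",
            W, "; affinity 0")
    return(0)
  }
  scan_region(enc, p$log_odds, pwm_revcomp(p)$log_odds,
              sum(apply(p$log_odds, 2, max)),
              params$r0_slope * W + params$r0_intercept, params$lambda)
}

# inner scan over a pre-encoded region with precomputed strand matrices;
# shared by region_affinity and the batched gene_scores path
scan_region <- function(enc, LO_fwd, LO_rev, consensus, lnR0, lambda) {
  if (length(enc) < ncol(LO_fwd)) return(0)
  scores <- c(site_logodds_vector(enc, LO_fwd),
              site_logodds_vector(enc, LO_rev))
  K <- exp(lnR0 - (consensus - scores) / lambda)
  sum(K / (1 + K))
}

#' Drop TFs not expressed in the RNA data
#'
#' Retains TFs whose matched gene has baseMean >= `cutoff` in the
#' differential-expression results; TFs absent from the table are dropped.
#'
#' @param pwms list of [pwm()] objects.
#' @param base_means named numeric vector of per-gene baseMean values (names
#'   matched against TF names, case-insensitively).
#' @param cutoff minimum baseMean (default 10).
#' @return filtered list of pwms.
#' @export
filter_expressed_tfs <- function(pwms, base_means, cutoff = 10) {
  nms <- toupper(vapply(pwms, function(p) p$name, character(1)))
  bm <- base_means[match(nms, toupper(names(base_means)))]
  keep <- !is.na(bm) & bm >= cutoff
  message("filter_expressed_tfs: ", sum(keep), " of ", length(pwms),
          " TFs retained at baseMean >= ", cutoff)
  pwms[keep]
}

#' Per-condition TF-gene affinity scores
#'
#' A[t, g] is the sum of [region_affinity()] over all peaks whose interval
#' overlaps the window \[tss - window, tss + window) of gene g. A peak
#' overlapping two genes' windows counts fully for both; no proration or
#' distance decay is applied.
#'
#' @param peaks data.frame of peak intervals (chrom, start, end, name;
#'   0-based half-open) for one condition-specific peak set.
#' @param genes gene annotation data.frame (see [read_genes()]).
#' @param pwms list of [pwm()] objects.
#' @param genome DNAStringSet holding the peak chromosomes.
#' @param window half-width in bp of the TSS window (default 50000).
#' @param anchor "tss" (default) anchors the window at the TSS; "gene_body"
#'   extends the window from both gene ends instead.
#' @param params [trap_params()].
#' @return TFs x genes numeric matrix with dimnames.
#' @export
gene_scores <- function(peaks, genes, pwms, genome, window = 50000,
                        anchor = c("tss", "gene_body"),
                        params = trap_params()) {
  anchor <- match.arg(anchor)
  missing_chrom <- setdiff(genes$chrom, names(genome))
  if (length(missing_chrom)) {
    stop("gene chromosome(s) absent from genome: ",
         paste(missing_chrom, collapse = ", "), " (genes: ",
         paste(genes$gene_id[genes$chrom %in% missing_chrom], collapse = ", "),
         ")")
  }
  tf_names <- vapply(pwms, function(p) p$name, character(1))
  A <- matrix(0, nrow = length(pwms), ncol = nrow(genes),
              dimnames = list(tf_names, genes$gene_id))
  if (nrow(peaks) == 0L || length(pwms) == 0L) return(A)

  win <- if (anchor == "tss") {
    data.frame(chrom = genes$chrom,
               start = pmax(0L, genes$tss - window),
               end = genes$tss + window)
  } else {
    data.frame(chrom = genes$chrom,
               start = pmax(0L, genes$start - window),
               end = genes$end + window)
  }
  hits <- GenomicRanges::findOverlaps(as_granges0(peaks), as_granges0(win))

  # score every peak once against every PWM, then aggregate by gene;
  # sequences are encoded once and strand matrices precomputed per PWM
  seqs <- extract_sequences(peaks, genome)
  encs <- lapply(seqs, encode_seq)
  R <- matrix(0, nrow = nrow(peaks), ncol = length(pwms))
  for (t in seq_along(pwms)) {
    p <- pwms[[t]]
    LO_rev <- pwm_revcomp(p)$log_odds
    consensus <- sum(apply(p$log_odds, 2, max))
    lnR0 <- params$r0_slope * p$width + params$r0_intercept
    R[, t] <- vapply(encs, scan_region, numeric(1), LO_fwd = p$log_odds,
                     LO_rev = LO_rev, consensus = consensus, lnR0 = lnR0,
                     lambda = params$lambda)
  }
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  for (t in seq_along(pwms)) {
    agg <- rowsum(R[qh, t], group = sh)
    A[t, as.integer(rownames(agg))] <- agg[, 1]
  }
  A
}

#' Extract peak sequences from a genome
#' @param peaks interval data.frame (0-based half-open).
#' @param genome DNAStringSet.
#' @return character vector of sequences.
#' @export
extract_sequences <- function(peaks, genome) {
  vapply(seq_len(nrow(peaks)), function(i) {
    chrom <- peaks$chrom[i]
    if (!chrom %in% names(genome)) {
      stop("peak chromosome '", chrom, "' absent from genome")
    }
    as.character(Biostrings::subseq(genome[[chrom]],
                                    start = peaks$start[i] + 1L,
                                    end = peaks$end[i]))
  }, character(1))
}

#' Pseudocounted log2 affinity quotient
#'
#' q[t, g] = log2((A_ldc[t, g] + eps) / (A_co[t, g] + eps)). Antisymmetric
#' under swapping conditions; exactly 0 where both affinities are 0.
#'
#' @param A_ldc,A_co TFs x genes matrices with identical dimnames.
#' @param eps pseudocount (default 1e-6).
#' @return TFs x genes matrix of log2 quotients.
#' @export
affinity_quotient <- function(A_ldc, A_co, eps = 1e-6) {
  if (!identical(dimnames(A_ldc), dimnames(A_co)) ||
      !identical(dim(A_ldc), dim(A_co))) {
    stop("affinity matrices have mismatched TF/gene index sets")
  }
  q <- log2((A_ldc + eps) / (A_co + eps))
  if (any(!is.finite(q))) stop("non-finite quotient; check for negative affinities")
  q
}
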