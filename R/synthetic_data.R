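#' @title Synthetic data generation
#' @description Generates every input the pipeline consumes, with the
#'   statistical structure the analysis assumes: a random genome with
#'   non-overlapping genes; open-chromatin peaks, a subset of which carry
#'   planted motif instances of "active" TFs near the TSS of their target
#'   cluster's genes and gain accessibility in the treatment condition (LDC)
#'   by a configurable log2 effect size; per-sample expression and a
#'   differential-expression table whose direction labels follow the planted
#'   accessibility changes; and methylation count/chromatogram tables with
#'   age- and diet-dependent shifts, including loci deliberately planted in
#'   opposite directions for the two contrasts. Every generator is a pure
#'   function of the configuration: the root seed is split into named
#'   substreams so adding one generator never perturbs another.
#' @name synthetic_data
NULL

# named substream: deterministic child seed from (root seed, stream name)
substream_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 1000003
  as.integer((abs(seed) * 1009 + h * 2531) %% 2147483629 + 1)
}

with_substream <- function(seed, name, expr) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(substream_seed(seed, name))
  force(expr)
}

#' Synthetic study configuration
#'
#' Defaults describe the toy-scale analogue of the study design: two diet
#' conditions (Co vs LDC), 4 gene clusters, 20 TFs of which 2 actively drive
#' the expression response, a 50 kb gene-score window's worth of genomic
#' spacing between genes, and methylation cohorts sized like the aging
#' validation groups.
#'
#' @param seed root RNG seed; all substreams derive from it.
#' @param n_genes total genes on the genome.
#' @param n_tfs number of TF motifs.
#' @param n_active_tfs TFs with a planted regulatory effect.
#' @param n_clusters gene clusters (default 4).
#' @param genome_length genome size in bp.
#' @param n_peaks background (non-planted) open-chromatin peaks.
#' @param peak_width peak width in bp.
#' @param motif_length motif width in bp.
#' @param effect_size log2-fold multiplier applied to the accessibility of
#'   motif-bearing peaks in condition LDC (0 = null model).
#' @param n_samples_per_group samples per condition/age group.
#' @param n_de_genes designated differentially expressed genes (partitioned
#'   into the clusters).
#' @param n_cpgs CpG sites in the methylation tables.
#' @param aging_delta methylation-fraction decrease in aged vs young at
#'   age-planted loci (in \[-1, 1\]).
#' @param diet_delta methylation-fraction increase in LDC vs Co at
#'   diet-planted loci (in \[-1, 1\]).
#' @param n_planted_age,n_planted_diet planted locus counts per contrast.
#' @param n_opposite loci planted in both contrasts with opposite direction
#'   (aging down, diet up); counted within the planted sets.
#' @param depth mean sequencing depth per CpG per sample.
#' @return validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1, n_genes = 450, n_tfs = 20,
                             n_active_tfs = 2, n_clusters = 4,
                             genome_length = 4e7, n_peaks = 300,
                             peak_width = 400, motif_length = 8,
                             effect_size = 1.5, n_samples_per_group = 4,
                             n_de_genes = 400, n_cpgs = 200,
                             aging_delta = 0.4, diet_delta = 0.3,
                             n_planted_age = 10, n_planted_diet = 10,
                             n_opposite = 6, depth = 100) {
  cfg <- list(seed = seed, n_genes = n_genes, n_tfs = n_tfs,
              n_active_tfs = n_active_tfs, n_clusters = n_clusters,
              genome_length = genome_length, n_peaks = n_peaks,
              peak_width = peak_width, motif_length = motif_length,
              effect_size = effect_size,
              n_samples_per_group = n_samples_per_group,
              n_de_genes = n_de_genes, n_cpgs = n_cpgs,
              aging_delta = aging_delta, diet_delta = diet_delta,
              n_planted_age = n_planted_age, n_planted_diet = n_planted_diet,
              n_opposite = n_opposite, depth = depth)
  counts <- cfg[c("n_genes", "n_tfs", "n_active_tfs", "n_clusters",
                  "genome_length", "n_peaks", "peak_width", "motif_length",
                  "n_samples_per_group", "n_de_genes", "n_cpgs", "depth")]
  if (any(unlist(counts) <= 0)) stop("all counts must be > 0")
  if (n_active_tfs > n_tfs) stop("n_active_tfs must not exceed n_tfs")
  if (n_clusters < 2) stop("n_clusters must be >= 2")
  if (n_de_genes > n_genes) stop("n_de_genes must not exceed n_genes")
  if (motif_length > peak_width) {
    stop("motif_length (", motif_length, ") exceeds peak_width (",
         peak_width, ")")
  }
  if (abs(aging_delta) > 1 || abs(diet_delta) > 1) {
    stop("methylation deltas must lie in [-1, 1]")
  }
  if (n_opposite > min(n_planted_age, n_planted_diet)) {
    stop("n_opposite exceeds a planted locus count")
  }
  structure(cfg, class = "synthetic_config")
}

random_dna <- function(n) {
  rawToChar(as.raw(c(65L, 67L, 71L, 84L))[sample.int(4L, n, replace = TRUE)])
}

#' Generate a random genome with non-overlapping genes
#'
#' One chromosome of i.i.d. uniform base composition. Gene bodies (2-8 kb)
#' are placed without overlap by distributing the leftover space as random
#' gaps; strands are random; gene ids are stable zero-padded identifiers.
#'
#' @param cfg a [synthetic_config()].
#' @return list with `genome` (DNAStringSet, one chromosome "chr1") and
#'   `genes` (gene annotation data.frame with 0-based half-open coords and
#'   strand-aware TSS).
#' @export
generate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_substream(cfg$seed, "genome", {
    max_len <- min(8000, max(2000, floor(cfg$genome_length / (2 * cfg$n_genes))))
    min_len <- max(1, min(2000, floor(max_len / 2)))
    lens <- sample(min_len:max_len, cfg$n_genes, replace = TRUE)
    total_gap <- cfg$genome_length - sum(lens)
    if (total_gap < cfg$n_genes) {
      stop("genome_length ", cfg$genome_length, " too small to place ",
           cfg$n_genes, " genes")
    }
    gap_w <- stats::rexp(cfg$n_genes + 1L)
    gaps <- floor(gap_w / sum(gap_w) * total_gap)
    starts <- cumsum(gaps[seq_len(cfg$n_genes)]) +
      c(0, cumsum(lens[-cfg$n_genes]))
    genes <- data.frame(
      gene_id = sprintf("g%04d", seq_len(cfg$n_genes)),
      chrom = "chr1",
      start = as.integer(starts),
      end = as.integer(starts + lens),
      strand = sample(c("+", "-"), cfg$n_genes, replace = TRUE),
      stringsAsFactors = FALSE
    )
    genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
    seqs <- Biostrings::DNAStringSet(random_dna(cfg$genome_length))
    names(seqs) <- "chr1"
    list(genome = seqs, genes = genes)
  })
}

# informative PFM: consensus base carries most of the count mass per column
random_pfm_counts <- function(width, consensus_weight = 85, other_weight = 5) {
  cons <- sample(1:4, width, replace = TRUE)
  counts <- matrix(other_weight, nrow = 4, ncol = width,
                   dimnames = list(BASES, NULL))
  counts[cbind(cons, seq_len(width))] <- consensus_weight
  counts
}

#' Generate peaks, motifs and the regulatory ground truth
#'
#' Draws `n_tfs` informative PFMs and marks the first `n_active_tfs` active,
#' assigning each a target cluster (round-robin over 1..n_clusters). The
#' designated DE genes are partitioned into the clusters. Every DE gene of a
#' targeted cluster receives one planted peak within 2 kb of its TSS whose
#' sequence carries the active TF's consensus motif (written into the genome),
#' and whose negative-binomial accessibility mean is multiplied by
#' 2^effect_size in condition LDC. Background peaks are placed uniformly with
#' equal means in both conditions. Per-peak logFC is log2 of the shifted
#' per-condition mean counts.
#'
#' @param cfg a [synthetic_config()].
#' @param genome,genes output of [generate_genome()].
#' @param nb_dispersion negative-binomial dispersion of accessibility counts
#'   (default 0.1).
#' @param base_mean baseline accessibility mean (default 100).
#' @return list with `peaks` (intervals + per-condition signal + logFC),
#'   `pwms`, the motif-edited `genome`, and `ground_truth` (active TFs with
#'   target clusters, gene->cluster map, DE direction, planted peaks).
#' @export
generate_regulatory_landscape <- function(cfg, genome, genes,
                                          nb_dispersion = 0.1,
                                          base_mean = 100) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_substream(cfg$seed, "landscape", {
    W <- cfg$motif_length
    tf_names <- sprintf("TF%02d", seq_len(cfg$n_tfs))
    pwms <- lapply(seq_len(cfg$n_tfs), function(i) {
      pwm(tf_names[i], random_pfm_counts(W))
    })
    names(pwms) <- tf_names
    active <- data.frame(
      tf = tf_names[seq_len(cfg$n_active_tfs)],
      target_cluster = ((seq_len(cfg$n_active_tfs) - 1L) %% cfg$n_clusters) + 1L,
      stringsAsFactors = FALSE
    )

    de_genes <- sort(sample(genes$gene_id, cfg$n_de_genes))
    gene_clusters <- setNames(
      rep_len(seq_len(cfg$n_clusters), cfg$n_de_genes)[sample.int(cfg$n_de_genes)],
      de_genes
    )

    # direction labels: targeted clusters follow the planted accessibility
    # gain (up in LDC when effect_size > 0); everything else is a coin flip
    de_direction <- setNames(
      sample(c("up", "down"), cfg$n_de_genes, replace = TRUE), de_genes)
    targeted <- gene_clusters %in% active$target_cluster
    if (cfg$effect_size > 0) {
      de_direction[targeted] <- "up"
    } else if (cfg$effect_size < 0) {
      de_direction[targeted] <- "down"
    }

    size <- 1 / nb_dispersion
    n <- cfg$n_samples_per_group
    half <- cfg$peak_width %/% 2

    # background peaks, uniform placement, equal means in both conditions
    bg_start <- sort(sample.int(cfg$genome_length - cfg$peak_width,
                                cfg$n_peaks))
    peaks <- data.frame(
      chrom = "chr1", start = bg_start, end = bg_start + cfg$peak_width,
      name = sprintf("bg_peak%04d", seq_len(cfg$n_peaks)),
      planted_tf = NA_character_, stringsAsFactors = FALSE
    )

    # planted peaks: one per DE gene of each active TF's target cluster
    chrom_seq <- genome[["chr1"]]
    planted <- list()
    motif_ranges <- list()
    motif_seqs <- character(0)
    for (a in seq_len(nrow(active))) {
      tgt_genes <- names(gene_clusters)[gene_clusters == active$target_cluster[a]]
      consensus <- pwm_consensus(pwms[[active$tf[a]]])
      for (g in tgt_genes) {
        tss <- genes$tss[genes$gene_id == g]
        center <- tss + sample(-2000:2000, 1)
        start <- max(0L, min(center - half, cfg$genome_length - cfg$peak_width))
        motif_at <- as.integer(start + half - W %/% 2)  # 0-based
        motif_ranges[[length(motif_ranges) + 1L]] <-
          as.integer(c(motif_at + 1L, motif_at + W))
        motif_seqs <- c(motif_seqs, consensus)
        planted[[length(planted) + 1L]] <- data.frame(
          chrom = "chr1", start = start, end = start + cfg$peak_width,
          name = sprintf("planted_%s_%s", active$tf[a], g),
          planted_tf = active$tf[a], stringsAsFactors = FALSE
        )
      }
    }
    if (length(motif_ranges)) {
      ir <- IRanges::IRanges(
        start = vapply(motif_ranges, `[`, integer(1), 1L),
        end = vapply(motif_ranges, `[`, integer(1), 2L))
      if (IRanges::isDisjoint(ir)) {
        chrom_seq <- Biostrings::replaceAt(chrom_seq, ir, motif_seqs)
      } else {
        # adjacent genes can yield overlapping plants; apply sequentially
        for (i in seq_along(motif_seqs)) {
          chrom_seq <- Biostrings::replaceAt(chrom_seq, ir[i], motif_seqs[i])
        }
      }
    }
    planted <- if (length(planted)) do.call(rbind, planted) else NULL
    peaks <- rbind(peaks, planted)
    genome[["chr1"]] <- chrom_seq

    mult <- ifelse(is.na(peaks$planted_tf), 1, 2^cfg$effect_size)
    mu_co <- rep(base_mean, nrow(peaks))
    mu_ldc <- base_mean * mult
    co_counts <- matrix(stats::rnbinom(nrow(peaks) * n, mu = mu_co, size = size),
                        ncol = n)
    ldc_counts <- matrix(stats::rnbinom(nrow(peaks) * n, mu = mu_ldc, size = size),
                         ncol = n)
    peaks$signal_Co <- rowMeans(co_counts)
    peaks$signal_LDC <- rowMeans(ldc_counts)
    peaks$logFC <- log2((peaks$signal_LDC + 1) / (peaks$signal_Co + 1))
    rownames(peaks) <- NULL

    list(
      peaks = peaks, pwms = pwms, genome = genome,
      ground_truth = list(
        active_tfs = active,
        gene_clusters = gene_clusters,
        de_direction = de_direction,
        planted_peaks = if (is.null(planted)) character(0) else planted$name
      )
    )
  })
}

#' Generate expression and differential-expression tables
#'
#' Per-sample FPM values follow a log-normal baseline with multiplicative
#' noise; designated DE genes shift their LDC samples by the planted log2
#' fold change. The DE table is a simplified stand-in for an external
#' count-model test: with a nonzero effect size, designated DE genes receive
#' adjusted p-values below 1e-3 and all other genes values in \[0.5, 1\];
#' with effect size 0, adjusted p-values are uniform on \[0, 1\] for every
#' gene, so downstream DE fractions are nominal. A small fraction of
#' non-DE genes is near-silent to exercise the FPM filter.
#'
#' @param cfg a [synthetic_config()].
#' @param ground_truth from [generate_regulatory_landscape()].
#' @param genes gene annotation from [generate_genome()].
#' @return list with `fpm` (genes x samples matrix, Co then LDC columns),
#'   `de_table` (gene, baseMean, log2FC, padj), `clusters` (data.frame gene,
#'   cluster) and `tf_expression` (tf, baseMean).
#' @export
generate_expression_tables <- function(cfg, ground_truth, genes) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_substream(cfg$seed, "expression", {
    n <- cfg$n_samples_per_group
    gid <- genes$gene_id
    ng <- length(gid)
    de <- names(ground_truth$gene_clusters)
    is_de <- gid %in% de

    baseline <- stats::rlnorm(ng, meanlog = 3, sdlog = 1)
    # ~5% of non-DE genes near-silent (exercise the detectability filter)
    silent <- !is_de & stats::runif(ng) < 0.05
    baseline[silent] <- 0.01

    lfc <- stats::rnorm(ng, 0, 0.2)
    if (cfg$effect_size != 0) {
      dir_sign <- ifelse(ground_truth$de_direction[gid[is_de]] == "up", 1, -1)
      lfc[is_de] <- dir_sign *
        (abs(cfg$effect_size) * 0.8 + abs(stats::rnorm(sum(is_de), 0, 0.2)))
    }

    fpm <- matrix(0, nrow = ng, ncol = 2 * n,
                  dimnames = list(gid, c(paste0("Co_", seq_len(n)),
                                         paste0("LDC_", seq_len(n)))))
    for (s in seq_len(n)) {
      fpm[, s] <- baseline * stats::rlnorm(ng, 0, 0.2)
      fpm[, n + s] <- baseline * 2^lfc * stats::rlnorm(ng, 0, 0.2)
    }

    padj <- if (cfg$effect_size == 0) {
      stats::runif(ng)
    } else {
      ifelse(is_de, stats::runif(ng, 0, 1e-3), stats::runif(ng, 0.5, 1))
    }
    de_table <- data.frame(
      gene = gid,
      baseMean = rowMeans(fpm) * 10,
      log2FC = lfc,
      padj = padj,
      stringsAsFactors = FALSE
    )
    tf_expression <- data.frame(
      tf = sprintf("TF%02d", seq_len(cfg$n_tfs)),
      baseMean = stats::runif(cfg$n_tfs, 50, 500),
      stringsAsFactors = FALSE
    )
    clusters <- data.frame(gene = names(ground_truth$gene_clusters),
                           cluster = as.integer(ground_truth$gene_clusters),
                           stringsAsFactors = FALSE)
    list(fpm = fpm, de_table = de_table, clusters = clusters,
         tf_expression = tf_expression)
  })
}

#' Generate methylation count and chromatogram tables
#'
#' CpG sites are simulated for five groups (young, mid, aged, Co, LDC) with
#' `n_samples_per_group` samples each: per-sample coverage is negative
#' binomial around `depth` and methylated counts are binomial around the
#' group's planted fraction. Age-planted loci lose `aging_delta` methylation
#' in aged vs young (half in mid-aged); diet-planted loci gain `diet_delta`
#' in LDC vs Co; `n_opposite` loci are planted in both contrasts with
#' opposite directions, emulating a discordant aging-versus-diet pattern.
#' Chromatogram peak heights are generated from the same underlying
#' fractions with multiplicative log-normal noise (sigma 0.1). Means pushed
#' outside \[0, 1\] by a delta are clipped with a warning.
#'
#' @param cfg a [synthetic_config()].
#' @param snupe_total total chromatogram height scale (arbitrary units).
#' @return list with `rrbs` (long table: site, chrom, pos, sample, group,
#'   meth_reads, total_reads), `snupe` (locus, sample, group, technology,
#'   h_M, h_UM), and `ground_truth` (site, planted_age, planted_diet in
#'   \{-1, 0, 1\}).
#' @export
generate_methylation_tables <- function(cfg, snupe_total = 1000) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_substream(cfg$seed, "methylation", {
    n <- cfg$n_samples_per_group
    ns <- cfg$n_cpgs
    site <- sprintf("cpg%04d", seq_len(ns))
    pos <- sort(sample.int(cfg$genome_length, ns))

    planted_age <- integer(ns)
    planted_diet <- integer(ns)
    if (cfg$aging_delta != 0 && cfg$n_planted_age > 0) {
      planted_age[seq_len(cfg$n_planted_age)] <- -1L  # aging hypomethylation
    }
    if (cfg$diet_delta != 0 && cfg$n_planted_diet > 0) {
      idx <- c(seq_len(cfg$n_opposite),
               cfg$n_planted_age + seq_len(cfg$n_planted_diet - cfg$n_opposite))
      planted_diet[idx] <- 1L  # diet hypermethylation
    }
    any_planted <- planted_age != 0 | planted_diet != 0
    base <- ifelse(any_planted, stats::runif(ns, 0.45, 0.55),
                   stats::runif(ns, 0.05, 0.95))

    clip01 <- function(x) {
      if (any(x < 0 | x > 1)) {
        warning("planted methylation mean clipped to [0, 1]")
      }
      pmin(pmax(x, 0.01), 0.99)
    }
    group_mean <- list(
      young = clip01(base),
      mid = clip01(base + planted_age * cfg$aging_delta / 2),
      aged = clip01(base + planted_age * cfg$aging_delta),
      Co = clip01(base),
      LDC = clip01(base + planted_diet * cfg$diet_delta)
    )

    rrbs <- do.call(rbind, lapply(names(group_mean), function(g) {
      do.call(rbind, lapply(seq_len(n), function(s) {
        total <- stats::rnbinom(ns, mu = cfg$depth, size = 10) + 1L
        meth <- stats::rbinom(ns, total, group_mean[[g]])
        data.frame(site = site, chrom = "chr1", pos = pos,
                   sample = paste0(g, "_", s), group = g,
                   meth_reads = meth, total_reads = total,
                   stringsAsFactors = FALSE)
      }))
    }))

    # chromatogram panel: planted loci plus an equal number of controls
    panel <- site[any_planted]
    n_ctrl <- min(sum(!any_planted), max(4L, length(panel)))
    panel <- c(panel, site[!any_planted][seq_len(n_ctrl)])
    snupe <- do.call(rbind, lapply(names(group_mean), function(g) {
      do.call(rbind, lapply(seq_len(n), function(s) {
        f <- group_mean[[g]][match(panel, site)]
        f_noisy <- pmin(pmax(
          f + stats::rnorm(length(panel), 0, 0.02), 0.005), 0.995)
        hm <- snupe_total * f_noisy * stats::rlnorm(length(panel), 0, 0.1)
        hum <- snupe_total * (1 - f_noisy) * stats::rlnorm(length(panel), 0, 0.1)
        data.frame(locus = panel, sample = paste0(g, "_", s), group = g,
                   technology = "SNuPE", h_M = hm, h_UM = hum,
                   stringsAsFactors = FALSE)
      }))
    }))
    rownames(rrbs) <- rownames(snupe) <- NULL

    list(
      rrbs = rrbs, snupe = snupe,
      ground_truth = data.frame(site = site, planted_age = planted_age,
                                planted_diet = planted_diet,
                                stringsAsFactors = FALSE)
    )
  })
}

#' Write all synthetic inputs to an output directory
#'
#' Materializes one synthetic study as plain-text files: genome FASTA, gene
#' and peak BED6, JASPAR PFM text, TSV tables (peak signal, FPM, DE results,
#' clusters, TF expression, RRBS counts, chromatogram heights) and a JSON
#' ground-truth file.
#'
#' @param cfg a [synthetic_config()].
#' @param outdir output directory (created if needed).
#' @return invisibly, a named list of the file paths written.
#' @export
simulate_study <- function(cfg, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  gen <- generate_genome(cfg)
  land <- generate_regulatory_landscape(cfg, gen$genome, gen$genes)
  expr <- generate_expression_tables(cfg, land$ground_truth, gen$genes)
  meth <- generate_methylation_tables(cfg)
  p <- function(f) file.path(outdir, f)

  write_genome(land$genome, p("genome.fa"))
  write_bed(data.frame(chrom = gen$genes$chrom, start = gen$genes$start,
                       end = gen$genes$end, name = gen$genes$gene_id,
                       score = 0, strand = gen$genes$strand), p("genes.bed"))
  write_bed(land$peaks[, c("chrom", "start", "end", "name")], p("peaks.bed"))
  write_pfm(land$pwms, p("motifs.pfm"))
  write_table(land$peaks, p("peak_signal.tsv"))
  write_table(as.data.frame(expr$fpm), p("fpm.tsv"), row_names = "gene")
  write_table(expr$de_table, p("de_table.tsv"))
  write_table(expr$clusters, p("clusters.tsv"))
  write_table(expr$tf_expression, p("tf_expression.tsv"))
  write_table(meth$rrbs, p("rrbs.tsv"))
  write_table(meth$snupe, p("snupe.tsv"))
  gt <- list(
    active_tfs = land$ground_truth$active_tfs,
    gene_clusters = as.list(land$ground_truth$gene_clusters),
    de_direction = as.list(land$ground_truth$de_direction),
    planted_peaks = land$ground_truth$planted_peaks,
    differentially_methylated_cpgs =
      meth$ground_truth[meth$ground_truth$planted_age != 0 |
                          meth$ground_truth$planted_diet != 0, ]
  )
  jsonlite::write_json(gt, p("ground_truth.json"), auto_unbox = TRUE,
                       digits = NA)
  files <- list(genome = p("genome.fa"), genes = p("genes.bed"),
                peaks = p("peaks.bed"), motifs = p("motifs.pfm"),
                peak_signal = p("peak_signal.tsv"), fpm = p("fpm.tsv"),
                de_table = p("de_table.tsv"), clusters = p("clusters.tsv"),
                tf_expression = p("tf_expression.tsv"), rrbs = p("rrbs.tsv"),
                snupe = p("snupe.tsv"), ground_truth = p("ground_truth.json"))
  invisible(files)
}
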