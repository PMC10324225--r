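test_that("synthetic_config validates its invariants", {
  expect_s3_class(tiny_cfg(), "synthetic_config")
  expect_error(tiny_cfg(n_tfs = 2, n_active_tfs = 3), "n_active_tfs")
  expect_error(tiny_cfg(n_clusters = 1), "n_clusters")
  expect_error(tiny_cfg(n_peaks = 0), "> 0")
  expect_error(tiny_cfg(motif_length = 500, peak_width = 400), "motif_length")
  expect_error(tiny_cfg(aging_delta = 1.5), "deltas")
  expect_error(tiny_cfg(n_opposite = 10, n_planted_age = 3), "n_opposite")
})

test_that("generate_genome places genes in bounds, deterministically", {
  cfg <- synthetic_config(seed = 1, n_genes = 50, genome_length = 1e6,
                          n_de_genes = 20)
  gen <- generate_genome(cfg)
  expect_equal(nrow(gen$genes), 50)
  expect_true(all(gen$genes$start >= 0 & gen$genes$end <= 1e6))
  expect_true(all(gen$genes$start < gen$genes$end))
  expect_true(all(gen$genes$strand %in% c("+", "-")))
  expect_true(all(gen$genes$tss >= gen$genes$start &
                    gen$genes$tss < gen$genes$end))
  # non-overlapping gene bodies
  ord <- order(gen$genes$start)
  expect_true(all(diff(gen$genes$start[ord]) >=
                    (gen$genes$end[ord] - gen$genes$start[ord])[-50]))
  # byte-identical regeneration under the same seed
  gen2 <- generate_genome(cfg)
  expect_identical(as.character(gen$genome), as.character(gen2$genome))
  expect_identical(gen$genes, gen2$genes)
  # pigeonhole: too many genes for the sequence
  expect_error(
    generate_genome(synthetic_config(n_genes = 10000, genome_length = 10000,
                                     n_de_genes = 10)),
    "too small")
})

test_that("regulatory landscape plants motifs with planted accessibility", {
  cfg <- tiny_cfg(seed = 2)
  gen <- generate_genome(cfg)
  land <- generate_regulatory_landscape(cfg, gen$genome, gen$genes)
  gt <- land$ground_truth
  expect_equal(nrow(gt$active_tfs), 2)
  expect_setequal(gt$active_tfs$tf, c("TF01", "TF02"))
  # planted peak sequences contain the exact consensus: the max log-odds
  # site over a brute-force scan equals the consensus score
  planted <- land$peaks[!is.na(land$peaks$planted_tf), ]
  expect_gt(nrow(planted), 0)
  for (i in sample(nrow(planted), 3)) {
    p <- land$pwms[[planted$planted_tf[i]]]
    s <- extract_sequences(planted[i, ], land$genome)
    best <- -Inf
    chars <- strsplit(s, "")[[1]]
    for (pos in 1:(nchar(s) - p$width + 1)) {
      for (strand in c("+", "-")) {
        site <- paste(chars[pos:(pos + p$width - 1)], collapse = "")
        if (strand == "-") site <- oracle_revcomp(site)
        sc_chars <- strsplit(site, "")[[1]]
        sc <- sum(vapply(seq_len(p$width),
                         function(j) p$log_odds[sc_chars[j], j], numeric(1)))
        best <- max(best, sc)
      }
    }
    expect_equal(best, sum(apply(p$log_odds, 2, max)), tolerance = 1e-9)
  }
  # every active TF has a motif peak within the score window of a target gene
  for (a in seq_len(nrow(gt$active_tfs))) {
    tf <- gt$active_tfs$tf[a]
    tgt <- names(gt$gene_clusters)[gt$gene_clusters ==
                                     gt$active_tfs$target_cluster[a]]
    pk <- land$peaks[!is.na(land$peaks$planted_tf) &
                       land$peaks$planted_tf == tf, ]
    tss <- gen$genes$tss[match(tgt, gen$genes$gene_id)]
    near <- outer(pk$start, tss, function(s, t) abs(s - t) < 50000)
    expect_true(all(rowSums(near) >= 1))
  }
  # planted peaks gain accessibility in LDC
  expect_gt(mean(planted$logFC), 0.5)
})

test_that("effect_size = 0 yields equal expected accessibility", {
  cfg <- tiny_cfg(seed = 3, effect_size = 0)
  gen <- generate_genome(cfg)
  land <- generate_regulatory_landscape(cfg, gen$genome, gen$genes)
  planted <- !is.na(land$peaks$planted_tf)
  # same NB mean in both conditions: group means agree within noise
  expect_equal(mean(land$peaks$signal_LDC[planted]),
               mean(land$peaks$signal_Co[planted]), tolerance = 0.1)
  expect_equal(mean(land$peaks$signal_LDC), mean(land$peaks$signal_Co),
               tolerance = 0.1)
})

test_that("expression tables encode planted DE structure", {
  cfg <- tiny_cfg(seed = 4)
  gen <- generate_genome(cfg)
  land <- generate_regulatory_landscape(cfg, gen$genome, gen$genes)
  expr <- generate_expression_tables(cfg, land$ground_truth, gen$genes)
  gt <- land$ground_truth
  de <- names(gt$gene_clusters)
  tab <- expr$de_table
  # planted up-genes have positive log2FC, down-genes negative
  up <- names(gt$de_direction)[gt$de_direction == "up"]
  down <- names(gt$de_direction)[gt$de_direction == "down"]
  expect_true(all(tab$log2FC[match(up, tab$gene)] > 0))
  expect_true(all(tab$log2FC[match(down, tab$gene)] < 0))
  # designated DE genes significant, others not
  expect_true(all(tab$padj[match(de, tab$gene)] < 0.05))
  expect_true(all(tab$padj[!tab$gene %in% de] >= 0.5))
  # cluster labels partition the DE genes into k non-empty groups
  expect_setequal(expr$clusters$gene, de)
  expect_equal(sort(unique(expr$clusters$cluster)), 1:4)
  expect_true(all(table(expr$clusters$cluster) > 0))
})

test_that("null expression tables give nominal DE fractions (20 seeds)", {
  fracs <- vapply(1:20, function(seed) {
    cfg <- tiny_cfg(seed = seed, effect_size = 0, n_genes = 200,
                    n_de_genes = 100)
    gen <- generate_genome(cfg)
    # expression only needs gene ids + a cluster map; skip the landscape
    gt <- list(gene_clusters = setNames(rep_len(1:4, 100),
                                        gen$genes$gene_id[1:100]),
               de_direction = setNames(rep(c("up", "down"), 50),
                                       gen$genes$gene_id[1:100]))
    expr <- generate_expression_tables(cfg, gt, gen$genes)
    mean(expr$de_table$padj < 0.05)
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.05), 0.015)
})

test_that("methylation tables plant aging/diet shifts at stated depth", {
  cfg <- tiny_cfg(seed = 5, depth = 1000)
  meth <- generate_methylation_tables(cfg)
  gt <- meth$ground_truth
  rrbs <- meth$rrbs
  beta_of <- function(site, group) {
    r <- rrbs[rrbs$site == site & rrbs$group == group, ]
    mean(r$meth_reads / r$total_reads)
  }
  # opposite-direction loci: age down, diet up, both near their deltas
  opp <- gt$site[gt$planted_age == -1 & gt$planted_diet == 1]
  expect_length(opp, 4)
  for (s in opp) {
    expect_equal(beta_of(s, "aged") - beta_of(s, "young"), -cfg$aging_delta,
                 tolerance = 0.05)
    expect_equal(beta_of(s, "LDC") - beta_of(s, "Co"), cfg$diet_delta,
                 tolerance = 0.05)
  }
  # chromatogram heights reflect the same fractions
  snupe <- meth$snupe
  s <- opp[1]
  idx <- methylation_index(snupe$h_M[snupe$locus == s & snupe$group == "aged"],
                           snupe$h_UM[snupe$locus == s & snupe$group == "aged"])
  expect_lt(abs(mean(idx) - beta_of(s, "aged")), 0.05)
})

test_that("zero deltas plant nothing; ground truth flags directions", {
  cfg0 <- tiny_cfg(seed = 6, aging_delta = 0, diet_delta = 0)
  meth0 <- generate_methylation_tables(cfg0)
  expect_true(all(meth0$ground_truth$planted_age == 0))
  expect_true(all(meth0$ground_truth$planted_diet == 0))
  cfg1 <- tiny_cfg(seed = 6)
  gt1 <- generate_methylation_tables(cfg1)$ground_truth
  opp <- gt1$planted_age != 0 & gt1$planted_diet != 0
  expect_true(all(sign(gt1$planted_age[opp]) != sign(gt1$planted_diet[opp])))
})

test_that("simulate_study writes a deterministic, self-consistent bundle", {
  cfg <- tiny_cfg(seed = 7)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- simulate_study(cfg, d1)
  f2 <- simulate_study(cfg, d2)
  for (nm in names(f1)) {
    expect_identical(readLines(f1[[nm]]), readLines(f2[[nm]]),
                     label = paste("file", nm))
  }
  genes <- read_genes(f1$genes)
  expect_equal(nrow(genes), cfg$n_genes)
  pwms <- read_pfm(f1$motifs)
  expect_length(pwms, cfg$n_tfs)
  gt <- jsonlite::read_json(f1$ground_truth)
  expect_length(gt$active_tfs, cfg$n_active_tfs)
})
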