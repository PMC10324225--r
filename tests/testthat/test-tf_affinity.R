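test_that("consensus site attains p = R0 / (1 + R0)", {
  counts <- random_pwm_counts(8, seed = 1)
  p <- pwm("T1", counts)
  consensus <- pwm_consensus(p)
  R0 <- exp(0.584 * 8 - 5.66)
  expect_equal(site_affinity(p, consensus, 1), R0 / (1 + R0), tolerance = 1e-12)
  # reverse strand of the reverse-complemented consensus scores the same
  rc <- oracle_revcomp(consensus)
  expect_equal(site_affinity(p, rc, 1, strand = "-"), R0 / (1 + R0),
               tolerance = 1e-12)
})

test_that("uniform PWM scores every position identically", {
  counts <- matrix(5, 4, 6, dimnames = list(c("A", "C", "G", "T"), NULL))
  p <- pwm("U", counts)
  set.seed(2)
  s <- random_dna_string(40)
  vals <- vapply(1:35, function(i) site_affinity(p, s, i), numeric(1))
  expect_equal(max(vals) - min(vals), 0, tolerance = 1e-12)
})

test_that("site_affinity matches the product-form oracle on random input", {
  set.seed(3)
  for (rep in 1:10) {
    counts <- random_pwm_counts(6)
    p <- pwm("T", counts)
    s <- random_dna_string(30)
    for (pos in sample(1:25, 4)) {
      for (strand in c("+", "-")) {
        expect_equal(site_affinity(p, s, pos, strand),
                     oracle_site_affinity(counts, s, pos, strand),
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("site_affinity handles N bases and range errors", {
  counts <- random_pwm_counts(5, seed = 4)
  p <- pwm("T", counts)
  s <- "ACNGTACGT"
  expect_equal(site_affinity(p, s, 1), oracle_site_affinity(counts, s, 1),
               tolerance = 1e-9)
  expect_error(site_affinity(p, s, 6), "out of range")
  expect_error(site_affinity(p, s, 0), "out of range")
})

test_that("region_affinity equals the brute-force double-strand scan", {
  set.seed(5)
  counts <- random_pwm_counts(6)
  p <- pwm("T", counts)
  s <- random_dna_string(200)
  expect_equal(region_affinity(p, s), oracle_region_affinity(counts, s),
               tolerance = 1e-9)
  # region of exactly motif width = one forward + one reverse site
  w <- random_dna_string(6)
  expect_equal(region_affinity(p, w),
               site_affinity(p, w, 1, "+") + site_affinity(p, w, 1, "-"),
               tolerance = 1e-12)
  # self-concatenation is superadditive (junction sites add)
  expect_gte(region_affinity(p, paste0(s, s)), 2 * region_affinity(p, s) - 1e-9)
  # shorter than the motif: affinity 0 with a warning, not an error
  expect_warning(a <- region_affinity(p, "ACG"), "shorter")
  expect_equal(a, 0)
})

test_that("region_affinity is strand symmetric", {
  set.seed(6)
  counts <- random_pwm_counts(7)
  p <- pwm("T", counts)
  for (rep in 1:5) {
    s <- random_dna_string(120)
    expect_equal(region_affinity(p, s), region_affinity(p, oracle_revcomp(s)),
                 tolerance = 1e-9)
  }
})

make_toy_landscape <- function(seed = 7) {
  set.seed(seed)
  genome <- Biostrings::DNAStringSet(c(chr1 = random_dna_string(20000),
                                       chr2 = random_dna_string(8000)))
  genes <- data.frame(
    gene_id = c("gA", "gB", "gC"), chrom = c("chr1", "chr1", "chr2"),
    start = c(2000L, 9000L, 1000L), end = c(4000L, 12000L, 3000L),
    strand = c("+", "-", "+"), stringsAsFactors = FALSE)
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  peaks <- data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    start = c(1500L, 5000L, 13000L, 500L),
    end = c(1900L, 5400L, 13400L, 900L),
    name = paste0("p", 1:4), stringsAsFactors = FALSE)
  pwms <- list(pwm("T1", random_pwm_counts(6)), pwm("T2", random_pwm_counts(8)))
  list(genome = genome, genes = genes, peaks = peaks, pwms = pwms)
}

test_that("gene_scores composes region affinities per TSS window", {
  toy <- make_toy_landscape()
  A <- gene_scores(toy$peaks, toy$genes, toy$pwms, toy$genome, window = 5000)
  seqs <- extract_sequences(toy$peaks, toy$genome)
  counts_list <- list(T1 = toy$pwms[[1]]$counts, T2 = toy$pwms[[2]]$counts)
  A_oracle <- oracle_gene_scores(toy$peaks, seqs, toy$genes, counts_list, 5000)
  expect_equal(A, A_oracle, tolerance = 1e-9)
  # gA (TSS 2000) window [-3000, 7000) catches peaks 1-2; gB (minus strand,
  # TSS 11999) window [6999, 16999) catches peak 3 only
  r2 <- vapply(toy$pwms, function(p) region_affinity(p, seqs[2]), numeric(1))
  r3 <- vapply(toy$pwms, function(p) region_affinity(p, seqs[3]), numeric(1))
  expect_true(all(A[, "gA"] >= r2 - 1e-9))
  expect_equal(unname(A[, "gB"]), unname(r3), tolerance = 1e-9)
  # widening the window to 8000 pulls peak 2 into gB's score as well:
  # one peak then counts fully for both genes
  A8 <- gene_scores(toy$peaks, toy$genes, toy$pwms, toy$genome, window = 8000)
  expect_equal(unname(A8[, "gB"]), unname(r2 + r3), tolerance = 1e-9)
  expect_true(all(A8[, "gA"] >= r2 - 1e-9))
  # no peak within a 100 bp window around gC's TSS
  A0 <- gene_scores(toy$peaks[3, ], toy$genes, toy$pwms, toy$genome,
                    window = 100)
  expect_equal(unname(A0[, "gC"]), c(0, 0))
})

test_that("gene_scores is invariant to peak order and errors on bad chrom", {
  toy <- make_toy_landscape()
  A1 <- gene_scores(toy$peaks, toy$genes, toy$pwms, toy$genome, window = 5000)
  A2 <- gene_scores(toy$peaks[4:1, ], toy$genes, toy$pwms, toy$genome,
                    window = 5000)
  expect_equal(A1, A2, tolerance = 1e-12)
  bad_genes <- toy$genes
  bad_genes$chrom[2] <- "chrX"
  expect_error(gene_scores(toy$peaks, bad_genes, toy$pwms, toy$genome),
               "chrX")
})

test_that("a planted consensus site strictly increases the gene score", {
  toy <- make_toy_landscape()
  p1 <- toy$pwms[[1]]
  A_before <- gene_scores(toy$peaks, toy$genes, toy$pwms, toy$genome,
                          window = 5000)
  genome2 <- toy$genome
  cons <- pwm_consensus(p1)
  genome2[["chr1"]] <- Biostrings::replaceAt(
    genome2[["chr1"]], IRanges::IRanges(5100, 5099 + nchar(cons)), cons)
  A_after <- gene_scores(toy$peaks, toy$genes, toy$pwms, genome2,
                         window = 5000)
  expect_gt(A_after["T1", "gA"], A_before["T1", "gA"])
  # the edited peak lies outside gB's window, whose score must not move
  expect_equal(A_after["T1", "gB"], A_before["T1", "gB"], tolerance = 1e-12)
})

test_that("affinity_quotient algebra: zero, doubling, antisymmetry", {
  set.seed(8)
  A <- matrix(stats::runif(12, 1, 5), 3, 4,
              dimnames = list(paste0("t", 1:3), paste0("g", 1:4)))
  expect_equal(affinity_quotient(A, A), 0 * A)
  expect_equal(affinity_quotient(2 * A, A), 0 * A + 1, tolerance = 1e-4)
  expect_equal(affinity_quotient(A, 2 * A), -affinity_quotient(2 * A, A),
               tolerance = 1e-12)
  Z <- 0 * A
  expect_equal(affinity_quotient(Z, Z), Z)  # eps/eps = 1, log2 = 0 exactly
  B <- A
  colnames(B) <- paste0("h", 1:4)
  expect_error(affinity_quotient(A, B), "mismatch")
})

test_that("expressed-TF filter drops low-baseMean TFs", {
  pwms <- list(pwm("AAA", random_pwm_counts(4, seed = 9)),
               pwm("BBB", random_pwm_counts(4)),
               pwm("CCC", random_pwm_counts(4)))
  bm <- c(AAA = 50, BBB = 9.99, ccc = 10)  # name matching is case-insensitive
  kept <- suppressMessages(filter_expressed_tfs(pwms, bm))
  expect_equal(vapply(kept, function(p) p$name, character(1)), c("AAA", "CCC"))
})
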