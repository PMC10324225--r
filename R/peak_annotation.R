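#' @title Differential peak annotation
#' @description Splits differential open-chromatin peaks by the sign of their
#'   log fold change (treatment over control), annotates each peak to a
#'   genomic context (promoter / gene body / intergenic, with promoter taking
#'   precedence), summarizes context proportions per sign class, and assigns
#'   chromatin domains to their closest gene within a distance window.
#' @name peak_annotation
NULL

#' Partition peaks by log fold change sign
#'
#' @param peaks data.frame with a `logFC` column (treatment over control).
#' @return list with data.frames `up` (logFC > 0), `down` (logFC < 0) and the
#'   integer `zero` count of excluded logFC == 0 peaks.
#' @export
split_by_sign <- function(peaks) {
  if (!"logFC" %in% names(peaks)) stop("peaks need a logFC column")
  bad <- which(!is.finite(peaks$logFC))
  if (length(bad)) {
    stop("non-finite logFC for peak(s): ",
         paste(utils::head(if (!is.null(peaks$name)) peaks$name[bad] else bad, 10),
               collapse = ", "))
  }
  up <- peaks[peaks$logFC > 0, , drop = FALSE]
  down <- peaks[peaks$logFC < 0, , drop = FALSE]
  zero <- sum(peaks$logFC == 0)
  message("split_by_sign: ", nrow(up), " up, ", nrow(down), " down, ",
          zero, " zero-logFC excluded")
  list(up = up, down = down, zero = zero)
}

#' Annotate peaks to promoter / gene body / intergenic context
#'
#' The promoter is the strand-oriented window \[TSS - promoter_up,
#' TSS + promoter_down) of each gene. Labels are exclusive with precedence
#' promoter > gene_body > intergenic: a peak overlapping any promoter is
#' "promoter"; otherwise a peak overlapping any gene body is "gene_body";
#' otherwise "intergenic".
#'
#' @param peaks interval data.frame (0-based half-open).
#' @param genes gene annotation (see [read_genes()]).
#' @param promoter_up bp upstream of the TSS (default 1000).
#' @param promoter_down bp downstream of the TSS (default 500).
#' @return `peaks` with a `context` factor column added.
#' @export
annotate_context <- function(peaks, genes, promoter_up = 1000,
                             promoter_down = 500) {
  if (nrow(peaks) == 0L) {
    peaks$context <- factor(character(),
                            levels = c("promoter", "gene_body", "intergenic"))
    return(peaks)
  }
  tss_gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$tss + 1L, width = 1L),
    strand = genes$strand
  )
  prom_gr <- suppressWarnings(
    GenomicRanges::promoters(tss_gr, upstream = promoter_up,
                             downstream = promoter_down)
  )
  prom_gr <- GenomicRanges::trim(prom_gr)
  body_gr <- as_granges0(genes)
  pk_gr <- as_granges0(peaks)
  in_prom <- IRanges::overlapsAny(pk_gr, prom_gr, ignore.strand = TRUE)
  in_body <- IRanges::overlapsAny(pk_gr, body_gr, ignore.strand = TRUE)
  ctx <- ifelse(in_prom, "promoter", ifelse(in_body, "gene_body", "intergenic"))
  peaks$context <- factor(ctx, levels = c("promoter", "gene_body", "intergenic"))
  peaks
}

#' Context percentages per sign class
#'
#' @param peaks annotated peaks (see [annotate_context()]) carrying `logFC`.
#' @return data.frame with one row per sign class and percentage columns
#'   promoter / gene_body / intergenic summing to 100 per row.
#' @export
context_summary <- function(peaks) {
  split <- split_by_sign(peaks)
  one <- function(df, label) {
    if (nrow(df) == 0L) {
      return(data.frame(sign_class = label, promoter = NA_real_,
                        gene_body = NA_real_, intergenic = NA_real_))
    }
    tab <- table(df$context)
    pct <- 100 * as.numeric(tab) / nrow(df)
    data.frame(sign_class = label, promoter = pct[1], gene_body = pct[2],
               intergenic = pct[3])
  }
  rbind(one(split$up, "up"), one(split$down, "down"))
}

#' Assign chromatin domains to their closest gene
#'
#' Each domain is assigned the single closest gene by minimal interval
#' distance (overlap = distance 0), reported only when the distance is at
#' most `window` bp. Ties on interval distance are broken by smaller distance
#' to the gene's TSS, then lexicographic gene id.
#'
#' @param domains interval data.frame (0-based half-open), e.g. differential
#'   chromatin domains from an external segmentation run.
#' @param genes gene annotation.
#' @param window maximum assignment distance in bp (default 50000).
#' @return data.frame with domain name/coords, assigned gene_id (NA when no
#'   gene within `window`) and the distance.
#' @export
domains_to_genes <- function(domains, genes, window = 50000) {
  if (nrow(domains) == 0L) {
    return(data.frame(domain = character(), chrom = character(),
                      start = integer(), end = integer(),
                      gene_id = character(), distance = numeric()))
  }
  dom_gr <- as_granges0(domains)
  gene_gr <- as_granges0(genes)
  nm <- if (!is.null(domains$name)) domains$name else as.character(seq_len(nrow(domains)))
  out <- data.frame(domain = nm, chrom = domains$chrom,
                    start = domains$start, end = domains$end,
                    gene_id = NA_character_, distance = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(domains))) {
    d <- suppressWarnings(
      GenomicRanges::distance(dom_gr[i], gene_gr, ignore.strand = TRUE)
    )
    d[is.na(d)] <- Inf  # different chromosome
    dmin <- min(d)
    if (!is.finite(dmin) || dmin > window) next
    cand <- which(d == dmin)
    if (length(cand) > 1L) {
      mid <- (domains$start[i] + domains$end[i]) / 2
      tss_d <- abs(genes$tss[cand] - mid)
      cand <- cand[order(tss_d, genes$gene_id[cand])]
    }
    out$gene_id[i] <- genes$gene_id[cand[1]]
    out$distance[i] <- dmin
  }
  out
}
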