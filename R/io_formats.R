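#' @title File formats and validation
#' @description Readers and writers for every external format the pipeline
#'   touches: FASTA genomes, BED6 intervals (0-based half-open), JASPAR-style
#'   position frequency matrices, header-carrying TSV tables, YAML configs and
#'   JSON ground-truth files. All coordinate I/O is 0-based half-open
#'   internally; parsers never silently drop records.
#' @name io_formats
NULL

#' Read a JASPAR-format position frequency matrix file
#'
#' Parses the JASPAR 2016 text dialect: a header line starting with `>`
#' (identifier and optional name), followed by four rows labelled
#' `A`, `C`, `G`, `T`, each carrying the same number of nonnegative counts,
#' optionally wrapped in square brackets. Counts are converted to
#' column-stochastic frequency matrices after adding `pseudo` to every cell
#' (this keeps downstream log-odds finite).
#'
#' @param path path to a JASPAR PFM text file.
#' @param pseudo pseudo-count added to every cell before normalization.
#' @return a list of [pwm()] objects, in file order.
#' @seealso [pwm()] for the in-memory motif representation.
#' @export
read_pfm <- function(path, pseudo = 1) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty PFM file: ", path)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop("no '>' motif header found in ", path)
  out <- vector("list", length(hdr))
  bounds <- c(hdr, length(lines) + 1L)
  for (k in seq_along(hdr)) {
    block <- lines[(bounds[k] + 1L):(bounds[k + 1L] - 1L)]
    if (length(block) != 4L) {
      stop("motif block at line ", hdr[k], " has ", length(block),
           " matrix rows; expected 4 (A/C/G/T)")
    }
    name <- sub("^>\\s*", "", lines[hdr[k]])
    name <- strsplit(trimws(name), "\\s+")[[1]]
    name <- name[length(name)]  # JASPAR headers are "ID NAME"; keep the name
    rows <- lapply(seq_along(block), function(i) {
      ln <- block[i]
      body <- sub("^\\s*[ACGTacgt]?\\s*\\[?", "", ln)
      body <- sub("\\]\\s*$", "", body)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(body), "\\s+")[[1]]))
      if (anyNA(vals)) {
        stop("unparseable counts at line ", hdr[k] + i, " of ", path)
      }
      vals
    })
    w <- unique(lengths(rows))
    if (length(w) != 1L) {
      stop("ragged matrix rows for motif '", name, "' starting at line ",
           hdr[k], " (widths ", paste(lengths(rows), collapse = "/"), ")")
    }
    counts <- do.call(rbind, rows)
    rownames(counts) <- c("A", "C", "G", "T")
    if (any(counts < 0)) {
      stop("negative count in motif '", name, "' at line ", hdr[k])
    }
    if (any(colSums(counts) == 0) && pseudo == 0) {
      stop("zero column sum in motif '", name, "' at line ", hdr[k])
    }
    out[[k]] <- pwm(name = name, counts = counts, pseudo = pseudo)
  }
  out
}

#' Write motifs in JASPAR text format
#'
#' @param pwms list of [pwm()] objects or raw 4 x W count matrices with
#'   rownames A/C/G/T.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_pfm <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    counts <- if (inherits(p, "pwm")) p$counts else p
    nm <- if (inherits(p, "pwm")) p$name else "motif"
    writeLines(paste0(">", nm, " ", nm), con)
    for (b in c("A", "C", "G", "T")) {
      writeLines(sprintf("%s  [ %s ]", b,
                         paste(format(counts[b, ], trim = TRUE), collapse = " ")),
                 con)
    }
  }
  invisible(path)
}

#' Read a BED file into an interval data frame
#'
#' Accepts BED3 through BED6. Coordinates stay 0-based half-open. Lines where
#' start >= end raise a validation error naming the offending line; comment
#' and track lines are skipped (and counted in a message).
#'
#' @param path BED file path.
#' @return data.frame with columns chrom, start, end, name, score, strand
#'   (missing BED columns filled with ".", 0, "*").
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  n_skipped <- sum(!keep)
  if (n_skipped > 0) message("read_bed: skipped ", n_skipped, " non-record lines")
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), score = numeric(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("BED line ", lineno[which(nf < 3L)[1]], " has fewer than 3 fields")
  }
  get <- function(i, default) {
    vapply(fields, function(f) if (length(f) >= i) f[i] else default, character(1))
  }
  df <- data.frame(
    chrom = get(1L, "."),
    start = suppressWarnings(as.integer(get(2L, NA_character_))),
    end = suppressWarnings(as.integer(get(3L, NA_character_))),
    name = get(4L, "."),
    score = suppressWarnings(as.numeric(get(5L, "0"))),
    strand = get(6L, "*"),
    stringsAsFactors = FALSE
  )
  bad <- which(is.na(df$start) | is.na(df$end))
  if (length(bad)) stop("non-numeric coordinates at BED line ", lineno[bad[1]])
  bad <- which(df$start >= df$end)
  if (length(bad)) {
    stop("invalid interval (start >= end) at BED line ", lineno[bad[1]],
         ": ", lines[bad[1]])
  }
  df
}

#' Write an interval data frame as BED6
#'
#' @param intervals data.frame with at least chrom/start/end; name, score,
#'   strand are filled with defaults when absent.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (any(intervals$start >= intervals$end)) {
    stop("invalid interval (start >= end) in row ",
         which(intervals$start >= intervals$end)[1])
  }
  df <- data.frame(
    chrom = intervals$chrom,
    start = as.integer(intervals$start),
    end = as.integer(intervals$end),
    name = if ("name" %in% names(intervals)) intervals$name else ".",
    score = if ("score" %in% names(intervals)) intervals$score else 0,
    strand = if ("strand" %in% names(intervals)) intervals$strand else "*",
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a TSV table and validate its schema
#'
#' Tables carry a header row; column order is not significant, names are.
#'
#' @param path TSV path.
#' @param schema character vector of required column names (NULL = no check).
#' @return data.frame.
#' @export
read_table <- function(path, schema = NULL) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(schema)) {
    missing <- setdiff(schema, names(df))
    if (length(missing)) {
      stop("table ", path, " is missing required column(s): ",
           paste(missing, collapse = ", "))
    }
  }
  df
}

#' Write a data frame as a TSV table with header
#' @param df data.frame.
#' @param path output path.
#' @param row_names write row names as a leading column named by `row_names`
#'   (NULL = drop them).
#' @return invisibly, `path`.
#' @export
write_table <- function(df, path, row_names = NULL) {
  if (!is.null(row_names)) {
    df <- data.frame(setNames(list(rownames(df)), row_names), df,
                     check.names = FALSE, stringsAsFactors = FALSE)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a genome FASTA
#' @param path FASTA path.
#' @return a [Biostrings::DNAStringSet].
#' @export
read_genome <- function(path) Biostrings::readDNAStringSet(path)

#' @rdname read_genome
#' @param genome DNAStringSet (or named character vector of sequences).
#' @export
write_genome <- function(genome, path) {
  if (!inherits(genome, "DNAStringSet")) {
    genome <- Biostrings::DNAStringSet(genome)
  }
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read a gene annotation BED with strand-aware TSS
#'
#' A BED6 file where the name column is the gene identifier. The TSS is the
#' start for + genes and end - 1 for - genes (0-based).
#'
#' @param path BED6 path.
#' @return data.frame with gene_id, chrom, start, end, strand, tss.
#' @export
read_genes <- function(path) {
  bed <- read_bed(path)
  if (any(!bed$strand %in% c("+", "-"))) {
    stop("gene annotation requires strand '+' or '-' for every record")
  }
  as_gene_annotation(bed)
}

#' Attach a strand-aware TSS to a BED-like gene table
#' @param bed data.frame with chrom/start/end/name/strand.
#' @return gene annotation data.frame (gene_id, chrom, start, end, strand, tss).
#' @export
as_gene_annotation <- function(bed) {
  data.frame(
    gene_id = bed$name, chrom = bed$chrom,
    start = bed$start, end = bed$end, strand = bed$strand,
    tss = ifelse(bed$strand == "+", bed$start, bed$end - 1L),
    stringsAsFactors = FALSE
  )
}

#' Read a YAML run configuration
#'
#' Config keys mirror CLI flags, one namespace per module; on conflict a CLI
#' flag wins over the file value.
#'
#' @param path YAML file.
#' @param overrides named list of CLI-level overrides (flat `module.key` names
#'   or nested lists).
#' @return nested named list.
#' @export
read_config <- function(path, overrides = list()) {
  cfg <- yaml::read_yaml(path)
  for (nm in names(overrides)) {
    keys <- strsplit(nm, ".", fixed = TRUE)[[1]]
    cfg <- modify_nested(cfg, keys, overrides[[nm]])
  }
  cfg
}

modify_nested <- function(x, keys, value) {
  if (length(keys) == 1L) {
    x[[keys]] <- value
    return(x)
  }
  x[[keys[1]]] <- modify_nested(
    if (is.null(x[[keys[1]]])) list() else x[[keys[1]]],
    keys[-1], value)
  x
}

# internal: intervals data.frame (0-based half-open) -> GRanges (1-based)
as_granges0 <- function(df, strand_col = NULL) {
  strand <- if (!is.null(strand_col) && strand_col %in% names(df)) {
    s <- df[[strand_col]]
    s[!s %in% c("+", "-")] <- "*"
    s
  } else "*"
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand
  )
}
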