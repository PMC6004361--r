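# Plain-text interchange: TSV tables, paired FASTQ, BED/GFF3 features.

#' Write / read paired FASTQ
#'
#' Reads are written with a constant Q30 quality placeholder; the
#' simulator models substitution error directly rather than per-base
#' qualities.
#'
#' @param read1,read2 character vectors of sequences.
#' @param path1,path2 output FASTQ paths (".gz" suffix gzips).
#' @param ids read names (without the /1 /2 mate suffix).
#' @return invisibly, the two paths.
#' @export
write_fastq_pairs <- function(read1, read2, path1, path2,
                              ids = sprintf("read%06d", seq_along(read1))) {
  stopifnot(length(read1) == length(read2))
  write_one <- function(seqs, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    qual <- Biostrings::BStringSet(
      vapply(nchar(seqs), function(l) strrep("?", l), character(1))
    )
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual,
                                compress = grepl("\\.gz$", path))
  }
  write_one(read1, path1)
  write_one(read2, path2)
  invisible(c(path1, path2))
}

#' @rdname write_fastq_pairs
#' @param path1,path2 FASTQ paths to read.
#' @return for the reader: data frame with `pair_id`, `read1`, `read2`;
#'   errors if the two files are desynchronised (ids or counts differ).
#' @export
read_fastq_pairs <- function(path1, path2) {
  r1 <- Biostrings::readDNAStringSet(path1, format = "fastq")
  r2 <- Biostrings::readDNAStringSet(path2, format = "fastq")
  strip <- function(x) sub("[/ ].*$", "", sub("/[12]$", "", names(x)))
  if (length(r1) != length(r2) || !identical(strip(r1), strip(r2))) {
    stopf("desynchronised FASTQ pair: read ids or counts differ")
  }
  data.frame(
    pair_id = strip(r1),
    read1 = as.character(r1),
    read2 = as.character(r2),
    stringsAsFactors = FALSE
  )
}

#' Read and write tab-separated tables
#'
#' Thin wrappers fixing the conventions used throughout the package
#' (header, no quoting, tab separation, missing values as NA).
#'
#' @param x data frame to write.
#' @param path file path.
#' @return `read_tsv_table()` returns a data frame.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write / read a genotype dosage matrix
#'
#' Individuals in rows, sites in columns, alt-allele dosages 0/1/2 with NA
#' for missing calls.
#'
#' @param geno integer matrix of dosages.
#' @param path TSV path.
#' @return the matrix, for the reader.
#' @export
write_genotype_matrix <- function(geno, path) {
  df <- data.frame(individual_id = rownames(geno), geno, check.names = FALSE)
  write_tsv_table(df, path)
}

#' @rdname write_genotype_matrix
#' @export
read_genotype_matrix <- function(path) {
  df <- read_tsv_table(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$individual_id
  storage.mode(m) <- "integer"
  m
}

#' Minimal VCF-like genotype export
#'
#' One line per target SNP with CHROM = amplicon id, POS = SNP offset and a
#' GT field per sample (0/0, 0/1, 1/1 or ./.).
#'
#' @param geno dosage matrix (individuals x sites).
#' @param targets an [make_amplicon_targets()] table matching the columns.
#' @param path output path.
#' @export
write_genotype_vcf <- function(geno, targets, path) {
  idx <- match(colnames(geno), targets$amplicon_id)
  if (any(is.na(idx))) stopf("targets table does not cover all matrix sites")
  gt_code <- c("0/0", "0/1", "1/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(geno)), collapse = "\t")
  )
  for (j in seq_len(ncol(geno))) {
    t <- idx[j]
    gt <- ifelse(is.na(geno[, j]), "./.", gt_code[geno[, j] + 1L])
    lines <- c(lines, paste(c(
      targets$amplicon_id[t], targets$snp_offset[t], colnames(geno)[j],
      targets$ref[t], targets$alt[t], ".", "PASS", ".", "GT", gt
    ), collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read gene features from BED or GFF3
#'
#' BED input (0-based half-open) is converted to 1-based inclusive
#' coordinates; the BED name field is expected as `gene_id|feature_kind`.
#' GFF3 input takes the feature kind from the type column and the gene id
#' from the `gene_id`, `ID` or `Parent` attribute.
#'
#' @param path annotation file path.
#' @param format `"bed"` or `"gff3"` (guessed from the extension by
#'   default).
#' @return data frame with `gene_id`, `contig`, `start`, `end`,
#'   `feature_kind`, `strand` as used by [annotate_candidates()].
#' @export
read_gene_features <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed(\\.gz)?$", path)) "bed" else "gff3"
  }
  gr <- rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3")
  df <- as.data.frame(gr)
  if (format == "bed") {
    parts <- strsplit(as.character(df$name), "|", fixed = TRUE)
    gene_id <- vapply(parts, `[`, character(1), 1)
    kind <- vapply(parts, function(p) if (length(p) > 1) p[2] else "other",
                   character(1))
  } else {
    gene_id <- if (!is.null(df$gene_id)) {
      as.character(df$gene_id)
    } else if (!is.null(df$ID)) {
      as.character(df$ID)
    } else {
      as.character(df$Parent)
    }
    kind <- as.character(df$type)
  }
  kind[!kind %in% c("exon", "promoter")] <- "other"
  data.frame(
    gene_id = gene_id,
    contig = as.character(df$seqnames),
    start = df$start,
    end = df$end,
    feature_kind = kind,
    strand = as.character(df$strand),
    stringsAsFactors = FALSE
  )
}
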