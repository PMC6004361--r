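# Pool-seq Fst scan from per-site allele counts of two DNA bulks.
#
# The statistic is the nucleotide-diversity (expected heterozygosity) based
# fixation index computed per SNP:
#   Pi        = 1 - fA^2 - fC^2 - fG^2 - fT^2
#   Pi_within = (Pi_pool1 + Pi_pool2) / 2
#   Pi_total  = Pi of the combined allele-frequency vector
#   Fst       = (Pi_total - Pi_within) / Pi_total
# Monomorphic sites (Pi_total = 0) have undefined Fst and are excluded.

#' Per-site nucleotide frequencies from pool read counts
#'
#' @param counts numeric vector (or 4-column matrix, columns A, C, G, T) of
#'   read counts per nucleotide.
#' @return frequency vector (or matrix) summing to 1 per site; all-NA where
#'   total depth is zero (undefined site).
#' @export
allele_frequencies <- function(counts) {
  if (is.matrix(counts)) {
    depth <- rowSums(counts)
    f <- counts / ifelse(depth > 0, depth, NA_real_)
    return(f)
  }
  stopifnot(length(counts) == 4L, all(counts >= 0))
  depth <- sum(counts)
  if (depth == 0) {
    return(rep(NA_real_, 4L))
  }
  counts / depth
}

#' Per-site nucleotide diversity
#'
#' `Pi = 1 - sum(f^2)` over the four nucleotide frequencies; the expected
#' heterozygosity of the site, bounded by 0.75 (all four bases equifrequent).
#'
#' @param freqs numeric vector of four frequencies summing to 1 (or a
#'   4-column matrix of per-site frequencies).
#' @return Pi in \[0, 0.75\].
#' @export
site_pi <- function(freqs) {
  if (is.matrix(freqs)) {
    return(1 - rowSums(freqs^2))
  }
  stopifnot(abs(sum(freqs) - 1) < 1e-8)
  1 - sum(freqs^2)
}

#' Fst between two pools at one site
#'
#' @param counts1,counts2 read counts per nucleotide (A, C, G, T) in each pool.
#' @param weighted if `TRUE`, the combined frequency vector for `Pi_total`
#'   weights each pool by its read depth; the default is the unweighted mean
#'   of the two pools' frequency vectors (equal-sized bulks).
#' @return a one-row data frame with `pi_pool1`, `pi_pool2`, `pi_within`,
#'   `pi_total`, `fst` (NA where `pi_total` is 0), `depth1`, `depth2`.
#' @export
site_fst <- function(counts1, counts2, weighted = FALSE) {
  d1 <- sum(counts1)
  d2 <- sum(counts2)
  if (d1 == 0 || d2 == 0) {
    stopf("site_fst: both pools need depth > 0 (got %d and %d)", d1, d2)
  }
  f1 <- counts1 / d1
  f2 <- counts2 / d2
  ftot <- if (weighted) (counts1 + counts2) / (d1 + d2) else (f1 + f2) / 2
  pi1 <- 1 - sum(f1^2)
  pi2 <- 1 - sum(f2^2)
  pi_within <- (pi1 + pi2) / 2
  pi_total <- 1 - sum(ftot^2)
  fst <- if (pi_total > 0) (pi_total - pi_within) / pi_total else NA_real_
  data.frame(
    pi_pool1 = pi1, pi_pool2 = pi2, pi_within = pi_within,
    pi_total = pi_total, fst = fst, depth1 = d1, depth2 = d2
  )
}

.count_matrix <- function(pool) {
  need <- c("nA", "nC", "nG", "nT")
  if (!all(need %in% names(pool))) {
    stopf("pool counts need columns %s", paste(need, collapse = ", "))
  }
  m <- as.matrix(pool[, need])
  colnames(m) <- BASES
  storage.mode(m) <- "double"
  if (any(m < 0)) stopf("negative read counts")
  m
}

#' Fst table for all shared sites of two pools
#'
#' Computes the per-site diversity decomposition for every site present in
#' both pool tables, without applying any filter. Sites present in only one
#' table are dropped with a warning.
#'
#' @param pool1,pool2 data frames with columns `site_id`, `contig`, `pos`,
#'   `nA`, `nC`, `nG`, `nT` (one row per site).
#' @inheritParams site_fst
#' @return data frame with site metadata, per-pool Pi, `pi_within`,
#'   `pi_total`, `fst` and depths, in `pool1` site order.
#' @export
fst_table <- function(pool1, pool2, weighted = FALSE) {
  shared <- intersect(pool1$site_id, pool2$site_id)
  if (length(shared) == 0L) stopf("the two pools share no sites")
  dropped <- length(union(pool1$site_id, pool2$site_id)) - length(shared)
  if (dropped > 0) {
    warnf("dropping %d site(s) present in only one pool", dropped)
  }
  p1 <- pool1[match(shared, pool1$site_id), , drop = FALSE]
  p2 <- pool2[match(shared, pool2$site_id), , drop = FALSE]
  c1 <- .count_matrix(p1)
  c2 <- .count_matrix(p2)
  d1 <- rowSums(c1)
  d2 <- rowSums(c2)
  ok <- d1 > 0 & d2 > 0
  f1 <- c1 / ifelse(d1 > 0, d1, NA_real_)
  f2 <- c2 / ifelse(d2 > 0, d2, NA_real_)
  ftot <- if (weighted) {
    (c1 + c2) / ifelse(d1 + d2 > 0, d1 + d2, NA_real_)
  } else {
    (f1 + f2) / 2
  }
  pi1 <- 1 - rowSums(f1^2)
  pi2 <- 1 - rowSums(f2^2)
  pi_within <- (pi1 + pi2) / 2
  pi_total <- 1 - rowSums(ftot^2)
  fst <- ifelse(ok & pi_total > 0, (pi_total - pi_within) / pi_total, NA_real_)
  out <- data.frame(
    site_id = shared,
    contig = p1$contig,
    pos = p1$pos,
    pi_pool1 = pi1, pi_pool2 = pi2,
    pi_within = pi_within, pi_total = pi_total, fst = fst,
    depth1 = d1, depth2 = d2,
    stringsAsFactors = FALSE
  )
  attr(out, "skipped_zero_depth") <- sum(!ok)
  out
}

#' Fst scan with read-support, Fst and coverage filters
#'
#' Retains sites where every reported allele (non-zero count) is supported by
#' at least `min_allele_reads` reads in each pool where it appears, the site
#' is polymorphic across the pools, `fst > min_fst`, and read depth exceeds
#' `min_coverage` in both pools. Results are sorted by descending Fst, ties
#' broken by (contig, position).
#'
#' @inheritParams fst_table
#' @param min_allele_reads minimum supporting reads for any called allele.
#' @param min_fst retain sites with Fst strictly above this value.
#' @param min_coverage required depth (strictly above) in both pools.
#' @return filtered, sorted data frame as in [fst_table()].
#' @export
fst_scan <- function(pool1, pool2, min_allele_reads = 4, min_fst = 0.5,
                     min_coverage = 20, weighted = FALSE) {
  tab <- fst_table(pool1, pool2, weighted = weighted)
  p1 <- pool1[match(tab$site_id, pool1$site_id), , drop = FALSE]
  p2 <- pool2[match(tab$site_id, pool2$site_id), , drop = FALSE]
  c1 <- .count_matrix(p1)
  c2 <- .count_matrix(p2)
  support_ok <- rowSums(c1 > 0 & c1 < min_allele_reads) == 0 &
    rowSums(c2 > 0 & c2 < min_allele_reads) == 0
  n_alleles <- rowSums((c1 + c2) > 0)
  keep <- !is.na(tab$fst) &
    tab$fst > min_fst &
    tab$depth1 > min_coverage &
    tab$depth2 > min_coverage &
    support_ok &
    n_alleles >= 2
  out <- tab[keep, , drop = FALSE]
  out <- out[order(-out$fst, out$contig, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map Fst hits to exon/promoter gene features
#'
#' A site is a candidate if its position overlaps (1-based, inclusive) an
#' `exon` or `promoter` feature; a site maps to every such feature it
#' overlaps, and sites with no exon/promoter overlap are excluded. SNP
#' positions are strandless, so feature strand is ignored.
#'
#' @param hits data frame of scan hits with `site_id`, `contig`, `pos`
#'   (e.g. from [fst_scan()]).
#' @param features data frame with `gene_id`, `contig`, `start`, `end`
#'   (1-based inclusive), `feature_kind` (`exon`, `promoter` or `other`).
#' @return list with `sites` (one row per site x overlapping feature:
#'   `site_id`, `contig`, `pos`, `fst` if present, `gene_id`,
#'   `feature_kind`) and `genes` (unique candidate genes with their SNP
#'   count).
#' @export
annotate_candidates <- function(hits, features) {
  bad <- which(features$start > features$end)
  if (length(bad) > 0) {
    stopf(
      "malformed interval (start > end) for feature(s): %s",
      paste(features$gene_id[bad], collapse = ", ")
    )
  }
  sel <- features$feature_kind %in% c("exon", "promoter")
  feat <- features[sel, , drop = FALSE]
  empty_sites <- data.frame(
    site_id = character(0), contig = character(0), pos = integer(0),
    gene_id = character(0), feature_kind = character(0),
    stringsAsFactors = FALSE
  )
  if (nrow(hits) == 0L || nrow(feat) == 0L) {
    return(list(sites = empty_sites, genes = data.frame(
      gene_id = character(0), n_snps = integer(0), stringsAsFactors = FALSE
    )))
  }
  site_gr <- GenomicRanges::GRanges(
    seqnames = hits$contig,
    ranges = IRanges::IRanges(start = hits$pos, width = 1L)
  )
  feat_gr <- GenomicRanges::GRanges(
    seqnames = feat$contig,
    ranges = IRanges::IRanges(start = feat$start, end = feat$end)
  )
  ov <- GenomicRanges::findOverlaps(site_gr, feat_gr, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(ov)
  si <- S4Vectors::subjectHits(ov)
  sites <- data.frame(
    site_id = hits$site_id[qi],
    contig = hits$contig[qi],
    pos = hits$pos[qi],
    gene_id = feat$gene_id[si],
    feature_kind = feat$feature_kind[si],
    stringsAsFactors = FALSE
  )
  if ("fst" %in% names(hits)) sites$fst <- hits$fst[qi]
  genes <- as.data.frame(table(gene_id = sites$gene_id[!duplicated(
    paste(sites$site_id, sites$gene_id)
  )]), stringsAsFactors = FALSE)
  names(genes) <- c("gene_id", "n_snps")
  genes <- genes[order(genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL
  list(sites = sites, genes = genes)
}
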