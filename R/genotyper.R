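# Amplicon allele pileup and diploid genotype calling.
#
# Demultiplexed reads are anchored to their amplicon by an exact match of
# the primer-landing region that follows the sample barcode (amplicons are
# short known sequences, so a full aligner is unnecessary); the base at
# each target SNP offset is tallied once per read pair, and diploid
# genotypes are called from the allele fractions.

#' Validate an amplicon target table
#'
#' @param targets data frame with `amplicon_id`, `sequence`, `snp_offset`
#'   (1-based), `ref`, `alt`.
#' @param primer_length anchor length at the amplicon 5' end.
#' @return the validated table (class `amplicon_targets`).
#' @export
amplicon_targets <- function(targets, primer_length = 20L) {
  need <- c("amplicon_id", "sequence", "snp_offset", "ref", "alt")
  if (!all(need %in% names(targets))) {
    stopf("targets need columns %s", paste(need, collapse = ", "))
  }
  if (any(nchar(targets$sequence) > 290)) {
    stopf("amplicon sequences must be at most 290 bases")
  }
  if (any(targets$snp_offset < 1 |
            targets$snp_offset > nchar(targets$sequence))) {
    stopf("snp_offset outside amplicon sequence")
  }
  at <- substr(targets$sequence, targets$snp_offset, targets$snp_offset)
  if (any(at != targets$ref)) {
    stopf("amplicon sequence must carry the ref allele at snp_offset")
  }
  if (is.null(attr(targets, "primer_length"))) {
    attr(targets, "primer_length") <- primer_length
  }
  if (!inherits(targets, "amplicon_targets")) {
    class(targets) <- c("amplicon_targets", "data.frame")
  }
  targets
}

# anchor read pairs to amplicons and extract the SNP base (one per pair);
# reads is a data frame with read1/read2 (read1 = F-read after demux)
.pair_snp_bases <- function(read1, read2, targets, barcode_length = 20L) {
  targets <- amplicon_targets(targets)
  plen <- attr(targets, "primer_length")
  fwd_primer <- substr(targets$sequence, 1L, plen)
  rev_primer <- substr(revcomp(targets$sequence), 1L, plen)
  read_len <- nchar(read1)
  insert_len <- read_len - barcode_length
  p1 <- substr(read1, barcode_length + 1L, barcode_length + plen)
  p2 <- substr(read2, barcode_length + 1L, barcode_length + plen)
  amp <- match(p1, fwd_primer)
  swapped <- is.na(amp)
  amp[swapped] <- match(p2[swapped], fwd_primer)
  fread <- ifelse(swapped, read2, read1)
  rread <- ifelse(swapped, read1, read2)
  # sanity: the mate should carry the reverse primer of the same amplicon
  ok <- !is.na(amp) &
    substr(rread, barcode_length + 1L, barcode_length + plen) ==
      rev_primer[ifelse(is.na(amp), 1L, amp)]
  base <- rep(NA_character_, length(read1))
  off <- targets$snp_offset[amp]
  len <- nchar(targets$sequence)[amp]
  # forward read covers the SNP?
  f_cov <- ok & off <= insert_len
  base[f_cov] <- substr(fread[f_cov], barcode_length + off[f_cov],
                        barcode_length + off[f_cov])
  # else the reverse read (position len - off + 1 of the revcomp)
  r_off <- len - off + 1L
  r_cov <- ok & !f_cov & r_off <= insert_len
  base[r_cov] <- complement_base(
    substr(rread[r_cov], barcode_length + r_off[r_cov],
           barcode_length + r_off[r_cov])
  )
  list(amplicon = targets$amplicon_id[amp], base = base,
       anchored = ok & !is.na(base))
}

#' Allele pileup for one sample's demultiplexed reads
#'
#' @param read1,read2 one sample's read pair sequences (read 1 carrying the
#'   F barcode).
#' @param targets an [amplicon_targets()] table.
#' @param barcode_length barcode prefix length to strip.
#' @return data frame with one row per amplicon: `amplicon_id`, `nA`,
#'   `nC`, `nG`, `nT`, `depth`; attribute `unanchored` counts dropped
#'   pairs.
#' @export
pileup_alleles <- function(read1, read2, targets, barcode_length = 20L) {
  targets <- amplicon_targets(targets)
  hit <- .pair_snp_bases(read1, read2, targets, barcode_length)
  keep <- hit$anchored
  tab <- table(
    factor(hit$amplicon[keep], levels = targets$amplicon_id),
    factor(hit$base[keep], levels = BASES)
  )
  out <- data.frame(
    amplicon_id = targets$amplicon_id,
    nA = as.integer(tab[, "A"]), nC = as.integer(tab[, "C"]),
    nG = as.integer(tab[, "G"]), nT = as.integer(tab[, "T"]),
    stringsAsFactors = FALSE
  )
  out$depth <- out$nA + out$nC + out$nG + out$nT
  attr(out, "unanchored") <- sum(!keep)
  out
}

#' Call a diploid genotype from allele counts
#'
#' Depth below `min_depth` gives a missing call; a top-allele fraction of
#' at least `hom_min` calls a homozygote; a second-allele fraction inside
#' `het_band` calls a heterozygote; anything else is missing (ambiguous).
#' Calls involving a base other than ref/alt are ambiguous.
#'
#' @param counts numeric vector of A/C/G/T read counts (named or in base
#'   order).
#' @param ref,alt target alleles.
#' @param min_depth minimum read depth for a call.
#' @param het_band allowed second-allele fraction range for heterozygotes.
#' @param hom_min minimum top-allele fraction for a homozygote.
#' @return list with `call` (`hom-ref`, `het`, `hom-alt`, `missing`),
#'   `dosage` (0/1/2 or NA), `reason`, `counts`, `depth`.
#' @export
call_genotype <- function(counts, ref, alt, min_depth = 10,
                          het_band = c(0.25, 0.75), hom_min = 0.9) {
  if (is.null(names(counts))) names(counts) <- BASES
  counts <- counts[BASES]
  depth <- sum(counts)
  res <- function(call, dosage, reason) {
    list(call = call, dosage = dosage, reason = reason,
         counts = counts, depth = depth)
  }
  if (depth < min_depth) return(res("missing", NA_integer_, "low-depth"))
  ord <- order(-counts, BASES) # deterministic tie-break by base order
  top <- BASES[ord[1]]
  second <- BASES[ord[2]]
  top_frac <- counts[[ord[1]]] / depth
  second_frac <- counts[[ord[2]]] / depth
  if (top_frac >= hom_min && top %in% c(ref, alt)) {
    if (top == ref) return(res("hom-ref", 0L, "called"))
    return(res("hom-alt", 2L, "called"))
  }
  if (second_frac >= het_band[1] && second_frac <= het_band[2] &&
      setequal(c(top, second), c(ref, alt))) {
    return(res("het", 1L, "called"))
  }
  res("missing", NA_integer_, "ambiguous")
}

#' Genotype all samples from demultiplexed reads
#'
#' Anchors every assigned read pair, tallies SNP bases per sample and
#' amplicon, and calls genotypes, producing a dosage matrix (individuals x
#' sites, site = amplicon id).
#'
#' @param assignments demultiplexed pairs (the `assignments` element of
#'   [demux()]): rows with `sample_id`, `read1`, `read2`; unassigned rows
#'   are ignored.
#' @param targets an [amplicon_targets()] table.
#' @param sample_ids row universe of the output matrix (defaults to the
#'   samples seen).
#' @inheritParams call_genotype
#' @param barcode_length barcode prefix length to strip.
#' @return integer dosage matrix with NA for missing calls; attribute
#'   `pileup` holds the per-sample/per-site counts.
#' @export
genotype_samples <- function(assignments, targets, sample_ids = NULL,
                             min_depth = 10, het_band = c(0.25, 0.75),
                             hom_min = 0.9, barcode_length = 20L) {
  targets <- amplicon_targets(targets)
  keep <- !is.na(assignments$sample_id)
  asg <- assignments[keep, , drop = FALSE]
  if (is.null(sample_ids)) sample_ids <- sort(unique(asg$sample_id))
  hit <- .pair_snp_bases(asg$read1, asg$read2, targets, barcode_length)
  ok <- hit$anchored
  counts <- table(
    sample = factor(asg$sample_id[ok], levels = sample_ids),
    amplicon = factor(hit$amplicon[ok], levels = targets$amplicon_id),
    base = factor(hit$base[ok], levels = BASES)
  )
  n <- length(sample_ids)
  m <- nrow(targets)
  geno <- matrix(NA_integer_, n, m,
                 dimnames = list(sample_ids, targets$amplicon_id))
  for (j in seq_len(m)) {
    cm <- matrix(counts[, j, ], ncol = 4L,
                 dimnames = list(NULL, BASES)) # n x 4, robust to n = 1
    geno[, j] <- .call_dosages(cm, targets$ref[j], targets$alt[j],
                               min_depth, het_band, hom_min)
  }
  attr(geno, "pileup") <- counts
  geno
}

# vectorised genotype calls for an n x 4 count matrix at one site
.call_dosages <- function(cm, ref, alt, min_depth, het_band, hom_min) {
  depth <- rowSums(cm)
  n <- nrow(cm)
  # top two alleles per row with deterministic base-order tie-break
  prio <- matrix(rep(seq_len(4L) * 1e-9, each = n), n, 4L)
  adj <- cm - prio
  top_i <- max.col(adj, ties.method = "first")
  adj2 <- adj
  adj2[cbind(seq_len(n), top_i)] <- -Inf
  sec_i <- max.col(adj2, ties.method = "first")
  top_c <- cm[cbind(seq_len(n), top_i)]
  sec_c <- cm[cbind(seq_len(n), sec_i)]
  top_b <- BASES[top_i]
  sec_b <- BASES[sec_i]
  top_f <- ifelse(depth > 0, top_c / depth, 0)
  sec_f <- ifelse(depth > 0, sec_c / depth, 0)
  dosage <- rep(NA_integer_, n)
  hom <- top_f >= hom_min & (top_b == ref | top_b == alt)
  dosage[hom & top_b == ref] <- 0L
  dosage[hom & top_b == alt] <- 2L
  het <- !hom & sec_f >= het_band[1] & sec_f <= het_band[2] &
    ((top_b == ref & sec_b == alt) | (top_b == alt & sec_b == ref))
  dosage[het] <- 1L
  dosage[depth < min_depth] <- NA_integer_
  dosage
}

#' Per-site minor allele frequency and call rate
#'
#' MAF is computed on allele counts (2 alleles per called individual);
#' call rate is the fraction of individuals with a non-missing call.
#'
#' @param geno dosage matrix (individuals x sites, NA = missing).
#' @return data frame with `site_id`, `maf`, `call_rate`, `n_called`.
#' @export
site_stats <- function(geno) {
  n <- nrow(geno)
  n_called <- colSums(!is.na(geno))
  p_alt <- colMeans(geno, na.rm = TRUE) / 2
  p_alt[n_called == 0] <- NA_real_
  maf <- pmin(p_alt, 1 - p_alt)
  data.frame(
    site_id = colnames(geno),
    maf = maf,
    call_rate = n_called / n,
    n_called = n_called,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Filter sites by minor allele frequency and call rate
#'
#' Retains sites with `maf > min_maf` (allele-count basis over called
#' genotypes) and `call_rate > min_call_rate`. Individuals are untouched;
#' the operation is idempotent.
#'
#' @param geno dosage matrix.
#' @param min_maf minimum (strict) minor allele frequency.
#' @param min_call_rate minimum (strict) call rate.
#' @return the filtered matrix, with the retained sites' statistics in
#'   attribute `site_stats`; a warning is emitted if no site survives.
#' @export
filter_sites <- function(geno, min_maf = 0.05, min_call_rate = 0.9) {
  st <- site_stats(geno)
  keep <- !is.na(st$maf) & st$maf > min_maf & st$call_rate > min_call_rate
  out <- geno[, keep, drop = FALSE]
  if (ncol(out) == 0L) warnf("all sites removed by MAF/call-rate filters")
  attr(out, "site_stats") <- st[keep, , drop = FALSE]
  out
}
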