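# Synthetic full-sib family generator.
#
# Emulates a het x het two-parent cross segregating a major and a helper
# growth locus: offspring genotypes follow Mendelian 1:2:1 segregation at
# unlinked markers, and each fish's body weight / length is the mean of its
# two-locus genotype class plus Gaussian noise. Defaults reproduce the
# bimodal weight structure of a 442-offspring transgenic carp family in
# which the major-locus classes differ by roughly 500 g.

#' Default two-locus genotype class means
#'
#' 3 x 3 tables of mean body weight (g) and body length (mm) indexed by
#' alt-allele dosage at the major locus (rows, 0..2) and the helper locus
#' (columns, 0..2). The default values follow the class means observed in a
#' transgenic common carp full-sib family (major-locus hom-alt classes near
#' 1 kg, hom-ref near 300-500 g).
#'
#' @return list with numeric 3x3 matrices `weight` and `length`.
#' @export
default_genotype_means <- function() {
  dn <- list(major = c("0", "1", "2"), helper = c("0", "1", "2"))
  weight <- matrix(c(
    490.26, 447.75, 288.92, # major hom-ref
    728.04, 746.30, 773.52, # major het
    994.04, 868.03, 961.29  # major hom-alt
  ), nrow = 3, byrow = TRUE, dimnames = dn)
  length_ <- matrix(c(
    233.78, 230.31, 192.00,
    282.88, 282.48, 285.16,
    331.81, 303.77, 328.79
  ), nrow = 3, byrow = TRUE, dimnames = dn)
  list(weight = weight, length = length_)
}

#' Simulation configuration for a synthetic full-sib family
#'
#' @param n_offspring number of offspring measured (default 442).
#' @param n_markers number of unlinked biallelic markers, all het x het in
#'   the two parents.
#' @param n_causal number of causal loci; the model is a major plus a helper
#'   locus, so this must be 2 (and at most `n_markers`).
#' @param genotype_means list of 3x3 matrices `weight` (g) and `length`
#'   (mm), rows = major-locus dosage 0..2, columns = helper-locus dosage
#'   0..2; every one of the 9 two-locus classes must have a finite mean.
#' @param residual_sd named numeric, Gaussian residual standard deviation
#'   for `weight` (g) and `length` (mm).
#' @param pool_size individuals per phenotype bulk (default 30).
#' @param pool_depth mean pooled read depth per site (Poisson mean).
#' @param amplicon_depth read pairs per sample per amplicon.
#' @param read_error_rate per-base substitution probability in simulated
#'   reads and pool counts.
#' @param nonspecific_fraction proportion of amplicon read pairs carrying
#'   random (unassignable) barcodes, emulating non-specific amplification.
#' @param seed integer seed; identical configurations give bit-identical
#'   simulations.
#' @return validated `sim_config` list.
#' @export
sim_config <- function(n_offspring = 442,
                       n_markers = 200,
                       n_causal = 2,
                       genotype_means = default_genotype_means(),
                       residual_sd = c(weight = 50, length = 12),
                       pool_size = 30,
                       pool_depth = 40,
                       amplicon_depth = 40,
                       read_error_rate = 0.001,
                       nonspecific_fraction = 0,
                       seed = 1L) {
  cfg <- list(
    n_offspring = n_offspring, n_markers = n_markers, n_causal = n_causal,
    genotype_means = genotype_means, residual_sd = residual_sd,
    pool_size = pool_size, pool_depth = pool_depth,
    amplicon_depth = amplicon_depth, read_error_rate = read_error_rate,
    nonspecific_fraction = nonspecific_fraction, seed = as.integer(seed)
  )
  if (!is_count(cfg$n_offspring)) stopf("n_offspring must be a positive count")
  if (!is_count(cfg$n_markers)) stopf("n_markers must be a positive count")
  if (cfg$n_causal != 2) {
    stopf("configuration error: the model has a major and a helper locus (n_causal = 2)")
  }
  if (cfg$n_causal > cfg$n_markers) {
    stopf("configuration error: n_causal (%d) > n_markers (%d)",
          cfg$n_causal, cfg$n_markers)
  }
  if (!is_count(cfg$pool_size) || cfg$pool_size > cfg$n_offspring / 2) {
    stopf("pool_size must be a count no larger than n_offspring/2")
  }
  for (rate in c(cfg$read_error_rate, cfg$nonspecific_fraction)) {
    if (!is.numeric(rate) || rate < 0 || rate > 1) {
      stopf("rates must lie in [0, 1]")
    }
  }
  gm <- cfg$genotype_means
  for (trait in c("weight", "length")) {
    m <- gm[[trait]]
    if (is.null(m) || !is.matrix(m) || !all(dim(m) == c(3, 3)) ||
        any(!is.finite(m))) {
      stopf("configuration error: genotype_means$%s must be a finite 3x3 matrix covering all 9 two-locus classes", trait)
    }
  }
  if (!all(c("weight", "length") %in% names(cfg$residual_sd)) ||
      any(cfg$residual_sd < 0)) {
    stopf("residual_sd needs non-negative 'weight' and 'length' entries")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a full-sib family
#'
#' Both parents are heterozygous at every marker (markers are assayed
#' because they segregate), so offspring dosages are the sum of two
#' independent Bernoulli(1/2) gametes: an unlinked 1:2:1 cross. Two markers
#' are designated the causal major and helper loci; phenotypes are the
#' two-locus class mean plus Gaussian noise, floored at 1 (weights and
#' lengths are positive).
#'
#' @param config a [sim_config()].
#' @return list of class `fsib_family` with elements `markers` (marker
#'   metadata with `marker_id`, `contig`, `pos`, `ref`, `alt`, `role`),
#'   `genotypes` (offspring x marker alt-dosage matrix), `parents` (both
#'   het at every marker), `causal` (named marker indices) and `phenotypes`
#'   (`individual_id`, `weight_g`, `length_mm`).
#' @export
simulate_family <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    n <- config$n_offspring
    m <- config$n_markers
    causal <- sort(sample.int(m, 2L))
    names(causal) <- c("major", "helper")
    ref <- character(m)
    alt <- character(m)
    for (j in seq_len(m)) {
      ra <- sample(BASES, 2L)
      ref[j] <- ra[1]
      alt[j] <- ra[2]
    }
    # conventional allele letters at the causal loci (major T->G, helper C->T)
    ref[causal["major"]] <- "T"; alt[causal["major"]] <- "G"
    ref[causal["helper"]] <- "C"; alt[causal["helper"]] <- "T"
    role <- rep(NA_character_, m)
    role[causal["major"]] <- "major"
    role[causal["helper"]] <- "helper"
    markers <- data.frame(
      marker_id = sprintf("M%04d", seq_len(m)),
      contig = paste0("LG", ((seq_len(m) - 1L) %% 10L) + 1L),
      pos = 1000L * (((seq_len(m) - 1L) %/% 10L) + 1L),
      ref = ref, alt = alt, role = role,
      stringsAsFactors = FALSE
    )
    markers$site_id <- paste0(markers$contig, "_", markers$pos)
    geno <- matrix(
      rbinom(n * m, 1L, 0.5) + rbinom(n * m, 1L, 0.5),
      nrow = n, ncol = m,
      dimnames = list(sprintf("ind%03d", seq_len(n)), markers$marker_id)
    )
    gm <- config$genotype_means
    gmaj <- geno[, causal["major"]]
    ghlp <- geno[, causal["helper"]]
    idx <- cbind(gmaj + 1L, ghlp + 1L)
    weight <- gm$weight[idx] + rnorm(n, 0, config$residual_sd["weight"])
    length_ <- gm$length[idx] + rnorm(n, 0, config$residual_sd["length"])
    phen <- data.frame(
      individual_id = rownames(geno),
      weight_g = pmax(weight, 1),
      length_mm = pmax(length_, 1),
      stringsAsFactors = FALSE
    )
    parents <- data.frame(
      marker_id = markers$marker_id,
      dam = paste0(ref, "/", alt),
      sire = paste0(ref, "/", alt),
      stringsAsFactors = FALSE
    )
    structure(
      list(markers = markers, genotypes = geno, parents = parents,
           causal = causal, phenotypes = phen, config = config),
      class = "fsib_family"
    )
  })
}

#' @export
print.fsib_family <- function(x, ...) {
  cat(sprintf(
    "Full-sib family: %d offspring x %d markers (major locus %s, helper %s)\n",
    nrow(x$genotypes), ncol(x$genotypes),
    x$markers$marker_id[x$causal["major"]],
    x$markers$marker_id[x$causal["helper"]]
  ))
  invisible(x)
}

# select the pool_size individuals nearest each weight mode
.select_pools <- function(fam, pool_size) {
  w <- fam$phenotypes$weight_g
  sp <- split_subgroups(fam$phenotypes)
  if (!isTRUE(sp$split)) {
    stopf("phenotype distribution is not bimodal; cannot form fast/slow pools")
  }
  fast_ids <- which(sp$labels == "fast")
  slow_ids <- which(sp$labels == "slow")
  if (length(fast_ids) < pool_size || length(slow_ids) < pool_size) {
    stopf("fewer than pool_size (%d) individuals on one side of the split",
          pool_size)
  }
  fast <- fast_ids[order(abs(w[fast_ids] - sp$modes_weight[2]))][seq_len(pool_size)]
  slow <- slow_ids[order(abs(w[slow_ids] - sp$modes_weight[1]))][seq_len(pool_size)]
  list(fast = sort(fast), slow = sort(slow), split = sp)
}

.pool_counts_one <- function(geno_pool, markers, depth_mean, error_rate) {
  m <- nrow(markers)
  p_alt <- colMeans(geno_pool) / 2
  depth <- rpois(m, depth_mean)
  n_alt <- rbinom(m, depth, p_alt)
  n_ref <- depth - n_alt
  counts <- matrix(0L, nrow = m, ncol = 4L, dimnames = list(NULL, BASES))
  iref <- match(markers$ref, BASES)
  ialt <- match(markers$alt, BASES)
  counts[cbind(seq_len(m), iref)] <- n_ref
  counts[cbind(seq_len(m), ialt)] <- counts[cbind(seq_len(m), ialt)] + n_alt
  if (error_rate > 0) {
    err <- matrix(rbinom(2L * m, c(n_ref, n_alt), error_rate), ncol = 2L)
    for (j in which(rowSums(err) > 0)) {
      for (k in 1:2) {
        if (err[j, k] == 0) next
        src <- if (k == 1) iref[j] else ialt[j]
        counts[j, src] <- counts[j, src] - err[j, k]
        dest <- sample(setdiff(1:4, src), err[j, k], replace = TRUE)
        for (d in dest) counts[j, d] <- counts[j, d] + 1L
      }
    }
  }
  data.frame(
    site_id = markers$site_id,
    contig = markers$contig,
    pos = markers$pos,
    ref = markers$ref,
    alt = markers$alt,
    nA = counts[, "A"], nC = counts[, "C"],
    nG = counts[, "G"], nT = counts[, "T"],
    stringsAsFactors = FALSE
  )
}

#' Simulate pooled read counts for the fast and slow bulks
#'
#' Splits the family at the valley between the two weight modes, takes the
#' `pool_size` individuals nearest each mode as the fast and slow DNA
#' bulks, and draws per-site read counts: depth ~ Poisson(`pool_depth`),
#' alt reads ~ Binomial(depth, pooled allele frequency), with each read
#' miscalled to a uniform random other base with probability
#' `read_error_rate`.
#'
#' @param fam a [simulate_family()] result.
#' @param config the [sim_config()] used (defaults to the family's own).
#' @return list with `fast` and `slow` pool-count tables (`site_id`,
#'   `contig`, `pos`, `ref`, `alt`, `nA`, `nC`, `nG`, `nT`) and `members`
#'   (the pooled individual ids).
#' @export
simulate_pool_counts <- function(fam, config = fam$config) {
  stopifnot(inherits(fam, "fsib_family"))
  pools <- .select_pools(fam, config$pool_size)
  withr::with_seed(config$seed + 1L, {
    fast <- .pool_counts_one(
      fam$genotypes[pools$fast, , drop = FALSE], fam$markers,
      config$pool_depth, config$read_error_rate
    )
    slow <- .pool_counts_one(
      fam$genotypes[pools$slow, , drop = FALSE], fam$markers,
      config$pool_depth, config$read_error_rate
    )
    list(
      fast = fast, slow = slow,
      members = list(
        fast = rownames(fam$genotypes)[pools$fast],
        slow = rownames(fam$genotypes)[pools$slow]
      )
    )
  })
}

#' Synthetic amplicon targets for a marker panel
#'
#' Draws a random reference amplicon per marker with the marker's reference
#' base at `snp_offset`. Amplicons are at most 290 bases (short-range PCR
#' products) and the SNP offset must be covered by both 150-base reads
#' after the 20-base sample barcode.
#'
#' @param markers marker metadata rows (from a `fsib_family`) to target.
#' @param amplicon_length total amplicon length in bases (<= 290).
#' @param snp_offset 1-based SNP position within the amplicon.
#' @param primer_length bases at each amplicon end treated as primer
#'   landing sites for anchoring.
#' @param seed integer seed.
#' @return `amplicon_targets` data frame: `amplicon_id` (= marker id),
#'   `site_id`, `sequence`, `snp_offset`, `ref`, `alt`.
#' @export
make_amplicon_targets <- function(markers, amplicon_length = 180,
                                  snp_offset = 60, primer_length = 20,
                                  seed = 1L) {
  if (amplicon_length > 290) stopf("amplicon_length must be <= 290")
  if (snp_offset <= primer_length || snp_offset > amplicon_length) {
    stopf("snp_offset must lie inside the amplicon, past the primer region")
  }
  withr::with_seed(as.integer(seed), {
    seqs <- random_dna(nrow(markers), amplicon_length)
    for (i in seq_len(nrow(markers))) {
      substr(seqs[i], snp_offset, snp_offset) <- markers$ref[i]
    }
    out <- data.frame(
      amplicon_id = markers$marker_id,
      site_id = markers$site_id,
      sequence = seqs,
      snp_offset = snp_offset,
      ref = markers$ref,
      alt = markers$alt,
      stringsAsFactors = FALSE
    )
    attr(out, "primer_length") <- primer_length
    class(out) <- c("amplicon_targets", "data.frame")
    out
  })
}

#' Generate barcoded paired amplicon reads for every individual
#'
#' Each read pair consists of read 1 = F barcode + the amplicon 5' prefix
#' and read 2 = R barcode + the reverse-complement amplicon prefix, both
#' 150 bases. The base at the target SNP reflects the individual's
#' genotype (heterozygotes emit each allele with probability 1/2 per
#' pair); `nonspecific_fraction` of pairs get random barcodes;
#' substitution errors are sprinkled uniformly at `read_error_rate` per
#' base (barcodes included).
#'
#' @param fam a [simulate_family()] result.
#' @param scheme a [barcode_scheme()] covering all individuals.
#' @param targets an [make_amplicon_targets()] table.
#' @param config the [sim_config()] used (defaults to the family's own).
#' @return data frame with one row per read pair: `pair_id`, `sample_id`,
#'   `amplicon_id`, `true_allele`, `nonspecific`, `read1`, `read2`.
#' @export
generate_amplicon_reads <- function(fam, scheme, targets,
                                    config = fam$config) {
  stopifnot(inherits(fam, "fsib_family"))
  scheme <- barcode_scheme(scheme)
  ids <- rownames(fam$genotypes)
  if (!all(ids %in% scheme$sample_id)) {
    stopf("scheme error: barcode scheme does not cover every individual")
  }
  read_len <- 150L
  bar_len <- unique(nchar(scheme$f_barcode))
  if (length(bar_len) != 1L) stopf("scheme error: mixed barcode lengths")
  insert_len <- read_len - bar_len
  withr::with_seed(config$seed + 2L, {
    n_s <- length(ids)
    n_a <- nrow(targets)
    depth <- config$amplicon_depth
    # templates: per amplicon x allele, read-1 and read-2 insert sequences
    seq_ref <- targets$sequence
    seq_alt <- seq_ref
    for (a in seq_len(n_a)) {
      substr(seq_alt[a], targets$snp_offset[a], targets$snp_offset[a]) <-
        targets$alt[a]
    }
    tpl_r1 <- cbind(ref = substr(seq_ref, 1, insert_len),
                    alt = substr(seq_alt, 1, insert_len))
    tpl_r2 <- cbind(ref = substr(revcomp(seq_ref), 1, insert_len),
                    alt = substr(revcomp(seq_alt), 1, insert_len))
    sample_idx <- rep(seq_len(n_s), each = n_a * depth)
    amp_idx <- rep(rep(seq_len(n_a), each = depth), times = n_s)
    n_reads <- length(sample_idx)
    marker_idx <- match(targets$amplicon_id[amp_idx],
                        fam$markers$marker_id)
    dosage <- fam$genotypes[cbind(sample_idx, marker_idx)]
    allele <- ifelse(
      dosage == 2L, "alt",
      ifelse(dosage == 0L, "ref",
             c("ref", "alt")[rbinom(n_reads, 1L, 0.5) + 1L])
    )
    sidx <- match(ids[sample_idx], scheme$sample_id)
    allele_col <- ifelse(allele == "ref", 1L, 2L)
    r1_ins <- tpl_r1[cbind(amp_idx, allele_col)]
    r2_ins <- tpl_r2[cbind(amp_idx, allele_col)]
    read1 <- paste0(scheme$f_barcode[sidx], r1_ins)
    read2 <- paste0(scheme$r_barcode[sidx], r2_ins)
    nonspecific <- runif(n_reads) < config$nonspecific_fraction
    n_ns <- sum(nonspecific)
    if (n_ns > 0) {
      read1[nonspecific] <- paste0(
        random_dna(n_ns, bar_len), substr(read1[nonspecific], bar_len + 1L, read_len)
      )
      read2[nonspecific] <- paste0(
        random_dna(n_ns, bar_len), substr(read2[nonspecific], bar_len + 1L, read_len)
      )
    }
    if (config$read_error_rate > 0) {
      n_err <- rbinom(1L, n_reads * 2L * read_len, config$read_error_rate)
      if (n_err > 0) {
        at <- sample.int(n_reads * 2L * read_len, n_err)
        mate <- ifelse(at > n_reads * read_len, 2L, 1L)
        off <- at - (mate - 1L) * n_reads * read_len
        ridx <- ((off - 1L) %% n_reads) + 1L
        pos <- ((off - 1L) %/% n_reads) + 1L
        i1 <- mate == 1L
        read1 <- substitute_bases(read1, ridx[i1], pos[i1])
        read2 <- substitute_bases(read2, ridx[!i1], pos[!i1])
      }
    }
    data.frame(
      pair_id = sprintf("pair%07d", seq_len(n_reads)),
      sample_id = ids[sample_idx],
      amplicon_id = targets$amplicon_id[amp_idx],
      true_allele = allele,
      nonspecific = nonspecific,
      read1 = read1,
      read2 = read2,
      stringsAsFactors = FALSE
    )
  })
}
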