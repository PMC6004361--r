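# Dual-barcode demultiplexing of pooled paired-end amplicon reads.
#
# Each sample is identified by an (F, R) barcode combination prepended to
# the forward and reverse PCR primers. Matching uses the 12-mer key formed
# by bases 9-20 of each barcode: a pair belongs to sample s iff one read
# carries s's F key and the mate carries s's R key, with the key starting
# within the first `max_key_start` read positions. Matching is exact (no
# mismatch tolerance); ambiguous pairs are discarded, not arbitrated.

#' Barcode matching key (bases 9-20)
#'
#' @param barcode DNA string(s) of length >= 20, ACGT only.
#' @param sample_id optional sample name(s) used in error messages.
#' @return the 12-mer at 1-based positions 9..20 of each barcode.
#' @export
barcode_key <- function(barcode, sample_id = NULL) {
  bad <- nchar(barcode) < 20 | grepl("[^ACGT]", barcode)
  if (any(bad)) {
    who <- if (is.null(sample_id)) which(bad) else sample_id[bad]
    stopf("scheme error: barcode for %s must be >= 20 bases of ACGT",
          paste(who, collapse = ", "))
  }
  substr(barcode, 9L, 20L)
}

#' Validate a dual-barcode scheme
#'
#' @param scheme data frame with `sample_id`, `f_barcode`, `r_barcode`.
#' @return the scheme with derived `f_key` / `r_key` columns, validated so
#'   every (f_key, r_key) pair is unique across samples.
#' @export
barcode_scheme <- function(scheme) {
  need <- c("sample_id", "f_barcode", "r_barcode")
  if (!all(need %in% names(scheme))) {
    stopf("barcode scheme needs columns %s", paste(need, collapse = ", "))
  }
  if (anyDuplicated(scheme$sample_id)) stopf("scheme error: duplicate sample_id")
  scheme$f_key <- barcode_key(scheme$f_barcode, scheme$sample_id)
  scheme$r_key <- barcode_key(scheme$r_barcode, scheme$sample_id)
  if (anyDuplicated(paste(scheme$f_key, scheme$r_key))) {
    stopf("scheme error: duplicate (F, R) barcode key combination")
  }
  class(scheme) <- c("barcode_scheme", "data.frame")
  scheme
}

#' Generate a combinatorial dual-barcode scheme
#'
#' Builds an F x R barcode grid large enough for all samples, with unique
#' 12-mer keys disjoint between the F and R sets, and assigns combinations
#' to samples row-major.
#'
#' @param sample_ids character vector of sample names.
#' @param barcode_length barcode length (>= 20).
#' @param seed integer seed.
#' @return a validated [barcode_scheme()].
#' @export
make_barcode_scheme <- function(sample_ids, barcode_length = 20, seed = 1L) {
  n <- length(sample_ids)
  n_f <- ceiling(sqrt(n))
  n_r <- ceiling(n / n_f)
  withr::with_seed(as.integer(seed), {
    draw_unique <- function(k, taken_keys) {
      out <- character(0)
      while (length(out) < k) {
        cand <- random_dna(k - length(out), barcode_length)
        keys <- substr(cand, 9L, 20L)
        ok <- !duplicated(keys) & !(keys %in% taken_keys)
        out <- c(out, cand[ok])
        taken_keys <- c(taken_keys, keys[ok])
      }
      out
    }
    f_bar <- draw_unique(n_f, character(0))
    r_bar <- draw_unique(n_r, substr(f_bar, 9L, 20L))
    combo <- expand.grid(r = seq_len(n_r), f = seq_len(n_f))[seq_len(n), ]
    barcode_scheme(data.frame(
      sample_id = sample_ids,
      f_barcode = f_bar[combo$f],
      r_barcode = r_bar[combo$r],
      stringsAsFactors = FALSE
    ))
  })
}

# For each read, which of `keys` occurs starting within the first
# `max_start` positions? Returns first hit index and a conflict flag when
# two different keys match the same read.
.key_hits <- function(reads, keys, max_start = 9L) {
  hit <- rep(NA_integer_, length(reads))
  conflict <- rep(FALSE, length(reads))
  for (s in seq_len(max_start)) {
    sub <- substr(reads, s, s + 11L)
    h <- match(sub, keys)
    new <- !is.na(h)
    conflict <- conflict | (new & !is.na(hit) & h != hit)
    hit[new & is.na(hit)] <- h[new & is.na(hit)]
  }
  list(hit = hit, conflict = conflict)
}

#' Assign read pairs to samples by dual-barcode keys
#'
#' Vectorised core of the demultiplexer. A pair is assigned to the unique
#' sample whose F key occurs in one read and R key in the mate (both
#' starting within the first `max_key_start` positions); orientation-swapped
#' pairs (F key on read 2) are accepted. Pairs matching the keys of two
#' different samples, or keys of two different barcodes on one read, are
#' unassigned with reason `conflicting`.
#'
#' @param read1,read2 character vectors of read sequences (synchronised).
#' @param scheme a [barcode_scheme()].
#' @param max_key_start latest read position at which a key may start.
#' @return data frame with `sample_id` (NA if unassigned), `reason`
#'   (`assigned`, `no-F-match`, `no-R-match`, `conflicting`,
#'   `unknown-combination`) and `orientation` (`FR` or `RF`).
#' @export
assign_pairs <- function(read1, read2, scheme, max_key_start = 9L) {
  scheme <- barcode_scheme(scheme)
  stopifnot(length(read1) == length(read2))
  n <- length(read1)
  fkeys <- unique(scheme$f_key)
  rkeys <- unique(scheme$r_key)
  combo <- paste(scheme$f_key, scheme$r_key)
  f1 <- .key_hits(read1, fkeys, max_key_start)
  r2 <- .key_hits(read2, rkeys, max_key_start)
  f2 <- .key_hits(read2, fkeys, max_key_start)
  r1 <- .key_hits(read1, rkeys, max_key_start)
  lookup <- function(fh, rh) {
    ok <- !is.na(fh) & !is.na(rh)
    out <- rep(NA_integer_, n)
    out[ok] <- match(paste(fkeys[fh[ok]], rkeys[rh[ok]]), combo)
    out
  }
  sampA <- lookup(f1$hit, r2$hit) # F on read1
  sampB <- lookup(f2$hit, r1$hit) # orientation swapped
  key_conflict <- f1$conflict | r2$conflict | f2$conflict | r1$conflict
  both_differ <- !is.na(sampA) & !is.na(sampB) & sampA != sampB
  sample_idx <- ifelse(is.na(sampA), sampB, sampA)
  orientation <- ifelse(is.na(sampA) & !is.na(sampB), "RF", "FR")
  has_f <- !is.na(f1$hit) | !is.na(f2$hit)
  has_r <- !is.na(r1$hit) | !is.na(r2$hit)
  reason <- rep("assigned", n)
  reason[is.na(sample_idx)] <- "unknown-combination"
  reason[is.na(sample_idx) & !has_r] <- "no-R-match"
  reason[is.na(sample_idx) & !has_f] <- "no-F-match"
  conflict <- key_conflict | both_differ
  reason[conflict] <- "conflicting"
  sample_idx[conflict] <- NA_integer_
  data.frame(
    sample_id = scheme$sample_id[sample_idx],
    reason = reason,
    orientation = ifelse(is.na(sample_idx), NA_character_, orientation),
    stringsAsFactors = FALSE
  )
}

#' Assign one read pair
#'
#' Single-pair convenience wrapper around [assign_pairs()].
#'
#' @inheritParams assign_pairs
#' @return list with `sample_id` (NA if unassigned) and `reason`.
#' @export
assign_pair <- function(read1, read2, scheme, max_key_start = 9L) {
  res <- assign_pairs(read1, read2, scheme, max_key_start)
  list(sample_id = res$sample_id[1], reason = res$reason[1])
}

.demux_report <- function(assign, scheme) {
  total <- nrow(assign)
  assigned <- sum(assign$reason == "assigned")
  per_sample <- table(factor(assign$sample_id, levels = scheme$sample_id))
  reasons <- table(assign$reason[assign$reason != "assigned"])
  rep <- list(
    total_pairs = total,
    assigned_pairs = assigned,
    assigned_fraction = if (total > 0) assigned / total else NA_real_,
    per_sample = as.data.frame(per_sample, responseName = "n_pairs",
                               stringsAsFactors = FALSE),
    unassigned_reasons = as.list(reasons)
  )
  names(rep$per_sample)[1] <- "sample_id"
  stopifnot(sum(rep$per_sample$n_pairs) == assigned)
  class(rep) <- "demux_report"
  rep
}

#' @export
print.demux_report <- function(x, ...) {
  cat(sprintf("Demultiplexing: %d / %d pairs assigned (%.2f%%)\n",
              x$assigned_pairs, x$total_pairs,
              100 * x$assigned_fraction))
  if (length(x$unassigned_reasons)) {
    for (r in names(x$unassigned_reasons)) {
      cat(sprintf("  unassigned (%s): %d\n", r, x$unassigned_reasons[[r]]))
    }
  }
  invisible(x)
}

#' Demultiplex pooled paired reads into per-sample sets
#'
#' Accepts either in-memory read pairs (a data frame with `read1` /
#' `read2`, e.g. from [generate_amplicon_reads()]) or a pair of FASTQ
#' files. Assigned pairs are orientation-normalised so `read1` always
#' carries the F barcode. Per-sample FASTQ files are written only when
#' `out_dir` is given.
#'
#' @param reads data frame with `read1`, `read2` columns, or the path of
#'   the R1 FASTQ file (plain or gzipped).
#' @param read2 path of the R2 FASTQ file when `reads` is a file path.
#' @param scheme a [barcode_scheme()].
#' @param out_dir optional directory for per-sample paired FASTQ output
#'   plus an `unassigned` sink.
#' @param max_key_start latest read position at which a key may start.
#' @return list with `assignments` (input rows + `sample_id`, `reason`,
#'   orientation-normalised `read1`/`read2`) and `report` (a
#'   `demux_report`: totals, per-sample counts, unassigned reasons).
#' @export
demux <- function(reads, read2 = NULL, scheme, out_dir = NULL,
                  max_key_start = 9L) {
  scheme <- barcode_scheme(scheme)
  if (is.character(reads)) {
    pairs <- read_fastq_pairs(reads, read2)
  } else {
    stopifnot(all(c("read1", "read2") %in% names(reads)))
    pairs <- reads
  }
  res <- assign_pairs(pairs$read1, pairs$read2, scheme, max_key_start)
  out <- pairs
  out$sample_id <- res$sample_id
  out$reason <- res$reason
  swap <- !is.na(res$orientation) & res$orientation == "RF"
  if (any(swap)) {
    tmp <- out$read1[swap]
    out$read1[swap] <- out$read2[swap]
    out$read2[swap] <- tmp
  }
  report <- .demux_report(res, scheme)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    groups <- split(seq_len(nrow(out)),
                    ifelse(is.na(out$sample_id), "unassigned", out$sample_id))
    for (g in names(groups)) {
      i <- groups[[g]]
      write_fastq_pairs(
        out$read1[i], out$read2[i],
        file.path(out_dir, paste0(g, "_R1.fastq")),
        file.path(out_dir, paste0(g, "_R2.fastq")),
        ids = sprintf("%s_%06d", g, seq_along(i))
      )
    }
  }
  list(assignments = out, report = report)
}
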