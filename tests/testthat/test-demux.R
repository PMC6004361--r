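# dual-barcode demultiplexing

test_that("barcode key is the 12-mer at positions 9-20", {
  expect_equal(barcode_key("AAAAAAAACGTACGTACGTA"), "CGTACGTACGTA")
  expect_equal(barcode_key(strrep("A", 20)), strrep("A", 12))
  withr::with_seed(2, {
    bars <- carpmap:::random_dna(20, 25)
    expect_true(all(nchar(barcode_key(bars)) == 12))
  })
  expect_error(barcode_key("ACGT", sample_id = "s7"), "s7")
  expect_error(barcode_key(strrep("N", 20), sample_id = "s8"), "s8")
})

test_that("scheme validation rejects duplicate key combinations", {
  s <- data.frame(
    sample_id = c("a", "b"),
    f_barcode = strrep("A", 20),
    r_barcode = strrep("C", 20),
    stringsAsFactors = FALSE
  )
  expect_error(barcode_scheme(s), "duplicate \\(F, R\\)")
  s$r_barcode[2] <- strrep("G", 20)
  expect_s3_class(barcode_scheme(s), "barcode_scheme")
})

test_that("pair assignment follows the F/R key rule with orientation swap", {
  scheme <- make_barcode_scheme(c("s1", "s2"), seed = 3)
  f <- scheme$f_barcode[1]
  r <- scheme$r_barcode[1]
  insert <- strrep("T", 120)
  read1 <- paste0(f, insert)
  read2 <- paste0(r, insert)
  expect_equal(assign_pair(read1, read2, scheme)$sample_id, "s1")
  # orientation swapped is accepted
  expect_equal(assign_pair(read2, read1, scheme)$sample_id, "s1")
  # F matches, R does not
  res <- assign_pair(read1, strrep("T", 140), scheme)
  expect_true(is.na(res$sample_id))
  expect_equal(res$reason, "no-R-match")
  # nothing matches
  expect_equal(assign_pair(strrep("T", 140), strrep("G", 140), scheme)$reason,
               "no-F-match")
})

test_that("ambiguous pairs are discarded, not arbitrated", {
  # crafted scheme in which two F keys can co-occur in one read
  scheme <- barcode_scheme(data.frame(
    sample_id = c("s1", "s2"),
    f_barcode = c(strrep("A", 20), paste0(strrep("A", 19), "C")),
    r_barcode = c(strrep("G", 20), strrep("T", 20)),
    stringsAsFactors = FALSE
  ))
  # "A"x12 matches s1's key at position 1 and s2's key ("A"x11+"C")
  # starts at position 2: two different F keys inside the window
  read1 <- paste0(strrep("A", 12), "C", strrep("T", 127))
  res <- assign_pairs(read1, paste0(strrep("G", 20), strrep("T", 120)),
                      scheme)
  expect_equal(res$reason, "conflicting")
  expect_true(is.na(res$sample_id))
  # a key outside the first-9-positions window does not match
  far <- paste0(strrep("T", 10), strrep("A", 12), strrep("T", 128))
  res2 <- assign_pairs(far, paste0(strrep("G", 20), strrep("T", 120)),
                       scheme)
  expect_equal(res2$reason, "no-F-match")
  # an F/R combination no sample owns is rejected
  scheme3 <- make_barcode_scheme(c("s1", "s2", "s3"), seed = 5)
  readA <- paste0(scheme3$f_barcode[scheme3$sample_id == "s3"],
                  strrep("T", 120))
  readB <- paste0(scheme3$r_barcode[scheme3$sample_id == "s2"],
                  strrep("T", 120))
  expect_equal(assign_pairs(readA, readB, scheme3)$reason,
               "unknown-combination")
})

test_that("demux round trip recovers the simulator's bookkeeping", {
  fam <- small_family(n = 24, m = 4, seed = 6,
                      amplicon_depth = 7, read_error_rate = 0)
  scheme <- make_barcode_scheme(rownames(fam$genotypes), seed = 7)
  targets <- make_amplicon_targets(fam$markers, seed = 8)
  reads <- generate_amplicon_reads(fam, scheme, targets)
  dm <- demux(reads, scheme = scheme)
  expect_equal(dm$report$assigned_pairs, nrow(reads))
  expect_identical(dm$assignments$sample_id, reads$sample_id)
  # per-sample counts match generation depths exactly
  expect_true(all(dm$report$per_sample$n_pairs == 4 * 7))
  # conservation
  expect_equal(
    dm$report$assigned_pairs +
      sum(unlist(dm$report$unassigned_reasons)),
    dm$report$total_pairs
  )
})

test_that("nonspecific pairs are unassigned at the configured rate", {
  fam <- small_family(n = 40, m = 4, seed = 9, amplicon_depth = 10,
                      read_error_rate = 0, nonspecific_fraction = 0.4)
  scheme <- make_barcode_scheme(rownames(fam$genotypes), seed = 10)
  targets <- make_amplicon_targets(fam$markers, seed = 11)
  reads <- generate_amplicon_reads(fam, scheme, targets)
  dm <- demux(reads, scheme = scheme)
  # every specific pair assigned to its generating sample
  spec <- !reads$nonspecific
  expect_identical(dm$assignments$sample_id[spec], reads$sample_id[spec])
  got <- dm$report$assigned_fraction
  se <- sqrt(0.4 * 0.6 / nrow(reads))
  expect_lt(abs(got - mean(spec)), 1e-9)
  expect_lt(abs(got - 0.6), 4 * se)
})

test_that("demux reads and writes FASTQ files faithfully", {
  fam <- small_family(n = 6, m = 2, seed = 12, amplicon_depth = 3,
                      read_error_rate = 0)
  scheme <- make_barcode_scheme(rownames(fam$genotypes), seed = 13)
  targets <- make_amplicon_targets(fam$markers[1, , drop = FALSE], seed = 14)
  reads <- generate_amplicon_reads(fam, scheme, targets)
  td <- withr::local_tempdir()
  f1 <- file.path(td, "R1.fastq")
  f2 <- file.path(td, "R2.fastq")
  write_fastq_pairs(reads$read1, reads$read2, f1, f2, ids = reads$pair_id)
  out <- withr::local_tempdir()
  dm <- demux(f1, f2, scheme = scheme, out_dir = out)
  expect_equal(dm$report$total_pairs, nrow(reads))
  expect_equal(dm$report$assigned_pairs, nrow(reads))
  # per-sample files exist and contain the right number of pairs
  s1 <- file.path(out, "ind001_R1.fastq")
  expect_true(file.exists(s1))
  # one amplicon at depth 3: three pairs for the sample
  expect_equal(length(Biostrings::readDNAStringSet(s1, format = "fastq")), 3)
})

test_that("empty input and desynchronised FASTQs are handled", {
  scheme <- make_barcode_scheme(c("a", "b"), seed = 15)
  dm <- demux(data.frame(read1 = character(0), read2 = character(0)),
              scheme = scheme)
  expect_equal(dm$report$total_pairs, 0)
  expect_equal(dm$report$assigned_pairs, 0)
  td <- withr::local_tempdir()
  f1 <- file.path(td, "a1.fastq")
  f2 <- file.path(td, "a2.fastq")
  write_fastq_pairs("ACGTACGT", "TTTTACGT", f1, f2, ids = "p1")
  f3 <- file.path(td, "b2.fastq")
  write_fastq_pairs(c("ACGTACGT", "AAAA"), c("TTTT", "CCCC"), f3, f3,
                    ids = c("q1", "q2"))
  expect_error(demux(f1, f3, scheme = scheme), "desynchronised")
})
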