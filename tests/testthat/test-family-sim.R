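# synthetic full-sib family generator

test_that("offspring segregate 1:2:1 at a het x het marker", {
  fam <- simulate_family(sim_config(
    n_offspring = 10000, n_markers = 2, pool_size = 10, seed = 42
  ))
  g <- fam$genotypes[, fam$causal["major"]]
  obs <- tabulate(g + 1L, nbins = 3)
  chi <- stats::chisq.test(obs, p = c(0.25, 0.5, 0.25))
  expect_gt(chi$p.value, 0.001)
})

test_that("zero residual noise gives exact class means, floored at 1", {
  cfg <- sim_config(n_offspring = 200, n_markers = 4,
                    residual_sd = c(weight = 0, length = 0), seed = 3)
  fam <- simulate_family(cfg)
  gm <- cfg$genotype_means
  idx <- cbind(fam$genotypes[, fam$causal["major"]] + 1L,
               fam$genotypes[, fam$causal["helper"]] + 1L)
  expect_equal(fam$phenotypes$weight_g, unname(gm$weight[idx]))
  expect_equal(fam$phenotypes$length_mm, unname(gm$length[idx]))
})

test_that("identical configuration gives bit-identical simulations", {
  cfg <- sim_config(n_offspring = 80, n_markers = 10, pool_size = 20,
                    amplicon_depth = 5, seed = 99)
  a <- simulate_family(cfg)
  b <- simulate_family(cfg)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(simulate_pool_counts(a), simulate_pool_counts(b))
  scheme <- make_barcode_scheme(rownames(a$genotypes), seed = 1)
  targets <- make_amplicon_targets(a$markers[1:3, ], seed = 2)
  expect_identical(generate_amplicon_reads(a, scheme, targets),
                   generate_amplicon_reads(b, scheme, targets))
})

test_that("configuration errors are caught", {
  expect_error(sim_config(n_causal = 3), "major and a helper")
  expect_error(sim_config(pool_size = 300, n_offspring = 442), "pool_size")
  expect_error(sim_config(read_error_rate = 1.5), "rates")
  gm <- default_genotype_means()
  gm$weight[2, 2] <- NA
  expect_error(sim_config(genotype_means = gm), "9 two-locus classes")
})

test_that("default family weight distribution is bimodal by mixture BIC", {
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))
  fam <- simulate_family(sim_config(n_offspring = 442, n_markers = 5,
                                    seed = 7))
  w <- fam$phenotypes$weight_g
  b1 <- Mclust(w, G = 1, verbose = FALSE)$bic
  b2 <- Mclust(w, G = 2, verbose = FALSE)$bic
  expect_gt(b2, b1)
})

test_that("pooled counts follow binomial sampling at the pool frequency", {
  # 1e4 replicate sites with pool allele frequency exactly 0.5
  m <- 10000
  markers <- data.frame(
    marker_id = sprintf("M%05d", 1:m), contig = "LG1", pos = 1:m,
    ref = "A", alt = "C", site_id = sprintf("s%05d", 1:m),
    stringsAsFactors = FALSE
  )
  geno <- matrix(1L, nrow = 30, ncol = m) # every pooled fish heterozygous
  withr::with_seed(5, {
    tab <- carpmap:::.pool_counts_one(geno, markers, depth_mean = 40,
                                      error_rate = 0)
  })
  depth <- tab$nA + tab$nC
  frac_alt <- sum(tab$nC) / sum(depth)
  se <- sqrt(0.25 / sum(depth))
  expect_lt(abs(frac_alt - 0.5), 3 * se)
  expect_equal(tab$nG + tab$nT, rep(0L, m)) # error 0: no third allele
})

test_that("pool counts are clean in fixed-genotype corner cases", {
  # all pooled individuals hom ref, no error: zero alt reads
  markers <- data.frame(
    marker_id = "M1", contig = "LG1", pos = 1L, ref = "T", alt = "G",
    site_id = "s1", stringsAsFactors = FALSE
  )
  withr::with_seed(8, {
    tab <- carpmap:::.pool_counts_one(matrix(0L, 30, 1), markers, 40, 0)
  })
  expect_equal(tab$nG, 0L)
  expect_gt(tab$nT, 0)
  # fixed ref pool vs fixed alt pool at high depth: Fst -> 1
  withr::with_seed(9, {
    p1 <- carpmap:::.pool_counts_one(matrix(0L, 30, 1), markers, 5000, 0)
    p2 <- carpmap:::.pool_counts_one(matrix(2L, 30, 1), markers, 5000, 0)
  })
  expect_equal(fst_table(p1, p2)$fst, 1)
})

test_that("pools are taken from opposite sides of the bimodal split", {
  fam <- simulate_family(sim_config(n_offspring = 300, n_markers = 10,
                                    pool_size = 25, seed = 21))
  pools <- simulate_pool_counts(fam)
  w <- stats::setNames(fam$phenotypes$weight_g, fam$phenotypes$individual_id)
  expect_length(pools$members$fast, 25)
  expect_length(pools$members$slow, 25)
  expect_gt(min(w[pools$members$fast]), max(w[pools$members$slow]))
})

test_that("amplicon reads carry the right barcodes and alleles", {
  fam <- small_family(n = 8, m = 2, seed = 4,
                      amplicon_depth = 10, read_error_rate = 0)
  scheme <- make_barcode_scheme(rownames(fam$genotypes), seed = 1)
  targets <- make_amplicon_targets(fam$markers[1, , drop = FALSE], seed = 2)
  reads <- generate_amplicon_reads(fam, scheme, targets)
  one <- reads[reads$sample_id == "ind001", ]
  expect_equal(nrow(one), 10)
  bar <- scheme$f_barcode[scheme$sample_id == "ind001"]
  expect_true(all(startsWith(one$read1, bar)))
  # SNP base in read 1 reflects the individual's genotype
  off <- 20 + targets$snp_offset[1]
  base <- substr(one$read1, off, off)
  dos <- fam$genotypes["ind001", targets$amplicon_id[1]]
  if (dos == 0) expect_true(all(base == targets$ref[1]))
  if (dos == 2) expect_true(all(base == targets$alt[1]))
})

test_that("heterozygote read allele fraction is binomial around 1/2", {
  fam <- simulate_family(sim_config(
    n_offspring = 40, n_markers = 2, pool_size = 10,
    amplicon_depth = 2000, read_error_rate = 0, seed = 13
  ))
  het <- which(fam$genotypes[, fam$causal["major"]] == 1L)[1]
  scheme <- make_barcode_scheme(rownames(fam$genotypes), seed = 1)
  targets <- make_amplicon_targets(
    fam$markers[fam$causal["major"], , drop = FALSE], seed = 2
  )
  reads <- generate_amplicon_reads(fam, scheme, targets)
  mine <- reads$true_allele[reads$sample_id == rownames(fam$genotypes)[het]]
  frac <- mean(mine == "alt")
  se <- sqrt(0.25 / length(mine))
  expect_lt(abs(frac - 0.5), 3 * se)
})

test_that("the causal locus dominates the Fst scan across replicates", {
  hits <- vapply(1:20, function(s) {
    fam <- simulate_family(sim_config(n_offspring = 442, n_markers = 50,
                                      seed = s))
    pools <- simulate_pool_counts(fam)
    tab <- fst_table(pools$fast, pools$slow)
    top <- tab$site_id[which.max(tab$fst)]
    top == fam$markers$site_id[fam$causal["major"]]
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
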