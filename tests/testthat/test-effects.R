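# subgroup splitting, ANOVA and genotype-effect summaries

test_that("two well-separated clusters split with >= 99% label accuracy", {
  withr::with_seed(61, {
    truth <- rep(c("slow", "fast"), each = 221)
    w <- c(rnorm(221, 190, 100), rnorm(221, 1120, 100))
    w <- pmax(w, 1)
    phen <- data.frame(individual_id = sprintf("i%03d", 1:442),
                       weight_g = w, length_mm = pmax(w / 4 + 100, 1))
    sp <- split_subgroups(phen)
    expect_true(sp$split)
    expect_gte(mean(sp$labels == truth), 0.99)
    expect_lt(max(phen$weight_g[sp$labels == "slow"]),
              min(phen$weight_g[sp$labels == "fast"]))
  })
})

test_that("a unimodal Gaussian gives a flagged no-split result", {
  withr::with_seed(62, {
    phen <- data.frame(individual_id = sprintf("i%03d", 1:442),
                       weight_g = rnorm(442, 700, 300),
                       length_mm = rnorm(442, 280, 50))
    phen$weight_g <- pmax(phen$weight_g, 1)
    sp <- split_subgroups(phen)
    expect_false(sp$split)
    expect_true(all(is.na(sp$labels)))
  })
  expect_error(split_subgroups(data.frame(individual_id = "a",
                                          weight_g = 1, length_mm = 1)),
               "at least 20")
})

test_that("study-scale subgroups are partitioned without any crossover", {
  # clusters on the published scale: slow around 187 g, fast around 1120 g
  withr::with_seed(63, {
    slow <- pmax(rnorm(184, 187, 90), 27)
    fast <- pmin(rnorm(258, 1120, 250), 1726)
    fast <- pmax(fast, 560)
    w <- c(slow, fast)
    phen <- data.frame(individual_id = sprintf("i%03d", seq_along(w)),
                       weight_g = w, length_mm = pmax(w / 4 + 80, 1))
    sp <- split_subgroups(phen)
    expect_true(sp$split)
    # threshold falls in the empty stretch between the two clusters
    expect_gt(sp$threshold_weight, max(slow))
    expect_lt(sp$threshold_weight, min(fast))
    expect_true(all(sp$labels[seq_along(slow)] == "slow"))
    expect_true(all(sp$labels[-seq_along(slow)] == "fast"))
  })
})

test_that("one-way ANOVA matches textbook sums of squares", {
  res <- one_way_anova(c(1, 2, 3, 2, 3, 4), rep(c("g1", "g2"), each = 3))
  expect_equal(res$f_stat, 1.5)
  expect_equal(res$df, c(1, 4))
  # identical constant groups: F = 0
  res0 <- one_way_anova(rep(5, 8), rep(c("a", "b"), each = 4))
  expect_equal(res0$f_stat, 0)
  # brute-force oracle on random groups
  withr::with_seed(64, {
    for (rep in 1:10) {
      k <- sample(2:4, 1)
      n_per <- sample(3:6, k, replace = TRUE)
      g <- rep(letters[1:k], n_per)
      v <- rnorm(length(g), as.numeric(factor(g)), 1)
      res <- one_way_anova(v, g)
      gm <- mean(v)
      ssb <- sum(tapply(v, g, function(x) length(x) * (mean(x) - gm)^2))
      ssw <- sum(tapply(v, g, function(x) sum((x - mean(x))^2)))
      f <- (ssb / (k - 1)) / (ssw / (length(v) - k))
      expect_equal(res$f_stat, f)
      expect_equal(res$p, stats::pf(f, k - 1, length(v) - k,
                                    lower.tail = FALSE))
    }
  })
})

test_that("ANOVA excludes tiny groups with a warning and flags
           untestable partitions", {
  expect_warning(res <- one_way_anova(c(1, 2, 3, 9), c("a", "a", "a", "b")),
                 "b")
  expect_true(res$untestable)
  expect_warning(res2 <- one_way_anova(c(1, 2, 3, 4, 5, 9),
                                       c("a", "a", "b", "b", "b", "c")),
                 "c")
  expect_false(res2$untestable)
})

test_that("genotype classes with published-scale separation test
           significant in nearly all replicates", {
  sig <- vapply(1:40, function(s) {
    withr::with_seed(2000 + s, {
      v <- c(rnorm(116, 919.87, 461.77), rnorm(227, 746.91, 510.23),
             rnorm(99, 419.12, 437.46))
      g <- rep(c("GG", "TG", "TT"), c(116, 227, 99))
      one_way_anova(v, g)$p < 0.01
    })
  }, logical(1))
  expect_gte(mean(sig), 0.95)
})

test_that("summaries reproduce exact threshold frequencies", {
  counts <- growth_class_counts()
  ind <- expand_class_counts(counts)
  phen <- ind[, c("individual_id", "weight_g", "length_mm")]
  gmaj <- data.frame(individual_id = ind$individual_id,
                     genotype = ind$genotype_major)
  gs <- genotype_summary(gmaj, phen, site_label = "17")
  get <- function(lab) gs$frequency_over_threshold[gs$label == lab]
  expect_equal(get("family"), 58.37)
  expect_equal(get("17GG"), 77.59)
  # classes where nobody (everybody) exceeds the threshold
  tiny <- data.frame(individual_id = c("x1", "x2", "y1"),
                     genotype = c("AA", "AA", "AT"))
  tphen <- data.frame(individual_id = c("x1", "x2", "y1"),
                      weight_g = c(100, 200, 900), length_mm = c(1, 1, 1))
  ts <- genotype_summary(tiny, tphen)
  expect_equal(ts$frequency_over_threshold[ts$label == "AA"], 0)
  expect_equal(ts$frequency_over_threshold[ts$label == "AT"], 100)
  # strictly-greater threshold: exactly 500 g does not count
  edge <- genotype_summary(
    data.frame(individual_id = "e1", genotype = "AA"),
    data.frame(individual_id = "e1", weight_g = 500, length_mm = 1)
  )
  expect_equal(edge$n_over_threshold[edge$label == "AA"], 0)
})

test_that("dosage-vector input produces field-style genotype labels", {
  dos <- stats::setNames(c(0L, 1L, 2L, NA), c("a", "b", "c", "d"))
  expect_equal(genotype_label(dos, "T", "G"),
               c("TT", "TG", "GG", NA))
  phen <- data.frame(individual_id = c("a", "b", "c", "d"),
                     weight_g = c(400, 600, 800, 900),
                     length_mm = rep(100, 4))
  gs <- genotype_summary(dos, phen, site_label = "17", ref = "T", alt = "G")
  expect_setequal(gs$label, c("family", "17TT", "17TG", "17GG"))
  # missing genotype excluded from classes, kept in the family row
  expect_equal(gs$n[gs$label == "family"], 4)
  expect_equal(sum(gs$n[gs$label != "family"]), 3)
})

test_that("combination classes partition the single-locus classes", {
  counts <- growth_class_counts()
  ind <- expand_class_counts(counts)
  phen <- ind[, c("individual_id", "weight_g", "length_mm")]
  gmaj <- data.frame(individual_id = ind$individual_id,
                     genotype = ind$genotype_major)
  ghlp <- data.frame(individual_id = ind$individual_id,
                     genotype = ind$genotype_helper)
  cs <- combination_summary(gmaj, ghlp, phen, labels = c("17", "14"))
  gg_rows <- grepl("^17GG", cs$label)
  expect_equal(sum(cs$n[gg_rows]), 116)
  gs <- genotype_summary(gmaj, phen, site_label = "17")
  for (g in c("GG", "TG", "TT")) {
    expect_equal(sum(cs$n[grepl(paste0("^17", g), cs$label)]),
                 gs$n[gs$label == paste0("17", g)])
  }
})

test_that("dominance ranking orders by frequency with deterministic ties", {
  counts <- growth_class_counts()
  ind <- expand_class_counts(counts)
  phen <- ind[, c("individual_id", "weight_g", "length_mm")]
  gmaj <- data.frame(individual_id = ind$individual_id,
                     genotype = ind$genotype_major)
  gs <- genotype_summary(gmaj, phen, site_label = "17")
  rk <- rank_dominant(gs, gs[gs$label == "family", ])
  expect_equal(rk$label[1], "17GG")
  expect_equal(rk$advantage_pp[1], 77.59 - 58.37)
  expect_false(any(rk$label == "family"))
  # equal frequencies rank stably by label
  s <- data.frame(label = c("bb", "aa"), n = c(20, 20),
                  n_over_threshold = c(10, 10),
                  frequency_over_threshold = c(50, 50),
                  mean_length = c(1, 1), sd_length = c(0, 0),
                  mean_weight = c(5, 5), sd_weight = c(0, 0))
  fam <- s[1, ]; fam$label <- "family"
  expect_equal(rank_dominant(s, fam)$label, c("aa", "bb"))
  # small classes are flagged
  s$n[1] <- 5
  rk2 <- rank_dominant(s, fam)
  expect_true(rk2$small_sample[rk2$label == "bb"])
  expect_false(rk2$small_sample[rk2$label == "aa"])
})

test_that("significance letters separate clearly different groups", {
  withr::with_seed(65, {
    g <- rep(c("GG", "TG", "TT"), each = 60)
    v <- rnorm(180, rep(c(900, 750, 420), each = 60), 80)
    phen <- data.frame(individual_id = sprintf("i%03d", 1:180),
                       weight_g = v, length_mm = rep(100, 180))
    gdf <- data.frame(individual_id = phen$individual_id, genotype = g)
    gs <- genotype_summary(gdf, phen, site_label = "", letters = TRUE)
    lw <- gs$letters_weight[match(c("GG", "TG", "TT"), gs$label)]
    expect_equal(lw, c("A", "B", "C"))
  })
})

test_that("frequency-distribution table conserves counts", {
  withr::with_seed(66, {
    w <- c(rnorm(100, 200, 40), rnorm(100, 900, 60))
    tab <- frequency_distribution(w, subgroup = w > 600, binwidth = 50)
    expect_equal(sum(tab$n_family), 200)
    expect_equal(sum(tab$n_subgroup), sum(w > 600))
  })
})
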