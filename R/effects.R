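# Verification stage: subgroup splitting, one-way ANOVA per locus, and
# genotype / two-locus genotype-combination summaries ranking dominant
# genotypes by the proportion of carriers above a body-weight threshold.

# prominent local maxima of a kernel density estimate (height >= 10% of
# the tallest), and the deepest valley between a consecutive pair of them
.find_modes <- function(x) {
  d <- stats::density(x) # Gaussian kernel, Silverman's rule-of-thumb bw
  peaks <- which(diff(sign(diff(d$y))) == -2) + 1L
  peaks <- peaks[d$y[peaks] >= 0.1 * max(d$y[peaks])]
  if (length(peaks) < 2L) {
    return(list(n_modes = length(peaks),
                modes = d$x[peaks], heights = d$y[peaks],
                valley_x = NA_real_, valley_y = NA_real_,
                valley_ratio = NA_real_, density = d))
  }
  best <- NULL
  for (i in seq_len(length(peaks) - 1L)) {
    seg <- seq(peaks[i], peaks[i + 1])
    vi <- seg[which.min(d$y[seg])]
    ratio <- d$y[vi] / min(d$y[peaks[i]], d$y[peaks[i + 1]])
    if (is.null(best) || ratio < best$valley_ratio) {
      best <- list(pair = c(peaks[i], peaks[i + 1]), vi = vi,
                   valley_ratio = ratio)
    }
  }
  list(
    n_modes = length(peaks),
    modes = d$x[best$pair], heights = d$y[best$pair],
    valley_x = d$x[best$vi], valley_y = d$y[best$vi],
    valley_ratio = best$valley_ratio,
    density = d
  )
}

# split a single trait vector; returns threshold & mode info, or NULL when
# the distribution looks unimodal. The valley must dip below 90% of the
# flanking peak heights to count as a real separation.
.split_one <- function(x, min_gap_n = 30L, max_valley_ratio = 0.9) {
  n <- length(x)
  if (n < min_gap_n) {
    # tiny-n fallback: midpoint of the largest gap in sorted values
    s <- sort(x)
    gaps <- diff(s)
    i <- which.max(gaps)
    return(list(threshold = (s[i] + s[i + 1]) / 2,
                modes = c(s[1], s[n]), method = "largest-gap"))
  }
  mm <- .find_modes(x)
  if (mm$n_modes < 2L || mm$valley_ratio > max_valley_ratio) return(NULL)
  # refine: threshold at the midpoint of the largest inter-point gap in the
  # low-density region between the two modes (keeps max(slow) < min(fast))
  inside <- sort(x[x > mm$modes[1] & x < mm$modes[2]])
  if (length(inside) >= 2L) {
    gaps <- diff(inside)
    i <- which.max(gaps)
    thr <- (inside[i] + inside[i + 1]) / 2
  } else {
    thr <- mm$valley_x
  }
  list(threshold = thr, modes = mm$modes, valley = mm$valley_x,
       method = "kde-valley")
}

#' Split a bimodal family into fast- and slow-growing subgroups
#'
#' Finds the two largest modes of the body-weight kernel density estimate
#' and places the threshold in the low-density valley between them (at the
#' midpoint of the largest gap between observed weights, so every slow
#' individual weighs less than every fast one). Clearly unimodal
#' distributions give a flagged no-split result. The same rule is applied
#' to body length for reporting.
#'
#' @param phen data frame with `individual_id`, `weight_g`, `length_mm`.
#' @return list of class `split_result`: `split` (logical), `labels`
#'   (`fast`/`slow` per individual, NA when no split), `threshold_weight`,
#'   `threshold_length`, `modes_weight`, `method`, and per-subgroup
#'   weight/length ranges and means.
#' @export
split_subgroups <- function(phen) {
  if (nrow(phen) < 20L) stopf("need at least 20 individuals to split")
  w <- phen$weight_g
  sw <- .split_one(w)
  if (is.null(sw)) {
    return(structure(list(
      split = FALSE, labels = rep(NA_character_, nrow(phen)),
      threshold_weight = NA_real_, threshold_length = NA_real_,
      modes_weight = NULL, method = "no-split"
    ), class = "split_result"))
  }
  labels <- ifelse(w > sw$threshold, "fast", "slow")
  sl <- .split_one(phen$length_mm)
  summarise <- function(v, lab) {
    list(range = range(v[labels == lab]), mean = mean(v[labels == lab]))
  }
  structure(list(
    split = TRUE,
    labels = labels,
    threshold_weight = sw$threshold,
    threshold_length = if (is.null(sl)) NA_real_ else sl$threshold,
    modes_weight = sw$modes,
    method = sw$method,
    fast = list(weight = summarise(w, "fast"),
                length = summarise(phen$length_mm, "fast")),
    slow = list(weight = summarise(w, "slow"),
                length = summarise(phen$length_mm, "slow"))
  ), class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  if (!x$split) {
    cat("No split: phenotype distribution judged unimodal\n")
    return(invisible(x))
  }
  cat(sprintf(
    "Split at %.2f g (%s): %d fast (%.2f-%.2f g), %d slow (%.2f-%.2f g)\n",
    x$threshold_weight, x$method,
    sum(x$labels == "fast"), x$fast$weight$range[1], x$fast$weight$range[2],
    sum(x$labels == "slow"), x$slow$weight$range[1], x$slow$weight$range[2]
  ))
  invisible(x)
}

#' One-way ANOVA of a trait across genotype groups
#'
#' Classical equal-variance one-way analysis of variance; groups with
#' fewer than 2 observations are excluded with a warning, and fewer than
#' two usable groups gives an untestable result instead of an error.
#'
#' @param values numeric trait values.
#' @param groups group labels (genotypes), same length.
#' @return list with `f_stat`, `p`, `df`, `group_means`, `untestable`.
#' @export
one_way_anova <- function(values, groups) {
  groups <- as.character(groups)
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- groups[keep]
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0) {
    warnf("excluding group(s) with < 2 observations: %s",
          paste(small, collapse = ", "))
    keep2 <- !(groups %in% small)
    values <- values[keep2]
    groups <- groups[keep2]
  }
  if (length(unique(groups)) < 2L) {
    return(list(f_stat = NA_real_, p = NA_real_, df = c(NA, NA),
                group_means = tapply(values, groups, mean),
                untestable = TRUE))
  }
  if (stats::var(values) == 0) {
    k <- length(unique(groups))
    return(list(f_stat = 0, p = 1, df = c(k - 1L, length(values) - k),
                group_means = tapply(values, groups, mean),
                untestable = FALSE))
  }
  fit <- stats::oneway.test(values ~ factor(groups), var.equal = TRUE)
  list(
    f_stat = unname(fit$statistic),
    p = unname(fit$p.value),
    df = unname(c(fit$parameter[1], fit$parameter[2])),
    group_means = tapply(values, groups, mean),
    untestable = FALSE
  )
}

# connected-letters display from pairwise Welch tests with Bonferroni
# correction (the published tables mark significance groups with letters;
# the exact post-hoc procedure behind them is a stated stand-in here)
.welch_letters <- function(values, groups, alpha = 0.01) {
  labs <- names(sort(tapply(values, groups, mean), decreasing = TRUE))
  k <- length(labs)
  if (k == 1L) return(stats::setNames("A", labs))
  differs <- matrix(FALSE, k, k, dimnames = list(labs, labs))
  n_tests <- k * (k - 1) / 2
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      vi <- values[groups == labs[i]]
      vj <- values[groups == labs[j]]
      p <- tryCatch(stats::t.test(vi, vj)$p.value, error = function(e) 1)
      differs[i, j] <- differs[j, i] <- (min(p * n_tests, 1) < alpha)
    }
  }
  # insert-and-absorb: grow letter groups of mutually non-different means
  groups_list <- list()
  for (i in seq_len(k)) {
    placed <- FALSE
    for (g in seq_along(groups_list)) {
      if (!any(differs[i, groups_list[[g]]])) {
        groups_list[[g]] <- c(groups_list[[g]], i)
        placed <- TRUE
      }
    }
    if (!placed) groups_list[[length(groups_list) + 1L]] <- i
  }
  letters_out <- stats::setNames(rep("", k), labs)
  for (g in seq_along(groups_list)) {
    for (i in groups_list[[g]]) {
      letters_out[i] <- paste0(letters_out[i], LETTERS[g])
    }
  }
  letters_out
}

.summarise_class <- function(label, w, l, threshold) {
  n <- length(w)
  n_over <- sum(w > threshold)
  data.frame(
    label = label,
    n = n,
    n_over_threshold = n_over,
    frequency_over_threshold = round(100 * n_over / n, 2),
    mean_length = mean(l), sd_length = stats::sd(l),
    mean_weight = mean(w), sd_weight = stats::sd(w),
    stringsAsFactors = FALSE
  )
}

#' Genotype class summaries at one site
#'
#' For each genotype class: n, the number and percentage of carriers with
#' body weight strictly above `weight_threshold`, and mean +/- sd of
#' weight and length; a family-wide row over all phenotyped individuals
#' is included first. Percentages are reported to 2 decimals.
#'
#' @param genotypes data frame with `individual_id` and `genotype` (class
#'   labels, e.g. "GG"; NA = missing, excluded), or a named dosage vector
#'   combined with `ref`/`alt`.
#' @param phen phenotype data frame (`individual_id`, `weight_g`,
#'   `length_mm`).
#' @param site_label prefix for class labels (e.g. `"17"` giving "17GG").
#' @param weight_threshold body weight cut, strictly exceeded (g).
#' @param ref,alt allele letters used when `genotypes` is a dosage vector.
#' @param letters add ANOVA-style significance letter groupings (pairwise
#'   Welch tests, Bonferroni at 0.01) for weight and length.
#' @return data frame of `SubgroupSummary` rows (family row first).
#' @export
genotype_summary <- function(genotypes, phen, site_label = "",
                             weight_threshold = 500, ref = NULL, alt = NULL,
                             letters = FALSE) {
  if (!is.data.frame(genotypes)) {
    genotypes <- data.frame(
      individual_id = names(genotypes),
      genotype = genotype_label(genotypes, ref, alt),
      stringsAsFactors = FALSE
    )
  }
  fam <- .summarise_class("family", phen$weight_g, phen$length_mm,
                          weight_threshold)
  df <- merge(genotypes, phen, by = "individual_id")
  df <- df[!is.na(df$genotype), , drop = FALSE]
  classes <- sort(unique(df$genotype))
  rows <- lapply(classes, function(g) {
    sel <- df$genotype == g
    .summarise_class(paste0(site_label, g), df$weight_g[sel],
                     df$length_mm[sel], weight_threshold)
  })
  out <- do.call(rbind, c(list(fam), rows))
  if (letters && length(classes) >= 2L) {
    lw <- .welch_letters(df$weight_g, paste0(site_label, df$genotype))
    ll <- .welch_letters(df$length_mm, paste0(site_label, df$genotype))
    out$letters_weight <- c("", lw[out$label[-1]])
    out$letters_length <- c("", ll[out$label[-1]])
  }
  rownames(out) <- NULL
  out
}

#' Two-locus genotype-combination summaries
#'
#' Individuals with calls at both sites are grouped into the (up to nine)
#' observed two-locus classes, labelled
#' `"<siteA><gtA> + <siteB><gtB>"`, and summarised as in
#' [genotype_summary()]; the family-wide row uses all phenotyped
#' individuals.
#'
#' @param genotypes_a,genotypes_b per-site genotype data frames
#'   (`individual_id`, `genotype`) or dosage vectors (see
#'   [genotype_summary()]).
#' @param phen phenotype data frame.
#' @param labels length-2 site label prefixes (e.g. `c("17", "14")`).
#' @param ref_a,alt_a,ref_b,alt_b allele letters for dosage-vector input.
#' @inheritParams genotype_summary
#' @return data frame of combination `SubgroupSummary` rows (family row
#'   first).
#' @export
combination_summary <- function(genotypes_a, genotypes_b, phen,
                                labels = c("A", "B"),
                                weight_threshold = 500,
                                ref_a = NULL, alt_a = NULL,
                                ref_b = NULL, alt_b = NULL) {
  as_df <- function(g, ref, alt) {
    if (is.data.frame(g)) return(g)
    data.frame(individual_id = names(g),
               genotype = genotype_label(g, ref, alt),
               stringsAsFactors = FALSE)
  }
  ga <- as_df(genotypes_a, ref_a, alt_a)
  gb <- as_df(genotypes_b, ref_b, alt_b)
  names(ga)[names(ga) == "genotype"] <- "genotype_a"
  names(gb)[names(gb) == "genotype"] <- "genotype_b"
  df <- merge(merge(ga, gb, by = "individual_id"), phen, by = "individual_id")
  df <- df[!is.na(df$genotype_a) & !is.na(df$genotype_b), , drop = FALSE]
  df$combo <- paste0(labels[1], df$genotype_a, " + ", labels[2], df$genotype_b)
  fam <- .summarise_class("family", phen$weight_g, phen$length_mm,
                          weight_threshold)
  rows <- lapply(sort(unique(df$combo)), function(g) {
    sel <- df$combo == g
    .summarise_class(g, df$weight_g[sel], df$length_mm[sel], weight_threshold)
  })
  out <- do.call(rbind, c(list(fam), rows))
  rownames(out) <- NULL
  out
}

#' Rank dominant genotypes
#'
#' Orders genotype / combination classes by the percentage of carriers
#' exceeding the weight threshold (descending; ties broken by mean weight,
#' then label), annotating each with its percentage-point advantage over
#' the family-wide rate. Classes below `min_n` carriers are flagged
#' `small_sample` and should not support statistical claims.
#'
#' @param summaries summary rows from [genotype_summary()] and/or
#'   [combination_summary()] (family rows are ignored).
#' @param family_summary the family-wide summary row (label "family").
#' @param min_n minimum class size for statistical claims.
#' @return ordered data frame with `advantage_pp` and `small_sample`
#'   columns added.
#' @export
rank_dominant <- function(summaries, family_summary, min_n = 10) {
  fam_freq <- family_summary$frequency_over_threshold[1]
  cls <- summaries[summaries$label != "family", , drop = FALSE]
  cls$advantage_pp <- cls$frequency_over_threshold - fam_freq
  cls$small_sample <- cls$n < min_n
  ord <- order(-cls$frequency_over_threshold, -cls$mean_weight, cls$label)
  out <- cls[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Frequency-distribution histogram table
#'
#' Binned counts of a trait for the whole family and optionally a
#' highlighted subgroup, mirroring the frequency-distribution figures used
#' to display bimodal growth.
#'
#' @param values numeric trait vector.
#' @param subgroup optional logical vector marking the highlighted class.
#' @param binwidth bin width in trait units.
#' @return data frame with `bin_mid`, `n_family`, `n_subgroup`.
#' @export
frequency_distribution <- function(values, subgroup = NULL, binwidth = 50) {
  breaks <- seq(floor(min(values) / binwidth) * binwidth,
                ceiling(max(values) / binwidth) * binwidth, by = binwidth)
  h <- graphics::hist(values, breaks = breaks, plot = FALSE)
  out <- data.frame(bin_mid = h$mids, n_family = h$counts)
  if (!is.null(subgroup)) {
    hs <- graphics::hist(values[subgroup], breaks = breaks, plot = FALSE)
    out$n_subgroup <- hs$counts
  }
  out
}
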