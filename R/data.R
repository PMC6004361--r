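# Worked-example data: published genotype-class counts from a transgenic
# common carp full-sib growth study (442 offspring; a major growth locus
# with genotypes GG/TG/TT and a helper locus with CC/CT/TT).

#' Genotype-class counts of the carp growth worked example
#'
#' Two-locus genotype-combination counts for 442 full-sib transgenic carp:
#' class size and the number of carriers with body weight above 500 g.
#' Single-locus margins follow by summation (e.g. the major-locus GG class
#' has 27 + 61 + 28 = 116 carriers, 90 of them above 500 g).
#'
#' @return data frame with `genotype_major` (GG/TG/TT),
#'   `genotype_helper` (CC/CT/TT), `n`, `n_over_500`.
#' @export
growth_class_counts <- function() {
  data.frame(
    genotype_major = rep(c("GG", "TG", "TT"), each = 3),
    genotype_helper = rep(c("CC", "CT", "TT"), times = 3),
    n = c(27L, 61L, 28L, 67L, 110L, 50L, 23L, 52L, 24L),
    n_over_500 = c(23L, 42L, 25L, 42L, 67L, 29L, 7L, 18L, 5L),
    stringsAsFactors = FALSE
  )
}

#' Expand class counts into per-individual records
#'
#' Reconstructs a per-individual table from class summary counts: each
#' class contributes `n` individuals, `n_over_500` of them with a weight
#' above the 500 g threshold. Weights and lengths are placeholder values
#' on the correct side of the threshold; only counts and threshold
#' frequencies are meaningful in the expansion.
#'
#' @param counts a table shaped like [growth_class_counts()].
#' @param over_weight,under_weight placeholder weights (g) for carriers
#'   above / below the threshold.
#' @param over_length,under_length placeholder lengths (mm).
#' @return data frame with `individual_id`, `genotype_major`,
#'   `genotype_helper`, `weight_g`, `length_mm`.
#' @export
expand_class_counts <- function(counts, over_weight = 750,
                                under_weight = 250,
                                over_length = 320, under_length = 200) {
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    n <- counts$n[i]
    k <- counts$n_over_500[i]
    data.frame(
      genotype_major = rep(counts$genotype_major[i], n),
      genotype_helper = rep(counts$genotype_helper[i], n),
      weight_g = c(rep(over_weight, k), rep(under_weight, n - k)),
      length_mm = c(rep(over_length, k), rep(under_length, n - k)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- cbind(
    individual_id = sprintf("ind%03d", seq_len(nrow(out))),
    out,
    stringsAsFactors = FALSE
  )
  out
}
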