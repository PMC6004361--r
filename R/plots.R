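# Plotting helpers (ggplot2).

#' Manhattan plot of an association scan
#'
#' Sites are placed at uniform spacing in input (gene) order; the y axis
#' is -log10(p). Dashed reference lines mark p = 0.05 and p = 0.1.
#'
#' @param results results data frame from [association_scan()].
#' @return a ggplot object.
#' @export
plot_manhattan <- function(results) {
  df <- results[!is.na(results$p), , drop = FALSE]
  df$x <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = neglog10p)) +
    ggplot2::geom_point(colour = "steelblue4") +
    ggplot2::geom_hline(yintercept = -log10(c(0.05, 0.1)),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_x_continuous(breaks = df$x, labels = df$site_id) +
    ggplot2::labs(x = "SNP locus (uniform spacing, gene order)",
                  y = expression(-log[10](italic(p)))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Frequency-distribution plot of body weight
#'
#' Family-wide histogram with an optional highlighted genotype subgroup,
#' the display used to show bimodal growth separation.
#'
#' @param phen phenotype data frame with `weight_g`.
#' @param subgroup optional logical vector marking highlighted
#'   individuals.
#' @param binwidth histogram bin width (g).
#' @return a ggplot object.
#' @export
plot_weight_distribution <- function(phen, subgroup = NULL, binwidth = 50) {
  tab <- frequency_distribution(phen$weight_g, subgroup, binwidth)
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = bin_mid,
                                         y = n_family)) +
    ggplot2::geom_col(fill = "lightblue2", colour = "grey30",
                      width = binwidth) +
    ggplot2::labs(x = "Body weight (g)", y = "Frequency") +
    ggplot2::theme_minimal()
  if (!is.null(subgroup)) {
    p <- p + ggplot2::geom_point(
      data = tab[tab$n_subgroup > 0, , drop = FALSE],
      ggplot2::aes(y = n_subgroup), colour = "red", size = 2
    )
  }
  p
}
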