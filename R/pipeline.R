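# End-to-end pipeline on one synthetic family: pools -> Fst scan ->
# candidate annotation -> amplicon genotyping of a candidate panel ->
# mixed-model association -> genotype-effect summaries.

#' Synthetic exon features for a marker panel
#'
#' Places every marker inside the exon of its own synthetic gene, so scan
#' hits can be carried through candidate annotation.
#'
#' @param markers marker metadata (`marker_id`, `contig`, `pos`).
#' @param halfwidth exon half-width in bases.
#' @return gene-feature data frame for [annotate_candidates()].
#' @export
make_gene_features <- function(markers, halfwidth = 200) {
  data.frame(
    gene_id = paste0("gene_", markers$marker_id),
    contig = markers$contig,
    start = pmax(markers$pos - halfwidth, 1),
    end = markers$pos + halfwidth,
    feature_kind = "exon",
    strand = "+",
    stringsAsFactors = FALSE
  )
}

#' Run the full growth-mapping pipeline on a synthetic family
#'
#' Simulates a family, builds the fast/slow bulks and their pooled read
#' counts, runs the Fst scan and exon/promoter candidate annotation,
#' re-genotypes a panel of top-Fst candidate sites by barcoded amplicon
#' sequencing (read generation, demultiplexing, pileup, genotype calls,
#' MAF/call-rate filters), scans the panel with the kinship mixed model
#' for both traits, and summarises genotype effects at the top weight
#' locus.
#'
#' @param config a [sim_config()].
#' @param panel_size number of top-Fst sites carried into amplicon
#'   re-genotyping.
#' @param features optional gene features (defaults to one synthetic exon
#'   per marker).
#' @return list with the family, pool tables, `fst` (full table), `hits`
#'   (filtered scan), `candidates`, the demux `report`, filtered genotype
#'   matrix, both association scans, the top-locus effect `summary` and
#'   `ranking`, and the causal major locus' `rank_fst` / `rank_mlm`.
#' @export
run_growth_pipeline <- function(config, panel_size = 12, features = NULL) {
  fam <- simulate_family(config)
  pools <- simulate_pool_counts(fam)
  fst <- fst_table(pools$fast, pools$slow)
  hits <- fst_scan(pools$fast, pools$slow)
  if (is.null(features)) features <- make_gene_features(fam$markers)
  candidates <- annotate_candidates(hits, features)
  major_site <- fam$markers$site_id[fam$causal["major"]]
  rank_fst <- match(major_site, fst$site_id[order(-fst$fst, na.last = TRUE)])

  # panel: candidate sites topped up to panel_size by Fst rank
  ord <- order(-fst$fst, na.last = TRUE)
  panel_sites <- unique(c(
    intersect(fst$site_id[ord], candidates$sites$site_id),
    fst$site_id[ord]
  ))[seq_len(min(panel_size, nrow(fst)))]
  panel <- fam$markers[match(panel_sites, fam$markers$site_id), ,
                       drop = FALSE]

  scheme <- make_barcode_scheme(rownames(fam$genotypes),
                                seed = config$seed + 3L)
  targets <- make_amplicon_targets(panel, seed = config$seed + 4L)
  reads <- generate_amplicon_reads(fam, scheme, targets)
  dm <- demux(reads, scheme = scheme)
  geno <- genotype_samples(dm$assignments, targets,
                           sample_ids = rownames(fam$genotypes))
  geno <- filter_sites(geno)
  phen <- fam$phenotypes

  K <- centered_ibs_kinship(geno)
  scan_weight <- association_scan(geno, phen$weight_g, K)
  scan_length <- association_scan(geno, phen$length_mm, K)

  major_marker <- fam$markers$marker_id[fam$causal["major"]]
  res_w <- scan_weight$results
  ok <- !is.na(res_w$p)
  rank_mlm <- match(major_marker, res_w$site_id[ok][order(res_w$p[ok])])

  top_marker <- res_w$site_id[ok][which.min(res_w$p[ok])]
  tidx <- match(top_marker, targets$amplicon_id)
  summary <- genotype_summary(
    stats::setNames(geno[, top_marker], rownames(geno)), phen,
    site_label = "", weight_threshold = 500,
    ref = targets$ref[tidx], alt = targets$alt[tidx]
  )
  ranking <- rank_dominant(summary, summary[summary$label == "family", ])

  list(
    family = fam, pools = pools, fst = fst, hits = hits,
    candidates = candidates, demux_report = dm$report,
    genotypes = geno, scan_weight = scan_weight, scan_length = scan_length,
    summary = summary, ranking = ranking,
    major_marker = major_marker, top_marker = top_marker,
    rank_fst = rank_fst, rank_mlm = rank_mlm
  )
}
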