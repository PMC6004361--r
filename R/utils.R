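#' @keywords internal
"_PACKAGE"

BASES <- c("A", "C", "G", "T")

# random DNA strings, one per element of n
random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(BASES, len, replace = TRUE), collapse = "")
  }, character(1))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

complement_base <- function(x) {
  chartr("ACGT", "TGCA", x)
}

# substitute a different random base at (string index, position) pairs
substitute_bases <- function(seqs, idx, pos) {
  for (k in seq_along(idx)) {
    i <- idx[k]
    p <- pos[k]
    old <- substr(seqs[i], p, p)
    new <- sample(setdiff(BASES, old), 1L)
    substr(seqs[i], p, p) <- new
  }
  seqs
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

# genotype string for an alt-allele dosage: 0 -> ref/ref, 1 -> ref/alt, 2 -> alt/alt
#' Genotype label from alt-allele dosage
#'
#' Formats a diploid genotype as the two allele letters, reference allele
#' first for heterozygotes (e.g. ref "T", alt "G": dosage 1 is "TG").
#'
#' @param dosage integer vector of alt-allele dosages (0, 1, 2 or NA).
#' @param ref,alt single reference / alternative allele characters.
#' @return character vector of two-letter genotype labels (NA preserved).
#' @export
genotype_label <- function(dosage, ref, alt) {
  out <- rep(NA_character_, length(dosage))
  out[!is.na(dosage) & dosage == 0] <- paste0(ref, ref)
  out[!is.na(dosage) & dosage == 1] <- paste0(ref, alt)
  out[!is.na(dosage) & dosage == 2] <- paste0(alt, alt)
  out
}
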