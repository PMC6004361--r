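# shared fixture builders (everything is generated in code at test time)

small_family <- function(n = 60, m = 8, seed = 11, ...) {
  simulate_family(sim_config(
    n_offspring = n, n_markers = m, pool_size = max(2, n %/% 6),
    seed = seed, ...
  ))
}

# pool-count table from explicit count rows (matrix with columns A,C,G,T)
pool_table <- function(counts, contig = "LG1") {
  if (!is.matrix(counts)) counts <- matrix(counts, ncol = 4, byrow = TRUE)
  data.frame(
    site_id = sprintf("s%03d", seq_len(nrow(counts))),
    contig = contig,
    pos = seq_len(nrow(counts)) * 100L,
    ref = "A", alt = "C",
    nA = counts[, 1], nC = counts[, 2], nG = counts[, 3], nT = counts[, 4],
    stringsAsFactors = FALSE
  )
}

# independent direct-formula Fst (oracle; kept deliberately naive)
oracle_fst <- function(c1, c2) {
  f1 <- c1 / sum(c1)
  f2 <- c2 / sum(c2)
  pi1 <- 1 - sum(f1^2)
  pi2 <- 1 - sum(f2^2)
  piw <- (pi1 + pi2) / 2
  pit <- 1 - sum(((f1 + f2) / 2)^2)
  if (pit == 0) return(NA_real_)
  (pit - piw) / pit
}
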