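# Mixed linear model association with a centered-IBS kinship.
#
# Model per marker:  y = mu + beta * dosage + g + e,
#   g ~ N(0, sigma_g^2 K),  e ~ N(0, sigma_e^2 I).
# Variance components are REML-estimated once under the null (P3D,
# "population parameters previously determined") via a one-dimensional
# search over the variance ratio on the eigenbasis of K, then held fixed
# for every marker's generalised-least-squares F test.

#' Centered-IBS kinship matrix
#'
#' Genotype dosages (0/1/2 alt-allele counts) are imputed to the site mean
#' where missing, centered per site, and cross-multiplied; the product is
#' scaled by the mean of its diagonal so that `mean(diag(K)) = 1`.
#'
#' @param geno dosage matrix, individuals x sites.
#' @return symmetric positive semidefinite kinship matrix with unit mean
#'   diagonal.
#' @export
centered_ibs_kinship <- function(geno) {
  if (nrow(geno) < 2L || ncol(geno) < 1L) {
    stopf("kinship needs at least 2 individuals and 1 site")
  }
  X <- apply(geno, 2, function(x) {
    mu <- mean(x, na.rm = TRUE)
    x[is.na(x)] <- mu
    x - mu
  })
  P <- tcrossprod(X)
  cc <- mean(diag(P))
  if (cc <= 0) stopf("all sites monomorphic: kinship undefined")
  K <- P / cc
  dimnames(K) <- list(rownames(geno), rownames(geno))
  K
}

# REML log-likelihood machinery on the eigenbasis of K.
# X: fixed-effect design; returns the profiled fit at variance ratio
# lambda = sigma_e^2 / sigma_g^2.
.reml_profile <- function(lambda, yt, Xt, d) {
  n <- length(yt)
  q <- ncol(Xt)
  w <- 1 / (d + lambda)
  XtW <- Xt * w
  A <- crossprod(Xt, XtW)
  beta <- solve(A, crossprod(XtW, yt))
  r <- yt - Xt %*% beta
  rss <- sum(w * r^2)
  s2g <- rss / (n - q)
  ll <- -0.5 * ((n - q) * log(2 * pi * s2g) + (n - q) +
                  sum(log(d + lambda)) + determinant(A)$modulus)
  list(ll = as.numeric(ll), s2g = s2g, beta = beta)
}

.reml_fit <- function(y, X, eig) {
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  yt <- crossprod(U, y)
  Xt <- crossprod(U, X)
  obj <- function(loglam) -.reml_profile(exp(loglam), yt, Xt, d)$ll
  opt <- stats::optimize(obj, interval = c(-14, 14), tol = 1e-8)
  # guard against boundary optima (sigma_g -> 0 or sigma_e -> 0)
  cand <- c(opt$minimum, -14, 14)
  vals <- vapply(cand, obj, numeric(1))
  loglam <- cand[which.min(vals)]
  if (!all(is.finite(vals))) stopf("REML did not converge (non-finite likelihood)")
  fit <- .reml_profile(exp(loglam), yt, Xt, d)
  lambda <- exp(loglam)
  list(
    sigma_g2 = fit$s2g,
    sigma_e2 = fit$s2g * lambda,
    lambda = lambda,
    loglik = fit$ll,
    eigen = list(values = d, vectors = U)
  )
}

#' Fit the null mixed model once (P3D)
#'
#' REML estimates of the variance components of `y = mu + g + e` with
#' `g ~ N(0, sigma_g^2 K)`, via eigendecomposition of K and a
#' one-dimensional search over the variance ratio. The estimates (and the
#' eigendecomposition) are reused unchanged by every marker test.
#'
#' @param phenotype numeric vector, finite, same order as `K` rows.
#' @param K kinship matrix from [centered_ibs_kinship()].
#' @return list with `sigma_g2`, `sigma_e2`, `lambda`
#'   (`sigma_e2 / sigma_g2`), `loglik` and the cached `eigen` pieces.
#' @export
fit_null_p3d <- function(phenotype, K) {
  stopifnot(is.numeric(phenotype), all(is.finite(phenotype)),
            length(phenotype) == nrow(K))
  eig <- eigen(K, symmetric = TRUE)
  .reml_fit(phenotype, matrix(1, length(phenotype), 1L), eig)
}

#' Single-marker generalised least squares test
#'
#' Fits `y = mu + beta * dosage + g + e` with the covariance shape
#' `sigma_g2 * K + sigma_e2 * I` held fixed from the null fit; the
#' residual scale is re-estimated per marker, giving an F test of
#' `beta = 0` on (1, n - 2) degrees of freedom that reduces exactly to the
#' ordinary regression F test when `K = I`. Individuals with a missing
#' dosage are dropped pairwise (K stays fixed; the test subsets it).
#'
#' @param dosage numeric vector of 0/1/2 dosages (NA allowed).
#' @param phenotype numeric vector.
#' @param K kinship matrix.
#' @param vc null-model fit from [fit_null_p3d()].
#' @param site_id label carried into the result.
#' @return one-row data frame: `site_id`, `beta`, `f_stat`, `p`,
#'   `neglog10p`, `n_used`, `sigma_g2`, `sigma_e2`, `flag`
#'   (`ok` or `untestable`).
#' @export
marker_test <- function(dosage, phenotype, K, vc, site_id = NA_character_) {
  cc <- !is.na(dosage)
  n_used <- sum(cc)
  out <- data.frame(
    site_id = site_id, beta = NA_real_, f_stat = NA_real_, p = NA_real_,
    neglog10p = NA_real_, n_used = n_used,
    sigma_g2 = vc$sigma_g2, sigma_e2 = vc$sigma_e2,
    flag = "untestable", stringsAsFactors = FALSE
  )
  if (n_used < 3L || length(unique(dosage[cc])) < 2L) {
    return(out)
  }
  y <- phenotype[cc]
  X <- cbind(1, dosage[cc])
  if (all(cc)) {
    d <- vc$eigen$values
    U <- vc$eigen$vectors
    w <- 1 / (vc$sigma_g2 * d + vc$sigma_e2)
    yt <- crossprod(U, y)
    Xt <- crossprod(U, X)
  } else {
    V <- vc$sigma_g2 * K[cc, cc, drop = FALSE] +
      diag(vc$sigma_e2, n_used)
    e <- eigen(V, symmetric = TRUE)
    w <- 1 / pmax(e$values, 1e-12)
    yt <- crossprod(e$vectors, y)
    Xt <- crossprod(e$vectors, X)
  }
  A <- crossprod(Xt, Xt * w)
  Ainv <- solve(A)
  beta <- Ainv %*% crossprod(Xt * w, yt)
  r <- yt - Xt %*% beta
  s2 <- sum(w * r^2) / (n_used - 2L)
  f_stat <- beta[2]^2 / (s2 * Ainv[2, 2])
  p <- stats::pf(f_stat, 1, n_used - 2L, lower.tail = FALSE)
  out$beta <- beta[2]
  out$f_stat <- f_stat
  out$p <- p
  out$neglog10p <- -log10(p)
  out$flag <- "ok"
  out
}

#' Association scan over a genotype matrix
#'
#' One mixed-model test per site, in input (gene) order, with variance
#' components estimated once under the null (P3D) or, optionally,
#' re-estimated per marker by full REML with the marker in the model
#' (`exact_reml = TRUE`). P values are raw (no multiplicity adjustment);
#' significant sets at the two conventional working thresholds are
#' returned alongside.
#'
#' @param geno dosage matrix (individuals x sites), typically after
#'   [filter_sites()].
#' @param phenotype numeric vector aligned with the matrix rows.
#' @param K optional precomputed kinship (defaults to
#'   [centered_ibs_kinship()] of `geno`).
#' @param exact_reml re-estimate variance components per marker instead of
#'   holding the null estimates fixed.
#' @return list with `results` (one row per site), `significant_05`,
#'   `significant_10` (site ids with p < 0.05 / p < 0.1), and `vc` (the
#'   null fit).
#' @export
association_scan <- function(geno, phenotype, K = NULL, exact_reml = FALSE) {
  stopifnot(nrow(geno) == length(phenotype))
  if (is.null(K)) K <- centered_ibs_kinship(geno)
  vc <- fit_null_p3d(phenotype, K)
  rows <- lapply(seq_len(ncol(geno)), function(j) {
    if (exact_reml) {
      dos <- geno[, j]
      cc <- !is.na(dos)
      if (sum(cc) == nrow(geno) && length(unique(dos)) >= 2L) {
        fitj <- .reml_fit(phenotype, cbind(1, dos), vc$eigen)
        vcj <- list(sigma_g2 = fitj$sigma_g2, sigma_e2 = fitj$sigma_e2,
                    eigen = vc$eigen)
        return(marker_test(dos, phenotype, K, vcj, colnames(geno)[j]))
      }
    }
    marker_test(geno[, j], phenotype, K, vc, colnames(geno)[j])
  })
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  list(
    results = results,
    significant_05 = results$site_id[!is.na(results$p) & results$p < 0.05],
    significant_10 = results$site_id[!is.na(results$p) & results$p < 0.1],
    vc = vc
  )
}
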