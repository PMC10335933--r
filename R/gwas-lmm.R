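#' Filter markers on MAF and missingness
#'
#' Standard GWAS marker QC: keeps markers with minor-allele (or minor-carrier)
#' frequency at least `maf` and missing-call fraction below `miss`.
#'
#' @param geno Dosage matrix, accessions x markers.
#' @param maf Minimum minor allele frequency (default 0.05).
#' @param miss Maximum missing fraction, exclusive (default 0.1).
#' @param ploidy 2 for SNP dosages, 1 for PAV carrier matrices.
#' @return The filtered matrix; removed marker ids in attribute `dropped`.
#' @export
filter_markers <- function(geno, maf = 0.05, miss = 0.1, ploidy = 2) {
  miss_frac <- colMeans(is.na(geno))
  p <- col_means_na(geno) / ploidy
  maf_v <- pmin(p, 1 - p)
  keep <- miss_frac < miss & maf_v >= maf
  out <- geno[, keep, drop = FALSE]
  attr(out, "dropped") <- colnames(geno)[!keep]
  out
}

#' VanRaden-style genomic kinship matrix
#'
#' Centered cross-product kinship
#' `K = Z Z' / (2 sum p (1 - p))` with `Z` the mean-imputed dosage matrix
#' centered by twice the allele frequency. Symmetric positive semi-definite
#' with diagonal mean near 1; zero-variance markers are excluded.
#'
#' @param geno Dosage matrix, accessions x markers (0..2, NA allowed).
#' @return Kinship matrix (accessions x accessions).
#' @export
kinship <- function(geno) {
  Z <- impute_mean(geno)
  p <- colMeans(Z) / 2
  keep <- apply(Z, 2, var) > 0
  if (!any(keep)) {
    warn("no polymorphic markers; kinship is the zero matrix")
    K <- matrix(0, nrow(geno), nrow(geno))
    dimnames(K) <- list(rownames(geno), rownames(geno))
    return(K)
  }
  Z <- Z[, keep, drop = FALSE]; p <- p[keep]
  Zc <- sweep(Z, 2, 2 * p)
  denom <- 2 * sum(p * (1 - p))
  K <- tcrossprod(Zc) / denom
  dimnames(K) <- list(rownames(geno), rownames(geno))
  K
}

#' Leading principal components of a genotype matrix
#'
#' @param geno Dosage matrix (mean-imputed internally).
#' @param n_pc Number of components.
#' @return Matrix of PC scores (accessions x n_pc).
#' @export
genotype_pcs <- function(geno, n_pc = 10) {
  if (n_pc == 0) return(NULL)
  Z <- impute_mean(geno)
  keep <- apply(Z, 2, var) > 0
  pr <- prcomp(Z[, keep, drop = FALSE], center = TRUE, scale. = FALSE,
               rank. = n_pc)
  pr$x[, seq_len(min(n_pc, ncol(pr$x))), drop = FALSE]
}

# REML estimate of delta = sigma_e^2 / sigma_g^2 for y = X b + u + e,
# u ~ N(0, sigma_g^2 K), via the eigendecomposition of K.
reml_delta <- function(yt, Xt, d) {
  n <- length(yt); q <- ncol(Xt)
  loglik <- function(log_delta) {
    delta <- exp(log_delta)
    w <- 1 / (d + delta)
    Xw <- Xt * sqrt(w); yw <- yt * sqrt(w)
    XtX <- crossprod(Xw)
    beta <- solve(XtX, crossprod(Xw, yw))
    r <- yw - Xw %*% beta
    rss <- sum(r^2)
    sigma2 <- rss / (n - q)
    -0.5 * ((n - q) * log(sigma2) - sum(log(w)) +
              determinant(XtX, logarithm = TRUE)$modulus + (n - q))
  }
  grid <- seq(log(1e-5), log(1e5), length.out = 80)
  ll <- vapply(grid, loglik, numeric(1))
  i <- which.max(ll)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- optimize(loglik, c(lo, hi), maximum = TRUE, tol = 1e-8)
  exp(opt$maximum)
}

#' EMMAX-style mixed-model association scan
#'
#' Single-trait genome scan under the linear mixed model
#' `y = X b + g beta + u + e` with `u ~ N(0, sigma_g^2 K)`. Variance
#' components are estimated once on the null model (no marker) by REML using
#' the eigendecomposition of `K`; each marker is then tested by generalized
#' least squares in the whitened space, with the residual scale re-estimated
#' per marker so the test reduces to an exact OLS t-test after whitening
#' (the EMMAX approximation). Principal components enter as fixed covariates.
#'
#' @param geno Filtered dosage matrix (accessions x markers; NA mean-imputed).
#' @param pheno Named numeric phenotype vector (one value per accession) or a
#'   tibble with `accession` and `value` columns.
#' @param K Kinship matrix from [kinship()]; identity gives ordinary least
#'   squares.
#' @param n_pc Number of genotype principal components included as fixed
#'   covariates (default 10).
#' @param info Optional marker info tibble (`id`, `chrom`, `pos`, optionally
#'   `type`) joined onto the result.
#' @return An `assoc_result` tibble: `id`, `maf`, `beta`, `se`, `p` (plus
#'   info columns when given), with attributes `sigma_g2`, `sigma_e2`,
#'   `delta`, `n`, `n_covariates`.
#' @export
lmm_assoc <- function(geno, pheno, K, n_pc = 10, info = NULL) {
  if (is.data.frame(pheno)) {
    pheno <- setNames(pheno$value, pheno$accession)
  }
  if (!is.null(names(pheno)) && !is.null(rownames(geno))) {
    pheno <- pheno[rownames(geno)]
  }
  y <- as.numeric(pheno)
  n <- length(y)
  stopifnot(nrow(geno) == n, nrow(K) == n)

  G <- impute_mean(geno)
  X <- cbind(`(Intercept)` = rep(1, n))
  if (n_pc > 0) {
    pcs <- genotype_pcs(geno, n_pc)
    colnames(pcs) <- paste0("PC", seq_len(ncol(pcs)))
    X <- cbind(X, pcs)
  }
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    abort(paste0("collinear covariate columns: ", paste(bad, collapse = ", ")))
  }

  eig <- eigen(K, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X)
  delta <- reml_delta(yt, Xt, d)

  w <- 1 / sqrt(d + delta)
  yw <- yt * w
  Xw <- Xt * w
  Gw <- crossprod(U, G) * w

  # residualize on covariates (Frisch-Waugh), then per-marker OLS t-test
  qX <- qr(Xw)
  yr <- qr.resid(qX, yw)
  Gr <- qr.resid(qX, Gw)
  gg <- colSums(Gr^2)
  gy <- drop(crossprod(Gr, yr))
  q <- ncol(Xw)
  df <- n - q - 1
  beta <- ifelse(gg > 0, gy / gg, NA_real_)
  rss <- sum(yr^2) - ifelse(gg > 0, beta^2 * gg, 0)
  sigma2 <- rss / df
  se <- sqrt(sigma2 / gg)
  tstat <- beta / se
  pval <- 2 * pt(-abs(tstat), df)

  # variance components on the null model at the REML optimum
  wr2 <- 1 / (d + delta)
  Xw0 <- Xt * sqrt(wr2); yw0 <- yt * sqrt(wr2)
  r0 <- qr.resid(qr(Xw0), yw0)
  sigma_g2 <- sum(r0^2) / (n - q)
  maf_v <- {
    p <- colMeans(G) / 2
    pmin(p, 1 - p)
  }

  out <- tibble(id = colnames(geno) %||% sprintf("m%05d", seq_len(ncol(geno))),
                maf = unname(maf_v), beta = unname(beta), se = unname(se),
                p = unname(pval))
  if (!is.null(info)) out <- left_join(out, info, by = "id")
  attr(out, "sigma_g2") <- sigma_g2
  attr(out, "sigma_e2") <- sigma_g2 * delta
  attr(out, "delta") <- delta
  attr(out, "n") <- n
  attr(out, "n_covariates") <- q
  class(out) <- c("assoc_result", class(out))
  out
}

#' @export
glance.assoc_result <- function(x, ...) {
  tibble(n = attr(x, "n"), n_markers = nrow(x),
         delta = attr(x, "delta"),
         sigma_g2 = attr(x, "sigma_g2"), sigma_e2 = attr(x, "sigma_e2"),
         min_p = min(x$p, na.rm = TRUE))
}
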