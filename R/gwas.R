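#' Genomic relationship matrix (VanRaden method 1)
#'
#' `G = M M' / m` with `M[, k] = (x_k - 2 p_k) / sqrt(2 p_k (1 - p_k))`,
#' missing genotypes mean-imputed per marker and monomorphic markers
#' skipped (logged as an attribute).
#'
#' @param gd a [GenotypeData-class] or a plain 0/1/2 dosage matrix with
#'   sample rownames.
#' @param freqs optional counted-allele frequencies of a reference (base)
#'   population; defaults to the sample frequencies. Sample frequencies
#'   shrink off-diagonals by about 1/n and deflate close relationships when
#'   the sample itself is pedigreed.
#' @return dense symmetric matrix with sample ids as dimnames; attributes
#'   `freqs` (counted-allele frequencies used) and `skipped` (monomorphic
#'   marker ids).
#' @export
computeGRM <- function(gd, freqs = NULL) {
  g <- if (is(gd, "GenotypeData")) genotypes(gd) else as.matrix(gd)
  p <- if (is.null(freqs)) colMeans(g, na.rm = TRUE) / 2 else freqs
  poly <- !is.na(p) & p > 0 & p < 1
  skipped <- colnames(g)[!poly]
  g <- g[, poly, drop = FALSE]; p <- p[poly]
  Mc <- sweep(g, 2, 2 * p)
  Mc[is.na(Mc)] <- 0  # mean imputation: centred value 0 at reference freq
  Mc <- sweep(Mc, 2, sqrt(2 * p * (1 - p)), "/")
  G <- tcrossprod(Mc) / ncol(Mc)
  dimnames(G) <- list(rownames(g), rownames(g))
  structure(G, freqs = p, skipped = skipped)
}

#' Sparsify a GRM by zeroing small off-diagonals
#'
#' Off-diagonal entries strictly below `cutoff` are set to zero (entries
#' exactly at the cutoff are kept); the diagonal is untouched.
#'
#' @param G dense GRM.
#' @param cutoff relatedness threshold (default 0.05).
#' @return sparse symmetric matrix (`dsCMatrix`).
#' @export
sparsifyGRM <- function(G, cutoff = 0.05) {
  Gs <- as.matrix(G)
  d <- diag(Gs)
  Gs[Gs < cutoff] <- 0
  diag(Gs) <- d
  methods::as(methods::as(Gs, "CsparseMatrix"), "symmetricMatrix")
}

#' Proportion of phenotypic variance explained by a SNP
#'
#' `PVE = 2 b^2 q (1-q) / (2 b^2 q (1-q) + se^2 * 2 N q (1-q))`, reported
#' as a percentage; algebraically `b^2 / (b^2 + N se^2)`.
#'
#' @param maf minor allele frequency in (0, 0.5].
#' @param beta estimated allele effect; @param se its standard error;
#' @param n sample size.
#' @return percent of phenotypic variance (vectorised); NA where maf is 0.
#' @examples
#' pve(0.06, 1.47, 0.12, 4808)  # ~3.0
#' @export
pve <- function(maf, beta, se, n) {
  num <- 2 * beta^2 * maf * (1 - maf)
  den <- num + se^2 * 2 * n * maf * (1 - maf)
  out <- 100 * num / den
  out[maf <= 0] <- NA_real_
  out
}

#' Bonferroni genome-wide significance threshold
#'
#' @param m number of markers tested.
#' @return p-value cut-off 0.05 / m.
#' @export
significanceThreshold <- function(m) {
  stopifnot(m >= 1)
  0.05 / m
}

## 1-D REML for y = Xb + g + e, g ~ N(0, Gs s2g), via eigendecomposition of
## the sparse GRM; returns variance components and the rotation.
nullModelREML <- function(y, X, Gs) {
  n <- length(y)
  eg <- eigen(as.matrix(Gs), symmetric = TRUE)
  U <- eg$vectors; lam <- eg$values
  yt <- as.numeric(crossprod(U, y))
  Xt <- crossprod(U, X)
  p <- ncol(X)
  obj <- function(h) {
    w <- h * lam + (1 - h)
    if (any(w < 1e-10)) return(1e30)
    xtwx <- crossprod(Xt, Xt / w)
    b <- solve(xtwx, crossprod(Xt, yt / w))
    r <- yt - Xt %*% b
    rss <- sum(r^2 / w)
    s2 <- rss / (n - p)
    sum(log(w)) + as.numeric(determinant(xtwx, logarithm = TRUE)$modulus) +
      (n - p) * log(s2)
  }
  op <- optimize(obj, c(0, 0.999))
  h <- op$minimum
  w <- h * lam + (1 - h)
  xtwx <- crossprod(Xt, Xt / w)
  b <- solve(xtwx, crossprod(Xt, yt / w))
  s2 <- sum((yt - Xt %*% b)^2 / w) / (n - p)
  list(U = U, lambda = lam, h = h, w = w,
       s2g = h * s2, s2e = (1 - h) * s2, s2 = s2)
}

#' Mixed-model association scan with a sparse GRM
#'
#' Association of a per-individual response (mean ACC per focal individual)
#' with each SNP: a genomic relationship matrix is computed, sparsified at
#' `grmCutoff`, and the null covariance `V = Gs s2g + I s2e` estimated once
#' by REML; each SNP is then tested by generalised least squares of the
#' response on intercept, `nPcs` principal components of the dense GRM and
#' the SNP dosage, with the covariance *shape* held fixed at the null
#' estimate and the overall scale re-estimated per SNP from the GLS
#' residuals (so with an identity GRM the fit reduces exactly to ordinary
#' least squares, including its t-based p-values).
#'
#' @param y named numeric response, one value per genotyped individual
#'   (names matched to genotype sample ids).
#' @param gd a [GenotypeData-class] for the same individuals.
#' @param nPcs number of GRM principal components as covariates.
#' @param grmCutoff sparsification threshold (default 0.05).
#' @param grm optional precomputed dense relationship matrix (defaults to
#'   [computeGRM()] of `gd`); with `grm = diag(n)` and `nPcs = 0` the scan
#'   reduces to per-SNP ordinary least squares.
#' @return data.frame (one row per polymorphic SNP): CHR, SNP, BP, A1
#'   (counted allele, \"B\"), FREQ_A1, BETA, SE, P, PVE_PCT, SIGNIF
#'   (P below 0.05/M), N; attributes `threshold`, `varComponents`.
#' @export
fastgwaFit <- function(y, gd, nPcs = 10, grmCutoff = 0.05, grm = NULL) {
  ids <- sampleIds(gd)
  if (!is.null(names(y))) {
    stopifnot(all(ids %in% names(y)))
    y <- as.numeric(y[ids])
  } else stopifnot(length(y) == length(ids))
  g <- genotypes(gd)
  n <- nrow(g)
  G <- if (is.null(grm)) computeGRM(gd) else as.matrix(grm)
  Gs <- sparsifyGRM(G, cutoff = grmCutoff)
  X <- matrix(1, n, 1)
  if (nPcs > 0) {
    pcs <- eigen(G, symmetric = TRUE)$vectors[, seq_len(nPcs), drop = FALSE]
    X <- cbind(X, pcs)
  }
  nm <- nullModelREML(y, X, Gs)
  U <- nm$U; w <- nm$w
  yt <- as.numeric(crossprod(U, y))
  Xt <- crossprod(U, X)

  p <- colMeans(g, na.rm = TRUE) / 2
  poly <- which(!is.na(p) & p > 0 & p < 1)
  gImp <- g[, poly, drop = FALSE]
  for (k in seq_len(ncol(gImp))) {
    miss <- is.na(gImp[, k])
    if (any(miss)) gImp[miss, k] <- 2 * p[poly[k]]
  }
  Gt <- crossprod(U, gImp)

  M <- length(poly)
  beta <- se <- pv <- numeric(M)
  df <- n - ncol(X) - 1L
  for (k in seq_len(M)) {
    Xs <- cbind(Xt, Gt[, k])
    xtwx <- crossprod(Xs, Xs / w)
    bk <- tryCatch(solve(xtwx, crossprod(Xs, yt / w)),
                   error = function(e) NULL)
    if (is.null(bk)) { beta[k] <- se[k] <- pv[k] <- NA_real_; next }
    r <- yt - Xs %*% bk
    s2 <- sum(r^2 / w) / df
    vb <- s2 * solve(xtwx)[ncol(Xs), ncol(Xs)]
    beta[k] <- bk[length(bk)]
    se[k] <- sqrt(vb)
    pv[k] <- 2 * pt(-abs(beta[k] / se[k]), df)
  }
  mk <- markerInfo(gd)[poly, , drop = FALSE]
  freq <- p[poly]
  maf <- pmin(freq, 1 - freq)
  thr <- significanceThreshold(M)
  out <- data.frame(CHR = mk$chrom, SNP = mk$marker, BP = mk$bp,
                    A1 = "B", FREQ_A1 = freq,
                    BETA = beta, SE = se, P = pv,
                    PVE_PCT = pve(maf, beta, se, n),
                    SIGNIF = !is.na(pv) & pv < thr, N = n,
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- thr
  attr(out, "varComponents") <- c(s2g = nm$s2g, s2e = nm$s2e)
  out
}

#' Mean ACC per focal individual
#'
#' Aggregates the gamete table to one response value per FID (the GWAS
#' response), regardless of how many gametes each FID contributed.
#'
#' @param acc gamete table from [collectACC()]; only `qcPass` rows are used.
#' @return named numeric vector of mean ACC per fid.
#' @export
meanAccPerFid <- function(acc) {
  tab <- acc[acc$qcPass, , drop = FALSE]
  out <- tapply(tab$acc, tab$fid, mean)
  setNames(as.numeric(out), names(out))
}
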