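## Linear mixed model core
##
## Kinship construction and maximum-likelihood machinery shared by the
## association scan, heritability, haplotype-effect and mediation modules.
## The model is y = X b + u + e with u ~ N(0, tau2 K), e ~ N(0, sigma2 I).
## A single eigendecomposition of K reduces every likelihood evaluation to
## O(n) diagonal algebra; the variance ratio is profiled out and maximised
## in one dimension.

#' Kinship matrix from founder dosages
#'
#' `K = (1 / 2L) * sum_m C_m C_m'` over the `L` markers, where `C_m` is the
#' column-centred `n x F` founder-dose matrix at marker `m`, rescaled so
#' the mean diagonal equals 1.  Centring removes the population-mean
#' founder composition (under exchangeable founders every animal averages
#' `2/F` doses of every founder), which would otherwise appear as one
#' large shared eigen-direction and bias the variance-ratio scale; what
#' remains is relatedness variation, the quantity the polygenic model
#' uses.  Positive semi-definite by construction and invariant to founder
#' relabelling.
#'
#' @param dosage a `founder_dosage` object.
#' @param markers optional marker index subset.
#' @param exclude_chrom optional chromosome name(s) to leave out
#'   (leave-one-chromosome-out kinship; off by default, matching the
#'   analysed design).
#' @return `n x n` kinship matrix with animal ids as dimnames.
#' @export
kinship_from_dosages <- function(dosage, markers = NULL,
                                 exclude_chrom = NULL) {
  stopifnot(inherits(dosage, "founder_dosage"))
  dm <- dim(dosage$dose)
  idx <- markers %||% seq_len(dm[2])
  if (!is.null(exclude_chrom)) {
    .assert(!is.null(dosage$markers), "dosage carries no marker table")
    idx <- setdiff(idx, which(dosage$markers$chrom %in% exclude_chrom))
  }
  L <- length(idx)
  .assert(L >= 1, "no markers selected for kinship")
  ## flatten: rows animals, columns (marker, founder) pairs, then centre
  flat <- matrix(aperm(dosage$dose[, idx, , drop = FALSE], c(1, 2, 3)),
                 dm[1], L * dm[3])
  flat <- sweep(flat, 2, colMeans(flat))
  K <- tcrossprod(flat) / (2 * L)
  .assert(mean(diag(K)) > 0, "dosages are constant across animals")
  K <- K / mean(diag(K))
  dimnames(K) <- list(dimnames(dosage$dose)[[1]], dimnames(dosage$dose)[[1]])
  K
}

## eigendecomposition with PSD check; values clipped at zero
.kinship_eigen <- function(K) {
  .assert(is.matrix(K) && nrow(K) == ncol(K), "kinship must be square")
  .assert(max(abs(K - t(K))) < 1e-8, "kinship must be symmetric")
  ev <- eigen(K, symmetric = TRUE)
  .assert(min(ev$values) > -1e-8 * max(abs(ev$values)),
          "kinship is not positive semi-definite (min eigenvalue %g)",
          min(ev$values))
  ev$values <- pmax(ev$values, 0)
  ev
}

## Profile log-likelihood at heritability-ratio h2 (lambda = h2/(1-h2)),
## in the rotated frame: yt = U'y, Xt = U'X, d = eigenvalues of K.
.profile_loglik <- function(h2, yt, Xt, d, REML = FALSE) {
  n <- length(yt)
  p <- ncol(Xt)
  lam <- h2 / (1 - h2)
  v <- lam * d + 1
  w <- 1 / v
  XtW <- Xt * w
  A <- crossprod(XtW, Xt)
  beta <- solve(A, crossprod(XtW, yt))
  r <- yt - Xt %*% beta
  rss <- sum(w * r^2)
  ldet <- sum(log(v))
  rss <- max(rss, 1e-290)   # collinear/duplicated responses: keep ll finite
  if (REML) {
    sigma2 <- rss / (n - p)
    ll <- -0.5 * ((n - p) * log(2 * pi) + (n - p) * log(sigma2) + ldet +
                    determinant(A, logarithm = TRUE)$modulus -
                    determinant(crossprod(Xt), logarithm = TRUE)$modulus +
                    (n - p))
  } else {
    sigma2 <- rss / n
    ll <- -0.5 * (n * log(2 * pi) + n * log(sigma2) + ldet + n)
  }
  list(loglik = as.numeric(ll), beta = drop(beta), sigma2 = sigma2,
       tau2 = lam * sigma2, h2 = h2)
}

#' Fit a linear mixed model by maximum likelihood
#'
#' Maximises the likelihood of `y = X b + u + e`, `u ~ N(0, tau2 K)`,
#' `e ~ N(0, sigma2 I)` via a single eigendecomposition of `K` and 1-D
#' optimisation of the variance ratio `h2 = tau2 / (tau2 + sigma2)` (coarse
#' grid then Brent refinement to 1e-10 on the ratio).  ML is the default so
#' likelihood-ratio tests of fixed effects are valid; REML is available
#' for variance reporting.
#'
#' @param y numeric response (finite, no missing).
#' @param K kinship matrix (or a cached `.kinship_eigen` result via
#'   `eigenK`).
#' @param X covariate matrix; an intercept column is prepended
#'   automatically.  Must be full rank after adding the intercept.
#' @param REML logical; restricted ML instead of ML.
#' @param eigenK optional precomputed eigendecomposition of `K`.
#' @return object of class `lmm_fit`: fixed effects, `tau2`, `sigma2`,
#'   `h2`, `loglik`, and the (rotated) design cache.
#' @export
fit_lmm <- function(y, K, X = NULL, REML = FALSE, eigenK = NULL) {
  .assert(all(is.finite(y)), "y must be finite with no missing values")
  n <- length(y)
  if (is.null(eigenK)) {
    .assert(nrow(K) == n, "length(y) = %d but kinship is %d x %d",
            n, nrow(K), ncol(K))
    eigenK <- .kinship_eigen(K)
  }
  X <- cbind(`(Intercept)` = rep(1, n), X)
  .assert(nrow(X) == n, "X row count does not match y")
  .assert(qr(X)$rank == ncol(X),
          "covariate matrix is rank deficient (%d columns, rank %d)",
          ncol(X), qr(X)$rank)
  U <- eigenK$vectors
  d <- eigenK$values
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X)
  f <- function(h2) .profile_loglik(h2, yt, Xt, d, REML)$loglik
  ## the ratio domain is closed at 0.995 (lambda <= 199) for numerical
  ## stability; coarse grid, then Brent within the bracketing interval
  grid <- seq(0, 0.995, length.out = 53)
  ll <- vapply(grid, f, 0)
  i <- which.max(ll)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-10)
  h2 <- if (opt$objective >= ll[i]) opt$maximum else grid[i]
  for (edge in unique(c(lo, hi))) if (f(edge) > f(h2)) h2 <- edge
  fit <- .profile_loglik(h2, yt, Xt, d, REML)
  .assert(is.finite(fit$loglik), "log-likelihood is not finite")
  structure(list(beta = fit$beta, tau2 = fit$tau2, sigma2 = fit$sigma2,
                 h2 = fit$h2, loglik = fit$loglik, REML = REML,
                 eigenK = eigenK, yt = yt, Xt = Xt, X = X, n = n),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("LMM fit (%s): loglik = %.4f, tau2 = %.4g, sigma2 = %.4g, h2 = %.3f\n",
              if (x$REML) "REML" else "ML", x$loglik, x$tau2, x$sigma2, x$h2))
  invisible(x)
}

## Batched grid profile likelihood for the scan machinery.
##
## yt: n x B rotated phenotypes; Dt: n x M rotated marker doses; Xt: n x p
## rotated covariates; d: kinship eigenvalues; h2_grid: ratio grid shared
## by null and alternative models, so LRT >= 0 by construction.
## Returns ll_null (B) and ll_alt (M x B), each maximised over the grid.
.grid_scan <- function(yt, Dt, Xt, d, h2_grid) {
  n <- nrow(yt)
  B <- ncol(yt)
  M <- ncol(Dt)
  ll_null <- rep(-Inf, B)
  ll_alt <- matrix(-Inf, M, B)
  const <- n * log(2 * pi) + n
  for (h2 in h2_grid) {
    lam <- h2 / (1 - h2)
    v <- lam * d + 1
    s <- 1 / sqrt(v)
    Xs <- Xt * s
    Qs <- qr.Q(qr(Xs))
    Ys <- yt * s
    Yr <- Ys - Qs %*% crossprod(Qs, Ys)
    Ds <- Dt * s
    Dr <- Ds - Qs %*% crossprod(Qs, Ds)
    rss0 <- colSums(Yr^2)
    num <- crossprod(Dr, Yr)            # M x B
    den <- colSums(Dr^2)
    ok <- den > 1e-12 * n
    imp <- num^2 / ifelse(ok, den, Inf)
    rss1 <- pmax(rep(rss0, each = M) - imp, 1e-300)
    ldet <- sum(log(v))
    lln <- -0.5 * (const + n * log(rss0 / n) + ldet)
    lla <- -0.5 * (const + n * log(rss1 / n) + ldet)
    ll_null <- pmax(ll_null, lln)
    ll_alt <- pmax(ll_alt, lla)
  }
  list(ll_null = ll_null, ll_alt = ll_alt)
}
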