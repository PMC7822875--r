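## Genome scan, parametric-bootstrap thresholds and LD support intervals

#' Likelihood-ratio association scan
#'
#' Tests each marker's dose as a single added fixed effect in the LMM and
#' reports `logP = -log10(1 - pchisq(2 * (ll_alt - ll_null), df = 1))`.
#' The variance ratio is re-maximised per marker over a shared dense grid
#' (null and alternative use the same grid, so the LRT is nonnegative by
#' construction; grid resolution contributes < ~0.01 logP at these sample
#' sizes).  The exact ML null fit is attached for bootstrap simulation.
#'
#' @param y phenotype vector (transformed, no missing).
#' @param snp_doses animal x marker matrix of allele doses.
#' @param K kinship matrix.
#' @param X optional covariates (intercept added automatically).
#' @param markers optional data.frame (`marker`, `chrom`, `bp`) describing
#'   the dose columns; defaults to column names.
#' @param h2_grid grid of variance-ratio values (default 200 points on
#'   `[0, 0.995]`, augmented with the null ML estimate).
#' @return object of class `scan_result`: data.frame with `marker`,
#'   `chrom`, `bp`, `lrt`, `logP`, plus attributes `null_fit` and
#'   `h2_grid`.
#' @export
lrt_scan <- function(y, snp_doses, K, X = NULL, markers = NULL,
                     h2_grid = NULL) {
  snp_doses <- as.matrix(snp_doses)
  n <- length(y)
  .assert(nrow(snp_doses) == n, "snp_doses rows must match length(y)")
  if (is.null(markers)) {
    markers <- data.frame(marker = colnames(snp_doses) %||%
                            paste0("m", seq_len(ncol(snp_doses))),
                          chrom = "chr1", bp = seq_len(ncol(snp_doses)),
                          stringsAsFactors = FALSE)
  }
  .assert(nrow(markers) == ncol(snp_doses),
          "markers table must describe every dose column")
  null_fit <- fit_lmm(y, K, X = X)
  if (is.null(h2_grid)) h2_grid <- seq(0, 0.995, length.out = 200)
  h2_grid <- sort(unique(c(h2_grid, null_fit$h2)))
  mono <- apply(snp_doses, 2, function(x) stats::var(x) < 1e-12)
  if (any(mono)) {
    warning(sprintf("%d monomorphic dose column(s); logP set to 0",
                    sum(mono)))
  }
  U <- null_fit$eigenK$vectors
  Dt <- crossprod(U, snp_doses)
  gs <- .grid_scan(matrix(null_fit$yt, ncol = 1), Dt, null_fit$Xt,
                   null_fit$eigenK$values, h2_grid)
  lrt <- pmax(2 * (drop(gs$ll_alt) - gs$ll_null), 0)
  lrt[mono] <- 0
  logP <- -stats::pchisq(lrt, df = 1, lower.tail = FALSE, log.p = TRUE) / log(10)
  out <- data.frame(marker = markers$marker, chrom = markers$chrom,
                    bp = markers$bp, lrt = lrt, logP = logP,
                    stringsAsFactors = FALSE)
  structure(out, class = c("scan_result", "data.frame"),
            null_fit = null_fit, h2_grid = h2_grid)
}

#' Genome-wide significance threshold by parametric bootstrap
#'
#' Simulates `B` phenotype vectors from the fitted null model
#' (`N(X b_hat, tau2_hat K + sigma2_hat I)`), rescans each over the same
#' marker set, records the genome-wide maximum logP, and returns the
#' empirical `(1 - alpha)` quantile (type 7).
#'
#' @param null_fit the `lmm_fit` attached to a [lrt_scan()] result (or any
#'   ML `lmm_fit` of the null model).
#' @param snp_doses the scanned animal x marker dose matrix.
#' @param B number of bootstrap samples (>= 50; default 1000).
#' @param alpha genome-wide error rate (default 0.05).
#' @param seed integer seed.
#' @param h2_grid variance-ratio grid (defaults as in [lrt_scan()]).
#' @return list with `threshold`, `max_logp` (the `B` maxima), `B`,
#'   `alpha`.
#' @export
bootstrap_threshold <- function(null_fit, snp_doses, B = 1000, alpha = 0.05,
                                seed = 1, h2_grid = NULL) {
  stopifnot(inherits(null_fit, "lmm_fit"))
  .assert(B >= 50, "B must be >= 50 (quantile unstable below), got %d", B)
  .assert(alpha > 0 && alpha <= 1, "alpha must lie in (0, 1]")
  snp_doses <- as.matrix(snp_doses)
  set.seed(seed)
  n <- null_fit$n
  d <- null_fit$eigenK$values
  if (is.null(h2_grid)) h2_grid <- seq(0, 0.995, length.out = 200)
  h2_grid <- sort(unique(c(h2_grid, null_fit$h2)))
  ## simulate directly in the rotated frame: U'y ~ N(Xt b, tau2 d + sigma2)
  sd_rot <- sqrt(null_fit$tau2 * d + null_fit$sigma2)
  mu <- drop(null_fit$Xt %*% null_fit$beta)
  Z <- matrix(stats::rnorm(n * B), n, B)
  Yt <- mu + sd_rot * Z
  U <- null_fit$eigenK$vectors
  Dt <- crossprod(U, snp_doses)
  gs <- .grid_scan(Yt, Dt, null_fit$Xt, d, h2_grid)
  lrt <- pmax(sweep(gs$ll_alt, 2, gs$ll_null, "-") * 2, 0)
  logP <- -stats::pchisq(lrt, df = 1, lower.tail = FALSE, log.p = TRUE) / log(10)
  keep <- apply(as.matrix(snp_doses), 2, function(x) stats::var(x) >= 1e-12)
  max_logp <- apply(logP[keep, , drop = FALSE], 2, max)
  list(threshold = stats::quantile(max_logp, 1 - alpha, type = 7,
                                   names = FALSE),
       max_logp = max_logp, B = B, alpha = alpha)
}

#' LD support interval around a scan peak
#'
#' Expands from the peak marker in both directions over consecutive
#' markers of the same chromosome while the squared Pearson correlation of
#' each marker's dose with the peak dose stays at or above `r2_min`,
#' stopping at the first failure on each side.  The interval is the bp
#' span of the retained markers (closed on both ends).
#'
#' @param scan a `scan_result`.
#' @param snp_doses the scanned dose matrix.
#' @param peak marker id or index; default the genome-wide logP maximum.
#' @param r2_min LD threshold (default 0.5).
#' @param threshold optional genome-wide threshold to record.
#' @param trait optional trait name to record.
#' @return object of class `qtl_interval`: list with `trait`, `chrom`,
#'   `peak_marker`, `peak_bp`, `start_bp`, `end_bp`, `peak_logP`,
#'   `threshold`, `r2_min` and the retained `markers`.
#' @export
ld_interval <- function(scan, snp_doses, peak = NULL, r2_min = 0.5,
                        threshold = NA_real_, trait = NA_character_) {
  stopifnot(inherits(scan, "scan_result"))
  snp_doses <- as.matrix(snp_doses)
  if (is.null(peak)) peak <- which.max(scan$logP)
  if (is.character(peak)) peak <- match(peak, scan$marker)
  .assert(length(peak) == 1L && !is.na(peak), "peak marker not found")
  chr <- scan$chrom[peak]
  on_chr <- which(scan$chrom == chr)
  pdose <- snp_doses[, peak]
  .assert(stats::var(pdose) > 0, "peak dose is constant; r2 undefined")
  pos <- match(peak, on_chr)
  r2_with_peak <- function(j) {
    x <- snp_doses[, on_chr[j]]
    if (stats::var(x) < 1e-12) return(0)
    stats::cor(x, pdose)^2
  }
  lo <- pos
  while (lo > 1L && r2_with_peak(lo - 1L) >= r2_min) lo <- lo - 1L
  hi <- pos
  while (hi < length(on_chr) && r2_with_peak(hi + 1L) >= r2_min) hi <- hi + 1L
  kept <- on_chr[lo:hi]
  structure(list(trait = trait, chrom = chr,
                 peak_marker = scan$marker[peak], peak_bp = scan$bp[peak],
                 start_bp = scan$bp[kept[1L]],
                 end_bp = scan$bp[kept[length(kept)]],
                 peak_logP = scan$logP[peak], threshold = threshold,
                 r2_min = r2_min, markers = scan$marker[kept]),
            class = "qtl_interval")
}

#' @export
print.qtl_interval <- function(x, ...) {
  cat(sprintf("QTL interval: %s %d-%d bp (peak %s, logP %.2f, r2 >= %s)\n",
              x$chrom, x$start_bp, x$end_bp, x$peak_marker, x$peak_logP,
              format(x$r2_min)))
  invisible(x)
}
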