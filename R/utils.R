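#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules: deterministic seed sub-streams,
## argument validation, and small numeric utilities.

#' Derive a deterministic sub-seed from a master seed
#'
#' All stochastic stages draw their seed from a single master seed so that a
#' whole pipeline run is reproducible from one integer.  Sub-streams are
#' labelled by a character tag; the derivation is a fixed integer hash kept
#' strictly below 2^31.
#'
#' @param seed master seed (single integer).
#' @param tag character label of the sub-stream.
#' @return a single integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(length(seed) == 1L, is.finite(seed), length(tag) == 1L)
  h <- as.double(seed) %% 2147483647
  for (ch in utf8ToInt(as.character(tag))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

.assert_prob <- function(p, name) {
  .assert(length(p) == 1L && is.finite(p) && p >= 0 && p <= 1,
          "%s must be a probability in [0, 1], got %s", name, format(p))
}

## shortest interval containing `level` posterior mass, from sorted draws
.hpd_interval <- function(draws, level = 0.95) {
  x <- sort(draws[is.finite(draws)])
  n <- length(x)
  .assert(n >= 10, "too few finite draws (%d) for an HPD interval", n)
  k <- max(1L, ceiling(level * n))
  if (k >= n) return(c(lower = x[1L], upper = x[n]))
  widths <- x[(k + 1L):n] - x[seq_len(n - k)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + k])
}

## Effective sample size via an AR-model spectral density at frequency zero
## (the standard time-series estimator); no external dependency.
.ess <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 10 || stats::var(x) == 0) return(0)
  fit <- try(stats::ar(x, aic = TRUE, order.max = min(50L, n %/% 4L)), silent = TRUE)
  if (inherits(fit, "try-error")) return(n)
  if (length(fit$ar) == 0) return(n)
  v0 <- fit$var.pred / (1 - sum(fit$ar))^2
  max(1, min(n, n * stats::var(x) / v0))
}

## Posterior mode of a (0,1)-valued parameter: Gaussian KDE on the logit
## scale with Silverman bandwidth, density back-transformed with the
## Jacobian, maximised on a fine grid.  Avoids boundary bias of a direct
## KDE on (0,1).
.mode_unit_interval <- function(draws, grid_n = 512L) {
  x <- draws[is.finite(draws)]
  x <- pmin(pmax(x, 1e-8), 1 - 1e-8)
  lx <- stats::qlogis(x)
  bw <- stats::bw.nrd0(lx)
  g <- seq(1e-4, 1 - 1e-4, length.out = grid_n)
  lg <- stats::qlogis(g)
  dens <- vapply(lg, function(z) mean(stats::dnorm(z, mean = lx, sd = bw)), 0)
  dens <- dens / (g * (1 - g))   # Jacobian of the logit transform
  g[which.max(dens)]
}
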