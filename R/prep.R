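## Trait and expression preprocessing

#' Rank-based inverse normal transformation
#'
#' Maps each value to the standard-normal quantile of its Blom plotting
#' position `(rank - 3/8) / (n + 1/4)` (ties receive the average rank),
#' then centres and scales to mean 0 / SD 1 over the non-missing entries.
#' Missing values are preserved; the transform is monotone and invariant
#' to any monotone pre-transform of the input.
#'
#' @param values numeric vector, possibly with `NA`.
#' @param offset plotting-position offset (default 3/8, Blom).
#' @return transformed vector, same length, `NA` preserved.
#' @export
rank_inverse_normal <- function(values, offset = 3 / 8) {
  ok <- !is.na(values)
  n <- sum(ok)
  .assert(n >= 3, "need at least 3 non-missing values, got %d", n)
  x <- values[ok]
  .assert(stats::var(x) > 0, "all values identical; transform undefined")
  r <- rank(x, ties.method = "average")
  z <- stats::qnorm((r - offset) / (n + 1 - 2 * offset))
  z <- (z - mean(z)) / stats::sd(z)
  out <- rep(NA_real_, length(values))
  out[ok] <- z
  out
}

#' Counts-per-million normalisation
#'
#' Scales each sample (column) of a nonnegative count matrix so its
#' column total is 10^6.
#'
#' @param counts gene x sample matrix of nonnegative counts.
#' @return matrix of the same shape with column sums 10^6.
#' @export
cpm_normalize <- function(counts) {
  counts <- as.matrix(counts)
  .assert(all(is.finite(counts)) && all(counts >= 0),
          "counts must be finite and nonnegative")
  tot <- colSums(counts)
  zero <- which(tot == 0)
  if (length(zero)) {
    nm <- colnames(counts)[zero[1]] %||% as.character(zero[1])
    stop(sprintf("sample '%s' has all-zero counts; CPM undefined", nm),
         call. = FALSE)
  }
  sweep(counts, 2, tot, "/") * 1e6
}

#' Centre and scale a vector to mean 0, SD 1
#'
#' @param values numeric vector, possibly with `NA`.
#' @return standardised vector; `NA` preserved.
#' @export
standardize <- function(values) {
  ok <- !is.na(values)
  .assert(stats::var(values[ok]) > 0, "all values identical; cannot scale")
  out <- values
  out[ok] <- (values[ok] - mean(values[ok])) / stats::sd(values[ok])
  out
}
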