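## Founder-haplotype hidden Markov model
##
## An HS animal's genome is a mosaic of the founder haplotypes.  At each
## marker the latent state is the unordered founder pair (diplotype); the
## transition kernel along a chromosome is the product of two independent
## per-haplotype ancestry jump processes, and the emission model accounts
## for per-allele genotyping error.  Forward-backward gives exact marginal
## posteriors, from which expected founder dosages are derived.

#' Enumerate unordered diplotype states
#'
#' For `F` founders there are `F(F+1)/2` unordered founder pairs: `F`
#' homozygous and `F(F-1)/2` heterozygous states.  The canonical ordering
#' is lexicographic in `(f1, f2)` with `f1 <= f2`:
#' `(1,1), (1,2), ..., (1,F), (2,2), (2,3), ...` — stable and documented so
#' state indices can be relied on across the package.
#'
#' @param n_founders number of founders (>= 2).
#' @param founders optional character vector of founder names.
#' @return data.frame with columns `state` (label), `f1`, `f2` (founder
#'   indices, `f1 <= f2`) and `het` (logical).
#' @examples
#' ds <- diplotype_states(8)
#' nrow(ds)      # 36
#' sum(ds$het)   # 28
#' @export
diplotype_states <- function(n_founders, founders = NULL) {
  .assert(length(n_founders) == 1L && n_founders >= 2,
          "n_founders must be a single integer >= 2")
  n_founders <- as.integer(n_founders)
  if (is.null(founders)) founders <- paste0("F", seq_len(n_founders))
  .assert(length(founders) == n_founders, "founders must have length n_founders")
  f1 <- unlist(lapply(seq_len(n_founders), function(i) rep(i, n_founders - i + 1L)))
  f2 <- unlist(lapply(seq_len(n_founders), function(i) i:n_founders))
  data.frame(
    state = paste(founders[f1], founders[f2], sep = "."),
    f1 = f1, f2 = f2, het = f1 != f2,
    stringsAsFactors = FALSE
  )
}

## Per-haplotype ancestry switch kernel over a map distance of d centiMorgans
## after G generations: a jump process with rate G per Morgan and uniform
## jump target (including the current founder).  Haldane map, no
## interference.
.hap_transition <- function(d_cM, G, n_founders) {
  .assert(d_cM >= 0, "map distance must be non-negative, got %s", format(d_cM))
  d <- d_cM / 100                      # Morgans
  stay <- exp(-G * d)
  off <- (1 - stay) / n_founders
  P <- matrix(off, n_founders, n_founders)
  diag(P) <- stay + off
  P
}

#' Diplotype transition matrix between adjacent markers
#'
#' The two haplotypes of an animal recombine independently, so the
#' diplotype kernel is the product of two per-haplotype kernels, mapped to
#' unordered states.  Rows sum to 1; `d_cM = 0` gives the identity.
#'
#' @param d_cM inter-marker distance in centiMorgans (>= 0).
#' @param G number of outbreeding generations (jump rate per Morgan).
#' @param n_founders number of founders.
#' @return an `S x S` stochastic matrix over [diplotype_states()] ordering,
#'   `S = F(F+1)/2`.
#' @export
transition_matrix <- function(d_cM, G, n_founders) {
  st <- diplotype_states(n_founders)
  H <- .hap_transition(d_cM, G, n_founders)
  S <- nrow(st)
  P <- matrix(0, S, S)
  for (i in seq_len(S)) {
    a <- st$f1[i]; b <- st$f2[i]
    same <- H[a, ] * H[b, ]            # ordered target (c, c) terms
    P[i, ] <- ifelse(st$het,
                     H[a, st$f1] * H[b, st$f2] + H[a, st$f2] * H[b, st$f1],
                     same[st$f1])
  }
  dimnames(P) <- list(st$state, st$state)
  P
}

#' Genotype emission probability under per-allele error
#'
#' Each of the two founder alleles is observed flipped independently with
#' probability `eps`; the observed genotype is the sum of the two observed
#' alleles.  Missing genotypes contribute likelihood 1 to every state.
#'
#' @param genotype observed genotype: 0, 1, 2 or `NA`.
#' @param a1,a2 the two founder alleles (0/1) of the state; vectors recycle.
#' @param eps per-allele flip probability in `[0, 0.5]`.
#' @return likelihood of the observation given the state (vectorised).
#' @export
emission_probability <- function(genotype, a1, a2, eps) {
  .assert(eps >= 0 && eps <= 0.5, "eps must lie in [0, 0.5]")
  n <- max(length(genotype), length(a1), length(a2))
  g <- rep_len(genotype, n)
  a1 <- rep_len(a1, n)
  a2 <- rep_len(a2, n)
  p1 <- a1 * (1 - eps) + (1 - a1) * eps  # P(first observed allele = 1)
  p2 <- a2 * (1 - eps) + (1 - a2) * eps
  out <- rep(NA_real_, n)
  out[is.na(g)] <- 1
  s <- !is.na(g) & g == 0
  out[s] <- (1 - p1[s]) * (1 - p2[s])
  s <- !is.na(g) & g == 1
  out[s] <- p1[s] * (1 - p2[s]) + (1 - p1[s]) * p2[s]
  s <- !is.na(g) & g == 2
  out[s] <- p1[s] * p2[s]
  .assert(!anyNA(out), "genotype values must be 0, 1, 2 or NA")
  out
}

## Emission table for one marker: S x 3 matrix of P(g = 0/1/2 | state).
.emission_table <- function(alleles_m, st, eps) {
  a1 <- alleles_m[st$f1]
  a2 <- alleles_m[st$f2]
  cbind(emission_probability(0, a1, a2, eps),
        emission_probability(1, a1, a2, eps),
        emission_probability(2, a1, a2, eps))
}

#' Diplotype posteriors by the forward-backward algorithm
#'
#' Computes, per animal and marker, the exact marginal posterior over the
#' `F(F+1)/2` unordered diplotype states under the ancestry-jump HMM, one
#' chromosome at a time, with per-step scaling so chromosomes of 10^4+
#' markers do not underflow.  The initial distribution is uniform per
#' haplotype — Hardy-Weinberg over diplotypes, the stationary law of the
#' exchangeable-founder kernel — so an uninformative chromosome returns
#' exactly that law at every marker.
#'
#' @param genotypes marker x animal matrix of genotypes (0/1/2/`NA`), rows
#'   in panel marker order.
#' @param panel a [founder_panel()] object.
#' @param G generations of outbreeding (default 70).
#' @param eps per-allele genotyping error rate (default 0.01).
#' @return object of class `diplotype_probs`: list with `states` (the state
#'   table), `markers` (the panel marker table), `probs` (array
#'   animal x marker x state) and `loglik` (per-animal log-likelihood).
#' @export
forward_backward <- function(genotypes, panel, G = 70, eps = 0.01) {
  stopifnot(inherits(panel, "founder_panel"))
  mk <- panel$markers
  .assert(nrow(genotypes) == nrow(mk),
          "genotypes has %d rows but panel has %d markers",
          nrow(genotypes), nrow(mk))
  n_f <- length(panel$founders)
  st <- diplotype_states(n_f, panel$founders)
  S <- nrow(st)
  n <- ncol(genotypes)
  M <- nrow(mk)
  probs <- array(NA_real_, dim = c(n, M, S),
                 dimnames = list(colnames(genotypes), mk$marker, st$state))
  loglik <- numeric(n)

  for (chr in unique(mk$chrom)) {
    idx <- which(mk$chrom == chr)
    m_chr <- length(idx)
    d <- diff(mk$cM[idx])
    .assert(all(d >= 0), "cM positions not sorted on chromosome %s", chr)
    Tm <- lapply(d, transition_matrix, G = G, n_founders = n_f)
    all_missing <- which(colSums(!is.na(genotypes[idx, , drop = FALSE])) == 0)
    for (i in all_missing) {
      warning(sprintf(
        "animal %d: all genotypes missing on chromosome %s; uniform posterior",
        i, chr))
    }
    ## emission likelihood per marker as S x n matrices (missing -> 1),
    ## so the whole cohort advances through each marker in one BLAS call
    Em <- vector("list", m_chr)
    for (m in seq_len(m_chr)) {
      tab <- cbind(.emission_table(panel$alleles[, idx[m]], st, eps), 1)
      g <- genotypes[idx[m], ]
      g[is.na(g)] <- 3L
      Em[[m]] <- tab[, g + 1L, drop = FALSE]
    }
    ## forward pass with per-animal scaling; Hardy-Weinberg initial law
    pi0 <- ifelse(st$het, 2, 1) / n_f^2
    alpha <- array(0, dim = c(S, n, m_chr))
    A <- pi0 * Em[[1L]]
    cs <- colSums(A)
    A <- sweep(A, 2, cs, "/")
    alpha[, , 1L] <- A
    ll <- log(cs)
    if (m_chr > 1L) for (m in 2:m_chr) {
      A <- crossprod(Tm[[m - 1L]], A) * Em[[m]]
      cs <- colSums(A)
      A <- sweep(A, 2, cs, "/")
      alpha[, , m] <- A
      ll <- ll + log(cs)
    }
    probs[, idx[m_chr], ] <- t(alpha[, , m_chr])
    ## backward pass, renormalised per step so no underflow
    B <- matrix(1, S, n)
    if (m_chr > 1L) for (m in (m_chr - 1L):1L) {
      B <- Tm[[m]] %*% (B * Em[[m + 1L]])
      B <- sweep(B, 2, colSums(B), "/")
      P <- alpha[, , m] * B
      probs[, idx[m], ] <- t(sweep(P, 2, colSums(P), "/"))
    }
    loglik <- loglik + ll
  }
  structure(list(states = st, founders = panel$founders, markers = mk,
                 probs = probs, loglik = loglik),
            class = "diplotype_probs")
}

#' @export
print.diplotype_probs <- function(x, ...) {
  cat(sprintf("diplotype posteriors: %d animals x %d markers x %d states\n",
              dim(x$probs)[1], dim(x$probs)[2], dim(x$probs)[3]))
  invisible(x)
}

#' Expected founder haplotype dosages from diplotype posteriors
#'
#' The dose of founder `f` is the posterior-expected number of copies of
#' `f`'s haplotype: sum over states of (copies of `f` in the state) times
#' the state probability.  Doses lie in `[0, 2]` and sum to 2 per
#' animal/marker.
#'
#' @param probs a `diplotype_probs` object.
#' @return object of class `founder_dosage`: list with `dose` (array
#'   animal x marker x founder), `markers`, `founders`.
#' @export
dosages_from_probs <- function(probs) {
  stopifnot(inherits(probs, "diplotype_probs"))
  st <- probs$states
  n_f <- max(st$f2)
  S <- nrow(st)
  C <- matrix(0, S, n_f)                      # copies of each founder per state
  for (k in seq_len(S)) {
    C[k, st$f1[k]] <- C[k, st$f1[k]] + 1
    C[k, st$f2[k]] <- C[k, st$f2[k]] + 1
  }
  dm <- dim(probs$probs)
  founders <- probs$founders %||% paste0("F", seq_len(n_f))
  flat <- matrix(probs$probs, dm[1] * dm[2], S)
  dose <- array(flat %*% C, dim = c(dm[1], dm[2], n_f),
                dimnames = list(dimnames(probs$probs)[[1]],
                                dimnames(probs$probs)[[2]], founders))
  structure(list(dose = dose, markers = probs$markers, founders = founders),
            class = "founder_dosage")
}

#' Expected SNP allele dosage from founder dosages
#'
#' Collapses founder haplotype doses onto the coded (allele 1) SNP dose:
#' `snp_dose = founder_dose %*% founder_alleles` per marker; values lie in
#' `[0, 2]`.
#'
#' @param dosage a `founder_dosage` object.
#' @param panel the matching [founder_panel()].
#' @return animal x marker matrix of expected allele-1 doses.
#' @export
snp_dosage <- function(dosage, panel) {
  stopifnot(inherits(dosage, "founder_dosage"), inherits(panel, "founder_panel"))
  dm <- dim(dosage$dose)
  .assert(dm[2] == nrow(panel$markers), "dosage/panel marker count mismatch")
  out <- matrix(NA_real_, dm[1], dm[2],
                dimnames = dimnames(dosage$dose)[1:2])
  for (m in seq_len(dm[2])) {
    out[, m] <- dosage$dose[, m, ] %*% panel$alleles[, m]
  }
  out
}

#' Posterior-mode diplotype state per animal and marker
#'
#' @param probs a `diplotype_probs` object.
#' @return animal x marker integer matrix of state indices.
#' @export
map_states <- function(probs) {
  stopifnot(inherits(probs, "diplotype_probs"))
  dm <- dim(probs$probs)
  out <- matrix(NA_integer_, dm[1], dm[2], dimnames = dimnames(probs$probs)[1:2])
  for (i in seq_len(dm[1])) {
    out[i, ] <- max.col(matrix(probs$probs[i, , ], dm[2], dm[3]),
                        ties.method = "first")
  }
  out
}
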