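## Shared fixtures and independent oracles for the test suite.
## Everything is generated in code; no data files.

## a small manual founder panel on one chromosome
tiny_panel <- function(n_founders = 3, cM = c(0, 5, 10),
                       alleles = NULL, chrom = "c1") {
  M <- length(cM)
  mk <- data.frame(marker = paste0("m", seq_len(M)), chrom = chrom,
                   bp = as.integer(round(cM * 2e6) + seq_len(M)), cM = cM,
                   stringsAsFactors = FALSE)
  if (is.null(alleles)) {
    alleles <- matrix(rbinom(n_founders * M, 1, 0.5), n_founders, M)
    ## force a contrast at every marker
    for (m in seq_len(M)) if (all(alleles[, m] == alleles[1, m])) {
      alleles[1, m] <- 1 - alleles[1, m]
    }
  }
  founder_panel(paste0("F", seq_len(n_founders)), mk, alleles)
}

## brute-force diplotype posteriors by explicit path enumeration
bf_posterior <- function(g, panel, G, eps) {
  Fn <- length(panel$founders)
  st <- diplotype_states(Fn)
  S <- nrow(st)
  M <- nrow(panel$markers)
  d <- diff(panel$markers$cM)
  Tm <- lapply(d, transition_matrix, G = G, n_founders = Fn)
  E <- sapply(seq_len(M), function(m)
    emission_probability(g[m], panel$alleles[st$f1, m],
                         panel$alleles[st$f2, m], eps))
  pi0 <- ifelse(st$het, 2, 1) / Fn^2     # Hardy-Weinberg initial law
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), M)))
  w <- apply(paths, 1, function(pth) {
    lik <- pi0[pth[1]] * E[pth[1], 1]
    if (M > 1) for (m in 2:M) {
      lik <- lik * Tm[[m - 1]][pth[m - 1], pth[m]] * E[pth[m], m]
    }
    lik
  })
  post <- sapply(seq_len(M), function(m)
    vapply(seq_len(S), function(k) sum(w[paths[, m] == k]), 0))
  post <- sweep(post, 2, colSums(post), "/")   # S x M, columns sum to 1
  list(post = t(post), loglik = log(sum(w)))
}

## brute-force Benjamini-Hochberg step-up, straight from the definition
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

## simulated HS population with a kinship, used across LMM/scan tests
sim_small_pop <- function(n_animals = 150, n_chrom = 2, n_markers = 60,
                          length_cM = 60, seed = 1, eps = 0.01,
                          missing_rate = 0, family_size = 5) {
  cfg <- sim_config(n_founders = 8,
                    chromosomes = data.frame(name = paste0("chr", seq_len(n_chrom)),
                                             length_cM = length_cM,
                                             n_markers = n_markers),
                    n_animals = n_animals, family_size = family_size,
                    genotyping_error = eps,
                    missing_rate = missing_rate, seed = seed)
  simulate_population(cfg)
}

## QQ slope of -log10(p) against uniform expectation
qq_slope <- function(p) {
  obs <- -log10(sort(p))
  ex <- -log10(stats::ppoints(length(p)))
  unname(stats::coef(stats::lm(obs ~ 0 + ex)))
}

## demo pipeline configuration (also shipped in inst/extdata)
demo_config <- function(seed = 42) {
  list(seed = seed,
       simulate = list(
         n_founders = 8, n_generations = 70, n_animals = 200,
         chromosomes = list(list(name = "chr1", length_cM = 60, n_markers = 60),
                            list(name = "chr2", length_cM = 60, n_markers = 60)),
         genotyping_error = 0.01, missing_rate = 0.01,
         qtl = list(list(marker = 30, effects = "snp", var_frac = 0.25)),
         h2 = 0.45, mediation_scenario = "full_mediation", qtl_frac = 0.25),
       scan = list(B = 100, alpha = 0.05, r2_min = 0.5),
       h2_mcmc = list(n_iter = 3000, burn_in = 500),
       effects = list(M = 15, n_iter = 400, burn_in = 100),
       mediation = list(fdr = 0.1))
}
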