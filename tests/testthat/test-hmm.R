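## Diplotype state space, transition/emission model and forward-backward

test_that("diplotype state space has the right size and composition", {
  for (Fn in c(2, 3, 8)) {
    st <- diplotype_states(Fn)
    expect_equal(nrow(st), Fn * (Fn + 1) / 2)
    expect_equal(sum(st$het), Fn * (Fn - 1) / 2)
    expect_equal(sum(!st$het), Fn)
    ## canonical lexicographic ordering, f1 <= f2
    expect_true(all(st$f1 <= st$f2))
    expect_equal(order(st$f1, st$f2), seq_len(nrow(st)))
    ## all unordered pairs present exactly once (enumeration oracle)
    expect_equal(anyDuplicated(paste(st$f1, st$f2)), 0L)
  }
  expect_error(diplotype_states(1), "n_founders")
})

test_that("transition matrix matches the two-haplotype kernel product", {
  ## d = 0 is the identity
  expect_equal(transition_matrix(0, 70, 8), diag(36),
               ignore_attr = TRUE)
  ## ergodic limit: rows converge to the Hardy-Weinberg stationary law
  st <- diplotype_states(8)
  stat <- ifelse(st$het, 2 / 64, 1 / 64)
  Tinf <- transition_matrix(1e7, 70, 8)
  expect_lt(max(abs(sweep(Tinf, 2, stat))), 1e-9)
  ## F=3, d=0.1 M, G=10: brute-force enumeration over ordered pairs
  Fn <- 3; G <- 10; d_cM <- 10
  H <- hsqtl:::.hap_transition(d_cM, G, Fn)
  st3 <- diplotype_states(3)
  S <- nrow(st3)
  bf <- matrix(0, S, S)
  for (i in seq_len(S)) for (j in seq_len(S)) {
    a <- st3$f1[i]; b <- st3$f2[i]; cc <- st3$f1[j]; dd <- st3$f2[j]
    bf[i, j] <- if (cc == dd) H[a, cc] * H[b, cc] else
      H[a, cc] * H[b, dd] + H[a, dd] * H[b, cc]
  }
  expect_equal(unname(transition_matrix(d_cM, G, Fn)), bf, tolerance = 1e-12)
  expect_equal(unname(rowSums(transition_matrix(3.7, 41, 5))), rep(1, 15),
               tolerance = 1e-12)
  expect_error(transition_matrix(-1, 70, 8), "non-negative")
})

test_that("emission probabilities follow the per-allele flip model", {
  ## error-free limits
  expect_equal(emission_probability(2, 1, 1, 0), 1)
  expect_equal(emission_probability(1, 1, 1, 0), 0)
  ## eps = 0.01, alleles (0,1), genotype 1: both correct or both flipped
  eps <- 0.01
  expect_equal(emission_probability(1, 0, 1, eps), (1 - eps)^2 + eps^2)
  ## missing genotype is uninformative for every state
  st <- diplotype_states(4)
  expect_equal(emission_probability(NA, st$f1 %% 2, st$f2 %% 2, 0.05),
               rep(1, nrow(st)))
  ## vectorised over states, each genotype column sums over the 3 outcomes
  al <- c(0, 1, 1)
  tab <- sapply(0:2, function(g)
    emission_probability(g, al[st$f1 %% 3 + 1], al[st$f2 %% 3 + 1], 0.02))
  expect_equal(rowSums(tab), rep(1, nrow(st)), tolerance = 1e-12)
  expect_error(emission_probability(3, 0, 1, 0.01), "genotype")
  expect_error(emission_probability(1, 0, 1, 0.7), "eps")
})

test_that("forward-backward equals brute-force path enumeration", {
  ## property over random small instances: F <= 3, M <= 4, random eps
  set.seed(20240901)
  for (rep in 1:12) {
    Fn <- sample(2:3, 1)
    M <- sample(2:4, 1)
    G <- runif(1, 1, 40)
    eps <- runif(1, 0, 0.2)
    panel <- tiny_panel(Fn, cM = sort(runif(M, 0, 30)))
    g <- sample(c(0:2, NA), M, replace = TRUE)
    if (all(is.na(g))) g[1] <- 1L
    bf <- bf_posterior(g, panel, G, eps)
    fb <- forward_backward(matrix(as.integer(g), ncol = 1), panel,
                           G = G, eps = eps)
    expect_lt(max(abs(bf$post - fb$probs[1, , ])), 1e-10)
    expect_lt(abs(bf$loglik - fb$loglik), 1e-10)
  }
})

test_that("fully informative markers pin the true state (identifiable limit)", {
  ## F = 2 founders with opposite alleles everywhere, no error, G = 0:
  ## genotypes determine the diplotype exactly
  M <- 30
  panel <- tiny_panel(2, cM = seq(0, 3, length.out = M),
                      alleles = rbind(rep(0, M), rep(1, M)))
  cfg <- sim_config(n_founders = 2, n_generations = 0,
                    chromosomes = data.frame(name = "c1", length_cM = 3,
                                             n_markers = M),
                    n_animals = 8, family_size = 1, genotyping_error = 0,
                    missing_rate = 0, seed = 7, founders = c("F1", "F2"))
  mos <- simulate_mosaics(cfg)
  geno <- simulate_genotypes(mos, panel, eps = 0, missing_rate = 0, seed = 2)
  fb <- forward_backward(geno, panel, G = 0.01, eps = 1e-4)
  ts <- true_states(mos, panel)
  for (i in 1:8) {
    expect_true(all(fb$probs[cbind(i, 1:M, ts[i, ])] >= 0.999))
  }
})

test_that("founder relabelling permutes posteriors identically", {
  set.seed(5)
  Fn <- 3
  panel <- tiny_panel(Fn, cM = c(0, 2, 4, 9))
  g <- matrix(c(1L, 0L, 2L, 1L), ncol = 1)
  fb <- forward_backward(g, panel, G = 20, eps = 0.02)
  ## permute founders 1 -> 2 -> 3 -> 1
  perm <- c(2, 3, 1)
  panel2 <- founder_panel(panel$founders, panel$markers,
                          panel$alleles[order(perm), ])
  fb2 <- forward_backward(g, panel2, G = 20, eps = 0.02)
  st <- diplotype_states(Fn)
  lut <- matrix(0L, Fn, Fn)
  for (k in seq_len(nrow(st))) {
    lut[st$f1[k], st$f2[k]] <- lut[st$f2[k], st$f1[k]] <- k
  }
  k_perm <- lut[cbind(pmin(perm[st$f1], perm[st$f2]),
                      pmax(perm[st$f1], perm[st$f2]))]
  expect_equal(fb$probs[1, , ], fb2$probs[1, , k_perm], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("simplex and dose-sum invariants hold on simulated data", {
  pop <- sim_small_pop(n_animals = 25, n_chrom = 2, n_markers = 30, seed = 3,
                       missing_rate = 0.05)
  fb <- forward_backward(pop$genotypes, pop$panel)
  expect_lt(max(abs(apply(fb$probs, 1:2, sum) - 1)), 1e-9)
  expect_true(all(fb$probs >= 0))
  expect_true(all(is.finite(fb$loglik)))
  dos <- dosages_from_probs(fb)
  expect_lt(max(abs(apply(dos$dose, 1:2, sum) - 2)), 1e-9)
  expect_true(all(dos$dose >= 0 & dos$dose <= 2))
  sdos <- snp_dosage(dos, pop$panel)
  expect_true(all(sdos >= -1e-9 & sdos <= 2 + 1e-9))
})

test_that("dosages follow the posterior: point mass, uniform, monomorphic", {
  st <- diplotype_states(8)
  S <- nrow(st)
  probs <- matrix(0, 3, S)
  probs[1, which(st$f1 == 2 & st$f2 == 2)] <- 1     # homozygous F2/F2
  probs[2, ] <- 1 / S                               # uniform posterior
  probs[3, which(st$f1 == 1 & st$f2 == 3)] <- 1     # heterozygous F1/F3
  mk <- data.frame(marker = "m1", chrom = "c1", bp = 1L, cM = 0)
  obj <- structure(list(states = st, founders = paste0("F", 1:8),
                        markers = mk,
                        probs = array(probs, dim = c(3, 1, S)),
                        loglik = rep(0, 3)),
                   class = "diplotype_probs")
  dos <- dosages_from_probs(obj)
  expect_equal(unname(dos$dose[1, 1, ]), c(0, 2, 0, 0, 0, 0, 0, 0))
  expect_equal(unname(dos$dose[2, 1, ]), rep(0.25, 8))  # 2/F
  expect_equal(unname(dos$dose[3, 1, ]), c(1, 0, 1, 0, 0, 0, 0, 0))
  ## monomorphic marker (all founders carry allele 1): SNP dose exactly 2
  panel <- founder_panel(paste0("F", 1:8), mk, matrix(1, 8, 1))
  expect_equal(unname(snp_dosage(dos, panel)[, 1]), rep(2, 3))
})

test_that("all-missing chromosome returns the stationary law with a warning", {
  panel <- tiny_panel(3, cM = c(0, 5))
  g <- matrix(NA_integer_, 2, 1)
  expect_warning(fb <- forward_backward(g, panel), "all genotypes missing")
  st <- diplotype_states(3)
  hw <- ifelse(st$het, 2, 1) / 9
  expect_equal(fb$probs[1, , ], rbind(hw, hw), ignore_attr = TRUE)
})

test_that("posterior-mode ancestry recovers dense-map simulated mosaics", {
  ## identifiable regime: ~20 markers per ancestry segment (12.5 cM, 500
  ## markers, G = 70); at sparser HS-array-like spacing the per-marker
  ## diplotype is intrinsically uncertain and only dosages are reliable
  cfg <- sim_config(n_founders = 8,
                    chromosomes = data.frame(name = "chr1", length_cM = 12.5,
                                             n_markers = 500),
                    n_animals = 10, family_size = 1,
                    genotyping_error = 0.005, missing_rate = 0, seed = 11)
  pop <- simulate_population(cfg)
  fb <- forward_backward(pop$genotypes, pop$panel, G = 70, eps = 0.005)
  match_frac <- mean(true_states(pop$mosaics, pop$panel) == map_states(fb))
  expect_gte(match_frac, 0.95)
})
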