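## Synthetic population generator: ancestry process, genotypes,
## phenotype variance decomposition, expression scenarios

test_that("sim_config validates its fields", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_founders = 1), "n_founders")
  expect_error(sim_config(genotyping_error = 1.5), "probability")
  expect_error(sim_config(chromosomes = data.frame(name = "c", length_cM = -1,
                                                   n_markers = 5)),
               "lengths")
})

test_that("G = 0 gives single-founder chromosomes; jump counts are Poisson", {
  cfg0 <- sim_config(n_generations = 0, family_size = 1,
                     chromosomes = data.frame(name = "c1", length_cM = 80,
                                              n_markers = 2),
                     n_animals = 20, seed = 4)
  mos0 <- simulate_mosaics(cfg0)
  expect_true(all(jump_counts(mos0)$jumps == 0))

  ## G = 70, 1 Morgan chromosome: mean jump count ~ Poisson(70)
  n_hap <- 10000
  cfg <- sim_config(n_generations = 70, family_size = 1,
                    chromosomes = data.frame(name = "c1", length_cM = 100,
                                             n_markers = 2),
                    n_animals = n_hap / 2, seed = 8)
  jc <- jump_counts(simulate_mosaics(cfg))$jumps
  expect_equal(length(jc), n_hap)
  se <- sqrt(70 / n_hap)
  expect_lt(abs(mean(jc) - 70), 3 * se)
})

test_that("marginal founder frequencies are uniform along the genome", {
  cfg <- sim_config(family_size = 1,
                    chromosomes = data.frame(name = "c1", length_cM = 100,
                                             n_markers = 3),
                    n_animals = 2000, seed = 12)
  mos <- simulate_mosaics(cfg)
  panel <- simulate_founder_panel(cfg)
  dose <- true_founder_dosage(mos, panel)
  for (m in 1:3) {
    counts <- colSums(dose$dose[, m, ])
    expect_gt(stats::chisq.test(counts)$p.value, 0.001)
  }
})

test_that("genotypes are founder-allele sums under the error model", {
  pop <- sim_small_pop(n_animals = 40, n_chrom = 1, n_markers = 50, seed = 6)
  cfg <- pop$config
  ## eps = 0, missing 0: deterministic equality with the mosaic truth
  g0 <- simulate_genotypes(pop$mosaics, pop$panel, eps = 0, missing_rate = 0,
                           seed = 1)
  expected <- sapply(seq_len(40), function(i)
    sapply(seq_len(50), function(m)
      sum(pop$dosage$dose[i, m, ] * pop$panel$alleles[, m])))
  expect_equal(unname(g0), unname(expected), ignore_attr = TRUE)

  ## eps = 0.01: flip fraction within 3 binomial SEs over 10^5 alleles
  cfg_big <- sim_config(n_founders = 8,
                        chromosomes = data.frame(name = "c1", length_cM = 100,
                                                 n_markers = 500),
                        n_animals = 100, seed = 31)
  pop_big <- simulate_population(cfg_big)
  g_clean <- simulate_genotypes(pop_big$mosaics, pop_big$panel, eps = 0,
                                missing_rate = 0, seed = 5)
  g_noisy <- simulate_genotypes(pop_big$mosaics, pop_big$panel, eps = 0.01,
                                missing_rate = 0, seed = 5)
  n_alleles <- 2 * length(g_clean)                 # 10^5 allele draws
  flips <- sum(abs(g_noisy - g_clean))             # double flips ~ eps^2, negligible
  se <- sqrt(0.01 * 0.99 / n_alleles)
  expect_lt(abs(flips / n_alleles - 0.01), 3 * se)

  ## eps = 0.5: genotype carries no ancestry information
  g_rand <- simulate_genotypes(pop_big$mosaics, pop_big$panel, eps = 0.5,
                               missing_rate = 0, seed = 5)
  cors <- sapply(seq_len(500), function(m) {
    if (stats::var(g_clean[m, ]) == 0 || stats::var(g_rand[m, ]) == 0) 0
    else stats::cor(g_clean[m, ], g_rand[m, ])
  })
  expect_lt(abs(mean(cors)), 0.02)

  ## missingness honoured
  g_miss <- simulate_genotypes(pop$mosaics, pop$panel, eps = 0,
                               missing_rate = 0.2, seed = 9)
  expect_gt(mean(is.na(g_miss)), 0.15)
  expect_lt(mean(is.na(g_miss)), 0.25)
})

test_that("phenotype variance decomposition hits its targets", {
  pop <- sim_small_pop(n_animals = 500, n_chrom = 2, n_markers = 40, seed = 13)
  ## QTL fraction 0.20: realised fraction within 0.03 across replicates
  fr <- sapply(1:10, function(r) {
    tr <- truth_record(qtl = list(list(marker = 20,
                                       effects = c(2, 0, 0, 0, 1, 0, 0, 0),
                                       var_frac = 0.2)), h2 = 0.45)
    y <- simulate_phenotype(pop$dosage, pop$kinship, tr, seed = 100 + r)
    comp <- attr(y, "components")
    stats::var(comp$qtl) / stats::var(as.numeric(y))
  })
  expect_lt(abs(mean(fr) - 0.2), 0.03)

  ## h2 = 0, no QTL: phenotype is pure noise
  y0 <- simulate_phenotype(pop$dosage, pop$kinship,
                           truth_record(qtl = list(), h2 = 0), seed = 3)
  comp0 <- attr(y0, "components")
  expect_equal(stats::var(comp0$polygenic), 0)
  expect_equal(stats::var(comp0$qtl), 0)

  ## equal founder effects contribute no variance regardless of target
  tr_eq <- truth_record(qtl = list(list(marker = 20, effects = rep(1, 8),
                                        var_frac = 0.3)), h2 = 0.2)
  y_eq <- simulate_phenotype(pop$dosage, pop$kinship, tr_eq, seed = 4)
  expect_equal(stats::var(attr(y_eq, "components")$qtl), 0)

  ## invalid kinship rejected
  expect_error(simulate_phenotype(pop$dosage, matrix(0, 500, 500),
                                  truth_record(h2 = 0.3), seed = 1),
               "singular")
})

test_that("truth_record validates variance fractions", {
  expect_error(truth_record(qtl = list(list(marker = 1, effects = 1:8,
                                            var_frac = 0.7)), h2 = 0.5),
               "sum above 1")
  expect_error(truth_record(h2 = 1), "h2")
  expect_error(truth_record(mediation_scenario = "nope"), "scenario")
})

test_that("expression scenarios wire the stated causal structure", {
  pop <- sim_small_pop(n_animals = 300, n_chrom = 2, n_markers = 40, seed = 17)
  qm <- 20
  x <- drop(pop$dosage$dose[, qm, ] %*% pop$panel$alleles[, qm])

  ## scenario none: no gene correlates with the marker beyond chance
  ex0 <- simulate_expression(qm, pop$dosage, pop$panel, pop$kinship,
                             scenario = "none", seed = 21, n_decoys = 100)
  cors <- apply(ex0$counts, 1, function(g) abs(stats::cor(g, x)))
  ## max |r| over ~100 null genes: bound by Bonferroni-style null quantile
  expect_lt(max(cors), stats::qnorm(1 - 0.0005 / length(cors)) / sqrt(300))
  expect_true(is.na(ex0$truth$mediator))

  ## full mediation: conditioning on the gene removes the marker-trait
  ## association (d-separation in the linear chain x -> z -> y)
  ex1 <- simulate_expression(qm, pop$dosage, pop$panel, pop$kinship,
                             scenario = "full_mediation", seed = 22)
  z <- rank_inverse_normal(cpm_normalize(ex1$counts)["gene_target", ])
  y <- as.numeric(ex1$phenotype)
  r_xy <- stats::cor(x, y)
  pcor <- {
    rx <- stats::residuals(stats::lm(x ~ z))
    ry <- stats::residuals(stats::lm(y ~ z))
    stats::cor(rx, ry)
  }
  expect_lt(abs(pcor), abs(r_xy) / 2)

  ## zero-inflated decoy (80% zeros) fails the strict >25% filter
  expect_false(expression_filter(ex1$counts["gene_zeroinf", , drop = FALSE]))
  expect_error(simulate_expression(qm, pop$dosage, pop$panel, pop$kinship,
                                   scenario = "bogus", seed = 1),
               "scenario")
})

test_that("simulation is byte-identical under a fixed seed", {
  cfg <- sim_config(chromosomes = data.frame(name = "c1", length_cM = 40,
                                             n_markers = 25),
                    n_animals = 15, seed = 99)
  p1 <- simulate_population(cfg, truth_record(h2 = 0.4))
  p2 <- simulate_population(cfg, truth_record(h2 = 0.4))
  expect_identical(p1$genotypes, p2$genotypes)
  expect_identical(p1$panel$alleles, p2$panel$alleles)
  expect_identical(as.numeric(p1$phenotype), as.numeric(p2$phenotype))
})
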