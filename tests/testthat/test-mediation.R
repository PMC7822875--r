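## Four-criterion mediation analysis

make_interval <- function(chrom = "chr1", start = 100, end = 900,
                          peak_marker = "m5", peak_bp = 500) {
  structure(list(trait = "t", chrom = chrom, peak_marker = peak_marker,
                 peak_bp = peak_bp, start_bp = start, end_bp = end,
                 peak_logP = 7, threshold = 4, r2_min = 0.5, markers = NULL),
            class = "qtl_interval")
}

test_that("locality is any overlap with the LD interval", {
  iv <- make_interval()
  ann <- data.frame(gene = c("inside", "other_chrom", "straddle_left",
                             "straddle_right", "outside"),
                    chrom = c("chr1", "chr2", "chr1", "chr1", "chr1"),
                    start = c(300, 300, 50, 850, 1000),
                    end = c(400, 400, 150, 950, 1200))
  expect_equal(select_local_genes(ann, iv),
               c(TRUE, FALSE, TRUE, TRUE, FALSE))
})

test_that("expression filter is strictly greater than 25% non-zero", {
  e26 <- c(rep(1, 26), rep(0, 74))
  e25 <- c(rep(1, 25), rep(0, 75))
  expect_true(expression_filter(e26))
  expect_false(expression_filter(e25))            # boundary fails
  expect_true(expression_filter(rep(3, 100)))
  m <- rbind(a = e26, b = e25)
  expect_equal(unname(expression_filter(m)), c(TRUE, FALSE))
})

test_that("BH adjustment equals a brute-force step-up oracle", {
  ## the worked example: discoveries {1, 2} at FDR 0.1
  p <- c(0.01, 0.02, 0.9)
  q <- stats::p.adjust(p, method = "BH")
  expect_equal(which(q <= 0.1), c(1L, 2L))
  expect_equal(q, bf_bh(p))
  set.seed(81)
  for (r in 1:20) {
    pv <- stats::runif(sample(2:40, 1))^sample(1:3, 1)
    expect_equal(stats::p.adjust(pv, method = "BH"), bf_bh(pv),
                 tolerance = 1e-12)
  }
})

test_that("verdicts follow the sequential rule", {
  tab <- data.frame(
    gene = letters[1:7],
    local = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
    filter_pass = c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE),
    cis_q = c(NA, NA, 0.5, 0.05, 0.05, 0.05, 0.05),
    full_plausible = c(NA, NA, NA, TRUE, FALSE, FALSE, TRUE),
    partial_q = c(NA, NA, NA, 0.9, 0.05, 0.9, 0.05))
  expect_equal(mediation_verdict(tab),
               c("not_local", "filtered", "no_cis_eqtl",
                 "candidate_mediator",     # steps 2 + 3 only
                 "candidate_mediator",     # steps 2 + 4 only
                 "not_mediator",           # step 2 only
                 "candidate_mediator"))    # steps 2 + 3 + 4
})

test_that("full- and partial-mediation tests behave on one simulated QTL", {
  pop <- sim_small_pop(n_animals = 245, n_chrom = 2, n_markers = 40, seed = 83)
  qm <- 20
  K <- pop$kinship

  ## full mediation: conditioning on the true mediator kills the signal
  ex <- simulate_expression(qm, pop$dosage, pop$panel, K,
                            scenario = "full_mediation", seed = 84)
  y <- rank_inverse_normal(as.numeric(ex$phenotype))
  x <- snp_dosage(pop$dosage, pop$panel)[, qm]
  z <- rank_inverse_normal(cpm_normalize(ex$counts)["gene_target", ])
  expect_lt(cis_eqtl_test(z, x, K), 1e-6)
  fm <- full_mediation_test(y, x, z, K)
  expect_gt(fm$p, 0.05)
  expect_true(fm$plausible)
  expect_lt(partial_mediation_test(y, x, z, K), 0.01)

  ## colocalised-but-not-mediating: conditioning leaves the QTL intact
  ex2 <- simulate_expression(qm, pop$dosage, pop$panel, K,
                             scenario = "colocal_no_mediation", seed = 85)
  y2 <- rank_inverse_normal(as.numeric(ex2$phenotype))
  z2 <- rank_inverse_normal(cpm_normalize(ex2$counts)["gene_target", ])
  expect_lt(full_mediation_test(y2, x, z2, K)$p, 0.05)

  ## an irrelevant mediator barely changes the conditioned p
  p_raw <- cis_eqtl_test(y2, x, K)     # marker effect without covariate
  set.seed(86)
  deltas <- sapply(1:5, function(i) {
    noise <- drop(scale(stats::rnorm(245)))
    abs(log10(full_mediation_test(y2, x, noise, K)$p) - log10(p_raw))
  })
  expect_lt(stats::median(deltas), 0.2)

  ## mediator identical to the response: degenerate, p floors at 0
  expect_warning(p_deg <- partial_mediation_test(y2, x, y2, K), "degenerate")
  expect_lt(p_deg, 1e-12)
})

test_that("partial-mediation p-values are calibrated under the null", {
  pop <- sim_small_pop(n_animals = 150, n_chrom = 1, n_markers = 30, seed = 87)
  x <- snp_dosage(pop$dosage, pop$panel)[, 15]
  K <- pop$kinship
  eigenK <- hsqtl:::.kinship_eigen(K)
  set.seed(88)
  pv <- replicate(200, {
    y <- drop(scale(stats::rnorm(150)))
    z <- drop(scale(stats::rnorm(150)))
    partial_mediation_test(y, x, z, K, eigenK)
  })
  expect_lt(abs(qq_slope(pv) - 1), 0.15)
})

test_that("mediate_qtl produces an auditable table end to end", {
  pop <- sim_small_pop(n_animals = 245, n_chrom = 2, n_markers = 40, seed = 89)
  qm <- 20
  ex <- simulate_expression(qm, pop$dosage, pop$panel, pop$kinship,
                            scenario = "full_mediation", seed = 90)
  y <- rank_inverse_normal(as.numeric(ex$phenotype))
  sdos <- snp_dosage(pop$dosage, pop$panel)
  sc <- lrt_scan(y, sdos, pop$kinship, markers = pop$panel$markers)
  iv <- ld_interval(sc, sdos, peak = qm)
  med <- mediate_qtl(y, sdos[, qm], pop$kinship, ex$counts, ex$annotations, iv)
  expect_s3_class(med, "mediation_table")
  expect_equal(nrow(med), nrow(ex$annotations))
  tg <- med[med$gene == "gene_target", ]
  expect_equal(tg$verdict, "candidate_mediator")
  expect_equal(med$verdict[med$gene == "gene_zeroinf"], "filtered")
  ## short-circuiting: later criteria not computed for filtered genes
  expect_true(is.na(med$cis_p[med$gene == "gene_zeroinf"]))
  ## off-chromosome decoys are not local
  far <- grepl("decoy1[1-9]|decoy20", med$gene)
  expect_true(all(med$verdict[far] == "not_local"))
  ## verdicts consistent with recorded criteria
  expect_identical(med$verdict, mediation_verdict(med))
})
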