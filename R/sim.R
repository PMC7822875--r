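## Synthetic HS population generator
##
## Generates populations with the statistical structure the inference
## assumes, with full knowledge of the truth: founder mosaics from an
## ancestry jump process, array genotypes with per-allele error and
## missingness, phenotypes from an additive-QTL + polygenic + noise
## decomposition, and expression traits wired into explicit mediation
## scenarios.  Defaults emulate the HS rat design: 8 founders, ~70
## generations of outbreeding, ~8,000 informative SNPs on 20 autosomes and
## n = 245 animals.

#' Simulation configuration
#'
#' @param n_founders number of inbred founders (default 8).
#' @param n_generations generations of outbreeding `G`, the ancestry jump
#'   rate per Morgan (default 70).
#' @param chromosomes data.frame with columns `name`, `length_cM`,
#'   `n_markers`; default 20 autosomes of 100 cM with 400 markers each
#'   (~8,000 markers genome-wide).
#' @param n_animals number of animals (default 245).
#' @param family_size animals per sibship (default 5).  Parent haplotypes
#'   follow the ancestry jump process; sibs are produced by meiosis from
#'   the same two parents, giving the relatedness variation that makes
#'   heritability identifiable (a colony of unrelated animals carries
#'   almost no information about h2).  Set to 1 for fully independent
#'   animals.
#' @param genotyping_error per-allele flip probability (default 0.01).
#' @param missing_rate genotype missingness probability (default 0.01).
#' @param founders optional founder names.
#' @param seed master seed; every stochastic stage derives its own
#'   sub-stream from it via [derive_seed()].
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_founders = 8,
                       n_generations = 70,
                       chromosomes = NULL,
                       n_animals = 245,
                       family_size = 5,
                       genotyping_error = 0.01,
                       missing_rate = 0.01,
                       founders = NULL,
                       seed = 1) {
  if (is.null(chromosomes)) {
    chromosomes <- data.frame(name = paste0("chr", 1:20),
                              length_cM = 100, n_markers = 400,
                              stringsAsFactors = FALSE)
  }
  .assert(n_founders >= 2, "n_founders must be >= 2")
  .assert(n_generations >= 0, "n_generations must be >= 0")
  .assert(all(chromosomes$length_cM > 0), "chromosome lengths must be > 0")
  .assert(all(chromosomes$n_markers >= 1), "need >= 1 marker per chromosome")
  .assert(n_animals >= 1, "n_animals must be >= 1")
  .assert(family_size >= 1, "family_size must be >= 1")
  .assert_prob(genotyping_error, "genotyping_error")
  .assert_prob(missing_rate, "missing_rate")
  if (is.null(founders)) founders <- paste0("F", seq_len(n_founders))
  .assert(length(founders) == n_founders, "founders must match n_founders")
  structure(list(n_founders = as.integer(n_founders),
                 n_generations = n_generations,
                 chromosomes = chromosomes,
                 n_animals = as.integer(n_animals),
                 family_size = as.integer(family_size),
                 genotyping_error = genotyping_error,
                 missing_rate = missing_rate,
                 founders = founders,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a founder allele panel
#'
#' Markers are evenly spaced in cM along each chromosome (1 cM is mapped to
#' 2 Mb of physical sequence, a typical mammalian average).  Each marker is
#' assigned a random biallelic pattern over founders with at least one
#' contrast: the count of allele-1 founders is uniform on `{1, ..., F-1}`,
#' so monomorphic-in-founders markers never occur, mirroring an
#' informative-marker filter.
#'
#' @param config a [sim_config()].
#' @return a [founder_panel()].
#' @export
simulate_founder_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "panel"))
  Fn <- config$n_founders
  tabs <- lapply(seq_len(nrow(config$chromosomes)), function(ci) {
    ch <- config$chromosomes[ci, ]
    m <- ch$n_markers
    cM <- if (m == 1) ch$length_cM / 2 else seq(0, ch$length_cM, length.out = m)
    data.frame(marker = sprintf("%s_m%04d", ch$name, seq_len(m)),
               chrom = ch$name, bp = round(cM * 2e6) + 1L, cM = cM,
               stringsAsFactors = FALSE)
  })
  markers <- do.call(rbind, tabs)
  M <- nrow(markers)
  alleles <- matrix(0L, Fn, M)
  k <- sample(seq_len(Fn - 1L), M, replace = TRUE)
  for (m in seq_len(M)) alleles[sample.int(Fn, k[m]), m] <- 1L
  founder_panel(config$founders, markers, alleles)
}

## one meiotic gamete from a pair of parental haplotypes: crossovers at
## rate 1 per Morgan (Haldane), alternating source haplotype
.meiosis <- function(h1, h2, len_cM) {
  n_xo <- stats::rpois(1, len_cM / 100)
  start <- sample.int(2L, 1L)
  if (n_xo == 0) return(if (start == 1L) h1 else h2)
  xo <- sort(stats::runif(n_xo, 0, len_cM))
  bounds <- c(0, xo, len_cM)
  src <- rep(c(start, 3L - start), length.out = n_xo + 1L)
  brk <- 0
  founder <- integer(0)
  for (s in seq_len(n_xo + 1L)) {
    h <- if (src[s] == 1L) h1 else h2
    lo <- bounds[s]; hi <- bounds[s + 1L]
    i0 <- findInterval(lo, h$brk, rightmost.closed = TRUE, all.inside = TRUE)
    i1 <- findInterval(hi, h$brk, rightmost.closed = TRUE, all.inside = TRUE)
    cuts <- c(h$brk[seq(i0 + 1L, length.out = max(0L, i1 - i0))], hi)
    brk <- c(brk, cuts)
    founder <- c(founder, h$founder[i0:i1])
  }
  list(brk = brk, founder = founder)
}

#' Simulate founder ancestry mosaics
#'
#' Each haplotype is a piecewise-constant founder assignment along each
#' chromosome, generated by a Markov jump process with rate `G` per Morgan
#' and a uniform jump target over founders (including the current one) —
#' exactly the transition family the HMM assumes.  The two haplotypes of an
#' animal are independent.
#'
#' When `family_size > 1`, animals are grouped into sibships: the jump
#' process generates the four parental haplotypes of each family and sibs
#' receive meiotic recombinants (crossover rate 1 per Morgan) of them.
#' This supplies the relatedness variation a heritability analysis needs
#' while leaving the per-haplotype ancestry law unchanged.
#'
#' With `family_size = 1`, self-target jumps are retained as distinct
#' segments, so `jump count = segments - 1` matches a Poisson(G x length)
#' oracle exactly.
#'
#' @param config a [sim_config()].
#' @return object of class `hs_mosaics`: per animal, per chromosome, two
#'   haplotypes each a list with `brk` (segment breakpoints in cM, from 0
#'   to the chromosome length) and `founder` (founder index per segment);
#'   plus the `family` index per animal.
#' @export
simulate_mosaics <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "mosaics"))
  G <- config$n_generations
  Fn <- config$n_founders
  fs <- config$family_size %||% 1L
  one_hap <- function(len_cM) {
    L <- len_cM / 100
    nj <- stats::rpois(1, G * L)
    pos <- sort(stats::runif(nj, 0, len_cM))
    founder <- sample.int(Fn, nj + 1L, replace = TRUE)
    list(brk = c(0, pos, len_cM), founder = founder)
  }
  n <- config$n_animals
  family <- rep(seq_len(ceiling(n / fs)), each = fs)[seq_len(n)]
  animals <- vector("list", n)
  for (fam in unique(family)) {
    kids <- which(family == fam)
    chroms_kids <- lapply(kids, function(i) {
      ch <- vector("list", nrow(config$chromosomes))
      names(ch) <- config$chromosomes$name
      ch
    })
    for (ci in seq_len(nrow(config$chromosomes))) {
      len <- config$chromosomes$length_cM[ci]
      if (fs == 1L) {
        chroms_kids[[1]][[ci]] <- list(hap1 = one_hap(len),
                                       hap2 = one_hap(len))
      } else {
        dam <- list(one_hap(len), one_hap(len))
        sire <- list(one_hap(len), one_hap(len))
        for (k in seq_along(kids)) {
          chroms_kids[[k]][[ci]] <- list(
            hap1 = .meiosis(dam[[1]], dam[[2]], len),
            hap2 = .meiosis(sire[[1]], sire[[2]], len))
        }
      }
    }
    for (k in seq_along(kids)) animals[[kids[k]]] <- chroms_kids[[k]]
  }
  structure(list(animals = animals, chromosomes = config$chromosomes,
                 n_founders = Fn, G = G, family = family),
            class = "hs_mosaics")
}

#' @export
print.hs_mosaics <- function(x, ...) {
  cat(sprintf("HS mosaics: %d animals, %d chromosome(s), %d founders, G = %s\n",
              length(x$animals), nrow(x$chromosomes), x$n_founders,
              format(x$G)))
  invisible(x)
}

## founder index of one haplotype at given cM positions
.hap_at <- function(hap, cM) {
  hap$founder[findInterval(cM, hap$brk, rightmost.closed = TRUE,
                           all.inside = TRUE)]
}

#' Ancestry jump counts per haplotype
#'
#' Number of jump events (including self-target jumps) per haplotype per
#' chromosome; the generative model makes these Poisson with rate
#' `G x length_in_Morgans`.
#'
#' @param mosaics an `hs_mosaics` object.
#' @return matrix (2 x animals) rows hap1/hap2 summed over chromosomes? No:
#'   a data.frame with columns `animal`, `chrom`, `hap`, `jumps`.
#' @export
jump_counts <- function(mosaics) {
  stopifnot(inherits(mosaics, "hs_mosaics"))
  out <- do.call(rbind, lapply(seq_along(mosaics$animals), function(i) {
    do.call(rbind, lapply(names(mosaics$animals[[i]]), function(ch) {
      a <- mosaics$animals[[i]][[ch]]
      data.frame(animal = i, chrom = ch, hap = 1:2,
                 jumps = c(length(a$hap1$founder) - 1L,
                           length(a$hap2$founder) - 1L))
    }))
  }))
  rownames(out) <- NULL
  out
}

#' True founder dosages at panel markers
#'
#' Evaluates the mosaics at the marker map: the dose of founder `f` is the
#' number of haplotypes (0, 1 or 2) descending from `f` at that marker.
#'
#' @param mosaics an `hs_mosaics` object.
#' @param panel a [founder_panel()] on the same chromosomes.
#' @return a `founder_dosage` object with integer doses.
#' @export
true_founder_dosage <- function(mosaics, panel) {
  stopifnot(inherits(mosaics, "hs_mosaics"), inherits(panel, "founder_panel"))
  n <- length(mosaics$animals)
  mk <- panel$markers
  Fn <- mosaics$n_founders
  dose <- array(0, dim = c(n, nrow(mk), Fn),
                dimnames = list(paste0("A", seq_len(n)), mk$marker,
                                panel$founders))
  for (chr in unique(mk$chrom)) {
    idx <- which(mk$chrom == chr)
    .assert(chr %in% mosaics$chromosomes$name,
            "chromosome %s present in panel but not in mosaics", chr)
    for (i in seq_len(n)) {
      h1 <- .hap_at(mosaics$animals[[i]][[chr]]$hap1, mk$cM[idx])
      h2 <- .hap_at(mosaics$animals[[i]][[chr]]$hap2, mk$cM[idx])
      for (k in seq_along(idx)) {
        dose[i, idx[k], h1[k]] <- dose[i, idx[k], h1[k]] + 1
        dose[i, idx[k], h2[k]] <- dose[i, idx[k], h2[k]] + 1
      }
    }
  }
  structure(list(dose = dose, markers = mk, founders = panel$founders),
            class = "founder_dosage")
}

#' True diplotype state indices at panel markers
#'
#' @param mosaics an `hs_mosaics` object.
#' @param panel a [founder_panel()].
#' @return animal x marker matrix of state indices in [diplotype_states()]
#'   ordering.
#' @export
true_states <- function(mosaics, panel) {
  stopifnot(inherits(mosaics, "hs_mosaics"), inherits(panel, "founder_panel"))
  st <- diplotype_states(mosaics$n_founders)
  lut <- matrix(0L, mosaics$n_founders, mosaics$n_founders)
  for (k in seq_len(nrow(st))) {
    lut[st$f1[k], st$f2[k]] <- k
    lut[st$f2[k], st$f1[k]] <- k
  }
  mk <- panel$markers
  n <- length(mosaics$animals)
  out <- matrix(NA_integer_, n, nrow(mk),
                dimnames = list(paste0("A", seq_len(n)), mk$marker))
  for (chr in unique(mk$chrom)) {
    idx <- which(mk$chrom == chr)
    for (i in seq_len(n)) {
      h1 <- .hap_at(mosaics$animals[[i]][[chr]]$hap1, mk$cM[idx])
      h2 <- .hap_at(mosaics$animals[[i]][[chr]]$hap2, mk$cM[idx])
      out[i, idx] <- lut[cbind(h1, h2)]
    }
  }
  out
}

#' Simulate array genotypes from mosaics
#'
#' The genotype at a marker is the sum of the two founder alleles carried
#' by the animal's haplotypes, each allele flipped independently with
#' probability `eps`, then set missing with probability `missing_rate`.
#'
#' @param mosaics an `hs_mosaics` object.
#' @param panel a [founder_panel()].
#' @param eps per-allele flip probability.
#' @param missing_rate probability a genotype call is missing.
#' @param seed integer seed.
#' @return marker x animal matrix with values in `{0, 1, 2, NA}`.
#' @export
simulate_genotypes <- function(mosaics, panel, eps = 0.01, missing_rate = 0.01,
                               seed = 1) {
  stopifnot(inherits(mosaics, "hs_mosaics"), inherits(panel, "founder_panel"))
  .assert_prob(eps, "eps"); .assert_prob(missing_rate, "missing_rate")
  set.seed(seed)
  mk <- panel$markers
  n <- length(mosaics$animals)
  M <- nrow(mk)
  geno <- matrix(NA_integer_, M, n,
                 dimnames = list(mk$marker, paste0("A", seq_len(n))))
  for (chr in unique(mk$chrom)) {
    idx <- which(mk$chrom == chr)
    .assert(chr %in% mosaics$chromosomes$name,
            "chromosome %s present in panel but not in mosaics", chr)
    for (i in seq_len(n)) {
      h1 <- .hap_at(mosaics$animals[[i]][[chr]]$hap1, mk$cM[idx])
      h2 <- .hap_at(mosaics$animals[[i]][[chr]]$hap2, mk$cM[idx])
      a1 <- panel$alleles[cbind(h1, idx)]
      a2 <- panel$alleles[cbind(h2, idx)]
      if (eps > 0) {
        f1 <- stats::rbinom(length(idx), 1, eps) == 1
        f2 <- stats::rbinom(length(idx), 1, eps) == 1
        a1[f1] <- 1 - a1[f1]
        a2[f2] <- 1 - a2[f2]
      }
      g <- a1 + a2
      if (missing_rate > 0) {
        g[stats::runif(length(idx)) < missing_rate] <- NA_integer_
      }
      geno[idx, i] <- as.integer(g)
    }
  }
  storage.mode(geno) <- "integer"
  geno
}

#' Truth record for phenotype simulation
#'
#' @param qtl list of QTL, each a list with `marker` (index into the marker
#'   table), `effects` (per-founder additive effects) and `var_frac`
#'   (target fraction of phenotypic variance).
#' @param h2 target polygenic variance fraction.
#' @param mediation_scenario one of `"none"`, `"full_mediation"`,
#'   `"colocal_no_mediation"`, `"partial_mediation"`.
#' @return object of class `truth_record`.
#' @export
truth_record <- function(qtl = list(), h2 = 0,
                         mediation_scenario = "none") {
  .assert(h2 >= 0 && h2 < 1, "h2 target must lie in [0, 1)")
  vf <- vapply(qtl, function(q) q$var_frac, 0)
  .assert(all(vf >= 0 & vf < 1), "QTL variance fractions must lie in [0, 1)")
  .assert(sum(vf) + h2 <= 1, "variance fractions sum above 1")
  .assert(mediation_scenario %in%
            c("none", "full_mediation", "colocal_no_mediation",
              "partial_mediation"),
          "unknown mediation scenario '%s'", mediation_scenario)
  structure(list(qtl = qtl, h2 = h2,
                 mediation_scenario = mediation_scenario),
            class = "truth_record")
}

## scale a centred component to an exact sample-variance target
.scale_component <- function(x, target_var) {
  x <- x - mean(x)
  v <- stats::var(x)
  if (v <= 0 || target_var <= 0) return(x * 0)
  x * sqrt(target_var / v)
}

#' Simulate a phenotype with known variance decomposition
#'
#' `y = sum of QTL additive founder effects + polygenic draw with
#' covariance proportional to the kinship + independent noise`.  Each
#' component is rescaled so its realised sample-variance fraction matches
#' its target (QTL fractions and `h2`), with noise filling the remainder;
#' total sample variance is 1.  A QTL whose founder effects are all equal
#' contributes nothing regardless of its target.
#'
#' @param dosage a `founder_dosage` (true or imputed).
#' @param kinship an `n x n` PSD kinship matrix.
#' @param truth a [truth_record()].
#' @param seed integer seed.
#' @return numeric phenotype vector with attribute `components` (list of
#'   the realised QTL, polygenic and noise parts).
#' @export
simulate_phenotype <- function(dosage, kinship, truth, seed = 1) {
  stopifnot(inherits(dosage, "founder_dosage"), inherits(truth, "truth_record"))
  n <- dim(dosage$dose)[1]
  .assert(is.matrix(kinship) && all(dim(kinship) == n),
          "kinship must be %d x %d", n, n)
  ev <- eigen(kinship, symmetric = TRUE)
  .assert(all(is.finite(ev$values)) && min(ev$values) > -1e-8,
          "kinship matrix is not positive semi-definite")
  .assert(max(ev$values) > 1e-12, "kinship matrix is singular (all-zero)")
  set.seed(seed)
  g <- rep(0, n)
  for (q in truth$qtl) {
    Dq <- dosage$dose[, q$marker, ]
    g <- g + .scale_component(drop(Dq %*% q$effects), q$var_frac)
  }
  u <- drop(ev$vectors %*% (sqrt(pmax(ev$values, 0)) * stats::rnorm(n)))
  u <- .scale_component(u, truth$h2)
  noise_frac <- 1 - truth$h2 - sum(vapply(truth$qtl, function(q) {
    if (stats::var(drop(dosage$dose[, q$marker, ] %*% q$effects)) > 0)
      q$var_frac else 0
  }, 0))
  e <- .scale_component(stats::rnorm(n), noise_frac)
  y <- g + u + e
  attr(y, "components") <- list(qtl = g, polygenic = u, noise = e)
  y
}

#' Simulate expression traits for a mediation scenario
#'
#' Builds a small expression panel around a detected QTL: one candidate
#' gene whose relationship to the marker and the phenotype is dictated by
#' the scenario, plus independent "decoy" genes (half local to the QTL,
#' half on another chromosome) and one zero-inflated local gene (80%
#' zeros) that must fail the >25% non-zero expression filter.
#'
#' Scenarios (x = standardised allele dose at the QTL marker, z = gene
#' liability, u = polygenic draw):
#' \describe{
#'   \item{full_mediation}{`z = a x + e_g`; the phenotype is regenerated as
#'     `y = b z + u + e`, so the whole QTL effect flows through the gene.}
#'   \item{colocal_no_mediation}{`z = a x + e_g` (a cis-eQTL is present)
#'     but `y = c x + u + e` directly; the gene is off the causal path.}
#'   \item{partial_mediation}{`y = c x + b z + u + e`: the marker retains a
#'     direct effect and the gene adds information beyond it.}
#'   \item{none}{all genes are decoys; `y = u + e`.}
#' }
#' Counts are Poisson with a log link on the liability, so CPM + INT
#' processing recovers an approximately linear readout.
#'
#' @param qtl_marker marker index of the QTL peak.
#' @param dosage a `founder_dosage`.
#' @param panel the matching [founder_panel()] (for the allele dose and
#'   gene coordinates).
#' @param kinship kinship matrix used to regenerate the phenotype.
#' @param scenario mediation scenario (see above).
#' @param seed integer seed.
#' @param qtl_frac variance fraction of the (mediated or direct) QTL
#'   effect on the phenotype (default 0.2).
#' @param h2 polygenic fraction of the regenerated phenotype (default 0.45).
#' @param cis_frac fraction of gene-liability variance explained by the
#'   marker (default 0.5, a strong cis-eQTL).
#' @param n_decoys number of decoy genes (default 20).
#' @return list with `counts` (gene x animal matrix), `annotations`
#'   (gene, chrom, start, end), `phenotype` (regenerated y) and `truth`
#'   (scenario, mediator gene, decoys, zero-inflated gene).
#' @export
simulate_expression <- function(qtl_marker, dosage, panel, kinship,
                                scenario = "full_mediation", seed = 1,
                                qtl_frac = 0.2, h2 = 0.45, cis_frac = 0.5,
                                n_decoys = 20) {
  stopifnot(inherits(dosage, "founder_dosage"), inherits(panel, "founder_panel"))
  .assert(scenario %in% c("none", "full_mediation", "colocal_no_mediation",
                          "partial_mediation"),
          "unknown mediation scenario '%s'", scenario)
  set.seed(seed)
  n <- dim(dosage$dose)[1]
  mk <- panel$markers
  x <- drop(dosage$dose[, qtl_marker, ] %*% panel$alleles[, qtl_marker])
  .assert(stats::var(x) > 0, "allele dose at the QTL marker is constant")
  x <- drop(scale(x))
  ev <- eigen(kinship, symmetric = TRUE)
  draw_u <- function() .scale_component(
    drop(ev$vectors %*% (sqrt(pmax(ev$values, 0)) * stats::rnorm(n))), h2)

  ## gene liability with (or without) a cis-eQTL at the marker
  z <- if (scenario == "none") stats::rnorm(n) else
    .scale_component(x, cis_frac) + .scale_component(stats::rnorm(n), 1 - cis_frac)
  z <- drop(scale(z))

  y <- switch(scenario,
    none = draw_u() + .scale_component(stats::rnorm(n), 1 - h2),
    full_mediation = .scale_component(z, qtl_frac) + draw_u() +
      .scale_component(stats::rnorm(n), 1 - qtl_frac - h2),
    colocal_no_mediation = .scale_component(x, qtl_frac) + draw_u() +
      .scale_component(stats::rnorm(n), 1 - qtl_frac - h2),
    partial_mediation = .scale_component(x, qtl_frac / 2) +
      .scale_component(z, qtl_frac / 2) + draw_u() +
      .scale_component(stats::rnorm(n), 1 - qtl_frac - h2))

  counts_from_liability <- function(l) {
    stats::rpois(n, exp(log(200) + 0.5 * l))
  }
  genes <- character(0); rows <- list(); ann <- list()
  peak_bp <- mk$bp[qtl_marker]
  peak_chr <- mk$chrom[qtl_marker]
  other_chr <- setdiff(unique(mk$chrom), peak_chr)
  other_chr <- if (length(other_chr)) other_chr[1] else peak_chr

  add_gene <- function(name, l, chrom, start, end) {
    genes[[length(genes) + 1L]] <<- name
    rows[[length(rows) + 1L]] <<- counts_from_liability(l)
    ann[[length(ann) + 1L]] <<- data.frame(gene = name, chrom = chrom,
                                           start = start, end = end,
                                           stringsAsFactors = FALSE)
  }
  mediator <- if (scenario == "none") NA_character_ else "gene_target"
  if (scenario != "none")
    add_gene("gene_target", z, peak_chr, peak_bp - 5e4, peak_bp + 5e4)
  ## zero-inflated local decoy: 80% zeros, fails the >25% non-zero filter
  zi <- counts_from_liability(stats::rnorm(n))
  zi[sample.int(n, ceiling(0.8 * n))] <- 0
  genes[[length(genes) + 1L]] <- "gene_zeroinf"
  rows[[length(rows) + 1L]] <- zi
  ann[[length(ann) + 1L]] <- data.frame(gene = "gene_zeroinf", chrom = peak_chr,
                                        start = peak_bp - 2e4, end = peak_bp + 2e4,
                                        stringsAsFactors = FALSE)
  for (j in seq_len(n_decoys)) {
    local <- j <= n_decoys / 2
    ## local decoys straddle the peak so they pass the locality criterion
    ## even for a single-marker LD interval
    add_gene(sprintf("gene_decoy%02d", j), stats::rnorm(n),
             if (local) peak_chr else other_chr,
             if (local) peak_bp - 1e4 - j * 100 else 1e6 + j * 1e3,
             if (local) peak_bp + 1e4 + j * 100 else 1e6 + j * 1e3 + 500)
  }
  counts <- do.call(rbind, rows)
  rownames(counts) <- unlist(genes)
  colnames(counts) <- dimnames(dosage$dose)[[1]]
  list(counts = counts,
       annotations = do.call(rbind, ann),
       phenotype = y,
       truth = list(scenario = scenario, mediator = mediator,
                    zero_inflated = "gene_zeroinf",
                    decoys = grep("decoy", unlist(genes), value = TRUE)))
}

#' One-shot population simulation
#'
#' Convenience wrapper chaining panel, mosaics, genotypes, true dosages and
#' kinship, and optionally a phenotype, all from the config's master seed.
#'
#' @param config a [sim_config()].
#' @param truth optional [truth_record()]; if supplied a phenotype is
#'   simulated from the true founder dosages.
#' @return list with `panel`, `mosaics`, `genotypes`, `dosage` (true
#'   founder dosages), `kinship`, and `phenotype`/`truth` when requested.
#' @export
simulate_population <- function(config, truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  panel <- simulate_founder_panel(config)
  mosaics <- simulate_mosaics(config)
  geno <- simulate_genotypes(mosaics, panel,
                             eps = config$genotyping_error,
                             missing_rate = config$missing_rate,
                             seed = derive_seed(config$seed, "genotypes"))
  dosage <- true_founder_dosage(mosaics, panel)
  K <- kinship_from_dosages(dosage)
  out <- list(panel = panel, mosaics = mosaics, genotypes = geno,
              dosage = dosage, kinship = K, config = config)
  if (!is.null(truth)) {
    out$phenotype <- simulate_phenotype(dosage, K, truth,
                                        seed = derive_seed(config$seed, "phenotype"))
    out$truth <- truth
  }
  out
}
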