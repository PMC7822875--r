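## Pipeline configuration and end-to-end driver

.config_schema <- list(
  seed = NULL,
  output_dir = NULL,
  simulate = c("n_founders", "n_generations", "n_animals", "family_size",
               "chromosomes", "genotyping_error", "missing_rate", "qtl",
               "h2", "mediation_scenario", "qtl_frac", "expression_h2"),
  hmm = c("G", "eps"),
  scan = c("B", "alpha", "r2_min"),
  h2_mcmc = c("n_iter", "burn_in"),
  effects = c("M", "n_iter", "burn_in"),
  mediation = c("fdr")
)

#' Validate a pipeline run configuration
#'
#' Schema-checks a configuration list (typically parsed from YAML or
#' JSON): unknown keys are rejected at both levels, `seed` is required,
#' and every stochastic stage therefore has an explicit seed derived from
#' it via [derive_seed()].
#'
#' @param config named list.
#' @return the validated config (with defaults filled in), invisibly
#'   classed `run_config`.
#' @export
validate_config <- function(config) {
  .assert(is.list(config), "config must be a named list")
  unknown <- setdiff(names(config), names(.config_schema))
  .assert(length(unknown) == 0, "unknown config key(s): %s",
          paste(unknown, collapse = ", "))
  .assert(!is.null(config$seed), "config must set an integer 'seed'")
  .assert(is.numeric(config$seed) && config$seed == round(config$seed),
          "'seed' must be an integer")
  for (blk in c("simulate", "hmm", "scan", "h2_mcmc", "effects", "mediation")) {
    if (is.null(config[[blk]])) next
    unknown <- setdiff(names(config[[blk]]), .config_schema[[blk]])
    .assert(length(unknown) == 0, "unknown key(s) in '%s': %s", blk,
            paste(unknown, collapse = ", "))
  }
  defaults <- list(
    hmm = list(G = 70, eps = 0.01),
    scan = list(B = 1000, alpha = 0.05, r2_min = 0.5),
    h2_mcmc = list(n_iter = 10000, burn_in = 1000),
    effects = list(M = 200, n_iter = 1000, burn_in = 200),
    mediation = list(fdr = 0.1)
  )
  for (blk in names(defaults)) {
    config[[blk]] <- utils::modifyList(defaults[[blk]],
                                       config[[blk]] %||% list())
  }
  structure(config, class = "run_config")
}

#' Read a pipeline configuration file (YAML or JSON)
#'
#' @param path configuration file; `.json` is parsed with jsonlite,
#'   anything else with yaml.
#' @return a validated `run_config`.
#' @export
read_config <- function(path) {
  .assert(file.exists(path), "config file not found: %s", path)
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  validate_config(cfg)
}

.provenance <- function(command, params, output_dir) {
  obj <- list(package = "hsqtl",
              version = as.character(utils::packageVersion("hsqtl")),
              r_version = paste(R.version$major, R.version$minor, sep = "."),
              command = command,
              parameters = params)
  jsonlite::write_json(obj, file.path(output_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

## simulate stage shared by `hs_cli simulate` and the pipeline
.stage_simulate <- function(config, out) {
  sim <- config$simulate %||% list()
  chrom <- if (!is.null(sim$chromosomes)) {
    do.call(rbind, lapply(sim$chromosomes, as.data.frame))
  } else NULL
  sc <- sim_config(n_founders = sim$n_founders %||% 8,
                   n_generations = sim$n_generations %||% 70,
                   chromosomes = chrom,
                   n_animals = sim$n_animals %||% 245,
                   family_size = sim$family_size %||% 5,
                   genotyping_error = sim$genotyping_error %||% 0.01,
                   missing_rate = sim$missing_rate %||% 0.01,
                   seed = config$seed)
  ## effects may be a numeric vector of per-founder effects, or the string
  ## "snp": the founder allele pattern at the QTL marker itself, i.e. the
  ## causal variant is the genotyped SNP
  panel_pre <- simulate_founder_panel(sc)
  qtl <- lapply(sim$qtl %||% list(), function(q) {
    eff <- if (identical(q$effects, "snp")) {
      as.numeric(panel_pre$alleles[, q$marker])
    } else unlist(q$effects)
    list(marker = q$marker, effects = eff, var_frac = q$var_frac)
  })
  truth <- truth_record(qtl = qtl, h2 = sim$h2 %||% 0,
                        mediation_scenario = sim$mediation_scenario %||% "none")
  pop <- simulate_population(sc, truth)
  y <- pop$phenotype
  expr <- NULL
  if (truth$mediation_scenario != "none") {
    .assert(length(qtl) >= 1, "a mediation scenario requires at least one QTL")
    expr <- simulate_expression(qtl[[1]]$marker, pop$dosage, pop$panel,
                                pop$kinship,
                                scenario = truth$mediation_scenario,
                                seed = derive_seed(config$seed, "expression"),
                                qtl_frac = sim$qtl_frac %||% 0.2,
                                h2 = truth$h2)
    y <- expr$phenotype
  }
  write_founder_panel(pop$panel, file.path(out, "panel.tsv"))
  write_genotypes(pop$genotypes, file.path(out, "genotypes.tsv"))
  write_phenotypes(data.frame(animal = paste0("A", seq_along(y)),
                              trait = as.numeric(y),
                              stringsAsFactors = FALSE),
                   file.path(out, "phenotypes.tsv"))
  write_truth(truth, pop$mosaics, file.path(out, "truth.json"))
  if (!is.null(expr)) {
    write_expression(expr$counts, file.path(out, "expression.tsv"))
    write_annotations(expr$annotations, file.path(out, "annotations.tsv"))
  }
  invisible(pop)
}

#' Run the full pipeline from a configuration
#'
#' Chains simulation (or reading of existing inputs), HMM imputation,
#' phenotype preparation, heritability, the genome scan with bootstrap
#' threshold and LD intervals, founder-effect estimation at the top peak,
#' and — when expression data exist — mediation analysis.  All outputs are
#' TSV/JSON files under `output_dir`, plus a provenance record sufficient
#' to reproduce the run (package version, full parameters, master seed).
#'
#' @param config a `run_config`, or path to a YAML/JSON config file.
#' @param output_dir output directory (created if needed); defaults to
#'   `config$output_dir`.
#' @return invisibly, a list of in-memory results.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- read_config(config)
  if (!inherits(config, "run_config")) config <- validate_config(config)
  out <- output_dir %||% config$output_dir
  .assert(!is.null(out), "an output directory is required")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed

  ## stage 1: synthetic inputs
  .stage_simulate(config, out)
  panel <- read_founder_panel(file.path(out, "panel.tsv"))
  geno <- read_genotypes(file.path(out, "genotypes.tsv"))
  pheno <- read_phenotypes(file.path(out, "phenotypes.tsv"))

  ## stage 2: HMM imputation, dosages, kinship
  keep <- informative_markers(panel, geno)
  panel_i <- subset_panel(panel, keep)
  geno_i <- geno[keep, , drop = FALSE]
  probs <- forward_backward(geno_i, panel_i, G = config$hmm$G,
                            eps = config$hmm$eps)
  fdos <- dosages_from_probs(probs)
  sdos <- snp_dosage(fdos, panel_i)
  K <- kinship_from_dosages(fdos)
  dimnames(K) <- list(colnames(geno_i), colnames(geno_i))
  write_founder_dosage(fdos, file.path(out, "founder_dosage.tsv"))
  write_snp_dosage(sdos, file.path(out, "snp_dosage.tsv"))
  write_kinship(K, file.path(out, "kinship.tsv"))

  ## stage 3: trait preparation
  y <- rank_inverse_normal(pheno$trait)
  write_phenotypes(data.frame(animal = pheno$animal, trait = y,
                              stringsAsFactors = FALSE),
                   file.path(out, "phenotypes_int.tsv"))

  ## stage 4: heritability
  h2 <- estimate_h2(y, K, n_iter = config$h2_mcmc$n_iter,
                    burn_in = config$h2_mcmc$burn_in,
                    seed = derive_seed(seed, "h2"))
  .write_tsv(data.frame(trait = "trait", mode = h2$mode,
                        hpd_lower = h2$hpd[1], hpd_upper = h2$hpd[2],
                        ess = h2$ess), file.path(out, "h2.tsv"))

  ## stages 5-7: scan, threshold, intervals
  scan <- lrt_scan(y, sdos, K, markers = panel_i$markers)
  write_scan(scan, file.path(out, "scan.tsv"))
  thr <- bootstrap_threshold(attr(scan, "null_fit"), sdos,
                             B = config$scan$B, alpha = config$scan$alpha,
                             seed = derive_seed(seed, "bootstrap"))
  jsonlite::write_json(list(threshold = thr$threshold, B = thr$B,
                            alpha = thr$alpha),
                       file.path(out, "threshold.json"),
                       auto_unbox = TRUE, digits = NA)
  ivs <- scan_intervals(scan, sdos, thr$threshold,
                        r2_min = config$scan$r2_min, trait = "trait")
  write_intervals(ivs, file.path(out, "intervals.tsv"))

  ## stage 8: founder effects at the strongest peak
  eff <- NULL
  if (length(ivs)) {
    peak_i <- match(ivs[[1]]$peak_marker, panel_i$markers$marker)
    eff <- diploffect_fit(y, probs, K, M = config$effects$M,
                          n_iter = config$effects$n_iter,
                          burn_in = config$effects$burn_in,
                          seed = derive_seed(seed, "effects"),
                          peak = peak_i, founders = panel_i$founders)
    .write_tsv(eff$founder_effects, file.path(out, "effects.tsv"))
    jsonlite::write_json(list(h2_qtl_mode = eff$h2_qtl$mode,
                              h2_qtl_mean = eff$h2_qtl_mean,
                              hpd = unname(eff$h2_qtl$hpd),
                              ess_importance = eff$ess),
                         file.path(out, "effects_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  ## stage 9: mediation, when expression data exist
  med <- NULL
  expr_path <- file.path(out, "expression.tsv")
  if (file.exists(expr_path) && length(ivs)) {
    counts <- read_expression(expr_path)
    annot <- read_annotations(file.path(out, "annotations.tsv"))
    peak_i <- match(ivs[[1]]$peak_marker, panel_i$markers$marker)
    med <- mediate_qtl(y, sdos[, peak_i], K, counts, annot, ivs[[1]],
                       fdr = config$mediation$fdr)
    write_mediation(med, file.path(out, "mediation.tsv"))
  }

  .provenance("pipeline", unclass(config), out)
  invisible(list(h2 = h2, scan = scan, threshold = thr, intervals = ivs,
                 effects = eff, mediation = med))
}

#' Detected-peak LD intervals from a scan
#'
#' One interval per chromosome whose maximum logP reaches the threshold,
#' each anchored at that chromosome's peak marker.
#'
#' @param scan a `scan_result`.
#' @param snp_doses the scanned dose matrix.
#' @param threshold genome-wide logP threshold.
#' @param r2_min LD threshold (default 0.5).
#' @param trait trait name to record.
#' @return list of `qtl_interval` (possibly empty).
#' @export
scan_intervals <- function(scan, snp_doses, threshold, r2_min = 0.5,
                           trait = NA_character_) {
  ivs <- list()
  for (chr in unique(scan$chrom)) {
    on_chr <- which(scan$chrom == chr)
    peak <- on_chr[which.max(scan$logP[on_chr])]
    if (scan$logP[peak] >= threshold) {
      ivs[[length(ivs) + 1L]] <- ld_interval(scan, snp_doses, peak = peak,
                                             r2_min = r2_min,
                                             threshold = threshold,
                                             trait = trait)
    }
  }
  ## strongest first
  if (length(ivs) > 1) {
    ivs <- ivs[order(vapply(ivs, function(x) -x$peak_logP, 0))]
  }
  ivs
}
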