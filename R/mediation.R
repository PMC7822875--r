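## Four-criterion expression mediation analysis at a detected QTL
##
## Given a detected QTL (criterion 1), a local gene's expression is a
## candidate mediator when (2) it has a cis-eQTL at the peak (BH FDR 0.1
## within the local gene set), and (3) conditioning the association on it
## abolishes the QTL signal (conditioned p > 0.05, plausible full
## mediation) and/or (4) it carries information beyond the QTL (1-df LRT
## for the mediator given the marker, BH q <= 0.1, partial mediation).
## Criteria run sequentially with short-circuiting; every computed value
## is retained for audit.

#' Select genes local to a QTL interval
#'
#' A gene is local if its span overlaps the interval `[start_bp, end_bp]`
#' on the same chromosome (any overlap, boundary-straddling genes
#' included).
#'
#' @param annotations data.frame with columns `gene`, `chrom`, `start`,
#'   `end`.
#' @param interval a `qtl_interval`.
#' @return logical vector over annotation rows.
#' @export
select_local_genes <- function(annotations, interval) {
  stopifnot(inherits(interval, "qtl_interval"))
  .assert(all(c("gene", "chrom", "start", "end") %in% names(annotations)),
          "annotations must have columns gene, chrom, start, end")
  annotations$chrom == interval$chrom &
    annotations$start <= interval$end_bp &
    annotations$end >= interval$start_bp
}

#' Non-zero expression filter
#'
#' A gene passes when its fraction of samples with expression strictly
#' greater than zero exceeds `min_frac` strictly (a gene at exactly the
#' threshold fails).
#'
#' @param expr matrix (genes x samples) of counts or CPM, or a single
#'   gene's vector.
#' @param min_frac threshold fraction (default 0.25).
#' @return logical vector (one entry per gene).
#' @export
expression_filter <- function(expr, min_frac = 0.25) {
  if (is.null(dim(expr))) expr <- matrix(expr, nrow = 1)
  rowMeans(expr > 0) > min_frac
}

## 1-df LRT p-value for adding column `test` to covariates `X0` in the LMM
.lmm_lrt_p <- function(y, K, X0, test, eigenK = NULL) {
  f0 <- fit_lmm(y, K, X = X0, eigenK = eigenK)
  f1 <- fit_lmm(y, K, X = cbind(X0, test), eigenK = eigenK)
  lrt <- max(0, 2 * (f1$loglik - f0$loglik))
  if (f1$sigma2 < 1e-12) {
    warning("degenerate fit: tested covariate explains the response exactly")
  }
  stats::pchisq(lrt, df = 1, lower.tail = FALSE)
}

#' cis-eQTL test at the QTL peak
#'
#' LRT p-value for the peak-marker dose as a fixed effect on a gene's
#' (INT-transformed) expression under the kinship LMM.
#'
#' @param expr_gene transformed expression vector for one gene.
#' @param peak_dose allele dose at the peak marker.
#' @param K kinship matrix.
#' @param eigenK optional cached eigendecomposition.
#' @return p-value.
#' @export
cis_eqtl_test <- function(expr_gene, peak_dose, K, eigenK = NULL) {
  .assert(stats::var(expr_gene) > 0, "expression is constant")
  .lmm_lrt_p(expr_gene, K, NULL, cbind(dose = peak_dose), eigenK)
}

#' Full-mediation test (conditioned QTL scan at the peak)
#'
#' Re-tests the peak-marker effect on the trait with the mediator's
#' expression added as a fixed covariate to both the null and alternative
#' models.  A conditioned p-value above 0.05 makes full mediation
#' plausible (the QTL signal is absorbed by the mediator).
#'
#' @param y transformed trait.
#' @param peak_dose allele dose at the peak marker.
#' @param mediator transformed expression of the candidate mediator.
#' @param K kinship matrix.
#' @param eigenK optional cached eigendecomposition.
#' @return list with `p` (conditioned QTL p-value) and `plausible`
#'   (`p > 0.05`).
#' @export
full_mediation_test <- function(y, peak_dose, mediator, K, eigenK = NULL) {
  .assert(stats::var(mediator) > 0, "mediator expression is constant")
  p <- .lmm_lrt_p(y, K, cbind(mediator = mediator), cbind(dose = peak_dose),
                  eigenK)
  list(p = p, plausible = p > 0.05)
}

#' Partial-mediation test (mediator beyond the QTL)
#'
#' 1-df LRT for the mediator coefficient in the model already containing
#' the peak-marker effect: compares trait ~ dose + mediator against
#' trait ~ dose.
#'
#' @inheritParams full_mediation_test
#' @return p-value.
#' @export
partial_mediation_test <- function(y, peak_dose, mediator, K, eigenK = NULL) {
  .assert(stats::var(mediator) > 0, "mediator expression is constant")
  .lmm_lrt_p(y, K, cbind(dose = peak_dose), cbind(mediator = mediator),
             eigenK)
}

#' Mediation verdicts from computed criteria
#'
#' `candidate_mediator` iff the cis-eQTL q-value is `<= fdr` and (full
#' mediation is plausible or the partial-mediation q-value is `<= fdr`);
#' otherwise the most specific failure label among `not_local`,
#' `filtered`, `no_cis_eqtl`, `not_mediator`.
#'
#' @param table a mediation table (see [mediate_qtl()]) with columns
#'   `local`, `filter_pass`, `cis_q`, `full_plausible`, `partial_q`.
#' @param fdr FDR level (default 0.1).
#' @return character vector of verdicts.
#' @export
mediation_verdict <- function(table, fdr = 0.1) {
  vapply(seq_len(nrow(table)), function(i) {
    r <- table[i, ]
    if (!isTRUE(r$local)) return("not_local")
    if (!isTRUE(r$filter_pass)) return("filtered")
    if (is.na(r$cis_q) || r$cis_q > fdr) return("no_cis_eqtl")
    full_ok <- isTRUE(r$full_plausible)
    part_ok <- !is.na(r$partial_q) && r$partial_q <= fdr
    if (full_ok || part_ok) "candidate_mediator" else "not_mediator"
  }, "")
}

#' Run the four-criterion mediation analysis at a QTL
#'
#' Applies the sequential procedure to every annotated gene: locality to
#' the LD interval, the strict >25% non-zero expression filter, the
#' cis-eQTL test with BH FDR control within the local gene set (local
#' testing makes genome-wide correction unnecessary), and — for genes with
#' a cis-eQTL — the full- and partial-mediation tests, the latter BH
#' corrected within the evaluated genes.  Expression is CPM normalised and
#' INT transformed before testing, matching the trait handling.
#'
#' @param y transformed trait.
#' @param peak_dose allele dose at the QTL peak marker.
#' @param K kinship matrix.
#' @param counts gene x sample count matrix (sample order matching `y`).
#' @param annotations data.frame with `gene`, `chrom`, `start`, `end`.
#' @param interval the QTL's `qtl_interval`.
#' @param fdr BH FDR level for criteria 2 and 4 (default 0.1).
#' @param full_p_cut conditioned-p cutoff for plausible full mediation
#'   (default 0.05).
#' @return a `mediation_table` data.frame, one row per annotated gene,
#'   with all computed criteria and the verdict.
#' @export
mediate_qtl <- function(y, peak_dose, K, counts, annotations, interval,
                        fdr = 0.1, full_p_cut = 0.05) {
  .assert(nrow(counts) == nrow(annotations),
          "counts and annotations must describe the same genes")
  .assert(ncol(counts) == length(y), "counts columns must match length(y)")
  eigenK <- .kinship_eigen(K)
  tab <- data.frame(gene = annotations$gene,
                    local = select_local_genes(annotations, interval),
                    filter_pass = NA, cis_p = NA_real_, cis_q = NA_real_,
                    full_p = NA_real_, full_plausible = NA,
                    partial_p = NA_real_, partial_q = NA_real_,
                    stringsAsFactors = FALSE)
  cpm <- cpm_normalize(counts)
  tab$filter_pass <- expression_filter(cpm)
  ## criterion 2: cis-eQTL among local, expressed genes
  test_idx <- which(tab$local & tab$filter_pass)
  for (i in test_idx) {
    expr <- rank_inverse_normal(cpm[i, ])
    tab$cis_p[i] <- cis_eqtl_test(expr, peak_dose, K, eigenK)
  }
  tab$cis_q[test_idx] <- stats::p.adjust(tab$cis_p[test_idx], method = "BH")
  ## criteria 3 and 4 for genes with a cis-eQTL
  cis_idx <- test_idx[!is.na(tab$cis_q[test_idx]) & tab$cis_q[test_idx] <= fdr]
  for (i in cis_idx) {
    expr <- rank_inverse_normal(cpm[i, ])
    fm <- full_mediation_test(y, peak_dose, expr, K, eigenK)
    tab$full_p[i] <- fm$p
    tab$full_plausible[i] <- fm$p > full_p_cut
    tab$partial_p[i] <- partial_mediation_test(y, peak_dose, expr, K, eigenK)
  }
  tab$partial_q[cis_idx] <- stats::p.adjust(tab$partial_p[cis_idx],
                                            method = "BH")
  tab$verdict <- mediation_verdict(tab, fdr)
  class(tab) <- c("mediation_table", "data.frame")
  tab
}
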