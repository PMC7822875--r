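#' Founder allele panel
#'
#' Container for the inbred founder reference: founder names, the marker
#' map (chromosome, 1-based bp, cM) and the biallelic founder alleles.
#' Founders are inbred, so each founder carries a single allele per marker.
#'
#' @param founders character vector of founder names (length `F >= 2`).
#' @param markers data.frame with columns `marker`, `chrom`, `bp`, `cM`;
#'   positions must be strictly increasing within each chromosome.
#' @param alleles `F x M` matrix of 0/1 founder alleles, columns in marker
#'   order.
#' @return object of class `founder_panel`.
#' @export
founder_panel <- function(founders, markers, alleles) {
  .assert(length(founders) >= 2, "need at least 2 founders")
  .assert(is.data.frame(markers) &&
            all(c("marker", "chrom", "bp", "cM") %in% names(markers)),
          "markers must have columns marker, chrom, bp, cM")
  .assert(!anyDuplicated(markers$marker), "duplicated marker ids")
  alleles <- as.matrix(alleles)
  .assert(nrow(alleles) == length(founders) && ncol(alleles) == nrow(markers),
          "alleles must be founders x markers (%d x %d), got %d x %d",
          length(founders), nrow(markers), nrow(alleles), ncol(alleles))
  .assert(all(alleles %in% c(0, 1)), "founder alleles must be 0/1")
  for (chr in unique(markers$chrom)) {
    i <- which(markers$chrom == chr)
    .assert(all(diff(markers$bp[i]) > 0) && all(diff(markers$cM[i]) >= 0),
            "marker positions not sorted on chromosome %s", chr)
  }
  rownames(alleles) <- founders
  colnames(alleles) <- markers$marker
  structure(list(founders = founders, markers = markers, alleles = alleles),
            class = "founder_panel")
}

#' @export
print.founder_panel <- function(x, ...) {
  cat(sprintf("founder panel: %d founders, %d markers on %d chromosome(s)\n",
              length(x$founders), nrow(x$markers),
              length(unique(x$markers$chrom))))
  invisible(x)
}

#' Informative-marker filter
#'
#' A marker is informative if it is polymorphic across the founder strains
#' (at least one allele contrast) and, when genotypes are supplied, its
#' call rate is at least `min_call_rate`.  Mirrors the reduction of an
#' array to the markers that actually distinguish founder haplotypes.
#'
#' @param panel a [founder_panel()].
#' @param genotypes optional marker x animal genotype matrix.
#' @param min_call_rate minimum fraction of non-missing calls (default 0.9).
#' @return logical vector over markers.
#' @export
informative_markers <- function(panel, genotypes = NULL, min_call_rate = 0.9) {
  poly <- apply(panel$alleles, 2, function(a) any(a != a[1]))
  if (!is.null(genotypes)) {
    cr <- rowMeans(!is.na(genotypes))
    poly & cr >= min_call_rate
  } else poly
}

#' Subset a founder panel to a marker set
#'
#' @param panel a [founder_panel()].
#' @param keep logical or integer index over markers.
#' @return the subsetted `founder_panel`.
#' @export
subset_panel <- function(panel, keep) {
  founder_panel(panel$founders,
                panel$markers[keep, , drop = FALSE],
                panel$alleles[, keep, drop = FALSE])
}
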