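## Tab-separated file formats
##
## All tables are UTF-8, tab-delimited, with a documented header and "NA"
## as the missing-value token.  Readers validate structure (header names,
## ragged rows, duplicate ids, sorted marker maps, value domains) and
## report errors with row/column coordinates; write-then-read is the
## identity on valid data.

.check_header <- function(got, want, path) {
  .assert(length(got) >= length(want) && all(got[seq_along(want)] == want),
          "%s: expected header to start with (%s), got (%s)",
          path, paste(want, collapse = ", "),
          paste(utils::head(got, length(want) + 2), collapse = ", "))
}

.read_tsv <- function(path) {
  .assert(file.exists(path), "file not found: %s", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  .assert(length(unique(nf)) == 1L,
          "%s: ragged rows (line %d has %d fields, line 1 has %d)",
          path, which(nf != nf[1])[1], nf[which(nf != nf[1])[1]], nf[1])
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Write / read a founder panel
#'
#' Columns: `marker`, `chrom`, `bp`, `cM`, then one 0/1 allele column per
#' founder.
#'
#' @param panel a [founder_panel()].
#' @param path file path.
#' @return `read_founder_panel` returns a `founder_panel`.
#' @export
write_founder_panel <- function(panel, path) {
  stopifnot(inherits(panel, "founder_panel"))
  df <- cbind(panel$markers, as.data.frame(t(panel$alleles)))
  .write_tsv(df, path)
}

#' @rdname write_founder_panel
#' @export
read_founder_panel <- function(path) {
  df <- .read_tsv(path)
  .check_header(names(df), c("marker", "chrom", "bp", "cM"), path)
  founders <- names(df)[-(1:4)]
  .assert(length(founders) >= 2, "%s: fewer than 2 founder columns", path)
  al <- t(as.matrix(df[founders]))
  bad <- which(!(al %in% c(0, 1)))
  .assert(length(bad) == 0, "%s: non 0/1 founder allele at founder %s, marker %s",
          path, founders[(bad[1] - 1) %% length(founders) + 1],
          df$marker[(bad[1] - 1) %/% length(founders) + 1])
  founder_panel(founders, df[, 1:4], al)
}

#' Write / read a genotype matrix
#'
#' Rows are markers (first column `marker`), remaining columns animals;
#' values 0/1/2 or `NA`.
#'
#' @param geno marker x animal matrix.
#' @param path file path.
#' @return `read_genotypes` returns the marker x animal integer matrix.
#' @export
write_genotypes <- function(geno, path) {
  df <- data.frame(marker = rownames(geno) %||% paste0("m", seq_len(nrow(geno))),
                   geno, check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(df, path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  df <- .read_tsv(path)
  .check_header(names(df), "marker", path)
  .assert(!anyDuplicated(df$marker), "%s: duplicated marker id '%s'",
          path, df$marker[anyDuplicated(df$marker)])
  .assert(!anyDuplicated(names(df)[-1]), "%s: duplicated animal id", path)
  g <- as.matrix(df[, -1, drop = FALSE])
  bad <- which(!(g %in% c(0L, 1L, 2L) | is.na(g)))
  if (length(bad)) {
    i <- (bad[1] - 1) %% nrow(g) + 1
    j <- (bad[1] - 1) %/% nrow(g) + 1
    stop(sprintf("%s: invalid genotype '%s' at marker %s, animal %s",
                 path, g[bad[1]], df$marker[i], colnames(g)[j]), call. = FALSE)
  }
  storage.mode(g) <- "integer"
  rownames(g) <- df$marker
  g
}

#' Write / read a phenotype table
#'
#' First column `animal`, remaining columns numeric traits.
#'
#' @param pheno data.frame with an `animal` column.
#' @param path file path.
#' @export
write_phenotypes <- function(pheno, path) {
  .assert("animal" %in% names(pheno), "phenotypes need an 'animal' column")
  .write_tsv(pheno, path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  df <- .read_tsv(path)
  .check_header(names(df), "animal", path)
  .assert(!anyDuplicated(df$animal), "%s: duplicated animal id '%s'",
          path, df$animal[anyDuplicated(df$animal)])
  df
}

#' Write / read an expression (or CPM) matrix
#'
#' First column `gene`, remaining columns animals.
#'
#' @param expr gene x animal matrix.
#' @param path file path.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .write_tsv(df, path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  df <- .read_tsv(path)
  .check_header(names(df), "gene", path)
  .assert(!anyDuplicated(df$gene), "%s: duplicated gene id", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene
  m
}

#' Write / read gene annotations (gene, chrom, start, end)
#'
#' @param annot annotation data.frame.
#' @param path file path.
#' @export
write_annotations <- function(annot, path) {
  .assert(all(c("gene", "chrom", "start", "end") %in% names(annot)),
          "annotations need columns gene, chrom, start, end")
  .write_tsv(annot, path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  df <- .read_tsv(path)
  .check_header(names(df), c("gene", "chrom", "start", "end"), path)
  df
}

#' Write / read a SNP dosage matrix
#'
#' Stored marker-major (rows markers, columns animals); the reader returns
#' the animal x marker orientation used by the scan functions.
#'
#' @param doses animal x marker dose matrix.
#' @param path file path.
#' @export
write_snp_dosage <- function(doses, path) {
  df <- data.frame(marker = colnames(doses) %||% paste0("m", seq_len(ncol(doses))),
                   t(doses), check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(df, path)
}

#' @rdname write_snp_dosage
#' @export
read_snp_dosage <- function(path) {
  df <- .read_tsv(path)
  .check_header(names(df), "marker", path)
  m <- t(as.matrix(df[, -1, drop = FALSE]))
  colnames(m) <- df$marker
  .assert(all(is.finite(m)) && all(m >= -1e-9 & m <= 2 + 1e-9),
          "%s: doses must lie in [0, 2]", path)
  m
}

#' Write / read founder dosages
#'
#' Stored marker-major with one column per `animal:founder` pair.
#'
#' @param dosage a `founder_dosage`.
#' @param path file path.
#' @export
write_founder_dosage <- function(dosage, path) {
  stopifnot(inherits(dosage, "founder_dosage"))
  dm <- dim(dosage$dose)
  animals <- dimnames(dosage$dose)[[1]] %||% paste0("A", seq_len(dm[1]))
  wide <- matrix(aperm(dosage$dose, c(2, 3, 1)), dm[2], dm[3] * dm[1])
  colnames(wide) <- as.vector(outer(dosage$founders, animals,
                                    function(f, a) paste(a, f, sep = ":")))
  df <- data.frame(marker = dosage$markers$marker,
                   chrom = dosage$markers$chrom,
                   bp = dosage$markers$bp, cM = dosage$markers$cM,
                   wide, check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(df, path)
}

#' @rdname write_founder_dosage
#' @export
read_founder_dosage <- function(path) {
  df <- .read_tsv(path)
  .check_header(names(df), c("marker", "chrom", "bp", "cM"), path)
  cols <- names(df)[-(1:4)]
  parts <- strsplit(cols, ":", fixed = TRUE)
  .assert(all(lengths(parts) == 2), "%s: dose columns must be animal:founder",
          path)
  animals <- unique(vapply(parts, `[`, "", 1))
  founders <- unique(vapply(parts, `[`, "", 2))
  M <- nrow(df)
  arr <- array(as.matrix(df[, -(1:4)]),
               dim = c(M, length(founders), length(animals)))
  dose <- aperm(arr, c(3, 1, 2))
  dimnames(dose) <- list(animals, df$marker, founders)
  structure(list(dose = dose, markers = df[, 1:4], founders = founders),
            class = "founder_dosage")
}

#' Write / read a kinship matrix with id header row and column
#'
#' @param K kinship matrix.
#' @param path file path.
#' @export
write_kinship <- function(K, path) {
  ids <- rownames(K) %||% paste0("A", seq_len(nrow(K)))
  df <- data.frame(id = ids, K, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("id", ids)
  .write_tsv(df, path)
}

#' @rdname write_kinship
#' @export
read_kinship <- function(path) {
  df <- .read_tsv(path)
  .check_header(names(df), "id", path)
  K <- as.matrix(df[, -1, drop = FALSE])
  rownames(K) <- df$id
  .assert(nrow(K) == ncol(K) && all(rownames(K) == colnames(K)),
          "%s: kinship row/column ids disagree", path)
  K
}

#' Write / read a scan result
#'
#' @param scan a `scan_result` (or compatible data.frame).
#' @param path file path.
#' @export
write_scan <- function(scan, path) {
  .write_tsv(as.data.frame(scan)[c("marker", "chrom", "bp", "lrt", "logP")],
             path)
}

#' @rdname write_scan
#' @export
read_scan <- function(path) {
  df <- .read_tsv(path)
  .check_header(names(df), c("marker", "chrom", "bp", "lrt", "logP"), path)
  structure(df, class = c("scan_result", "data.frame"))
}

#' Write / read QTL intervals
#'
#' @param intervals a `qtl_interval` or list of them.
#' @param path file path.
#' @export
write_intervals <- function(intervals, path) {
  if (inherits(intervals, "qtl_interval")) intervals <- list(intervals)
  df <- do.call(rbind, lapply(intervals, function(x)
    data.frame(trait = x$trait, chrom = x$chrom, peak_marker = x$peak_marker,
               peak_bp = x$peak_bp, start_bp = x$start_bp, end_bp = x$end_bp,
               peak_logP = x$peak_logP, threshold = x$threshold,
               r2_min = x$r2_min, stringsAsFactors = FALSE)))
  .write_tsv(df, path)
}

#' @rdname write_intervals
#' @export
read_intervals <- function(path) {
  df <- .read_tsv(path)
  .check_header(names(df), c("trait", "chrom", "peak_marker", "peak_bp",
                             "start_bp", "end_bp", "peak_logP", "threshold",
                             "r2_min"), path)
  lapply(seq_len(nrow(df)), function(i) {
    structure(c(as.list(df[i, ]), list(markers = NULL)),
              class = "qtl_interval")
  })
}

#' Write a mediation table
#'
#' @param table a `mediation_table`.
#' @param path file path.
#' @export
write_mediation <- function(table, path) .write_tsv(as.data.frame(table), path)

#' Import genotypes from a VCF (v4.2, GT field only, unphased)
#'
#' Convenience importer: reads the GT field of a plain-text VCF and counts
#' ALT alleles per sample (0/1/2; `./.` becomes `NA`).  Multi-allelic
#' records are rejected.
#'
#' @param path VCF file path.
#' @return list with `genotypes` (marker x sample matrix) and `markers`
#'   (data.frame marker, chrom, bp).
#' @export
read_vcf_genotypes <- function(path) {
  .assert(file.exists(path), "file not found: %s", path)
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  .assert(length(hdr) == 1, "%s: missing #CHROM header line", path)
  cols <- strsplit(sub("^#", "", lines[hdr]), "\t")[[1]]
  samples <- cols[-(1:9)]
  .assert(length(samples) >= 1, "%s: no sample columns", path)
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]
  rec <- strsplit(body, "\t")
  g <- matrix(NA_integer_, length(rec), length(samples))
  mk <- data.frame(marker = character(length(rec)),
                   chrom = character(length(rec)),
                   bp = integer(length(rec)), stringsAsFactors = FALSE)
  for (i in seq_along(rec)) {
    f <- rec[[i]]
    .assert(length(f) == length(cols), "%s: ragged record at line %d",
            path, hdr + i)
    .assert(!grepl(",", f[5], fixed = TRUE),
            "%s: multi-allelic record at line %d", path, hdr + i)
    mk$marker[i] <- if (f[3] == ".") paste0(f[1], "_", f[2]) else f[3]
    mk$chrom[i] <- f[1]
    mk$bp[i] <- as.integer(f[2])
    fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    gt_i <- match("GT", fmt)
    .assert(!is.na(gt_i), "%s: no GT field at line %d", path, hdr + i)
    gt <- vapply(strsplit(f[-(1:9)], ":", fixed = TRUE), `[`, "", gt_i)
    al <- strsplit(gt, "[/|]")
    g[i, ] <- vapply(al, function(a) {
      if (any(a == ".")) NA_integer_ else sum(as.integer(a) > 0L)
    }, 0L)
  }
  rownames(g) <- mk$marker
  colnames(g) <- samples
  list(genotypes = g, markers = mk)
}

#' Write a truth record (plus mosaic intervals) as JSON
#'
#' @param truth a [truth_record()].
#' @param mosaics optional `hs_mosaics`.
#' @param path file path.
#' @export
write_truth <- function(truth, mosaics = NULL, path) {
  obj <- list(qtl = truth$qtl, h2 = truth$h2,
              mediation_scenario = truth$mediation_scenario)
  if (!is.null(mosaics)) {
    obj$mosaics <- lapply(mosaics$animals, function(a)
      lapply(a, function(ch) list(
        hap1 = list(brk = ch$hap1$brk, founder = ch$hap1$founder),
        hap2 = list(brk = ch$hap2$brk, founder = ch$hap2$founder))))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
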