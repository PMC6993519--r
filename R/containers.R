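#' Genotype container
#'
#' Bundles an animals x SNPs dosage matrix (allele counts 0/1/2, `NA` for a
#' failed call) with its genomic SNP map. Dosage columns and map rows must
#' be in the same order; the map is sorted by chromosome then position.
#'
#' @param dosage Integer matrix, animals in rows (rownames = animal ids),
#'   SNPs in columns (colnames = SNP ids), entries in `{0, 1, 2, NA}`.
#' @param snp_map `data.frame` with columns `snp_id`, `chrom`, `pos`
#'   (1-based bp), one row per dosage column.
#' @param animals Optional `data.frame` of per-animal metadata with an
#'   `animal_id` column (e.g. breed group, ancestry fraction, year of birth).
#' @return An object of class `genotype_data`.
#' @export
genotype_data <- function(dosage, snp_map, animals = NULL) {
  dosage <- as.matrix(dosage)
  if (ncol(dosage) > 0 &&
      (is.null(rownames(dosage)) || is.null(colnames(dosage))))
    stop("dosage must have animal rownames and SNP colnames")
  cn <- if (is.null(colnames(dosage))) character(0) else colnames(dosage)
  if (!identical(cn, as.character(snp_map$snp_id)))
    stop("snp_map rows must match dosage columns (same ids, same order)")
  if (anyDuplicated(snp_map$snp_id)) stop("snp_ids must be unique")
  if (anyDuplicated(rownames(dosage))) stop("animal ids must be unique")
  bad <- !(dosage %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("dosage entries must be 0, 1, 2 or NA")
  snp_map$chrom <- as.character(snp_map$chrom)
  snp_map$pos <- as.integer(snp_map$pos)
  # keep map (and matrix) sorted by chromosome then position
  o <- order(snp_map$chrom, snp_map$pos)
  if (!identical(o, seq_len(nrow(snp_map)))) {
    snp_map <- snp_map[o, , drop = FALSE]
    dosage <- dosage[, o, drop = FALSE]
  }
  rownames(snp_map) <- NULL
  structure(list(dosage = dosage, snp_map = snp_map, animals = animals),
            class = "genotype_data")
}

#' @export
print.genotype_data <- function(x, ...) {
  cat(sprintf("genotype_data: %d animals x %d SNPs on %d chromosome(s)\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$snp_map$chrom))))
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' Feature count container
#'
#' A features x animals matrix of nonnegative integer counts at gene or
#' exon level, plus the map tying each feature to its gene and genomic span.
#' Exon features carry their parent gene's coordinates for cis/trans work.
#'
#' @param counts Integer matrix, features in rows (rownames = feature ids),
#'   animals in columns.
#' @param feature_map `data.frame` with columns `feature_id`, `gene_id`,
#'   `chrom`, `start`, `end` (1-based inclusive), one row per count row.
#' @param level `"gene"` or `"exon"`.
#' @return An object of class `feature_counts`.
#' @export
feature_counts <- function(counts, feature_map, level = c("gene", "exon")) {
  level <- match.arg(level)
  counts <- as.matrix(counts)
  if (nrow(counts) > 0 &&
      (is.null(rownames(counts)) || is.null(colnames(counts))))
    stop("counts must have feature rownames and animal colnames")
  rn <- if (is.null(rownames(counts))) character(0) else rownames(counts)
  if (!identical(rn, as.character(feature_map$feature_id)))
    stop("feature_map rows must match count rows (same ids, same order)")
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be nonnegative")
  rownames(feature_map) <- NULL
  structure(list(counts = counts, feature_map = feature_map, level = level),
            class = "feature_counts")
}

#' @export
print.feature_counts <- function(x, ...) {
  cat(sprintf("feature_counts (%s level): %d features x %d animals\n",
              x$level, nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' @export
print.transformed_expression <- function(x, ...) {
  cat(sprintf("transformed_expression: %d features x %d animals (%s)\n",
              nrow(x$values), ncol(x$values), x$method))
  if (!is.null(x$dispersion))
    cat(sprintf("  dispersion alpha-hat = %.4g\n", x$dispersion))
  invisible(x)
}
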