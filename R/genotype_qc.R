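#' Minor allele frequency of one SNP
#'
#' `min(f, 1 - f)` where `f` is the alternate-allele frequency
#' `sum(dosage) / (2 * non-missing animals)`; missing calls are excluded
#' from both numerator and denominator.
#'
#' @param dosage_column Numeric vector of dosages in `{0, 1, 2, NA}`.
#' @return MAF in `[0, 0.5]`.
#' @export
compute_maf <- function(dosage_column) {
  ok <- !is.na(dosage_column)
  if (!any(ok)) stop("MAF undefined: all calls missing")
  f <- sum(dosage_column[ok]) / (2 * sum(ok))
  min(f, 1 - f)
}

# vectorized over the columns of a genotype_data dosage matrix
snp_mafs <- function(genotypes) {
  d <- genotypes$dosage
  nobs <- colSums(!is.na(d))
  if (any(nobs == 0)) stop("MAF undefined: all calls missing for some SNP")
  f <- colSums(d, na.rm = TRUE) / (2 * nobs)
  pmin(f, 1 - f)
}

#' Filter SNPs on minor allele frequency and call rate
#'
#' Retains SNPs with MAF >= `maf_min` and call rate >= `call_rate_min`
#' (both boundaries inclusive: the exclusion rules are "lower than" /
#' "< "). Optionally a genotype-count rule can replace the allele-frequency
#' rule: keep SNPs whose rarest observed genotype class is carried by at
#' least `min_genotype_count` animals (monomorphic SNPs fail it).
#'
#' @param genotypes A [genotype_data()].
#' @param maf_min Minimum minor allele frequency (default 0.03).
#' @param call_rate_min Minimum fraction of non-missing calls (default 0.9).
#' @param genotype_count_rule If `TRUE`, use the genotype-count criterion
#'   instead of the allele-frequency one.
#' @param min_genotype_count Animals required in the least frequent
#'   observed genotype class (default 2).
#' @return List with the filtered `genotypes` and a `report` data.frame
#'   (snp_id, maf, call_rate, removed, reason).
#' @export
filter_snps <- function(genotypes, maf_min = 0.03, call_rate_min = 0.9,
                        genotype_count_rule = FALSE, min_genotype_count = 2) {
  stopifnot(maf_min >= 0, maf_min <= 1, call_rate_min >= 0, call_rate_min <= 1)
  d <- genotypes$dosage
  maf <- snp_mafs(genotypes)
  call_rate <- colMeans(!is.na(d))
  if (genotype_count_rule) {
    rare <- apply(d, 2, function(x) {
      tab <- table(factor(x[!is.na(x)], levels = 0:2))
      tab <- tab[tab > 0]
      if (length(tab) < 2) 0L else min(tab)
    })
    maf_fail <- rare < min_genotype_count
  } else {
    maf_fail <- maf < maf_min
  }
  cr_fail <- call_rate < call_rate_min
  reason <- character(ncol(d))
  reason[maf_fail] <- "MAF"
  reason[cr_fail] <- "call_rate"
  reason[maf_fail & cr_fail] <- "MAF;call_rate"
  removed <- maf_fail | cr_fail
  report <- data.frame(snp_id = genotypes$snp_map$snp_id, maf = unname(maf),
                       call_rate = unname(call_rate), removed = removed,
                       reason = reason)
  keep <- which(!removed)
  if (!length(keep)) warning("no SNPs pass the filters")
  out <- genotype_data(d[, keep, drop = FALSE],
                       genotypes$snp_map[keep, , drop = FALSE],
                       animals = genotypes$animals)
  list(genotypes = out, report = report)
}

#' Genotype PCA for population structure
#'
#' PCA of the column-standardized dosage matrix; missing dosages are
#' mean-imputed (imputation is used for the PCA only). The sign of each
#' component is fixed so its largest-magnitude SNP loading is positive,
#' making PC1 reproducible as a structure covariate.
#'
#' @param genotypes A post-QC [genotype_data()].
#' @param n_components Number of PCs to return (default 10, capped by the
#'   data rank).
#' @return List of class `genotype_pca`: `scores` (animals x PCs), `pc1`,
#'   `explained_variance_fraction` (per returned PC), `sdev`.
#' @export
genotype_pca <- function(genotypes, n_components = 10) {
  d <- genotypes$dosage
  if (nrow(d) < 2) stop("genotype PCA needs at least 2 animals")
  d <- apply(d, 2, function(x) {
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    x
  })
  sds <- apply(d, 2, sd)
  if (all(sds == 0)) stop("degenerate PCA: all SNPs have zero variance")
  d <- d[, sds > 0, drop = FALSE]
  z <- scale(d)
  pc <- prcomp(z, center = FALSE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {                 # sign convention
    if (rot[which.max(abs(rot[, j])), j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ev <- pc$sdev^2
  structure(list(scores = scores, pc1 = setNames(scores[, 1], rownames(d)),
                 explained_variance_fraction = ev[seq_len(k)] / sum(ev),
                 sdev = pc$sdev[seq_len(k)], loadings = rot),
            class = "genotype_pca")
}
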