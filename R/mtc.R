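#' simpleM effective number of independent tests
#'
#' Eigendecomposes the SNP x SNP Pearson correlation matrix of a dosage
#' block (missing dosages mean-imputed) and returns the smallest k such
#' that the top-k eigenvalues capture at least `variance_fraction` of the
#' total variance. Zero-variance SNPs are excluded with a warning.
#'
#' @param dosage_block Animals x SNPs numeric matrix (one block).
#' @param variance_fraction Fraction of variance the retained eigenvalues
#'   must reach (default 0.995, the simpleM constant).
#' @return Integer `m_eff`, `1 <= m_eff <=` number of usable SNPs.
#' @export
simple_m <- function(dosage_block, variance_fraction = 0.995) {
  m <- as.matrix(dosage_block)
  if (ncol(m) < 1) stop("empty dosage block")
  m <- apply(m, 2, function(x) {
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    x
  })
  m <- matrix(m, nrow = nrow(dosage_block))
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance SNP(s) excluded from simpleM block")
    m <- m[, sds > 0, drop = FALSE]
  }
  k <- ncol(m)
  if (k == 0) stop("no variable SNPs left in simpleM block")
  if (k == 1) return(1L)
  ev <- eigen(cor(m), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  frac <- cumsum(ev) / sum(ev)
  as.integer(which(frac >= variance_fraction - 1e-12)[1])
}

#' Genome-wide effective number of tests
#'
#' Processes the SNPs in consecutive map-ordered blocks (restarting at each
#' chromosome) and sums the per-block [simple_m()] values -- the standard
#' windowed simpleM practice, since a single eigendecomposition of a full
#' panel is infeasible.
#'
#' @param genotypes A post-QC [genotype_data()].
#' @param block_size SNPs per block (default 133, the simpleM window).
#' @param variance_fraction Passed to [simple_m()].
#' @return Integer `m_eff` with attribute `n_tests` (the SNP count).
#' @export
genomewide_meff <- function(genotypes, block_size = 133,
                            variance_fraction = 0.995) {
  blk <- block_ids(genotypes$snp_map$chrom, block_size)
  meff <- sum(vapply(unique(blk), function(b) {
    simple_m(genotypes$dosage[, blk == b, drop = FALSE], variance_fraction)
  }, integer(1)))
  structure(as.integer(meff), n_tests = ncol(genotypes$dosage))
}

#' Bonferroni threshold from an effective test count
#'
#' @param m_eff Effective number of independent tests (>= 1).
#' @param alpha Family-wise level (default 0.05).
#' @return `alpha / m_eff`.
#' @export
bonferroni_threshold <- function(m_eff, alpha = 0.05) {
  if (m_eff < 1) stop("m_eff must be >= 1")
  alpha / m_eff
}

#' Per-gene cis significance thresholds
#'
#' For each gene, collects the SNPs in its cis window (same rule as
#' [classify_location()]), computes the simpleM effective number of tests
#' on that block, and emits the Bonferroni threshold `alpha / m_eff`.
#' Genes with no cis SNP are omitted from the table (and listed in the
#' `no_cis_snps` attribute).
#'
#' @param genotypes A post-QC [genotype_data()].
#' @param gene_models `data.frame` with `gene_id`, `chrom`, `start`, `end`.
#' @param window Cis window in bp (default 1e6); windows are clipped at
#'   position 1.
#' @param alpha Family-wise level per gene (default 0.05).
#' @param variance_fraction Passed to [simple_m()].
#' @return `data.frame` with `gene_id`, `n_tests`, `m_eff`, `alpha`,
#'   `threshold`; attribute `no_cis_snps` lists genes without cis SNPs.
#' @export
per_gene_cis_thresholds <- function(genotypes, gene_models, window = 1e6,
                                    alpha = 0.05, variance_fraction = 0.995) {
  map <- genotypes$snp_map
  rows <- lapply(seq_len(nrow(gene_models)), function(i) {
    lo <- max(1, gene_models$start[i] - window)
    hi <- gene_models$end[i] + window
    idx <- which(map$chrom == gene_models$chrom[i] &
                   map$pos >= lo & map$pos <= hi)
    if (!length(idx)) return(NULL)
    meff <- tryCatch(
      suppressWarnings(
        simple_m(genotypes$dosage[, idx, drop = FALSE], variance_fraction)),
      error = function(e) NA_integer_)
    if (is.na(meff)) return(NULL)
    data.frame(gene_id = gene_models$gene_id[i], n_tests = length(idx),
               m_eff = meff, alpha = alpha,
               threshold = bonferroni_threshold(meff, alpha))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(0), n_tests = integer(0),
                      m_eff = integer(0), alpha = numeric(0),
                      threshold = numeric(0))
  missing_genes <- setdiff(gene_models$gene_id, out$gene_id)
  if (length(missing_genes))
    message(length(missing_genes), " gene(s) without cis SNPs: no cis threshold")
  attr(out, "no_cis_snps") <- missing_genes
  out
}
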