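# Design matrix for the scan covariates: intercept, treatment-coded year,
# structure PC1. A single-level year factor is dropped rather than erroring.
make_design <- function(n, year = NULL, pc1 = NULL) {
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(year)) {
    year <- droplevels(factor(year))
    if (nlevels(year) >= 2)
      X <- cbind(X, model.matrix(~year)[, -1, drop = FALSE])
  }
  if (!is.null(pc1)) X <- cbind(X, pc1 = as.numeric(pc1))
  X
}

#' Single SNP-feature association fit
#'
#' OLS of `feature ~ dosage + year + PC1` on the animals with a non-missing
#' dosage; the reported effect, t statistic and two-sided p-value are for
#' the dosage coefficient with residual degrees of freedom.
#'
#' @param feature_values Numeric feature values per animal (VST scale).
#' @param dosage Dosage vector in `{0, 1, 2, NA}`.
#' @param year,pc1 Optional covariates (see [make_design]).
#' @return Named vector `c(beta, t, p, n)`; `NA`s when the SNP is
#'   monomorphic among the non-missing animals or df <= 0.
#' @export
fit_association <- function(feature_values, dosage, year = NULL, pc1 = NULL) {
  ok <- !is.na(dosage) & !is.na(feature_values)
  x <- as.numeric(dosage[ok])
  y <- as.numeric(feature_values[ok])
  if (length(unique(x)) < 2)
    return(c(beta = NA_real_, t = NA_real_, p = NA_real_, n = sum(ok)))
  C <- make_design(sum(ok),
                   year = if (!is.null(year)) year[ok],
                   pc1 = if (!is.null(pc1)) pc1[ok])
  qrC <- qr(C)
  Q <- qr.Q(qrC)[, seq_len(qrC$rank), drop = FALSE]
  df <- sum(ok) - qrC$rank - 1L
  if (df <= 0) return(c(beta = NA_real_, t = NA_real_, p = NA_real_, n = sum(ok)))
  xr <- x - Q %*% crossprod(Q, x)
  yr <- y - Q %*% crossprod(Q, y)
  xx <- sum(xr^2)
  if (xx < 1e-10)
    return(c(beta = NA_real_, t = NA_real_, p = NA_real_, n = sum(ok)))
  beta <- sum(xr * yr) / xx
  sse <- max(sum(yr^2) - beta^2 * xx, 0)
  tval <- beta / sqrt(sse / df / xx)
  c(beta = beta, t = tval, p = 2 * pt(-abs(tval), df), n = sum(ok))
}

#' All-pairs association scan
#'
#' Fits every SNP x feature pair by covariate-residualized OLS (project
#' year + PC1 out of the features and the dosages once, then simple
#' regression on the residuals -- numerically identical to the full OLS).
#' SNPs with missing calls are handled per SNP on their pairwise-complete
#' animals; SNPs monomorphic among the used animals are skipped.
#'
#' @param genotypes A [genotype_data()] (animals must match the value
#'   columns by id).
#' @param values A `transformed_expression` or features x animals matrix.
#' @param year,pc1 Optional covariates per animal.
#' @return List of class `association_scan`: matrices `beta`, `tstat`,
#'   `pval` (features x SNPs), `df` per SNP, and `skipped` SNP ids.
#' @export
association_scan <- function(genotypes, values, year = NULL, pc1 = NULL) {
  v <- if (inherits(values, "transformed_expression")) values$values
  else as.matrix(values)
  X <- genotypes$dosage
  if (!setequal(rownames(X), colnames(v)))
    stop("animal ids of genotypes and values do not match")
  X <- X[colnames(v), , drop = FALSE]
  n <- nrow(X)
  C <- make_design(n, year, pc1)
  p <- ncol(C)
  Q <- qr.Q(qr(C))
  Yr <- v - (v %*% Q) %*% t(Q)
  ssY <- rowSums(Yr^2)
  nmiss <- colSums(is.na(X))
  ndist <- apply(X, 2, function(x) length(unique(x[!is.na(x)])))
  S <- ncol(X)
  beta <- tstat <- pval <- matrix(
    NA_real_, nrow(v), S, dimnames = list(rownames(v), colnames(X)))
  dfs <- setNames(rep(NA_integer_, S), colnames(X))
  usable <- ndist >= 2
  idx <- which(nmiss == 0 & usable)
  if (length(idx)) {
    Xc <- X[, idx, drop = FALSE] * 1.0
    Xr <- Xc - Q %*% crossprod(Q, Xc)
    xx <- colSums(Xr^2)
    good <- xx > 1e-10
    idx <- idx[good]; Xr <- Xr[, good, drop = FALSE]; xx <- xx[good]
    if (length(idx)) {
      df <- n - p - 1L
      num <- Yr %*% Xr
      b <- sweep(num, 2, xx, "/")
      sse <- pmax(ssY - sweep(b^2, 2, xx, "*"), 0)
      tv <- b / sqrt(sweep(sse / df, 2, xx, "/"))
      beta[, idx] <- b
      tstat[, idx] <- tv
      pval[, idx] <- 2 * pt(-abs(tv), df)
      dfs[idx] <- df
    }
  }
  for (j in which(nmiss > 0 & usable)) {
    obs <- !is.na(X[, j])
    Cs <- C[obs, , drop = FALSE]
    qrs <- qr(Cs)
    Qs <- qr.Q(qrs)[, seq_len(qrs$rank), drop = FALSE]
    df <- sum(obs) - qrs$rank - 1L
    if (df <= 0) next
    x <- as.numeric(X[obs, j])
    if (length(unique(x)) < 2) next
    xr <- x - Qs %*% crossprod(Qs, x)
    xx <- sum(xr^2)
    if (xx < 1e-10) next
    Ys <- v[, obs, drop = FALSE]
    Yrs <- Ys - (Ys %*% Qs) %*% t(Qs)
    b <- as.numeric(Yrs %*% xr) / xx
    sse <- pmax(rowSums(Yrs^2) - b^2 * xx, 0)
    tv <- b / sqrt(sse / df / xx)
    beta[, j] <- b
    tstat[, j] <- tv
    pval[, j] <- 2 * pt(-abs(tv), df)
    dfs[j] <- df
  }
  skipped <- colnames(X)[!usable]
  if (length(skipped))
    message(length(skipped), " SNP(s) monomorphic in sample; skipped")
  structure(list(beta = beta, tstat = tstat, pval = pval, df = dfs,
                 skipped = skipped),
            class = "association_scan")
}

#' Classify a SNP as cis or trans for a gene
#'
#' Cis means same chromosome and SNP position within 1 Mb of the gene span,
#' i.e. in `[start - window, end + window]` inclusive on both boundaries
#' ("no more than 1 Mb"). Vectorized over SNPs.
#'
#' @param snp_chrom,snp_pos SNP coordinates.
#' @param gene_chrom,gene_start,gene_end Gene span (1-based inclusive).
#' @param window Cis window in bp (default 1e6).
#' @return Character vector `"cis"` / `"trans"`.
#' @export
classify_location <- function(snp_chrom, snp_pos, gene_chrom, gene_start,
                              gene_end, window = 1e6) {
  ifelse(snp_chrom == gene_chrom &
           snp_pos >= gene_start - window & snp_pos <= gene_end + window,
         "cis", "trans")
}

#' Threshold a scan into classified QTL records
#'
#' Runs (or reuses) the all-pairs scan, classifies each pair as cis or
#' trans by the 1 Mb window around the feature's parent gene span, and
#' retains pairs with `p <= threshold`, where the trans threshold is a
#' global cutoff and the cis threshold is either a global cutoff or a
#' per-gene value (e.g. simpleM Bonferroni thresholds from
#' [per_gene_cis_thresholds()]). Each retained record also carries a
#' DEG / non-DEG label from membership of its gene in `deg_genes`, giving
#' the four classes cis, trans, DEG cis and DEG trans.
#'
#' @inheritParams association_scan
#' @param gene_models `data.frame` with `gene_id`, `chrom`, `start`, `end`.
#' @param deg_genes Character vector of DEG gene ids.
#' @param trans_threshold Global trans p-value cutoff.
#' @param cis_thresholds Single numeric cutoff, or a `data.frame` from
#'   [per_gene_cis_thresholds()] (columns `gene_id`, `threshold`). A gene
#'   with cis SNPs but no threshold entry is an error.
#' @param cis_window Cis window in bp (default 1e6).
#' @param scan Optional precomputed [association_scan()] result.
#' @return `data.frame` of class `qtl_records`: one row per retained
#'   association with SNP/feature coordinates, `beta`, `t`, `p`,
#'   `location_class`, `deg_class` and combined `class`; attributes
#'   `n_tests` and `thresholds`.
#' @export
qtl_scan <- function(genotypes, values, gene_models, deg_genes = character(0),
                     trans_threshold = 1e-5, cis_thresholds = 2e-4,
                     year = NULL, pc1 = NULL, cis_window = 1e6, scan = NULL) {
  if (is.null(scan)) scan <- association_scan(genotypes, values, year, pc1)
  fmap <- if (inherits(values, "transformed_expression")) values$feature_map
  else NULL
  if (is.null(fmap))
    fmap <- data.frame(feature_id = rownames(scan$pval),
                       gene_id = rownames(scan$pval))
  gm <- gene_models[match(fmap$gene_id, gene_models$gene_id), , drop = FALSE]
  if (anyNA(gm$gene_id))
    stop("unknown gene for feature(s): ",
         paste(utils::head(fmap$feature_id[is.na(gm$gene_id)]), collapse = ", "))
  per_gene <- is.data.frame(cis_thresholds)
  cis_thr_of <- if (per_gene)
    setNames(cis_thresholds$threshold, cis_thresholds$gene_id)
  else NULL
  map <- genotypes$snp_map
  map <- map[match(colnames(scan$pval), map$snp_id), ]
  recs <- vector("list", nrow(fmap))
  for (i in seq_len(nrow(fmap))) {
    pv <- scan$pval[i, ]
    loc <- classify_location(map$chrom, map$pos, gm$chrom[i], gm$start[i],
                             gm$end[i], window = cis_window)
    thr_cis <- if (per_gene) cis_thr_of[gm$gene_id[i]] else cis_thresholds
    if (any(loc == "cis" & !is.na(pv)) && (is.null(thr_cis) || is.na(thr_cis)))
      stop("missing cis threshold for gene ", gm$gene_id[i])
    thr <- ifelse(loc == "cis", thr_cis, trans_threshold)
    keep <- which(!is.na(pv) & pv <= thr)
    if (!length(keep)) next
    recs[[i]] <- data.frame(
      snp_id = map$snp_id[keep], snp_chrom = map$chrom[keep],
      snp_pos = map$pos[keep], feature_id = fmap$feature_id[i],
      gene_id = gm$gene_id[i], beta = scan$beta[i, keep],
      t = scan$tstat[i, keep], p = pv[keep], location_class = loc[keep])
  }
  out <- do.call(rbind, recs)
  if (is.null(out))
    out <- data.frame(snp_id = character(0), snp_chrom = character(0),
                      snp_pos = integer(0), feature_id = character(0),
                      gene_id = character(0), beta = numeric(0), t = numeric(0),
                      p = numeric(0), location_class = character(0))
  out$deg_class <- ifelse(out$gene_id %in% deg_genes, "DEG", "non-DEG")
  out$class <- ifelse(out$deg_class == "DEG",
                      paste("DEG", out$location_class), out$location_class)
  rownames(out) <- NULL
  attr(out, "n_tests") <- sum(!is.na(scan$pval))
  attr(out, "thresholds") <- list(trans = trans_threshold, cis = cis_thresholds)
  class(out) <- c("qtl_records", "data.frame")
  out
}
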