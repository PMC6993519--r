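#' Drop features with too few counts overall
#'
#' Keeps features whose total count across all animals is at least
#' `min_total` (the exclusion rule is strict "less than", so a row total
#' exactly at `min_total` is retained).
#'
#' @param counts A [feature_counts()].
#' @param min_total Minimum row total (default 10).
#' @return Filtered [feature_counts()].
#' @export
filter_low_counts <- function(counts, min_total = 10) {
  stopifnot(inherits(counts, "feature_counts"))
  keep <- rowSums(counts$counts) >= min_total
  if (!any(keep)) warning("no features pass the low-count filter")
  feature_counts(counts$counts[keep, , drop = FALSE],
                 counts$feature_map[keep, , drop = FALSE],
                 level = counts$level)
}

#' TMM scaling factors
#'
#' Per-animal scaling factors from the trimmed mean of M-values against a
#' reference animal. M is the log2 ratio of raw counts between an animal
#' and the reference over features expressed in both, doubly trimmed (30%
#' of M, 5% of A by default) and weighted by the inverse asymptotic
#' (delta-method binomial) variance. Factors are rescaled to geometric
#' mean 1 and carry size-factor semantics: they include sequencing depth,
#' so `counts / factor` is the normalized expression.
#'
#' @param counts A [feature_counts()] or a features x animals matrix.
#' @param logratio_trim Fraction of M values trimmed from each tail (0.3).
#' @param sum_trim Fraction of A values trimmed from each tail (0.05).
#' @param reference Column index/name of the reference animal, or `NULL` to
#'   pick the animal whose upper-quartile relative expression is closest to
#'   the mean (the usual TMM reference rule).
#' @return Named numeric vector of factors (geometric mean 1), with
#'   attribute `reference`.
#' @export
tmm_factors <- function(counts, logratio_trim = 0.3, sum_trim = 0.05,
                        reference = NULL) {
  m <- if (inherits(counts, "feature_counts")) counts$counts else as.matrix(counts)
  if (ncol(m) < 2) stop("TMM needs at least 2 animals")
  lib <- colSums(m)
  if (any(lib == 0)) stop("TMM undefined for an all-zero library")
  if (is.null(reference)) {
    uq <- apply(sweep(m, 2, lib, "/"), 2, quantile, probs = 0.75)
    reference <- which.min(abs(uq - mean(uq)))
  } else if (is.character(reference)) {
    reference <- match(reference, colnames(m))
  }
  yr <- m[, reference]
  f <- vapply(seq_len(ncol(m)), function(j) {
    ys <- m[, j]
    ok <- ys > 0 & yr > 0
    if (!any(ok)) stop("animal ", j, " shares no expressed feature with the reference")
    ys <- ys[ok]; yo <- yr[ok]
    M <- log2(ys / yo)
    A <- 0.5 * log2(ys * yo)
    w <- 1 / ((lib[j] - ys) / (lib[j] * ys) + (lib[reference] - yo) / (lib[reference] * yo))
    n <- length(M)
    loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
    loA <- floor(n * sum_trim) + 1;      hiA <- n + 1 - loA
    rM <- rank(M); rA <- rank(A)
    keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (!any(keep)) keep <- rep(TRUE, n)          # fully tied M/A: no trimming
    w <- w[keep]
    wk <- if (all(is.finite(w)) && sum(w) > 0) w else rep(1, sum(keep))
    2^(sum(wk * M[keep]) / sum(wk))
  }, numeric(1))
  f <- f / geomean(f)
  structure(setNames(f, colnames(m)), reference = colnames(m)[reference])
}

# closed-form variance stabilizer for NB counts with common dispersion alpha
vst_asinh <- function(q, alpha) (2 / sqrt(alpha)) * asinh(sqrt(alpha * q))

#' Variance stabilizing transformation
#'
#' Normalizes counts by size factors (`q = count / size_factor`), estimates
#' a single dataset-level negative-binomial dispersion `alpha` (median of
#' per-feature method-of-moments estimates `max(0, (s^2 - qbar) / qbar^2)`),
#' and applies the exact variance stabilizer for an NB with common
#' dispersion, `t(q) = (2 / sqrt(alpha)) * asinh(sqrt(alpha * q))`, affinely
#' rescaled so `t(q) -> log2(q)` for large `q`. When the dispersion
#' estimate is zero the transform falls back to `log2(q + 1)` with a
#' notice.
#'
#' @param counts A [feature_counts()] or features x animals matrix.
#' @param size_factors Positive per-animal size factors; `NULL` estimates
#'   median-of-ratios factors against the geometric-mean pseudo-reference
#'   over features with all-nonzero counts.
#' @param dispersion Optional fixed dispersion alpha, bypassing estimation.
#' @return List of class `transformed_expression`: `values` (same shape as
#'   the counts), `size_factors`, `dispersion`, `method`, and the
#'   `feature_map`/`level` when a [feature_counts()] was supplied.
#' @export
vst_transform <- function(counts, size_factors = NULL, dispersion = NULL) {
  fc <- if (inherits(counts, "feature_counts")) counts else NULL
  m <- if (is.null(fc)) as.matrix(counts) else fc$counts
  if (is.null(size_factors)) size_factors <- median_of_ratios(m)
  if (any(size_factors <= 0)) stop("size factors must be > 0")
  q <- sweep(m, 2, size_factors, "/")
  if (is.null(dispersion)) {
    qbar <- rowMeans(q)
    s2 <- apply(q, 1, var)
    ok <- qbar > 0
    alphas <- pmax(0, (s2[ok] - qbar[ok]) / qbar[ok]^2)
    dispersion <- if (any(ok)) median(alphas) else 0
  }
  if (dispersion <= 0) {
    message("dispersion estimate is zero; falling back to log2(q + 1)")
    values <- log2(q + 1)
    method <- "log2"
    dispersion <- 0
  } else {
    values <- vst_asinh(q, dispersion) * sqrt(dispersion) / log(2) -
      log2(4 * dispersion)
    method <- "asinh-vst"
  }
  out <- list(values = values, size_factors = size_factors,
              dispersion = dispersion, method = method,
              feature_map = fc$feature_map, level = fc$level)
  class(out) <- "transformed_expression"
  out
}

# median-of-ratios size factors (geometric-mean pseudo-reference over
# features observed in every animal), rescaled to geometric mean 1
median_of_ratios <- function(m) {
  all_pos <- rowSums(m == 0) == 0
  if (!any(all_pos)) {
    message("no feature is nonzero in every animal; size factors from library totals")
    sf <- colSums(m)
    return(sf / geomean(sf))
  }
  sub <- m[all_pos, , drop = FALSE]
  ref <- exp(rowMeans(log(sub)))
  sf <- apply(sub / ref, 2, median)
  sf / geomean(sf)
}

#' Exon usage fractions as integer counts
#'
#' For each exon, the fraction of its gene's counts allocated to the exon,
#' kept to three decimal digits and scaled by 1000 (so 0.370 becomes 370).
#' A zero gene count yields fraction 0; an exon exceeding its gene count is
#' clamped to 1000 with a warning. Rounding is half-up by default;
#' truncation is available since the convention is a choice.
#'
#' @param exon_counts Exon-level [feature_counts()].
#' @param gene_counts Gene-level [feature_counts()] holding every parent
#'   gene.
#' @param rounding `"round"` (half-up) or `"truncate"`.
#' @return Exon-level [feature_counts()] of integerized fractions in
#'   `[0, 1000]`, suitable as input to [vst_transform()].
#' @export
exon_fraction_counts <- function(exon_counts, gene_counts,
                                 rounding = c("round", "truncate")) {
  rounding <- match.arg(rounding)
  stopifnot(inherits(exon_counts, "feature_counts"),
            inherits(gene_counts, "feature_counts"))
  parents <- exon_counts$feature_map$gene_id
  if (!all(parents %in% rownames(gene_counts$counts)))
    stop("parent gene(s) missing from gene_counts: ",
         paste(utils::head(setdiff(parents, rownames(gene_counts$counts))),
               collapse = ", "))
  g <- gene_counts$counts[parents, colnames(exon_counts$counts), drop = FALSE]
  frac <- ifelse(g > 0, exon_counts$counts / g, 0)
  if (any(frac > 1)) {
    warning("exon count exceeds gene count for ",
            sum(rowSums(frac > 1) > 0), " exon(s); fractions clamped to 1")
    frac <- pmin(frac, 1)
  }
  scaled <- frac * 1000
  vals <- if (rounding == "round") floor(scaled + 0.5) else floor(scaled + 1e-9)
  storage.mode(vals) <- "integer"
  dimnames(vals) <- dimnames(exon_counts$counts)
  feature_counts(vals, exon_counts$feature_map, level = "exon")
}
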