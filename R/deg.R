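#' Huber M-estimator robust regression
#'
#' Iteratively reweighted least squares with Huber's psi and a concurrent
#' MAD-based robust scale, iterated until the coefficient change falls
#' below `tol`. Standard errors come from the usual M-estimator sandwich
#' (with the small-sample correction factor of Huber's Proposal 2
#' covariance), and p-values from a t reference distribution with `n - p`
#' degrees of freedom.
#'
#' @param response Numeric response vector.
#' @param covariates Numeric matrix (or vector) of covariates; an intercept
#'   column is added unless `intercept = FALSE`.
#' @param tuning Huber tuning constant `k` in residual-scale units
#'   (default 1.345, 95% Gaussian efficiency). `Inf` reproduces OLS.
#' @param max_iter,tol IRLS iteration cap and convergence tolerance on the
#'   relative coefficient change.
#' @param intercept Add an intercept column (default `TRUE`).
#' @return List of class `huber_fit`: `coefficients`, `se`, `t`, `p.value`,
#'   `scale`, `iterations`, `converged`, `residuals`.
#' @export
huber_fit <- function(response, covariates, tuning = 1.345, max_iter = 50,
                      tol = 1e-8, intercept = TRUE) {
  y <- as.numeric(response)
  X <- as.matrix(covariates)
  if (is.null(colnames(X)))
    colnames(X) <- if (ncol(X) == 1) "x" else paste0("x", seq_len(ncol(X)))
  if (intercept) X <- cbind("(Intercept)" = 1, X)
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("need more observations than parameters")
  if (qr(X)$rank < p) stop("design matrix is rank deficient")
  fit <- stats::lm.fit(X, y)
  b <- fit$coefficients
  converged <- FALSE
  it <- 0L
  s <- 0
  repeat {
    r <- y - as.numeric(X %*% b)
    s <- mad(r, center = 0)
    if (s < 1e-10 * max(1, mad(y, center = median(y)), abs(median(y)))) {
      # (near-)exact fit: scale collapses, coefficients are final
      s <- 0
      converged <- TRUE
      break
    }
    u <- r / s
    w <- pmin(1, tuning / abs(u))
    w[!is.finite(w)] <- 1        # tuning = Inf or zero residual
    bn <- stats::lm.wfit(X, y, w)$coefficients
    it <- it + 1L
    if (max(abs(bn - b)) < tol * max(1, max(abs(bn)))) {
      b <- bn
      converged <- TRUE
      break
    }
    b <- bn
    if (it >= max_iter) break
  }
  r <- y - as.numeric(X %*% b)
  if (s == 0) {
    se <- rep(0, p)
    tval <- ifelse(b == 0, 0, sign(b) * Inf)
    pval <- as.numeric(b == 0)
  } else {
    u <- r / s
    psi <- pmax(-tuning, pmin(tuning, u))
    dpsi <- as.numeric(abs(u) <= tuning)
    m1 <- mean(dpsi)
    kappa <- 1 + p * var(dpsi) / (n * m1^2)
    v_scalar <- kappa^2 * s^2 * sum(psi^2) / (n - p) / m1^2
    XtX_inv <- chol2inv(chol(crossprod(X)))
    se <- sqrt(v_scalar * diag(XtX_inv))
    tval <- b / se
    pval <- 2 * pt(-abs(tval), df = n - p)
  }
  structure(list(coefficients = setNames(b, colnames(X)),
                 se = setNames(se, colnames(X)),
                 t = setNames(tval, colnames(X)),
                 p.value = setNames(pval, colnames(X)),
                 scale = s, iterations = it, converged = converged,
                 residuals = r),
            class = "huber_fit")
}

#' @export
print.huber_fit <- function(x, ...) {
  tab <- data.frame(estimate = x$coefficients, se = x$se, t = x$t,
                    p = x$p.value)
  print(tab, ...)
  cat(sprintf("robust scale %.4g; %d IRLS iteration(s)%s\n", x$scale,
              x$iterations, if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Scan features for association with the meat-quality index
#'
#' For every feature, fits `index ~ expression + year + PC1` by Huber
#' robust regression and tests the expression coefficient. This is the
#' differential-expression branch: a gene is "DEG" when its gene-level
#' expression is associated at `p < alpha`, or when at least `min_exons`
#' of its exons are.
#'
#' @param expression A `transformed_expression` or features x animals
#'   matrix (column names = animal ids).
#' @param quality_index Named numeric index (or `quality_index` object);
#'   names must match the expression columns.
#' @param year Factor-like year of birth per animal (optional).
#' @param pc1 Numeric structure covariate per animal (optional).
#' @param alpha Significance level on the expression coefficient (0.05).
#' @param tuning Huber tuning constant passed to [huber_fit()].
#' @return `data.frame` with one row per feature: `feature_id`, `estimate`,
#'   `scale`, `t`, `p`, `significant`.
#' @export
deg_scan <- function(expression, quality_index, year = NULL, pc1 = NULL,
                     alpha = 0.05, tuning = 1.345) {
  vals <- if (inherits(expression, "transformed_expression"))
    expression$values else as.matrix(expression)
  if (inherits(quality_index, "quality_index"))
    quality_index <- quality_index$index
  ids <- colnames(vals)
  if (is.null(names(quality_index)) || !setequal(names(quality_index), ids))
    stop("animal ids of the index and the expression matrix do not match")
  y <- quality_index[ids]
  base <- make_design(length(ids), year = year, pc1 = pc1)[, -1, drop = FALSE]
  res <- lapply(rownames(vals), function(f) {
    X <- cbind(expr = vals[f, ], base)
    if (sd(vals[f, ]) == 0)
      return(data.frame(feature_id = f, estimate = NA_real_, scale = NA_real_,
                        t = NA_real_, p = NA_real_, significant = FALSE))
    fit <- huber_fit(y, X, tuning = tuning)
    data.frame(feature_id = f, estimate = fit$coefficients[["expr"]],
               scale = fit$scale, t = fit$t[["expr"]],
               p = fit$p.value[["expr"]],
               significant = is.finite(fit$p.value[["expr"]]) &&
                 fit$p.value[["expr"]] < alpha)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Call the DEG set from gene- and exon-level scans
#'
#' A gene is DEG iff its gene-level association has `p < alpha` or at
#' least `min_exons` of its exons are individually associated at
#' `p < alpha`. Externally derived DEG calls (e.g. from a categorical
#' contrast analysis run elsewhere) can be merged in.
#'
#' @param gene_result Gene-level result from [deg_scan()].
#' @param exon_result Optional exon-level result from [deg_scan()].
#' @param exon_gene_map `data.frame` mapping `feature_id` to `gene_id` for
#'   the exon features (required when `exon_result` is given).
#' @param min_exons Exons required for the exon-aggregated call (default 3).
#' @param extra_deg Character vector of externally supplied DEG gene ids to
#'   union in.
#' @return List of class `deg_result`: `deg_genes`, `gene_table` (with
#'   `n_significant_exons` and `is_deg`), `exon_table`.
#' @export
call_degs <- function(gene_result, exon_result = NULL, exon_gene_map = NULL,
                      min_exons = 3, extra_deg = character(0)) {
  gene_table <- gene_result
  n_sig <- setNames(integer(nrow(gene_table)), gene_table$feature_id)
  if (!is.null(exon_result)) {
    if (is.null(exon_gene_map))
      stop("exon_gene_map is required with exon_result")
    g <- exon_gene_map$gene_id[match(exon_result$feature_id,
                                     exon_gene_map$feature_id)]
    tab <- tapply(exon_result$significant, g, sum)
    n_sig[names(tab)] <- as.integer(tab)
  }
  cnt <- n_sig[gene_table$feature_id]
  cnt[is.na(cnt)] <- 0L
  gene_table$n_significant_exons <- as.integer(cnt)
  gene_table$is_deg <- (gene_table$significant %in% TRUE) |
    gene_table$n_significant_exons >= min_exons |
    gene_table$feature_id %in% extra_deg
  exon_only_deg <- names(n_sig)[n_sig >= min_exons]
  deg <- sort(unique(c(gene_table$feature_id[gene_table$is_deg],
                       exon_only_deg, extra_deg)))
  structure(list(deg_genes = deg, gene_table = gene_table,
                 exon_table = exon_result),
            class = "deg_result")
}
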