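toy_counts <- function(m, level = "gene") {
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("a%03d", seq_len(ncol(m)))
  feature_counts(m, data.frame(feature_id = rownames(m),
                               gene_id = rownames(m), chrom = "chr1",
                               start = seq_len(nrow(m)) * 1e5,
                               end = seq_len(nrow(m)) * 1e5 + 5e4),
                 level = level)
}

test_that("the low-count filter is strict at 'less than'", {
  m <- rbind(nine = rep(c(3L, 0L), c(3, 7)),     # total 9: removed
             ten = rep(c(5L, 0L), c(2, 8)),      # total 10: kept
             big = rep(100L, 10))
  colnames(m) <- sprintf("a%02d", 1:10)
  fc <- filter_low_counts(toy_counts(m), min_total = 10)
  expect_setequal(rownames(fc$counts), c("ten", "big"))
  zero <- toy_counts(matrix(0L, 3, 4))
  expect_warning(out <- filter_low_counts(zero), "no features")
  expect_identical(nrow(out$counts), 0L)
})

test_that("TMM factors are 1 for identical libraries and have geometric mean 1", {
  m <- matrix(rep(c(10L, 50L, 200L, 0L, 7L), 4), 5, 4)
  f <- tmm_factors(toy_counts(m))
  expect_equal(as.numeric(f), rep(1, 4))
  dat <- small_dataset()
  f2 <- tmm_factors(dat$gene_counts)
  expect_equal(exp(mean(log(f2))), 1, tolerance = 1e-12)
})

test_that("a pure depth difference yields sqrt(2) / 1/sqrt(2) factors", {
  a <- c(10L, 50L, 200L, 7L, 33L, 120L)
  m <- cbind(A = a, B = 2L * a)
  rownames(m) <- sprintf("g%03d", 1:6)
  f <- tmm_factors(toy_counts(m))
  # M is constant (-1 or +1) across features, so the trimmed weighted mean
  # is the pure depth ratio; geometric-mean rescaling gives sqrt(2)
  expect_equal(unname(f["B"] / f["A"]), 2)
  expect_equal(unname(f["B"]), sqrt(2))
  expect_equal(unname(f["A"]), 1 / sqrt(2))
})

test_that("TMM factors follow the animal, not the column order", {
  dat <- small_dataset()
  m <- dat$gene_counts$counts
  f1 <- tmm_factors(m)
  perm <- rev(seq_len(ncol(m)))
  f2 <- tmm_factors(m[, perm])
  expect_equal(f1[colnames(m)[perm]], f2, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("TMM agrees with the edgeR implementation", {
  dat <- small_dataset()
  m <- dat$gene_counts$counts
  f <- tmm_factors(m, reference = 1)
  nf <- edgeR::calcNormFactors(m, method = "TMM", refColumn = 1)
  ef <- nf * colSums(m)
  ef <- ef / exp(mean(log(ef)))          # edgeR factor x depth, geomean 1
  expect_equal(as.numeric(f), as.numeric(ef), tolerance = 1e-3)
})

test_that("the VST closed form matches its analytic values", {
  expect_equal(meatqtl:::vst_asinh(0, 1), 0)
  expect_equal(meatqtl:::vst_asinh(1, 1), 2 * log(1 + sqrt(2)))  # 1.7627...
  # large-count behavior: the rescaled transform tracks log2(q)
  v <- vst_transform(matrix(c(2^20, 2^21), 1, 2,
                            dimnames = list("g", c("a", "b"))),
                     size_factors = c(1, 1), dispersion = 0.1)
  expect_equal(unname(v$values[1, ]), c(20, 21), tolerance = 1e-3)
})

test_that("VST is invariant to count/size-factor doubling and monotone", {
  set.seed(5)
  m <- matrix(rnbinom(200, mu = 50, size = 5), 20, 10)
  dimnames(m) <- list(sprintf("g%02d", 1:20), sprintf("a%02d", 1:10))
  sf <- runif(10, 0.5, 2)
  v1 <- vst_transform(m, size_factors = sf)
  v2 <- vst_transform(2 * m, size_factors = 2 * sf,
                      dispersion = v1$dispersion)
  expect_equal(v1$values, v2$values)
  q <- sort(unique(as.numeric(m)))
  tq <- meatqtl:::vst_asinh(q, 0.2)
  expect_true(all(diff(tq) > 0))
})

test_that("VST flattens the NB mean-variance relationship", {
  set.seed(77)
  n <- 60
  mu <- exp(seq(log(5), log(5000), length.out = 200))
  m <- t(vapply(mu, function(x) rnbinom(n, mu = x, size = 1 / 0.08),
                numeric(n)))
  dimnames(m) <- list(sprintf("g%03d", seq_along(mu)), sprintf("a%02d", 1:n))
  slope_of <- function(vals) {
    mn <- rowMeans(vals); vr <- apply(vals, 1, var)
    unname(coef(lm(log(vr) ~ log(mn)))[2])
  }
  raw_slope <- {
    mn <- rowMeans(m); vr <- apply(m, 1, var)
    unname(coef(lm(log(vr) ~ log(mn)))[2])
  }
  v <- vst_transform(m, size_factors = rep(1, n))
  expect_gt(raw_slope, 0.8)                  # ~1-2 untransformed
  vals <- v$values
  mn_t <- rowMeans(vals)
  vr_t <- apply(vals, 1, var)
  vst_slope <- unname(coef(lm(log(vr_t) ~ log(rowMeans(m))))[2])
  expect_lt(abs(vst_slope), 0.2)
})

test_that("a zero dispersion estimate falls back to log2(q + 1)", {
  m <- matrix(rep(c(5L, 10L, 20L), 4), 3, 4)       # no overdispersion
  dimnames(m) <- list(c("g1", "g2", "g3"), sprintf("a%d", 1:4))
  expect_message(v <- vst_transform(m, size_factors = rep(1, 4)), "log2")
  expect_equal(v$values, log2(m + 1))
  expect_identical(v$method, "log2")
})

test_that("exon fractions integerize with half-up rounding", {
  ex <- matrix(c(37L, 1L, 0L), 3, 1,
               dimnames = list(c("gA:exon001", "gB:exon001", "gC:exon001"), "a1"))
  gn <- matrix(c(100L, 3L, 0L), 3, 1, dimnames = list(c("gA", "gB", "gC"), "a1"))
  exc <- feature_counts(ex, data.frame(
    feature_id = rownames(ex), gene_id = c("gA", "gB", "gC"), chrom = "chr1",
    start = 1, end = 10), level = "exon")
  gc_ <- toy_counts(gn)
  out <- exon_fraction_counts(exc, gc_)
  expect_identical(unname(out$counts[, 1]), c(370L, 333L, 0L))
  # truncation alternative: 2/3 -> 666 instead of 667
  ex2 <- matrix(2L, 1, 1, dimnames = list("gB:exon001", "a1"))
  exc2 <- feature_counts(ex2, data.frame(feature_id = "gB:exon001",
                                         gene_id = "gB", chrom = "chr1",
                                         start = 1, end = 10), level = "exon")
  expect_identical(unname(exon_fraction_counts(exc2, gc_)$counts[1, 1]), 667L)
  expect_identical(
    unname(exon_fraction_counts(exc2, gc_, rounding = "truncate")$counts[1, 1]),
    666L)
  # exon exceeding its gene clamps at 1000 with a warning
  ex3 <- matrix(5L, 1, 1, dimnames = list("gB:exon001", "a1"))
  exc3 <- feature_counts(ex3, data.frame(feature_id = "gB:exon001",
                                         gene_id = "gB", chrom = "chr1",
                                         start = 1, end = 10), level = "exon")
  expect_warning(out3 <- exon_fraction_counts(exc3, gc_), "clamped")
  expect_identical(unname(out3$counts[1, 1]), 1000L)
})

test_that("integer fractions sum to 1000 within rounding slack per gene", {
  dat <- small_dataset()
  frac <- exon_fraction_counts(dat$exon_counts, dat$gene_counts)
  sums <- rowsum(frac$counts, frac$feature_map$gene_id)
  n_ex <- table(frac$feature_map$gene_id)[rownames(sums)]
  gene_tot <- dat$gene_counts$counts[rownames(sums), ]
  nonzero <- gene_tot > 0
  dev <- abs(sums - 1000)
  slack <- matrix(as.numeric(n_ex), nrow(sums), ncol(sums))
  expect_true(all(dev[nonzero] <= slack[nonzero]))
  expect_true(all(sums[!nonzero] == 0))
})
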