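# a small random scan problem with covariates and some missing dosages
scan_problem <- function(seed = 1, n = 60, S = 25, G = 12, missing = TRUE) {
  set.seed(seed)
  d <- matrix(rbinom(n * S, 2, runif(S, 0.1, 0.5)), n, S, byrow = TRUE)
  if (missing) d[sample(length(d), round(0.03 * length(d)))] <- NA
  rownames(d) <- sprintf("a%03d", seq_len(n))
  g <- toy_genotypes(d)
  vals <- matrix(rnorm(G * n), G, n,
                 dimnames = list(sprintf("g%03d", 1:G), rownames(d)))
  year <- factor(rep(c(2013, 2014), length.out = n))
  pc1 <- rnorm(n)
  list(g = g, vals = vals, year = year, pc1 = pc1)
}

test_that("a feature equal to the dosage is recovered exactly", {
  set.seed(11)
  d <- matrix(rbinom(50, 2, 0.4), 50, 1,
              dimnames = list(sprintf("a%03d", 1:50), "s001"))
  g <- toy_genotypes(d)
  vals <- matrix(d[, 1], 1, 50, dimnames = list("g1", rownames(d)))
  r <- fit_association(vals[1, ], g$dosage[, 1])
  expect_equal(unname(r["beta"]), 1)
  expect_lt(unname(r["p"]), 1e-200)
})

test_that("fit_association matches the lm oracle with covariates and missingness", {
  pr <- scan_problem(seed = 2)
  for (j in c(1, 5, 10)) {
    x <- pr$g$dosage[, j]
    ok <- !is.na(x)
    r <- fit_association(pr$vals[3, ], x, year = pr$year, pc1 = pr$pc1)
    o <- lm_oracle(pr$vals[3, ok], x[ok], pr$year[ok], pr$pc1[ok])
    expect_equal(unname(r[c("beta", "t", "p")]), unname(o), tolerance = 1e-8)
  }
})

test_that("the vectorized scan equals the per-pair OLS oracle record for record", {
  pr <- scan_problem(seed = 3, n = 80, S = 50, G = 20)
  sc <- association_scan(pr$g, pr$vals, year = pr$year, pc1 = pr$pc1)
  worst <- 0
  for (j in seq_len(ncol(pr$g$dosage))) {
    x <- pr$g$dosage[, j]
    ok <- !is.na(x)
    if (length(unique(x[ok])) < 2) {
      expect_true(all(is.na(sc$pval[, j])))
      next
    }
    for (i in seq_len(nrow(pr$vals))) {
      o <- lm_oracle(pr$vals[i, ok], x[ok], pr$year[ok], pr$pc1[ok])
      worst <- max(worst,
                   abs(sc$beta[i, j] - o["beta"]),
                   abs(sc$tstat[i, j] - o["t"]),
                   abs(sc$pval[i, j] - o["p"]))
    }
  }
  expect_lt(worst, 1e-8)
})

test_that("monomorphic SNPs are skipped with a message", {
  set.seed(4)
  d <- cbind(mono = rep(1L, 30), poly = rbinom(30, 2, 0.5))
  rownames(d) <- sprintf("a%03d", 1:30)
  g <- toy_genotypes(d)
  vals <- matrix(rnorm(60), 2, 30,
                 dimnames = list(c("g1", "g2"), rownames(d)))
  expect_message(sc <- association_scan(g, vals), "monomorphic")
  expect_true(all(is.na(sc$pval[, "mono"])))
  expect_true(all(!is.na(sc$pval[, "poly"])))
  expect_identical(sc$skipped, "mono")
})

test_that("null association p-values are uniform", {
  pr <- scan_problem(seed = 5, n = 80, S = 100, G = 100, missing = FALSE)
  sc <- association_scan(pr$g, pr$vals, year = pr$year, pc1 = pr$pc1)
  pv <- as.numeric(sc$pval)
  pv <- pv[!is.na(pv)]
  expect_gt(length(pv), 9000)
  expect_gt(suppressWarnings(ks.test(pv, "punif")$p.value), 0.01)
})

test_that("cis classification boundaries are inclusive at exactly 1 Mb", {
  expect_equal(classify_location("chr1", 5e6 - 1e6, "chr1", 5e6, 6e6), "cis")
  expect_equal(classify_location("chr1", 5e6 - 1e6 - 1, "chr1", 5e6, 6e6),
               "trans")
  expect_equal(classify_location("chr1", 5.5e6, "chr1", 5e6, 6e6), "cis")
  expect_equal(classify_location("chr1", 6e6 + 1e6, "chr1", 5e6, 6e6), "cis")
  expect_equal(classify_location("chr1", 6e6 + 1e6 + 1, "chr1", 5e6, 6e6),
               "trans")
  expect_equal(classify_location("chr2", 5.5e6, "chr1", 5e6, 6e6), "trans")
})

test_that("records are retained at p <= threshold and classified into four classes", {
  # two features: one cis to the SNPs, one on another chromosome (trans)
  n <- 40
  ids <- sprintf("a%03d", 1:n)
  d <- matrix(rbinom(3 * n, 2, 0.5), n, 3)
  rownames(d) <- ids
  colnames(d) <- c("s1", "s2", "s3")
  g <- genotype_data(d, data.frame(snp_id = c("s1", "s2", "s3"), chrom = "chr1",
                                   pos = c(1e6, 2e6, 3e6)))
  gm <- data.frame(gene_id = c("gcis", "gtrans"), chrom = c("chr1", "chr2"),
                   start = c(2e6, 2e6), end = c(2.5e6, 2.5e6))
  vals <- matrix(rnorm(2 * n), 2, n, dimnames = list(c("gcis", "gtrans"), ids))
  sc <- association_scan(g, vals)
  # craft exact p-values at and beyond each boundary
  sc$pval[] <- 0.5
  sc$pval["gtrans", "s1"] <- 1e-5          # retained (= trans threshold)
  sc$pval["gtrans", "s2"] <- 1.01e-5       # dropped
  sc$pval["gcis", "s1"] <- 2e-4            # retained (= cis threshold)
  sc$pval["gcis", "s2"] <- 2.1e-4          # dropped
  rec <- qtl_scan(g, vals, gm, deg_genes = "gtrans",
                  trans_threshold = 1e-5, cis_thresholds = 2e-4, scan = sc)
  expect_setequal(paste(rec$feature_id, rec$snp_id),
                  c("gtrans s1", "gcis s1"))
  expect_equal(rec$class[rec$feature_id == "gtrans"], "DEG trans")
  expect_equal(rec$class[rec$feature_id == "gcis"], "cis")
  # the four combined classes partition the records
  expect_true(all(rec$class %in% c("cis", "trans", "DEG cis", "DEG trans")))
  expect_equal(nrow(rec), sum(table(rec$class)))
})

test_that("per-gene cis thresholds are honored and missing ones are an error", {
  n <- 40
  ids <- sprintf("a%03d", 1:n)
  set.seed(6)
  d <- matrix(rbinom(2 * n, 2, 0.5), n, 2)
  rownames(d) <- ids; colnames(d) <- c("s1", "s2")
  g <- genotype_data(d, data.frame(snp_id = c("s1", "s2"), chrom = "chr1",
                                   pos = c(1e6, 2e6)))
  gm <- data.frame(gene_id = "gA", chrom = "chr1", start = 1.5e6, end = 1.6e6)
  vals <- matrix(rnorm(n), 1, n, dimnames = list("gA", ids))
  sc <- association_scan(g, vals)
  sc$pval[] <- 0.012
  thr <- data.frame(gene_id = "gA", n_tests = 2, m_eff = 2, alpha = 0.05,
                    threshold = 0.025)
  rec <- qtl_scan(g, vals, gm, trans_threshold = 1e-5, cis_thresholds = thr,
                  scan = sc)
  expect_equal(nrow(rec), 2L)                      # 0.012 <= 0.05 / 2
  bad <- data.frame(gene_id = "gZ", n_tests = 1, m_eff = 1, alpha = 0.05,
                    threshold = 0.05)
  expect_error(qtl_scan(g, vals, gm, trans_threshold = 1e-5,
                        cis_thresholds = bad, scan = sc),
               "missing cis threshold")
})

test_that("dropping the structure covariate inflates null trans discoveries", {
  cfg <- null_config(n_snps = 120, n_genes = 80, seed = 13, n_animals = 100)
  cfg$structure_expr_sd <- 1.0        # expression tracks ancestry
  cfg$pool_divergence <- 0.5
  dat <- simulate_dataset(cfg)
  v <- vst_transform(filter_low_counts(dat$gene_counts))
  pca <- genotype_pca(dat$genotypes)
  year <- factor(dat$genotypes$animals$year)
  with_pc <- association_scan(dat$genotypes, v, year = year, pc1 = pca$pc1)
  without <- association_scan(dat$genotypes, v, year = year)
  rate_with <- mean(with_pc$pval < 0.05, na.rm = TRUE)
  rate_without <- mean(without$pval < 0.05, na.rm = TRUE)
  expect_gt(rate_without, rate_with * 1.5)
  expect_lt(rate_with, 0.09)
})
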