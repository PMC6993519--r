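test_that("generators are deterministic under a fixed seed", {
  cfg <- sim_config(n_snps = 100, n_genes = 20, hotspot_targets = 10,
                    n_cis_effects = 3, n_sqtl = 2, n_deg_genes = 5, seed = 11)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1$dosage, g2$dosage)
  expect_identical(g1$snp_map, g2$snp_map)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$gene_counts$counts, d2$gene_counts$counts)
  expect_identical(d1$exon_counts$counts, d2$exon_counts$counts)
  expect_identical(d1$phenotypes, d2$phenotypes)
  g3 <- simulate_genotypes(cfg, seed = 12)
  expect_false(identical(g1$dosage, g3$dosage))
})

test_that("empirical MAF respects the configured bounds", {
  cfg <- sim_config(n_snps = 200, n_genes = 20, maf_range = c(0.5, 0.5),
                    hotspot_targets = 10, missing_rate = 0, seed = 3)
  g <- simulate_genotypes(cfg)
  maf <- apply(g$dosage, 2, compute_maf)
  expect_true(all(maf <= 0.5))
  expect_true(all(maf > 0))
})

test_that("independent-SNP MAF matches the binomial sampling oracle", {
  n <- 10000
  cfg <- sim_config(n_animals = n, n_snps = 150, n_genes = 20,
                    maf_range = c(0.3, 0.3), pool_divergence = 0, n_hotspots = 0,
                    ld_r = 0, ld_block_size = 1, missing_rate = 0, seed = 5)
  g <- simulate_genotypes(cfg)
  maf <- apply(g$dosage, 2, compute_maf)
  # binomial oracle: each allele count ~ Bin(2n, 0.3); nearly all draws
  # fall within +/- 0.02 of the target frequency
  cover <- pbinom(ceiling(0.32 * 2 * n), 2 * n, 0.3) -
    pbinom(floor(0.28 * 2 * n) - 1, 2 * n, 0.3)
  expect_gt(cover, 0.95)
  expect_gte(mean(abs(maf - 0.3) <= 0.02), 0.95)
})

test_that("admixture gradient creates genotype structure along PC1", {
  dat <- small_dataset()
  pca <- genotype_pca(dat$genotypes)
  grp <- dat$genotypes$animals$breed_group
  expect_gt(abs(cor(pca$pc1, grp)), 0.6)
})

test_that("exon counts are an exact multinomial split of gene counts", {
  dat <- small_dataset()
  by_gene <- rowsum(dat$exon_counts$counts, dat$exon_counts$feature_map$gene_id)
  expect_identical(unname(by_gene[rownames(dat$gene_counts$counts), ]),
                   unname(dat$gene_counts$counts))
})

test_that("planted truth is structurally recoverable", {
  dat <- small_dataset()
  tc <- dat$truth$planted_cis
  map <- dat$genotypes$snp_map
  gm <- dat$gene_models
  for (k in seq_len(nrow(tc))) {
    s <- map[map$snp_id == tc$snp_id[k], ]
    g <- gm[gm$gene_id == tc$gene_id[k], ]
    expect_equal(classify_location(s$chrom, s$pos, g$chrom, g$start, g$end),
                 "cis")
  }
  tgt <- table(dat$truth$hotspot_targets$snp_id)
  expect_true(all(tgt >= dat$config$hotspot_targets))
})

test_that("zero-dispersion null counts behave like Poisson (variance ~ mean)", {
  cfg <- null_config(n_snps = 50, n_genes = 150, seed = 8, n_animals = 200)
  cfg$dispersion <- 0
  cfg$libsize_sd <- 0
  cfg$expr_batch_sd <- 0
  g <- simulate_genotypes(cfg)
  gm <- simulate_gene_models(cfg)
  tr <- plant_truth(g, gm, cfg)
  fc <- simulate_expression(g, gm, tr, cfg)
  m <- rowMeans(fc$counts)
  v <- apply(fc$counts, 1, var)
  ratio <- v[m > 20] / m[m > 20]
  expect_lt(abs(median(ratio) - 1), 0.2)
})

test_that("zero planted effects leave an empty recovery set", {
  cfg <- null_config(n_snps = 50, n_genes = 20, seed = 2)
  g <- simulate_genotypes(cfg)
  gm <- simulate_gene_models(cfg)
  tr <- plant_truth(g, gm, cfg)
  expect_identical(nrow(tr$planted_cis), 0L)
  expect_identical(nrow(tr$hotspot_targets), 0L)
  expect_identical(length(tr$deg_genes), 0L)
})

test_that("a planted VST effect of 1 per allele shifts group means by ~2", {
  # 200 replicates of an NB gene with log2-scale effect 1.0 per allele copy,
  # MAF 0.3, n = 80; compare VST means of dosage-0 vs dosage-2 animals
  set.seed(91)
  diffs <- replicate(200, {
    d <- rbinom(80, 2, 0.3)
    mu <- 100 * 2^(1.0 * d)
    y <- rnbinom(80, mu = mu, size = 1 / 0.1)
    v <- vst_transform(matrix(y, 1, dimnames = list("g", paste0("a", 1:80))),
                       size_factors = rep(1, 80), dispersion = 0.1)$values
    mean(v[d == 2]) - mean(v[d == 0])
  })
  expect_lt(abs(mean(diffs) - 2.0), 0.15)
})

test_that("a planted usage shift moves the exon fraction as configured", {
  # base usage 0.3 shifted by 0.1 per allele: dosage-2 animals ~ 0.5
  set.seed(14)
  cfg <- sim_config(n_snps = 10, n_genes = 2, n_hotspots = 0, n_cis_effects = 0,
                    n_sqtl = 1, seed = 14, susage_effect = 0.1)
  fracs <- replicate(200, {
    n <- 80
    counts <- rep(5000L, n)
    d <- rbinom(n, 2, 0.4)
    p <- 0.3 + d * 0.1
    x <- rbinom(n, counts, p)
    mean((x / counts)[d == 2])
  })
  expect_lt(abs(mean(fracs) - 0.5), 0.01)
  # and through the generator itself
  g <- toy_genotypes(matrix(rep(0:2, length.out = 80 * 10), 80, 10))
  g$animals <- data.frame(animal_id = rownames(g$dosage),
                          breed_group = 1, ancestry = 0.5, year = 2013L)
  gm <- data.frame(gene_id = "gene1", chrom = "chr1", start = 1e6,
                   end = 1.1e6, n_exons = 2L)
  truth <- structure(list(
    planted_cis = data.frame(snp_id = character(0), gene_id = character(0),
                             beta = numeric(0)),
    planted_hotspots = data.frame(), hotspot_targets =
      data.frame(snp_id = character(0), gene_id = character(0),
                 beta = numeric(0)),
    planted_sqtl = data.frame(snp_id = "s001", exon_id = "gene1:exon001",
                              gene_id = "gene1", shift = 0.1),
    deg_genes = character(0)), class = "truth_table")
  counts <- matrix(5000L, 1, 80,
                   dimnames = list("gene1", rownames(g$dosage)))
  fc <- feature_counts(counts, data.frame(
    feature_id = "gene1", gene_id = "gene1", chrom = "chr1",
    start = 1e6, end = 1.1e6), level = "gene")
  ex <- simulate_exon_counts(fc, g, gm, truth, cfg, seed = 4)
  frac <- ex$counts["gene1:exon001", ] / 5000
  d <- g$dosage[, "s001"]
  base_hat <- mean(frac[d == 0])
  expected <- min(base_hat + 0.2, 1)      # shift is clipped to the simplex
  expect_lt(abs(mean(frac[d == 2]) - expected), 0.03)
})

test_that("phenotypes collapse to constants when all signal is off", {
  cfg <- null_config(n_snps = 20, n_genes = 10, seed = 6)
  cfg$pheno_noise_sd <- 0
  cfg$year_effect_sd <- 0
  dat <- simulate_dataset(cfg)
  traits <- dat$phenotypes[, quality_traits]
  expect_true(all(apply(traits, 2, function(x) length(unique(x))) == 1))
})

test_that("a strong single-factor construction puts >= 80% of trait variance on PC1", {
  cfg <- sim_config(n_snps = 50, n_genes = 40, n_deg_genes = 20,
                    n_cis_effects = 0, n_hotspots = 0, n_sqtl = 0,
                    deg_pheno_weight = 2, pheno_noise_sd = 0.2,
                    year_effect_sd = 0, seed = 21)
  dat <- simulate_dataset(cfg)
  idx <- compute_index(dat$phenotypes)
  # oracle: for traits l_k * L + e with iid noise, the trait correlation
  # matrix is R = D l l' D + diag(...) with D = diag(1/sqrt(l_k^2 + s^2));
  # its leading eigenvalue bounds the empirical PC1 share from below
  l <- 2 * c(0.9, 1.0, 0.7, 0.8, 1.0, 0.8)       # |loadings| * weight
  s2 <- 0.2^2
  R <- outer(l, l) / sqrt(outer(l^2 + s2, l^2 + s2))
  diag(R) <- 1
  oracle_share <- eigen(R, symmetric = TRUE)$values[1] / 6
  expect_gt(oracle_share, 0.8)
  expect_gt(idx$explained_variance[1], 0.8)
  expect_lt(abs(idx$explained_variance[1] - oracle_share), 0.05)
})

test_that("configuration validation rejects impossible settings", {
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_config(n_snps = 100, ld_block_size = 200), "ld_block_size")
  expect_error(sim_config(n_genes = 10, hotspot_targets = 25),
               "hotspot_targets")
  expect_error(sim_config(susage_effect = 0.9), "susage_effect")
  expect_error(sim_config(exons_per_gene = c(1L, 4L)), "exons_per_gene")
})
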