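# Shared fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

# small but complete simulated study reused across test files
small_dataset <- function() {
  if (is.null(.fixture_cache$small)) {
    cfg <- sim_config(n_snps = 300, n_genes = 60, exons_per_gene = c(2L, 5L),
                      n_cis_effects = 10, n_hotspots = 1, hotspot_targets = 25,
                      n_sqtl = 5, n_deg_genes = 15, seed = 42)
    .fixture_cache$small <- simulate_dataset(cfg)
  }
  .fixture_cache$small
}

# configuration with every planted effect switched off
null_config <- function(n_snps = 200, n_genes = 100, seed = 1,
                        n_animals = 80, ...) {
  sim_config(n_animals = n_animals, n_snps = n_snps, n_genes = n_genes,
             n_cis_effects = 0, n_hotspots = 0, n_sqtl = 0, n_deg_genes = 0,
             structure_expr_sd = 0, mean_count_range = c(5, 500),
             seed = seed, ...)
}

# genotype_data straight from a dosage matrix with an evenly spaced map
toy_genotypes <- function(dosage, chrom = "chr1", spacing = 1e5) {
  n_snp <- ncol(dosage)
  if (is.null(colnames(dosage)))
    colnames(dosage) <- sprintf("s%03d", seq_len(n_snp))
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("a%03d", seq_len(nrow(dosage)))
  genotype_data(dosage,
                data.frame(snp_id = colnames(dosage),
                           chrom = rep_len(chrom, n_snp),
                           pos = seq_len(n_snp) * spacing))
}

# per-pair OLS oracle: plain lm() fit of value ~ dosage (+ year + pc1)
lm_oracle <- function(y, dosage, year = NULL, pc1 = NULL) {
  df <- data.frame(y = y, dosage = dosage)
  form <- "y ~ dosage"
  if (!is.null(year)) { df$year <- factor(year); form <- paste(form, "+ year") }
  if (!is.null(pc1)) { df$pc1 <- pc1; form <- paste(form, "+ pc1") }
  fit <- summary(lm(as.formula(form), data = df))$coefficients
  c(beta = fit["dosage", 1], t = fit["dosage", 3], p = fit["dosage", 4])
}
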