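#' Simulation configuration
#'
#' Defines the synthetic study: a multibreed herd genotyped on a dense SNP
#' panel, RNA-seq gene and exon counts on muscle, and six correlated
#' meat-quality traits. Defaults emulate a 120-steer population in six
#' breed-composition groups along an admixture gradient, SNPs in LD blocks,
#' negative-binomial counts with planted cis effects, trans hotspots,
#' genotype-shifted exon usage, and a year-of-birth batch effect.
#'
#' @param n_animals Number of animals (default 120).
#' @param n_snps Number of SNPs across the genome.
#' @param n_genes Number of genes.
#' @param exons_per_gene Integer range (length 2) of exons per gene.
#' @param n_chromosomes,chrom_length Genome layout (equal-length chromosomes, bp).
#' @param maf_range Range the base minor allele frequency is drawn from;
#'   both ends in (0, 0.5].
#' @param ld_block_size SNPs per LD block (consecutive on the map).
#' @param ld_r Latent within-block haplotype correlation in `[0, 1)`.
#' @param pool_divergence Maximum allele-frequency divergence between the
#'   two ancestral pools; 0 removes population structure.
#' @param missing_rate Fraction of genotype calls set missing.
#' @param n_cis_effects,cis_beta Number of planted cis eQTLs and their
#'   effect size in VST units per allele copy.
#' @param n_hotspots,hotspot_targets,hotspot_beta Planted trans hotspots:
#'   how many SNPs, how many target genes each (>= 20 to be detectable), and
#'   the per-allele effect size (VST units, random sign per target).
#' @param n_sqtl,susage_effect Planted sQTLs: count, and the shift in the
#'   target exon's usage fraction per allele copy (clipped to the simplex).
#' @param n_deg_genes Number of genes driving the meat-quality traits (the
#'   planted "DEG" set).
#' @param deg_pheno_weight Strength of the expression-to-trait coupling.
#' @param pheno_noise_sd Independent trait noise (standardized trait units).
#' @param year_effect_sd SD of the per-trait year-of-birth effect
#'   (standardized trait units).
#' @param expr_batch_sd SD of the per-gene year batch effect on log counts.
#' @param structure_expr_sd SD of per-gene loadings of expression on
#'   ancestry; 0 decouples expression from population structure.
#' @param n_breed_groups Number of breed-composition groups (default 6).
#' @param dispersion Negative-binomial dispersion alpha (variance
#'   mu + alpha mu^2); 0 gives Poisson counts.
#' @param mean_count_range Range baseline per-gene mean counts are drawn
#'   from (log-uniform); spans sub-10-total genes so low-count filtering is
#'   exercised.
#' @param libsize_sd SD of log relative library size across animals.
#' @param seed Default seed used by the generators when none is passed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_animals = 120, n_snps = 2000, n_genes = 300,
                       exons_per_gene = c(2L, 8L), n_chromosomes = 5,
                       chrom_length = 5e7, maf_range = c(0.05, 0.5),
                       ld_block_size = 10, ld_r = 0.6, pool_divergence = 0.3,
                       missing_rate = 0.02, n_cis_effects = 20, cis_beta = 1.0,
                       n_hotspots = 2, hotspot_targets = 25, hotspot_beta = 1.0,
                       n_sqtl = 10, susage_effect = 0.1, n_deg_genes = 30,
                       deg_pheno_weight = 1.0, pheno_noise_sd = 0.5,
                       year_effect_sd = 0.5, expr_batch_sd = 0.3,
                       structure_expr_sd = 0.25, n_breed_groups = 6,
                       dispersion = 0.1, mean_count_range = c(0.05, 500),
                       libsize_sd = 0.2, seed = 1L) {
  cfg <- as.list(environment())
  counts <- c("n_animals", "n_snps", "n_genes", "n_chromosomes", "n_breed_groups")
  for (nm in counts)
    if (length(cfg[[nm]]) != 1 || cfg[[nm]] < 1) stop(nm, " must be a positive count")
  if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2])
    stop("maf_range must be within (0, 0.5] and nondecreasing")
  if (ld_block_size < 1 || ld_block_size > n_snps)
    stop("ld_block_size must be in [1, n_snps]")
  if (ld_r < 0 || ld_r >= 1) stop("ld_r must be in [0, 1)")
  if (n_hotspots > 0 && hotspot_targets > n_genes)
    stop("hotspot_targets must be <= n_genes")
  if (length(exons_per_gene) != 2 || exons_per_gene[1] < 2)
    stop("exons_per_gene must be a range with lower end >= 2")
  if (susage_effect < 0 || susage_effect > 0.5)
    stop("susage_effect must be in [0, 0.5] so shifted fractions stay in [0, 1]")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  if (dispersion < 0) stop("dispersion must be >= 0")
  cfg$exons_per_gene <- as.integer(exons_per_gene)
  class(cfg) <- "sim_config"
  cfg
}

# consecutive block ids restarting at each chromosome
block_ids <- function(chrom, block_size) {
  out <- integer(length(chrom))
  nxt <- 1L
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    b <- (seq_along(idx) - 1L) %/% block_size
    out[idx] <- nxt + b
    nxt <- nxt + max(b) + 1L
  }
  out
}

#' Simulate genotypes on an admixture gradient with LD blocks
#'
#' Animals belong to breed-composition groups whose ancestry fraction
#' interpolates between two ancestral allele-frequency pools, so the first
#' genotype PC tracks breed composition. Consecutive SNPs within a block
#' share a latent haplotype draw (Gaussian copula), inducing LD; a
#' configurable fraction of calls is set missing.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A [genotype_data()] whose `animals` table records breed group,
#'   ancestry fraction and year of birth.
#' @export
simulate_genotypes <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n <- config$n_animals; S <- config$n_snps
  per_chr <- diff(round(seq(0, S, length.out = config$n_chromosomes + 1)))
  chrom <- rep(paste0("chr", seq_len(config$n_chromosomes)), per_chr)
  pos <- unlist(lapply(per_chr, function(k)
    sort(sample.int(config$chrom_length - 1L, k))))
  base_f <- runif(S, config$maf_range[1], config$maf_range[2])
  div <- runif(S, 0, config$pool_divergence)
  p1 <- clip(base_f - div / 2, 0.005, 0.995)
  p2 <- clip(base_f + div / 2, 0.005, 0.995)
  grp <- sort(rep_len(seq_len(config$n_breed_groups), n))
  anc <- clip((grp - 0.5) / config$n_breed_groups + rnorm(n, 0, 0.05), 0, 1)
  f <- (1 - anc) %o% p1 + anc %o% p2           # n x S per-animal allele freq
  blk <- block_ids(chrom, config$ld_block_size)
  r <- config$ld_r
  dosage <- matrix(0L, n, S)
  for (copy in 1:2) {
    z0 <- matrix(rnorm(n * max(blk)), n, max(blk))
    z <- sqrt(r) * z0[, blk, drop = FALSE] +
      sqrt(1 - r) * matrix(rnorm(n * S), n, S)
    dosage <- dosage + (pnorm(z) < f)
  }
  storage.mode(dosage) <- "integer"
  if (config$missing_rate > 0)
    dosage[runif(n * S) < config$missing_rate] <- NA_integer_
  animal_ids <- sprintf("an%03d", seq_len(n))
  dimnames(dosage) <- list(animal_ids, sprintf("snp%05d", seq_len(S)))
  animals <- data.frame(animal_id = animal_ids, breed_group = grp,
                        ancestry = anc,
                        year = sample(rep_len(c(2013L, 2014L), n)))
  genotype_data(dosage,
                data.frame(snp_id = colnames(dosage), chrom = chrom, pos = pos),
                animals = animals)
}

#' Simulate gene models
#'
#' Places genes uniformly on the simulated genome with log-uniform widths
#' (5-200 kb) and a random exon count in the configured range.
#'
#' @inheritParams simulate_genotypes
#' @return `data.frame` with `gene_id`, `chrom`, `start`, `end`, `n_exons`,
#'   sorted by position; ids assigned in genome order.
#' @export
simulate_gene_models <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  G <- config$n_genes
  width <- round(exp(runif(G, log(5e3), log(2e5))))
  chrom <- sample(paste0("chr", seq_len(config$n_chromosomes)), G, replace = TRUE)
  start <- vapply(width, function(w)
    sample.int(config$chrom_length - w, 1L), 1L)
  n_exons <- sample(seq(config$exons_per_gene[1], config$exons_per_gene[2]),
                    G, replace = TRUE)
  gm <- data.frame(chrom = chrom, start = as.integer(start),
                   end = as.integer(start + width - 1), n_exons = n_exons)
  gm <- gm[order(gm$chrom, gm$start), , drop = FALSE]
  gm <- cbind(gene_id = sprintf("gene%04d", seq_len(G)), gm)
  rownames(gm) <- NULL
  gm
}

#' Plant the ground truth for a simulated dataset
#'
#' Chooses the cis SNP-gene pairs (SNP within the 1 Mb cis window of the
#' gene span), the hotspot SNPs with their trans target genes (targets on
#' other chromosomes), the sQTL SNP-exon pairs (SNP in the gene's cis
#' window), and the DEG gene set that will drive the phenotypes.
#'
#' @param genotypes A [genotype_data()].
#' @param gene_models Output of [simulate_gene_models()].
#' @inheritParams simulate_genotypes
#' @param cis_window Cis window in bp (default 1 Mb, matching the scan).
#' @return A list of class `truth_table` with elements `planted_cis`,
#'   `planted_hotspots`, `hotspot_targets`, `planted_sqtl`, `deg_genes`.
#' @export
plant_truth <- function(genotypes, gene_models, config, seed = config$seed,
                        cis_window = 1e6) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  map <- genotypes$snp_map
  used_snps <- character(0)
  cis_snps_of <- function(g) {
    row <- gene_models[gene_models$gene_id == g, ]
    map$snp_id[map$chrom == row$chrom &
                 map$pos >= row$start - cis_window &
                 map$pos <= row$end + cis_window]
  }
  # cis effects
  cis <- data.frame(snp_id = character(0), gene_id = character(0),
                    beta = numeric(0))
  for (g in sample(gene_models$gene_id)) {
    if (nrow(cis) >= config$n_cis_effects) break
    cand <- setdiff(cis_snps_of(g), used_snps)
    if (!length(cand)) next
    s <- if (length(cand) == 1) cand else sample(cand, 1)
    cis <- rbind(cis, data.frame(snp_id = s, gene_id = g,
                                 beta = config$cis_beta))
    used_snps <- c(used_snps, s)
  }
  if (nrow(cis) < config$n_cis_effects)
    warning("only ", nrow(cis), " of ", config$n_cis_effects,
            " cis effects could be planted")
  # hotspots: trans targets on other chromosomes, away from cis genes
  hs <- data.frame(snp_id = character(0), regulator_gene_id = character(0),
                   beta = numeric(0))
  hs_targets <- data.frame(snp_id = character(0), gene_id = character(0),
                           beta = numeric(0))
  free_snps <- setdiff(map$snp_id, used_snps)
  if (config$n_hotspots > 0) {
    picks <- sample(free_snps, config$n_hotspots)
    for (s in picks) {
      srow <- map[map$snp_id == s, ]
      pool <- gene_models$gene_id[gene_models$chrom != srow$chrom &
                                    !(gene_models$gene_id %in% cis$gene_id)]
      tg <- sample(pool, min(config$hotspot_targets, length(pool)))
      reg <- nearest_gene(srow$chrom, srow$pos, gene_models)
      hs <- rbind(hs, data.frame(snp_id = s, regulator_gene_id = reg,
                                 beta = config$hotspot_beta))
      hs_targets <- rbind(hs_targets, data.frame(
        snp_id = s, gene_id = tg,
        beta = config$hotspot_beta * sample(c(-1, 1), length(tg), replace = TRUE)))
    }
    used_snps <- c(used_snps, picks)
  }
  # sQTLs: one exon per chosen gene, SNP in the gene's cis window
  sqtl <- data.frame(snp_id = character(0), exon_id = character(0),
                     gene_id = character(0), shift = numeric(0))
  if (config$n_sqtl > 0) {
    for (g in sample(setdiff(gene_models$gene_id, cis$gene_id))) {
      if (nrow(sqtl) >= config$n_sqtl) break
      cand <- setdiff(cis_snps_of(g), used_snps)
      if (!length(cand)) next
      s <- if (length(cand) == 1) cand else sample(cand, 1)
      k <- sample.int(gene_models$n_exons[gene_models$gene_id == g], 1)
      sqtl <- rbind(sqtl, data.frame(
        snp_id = s, exon_id = sprintf("%s:exon%03d", g, k), gene_id = g,
        shift = config$susage_effect))
      used_snps <- c(used_snps, s)
    }
    if (nrow(sqtl) < config$n_sqtl)
      warning("only ", nrow(sqtl), " of ", config$n_sqtl,
              " sQTLs could be planted")
  }
  deg <- if (config$n_deg_genes > 0)
    sample(gene_models$gene_id, min(config$n_deg_genes, config$n_genes))
  else character(0)
  structure(list(planted_cis = cis, planted_hotspots = hs,
                 hotspot_targets = hs_targets, planted_sqtl = sqtl,
                 deg_genes = deg),
            class = "truth_table")
}

# id of the gene nearest to (chrom, pos); NA if the chromosome has no gene
nearest_gene <- function(chrom, pos, gene_models) {
  gm <- gene_models[gene_models$chrom == chrom, ]
  if (!nrow(gm)) return(NA_character_)
  d <- pmax(gm$start - pos, pos - gm$end, 0)
  gm$gene_id[order(d, gm$start)][1]
}

# dosage column with missing entries replaced by the column mean
impute_dosage <- function(genotypes, snp) {
  x <- as.numeric(genotypes$dosage[, snp])
  x[is.na(x)] <- mean(x, na.rm = TRUE)
  x
}

#' Simulate gene-level counts with planted genotype effects
#'
#' Counts are negative binomial with log-mean
#' `log(mu0_g) + log(lib_i) + batch + structure + log(2) * beta * dosage`,
#' so a planted effect of `beta` VST units per allele copy shifts the
#' variance-stabilized expression by `beta` per allele. Baseline means span
#' sub-10-total to highly expressed genes.
#'
#' @inheritParams plant_truth
#' @param truth A `truth_table` from [plant_truth()].
#' @return A gene-level [feature_counts()].
#' @export
simulate_expression <- function(genotypes, gene_models, truth, config,
                                seed = config$seed) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "truth_table"))
  set.seed(seed)
  planted <- unique(c(truth$planted_cis$gene_id, truth$hotspot_targets$gene_id))
  if (!all(planted %in% gene_models$gene_id))
    stop("planted gene absent from gene_models")
  G <- nrow(gene_models); n <- nrow(genotypes$dosage)
  mu0 <- exp(runif(G, log(config$mean_count_range[1]),
                   log(config$mean_count_range[2])))
  # planted effects sit on expressed genes: an effect on a gene whose
  # counts hover at zero is unmeasurable by construction, and sQTL usage
  # fractions need non-trivial gene counts to exist at all
  hi <- config$mean_count_range[2]
  planted_expr <- unique(c(truth$planted_cis$gene_id,
                           truth$hotspot_targets$gene_id))
  pi_ <- match(planted_expr, gene_models$gene_id)
  if (length(pi_))
    mu0[pi_] <- exp(runif(length(pi_), log(min(20, hi)), log(hi)))
  si_ <- match(setdiff(truth$planted_sqtl$gene_id, planted_expr),
               gene_models$gene_id)
  if (length(si_))
    mu0[si_] <- exp(runif(length(si_), log(min(50, hi)), log(hi)))
  lib <- exp(rnorm(n, 0, config$libsize_sd))
  yr <- as.numeric(genotypes$animals$year == max(genotypes$animals$year))
  batch <- rnorm(G, 0, config$expr_batch_sd)
  strc <- rnorm(G, 0, config$structure_expr_sd)
  anc <- genotypes$animals$ancestry - mean(genotypes$animals$ancestry)
  eta <- log(mu0) + batch %o% yr + strc %o% anc +
    matrix(log(lib), G, n, byrow = TRUE)
  gi <- setNames(seq_len(G), gene_models$gene_id)
  add_effect <- function(snp, gene, beta) {
    d <- impute_dosage(genotypes, snp)
    eta[gi[gene], ] <<- eta[gi[gene], ] + log(2) * beta * d
  }
  cis <- truth$planted_cis
  for (k in seq_len(nrow(cis)))
    add_effect(cis$snp_id[k], cis$gene_id[k], cis$beta[k])
  ht <- truth$hotspot_targets
  for (k in seq_len(nrow(ht)))
    add_effect(ht$snp_id[k], ht$gene_id[k], ht$beta[k])
  mu <- exp(eta)
  cnt <- if (config$dispersion > 0)
    rnbinom(G * n, mu = mu, size = 1 / config$dispersion)
  else rpois(G * n, mu)
  counts <- matrix(as.integer(cnt), G, n,
                   dimnames = list(gene_models$gene_id,
                                   genotypes$animals$animal_id))
  fm <- data.frame(feature_id = gene_models$gene_id,
                   gene_id = gene_models$gene_id,
                   chrom = gene_models$chrom, start = gene_models$start,
                   end = gene_models$end)
  feature_counts(counts, fm, level = "gene")
}

#' Simulate exon counts as a multinomial split of gene counts
#'
#' Each gene x animal count is split across the gene's exons with a
#' Dirichlet-drawn base usage; a planted sQTL shifts the target exon's
#' allocation probability by `dosage * shift` (clipped to the simplex, the
#' other exons rescaled proportionally). Exon counts therefore sum exactly
#' to the gene count.
#'
#' @inheritParams simulate_expression
#' @param gene_counts Gene-level [feature_counts()] from
#'   [simulate_expression()].
#' @return An exon-level [feature_counts()]; exon ids are
#'   `geneid:exonNNN` and exons inherit coordinate chunks of the gene span.
#' @export
simulate_exon_counts <- function(gene_counts, genotypes, gene_models, truth,
                                 config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "truth_table"))
  if (any(gene_models$n_exons < 2)) stop("each gene must have >= 2 exons")
  set.seed(seed)
  n <- ncol(gene_counts$counts)
  sq <- truth$planted_sqtl
  counts_l <- vector("list", nrow(gene_models))
  maps_l <- vector("list", nrow(gene_models))
  for (g in seq_len(nrow(gene_models))) {
    gene <- gene_models$gene_id[g]
    K <- gene_models$n_exons[g]
    base <- rgamma(K, shape = 5); base <- base / sum(base)
    probs <- matrix(base, K, n)
    hit <- sq[sq$gene_id == gene, , drop = FALSE]
    for (k in seq_len(nrow(hit))) {
      tgt <- as.integer(sub(".*:exon0*", "", hit$exon_id[k]))
      d <- impute_dosage(genotypes, hit$snp_id[k])
      pt_new <- clip(base[tgt] + d * hit$shift[k], 0, 1)
      scale_others <- if (base[tgt] < 1) (1 - pt_new) / (1 - base[tgt])
      else rep(0, length(pt_new))
      probs <- probs * rep(scale_others, each = K)
      probs[tgt, ] <- pt_new
    }
    gc_row <- gene_counts$counts[gene, ]
    ex <- vapply(seq_len(n), function(i) {
      if (gc_row[i] == 0) return(integer(K))
      as.integer(rmultinom(1, gc_row[i], probs[, i]))
    }, integer(K))
    ex <- matrix(ex, K, n)
    # exon coordinate chunks of the gene span (synthetic, contiguous)
    brk <- round(seq(gene_models$start[g], gene_models$end[g] + 1,
                     length.out = K + 1))
    counts_l[[g]] <- ex
    maps_l[[g]] <- data.frame(
      feature_id = sprintf("%s:exon%03d", gene, seq_len(K)),
      gene_id = gene, chrom = gene_models$chrom[g],
      start = as.integer(brk[-(K + 1)]), end = as.integer(brk[-1] - 1))
  }
  counts <- do.call(rbind, counts_l)
  fm <- do.call(rbind, maps_l)
  dimnames(counts) <- list(fm$feature_id, colnames(gene_counts$counts))
  feature_counts(counts, fm, level = "exon")
}

#' Simulate six correlated meat-quality traits
#'
#' Traits are linear combinations of one latent factor (the mean
#' variance-stabilized expression of the planted DEG genes), a per-trait
#' year-of-birth effect, and independent noise, mapped onto realistic
#' scales: marbling score (100-999), Warner-Bratzler shear force (kg),
#' cooking loss (%), and sensory juiciness / tenderness / connective
#' tissue (1-8). Shear force and cooking loss load negatively on the
#' quality factor; sensory traits positively.
#'
#' @inheritParams simulate_expression
#' @param gene_counts Gene-level [feature_counts()].
#' @return `data.frame` with `animal_id`, the six traits, `year_of_birth`
#'   and `breed_group`.
#' @export
simulate_phenotypes <- function(gene_counts, genotypes, truth, config,
                                seed = config$seed) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "truth_table"))
  set.seed(seed)
  n <- ncol(gene_counts$counts)
  deg <- intersect(truth$deg_genes, rownames(gene_counts$counts))
  latent <- if (length(deg) && config$deg_pheno_weight > 0) {
    v <- vst_transform(gene_counts)$values[deg, , drop = FALSE]
    m <- colMeans(v)
    if (sd(m) > 0) as.numeric(scale(m)) else rep(0, n)
  } else rep(0, n)
  yr <- as.numeric(genotypes$animals$year == max(genotypes$animals$year))
  loads <- c(marbling = 0.9, wbsf = -1.0, cooking_loss = -0.7,
             juiciness = 0.8, tenderness = 1.0, connective_tissue = 0.8)
  ycoef <- rnorm(6, 0, config$year_effect_sd)
  z <- sapply(seq_along(loads), function(k)
    config$deg_pheno_weight * loads[k] * latent + ycoef[k] * yr +
      rnorm(n, 0, config$pheno_noise_sd))
  out <- data.frame(
    animal_id = colnames(gene_counts$counts),
    marbling = clip(round(500 + 120 * z[, 1]), 100, 999),
    wbsf = clip(round(3.8 + 0.9 * z[, 2], 2), 1.2, 9),
    cooking_loss = clip(round(20 + 2.5 * z[, 3], 2), 5, 40),
    juiciness = clip(round(4.5 + 1.1 * z[, 4], 2), 1, 8),
    tenderness = clip(round(4.5 + 1.1 * z[, 5], 2), 1, 8),
    connective_tissue = clip(round(4.5 + 1.1 * z[, 6], 2), 1, 8),
    year_of_birth = genotypes$animals$year,
    breed_group = genotypes$animals$breed_group)
  rownames(out) <- NULL
  out
}

#' Simulate a complete dataset with known truth
#'
#' Runs the four generators in order (genotypes, gene models + planted
#' truth, gene counts, exon counts, phenotypes) with seeds derived from
#' `seed` (offsets 0-4), so the whole bundle is reproducible from one
#' integer.
#'
#' @inheritParams simulate_genotypes
#' @return List with `genotypes`, `gene_models`, `truth`, `gene_counts`,
#'   `exon_counts`, `phenotypes`, and the `config` used.
#' @export
simulate_dataset <- function(config, seed = config$seed) {
  genotypes <- simulate_genotypes(config, seed)
  gene_models <- simulate_gene_models(config, seed + 1L)
  truth <- plant_truth(genotypes, gene_models, config, seed + 2L)
  gene_counts <- simulate_expression(genotypes, gene_models, truth, config,
                                     seed + 3L)
  exon_counts <- simulate_exon_counts(gene_counts, genotypes, gene_models,
                                      truth, config, seed + 4L)
  phenotypes <- simulate_phenotypes(gene_counts, genotypes, truth, config,
                                    seed + 5L)
  list(genotypes = genotypes, gene_models = gene_models, truth = truth,
       gene_counts = gene_counts, exon_counts = exon_counts,
       phenotypes = phenotypes, config = config)
}
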