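#' Pipeline configuration
#'
#' Flat list of every threshold the pipeline applies, with defaults at the
#' analysis' standard values: MAF >= 3% and call rate >= 0.9 genotype QC,
#' features with fewer than 10 total counts removed, DEG calling at nominal
#' p < 0.05 (>= 3 exons for the exon-aggregated call), final trans
#' thresholds 1e-5 (eQTL) and 1e-6 (sQTL), cis eQTL thresholds from
#' per-gene simpleM Bonferroni correction, final cis sQTL threshold 2e-4,
#' hotspots at >= 20 targets, 1 Mb cis window, simpleM variance fraction
#' 0.995 in blocks of 133 SNPs, and 80 extreme animals selected of 120.
#'
#' @param maf_min,call_rate_min Genotype QC thresholds.
#' @param min_total_counts Low-count feature filter.
#' @param n_select Animals kept after extreme-index selection.
#' @param deg_alpha,deg_min_exons DEG calling parameters.
#' @param trans_p_eqtl,trans_p_sqtl Final trans p-value cutoffs.
#' @param cis_p_sqtl Final cis sQTL cutoff.
#' @param cis_alpha Per-gene family-wise level for cis eQTL thresholds.
#' @param hotspot_min Minimum targets for a hotspot.
#' @param cis_window Cis window (bp).
#' @param meff_variance_fraction,meff_block simpleM parameters.
#' @param cluster_window Hotspot clustering window (bp).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(maf_min = 0.03, call_rate_min = 0.9,
                            min_total_counts = 10, n_select = 80,
                            deg_alpha = 0.05, deg_min_exons = 3,
                            trans_p_eqtl = 1e-5, trans_p_sqtl = 1e-6,
                            cis_p_sqtl = 2e-4, cis_alpha = 0.05,
                            hotspot_min = 20, cis_window = 1e6,
                            meff_variance_fraction = 0.995, meff_block = 133,
                            cluster_window = 1e6) {
  cfg <- as.list(environment())
  stopifnot(maf_min >= 0, maf_min <= 1, call_rate_min >= 0, call_rate_min <= 1,
            min_total_counts >= 0, deg_alpha > 0, deg_alpha < 1,
            trans_p_eqtl > 0, trans_p_sqtl > 0, cis_p_sqtl > 0,
            hotspot_min >= 1, cis_window >= 0)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full eQTL/sQTL mapping pipeline
#'
#' Executes, in order: genotype QC, structure PCA, meat-quality index and
#' extreme-animal selection, low-count filtering, TMM normalization and
#' robust-regression DEG calling, simpleM thresholds (genome-wide and
#' per-gene cis), the VST eQTL scan, the exon-usage sQTL scan, hotspot
#' detection with clustering and master-regulator assignment, and network
#' export. Every stage logs the thresholds it applied. When `outdir` is
#' given, each stage writes its artifact (TSV/CSV/JSON).
#'
#' @param data List with `genotypes`, `gene_models`, `gene_counts`,
#'   `exon_counts`, `phenotypes` (e.g. from [simulate_dataset()]), and
#'   optionally `external_deg` (gene ids merged into the DEG set).
#' @param config A [pipeline_config()].
#' @param outdir Optional output directory.
#' @return List with every stage result and a `summary` of per-class QTL
#'   counts and percentages.
#' @export
run_pipeline <- function(data, config = pipeline_config(), outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  need <- c("genotypes", "gene_models", "gene_counts", "exon_counts",
            "phenotypes")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing pipeline inputs: ", paste(miss, collapse = ", "))
  log_stage <- function(...) message("[meatqtl] ", sprintf(...))

  # 1. genotype QC
  qc <- filter_snps(data$genotypes, maf_min = config$maf_min,
                    call_rate_min = config$call_rate_min)
  log_stage("QC: %d of %d SNPs retained (MAF >= %g, call rate >= %g)",
            ncol(qc$genotypes$dosage), ncol(data$genotypes$dosage),
            config$maf_min, config$call_rate_min)

  # 2. meat-quality index on all phenotyped animals, then extreme selection
  idx <- compute_index(data$phenotypes)
  sel <- select_extremes(idx$index, n_select = config$n_select)
  log_stage("index: %d animals indexed, %d extremes selected",
            length(idx$index), length(sel))

  # 3. subset everything to the selected animals
  geno <- genotype_data(qc$genotypes$dosage[sel, , drop = FALSE],
                        qc$genotypes$snp_map,
                        animals = if (!is.null(qc$genotypes$animals))
                          qc$genotypes$animals[
                            match(sel, qc$genotypes$animals$animal_id), ,
                            drop = FALSE])
  pca <- genotype_pca(geno)
  log_stage("structure PCA: PC1 explains %.1f%% of genotype variance",
            100 * pca$explained_variance_fraction[1])
  pheno <- data$phenotypes[match(sel, data$phenotypes$animal_id), , drop = FALSE]
  year <- factor(pheno$year_of_birth)
  pc1 <- pca$pc1
  gcounts <- feature_counts(data$gene_counts$counts[, sel, drop = FALSE],
                            data$gene_counts$feature_map, level = "gene")
  ecounts <- feature_counts(data$exon_counts$counts[, sel, drop = FALSE],
                            data$exon_counts$feature_map, level = "exon")

  # 4. low-count filtering
  gcounts <- filter_low_counts(gcounts, config$min_total_counts)
  ecounts <- filter_low_counts(ecounts, config$min_total_counts)
  log_stage("count filter (< %d total removed): %d genes, %d exons kept",
            config$min_total_counts, nrow(gcounts$counts), nrow(ecounts$counts))

  # 5. DEG branch: TMM-normalized log2 expression, Huber regression
  tmm <- tmm_factors(gcounts)
  gexpr_deg <- log2(sweep(gcounts$counts, 2, tmm, "/") + 1)
  eexpr_deg <- log2(sweep(ecounts$counts, 2,
                          tmm[colnames(ecounts$counts)], "/") + 1)
  iv <- idx$index[sel]
  deg_gene <- deg_scan(gexpr_deg, iv, year = year, pc1 = pc1,
                       alpha = config$deg_alpha)
  deg_exon <- deg_scan(eexpr_deg, iv, year = year, pc1 = pc1,
                       alpha = config$deg_alpha)
  degs <- call_degs(deg_gene, deg_exon, ecounts$feature_map,
                    min_exons = config$deg_min_exons,
                    extra_deg = if (!is.null(data$external_deg))
                      data$external_deg else character(0))
  log_stage("DEG: %d genes (p < %g at gene level or >= %d exons)",
            length(degs$deg_genes), config$deg_alpha, config$deg_min_exons)

  # 6. multiple-testing correction
  meff <- genomewide_meff(geno, block_size = config$meff_block,
                          variance_fraction = config$meff_variance_fraction)
  trans_bonf <- bonferroni_threshold(meff, alpha = config$cis_alpha)
  cis_thr <- per_gene_cis_thresholds(
    geno, data$gene_models, window = config$cis_window,
    alpha = config$cis_alpha,
    variance_fraction = config$meff_variance_fraction)
  log_stage(paste("simpleM: %d of %d effective tests; Bonferroni trans",
                  "threshold %.3g (final thresholds used: eQTL %g, sQTL %g)"),
            as.integer(meff), attr(meff, "n_tests"), trans_bonf,
            config$trans_p_eqtl, config$trans_p_sqtl)

  # 7. eQTL scan on VST gene expression
  gvst <- vst_transform(gcounts)
  eqtl <- qtl_scan(geno, gvst, data$gene_models, deg_genes = degs$deg_genes,
                   trans_threshold = config$trans_p_eqtl,
                   cis_thresholds = cis_thr, year = year, pc1 = pc1,
                   cis_window = config$cis_window)
  log_stage("eQTL scan: %d associations retained", nrow(eqtl))

  # 8. sQTL scan on VST exon-usage fractions
  frac <- exon_fraction_counts(ecounts, gcounts)
  svst <- vst_transform(frac)
  sqtl <- qtl_scan(geno, svst, data$gene_models, deg_genes = degs$deg_genes,
                   trans_threshold = config$trans_p_sqtl,
                   cis_thresholds = config$cis_p_sqtl, year = year, pc1 = pc1,
                   cis_window = config$cis_window)
  log_stage("sQTL scan: %d associations retained", nrow(sqtl))

  # 9. hotspots, clusters, master regulators, networks
  ehot <- detect_hotspots(eqtl, min_targets = config$hotspot_min,
                          level = "gene")
  ehot <- cluster_hotspots(ehot, window = config$cluster_window)
  ehot <- assign_master_regulator(ehot, data$gene_models)
  shot <- detect_hotspots(sqtl, min_targets = config$hotspot_min,
                          level = "exon")
  shot <- cluster_hotspots(shot, window = config$cluster_window)
  shot <- assign_master_regulator(shot, data$gene_models)
  log_stage("hotspots (>= %d targets): %d expression, %d splicing",
            config$hotspot_min, nrow(ehot), nrow(shot))
  enet <- export_network(ehot, eqtl, level = "gene")
  snet <- export_network(shot, sqtl, level = "exon")

  cls <- c("cis", "trans", "DEG cis", "DEG trans")
  count_classes <- function(r) {
    n <- vapply(cls, function(k) sum(r$class == k), integer(1))
    list(counts = as.list(n), total = nrow(r),
         pct = as.list(if (nrow(r)) round(100 * n / nrow(r), 1) else n * 0))
  }
  summary <- list(
    n_snps_post_qc = ncol(geno$dosage),
    n_animals = length(sel),
    n_genes = nrow(gcounts$counts), n_exons = nrow(ecounts$counts),
    n_deg_genes = length(degs$deg_genes),
    m_eff = as.integer(meff), bonferroni_trans = trans_bonf,
    thresholds = list(trans_p_eqtl = config$trans_p_eqtl,
                      trans_p_sqtl = config$trans_p_sqtl,
                      cis_p_sqtl = config$cis_p_sqtl,
                      cis_eqtl = "per-gene simpleM Bonferroni"),
    eqtl = count_classes(eqtl), sqtl = count_classes(sqtl),
    n_expression_hotspots = nrow(ehot), n_splicing_hotspots = nrow(shot))

  out <- list(qc_report = qc$report, index = idx, selected = sel, pca = pca,
              tmm = tmm, deg = degs, meff = meff,
              cis_thresholds = cis_thr, eqtl = eqtl, sqtl = sqtl,
              expression_hotspots = ehot, splicing_hotspots = shot,
              expression_network = enet, splicing_network = snet,
              summary = summary, config = config)

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(df, nm) write.table(df, file.path(outdir, nm), sep = "\t",
                                       quote = FALSE, row.names = FALSE)
    wt(qc$report, "qc_report.tsv")
    write.table(data.frame(animal_id = names(idx$index),
                           idx$scores[, 1:3], index = idx$index,
                           selected = names(idx$index) %in% sel),
                file.path(outdir, "quality_index.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    wt(degs$gene_table, "deg_genes.tsv")
    writeLines(degs$deg_genes, file.path(outdir, "deg_gene_list.txt"))
    wt(cbind(scope = "genome",
             data.frame(n_tests = attr(meff, "n_tests"),
                        m_eff = as.integer(meff), threshold = trans_bonf)),
       "meff_genome.tsv")
    wt(cis_thr, "meff_cis_by_gene.tsv")
    wt(as.data.frame(eqtl), "eqtl_records.tsv")
    wt(as.data.frame(sqtl), "sqtl_records.tsv")
    wt(ehot, "expression_hotspots.tsv")
    wt(shot, "splicing_hotspots.tsv")
    export_network(ehot, eqtl, level = "gene", dir = outdir,
                   prefix = "expression_network")
    export_network(shot, sqtl, level = "exon", dir = outdir,
                   prefix = "splicing_network")
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}
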