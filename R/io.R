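#' Read genotypes from VCF or dosage TSV + map
#'
#' VCF: dosages from the GT field (`0/0` -> 0, `0/1` or `1/0` -> 1,
#' `1/1` -> 2, `./.` -> missing; phased separators accepted); multiallelic
#' sites are skipped with a message. TSV: an animals x SNPs dosage table
#' plus a 3-column map file (`snp_id`, `chrom`, `pos`, 1-based).
#'
#' @param path VCF path (or dosage TSV path for `format = "tsv"`).
#' @param format `"vcf"` or `"tsv"`.
#' @param map_path SNP map TSV path (required for `format = "tsv"`).
#' @return A [genotype_data()].
#' @export
read_genotypes <- function(path, format = c("vcf", "tsv"), map_path = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    if (is.null(map_path)) stop("map_path is required for tsv genotypes")
    d <- as.matrix(read.delim(path, row.names = 1, check.names = FALSE))
    map <- read.delim(map_path)
    return(genotype_data(d, map))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi))
    message(sum(multi), " multiallelic site(s) skipped")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  code <- function(g) {
    g <- gsub("|", "/", g, fixed = TRUE)
    out <- rep(NA_integer_, length(g))
    out[g == "0/0"] <- 0L
    out[g %in% c("0/1", "1/0")] <- 1L
    out[g == "1/1"] <- 2L
    bad <- !is.na(g) & !(g %in% c("0/0", "0/1", "1/0", "1/1", "./."))
    if (any(bad)) stop("malformed GT value(s): ",
                       paste(utils::head(unique(g[bad])), collapse = ", "))
    out
  }
  dosage <- apply(gt, 2, code)
  dosage <- matrix(dosage, nrow = nrow(gt),
                   dimnames = list(fix[, "ID"], colnames(gt)))
  genotype_data(t(dosage),
                data.frame(snp_id = fix[, "ID"], chrom = fix[, "CHROM"],
                           pos = as.integer(fix[, "POS"])))
}

#' Write genotypes as an unphased VCF (GT field only)
#'
#' Placeholder REF/ALT alleles (A/G) are used: only the genotype calls and
#' the map carry information for the association analysis.
#'
#' @param genotypes A [genotype_data()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(genotypes, path) {
  map <- genotypes$snp_map
  d <- genotypes$dosage
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  body <- vapply(seq_len(nrow(map)), function(j) {
    g <- d[, j]
    gt <- ifelse(is.na(g), "./.", gt_code[as.character(g)])
    paste(c(map$chrom[j], map$pos[j], map$snp_id[j], "A", "G", ".", "PASS",
            ".", "GT", gt), collapse = "\t")
  }, character(1))
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(d)), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write the SNP map as TSV
#' @param genotypes A [genotype_data()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_snp_map <- function(genotypes, path) {
  write.table(genotypes$snp_map, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write genotype dosages as TSV (animals x SNPs)
#' @inheritParams write_snp_map
#' @export
write_genotype_tsv <- function(genotypes, path) {
  write.table(genotypes$dosage, path, sep = "\t", quote = FALSE,
              col.names = NA)
  invisible(path)
}

#' Read or write gene models as GFF3
#'
#' Gene models travel as GFF3 `gene` features (1-based inclusive, the GFF
#' convention, matching the package's internal coordinates) with `ID` and
#' an `n_exons` attribute.
#'
#' @param gene_models `data.frame` with `gene_id`, `chrom`, `start`, `end`,
#'   `n_exons`.
#' @param path File path.
#' @return `read_gene_models_gff3` returns the gene-model `data.frame`.
#' @export
write_gene_models_gff3 <- function(gene_models, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = gene_models$chrom,
    ranges = IRanges::IRanges(gene_models$start, gene_models$end),
    type = "gene", ID = gene_models$gene_id,
    n_exons = gene_models$n_exons)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_gene_models_gff3
#' @export
read_gene_models_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  out <- data.frame(gene_id = as.character(gr$ID),
                    chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr),
                    n_exons = if (!is.null(gr$n_exons))
                      as.integer(gr$n_exons) else NA_integer_)
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Convert between BED intervals and 1-based gene models
#'
#' BED is 0-based half-open; internal gene models are 1-based inclusive.
#' The two converters are exact inverses on valid records:
#' `start_1based = start_bed + 1`, `end_1based = end_bed`.
#'
#' @param bed `data.frame` with columns `chrom`, `start`, `end`, `name`.
#' @param gene_models Internal gene-model `data.frame`.
#' @return The converted `data.frame`.
#' @export
bed_to_gene_models <- function(bed) {
  data.frame(gene_id = bed$name, chrom = bed$chrom,
             start = bed$start + 1L, end = bed$end,
             n_exons = if ("n_exons" %in% names(bed)) bed$n_exons
             else NA_integer_)
}

#' @rdname bed_to_gene_models
#' @export
gene_models_to_bed <- function(gene_models) {
  data.frame(chrom = gene_models$chrom, start = gene_models$start - 1L,
             end = gene_models$end, name = gene_models$gene_id)
}

#' Read or write a BED4 file
#' @param path File path.
#' @param bed `data.frame` with `chrom`, `start`, `end`, `name`.
#' @return `read_bed` returns the BED `data.frame`.
#' @export
read_bed <- function(path) {
  out <- read.delim(path, header = FALSE)
  names(out)[1:4] <- c("chrom", "start", "end", "name")
  out
}

#' @rdname read_bed
#' @export
write_bed <- function(bed, path) {
  write.table(bed[, c("chrom", "start", "end", "name")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read or write a count matrix as TSV
#'
#' Counts are stored features x animals with the feature id in the first
#' column. On read, feature coordinates are joined from gene models (exon
#' ids of the form `geneid:exonNNN` inherit the parent gene's record).
#'
#' @param counts A [feature_counts()].
#' @param path File path.
#' @param gene_models Gene-model `data.frame` for the coordinate join.
#' @param level `"gene"` or `"exon"`.
#' @return `read_counts_tsv` returns a [feature_counts()].
#' @export
write_counts_tsv <- function(counts, path) {
  write.table(counts$counts, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path, gene_models, level = c("gene", "exon")) {
  level <- match.arg(level)
  m <- as.matrix(read.delim(path, row.names = 1, check.names = FALSE))
  gene_of <- if (level == "exon") sub(":exon[0-9]+$", "", rownames(m))
  else rownames(m)
  i <- match(gene_of, gene_models$gene_id)
  if (anyNA(i))
    stop("features with unknown genes: ",
         paste(utils::head(rownames(m)[is.na(i)]), collapse = ", "))
  fm <- data.frame(feature_id = rownames(m), gene_id = gene_of,
                   chrom = gene_models$chrom[i],
                   start = gene_models$start[i], end = gene_models$end[i])
  feature_counts(m, fm, level = level)
}

#' Read or write the phenotype table as CSV
#' @param phenotypes Phenotype `data.frame` (see [simulate_phenotypes()]).
#' @param path File path.
#' @return `read_phenotypes_csv` returns the phenotype `data.frame`.
#' @export
write_phenotypes_csv <- function(phenotypes, path) {
  write.csv(phenotypes, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes_csv
#' @export
read_phenotypes_csv <- function(path) {
  out <- read.csv(path)
  out$animal_id <- as.character(out$animal_id)
  out
}

#' Write a planted-truth table as TSVs
#'
#' One file per truth component (`<prefix>_cis.tsv`, `_hotspots.tsv`,
#' `_hotspot_targets.tsv`, `_sqtl.tsv`, `_deg_genes.txt`).
#'
#' @param truth A `truth_table` from [plant_truth()].
#' @param dir Output directory.
#' @param prefix File prefix (default `"truth"`).
#' @return The directory, invisibly.
#' @export
write_truth <- function(truth, dir, prefix = "truth") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, nm) write.table(df, file.path(dir, paste0(prefix, nm)),
                                    sep = "\t", quote = FALSE, row.names = FALSE)
  w(truth$planted_cis, "_cis.tsv")
  w(truth$planted_hotspots, "_hotspots.tsv")
  w(truth$hotspot_targets, "_hotspot_targets.tsv")
  w(truth$planted_sqtl, "_sqtl.tsv")
  writeLines(truth$deg_genes, file.path(dir, paste0(prefix, "_deg_genes.txt")))
  invisible(dir)
}
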