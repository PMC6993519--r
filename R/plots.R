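#' QTL map scatter plot
#'
#' Plots each retained association at (SNP genomic position, regulated
#' gene's genomic position) with point size scaled by significance
#' (-log10 p) and color by class -- the standard genome-vs-genome QTL map
#' on which the cis diagonal and trans hotspot columns are visible.
#'
#' @param records A `qtl_records` table from [qtl_scan()].
#' @param gene_models Gene models (for chromosome offsets).
#' @param snp_map SNP map (for chromosome offsets); defaults to the
#'   chromosomes present in `records`.
#' @param main Plot title.
#' @return Invisibly, the data.frame of plotted coordinates.
#' @export
plot_qtl_map <- function(records, gene_models, snp_map = NULL,
                         main = "QTL map") {
  chroms <- sort(unique(c(gene_models$chrom, records$snp_chrom)))
  span <- vapply(chroms, function(ch)
    max(gene_models$end[gene_models$chrom == ch],
        records$snp_pos[records$snp_chrom == ch], 1), numeric(1))
  offset <- setNames(cumsum(c(0, span[-length(span)])), chroms)
  gx <- gene_models[match(records$gene_id, gene_models$gene_id), ]
  df <- data.frame(
    x = offset[records$snp_chrom] + records$snp_pos,
    y = offset[gx$chrom] + (gx$start + gx$end) / 2,
    class = records$class,
    cex = 0.3 + 0.25 * pmin(-log10(pmax(records$p, 1e-30)), 20) / 5)
  pal <- c(cis = "#1b9e77", trans = "#7570b3", `DEG cis` = "#d95f02",
           `DEG trans` = "#e7298a")
  graphics::plot(df$x, df$y, pch = 16, cex = df$cex, col = pal[df$class],
                 xlab = "SNP position (concatenated genome)",
                 ylab = "gene position (concatenated genome)", main = main)
  graphics::abline(v = cumsum(span), h = cumsum(span),
                   col = "grey85", lty = 3)
  graphics::legend("topleft", legend = names(pal), col = pal, pch = 16,
                   cex = 0.8, bg = "white")
  invisible(df)
}
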