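#' Detect trans hotspots
#'
#' A hotspot is a SNP trans-associated with at least `min_targets` distinct
#' regulated genes (eQTL mode) or distinct exons (sQTL mode). Only trans
#' records (including DEG trans) count; the DEG percentage is
#' `100 * DEG targets / targets`.
#'
#' @param records A `qtl_records` table from [qtl_scan()].
#' @param min_targets Minimum distinct targets (default 20).
#' @param level `"gene"` (count distinct regulated genes) or `"exon"`
#'   (count distinct regulated exons).
#' @return `data.frame` of class `hotspots`: `snp_id`, `chrom`, `pos`,
#'   `n_targets`, `pct_deg`, sorted by genome position.
#' @export
detect_hotspots <- function(records, min_targets = 20,
                            level = c("gene", "exon")) {
  level <- match.arg(level)
  tr <- records[records$location_class == "trans", , drop = FALSE]
  tgt_col <- if (level == "gene") "gene_id" else "feature_id"
  empty <- data.frame(snp_id = character(0), chrom = character(0),
                      pos = integer(0), n_targets = integer(0),
                      pct_deg = numeric(0))
  if (!nrow(tr)) return(structure(empty, class = c("hotspots", "data.frame")))
  key <- paste(tr$snp_id, tr[[tgt_col]])
  tr <- tr[!duplicated(key), , drop = FALSE]        # distinct targets per SNP
  n_tgt <- tapply(tr[[tgt_col]], tr$snp_id, length)
  n_deg <- tapply(tr$deg_class == "DEG", tr$snp_id, sum)
  pos <- tapply(tr$snp_pos, tr$snp_id, `[`, 1)
  chrom <- tapply(tr$snp_chrom, tr$snp_id, `[`, 1)
  out <- data.frame(snp_id = names(n_tgt), chrom = as.character(chrom),
                    pos = as.integer(pos), n_targets = as.integer(n_tgt),
                    pct_deg = 100 * as.numeric(n_deg) / as.numeric(n_tgt))
  out <- out[out$n_targets >= min_targets, , drop = FALSE]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("hotspots", "data.frame"))
}

#' Cluster nearby hotspot SNPs
#'
#' Single-linkage positional clustering: consecutive hotspot SNPs on the
#' same chromosome at most `window` bp apart share a cluster. Clusters are
#' numbered in genome order from 1. The result is invariant under input
#' row order.
#'
#' @param hotspots A `hotspots` table from [detect_hotspots()].
#' @param window Maximum gap joining two hotspots (default 1e6 bp).
#' @return The table with a `cluster_id` column, sorted by genome position.
#' @export
cluster_hotspots <- function(hotspots, window = 1e6) {
  h <- hotspots[order(hotspots$chrom, hotspots$pos), , drop = FALSE]
  if (!nrow(h)) {
    h$cluster_id <- integer(0)
    return(h)
  }
  newc <- c(TRUE, h$chrom[-1] != h$chrom[-nrow(h)] |
              diff(h$pos) > window)
  h$cluster_id <- cumsum(newc)
  rownames(h) <- NULL
  h
}

#' Assign master-regulator genes to hotspots
#'
#' The hotspot's putative master regulator is the gene harboring the SNP
#' (position within the gene span); for an intergenic SNP both flanking
#' genes are reported with their distances and the nearer one is marked
#' primary (ties broken by lower start coordinate and flagged). A SNP on a
#' chromosome without genes is left unassigned.
#'
#' @param hotspots A `hotspots` table (optionally clustered).
#' @param gene_models `data.frame` with `gene_id`, `chrom`, `start`, `end`.
#' @return The table with `regulator_gene_id`, `regulator_assignment`
#'   (`"harboring"` / `"nearest-flanking"`), `flanking_genes`,
#'   `flanking_distances` (both `;`-separated), `tie` flag.
#' @export
assign_master_regulator <- function(hotspots, gene_models) {
  n <- nrow(hotspots)
  reg <- assign <- flank <- fdist <- rep(NA_character_, n)
  tie <- rep(FALSE, n)
  for (i in seq_len(n)) {
    gm <- gene_models[gene_models$chrom == hotspots$chrom[i], , drop = FALSE]
    if (!nrow(gm)) {
      message("hotspot ", hotspots$snp_id[i],
              ": no genes on its chromosome, regulator unassigned")
      next
    }
    pos <- hotspots$pos[i]
    inside <- gm$start <= pos & gm$end >= pos
    if (any(inside)) {
      cand <- gm[inside, , drop = FALSE]
      cand <- cand[order(cand$start), , drop = FALSE]
      reg[i] <- cand$gene_id[1]
      assign[i] <- "harboring"
      tie[i] <- nrow(cand) > 1
      next
    }
    up <- gm[gm$end < pos, , drop = FALSE]      # upstream in coordinate sense
    dn <- gm[gm$start > pos, , drop = FALSE]
    cand <- rbind(
      if (nrow(up)) up[which.max(up$end), , drop = FALSE],
      if (nrow(dn)) dn[which.min(dn$start), , drop = FALSE])
    d <- pmax(cand$start - pos, pos - cand$end)
    o <- order(d, cand$start)
    cand <- cand[o, , drop = FALSE]; d <- d[o]
    reg[i] <- cand$gene_id[1]
    assign[i] <- "nearest-flanking"
    flank[i] <- paste(cand$gene_id, collapse = ";")
    fdist[i] <- paste(d, collapse = ";")
    tie[i] <- length(d) == 2 && d[1] == d[2]
    if (tie[i])
      message("hotspot ", hotspots$snp_id[i],
              ": equidistant flanking genes, tie broken by start coordinate")
  }
  hotspots$regulator_gene_id <- reg
  hotspots$regulator_assignment <- assign
  hotspots$flanking_genes <- flank
  hotspots$flanking_distances <- fdist
  hotspots$tie <- tie
  hotspots
}

#' Export the regulator-target network
#'
#' Builds the bipartite edge list (master-regulator gene -> trans-regulated
#' target) underlying a regulator network figure, with node attributes, and
#' optionally writes it as TSV and SIF.
#'
#' @param hotspots A `hotspots` table with `regulator_gene_id` assigned.
#' @param records The `qtl_records` the hotspots were detected from.
#' @param level `"gene"` or `"exon"` target identity (as in
#'   [detect_hotspots()]).
#' @param dir Optional output directory; writes `<prefix>_edges.tsv`,
#'   `<prefix>_nodes.tsv` and `<prefix>.sif`.
#' @param prefix File name prefix (default `"network"`).
#' @return List with `edges` (`regulator`, `target`, `snp_id`) and `nodes`
#'   (`node`, `type`, `is_deg`, `is_master_regulator`), invisibly when
#'   writing.
#' @export
export_network <- function(hotspots, records, level = c("gene", "exon"),
                           dir = NULL, prefix = "network") {
  level <- match.arg(level)
  tgt_col <- if (level == "gene") "gene_id" else "feature_id"
  edges <- data.frame(regulator = character(0), target = character(0),
                      snp_id = character(0))
  deg_of <- character(0)
  if (nrow(hotspots)) {
    tr <- records[records$location_class == "trans" &
                    records$snp_id %in% hotspots$snp_id, , drop = FALSE]
    if (nrow(tr)) {
      reg <- setNames(hotspots$regulator_gene_id, hotspots$snp_id)
      key <- paste(tr$snp_id, tr[[tgt_col]])
      tr <- tr[!duplicated(key), , drop = FALSE]
      edges <- data.frame(regulator = unname(reg[tr$snp_id]),
                          target = tr[[tgt_col]], snp_id = tr$snp_id)
      deg_of <- unique(tr[[tgt_col]][tr$deg_class == "DEG"])
    }
  }
  nodes <- data.frame(node = unique(c(edges$regulator, edges$target)))
  nodes$type <- ifelse(nodes$node %in% edges$regulator, "regulator", "target")
  nodes$is_deg <- nodes$node %in% deg_of
  nodes$is_master_regulator <- nodes$node %in% edges$regulator
  out <- list(edges = edges, nodes = nodes)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write.table(edges, file.path(dir, paste0(prefix, "_edges.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(nodes, file.path(dir, paste0(prefix, "_nodes.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    sif <- if (nrow(edges))
      paste(edges$regulator, "regulates", edges$target) else character(0)
    writeLines(sif, file.path(dir, paste0(prefix, ".sif")))
    return(invisible(out))
  }
  out
}
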