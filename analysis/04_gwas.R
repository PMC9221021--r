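#!/usr/bin/env Rscript
# GWAS cell-type enrichment on the synthetic study: SNP-window gene
# association (+/- 500 kb, inclusive), human-to-mouse ortholog transfer
# (union of catalogs, deduplicated), 25+0 expression binning per population,
# one-sided Welch enrichment of SNP-gene bins, top-20th-percentile gene sets
# and their overlap with the DEG calls.
#
# Usage: Rscript analysis/04_gwas.R   (after 02_differential.R)

library(cregrammar)

dir <- "results/synthetic"
genes <- read_tsv(file.path(dir, "genes.tsv"))
snps <- read_tsv(file.path(dir, "snps.tsv"))
orthologs <- read_tsv(file.path(dir, "orthologs.tsv"))
expr <- read_counts(file.path(dir, "expr"))
labels <- read_tsv(file.path(dir, "labels.tsv"))

pops <- unique(labels$population)
mean_expr <- t(vapply(pops, function(pop) {
  Matrix::rowMeans(expr[, labels$barcode[labels$population == pop],
                        drop = FALSE])
}, numeric(nrow(expr))))
rownames(mean_expr) <- pops
bins <- bin_expression(mean_expr)

# SNP windows are defined on the human annotation (HS_ prefix), then
# transferred to mouse gene ids through the ortholog union
human_genes <- transform(genes, gene_id = paste0("HS_", gene_id))
sm <- snp_to_genes(snps, human_genes, window_bp = 5e5)
mapped <- map_orthologs(unique(sm$pairs$gene_id), orthologs)
cat(sprintf("%d SNPs -> %d human genes in windows; %d mapped to mouse, %d unmapped\n",
            length(sm$snp_ids), length(unique(sm$pairs$gene_id)),
            length(mapped$mouse_genes), length(mapped$unmapped)))

enrich <- welch_cluster_enrichment(bins, mapped$mouse_genes)
write_tsv(enrich, "results/gwas_enrichment.tsv")
print(enrich)

# top-20th-percentile SNP-gene sets per cluster (on mouse ids)
sm_mouse <- sm
sm_mouse$pairs <- merge(sm$pairs, mapped$pairs,
                        by.x = "gene_id", by.y = "human_gene")
sm_mouse$pairs <- data.frame(snp_id = sm_mouse$pairs$snp_id,
                             gene_id = sm_mouse$pairs$mouse_gene,
                             distance = sm_mouse$pairs$distance)
tp <- top_percentile_sets(bins, sm_mouse, pct = 20)
for (cl in names(tp$gene_sets))
  cat(sprintf("%s: %d SNP-associated genes in the top 20th percentile\n",
              cl, length(tp$gene_sets[[cl]])))
write_tsv(data.frame(snp_id = rownames(tp$snp_flags), tp$snp_flags),
          "results/snp_flags.tsv")

# overlap of the DEG calls with the top-percentile sets
deg_sets <- list()
for (pop in pops) {
  degs <- read_tsv(sprintf("results/degs_%s.tsv", pop))
  for (d in c("up", "down"))
    deg_sets[[paste(pop, d, sep = "_")]] <-
      degs$feature_id[degs$direction == d]
}
universe <- rownames(expr)[Matrix::rowSums(expr) > 0]
ov <- deg_overlap_enrichment(deg_sets, tp$gene_sets, universe)
write_tsv(ov, "results/deg_top_overlap.tsv")
cat("DEG x top-percentile overlaps written to results/deg_top_overlap.tsv\n")
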