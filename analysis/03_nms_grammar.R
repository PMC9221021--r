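#!/usr/bin/env Rscript
# Focal-motif scoring and grammar networks on the synthetic study:
# PWM scan at the exact p < 1e-4 threshold, normalized motif scores
# NMS = (A x O / L) x 10,000 per population, focal-motif CRE selection at
# direction-matched DEGs, per-family colocalization rates, co-occurrence
# correlation matrices, spectral communities, and the up-vs-down contrast.
#
# Usage: Rscript analysis/03_nms_grammar.R   (after 02_differential.R)

library(cregrammar)

dir <- "results/synthetic"
seqs <- read_fasta(file.path(dir, "peaks.fasta"))
pwms <- read_meme(file.path(dir, "motifs.meme"))
fam_tab <- read_tsv(file.path(dir, "family_map.tsv"))
familymap <- family_map(fam_tab$motif_id, fam_tab$family, fam_tab$tf_gene)
peaks <- read_bed(file.path(dir, "peaks.bed"))
peaks_ct <- read_counts(file.path(dir, "peaks"))
expr <- read_counts(file.path(dir, "expr"))
labels <- read_tsv(file.path(dir, "labels.tsv"))
links_tab <- read_tsv("results/peak_gene_links.tsv")
links <- structure(list(links = links_tab, domain_of = integer()),
                   class = "region_gene_links")

focal <- "PITX2.syn"
hits <- scan_peaks(seqs, pwms, alpha = 1e-4)
hm <- build_hit_matrix(hits, peaks, familymap)
cat(sprintf("scan: %d hits over %d peaks; %d peaks carry the focal motif\n",
            nrow(hits), nrow(peaks), sum(hm$occurrences[, focal] > 0)))

for (pop in unique(labels$population)) {
  nuclei <- labels$barcode[labels$population == pop]
  A <- pseudobulk_accessibility(peaks_ct, nuclei)
  nms <- compute_nms(A, hm, focal, peaks, population = pop)
  write_tsv(nms, sprintf("results/nms_%s.tsv", pop))
  degs <- read_tsv(sprintf("results/degs_%s.tsv", pop))
  # expressed TFs: detected in >= 5% of the population's nuclei
  tf_genes <- intersect(familymap$map$tf_gene, rownames(expr))
  det <- Matrix::rowMeans(expr[tf_genes, nuclei, drop = FALSE] > 0)
  expressed <- names(det)[det >= 0.05]
  cat(sprintf("%s: %d active focal peaks; expressed TFs: %s\n", pop,
              sum(nms$active), paste(expressed, collapse = ", ")))
  grams <- list()
  for (d in c("up", "down")) {
    cres <- select_cres(nms, links, degs, d)
    cat(sprintf("  %s: %d CREs at %d %s-DEGs\n", d, length(cres$members),
                cres$n_degs_with_cre, d))
    if (length(cres$members) >= 3) {
      rates <- colocalization_rates(cres, hm, familymap, expressed)
      write_tsv(rates, sprintf("results/colocalization_%s_%s.tsv", pop, d))
      gram <- cooccurrence_correlation(cres$members, hm, familymap, expressed)
      write_matrix_tsv(gram$r, sprintf("results/grammar_%s_%s.tsv", pop, d))
      grams[[d]] <- gram
      if (length(setdiff(gram$families, gram$missing)) >= 2) {
        net <- tryCatch(spectral_communities(gram),
                        warning = function(w) NULL)
        if (!is.null(net)) {
          write_tsv(data.frame(family = net$nodes,
                               community = unname(net$communities)),
                    sprintf("results/communities_%s_%s.tsv", pop, d))
          cat(sprintf("    grammar network: %d communities, Q = %.3f\n",
                      net$n_communities, net$modularity))
        }
      }
    }
  }
  if (length(grams) == 2) {
    contrast <- differential_grammar(grams$up, grams$down)
    write_matrix_tsv(contrast, sprintf("results/grammar_contrast_%s.tsv", pop))
    ut <- which(upper.tri(contrast), arr.ind = TRUE)
    vals <- contrast[ut]
    ok <- which(!is.na(vals))
    top <- ut[ok[which.max(vals[ok])], ]
    cat(sprintf("  strongest up-vs-down contrast: %s-%s (delta r = %.3f)\n",
                rownames(contrast)[top[1]], colnames(contrast)[top[2]],
                max(vals[ok])))
  }
}
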