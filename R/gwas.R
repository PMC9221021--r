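# SNP-window gene association, ortholog transfer, binned-expression cell-type
# enrichment, top-percentile gene sets and DEG overlap.

#' Associate SNPs with genes whose TSS lies within a window
#'
#' A (snp, gene) pair is emitted iff `|TSS - pos| <= window_bp` (inclusive)
#' on the same chromosome. SNPs with no gene are retained with an empty
#' mapping.
#'
#' @param snps data.frame (snp_id, chrom, pos), 0-based positions.
#' @param genes data.frame (gene_id, chrom, tss).
#' @param window_bp half-window in bp (default 500,000).
#' @return object of class `snp_gene_map`: list with `pairs` (data.frame
#'   snp_id, gene_id, distance) and `snp_ids` (all SNPs, mapped or not).
#' @export
snp_to_genes <- function(snps, genes, window_bp = 5e5) {
  stopifnot(all(snps$pos >= 0), !anyDuplicated(snps$snp_id))
  rows <- lapply(seq_len(nrow(snps)), function(i) {
    sel <- genes$chrom == snps$chrom[i] &
      abs(genes$tss - snps$pos[i]) <= window_bp
    if (!any(sel)) return(NULL)
    data.frame(snp_id = snps$snp_id[i], gene_id = genes$gene_id[sel],
               distance = abs(genes$tss[sel] - snps$pos[i]),
               stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, rows)
  if (is.null(pairs))
    pairs <- data.frame(snp_id = character(), gene_id = character(),
                        distance = numeric(), stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$snp_id, pairs$gene_id), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, snp_ids = snps$snp_id, window_bp = window_bp),
            class = "snp_gene_map")
}

#' Map human genes to mouse orthologs (union of catalogs)
#'
#' All mouse partners of each human gene are kept (one-to-many preserved);
#' duplicate pairs contributed by multiple source catalogs are emitted once.
#'
#' @param human_genes character vector of human gene ids.
#' @param table data.frame (human_gene, mouse_gene[, source]).
#' @return list with `pairs` (deduplicated data.frame human_gene, mouse_gene),
#'   `mouse_genes` (unique mapped set) and `unmapped` (human genes without a
#'   partner).
#' @export
map_orthologs <- function(human_genes, table) {
  if (nrow(table) == 0) stop("empty ortholog table")
  tab <- unique(table[, c("human_gene", "mouse_gene")])
  hit <- tab[tab$human_gene %in% human_genes, , drop = FALSE]
  hit <- hit[order(hit$human_gene, hit$mouse_gene), , drop = FALSE]
  rownames(hit) <- NULL
  list(pairs = hit,
       mouse_genes = sort(unique(hit$mouse_gene)),
       unmapped = sort(setdiff(human_genes, tab$human_gene)))
}

#' Bin per-cluster gene expression into 25 equal-size bins plus a zero bin
#'
#' Per cluster: genes with mean expression exactly 0 get bin 0; the remaining
#' genes are ranked ascending by mean (ties broken by gene id) and split into
#' `n_bins` contiguous rank bins of equal size, the remainder going to the
#' lowest bins. Higher bin = higher expression. Binning depends only on ranks,
#' so any strictly monotone transform of the means leaves it unchanged.
#'
#' @param mean_expr cluster x gene numeric matrix (means >= 0) with dimnames.
#' @param n_bins number of nonzero bins (default 25).
#' @return cluster x gene integer matrix of bins in `0..n_bins`.
#' @export
bin_expression <- function(mean_expr, n_bins = 25) {
  stopifnot(all(mean_expr >= 0), !is.null(colnames(mean_expr)))
  out <- matrix(0L, nrow(mean_expr), ncol(mean_expr),
                dimnames = dimnames(mean_expr))
  for (cl in seq_len(nrow(mean_expr))) {
    mu <- mean_expr[cl, ]
    nz <- which(mu > 0)
    if (length(nz) == 0) {
      warning("cluster ", rownames(mean_expr)[cl],
              " has no expressed genes; all bins 0")
      next
    }
    ord <- nz[order(mu[nz], colnames(mean_expr)[nz])]
    n <- length(ord)
    base <- n %/% n_bins
    rem <- n %% n_bins
    sizes <- rep(base, n_bins)
    if (rem > 0) sizes[seq_len(rem)] <- base + 1L
    out[cl, ord] <- rep(seq_len(n_bins), times = sizes)
  }
  out
}

#' Per-cluster SNP-gene enrichment by one-sided Welch t-test
#'
#' Per cluster, bin values of SNP-associated genes are compared with those of
#' the remaining genes by a one-sided (greater) Welch two-sample t-test with
#' Welch-Satterthwaite degrees of freedom; BH FDR across clusters.
#' Zero-variance groups receive a variance floor `eps` so the statistic stays
#' finite (only degenerate synthetic inputs hit it).
#'
#' @param bins cluster x gene bin matrix from [bin_expression()].
#' @param snp_genes character vector of SNP-associated gene ids (post ortholog
#'   transfer).
#' @param eps variance floor per group.
#' @return data.frame (cluster, t, df, pvalue, fdr, n_snp_genes,
#'   n_background); clusters with < 2 genes in either group are skipped with a
#'   warning.
#' @export
welch_cluster_enrichment <- function(bins, snp_genes, eps = 1e-12) {
  in_set <- colnames(bins) %in% snp_genes
  res <- list()
  for (cl in rownames(bins)) {
    x <- bins[cl, in_set]
    y <- bins[cl, !in_set]
    if (length(x) < 2 || length(y) < 2) {
      warning("cluster ", cl, " skipped: fewer than 2 genes in a group")
      next
    }
    vx <- max(stats::var(x), eps)
    vy <- max(stats::var(y), eps)
    se2 <- vx / length(x) + vy / length(y)
    t <- (mean(x) - mean(y)) / sqrt(se2)
    df <- se2^2 / (vx^2 / (length(x)^2 * (length(x) - 1)) +
                     vy^2 / (length(y)^2 * (length(y) - 1)))
    p <- stats::pt(t, df, lower.tail = FALSE)
    res[[cl]] <- data.frame(cluster = cl, t = t, df = df, pvalue = p,
                            n_snp_genes = length(x),
                            n_background = length(y),
                            stringsAsFactors = FALSE)
  }
  if (!length(res))
    return(data.frame(cluster = character(), t = numeric(), df = numeric(),
                      pvalue = numeric(), fdr = numeric(),
                      n_snp_genes = integer(), n_background = integer()))
  out <- do.call(rbind, res)
  out$fdr <- stats::p.adjust(out$pvalue, method = "BH")
  out <- out[, c("cluster", "t", "df", "pvalue", "fdr", "n_snp_genes",
                 "n_background")]
  rownames(out) <- NULL
  out
}

#' Top-percentile SNP-associated gene sets per cluster
#'
#' Per cluster, SNP-associated genes whose bin exceeds
#' `n_bins * (1 - pct/100)` (default: bins 21-25 of 25 = top 20%); per SNP, a
#' flag per cluster when >= 1 of its genes qualifies.
#'
#' @param bins cluster x gene bin matrix.
#' @param snp_map a [snp_to_genes()] result; gene ids must match `bins`
#'   columns (i.e. after ortholog transfer).
#' @param pct top percentile retained (default 20).
#' @param n_bins the binning scheme's nonzero bin count (default 25).
#' @return list with `gene_sets` (per-cluster character vectors), `snp_flags`
#'   (snp x cluster logical matrix) and `cutoff_bin` (smallest qualifying
#'   bin).
#' @export
top_percentile_sets <- function(bins, snp_map, pct = 20, n_bins = 25) {
  cutoff <- n_bins * (1 - pct / 100)
  snp_genes <- unique(snp_map$pairs$gene_id)
  snp_genes <- intersect(snp_genes, colnames(bins))
  gene_sets <- lapply(rownames(bins), function(cl) {
    sort(snp_genes[bins[cl, snp_genes] > cutoff])
  })
  names(gene_sets) <- rownames(bins)
  flags <- matrix(FALSE, length(snp_map$snp_ids), nrow(bins),
                  dimnames = list(snp_map$snp_ids, rownames(bins)))
  for (cl in rownames(bins)) {
    qual <- gene_sets[[cl]]
    ok <- unique(snp_map$pairs$snp_id[snp_map$pairs$gene_id %in% qual])
    flags[ok, cl] <- TRUE
  }
  list(gene_sets = gene_sets, snp_flags = flags, cutoff_bin = floor(cutoff) + 1)
}

#' Enrichment of DEG sets among top-percentile SNP-associated genes
#'
#' Per (comparison, cluster): 2x2 over the universe, (in DEG set vs not) x
#' (in the cluster's top-percentile SNP gene set vs not), two-sided Fisher
#' exact test; BH FDR across all reported tests.
#'
#' @param deg_sets named list of gene sets (one per comparison/direction).
#' @param top_sets named list of per-cluster gene sets
#'   (`top_percentile_sets()$gene_sets`).
#' @param universe gene universe covering both.
#' @return data.frame (comparison, cluster, overlap, odds_ratio,
#'   odds_ratio_haldane, pvalue, fdr, computable).
#' @export
deg_overlap_enrichment <- function(deg_sets, top_sets, universe) {
  if (length(universe) == 0) stop("universe must be non-empty")
  universe <- unique(universe)
  rows <- list()
  for (cmp in names(deg_sets)) {
    degs <- intersect(deg_sets[[cmp]], universe)
    for (cl in names(top_sets)) {
      tops <- intersect(top_sets[[cl]], universe)
      a <- length(intersect(degs, tops))
      b <- length(setdiff(degs, tops))
      c_ <- length(setdiff(tops, degs))
      d <- length(universe) - a - b - c_
      ft <- fisher_exact_2x2(matrix(c(a, b, c_, d), 2, byrow = TRUE))
      rows[[paste(cmp, cl)]] <- data.frame(
        comparison = cmp, cluster = cl, overlap = a,
        odds_ratio = ft$odds_ratio,
        odds_ratio_haldane = ft$odds_ratio_haldane,
        pvalue = ft$pvalue, computable = ft$computable,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$pvalue, method = "BH")
  rownames(out) <- NULL
  out
}
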