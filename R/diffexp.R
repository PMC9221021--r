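# Wilcoxon differential expression/accessibility, composition chi-square
# tests, and DEG <-> DAR Fisher association.

#' Scale per-nucleus counts to counts-per-10k
#'
#' Each nucleus's counts are rescaled to a common total of 10,000. Nuclei with
#' zero total counts stay all-zero.
#'
#' @param counts feature x nucleus matrix (dense or `Matrix` sparse).
#' @return matrix of the same shape.
#' @export
normalize_cp10k <- function(counts, total = 1e4) {
  cs <- Matrix::colSums(counts)
  sf <- ifelse(cs > 0, total / cs, 0)
  if (inherits(counts, "Matrix")) {
    counts %*% Matrix::Diagonal(x = sf)
  } else {
    sweep(counts, 2, sf, `*`)
  }
}

# Two-sided rank-sum p-value. Exact enumeration over all C(n, nA) label
# assignments when n <= exact_max (valid with ties); tie-corrected normal
# approximation with continuity correction otherwise. Statistic W = rank sum
# of group A. "As extreme" = |W - E(W)| >= |W_obs - E(W)| under the
# permutation null.
rank_sum_test <- function(x, y, exact_max = 12) {
  nA <- length(x); nB <- length(y); n <- nA + nB
  r <- rank(c(x, y))
  W <- sum(r[seq_len(nA)])
  if (n <= exact_max) {
    combos <- utils::combn(n, nA)
    Wperm <- colSums(matrix(r[combos], nrow = nA))
    mu <- mean(Wperm)
    p <- mean(abs(Wperm - mu) >= abs(W - mu) - 1e-9)
    return(list(statistic = W, pvalue = p, exact = TRUE))
  }
  mu <- nA * (n + 1) / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  v <- nA * nB / 12 * ((n + 1) - tie_term)
  if (v <= 0) return(list(statistic = W, pvalue = 1, exact = FALSE))
  z <- (W - mu - sign(W - mu) * 0.5) / sqrt(v)
  list(statistic = W, pvalue = min(1, 2 * stats::pnorm(-abs(z))),
       exact = FALSE)
}

#' Call differential features between two nucleus groups (Wilcoxon)
#'
#' Per-nucleus counts are rescaled to counts-per-10k; each detected feature is
#' tested with the two-sided Wilcoxon rank-sum test (exact enumeration for
#' small groups, tie-corrected normal approximation otherwise); BH FDR across
#' tested features. `log2fc = log2((mean_A + 1) / (mean_B + 1))` on the
#' rescaled scale. A feature is `up` iff `log2fc > log2fc_min` and
#' `fdr < fdr_max` (strict), `down` symmetric, else `ns`.
#'
#' @param counts feature x nucleus count matrix with dimnames.
#' @param groupA,groupB disjoint nucleus (column) name sets, each >= 3.
#' @param log2fc_min,fdr_max direction thresholds (defaults 0.25, 0.01).
#' @param min_detect detection filter: tested iff detected (count > 0) in at
#'   least this fraction of nuclei of one group.
#' @param exact_max exact enumeration when nA + nB <= exact_max.
#' @return data.frame (feature_id, log2fc, pvalue, fdr, direction); features
#'   failing the detection filter are omitted.
#' @export
wilcoxon_markers <- function(counts, groupA, groupB, log2fc_min = 0.25,
                             fdr_max = 0.01, min_detect = 0.1,
                             exact_max = 12) {
  if (length(intersect(groupA, groupB)) > 0)
    stop("groups must be disjoint")
  if (length(groupA) < 3 || length(groupB) < 3)
    stop("each group must have at least 3 nuclei")
  missing <- setdiff(c(groupA, groupB), colnames(counts))
  if (length(missing))
    stop("nuclei absent from counts: ", paste(utils::head(missing, 3),
                                              collapse = ", "))
  m <- counts[, c(groupA, groupB), drop = FALSE]
  iA <- seq_along(groupA)
  iB <- length(groupA) + seq_along(groupB)
  detA <- Matrix::rowMeans(m[, iA, drop = FALSE] > 0)
  detB <- Matrix::rowMeans(m[, iB, drop = FALSE] > 0)
  keep <- which(detA >= min_detect | detB >= min_detect)
  norm <- as.matrix(normalize_cp10k(m))
  res <- lapply(keep, function(i) {
    xA <- norm[i, iA]; xB <- norm[i, iB]
    rt <- rank_sum_test(xA, xB, exact_max = exact_max)
    lfc <- log2((mean(xA) + 1) / (mean(xB) + 1))
    data.frame(feature_id = rownames(m)[i], log2fc = lfc,
               pvalue = rt$pvalue, stringsAsFactors = FALSE)
  })
  if (!length(res)) {
    return(data.frame(feature_id = character(), log2fc = numeric(),
                      pvalue = numeric(), fdr = numeric(),
                      direction = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out$fdr <- stats::p.adjust(out$pvalue, method = "BH")
  out$direction <- ifelse(out$log2fc > log2fc_min & out$fdr < fdr_max, "up",
                   ifelse(out$log2fc < -log2fc_min & out$fdr < fdr_max,
                          "down", "ns"))
  rownames(out) <- NULL
  out
}

#' Call differentially accessible regions between two nucleus groups
#'
#' Identical contract to [wilcoxon_markers()] applied to peak counts; the
#' thresholds default to the gene thresholds (log2FC > 0.25, FDR < 0.01) and
#' are configurable.
#'
#' @inheritParams wilcoxon_markers
#' @param peak_counts peak x nucleus count matrix.
#' @export
call_dars <- function(peak_counts, groupA, groupB, log2fc_min = 0.25,
                      fdr_max = 0.01, min_detect = 0.1, exact_max = 12) {
  wilcoxon_markers(peak_counts, groupA, groupB, log2fc_min = log2fc_min,
                   fdr_max = fdr_max, min_detect = min_detect,
                   exact_max = exact_max)
}

#' Per-cluster composition chi-square tests between sample pairs
#'
#' For each cluster and each sample pair, a 2x2 table (cluster vs rest) x
#' (sample A vs sample B) is tested with Pearson's chi-square without
#' continuity correction; BH FDR across all tests in the call; significance
#' at FDR < 1e-5.
#'
#' @param cluster_counts cluster x sample integer matrix with dimnames.
#' @param pairs list of length-2 character vectors of sample names.
#' @return data.frame (cluster, sampleA, sampleB, chi2, pvalue, fdr,
#'   significant).
#' @export
composition_test <- function(cluster_counts, pairs, fdr_sig = 1e-5) {
  stopifnot(nrow(cluster_counts) >= 2)
  tot <- colSums(cluster_counts)
  res <- list()
  for (pr in pairs) {
    sA <- pr[1]; sB <- pr[2]
    if (tot[sA] == 0 || tot[sB] == 0)
      stop("sample with zero total nuclei: ",
           if (tot[sA] == 0) sA else sB)
    for (cl in rownames(cluster_counts)) {
      a <- cluster_counts[cl, sA]; b <- cluster_counts[cl, sB]
      tab <- matrix(c(a, tot[sA] - a, b, tot[sB] - b), nrow = 2)
      if (any(rowSums(tab) == 0)) {
        chi2 <- 0; p <- 1
      } else {
        ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
        chi2 <- unname(ct$statistic); p <- ct$p.value
      }
      res[[length(res) + 1L]] <- data.frame(
        cluster = cl, sampleA = sA, sampleB = sB, chi2 = chi2,
        pvalue = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  out$fdr <- stats::p.adjust(out$pvalue, method = "BH")
  out$significant <- out$fdr < fdr_sig
  rownames(out) <- NULL
  out
}

#' Association between direction-matched DEGs and linked DARs
#'
#' 2x2 over the gene universe: (gene is a direction-d DEG vs not) x (gene
#' linked to >= 1 same-direction DAR vs not); two-sided Fisher exact test.
#' Default universe: genes with at least one linked peak, configurable.
#'
#' @param degs,dars data.frames as returned by [wilcoxon_markers()] /
#'   [call_dars()].
#' @param links a [link_peaks_to_genes()] result.
#' @param universe character vector of gene ids (must cover the DEG features
#'   considered).
#' @param direction "up" or "down".
#' @return list per [fisher_exact_2x2()] plus `direction` and the component
#'   gene sets; degenerate tables are flagged `computable = FALSE`.
#' @export
deg_dar_association <- function(degs, dars, links, universe,
                                direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (length(universe) == 0) stop("universe must be non-empty")
  universe <- unique(universe)
  deg_set <- intersect(degs$feature_id[degs$direction == direction], universe)
  dar_peaks <- dars$feature_id[dars$direction == direction]
  linked_genes <- unique(links$links$gene_id[
    links$links$peak_id %in% dar_peaks])
  linked_set <- intersect(linked_genes, universe)
  a <- length(intersect(deg_set, linked_set))
  b <- length(setdiff(deg_set, linked_set))
  c_ <- length(setdiff(linked_set, deg_set))
  d <- length(universe) - a - b - c_
  tab <- matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE,
                dimnames = list(c("deg", "not_deg"),
                                c("linked", "not_linked")))
  ft <- fisher_exact_2x2(tab)
  c(ft, list(direction = direction, deg_genes = deg_set,
             linked_genes = linked_set))
}
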