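# Normalized motif scores (NMS), focal-motif CRE selection, family
# colocalization rates, and co-occurrence correlation matrices.

#' Pseudo-bulk accessibility of an "average" nucleus
#'
#' `A_i` = mean raw fragment count per nucleus at peak i over the population
#' (zeros preserved; no normalization, the NMS x 10,000 factor absorbs scale).
#'
#' @param peak_counts peak x nucleus raw count matrix with dimnames.
#' @param population character vector of nucleus (column) names.
#' @return named numeric vector of A_i over all peaks.
#' @export
pseudobulk_accessibility <- function(peak_counts, population) {
  if (length(population) == 0) stop("population must be non-empty")
  missing <- setdiff(population, colnames(peak_counts))
  if (length(missing))
    stop("nuclei absent from counts: ",
         paste(utils::head(missing, 3), collapse = ", "))
  a <- Matrix::rowMeans(peak_counts[, population, drop = FALSE])
  stats::setNames(as.numeric(a), rownames(peak_counts))
}

#' Compute normalized motif scores for a focal motif
#'
#' `NMS_i = (A_i x O_i / L_i) x 10,000` where `A_i` is the pseudo-bulk
#' accessibility, `O_i` the focal-motif occurrence count and `L_i` the peak
#' length in bp. A peak is active iff `NMS > 1` (strict; `NMS = 1` is
#' inactive).
#'
#' @param profile named `A_i` vector from [pseudobulk_accessibility()].
#' @param hits a [build_hit_matrix()] result (or a named occurrence vector).
#' @param focal_motif motif id whose occurrence counts form `O_i`.
#' @param peaks data.frame (chrom, start, end, id); `L_i = end - start`.
#' @param population label stored on the table.
#' @return data.frame (peak_id, population, A, O, L, nms, active).
#' @export
compute_nms <- function(profile, hits, focal_motif, peaks,
                        population = NA_character_) {
  L <- peaks$end - peaks$start
  if (any(L <= 0)) stop("zero-length peak violates interval invariants")
  O <- if (inherits(hits, "hit_matrix")) {
    if (!focal_motif %in% colnames(hits$occurrences))
      stop("focal motif not in hit matrix: ", focal_motif)
    hits$occurrences[peaks$id, focal_motif]
  } else hits[peaks$id]
  A <- profile[peaks$id]
  if (anyNA(A)) stop("peaks missing from accessibility profile")
  nms <- (A * O / L) * 1e4
  data.frame(peak_id = peaks$id, population = population,
             A = as.numeric(A), O = as.integer(O), L = as.numeric(L),
             nms = as.numeric(nms), active = nms > 1,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Select focal-motif-containing CREs at direction-d DEGs
#'
#' Members are peaks that are active (`NMS > 1`, hence `O >= 1`) and linked
#' (same TAD/inter-TAD domain) to at least one DEG of the requested direction.
#' Also reports the number of such DEGs having >= 1 selected CRE.
#'
#' @param nms data.frame from [compute_nms()].
#' @param links a [link_peaks_to_genes()] result.
#' @param degs data.frame from [wilcoxon_markers()] (needs `direction`).
#' @param direction "up" or "down".
#' @return object of class `cre_set`: list (members, direction, population,
#'   n_degs_with_cre, deg_genes).
#' @export
select_cres <- function(nms, links, degs, direction = c("up", "down")) {
  direction <- match.arg(direction)
  deg_genes <- degs$feature_id[degs$direction == direction]
  lk <- links$links[links$links$gene_id %in% deg_genes, , drop = FALSE]
  active_peaks <- nms$peak_id[nms$active & nms$O >= 1]
  lk <- lk[lk$peak_id %in% active_peaks, , drop = FALSE]
  members <- sort(unique(lk$peak_id))
  structure(list(members = members, direction = direction,
                 population = nms$population[1],
                 n_degs_with_cre = length(unique(lk$gene_id)),
                 deg_genes = sort(unique(lk$gene_id))),
            class = "cre_set")
}

# motif ids of expressed TFs, per family, from a family map
expressed_motifs <- function(familymap, expressed_tfs) {
  familymap$map[familymap$map$tf_gene %in% expressed_tfs, , drop = FALSE]
}

#' Mean motif colocalization percentage by TF family
#'
#' Colocalization of a TF = percentage of CRE-set peaks carrying >= 1 of its
#' motifs; family value = mean over the family's expressed TFs. Only expressed
#' TFs are considered; families with no expressed TF are omitted.
#'
#' @param creset a [select_cres()] result (non-empty).
#' @param hits a [build_hit_matrix()] result.
#' @param familymap a [family_map()].
#' @param expressed_tfs character vector of expressed TF gene ids.
#' @return data.frame (family, mean_pct, n_tfs) sorted by family; attribute
#'   `per_tf` holds the per-TF rates.
#' @export
colocalization_rates <- function(creset, hits, familymap, expressed_tfs) {
  if (length(creset$members) == 0) stop("empty CRE set")
  occ <- hits$occurrences[creset$members, , drop = FALSE]
  fm <- expressed_motifs(familymap, expressed_tfs)
  if (nrow(fm) == 0) stop("no expressed TFs with motifs")
  per_tf <- vapply(split(fm$motif_id, fm$tf_gene), function(ms) {
    100 * mean(rowSums(occ[, ms, drop = FALSE]) >= 1)
  }, numeric(1))
  tf_fam <- fm$family[match(names(per_tf), fm$tf_gene)]
  fam_mean <- vapply(split(per_tf, tf_fam), mean, numeric(1))
  out <- data.frame(family = names(fam_mean), mean_pct = as.numeric(fam_mean),
                    n_tfs = as.integer(table(tf_fam)[names(fam_mean)]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$family), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "per_tf") <- data.frame(tf_gene = names(per_tf),
                                    family = tf_fam,
                                    pct = as.numeric(per_tf),
                                    stringsAsFactors = FALSE)
  out
}

#' Family co-occurrence (grammar) correlation matrix
#'
#' Per family, a binary presence indicator over the peak set restricted to
#' motifs of expressed TFs; Pearson correlation between indicators for every
#' family pair. Zero-variance families are marked missing (NA row/column) and
#' excluded from downstream networks.
#'
#' @param peak_set character vector of peak ids (>= 3).
#' @param hits a [build_hit_matrix()] result.
#' @param familymap a [family_map()].
#' @param expressed_tfs expressed TF gene ids.
#' @return object of class `grammar_matrix`: list (families, r, n_peaks,
#'   missing).
#' @export
cooccurrence_correlation <- function(peak_set, hits, familymap,
                                     expressed_tfs) {
  if (length(peak_set) < 3)
    stop("at least 3 peaks required for correlation")
  occ <- hits$occurrences[peak_set, , drop = FALSE]
  fm <- expressed_motifs(familymap, expressed_tfs)
  fams <- sort(unique(fm$family))
  ind <- vapply(fams, function(f) {
    ms <- fm$motif_id[fm$family == f]
    as.numeric(rowSums(occ[, ms, drop = FALSE]) >= 1)
  }, numeric(length(peak_set)))
  ind <- matrix(ind, ncol = length(fams), dimnames = list(peak_set, fams))
  vars <- apply(ind, 2, stats::var)
  missing <- fams[vars == 0]
  r <- suppressWarnings(stats::cor(ind))
  diag(r)[vars > 0] <- 1
  r[vars == 0, ] <- NA_real_
  r[, vars == 0] <- NA_real_
  structure(list(families = fams, r = r, n_peaks = length(peak_set),
                 missing = missing),
            class = "grammar_matrix")
}

#' Contrast two grammar correlation matrices
#'
#' Element-wise `r_up - r_down`; missing entries propagate; antisymmetric
#' under swapping the arguments.
#'
#' @param grammar_up,grammar_down [cooccurrence_correlation()] results over
#'   the same family ordering.
#' @return family x family numeric matrix.
#' @export
differential_grammar <- function(grammar_up, grammar_down) {
  if (!identical(grammar_up$families, grammar_down$families))
    stop("grammar matrices have mismatched family sets")
  grammar_up$r - grammar_down$r
}
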