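#' Derive a named pseudo-random substream seed
#'
#' Each synthetic artifact (genome, counts, SNP catalog, ...) draws from its
#' own stream derived from one master seed, so regenerating one artifact never
#' perturbs the others.
#'
#' @param seed master integer seed.
#' @param name stream name (e.g. "genome").
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  codes <- utf8ToInt(name)
  h <- sum(codes * seq_along(codes) * 131)
  as.integer((abs(seed) * 1000003 + h) %% 2147483646)
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' p-value from [stats::fisher.test()]; the odds ratio reported is the sample
#' odds ratio `ad/bc` (with a `+Inf` sentinel when `bc = 0` and `ad > 0`)
#' together with the Haldane-Anscombe corrected version
#' `(a+.5)(d+.5) / ((b+.5)(c+.5))`. Tables with a zero margin are flagged
#' `computable = FALSE` (odds ratio undefined).
#'
#' @param tab 2x2 non-negative integer matrix: rows = condition (in/out),
#'   columns = membership (in/out).
#' @return list with `odds_ratio`, `odds_ratio_haldane`, `pvalue`,
#'   `computable`, `table`.
#' @export
fisher_exact_2x2 <- function(tab) {
  stopifnot(is.matrix(tab), all(dim(tab) == 2L), all(tab >= 0))
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  computable <- all(rowSums(tab) > 0) && all(colSums(tab) > 0)
  or <- if (b * c_ == 0) {
    if (a * d == 0) NA_real_ else Inf
  } else (a * d) / (b * c_)
  or_h <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
  p <- if (computable) stats::fisher.test(tab)$p.value else NA_real_
  list(odds_ratio = if (computable) or else NA_real_,
       odds_ratio_haldane = or_h, pvalue = p,
       computable = computable, table = tab)
}

#' Adjusted Rand index between two partitions
#'
#' @param a,b integer/character membership vectors of equal length.
#' @return ARI in `[-1, 1]`; 1 iff identical up to relabeling.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  exp_idx <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == exp_idx) return(1)
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
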