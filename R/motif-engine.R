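# PWM scanning with exact null p-value thresholds.
#
# Scores are log2 odds of the (pseudocounted) motif model against a 0-order
# background, discretized to a fixed granularity. The null distribution of a
# window score is computed exactly by dynamic programming over the discretized
# per-position score distributions, so p-value thresholds are exact at the
# chosen granularity (for motif length <= 8 this is verifiable against
# enumeration of all 4^L words).

DNA_BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix model
#'
#' @param motif_id motif identifier.
#' @param probs 4 x L numeric matrix of per-position base probabilities
#'   (rows A, C, G, T); each column must sum to 1.
#' @param background length-4 positive base frequencies summing to 1.
#' @return object of class `pwm`.
#' @export
pwm <- function(motif_id, probs, background = rep(0.25, 4)) {
  probs <- as.matrix(probs)
  stopifnot(nrow(probs) == 4, ncol(probs) >= 1,
            length(background) == 4, all(background > 0))
  if (any(abs(colSums(probs) - 1) > 1e-6))
    stop("each PWM column must sum to 1")
  if (abs(sum(background) - 1) > 1e-6)
    stop("background must sum to 1")
  rownames(probs) <- DNA_BASES
  background <- as.numeric(background)
  names(background) <- DNA_BASES
  structure(list(motif_id = as.character(motif_id), probs = probs,
                 background = background),
            class = "pwm")
}

#' Estimate a 0-order background model from sequences
#'
#' Base counts over all supplied sequences with a +1 pseudocount per base,
#' normalized. `N` characters are ignored.
#'
#' @param sequences character vector of DNA strings.
#' @return length-4 named frequency vector (A, C, G, T).
#' @export
estimate_background <- function(sequences) {
  tab <- table(factor(strsplit(paste(toupper(sequences), collapse = ""),
                               "")[[1]], levels = DNA_BASES))
  cnt <- as.numeric(tab) + 1
  stats::setNames(cnt / sum(cnt), DNA_BASES)
}

# Discretized log2-odds integer score matrix (4 x L), after mixing the motif
# probabilities with the background: (1-eps) p + eps b.
int_score_matrix <- function(pwm, epsilon = 1e-4, granularity = 1e-3) {
  p <- (1 - epsilon) * pwm$probs + epsilon * pwm$background
  s <- log2(p / pwm$background)
  m <- round(s / granularity)
  storage.mode(m) <- "integer"
  m
}

# Exact null distribution of the total integer window score under the
# background model: dense probability vector over [min_score, max_score].
int_score_distribution <- function(intS, background) {
  offset <- 0L
  v <- 1
  for (j in seq_len(ncol(intS))) {
    s <- intS[, j]
    lo <- min(s); hi <- max(s)
    nv <- numeric(length(v) + hi - lo)
    for (a in 1:4) {
      idx <- seq_along(v) + (s[a] - lo)
      nv[idx] <- nv[idx] + v * background[a]
    }
    v <- nv
    offset <- offset + lo
  }
  list(min_score = offset, probs = v)
}

# Exceedance P(score >= s) for integer scores, as a dense vector aligned with
# the distribution (index k corresponds to score min_score + k - 1).
int_tail <- function(dist) rev(cumsum(rev(dist$probs)))

# Minimal integer score whose exceedance is <= alpha, among achievable scores;
# max achievable + 1 when no achievable score qualifies.
int_threshold <- function(dist, alpha) {
  tail <- int_tail(dist)
  achievable <- dist$probs > 0
  ok <- achievable & (tail <= alpha + 1e-12)
  if (!any(ok)) return(dist$min_score + length(dist$probs))
  dist$min_score + (which(ok)[1] - 1L)
}

#' Exact log-odds score threshold for a p-value cutoff
#'
#' Minimal score s with `P(window score >= s | background) <= alpha`, computed
#' by exact dynamic programming over the discretized score distribution.
#'
#' @param pwm a [pwm()].
#' @param alpha p-value cutoff in (0, 1].
#' @param epsilon pseudocount mixing weight toward the background.
#' @param granularity score discretization step (log2 units).
#' @return threshold in log2-odds units; `scan_pwm()` reports windows with
#'   discretized score >= this value.
#' @export
score_threshold_for_pvalue <- function(pwm, alpha, epsilon = 1e-4,
                                       granularity = 1e-3) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha > 1)
    stop("alpha must be in (0, 1]")
  intS <- int_score_matrix(pwm, epsilon, granularity)
  dist <- int_score_distribution(intS, pwm$background)
  int_threshold(dist, alpha) * granularity
}

# Integer scores of all windows of a coded sequence (NA where window has N).
window_int_scores <- function(codes, intS) {
  L <- ncol(intS)
  n <- length(codes) - L + 1L
  if (n < 1L) return(numeric(0))
  total <- numeric(n)
  for (j in seq_len(L)) {
    total <- total + intS[, j][codes[j:(j + n - 1L)]]
  }
  total
}

encode_dna <- function(sequence) {
  ch <- strsplit(toupper(sequence), "")[[1]]
  bad <- !(ch %in% c(DNA_BASES, "N"))
  if (any(bad))
    stop("invalid sequence characters: ",
         paste(unique(ch[bad]), collapse = ", "))
  match(ch, DNA_BASES)  # N -> NA
}

# Precompute everything a scan needs for one PWM (score matrices, exact null
# distribution, threshold) so batch scans do the DP once per motif.
prepare_scanner <- function(pwm, alpha, epsilon = 1e-4, granularity = 1e-3) {
  intS <- int_score_matrix(pwm, epsilon, granularity)
  dist <- int_score_distribution(intS, pwm$background)
  L <- ncol(intS)
  list(motif_id = pwm$motif_id, L = L,
       intS = intS,
       intS_rc = intS[c(4L, 3L, 2L, 1L), rev(seq_len(L)), drop = FALSE],
       thr = int_threshold(dist, alpha),
       tail = int_tail(dist),
       min_score = dist$min_score,
       granularity = granularity)
}

scan_coded <- function(codes, sc, peak_id) {
  rows <- list()
  for (str in c("+", "-")) {
    s <- window_int_scores(codes, if (str == "+") sc$intS else sc$intS_rc)
    hit <- which(!is.na(s) & s >= sc$thr)
    if (length(hit)) {
      si <- s[hit]
      rows[[str]] <- data.frame(
        peak_id = peak_id, offset = hit - 1L, strand = str,
        motif_id = sc$motif_id, score = si * sc$granularity,
        pvalue = sc$tail[si - sc$min_score + 1L],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  out[order(out$offset, match(out$strand, c("+", "-"))), , drop = FALSE]
}

#' Scan many peak sequences with one or more PWMs
#'
#' Batch form of [scan_pwm()]: the exact null distribution and threshold are
#' computed once per motif and reused over all sequences.
#'
#' @param sequences named character vector (names = peak ids).
#' @param pwms a [pwm()] or list of them.
#' @inheritParams scan_pwm
#' @return data.frame as in [scan_pwm()], rows over all peaks and motifs.
#' @export
scan_peaks <- function(sequences, pwms, alpha = 1e-4, epsilon = 1e-4,
                       granularity = 1e-3) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  coded <- lapply(sequences, encode_dna)
  out <- list()
  for (p in pwms) {
    sc <- prepare_scanner(p, alpha, epsilon, granularity)
    for (id in names(sequences)) {
      if (length(coded[[id]]) < sc$L) next
      h <- scan_coded(coded[[id]], sc, id)
      if (!is.null(h)) out[[length(out) + 1L]] <- h
    }
  }
  if (!length(out))
    return(data.frame(peak_id = character(), offset = integer(),
                      strand = character(), motif_id = character(),
                      score = numeric(), pvalue = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Scan a sequence with a PWM at an exact p-value cutoff
#'
#' Both strands are scanned; a window is reported when its discretized
#' log2-odds score reaches [score_threshold_for_pvalue()]. Windows containing
#' `N` are skipped. The reverse strand is scored with the reverse-complemented
#' matrix against the same background and threshold. Overlapping hits are all
#' reported (no greedy pruning), matching an occurrence-count reading of
#' motif content.
#'
#' @param sequence DNA string over A, C, G, T, N.
#' @param pwm a [pwm()].
#' @param alpha p-value cutoff in (0, 1].
#' @param peak_id optional id recorded on each hit.
#' @inheritParams score_threshold_for_pvalue
#' @return data.frame (peak_id, offset, strand, motif_id, score, pvalue)
#'   sorted by offset then strand (`+` before `-`). Offsets are 0-based
#'   positions of the window's leftmost base on the forward strand.
#' @export
scan_pwm <- function(sequence, pwm, alpha = 1e-4, peak_id = NA_character_,
                     epsilon = 1e-4, granularity = 1e-3) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha > 1)
    stop("alpha must be in (0, 1]")
  codes <- encode_dna(sequence)
  empty <- data.frame(peak_id = character(), offset = integer(),
                      strand = character(), motif_id = character(),
                      score = numeric(), pvalue = numeric(),
                      stringsAsFactors = FALSE)
  if (length(codes) < ncol(pwm$probs)) return(empty)
  sc <- prepare_scanner(pwm, alpha, epsilon, granularity)
  out <- scan_coded(codes, sc, peak_id)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}

#' Construct a motif -> family -> TF map
#'
#' Each motif belongs to exactly one TF gene and one family; the family ->
#' TF-gene map is derived.
#'
#' @param motif_id,family,tf_gene parallel character vectors (one row per
#'   motif).
#' @return object of class `family_map`: data.frame plus derived lookup.
#' @export
family_map <- function(motif_id, family, tf_gene) {
  df <- data.frame(motif_id = as.character(motif_id),
                   family = as.character(family),
                   tf_gene = as.character(tf_gene), stringsAsFactors = FALSE)
  if (anyDuplicated(df$motif_id)) stop("each motif maps to exactly one family")
  structure(list(map = df,
                 families = sort(unique(df$family))),
            class = "family_map")
}

#' Aggregate motif hits into a peak x motif / peak x family hit matrix
#'
#' @param hits data.frame as returned by [scan_pwm()] (rows may be
#'   concatenated over motifs/peaks).
#' @param peaks data.frame of peak intervals (chrom, start, end, id).
#' @param familymap a [family_map()].
#' @return object of class `hit_matrix`: list with `occurrences` (peak x motif
#'   integer counts, both strands pooled), `family_presence` (peak x family
#'   0/1), and the family map.
#' @export
build_hit_matrix <- function(hits, peaks, familymap) {
  stopifnot(inherits(familymap, "family_map"))
  motifs <- familymap$map$motif_id
  occ <- matrix(0L, nrow = nrow(peaks), ncol = length(motifs),
                dimnames = list(peaks$id, motifs))
  if (nrow(hits) > 0) {
    orphan_p <- setdiff(unique(hits$peak_id), peaks$id)
    if (length(orphan_p))
      stop("hits reference unknown peak ids: ",
           paste(orphan_p, collapse = ", "))
    orphan_m <- setdiff(unique(hits$motif_id), motifs)
    if (length(orphan_m))
      stop("hits reference unknown motif ids: ",
           paste(orphan_m, collapse = ", "))
    tab <- table(factor(hits$peak_id, levels = peaks$id),
                 factor(hits$motif_id, levels = motifs))
    occ <- occ + unclass(tab)
  }
  fams <- familymap$families
  fam_of <- familymap$map$family
  presence <- vapply(fams, function(f) {
    as.integer(rowSums(occ[, fam_of == f, drop = FALSE]) >= 1)
  }, integer(nrow(peaks)))
  presence <- matrix(presence, nrow = nrow(peaks),
                     dimnames = list(peaks$id, fams))
  structure(list(occurrences = occ, family_presence = presence,
                 familymap = familymap),
            class = "hit_matrix")
}

#' Target-vs-background motif enrichment by exact tests
#'
#' For each motif, a 2x2 table (with motif / without) x (target / background)
#' is tested with the two-sided Fisher exact test; BH FDR across motifs.
#'
#' @param target_presence,background_presence peak x motif 0/1 matrices over
#'   the same motif universe and disjoint peak sets.
#' @return data.frame (motif_id, n_target, n_background, with_target,
#'   with_background, odds_ratio, odds_ratio_haldane, pvalue, fdr) ranked by
#'   fdr then decreasing odds ratio.
#' @export
differential_motif_enrichment <- function(target_presence,
                                          background_presence) {
  if (nrow(target_presence) == 0 || nrow(background_presence) == 0)
    stop("target and background peak sets must be non-empty")
  if (!identical(colnames(target_presence), colnames(background_presence)))
    stop("target and background must share the same motif universe")
  shared <- intersect(rownames(target_presence), rownames(background_presence))
  if (length(shared))
    stop("target and background peak sets must be disjoint; shared: ",
         paste(utils::head(shared, 3), collapse = ", "))
  nt <- nrow(target_presence); nb <- nrow(background_presence)
  res <- lapply(colnames(target_presence), function(m) {
    a <- sum(target_presence[, m]); c_ <- sum(background_presence[, m])
    tab <- matrix(c(a, nt - a, c_, nb - c_), nrow = 2,
                  dimnames = list(c("with", "without"),
                                  c("target", "background")))
    ft <- fisher_exact_2x2(tab)
    data.frame(motif_id = m, n_target = nt, n_background = nb,
               with_target = a, with_background = c_,
               odds_ratio = ft$odds_ratio,
               odds_ratio_haldane = ft$odds_ratio_haldane,
               pvalue = ft$pvalue, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- stats::p.adjust(out$pvalue, method = "BH")
  out <- out[order(out$fdr, -out$odds_ratio, out$motif_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
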