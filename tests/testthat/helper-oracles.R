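# Independent oracles used across the suite. These re-derive expected values
# from first principles (full enumeration, textbook formulas) and never call
# the implementation paths they check.

BASES <- c("A", "C", "G", "T")

random_pwm <- function(L, id = "m", bg = rep(0.25, 4)) {
  p <- matrix(stats::rgamma(4 * L, 1), 4, L)
  p <- sweep(p, 2, colSums(p), "/")
  pwm(id, p, background = bg)
}

consensus_pwm <- function(word, id = word, major = 0.85,
                          bg = rep(0.25, 4)) {
  bases <- strsplit(word, "")[[1]]
  p <- matrix((1 - major) / 3, 4, length(bases),
              dimnames = list(BASES, NULL))
  p[cbind(match(bases, BASES), seq_along(bases))] <- major
  pwm(id, p, background = bg)
}

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE),
                                collapse = "")

revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# discretized per-word scores of every 4^L word, with background weights
enum_all_words <- function(pwm_obj, epsilon = 1e-4, granularity = 1e-3) {
  p <- (1 - epsilon) * pwm_obj$probs + epsilon * pwm_obj$background
  S <- round(log2(p / pwm_obj$background) / granularity)
  L <- ncol(S)
  words <- as.matrix(expand.grid(rep(list(1:4), L)))
  sc <- rowSums(matrix(S[cbind(as.vector(words),
                               rep(seq_len(L), each = nrow(words)))],
                       nrow(words)))
  pr <- exp(rowSums(matrix(log(pwm_obj$background)[as.vector(words)],
                           nrow(words))))
  list(scores = sc, probs = pr, granularity = granularity)
}

# minimal achievable word score with exceedance <= alpha, by enumeration
oracle_threshold <- function(pwm_obj, alpha, epsilon = 1e-4,
                             granularity = 1e-3) {
  e <- enum_all_words(pwm_obj, epsilon, granularity)
  sc <- sort(unique(e$scores), decreasing = TRUE)
  tail <- cumsum(vapply(sc, function(s) sum(e$probs[e$scores == s]),
                        numeric(1)))
  ok <- tail <= alpha + 1e-12
  if (!any(ok)) return((max(sc) + 1) * granularity)
  min(sc[ok]) * granularity
}

# brute-force both-strand scan: score every window (forward word directly,
# reverse strand = forward score of the window's reverse complement)
oracle_scan <- function(sequence, pwm_obj, alpha, epsilon = 1e-4,
                        granularity = 1e-3) {
  p <- (1 - epsilon) * pwm_obj$probs + epsilon * pwm_obj$background
  S <- round(log2(p / pwm_obj$background) / granularity)
  thr <- round(oracle_threshold(pwm_obj, alpha, epsilon, granularity) /
                 granularity)
  L <- ncol(S)
  chars <- strsplit(toupper(sequence), "")[[1]]
  n <- length(chars) - L + 1
  rows <- list()
  if (n >= 1) for (off in 0:(n - 1)) {
    w <- chars[(off + 1):(off + L)]
    if (any(!w %in% BASES)) next
    fwd <- sum(S[cbind(match(w, BASES), seq_len(L))])
    rcw <- strsplit(revcomp(paste(w, collapse = "")), "")[[1]]
    rev_ <- sum(S[cbind(match(rcw, BASES), seq_len(L))])
    if (fwd >= thr)
      rows[[length(rows) + 1]] <- data.frame(offset = off, strand = "+",
                                             score = fwd * granularity)
    if (rev_ >= thr)
      rows[[length(rows) + 1]] <- data.frame(offset = off, strand = "-",
                                             score = rev_ * granularity)
  }
  if (!length(rows))
    return(data.frame(offset = integer(), strand = character(),
                      score = numeric()))
  do.call(rbind, rows)
}

# two-sided Fisher p by full hypergeometric enumeration over the margin
oracle_fisher_two_sided <- function(a, b, c_, d) {
  k <- a + b          # draws (row 1 total)
  m <- a + c_         # white balls (col 1 total)
  n <- b + d          # black balls
  xs <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(xs, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# two-sided rank-sum p by enumeration of all C(n, nA) label assignments
oracle_ranksum <- function(x, y) {
  nA <- length(x)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(nA)])
  combos <- utils::combn(length(r), nA)
  Wp <- colSums(matrix(r[combos], nrow = nA))
  mu <- mean(Wp)
  mean(abs(Wp - mu) >= abs(W - mu) - 1e-9)
}

# all set partitions of n elements (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxlab) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (l in seq_len(maxlab + 1)) rec(c(prefix, l), max(maxlab, l))
  }
  rec(integer(0), 0L)
  out
}

# modularity by the definition, looped
oracle_modularity <- function(W, mem) {
  W <- as.matrix(W)
  diag(W) <- 0
  m2 <- sum(W)
  if (m2 == 0) return(0)
  k <- rowSums(W)
  q <- 0
  for (i in seq_len(nrow(W))) for (j in seq_len(ncol(W)))
    if (mem[i] == mem[j]) q <- q + W[i, j] - k[i] * k[j] / m2
  q / m2
}

# exhaustive maximum-modularity partition
oracle_best_partition <- function(W) {
  parts <- all_partitions(nrow(W))
  qs <- vapply(parts, function(p) oracle_modularity(W, p), numeric(1))
  list(q = max(qs), membership = parts[[which.max(qs)]])
}

# block-correlation weight matrix with planted communities
planted_block_matrix <- function(sizes, within = 0.8, between = 0.0) {
  n <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  W <- matrix(between, n, n)
  W[outer(lab, lab, `==`)] <- within
  diag(W) <- 1
  dimnames(W) <- list(sprintf("n%02d", 1:n), sprintf("n%02d", 1:n))
  list(W = W, labels = lab)
}

# tiny labeled count matrix for diffexp tests
toy_counts <- function(n_feat = 20, nA = 10, nB = 10, seed = 1, mu = 2,
                       lfc_feat = integer(0), lfc = 2, dispersion = 0.3) {
  set.seed(seed)
  n <- nA + nB
  m <- matrix(stats::rnbinom(n_feat * n, mu = mu, size = 1 / dispersion),
              n_feat, n,
              dimnames = list(sprintf("f%03d", 1:n_feat),
                              sprintf("c%03d", 1:n)))
  if (length(lfc_feat))
    m[lfc_feat, 1:nA] <- stats::rnbinom(length(lfc_feat) * nA,
                                        mu = mu * 2^lfc,
                                        size = 1 / dispersion)
  list(counts = m, groupA = colnames(m)[1:nA],
       groupB = colnames(m)[(nA + 1):n])
}
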