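make_hit_matrix <- function(occ, fam, tf = NULL) {
  # occ: peak x motif integer matrix; fam: motif -> family; tf: motif -> TF
  motifs <- colnames(occ)
  tf <- tf %||% paste0("tf_", motifs)
  fmap <- family_map(motifs, fam, tf)
  peaks <- genomic_intervals("chr1", seq(0, by = 1000,
                                         length.out = nrow(occ)),
                             seq(0, by = 1000, length.out = nrow(occ)) + 500,
                             rownames(occ))
  hits <- do.call(rbind, lapply(motifs, function(m) {
    idx <- rep(seq_len(nrow(occ)), occ[, m])
    if (!length(idx)) return(NULL)
    data.frame(peak_id = rownames(occ)[idx], offset = 0, strand = "+",
               motif_id = m, score = 1, pvalue = 0.01,
               stringsAsFactors = FALSE)
  }))
  if (is.null(hits))
    hits <- data.frame(peak_id = character(), offset = integer(),
                       strand = character(), motif_id = character(),
                       score = numeric(), pvalue = numeric())
  build_hit_matrix(hits, peaks, fmap)
}

test_that("pseudo-bulk accessibility is the per-nucleus mean of raw counts", {
  m <- rbind(pkA = c(1, 3, 0, 8), pkB = c(0, 0, 0, 0))
  colnames(m) <- paste0("n", 1:4)
  a <- pseudobulk_accessibility(m, c("n1", "n2"))
  expect_equal(unname(a["pkA"]), 2.0)
  expect_equal(unname(a["pkB"]), 0.0)
  expect_error(pseudobulk_accessibility(m, character()), "non-empty")
  # sparse input equals dense recomputation on a larger random case
  set.seed(8)
  big <- matrix(stats::rpois(100 * 100, 0.5), 100, 100,
                dimnames = list(sprintf("p%03d", 1:100),
                                sprintf("n%03d", 1:100)))
  sp <- Matrix::Matrix(big, sparse = TRUE)
  pop <- sample(colnames(big), 37)
  expect_equal(pseudobulk_accessibility(sp, pop),
               rowMeans(big[, pop]))
})

test_that("NMS follows the formula with a strict activity boundary", {
  peaks <- genomic_intervals("chr1", c(0, 1000, 2000),
                             c(600, 1500, 7000), c("p1", "p2", "p3"))
  profile <- c(p1 = 2.0, p2 = 1.0, p3 = 0.5)
  occ <- c(p1 = 3L, p2 = 0L, p3 = 1L)
  tab <- compute_nms(profile, occ, "focal", peaks, population = "CM1")
  expect_equal(tab$nms, c((2 * 3 / 600) * 1e4, 0, (0.5 * 1 / 5000) * 1e4))
  expect_equal(tab$nms[1], 100)
  expect_true(tab$active[1])
  expect_false(tab$active[2])          # O = 0 -> NMS 0
  expect_equal(tab$nms[3], 1.0)
  expect_false(tab$active[3])          # NMS = 1 exactly is inactive
})

test_that("NMS is homogeneous in counts and monotone in A, O, L", {
  set.seed(14)
  m <- matrix(stats::rpois(50 * 20, 1), 50, 20,
              dimnames = list(sprintf("p%02d", 1:50), sprintf("n%02d", 1:20)))
  peaks <- genomic_intervals("chr1", seq(0, by = 2000, length.out = 50),
                             seq(0, by = 2000, length.out = 50) + 500,
                             rownames(m))
  occ <- stats::setNames(sample(0:3, 50, TRUE), rownames(m))
  pop <- colnames(m)
  a1 <- pseudobulk_accessibility(m, pop)
  a2 <- pseudobulk_accessibility(2 * m, pop)
  expect_equal(a2, 2 * a1)
  n1 <- compute_nms(a1, occ, "f", peaks)
  n2 <- compute_nms(a2, occ, "f", peaks)
  expect_equal(n2$nms, 2 * n1$nms)
  expect_true(all((n1$nms == 0) == (n1$O == 0 | n1$A == 0)))
})

test_that("CRE selection filters on activity, focal occurrence and direction", {
  peaks <- genomic_intervals("chr1", c(0, 700, 1400), c(500, 1200, 1900),
                             c("p1", "p2", "p3"))
  nms <- data.frame(peak_id = c("p1", "p2", "p3"), population = "CM1",
                    A = c(2, 2, 2), O = c(2L, 1L, 1L), L = 500,
                    nms = c(80, 1.0, 40), active = c(TRUE, FALSE, TRUE),
                    stringsAsFactors = FALSE)
  links <- structure(list(links = data.frame(
    peak_id = c("p1", "p2", "p3"), gene_id = c("gU", "gU", "gD"),
    domain = c(1L, 1L, 2L), stringsAsFactors = FALSE),
    domain_of = integer()), class = "region_gene_links")
  degs <- data.frame(feature_id = c("gU", "gD"), log2fc = c(1, -1),
                     pvalue = 0.001, fdr = 0.001,
                     direction = c("up", "down"), stringsAsFactors = FALSE)
  up <- select_cres(nms, links, degs, "up")
  expect_equal(up$members, "p1")       # p2 inactive (NMS = 1), p3 down-linked
  expect_equal(up$n_degs_with_cre, 1L)
  down <- select_cres(nms, links, degs, "down")
  expect_equal(down$members, "p3")
  # brute-force filter oracle on a random instance
  set.seed(15)
  n <- 40
  nms_r <- data.frame(peak_id = sprintf("q%02d", 1:n), population = "x",
                      A = 1, O = sample(0:2, n, TRUE), L = 500,
                      nms = stats::runif(n, 0, 3), stringsAsFactors = FALSE)
  nms_r$nms[nms_r$O == 0] <- 0
  nms_r$active <- nms_r$nms > 1
  lk <- data.frame(peak_id = sample(nms_r$peak_id, 60, TRUE),
                   gene_id = sample(c("g1", "g2", "g3", "g4"), 60, TRUE),
                   domain = 1L, stringsAsFactors = FALSE)
  links_r <- structure(list(links = lk, domain_of = integer()),
                       class = "region_gene_links")
  degs_r <- data.frame(feature_id = c("g1", "g2", "g3", "g4"),
                       log2fc = c(1, 1, -1, 0), pvalue = 0.01, fdr = 0.001,
                       direction = c("up", "up", "down", "ns"),
                       stringsAsFactors = FALSE)
  got <- select_cres(nms_r, links_r, degs_r, "up")$members
  want <- sort(unique(lk$peak_id[
    lk$gene_id %in% c("g1", "g2") &
      lk$peak_id %in% nms_r$peak_id[nms_r$active & nms_r$O >= 1]]))
  expect_equal(got, want)
})

test_that("colocalization rates average per-TF percentages within families", {
  # 10 CRE peaks; m1/m2/m3 same family (3 TFs), m4 its own family
  occ <- matrix(0L, 10, 4, dimnames = list(sprintf("p%02d", 1:10),
                                           c("m1", "m2", "m3", "m4")))
  occ[1, "m1"] <- 1L                      # tf1: 10%
  occ[1:2, "m2"] <- 1L                    # tf2: 20%
  occ[1:6, "m3"] <- 1L                    # tf3: 60%
  occ[, "m4"] <- 1L                       # tf4: 100%
  hm <- make_hit_matrix(occ, c("famA", "famA", "famA", "famB"),
                        c("tf1", "tf2", "tf3", "tf4"))
  cre <- structure(list(members = rownames(occ), direction = "up",
                        population = "CM1", n_degs_with_cre = 5L),
                   class = "cre_set")
  rates <- colocalization_rates(cre, hm, hm$familymap,
                                expressed_tfs = c("tf1", "tf2", "tf3", "tf4"))
  expect_equal(rates$mean_pct[rates$family == "famA"], mean(c(10, 20, 60)))
  expect_equal(rates$mean_pct[rates$family == "famB"], 100)
  # families with no expressed TF are omitted; zero-hit TFs give 0%
  r2 <- colocalization_rates(cre, hm, hm$familymap, expressed_tfs = "tf1")
  expect_equal(r2$family, "famA")
  expect_equal(r2$mean_pct, 10)
  occ0 <- occ; occ0[, "m4"] <- 0L
  hm0 <- make_hit_matrix(occ0, c("famA", "famA", "famA", "famB"),
                         c("tf1", "tf2", "tf3", "tf4"))
  r3 <- colocalization_rates(cre, hm0, hm0$familymap,
                             expressed_tfs = c("tf1", "tf4"))
  expect_equal(r3$mean_pct[r3$family == "famB"], 0)
  expect_error(colocalization_rates(
    structure(list(members = character()), class = "cre_set"),
    hm, hm$familymap, "tf1"), "empty CRE set")
})

test_that("co-occurrence correlation is Pearson on family indicators", {
  occ <- matrix(0L, 8, 3, dimnames = list(sprintf("p%d", 1:8),
                                          c("m1", "m2", "m3")))
  occ[1:4, "m1"] <- 1L
  occ[1:4, "m2"] <- 1L     # identical indicator to m1
  occ[5:8, "m3"] <- 1L     # complementary indicator
  hm <- make_hit_matrix(occ, c("A", "B", "C"))
  g <- cooccurrence_correlation(rownames(occ), hm, hm$familymap,
                                expressed_tfs = paste0("tf_m", 1:3))
  expect_equal(g$r["A", "B"], 1)
  expect_equal(g$r["A", "C"], -1)
  expect_equal(g$r, t(g$r))
  expect_equal(unname(diag(g$r)), c(1, 1, 1))
  # invariant to peak ordering
  g2 <- cooccurrence_correlation(rev(rownames(occ)), hm, hm$familymap,
                                 paste0("tf_m", 1:3))
  expect_equal(g$r, g2$r)
  # zero-variance family is marked missing
  occ[, "m3"] <- 1L
  hm2 <- make_hit_matrix(occ, c("A", "B", "C"))
  g3 <- cooccurrence_correlation(rownames(occ), hm2, hm2$familymap,
                                 paste0("tf_m", 1:3))
  expect_equal(g3$missing, "C")
  expect_true(all(is.na(g3$r["C", ])))
  expect_error(cooccurrence_correlation(rownames(occ)[1:2], hm, hm$familymap,
                                        paste0("tf_m", 1:3)), "at least 3")
})

test_that("planted co-occurring pair out-correlates an independent pair", {
  set.seed(16)
  wins <- 0
  for (rep in 1:30) {
    n <- 500
    p0 <- 0.35
    p11 <- cregrammar:::joint_prob_for_odds(p0, p0, 9)
    u <- stats::runif(n)
    x <- as.integer(u < p0)
    y <- integer(n)
    y[u < p11] <- 1L
    y[u >= p0] <- as.integer(stats::runif(sum(u >= p0)) <
                               (p0 - p11) / (1 - p0))
    w <- stats::rbinom(n, 1, p0); z <- stats::rbinom(n, 1, p0)
    occ <- cbind(mX = x, mY = y, mW = w, mZ = z)
    rownames(occ) <- sprintf("p%03d", 1:n)
    hm <- make_hit_matrix(occ, c("X", "Y", "W", "Z"))
    g <- cooccurrence_correlation(rownames(occ), hm, hm$familymap,
                                  paste0("tf_m", c("X", "Y", "W", "Z")))
    if (g$r["X", "Y"] > g$r["W", "Z"]) wins <- wins + 1
  }
  expect_gte(wins / 30, 0.95)
})

test_that("differential grammar contrast is antisymmetric and zero on equal input", {
  set.seed(18)
  occ <- matrix(rbinom(60, 1, 0.5), 20, 3,
                dimnames = list(sprintf("p%d", 1:20), c("m1", "m2", "m3")))
  hm <- make_hit_matrix(occ, c("A", "B", "C"))
  g <- cooccurrence_correlation(rownames(occ), hm, hm$familymap,
                                paste0("tf_m", 1:3))
  expect_equal(differential_grammar(g, g),
               matrix(0, 3, 3, dimnames = dimnames(g$r)))
  occ2 <- occ; occ2[, "m2"] <- rev(occ2[, "m2"])
  hm2 <- make_hit_matrix(occ2, c("A", "B", "C"))
  g2 <- cooccurrence_correlation(rownames(occ2), hm2, hm2$familymap,
                                 paste0("tf_m", 1:3))
  expect_equal(differential_grammar(g, g2), -differential_grammar(g2, g))
  g3 <- g2; g3$families <- c("A", "B", "D")
  expect_error(differential_grammar(g, g3), "mismatched")
})

test_that("leading-eigenvector communities recover separated structures", {
  # two disjoint 3-cliques: exactly the cliques, matching exhaustive search
  W <- matrix(0, 6, 6, dimnames = list(paste0("n", 1:6), paste0("n", 1:6)))
  W[1:3, 1:3] <- 1; W[4:6, 4:6] <- 1; diag(W) <- 0
  net <- spectral_communities(W)
  expect_equal(net$n_communities, 2L)
  expect_equal(unname(net$communities[1:3]), rep(net$communities[["n1"]], 3))
  expect_equal(unname(net$communities[4:6]), rep(net$communities[["n4"]], 3))
  best <- oracle_best_partition(W)
  expect_equal(net$modularity, best$q, tolerance = 1e-9)

  # complete graph with equal weights: a single community
  K <- matrix(1, 5, 5, dimnames = list(paste0("n", 1:5), paste0("n", 1:5)))
  diag(K) <- 0
  expect_equal(spectral_communities(K)$n_communities, 1L)

  # planted 3-block correlation matrix: ARI 1 vs planted labels
  pb <- planted_block_matrix(c(4, 4, 4), within = 0.8, between = 0)
  net3 <- spectral_communities(pb$W)
  expect_equal(adjusted_rand_index(net3$communities, pb$labels), 1)
})

test_that("returned modularity beats trivial and is deterministic", {
  set.seed(17)
  for (rep in 1:10) {
    n <- sample(4:7, 1)
    W <- matrix(0, n, n)
    W[upper.tri(W)] <- stats::rbinom(n * (n - 1) / 2, 1, 0.5) *
      stats::runif(n * (n - 1) / 2, 0.2, 1)
    W <- W + t(W)
    dimnames(W) <- list(paste0("n", 1:n), paste0("n", 1:n))
    if (sum(W) == 0) next
    net <- suppressWarnings(spectral_communities(W))
    expect_gte(net$modularity, 0 - 1e-12)  # trivial partition has Q = 0
    expect_lte(net$modularity, oracle_best_partition(W)$q + 1e-9)
    net_b <- suppressWarnings(spectral_communities(W))
    expect_identical(net$communities, net_b$communities)
  }
})

test_that("empty graph after thresholding warns and returns one community", {
  W <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_warning(net <- spectral_communities(W), "no edges")
  expect_equal(net$n_communities, 1L)
  expect_equal(net$modularity, 0)
})
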