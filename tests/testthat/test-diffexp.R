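test_that("exact rank-sum p matches label-assignment enumeration", {
  expect_equal(rank_sum_test(c(1, 2, 3), c(4, 5, 6))$pvalue, 0.1)
  expect_equal(rank_sum_test(c(1, 2, 3), c(4, 5, 6))$pvalue,
               oracle_ranksum(c(1, 2, 3), c(4, 5, 6)))
  set.seed(12)
  for (rep in 1:10) {
    nA <- sample(3:6, 1); nB <- sample(3:6, 1)
    x <- sample(0:4, nA, TRUE); y <- sample(0:4, nB, TRUE)  # heavy ties
    expect_equal(rank_sum_test(x, y)$pvalue, oracle_ranksum(x, y))
  }
  # tie-free cases also agree with the standard exact test
  for (rep in 1:5) {
    x <- stats::rnorm(5); y <- stats::rnorm(6)
    expect_equal(rank_sum_test(x, y)$pvalue,
                 stats::wilcox.test(x, y, exact = TRUE)$p.value)
  }
})

test_that("normal approximation tracks exact enumeration at nA = nB = 6", {
  set.seed(13)
  for (rep in 1:20) {
    x <- stats::rnorm(6); y <- stats::rnorm(6, mean = stats::runif(1, 0, 2))
    p_ex <- rank_sum_test(x, y, exact_max = 12)$pvalue
    p_no <- rank_sum_test(x, y, exact_max = 0)$pvalue
    expect_lte(abs(p_ex - p_no), 0.02)
  }
})

test_that("wilcoxon_markers applies thresholds, filters and direction rules", {
  tc <- toy_counts(n_feat = 30, nA = 10, nB = 10, seed = 5,
                   lfc_feat = 1:5, lfc = 3)
  res <- wilcoxon_markers(tc$counts, tc$groupA, tc$groupB)
  expect_true(all(res$direction[res$log2fc > 0.25 & res$fdr < 0.01] == "up"))
  expect_true(all(res$direction[abs(res$log2fc) <= 0.25 | res$fdr >= 0.01]
                  == "ns"))
  # boundary: log2fc exactly 0.25 or fdr not < 0.01 is ns (strict rules)
  fake <- data.frame(log2fc = c(0.25, 0.3, -0.3), fdr = c(0.001, 0.01, 0.001))
  dir <- ifelse(fake$log2fc > 0.25 & fake$fdr < 0.01, "up",
         ifelse(fake$log2fc < -0.25 & fake$fdr < 0.01, "down", "ns"))
  expect_equal(dir, c("ns", "ns", "down"))

  # feature identical across groups (after per-nucleus rescaling, enforced
  # here by constant column totals) -> lfc 0, p 1, ns
  set.seed(6)
  x <- sample(0:8, 12, TRUE)
  m <- rbind(f1 = rep(2L, 12), f2 = x, f3 = 8L - x, f4 = rep(5L, 12))
  colnames(m) <- sprintf("n%02d", 1:12)
  r <- wilcoxon_markers(m, colnames(m)[1:6], colnames(m)[7:12])
  row <- r[r$feature_id == "f1", ]
  expect_equal(row$log2fc, 0)
  expect_equal(row$pvalue, 1)
  expect_equal(row$direction, "ns")

  # all-zero feature is excluded by the detection filter
  m2 <- rbind(m, f5 = rep(0L, 12))
  r2 <- wilcoxon_markers(m2, colnames(m)[1:6], colnames(m)[7:12])
  expect_false("f5" %in% r2$feature_id)

  expect_error(wilcoxon_markers(m, colnames(m)[1:6], colnames(m)[1:6]),
               "disjoint")
  expect_error(wilcoxon_markers(m, colnames(m)[1:2], colnames(m)[7:12]),
               "at least 3")
})

test_that("swapping group labels negates log2fc and preserves p", {
  tc <- toy_counts(n_feat = 25, nA = 8, nB = 12, seed = 9,
                   lfc_feat = 1:4, lfc = 2)
  ab <- wilcoxon_markers(tc$counts, tc$groupA, tc$groupB)
  ba <- call_dars(tc$counts, tc$groupB, tc$groupA)
  m <- match(ab$feature_id, ba$feature_id)
  expect_equal(ab$log2fc, -ba$log2fc[m])
  expect_equal(ab$pvalue, ba$pvalue[m])
})

test_that("BH step-up identities hold on the reported FDRs", {
  tc <- toy_counts(n_feat = 40, nA = 10, nB = 10, seed = 21,
                   lfc_feat = 1:6, lfc = 2.5)
  res <- wilcoxon_markers(tc$counts, tc$groupA, tc$groupB)
  res <- res[order(res$pvalue), ]
  expect_true(all(diff(res$fdr) >= -1e-12))     # monotone after step-up
  expect_true(all(res$fdr >= res$pvalue - 1e-12))
  expect_equal(res$fdr, stats::p.adjust(res$pvalue, "BH"))
})

test_that("composition chi-square matches hand computation", {
  counts <- rbind(cl1 = c(s1 = 90, s2 = 50), cl2 = c(s1 = 10, s2 = 50))
  res <- composition_test(counts, list(c("s1", "s2")))
  # Sum (O-E)^2/E with margins (100,100)x(140,60): 2*400/70 + 2*400/30
  expect_equal(res$chi2[res$cluster == "cl1"], 800 / 21, tolerance = 1e-12)
  expect_equal(res$chi2[res$cluster == "cl1"], res$chi2[res$cluster == "cl2"])

  same <- rbind(cl1 = c(s1 = 30, s2 = 60), cl2 = c(s1 = 20, s2 = 40))
  r2 <- composition_test(same, list(c("s1", "s2")))
  expect_equal(r2$chi2, c(0, 0))
  expect_equal(r2$pvalue, c(1, 1))

  # single test: fdr equals p
  one <- composition_test(counts[, , drop = FALSE], list(c("s1", "s2")))
  expect_equal(one$fdr[1], one$pvalue[1] * 2 / 2)  # m tests share BH; check m=1
  single <- composition_test(rbind(a = c(x = 5, y = 9), b = c(x = 5, y = 1)),
                             list(c("x", "y")))
  expect_equal(single$fdr, stats::p.adjust(single$pvalue, "BH"))

  zero <- rbind(cl1 = c(s1 = 0, s2 = 10), cl2 = c(s1 = 0, s2 = 5))
  expect_error(composition_test(zero, list(c("s1", "s2"))), "zero total")
})

test_that("Fisher two-sided p matches hypergeometric enumeration", {
  set.seed(33)
  for (rep in 1:40) {
    a <- sample(0:15, 1); b <- sample(0:15, 1)
    c_ <- sample(0:15, 1); d <- sample(0:15, 1)
    if ((a + b) == 0 || (c_ + d) == 0 || (a + c_) == 0 || (b + d) == 0) next
    ft <- fisher_exact_2x2(matrix(c(a, b, c_, d), 2, byrow = TRUE))
    expect_equal(ft$pvalue, oracle_fisher_two_sided(a, b, c_, d),
                 tolerance = 1e-9)
  }
  ft <- fisher_exact_2x2(matrix(c(3, 1, 1, 3), 2))
  expect_equal(ft$pvalue, 34 / 70)
})

test_that("DEG-DAR association builds the right 2x2 and flags degeneracy", {
  tm <- build_tad_map(genomic_intervals("chr1", 0, 1000, "t1"),
                      c(chr1 = 2000))
  peaks <- genomic_intervals("chr1", c(100, 300, 1200), c(200, 400, 1300),
                             c("pk1", "pk2", "pk3"))
  genes <- data.frame(gene_id = c("g1", "g2", "g3"), chrom = "chr1",
                      tss = c(150, 500, 1500), stringsAsFactors = FALSE)
  links <- link_peaks_to_genes(peaks, genes, tm)
  degs <- data.frame(feature_id = c("g1", "g2", "g3"),
                     log2fc = c(1, 1, -1), pvalue = 0.001, fdr = 0.001,
                     direction = c("up", "up", "down"),
                     stringsAsFactors = FALSE)
  dars <- data.frame(feature_id = c("pk1", "pk3"), log2fc = 1,
                     pvalue = 0.001, fdr = 0.001, direction = "up",
                     stringsAsFactors = FALSE)
  res <- deg_dar_association(degs, dars, links, universe = c("g1", "g2", "g3"),
                             direction = "up")
  # g1,g2 up-DEGs; genes linked to up-DARs: pk1 -> g1,g2 (same TAD); pk3 -> g3
  expect_equal(unname(res$table[1, ]), c(2, 0))
  expect_equal(unname(res$table[2, ]), c(1, 0))
  expect_false(res$computable)  # second column empty -> degenerate

  # non-degenerate random check against direct construction
  res2 <- deg_dar_association(degs, dars, links,
                              universe = c("g1", "g2", "g3", "gx", "gy"),
                              direction = "up")
  expect_equal(sum(res2$table), 5)
  expect_error(deg_dar_association(degs, dars, links, universe = character()),
               "non-empty")
})

test_that("planted DEG-DAR coupling in shared TADs is detected as enrichment", {
  # DARs planted preferentially (weight 20) in domains hosting a same-
  # direction planted DEG; association tested on the planted labels over a
  # sparse-domain genome (~2 genes per domain)
  wins <- 0
  for (rep in 1:50) {
    cfg <- synthetic_config(seed = 8100 + rep, n_genes = 200, n_peaks = 300,
                            chrom_length = 1e7, n_tads_per_chrom = 25,
                            planted_deg_fraction = 0.2,
                            planted_dar_fraction = 0.25,
                            dar_deg_coupling = 20)
    g <- generate_genome(cfg)
    tru_deg <- g$truth$deg[g$truth$deg$population == "CM1", ]
    tru_dar <- g$truth$dar[g$truth$dar$population == "CM1", ]
    degs <- data.frame(feature_id = g$genes$gene_id, log2fc = 0, pvalue = 1,
                       fdr = 1, direction = "ns", stringsAsFactors = FALSE)
    degs$direction[match(tru_deg$gene_id, degs$feature_id)] <-
      tru_deg$direction
    dars <- data.frame(feature_id = g$peaks$id, log2fc = 0, pvalue = 1,
                       fdr = 1, direction = "ns", stringsAsFactors = FALSE)
    dars$direction[match(tru_dar$peak_id, dars$feature_id)] <-
      tru_dar$direction
    a <- deg_dar_association(degs, dars, g$links,
                             unique(g$links$links$gene_id), "up")
    if (isTRUE(a$computable) && a$odds_ratio > 1 && a$pvalue < 0.01)
      wins <- wins + 1
  }
  expect_gte(wins / 50, 0.95)
})
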