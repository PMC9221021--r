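# Seeded synthetic-study generator with planted ground truth: genome + TADs,
# peak sequences with planted motif occurrences and family co-occurrence
# structure, negative-binomial expression/accessibility counts with planted
# DEG/DAR effects, and a SNP catalog whose windows are enriched for genes
# highly expressed in one planted cluster.
#
# One master seed drives a named pseudo-random substream per artifact
# (genome, counts, snps), so regenerating one artifact never perturbs the
# others and every output is byte-reproducible.

#' Built-in synthetic motif library
#'
#' Eight 8-bp PWMs (0.85 consensus base, 0.05 elsewhere) for one focal
#' homeodomain TF plus five cofactor families, with a motif -> family -> TF
#' map. Consensus words are mutually distinct (also after reverse complement),
#' so at the 1e-4 scan cutoff each motif reports essentially its own planted
#' occurrences.
#'
#' @param background length-4 base frequencies.
#' @return list with `pwms` (named list of [pwm()]), `familymap`
#'   ([family_map()]), `consensus` (named character).
#' @export
motif_library <- function(background = rep(0.25, 4)) {
  defs <- data.frame(
    motif_id = c("PITX2.syn", "TBX20.syn", "TBX5.syn", "TCF12.syn",
                 "TCF3.syn", "SOX4.syn", "SMAD4.syn", "MEF2C.syn"),
    consensus = c("GTAATCCC", "AGGTGTGA", "AGGTGTAC", "AACAGCTG",
                  "GACAGCTG", "AACAATGG", "GTCTGGAC", "CTATTTAT"),
    family = c("homeodomain", "Tbox", "Tbox", "bHLH", "bHLH", "Sox", "SMAD",
               "MADS"),
    tf_gene = c("Pitx2", "Tbx20", "Tbx5", "Tcf12", "Tcf3", "Sox4", "Smad4",
                "Mef2c"),
    stringsAsFactors = FALSE)
  pwms <- lapply(seq_len(nrow(defs)), function(i) {
    bases <- strsplit(defs$consensus[i], "")[[1]]
    probs <- matrix(0.05, 4, length(bases), dimnames = list(DNA_BASES, NULL))
    probs[cbind(match(bases, DNA_BASES), seq_along(bases))] <- 0.85
    pwm(defs$motif_id[i], probs, background = background)
  })
  names(pwms) <- defs$motif_id
  list(pwms = pwms,
       familymap = family_map(defs$motif_id, defs$family, defs$tf_gene),
       consensus = stats::setNames(defs$consensus, defs$motif_id))
}

#' Configuration of a synthetic study
#'
#' Defaults are the study conditions all planted-truth validation runs under:
#' two cardiomyocyte-like populations of 50 nuclei per genotype, 4-fold
#' (log2 = 2) planted expression/accessibility effects at negative-binomial
#' dispersion 0.3, a family pair co-occurring at odds ratio 9 restricted to
#' peaks linked to upregulated genes, and 40 SNPs placed at odds 9 toward
#' genes highly expressed in one planted cluster.
#'
#' @param seed master integer seed.
#' @param ... overrides of the defaults listed below.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_chrom = 2L,
    chrom_length = 2e7,
    n_tads_per_chrom = 10L,
    n_genes = 2000L,
    n_peaks = 500L,
    peak_length_range = c(300L, 700L),
    populations = c(CM1 = 50L, CM2 = 50L),  # nuclei per genotype
    genotypes = c("ctrl", "mut"),
    planted_deg_fraction = 0.02,
    deg_log2fc = 2,
    planted_dar_fraction = 0.05,
    dar_log2fc = 2,
    dar_deg_coupling = 1,
    nb_dispersion = 0.3,
    expr_meanlog = log(0.3),
    expr_sdlog = 1.2,
    expr_zero_fraction = 0.10,
    peak_mu_shape = 2,
    peak_mu_scale = 0.3,
    focal_family = "homeodomain",
    focal_plant_fraction = 0.6,
    family_base_prob = 0.30,
    cooccur_pair = c("Tbox", "bHLH"),
    cooccur_odds = 9,
    grammar_population = "CM1",
    n_snps = 40L,
    snp_enriched_cluster = "CM1",
    snp_enrichment_odds = 9,
    snp_window_bp = 5e5,
    ortholog_unmapped_fraction = 0.10,
    alpha = 1e-4
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  with(cfg, {
    stopifnot(n_chrom >= 1, n_genes >= 1, n_peaks >= 1,
              n_tads_per_chrom >= 1,
              planted_deg_fraction >= 0, planted_deg_fraction <= 1,
              planted_dar_fraction >= 0, planted_dar_fraction <= 1,
              deg_log2fc >= 0, dar_log2fc >= 0, nb_dispersion > 0,
              cooccur_odds > 0, snp_enrichment_odds > 0,
              all(populations >= 3))
  })
  if ((2 * cfg$n_tads_per_chrom + 1) * 10 > cfg$chrom_length)
    stop("infeasible packing: too many TADs for chromosome length")
  if (max(cfg$peak_length_range) > cfg$chrom_length)
    stop("infeasible packing: peaks longer than chromosome")
  structure(cfg, class = "synthetic_config")
}

# Joint Bernoulli(p, q) with a given odds ratio: returns P(X=1, Y=1).
joint_prob_for_odds <- function(p, q, or) {
  if (abs(or - 1) < 1e-12) return(p * q)
  a <- or - 1
  b <- -(a * (p + q) + 1)
  cc <- or * p * q
  root <- (-b - sqrt(b^2 - 4 * a * cc)) / (2 * a)
  max(max(0, p + q - 1), min(root, min(p, q)))
}

# Insert a word into a sequence at a random offset avoiding given occupied
# windows; returns list(seq, offset) or NULL when no room.
plant_word <- function(seq_chars, word, occupied, tries = 50) {
  L <- length(word)
  n <- length(seq_chars)
  for (t in seq_len(tries)) {
    off <- sample.int(n - L + 1L, 1L) - 1L
    if (!any(occupied[(off + 1):(off + L)])) {
      seq_chars[(off + 1):(off + L)] <- word
      occupied[(off + 1):(off + L)] <- TRUE
      return(list(seq = seq_chars, occupied = occupied, offset = off))
    }
  }
  NULL
}

#' Generate the synthetic genome: TADs, genes, peaks, sequences with planted
#' motifs, and the planted-truth ledger
#'
#' Peak sequences are iid uniform ACGT with consensus insertions: the focal
#' motif in a configured fraction of peaks (1-3 copies), cofactor family
#' motifs at a base rate, and the configured family pair drawn jointly at the
#' planted odds ratio in peaks that carry the focal motif and are linked
#' (same TAD/inter-TAD domain) to a planted upregulated gene of the grammar
#' population.
#'
#' @param config a [synthetic_config()].
#' @return list (chrom_sizes, tads, genes, peaks, sequences, pwms, familymap,
#'   tadmap, links, truth).
#' @export
generate_genome <- function(config) {
  set.seed(substream_seed(config$seed, "genome"))
  lib <- motif_library()
  chroms <- paste0("chr", seq_len(config$n_chrom))
  chrom_sizes <- stats::setNames(rep(config$chrom_length, config$n_chrom),
                                 chroms)
  # TADs: alternating gap/TAD segments with gamma-distributed widths
  tad_rows <- list()
  for (ch in chroms) {
    nseg <- 2L * config$n_tads_per_chrom + 1L
    w <- stats::rgamma(nseg, shape = 3)
    bounds <- round(cumsum(w) / sum(w) * config$chrom_length)
    starts <- c(0, bounds[-nseg])
    ends <- bounds
    tad_i <- seq(2, nseg, by = 2)
    keep <- ends[tad_i] > starts[tad_i]
    tad_rows[[ch]] <- data.frame(chrom = ch, start = starts[tad_i][keep],
                                 end = ends[tad_i][keep],
                                 stringsAsFactors = FALSE)
  }
  tads <- do.call(rbind, tad_rows)
  tads$id <- sprintf("tad%04d", seq_len(nrow(tads)))
  rownames(tads) <- NULL
  tadmap <- build_tad_map(tads, chrom_sizes)

  # genes: TF genes of the motif library first, then filler ids
  tf_genes <- lib$familymap$map$tf_gene
  gene_ids <- c(tf_genes,
                sprintf("gene%04d", seq_len(config$n_genes - length(tf_genes))))
  genes <- data.frame(
    gene_id = gene_ids,
    chrom = sample(chroms, config$n_genes, replace = TRUE),
    tss = floor(stats::runif(config$n_genes, 0, config$chrom_length)),
    strand = sample(c("+", "-"), config$n_genes, replace = TRUE),
    stringsAsFactors = FALSE)

  # planted DEG labels, independently per population. Planted genes of one
  # population sit in distinct TAD/inter-TAD domains wherever possible, so a
  # domain's direction label (hence a linked peak's ground truth) is
  # unambiguous.
  gene_dom <- assign_to_domain(genes$chrom, genes$tss, NULL, tadmap)
  deg_truth <- do.call(rbind, lapply(names(config$populations), function(pop) {
    n_deg <- round(config$planted_deg_fraction * config$n_genes)
    if (n_deg == 0)
      return(data.frame(gene_id = character(), population = character(),
                        direction = character(), stringsAsFactors = FALSE))
    ord <- sample.int(config$n_genes)
    distinct <- ord[!duplicated(gene_dom[ord])]
    picked_i <- utils::head(distinct, n_deg)
    if (length(picked_i) < n_deg)
      picked_i <- c(picked_i,
                    utils::head(setdiff(ord, picked_i),
                                n_deg - length(picked_i)))
    data.frame(gene_id = gene_ids[picked_i], population = pop,
               direction = sample(c("up", "down"), n_deg, replace = TRUE),
               stringsAsFactors = FALSE)
  }))

  # peaks
  plen <- sample(seq(config$peak_length_range[1], config$peak_length_range[2]),
                 config$n_peaks, replace = TRUE)
  pchrom <- sample(chroms, config$n_peaks, replace = TRUE)
  pstart <- floor(stats::runif(config$n_peaks, 0,
                               config$chrom_length - plen))
  ord <- order(pchrom, pstart)
  peaks <- genomic_intervals(pchrom[ord], pstart[ord], pstart[ord] + plen[ord],
                             sprintf("peak%05d", seq_len(config$n_peaks)))
  links <- link_peaks_to_genes(peaks, genes, tadmap)

  # planted DAR labels per population; with dar_deg_coupling > 1, a DAR of
  # direction d preferentially sits in a domain hosting a planted DEG of the
  # same direction (coupling through shared TADs)
  peak_dom <- assign_to_domain(peaks$chrom, peaks$start, peaks$end, tadmap)
  dar_truth <- do.call(rbind, lapply(names(config$populations), function(pop) {
    n_dar <- round(config$planted_dar_fraction * config$n_peaks)
    if (n_dar == 0)
      return(data.frame(peak_id = character(), population = character(),
                        direction = character(), stringsAsFactors = FALSE))
    deg_pop <- deg_truth[deg_truth$population == pop, , drop = FALSE]
    deg_dom <- gene_dom[match(deg_pop$gene_id, gene_ids)]
    dirs <- sample(c("up", "down"), n_dar, replace = TRUE)
    picked <- character(n_dar)
    avail <- rep(TRUE, nrow(peaks))
    for (j in seq_len(n_dar)) {
      w <- ifelse(peak_dom %in% deg_dom[deg_pop$direction == dirs[j]],
                  config$dar_deg_coupling, 1)
      w[!avail] <- 0
      k <- sample.int(nrow(peaks), 1, prob = w)
      picked[j] <- peaks$id[k]
      avail[k] <- FALSE
    }
    data.frame(peak_id = picked, population = pop, direction = dirs,
               stringsAsFactors = FALSE)
  }))

  # peaks linked to planted up-genes of the grammar population
  up_genes <- deg_truth$gene_id[deg_truth$population ==
                                  config$grammar_population &
                                  deg_truth$direction == "up"]
  uplinked <- unique(links$links$peak_id[links$links$gene_id %in% up_genes])

  # sequences with planted insertions
  fm <- lib$familymap$map
  focal_motifs <- fm$motif_id[fm$family == config$focal_family]
  cofactor_fams <- setdiff(lib$familymap$families, config$focal_family)
  pairX <- config$cooccur_pair[1]
  pairY <- config$cooccur_pair[2]
  p0 <- config$family_base_prob
  p11 <- joint_prob_for_odds(p0, p0, config$cooccur_odds)
  focal_planted <- integer(config$n_peaks)
  fam_planted <- matrix(0L, config$n_peaks, length(cofactor_fams),
                        dimnames = list(peaks$id, cofactor_fams))
  seqs <- character(config$n_peaks)
  plant_focal <- stats::runif(config$n_peaks) < config$focal_plant_fraction
  for (i in seq_len(config$n_peaks)) {
    len <- peaks$end[i] - peaks$start[i]
    sq <- sample(DNA_BASES, len, replace = TRUE)
    occ <- rep(FALSE, len)
    if (plant_focal[i]) {
      k <- 1L + stats::rbinom(1L, 2L, 0.3)
      for (j in seq_len(k)) {
        m <- sample(focal_motifs, 1L)
        res <- plant_word(sq, strsplit(lib$consensus[[m]], "")[[1]], occ)
        if (!is.null(res)) {
          sq <- res$seq; occ <- res$occupied
          focal_planted[i] <- focal_planted[i] + 1L
        }
      }
    }
    # family presence draws; planted pair is joint in focal+uplinked peaks
    pres <- stats::setNames(stats::runif(length(cofactor_fams)) < p0,
                            cofactor_fams)
    if (focal_planted[i] >= 1L && peaks$id[i] %in% uplinked) {
      # one draw from the joint (p11, p10, p01, p00) table at the planted odds
      cell <- stats::runif(1)
      if (cell < p11) { pres[pairX] <- TRUE; pres[pairY] <- TRUE }
      else if (cell < p0) { pres[pairX] <- TRUE; pres[pairY] <- FALSE }
      else if (cell < 2 * p0 - p11) { pres[pairX] <- FALSE; pres[pairY] <- TRUE }
      else { pres[pairX] <- FALSE; pres[pairY] <- FALSE }
    }
    for (f in cofactor_fams) {
      if (isTRUE(pres[[f]])) {
        m <- sample(fm$motif_id[fm$family == f], 1L)
        res <- plant_word(sq, strsplit(lib$consensus[[m]], "")[[1]], occ)
        if (!is.null(res)) {
          sq <- res$seq; occ <- res$occupied
          fam_planted[i, f] <- 1L
        }
      }
    }
    seqs[i] <- paste(sq, collapse = "")
  }
  names(seqs) <- peaks$id

  truth <- list(
    deg = deg_truth, dar = dar_truth,
    focal_planted = stats::setNames(focal_planted, peaks$id),
    family_planted = fam_planted,
    uplinked_peaks = sort(uplinked),
    cooccur_pair = config$cooccur_pair,
    grammar_population = config$grammar_population)
  list(chrom_sizes = chrom_sizes, tads = tads, genes = genes, peaks = peaks,
       sequences = seqs, pwms = lib$pwms, familymap = lib$familymap,
       consensus = lib$consensus, tadmap = tadmap, links = links,
       truth = truth, config = config)
}

#' Generate expression and peak count matrices with planted effects
#'
#' Negative-binomial counts per nucleus. Mean structure: per-gene (or
#' per-peak) baseline x population factor x genotype effect (`2^(+/- log2fc)`
#' in mutants for planted features of that population).
#'
#' @param config a [synthetic_config()].
#' @param genome a [generate_genome()] result.
#' @return list (expr, peak_counts, labels) with sparse `dgCMatrix` counts and
#'   a labels data.frame (barcode, population, genotype, sample).
#' @export
generate_counts <- function(config, genome) {
  set.seed(substream_seed(config$seed, "counts"))
  pops <- names(config$populations)
  labels <- do.call(rbind, lapply(pops, function(pop) {
    do.call(rbind, lapply(config$genotypes, function(gt) {
      n <- config$populations[[pop]]
      data.frame(
        barcode = sprintf("%s_%s_%03d", pop, gt, seq_len(n)),
        population = pop, genotype = gt, sample = paste(pop, gt, sep = "_"),
        stringsAsFactors = FALSE)
    }))
  }))
  gene_ids <- genome$genes$gene_id
  n_genes <- length(gene_ids)
  tf_genes <- genome$familymap$map$tf_gene

  # per gene x population baseline means, with a zero fraction (bin-0 genes);
  # TF genes kept expressed everywhere so expressed-TF selection is exercised
  base_mu <- matrix(stats::rlnorm(n_genes * length(pops),
                                  config$expr_meanlog, config$expr_sdlog),
                    n_genes, length(pops), dimnames = list(gene_ids, pops))
  zero <- matrix(stats::runif(n_genes * length(pops)) <
                   config$expr_zero_fraction, n_genes, length(pops))
  zero[gene_ids %in% tf_genes, ] <- FALSE
  base_mu[zero] <- 0
  base_mu[gene_ids %in% tf_genes, ] <- pmax(
    base_mu[gene_ids %in% tf_genes, ], 0.5)

  nb_size <- 1 / config$nb_dispersion
  expr <- matrix(0L, n_genes, nrow(labels),
                 dimnames = list(gene_ids, labels$barcode))
  for (pop in pops) {
    deg <- genome$truth$deg[genome$truth$deg$population == pop, ]
    for (gt in config$genotypes) {
      mu <- base_mu[, pop]
      if (gt == "mut" && nrow(deg) > 0) {
        idx <- match(deg$gene_id, gene_ids)
        mu[idx] <- mu[idx] *
          2^(ifelse(deg$direction == "up", 1, -1) * config$deg_log2fc)
      }
      cols <- which(labels$population == pop & labels$genotype == gt)
      expr[, cols] <- stats::rnbinom(n_genes * length(cols),
                                     mu = rep(mu, times = length(cols)),
                                     size = nb_size)
    }
  }

  peak_ids <- genome$peaks$id
  n_peaks <- length(peak_ids)
  peak_mu <- matrix(stats::rgamma(n_peaks * length(pops),
                                  shape = config$peak_mu_shape,
                                  scale = config$peak_mu_scale),
                    n_peaks, length(pops), dimnames = list(peak_ids, pops))
  pk <- matrix(0L, n_peaks, nrow(labels),
               dimnames = list(peak_ids, labels$barcode))
  for (pop in pops) {
    dar <- genome$truth$dar[genome$truth$dar$population == pop, ]
    for (gt in config$genotypes) {
      mu <- peak_mu[, pop]
      if (gt == "mut" && nrow(dar) > 0) {
        idx <- match(dar$peak_id, peak_ids)
        mu[idx] <- mu[idx] *
          2^(ifelse(dar$direction == "up", 1, -1) * config$dar_log2fc)
      }
      cols <- which(labels$population == pop & labels$genotype == gt)
      pk[, cols] <- stats::rnbinom(n_peaks * length(cols),
                                   mu = rep(mu, times = length(cols)),
                                   size = nb_size)
    }
  }
  list(expr = methods::as(Matrix::Matrix(expr, sparse = TRUE),
                          "CsparseMatrix"),
       peak_counts = methods::as(Matrix::Matrix(pk, sparse = TRUE),
                                 "CsparseMatrix"),
       labels = labels)
}

#' Generate a SNP catalog with a planted cell-type enrichment, plus a
#' synthetic ortholog table
#'
#' Each SNP is anchored to a gene drawn with weight `snp_enrichment_odds` for
#' genes binned in the top 20th percentile of the planted cluster (weight 1
#' otherwise) and placed uniformly within 80% of the window around its TSS.
#' Human gene ids are the mouse ids with an `HS_` prefix; a configured
#' fraction of genes is left unmapped, and a random subset of mapped pairs is
#' listed in both source catalogs (deduplicated by the reader).
#'
#' @param config a [synthetic_config()].
#' @param genome a [generate_genome()] result.
#' @param bins cluster x gene bin matrix from [bin_expression()] on the
#'   synthetic counts.
#' @return list (snps, orthologs, truth).
#' @export
generate_snp_catalog <- function(config, genome, bins) {
  set.seed(substream_seed(config$seed, "snps"))
  genes <- genome$genes
  cl <- config$snp_enriched_cluster
  if (!cl %in% rownames(bins)) stop("planted cluster absent from bins: ", cl)
  top <- bins[cl, genes$gene_id] > 20
  w <- ifelse(top, config$snp_enrichment_odds, 1)
  anchor <- sample(seq_len(nrow(genes)), config$n_snps, replace = TRUE,
                   prob = w / sum(w))
  offset <- round(stats::runif(config$n_snps, -0.8, 0.8) * config$snp_window_bp)
  pos <- pmin(pmax(genes$tss[anchor] + offset, 0),
              genome$chrom_sizes[genes$chrom[anchor]] - 1)
  snps <- data.frame(snp_id = sprintf("rs%06d", seq_len(config$n_snps)),
                     chrom = genes$chrom[anchor], pos = pos,
                     stringsAsFactors = FALSE)
  n_unmapped <- round(config$ortholog_unmapped_fraction * nrow(genes))
  unmapped <- sort(sample(genes$gene_id, n_unmapped))
  mapped <- setdiff(genes$gene_id, unmapped)
  src <- sample(c("ensembl", "homologene", "both"), length(mapped),
                replace = TRUE, prob = c(0.45, 0.45, 0.10))
  orth <- data.frame(human_gene = paste0("HS_", mapped), mouse_gene = mapped,
                     source = src, stringsAsFactors = FALSE)
  dup <- orth[orth$source == "both", ]
  if (nrow(dup) > 0) {
    orth$source[orth$source == "both"] <- "ensembl"
    dup$source <- "homologene"
    orth <- rbind(orth, dup)
  }
  orth <- orth[order(orth$human_gene, orth$source), ]
  rownames(orth) <- NULL
  list(snps = snps, orthologs = orth,
       truth = list(enriched_cluster = cl,
                    anchor_gene = genes$gene_id[anchor],
                    unmapped_genes = unmapped))
}

#' Generate and (optionally) write a complete synthetic study
#'
#' Runs [generate_genome()], [generate_counts()] and
#' [generate_snp_catalog()] and, when `dir` is given, writes every artifact in
#' the formats the pipeline readers consume (BED, FASTA, MEME, MTX + TSVs,
#' truth JSON).
#'
#' @param config a [synthetic_config()].
#' @param dir output directory (created), or NULL to skip writing.
#' @return list (genome, counts, snps, bins, paths).
#' @export
simulate_study <- function(config, dir = NULL) {
  genome <- generate_genome(config)
  counts <- generate_counts(config, genome)
  pops <- names(config$populations)
  mean_expr <- t(vapply(pops, function(pop) {
    Matrix::rowMeans(counts$expr[, counts$labels$barcode[
      counts$labels$population == pop], drop = FALSE])
  }, numeric(nrow(counts$expr))))
  rownames(mean_expr) <- pops
  bins <- bin_expression(mean_expr)
  snps <- generate_snp_catalog(config, genome, bins)
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(dir, f)
    write_bed(genome$tads, p("tads.bed"))
    utils::write.table(
      data.frame(names(genome$chrom_sizes), genome$chrom_sizes),
      p("chrom_sizes.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
    write_tsv(genome$genes, p("genes.tsv"))
    write_bed(genome$peaks, p("peaks.bed"))
    write_fasta(genome$sequences, p("peaks.fasta"))
    write_meme(genome$pwms, p("motifs.meme"))
    write_tsv(genome$familymap$map, p("family_map.tsv"))
    write_counts(counts$expr, p("expr"))
    write_counts(counts$peak_counts, p("peaks"))
    write_tsv(counts$labels, p("labels.tsv"))
    write_tsv(snps$snps, p("snps.tsv"))
    write_tsv(snps$orthologs, p("orthologs.tsv"))
    truth <- c(genome$truth, snps$truth)
    truth$family_planted <- as.data.frame(truth$family_planted)
    truth$family_planted$peak_id <- genome$peaks$id
    jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                         digits = NA, dataframe = "columns")
    paths <- list(dir = dir)
  }
  list(genome = genome, counts = counts, snps = snps, bins = bins,
       mean_expr = mean_expr, paths = paths)
}
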