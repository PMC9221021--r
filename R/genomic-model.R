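# Coordinate conventions: 0-based half-open [start, end) everywhere (BED).
# A TSS is a single 0-based point supplied by the annotation (not recomputed
# from strand here).

#' Construct a validated table of genomic intervals
#'
#' @param chrom chromosome names.
#' @param start,end 0-based half-open coordinates, `start < end`, `start >= 0`.
#' @param id unique interval identifiers.
#' @return data.frame with columns chrom, start, end, id.
#' @export
genomic_intervals <- function(chrom, start, end, id) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start), end = as.numeric(end),
                   id = as.character(id), stringsAsFactors = FALSE)
  if (any(df$start < 0)) stop("interval start must be >= 0")
  if (any(df$start >= df$end)) stop("interval start must be < end")
  if (anyDuplicated(df$id)) stop("interval ids must be unique")
  df
}

#' Build a TAD / inter-TAD partition of the genome
#'
#' TADs plus the inter-TAD gaps between and flanking them form a full
#' partition of every chromosome carrying at least one TAD (and a single
#' inter-TAD domain for chromosomes with none). Inter-TAD gaps, including
#' chromosome-terminal ones, are first-class domains: peaks and genes can be
#' linked within them exactly as within TADs.
#'
#' @param tads data.frame of TAD intervals (chrom, start, end[, id]).
#' @param chrom_sizes named numeric vector, chromosome -> length in bp.
#' @return object of class `tad_map`: list with `domains` (data.frame chrom,
#'   start, end, domain (global 1-based index), is_tad) and `chrom_sizes`.
#' @export
build_tad_map <- function(tads, chrom_sizes) {
  stopifnot(is.numeric(chrom_sizes), !is.null(names(chrom_sizes)))
  if (nrow(tads) > 0) {
    bad_chrom <- setdiff(unique(tads$chrom), names(chrom_sizes))
    if (length(bad_chrom))
      stop("TADs on chromosomes absent from chrom_sizes: ",
           paste(bad_chrom, collapse = ", "))
  }
  dom_list <- list()
  for (ch in names(chrom_sizes)) {
    len <- chrom_sizes[[ch]]
    t_ch <- tads[tads$chrom == ch, , drop = FALSE]
    t_ch <- t_ch[order(t_ch$start, t_ch$end), , drop = FALSE]
    if (nrow(t_ch) > 0) {
      if (any(t_ch$end > len) || any(t_ch$start < 0)) {
        bad <- which(t_ch$end > len | t_ch$start < 0)[1]
        stop(sprintf("TAD [%g,%g) exceeds chromosome %s bounds [0,%g)",
                     t_ch$start[bad], t_ch$end[bad], ch, len))
      }
      ov <- which(t_ch$start[-1] < t_ch$end[-nrow(t_ch)])
      if (length(ov)) {
        i <- ov[1]
        stop(sprintf(
          "overlapping TADs on %s: [%g,%g) and [%g,%g)",
          ch, t_ch$start[i], t_ch$end[i], t_ch$start[i + 1], t_ch$end[i + 1]))
      }
    }
    # interleave gaps and TADs, dropping zero-width gaps
    bounds <- c(0, as.vector(rbind(t_ch$start, t_ch$end)), len)
    starts <- bounds[-length(bounds)]
    ends <- bounds[-1]
    is_tad <- rep(FALSE, length(starts))
    if (nrow(t_ch) > 0) is_tad[seq(2, by = 2, length.out = nrow(t_ch))] <- TRUE
    keep <- ends > starts
    dom_list[[ch]] <- data.frame(chrom = ch, start = starts[keep],
                                 end = ends[keep], is_tad = is_tad[keep],
                                 stringsAsFactors = FALSE)
  }
  domains <- do.call(rbind, dom_list)
  rownames(domains) <- NULL
  domains$domain <- seq_len(nrow(domains))
  domains <- domains[, c("chrom", "start", "end", "domain", "is_tad")]
  structure(list(domains = domains, chrom_sizes = chrom_sizes),
            class = "tad_map")
}

#' Assign intervals or points to TAD/inter-TAD domains
#'
#' Intervals are assigned by their midpoint `floor((start + end) / 2)`, so an
#' interval spanning a domain boundary receives exactly one domain,
#' deterministically. Points (TSSs, SNPs) pass `end = NULL`.
#'
#' @param chrom chromosome names (vectorized).
#' @param start 0-based start (or point position).
#' @param end 0-based exclusive end, or NULL for points.
#' @param tadmap a `tad_map`.
#' @return integer vector of global domain indices.
#' @export
assign_to_domain <- function(chrom, start, end = NULL, tadmap) {
  stopifnot(inherits(tadmap, "tad_map"))
  pos <- if (is.null(end)) as.numeric(start) else floor((start + end) / 2)
  chrom <- as.character(chrom)
  unknown <- setdiff(unique(chrom), names(tadmap$chrom_sizes))
  if (length(unknown))
    stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
  out <- integer(length(pos))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    d <- tadmap$domains[tadmap$domains$chrom == ch, , drop = FALSE]
    idx <- findInterval(pos[sel], d$start)
    if (any(idx < 1) || any(pos[sel] >= d$end[nrow(d)]))
      stop("position outside chromosome ", ch)
    out[sel] <- d$domain[idx]
  }
  out
}

#' Link peaks to genes sharing a TAD/inter-TAD domain
#'
#' A (peak, gene) pair is emitted iff the peak's midpoint and the gene's TSS
#' fall in the same domain. Output is sorted by peak_id then gene_id.
#'
#' @param peaks data.frame (chrom, start, end, id).
#' @param genes data.frame (gene_id, chrom, tss[, strand]).
#' @param tadmap a `tad_map`.
#' @return object of class `region_gene_links`: list with `links` (data.frame
#'   peak_id, gene_id, domain) and `domain_of` (named integer vector over both
#'   peak and gene ids).
#' @export
link_peaks_to_genes <- function(peaks, genes, tadmap) {
  if (nrow(peaks) == 0 || nrow(genes) == 0) {
    links <- data.frame(peak_id = character(), gene_id = character(),
                        domain = integer(), stringsAsFactors = FALSE)
    return(structure(list(links = links, domain_of = integer()),
                     class = "region_gene_links"))
  }
  pd <- assign_to_domain(peaks$chrom, peaks$start, peaks$end, tadmap)
  gd <- assign_to_domain(genes$chrom, genes$tss, NULL, tadmap)
  names(pd) <- peaks$id
  names(gd) <- genes$gene_id
  by_dom <- split(genes$gene_id, gd)
  hit <- as.character(pd) %in% names(by_dom)
  rows <- lapply(which(hit), function(i) {
    g <- by_dom[[as.character(pd[i])]]
    data.frame(peak_id = peaks$id[i], gene_id = unname(g),
               domain = unname(pd[i]), stringsAsFactors = FALSE)
  })
  links <- if (length(rows)) do.call(rbind, rows) else
    data.frame(peak_id = character(), gene_id = character(),
               domain = integer(), stringsAsFactors = FALSE)
  links <- links[order(links$peak_id, links$gene_id), , drop = FALSE]
  rownames(links) <- NULL
  structure(list(links = links, domain_of = c(pd, gd)),
            class = "region_gene_links")
}
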