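---
title: "Scoring focal-motif CREs and their cis-regulatory grammar in single-nuclei multiomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring focal-motif CREs and their cis-regulatory grammar in single-nuclei multiomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cregrammar)
```

## The problem

Single-nuclei multiomic studies (snRNA-seq plus snATAC-seq of the same
tissue) ask how a focal transcription factor (TF) — here a homeodomain
factor expressed in pulmonary-vein and left-atrial cardiomyocytes — drives
cell-type-specific gene expression through the cis-regulatory elements (CREs)
it binds. `cregrammar` implements the downstream computations of such a
study as reusable, tested functions:

1. score accessible peaks for focal-motif activity (the **normalized motif
   score**, NMS);
2. link peaks to genes through **TAD/inter-TAD domains**;
3. describe the **cis-regulatory grammar** — which TF families co-occur with
   the focal motif at CREs of up- versus down-regulated genes — as
   correlation networks with spectral communities;
4. provide the surrounding statistics (Wilcoxon differential calling,
   composition chi-square, Fisher enrichment);
5. relate the perturbed genes to human GWAS through SNP-window genes,
   ortholog transfer, expression binning and a one-sided Welch test.

Everything runs on synthetic data with planted ground truth
(`simulate_study()`), so every stage's statistical behaviour — calibration
under the null, power at planted effects — is verifiable without access to
any deposited dataset.

## The normalized motif score

For peak $i$ in a nucleus population, with pseudo-bulk accessibility $A_i$
(mean raw fragment count per nucleus), focal-motif occurrence count $O_i$,
and peak length $L_i$ in bp:

$$\mathrm{NMS}_i = \frac{A_i \times O_i}{L_i} \times 10{,}000$$

A peak is an **active** focal-motif site iff $\mathrm{NMS}_i > 1$, strictly:
a peak with $\mathrm{NMS} = 1$ exactly is inactive. $A_i$ deliberately uses
raw (non-normalized) counts: the score's scale is absorbed by the
$\times 10{,}000$ factor, and the $>1$ rule is calibrated against that
convention. $O_i$ counts all scanned occurrences on both strands without
overlap pruning; deduplication of overlapping windows is not applied (the
occurrence count, not the covered base count, is the unit).

## Motif scanning with exact thresholds

Occurrences come from a PWM scan with an exact null p-value threshold
(`score_threshold_for_pvalue()`, default $\alpha = 10^{-4}$). Scores are
log2 odds of the pseudocounted motif model against a 0-order background
(mixing weight $\varepsilon = 10^{-4}$ toward the background avoids
$-\infty$ scores), discretized at $10^{-3}$ log2 units. The null score
distribution is computed by exact dynamic programming over the discretized
per-position distributions, so the threshold is the *smallest achievable*
score $s$ with $P(\text{score} \ge s) \le \alpha$ — identical to exhaustive
enumeration of all $4^L$ words (asserted in the tests for $L \le 8$). Note a
consequence the tests also exercise: a 6-bp motif cannot pass
$\alpha = 10^{-4}$ at a uniform background because even the consensus word
has $P = 4^{-6} \approx 2.4 \times 10^{-4}$; the built-in synthetic motif
library therefore uses 8-bp motifs.

Both strands are scanned (the reverse strand through the reverse-complemented
matrix at the same threshold); windows containing `N` are skipped; ties and
orderings are deterministic.

## TAD-constrained peak-to-gene linking

Peaks and TSSs are assigned to a full partition of each chromosome into TADs
and inter-TAD gaps (`build_tad_map()`), both first-class domains, including
chromosome-terminal gaps. A (peak, gene) link exists iff both fall in the
same domain. Two conventions the underlying study leaves open are fixed
here:

* **Boundary-spanning peaks** are assigned by midpoint,
  $\lfloor (start + end)/2 \rfloor$ — deterministic and unbiased.
* **Terminal inter-TAD gaps** are kept as domains, treating "TAD/inter-TAD"
  symmetrically.

Coordinates are 0-based half-open throughout (BED convention); a TSS is a
single 0-based point supplied by the annotation.

## CRE selection and grammar networks

For a population and a direction $d \in \{up, down\}$, the CRE set is: peaks
with active NMS, linked to at least one DEG of direction $d$
(`select_cres()`). On a peak set, each TF family gets a binary presence
indicator (restricted to motifs of *expressed* TFs — default: TF gene
detected in $\ge 5\%$ of the population's nuclei); the **grammar matrix** is
the Pearson correlation between family indicators. Binary presence (not
occurrence counts) is used because colocalization is defined as "at least
one motif present"; zero-variance families are marked missing and excluded
from networks.

The **grammar network** thresholds the correlations (default: keep $r > 0$)
and finds communities by the leading-eigenvector method: recursively split
by the sign pattern of the eigenvector of the (generalized) modularity
matrix belonging to its largest positive eigenvalue, stopping when no
positive eigenvalue exists or the split does not increase modularity. Two
determinism conventions: eigenvectors are oriented so the entry of the
lexicographically smallest node is non-negative, and zero entries join the
positive side. On all graphs small enough to enumerate, the returned
partition's modularity is bounded by the exhaustive optimum and attains it
on well-separated fixtures (tested).

The **differential grammar** (up- vs down-regulated genes) is the
element-wise contrast $r_{up} - r_{down}$; missing entries propagate. The
peak universe for the contrast is configurable: the strict focal-motif CRE
sets, or all active linked peaks irrespective of focal-motif content (pass
the corresponding peak sets to `cooccurrence_correlation()`).

## Differential statistics

* **DEGs/DARs** (`wilcoxon_markers()`, `call_dars()`): per-nucleus counts
  are rescaled to a common total of 10,000; the Wilcoxon rank-sum test is
  exact (full enumeration of label assignments, valid under ties) when
  $n_A + n_B \le 12$ and a tie-corrected normal approximation with
  continuity correction otherwise; BH FDR across tested features. A feature
  is tested only if detected in $\ge 10\%$ of nuclei of one group
  (configurable). Direction rules are strict: up iff
  $\log_2 FC > 0.25$ *and* $FDR < 0.01$. The same thresholds are reused for
  DARs (configurable; the study states them only for genes).
  $\log_2 FC = \log_2((\bar x_A + 1)/(\bar x_B + 1))$ on the rescaled scale —
  monotone and pseudocounted, which is all downstream logic relies on.
* **Composition** (`composition_test()`): per cluster and sample pair, a
  2x2 (cluster vs rest) chi-square without continuity correction;
  significance at $FDR < 10^{-5}$.
* **Enrichment**: all 2x2 enrichment tests are two-sided Fisher exact tests.
  The sample odds ratio $ad/bc$ is reported with a $+\infty$ sentinel and a
  Haldane–Anscombe corrected companion; FDR always from the raw exact p.
  The DEG–DAR association universe defaults to genes with $\ge 1$ linked
  peak (the study does not state one; configurable).

## GWAS cell-type enrichment

SNP-associated genes are those with a TSS within $\pm 500$ kb of a tagging
SNP, boundary inclusive. Human-to-mouse transfer takes the union of two
catalogs, deduplicated, keeping one-to-many pairs. Within each cluster,
genes are binned: bin 0 iff mean expression is exactly 0, the rest ranked
ascending (ties broken by gene id) into 25 equal-size bins, remainder to the
lowest bins — so binning is invariant under any strictly monotone transform
of the means. Enrichment per cluster is a one-sided (greater) Welch t-test
of bin values, SNP-associated vs the rest, with BH correction across
clusters; bin indices (not underlying means) are the test variable, matching
the binned-expression reading of the method. A variance floor
$\varepsilon = 10^{-12}$ keeps the statistic finite on degenerate synthetic
groups. "Top 20th percentile" means bins 21–25 of 25 — the only reading
consistent with 25 equal bins.

## The synthetic study and what it does (not) show

`synthetic_config()` fixes the study conditions: two cardiomyocyte-like
populations of 50 nuclei per genotype; negative-binomial counts at
dispersion 0.3; planted 4-fold ($\log_2 = 2$) expression and accessibility
effects; a family pair (Tbox–bHLH) co-occurring at odds ratio 9 restricted
to focal-motif peaks linked to upregulated genes; 40 SNPs placed at odds 9
toward genes in the planted cluster's top expression quintile. Sequences
are iid uniform ACGT with consensus insertions at recorded positions; one
master seed drives a named substream per artifact, so every output is
byte-reproducible and regenerating one artifact does not perturb the others.

Design choices worth knowing:

* **Planted DEGs occupy distinct domains** (per population) wherever the
  domain count allows. Without this, a domain carrying both an up- and a
  down-regulated planted gene makes the direction label of its peaks
  ambiguous — the planted truth itself, not the method, becomes ill-defined.
* **DEG–DAR coupling** is off by default (`dar_deg_coupling = 1`); when
  enabled, a planted DAR of direction $d$ is placed with the configured
  weight on peaks in domains hosting a same-direction planted DEG.
* **Orthology** is simulated as a prefix rename (`HS_`) with a 10% unmapped
  fraction and duplicate listings across two source tags, keeping the join
  and dedup logic honest without shipping real catalogs.
* **Problem sizes** used by the validation suite: grammar recovery runs at
  500 peaks with 100 genes over ~50 domains (so planted DEGs sit in distinct
  domains) and a focal-motif prevalence of 0.8 — prevalence in that range is
  what the underlying biology reports for focal-motif CREs at DEGs; GWAS
  recovery runs at 40 SNPs over 2,000 genes with a gene density of about one
  gene per ±500 kb window, emulating GWAS loci that tag a small number of
  genes; the DEG–DAR coupling check uses ~2 genes per domain, where
  domain-level coupling is identifiable at the gene level. With many genes
  per domain, co-habitant genes dilute the gene-level odds ratio toward a
  small constant — a geometric fact about TAD-constrained linking, not a
  power failure.

What passing tests show: exactness of the scores and exact tests,
calibration under planted nulls, and recovery of planted effects under the
stated conditions. What they do not show: behaviour under real chromatin
fragment models, doublets, batch effects, ambient contamination, correlated
gene programs, or LD structure — none of which the generator emulates.

## Numerical conventions

* Score discretization $10^{-3}$ log2 units; thresholds compare discretized
  scores, so scanner and enumeration agree exactly.
* All output orderings (links, hits, tables) are deterministic; ties break
  lexicographically.
* Degenerate 2x2 tables (a zero margin) are reported as not-computable
  records rather than errors.
* Exact rank-sum enumeration caps at $n_A + n_B \le 12$
  ($\binom{12}{6} = 924$ assignments).
* `fisher.test`'s conditional-MLE odds ratio is *not* used; the sample OR is
  reported (with the Haldane–Anscombe companion) because downstream logic
  and the tests reason about $ad/bc$.

## A worked run

```{r example, eval = FALSE}
cfg <- synthetic_config(seed = 1)
st <- simulate_study(cfg, dir = "synthetic")

# scan, score, select CREs for CM1
lab <- st$counts$labels
cm1 <- lab$barcode[lab$population == "CM1"]
hits <- scan_peaks(st$genome$sequences, st$genome$pwms, alpha = 1e-4)
hm <- build_hit_matrix(hits, st$genome$peaks, st$genome$familymap)
A <- pseudobulk_accessibility(st$counts$peak_counts, cm1)
nms <- compute_nms(A, hm, "PITX2.syn", st$genome$peaks, "CM1")
head(nms[nms$active, ])
```

The numbered scripts under `analysis/` run the full workflow on the
synthetic study (simulate, differential statistics, NMS + grammar, GWAS) and
write their tables under `results/`; `scripts/acceptance.R` recomputes the
headline quantities from scratch at a given seed.

## Known limitations

* The scanner's background model is 0-order; strand symmetry of hit sets is
  exact only for a complement-symmetric background (the default uniform one
  is).
* The leading-eigenvector method explores recursive bisections only; on
  graphs where the optimal partition is not reachable by bisection it can
  return a lower-modularity partition (bounded by the exhaustive optimum in
  tests).
* Pseudobulk NMS compares populations on raw mean counts; depth differences
  between populations are not corrected, by design — apply external
  normalization first if populations differ grossly in per-nucleus depth.
* The Wilcoxon caller tests nuclei as replicates (no pseudo-replication or
  covariate regression), matching the study-level method it implements.
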