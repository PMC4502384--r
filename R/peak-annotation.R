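## peak_annotation: nearest-gene assignment, promoter binding calls,
## two-factor co-binding classification, and peak-set overlap statistics.

## anchor of a peak: summit when present, else interval midpoint (floor)
peak_anchor <- function(peaks) {
  ifelse(is.na(peaks$summit), (peaks$start + peaks$end) %/% 2L, peaks$summit)
}

## 0-based position of the TSS base
tss0 <- function(genes) genes$tss - 1L

#' Assign each peak to its nearest gene TSS
#'
#' The peak anchor (summit if present, else midpoint) is matched to the
#' gene minimizing `|anchor - tss|` on the same chromosome; ties break by
#' lexicographic gene_id.  The signed distance is strand-aware: negative
#' means upstream of the TSS.  Region labels: `promoter` when the
#' distance falls in the annotation window (default -1000..+100),
#' `gene_body` when the anchor lies inside the assigned gene's span,
#' else `intergenic`.  Peaks on chromosomes absent from the annotation
#' get gene_id NA and label `intergenic` (with a warning).
#'
#' @param peaks peak data.frame ([read_bed_peaks()])
#' @param genes gene data.frame ([read_gene_table()])
#' @param promoter_window length-2 numeric, signed distance bounds for
#'   the promoter label (inclusive)
#' @return data.frame peak_name, chrom, anchor, gene_id, distance, region_label
#' @export
assign_peaks_to_genes <- function(peaks, genes, promoter_window = c(-1000, 100)) {
  stopifnot(length(promoter_window) == 2L, promoter_window[1] <= promoter_window[2])
  anchor <- peak_anchor(peaks)
  n <- nrow(peaks)
  gene_id <- rep(NA_character_, n)
  distance <- rep(NA_integer_, n)
  label <- rep("intergenic", n)
  ## genes ordered by id so which.min's first-match rule breaks ties
  ## lexicographically
  genes <- genes[order(genes$gene_id), , drop = FALSE]
  gt <- tss0(genes)
  missing_chrom <- character(0)
  for (i in seq_len(n)) {
    sel <- which(genes$chrom == peaks$chrom[i])
    if (length(sel) == 0L) { missing_chrom <- c(missing_chrom, peaks$chrom[i]); next }
    d <- abs(anchor[i] - gt[sel])
    j <- sel[which.min(d)]
    gene_id[i] <- genes$gene_id[j]
    raw <- anchor[i] - gt[j]
    distance[i] <- if (genes$strand[j] == "+") raw else -raw
    if (distance[i] >= promoter_window[1] && distance[i] <= promoter_window[2]) {
      label[i] <- "promoter"
    } else if (anchor[i] >= genes$start[j] && anchor[i] < genes$end[j]) {
      label[i] <- "gene_body"
    }
  }
  if (length(missing_chrom))
    warning(sprintf("%d peak(s) on chromosome(s) absent from annotation: %s",
                    length(missing_chrom), paste(unique(missing_chrom), collapse = ", ")))
  data.frame(peak_name = peaks$name, chrom = peaks$chrom, anchor = anchor,
             gene_id = gene_id, distance = distance, region_label = label,
             stringsAsFactors = FALSE)
}

#' Promoter binding call for one or more genes
#'
#' A gene is called bound when some peak anchor lies within `max_dist`
#' bases of its TSS, inclusive on both sides.
#'
#' @param peaks peak data.frame
#' @param genes gene data.frame (one row per gene)
#' @param max_dist maximum anchor-to-TSS distance in bases (default 500)
#' @return logical vector, one per gene
#' @export
call_promoter_binding <- function(peaks, genes, max_dist = 500L) {
  stopifnot(max_dist >= 0)
  if (nrow(peaks) == 0L) return(rep(FALSE, nrow(genes)))
  anchor <- peak_anchor(peaks)
  gt <- tss0(genes)
  vapply(seq_len(nrow(genes)), function(i) {
    any(peaks$chrom == genes$chrom[i] & abs(anchor - gt[i]) <= max_dist)
  }, TRUE)
}

#' Classify genes by two-factor promoter co-binding
#'
#' Combines the per-factor [call_promoter_binding()] verdicts into the
#' partition both / A_only / B_only / none over the gene universe.
#'
#' @param peaks_A,peaks_B peak data.frames for the two factors
#' @param genes gene universe
#' @param max_dist anchor-to-TSS distance for the binding call
#' @param factors length-2 character, factor names for provenance
#' @return data.frame gene_id, class (with attributes `factors`,
#'   `max_dist`, and a `counts` table)
#' @export
classify_cobinding <- function(peaks_A, peaks_B, genes, max_dist = 500L,
                               factors = c("A", "B")) {
  if (nrow(genes) == 0L) stop("empty gene universe")
  stopifnot(length(factors) == 2L, factors[1] != factors[2])
  a <- call_promoter_binding(peaks_A, genes, max_dist)
  b <- call_promoter_binding(peaks_B, genes, max_dist)
  class <- ifelse(a & b, "both", ifelse(a, "A_only", ifelse(b, "B_only", "none")))
  out <- data.frame(gene_id = genes$gene_id, class = class, stringsAsFactors = FALSE)
  attr(out, "factors") <- factors
  attr(out, "max_dist") <- max_dist
  attr(out, "counts") <- table(factor(class, levels = c("both", "A_only", "B_only", "none")))
  out
}

#' Overlap two peak sets with a hypergeometric significance model
#'
#' A peak in set A counts as overlapping when some peak in B has an
#' anchor within `threshold` bases or an intersecting interval.
#' Significance uses a genome-binning null: the genome is divided into
#' bins of width `2*threshold`; with `a` bins occupied by A anchors and
#' `b` by B anchors out of `N`, the upper-tail hypergeometric
#' probability of the observed number of shared bins is reported as
#' log10.
#'
#' @param peaks_A,peaks_B peak data.frames
#' @param threshold anchor-distance threshold in bases (default 100)
#' @param genome_size total genome length in bases
#' @return list n_A, n_B, n_overlap, n_shared_bins, expected_overlap, log10_p
#' @export
overlap_peak_sets <- function(peaks_A, peaks_B, threshold = 100L, genome_size) {
  stopifnot(threshold >= 0)
  if (genome_size <= 0) stop("genome_size must be positive")
  n_A <- nrow(peaks_A); n_B <- nrow(peaks_B)
  aA <- peak_anchor(peaks_A); aB <- peak_anchor(peaks_B)
  hit <- vapply(seq_len(n_A), function(i) {
    same <- peaks_B$chrom == peaks_A$chrom[i]
    if (!any(same)) return(FALSE)
    any(abs(aB[same] - aA[i]) <= threshold) ||
      any(peaks_B$start[same] < peaks_A$end[i] & peaks_A$start[i] < peaks_B$end[same])
  }, TRUE)
  n_overlap <- sum(hit)

  binw <- max(1L, 2L * as.integer(threshold))
  ## bins keyed by chromosome so different chromosomes never share a bin
  bin_id <- function(peaks, anchors)
    unique(paste0(peaks$chrom, ":", anchors %/% binw))
  bins_A <- bin_id(peaks_A, aA)
  bins_B <- bin_id(peaks_B, aB)
  N <- as.integer(ceiling(genome_size / binw))
  a <- length(bins_A); b <- length(bins_B)
  shared <- length(intersect(bins_A, bins_B))
  expected <- a * b / N
  log10_p <- stats::phyper(shared - 1L, b, N - b, a,
                           lower.tail = FALSE, log.p = TRUE) / log(10)
  list(n_A = n_A, n_B = n_B, n_overlap = n_overlap, n_shared_bins = shared,
       expected_overlap = expected, log10_p = log10_p)
}
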