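## promoter_signal: the max-average sliding-window enrichment statistic.

#' Maximum average signal over a sliding window
#'
#' Slides a length-`window_w` window (step 1) across the interval and
#' returns the largest window mean.  Intervals shorter than the window
#' fall back to the mean over the whole interval; empty intervals give 0.
#' Bases beyond the recorded track are treated as coverage 0.
#'
#' @param values numeric per-base coverage vector for one chromosome
#' @param start,end interval, 0-based half-open
#' @param window_w window width in bases (>= 1)
#' @return the max-average statistic (nonnegative if the track is)
#' @export
max_average_signal <- function(values, start, end, window_w = 50L) {
  if (window_w <= 0) stop("window_w must be >= 1")
  start <- max(0L, as.integer(start)); end <- as.integer(end)
  if (end <= start) return(0)
  idx <- (start + 1L):end            # 1-based into values
  v <- numeric(length(idx))
  inside <- idx <= length(values)
  v[inside] <- values[idx[inside]]
  n <- length(v)
  if (n <= window_w) return(mean(v))
  cs <- cumsum(c(0, v))
  max(cs[(window_w + 1L):(n + 1L)] - cs[1L:(n - window_w + 1L)]) / window_w
}

#' Promoter enrichment table for one factor
#'
#' One record per gene: the max-average statistic over the gene's
#' strand-aware promoter window (default 500 bp upstream of the TSS).
#' Genes whose promoter window truncates to nothing, or whose chromosome
#' is absent from the track, get enrichment 0 with a warning.
#'
#' @param track coverage track ([read_coverage()])
#' @param genes gene data.frame
#' @param factor_name label recorded in the output
#' @param upstream,downstream promoter window relative to the TSS
#' @param window_w sliding-window width in bases
#' @param chrom_lengths optional named lengths for window truncation
#' @return data.frame gene_id, factor, enrichment, window_w, chrom, start, end
#' @export
build_enrichment_table <- function(track, genes, factor_name = "A",
                                   upstream = 500L, downstream = 0L,
                                   window_w = 50L, chrom_lengths = NULL) {
  if (nrow(genes) == 0L) stop("empty gene table")
  if (is.null(chrom_lengths))
    chrom_lengths <- vapply(track, length, 0L)
  iv <- promoter_interval(genes, upstream, downstream, chrom_lengths)
  enr <- numeric(nrow(iv))
  n_missing <- 0L; n_empty <- 0L
  for (i in seq_len(nrow(iv))) {
    if (!iv$chrom[i] %in% names(track)) { n_missing <- n_missing + 1L; next }
    if (iv$end[i] <= iv$start[i]) { n_empty <- n_empty + 1L; next }
    enr[i] <- max_average_signal(track[[iv$chrom[i]]], iv$start[i], iv$end[i], window_w)
  }
  if (n_missing > 0L)
    warning(sprintf("%d gene(s) on chromosomes missing from the track; enrichment set to 0", n_missing))
  if (n_empty > 0L)
    warning(sprintf("%d gene(s) with empty truncated promoter windows; enrichment set to 0", n_empty))
  data.frame(gene_id = iv$gene_id, factor = factor_name, enrichment = enr,
             window_w = window_w, chrom = iv$chrom, start = iv$start, end = iv$end,
             stringsAsFactors = FALSE)
}
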