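## association_stats: the motif-affinity / ChIP-enrichment correlation
## screen, the co-bound vs single-factor site-strength comparison, and
## gene-set binding-fraction summaries.

#' Pearson correlation with explicit degenerate handling
#'
#' Standard product-moment correlation.  Vectors shorter than 3 are an
#' error; a constant vector yields NA (undefined correlation), never 0.
#'
#' @param x,y numeric vectors of equal length
#' @return correlation in \[-1, 1\], or NA when undefined
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Motif-occupancy vs ChIP-enrichment correlation screen
#'
#' For every motif, the Pearson correlation between its per-gene
#' occupancy scores and the observed promoter enrichment of each factor,
#' computed on the intersection of the gene universes.  Categories
#' follow fixed correlation thresholds: `high` above `r_high`,
#' `negative` below 0, `medium` otherwise; the between-factor
#' correlation difference is `shared` below `delta_shared`,
#' `differential` above `delta_diff`, `intermediate` otherwise.
#' Results are sorted by `max(r_A, r_B)` descending; motifs with
#' constant occupancy are retained with NA correlations and a flag.
#'
#' @param occupancy genes x motifs matrix ([scan_promoters()])
#' @param enrichment_A,enrichment_B enrichment data.frames
#'   ([build_enrichment_table()]) or named numeric vectors
#' @param r_high,delta_shared,delta_diff categorization thresholds
#'   (defaults 0.19, 0.04, 0.14)
#' @return data.frame motif_id, r_A, r_B, delta, category_A, category_B,
#'   delta_category, constant_occupancy
#' @export
motif_association_screen <- function(occupancy, enrichment_A, enrichment_B,
                                     r_high = 0.19, delta_shared = 0.04,
                                     delta_diff = 0.14) {
  as_vec <- function(e) {
    if (is.data.frame(e)) stats::setNames(e$enrichment, e$gene_id) else e
  }
  eA <- as_vec(enrichment_A); eB <- as_vec(enrichment_B)
  genes <- Reduce(intersect, list(rownames(occupancy), names(eA), names(eB)))
  if (length(genes) < 3L) stop("gene universes intersect in fewer than 3 genes")
  eA <- eA[genes]; eB <- eB[genes]
  occ <- occupancy[genes, , drop = FALSE]
  categorize <- function(r) {
    ifelse(is.na(r), NA_character_,
           ifelse(r > r_high, "high", ifelse(r < 0, "negative", "medium")))
  }
  res <- lapply(colnames(occ), function(m) {
    o <- occ[, m]
    const <- stats::sd(o) == 0
    r_A <- if (const || stats::sd(eA) == 0) NA_real_ else stats::cor(o, eA)
    r_B <- if (const || stats::sd(eB) == 0) NA_real_ else stats::cor(o, eB)
    delta <- abs(r_A - r_B)
    data.frame(motif_id = m, r_A = r_A, r_B = r_B, delta = delta,
               category_A = categorize(r_A), category_B = categorize(r_B),
               delta_category = ifelse(is.na(delta), NA_character_,
                                       ifelse(delta < delta_shared, "shared",
                                              ifelse(delta > delta_diff, "differential",
                                                     "intermediate"))),
               constant_occupancy = const, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  key <- pmax(out$r_A, out$r_B)
  out <- out[order(-key, out$motif_id, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_genes") <- length(genes)
  out
}

#' Mann-Whitney U test (one-sided)
#'
#' U from midrank assignment.  The p-value is exact (enumeration of the
#' rank-sum distribution) when `n_x + n_y <= 20` and there are no ties,
#' else the normal approximation with tie correction and continuity
#' correction.
#'
#' @param x,y numeric samples (non-empty)
#' @param alternative `x_greater` tests whether x is stochastically
#'   larger than y; `y_greater` the reverse
#' @return list U (for x), p_one_sided, method
#' @export
mann_whitney_u <- function(x, y, alternative = c("x_greater", "y_greater")) {
  alternative <- match.arg(alternative)
  if (length(x) == 0L || length(y) == 0L) stop("empty sample")
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- any(duplicated(c(x, y)))
  exact <- (nx + ny <= 20L) && !ties
  wt <- suppressWarnings(stats::wilcox.test(
    x, y, alternative = if (alternative == "x_greater") "greater" else "less",
    exact = exact, correct = TRUE))
  list(U = U, p_one_sided = wt$p.value,
       method = if (exact) "exact" else "normal_approx")
}

#' Compare motif site strength between co-bound and single-factor promoters
#'
#' Pools the non-overlapping sites of one motif across the promoters of
#' each co-binding group, transforms site p-values to -log10 (stronger
#' site = larger value), and tests whether the co-bound group's site
#' strengths are stochastically larger (one-sided Mann-Whitney U).  The
#' opposite direction is reported as its own column rather than by
#' flipping the hypothesis.  A group with zero sites makes the result
#' untestable (no p reported).
#'
#' @param sites site table with columns sequence_id, motif_id, p_value
#'   (sites already non-overlapping per promoter)
#' @param cobinding co-binding table ([classify_cobinding()])
#' @param motif_id motif to test
#' @param groups length-2 character: the co-bound class and the
#'   single-factor class (defaults `both` vs `B_only`)
#' @param alpha significance threshold on the one-sided p (default 0.05)
#' @return one-row data.frame motif_id, n_cobound, n_single, U,
#'   p_cobound_greater, p_single_greater, direction, significant, testable
#' @export
site_strength_comparison <- function(sites, cobinding, motif_id,
                                     groups = c("both", "B_only"), alpha = 0.05) {
  stopifnot(length(groups) == 2L)
  ms <- sites[sites$motif_id == motif_id, , drop = FALSE]
  g1 <- cobinding$gene_id[cobinding$class == groups[1L]]
  g2 <- cobinding$gene_id[cobinding$class == groups[2L]]
  s1 <- -log10(ms$p_value[ms$sequence_id %in% g1])
  s2 <- -log10(ms$p_value[ms$sequence_id %in% g2])
  base <- data.frame(motif_id = motif_id, n_cobound = length(s1),
                     n_single = length(s2), stringsAsFactors = FALSE)
  if (length(s1) == 0L || length(s2) == 0L) {
    return(cbind(base, U = NA_real_, p_cobound_greater = NA_real_,
                 p_single_greater = NA_real_, direction = NA_character_,
                 significant = NA, testable = FALSE))
  }
  up <- mann_whitney_u(s1, s2, "x_greater")
  down <- mann_whitney_u(s1, s2, "y_greater")
  direction <- if (up$U > length(s1) * length(s2) / 2) "cobound" else
    if (up$U < length(s1) * length(s2) / 2) "single" else "tied"
  cbind(base, U = up$U, p_cobound_greater = up$p_one_sided,
        p_single_greater = down$p_one_sided, direction = direction,
        significant = up$p_one_sided < alpha, testable = TRUE)
}

#' Site-strength comparison over a motif library
#'
#' Runs [site_strength_comparison()] per motif and appends a
#' Benjamini-Hochberg FDR column across testable motifs (advisory; the
#' raw one-sided threshold reproduces the primary decision rule).
#'
#' @inheritParams site_strength_comparison
#' @param motif_ids motifs to test (default: all in `sites`)
#' @export
site_strength_table <- function(sites, cobinding, motif_ids = NULL,
                                groups = c("both", "B_only"), alpha = 0.05) {
  if (is.null(motif_ids)) motif_ids <- unique(sites$motif_id)
  out <- do.call(rbind, lapply(motif_ids, function(m)
    site_strength_comparison(sites, cobinding, m, groups, alpha)))
  out$fdr <- NA_real_
  out$fdr[out$testable] <- stats::p.adjust(out$p_cobound_greater[out$testable], "BH")
  out
}

#' Binding fractions and enrichment of gene sets
#'
#' For each named gene set: the fraction of its (universe-resident)
#' genes bound by factor A (classes both or A_only) and by factor B
#' (both or B_only), plus upper-tail hypergeometric enrichment p-values
#' of the set among each factor's bound genes relative to the universe.
#' Genes absent from the universe are counted separately, never
#' silently dropped.
#'
#' @param gene_sets named list of character vectors of gene ids
#' @param cobinding co-binding table ([classify_cobinding()])
#' @return data.frame set, n_set, n_in_universe, n_missing, frac_A,
#'   frac_B, p_hyper_A, p_hyper_B
#' @export
binding_fraction_summary <- function(gene_sets, cobinding) {
  stopifnot(length(gene_sets) > 0, all(lengths(gene_sets) > 0))
  universe <- cobinding$gene_id
  bound_A <- cobinding$gene_id[cobinding$class %in% c("both", "A_only")]
  bound_B <- cobinding$gene_id[cobinding$class %in% c("both", "B_only")]
  N <- length(universe)
  one <- function(nm) {
    set <- unique(gene_sets[[nm]])
    inu <- intersect(set, universe)
    n <- length(inu)
    kA <- length(intersect(inu, bound_A)); kB <- length(intersect(inu, bound_B))
    hyp <- function(k, K) {
      if (n == 0L) return(NA_real_)
      stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    }
    data.frame(set = nm, n_set = length(set), n_in_universe = n,
               n_missing = length(set) - n,
               frac_A = if (n) kA / n else NA_real_,
               frac_B = if (n) kB / n else NA_real_,
               p_hyper_A = hyp(kA, length(bound_A)),
               p_hyper_B = hyp(kB, length(bound_B)),
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(names(gene_sets), one))
  rownames(out) <- NULL
  out
}
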