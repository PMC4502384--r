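## motif_engine: PWM log-odds scanning with exact site p-values under the
## i.i.d. background model, non-overlapping site extraction, and a
## parameter-free relative-affinity occupancy score per sequence.
##
## Scores are log2 odds throughout.  Site p-values come from the exact
## enumeration of all words for narrow motifs (width <= 6) and from a
## dynamic-programming convolution of per-position discretized score
## distributions otherwise (the classical MAST/FIMO construction).

EXACT_ENUM_MAX_WIDTH <- 6L

#' Scan configuration
#'
#' @param max_p site p-value cutoff (default 0.0005)
#' @param both_strands scan the reverse strand too (default TRUE)
#' @param n_policy `skip_window` drops windows containing N;
#'   `score_as_background` lets N contribute a zero log-odds term
#' @param bins score-discretization bins per position for the DP
#'   p-value distribution (>= 100)
#' @param e_value_cap accepted for MAST compatibility; the site-level
#'   `max_p` filter is the operative threshold and the cap is not applied
#' @export
scan_config <- function(max_p = 5e-4, both_strands = TRUE,
                        n_policy = c("skip_window", "score_as_background"),
                        bins = 1000L, e_value_cap = 10000) {
  stopifnot(max_p > 0, max_p <= 1, bins >= 100L)
  list(max_p = max_p, both_strands = both_strands,
       n_policy = match.arg(n_policy), bins = as.integer(bins),
       e_value_cap = e_value_cap)
}

#' Log-odds matrix of a PWM
#'
#' `entry[j, b] = log2(prob[j, b] / background[b])` for the regularized
#' probability matrix.
#'
#' @param pwm a pwm object ([new_pwm()])
#' @param background optional override of the PWM's background
#' @return width x 4 matrix (columns A,C,G,T)
#' @export
log_odds_matrix <- function(pwm, background = pwm$background) {
  if (any(background <= 0)) stop("zero background frequency")
  log2(sweep(pwm$prob, 2L, background, "/"))
}

encode_dna <- function(sequence) {
  code <- match(strsplit(toupper(sequence), "")[[1L]], DNA_BASES)
  code[is.na(code)] <- 5L      # N (and any other letter)
  code
}

## Exact score distribution: enumerate all 4^w words.
enum_distribution <- function(lom, background) {
  w <- nrow(lom)
  scores <- 0; probs <- 1
  for (j in seq_len(w)) {
    scores <- as.vector(outer(scores, lom[j, 1:4], "+"))
    probs <- as.vector(outer(probs, background, "*"))
  }
  key <- round(scores, 10L)
  agg <- rowsum(probs, key)
  grid <- as.numeric(rownames(agg))
  o <- order(grid)
  list(grid = grid[o], tails = rev(cumsum(rev(agg[o, 1L]))))
}

## DP over integer-quantized per-position scores.
dp_distribution <- function(lom, background, bins) {
  rng <- max(lom) - min(lom)
  if (rng <= 0) return(list(delta = 1, ik = matrix(0L, nrow(lom), 4L),
                            K0 = 0L, tails = 1))
  delta <- rng / bins
  ik <- matrix(as.integer(round(lom / delta)), nrow(lom), 4L)
  K0 <- sum(apply(ik, 1L, min)); K1 <- sum(apply(ik, 1L, max))
  d <- 1; off <- 0L                      # totals in off..off+length(d)-1
  for (j in seq_len(nrow(ik))) {
    mn <- min(ik[j, ]); mx <- max(ik[j, ])
    nd <- numeric(length(d) + (mx - mn))
    for (b in 1:4) {
      sh <- ik[j, b] - mn
      nd[(sh + 1L):(sh + length(d))] <- nd[(sh + 1L):(sh + length(d))] + background[b] * d
    }
    d <- nd; off <- off + mn
  }
  stopifnot(off == K0, length(d) == K1 - K0 + 1L)
  list(delta = delta, ik = ik, K0 = K0, tails = rev(cumsum(rev(d))))
}

## tail lookup for integer totals (vectorized, clamped)
dp_tail <- function(dist, k) {
  i <- pmin(pmax(k - dist$K0 + 1L, 1L), length(dist$tails))
  p <- dist$tails[i]
  p[which(k < dist$K0)] <- 1
  pmin(p, 1)
}

#' Exact site p-value function for a PWM
#'
#' Returns the right tail of the null score distribution under the
#' i.i.d. background model: `p(s) = P(score of a random window >= s)`.
#' The function is non-increasing and right-continuous with
#' `p(minimum score) = 1`.  Exact word enumeration is used for widths up
#' to 6; wider motifs use the discretized dynamic-programming
#' distribution (`bins` levels per position).
#'
#' @inheritParams log_odds_matrix
#' @param bins discretization bins per position (DP path)
#' @return function mapping log2-odds score(s) to p-value(s)
#' @export
site_pvalue_function <- function(pwm, background = pwm$background, bins = 1000L) {
  stopifnot(bins >= 100L)
  lom <- log_odds_matrix(pwm, background)
  if (nrow(lom) <= EXACT_ENUM_MAX_WIDTH) {
    en <- enum_distribution(lom, background)
    function(s) {
      pos <- findInterval(s - 1e-9, en$grid)
      idx <- pmin(pos + 1L, length(en$grid))
      p <- en$tails[idx]
      p[which(pos >= length(en$grid))] <- en$tails[length(en$grid)]
      pmin(p, 1)
    }
  } else {
    dist <- dp_distribution(lom, background, bins)
    function(s) dp_tail(dist, as.integer(round(s / dist$delta)))
  }
}

#' Precompile a PWM for repeated scanning
#'
#' Bundles the forward and reverse-complement log-odds matrices, their
#' null score distributions, and the maximum achievable score, so that
#' scanning many sequences does not recompute them.
#'
#' @param pwm a pwm object
#' @param config a [scan_config()]
#' @return object of class `pwm_compiled`
#' @export
compile_pwm <- function(pwm, config = scan_config()) {
  bg <- pwm$background
  lom <- log_odds_matrix(pwm)
  rc_lom <- log2(sweep(pwm$prob[pwm$width:1L, 4:1, drop = FALSE], 2L, bg, "/"))
  exact <- pwm$width <= EXACT_ENUM_MAX_WIDTH
  mk <- function(m) {
    if (exact) list(exact = TRUE, en = enum_distribution(m, bg))
    else c(list(exact = FALSE), dp_distribution(m, bg, config$bins))
  }
  ## 5th column: N contributes 0 under score_as_background, flagged under
  ## skip_window
  pad <- function(m) cbind(m, 0)
  structure(list(pwm = pwm, width = pwm$width,
                 lom = pad(lom), rc_lom = pad(rc_lom),
                 fwd = mk(lom), rev = mk(rc_lom),
                 smax = sum(apply(lom, 1L, max)),
                 config = config),
            class = "pwm_compiled")
}

## raw window scores of matrix M (w x 5) along integer codes; NA for
## windows containing N when skipping
window_scores <- function(code, M, skip_n) {
  w <- nrow(M); L <- length(code)
  n <- L - w + 1L
  if (n < 1L) return(numeric(0))
  s <- numeric(n)
  for (j in seq_len(w)) s <- s + M[j, code[j:(j + n - 1L)]]
  if (skip_n && any(code == 5L)) {
    isn <- cumsum(code == 5L)
    bad <- (isn[w:L] - c(0L, isn[seq_len(n - 1L)])) > 0L
    s[bad] <- NA_real_
  }
  s
}

window_pvalues <- function(scores, dist) {
  if (dist$exact) {
    pos <- findInterval(scores - 1e-9, dist$en$grid)
    idx <- pmin(pos + 1L, length(dist$en$grid))
    p <- dist$en$tails[idx]
    p[which(pos >= length(dist$en$grid))] <- dist$en$tails[length(dist$en$grid)]
    pmin(p, 1)
  } else {
    dp_tail(dist, as.integer(round(scores / dist$delta)))
  }
}

#' Find motif sites in a sequence
#'
#' All windows (both strands when configured) whose site p-value is at
#' most `config$max_p`, sorted by offset.  Minus-strand sites are scored
#' on the reverse complement and reported in forward coordinates.
#' Sequences shorter than the motif give an empty result.
#'
#' @param sequence DNA string
#' @param pwm a pwm or pwm_compiled object
#' @param config a [scan_config()]
#' @return data.frame offset (0-based), strand, score, p_value
#' @export
find_sites <- function(sequence, pwm, config = scan_config()) {
  cp <- if (is(pwm, "pwm_compiled")) pwm else compile_pwm(pwm, config)
  empty <- data.frame(offset = integer(0), strand = character(0),
                      score = numeric(0), p_value = numeric(0))
  if (nchar(sequence) < cp$width) return(empty)
  code <- encode_dna(sequence)
  skip <- config$n_policy == "skip_window"
  out <- list()
  sf <- window_scores(code, cp$lom, skip)
  pf <- window_pvalues(sf, cp$fwd)
  keep <- !is.na(sf) & pf <= config$max_p
  if (any(keep))
    out$f <- data.frame(offset = which(keep) - 1L, strand = "+",
                        score = sf[keep], p_value = pf[keep])
  if (config$both_strands) {
    sr <- window_scores(code, cp$rc_lom, skip)
    pr <- window_pvalues(sr, cp$rev)
    keep <- !is.na(sr) & pr <= config$max_p
    if (any(keep))
      out$r <- data.frame(offset = which(keep) - 1L, strand = "-",
                          score = sr[keep], p_value = pr[keep])
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$offset, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Greedy non-overlapping site selection
#'
#' Sites are visited by ascending p-value (ties: lower offset, then +
#' strand); a site is kept iff it shares no base with an already-kept
#' site.  The result is sorted by offset.
#'
#' @param sites site data.frame from [find_sites()] (one sequence, one motif)
#' @param width motif width in bases
#' @return filtered site data.frame
#' @export
nonoverlapping_sites <- function(sites, width) {
  if (nrow(sites) <= 1L) return(sites)
  o <- order(sites$p_value, sites$offset, sites$strand)
  kept <- integer(0)
  for (i in o) {
    s <- sites$offset[i]; e <- s + width
    if (!any(sites$offset[kept] < e & s < sites$offset[kept] + width))
      kept <- c(kept, i)
  }
  res <- sites[sort(kept), , drop = FALSE]
  res <- res[order(res$offset), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Relative-affinity occupancy score of a sequence
#'
#' Sum over all windows (both strands by default) of the relative
#' affinity `2^(s - s_max)`, where `s` is the window's log2-odds score
#' and `s_max` the maximum achievable score of the motif.  A sequence
#' consisting solely of the consensus word contributes 1 per matching
#' strand; background windows contribute nearly 0.  This is a
#' parameter-free stand-in for a fitted thermodynamic occupancy model:
#' it preserves the ranking contract of a correlation screen without a
#' fitted concentration parameter.
#'
#' @param sequence DNA string (length < width gives 0)
#' @param pwm a pwm or pwm_compiled object
#' @param both_strands include the reverse strand (default TRUE)
#' @param config a [scan_config()] (controls N handling)
#' @return nonnegative real
#' @export
occupancy_score <- function(sequence, pwm, both_strands = TRUE,
                            config = scan_config()) {
  cp <- if (is(pwm, "pwm_compiled")) pwm else compile_pwm(pwm, config)
  if (nchar(sequence) < cp$width) return(0)
  code <- encode_dna(sequence)
  skip <- config$n_policy == "skip_window"
  s <- window_scores(code, cp$lom, skip)
  occ <- sum(2^(s - cp$smax), na.rm = TRUE)
  if (both_strands) {
    sr <- window_scores(code, cp$rc_lom, skip)
    occ <- occ + sum(2^(sr - cp$smax), na.rm = TRUE)
  }
  occ
}

#' Scan a set of promoter sequences with a motif library
#'
#' Convenience wrapper used by the pipeline: per-motif compiled scans
#' over all sequences, returning the pooled non-overlapping site table
#' and the sequence x motif occupancy matrix.
#'
#' @param seqs named character vector of sequences
#' @param motifs named list of pwm objects
#' @param config a [scan_config()]
#' @return list with `sites` (data.frame sequence_id, motif_id, offset,
#'   strand, score, p_value) and `occupancy` (matrix, sequences x motifs)
#' @export
scan_promoters <- function(seqs, motifs, config = scan_config()) {
  occ <- matrix(0, length(seqs), length(motifs),
                dimnames = list(names(seqs), names(motifs)))
  skip <- config$n_policy == "skip_window"
  ## one concatenated scan per motif: sequences joined with an N spacer,
  ## windows straddling sequence boundaries masked out explicitly
  lens <- nchar(seqs)
  codes <- lapply(seqs, encode_dna)
  spacer_w <- max(vapply(motifs, function(m)
    if (is(m, "pwm_compiled")) m$width else m$width, 0L))
  sep <- rep(5L, spacer_w)
  code_all <- unlist(lapply(codes, function(cc) c(cc, sep)), use.names = FALSE)
  seq_start0 <- cumsum(c(0L, lens[-length(lens)] + spacer_w))  # 0-based
  seq_end0 <- seq_start0 + lens

  all_sites <- list()
  for (m in names(motifs)) {
    cp <- if (is(motifs[[m]], "pwm_compiled")) motifs[[m]] else
      compile_pwm(motifs[[m]], config)
    w <- cp$width
    n <- length(code_all) - w + 1L
    if (n < 1L) next
    off0 <- 0L:(n - 1L)                       # 0-based window starts
    seq_i <- findInterval(off0, seq_start0)
    valid <- off0 + w <= seq_end0[seq_i]      # window inside one sequence
    sf <- window_scores(code_all, cp$lom, skip)
    sr <- if (config$both_strands) window_scores(code_all, cp$rc_lom, skip) else NULL
    aff <- 2^(sf - cp$smax)
    aff[!valid | is.na(sf)] <- 0
    ocol <- rowsum(aff, seq_i)
    occ[as.integer(rownames(ocol)), m] <- ocol[, 1L]
    if (!is.null(sr)) {
      aff <- 2^(sr - cp$smax)
      aff[!valid | is.na(sr)] <- 0
      ocol <- rowsum(aff, seq_i)
      occ[as.integer(rownames(ocol)), m] <- occ[as.integer(rownames(ocol)), m] + ocol[, 1L]
    }
    collect <- function(s, dist, strand) {
      p <- window_pvalues(s, dist)
      k <- which(valid & !is.na(s) & p <= config$max_p)
      if (length(k) == 0L) return(NULL)
      data.frame(seq_i = seq_i[k], offset = off0[k] - seq_start0[seq_i[k]],
                 strand = strand, score = s[k], p_value = p[k])
    }
    st <- rbind(collect(sf, cp$fwd, "+"),
                if (!is.null(sr)) collect(sr, cp$rev, "-"))
    if (is.null(st) || nrow(st) == 0L) next
    for (i in unique(st$seq_i)) {
      si <- st[st$seq_i == i, c("offset", "strand", "score", "p_value")]
      si <- nonoverlapping_sites(si[order(si$offset, si$strand), , drop = FALSE], w)
      if (nrow(si))
        all_sites[[length(all_sites) + 1L]] <-
          cbind(sequence_id = names(seqs)[i], motif_id = m, si)
    }
  }
  sites <- if (length(all_sites)) do.call(rbind, all_sites) else
    data.frame(sequence_id = character(0), motif_id = character(0),
               offset = integer(0), strand = character(0),
               score = numeric(0), p_value = numeric(0))
  rownames(sites) <- NULL
  list(sites = sites, occupancy = occ)
}
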