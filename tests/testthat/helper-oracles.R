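## Independent brute-force oracles and small fixture builders.  Each
## oracle is deliberately naive (loops, enumeration, direct summation)
## and shares no code path with the package implementation it checks.

BASES <- c("A", "C", "G", "T")

rand_seq <- function(len, prob = rep(0.25, 4)) {
  paste(sample(BASES, len, replace = TRUE, prob = prob), collapse = "")
}

rand_pwm <- function(width, id = "m", conc = c(6, 0.8)) {
  mat <- t(vapply(seq_len(width), function(j) {
    a <- rep(conc[2], 4); a[sample.int(4, 1)] <- conc[1]
    g <- rgamma(4, a); g / sum(g)
  }, numeric(4)))
  new_pwm(id, mat)
}

rand_genes <- function(n, chrom = "chr1", chrom_len = 100000) {
  tss0 <- sort(sample.int(chrom_len - 4000, n)) + 2000
  strand <- sample(c("+", "-"), n, replace = TRUE)
  len <- sample(500:1500, n, replace = TRUE)
  data.frame(gene_id = sprintf("g%03d", seq_len(n)), chrom = chrom,
             strand = strand, tss = tss0 + 1L,
             start = ifelse(strand == "+", tss0, tss0 + 1L - len),
             end = ifelse(strand == "+", tss0 + len, tss0 + 1L),
             stringsAsFactors = FALSE)
}

rand_peaks <- function(n, chrom = "chr1", chrom_len = 100000, with_summit = TRUE) {
  start <- sample.int(chrom_len - 400, n)
  width <- sample(50:300, n, replace = TRUE)
  summit <- if (with_summit) start + sample.int(49, n, replace = TRUE) else NA_integer_
  data.frame(chrom = chrom, start = start, end = start + width,
             name = sprintf("p%03d", seq_len(n)),
             score = round(runif(n, 0, 100), 3), summit = summit,
             stringsAsFactors = FALSE)
}

## exhaustive per-window log-odds scores via substring lookup
oracle_window_scores <- function(sequence, lom) {
  w <- nrow(lom)
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars) - w + 1
  if (n < 1) return(numeric(0))
  vapply(seq_len(n), function(i) {
    s <- 0
    for (j in seq_len(w)) {
      b <- match(chars[i + j - 1], BASES)
      if (is.na(b)) return(NA_real_)
      s <- s + lom[j, b]
    }
    s
  }, 0)
}

## exact p-value by full word enumeration (width <= ~8 practical)
oracle_pvalue_fn <- function(lom, background) {
  w <- nrow(lom)
  grid <- as.matrix(expand.grid(rep(list(1:4), w)))
  scores <- apply(grid, 1, function(g) sum(lom[cbind(seq_len(w), g)]))
  probs <- apply(grid, 1, function(g) prod(background[g]))
  function(s) vapply(s, function(si) sum(probs[scores >= si - 1e-9]), 0)
}

oracle_max_avg <- function(values, start, end, w) {
  if (end <= start) return(0)
  v <- numeric(end - start)
  for (k in seq_along(v)) {
    pos <- start + k            # 1-based index into values
    v[k] <- if (pos <= length(values)) values[pos] else 0
  }
  n <- length(v)
  if (n <= w) return(mean(v))
  best <- -Inf
  for (i in 1:(n - w + 1)) best <- max(best, mean(v[i:(i + w - 1)]))
  best
}

oracle_nearest <- function(peaks, genes) {
  anchor <- ifelse(is.na(peaks$summit), (peaks$start + peaks$end) %/% 2, peaks$summit)
  out <- character(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    best <- Inf; bestg <- NA_character_
    for (j in seq_len(nrow(genes))) {
      if (genes$chrom[j] != peaks$chrom[i]) next
      d <- abs(anchor[i] - (genes$tss[j] - 1))
      if (d < best || (d == best && genes$gene_id[j] < bestg)) {
        best <- d; bestg <- genes$gene_id[j]
      }
    }
    out[i] <- bestg
  }
  out
}

oracle_overlap_count <- function(pa, pb, threshold) {
  aa <- ifelse(is.na(pa$summit), (pa$start + pa$end) %/% 2, pa$summit)
  ab <- ifelse(is.na(pb$summit), (pb$start + pb$end) %/% 2, pb$summit)
  cnt <- 0
  for (i in seq_len(nrow(pa))) {
    hit <- FALSE
    for (j in seq_len(nrow(pb))) {
      if (pa$chrom[i] != pb$chrom[j]) next
      if (abs(aa[i] - ab[j]) <= threshold ||
          (pb$start[j] < pa$end[i] && pa$start[i] < pb$end[j])) hit <- TRUE
    }
    cnt <- cnt + hit
  }
  cnt
}

## upper-tail hypergeometric by direct summation of the mass function
oracle_hyper_tail <- function(k, K, N, n) {
  sum(vapply(k:min(K, n), function(x) stats::dhyper(x, K, N - K, n), 0))
}

## exact one-sided Mann-Whitney p by enumeration of group assignments
oracle_mw_exact <- function(x, y, alternative = "x_greater") {
  pool <- c(x, y); nx <- length(x)
  u_of <- function(idx) {
    r <- rank(pool)
    sum(r[idx]) - nx * (nx + 1) / 2
  }
  u_obs <- u_of(seq_len(nx))
  combos <- utils::combn(length(pool), nx)
  us <- apply(combos, 2, u_of)
  if (alternative == "x_greater") mean(us >= u_obs) else mean(us <= u_obs)
}

## strand-mirror transform of a dataset (0-based coords, chrom length L)
mirror_genes <- function(genes, L) {
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             strand = ifelse(genes$strand == "+", "-", "+"),
             tss = L - genes$tss + 1L,
             start = L - genes$end, end = L - genes$start,
             stringsAsFactors = FALSE)
}

mirror_peaks <- function(peaks, L) {
  data.frame(chrom = peaks$chrom, start = L - peaks$end, end = L - peaks$start,
             name = peaks$name, score = peaks$score,
             summit = ifelse(is.na(peaks$summit), NA_integer_, L - 1L - peaks$summit),
             stringsAsFactors = FALSE)
}

mirror_track <- function(track) lapply(track, rev)

mirror_genome <- function(genome) {
  out <- Biostrings::reverseComplement(genome)
  names(out) <- names(genome)
  out
}
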