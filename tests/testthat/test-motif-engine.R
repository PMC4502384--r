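test_that("log-odds matrices follow the closed form and identify the consensus", {
  m <- new_pwm("u", matrix(0.25, 3, 4), pseudocount = 1e-9)
  expect_equal(unname(log_odds_matrix(m)), matrix(0, 3, 4), tolerance = 1e-6)
  m2 <- new_pwm("h", rbind(c(0.5, 0.5 / 3, 0.5 / 3, 0.5 / 3)), pseudocount = 1e-9)
  expect_equal(unname(log_odds_matrix(m2)[1, 1]), 1, tolerance = 1e-6)  # log2(0.5/0.25)
  expect_error(log_odds_matrix(m, background = c(0, .5, .25, .25)), "background")

  ## the maximum-scoring word is the per-position argmax
  set.seed(401)
  for (rep in 1:5) {
    pwm <- rand_pwm(4)
    lom <- log_odds_matrix(pwm)
    grid <- as.matrix(expand.grid(rep(list(1:4), 4)))
    scores <- apply(grid, 1, function(g) sum(lom[cbind(1:4, g)]))
    best <- paste(BASES[grid[which.max(scores), ]], collapse = "")
    expect_equal(best, pwm_consensus(pwm))
    expect_equal(max(scores), sum(apply(lom, 1, max)))
  }
})

test_that("site p-values are exact for narrow motifs", {
  ## width 1: four distinct scores give tails 0.25, 0.5, 0.75, 1
  set.seed(402)
  pwm <- rand_pwm(1)
  pf <- site_pvalue_function(pwm)
  lom <- log_odds_matrix(pwm)
  expect_equal(sort(unname(pf(sort(lom[1, ])))), c(0.25, 0.5, 0.75, 1))
  ## width 2: matches exhaustive dinucleotide enumeration
  pwm <- rand_pwm(2)
  pf <- site_pvalue_function(pwm)
  oracle <- oracle_pvalue_fn(log_odds_matrix(pwm), pwm$background)
  lom <- log_odds_matrix(pwm)
  test_scores <- as.vector(outer(lom[1, ], lom[2, ], "+"))
  expect_equal(unname(pf(test_scores)), unname(oracle(test_scores)), tolerance = 1e-10)
  ## p at the maximum achievable score is the background probability of
  ## the consensus word
  for (w in c(3, 5, 8)) {
    pwm <- rand_pwm(w)
    pf <- site_pvalue_function(pwm)
    lom <- log_odds_matrix(pwm)
    smax <- sum(apply(lom, 1, max))
    p_cons <- prod(pwm$background[apply(lom, 1, which.max)])
    tol <- if (w <= 6) 1e-10 else 1 / 1000
    expect_equal(unname(pf(smax)), unname(p_cons), tolerance = tol)
    expect_gte(pf(smax), p_cons * (1 - 1e-9))
    ## p is 1 at the minimum achievable score
    expect_equal(unname(pf(sum(apply(lom, 1, min)))), 1)
  }
})

test_that("doubling the discretization bins moves p-values by less than 1/bins", {
  set.seed(403)
  pwm <- rand_pwm(9)
  p1 <- site_pvalue_function(pwm, bins = 1000)
  p2 <- site_pvalue_function(pwm, bins = 2000)
  seqs <- vapply(1:20, function(i) rand_seq(9), "")
  lom <- log_odds_matrix(pwm)
  scores <- vapply(seqs, function(s) sum(lom[cbind(1:9, match(strsplit(s, "")[[1]], BASES))]), 0)
  expect_true(all(abs(p1(scores) - p2(scores)) < 1 / 1000))
})

test_that("site finding matches a brute-force scan with enumerated p-values", {
  set.seed(404)
  pwm <- rand_pwm(5)
  cfg <- scan_config(max_p = 0.01)
  oracle_p <- oracle_pvalue_fn(log_odds_matrix(pwm), pwm$background)
  rc_lom <- log_odds_matrix(pwm)[5:1, 4:1]
  oracle_p_rc <- oracle_pvalue_fn(rc_lom, pwm$background)
  for (rep in 1:20) {
    s <- rand_seq(120)
    got <- find_sites(s, pwm, cfg)
    fw <- oracle_window_scores(s, log_odds_matrix(pwm))
    rv <- oracle_window_scores(s, rc_lom)
    mkdf <- function(idx, st) if (length(idx)) data.frame(offset = idx - 1L, strand = st) else NULL
    want <- rbind(mkdf(which(oracle_p(fw) <= 0.01), "+"),
                  mkdf(which(oracle_p_rc(rv) <= 0.01), "-"))
    if (is.null(want)) want <- data.frame(offset = integer(0), strand = character(0))
    want <- want[order(want$offset, want$strand), ]
    expect_equal(got$offset, want$offset)
    expect_equal(got$strand, want$strand)
    if (nrow(got) > 0)
      expect_equal(got$p_value,
                   ifelse(got$strand == "+", oracle_p(fw[got$offset + 1]),
                          oracle_p_rc(rv[got$offset + 1])),
                   tolerance = 1e-10)
  }
})

test_that("planted consensus words are found; N and short sequences are handled", {
  set.seed(405)
  pwm <- rand_pwm(6)
  cons <- pwm_consensus(pwm)
  s <- rand_seq(500)
  substr(s, 38, 43) <- cons      # offset 37, 0-based
  sites <- find_sites(s, pwm)
  hit <- sites[sites$offset == 37 & sites$strand == "+", ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$score, sum(apply(log_odds_matrix(pwm), 1, max)), tolerance = 1e-9)
  expect_equal(nrow(find_sites(strrep("N", 100), pwm)), 0L)
  expect_equal(nrow(find_sites("ACG", pwm)), 0L)
})

test_that("non-overlapping selection is greedy by p-value and matches exhaustive replay", {
  sites <- data.frame(offset = c(0L, 1L), strand = "+",
                      score = c(10, 5), p_value = c(1e-6, 1e-4))
  kept <- nonoverlapping_sites(sites, width = 8)
  expect_equal(kept$offset, 0L)
  sites2 <- data.frame(offset = c(0L, 100L), strand = "+",
                       score = c(5, 5), p_value = c(1e-4, 1e-4))
  expect_equal(nrow(nonoverlapping_sites(sites2, 8)), 2L)

  oracle_greedy <- function(st, w) {
    o <- order(st$p_value, st$offset, st$strand)
    kept <- st[0, ]
    for (i in o) {
      ok <- TRUE
      if (nrow(kept) > 0)
        for (j in seq_len(nrow(kept)))
          if (st$offset[i] < kept$offset[j] + w && kept$offset[j] < st$offset[i] + w)
            ok <- FALSE
      if (ok) kept <- rbind(kept, st[i, ])
    }
    kept[order(kept$offset), ]
  }
  set.seed(406)
  for (rep in 1:20) {
    n <- sample(3:15, 1)
    st <- data.frame(offset = sample.int(60, n), strand = sample(c("+", "-"), n, TRUE),
                     score = runif(n), p_value = 10^-runif(n, 1, 8))
    got <- nonoverlapping_sites(st, 8)
    want <- oracle_greedy(st, 8)
    expect_equal(got$offset, want$offset)
    expect_equal(got$p_value, want$p_value)
  }
})

test_that("occupancy is a relative-affinity window sum with strand symmetry", {
  ## palindromic consensus at exactly motif width scores 1 per strand
  pal <- new_pwm("pal", rbind(c(.97, .01, .01, .01), c(.01, .97, .01, .01),
                              c(.01, .01, .97, .01), c(.01, .01, .01, .97)),
                 pseudocount = 1e-6)
  expect_equal(pwm_consensus(pal), "ACGT")  # reverse complement of ACGT is ACGT
  expect_equal(occupancy_score("ACGT", pal), 2, tolerance = 1e-3)

  set.seed(407)
  pwm <- rand_pwm(6)
  lom <- log_odds_matrix(pwm)
  rc_lom <- lom[6:1, 4:1]
  smax <- sum(apply(lom, 1, max))
  for (rep in 1:10) {
    s <- rand_seq(200)
    occ <- occupancy_score(s, pwm)
    brute <- sum(2^(oracle_window_scores(s, lom) - smax)) +
      sum(2^(oracle_window_scores(s, rc_lom) - smax))
    expect_equal(occ, brute, tolerance = 1e-9)
    ## strand symmetry: reverse complement gives identical occupancy and
    ## mirrored sites
    expect_equal(occupancy_score(revcomp(s), pwm), occ, tolerance = 1e-9)
    sites <- find_sites(s, pwm, scan_config(max_p = 0.01))
    sites_rc <- find_sites(revcomp(s), pwm, scan_config(max_p = 0.01))
    expect_equal(sites_rc$offset, sort(200 - 6 - sites$offset))
    expect_equal(sort(round(sites_rc$score, 9)), sort(round(sites$score, 9)))
  }
})

test_that("planting a consensus site into a fixed background increases occupancy", {
  set.seed(408)
  pwm <- rand_pwm(7)
  s <- rand_seq(300)
  s2 <- s
  substr(s2, 150, 156) <- pwm_consensus(pwm)
  expect_gt(occupancy_score(s2, pwm), occupancy_score(s, pwm))
})

test_that("pooled promoter scanning agrees with per-sequence scanning", {
  set.seed(409)
  motifs <- list(a = rand_pwm(5, "a"), b = rand_pwm(8, "b"))
  seqs <- c(s1 = rand_seq(300), s2 = rand_seq(40), s3 = rand_seq(300),
            s4 = "ACG")  # shorter than both motifs
  substr(seqs[1], 50, 54) <- pwm_consensus(motifs$a)
  cfg <- scan_config(max_p = 0.01)
  sc <- scan_promoters(seqs, motifs, cfg)
  for (m in names(motifs)) {
    for (i in seq_along(seqs)) {
      ind <- nonoverlapping_sites(find_sites(seqs[[i]], motifs[[m]], cfg),
                                  motifs[[m]]$width)
      pooled <- sc$sites[sc$sites$sequence_id == names(seqs)[i] &
                           sc$sites$motif_id == m,
                         c("offset", "strand", "score", "p_value")]
      rownames(pooled) <- NULL
      expect_equal(pooled, ind, ignore_attr = TRUE)
      expect_equal(sc$occupancy[i, m], occupancy_score(seqs[[i]], motifs[[m]],
                                                       config = cfg),
                   tolerance = 1e-9)
    }
  }
})
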