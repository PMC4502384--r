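test_that("FASTA reading normalizes case, enforces the alphabet, rejects duplicates", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1 descriptive text", "acgt", ">chr2", "NNNN"), f)
  g <- read_fasta(f)
  expect_equal(names(g), c("chr1", "chr2"))
  expect_equal(unname(Biostrings::width(g)), c(4L, 4L))
  expect_equal(as.character(g[["chr1"]]), "ACGT")

  writeLines(c(">a", "ACGT", ">a", "TTTT"), f)
  expect_error(read_fasta(f), "duplicate")
  writeLines(character(0), f)
  expect_error(read_fasta(f), class = "dualchip_format_error")
  writeLines(c(">a", "ACRT"), f)   # R = ambiguity code outside A,C,G,T,N
  expect_error(read_fasta(f), "non-ACGTN")
})

test_that("FASTA write/read round-trips 100 random records exactly", {
  set.seed(101)
  seqs <- vapply(1:100, function(i) rand_seq(sample(20:200, 1)), "")
  names(seqs) <- sprintf("ctg%03d", 1:100)
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(seqs, f)
  back <- read_fasta(f)
  expect_equal(as.character(back), seqs)
})

test_that("BED peaks parse with defaults, scores, summits and line-numbered errors", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("track name=x", "# comment", "chr1\t100\t200",
               "chr1\t300\t400\tp1\t37"), f)
  p <- read_bed_peaks(f)
  expect_equal(p$start, c(100L, 300L))
  expect_equal(p$end, c(200L, 400L))
  expect_equal(p$score, c(0, 37))
  expect_true(all(is.na(p$summit)))

  writeLines("chr1\t200\t100", f)
  expect_error(read_bed_peaks(f), "line 1: end <= start")
  writeLines(c("chr1\t1\t2", "chr1\tx\t200"), f)
  expect_error(read_bed_peaks(f), "line 2: non-integer")
  writeLines(c("# only comments"), f)
  expect_warning(p0 <- read_bed_peaks(f), "empty peak set")
  expect_equal(nrow(p0), 0L)
})

test_that("narrowPeak write/read round-trips 50 random peaks including summits", {
  set.seed(102)
  peaks <- rand_peaks(50)
  f <- withr::local_tempfile(fileext = ".narrowPeak")
  write_bed_peaks(peaks, f)
  back <- read_bed_peaks(f)
  expect_equal(back[c("chrom", "start", "end", "name", "summit")],
               peaks[c("chrom", "start", "end", "name", "summit")])
  expect_equal(back$score, peaks$score, tolerance = 1e-6)
})

test_that("gene tables convert coordinates correctly in both formats", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tchrom\tstrand\ttss\tstart\tend",
               "g1\tchr1\t+\t1000\t1000\t3000"), f)
  g <- read_gene_table(f)
  expect_equal(g$tss, 1000L)
  expect_equal(g$start, 999L)   # 0-based half-open span [999, 3000)
  expect_equal(g$end, 3000L)

  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\t.\tgene\t1000\t3000\t.\t-\t.\tID=g2"), gff)
  g2 <- read_gene_table(gff)
  expect_equal(g2$tss, 3000L)   # minus-strand TSS = end field
  expect_equal(g2$start, 999L)

  writeLines(c("gene_id\tchrom\tstrand\ttss\tstart\tend",
               "g1\tchr1\t*\t10\t10\t20"), f)
  expect_error(read_gene_table(f), "strand")
  writeLines(c("gene_id\tchrom\tstrand\ttss\tstart\tend",
               "g1\tchr1\t+\t10\t10\t20", "g1\tchr1\t+\t30\t30\t40"), f)
  expect_error(read_gene_table(f), "duplicate")
})

test_that("gene table round-trips 20 random genes", {
  set.seed(103)
  genes <- rand_genes(20)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_gene_table(genes, f)
  expect_equal(read_gene_table(f), genes)
})

test_that("wiggle and bedGraph dialects parse to identical base-resolution vectors", {
  f <- withr::local_tempfile(fileext = ".wig")
  writeLines(c("fixedStep chrom=chr1 start=11 step=1", "5", "5"), f)
  v <- read_coverage(f)
  expect_equal(v$chr1[11:12], c(5, 5))   # 1-based wiggle -> 0-based indices 10,11
  expect_equal(sum(v$chr1), 10)

  g <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines("chr1\t0\t3\t2.5", g)
  vb <- read_coverage(g)
  expect_equal(vb$chr1, c(2.5, 2.5, 2.5))

  set.seed(104)
  track <- list(chr1 = as.numeric(rpois(3000, 2)), chr2 = as.numeric(rpois(500, 5)))
  w1 <- withr::local_tempfile(fileext = ".wig")
  w2 <- withr::local_tempfile(fileext = ".bedGraph")
  write_coverage(track, w1, "wig")
  write_coverage(track, w2, "bedGraph")
  lens <- c(chr1 = 3000L, chr2 = 500L)
  t1 <- read_coverage(w1, lens)
  t2 <- read_coverage(w2, lens)
  expect_equal(t1[names(track)], track)
  expect_equal(t2[names(track)], track)

  writeLines(c("chr1\t0\t10\t1", "chr1\t5\t15\t2"), g)
  expect_error(read_coverage(g), "overlapping")
})

test_that("MEME motifs regularize on read, default to uniform background, and round-trip", {
  f <- withr::local_tempfile(fileext = ".meme")
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "MOTIF m1",
               "letter-probability matrix: alength= 4 w= 2 nsites= 20 E= 0",
               "1 0 0 0", "0 1 0 0"), f)
  m <- read_meme_motifs(f, pseudocount = 0.01)
  expect_equal(m$m1$background, c(A = .25, C = .25, G = .25, T = .25))
  expect_equal(rowSums(m$m1$prob), c(1, 1), tolerance = 1e-9)
  expect_true(all(m$m1$prob > 0) && max(m$m1$prob) < 1)
  expect_equal(pwm_consensus(m$m1), "AC")

  writeLines(c("MEME version 4", "MOTIF bad",
               "letter-probability matrix: alength= 4 w= 1",
               "0.5 0.1 0.1 0.1"), f)
  expect_error(read_meme_motifs(f), "sum to 1")

  set.seed(105)
  lib <- lapply(1:10, function(i) rand_pwm(sample(4:10, 1), sprintf("m%02d", i)))
  names(lib) <- vapply(lib, `[[`, "", "motif_id")
  out <- withr::local_tempfile(fileext = ".meme")
  write_meme_motifs(lib, out)
  back <- read_meme_motifs(out)
  expect_equal(names(back), names(lib))
  for (id in names(lib)) {
    expect_equal(back[[id]]$prob_raw, lib[[id]]$prob_raw, tolerance = 1e-9)
    expect_equal(back[[id]]$prob, lib[[id]]$prob, tolerance = 1e-9)
  }
})

test_that("promoter windows follow strand, truncate at bounds, and mirror correctly", {
  genes <- data.frame(gene_id = c("gp", "gm", "gt"), chrom = "chr1",
                      strand = c("+", "-", "+"), tss = c(1000L, 1000L, 100L),
                      start = c(999L, 500L, 99L), end = c(2000L, 1000L, 600L))
  iv <- promoter_interval(genes, upstream = 500)
  expect_equal(iv$start, c(499L, 1000L, 0L))
  expect_equal(iv$end, c(999L, 1500L, 99L))    # third gene truncated at 0

  ## sequence orientation: plant a word upstream of a minus-strand TSS
  set.seed(106)
  bases <- sample(BASES, 2000, replace = TRUE)
  word <- "TTGACCGA"
  bases[1001:1008] <- strsplit(revcomp(word), "")[[1]]   # genomic [1000,1008)
  genome <- Biostrings::DNAStringSet(c(chr1 = paste(bases, collapse = "")))
  seqs <- promoter_sequences(genome, genes[2, ], upstream = 500)
  expect_equal(substr(seqs[["gm"]], 493, 500), word)

  ## strand-mirror: intervals map onto each other under genome reversal
  L <- 2000L
  ivm <- promoter_interval(mirror_genes(genes, L), upstream = 500,
                           chrom_lengths = c(chr1 = L))
  expect_equal(ivm$start, pmax(L - iv$end, 0L))
  expect_equal(ivm$end, L - iv$start)
  expect_error(promoter_interval(genes, upstream = 0, downstream = 0))
})
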