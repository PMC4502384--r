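## synthetic_data: truth-annotated synthetic inputs with the statistical
## structure the analysis assumes — promoter groups co-bound by two
## factors vs bound by one, motif sites planted with group-dependent
## strength, Gaussian coverage bumps over Poisson background, and peaks
## jittered around the true binding positions.

#' Specification of a synthetic dataset
#'
#' The defaults define the package's reference study conditions: a
#' 200 kb chromosome carrying 100 non-overlapping genes, of which 20%
#' are co-bound by both factors, 10% by A only and 25% by B only
#' (factor B targets roughly twice as many genes as A); bound promoters
#' carry one planted site of the target motif, sampled close to
#' consensus (temperature 0.35) in co-bound promoters and at the PWM's
#' own entropy (temperature 1.0) in single-factor promoters; ChIP
#' coverage is Poisson(2) background plus Gaussian bumps of amplitude
#' 20 and sd 60 bp centered on the planted site; peak calls are
#' jittered uniformly by up to 50 bp around the site center.  Planted
#' sites keep a margin of `peak_jitter + motif width` from the promoter
#' edges so binding calls are exercised without boundary dropout.
#'
#' @param seed master seed; per-stage child seeds derive from it
#' @param n_chroms,chrom_length chromosome count and length (bases)
#' @param n_genes number of genes; total length must be >= 2000 per gene
#' @param promoter_upstream promoter window, bases upstream of the TSS
#' @param fractions named fractions both / A_only / B_only (sum <= 1)
#' @param temperature_cobound,temperature_single site-sampling
#'   temperatures (lower = closer to consensus = stronger site)
#' @param peak_amplitude,peak_sigma Gaussian bump height and sd (bases)
#' @param background_lambda Poisson mean of the coverage background
#' @param peak_jitter max displacement of the peak anchor from the true
#'   site center (bases)
#' @param base_comp background base composition (A,C,G,T)
#' @param factors length-2 factor names
#' @return object of class `synthetic_spec`
#' @export
synthetic_spec <- function(seed = 1L, n_chroms = 1L, chrom_length = 200000L,
                           n_genes = 100L, promoter_upstream = 500L,
                           fractions = c(both = 0.20, A_only = 0.10, B_only = 0.25),
                           temperature_cobound = 0.35, temperature_single = 1.0,
                           peak_amplitude = 20, peak_sigma = 60,
                           background_lambda = 2, peak_jitter = 50L,
                           base_comp = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3),
                           factors = c("A", "B")) {
  stopifnot(all(fractions >= 0), sum(fractions) <= 1,
            all(c("both", "A_only", "B_only") %in% names(fractions)),
            n_chroms * chrom_length >= n_genes * 2000,
            temperature_cobound > 0, temperature_single > 0,
            peak_amplitude >= 0, peak_sigma > 0, background_lambda >= 0,
            peak_jitter >= 0, length(factors) == 2L)
  structure(list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
                 chrom_length = as.integer(chrom_length),
                 n_genes = as.integer(n_genes),
                 promoter_upstream = as.integer(promoter_upstream),
                 fractions = fractions,
                 temperature_cobound = temperature_cobound,
                 temperature_single = temperature_single,
                 peak_amplitude = peak_amplitude, peak_sigma = peak_sigma,
                 background_lambda = background_lambda,
                 peak_jitter = as.integer(peak_jitter),
                 base_comp = base_comp / sum(base_comp),
                 factors = factors),
            class = "synthetic_spec")
}

## deterministic per-stage child seed below 2^31
child_seed <- function(seed, stage) {
  u <- utf8ToInt(stage)
  as.integer((as.numeric(seed) * 1009 + sum(u * seq_along(u)) * 9973) %% 2147483629)
}

#' Simulate a PWM library: one target motif plus decoys
#'
#' Each position takes a dominant base with Dirichlet-distributed
#' probabilities (concentration `alpha_major` on the dominant base,
#' `alpha_minor` elsewhere), giving informative motifs of roughly 1
#' bit per position.
#'
#' @param n_decoys number of decoy motifs (default 20)
#' @param width motif width (default 8)
#' @param seed RNG seed
#' @param alpha_major,alpha_minor Dirichlet concentrations
#' @param planted_id name of the target motif
#' @return named list of pwm objects; the first is the target
#' @export
simulate_pwm_library <- function(n_decoys = 20L, width = 8L, seed = 7L,
                                 alpha_major = 10, alpha_minor = 0.8,
                                 planted_id = "planted") {
  set.seed(seed)
  rdir <- function(alpha) { g <- stats::rgamma(length(alpha), alpha); g / sum(g) }
  mk <- function(id) {
    mat <- t(vapply(seq_len(width), function(j) {
      a <- rep(alpha_minor, 4L)
      a[sample.int(4L, 1L)] <- alpha_major
      rdir(a)
    }, numeric(4L)))
    new_pwm(id, mat)
  }
  ids <- c(planted_id, sprintf("decoy_%02d", seq_len(n_decoys)))
  stats::setNames(lapply(ids, mk), ids)
}

#' Sample a site word from a PWM at a given temperature
#'
#' Position `j` draws base `b` with probability proportional to
#' `prob[j, b]^(1/temperature)`.  Temperature near 0 returns the
#' consensus word; temperature 1 samples the PWM itself.
#'
#' @param pwm a pwm object
#' @param temperature sampling temperature (> 0)
#' @param n number of words to draw
#' @return character vector of length `n`
#' @export
sample_site_from_pwm <- function(pwm, temperature = 1, n = 1L) {
  stopifnot(temperature > 0)
  ## log-space tempering: stable down to temperatures near 0
  lp <- log(pwm$prob) / temperature
  p <- exp(lp - apply(lp, 1L, max))
  p <- p / rowSums(p)
  vapply(seq_len(n), function(k) {
    paste(DNA_BASES[vapply(seq_len(pwm$width),
                           function(j) sample.int(4L, 1L, prob = p[j, ]), 0L)],
          collapse = "")
  }, "")
}

#' Generate a complete synthetic dataset with recorded ground truth
#'
#' Emits every input the pipeline consumes — genome FASTA, gene table,
#' one narrowPeak and one wiggle track per factor, a MEME motif file —
#' plus a truth TSV recording the per-gene co-binding class and the
#' planted site of the target motif (position, strand, word,
#' temperature).  The first motif of `pwm_library` is the planted
#' target; the rest are decoys present only in the motif file.  All
#' randomness derives from `spec$seed` through per-stage child seeds,
#' so two runs with the same spec are byte-identical.
#'
#' @param spec a [synthetic_spec()]
#' @param pwm_library named list of pwm objects (default:
#'   [simulate_pwm_library()] seeded from the spec)
#' @param dir output directory (created if needed)
#' @return invisible list: `files` (named paths), `truth` (data.frame),
#'   `spec`, `planted_motif`
#' @export
generate_dataset <- function(spec, pwm_library = NULL, dir = tempfile("synthdata")) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(pwm_library))
    pwm_library <- simulate_pwm_library(seed = child_seed(spec$seed, "motifs"))
  planted <- pwm_library[[1L]]
  w <- planted$width
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  ## genome as per-chromosome base vectors (collapsed after site planting)
  set.seed(child_seed(spec$seed, "genome"))
  chroms <- sprintf("chr%d", seq_len(spec$n_chroms))
  genome_bases <- lapply(chroms, function(ch)
    sample(DNA_BASES, spec$chrom_length, replace = TRUE, prob = spec$base_comp))
  names(genome_bases) <- chroms

  ## non-overlapping gene placement on a 2-kb slot grid
  set.seed(child_seed(spec$seed, "genes"))
  slot_w <- 2000L
  slots_per_chrom <- spec$chrom_length %/% slot_w
  all_slots <- expand.grid(chrom = chroms, slot = seq_len(slots_per_chrom) - 1L,
                           stringsAsFactors = FALSE)
  if (nrow(all_slots) < spec$n_genes)
    stop("gene placement infeasible: need ", spec$n_genes, " slots, have ", nrow(all_slots))
  pick <- sort(sample.int(nrow(all_slots), spec$n_genes))
  strand <- sample(c("+", "-"), spec$n_genes, replace = TRUE)
  body_len <- sample(500:1100, spec$n_genes, replace = TRUE)
  slot0 <- all_slots$slot[pick] * slot_w
  tss0 <- ifelse(strand == "+",
                 slot0 + sample(600:800, spec$n_genes, replace = TRUE),
                 slot0 + sample(1200:1400, spec$n_genes, replace = TRUE))
  genes <- data.frame(
    gene_id = sprintf("g%04d", seq_len(spec$n_genes)),
    chrom = all_slots$chrom[pick], strand = strand,
    tss = tss0 + 1L,
    start = ifelse(strand == "+", tss0, tss0 + 1L - body_len),
    end = ifelse(strand == "+", tss0 + body_len, tss0 + 1L),
    stringsAsFactors = FALSE)

  ## co-binding classes
  set.seed(child_seed(spec$seed, "classes"))
  f <- spec$fractions
  class <- sample(c("both", "A_only", "B_only", "none"), spec$n_genes,
                  replace = TRUE,
                  prob = c(f[["both"]], f[["A_only"]], f[["B_only"]],
                           1 - sum(f[c("both", "A_only", "B_only")])))

  ## plant one target-motif site per bound promoter
  set.seed(child_seed(spec$seed, "sites"))
  margin <- spec$peak_jitter + w
  pint <- promoter_interval(genes, spec$promoter_upstream, 0L,
                            stats::setNames(rep(spec$chrom_length, spec$n_chroms), chroms))
  site_start <- rep(NA_integer_, spec$n_genes)
  site_strand <- rep(NA_character_, spec$n_genes)
  site_word <- rep(NA_character_, spec$n_genes)
  site_temp <- rep(NA_real_, spec$n_genes)
  for (i in seq_len(spec$n_genes)) {
    if (class[i] == "none") next
    temp <- if (class[i] == "both") spec$temperature_cobound else spec$temperature_single
    lo <- pint$start[i] + margin
    hi <- pint$end[i] - margin - w
    if (hi < lo) stop("site placement infeasible: promoter narrower than 2*margin + width")
    pos <- lo + sample.int(hi - lo + 1L, 1L) - 1L
    word <- sample_site_from_pwm(planted, temp)
    sstr <- sample(c("+", "-"), 1L)
    ins <- if (sstr == "+") word else revcomp(word)
    genome_bases[[pint$chrom[i]]][(pos + 1L):(pos + w)] <- strsplit(ins, "")[[1L]]
    site_start[i] <- pos; site_strand[i] <- sstr
    site_word[i] <- word; site_temp[i] <- temp
  }
  genome <- Biostrings::DNAStringSet(vapply(genome_bases, paste, "", collapse = ""))
  names(genome) <- chroms

  ## coverage: Poisson background + Gaussian bumps at planted sites
  set.seed(child_seed(spec$seed, "coverage"))
  bound_by <- list(A = class %in% c("both", "A_only"),
                   B = class %in% c("both", "B_only"))
  tracks <- lapply(c("A", "B"), function(fac) {
    tr <- lapply(chroms, function(ch) as.numeric(rpois(spec$chrom_length, spec$background_lambda)))
    names(tr) <- chroms
    if (spec$peak_amplitude > 0) {
      for (i in which(bound_by[[fac]])) {
        ctr <- site_start[i] + w %/% 2L
        lo <- max(0L, ctr - 4L * as.integer(spec$peak_sigma))
        hi <- min(spec$chrom_length - 1L, ctr + 4L * as.integer(spec$peak_sigma))
        x <- lo:hi
        tr[[pint$chrom[i]]][x + 1L] <- tr[[pint$chrom[i]]][x + 1L] +
          spec$peak_amplitude * exp(-(x - ctr)^2 / (2 * spec$peak_sigma^2))
      }
    }
    tr
  })
  names(tracks) <- c("A", "B")

  ## peaks at true binding positions with uniform jitter
  set.seed(child_seed(spec$seed, "peaks"))
  peaks <- lapply(c("A", "B"), function(fac) {
    idx <- which(bound_by[[fac]])
    if (length(idx) == 0L)
      return(data.frame(chrom = character(0), start = integer(0), end = integer(0),
                        name = character(0), score = numeric(0), summit = integer(0)))
    jit <- if (spec$peak_jitter > 0)
      sample(seq.int(-spec$peak_jitter, spec$peak_jitter), length(idx), replace = TRUE)
    else rep(0L, length(idx))
    anchor <- site_start[idx] + w %/% 2L + jit
    data.frame(chrom = pint$chrom[idx],
               start = pmax(0L, anchor - 100L),
               end = pmin(spec$chrom_length, anchor + 100L),
               name = sprintf("%s_peak_%03d", fac, seq_along(idx)),
               score = round(spec$peak_amplitude + spec$background_lambda, 3),
               summit = anchor, stringsAsFactors = FALSE)
  })
  names(peaks) <- c("A", "B")

  truth <- data.frame(gene_id = genes$gene_id, class = class,
                      site_start = site_start, site_strand = site_strand,
                      site_word = site_word, site_temperature = site_temp,
                      stringsAsFactors = FALSE)

  fa <- spec$factors
  files <- c(genome = file.path(dir, "genome.fa"),
             genes = file.path(dir, "genes.tsv"),
             motifs = file.path(dir, "motifs.meme"),
             truth = file.path(dir, "truth.tsv"),
             stats::setNames(file.path(dir, sprintf("peaks_%s.narrowPeak", fa)),
                             paste0("peaks_", c("A", "B"))),
             stats::setNames(file.path(dir, sprintf("coverage_%s.wig", fa)),
                             paste0("coverage_", c("A", "B"))))
  write_fasta(genome, files[["genome"]])
  write_gene_table(genes, files[["genes"]])
  write_meme_motifs(pwm_library, files[["motifs"]])
  write_bed_peaks(peaks$A, files[["peaks_A"]])
  write_bed_peaks(peaks$B, files[["peaks_B"]])
  write_coverage(tracks$A, files[["coverage_A"]], format = "wig")
  write_coverage(tracks$B, files[["coverage_B"]], format = "wig")
  utils::write.table(truth, files[["truth"]], sep = "\t", quote = FALSE, row.names = FALSE)

  invisible(list(files = files, truth = truth, spec = spec,
                 planted_motif = planted$motif_id, dir = dir))
}

#' Score pipeline outputs against the generator's ground truth
#'
#' @param cobinding co-binding table from the pipeline
#' @param screen association-screen table ([motif_association_screen()])
#' @param strength one-row strength result for the planted motif
#'   ([site_strength_comparison()]), or NULL to skip
#' @param truth truth data.frame from [generate_dataset()]
#' @param planted_motif id of the planted motif
#' @param r_high screen threshold used for decoy false-positive counting
#' @return list: confusion (4x4 table), class_accuracy, planted ranks and
#'   correlations per factor, decoy screen false positives, strength
#'   significance/direction agreement
#' @export
evaluate_recovery <- function(cobinding, screen, strength = NULL, truth,
                              planted_motif = "planted", r_high = 0.19) {
  if (!setequal(cobinding$gene_id, truth$gene_id))
    stop("gene universe mismatch between pipeline output and truth")
  m <- match(truth$gene_id, cobinding$gene_id)
  lev <- c("both", "A_only", "B_only", "none")
  confusion <- table(truth = factor(truth$class, lev),
                     called = factor(cobinding$class[m], lev))
  acc <- sum(diag(confusion)) / sum(confusion)
  rank_of <- function(col) {
    o <- order(-screen[[col]], na.last = TRUE)
    match(planted_motif, screen$motif_id[o])
  }
  is_planted <- screen$motif_id == planted_motif
  out <- list(confusion = confusion, class_accuracy = acc,
              planted_rank_A = rank_of("r_A"), planted_rank_B = rank_of("r_B"),
              planted_r_A = screen$r_A[is_planted],
              planted_r_B = screen$r_B[is_planted],
              decoy_screen_fp = sum(pmax(screen$r_A[!is_planted],
                                         screen$r_B[!is_planted]) > r_high,
                                    na.rm = TRUE),
              n_decoys = sum(!is_planted))
  if (!is.null(strength)) {
    out$strength_significant <- isTRUE(strength$significant)
    out$strength_direction_ok <- identical(strength$direction, "cobound")
  }
  out
}
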