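## formats_io: readers/writers for every external format the pipeline touches.
## Internal convention is 0-based half-open throughout; conversions to the
## 1-based conventions of wiggle / gene-table TSS / GFF3 happen only here.

DNA_BASES <- c("A", "C", "G", "T")

#' Read a genome from a FASTA file
#'
#' The token before the first whitespace of each header becomes the
#' chromosome name.  Sequences are stored uppercase; the allowed alphabet
#' is A, C, G, T, N.
#'
#' @param path path to a FASTA file
#' @return a [Biostrings::DNAStringSet] named by chromosome
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) format_error("file does not exist", path)
  x <- tryCatch(Biostrings::readDNAStringSet(path),
                error = function(e) format_error(conditionMessage(e), path))
  if (length(x) == 0L) format_error("empty FASTA file", path)
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x)))
    format_error(sprintf("duplicate FASTA header: %s",
                         names(x)[duplicated(names(x))][1L]), path)
  af <- Biostrings::alphabetFrequency(x)
  bad <- rowSums(af[, setdiff(colnames(af), c(DNA_BASES, "N")), drop = FALSE]) > 0
  if (any(bad))
    format_error(sprintf("non-ACGTN character in record '%s'",
                         names(x)[bad][1L]), path)
  if (any(Biostrings::width(x) < 1L))
    format_error("zero-length sequence record", path)
  x
}

#' Write a genome to FASTA
#'
#' @param genome a DNAStringSet (or named character vector)
#' @param path output path
#' @export
write_fasta <- function(genome, path) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

#' Named chromosome lengths of a genome
#' @param genome a DNAStringSet
#' @export
chrom_lengths <- function(genome) {
  stats::setNames(Biostrings::width(genome), names(genome))
}

#' Read ChIP peaks from a BED / narrowPeak file
#'
#' Coordinates are taken verbatim as 0-based half-open.  Column 5 becomes
#' the score when present (else 0).  For 10-column narrowPeak input the
#' 10th column (summit offset from peak start, -1 for absent) defines the
#' summit; `summit_col` overrides the column index holding that offset.
#' `track`/`browser` lines and `#` comments are skipped.
#'
#' @param path BED3+ file
#' @param summit_col optional 1-based index of a summit-offset column
#' @return data.frame with columns chrom, start, end, name, score, summit
#' @export
read_bed_peaks <- function(path, summit_col = NULL) {
  if (!file.exists(path)) format_error("file does not exist", path)
  raw <- readLines(path)
  keep <- !grepl("^\\s*(#|track\\b|browser\\b|$)", raw)
  lines <- raw[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) {
    warning(sprintf("no peak records in %s; returning empty peak set", path))
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      name = character(0), score = numeric(0), summit = integer(0),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3L))
    format_error(sprintf("line %d: fewer than 3 columns", lineno[nf < 3L][1L]), path)
  getcol <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i] else NA_character_, "")
  chrom <- getcol(1L)
  start <- suppressWarnings(as.integer(getcol(2L)))
  end   <- suppressWarnings(as.integer(getcol(3L)))
  badc <- is.na(start) | is.na(end)
  if (any(badc))
    format_error(sprintf("line %d: non-integer coordinate", lineno[badc][1L]), path)
  bad <- end <= start
  if (any(bad))
    format_error(sprintf("line %d: end <= start", lineno[bad][1L]), path)
  name <- getcol(4L)
  name[is.na(name) | name == "."] <- sprintf("peak_%d", which(is.na(name) | name == "."))
  score <- suppressWarnings(as.numeric(getcol(5L)))
  score[is.na(score)] <- 0
  if (is.null(summit_col) && all(nf >= 10L)) summit_col <- 10L
  summit <- rep(NA_integer_, length(chrom))
  if (!is.null(summit_col)) {
    off <- suppressWarnings(as.integer(getcol(summit_col)))
    ok <- !is.na(off) & off >= 0L
    summit[ok] <- start[ok] + off[ok]
    outside <- !is.na(summit) & (summit < start | summit >= end)
    if (any(outside))
      format_error(sprintf("line %d: summit outside peak interval", lineno[outside][1L]), path)
  }
  data.frame(chrom = chrom, start = start, end = end, name = name,
             score = score, summit = summit, stringsAsFactors = FALSE)
}

#' Write peaks as narrowPeak (BED6+4)
#'
#' The 10th column carries the summit as an offset from start (-1 when
#' absent) so [read_bed_peaks()] round-trips the full record.
#'
#' @param peaks peak data.frame as returned by [read_bed_peaks()]
#' @param path output path
#' @export
write_bed_peaks <- function(peaks, path) {
  off <- ifelse(is.na(peaks$summit), -1L, peaks$summit - peaks$start)
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t.\t%s\t-1\t-1\t%d",
                   peaks$chrom, peaks$start, peaks$end, peaks$name,
                   format_num(peaks$score), format_num(peaks$score), off)
  writeLines(lines, path)
  invisible(path)
}

## fixed formatting keeps generator output byte-stable across runs
format_num <- function(x) sprintf("%.6g", x)

#' Read a gene annotation table
#'
#' Accepts either the package's tab-separated gene table (header columns
#' gene_id, chrom, strand, tss, start, end; tss and start/end 1-based
#' inclusive) or a GFF3 subset of `gene` lines with an `ID` attribute.
#' The gene span is stored 0-based half-open; the TSS stays 1-based.  For
#' GFF3 input the TSS is the `start` field on + strand and the `end`
#' field on - strand.
#'
#' @param path gene table TSV or GFF3 file
#' @return data.frame with columns gene_id, chrom, strand, tss, start, end
#' @export
read_gene_table <- function(path) {
  if (!file.exists(path)) format_error("file does not exist", path)
  head1 <- readLines(path, n = 1L)
  is_gff <- grepl("^##gff-version", head1) || grepl("\\.gff3?$", path)
  if (is_gff) {
    gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                   error = function(e) format_error(conditionMessage(e), path))
    gr <- gr[gr$type == "gene"]
    if (length(gr) == 0L) format_error("no gene features in GFF3", path)
    strand <- as.character(GenomicRanges::strand(gr))
    if (any(!strand %in% c("+", "-")))
      format_error("unknown strand symbol in GFF3 gene line", path)
    ids <- as.character(gr$ID)
    genes <- data.frame(
      gene_id = ids,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      strand = strand,
      tss = ifelse(strand == "+", GenomicRanges::start(gr), GenomicRanges::end(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                             stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "strand", "tss", "start", "end")
    if (!all(need %in% names(tab)))
      format_error(paste("gene table must have columns:", paste(need, collapse = ", ")), path)
    if (any(!tab$strand %in% c("+", "-")))
      format_error(sprintf("unknown strand symbol '%s'",
                           tab$strand[!tab$strand %in% c("+", "-")][1L]), path)
    genes <- data.frame(
      gene_id = as.character(tab$gene_id), chrom = as.character(tab$chrom),
      strand = tab$strand, tss = as.integer(tab$tss),
      start = as.integer(tab$start) - 1L, end = as.integer(tab$end),
      stringsAsFactors = FALSE)
  }
  if (anyDuplicated(genes$gene_id))
    format_error(sprintf("duplicate gene_id: %s",
                         genes$gene_id[duplicated(genes$gene_id)][1L]), path)
  genes
}

#' Write the tab-separated gene table
#'
#' Inverse of the TSV branch of [read_gene_table()] (start/end written
#' back as 1-based inclusive).
#'
#' @param genes gene data.frame
#' @param path output path
#' @export
write_gene_table <- function(genes, path) {
  out <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                    strand = genes$strand, tss = genes$tss,
                    start = genes$start + 1L, end = genes$end)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a coverage track (wiggle or bedGraph) to base resolution
#'
#' The dialect is auto-detected: `fixedStep`/`variableStep` declarations
#' mean UCSC wiggle (1-based), otherwise bedGraph (0-based half-open).
#' Values are expanded to one number per base; unspecified bases are 0.
#'
#' @param path coverage file
#' @param chrom_lengths optional named vector of chromosome lengths; when
#'   given, each vector is padded/checked to that length
#' @return named list of numeric vectors (0-based indexing by position+1)
#' @export
read_coverage <- function(path, chrom_lengths = NULL) {
  if (!file.exists(path)) format_error("file does not exist", path)
  body <- readLines(path, n = 50L)
  body <- body[!grepl("^\\s*(#|track\\b|browser\\b|$)", body)]
  if (length(body) == 0L) format_error("empty coverage file", path)
  fmt <- if (grepl("^(fixedStep|variableStep)", body[1L])) "wig" else "bedGraph"
  gr <- tryCatch(rtracklayer::import(path, format = fmt),
                 error = function(e) format_error(conditionMessage(e), path))
  if (any(gr$score < 0)) format_error("negative coverage value", path)
  if (fmt == "bedGraph") {
    hits <- GenomicRanges::countOverlaps(gr, gr)
    if (any(hits > 1L)) format_error("overlapping bedGraph intervals", path)
  }
  chroms <- unique(as.character(GenomicRanges::seqnames(gr)))
  out <- vector("list", length(chroms))
  names(out) <- chroms
  for (ch in chroms) {
    g <- gr[GenomicRanges::seqnames(gr) == ch]
    len <- if (!is.null(chrom_lengths) && ch %in% names(chrom_lengths))
      as.integer(chrom_lengths[[ch]]) else max(GenomicRanges::end(g))
    if (max(GenomicRanges::end(g)) > len)
      format_error(sprintf("coverage extends past chromosome %s length %d", ch, len), path)
    idx <- IRanges::IRanges(GenomicRanges::start(g), GenomicRanges::end(g))  # 1-based closed
    out[[ch]] <- as.numeric(IRanges::coverage(idx, weight = g$score, width = len))
  }
  out
}

#' Write a coverage track
#'
#' @param track named list of per-base numeric vectors
#' @param path output path
#' @param format "wig" (fixedStep, step 1) or "bedGraph"
#' @export
write_coverage <- function(track, path, format = c("wig", "bedGraph")) {
  format <- match.arg(format)
  stopifnot(all(vapply(track, function(v) all(v >= 0), TRUE)))
  if (format == "wig") {
    con <- file(path, "w")
    on.exit(close(con))
    for (ch in names(track)) {
      writeLines(sprintf("fixedStep chrom=%s start=1 step=1 span=1", ch), con)
      writeLines(format_num(track[[ch]]), con)
    }
  } else {
    grl <- lapply(names(track), function(ch) {
      r <- S4Vectors::Rle(track[[ch]])
      n <- S4Vectors::nrun(r)
      starts <- cumsum(c(1, S4Vectors::runLength(r)[-n]))
      GenomicRanges::GRanges(ch, IRanges::IRanges(starts, width = S4Vectors::runLength(r)),
                             score = S4Vectors::runValue(r))
    })
    gr <- suppressWarnings(do.call(c, grl))
    rtracklayer::export(gr, path, format = "bedGraph")
  }
  invisible(path)
}

#' Read motifs in MEME minimal format
#'
#' Each probability row must sum to 1 within 1e-3 as read; rows are then
#' regularized with the pseudocount, `(p + pc) / (1 + 4 pc)`, and the
#' regularized matrix (strictly positive, rows summing to 1) is what the
#' scanner uses.  The raw matrix is retained so files round-trip.  A
#' file-level `Background letter frequencies` line is used when present,
#' else a uniform background.
#'
#' @param path MEME minimal format file
#' @param pseudocount regularization pseudocount (> 0)
#' @return named list of `pwm` objects (fields: motif_id, width, prob,
#'   prob_raw, background, pseudocount)
#' @export
read_meme_motifs <- function(path, pseudocount = 0.01) {
  stopifnot(pseudocount > 0)
  if (!file.exists(path)) format_error("file does not exist", path)
  lines <- readLines(path)
  if (!any(grepl("^MEME version", lines)))
    format_error("missing 'MEME version' header", path)
  background <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bg_i <- grep("^Background letter frequencies", lines)
  if (length(bg_i)) {
    toks <- strsplit(trimws(lines[bg_i[1L] + 1L]), "\\s+")[[1L]]
    vals <- suppressWarnings(as.numeric(toks[c(FALSE, TRUE)]))
    names(vals) <- toupper(toks[c(TRUE, FALSE)])
    if (anyNA(vals[DNA_BASES]) || abs(sum(vals[DNA_BASES]) - 1) > 1e-3)
      format_error("malformed background line", path)
    background <- vals[DNA_BASES] / sum(vals[DNA_BASES])
  }
  motif_i <- grep("^MOTIF\\b", lines)
  if (length(motif_i) == 0L) format_error("no MOTIF blocks", path)
  motifs <- list()
  for (mi in motif_i) {
    id <- strsplit(trimws(lines[mi]), "\\s+")[[1L]][2L]
    li <- mi + 1L
    while (li <= length(lines) && !grepl("^letter-probability matrix", lines[li])) li <- li + 1L
    if (li > length(lines)) format_error(sprintf("motif %s: no matrix block", id), path)
    w_decl <- suppressWarnings(as.integer(sub(".*\\bw=\\s*(\\d+).*", "\\1", lines[li])))
    rows <- list(); li <- li + 1L
    while (li <= length(lines) && grepl("^\\s*[0-9.eE+-]", lines[li])) {
      vals <- suppressWarnings(as.numeric(strsplit(trimws(lines[li]), "\\s+")[[1L]]))
      if (length(vals) != 4L || anyNA(vals))
        format_error(sprintf("motif %s: malformed matrix row at line %d", id, li), path)
      rows[[length(rows) + 1L]] <- vals
      li <- li + 1L
    }
    mat <- do.call(rbind, rows)
    if (!is.na(w_decl) && nrow(mat) != w_decl)
      format_error(sprintf("motif %s: %d rows but declared w=%d", id, nrow(mat), w_decl), path)
    if (nrow(mat) < 1L) format_error(sprintf("motif %s: empty matrix", id), path)
    if (any(abs(rowSums(mat) - 1) > 1e-3))
      format_error(sprintf("motif %s: matrix row does not sum to 1", id), path)
    colnames(mat) <- DNA_BASES
    motifs[[id]] <- new_pwm(id, mat, background, pseudocount)
  }
  if (anyDuplicated(names(motifs))) format_error("duplicate motif id", path)
  motifs
}

#' Construct a pwm object from a raw probability matrix
#'
#' @param motif_id motif identifier
#' @param prob_raw width x 4 probability matrix (columns A,C,G,T)
#' @param background length-4 background distribution
#' @param pseudocount regularization pseudocount
#' @export
new_pwm <- function(motif_id, prob_raw, background = c(A = .25, C = .25, G = .25, T = .25),
                    pseudocount = 0.01) {
  prob_raw <- as.matrix(prob_raw)
  colnames(prob_raw) <- DNA_BASES
  prob <- (prob_raw + pseudocount) / (1 + 4 * pseudocount)
  prob <- prob / rowSums(prob)
  stopifnot(all(prob > 0), abs(sum(background) - 1) < 1e-6)
  structure(list(motif_id = motif_id, width = nrow(prob), prob = prob,
                 prob_raw = prob_raw, background = stats::setNames(as.numeric(background), DNA_BASES),
                 pseudocount = pseudocount),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM %s (width %d), consensus %s\n", x$motif_id, x$width, pwm_consensus(x)))
  invisible(x)
}

#' Consensus word of a PWM (per-position argmax)
#' @param pwm a pwm object
#' @export
pwm_consensus <- function(pwm) {
  paste(DNA_BASES[apply(pwm$prob, 1L, which.max)], collapse = "")
}

#' Write motifs in MEME minimal format
#'
#' Raw (pre-regularization) probabilities are written, so reading the
#' file back with the same pseudocount reproduces the input motifs.
#'
#' @param motifs named list of pwm objects
#' @param path output path
#' @export
write_meme_motifs <- function(motifs, path) {
  bg <- motifs[[1L]]$background
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "Background letter frequencies",
               sprintf("A %.6f C %.6f G %.6f T %.6f", bg[1], bg[2], bg[3], bg[4]), ""), con)
  for (m in motifs) {
    writeLines(sprintf("MOTIF %s", m$motif_id), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0", m$width), con)
    writeLines(apply(m$prob_raw, 1L, function(r) paste(sprintf("%.10g", r), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Promoter interval of a gene, strand-aware
#'
#' For a + strand gene with 1-based TSS `t` the window is
#' `[t-1-upstream, t-1+downstream)` in 0-based coordinates; for a -
#' strand gene, `[t-downstream, t+upstream)`.  Windows are truncated at
#' chromosome bounds; an interval falling entirely outside the
#' chromosome comes back empty (start == end), not as an error.
#'
#' @param genes gene data.frame ([read_gene_table()])
#' @param upstream bases upstream of the TSS (default 500)
#' @param downstream bases downstream (default 0); upstream+downstream > 0
#' @param chrom_lengths named vector of chromosome lengths (optional;
#'   without it only the lower bound is enforced)
#' @return data.frame gene_id, chrom, strand, start, end (0-based half-open)
#' @export
promoter_interval <- function(genes, upstream = 500L, downstream = 0L,
                              chrom_lengths = NULL) {
  stopifnot(upstream >= 0, downstream >= 0, upstream + downstream > 0)
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss - 1L - upstream, genes$tss - downstream)
  end   <- ifelse(plus, genes$tss - 1L + downstream, genes$tss + upstream)
  start <- pmax(start, 0L)
  if (!is.null(chrom_lengths)) {
    len <- as.integer(chrom_lengths[genes$chrom])
    end <- pmin(end, len)
    start <- pmin(start, len)
  }
  end <- pmax(end, start)
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom, strand = genes$strand,
             start = as.integer(start), end = as.integer(end), stringsAsFactors = FALSE)
}

#' Extract promoter sequences, reverse-complemented for - strand genes
#'
#' "Upstream" is always biologically upstream: the returned string reads
#' 5' to 3' toward the TSS for both strands.
#'
#' @inheritParams promoter_interval
#' @param genome DNAStringSet from [read_fasta()]
#' @return named character vector (gene_id -> sequence; empty string for
#'   empty windows)
#' @export
promoter_sequences <- function(genome, genes, upstream = 500L, downstream = 0L) {
  iv <- promoter_interval(genes, upstream, downstream, chrom_lengths(genome))
  seqs <- character(nrow(iv))
  for (i in seq_len(nrow(iv))) {
    if (iv$end[i] <= iv$start[i] || !iv$chrom[i] %in% names(genome)) { seqs[i] <- ""; next }
    s <- Biostrings::subseq(genome[[iv$chrom[i]]], iv$start[i] + 1L, iv$end[i])
    if (iv$strand[i] == "-") s <- Biostrings::reverseComplement(s)
    seqs[i] <- as.character(s)
  }
  stats::setNames(seqs, iv$gene_id)
}

#' Reverse-complement a DNA string (A/C/G/T/N)
#' @param x character vector of sequences
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    if (nchar(s) == 0L) return("")
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, "", USE.NAMES = FALSE)
}
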