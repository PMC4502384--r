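## pipeline_cli: configured, logged, deterministic orchestration of the
## stages: annotate -> classify -> enrich -> scan -> screen ->
## compare-strength -> summarize.  Every output TSV carries a provenance
## header; a JSON manifest lists outputs with md5 checksums.

#' Pipeline configuration
#'
#' Bundles input paths, factor names and every tunable constant.  Any
#' unset key takes its default (and is logged as such when the pipeline
#' runs).  Defaults: 500 bp upstream promoter analysis window,
#' -1000..+100 annotation window, 500 bp binding-call distance, 100 bp
#' overlap threshold, 50 bp enrichment sliding window, site p-value
#' cutoff 0.0005, screen thresholds 0.19 / 0.04 / 0.14, strength test
#' alpha 0.05.
#'
#' @param genome,genes,motifs input paths (FASTA, gene table/GFF3, MEME)
#' @param peaks named character vector of 2 peak paths (names = factors)
#' @param coverage named character vector of 2 coverage paths
#' @param gene_sets optional named character vector of gene-list paths
#'   (one gene id per line)
#' @param outdir output directory
#' @param factors length-2 factor names (default: names of `peaks`)
#' @param promoter_upstream,annotation_window,binding_max_dist,
#'   overlap_threshold,enrichment_window,scan_max_p,r_high,delta_shared,
#'   delta_diff,strength_alpha analysis constants
#' @param strength_groups co-binding classes compared by the strength
#'   test (default both vs B_only)
#' @param seed seed recorded in provenance (the pipeline itself is
#'   deterministic given its inputs)
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(genome, genes, peaks, coverage, motifs,
                            gene_sets = NULL, outdir = "dualchip_out",
                            factors = names(peaks),
                            promoter_upstream = 500L,
                            annotation_window = c(-1000, 100),
                            binding_max_dist = 500L,
                            overlap_threshold = 100L,
                            enrichment_window = 50L,
                            scan_max_p = 5e-4,
                            r_high = 0.19, delta_shared = 0.04, delta_diff = 0.14,
                            strength_alpha = 0.05,
                            strength_groups = c("both", "B_only"),
                            seed = 1L) {
  stopifnot(length(peaks) == 2L, length(coverage) == 2L, length(factors) == 2L,
            promoter_upstream > 0, binding_max_dist >= 0, overlap_threshold >= 0,
            enrichment_window >= 1, scan_max_p > 0, strength_alpha > 0)
  structure(list(genome = genome, genes = genes, peaks = peaks,
                 coverage = coverage, motifs = motifs, gene_sets = gene_sets,
                 outdir = outdir, factors = factors,
                 promoter_upstream = as.integer(promoter_upstream),
                 annotation_window = annotation_window,
                 binding_max_dist = as.integer(binding_max_dist),
                 overlap_threshold = as.integer(overlap_threshold),
                 enrichment_window = as.integer(enrichment_window),
                 scan_max_p = scan_max_p, r_high = r_high,
                 delta_shared = delta_shared, delta_diff = delta_diff,
                 strength_alpha = strength_alpha,
                 strength_groups = strength_groups,
                 seed = as.integer(seed)),
            class = c("pipeline_config", "list"))
}

#' Load a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; unset keys take
#' the defaults.  Relative input paths are resolved against the YAML
#' file's directory.
#'
#' @param path YAML file
#' @export
load_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  fix <- function(p) {
    if (is.null(p)) return(NULL)
    out <- ifelse(grepl("^/", unlist(p)), unlist(p), file.path(base, unlist(p)))
    stats::setNames(out, names(unlist(p)))
  }
  for (k in c("genome", "genes", "motifs")) y[[k]] <- fix(y[[k]])
  for (k in c("peaks", "coverage", "gene_sets")) y[[k]] <- fix(y[[k]])
  do.call(pipeline_config, y)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config), tmp)
  unname(tools::md5sum(tmp))
}

write_tsv_prov <- function(df, path, config, params = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# dualchip %s", as.character(utils::packageVersion("dualchip"))),
               sprintf("# config_hash=%s", config_hash(config)),
               sprintf("# seed=%d", config$seed),
               sprintf("# %s", params)), con)
  suppressWarnings(utils::write.table(df, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE))
  path
}

#' Read a pipeline output TSV (skipping provenance comments)
#' @param path TSV written by [run_pipeline()]
#' @export
read_pipeline_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

pipe_log <- function(...) message(sprintf("[dualchip] %s", sprintf(...)))

#' Run the full analysis pipeline
#'
#' Stages: read inputs, annotate peaks to nearest genes, classify
#' co-binding, quantify promoter enrichment, scan promoters with the
#' motif library, run the occupancy/enrichment correlation screen,
#' compare site strength between co-bound and single-factor promoters,
#' and summarize (peak-set overlap and optional gene-set binding
#' fractions).  All outputs are TSVs with provenance headers plus a
#' `manifest.json` of md5 checksums; rerunning with identical inputs
#' and config reproduces identical checksums.
#'
#' @param config a [pipeline_config()] or path to a YAML config
#' @return invisible list of all stage results and output paths
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    pipe_log("stage %s", name)
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  fa <- config$factors
  out_files <- character(0)
  emit <- function(df, name, params = character(0)) {
    p <- file.path(config$outdir, name)
    write_tsv_prov(df, p, config, params)
    out_files[[name]] <<- p
    p
  }

  genome <- stage("read-genome", read_fasta(config$genome))
  genes <- stage("read-genes", read_gene_table(config$genes))
  peaks <- stage("read-peaks", lapply(config$peaks, read_bed_peaks))
  tracks <- stage("read-coverage",
                  lapply(config$coverage, read_coverage, chrom_lengths = chrom_lengths(genome)))
  motifs <- stage("read-motifs", read_meme_motifs(config$motifs))

  ann <- stage("annotate", {
    lapply(seq_along(peaks), function(i)
      suppressWarnings(assign_peaks_to_genes(peaks[[i]], genes, config$annotation_window)))
  })
  for (i in 1:2)
    emit(ann[[i]], sprintf("assignments_%s.tsv", fa[i]),
         sprintf("annotation_window=%d..%d", config$annotation_window[1],
                 config$annotation_window[2]))

  cobind <- stage("classify",
                  classify_cobinding(peaks[[1L]], peaks[[2L]], genes,
                                     config$binding_max_dist, fa))
  emit(cobind, "cobinding.tsv", sprintf("binding_max_dist=%d", config$binding_max_dist))

  enrich <- stage("enrich", lapply(1:2, function(i)
    suppressWarnings(build_enrichment_table(
      tracks[[i]], genes, fa[i], config$promoter_upstream, 0L,
      config$enrichment_window, chrom_lengths(genome)))))
  for (i in 1:2)
    emit(enrich[[i]], sprintf("enrichment_%s.tsv", fa[i]),
         sprintf("window_w=%d upstream=%d", config$enrichment_window,
                 config$promoter_upstream))

  scan <- stage("scan", {
    seqs <- promoter_sequences(genome, genes, config$promoter_upstream)
    scan_promoters(seqs, motifs, scan_config(max_p = config$scan_max_p))
  })
  emit(scan$sites, "sites.tsv", sprintf("max_p=%g", config$scan_max_p))
  occ_df <- data.frame(gene_id = rownames(scan$occupancy), scan$occupancy,
                       check.names = FALSE)
  emit(occ_df, "occupancy.tsv", "occupancy=relative_affinity_sum")

  screen <- stage("screen",
                  motif_association_screen(scan$occupancy, enrich[[1L]], enrich[[2L]],
                                           config$r_high, config$delta_shared,
                                           config$delta_diff))
  emit(screen, "screen.tsv",
       sprintf("r_high=%g delta_shared=%g delta_diff=%g", config$r_high,
               config$delta_shared, config$delta_diff))

  strength <- stage("compare-strength",
                    site_strength_table(scan$sites, cobind,
                                        groups = config$strength_groups,
                                        alpha = config$strength_alpha))
  emit(strength, "strength.tsv",
       sprintf("groups=%s,%s alpha=%g", config$strength_groups[1],
               config$strength_groups[2], config$strength_alpha))

  overlap <- stage("summarize-overlap",
                   overlap_peak_sets(peaks[[1L]], peaks[[2L]],
                                     config$overlap_threshold,
                                     sum(chrom_lengths(genome))))
  emit(as.data.frame(overlap), "overlap.tsv",
       sprintf("threshold=%d", config$overlap_threshold))

  fractions <- NULL
  if (!is.null(config$gene_sets)) {
    sets <- lapply(config$gene_sets, function(p) readLines(p, warn = FALSE))
    fractions <- stage("summarize-fractions", binding_fraction_summary(sets, cobind))
    emit(fractions, "fractions.tsv")
  }

  manifest <- list(tool = "dualchip",
                   version = as.character(utils::packageVersion("dualchip")),
                   config_hash = config_hash(config), seed = config$seed,
                   files = as.list(vapply(out_files, function(p)
                     unname(tools::md5sum(p)), "")))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(assignments = ann, cobinding = cobind, enrichment = enrich,
                 sites = scan$sites, occupancy = scan$occupancy,
                 screen = screen, strength = strength, overlap = overlap,
                 fractions = fractions, files = out_files,
                 manifest = file.path(config$outdir, "manifest.json")))
}
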