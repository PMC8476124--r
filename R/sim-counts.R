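#' Simulate a two-condition RNA-seq count matrix with target de-repression
#'
#' Gene baselines are drawn log-uniform over `baseline_mean_log10_range`.
#' Counts are negative-binomial with a shared dispersion; in treatment
#' samples the mean of a targeted gene is multiplied by `2^delta`, where
#' `delta` is the gene's ground-truth de-repression effect (the maximum over
#' the families targeting it). Means are capped at 1e8 to keep the NB
#' sampler away from integer overflow; with the default baseline range the
#' cap is never active.
#'
#' @inheritParams sim_ground_truth
#' @param ground_truth result of [sim_ground_truth()].
#' @return list with `counts` (integer matrix, genes x samples), and
#'   `conditions` (data.frame: `sample`, `condition` in
#'   `{"control","treatment"}`).
#' @export
sim_counts <- function(target_map, ground_truth, config) {
  config <- validate_sim_config(config)
  missing_tgt <- setdiff(target_map$gene_id, gene_universe(config))
  if (length(missing_tgt) > 0) {
    stop("target genes outside the gene universe: ",
         paste(utils::head(missing_tgt, 5), collapse = ", "))
  }
  set.seed(stage_seed(config, "counts"))
  genes <- gene_universe(config)
  r <- config$baseline_mean_log10_range
  baseline <- 10^stats::runif(config$n_genes, r[1], r[2])
  delta <- stats::setNames(rep(0, config$n_genes), genes)
  delta[ground_truth$gene_effects$gene_id] <- ground_truth$gene_effects$delta

  k <- config$n_samples_per_condition
  samples <- c(sprintf("ctl_%d", seq_len(k)), sprintf("trt_%d", seq_len(k)))
  condition <- rep(c("control", "treatment"), each = k)
  mu <- cbind(
    matrix(rep(baseline, k), ncol = k),
    matrix(rep(pmin(baseline * 2^delta, 1e8), k), ncol = k)
  )
  size <- 1 / config$nb_dispersion
  counts <- matrix(
    stats::rnbinom(length(mu), mu = as.vector(mu), size = size),
    nrow = config$n_genes, dimnames = list(genes, samples)
  )
  storage.mode(counts) <- "integer"
  list(counts = counts,
       conditions = data.frame(sample = samples, condition = condition,
                               stringsAsFactors = FALSE))
}

#' Simulate a complete experiment
#'
#' Convenience wrapper chaining [sim_annotation()], [sim_target_map()],
#' [sim_ground_truth()], optionally [sim_small_rna()], and [sim_counts()].
#'
#' @param config a [sim_config()] object.
#' @param reads if `FALSE`, skip the small-RNA read realization (the
#'   ground-truth abundances are still drawn); useful for expression-only
#'   simulations.
#' @return list with components `config`, `annotation`, `target_map`,
#'   `ground_truth`, `small_rna` (or `NULL`), `counts`, `conditions`.
#' @export
sim_dataset <- function(config = sim_config(), reads = TRUE) {
  config <- validate_sim_config(config)
  ann <- sim_annotation(config)
  tm <- sim_target_map(config, ann$families)
  gt <- sim_ground_truth(ann, tm, config)
  sr <- if (reads) sim_small_rna(ann, gt, config) else NULL
  cm <- sim_counts(tm, gt, config)
  list(config = config, annotation = ann, target_map = tm, ground_truth = gt,
       small_rna = sr, counts = cm$counts, conditions = cm$conditions)
}

#' Write a simulated dataset to disk in standard formats
#'
#' Writes precursor FASTA, mature-annotation GFF3 (miRBase dialect: `miRNA`
#' features with a `Derives_from` attribute naming the precursor), SAM
#' alignments, the count matrix and condition TSVs, family and target TSVs,
#' and a ground-truth JSON.
#'
#' @param sim result of [sim_dataset()].
#' @param outdir output directory (created if absent).
#' @return named character vector of written paths, invisibly.
#' @export
write_sim_dataset <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  paths <- c(
    fasta = p("precursors.fa"), gff3 = p("matures.gff3"),
    sam = p("reads.sam"), counts = p("counts.tsv"),
    conditions = p("conditions.tsv"), families = p("families.tsv"),
    targets = p("targets.tsv"), ground_truth = p("ground_truth.json")
  )
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sim$annotation$precursors), paths["fasta"])
  export_mature_gff3(sim$annotation, paths["gff3"])
  if (!is.null(sim$small_rna)) {
    write_sam(sim$small_rna$reads, sim$annotation$precursors, paths["sam"])
  } else {
    paths <- paths[names(paths) != "sam"]
  }
  write_tsv(data.frame(feature_id = rownames(sim$counts), sim$counts,
                       check.names = FALSE), paths["counts"])
  write_tsv(sim$conditions, paths["conditions"])
  write_tsv(sim$annotation$families, paths["families"])
  write_tsv(sim$target_map, paths["targets"])
  jsonlite::write_json(
    list(
      families = sim$ground_truth$families,
      mature_reads = sim$ground_truth$mature_reads,
      gene_effects = sim$ground_truth$gene_effects
    ),
    paths["ground_truth"], digits = NA, dataframe = "columns"
  )
  invisible(paths)
}

#' @keywords internal
export_mature_gff3 <- function(annotation, path) {
  prec <- annotation$precursors
  mat <- annotation$matures
  gr_prec <- GenomicRanges::GRanges(
    seqnames = names(prec),
    ranges = IRanges::IRanges(start = 1L, end = nchar(prec)),
    strand = "+",
    type = "miRNA_primary_transcript",
    ID = names(prec), Name = names(prec)
  )
  gr_mat <- GenomicRanges::GRanges(
    seqnames = mat$precursor_id,
    ranges = IRanges::IRanges(start = mat$start, end = mat$end),
    strand = "+",
    type = "miRNA",
    ID = mat$mature_id, Name = mat$mature_id
  )
  S4Vectors::mcols(gr_mat)$Derives_from <- mat$precursor_id
  S4Vectors::mcols(gr_prec)$Derives_from <- NA_character_
  gr <- c(gr_prec, gr_mat)
  GenomeInfoDb::seqlengths(gr) <- stats::setNames(nchar(prec), names(prec))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE, ...)
}
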