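#' Simulate ground-truth family abundances and de-repression effects
#'
#' Draws expected small-RNA read totals per family across three decades
#' (`reads_per_mirna_scale * 10^Uniform(0,3)`), splits them over family
#' members, and realizes per-mature read counts as Poisson draws. The family
#' abundance is `a_f = log10(total realized reads)` and the de-repression
#' effect assigned to the family's targets is linear in log abundance:
#' `delta_f = max_effect_log2 * a_f / max(a)`, so the effect is monotone
#' (and roughly proportional) in family abundance. A gene predicted as a
#' target of several families takes the maximum delta over them.
#'
#' @param annotation result of [sim_annotation()].
#' @param target_map result of [sim_target_map()].
#' @param config a [sim_config()] object.
#' @return list with components `mature_reads` (data.frame: `mature_id`,
#'   `family_id`, `n_reads`), `families` (data.frame: `family_id`,
#'   `total_reads`, `abundance_log10`, `delta`), and `gene_effects`
#'   (data.frame: `gene_id`, `delta` for every targeted gene).
#' @export
sim_ground_truth <- function(annotation, target_map, config) {
  config <- validate_sim_config(config)
  set.seed(stage_seed(config, "ground_truth"))
  mat <- annotation$matures
  fam_ids <- sort(unique(mat$family_id))
  u <- stats::runif(length(fam_ids), 0, 3)
  lambda_fam <- config$reads_per_mirna_scale * 10^u
  names(lambda_fam) <- fam_ids

  w <- stats::runif(nrow(mat), 0.5, 1.5)
  w_sum <- tapply(w, mat$family_id, sum)
  lambda_mat <- lambda_fam[mat$family_id] * w / w_sum[mat$family_id]
  n_reads <- stats::rpois(nrow(mat), lambda_mat)

  mature_reads <- data.frame(
    mature_id = mat$mature_id,
    family_id = mat$family_id,
    n_reads = as.integer(n_reads),
    stringsAsFactors = FALSE
  )
  total <- tapply(mature_reads$n_reads, mature_reads$family_id, sum)[fam_ids]
  abundance <- ifelse(total > 0, log10(total), NA_real_)
  amax <- suppressWarnings(max(abundance, na.rm = TRUE))
  delta <- if (is.finite(amax) && amax > 0) {
    ifelse(is.na(abundance), 0, config$max_effect_log2 * abundance / amax)
  } else {
    rep(0, length(fam_ids))
  }
  families <- data.frame(
    family_id = fam_ids,
    total_reads = as.integer(total),
    abundance_log10 = as.numeric(abundance),
    delta = as.numeric(delta),
    stringsAsFactors = FALSE
  )

  fam_delta <- stats::setNames(families$delta, families$family_id)
  per_gene <- tapply(fam_delta[target_map$family_id], target_map$gene_id, max)
  gene_effects <- data.frame(
    gene_id = names(per_gene),
    delta = as.numeric(per_gene),
    stringsAsFactors = FALSE
  )
  list(mature_reads = mature_reads, families = families,
       gene_effects = gene_effects)
}

#' Simulate small-RNA read alignments in precursor space
#'
#' Emits, for each mature, the ground-truth number of reads whose 5' and 3'
#' ends are the annotated mature ends plus independent offsets drawn from
#' `end_jitter_probs` (emulating isomiR end heterogeneity). All reads are
#' sense-strand primary alignments. A read is counted as in-window when both
#' end offsets have absolute value <= 4 nt, matching the quantifier's
#' counting rule.
#'
#' @inheritParams sim_ground_truth
#' @param ground_truth result of [sim_ground_truth()].
#' @return list with `reads` (data.frame: `read_id`, `precursor_id`,
#'   `aln_start`, `aln_end`, `strand`, `is_primary`, `offset5`, `offset3`,
#'   `mature_id`, `in_window`) and `truth_counts` (data.frame: `mature_id`,
#'   `count` of in-window reads).
#' @export
sim_small_rna <- function(annotation, ground_truth, config) {
  config <- validate_sim_config(config)
  set.seed(stage_seed(config, "reads"))
  mat <- annotation$matures
  n_reads <- ground_truth$mature_reads$n_reads[
    match(mat$mature_id, ground_truth$mature_reads$mature_id)]
  idx <- rep(seq_len(nrow(mat)), n_reads)
  n <- length(idx)
  support <- jitter_support(config)
  # index-based draw: sample(x, ...) on a length-1 integer would sample 1:x
  off5 <- support[sample.int(length(support), n, replace = TRUE,
                             prob = config$end_jitter_probs)]
  off3 <- support[sample.int(length(support), n, replace = TRUE,
                             prob = config$end_jitter_probs)]
  aln_start <- mat$start[idx] + off5
  aln_end <- mat$end[idx] + off3
  prec_len <- nchar(annotation$precursors)[
    match(mat$precursor_id[idx], names(annotation$precursors))]
  if (any(aln_start < 1L | aln_end > prec_len | aln_start > aln_end)) {
    stop("simulated read exceeds precursor bounds; increase precursor margins")
  }
  reads <- data.frame(
    read_id = sprintf("read%07d", seq_len(n)),
    precursor_id = mat$precursor_id[idx],
    aln_start = as.integer(aln_start),
    aln_end = as.integer(aln_end),
    strand = "+",
    is_primary = TRUE,
    offset5 = as.integer(off5),
    offset3 = as.integer(off3),
    mature_id = mat$mature_id[idx],
    in_window = abs(off5) <= 4L & abs(off3) <= 4L,
    stringsAsFactors = FALSE
  )
  cnt <- tapply(reads$in_window, factor(reads$mature_id, levels = mat$mature_id),
                sum, default = 0L)
  truth_counts <- data.frame(
    mature_id = mat$mature_id,
    count = as.integer(cnt),
    stringsAsFactors = FALSE
  )
  list(reads = reads, truth_counts = truth_counts)
}

#' Write simulated reads as a SAM file
#'
#' Emits a valid SAM file with one `@SQ` header line per precursor and one
#' ungapped (`<len>M`) sense-strand primary record per simulated read, with
#' the read sequence taken from the precursor.
#'
#' @param reads data.frame from [sim_small_rna()]`$reads`.
#' @param precursors named character vector of precursor sequences.
#' @param path output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, precursors, path) {
  header <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", names(precursors), nchar(precursors))
  )
  if (nrow(reads) > 0) {
    seqs <- substring(precursors[reads$precursor_id], reads$aln_start,
                      reads$aln_end)
    body <- paste(
      reads$read_id,
      ifelse(reads$strand == "+", 0L, 16L) + ifelse(reads$is_primary, 0L, 256L),
      reads$precursor_id,
      reads$aln_start,
      255L,
      sprintf("%dM", reads$aln_end - reads$aln_start + 1L),
      "*", 0L, 0L,
      seqs,
      "*",
      sep = "\t"
    )
  } else {
    body <- character(0)
  }
  writeLines(c(header, body), path)
  invisible(path)
}
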