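#' Read mature miRNA annotations from a miRBase-dialect GFF3
#'
#' Every `miRNA` feature becomes one mature record; its `Derives_from`
#' attribute must name the precursor whose coordinate system the feature
#' lives in. Coordinates are kept 1-based inclusive as in the file.
#'
#' @param path GFF3 file.
#' @param families optional family table (data.frame with `family_id` and
#'   `member_mirna`, as read by [read_family_table()]); when supplied, a
#'   `family_id` column is joined onto the result.
#' @return data.frame: `mature_id`, `precursor_id`, `start`, `end`
#'   (and `family_id` when `families` is given).
#' @export
read_mature_gff3 <- function(path, families = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[S4Vectors::mcols(gr)$type == "miRNA"]
  if (length(gr) == 0) {
    out <- data.frame(mature_id = character(0), precursor_id = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE)
    return(out)
  }
  ids <- as.character(S4Vectors::mcols(gr)$ID)
  if (is.null(ids) || anyNA(ids)) stop("miRNA feature without an ID attribute")
  df <- S4Vectors::mcols(gr)$Derives_from
  # rtracklayer may return multi-valued attributes as a CharacterList
  if (methods::is(df, "List")) {
    lens <- lengths(df)
    if (any(lens == 0)) {
      stop("miRNA feature missing Derives_from: ",
           paste(ids[lens == 0], collapse = ", "))
    }
    df <- vapply(df, `[`, character(1), 1L)
  }
  if (is.null(df) || anyNA(df) || any(!nzchar(df))) {
    bad <- if (is.null(df)) ids else ids[is.na(df) | !nzchar(df)]
    stop("miRNA feature missing Derives_from: ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(ids)) {
    stop("duplicate mature_id in annotation: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  out <- data.frame(
    mature_id = ids,
    precursor_id = as.character(df),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  if (!is.null(families)) {
    out$family_id <- families$family_id[match(out$mature_id,
                                              families$member_mirna)]
  }
  out
}

#' Read a seed-family membership table
#'
#' @param path TSV with columns `family_id`, `seed`, `member_mirna`.
#' @return the table as a data.frame.
#' @export
read_family_table <- function(path) {
  df <- read_tsv(path)
  need <- c("family_id", "member_mirna")
  if (!all(need %in% names(df))) {
    stop("family table must have columns: ", paste(need, collapse = ", "))
  }
  df
}

#' Read precursor-space small-RNA alignments from SAM or BAM
#'
#' Alignment ends are aligned-segment ends in precursor coordinates
#' (soft-clipped bases excluded), the coordinates the end-window counting
#' rule is defined on. SAM input is converted through [Rsamtools::asBam()].
#'
#' @param path SAM or BAM file.
#' @return data.frame: `read_id`, `precursor_id`, `aln_start`, `aln_end`
#'   (1-based inclusive), `strand`, `is_primary`.
#' @export
read_precursor_alignments <- function(path) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(what = c("qname", "flag"))
  ga <- GenomicAlignments::readGAlignments(bam, param = param)
  mc <- S4Vectors::mcols(ga)
  data.frame(
    read_id = mc$qname,
    precursor_id = as.character(GenomicAlignments::seqnames(ga)),
    aln_start = GenomicAlignments::start(ga),
    aln_end = GenomicAlignments::end(ga),
    strand = as.character(GenomicAlignments::strand(ga)),
    is_primary = bitwAnd(mc$flag, 256L) == 0L,
    stringsAsFactors = FALSE
  )
}

#' End-window matching rule for a single alignment
#'
#' A read matches a mature miRNA when both its 5' and 3' aligned ends fall
#' within `window` nt of the annotated mature ends (bounds inclusive), it is
#' on the sense strand, and it is a primary alignment.
#'
#' @param aln one alignment as a list/one-row data.frame with fields
#'   `precursor_id`, `aln_start`, `aln_end`, `strand`, `is_primary`.
#' @param mature one mature record with fields `precursor_id`, `start`, `end`.
#' @param window maximum absolute end offset in nt (default 4).
#' @return logical scalar.
#' @export
match_read <- function(aln, mature, window = 4L) {
  if (aln$precursor_id[1] != mature$precursor_id[1]) {
    stop("alignment and mature are on different precursors (caller bug): ",
         aln$precursor_id[1], " vs ", mature$precursor_id[1])
  }
  isTRUE(aln$strand[1] == "+") && isTRUE(aln$is_primary[1]) &&
    abs(aln$aln_start[1] - mature$start[1]) <= window &&
    abs(aln$aln_end[1] - mature$end[1]) <= window
}

#' Count reads per mature miRNA with the end-window rule
#'
#' Counts primary, sense-strand alignments whose ends fall within `window`
#' nt of a mature's annotated 5' and 3' ends. Each read contributes at most
#' one count; a read compatible with several matures is assigned to the one
#' minimizing the total end offset `|d5| + |d3|`, ties broken by the
#' lexicographically smallest `mature_id`. Alignments on precursors absent
#' from the annotation are tallied as `unassigned_reference`, never silently
#' dropped.
#'
#' @param alignments data.frame from [read_precursor_alignments()].
#' @param annotations data.frame of mature records (see [read_mature_gff3()]).
#' @param window maximum absolute end offset in nt (default 4).
#' @param rule `"both_ends"` (default): both ends must be in-window;
#'   `"either_end"`: one suffices.
#' @param multi `"closest"` (default): a multi-matching read is assigned
#'   once, to the closest mature; `"all"`: it increments every matching
#'   mature (per-hit counting).
#' @return list with `counts` (data.frame: `mature_id`, `count`, including
#'   zero rows) and `qc` (list: `total_alignments`, `primary_plus`,
#'   `assigned`, `unmatched`, `unassigned_reference`,
#'   `secondary_or_antisense`).
#' @export
count_mature <- function(alignments, annotations, window = 4L,
                         rule = c("both_ends", "either_end"),
                         multi = c("closest", "all")) {
  rule <- match.arg(rule)
  multi <- match.arg(multi)
  if (nrow(annotations) == 0) stop("annotations must be non-empty")
  total <- nrow(alignments)
  keep <- alignments$is_primary & alignments$strand == "+"
  aln <- alignments[keep, , drop = FALSE]
  known <- aln$precursor_id %in% annotations$precursor_id
  unassigned_reference <- sum(!known)
  aln <- aln[known, , drop = FALSE]

  zero <- stats::setNames(integer(nrow(annotations)), annotations$mature_id)
  assigned <- 0L
  if (nrow(aln) > 0) {
    cand <- merge(
      aln[, c("read_id", "precursor_id", "aln_start", "aln_end")],
      annotations[, c("mature_id", "precursor_id", "start", "end")],
      by = "precursor_id"
    )
    d5 <- abs(cand$aln_start - cand$start)
    d3 <- abs(cand$aln_end - cand$end)
    ok <- if (rule == "both_ends") d5 <= window & d3 <= window
          else d5 <= window | d3 <= window
    cand <- cand[ok, , drop = FALSE]
    dist <- (d5 + d3)[ok]
    if (multi == "closest" && nrow(cand) > 0) {
      o <- order(cand$read_id, dist, cand$mature_id)
      cand <- cand[o, , drop = FALSE]
      cand <- cand[!duplicated(cand$read_id), , drop = FALSE]
    }
    assigned <- length(unique(cand$read_id))
    tab <- table(factor(cand$mature_id, levels = annotations$mature_id))
    zero[names(tab)] <- as.integer(tab)
  }
  counts <- data.frame(mature_id = annotations$mature_id,
                       count = as.integer(zero[annotations$mature_id]),
                       stringsAsFactors = FALSE)
  qc <- list(
    total_alignments = total,
    primary_plus = sum(keep),
    assigned = assigned,
    unmatched = sum(keep) - unassigned_reference - assigned,
    unassigned_reference = unassigned_reference,
    secondary_or_antisense = total - sum(keep)
  )
  list(counts = counts, qc = qc)
}

#' Aggregate mature counts to seed families
#'
#' Sums read counts over the members of each seed family and reports the
#' family abundance as the log (base `log_base`, default 10) of the summed
#' count. Families whose members received zero reads have undefined
#' abundance and are flagged for downstream exclusion.
#'
#' @param mature_counts data.frame (`mature_id`, `count`).
#' @param families family table (`family_id`, `member_mirna`).
#' @param log_base base of the abundance logarithm (default 10).
#' @return data.frame: `family_id`, `family_count`, `abundance_log10`
#'   (NA when undefined), `abundance_undefined`.
#' @export
aggregate_families <- function(mature_counts, families, log_base = 10) {
  fam <- families$family_id[match(mature_counts$mature_id,
                                  families$member_mirna)]
  if (anyNA(fam)) {
    stop("matures with no family assignment: ",
         paste(mature_counts$mature_id[is.na(fam)], collapse = ", "))
  }
  total <- tapply(mature_counts$count, fam, sum)
  out <- data.frame(
    family_id = names(total),
    family_count = as.integer(total),
    stringsAsFactors = FALSE
  )
  out$abundance_log10 <- ifelse(out$family_count > 0,
                                log(out$family_count, base = log_base),
                                NA_real_)
  out$abundance_undefined <- out$family_count == 0
  out[order(out$family_id), , drop = FALSE]
}

#' Compare per-miRNA abundance between two libraries
#'
#' Normalizes both count vectors to counts-per-million and reports the
#' per-mature log2 ratio (with a small CPM pseudocount so zeros are finite)
#' and the Spearman correlation between the two libraries, the summary used
#' for abundance scatter plots comparing conditions.
#'
#' @param counts_a,counts_b named integer vectors over the same mature
#'   universe.
#' @param pseudo_cpm pseudocount added on the CPM scale (default 0.5).
#' @return list with `table` (data.frame: `mature_id`, `cpm_a`, `cpm_b`,
#'   `log2_ratio`) and `spearman_rho`.
#' @export
compare_mirna_abundance <- function(counts_a, counts_b, pseudo_cpm = 0.5) {
  if (is.null(names(counts_a)) || is.null(names(counts_b)) ||
      !setequal(names(counts_a), names(counts_b))) {
    stop("both count vectors must be named over the same mature universe")
  }
  counts_b <- counts_b[names(counts_a)]
  ta <- sum(counts_a); tb <- sum(counts_b)
  if (ta <= 0 || tb <= 0) stop("zero-total library")
  cpm_a <- counts_a / ta * 1e6
  cpm_b <- counts_b / tb * 1e6
  tab <- data.frame(
    mature_id = names(counts_a),
    cpm_a = as.numeric(cpm_a),
    cpm_b = as.numeric(cpm_b),
    log2_ratio = log2((cpm_a + pseudo_cpm) / (cpm_b + pseudo_cpm)),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  list(table = tab,
       spearman_rho = stats::cor(cpm_a, cpm_b, method = "spearman"))
}
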