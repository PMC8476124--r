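# Independent oracles, deliberately naive: these re-derive expected values
# by direct enumeration / direct formula application and must stay
# independent of the package's optimized code paths.

# O(reads x matures) end-window matcher with the closest-assignment tie rule.
brute_count <- function(alignments, matures, window = 4L) {
  counts <- stats::setNames(integer(nrow(matures)), matures$mature_id)
  a_prec <- alignments$precursor_id; a_s <- alignments$aln_start
  a_e <- alignments$aln_end; a_str <- alignments$strand
  a_pri <- alignments$is_primary
  m_prec <- matures$precursor_id; m_s <- matures$start; m_e <- matures$end
  m_id <- matures$mature_id
  unassigned_reference <- 0L
  for (i in seq_along(a_prec)) {
    if (!isTRUE(a_pri[i]) || a_str[i] != "+") next
    if (!a_prec[i] %in% m_prec) {
      unassigned_reference <- unassigned_reference + 1L
      next
    }
    best <- NA_character_
    best_d <- Inf
    for (j in seq_along(m_prec)) {
      if (m_prec[j] != a_prec[i]) next
      d5 <- abs(a_s[i] - m_s[j])
      d3 <- abs(a_e[i] - m_e[j])
      if (d5 <= window && d3 <= window) {
        d <- d5 + d3
        if (d < best_d || (d == best_d && m_id[j] < best)) {
          best <- m_id[j]
          best_d <- d
        }
      }
    }
    if (!is.na(best)) counts[best] <- counts[best] + 1L
  }
  list(counts = counts, unassigned_reference = unassigned_reference)
}

# direct median-of-ratios formula, written out long-hand
oracle_size_factors <- function(counts) {
  geo <- apply(counts, 1, function(g) prod(g)^(1 / length(g)))
  ok <- geo > 0
  vapply(seq_len(ncol(counts)), function(s) {
    stats::median(counts[ok, s] / geo[ok])
  }, numeric(1))
}

# small fold-change table builder
make_fc <- function(log2fc, gene_id = sprintf("g%03d", seq_along(log2fc)),
                    mean_expr = 100, expressed = TRUE) {
  data.frame(gene_id = gene_id, log2fc = log2fc, mean_expr = mean_expr,
             expressed = expressed, stringsAsFactors = FALSE)
}

# Kolmogorov distance between a sample and the standard normal
ks_dist_normal <- function(z) {
  z <- sort(z)
  n <- length(z)
  max(abs(stats::pnorm(z) - (seq_len(n) - 1) / n),
      abs(stats::pnorm(z) - seq_len(n) / n))
}

read_tsv <- derepressr:::read_tsv

# compact simulation config for fast tests
quick_config <- function(...) {
  sim_config(n_genes = 400, n_families = 5, targets_per_family = 20,
             reads_per_mirna_scale = 5, ...)
}
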