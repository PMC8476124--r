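#' Background distribution of log2-fold changes
#'
#' Mean and sample standard deviation (n-1 denominator) of log2-fold
#' changes over expressed genes outside `exclude` — the transcriptome
#' background a target set is standardized against.
#'
#' @param fc fold-change table with `gene_id`, `log2fc`, `expressed`.
#' @param exclude character vector of gene ids to leave out (typically the
#'   target set being scored).
#' @return list: `mu`, `sd`, `n_background`.
#' @export
background_stats <- function(fc, exclude = character(0)) {
  vals <- fc$log2fc[fc$expressed & !(fc$gene_id %in% exclude)]
  if (length(vals) < 2) {
    stop("empty background: fewer than 2 expressed genes outside the ",
         "excluded set")
  }
  s <- stats::sd(vals)
  if (s == 0) stop("degenerate background: all background log2fc equal")
  list(mu = mean(vals), sd = s, n_background = length(vals))
}

#' De-repression z-score of a target gene set
#'
#' Standardizes the mean log2-fold change of a family's expressed predicted
#' targets against the background: `z = (Sm - mu) * sqrt(m) / sd`, where
#' `Sm` is the target-set mean, `m` the number of expressed targets, and
#' `mu`, `sd` the background mean and standard deviation. A positive z-score
#' means the targets are preferentially upregulated (de-repressed) relative
#' to the rest of the transcriptome.
#'
#' @param fc fold-change table.
#' @param targets character vector of predicted target gene ids.
#' @param bg background statistics from [background_stats()].
#' @return list: `Sm`, `m`, `z`.
#' @export
family_zscore <- function(fc, targets, bg) {
  vals <- fc$log2fc[fc$expressed & fc$gene_id %in% targets]
  m <- length(vals)
  if (m < 1) stop("no expressed genes in the target set")
  Sm <- mean(vals)
  list(Sm = Sm, m = m, z = (Sm - bg$mu) * sqrt(m) / bg$sd)
}

#' Cumulative-distribution comparison of targets versus background
#'
#' Empirical CDFs of log2-fold changes for the target and background sets,
#' with the two-sample Kolmogorov-Smirnov statistic `D = sup |F_t - F_b|`
#' and its one-sided components. `shift_direction` is `+1` when the targets'
#' CDF is right-shifted relative to background (de-repression), `-1` when
#' left-shifted. The p-value comes from the two-sided two-sample KS test,
#' exact when the smaller set has at most 25 members, asymptotic otherwise.
#'
#' @param fc fold-change table.
#' @param targets,background character vectors of gene ids; only expressed
#'   genes are used, and each set needs at least 2.
#' @param exact logical or `NULL` (default: exact when `min(m, n) <= 25`).
#' @return list: `ks_D`, `ks_p`, `D_plus`, `D_minus`, `shift_direction`,
#'   and `curves` (list of two data.frames with columns `x`, `F`).
#' @export
cdf_compare <- function(fc, targets, background, exact = NULL) {
  use <- fc[fc$expressed, , drop = FALSE]
  x <- use$log2fc[use$gene_id %in% targets]
  y <- use$log2fc[use$gene_id %in% background]
  if (length(x) < 2) stop("target set has fewer than 2 expressed genes")
  if (length(y) < 2) stop("background set has fewer than 2 expressed genes")
  grid <- sort(unique(c(x, y)))
  Fx <- stats::ecdf(x)(grid)
  Fy <- stats::ecdf(y)(grid)
  d_plus <- max(Fy - Fx)   # targets right-shifted: F_targets below F_background
  d_minus <- max(Fx - Fy)
  if (is.null(exact)) exact <- min(length(x), length(y)) <= 25
  p <- suppressWarnings(
    stats::ks.test(x, y, alternative = "two.sided", exact = exact)$p.value
  )
  list(
    ks_D = max(d_plus, d_minus),
    ks_p = p,
    D_plus = d_plus,
    D_minus = d_minus,
    shift_direction = ifelse(d_plus >= d_minus, 1L, -1L),
    curves = list(
      targets = data.frame(x = grid, F = Fx),
      background = data.frame(x = grid, F = Fy)
    )
  )
}

#' Per-family target de-repression scores
#'
#' For every seed family: intersects its predicted targets with the
#' expressed gene universe, computes the background (by default the
#' expressed transcriptome minus that family's own targets — targets of
#' other families stay in), the z-score of the target-set mean log2-fold
#' change, and the target-versus-background KS comparison. Families with
#' fewer than `m_min` expressed targets are reported with status
#' `too_few_targets` rather than raising an error. Benjamini-Hochberg
#' adjusted KS p-values across scored families are reported alongside the
#' raw ones as a convenience addition.
#'
#' @param fc fold-change table.
#' @param target_map data.frame with `family_id`, `gene_id`.
#' @param abundance optional family-abundance table with `family_id` and
#'   `abundance_log10` (see [aggregate_families()]); families with undefined
#'   abundance get status `abundance_undefined`.
#' @param m_min minimum expressed-target count to score a family
#'   (default 10, guarding the normal approximation behind the z-score).
#' @param per_family_background if `TRUE` (default) each family's own
#'   targets are excluded from its background; if `FALSE` the background is
#'   all expressed genes.
#' @param with_ks compute the per-family KS comparison (default `TRUE`).
#' @return data.frame with one row per family, columns `family_id`, `m`,
#'   `Sm`, `mu`, `sd`, `z`, `abundance_log10`, `ks_D`, `ks_p`, `ks_p_bh`,
#'   `status`.
#' @export
derepression_scores <- function(fc, target_map, abundance = NULL, m_min = 10,
                                per_family_background = TRUE, with_ks = TRUE) {
  fam_ids <- sort(unique(target_map$family_id))
  expressed <- fc$gene_id[fc$expressed]
  tgt_by_fam <- split(target_map$gene_id, target_map$family_id)
  rows <- lapply(fam_ids, function(f) {
    targets <- unique(tgt_by_fam[[f]])
    m <- sum(targets %in% expressed)
    out <- data.frame(
      family_id = f, m = m, Sm = NA_real_, mu = NA_real_, sd = NA_real_,
      z = NA_real_, abundance_log10 = NA_real_, ks_D = NA_real_,
      ks_p = NA_real_, ks_p_bh = NA_real_, status = "ok",
      stringsAsFactors = FALSE
    )
    if (m < m_min) {
      out$status <- "too_few_targets"
      return(out)
    }
    excl <- if (per_family_background) targets else character(0)
    bg <- background_stats(fc, exclude = excl)
    fz <- family_zscore(fc, targets, bg)
    out$Sm <- fz$Sm; out$mu <- bg$mu; out$sd <- bg$sd; out$z <- fz$z
    if (with_ks) {
      ks <- cdf_compare(fc, targets, setdiff(expressed, targets))
      out$ks_D <- ks$ks_D; out$ks_p <- ks$ks_p
    }
    out
  })
  res <- do.call(rbind, rows)
  if (!is.null(abundance)) {
    res$abundance_log10 <- abundance$abundance_log10[
      match(res$family_id, abundance$family_id)]
    undef <- is.na(res$abundance_log10) & res$status == "ok"
    res$status[undef] <- "abundance_undefined"
  }
  ok <- res$status == "ok" & !is.na(res$ks_p)
  res$ks_p_bh[ok] <- stats::p.adjust(res$ks_p[ok], method = "BH")
  rownames(res) <- NULL
  res
}

#' Assemble the bubble-plot table
#'
#' One row per scored family with defined abundance, sorted by abundance
#' descending: z-score on y, log10 family abundance on x, bubble area
#' proportional to the number of expressed predicted targets.
#'
#' @param records result of [derepression_scores()].
#' @return data.frame: `family_id`, `z`, `abundance_log10`, `m`.
#' @export
assemble_bubble_table <- function(records) {
  keep <- records$status == "ok" & !is.na(records$abundance_log10) &
    !is.na(records$z)
  tab <- records[keep, c("family_id", "z", "abundance_log10", "m"),
                 drop = FALSE]
  tab <- tab[order(-tab$abundance_log10), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
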