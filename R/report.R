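#' Render figure-style outputs from a pipeline output directory
#'
#' Builds the standard summary figures from the analysis tables written by
#' [run_pipeline()]: the bubble plot (z-score vs. log10 family abundance,
#' bubble area proportional to target-set size), overlay CDF panels of
#' targets vs. background for the most abundant families, and the
#' per-miRNA abundance scatter between conditions. Figures are written as
#' PDF next to the tables together with a markdown summary; sections whose
#' stage output is missing are marked unavailable rather than failing.
#'
#' @param outdir a directory produced by [run_pipeline()].
#' @param file name of the PDF to write (default `"report.pdf"`).
#' @return invisibly, a named list of ggplot objects (`bubble`, `cdf`,
#'   `scatter`; absent sections are `NULL`).
#' @export
render_report <- function(outdir, file = "report.pdf") {
  plots <- list(bubble = NULL, cdf = NULL, scatter = NULL)
  notes <- character(0)

  bubble_path <- file.path(outdir, "bubble.tsv")
  if (file.exists(bubble_path)) {
    bubble <- read_tsv(bubble_path)
    if (nrow(bubble) > 0) {
      plots$bubble <- ggplot2::ggplot(
        bubble,
        ggplot2::aes(x = .data$abundance_log10, y = .data$z,
                     size = .data$m)
      ) +
        ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                            colour = "grey50") +
        ggplot2::geom_point(alpha = 0.6, colour = "#2166ac") +
        ggplot2::scale_size_area(max_size = 10) +
        ggplot2::labs(
          x = "family abundance (log10 summed reads)",
          y = "target de-repression z-score",
          size = "predicted targets",
          title = "Target de-repression vs. miRNA family abundance"
        ) +
        ggplot2::theme_bw()
    } else {
      notes <- c(notes, "bubble: no families reported")
    }
  } else {
    notes <- c(notes, "bubble: stage output unavailable")
  }

  cdf_paths <- list.files(outdir, pattern = "^cdf_.*\\.tsv$",
                          full.names = TRUE)
  if (length(cdf_paths) > 0) {
    curves <- do.call(rbind, lapply(cdf_paths, function(p) {
      d <- read_tsv(p)
      d$family_id <- sub("^cdf_(.*)\\.tsv$", "\\1", basename(p))
      d
    }))
    plots$cdf <- ggplot2::ggplot(
      curves, ggplot2::aes(x = .data$x, y = .data$F, colour = .data$set)
    ) +
      ggplot2::geom_step() +
      ggplot2::facet_wrap(~family_id) +
      ggplot2::labs(x = "log2 fold change", y = "cumulative fraction",
                    colour = NULL,
                    title = "Predicted targets vs. background") +
      ggplot2::theme_bw()
  } else {
    notes <- c(notes, "cdf: stage output unavailable")
  }

  cmp_path <- file.path(outdir, "mirna_comparison.tsv")
  if (file.exists(cmp_path)) {
    cmp <- read_tsv(cmp_path)  # table from compare_mirna_abundance()
    plots$scatter <- ggplot2::ggplot(
      cmp, ggplot2::aes(x = log10(.data$cpm_a + 0.5),
                        y = log10(.data$cpm_b + 0.5))
    ) +
      ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
      ggplot2::geom_point(alpha = 0.5) +
      ggplot2::labs(x = "log10 CPM, condition A",
                    y = "log10 CPM, condition B",
                    title = "Mature miRNA abundance between conditions") +
      ggplot2::theme_bw()
  } else {
    notes <- c(notes, "scatter: no miRNA comparison table present")
  }

  pdf_path <- file.path(outdir, file)
  grDevices::pdf(pdf_path, width = 7, height = 5)
  for (pl in Filter(Negate(is.null), plots)) print(pl)
  if (all(vapply(plots, is.null, logical(1)))) {
    graphics::plot.new()
    graphics::text(0.5, 0.5, "no families reported")
  }
  grDevices::dev.off()

  md <- c(
    "# De-repression analysis report", "",
    sprintf("- bubble plot: %s",
            if (is.null(plots$bubble)) "unavailable (no families reported)"
            else "ok"),
    sprintf("- CDF panels: %s",
            if (is.null(plots$cdf)) "unavailable" else "ok"),
    sprintf("- abundance scatter: %s",
            if (is.null(plots$scatter)) "unavailable" else "ok"),
    if (length(notes)) c("", "## Notes", paste("-", notes)) else character(0)
  )
  writeLines(md, file.path(outdir, "report.md"))
  invisible(plots)
}
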