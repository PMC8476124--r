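#' Simulation configuration
#'
#' Builds and validates the configuration object consumed by all generators
#' in the synthetic-data module. The defaults emulate a two-condition bulk
#' RNA-seq experiment (miRISC inhibition vs. control, three replicates each)
#' together with a matched small-RNA library in miRNA-precursor space.
#'
#' Family abundances span three decades: the expected total read count of
#' family *f* is `reads_per_mirna_scale * 10^u_f` with `u_f ~ Uniform(0, 3)`,
#' mirroring the dynamic range typical of small-RNA-seq seed families. The
#' per-family de-repression effect is linear in log10 abundance,
#' `delta_f = max_effect_log2 * a_f / max(a)`, so the most abundant family
#' de-represses its targets by `max_effect_log2` log2 units.
#'
#' @param n_genes number of genes in the expression universe.
#' @param n_families number of miRNA seed families.
#' @param targets_per_family predicted targets drawn for each family.
#' @param n_samples_per_condition replicates per condition.
#' @param baseline_mean_log10_range length-2 numeric; baseline gene means are
#'   `10^Uniform(lo, hi)` normalized counts.
#' @param nb_dispersion shared negative-binomial dispersion (`1/size`); the
#'   count variance is `mu + dispersion * mu^2`.
#' @param max_effect_log2 de-repression (log2 units) of the most abundant
#'   family's targets in the treatment condition; 0 gives a null dataset.
#' @param reads_per_mirna_scale multiplier on expected family read totals.
#' @param end_jitter_probs named numeric vector of probabilities over integer
#'   end offsets (names, in nt); applied independently to the 5' and 3' read
#'   ends. Must sum to 1.
#' @param target_overlap if `TRUE` (default) each family samples its targets
#'   independently so a gene may be targeted by several families; if `FALSE`
#'   target sets form a disjoint partition of the gene universe.
#' @param mature_len_range,precursor_len_range length-2 integer ranges (nt)
#'   for mature and precursor lengths.
#' @param rng_seed integer seed; every generator derives its stream from it.
#'
#' @return a validated list of class `"sim_config"`.
#' @export
#' @examples
#' cfg <- sim_config(n_families = 3, rng_seed = 0)
#' cfg$n_families
sim_config <- function(n_genes = 8000,
                       n_families = 20,
                       targets_per_family = 100,
                       n_samples_per_condition = 3,
                       baseline_mean_log10_range = c(1, 3),
                       nb_dispersion = 0.05,
                       max_effect_log2 = 0.5,
                       reads_per_mirna_scale = 10,
                       end_jitter_probs = c(
                         "-6" = 0.02, "-5" = 0.02, "-2" = 0.10, "-1" = 0.13,
                         "0" = 0.46, "1" = 0.13, "2" = 0.10, "5" = 0.02,
                         "6" = 0.02
                       ),
                       target_overlap = TRUE,
                       mature_len_range = c(20L, 23L),
                       precursor_len_range = c(70L, 100L),
                       rng_seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_families = as.integer(n_families),
    targets_per_family = as.integer(targets_per_family),
    n_samples_per_condition = as.integer(n_samples_per_condition),
    baseline_mean_log10_range = as.numeric(baseline_mean_log10_range),
    nb_dispersion = as.numeric(nb_dispersion),
    max_effect_log2 = as.numeric(max_effect_log2),
    reads_per_mirna_scale = as.numeric(reads_per_mirna_scale),
    end_jitter_probs = end_jitter_probs,
    target_overlap = isTRUE(target_overlap),
    mature_len_range = as.integer(mature_len_range),
    precursor_len_range = as.integer(precursor_len_range),
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  counts <- c(
    n_genes = cfg$n_genes, n_families = cfg$n_families,
    targets_per_family = cfg$targets_per_family,
    n_samples_per_condition = cfg$n_samples_per_condition
  )
  if (any(is.na(counts)) || any(counts < 1L)) {
    stop("all count parameters must be >= 1; offending: ",
         paste(names(counts)[is.na(counts) | counts < 1L], collapse = ", "))
  }
  if (!is.finite(cfg$nb_dispersion) || cfg$nb_dispersion <= 0) {
    stop("nb_dispersion must be > 0")
  }
  if (!is.finite(cfg$reads_per_mirna_scale) || cfg$reads_per_mirna_scale <= 0) {
    stop("reads_per_mirna_scale must be > 0")
  }
  if (length(cfg$baseline_mean_log10_range) != 2L ||
      diff(cfg$baseline_mean_log10_range) < 0) {
    stop("baseline_mean_log10_range must be an increasing length-2 range")
  }
  jp <- cfg$end_jitter_probs
  if (is.null(names(jp)) || anyNA(suppressWarnings(as.integer(names(jp))))) {
    stop("end_jitter_probs must be named by integer offsets")
  }
  if (any(jp < 0) || abs(sum(jp) - 1) > 1e-8) {
    stop("end_jitter_probs must be non-negative and sum to 1")
  }
  if (length(cfg$mature_len_range) != 2L || length(cfg$precursor_len_range) != 2L ||
      diff(cfg$mature_len_range) < 0 || diff(cfg$precursor_len_range) < 0) {
    stop("length ranges must be increasing length-2 integer ranges")
  }
  margin <- max(abs(jitter_support(cfg)), 4L)
  # two mature arms + jitter margins + a 4 nt loop must fit the shortest precursor
  need <- 2L * max(cfg$mature_len_range) + 2L * margin + 4L
  if (min(cfg$precursor_len_range) < need) {
    stop("mature length exceeds precursor capacity: precursors of ",
         min(cfg$precursor_len_range), " nt cannot contain two ",
         max(cfg$mature_len_range), " nt matures with ", margin,
         " nt end margins (need >= ", need, " nt)")
  }
  if (!is.finite(cfg$rng_seed)) stop("rng_seed must be a finite integer")
  cfg
}

#' @keywords internal
jitter_support <- function(cfg) as.integer(names(cfg$end_jitter_probs))

# Stage-specific seeds derived from the one user-facing seed, so each
# generator is individually reproducible and jointly non-overlapping.
stage_seed <- function(cfg, stage) {
  offs <- c(annotation = 0L, targets = 1L, ground_truth = 2L,
            reads = 3L, counts = 4L)
  (cfg$rng_seed %% 200000000L) * 10L + offs[[stage]]
}
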