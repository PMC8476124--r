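#' Simulate a miRNA precursor annotation with seed families
#'
#' Generates random precursor hairpin sequences, each carrying one or two
#' mature miRNA arms (5p/3p), and groups matures into seed families. Members
#' of a family share a 7-nt seed (positions 2-8 of the mature), the defining
#' property of a TargetScan-style seed family. Matures are placed with an end
#' margin at least as large as the widest configured end jitter so simulated
#' reads never fall off the precursor.
#'
#' @param config a [sim_config()] object.
#' @return list with components:
#'   \describe{
#'     \item{precursors}{named character vector of precursor sequences.}
#'     \item{matures}{data.frame: `mature_id`, `precursor_id`, `start`,
#'       `end` (1-based inclusive, precursor coordinates), `family_id`.}
#'     \item{families}{data.frame: `family_id`, `seed`, `member_mirna`
#'       (one row per member).}
#'   }
#' @export
sim_annotation <- function(config) {
  config <- validate_sim_config(config)
  set.seed(stage_seed(config, "annotation"))
  nf <- config$n_families
  margin <- max(abs(jitter_support(config)), 4L)
  bases <- c("A", "C", "G", "T")

  family_id <- sprintf("fam-%03d", seq_len(nf))
  seeds <- random_kmers(nf, 7L, bases)
  n_members <- sample(1:3, nf, replace = TRUE, prob = c(0.45, 0.40, 0.15))

  fam_of_mature <- rep(family_id, n_members)
  n_mat <- length(fam_of_mature)

  # pair consecutive matures onto a shared precursor (5p + 3p arms) ~35% of
  # the time; otherwise one mature per precursor
  arm <- character(n_mat)
  prec_index <- integer(n_mat)
  pi <- 0L
  i <- 1L
  while (i <= n_mat) {
    pi <- pi + 1L
    if (i < n_mat && stats::runif(1) < 0.35) {
      prec_index[c(i, i + 1L)] <- pi
      arm[c(i, i + 1L)] <- c("5p", "3p")
      i <- i + 2L
    } else {
      prec_index[i] <- pi
      arm[i] <- "5p"
      i <- i + 1L
    }
  }
  n_prec <- pi
  precursor_id <- sprintf("sim-mir-%04d", seq_len(n_prec))

  prec_len <- sample(seq(config$precursor_len_range[1],
                         config$precursor_len_range[2]), n_prec, replace = TRUE)
  prec_seq <- vapply(prec_len, function(L) {
    paste(sample(bases, L, replace = TRUE), collapse = "")
  }, character(1))
  names(prec_seq) <- precursor_id

  mat_len <- sample(seq(config$mature_len_range[1], config$mature_len_range[2]),
                    n_mat, replace = TRUE)
  start <- integer(n_mat)
  end <- integer(n_mat)
  for (j in seq_len(n_mat)) {
    L <- prec_len[prec_index[j]]
    if (arm[j] == "5p") {
      start[j] <- margin + sample(1:3, 1)
    } else {
      end3 <- L - margin - sample(0:2, 1)
      start[j] <- end3 - mat_len[j] + 1L
    }
    end[j] <- start[j] + mat_len[j] - 1L
    if (start[j] < 1L || end[j] > L) {
      stop("mature placement exceeds precursor bounds (internal error)")
    }
    # write the family seed into positions 2-8 of the mature
    seq_chars <- strsplit(prec_seq[[prec_index[j]]], "")[[1]]
    seed_chars <- strsplit(seeds[match(fam_of_mature[j], family_id)], "")[[1]]
    seq_chars[(start[j] + 1L):(start[j] + 7L)] <- seed_chars
    prec_seq[prec_index[j]] <- paste(seq_chars, collapse = "")
  }

  mature_id <- paste0(precursor_id[prec_index], "-", arm)
  stopifnot(!anyDuplicated(mature_id))
  matures <- data.frame(
    mature_id = mature_id,
    precursor_id = precursor_id[prec_index],
    start = start, end = end,
    family_id = fam_of_mature,
    stringsAsFactors = FALSE
  )
  families <- data.frame(
    family_id = fam_of_mature,
    seed = seeds[match(fam_of_mature, family_id)],
    member_mirna = mature_id,
    stringsAsFactors = FALSE
  )
  families <- families[order(families$family_id, families$member_mirna), ,
                       drop = FALSE]
  rownames(families) <- NULL
  list(precursors = prec_seq, matures = matures, families = families)
}

random_kmers <- function(n, k, bases) {
  out <- vapply(seq_len(n), function(i) {
    paste(sample(bases, k, replace = TRUE), collapse = "")
  }, character(1))
  while (anyDuplicated(out)) {
    dup <- which(duplicated(out))
    out[dup] <- vapply(dup, function(i) {
      paste(sample(bases, k, replace = TRUE), collapse = "")
    }, character(1))
  }
  out
}

#' Simulate a TargetScan-style predicted-target map
#'
#' Assigns each family a set of predicted target genes drawn from the gene
#' universe `gene00001..gene<n_genes>`. With `target_overlap = TRUE` families
#' sample independently (a gene may be a predicted target of several
#' families, as in real TargetScan tables); with `FALSE` the sets are a
#' disjoint partition, leaving `n_genes - n_families * targets_per_family`
#' genes untargeted.
#'
#' @param config a [sim_config()] object.
#' @param families data.frame from [sim_annotation()] (used for family ids).
#' @return data.frame with columns `family_id`, `gene_id`.
#' @export
sim_target_map <- function(config, families) {
  config <- validate_sim_config(config)
  set.seed(stage_seed(config, "targets"))
  fam_ids <- sort(unique(families$family_id))
  genes <- gene_universe(config)
  k <- config$targets_per_family
  if (config$target_overlap) {
    tgt <- lapply(fam_ids, function(f) sample(genes, k))
  } else {
    need <- length(fam_ids) * k
    if (need > length(genes)) {
      stop("disjoint target sets need ", need, " genes but universe has ",
           length(genes))
    }
    pool <- sample(genes, need)
    tgt <- split(pool, rep(fam_ids, each = k))[fam_ids]
  }
  data.frame(
    family_id = rep(fam_ids, each = k),
    gene_id = unlist(tgt, use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

gene_universe <- function(config) sprintf("gene%05d", seq_len(config$n_genes))
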