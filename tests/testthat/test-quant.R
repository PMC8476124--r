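test_that("GFF3 annotation round-trips through export and import", {
  cfg <- quick_config(rng_seed = 21)
  ann <- sim_annotation(cfg)
  path <- tempfile(fileext = ".gff3")
  derepressr:::export_mature_gff3(ann, path)
  back <- read_mature_gff3(path, families = ann$families)
  m <- ann$matures[order(ann$matures$mature_id), ]
  b <- back[order(back$mature_id), ]
  rownames(m) <- rownames(b) <- NULL
  expect_identical(b[, c("mature_id", "precursor_id", "start", "end",
                         "family_id")],
                   m[, c("mature_id", "precursor_id", "start", "end",
                         "family_id")])
})

test_that("malformed annotations are rejected with named offenders", {
  path <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "pre1\t.\tmiRNA_primary_transcript\t1\t80\t.\t+\t.\tID=pre1",
    "pre1\t.\tmiRNA\t10\t31\t.\t+\t.\tID=mat-lost"
  ), path)
  expect_error(read_mature_gff3(path), "Derives_from.*mat-lost")

  writeLines(c(
    "##gff-version 3",
    "pre1\t.\tmiRNA\t10\t31\t.\t+\t.\tID=mat-a;Derives_from=pre1",
    "pre1\t.\tmiRNA\t12\t33\t.\t+\t.\tID=mat-a;Derives_from=pre1"
  ), path)
  expect_error(read_mature_gff3(path), "duplicate mature_id.*mat-a")

  writeLines("##gff-version 3", path)
  expect_identical(nrow(read_mature_gff3(path)), 0L)
})

test_that("end-window rule is a both-end, bounds-inclusive conjunction", {
  mature <- list(precursor_id = "p", start = 10L, end = 31L)
  aln <- function(s, e, strand = "+", primary = TRUE, prec = "p") {
    list(precursor_id = prec, aln_start = s, aln_end = e, strand = strand,
         is_primary = primary)
  }
  expect_true(match_read(aln(10, 31), mature))
  expect_true(match_read(aln(6, 35), mature))    # offsets -4/+4, inclusive
  expect_false(match_read(aln(15, 31), mature))  # 5' offset 5 > 4
  expect_false(match_read(aln(10, 36), mature))  # 3' offset 5 > 4
  expect_false(match_read(aln(5, 31), mature))
  expect_false(match_read(aln(10, 31, strand = "-"), mature))
  expect_false(match_read(aln(10, 31, primary = FALSE), mature))
  expect_error(match_read(aln(10, 31, prec = "q"), mature),
               "different precursors")
})

test_that("optimized counting matches the brute-force matcher on seeded fixtures", {
  for (seed in 1:6) {
    cfg <- quick_config(rng_seed = seed)
    ann <- sim_annotation(cfg)
    tm <- sim_target_map(cfg, ann$families)
    gt <- sim_ground_truth(ann, tm, cfg)
    sr <- sim_small_rna(ann, gt, cfg)
    res <- count_mature(sr$reads, ann$matures)
    oracle <- brute_count(sr$reads, ann$matures)
    expect_identical(stats::setNames(res$counts$count, res$counts$mature_id),
                     oracle$counts)
    # conservation of primary plus-strand alignments
    expect_identical(
      res$qc$assigned + res$qc$unmatched + res$qc$unassigned_reference,
      res$qc$primary_plus
    )
  }
})

test_that("counting via a written SAM file equals in-memory counting", {
  cfg <- quick_config(rng_seed = 31)
  ann <- sim_annotation(cfg)
  tm <- sim_target_map(cfg, ann$families)
  gt <- sim_ground_truth(ann, tm, cfg)
  sr <- sim_small_rna(ann, gt, cfg)
  sam <- tempfile(fileext = ".sam")
  write_sam(sr$reads, ann$precursors, sam)
  aln <- read_precursor_alignments(sam)
  expect_identical(nrow(aln), nrow(sr$reads))
  res_file <- count_mature(aln, ann$matures)
  res_mem <- count_mature(sr$reads, ann$matures)
  expect_identical(res_file$counts, res_mem$counts)
  # no-jitter reads reproduce the generator's totals exactly
  cfg0 <- quick_config(rng_seed = 31, end_jitter_probs = c("0" = 1))
  sr0 <- sim_small_rna(ann, gt, cfg0)
  res0 <- count_mature(sr0$reads, ann$matures)
  expect_identical(
    res0$counts$count,
    gt$mature_reads$n_reads[match(res0$counts$mature_id,
                                  gt$mature_reads$mature_id)]
  )
})

test_that("counts are non-decreasing in the window width", {
  cfg <- quick_config(rng_seed = 41)
  ann <- sim_annotation(cfg)
  tm <- sim_target_map(cfg, ann$families)
  gt <- sim_ground_truth(ann, tm, cfg)
  sr <- sim_small_rna(ann, gt, cfg)
  totals <- vapply(0:6, function(w) {
    sum(count_mature(sr$reads, ann$matures, window = w)$counts$count)
  }, numeric(1))
  expect_true(all(diff(totals) >= 0))
})

test_that("alignments to unknown precursors are tallied, not dropped", {
  ann <- data.frame(mature_id = "m1", precursor_id = "p1",
                    start = 10L, end = 31L, stringsAsFactors = FALSE)
  aln <- data.frame(
    read_id = c("r1", "r2", "r3"),
    precursor_id = c("p1", "pX", "p1"),
    aln_start = c(10L, 10L, 50L), aln_end = c(31L, 31L, 70L),
    strand = "+", is_primary = TRUE, stringsAsFactors = FALSE
  )
  res <- count_mature(aln, ann)
  expect_identical(res$counts$count, 1L)
  expect_identical(res$qc$unassigned_reference, 1L)
  expect_identical(res$qc$unmatched, 1L)
  expect_error(count_mature(aln, ann[0, ]), "non-empty")
})

test_that("family aggregation sums members and flags zero-count families", {
  fam <- data.frame(
    family_id = c("fA", "fA", "fB", "fC"),
    member_mirna = c("m1", "m2", "m3", "m4"),
    stringsAsFactors = FALSE
  )
  cnt <- data.frame(mature_id = c("m1", "m2", "m3", "m4"),
                    count = c(100L, 50L, 1L, 0L), stringsAsFactors = FALSE)
  out <- aggregate_families(cnt, fam)
  expect_identical(out$family_count, c(150L, 1L, 0L))
  expect_equal(out$abundance_log10[out$family_id == "fA"], log10(150))
  expect_equal(out$abundance_log10[out$family_id == "fB"], 0)
  expect_true(is.na(out$abundance_log10[out$family_id == "fC"]))
  expect_identical(out$abundance_undefined, c(FALSE, FALSE, TRUE))
  cnt$mature_id[4] <- "m-orphan"
  expect_error(aggregate_families(cnt, fam), "no family.*m-orphan")
})

test_that("miRNA abundance comparison is normalization-invariant", {
  set.seed(1)
  a <- stats::setNames(rpois(50, 200), sprintf("m%02d", 1:50))
  expect_error(compare_mirna_abundance(a, a * 0L), "zero-total")

  same <- compare_mirna_abundance(a, a)
  expect_true(all(same$table$log2_ratio == 0))
  expect_equal(same$spearman_rho, 1)

  doubled <- compare_mirna_abundance(a, a * 2L)
  expect_equal(doubled$table$cpm_a, doubled$table$cpm_b)
  expect_true(all(abs(doubled$table$log2_ratio) < 1e-12))

  b <- stats::setNames(rpois(50, 200), names(a))
  res <- compare_mirna_abundance(a, b)
  # independent rank-correlation computation
  oracle <- stats::cor(rank(a / sum(a)), rank(b / sum(b)))
  expect_equal(unname(res$spearman_rho), unname(oracle))
})
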