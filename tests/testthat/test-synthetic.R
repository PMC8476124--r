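test_that("config validation rejects degenerate parameter settings", {
  expect_error(sim_config(n_genes = 0), "count parameters")
  expect_error(sim_config(nb_dispersion = 0), "nb_dispersion")
  expect_error(sim_config(end_jitter_probs = c("0" = 0.5)), "sum to 1")
  expect_error(sim_config(end_jitter_probs = c(a = 1)), "integer offsets")
  expect_error(
    sim_config(mature_len_range = c(40L, 45L),
               precursor_len_range = c(70L, 80L)),
    "mature length exceeds precursor capacity"
  )
})

test_that("annotation generator yields contained matures and a family partition", {
  cfg <- sim_config(n_families = 50, rng_seed = 1)
  ann <- sim_annotation(cfg)
  mat <- ann$matures
  plen <- nchar(ann$precursors)[mat$precursor_id]
  expect_true(all(mat$start >= 1 & mat$end <= plen & mat$start <= mat$end))
  expect_false(anyDuplicated(mat$mature_id) > 0)
  # partition: each mature appears exactly once in the family table, with one family
  expect_setequal(ann$families$member_mirna, mat$mature_id)
  expect_false(anyDuplicated(ann$families$member_mirna) > 0)
  expect_length(unique(ann$families$family_id), 50)
  expect_true(all(table(mat$precursor_id) <= 2))
  expect_true(all(nchar(ann$families$seed) == 7))
  # members of a family share the seed at mature positions 2-8
  seq_at <- substring(ann$precursors[mat$precursor_id],
                      mat$start + 1L, mat$start + 7L)
  expect_identical(unname(seq_at),
                   ann$families$seed[match(mat$mature_id,
                                           ann$families$member_mirna)])
})

test_that("identical config and seed give byte-identical outputs", {
  cfg <- quick_config(rng_seed = 3)
  d1 <- sim_dataset(cfg)
  d2 <- sim_dataset(cfg)
  expect_identical(d1$annotation, d2$annotation)
  expect_identical(d1$small_rna, d2$small_rna)
  expect_identical(d1$counts, d2$counts)
  o1 <- tempfile(); o2 <- tempfile()
  p1 <- write_sim_dataset(d1, o1)
  p2 <- write_sim_dataset(d2, o2)
  expect_identical(unname(tools::md5sum(unname(p1))),
                   unname(tools::md5sum(unname(p2))))
})

test_that("end jitter controls ground-truth in-window read counts", {
  base <- quick_config(rng_seed = 5)  # default jitter: 6 nt placement margin
  ann <- sim_annotation(base)
  tm <- sim_target_map(base, ann$families)
  gt <- sim_ground_truth(ann, tm, base)
  cfg0 <- quick_config(end_jitter_probs = c("0" = 1), rng_seed = 5)
  sr <- sim_small_rna(ann, gt, cfg0)
  # no jitter: every simulated read is in-window
  expect_identical(
    sr$truth_counts$count,
    gt$mature_reads$n_reads[match(sr$truth_counts$mature_id,
                                  gt$mature_reads$mature_id)]
  )

  cfg5 <- quick_config(end_jitter_probs = c("5" = 1), rng_seed = 5)
  sr5 <- sim_small_rna(ann, gt, cfg5)
  expect_true(all(sr5$truth_counts$count == 0L))
  expect_gt(nrow(sr5$reads), 0)
})

test_that("de-repression effect is monotone in realized family abundance", {
  cfg <- sim_config(n_families = 40, max_effect_log2 = 0.5, rng_seed = 11)
  ann <- sim_annotation(cfg)
  tm <- sim_target_map(cfg, ann$families)
  gt <- sim_ground_truth(ann, tm, cfg)
  fam <- gt$families[order(gt$families$abundance_log10), ]
  expect_true(all(diff(fam$delta) >= 0))
  expect_equal(max(fam$delta), 0.5)
  expect_equal(fam$delta,
               0.5 * fam$abundance_log10 / max(fam$abundance_log10))
  # realized totals match the mature-level reads
  agg <- tapply(gt$mature_reads$n_reads, gt$mature_reads$family_id, sum)
  expect_identical(as.integer(agg[gt$families$family_id]),
                   gt$families$total_reads)
})

test_that("null simulation is exchangeable between conditions", {
  cfg <- sim_config(n_genes = 3000, max_effect_log2 = 0, rng_seed = 2)
  d <- sim_dataset(cfg, reads = FALSE)
  ctl <- d$conditions$sample[d$conditions$condition == "control"]
  trt <- d$conditions$sample[d$conditions$condition == "treatment"]
  m_ctl <- rowMeans(d$counts[, ctl])
  m_trt <- rowMeans(d$counts[, trt])
  lfc <- log2((m_trt + 0.5) / (m_ctl + 0.5))
  expect_lt(abs(mean(lfc)), 0.02)
  # condition-level totals agree at Monte-Carlo tolerance
  expect_lt(abs(log2(sum(m_trt) / sum(m_ctl))), 0.05)
})

test_that("targeted genes are de-repressed by 2^delta in expectation", {
  cfg <- sim_config(n_genes = 1500, n_families = 8, max_effect_log2 = 1,
                    n_samples_per_condition = 40, nb_dispersion = 0.02,
                    rng_seed = 9)
  d <- sim_dataset(cfg, reads = FALSE)
  top <- d$ground_truth$families$family_id[
    which.max(d$ground_truth$families$abundance_log10)]
  expect_equal(max(d$ground_truth$families$delta), 1)
  tg <- d$target_map$gene_id[d$target_map$family_id == top]
  delta_g <- d$ground_truth$gene_effects$delta[
    match(tg, d$ground_truth$gene_effects$gene_id)]
  ctl <- d$conditions$sample[d$conditions$condition == "control"]
  trt <- d$conditions$sample[d$conditions$condition == "treatment"]
  ratio <- rowMeans(d$counts[tg, trt]) / rowMeans(d$counts[tg, ctl])
  # mean observed log2 ratio across targets matches the assigned effects
  expect_equal(mean(log2(ratio)), mean(delta_g), tolerance = 0.05)
})
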