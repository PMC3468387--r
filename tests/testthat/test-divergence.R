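# Hand-built column table: `n` match sites plus specified special columns.
div_cols <- function(n_match = 1000, extras = NULL, bq = 40L, len = 50L) {
  per_read <- len
  n_reads <- ceiling(n_match / per_read)
  cols <- dplyr::bind_rows(lapply(seq_len(n_reads), function(i) {
    tibble::tibble(read_id = paste0("d", i), read_pos = seq_len(per_read),
                   ref_pos = seq_len(per_read), ref_base = "A",
                   read_base = "A", event = "match", base_qual = bq,
                   read_len = len)
  }))[seq_len(n_match), ]
  dplyr::bind_rows(cols, extras)
}

mk_col <- function(read_id, pos, ref, read, event, bq = 40L, len = 50L) {
  tibble::tibble(read_id = read_id, read_pos = as.integer(pos),
                 ref_pos = as.integer(pos), ref_base = ref, read_base = read,
                 event = event, base_qual = bq, read_len = len)
}

test_that("the divergence statistic follows its defining formula", {
  # 1000 sites: 2 transversions, 1 inserted base, 1 A->G among them
  extras <- dplyr::bind_rows(
    mk_col("x1", 25, "A", "T", "mismatch"),
    mk_col("x2", 25, "C", "G", "mismatch"),
    mk_col("x3", 25, NA, "G", "insertion"),
    mk_col("x4", 25, "A", "G", "mismatch")
  )
  cols <- div_cols(997, extras)  # 997 matches + 3 aligned mismatch columns
  est <- estimate_divergence(cols, bq_threshold = 30)
  expect_equal(est$n_sites, 1000)
  expect_equal(est$n_transversions, 2)
  expect_equal(est$n_indel_bases, 1)
  expect_equal(est$n_AT_to_GC, 1)
  expect_equal(est$divergence, (2 + 1 + 2 * 1) / 1000)

  # identical sequences -> divergence 0
  expect_equal(estimate_divergence(div_cols(500), 30)$divergence, 0)

  # GC->AT transitions move the damage proxy, not the divergence
  dmg <- div_cols(998, dplyr::bind_rows(mk_col("y", 25, "C", "T", "mismatch"),
                                        mk_col("y2", 25, "G", "A", "mismatch")))
  est_dmg <- estimate_divergence(dmg, 30)
  expect_equal(est_dmg$divergence, 0)
  expect_equal(est_dmg$gc_to_at_rate, 2 / 1000)
})

test_that("end masking excludes terminal columns from the estimate", {
  # mismatches only at read positions 1-4 of 50-nt reads
  extras <- dplyr::bind_rows(lapply(1:4, function(p) {
    mk_col(paste0("m", p), p, "C", "T", "mismatch")
  }))
  cols <- div_cols(500, extras)
  masked <- estimate_divergence(cols, 30, end_mask = 5)
  clean <- estimate_divergence(div_cols(500), 30, end_mask = 5)
  expect_equal(masked$gc_to_at_rate, clean$gc_to_at_rate)
  expect_equal(masked$divergence, clean$divergence)
  unmasked <- estimate_divergence(cols, 30, end_mask = 0)
  expect_gt(unmasked$gc_to_at_rate, 0)
})

test_that("quality handling: quality-free input errors, empty grid cells go absent", {
  cols <- div_cols(100)
  cols$base_qual <- NA_integer_
  expect_error(estimate_divergence(cols, 30), "base qualities")

  curve <- divergence_curve(div_cols(100), bq_grid = c(10, 45))
  expect_true(is.na(curve$divergence[curve$bq_threshold == 45]))
  expect_equal(curve$n_sites[curve$bq_threshold == 45], 0)
})

test_that("divergence and site counts respond monotonically to the BQ threshold", {
  ref <- random_reference(40000, seed = 30)
  cfg <- sim_config(platform = "illumina", insertion_rate = 0,
                    deletion_rate = 0, substitution_rate = 0.002,
                    low_q_frac = 0.2, low_q_sub_rate = 0.1, seed = 31)
  sim <- simulate_reads(ref, cfg, 1500)
  cols <- reconstruct_columns(truth_hits(sim))
  curve <- divergence_curve(cols, bq_grid = c(0, 20, 39))
  expect_true(all(diff(curve$n_sites) <= 0))
  # low-quality bases carry extra substitution error: divergence drops as
  # the threshold excludes them
  expect_gt(curve$divergence[1], curve$divergence[3])
  gl <- glance(curve)
  expect_equal(gl$divergence_at_max_bq, curve$divergence[3])
})

test_that("divergence recovery: synthetic genome pairs at 1% with and without damage", {
  ref <- random_reference(50000, seed = 7)
  refB <- make_diverged_reference(ref, 0.01, seed = 31, name = "chr1")
  cfg <- sim_config(platform = "illumina", insertion_rate = 0,
                    deletion_rate = 0, substitution_rate = 0, seed = 22)
  sim <- simulate_reads(ref, cfg, 2500)
  cols <- reconstruct_columns(truth_hits(sim, reference = refB))
  est <- estimate_divergence(cols, 30, end_mask = 0)
  expect_binomial_ci_covers(est$divergence, 0.01, est$n_sites)

  # 5'-terminal damage with end_mask 5: estimate unchanged within CI
  cfg_d <- sim_config(platform = "illumina", insertion_rate = 0,
                      deletion_rate = 0, substitution_rate = 0,
                      damage = list(p0 = 0.3, decay = 0.5, max_overhang = 4),
                      seed = 23)
  sim_d <- simulate_reads(ref, cfg_d, 2500)
  cols_d <- reconstruct_columns(truth_hits(sim_d, reference = refB))
  est_d <- estimate_divergence(cols_d, 30, end_mask = 5)
  expect_binomial_ci_covers(est_d$divergence, 0.01, est_d$n_sites)
  # while the unmasked damage proxy clearly rises
  est_u <- estimate_divergence(cols_d, 30, end_mask = 0)
  expect_gt(est_u$gc_to_at_rate, 2 * est_d$gc_to_at_rate)
})

test_that("the mapping-count chi-square is the Pearson statistic without correction", {
  even <- mapping_count_test(matrix(c(50, 50, 50, 50), 2))
  expect_equal(unname(even$statistic), 0)
  expect_equal(even$p.value, 1)

  skew <- mapping_count_test(matrix(c(10, 20, 20, 10), 2))
  # hand evaluation of the Pearson formula: expected 15 in every cell
  expect_equal(unname(skew$statistic), 4 * 25 / 15, tolerance = 1e-12)
  expect_equal(unname(skew$statistic), 20 / 3, tolerance = 1e-12)

  dbl <- mapping_count_test(2 * matrix(c(10, 20, 20, 10), 2))
  expect_equal(unname(dbl$statistic), 2 * unname(skew$statistic))

  expect_error(mapping_count_test(matrix(c(0, 0, 5, 5), 2)), "margin")
})
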