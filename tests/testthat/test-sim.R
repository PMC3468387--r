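test_that("PWM construction normalizes context frequencies with pseudocounts", {
  # identical contexts concentrate mass on one base per column
  pwm <- build_pwm(rep("ACGTAACGTAC", 20))
  expect_equal(dim(pwm), c(11, 4))
  expect_true(all(abs(rowSums(pwm) - 1) < 1e-12))
  expect_equal(pwm[1, "A"], 1)
  expect_equal(pwm[4, "T"], 1)

  # uniform random contexts approach 0.25 per cell
  set.seed(2)
  ctx <- vapply(1:10000, function(i) {
    paste(sample(c("A", "C", "G", "T"), 11, TRUE), collapse = "")
  }, character(1))
  pwm_u <- build_pwm(ctx)
  expect_true(all(abs(pwm_u - 0.25) < 0.02))

  # empty input: pseudocount 1 gives the uniform PWM, none is an error
  expect_equal(unname(build_pwm(character(0), pseudocount = 1)),
               matrix(0.25, 11, 4))
  expect_error(build_pwm(character(0)), "zero pseudocount")
})

test_that("start-site sampling is deterministic, PWM-responsive and near-uniform when flat", {
  ref <- random_reference(20000, seed = 40)
  s1 <- sample_start_sites(ref, NULL, 2000, seed = 41)
  s2 <- sample_start_sites(ref, NULL, 2000, seed = 41)
  expect_identical(s1, s2)
  expect_true(all(s1$strand %in% c("forward", "reverse")))

  # flat PWM: positions uniform over the usable range (chi-square GOF)
  s3 <- sample_start_sites(ref, matrix(0.25, 11, 4), 20000, seed = 42)
  bins <- cut(s3$position, breaks = seq(0, 20000, by = 2000))
  gof <- chisq.test(table(bins))
  expect_gt(gof$p.value, 0.01)

  # degenerate PWM forcing T at the start position
  pwm_t <- matrix(0.25, 11, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  pwm_t[6, ] <- c(0, 0, 0, 1)
  s4 <- sample_start_sites(ref, pwm_t, 300, seed = 43)
  merged <- paste0(ref, paleomapr:::revcomp_chr(ref))
  base_at <- function(row) {
    mp <- if (row$strand == "forward") row$position else
      2L * nchar(ref) - row$position + 1L
    substring(merged, mp, mp)
  }
  starts <- vapply(seq_len(nrow(s4)), function(i) base_at(s4[i, ]),
                   character(1))
  expect_true(all(starts == "T"))

  expect_error(sample_start_sites(c(x = "ACGTACGT"), NULL, 5), "at least 11")
})

test_that("error-free simulation yields exact reference substrings with empty event lists", {
  ref <- random_reference(20000, seed = 5)
  cfg <- sim_config(insertion_rate = 0, deletion_rate = 0,
                    substitution_rate = 0, seed = 11)
  sim <- simulate_reads(ref, cfg, 150)
  expect_equal(nrow(sim$events), 0)
  expect_equal(nrow(sim$reads), 150)
  for (i in seq_len(50)) {
    tr <- sim$truth[i, ]
    sub <- unname(substr(ref, tr$start, tr$end))
    expected <- if (tr$strand == "forward") sub else
      paleomapr:::revcomp_chr(sub)
    expect_equal(sim$reads$bases[sim$reads$read_id == tr$read_id], expected)
  }
  # same seed -> identical output
  sim2 <- simulate_reads(ref, cfg, 150)
  expect_identical(sim$reads, sim2$reads)
  expect_identical(sim$truth, sim2$truth)
})

test_that("realized error rates match the configured probabilities within 3 SD", {
  ref <- random_reference(60000, seed = 17)
  cfg <- sim_config(insertion_rate = 0.015, deletion_rate = 0.03,
                    substitution_rate = 0.01, seed = 101)
  sim <- simulate_reads(ref, cfg, 20000)
  ins_rate <- sim$n_inserted / sim$n_emitted
  del_rate <- sim$n_deleted / sim$n_traversed
  sub_rate <- sim$n_substituted / (sim$n_emitted - sim$n_inserted)
  expect_lt(abs(ins_rate - 0.015), 3 * sqrt(0.015 * 0.985 / sim$n_emitted))
  expect_lt(abs(del_rate - 0.03), 3 * sqrt(0.03 * 0.97 / sim$n_traversed))
  expect_lt(abs(sub_rate - 0.01),
            3 * sqrt(0.01 * 0.99 / (sim$n_emitted - sim$n_inserted)))
  # deamination recovery at 5' position 1
  cfg_d <- sim_config(insertion_rate = 0, deletion_rate = 0,
                      substitution_rate = 0,
                      damage = list(p0 = 0.2, decay = 0.5, max_overhang = 2),
                      seed = 102)
  sim_d <- simulate_reads(ref, cfg_d, 10000)
  ev1 <- sim_d$events[sim_d$events$read_pos == 1 &
                        sim_d$events$type == "deamination", ]
  # denominator: reads whose template starts with C = damaged + undamaged-C
  first_ref <- ifelse(
    sim_d$truth$strand == "forward",
    substring(ref, sim_d$truth$start, sim_d$truth$start),
    paleomapr:::complement_chr(substring(ref, sim_d$truth$end,
                                         sim_d$truth$end)))
  n_c <- sum(first_ref == "C")
  expect_lt(abs(nrow(ev1) / n_c - 0.2), 3 * sqrt(0.2 * 0.8 / n_c))
})

test_that("random null reads follow the configured composition and length support", {
  ld <- tibble::tibble(length = 25:40, prob = rep(1 / 16, 16))
  comp <- c(A = 0.4, C = 0.1, G = 0.2, T = 0.3)
  reads <- simulate_random_reads(comp, ld, 20000, seed = 50)
  expect_true(all(nchar(reads$bases) > 24))
  obs <- table(factor(paleomapr:::explode_chars(reads$bases),
                      levels = c("A", "C", "G", "T")))
  gof <- chisq.test(obs, p = comp)
  expect_gt(gof$p.value, 0.001)
  # degenerate composition
  all_a <- simulate_random_reads(c(A = 1, C = 0, G = 0, T = 0), ld, 10,
                                 seed = 51)
  expect_true(all(grepl("^A+$", all_a$bases)))
  expect_error(simulate_random_reads(comp,
                                     tibble::tibble(length = 20, prob = 1), 5))
})

test_that("truth SAM fields are exact for event-free and event-carrying reads", {
  ref <- c(chr1 = strrep("ACGT", 50))
  sim <- list(
    reads = read_table(c("a", "b"), c("ACGTACGTAC", "ACGTACGTAC"), NA,
                       "helicos"),
    truth = tibble::tibble(read_id = c("a", "b"),
                           source_sequence = "chr1", strand = "forward",
                           start = c(1L, 21L), end = c(10L, 30L)),
    events = tibble::tibble(read_id = "b", read_pos = 3L,
                            type = "substitution", ref_base = "G",
                            read_base = "G")
  )
  class(sim) <- "sim_result"
  # event-free read: CIGAR "10M", MD "10", NM 0
  hits <- truth_hits(sim)
  expect_equal(hits$cigar[1], "10M")
  expect_equal(hits$md[1], "10")
  expect_equal(hits$nm[1], 0L)
  sim$events$read_base <- "A"
  sim$reads$bases[2] <- "ACATACGTAC"
  hits2 <- truth_hits(sim)
  expect_equal(hits2$nm[2], 1L)
  expect_equal(hits2$md[2], "2G7")  # MD encodes the reference base
})

test_that("poly-T start trimming emulation removes leading thymine runs", {
  ref <- c(chr1 = strrep("ACGT", 5000))
  cfg <- sim_config(insertion_rate = 0, deletion_rate = 0,
                    substitution_rate = 0, polyT_trim = TRUE, seed = 61)
  sim <- simulate_reads(ref, cfg, 300)
  expect_false(any(grepl("^TT", sim$reads$bases)))
  expect_true("polyT_trimmed" %in% names(sim$truth))
  # truth hits silently exclude coordinate-shifted trimmed reads
  hits <- truth_hits(sim)
  expect_false(any(hits$read_id %in%
                     sim$truth$read_id[sim$truth$polyT_trimmed]))
})
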