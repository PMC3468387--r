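# Columns for a batch of simple reads: all matches except as specified.
cols_fixture <- function(n_reads = 10, len = 10,
                         ref5 = rep("A", n_reads),
                         mismatch = NULL, insertion = NULL) {
  rows <- lapply(seq_len(n_reads), function(i) {
    ref <- c(ref5[i], rep("A", len - 1))
    tibble::tibble(
      read_id = paste0("r", i), read_pos = seq_len(len),
      ref_pos = 100L + seq_len(len), ref_base = ref, read_base = ref,
      event = "match", base_qual = 40L, read_len = len
    )
  })
  cols <- dplyr::bind_rows(rows)
  if (!is.null(mismatch)) {
    for (m in mismatch) {
      i <- cols$read_id == m$read & cols$read_pos == m$pos
      cols$read_base[i] <- m$to
      cols$event[i] <- "mismatch"
    }
  }
  if (!is.null(insertion)) {
    for (m in insertion) {
      i <- cols$read_id == m$read & cols$read_pos == m$pos
      cols$ref_base[i] <- NA
      cols$event[i] <- "insertion"
    }
  }
  cols
}

test_that("substitution rates divide mismatches by per-position reference-base counts", {
  # refs at position 1: 4 C, 6 A; one C read as T -> C>T rate 1/4
  cols <- cols_fixture(10, ref5 = c(rep("C", 4), rep("A", 6)),
                       mismatch = list(list(read = "r1", pos = 1, to = "T")))
  prof <- accumulate_profile(cols, 5)
  row <- prof[prof$end == "5p" & prof$position == 1 & prof$class == "C>T", ]
  expect_equal(row$count, 1L)
  expect_equal(row$denom, 4L)
  expect_equal(row$rate, 0.25)
  # nothing else is non-zero among substitutions at position 1
  other <- prof[prof$end == "5p" & prof$position == 1 &
                  prof$class %in% setdiff(paleomapr:::SUB_CLASSES, "C>T"), ]
  expect_true(all(other$count == 0))
})

test_that("indel rates are depth-normalized and a clean profile is all-zero", {
  cols <- cols_fixture(10, insertion = list(list(read = "r1", pos = 3),
                                            list(read = "r2", pos = 3)))
  prof <- accumulate_profile(cols, 5)
  ins <- prof[prof$end == "5p" & prof$position == 3 & prof$class == "insertion", ]
  expect_equal(ins$rate, 0.2)

  clean <- accumulate_profile(cols_fixture(5), 5)
  expect_true(all(clean$count[clean$class %in% paleomapr:::SUB_CLASSES] == 0))
  expect_true(all(clean$rate[!is.na(clean$rate)] %in% 0))
})

test_that("profiles conserve counts and are invariant to read order", {
  ref <- random_reference(20000, seed = 9)
  cfg <- sim_config(insertion_rate = 0.02, deletion_rate = 0.02,
                    substitution_rate = 0.02, seed = 10)
  sim <- simulate_reads(ref, cfg, 300)
  cols <- reconstruct_columns(truth_hits(sim))
  prof <- accumulate_profile(cols, 15)
  # conservation: per position, mismatch counts from ref base X never exceed
  # the X denominator, and match+mismatch counts equal it
  for (p in c(1, 5, 15)) {
    for (b in c("A", "C", "G", "T")) {
      cls <- paste0(b, ">", setdiff(c("A", "C", "G", "T"), b))
      sub <- prof[prof$end == "5p" & prof$position == p & prof$class %in% cls, ]
      aligned <- cols[cols$read_pos == p & cols$event %in% c("match", "mismatch") &
                        cols$ref_base == b & cols$read_base != "N", ]
      expect_equal(sum(sub$count),
                   sum(aligned$event == "mismatch"))
      expect_equal(unique(sub$denom), nrow(aligned))
    }
  }
  shuffled <- cols[sample(nrow(cols)), ]
  expect_equal(as.data.frame(accumulate_profile(shuffled, 15)),
               as.data.frame(prof))
})

test_that("terminal damage fraction follows its defining ratio", {
  # all mismatches are C>T at position 1 -> fraction 1
  cols <- cols_fixture(6, ref5 = rep("C", 6),
                       mismatch = list(list(read = "r1", pos = 1, to = "T"),
                                       list(read = "r2", pos = 1, to = "T")))
  expect_equal(cumulative_terminal_damage(accumulate_profile(cols, Inf)), 1)
  # no GC->AT among mismatches -> 0
  cols2 <- cols_fixture(6, mismatch = list(list(read = "r1", pos = 1, to = "C")))
  expect_equal(cumulative_terminal_damage(accumulate_profile(cols2, Inf)), 0)
  # mixed: 8 terminal GC>AT of 25 mismatches -> 0.32
  mm <- c(lapply(1:8, function(i) list(read = paste0("r", i), pos = 1, to = "T")),
          lapply(1:17, function(i) list(read = paste0("r", i), pos = 8, to = "C")))
  cols3 <- cols_fixture(20, len = 16, ref5 = rep("C", 20), mismatch = mm)
  expect_equal(cumulative_terminal_damage(accumulate_profile(cols3, Inf),
                                          n_terminal = 5), 0.32)
  # no mismatches at all -> absent, not zero
  expect_true(is.na(cumulative_terminal_damage(accumulate_profile(
    cols_fixture(3), Inf))))
})

test_that("profile recovers the configured 5' deamination probability", {
  ref <- random_reference(50000, seed = 7)
  cfg <- sim_config(platform = "illumina", insertion_rate = 0,
                    deletion_rate = 0, substitution_rate = 0,
                    damage = list(p0 = 0.3, decay = 0.5, max_overhang = 3),
                    seed = 21)
  sim <- simulate_reads(ref, cfg, 4000)
  prof <- accumulate_profile(reconstruct_columns(truth_hits(sim)), 5)
  r1 <- prof[prof$end == "5p" & prof$position == 1 & prof$class == "C>T", ]
  expect_binomial_ci_covers(r1$rate, 0.3, r1$denom)
})

test_that("damage-length correlation responds to length-biased mapping of damaged reads", {
  # deterministic per-length rates exactly linear in length -> r = 1
  lens <- c(30, 35, 40, 45)
  rows <- list()
  for (j in seq_along(lens)) {
    L <- lens[j]
    n_dmg <- j        # rate grows linearly with length: j / 10
    for (i in 1:10) {
      dmg <- i <= n_dmg
      rows[[length(rows) + 1]] <- tibble::tibble(
        read_id = paste0("L", L, "_", i), read_pos = 1L, ref_pos = 1L,
        ref_base = "G", read_base = if (dmg) "A" else "G",
        event = if (dmg) "mismatch" else "match",
        base_qual = 40L, read_len = L
      )
    }
  }
  cols <- dplyr::bind_rows(rows)
  res <- damage_length_correlation(cols, "G>A")
  expect_equal(res$estimate, 1.0, tolerance = 1e-8)
  expect_lt(res$p_value, 0.01)
  expect_equal(nrow(tidy(res)), 4)
  expect_equal(glance(res)$estimate, res$estimate)

  # constant rates: degenerate variance is flagged, not a spurious r
  flat <- dplyr::mutate(cols, read_base = "G", event = "match")
  res_flat <- damage_length_correlation(flat, "G>A")
  expect_true(is.na(res_flat$estimate))
  expect_equal(res_flat$p_value, 1)
})
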