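test_that("trim candidates enforce the 30-nt pre-trim minimum and strict prefix removal", {
  reads <- read_table(
    c("short", "exact", "long"),
    c(strrep("A", 29), paste0("TT", strrep("G", 28)), strrep("C", 40)),
    NA, "helicos"
  )
  out <- trim_candidates(reads, 2)
  expect_false("short" %in% out$records$read_id)   # 29 nt: never trimmed
  expect_equal(nchar(out$reads$bases[out$reads$read_id == "exact"]), 28)
  expect_equal(out$records$trimmed_bases[out$records$read_id == "exact"], "TT")
  # suffix unchanged
  expect_equal(out$reads$bases[out$reads$read_id == "long"], strrep("C", 38))
  expect_error(trim_candidates(reads, 3))
})

test_that("trimmed bases are classified against the strand-aware upstream reference", {
  #              1234567890123
  ref <- c(ctg = "ACGTTCAGGTACC")
  # forward hit at position 3 after trimming 1 base "T"; upstream ref base
  # (position 2) is C -> class C>T
  recs <- tibble::tibble(read_id = "f1", n_trimmed = 1L, trimmed_bases = "T")
  hit <- make_hit("f1", reference_name = "ctg", position = 3L, cigar = "4M",
                  seq = "GTTC", md = "4")
  out <- classify_trimmed(recs, hit, ref)
  expect_equal(out$inferred_ref_bases, "C")
  expect_equal(out$mismatch_class, "C>T")

  # trimmed base equal to the upstream base -> match
  recs2 <- tibble::tibble(read_id = "f2", n_trimmed = 1L, trimmed_bases = "C")
  out2 <- classify_trimmed(recs2, hit |> dplyr::mutate(read_id = "f2"), ref)
  expect_equal(out2$mismatch_class, "match")

  # reverse strand: upstream in read orientation lies past the reference end,
  # complemented; ref positions 8,9 = G,G -> complement C,C; trimmed TT -> two C>T
  recs3 <- tibble::tibble(read_id = "rv", n_trimmed = 2L, trimmed_bases = "TT")
  hit3 <- make_hit("rv", reference_name = "ctg", position = 4L, cigar = "4M",
                   seq = "TTCA", md = "4", flag = 16L, strand = "reverse")
  out3 <- classify_trimmed(recs3, hit3, ref)
  expect_equal(out3$mismatch_class, "C>T,C>T")

  # no upstream base: unclassifiable
  recs4 <- tibble::tibble(read_id = "edge", n_trimmed = 1L, trimmed_bases = "T")
  hit4 <- make_hit("edge", reference_name = "ctg", position = 1L,
                   cigar = "4M", seq = "ACGT", md = "4")
  expect_equal(classify_trimmed(recs4, hit4, ref)$mismatch_class,
               "unclassifiable")

  # unknown contig is an error
  hit5 <- make_hit("f1", reference_name = "nope", position = 3L)
  expect_error(classify_trimmed(recs, hit5, ref), "absent from FASTA")
})

test_that("trim classification matches injected deamination events on simulator truth", {
  ref <- random_reference(30000, seed = 12)
  cfg <- sim_config(insertion_rate = 0, deletion_rate = 0,
                    substitution_rate = 0, length_range = c(32, 45),
                    damage = list(p0 = 1, decay = 1, max_overhang = 1),
                    seed = 13)
  sim <- simulate_reads(ref, cfg, 300)
  # every read whose template starts with C carries a deamination at pos 1
  dmg_ids <- sim$events$read_id[sim$events$type == "deamination" &
                                  sim$events$read_pos == 1]
  tr <- trim_candidates(sim$reads, 1, min_length = 30)
  # post-trim truth alignment: one base shorter at the 5' end
  t2 <- sim$truth
  fwd <- t2$strand == "forward"
  t2$start[fwd] <- t2$start[fwd] + 1L
  t2$end[!fwd] <- t2$end[!fwd] - 1L
  trimmed_reads <- tr$reads
  post <- dplyr::bind_rows(lapply(seq_len(nrow(trimmed_reads)), function(i) {
    id <- trimmed_reads$read_id[i]
    ti <- t2[t2$read_id == id, ]
    L <- nchar(trimmed_reads$bases[i])
    seq_sam <- if (ti$strand == "forward") trimmed_reads$bases[i] else
      paleomapr:::revcomp_chr(trimmed_reads$bases[i])
    make_hit(id, reference_name = ti$source_sequence, position = ti$start,
             cigar = paste0(L, "M"), seq = seq_sam, md = as.character(L),
             nm = 0L, flag = if (ti$strand == "forward") 0L else 16L,
             strand = ti$strand)
  }))
  recs <- classify_trimmed(tr$records, post, ref)
  trimmed_dmg <- recs$read_id %in% dmg_ids
  expect_true(all(recs$mismatch_class[trimmed_dmg] == "C>T"))
  expect_true(all(recs$mismatch_class[!trimmed_dmg] == "match"))
})

test_that("gain report bins recovered reads and conserves counts", {
  recs <- tibble::tibble(
    read_id = paste0("r", 1:6),
    n_trimmed = 1L,
    trimmed_bases = c("T", "T", "A", "G", "T", "C"),
    inferred_ref_bases = c("C", "C", "A", "T", "C", "C"),
    mismatch_class = c("C>T", "C>T", "match", "T>G", "C>T", "match")
  )
  # only r1, r2, r4 became hq
  rep1 <- gain_report(recs, c("r1", "r2", "r4"), baseline_hq = 100)
  expect_equal(sum(rep1$n_recovered), 3)
  expect_equal(rep1$n_recovered[rep1$class == "C>T"], 2)
  expect_equal(rep1$gain[rep1$class == "C>T"], 0.02)
  expect_true(all(rep1$gain >= 0 & rep1$gain <= 1))
  # no recoveries -> empty report
  expect_equal(nrow(gain_report(recs, character(0), 100)), 0)
  # permutation invariance
  rep2 <- gain_report(recs[sample(6), ], c("r1", "r2", "r4"), 100)
  expect_equal(dplyr::arrange(rep2, class), dplyr::arrange(rep1, class))
})

test_that("two-base bins require both classes equal under the default mode", {
  recs <- tibble::tibble(
    read_id = c("both", "mixed"), n_trimmed = 2L,
    trimmed_bases = c("TT", "TA"), inferred_ref_bases = c("CC", "CA"),
    mismatch_class = c("C>T,C>T", "C>T,match")
  )
  rep_both <- gain_report(recs, c("both", "mixed"), 10)
  expect_equal(rep_both$n_recovered[rep_both$class == "C>T"], 1)
  expect_equal(rep_both$n_recovered[rep_both$class == "mixed"], 1)
  rep_any <- gain_report(recs, c("both", "mixed"), 10, damage_mode = "any")
  expect_equal(rep_any$n_recovered[rep_any$class == "C>T"], 2)
})

test_that("conservative post-trim filtering excludes reads mapping in either version", {
  untrimmed <- make_hits(
    make_hit("a"), make_hit("b", uniqueness = "unmapped", position = NA),
    make_hit("c", uniqueness = "unmapped", position = NA)
  )
  trimmed <- make_hits(
    make_hit("a"), make_hit("b"),
    make_hit("c", uniqueness = "unmapped", position = NA)
  )
  expect_equal(conservative_posttrim_filter(untrimmed, trimmed,
                                            c("a", "b", "c")), "c")
})
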