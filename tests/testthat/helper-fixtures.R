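# Fixtures are generated in code; nothing is stored on disk.

# One-row hit table with sensible defaults, overridable per field.
make_hit <- function(read_id = "r1", flag = 0L, reference_name = "chr1",
                     position = 100L, mapq = 37L, cigar = "10M",
                     seq = "ACGTACGTAC", qual = NA_character_,
                     strand = "forward", uniqueness = "unique",
                     best_hits = 1L, alt_hits = 0L, nm = 0L,
                     md = "10", is_duplicate = FALSE) {
  tibble::tibble(
    read_id = read_id, flag = flag, reference_name = reference_name,
    position = as.integer(position), mapq = as.integer(mapq), cigar = cigar,
    seq = seq, qual = qual, strand = strand, uniqueness = uniqueness,
    best_hits = as.integer(best_hits), alt_hits = as.integer(alt_hits),
    nm = as.integer(nm), md = md, is_duplicate = is_duplicate
  )
}

make_hits <- function(...) dplyr::bind_rows(...)

# Target genome, contaminant copy at 15% divergence sharing an identical
# conserved block, and a distant outgroup: the standard filter fixture.
fixture_genomes <- function(seed = 3, n_bases = 30000,
                            conserved = c(10000, 13000)) {
  target <- random_reference(n_bases, seed = seed, name = "target")
  contaminant <- make_diverged_reference(target, 0.15, conserved = conserved,
                                         seed = seed + 1, name = "target")
  outgroup <- random_reference(n_bases, seed = seed + 2, name = "outgroup")
  list(target = target, contaminant = contaminant, outgroup = outgroup,
       conserved = conserved)
}

# Error-free reads from the target plus target/contaminant truth hit
# tables with aligner mappability emulated on the contaminant side.
fixture_filter_sets <- function(n = 1000, seed = 55) {
  g <- fixture_genomes()
  cfg <- sim_config(insertion_rate = 0, deletion_rate = 0,
                    substitution_rate = 0, seed = seed)
  sim <- simulate_reads(g$target, cfg, n)
  target_hits <- truth_hits(sim)
  contaminant_hits <- simulate_mappability(truth_hits(sim, reference = g$contaminant))
  list(genomes = g, sim = sim, target_hits = target_hits,
       contaminant_hits = contaminant_hits)
}

expect_binomial_ci_covers <- function(estimate, truth, n, level_z = 1.96) {
  half <- level_z * sqrt(truth * (1 - truth) / n)
  expect_lt(abs(estimate - truth), half + 1e-12)
}
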