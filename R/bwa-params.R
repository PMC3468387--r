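#' Read-length-dependent maximum edit distance
#'
#' The maxdiff construction used by BWA's `aln` mode: for a read of length
#' L and a per-base error rate e, the number of errors is modelled as
#' Poisson with mean L*e, and the maximum tolerated edit distance is the
#' smallest k >= 1 whose upper-tail probability P(X > k) falls strictly
#' below the missing-alignment fraction (the `-n` option).
#'
#' @param read_length Integer vector of read lengths (>= 1).
#' @param per_base_error Assumed per-base error rate (BWA's internal
#'   constant, 0.02).
#' @param missing_fraction Tolerated fraction of missed alignments
#'   (`-n`; default 0.04).
#' @return Integer vector of maximum edit distances.
#' @export
#'
#' @examples
#' max_edit_distance(c(37, 38, 63, 64))
max_edit_distance <- function(read_length, per_base_error = 0.02,
                              missing_fraction = 0.04) {
  stopifnot(all(read_length >= 1),
            per_base_error > 0, per_base_error < 1,
            missing_fraction > 0, missing_fraction < 1)
  vapply(read_length, function(L) {
    lambda <- L * per_base_error
    for (k in 1:1000) {
      if (1 - ppois(k, lambda) < missing_fraction) return(as.integer(k))
    }
    stop("maximum edit distance did not converge below k = 1000",
         call. = FALSE)
  }, integer(1))
}

#' Edit-distance threshold table
#'
#' The read lengths at which [max_edit_distance()] changes value over a
#' length range — the breakpoints an aligner log reports as "k mismatches
#' are tolerated up to length L".
#'
#' @inheritParams max_edit_distance
#' @param min_len,max_len Length range to scan.
#' @return A tibble with `first_length` (the smallest read length taking
#'   the new value) and `max_diff`.
#' @export
threshold_table <- function(per_base_error = 0.02, missing_fraction = 0.04,
                            min_len = 17, max_len = 250) {
  stopifnot(min_len <= max_len)
  lens <- min_len:max_len
  k <- max_edit_distance(lens, per_base_error, missing_fraction)
  change <- c(TRUE, diff(k) != 0)
  tibble(first_length = lens[change], max_diff = k[change])
}

#' Recommended platform-specific alignment parameters
#'
#' The parameter sets recommended for mapping ancient-DNA reads with
#' `bwa aln`: for Illumina, defaults with the seed disabled (`-l 1024`);
#' for Helicos tSMS (indel-dominated errors), additionally indels allowed
#' at read termini (`-i 0`), up to two gap opens (`-o 2`) and a slightly
#' relaxed edit distance (`-n 0.03`). Mismatch/gap-open/gap-extension
#' penalties stay at their defaults (3/11/4), which were found to perform
#' best.
#'
#' @param platform `"illumina"` or `"helicos"`.
#' @return A one-row tibble with the parameter vector: `platform`,
#'   `seed_length`, `indel_end_distance`, `max_gap_opens`,
#'   `gap_open_penalty`, `gap_extend_penalty`, `mismatch_penalty`,
#'   `missing_fraction`.
#' @export
#'
#' @examples
#' recommend_parameters("helicos")
recommend_parameters <- function(platform = c("illumina", "helicos")) {
  platform <- match.arg(platform)
  defaults <- tibble(
    platform = platform,
    seed_length = 1024L,         # -l; 1024 disables the seed
    indel_end_distance = 5L,     # -i
    max_gap_opens = 1L,          # -o
    gap_open_penalty = 11L,      # -O
    gap_extend_penalty = 4L,     # -E
    mismatch_penalty = 3L,       # -M
    missing_fraction = 0.04      # -n
  )
  if (platform == "helicos") {
    defaults$indel_end_distance <- 0L
    defaults$max_gap_opens <- 2L
    defaults$missing_fraction <- 0.03
  }
  defaults
}

#' Render a parameter set as a `bwa aln` command line
#'
#' Non-default flags appear exactly once; defaults are omitted.
#'
#' @param params A one-row tibble from [recommend_parameters()].
#' @param reference,reads_fastq Optional file paths appended to the
#'   command.
#' @return A single command string.
#' @export
bwa_command <- function(params, reference = "<reference.fa>",
                        reads_fastq = "<reads.fastq>") {
  stopifnot(nrow(params) == 1)
  flags <- character(0)
  add <- function(flags, flag, value, default) {
    if (!isTRUE(all.equal(value, default))) c(flags, paste(flag, value)) else flags
  }
  flags <- add(flags, "-l", params$seed_length, 32L)
  flags <- add(flags, "-i", params$indel_end_distance, 5L)
  flags <- add(flags, "-o", params$max_gap_opens, 1L)
  flags <- add(flags, "-O", params$gap_open_penalty, 11L)
  flags <- add(flags, "-E", params$gap_extend_penalty, 4L)
  flags <- add(flags, "-M", params$mismatch_penalty, 3L)
  flags <- add(flags, "-n", params$missing_fraction, 0.04)
  paste(c("bwa aln", flags, reference, reads_fastq), collapse = " ")
}
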