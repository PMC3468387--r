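#' Pre-mapping read QC configuration
#'
#' Thresholds for the pre-mapping filters applied to quality-scored
#' (Illumina) reads: minimum retained length, minimum base quality of the
#' first sequenced base, the terminal quality at or below which bases are
#' stripped from both ends, and optional 3' adapter sequences.
#'
#' @param min_length Minimum read length kept after trimming (default 25).
#' @param min_start_quality Reject reads whose first base has a PHRED score
#'   below this (default 10).
#' @param trim_end_quality Strip terminal bases with PHRED score at or
#'   below this from both ends (default 2).
#' @param adapters Character vector of adapter sequences matched at the
#'   read 3' end (exact match of an adapter prefix of at least 8 nt).
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(min_length = 25, min_start_quality = 10,
                      trim_end_quality = 2, adapters = character()) {
  stopifnot(min_length >= 1, min_start_quality >= 0, trim_end_quality >= 0)
  structure(
    list(min_length = as.integer(min_length),
         min_start_quality = as.integer(min_start_quality),
         trim_end_quality = as.integer(trim_end_quality),
         adapters = toupper(adapters)),
    class = "qc_config"
  )
}

#' Adapter and quality trimming
#'
#' Removes a 3' adapter occurrence (the read suffix equal to a prefix of a
#' configured adapter, requiring at least 8 matching nucleotides) and then
#' strips terminal bases with quality at or below `trim_end_quality` from
#' both ends. Reads without base qualities are returned unchanged.
#'
#' @param reads A read table.
#' @param cfg A [qc_config()].
#' @return The read table with trimmed `bases`/`qual`; possibly empty reads.
#' @export
quality_trim <- function(reads, cfg = qc_config()) {
  validate_reads(reads)
  out <- reads
  for (i in seq_len(nrow(out))) {
    q <- out$qual[i]
    if (is.na(q)) next
    b <- out$bases[i]
    cut <- adapter_cut(b, cfg$adapters)
    if (!is.na(cut)) {
      b <- substring(b, 1, cut - 1L)
      q <- substring(q, 1, cut - 1L)
    }
    sc <- as.integer(utf8ToInt(q)) - 33L
    keep <- which(sc > cfg$trim_end_quality)
    if (length(keep) == 0) {
      b <- ""; q <- ""
    } else {
      b <- substring(b, keep[1], keep[length(keep)])
      q <- substring(q, keep[1], keep[length(keep)])
    }
    out$bases[i] <- b
    out$qual[i] <- q
  }
  out
}

## Leftmost read position at which a >= 8 nt prefix of an adapter occupies
## the read suffix; NA if none.
adapter_cut <- function(bases, adapters) {
  L <- nchar(bases)
  best <- NA_integer_
  for (ad in adapters) {
    max_k <- min(L, nchar(ad))
    if (max_k < 8) next
    for (k in max_k:8) {  # prefer the longest (leftmost) occurrence
      if (substring(bases, L - k + 1L, L) == substring(ad, 1L, k)) {
        cand <- L - k + 1L
        if (is.na(best) || cand < best) best <- cand
        break
      }
    }
  }
  best
}

#' Sequencing-start filter
#'
#' Rejects reads whose first base is undetermined (N) or has a base
#' quality below `min_start_quality`. Reads without qualities are judged
#' on the N criterion only.
#'
#' @inheritParams quality_trim
#' @return A logical vector, `TRUE` for reads to keep.
#' @export
start_filter <- function(reads, cfg = qc_config()) {
  validate_reads(reads)
  first_base <- substring(reads$bases, 1, 1)
  first_q <- vapply(reads$qual, function(q) {
    if (is.na(q) || nchar(q) == 0) NA_integer_
    else as.integer(utf8ToInt(substring(q, 1, 1))) - 33L
  }, integer(1), USE.NAMES = FALSE)
  ok_base <- nchar(reads$bases) > 0 & first_base != "N"
  ok_q <- is.na(first_q) | first_q >= cfg$min_start_quality
  ok_base & ok_q
}

#' Length filter
#'
#' Retains reads with at least `min_length` bases, preserving order. The
#' default of 25 nt reduces the chance of spurious hits from very short
#' fragments.
#'
#' @inheritParams quality_trim
#' @param min_length Minimum length kept.
#' @return The surviving rows of `reads`.
#' @export
length_filter <- function(reads, min_length = 25) {
  dplyr::filter(reads, nchar(.data$bases) >= min_length)
}

#' Full pre-mapping QC pass
#'
#' Applies [quality_trim()], [start_filter()] and [length_filter()] in
#' order and records how many reads each step removed.
#'
#' @inheritParams quality_trim
#' @return The surviving read table; attribute `"qc_summary"` is a tibble
#'   of per-step input/removed counts.
#' @export
run_qc <- function(reads, cfg = qc_config()) {
  n0 <- nrow(reads)
  trimmed <- quality_trim(reads, cfg)
  keep_start <- start_filter(trimmed, cfg)
  after_start <- trimmed[keep_start, , drop = FALSE]
  out <- length_filter(after_start, cfg$min_length)
  summary <- tibble(
    step = c("start_filter", "length_filter"),
    n_in = c(n0, nrow(after_start)),
    n_removed = c(n0 - nrow(after_start), nrow(after_start) - nrow(out))
  )
  attr(out, "qc_summary") <- summary
  out
}
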