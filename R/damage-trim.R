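#' Select and trim 5'-damage candidates
#'
#' Reads that failed high-quality classification are trimmed of one or two
#' bases from the 5' end — the positions that carry most post-mortem
#' cytosine deaminations — and realigned. Only reads of at least
#' `min_length` nucleotides before trimming are considered, to limit
#' spurious alignments of shortened queries; trimming is a strict prefix
#' removal.
#'
#' @param reads A read table of previously unmapped / non-hq reads.
#' @param n_bases Number of 5' bases to remove (1 or 2).
#' @param min_length Minimum pre-trim length (default 30).
#' @return A list with `reads` (the trimmed read table) and `records` (a
#'   tibble of trim stubs: `read_id`, `n_trimmed`, `trimmed_bases`).
#' @export
trim_candidates <- function(reads, n_bases, min_length = 30) {
  stopifnot(n_bases %in% c(1L, 2L))
  validate_reads(reads)
  keep <- nchar(reads$bases) >= min_length
  kept <- reads[keep, , drop = FALSE]
  records <- tibble(
    read_id = kept$read_id,
    n_trimmed = as.integer(n_bases),
    trimmed_bases = substring(kept$bases, 1, n_bases)
  )
  kept$bases <- substring(kept$bases, n_bases + 1L)
  kept$qual <- ifelse(is.na(kept$qual), NA_character_,
                      substring(kept$qual, n_bases + 1L))
  list(reads = kept, records = records)
}

#' Infer the mismatch class the trimmed bases would have caused
#'
#' Once a trimmed read maps, the alignment is extended upstream by the
#' number of trimmed bases — on the forward strand to reference positions
#' just before the hit start, on the reverse strand to the
#' (complemented, reversed) positions just past the hit's reference end,
#' so trimmed-base order matches sequencing order — and each trimmed base
#' is classified against the reference base it would have aligned to.
#'
#' @param records Trim stubs from [trim_candidates()].
#' @param hits Post-trim hit table (uniquely mapped rows are classified).
#' @param reference Named character vector of reference sequences
#'   ([read_reference()]).
#' @return The records tibble extended with `inferred_ref_bases` and
#'   `mismatch_class` (comma-separated per trimmed base: a substitution
#'   class, `match`, or `unclassifiable` for positions off the contig
#'   edge or against N).
#' @export
classify_trimmed <- function(records, hits, reference) {
  joined <- dplyr::left_join(
    records,
    dplyr::select(hits, "read_id", "reference_name", "position", "strand",
                  "cigar", "uniqueness"),
    by = "read_id"
  )
  n <- nrow(joined)
  ref_bases <- rep(NA_character_, n)
  classes <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (is.na(joined$uniqueness[i]) || joined$uniqueness[i] != "unique") next
    rn <- joined$reference_name[i]
    if (!rn %in% names(reference)) {
      stop("reference sequence '", rn, "' absent from FASTA", call. = FALSE)
    }
    contig <- reference[[rn]]
    k <- joined$n_trimmed[i]
    tb <- explode_chars(joined$trimmed_bases[i])
    if (joined$strand[i] == "forward") {
      pos <- (joined$position[i] - k):(joined$position[i] - 1L)
      rb <- ifelse(pos >= 1, substring(contig, pos, pos), NA_character_)
    } else {
      span <- cigar_ref_span(joined$cigar[i])
      end <- joined$position[i] + span - 1L
      pos <- (end + k):(end + 1L)   # sequencing order: furthest first
      rb <- ifelse(pos <= nchar(contig),
                   complement_chr(substring(contig, pos, pos)), NA_character_)
    }
    cls <- dplyr::case_when(
      is.na(rb) | rb == "N" | tb == "N" ~ "unclassifiable",
      rb == tb ~ "match",
      TRUE ~ paste0(rb, ">", tb)
    )
    ref_bases[i] <- paste(ifelse(is.na(rb), ".", rb), collapse = "")
    classes[i] <- paste(cls, collapse = ",")
  }
  joined$inferred_ref_bases <- ref_bases
  joined$mismatch_class <- classes
  dplyr::select(joined, "read_id", "n_trimmed", "trimmed_bases",
                "inferred_ref_bases", "mismatch_class")
}

cigar_ref_span <- function(cigar) {
  vapply(cigar, function(cg) {
    ops <- parse_cigar(cg)
    sum(ops$len[ops$op %in% c("M", "D")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Recovery gains after damage trimming, binned by mismatch class
#'
#' Bins reads that became high-quality hits after 5' trimming by the
#' mismatch class their trimmed bases would have caused, and reports each
#' bin's count and its gain as a fraction of the baseline high-quality
#' count. The deamination bin (C->T for Illumina, G->A for Helicos)
#' against the other-class control bins shows whether recovered reads are
#' damage-driven.
#'
#' @param records Classified trim records from [classify_trimmed()].
#' @param hq_after_trim Character vector of read ids that are hq after
#'   trimming (and pass contamination filtering).
#' @param baseline_hq Baseline high-quality hit count (the denominator of
#'   gain fractions).
#' @param damage_mode For two-base trims, require both trimmed bases to be
#'   the same class (`"both"`, the default, matching "two consecutive
#'   mismatches") or bin by any class present (`"any"`, which bins a read
#'   once per distinct class).
#' @return A tibble with `class`, `n_recovered`, `gain` sorted by count.
#' @export
gain_report <- function(records, hq_after_trim, baseline_hq,
                        damage_mode = c("both", "any")) {
  damage_mode <- match.arg(damage_mode)
  rec <- dplyr::filter(records, .data$read_id %in% hq_after_trim,
                       !is.na(.data$mismatch_class))
  bins <- lapply(strsplit(rec$mismatch_class, ",", fixed = TRUE), function(cl) {
    if (damage_mode == "both") {
      if (length(unique(cl)) == 1) cl[1] else "mixed"
    } else {
      unique(cl)
    }
  })
  cls_vec <- unlist(bins, use.names = FALSE)
  out <- tibble(
    read_id = rep(rec$read_id, lengths(bins)),
    class = if (is.null(cls_vec)) character(0) else cls_vec
  ) |>
    dplyr::count(.data$class, name = "n_recovered") |>
    dplyr::mutate(gain = if (baseline_hq > 0) .data$n_recovered / baseline_hq
                  else 0) |>
    dplyr::arrange(dplyr::desc(.data$n_recovered))
  out
}

#' Conservative contaminant filter across trimmed and untrimmed versions
#'
#' After trimming, a candidate read is excluded when either its untrimmed
#' or its trimmed version maps to the contaminant genome — a conservative
#' guard, since shortening queries inflates chance alignments.
#'
#' @param untrimmed_contaminant_hits,trimmed_contaminant_hits Contaminant
#'   hit tables keyed by read id.
#' @param candidates Character vector of candidate read ids.
#' @return The retained read ids.
#' @export
conservative_posttrim_filter <- function(untrimmed_contaminant_hits,
                                         trimmed_contaminant_hits,
                                         candidates) {
  mapped <- function(h) h$read_id[h$uniqueness != "unmapped"]
  bad <- union(mapped(untrimmed_contaminant_hits),
               mapped(trimmed_contaminant_hits))
  setdiff(candidates, bad)
}
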