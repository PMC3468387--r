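#' Classify hits as high-quality endogenous
#'
#' A hit is a high-quality (hq) endogenous candidate when it maps to a
#' unique location (XT-style tag), has no suboptimal alternative hits
#' (X1 = 0), a mapping quality of at least `mapq_min`, and — when duplicate
#' exclusion is enabled — is not flagged as a PCR duplicate.
#'
#' @param hits A hit table ([read_sam()]).
#' @param mapq_min Minimum mapping quality (default 25).
#' @param exclude_duplicates Exclude reads flagged as PCR duplicates
#'   (flag 0x400); used for merged Illumina alignments.
#' @return A tibble with `read_id`, `status` (one of `hq_endogenous`,
#'   `non_unique`, `low_mapq`, `duplicate`, `unmapped`), `reason`, `mapq`
#'   and `nm`.
#' @export
classify_hits <- function(hits, mapq_min = 25, exclude_duplicates = TRUE) {
  alt <- ifelse(is.na(hits$alt_hits), 0L, hits$alt_hits)
  status <- dplyr::case_when(
    hits$uniqueness == "unmapped" ~ "unmapped",
    exclude_duplicates & isTRUE_vec(hits$is_duplicate) ~ "duplicate",
    hits$uniqueness != "unique" | alt > 0L ~ "non_unique",
    hits$mapq < mapq_min ~ "low_mapq",
    TRUE ~ "hq_endogenous"
  )
  reason <- dplyr::case_when(
    status == "hq_endogenous" ~ "unique, no alternative hits, mapq >= threshold",
    status == "unmapped" ~ "read did not map",
    status == "duplicate" ~ "flagged as PCR duplicate",
    status == "non_unique" ~ "repeat placement or suboptimal alternative hits",
    status == "low_mapq" ~ paste0("mapq below ", mapq_min)
  )
  tibble(read_id = hits$read_id, status = status, reason = reason,
         mapq = hits$mapq, nm = hits$nm)
}

hq_ids <- function(hits, mapq_min = 25, exclude_duplicates = TRUE) {
  cls <- classify_hits(hits, mapq_min, exclude_duplicates)
  cls$read_id[cls$status == "hq_endogenous"]
}

check_unique_ids <- function(hits, label) {
  if (anyDuplicated(hits$read_id)) {
    stop("duplicate read_id in ", label, " alignment set", call. = FALSE)
  }
}

#' Strict contamination filter
#'
#' Retains target high-quality hits for reads with no qualifying hit on
#' the contaminant genome. With `contaminant_mode = "any_hit"` (the
#' conservative mode used for Illumina data), every mapped contaminant
#' hit counts, even repeat placements with alternative hits (paralogs);
#' with `"hq_hit"` only contaminant hits that are themselves high-quality
#' count.
#'
#' @param target_hits,contaminant_hits Hit tables keyed by `read_id`
#'   (one row per read).
#' @param contaminant_mode `"any_hit"` or `"hq_hit"`.
#' @param mapq_min Minimum mapping quality for high-quality status.
#' @param exclude_duplicates Duplicate exclusion for the *target* side;
#'   contaminant duplicate flags are not trusted.
#' @return Character vector of retained read ids.
#' @export
strict_filter <- function(target_hits, contaminant_hits,
                          contaminant_mode = c("any_hit", "hq_hit"),
                          mapq_min = 25, exclude_duplicates = TRUE) {
  contaminant_mode <- match.arg(contaminant_mode)
  check_unique_ids(target_hits, "target")
  check_unique_ids(contaminant_hits, "contaminant")
  hq <- hq_ids(target_hits, mapq_min, exclude_duplicates)
  bad <- if (contaminant_mode == "any_hit") {
    contaminant_hits$read_id[contaminant_hits$uniqueness != "unmapped"]
  } else {
    hq_ids(contaminant_hits, mapq_min, exclude_duplicates = FALSE)
  }
  setdiff(hq, bad)
}

#' Best-hit contamination filter
#'
#' Retains a target high-quality hit with a mapped contaminant hit only
#' when its edit distance to the target genome is strictly smaller than to
#' the contaminant genome; ties are filtered (the conservative reading of
#' "greater or equal edit distance"). Reads with no contaminant hit are
#' always retained.
#'
#' @inheritParams strict_filter
#' @return Character vector of retained read ids.
#' @export
besthit_filter <- function(target_hits, contaminant_hits, mapq_min = 25,
                           exclude_duplicates = TRUE) {
  check_unique_ids(target_hits, "target")
  check_unique_ids(contaminant_hits, "contaminant")
  hq <- hq_ids(target_hits, mapq_min, exclude_duplicates)
  cont <- contaminant_hits[contaminant_hits$uniqueness != "unmapped", ,
                           drop = FALSE]
  cmp <- dplyr::inner_join(
    tibble(read_id = hq),
    dplyr::select(target_hits, "read_id", target_nm = "nm"),
    by = "read_id"
  )
  cmp <- dplyr::left_join(
    cmp, dplyr::select(cont, "read_id", contaminant_nm = "nm"),
    by = "read_id"
  )
  compared <- !is.na(cmp$contaminant_nm) | cmp$read_id %in% cont$read_id
  if (any(cmp$read_id %in% cont$read_id & is.na(cmp$contaminant_nm)) ||
      any(compared & is.na(cmp$target_nm))) {
    stop("NM missing on a compared hit; best-hit filtering needs edit distances",
         call. = FALSE)
  }
  keep <- is.na(cmp$contaminant_nm) | cmp$target_nm < cmp$contaminant_nm
  cmp$read_id[keep]
}

#' Spurious-alignment rate against an outgroup genome
#'
#' The fraction of reads attracting high-quality hits on a distant
#' outgroup genome (e.g. chicken for a mammal study) monitors the level of
#' chance alignments a parameter set admits; a read-length histogram of
#' those hits is returned for diagnostics, as short spurious hits dominate.
#'
#' @param reads A read table (the denominators).
#' @param outgroup_hits Hit table against the outgroup genome.
#' @param mapq_min Minimum mapping quality for high-quality status.
#' @return A list with `count`, `rate` and `size_histogram` (tibble of
#'   `length`, `n`).
#' @export
spurious_rate <- function(reads, outgroup_hits, mapq_min = 25) {
  ids <- hq_ids(outgroup_hits, mapq_min, exclude_duplicates = FALSE)
  ids <- intersect(ids, reads$read_id)
  lens <- nchar(reads$bases[reads$read_id %in% ids])
  hist <- if (length(lens) == 0) {
    tibble(length = integer(0), n = integer(0))
  } else {
    dplyr::count(tibble(length = lens), .data$length, name = "n")
  }
  list(
    count = length(ids),
    rate = if (nrow(reads) == 0) 0 else length(ids) / nrow(reads),
    size_histogram = hist
  )
}
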