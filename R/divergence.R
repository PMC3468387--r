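#' Damage-aware divergence estimate
#'
#' Post-mortem deamination inflates GC->AT transitions, so raw mismatch
#' rates overestimate divergence in ancient samples. This estimator sums,
#' over aligned sites passing a base-quality threshold, all transversions,
#' indel bases and twice the AT->GC transitions (true-divergence
#' transitions are symmetric between the two transition classes, while
#' GC->AT is damage-inflated, so the unaffected class is doubled):
#'
#' divergence = (transversions + indel bases + 2 * AT->GC) / sites
#'
#' Columns within `end_mask` positions of either read end are excluded.
#' Base qualities are required (quality-free platforms such as Helicos
#' tSMS cannot be used); deletion columns carry no base quality and are
#' exempt from the threshold, while insertion bases must pass it.
#'
#' @param columns A column table from [reconstruct_columns()] with base
#'   qualities.
#' @param bq_threshold Minimum base quality of counted columns.
#' @param end_mask Positions masked at both read ends (0, 5 or 10 are the
#'   usual choices).
#' @param indel_per Count indels per `"base"` (default; shares the
#'   per-site denominator) or per `"event"`.
#' @return A one-row tibble: `bq_threshold`, `end_mask`, `n_sites`
#'   (aligned, non-masked columns passing the threshold, mismatches
#'   included), `n_transversions`, `n_indel_bases`, `n_AT_to_GC`,
#'   `n_GC_to_AT`, `divergence`, `gc_to_at_rate`. All counts are 0 and the
#'   rates `NA` when no site qualifies.
#' @export
estimate_divergence <- function(columns, bq_threshold = 35, end_mask = 0,
                                indel_per = c("base", "event")) {
  indel_per <- match.arg(indel_per)
  if (nrow(columns) > 0 &&
      all(is.na(columns$base_qual[columns$event != "deletion"]))) {
    stop("columns carry no base qualities; divergence estimation requires ",
         "quality-scored (Illumina-profile) input", call. = FALSE)
  }
  ok_n <- (is.na(columns$ref_base) | columns$ref_base != "N") &
    (is.na(columns$read_base) | columns$read_base != "N")
  pos3 <- columns$read_len - columns$read_pos + 1L
  unmasked <- columns$read_pos > end_mask & pos3 > end_mask
  d <- columns[ok_n & unmasked, , drop = FALSE]

  aligned <- d$event %in% c("match", "mismatch") & !is.na(d$base_qual) &
    d$base_qual >= bq_threshold
  sites <- d[aligned, , drop = FALSE]
  cls <- paste0(sites$ref_base, ">", sites$read_base)
  is_mm <- sites$event == "mismatch"
  transitions_at_gc <- c("A>G", "T>C")
  transitions_gc_at <- c("C>T", "G>A")
  n_tv <- sum(is_mm & !cls %in% c(transitions_at_gc, transitions_gc_at))
  n_at_gc <- sum(is_mm & cls %in% transitions_at_gc)
  n_gc_at <- sum(is_mm & cls %in% transitions_gc_at)

  ins <- d$event == "insertion" & !is.na(d$base_qual) &
    d$base_qual >= bq_threshold
  del <- d$event == "deletion"
  n_indel <- if (indel_per == "base") {
    sum(ins) + sum(del)
  } else {
    ## events: runs of adjacent indel columns of one read collapse to one
    idx <- d[ins | del, c("read_id", "read_pos", "event")]
    if (nrow(idx) == 0) 0L else {
      idx |>
        dplyr::distinct(.data$read_id, .data$read_pos, .data$event) |>
        nrow()
    }
  }

  n_sites <- nrow(sites)
  tibble(
    bq_threshold = bq_threshold,
    end_mask = as.integer(end_mask),
    n_sites = n_sites,
    n_transversions = n_tv,
    n_indel_bases = n_indel,
    n_AT_to_GC = n_at_gc,
    n_GC_to_AT = n_gc_at,
    divergence = if (n_sites > 0) (n_tv + n_indel + 2 * n_at_gc) / n_sites
                 else NA_real_,
    gc_to_at_rate = if (n_sites > 0) n_gc_at / n_sites else NA_real_
  )
}

#' Divergence as a function of base quality
#'
#' One [estimate_divergence()] per threshold of an ascending base-quality
#' grid, pairing the divergence estimate with the GC->AT misincorporation
#' rate (the damage proxy). Thresholds are cumulative by default (sites
#' with BQ >= t); `mode = "bin"` restricts each estimate to sites whose
#' quality falls between consecutive grid values.
#'
#' @inheritParams estimate_divergence
#' @param bq_grid Ascending numeric vector of thresholds.
#' @param mode `"cumulative"` or `"bin"`.
#' @return A tibble of class `divergence_curve`, one row per threshold.
#' @export
divergence_curve <- function(columns, bq_grid = seq(0, 40, by = 5),
                             end_mask = 0, mode = c("cumulative", "bin")) {
  mode <- match.arg(mode)
  stopifnot(length(bq_grid) > 0, !is.unsorted(bq_grid))
  rows <- purrr::map(seq_along(bq_grid), function(i) {
    t0 <- bq_grid[i]
    cols <- columns
    if (mode == "bin" && i < length(bq_grid)) {
      drop <- !is.na(cols$base_qual) & cols$base_qual >= bq_grid[i + 1]
      cols <- cols[!drop, , drop = FALSE]
    }
    estimate_divergence(cols, bq_threshold = t0, end_mask = end_mask)
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("divergence_curve", class(out)))
}

#' Chi-square comparison of mapping counts
#'
#' Pearson chi-square test (1 df, no continuity correction) on a 2x2 table
#' of read-mapping counts — e.g. reads mapping to two mitochondrial
#' references under two alignment parameter sets — to check whether a
#' parameter change shifts the relative recovery.
#'
#' @param counts A 2x2 matrix (or coercible) of non-negative counts with
#'   positive margins.
#' @return An `htest` object (compatible with `broom::tidy()`).
#' @export
mapping_count_test <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(2, 2)), all(counts >= 0))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("chi-square test undefined: zero row or column margin", call. = FALSE)
  }
  chisq.test(counts, correct = FALSE)
}
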