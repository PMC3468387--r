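#' Position-specific misincorporation table
#'
#' Accumulates, from reconstructed alignment columns, the per-position
#' rates of the 12 ordered substitution classes and of insertions,
#' deletions and soft-clipped bases, counted inward from each read end
#' (in read orientation, position 1 = sequenced 5' terminus). Substitution
#' rates divide mismatch counts by the number of reference bases of the
#' source base observed at that position; insertion/deletion/clip rates
#' divide event bases by the total read depth at that position. Columns
#' with N in read or reconstructed reference are excluded entirely.
#'
#' @param columns A column table from [reconstruct_columns()].
#' @param window Number of positions profiled from each end (default 15,
#'   the terminal window in which post-mortem deamination concentrates;
#'   use `Inf` for full-length profiles).
#' @return A tibble of class `damage_profile` with columns `end`
#'   (`"5p"`/`"3p"`), `position`, `class`, `count`, `denom`, `rate`
#'   (`NA` where the denominator is zero).
#' @export
accumulate_profile <- function(columns, window = 15) {
  if (nrow(columns) > 0) {
    ok_n <- (is.na(columns$ref_base) | columns$ref_base != "N") &
      (is.na(columns$read_base) | columns$read_base != "N")
    columns <- columns[ok_n, , drop = FALSE]
  }
  win <- if (is.finite(window)) as.integer(window) else {
    if (nrow(columns) == 0) 1L else max(columns$read_len)
  }
  template <- tidyr::expand_grid(
    end = c("5p", "3p"),
    position = seq_len(win),
    class = RATE_CLASSES
  )
  if (nrow(columns) == 0) {
    out <- dplyr::mutate(template, count = 0L, denom = 0L, rate = NA_real_)
    return(structure(out, class = c("damage_profile", class(out)),
                     window = win))
  }

  long <- dplyr::bind_rows(
    dplyr::mutate(columns, end = "5p", position = .data$read_pos),
    dplyr::mutate(columns, end = "3p",
                  position = .data$read_len - .data$read_pos + 1L)
  )
  long <- dplyr::filter(long, .data$position >= 1L, .data$position <= win)

  ## substitution classes: denominators are per-position reference-base counts
  aligned <- dplyr::filter(long, .data$event %in% c("match", "mismatch"))
  ref_counts <- aligned |>
    dplyr::count(.data$end, .data$position, .data$ref_base, name = "denom")
  sub_counts <- aligned |>
    dplyr::filter(.data$event == "mismatch") |>
    dplyr::count(.data$end, .data$position, .data$ref_base, .data$read_base,
                 name = "count")
  subs <- template |>
    dplyr::filter(.data$class %in% SUB_CLASSES) |>
    dplyr::mutate(ref_base = substring(.data$class, 1, 1),
                  read_base = substring(.data$class, 3, 3)) |>
    dplyr::left_join(sub_counts, by = c("end", "position", "ref_base", "read_base")) |>
    dplyr::left_join(ref_counts, by = c("end", "position", "ref_base")) |>
    dplyr::select(-"ref_base", -"read_base")

  ## indels and clips: denominators are read depth (one per read base)
  depth <- long |>
    dplyr::filter(.data$event != "deletion") |>
    dplyr::count(.data$end, .data$position, name = "denom")
  ev_counts <- long |>
    dplyr::filter(.data$event %in% c("insertion", "deletion", "softclip")) |>
    dplyr::count(.data$end, .data$position, .data$event, name = "count")
  evs <- template |>
    dplyr::filter(!.data$class %in% SUB_CLASSES) |>
    dplyr::left_join(ev_counts, by = c("end", "position", class = "event")) |>
    dplyr::left_join(depth, by = c("end", "position"))

  out <- dplyr::bind_rows(subs, evs) |>
    dplyr::mutate(
      count = ifelse(is.na(.data$count), 0L, .data$count),
      denom = ifelse(is.na(.data$denom), 0L, .data$denom),
      rate = ifelse(.data$denom > 0, .data$count / .data$denom, NA_real_)
    ) |>
    dplyr::arrange(match(.data$end, c("5p", "3p")), .data$position,
                   match(.data$class, RATE_CLASSES))
  structure(out, class = c("damage_profile", class(out)), window = win)
}

#' The deamination-signal substitution class for a platform
#'
#' Post-mortem cytosine deamination is read as C->T at 5' ends (and G->A
#' at 3' ends) on Illumina libraries; on Helicos tSMS the template strand
#' is sequenced, so the 5' signal is G->A.
#'
#' @param platform `"illumina"` or `"helicos"`.
#' @param end `"5p"` or `"3p"`.
#' @return A substitution-class string such as `"C>T"`.
#' @export
damage_class <- function(platform = c("illumina", "helicos"),
                         end = c("5p", "3p")) {
  platform <- match.arg(platform)
  end <- match.arg(end)
  if (platform == "illumina") {
    if (end == "5p") "C>T" else "G>A"
  } else {
    if (end == "5p") "G>A" else "C>T"
  }
}

#' Cumulative terminal deamination fraction
#'
#' The fraction of all observed mismatches that are GC->AT (C->T or G->A)
#' and fall within the `n_terminal` positions at read termini — the
#' summary used to argue that deamination dominates alignment edit
#' distances. Totals are taken over all positions of the 5' block, so the
#' profile should be built with a window covering full read length
#' (`window = Inf`) for an exact full-read denominator.
#'
#' @param table A `damage_profile` from [accumulate_profile()].
#' @param n_terminal Number of terminal positions (default 5).
#' @param ends Pool GC->AT mismatches from both termini (`"both"`) or the
#'   5' terminus only (`"five_prime"`). With `"both"`, a mismatch within
#'   `n_terminal` of both ends of a very short read is counted once per
#'   end.
#' @return A single fraction, or `NA` when no mismatches were observed.
#' @export
cumulative_terminal_damage <- function(table, n_terminal = 5,
                                       ends = c("both", "five_prime")) {
  ends <- match.arg(ends)
  stopifnot(attr(table, "window") >= n_terminal)
  gc_at <- c("C>T", "G>A")
  total <- sum(table$count[table$end == "5p" & table$class %in% SUB_CLASSES])
  if (total == 0) return(NA_real_)
  term5 <- sum(table$count[table$end == "5p" & table$class %in% gc_at &
                             table$position <= n_terminal])
  term <- term5
  if (ends == "both") {
    term <- term + sum(table$count[table$end == "3p" &
                                     table$class %in% gc_at &
                                     table$position <= n_terminal])
  }
  term / total
}

#' Correlation between terminal damage rate and read length
#'
#' Mapping short damaged reads fails more often than mapping short
#' undamaged reads, so among successfully aligned reads the terminal
#' deamination rate rises with read length. This computes, per read
#' length, the damage-class rate at 5' position 1, and the Pearson
#' correlation of that rate with length.
#'
#' @param columns A column table from [reconstruct_columns()].
#' @param damage_class Substitution class to track (e.g. `"G>A"` for
#'   Helicos, `"C>T"` for Illumina).
#' @return An object of class `damage_length_cor`: a list with `estimate`
#'   (Pearson r), `p_value` (two-sided, t-transform), `per_length` (tibble
#'   of `length`, `count`, `denom`, `rate`) and `damage_class`. With fewer
#'   than 3 informative lengths or degenerate variance, `estimate` is `NA`.
#' @export
damage_length_correlation <- function(columns, damage_class = "G>A") {
  src <- substring(damage_class, 1, 1)
  dst <- substring(damage_class, 3, 3)
  first <- columns |>
    dplyr::filter(.data$read_pos == 1L,
                  .data$event %in% c("match", "mismatch"),
                  .data$ref_base == src, .data$read_base != "N")
  per_length <- first |>
    dplyr::group_by(length = .data$read_len) |>
    dplyr::summarise(
      count = sum(.data$event == "mismatch" & .data$read_base == dst),
      denom = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::mutate(rate = .data$count / .data$denom)
  out <- list(estimate = NA_real_, p_value = NA_real_,
              per_length = per_length, damage_class = damage_class)
  class(out) <- "damage_length_cor"
  if (nrow(per_length) < 3) return(out)
  if (stats::sd(per_length$rate) == 0 || stats::sd(per_length$length) == 0) {
    out$p_value <- 1
    return(out)
  }
  ct <- cor.test(per_length$length, per_length$rate, method = "pearson")
  out$estimate <- unname(ct$estimate)
  out$p_value <- ct$p.value
  out
}

#' @export
print.damage_length_cor <- function(x, ...) {
  cat("Damage-vs-length correlation (", x$damage_class, " at 5' position 1)\n",
      sep = "")
  cat("  Pearson r =", format(x$estimate, digits = 3),
      " p =", format(x$p_value, digits = 3),
      " over", nrow(x$per_length), "read lengths\n")
  invisible(x)
}
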