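#' Read length implied by a CIGAR string
#'
#' Sum of M, I and S operation lengths.
#'
#' @param cigar Character vector of CIGAR strings.
#' @return Integer vector.
#' @export
cigar_read_length <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg)) return(NA_integer_)
    ops <- parse_cigar(cg)
    sum(ops$len[ops$op %in% c("M", "I", "S")])
  }, integer(1), USE.NAMES = FALSE)
}

parse_cigar <- function(cg) {
  toks <- regmatches(cg, gregexpr("[0-9]+[MIDSHNP=X]", cg))[[1]]
  if (length(toks) == 0 || paste(toks, collapse = "") != cg) {
    stop("malformed CIGAR: ", cg, call. = FALSE)
  }
  op <- substring(toks, nchar(toks), nchar(toks))
  if (any(!op %in% c("M", "I", "D", "S"))) {
    stop("unsupported CIGAR operation in: ", cg,
         " (only M/I/D/S are handled)", call. = FALSE)
  }
  list(op = op, len = as.integer(substring(toks, 1, nchar(toks) - 1)))
}

## Expand an MD tag into one record per aligned reference column:
## kind "m" (match), "x" (mismatch, ref base given), "d" (deleted ref base).
parse_md <- function(md) {
  toks <- regmatches(md, gregexpr("[0-9]+|\\^[A-Za-z]+|[A-Za-z]", md))[[1]]
  if (paste(toks, collapse = "") != md) {
    stop("malformed MD tag: ", md, call. = FALSE)
  }
  kind <- character(0)
  base <- character(0)
  for (t in toks) {
    if (grepl("^[0-9]+$", t)) {
      n <- as.integer(t)
      if (n > 0) {
        kind <- c(kind, rep("m", n))
        base <- c(base, rep(NA_character_, n))
      }
    } else if (startsWith(t, "^")) {
      del <- explode_chars(toupper(substring(t, 2)))
      kind <- c(kind, rep("d", length(del)))
      base <- c(base, del)
    } else {
      kind <- c(kind, "x")
      base <- c(base, toupper(t))
    }
  }
  list(kind = kind, base = base)
}

#' Reconstruct per-position alignment columns from CIGAR and MD
#'
#' Recovers, without the reference FASTA, the aligned read-versus-reference
#' columns of each hit: one row per column with the read position (1-based,
#' indexed from the read's sequencing 5' end), the reference and read base,
#' the event class (`match`, `mismatch`, `insertion`, `deletion`,
#' `softclip`) and the base quality. For reverse-strand hits both sequences
#' are complemented and positions re-indexed so that position 1 is the
#' sequenced 5' end (the mapDamage orientation convention); deletion
#' columns carry the deleted reference base and are anchored to the read
#' position that follows them.
#'
#' @param hits A hit table ([read_sam()]) whose rows carry `cigar`, `md`
#'   and `seq`. Unmapped rows and rows with missing CIGAR/MD are skipped
#'   with a warning unless `strict = TRUE`.
#' @param strict Error (instead of skipping) on hits lacking CIGAR or MD.
#' @return A tibble with columns `read_id`, `read_pos`, `ref_pos`
#'   (reference coordinate; `NA` for insertions and soft clips),
#'   `ref_base`, `read_base`, `event`, `base_qual`, `read_len`.
#' @export
#'
#' @examples
#' h <- tibble::tibble(read_id = "r", position = 10L, strand = "forward",
#'                     cigar = "4M", md = "0C3", seq = "TCGA", qual = "IIII",
#'                     uniqueness = "unique")
#' reconstruct_columns(h)
reconstruct_columns <- function(hits, strict = FALSE) {
  usable <- !is.na(hits$cigar) & !is.na(hits$md) & !is.na(hits$seq) &
    hits$uniqueness != "unmapped"
  if (strict && !all(usable)) {
    stop("hit without CIGAR/MD/SEQ cannot be profiled (read '",
         hits$read_id[which(!usable)[1]], "')", call. = FALSE)
  }
  if (any(!usable & hits$uniqueness != "unmapped")) {
    warning(sum(!usable & hits$uniqueness != "unmapped"),
            " mapped hit(s) lacking CIGAR/MD/SEQ were skipped")
  }
  idx <- which(usable)
  parts <- purrr::map(idx, function(i) {
    hit_columns(
      read_id = hits$read_id[i], position = hits$position[i],
      strand = hits$strand[i], cigar = hits$cigar[i], md = hits$md[i],
      seq = hits$seq[i], qual = if ("qual" %in% names(hits)) hits$qual[i] else NA_character_
    )
  })
  if (length(parts) == 0) {
    return(tibble(read_id = character(0), read_pos = integer(0),
                  ref_pos = integer(0), ref_base = character(0),
                  read_base = character(0), event = character(0),
                  base_qual = integer(0), read_len = integer(0)))
  }
  tibble(
    read_id = unlist(lapply(parts, `[[`, "read_id"), use.names = FALSE),
    read_pos = unlist(lapply(parts, `[[`, "read_pos"), use.names = FALSE),
    ref_pos = unlist(lapply(parts, `[[`, "ref_pos"), use.names = FALSE),
    ref_base = unlist(lapply(parts, `[[`, "ref_base"), use.names = FALSE),
    read_base = unlist(lapply(parts, `[[`, "read_base"), use.names = FALSE),
    event = unlist(lapply(parts, `[[`, "event"), use.names = FALSE),
    base_qual = unlist(lapply(parts, `[[`, "base_qual"), use.names = FALSE),
    read_len = unlist(lapply(parts, `[[`, "read_len"), use.names = FALSE)
  )
}

hit_columns <- function(read_id, position, strand, cigar, md, seq, qual) {
  ops <- parse_cigar(cigar)
  mdx <- parse_md(md)
  read_chars <- explode_chars(seq)
  L <- length(read_chars)
  if (sum(ops$len[ops$op %in% c("M", "I", "S")]) != L) {
    stop("CIGAR/sequence length disagreement for read '", read_id, "'",
         call. = FALSE)
  }
  bq <- if (!is.na(qual)) as.integer(utf8ToInt(qual)) - 33L else rep(NA_integer_, L)

  n_cols <- sum(ops$len)
  read_pos <- integer(n_cols)
  ref_pos <- rep(NA_integer_, n_cols)
  ref_base <- rep(NA_character_, n_cols)
  read_base <- rep(NA_character_, n_cols)
  event <- character(n_cols)
  base_qual <- rep(NA_integer_, n_cols)

  r <- 1L   # read cursor
  g <- position   # reference cursor
  m <- 1L   # MD stream cursor
  k <- 0L   # output cursor
  for (j in seq_along(ops$op)) {
    op <- ops$op[j]; len <- ops$len[j]
    sel <- k + seq_len(len)
    if (op == "M") {
      if (length(mdx$kind) < m + len - 1L) {
        stop("MD tag inconsistent with CIGAR for read '", read_id, "'",
             call. = FALSE)
      }
      kinds <- mdx$kind[m:(m + len - 1L)]
      if (any(kinds == "d")) {
        stop("MD tag inconsistent with CIGAR for read '", read_id, "'",
             call. = FALSE)
      }
      rb <- read_chars[r:(r + len - 1L)]
      fb <- ifelse(kinds == "m", rb, mdx$base[m:(m + len - 1L)])
      read_pos[sel] <- r:(r + len - 1L)
      ref_pos[sel] <- g:(g + len - 1L)
      ref_base[sel] <- fb
      read_base[sel] <- rb
      event[sel] <- ifelse(kinds == "m", "match", "mismatch")
      base_qual[sel] <- bq[r:(r + len - 1L)]
      r <- r + len; g <- g + len; m <- m + len
    } else if (op == "I") {
      read_pos[sel] <- r:(r + len - 1L)
      read_base[sel] <- read_chars[r:(r + len - 1L)]
      event[sel] <- "insertion"
      base_qual[sel] <- bq[r:(r + len - 1L)]
      r <- r + len
    } else if (op == "D") {
      if (length(mdx$kind) < m + len - 1L) {
        stop("MD tag inconsistent with CIGAR for read '", read_id, "'",
             call. = FALSE)
      }
      kinds <- mdx$kind[m:(m + len - 1L)]
      if (any(kinds != "d")) {
        stop("MD tag inconsistent with CIGAR for read '", read_id, "'",
             call. = FALSE)
      }
      read_pos[sel] <- r   # anchored to the following read base
      ref_pos[sel] <- g:(g + len - 1L)
      ref_base[sel] <- mdx$base[m:(m + len - 1L)]
      event[sel] <- "deletion"
      g <- g + len; m <- m + len
    } else { # S
      read_pos[sel] <- r:(r + len - 1L)
      read_base[sel] <- read_chars[r:(r + len - 1L)]
      event[sel] <- "softclip"
      base_qual[sel] <- bq[r:(r + len - 1L)]
      r <- r + len
    }
    k <- k + len
  }
  if (m != length(mdx$kind) + 1L) {
    stop("MD tag inconsistent with CIGAR for read '", read_id, "'",
         call. = FALSE)
  }

  if (strand == "reverse") {
    is_del <- event == "deletion"
    read_pos <- ifelse(is_del, L - read_pos + 2L, L - read_pos + 1L)
    ref_base <- complement_chr(ref_base)
    read_base <- complement_chr(read_base)
    ord <- order(read_pos, !is_del)
    read_pos <- read_pos[ord]; ref_pos <- ref_pos[ord]
    ref_base <- ref_base[ord]; read_base <- read_base[ord]
    event <- event[ord]; base_qual <- base_qual[ord]
  }

  list(read_id = rep(read_id, n_cols), read_pos = read_pos, ref_pos = ref_pos,
       ref_base = ref_base, read_base = read_base, event = event,
       base_qual = base_qual, read_len = rep(L, n_cols))
}

#' Edit distance implied by reconstructed columns
#'
#' Mismatch columns plus inserted plus deleted bases — the NM convention
#' adopted throughout the package (soft-clipped bases are not counted).
#'
#' @param columns A column table from [reconstruct_columns()].
#' @return A tibble with `read_id` and `nm`.
#' @export
nm_from_columns <- function(columns) {
  columns |>
    dplyr::group_by(.data$read_id) |>
    dplyr::summarise(
      nm = sum(.data$event %in% c("mismatch", "insertion", "deletion")),
      .groups = "drop"
    )
}
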