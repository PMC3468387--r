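#' Read and write SAM alignments
#'
#' `read_sam()` parses a text SAM file into a hit table: one row per
#' alignment record with columns `read_id`, `flag`, `reference_name`,
#' `position` (1-based leftmost), `mapq`, `cigar`, `seq`, `qual`, `strand`
#' (`"forward"`/`"reverse"`), `uniqueness` (`"unique"`/`"repeat"`/
#' `"unmapped"`, from the XT tag and the unmapped flag), `best_hits` (X0),
#' `alt_hits` (X1), `nm` (NM edit distance), `md` (MD tag) and
#' `is_duplicate` (flag 0x400). Missing optional tags are `NA`, never
#' silently defaulted. The header is kept as an attribute `"header"` so
#' [write_sam()] can round-trip the file.
#'
#' @param path Path to a SAM file.
#' @return A tibble of hits (attribute `"header"` holds the header lines).
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "@")
  header <- lines[is_hdr]
  recs <- lines[!is_hdr]
  recs <- recs[nzchar(recs)]
  if (length(recs) == 0) {
    hits <- empty_hits()
    attr(hits, "header") <- header
    return(hits)
  }
  fields <- strsplit(recs, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11)) {
    stop("SAM record ", which(nf < 11)[1], " has fewer than 11 fields",
         call. = FALSE)
  }
  fld <- function(i) vapply(fields, `[[`, character(1), i)
  flag <- as.integer(fld(2))
  seq_ <- toupper(fld(10))
  cigar <- fld(6)
  tags <- lapply(fields, function(f) if (length(f) > 11) f[12:length(f)] else character(0))
  tag_value <- function(code) {
    vapply(tags, function(t) {
      hit <- t[startsWith(t, code)]
      if (length(hit) == 0) NA_character_ else sub("^[^:]+:[^:]:", "", hit[1])
    }, character(1))
  }
  unmapped <- bitwAnd(flag, 4L) != 0L
  xt <- tag_value("XT:")
  uniqueness <- dplyr::case_when(
    unmapped ~ "unmapped",
    xt == "U" ~ "unique",
    xt == "R" ~ "repeat",
    xt == "N" ~ "unmapped",
    TRUE ~ NA_character_
  )
  hits <- tibble(
    read_id = fld(1),
    flag = flag,
    reference_name = fld(3),
    position = ifelse(unmapped, NA_integer_, as.integer(fld(4))),
    mapq = as.integer(fld(5)),
    cigar = ifelse(cigar == "*", NA_character_, cigar),
    seq = ifelse(seq_ == "*", NA_character_, seq_),
    qual = ifelse(fld(11) == "*", NA_character_, fld(11)),
    strand = ifelse(bitwAnd(flag, 16L) != 0L, "reverse", "forward"),
    uniqueness = uniqueness,
    best_hits = suppressWarnings(as.integer(tag_value("X0:"))),
    alt_hits = suppressWarnings(as.integer(tag_value("X1:"))),
    nm = suppressWarnings(as.integer(tag_value("NM:"))),
    md = tag_value("MD:"),
    is_duplicate = bitwAnd(flag, 1024L) != 0L
  )
  bad <- which(!unmapped & !is.na(hits$cigar) & !is.na(hits$seq) &
                 cigar_read_length(hits$cigar) != nchar(hits$seq))
  if (length(bad) > 0) {
    stop("CIGAR/sequence length disagreement for read '",
         hits$read_id[bad[1]], "' (record ", bad[1], ")", call. = FALSE)
  }
  if (any(!unmapped & !is.na(hits$position) & hits$position < 1)) {
    stop("mapped record with position < 1", call. = FALSE)
  }
  attr(hits, "header") <- header
  hits
}

empty_hits <- function() {
  tibble(
    read_id = character(0), flag = integer(0), reference_name = character(0),
    position = integer(0), mapq = integer(0), cigar = character(0),
    seq = character(0), qual = character(0), strand = character(0),
    uniqueness = character(0), best_hits = integer(0), alt_hits = integer(0),
    nm = integer(0), md = character(0), is_duplicate = logical(0)
  )
}

#' @rdname read_sam
#' @param hits A hit table as returned by [read_sam()] (or built by the
#'   simulator). If `flag` is absent it is reconstructed from `strand`,
#'   `uniqueness` and `is_duplicate`.
#' @param header Character vector of header lines; defaults to the table's
#'   `"header"` attribute (a minimal `@HD` line if none).
#' @export
write_sam <- function(hits, path, header = NULL) {
  if (is.null(header)) header <- attr(hits, "header")
  if (is.null(header)) header <- "@HD\tVN:1.6\tSO:unsorted"
  n <- nrow(hits)
  flag <- if ("flag" %in% names(hits)) hits$flag else {
    as.integer(ifelse(hits$uniqueness == "unmapped", 4L, 0L)) +
      ifelse(hits$strand == "reverse", 16L, 0L) +
      ifelse(isTRUE_vec(hits$is_duplicate), 1024L, 0L)
  }
  opt <- function(code, type, v) {
    ifelse(is.na(v), "", paste0("\t", code, ":", type, ":", v))
  }
  xt <- dplyr::case_when(
    hits$uniqueness == "unique" ~ "U",
    hits$uniqueness == "repeat" ~ "R",
    hits$uniqueness == "unmapped" & bitwAnd(flag, 4L) == 0L ~ "N",
    TRUE ~ NA_character_
  )
  recs <- paste0(
    hits$read_id, "\t", flag, "\t",
    ifelse(is.na(hits$reference_name), "*", hits$reference_name), "\t",
    ifelse(is.na(hits$position), 0L, hits$position), "\t",
    hits$mapq, "\t",
    ifelse(is.na(hits$cigar), "*", hits$cigar), "\t*\t0\t0\t",
    ifelse(is.na(hits$seq), "*", hits$seq), "\t",
    ifelse(is.na(hits$qual), "*", hits$qual),
    opt("XT", "A", xt),
    opt("X0", "i", hits$best_hits),
    opt("X1", "i", hits$alt_hits),
    opt("NM", "i", hits$nm),
    opt("MD", "Z", hits$md)
  )
  writeLines(c(header, recs), path)
  invisible(path)
}

isTRUE_vec <- function(x) !is.na(x) & x
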