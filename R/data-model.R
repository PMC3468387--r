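#' Construct a read table
#'
#' Reads are represented as a tibble with one row per read: `read_id`,
#' `bases` (a string over A/C/G/T/N), `qual` (PHRED+33-encoded quality
#' string, or `NA` for platforms without base qualities, e.g. Helicos tSMS)
#' and `platform` (`"illumina"` or `"helicos"`).
#'
#' @param read_id Character vector of read identifiers.
#' @param bases Character vector of base strings.
#' @param qual Character vector of PHRED+33 quality strings, or `NA`.
#' @param platform `"illumina"` or `"helicos"` (recycled).
#'
#' @return A tibble with columns `read_id`, `bases`, `qual`, `platform`.
#' @export
#'
#' @examples
#' read_table("r1", "ACGT", "IIII")
read_table <- function(read_id, bases, qual = NA_character_,
                       platform = "illumina") {
  platform <- match_platform(platform)
  out <- tibble(
    read_id = as.character(read_id),
    bases = toupper(as.character(bases)),
    qual = as.character(qual),
    platform = platform
  )
  validate_reads(out)
  out
}

match_platform <- function(platform) {
  ok <- platform %in% c("illumina", "helicos")
  if (!all(ok)) {
    stop("unknown platform: ", paste(unique(platform[!ok]), collapse = ", "),
         call. = FALSE)
  }
  platform
}

validate_reads <- function(reads) {
  stopifnot(all(c("read_id", "bases", "qual", "platform") %in% names(reads)))
  has_q <- !is.na(reads$qual)
  bad <- which(has_q & nchar(reads$qual) != nchar(reads$bases))
  if (length(bad) > 0) {
    stop("quality string length differs from base string length for read(s): ",
         paste(reads$read_id[bad[seq_len(min(3, length(bad)))]], collapse = ", "),
         call. = FALSE)
  }
  invisible(reads)
}

#' Decode / encode PHRED+33 quality strings
#'
#' @param qual Character vector of PHRED+33 strings (may contain `NA`).
#' @return `phred_decode()`: a list of integer vectors (NULL elements for
#'   `NA` input). `phred_encode()`: a character vector.
#' @export
phred_decode <- function(qual) {
  lapply(qual, function(q) {
    if (is.na(q)) return(NULL)
    as.integer(utf8ToInt(q)) - 33L
  })
}

#' @rdname phred_decode
#' @param scores List of integer vectors of PHRED scores.
#' @export
phred_encode <- function(scores) {
  vapply(scores, function(s) {
    if (is.null(s)) return(NA_character_)
    intToUtf8(as.integer(s) + 33L)
  }, character(1))
}

## Complement in sequencing alphabet; IUPAC beyond N is not expected here.
complement_chr <- function(x) chartr("ACGTNacgtn", "TGCANtgcan", x)

revcomp_chr <- function(x) {
  vapply(x, function(s) {
    if (is.na(s)) return(NA_character_)
    intToUtf8(rev(utf8ToInt(complement_chr(s))))
  }, character(1), USE.NAMES = FALSE)
}

reverse_chr <- function(x) {
  vapply(x, function(s) {
    if (is.na(s)) return(NA_character_)
    intToUtf8(rev(utf8ToInt(s)))
  }, character(1), USE.NAMES = FALSE)
}

## Split a vector of strings into one character vector of single bases.
explode_chars <- function(x) {
  if (length(x) == 0) return(character(0))
  unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE)
}
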