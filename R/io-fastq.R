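#' Read and write FASTQ
#'
#' `read_fastq()` parses a (plain-text, 4-line-per-record) FASTQ file into a
#' read table. Records are returned in file order; qualities are kept in
#' their PHRED+33 encoding (decode with [phred_decode()]). A malformed
#' record raises an error naming the record index.
#'
#' @param path Path to a FASTQ file.
#' @param platform Platform label attached to every read
#'   (`"illumina"` or `"helicos"`).
#' @return A read table (see [read_table()]).
#' @export
read_fastq <- function(path, platform = "illumina") {
  platform <- match_platform(platform)
  lines <- readLines(path)
  if (length(lines) == 0) {
    return(read_table(character(0), character(0), character(0), character(0)))
  }
  if (length(lines) %% 4 != 0) {
    stop("truncated FASTQ record at record index ",
         length(lines) %/% 4 + 1, " in ", path, call. = FALSE)
  }
  n <- length(lines) / 4
  hdr <- lines[seq(1, length(lines), by = 4)]
  seq_ <- lines[seq(2, length(lines), by = 4)]
  plus <- lines[seq(3, length(lines), by = 4)]
  qual <- lines[seq(4, length(lines), by = 4)]

  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+"))
  if (length(bad) > 0) {
    stop("malformed FASTQ record at record index ", bad[1], " in ", path,
         call. = FALSE)
  }
  bad <- which(nchar(qual) != nchar(seq_))
  if (length(bad) > 0) {
    stop("quality/base length mismatch at record index ", bad[1], " in ", path,
         call. = FALSE)
  }
  ids <- sub("\\s.*$", "", substring(hdr, 2))
  read_table(ids, seq_, qual, platform)
}

#' @rdname read_fastq
#' @param reads A read table.
#' @details `write_fastq()` writes reads lacking base qualities (`qual` of
#'   `NA`) with a placeholder run of `"!"` (PHRED 0), the conventional
#'   stand-in for quality-free platforms.
#' @export
write_fastq <- function(reads, path) {
  validate_reads(reads)
  qual <- ifelse(is.na(reads$qual),
                 strrep("!", nchar(reads$bases)),
                 reads$qual)
  out <- character(4 * nrow(reads))
  out[seq(1, length(out), by = 4)] <- paste0("@", reads$read_id)
  out[seq(2, length(out), by = 4)] <- reads$bases
  out[seq(3, length(out), by = 4)] <- "+"
  out[seq(4, length(out), by = 4)] <- qual
  writeLines(out, path)
  invisible(path)
}

#' Read and write reference FASTA
#'
#' Thin wrappers over Biostrings returning/accepting a named character
#' vector of upper-case sequences, the in-memory reference representation
#' used throughout the package.
#'
#' @param path Path to a FASTA file.
#' @return `read_reference()`: a named character vector.
#' @export
read_reference <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' @rdname read_reference
#' @param reference Named character vector of sequences.
#' @export
write_reference <- function(reference, path) {
  x <- Biostrings::DNAStringSet(reference)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
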