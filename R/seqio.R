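#' Reverse complement of nucleotide strings
#'
#' Vectorized; accepts A, C, G, T, N (case-insensitive, returned uppercase).
#' N maps to N. An empty string returns an empty string.
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector of reverse complements.
#' @examples
#' revComp("AAGCTG")  # "CAGCTT"
#' @export
revComp <- function(x) {
  x <- toupper(x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad))
    stop("non-nucleotide character in sequence: ",
         substr(x[which(bad)[1]], 1, 40))
  cpp_revcomp(x)
}

# internal fast path, no validation (node sequences are clean ACGT)
.rc <- function(x) cpp_revcomp(x)

#' Quality-trim a single read
#'
#' Removes all positions including and to the right of the first position
#' whose quality score falls below \code{threshold}. Reads without qualities
#' (FASTA input) pass through unchanged.
#'
#' @param seq nucleotide string.
#' @param quals integer vector of Phred scores, same length as seq, or NULL.
#' @param threshold minimum acceptable quality (default 15).
#' @return list(seq, quals) after trimming.
#' @examples
#' trimRead("ACGTA", c(30L, 30L, 10L, 30L, 30L), 15L)$seq  # "AC"
#' @export
trimRead <- function(seq, quals = NULL, threshold = 15L) {
  if (is.null(quals)) return(list(seq = seq, quals = NULL))
  if (length(quals) != nchar(seq))
    stop("quals length (", length(quals), ") != seq length (", nchar(seq), ")")
  bad <- which(quals < threshold)
  if (length(bad)) {
    keep <- bad[1] - 1L
    seq <- substr(seq, 1L, keep)
    quals <- quals[seq_len(keep)]
  }
  list(seq = seq, quals = quals)
}

.phredToInt <- function(q) {
  if (nchar(q) == 0L) return(integer())
  utf8ToInt(q) - 33L
}

.intToPhred <- function(v) {
  if (length(v) == 0L) return("")
  intToUtf8(v + 33L)
}

#' Quality-trim a set of reads
#'
#' Applies [trimRead] to every record of a read table (as returned by
#' [readFastq] or [simulateReads]).
#'
#' @param reads data.frame with columns id, seq, qual (Phred+33 string).
#' @param threshold minimum acceptable quality (default 15).
#' @return data.frame of the same shape with trimmed seq and qual.
#' @export
trimReads <- function(reads, threshold = 15L) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  n <- nrow(reads)
  if (n == 0L) return(reads)
  keep <- vapply(reads$qual, function(q) {
    v <- .phredToInt(q)
    bad <- which(v < threshold)
    if (length(bad)) bad[1] - 1L else length(v)
  }, integer(1), USE.NAMES = FALSE)
  reads$seq <- substr(reads$seq, 1L, keep)
  reads$qual <- substr(reads$qual, 1L, keep)
  reads
}

#' Read a FASTA file
#'
#' Handles wrapped or unwrapped records. The alphabet is not validated here;
#' use the result with [transcriptDb] which encodes per mode.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
readFasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(x))
  # keep only the first whitespace-delimited token of each header
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @param width line-wrap width (default 70).
#' @return invisibly, the path.
#' @export
writeFasta <- function(seqs, path, width = 70L) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read a FASTQ file (4-line records, Phred+33)
#'
#' @param path FASTQ file.
#' @return data.frame with columns id, seq, qual (Phred+33 string).
#' @export
readFastq <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(ln) | seq_along(ln) %% 4L != 0L]  # tolerate trailing blank
  if (length(ln) %% 4L != 0L)
    stop("malformed FASTQ: ", path, " has ", length(ln),
         " lines (not a multiple of 4)")
  idx <- seq(1L, length(ln), by = 4L)
  hdr <- ln[idx]
  seq <- ln[idx + 1L]
  plus <- ln[idx + 2L]
  qual <- ln[idx + 3L]
  badh <- which(!startsWith(hdr, "@"))
  if (length(badh))
    stop("malformed FASTQ record at line ", idx[badh[1]], ": header must start with '@'")
  badp <- which(!startsWith(plus, "+"))
  if (length(badp))
    stop("malformed FASTQ record at line ", idx[badp[1]] + 2L,
         ": separator must start with '+'")
  badl <- which(nchar(seq) != nchar(qual))
  if (length(badl))
    stop("malformed FASTQ record at line ", idx[badl[1]] + 1L,
         ": sequence and quality lengths differ")
  data.frame(
    id = sub("\\s.*$", "", substring(hdr, 2L)),
    seq = toupper(seq),
    qual = qual,
    stringsAsFactors = FALSE
  )
}

#' Write reads to FASTQ (Phred+33)
#'
#' @param reads data.frame with columns id, seq, qual.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeFastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  out <- character(4L * nrow(reads))
  out[seq(1L, length.out = nrow(reads), by = 4L)] <- paste0("@", reads$id)
  out[seq(2L, length.out = nrow(reads), by = 4L)] <- reads$seq
  out[seq(3L, length.out = nrow(reads), by = 4L)] <- "+"
  out[seq(4L, length.out = nrow(reads), by = 4L)] <- reads$qual
  writeLines(out, path)
  invisible(path)
}
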