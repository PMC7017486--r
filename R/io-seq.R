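#' Read a FASTA file into a named character vector
#'
#' @param path Path to a (plain-text) FASTA file.
#' @return Named character vector, one element per record.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path Path to a plain-text FASTQ file.
#' @return List with character vectors `name`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) {
    stop_graphsv("truncated FASTQ: ", path, " has ", length(lines), " lines")
  }
  idx <- seq(1L, length(lines), by = 4L)
  list(
    name = sub("^@", "", sub("\\s.*$", "", lines[idx])),
    seq = toupper(lines[idx + 1L]),
    qual = lines[idx + 3L]
  )
}

#' Write paired reads to FASTQ
#'
#' @param reads List with `name`, `seq`, `qual` character vectors.
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  n <- length(reads$seq)
  out <- character(4L * n)
  out[seq(1L, 4L * n, by = 4L)] <- paste0("@", reads$name)
  out[seq(2L, 4L * n, by = 4L)] <- reads$seq
  out[seq(3L, 4L * n, by = 4L)] <- "+"
  out[seq(4L, 4L * n, by = 4L)] <- reads$qual
  writeLines(out, path)
  invisible(path)
}
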