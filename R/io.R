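# Sequence file IO. Format detection and parsing go through Biostrings;
# gzip is handled transparently ('.gz' paths are opened through a
# decompressing connection for sniffing, and by Biostrings on read).

# first non-blank character decides the format: '>' FASTA, '@' FASTQ
detect_seq_format <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  repeat {
    ln <- readLines(con, n = 1L, warn = FALSE)
    if (length(ln) == 0L)
      stop("cannot detect format of '", path, "': file is empty", call. = FALSE)
    ln <- trimws(ln)
    if (ln != "") break
  }
  ch <- substr(ln, 1L, 1L)
  if (ch == ">") return("fasta")
  if (ch == "@") return("fastq")
  stop("cannot detect format of '", path, "': first record starts with '",
       ch, "', expected '>' or '@'", call. = FALSE)
}

#' Read sequences from a FASTA or FASTQ file
#'
#' The format is auto-detected per file from the first non-blank character;
#' gzip-compressed files are decompressed transparently. Multi-line FASTA is
#' accepted and FASTQ `+` separator lines may or may not repeat the record
#' id.
#'
#' @param path path to a FASTA or FASTQ file, optionally gzipped.
#' @return character vector of uppercase sequences, named by record id.
#' @export
read_sequences <- function(path) {
  if (!file.exists(path)) stop("sequence file not found: ", path, call. = FALSE)
  fmt <- detect_seq_format(path)
  set <- tryCatch(
    Biostrings::readDNAStringSet(path, format = fmt),
    error = function(e) stop("failed to parse '", path, "' as ", toupper(fmt),
                             ": ", conditionMessage(e), call. = FALSE))
  out <- toupper(as.character(set))
  names(out) <- names(set)
  out
}

#' Write sequences to FASTA
#'
#' @param seqs character vector of sequences; names become record ids
#'   (unnamed vectors get 0-based integer ids).
#' @param path output path; a `.gz` suffix enables compression.
#' @return number of records written, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  ids <- names(seqs)
  if (is.null(ids)) ids <- as.character(seq_along(seqs) - 1L)
  set <- Biostrings::DNAStringSet(unname(seqs))
  names(set) <- ids
  Biostrings::writeXStringSet(set, path, compress = endsWith(path, ".gz"))
  invisible(length(seqs))
}

# write a reads tibble (id, seq, qual) as FASTQ, gzipped when path ends .gz
write_fastq <- function(reads, path) {
  set <- Biostrings::DNAStringSet(reads$seq)
  names(set) <- reads$id
  qual <- Biostrings::BStringSet(reads$qual)
  Biostrings::writeXStringSet(set, path, format = "fastq", qualities = qual,
                              compress = endsWith(path, ".gz"))
  invisible(nrow(reads))
}
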