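new_kmer_matrix <- function(tbl, k) {
  attr(tbl, "k") <- as.integer(k)
  class(tbl) <- c("kmer_matrix", class(tibble()))
  tbl
}

#' @export
print.kmer_matrix <- function(x, ...) {
  cat(sprintf("# k-mer matrix: %d k-mers (k = %d) x %d samples\n",
              nrow(x), attr(x, "k"), ncol(x) - 1L))
  NextMethod()
}

#' Size parameters of a k-mer matrix
#'
#' @param x a `kmer_matrix` tibble.
#' @return `kmer_size()` the k-mer length; `sample_ids()` the ordered sample
#'   identifiers (matrix column order).
#' @export
kmer_size <- function(x) attr(x, "k")

#' @rdname kmer_size
#' @export
sample_ids <- function(x) setdiff(names(x), "kmer")

#' Count canonical k-mers in a set of sequences
#'
#' Every length-`k` window of every sequence inside a maximal A/C/G/T run is
#' canonicalized and tallied. Counts below `min_abundance` are dropped: a
#' k-mer seen fewer times than the floor is treated as absent, which removes
#' most singleton sequencing errors before any matrix is built.
#'
#' @param seqs character vector of DNA sequences (reads or genomes).
#' @param k k-mer size (odd, 3--31).
#' @param min_abundance minimum count for a k-mer to be reported (default 1
#'   here; the per-sample counter [count_sample()] defaults to 2).
#' @return tibble with columns `kmer` (canonical string) and `count`
#'   (integer), sorted by ascending k-mer code (equivalently, lexicographic
#'   order).
#' @examples
#' count_kmers("ACGACG", k = 3)
#' @export
count_kmers <- function(seqs, k, min_abundance = 1) {
  k <- check_odd_k(k)
  stopifnot(min_abundance >= 1)
  res <- cpp_count_kmers(as.character(seqs), k)
  tbl <- tibble(kmer = res$kmer, count = as.integer(res$count))
  tbl[tbl$count >= min_abundance, ]
}

#' Count the canonical k-mers of one sample
#'
#' Reads all of a sample's FASTA/FASTQ files (plain or gzipped, auto-detected
#' per file) and tallies canonical k-mers across every record. Counts below
#' `min_abundance` are zeroed and dropped at counting time, so a sub-floor
#' k-mer is absent from the sample for all downstream purposes.
#'
#' @param files character vector of sequence file paths.
#' @param k k-mer size (odd, 3--31).
#' @param min_abundance abundance floor (default 2: singletons are treated
#'   as sequencing errors; set to 1 to keep everything).
#' @return tibble with columns `kmer`, `count`, sorted by k-mer.
#' @export
count_sample <- function(files, k, min_abundance = 2) {
  k <- check_odd_k(k)
  seqs <- unlist(lapply(files, read_sequences), use.names = FALSE)
  tbl <- count_kmers(seqs, k, min_abundance = min_abundance)
  if (nrow(tbl) == 0L)
    warning("sample yielded no k-mers above the abundance floor (files: ",
            paste(basename(files), collapse = ", "), ")", call. = FALSE)
  tbl
}

#' Merge per-sample k-mer count tables into a k-mer matrix
#'
#' The matrix is the union of all k-mers seen in any sample, sorted by
#' ascending canonical code; each cell holds that sample's count, or 0 where
#' the sample lacks the k-mer. All-zero rows are impossible by construction.
#'
#' @param tables list of per-sample count tibbles (columns `kmer`, `count`),
#'   as returned by [count_sample()], all with the same `k`.
#' @param sample_ids character vector of sample names, one per table, in
#'   column order.
#' @param k k-mer size shared by all tables.
#' @return a `kmer_matrix`: a tibble with column `kmer` followed by one
#'   integer count column per sample.
#' @export
merge_tables <- function(tables, sample_ids, k) {
  k <- check_odd_k(k)
  stopifnot(length(tables) == length(sample_ids), length(tables) >= 1L)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids", call. = FALSE)
  for (t in tables) {
    if (nrow(t) > 0L && any(nchar(t$kmer) != k))
      stop("mixed k across count tables", call. = FALSE)
  }
  keys <- sort(unique(unlist(lapply(tables, `[[`, "kmer"), use.names = FALSE)))
  out <- tibble(kmer = keys)
  for (j in seq_along(tables)) {
    v <- integer(length(keys))
    m <- match(tables[[j]]$kmer, keys)
    v[m] <- tables[[j]]$count
    out[[sample_ids[j]]] <- v
  }
  new_kmer_matrix(out, k)
}

#' Build the multi-sample k-mer abundance matrix
#'
#' Counts each sample independently (optionally in parallel across samples)
#' and merges the per-sample tables with [merge_tables()]. Sample order in
#' the manifest defines matrix column order.
#'
#' @param fof a manifest tibble from [read_fof()], or a path to a
#'   file-of-files.
#' @param k k-mer size (odd, 3--31; the pipeline default is 31).
#' @param min_abundance per-sample abundance floor (default 2).
#' @param threads number of samples counted concurrently (forked processes;
#'   results are merged in manifest order, so the output is identical for
#'   any thread count).
#' @return a `kmer_matrix` tibble.
#' @export
kmer_count_matrix <- function(fof, k = 31, min_abundance = 2, threads = 1) {
  k <- check_odd_k(k)
  if (is.character(fof)) fof <- read_fof(fof)
  stopifnot(nrow(fof) >= 1L)
  counter <- function(i) count_sample(fof$files[[i]], k, min_abundance)
  idx <- seq_len(nrow(fof))
  tables <- if (threads > 1L) {
    parallel::mclapply(idx, counter, mc.cores = threads)
  } else {
    lapply(idx, counter)
  }
  err <- vapply(tables, inherits, logical(1), "try-error")
  if (any(err)) stop("counting failed for sample ", fof$sample_id[which(err)[1]],
                     call. = FALSE)
  merge_tables(tables, fof$sample_id, k)
}

#' Read and write k-mer matrices in text format
#'
#' One row per k-mer: the canonical k-mer string followed by one count per
#' sample, single-space separated. An optional header line
#' `#kmer <s1> ... <sn>` carries the sample names; without it, samples are
#' named `s1 ... sn` on read. A `.gz` suffix compresses/decompresses
#' transparently. `read_kmer_matrix()` validates every line: wrong-length or
#' non-canonical k-mer strings, ragged rows and negative counts are rejected
#' with their line number.
#'
#' @param x a `kmer_matrix` tibble.
#' @param path file path (`.gz` for gzip).
#' @param header write/expect the `#kmer ...` header line (default `FALSE`,
#'   auto-detected on read).
#' @param k expected k-mer size on read.
#' @return `write_kmer_matrix()` returns `path` invisibly;
#'   `read_kmer_matrix()` returns a `kmer_matrix` tibble.
#' @export
write_kmer_matrix <- function(x, path, header = FALSE) {
  con <- if (endsWith(path, ".gz")) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  if (header)
    writeLines(paste(c("#kmer", sample_ids(x)), collapse = " "), con)
  if (nrow(x) > 0L) {
    counts <- as.matrix(x[setdiff(names(x), "kmer")])
    writeLines(paste(x$kmer, apply(counts, 1L, paste, collapse = " ")), con)
  }
  invisible(path)
}

#' @rdname write_kmer_matrix
#' @export
read_kmer_matrix <- function(path, k) {
  k <- check_odd_k(k)
  if (!file.exists(path)) stop("matrix file not found: ", path, call. = FALSE)
  lines <- readLines(gzfile(path), warn = FALSE)
  ids <- NULL
  start <- 1L
  if (length(lines) > 0L && startsWith(lines[1], "#")) {
    hdr <- strsplit(trimws(sub("^#", "", lines[1])), " ", fixed = TRUE)[[1]]
    ids <- hdr[-1]
    start <- 2L
  }
  body <- if (start > length(lines)) character(0) else lines[start:length(lines)]
  body <- body[trimws(body) != ""]
  if (length(body) == 0L) {
    out <- tibble(kmer = character(0))
    for (s in (ids %||% character(0))) out[[s]] <- integer(0)
    return(new_kmer_matrix(out, k))
  }
  parts <- strsplit(body, " ", fixed = TRUE)
  ncols <- lengths(parts)
  if (length(unique(ncols)) != 1L) {
    bad <- which(ncols != ncols[1])[1]
    stop(sprintf("line %d: ragged row (%d fields, expected %d)",
                 bad + start - 1L, ncols[bad], ncols[1]), call. = FALSE)
  }
  n_samp <- ncols[1] - 1L
  if (n_samp < 1L) stop("matrix has no sample columns", call. = FALSE)
  kmers <- vapply(parts, `[[`, character(1), 1L)
  badlen <- which(nchar(kmers) != k)
  if (length(badlen) > 0L)
    stop(sprintf("line %d: k-mer '%s' has length %d, expected %d",
                 badlen[1] + start - 1L, kmers[badlen[1]],
                 nchar(kmers[badlen[1]]), k), call. = FALSE)
  canon <- cpp_canonical(kmers, k)
  if (any(canon != kmers)) {
    bad <- which(canon != kmers)[1]
    stop(sprintf("line %d: k-mer '%s' is not canonical", bad + start - 1L,
                 kmers[bad]), call. = FALSE)
  }
  counts <- matrix(0L, nrow = length(parts), ncol = n_samp)
  for (j in seq_len(n_samp)) {
    v <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), j + 1L)))
    if (anyNA(v) || any(v < 0) || any(v != floor(v))) {
      bad <- which(is.na(v) | v < 0 | v != floor(v))[1]
      stop(sprintf("line %d: invalid count in sample column %d",
                   bad + start - 1L, j), call. = FALSE)
    }
    counts[, j] <- as.integer(v)
  }
  if (is.null(ids)) ids <- paste0("s", seq_len(n_samp))
  if (length(ids) != n_samp)
    stop("header names ", length(ids), " samples but rows have ", n_samp,
         " count columns", call. = FALSE)
  out <- tibble(kmer = kmers)
  for (j in seq_len(n_samp)) out[[ids[j]]] <- counts[, j]
  new_kmer_matrix(out, k)
}

#' Dump the k-mers of a matrix to FASTA
#'
#' One record per matrix row, in row order, headed by the 0-based row index;
#' the sequence is the canonical k-mer string. This is the hand-off format
#' between the filtered matrix and unitig construction.
#'
#' @param x a `kmer_matrix` tibble.
#' @param path output FASTA path.
#' @return the number of records written.
#' @export
kmer_matrix_fasta <- function(x, path) {
  seqs <- x$kmer
  names(seqs) <- as.character(seq_along(seqs) - 1L)
  if (length(seqs) == 0L) {
    file.create(path)
    return(0L)
  }
  write_fasta(seqs, path)
  length(seqs)
}

#' @export
glance.kmer_matrix <- function(x, ...) {
  counts <- as.matrix(x[setdiff(names(x), "kmer")])
  tibble(n_kmers = nrow(x), n_samples = ncol(counts), k = kmer_size(x),
         density = if (nrow(x) == 0L) NA_real_ else mean(counts > 0),
         total_count = sum(counts))
}

#' @export
tidy.kmer_matrix <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x), -"kmer", names_to = "sample_id",
                      values_to = "count")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
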