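new_unitig_set <- function(sequences, k, dropped_kmers = character(0)) {
  tbl <- tibble(id = seq_along(sequences) - 1L,
                sequence = sequences,
                length = nchar(sequences),
                n_kmers = nchar(sequences) - as.integer(k) + 1L)
  attr(tbl, "k") <- as.integer(k)
  attr(tbl, "dropped_kmers") <- dropped_kmers
  class(tbl) <- c("unitig_set", class(tibble()))
  tbl
}

#' @export
print.unitig_set <- function(x, ...) {
  cat(sprintf("# unitig set: %d unitigs (k = %d), %d k-mers\n",
              nrow(x), attr(x, "k"), sum(x$n_kmers)))
  NextMethod()
}

#' Forward neighbors of an oriented k-mer in the bidirected de Bruijn graph
#'
#' For the oriented sequence w of `node` (its canonical string when
#' `orientation` is `"+"`, its reverse complement when `"-"`), returns every
#' member of the k-mer set whose oriented string equals `w[2:k]` plus one
#' appended base, with the orientation that realizes it, sorted by appended
#' base. Edges from a node to itself (homopolymer loops and hairpins into
#' the node's own reverse complement) are artifacts of canonical
#' identification and are not reported. At most four neighbors exist.
#'
#' @param members character vector of canonical k-mers (the graph's nodes).
#' @param node a canonical member k-mer.
#' @param orientation `"+"` or `"-"`.
#' @param k k-mer size; defaults to the node length.
#' @return tibble with columns `kmer` (canonical neighbor) and
#'   `orientation`.
#' @examples
#' forward_neighbors(c("ACC", "ACG", "CCG"), "ACG", "+")  # CCG on strand "-"
#' @export
forward_neighbors <- function(members, node, orientation = "+", k = nchar(node)) {
  k <- check_odd_k(k)
  stopifnot(orientation %in% c("+", "-"))
  res <- cpp_forward_neighbors(as.character(members), node, orientation, k)
  tibble(kmer = res$kmer, orientation = res$orientation)
}

#' Compact a canonical k-mer set into maximal unitigs
#'
#' Builds the bidirected de Bruijn graph whose nodes are the canonical
#' k-mers and whose edges are their (k-1)-base prefix-suffix overlaps, and
#' spells every maximal non-branching path as a single sequence. Adjacency
#' is computed by membership queries on the four possible one-base
#' extensions of each oriented k-mer, never stored, so memory is
#' proportional to the k-mer set.
#'
#' The construction is deterministic: k-mers are visited in ascending
#' canonical code order; a path is extended from oriented node x to y only
#' when y is x's unique forward neighbor and x is y's unique backward
#' neighbor (the mutual-uniqueness rule -- anything weaker would merge
#' across branches and break the k-mer-to-unitig bijection downstream).
#' Isolated simple cycles are linearized starting at their smallest
#' canonical code, so a cycle of m nodes yields one unitig of length
#' m + k - 1. Each unitig is reported in its canonical orientation (the
#' lexicographically smaller of the sequence and its reverse complement;
#' odd k makes a tie impossible) and unitigs are sorted by sequence, with
#' ids 0..m-1 assigned in that order. Every input k-mer ends up in exactly
#' one unitig.
#'
#' @param kmers character vector of canonical k-mers (e.g. the `kmer` column
#'   of a filtered [kmer_count_matrix()]), or a `kmer_matrix` tibble.
#' @param k k-mer size (odd, 3--31); defaults to the matrix's k when `kmers`
#'   is a `kmer_matrix`.
#' @return a `unitig_set`: a tibble with columns `id` (0-based), `sequence`,
#'   `length` and `n_kmers` (= length - k + 1).
#' @examples
#' build_unitigs(c("ACC", "ACG", "CCG"), k = 3)  # one unitig "ACCGT"
#' @export
build_unitigs <- function(kmers, k = NULL) {
  if (inherits(kmers, "kmer_matrix")) {
    k <- k %||% kmer_size(kmers)
    kmers <- kmers$kmer
  }
  if (is.null(k)) k <- nchar(kmers[1])
  k <- check_odd_k(k)
  seqs <- cpp_build_unitigs(as.character(kmers), k)
  new_unitig_set(seqs, k)
}

#' Drop unitigs below a minimum length
#'
#' Unitigs shorter than `min_length` (default 2k-1, i.e. at least k k-mers)
#' are discarded. Survivors keep their sort order and are re-assigned dense
#' ids 0..m'-1. The canonical k-mers of discarded unitigs are recorded in
#' the `dropped_kmers` attribute so downstream stages can drop their matrix
#' rows.
#'
#' @param x a `unitig_set`.
#' @param min_length minimum sequence length in base pairs; must be >= k.
#'   Default `2 * k - 1`.
#' @return the filtered `unitig_set`.
#' @export
filter_unitigs <- function(x, min_length = NULL) {
  k <- attr(x, "k")
  min_length <- min_length %||% (2L * k - 1L)
  if (min_length < k)
    stop("min_length (", min_length, ") must be at least k (", k, ")",
         call. = FALSE)
  drop <- x$length < min_length
  dropped_kmers <- if (any(drop)) {
    w <- cpp_unitig_windows(x$sequence[drop], k)
    unique(w$kmer)
  } else character(0)
  new_unitig_set(sort(x$sequence[!drop]), k, dropped_kmers = dropped_kmers)
}

#' Unitig FASTA input and output
#'
#' Each record's header is the unitig id (its row index in the unitig
#' matrix); record order defines the ids on read. Reading rejects duplicate
#' headers and sequences shorter than k.
#'
#' @param x a `unitig_set`.
#' @param path FASTA path (`.gz` accepted).
#' @param k k-mer size the set was built with.
#' @return `write_unitig_fasta()` returns `path` invisibly;
#'   `read_unitig_fasta()` returns a `unitig_set`.
#' @export
write_unitig_fasta <- function(x, path) {
  seqs <- x$sequence
  names(seqs) <- as.character(x$id)
  if (length(seqs) == 0L) file.create(path) else write_fasta(seqs, path)
  invisible(path)
}

#' @rdname write_unitig_fasta
#' @export
read_unitig_fasta <- function(path, k) {
  k <- check_odd_k(k)
  if (file.size(path) == 0L) return(new_unitig_set(character(0), k))
  seqs <- read_sequences(path)
  ids <- names(seqs)
  if (anyDuplicated(ids))
    stop("duplicate FASTA header '", ids[duplicated(ids)][1], "'", call. = FALSE)
  short <- which(nchar(seqs) < k)
  if (length(short) > 0L)
    stop("record ", short[1], " is shorter than k = ", k, call. = FALSE)
  new_unitig_set(unname(seqs), k)
}

#' @export
glance.unitig_set <- function(x, ...) {
  tibble(n_unitigs = nrow(x), k = attr(x, "k"),
         total_kmers = sum(x$n_kmers),
         mean_length = if (nrow(x) == 0L) NA_real_ else mean(x$length),
         max_length = if (nrow(x) == 0L) NA_integer_ else max(x$length))
}

#' Unitig length distribution plot
#'
#' @param object a `unitig_set`.
#' @param ... unused.
#' @return a ggplot histogram of unitig lengths.
#' @export
autoplot.unitig_set <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$length)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "grey20") +
    ggplot2::labs(x = "unitig length (bp)", y = "unitigs",
                  title = sprintf("Unitig lengths (k = %d)", attr(object, "k"))) +
    ggplot2::theme_minimal()
}
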