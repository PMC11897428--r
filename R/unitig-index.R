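#' Exact k-mer to unitig dictionary
#'
#' Maps every canonical k-mer of a unitig set to its unique location: the
#' unitig id, the 0-based window offset, and the strand on which the window
#' matches its canonical form (`+`) or its reverse complement (`-`).
#' Implemented as an exact table over the canonical k-mer strings; the
#' lookup never returns a false positive. Building verifies the no-duplicate
#' invariant of the unitig set and fails naming both locations when a k-mer
#' occurs twice.
#'
#' @param x a `unitig_set`.
#' @return a `unitig_index`: a tibble with columns `kmer`, `unitig_id`,
#'   `offset`, `strand`, carrying the per-unitig k-mer totals in the
#'   `n_kmers` attribute (named integer vector indexed by unitig id).
#' @examples
#' u <- build_unitigs(c("ACC", "ACG", "CCG"), k = 3)
#' unitig_index(u)
#' @export
unitig_index <- function(x) {
  k <- attr(x, "k")
  if (nrow(x) == 0L) {
    idx <- tibble(kmer = character(0), unitig_id = integer(0),
                  offset = integer(0), strand = character(0))
    attr(idx, "k") <- k
    attr(idx, "n_kmers") <- integer(0)
    class(idx) <- c("unitig_index", class(tibble()))
    return(idx)
  }
  w <- cpp_unitig_windows(x$sequence, k)
  idx <- tibble(kmer = w$kmer, unitig_id = x$id[w$unitig_id + 1L],
                offset = w$offset, strand = w$strand)
  dup <- which(duplicated(idx$kmer))
  if (length(dup) > 0L) {
    d <- idx$kmer[dup[1]]
    at <- idx[idx$kmer == d, ]
    stop(sprintf(
      "k-mer '%s' occurs twice: unitig %d offset %d and unitig %d offset %d",
      d, at$unitig_id[1], at$offset[1], at$unitig_id[2], at$offset[2]),
      call. = FALSE)
  }
  n_kmers <- stats::setNames(x$n_kmers, as.character(x$id))
  attr(idx, "k") <- k
  attr(idx, "n_kmers") <- n_kmers
  class(idx) <- c("unitig_index", class(tibble()))
  idx
}

#' @export
print.unitig_index <- function(x, ...) {
  cat(sprintf("# unitig index: %d k-mers over %d unitigs (k = %d)\n",
              nrow(x), length(attr(x, "n_kmers")), attr(x, "k")))
  NextMethod()
}

#' Look up canonical k-mers in a unitig index
#'
#' @param index a `unitig_index`.
#' @param kmers character vector of canonical k-mers to query. Non-canonical
#'   queries are rejected (canonicalize first with [kmer_canonical()]).
#' @return a tibble with one row per query: `kmer`, `unitig_id`, `offset`,
#'   `strand`; the last three are `NA` for k-mers absent from every unitig.
#' @export
lookup_kmers <- function(index, kmers) {
  k <- attr(index, "k")
  if (length(kmers) > 0L) {
    canon <- cpp_canonical(as.character(kmers), k)
    if (any(canon != kmers))
      stop("query k-mer '", kmers[canon != kmers][1], "' is not canonical",
           call. = FALSE)
  }
  m <- match(kmers, index$kmer)
  tibble(kmer = as.character(kmers),
         unitig_id = index$unitig_id[m],
         offset = index$offset[m],
         strand = index$strand[m])
}
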