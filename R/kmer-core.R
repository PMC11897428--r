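#' Encode and decode k-mers as 2-bit integer codes
#'
#' A k-mer over \{A,C,G,T\} maps to a non-negative integer with two bits per
#' base (A=0, C=1, G=2, T=3), the first base in the highest-order bit pair.
#' Codes are returned as R numerics, which represent integers exactly only up
#' to 2^53; `k` is therefore limited to 26 here. The pipeline itself carries
#' k-mers as canonical strings at the R boundary (and as 64-bit words
#' internally), so all other functions accept the full odd range 3--31.
#'
#' @param kmers character vector of k-mer strings (lowercase accepted).
#' @param codes numeric vector of integer codes in `[0, 4^k)`.
#' @param k k-mer size; odd, between 3 and 25 for the code representation.
#' @return `kmer_encode()` a numeric vector of codes; `kmer_decode()` a
#'   character vector of uppercase k-mer strings.
#' @examples
#' kmer_encode(c("AAA", "ACG", "TTT"), k = 3)
#' kmer_decode(c(0, 6, 63), k = 3)
#' @export
kmer_encode <- function(kmers, k = nchar(kmers[1])) {
  k <- check_odd_k(k)
  cpp_encode(as.character(kmers), k)
}

#' @rdname kmer_encode
#' @export
kmer_decode <- function(codes, k) {
  k <- check_odd_k(k)
  cpp_decode(as.numeric(codes), k)
}

#' Reverse complement of DNA sequences
#'
#' Accepts strings of any length over A, C, G, T and N (case-insensitive);
#' the result is uppercase.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @examples
#' kmer_revcomp("ACG")   # "CGT"
#' @export
kmer_revcomp <- function(x) {
  cpp_revcomp_seq(as.character(x))
}

#' Canonical form of k-mers
#'
#' The canonical form of a k-mer is the lexicographically smaller of the
#' k-mer and its reverse complement under A<C<G<T (equivalently the numeric
#' minimum of their 2-bit codes). Both strands of a sequence then contribute
#' the same canonical k-mers, so forward and reverse reads count identically.
#' Odd k forbids self-reverse-complement palindromes, so the minimum is
#' always strict.
#'
#' @param kmers character vector of k-mer strings.
#' @param k k-mer size (odd, 3--31); defaults to the length of the first
#'   element.
#' @return character vector of canonical uppercase k-mers.
#' @examples
#' kmer_canonical(c("ACG", "TTT"))  # "ACG", "AAA"
#' @export
kmer_canonical <- function(kmers, k = nchar(kmers[1])) {
  k <- check_odd_k(k)
  cpp_canonical(as.character(kmers), k)
}

#' Extract the canonical k-mers of a sequence
#'
#' Slides a window of size `k` over `sequence` and returns the canonical
#' form of every window that lies entirely within a maximal run of
#' A/C/G/T characters, in left-to-right order. Windows spanning an N or any
#' other non-ACGT character are skipped, so ambiguous bases never fabricate
#' k-mers. Sequences shorter than `k` yield an empty vector. The extraction
#' is rolling: each successive window costs constant work.
#'
#' @param sequence a single DNA string (any characters allowed).
#' @param k k-mer size (odd, 3--31).
#' @return character vector of canonical k-mers, one per retained window.
#' @examples
#' kmer_windows("ACGTNACG", 3)  # "ACG" "ACG" "ACG"
#' @export
kmer_windows <- function(sequence, k) {
  k <- check_odd_k(k)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  cpp_iterate_kmers(sequence, k)
}
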