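#' Resolve a presence/absence threshold to a sample count
#'
#' Thresholds may be given as a fraction of the samples or as an absolute
#' number. A fraction `f` resolves to `ceiling(f * n_samples)`, floored at 1:
#' "at least 10% of the samples" is read conservatively, never rounding a
#' strict requirement down, and a tiny cohort never yields a vacuous
#' threshold.
#'
#' @param value a fraction in (0, 1] (when `absolute = FALSE`) or a positive
#'   integer count.
#' @param n_samples number of samples in the matrix.
#' @param absolute interpret `value` as an absolute count.
#' @return a positive integer threshold.
#' @examples
#' resolve_threshold(0.1, 20)  # 2
#' resolve_threshold(0.1, 15)  # 2  (ceiling of 1.5)
#' resolve_threshold(3, 10, absolute = TRUE)
#' @export
resolve_threshold <- function(value, n_samples, absolute = FALSE) {
  stopifnot(n_samples >= 1)
  if (absolute) {
    if (value < 1 || value != floor(value))
      stop("absolute threshold must be a positive integer", call. = FALSE)
    t <- as.integer(value)
  } else {
    if (value <= 0 || value > 1)
      stop("fractional threshold must lie in (0, 1]", call. = FALSE)
    t <- max(1L, as.integer(ceiling(value * n_samples)))
  }
  if (t > n_samples)
    stop("threshold ", t, " exceeds the number of samples (", n_samples, ")",
         call. = FALSE)
  t
}

#' Filter a k-mer matrix for discriminative k-mers
#'
#' Keeps the k-mers that can distinguish samples: present (count > 0) in at
#' least `min_present` of the samples AND absent (count == 0) in at least
#' `min_absent` of them. By default both thresholds are 10% of the samples.
#' Either side may instead be given as an absolute sample count via
#' `abs_present` / `abs_absent`. Row and column order and all counts are
#' preserved; the filter only drops rows.
#'
#' The two resolved thresholds must satisfy
#' `t_present + t_absent <= n_samples`; otherwise no row can ever pass and
#' the specification is rejected up front.
#'
#' @param x a `kmer_matrix` tibble.
#' @param min_present,min_absent fractional thresholds in (0, 1]
#'   (defaults 0.1 and 0.1). Ignored when the corresponding absolute
#'   threshold is given.
#' @param abs_present,abs_absent optional absolute thresholds (positive
#'   integers); each side accepts either the fraction or the absolute form,
#'   not both.
#' @return the filtered `kmer_matrix`.
#' @examples
#' m <- merge_tables(list(tibble::tibble(kmer = c("AAA", "ACG"), count = c(1L, 2L)),
#'                        tibble::tibble(kmer = "ACG", count = 1L)),
#'                   c("a", "b"), k = 3)
#' filter_kmer_matrix(m, abs_present = 1, abs_absent = 1)
#' @export
filter_kmer_matrix <- function(x, min_present = 0.1, min_absent = 0.1,
                               abs_present = NULL, abs_absent = NULL) {
  n <- length(sample_ids(x))
  t_present <- if (!is.null(abs_present)) {
    resolve_threshold(abs_present, n, absolute = TRUE)
  } else resolve_threshold(min_present, n)
  t_absent <- if (!is.null(abs_absent)) {
    resolve_threshold(abs_absent, n, absolute = TRUE)
  } else resolve_threshold(min_absent, n)
  if (t_present + t_absent > n)
    stop("unsatisfiable filter: t_present (", t_present, ") + t_absent (",
         t_absent, ") > n_samples (", n, ")", call. = FALSE)
  if (nrow(x) == 0L) return(x)
  counts <- as.matrix(x[setdiff(names(x), "kmer")])
  nz <- rowSums(counts > 0)
  keep <- nz >= t_present & (n - nz) >= t_absent
  new_kmer_matrix(as_tibble(x)[keep, ], kmer_size(x))
}
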