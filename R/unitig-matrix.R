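new_unitig_matrix <- function(tbl, k, n_kmers, sample_ids, n_skipped = 0L) {
  attr(tbl, "k") <- as.integer(k)
  attr(tbl, "n_kmers") <- n_kmers
  attr(tbl, "sample_ids") <- sample_ids
  attr(tbl, "n_skipped") <- as.integer(n_skipped)
  class(tbl) <- c("unitig_matrix", class(tibble()))
  tbl
}

#' @export
print.unitig_matrix <- function(x, ...) {
  cat(sprintf("# unitig matrix: %d unitigs x %d samples (k = %d)\n",
              length(unique(x$unitig_id)), length(attr(x, "sample_ids")),
              attr(x, "k")))
  NextMethod()
}

#' Aggregate a k-mer matrix at the unitig level
#'
#' For every unitig u with N constituent k-mers and every sample S, computes
#' the fraction of u's k-mers present in S,
#' \deqn{f(u,S) = \sum_{i=1}^{N} x_i / N,}
#' where \eqn{x_i} is 1 when the i-th k-mer of u has a non-zero count in S
#' and 0 otherwise, and the average abundance
#' \deqn{A(u,S) = \sum_{i=1}^{N} c_i / N,}
#' where \eqn{c_i} is the count of the i-th k-mer in S. The matrix is
#' streamed row by row: each k-mer row is assigned to its unitig via the
#' index and added to that unitig's presence and abundance accumulators,
#' which are finally divided by N.
#'
#' Matrix rows whose k-mer is not in the index (k-mers of unitigs removed by
#' the length filter) are skipped and counted in the `n_skipped` attribute.
#' Index k-mers never seen in the matrix contribute 0 presence and 0 count
#' implicitly.
#'
#' @param x a filtered `kmer_matrix`.
#' @param index a `unitig_index` over the (length-filtered) unitig set,
#'   built with the same k.
#' @return a `unitig_matrix`: a long tibble with columns `unitig_id`,
#'   `sample_id`, `frac` (in `[0, 1]`) and `abundance` (mean count), one row
#'   per unitig-sample pair, ordered by unitig then by sample column order.
#' @examples
#' u <- build_unitigs(c("ACC", "ACG", "CCG"), k = 3)
#' m <- merge_tables(list(tibble::tibble(kmer = c("ACC", "ACG"), count = c(2L, 4L))),
#'                   "s1", k = 3)
#' unitig_matrix(m, unitig_index(u))  # f = 2/3, A = 2
#' @export
unitig_matrix <- function(x, index) {
  k <- kmer_size(x)
  if (k != attr(index, "k"))
    stop("k mismatch: matrix has k = ", k, ", index has k = ",
         attr(index, "k"), call. = FALSE)
  if (anyDuplicated(x$kmer))
    stop("duplicate matrix row for k-mer '",
         x$kmer[duplicated(x$kmer)][1], "'", call. = FALSE)
  ids <- sample_ids(x)
  n_kmers <- attr(index, "n_kmers")
  uids <- as.integer(names(n_kmers))
  m <- match(x$kmer, index$kmer)
  n_skipped <- sum(is.na(m))
  n_s <- length(ids)
  n_u <- length(uids)
  if (n_u == 0L) {
    tbl <- tibble(unitig_id = integer(0), sample_id = character(0),
                  frac = numeric(0), abundance = numeric(0))
    return(new_unitig_matrix(tbl, k, n_kmers, ids, n_skipped))
  }
  counts <- as.matrix(x[ids])
  keep <- !is.na(m)
  counts <- counts[keep, , drop = FALSE]
  grp <- as.character(index$unitig_id[m[keep]])
  # accumulate presence (x_i) and counts (c_i) per unitig; unitigs with no
  # matrix row at all stay at zero
  sum_c <- matrix(0, n_u, n_s, dimnames = list(as.character(uids), ids))
  sum_x <- sum_c
  if (nrow(counts) > 0L) {
    sc <- rowsum(counts, grp)
    sx <- rowsum((counts > 0) + 0L, grp)
    sum_c[rownames(sc), ] <- sc
    sum_x[rownames(sx), ] <- sx
  }
  frac <- sum_x / n_kmers
  abund <- sum_c / n_kmers
  tbl <- tibble(
    unitig_id = rep(uids, each = n_s),
    sample_id = rep(ids, times = n_u),
    frac = as.vector(t(frac)),
    abundance = as.vector(t(abund)))
  new_unitig_matrix(tbl, k, n_kmers, ids, n_skipped)
}

#' Binarize a unitig matrix into presence-absence form
#'
#' A unitig counts as present in a sample when at least `min_frac` of its
#' k-mers are present there. The default of 0.8 reflects that in real data
#' the per-sample mean fraction of present k-mers in a unitig sits around
#' 80% regardless of unitig length, so a unitig genuinely carried by a
#' sample typically clears this bar while spurious partial overlaps do not.
#'
#' @param x a `unitig_matrix`.
#' @param min_frac presence threshold on the k-mer fraction, in (0, 1].
#' @return a tibble with column `unitig_id` followed by one 0/1 integer
#'   column per sample.
#' @export
binarize_unitig_matrix <- function(x, min_frac = 0.8) {
  if (!is.numeric(min_frac) || length(min_frac) != 1L ||
      min_frac <= 0 || min_frac > 1)
    stop("min_frac must lie in (0, 1]", call. = FALSE)
  wide <- tidyr::pivot_wider(
    dplyr::mutate(as_tibble(x), present = as.integer(.data$frac >= min_frac)),
    id_cols = "unitig_id", names_from = "sample_id", values_from = "present")
  wide[order(wide$unitig_id), ]
}

fmt_num <- function(v, digits) {
  if (is.null(digits)) format(v, scientific = FALSE, trim = TRUE)
  else formatC(v, format = "f", digits = digits)
}

#' Write and read unitig matrices
#'
#' Writes `<prefix>.frac.mat` (fraction of k-mers present) and
#' `<prefix>.abundance.mat` (average abundance), each line
#' `<unitig_id> <v1> ... <vn>` in ascending id order with values formatted
#' to `digits` decimal places; optionally a combined `<prefix>.mat` with
#' `f:a` cells and an optional `#unitig <s1> ... <sn>` header. Unitig ids
#' match the unitigs FASTA headers exactly.
#'
#' @param x a `unitig_matrix`.
#' @param prefix output path prefix.
#' @param digits decimal places (default 2; `NULL` for full precision).
#' @param combined also write the combined `f:a` file.
#' @param header write the `#unitig ...` header line.
#' @return `write_unitig_matrix()` returns the written paths invisibly;
#'   `read_unitig_matrix()` returns a `unitig_matrix` (its `n_kmers`
#'   attribute is not recoverable from disk and is left empty).
#' @export
write_unitig_matrix <- function(x, prefix, digits = 2, combined = FALSE,
                                header = FALSE) {
  ids <- attr(x, "sample_ids")
  uids <- sort(unique(x$unitig_id))
  n_s <- length(ids)
  ord <- order(x$unitig_id, match(x$sample_id, ids))
  frac <- matrix(x$frac[ord], ncol = n_s, byrow = TRUE)
  abund <- matrix(x$abundance[ord], ncol = n_s, byrow = TRUE)
  emit <- function(mat, path, fmt) {
    con <- file(path, "wb")
    on.exit(close(con))
    if (header) writeLines(paste(c("#unitig", ids), collapse = " "), con)
    if (length(uids) > 0L)
      writeLines(paste(uids, apply(mat, 1L, fmt)), con)
  }
  p_frac <- paste0(prefix, ".frac.mat")
  p_abund <- paste0(prefix, ".abundance.mat")
  emit(frac, p_frac, function(r) paste(fmt_num(r, digits), collapse = " "))
  emit(abund, p_abund, function(r) paste(fmt_num(r, digits), collapse = " "))
  paths <- c(p_frac, p_abund)
  if (combined) {
    p_comb <- paste0(prefix, ".mat")
    con <- file(p_comb, "wb")
    if (header) writeLines(paste(c("#unitig", ids), collapse = " "), con)
    if (length(uids) > 0L) {
      cells <- matrix(paste0(fmt_num(frac, digits), ":", fmt_num(abund, digits)),
                      nrow = nrow(frac))
      writeLines(paste(uids, apply(cells, 1L, paste, collapse = " ")), con)
    }
    close(con)
    paths <- c(paths, p_comb)
  }
  invisible(paths)
}

#' @rdname write_unitig_matrix
#' @param k k-mer size to record on the object read back.
#' @export
read_unitig_matrix <- function(prefix, k) {
  k <- check_odd_k(k)
  read_one <- function(path) {
    lines <- readLines(path, warn = FALSE)
    ids <- NULL
    if (length(lines) > 0L && startsWith(lines[1], "#")) {
      ids <- strsplit(trimws(sub("^#", "", lines[1])), " ")[[1]][-1]
      lines <- lines[-1]
    }
    lines <- lines[trimws(lines) != ""]
    if (length(lines) == 0L)
      return(list(uid = integer(0), vals = matrix(numeric(0), 0, 0), ids = ids))
    parts <- strsplit(lines, " ", fixed = TRUE)
    if (length(unique(lengths(parts))) != 1L)
      stop("ragged rows in ", path, call. = FALSE)
    uid <- as.integer(vapply(parts, `[[`, character(1), 1L))
    vals <- t(vapply(parts, function(p) as.numeric(p[-1]),
                     numeric(length(parts[[1]]) - 1L)))
    list(uid = uid, vals = vals, ids = ids)
  }
  fr <- read_one(paste0(prefix, ".frac.mat"))
  ab <- read_one(paste0(prefix, ".abundance.mat"))
  if (!identical(fr$uid, ab$uid))
    stop("fraction and abundance matrices disagree on unitig ids", call. = FALSE)
  n_s <- if (nrow(fr$vals) > 0L) ncol(fr$vals) else length(fr$ids %||% character(0))
  ids <- fr$ids %||% paste0("s", seq_len(n_s))
  tbl <- tibble(
    unitig_id = rep(fr$uid, each = length(ids)),
    sample_id = rep(ids, times = length(fr$uid)),
    frac = as.vector(t(fr$vals)),
    abundance = as.vector(t(ab$vals)))
  new_unitig_matrix(tbl, k, integer(0), ids)
}

#' @export
tidy.unitig_matrix <- function(x, ...) as_tibble(x)

#' @export
glance.unitig_matrix <- function(x, ...) {
  tibble(n_unitigs = length(unique(x$unitig_id)),
         n_samples = length(attr(x, "sample_ids")),
         k = attr(x, "k"),
         mean_frac = if (nrow(x) == 0L) NA_real_ else mean(x$frac),
         mean_abundance = if (nrow(x) == 0L) NA_real_ else mean(x$abundance),
         skipped_kmer_rows = attr(x, "n_skipped"))
}

#' Heatmap of the per-sample fraction of k-mers present
#'
#' @param object a `unitig_matrix`.
#' @param value which cell value to draw, `"frac"` or `"abundance"`.
#' @param ... unused.
#' @return a ggplot tile plot (unitigs by samples).
#' @export
autoplot.unitig_matrix <- function(object, value = c("frac", "abundance"), ...) {
  value <- match.arg(value)
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$sample_id,
                               y = factor(.data$unitig_id),
                               fill = .data[[value]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = value) +
    ggplot2::labs(x = "sample", y = "unitig") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
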