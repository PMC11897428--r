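#' Run the full unitig-matrix pipeline
#'
#' Executes the four stages in order: (i) per-sample canonical k-mer
#' counting and k-mer matrix assembly, (ii) discriminative k-mer filtering
#' (present in >= `min_present` and absent in >= `min_absent` of the
#' samples), (iii) compaction of the surviving k-mers into maximal unitigs
#' of the bidirected de Bruijn graph followed by the minimum-length filter,
#' and (iv) aggregation of k-mer counts into the per-unitig, per-sample
#' fraction-present and average-abundance matrices. All stage outputs are
#' written under `out_dir` along with a `manifest.txt` of `key: value`
#' lines recording parameters and per-stage row/unitig counts.
#'
#' The pipeline is fully deterministic: outputs are byte-identical across
#' reruns and thread counts, and invariant to read order within a sample.
#'
#' @param fof file-of-files path or manifest tibble from [read_fof()].
#' @param out_dir output directory (created if needed).
#' @param k k-mer size (odd, 3--31; default 31).
#' @param min_abundance per-sample abundance floor at counting (default 2).
#' @param min_present,min_absent fractional filter thresholds (defaults
#'   0.1/0.1); `abs_present`/`abs_absent` give the absolute forms.
#' @param abs_present,abs_absent optional absolute thresholds.
#' @param min_unitig_length minimum unitig length in bp (default `2*k - 1`).
#' @param skip_filter disable stage (ii) entirely (all counted k-mers pass).
#' @param pa presence-absence mode: emit only the binarized unitig matrix.
#' @param min_frac binarization threshold for `pa` mode (default 0.8).
#' @param threads samples counted concurrently (default 1).
#' @param header write header lines on matrix files.
#' @param combined also write the combined `f:a` unitig matrix.
#' @param digits decimal places in the unitig matrix files (default 2).
#' @param quiet suppress progress messages on standard error.
#' @return the manifest as a named list (invisibly); also written to
#'   `<out_dir>/manifest.txt`.
#' @export
run_pipeline <- function(fof, out_dir, k = 31, min_abundance = 2,
                         min_present = 0.1, min_absent = 0.1,
                         abs_present = NULL, abs_absent = NULL,
                         min_unitig_length = NULL, skip_filter = FALSE,
                         pa = FALSE, min_frac = 0.8, threads = 1,
                         header = FALSE, combined = FALSE, digits = 2,
                         quiet = TRUE) {
  k <- check_odd_k(k)
  min_unitig_length <- min_unitig_length %||% (2L * k - 1L)
  if (min_unitig_length < k)
    stop("min_unitig_length must be at least k", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[unitigr] ", sprintf(...))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(force(expr), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    say("%s done in %.1fs", name, as.numeric(Sys.time() - t0, units = "secs"))
    res
  }

  if (is.character(fof)) fof <- read_fof(fof)
  n_samples <- nrow(fof)

  # (i) k-mer matrix construction
  kmat <- stage("count", kmer_count_matrix(fof, k = k,
                                           min_abundance = min_abundance,
                                           threads = threads))
  write_kmer_matrix(kmat, file.path(out_dir, "kmer_matrix.mat"),
                    header = header)

  # (ii) k-mer matrix filtering
  fmat <- if (skip_filter) kmat else {
    stage("filter", filter_kmer_matrix(kmat, min_present = min_present,
                                       min_absent = min_absent,
                                       abs_present = abs_present,
                                       abs_absent = abs_absent))
  }
  write_kmer_matrix(fmat, file.path(out_dir, "kmer_matrix.filtered.mat"),
                    header = header)
  if (nrow(fmat) == 0L)
    warning("filtered k-mer matrix is empty; downstream outputs are empty",
            call. = FALSE)
  kmer_matrix_fasta(fmat, file.path(out_dir, "kmers.fasta"))

  # (iii) unitig construction + length filter
  uall <- stage("unitig", build_unitigs(fmat))
  ukept <- filter_unitigs(uall, min_length = min_unitig_length)
  write_unitig_fasta(ukept, file.path(out_dir, "unitigs.fasta"))
  dropped <- attr(ukept, "dropped_kmers")

  # (iv) unitig matrix construction
  idx <- unitig_index(ukept)
  umat <- stage("aggregate", unitig_matrix(fmat, idx))
  paths <- if (pa) {
    bin <- binarize_unitig_matrix(umat, min_frac = min_frac)
    p <- file.path(out_dir, "unitigs.pa.mat")
    write_pa_matrix(bin, p, header = header)
    p
  } else {
    write_unitig_matrix(umat, file.path(out_dir, "unitigs"),
                        digits = digits, combined = combined, header = header)
  }

  manifest <- list(
    k = k,
    n_samples = n_samples,
    min_abundance = min_abundance,
    skip_filter = skip_filter,
    t_present = if (skip_filter) NA else if (!is.null(abs_present))
      resolve_threshold(abs_present, n_samples, absolute = TRUE)
      else resolve_threshold(min_present, n_samples),
    t_absent = if (skip_filter) NA else if (!is.null(abs_absent))
      resolve_threshold(abs_absent, n_samples, absolute = TRUE)
      else resolve_threshold(min_absent, n_samples),
    min_unitig_length = min_unitig_length,
    pa_mode = pa,
    kmers_counted = nrow(kmat),
    kmers_after_filter = nrow(fmat),
    kmers_dropped_by_filter = nrow(kmat) - nrow(fmat),
    unitigs_built = nrow(uall),
    unitigs_kept = nrow(ukept),
    unitigs_dropped_by_length = nrow(uall) - nrow(ukept),
    kmers_dropped_by_length = length(dropped),
    kmer_rows_skipped_in_aggregation = attr(umat, "n_skipped"),
    mean_unitig_length = if (nrow(ukept) > 0L) mean(ukept$length) else NA)
  write_manifest(manifest, file.path(out_dir, "manifest.txt"))
  invisible(manifest)
}

#' Run the presence-absence pipeline
#'
#' Identical to [run_pipeline()] but with the discriminative k-mer filter
#' disabled (all counted k-mers pass to compaction) and only the binarized
#' presence-absence unitig matrix emitted.
#'
#' @inheritParams run_pipeline
#' @return the manifest list, invisibly.
#' @export
run_pa_pipeline <- function(fof, out_dir, k = 31, min_abundance = 2,
                            min_frac = 0.8, min_unitig_length = NULL,
                            threads = 1, header = FALSE, quiet = TRUE) {
  run_pipeline(fof, out_dir, k = k, min_abundance = min_abundance,
               min_unitig_length = min_unitig_length, skip_filter = TRUE,
               pa = TRUE, min_frac = min_frac, threads = threads,
               header = header, quiet = quiet)
}

# binary matrix writer: "<unitig_id> <0/1> ..."
write_pa_matrix <- function(bin, path, header = FALSE) {
  con <- file(path, "wb")
  on.exit(close(con))
  ids <- setdiff(names(bin), "unitig_id")
  if (header) writeLines(paste(c("#unitig", ids), collapse = " "), con)
  if (nrow(bin) > 0L) {
    m <- as.matrix(bin[ids])
    writeLines(paste(bin$unitig_id, apply(m, 1L, paste, collapse = " ")), con)
  }
  invisible(path)
}

write_manifest <- function(manifest, path) {
  vals <- vapply(manifest, function(v)
    if (is.numeric(v)) format(v, scientific = FALSE) else as.character(v),
    character(1))
  writeLines(paste0(names(manifest), ": ", vals), path)
  invisible(path)
}

#' Read a pipeline run manifest
#'
#' @param path path to a `manifest.txt` written by [run_pipeline()].
#' @return a named list; numeric-looking values are converted to numbers.
#' @export
read_manifest <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- strsplit(lines, ": ", fixed = TRUE)
  out <- lapply(kv, function(p) {
    v <- p[2]
    n <- suppressWarnings(as.numeric(v))
    if (!is.na(n)) n else if (v %in% c("TRUE", "FALSE")) as.logical(v) else v
  })
  stats::setNames(out, vapply(kv, `[[`, character(1), 1L))
}
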