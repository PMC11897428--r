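#' Read a file-of-files sample manifest
#'
#' Each non-empty, non-comment line names one sample and its read files:
#' \preformatted{<sample_id> : <path>[ ; <path> ...]}
#' Comment lines start with `#`. Sample order is preserved and defines the
#' column order of every downstream matrix. Sample identifiers must be
#' unique and may not contain whitespace, `:` or `;` (reserved by the
#' syntax).
#'
#' @param path path to the manifest file.
#' @param check_files verify that every listed read file exists (default
#'   `TRUE`).
#' @return a tibble with one row per sample: `sample_id` (character) and
#'   `files` (list column of character path vectors). Relative paths are
#'   resolved against the directory containing the manifest.
#' @examples
#' fof <- tempfile()
#' writeLines(c("# two samples", "s1 : a.fa", "s2 : b1.fq.gz ; b2.fq.gz"), fof)
#' read_fof(fof, check_files = FALSE)
#' @export
read_fof <- function(path, check_files = TRUE) {
  if (!file.exists(path)) stop("file-of-files not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  base <- dirname(normalizePath(path))
  ids <- character(0)
  files <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#")) next
    if (!grepl(":", ln, fixed = TRUE))
      stop(sprintf("line %d: malformed (missing ':'): %s", i, ln), call. = FALSE)
    id <- trimws(sub(":.*$", "", ln))
    rest <- trimws(sub("^[^:]*:", "", ln))
    if (id == "")
      stop(sprintf("line %d: empty sample id", i), call. = FALSE)
    if (grepl("[[:space:];:]", id))
      stop(sprintf("line %d: sample id '%s' contains whitespace, ':' or ';'", i, id),
           call. = FALSE)
    if (id %in% ids)
      stop(sprintf("line %d: duplicate sample id '%s'", i, id), call. = FALSE)
    paths <- trimws(strsplit(rest, ";", fixed = TRUE)[[1]])
    paths <- paths[paths != ""]
    if (length(paths) == 0L)
      stop(sprintf("line %d: no files listed for sample '%s'", i, id), call. = FALSE)
    abs <- ifelse(grepl("^(/|~)", paths), paths, file.path(base, paths))
    if (check_files) {
      bad <- abs[!file.exists(abs)]
      if (length(bad) > 0L)
        stop(sprintf("line %d: unreadable file(s) for sample '%s': %s",
                     i, id, paste(bad, collapse = ", ")), call. = FALSE)
    }
    ids <- c(ids, id)
    files[[length(files) + 1L]] <- abs
  }
  tibble(sample_id = ids, files = files)
}

#' Write a file-of-files sample manifest
#'
#' @param fof tibble with columns `sample_id` and `files` (list column), as
#'   returned by [read_fof()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fof <- function(fof, path) {
  stopifnot(all(c("sample_id", "files") %in% names(fof)))
  lines <- vapply(seq_len(nrow(fof)), function(i) {
    paste0(fof$sample_id[i], " : ", paste(fof$files[[i]], collapse = " ; "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
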