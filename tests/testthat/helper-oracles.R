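# Independent naive oracles used to cross-check the package implementation.
# Everything here is deliberately written by different means than the
# package internals: plain string manipulation and exhaustive enumeration.

naive_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCATGCA", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

naive_canonical <- function(s) {
  s <- toupper(s)
  r <- naive_revcomp(s)
  if (s <= r) s else r
}

# per-window canonical k-mers of one sequence, skipping windows with
# non-ACGT characters
naive_windows <- function(s, k) {
  s <- toupper(s)
  n <- nchar(s)
  if (n < k) return(character(0))
  out <- character(0)
  for (i in seq_len(n - k + 1L)) {
    w <- substr(s, i, i + k - 1L)
    if (grepl("^[ACGT]+$", w)) out <- c(out, naive_canonical(w))
  }
  out
}

naive_count <- function(seqs, k, min_abundance = 1) {
  tab <- table(unlist(lapply(seqs, naive_windows, k = k)))
  tab <- tab[tab >= min_abundance]
  tibble::tibble(kmer = names(tab), count = as.integer(tab))[order(names(tab)), ]
}

# random set of distinct canonical k-mers
random_kmer_set <- function(n, k) {
  raw <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = ""),
    character(1))
  sort(unique(vapply(raw, naive_canonical, character(1), USE.NAMES = FALSE)))
}

random_genome <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Brute-force maximal-unitig oracle: enumerates the full oriented-k-mer
# digraph as an explicit edge list, marks "safe" edges (unique out-degree at
# the tail, unique in-degree at the head), and reads off maximal chains of
# safe edges. Self-edges (head and tail on the same canonical k-mer) are
# artifacts of canonical identification and excluded. Isolated cycles are
# linearized starting at the smallest canonical k-mer. Returns the sorted
# canonical (min of sequence/revcomp) unitig sequences.
oracle_unitigs <- function(kmers, k) {
  if (length(kmers) == 0L) return(character(0))
  rc <- vapply(kmers, naive_revcomp, character(1), USE.NAMES = FALSE)
  n2 <- 2L * length(kmers)
  canon <- rep(kmers, 2L)
  str <- c(kmers, rc)
  pre <- substr(str, 1L, k - 1L)
  suf <- substr(str, 2L, k)
  # all ordered pairs with a (k-1)-overlap, excluding same-canonical pairs
  by_pre <- split(seq_len(n2), pre)
  from <- integer(0); to <- integer(0)
  for (i in seq_len(n2)) {
    j <- by_pre[[suf[i]]]
    j <- j[canon[j] != canon[i]]
    if (length(j) > 0L) { from <- c(from, rep(i, length(j))); to <- c(to, j) }
  }
  succ <- rep(NA_integer_, n2)
  has_pred <- rep(FALSE, n2)
  if (length(from) > 0L) {
    outdeg <- tabulate(from, n2)
    indeg <- tabulate(to, n2)
    safe <- outdeg[from] == 1 & indeg[to] == 1
    succ[from[safe]] <- to[safe]
    has_pred[to[safe]] <- TRUE
  }
  spell <- function(chain) {
    s <- paste0(str[chain[1]], paste(substr(str[chain[-1]], k, k), collapse = ""))
    min(s, naive_revcomp(s))
  }
  out <- character(0)
  covered <- character(0)
  # chains: walk forward from every node with no safe predecessor
  for (i in seq_len(n2)) {
    if (has_pred[i]) next
    chain <- i
    cur <- i
    while (!is.na(succ[cur])) {
      cur <- succ[cur]
      chain <- c(chain, cur)
    }
    out <- c(out, spell(chain))
    covered <- union(covered, canon[chain])
  }
  # isolated cycles: every remaining node has a safe predecessor
  left <- setdiff(kmers, covered)
  while (length(left) > 0L) {
    start <- which(canon == min(left) & seq_len(n2) <= length(kmers))  # "+"
    chain <- start
    cur <- start
    repeat {
      nxt <- succ[cur]
      if (canon[nxt] == canon[start]) break
      chain <- c(chain, nxt)
      cur <- nxt
    }
    out <- c(out, spell(chain))
    left <- setdiff(left, canon[chain])
  }
  sort(unique(out))
}

# naive per-unitig aggregation straight from the definitions
naive_aggregate <- function(kmat, uset) {
  k <- attr(uset, "k")
  ids <- setdiff(names(kmat), "kmer")
  rows <- list()
  for (i in seq_len(nrow(uset))) {
    wins <- naive_windows(uset$sequence[i], k)
    n <- length(wins)
    for (s in ids) {
      cnt <- vapply(wins, function(w) {
        j <- which(kmat$kmer == w)
        if (length(j) == 0L) 0L else kmat[[s]][j]
      }, integer(1))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        unitig_id = uset$id[i], sample_id = s,
        frac = sum(cnt > 0) / n, abundance = sum(cnt) / n)
    }
  }
  dplyr::bind_rows(rows)
}

# re-tag a plain data frame as a kmer_matrix (attributes are lost by
# ordinary subsetting)
new_kmer_matrix_for_test <- function(tbl, k) {
  tbl <- tibble::as_tibble(tbl)
  attr(tbl, "k") <- as.integer(k)
  class(tbl) <- c("kmer_matrix", class(tibble::tibble()))
  tbl
}

# assemble a unitig_set object directly from sequences (bypasses compaction)
new_unitig_set_for_test <- function(sequences, k) {
  sequences <- sort(sequences)
  tbl <- tibble::tibble(id = seq_along(sequences) - 1L,
                        sequence = sequences,
                        length = nchar(sequences),
                        n_kmers = nchar(sequences) - as.integer(k) + 1L)
  attr(tbl, "k") <- as.integer(k)
  attr(tbl, "dropped_kmers") <- character(0)
  class(tbl) <- c("unitig_set", class(tibble::tibble()))
  tbl
}

# small helper: build a kmer_matrix from a named list of count tibbles
make_matrix <- function(tables, k) {
  merge_tables(tables, names(tables), k)
}

# random kmer_matrix over n_samples with given distinct canonical kmers
random_matrix <- function(n_kmers, n_samples, k, p_zero = 0.4, max_count = 9) {
  km <- random_kmer_set(n_kmers, k)
  tabs <- lapply(seq_len(n_samples), function(j) {
    cnt <- ifelse(stats::runif(length(km)) < p_zero, 0L,
                  sample.int(max_count, length(km), replace = TRUE))
    tibble::tibble(kmer = km, count = cnt)[cnt > 0, ]
  })
  names(tabs) <- paste0("s", seq_len(n_samples))
  m <- make_matrix(tabs, k)
  m
}
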