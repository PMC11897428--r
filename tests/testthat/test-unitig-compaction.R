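test_that("forward neighbors follow the (k-1)-overlap with orientations", {
  # ACG read forward extends to CGG, whose canonical form is CCG on strand -
  nb <- forward_neighbors(c("ACG", "CCG", "ACC"), "ACG", "+")
  expect_equal(nb$kmer, "CCG")
  expect_equal(nb$orientation, "-")
  # no overlap partner
  expect_equal(nrow(forward_neighbors("ACG", "ACG", "+")), 0L)
  # two successors make a fork
  nb2 <- forward_neighbors(c("ACG", "CGA", "CGC"), "ACG", "+")
  expect_equal(nrow(nb2), 2L)
  expect_error(forward_neighbors(c("ACG"), "CGT", "+"), "canonical")
})

test_that("compaction merges a simple path into one unitig", {
  u <- build_unitigs(c("ACG", "CCG", "ACC"), k = 3)  # k-mers of "ACGGT"
  expect_equal(nrow(u), 1L)
  expect_equal(u$sequence, "ACCGT")  # lexicographic min of {ACGGT, ACCGT}
  expect_equal(u$n_kmers, 3L)
})

test_that("a fork blocks merging: three k-mers stay three unitigs", {
  u <- build_unitigs(c("ACG", "CGA", "CGC"), k = 3)
  expect_equal(nrow(u), 3L)
  expect_true(all(u$length == 3L))
})

test_that("a singleton set yields one unitig of length k", {
  u <- build_unitigs("AAC", k = 3)
  expect_equal(u$sequence, "AAC")
  expect_equal(build_unitigs(character(0), k = 3)$sequence, character(0))
})

test_that("non-canonical or duplicate input k-mers are rejected", {
  expect_error(build_unitigs(c("CGT"), k = 3), "not canonical")
  expect_error(build_unitigs(c("ACG", "ACG"), k = 3), "duplicate")
})

test_that("an isolated cycle is linearized at its smallest k-mer", {
  # circular genome whose canonical 5-mer graph is a chord-free 12-cycle
  # (every node has exactly one forward and one backward neighbor)
  circ <- "ATGACAGGCCGG"
  k <- 5
  doubled <- paste0(circ, substr(circ, 1, k - 1))
  km <- sort(unique(kmer_windows(doubled, k)))
  expect_length(km, nchar(circ))
  for (x in km) {
    expect_equal(nrow(forward_neighbors(km, x, "+")), 1L)
    expect_equal(nrow(forward_neighbors(km, x, "-")), 1L)
  }
  u <- build_unitigs(km, k)
  # a cycle of m nodes yields one unitig of length m + k - 1, starting at
  # the smallest canonical k-mer
  expect_equal(nrow(u), 1L)
  expect_equal(u$length, length(km) + k - 1L)
  expect_equal(sum(u$n_kmers), length(km))
  expect_true(startsWith(u$sequence, min(km)) ||
                endsWith(u$sequence, kmer_revcomp(min(km))))
})

test_that("every input k-mer lands in exactly one unitig (conservation)", {
  set.seed(41)
  for (rep in 1:10) {
    k <- sample(c(3, 5), 1)
    km <- random_kmer_set(sample(10:150, 1), k)
    u <- build_unitigs(km, k)
    expect_equal(sum(u$n_kmers), length(km))
    idx <- unitig_index(u)
    expect_equal(sort(idx$kmer), km)
  }
})

test_that("compaction equals the brute-force maximal-path oracle", {
  set.seed(42)
  for (rep in 1:60) {
    k <- sample(c(3, 5), 1)
    n <- sample(5:200, 1)
    km <- random_kmer_set(n, k)
    got <- build_unitigs(km, k)$sequence
    want <- oracle_unitigs(km, k)
    expect_equal(got, want)
  }
})

test_that("a genome with unique (k-1)-mers reconstructs as one unitig", {
  set.seed(43)
  k <- 15
  done <- 0
  while (done < 5) {
    g <- random_genome(500)
    # require all (k-1)-mers distinct across both strands
    sub <- c(substring(g, 1:(500 - k + 2), (k - 1):500),
             substring(kmer_revcomp(g), 1:(500 - k + 2), (k - 1):500))
    if (anyDuplicated(sub)) next
    done <- done + 1
    km <- sort(unique(kmer_windows(g, k)))
    u <- build_unitigs(km, k)
    expect_equal(nrow(u), 1L)
    expect_true(u$sequence %in% c(g, kmer_revcomp(g)))
  }
})

test_that("output is deterministic and independent of input order and strand", {
  set.seed(44)
  km <- random_kmer_set(120, 5)
  u1 <- build_unitigs(km, 5)
  u2 <- build_unitigs(sample(km), 5)
  expect_identical(as.data.frame(u1), as.data.frame(u2))
  g <- random_genome(300)
  ua <- build_unitigs(sort(unique(kmer_windows(g, 7))), 7)
  ub <- build_unitigs(sort(unique(kmer_windows(kmer_revcomp(g), 7))), 7)
  expect_identical(ua$sequence, ub$sequence)
})

test_that("length filter keeps >= min_length, re-ids, and records drops", {
  set.seed(45)
  km <- random_kmer_set(150, 5)
  u <- build_unitigs(km, 5)
  f <- filter_unitigs(u, min_length = 9)  # default 2k - 1
  expect_true(all(f$length >= 9))
  expect_equal(f$id, seq_len(nrow(f)) - 1L)
  dropped <- attr(f, "dropped_kmers")
  expect_equal(sum(f$n_kmers) + length(dropped), length(km))
  expect_length(intersect(dropped, unitig_index(f)$kmer), 0L)
  # min_length = k is the identity
  expect_equal(filter_unitigs(u, min_length = 5)$sequence, u$sequence)
  expect_error(filter_unitigs(u, min_length = 4), "at least k")
})

test_that("length filter boundary sits at 2k - 1 for k = 31", {
  set.seed(46)
  g60 <- random_genome(60)
  g61 <- random_genome(61)
  u <- new_unitig_set_for_test(c(g60, g61), 31)
  f <- filter_unitigs(u)  # default 2*31 - 1 = 61
  expect_equal(f$length, 61L)
  expect_equal(f$sequence, g61)
  # all unitigs short -> empty set
  expect_equal(nrow(filter_unitigs(new_unitig_set_for_test(g60, 31))), 0L)
})

test_that("unitig FASTA round-trips with ids as headers", {
  set.seed(47)
  km <- random_kmer_set(80, 5)
  u <- build_unitigs(km, 5)
  p <- tempfile(fileext = ".fasta")
  write_unitig_fasta(u, p)
  lines <- readLines(p)
  expect_equal(lines[1], ">0")
  u2 <- read_unitig_fasta(p, 5)
  expect_equal(as.data.frame(u2), as.data.frame(u))
  p2 <- tempfile(fileext = ".fasta")
  write_unitig_fasta(u2, p2)
  expect_identical(readLines(p2), lines)
  # single unitig formatting
  p3 <- tempfile(fileext = ".fasta")
  write_unitig_fasta(build_unitigs(c("ACG", "CCG", "ACC"), 3), p3)
  expect_equal(readLines(p3), c(">0", "ACCGT"))
})

test_that("unitig FASTA reading rejects short records and duplicate ids", {
  p <- tempfile(fileext = ".fasta")
  writeLines(c(">0", "ACGT"), p)
  expect_error(read_unitig_fasta(p, 5), "shorter than k")
  writeLines(c(">0", "ACGTA", ">0", "CCGTA"), p)
  expect_error(read_unitig_fasta(p, 5), "duplicate")
})
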