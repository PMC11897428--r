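write_tmp_fasta <- function(seqs, dir = tempdir(), gz = FALSE) {
  p <- tempfile(tmpdir = dir, fileext = if (gz) ".fasta.gz" else ".fasta")
  write_fasta(seqs, p)
  p
}

test_that("file-of-files parsing: syntax, comments, order", {
  d <- withr::local_tempdir()
  writeLines("A", file.path(d, "a.fa"))  # placeholder targets
  writeLines("A", file.path(d, "b1.fq.gz"))
  writeLines("A", file.path(d, "b2.fq.gz"))
  fof <- file.path(d, "samples.fof")
  writeLines(c("# comment", "", "s1 : a.fa", "s2 : b1.fq.gz ; b2.fq.gz"), fof)
  out <- read_fof(fof)
  expect_equal(out$sample_id, c("s1", "s2"))
  expect_length(out$files[[1]], 1)
  expect_length(out$files[[2]], 2)
})

test_that("file-of-files parsing rejects malformed input with line numbers", {
  d <- withr::local_tempdir()
  writeLines("A", file.path(d, "a.fa"))
  fof <- file.path(d, "f.fof")
  writeLines(c("s1 : a.fa", "s1 : a.fa"), fof)
  expect_error(read_fof(fof), "line 2.*s1")
  writeLines(c("s1 : a.fa", "no-colon-here"), fof)
  expect_error(read_fof(fof), "line 2.*missing ':'")
  writeLines("s1 : does_not_exist.fa", fof)
  expect_error(read_fof(fof), "unreadable")
  writeLines("bad id : a.fa", fof)
  expect_error(read_fof(fof), "whitespace")
})

test_that("counting one read matches hand enumeration and honours the floor", {
  d <- withr::local_tempdir()
  p <- write_tmp_fasta(c(r1 = "ACGACG"), d)
  t1 <- count_sample(p, k = 3, min_abundance = 1)
  expect_equal(t1, tibble::tibble(kmer = c("ACG", "CGA", "GAC"),
                                  count = c(2L, 1L, 1L)))
  t2 <- count_sample(p, k = 3, min_abundance = 2)
  expect_equal(t2, tibble::tibble(kmer = "ACG", count = 2L))
})

test_that("forward and reverse-complement reads merge under canonicalization", {
  d <- withr::local_tempdir()
  p <- write_tmp_fasta(c(r1 = "ACG", r2 = "CGT"), d)
  expect_equal(count_sample(p, k = 3, min_abundance = 1),
               tibble::tibble(kmer = "ACG", count = 2L))
})

test_that("counting equals the naive dictionary oracle on random reads", {
  set.seed(21)
  for (rep in 1:5) {
    reads <- vapply(1:30, function(i) random_genome(40), character(1))
    for (k in c(5, 9)) {
      got <- count_kmers(reads, k)
      want <- naive_count(reads, k)
      expect_equal(got$kmer, want$kmer)
      expect_equal(got$count, want$count)
    }
  }
})

test_that("counting is invariant to file order and read strand", {
  d <- withr::local_tempdir()
  set.seed(22)
  reads <- vapply(1:20, function(i) random_genome(50), character(1))
  names(reads) <- paste0("r", 1:20)
  p1 <- write_tmp_fasta(reads[1:10], d)
  p2 <- write_tmp_fasta(reads[11:20], d)
  t12 <- count_sample(c(p1, p2), k = 7)
  t21 <- count_sample(c(p2, p1), k = 7)
  expect_equal(t12, t21)
  flipped <- reads
  flipped[seq(1, 20, 2)] <- kmer_revcomp(flipped[seq(1, 20, 2)])
  p3 <- write_tmp_fasta(flipped, d)
  expect_equal(count_sample(p3, k = 7), t12)
})

test_that("fastq and gzip inputs are auto-detected and parsed", {
  d <- withr::local_tempdir()
  reads <- tibble::tibble(id = c("r1", "r2"), seq = c("ACGACG", "TTTACG"),
                          qual = c("IIIIII", "IIIIII"))
  p <- file.path(d, "reads.fastq.gz")
  write_fastq(reads, p)
  got <- count_sample(p, k = 3, min_abundance = 1)
  expect_equal(got, naive_count(reads$seq, 3))
})

test_that("merging tables takes the sorted union without cross-talk", {
  t1 <- tibble::tibble(kmer = "ACG", count = 2L)
  t2 <- tibble::tibble(kmer = c("ACG", "CGA"), count = c(1L, 5L))
  m <- merge_tables(list(t1, t2), c("a", "b"), k = 3)
  expect_equal(m$kmer, c("ACG", "CGA"))
  expect_equal(m$a, c(2L, 0L))
  expect_equal(m$b, c(1L, 5L))
  # single empty table -> 0 rows
  e <- merge_tables(list(tibble::tibble(kmer = character(0), count = integer(0))),
                    "a", k = 3)
  expect_equal(nrow(e), 0L)
  # N copies of one table -> constant rows
  m3 <- merge_tables(list(t2, t2, t2), c("x", "y", "z"), k = 3)
  expect_true(all(m3$x == m3$y & m3$y == m3$z))
  # column j equals table j exactly
  set.seed(23)
  tabs <- lapply(1:4, function(i) {
    km <- random_kmer_set(30, 5)
    keep <- sample(c(TRUE, FALSE), length(km), replace = TRUE)
    tibble::tibble(kmer = km[keep],
                   count = sample.int(9, sum(keep), replace = TRUE))
  })
  mm <- merge_tables(tabs, paste0("s", 1:4), k = 5)
  for (j in 1:4) {
    sub <- mm[mm[[paste0("s", j)]] > 0, c("kmer", paste0("s", j))]
    expect_equal(sub$kmer, tabs[[j]]$kmer[order(tabs[[j]]$kmer)])
    expect_equal(sub[[2]], tabs[[j]]$count[order(tabs[[j]]$kmer)])
  }
})

test_that("matrix text dialect round-trips, with and without gzip and header", {
  set.seed(24)
  m <- random_matrix(40, 3, k = 5)
  for (ext in c(".mat", ".mat.gz")) {
    p <- tempfile(fileext = ext)
    write_kmer_matrix(m, p)
    m2 <- read_kmer_matrix(p, k = 5)
    expect_equal(as.data.frame(m2), as.data.frame(m))
    p2 <- tempfile(fileext = ext)
    write_kmer_matrix(m2, p2)
    expect_identical(readLines(gzfile(p)), readLines(gzfile(p2)))
  }
  p <- tempfile(fileext = ".mat")
  write_kmer_matrix(m, p, header = TRUE)
  expect_match(readLines(p, n = 1), "^#kmer s1 s2 s3$")
  m3 <- read_kmer_matrix(p, k = 5)
  expect_equal(sample_ids(m3), c("s1", "s2", "s3"))
})

test_that("matrix format is the documented one and rejects bad lines", {
  m <- merge_tables(list(tibble::tibble(kmer = "ACG", count = 2L),
                         tibble::tibble(kmer = "ACG", count = 1L)),
                    c("a", "b"), k = 3)
  p <- tempfile()
  write_kmer_matrix(m, p)
  expect_equal(readLines(p), "ACG 2 1")
  writeLines("ACGT 1", p)
  expect_error(read_kmer_matrix(p, k = 3), "line 1.*length")
  writeLines("CGT 1", p)
  expect_error(read_kmer_matrix(p, k = 3), "not canonical")
  writeLines(c("ACG 1 2", "AAC 1"), p)
  expect_error(read_kmer_matrix(p, k = 3), "line 2.*ragged")
  writeLines("ACG -1", p)
  expect_error(read_kmer_matrix(p, k = 3), "line 1.*count")
})

test_that("k-mer FASTA dump writes one indexed record per row", {
  m <- merge_tables(list(tibble::tibble(kmer = c("AAC", "ACG"),
                                        count = c(1L, 2L))), "a", k = 3)
  p <- tempfile(fileext = ".fasta")
  expect_equal(kmer_matrix_fasta(m, p), 2L)
  expect_equal(readLines(p), c(">0", "AAC", ">1", "ACG"))
  e <- merge_tables(list(tibble::tibble(kmer = character(0),
                                        count = integer(0))), "a", k = 3)
  expect_equal(kmer_matrix_fasta(e, tempfile()), 0L)
})
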