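# Deterministic synthetic data: an ancestral genome, per-sample mutated
# variants, and error-bearing reads. All randomness flows from one explicit
# integer seed and never touches the caller's RNG stream.

BASES <- c("A", "C", "G", "T")

# derived per-sample seeds stay inside 32-bit integer range
derive_seed <- function(seed, tag, i) {
  as.integer((as.numeric(seed) * tag + i) %% 2147483647)
}

#' Generate a random genome
#'
#' Bases are i.i.d. uniform over A/C/G/T; the same seed always yields the
#' same genome.
#'
#' @param length genome length in bp (>= 1).
#' @param seed integer seed.
#' @return a single DNA string.
#' @export
sim_genome <- function(length, seed) {
  stopifnot(length >= 1)
  with_seed(seed, function() {
    paste(sample(BASES, length, replace = TRUE), collapse = "")
  })
}

#' Mutate a genome
#'
#' Per position: a substitution to one of the three other bases with
#' probability `snp_rate`, and independently a single-base indel with
#' probability `indel_rate` (deletion or insertion after the position, with
#' equal odds). Single-base indels suffice to exercise unitig splitting;
#' longer structural events are out of scope.
#'
#' @param genome DNA string.
#' @param snp_rate per-base substitution probability in `[0, 1)`.
#' @param indel_rate per-base indel probability in `[0, 1)`.
#' @param seed integer seed.
#' @return the mutated DNA string.
#' @export
mutate_genome <- function(genome, snp_rate = 0, indel_rate = 0, seed) {
  stopifnot(snp_rate >= 0, snp_rate <= 1, indel_rate >= 0, indel_rate < 1)
  n <- nchar(genome)
  with_seed(seed, function() {
    bases <- strsplit(genome, "", fixed = TRUE)[[1]]
    sub_at <- stats::runif(n) < snp_rate
    if (any(sub_at)) {
      # shift by 1..3 positions in base order: always a different base
      cur <- match(bases[sub_at], BASES)
      bases[sub_at] <- BASES[1L + (cur - 1L + sample(1:3, sum(sub_at),
                                                     replace = TRUE)) %% 4L]
    }
    indel_at <- stats::runif(n) < indel_rate
    if (any(indel_at)) {
      is_del <- stats::runif(sum(indel_at)) < 0.5
      ins_base <- sample(BASES, sum(indel_at), replace = TRUE)
      pieces <- bases
      w <- which(indel_at)
      pieces[w[is_del]] <- ""
      pieces[w[!is_del]] <- paste0(bases[w[!is_del]], ins_base[!is_del])
      bases <- pieces
    }
    paste(bases, collapse = "")
  })
}

#' Simulate shotgun reads
#'
#' Reads of fixed length are placed at evenly spaced start positions
#' spanning the genome (so that the requested depth guarantees every
#' window is sampled -- random placement would leave the genome ends
#' systematically undercovered and make error-free reconstruction
#' stochastic), each on the forward or reverse strand with probability 1/2,
#' with independent per-base substitution errors at `error_rate`. The read
#' count is `ceiling(coverage * genome_length / read_length)` and qualities
#' are a constant string.
#'
#' @param genome DNA string (length >= `read_length`).
#' @param coverage mean per-base depth (> 0).
#' @param read_length read length in bp.
#' @param error_rate per-base substitution error probability in `[0, 1)`.
#' @param seed integer seed.
#' @return a tibble of FASTQ records: `id`, `seq`, `qual`.
#' @export
simulate_reads <- function(genome, coverage, read_length, error_rate = 0, seed) {
  glen <- nchar(genome)
  stopifnot(read_length <= glen, coverage > 0,
            error_rate >= 0, error_rate < 1)
  n_reads <- as.integer(ceiling(coverage * glen / read_length))
  with_seed(seed, function() {
    starts <- as.integer(floor(seq(1L, glen - read_length + 1L,
                                   length.out = n_reads)))
    fwd <- stats::runif(n_reads) < 0.5
    seqs <- substring(genome, starts, starts + read_length - 1L)
    seqs[!fwd] <- cpp_revcomp_seq(seqs[!fwd])
    if (error_rate > 0) {
      seqs <- vapply(seqs, function(s) {
        hit <- stats::runif(read_length) < error_rate
        if (!any(hit)) return(s)
        b <- strsplit(s, "", fixed = TRUE)[[1]]
        cur <- match(b[hit], BASES)
        b[hit] <- BASES[1L + (cur - 1L + sample(1:3, sum(hit),
                                                replace = TRUE)) %% 4L]
        paste(b, collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }
    tibble(id = sprintf("read_%d", seq_len(n_reads)),
           seq = seqs,
           qual = strrep("I", read_length))
  })
}

#' Generate a complete synthetic dataset
#'
#' Writes an ancestral genome, one mutated variant per sample, per-sample
#' gzipped FASTQ reads, and a file-of-files manifest consumable by
#' [read_fof()] / [run_pipeline()]. Per-sample seeds are derived
#' deterministically from `seed`, so the whole dataset is a pure function of
#' its arguments.
#'
#' @param out_dir output directory (created if needed).
#' @param genome_length ancestral genome length in bp.
#' @param n_samples number of samples.
#' @param snp_rate,indel_rate per-base mutation rates applied independently
#'   to each sample's variant of the ancestor.
#' @param coverage mean read depth per sample.
#' @param read_length read length in bp.
#' @param error_rate per-base sequencing error rate.
#' @param seed master integer seed.
#' @return the path of the written file-of-files manifest.
#' @export
sim_dataset <- function(out_dir, genome_length = 10000, n_samples = 10,
                        snp_rate = 0.005, indel_rate = 0.0005,
                        coverage = 10, read_length = 100,
                        error_rate = 0.001, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ancestor <- sim_genome(genome_length, seed)
  write_fasta(c(ancestor = ancestor), file.path(out_dir, "ancestor.fasta"))
  ids <- sprintf("sample_%02d", seq_len(n_samples))
  files <- character(n_samples)
  for (i in seq_len(n_samples)) {
    gi <- mutate_genome(ancestor, snp_rate, indel_rate,
                        seed = derive_seed(seed, 1009, i))
    write_fasta(stats::setNames(gi, ids[i]),
                file.path(out_dir, paste0(ids[i], ".genome.fasta")))
    reads <- simulate_reads(gi, coverage, read_length, error_rate,
                            seed = derive_seed(seed, 2003, i))
    files[i] <- file.path(out_dir, paste0(ids[i], ".fastq.gz"))
    write_fastq(reads, files[i])
  }
  fof <- file.path(out_dir, "samples.fof")
  write_fof(tibble(sample_id = ids, files = as.list(files)), fof)
  fof
}
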