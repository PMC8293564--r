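#' Simulation configuration
#'
#' Controls the bundled Illumina-style read simulator used for testing
#' the pipeline end to end: fragment coverage, read and insert geometry,
#' substitution errors (optionally strand-biased, to exercise the
#' strand-balance filter), haplotypes and carryover-style contamination.
#'
#' @param seed RNG seed (reproducible given the seed).
#' @param genome_len genome length in bp.
#' @param n_haplotypes number of haplotypes (SNPs at `snp_rate`).
#' @param snp_rate per-base probability of a haplotype SNP.
#' @param target_identity identity of simulated homolog targets.
#' @param coverage fold coverage.
#' @param read_len read length in bp.
#' @param insert_mean,insert_sd insert-size distribution (bp), truncated
#'   at `read_len`.
#' @param error_rate per-base substitution error rate.
#' @param strand_biased_error logical; plant a fixed substitution on
#'   forward-oriented reads at `bias_locus`.
#' @param strand_bias_rate fraction of forward-oriented reads covering
#'   the locus that receive the substitution.
#' @param bias_locus 1-based genome position of the planted error
#'   (defaults to the genome midpoint).
#' @param contaminant_fraction fraction of pairs drawn from an unrelated
#'   random sequence.
#' @return named list.
#' @export
sim_config <- function(seed = 1L, genome_len = 2000L, n_haplotypes = 1L,
                       snp_rate = 0, target_identity = 0.85,
                       coverage = 30, read_len = 150L,
                       insert_mean = 300L, insert_sd = 10L,
                       error_rate = 0, strand_biased_error = FALSE,
                       strand_bias_rate = 0.2, bias_locus = NULL,
                       contaminant_fraction = 0) {
  stopifnot(coverage > 0, error_rate >= 0, error_rate <= 1,
            snp_rate >= 0, snp_rate <= 1,
            contaminant_fraction >= 0, contaminant_fraction <= 1)
  cfg <- as.list(environment())
  if (is.null(cfg$bias_locus)) cfg$bias_locus <- genome_len %/% 2L
  cfg
}

#' Simulate a genome and haplotypes
#'
#' Draws a random genome and derives `n_haplotypes` copies differing at
#' SNP positions (drawn at `snp_rate`, or given explicitly).
#'
#' @param config from [sim_config()].
#' @param snp_positions optional explicit SNP positions (1-based).
#' @return list with `genome` and `haplotypes` (character vector).
#' @export
simulate_genome <- function(config, snp_positions = NULL) {
  set.seed(config$seed)
  genome <- random_dna(config$genome_len)
  haps <- rep(genome, max(1L, config$n_haplotypes))
  if (length(haps) > 1L) {
    if (is.null(snp_positions)) {
      n_snp <- stats::rbinom(1L, config$genome_len, config$snp_rate)
      snp_positions <- sort(sample.int(config$genome_len, n_snp))
    }
    for (p in snp_positions) {
      ref <- substr(genome, p, p)
      for (h in 2:length(haps)) {
        alt <- sample(setdiff(DNA_BASES, ref), 1L)
        substr(haps[h], p, p) <- alt
      }
    }
  }
  list(genome = genome, haplotypes = haps, snp_positions = snp_positions)
}

#' Mutate a sequence to a requested identity
#'
#' Substitutions are placed uniformly; the realised identity is within
#' half a percent of the request. Nucleotide sequences mutate bases;
#' protein sequences mutate residues over the 20 amino acids.
#'
#' @param sequence nucleotide or protein string.
#' @param identity target fraction identity in (0, 1].
#' @param seed RNG seed.
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @return mutated sequence string.
#' @export
mutate_target <- function(sequence, identity, seed = 1L,
                          alphabet = c("nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  set.seed(seed)
  n <- nchar(sequence)
  n_mut <- round((1 - identity) * n)
  if (n_mut == 0L) return(sequence)
  pos <- sample.int(n, n_mut)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  pool <- if (alphabet == "nucleotide") DNA_BASES
          else strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  for (p in pos) chars[p] <- sample(setdiff(pool, chars[p]), 1L)
  paste(chars, collapse = "")
}

#' Simulate paired reads from haplotypes
#'
#' The number of pairs is `round(genome_len * coverage / (2 * read_len))`,
#' split evenly across haplotypes. Inserts are Normal(mean, sd) truncated
#' to at least the read length; fragments start uniformly. Mate 0 is the
#' forward end of plus-strand fragments (reverse for minus-strand
#' fragments), giving reads on both strands. Substitution errors are
#' optional; with `strand_biased_error` a fixed substitution is planted
#' only on forward-oriented reads covering `bias_locus`. Contaminant
#' pairs come from an unrelated random sequence.
#'
#' @param haplotypes character vector of haplotype sequences.
#' @param config from [sim_config()].
#' @return a `read_set` (pairs ordered mate 0 then mate 1).
#' @export
simulate_reads <- function(haplotypes, config) {
  set.seed(config$seed + 1L)
  L <- config$read_len
  glen <- min(nchar(haplotypes))
  n_pairs <- round(config$genome_len * config$coverage / (2 * L))
  contam <- if (config$contaminant_fraction > 0) random_dna(glen) else NULL
  bias_base <- NULL
  if (config$strand_biased_error) {
    ref <- substr(haplotypes[1L], config$bias_locus, config$bias_locus)
    bias_base <- setdiff(DNA_BASES, ref)[1L]
  }
  seqs <- character(2L * n_pairs)
  mate <- integer(2L * n_pairs)
  pid <- character(2L * n_pairs)
  for (i in seq_len(n_pairs)) {
    from_contam <- !is.null(contam) && stats::runif(1) < config$contaminant_fraction
    src <- if (from_contam) contam
           else haplotypes[((i - 1L) %% length(haplotypes)) + 1L]
    ins <- max(L, round(stats::rnorm(1L, config$insert_mean, config$insert_sd)))
    ins <- min(ins, nchar(src))
    start <- sample.int(nchar(src) - ins + 1L, 1L)
    frag <- substr(src, start, start + ins - 1L)
    left <- substr(frag, 1L, L)
    right <- revcomp(substr(frag, ins - L + 1L, ins))
    plus_frag <- stats::runif(1) < 0.5
    ## orientation of each mate on the genome: left is forward,
    ## right is reverse; mate roles swap for minus-strand fragments
    m0 <- if (plus_frag) left else right
    m1 <- if (plus_frag) right else left
    m0_fwd <- plus_frag
    ## per-base substitution errors
    add_err <- function(s) {
      if (config$error_rate <= 0) return(s)
      ch <- strsplit(s, "", fixed = TRUE)[[1L]]
      hit <- which(stats::runif(length(ch)) < config$error_rate)
      for (p in hit) ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1L)
      paste(ch, collapse = "")
    }
    m0 <- add_err(m0); m1 <- add_err(m1)
    ## strand-biased planted error on forward-oriented reads
    if (!is.null(bias_base) && !from_contam) {
      plant <- function(s, s_start, fwd) {
        off <- config$bias_locus - s_start + 1L
        if (fwd && off >= 1L && off <= L &&
            stats::runif(1) < config$strand_bias_rate)
          substr(s, off, off) <- bias_base
        s
      }
      l_start <- start
      r_start <- start + ins - L
      if (plus_frag) m0 <- plant(m0, l_start, TRUE)
      else m1 <- plant(m1, l_start, TRUE)
    }
    j <- 2L * i - 1L
    seqs[j] <- m0; seqs[j + 1L] <- m1
    mate[j] <- 0L; mate[j + 1L] <- 1L
    pid[c(j, j + 1L)] <- sprintf("sim%06d", i)
  }
  read_set(seqs, mate = mate, pair_id = pid,
           id = sprintf("%s/%d", pid, mate + 1L))
}

#' Write a read set as paired FASTQ files
#'
#' @param reads a `read_set` with pairs.
#' @param prefix output prefix; writes `<prefix>_1.fq` and `<prefix>_2.fq`
#'   (unpaired reads go to `<prefix>_0.fq`).
#' @return character vector of written paths.
#' @export
write_fastq <- function(reads, prefix) {
  write_one <- function(idx, path) {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in idx) {
      writeLines(c(paste0("@", reads$id[i]), reads$seq[i], "+",
                   strrep("I", nchar(reads$seq[i]))), con)
    }
    path
  }
  out <- character(0)
  i0 <- which(!is.na(reads$mate) & reads$mate == 0L)
  i1 <- which(!is.na(reads$mate) & reads$mate == 1L)
  iu <- which(is.na(reads$mate))
  if (length(i0)) out <- c(out, write_one(i0, paste0(prefix, "_1.fq")))
  if (length(i1)) out <- c(out, write_one(i1, paste0(prefix, "_2.fq")))
  if (length(iu)) out <- c(out, write_one(iu, paste0(prefix, "_0.fq")))
  out
}
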