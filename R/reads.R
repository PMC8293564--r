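#' Read sets
#'
#' A read set is a plain list of parallel vectors: `id`, `seq`, `mate`
#' (0, 1 or `NA` for unpaired) and `pair_id` (`NA` for unpaired). Reads
#' containing N are split at runs of N into sub-reads; a sub-read keeps its
#' pairing metadata only when it is the complete mate.
#'
#' @name read_set
NULL

new_read_set <- function(id, seq, mate, pair_id) {
  structure(list(id = as.character(id), seq = toupper(as.character(seq)),
                 mate = as.integer(mate), pair_id = as.character(pair_id)),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  np <- sum(!is.na(x$pair_id)) / 2
  cat(sprintf("<read_set> %d reads (%g pairs), lengths %d-%d\n",
              length(x$seq), np,
              if (length(x$seq)) min(nchar(x$seq)) else 0L,
              if (length(x$seq)) max(nchar(x$seq)) else 0L))
  invisible(x)
}

#' @export
length.read_set <- function(x) length(x$seq)

read_fastx_file <- function(path) {
  fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
    "fastq" else "fasta"
  xs <- Biostrings::readDNAStringSet(path, format = fmt)
  list(id = names(xs), seq = as.character(xs))
}

## Split a sequence at runs of N; returns character vector of N-free pieces.
split_at_n <- function(seq) {
  pieces <- strsplit(seq, "N+")[[1L]]
  pieces[nchar(pieces) > 0L]
}

#' Load reads from FASTA/FASTQ files
#'
#' Accepts one or two files (optionally gzip-compressed; format detected
#' from the extension). In paired mode, two files are read as mate 0 /
#' mate 1 with matching record order, or a single file is treated as
#' interleaved. Records containing N are split at N runs into sub-reads;
#' a sub-read keeps pairing metadata only if it equals the whole mate.
#'
#' @param paths character vector of one or two file paths.
#' @param paired logical; treat input as mate pairs.
#' @param interleaved logical; with `paired = TRUE` and one file, mates
#'   alternate within the file.
#' @return a `read_set`.
#' @export
load_reads <- function(paths, paired = FALSE, interleaved = FALSE) {
  if (length(paths) == 0L) stop("no read files given")
  recs <- lapply(paths, read_fastx_file)
  ids <- unlist(lapply(recs, `[[`, "id"), use.names = FALSE)
  seqs <- toupper(unlist(lapply(recs, `[[`, "seq"), use.names = FALSE))
  if (length(seqs) == 0L) stop("empty read input: ", paste(paths, collapse = ", "))

  if (paired) {
    if (length(paths) == 2L) {
      n1 <- length(recs[[1L]]$id); n2 <- length(recs[[2L]]$id)
      if (n1 != n2)
        stop(sprintf("mismatched pair counts: %s has %d records, %s has %d",
                     paths[1L], n1, paths[2L], n2))
      mate <- rep(c(0L, 1L), each = n1)
      pair_id <- c(sprintf("p%06d", seq_len(n1)), sprintf("p%06d", seq_len(n2)))
      ord <- order(pair_id, mate)
      ids <- ids[ord]; seqs <- seqs[ord]; mate <- mate[ord]; pair_id <- pair_id[ord]
    } else {
      n <- length(seqs)
      if (n %% 2L != 0L)
        stop("interleaved paired input has an odd number of records: ", paths[1L])
      mate <- rep(c(0L, 1L), n / 2L)
      pair_id <- rep(sprintf("p%06d", seq_len(n / 2L)), each = 2L)
    }
  } else {
    mate <- rep(NA_integer_, length(seqs))
    pair_id <- rep(NA_character_, length(seqs))
  }

  ## N-splitting: sub-reads lose pairing unless the whole mate survived.
  out_id <- character(0); out_seq <- character(0)
  out_mate <- integer(0); out_pid <- character(0)
  for (i in seq_along(seqs)) {
    pieces <- split_at_n(seqs[i])
    if (length(pieces) == 1L && pieces[1L] == seqs[i]) {
      out_id <- c(out_id, ids[i]); out_seq <- c(out_seq, pieces)
      out_mate <- c(out_mate, mate[i]); out_pid <- c(out_pid, pair_id[i])
    } else if (length(pieces) >= 1L) {
      out_id <- c(out_id, paste0(ids[i], ".", seq_along(pieces)))
      out_seq <- c(out_seq, pieces)
      out_mate <- c(out_mate, rep(NA_integer_, length(pieces)))
      out_pid <- c(out_pid, rep(NA_character_, length(pieces)))
    }
  }
  if (length(out_seq) == 0L) stop("no usable reads after N-splitting")
  new_read_set(out_id, out_seq, out_mate, out_pid)
}

#' Build a read set directly from character vectors
#'
#' Convenience constructor used by the simulator and tests.
#'
#' @param seqs character vector of read sequences.
#' @param mate optional integer vector (0/1/NA).
#' @param pair_id optional character vector.
#' @param id optional read names.
#' @return a `read_set`.
#' @export
read_set <- function(seqs, mate = NULL, pair_id = NULL, id = NULL) {
  n <- length(seqs)
  new_read_set(id %||% sprintf("r%06d", seq_len(n)), seqs,
               mate %||% rep(NA_integer_, n),
               pair_id %||% rep(NA_character_, n))
}

largest_odd_leq <- function(x, multiple_of_3 = FALSE) {
  x <- as.integer(floor(x))
  while (x >= 1L && (x %% 2L == 0L || (multiple_of_3 && x %% 3L != 0L)))
    x <- x - 1L
  x
}

#' Automatic choice of primary and secondary k-mer sizes
#'
#' The primary k is the largest odd integer at most half the read length;
#' the secondary k is the larger of 21 and the largest odd integer at most
#' a fifth of the read length. In protein mode both must additionally be
#' multiples of three. The representative read length is the maximum
#' observed length. If the primary k comes out below 21, automatic
#' detection fails and the caller must supply k-mer sizes explicitly.
#'
#' @param read_lengths integer vector of read lengths.
#' @param protein_mode logical.
#' @return list with `primary_k` and `secondary_k`.
#' @export
choose_kmer_sizes <- function(read_lengths, protein_mode = FALSE) {
  if (length(read_lengths) == 0L) stop("no read lengths supplied")
  len <- max(read_lengths)
  primary <- largest_odd_leq(len / 2, protein_mode)
  if (primary < 21L)
    stop("automatic k-mer size detection fails for read length ", len,
         ": please supply the k-mer sizes to use")
  secondary <- max(21L, largest_odd_leq(len / 5, protein_mode))
  list(primary_k = primary, secondary_k = secondary)
}

#' Count canonical k-mers with per-strand counts
#'
#' Every k-length window of every read is canonicalised; an occurrence
#' equal to its canonical form increments the plus count, otherwise the
#' minus count. Windows are N-free because reads are N-split on input.
#'
#' @param reads a `read_set`.
#' @param k k-mer size.
#' @return a `kmer_counts` object: sorted `kmer` vector with parallel
#'   integer `plus` and `minus` counts and total `n_windows`.
#' @export
count_kmers <- function(reads, k) {
  lens <- nchar(reads$seq)
  if (all(lens < k)) stop("k = ", k, " exceeds every read length")
  wins <- unlist(lapply(reads$seq[lens >= k], kmer_windows, k = k),
                 use.names = FALSE)
  rc <- revcomp_many(wins)
  is_plus <- wins <= rc
  canon <- ifelse(is_plus, wins, rc)
  m <- rowsum(cbind(plus = as.integer(is_plus), minus = as.integer(!is_plus)),
              group = canon)
  structure(list(k = as.integer(k), kmer = rownames(m),
                 plus = as.integer(m[, "plus"]), minus = as.integer(m[, "minus"]),
                 n_windows = length(wins)),
            class = "kmer_counts")
}

#' @export
print.kmer_counts <- function(x, ...) {
  cat(sprintf("<kmer_counts> k=%d, %d distinct canonical k-mers, %d windows\n",
              x$k, length(x$kmer), x$n_windows))
  invisible(x)
}

#' Build a de Bruijn graph from k-mer counts
#'
#' Retains the canonical k-mers whose total count (plus + minus) is at
#' least `min_count`. Both orientations of each surviving k-mer are hashed
#' so that membership and extension queries are strand-agnostic.
#'
#' @param counts a `kmer_counts` object.
#' @param min_count minimum read count (default 2; 1 for low-coverage runs).
#' @return a `dbg` object.
#' @export
build_dbg <- function(counts, min_count = 2L) {
  stopifnot(min_count >= 1L)
  keep <- (counts$plus + counts$minus) >= min_count
  kmers <- counts$kmer[keep]
  plus <- counts$plus[keep]; minus <- counts$minus[keep]
  env <- new.env(hash = TRUE, parent = emptyenv(),
                 size = max(2L * length(kmers), 16L))
  if (length(kmers)) {
    rcs <- revcomp_many(kmers)
    for (i in seq_along(kmers)) {
      assign(kmers[i], c(plus[i], minus[i]), envir = env)
      if (rcs[i] != kmers[i])
        assign(rcs[i], c(minus[i], plus[i]), envir = env)
    }
  }
  structure(list(k = counts$k, min_count = as.integer(min_count),
                 kmers = kmers, env = env),
            class = "dbg")
}

#' @export
print.dbg <- function(x, ...) {
  cat(sprintf("<dbg> k=%d, min_count=%d, %d canonical k-mers\n",
              x$k, x$min_count, length(x$kmers)))
  invisible(x)
}

## Strand-agnostic membership / count lookup for an oriented k-mer.
## Returns c(plus, minus) in the orientation of `kmer`, or NULL.
dbg_lookup <- function(dbg, kmer) {
  get0(kmer, envir = dbg$env, inherits = FALSE)
}

## Lean extension query: list of parallel vectors (no data.frame); the
## workhorse for all hot loops.
.dbg_ext <- function(dbg, kmer, side = "right") {
  k <- dbg$k
  core <- if (side == "right") substr(kmer, 2L, k) else substr(kmer, 1L, k - 1L)
  cand <- if (side == "right") paste0(core, DNA_BASES) else paste0(DNA_BASES, core)
  base <- character(0); fwd <- numeric(0); rv <- numeric(0)
  for (i in 1:4) {
    v <- get0(cand[i], envir = dbg$env, inherits = FALSE)
    if (!is.null(v)) {
      base <- c(base, DNA_BASES[i]); fwd <- c(fwd, v[1L]); rv <- c(rv, v[2L])
    }
  }
  list(base = base, count = fwd + rv, fwd = fwd, rev = rv)
}

#' Query base extensions of an oriented k-mer
#'
#' @param dbg a `dbg`.
#' @param kmer oriented k-mer (length `dbg$k`).
#' @param side `"right"` (append base) or `"left"` (prepend base).
#' @return data.frame with `base`, `count`, `fwd`, `rev` for each
#'   extension present in the graph (fwd/rev are the per-strand counts of
#'   the extension k-mer, fwd being the strand of the oriented query).
#' @export
dbg_extensions <- function(dbg, kmer, side = c("right", "left")) {
  side <- match.arg(side)
  e <- .dbg_ext(dbg, kmer, side)
  data.frame(base = e$base, count = e$count, fwd = e$fwd, rev = e$rev,
             stringsAsFactors = FALSE)
}

#' Estimate the insert-size range by joining mates through the graph
#'
#' For each pair, the first mate is extended through strictly unambiguous
#' single-choice graph steps up to `cap` bases; if the reverse complement
#' of the second mate occurs exactly once in the joined sequence, the pair
#' is joined and its insert length recorded. The returned range is the
#' 1st-99th percentile of joined lengths.
#'
#' @param reads a `read_set` with paired reads.
#' @param graph a `dbg`.
#' @param cap maximum walk length in bases (default 1000).
#' @param min_joins minimum number of joined pairs before falling back to
#'   a conservative default range (default 100).
#' @return list with `min_len`, `max_len`, `samples`.
#' @export
estimate_insert_size <- function(reads, graph, cap = 1000L, min_joins = 100L) {
  k <- graph$k
  paired <- which(!is.na(reads$pair_id) & reads$mate == 0L)
  lens <- numeric(0)
  for (i in paired) {
    j <- which(reads$pair_id == reads$pair_id[i] & reads$mate == 1L)
    if (length(j) != 1L) next
    s1 <- reads$seq[i]; s2 <- reads$seq[j]
    if (nchar(s1) < k || nchar(s2) < k) next
    pat <- revcomp(s2)
    seq <- s1
    steps <- 0L
    while (nchar(seq) < cap) {
      ext <- .dbg_ext(graph, substr(seq, nchar(seq) - k + 1L, nchar(seq)))
      if (length(ext$base) != 1L) break
      seq <- paste0(seq, ext$base)
      steps <- steps + 1L
      if (steps %% 32L == 0L && grepl(pat, seq, fixed = TRUE)) break
    }
    hits <- gregexpr(pat, seq, fixed = TRUE)[[1L]]
    if (length(hits) == 1L && hits[1L] > 0L)
      lens <- c(lens, hits[1L] + nchar(pat) - 1L)
  }
  if (length(lens) < min_joins) {
    rl <- if (length(reads$seq)) max(nchar(reads$seq)) else cap
    warning(sprintf("only %d mate pairs joined (< %d); using fallback insert range",
                    length(lens), min_joins))
    return(list(min_len = rl, max_len = 2L * cap, samples = length(lens)))
  }
  q <- stats::quantile(lens, c(0.01, 0.99), names = FALSE, type = 1)
  list(min_len = as.integer(q[1L]), max_len = as.integer(q[2L]),
       samples = length(lens))
}
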