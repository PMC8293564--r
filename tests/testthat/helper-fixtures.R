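# Shared fixture builders. All fixtures are generated in code.

# A dbg built directly from a named list kmer -> c(plus, minus); k-mers
# are stored under both orientations like build_dbg does.
make_dbg <- function(counts, k) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (km in names(counts)) {
    v <- counts[[km]]
    assign(km, v, envir = env)
    rc <- revcomp(km)
    if (rc != km) assign(rc, c(v[2L], v[1L]), envir = env)
  }
  structure(list(k = as.integer(k), min_count = 1L,
                 kmers = sort(names(counts)), env = env),
            class = "dbg")
}

# dbg containing every k-mer of the given sequences at the given
# per-strand counts (same counts for all k-mers).
make_dbg_from_seqs <- function(seqs, k, plus = 10, minus = 10) {
  wins <- unique(unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    substring(s, 1:(n - k + 1L), k:n)
  })))
  canon <- unique(canonical_kmer(wins))
  make_dbg(stats::setNames(rep(list(c(plus, minus)), length(canon)), canon), k)
}

# Hand-built fork-context graph shaped like the read/pair filtering
# figure: A,B -> C -> D,E with k-1 overlaps, distinguishing bases placed
# directly at the junctions.
make_fork_graph <- function(k = 11L, core_len = 30L, arm_len = 20L,
                            seed = 42L) {
  set.seed(seed)
  o <- k - 1L
  jnA <- random_dna(o); jnD <- random_dna(o)   # overlap contexts
  aB <- random_dna(arm_len); bB <- random_dna(arm_len)
  dB <- random_dna(arm_len); eB <- random_dna(arm_len)
  core <- random_dna(core_len)
  A <- paste0(aB, jnA); B <- paste0(bB, jnA)
  C <- paste0(jnA, core, jnD)
  D <- paste0(jnD, dB); E <- paste0(jnD, eB)
  segments <- c(A = A, B = B, C = C, D = D, E = E)
  links <- data.frame(from = c("A", "B", "C", "C"),
                      to = c("C", "C", "D", "E"),
                      overlap = o, stringsAsFactors = FALSE)
  g <- targetasm:::new_assembled_graph(segments, links, k,
                                       max(5L, k %/% 2L), "fig1",
                                       target_len_nt = core_len + 2L * arm_len)
  g
}

# Full path sequence through a fork graph.
fork_path_seq <- function(g, segs) targetasm:::merge_segments(g, segs)

write_temp_fasta <- function(seqs, ext = ".fa") {
  f <- tempfile(fileext = ext)
  write_fasta(seqs, f)
  f
}

# A linear chain graph P -> arms -> Q for bubble tests.
make_bubble_graph <- function(k = 11L, n_sites = 1L, arm_len = 20L,
                              seed = 7L, indel = FALSE) {
  set.seed(seed)
  o <- k - 1L
  segs <- c(); links <- data.frame(from = character(0), to = character(0),
                                   overlap = integer(0), stringsAsFactors = FALSE)
  prev <- "P0"
  segs["P0"] <- targetasm:::random_dna(30L)
  for (i in seq_len(n_sites)) {
    ov <- substr(segs[[prev]], nchar(segs[[prev]]) - o + 1L, nchar(segs[[prev]]))
    ov2 <- targetasm:::random_dna(o)
    armA <- paste0(ov, "A", ov2)
    armB <- if (indel) paste0(ov, ov2) else paste0(ov, "G", ov2)
    nxt <- sprintf("P%d", i)
    segs[sprintf("A%d", i)] <- armA
    segs[sprintf("B%d", i)] <- armB
    segs[nxt] <- paste0(ov2, targetasm:::random_dna(30L))
    links <- rbind(links, data.frame(
      from = c(prev, prev, sprintf("A%d", i), sprintf("B%d", i)),
      to = c(sprintf("A%d", i), sprintf("B%d", i), nxt, nxt),
      overlap = o, stringsAsFactors = FALSE))
    prev <- nxt
  }
  targetasm:::new_assembled_graph(segs, links, k, 7L, "bubble",
                                  target_len_nt = 30L + n_sites * 40L)
}

counts_for <- function(seqs, k2 = 7L) count_kmers(read_set(seqs), k2)

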