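# Independent brute-force affine-gap DP oracle.
#
# Recomputes, from scratch with full score matrices, the best alignment
# score of every path prefix P[1..i] against any prefix of the target
# symbol vector, under the Gotoh recurrence with anchored start (path
# position 0 at target position 0) and gap cost open + len * extend.
# Used to cross-check the package's incremental frontier implementation.
oracle_prefix_scores <- function(path_syms, target_syms, scheme) {
  n <- length(path_syms)
  m <- length(target_syms)
  go <- scheme$gap_open; ge <- scheme$gap_extend
  subst <- function(a, b) {
    if (scheme$mode == "nucleotide") {
      if (a == b && b != "N") scheme$reward else -scheme$penalty
    } else {
      if (a == "*") min(scheme$matrix["*", b]) else scheme$matrix[a, b]
    }
  }
  M <- matrix(-Inf, n + 1L, m + 1L)
  X <- matrix(-Inf, n + 1L, m + 1L)  # gap in target (path consumed)
  Y <- matrix(-Inf, n + 1L, m + 1L)  # gap in path (target consumed)
  M[1L, 1L] <- 0
  for (j in seq_len(m)) Y[1L, j + 1L] <- -(go + ge * j)
  for (i in seq_len(n)) {
    for (j in 0:m) {
      X[i + 1L, j + 1L] <- max(M[i, j + 1L] - go - ge, X[i, j + 1L] - ge)
      if (j > 0L) {
        M[i + 1L, j + 1L] <- subst(path_syms[i], target_syms[j]) +
          max(M[i, j], X[i, j], Y[i, j])
        Y[i + 1L, j + 1L] <- max(M[i + 1L, j] - go - ge, Y[i + 1L, j] - ge)
      }
    }
  }
  vapply(seq_len(n), function(i)
    max(pmax(M[i + 1L, ], X[i + 1L, ])), numeric(1L))
}

# Oracle for a nucleotide path string against a target string.
oracle_scores_nt <- function(path, target_str, scheme) {
  oracle_prefix_scores(strsplit(path, "", fixed = TRUE)[[1L]],
                       strsplit(target_str, "", fixed = TRUE)[[1L]],
                       scheme)
}

# Incremental scores from the package implementation, one per path base
# (nucleotide) or per completed codon (protein).
incremental_scores <- function(path, target_chars, scheme,
                               revcomp_codon = FALSE) {
  st <- alignment_init(target_chars, scheme)
  out <- numeric(0)
  for (b in strsplit(path, "", fixed = TRUE)[[1L]]) {
    r <- extend_alignment(st, b, revcomp_codon = revcomp_codon)
    st <- r$state
    if (scheme$mode == "nucleotide" || length(st$codon_buf) == 0L)
      out <- c(out, st$current_score)
  }
  list(scores = out, state = st)
}

random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]], n, replace = TRUE),
        collapse = "")
}

# Reverse-translate a protein using the standard code (arbitrary codons).
reverse_translate <- function(prot, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  code <- Biostrings::getGeneticCode("1")
  aa <- strsplit(prot, "", fixed = TRUE)[[1L]]
  paste(vapply(aa, function(a) {
    cands <- names(code)[code == a]
    sample(cands, 1L)
  }, character(1L)), collapse = "")
}
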