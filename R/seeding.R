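#' Nucleotide good-alignment test for a k-mer at a target position
#'
#' A k-mer S has a good alignment at target position p (0-based) when
#' (1) the last `word` bases of S exactly match the last `word` bases of
#' the target window, and (2) the number of Hamming matches M exceeds
#' `min(k - 1, V)` with `V = floor(k/10) + k * penalty / (reward + penalty)`.
#' For reverse orientation the first `word` bases of the reverse
#' complement of S are matched against the start of the window (the seed
#' hash is built over k-mer suffixes).
#'
#' @param S oriented k-mer.
#' @param target a `target` (nucleotide).
#' @param p 0-based target position.
#' @param scheme a `scoring_scheme` (nucleotide).
#' @param orientation `"forward"` or `"reverse"`.
#' @return logical.
#' @export
good_alignment_nt <- function(S, target, p, scheme, orientation = "forward") {
  k <- nchar(S)
  tl <- nchar(target$sequence)
  if (p + k > tl) return(FALSE)
  if (any(target$mask[(p + 1L):(p + k)])) return(FALSE)
  R <- substr(target$sequence, p + 1L, p + k)
  w <- scheme$word
  Sor <- if (orientation == "forward") S else revcomp(S)
  ok_word <- if (orientation == "forward")
    substr(Sor, k - w + 1L, k) == substr(R, k - w + 1L, k)
  else
    substr(Sor, 1L, w) == substr(R, 1L, w)
  if (!ok_word) return(FALSE)
  M <- hamming_matches(Sor, R)
  V <- floor(k / 10) + k * scheme$penalty / (scheme$reward + scheme$penalty)
  M > min(k - 1, V)
}

#' Protein good-alignment test for a k-mer at a target residue position
#'
#' The translation T of S (reverse complement of S for reverse
#' orientation) must match the target fragment R exactly over the last
#' `word/3` residues (first `word/3` for reverse orientation), and the
#' gap-free BLOSUM62 score of R vs T must exceed `0.75 * self_score(R)`.
#'
#' @param S oriented k-mer (length a multiple of 3).
#' @param target a `target` (protein).
#' @param p 0-based residue position.
#' @param scheme a `scoring_scheme` (protein).
#' @param orientation `"forward"` or `"reverse"`.
#' @return logical.
#' @export
good_alignment_prot <- function(S, target, p, scheme, orientation = "forward") {
  k <- nchar(S)
  stopifnot(k %% 3L == 0L)
  ka <- k %/% 3L
  tl <- nchar(target$sequence)
  if (p + ka > tl) return(FALSE)
  if (any(target$mask[(p + 1L):(p + ka)])) return(FALSE)
  R <- substr(target$sequence, p + 1L, p + ka)
  Sor <- if (orientation == "forward") S else revcomp(S)
  Tt <- tryCatch(translate_dna(Sor, scheme$genetic_code),
                 error = function(e) NULL)
  if (is.null(Tt) || grepl("*", Tt, fixed = TRUE)) return(FALSE)
  wa <- scheme$word %/% 3L
  ok_word <- if (orientation == "forward")
    substr(Tt, ka - wa + 1L, ka) == substr(R, ka - wa + 1L, ka)
  else
    substr(Tt, 1L, wa) == substr(R, 1L, wa)
  if (!ok_word) return(FALSE)
  blosum_pair_score(R, Tt, scheme$matrix) > 0.75 * self_score(R, scheme$matrix)
}

## Existential DFS: can `kmer` extend by at least `depth` node steps in
## the graph on `side`? Cycles may contribute length.
can_extend_bp <- function(dbg, kmer, side, depth) {
  if (depth <= 0L) return(TRUE)
  stack <- list(list(km = kmer, d = 0L))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    ext <- .dbg_ext(dbg, top$km, side)
    if (length(ext$base) == 0L) next
    if (top$d + 1L >= depth) return(TRUE)
    k <- dbg$k
    for (b in ext$base) {
      nk <- if (side == "right")
        paste0(substr(top$km, 2L, k), b) else paste0(b, substr(top$km, 1L, k - 1L))
      stack[[length(stack) + 1L]] <- list(km = nk, d = top$d + 1L)
    }
  }
  FALSE
}

#' Find seed k-mers for a target
#'
#' Seeds anchor assembly. A graph k-mer K with read count L is a seed when
#' it (1) is in the primary graph, (2) has a good alignment to exactly one
#' target position p over both orientations, (3) can extend about 100 bp
#' from both ends in the graph (skipped on the side where p is within
#' 100 bp / 34 aa of the target end when `protect_reference_ends` is set),
#' (4) has L > 1, and (5) has `L >= N * fraction` where N is the maximum
#' read count among k-mers satisfying (1)-(4) at p. The strand-balance
#' rule used for extension choices also applies per position: candidates
#' seen predominantly on one strand are dropped when a balanced candidate
#' seeds the same position (keeps strand-specific sequencing errors out
#' of the seed pool). Positions where the
#' number of surviving k-mers reaches `kmer_complexity` lose all their
#' seeds and the k-length target window starting there is hard-masked.
#'
#' Candidate placements come from hashing target words of length `word`
#' (bases, or `word/3` residues for protein targets) and matching k-mer
#' suffix words in both orientations.
#'
#' @param dbg primary `dbg`.
#' @param target a `target` (its mask may be updated).
#' @param scheme a `scoring_scheme`.
#' @param fraction per-position read-count fraction filter (default 0.05).
#' @param kmer_complexity position seed-count cutoff (default 2000).
#' @param protect_reference_ends logical.
#' @return list with `seeds` (data.frame `kmer`, `target_pos`,
#'   `orientation`, `count`) and `target` (possibly re-masked).
#' @export
find_seeds <- function(dbg, target, scheme,
                       fraction = 0.05, kmer_complexity = 2000L,
                       protect_reference_ends = FALSE) {
  k <- dbg$k
  protein <- target$alphabet == "protein"
  k_t <- if (protein) k %/% 3L else k       # target units spanned by a k-mer
  w_t <- if (protein) scheme$word %/% 3L else scheme$word
  tl <- nchar(target$sequence)
  good_fun <- if (protein) good_alignment_prot else good_alignment_nt

  ## hash of target words -> start positions (0-based)
  word_pos <- new.env(hash = TRUE, parent = emptyenv())
  if (tl >= w_t) {
    starts <- 0:(tl - w_t)
    words <- substring(target$sequence, starts + 1L, starts + w_t)
    for (i in seq_along(words)) {
      assign(words[i], c(get0(words[i], envir = word_pos, inherits = FALSE),
                         starts[i]), envir = word_pos)
    }
  }

  ## candidate (kmer, pos, orientation) triples via suffix-word matching
  cand_k <- character(0); cand_p <- integer(0); cand_o <- character(0)
  for (km in dbg$kmers) {
    for (orient in c("forward", "reverse")) {
      Sor <- if (orient == "forward") km else revcomp(km)
      if (protein) {
        Tt <- tryCatch(translate_dna(Sor, scheme$genetic_code),
                       error = function(e) NULL)
        if (is.null(Tt)) next
        wrd <- if (orient == "forward")
          substr(Tt, nchar(Tt) - w_t + 1L, nchar(Tt)) else substr(Tt, 1L, w_t)
      } else {
        wrd <- if (orient == "forward")
          substr(Sor, k - w_t + 1L, k) else substr(Sor, 1L, w_t)
      }
      qpos <- get0(wrd, envir = word_pos, inherits = FALSE)
      if (is.null(qpos)) next
      ## word start q maps to window start p
      p <- if (orient == "forward") qpos - (k_t - w_t) else qpos
      p <- p[p >= 0L & p + k_t <= tl]
      for (pp in p) {
        if (good_fun(km, target, pp, scheme, orient)) {
          cand_k <- c(cand_k, km); cand_p <- c(cand_p, pp)
          cand_o <- c(cand_o, orient)
        }
      }
    }
  }

  empty <- data.frame(kmer = character(0), target_pos = integer(0),
                      orientation = character(0), count = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(cand_k) == 0L) return(list(seeds = empty, target = target))

  ## uniqueness: exactly one good-alignment position (over both orientations)
  df <- data.frame(kmer = cand_k, target_pos = cand_p, orientation = cand_o,
                   stringsAsFactors = FALSE)
  df <- unique(df)
  npos <- tapply(df$target_pos, df$kmer, function(x) length(unique(x)))
  multi <- names(npos[npos > 1L])
  ## a k-mer good-aligning forward at one position and reverse at another
  ## violates uniqueness (logged, not silently guessed)
  if (length(multi))
    message(sprintf("seeding %s: %d k-mers aligned at multiple positions, discarded",
                    target$id, length(multi)))
  df <- df[!(df$kmer %in% multi), , drop = FALSE]
  ## same kmer, same position, both orientations: keep forward
  df <- df[order(df$target_pos, df$kmer, df$orientation), , drop = FALSE]
  df <- df[!duplicated(df[c("kmer", "target_pos")]), , drop = FALSE]
  if (nrow(df) == 0L) return(list(seeds = empty, target = target))

  ## read count (L > 1)
  cnt <- vapply(df$kmer, function(km) {
    v <- dbg_lookup(dbg, km); if (is.null(v)) 0 else sum(v)
  }, numeric(1L))
  df$count <- cnt
  df <- df[df$count > 1, , drop = FALSE]
  if (nrow(df) == 0L) return(list(seeds = empty, target = target))

  ## 100-bp extensibility from both ends (existential DFS)
  depth <- max(0L, 100L - k + 1L)
  end_prot_units <- if (protein) 34L else 100L
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    p <- df$target_pos[i]
    skip_left <- protect_reference_ends && p < end_prot_units
    skip_right <- protect_reference_ends && (tl - (p + k_t)) < end_prot_units
    ## left/right in target frame; reverse-orientation k-mers swap sides
    fwd <- df$orientation[i] == "forward"
    left_side <- if (fwd) "left" else "right"
    right_side <- if (fwd) "right" else "left"
    ok_l <- skip_left || can_extend_bp(dbg, df$kmer[i], left_side, depth)
    ok_r <- skip_right || can_extend_bp(dbg, df$kmer[i], right_side, depth)
    keep[i] <- ok_l && ok_r
  }
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0L) return(list(seeds = empty, target = target))

  ## per-position fraction filter and strand-balance rule (a candidate
  ## seen predominantly on one strand is dropped when a balanced
  ## candidate seeds the same position -- keeps strand-specific
  ## sequencing errors out of the seed pool), then complexity cutoff +
  ## hard-masking
  strand <- vapply(df$kmer, function(km) {
    v <- dbg_lookup(dbg, km)
    min(v) / max(sum(v), 1)
  }, numeric(1L))
  out <- df[0, , drop = FALSE]
  for (p in sort(unique(df$target_pos))) {
    sel <- df$target_pos == p
    at_p <- df[sel, , drop = FALSE]
    balanced <- strand[sel] >= 0.1
    if (any(balanced) && !all(balanced))
      at_p <- at_p[balanced, , drop = FALSE]
    N <- max(at_p$count)
    at_p <- at_p[at_p$count >= N * fraction, , drop = FALSE]
    if (nrow(at_p) >= kmer_complexity) {
      win <- (p + 1L):min(tl, p + k_t)
      target$mask[win] <- TRUE
    } else {
      out <- rbind(out, at_p)
    }
  }
  ## drop seeds whose window now overlaps a masked position
  if (any(target$mask) && nrow(out)) {
    ok <- vapply(seq_len(nrow(out)), function(i) {
      win <- (out$target_pos[i] + 1L):(out$target_pos[i] + k_t)
      !any(target$mask[win])
    }, logical(1L))
    out <- out[ok, , drop = FALSE]
  }
  rownames(out) <- NULL
  list(seeds = out, target = target)
}
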