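#' Default assembly parameters
#'
#' @param min_count minimum k-mer count for the graphs (default 2; 1 for
#'   low-coverage runs).
#' @param extension_fraction extension-candidate noise cutoff relative to
#'   the maximum candidate count (default 0.1).
#' @param strand_fraction minor-strand fraction below which a candidate
#'   counts as predominantly one strand (default 0.1).
#' @param secondary_kmer_threshold read count at or below which a single
#'   primary extension also consults the secondary graph (default 1).
#' @param buf_length trailing window for the fork-density guard (default
#'   200 bp).
#' @param max_fork_density abort assembling the current seed when the
#'   fork density of the trailing window exceeds this (default 0.1).
#' @param branch_budget per-seed cap on explored branches.
#' @param fraction seed read-count fraction filter (default 0.05).
#' @param kmer_complexity seed-count cutoff per target position (default
#'   2000).
#' @param protect_reference_ends skip the 100-bp extensibility check near
#'   target ends (RNA-seq style runs).
#' @param aligned_count,not_aligned_count,not_aligned_len read/pair
#'   filtering thresholds (defaults 2, 3, 10).
#' @param max_path cap on sequences enumerated when expanding around a
#'   fork for filtering (default 1000).
#' @param target_coverage minimum assembled fraction of the target length
#'   for a variant to be reported (default 0.5).
#' @param min_hit_len absolute minimum variant length overriding
#'   `target_coverage` when set.
#' @param max_variants maximum variants reported per graph (default 1000).
#' @param keep_subgraphs disable cross-target redundancy removal.
#' @param extend_ends extend terminal segments through unambiguous graph
#'   steps after filtering.
#' @param collapse_snps collapse substitution-only bubbles into IUPAC
#'   ambiguity codes.
#' @return named list of parameters.
#' @export
assembly_params <- function(min_count = 2L,
                            extension_fraction = 0.1,
                            strand_fraction = 0.1,
                            secondary_kmer_threshold = 1L,
                            buf_length = 200L,
                            max_fork_density = 0.1,
                            branch_budget = 10000L,
                            fraction = 0.05,
                            kmer_complexity = 2000L,
                            protect_reference_ends = FALSE,
                            aligned_count = 2L,
                            not_aligned_count = 3L,
                            not_aligned_len = 10L,
                            max_path = 1000L,
                            target_coverage = 0.5,
                            min_hit_len = NULL,
                            max_variants = 1000L,
                            keep_subgraphs = FALSE,
                            extend_ends = FALSE,
                            collapse_snps = FALSE) {
  as.list(environment())
}

#' Classify the extension of an oriented k-mer
#'
#' Candidate bases come from the primary graph. Candidates with count
#' below `extension_fraction` times the maximum candidate count are noise
#' and dropped. If more than one candidate survives and at least one has
#' counts balanced across strands, candidates seen predominantly on one
#' strand are dropped. More than one survivor is a fork; survivors are
#' ordered by descending count with ties broken lexicographically.
#'
#' @param dbg_primary primary `dbg`.
#' @param kmer oriented k-mer.
#' @param params `assembly_params()`.
#' @return list with `type` (`"dead_end"`, `"single"` or `"fork"`) and
#'   `bases` (ordered data.frame of surviving candidates).
#' @export
classify_extension <- function(dbg_primary, kmer, params = assembly_params()) {
  e <- .filter_candidates(.dbg_ext(dbg_primary, kmer), params)
  list(type = if (length(e$base) == 0L) "dead_end"
              else if (length(e$base) == 1L) "single" else "fork",
       bases = data.frame(base = e$base, count = e$count, fwd = e$fwd,
                          rev = e$rev, stringsAsFactors = FALSE))
}

## Noise + strand filtering and ordering of an extension candidate list.
.filter_candidates <- function(e, params) {
  n <- length(e$base)
  if (n == 0L) return(e)
  keep <- e$count >= max(e$count) * params$extension_fraction
  if (!all(keep)) {
    e <- lapply(e, `[`, keep)
    n <- length(e$base)
  }
  if (n > 1L) {
    minor <- pmin(e$fwd, e$rev)
    balanced <- minor >= params$strand_fraction * e$count & minor > 0
    if (any(balanced) && !all(balanced)) {
      e <- lapply(e, `[`, balanced)
      n <- length(e$base)
    }
  }
  if (n > 1L) {
    o <- order(-e$count, e$base)
    e <- lapply(e, `[`, o)
  }
  e
}

#' Secondary-graph rescue of an extension
#'
#' Consulted when the primary graph offers no extension, or a single
#' extension whose new k-mer count is at most `secondary_kmer_threshold`
#' (with the default minimum count of 2 and threshold 1 the second case
#' never fires; it matters for low-coverage runs with min_count 1). The
#' candidate base must complete a secondary-k k-mer present in the
#' secondary graph; the next step reverts to the primary k.
#'
#' @param path current path string (working frame).
#' @param dbg_secondary secondary `dbg`.
#' @param params `assembly_params()`.
#' @return data.frame of candidate bases with counts (possibly empty).
#' @export
try_secondary_rescue <- function(path, dbg_secondary, params = assembly_params()) {
  e <- .rescue(path, dbg_secondary, params)
  data.frame(base = e$base, count = e$count, fwd = e$fwd, rev = e$rev,
             stringsAsFactors = FALSE)
}

## Lean secondary-rescue candidate query on the path suffix.
.rescue <- function(path, dbg2, params) {
  k2 <- dbg2$k
  n <- nchar(path)
  empty <- list(base = character(0), count = numeric(0),
                fwd = numeric(0), rev = numeric(0))
  if (n < k2 - 1L) return(empty)
  tailk <- substr(path, n - k2 + 2L, n)
  cand <- paste0(tailk, DNA_BASES)
  base <- character(0); fwd <- numeric(0); rv <- numeric(0)
  for (i in 1:4) {
    v <- get0(cand[i], envir = dbg2$env, inherits = FALSE)
    if (!is.null(v)) {
      base <- c(base, DNA_BASES[i]); fwd <- c(fwd, v[1L]); rv <- c(rv, v[2L])
    }
  }
  .filter_candidates(list(base = base, count = fwd + rv, fwd = fwd, rev = rv),
                     params)
}

## Candidates for extending `path` by one base: primary classification plus
## secondary rescue per the trigger rules. Returns an ordered lean list.
.extension_candidates <- function(path, dbg1, dbg2, params) {
  k <- dbg1$k
  n <- nchar(path)
  km <- substr(path, n - k + 1L, n)
  e <- .filter_candidates(.dbg_ext(dbg1, km), params)
  if (!is.null(dbg2)) {
    if (length(e$base) == 0L) {
      e <- .rescue(path, dbg2, params)
    } else if (length(e$base) == 1L) {
      newk <- paste0(substr(km, 2L, k), e$base[1L])
      v <- dbg_lookup(dbg1, newk)
      if (!is.null(v) && sum(v) <= params$secondary_kmer_threshold) {
        resc <- .rescue(path, dbg2, params)
        new <- !(resc$base %in% e$base)
        if (any(new)) {
          e <- list(base = c(e$base, resc$base[new]),
                    count = c(e$count, resc$count[new]),
                    fwd = c(e$fwd, resc$fwd[new]),
                    rev = c(e$rev, resc$rev[new]))
          o <- order(-e$count, e$base)
          e <- lapply(e, `[`, o)
        }
      }
    }
  }
  e
}

## Double-step rule: a base is accepted only if the new k-mer itself
## admits a continuation (primary classification non-dead, or a secondary
## successor exists).
.can_continue <- function(path_plus, dbg1, dbg2, params) {
  k <- dbg1$k
  n <- nchar(path_plus)
  km <- substr(path_plus, n - k + 1L, n)
  e <- .filter_candidates(.dbg_ext(dbg1, km), params)
  if (length(e$base) > 0L) return(TRUE)
  if (is.null(dbg2)) return(FALSE)
  length(.rescue(path_plus, dbg2, params)$base) > 0L
}

#' Fork-density abort test
#'
#' Density is the number of fork positions within the trailing
#' `buf_length` bases divided by `buf_length` (or by the actual extension
#' length when shorter). Assembly of the current seed stops when the
#' density strictly exceeds `max_fork_density`.
#'
#' @param fork_positions integer vector of fork coordinates (bases, along
#'   the extension).
#' @param path_len current extension length in bases.
#' @param params `assembly_params()`.
#' @return logical.
#' @export
fork_density_abort <- function(fork_positions, path_len,
                               params = assembly_params()) {
  buf <- min(params$buf_length, max(path_len, 1L))
  n_forks <- sum(fork_positions > path_len - buf)
  (n_forks / buf) > params$max_fork_density
}

#' Anchor-merge test
#'
#' When appending base `b` yields k-mer `A`, a path merges into a
#' previously registered anchor for `A` if its best-scoring target
#' coordinate matches the registered one; it then stops extending (the
#' continuation already exists). Anchors are registered only while the
#' distance `d` past the best-scoring position is strictly below `k/4`.
#'
#' @param anchors environment mapping k-mer -> best target coordinate.
#' @param A new k-mer.
#' @param best_j current best-scoring target coordinate.
#' @param d bases since the best-scoring position.
#' @param k primary k-mer size.
#' @return `"merged"`, `"registered"` or `"continue"`.
#' @export
merge_at_anchor <- function(anchors, A, best_j, d, k) {
  reg <- get0(A, envir = anchors, inherits = FALSE)
  if (!is.null(reg) && !is.na(best_j) && reg == best_j) return("merged")
  if (is.null(reg) && !is.na(best_j) && !is.na(d) && d < k / 4) {
    assign(A, best_j, envir = anchors)
    return("registered")
  }
  "continue"
}

#' Extend a seed in one direction through the graphs
#'
#' Depth-first exploration of the branch stack starting from the seed
#' sequence (already oriented into the working frame: target frame for
#' right extensions, reverse-complement frame for left extensions). Each
#' accepted base must itself admit a continuation (double-step rule).
#' Paths end at dead ends, drop-off clips (clipped back to the best
#' scoring position, which also discards pending branches beyond it), or
#' anchor merges. Emits only paths whose best-scoring position is known.
#'
#' @param seed_seq working-frame seed sequence (length k).
#' @param target_chars DP target symbols for this direction.
#' @param dbg_primary,dbg_secondary graphs (`dbg_secondary` may be NULL).
#' @param scheme a `scoring_scheme`.
#' @param params `assembly_params()`.
#' @param revcomp_codon protein-mode left-extension codon handling.
#' @return list with `paths` (character, each starting with the seed),
#'   `fork_kmers` (working-frame k-mers at fork/clip positions),
#'   `aborted` (fork-density flag).
#' @export
extend_direction <- function(seed_seq, target_chars, dbg_primary,
                             dbg_secondary, scheme, params = assembly_params(),
                             revcomp_codon = FALSE) {
  k <- dbg_primary$k
  anchors <- new.env(hash = TRUE, parent = emptyenv())
  paths_out <- character(0)
  fork_kmers <- character(0)
  aborted <- FALSE
  budget <- params$branch_budget

  st0 <- alignment_init(target_chars, scheme)
  stack <- list(list(path = seed_seq, state = st0, forks = integer(0)))

  emit <- function(path, state, clip = FALSE) {
    if (is.na(state$best_pos)) return(invisible(NULL))
    if (clip) {
      path <- substr(path, 1L, k + state$best_pos)
      fork_kmers <<- c(fork_kmers,
                       substr(path, nchar(path) - k + 1L, nchar(path)))
    }
    paths_out <<- c(paths_out, path)
    invisible(NULL)
  }

  ## accept one base onto (path, state); returns the updated frame plus a
  ## `stop` reason ("" to continue, "clip", "merged")
  accept_base <- function(path, state, b) {
    res <- extend_alignment(state, b, revcomp_codon = revcomp_codon)
    state <- res$state
    path <- paste0(path, b)
    if (res$verdict == "clip")
      return(list(path = path, state = state, stop = "clip"))
    A <- substr(path, nchar(path) - k + 1L, nchar(path))
    d <- if (is.na(state$best_pos)) NA_integer_ else state$nbases - state$best_pos
    act <- merge_at_anchor(anchors, A, state$best_j, d, k)
    list(path = path, state = state,
         stop = if (act == "merged") "merged" else "")
  }

  while (length(stack) > 0L && budget > 0L && !aborted) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    budget <- budget - 1L
    path <- fr$path; state <- fr$state; forks <- fr$forks
    stopped <- FALSE

    if (!is.null(fr$pending_base)) {    # saved branch: apply its base now
      acc <- accept_base(path, state, fr$pending_base)
      path <- acc$path; state <- acc$state
      if (acc$stop == "clip") {
        emit(path, state, clip = TRUE)
        stopped <- TRUE
      } else if (acc$stop == "merged") {
        emit(path, state)
        stopped <- TRUE
      }
    }

    while (!stopped) {
      ext_len <- nchar(path) - k
      if (fork_density_abort(forks, ext_len, params)) {
        aborted <- TRUE
        emit(path, state)
        break
      }
      cands <- .extension_candidates(path, dbg_primary, dbg_secondary, params)
      if (length(cands$base) > 0L) {
        ok <- vapply(cands$base, function(b)
          .can_continue(paste0(path, b), dbg_primary, dbg_secondary, params),
          logical(1L), USE.NAMES = FALSE)
        cands <- lapply(cands, `[`, ok)
      }
      if (length(cands$base) == 0L) {   # dead end
        emit(path, state)
        break
      }
      if (length(cands$base) > 1L) {    # fork
        forks <- c(forks, ext_len + 1L)
        fork_kmers <- c(fork_kmers, substr(path, nchar(path) - k + 1L, nchar(path)))
        for (b in rev(cands$base[-1L]))
          stack[[length(stack) + 1L]] <-
            list(path = path, state = state, pending_base = b, forks = forks)
      }
      acc <- accept_base(path, state, cands$base[1L])
      path <- acc$path; state <- acc$state
      if (acc$stop == "clip") {
        emit(path, state, clip = TRUE)
        ## stored branch points beyond the best position are clipped away
        if (!is.na(state$best_pos) && length(stack)) {
          keep <- vapply(stack, function(s)
            (nchar(s$path) - k) < state$best_pos, logical(1L))
          stack <- stack[keep]
        }
        break
      }
      if (acc$stop == "merged") {
        emit(path, state)
        break
      }
    }
  }

  list(paths = paths_out, fork_kmers = unique(fork_kmers), aborted = aborted)
}
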