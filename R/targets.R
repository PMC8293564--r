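#' Load target sequences from FASTA
#'
#' @param path FASTA file (nucleotide or amino acid per `alphabet`).
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @return list of `target` objects (fields `id`, `alphabet`, `sequence`,
#'   logical `mask`), in file order. Input is uppercased. Protein
#'   sequences may end in `*` (stripped) but must not contain internal
#'   stops.
#' @export
load_targets <- function(path, alphabet = c("nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  xs <- if (alphabet == "nucleotide")
    Biostrings::readBStringSet(path) else Biostrings::readBStringSet(path)
  if (length(xs) == 0L) stop("empty target file: ", path)
  ids <- sub("\\s.*$", "", names(xs))
  if (anyDuplicated(ids)) stop("duplicate target ids in ", path)
  seqs <- unname(toupper(as.character(xs)))
  lapply(seq_along(ids), function(i) {
    s <- seqs[i]
    if (alphabet == "protein") {
      s <- sub("\\*$", "", s)
      if (grepl("*", s, fixed = TRUE))
        stop("target ", ids[i], " contains an internal stop codon '*'")
      if (grepl("[^ACDEFGHIKLMNPQRSTVWYX]", s))
        stop("illegal characters in protein target ", ids[i])
    } else {
      if (grepl("[^ACGTN]", s))
        stop("illegal characters in nucleotide target ", ids[i])
    }
    new_target(ids[i], alphabet, s)
  })
}

new_target <- function(id, alphabet, sequence) {
  structure(list(id = id, alphabet = alphabet, sequence = sequence,
                 mask = rep(FALSE, nchar(sequence))),
            class = "target")
}

#' Construct a target in code
#' @param sequence sequence string.
#' @param id identifier.
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @return a `target`.
#' @export
target <- function(sequence, id = "target", alphabet = "nucleotide") {
  new_target(id, alphabet, toupper(sequence))
}

#' Masked rendering of a target
#'
#' Hard-masked positions render as N (nucleotide) or X (protein).
#' @param x a `target`.
#' @return character string.
#' @export
masked_sequence <- function(x) {
  if (!any(x$mask)) return(x$sequence)
  chars <- strsplit(x$sequence, "", fixed = TRUE)[[1L]]
  chars[x$mask] <- if (x$alphabet == "protein") "X" else "N"
  paste(chars, collapse = "")
}

#' Alignment scoring scheme
#'
#' Bundles the scoring parameters for aligning assembled paths to a
#' target. Nucleotide mode uses match reward / mismatch penalty; protein
#' mode uses BLOSUM62 (half-bit integer scores) with the path translated
#' codon by codon under the chosen NCBI genetic code. Defaults mirror
#' common BLAST-family settings.
#'
#' @param mode `"nucleotide"` or `"protein"`.
#' @param reward,penalty nucleotide match/mismatch scores (penalty stored
#'   positive).
#' @param gap_open,gap_extend affine gap scores (positive); a gap of
#'   length L costs `gap_open + L * gap_extend`.
#' @param frameshift_open gap-open used for length-1/2 gaps inside a codon
#'   when frameshifts are allowed (must exceed `gap_open`).
#' @param drop_off clip when the running score falls more than this below
#'   the best score.
#' @param word exact-match word size for seeding, in bases (default 8 nt,
#'   12 nt = 4 aa in protein mode).
#' @param genetic_code NCBI translation table id (protein mode).
#' @return a `scoring_scheme`.
#' @export
scoring_scheme <- function(mode = c("nucleotide", "protein"),
                           reward = 1, penalty = 2,
                           gap_open = if (mode == "protein") 11 else 5,
                           gap_extend = if (mode == "protein") 1 else 2,
                           frameshift_open = 30,
                           drop_off = if (mode == "protein") 50 else 25,
                           word = if (mode == "protein") 12L else 8L,
                           genetic_code = 1L) {
  mode <- match.arg(mode)
  stopifnot(reward > 0, penalty > 0, gap_open > 0, gap_extend > 0,
            drop_off > 0, frameshift_open > gap_open)
  if (mode == "protein" && word %% 3L != 0L)
    stop("protein-mode word size must be a multiple of 3 bases")
  structure(list(mode = mode, reward = reward, penalty = penalty,
                 gap_open = gap_open, gap_extend = gap_extend,
                 frameshift_open = frameshift_open, drop_off = drop_off,
                 word = as.integer(word),
                 genetic_code = as.integer(genetic_code),
                 matrix = if (mode == "protein") blosum62() else NULL),
            class = "scoring_scheme")
}

## Genetic-code tables from Biostrings, cached per table id.
.code_cache <- new.env(parent = emptyenv())
.genetic_code <- function(id) {
  key <- as.character(id)
  code <- get0(key, envir = .code_cache)
  if (is.null(code)) {
    code <- Biostrings::getGeneticCode(key)
    assign(key, code, envir = .code_cache)
  }
  code
}

## BLOSUM62 from Biostrings, cached.
.blosum_cache <- new.env(parent = emptyenv())
blosum62 <- function() {
  m <- get0("m", envir = .blosum_cache)
  if (is.null(m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62
    assign("m", m, envir = .blosum_cache)
  }
  m
}

#' Translate DNA under an NCBI genetic-code table
#'
#' @param nt DNA string, length a multiple of 3, no N.
#' @param genetic_code NCBI translation table id (default 1). Stop codons
#'   translate to `*`.
#' @return protein string.
#' @export
translate_dna <- function(nt, genetic_code = 1L) {
  n <- nchar(nt)
  if (n %% 3L != 0L) stop("sequence length not a multiple of 3")
  if (n == 0L) return("")
  code <- .genetic_code(genetic_code)
  starts <- seq(1L, n, by = 3L)
  codons <- substring(nt, starts, starts + 2L)
  paste(unname(code[codons]), collapse = "")
}

#' Self-score of a protein fragment under BLOSUM62
#'
#' Sum of diagonal matrix entries over the fragment's residues.
#'
#' @param fragment protein string (non-empty).
#' @param matrix substitution matrix (default BLOSUM62).
#' @return integer score.
#' @export
self_score <- function(fragment, matrix = blosum62()) {
  if (nchar(fragment) == 0L) stop("empty protein fragment")
  aa <- strsplit(fragment, "", fixed = TRUE)[[1L]]
  sum(matrix[cbind(aa, aa)])
}

## Gap-free BLOSUM score of two equal-length protein strings.
blosum_pair_score <- function(a, b, matrix = blosum62()) {
  av <- strsplit(a, "", fixed = TRUE)[[1L]]
  bv <- strsplit(b, "", fixed = TRUE)[[1L]]
  stopifnot(length(av) == length(bv))
  sum(matrix[cbind(av, bv)])
}

## Substitution score of one path symbol against a vector of target symbols.
.sub_scores <- function(sym, tvec, scheme) {
  if (scheme$mode == "nucleotide") {
    ifelse(tvec == sym & tvec != "N", scheme$reward, -scheme$penalty)
  } else {
    m <- scheme$matrix
    ## masked residues (X) score via the matrix X row; '*' in path uses the
    ## minimum of the matrix '*' column (path not force-terminated here).
    if (sym == "*") {
      rep(min(m["*", intersect(colnames(m), unique(tvec))]), length(tvec))
    } else {
      m[sym, tvec]
    }
  }
}

#' Initialise an incremental path-to-target alignment
#'
#' Sets up the affine-gap dynamic-programming frontier for extending a
#' path co-linearly against a target suffix, anchored so that path
#' position 0 aligns to target position 0 of `target_chars`. The initial
#' state has best score 0 and unknown best position.
#'
#' @param target_chars character vector of target symbols in extension
#'   order (bases, or residues in protein mode), already oriented for the
#'   extension direction.
#' @param scheme a `scoring_scheme`.
#' @return an `alignment_state`.
#' @export
alignment_init <- function(target_chars, scheme) {
  tl <- length(target_chars)
  go <- scheme$gap_open; ge <- scheme$gap_extend
  M <- c(0, rep(-Inf, tl))
  Y <- c(-Inf, if (tl) -(go + ge * seq_len(tl)) else numeric(0))
  X <- rep(-Inf, tl + 1L)
  structure(list(scheme = scheme, tchars = target_chars,
                 M = M, X = X, Y = Y,
                 i = 0L, nbases = 0L, codon_buf = character(0),
                 best_score = 0, best_pos = NA_integer_, best_j = NA_integer_,
                 current_score = 0),
            class = "alignment_state")
}

## Advance the DP frontier by one path symbol. Internal.
.advance_row <- function(st, sym) {
  sc <- st$scheme; tl <- length(st$tchars)
  go <- sc$gap_open; ge <- sc$gap_extend
  s <- if (tl) .sub_scores(sym, st$tchars, sc) else numeric(0)
  prevbest <- pmax(st$M, st$X, st$Y)
  Mn <- c(-Inf, if (tl) s + prevbest[seq_len(tl)] else numeric(0))
  Xn <- pmax(st$M - go - ge, st$X - ge)
  if (tl) {
    idx <- 0:tl
    run <- cummax(Mn + idx * ge)
    Yn <- c(-Inf, run[seq_len(tl)] - go - (seq_len(tl)) * ge)
  } else Yn <- -Inf
  st$M <- Mn; st$X <- Xn; st$Y <- Yn
  st$i <- st$i + 1L
  ends <- pmax(Mn, Xn)
  st$current_score <- max(ends)
  st$cur_j <- which.max(ends) - 1L
  st
}

#' Extend an incremental alignment by one path base
#'
#' In nucleotide mode every base advances the DP by one position. In
#' protein mode bases are buffered and the DP advances one residue per
#' complete codon (translated on the fly; `revcomp_codon = TRUE` for left
#' extensions, where appended bases are the reverse complement of the
#' original codon). The verdict is `"improved"` when the score sets a new
#' best, `"within_dropoff"` while the deficit is at most `drop_off`, and
#' `"clip"` once the deficit exceeds it: the caller should clip the path
#' back to `best_pos` (a path coordinate in bases).
#'
#' @param state an `alignment_state`.
#' @param new_base one of A/C/G/T.
#' @param revcomp_codon logical; protein left-extension codon handling.
#' @return list with `state` and `verdict`.
#' @export
extend_alignment <- function(state, new_base, revcomp_codon = FALSE) {
  sc <- state$scheme
  state$nbases <- state$nbases + 1L
  if (sc$mode == "nucleotide") {
    state <- .advance_row(state, new_base)
  } else {
    state$codon_buf <- c(state$codon_buf, new_base)
    if (length(state$codon_buf) == 3L) {
      codon <- paste(state$codon_buf, collapse = "")
      if (revcomp_codon) codon <- revcomp(codon)
      aa <- translate_dna(codon, sc$genetic_code)
      state$codon_buf <- character(0)
      state <- .advance_row(state, aa)
    } else {
      ## mid-codon: score unchanged, cannot clip yet
      return(list(state = state,
                  verdict = if (state$best_score - state$current_score > sc$drop_off)
                    "clip" else "within_dropoff"))
    }
  }
  verdict <- if (state$current_score > state$best_score) {
    state$best_score <- state$current_score
    state$best_pos <- state$nbases
    state$best_j <- state$cur_j
    "improved"
  } else if (state$best_score - state$current_score > sc$drop_off) {
    "clip"
  } else "within_dropoff"
  list(state = state, verdict = verdict)
}
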