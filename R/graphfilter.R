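#' Read support for one fork-context path
#'
#' For a path A-C-D (left choice, middle segment, right choice), reads
#' containing the sequence of C (either strand) are anchored at C and
#' extended outward without mismatches. A read confirms the path when the
#' extension covers at least Y bases of A and Y bases of D. It
#' contradicts the path when one side satisfies the condition, zero bases
#' align to the other side, and at least 2Y unaligned read bases were
#' available toward that side. Y is half of `not_aligned_len`.
#'
#' @param a,c_,d sequences of the three segments (target orientation),
#'   overlapping by `overlap` bases at each junction.
#' @param reads a `read_set`.
#' @param y integer Y.
#' @param overlap link overlap (k - 1).
#' @return list with `confirm` and `contradict` counts.
#' @export
support_by_reads <- function(a, c_, d, reads, y, overlap) {
  path <- paste0(a, substring(c_, overlap + 1L), substring(d, overlap + 1L))
  c_start <- nchar(a) - overlap + 1L        # C occupies c_start..c_end in path
  c_end <- c_start + nchar(c_) - 1L
  pl <- nchar(path)
  confirm <- 0L; contradict <- 0L
  pchars <- strsplit(path, "", fixed = TRUE)[[1L]]
  for (i in seq_along(reads$seq)) {
    verdict <- 0L  # 1 confirm, -1 contradict
    for (r in c(reads$seq[i], revcomp(reads$seq[i]))) {
      hits <- gregexpr(c_, r, fixed = TRUE)[[1L]]
      if (hits[1L] == -1L) next
      rchars <- strsplit(r, "", fixed = TRUE)[[1L]]
      rl <- length(rchars)
      for (h in hits) {
        ## read position h aligns to path position c_start
        off <- c_start - h          # path = read index + off
        ## extend left
        la <- 0L
        ri <- h - 1L
        while (ri >= 1L && ri + off >= 1L && rchars[ri] == pchars[ri + off]) {
          la <- la + 1L; ri <- ri - 1L
        }
        left_avail <- h - 1L
        ## extend right
        ra <- 0L
        ri <- h + nchar(c_)
        while (ri <= rl && ri + off <= pl && rchars[ri] == pchars[ri + off]) {
          ra <- ra + 1L; ri <- ri + 1L
        }
        right_avail <- rl - (h + nchar(c_) - 1L)
        ## bases aligned beyond C into A / D
        in_a <- max(0L, min(la, c_start - 1L))
        in_d <- max(0L, min(ra, pl - c_end))
        if (in_a >= y && in_d >= y) { verdict <- 1L; break }
        if (in_a >= y && in_d == 0L && right_avail >= 2L * y) verdict <- -1L
        if (in_d >= y && in_a == 0L && left_avail >= 2L * y) verdict <- -1L
      }
      if (verdict == 1L) break
    }
    if (verdict == 1L) confirm <- confirm + 1L
    else if (verdict == -1L) contradict <- contradict + 1L
  }
  list(confirm = confirm, contradict = contradict)
}

## Exact seed-and-extend placement of a mate on a path string: exact
## 12-mer anchors slid every 6 bases, each extended to its maximal exact
## match (a mismatch stops the extension, per the
## extend-without-mismatches rule). Returns a list of matched intervals
## c(s_start, s_end, m_start, m_end).
.anchor_w <- 12L
.place_mate <- function(m, pchars, pidx) {
  ml <- nchar(m)
  if (ml < .anchor_w) return(list())
  anchors <- unique(c(seq(1L, ml - .anchor_w + 1L, by = 6L), ml - .anchor_w + 1L))
  mchars <- strsplit(m, "", fixed = TRUE)[[1L]]
  pl <- length(pchars)
  out <- list()
  seen_off <- integer(0)
  for (a in anchors) {
    w <- substr(m, a, a + .anchor_w - 1L)
    pos <- get0(w, envir = pidx, inherits = FALSE)
    if (is.null(pos)) next
    for (s in pos) {
      off <- s - a                 # path index = mate index + off
      if (off %in% seen_off) next
      seen_off <- c(seen_off, off)
      ## maximal exact extension around the anchor
      lo <- a
      while (lo > 1L && lo - 1L + off >= 1L && mchars[lo - 1L] == pchars[lo - 1L + off])
        lo <- lo - 1L
      hi <- a + .anchor_w - 1L
      while (hi < ml && hi + 1L + off <= pl && mchars[hi + 1L] == pchars[hi + 1L + off])
        hi <- hi + 1L
      out[[length(out) + 1L]] <- c(lo + off, hi + off, lo, hi)
    }
  }
  out
}

## Judge one junction (first base of the right part at path position j)
## from a matched interval iv = c(s_start, s_end, m_start, m_end) of a
## mate of length ml. Returns 1 confirm, -1 contradict, 0 neither.
.judge_junction <- function(iv, j, y, ml) {
  sa <- iv[1L]; sb <- iv[2L]
  if (sa <= j - y && sb >= j + y - 1L) return(1L)
  ## approached from the left, stopped exactly at the junction
  if (sb == j - 1L && sa <= j - y && (ml - iv[4L]) >= 2L * y) return(-1L)
  ## approached from the right, stopped exactly at the junction
  if (sa == j && sb >= j + y - 1L && (iv[3L] - 1L) >= 2L * y) return(-1L)
  0L
}

#' Read-pair support for one fork-context path
#'
#' One mate is judged at the left fork junction and the other at the
#' right fork junction, with the implied pair span within the insert
#' range and innie orientation. Confirmation and contradiction follow the
#' same Y rules as read support, applied per junction per mate.
#'
#' @param a,c_,d segment sequences as in [support_by_reads()].
#' @param reads a `read_set` with pairs.
#' @param insert list with `min_len`, `max_len`.
#' @param y integer Y.
#' @param overlap link overlap.
#' @param left_ctx,right_ctx optional extra context sequence prepended to
#'   A / appended to D (expansion for mate placement).
#' @return list with `confirm` and `contradict`.
#' @export
support_by_pairs <- function(a, c_, d, reads, insert, y, overlap,
                             left_ctx = "", right_ctx = "") {
  path <- paste0(left_ctx, a, substring(c_, overlap + 1L),
                 substring(d, overlap + 1L), right_ctx)
  jl <- nchar(left_ctx) + nchar(a) - overlap + 1L   # first base of C region
  jr <- jl + nchar(c_)                              # first base of D-exclusive
  pchars <- strsplit(path, "", fixed = TRUE)[[1L]]
  pl <- length(pchars)
  pidx <- new.env(hash = TRUE, parent = emptyenv())
  if (pl >= .anchor_w) {
    starts <- seq_len(pl - .anchor_w + 1L)
    wins <- substring(path, starts, starts + .anchor_w - 1L)
    for (i in seq_along(wins))
      assign(wins[i], c(get0(wins[i], envir = pidx, inherits = FALSE),
                        starts[i]), envir = pidx)
  }
  pids <- unique(reads$pair_id[!is.na(reads$pair_id)])
  confirm <- 0L; contradict <- 0L
  for (pid in pids) {
    m0 <- reads$seq[which(reads$pair_id == pid & reads$mate == 0L)]
    m1 <- reads$seq[which(reads$pair_id == pid & reads$mate == 1L)]
    if (length(m0) != 1L || length(m1) != 1L) next
    verdict <- 0L
    for (assignment in 1:2) {
      f <- if (assignment == 1L) m0 else m1        # forward, left side
      r <- revcomp(if (assignment == 1L) m1 else m0)  # reverse mate, right side
      pf <- .place_mate(f, pchars, pidx)
      pr <- .place_mate(r, pchars, pidx)
      if (!length(pf) || !length(pr)) next
      for (ivf in pf) for (ivr in pr) {
        span <- (ivr[2L] + (nchar(r) - ivr[4L])) - (ivf[1L] - (ivf[3L] - 1L)) + 1L
        if (span < insert$min_len || span > insert$max_len) next
        if (ivf[1L] > ivr[1L]) next                # innie order
        vl <- .judge_junction(ivf, jl, y, nchar(f))
        vr <- .judge_junction(ivr, jr, y, nchar(r))
        if (vl == 1L && vr == 1L) { verdict <- 1L; break }
        if ((vl == 1L && vr == -1L) || (vl == -1L && vr == 1L)) verdict <- -1L
      }
      if (verdict == 1L) break
    }
    if (verdict == 1L) confirm <- confirm + 1L
    else if (verdict == -1L) contradict <- contradict + 1L
  }
  list(confirm = confirm, contradict = contradict)
}

## Expand context upstream (side = "left") or downstream of a segment
## through unambiguous links, up to `cap` extra bases.
.expand_context <- function(g, seg, side, cap) {
  ctx <- ""
  cur <- seg
  while (nchar(ctx) < cap) {
    nb <- if (side == "left") seg_preds(g, cur) else seg_succs(g, cur)
    if (length(nb) != 1L) break
    other <- if (side == "left") seg_succs(g, nb) else seg_preds(g, nb)
    if (length(other) != 1L) break
    nxt <- nb
    if (nxt == seg || nxt == cur) break
    s <- g$segments[[nxt]]
    body <- if (side == "left") substr(s, 1L, nchar(s) - g$k + 1L)
            else substring(s, g$k)
    ctx <- if (side == "left") paste0(body, ctx) else paste0(ctx, body)
    cur <- nxt
  }
  if (nchar(ctx) > cap) {
    ctx <- if (side == "left") substring(ctx, nchar(ctx) - cap + 1L)
           else substr(ctx, 1L, cap)
  }
  ctx
}

## Apply removals for one context: drop disallowed (left, right)
## combinations around middle segment mid, duplicating mid as needed.
.apply_context_removal <- function(g, mid, allowed) {
  all_lefts <- sort(seg_preds(g, mid))
  right_sets <- lapply(all_lefts, function(L)
    sort(allowed$right[allowed$left == L]))
  names(right_sets) <- all_lefts
  ## group left choices by identical allowed right sets; each group gets
  ## its own copy of the middle segment (the first reuses it)
  keys <- vapply(right_sets, paste, character(1L), collapse = ",")
  groups <- split(all_lefts, keys)
  g$links <- g$links[g$links$to != mid & g$links$from != mid, , drop = FALSE]
  used_mid <- FALSE
  copy_i <- 0L
  for (key in sort(names(groups), decreasing = TRUE)) {
    gl <- groups[[key]]
    rset <- right_sets[[gl[1L]]]
    if (length(rset) == 0L) next        # these left choices lose the path
    if (!used_mid) {
      node <- mid
      used_mid <- TRUE
    } else {
      copy_i <- copy_i + 1L
      node <- sprintf("%s.%d", mid, copy_i)
      g$segments[node] <- g$segments[[mid]]
    }
    g$links <- rbind(g$links,
                     data.frame(from = gl, to = node, overlap = g$k - 1L,
                                stringsAsFactors = FALSE),
                     data.frame(from = node, to = rset, overlap = g$k - 1L,
                                stringsAsFactors = FALSE))
  }
  g$links <- unique(g$links)
  rownames(g$links) <- NULL
  g
}

#' Filter an assembled graph by reads and read pairs
#'
#' For every segment flanked by forks on both sides, confirm and
#' contradict counts are computed for each left-right combination, first
#' from single reads, then from read pairs (with the pair span checked
#' against the insert range). A combination is removed when its
#' contradict count reaches `not_aligned_count` and its confirm count is
#' strictly below `aligned_count`; removal may duplicate the middle
#' segment. If the segment count grows beyond 15 times the initial
#' count, the whole filtering pass is rolled back and the input graph
#' returned unchanged.
#'
#' @param g an `assembled_graph`.
#' @param reads a `read_set`.
#' @param insert insert-size range (list with `min_len`, `max_len`), or
#'   NULL to skip pair filtering.
#' @param params `assembly_params()`.
#' @return filtered `assembled_graph`.
#' @export
filter_graph <- function(g, reads, insert = NULL, params = assembly_params()) {
  init_n <- max(1L, length(g$segments))
  y <- params$not_aligned_len %/% 2L
  g0 <- g
  has_pairs <- !is.null(insert) && any(!is.na(reads$pair_id))

  for (mode in c("reads", if (has_pairs) "pairs")) {
    mids <- names(g$segments)[vapply(names(g$segments), function(s)
      length(seg_preds(g, s)) >= 2L && length(seg_succs(g, s)) >= 2L,
      logical(1L))]
    for (mid in mids) {
      P <- sort(seg_preds(g, mid)); S <- sort(seg_succs(g, mid))
      if (length(P) < 2L || length(S) < 2L) next
      combos <- expand.grid(left = P, right = S, stringsAsFactors = FALSE)
      keep <- logical(nrow(combos))
      for (ci in seq_len(nrow(combos))) {
        A <- g$segments[[combos$left[ci]]]
        D <- g$segments[[combos$right[ci]]]
        C <- g$segments[[mid]]
        sup <- if (mode == "reads") {
          support_by_reads(A, C, D, reads, y, g$k - 1L)
        } else {
          cap <- min(insert$max_len, params$max_path)
          support_by_pairs(A, C, D, reads, insert, y, g$k - 1L,
                           left_ctx = .expand_context(g, combos$left[ci], "left", cap),
                           right_ctx = .expand_context(g, combos$right[ci], "right", cap))
        }
        keep[ci] <- !(sup$contradict >= params$not_aligned_count &&
                      sup$confirm < params$aligned_count)
      }
      if (all(keep)) next
      g <- .apply_context_removal(g, mid, combos[keep, , drop = FALSE])
      if (length(g$segments) > 15L * init_n) return(g0)
    }
  }
  if (length(g$segments) > 15L * init_n) return(g0)
  simplify_graph(g)
}
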