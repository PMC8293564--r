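#' Remove cross-target redundant graphs
#'
#' A graph X is redundant when its full canonical secondary-k k-mer set
#' is contained in another graph's set; mutual containment keeps the
#' first by target order. With `keep_subgraphs` the list is returned
#' unchanged.
#'
#' @param graphs list of `assembled_graph`.
#' @param keep_subgraphs logical.
#' @return filtered list.
#' @export
remove_redundant <- function(graphs, keep_subgraphs = FALSE) {
  if (keep_subgraphs || length(graphs) < 2L) return(graphs)
  sets <- lapply(graphs, graph_kmer_set)
  n <- length(graphs)
  drop <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (drop[i] || length(sets[[i]]) == 0L) next
    for (j in seq_len(n)) {
      if (i == j || drop[j]) next
      if (length(sets[[j]]) == 0L) next
      contained <- all(sets[[j]] %in% sets[[i]])
      if (contained) {
        mutual <- length(sets[[i]]) == length(sets[[j]])
        if (!mutual || j > i) drop[j] <- TRUE
      }
    }
  }
  graphs[!drop]
}

#' Extend terminal segment ends through unambiguous graph steps
#'
#' Each source segment start and sink segment end walks single-choice
#' extensions in the primary graph (strictly unambiguous: exactly one
#' extension k-mer, no noise or strand filtering) until a fork, a dead
#' end, or a k-mer revisit. Added lengths are recorded so reporting
#' filters can use pre-extension coordinates.
#'
#' @param g an `assembled_graph`.
#' @param dbg_primary primary `dbg`.
#' @param cap maximum added bases per end (default 10000).
#' @return extended `assembled_graph`.
#' @export
extend_graph_ends <- function(g, dbg_primary, cap = 10000L) {
  k <- g$k
  walk <- function(seq, side) {
    added <- 0L
    visited <- new.env(hash = TRUE, parent = emptyenv())
    repeat {
      km <- if (side == "right") substr(seq, nchar(seq) - k + 1L, nchar(seq))
            else substr(seq, 1L, k)
      if (!is.null(get0(km, envir = visited, inherits = FALSE))) break
      assign(km, TRUE, envir = visited)
      ext <- .dbg_ext(dbg_primary, km, side)
      if (length(ext$base) != 1L) break
      seq <- if (side == "right") paste0(seq, ext$base) else paste0(ext$base, seq)
      added <- added + 1L
      if (added >= cap) break
    }
    list(seq = seq, added = added)
  }
  for (s in names(g$segments)) {
    al <- 0L; ar <- 0L
    if (length(seg_preds(g, s)) == 0L) {
      w <- walk(g$segments[[s]], "left")
      g$segments[[s]] <- w$seq; al <- w$added
    }
    if (length(seg_succs(g, s)) == 0L) {
      w <- walk(g$segments[[s]], "right")
      g$segments[[s]] <- w$seq; ar <- w$added
    }
    if (al > 0L || ar > 0L) {
      prev <- g$ext_added[[s]] %||% c(0L, 0L)
      g$ext_added[[s]] <- c(prev[1L] + al, prev[2L] + ar)
    }
  }
  g
}

## Sum of secondary-k read counts over all windows of a sequence.
variant_support <- function(seq, counts_env, k2) {
  wins <- kmer_windows(seq, k2)
  if (length(wins) == 0L) return(0)
  canon <- canonical_kmer(wins)
  sum(vapply(canon, function(w) {
    v <- get0(w, envir = counts_env, inherits = FALSE)
    if (is.null(v)) 0 else v
  }, numeric(1L)))
}

## Build a total-count lookup environment from kmer_counts.
counts_env <- function(counts) {
  e <- new.env(hash = TRUE, parent = emptyenv(),
               size = max(16L, length(counts$kmer)))
  tot <- counts$plus + counts$minus
  for (i in seq_along(counts$kmer)) assign(counts$kmer[i], tot[i], envir = e)
  e
}

## Enumerate source-to-sink paths as lists of segment names (each link
## used at most once per path), stopping after `cap` paths.
.enumerate_paths <- function(g, cap) {
  segs <- names(g$segments)
  sources <- segs[vapply(segs, function(s) length(seg_preds(g, s)) == 0L,
                         logical(1L))]
  if (length(sources) == 0L && length(segs)) sources <- segs[1L]  # all-cycle
  out <- list()
  linkkey <- function(u, v) paste0(u, ">", v)
  dfs <- function(pathsegs, used) {
    if (length(out) > cap) return(invisible(NULL))
    cur <- pathsegs[length(pathsegs)]
    nxt <- sort(seg_succs(g, cur))
    nxt <- nxt[!(vapply(nxt, function(v) linkkey(cur, v), character(1L)) %in% used)]
    if (length(nxt) == 0L) {
      out[[length(out) + 1L]] <<- pathsegs
      return(invisible(NULL))
    }
    for (v in nxt) {
      dfs(c(pathsegs, v), c(used, linkkey(cur, v)))
      if (length(out) > cap) return(invisible(NULL))
    }
  }
  for (s in sort(sources)) dfs(s, character(0))
  out
}

#' Enumerate, filter and rank variants of an assembled graph
#'
#' Walks all source-to-sink paths (each link at most once per path),
#' suppresses variants shorter than `target_coverage` times the target
#' length (pre-end-extension coordinates; or shorter than `min_hit_len`
#' when that is set instead), and ranks by support: the sum of
#' secondary-k read counts over all k-mers of the variant, descending,
#' ties broken lexicographically. When more variants exist than
#' `max_variants`, the top `max_variants` are reported and the set is
#' flagged truncated.
#'
#' @param g an `assembled_graph`.
#' @param counts_secondary secondary `kmer_counts`.
#' @param params `assembly_params()`.
#' @return a `variant_set`: list with `graph_id`, `variants` (data.frame
#'   `sequence`, `support`), `truncated`, `n_total`.
#' @export
enumerate_variants <- function(g, counts_secondary, params = assembly_params()) {
  cap <- params$max_variants
  paths <- .enumerate_paths(g, cap)
  n_total <- length(paths)
  truncated <- n_total > cap
  seqs <- vapply(paths, function(p) merge_segments(g, p), character(1L))
  ## reporting length in pre-extension coordinates
  eff_len <- vapply(seq_along(paths), function(i) {
    p <- paths[[i]]
    len <- nchar(seqs[i])
    len - (g$ext_added[[p[1L]]] %||% c(0L, 0L))[1L] -
      (g$ext_added[[p[length(p)]]] %||% c(0L, 0L))[2L]
  }, numeric(1L))
  min_len <- if (!is.null(params$min_hit_len)) params$min_hit_len
             else params$target_coverage * g$target_len_nt
  keep <- eff_len >= min_len
  seqs <- unique(seqs[keep])
  env <- counts_env(counts_secondary)
  sup <- vapply(seqs, variant_support, numeric(1L),
                counts_env = env, k2 = counts_secondary$k)
  ord <- order(-sup, seqs)
  seqs <- seqs[ord]; sup <- sup[ord]
  if (length(seqs) > cap) {
    seqs <- seqs[seq_len(cap)]; sup <- sup[seq_len(cap)]
    truncated <- TRUE
  }
  structure(list(graph_id = g$target_id,
                 variants = data.frame(sequence = unname(seqs),
                                       support = unname(sup),
                                       stringsAsFactors = FALSE),
                 truncated = truncated, n_total = n_total),
            class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("<variant_set> graph %s: %d variants%s\n", x$graph_id,
              nrow(x$variants), if (x$truncated) " (truncated)" else ""))
  invisible(x)
}

#' Best supported path per link
#'
#' For each link of the graph, reports the maximum-support source-to-sink
#' path through that link; paths shared between links are reported once.
#' Intended for graphs whose full variant enumeration is too large.
#'
#' @param g an `assembled_graph`.
#' @param counts_secondary secondary `kmer_counts`.
#' @param params `assembly_params()`.
#' @return character vector of sequences.
#' @export
select_variants <- function(g, counts_secondary, params = assembly_params()) {
  if (length(g$segments) == 0L) return(character(0))
  paths <- .enumerate_paths(g, max(params$max_path, params$max_variants))
  if (length(paths) == 0L) return(character(0))
  seqs <- vapply(paths, function(p) merge_segments(g, p), character(1L))
  env <- counts_env(counts_secondary)
  sup <- vapply(seqs, variant_support, numeric(1L),
                counts_env = env, k2 = counts_secondary$k)
  if (nrow(g$links) == 0L) {
    best <- order(-sup, seqs)[1L]
    return(unname(seqs[best]))
  }
  out <- character(0)
  for (li in seq_len(nrow(g$links))) {
    u <- g$links$from[li]; v <- g$links$to[li]
    through <- vapply(paths, function(p) {
      idx <- which(p == u)
      any(idx < length(p) & p[pmin(idx + 1L, length(p))] == v)
    }, logical(1L))
    if (!any(through)) next
    cand <- which(through)
    best <- cand[order(-sup[cand], seqs[cand])[1L]]
    out <- c(out, seqs[best])
  }
  unique(unname(out))
}

iupac_merge <- function(bases) {
  key <- paste(sort(unique(bases)), collapse = "")
  map <- c(A = "A", C = "C", G = "G", T = "T",
           AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
           ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N")
  unname(map[key])
}

#' Collapse substitution-only bubbles into IUPAC ambiguity codes
#'
#' Simple bubbles — two or more segments sharing one predecessor and one
#' successor, all of equal length — whose branches differ by
#' substitutions only are merged into a single segment with IUPAC codes
#' at the differing positions. Indel bubbles are left untouched.
#'
#' @param g an `assembled_graph`.
#' @return collapsed `assembled_graph`.
#' @export
collapse_snp_bubbles <- function(g) {
  repeat {
    done <- TRUE
    segs <- names(g$segments)
    arms <- segs[vapply(segs, function(s)
      length(seg_preds(g, s)) == 1L && length(seg_succs(g, s)) == 1L,
      logical(1L))]
    if (length(arms) >= 2L) {
      key <- vapply(arms, function(s)
        paste(seg_preds(g, s), seg_succs(g, s), sep = ">"), character(1L))
      for (grp in split(arms, key)) {
        if (length(grp) < 2L) next
        lens <- nchar(g$segments[grp])
        if (length(unique(lens)) != 1L) next      # indel bubble: untouched
        mats <- do.call(rbind, strsplit(unname(g$segments[grp]), "", fixed = TRUE))
        merged <- apply(mats, 2L, iupac_merge)
        keep <- grp[1L]
        g$segments[[keep]] <- paste(merged, collapse = "")
        for (s in grp[-1L]) {
          g$links <- g$links[g$links$from != s & g$links$to != s, , drop = FALSE]
          g$segments <- g$segments[names(g$segments) != s]
          g$ext_added[[s]] <- NULL
        }
        done <- FALSE
        break
      }
    }
    if (done) break
  }
  simplify_graph(g)
}

#' Write an assembled graph (or list of graphs) as GFA 1.0
#'
#' Emits an H line with the version, S lines with segment names and
#' sequences, and L lines with `(k-1)M` overlap CIGARs; all links are
#' plus-orientation in target frame. Segment names are prefixed with the
#' graph's target id when several graphs are written together.
#'
#' @param graphs an `assembled_graph` or list of them.
#' @param path output file.
#' @export
write_gfa <- function(graphs, path) {
  if (inherits(graphs, "assembled_graph")) graphs <- list(graphs)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("H\tVN:Z:1.0", con)
  multi <- length(graphs) > 1L
  for (g in graphs) {
    pre <- if (multi) paste0(g$target_id, ":") else ""
    for (s in names(g$segments))
      writeLines(sprintf("S\t%s%s\t%s", pre, s, g$segments[[s]]), con)
    if (nrow(g$links))
      for (i in seq_len(nrow(g$links)))
        writeLines(sprintf("L\t%s%s\t+\t%s%s\t+\t%dM", pre, g$links$from[i],
                           pre, g$links$to[i], g$links$overlap[i]), con)
  }
  invisible(path)
}

#' Parse a GFA 1.0 file written by [write_gfa()]
#'
#' @param path GFA file.
#' @param k primary k-mer size of the graph (overlap + 1 when omitted).
#' @return an `assembled_graph` (single-graph files only).
#' @export
read_gfa <- function(path, k = NULL) {
  lines <- readLines(path)
  sl <- strsplit(lines[startsWith(lines, "S\t")], "\t", fixed = TRUE)
  ll <- strsplit(lines[startsWith(lines, "L\t")], "\t", fixed = TRUE)
  segments <- setNames(vapply(sl, `[`, character(1L), 3L),
                       vapply(sl, `[`, character(1L), 2L))
  links <- if (length(ll)) {
    data.frame(from = vapply(ll, `[`, character(1L), 2L),
               to = vapply(ll, `[`, character(1L), 4L),
               overlap = as.integer(sub("M$", "",
                                        vapply(ll, `[`, character(1L), 6L))),
               stringsAsFactors = FALSE)
  } else {
    data.frame(from = character(0), to = character(0), overlap = integer(0),
               stringsAsFactors = FALSE)
  }
  if (is.null(k))
    k <- if (nrow(links)) links$overlap[1L] + 1L else 21L
  new_assembled_graph(segments, links, k, max(21L, k %/% 2L), "gfa",
                      target_len_nt = if (length(segments))
                        max(nchar(segments)) else 0L)
}

#' Write sequences as FASTA (80-column lines)
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, max(nchar(s), 1L), by = 80L)
    writeLines(substring(s, starts, pmin(starts + 79L, nchar(s))), con)
  }
  invisible(path)
}
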