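#' Assembled graphs
#'
#' An assembled graph holds the subgraph of the read de Bruijn graph found
#' for one target: unitig-compressed `segments` (named sequences, all in
#' target orientation), `links` (data.frame `from`, `to`, `overlap` =
#' k - 1), the k-mer sizes used, the originating target id and length (in
#' bases), and the k-mers recorded as fork/clip marks during assembly.
#'
#' @name assembled_graph
NULL

new_assembled_graph <- function(segments, links, k, k2, target_id,
                                target_len_nt, fork_kmers = character(0)) {
  structure(list(segments = segments, links = links, k = as.integer(k),
                 k2 = as.integer(k2), target_id = target_id,
                 target_len_nt = as.integer(target_len_nt),
                 fork_kmers = fork_kmers,
                 ext_added = list()),
            class = "assembled_graph")
}

#' @export
print.assembled_graph <- function(x, ...) {
  cat(sprintf("<assembled_graph> target %s: %d segments, %d links (k=%d)\n",
              x$target_id, length(x$segments), nrow(x$links), x$k))
  invisible(x)
}

seg_preds <- function(g, seg) unique(g$links$from[g$links$to == seg])
seg_succs <- function(g, seg) unique(g$links$to[g$links$from == seg])

## Merge an ordered run of segments into one sequence (k-1 overlaps).
merge_segments <- function(g, segs) {
  o <- g$k - 1L
  seqs <- unname(g$segments[segs])
  if (length(seqs) == 1L) return(seqs)
  paste0(seqs[1L], paste(substring(seqs[-1L], o + 1L), collapse = ""))
}

## Build a unitig-compressed assembled graph from emitted path strings.
build_assembled_graph <- function(paths, k, k2, target_id, target_len_nt,
                                  fork_kmers = character(0)) {
  paths <- unique(paths[nchar(paths) >= k])
  if (length(paths) == 0L)
    return(new_assembled_graph(setNames(character(0), character(0)),
                               data.frame(from = character(0), to = character(0),
                                          overlap = integer(0),
                                          stringsAsFactors = FALSE),
                               k, k2, target_id, target_len_nt))
  succ <- new.env(hash = TRUE, parent = emptyenv())
  pred <- new.env(hash = TRUE, parent = emptyenv())
  nodes <- new.env(hash = TRUE, parent = emptyenv())
  add_edge <- function(u, v) {
    s <- get0(u, envir = succ, inherits = FALSE)
    if (is.null(s) || !(v %in% s)) assign(u, c(s, v), envir = succ)
    p <- get0(v, envir = pred, inherits = FALSE)
    if (is.null(p) || !(u %in% p)) assign(v, c(p, u), envir = pred)
  }
  for (p in paths) {
    wins <- kmer_windows(p, k)
    for (w in wins) assign(w, TRUE, envir = nodes)
    if (length(wins) > 1L)
      for (i in seq_len(length(wins) - 1L)) add_edge(wins[i], wins[i + 1L])
  }
  all_nodes <- sort(ls(nodes))
  outdeg <- function(u) length(get0(u, envir = succ, inherits = FALSE))
  indeg <- function(u) length(get0(u, envir = pred, inherits = FALSE))

  is_start <- vapply(all_nodes, function(u) {
    p <- get0(u, envir = pred, inherits = FALSE)
    length(p) != 1L || outdeg(p[1L]) != 1L
  }, logical(1L))
  starts <- all_nodes[is_start]
  assigned <- new.env(hash = TRUE, parent = emptyenv())
  chains <- list()
  walk_chain <- function(s) {
    chain <- s
    assign(s, TRUE, envir = assigned)
    cur <- s
    repeat {
      nx <- get0(cur, envir = succ, inherits = FALSE)
      if (length(nx) != 1L) break
      nx <- nx[1L]
      if (indeg(nx) != 1L) break
      if (!is.null(get0(nx, envir = assigned, inherits = FALSE))) break
      chain <- c(chain, nx)
      assign(nx, TRUE, envir = assigned)
      cur <- nx
    }
    chain
  }
  for (s in starts) chains[[length(chains) + 1L]] <- walk_chain(s)
  ## leftover pure cycles: force a deterministic start
  left <- all_nodes[vapply(all_nodes, function(u)
    is.null(get0(u, envir = assigned, inherits = FALSE)), logical(1L))]
  while (length(left)) {
    chains[[length(chains) + 1L]] <- walk_chain(left[1L])
    left <- left[vapply(left, function(u)
      is.null(get0(u, envir = assigned, inherits = FALSE)), logical(1L))]
  }

  ## deterministic naming by first k-mer
  ord <- order(vapply(chains, `[`, character(1L), 1L))
  chains <- chains[ord]
  seg_seq <- vapply(chains, function(ch) {
    if (length(ch) == 1L) ch else
      paste0(ch[1L], paste(substr(ch[-1L], k, k), collapse = ""))
  }, character(1L))
  seg_names <- sprintf("S%03d", seq_along(chains))
  names(seg_seq) <- seg_names
  node2seg <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(chains)) {
    assign(chains[[i]][1L], c(i, 1L), envir = node2seg)  # chain start
  }
  from <- character(0); to <- character(0)
  for (i in seq_along(chains)) {
    last <- chains[[i]][length(chains[[i]])]
    for (v in get0(last, envir = succ, inherits = FALSE)) {
      tgt <- get0(v, envir = node2seg, inherits = FALSE)
      if (is.null(tgt)) next  # successor mid-chain: only via cycle guard
      from <- c(from, seg_names[i]); to <- c(to, seg_names[tgt[1L]])
    }
  }
  links <- unique(data.frame(from = from, to = to,
                             overlap = rep(k - 1L, length(from)),
                             stringsAsFactors = FALSE))
  links <- links[order(links$from, links$to), , drop = FALSE]
  rownames(links) <- NULL
  new_assembled_graph(seg_seq, links, k, k2, target_id, target_len_nt,
                      fork_kmers)
}

## Merge trivial chains (single-successor into single-predecessor) left
## behind by link removal during filtering.
simplify_graph <- function(g) {
  repeat {
    merged <- FALSE
    for (u in names(g$segments)) {
      ss <- seg_succs(g, u)
      if (length(ss) != 1L) next
      v <- ss
      if (v == u) next
      if (length(seg_preds(g, v)) != 1L) next
      ## merge v into u
      g$segments[[u]] <- paste0(g$segments[[u]],
                                substring(g$segments[[v]], g$k))
      g$links <- g$links[!(g$links$from == u & g$links$to == v), , drop = FALSE]
      g$links$from[g$links$from == v] <- u
      g$segments <- g$segments[names(g$segments) != v]
      la <- g$ext_added[[u]]; lb <- g$ext_added[[v]]
      if (!is.null(la) || !is.null(lb))
        g$ext_added[[u]] <- c((la %||% c(0L, 0L))[1L], (lb %||% c(0L, 0L))[2L])
      g$ext_added[[v]] <- NULL
      merged <- TRUE
      break
    }
    if (!merged) break
  }
  g$links <- unique(g$links)
  rownames(g$links) <- NULL
  g
}

#' Canonical secondary-k k-mer set of an assembled graph
#'
#' Because the secondary k is smaller than the segment overlap, every
#' k-mer of every walk through the graph lies within a single segment, so
#' the union over segments is the full set.
#'
#' @param g an `assembled_graph`.
#' @param k2 k-mer size (defaults to the graph's secondary k).
#' @return character vector of canonical k-mers.
#' @export
graph_kmer_set <- function(g, k2 = g$k2) {
  wins <- unlist(lapply(g$segments, kmer_windows, k = k2), use.names = FALSE)
  unique(canonical_kmer(wins))
}

#' Assemble the subgraph for one target
#'
#' Finds seed k-mers, extends each remaining seed left and right through
#' the primary (and, where the rescue rules allow, secondary) graph, and
#' merges all emitted paths for the target into one unitig-compressed
#' assembled graph. Seeds whose k-mer appears in an earlier extension are
#' consumed and not re-extended. Left extensions run as right extensions
#' of the reverse complement against the reverse-complemented (protein:
#' reversed) target prefix.
#'
#' @param target a `target`.
#' @param dbg_primary,dbg_secondary `dbg` objects (secondary may be NULL).
#' @param scheme a `scoring_scheme` matching the target alphabet.
#' @param params `assembly_params()`.
#' @return an `assembled_graph`.
#' @export
assemble_target <- function(target, dbg_primary, dbg_secondary, scheme,
                            params = assembly_params()) {
  k <- dbg_primary$k
  k2 <- if (!is.null(dbg_secondary)) dbg_secondary$k else max(21L, k %/% 2L)
  protein <- target$alphabet == "protein"
  target_len_nt <- if (protein) 3L * nchar(target$sequence) else nchar(target$sequence)

  sr <- find_seeds(dbg_primary, target, scheme,
                   fraction = params$fraction,
                   kmer_complexity = params$kmer_complexity,
                   protect_reference_ends = params$protect_reference_ends)
  seeds <- sr$seeds
  tgt <- sr$target
  if (nrow(seeds) == 0L)
    return(build_assembled_graph(character(0), k, k2, target$id, target_len_nt))

  tch <- strsplit(masked_sequence(tgt), "", fixed = TRUE)[[1L]]
  k_t <- if (protein) k %/% 3L else k
  tl <- length(tch)

  ord <- order(-seeds$count, seeds$target_pos, seeds$kmer)
  seeds <- seeds[ord, , drop = FALSE]
  remaining <- rep(TRUE, nrow(seeds))
  paths_all <- character(0)
  forks_all <- character(0)
  seen_kmers <- new.env(hash = TRUE, parent = emptyenv())

  for (i in seq_len(nrow(seeds))) {
    if (!remaining[i]) next
    remaining[i] <- FALSE
    km <- seeds$kmer[i]
    p <- seeds$target_pos[i]
    fwd <- seeds$orientation[i] == "forward"
    seed_fr <- if (fwd) km else revcomp(km)

    right_t <- if (p + k_t < tl) tch[(p + k_t + 1L):tl] else character(0)
    left_raw <- if (p > 0L) tch[seq_len(p)] else character(0)
    left_t <- if (protein) rev(left_raw)
              else rev(chartr("ACGTN", "TGCAN", left_raw))

    r <- extend_direction(seed_fr, right_t, dbg_primary, dbg_secondary,
                          scheme, params, revcomp_codon = FALSE)
    l <- extend_direction(revcomp(seed_fr), left_t, dbg_primary, dbg_secondary,
                          scheme, params, revcomp_codon = protein)

    contrib <- unique(c(seed_fr, r$paths,
                        if (length(l$paths)) revcomp_many(l$paths)))
    paths_all <- c(paths_all, contrib)
    forks_all <- c(forks_all, r$fork_kmers,
                   if (length(l$fork_kmers)) revcomp_many(l$fork_kmers))

    ## consume seeds found inside the extensions
    wins <- unique(unlist(lapply(contrib, kmer_windows, k = k),
                          use.names = FALSE))
    canon <- unique(canonical_kmer(wins))
    for (w in canon) assign(w, TRUE, envir = seen_kmers)
    if (any(remaining)) {
      hit <- vapply(seeds$kmer[remaining], function(x)
        !is.null(get0(x, envir = seen_kmers, inherits = FALSE)), logical(1L))
      remaining[remaining] <- !hit
    }
  }

  build_assembled_graph(unique(paths_all), k, k2, target$id, target_len_nt,
                        unique(forks_all))
}
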