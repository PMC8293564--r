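#' Run the full assembly pipeline on in-memory objects
#'
#' Wires the stages together: k-mer size selection, k-mer counting at
#' both sizes, graph construction, insert-size estimation, per-target
#' seeding and extension, read/pair filtering, cross-target redundancy
#' removal, optional end extension and SNP collapsing, and variant
#' enumeration and selection.
#'
#' @param reads a `read_set`.
#' @param targets list of `target` objects (all the same alphabet).
#' @param params `assembly_params()`.
#' @param kmer,secondary_kmer explicit k-mer sizes (both or neither);
#'   bypass automatic selection.
#' @param genetic_code NCBI table id (protein mode).
#' @param scheme optional `scoring_scheme` override.
#' @param insert_cap,insert_min_joins insert-size estimation controls.
#' @param verbose log progress via `message()`.
#' @return list with `graphs`, `variants` (list of `variant_set`),
#'   `selected` (list of character vectors), `insert`, `k`, `k2`,
#'   `counts_secondary`.
#' @export
assemble_pipeline <- function(reads, targets, params = assembly_params(),
                              kmer = NULL, secondary_kmer = NULL,
                              genetic_code = 1L, scheme = NULL,
                              insert_cap = 1000L, insert_min_joins = 100L,
                              verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  if (length(targets) == 0L) stop("no targets supplied")
  mode <- targets[[1L]]$alphabet
  protein <- mode == "protein"
  if (!all(vapply(targets, `[[`, character(1L), "alphabet") == mode))
    stop("targets mix nucleotide and protein alphabets")

  if (is.null(kmer) != is.null(secondary_kmer))
    stop("supply both k-mer sizes or neither")
  if (is.null(kmer)) {
    ks <- choose_kmer_sizes(nchar(reads$seq), protein_mode = protein)
    k <- ks$primary_k; k2 <- ks$secondary_k
  } else {
    k <- as.integer(kmer); k2 <- as.integer(secondary_kmer)
    if (protein && (k %% 3L != 0L || k2 %% 3L != 0L))
      stop("k-mer sizes must be multiples of three in protein mode")
  }
  say("k-mer sizes: primary %d, secondary %d", k, k2)

  counts1 <- count_kmers(reads, k)
  counts2 <- count_kmers(reads, k2)
  dbg1 <- build_dbg(counts1, params$min_count)
  dbg2 <- build_dbg(counts2, params$min_count)
  say("graphs: %d primary k-mers, %d secondary k-mers (min_count %d)",
      length(dbg1$kmers), length(dbg2$kmers), params$min_count)

  paired <- any(!is.na(reads$pair_id))
  insert <- if (paired) {
    withCallingHandlers(
      estimate_insert_size(reads, dbg1, cap = insert_cap,
                           min_joins = insert_min_joins),
      warning = function(w) {
        say("%s", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  } else NULL
  if (!is.null(insert))
    say("insert size: %d-%d (%d joins)", insert$min_len, insert$max_len,
        insert$samples)

  if (is.null(scheme))
    scheme <- scoring_scheme(mode, genetic_code = genetic_code)

  graphs <- lapply(targets, function(tg) {
    g <- assemble_target(tg, dbg1, dbg2, scheme, params)
    say("target %s: %d segments, %d links", tg$id,
        length(g$segments), nrow(g$links))
    g
  })
  graphs <- Filter(function(g) length(g$segments) > 0L, graphs)

  graphs <- remove_redundant(graphs, params$keep_subgraphs)
  graphs <- lapply(graphs, function(g) {
    gf <- filter_graph(g, reads, insert, params)
    if (length(gf$segments) != length(g$segments))
      say("target %s: filtering %d -> %d segments", g$target_id,
          length(g$segments), length(gf$segments))
    gf
  })
  graphs <- remove_redundant(graphs, params$keep_subgraphs)

  if (params$collapse_snps)
    graphs <- lapply(graphs, collapse_snp_bubbles)
  if (params$extend_ends)
    graphs <- lapply(graphs, extend_graph_ends, dbg_primary = dbg1)

  variants <- lapply(graphs, enumerate_variants, counts_secondary = counts2,
                     params = params)
  selected <- lapply(graphs, select_variants, counts_secondary = counts2,
                     params = params)
  for (v in variants)
    say("graph %s: %d variants%s", v$graph_id, nrow(v$variants),
        if (v$truncated) " (truncated)" else "")

  list(graphs = graphs, variants = variants, selected = selected,
       insert = insert, k = k, k2 = k2, counts_secondary = counts2)
}

.write_pipeline_outputs <- function(res, gfa = NULL, all_variants = NULL,
                                    selected_variants = NULL) {
  if (!is.null(gfa)) write_gfa(res$graphs, gfa)
  if (!is.null(all_variants)) {
    seqs <- character(0)
    for (v in res$variants) {
      if (nrow(v$variants) == 0L) next
      nm <- sprintf("%s.v%d support=%g", v$graph_id,
                    seq_len(nrow(v$variants)), v$variants$support)
      seqs <- c(seqs, setNames(v$variants$sequence, nm))
    }
    write_fasta(seqs, all_variants)
  }
  if (!is.null(selected_variants)) {
    seqs <- character(0)
    for (i in seq_along(res$selected)) {
      s <- res$selected[[i]]
      if (length(s) == 0L) next
      nm <- sprintf("%s.sel%d", res$graphs[[i]]$target_id, seq_along(s))
      seqs <- c(seqs, setNames(s, nm))
    }
    write_fasta(seqs, selected_variants)
  }
  invisible(NULL)
}

#' Run the nucleotide-mode pipeline on files
#'
#' @param reads character vector of one or two FASTA/FASTQ files
#'   (gzip allowed); two files or an interleaved file are treated as
#'   pairs unless `paired = FALSE`.
#' @param targets nucleotide target FASTA.
#' @param gfa,all_variants,selected_variants output paths (NULL to skip).
#' @param params `assembly_params()`.
#' @param kmer,secondary_kmer explicit k-mer sizes.
#' @param paired logical.
#' @param verbose logical.
#' @return pipeline result list, invisibly.
#' @export
run_nucleotide <- function(reads, targets, gfa = NULL, all_variants = NULL,
                           selected_variants = NULL,
                           params = assembly_params(),
                           kmer = NULL, secondary_kmer = NULL,
                           paired = length(reads) == 2L, verbose = TRUE) {
  rs <- load_reads(reads, paired = paired,
                   interleaved = paired && length(reads) == 1L)
  tg <- load_targets(targets, "nucleotide")
  res <- assemble_pipeline(rs, tg, params, kmer, secondary_kmer,
                           verbose = verbose)
  .write_pipeline_outputs(res, gfa, all_variants, selected_variants)
  invisible(res)
}

#' Run the protein-mode pipeline on files
#'
#' As [run_nucleotide()] but with amino-acid targets, translated seeding
#' and alignment, and a required NCBI genetic code. K-mer sizes must be
#' multiples of three.
#'
#' @inheritParams run_nucleotide
#' @param genetic_code NCBI translation table id (required).
#' @return pipeline result list, invisibly.
#' @export
run_protein <- function(reads, targets, genetic_code, gfa = NULL,
                        all_variants = NULL, selected_variants = NULL,
                        params = assembly_params(),
                        kmer = NULL, secondary_kmer = NULL,
                        paired = length(reads) == 2L, verbose = TRUE) {
  if (missing(genetic_code) || is.null(genetic_code))
    stop("protein mode requires --genetic_code")
  rs <- load_reads(reads, paired = paired,
                   interleaved = paired && length(reads) == 1L)
  tg <- load_targets(targets, "protein")
  res <- assemble_pipeline(rs, tg, params, kmer, secondary_kmer,
                           genetic_code = genetic_code, verbose = verbose)
  .write_pipeline_outputs(res, gfa, all_variants, selected_variants)
  invisible(res)
}
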