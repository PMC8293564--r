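test_that("redundant graphs are removed unless kept explicitly", {
  set.seed(17)
  gene <- targetasm:::random_dna(120L)
  fusion <- paste0(gene, targetasm:::random_dna(120L))
  mk <- function(seq, id) targetasm:::new_assembled_graph(
    c(S001 = seq), data.frame(from = character(0), to = character(0),
                              overlap = integer(0), stringsAsFactors = FALSE),
    31L, 21L, id, nchar(seq))
  g_gene <- mk(gene, "gene"); g_fus <- mk(fusion, "fusion")
  out <- remove_redundant(list(g_gene, g_fus))
  expect_length(out, 1L)
  expect_equal(out[[1L]]$target_id, "fusion")
  expect_length(remove_redundant(list(g_gene, g_fus), keep_subgraphs = TRUE), 2L)
  ## disjoint graphs are both retained
  g_other <- mk(targetasm:::random_dna(120L), "other")
  expect_length(remove_redundant(list(g_gene, g_other)), 2L)
})

test_that("terminal ends extend only through unambiguous choices", {
  set.seed(27)
  genome <- targetasm:::random_dna(300L)
  dbg <- build_dbg(count_kmers(read_set(rep(substring(genome, 1:241, 60:300), 2L)),
                               21L), 2L)
  mk <- function(seq) targetasm:::new_assembled_graph(
    c(S001 = seq), data.frame(from = character(0), to = character(0),
                              overlap = integer(0), stringsAsFactors = FALSE),
    21L, 11L, "t", nchar(seq))
  g <- extend_graph_ends(mk(substr(genome, 101L, 200L)), dbg)
  ## unique flank appended out to the coverage ends
  expect_equal(g$segments[["S001"]], genome)
  expect_equal(g$ext_added[["S001"]], c(100L, 100L))
  ## a fork in the flank stops the walk
  alt <- genome
  substr(alt, 251L, 251L) <- setdiff(c("A", "C", "G", "T"),
                                     substr(genome, 251L, 251L))[1L]
  dbg2 <- build_dbg(count_kmers(read_set(rep(c(substring(genome, 1:241, 60:300),
                                               substring(alt, 1:241, 60:300)), 2L)),
                                21L), 2L)
  g2 <- extend_graph_ends(mk(substr(genome, 101L, 200L)), dbg2)
  expect_equal(nchar(g2$segments[["S001"]]), 250L - 101L + 1L + 100L)
  ## a circular unique context terminates on k-mer revisit
  circ <- paste0(genome[1], collapse = "")
  circ_seq <- substr(genome, 1L, 150L)
  circ_reads <- substring(paste0(circ_seq, circ_seq), 1:150, 40:189)
  dbg3 <- build_dbg(count_kmers(read_set(rep(circ_reads, 2L)), 21L), 2L)
  g3 <- extend_graph_ends(mk(substr(circ_seq, 31L, 90L)), dbg3)
  ## terminates after at most one full lap per side
  expect_lte(nchar(g3$segments[["S001"]]), 2L * 150L + 60L)
})

test_that("bubble graphs enumerate one variant per path with ranking", {
  g1 <- make_bubble_graph(n_sites = 1L)
  ## support: arm A at 3 copies, arm B at 1
  vA <- targetasm:::merge_segments(g1, c("P0", "A1", "P1"))
  vB <- targetasm:::merge_segments(g1, c("P0", "B1", "P1"))
  cnt <- counts_for(c(rep(vA, 3L), vB))
  vs <- enumerate_variants(g1, cnt, assembly_params())
  expect_equal(nrow(vs$variants), 2L)
  expect_false(vs$truncated)
  expect_setequal(vs$variants$sequence, c(vA, vB))
  expect_equal(vs$variants$sequence[1L], vA)   # higher support first
  ## three unphased sites give 8 variants; max_variants 2 keeps the top 2
  g3 <- make_bubble_graph(n_sites = 3L)
  seqs <- vapply(targetasm:::.enumerate_paths(g3, 100L), function(p)
    targetasm:::merge_segments(g3, p), character(1L))
  expect_length(seqs, 8L)
  cnt3 <- counts_for(c(rep(seqs[1L], 5L), seqs))
  vs3 <- enumerate_variants(g3, cnt3, assembly_params())
  expect_equal(nrow(vs3$variants), 8L)
  vs3b <- enumerate_variants(g3, cnt3, assembly_params(max_variants = 2L))
  expect_equal(nrow(vs3b$variants), 2L)
  expect_true(vs3b$truncated)
  expect_equal(vs3b$variants$sequence[1L], seqs[1L])
})

test_that("short variants are suppressed by target coverage or min_hit_len", {
  g <- make_bubble_graph(n_sites = 1L)
  g$target_len_nt <- 250L        # paths are ~100 bp = 0.4 of the target
  cnt <- counts_for(targetasm:::merge_segments(g, c("P0", "A1", "P1")))
  vs <- enumerate_variants(g, cnt, assembly_params(target_coverage = 0.5))
  expect_equal(nrow(vs$variants), 0L)
  ## min_hit_len overrides the coverage rule
  vs2 <- enumerate_variants(g, cnt, assembly_params(min_hit_len = 50L))
  expect_equal(nrow(vs2$variants), 2L)
})

test_that("selected variants report the best path per link once", {
  g <- make_bubble_graph(n_sites = 1L)
  vA <- targetasm:::merge_segments(g, c("P0", "A1", "P1"))
  vB <- targetasm:::merge_segments(g, c("P0", "B1", "P1"))
  cnt <- counts_for(c(rep(vA, 3L), vB))
  sel <- select_variants(g, cnt, assembly_params())
  ## 4 links, best paths collapse to the two distinct sequences
  expect_setequal(sel, c(vA, vB))
  ## linear graph: single sequence
  lin <- targetasm:::new_assembled_graph(
    c(S001 = vA), data.frame(from = character(0), to = character(0),
                             overlap = integer(0), stringsAsFactors = FALSE),
    11L, 7L, "lin", nchar(vA))
  expect_equal(select_variants(lin, cnt, assembly_params()), vA)
})

test_that("substitution bubbles collapse to IUPAC codes, indels do not", {
  g <- make_bubble_graph(n_sites = 1L)    # A/G bubble
  gc <- collapse_snp_bubbles(g)
  expect_length(gc$segments, 1L)
  expect_true(grepl("R", gc$segments[[1L]], fixed = TRUE))
  ## indel bubble untouched
  gi <- make_bubble_graph(n_sites = 1L, indel = TRUE)
  gci <- collapse_snp_bubbles(gi)
  expect_length(gci$segments, length(gi$segments))
  ## a 10-site unphased toy: 1024 variants collapse to 1
  g10 <- make_bubble_graph(n_sites = 10L)
  cnt <- counts_for(targetasm:::merge_segments(
    g10, c("P0", paste0(rbind(sprintf("A%d", 1:10), sprintf("P%d", 1:10))))))
  vs <- enumerate_variants(g10, cnt, assembly_params())
  expect_equal(nrow(vs$variants), 1000L)
  expect_true(vs$truncated)
  g10c <- collapse_snp_bubbles(g10)
  vsc <- enumerate_variants(g10c, cnt, assembly_params())
  expect_lt(nrow(vsc$variants), 1024L)
  expect_equal(nrow(vsc$variants), 1L)
})

test_that("GFA output round-trips and FASTA wraps at 80 columns", {
  g <- make_bubble_graph(n_sites = 1L)
  f <- tempfile(fileext = ".gfa")
  write_gfa(g, f)
  lines <- readLines(f)
  expect_equal(lines[1L], "H\tVN:Z:1.0")
  expect_equal(sum(startsWith(lines, "S\t")), length(g$segments))
  expect_equal(sum(startsWith(lines, "L\t")), nrow(g$links))
  expect_true(all(grepl("10M$", lines[startsWith(lines, "L\t")])))
  g2 <- read_gfa(f)
  expect_equal(g2$segments, g$segments)
  expect_equal(g2$links[order(g2$links$from, g2$links$to), ],
               g$links[order(g$links$from, g$links$to), ])
  ## single-segment graph: one S line, no L lines
  lin <- targetasm:::new_assembled_graph(
    c(S001 = strrep("ACGT", 50L)),
    data.frame(from = character(0), to = character(0), overlap = integer(0),
               stringsAsFactors = FALSE), 11L, 7L, "lin", 200L)
  f2 <- tempfile(fileext = ".gfa")
  write_gfa(lin, f2)
  l2 <- readLines(f2)
  expect_equal(sum(startsWith(l2, "S\t")), 1L)
  expect_equal(sum(startsWith(l2, "L\t")), 0L)
  ## FASTA wrapping
  ff <- tempfile(fileext = ".fa")
  write_fasta(c(x = strrep("A", 200L)), ff)
  fl <- readLines(ff)
  expect_equal(fl[1L], ">x")
  expect_equal(nchar(fl[2L]), 80L)
  expect_equal(sum(nchar(fl[-1L])), 200L)
})
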