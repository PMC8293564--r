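# Helper: substring of the merged A-C-D path of a fork graph.
path_sub <- function(g, segs, from, to) {
  substr(fork_path_seq(g, segs), from, to)
}

# Complement every base (guaranteed mismatch at each position).
mismatch_all <- function(s) chartr("ACGT", "TGCA", s)

test_that("read support counts confirms and contradicts per the Y rule", {
  g <- make_fork_graph()     # A,B -> C -> D,E; k = 11, Y = 5 below
  A <- g$segments[["A"]]; C <- g$segments[["C"]]; D <- g$segments[["D"]]
  acd <- fork_path_seq(g, c("A", "C", "D"))
  ## A-exclusive is 1..20, C occupies 21..70, D-exclusive is 71..90
  r_confirm <- substr(acd, 15L, 75L)            # 6 bases of A, all C, 5 of D
  sup <- support_by_reads(A, C, D, read_set(r_confirm), y = 5L, overlap = 10L)
  expect_equal(sup$confirm, 1L)
  expect_equal(sup$contradict, 0L)
  ## 7 bases of A + C + 12 bases mismatching D immediately: contradict
  r_contra <- paste0(substr(acd, 14L, 70L), mismatch_all(substr(acd, 71L, 82L)))
  sup2 <- support_by_reads(A, C, D, read_set(r_contra), y = 5L, overlap = 10L)
  expect_equal(sup2$confirm, 0L)
  expect_equal(sup2$contradict, 1L)
  ## a read ending exactly at the C/D junction is neither
  r_end <- substr(acd, 10L, 70L)
  sup3 <- support_by_reads(A, C, D, read_set(r_end), y = 5L, overlap = 10L)
  expect_equal(sup3$confirm + sup3$contradict, 0L)
  ## reverse-strand reads are handled symmetrically
  sup4 <- support_by_reads(A, C, D, read_set(revcomp(r_confirm)),
                           y = 5L, overlap = 10L)
  expect_equal(sup4$confirm, 1L)
})

test_that("pair support judges each junction by its own mate", {
  g <- make_fork_graph()
  A <- g$segments[["A"]]; C <- g$segments[["C"]]
  D <- g$segments[["D"]]; E <- g$segments[["E"]]
  acd <- fork_path_seq(g, c("A", "C", "D"))
  ace <- fork_path_seq(g, c("A", "C", "E"))
  ins <- list(min_len = 50L, max_len = 100L)
  ## pair straddling C with the correct span confirms
  pr <- read_set(c(substr(acd, 5L, 34L), revcomp(substr(acd, 60L, 89L))),
                 mate = c(0L, 1L), pair_id = c("p1", "p1"))
  sup <- support_by_pairs(A, C, D, pr, ins, y = 5L, overlap = 10L)
  expect_equal(sup$confirm, 1L)
  expect_equal(sup$contradict, 0L)
  ## a pair phased with E contradicts A-C-D: its right mate reaches the
  ## junction exactly and then mismatches D
  prE <- read_set(c(substr(ace, 5L, 34L), revcomp(substr(ace, 55L, 84L))),
                  mate = c(0L, 1L), pair_id = c("p1", "p1"))
  supE <- support_by_pairs(A, C, D, prE, ins, y = 5L, overlap = 10L)
  expect_equal(supE$confirm, 0L)
  expect_equal(supE$contradict, 1L)
  ## and the same pair confirms A-C-E
  supE2 <- support_by_pairs(A, C, E, prE, ins, y = 5L, overlap = 10L)
  expect_equal(supE2$confirm, 1L)
  ## spans outside the insert range are ignored
  ins2 <- list(min_len = 10L, max_len = 60L)
  sup3 <- support_by_pairs(A, C, D, pr, ins2, y = 5L, overlap = 10L)
  expect_equal(sup3$confirm + sup3$contradict, 0L)
})

# Reads phased with the two true paths A-C-E and B-C-D: n copies each of
# a spanning read per phase.
phased_reads <- function(g, n = 3L) {
  ace <- fork_path_seq(g, c("A", "C", "E"))
  bcd <- fork_path_seq(g, c("B", "C", "D"))
  read_set(rep(c(substr(ace, 10L, 80L), substr(bcd, 10L, 80L)), n))
}

test_that("unsupported fork combinations are removed with duplication", {
  g <- make_fork_graph()
  reads <- phased_reads(g, 3L)
  gf <- filter_graph(g, reads, insert = NULL, params = assembly_params())
  ## cross paths A-C-D and B-C-E are gone; true paths survive
  paths <- targetasm:::.enumerate_paths(gf, 100L)
  seqs <- vapply(paths, function(p) targetasm:::merge_segments(gf, p),
                 character(1L))
  expect_true(fork_path_seq(g, c("A", "C", "E")) %in% seqs)
  expect_true(fork_path_seq(g, c("B", "C", "D")) %in% seqs)
  expect_false(fork_path_seq(g, c("A", "C", "D")) %in% seqs)
  expect_false(fork_path_seq(g, c("B", "C", "E")) %in% seqs)
  ## the multiset of primary k-mers on surviving paths is preserved
  expect_setequal(graph_kmer_set(gf, g$k), graph_kmer_set(g, g$k))
  ## filtering is idempotent here
  gf2 <- filter_graph(gf, reads, insert = NULL, params = assembly_params())
  expect_setequal(
    vapply(targetasm:::.enumerate_paths(gf2, 100L),
           function(p) targetasm:::merge_segments(gf2, p), character(1L)),
    seqs)
})

test_that("exactly aligned_count confirming reads keep a contradicted path", {
  g <- make_fork_graph()
  acd <- fork_path_seq(g, c("A", "C", "D"))
  ace <- fork_path_seq(g, c("A", "C", "E"))
  bcd <- fork_path_seq(g, c("B", "C", "D"))
  ## 2 confirms (= aligned_count) and 5 contradicts for A-C-D: kept,
  ## because removal needs confirm strictly below aligned_count
  reads <- read_set(c(rep(substr(acd, 10L, 80L), 2L),
                      rep(substr(ace, 10L, 80L), 5L),
                      rep(substr(bcd, 10L, 80L), 5L)))
  sup <- support_by_reads(g$segments[["A"]], g$segments[["C"]],
                          g$segments[["D"]], reads, 5L, 10L)
  expect_equal(sup$confirm, 2L)
  ## both phased read groups contradict A-C-D (one from each side)
  expect_equal(sup$contradict, 10L)
  gf <- filter_graph(g, reads, insert = NULL, params = assembly_params())
  seqs <- vapply(targetasm:::.enumerate_paths(gf, 100L),
                 function(p) targetasm:::merge_segments(gf, p), character(1L))
  expect_true(acd %in% seqs)
})

test_that("filtering is monotone in its thresholds", {
  g <- make_fork_graph()
  reads <- phased_reads(g, 3L)
  ## aligned_count 0: confirm < 0 is impossible, nothing is removed
  gf0 <- filter_graph(g, reads, NULL, assembly_params(aligned_count = 0L))
  expect_equal(length(gf0$segments), length(g$segments))
  expect_equal(nrow(gf0$links), nrow(g$links))
  ## a huge not_aligned_count likewise removes nothing
  gfInf <- filter_graph(g, reads, NULL,
                        assembly_params(not_aligned_count = 10000L))
  expect_equal(nrow(gfInf$links), nrow(g$links))
})
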