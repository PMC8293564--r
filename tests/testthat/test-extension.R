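test_that("extension classification applies noise, strand and tie rules", {
  p <- assembly_params()
  ## single candidate
  d1 <- make_dbg(list(CGA = c(20, 20), GAA = c(20, 20)), 3L)
  cls <- classify_extension(d1, "CCG", p)   # successors of CCG: CGA
  expect_equal(cls$type, "single")
  expect_equal(cls$bases$base, "A")
  ## balanced choice present: one-strand candidates are dropped
  d2 <- make_dbg(list(CGA = c(20, 20), CGC = c(4, 0)), 3L)
  cls2 <- classify_extension(d2, "CCG", p)
  expect_equal(cls2$type, "single")
  expect_equal(cls2$bases$base, "A")
  ## equal balanced counts fork, ordered lexicographically
  d3 <- make_dbg(list(CGA = c(15, 15), CGG = c(14, 16)), 3L)
  cls3 <- classify_extension(d3, "CCG", p)
  expect_equal(cls3$type, "fork")
  expect_equal(cls3$bases$base, c("A", "G"))
  ## noise rule: counts below extension_fraction * max are dropped
  d4 <- make_dbg(list(CGA = c(30, 30), CGC = c(2, 2)), 3L)
  cls4 <- classify_extension(d4, "CCG", p)
  expect_equal(cls4$type, "single")
})

test_that("secondary rescue fires on dead ends but not on healthy singles", {
  p <- assembly_params(min_count = 2L)
  path <- "ACCTG"
  ## primary k = 5 dead end; secondary k = 3 offers TGA -> base A
  d1 <- make_dbg(list(), 5L)
  d2 <- make_dbg(list(TGA = c(1, 0)), 3L)
  resc <- try_secondary_rescue(path, d2, p)
  expect_equal(resc$base, "A")
  cands <- targetasm:::.extension_candidates(path, d1, d2, p)
  expect_equal(cands$base, "A")
  ## single primary extension with count 2 > threshold 1: rescue ignored
  d1b <- make_dbg(list(CCTGG = c(1, 1)), 5L)
  d2b <- make_dbg(list(TGA = c(5, 5)), 3L)
  cands2 <- targetasm:::.extension_candidates(path, d1b, d2b, p)
  expect_equal(cands2$base, "G")
  ## with min_count 1 the same single extension at count 1 adds secondary
  d1c <- make_dbg(list(CCTGG = c(1, 0)), 5L)
  cands3 <- targetasm:::.extension_candidates(path, d1c, d2b, p)
  expect_setequal(cands3$base, c("A", "G"))
})

test_that("fork density aborts above the threshold, strictly", {
  p <- assembly_params()   # buf 200, max density 0.1
  expect_true(fork_density_abort(981:1001, 1000L, p))    # 21/200 = 0.105
  expect_false(fork_density_abort(982:1001, 1000L, p))   # 20/200 = 0.100
  ## shorter paths use the actual length as denominator
  expect_true(fork_density_abort(c(10L, 20L, 40L, 45L, 50L, 55L), 50L, p))
  expect_false(fork_density_abort(c(10L, 50L), 50L, p))
})

test_that("anchor registration respects d < k/4 and target coordinates", {
  k <- 75L
  anchors <- new.env(parent = emptyenv())
  ## d = 10 < 18.75: registers
  expect_equal(merge_at_anchor(anchors, "KM1", 100L, 10L, k), "registered")
  ## same k-mer, same best position: merges
  expect_equal(merge_at_anchor(anchors, "KM1", 100L, 3L, k), "merged")
  ## same k-mer, different best position: continues independently
  expect_equal(merge_at_anchor(anchors, "KM1", 90L, 3L, k), "continue")
  ## d = 19 at k = 75 (bound 18.75): no registration
  a2 <- new.env(parent = emptyenv())
  expect_equal(merge_at_anchor(a2, "KM2", 50L, 19L, k), "continue")
  expect_null(get0("KM2", envir = a2))
})

test_that("a linear error-free region extends to the target end and clips", {
  set.seed(66)
  genome <- targetasm:::random_dna(400L)
  reads <- read_set(rep(substring(genome, 1:341, 60:400), 2L))
  k <- 31L
  dbg <- build_dbg(count_kmers(reads, k), 2L)
  tgt_seq <- substr(genome, 101L, 300L)
  sc <- scoring_scheme("nucleotide")
  seed_km <- substr(tgt_seq, 1L, k)
  tch <- strsplit(substr(tgt_seq, k + 1L, nchar(tgt_seq)), "")[[1L]]
  r <- extend_direction(seed_km, tch, dbg, NULL, sc)
  expect_length(r$paths, 1L)
  ## the single path reproduces the target region exactly at full length
  expect_equal(r$paths[[1L]], tgt_seq)
  expect_false(r$aborted)
})

test_that("a balanced SNP creates exactly one fork and two paths", {
  set.seed(77)
  genome <- targetasm:::random_dna(400L)
  alt <- genome
  substr(alt, 250L, 250L) <- setdiff(c("A", "C", "G", "T"),
                                     substr(genome, 250L, 250L))[1L]
  reads <- read_set(rep(c(substring(genome, 1:341, 60:400),
                          substring(alt, 1:341, 60:400)), 2L))
  k <- 31L
  dbg <- build_dbg(count_kmers(reads, k), 2L)
  tgt_seq <- substr(genome, 101L, 350L)
  sc <- scoring_scheme("nucleotide")
  seed_km <- substr(tgt_seq, 1L, k)
  tch <- strsplit(substr(tgt_seq, k + 1L, nchar(tgt_seq)), "")[[1L]]
  r <- extend_direction(seed_km, tch, dbg, NULL, sc)
  expect_length(r$paths, 2L)
  ## one true fork plus the shared clip mark at the target end
  expect_length(r$fork_kmers, 2L)
  branch_km <- substr(tgt_seq, 150L - 31L, 149L)  # k-mer ending before the SNP
  expect_true(branch_km %in% r$fork_kmers)
  ## both alleles are represented at the SNP (path coordinate 150)
  expect_setequal(substr(r$paths, 150L, 150L),
                  c(substr(genome, 250L, 250L), substr(alt, 250L, 250L)))
})

test_that("assembly of a single gene yields one spanning segment", {
  set.seed(88)
  genome <- targetasm:::random_dna(500L)
  reads <- read_set(rep(substring(genome, 1:441, 60:500), 2L))
  k <- 31L
  dbg1 <- build_dbg(count_kmers(reads, k), 2L)
  dbg2 <- build_dbg(count_kmers(reads, 21L), 2L)
  gene <- substr(genome, 101L, 400L)
  tg <- target(mutate_target(gene, 0.9, seed = 12), id = "g")
  sc <- scoring_scheme("nucleotide")
  g <- assemble_target(tg, dbg1, dbg2, sc)
  expect_equal(length(g$segments), 1L)
  expect_equal(nrow(g$links), 0L)
  ## drop-off clipping may trim a couple of terminal bases when the
  ## homolog mismatches the gene near its ends; the interior is exact
  expect_true(grepl(substr(gene, 11L, 290L), g$segments[[1L]], fixed = TRUE))
  expect_gte(nchar(g$segments[[1L]]), 280L)
  ## no segment k-mer is absent from the graphs
  wins <- targetasm:::kmer_windows(g$segments[[1L]], k)
  expect_true(all(vapply(wins, function(w)
    !is.null(targetasm:::dbg_lookup(dbg1, w)), logical(1L))))
})

test_that("a heterozygous SNP assembles into a four-segment bubble", {
  set.seed(99)
  genome <- targetasm:::random_dna(500L)
  alt <- genome
  substr(alt, 250L, 250L) <- setdiff(c("A", "C", "G", "T"),
                                     substr(genome, 250L, 250L))[1L]
  reads <- read_set(rep(c(substring(genome, 1:441, 60:500),
                          substring(alt, 1:441, 60:500)), 2L))
  k <- 31L
  dbg1 <- build_dbg(count_kmers(reads, k), 2L)
  tg <- target(substr(genome, 101L, 400L), id = "het")
  sc <- scoring_scheme("nucleotide")
  g <- assemble_target(tg, dbg1, NULL, sc)
  expect_equal(length(g$segments), 4L)
  expect_equal(nrow(g$links), 4L)
  ## two arms of equal length differing by substitution only
  arms <- names(g$segments)[vapply(names(g$segments), function(s)
    length(targetasm:::seg_preds(g, s)) == 1L &&
      length(targetasm:::seg_succs(g, s)) == 1L, logical(1L))]
  expect_length(arms, 2L)
  expect_equal(nchar(g$segments[[arms[1L]]]), nchar(g$segments[[arms[2L]]]))
})

test_that("a target unrelated to the reads yields an empty graph", {
  set.seed(111)
  reads <- read_set(rep(substring(targetasm:::random_dna(300L), 1:241, 60:300), 2L))
  dbg <- build_dbg(count_kmers(reads, 31L), 2L)
  tg <- target(targetasm:::random_dna(200L), id = "none")
  g <- assemble_target(tg, dbg, NULL, scoring_scheme("nucleotide"))
  expect_equal(length(g$segments), 0L)
})

test_that("assembly is deterministic and consumes contained seeds", {
  set.seed(121)
  genome <- targetasm:::random_dna(400L)
  reads <- read_set(rep(substring(genome, 1:341, 60:400), 2L))
  dbg <- build_dbg(count_kmers(reads, 31L), 2L)
  tg <- target(substr(genome, 51L, 350L), id = "det")
  sc <- scoring_scheme("nucleotide")
  g1 <- assemble_target(tg, dbg, NULL, sc)
  g2 <- assemble_target(tg, dbg, NULL, sc)
  expect_identical(g1$segments, g2$segments)
  expect_identical(g1$links, g2$links)
})
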