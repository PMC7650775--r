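test_that("ORF caller handles trivial, wrapped and collapsed cases", {
  # T-free sequence: no start codon on either strand -> no ORFs
  set.seed(3)
  g0 <- circular_genome(paste(sample(c("A", "C", "G"), 200, TRUE), collapse = ""))
  expect_equal(nrow(find_orfs(g0, min_codons = 5)), 0L)
  # a 60-codon ORF spanning the origin is found with wrap = TRUE
  cds <- paste0("ATG", strrep("GCT", 59), "TAA")   # 60 codons + stop
  filler <- strrep("CCA", 100)                     # inert: no starts, no stops
  lin <- paste0("TAA", cds, "TAA", filler)         # guards around the ORF
  rot <- 50L  # rotate backwards so the ORF crosses the origin
  s <- paste0(substr(lin, rot + 1L, nchar(lin)), substr(lin, 1L, rot))
  g1 <- circular_genome(s)
  orfs <- find_orfs(g1, min_codons = 50)
  hit <- orfs[orfs$codons == 60L, ]
  expect_equal(nrow(hit), 1L)
  expect_true(hit$wrap)
  expect_equal(substr(hit$translation, 1, 1), "M")
  expect_equal(nchar(hit$translation), 60L)
  # candidates sharing a stop collapse to the most upstream start
  g2 <- circular_genome(paste0("TAG", "ATG", strrep("AAA", 10), "ATG",
                               strrep("AAA", 10), "TAA", strrep("C", 30)))
  o2 <- find_orfs(g2, min_codons = 5)
  plus <- o2[o2$strand == "+", ]
  expect_equal(nrow(plus), 1L)
  expect_equal(plus$codons, 22L)  # the longer of the two nested candidates
})

test_that("ORF caller equals six-frame brute force on random circular genomes", {
  set.seed(101)
  for (rep in 1:10) {
    L <- sample(500:3000, 1)
    g <- circular_genome(random_dna(L, gc = runif(1, 0.3, 0.6)))
    mc <- sample(c(10L, 20L, 50L), 1)
    got <- find_orfs(g, min_codons = mc)
    want <- oracle_orfs(g, min_codons = mc)
    got_key <- sort(paste(got$start, got$end, got$strand, got$codons))
    want_key <- sort(paste(want$start, want$end, want$strand, want$codons))
    expect_equal(got_key, want_key)
  }
})

test_that("overlap resolution is greedy-longest with deterministic tie-breaks", {
  # identical spans on opposite strands: exactly one survives (the + strand)
  cand <- make_orf_table(data.frame(
    orf_id = c("a", "b"), start = c(0L, 0L), end = c(90L, 90L),
    strand = c("-", "+"), codons = c(29L, 29L),
    translation = c("x", "x"), wrap = FALSE
  ), genome_length = 500L)
  kept <- resolve_overlaps(cand, max_overlap_bp = 30)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$strand, "+")
  # nested candidate inside an accepted ORF is rejected; disjoint retained
  set.seed(21)
  df <- data.frame(
    orf_id = paste0("c", 1:10),
    start = c(0L, 10L, 200L, 220L, 400L, 600L, 800L, 820L, 1000L, 1200L),
    end = c(150L, 100L, 380L, 300L, 520L, 720L, 950L, 890L, 1090L, 1290L),
    strand = "+", translation = "x", wrap = FALSE
  )
  df$codons <- as.integer((df$end - df$start) / 3 - 1)
  cand <- make_orf_table(df, genome_length = 2000L)
  kept <- resolve_overlaps(cand, max_overlap_bp = 30)
  # oracle: exhaustive pairwise overlap check on the result
  ov <- function(i, j) max(0, min(kept$end[i], kept$end[j]) -
                             max(kept$start[i], kept$start[j]))
  for (i in seq_len(nrow(kept))) {
    for (j in seq_len(nrow(kept))) {
      if (i != j) expect_lte(ov(i, j), 30)
    }
  }
  # output is a subset of input, and every rejected candidate conflicts
  expect_true(all(kept$start %in% df$start))
  rejected <- df[!paste(df$start, df$end) %in% paste(kept$start, kept$end), ]
  for (i in seq_len(nrow(rejected))) {
    conflicts <- any(pmax(0, pmin(kept$end, rejected$end[i]) -
                            pmax(kept$start, rejected$start[i])) > 30)
    expect_true(conflicts)
  }
  # disjoint candidates all retained
  expect_true(all(c(0L, 200L, 400L, 600L, 800L, 1000L, 1200L) %in% kept$start))
  expect_error(resolve_overlaps(cand, max_overlap_bp = -1), ">= 0")
})

test_that("overlap resolution respects the circle for wrapped ORFs", {
  cand <- make_orf_table(data.frame(
    orf_id = c("w", "h"), start = c(950L, 10L), end = c(1060L, 100L),
    strand = "+", codons = c(35L, 29L), translation = "x",
    wrap = c(TRUE, FALSE)
  ), genome_length = 1000L)
  # w covers 950..1000 and 0..60; h covers 10..100 -> overlap 50 > 30
  kept <- resolve_overlaps(cand, max_overlap_bp = 30)
  expect_equal(kept$codons, 35L)
  kept2 <- resolve_overlaps(cand, max_overlap_bp = 60)
  expect_equal(nrow(kept2), 2L)
})

test_that("linearize_on rotates correctly and is invertible", {
  set.seed(5)
  g <- circular_genome(random_dna(300))
  expect_equal(linearize_on(g, 0, "+")$seq, g$seq)
  k <- 123L
  expect_equal(linearize_on(linearize_on(g, k, "+"), 300L - k, "+")$seq, g$seq)
  # minus-strand anchor: output begins with the revcomp'd gene's ATG
  gene <- "ATGGCTAAATAA"
  gm <- circular_genome(paste0("TTTT", oracle_revcomp(gene), "CCCC"))
  gl <- linearize_on(gm, 15, "-")  # highest-coordinate base of the start codon
  expect_equal(substr(gl$seq, 1, nchar(gene)), gene)
  expect_error(linearize_on(circular_genome("ATGC", topology = "linear"), 0),
               "circular")
})

test_that("linearize_features remaps coordinates consistently with the genome", {
  set.seed(9)
  sp <- genome_spec(length_bp = 6000L, n_orfs = 4L, hr_specs = list(),
                    dr_specs = list(), seed = 31)
  gt <- generate_genome(sp)
  o <- gt$truth$orfs
  anchor <- o$start[2]
  g2 <- linearize_on(gt$genome, anchor, "+")
  f2 <- linearize_features(o, anchor, "+")
  # remapping reorders rows into the new genome order; compare as sets
  got <- sort(vapply(seq_len(nrow(f2)), function(i)
    subsequence(g2, f2$start[i], f2$end[i], f2$strand[i]), character(1)))
  want <- sort(vapply(seq_len(nrow(o)), function(i)
    subsequence(gt$genome, o$start[i], o$end[i], o$strand[i]), character(1)))
  expect_equal(got, want)
  # the anchored ORF now starts at position 0
  expect_true(any(f2$start == 0L))
})

test_that("genome summary computes GC and union coding density", {
  g <- circular_genome("GCGC")
  s <- summarize_genome(g, NULL)
  expect_equal(s$gc_percent, 100)
  expect_equal(s$coding_percent, 0)
  g2 <- circular_genome(random_dna(300))
  tb <- feature_table(c("a", "b"), c(0L, 50L), c(100L, 150L), "+", "CDS",
                      genome_id = g2$id, genome_length = 300L)
  s2 <- summarize_genome(g2, tb)
  expect_equal(s2$coding_percent, 50)  # union of overlapping CDS, not the sum
  expect_equal(s2$orf_count, 2L)
  # N excluded from both numerator and denominator
  gN <- circular_genome("GCNNAT")
  expect_equal(summarize_genome(gN)$gc_percent, 50)
  # GC and coding density invariant under rotation
  set.seed(44)
  g3 <- circular_genome(random_dna(500))
  tb3 <- feature_table("a", 100L, 400L, "+", "CDS", genome_id = g3$id,
                       genome_length = 500L)
  r <- 222L
  g3r <- linearize_on(g3, r, "+")
  tb3r <- linearize_features(tb3, r, "+")
  expect_equal(summarize_genome(g3r, tb3r)$gc_percent,
               summarize_genome(g3, tb3)$gc_percent)
  expect_equal(summarize_genome(g3r, tb3r)$coding_percent,
               summarize_genome(g3, tb3)$coding_percent)
})
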