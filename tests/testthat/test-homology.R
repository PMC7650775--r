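test_that("protein alignment scores, identities and validation behave", {
  al <- align_proteins("MKV", "MKV", mode = "global")
  expect_equal(al$identity, 1)
  # 10 substitutions in a 100-aa sequence: identity 0.90
  set.seed(12)
  a <- random_protein(100)
  v <- strsplit(a, "")[[1]]
  at <- sample(100, 10)
  v[at] <- vapply(v[at], function(r)
    sample(setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], r), 1),
    character(1))
  b <- paste(v, collapse = "")
  expect_equal(align_proteins(a, b, mode = "global")$identity, 0.90)
  expect_error(align_proteins("MK1", "MKV"), "invalid residue")
  expect_error(align_proteins("", "MKV"), "empty")
})

test_that("global alignment score equals an independent affine-gap DP", {
  set.seed(41)
  for (rep in 1:12) {
    a <- random_protein(sample(5:12, 1))
    b <- random_protein(sample(5:12, 1))
    got <- align_proteins(a, b, mode = "global")$score
    expect_equal(got, oracle_global_score(a, b), info = paste(a, b))
  }
})

make_panel <- function(n = 6) {
  tibble::tibble(
    gene_name = paste0("gene", 1:n),
    class = rep(c("core", "lepidopteran_conserved", "other"), length.out = n),
    seq = vapply(1:n, function(i) random_protein(150), character(1))
  )
}

test_that("classification assigns panel genes and falls back to unique", {
  set.seed(52)
  panel <- make_panel()
  orfs <- make_orf_table(data.frame(
    orf_id = c("orf1", "orf2"),
    start = c(0L, 600L), end = c(453L, 1053L), strand = "+",
    codons = 150L, wrap = FALSE,
    translation = c(panel$seq[3],
                    paste(sample(strsplit(panel$seq[3], "")[[1]]), collapse = ""))
  ), genome_length = 2000L)
  cls <- classify_orfs(orfs, panel)
  expect_equal(cls$gene_name[1], "gene3")
  expect_equal(cls$class[1], panel$class[3])
  expect_equal(cls$best_identity[1], 1)
  # residue-shuffled decoy keeps composition but loses homology
  expect_equal(cls$class[2], "unique")
  counts <- summarize_classes(cls)
  expect_equal(counts$n[counts$class == "unique"], 1L)
  expect_error(classify_orfs(orfs, panel[0, ]), "empty")
})

test_that("the bundled gene panel transcribes the published gene classes", {
  panel <- read_gene_panel()
  counts <- table(panel$class)
  expect_equal(unname(counts[["core"]]), 38L)
  expect_equal(unname(counts[["lepidopteran_conserved"]]), 16L)
  expect_equal(unname(counts[["unique"]]), 5L)
  expect_equal(unname(counts[["other"]]), 20L)
  expect_false(any(duplicated(panel$gene_name)))
  # the conflicting iap names are surfaced as aliases, not silently resolved
  expect_equal(panel$alias[panel$orf_id == "orf85"], "iap-6")
  expect_equal(panel$alias[panel$orf_id == "orf105"], "iap-5")
})

test_that("homolog mapping is reciprocal, complete on self, empty on decoys", {
  sp <- genome_spec(length_bp = 9000L, n_orfs = 6L, hr_specs = list(),
                    dr_specs = list(), orf_codon_range = c(80L, 150L),
                    seed = 81)
  gt <- generate_genome(sp)
  o <- gt$truth$orfs
  self <- map_homologs(o, o)
  expect_equal(nrow(self), nrow(o))
  expect_equal(self$orf_a, self$orf_b)
  # 20% protein divergence: nearly all true pairs recovered
  dv <- diverge_genome_pair(gt$genome, gt$truth, d_true = 0.2, kappa = 2,
                            seed = 82)
  hm <- map_homologs(o, dv$orfs)
  truth_pairs <- paste(dv$homologs$orf_a, dv$homologs$orf_b)
  expect_gte(mean(truth_pairs %in% paste(hm$orf_a, hm$orf_b)), 0.95)
  # reciprocity
  hm_rev <- map_homologs(dv$orfs, o)
  expect_equal(sort(paste(hm$orf_a, hm$orf_b)),
               sort(paste(hm_rev$orf_b, hm_rev$orf_a)))
  # unrelated random ORFs produce (almost) no pairs
  set.seed(83)
  decoys <- make_orf_table(data.frame(
    orf_id = paste0("d", 1:6), start = seq(0, 5000, by = 1000)[1:6],
    end = seq(0, 5000, by = 1000)[1:6] + 453L, strand = "+", codons = 150L,
    wrap = FALSE,
    translation = vapply(1:6, function(i) random_protein(150), character(1))
  ), genome_length = 9000L)
  expect_lte(nrow(map_homologs(o, decoys)), 1L)
})

test_that("parity collinearity matches the combinatorial oracle", {
  ids <- function(n) paste0("g", seq_len(n))
  diag_pairs <- tibble::tibble(orf_a = ids(12), orf_b = ids(12))
  pd <- parity_data(ids(12), ids(12), diag_pairs)
  expect_equal(pd$collinearity, 1)
  expect_equal(pd$pairs$index_a, pd$pairs$index_b)
  # fully reversed order: perfect only because reflection is allowed
  rev_pairs <- tibble::tibble(orf_a = ids(12), orf_b = rev(ids(12)))
  expect_equal(parity_data(ids(12), ids(12), rev_pairs)$collinearity, 1)
  norefl <- parity_data(ids(12), ids(12), rev_pairs, allow_reflection = FALSE)
  expect_equal(norefl$collinearity,
               oracle_collinearity(1:12, 12:1, 12, 12, allow_reflection = FALSE))
  # translocated block of 10 in 50 genes
  perm <- c(11:20, 1:10, 21:50)
  tr_pairs <- tibble::tibble(orf_a = ids(50)[perm], orf_b = ids(50))
  pd_tr <- parity_data(ids(50), ids(50), tr_pairs)
  expect_equal(pd_tr$collinearity, 0.8)
  # random permutations against the exhaustive oracle
  set.seed(19)
  for (rep in 1:5) {
    n <- sample(6:9, 1)
    pb <- sample(n)
    pr <- tibble::tibble(orf_a = ids(n), orf_b = ids(n)[pb])
    pd2 <- parity_data(ids(n), ids(n), pr)
    expect_equal(pd2$collinearity,
                 oracle_collinearity(1:n, order(pb), n, n))
  }
  # collinearity invariant under rotation of either gene order
  rot <- function(v, k) c(v[-(1:k)], v[1:k])
  base <- tibble::tibble(orf_a = ids(10), orf_b = ids(10)[sample(10)])
  c0 <- parity_data(ids(10), ids(10), base)$collinearity
  expect_equal(parity_data(rot(ids(10), 3), ids(10), base)$collinearity, c0)
  expect_equal(parity_data(ids(10), rot(ids(10), 6), base)$collinearity, c0)
  expect_error(parity_data(ids(5), ids(5),
                           tibble::tibble(orf_a = "zz", orf_b = "g1")),
               "unknown genes")
})

test_that("parity tidiers expose pairs and the collinearity statistic", {
  ids <- paste0("g", 1:8)
  pd <- parity_data(ids, ids, tibble::tibble(orf_a = ids, orf_b = ids))
  expect_equal(nrow(generics::tidy(pd)), 8L)
  gl <- generics::glance(pd)
  expect_equal(gl$collinearity, 1)
  expect_s3_class(ggplot2::autoplot(pd), "ggplot")
})

test_that("k-mer identity behaves as a containment surrogate", {
  set.seed(29)
  g <- circular_genome(random_dna(4000, gc = 0.4))
  expect_equal(kmer_identity(g, g), 1)
  g2 <- circular_genome(random_dna(4000, gc = 0.4))
  expect_lte(kmer_identity(g, g2), 0.01)  # collision-probability bound
  expect_error(kmer_identity(g, g2, k = 16), "odd")
  expect_error(kmer_identity(g, g2, k = 9), "odd")
  # diverged pair: shared fraction near (1 - d)^k
  d <- 0.05; k <- 17
  g3 <- circular_genome(diverge(g$seq, d, 2, seed = 30))
  expect_lte(abs(kmer_identity(g, g3, k = k) - (1 - d)^k), 0.05)
})
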