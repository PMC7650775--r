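test_that("K2P distance matches the closed form and pairwise deletion rules", {
  s <- strrep("ACGT", 25)
  expect_equal(k2p_distance(s, s)$d, 0)
  # 100 sites, 10 transitions, 5 transversions
  a <- paste(rep("A", 100), collapse = "")
  b <- paste(c(rep("G", 10), rep("C", 5), rep("A", 85)), collapse = "")
  r <- k2p_distance(a, b)
  expect_equal(r$P, 0.10)
  expect_equal(r$Q, 0.05)
  expect_equal(r$d, oracle_k2p(0.10, 0.05), tolerance = 1e-12)
  # gaps and ambiguity codes excluded per pair
  a2 <- "ACGT-ACGTR"
  b2 <- "ACGTTAC-TA"
  expect_equal(k2p_distance(a2, b2)$n_compared, 7L)
  expect_error(k2p_distance("AC", "ACG"), "equal length")
  expect_error(k2p_distance("----", "AAAA"), "no comparable sites")
  # saturation yields the undefined marker, not an error
  sat <- k2p_distance(paste(rep("A", 10), collapse = ""),
                      paste(rep("G", 10), collapse = ""))
  expect_true(is.na(sat$d))
})

test_that("K2P equals the closed form across the defined (P, Q) region", {
  set.seed(63)
  draws <- 0
  while (draws < 200) {
    P <- runif(1, 0, 0.5); Q <- runif(1, 0, 0.4)
    if (1 - 2 * P - Q <= 0.02 || 1 - 2 * Q <= 0.02 || P + Q > 0.9) next
    n <- 1000L
    nP <- round(P * n); nQ <- round(Q * n)
    a <- paste(rep("A", n), collapse = "")
    b <- paste(c(rep("G", nP), rep("T", nQ), rep("A", n - nP - nQ)),
               collapse = "")
    r <- k2p_distance(a, b)
    expect_equal(r$d, oracle_k2p(nP / n, nQ / n), tolerance = 1e-12)
    draws <- draws + 1
  }
  # monotone in P at fixed Q
  ds <- vapply(seq(0.01, 0.3, by = 0.01), function(P)
    oracle_k2p(P, 0.1), double(1))
  expect_true(all(diff(ds) > 0))
})

test_that("pairwise K2P matrices agree with the reference implementation", {
  skip_if_not_installed("ape")
  set.seed(64)
  for (rep in 1:5) {
    n <- sample(4:6, 1)
    width <- 600L
    base <- random_dna(width, gc = 0.45)
    aln <- vapply(seq_len(n), function(i)
      diverge(base, runif(1, 0.01, 0.2), 2, seed = 640 + rep * 10 + i),
      character(1))
    names(aln) <- paste0("t", seq_len(n))
    got <- pairwise_distances(aln)
    bin <- ape::as.DNAbin(t(sapply(strsplit(tolower(aln), ""), identity)))
    want <- as.matrix(ape::dist.dna(bin, model = "K80",
                                    pairwise.deletion = TRUE))
    expect_equal(unname(got$d), unname(want[rownames(got$d), colnames(got$d)]),
                 tolerance = 1e-9)
    expect_equal(diag(got$d), setNames(rep(0, n), names(aln)))
    expect_equal(got$d, t(got$d))
  }
  expect_error(pairwise_distances(c(a = "ACGT", b = "ACG")), "unequal")
})

test_that("species demarcation applies the strict > 0.05 rule", {
  expect_equal(demarcate(c(granulin = 0, lef8 = 0, lef9 = 0))$verdict,
               "same_species")
  v <- demarcate(c(granulin = 0.21, lef8 = 0.18, lef9 = 0.19))
  expect_equal(v$verdict, "distinct_species")
  expect_true(all(generics::tidy(v)$exceeds_threshold))
  expect_equal(demarcate(c(granulin = 0.06, lef8 = 0.04))$verdict,
               "inconclusive")
  # exactly at the threshold is not "more than"
  expect_equal(demarcate(c(granulin = 0.05))$verdict, "same_species")
  expect_equal(demarcate(c(granulin = NA, lef8 = 0.2))$verdict, "inconclusive")
  expect_error(demarcate(numeric()), "no gene distances")
  expect_equal(generics::glance(v)$n_genes, 3L)
})

test_that("NJ solves three taxa in closed form and recovers additive trees", {
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  nwk <- nj_tree(d3)
  skip_if_not_installed("ape")
  tr <- ape::read.tree(text = unclass(nwk))
  cd <- ape::cophenetic.phylo(tr)[c("a", "b", "c"), c("a", "b", "c")]
  expect_equal(unname(cd), unname(d3), tolerance = 1e-6)
  # additive 5-taxon matrices are recovered exactly (topology and lengths)
  set.seed(65)
  for (rep in 1:5) {
    phy <- ape::rtree(5, br = function(n) runif(n, 0.05, 1))
    dm <- oracle_tree_matrix(phy)
    out <- ape::read.tree(text = unclass(nj_tree(dm)))
    expect_equal(unname(ape::cophenetic.phylo(out)[rownames(dm), colnames(dm)]),
                 unname(dm), tolerance = 1e-6)
    expect_equal(phangorn::RF.dist(ape::unroot(phy), out), 0)
  }
  dna <- matrix(NA_real_, 3, 3)
  dimnames(dna) <- list(letters[1:3], letters[1:3])
  diag(dna) <- 0
  expect_error(nj_tree(dna), "undefined")
  expect_error(nj_tree(d3[1:2, 1:2]), "at least 3")
})

test_that("NJ agrees with the reference NJ on random noisy matrices", {
  skip_if_not_installed("ape")
  skip_if_not_installed("phangorn")
  set.seed(66)
  for (rep in 1:5) {
    phy <- ape::rtree(7, br = function(n) runif(n, 0.05, 0.5))
    dm <- oracle_tree_matrix(phy)
    noise <- matrix(runif(49, 0, 0.01), 7)
    noise <- (noise + t(noise)) / 2
    diag(noise) <- 0
    dn <- dm + noise
    mine <- ape::read.tree(text = unclass(nj_tree(dn)))
    ref <- ape::nj(as.dist(dn))
    expect_equal(phangorn::RF.dist(mine, ref), 0)
  }
})

test_that("negative NJ branches are clamped with the deficit moved over", {
  # a non-additive matrix known to produce a negative branch estimate
  d <- matrix(c(0, 1, 6, 6,
                1, 0, 6, 6,
                6, 6, 0, 1,
                6, 6, 1, 0), 4,
              dimnames = list(letters[1:4], letters[1:4]))
  d["a", "b"] <- 0.01; d["b", "a"] <- 0.01
  nwk <- unclass(nj_tree(d))
  lens <- as.numeric(stringr::str_match_all(nwk, ":([-0-9.eE+]+)")[[1]][, 2])
  expect_true(all(lens >= 0))
})

test_that("alignment concatenation preserves blocks, offsets and distances", {
  a1 <- c(x = "ACGTACGTAC", y = "ACGTACGTAT", z = "ACGAACGTAC")
  a2 <- c(y = "TTTTGGGGCC", x = "TTTTGGGGCA", z = "TTATGGGGCC")
  cc <- concat_alignments(list(g1 = a1, g2 = a2))
  expect_equal(nchar(cc[["x"]]), 20L)
  off <- attr(cc, "offsets")
  expect_equal(off$start, c(1L, 11L))
  expect_equal(off$end, c(10L, 20L))
  expect_equal(cc[["x"]], paste0(a1[["x"]], a2[["x"]]))
  # permuting block order changes columns but not pairwise distances
  cc2 <- concat_alignments(list(g1 = a1, g2 = a2), order = c("g2", "g1"))
  expect_equal(pairwise_distances(cc)$d, pairwise_distances(cc2)$d)
  a3 <- c(x = "AAAA", y = "AAAA")  # z missing
  expect_error(concat_alignments(list(g1 = a1, g3 = a3)), "missing z")
  expect_error(concat_alignments(list(g1 = a1), order = "nope"), "unknown genes")
})

test_that("bootstrap support is reproducible and bounded", {
  set.seed(67)
  base <- random_dna(400, gc = 0.45)
  aln <- c(a = base,
           b = diverge(base, 0.02, 2, seed = 1),
           c = diverge(base, 0.25, 2, seed = 2),
           d = diverge(base, 0.28, 2, seed = 3))
  b1 <- bootstrap_support(aln, n = 30, seed = 5)
  b2 <- bootstrap_support(aln, n = 30, seed = 5)
  expect_equal(b1, b2)
  expect_true(all(b1$support >= 0 & b1$support <= 1))
  expect_error(bootstrap_support(aln, n = 10), "seed")
})
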