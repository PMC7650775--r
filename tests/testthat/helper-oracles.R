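# Independent oracles used across the suite. These re-derive expected
# results by brute force or closed form, through different code paths than
# the implementation under test.

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

oracle_revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# six-frame ORF enumeration on the doubled sequence, deduplicated
oracle_orfs <- function(genome, min_codons = 50L) {
  L <- genome_length(genome)
  circ <- genome$topology == "circular"
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") genome$seq else oracle_revcomp(genome$seq)
    work <- if (circ) paste0(s, s) else s
    n <- nchar(work)
    for (f in 0:2) {
      pos1 <- seq(f + 1L, n - 2L, by = 3L)
      cods <- substring(work, pos1, pos1 + 2L)
      stopi <- which(cods %in% c("TAA", "TAG", "TGA"))
      atgi <- which(cods == "ATG")
      kfirst <- if (circ) 2L else 1L
      if (length(stopi) < kfirst) next
      for (k in kfirst:length(stopi)) {
        prev <- if (k == 1L) 0L else stopi[k - 1L]
        cand <- atgi[atgi > prev & atgi < stopi[k]]
        if (length(cand) == 0L) next
        ncod <- stopi[k] - cand[1]
        if (ncod < min_codons) next
        a0 <- pos1[cand[1]] - 1L
        e0 <- pos1[stopi[k]] + 2L
        if (circ && a0 >= L) next
        if (e0 - a0 > L) next
        if (strand == "+") {
          st <- a0; en <- e0
        } else {
          st <- (L - e0) %% L; en <- st + (e0 - a0)
        }
        rows[[length(rows) + 1L]] <- data.frame(start = st, end = en,
                                                strand = strand,
                                                codons = ncod)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), codons = integer()))
  }
  out <- unique(do.call(rbind, rows))
  out[order(out$start, out$end, out$strand), ]
}

# regex-expansion IUPAC matcher (mapping taken from Biostrings, not from
# the package's own table)
oracle_iupac <- function(pattern, window) {
  map <- Biostrings::IUPAC_CODE_MAP
  rx <- paste0("(?=", paste(vapply(strsplit(pattern, "")[[1]], function(ch)
    paste0("[", map[[ch]], "]"), character(1)), collapse = ""), ")")
  m <- gregexpr(rx, window, perl = TRUE)[[1]]
  if (m[1] == -1L) integer() else as.integer(m) - 1L
}

# all promoter-class hits in an upstream window, by brute force
oracle_promoter_hits <- function(win, spacing = 25:35) {
  n <- nchar(win)
  rel <- function(o) o - n
  rows <- list()
  for (t in oracle_iupac("TATAW", win)) {
    for (c0 in oracle_iupac("CAKT", win)) {
      if ((c0 - t) %in% spacing) {
        rows[[length(rows) + 1L]] <- data.frame(class = "early_tata_cakt",
                                                rel_start = rel(t),
                                                spacing_nt = c0 - t)
      }
    }
  }
  for (o in oracle_iupac("TAATWAA", win)) {
    rows[[length(rows) + 1L]] <- data.frame(class = "lef_tata_like",
                                            rel_start = rel(o),
                                            spacing_nt = NA_integer_)
  }
  for (o in oracle_iupac("DTAAG", win)) {
    rows[[length(rows) + 1L]] <- data.frame(class = "late",
                                            rel_start = rel(o),
                                            spacing_nt = NA_integer_)
  }
  if (length(rows) == 0L) {
    return(data.frame(class = character(), rel_start = integer(),
                      spacing_nt = integer()))
  }
  out <- do.call(rbind, rows)
  out[order(out$class, out$rel_start, out$spacing_nt), ]
}

# O(n^2) all-substring perfect-palindrome check returning maximal spans
# (early exit at the first non-complementary outer pair keeps it tractable)
oracle_palindromes <- function(seq, min_len) {
  x <- strsplit(seq, "")[[1]]
  cmp <- c(A = "T", T = "A", C = "G", G = "C")[x]
  cmp[is.na(cmp)] <- "?"
  n <- length(x)
  is_pal <- function(a, b) {  # 1-based inclusive, outside-in with early exit
    while (a < b) {
      if (is.na(x[a]) || x[a] != cmp[b]) return(FALSE)
      a <- a + 1L; b <- b - 1L
    }
    TRUE
  }
  rows <- list()
  for (a in 1:(n - min_len + 1L)) {
    for (len in seq(min_len, n - a + 1L, by = 2L)) {
      b <- a + len - 1L
      if (!is_pal(a, b)) next
      extendable <- a > 1L && b < n && is_pal(a - 1L, b + 1L)
      if (!extendable) {
        rows[[length(rows) + 1L]] <- data.frame(start = a - 1L, length = len)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(start = integer(), length = integer()))
  }
  out <- unique(do.call(rbind, rows))
  out[order(out$start, out$length), ]
}

# closed-form K2P
oracle_k2p <- function(P, Q) -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))

# additive distance matrix from a tree given as merge structure:
# leaf-to-leaf path lengths on an ape phylo object
oracle_tree_matrix <- function(phy) {
  m <- ape::cophenetic.phylo(phy)
  m[phy$tip.label, phy$tip.label]
}

# O(n^2) longest strictly-increasing subsequence
oracle_lis <- function(v) {
  n <- length(v)
  if (n == 0L) return(0L)
  best <- rep(1L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (v[j] < v[i] && best[j] + 1L > best[i]) best[i] <- best[j] + 1L
    }
  }
  max(best)
}

# exhaustive collinearity over rotations of both orders and reflection
oracle_collinearity <- function(ia, ib, na, nb, allow_reflection = TRUE) {
  best <- 0L
  for (refl in c(FALSE, if (allow_reflection) TRUE)) {
    jb <- if (refl) nb + 1L - ib else ib
    for (ra in seq_len(na)) {
      aa <- (ia - ra) %% na
      ord <- order(aa)
      for (rb in seq_len(nb)) {
        bb <- (jb[ord] - rb) %% nb
        best <- max(best, oracle_lis(bb))
      }
    }
  }
  best / length(ia)
}

# affine-gap global alignment score by independent 3-state DP
# (gap of length k costs open + k * ext, matching the package scoring)
oracle_global_score <- function(a, b, open = 10, ext = 1) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  S <- get("BLOSUM62", envir = environment())
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)  # gap in b (a consumed)
  Y <- matrix(NEG, n + 1L, m + 1L)  # gap in a
  M[1, 1] <- 0
  for (i in 2:(n + 1L)) X[i, 1] <- -open - (i - 1L) * ext
  for (j in 2:(m + 1L)) Y[1, j] <- -open - (j - 1L) * ext
  for (i in 2:(n + 1L)) {
    for (j in 2:(m + 1L)) {
      sc <- S[av[i - 1L], bv[j - 1L]]
      M[i, j] <- max(M[i - 1L, j - 1L], X[i - 1L, j - 1L],
                     Y[i - 1L, j - 1L]) + sc
      X[i, j] <- max(M[i - 1L, j] - open - ext, X[i - 1L, j] - ext)
      Y[i, j] <- max(M[i, j - 1L] - open - ext, Y[i, j - 1L] - ext)
    }
  }
  max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
}

random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# orf-table scaffold for tests that need hand-built candidates
make_orf_table <- function(df, genome_length, genome_id = "toy") {
  tb <- tibble::as_tibble(df)
  attr(tb, "genome_id") <- genome_id
  attr(tb, "genome_length") <- genome_length
  class(tb) <- c("orf_table", class(tb))
  tb
}
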