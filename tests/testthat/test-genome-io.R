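test_that("circular subsequence wraps, reverse-complements, and validates", {
  g <- circular_genome("ATGC", id = "toy")
  expect_equal(genome_length(g), 4L)
  expect_equal(subsequence(g, 3, 6, "+"), "CAT")
  expect_equal(subsequence(g, 0, 4, "-"), "GCAT")
  expect_error(circular_genome(""), "non-empty")
  expect_error(circular_genome("ATXG"), "invalid character 'X' at position 3")
  lin <- circular_genome("ATGC", topology = "linear")
  expect_error(subsequence(lin, 3, 6), "circular")
  # property: minus strand equals revcomp of the plus slice
  set.seed(11)
  g2 <- circular_genome(random_dna(200))
  for (i in 1:50) {
    s <- sample(0:199, 1); w <- sample(1:200, 1)
    expect_equal(subsequence(g2, s, s + w, "-"),
                 oracle_revcomp(subsequence(g2, s, s + w, "+")))
  }
})

test_that("FASTA reading round-trips and rejects malformed input", {
  td <- withr::local_tempdir()
  fa <- file.path(td, "g.fa")
  g <- circular_genome(random_dna(150), id = "toyG")
  write_genome_fasta(g, fa)
  back <- read_genome_fasta(fa)
  expect_equal(back$seq, g$seq)
  expect_equal(back$id, "toyG")
  expect_equal(back$topology, "circular")
  writeLines(c(">a", "ATGC", ">b", "ATGC"), fa)
  expect_error(read_genome_fasta(fa), "single genome record")
  writeLines(c(">a", "ATGXC"), fa)
  expect_error(read_genome_fasta(fa), "position 4")
  expect_error(read_genome_fasta(file.path(td, "missing.fa")), "not found")
})

test_that("GFF3 and GenBank round-trip feature tables, including origin spans", {
  td <- withr::local_tempdir()
  set.seed(7)
  mk_table <- function() {
    n <- 10L
    L <- 5000L
    start <- sort(sample(0:(L - 400L), n))
    width <- sample(seq(90L, 390L, by = 3L), n, replace = TRUE)
    feature_table(
      feature_id = paste0("f", 1:n), start = start, end = start + width,
      strand = sample(c("+", "-"), n, replace = TRUE), kind = "CDS",
      gene = paste0("gene", 1:n), product = "hypothetical protein",
      genome_id = "toy", genome_length = L
    )
  }
  for (dialect in c("gff3", "genbank")) {
    for (rep in 1:3) {
      tb <- mk_table()
      p <- file.path(td, paste0("t.", dialect))
      write_annotation(tb, p, dialect)
      back <- read_annotation(p, dialect)
      expect_equal(as.data.frame(back[, 1:8]), as.data.frame(tb[, 1:8]))
      expect_equal(attr(back, "genome_length"), attr(tb, "genome_length"))
    }
    # origin-spanning feature emitted as a join and reconstructed
    wrap_tb <- feature_table("w1", 4900L, 5000L + 150L, "+", "CDS",
                             gene = "wrapper", genome_id = "toy",
                             genome_length = 5000L)
    p <- file.path(td, paste0("w.", dialect))
    write_annotation(wrap_tb, p, dialect)
    back <- read_annotation(p, dialect)
    expect_true(back$wrap[1])
    expect_equal(back$start, 4900L)
    expect_equal(back$end, 5150L)
    raw <- paste(readLines(p), collapse = "\n")
    if (dialect == "genbank") expect_match(raw, "join\\(4901\\.\\.5000,1\\.\\.150\\)")
  }
})

test_that("GFF3 writer emits 1-based inclusive coordinates with CDS phase", {
  td <- withr::local_tempdir()
  tb <- feature_table("c1", 0L, 300L, "+", "CDS", genome_id = "g",
                      genome_length = 1000L)
  p <- file.path(td, "one.gff3")
  write_annotation(tb, p, "gff3")
  body <- grep("^[^#]", readLines(p), value = TRUE)
  f <- strsplit(body, "\t")[[1]]
  expect_equal(as.integer(f[4:5]), c(1L, 300L))
  expect_equal(f[8], "0")
  back <- read_annotation(p, "gff3")
  expect_equal(c(back$start, back$end), c(0L, 300L))
})

test_that("empty tables, unknown kinds and bad coordinates are handled", {
  td <- withr::local_tempdir()
  empty <- feature_table(genome_id = "g", genome_length = 100L)
  for (dialect in c("gff3", "genbank")) {
    p <- file.path(td, paste0("e.", dialect))
    write_annotation(empty, p, dialect)
    back <- read_annotation(p, dialect)
    expect_equal(nrow(back), 0L)
  }
  # unknown kind kept as "other" with a warning
  writeLines(c("##gff-version 3", "##sequence-region g 1 100",
               paste("g", "x", "mobile_element", "5", "20", ".", "+", ".",
                     "ID=me1", sep = "\t")), file.path(td, "u.gff3"))
  expect_warning(tb <- read_annotation(file.path(td, "u.gff3")), "mobile_element")
  expect_equal(tb$kind, "other")
  # coordinate beyond the genome is an error
  writeLines(c("##gff-version 3", "##sequence-region g 1 100",
               paste("g", "x", "CDS", "5", "200", ".", "+", "0",
                     "ID=bad", sep = "\t")), file.path(td, "b.gff3"))
  expect_error(read_annotation(file.path(td, "b.gff3")), "outside genome length")
})

test_that("GenBank parsing copes with archive-style records", {
  td <- withr::local_tempdir()
  gb <- file.path(td, "real.gb")
  writeLines(c(
    "LOCUS       TV000001              1200 bp    DNA     circular VRL 01-JAN-2020",
    "DEFINITION  toy virus, complete genome.",
    "FEATURES             Location/Qualifiers",
    "     source          1..1200",
    '                     /organism="toy virus"',
    "     gene            1..300",
    '                     /gene="granulin"',
    "     CDS             1..300",
    '                     /gene="granulin"',
    '                     /product="occlusion body matrix',
    '                     protein granulin"',
    '                     /protein_id="QQQ00001.1"',
    "     CDS             complement(join(1100..1200,1..60))",
    '                     /gene="me53"',
    "ORIGIN",
    "//"
  ), gb)
  expect_warning(tb <- read_annotation(gb, "genbank"), "gene")
  cds <- tb[tb$kind == "CDS", ]
  expect_equal(nrow(cds), 2L)
  expect_equal(cds$gene, c("granulin", "me53"))
  expect_equal(cds$start[1], 0L)
  expect_equal(cds$end[1], 300L)
  # the wrapped qualifier did not corrupt the next feature's location
  expect_true(cds$wrap[2])
  expect_equal(cds$start[2], 1099L)
  expect_equal(cds$end[2], 1260L)
  expect_equal(cds$strand[2], "-")
})

test_that("internal/external coordinate conversion is an involution", {
  set.seed(13)
  L <- 10000L
  n <- 500L
  start <- sample(0:(L - 1L), n, replace = TRUE)
  width <- sample(30:600, n, replace = TRUE)
  tb <- feature_table(paste0("f", 1:n), start, start + width,
                      sample(c("+", "-"), n, TRUE), "CDS",
                      genome_id = "g", genome_length = L)
  td <- withr::local_tempdir()
  p <- file.path(td, "many.gff3")
  write_annotation(tb, p, "gff3")
  back <- read_annotation(p)
  ord <- order(tb$start, tb$end, tb$feature_id)
  ord2 <- order(back$start, back$end, back$feature_id)
  expect_equal(as.data.frame(back[ord2, 1:8]), as.data.frame(tb[ord, 1:8]))
})
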