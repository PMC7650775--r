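#' Predict open reading frames on a (circular) genome
#'
#' Scans all six reading frames for start-to-stop ORFs of at least
#' `min_codons` codons (stop codon excluded from the count and the
#' translation). On circular genomes the scan runs over the doubled
#' sequence, so ORFs spanning the origin are found and flagged with
#' `wrap = TRUE`. Candidates sharing a stop codon are collapsed to the
#' longest (most upstream start).
#'
#' Reported coordinates include the stop codon, matching the usual CDS
#' convention, so `(end - start) %% 3 == 0` and
#' `codons == (end - start) / 3 - 1`.
#'
#' @param genome A [circular_genome()].
#' @param min_codons Minimum ORF length in codons (default 50, the usual
#'   small-ORF floor for baculovirus annotation).
#' @param start_codons Character vector of accepted start codons
#'   (default `"ATG"`; add `"GTG"`/`"TTG"` for alternative starts).
#' @param table Genetic code id (only 1, the standard code, is supported).
#' @return A tibble of class `orf_table` with columns `orf_id`, `start`,
#'   `end`, `strand`, `codons`, `translation`, `wrap`, ordered by genome
#'   position, plus `genome_id`/`genome_length` attributes.
#' @examples
#' g <- circular_genome(paste0("ATG", strrep("GCT", 60), "TAA", strrep("T", 40)))
#' find_orfs(g, min_codons = 50)
#' @export
find_orfs <- function(genome, min_codons = 50L, start_codons = "ATG",
                      table = 1L) {
  stopifnot(inherits(genome, "circular_genome"))
  if (min_codons < 1L) abort("min_codons must be >= 1")
  if (!identical(as.integer(table), 1L)) {
    abort("only the standard genetic code (table = 1) is supported")
  }
  if (!all(grepl("^[ACGT]{3}$", start_codons))) {
    abort("start codons must be DNA triplets")
  }
  L <- genome_length(genome)
  circ <- genome$topology == "circular"
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") genome$seq else revcomp(genome$seq)
    work <- if (circ) paste0(s, s) else s
    starts <- regex_offsets(work, paste0("(?=(", paste(start_codons, collapse = "|"), "))"))
    stops <- regex_offsets(work, "(?=(TAA|TAG|TGA))")
    for (f in 0:2) {
      st_f <- starts[starts %% 3L == f]
      sp_f <- stops[stops %% 3L == f]
      if (length(sp_f) == 0L) next
      first <- if (circ) 2L else 1L  # circular: first stop lacks upstream context
      if (length(sp_f) < first) next
      for (k in first:length(sp_f)) {
        stop_pos <- sp_f[k]
        prev_end <- if (k == 1L) f - 3L else sp_f[k - 1L]
        cand <- st_f[st_f > prev_end & st_f < stop_pos]
        if (length(cand) == 0L) next
        a <- cand[1L]  # most upstream start after the previous stop
        if (circ && a >= L) next  # duplicate of the first-copy ORF
        codons <- (stop_pos - a) %/% 3L
        if (codons < min_codons) next
        span_end <- stop_pos + 3L
        if (span_end - a > L) next  # cannot exceed the genome
        out[[length(out) + 1L]] <- c(a = a, e = span_end,
                                     strand = if (strand == "+") 1L else -1L,
                                     codons = codons)
      }
    }
  }
  if (length(out) == 0L) {
    return(orf_table(tibble(orf_id = character(), start = integer(),
                            end = integer(), strand = character(),
                            codons = integer(), translation = character(),
                            wrap = logical()), genome))
  }
  m <- do.call(rbind, out)
  # map minus-strand local coordinates back onto the plus strand
  df <- tibble(
    start = as.integer(ifelse(m[, "strand"] == 1L, m[, "a"], (L - m[, "e"]) %% L)),
    width = as.integer(m[, "e"] - m[, "a"]),
    strand = ifelse(m[, "strand"] == 1L, "+", "-"),
    codons = as.integer(unname(m[, "codons"]))
  ) |>
    mutate(start = as.integer(.data$start),
           end = as.integer(.data$start + .data$width),
           wrap = .data$end > L) |>
    distinct(.data$start, .data$end, .data$strand, .keep_all = TRUE) |>
    arrange(.data$start, .data$end, .data$strand)
  df$translation <- vapply(seq_len(nrow(df)), function(i) {
    translate_cds(subsequence(genome, df$start[i], df$end[i], df$strand[i]))
  }, character(1))
  df$orf_id <- paste0("orf", seq_len(nrow(df)))
  orf_table(df[, c("orf_id", "start", "end", "strand", "codons",
                   "translation", "wrap")], genome)
}

regex_offsets <- function(s, pattern) {
  m <- gregexpr(pattern, s, perl = TRUE)[[1]]
  if (m[1] == -1L) integer() else as.integer(m) - 1L
}

translate_cds <- function(cds) {
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                           if.fuzzy.codon = "solve"))
  sub("\\*$", "", aa)
}

orf_table <- function(df, genome) {
  tb <- as_tibble(df)
  attr(tb, "genome_id") <- genome$id
  attr(tb, "genome_length") <- genome_length(genome)
  class(tb) <- c("orf_table", class(tb))
  tb
}

#' Resolve overlapping ORF candidates ("minimal overlap" rule)
#'
#' Greedy selection by descending codon count (ties: smaller start, then
#' plus strand): a candidate is rejected iff it overlaps an already
#' accepted ORF by more than `max_overlap_bp` on either strand. Overlap is
#' computed on the circle (origin-spanning ORFs count correctly). Survivors
#' are renumbered `orf1..orfN` in genome order.
#'
#' @param candidates An `orf_table` from [find_orfs()].
#' @param max_overlap_bp Maximum tolerated overlap in bp (default 30).
#' @return An `orf_table` subset of the input, renumbered in genome order.
#' @export
resolve_overlaps <- function(candidates, max_overlap_bp = 30L) {
  if (max_overlap_bp < 0L) abort("max_overlap_bp must be >= 0")
  L <- attr(candidates, "genome_length")
  if (nrow(candidates) <= 1L) return(renumber_orfs(candidates))
  ord <- order(-candidates$codons, candidates$start,
               candidates$strand != "+")
  accepted <- integer()
  for (i in ord) {
    ok <- TRUE
    for (j in accepted) {
      ov <- circular_overlap_bp(candidates$start[i], candidates$end[i],
                                candidates$start[j], candidates$end[j], L)
      if (ov > max_overlap_bp) { ok <- FALSE; break }
    }
    if (ok) accepted <- c(accepted, i)
  }
  renumber_orfs(candidates[sort(accepted), ])
}

renumber_orfs <- function(tb) {
  if (nrow(tb) > 0L) {
    tb <- tb[order(tb$start, tb$end), ]
    tb$orf_id <- paste0("orf", seq_len(nrow(tb)))
  }
  tb
}

# overlap in bp between two 0-based half-open intervals on a circle of size L
circular_overlap_bp <- function(s1, e1, s2, e2, L) {
  segs <- function(s, e) {
    if (is.na(L) || e <= L) list(c(s, e))
    else list(c(s, L), c(0L, e - L))
  }
  a <- segs(s1, e1); b <- segs(s2, e2)
  tot <- 0L
  for (x in a) for (y in b) {
    tot <- tot + max(0L, min(x[2], y[2]) - max(x[1], y[1]))
  }
  tot
}

#' Rotate a circular genome so an anchor gene starts at position 1
#'
#' Mirrors the convention of placing a chosen first ORF (granulin for
#' granuloviruses) with its start codon as the first three nucleotides of
#' the published genome. For a minus-strand anchor the genome is
#' reverse-complemented first; `anchor_start` is then the position of the
#' first base of the start codon in the anchor's own reading direction
#' (i.e. the highest-coordinate base of the codon on the plus strand).
#'
#' @param genome A circular [circular_genome()].
#' @param anchor_start 0-based position of the first base of the anchor
#'   start codon (see Details for minus-strand anchors).
#' @param anchor_strand `"+"` or `"-"`.
#' @return A rotated (and possibly reverse-complemented) genome.
#' @export
linearize_on <- function(genome, anchor_start, anchor_strand = "+") {
  stopifnot(inherits(genome, "circular_genome"))
  if (genome$topology != "circular") abort("linearize_on requires a circular genome")
  L <- genome_length(genome)
  if (anchor_start < 0 || anchor_start >= L) abort("anchor outside genome")
  if (anchor_strand == "+") {
    s <- genome$seq
    r <- anchor_start
  } else {
    s <- revcomp(genome$seq)
    r <- L - 1L - anchor_start
  }
  rotated <- if (r == 0L) s else paste0(substr(s, r + 1L, L), substr(s, 1L, r))
  circular_genome(rotated, id = genome$id, topology = "circular")
}

#' Remap feature coordinates under [linearize_on()]
#'
#' @param table A [feature_table()] or `orf_table` on the original genome.
#' @param anchor_start,anchor_strand As in [linearize_on()].
#' @return The table with coordinates (and strands, for a minus-strand
#'   anchor) remapped onto the rotated genome.
#' @export
linearize_features <- function(table, anchor_start, anchor_strand = "+") {
  L <- attr(table, "genome_length")
  if (is.na(L)) abort("table lacks a genome_length attribute")
  w <- table$end - table$start
  if (anchor_strand == "+") {
    ns <- (table$start - anchor_start) %% L
  } else {
    r <- L - 1L - anchor_start
    # position p maps to L-1-p under revcomp; the new start is the image of
    # the feature's last base, then everything rotates by r
    ns <- (L - ((table$start + w - 1L) %% L) - 1L - r) %% L
    table$strand <- ifelse(table$strand == "+", "-", "+")
  }
  table$start <- as.integer(ns)
  table$end <- as.integer(ns + w)
  if ("wrap" %in% names(table)) table$wrap <- table$end > L
  table[order(table$start, table$end), ]
}

#' Genome summary statistics
#'
#' GC is computed over unambiguous bases only; coding density is the
#' fraction of genome positions covered by at least one CDS (overlaps
#' counted once, origin-spanning CDS handled on the circle).
#'
#' @param genome A [circular_genome()].
#' @param table A [feature_table()] or `orf_table`; rows with
#'   `kind == "CDS"` (or all rows of an `orf_table`) are counted as coding.
#' @return A one-row tibble: `length_bp`, `gc_percent`, `orf_count`,
#'   `coding_percent`.
#' @export
summarize_genome <- function(genome, table = NULL) {
  L <- genome_length(genome)
  if (is.null(table) || nrow(table) == 0L) {
    cds <- tibble(start = integer(), end = integer())
  } else if ("kind" %in% names(table)) {
    cds <- table[table$kind == "CDS", c("start", "end")]
  } else {
    cds <- table[, c("start", "end")]
  }
  covered <- logical(L)
  for (i in seq_len(nrow(cds))) {
    idx <- (cds$start[i]:(cds$end[i] - 1L)) %% L + 1L
    covered[idx] <- TRUE
  }
  tibble(
    length_bp = L,
    gc_percent = gc_percent(genome),
    orf_count = nrow(cds),
    coding_percent = 100 * sum(covered) / L
  )
}

#' Build an ORF table from an annotation's CDS features
#'
#' Pass-through companion to [find_orfs()]: takes CDS rows of a
#' [feature_table()] (e.g. read from GenBank/GFF3), extracts translations
#' from the genome and renumbers the ORFs `orf1..orfN` in genome order.
#'
#' @param genome A [circular_genome()].
#' @param features A [feature_table()] (rows with `kind != "CDS"` are
#'   dropped) or any tibble with `start`, `end`, `strand`.
#' @return An `orf_table`.
#' @export
orf_table_from_features <- function(genome, features) {
  if ("kind" %in% names(features)) {
    features <- features[features$kind == "CDS", ]
  }
  features <- features[order(features$start, features$end), ]
  tb <- tibble(
    orf_id = paste0("orf", seq_len(nrow(features))),
    start = features$start, end = features$end, strand = features$strand,
    codons = as.integer((features$end - features$start) / 3 - 1),
    translation = vapply(seq_len(nrow(features)), function(i) {
      gsub("\\*", "X", translate_cds(
        subsequence(genome, features$start[i], features$end[i],
                    features$strand[i])))
    }, character(1)),
    wrap = features$end > genome_length(genome)
  )
  orf_table(tb, genome)
}

#' Convert an ORF table to a CDS feature table
#'
#' @param orfs An `orf_table`.
#' @param genome_id,genome_length Overrides; default from the table.
#' @return A [feature_table()] of CDS features.
#' @export
orfs_as_features <- function(orfs, genome_id = NULL, genome_length = NULL) {
  feature_table(
    feature_id = orfs$orf_id, start = orfs$start, end = orfs$end,
    strand = orfs$strand, kind = "CDS", gene = orfs$orf_id,
    product = "hypothetical protein",
    genome_id = genome_id %||% attr(orfs, "genome_id") %||% "genome",
    genome_length = genome_length %||% attr(orfs, "genome_length")
  )
}
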