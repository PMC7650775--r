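#' Circular genome container
#'
#' A light container for a (usually circular) dsDNA genome sequence. The
#' sequence is stored uppercase over the alphabet `A`, `C`, `G`, `T`, `N`.
#' All coordinates used by the package are 0-based half-open on the plus
#' strand of this sequence; for circular genomes index arithmetic is modulo
#' the genome length, and slices may run across the origin.
#'
#' @param seq Single character string of DNA.
#' @param id Text label for the record.
#' @param topology `"circular"` (default) or `"linear"`.
#' @return An object of class `circular_genome` with fields `id`, `seq`,
#'   `topology`.
#' @examples
#' g <- circular_genome("ATGCATGCAT", id = "toy")
#' genome_length(g)
#' subsequence(g, 8, 12)  # wraps across the origin
#' @export
circular_genome <- function(seq, id = "genome", topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (nchar(seq) == 0L) abort("genome sequence must be non-empty")
  bad <- stringr::str_locate(seq, "[^ACGTN]")[1, "start"]
  if (!is.na(bad)) {
    abort(sprintf(
      "invalid character '%s' at position %d of record '%s' (alphabet is A/C/G/T/N)",
      substr(seq, bad, bad), bad, id
    ))
  }
  structure(list(id = id, seq = seq, topology = topology),
            class = "circular_genome")
}

#' @export
print.circular_genome <- function(x, ...) {
  cat(sprintf("<circular_genome> %s: %s bp, %s\n", x$id,
              format(genome_length(x), big.mark = ","), x$topology))
  invisible(x)
}

#' Genome length in base pairs
#' @param genome A [circular_genome()].
#' @return Integer number of bases.
#' @export
genome_length <- function(genome) {
  stopifnot(inherits(genome, "circular_genome"))
  nchar(genome$seq)
}

#' Reverse complement of a DNA string
#'
#' IUPAC ambiguity codes are complemented as well, so patterns and sequences
#' can both be flipped.
#'
#' @param seq Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(seq) {
  fwd <- "ACGTNRYSWKMBDHV"
  rev <- "TGCANYRSWMKVHDB"
  vapply(seq, function(s) {
    stringi_rev(chartr(fwd, rev, toupper(s)))
  }, character(1), USE.NAMES = FALSE)
}

# base-R string reversal (no stringi dependency)
stringi_rev <- function(s) {
  paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
}

#' Extract a (possibly origin-spanning) subsequence
#'
#' Coordinates are 0-based half-open on the plus strand. For circular
#' genomes `end` may exceed the genome length, in which case the slice wraps
#' across the origin and the tail and head are concatenated. For
#' `strand = "-"` the reverse complement of the plus-strand slice is
#' returned.
#'
#' @param genome A [circular_genome()].
#' @param start,end 0-based half-open interval; `start` may be negative for
#'   circular genomes (interpreted modulo length).
#' @param strand `"+"` or `"-"`.
#' @return A character string of length `end - start`.
#' @export
subsequence <- function(genome, start, end, strand = "+") {
  stopifnot(inherits(genome, "circular_genome"))
  L <- genome_length(genome)
  if (end < start) abort("end must be >= start")
  if (end - start > L) abort("requested slice longer than the genome")
  if (genome$topology == "linear") {
    if (start < 0 || end > L) {
      abort("slice runs outside a linear genome (wrap requires circular topology)")
    }
  } else {
    # normalise start into [0, L)
    shift <- ((start %% L) - start)
    start <- start + shift
    end <- end + shift
  }
  if (end <= L) {
    s <- substr(genome$seq, start + 1L, end)
  } else {
    s <- paste0(substr(genome$seq, start + 1L, L),
                substr(genome$seq, 1L, end - L))
  }
  if (strand == "-") revcomp(s) else s
}

#' Read a genome from a FASTA file
#'
#' FASTA structure is parsed with Biostrings; the record is then validated
#' against the package alphabet (`A/C/G/T/N`), reporting the offending
#' record and offset on failure. In genome mode (the default) exactly one
#' record is required.
#'
#' @param path Path to a FASTA file.
#' @param topology Topology flag attached to the genome, default circular.
#' @param multi Allow multiple records? If `TRUE`, a list of genomes is
#'   returned.
#' @return A [circular_genome()] (or list thereof when `multi = TRUE`).
#' @export
read_genome_fasta <- function(path, topology = c("circular", "linear"),
                              multi = FALSE) {
  topology <- match.arg(topology)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) abort(sprintf("empty FASTA file: %s", path))
  if (!multi && length(recs) > 1L) {
    abort(sprintf("expected a single genome record, found %d in %s",
                  length(recs), path))
  }
  ids <- stringr::word(names(recs), 1)
  out <- lapply(seq_along(recs), function(i) {
    circular_genome(as.character(recs[[i]]), id = ids[i], topology = topology)
  })
  if (multi) out else out[[1]]
}

#' Write genomes to FASTA (60-column wrap)
#'
#' @param genomes A [circular_genome()] or list of them.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_genome_fasta <- function(genomes, path) {
  if (inherits(genomes, "circular_genome")) genomes <- list(genomes)
  set <- Biostrings::BStringSet(vapply(genomes, `[[`, character(1), "seq"))
  names(set) <- vapply(genomes, `[[`, character(1), "id")
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' GC content of a DNA string or genome, percent
#'
#' `N` bases are excluded from both numerator and denominator.
#'
#' @param x A [circular_genome()] or character DNA string.
#' @return Percentage of G+C among unambiguous bases.
#' @export
gc_percent <- function(x) {
  s <- if (inherits(x, "circular_genome")) x$seq else toupper(x)
  counts <- table(factor(strsplit(s, "", fixed = TRUE)[[1]],
                         levels = c("A", "C", "G", "T", "N")))
  acgt <- sum(counts[c("A", "C", "G", "T")])
  if (acgt == 0) return(NA_real_)
  100 * sum(counts[c("G", "C")]) / acgt
}
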