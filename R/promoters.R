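iupac_classes <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]",
  B = "[CGT]", D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]"
)

#' Match an IUPAC DNA pattern against a window
#'
#' Returns every 0-based offset at which the pattern matches; overlapping
#' matches are all reported. An `N` in the *window* never matches (pattern
#' classes expand to explicit base sets).
#'
#' @param pattern IUPAC DNA pattern (e.g. `"TATAW"`, `"DTAAG"`).
#' @param window DNA string to scan.
#' @return Integer vector of 0-based match offsets.
#' @examples
#' iupac_match("TATAW", "GGTATAAGG")
#' @export
iupac_match <- function(pattern, window) {
  pattern <- toupper(pattern)
  letters <- strsplit(pattern, "", fixed = TRUE)[[1]]
  bad <- setdiff(letters, names(iupac_classes))
  if (length(bad) > 0L) {
    abort(sprintf("invalid IUPAC letter(s) in pattern: %s",
                  paste(unique(bad), collapse = ", ")))
  }
  rx <- paste0("(?=", paste(iupac_classes[letters], collapse = ""), ")")
  regex_offsets(toupper(window), rx)
}

# the three baculovirus promoter element classes
promoter_patterns <- list(
  early_tata_cakt = c(tata = "TATAW", initiator = "CAKT"),
  lef_tata_like = "TAATWAA",
  late = "DTAAG"
)

#' Screen ORF upstream regions for baculovirus promoter elements
#'
#' For every ORF the `window_nt` nucleotides upstream of the initiation
#' codon (on the coding strand; wrapping across the origin on circular
#' genomes) are scanned for the three element classes:
#'
#' * `early_tata_cakt` — a TATA box (`TATAW`) with a `CAKT` mRNA start-site
#'   motif beginning 25–35 nt downstream (spacing measured start-to-start);
#' * `lef_tata_like` — the TATA-like element `TAATWAA` first described
#'   upstream of *lef* genes;
#' * `late` — the late element `DTAAG`.
#'
#' Positions are reported relative to the `A` of the start codon (that `A`
#' is position 0; upstream positions are negative). A late element whose
#' match starts within `proximal_nt` of the start codon sets
#' `proximal_late`.
#'
#' @param genome A [circular_genome()].
#' @param orfs An `orf_table` (or feature-table-like tibble with `orf_id`
#'   or `feature_id`, `start`, `end`, `strand`).
#' @param window_nt Upstream window length (default 180 nt).
#' @param cakt_spacing Two-element range of allowed TATAW-start to
#'   CAKT-start spacings (default `c(25, 35)` nt).
#' @param proximal_nt Distance defining a "proximal" late element
#'   (default 15 nt).
#' @param spacing_anchor `"start"` (default) measures the CAKT spacing from
#'   the start of the TATAW match; `"end"` measures from the base after it.
#' @return A tibble with one row per hit: `orf_id`, `class`,
#'   `rel_start`, `matched_text`, `spacing_nt` (early class only),
#'   `proximal_late` (per-ORF flag, repeated on each row of that ORF).
#'   ORFs without hits contribute no rows.
#' @export
scan_promoters <- function(genome, orfs, window_nt = 180L,
                           cakt_spacing = c(25L, 35L), proximal_nt = 15L,
                           spacing_anchor = c("start", "end")) {
  spacing_anchor <- match.arg(spacing_anchor)
  longest <- max(nchar(unlist(promoter_patterns)))
  if (window_nt < longest) {
    abort(sprintf("window_nt must be at least %d (longest pattern)", longest))
  }
  ids <- orfs[[if ("orf_id" %in% names(orfs)) "orf_id" else "feature_id"]]
  L <- genome_length(genome)
  res <- purrr::map(seq_len(nrow(orfs)), function(i) {
    win <- upstream_window(genome, orfs$start[i], orfs$end[i],
                           orfs$strand[i], window_nt)
    hits <- scan_window(win, window_nt, cakt_spacing, spacing_anchor)
    if (nrow(hits) == 0L) return(NULL)
    hits$orf_id <- ids[i]
    hits
  })
  out <- bind_rows(res)
  if (nrow(out) == 0L) {
    return(tibble(orf_id = character(), class = character(),
                  rel_start = integer(), matched_text = character(),
                  spacing_nt = integer(), proximal_late = logical()))
  }
  out |>
    group_by(.data$orf_id) |>
    mutate(proximal_late = any(.data$class == "late" &
                                 .data$rel_start >= -proximal_nt)) |>
    ungroup() |>
    select("orf_id", "class", "rel_start", "matched_text", "spacing_nt",
           "proximal_late")
}

# the window_nt bases immediately 5' of the start codon, on the coding strand
upstream_window <- function(genome, start, end, strand, window_nt) {
  L <- genome_length(genome)
  if (strand == "+") {
    a <- start - window_nt
    if (genome$topology == "linear") a <- max(0L, a)
    subsequence(genome, a, a + min(window_nt, start - a), "+")
  } else {
    b <- end + window_nt
    if (genome$topology == "linear") b <- min(L, b)
    subsequence(genome, end, b, "-")
  }
}

scan_window <- function(win, window_nt, cakt_spacing, spacing_anchor) {
  n <- nchar(win)
  rel <- function(off) off - n  # offset 0-based in window -> position rel. start codon
  rows <- list()
  # early: TATAW with CAKT 25-35 nt downstream
  tata <- iupac_match("TATAW", win)
  for (t in tata) {
    anchor <- if (spacing_anchor == "start") t else t + 5L
    cakt <- iupac_match("CAKT", win)
    sp <- cakt - anchor
    ok <- sp >= cakt_spacing[1] & sp <= cakt_spacing[2]
    if (any(ok)) {
      for (k in which(ok)) {
        rows[[length(rows) + 1L]] <- tibble(
          class = "early_tata_cakt", rel_start = rel(t),
          matched_text = substr(win, t + 1L, t + 5L),
          spacing_nt = as.integer(sp[k])
        )
      }
    }
  }
  for (off in iupac_match("TAATWAA", win)) {
    rows[[length(rows) + 1L]] <- tibble(
      class = "lef_tata_like", rel_start = rel(off),
      matched_text = substr(win, off + 1L, off + 7L), spacing_nt = NA_integer_
    )
  }
  for (off in iupac_match("DTAAG", win)) {
    rows[[length(rows) + 1L]] <- tibble(
      class = "late", rel_start = rel(off),
      matched_text = substr(win, off + 1L, off + 5L), spacing_nt = NA_integer_
    )
  }
  out <- bind_rows(rows)
  if (nrow(out)) out$rel_start <- as.integer(out$rel_start)
  out
}

#' Summarise promoter hits per class
#'
#' @param hits Output of [scan_promoters()].
#' @return A tibble with per-class hit counts, number of ORFs hit, and the
#'   mean element offset (the late-element mean offset is the statistic
#'   usually quoted as "on average about -60 nt").
#' @export
summarize_promoters <- function(hits) {
  if (nrow(hits) == 0L) {
    return(tibble(class = character(), n_hits = integer(),
                  n_orfs = integer(), mean_offset = double()))
  }
  hits |>
    group_by(class = .data$class) |>
    summarise(n_hits = dplyr::n(),
              n_orfs = dplyr::n_distinct(.data$orf_id),
              mean_offset = mean(.data$rel_start), .groups = "drop")
}
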