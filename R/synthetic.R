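#' Specification for a synthetic baculovirus-like genome
#'
#' The defaults emulate a granulovirus-like genome at desk scale: AT-rich
#' (37.18% GC), tiled with non-overlapping ORFs on both strands, one hr
#' with five 104-bp repeat units in mixed orientation around a perfect
#' 12-bp palindromic core, and one AT-rich tandem direct repeat. All
#' generation is seeded and deterministic; there is no unseeded mode.
#'
#' @param length_bp Genome length (default 20,000 bp: large enough to
#'   carry every feature class, small enough for fast replicated tests).
#' @param gc_percent Background GC target; the generator samples the
#'   exact composition, so background GC lands within 0.5 of this value.
#' @param n_orfs Number of implanted ORFs.
#' @param orf_codon_range Min/max ORF length in codons (default 80-300;
#'   above the 50-codon annotation floor so implants outrank chance ORFs).
#' @param strand_fraction_plus Probability an ORF goes on the plus strand.
#' @param promoter_plan Per-class implant probabilities:
#'   `early`, `lef`, `late`, and `proximal_late` (probability that an
#'   implanted late element sits within 15 nt of the start codon).
#' @param hr_specs List of hr specs: each a list with `unit_length`,
#'   `n_units`, `n_reverse`, `core` (a perfect palindrome), and
#'   `mutation_rate` (per-base substitution rate per copy).
#' @param dr_specs List of dr specs: each a list with `unit` and `copies`.
#' @param seed Mandatory RNG seed.
#' @return A `genome_spec` list.
#' @export
genome_spec <- function(length_bp = 20000L, gc_percent = 37.18,
                        n_orfs = 15L, orf_codon_range = c(80L, 300L),
                        strand_fraction_plus = 0.7,
                        promoter_plan = list(early = 0.3, lef = 0.2,
                                             late = 0.5, proximal_late = 0.25),
                        hr_specs = list(list(unit_length = 104L, n_units = 5L,
                                             n_reverse = 2L,
                                             core = "GTAAACGTTTAC",
                                             mutation_rate = 0.05)),
                        dr_specs = list(list(unit = "AT", copies = 30L)),
                        seed) {
  if (missing(seed) || is.null(seed)) abort("seed is mandatory")
  for (h in hr_specs) {
    if (h$core != revcomp(h$core)) abort("hr core must be a perfect palindrome")
    if (h$n_reverse >= h$n_units) abort("n_reverse must be < n_units")
  }
  structure(list(length_bp = as.integer(length_bp), gc_percent = gc_percent,
                 n_orfs = as.integer(n_orfs),
                 orf_codon_range = as.integer(orf_codon_range),
                 strand_fraction_plus = strand_fraction_plus,
                 promoter_plan = promoter_plan, hr_specs = hr_specs,
                 dr_specs = dr_specs, seed = as.integer(seed)),
            class = "genome_spec")
}

# exact-composition background: GC count is fixed, positions shuffled
random_background <- function(n, gc) {
  if (n <= 0L) return("")
  ngc <- round(gc / 100 * n)
  bases <- c(sample(c("G", "C"), ngc, replace = TRUE),
             sample(c("A", "T"), n - ngc, replace = TRUE))
  paste(sample(bases), collapse = "")
}

stop_codons <- c("TAA", "TAG", "TGA")

all_codons <- local({
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
})

codon_weights <- function(gc) {
  pg <- gc / 200; pa <- (100 - gc) / 200
  p <- setNames(vapply(all_codons, function(cd) {
    prod(vapply(strsplit(cd, "")[[1]],
                function(ch) if (ch %in% c("G", "C")) pg else pa, double(1)))
  }, double(1)), all_codons)
  p[stop_codons] <- 0
  p / sum(p)
}

random_orf_seq <- function(codons, gc) {
  w <- codon_weights(gc)
  body <- sample(names(w), codons - 1L, replace = TRUE, prob = w)
  stopc <- sample(stop_codons, 1L, prob = c(0.5, 0.25, 0.25))
  paste0("ATG", paste(body, collapse = ""), stopc)
}

#' Generate a synthetic genome with full ground truth
#'
#' Implants ORFs (each preceded on its coding strand by an in-frame stop
#' so the annotated start codon is the unambiguous most-upstream start),
#' promoter elements of the three classes in rejection-sampled upstream
#' windows that contain exactly the planned motifs, hr loci with
#' mixed-orientation repeat units around a palindromic core, and tandem
#' direct repeats, all embedded in exact-composition background. Output
#' is deterministic under the spec seed.
#'
#' @param spec A [genome_spec()].
#' @return List with `genome` (a [circular_genome()]) and `truth` (class
#'   `genome_truth`): `orfs` (an `orf_table`), `promoters`, `hrs`, `drs`,
#'   and a combined [feature_table()] in `features`.
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  set.seed(spec$seed)
  gc <- spec$gc_percent
  blocks <- list()
  for (i in seq_len(spec$n_orfs)) {
    codons <- sample(spec$orf_codon_range[1]:spec$orf_codon_range[2], 1L)
    strand <- if (runif(1) < spec$strand_fraction_plus) "+" else "-"
    cds <- random_orf_seq(codons, gc)
    plan <- draw_promoter_plan(spec$promoter_plan)
    win <- if (is.null(plan)) NULL else build_promoter_window(gc, plan)
    coding <- paste0(if (is.null(win)) "" else win$seq, "TAA", cds)
    blocks[[length(blocks) + 1L]] <- list(
      type = "orf",
      seq = if (strand == "+") coding else revcomp(coding),
      strand = strand, codons = codons, cds_len = nchar(cds),
      win_len = if (is.null(win)) 0L else nchar(win$seq),
      promoters = if (is.null(win)) NULL else win$truth
    )
  }
  for (h in spec$hr_specs) blocks[[length(blocks) + 1L]] <- build_hr_block(h, gc)
  for (d in spec$dr_specs) {
    blocks[[length(blocks) + 1L]] <- list(
      type = "dr", seq = strrep(d$unit, d$copies), unit = d$unit,
      copies = as.integer(d$copies)
    )
  }
  if (length(blocks) == 0L) {
    genome <- circular_genome(random_background(spec$length_bp, gc),
                              id = sprintf("synthetic_gv_seed%d", spec$seed))
    empty_orfs <- tibble(orf_id = character(), start = integer(),
                         end = integer(), strand = character(),
                         codons = integer(), translation = character(),
                         wrap = logical())
    truth <- structure(list(orfs = orf_table(empty_orfs, genome),
                            promoters = tibble(), hrs = list(),
                            drs = tibble(), spec = spec),
                       class = "genome_truth")
    truth$features <- feature_table(genome_id = genome$id,
                                    genome_length = spec$length_bp)
    return(list(genome = genome, truth = truth))
  }
  blocks <- blocks[sample(length(blocks))]
  block_len <- vapply(blocks, function(b) nchar(b$seq), integer(1))
  n_gaps <- length(blocks)
  min_gap <- 20L
  spare <- spec$length_bp - sum(block_len) - n_gaps * min_gap
  if (spare < 0L) {
    abort(sprintf(
      "infeasible packing: features need %d bp plus %d bp of gaps, genome is %d bp",
      sum(block_len), n_gaps * min_gap, spec$length_bp))
  }
  gap_len <- min_gap +
    tabulate(sample.int(n_gaps, spare, replace = TRUE), nbins = n_gaps)
  pieces <- character(0)
  pos <- 0L
  orf_truth <- list(); prom_truth <- list(); hr_truth <- list(); dr_truth <- list()
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    gap <- random_background(gap_len[i], gc)
    prev <- if (i > 1L) blocks[[i - 1L]] else blocks[[length(blocks)]]
    gap <- break_periodicity(gap, before = b, after = prev)
    pieces <- c(pieces, gap)
    pos <- pos + nchar(gap)
    if (b$type == "orf") {
      if (b$strand == "+") {
        cds_start <- pos + b$win_len + 3L
      } else {
        cds_start <- pos
      }
      cds_end <- cds_start + b$cds_len
      orf_truth[[length(orf_truth) + 1L]] <- tibble(
        start = cds_start, end = cds_end, strand = b$strand, codons = b$codons
      )
      if (!is.null(b$promoters)) {
        anchor <- if (b$strand == "+") cds_start else cds_end
        prom_truth[[length(prom_truth) + 1L]] <- b$promoters |>
          mutate(orf_index = length(orf_truth),
                 genome_start = if (b$strand == "+")
                   anchor + .data$rel_start
                 else anchor - .data$rel_start - nchar(.data$motif))
      }
    } else if (b$type == "hr") {
      hr_truth[[length(hr_truth) + 1L]] <- list(
        start = pos, end = pos + nchar(b$seq),
        units = b$units |> mutate(start = .data$start + pos,
                                  end = .data$end + pos),
        core = b$core, core_start = pos + b$core_offset,
        unit_length = b$unit_length, mutation_log = b$mutation_log
      )
    } else if (b$type == "dr") {
      dr_truth[[length(dr_truth) + 1L]] <- tibble(
        start = pos, end = pos + nchar(b$seq), unit = b$unit,
        copies = b$copies
      )
    }
    pieces <- c(pieces, b$seq)
    pos <- pos + nchar(b$seq)
  }
  seqstr <- paste(pieces, collapse = "")
  stopifnot(nchar(seqstr) == spec$length_bp)
  genome <- circular_genome(seqstr, id = sprintf("synthetic_gv_seed%d", spec$seed))
  ins <- bind_rows(orf_truth)
  ord <- order(ins$start)
  orfs <- ins[ord, ] |>
    mutate(orf_id = paste0("orf", row_number()), wrap = FALSE)
  orfs$translation <- vapply(seq_len(nrow(orfs)), function(i) {
    translate_cds(subsequence(genome, orfs$start[i], orfs$end[i], orfs$strand[i]))
  }, character(1))
  orfs <- orfs[, c("orf_id", "start", "end", "strand", "codons",
                   "translation", "wrap")]
  proms <- bind_rows(prom_truth)
  if (nrow(proms) > 0L) {
    proms$orf_id <- paste0("orf", match(proms$orf_index, ord))
    proms <- proms[, c("orf_id", "class", "rel_start", "motif", "spacing",
                       "genome_start")]
  }
  truth <- structure(list(
    orfs = orf_table(orfs, genome), promoters = proms,
    hrs = hr_truth, drs = bind_rows(dr_truth), spec = spec
  ), class = "genome_truth")
  truth$features <- truth_features(truth, genome)
  list(genome = genome, truth = truth)
}

draw_promoter_plan <- function(pl) {
  classes <- c(
    if (runif(1) < (pl$early %||% 0)) "early_tata_cakt",
    if (runif(1) < (pl$lef %||% 0)) "lef_tata_like",
    if (runif(1) < (pl$late %||% 0)) "late"
  )
  if (length(classes) == 0L) return(NULL)
  list(classes = classes, proximal = runif(1) < (pl$proximal_late %||% 0))
}

# a 180-nt coding-strand upstream window containing exactly the planned
# motifs; verified as the promoter scanner will see it (through the 3-bp
# guard stop that follows the window)
build_promoter_window <- function(gc, plan, window_nt = 180L) {
  for (try in 1:400) {
    win <- random_background(window_nt, gc)
    if (length(iupac_match("TATAW", win)) || length(iupac_match("TAATWAA", win)) ||
        length(iupac_match("DTAAG", win)) || length(iupac_match("CAKT", win))) next
    placed <- place_motifs(win, plan, window_nt)
    if (is.null(placed)) next
    seen <- substr(paste0(placed$win, "TAA"), 4L, window_nt + 3L)
    hits <- scan_window(seen, window_nt, c(25L, 35L), "start")
    got <- sort(unique(paste(hits$class, hits$rel_start)))
    want <- sort(unique(paste(placed$truth$class, placed$truth$rel_start)))
    if (identical(got, want)) {
      return(list(seq = placed$win, truth = placed$truth))
    }
  }
  abort("could not build a clean promoter window (rejection cap reached)")
}

# write motif instances into a clean window; rel offsets are relative to
# the start-codon A (= 0); the window is followed by a 3-bp guard stop
place_motifs <- function(win, plan, window_nt) {
  guard <- 3L
  occupied <- integer(0)
  rows <- list()
  wchars <- strsplit(win, "")[[1]]
  put <- function(motif, rel) {
    widx <- window_nt + guard + rel + 1L  # 1-based position in the window
    if (widx < 1L || widx + nchar(motif) - 1L > window_nt) return(FALSE)
    span <- widx:(widx + nchar(motif) - 1L)
    if (length(intersect(span, occupied))) return(FALSE)
    wchars[span] <<- strsplit(motif, "")[[1]]
    occupied <<- c(occupied, span)
    TRUE
  }
  for (cl in plan$classes) {
    ok <- FALSE
    for (attempt in 1:30) {
      if (cl == "early_tata_cakt") {
        tata <- paste0("TATA", sample(c("A", "T"), 1L))
        cakt <- paste0("CA", sample(c("G", "T"), 1L), "T")
        sp <- sample(25:35, 1L)
        rel <- -sample((sp + 12L):150L, 1L)
        if (put(tata, rel) && put(cakt, rel + sp)) {
          rows[[length(rows) + 1L]] <- tibble(class = cl, rel_start = rel,
                                              motif = tata, spacing = sp)
          ok <- TRUE
        }
      } else if (cl == "lef_tata_like") {
        motif <- paste0("TAAT", sample(c("A", "T"), 1L), "AA")
        rel <- -sample(15:170, 1L)
        if (put(motif, rel)) {
          rows[[length(rows) + 1L]] <- tibble(class = cl, rel_start = rel,
                                              motif = motif,
                                              spacing = NA_integer_)
          ok <- TRUE
        }
      } else {
        motif <- paste0(sample(c("A", "G", "T"), 1L), "TAAG")
        rel <- if (plan$proximal) -sample(8:15, 1L) else
          -min(170L, max(16L, round(stats::rnorm(1, 60, 20))))
        if (put(motif, rel)) {
          rows[[length(rows) + 1L]] <- tibble(class = cl, rel_start = rel,
                                              motif = motif,
                                              spacing = NA_integer_)
          ok <- TRUE
        }
      }
      if (ok) break
    }
    if (!ok) return(NULL)
  }
  list(win = paste(wchars, collapse = ""), truth = bind_rows(rows))
}

build_hr_block <- function(h, gc) {
  u <- as.integer(h$unit_length)
  base <- random_background(u, gc)
  n_fwd <- h$n_units - h$n_reverse
  oris <- c(rep("+", n_fwd), rep("-", h$n_reverse))
  copies <- character(h$n_units)
  mutlog <- list()
  for (i in seq_len(h$n_units)) {
    cp <- strsplit(base, "")[[1]]
    nmut <- stats::rbinom(1, u, h$mutation_rate)
    if (nmut > 0L) {
      at <- sample.int(u, nmut)
      cp[at] <- vapply(cp[at], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
      mutlog[[i]] <- sort(at)
    } else mutlog[[i]] <- integer()
    copies[i] <- paste(cp, collapse = "")
  }
  gap_seq <- function(n) {
    repeat {
      g <- random_background(n, gc)
      if (nrow(find_palindromes(g, min_len = 8L)) == 0L) return(g)
    }
  }
  pieces <- character(0)
  unit_rows <- list()
  pos <- 0L
  core_offset <- NA_integer_
  for (i in seq_len(h$n_units)) {
    if (i > 1L) {
      if (oris[i] == "-" && oris[i - 1L] == "+") {
        # the forward/reverse junction carries the palindromic core; the
        # flanks must not extend the palindrome by complementary bases
        repeat {
          pre <- gap_seq(6L); post <- gap_seq(6L)
          if (substr(post, 1L, 1L) !=
              revcomp(substr(pre, nchar(pre), nchar(pre)))) break
        }
        core_offset <- pos + nchar(pre)
        mid <- paste0(pre, h$core, post)
      } else {
        mid <- gap_seq(sample(10:18, 1L))
      }
      pieces <- c(pieces, mid)
      pos <- pos + nchar(mid)
    }
    us <- if (oris[i] == "-") revcomp(copies[i]) else copies[i]
    unit_rows[[i]] <- tibble(start = pos, end = pos + u, orientation = oris[i])
    pieces <- c(pieces, us)
    pos <- pos + u
  }
  list(type = "hr", seq = paste(pieces, collapse = ""),
       units = bind_rows(unit_rows), core = h$core, core_offset = core_offset,
       unit_length = u, mutation_log = mutlog)
}

# tandem arrays must not bleed into AT-rich background: force the gap base
# adjacent to a dr block off the unit period
break_periodicity <- function(gap, before, after) {
  if (nchar(gap) == 0L) return(gap)
  if (identical(before$type, "dr")) {
    last_unit_base <- substr(before$unit, nchar(before$unit), nchar(before$unit))
    substr(gap, nchar(gap), nchar(gap)) <-
      setdiff(c("G", "C", "A"), last_unit_base)[1]
  }
  if (identical(after$type, "dr")) {
    first_unit_base <- substr(after$unit, 1L, 1L)
    substr(gap, 1L, 1L) <- setdiff(c("G", "C", "A"), first_unit_base)[1]
  }
  gap
}

truth_features <- function(truth, genome) {
  L <- genome_length(genome)
  rows <- list()
  o <- truth$orfs
  if (nrow(o)) {
    rows[[length(rows) + 1L]] <- tibble(
      feature_id = o$orf_id, start = o$start, end = o$end, strand = o$strand,
      kind = "CDS", gene = o$orf_id, product = "hypothetical protein"
    )
  }
  if (!is.null(truth$promoters) && nrow(truth$promoters)) {
    p <- truth$promoters
    rows[[length(rows) + 1L]] <- tibble(
      feature_id = paste0(p$orf_id, "_prom", seq_len(nrow(p))),
      start = p$genome_start, end = p$genome_start + nchar(p$motif),
      strand = "+", kind = "promoter", gene = p$orf_id, product = p$class
    )
  }
  for (i in seq_along(truth$hrs)) {
    h <- truth$hrs[[i]]
    rows[[length(rows) + 1L]] <- tibble(
      feature_id = paste0("hr", i), start = h$start, end = h$end,
      strand = "+", kind = "repeat_region", gene = NA_character_,
      product = "homologous repeat region"
    )
  }
  if (nrow(truth$drs)) {
    rows[[length(rows) + 1L]] <- tibble(
      feature_id = paste0("dr", seq_len(nrow(truth$drs))),
      start = truth$drs$start, end = truth$drs$end, strand = "+",
      kind = "repeat_region", gene = NA_character_, product = "direct repeat"
    )
  }
  df <- bind_rows(rows) |> arrange(.data$start)
  feature_table(df$feature_id, df$start, df$end, df$strand, df$kind,
                df$gene, df$product, genome_id = genome$id, genome_length = L)
}

#' Diverge a DNA sequence under a two-parameter substitution process
#'
#' Per-site independent substitutions with expected distance `d_true` and
#' transition:transversion ratio `kappa` (`kappa` approximates `P/Q` in
#' the low-divergence limit). Per-site transition and transversion
#' probabilities come from the Kimura model's transition-probability
#' formulas, so the K2P estimator recovers `d_true` in expectation. No
#' indels; `N` bases are left untouched.
#'
#' @param seq DNA string.
#' @param d_true Expected substitutions/site, in `[0, 0.75)`.
#' @param kappa Transition/transversion ratio (> 0).
#' @param seed RNG seed (mandatory).
#' @return The diverged DNA string.
#' @export
diverge <- function(seq, d_true, kappa, seed) {
  if (missing(seed)) abort("seed is mandatory")
  if (d_true < 0 || d_true >= 0.75) abort("d_true must be in [0, 0.75)")
  if (kappa <= 0) abort("kappa must be > 0")
  set.seed(seed)
  if (d_true == 0) return(seq)
  pq <- k2p_site_probs(d_true, kappa)
  x <- strsplit(toupper(seq), "")[[1]]
  u <- runif(length(x))
  transit <- u < pq$P
  transv <- !transit & u < pq$P + pq$Q
  ts_map <- c(A = "G", G = "A", C = "T", T = "C")
  tv_map <- list(A = c("C", "T"), G = c("C", "T"),
                 C = c("A", "G"), T = c("A", "G"))
  std <- x %in% c("A", "C", "G", "T")
  idx <- which(transit & std)
  x[idx] <- ts_map[x[idx]]
  idx <- which(transv & std)
  if (length(idx)) {
    pick <- runif(length(idx)) < 0.5
    x[idx] <- vapply(seq_along(idx), function(k)
      tv_map[[x[idx[k]]]][1L + pick[k]], character(1))
  }
  paste(x, collapse = "")
}

# expected transition (P) and transversion (Q) proportions at distance d
# for ts/tv ratio kappa = alpha / (2 beta)
k2p_site_probs <- function(d, kappa) {
  bt <- d / (2 * (kappa + 1))   # beta * t
  at <- kappa * d / (kappa + 1) # alpha * t
  list(P = 0.25 + 0.25 * exp(-4 * bt) - 0.5 * exp(-2 * (at + bt)),
       Q = 0.5 - 0.5 * exp(-4 * bt))
}

#' Diverge a whole annotated genome, with optional synteny shuffling
#'
#' The genome is diverged with [diverge()]; substitutions that would
#' introduce an in-frame stop inside an implanted ORF are reverted (a
#' crude stand-in for purifying selection; it also keeps translations
#' usable downstream). Optionally, blocks of consecutive genes are
#' inverted or translocated, with the permutation recorded so downstream
#' homolog and parity results can be checked against truth.
#'
#' @param genome A [circular_genome()] from [generate_genome()].
#' @param truth Its `genome_truth`.
#' @param d_true,kappa,seed As in [diverge()].
#' @param plan Optional list of moves, each
#'   `list(type = "invert"|"translocate", genes = <consecutive indices>,
#'   dest = <insertion position among remaining genes, translocate only>)`.
#' @return List with `genome` (diverged genome), `orfs` (new
#'   `orf_table`), and `homologs` (tibble `orf_a`, `orf_b` of true
#'   ortholog pairs between the original and the diverged genome).
#' @export
diverge_genome_pair <- function(genome, truth, d_true, kappa, seed,
                                plan = NULL) {
  newseq <- diverge(genome$seq, d_true, kappa, seed)
  o <- truth$orfs
  n <- nrow(o)
  g2 <- circular_genome(newseq, id = paste0(genome$id, "_div"))
  chars <- strsplit(newseq, "")[[1]]
  orig_chars <- strsplit(genome$seq, "")[[1]]
  L <- genome_length(genome)
  for (i in seq_len(n)) {
    cds <- subsequence(g2, o$start[i], o$end[i], o$strand[i])
    ncod <- nchar(cds) %/% 3L
    for (ci in seq_len(ncod - 1L)) {
      cd <- substr(cds, 3L * ci - 2L, 3L * ci)
      if (cd %in% stop_codons) {
        rel <- (3L * ci - 3L):(3L * ci - 1L)
        posn <- if (o$strand[i] == "+") (o$start[i] + rel) %% L
        else (o$end[i] - 1L - rel) %% L
        chars[posn + 1L] <- orig_chars[posn + 1L]
      }
    }
  }
  newseq <- paste(chars, collapse = "")
  if (is.null(plan)) {
    g2 <- circular_genome(newseq, id = paste0(genome$id, "_div"))
    new_orfs <- o
    new_orfs$translation <- vapply(seq_len(n), function(i) {
      gsub("\\*", "X", translate_cds(subsequence(g2, o$start[i], o$end[i],
                                                 o$strand[i])))
    }, character(1))
    return(list(genome = g2, orfs = orf_table(new_orfs, g2),
                homologs = tibble(orf_a = o$orf_id, orf_b = o$orf_id)))
  }
  permute_genome(newseq, genome, o, plan)
}

# cut the diverged sequence into per-gene segments (gene plus trailing
# intergenic), apply the block moves, rebuild genome and truth
permute_genome <- function(newseq, genome, o, plan) {
  L <- genome_length(genome)
  n <- nrow(o)
  g0 <- circular_genome(newseq, id = paste0(genome$id, "_div"))
  seg_start <- o$start
  seg_end <- c(o$start[-1], o$start[1] + L)
  segs <- lapply(seq_len(n), function(i) {
    list(seq = subsequence(g0, seg_start[i], seg_end[i], "+"),
         orf_len = o$end[i] - o$start[i], strand = o$strand[i],
         codons = o$codons[i], old_id = o$orf_id[i])
  })
  order_idx <- seq_len(n)
  inverted <- rep(FALSE, n)
  for (mv in plan) {
    gi <- mv$genes
    if (any(!gi %in% order_idx)) abort("permutation plan references unknown genes")
    posns <- match(gi, order_idx)
    if (any(diff(posns) != 1L)) abort("plan blocks must be consecutive genes")
    if (mv$type == "invert") {
      order_idx[posns] <- rev(order_idx[posns])
      inverted[order_idx[posns]] <- !inverted[order_idx[posns]]
    } else if (mv$type == "translocate") {
      block <- order_idx[posns]
      rest <- order_idx[-posns]
      dest <- min(max(mv$dest %||% 1L, 1L), length(rest) + 1L)
      order_idx <- append(rest, block, after = dest - 1L)
    } else abort("unknown move type")
  }
  pieces <- character(n)
  rows <- list()
  pos <- 0L
  for (k in seq_len(n)) {
    i <- order_idx[k]
    sg <- segs[[i]]
    if (inverted[i]) {
      pieces[k] <- revcomp(sg$seq)
      orf_start <- pos + (nchar(sg$seq) - sg$orf_len)
      strand <- if (sg$strand == "+") "-" else "+"
    } else {
      pieces[k] <- sg$seq
      orf_start <- pos
      strand <- sg$strand
    }
    rows[[k]] <- tibble(old_id = sg$old_id, start = orf_start,
                        end = orf_start + sg$orf_len, strand = strand,
                        codons = sg$codons)
    pos <- pos + nchar(pieces[k])
  }
  g2 <- circular_genome(paste(pieces, collapse = ""),
                        id = paste0(genome$id, "_perm"))
  new_o <- bind_rows(rows) |> arrange(.data$start) |>
    mutate(orf_id = paste0("orf", row_number()), wrap = FALSE)
  new_o$translation <- vapply(seq_len(nrow(new_o)), function(i) {
    gsub("\\*", "X", translate_cds(subsequence(g2, new_o$start[i],
                                               new_o$end[i], new_o$strand[i])))
  }, character(1))
  homologs <- tibble(orf_a = new_o$old_id, orf_b = new_o$orf_id)
  new_o <- new_o[, c("orf_id", "start", "end", "strand", "codons",
                     "translation", "wrap")]
  list(genome = g2, orfs = orf_table(new_o, g2), homologs = homologs)
}
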