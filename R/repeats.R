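comp_int <- local({
  map <- integer(128)
  map[utf8ToInt("A")] <- utf8ToInt("T"); map[utf8ToInt("T")] <- utf8ToInt("A")
  map[utf8ToInt("C")] <- utf8ToInt("G"); map[utf8ToInt("G")] <- utf8ToInt("C")
  map[utf8ToInt("N")] <- utf8ToInt("N")
  map
})

#' Find maximal DNA palindromes (reverse-complement symmetric spans)
#'
#' A DNA palindrome is an even-length span equal to its own reverse
#' complement (the motif a cruciform can extrude from). For every center
#' the arms are extended outward while at most `max_mismatch` base pairs
#' fail to complement; the maximal span at each center is reported if it
#' reaches `min_len`.
#'
#' @param seq DNA string.
#' @param min_len Minimum palindrome length; must be even and >= 4
#'   (perfect biological palindromes are even-length).
#' @param max_mismatch Mismatching pair budget (default 0 = perfect).
#' @return A tibble with 0-based `start`, `length`, `mismatches`.
#' @examples
#' find_palindromes("GTAAACGTTTAC", min_len = 6)
#' @export
find_palindromes <- function(seq, min_len = 6L, max_mismatch = 0L) {
  if (min_len %% 2L != 0L || min_len < 4L) {
    abort("min_len must be even and >= 4")
  }
  x <- utf8ToInt(toupper(seq))
  n <- length(x)
  comp <- ifelse(x <= 128L, comp_int[x], 0L)
  rows <- list()
  for (c0 in 1:(n - 1L)) {           # center between positions c0 and c0+1
    arm <- 0L; mm <- 0L
    best_arm <- 0L; best_mm <- 0L
    while (c0 - arm >= 1L && c0 + 1L + arm <= n) {
      pair_mm <- as.integer(x[c0 - arm] != comp[c0 + 1L + arm] ||
                              x[c0 - arm] == utf8ToInt("N"))
      if (mm + pair_mm > max_mismatch) break
      mm <- mm + pair_mm
      arm <- arm + 1L
      best_arm <- arm; best_mm <- mm
    }
    if (2L * best_arm >= min_len) {
      rows[[length(rows) + 1L]] <- c(start = c0 - best_arm, len = 2L * best_arm,
                                     mm = best_mm)
    }
  }
  if (length(rows) == 0L) {
    return(tibble(start = integer(), length = integer(), mismatches = integer()))
  }
  m <- do.call(rbind, rows)
  tibble(start = as.integer(m[, "start"]), length = as.integer(m[, "len"]),
         mismatches = as.integer(m[, "mm"]))
}

repeat_region_tibble <- function() {
  tibble(region_id = character(), kind = character(), start = integer(),
         end = integer(), n_units = integer(), unit_length = integer(),
         consensus = character(), palindrome_core = character(),
         at_percent = double(), units = list())
}

#' Find tandem direct repeats (drs)
#'
#' Detects arrays where a unit of `min_unit`–`max_unit` bp occurs at least
#' `min_copies` times head-to-tail with adjacent-copy identity at least
#' `min_identity`. Overlapping calls at different unit sizes are merged,
#' keeping the higher score (`copies * identity * unit_length`; ties go to
#' the shorter unit). AT content is reported over the array span. The scan
#' is on the linearized plus strand; arrays crossing the origin are not
#' chased (intergenic drs sit away from the conventional origin).
#'
#' @param genome A [circular_genome()] or DNA string.
#' @param min_unit,max_unit Unit length bounds in bp.
#' @param min_copies Minimum copies in the array (default 1.8, i.e. two
#'   full copies).
#' @param min_identity Minimum adjacent-copy identity (default 0.8).
#' @return A repeat-region tibble (kind `"dr"`): `region_id`, `kind`,
#'   `start`, `end` (0-based half-open), `n_units`, `unit_length`,
#'   `consensus`, `palindrome_core` (always `NA` for drs), `at_percent`,
#'   and a `units` list-column of per-copy coordinates.
#' @export
find_tandem_repeats <- function(genome, min_unit = 10L, max_unit = 200L,
                                min_copies = 1.8, min_identity = 0.8) {
  s <- if (inherits(genome, "circular_genome")) genome$seq else toupper(genome)
  if (min_unit < 2L || max_unit < min_unit || min_identity <= 0 ||
      min_identity > 1 || min_copies < 1) {
    abort("unreasonable tandem-repeat parameters")
  }
  x <- utf8ToInt(s)
  L <- length(x)
  cand <- list()
  for (u in min_unit:min(max_unit, L %/% 2L)) {
    m <- as.integer(x[seq_len(L - u)] == x[(u + 1L):L])
    if (L - 2L * u + 1L < 1L) next
    cm <- cumsum(m)
    # identity of copy starting at i (1-based) with the next copy
    idx <- seq_len(L - 2L * u + 1L)
    ident <- (cm[idx + u - 1L] - c(0L, cm)[idx]) / u
    good <- ident >= min_identity
    r <- rle(good)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ga <- starts[r$values]; gb <- ends[r$values]
    if (length(ga) == 0L) next
    # merge runs broken by mutation clusters at copy boundaries
    merged_a <- ga[1]; merged_b <- gb[1]
    runs <- list()
    for (j in seq_along(ga)[-1]) {
      if (ga[j] - merged_b[length(merged_b)] <= u) {
        merged_b[length(merged_b)] <- gb[j]
      } else {
        merged_a <- c(merged_a, ga[j]); merged_b <- c(merged_b, gb[j])
      }
    }
    for (j in seq_along(merged_a)) {
      a <- merged_a[j]; b <- merged_b[j]
      span_start <- a - 1L              # 0-based
      span_end <- b - 1L + 2L * u       # 0-based half-open
      # trim flank bases that break the period (the two outermost bases on
      # each side must both be period-consistent, so a single coincidental
      # flank match does not stall the trim)
      while (span_start < span_end - u &&
             (x[span_start + 1L] != x[span_start + u + 1L] ||
              x[span_start + 2L] != x[span_start + u + 2L])) {
        span_start <- span_start + 1L
      }
      while (span_end - u > span_start &&
             (x[span_end] != x[span_end - u] ||
              x[span_end - 1L] != x[span_end - 1L - u])) {
        span_end <- span_end - 1L
      }
      copies <- (span_end - span_start) / u
      if (copies < min_copies) next
      mean_id <- mean(m[(span_start + 1L):(span_end - u)])
      if (mean_id < min_identity) next
      cand[[length(cand) + 1L]] <- tibble(
        start = span_start, end = span_end, unit_length = u,
        n_units = as.integer(floor(copies)), identity = mean_id,
        score = copies * mean_id * u
      )
    }
  }
  if (length(cand) == 0L) return(repeat_region_tibble())
  cand <- bind_rows(cand) |> arrange(desc(.data$score), .data$unit_length)
  keep <- integer()
  for (i in seq_len(nrow(cand))) {
    if (!any(vapply(keep, function(j) {
      cand$start[i] < cand$end[j] && cand$end[i] > cand$start[j]
    }, logical(1)))) keep <- c(keep, i)
  }
  # report the fundamental period: a kept call whose unit is a multiple of a
  # smaller-unit call covering (nearly) the same span is replaced by it
  keep <- vapply(keep, function(j) {
    div <- which(cand$unit_length < cand$unit_length[j] &
                   cand$unit_length[j] %% cand$unit_length == 0L)
    if (length(div)) {
      ov <- pmin(cand$end[div], cand$end[j]) - pmax(cand$start[div], cand$start[j])
      div <- div[ov >= 0.9 * (cand$end[j] - cand$start[j])]
      if (length(div)) return(div[which.min(cand$unit_length[div])])
    }
    j
  }, integer(1))
  cand <- cand[sort(unique(keep)), ]
  rows <- purrr::map(seq_len(nrow(cand)), function(i) {
    u <- cand$unit_length[i]
    copies <- seq(cand$start[i], by = u, length.out = cand$n_units[i])
    unit_seqs <- substring(s, copies + 1L, copies + u)
    cons <- majority_consensus(unit_seqs)
    span_seq <- substr(s, cand$start[i] + 1L, cand$end[i])
    tibble(
      region_id = NA_character_, kind = "dr",
      start = as.integer(cand$start[i]), end = as.integer(cand$end[i]),
      n_units = cand$n_units[i], unit_length = as.integer(u),
      consensus = cons, palindrome_core = NA_character_,
      at_percent = 100 - gc_percent(span_seq),
      units = list(tibble(start = as.integer(copies),
                          end = as.integer(copies + u),
                          orientation = "+",
                          identity_to_consensus = vapply(unit_seqs, function(q)
                            string_identity(q, cons), double(1),
                            USE.NAMES = FALSE)))
    )
  })
  out <- bind_rows(rows) |> arrange(.data$start)
  out$region_id <- paste0("dr", seq_len(nrow(out)))
  out
}

majority_consensus <- function(seqs) {
  len <- max(nchar(seqs))
  mat <- vapply(seqs, function(q) {
    ch <- strsplit(q, "", fixed = TRUE)[[1]]
    c(ch, rep(NA_character_, len - length(ch)))
  }, character(len))
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = len)
  cons <- apply(mat, 1, function(col) {
    col <- col[!is.na(col)]
    if (length(col) == 0L) return("N")
    names(sort(table(col), decreasing = TRUE))[1]
  })
  paste(cons, collapse = "")
}

string_identity <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0)
  mean(utf8ToInt(substr(a, 1, n)) == utf8ToInt(substr(b, 1, n)))
}

#' Find homologous repeat regions (hrs)
#'
#' Discovers clusters of similar repeat units in either orientation:
#' exact 12-mer seed matches (forward-forward and forward-reverse
#' complement) are chained along diagonals and extended gap-free under a
#' +1/-1 score with an X-drop cut back to the best-scoring endpoints.
#' Matched intervals are clustered into unit instances, orientations are
#' propagated from the pairwise match orientations, a majority-vote
#' consensus is built over orientation-normalized units, and the longest
#' perfect palindrome (>= 8 bp) found in the gaps between
#' opposite-orientation neighbours is reported as the region's palindromic
#' core.
#'
#' @param genome A [circular_genome()] or DNA string.
#' @param min_unit Minimum unit length in bp (default 40).
#' @param min_units Minimum units per region (default 2).
#' @param min_identity Minimum unit identity to the consensus (default 0.7).
#' @param region_gap Units separated by more than this many bp are split
#'   into separate regions (default 2000).
#' @param k Seed length (default 12).
#' @return A repeat-region tibble (kind `"hr"`): one row per region with a
#'   `units` list-column (`start`, `end`, `orientation`,
#'   `identity_to_consensus`).
#' @export
find_hrs <- function(genome, min_unit = 40L, min_units = 2L,
                     min_identity = 0.7, region_gap = 2000L, k = 12L) {
  s <- if (inherits(genome, "circular_genome")) genome$seq else toupper(genome)
  L <- nchar(s)
  if (L < min_unit * min_units) abort("genome shorter than min_unit * min_units")
  seg <- hr_segment_matches(s, k)
  if (nrow(seg) == 0L) return(repeat_region_tibble())
  seg <- hr_extend_segments(s, seg)
  seg <- seg[seg$len >= min_unit, , drop = FALSE]
  if (nrow(seg) == 0L) return(repeat_region_tibble())
  units <- hr_cluster_units(seg, min_unit)
  if (nrow(units$units) == 0L) return(repeat_region_tibble())
  hr_build_regions(s, units$units, units$edges, min_units, min_identity,
                   region_gap)
}

# ---- hr internals ----

# seed matches chained along (anti)diagonals into candidate segment pairs
hr_segment_matches <- function(s, k) {
  L <- nchar(s)
  if (L < 2L * k) return(tibble())
  pos <- seq_len(L - k + 1L)
  kmers <- substring(s, pos, pos + k - 1L)
  rc <- revcomp(s)
  # reverse complement of the k-mer at forward position i
  rckmers <- substring(rc, L - pos - k + 2L, L - pos + 1L)
  pairs <- list()
  # forward-forward
  grp <- split(pos, kmers)
  grp <- grp[lengths(grp) > 1L & lengths(grp) <= 50L]
  for (g in grp) {
    cmb <- utils::combn(g, 2L)
    pairs[[length(pairs) + 1L]] <- tibble(i = cmb[1, ], j = cmb[2, ], ori = "+")
  }
  # forward-reverse: kmer at i equals revcomp of kmer at j
  idx <- split(pos, rckmers)
  fwd <- split(pos, kmers)
  shared <- intersect(names(idx), names(fwd))
  for (nm in shared) {
    ii <- fwd[[nm]]; jj <- idx[[nm]]
    if (length(ii) * length(jj) > 2500L) next
    grid <- expand.grid(i = ii, j = jj)
    grid <- grid[grid$i < grid$j, , drop = FALSE]
    if (nrow(grid)) {
      pairs[[length(pairs) + 1L]] <- tibble(i = grid$i, j = grid$j, ori = "-")
    }
  }
  if (length(pairs) == 0L) return(tibble())
  pr <- bind_rows(pairs) |> distinct()
  # chain seeds sharing a diagonal (+: j-i, -: i+j) with gaps <= 2k
  pr$diag <- ifelse(pr$ori == "+", pr$j - pr$i, pr$i + pr$j)
  pr |>
    group_by(.data$ori, .data$diag) |>
    dplyr::group_map(function(g, key) {
      g <- g[order(g$i), ]
      brk <- cumsum(c(1L, diff(g$i) > 2L * k))
      purrr::map(split(g, brk), function(h) {
        i1 <- min(h$i); i2 <- max(h$i) + k - 1L
        if (key$ori == "+") {
          tibble(a1 = i1, a2 = i2, b1 = i1 + key$diag, b2 = i2 + key$diag,
                 ori = "+")
        } else {
          # j = diag - i: the partner of [i1,i2] is [diag-i2, diag-i1+k-1]
          tibble(a1 = i1, a2 = i2, b1 = key$diag - i2, b2 = key$diag - i1 + k - 1L,
                 ori = "-")
        }
      }) |> bind_rows()
    }) |>
    bind_rows() |>
    filter(.data$b1 > .data$a2 | .data$ori == "-")  # drop self-overlapping fwd hits
}

# gap-free X-drop extension of a segment pair; trims to best-scoring ends
hr_extend_segments <- function(s, seg, xdrop = 10L) {
  x <- utf8ToInt(s)
  L <- length(x)
  comp <- ifelse(x <= 128L, comp_int[x], 0L)
  ext <- purrr::map(seq_len(nrow(seg)), function(r) {
    a1 <- seg$a1[r]; a2 <- seg$a2[r]; b1 <- seg$b1[r]; b2 <- seg$b2[r]
    if (seg$ori[r] == "+") {
      # extend right: compare a2+t with b2+t
      right <- xdrop_walk(function(t) {
        if (a2 + t > L || b2 + t > L || a2 + t >= b1) return(NA)
        x[a2 + t] == x[b2 + t]
      }, xdrop)
      left <- xdrop_walk(function(t) {
        if (a1 - t < 1L || b1 - t <= a2) return(NA)
        x[a1 - t] == x[b1 - t]
      }, xdrop)
      tibble(a1 = a1 - left, a2 = a2 + right,
             b1 = b1 - left, b2 = b2 + right, ori = "+")
    } else {
      # inverted: extending A right extends B left (B is revcomp of A)
      right <- xdrop_walk(function(t) {
        if (a2 + t > L || b1 - t < 1L) return(NA)
        x[a2 + t] == comp[b1 - t]
      }, xdrop)
      left <- xdrop_walk(function(t) {
        if (a1 - t < 1L || b2 + t > L) return(NA)
        x[a1 - t] == comp[b2 + t]
      }, xdrop)
      tibble(a1 = a1 - left, a2 = a2 + right,
             b1 = b1 - right, b2 = b2 + left, ori = "-")
    }
  })
  seg <- bind_rows(ext)
  seg$len <- seg$a2 - seg$a1 + 1L
  seg
}

# walk t = 1, 2, ... scoring +1 on ok(t), -1 otherwise; NA = hard boundary.
# Stops once the score falls xdrop below the best; returns the t of the best.
xdrop_walk <- function(ok, xdrop) {
  t <- 0L; score <- 0L; best <- 0L; best_t <- 0L
  repeat {
    t <- t + 1L
    res <- ok(t)
    if (is.na(res)) break
    score <- score + (if (res) 1L else -1L)
    if (score > best) { best <- score; best_t <- t }
    if (best - score >= xdrop || t > 20000L) break
  }
  best_t
}

# cluster matched intervals into unit instances; edges keep orientations
hr_cluster_units <- function(seg, min_unit) {
  ivals <- bind_rows(
    tibble(seg_id = seq_len(nrow(seg)), side = "a",
           start = seg$a1 - 1L, end = seg$a2, ori = seg$ori),
    tibble(seg_id = seq_len(nrow(seg)), side = "b",
           start = seg$b1 - 1L, end = seg$b2, ori = seg$ori)
  ) |> arrange(.data$start, .data$end)
  # greedy clustering: an interval joins a cluster it reciprocally overlaps
  # by >= 50% of the shorter
  cl <- integer(nrow(ivals)); ncl <- 0L
  bounds <- list()
  for (i in seq_len(nrow(ivals))) {
    assigned <- FALSE
    for (j in seq_len(ncl)) {
      b <- bounds[[j]]
      ov <- min(ivals$end[i], b[2]) - max(ivals$start[i], b[1])
      short <- min(ivals$end[i] - ivals$start[i], b[2] - b[1])
      if (ov >= 0.5 * short) {
        cl[i] <- j
        bounds[[j]] <- c(min(b[1], ivals$start[i]), max(b[2], ivals$end[i]))
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      ncl <- ncl + 1L
      cl[i] <- ncl
      bounds[[ncl]] <- c(ivals$start[i], ivals$end[i])
    }
  }
  ivals$cluster <- cl
  units <- ivals |>
    group_by(.data$cluster) |>
    summarise(start = as.integer(round(median(.data$start))),
              end = as.integer(round(median(.data$end))), .groups = "drop")
  units <- units[units$end - units$start >= min_unit, ]
  # edges between clusters, carrying each matched pair's orientation
  amap <- ivals$cluster[ivals$side == "a"][order(ivals$seg_id[ivals$side == "a"])]
  bmap <- ivals$cluster[ivals$side == "b"][order(ivals$seg_id[ivals$side == "b"])]
  edges <- tibble(u = amap, v = bmap, ori = seg$ori)
  edges <- edges[edges$u %in% units$cluster & edges$v %in% units$cluster, ]
  list(units = units, edges = edges)
}

hr_build_regions <- function(s, units, edges, min_units, min_identity,
                             region_gap) {
  # assign orientations by propagating pair orientations from the first unit
  units <- units[order(units$start), ]
  ids <- units$cluster
  orient <- setNames(rep(NA_character_, length(ids)), ids)
  for (seed in as.character(ids)) {
    if (!is.na(orient[seed])) next
    orient[seed] <- "+"
    queue <- seed
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      hit <- edges$u == as.integer(u) | edges$v == as.integer(u)
      for (e in which(hit)) {
        other <- as.character(if (edges$u[e] == as.integer(u)) edges$v[e] else edges$u[e])
        want <- if (edges$ori[e] == "+") orient[u] else flip_ori(orient[u])
        if (is.na(orient[other])) {
          orient[other] <- want
          queue <- c(queue, other)
        }
      }
    }
  }
  units$orientation <- unname(orient[as.character(units$cluster)])
  # connected components restricted by genomic gap -> regions
  grp <- cumsum(c(1L, diff(units$start) > region_gap))
  regions <- purrr::map(split(units, grp), function(un) {
    if (nrow(un) < min_units) return(NULL)
    un <- un[order(un$start), ]
    norm <- vapply(seq_len(nrow(un)), function(i) {
      q <- substr(s, un$start[i] + 1L, un$end[i])
      if (un$orientation[i] == "-") revcomp(q) else q
    }, character(1))
    reg <- register_units(norm)
    cons <- reg$consensus
    ident <- vapply(reg$aligned, function(q) string_identity(q, cons), double(1))
    keep <- ident >= min_identity
    if (sum(keep) < min_units) return(NULL)
    un <- un[keep, ]; ident <- ident[keep]
    core <- hr_palindrome_core(s, un)
    tibble(
      region_id = NA_character_, kind = "hr",
      start = min(un$start), end = max(un$end),
      n_units = nrow(un), unit_length = nchar(cons),
      consensus = cons, palindrome_core = core,
      at_percent = 100 - gc_percent(substr(s, min(un$start) + 1L, max(un$end))),
      units = list(tibble(start = un$start, end = un$end,
                          orientation = un$orientation,
                          identity_to_consensus = ident))
    )
  })
  out <- bind_rows(regions)
  if (nrow(out) == 0L) return(repeat_region_tibble())
  out <- out[order(out$start), ]
  out$region_id <- paste0("hr", seq_len(nrow(out)))
  out
}

flip_ori <- function(o) ifelse(o == "+", "-", "+")

# co-register orientation-normalized unit strings on the first unit by the
# best small offset, build a majority consensus, trim to majority support
register_units <- function(norm) {
  ref <- norm[[1]]
  offs <- vapply(norm, function(q) best_offset(ref, q, 6L), integer(1))
  offs <- offs - min(offs)
  width <- max(offs + nchar(norm))
  aligned <- vapply(seq_along(norm), function(i) {
    paste0(strrep(" ", offs[i]), norm[[i]],
           strrep(" ", width - offs[i] - nchar(norm[[i]])))
  }, character(1))
  mat <- do.call(rbind, strsplit(aligned, "", fixed = TRUE))
  support <- colSums(mat != " ")
  keep <- support >= ceiling(length(norm) / 2)
  first <- which(keep)[1]; last <- tail(which(keep), 1)
  mat <- mat[, first:last, drop = FALSE]
  cons <- apply(mat, 2, function(col) {
    col <- col[col != " "]
    names(sort(table(col), decreasing = TRUE))[1]
  })
  list(consensus = paste(cons, collapse = ""),
       aligned = substring(aligned, first, last))
}

best_offset <- function(ref, q, max_shift) {
  shifts <- -max_shift:max_shift
  sc <- vapply(shifts, function(d) {
    if (d >= 0) {
      n <- min(nchar(ref) - d, nchar(q))
      if (n <= 0) return(-1)
      mean(utf8ToInt(substr(ref, d + 1L, d + n)) == utf8ToInt(substr(q, 1L, n)))
    } else {
      n <- min(nchar(ref), nchar(q) + d)
      if (n <= 0) return(-1)
      mean(utf8ToInt(substr(ref, 1L, n)) == utf8ToInt(substr(q, 1L - d, n - d)))
    }
  }, double(1))
  shifts[which.max(sc)]
}

hr_palindrome_core <- function(s, un) {
  un <- un[order(un$start), ]
  best <- NA_character_
  for (i in seq_len(nrow(un) - 1L)) {
    if (un$orientation[i] == un$orientation[i + 1L]) next
    gap_start <- un$end[i]; gap_end <- un$start[i + 1L]
    if (gap_end - gap_start < 8L) next
    gap <- substr(s, gap_start + 1L, gap_end)
    pal <- find_palindromes(gap, min_len = 8L, max_mismatch = 0L)
    if (nrow(pal) == 0L) next
    top <- pal[which.max(pal$length), ]
    hit <- substr(gap, top$start + 1L, top$start + top$length)
    if (is.na(best) || nchar(hit) > nchar(best)) best <- hit
  }
  best
}

#' Render an hr unit alignment as a text block
#'
#' Units are orientation-normalized onto the consensus strand; each row
#' shows the unit name (reverse-strand units tagged `(rc)`), the genome
#' coordinates of both unit ends, and the unit sequence. A marker line
#' flags columns where more than half the units agree with the consensus.
#'
#' @param region One row of a repeat-region tibble from [find_hrs()].
#' @param genome The [circular_genome()] (or DNA string) the region was
#'   found on.
#' @return Character vector of lines (class `unit_alignment`), printable
#'   with `cat(x, sep = "\n")`.
#' @export
render_unit_alignment <- function(region, genome) {
  if (region$kind != "hr") abort("render_unit_alignment expects an hr region")
  un <- region$units[[1]]
  if (nrow(un) < 2L) abort("region has fewer than 2 units")
  s <- if (inherits(genome, "circular_genome")) genome$seq else toupper(genome)
  norm <- vapply(seq_len(nrow(un)), function(i) {
    q <- substr(s, un$start[i] + 1L, un$end[i])
    if (un$orientation[i] == "-") revcomp(q) else q
  }, character(1))
  width <- max(nchar(norm))
  padded <- formatC(norm, width = -width)
  mat <- do.call(rbind, strsplit(padded, "", fixed = TRUE))
  cons <- strsplit(region$consensus, "", fixed = TRUE)[[1]]
  cons <- c(cons, rep(" ", max(0L, width - length(cons))))[seq_len(width)]
  marks <- vapply(seq_len(width), function(j) {
    if (mean(mat[, j] == cons[j]) > 0.5 && cons[j] != " ") "*" else " "
  }, character(1))
  names_col <- sprintf("%s%s", paste0(region$region_id, letters[seq_len(nrow(un))]),
                       ifelse(un$orientation == "-", " (rc)", ""))
  namew <- max(nchar(names_col))
  body <- vapply(seq_len(nrow(un)), function(i) {
    sprintf("%-*s %8d> %s <%d", namew, names_col[i], un$start[i] + 1L,
            padded[i], un$end[i])
  }, character(1))
  lines <- c(
    sprintf("%s: %d units, consensus %d bp", region$region_id,
            nrow(un), region$unit_length),
    body,
    sprintf("%-*s %9s %s", namew, "consensus", "", paste(cons, collapse = "")),
    sprintf("%-*s %9s %s", namew, "", "", paste(marks, collapse = ""))
  )
  structure(lines, class = "unit_alignment")
}

#' @export
print.unit_alignment <- function(x, ...) {
  cat(unclass(x), sep = "\n")
  invisible(x)
}
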