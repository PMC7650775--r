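#' Kimura two-parameter distance between two aligned sequences
#'
#' Sites where either sequence has a gap or an ambiguity code are excluded
#' (pairwise deletion). Transitions are A<->G and C<->T; all other
#' mismatches are transversions. The distance is the closed form
#' `d = -1/2 * ln[(1 - 2P - Q) * sqrt(1 - 2Q)]` with `P` and `Q` the
#' transition and transversion proportions over the compared sites.
#' Saturated pairs (`1 - 2P - Q <= 0` or `1 - 2Q <= 0`) get `NA` rather
#' than an error, so they can be flagged downstream.
#'
#' @param a,b Equal-length gap-containing DNA strings.
#' @return One-row tibble: `d`, `P`, `Q`, `n_compared`.
#' @examples
#' k2p_distance("ACGTACGTAC", "ACGTACGTAC")
#' @export
k2p_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) abort("aligned sequences must have equal length")
  xa <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  xb <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  ok <- xa %in% c("A", "C", "G", "T") & xb %in% c("A", "C", "G", "T")
  n <- sum(ok)
  if (n == 0L) abort("no comparable sites (all gapped or ambiguous)")
  xa <- xa[ok]; xb <- xb[ok]
  diff <- xa != xb
  purine <- function(x) x %in% c("A", "G")
  ts <- diff & (purine(xa) == purine(xb))
  P <- sum(ts) / n
  Q <- sum(diff & !ts) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  d <- if (w1 <= 0 || w2 <= 0) NA_real_ else -0.5 * log(w1 * sqrt(w2))
  tibble(d = d, P = P, Q = Q, n_compared = n)
}

#' All-pairs K2P distances for a multiple alignment
#'
#' @param alignment A named character vector of equal-length aligned DNA
#'   strings, a `DNAStringSet`, or a tibble with `label` and `seq`.
#' @return Object of class `dist_matrix`: list with `labels` and the
#'   symmetric matrix `d` (`NA` marks saturated/undefined pairs).
#' @export
pairwise_distances <- function(alignment) {
  aln <- as_alignment(alignment)
  if (length(aln) < 2L) abort("need at least 2 sequences")
  if (length(unique(nchar(aln))) != 1L) {
    abort("alignment rows have unequal lengths")
  }
  n <- length(aln)
  d <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- k2p_distance(aln[[i]], aln[[j]])$d
    }
  }
  structure(list(labels = names(aln), d = d), class = "dist_matrix")
}

as_alignment <- function(alignment) {
  if (inherits(alignment, "DNAStringSet") || inherits(alignment, "BStringSet")) {
    aln <- as.character(alignment)
  } else if (is.data.frame(alignment)) {
    aln <- setNames(alignment$seq, alignment$label)
  } else {
    aln <- alignment
  }
  if (is.null(names(aln)) || any(!nzchar(names(aln)))) {
    names(aln) <- paste0("seq", seq_along(aln))
  }
  aln
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("<dist_matrix> %d taxa (K2P, pairwise deletion)\n",
              length(x$labels)))
  print(round(x$d, 4))
  invisible(x)
}

#' @export
tidy.dist_matrix <- function(x, ...) {
  n <- length(x$labels)
  idx <- which(upper.tri(x$d), arr.ind = TRUE)
  tibble(taxon_a = x$labels[idx[, 1]], taxon_b = x$labels[idx[, 2]],
         d = x$d[idx])
}

#' @method as.matrix dist_matrix
#' @export
as.matrix.dist_matrix <- function(x, ...) x$d

#' Apply the baculovirus species-demarcation rule
#'
#' Two isolates are treated as distinct species when every supplied
#' marker-gene K2P distance (granulin/polyhedrin, lef-8, lef-9) exceeds
#' the threshold of 0.05 substitutions/site; as the same species when
#' every distance is at or below it; otherwise (mixed, or any undefined
#' distance) the verdict is inconclusive. Only the "more than 0.05 means
#' distinct" direction is applied; no lower same-species bound is used.
#'
#' @param distances Named numeric vector of per-gene distances, or a
#'   tibble with `gene` and `distance`.
#' @param threshold Demarcation threshold (default 0.05 subs/site).
#' @return Object of class `demarcation_verdict`: list with `genes`
#'   (tibble `gene`, `distance`, `exceeds_threshold`), `threshold`,
#'   `verdict`.
#' @export
demarcate <- function(distances, threshold = 0.05) {
  if (is.data.frame(distances)) {
    genes <- tibble(gene = distances$gene, distance = distances$distance)
  } else {
    if (length(distances) == 0L) abort("no gene distances supplied")
    genes <- tibble(gene = names(distances) %||%
                      paste0("gene", seq_along(distances)),
                    distance = as.numeric(distances))
  }
  if (nrow(genes) == 0L) abort("no gene distances supplied")
  genes$exceeds_threshold <- genes$distance > threshold
  verdict <- if (anyNA(genes$distance)) {
    "inconclusive"
  } else if (all(genes$exceeds_threshold)) {
    "distinct_species"
  } else if (all(!genes$exceeds_threshold)) {
    "same_species"
  } else {
    "inconclusive"
  }
  structure(list(genes = genes, threshold = threshold, verdict = verdict),
            class = "demarcation_verdict")
}

#' @export
print.demarcation_verdict <- function(x, ...) {
  cat(sprintf("<demarcation_verdict> %s (threshold %g subs/site)\n",
              x$verdict, x$threshold))
  print(as.data.frame(x$genes))
  invisible(x)
}

#' @export
tidy.demarcation_verdict <- function(x, ...) x$genes

#' @export
glance.demarcation_verdict <- function(x, ...) {
  tibble(verdict = x$verdict, threshold = x$threshold,
         n_genes = nrow(x$genes))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration. Negative branch lengths are
#' clamped to zero with the deficit moved to the sister branch (total
#' path length preserved). The unrooted tree is returned as Newick text
#' with branch lengths.
#'
#' @param matrix A `dist_matrix` from [pairwise_distances()], a plain
#'   labeled symmetric matrix, or a `dist`.
#' @return Newick string (class `newick`), terminated with `;`.
#' @export
nj_tree <- function(matrix) {
  if (inherits(matrix, "dist_matrix")) {
    d <- matrix$d
  } else if (inherits(matrix, "dist")) {
    d <- as.matrix(matrix)
  } else {
    d <- matrix
  }
  n <- nrow(d)
  if (n < 3L) abort("need at least 3 taxa")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", 1:n)
  if (anyNA(d[upper.tri(d)])) {
    abort("distance matrix has undefined (saturated) entries; exclude those taxa")
  }
  labels <- rownames(d)
  nodes <- as.list(labels)   # growing newick fragments
  active <- seq_len(n)
  dm <- d
  while (length(active) > 3L) {
    m <- length(active)
    sub <- dm[active, active, drop = FALSE]
    r <- rowSums(sub)
    q <- (m - 2) * sub - outer(r, r, `+`)
    diag(q) <- Inf
    ij <- which(q == min(q), arr.ind = TRUE)[1, ]  # deterministic tie-break
    ii <- min(ij); jj <- max(ij)
    i <- active[ii]; j <- active[jj]
    ri <- r[ii]; rj <- r[jj]
    li <- dm[i, j] / 2 + (ri - rj) / (2 * (m - 2))
    lj <- dm[i, j] - li
    bl <- clamp_branches(li, lj)
    # distances from the new node u to every other active node
    others <- setdiff(active, c(i, j))
    du <- (dm[i, others] + dm[j, others] - dm[i, j]) / 2
    u <- nrow(dm) + 1L
    dm <- rbind(cbind(dm, 0), 0)
    rownames(dm)[u] <- colnames(dm)[u] <- paste0("node", u)
    dm[u, others] <- dm[others, u] <- du
    nodes[[u]] <- sprintf("(%s:%s,%s:%s)", nodes[[i]], fmt_bl(bl[1]),
                          nodes[[j]], fmt_bl(bl[2]))
    active <- c(others, u)
  }
  a <- active[1]; b <- active[2]; c3 <- active[3]
  la <- (dm[a, b] + dm[a, c3] - dm[b, c3]) / 2
  lb <- dm[a, b] - la
  lc <- dm[a, c3] - la
  ls <- clamp_branches3(la, lb, lc)
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", nodes[[a]], fmt_bl(ls[1]),
                 nodes[[b]], fmt_bl(ls[2]), nodes[[c3]], fmt_bl(ls[3]))
  structure(nwk, class = "newick")
}

fmt_bl <- function(x) sprintf("%.8g", x)

clamp_branches <- function(li, lj) {
  if (li < 0) { lj <- lj + li; li <- 0 }
  if (lj < 0) { li <- li + lj; lj <- 0 }
  c(max(li, 0), max(lj, 0))
}

clamp_branches3 <- function(la, lb, lc) {
  v <- c(la, lb, lc)
  for (i in seq_along(v)) {
    if (v[i] < 0) {
      # move the deficit onto the other two branches equally
      v[-i] <- v[-i] + v[i] / 2
      v[i] <- 0
    }
  }
  pmax(v, 0)
}

#' @export
print.newick <- function(x, ...) {
  cat(unclass(x), "\n")
  invisible(x)
}

#' Write a Newick tree to file
#' @param tree `newick` string from [nj_tree()].
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  writeLines(unclass(tree), path)
  invisible(path)
}

#' Concatenate per-gene alignments in a reference gene order
#'
#' @param alignments Named list of alignments (each a named character
#'   vector of equal-length rows); every alignment must contain the same
#'   taxon set.
#' @param order Character vector giving the gene concatenation order
#'   (default: the list's own order).
#' @return A named character vector (the concatenated alignment) with an
#'   `offsets` attribute: tibble `gene`, `start`, `end` (1-based columns).
#' @export
concat_alignments <- function(alignments, order = names(alignments)) {
  if (is.null(names(alignments))) abort("alignments must be a named list")
  missing_genes <- setdiff(order, names(alignments))
  if (length(missing_genes)) {
    abort(sprintf("unknown genes in order: %s",
                  paste(missing_genes, collapse = ", ")))
  }
  alns <- lapply(alignments[order], as_alignment)
  taxa <- sort(names(alns[[1]]))
  for (g in seq_along(alns)) {
    absent <- setdiff(taxa, names(alns[[g]]))
    extra <- setdiff(names(alns[[g]]), taxa)
    if (length(absent) || length(extra)) {
      abort(sprintf("taxon set mismatch in block '%s': missing %s",
                    order[g],
                    paste(c(absent, paste0("(extra) ", extra)), collapse = ", ")))
    }
  }
  widths <- vapply(alns, function(a) nchar(a[[1]]), integer(1))
  out <- setNames(vapply(taxa, function(tx) {
    paste(vapply(alns, function(a) a[[tx]], character(1)), collapse = "")
  }, character(1)), taxa)
  ends <- unname(cumsum(widths))
  attr(out, "offsets") <- tibble(gene = order,
                                 start = ends - unname(widths) + 1L,
                                 end = ends)
  out
}

#' Bootstrap support for neighbor-joining splits
#'
#' Site-resampling bootstrap: alignment columns are resampled with
#' replacement, the K2P matrix and NJ tree recomputed, and each internal
#' bipartition of the full-data tree is scored by how often it recurs.
#'
#' @param alignment As in [pairwise_distances()].
#' @param n Number of replicates (default 100).
#' @param seed RNG seed (required; bootstrap is always reproducible).
#' @return Tibble: `split` (taxon set on the smaller side, comma-joined),
#'   `support` (fraction of replicates).
#' @export
bootstrap_support <- function(alignment, n = 100L, seed) {
  if (missing(seed)) abort("seed is required")
  aln <- as_alignment(alignment)
  width <- nchar(aln[[1]])
  base_splits <- newick_splits(nj_tree(pairwise_distances(aln)), names(aln))
  counts <- setNames(rep(0L, length(base_splits)), base_splits)
  set.seed(seed)
  mats <- lapply(aln, function(s) strsplit(s, "", fixed = TRUE)[[1]])
  for (b in seq_len(n)) {
    cols <- sample.int(width, width, replace = TRUE)
    rep_aln <- vapply(mats, function(v) paste(v[cols], collapse = ""),
                      character(1))
    tr <- try(nj_tree(pairwise_distances(rep_aln)), silent = TRUE)
    if (inherits(tr, "try-error")) next
    got <- newick_splits(tr, names(aln))
    hit <- base_splits %in% got
    counts[hit] <- counts[hit] + 1L
  }
  tibble(split = base_splits, support = as.numeric(counts) / n)
}

# internal bipartitions of an unrooted newick tree, canonicalized as the
# lexicographically smaller comma-joined taxon set
newick_splits <- function(nwk, taxa) {
  clades <- list()
  # simple recursive-descent parse
  s <- gsub(";$", "", unclass(nwk))
  pos <- 1L
  parse_clade <- function() {
    tips <- character()
    if (substr(s, pos, pos) == "(") {
      pos <<- pos + 1L
      repeat {
        tips <- c(tips, parse_clade())
        ch <- substr(s, pos, pos)
        if (ch == ",") { pos <<- pos + 1L; next }
        if (ch == ")") { pos <<- pos + 1L; break }
        abort("malformed newick")
      }
      # skip branch length
      m <- regexpr("^:[-0-9.eE+]+", substr(s, pos, nchar(s)))
      if (m == 1L) pos <<- pos + attr(m, "match.length")
      clades[[length(clades) + 1L]] <<- tips
      tips
    } else {
      m <- regexpr("^[^,():;]+", substr(s, pos, nchar(s)))
      tip <- substr(s, pos, pos + attr(m, "match.length") - 1L)
      pos <<- pos + attr(m, "match.length")
      m2 <- regexpr("^:[-0-9.eE+]+", substr(s, pos, nchar(s)))
      if (m2 == 1L) pos <<- pos + attr(m2, "match.length")
      tip
    }
  }
  parse_clade()
  canon <- vapply(clades, function(cl) {
    if (length(cl) <= 1L || length(cl) >= length(taxa) - 1L) return(NA_character_)
    other <- setdiff(taxa, cl)
    a <- paste(sort(cl), collapse = ",")
    b <- paste(sort(other), collapse = ",")
    min(a, b)
  }, character(1))
  unique(canon[!is.na(canon)])
}
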