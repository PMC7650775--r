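#' Feature tables
#'
#' Annotations are carried as tibbles ("feature tables") with one row per
#' logical feature. Coordinates are internal convention: 0-based half-open
#' on the plus strand. An origin-spanning feature on a circular genome is a
#' single row whose `end` exceeds the genome length (`wrap = TRUE`); on
#' export it becomes a `join` of two spans, and re-import reconstructs the
#' single wrapped row.
#'
#' @param feature_id,start,end,strand,kind,gene,product Vectors of equal
#'   length (or length 1) describing the features. `kind` is typically one
#'   of `CDS`, `repeat_region`, `promoter`; other kinds are allowed.
#' @param genome_id Identifier of the genome the features annotate.
#' @param genome_length Length of that genome in bp.
#' @return A tibble of class `feature_table` with attributes `genome_id`
#'   and `genome_length`.
#' @export
feature_table <- function(feature_id = character(), start = integer(),
                          end = integer(), strand = character(),
                          kind = character(), gene = NA_character_,
                          product = NA_character_,
                          genome_id = "genome", genome_length = NA_integer_) {
  tb <- tibble(
    feature_id = as.character(feature_id),
    start = as.integer(start),
    end = as.integer(end),
    strand = as.character(strand),
    kind = as.character(kind),
    gene = as.character(gene),
    product = as.character(product)
  )
  validate_feature_table(tb, genome_length)
  tb$wrap <- !is.na(genome_length) & tb$end > genome_length
  attr(tb, "genome_id") <- genome_id
  attr(tb, "genome_length") <- as.integer(genome_length)
  class(tb) <- c("feature_table", class(tb))
  tb
}

validate_feature_table <- function(tb, genome_length) {
  if (nrow(tb) == 0L) return(invisible(tb))
  if (any(tb$start < 0L)) abort("feature start coordinates must be >= 0")
  if (any(tb$end <= tb$start)) abort("features must satisfy start < end")
  if (!all(tb$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  if (!is.na(genome_length)) {
    if (any(tb$start >= genome_length)) {
      abort("feature start beyond genome length")
    }
    if (any(tb$end > 2L * genome_length)) {
      abort("feature coordinates outside genome length")
    }
  }
  invisible(tb)
}

ft_attrs <- function(tb) {
  list(genome_id = attr(tb, "genome_id") %||% "genome",
       genome_length = attr(tb, "genome_length") %||% NA_integer_)
}

#' Read an annotation file into a feature table
#'
#' Supports GFF3 and GenBank flat files. External 1-based inclusive
#' coordinates are converted to the internal 0-based half-open convention;
#' `join`ed two-span features that run across the origin of a circular
#' genome are reconstructed as single wrapped rows. Feature kinds other
#' than `CDS`, `repeat_region`, `promoter` and `source` are kept with kind
#' `"other"` (a warning lists them).
#'
#' @param path Annotation file path.
#' @param dialect `"gff3"` or `"genbank"` (default guessed from extension).
#' @param genome_length Genome length in bp; required for GFF3 files that
#'   lack a `##sequence-region` pragma.
#' @return A [feature_table()].
#' @export
read_annotation <- function(path, dialect = c("auto", "gff3", "genbank"),
                            genome_length = NA_integer_) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (dialect == "auto") {
    dialect <- if (grepl("\\.(gb|gbk|genbank)$", path, ignore.case = TRUE))
      "genbank" else "gff3"
  }
  switch(dialect,
         gff3 = read_gff3(path, genome_length),
         genbank = read_genbank(path))
}

#' Write a feature table to GFF3 or GenBank
#'
#' The emitted file re-parses (with [read_annotation()]) to a field-equal
#' table. GFF3 output is 1-based inclusive with CDS phase; origin-spanning
#' features are emitted as two spans sharing one `ID`. GenBank output uses
#' `join()`/`complement()` location strings.
#'
#' @param table A [feature_table()].
#' @param path Output path.
#' @param dialect `"gff3"` or `"genbank"`.
#' @param genome Optional [circular_genome()]; when supplied to the GenBank
#'   writer, an `ORIGIN` sequence block is included.
#' @return Invisibly, `path`.
#' @export
write_annotation <- function(table, path, dialect = c("gff3", "genbank"),
                             genome = NULL) {
  dialect <- match.arg(dialect)
  switch(dialect,
         gff3 = write_gff3(table, path),
         genbank = write_genbank(table, path, genome))
  invisible(path)
}

known_kinds <- c("CDS", "repeat_region", "promoter", "source", "other")

## ---- GFF3 ----

gff3_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  gsub(",", "%2C", x, fixed = TRUE)
}
gff3_unescape <- function(x) {
  x <- gsub("%3B", ";", x, fixed = TRUE)
  x <- gsub("%3D", "=", x, fixed = TRUE)
  x <- gsub("%2C", ",", x, fixed = TRUE)
  gsub("%25", "%", x, fixed = TRUE)
}

write_gff3 <- function(table, path) {
  at <- ft_attrs(table)
  L <- at$genome_length
  lines <- c("##gff-version 3")
  if (!is.na(L)) {
    lines <- c(lines, sprintf("##sequence-region %s 1 %d", at$genome_id, L))
  }
  if (nrow(table) > 0L) {
    rows <- purrr::pmap(table, function(feature_id, start, end, strand, kind,
                                        gene, product, wrap, ...) {
      attrs <- sprintf("ID=%s", gff3_escape(feature_id))
      if (!is.na(gene)) attrs <- paste0(attrs, ";gene=", gff3_escape(gene))
      if (!is.na(product)) attrs <- paste0(attrs, ";product=", gff3_escape(product))
      spans <- if (isTRUE(wrap)) {
        list(c(start + 1L, L), c(1L, end - L))
      } else {
        list(c(start + 1L, end))
      }
      # phase: bases to trim from the 5' end of each span to reach codon start
      phases <- rep(".", length(spans))
      if (kind == "CDS") {
        lens <- vapply(spans, function(sp) sp[2] - sp[1] + 1L, integer(1))
        # reading order of spans along the coding strand
        ord <- if (strand == "+") seq_along(spans) else rev(seq_along(spans))
        ph <- integer(length(spans))
        consumed <- 0L
        for (i in ord) {
          ph[i] <- (3L - consumed %% 3L) %% 3L
          consumed <- consumed + lens[i]
        }
        phases <- as.character(ph)
      }
      vapply(seq_along(spans), function(i) {
        paste(at$genome_id, "baculokit", kind, spans[[i]][1], spans[[i]][2],
              ".", strand, phases[i], attrs, sep = "\t")
      }, character(1))
    })
    lines <- c(lines, unlist(rows))
  }
  writeLines(lines, path)
}

read_gff3 <- function(path, genome_length = NA_integer_) {
  lines <- readLines(path, warn = FALSE)
  genome_id <- "genome"
  sr <- grep("^##sequence-region", lines, value = TRUE)
  if (length(sr) >= 1L) {
    parts <- strsplit(trimws(sr[1]), "\\s+")[[1]]
    genome_id <- parts[2]
    genome_length <- as.integer(parts[4])
  }
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(body) == 0L) {
    return(feature_table(genome_id = genome_id, genome_length = genome_length))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(f) != 9L)) abort(sprintf("malformed GFF3 line in %s", path))
  f <- do.call(rbind, f)
  get_attr <- function(attrs, key) {
    m <- stringr::str_match(attrs, paste0("(?:^|;)", key, "=([^;]*)"))[, 2]
    gff3_unescape(m)
  }
  df <- tibble(
    seqid = f[, 1], kind = f[, 3],
    start1 = as.integer(f[, 4]), end1 = as.integer(f[, 5]),
    strand = f[, 7],
    feature_id = get_attr(f[, 9], "ID"),
    gene = get_attr(f[, 9], "gene"),
    product = get_attr(f[, 9], "product")
  )
  if (anyNA(df$feature_id)) {
    df$feature_id[is.na(df$feature_id)] <-
      paste0("feat", which(is.na(df$feature_id)))
  }
  df <- normalise_kinds(df, path)
  assemble_features(df, genome_id, genome_length)
}

normalise_kinds <- function(df, path) {
  unknown <- setdiff(unique(df$kind), known_kinds)
  if (length(unknown) > 0L) {
    warn(sprintf("unknown feature kinds in %s kept as 'other': %s",
                 path, paste(unknown, collapse = ", ")))
    df$kind[df$kind %in% unknown] <- "other"
  }
  df[df$kind != "source", , drop = FALSE]
}

# merge two-span joins back into single wrapped rows
assemble_features <- function(df, genome_id, genome_length) {
  merged <- df |>
    group_by(.data$feature_id) |>
    dplyr::group_map(function(g, key) {
      if (nrow(g) == 1L) {
        if (!is.na(genome_length) && g$end1 > genome_length) {
          abort(sprintf("feature %s: coordinate outside genome length",
                        key$feature_id))
        }
        tibble(feature_id = key$feature_id, start = g$start1 - 1L,
               end = g$end1, strand = g$strand, kind = g$kind,
               gene = g$gene, product = g$product)
      } else if (nrow(g) == 2L) {
        if (is.na(genome_length)) {
          abort("two-span joined feature requires a known genome length")
        }
        g <- g[order(g$start1), ]
        tail_part <- g[2, ]; head_part <- g[1, ]
        if (tail_part$end1 != genome_length || head_part$start1 != 1L) {
          abort(sprintf("feature %s: unsupported multi-span layout",
                        key$feature_id))
        }
        tibble(feature_id = key$feature_id, start = tail_part$start1 - 1L,
               end = genome_length + head_part$end1,
               strand = tail_part$strand, kind = tail_part$kind,
               gene = tail_part$gene, product = tail_part$product)
      } else {
        abort(sprintf("feature %s has %d spans; at most 2 supported",
                      key$feature_id, nrow(g)))
      }
    }) |>
    bind_rows()
  merged <- merged[order(merged$start, merged$end), ]
  feature_table(merged$feature_id, merged$start, merged$end, merged$strand,
                merged$kind, merged$gene, merged$product,
                genome_id = genome_id, genome_length = genome_length)
}

## ---- GenBank flat file ----

gb_location <- function(start, end, strand, wrap, L) {
  loc <- if (isTRUE(wrap)) {
    sprintf("join(%d..%d,1..%d)", start + 1L, L, end - L)
  } else {
    sprintf("%d..%d", start + 1L, end)
  }
  if (strand == "-") sprintf("complement(%s)", loc) else loc
}

write_genbank <- function(table, path, genome = NULL) {
  at <- ft_attrs(table)
  L <- at$genome_length
  if (is.na(L) && !is.null(genome)) L <- genome_length(genome)
  topo <- if (!is.null(genome) && genome$topology == "linear") "linear  " else "circular"
  lines <- c(
    sprintf("LOCUS       %-16s %d bp    DNA     %s VRL",
            at$genome_id, if (is.na(L)) 0L else L, topo),
    sprintf("DEFINITION  %s.", at$genome_id),
    "FEATURES             Location/Qualifiers"
  )
  if (!is.na(L)) {
    lines <- c(lines, sprintf("     %-16s%s", "source", sprintf("1..%d", L)))
  }
  if (nrow(table) > 0L) {
    for (i in seq_len(nrow(table))) {
      r <- table[i, ]
      lines <- c(lines, sprintf("     %-16s%s", r$kind,
                                gb_location(r$start, r$end, r$strand, r$wrap, L)))
      lines <- c(lines, sprintf('                     /locus_tag="%s"', r$feature_id))
      if (!is.na(r$gene)) {
        lines <- c(lines, sprintf('                     /gene="%s"', r$gene))
      }
      if (!is.na(r$product)) {
        lines <- c(lines, sprintf('                     /product="%s"', r$product))
      }
    }
  }
  if (!is.null(genome)) {
    lines <- c(lines, "ORIGIN")
    s <- tolower(genome$seq)
    starts <- seq(1L, nchar(s), by = 60L)
    for (st in starts) {
      chunk <- substr(s, st, min(st + 59L, nchar(s)))
      blocks <- substring(chunk, seq(1, nchar(chunk), 10),
                          pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
      lines <- c(lines, sprintf("%9d %s", st, paste(blocks, collapse = " ")))
    }
  }
  lines <- c(lines, "//")
  writeLines(lines, path)
}

#' @rdname read_annotation
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)[1]
  if (is.na(locus)) abort(sprintf("no LOCUS line in %s", path))
  toks <- strsplit(trimws(locus), "\\s+")[[1]]
  genome_id <- toks[2]
  genome_length <- suppressWarnings(as.integer(toks[which(toks == "bp") - 1L]))
  if (length(genome_length) == 0L) genome_length <- NA_integer_
  fstart <- grep("^FEATURES", lines)
  fend <- grep("^(ORIGIN|//)", lines)
  fend <- if (length(fend)) min(fend[fend > fstart]) else length(lines) + 1L
  if (length(fstart) == 0L) {
    return(feature_table(genome_id = genome_id, genome_length = genome_length))
  }
  block <- lines[(fstart + 1L):(fend - 1L)]
  # a feature header starts at column 6; qualifier/continuation lines at 22
  is_header <- grepl("^     \\S", block)
  idx <- cumsum(is_header)
  feats <- split(block, idx)
  feats <- feats[names(feats) != "0"]
  rows <- purrr::map(feats, function(fl) {
    hdr <- fl[1]
    kind <- trimws(substr(hdr, 1, 20))
    loc <- trimws(substr(hdr, 21, nchar(hdr)))
    quals <- fl[-1]
    # the location may continue over lines, but only before the first
    # qualifier; later non-'/' lines are wrapped qualifier values
    qstart <- which(grepl("^\\s*/", quals))[1]
    cont <- if (is.na(qstart)) quals else quals[seq_len(qstart - 1L)]
    if (length(cont)) loc <- paste0(loc, paste(trimws(cont), collapse = ""))
    quals <- if (is.na(qstart)) character() else quals[qstart:length(quals)]
    qget <- function(key) {
      m <- stringr::str_match(quals, sprintf('^\\s*/%s="?([^"]*)"?', key))[, 2]
      m <- m[!is.na(m)]
      if (length(m)) m[1] else NA_character_
    }
    p <- parse_gb_location(loc, genome_length)
    tibble(feature_id = qget("locus_tag"), start = p$start, end = p$end,
           strand = p$strand, kind = kind, gene = qget("gene"),
           product = qget("product"))
  })
  df <- bind_rows(rows)
  df <- df[df$kind != "source", , drop = FALSE]
  if (nrow(df) == 0L) {
    return(feature_table(genome_id = genome_id, genome_length = genome_length))
  }
  if (anyNA(df$feature_id)) {
    df$feature_id[is.na(df$feature_id)] <-
      paste0("feat", which(is.na(df$feature_id)))
  }
  unknown <- setdiff(unique(df$kind), known_kinds)
  if (length(unknown) > 0L) {
    warn(sprintf("unknown feature kinds in %s kept as 'other': %s",
                 path, paste(unknown, collapse = ", ")))
    df$kind[df$kind %in% unknown] <- "other"
  }
  if (!is.na(genome_length) && any(df$end > 2L * genome_length)) {
    abort("coordinate outside genome length")
  }
  df <- df[order(df$start, df$end), ]
  feature_table(df$feature_id, df$start, df$end, df$strand, df$kind,
                df$gene, df$product,
                genome_id = genome_id, genome_length = genome_length)
}

parse_gb_location <- function(loc, L) {
  strand <- "+"
  loc <- gsub("\\s", "", loc)
  if (startsWith(loc, "complement(")) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (startsWith(loc, "join(")) {
    inner <- sub("^join\\((.*)\\)$", "\\1", loc)
    spans <- strsplit(inner, ",", fixed = TRUE)[[1]]
    sp <- lapply(spans, function(s) as.integer(strsplit(s, "..", fixed = TRUE)[[1]]))
    if (length(sp) != 2L || is.na(L)) {
      abort(sprintf("unsupported join location: %s", loc))
    }
    # origin-spanning join: (x..L, 1..y)
    if (sp[[1]][2] == L && sp[[2]][1] == 1L) {
      return(list(start = sp[[1]][1] - 1L, end = L + sp[[2]][2], strand = strand))
    }
    abort(sprintf("unsupported join location: %s", loc))
  }
  ends <- as.integer(stringr::str_match(loc, "^[<>]?(\\d+)\\.\\.[<>]?(\\d+)$")[, 2:3])
  if (anyNA(ends)) abort(sprintf("cannot parse location: %s", loc))
  if (!is.na(L) && ends[2] > L) abort("coordinate outside genome length")
  list(start = ends[1] - 1L, end = ends[2], strand = strand)
}
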