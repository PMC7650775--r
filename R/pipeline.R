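#' Run the full genome-characterization pipeline
#'
#' Wires the stages together: read genome, annotate ORFs (or pass through
#' an existing annotation), summarise, scan promoters, find repeats,
#' optionally classify against a panel and compute per-gene K2P distances
#' / demarcation / an NJ tree when marker alignments are supplied. All
#' artifacts are written under `out_dir` together with `report.md`,
#' `report.json` and a checksummed file manifest. `report.json` is
#' deterministic for identical inputs and configuration.
#'
#' @param config A YAML file path or a list with elements:
#'   `fasta` (required), `annotation` (optional GFF3/GenBank path;
#'   when given, annotation is pass-through instead of predicted),
#'   `panel` + `panel_fasta` (optional classification inputs),
#'   `alignments` (optional named list of aligned marker FASTA paths,
#'   e.g. granulin/lef-8/lef-9, each containing the two taxa to compare),
#'   `out_dir` (default `"baculokit_run"`), and `params` (overrides for
#'   `min_codons`, `max_overlap`, `window_nt`, `demarcation_threshold`).
#' @return A `report_bundle` list (also serialized to `report.json`):
#'   `summary`, `classification_counts`, `promoter_summary`,
#'   `repeats`, `demarcation`, `files`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$fasta)) abort("config must name an input 'fasta'")
  out_dir <- config$out_dir %||% "baculokit_run"
  params <- utils::modifyList(
    list(min_codons = 50L, max_overlap = 30L, window_nt = 180L,
         demarcation_threshold = 0.05),
    config$params %||% list()
  )
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  stage <- "genome_io"
  res <- tryCatch({
    genome <- read_genome_fasta(config$fasta)
    stage <- "orf_annotation"
    if (!is.null(config$annotation)) {
      feats <- read_annotation(config$annotation,
                               genome_length = genome_length(genome))
      orfs <- orf_table_from_features(genome, feats)
    } else {
      orfs <- find_orfs(genome, min_codons = params$min_codons) |>
        resolve_overlaps(max_overlap_bp = params$max_overlap)
    }
    features <- orfs_as_features(orfs)
    gff_path <- file.path(out_dir, "annotation.gff3")
    write_annotation(features, gff_path, "gff3")
    gbk_path <- file.path(out_dir, "annotation.gbk")
    write_annotation(features, gbk_path, "genbank", genome = genome)
    written <- c(written, gff_path, gbk_path)
    summary <- summarize_genome(genome, features)
    stage <- "promoter_scan"
    prom <- scan_promoters(genome, orfs, window_nt = params$window_nt)
    prom_path <- file.path(out_dir, "promoters.tsv")
    utils::write.table(prom, prom_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    written <- c(written, prom_path)
    stage <- "repeat_analysis"
    hrs <- find_hrs(genome)
    drs <- find_tandem_repeats(genome)
    repeats <- bind_rows(hrs, drs) |> arrange(.data$start)
    rep_path <- file.path(out_dir, "repeats.tsv")
    utils::write.table(repeats |> select(-"units"), rep_path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    written <- c(written, rep_path)
    stage <- "homology_classify"
    classification <- NULL
    if (!is.null(config$panel)) {
      panel <- read_gene_panel(config$panel)
      if (!is.null(config$panel_fasta)) {
        panel <- panel_with_sequences(panel, config$panel_fasta)
        classification <- classify_orfs(orfs, panel)
        cls_path <- file.path(out_dir, "classification.tsv")
        utils::write.table(classification, cls_path, sep = "\t",
                           row.names = FALSE, quote = FALSE)
        written <- c(written, cls_path)
      }
    }
    stage <- "phylo"
    demarcation <- NULL
    if (!is.null(config$alignments)) {
      dists <- vapply(names(config$alignments), function(g) {
        aln <- as_alignment(Biostrings::readBStringSet(config$alignments[[g]]))
        if (length(aln) != 2L) {
          abort(sprintf("marker alignment '%s' must contain exactly 2 taxa", g))
        }
        k2p_distance(aln[[1]], aln[[2]])$d
      }, double(1))
      d_path <- file.path(out_dir, "distances.tsv")
      utils::write.table(tibble(gene = names(dists), distance = dists),
                         d_path, sep = "\t", row.names = FALSE, quote = FALSE)
      written <- c(written, d_path)
      demarcation <- demarcate(dists, threshold = params$demarcation_threshold)
    }
    list(genome = genome, orfs = orfs, summary = summary, prom = prom,
         repeats = repeats, classification = classification,
         demarcation = demarcation)
  }, error = function(e) {
    unlink(written)
    abort(sprintf("pipeline failed at stage '%s': %s", stage,
                  conditionMessage(e)))
  })
  bundle <- list(
    genome_id = res$genome$id,
    parameters = params,
    summary = as.list(res$summary),
    orf_count = nrow(res$orfs),
    classification_counts = if (!is.null(res$classification))
      as.list(setNames(summarize_classes(res$classification)$n,
                       summarize_classes(res$classification)$class)),
    promoter_summary = lapply(split(summarize_promoters(res$prom),
                                    seq_len(nrow(summarize_promoters(res$prom)))),
                              as.list),
    repeats = lapply(seq_len(nrow(res$repeats)), function(i)
      as.list(res$repeats[i, setdiff(names(res$repeats), "units")])),
    demarcation = if (!is.null(res$demarcation))
      list(verdict = res$demarcation$verdict,
           threshold = res$demarcation$threshold,
           genes = as.list(setNames(res$demarcation$genes$distance,
                                    res$demarcation$genes$gene)))
  )
  json_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(bundle, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  written <- c(written, json_path)
  md_path <- file.path(out_dir, "report.md")
  writeLines(render_report_md(bundle), md_path)
  written <- c(written, md_path)
  manifest <- tibble(file = basename(written),
                     md5 = unname(tools::md5sum(written)))
  man_path <- file.path(out_dir, "manifest.tsv")
  utils::write.table(manifest, man_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  bundle$files <- manifest
  class(bundle) <- "report_bundle"
  invisible(bundle)
}

render_report_md <- function(b) {
  s <- b$summary
  lines <- c(
    sprintf("# Genome characterization report: %s", b$genome_id),
    "",
    "## Genome summary",
    sprintf("- length: %s bp", format(s$length_bp, big.mark = ",")),
    sprintf("- GC content: %.2f%%", s$gc_percent),
    sprintf("- ORFs: %d", b$orf_count),
    sprintf("- coding density: %.2f%%", s$coding_percent),
    ""
  )
  if (!is.null(b$classification_counts)) {
    lines <- c(lines, "## Gene-content classes",
               vapply(names(b$classification_counts), function(cl)
                 sprintf("- %s: %d", cl, b$classification_counts[[cl]]),
                 character(1)), "")
  }
  if (length(b$promoter_summary)) {
    lines <- c(lines, "## Promoter elements",
               vapply(b$promoter_summary, function(r)
                 sprintf("- %s: %d hits in %d ORFs (mean offset %.1f nt)",
                         r$class, r$n_hits, r$n_orfs, r$mean_offset),
                 character(1)), "")
  }
  if (length(b$repeats)) {
    lines <- c(lines, "## Repeat regions",
               vapply(b$repeats, function(r)
                 sprintf("- %s (%s): %d..%d, %d units of %d bp, AT %.1f%%%s",
                         r$region_id, r$kind, r$start + 1L, r$end,
                         r$n_units, r$unit_length, r$at_percent,
                         if (!is.null(r$palindrome_core) &&
                             !is.na(r$palindrome_core))
                           paste0(", core ", r$palindrome_core) else ""),
                 character(1)), "")
  } else {
    lines <- c(lines, "## Repeat regions", "- none detected", "")
  }
  if (!is.null(b$demarcation)) {
    lines <- c(lines, "## Species demarcation",
               sprintf("- verdict: %s (threshold %g subs/site)",
                       b$demarcation$verdict, b$demarcation$threshold),
               vapply(names(b$demarcation$genes), function(g)
                 sprintf("- %s: %.4f", g, b$demarcation$genes[[g]]),
                 character(1)), "")
  } else {
    lines <- c(lines, "## Species demarcation", "- not run (no alignments supplied)", "")
  }
  lines
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(render_report_md(x), sep = "\n")
  invisible(x)
}
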