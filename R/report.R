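#' Run configuration for a full profiling run
#'
#' Collects input paths and every tunable of the pipeline. Input files are
#' checked for existence at construction time; the output directory is
#' created on demand by [run_profile()].
#'
#' @param bam Path to the BAM or SAM alignment.
#' @param ref Path to the single-record reference FASTA.
#' @param tree Optional haplogroup tree TSV (enables haplogroup assignment
#'   and the contamination indicator).
#' @param annotation_dbs Character vector of annotation CSV paths.
#' @param out_dir Output directory.
#' @param mode Consensus mode (`"majority"`, `"bestscore"`,
#'   `"majority+bestscore"`).
#' @param min_base_quality,min_mapping_quality Pileup filter thresholds.
#' @param maf_threshold,min_depth Heteroplasmy detection parameters.
#' @param damage_min_base_quality,damage_K Damage profiling parameters.
#' @param heteroplasmy,annotation,ancient_dna Logical switches for the
#'   optional sections.
#' @return A `RunConfig` list.
#' @export
run_config <- function(bam, ref, tree = NULL, annotation_dbs = character(0),
                       out_dir, mode = "majority",
                       min_base_quality = 30L, min_mapping_quality = 20L,
                       maf_threshold = 0.10, min_depth = 10L,
                       damage_min_base_quality = 20L, damage_K = 25L,
                       heteroplasmy = TRUE,
                       annotation = length(annotation_dbs) > 0L,
                       ancient_dna = TRUE) {
  for (p in c(bam, ref, tree, annotation_dbs))
    if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
  mode <- norm_mode(mode)
  structure(list(bam = bam, ref = ref, tree = tree,
                 annotation_dbs = annotation_dbs, out_dir = out_dir,
                 mode = mode,
                 min_base_quality = as.integer(min_base_quality),
                 min_mapping_quality = as.integer(min_mapping_quality),
                 maf_threshold = maf_threshold,
                 min_depth = as.integer(min_depth),
                 damage_min_base_quality = as.integer(damage_min_base_quality),
                 damage_K = as.integer(damage_K),
                 heteroplasmy = isTRUE(heteroplasmy),
                 annotation = isTRUE(annotation),
                 ancient_dna = isTRUE(ancient_dna)),
            class = "RunConfig")
}

#' Read a run configuration from YAML
#'
#' The YAML keys mirror the [run_config()] arguments; `overrides` (e.g.
#' from CLI flags) replace the file's values.
#'
#' @param path YAML path.
#' @param overrides Named list of values overriding the file.
#' @return A `RunConfig`.
#' @export
read_run_config <- function(path, overrides = list()) {
  y <- yaml::read_yaml(path)
  y[names(overrides)] <- overrides
  do.call(run_config, y)
}

#' Execute the full profiling pipeline
#'
#' Fixed stage order: load inputs, pileup + summary statistics, consensus,
#' then the enabled optional sections — haplogroup assignment with the
#' contamination indicator, heteroplasmy detection, consensus-versus-
#' reference variants with annotation, damage profile and substitution
#' spectrum. Every table behind the HTML report is also written as
#' TSV/JSON, so nothing is image-only; input problems (unreadable files,
#' tree positions outside the reference) abort before any output is
#' written. Outputs are deterministic given the inputs; only the HTML
#' report carries a timestamp.
#'
#' @param config A [run_config()].
#' @return A `RunResult` list with elements `summary`, `pileup`,
#'   `consensus`, `haplogroup` (`NULL` when no tree), `p_mismatch`,
#'   `heteroplasmy`, `variants`, `annotated`, `spectrum`, `damage`,
#'   `fragmentation`, `skipped` (named logical), and `provenance`.
#' @export
run_profile <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  ref <- load_reference(config$ref)
  reads <- read_alignments(config$bam)
  tree <- if (!is.null(config$tree)) parse_haplotree(config$tree, ref) else NULL

  policy <- filter_policy(config$min_base_quality, config$min_mapping_quality)
  pileup <- build_pileup(reads, ref, policy)
  stats <- summarize_alignment(reads, pileup, ref)
  consensus <- build_consensus(pileup, config$mode)

  skipped <- c(haplogroup = is.null(tree),
               heteroplasmy = !config$heteroplasmy,
               annotation = !config$annotation,
               ancient_dna = !config$ancient_dna)

  hg <- NULL; pm <- NA_real_
  if (!is.null(tree)) {
    hg <- assign_haplogroup(pileup, tree)
    pm <- tryCatch(as.numeric(p_mismatch(pileup, tree, hg$best)),
                   error = function(e) NA_real_)
  }

  het <- NULL
  if (config$heteroplasmy)
    het <- detect_heteroplasmy(pileup, consensus, config$maf_threshold,
                               config$min_depth)

  aln <- align_consensus_to_reference(consensus_string(consensus), ref)
  vars <- call_variants(aln)

  ann <- NULL
  if (config$annotation && length(config$annotation_dbs)) {
    db <- do.call(rbind, lapply(config$annotation_dbs, read_annotation_csv))
    ann <- annotate_variants(vars$variants, db)
  }

  dmg <- NULL; frag <- NULL; spec <- NULL
  if (config$ancient_dna) {
    dmg <- damage_profile(reads, ref,
                          filter_policy(config$damage_min_base_quality,
                                        config$min_mapping_quality),
                          K = config$damage_K)
    frag <- fragmentation_summary(reads)
    spec <- substitution_spectrum(reads, ref, policy)
  }

  result <- structure(list(
    summary = stats, pileup = pileup, consensus = consensus,
    haplogroup = hg, p_mismatch = pm, heteroplasmy = het,
    variants = vars, annotated = ann, spectrum = spec, damage = dmg,
    fragmentation = frag, skipped = skipped, ref = ref,
    provenance = list(tool = "mitoprofile",
                      version = as.character(utils::packageVersion("mitoprofile")),
                      config = unclass(config))),
    class = "RunResult")

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_run_outputs(result, config$out_dir)
  result
}

# Write every machine-readable artifact of a run. File names are fixed for
# reproducible downstream tooling.
write_run_outputs <- function(result, dir) {
  write_summary(result$summary, dir)
  write_depth_tsv(result$pileup, file.path(dir, "depth.tsv"))
  write_consensus_fasta(result$consensus, file.path(dir, "consensus.fa"))
  write_consensus_tsv(result$consensus, file.path(dir, "consensus_sites.tsv"))
  if (!is.null(result$haplogroup))
    write_haplogroup_tsv(result$haplogroup, file.path(dir, "haplogroup.tsv"))
  if (!is.null(result$heteroplasmy))
    utils::write.table(result$heteroplasmy,
                       file.path(dir, "heteroplasmy.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$variants$variants, file.path(dir, "variants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(result$annotated))
    utils::write.table(result$annotated,
                       file.path(dir, "variants_annotated.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(result$spectrum)) {
    utils::write.table(
      data.frame(substitution = names(result$spectrum$counts),
                 count = as.integer(result$spectrum$counts),
                 percentage = as.numeric(result$spectrum$percentage)),
      file.path(dir, "substitution_spectrum.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(result$damage))
    write_damage_tsv(result$damage, file.path(dir, "damage.tsv"))
  if (!is.null(result$fragmentation))
    utils::write.table(result$fragmentation$histogram,
                       file.path(dir, "read_lengths.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  run <- list(provenance = result$provenance,
              p_mismatch = if (is.na(result$p_mismatch)) NULL
                           else result$p_mismatch,
              best_haplogroup = if (is.null(result$haplogroup)) NULL
                                else result$haplogroup$best,
              skipped = as.list(result$skipped))
  jsonlite::write_json(run, file.path(dir, "run.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  render_html(result, file.path(dir, "results.html"))
  invisible(dir)
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

html_table <- function(df, max_rows = 50L) {
  if (is.null(df) || nrow(df) == 0L) return("<p><em>no rows</em></p>")
  shown <- utils::head(df, max_rows)
  num <- vapply(shown, is.numeric, logical(1))
  shown[num] <- lapply(shown[num], function(x) signif(x, 6))
  hd <- paste0("<tr>", paste0("<th>", html_escape(names(shown)), "</th>",
                              collapse = ""), "</tr>")
  rows <- apply(shown, 1L, function(r)
    paste0("<tr>", paste0("<td>", html_escape(as.character(r)), "</td>",
                          collapse = ""), "</tr>"))
  note <- if (nrow(df) > max_rows)
    sprintf("<p><em>%d of %d rows shown</em></p>", max_rows, nrow(df)) else ""
  paste0("<table>", hd, paste(rows, collapse = ""), "</table>", note)
}

# Inline SVG polyline chart of one or more series over x = 1..n.
svg_lines <- function(series, width = 640, height = 180, colors = NULL,
                      ylab = "") {
  n <- max(vapply(series, length, integer(1)))
  ymax <- max(1e-9, unlist(series), na.rm = TRUE)
  if (is.null(colors))
    colors <- rep(c("#1f77b4", "#d62728", "#2ca02c", "#999999"),
                  length.out = length(series))
  polys <- mapply(function(y, col) {
    x <- seq_along(y)
    ok <- !is.na(y)
    pts <- paste(sprintf("%.1f,%.1f", (x[ok] - 1) / max(1, n - 1) * (width - 20) + 10,
                         height - 15 - y[ok] / ymax * (height - 30)),
                 collapse = " ")
    sprintf('<polyline fill="none" stroke="%s" stroke-width="1.5" points="%s"/>',
            col, pts)
  }, series, colors)
  legend <- paste(mapply(function(nm, col, i)
    sprintf('<text x="%d" y="12" fill="%s" font-size="10">%s</text>',
            10 + (i - 1) * 90, col, html_escape(nm)),
    names(series), colors, seq_along(series)), collapse = "")
  sprintf('<svg width="%d" height="%d" xmlns="http://www.w3.org/2000/svg"><rect width="100%%" height="100%%" fill="#fcfcfc"/>%s%s<text x="5" y="%d" font-size="10">%s (max %.4g)</text></svg>',
          width, height, paste(polys, collapse = ""), legend, height - 3,
          html_escape(ylab), ymax)
}

#' Render a run result as one self-contained static HTML report
#'
#' A single file with no external assets: summary-statistics table, a depth
#' chart across the genome, the haplogroup panel, heteroplasmy and
#' annotated-variant tables, the base-substitution spectrum and the damage
#' line plots (all chart data is also written as TSV alongside). Sections
#' disabled in the run are marked "not run". The timestamp in the footer
#' is the only non-deterministic content.
#'
#' @param result A [run_profile()] `RunResult`.
#' @param path Output HTML path.
#' @return Invisibly, `path`.
#' @export
render_html <- function(result, path) {
  s <- result$summary
  sec <- function(id, title, body)
    sprintf('<section id="%s"><h2>%s</h2>%s</section>', id, title, body)
  not_run <- "<p><em>not run</em></p>"

  summary_df <- data.frame(
    metric = c("total reads", "mapped reads", "duplicate reads",
               "mean depth", "median depth", "mean read length",
               "mean GC content", "mean mapping quality", "mean base quality",
               paste("breadth", names(s$coverage_breadth))),
    value = c(s$total_reads, s$mapped_reads, s$duplicate_reads,
              round(s$depth$mean, 3), s$depth$median,
              round(s$read_length$mean, 2), round(s$gc_content$mean, 4),
              round(s$mapping_quality$mean, 2), round(s$base_quality$mean, 2),
              round(unname(s$coverage_breadth), 4)))

  hg_body <- if (is.null(result$haplogroup)) not_run else paste0(
    sprintf("<p>Best haplogroup: <strong>%s</strong>; contamination indicator P<sub>mismatch</sub> = %s%%</p>",
            html_escape(result$haplogroup$best),
            if (is.na(result$p_mismatch)) "NA"
            else sprintf("%.3f", result$p_mismatch)),
    html_table(result$haplogroup$ranking, 10L))

  het_body <- if (is.null(result$heteroplasmy)) not_run else
    html_table(result$heteroplasmy[result$heteroplasmy$flagged, , drop = FALSE])

  spec_body <- if (is.null(result$spectrum)) not_run else paste0(
    if (result$spectrum$no_mismatch) "<p><em>no mismatches observed</em></p>" else "",
    html_table(data.frame(substitution = names(result$spectrum$counts),
                          count = as.integer(result$spectrum$counts),
                          percentage = round(as.numeric(result$spectrum$percentage), 3))))

  dmg_body <- if (is.null(result$damage)) not_run else paste0(
    svg_lines(list(`5p C>T` = result$damage$rate_5p[, "C>T"],
                   `5p G>A` = result$damage$rate_5p[, "G>A"]),
              ylab = "rate vs 5' offset"),
    svg_lines(list(`3p G>A` = result$damage$rate_3p[, "G>A"],
                   `3p C>T` = result$damage$rate_3p[, "C>T"]),
              ylab = "rate vs 3' offset"),
    sprintf("<p>Mean aligned read length: %s</p>",
            if (is.null(result$fragmentation) || is.na(result$fragmentation$mean))
              "NA" else sprintf("%.1f", result$fragmentation$mean)))

  depth_body <- svg_lines(list(raw_depth = result$pileup$raw_depth),
                          ylab = "raw depth by position")

  ann_body <- if (is.null(result$annotated)) not_run else
    html_table(result$annotated)

  html <- paste0(
    "<!DOCTYPE html><html><head><meta charset='utf-8'>",
    "<title>mitoprofile report</title>",
    "<style>body{font-family:sans-serif;margin:2em;max-width:900px}",
    "table{border-collapse:collapse}td,th{border:1px solid #ccc;",
    "padding:2px 8px;font-size:13px}h2{border-bottom:1px solid #888}</style>",
    "</head><body><h1>mitoprofile report</h1>",
    sprintf("<p>Reference: %s (%d bp)</p>",
            html_escape(result$ref$name), result$ref$length),
    if (s$no_data) "<p><strong>no data: the alignment contains no mapped reads</strong></p>" else "",
    sec("summary", "Summary statistics", html_table(summary_df)),
    sec("depth", "Depth of coverage", depth_body),
    sec("haplogroup", "Haplogroup assignment", hg_body),
    sec("heteroplasmy", "Heteroplasmic sites", het_body),
    sec("variants", "Consensus variants",
        html_table(result$variants$variants, 100L)),
    sec("annotation", "Variant annotation", ann_body),
    sec("spectrum", "Base-substitution spectrum", spec_body),
    sec("damage", "Ancient-DNA damage", dmg_body),
    sprintf("<footer><p>mitoprofile %s &middot; generated %s</p></footer>",
            result$provenance$version, format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    "</body></html>")
  writeLines(html, path)
  invisible(path)
}
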