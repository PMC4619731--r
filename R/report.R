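#' Write splice events as a junction BED12 track
#'
#' One BED12 record per junction in the two-anchor-block junction dialect
#' used by junction viewers: two fixed-width anchor blocks strictly flank
#' the gap, the score is the read support capped at 1000, and the name is
#' `category:gap_start-gap_end`. All file coordinates are 0-based
#' half-open; the gap itself is recoverable exactly (see
#' [read_junction_bed()]).
#'
#' @param events event `data.frame` with `gap_start`, `gap_end` and
#'   optionally `chrom`, `category`, `support_total`, `strand`.
#' @param path output BED file.
#' @param anchor anchor block width in nt.
#' @return `path`, invisibly.
#' @export
write_junction_bed <- function(events, path, anchor = 8L) {
  ev <- events[order(events$gap_start, events$gap_end), , drop = FALSE]
  n <- nrow(ev)
  if (n == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  chrom <- if ("chrom" %in% names(ev)) ev$chrom else rep(".", n)
  cat_ <- if ("category" %in% names(ev)) ev$category else rep("junction", n)
  supp <- if ("support_total" %in% names(ev)) ev$support_total else rep(0L, n)
  strand <- if ("strand" %in% names(ev)) ev$strand else rep(".", n)
  chrom_start <- ev$gap_start - 1L - anchor
  chrom_end <- ev$gap_end + anchor
  gap_len <- ev$gap_end - ev$gap_start + 1L
  bed <- data.frame(
    chrom = chrom, chromStart = chrom_start, chromEnd = chrom_end,
    name = sprintf("%s:%d-%d", cat_, ev$gap_start, ev$gap_end),
    score = pmin(as.integer(supp), 1000L), strand = strand,
    thickStart = chrom_start, thickEnd = chrom_end, itemRgb = "0,0,0",
    blockCount = 2L, blockSizes = sprintf("%d,%d", anchor, anchor),
    blockStarts = sprintf("0,%d", gap_len + anchor),
    stringsAsFactors = FALSE)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a junction BED12 track back into an event table
#'
#' Inverse of [write_junction_bed()]: the gap is the span between the two
#' anchor blocks.
#'
#' @param path BED file written by [write_junction_bed()].
#' @return `data.frame` with `chrom`, `gap_start`, `gap_end`, `category`,
#'   `support_total`, `strand`.
#' @export
read_junction_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  if (length(gr) == 0L)
    return(data.frame(chrom = character(), gap_start = integer(),
                      gap_end = integer(), category = character(),
                      support_total = integer(), strand = character()))
  blocks <- gr$blocks
  if (any(lengths(blocks) != 2L))
    stop("not a two-anchor junction BED: ", path)
  abs_blocks <- IRanges::shift(blocks, GenomicRanges::start(gr) - 1L)
  gap_start <- vapply(abs_blocks, function(b) IRanges::end(b)[1] + 1L, 0L)
  gap_end <- vapply(abs_blocks, function(b) IRanges::start(b)[2] - 1L, 0L)
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             gap_start = gap_start, gap_end = gap_end,
             category = sub(":.*$", "", gr$name),
             support_total = as.integer(gr$score),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Run the full splice-event pipeline
#'
#' Loads region-restricted primary alignments for every sample, merges them
#' within conditions and overall, extracts and aggregates alignment gaps,
#' filters by superset read support, classifies events against the
#' canonical model, groups them into loci, profiles per-feature coverage,
#' and writes a deterministic output bundle: `events.tsv`, `junctions.bed`,
#' `coverage.tsv`, `run_log.txt` (and `coverage.png` when `plot = TRUE`).
#' Any stage failure aborts with the stage name and removes partial
#' outputs.
#'
#' @param annotation annotation path (GTF/BED12) or a [gene_model()].
#' @param transcript_id canonical transcript (ignored when `annotation` is
#'   already a model).
#' @param sheet sample sheet path or `data.frame` (see
#'   [read_sample_sheet()]).
#' @param out_dir output directory.
#' @param region region string or `GRanges`; default: the model span padded
#'   by 1 kb.
#' @param min_gap minimum alignment gap in nt to call a splicing event.
#' @param min_support minimum superset read support to report an event.
#' @param anchor junction BED anchor width.
#' @param plot also render the coverage figure.
#' @return invisibly, a list with `model`, `events` (classified + locus
#'   ids), `loci`, `coverage`, `groups`, and `files`.
#' @export
run_pipeline <- function(annotation, transcript_id = NULL, sheet, out_dir,
                         region = NULL, min_gap = 10L, min_support = 10L,
                         anchor = 8L, plot = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  made <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(made)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  model <- stage("gene_model", {
    if (inherits(annotation, "gene_model")) annotation
    else read_gene_model(annotation, transcript_id)
  })
  sheet <- stage("sample_sheet", {
    if (is.character(sheet)) read_sample_sheet(sheet)
    else validate_sample_sheet(sheet)
  })
  if (is.null(region))
    region <- GenomicRanges::GRanges(
      model$chrom,
      IRanges::IRanges(max(1L, min(start(model$exons)) - 1000L),
                       max(end(model$exons)) + 1000L))
  groups <- stage("alignment_io", merge_groups(sheet, region))
  events_all <- stage("junction_extract", aggregate_junctions(groups, min_gap))
  events <- stage("junction_extract", filter_support(events_all, min_support))
  events <- stage("as_classify", classify_events(events, model))
  grouped <- stage("as_classify", group_loci(events))
  events <- grouped$events
  feats <- derive_features(model)
  counts <- stage("coverage_profile",
                  count_feature_bases(groups, feats,
                                      conditions = unique(sheet$condition)))
  coverage <- stage("coverage_profile", summarize_coverage(counts, sheet))

  f_events <- file.path(out_dir, "events.tsv")
  f_bed <- file.path(out_dir, "junctions.bed")
  f_cov <- file.path(out_dir, "coverage.tsv")
  f_log <- file.path(out_dir, "run_log.txt")
  made <- c(f_events, f_bed, f_cov, f_log)
  stage("report", {
    write_junction_tsv(events, f_events, strand = model$strand)
    write_junction_bed(events, f_bed, anchor = anchor)
    write_coverage_tsv(coverage, f_cov)
  })
  files <- c(events = f_events, bed = f_bed, coverage = f_cov, log = f_log)
  if (plot) {
    f_png <- file.path(out_dir, "coverage.png")
    made <- c(made, f_png)
    stage("report", ggplot2::ggsave(f_png, plot_coverage(coverage),
                                    width = 10, height = 5, dpi = 150))
    files <- c(files, figure = f_png)
  }
  stage("report", {
    rg <- parse_region(region)
    cond_counts <- vapply(groups$by_condition, function(s) nrow(s$reads), 0L)
    log <- c(
      sprintf("spliceGaps %s", as.character(utils::packageVersion("spliceGaps"))),
      sprintf("model: %s (%s) %s:%d-%d [%s], %d exons",
              model$gene_id, model$transcript_id, model$chrom,
              min(start(model$exons)), max(end(model$exons)), model$strand,
              length(model$exons)),
      sprintf("region: %s:%d-%d", as.character(GenomicRanges::seqnames(rg)),
              GenomicRanges::start(rg), GenomicRanges::end(rg)),
      sprintf("min_gap: %d", min_gap),
      sprintf("min_support: %d", min_support),
      sprintf("records: superset=%d %s", nrow(groups$superset$reads),
              paste(sprintf("%s=%d", names(cond_counts), cond_counts),
                    collapse = " ")),
      sprintf("events: aggregated=%d supported=%d alternative=%d loci=%d",
              nrow(events_all), nrow(events), count_alternative(events),
              nrow(grouped$loci)),
      "input checksums:",
      sprintf("  %s  %s", tools::md5sum(sheet$path), sheet$path))
    writeLines(log, f_log)
  })
  invisible(list(model = model, events = events, loci = grouped$loci,
                 coverage = coverage, groups = groups, files = files))
}
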