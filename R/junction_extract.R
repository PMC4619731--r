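#' Extract alignment gaps (candidate splice junctions) from one record
#'
#' A splicing event is a contiguous gap of at least `min_gap` bases between
#' consecutive reference-aligned blocks of one read alignment (the default,
#' 10, reports gaps greater than 9 bases). Coordinates are the first and
#' last gapped base, 1-based inclusive.
#'
#' @param blocks the record's aligned blocks: two-column matrix/data.frame of
#'   `start`,`end` (1-based inclusive, sorted, non-overlapping) or an
#'   `IRanges`.
#' @param min_gap minimum gap length in nt.
#' @return `data.frame` with columns `gap_start`, `gap_end` (possibly 0
#'   rows; a single-block record yields none).
#' @examples
#' extract_gaps(cbind(1001, 1050))                     # no gap
#' extract_gaps(rbind(c(1001, 1050), c(2051, 2101)))   # gap 1051-2050
#' @export
extract_gaps <- function(blocks, min_gap = 10L) {
  if (inherits(blocks, "IRanges")) {
    s <- IRanges::start(blocks); e <- IRanges::end(blocks)
  } else {
    blocks <- as.matrix(blocks)
    s <- as.integer(blocks[, 1]); e <- as.integer(blocks[, 2])
  }
  if (length(s) < 1L) stop("record has no aligned blocks")
  o <- order(s)
  s <- s[o]; e <- e[o]
  if (length(s) == 1L)
    return(data.frame(gap_start = integer(), gap_end = integer()))
  gs <- e[-length(e)] + 1L
  ge <- s[-1] - 1L
  keep <- (ge - gs + 1L) >= min_gap
  data.frame(gap_start = gs[keep], gap_end = ge[keep])
}

#' Aggregate alignment gaps into read-supported splice events
#'
#' Every inter-block gap of length `>= min_gap` in every alignment record is
#' a (read, gap) incidence; identical gaps (exact `gap_start`, `gap_end`
#' match) are aggregated into one splice event whose support is the number
#' of read alignments containing that gap. Each mate of a pair counts
#' independently. Per-condition supports come from record provenance.
#'
#' @param aln an `alignment_set` or `alignment_groups` (the superset is
#'   used; per-condition supports always come from record provenance).
#' @param min_gap minimum gap length in nt (default 10).
#' @return `data.frame` of events sorted by (`gap_start`, `gap_end`):
#'   `chrom`, `gap_start`, `gap_end`, `support_total`, and one
#'   `support.<condition>` column per condition present.
#' @export
aggregate_junctions <- function(aln, min_gap = 10L) {
  if (inherits(aln, "alignment_groups")) aln <- aln$superset
  stopifnot(inherits(aln, "alignment_set"))
  conds <- sort(unique(aln$reads$condition))
  empty <- data.frame(chrom = character(), gap_start = integer(),
                      gap_end = integer(), support_total = integer())
  for (cc in conds) empty[[paste0("support.", cc)]] <- integer()
  b <- aln$blocks
  if (nrow(b) == 0L) return(empty)
  b <- data.table::copy(b)
  data.table::setorder(b, read_uid, start)
  nxt_start <- data.table::shift(b$start, type = "lead")
  same_read <- data.table::shift(b$read_uid, type = "lead") == b$read_uid
  gaps <- data.table::data.table(
    read_uid = b$read_uid,
    gap_start = b$end + 1L,
    gap_end = nxt_start - 1L
  )[same_read %in% TRUE][gap_end - gap_start + 1L >= min_gap]
  if (nrow(gaps) == 0L) return(empty)
  gaps <- merge(gaps, aln$reads[, c("read_uid", "condition")],
                by = "read_uid", sort = FALSE)
  counts <- gaps[, .N, by = .(gap_start, gap_end, condition)]
  wide <- data.table::dcast(counts, gap_start + gap_end ~ condition,
                            value.var = "N", fill = 0L)
  cond_cols <- setdiff(names(wide), c("gap_start", "gap_end"))
  wide[, support_total := rowSums(.SD), .SDcols = cond_cols]
  data.table::setnames(wide, cond_cols, paste0("support.", cond_cols))
  data.table::setorder(wide, gap_start, gap_end)
  out <- data.frame(chrom = aln$chrom, as.data.frame(wide),
                    stringsAsFactors = FALSE, check.names = FALSE)
  cols <- c("chrom", "gap_start", "gap_end", "support_total",
            paste0("support.", sort(cond_cols)))
  out[, cols]
}

#' Filter splice events by superset read support
#'
#' Retains events with `support_total >= min_support` (the default, 10,
#' reports events supported by at least 10 reads across all conditions).
#' Filtering is on superset support, never per-condition.
#'
#' @param events event `data.frame` from [aggregate_junctions()].
#' @param min_support minimum superset read support (must be >= 1).
#' @return the retained events, same columns and ordering.
#' @export
filter_support <- function(events, min_support = 10L) {
  if (min_support < 1L) stop("min_support must be >= 1")
  events[events$support_total >= min_support, , drop = FALSE]
}

#' Write the junction table as TSV
#'
#' @param events event `data.frame` (optionally classified/grouped).
#' @param path output file.
#' @param strand strand to report if the events carry none.
#' @return `path`, invisibly.
#' @export
write_junction_tsv <- function(events, path, strand = "*") {
  ev <- events
  if (!"strand" %in% names(ev)) ev$strand <- strand
  lead <- intersect(c("locus_id", "chrom", "gap_start", "gap_end", "strand",
                      "category", "novel_end_context", "skipped_exons",
                      "support_total"), names(ev))
  ev <- ev[, c(lead, setdiff(names(ev), lead)), drop = FALSE]
  utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
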