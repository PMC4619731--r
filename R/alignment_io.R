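#' Parse a genomic region string
#'
#' Accepts `"chr4:3,074,681-3,243,960"` style strings (commas optional) or a
#' `GRanges` of length 1, and returns a `GRanges`.
#'
#' @param region region string or `GRanges`.
#' @return `GRanges` of length 1.
#' @export
parse_region <- function(region) {
  if (inherits(region, "GRanges")) {
    if (length(region) != 1L) stop("region must be a single interval")
    return(region)
  }
  m <- regmatches(region, regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", region))[[1]]
  if (length(m) != 4L) stop("cannot parse region '", region, "'; expected chrom:start-end")
  s <- as.integer(gsub(",", "", m[3])); e <- as.integer(gsub(",", "", m[4]))
  if (e < s) stop("region end precedes start: ", region)
  GenomicRanges::GRanges(m[2], IRanges::IRanges(s, e))
}

#' Read a sample sheet
#'
#' Tab-separated file with a header and columns `sample_id`, `path`,
#' `condition`. Relative alignment paths are resolved against the sheet's
#' directory. Sample ids must be unique and every path must exist.
#'
#' @param path sample sheet TSV.
#' @return `data.frame` with columns `sample_id`, `path`, `condition`.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  sheet <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, comment.char = "")
  validate_sample_sheet(sheet, dir = dirname(path))
}

#' @rdname read_sample_sheet
#' @param sheet in-memory sample sheet `data.frame`.
#' @param dir directory against which relative paths are resolved.
#' @export
validate_sample_sheet <- function(sheet, dir = ".") {
  need <- c("sample_id", "path", "condition")
  if (!all(need %in% names(sheet)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  if (nrow(sheet) == 0L) return(sheet[, need])
  if (anyDuplicated(sheet$sample_id))
    stop("duplicate sample_id in sample sheet: ",
         paste(unique(sheet$sample_id[duplicated(sheet$sample_id)]), collapse = ", "))
  resolved <- ifelse(file.exists(sheet$path), sheet$path,
                     file.path(dir, sheet$path))
  missing <- !file.exists(resolved)
  if (any(missing))
    stop("alignment file(s) not found: ", paste(sheet$path[missing], collapse = ", "))
  sheet$path <- resolved
  sheet[, need]
}

# Return an indexed, coordinate-sorted BAM for a SAM/BAM input.
# SAM inputs are converted (sorted + indexed) into tempdir().
.as_indexed_bam <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "sam") {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = TRUE)
    return(bam)
  }
  bai <- c(paste0(path, ".bai"), sub("\\.bam$", ".bai", path))
  if (!any(file.exists(bai))) {
    stop("BAM file is not indexed: ", path,
         "\nCreate an index first (e.g. 'samtools index ", path,
         "' or Rsamtools::indexBam) to allow region queries.")
  }
  path
}

#' Load region-restricted primary alignments from one SAM/BAM file
#'
#' Streams mapped, primary (non-secondary, non-supplementary) alignments
#' overlapping `region`, reduced to their reference-aligned blocks. Blocks
#' are the maximal runs of aligned bases (CIGAR `M`/`=`/`X`); both skips
#' (`N`) and deletions (`D`) separate blocks, and adjacent gap operations
#' merge into one contiguous gap. Reads partially overlapping the region
#' boundary are kept whole.
#'
#' @param path SAM or BAM file. SAM inputs are converted and indexed into a
#'   temporary location; unindexed BAM inputs are an error.
#' @param region region string or `GRanges` (see [parse_region()]).
#' @param sample_id,condition provenance attached to every record.
#' @param min_mapq minimum mapping quality (default 0: no filter).
#' @return An `alignment_set`: list with `reads` (one row per alignment:
#'   `read_uid`, `read_id`, `sample_id`, `condition`), `blocks` (one row per
#'   aligned block: `read_uid`, `start`, `end`, 1-based inclusive), and
#'   `chrom`.
#' @export
load_region <- function(path, region, sample_id = "sample", condition = "all",
                        min_mapq = 0L) {
  region <- parse_region(region)
  bam <- .as_indexed_bam(path)
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  chrom <- as.character(GenomicRanges::seqnames(region))
  if (!chrom %in% names(hdr))
    stop("region chromosome '", chrom, "' absent from alignment header of ", path)
  param <- Rsamtools::ScanBamParam(
    which = region,
    what = c("qname", "flag", "mapq"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE),
    mapqFilter = as.integer(min_mapq)
  )
  g <- GenomicAlignments::readGAlignments(bam, param = param)
  n <- length(g)
  if (n == 0L) {
    return(.alignment_set(
      reads = data.table::data.table(read_uid = integer(), read_id = character(),
                                     sample_id = character(), condition = character()),
      blocks = data.table::data.table(read_uid = integer(), start = integer(),
                                      end = integer()),
      chrom = chrom))
  }
  rng <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    GenomicAlignments::cigar(g), pos = GenomicRanges::start(g),
    ops = c("M", "=", "X"), reduce.ranges = TRUE)
  nb <- lengths(rng)
  flat <- unlist(rng, use.names = FALSE)
  reads <- data.table::data.table(
    read_uid = seq_len(n),
    read_id = S4Vectors::mcols(g)$qname,
    sample_id = sample_id, condition = condition)
  blocks <- data.table::data.table(
    read_uid = rep.int(seq_len(n), nb),
    start = IRanges::start(flat), end = IRanges::end(flat))
  .alignment_set(reads, blocks, chrom)
}

.alignment_set <- function(reads, blocks, chrom) {
  structure(list(reads = reads, blocks = blocks, chrom = chrom),
            class = "alignment_set")
}

#' @export
print.alignment_set <- function(x, ...) {
  cat(sprintf("alignment_set: %d records (%d blocks) on %s; samples: %s\n",
              nrow(x$reads), nrow(x$blocks), x$chrom,
              paste(unique(x$reads$sample_id), collapse = ", ")))
  invisible(x)
}

#' Number of alignment records in an alignment set
#' @param x an `alignment_set`.
#' @return integer count of alignment records.
#' @export
n_records <- function(x) nrow(x$reads)

# concatenate alignment sets, re-keying read_uids to stay unique
.bind_alignment_sets <- function(sets) {
  sets <- Filter(Negate(is.null), sets)
  chroms <- unique(vapply(sets, function(s) s$chrom, ""))
  if (length(chroms) > 1L)
    stop("cannot merge alignment sets from different chromosomes: ",
         paste(chroms, collapse = ", "))
  offset <- 0L
  reads <- vector("list", length(sets)); blocks <- vector("list", length(sets))
  for (i in seq_along(sets)) {
    r <- data.table::copy(sets[[i]]$reads); b <- data.table::copy(sets[[i]]$blocks)
    r[, read_uid := read_uid + offset]
    b[, read_uid := read_uid + offset]
    offset <- offset + nrow(sets[[i]]$reads)
    reads[[i]] <- r; blocks[[i]] <- b
  }
  .alignment_set(data.table::rbindlist(reads), data.table::rbindlist(blocks),
                 if (length(chroms)) chroms else NA_character_)
}

#' Load and merge samples by condition and overall ("superset")
#'
#' Loads every sample in the sheet restricted to `region` and builds merged
#' collections within each condition plus the all-condition superset, with
#' per-record sample/condition provenance preserved. The same file listed
#' under two sample ids is counted twice (no deduplication).
#'
#' @param sheet sample sheet `data.frame` (see [read_sample_sheet()]).
#' @param region region string or `GRanges`.
#' @param min_mapq minimum mapping quality passed to [load_region()].
#' @return An `alignment_groups` object: list with `superset`
#'   (an `alignment_set` over all samples), `by_condition` (named list of
#'   `alignment_set`), and `sheet`.
#' @export
merge_groups <- function(sheet, region, min_mapq = 0L) {
  sheet <- validate_sample_sheet(sheet)
  if (nrow(sheet) == 0L) {
    empty <- .alignment_set(
      reads = data.table::data.table(read_uid = integer(), read_id = character(),
                                     sample_id = character(), condition = character()),
      blocks = data.table::data.table(read_uid = integer(), start = integer(),
                                      end = integer()),
      chrom = NA_character_)
    return(structure(list(superset = empty, by_condition = list(), sheet = sheet),
                     class = "alignment_groups"))
  }
  sets <- lapply(seq_len(nrow(sheet)), function(i)
    load_region(sheet$path[i], region, sheet$sample_id[i], sheet$condition[i],
                min_mapq = min_mapq))
  superset <- .bind_alignment_sets(sets)
  conds <- unique(sheet$condition)
  by_condition <- lapply(conds, function(cc)
    .bind_alignment_sets(sets[sheet$condition == cc]))
  names(by_condition) <- conds
  structure(list(superset = superset, by_condition = by_condition, sheet = sheet),
            class = "alignment_groups")
}

#' @export
print.alignment_groups <- function(x, ...) {
  cat(sprintf("alignment_groups: superset %d records; conditions: %s\n",
              nrow(x$superset$reads),
              paste(sprintf("%s=%d", names(x$by_condition),
                            vapply(x$by_condition, function(s) nrow(s$reads), 0L)),
                    collapse = ", ")))
  invisible(x)
}
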