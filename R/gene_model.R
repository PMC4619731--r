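#' Construct a canonical gene model
#'
#' A gene model is a single canonical transcript: an ordered set of exons on
#' one chromosome and strand. Introns, the exon/intron feature ladder and the
#' canonical junction set are all derived from it.
#'
#' @param exons two-column matrix/data.frame of exon `start`,`end` (1-based
#'   inclusive) or an [IRanges::IRanges] object. Exons must be non-overlapping
#'   and are sorted by start.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param gene_id,transcript_id identifiers carried through to outputs.
#' @return An object of class `gene_model`.
#' @examples
#' gm <- gene_model(cbind(c(101, 301, 501), c(200, 400, 600)), "chr1", "+",
#'                  "G1", "G1-001")
#' canonical_junctions(gm)
#' @export
gene_model <- function(exons, chrom, strand, gene_id = "gene", transcript_id = "tx") {
  if (inherits(exons, "IRanges")) {
    ex <- exons
  } else {
    exons <- as.matrix(exons)
    if (ncol(exons) != 2L) stop("'exons' must have two columns (start, end)")
    ex <- IRanges::IRanges(start = as.integer(exons[, 1]), end = as.integer(exons[, 2]))
  }
  ex <- sort(ex)
  if (length(ex) < 2L)
    stop("gene model for transcript '", transcript_id,
         "' has fewer than 2 exons; no junctions exist")
  if (any(width(ex) < 1L)) stop("exon with non-positive width")
  if (length(ex) > 1L && any(start(ex)[-1] <= end(ex)[-length(ex)]))
    stop("exons overlap or abut; a canonical transcript must have introns of length >= 1")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  structure(
    list(gene_id = gene_id, transcript_id = transcript_id,
         chrom = as.character(chrom), strand = strand, exons = ex),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model: %s (%s) %s:%d-%d [%s], %d exons\n",
              x$gene_id, x$transcript_id, x$chrom,
              min(start(x$exons)), max(end(x$exons)), x$strand,
              length(x$exons)))
  invisible(x)
}

#' Read a gene model from GTF (GENCODE dialect) or BED12
#'
#' For GTF, exon records of the named transcript are used (attributes must be
#' GENCODE-style quoted key-value pairs, which is what [rtracklayer::import]
#' parses). For BED12, the record whose `name` equals `transcript_id` is used
#' and exons are taken from its blocks.
#'
#' @param path annotation file; format inferred from extension unless given.
#' @param transcript_id canonical transcript to extract (e.g. `"HTT-001"`).
#' @param gene_id optional gene id; for GTF defaults to the transcript's
#'   `gene_id` attribute, for BED12 to the record name.
#' @param format `"auto"`, `"gtf"` or `"bed"`.
#' @return A [gene_model()].
#' @export
read_gene_model <- function(path, transcript_id, gene_id = NULL,
                            format = c("auto", "gtf", "bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- if (ext %in% c("gtf", "gff")) "gtf" else if (ext %in% c("bed", "bed12")) "bed"
              else stop("cannot infer annotation format from extension '", ext, "'")
  }
  if (format == "gtf") .read_model_gtf(path, transcript_id, gene_id)
  else .read_model_bed12(path, transcript_id, gene_id)
}

.check_gtf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf < 8L)) {
    bad <- which(body)[which(nf < 8L)[1]]
    stop("malformed GTF line ", bad, " in ", path, " (expected >= 8 tab-separated fields)")
  }
  invisible(TRUE)
}

.read_model_gtf <- function(path, transcript_id, gene_id) {
  .check_gtf_lines(path)
  gr <- rtracklayer::import(path, format = "gtf")
  if (!"transcript_id" %in% names(S4Vectors::mcols(gr)))
    stop("GTF has no transcript_id attribute (GENCODE dialect required): ", path)
  ex <- gr[gr$type == "exon" & !is.na(gr$transcript_id) & gr$transcript_id == transcript_id]
  if (length(ex) == 0L)
    stop("transcript '", transcript_id, "' not found in ", path)
  if (length(ex) == 1L)
    stop("transcript '", transcript_id, "' has a single exon; no junctions exist")
  chrom <- unique(as.character(GenomicRanges::seqnames(ex)))
  if (length(chrom) != 1L)
    stop("transcript '", transcript_id, "' spans multiple chromosomes")
  strand <- unique(as.character(GenomicRanges::strand(ex)))
  if (!strand %in% c("+", "-"))
    stop("transcript '", transcript_id, "' has no defined strand")
  gid <- gene_id
  if (is.null(gid))
    gid <- if ("gene_id" %in% names(S4Vectors::mcols(ex))) ex$gene_id[1] else transcript_id
  gene_model(IRanges::ranges(ex), chrom, strand, gid, transcript_id)
}

.read_model_bed12 <- function(path, transcript_id, gene_id) {
  gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                 error = function(e) stop("malformed BED file ", path, ": ",
                                          conditionMessage(e)))
  if (!"blocks" %in% names(S4Vectors::mcols(gr)))
    stop("BED file has no block structure (BED12 required): ", path)
  hit <- which(gr$name == transcript_id)
  if (length(hit) == 0L) stop("transcript '", transcript_id, "' not found in ", path)
  rec <- gr[hit[1]]
  blocks <- rec$blocks[[1]]  # relative to chromStart, 1-based within record
  if (length(blocks) < 2L)
    stop("transcript '", transcript_id, "' has a single exon; no junctions exist")
  ex <- IRanges::shift(blocks, start(rec) - 1L)
  gene_model(ex, as.character(GenomicRanges::seqnames(rec)),
             as.character(GenomicRanges::strand(rec)),
             if (is.null(gene_id)) transcript_id else gene_id, transcript_id)
}

#' Derive the exon/intron feature ladder
#'
#' Returns the `2E - 1` alternating exon and intron features of an `E`-exon
#' model, in transcription order, with indices `1..E` (exons) and `1..E-1`
#' (introns). On the minus strand exon 1 is the genomically rightmost exon.
#'
#' @param model a [gene_model()].
#' @return `data.frame` with columns `kind`, `index`, `chrom`, `start`,
#'   `end`, `length`, `strand`; rows in transcription order.
#' @export
derive_features <- function(model) {
  stopifnot(inherits(model, "gene_model"))
  ex <- model$exons
  E <- length(ex)
  ints <- IRanges::IRanges(start = end(ex)[-E] + 1L, end = start(ex)[-1] - 1L)
  # genomic order indices -> transcription order indices
  if (model$strand == "+") {
    ex_idx <- seq_len(E); in_idx <- seq_len(E - 1L)
  } else {
    ex_idx <- rev(seq_len(E)); in_idx <- rev(seq_len(E - 1L))
  }
  feats <- data.frame(
    kind   = c(rep("exon", E), rep("intron", E - 1L)),
    index  = c(ex_idx, in_idx),
    chrom  = model$chrom,
    start  = c(start(ex), start(ints)),
    end    = c(end(ex), end(ints)),
    stringsAsFactors = FALSE
  )
  feats$length <- feats$end - feats$start + 1L
  feats$strand <- model$strand
  # transcription order: genomic order on +, reversed on -
  feats <- feats[order(feats$start), , drop = FALSE]
  if (model$strand == "-") feats <- feats[rev(seq_len(nrow(feats))), , drop = FALSE]
  rownames(feats) <- NULL
  feats
}

#' Canonical junction set of a gene model
#'
#' One junction per intron. `gap_start`/`gap_end` are the first and last
#' intronic bases, 1-based inclusive.
#'
#' @param model a [gene_model()].
#' @return `data.frame` with columns `chrom`, `gap_start`, `gap_end`,
#'   `strand`, `intron_index` (transcription order), sorted by `gap_start`.
#' @export
canonical_junctions <- function(model) {
  stopifnot(inherits(model, "gene_model"))
  ex <- model$exons
  E <- length(ex)
  gs <- end(ex)[-E] + 1L
  ge <- start(ex)[-1] - 1L
  idx <- if (model$strand == "+") seq_len(E - 1L) else rev(seq_len(E - 1L))
  data.frame(chrom = model$chrom, gap_start = gs, gap_end = ge,
             strand = model$strand, intron_index = idx,
             stringsAsFactors = FALSE)
}

#' Build a surrogate gene model from a canonical junction set
#'
#' When only the canonical splice junctions of a locus are known (for example
#' a published junction table rather than a full annotation), a reference
#' model can be induced: junction gaps become introns and the spans between
#' consecutive gaps (plus terminal flanks) become exons. Exons inferred this
#' way carry no information about true exon boundaries beyond the splice
#' sites themselves.
#'
#' @param junctions data.frame with `gap_start`, `gap_end` (1-based
#'   inclusive), non-overlapping.
#' @param chrom,strand placement of the model.
#' @param flank width of the terminal pseudo-exons beyond the outermost
#'   junctions.
#' @inheritParams gene_model
#' @return A [gene_model()] whose canonical junctions equal `junctions`.
#' @export
model_from_junctions <- function(junctions, chrom, strand = "+", flank = 100L,
                                 gene_id = "induced", transcript_id = "induced-001") {
  j <- junctions[order(junctions$gap_start), , drop = FALSE]
  if (any(j$gap_start[-1] <= j$gap_end[-nrow(j)]))
    stop("canonical junctions overlap; cannot induce a single transcript model")
  starts <- c(min(j$gap_start) - flank, j$gap_end + 1L)
  ends   <- c(j$gap_start - 1L, max(j$gap_end) + flank)
  gene_model(cbind(starts, ends), chrom, strand, gene_id, transcript_id)
}

#' Write a gene model as BED12
#'
#' @param model a [gene_model()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_model_bed <- function(model, path) {
  ex <- model$exons
  gr <- GenomicRanges::GRanges(
    model$chrom,
    IRanges::IRanges(min(start(ex)), max(end(ex))),
    strand = model$strand,
    name = model$transcript_id, score = 0L,
    thick = IRanges::IRanges(min(start(ex)), max(end(ex))),
    blocks = IRanges::IRangesList(IRanges::shift(ex, 1L - min(start(ex))))
  )
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}
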