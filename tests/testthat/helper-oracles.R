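# Independent brute-force oracles and tiny fixture builders used across tests.

# Per-position gap oracle: enumerate every reference position covered by the
# alignment blocks and report maximal uncovered runs (between covered
# positions) of length >= min_gap. Deliberately naive.
oracle_gaps <- function(blocks, min_gap = 10L) {
  blocks <- as.matrix(blocks)
  covered <- sort(unique(unlist(
    lapply(seq_len(nrow(blocks)), function(i) blocks[i, 1]:blocks[i, 2]))))
  if (length(covered) < 2L)
    return(data.frame(gap_start = integer(), gap_end = integer()))
  all_pos <- min(covered):max(covered)
  un <- setdiff(all_pos, covered)
  if (length(un) == 0L)
    return(data.frame(gap_start = integer(), gap_end = integer()))
  run_id <- cumsum(c(1L, diff(un) != 1L))
  runs <- do.call(rbind, lapply(split(un, run_id), range))
  keep <- (runs[, 2] - runs[, 1] + 1L) >= min_gap
  out <- data.frame(gap_start = as.integer(runs[keep, 1]),
                    gap_end = as.integer(runs[keep, 2]))
  out <- out[order(out$gap_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Per-base coverage oracle: tally every covered position into the feature
# containing it; returns named vector in the row order of `features`.
oracle_feature_bases <- function(blocks, features) {
  pos <- unlist(lapply(seq_len(nrow(blocks)), function(i)
    blocks[i, 1]:blocks[i, 2]))
  vapply(seq_len(nrow(features)), function(k)
    sum(pos >= features$start[k] & pos <= features$end[k]), 0)
}

# CIGAR walker: reference positions covered by aligned (M/=/X) ops.
oracle_cigar_covered <- function(cigar, pos) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  n <- as.integer(sub("[A-Z=]$", "", ops))
  op <- sub("^[0-9]+", "", ops)
  covered <- integer(0)
  ref <- pos
  for (i in seq_along(op)) {
    if (op[i] %in% c("M", "=", "X")) {
      covered <- c(covered, ref:(ref + n[i] - 1L))
      ref <- ref + n[i]
    } else if (op[i] %in% c("D", "N")) {
      ref <- ref + n[i]
    } # I, S, H, P: no reference advance
  }
  covered
}

# random spliced-alignment block structures (sorted, gaps >= 1)
random_blocks <- function(max_blocks = 4L, max_block = 80L, max_gap = 60L,
                          origin = 1000L) {
  nb <- sample.int(max_blocks, 1L)
  widths <- sample.int(max_block, nb, replace = TRUE)
  gaps <- if (nb > 1L) sample.int(max_gap, nb - 1L, replace = TRUE) else integer(0)
  starts <- origin + cumsum(c(0L, widths[-nb] + gaps))
  cbind(starts, starts + widths - 1L)
}

# minimal SAM writer for hand-built records
write_sam <- function(path, records, chrom = "chrT", chrom_len = 100000L) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", chrom, chrom_len))
  records <- records[order(records$pos), , drop = FALSE]
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*",
                   records$qname, records$flag, chrom, records$pos,
                   if (!is.null(records$mapq)) records$mapq else 60L,
                   records$cigar)
  writeLines(c(hdr, lines), path)
  path
}

sam_record <- function(qname, pos, cigar, flag = 0L, mapq = 60L) {
  data.frame(qname = qname, flag = flag, pos = pos, cigar = cigar,
             mapq = mapq, stringsAsFactors = FALSE)
}

# three-exon toy model used across tests (1-based exons 101-200/301-400/501-600)
three_exon_model <- function(strand = "+") {
  gene_model(cbind(c(101L, 301L, 501L), c(200L, 400L, 600L)), "chrT", strand,
             "G1", "G1-001")
}

# build an alignment_set directly from blocks + provenance (bypasses SAM I/O)
make_alignment_set <- function(block_list, conditions, chrom = "chrT",
                               sample_ids = NULL) {
  n <- length(block_list)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(n))
  reads <- data.table::data.table(
    read_uid = seq_len(n), read_id = paste0("r", seq_len(n)),
    sample_id = sample_ids, condition = conditions)
  blocks <- data.table::rbindlist(lapply(seq_len(n), function(i) {
    b <- as.matrix(block_list[[i]])
    data.table::data.table(read_uid = i, start = as.integer(b[, 1]),
                           end = as.integer(b[, 2]))
  }))
  spliceGaps:::.alignment_set(reads, blocks, chrom)
}
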