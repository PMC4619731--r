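#' Count aligned bases per feature and condition
#'
#' Every reference-aligned base of every record is assigned to the unique
#' feature (exon or intron) containing it; gapped (skipped/deleted)
#' positions contribute nothing. Bases falling outside the feature span are
#' excluded from feature totals but reported in an `"outside"` diagnostic
#' attribute.
#'
#' @param aln an `alignment_set` or `alignment_groups` (superset used;
#'   conditions come from record provenance).
#' @param features feature `data.frame` from [derive_features()]
#'   (non-overlapping; checked).
#' @param conditions conditions to report; defaults to those present in
#'   `aln`. Conditions without records get zero counts.
#' @return long `data.frame`: one row per (feature, condition) with columns
#'   `kind`, `index`, `chrom`, `start`, `end`, `length`, `condition`,
#'   `bases`; rows in transcription order. Attribute `outside` holds
#'   per-condition base counts outside the feature span.
#' @export
count_feature_bases <- function(aln, features, conditions = NULL) {
  if (inherits(aln, "alignment_groups")) aln <- aln$superset
  stopifnot(inherits(aln, "alignment_set"))
  fo <- features[order(features$start), , drop = FALSE]
  if (nrow(fo) > 1L && any(fo$start[-1] <= fo$end[-nrow(fo)]))
    stop("features overlap; cannot assign bases uniquely")
  conds <- sort(union(unique(aln$reads$condition), conditions))
  feat_rng <- IRanges::IRanges(features$start, features$end)
  out <- vector("list", length(conds))
  outside <- stats::setNames(numeric(length(conds)), conds)
  for (ci in seq_along(conds)) {
    uids <- aln$reads$read_uid[aln$reads$condition == conds[ci]]
    b <- aln$blocks[aln$blocks$read_uid %in% uids, ]
    if (nrow(b) == 0L) {
      bases <- rep(0, nrow(features))
      total <- 0
    } else {
      cvg <- IRanges::coverage(IRanges::IRanges(b$start, b$end),
                               width = max(b$end, features$end))
      bases <- as.numeric(IRanges::viewSums(IRanges::Views(cvg, feat_rng)))
      total <- sum(as.numeric(b$end - b$start + 1L))
    }
    out[[ci]] <- data.frame(features[, c("kind", "index", "chrom", "start",
                                         "end", "length")],
                            condition = conds[ci], bases = bases,
                            row.names = NULL)
    outside[ci] <- total - sum(bases)
  }
  res <- do.call(rbind, out)
  # transcription order within condition blocks -> interleave by feature order
  res <- res[order(match(paste(res$kind, res$index),
                         paste(features$kind, features$index)),
                   res$condition), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "outside") <- outside
  res
}

#' Average per-sample feature coverage by condition
#'
#' Applies the two-step normalization: aligned bases are divided by the
#' feature length (average read coverage within the condition) and then by
#' the number of samples in the condition, giving the average coverage per
#' feature per sample.
#'
#' @param counts output of [count_feature_bases()].
#' @param sheet sample sheet `data.frame` (gives per-condition sample
#'   counts).
#' @return `counts` with columns `n_samples` and `mean_coverage` appended;
#'   deterministic ordering by feature then condition.
#' @export
summarize_coverage <- function(counts, sheet) {
  n_by_cond <- table(sheet$condition)
  missing <- setdiff(unique(counts$condition), names(n_by_cond))
  if (length(missing) > 0L)
    stop("condition(s) with zero samples in sheet: ",
         paste(missing, collapse = ", "))
  counts$n_samples <- as.integer(n_by_cond[counts$condition])
  counts$mean_coverage <- counts$bases / (counts$length * counts$n_samples)
  counts
}

#' Write the feature coverage table as TSV
#'
#' @param cov output of [summarize_coverage()] (or [count_feature_bases()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_coverage_tsv <- function(cov, path) {
  utils::write.table(cov, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Paired bar chart of feature coverage (exons up, introns down)
#'
#' Renders mean per-sample coverage by condition with exon bars above and
#' intron bars below the axis, features in transcription order.
#'
#' @param cov output of [summarize_coverage()].
#' @return a `ggplot` object.
#' @export
plot_coverage <- function(cov) {
  d <- cov
  d$pos <- match(paste(d$kind, d$index), unique(paste(d$kind, d$index)))
  d$y <- ifelse(d$kind == "exon", d$mean_coverage, -d$mean_coverage)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pos, y = .data$y,
                                  fill = .data$condition)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "feature (transcription order; exons up, introns down)",
                  y = "mean per-sample coverage", fill = "condition") +
    ggplot2::theme_minimal()
}
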