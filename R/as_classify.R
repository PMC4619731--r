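#' Classify splice junctions against a canonical gene model
#'
#' Assigns each junction one of five categories by a deterministic decision
#' cascade against the model's canonical junction set:
#'
#' 1. exact coordinate match -> `Canonical`;
#' 2. both ends match the ends of two *different* canonical junctions ->
#'    `SkippedExon` (the skipped exons are those wholly contained in the
#'    gap, reported by transcription-order index);
#' 3. one end on a canonical splice site, the other strictly inside the same
#'    intron, with a reciprocal partner junction in `all_junctions` closing
#'    a novel internal exon -> `AddedExon` (both partners);
#' 4. exactly one end shared with a canonical junction -> `Acceptor` or
#'    `Donor`, by which end is novel (strand-aware: the donor is the 5'
#'    side of the gap, i.e. `gap_start` on `+`, `gap_end` on `-`);
#' 5. neither end shared -> composite acceptor-and-donor event, reported as
#'    category `Acceptor` with both novel-end contexts recorded in `notes`.
#'
#' `novel_end_context` records where a novel end falls: inside an annotated
#' exon (`exonic`), inside an intron (`intronic`), or `none` for fully
#' canonical ends. A position outside the gene span takes the context of
#' the nearest feature (the terminal exon). Without the reciprocal partner,
#' an added-exon junction reports as `Acceptor`/`Donor` with
#' `novel_end_context = "intronic"`; likewise a skipped exon whose far-side
#' canonical junction is absent from the reference reports as
#' `Acceptor`/`Donor` with the novel end beyond the matched canonical
#' junction. Both degradations are deliberate: coordinates alone cannot
#' distinguish these cases from novel splice-site use.
#'
#' @param events event `data.frame` with `gap_start`, `gap_end` columns
#'   (e.g. from [aggregate_junctions()]).
#' @param model a [gene_model()] on the events' chromosome.
#' @param all_junctions optional `data.frame` of junctions searched for
#'   reciprocal added-exon partners; defaults to `events` itself.
#' @return `events` with columns `category`, `novel_end_context`,
#'   `skipped_exons` (comma-separated transcription-order exon indices, `""`
#'   if none) and `notes` appended, plus `strand` from the model.
#' @export
classify_events <- function(events, model, all_junctions = NULL) {
  stopifnot(inherits(model, "gene_model"))
  if (is.null(all_junctions)) all_junctions <- events
  canon <- canonical_junctions(model)
  n <- nrow(events)
  category <- character(n); context <- character(n)
  skipped <- character(n); notes <- character(n)
  for (i in seq_len(n)) {
    res <- .classify_one(events$gap_start[i], events$gap_end[i], model, canon,
                         all_junctions)
    category[i] <- res$category; context[i] <- res$context
    skipped[i] <- res$skipped; notes[i] <- res$notes
  }
  events$strand <- rep(model$strand, n)
  events$category <- category
  events$novel_end_context <- context
  events$skipped_exons <- skipped
  events$notes <- notes
  events
}

#' @rdname classify_events
#' @param gap_start,gap_end a single junction (first/last gapped base,
#'   1-based inclusive).
#' @export
classify_junction <- function(gap_start, gap_end, model, all_junctions = NULL) {
  ev <- data.frame(gap_start = gap_start, gap_end = gap_end)
  classify_events(ev, model, all_junctions = all_junctions)
}

# transcription-order index of genomically k-th exon
.tx_exon_index <- function(k, model) {
  E <- length(model$exons)
  if (model$strand == "+") k else E + 1L - k
}

# context of a single genomic position against the feature ladder;
# positions outside the gene span take the nearest feature's kind (exonic).
.end_context <- function(pos, model) {
  ex <- model$exons
  if (any(pos >= start(ex) & pos <= end(ex))) return("exonic")
  if (pos >= min(start(ex)) && pos <= max(end(ex))) return("intronic")
  "exonic"
}

.skipped_indices <- function(s, e, model) {
  ex <- model$exons
  k <- which(start(ex) >= s & end(ex) <= e)
  if (length(k) == 0L) return("")
  idx <- sort(vapply(k, .tx_exon_index, 0L, model = model))
  paste(idx, collapse = ",")
}

.classify_one <- function(s, e, model, canon, allj) {
  plus <- model$strand == "+"
  left_hit <- which(canon$gap_start == s)
  right_hit <- which(canon$gap_end == e)
  # 1. exact canonical match
  if (length(intersect(left_hit, right_hit)) > 0L)
    return(list(category = "Canonical", context = "none", skipped = "", notes = ""))
  # 2. ends of two different canonical junctions -> exon skipping
  if (length(left_hit) > 0L && length(right_hit) > 0L)
    return(list(category = "SkippedExon", context = "none",
                skipped = .skipped_indices(s, e, model), notes = ""))
  # 3. reciprocal intronic pair -> added (novel internal) exon
  if (length(left_hit) > 0L && e < canon$gap_end[left_hit[1]]) {
    k <- left_hit[1]
    partner <- allj$gap_end == canon$gap_end[k] &
      allj$gap_start > canon$gap_start[k] &   # strictly inside the intron
      allj$gap_start >= e + 2L                # novel exon of width >= 1
    if (any(partner))
      return(list(category = "AddedExon", context = "intronic", skipped = "",
                  notes = ""))
  }
  if (length(right_hit) > 0L && s > canon$gap_start[right_hit[1]]) {
    k <- right_hit[1]
    partner <- allj$gap_start == canon$gap_start[k] &
      allj$gap_end < canon$gap_end[k] &
      allj$gap_end <= s - 2L
    if (any(partner))
      return(list(category = "AddedExon", context = "intronic", skipped = "",
                  notes = ""))
  }
  # 4. one shared end -> alternative acceptor/donor by which end is novel
  if (length(left_hit) > 0L) {
    return(list(category = if (plus) "Acceptor" else "Donor",
                context = .end_context(e, model), skipped = "", notes = ""))
  }
  if (length(right_hit) > 0L) {
    return(list(category = if (plus) "Donor" else "Acceptor",
                context = .end_context(s, model), skipped = "", notes = ""))
  }
  # 5. neither end canonical: composite acceptor-and-donor event
  donor_end <- if (plus) s else e
  acceptor_end <- if (plus) e else s
  dctx <- .end_context(donor_end, model)
  actx <- .end_context(acceptor_end, model)
  list(category = "Acceptor", context = actx, skipped = "",
       notes = sprintf("composite: donor=%s, acceptor=%s", dctx, actx))
}

#' Group splice events into loci
#'
#' Single-linkage merge of junction gap intervals that overlap after
#' symmetric padding. Locus ids are assigned in coordinate order and every
#' event belongs to exactly one locus.
#'
#' @param events event `data.frame` with `gap_start`, `gap_end`.
#' @param pad symmetric padding in nt applied before the overlap test.
#' @return list with `events` (input plus `locus_id` column) and `loci`
#'   (`data.frame`: `locus_id`, `start`, `end` spanning member junctions,
#'   `n_events`).
#' @export
group_loci <- function(events, pad = 0L) {
  if (nrow(events) == 0L) {
    events$locus_id <- integer()
    return(list(events = events,
                loci = data.frame(locus_id = integer(), start = integer(),
                                  end = integer(), n_events = integer())))
  }
  padded <- IRanges::IRanges(pmax(1L, events$gap_start - pad),
                             events$gap_end + pad)
  merged <- IRanges::reduce(padded, min.gapwidth = 0L)
  hit <- IRanges::findOverlaps(padded, merged)
  events$locus_id <- S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))]
  loci <- do.call(rbind, lapply(sort(unique(events$locus_id)), function(id) {
    m <- events[events$locus_id == id, ]
    data.frame(locus_id = id, start = min(m$gap_start), end = max(m$gap_end),
               n_events = nrow(m))
  }))
  list(events = events, loci = loci)
}

#' Count alternative (non-canonical) splice events
#'
#' @param events classified event `data.frame` (see [classify_events()]).
#' @return integer count of events whose category is not `Canonical`.
#' @export
count_alternative <- function(events) {
  if (nrow(events) == 0L) return(0L)
  if (!"category" %in% names(events) || anyNA(events$category))
    stop("events must be classified before counting alternative events")
  sum(events$category != "Canonical")
}
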