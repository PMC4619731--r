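# reported HTT junctions and the reference induced from their canonical rows
htt_classified <- function() {
  j <- htt_junctions()
  model <- htt_canonical_model()
  ev <- classify_events(j[, c("gap_start", "gap_end")], model)
  ev$reported <- j$as_type
  ev
}

test_that("reported HTT junctions classify to their reported AS types", {
  ev <- htt_classified()
  # exact canonical matches
  expect_equal(ev$category[ev$reported == "Canonical"],
               rep("Canonical", 8L))
  # alternative acceptor and donor rows match directly
  expect_equal(ev$category[ev$reported == "Acceptor"],
               rep("Acceptor", sum(ev$reported == "Acceptor")))
  expect_equal(ev$category[ev$reported == "Donor"],
               rep("Donor", sum(ev$reported == "Donor")))
  # the mid-intron acceptor at the 5'-most locus is intronic
  expect_equal(ev$novel_end_context[ev$gap_start == 3122936 &
                                      ev$gap_end == 3124249], "intronic")
  # the exon-40-to-42 skip matches both flanking canonical junctions
  row_e <- ev[ev$gap_start == 3189093 & ev$gap_end == 3204006, ]
  expect_equal(row_e$category, "SkippedExon")
  expect_match(row_e$skipped_exons, "^[0-9]+$")
})

test_that("added-exon junctions need a reciprocal partner, else report as intronic acceptor", {
  ev <- htt_classified()
  added <- ev[ev$reported == "Added Exon", ]
  # without the downstream partner junction: acceptor with intronic novel end
  expect_equal(added$category, rep("Acceptor", 2L))
  expect_equal(added$novel_end_context, rep("intronic", 2L))
  # supplying a synthetic reciprocal partner (novel-exon donor to the
  # canonical acceptor) upgrades both to AddedExon
  model <- htt_canonical_model()
  withp <- rbind(ev[, c("gap_start", "gap_end")],
                 data.frame(gap_start = 3203034L, gap_end = 3204006L))
  ev2 <- classify_events(withp, model)
  expect_equal(ev2$category[ev2$gap_start == 3199939 & ev2$gap_end == 3202976],
               "AddedExon")
  expect_equal(ev2$category[ev2$gap_start == 3203034 & ev2$gap_end == 3204006],
               "AddedExon")
})

test_that("a skipped exon whose far-side canonical junction is unknown degrades to Acceptor", {
  ev <- htt_classified()
  row_c <- ev[ev$gap_start == 3148207 & ev$gap_end == 3160281, ]
  expect_equal(row_c$reported, "Skipped Exon")
  expect_equal(row_c$category, "Acceptor")
  # its novel acceptor lies beyond the matched canonical junction's acceptor
  model <- htt_canonical_model()
  canon <- canonical_junctions(model)
  matched_end <- canon$gap_end[canon$gap_start == 3148207]
  expect_gt(row_c$gap_end, matched_end)
})

test_that("classification is exact: Canonical iff the pair is in the canonical set", {
  toy <- toy_splice_gene()
  canon <- canonical_junctions(toy$model)
  for (k in seq_len(nrow(canon))) {
    expect_equal(classify_junction(canon$gap_start[k], canon$gap_end[k],
                                   toy$model)$category, "Canonical")
    # any single-coordinate perturbation breaks canonicity
    expect_false(classify_junction(canon$gap_start[k] + 1L, canon$gap_end[k],
                                   toy$model)$category == "Canonical")
    expect_false(classify_junction(canon$gap_start[k], canon$gap_end[k] - 1L,
                                   toy$model)$category == "Canonical")
  }
})

test_that("every junction receives exactly one category (cascade is total)", {
  toy <- toy_splice_gene()
  set.seed(11)
  gs <- sort(sample(500:11000, 200))
  ge <- gs + sample(10:3000, 200, replace = TRUE)
  ev <- classify_events(data.frame(gap_start = gs, gap_end = ge), toy$model)
  expect_false(anyNA(ev$category))
  expect_true(all(ev$category %in%
                    c("Canonical", "Acceptor", "Donor", "SkippedExon", "AddedExon")))
  expect_true(all(ev$novel_end_context %in% c("none", "exonic", "intronic")))
  expect_true(all(ev$skipped_exons[ev$category == "SkippedExon"] != ""))
  expect_true(all(ev$skipped_exons[ev$category == "Canonical"] == ""))
})

test_that("mirroring a gene model swaps Acceptor and Donor and preserves the rest", {
  toy <- toy_splice_gene()
  model <- toy$model
  # events of each category, partners present for the added pair
  ev <- data.frame(
    gap_start = c(1301L, 2301L, 3381L, 4301L, 9301L, 9581L),
    gap_end   = c(1900L, 3030L, 4000L, 6000L, 9500L, 10000L))
  lab <- classify_events(ev, model)$category
  expect_equal(lab, c("Acceptor", "Acceptor", "Donor", "SkippedExon",
                      "AddedExon", "AddedExon"))
  pivot <- 20000L
  refl <- function(s, e) cbind(pivot - e, pivot - s)
  ex <- cbind(IRanges::start(model$exons), IRanges::end(model$exons))
  ev_ref <- as.data.frame(refl(ev$gap_start, ev$gap_end))
  names(ev_ref) <- c("gap_start", "gap_end")
  # reflecting coordinates while keeping the annotated strand exchanges the
  # donor and acceptor roles of the two gap ends
  m_plus <- gene_model(refl(ex[, 1], ex[, 2]), model$chrom, "+")
  lab_plus <- classify_events(ev_ref, m_plus)$category
  swap <- c(Acceptor = "Donor", Donor = "Acceptor", Canonical = "Canonical",
            SkippedExon = "SkippedExon", AddedExon = "AddedExon")
  expect_equal(lab_plus, unname(swap[lab]))
  # reflecting coordinates AND flipping the strand is the same biological
  # gene read in the opposite direction: labels are preserved
  m_minus <- gene_model(refl(ex[, 1], ex[, 2]), model$chrom, "-")
  lab_minus <- classify_events(ev_ref, m_minus)$category
  expect_equal(lab_minus, lab)
})

test_that("skipped-exon indices follow transcription order on both strands", {
  toy <- toy_splice_gene()
  ev <- classify_events(data.frame(gap_start = c(4301L, 6301L),
                                   gap_end = c(6000L, 9000L)), toy$model)
  expect_equal(ev$skipped_exons, c("5", "7,8"))
  # on the minus strand the same genomic skip covers mirrored indices
  ex <- cbind(IRanges::start(toy$model$exons), IRanges::end(toy$model$exons))
  m_minus <- gene_model(ex, "chrS", "-")
  ev_minus <- classify_events(data.frame(gap_start = 4301L, gap_end = 6000L),
                              m_minus)
  expect_equal(ev_minus$skipped_exons, "6")  # 10 + 1 - 5
})

test_that("junctions outside the gene span are still labeled, with flanking context", {
  toy <- toy_splice_gene()
  canon <- canonical_junctions(toy$model)
  # shares the last canonical acceptor; donor end beyond the gene span
  ev <- classify_junction(400L, canon$gap_end[1], toy$model)
  expect_equal(ev$category, "Donor")
  expect_equal(ev$novel_end_context, "exonic")
})

test_that("locus grouping is single-linkage on junction overlap", {
  ev <- data.frame(gap_start = c(100L, 150L), gap_end = c(200L, 300L))
  expect_equal(nrow(group_loci(ev)$loci), 1L)
  ev2 <- data.frame(gap_start = c(100L, 250L), gap_end = c(200L, 300L))
  expect_equal(nrow(group_loci(ev2)$loci), 2L)
  # padding can bridge the gap
  expect_equal(nrow(group_loci(ev2, pad = 30L)$loci), 1L)
  # the six junctions of the densest reported HTT locus form one locus
  j <- htt_junctions()
  e_rows <- j[j$gap_start >= 3189093 & j$gap_end <= 3204009,
              c("gap_start", "gap_end")]
  expect_equal(nrow(e_rows), 6L)
  gl <- group_loci(e_rows)
  expect_equal(nrow(gl$loci), 1L)
  expect_equal(gl$loci$n_events, 6L)
  # every event in exactly one locus
  expect_false(anyNA(gl$events$locus_id))
})

test_that("count_alternative counts non-canonical events and demands classification", {
  ev <- htt_classified()
  expect_equal(count_alternative(ev), 12L)
  expect_equal(count_alternative(ev[0, ]), 0L)
  all_canon <- ev[ev$category == "Canonical", ]
  expect_equal(count_alternative(all_canon), 0L)
  expect_error(count_alternative(data.frame(gap_start = 1L, gap_end = 2L)),
               "classified")
})
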