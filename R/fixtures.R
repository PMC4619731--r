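#' Toy multi-exon gene with one instance of each alternative-splicing pattern
#'
#' A compact 10-exon plus-strand gene (exon k spans `1000k+1 .. 1000k+300`,
#' introns of 700 nt) with a canonical isoform and five low-abundance
#' alternative isoforms that together produce six distinct event loci:
#' an alternative acceptor with an intronic novel end, an alternative
#' acceptor with an exonic novel end, an alternative donor, a single exon
#' skip, a double exon skip, and a reciprocal added-exon pair (a novel
#' 80 nt internal exon inside the last intron). Truth labels are attached
#' by construction.
#'
#' @param canonical_weight mixture weight of the canonical isoform; the five
#'   alternative isoforms share the remainder equally.
#' @return list with `model` (a [gene_model()]), `isoforms` (list of
#'   [isoform_spec()]), and `truth_labels` (`data.frame`: `gap_start`,
#'   `gap_end`, `category`).
#' @export
toy_splice_gene <- function(canonical_weight = 0.90) {
  ex <- cbind(1000L * (1:10) + 1L, 1000L * (1:10) + 300L)
  model <- gene_model(ex, "chrS", "+", "TOYG", "TOYG-001")
  e <- function(k) ex[k, , drop = FALSE]
  chain <- function(...) do.call(rbind, list(...))
  aw <- (1 - canonical_weight) / 5
  isoforms <- list(
    isoform_spec("canonical", ex, canonical_weight),
    # novel acceptor 100 nt inside intron 1 (exon 2 extended 5')
    isoform_spec("acc_intronic",
                 chain(e(1), cbind(1901L, 2300L), ex[3:10, ]), aw),
    # novel donor 80 nt inside intron 3 (exon 3 extended 3')
    isoform_spec("don_intronic",
                 chain(ex[1:2, ], cbind(3001L, 3380L), ex[4:10, ]), aw),
    # novel acceptor 30 nt inside exon 3, plus a double skip of exons 7-8
    isoform_spec("acc_exonic_dblskip",
                 chain(ex[1:2, ], cbind(3031L, 3300L), ex[4:6, ], ex[9:10, ]),
                 aw),
    # single skip of exon 5
    isoform_spec("skip_e5", chain(ex[1:4, ], ex[6:10, ]), aw),
    # novel 80 nt exon inside intron 9 (reciprocal junction pair)
    isoform_spec("added_exon",
                 chain(ex[1:9, ], cbind(9501L, 9580L), e(10)), aw)
  )
  truth_labels <- data.frame(
    gap_start = c(1301L, 2301L, 3381L, 4301L, 6301L, 9301L, 9581L),
    gap_end   = c(1900L, 3030L, 4000L, 6000L, 9000L, 9500L, 10000L),
    category  = c("Acceptor", "Acceptor", "Donor", "SkippedExon",
                  "SkippedExon", "AddedExon", "AddedExon"),
    stringsAsFactors = FALSE)
  list(model = model, isoforms = isoforms, truth_labels = truth_labels)
}

#' Default simulation configuration over the toy gene
#'
#' Eight samples in three condition groups of unequal size (HD, PD: 2 each;
#' C: 4), mirroring a disease/disease/control design at desk scale. All
#' sequencing parameters default to the emulated library: 101 nt paired-end
#' reads from ~300 nt fragments with moderate poly-A 3' bias.
#'
#' @param n_fragments fragments per sample (default 20000).
#' @param seed root seed.
#' @param three_prime_bias exponential 3'-bias decay rate per nt.
#' @param unspliced_weight optional weight of an unspliced pre-mRNA
#'   background isoform (taken out of the canonical weight).
#' @param canonical_weight weight of the canonical isoform before any
#'   unspliced reallocation.
#' @return a [sim_config()].
#' @export
toy_sim_config <- function(n_fragments = 20000L, seed = 1L,
                           three_prime_bias = 5e-4, unspliced_weight = 0,
                           canonical_weight = 0.90) {
  toy <- toy_splice_gene(canonical_weight)
  isoforms <- toy$isoforms
  if (unspliced_weight > 0) {
    isoforms[[1]]$weight <- isoforms[[1]]$weight - unspliced_weight
    isoforms <- c(isoforms,
                  list(isoform_spec("pre_mRNA", NULL, unspliced_weight,
                                    unspliced = TRUE)))
  }
  samples <- data.frame(
    sample_id = c("HD1", "HD2", "PD1", "PD2", "C1", "C2", "C3", "C4"),
    condition = c("HD", "HD", "PD", "PD", "C", "C", "C", "C"),
    stringsAsFactors = FALSE)
  sim_config(toy$model, isoforms, samples, n_fragments = n_fragments,
             seed = seed, three_prime_bias = three_prime_bias,
             truth_labels = toy$truth_labels)
}

#' Previously reported HTT superset splice junctions (hg38)
#'
#' The selection of splice events detected in the HTT locus superset of
#' post mortem brain mRNA-Seq (28 Huntington's, 29 Parkinson's, 50 control
#' samples), with their reported AS types and junction read supports.
#' Coordinates are 1-based inclusive gap spans on chr4 (+ strand).
#'
#' @return `data.frame` with columns `locus`, `fig_label`, `gap_start`,
#'   `gap_end`, `as_type`, `read_support`.
#' @export
htt_junctions <- function() {
  path <- system.file("extdata", "htt_events.tsv", package = "spliceGaps",
                      mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Surrogate HTT reference model induced from the reported canonical junctions
#'
#' Builds a [gene_model()] whose introns are the junctions reported as
#' Canonical in [htt_junctions()]. Exons between distant loci are
#' placeholders (the spans between consecutive reported junctions), so the
#' model carries no information about true exon boundaries beyond the
#' reported splice sites; see [model_from_junctions()].
#'
#' @return a [gene_model()] on chr4, plus strand.
#' @export
htt_canonical_model <- function() {
  j <- htt_junctions()
  canon <- j[j$as_type == "Canonical", c("gap_start", "gap_end")]
  model_from_junctions(canon, "chr4", "+", flank = 100L,
                       gene_id = "HTT", transcript_id = "HTT-001-induced")
}
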