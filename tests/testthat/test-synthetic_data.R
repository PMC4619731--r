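test_that("identical seeds give byte-identical SAM output", {
  cfg <- toy_sim_config(n_fragments = 400L, seed = 99L)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  s1 <- simulate_reads(cfg, d1)
  s2 <- simulate_reads(cfg, d2)
  expect_equal(unname(tools::md5sum(s1$sam)), unname(tools::md5sum(s2$sam)))
  # a different seed changes the reads
  s3 <- simulate_reads(toy_sim_config(n_fragments = 400L, seed = 100L),
                       file.path(tempdir(), "det3"))
  expect_false(all(unname(tools::md5sum(s1$sam)) ==
                     unname(tools::md5sum(s3$sam))))
})

test_that("truth-set junction supports match a closed form for fixed fragment length", {
  # uniform positional model (no 3' bias), effectively fixed fragment length:
  # a mate spans an interior junction for R-1 of the M = L-f+1 equally likely
  # 3'-end positions, so E[support] = n_frags * n_samples * w * 2(R-1)/M.
  m <- gene_model(cbind(c(1001L, 2001L, 3001L), c(1200L, 2200L, 3200L)),
                  "chrT", "+", "G", "G-001")
  iso <- list(isoform_spec("canonical",
                           cbind(c(1001L, 2001L, 3001L), c(1200L, 2200L, 3200L)),
                           1.0))
  samples <- data.frame(sample_id = c("a", "b"), condition = "A")
  R <- 50L; f <- 120
  cfg <- sim_config(m, iso, samples, n_fragments = 1000L, read_length = R,
                    frag_mean = f, frag_sd = 1e-6, three_prime_bias = 0,
                    seed = 5L)
  tr <- truth_set(cfg)
  L <- 600; M <- L - f + 1
  expected <- 1000 * 2 * 1.0 * 2 * (R - 1) / M
  expect_equal(tr$junctions$expected_support, rep(expected, 2), tolerance = 1e-10)
  # mates cannot both span one junction when f > 2R - 2
  expect_equal(tr$junctions$sd_support,
               rep(sqrt(2000 * (expected / 2000) * (1 - expected / 2000)), 2),
               tolerance = 1e-10)
  # expected bases in the fully interior middle exon: 200 positions * 2R/M
  fx <- tr$features
  mid <- fx$kind == "exon" & fx$index == 2L
  expect_equal(fx$expected_bases[mid], 2000 * 200 * 2 * R / M,
               tolerance = 1e-10)
})

test_that("observed supports and coverage match analytic truth at 3 sigma (uniform)", {
  toy <- toy_splice_gene()
  samples <- data.frame(sample_id = c("u1", "u2"), condition = "U")
  cfg <- sim_config(toy$model, toy$isoforms, samples, n_fragments = 5000L,
                    three_prime_bias = 0, seed = 31L,
                    truth_labels = toy$truth_labels)
  out <- simulate_reads(cfg, file.path(tempdir(), "unif"))
  groups <- merge_groups(out$sheet, paste0("chrS:1-", cfg$chrom_len))
  ev <- aggregate_junctions(groups)
  tr <- out$truth$junctions
  mrg <- merge(ev, tr, by = c("gap_start", "gap_end"))
  expect_equal(nrow(mrg), nrow(tr))           # all truth junctions seen
  z <- abs(mrg$support_total - mrg$expected_support) / mrg$sd_support
  expect_lt(max(z), 3)
  # feature coverage within 3 sigma of truth (where the expectation is nonzero)
  cnt <- count_feature_bases(groups, derive_features(toy$model))
  ftr <- out$truth$features
  mrg2 <- merge(cnt, ftr, by = c("kind", "index"))
  nz <- mrg2$sd_bound > 0
  dev <- abs(mrg2$bases[nz] - mrg2$expected_bases[nz]) / mrg2$sd_bound[nz]
  expect_lt(max(dev), 3)
  expect_true(all(mrg2$bases[!nz] == 0))
  # away from the transcript-end ramp-up/fall-off (about one fragment
  # length), unbiased sampling gives near-uniform exon coverage
  interior <- mrg2[mrg2$kind == "exon" & mrg2$index %in% 3:8, ]
  expect_lt(diff(range(interior$expected_bases)) /
              mean(interior$expected_bases), 0.10)
})

test_that("unspliced pre-mRNA raises intron coverage without creating junctions", {
  ex <- cbind(c(1001L, 2001L, 3001L), c(1500L, 2500L, 3500L))
  m <- gene_model(ex, "chrT", "+", "G", "G-001")
  samples <- data.frame(sample_id = "s1", condition = "A")
  base_iso <- list(isoform_spec("canonical", ex, 1.0))
  mix_iso <- list(isoform_spec("canonical", ex, 0.9),
                  isoform_spec("pre_mRNA", NULL, 0.1, unspliced = TRUE))
  run <- function(isos, seed) {
    cfg <- sim_config(m, isos, samples, n_fragments = 4000L, seed = seed,
                      three_prime_bias = 0)
    out <- simulate_reads(cfg, tempfile())
    groups <- merge_groups(out$sheet, paste0("chrT:1-", cfg$chrom_len))
    list(ev = aggregate_junctions(groups),
         cnt = count_feature_bases(groups, derive_features(m)))
  }
  pure <- run(base_iso, 7L)
  mix <- run(mix_iso, 7L)
  # same junction coordinates, no new ones
  expect_equal(mix$ev[, c("gap_start", "gap_end")],
               pure$ev[, c("gap_start", "gap_end")])
  # intron coverage rises substantially
  i_pure <- sum(pure$cnt$bases[pure$cnt$kind == "intron"])
  i_mix <- sum(mix$cnt$bases[mix$cnt$kind == "intron"])
  expect_gt(i_mix, i_pure + 1000)
})

test_that("simulator rejects impossible configurations", {
  ex <- cbind(c(101L, 301L), c(140L, 340L))   # 80 nt transcript
  m <- gene_model(ex, "chrT", "+")
  iso <- list(isoform_spec("c", ex, 1.0))
  samples <- data.frame(sample_id = "s", condition = "A")
  cfg <- sim_config(m, iso, samples, n_fragments = 10L, read_length = 101L,
                    frag_mean = 150)
  expect_error(truth_set(cfg), "shorter than read length")
  # weights must sum to one
  expect_error(sim_config(m, list(isoform_spec("c", ex, 0.5)), samples, 10L),
               "sum to 1")
  # minus-strand simulation is not supported
  m_minus <- gene_model(ex, "chrT", "-")
  expect_error(sim_config(m_minus, iso, samples, 10L), "plus-strand")
  # fragment mean below read length is rejected
  expect_error(sim_config(m, iso, samples, 10L, read_length = 101L,
                          frag_mean = 80), "read_length")
})

test_that("simulation configs round-trip through JSON", {
  cfg <- toy_sim_config(n_fragments = 123L, seed = 42L,
                        three_prime_bias = 1e-3)
  p <- tempfile(fileext = ".json")
  write_sim_config(cfg, p)
  cfg2 <- read_sim_config(p)
  expect_equal(cfg2$n_fragments, cfg$n_fragments)
  expect_equal(cfg2$seed, cfg$seed)
  expect_equal(cfg2$three_prime_bias, cfg$three_prime_bias)
  expect_equal(IRanges::start(cfg2$model$exons), IRanges::start(cfg$model$exons))
  expect_equal(vapply(cfg2$isoforms, function(i) i$weight, 0),
               vapply(cfg$isoforms, function(i) i$weight, 0),
               ignore_attr = TRUE)
  # simulating from the reloaded config reproduces the same reads
  s1 <- simulate_reads(cfg, tempfile(), write_truth = FALSE)
  s2 <- simulate_reads(cfg2, tempfile(), write_truth = FALSE)
  expect_equal(unname(tools::md5sum(s1$sam)), unname(tools::md5sum(s2$sam)))
})
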