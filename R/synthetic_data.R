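#' Define an isoform for simulation
#'
#' An isoform is an ordered chain of genomic blocks (1-based inclusive) that
#' a mature transcript splices together. Chains may shift splice sites,
#' skip annotated exons, or insert novel blocks inside annotated introns.
#' An unspliced isoform models pre-mRNA background: one block spanning the
#' whole gene, producing intronic coverage but no junctions.
#'
#' @param name isoform name.
#' @param exon_chain two-column matrix/data.frame of block `start`,`end`
#'   (1-based inclusive), strictly increasing; ignored if `unspliced`.
#' @param weight mixture proportion in `[0, 1]`.
#' @param unspliced if `TRUE`, the chain is a single block spanning the gene.
#' @return an `isoform_spec` object.
#' @export
isoform_spec <- function(name, exon_chain = NULL, weight, unspliced = FALSE) {
  if (!unspliced) {
    exon_chain <- as.matrix(exon_chain)
    if (ncol(exon_chain) != 2L) stop("exon_chain must have two columns")
    storage.mode(exon_chain) <- "integer"
    if (nrow(exon_chain) > 1L &&
        any(exon_chain[-1, 1] <= exon_chain[-nrow(exon_chain), 2]))
      stop("isoform '", name, "': exon_chain blocks must be increasing and non-overlapping")
  }
  if (weight < 0 || weight > 1) stop("weight must be in [0, 1]")
  structure(list(name = name, exon_chain = exon_chain, weight = weight,
                 unspliced = unspliced),
            class = "isoform_spec")
}

#' Build a simulation configuration
#'
#' Defines the isoform mixture, sequencing geometry and positional bias of
#' the simulated library. Fragment 3' ends are drawn with weight
#' `exp(-three_prime_bias * distance_from_3'_end)` along transcript
#' coordinates (poly-A selection bias; 0 gives uniform coverage); fragment
#' lengths are rounded normal, truncated to `[read_length, transcript
#' length]` by resampling.
#'
#' @param model a [gene_model()] (plus strand).
#' @param isoforms list of [isoform_spec()]; weights must sum to 1.
#' @param samples `data.frame` with columns `sample_id`, `condition`.
#' @param n_fragments fragments per sample.
#' @param read_length mate length in nt (default 101).
#' @param frag_mean,frag_sd fragment length distribution in nt (default
#'   300/50).
#' @param three_prime_bias exponential decay rate per nt (default 5e-4,
#'   i.e. a 2 kb decay length - a moderate poly-A selection skew).
#' @param seed root seed; per-sample seeds are derived from it.
#' @param chrom_len reference length written to the SAM header (default:
#'   model/isoform span plus 1 kb).
#' @param truth_labels optional `data.frame` (`gap_start`, `gap_end`,
#'   `category`) of known labels for novel junctions, carried into the
#'   truth set; junctions without a supplied label are classified against
#'   the model.
#' @return a `sim_config` object.
#' @export
sim_config <- function(model, isoforms, samples, n_fragments,
                       read_length = 101L, frag_mean = 300, frag_sd = 50,
                       three_prime_bias = 5e-4, seed = 1L, chrom_len = NULL,
                       truth_labels = NULL) {
  stopifnot(inherits(model, "gene_model"))
  if (model$strand != "+")
    stop("the simulator supports plus-strand gene models only")
  w <- vapply(isoforms, function(x) x$weight, 0)
  if (abs(sum(w) - 1) > 1e-8) stop("isoform weights must sum to 1 (got ", sum(w), ")")
  if (read_length < 1L) stop("read_length must be >= 1")
  if (frag_mean < read_length) stop("fragment mean must be >= read_length")
  if (is.null(names(isoforms)))
    names(isoforms) <- vapply(isoforms, function(x) x$name, "")
  need <- c("sample_id", "condition")
  if (!all(need %in% names(samples))) stop("samples needs sample_id, condition")
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample_id in samples")
  span_hi <- max(end(model$exons),
                 vapply(isoforms, function(x)
                   if (x$unspliced) max(end(model$exons)) else max(x$exon_chain[, 2]),
                   0))
  structure(list(model = model, isoforms = isoforms,
                 samples = as.data.frame(samples)[, need],
                 n_fragments = as.integer(n_fragments),
                 read_length = as.integer(read_length),
                 frag_mean = frag_mean, frag_sd = frag_sd,
                 three_prime_bias = three_prime_bias, seed = as.integer(seed),
                 chrom_len = if (is.null(chrom_len)) span_hi + 1000L
                             else as.integer(chrom_len),
                 truth_labels = truth_labels),
            class = "sim_config")
}

# resolved chain, cumulative transcript geometry
.iso_geom <- function(iso, model) {
  chain <- if (iso$unspliced)
    cbind(min(start(model$exons)), max(end(model$exons)))
  else iso$exon_chain
  ws <- chain[, 2] - chain[, 1] + 1L
  list(gs = chain[, 1], ge = chain[, 2], ws = ws,
       cum0 = c(0L, cumsum(ws)), L = sum(ws))
}

# genomic position of transcript coordinate t (plus strand)
.t2g <- function(t, geom) {
  k <- findInterval(t - 1L, geom$cum0[-1]) + 1L
  geom$gs[k] + (t - geom$cum0[k] - 1L)
}

# --- fragment-position distributions (shared by simulator and truth set) ---
# P(f): rounded-normal fragment length renormalized on [R, min(L, mu+10sd)]
# P(q|f) prop exp(-lambda (L - q)) on [f, L]
.iso_dists <- function(L, R, mu, sd, lambda) {
  f_lo <- R
  f_hi <- min(L, as.integer(ceiling(mu + 10 * sd)))
  if (f_hi < f_lo) stop("transcript (", L, " nt) shorter than read length")
  fr <- f_lo:f_hi
  pf <- stats::pnorm(fr + 0.5, mu, sd) - stats::pnorm(fr - 0.5, mu, sd)
  pf <- pf / sum(pf)
  q_all <- 1:L
  wq <- exp(-lambda * (L - q_all))
  Swq_suffix <- rev(cumsum(rev(wq)))          # S(f) = sum_{q>=f} wq
  Sf <- Swq_suffix[fr]
  # marginal P(q): wq(q) * sum_{f <= q, f in fr} pf/Sf
  af <- numeric(L); af[fr] <- pf / Sf
  Pq <- wq * cumsum(af)
  # marginal P(p): P(p=s) = sum_f pf(f) wq(s+f-1)/Sf, s in [1, L-f+1]
  Pp <- numeric(L)
  for (i in seq_along(fr)) {
    f <- fr[i]
    s_max <- L - f + 1L
    if (s_max >= 1L)
      Pp[1:s_max] <- Pp[1:s_max] + pf[i] * wq[f:L] / Sf[i]
  }
  list(fr = fr, pf = pf, wq = wq, Sf = Sf, Pq = Pq, Pp = Pp,
       cwq = cumsum(wq), L = L, R = R)
}

.wsum <- function(cum, lo, hi) {           # sum v[lo..hi] from cumsum(v)
  lo <- max(lo, 1L); hi <- min(hi, length(cum))
  if (hi < lo) return(0)
  cum[hi] - if (lo > 1L) cum[lo - 1L] else 0
}

# per-fragment spanning moments for the junction after transcript pos t:
# X = #mates whose alignment contains the gap; returns E[X], E[X^2]
.span_moments <- function(d, t) {
  R <- d$R; L <- d$L
  cPp <- cumsum(d$Pp); cPq <- cumsum(d$Pq)
  e1 <- .wsum(cPp, t - R + 2L, t) +          # mate 1 start p in window
        .wsum(cPq, t + 1L, t + R - 1L)       # mate 2: q in [t+1, t+R-1]
  # P(both mates span): per f, q in [t+f-R+1, t+f-1] ∩ [t+1, t+R-1] ∩ [f, L]
  pboth <- 0
  for (i in seq_along(d$fr)) {
    f <- d$fr[i]
    lo <- max(t + f - R + 1L, t + 1L, f)
    hi <- min(t + f - 1L, t + R - 1L, L)
    if (hi >= lo)
      pboth <- pboth + d$pf[i] * .wsum(d$cwq, lo, hi) / d$Sf[i]
  }
  c(e1 = e1, e2 = e1 + 2 * pboth)
}

# expected per-transcript-position coverage (both mates) per fragment
.cov_profile <- function(d) {
  R <- d$R; L <- d$L
  cs_p <- c(0, cumsum(d$Pp)); cs_q <- c(0, cumsum(d$Pq))   # cs[k+1] = sum v[1..k]
  t <- 1:L
  lo1 <- pmax(t - R + 1L, 1L)
  c1 <- cs_p[t + 1L] - cs_p[lo1]                           # p in [t-R+1, t]
  hi2 <- pmin(t + R - 1L, L)
  c2 <- cs_q[hi2 + 1L] - cs_q[t]                           # q in [t, t+R-1]
  c1 + c2
}

#' Analytic ground truth for a simulation configuration
#'
#' Computes, exactly under the generative model (mixture weights, truncated
#' rounded-normal fragment lengths, exponential 3' positional bias), the
#' expected read support and its standard deviation for every junction of
#' every spliced isoform, and the expected aligned-base count per
#' exon/intron feature per condition. Junction supports use exact first and
#' second moments of the per-fragment span count; feature-count standard
#' deviations use the conservative bound `Var(X) <= 2 * read_length * E(X)`.
#'
#' @param config a [sim_config()].
#' @return list with `junctions` (`data.frame`: `chrom`, `gap_start`,
#'   `gap_end`, `gap_len`, `category`, `expected_support`, `sd_support`,
#'   one `expected.<condition>` column per condition) and `features`
#'   (`data.frame`: `kind`, `index`, `condition`, `expected_bases`,
#'   `sd_bound`).
#' @export
truth_set <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  model <- config$model
  feats <- derive_features(model)
  conds <- unique(config$samples$condition)
  n_cond <- table(config$samples$condition)[conds]
  n <- config$n_fragments

  jlist <- list(); fcov <- list()
  for (iso in config$isoforms) {
    geom <- .iso_geom(iso, model)
    d <- .iso_dists(geom$L, config$read_length, config$frag_mean,
                    config$frag_sd, config$three_prime_bias)
    nb <- length(geom$ws)
    if (!iso$unspliced && nb > 1L) {
      for (k in seq_len(nb - 1L)) {
        t <- geom$cum0[k + 1L]                      # junction after block k
        m <- .span_moments(d, t)
        jlist[[length(jlist) + 1L]] <- data.frame(
          gap_start = geom$ge[k] + 1L, gap_end = geom$gs[k + 1L] - 1L,
          weight = iso$weight, e1 = m[["e1"]], e2 = m[["e2"]])
      }
    }
    # expected coverage per genomic position -> per feature
    prof <- .cov_profile(d)
    gpos <- .t2g(seq_len(geom$L), geom)
    fidx <- findInterval(gpos, sort(feats$start))
    fo <- order(feats$start)
    perfeat <- numeric(nrow(feats))
    keep <- fidx >= 1L & gpos <= max(feats$end)
    agg <- tapply(prof[keep], fidx[keep], sum)
    perfeat[fo[as.integer(names(agg))]] <- as.numeric(agg)
    fcov[[length(fcov) + 1L]] <- perfeat * iso$weight
  }

  # aggregate junction moments over isoforms sharing a junction
  jdt <- data.table::rbindlist(jlist)
  jagg <- jdt[, .(e1 = sum(weight * e1), e2 = sum(weight * e2)),
              by = .(gap_start, gap_end)]
  jn <- as.data.frame(jagg)
  jn$gap_len <- jn$gap_end - jn$gap_start + 1L
  for (cc in conds) {
    nf <- n * as.integer(n_cond[cc])
    jn[[paste0("expected.", cc)]] <- nf * jn$e1
  }
  n_total <- n * nrow(config$samples)
  jn$expected_support <- n_total * jn$e1
  jn$sd_support <- sqrt(n_total * pmax(jn$e2 - jn$e1^2, 0))
  jn$chrom <- model$chrom

  # labels: supplied truth labels win; otherwise classify against the model
  lab <- classify_events(jn[, c("gap_start", "gap_end")], model,
                         all_junctions = jn)
  jn$category <- lab$category
  if (!is.null(config$truth_labels)) {
    key <- paste(jn$gap_start, jn$gap_end)
    tl <- config$truth_labels
    hit <- match(key, paste(tl$gap_start, tl$gap_end))
    jn$category[!is.na(hit)] <- tl$category[hit[!is.na(hit)]]
  }
  jn <- jn[order(jn$gap_start, jn$gap_end),
           c("chrom", "gap_start", "gap_end", "gap_len", "category",
             "expected_support", "sd_support",
             paste0("expected.", conds))]
  rownames(jn) <- NULL

  mix_cov <- Reduce(`+`, fcov)                 # per-feature per-fragment
  fx <- do.call(rbind, lapply(conds, function(cc) {
    nf <- n * as.integer(n_cond[cc])
    data.frame(kind = feats$kind, index = feats$index, length = feats$length,
               condition = cc, expected_bases = nf * mix_cov,
               sd_bound = sqrt(2 * config$read_length * nf * mix_cov))
  }))
  rownames(fx) <- NULL
  list(junctions = jn, features = fx)
}

# ---- simulation ----

# sample fragment placements for n fragments on one isoform; returns
# data.table(p, q, f) in transcript coordinates (1-based)
.sample_placements <- function(nfrag, d, max_retry = 1000L) {
  L <- d$L; R <- d$R
  f <- integer(nfrag); todo <- seq_len(nfrag); it <- 0L
  mu <- attr(d, "mu"); sd <- attr(d, "sd")
  while (length(todo) > 0L) {
    it <- it + 1L
    if (it > max_retry)
      stop("could not draw a fragment length within [read_length, transcript]",
           " after ", max_retry, " rounds (fragment longer than transcript?)")
    cand <- as.integer(round(stats::rnorm(length(todo), mu, sd)))
    ok <- cand >= R & cand <= L
    f[todo[ok]] <- cand[ok]
    todo <- todo[!ok]
  }
  # q | f: exp-weighted on [f, L]; rejection from the unconditional weights
  q <- integer(nfrag); todo <- seq_len(nfrag); it <- 0L
  lambda <- attr(d, "lambda")
  while (length(todo) > 0L) {
    it <- it + 1L
    if (it > max_retry) stop("3'-end sampling failed to converge")
    m <- length(todo)
    cand <- if (lambda == 0) sample.int(L, m, replace = TRUE)
            else sample.int(L, m, replace = TRUE, prob = d$wq)
    ok <- cand >= f[todo]
    q[todo[ok]] <- cand[ok]
    todo <- todo[!ok]
  }
  data.table::data.table(f = f, q = q, p = q - f + 1L)
}

# genomic blocks + CIGAR for transcript intervals [a, b] on one isoform
.project_reads <- function(a, b, geom) {
  k1 <- findInterval(a - 1L, geom$cum0[-1]) + 1L
  k2 <- findInterval(b - 1L, geom$cum0[-1]) + 1L
  nb <- k2 - k1 + 1L
  idx <- rep.int(seq_along(a), nb)
  blk <- unlist(lapply(seq_along(a), function(i) k1[i]:k2[i]), use.names = FALSE)
  bs <- ifelse(blk == k1[idx],
               geom$gs[blk] + (a[idx] - geom$cum0[blk] - 1L), geom$gs[blk])
  be <- ifelse(blk == k2[idx],
               geom$gs[blk] + (b[idx] - geom$cum0[blk] - 1L), geom$ge[blk])
  dt <- data.table::data.table(idx = idx, bs = bs, be = be)
  dt[, {
    w <- be - bs + 1L
    if (.N == 1L) {
      list(pos = bs[1], cigar = paste0(w, "M"), gend = be[.N])
    } else {
      gapn <- bs[-1] - be[-.N] - 1L
      list(pos = bs[1],
           cigar = paste0(w[1], "M",
                          paste0(gapn, "N", w[-1], "M", collapse = "")),
           gend = be[.N])
    }
  }, by = idx]
}

#' Simulate spliced paired-end alignments and write SAM plus ground truth
#'
#' Alignments are generated directly (no sequencing-error or aligner model):
#' each fragment picks an isoform by mixture weight, a 3'-biased position
#' and a truncated-normal length, and emits two mates whose reference block
#' structure reflects the isoform's splicing (gaps encoded as `N`). Output
#' SAM files are coordinate-sorted and byte-identical for identical seeds.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @param write_truth also write `truth_junctions.tsv`, `truth_features.tsv`
#'   and `sim_config.json` next to the SAM files.
#' @return list with `sam` (named vector of per-sample SAM paths), `truth`
#'   (see [truth_set()]), `sheet` (sample sheet `data.frame` pointing at
#'   the SAM files), and `config`.
#' @export
simulate_reads <- function(config, out_dir, write_truth = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  model <- config$model
  geoms <- lapply(config$isoforms, .iso_geom, model = model)
  dists <- lapply(geoms, function(g) {
    d <- .iso_dists(g$L, config$read_length, config$frag_mean, config$frag_sd,
                    config$three_prime_bias)
    attr(d, "mu") <- config$frag_mean; attr(d, "sd") <- config$frag_sd
    attr(d, "lambda") <- config$three_prime_bias
    d
  })
  w <- vapply(config$isoforms, function(x) x$weight, 0)
  R <- config$read_length
  set.seed(config$seed)
  sample_seeds <- sample.int(.Machine$integer.max - 1L, nrow(config$samples))

  sam_paths <- character(nrow(config$samples))
  for (si in seq_len(nrow(config$samples))) {
    sid <- config$samples$sample_id[si]
    set.seed(sample_seeds[si])
    iso_n <- as.vector(stats::rmultinom(1, config$n_fragments, w))
    recs <- list()
    frag0 <- 0L
    for (ii in seq_along(config$isoforms)) {
      if (iso_n[ii] == 0L) next
      pl <- .sample_placements(iso_n[ii], dists[[ii]])
      g <- geoms[[ii]]
      r1 <- .project_reads(pl$p, pl$p + R - 1L, g)
      r2 <- .project_reads(pl$q - R + 1L, pl$q, g)
      fs <- .t2g(pl$p, g); fe <- .t2g(pl$q, g)
      qn <- sprintf("%s_f%07d", sid, frag0 + seq_len(iso_n[ii]))
      recs[[length(recs) + 1L]] <- data.table::data.table(
        qname = c(qn, qn),
        flag = rep(c(99L, 147L), each = iso_n[ii]),
        pos = c(r1$pos, r2$pos), cigar = c(r1$cigar, r2$cigar),
        pnext = c(r2$pos, r1$pos),
        tlen = c(fe - fs + 1L, -(fe - fs + 1L)))
      frag0 <- frag0 + iso_n[ii]
    }
    dt <- data.table::rbindlist(recs)
    data.table::setorder(dt, pos, qname, flag)
    lines <- sprintf("%s\t%d\t%s\t%d\t255\t%s\t=\t%d\t%d\t*\t*",
                     dt$qname, dt$flag, model$chrom, dt$pos, dt$cigar,
                     dt$pnext, dt$tlen)
    hdr <- c("@HD\tVN:1.6\tSO:coordinate",
             sprintf("@SQ\tSN:%s\tLN:%d", model$chrom, config$chrom_len))
    sam_paths[si] <- file.path(out_dir, paste0(sid, ".sam"))
    writeLines(c(hdr, lines), sam_paths[si])
  }
  names(sam_paths) <- config$samples$sample_id
  truth <- truth_set(config)
  sheet <- data.frame(sample_id = config$samples$sample_id,
                      path = unname(sam_paths),
                      condition = config$samples$condition,
                      stringsAsFactors = FALSE)
  if (write_truth) {
    utils::write.table(truth$junctions, file.path(out_dir, "truth_junctions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(truth$features, file.path(out_dir, "truth_features.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_sim_config(config, file.path(out_dir, "sim_config.json"))
    utils::write.table(sheet, file.path(out_dir, "samples.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(sam = sam_paths, truth = truth, sheet = sheet, config = config)
}

#' Save / reload a simulation configuration as JSON
#'
#' @param config a [sim_config()].
#' @param path JSON file path.
#' @return `path` (write) or a `sim_config` (read).
#' @export
write_sim_config <- function(config, path) {
  x <- list(
    model = list(gene_id = config$model$gene_id,
                 transcript_id = config$model$transcript_id,
                 chrom = config$model$chrom, strand = config$model$strand,
                 exons = cbind(start(config$model$exons), end(config$model$exons))),
    isoforms = lapply(config$isoforms, function(i)
      list(name = i$name, weight = i$weight, unspliced = i$unspliced,
           exon_chain = i$exon_chain)),
    samples = config$samples,
    n_fragments = config$n_fragments, read_length = config$read_length,
    frag_mean = config$frag_mean, frag_sd = config$frag_sd,
    three_prime_bias = config$three_prime_bias, seed = config$seed,
    chrom_len = config$chrom_len, truth_labels = config$truth_labels)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- gene_model(x$model$exons, x$model$chrom, x$model$strand,
                      x$model$gene_id, x$model$transcript_id)
  isoforms <- lapply(x$isoforms, function(i)
    isoform_spec(i$name, if (isTRUE(i$unspliced)) NULL else i$exon_chain,
                 i$weight, isTRUE(i$unspliced)))
  sim_config(model, isoforms, x$samples, x$n_fragments, x$read_length,
             x$frag_mean, x$frag_sd, x$three_prime_bias, x$seed, x$chrom_len,
             x$truth_labels)
}
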