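# Molecular diversity statistics: allele frequencies, polymorphism census,
# molecular variance / AMOVA, genetic distances, LD, LD-decay fit,
# cross-chromosome LD, linkage-phase similarity.

#' Allele frequencies of a population
#'
#' @param pop a `gc_pop` (or a dosage matrix coded 0/1/2).
#' @return numeric vector: mean capture-allele dose / 2 per marker.
#' @export
allele_frequencies <- function(pop) {
  d <- if (inherits(pop, "gc_pop")) dose_matrix(pop) else pop
  if (nrow(d) == 0) stop_gc("empty population")
  colMeans(d) / 2
}

#' Gamete-resampling polymorphism census
#'
#' For each replicate, samples `n_gametes` gametes without replacement from
#' each population, classifies every marker by the set of populations in
#' which it segregates (both alleles present among the sampled gametes),
#' and tallies the Venn regions.  Additionally counts, among markers
#' segregating only in the last population (typically GC), those
#' attributable to the capture line: the other populations' samples are
#' monomorphic for the non-capture allele (dose 0).  Defaults follow the
#' 80-gamete, 500-replicate resampling scheme.
#'
#' @param populations named list of `gc_pop`s (e.g. `list(LS=, DH=, GC=)`).
#' @param n_gametes gametes sampled per population per replicate.
#' @param n_reps number of replicates.
#' @param seed integer seed.
#' @return list with `mean` and `sd` (named vectors over Venn regions,
#'   names like `"LS:DH:GC"`), `capture_private` (mean, sd) and
#'   `n_polymorphic` (mean count of markers polymorphic anywhere).
#' @export
polymorphism_census <- function(populations, n_gametes = 80, n_reps = 500,
                                seed = NULL) {
  stopifnot(length(populations) >= 2, !is.null(names(populations)))
  gam <- lapply(populations, pop_gametes)
  for (nm in names(gam)) {
    if (nrow(gam[[nm]]) < n_gametes) {
      stop_gc("population ", nm, " supplies fewer than n_gametes gametes")
    }
  }
  pops <- names(populations)
  k <- length(pops)
  region_names <- apply(as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), k)))[-1, , drop = FALSE],
                        1, function(r) paste(pops[r], collapse = ":"))
  # markers fixed for the non-capture allele in every population but the last
  # (classification uses the full line sets; segregation status is resampled)
  mono_zero <- rowSums(sapply(seq_len(k - 1), function(j) {
    colMeans(gam[[j]]) == 0
  })) == (k - 1)
  with_seed(seed, {
    tallies <- matrix(0, n_reps, length(region_names),
                      dimnames = list(NULL, region_names))
    cap_priv <- numeric(n_reps)
    n_poly <- numeric(n_reps)
    for (rep_i in seq_len(n_reps)) {
      seg <- sapply(gam, function(g) {
        s <- g[sample.int(nrow(g), n_gametes), , drop = FALSE]
        f <- colMeans(s)
        f > 0 & f < 1
      })
      any_seg <- rowSums(seg) > 0
      n_poly[rep_i] <- sum(any_seg)
      code <- apply(seg, 1, function(r) paste(pops[r], collapse = ":"))
      tab <- table(factor(code[any_seg], levels = region_names))
      tallies[rep_i, ] <- as.numeric(tab)
      only_last <- seg[, k] & rowSums(seg[, -k, drop = FALSE]) == 0
      cap_priv[rep_i] <- sum(only_last & mono_zero)
    }
    list(mean = colMeans(tallies), sd = apply(tallies, 2, stats::sd),
         capture_private = c(mean = mean(cap_priv), sd = stats::sd(cap_priv)),
         n_polymorphic = mean(n_poly))
  })
}

#' Molecular variance and AMOVA decomposition
#'
#' Per-locus molecular variance `2 f (1 - f)` from the realized allele
#' frequency, and an analysis of molecular variance on squared Euclidean
#' allele distances partitioning variation between individuals and within
#' individuals (between the two gametes of an individual).  Method-of-
#' moments components that come out negative are truncated at zero and
#' flagged.
#'
#' @param pop a diploid `gc_pop`.
#' @return list with `per_locus` (2f(1-f) per marker), `total` (their sum),
#'   and `amova`: data.frame with sums of squares, df, and variance
#'   components for between- and within-individual strata, plus a
#'   `truncated` flag.
#' @export
molecular_variance <- function(pop) {
  g <- pop_gametes(pop)
  n <- pop_size(pop)
  f <- colMeans(g)
  per_locus <- 2 * f * (1 - f)
  ind <- rep(seq_len(n), each = 2L)
  # per-locus sums of squares, accumulated over loci
  gm <- matrix(colMeans(g), nrow = 2L * n, ncol = ncol(g), byrow = TRUE)
  ss_total <- sum((g - gm)^2)
  im <- (pop$geno_a + pop$geno_b) / 2
  ind_mean <- im[ind, , drop = FALSE]
  ss_within <- sum((g - ind_mean)^2)
  ss_between <- ss_total - ss_within
  df_between <- n - 1
  df_within <- n
  ms_b <- ss_between / df_between
  ms_w <- ss_within / df_within
  sigma_w <- ms_w
  sigma_b <- (ms_b - ms_w) / 2
  truncated <- sigma_b < 0
  if (truncated) sigma_b <- 0
  amova <- data.frame(
    stratum = c("between_individuals", "within_individuals"),
    df = c(df_between, df_within),
    SS = c(ss_between, ss_within),
    MS = c(ms_b, ms_w),
    variance = c(sigma_b, sigma_w),
    stringsAsFactors = FALSE)
  list(per_locus = per_locus, total = sum(per_locus), amova = amova,
       truncated = truncated)
}

#' Genetic distance (1 - simple matching)
#'
#' Per-locus allele-sharing score: 1 for identical genotypes, 0.5 when the
#' two genotypes share one allele, 0 otherwise; `SM` is the mean score over
#' loci and `GD = 1 - SM`.  On 0/1/2 dosages the score is
#' `1 - |g_a - g_b| / 2`.
#'
#' @param genotype_a,genotype_b dosage vectors over a shared marker set.
#' @return GD in `[0, 1]`.
#' @export
genetic_distance <- function(genotype_a, genotype_b) {
  if (length(genotype_a) == 0) stop_gc("empty marker set")
  mean(abs(genotype_a - genotype_b)) / 2
}

#' Pairwise genetic-distance matrix
#'
#' @param pop a `gc_pop`, or a dosage matrix; two populations may be given
#'   as a list to obtain the cross-population block as well (rows are the
#'   concatenated individuals).
#' @param marker_subset optional marker indices (non-empty).
#' @return a symmetric matrix of GD values.
#' @export
genetic_distance_matrix <- function(pop, marker_subset = NULL) {
  d <- if (inherits(pop, "gc_pop")) dose_matrix(pop)
       else if (is.list(pop)) do.call(rbind, lapply(pop, dose_matrix))
       else pop
  if (!is.null(marker_subset)) {
    if (length(marker_subset) == 0) stop_gc("empty marker subset")
    d <- d[, marker_subset, drop = FALSE]
  }
  as.matrix(stats::dist(d, method = "manhattan")) / (2 * ncol(d))
}

#' Pairwise LD within a physical distance
#'
#' Computes the signed correlation `r` of allele indicators across phased
#' gametes for every same-chromosome marker pair within `max_dist_bp`.
#' Monomorphic markers are skipped.
#'
#' @param gametes gamete x marker 0/1 matrix (e.g. [pop_gametes()] output,
#'   typically a sample of 94 gametes).
#' @param map the `gc_map` for the columns.
#' @param max_dist_bp maximum pair distance (default 1 Mb).
#' @return data.frame with `marker1`, `marker2`, `chrom`, `dist_bp`, `r`,
#'   `r2`.
#' @export
ld_pairs <- function(gametes, map, max_dist_bp = 1e6) {
  out <- list()
  for (i_ch in chrom_index(map)) {
    f <- colMeans(gametes[, i_ch, drop = FALSE])
    poly <- f > 0 & f < 1
    idx <- i_ch[poly]
    if (length(idx) < 2) next
    pos <- map$pos_bp[idx]
    cc <- suppressWarnings(stats::cor(gametes[, idx, drop = FALSE]))
    pr <- which(upper.tri(cc), arr.ind = TRUE)
    dist_bp <- pos[pr[, 2]] - pos[pr[, 1]]
    keep <- dist_bp <= max_dist_bp
    if (!any(keep)) next
    pr <- pr[keep, , drop = FALSE]
    out[[length(out) + 1L]] <- data.frame(
      marker1 = map$marker[idx[pr[, 1]]],
      marker2 = map$marker[idx[pr[, 2]]],
      chrom = map$chrom[idx[pr[, 1]]],
      dist_bp = dist_bp[keep],
      r = cc[pr],
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(marker1 = character(0), marker2 = character(0),
                      chrom = integer(0), dist_bp = numeric(0),
                      r = numeric(0), r2 = numeric(0)))
  }
  res <- do.call(rbind, out)
  res$r2 <- res$r^2
  rownames(res) <- NULL
  res
}

#' Expected r-squared under drift-recombination equilibrium
#'
#' The Hill-Weir expectation of `r^2` as a function of `C = rho * d`
#' (population recombination parameter times distance) including the
#' finite-sample term for `n` sampled gametes:
#' `E[r2] = ((10 + C) / ((2 + C)(11 + C))) *
#'          (1 + ((3 + C)(12 + 12 C + C^2)) / (n (2 + C)(11 + C)))`.
#'
#' @param C non-negative numeric.
#' @param n number of sampled gametes.
#' @export
hill_weir_er2 <- function(C, n) {
  ((10 + C) / ((2 + C) * (11 + C))) *
    (1 + ((3 + C) * (12 + 12 * C + C^2)) / (n * (2 + C) * (11 + C)))
}

#' Fit the LD decay curve and decay distance
#'
#' Nonlinear least-squares fit of the Hill-Weir expected `r^2` curve to raw
#' marker-pair `r^2` against physical distance, estimating the per-bp
#' recombination-scale coefficient `rho` (so `C = rho * dist_bp`).  The
#' decay distance `delta` is the distance at which the fitted curve
#' reaches `r^2 = 0.2`, found by bisection; if the curve stays above 0.2
#' within 10x the observed distance range `delta` is `NA` (flagged).
#' An optional `weighted = "bins"` mode fits bin-averaged `r^2` instead.
#'
#' @param ld_records data.frame from [ld_pairs()] (needs `dist_bp`, `r2`);
#'   at least 10 rows.
#' @param n_gametes gamete sample size used for the records.
#' @param weighted `"raw"` (default) or `"bins"` (1 kb bin averages).
#' @return object of class `ld_decay_fit`: list with `rho`, `n`,
#'   `delta_kb`, `converged`, `fit` (the `nls` object).
#' @export
fit_ld_decay <- function(ld_records, n_gametes, weighted = c("raw", "bins")) {
  weighted <- match.arg(weighted)
  if (nrow(ld_records) < 10) stop_gc("need at least 10 LD records")
  dat <- data.frame(d = ld_records$dist_bp, r2 = ld_records$r2)
  if (weighted == "bins") {
    b <- floor(dat$d / 1000)
    dat <- data.frame(d = tapply(dat$d, b, mean), r2 = tapply(dat$r2, b, mean))
  }
  n <- n_gametes
  start_rho <- 1 / max(stats::median(dat$d), 1)
  fit <- minpack.lm::nlsLM(r2 ~ hill_weir_er2(rho * d, n),
                           data = dat, start = list(rho = start_rho),
                           lower = 1e-15, control = minpack.lm::nls.lm.control(maxiter = 200))
  rho <- stats::coef(fit)[["rho"]]
  dmax <- 10 * max(dat$d)
  delta <- NA_real_
  if (hill_weir_er2(rho * dmax, n) < 0.2 && hill_weir_er2(0, n) > 0.2) {
    delta <- stats::uniroot(function(d) hill_weir_er2(rho * d, n) - 0.2,
                            c(1e-6, dmax), tol = 1e-6)$root / 1000
  }
  structure(list(rho = rho, n = n, delta_kb = delta,
                 converged = isTRUE(fit$convInfo$isConv), fit = fit),
            class = "ld_decay_fit")
}

#' @export
print.ld_decay_fit <- function(x, ...) {
  cat(sprintf("LD decay fit (Hill-Weir, n = %d gametes): rho = %.3g /bp, delta(r2 = 0.2) = %s kb\n",
              x$n, x$rho,
              if (is.na(x$delta_kb)) "undefined" else sprintf("%.1f", x$delta_kb)))
  invisible(x)
}

#' Mean LD between chromosomes
#'
#' Samples `n_pairs_per_chrom_pair` marker pairs (markers drawn with
#' replacement) for every pairwise combination of chromosomes and returns
#' the mean `r^2`; with independent chromosomes this sits at the `1/n`
#' sampling-noise floor.
#'
#' @param gametes gamete x marker 0/1 matrix.
#' @param map the `gc_map`.
#' @param n_pairs_per_chrom_pair pairs sampled per chromosome pair.
#' @param seed integer seed.
#' @return list with `mean_r2`, `n_chrom_pairs`, `n_pairs`.
#' @export
cross_chromosome_ld <- function(gametes, map, n_pairs_per_chrom_pair = 5000,
                                seed = NULL) {
  idx <- chrom_index(map)
  if (length(idx) < 2) stop_gc("need at least 2 chromosomes")
  poly <- lapply(idx, function(i) {
    f <- colMeans(gametes[, i, drop = FALSE])
    i[f > 0 & f < 1]
  })
  combos <- utils::combn(length(idx), 2)
  with_seed(seed, {
    r2s <- numeric(0)
    for (k in seq_len(ncol(combos))) {
      i1 <- poly[[combos[1, k]]]; i2 <- poly[[combos[2, k]]]
      if (length(i1) == 0 || length(i2) == 0) next
      m1 <- sample(i1, n_pairs_per_chrom_pair, replace = TRUE)
      m2 <- sample(i2, n_pairs_per_chrom_pair, replace = TRUE)
      # column-wise correlations of the paired markers
      x <- gametes[, m1, drop = FALSE]; y <- gametes[, m2, drop = FALSE]
      xc <- sweep(x, 2, colMeans(x)); yc <- sweep(y, 2, colMeans(y))
      r <- colSums(xc * yc) /
        sqrt(colSums(xc^2) * colSums(yc^2))
      r2s <- c(r2s, r^2)
    }
    list(mean_r2 = mean(r2s), n_chrom_pairs = ncol(combos),
         n_pairs = length(r2s))
  })
}

#' Linkage-phase similarity between two populations
#'
#' For marker pairs polymorphic in both populations, grouped into
#' half-open physical-distance bins `[lo, hi)` of `bin_kb` up to
#' `max_dist_kb`, LPS is the proportion of pairs whose signed LD
#' correlation `r` has the same sign in both populations
#' (`mode = "same_sign"`, default) or the correlation of the signed `r`
#' values (`mode = "correlation"`).  Consistent allele orientation is
#' guaranteed by the package-wide capture-allele coding.  Bins without
#' shared polymorphic pairs are returned as `NA` with `n_pairs = 0`.
#'
#' @param gametes_A,gametes_B gamete x marker 0/1 matrices over the same
#'   map.
#' @param map the `gc_map`.
#' @param bin_kb bin width in kb (default 10).
#' @param max_dist_kb maximum distance in kb (default 1000).
#' @param mode `"same_sign"` or `"correlation"`.
#' @return data.frame with `bin_lo_kb`, `bin_hi_kb`, `lps`, `n_pairs` and
#'   attribute `mode`.
#' @export
linkage_phase_similarity <- function(gametes_A, gametes_B, map, bin_kb = 10,
                                     max_dist_kb = 1000,
                                     mode = c("same_sign", "correlation")) {
  mode <- match.arg(mode)
  max_bp <- max_dist_kb * 1000
  pairs <- list()
  for (i_ch in chrom_index(map)) {
    fa <- colMeans(gametes_A[, i_ch, drop = FALSE])
    fb <- colMeans(gametes_B[, i_ch, drop = FALSE])
    poly <- fa > 0 & fa < 1 & fb > 0 & fb < 1
    idx <- i_ch[poly]
    if (length(idx) < 2) next
    pos <- map$pos_bp[idx]
    ca <- suppressWarnings(stats::cor(gametes_A[, idx, drop = FALSE]))
    cb <- suppressWarnings(stats::cor(gametes_B[, idx, drop = FALSE]))
    pr <- which(upper.tri(ca), arr.ind = TRUE)
    dist_bp <- pos[pr[, 2]] - pos[pr[, 1]]
    keep <- dist_bp < max_bp
    pairs[[length(pairs) + 1L]] <- data.frame(
      dist_bp = dist_bp[keep], rA = ca[pr][keep], rB = cb[pr][keep])
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs)
           else data.frame(dist_bp = numeric(0), rA = numeric(0), rB = numeric(0))
  edges <- seq(0, max_dist_kb, by = bin_kb) * 1000
  bin <- findInterval(pairs$dist_bp, edges, rightmost.closed = FALSE)
  out <- data.frame(bin_lo_kb = edges[-length(edges)] / 1000,
                    bin_hi_kb = edges[-1] / 1000,
                    lps = NA_real_, n_pairs = 0L)
  for (b in seq_len(nrow(out))) {
    sel <- bin == b & !is.na(pairs$rA) & !is.na(pairs$rB)
    nb <- sum(sel)
    out$n_pairs[b] <- nb
    if (nb == 0) next
    out$lps[b] <- switch(mode,
      same_sign = mean(sign(pairs$rA[sel]) == sign(pairs$rB[sel])),
      correlation = if (nb >= 3) suppressWarnings(stats::cor(pairs$rA[sel], pairs$rB[sel])) else NA_real_)
  }
  attr(out, "mode") <- mode
  out
}
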