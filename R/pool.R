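# Ancestral landrace gamete pool.
#
# A `gamete_pool` is a list:
#   gametes : integer matrix (gamete x marker), alleles coded 0/1 where,
#             once a capture line exists, allele 1 is by convention the
#             capture-line allele at every marker,
#   map     : the gc_map the columns refer to,
#   p       : realized frequency of allele 1 per marker (recomputed from the
#             gametes, never assumed).

new_pool <- function(gametes, map) {
  structure(
    list(gametes = gametes, map = map, p = colMeans(gametes)),
    class = "gamete_pool"
  )
}

#' Simulate the ancestral landrace gamete pool
#'
#' Target allele frequencies are drawn from a configurable spectrum, founder
#' gametes are sampled independently per locus at those frequencies (linkage
#' equilibrium), and `burnin_generations` rounds of random mating with
#' recombination within a finite pool then build up within-chromosome LD by
#' drift while leaving cross-chromosome LD negligible.  Each new generation
#' consists of `pool_size` gametes, each produced by one meiosis of a
#' diploid formed from two distinct random gametes of the previous
#' generation.  The returned `p` is the realized post-burn-in frequency.
#'
#' @param map a `gc_map`.
#' @param pool_size even number of gametes (>= 4).
#' @param freq_spectrum list describing the sampling distribution of the
#'   founder allele frequency: `list(type = "beta_u")` (default;
#'   Beta(0.5, 0.5) truncated to `[0.02, 0.98]`, the U-shaped spectrum
#'   typical of landraces), `list(type = "uniform", min =, max =)`, or
#'   `list(type = "fixed", p =)` with a scalar or per-marker vector.
#' @param burnin_generations non-negative number of random-mating rounds.
#' @param seed integer seed.
#' @return a `gamete_pool`.
#' @export
simulate_ancestral_pool <- function(map, pool_size,
                                    freq_spectrum = list(type = "beta_u"),
                                    burnin_generations = 0, seed = NULL) {
  if (pool_size < 4 || pool_size %% 2 != 0) stop_gc("pool_size must be an even number >= 4")
  if (burnin_generations < 0) stop_gc("burnin_generations must be >= 0")
  m <- n_markers(map)
  with_seed(seed, {
    p0 <- draw_freq_spectrum(freq_spectrum, m)
    gam <- matrix(stats::rbinom(pool_size * m, 1L, rep(p0, each = pool_size)),
                  nrow = pool_size, ncol = m)
    if (burnin_generations > 0) {
      cache <- map_cache(map)
      for (g in seq_len(burnin_generations)) {
        nxt <- matrix(0L, pool_size, m)
        for (k in seq_len(pool_size)) {
          par <- sample.int(pool_size, 2L)
          nxt[k, ] <- meiosis_core(gam[par[1L], ], gam[par[2L], ], cache)
        }
        gam <- nxt
      }
    }
    new_pool(gam, map)
  })
}

draw_freq_spectrum <- function(spec, m) {
  type <- spec$type %||% "beta_u"
  switch(type,
    beta_u = {
      lo <- spec$min %||% 0.02
      hi <- spec$max %||% 0.98
      q <- stats::runif(m, stats::pbeta(lo, 0.5, 0.5), stats::pbeta(hi, 0.5, 0.5))
      stats::qbeta(q, 0.5, 0.5)
    },
    uniform = stats::runif(m, spec$min %||% 0.05, spec$max %||% 0.95),
    fixed = rep_len(spec$p, m),
    stop_gc("unknown frequency spectrum type: ", type)
  )
}

#' @export
print.gamete_pool <- function(x, ...) {
  cat("Ancestral gamete pool:", nrow(x$gametes), "gametes x",
      ncol(x$gametes), "markers on", length(unique(x$map$chrom)),
      "chromosome(s)\n")
  cat("  mean allele-1 frequency:", round(mean(x$p), 4), "\n")
  invisible(x)
}

#' Create the inbred capture line and re-orient allele coding
#'
#' A fraction of markers is made private to the capture line: the pool is
#' fixed for allele 0 there (`p = 0`) while the capture line carries allele
#' 1, emulating capture-line alleles absent from the landrace.  At all other
#' markers the capture allele is a function of the pool frequency `p`:
#' `"random_gamete"` (default) takes one random gamete from the pool, so the
#' capture line is a possible landrace gamete (a random DH line from the
#' ancestral landrace) and carries each marker's allele 1 with probability
#' `p`; `"bernoulli_p"` draws each allele independently Bernoulli(`p`).
#' Finally the package-wide coding convention is re-established: wherever
#' the capture line carries allele 0 the column coding is flipped so that
#' allele 1 is the capture-line allele at every marker, and `p` is
#' re-expressed as the frequency of the capture-line allele.
#'
#' @param pool a `gamete_pool`.
#' @param private_fraction fraction of markers made private, in `[0, 0.2]`.
#' @param private_locus_rule `"random_gamete"` or `"bernoulli_p"`.
#' @param seed integer seed.
#' @return list with `capture` (a `capture_line`: all-ones haploid `genome`,
#'   `private_idx`, the map) and `pool` (the re-coded `gamete_pool`).
#' @export
make_capture_line <- function(pool, private_fraction = 0.03,
                              private_locus_rule = c("random_gamete", "bernoulli_p"),
                              seed = NULL) {
  if (private_fraction < 0 || private_fraction > 0.2) {
    stop_gc("private_fraction must be in [0, 0.2]")
  }
  rule <- match.arg(private_locus_rule)
  m <- ncol(pool$gametes)
  with_seed(seed, {
    n_priv <- round(private_fraction * m)
    priv <- if (n_priv > 0) sort(sample.int(m, n_priv)) else integer(0)
    cap <- switch(rule,
      random_gamete = pool$gametes[sample.int(nrow(pool$gametes), 1L), ],
      bernoulli_p = stats::rbinom(m, 1L, pool$p)
    )
    # private loci: landrace fixed for the non-capture allele
    if (n_priv > 0) {
      pool$gametes[, priv] <- 0L
      cap[priv] <- 1L
    }
    # coding flip: allele 1 := capture-line allele everywhere
    flip <- cap == 0L
    if (any(flip)) pool$gametes[, flip] <- 1L - pool$gametes[, flip]
    pool$p <- colMeans(pool$gametes)
    capture <- structure(
      list(genome = rep(1L, m), private_idx = priv, map = pool$map),
      class = "capture_line"
    )
    list(capture = capture, pool = pool)
  })
}

#' Sample diploid plants from the gamete pool
#'
#' Forms `n` diploid individuals from `2n` gametes drawn without
#' replacement, i.e. a random sample of the ancestral landrace (LS).
#'
#' @param pool a `gamete_pool`.
#' @param n number of plants; `2n` must not exceed the pool size.
#' @param seed integer seed.
#' @return a `gc_pop` of type `"LS"`.
#' @export
sample_plants <- function(pool, n, seed = NULL) {
  if (2 * n > nrow(pool$gametes)) stop_gc("2n exceeds the pool size")
  with_seed(seed, {
    pick <- sample.int(nrow(pool$gametes), 2L * n)
    new_population(
      geno_a = pool$gametes[pick[seq_len(n)], , drop = FALSE],
      geno_b = pool$gametes[pick[n + seq_len(n)], , drop = FALSE],
      type = "LS", map = pool$map
    )
  })
}
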