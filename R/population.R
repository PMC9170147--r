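# Populations of phased diploids.
#
# A `gc_pop` is a list:
#   geno_a, geno_b : integer matrices (individual x marker), the two phased
#                    gametes of each individual, allele 1 = capture allele,
#   type           : one of LS, DH, GC_S0, GC_S1, GC_S1_2, TESTCROSS,
#   family         : integer family id (S0 family for GC generations),
#   parents        : optional integer parent indices,
#   map            : the gc_map.

POP_TYPES <- c("LS", "DH", "GC_S0", "GC_S1", "GC_S1_2", "TESTCROSS")

new_population <- function(geno_a, geno_b, type, map,
                           family = seq_len(nrow(geno_a)), parents = NULL) {
  type <- match.arg(type, POP_TYPES)
  stopifnot(identical(dim(geno_a), dim(geno_b)), ncol(geno_a) == nrow(map))
  structure(
    list(geno_a = geno_a, geno_b = geno_b, type = type,
         family = family, parents = parents, map = map),
    class = "gc_pop"
  )
}

#' Number of individuals in a population
#' @param pop a `gc_pop`.
#' @export
pop_size <- function(pop) nrow(pop$geno_a)

#' Allele-dosage matrix of a population
#'
#' @param pop a `gc_pop`.
#' @return integer matrix (individual x marker) with entries 0/1/2, counts
#'   of the capture-line allele.
#' @export
dose_matrix <- function(pop) pop$geno_a + pop$geno_b

#' Stack the phased gametes of a population
#'
#' @param pop a `gc_pop`.
#' @return integer matrix (2N x markers); rows `2i-1`, `2i` are individual
#'   `i`'s two gametes.
#' @export
pop_gametes <- function(pop) {
  n <- pop_size(pop)
  out <- matrix(0L, 2L * n, ncol(pop$geno_a))
  out[seq(1L, 2L * n, by = 2L), ] <- pop$geno_a
  out[seq(2L, 2L * n, by = 2L), ] <- pop$geno_b
  out
}

#' @export
print.gc_pop <- function(x, ...) {
  cat(sprintf("<gc_pop> %s population: %d individuals x %d markers\n",
              x$type, pop_size(x), ncol(x$geno_a)))
  invisible(x)
}

# Derivations ----------------------------------------------------------

#' Derive doubled-haploid lines
#'
#' Each DH line is one random gamete duplicated into both gamete slots.
#' With `source = "meiosis"` the gamete is produced by meiosis of a random
#' plant of an LS population (or of a random diploid formed from the pool);
#' with `source = "pool"` (only when `from` is a `gamete_pool`) gametes are
#' drawn directly from the pool without replacement.
#'
#' @param from a `gamete_pool` or an LS `gc_pop`.
#' @param n_lines number of DH lines.
#' @param source `"meiosis"` or `"pool"`.
#' @param seed integer seed.
#' @return a `gc_pop` of type `"DH"`.
#' @export
derive_dh <- function(from, n_lines, source = c("meiosis", "pool"), seed = NULL) {
  source <- match.arg(source)
  if (n_lines < 1) stop_gc("n_lines must be >= 1")
  with_seed(seed, {
    if (inherits(from, "gamete_pool")) {
      if (source == "pool") {
        if (n_lines > nrow(from$gametes)) stop_gc("n_lines exceeds pool size")
        gam <- from$gametes[sample.int(nrow(from$gametes), n_lines), , drop = FALSE]
      } else {
        cache <- map_cache(from$map)
        gam <- matrix(0L, n_lines, ncol(from$gametes))
        for (k in seq_len(n_lines)) {
          par <- sample.int(nrow(from$gametes), 2L)
          gam[k, ] <- meiosis_core(from$gametes[par[1L], ], from$gametes[par[2L], ], cache)
        }
      }
      map <- from$map
    } else if (inherits(from, "gc_pop")) {
      if (pop_size(from) < 1) stop_gc("empty source population")
      cache <- map_cache(from$map)
      gam <- matrix(0L, n_lines, ncol(from$geno_a))
      for (k in seq_len(n_lines)) {
        i <- sample.int(pop_size(from), 1L)
        gam[k, ] <- meiosis_core(from$geno_a[i, ], from$geno_b[i, ], cache)
      }
      map <- from$map
    } else stop_gc("`from` must be a gamete_pool or gc_pop")
    new_population(gam, gam, "DH", map)
  })
}

#' Derive gamete-capture S0 and S1 generations
#'
#' Each S0 plant is a half-sib carrying the capture-line gamete and one
#' random landrace gamete (drawn from the pool without replacement across
#' families).  Each family then contributes exactly one S1 plant, produced
#' by selfing its S0 (two independent meioses).
#'
#' @param pool a `gamete_pool` (post `make_capture_line` coding).
#' @param capture a `capture_line`.
#' @param n_families number of S0 families.
#' @param seed integer seed.
#' @return list with `s0` and `s1`, both `gc_pop`s sharing family ids.
#' @export
derive_gc <- function(pool, capture, n_families, seed = NULL) {
  if (n_families < 1) stop_gc("n_families must be >= 1")
  if (n_families > nrow(pool$gametes)) stop_gc("n_families exceeds pool size")
  with_seed(seed, {
    m <- ncol(pool$gametes)
    cache <- map_cache(pool$map)
    land <- pool$gametes[sample.int(nrow(pool$gametes), n_families), , drop = FALSE]
    cap_mat <- matrix(rep(capture$genome, each = n_families), n_families, m)
    s0 <- new_population(cap_mat, land, "GC_S0", pool$map,
                         family = seq_len(n_families))
    s1a <- matrix(0L, n_families, m)
    s1b <- matrix(0L, n_families, m)
    for (k in seq_len(n_families)) {
      s1a[k, ] <- meiosis_core(s0$geno_a[k, ], s0$geno_b[k, ], cache)
      s1b[k, ] <- meiosis_core(s0$geno_a[k, ], s0$geno_b[k, ], cache)
    }
    s1 <- new_population(s1a, s1b, "GC_S1", pool$map,
                         family = seq_len(n_families),
                         parents = seq_len(n_families))
    list(s0 = s0, s1 = s1)
  })
}

#' Self progeny of one individual
#'
#' Produces `n_offspring` selfed offspring, each from an independent pair of
#' meioses of the same parent.  Used e.g. to represent an S1:2 entry by its
#' S2 family.
#'
#' @param individual list with `gamete_a`/`gamete_b` (or a row of a
#'   `gc_pop`, see [pop_individual()]).
#' @param n_offspring family size.
#' @param map a `gc_map`.
#' @param type population tag of the offspring (default `"GC_S1_2"`).
#' @param seed integer seed.
#' @return a `gc_pop` (all offspring share family id 1).
#' @export
self_progeny <- function(individual, n_offspring, map, type = "GC_S1_2",
                         seed = NULL) {
  if (n_offspring < 1) stop_gc("n_offspring must be >= 1")
  ga <- individual$gamete_a %||% individual[[1]]
  gb <- individual$gamete_b %||% individual[[2]]
  with_seed(seed, {
    cache <- map_cache(map)
    oa <- matrix(0L, n_offspring, length(ga))
    ob <- matrix(0L, n_offspring, length(ga))
    for (k in seq_len(n_offspring)) {
      oa[k, ] <- meiosis_core(ga, gb, cache)
      ob[k, ] <- meiosis_core(ga, gb, cache)
    }
    new_population(oa, ob, type, map, family = rep(1L, n_offspring))
  })
}

#' Extract one individual from a population
#' @param pop a `gc_pop`; @param i row index.
#' @return list with `gamete_a`, `gamete_b`.
#' @export
pop_individual <- function(pop, i) {
  list(gamete_a = pop$geno_a[i, ], gamete_b = pop$geno_b[i, ])
}

#' Testcross genotype with an inbred tester
#'
#' The testcross of a fully inbred entry is deterministic: its single
#' gamete type paired with the tester gamete.  For segregating entries the
#' testcross is represented by the entry's expected gamete (allele dosage /
#' 2) paired with the tester; downstream genotypic values then equal the
#' expectation over testcross progeny (a `sample` mode draws one actual
#' gamete instead).
#'
#' @param line list with `gamete_a`/`gamete_b` over the map.
#' @param tester_line 0/1 haploid vector, or a list whose two gametes are
#'   identical (heterozygous testers are rejected).
#' @param mode `"expected"` or `"sample"`.
#' @param map needed for `mode = "sample"`.
#' @param seed integer seed for `mode = "sample"`.
#' @return list with `gamete_a` (entry side; numeric expectation in
#'   expected mode), `gamete_b` (tester gamete).
#' @export
make_testcross <- function(line, tester_line, mode = c("expected", "sample"),
                           map = NULL, seed = NULL) {
  mode <- match.arg(mode)
  tg <- tester_gamete(tester_line)
  ga <- line$gamete_a %||% line[[1]]
  gb <- line$gamete_b %||% line[[2]]
  entry_side <- switch(mode,
    expected = (ga + gb) / 2,
    sample = {
      if (is.null(map)) stop_gc("map required for mode = 'sample'")
      with_seed(seed, meiosis_core(ga, gb, map_cache(map)))
    }
  )
  list(gamete_a = entry_side, gamete_b = tg)
}

tester_gamete <- function(tester_line) {
  if (is.list(tester_line)) {
    ta <- tester_line$gamete_a %||% tester_line[[1]]
    tb <- tester_line$gamete_b %||% tester_line[[2]]
    if (!identical(as.integer(ta), as.integer(tb))) {
      stop_gc("tester must be fully homozygous")
    }
    as.integer(ta)
  } else as.integer(tester_line)
}

#' Capture-line genome proportion of GC plants
#'
#' Proportion of capture-line alleles carried at diagnostic loci (markers
#' where the landrace is fixed for the non-capture allele, `p = 0`):
#' count of capture alleles / (2 x number of diagnostic loci).
#'
#' @param pop a `gc_pop`.
#' @param diagnostic_loci integer marker indices with `p = 0` in the
#'   landrace; non-empty.
#' @return numeric vector, one proportion in `[0, 1]` per individual.
#' @export
capture_genome_proportion <- function(pop, diagnostic_loci) {
  if (length(diagnostic_loci) == 0) stop_gc("empty diagnostic locus set")
  d <- dose_matrix(pop)[, diagnostic_loci, drop = FALSE]
  rowSums(d) / (2 * length(diagnostic_loci))
}
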