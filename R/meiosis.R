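# Meiosis under the Haldane (no-interference) model: crossover count per
# chromosome ~ Poisson(length in Morgans), breakpoints uniform on the cM
# scale, independent assortment across chromosomes.

# Precomputed per-chromosome structure used by the simulators so the map is
# not re-split at every meiosis.
map_cache <- function(map) {
  idx <- chrom_index(map)
  lapply(idx, function(i) {
    pos <- map$pos_cM[i]
    list(idx = i, pos = pos, len = max(pos) - min(pos), origin = min(pos))
  })
}

# one gamete from phased parent (ga, gb); `cache` from map_cache()
meiosis_core <- function(ga, gb, cache) {
  out <- ga
  for (ch in cache) {
    n_x <- stats::rpois(1L, ch$len / 100)
    start <- sample.int(2L, 1L)
    if (n_x == 0L) {
      if (start == 2L) out[ch$idx] <- gb[ch$idx]
      next
    }
    bp <- sort(stats::runif(n_x, 0, ch$len)) + ch$origin
    seg <- (start + findInterval(ch$pos, bp)) %% 2L
    take_b <- seg == 0L
    if (any(take_b)) out[ch$idx][take_b] <- gb[ch$idx][take_b]
  }
  out
}

#' Simulate one meiosis
#'
#' Draws a recombinant gamete from a phased diploid parent.  Crossovers per
#' chromosome are Poisson with mean equal to the chromosome's genetic length
#' in Morgans, breakpoints are uniform on the cM scale (no interference,
#' i.e. recombination fractions follow Haldane's map function), and
#' chromosomes assort independently.  A 0 cM chromosome yields no crossover
#' and a random parental chromosome.
#'
#' @param individual list with `gamete_a` and `gamete_b` 0/1 vectors over the
#'   map's markers (or a length-2 list).
#' @param map a `gc_map`.
#' @param seed optional integer seed.
#' @return 0/1 integer vector (one gamete).
#' @export
meiosis <- function(individual, map, seed = NULL) {
  ga <- individual$gamete_a %||% individual[[1]]
  gb <- individual$gamete_b %||% individual[[2]]
  if (length(ga) != nrow(map) || length(gb) != nrow(map)) {
    stop_gc("parent gametes must cover the map's markers")
  }
  with_seed(seed, meiosis_core(ga, gb, map_cache(map)))
}
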