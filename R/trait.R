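# Trait architecture and genotypic values.
#
# Per-QTL parameterization (capture-allele coding: marker allele 1 is the
# capture-line allele everywhere, allele 0 the alternative landrace allele):
#
#   class "landrace": the capture line carries a landrace allele (A1 := the
#     capture allele).  Genotype values per locus: A1A1 = +a, A2A2 = -a,
#     A1A2 = d12 (midpoint 0 + dominance).  delta = 0 by construction.
#   class "private": the landrace is fixed for allele 0 (A2, p = 0) and the
#     capture allele Ax is novel.  Values: AxAx = a + delta, A2A2 = -a,
#     A2Ax = delta/2 + d2x (midpoint + dominance).
#
# The dominance collapses d1x = 0, d2x = d12 at "landrace" loci follow from
# Ax == A1 and are implicit in the single heterozygote class of a biallelic
# marker.  The trait intercept xbar is the population base value.

new_trait <- function(qtl, a, delta, d12, d2x, class, tester_d, xbar, map) {
  v0 <- -a
  v2 <- a + delta
  mid <- (v0 + v2) / 2
  dd <- ifelse(class == "private", d2x, d12)
  v1 <- mid + dd
  structure(
    list(qtl = qtl, a = a, delta = delta, d12 = d12, d2x = d2x,
         class = class, tester_d = tester_d, xbar = xbar,
         v0 = v0, v1 = v1, v2 = v2, map = map),
    class = "trait_arch"
  )
}

#' Draw a trait architecture on the marker map
#'
#' Samples `n_qtl` QTL from the markers and assigns per-QTL effects.
#' `a` is the additive effect of the landrace allele contrast (half the
#' difference between the two homozygotes); at loci private to the capture
#' line the capture allele's effect is `a + delta`.  With
#' `dominance_spec = NULL` the trait is purely additive (all dominance
#' terms zero).
#'
#' @param map a `gc_map`.
#' @param n_qtl number of QTL (1 .. number of markers).
#' @param effect_distribution function `(n) -> numeric` for `a` (default
#'   standard normal), or a single number recycled.
#' @param dominance_spec `NULL`, or a list with optional entries `d12`,
#'   `d2x`, `delta`, `tester_d`, each a function `(n) -> numeric` or a
#'   number.
#' @param private_idx marker indices private to the capture line (their QTL
#'   get class `"private"`); typically `capture$private_idx`.
#' @param xbar trait intercept.
#' @param seed integer seed.
#' @return a `trait_arch`.
#' @export
assign_trait <- function(map, n_qtl, effect_distribution = stats::rnorm,
                         dominance_spec = NULL, private_idx = integer(0),
                         xbar = 0, seed = NULL) {
  if (n_qtl <= 0) stop_gc("n_qtl must be positive")
  if (n_qtl > nrow(map)) stop_gc("n_qtl exceeds the number of markers")
  draw <- function(spec, n, default = 0) {
    if (is.null(spec)) rep(default, n)
    else if (is.function(spec)) spec(n)
    else rep_len(spec, n)
  }
  with_seed(seed, {
    qtl <- sort(sample.int(nrow(map), n_qtl))
    a <- draw(effect_distribution, n_qtl)
    d12 <- draw(dominance_spec$d12, n_qtl)
    d2x <- draw(dominance_spec$d2x, n_qtl)
    delta <- draw(dominance_spec$delta, n_qtl)
    tester_d <- draw(dominance_spec$tester_d, n_qtl)
    cls <- ifelse(qtl %in% private_idx, "private", "landrace")
    delta[cls == "landrace"] <- 0
    new_trait(qtl, a, delta, d12, d2x, cls, tester_d, xbar, map)
  })
}

#' @export
print.trait_arch <- function(x, ...) {
  cat(sprintf("<trait_arch> %d QTL (%d private), xbar = %g\n",
              length(x$qtl), sum(x$class == "private"), x$xbar))
  invisible(x)
}

qtl_dose <- function(x, trait) {
  d <- if (inherits(x, "gc_pop")) dose_matrix(x)
       else if (is.list(x)) rbind((x$gamete_a %||% x[[1]]) + (x$gamete_b %||% x[[2]]))
       else rbind(x)
  if (ncol(d) == length(trait$qtl)) d else d[, trait$qtl, drop = FALSE]
}

#' Per se genotypic value
#'
#' Sums the per-locus genotype values over the QTL:
#' `xbar + sum(v[dose])` with `v = (v0, v1, v2)` per locus as documented in
#' [assign_trait()].  Fully additive traits give heterozygotes the
#' homozygote midpoint.
#'
#' @param x a `gc_pop`, an individual (list of two gametes), or a dosage
#'   vector/matrix over the trait's QTL (or over all markers).
#' @param trait a `trait_arch`.
#' @return numeric vector of genotypic values.
#' @export
genotypic_value_pp <- function(x, trait) {
  d <- qtl_dose(x, trait)
  if (!all(d %in% 0:2)) stop_gc("genotype doses must be coded 0/1/2 (capture-allele counts)")
  half <- (trait$v2 - trait$v0) / 2
  dom <- trait$v1 - (trait$v0 + trait$v2) / 2
  base <- trait$xbar + sum(trait$v0)
  as.numeric(base + d %*% half + (d == 1) %*% dom)
}

#' Genotypic value of an S1:2 entry (expected S2-family mean)
#'
#' An S1:2 entry is represented in the field by its S2 family; its entry
#' value is the expected mean genotypic value of that family, obtained from
#' the S1 genotype through the selfing transition (heterozygous loci
#' contribute `(v0 + 2 v1 + v2)/4`).
#'
#' @inheritParams genotypic_value_pp
#' @export
genotypic_value_s12 <- function(x, trait) {
  d <- qtl_dose(x, trait)
  half <- (trait$v2 - trait$v0) / 2
  het_val <- (trait$v0 + 2 * trait$v1 + trait$v2) / 4 - (trait$v0 + trait$v2) / 2
  base <- trait$xbar + sum(trait$v0)
  as.numeric(base + d %*% half + (d == 1) %*% het_val)
}

#' Testcross genotypic value
#'
#' Expected genotypic value of an entry's testcross progeny with a fully
#' homozygous tester: the expectation over the entry's gametes of the value
#' of (gamete, tester gamete) pairs.  Per locus the testcross plant is
#' either homozygous (additive value) or a tester heterozygote whose value
#' is the homozygote midpoint plus the tester-interaction dominance term
#' `tester_d`.  The result is linear in the entry's allele dosage, so the
#' testcross level is purely additive regardless of per se dominance.
#'
#' @param x entry/entries as in [genotypic_value_pp()].
#' @param trait a `trait_arch`.
#' @param tester 0/1 haploid vector over all markers or over the QTL (a
#'   homozygous inbred's gamete).
#' @return numeric vector of testcross values.
#' @export
genotypic_value_tp <- function(x, trait, tester) {
  d <- qtl_dose(x, trait)
  t_al <- tester_gamete(tester)
  if (length(t_al) != length(trait$qtl)) t_al <- t_al[trait$qtl]
  u <- tp_gamete_values(trait, t_al)
  # entry value = xbar + sum_j [ u0 + (u1 - u0) * dose/2 ]
  as.numeric(trait$xbar + sum(u$u0) + d %*% ((u$u1 - u$u0) / 2))
}

# gamete-level testcross values: u0 = value of (allele 0, tester),
# u1 = value of (allele 1, tester)
tp_gamete_values <- function(trait, t_al) {
  add <- function(dose) trait$v0 + (trait$v2 - trait$v0) * dose / 2
  mid <- (trait$v0 + trait$v2) / 2
  u0 <- ifelse(t_al == 0L, trait$v0, mid + trait$tester_d)
  u1 <- ifelse(t_al == 1L, trait$v2, mid + trait$tester_d)
  list(u0 = u0, u1 = u1, add = add)
}

#' Serialize / read a trait architecture as TSV
#' @param trait a `trait_arch`; @param path file path; @param map the map
#'   the QTL indices refer to (for reading).
#' @export
write_trait <- function(trait, path) {
  df <- data.frame(qtl = trait$qtl, class = trait$class, a = trait$a,
                   delta = trait$delta, d12 = trait$d12, d2x = trait$d2x,
                   tester_d = trait$tester_d)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# xbar=%.17g", trait$xbar), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trait
#' @export
read_trait <- function(path, map) {
  first <- readLines(path, n = 1L)
  xbar <- as.numeric(sub("# xbar=", "", first, fixed = TRUE))
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  new_trait(df$qtl, df$a, df$delta, df$d12, df$d2x, df$class, df$tester_d,
            xbar, map)
}
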