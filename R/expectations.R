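# Closed-form quantitative-genetic expectations for LS, DH and GC
# populations: population means and additive-variance decompositions per
# population type and performance level, molecular variances, and the
# allele-frequency thresholds governing when the gamete-capture population
# exceeds the landrace sample / DH population in variance.

# coefficient tables --------------------------------------------------
# mean columns: (a + delta), (p - q) a, [d], [d*]
.mean_coef <- rbind(
  LS       = c(0,   1,   1, 0),
  DH       = c(0,   1,   0, 0),
  GC_S1_2  = c(1/2, 1/2, 0, 1/4),
  GC_S1_inf= c(1/2, 1/2, 0, 0),
  FV2      = c(1,   0,   0, 0)
)
# variance coefficient pairs (sigma2_A, sigma2_A*)
.var_coef <- list(
  LS        = list(primary = c(1, 0),     within = c(0, 0),     total = c(1, 0)),
  DH        = list(primary = c(2, 0),     within = c(0, 0),     total = c(2, 0)),
  GC_S1_2   = list(primary = c(3/4, 1/4), within = c(1/8, 1/8), total = c(7/8, 3/8)),
  GC_S1_inf = list(primary = c(3/4, 1/4), within = c(1/4, 1/4), total = c(1, 1/2)),
  FV2       = list(primary = c(0, 0),     within = c(0, 0),     total = c(0, 0))
)

# per-locus parameter set for one performance level
locus_params <- function(a, delta, p, d12_eff, dstar_eff, offset = 0) {
  q <- 1 - p
  list(
    aD = a + delta,
    pq_a = (p - q) * a,
    d = 2 * p * q * d12_eff,
    dstar = q * dstar_eff,           # p*d1x + q*d2x with d1x = 0 (see trait.R)
    s2A = 2 * p * q * a^2,
    s2Astar = 2 * (q * a + delta / 2)^2,
    offset = offset
  )
}

#' Expected population means and variances (closed form)
#'
#' Evaluates the per-locus closed-form expectations of population means and
#' additive genetic variances for the landrace sample (LS), DH lines,
#' GC-S1:2 entries, fully inbred GC-S1:inf lines and the capture line, for
#' per se performance and (when a tester is supplied) testcross
#' performance, summing independent per-locus contributions over the QTL.
#'
#' The variance cells are exact under additivity at the respective level
#' (at the testcross level additivity always holds); per se dominance
#' affects the mean cells through the cumulated contributions
#' `[d] = sum 2 p q d12` and `[d*] = sum (p d1x + (1-p) d2x)`, not the
#' reported variance columns.  The per-locus sums assume linkage
#' equilibrium between QTL; if two QTL share a chromosome the report is
#' flagged `linked_qtl = TRUE` and the closed forms are approximate.
#'
#' @param trait a `trait_arch`.
#' @param p_vector landrace frequency of the capture allele at each QTL.
#' @param tester optional 0/1 tester gamete (over all markers or the QTL);
#'   adds the TP block.
#' @return a `pop_expectations`: data.frame with columns `population`,
#'   `level`, `mean`, `primary_var`, `within_var`, `total_var`, plus
#'   attributes `components` (summed sigma2_A, sigma2_A*, [d], [d*] per
#'   level) and `linked_qtl`.
#' @export
expected_population_stats <- function(trait, p_vector, tester = NULL) {
  if (any(p_vector < 0 | p_vector > 1)) stop_gc("p must lie in [0, 1]")
  stopifnot(length(p_vector) == length(trait$qtl))
  dom_dev <- trait$v1 - (trait$v0 + trait$v2) / 2
  pp <- locus_params(trait$a, trait$delta, p_vector, dom_dev, dom_dev)
  blocks <- list(PP = pp)
  if (!is.null(tester)) {
    t_al <- tester_gamete(tester)
    if (length(t_al) != length(trait$qtl)) t_al <- t_al[trait$qtl]
    u <- tp_gamete_values(trait, t_al)
    a_t <- (u$u1 - u$u0) / 2               # effective additive effect at TP level
    off <- (u$u0 + u$u1) / 2               # per-locus TP midpoint (into the mean)
    blocks$TP <- locus_params(a_t, rep(0, length(a_t)), p_vector,
                              rep(0, length(a_t)), rep(0, length(a_t)),
                              offset = off)
  }
  rows <- list()
  comps <- list()
  for (lev in names(blocks)) {
    b <- blocks[[lev]]
    for (popn in rownames(.mean_coef)) {
      mc <- .mean_coef[popn, ]
      mu <- trait$xbar + sum(b$offset) +
        sum(mc[1] * b$aD + mc[2] * b$pq_a + mc[3] * b$d + mc[4] * b$dstar)
      vc <- .var_coef[[popn]]
      v <- vapply(vc, function(co) sum(co[1] * b$s2A + co[2] * b$s2Astar), 0)
      rows[[paste(popn, lev)]] <- data.frame(
        population = popn, level = lev, mean = mu,
        primary_var = v[["primary"]], within_var = v[["within"]],
        total_var = v[["total"]], stringsAsFactors = FALSE)
    }
    comps[[lev]] <- c(sigma2_A = sum(b$s2A), sigma2_Astar = sum(b$s2Astar),
                      d = sum(b$d), dstar = sum(b$dstar))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  qtl_chrom <- trait$map$chrom[trait$qtl]
  structure(out,
            components = comps,
            linked_qtl = anyDuplicated(qtl_chrom) > 0,
            class = c("pop_expectations", "data.frame"))
}

#' @export
print.pop_expectations <- function(x, ...) {
  cat("Expected population means and additive variances\n")
  if (isTRUE(attr(x, "linked_qtl"))) {
    cat("  (QTL share chromosomes: linkage-equilibrium closed forms are approximate)\n")
  }
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Expected per-locus molecular variance
#'
#' `2 p (1 - p)` for the landrace sample and DH lines, and
#' `0.5 (1 + p) (1 - p)` for GC-S1 (equivalently `2 f (1 - f)` with
#' `f = (p + 1)/2`), with `p` the landrace frequency of the capture allele.
#'
#' @param pop_type one of `"LS"`, `"DH"`, `"GC_S1"`.
#' @param p landrace capture-allele frequency, vectorized.
#' @return numeric vector of per-locus variances.
#' @export
molecular_variance_expected <- function(pop_type, p) {
  if (any(p < 0 | p > 1)) stop_gc("p must lie in [0, 1]")
  switch(pop_type,
    LS = ,
    DH = 2 * p * (1 - p),
    GC_S1 = 0.5 * (1 + p) * (1 - p),
    stop_gc("unknown population type: ", pop_type)
  )
}

#' Expected GC-S1 capture-allele frequency
#'
#' `f = (p + 1) / 2`: the S0 carries the capture gamete plus a landrace
#' gamete, and selfing preserves the expected frequency.
#'
#' @param p landrace capture-allele frequency.
#' @export
expected_gc_frequency <- function(p) {
  if (any(p < 0 | p > 1)) stop_gc("p must lie in [0, 1]")
  (p + 1) / 2
}

#' Allele-frequency thresholds for GC superiority
#'
#' Solves numerically (bisection via [stats::uniroot()], tolerance 1e-12,
#' nothing hard-coded) for the two boundary frequencies:
#' `p_gc_vs_ls`, below which the GC-S1 per-locus molecular variance
#' `0.5 (1 + p)(1 - p)` exceeds the landrace value `2 p (1 - p)`; and
#' `p_gc_vs_dh`, below which the GC between-family genetic variance
#' (`3/4 sigma2_A + 1/4 sigma2_A*` with a capture allele carrying a
#' landrace allele, so `sigma2_A* = 2 (1 - p)^2 a^2`) exceeds the DH
#' variance `2 sigma2_A`.  Both are independent of the effect size `a`.
#'
#' @return named numeric vector `c(p_gc_vs_ls =, p_gc_vs_dh =)`.
#' @export
variance_thresholds <- function() {
  f_mol <- function(p) 0.5 * (1 + p) * (1 - p) - 2 * p * (1 - p)
  f_gen <- function(p) {
    q <- 1 - p
    (3 / 4) * (2 * p * q) + (1 / 4) * (2 * q^2) - 2 * (2 * p * q)
  }
  c(p_gc_vs_ls = stats::uniroot(f_mol, c(1e-9, 0.9), tol = 1e-12)$root,
    p_gc_vs_dh = stats::uniroot(f_gen, c(1e-9, 0.9), tol = 1e-12)$root)
}

#' Estimate cumulated dominance contributions from population means
#'
#' From the coefficient structure of the expected means:
#' `[d] = mean_LS - mean_DH` and
#' `[d*] = 4 (mean_GC - (mean_DH + mean_FV2)/2)` (the GC-S1:2 mean carries
#' `1/4 [d*]`, and lies exactly between the DH mean and the capture line
#' under additivity).
#'
#' @param mean_LS,mean_DH,mean_GC,mean_FV2 population means on a common
#'   scale (`mean_GC` refers to GC-S1:2 entries).
#' @return named vector `c(d =, dstar =)`.
#' @export
estimate_inbreeding_contributions <- function(mean_LS, mean_DH, mean_GC,
                                              mean_FV2) {
  c(d = mean_LS - mean_DH,
    dstar = 4 * (mean_GC - (mean_DH + mean_FV2) / 2))
}
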