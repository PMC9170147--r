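test_that("trait assignment is deterministic and respects the dominance spec", {
  map <- make_genetic_map(2, 100, 100, 100e6)
  t1 <- assign_trait(map, 20, seed = 1)
  t2 <- assign_trait(map, 20, seed = 1)
  expect_identical(t1$a, t2$a)
  expect_identical(t1$qtl, t2$qtl)
  # dominance_spec = NULL -> purely additive: heterozygote at the midpoint
  expect_equal(t1$v1, (t1$v0 + t1$v2) / 2)
  expect_error(assign_trait(map, 0), "positive")
  expect_error(assign_trait(map, 1000), "exceeds")
})

test_that("per se genotypic values follow the documented parameterization", {
  tr <- one_locus_trait(a = 2)
  # single landrace QTL, a = 2: homozygotes at +/- 2a contrast, het midpoint
  expect_equal(genotypic_value_pp(2, tr), 2)
  expect_equal(genotypic_value_pp(0, tr), -2)
  expect_equal(genotypic_value_pp(1, tr), 0)
  # enumerating all three landrace genotypes reproduces mean (p-q)a and
  # variance 2p(1-p)a^2 under HWE
  for (p in c(0.2, 0.7)) {
    probs <- c((1 - p)^2, 2 * p * (1 - p), p^2)
    vals <- genotypic_value_pp(rbind(0, 1, 2), tr)
    expect_equal(dist_mean(probs, vals), (p - (1 - p)) * 2)
    expect_equal(dist_var(probs, vals), 2 * p * (1 - p) * 4)
  }
  # heterozygote = midpoint + d12
  trd <- one_locus_trait(a = 1.5, d12 = 0.6)
  expect_equal(genotypic_value_pp(1, trd), 0.6)
  expect_error(genotypic_value_pp(3, tr), "0/1/2")
})

test_that("testcross values are additive and halve the contrast under the capture tester", {
  tr <- one_locus_trait(a = 1)
  # DH entries, tester = capture allele, no dominance: TP contrast is half
  # the PP contrast
  pp_contrast <- genotypic_value_pp(2, tr) - genotypic_value_pp(0, tr)
  tp_contrast <- genotypic_value_tp(2, tr, 1L) - genotypic_value_tp(0, tr, 1L)
  expect_equal(tp_contrast, pp_contrast / 2)
  # heterozygous entry: TP = mean of the two gametes' testcross values
  expect_equal(genotypic_value_tp(1, tr, 0L),
               (genotypic_value_tp(0, tr, 0L) + genotypic_value_tp(2, tr, 0L)) / 2)
  # with per se dominance the TP stays linear in dosage
  trd <- one_locus_trait(a = 1, d12 = 0.8, tester_d = 0.3)
  vals <- genotypic_value_tp(rbind(0, 1, 2), trd, 0L)
  expect_equal(vals[2], mean(vals[c(1, 3)]))
})

test_that("every Table-1 cell matches the single-locus enumeration oracle", {
  # means at arbitrary (a, delta, d); variance cells under additivity
  set.seed(20)
  grid_p <- seq(0, 1, by = 0.1)
  for (case in 1:6) {
    a <- rnorm(1, 0, 2)
    delta <- rnorm(1)
    d12 <- rnorm(1)
    d2x <- rnorm(1)
    private <- case %% 2 == 0
    for (p in if (private) 0 else grid_p) {
      # mean cells: arbitrary dominance
      tr <- one_locus_trait(a, delta = delta, d12 = d12, d2x = d2x,
                            private = private)
      es <- expected_population_stats(tr, p)
      v <- c(tr$v0, tr$v1, tr$v2)
      for (popn in c("LS", "DH", "GC_S1_2", "GC_S1_inf", "FV2")) {
        orc <- oracle_stats(popn, p, v)
        row <- es[es$population == popn & es$level == "PP", ]
        expect_equal(row$mean, orc$mean, tolerance = 1e-12)
      }
      # variance cells: additive at the per se level
      tra <- one_locus_trait(a, delta = delta, private = private)
      esa <- expected_population_stats(tra, p)
      va <- c(tra$v0, tra$v1, tra$v2)
      for (popn in c("LS", "DH", "GC_S1_2", "GC_S1_inf", "FV2")) {
        orc <- oracle_stats(popn, p, va)
        row <- esa[esa$population == popn & esa$level == "PP", ]
        expect_equal(row$primary_var, orc$primary, tolerance = 1e-10)
        expect_equal(row$within_var, orc$within, tolerance = 1e-10)
        expect_equal(row$total_var, orc$total, tolerance = 1e-10)
        expect_equal(row$total_var, row$primary_var + row$within_var,
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("testcross expectations match the oracle including tester dominance", {
  set.seed(21)
  for (case in 1:4) {
    a <- rnorm(1); delta <- rnorm(1); d12 <- rnorm(1); dt <- rnorm(1)
    private <- case > 2
    t_allele <- case %% 2
    for (p in if (private) 0 else c(0.15, 0.5, 0.85)) {
      tr <- one_locus_trait(a, delta = delta, d12 = d12, tester_d = dt,
                            private = private)
      es <- expected_population_stats(tr, p, tester = t_allele)
      v <- c(tr$v0, tr$v1, tr$v2)
      for (popn in c("LS", "DH", "GC_S1_2", "GC_S1_inf", "FV2")) {
        orc <- oracle_tp_stats(popn, p, v, t_allele, dt)
        row <- es[es$population == popn & es$level == "TP", ]
        expect_equal(row$mean, orc$mean, tolerance = 1e-10)
        expect_equal(row$primary_var, orc$primary, tolerance = 1e-10)
        expect_equal(row$total_var, orc$total, tolerance = 1e-10)
      }
      # TP variance is 1/4 of the PP allele-substitution variance for
      # inbred entries when tester dominance is absent
      tr0 <- one_locus_trait(a, delta = delta, private = private)
      es0 <- expected_population_stats(tr0, p, tester = 1L)
      dh_pp <- es0[es0$population == "DH" & es0$level == "PP", "total_var"]
      dh_tp <- es0[es0$population == "DH" & es0$level == "TP", "total_var"]
      expect_equal(dh_tp, dh_pp / 4, tolerance = 1e-10)
    }
  }
})

test_that("GC mean lies between DH and capture line exactly when [d*] = 0", {
  tr <- one_locus_trait(a = 1.3, delta = 0.4, private = TRUE)
  es <- expected_population_stats(tr, 0)
  m <- function(popn) es[es$population == popn & es$level == "PP", "mean"]
  expect_equal(m("GC_S1_2"), (m("DH") + m("FV2")) / 2, tolerance = 1e-12)
  # with capture-line dominance the GC mean shifts toward the dominant side
  trd <- one_locus_trait(a = 1.3, delta = 0.4, d2x = 0.9, private = TRUE)
  esd <- expected_population_stats(trd, 0)
  expect_gt(esd[esd$population == "GC_S1_2" & esd$level == "PP", "mean"],
            m("GC_S1_2"))
})

test_that("molecular variance expectations and thresholds reproduce the closed forms", {
  p <- seq(0, 1, by = 0.05)
  expect_equal(molecular_variance_expected("LS", p), 2 * p * (1 - p))
  expect_equal(molecular_variance_expected("DH", p),
               molecular_variance_expected("LS", p))
  expect_equal(molecular_variance_expected("GC_S1", 0), 0.5)
  expect_equal(molecular_variance_expected("GC_S1", 1), 0)
  expect_equal(molecular_variance_expected("LS", 1), 0)
  # GC formula equals 2 f (1 - f) at f = (p+1)/2
  f <- expected_gc_frequency(p)
  expect_equal(molecular_variance_expected("GC_S1", p), 2 * f * (1 - f))
  # equality of GC and LS at the boundary p = 1/3 (both 4/9)
  expect_equal(molecular_variance_expected("GC_S1", 1 / 3), 4 / 9)
  expect_equal(molecular_variance_expected("LS", 1 / 3), 4 / 9)
  expect_error(molecular_variance_expected("XX", 0.5), "unknown")
  expect_error(molecular_variance_expected("LS", 1.2), "0, 1")

  th <- variance_thresholds()
  expect_equal(th[["p_gc_vs_ls"]], 1 / 3, tolerance = 1e-9)
  expect_equal(th[["p_gc_vs_dh"]], 1 / 6, tolerance = 1e-9)
})

test_that("expected GC frequency is (p+1)/2 and monotone", {
  expect_equal(expected_gc_frequency(0), 0.5)
  expect_equal(expected_gc_frequency(1), 1)
  p <- seq(0, 1, 0.01)
  expect_true(all(diff(expected_gc_frequency(p)) > 0))
})

test_that("a random-DH capture line restores sigma2_A* = sigma2_A on average", {
  # closed-form identity: averaging sigma2_A* over the capture allele drawn
  # as a random landrace gamete (allele 1 kept w.p. p, else the coding flips
  # p -> 1-p and a -> -a) returns sigma2_A
  for (p in seq(0.05, 0.95, by = 0.1)) {
    a <- 1.7
    s2A <- 2 * p * (1 - p) * a^2
    keep <- 2 * ((1 - p) * a)^2          # capture carries allele 1
    flip <- 2 * (p * a)^2                # capture carries allele 0
    expect_equal(p * keep + (1 - p) * flip, s2A, tolerance = 1e-12)
  }
})

test_that("dominance contributions are recovered from population means", {
  # plug-in identities on expected means
  tr <- one_locus_trait(a = 0.8, d12 = 0.5)
  p <- 0.3
  es <- expected_population_stats(tr, p)
  m <- function(popn) es[es$population == popn & es$level == "PP", "mean"]
  est <- estimate_inbreeding_contributions(m("LS"), m("DH"), m("GC_S1_2"),
                                           m("FV2"))
  expect_equal(est[["d"]], 2 * p * (1 - p) * 0.5, tolerance = 1e-12)

  trp <- one_locus_trait(a = 0.8, delta = 0.3, d2x = 0.7, private = TRUE)
  esp <- expected_population_stats(trp, 0)
  mp <- function(popn) esp[esp$population == popn & esp$level == "PP", "mean"]
  estp <- estimate_inbreeding_contributions(mp("LS"), mp("DH"), mp("GC_S1_2"),
                                            mp("FV2"))
  expect_equal(estp[["dstar"]], 0.7, tolerance = 1e-12)  # (1-p) d2x at p = 0

  # simulation route: dominance at all QTL, [d]_hat from simulated means
  map <- make_genetic_map(40, 1, 50, 1e6)
  pool <- simulate_ancestral_pool(map, 5000,
                                  freq_spectrum = list(type = "uniform",
                                                       min = 0.1, max = 0.9),
                                  burnin_generations = 0, seed = 31)
  cl <- make_capture_line(pool, 0, seed = 32)
  tr2 <- assign_trait(cl$pool$map, 40, effect_distribution = function(n) rnorm(n),
                      dominance_spec = list(d12 = 0.4), seed = 33)
  ls <- sample_plants(cl$pool, 2500, seed = 34)
  dh <- derive_dh(cl$pool, 5000, source = "pool", seed = 35)
  d_hat <- mean(genotypic_value_pp(ls, tr2)) - mean(genotypic_value_pp(dh, tr2))
  p_qtl <- cl$pool$p[tr2$qtl]
  expect_equal(d_hat, sum(2 * p_qtl * (1 - p_qtl) * 0.4), tolerance = 0.25)

  # purely additive: both estimates vanish
  es_add <- expected_population_stats(one_locus_trait(a = 1), 0.4)
  ma <- function(popn) es_add[es_add$population == popn & es_add$level == "PP", "mean"]
  est0 <- estimate_inbreeding_contributions(ma("LS"), ma("DH"), ma("GC_S1_2"),
                                            ma("FV2"))
  expect_equal(unname(est0), c(0, 0), tolerance = 1e-12)
})

test_that("trait architectures round-trip through TSV", {
  map <- make_genetic_map(1, 50, 100, 50e6)
  tr <- assign_trait(map, 10,
                     dominance_spec = list(d12 = function(n) rnorm(n),
                                           delta = 0.2, tester_d = 0.1),
                     private_idx = c(3L, 7L), xbar = 5, seed = 44)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trait(tr, path)
  tr2 <- read_trait(path, map)
  expect_equal(tr2$a, tr$a)
  expect_equal(tr2$v1, tr$v1)
  expect_equal(tr2$xbar, tr$xbar)
  expect_equal(tr2$class, tr$class)
})
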