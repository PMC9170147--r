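# Independent single-locus enumeration oracles.
#
# All population genotype distributions at one biallelic locus (allele 1 =
# capture allele, landrace frequency p) are enumerated exactly from first
# principles: Hardy-Weinberg for the landrace sample, gamete doubling for
# DH, and the selfing transition matrix for the gamete-capture generations.
# Genotype values are an arbitrary triple (v0, v1, v2).  These oracles share
# no code with the package's closed-form coefficient tables.

dist_mean <- function(probs, vals) sum(probs * vals)
dist_var <- function(probs, vals) sum(probs * vals^2) - dist_mean(probs, vals)^2

# selfing transition: row = parent dose 0/1/2, col = offspring dose
selfing_T <- matrix(c(1, 0, 0,
                      1/4, 1/2, 1/4,
                      0, 0, 1), nrow = 3, byrow = TRUE)

# S1 dose distribution (one S1 per S0 family), landrace freq p:
# S0 dose is 2 w.p. p (capture gamete + allele-1 landrace gamete) else 1
s1_dose_dist <- function(p) {
  q <- 1 - p
  p * selfing_T[3, ] + q * selfing_T[2, ]
}

# entry value of an S1:2 line given its S1 dose: expected S2-family mean
s12_entry_values <- function(v) {
  c(v[1], sum(selfing_T[2, ] * v), v[3])
}

# oracle population statistics for per se values (v = c(v0,v1,v2)):
# mean, primary (between-entry/family) variance, expected within-family
# variance, total variance (among final sampled plants)
oracle_stats <- function(pop, p, v) {
  q <- 1 - p
  switch(pop,
    LS = {
      probs <- c(q^2, 2 * p * q, p^2)
      list(mean = dist_mean(probs, v), primary = dist_var(probs, v),
           within = 0, total = dist_var(probs, v))
    },
    DH = {
      probs <- c(q, 0, p)
      list(mean = dist_mean(probs, v), primary = dist_var(probs, v),
           within = 0, total = dist_var(probs, v))
    },
    GC_S1_2 = {
      s1 <- s1_dose_dist(p)
      ev <- s12_entry_values(v)
      within_each <- c(0, dist_var(selfing_T[2, ], v), 0)
      list(mean = dist_mean(s1, ev), primary = dist_var(s1, ev),
           within = sum(s1 * within_each),
           total = dist_var(s1, ev) + sum(s1 * within_each))
    },
    GC_S1_inf = {
      s1 <- s1_dose_dist(p)
      # inbred descendant dose: het -> 0/2 equally; entry mean given S1
      inbred_given_s1 <- rbind(c(1, 0, 0), c(1/2, 0, 1/2), c(0, 0, 1))
      ev <- inbred_given_s1 %*% v
      within_each <- apply(inbred_given_s1, 1, dist_var, vals = v)
      list(mean = sum(s1 * ev), primary = dist_var(s1, drop(ev)),
           within = sum(s1 * within_each),
           total = dist_var(s1, drop(ev)) + sum(s1 * within_each))
    },
    FV2 = list(mean = v[3], primary = 0, within = 0, total = 0)
  )
}

# testcross gamete values for tester allele t and tester dominance dt:
# value of testcross plant from entry gamete allele e
oracle_tc_values <- function(v, t, dt) {
  mid <- (v[1] + v[3]) / 2
  u0 <- if (t == 0) v[1] else mid + dt
  u1 <- if (t == 1) v[3] else mid + dt
  c(u0, u1)
}

# oracle TP stats: entry TP value is linear in the entry's (family-mean)
# dose g: u0 + (u1-u0) g / 2, applied to the same entry-dose distributions
oracle_tp_stats <- function(pop, p, v, t, dt) {
  u <- oracle_tc_values(v, t, dt)
  w <- c(u[1], mean(u), u[2])   # TP value at entry dose 0/1/2
  oracle_stats(pop, p, w)
}

# build a single-QTL trait on a 1-marker map
one_locus_trait <- function(a, delta = 0, d12 = 0, d2x = 0, tester_d = 0,
                            private = FALSE, xbar = 0) {
  map <- make_genetic_map(1, 1, 100, 1e6)
  assign_trait(map, 1, effect_distribution = a,
               dominance_spec = list(d12 = d12, d2x = d2x, delta = delta,
                                     tester_d = tester_d),
               private_idx = if (private) 1L else integer(0),
               xbar = xbar, seed = 1)
}

# small standard fixture: pool + capture line + populations
make_fixture <- function(n_chrom = 2, m = 120, pool_size = 200, burnin = 4,
                         private_fraction = 0.05, seed = 42) {
  map <- make_genetic_map(n_chrom, m / n_chrom, 120, 120e6)
  pool <- simulate_ancestral_pool(map, pool_size, burnin_generations = burnin,
                                  seed = seed)
  cl <- make_capture_line(pool, private_fraction, seed = seed + 1)
  list(map = map, pool = cl$pool, capture = cl$capture)
}
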