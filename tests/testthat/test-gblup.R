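# shared fixture: genotypes, relationship matrix and a heritable trait
gblup_fixture <- function(n = 120, m = 400, seed = 1) {
  withr::with_seed(seed, {
    p <- runif(m, 0.1, 0.9)
    geno <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m)
    rownames(geno) <- sprintf("L%04d", seq_len(n))
    U <- vanraden_g(geno)
    beta <- rnorm(m, 0, sqrt(1 / m))
    g <- drop(scale(geno %*% beta, scale = FALSE))
    y <- stats::setNames(g + rnorm(n, 0, sd(g) / 2), rownames(geno))
    list(geno = geno, U = U, g = g, y = y)
  })
}

test_that("VanRaden method-1 matrix has the expected structure", {
  fx <- gblup_fixture()
  U <- fx$U
  expect_true(isSymmetric(U, tol = 1e-10))
  expect_gt(min(eigen(U, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  # centering with own frequencies: row sums ~ 0
  expect_lt(max(abs(rowSums(U))), 1e-8)
  # invariant to marker order
  perm <- sample(ncol(fx$geno))
  expect_equal(vanraden_g(fx$geno[, perm]), U, tolerance = 1e-12)
  # duplicated inbred rows share their diagonal value off-diagonally
  inb <- rbind(a = rep(c(0, 2), 50), b = rep(c(0, 2), 50), c = rep(c(2, 0), 50))
  Ui <- vanraden_g(inb)
  expect_equal(Ui["a", "b"], Ui["a", "a"])
  expect_error(vanraden_g(matrix(2, 5, 4)), "monomorphic")
})

test_that("mean diagonal is ~1 for HWE samples and ~2 for DH lines", {
  map <- make_genetic_map(5, 200, 100, 100e6)
  pool <- simulate_ancestral_pool(map, 2000,
                                  freq_spectrum = list(type = "uniform",
                                                       min = 0.1, max = 0.9),
                                  burnin_generations = 0, seed = 2)
  ls <- sample_plants(pool, 1000, seed = 3)
  g_ls <- dose_matrix(ls); rownames(g_ls) <- sprintf("ls%d", 1:1000)
  expect_equal(mean(diag(vanraden_g(g_ls))), 1, tolerance = 0.03)
  dh <- derive_dh(pool, 1000, source = "pool", seed = 4)
  g_dh <- dose_matrix(dh); rownames(g_dh) <- sprintf("dh%d", 1:1000)
  expect_equal(mean(diag(vanraden_g(g_dh))), 2, tolerance = 0.06)
})

test_that("REML fit matches a brute-force grid-search oracle", {
  fx <- gblup_fixture(n = 50, m = 300, seed = 5)
  fit <- fit_gblup(fx$y, fx$U)
  # oracle: direct restricted likelihood on a fine grid of the variance
  # ratio, with matrix determinants (no shared code path)
  rll_direct <- function(delta) {
    n <- length(fx$y)
    V <- fx$U + diag(delta, n)
    Vi <- solve(V)
    X <- matrix(1, n, 1)
    xvx <- drop(t(X) %*% Vi %*% X)
    P <- Vi - Vi %*% X %*% t(X) %*% Vi / xvx
    ypy <- drop(t(fx$y) %*% P %*% fx$y)
    s2 <- ypy / (n - 1)
    -0.5 * ((n - 1) * (log(2 * pi) + log(s2) + 1) +
              determinant(V)$modulus + log(xvx))
  }
  grid <- 10^seq(-4, 4, by = 0.001)
  vals <- vapply(grid, rll_direct, 0)
  delta_oracle <- grid[which.max(vals)]
  expect_equal(fit$delta, delta_oracle, tolerance = 5e-3)
  expect_equal(fit$loglik, max(vals), tolerance = 1e-4)
  expect_gte(fit$loglik, max(vals) - 1e-3)
})

test_that("GBLUP equals ridge regression on centered markers", {
  fx <- gblup_fixture(n = 50, m = 500, seed = 6)
  fit <- fit_gblup(fx$y, fx$U)
  p <- colMeans(fx$geno) / 2
  keep <- p > 0 & p < 1
  W <- sweep(fx$geno[, keep], 2, 2 * p[keep])
  lam <- fit$delta * 2 * sum(p[keep] * (1 - p[keep]))
  yc <- fx$y - fit$mu
  beta <- solve(crossprod(W) + diag(lam, ncol(W)), crossprod(W, yc))
  u_ridge <- unname(drop(W %*% beta))
  expect_equal(unname(fit$u), u_ridge, tolerance = 1e-6)
})

test_that("variance parameters are recovered across replicates", {
  set.seed(7)
  n <- 200
  # one fixed relationship matrix, many trait replicates
  fx <- gblup_fixture(n = n, m = 600, seed = 8)
  L <- t(chol(fx$U + diag(1e-8, n)))
  reps <- 100
  est <- matrix(0, reps, 2)
  for (r in seq_len(reps)) {
    y <- stats::setNames(drop(L %*% rnorm(n, 0, 2)) + rnorm(n, 0, 1),
                         rownames(fx$U))
    f <- fit_gblup(y, fx$U)
    est[r, ] <- c(f$sigma2_g, f$sigma2_e)
  }
  mc_se <- apply(est, 2, sd) / sqrt(reps)
  expect_lt(abs(mean(est[, 1]) - 4), 2 * mc_se[1] + 0.05)
  expect_lt(abs(mean(est[, 2]) - 1), 2 * mc_se[2] + 0.05)
})

test_that("degenerate and null responses are flagged, LRT is calibrated", {
  fx <- gblup_fixture(n = 60, m = 200, seed = 9)
  flat <- stats::setNames(rep(3, 60), rownames(fx$U))
  f0 <- fit_gblup(flat, fx$U)
  expect_equal(f0$sigma2_g, 0)
  expect_equal(f0$lrt_p, 1)
  # pure noise: non-significant genomic variance most of the time
  set.seed(10)
  ps <- replicate(40, {
    y <- stats::setNames(rnorm(60), rownames(fx$U))
    fit_gblup(y, fx$U)$lrt_p
  })
  expect_gt(mean(ps > 0.05), 0.6)
  # y drawn from the GBLUP model itself: mostly significant
  set.seed(11)
  fx2 <- gblup_fixture(n = 120, m = 400, seed = 11)
  L <- t(chol(fx2$U + diag(1e-8, 120)))
  ps1 <- replicate(10, {
    y <- stats::setNames(drop(L %*% rnorm(120, 0, 2)) + rnorm(120, 0, 1),
                         rownames(fx2$U))
    fit_gblup(y, fx2$U)$lrt_p
  })
  expect_gt(mean(ps1 < 0.05), 0.6)
})

test_that("prediction of unphenotyped entries matches the joint-BLUP oracle", {
  fx <- gblup_fixture(n = 60, m = 500, seed = 11)
  train <- rownames(fx$U)[1:45]
  pred <- rownames(fx$U)[46:60]
  fit <- fit_gblup(fx$y[train], fx$U)
  u_hat <- predict_unphenotyped(fit, fx$U, train, pred, fx$y)
  # oracle: mixed-model equations on the full entry set with missing
  # phenotypes (incidence matrix selecting training rows)
  n <- 60
  Z <- diag(n)[match(train, rownames(fx$U)), ]
  Ui <- solve(fx$U + diag(1e-8, n))
  lhs <- crossprod(Z) + fit$delta * Ui
  rhs <- crossprod(Z, fx$y[train] - fit$mu)
  u_all <- solve(lhs, rhs)
  expect_equal(unname(u_hat), u_all[match(pred, rownames(fx$U))],
               tolerance = 1e-5)
  # invariance to entry ordering
  u_hat2 <- predict_unphenotyped(fit, fx$U, train, rev(pred), fx$y)
  expect_equal(u_hat2[pred], u_hat[pred])
  expect_error(predict_unphenotyped(fit, fx$U, train, train[1:2], fx$y),
               "disjoint")
})

test_that("prediction limits: shrinkage to zero and near-interpolation", {
  fx <- gblup_fixture(n = 40, m = 300, seed = 12)
  train <- rownames(fx$U)[1:39]
  fit <- fit_gblup(fx$y[train], fx$U)
  # lambda -> infinity: predictions -> 0 deviation
  fit_inf <- fit
  fit_inf$delta <- 1e10
  expect_lt(abs(predict_unphenotyped(fit_inf, fx$U, train,
                                     rownames(fx$U)[40], fx$y)), 1e-6)
  # duplicated entry at lambda -> 0 approaches the training entry's value
  U2 <- fx$U[c(1:39, 1), c(1:39, 1)]
  dimnames(U2) <- list(c(train, "copy"), c(train, "copy"))
  fit_small <- fit
  fit_small$delta <- 1e-6
  u_copy <- predict_unphenotyped(fit_small, U2, train, "copy", fx$y)
  expect_equal(unname(u_copy), unname(fx$y[train[1]] - fit$mu),
               tolerance = 1e-3)
})

test_that("prediction accuracy is the h2-corrected correlation", {
  set.seed(13)
  obs <- rnorm(50)
  expect_equal(prediction_accuracy(obs, obs, 1), 1)
  expect_equal(prediction_accuracy(obs, obs, 0.81),
               stats::cor(obs, obs) / 0.9)
  pred <- rnorm(50)
  expect_equal(prediction_accuracy(pred, obs, 0.81),
               stats::cor(obs, pred) / 0.9)
  expect_true(is.na(prediction_accuracy(rep(1, 50), obs, 0.9)))
  expect_error(prediction_accuracy(pred, obs, 0), "h2")
  expect_error(prediction_accuracy(pred[1:2], obs[1:2], 1), "3 pairs")
})

test_that("accuracy pipeline: noise gives zero, h2 = 1 approaches one", {
  fx <- gblup_fixture(n = 200, m = 400, seed = 14)
  set.seed(15)
  rho_noise <- replicate(100, {
    y <- stats::setNames(rnorm(200), rownames(fx$U))
    tr <- sample(rownames(fx$U), 150)
    pr <- setdiff(rownames(fx$U), tr)
    fit <- fit_gblup(y[tr], fx$U)
    prd <- predict_unphenotyped(fit, fx$U, tr, pr, y)
    prd <- prd + rnorm(length(prd), 0, 1e-10)  # guard zero-variance predictions
    prediction_accuracy(prd, y[pr], 0.9)
  })
  expect_lt(abs(mean(rho_noise)), 0.05)
})

test_that("within-population CV improves with N and flags noise", {
  # heritable trait: accuracy rises monotonically-in-mean with sample size
  fx <- gblup_fixture(n = 260, m = 300, seed = 16)
  h2 <- 0.9
  y <- stats::setNames(fx$g + rnorm(260, 0, sqrt(var(fx$g) * (1 - h2) / h2)),
                       rownames(fx$geno))
  dat <- list(geno = fx$geno, y = y, h2 = h2)
  rho_n <- sapply(c(50, 150, 250), function(N) {
    cv_within(dat, n_lines = N, reps = 3, seed = 17, n_repeats = 2)$mean_rho
  })
  expect_true(all(diff(rho_n) > 0))
  expect_gt(rho_n[3], 0.5)
  # all-noise phenotypes: accuracy ~ 0, many non-significant fits
  dat0 <- list(geno = fx$geno,
               y = stats::setNames(rnorm(260), rownames(fx$geno)), h2 = 0.9)
  cv0 <- cv_within(dat0, n_lines = 100, reps = 4, seed = 18, n_repeats = 2)
  expect_lt(abs(cv0$mean_rho), 0.25)
  expect_gt(sum(cv0$per_replicate$nonsig), 0)
  expect_error(cv_within(dat, n_lines = 5), ">= 10")
  # replicate bookkeeping
  expect_equal(nrow(cv0$per_replicate), 4)
})

test_that("across-population prediction agrees with matched within-population CV", {
  fx <- gblup_fixture(n = 300, m = 300, seed = 19)
  h2 <- 0.9
  y <- stats::setNames(fx$g + rnorm(300, 0, sqrt(var(fx$g) * (1 - h2) / h2)),
                       rownames(fx$geno))
  dat <- list(geno = fx$geno, y = y, h2 = h2)
  same <- cv_across(dat, dat, n_train = 200, n_predict = 50, reps = 8,
                    seed = 20)
  expect_equal(nrow(same$per_replicate), 8)
  within <- cv_within(dat, n_lines = 250, reps = 3, seed = 21, n_repeats = 2)
  expect_equal(same$mean_rho, within$mean_rho, tolerance = 0.15)
  expect_error(cv_across(dat, dat, n_train = 290, n_predict = 50), "exceeds")
})

test_that("opposite linkage phase destroys across-population transfer", {
  # two populations with the same QTL effects but markers in opposite phase:
  # train on one, predict the other
  withr::with_seed(22, {
    n <- 150; m <- 200
    hap_q <- matrix(rbinom(n * m, 1, 0.5), n, m)
    # population A: marker = QTL allele; population B: marker = 1 - QTL allele
    gA <- 2 * hap_q
    hap_q2 <- matrix(rbinom(n * m, 1, 0.5), n, m)
    gB <- 2 * (1 - hap_q2)
    rownames(gA) <- sprintf("A%03d", 1:n); rownames(gB) <- sprintf("B%03d", 1:n)
    beta <- rnorm(m, 0, sqrt(1 / m))
    yA <- stats::setNames(drop(2 * hap_q %*% beta), rownames(gA))
    yB <- stats::setNames(drop(2 * hap_q2 %*% beta), rownames(gB))
    datA <- list(geno = gA, y = yA + rnorm(n, 0, sd(yA) / 3), h2 = 0.9)
    datB <- list(geno = gB, y = yB + rnorm(n, 0, sd(yB) / 3), h2 = 0.9)
  })
  within_A <- cv_across(datA, datA, n_train = 100, n_predict = 25, reps = 6,
                        seed = 23)
  across <- cv_across(datA, datB, n_train = 100, n_predict = 25, reps = 6,
                      seed = 24)
  expect_gt(within_A$mean_rho, 0.5)
  # marker coded opposite to QTL: predictions anti-correlate
  expect_lt(across$mean_rho, -0.3)
})

test_that("combined training reports baseline and pooled accuracy per population", {
  fx <- gblup_fixture(n = 200, m = 250, seed = 25)
  h2 <- 0.8
  y <- stats::setNames(fx$g + rnorm(200, 0, sqrt(var(fx$g) * (1 - h2) / h2)),
                       rownames(fx$geno))
  split <- list(P1 = 1:100, P2 = 101:200)
  pops <- lapply(split, function(i) {
    list(geno = fx$geno[i, ], y = y[i], h2 = h2)
  })
  res <- cv_combined(pops, n_train = 60, n_predict = 20, reps = 4, seed = 26)
  expect_equal(res$population, c("P1", "P2"))
  expect_true(all(is.finite(res$baseline_rho)))
  expect_true(all(is.finite(res$combined_rho)))
  # two halves of one population: pooling should not hurt much
  expect_gt(mean(res$combined_rho), mean(res$baseline_rho) - 0.15)
  expect_error(cv_combined(pops["P1"]), "2 populations")
})

test_that("seeded CV runs are reproducible", {
  fx <- gblup_fixture(n = 80, m = 150, seed = 27)
  dat <- list(geno = fx$geno, y = fx$y, h2 = 0.9)
  a <- cv_within(dat, n_lines = 60, reps = 2, seed = 99, n_repeats = 1)
  b <- cv_within(dat, n_lines = 60, reps = 2, seed = 99, n_repeats = 1)
  expect_identical(a$per_replicate, b$per_replicate)
})
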