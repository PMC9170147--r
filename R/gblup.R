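# Genomic prediction: VanRaden method-1 relationship matrix, REML GBLUP
# via the spectral decomposition of the relationship matrix, prediction of
# unphenotyped entries, prediction accuracy, and the cross-validation
# scenario engine (within population, across populations / landraces,
# combined training sets).

#' VanRaden method-1 genomic relationship matrix
#'
#' `U = W W' / (2 sum p_j (1 - p_j))` with `W` the dosage matrix centered
#' by twice the allele frequency per column.  Frequencies default to the
#' supplied entry set itself; pass `allele_freqs` computed over a combined
#' entry set to treat several populations as one (the default in the
#' study-level pipeline).  Monomorphic columns (at the used frequencies)
#' are dropped.
#'
#' @param marker_matrix entries x markers dosage matrix (0/1/2, counts of
#'   the capture-line allele), rownames = entry ids.
#' @param allele_freqs optional per-marker frequencies.
#' @return symmetric relationship matrix with entry dimnames.
#' @export
vanraden_g <- function(marker_matrix, allele_freqs = NULL) {
  M <- as.matrix(marker_matrix)
  p <- allele_freqs %||% (colMeans(M) / 2)
  keep <- p > 0 & p < 1
  if (!any(keep)) stop_gc("all markers are monomorphic")
  M <- M[, keep, drop = FALSE]; p <- p[keep]
  W <- sweep(M, 2, 2 * p)
  U <- tcrossprod(W) / (2 * sum(p * (1 - p)))
  dimnames(U) <- list(rownames(marker_matrix), rownames(marker_matrix))
  U
}

# restricted log-likelihood of y = 1 mu + g + e at variance ratio
# delta = sigma2_e / sigma2_g, profiled over sigma2_g, in the rotated
# coordinates of U = Q Xi Q'
rll_profile <- function(delta, xi, yt, xt) {
  v <- xi + delta
  xvx <- sum(xt^2 / v)
  xvy <- sum(xt * yt / v)
  ypy <- sum(yt^2 / v) - xvy^2 / xvx
  n <- length(yt)
  s2 <- ypy / (n - 1)
  if (s2 <= 0) return(list(rll = -Inf, s2 = 0, mu = xvy / xvx))
  rll <- -0.5 * ((n - 1) * (log(2 * pi) + log(s2) + 1) +
                   sum(log(v)) + log(xvx))
  list(rll = rll, s2 = s2, mu = xvy / xvx)
}

#' Fit a GBLUP model by REML
#'
#' Fits `y = 1 mu + u + e` with `u ~ N(0, U sigma2_g)` and
#' `e ~ N(0, I sigma2_e)` to training BLUEs.  The restricted likelihood is
#' profiled over the variance ratio `delta = sigma2_e / sigma2_g` and
#' maximized by 1-D optimization of `log10(delta)` on `[-8, 8]` (tolerance
#' 1e-10) after one spectral decomposition of `U`.  The genomic variance
#' is tested by a likelihood-ratio test against the variance-only null
#' model `y = 1 mu + e` with a chi-square(1) reference (a boundary-
#' corrected 0.5 chi0:chi1 mixture is available via `lrt_boundary`).
#'
#' @param y named numeric vector of training BLUEs.
#' @param U relationship matrix over (at least) the training entries.
#' @param lrt_boundary use the 0.5 chi0:chi1 mixture p-value.
#' @return a `gblup` object: `mu`, `sigma2_g`, `sigma2_e`, `delta`, `u`
#'   (training genetic-value deviations), `loglik`, `loglik_null`,
#'   `lrt_p`, `converged`.
#' @export
fit_gblup <- function(y, U, lrt_boundary = FALSE) {
  ids <- names(y) %||% rownames(U)[seq_along(y)]
  U <- U[ids, ids]
  n <- length(y)
  if (stats::sd(y) < 1e-12) {
    return(structure(list(mu = mean(y), sigma2_g = 0, sigma2_e = 0,
                          delta = Inf, u = stats::setNames(rep(0, n), ids),
                          loglik = NA_real_, loglik_null = NA_real_,
                          lrt_p = 1, converged = TRUE, ids = ids,
                          eig = NULL),
                     class = "gblup"))
  }
  eig <- eigen(U, symmetric = TRUE)
  xi <- pmax(eig$values, 0)
  yt <- drop(crossprod(eig$vectors, y))
  xt <- drop(crossprod(eig$vectors, rep(1, n)))
  obj <- function(l10) rll_profile(10^l10, xi, yt, xt)$rll
  opt <- tryCatch(stats::optimize(obj, c(-8, 8), maximum = TRUE, tol = 1e-10),
                  error = function(e) NULL)
  if (is.null(opt)) {
    return(structure(list(mu = mean(y), sigma2_g = NA, sigma2_e = NA,
                          delta = NA, u = NULL, loglik = NA, loglik_null = NA,
                          lrt_p = NA, converged = FALSE, ids = ids, eig = NULL),
                     class = "gblup"))
  }
  delta <- 10^opt$maximum
  prof <- rll_profile(delta, xi, yt, xt)
  # null: V = sigma2_e I  (same restricted-likelihood formula, U absent)
  null <- rll_profile(1, rep(0, n), yt, xt)  # xi = 0, delta = 1 -> V = s2 I
  lrt <- max(0, 2 * (prof$rll - null$rll))
  p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  if (lrt_boundary) p <- 0.5 * p + if (lrt == 0) 0.5 else 0
  mu <- prof$mu
  r <- y - mu
  rt <- drop(crossprod(eig$vectors, r))
  u <- drop(eig$vectors %*% (xi / (xi + delta) * rt))
  structure(list(mu = mu, sigma2_g = prof$s2, sigma2_e = delta * prof$s2,
                 delta = delta, u = stats::setNames(u, ids),
                 loglik = prof$rll, loglik_null = null$rll, lrt_p = p,
                 converged = TRUE, ids = ids,
                 boundary = opt$maximum <= -8 + 1e-6 || opt$maximum >= 8 - 1e-6),
            class = "gblup")
}

#' @export
print.gblup <- function(x, ...) {
  cat(sprintf("GBLUP fit (n = %d): mu = %.4g, sigma2_g = %.4g, sigma2_e = %.4g\n",
              length(x$ids), x$mu, x$sigma2_g, x$sigma2_e))
  cat(sprintf("  REML logLik = %.4f, LRT p(sigma2_g > 0) = %.3g%s\n",
              x$loglik, x$lrt_p,
              if (!x$converged) " [did not converge]" else ""))
  invisible(x)
}

#' @export
coef.gblup <- function(object, ...) object$u

#' @export
summary.gblup <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Predict genetic values of unphenotyped entries
#'
#' `u_pred = U[pred, train] (U[train, train] + delta I)^-1 (y - mu)`.
#' The result is invariant to entry ordering.  A numerically singular
#' system gets a 1e-8 ridge on the diagonal (noted in the returned
#' attribute `jitter`).
#'
#' @param fit a `gblup` fit (its training entries must match
#'   `training_ids`).
#' @param U_full relationship matrix spanning training and prediction
#'   entries.
#' @param training_ids,prediction_ids disjoint entry id vectors.
#' @param y training BLUEs (defaults to the values used in `fit` being
#'   re-supplied; required because the fit stores only `u`).
#' @return named vector of predicted genetic-value deviations.
#' @export
predict_unphenotyped <- function(fit, U_full, training_ids, prediction_ids,
                                 y) {
  if (length(intersect(training_ids, prediction_ids)) > 0) {
    stop_gc("prediction entries must be disjoint from training entries")
  }
  Utt <- U_full[training_ids, training_ids]
  Upt <- U_full[prediction_ids, training_ids, drop = FALSE]
  r <- y[training_ids] - fit$mu
  if (!is.finite(fit$delta)) {            # sigma2_g = 0: no information
    return(stats::setNames(rep(0, length(prediction_ids)), prediction_ids))
  }
  A <- Utt + diag(fit$delta, length(training_ids))
  sol <- tryCatch(solve(A, r), error = function(e) NULL)
  jitter <- FALSE
  if (is.null(sol)) {
    sol <- solve(A + diag(1e-8, nrow(A)), r)
    jitter <- TRUE
  }
  out <- stats::setNames(drop(Upt %*% sol), prediction_ids)
  if (jitter) attr(out, "jitter") <- TRUE
  out
}

#' @export
predict.gblup <- function(object, U_full, prediction_ids, y, ...) {
  predict_unphenotyped(object, U_full, object$ids, prediction_ids, y)
}

#' Genomic prediction accuracy
#'
#' `rho = cor(observed, predicted) / sqrt(h2)`: the Pearson correlation of
#' observed phenotypes (BLUEs) of the prediction set with the estimated
#' genetic values, divided by the square root of the prediction set's
#' entry-mean heritability.  Values can exceed 1 by sampling noise and are
#' not clipped.  A zero-variance input yields `NA` (missing, flagged).
#'
#' @param predicted,observed_phenotypes numeric vectors (>= 3 pairs).
#' @param h2_prediction_set heritability in (0, 1].
#' @return numeric scalar (possibly `NA`).
#' @export
prediction_accuracy <- function(predicted, observed_phenotypes,
                                h2_prediction_set) {
  if (length(predicted) < 3) stop_gc("need >= 3 pairs")
  if (h2_prediction_set <= 0 || h2_prediction_set > 1) stop_gc("h2 must be in (0, 1]")
  if (stats::sd(predicted) < 1e-14 || stats::sd(observed_phenotypes) < 1e-14) {
    return(NA_real_)
  }
  stats::cor(observed_phenotypes, predicted) / sqrt(h2_prediction_set)
}

# shared bookkeeping for CV scenarios
new_cv_result <- function(scenario, per_rep, reps) {
  rho <- per_rep$rho
  structure(list(scenario = scenario, per_replicate = per_rep,
                 mean_rho = mean(rho, na.rm = TRUE),
                 q025 = stats::quantile(rho, 0.025, na.rm = TRUE, names = FALSE),
                 q975 = stats::quantile(rho, 0.975, na.rm = TRUE, names = FALSE),
                 n_missing = sum(is.na(rho)), reps = reps),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("Cross-validation:", x$scenario, "\n")
  cat(sprintf("  mean rho = %.3f  [95%% band %.3f, %.3f]  (%d replicates, %d missing, %d non-significant)\n",
              x$mean_rho, x$q025, x$q975, nrow(x$per_replicate), x$n_missing,
              sum(x$per_replicate$nonsig, na.rm = TRUE)))
  invisible(x)
}

# one k-fold x n_repeat CV inside a sampled entry set; returns mean rho over
# folds plus missing / non-significant counts
run_cv_folds <- function(geno, y, h2, n_folds = 5, n_repeats = 10,
                         freqs = NULL) {
  U <- vanraden_g(geno, freqs)
  ids <- rownames(geno)
  rhos <- c(); miss <- 0L; nonsig <- 0L
  for (t in seq_len(n_repeats)) {
    fold <- sample(rep_len(seq_len(n_folds), length(ids)))
    for (f in seq_len(n_folds)) {
      test <- ids[fold == f]; train <- ids[fold != f]
      fit <- fit_gblup(y[train], U)
      if (!fit$converged) { rhos <- c(rhos, NA); miss <- miss + 1L; next }
      if (fit$lrt_p > 0.05) nonsig <- nonsig + 1L
      pred <- predict_unphenotyped(fit, U, train, test, y)
      rhos <- c(rhos, prediction_accuracy(pred, y[test], h2))
    }
  }
  list(rho = mean(rhos, na.rm = TRUE), n_missing = miss, nonsig = nonsig)
}

#' Within-population cross-validation
#'
#' For each outer replicate, samples `n_lines` entries without replacement
#' (and/or `n_markers` markers), then runs `n_repeats` x `n_folds`-fold
#' cross-validation (defaults 10 x 5) with GBLUP, recording the mean
#' prediction accuracy per replicate.  Non-converged fits are recorded as
#' missing; fits with a non-significant genomic variance (LRT p > 0.05)
#' are counted per replicate.  Default replicate count is 100.
#'
#' @param population_data list with `geno` (entries x markers dosage
#'   matrix with rownames), `y` (named BLUEs), `h2` (entry-mean
#'   heritability of the population).
#' @param n_lines entries per replicate (`NULL` = all; minimum 10).
#' @param n_markers markers per replicate (`NULL` = all).
#' @param reps outer sampling replicates.
#' @param seed integer seed.
#' @param n_folds,n_repeats CV geometry.
#' @return a `cv_result`.
#' @export
cv_within <- function(population_data, n_lines = NULL, n_markers = NULL,
                      reps = 100, seed = NULL, n_folds = 5, n_repeats = 10) {
  geno <- population_data$geno; y <- population_data$y
  h2 <- population_data$h2
  ids <- rownames(geno)
  n_lines <- n_lines %||% length(ids)
  if (n_lines < 10) stop_gc("n_lines must be >= 10 for 5-fold CV")
  if (n_lines > length(ids)) stop_gc("n_lines exceeds population size")
  child <- split_seed(seed %||% 1L, reps)
  rows <- vector("list", reps)
  for (rr in seq_len(reps)) {
    rows[[rr]] <- with_seed(child[rr], {
      sel <- sample(ids, n_lines)
      g <- geno[sel, , drop = FALSE]
      if (!is.null(n_markers)) {
        g <- g[, sample.int(ncol(g), min(n_markers, ncol(g))), drop = FALSE]
      }
      res <- run_cv_folds(g, y[sel], h2, n_folds, n_repeats)
      data.frame(rep = rr, rho = res$rho, n_missing = res$n_missing,
                 nonsig = res$nonsig)
    })
  }
  new_cv_result(sprintf("within-population CV (N = %d, M = %s, %dx%d-fold)",
                        n_lines, n_markers %||% ncol(geno), n_repeats, n_folds),
                do.call(rbind, rows), reps)
}

#' Across-population / across-landrace prediction
#'
#' Per replicate, `n_train` lines are sampled from the training population
#' and a disjoint set of `n_predict` lines from the prediction population
#' (the same population gives the paper's disjoint within-population
#' scenario; a different population of the same or another landrace gives
#' the across-population and across-landrace scenarios).  Defaults are the
#' per se configuration `n_train = 200`, `n_predict = 50` (use 75/25 for
#' testcross data) with 100 replicates.  The relationship matrix is built
#' over the union of both entry sets with combined allele frequencies.
#'
#' @param train_population,predict_population lists as in [cv_within()]
#'   (`geno`, `y`, `h2`); `predict_population$h2` enters the accuracy.
#' @param n_train,n_predict sample sizes.
#' @param reps replicates.
#' @param seed integer seed.
#' @param level label only (`"PP"` or `"TP"`).
#' @return a `cv_result`.
#' @export
cv_across <- function(train_population, predict_population, n_train = 200,
                      n_predict = 50, reps = 100, seed = NULL, level = "PP") {
  same <- identical(rownames(train_population$geno),
                    rownames(predict_population$geno))
  tr_ids <- rownames(train_population$geno)
  pr_ids <- rownames(predict_population$geno)
  if (same && n_train + n_predict > length(tr_ids)) {
    stop_gc("n_train + n_predict exceeds the population size")
  }
  if (n_train > length(tr_ids) || n_predict > length(pr_ids)) {
    stop_gc("insufficient entries")
  }
  child <- split_seed(seed %||% 1L, reps)
  rows <- vector("list", reps)
  for (rr in seq_len(reps)) {
    rows[[rr]] <- with_seed(child[rr], {
      tr <- sample(tr_ids, n_train)
      pr <- if (same) sample(setdiff(pr_ids, tr), n_predict)
            else sample(pr_ids, n_predict)
      g_tr <- train_population$geno[tr, , drop = FALSE]
      g_pr <- predict_population$geno[pr, , drop = FALSE]
      rownames(g_pr) <- paste0("pred_", pr)   # guard against id clashes
      gg <- rbind(g_tr, g_pr)
      U <- vanraden_g(gg)
      fit <- fit_gblup(train_population$y[tr], U)
      if (!fit$converged) {
        data.frame(rep = rr, rho = NA_real_, n_missing = 1L, nonsig = 0L)
      } else {
        pred <- predict_unphenotyped(fit, U, tr, paste0("pred_", pr),
                                     train_population$y)
        rho <- prediction_accuracy(pred, predict_population$y[pr],
                                   predict_population$h2)
        data.frame(rep = rr, rho = rho, n_missing = 0L,
                   nonsig = as.integer(fit$lrt_p > 0.05))
      }
    })
  }
  new_cv_result(sprintf("across prediction (%s, N = %d -> %d)",
                        level, n_train, n_predict),
                do.call(rbind, rows), reps)
}

#' Combined-population training
#'
#' Pools training lines across populations and predicts within each
#' population, reporting the combined accuracy next to the
#' within-population baseline at the same training size per population.
#'
#' @param populations named list (>= 2) of population data lists (`geno`,
#'   `y`, `h2`).
#' @param n_train training lines drawn from each population.
#' @param n_predict prediction lines per target population.
#' @param reps replicates.
#' @param seed integer seed.
#' @return data.frame with one row per target population: mean baseline
#'   and combined accuracies; attribute `results` holds the `cv_result`
#'   pair per population.
#' @export
cv_combined <- function(populations, n_train = 200, n_predict = 50,
                        reps = 100, seed = NULL) {
  if (length(populations) < 2) stop_gc("need >= 2 populations")
  child <- split_seed(seed %||% 1L, length(populations) * 2L)
  out <- list(); details <- list()
  k <- 0L
  for (target in names(populations)) {
    tp <- populations[[target]]
    others <- populations[names(populations) != target]
    k <- k + 1L
    baseline <- cv_across(tp, tp, n_train, n_predict, reps, seed = child[k])
    k <- k + 1L
    combined <- with_seed(child[k], {
      rows <- vector("list", reps)
      sub_child <- sample.int(.Machine$integer.max - 1L, reps)
      for (rr in seq_len(reps)) {
        rows[[rr]] <- with_seed(sub_child[rr], {
          pr <- sample(rownames(tp$geno), n_predict)
          tr_t <- sample(setdiff(rownames(tp$geno), pr),
                         min(n_train, nrow(tp$geno) - n_predict))
          g_list <- list(tp$geno[tr_t, , drop = FALSE])
          y_tr <- tp$y[tr_t]
          for (nm in names(others)) {
            o <- others[[nm]]
            tr_o <- sample(rownames(o$geno), min(n_train, nrow(o$geno)))
            go <- o$geno[tr_o, , drop = FALSE]
            rownames(go) <- paste0(nm, "_", tr_o)
            g_list[[length(g_list) + 1L]] <- go
            y_tr <- c(y_tr, stats::setNames(o$y[tr_o], paste0(nm, "_", tr_o)))
          }
          gg <- do.call(rbind, c(g_list, list(tp$geno[pr, , drop = FALSE])))
          U <- vanraden_g(gg)
          tr_all <- setdiff(rownames(gg), pr)
          fit <- fit_gblup(y_tr[tr_all], U)
          if (!fit$converged) {
            data.frame(rep = rr, rho = NA_real_, n_missing = 1L, nonsig = 0L)
          } else {
            pred <- predict_unphenotyped(fit, U, tr_all, pr, y_tr)
            data.frame(rep = rr,
                       rho = prediction_accuracy(pred, tp$y[pr], tp$h2),
                       n_missing = 0L,
                       nonsig = as.integer(fit$lrt_p > 0.05))
          }
        })
      }
      new_cv_result(sprintf("combined training -> %s", target),
                    do.call(rbind, rows), reps)
    })
    out[[target]] <- data.frame(population = target,
                                baseline_rho = baseline$mean_rho,
                                combined_rho = combined$mean_rho,
                                stringsAsFactors = FALSE)
    details[[target]] <- list(baseline = baseline, combined = combined)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "results") <- details
  res
}
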