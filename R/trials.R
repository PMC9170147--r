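# Multi-environment replicated field trials: simulation, variance
# components (REML / closed-form ANOVA for balanced designs), BLUEs,
# entry-mean heritability, significance rule, PP-TP genetic correlation.

#' Simulate a multi-environment replicated trial
#'
#' Plot phenotypes follow
#' `y = mu + g_entry + env + (g x env) + error`, with Gaussian environment
#' main effects, genotype-by-environment deviations and plot errors.  When
#' `target_h2` is given, the error and g-by-e variances are back-solved
#' from the entry-mean heritability
#' `h2 = s2_g / (s2_g + s2_ge/E + s2_e/(E R))` using the realized genetic
#' variance of `genotypic_values` and the fixed ratio
#' `s2_ge = ge_ratio * s2_e` (default 0.5); alternatively pass `sigma2_ge`
#' and `sigma2_e` explicitly.
#'
#' @param genotypic_values named numeric vector of true entry values
#'   (names become entry ids).
#' @param E,R number of environments and replicates (defaults 4 and 2, the
#'   per se trial design).
#' @param target_h2 entry-mean heritability in (0, 1].
#' @param sigma2_ge,sigma2_e explicit variance components (override
#'   `target_h2`).
#' @param ge_ratio ratio s2_ge / s2_e used when back-solving.
#' @param sigma2_env variance of environment main effects (nuisance;
#'   default equal to the genetic variance).
#' @param population optional population tag per entry (recycled).
#' @param seed integer seed.
#' @return `trial_data`: long data.frame (entry, population, env, rep,
#'   value) with attribute `truth` (generating components and values).
#' @export
simulate_trials <- function(genotypic_values, E = 4, R = 2, target_h2 = NULL,
                            sigma2_ge = NULL, sigma2_e = NULL, ge_ratio = 0.5,
                            sigma2_env = NULL, population = "POP", seed = NULL) {
  n <- length(genotypic_values)
  if (E < 1 || R < 1) stop_gc("E and R must be >= 1")
  ids <- names(genotypic_values) %||% sprintf("entry_%04d", seq_len(n))
  if (is.null(names(genotypic_values))) names(genotypic_values) <- ids
  s2g <- stats::var(genotypic_values)
  if (is.null(sigma2_e)) {
    if (is.null(target_h2)) stop_gc("give target_h2 or explicit variances")
    if (target_h2 <= 0 || target_h2 > 1) stop_gc("target_h2 must be in (0, 1]")
    rhs <- s2g * (1 / target_h2 - 1)
    sigma2_e <- rhs / (ge_ratio / E + 1 / (E * R))
    sigma2_ge <- ge_ratio * sigma2_e
  }
  sigma2_ge <- sigma2_ge %||% 0
  if (sigma2_e < 0 || sigma2_ge < 0) stop_gc("infeasible variance configuration")
  sigma2_env <- sigma2_env %||% s2g
  population <- rep_len(population, n)
  with_seed(seed, {
    env_eff <- stats::rnorm(E, 0, sqrt(sigma2_env))
    ge <- matrix(stats::rnorm(n * E, 0, sqrt(sigma2_ge)), n, E)
    df <- expand.grid(entry = ids, env = sprintf("env%d", seq_len(E)),
                      rep = seq_len(R), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
    i <- match(df$entry, ids)
    j <- as.integer(sub("env", "", df$env))
    df$population <- population[i]
    df$value <- genotypic_values[i] + env_eff[j] + ge[cbind(i, j)] +
      stats::rnorm(nrow(df), 0, sqrt(sigma2_e))
    df <- df[, c("entry", "population", "env", "rep", "value")]
    attr(df, "truth") <- list(genotypic_values = genotypic_values,
                              sigma2_g = s2g, sigma2_ge = sigma2_ge,
                              sigma2_e = sigma2_e, E = E, R = R)
    class(df) <- c("trial_data", "data.frame")
    df
  })
}

# closed-form ANOVA/EMS estimates for a balanced entry x env x rep layout;
# equal to REML in the interior of the parameter space
anova_components <- function(df) {
  n <- length(unique(df$entry)); E <- length(unique(df$env))
  R <- nrow(df) / (n * E)
  gmean <- mean(df$value)
  m_i <- tapply(df$value, df$entry, mean)
  m_j <- tapply(df$value, df$env, mean)
  m_ij <- tapply(df$value, list(df$entry, df$env), mean)
  ss_g <- E * R * sum((m_i - gmean)^2)
  ss_e <- n * R * sum((m_j - gmean)^2)
  ss_ge <- R * sum((m_ij - outer(m_i, rep(1, E)) -
                      outer(rep(1, n), m_j) + gmean)^2)
  ss_err <- sum((df$value - m_ij[cbind(df$entry, df$env)])^2)
  df_g <- n - 1; df_ge <- (n - 1) * (E - 1); df_err <- n * E * (R - 1)
  ms <- c(g = ss_g / df_g, ge = ss_ge / df_ge,
          err = if (df_err > 0) ss_err / df_err else NA_real_)
  if (df_err == 0) {  # R = 1: g x e and error confounded
    ms[["err"]] <- 0
    df_err <- 1
  }
  A <- rbind(sigma2_g  = c(1 / (E * R), -1 / (E * R), 0),
             sigma2_ge = c(0, 1 / R, -1 / R),
             sigma2_e  = c(0, 0, 1))
  est <- as.numeric(A %*% ms)
  names(est) <- rownames(A)
  vms <- diag(2 * ms^2 / c(df_g, df_ge, df_err))
  V <- A %*% vms %*% t(A)
  dimnames(V) <- list(rownames(A), rownames(A))
  truncated <- est < 0
  est[truncated] <- 0
  list(est = est, se = sqrt(diag(V)), vcov = V, truncated = truncated,
       loglik = NA_real_, converged = TRUE, method = "anova_ems",
       E = E, R = R, n = n)
}

# iterative REML via lme4 for unbalanced layouts
lmer_components <- function(df) {
  n <- length(unique(df$entry)); E <- length(unique(df$env))
  fit <- tryCatch(
    lme4::lmer(value ~ env + (1 | entry) + (1 | entry:env), data = df,
               REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore")),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(est = c(sigma2_g = NA, sigma2_ge = NA, sigma2_e = NA),
                se = rep(NA_real_, 3), vcov = NULL, truncated = rep(FALSE, 3),
                loglik = NA_real_, converged = FALSE, method = "reml_lme4",
                E = E, R = round(nrow(df) / (n * E)), n = n))
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  est <- c(sigma2_g = vc$vcov[vc$grp == "entry"],
           sigma2_ge = vc$vcov[vc$grp == "entry:env"],
           sigma2_e = vc$vcov[vc$grp == "Residual"])
  conv <- length(fit@optinfo$conv$lme4$messages) == 0
  list(est = est, se = rep(NA_real_, 3), vcov = NULL,
       truncated = est <= 1e-10, loglik = as.numeric(stats::logLik(fit)),
       converged = conv, method = "reml_lme4",
       E = E, R = round(nrow(df) / (n * E)), n = n, fit = fit)
}

is_balanced <- function(df) {
  tab <- table(df$entry, df$env)
  length(unique(as.vector(tab))) == 1 && all(tab > 0)
}

#' REML variance components and BLUEs from trial data
#'
#' Fits the random-genotype model `value ~ env + genotype + genotype:env +
#' error` per population tag: balanced layouts use the closed-form
#' ANOVA/expected-mean-squares solution (identical to REML in the interior
#' of the parameter space, with standard errors from the mean-square
#' chi-square approximation); unbalanced layouts use iterative REML
#' (lme4).  Negative method-of-moments components are truncated at zero
#' and flagged.  BLUEs come from the fixed-genotype refit
#' `value ~ 0 + entry + env`, averaged over environments, fitted jointly
#' across populations.
#'
#' @param trial_data a `trial_data` long data.frame (entry, population,
#'   env, rep, value).
#' @return a `trial_fit`: list with `components` (per-population
#'   data.frame of estimates, SEs, flags), `vcov` (per-population
#'   component covariance when available), `blues` (entry, population,
#'   blue), `E`, `R`.
#' @export
fit_variance_components <- function(trial_data) {
  df <- as.data.frame(trial_data)
  if (length(unique(df$env)) < 2) {
    stop_gc("need >= 2 environments to separate g x e from error")
  }
  pops <- unique(df$population)
  comp_rows <- list(); vcovs <- list()
  for (pp in pops) {
    sub <- df[df$population == pp, ]
    res <- if (is_balanced(sub)) anova_components(sub) else lmer_components(sub)
    comp_rows[[pp]] <- data.frame(
      population = pp,
      component = names(res$est),
      estimate = as.numeric(res$est),
      se = res$se,
      truncated = res$truncated,
      stringsAsFactors = FALSE)
    vcovs[[pp]] <- res$vcov
    attr(comp_rows[[pp]], "meta") <- res[c("method", "converged", "E", "R", "n")]
  }
  meta <- lapply(comp_rows, attr, "meta")
  components <- do.call(rbind, comp_rows)
  rownames(components) <- NULL
  # joint fixed-genotype refit for BLUEs
  df$entry <- factor(df$entry); df$env <- factor(df$env)
  lmfit <- stats::lm(value ~ 0 + entry + env, data = df)
  cf <- stats::coef(lmfit)
  env_terms <- cf[grepl("^env", names(cf))]
  env_adj <- sum(c(0, env_terms), na.rm = TRUE) / nlevels(df$env)
  blue <- cf[paste0("entry", levels(df$entry))] + env_adj
  blues <- data.frame(entry = levels(df$entry),
                      population = df$population[match(levels(df$entry), df$entry)],
                      blue = as.numeric(blue), stringsAsFactors = FALSE)
  structure(list(components = components, vcov = vcovs, blues = blues,
                 meta = meta,
                 E = length(unique(df$env)),
                 R = round(nrow(df) / (nlevels(df$entry) * length(unique(df$env))))),
            class = "trial_fit")
}

#' @export
print.trial_fit <- function(x, ...) {
  cat("Trial analysis:", length(x$meta), "population(s),",
      nrow(x$blues), "entries, E =", x$E, ", R =", x$R, "\n")
  print(x$components, digits = 4)
  invisible(x)
}

#' @export
summary.trial_fit <- function(object, ...) {
  h <- lapply(names(object$meta), function(pp) {
    entry_mean_heritability(object, population = pp)
  })
  names(h) <- names(object$meta)
  out <- list(fit = object, h2 = h)
  class(out) <- "summary.trial_fit"
  out
}

#' @export
print.summary.trial_fit <- function(x, ...) {
  print(x$fit)
  for (pp in names(x$h2)) {
    h <- x$h2[[pp]]
    cat(sprintf("  %s: h2 = %.3f (SE %.3f)%s\n", pp, h[["h2"]], h[["se"]],
                if (significance_by_2se(h[["h2"]], h[["se"]])) " *" else ""))
  }
  invisible(x)
}

#' Entry-mean heritability with delta-method SE
#'
#' `h2 = s2_g / (s2_g + s2_ge/E + s2_e/(E R))`; the SE propagates the
#' covariance matrix of the component estimates through the gradient of
#' this ratio (delta method).
#'
#' @param components a `trial_fit` (use `population` to pick the tag), or
#'   a named numeric vector with `sigma2_g`, `sigma2_ge`, `sigma2_e`.
#' @param E,R design dimensions (taken from the fit when available).
#' @param vcov optional 3x3 covariance matrix of the components.
#' @param population population tag when `components` is a `trial_fit`.
#' @return named vector `c(h2 =, se =)`; `h2` is `NA` (flagged undefined)
#'   when all components are zero.
#' @export
entry_mean_heritability <- function(components, E = NULL, R = NULL,
                                    vcov = NULL, population = NULL) {
  if (inherits(components, "trial_fit")) {
    fit <- components
    population <- population %||% fit$components$population[1]
    sub <- fit$components[fit$components$population == population, ]
    est <- stats::setNames(sub$estimate, sub$component)
    vcov <- vcov %||% fit$vcov[[population]]
    E <- E %||% fit$meta[[population]]$E
    R <- R %||% fit$meta[[population]]$R
    components <- est
  }
  sg <- components[["sigma2_g"]]; sge <- components[["sigma2_ge"]]
  se_ <- components[["sigma2_e"]]
  if (E < 1 || R < 1) stop_gc("E and R must be >= 1")
  D <- sg + sge / E + se_ / (E * R)
  if (!is.finite(D) || D <= 0) return(c(h2 = NA_real_, se = NA_real_))
  h2 <- sg / D
  se_h2 <- NA_real_
  if (!is.null(vcov)) {
    grad <- c((sge / E + se_ / (E * R)) / D^2, -sg / (E * D^2),
              -sg / (E * R * D^2))
    se_h2 <- sqrt(drop(t(grad) %*% vcov %*% grad))
  }
  c(h2 = h2, se = se_h2)
}

#' Two-standard-error significance rule
#'
#' An estimate is declared significant when it exceeds twice its standard
#' error.
#'
#' @param estimate,SE numeric (vectorized).
#' @return logical.
#' @export
significance_by_2se <- function(estimate, SE) {
  if (any(SE < 0, na.rm = TRUE)) stop_gc("SE must be >= 0")
  !is.na(estimate) & !is.na(SE) & estimate > 2 * SE
}

#' Genetic correlation between per se and testcross performance
#'
#' Pearson correlation of the estimated genetic values (BLUEs) of entries
#' evaluated at both levels, with an optional attenuation-corrected
#' estimate `r / sqrt(h2_pp * h2_tp)` clipped to `[-1, 1]`.
#'
#' @param blues_pp,blues_tp named numeric vectors of BLUEs (or data.frames
#'   with `entry` and `blue` columns).
#' @param h2_pp,h2_tp entry-mean heritabilities for the correction
#'   (optional).
#' @return list with `r`, `r_corrected`, `n`.
#' @export
pp_tp_genetic_correlation <- function(blues_pp, blues_tp, h2_pp = NULL,
                                      h2_tp = NULL) {
  as_named <- function(x) {
    if (is.data.frame(x)) stats::setNames(x$blue, x$entry) else x
  }
  bp <- as_named(blues_pp); bt <- as_named(blues_tp)
  common <- intersect(names(bp), names(bt))
  if (length(common) < 3) stop_gc("need >= 3 common entries")
  r <- stats::cor(bp[common], bt[common])
  rc <- NA_real_
  if (!is.null(h2_pp) && !is.null(h2_tp)) {
    rc <- max(-1, min(1, r / sqrt(h2_pp * h2_tp)))
  }
  list(r = r, r_corrected = rc, n = length(common))
}
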